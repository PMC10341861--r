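random_cpg_fixture <- function(n_sites = 50L, n_case = 3L, n_ctrl = 3L,
                               cov_max = 12L) {
  n <- n_case + n_ctrl
  cov <- matrix(sample(0:cov_max, n_sites * n, replace = TRUE), n_sites, n)
  meth <- matrix(rbinom(n_sites * n, as.vector(cov), 0.5), n_sites, n)
  colnames(cov) <- colnames(meth) <- sprintf("s%d", seq_len(n))
  make_cpg(chrom = rep("chr1", n_sites),
           pos = sort(sample.int(1e6, n_sites)),
           meth = meth, cov = cov,
           group = rep(c("case", "control"), c(n_case, n_ctrl)))
}

test_that("coverage filter applies the 6x / 50%-of-both-groups rule", {
  grp <- rep(c("case", "control"), c(11, 13))
  cov <- matrix(10L, 3, 24)
  cov[2, 1:6] <- 2L          # 5/11 case samples adequate (45%) -> dropped
  cov[3, 12:24] <- 3L        # all controls inadequate -> dropped
  meth <- matrix(1L, 3, 24)
  colnames(cov) <- colnames(meth) <- sprintf("s%02d", 1:24)
  cpg <- make_cpg(rep("chr1", 3), c(10L, 20L, 30L), meth, cov, grp)
  filt <- filter_cpg_coverage(cpg)
  expect_equal(filt$sites$pos, 10L)
  expect_error(
    filter_cpg_coverage(make_cpg("chr1", 1L, matrix(0L, 1, 24),
                                 matrix(1L, 1, 24), grp)),
    "no CpG sites survive")
})

test_that("coverage filter matches the brute-force oracle on random fixtures", {
  set.seed(401)
  for (rep in 1:5) {
    cpg <- random_cpg_fixture()
    oracle <- bf_filter(cpg$cov, cpg$group)
    if (!any(oracle$keep)) next
    filt <- filter_cpg_coverage(cpg)
    expect_equal(filt$sites$pos, cpg$sites$pos[oracle$keep])
    # zeroing: sub-coverage entries treated as missing
    expect_true(all(filt$cov[filt$cov > 0] >= 6))
    kept_cov <- cpg$cov[oracle$keep, , drop = FALSE]
    kept_cov[oracle$zeroed[oracle$keep, , drop = FALSE]] <- 0L
    expect_equal(filt$cov, kept_cov)
  }
})

test_that("identity 'permutation' reproduces the observed region statistic", {
  set.seed(402)
  cfg <- small_config(seed = 402L)
  m <- simulate_methylation(cfg)
  filt <- filter_cpg_coverage(m$cpg)
  beta_z <- filt$meth / filt$cov
  beta_z[filt$cov == 0] <- 0
  has <- (filt$cov > 0) + 0
  ind <- as.numeric(filt$group == "case")
  d1 <- dmrlinc:::site_group_diff(beta_z, has, ind)
  # identity relabeling computed the naive way must reproduce it exactly
  beta_na <- filt$meth / filt$cov
  beta_na[filt$cov == 0] <- NA
  d2 <- rowMeans(beta_na[, filt$group == "case"], na.rm = TRUE) -
    rowMeans(beta_na[, filt$group == "control"], na.rm = TRUE)
  d2[is.nan(d2)] <- NA
  expect_equal(d1, unname(d2))
  w <- rowSums(filt$cov)
  sm <- dmrlinc:::running_mean(d1, 5L)
  r1 <- dmrlinc:::find_candidate_regions(filt$sites, sm, d1, w, 0.1,
                                         1000L, 5L)
  r2 <- dmrlinc:::find_candidate_regions(filt$sites, sm, d2, w, 0.1,
                                         1000L, 5L)
  expect_identical(r1$stat, r2$stat)
})

test_that("a single planted DMR is recovered with q < 0.05", {
  set.seed(403)
  cfg <- sim_config(n_case = 11L, n_control = 13L, genome = c(chr1 = 12e6),
                    n_cpg = 1000L, n_planted_dmrs = 1L, delta_beta = 0.3,
                    n_lnc_linked = 0L, n_prot_linked = 0L,
                    n_lnc_decoy = 0L, n_prot_decoy = 0L, seed = 403L)
  m <- simulate_methylation(cfg)
  filt <- filter_cpg_coverage(m$cpg)
  dmrs <- call_dmrs(filt, n_perm = 100L)
  rec <- region_recovery(dmrs[dmrs$significant == TRUE, ], m$true_dmrs)
  expect_true(all(rec$recovered))
})

test_that("caller refuses groups with too few distinct permutations", {
  cpg <- make_cpg(rep("chr1", 4), c(1L, 2L, 3L, 4L),
                  matrix(3L, 4, 4), matrix(6L, 4, 4),
                  rep(c("case", "control"), each = 2))  # choose(4,2) = 6 < 10
  expect_error(call_dmrs(cpg), "permutations")
})

test_that("region beta means are exact and match the brute-force oracle", {
  cov <- matrix(c(10L, 10L, 10L, 10L), 2, 2)
  meth <- matrix(c(8L, 2L, 8L, 6L), 2, 2)
  colnames(cov) <- colnames(meth) <- c("a", "b")
  cpg <- make_cpg(rep("chr1", 2), c(100L, 120L), meth, cov,
                  c("case", "control"))
  one <- region_beta_matrix(cpg, data.table::data.table(
    chrom = "chr1", start = 99L, end = 100L, dmr_id = "r1"))
  expect_equal(unname(one["r1", "a"]), 0.8)
  both <- region_beta_matrix(cpg, data.table::data.table(
    chrom = "chr1", start = 90L, end = 130L, dmr_id = "r2"))
  expect_equal(unname(both["r2", "b"]), mean(c(0.8, 0.6)))
  # random fixture vs oracle
  set.seed(404)
  for (rep in 1:3) {
    cpgr <- random_cpg_fixture(n_sites = 40L)
    regions <- data.table::data.table(
      chrom = "chr1",
      start = sort(sample.int(9e5, 4L)))
    regions$end <- regions$start + sample.int(2e5, 4L)
    regions$dmr_id <- paste0("r", 1:4)
    got <- suppressWarnings(region_beta_matrix(cpgr, regions))
    want <- bf_region_beta(cpgr$sites, cpgr$meth, cpgr$cov, regions)
    want <- want[rownames(got), , drop = FALSE]
    expect_equal(got, want, tolerance = 1e-12)
    expect_true(all(got >= 0 & got <= 1, na.rm = TRUE))
  }
})

test_that("direction classification is consistent with the caller's sign", {
  beta <- rbind(r1 = c(0.7, 0.7, 0.3, 0.3), r2 = c(0.3, 0.3, 0.7, 0.7))
  grp <- c("case", "case", "control", "control")
  expect_equal(unname(classify_direction(beta, grp)), c("hyper", "hypo"))
  expect_warning(classify_direction(rbind(r = c(0.5, 0.5)), c("case", "control")),
                 "tie")
  # cross-operation consistency on simulated data
  set.seed(405)
  cfg <- small_config(seed = 405L)
  m <- simulate_methylation(cfg)
  filt <- filter_cpg_coverage(m$cpg)
  dmrs <- call_dmrs(filt, n_perm = 30L)
  if (nrow(dmrs)) {
    beta <- region_beta_matrix(filt, dmrs)
    dir <- classify_direction(beta[dmrs$dmr_id, , drop = FALSE],
                              filt$group)
    expect_equal(unname(dir), dmrs$direction)
    expect_equal(unname(dir == "hyper"), dmrs$stat > 0)
  }
})

test_that("recovery is monotone in the planted effect size", {
  deltas <- c(0.1, 0.2, 0.3)
  rates <- vapply(deltas, function(db) {
    hits <- vapply(1:20, function(r) {
      set.seed(1000L + r)   # common random numbers across effect sizes
      cfg <- sim_config(n_case = 6L, n_control = 6L,
                        genome = c(chr1 = 12e6), n_cpg = 600L,
                        n_planted_dmrs = 3L, delta_beta = db,
                        n_lnc_linked = 0L, n_prot_linked = 0L,
                        n_lnc_decoy = 0L, n_prot_decoy = 0L, seed = 1L)
      m <- simulate_methylation(cfg)
      filt <- filter_cpg_coverage(m$cpg)
      dmrs <- call_dmrs(filt, n_perm = 50L)
      rec <- region_recovery(dmrs[dmrs$significant == TRUE, ],
                             m$true_dmrs)
      mean(rec$recovered)
    }, numeric(1))
    mean(hits)
  }, numeric(1))
  expect_true(all(diff(rates) >= 0))
})
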