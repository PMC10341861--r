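test_that("probe mapping uses half-open DMR intervals and reports the fraction", {
  ref <- data.table::data.table(
    locus_id = c("p1", "p2", "p3"), chrom = "chr1",
    pos = c(150L, 200L, 5000L),
    epithelial = c(0.9, 0.1, 0.5), fibroblast = c(0.2, 0.8, 0.5),
    immune = c(0.1, 0.3, 0.5))
  dmrs <- data.table::data.table(
    dmr_id = c("d1", "d2"), chrom = "chr1",
    start = c(100L, 100L), end = c(200L, 120L))
  m <- map_regions_to_probes(dmrs[1], ref)
  expect_equal(m$mapping$locus_id, "p1")   # pos 150 inside [100,200);
  expect_equal(m$mapped_fraction, 1)       # pos 200 excluded (half-open)
  m2 <- map_regions_to_probes(dmrs, ref)
  expect_equal(m2$mapped_fraction, 0.5)    # d2 = [100,120) covers no probe
  # several probes in one DMR: first by coordinate wins, with a warning
  wide <- data.table::data.table(dmr_id = "dw", chrom = "chr1",
                                 start = 100L, end = 6000L)
  expect_warning(mw <- map_regions_to_probes(wide, ref), "several")
  expect_equal(mw$mapping$locus_id, "p1")
  expect_error(map_regions_to_probes(
    data.table::data.table(dmr_id = "dx", chrom = "chr9",
                           start = 1L, end = 2L), ref),
    "impossible")
})

test_that("constructive 70%-overlap reference maps ~70% of DMRs", {
  st <- default_study()
  ref <- dmrlinc::read_table(file.path(st$out_dir,
                                       "reference_profiles.tsv"))
  m <- map_regions_to_probes(st$meth$true_dmrs, ref)
  expect_equal(m$mapped_fraction,
               floor(0.7 * nrow(st$meth$true_dmrs)) /
                 nrow(st$meth$true_dmrs))
})

test_that("noiseless mixtures are recovered exactly", {
  set.seed(701)
  ref <- matrix(runif(300), 100, 3,
                dimnames = list(paste0("r", 1:100),
                                c("epithelial", "fibroblast", "immune")))
  mix <- cbind(ref %*% c(0.6, 0, 0.4), ref[, 1])
  dimnames(mix) <- list(rownames(ref), c("s1", "s2"))
  fr <- rpc_fractions(mix, ref)
  expect_equal(unname(fr["s1", ]), c(0.6, 0, 0.4), tolerance = 1e-6)
  expect_equal(unname(fr["s2", ]), c(1, 0, 0), tolerance = 1e-6)
  # noiseless recovery for arbitrary simplex weights
  w <- c(0.25, 0.7, 0.05)
  mix2 <- ref %*% w
  dimnames(mix2) <- list(rownames(ref), "s")
  expect_equal(unname(rpc_fractions(mix2, ref)["s", ]), w,
               tolerance = 1e-6)
})

test_that("noisy mixtures are recovered with small error; invariants hold", {
  set.seed(702)
  sim <- simulate_reference_mixtures(n_regions = 200L, n_samples = 20L,
                                     noise_sd = 0.02)
  refmat <- as.matrix(sim$reference[, c("epithelial", "fibroblast",
                                        "immune")])
  rownames(refmat) <- sim$reference$locus_id
  rownames(sim$mixtures) <- sim$reference$locus_id
  fr <- rpc_fractions(sim$mixtures, refmat)
  expect_lt(mean(abs(fr - sim$fractions)), 0.03)
  expect_true(all(fr >= 0))
  expect_equal(unname(rowSums(fr)), rep(1, 20), tolerance = 1e-9)
  # permuting cell-type columns permutes the output identically
  perm <- c(3, 1, 2)
  fr_perm <- rpc_fractions(sim$mixtures, refmat[, perm])
  expect_equal(fr_perm, fr[, perm])
})

test_that("singular references are refused", {
  ref <- matrix(runif(40), 20, 2)
  ref <- cbind(ref, ref[, 1] * 2)   # collinear third column
  colnames(ref) <- c("a", "b", "c")
  rownames(ref) <- paste0("r", 1:20)
  mix <- ref %*% c(0.5, 0.3, 0.2)
  dimnames(mix) <- list(rownames(ref), "s")
  expect_error(rpc_fractions(mix, ref), "collinear")
})

test_that("rank-sum statistic matches the brute-force U on a 6-sample fixture", {
  fr <- matrix(c(0.7, 0.5, 0.6, 0.2, 0.3, 0.2,
                 0.3, 0.5, 0.4, 0.8, 0.7, 0.8), 6, 2,
               dimnames = list(paste0("s", 1:6), c("immune", "epithelial")))
  grp <- rep(c("case", "control"), each = 3)
  res <- compare_fractions(fr, grp)
  expect_equal(res$statistic[res$cell_type == "immune"],
               bf_U(fr[1:3, "immune"], fr[4:6, "immune"]))
  expect_equal(res$statistic[res$cell_type == "epithelial"],
               bf_U(fr[1:3, "epithelial"], fr[4:6, "epithelial"]))
  expect_equal(res$direction, c("case>control", "case<control"))
})

test_that("group comparison: calibrated under the null, powered under a shift", {
  # null: exchangeable fractions should not produce systematically small p
  set.seed(703)
  small_p <- vapply(1:20, function(i) {
    e <- matrix(rexp(20 * 3), 20, 3)
    fr <- e / rowSums(e)
    colnames(fr) <- c("a", "b", "c")
    rownames(fr) <- paste0("s", 1:20)
    res <- compare_fractions(fr, rep(c("case", "control"), each = 10))
    min(res$pvalue)
  }, numeric(1))
  expect_lte(mean(small_p < 0.05), 0.35)  # ~3 tests/seed, Bonferroni-ish bound
  # immune-enriched case group recovered through the full rpc path
  set.seed(704)
  ref <- matrix(runif(600), 200, 3,
                dimnames = list(paste0("r", 1:200),
                                c("epithelial", "fibroblast", "immune")))
  w_ctrl <- c(0.4, 0.3, 0.3)
  w_case <- c(0.3, 0.2, 0.5)   # immune +0.2
  mk <- function(w, n, pre) {
    m <- ref %*% matrix(rep(w, n), 3, n) +
      matrix(rnorm(200 * n, 0, 0.02), 200, n)
    colnames(m) <- paste0(pre, 1:n)
    pmin(pmax(m, 0), 1)
  }
  mix <- cbind(mk(w_case, 10, "case"), mk(w_ctrl, 10, "ctrl"))
  rownames(mix) <- rownames(ref)
  fr <- rpc_fractions(mix, ref)
  res <- compare_fractions(fr, rep(c("case", "control"), each = 10))
  imm <- res[res$cell_type == "immune", ]
  expect_lt(imm$pvalue, 0.01)
  expect_equal(imm$direction, "case>control")
})
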