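test_that("interval distance: overlap, gap, cross-chromosome", {
  expect_equal(interval_distance("chr1", 100L, 200L, "chr1", 150L, 250L), 0L)
  expect_equal(interval_distance("chr1", 100L, 200L, "chr1", 250L, 300L), 50L)
  expect_equal(interval_distance("chr1", 250L, 300L, "chr1", 100L, 200L), 50L)
  expect_equal(interval_distance("chr1", 100L, 200L, "chr1", 200L, 300L), 0L)
  expect_true(is.na(interval_distance("chr1", 100L, 200L,
                                      "chr2", 100L, 200L)))
})

test_that("lncRNA-DMR pairing respects the 20 kb boundary", {
  dmr <- data.table::data.table(dmr_id = "d1", chrom = "chr1",
                                start = 100000L, end = 100300L)
  lnc <- data.table::data.table(
    transcript_id = c("in", "out"), chrom = "chr1",
    start = c(100300L + 19999L, 100300L + 20001L))
  lnc$end <- lnc$start + 1000L
  p <- pair_lnc_dmr(lnc, dmr, window = 20000L)
  expect_equal(p$lnc_transcript_id, "in")
  expect_equal(p$distance_bp, 19999L)
})

test_that("window pairing matches the brute-force all-pairs scan", {
  set.seed(601)
  rand_features <- function(n, prefix) {
    d <- data.table::data.table(
      id = paste0(prefix, seq_len(n)),
      chrom = sample(c("chr1", "chr2", "chr3"), n, replace = TRUE),
      start = sample.int(2e6, n))
    d$end <- d$start + sample.int(5000, n)
    d
  }
  for (rep in 1:3) {
    left <- rand_features(60, "L")
    right <- rand_features(60, "R")
    for (window in c(0L, 10000L, 200000L)) {
      got <- dmrlinc:::window_pairs(left, right, window)
      want <- bf_pairs(left, right, window)
      key <- function(d) sort(paste(d$left_id, d$right_id, d$distance_bp))
      expect_identical(key(got), key(want))
    }
  }
  # vectorized distance equals enumeration oracle case by case
  for (i in 1:200) {
    a <- c(sample(c("chr1", "chr2"), 1), sort(sample.int(1000, 2)))
    b <- c(sample(c("chr1", "chr2"), 1), sort(sample.int(1000, 2)))
    expect_identical(
      interval_distance(a[1], as.integer(a[2]), as.integer(a[3]),
                        b[1], as.integer(b[2]), as.integer(b[3])),
      bf_distance(a[1], as.integer(a[2]), as.integer(a[3]),
                  b[1], as.integer(b[2]), as.integer(b[3])))
  }
})

test_that("correlate: closed-form cases and permutation-oracle p-value", {
  expect_equal(correlate(1:4, 4:1), list(r = -1, pvalue = 0, n = 4L),
               ignore_attr = TRUE)
  expect_equal(correlate(1:4, 1:4)$r, 1)
  expect_equal(correlate(1:4, 1:4)$pvalue, 0)
  expect_warning(out <- correlate(c(1, 1, 1, 1), 1:4), "zero variance")
  expect_true(is.na(out$r))
  expect_equal(correlate(c(1, NA, 2), c(1, 2, 3))$n, 2L)
  expect_true(is.na(correlate(c(1, NA, 2), c(1, 2, 3))$r))
  # fixed 10-sample fixture: t-based p vs label permutation p
  set.seed(602)
  x <- c(0.1, 0.9, 0.4, 0.7, 0.2, 0.8, 0.3, 0.6, 0.55, 0.15)
  y <- -2 * x + rnorm(10, 0, 0.5)
  obs <- correlate(x, y)
  perm_r <- replicate(10000, cor(x, sample(y)))
  p_perm <- mean(abs(perm_r) >= abs(obs$r))
  expect_lt(abs(obs$pvalue - p_perm),
            0.02 + 3 * sqrt(p_perm * (1 - p_perm) / 10000))
})

test_that("negative-correlation filter keeps the sign rule", {
  s <- paste0("s", 1:10)
  set.seed(603)
  base <- runif(10)
  beta <- rbind(d_neg = base, d_pos = base)
  colnames(beta) <- s
  expr <- rbind(lnc_a = -base + rnorm(10, 0, 0.05),
                lnc_b = base + rnorm(10, 0, 0.05))
  colnames(expr) <- s
  pairs <- data.table::data.table(
    dmr_id = c("d_neg", "d_pos"),
    lnc_transcript_id = c("lnc_a", "lnc_b"),
    distance_bp = c(100L, 100L))
  de <- data.table::data.table(transcript_id = c("lnc_a", "lnc_b"),
                               log2fc = c(-1, 1))
  kept <- dmr_regulated_lncrnas(pairs, beta, expr, de)
  expect_equal(kept$lnc_transcript_id, "lnc_a")
  expect_true(kept$r_meth_lnc < 0 & kept$p_meth_lnc < 0.05)
  expect_equal(kept$lnc_de_direction, "down")
})

test_that("triplet invariants hold on the default study output", {
  r <- default_run()
  tr <- r$triplets
  expect_gt(nrow(tr), 0)
  expect_true(all(tr$r_meth_lnc < 0))
  expect_true(all(tr$p_meth_lnc < 0.05))
  expect_true(all(tr$r_lnc_prot < 0))
  expect_true(all(tr$p_lnc_prot < 0.05))
  expect_true(all(tr$dist_dmr_lnc <= 20000L))
  expect_true(all(tr$dist_lnc_prot <= 500000L))
  expect_true(all(tr$dmr_direction %in% c("hyper", "hypo")))
})

test_that("enlarging the windows never removes a triplet", {
  r <- default_run()
  ann <- r$annotation
  de_prot_ann <- ann[ann$transcript_id %in%
                       r$de_sets$protein_coding$transcript_id, ]
  de_lnc_ann <- ann[ann$transcript_id %in%
                      r$de_sets$lncRNA$transcript_id, ]
  trip_at <- function(w_lnc, w_prot) {
    pairs <- pair_lnc_dmr(de_lnc_ann, r$sig_dmrs, window = w_lnc)
    reg <- dmr_regulated_lncrnas(pairs, r$beta, r$norm, r$de)
    cands <- pair_lnc_protein(reg, de_prot_ann, ann, window = w_prot)
    lnc_protein_targets(cands, r$norm, reg, r$sig_dmrs)
  }
  small <- trip_at(8000L, 200000L)
  big <- trip_at(20000L, 500000L)
  key <- function(t) paste(t$dmr_id, t$lnc_transcript_id,
                           t$prot_transcript_id)
  expect_true(all(key(small) %in% key(big)))
})

test_that("hyper-DMR linked lncRNAs are predominantly down in cases", {
  r <- default_run()
  hyper <- r$reg_lnc[r$reg_lnc$dmr_id %in%
                       r$sig_dmrs$dmr_id[r$sig_dmrs$direction == "hyper"], ]
  expect_gt(nrow(hyper), 0)
  expect_gte(mean(hyper$lnc_de_direction == "down"), 0.8)
})

test_that("region report lists the features around each emitted DMR", {
  r <- default_run()
  rep_tab <- r$report
  expect_true(all(unique(r$triplets$dmr_id) %in% rep_tab$dmr_id))
  expect_true(all(rep_tab$feature_type %in%
                    c("lncRNA_transcript", "protein_transcript",
                      "other_transcript", "cpg_island", "tss")))
  # each triplet lncRNA appears in its own DMR's report window
  i <- 1L
  expect_true(any(rep_tab$dmr_id == r$triplets$dmr_id[i] &
                    rep_tab$feature_id == r$triplets$lnc_transcript_id[i]))
})
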