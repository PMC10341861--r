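# Coverage filtering, simplified permutation-based DMR calling, per-region
# beta summarization and hyper/hypo classification.
#
# The DMR caller is a deliberately simple substitute for smoothing-based
# WGBS callers: a running-mean smoothed group difference defines candidate
# regions, and significance comes from a genome-wide max-statistic label
# permutation null. Externally called regions can be supplied as BED to
# bypass this stage entirely.

#' Assemble per-sample cytosine tables into aligned site matrices
#'
#' Outer-joins the (chrom, pos) site sets of all samples; samples lacking a
#' site get zero coverage there.
#'
#' @param tables Named list of tables from [read_cytosine_report()].
#' @param group Character vector (`case`/`control`) aligned with `tables`,
#'   or named by sample id.
#' @return A list of class `cpg_matrix`: `sites` (data.table `chrom`,
#'   `pos`, sorted), `meth` and `cov` (sites x samples integer matrices)
#'   and `group`.
#' @export
build_cpg_matrix <- function(tables, group) {
  if (is.null(names(tables))) {
    names(tables) <- vapply(tables, function(t) {
      sid <- attr(t, "sample_id")
      if (is.null(sid)) stop("unnamed cytosine table without sample_id")
      sid
    }, character(1))
  }
  if (!is.null(names(group))) group <- group[names(tables)]
  stopifnot(length(group) == length(tables))
  sites <- unique(rbindlist(
    lapply(tables, function(t) t[, .(chrom, pos)])
  ))
  setkey(sites, chrom, pos)
  n <- nrow(sites)
  meth <- cov <- matrix(0L, n, length(tables),
                        dimnames = list(NULL, names(tables)))
  for (j in seq_along(tables)) {
    idx <- sites[tables[[j]], on = c("chrom", "pos"), which = TRUE]
    meth[idx, j] <- tables[[j]]$meth
    cov[idx, j] <- tables[[j]]$meth + tables[[j]]$unmeth
  }
  structure(list(sites = sites, meth = meth, cov = cov,
                 group = as.character(group)),
            class = "cpg_matrix")
}

#' Filter CpG sites on per-group coverage
#'
#' Samples with coverage below `min_cov` at a site have their counts zeroed
#' (treated as missing, not as 0% methylation). A site is retained iff the
#' fraction of samples with coverage at or above `min_cov` is at least
#' `min_frac` in the case group AND in the control group.
#'
#' @param cpg A `cpg_matrix` from [build_cpg_matrix()].
#' @param min_cov Minimum read coverage (default 6).
#' @param min_frac Minimum fraction of adequately covered samples per group
#'   (default 0.5).
#' @return A filtered `cpg_matrix` (sub-coverage entries zeroed).
#' @export
filter_cpg_coverage <- function(cpg, min_cov = 6L, min_frac = 0.5) {
  stopifnot(inherits(cpg, "cpg_matrix"))
  g <- cpg$group
  if (sum(g == "case") < 2L || sum(g == "control") < 2L) {
    stop("need at least 2 samples per group")
  }
  ok <- cpg$cov >= min_cov
  frac_case <- rowMeans(ok[, g == "case", drop = FALSE])
  frac_ctrl <- rowMeans(ok[, g == "control", drop = FALSE])
  keep <- frac_case >= min_frac & frac_ctrl >= min_frac
  if (!any(keep)) {
    stop("no CpG sites survive the coverage filter; ",
         "consider lowering min_cov or min_frac")
  }
  meth <- cpg$meth[keep, , drop = FALSE]
  cov <- cpg$cov[keep, , drop = FALSE]
  sub <- cov < min_cov
  meth[sub] <- 0L
  cov[sub] <- 0L
  structure(list(sites = cpg$sites[keep], meth = meth, cov = cov,
                 group = g),
            class = "cpg_matrix")
}

# centered running mean of width k with partial windows at the edges,
# NA-skipping
running_mean <- function(x, k = 5L) {
  h <- (k - 1L) %/% 2L
  v <- ifelse(is.na(x), 0, x)
  m <- as.numeric(!is.na(x))
  cs_v <- cumsum(v)
  cs_m <- cumsum(m)
  n <- length(x)
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  sum_v <- cs_v[hi] - c(0, cs_v)[lo]
  sum_m <- cs_m[hi] - c(0, cs_m)[lo]
  out <- sum_v / sum_m
  out[sum_m == 0] <- NA_real_
  out
}

# per-site group mean betas for a given case indicator (vectorized over
# permutations via matrix products)
site_group_diff <- function(beta_zeroed, has_beta, case_ind) {
  n_case_obs <- has_beta %*% case_ind
  n_ctrl_obs <- has_beta %*% (1 - case_ind)
  s_case <- beta_zeroed %*% case_ind
  s_ctrl <- beta_zeroed %*% (1 - case_ind)
  d <- s_case / n_case_obs - s_ctrl / n_ctrl_obs
  d[!is.finite(d)] <- NA_real_
  drop(d)
}

# candidate regions: maximal same-sign runs of CpGs with smoothed
# |d| > cutoff and inter-CpG gap <= max_gap, at least min_cpgs long.
# Because the running mean bleeds a strong signal into a couple of
# flanking CpGs, each run is trimmed to the first/last CpG whose RAW
# group difference also exceeds the cutoff with the run's sign; runs with
# fewer than min_cpgs raw-supported CpGs are dropped. Returns a
# data.table of (start_idx, end_idx, stat) over row indices of `sites`.
find_candidate_regions <- function(sites, d, d_raw, w, cutoff, max_gap,
                                   min_cpgs) {
  sgn <- sign(d)
  sgn[is.na(d) | abs(d) <= cutoff] <- 0
  new_chrom <- c(TRUE, sites$chrom[-1L] != sites$chrom[-nrow(sites)])
  gap_break <- c(TRUE, diff(sites$pos) > max_gap) | new_chrom
  sign_change <- c(TRUE, sgn[-1L] != sgn[-length(sgn)])
  run_start <- gap_break | sign_change
  run_id <- cumsum(run_start)
  ok <- sgn != 0
  empty <- data.table(start_idx = integer(), end_idx = integer(),
                      stat = numeric(), n_cpgs = integer())
  if (!any(ok)) return(empty)
  raw_ok <- !is.na(d_raw) & abs(d_raw) > cutoff & sign(d_raw) == sgn
  dt <- data.table(idx = which(ok), run_id = run_id[ok],
                   wd = (w * d)[ok], wt = w[ok], raw_ok = raw_ok[ok])
  # region statistic: coverage-weighted MEAN smoothed difference. An
  # additive sum would scale with region size, letting the genome-wide
  # max-statistic permutation null (dominated by the largest regions
  # under partially aligned label permutations) swamp smaller regions of
  # identical effect size; the weighted mean equalizes power across
  # region sizes.
  regs <- dt[, {
    supp <- idx[raw_ok]
    if (length(supp) == 0L) {
      list(start_idx = NA_integer_, end_idx = NA_integer_,
           stat = NA_real_, n_cpgs = 0L)
    } else {
      lo <- min(supp); hi <- max(supp)
      keep <- idx >= lo & idx <= hi
      list(start_idx = lo, end_idx = hi,
           stat = sum(wd[keep]) / sum(wt[keep]), n_cpgs = sum(keep))
    }
  }, by = run_id]
  regs <- regs[!is.na(start_idx) & n_cpgs >= min_cpgs]
  if (nrow(regs) == 0L) return(empty)
  regs[, .(start_idx, end_idx, stat, n_cpgs)]
}

#' Call differentially methylated regions by smoothed difference and
#' label permutation
#'
#' Per-site case-minus-control mean beta differences are smoothed by a
#' centered running mean over `k` neighboring CpGs within each chromosome.
#' Candidate regions are maximal same-sign runs with `|d| > cutoff`,
#' inter-CpG gaps at most `max_gap` bp and at least `min_cpgs` CpGs,
#' trimmed at both ends to CpGs whose raw (unsmoothed) difference also
#' exceeds the cutoff; the region statistic is the coverage-weighted
#' mean of the smoothed differences over the region's CpGs.
#' Significance uses a genome-wide max-statistic null: for each of `n_perm`
#' random group-label permutations the candidate search is re-run and the
#' maximum absolute region statistic recorded; each observed region's
#' p-value is the +1-smoothed fraction of permutation maxima at or above
#' its absolute statistic. Q-values are Benjamini-Hochberg over candidates.
#'
#' @param filtered A `cpg_matrix` from [filter_cpg_coverage()].
#' @param min_cpgs Minimum CpGs per region (default 5).
#' @param max_gap Maximum gap between consecutive region CpGs, bp (default
#'   1000).
#' @param cutoff Smoothed-difference magnitude defining candidate sites
#'   (default 0.1).
#' @param n_perm Number of label permutations (default 100).
#' @param k Running-mean width in CpGs (default 5).
#' @param q_cut Significance threshold on q-values (default 0.05); only
#'   stored in the `significant` column, all candidates are returned.
#' @return A `data.table` with one row per candidate region: `chrom`,
#'   `start`, `end` (0-based half-open), `dmr_id` (`<chrom>.<rank>`),
#'   `n_cpgs`, `stat`, `pvalue`, `qvalue`, `direction` (`hyper`/`hypo` in
#'   the case group), `significant`.
#' @export
call_dmrs <- function(filtered, min_cpgs = 5L, max_gap = 1000L,
                      cutoff = 0.1, n_perm = 100L, k = 5L, q_cut = 0.05) {
  stopifnot(inherits(filtered, "cpg_matrix"))
  g <- filtered$group
  n_case <- sum(g == "case")
  if (choose(length(g), n_case) < 10) {
    stop("groups too small: fewer than 10 distinct label permutations")
  }
  sites <- filtered$sites
  beta <- filtered$meth / filtered$cov   # NaN where cov == 0 (missing)
  has_beta <- (filtered$cov > 0) + 0
  beta_z <- beta
  beta_z[filtered$cov == 0] <- 0
  w <- rowSums(filtered$cov)
  chrom_rle <- rle(sites$chrom)
  smooth_by_chrom <- function(d) {
    unlist(lapply(split(d, rep(seq_along(chrom_rle$lengths),
                               chrom_rle$lengths)),
                  running_mean, k = k), use.names = FALSE)
  }
  case_ind <- as.numeric(g == "case")
  d_raw_obs <- site_group_diff(beta_z, has_beta, case_ind)
  d_obs <- smooth_by_chrom(d_raw_obs)
  obs <- find_candidate_regions(sites, d_obs, d_raw_obs, w, cutoff,
                                max_gap, min_cpgs)
  # permutation null: genome-wide max |stat| per permutation
  null_max <- numeric(n_perm)
  for (p in seq_len(n_perm)) {
    perm_ind <- sample(case_ind)
    d_raw_p <- site_group_diff(beta_z, has_beta, perm_ind)
    d_p <- smooth_by_chrom(d_raw_p)
    regs <- find_candidate_regions(sites, d_p, d_raw_p, w, cutoff,
                                   max_gap, min_cpgs)
    null_max[p] <- if (nrow(regs)) max(abs(regs$stat)) else 0
  }
  if (nrow(obs) == 0L) {
    return(data.table(chrom = character(), start = integer(),
                      end = integer(), dmr_id = character(),
                      n_cpgs = integer(), stat = numeric(),
                      pvalue = numeric(), qvalue = numeric(),
                      direction = character(), significant = logical()))
  }
  pvals <- vapply(abs(obs$stat),
                  function(s) (1 + sum(null_max >= s)) / (n_perm + 1),
                  numeric(1))
  out <- data.table(
    chrom = sites$chrom[obs$start_idx],
    start = sites$pos[obs$start_idx] - 1L,   # 1-based CpG -> 0-based interval
    end = sites$pos[obs$end_idx],
    n_cpgs = obs$n_cpgs,
    stat = obs$stat,
    pvalue = pvals
  )
  out[, qvalue := bh_adjust(pvalue)]
  out[, direction := ifelse(stat > 0, "hyper", "hypo")]
  setorder(out, chrom, start)
  out[, dmr_id := paste0(chrom, ".", seq_len(.N)), by = chrom]
  out[, significant := qvalue < q_cut]
  setcolorder(out, c("chrom", "start", "end", "dmr_id", "n_cpgs", "stat",
                     "pvalue", "qvalue", "direction", "significant"))
  out[]
}

#' Per-region, per-sample mean relative methylation (beta matrix)
#'
#' Entry (r, s) is the unweighted mean over the CpGs inside region r of
#' `meth / coverage` for sample s, skipping sites zeroed by the coverage
#' filter; `NA` if every site is missing for that sample. Regions with no
#' surviving CpGs are dropped with a warning.
#'
#' @param filtered A `cpg_matrix` from [filter_cpg_coverage()].
#' @param regions DMR table with `chrom`, `start`, `end`, `dmr_id`
#'   (0-based half-open intervals).
#' @return Numeric matrix, regions x samples, rownames `dmr_id`, values in
#'   `[0, 1]` or `NA`.
#' @export
region_beta_matrix <- function(filtered, regions) {
  stopifnot(inherits(filtered, "cpg_matrix"))
  sites <- filtered$sites
  beta <- filtered$meth / filtered$cov
  out <- matrix(NA_real_, nrow(regions), ncol(filtered$meth),
                dimnames = list(regions$dmr_id, colnames(filtered$meth)))
  pos0 <- sites$pos - 1L   # CpG position as 0-based point
  empty <- logical(nrow(regions))
  for (i in seq_len(nrow(regions))) {
    in_reg <- sites$chrom == regions$chrom[i] &
      pos0 >= regions$start[i] & pos0 < regions$end[i]
    if (!any(in_reg)) {
      empty[i] <- TRUE
      next
    }
    out[i, ] <- colMeans(beta[in_reg, , drop = FALSE], na.rm = TRUE)
  }
  out[is.nan(out)] <- NA_real_
  if (any(empty)) {
    warning("dropping ", sum(empty), " region(s) with no surviving CpGs: ",
            paste(regions$dmr_id[empty], collapse = ", "))
    out <- out[!empty, , drop = FALSE]
  }
  out
}

#' Classify regions as hyper- or hypomethylated in the case group
#'
#' `hyper` iff the case-group mean beta exceeds the control-group mean for
#' that region; exact ties are broken as `hypo` with a warning.
#'
#' @param beta Region beta matrix from [region_beta_matrix()].
#' @param group Character vector (`case`/`control`) aligned with the matrix
#'   columns.
#' @return Named character vector of directions per region.
#' @export
classify_direction <- function(beta, group) {
  stopifnot(ncol(beta) == length(group))
  mc <- rowMeans(beta[, group == "case", drop = FALSE], na.rm = TRUE)
  mo <- rowMeans(beta[, group == "control", drop = FALSE], na.rm = TRUE)
  if (any(mc == mo, na.rm = TRUE)) {
    warning("exact case/control tie in ", sum(mc == mo, na.rm = TRUE),
            " region(s); classified as hypo")
  }
  setNames(ifelse(mc > mo, "hyper", "hypo"), rownames(beta))
}
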