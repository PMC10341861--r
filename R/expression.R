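# Normalization and a simplified negative-binomial Wald differential
# expression stage: median-of-ratios size factors, method-of-moments
# dispersion, two-group NB log-link GLM fit by IRLS, Benjamini-Hochberg
# adjustment and threshold-based DE selection.

#' Median-of-ratios size factors
#'
#' The reference per transcript is the geometric mean of its counts across
#' samples; a sample's factor is the median ratio of its counts to that
#' reference, over transcripts whose counts are positive in every sample.
#' If no transcript is everywhere-positive, each sample falls back to the
#' transcripts positive in that sample, with a warning.
#'
#' @param counts Integer matrix, transcripts x samples (or a
#'   `count_matrix`).
#' @return Positive numeric vector of per-sample factors.
#' @export
size_factors <- function(counts) {
  if (inherits(counts, "count_matrix")) counts <- counts$counts
  log_gm <- rowMeans(log(counts))
  use <- is.finite(log_gm)
  if (any(use)) {
    ratios <- counts[use, , drop = FALSE] / exp(log_gm[use])
    sf <- apply(ratios, 2L, median)
  } else {
    warning("no transcript with all-positive counts; ",
            "falling back to per-sample positive transcripts")
    log_gm_all <- rowMeans(ifelse(counts > 0, log(counts), NA), na.rm = TRUE)
    sf <- vapply(seq_len(ncol(counts)), function(j) {
      pos <- counts[, j] > 0 & is.finite(log_gm_all)
      if (!any(pos)) return(1)
      median(counts[pos, j] / exp(log_gm_all[pos]))
    }, numeric(1))
  }
  setNames(sf, colnames(counts))
}

#' Log2 normalized expression matrix
#'
#' `log2(count / size_factor + 1)`: a variance-taming monotone transform
#' standing in for a variance-stabilizing transform, sufficient for the
#' downstream Pearson correlation stages.
#'
#' @param counts Integer matrix or `count_matrix`.
#' @param sf Size factors; computed with [size_factors()] if omitted.
#' @return Numeric matrix of the same shape.
#' @export
normalize_counts <- function(counts, sf = NULL) {
  if (inherits(counts, "count_matrix")) counts <- counts$counts
  if (is.null(sf)) sf <- size_factors(counts)
  log2(sweep(counts, 2L, sf, "/") + 1)
}

# method-of-moments NB dispersion per transcript, pooled within groups so
# a real group effect is not counted as dispersion
mom_dispersion <- function(q, case, floor = 1e-8) {
  disp_group <- function(qg) {
    mu <- rowMeans(qg)
    s2 <- apply(qg, 1L, var)
    a <- (s2 - mu) / mu^2
    a[!is.finite(a)] <- 0
    a
  }
  n1 <- sum(case); n0 <- sum(!case)
  a1 <- disp_group(q[, case, drop = FALSE])
  a0 <- disp_group(q[, !case, drop = FALSE])
  a <- (a1 * (n1 - 1) + a0 * (n0 - 1)) / (n1 + n0 - 2)
  pmax(a, floor)
}

#' Two-group negative-binomial Wald differential expression
#'
#' Per transcript: dispersion alpha by method of moments on size-factor
#' normalized counts (pooled within groups, floored at 1e-8); a two-group
#' NB GLM with log link and log size factors as offset, fit by iteratively
#' reweighted least squares at fixed alpha; the Wald p-value compares the
#' group coefficient over its standard error against a standard normal.
#' All-zero transcripts get `log2fc = 0`, `p = 1`; transcripts whose IRLS
#' does not converge in `max_iter` iterations are flagged and set to
#' `p = 1` with a warning.
#'
#' @param counts Integer matrix (transcripts x samples) or `count_matrix`.
#' @param group `case`/`control` labels (taken from the `count_matrix` if
#'   omitted).
#' @param sf Size factors; computed if omitted.
#' @param max_iter IRLS iteration cap (default 100).
#' @param tol Convergence tolerance on coefficients (default 1e-8).
#' @return `data.table` with `transcript_id`, `base_mean`, `log2fc`
#'   (case vs control), `se` (log2 scale), `wald_stat`, `pvalue`, `padj`,
#'   `converged`, `de_flag` (`padj < 0.05` and `|log2fc| > 0.5`).
#' @export
nb_wald_de <- function(counts, group = NULL, sf = NULL,
                       max_iter = 100L, tol = 1e-8) {
  if (inherits(counts, "count_matrix")) {
    if (is.null(group)) group <- counts$group
    counts <- counts$counts
  }
  stopifnot(!is.null(group), length(group) == ncol(counts))
  case <- group == "case"
  if (is.null(sf)) sf <- size_factors(counts)
  y <- counts
  n_t <- nrow(y)
  q <- sweep(y, 2L, sf, "/")
  alpha <- mom_dispersion(q, case)
  base_mean <- rowMeans(q)
  off <- matrix(log(sf), n_t, ncol(y), byrow = TRUE)
  g <- as.numeric(case)
  # init from group means of normalized counts
  eps <- 0.5
  b0 <- log(rowMeans(q[, !case, drop = FALSE]) + eps)
  b1 <- log(rowMeans(q[, case, drop = FALSE]) + eps) - b0
  active <- rowSums(y) > 0
  converged <- !active   # all-zero rows count as trivially done
  A11 <- A12 <- A22 <- se1 <- rep(NA_real_, n_t)
  for (it in seq_len(max_iter)) {
    idx <- which(active & !converged)
    if (!length(idx)) break
    eta <- off[idx, , drop = FALSE] + b0[idx] + outer(b1[idx], g)
    eta <- pmin(pmax(eta, -30), 30)
    mu <- exp(eta)
    w <- mu / (1 + alpha[idx] * mu)
    z <- eta - off[idx, , drop = FALSE] + (y[idx, , drop = FALSE] - mu) / mu
    sw <- rowSums(w)
    swg <- w %*% g
    swz <- rowSums(w * z)
    swzg <- (w * z) %*% g
    det <- sw * swg - swg^2      # X = [1, g]; g^2 = g
    nb0 <- drop((swg * swz - swg * swzg) / det)
    nb1 <- drop((sw * swzg - swg * swz) / det)
    delta <- pmax(abs(nb0 - b0[idx]), abs(nb1 - b1[idx]))
    b0[idx] <- nb0
    b1[idx] <- nb1
    A11[idx] <- sw; A12[idx] <- drop(swg); A22[idx] <- drop(swg)
    converged[idx] <- delta < tol
  }
  se_b1 <- sqrt(A11 / (A11 * A22 - A12^2))
  log2fc <- b1 / log(2)
  se <- se_b1 / log(2)
  wald <- b1 / se_b1
  pvalue <- 2 * pnorm(-abs(wald))
  # degenerate rows
  zero <- !(rowSums(y) > 0)
  log2fc[zero] <- 0; se[zero] <- NA_real_; wald[zero] <- 0; pvalue[zero] <- 1
  failed <- active & !converged
  if (any(failed)) {
    warning(sum(failed), " transcript(s) did not converge in ", max_iter,
            " IRLS iterations; p-value set to 1")
    pvalue[failed] <- 1
  }
  pvalue[!is.finite(pvalue)] <- 1
  out <- data.table(
    transcript_id = if (is.null(rownames(y))) as.character(seq_len(n_t))
      else rownames(y),
    base_mean = base_mean,
    log2fc = log2fc,
    se = se,
    wald_stat = wald,
    pvalue = pvalue,
    converged = converged | zero
  )
  out[, padj := bh_adjust(pvalue)]
  out[, de_flag := padj < 0.05 & abs(log2fc) > 0.5]
  out[]
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' Standard step-up procedure with monotonicity enforcement; the result is
#' returned in the input order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  m <- length(p)
  if (m == 0L) return(numeric())
  ord <- order(p, decreasing = TRUE)
  adj <- pmin(1, cummin(m / (m:1) * p[ord]))
  adj[order(ord)]
}

#' Select differentially expressed transcripts by threshold and biotype
#'
#' Strict inequalities on both thresholds: a transcript is DE iff
#' `padj < padj_cut` and `|log2fc| > lfc_cut`. The result is partitioned by
#' annotation biotype.
#'
#' @param results Table from [nb_wald_de()].
#' @param annotation Annotation table from [read_annotation()].
#' @param padj_cut Adjusted p-value threshold (default 0.05).
#' @param lfc_cut Absolute log2 fold-change threshold (default 0.5).
#' @return List with `all` (results joined with biotype and a recomputed
#'   `de_flag`), `lncRNA` and `protein_coding` (DE-only subsets).
#' @export
select_de <- function(results, annotation, padj_cut = 0.05, lfc_cut = 0.5) {
  res <- merge(as.data.table(results),
               annotation[, .(transcript_id, biotype)],
               by = "transcript_id", all.x = TRUE, sort = FALSE)
  res[, de_flag := padj < padj_cut & abs(log2fc) > lfc_cut]
  list(all = res,
       lncRNA = res[de_flag == TRUE & biotype == "lncRNA"],
       protein_coding = res[de_flag == TRUE & biotype == "protein_coding"])
}
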