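# Reference-based cell-type deconvolution of the DMR beta matrix:
# DMRs are mapped onto reference probe loci by coordinate overlap, then
# each sample's beta vector is robustly regressed (Huber M-estimation,
# no intercept) on the reference methylation profiles; negative
# coefficients are truncated at zero and the rest renormalized onto the
# simplex. Group differences per cell type use Wilcoxon rank-sum tests.

#' Map DMRs onto reference probe loci
#'
#' A DMR maps to a reference locus when the locus position (a point in
#' the same 0-based coordinate frame as the intervals) falls inside the
#' DMR's half-open interval: `start <= pos < end`. A DMR overlapping
#' several loci adopts the first by coordinate, with a warning. The
#' mapped fraction of DMRs is reported.
#'
#' @param dmrs DMR table (`dmr_id`, `chrom`, `start`, `end`).
#' @param reference Reference profile table: columns `locus_id`, `chrom`,
#'   `pos` (1-based), then one numeric beta column per cell type.
#' @return List: `mapping` (`dmr_id`, `locus_id`), `mapped_fraction`,
#'   `reference` (cell-type beta matrix, rows = mapped DMRs).
#' @export
map_regions_to_probes <- function(dmrs, reference) {
  cell_cols <- setdiff(names(reference), c("locus_id", "chrom", "pos"))
  if (length(cell_cols) < 2L) stop("reference needs at least 2 cell types")
  ref <- as.data.table(reference)
  setorder(ref, chrom, pos)
  maps <- vector("list", nrow(dmrs))
  multi <- 0L
  for (i in seq_len(nrow(dmrs))) {
    hit <- ref[chrom == dmrs$chrom[i] &
                 pos >= dmrs$start[i] & pos < dmrs$end[i]]
    if (nrow(hit) == 0L) next
    if (nrow(hit) > 1L) multi <- multi + 1L
    maps[[i]] <- data.table(dmr_id = dmrs$dmr_id[i],
                            locus_id = hit$locus_id[1L])
  }
  if (multi > 0L) {
    warning(multi, " DMR(s) overlap several reference loci; ",
            "first locus by coordinate used")
  }
  mapping <- rbindlist(maps)
  if (nrow(mapping) == 0L) {
    stop("no DMR overlaps any reference locus; deconvolution impossible")
  }
  refmat <- as.matrix(ref[match(mapping$locus_id, ref$locus_id),
                          cell_cols, with = FALSE])
  rownames(refmat) <- mapping$dmr_id
  list(mapping = mapping,
       mapped_fraction = nrow(mapping) / nrow(dmrs),
       reference = refmat)
}

#' Robust-regression cell-type fractions from a beta matrix
#'
#' Per sample, the beta vector over mapped regions is regressed on the
#' reference cell-type profiles by Huber M-estimation (tuning constant
#' 1.345, at most 50 iterations, no intercept); negative coefficients are
#' truncated to zero and the remainder renormalized to sum to one. If all
#' coefficients are non-positive the sample gets uniform fractions with a
#' warning.
#'
#' @param beta Region beta matrix (regions x samples), rows matching
#'   `reference` rows.
#' @param reference Cell-type reference matrix (regions x cell types),
#'   e.g. `map_regions_to_probes(...)$reference`.
#' @param k Huber tuning constant (default 1.345).
#' @param maxit Iteration cap (default 50).
#' @return Fraction matrix, samples x cell types; rows sum to 1.
#' @export
rpc_fractions <- function(beta, reference, k = 1.345, maxit = 50L) {
  common <- intersect(rownames(beta), rownames(reference))
  if (length(common) < ncol(reference) + 1L) {
    stop("too few shared regions between beta matrix and reference")
  }
  X <- reference[common, , drop = FALSE]
  if (qr(X)$rank < ncol(X)) {
    stop("singular reference design; collinear cell types among: ",
         paste(colnames(X), collapse = ", "))
  }
  B <- beta[common, , drop = FALSE]
  out <- matrix(NA_real_, ncol(B), ncol(X),
                dimnames = list(colnames(B), colnames(X)))
  for (s in seq_len(ncol(B))) {
    y <- B[, s]
    ok <- is.finite(y)
    # matrix-interface rlm fits exactly the supplied columns: no intercept
    fit <- MASS::rlm(X[ok, , drop = FALSE], y[ok], psi = MASS::psi.huber,
                     k = k, maxit = maxit)
    co <- pmax(coef(fit), 0)
    if (sum(co) <= 0) {
      warning("all coefficients non-positive for sample ", colnames(B)[s],
              "; uniform fractions assigned")
      co <- rep(1, ncol(X))
    }
    out[s, ] <- co / sum(co)
  }
  out
}

#' Compare cell-type fractions between groups
#'
#' Two-sided Wilcoxon rank-sum test per cell type, with group medians and
#' the direction of the shift.
#'
#' @param fractions Samples x cell types matrix from [rpc_fractions()].
#' @param group `case`/`control` labels aligned with rows.
#' @return `data.table`: `cell_type`, `median_case`, `median_control`,
#'   `direction` (`case>control` / `case<control` / `equal`), `statistic`
#'   (rank-sum U for the case group), `pvalue`.
#' @export
compare_fractions <- function(fractions, group) {
  stopifnot(nrow(fractions) == length(group))
  case <- group == "case"
  rbindlist(lapply(colnames(fractions), function(ct) {
    x <- fractions[case, ct]
    y <- fractions[!case, ct]
    wt <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE))
    mc <- median(x); mo <- median(y)
    data.table(cell_type = ct, median_case = mc, median_control = mo,
               direction = if (mc > mo) "case>control"
                           else if (mc < mo) "case<control" else "equal",
               statistic = unname(wt$statistic), pvalue = wt$p.value)
  }))
}
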