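# Cross-dataset verification: re-test discovered lncRNA-protein pairs in
# independent normalized expression matrices and summarize confirmation
# rates per lncRNA. The same correlate() operation as the discovery stage
# is used; confirmation defaults to the discovery rule (negative r, raw
# p < 0.05), with a two-sided "any significant correlation" mode behind a
# flag. Identifier matching is exact (optionally through an alias table);
# unmatched ids simply leave found_both false and are excluded from the
# confirmation denominator.

#' Verify lncRNA-protein pairs in external expression datasets
#'
#' @param pairs Table with `lnc_transcript_id` and `prot_transcript_id`
#'   (e.g. the triplet table; duplicates are collapsed).
#' @param datasets Named list of normalized expression matrices (features
#'   x samples, rownames = feature ids).
#' @param p_cut Raw correlation p-value threshold (default 0.05).
#' @param mode `"negative"` (default: confirmed iff `r < 0` and
#'   `p < p_cut`) or `"any"` (confirmed iff `p < p_cut`, either sign).
#' @param alias Optional two-column table (`from`, `to`) translating the
#'   pipeline's ids into a dataset's id namespace before matching.
#' @param method Correlation method (default Pearson).
#' @return List of class `verification_summary`: `long` (per pair per
#'   dataset: `found_both`, `r`, `pvalue`, `confirmed`), `by_lnc` (per
#'   lncRNA: `n_datasets_tested`, `n_confirmed`, `fraction_confirmed`),
#'   `n_lnc_confirmed` (lncRNAs confirmed in at least one dataset) and
#'   `mean_fraction_confirmed`.
#' @export
verify_pairs <- function(pairs, datasets, p_cut = 0.05,
                         mode = c("negative", "any"), alias = NULL,
                         method = "pearson") {
  mode <- match.arg(mode)
  up <- unique(as.data.table(pairs)[, .(lnc_transcript_id,
                                        prot_transcript_id)])
  translate <- function(ids) {
    if (is.null(alias)) return(ids)
    m <- match(ids, alias$from)
    ifelse(is.na(m), ids, alias$to[m])
  }
  if (is.null(names(datasets)) || any(names(datasets) == "")) {
    stop("datasets must be a named list")
  }
  long <- list()
  for (ds in names(datasets)) {
    mat <- datasets[[ds]]
    if (anyDuplicated(rownames(mat))) {
      stop("identifier collisions in dataset ", ds)
    }
    if (ncol(mat) < 3L) {
      warning("dataset ", ds, " has fewer than 3 samples; skipped")
      next
    }
    lid <- translate(up$lnc_transcript_id)
    pid <- translate(up$prot_transcript_id)
    found <- lid %in% rownames(mat) & pid %in% rownames(mat)
    r <- p <- rep(NA_real_, nrow(up))
    for (i in which(found)) {
      cc <- correlate(mat[lid[i], ], mat[pid[i], ], method = method)
      r[i] <- cc$r; p[i] <- cc$pvalue
    }
    conf <- !is.na(p) & p < p_cut & (mode == "any" | (!is.na(r) & r < 0))
    long[[ds]] <- data.table(dataset = ds,
                             lnc_transcript_id = up$lnc_transcript_id,
                             prot_transcript_id = up$prot_transcript_id,
                             found_both = found, r = r, pvalue = p,
                             confirmed = conf)
  }
  long <- rbindlist(long)
  if (nrow(long) == 0L) stop("no usable verification dataset")
  by_lnc <- long[found_both == TRUE,
                 .(n_datasets_tested = uniqueN(dataset),
                   n_confirmed = uniqueN(dataset[confirmed])),
                 by = lnc_transcript_id]
  by_lnc[, fraction_confirmed := n_confirmed / n_datasets_tested]
  structure(list(long = long, by_lnc = by_lnc,
                 n_lnc_confirmed = sum(by_lnc$n_confirmed > 0),
                 mean_fraction_confirmed =
                   if (nrow(by_lnc)) mean(by_lnc$fraction_confirmed) else
                     NA_real_),
            class = "verification_summary")
}

#' @export
print.verification_summary <- function(x, ...) {
  cat("verification across", uniqueN(x$long$dataset), "dataset(s):",
      x$n_lnc_confirmed, "of", nrow(x$by_lnc),
      "testable lncRNAs confirmed in >=1 dataset;",
      "mean confirmation fraction",
      round(x$mean_fraction_confirmed, 3), "\n")
  invisible(x)
}
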