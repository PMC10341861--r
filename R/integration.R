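# The core inference: pair DE lncRNAs with DMRs inside a 20 kb window and
# keep pairs whose expression is significantly negatively correlated with
# DMR methylation; then pair the surviving "DMR-regulated" lncRNAs with DE
# protein-coding transcripts inside a 500 kb window and keep significantly
# negatively correlated pairs, emitting (DMR, lncRNA, protein) triplets.
#
# Distances are measured between full feature spans (transcript body vs
# region span), on the same chromosome only; strand is ignored. Correlation
# is Pearson on region mean betas vs log2-normalized expression; the
# discovery filter uses raw correlation p-values (BH-adjusted values are
# reported as an extra column, never filtered on).

#' Gap between two genomic intervals
#'
#' 0 if the intervals overlap or are adjacent, the bp gap otherwise, `NA`
#' if the intervals are on different chromosomes (such pairs are excluded
#' from windowed pairing). Vectorized; intervals are 0-based half-open.
#'
#' @param chrom_a,start_a,end_a First interval(s).
#' @param chrom_b,start_b,end_b Second interval(s).
#' @return Integer bp distance(s), `NA` across chromosomes.
#' @export
interval_distance <- function(chrom_a, start_a, end_a,
                              chrom_b, start_b, end_b) {
  gap <- pmax(start_a, start_b) - pmin(end_a, end_b)
  d <- pmax(gap, 0L)
  d[chrom_a != chrom_b] <- NA_integer_
  d
}

# all same-chromosome pairs between two interval tables within `window` bp
window_pairs <- function(left, right, window) {
  if (nrow(left) == 0L || nrow(right) == 0L) {
    return(data.table(left_id = character(), right_id = character(),
                      distance_bp = integer()))
  }
  li <- left[, .(left_id = id, chrom, lstart = start, lend = end)]
  ri <- right[, .(right_id = id, chrom, rstart = start, rend = end)]
  joined <- li[ri, on = "chrom", allow.cartesian = TRUE, nomatch = NULL]
  joined[, distance_bp := interval_distance(chrom, lstart, lend,
                                            chrom, rstart, rend)]
  joined[distance_bp <= window,
         .(left_id, right_id, distance_bp)]
}

#' Pair DE lncRNAs with DMRs by genomic window
#'
#' Keeps every (lncRNA transcript, DMR) pair on the same chromosome whose
#' span-to-span distance is at most `window` bp (default 20 kb). A lncRNA
#' may pair with several DMRs and vice versa.
#'
#' @param de_lnc Annotation rows of the DE lncRNAs (`transcript_id`,
#'   `chrom`, `start`, `end`).
#' @param dmrs DMR table (`dmr_id`, `chrom`, `start`, `end`).
#' @param window Window in bp (default 20000).
#' @return `data.table` of `lnc_transcript_id`, `dmr_id`, `distance_bp`.
#' @export
pair_lnc_dmr <- function(de_lnc, dmrs, window = 20000L) {
  if (nrow(de_lnc) == 0L) {
    warning("no DE lncRNAs to pair")
  }
  p <- window_pairs(de_lnc[, .(id = transcript_id, chrom, start, end)],
                    dmrs[, .(id = dmr_id, chrom, start, end)], window)
  setnames(p, c("left_id", "right_id"), c("lnc_transcript_id", "dmr_id"))
  p[]
}

#' Pearson correlation with a t-distribution p-value
#'
#' Samples missing in either vector are dropped pairwise; at least 3
#' complete pairs are required. The two-sided p-value comes from the t
#' distribution with n - 2 degrees of freedom; `|r| = 1` gives `p = 0`.
#' Zero variance in either vector yields `r = NA` (the caller excludes
#' such pairs) with a warning.
#'
#' @param x,y Numeric vectors of equal length.
#' @param method `"pearson"` (default) or `"spearman"` (ranks first, then
#'   the same t approximation).
#' @return List with `r`, `pvalue`, `n` (complete pairs used).
#' @export
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) return(list(r = NA_real_, pvalue = NA_real_, n = n))
  if (method == "spearman") {
    x <- rank(x); y <- rank(y)
  }
  if (sd(x) == 0 || sd(y) == 0) {
    warning("zero variance in correlation input; pair excluded")
    return(list(r = NA_real_, pvalue = NA_real_, n = n))
  }
  r <- cor(x, y)
  if (abs(r) >= 1) return(list(r = sign(r), pvalue = 0, n = n))
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, pvalue = 2 * pt(-abs(tstat), df = n - 2), n = n)
}

# correlate matrix rows for a table of (left_id, right_id) pairs
correlate_pairs <- function(pairs, left_mat, right_mat, method = "pearson") {
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    l <- pairs$left_id[i]; rt <- pairs$right_id[i]
    if (!l %in% rownames(left_mat) || !rt %in% rownames(right_mat)) {
      return(list(r = NA_real_, pvalue = NA_real_, n = 0L))
    }
    correlate(left_mat[l, ], right_mat[rt, ], method = method)
  })
  pairs <- copy(pairs)
  pairs[, r := vapply(res, `[[`, numeric(1), "r")]
  pairs[, pvalue := vapply(res, `[[`, numeric(1), "pvalue")]
  pairs[, n := vapply(res, function(z) as.integer(z$n), integer(1))]
  pairs[]
}

#' Filter lncRNA-DMR pairs to negatively correlated "DMR-regulated" links
#'
#' Computes the Pearson correlation between each DMR's per-sample mean
#' beta and the paired lncRNA's normalized expression across samples, then
#' keeps pairs with `r < 0` and raw `p < 0.05`. Each surviving pair is
#' tagged with the lncRNA's DE direction (`up`/`down` in the case group)
#' and a BH-adjusted p-value over the tested pairs is reported as an extra
#' column (not filtered on).
#'
#' @param pairs Output of [pair_lnc_dmr()].
#' @param beta Region beta matrix ([region_beta_matrix()]).
#' @param norm_expr Normalized expression matrix
#'   ([normalize_counts()]), transcripts x samples.
#' @param de_results DE table ([nb_wald_de()]) supplying `log2fc`.
#' @param p_cut Raw p-value threshold (default 0.05).
#' @param method Correlation method (default Pearson).
#' @return Filtered pair table with `r_meth_lnc`, `p_meth_lnc`,
#'   `padj_meth_lnc`, `n`, `lnc_de_direction`.
#' @export
dmr_regulated_lncrnas <- function(pairs, beta, norm_expr, de_results,
                                  p_cut = 0.05, method = "pearson") {
  cp <- correlate_pairs(
    pairs[, .(left_id = dmr_id, right_id = lnc_transcript_id, distance_bp)],
    beta, norm_expr, method = method)
  cp[, padj := bh_adjust(pvalue)]
  keep <- cp[!is.na(r) & r < 0 & pvalue < p_cut]
  setnames(keep,
           c("left_id", "right_id", "r", "pvalue", "padj"),
           c("dmr_id", "lnc_transcript_id", "r_meth_lnc", "p_meth_lnc",
             "padj_meth_lnc"))
  lfc <- setNames(de_results$log2fc, de_results$transcript_id)
  keep[, lnc_de_direction := ifelse(lfc[lnc_transcript_id] > 0, "up", "down")]
  setcolorder(keep, c("dmr_id", "lnc_transcript_id", "distance_bp",
                      "r_meth_lnc", "p_meth_lnc", "padj_meth_lnc", "n",
                      "lnc_de_direction"))
  keep[]
}

#' Pair DMR-regulated lncRNAs with DE protein-coding transcripts
#'
#' Same span-to-span window rule as [pair_lnc_dmr()], at 500 kb by
#' default.
#'
#' @param reg_lnc Table from [dmr_regulated_lncrnas()] (distinct lncRNAs
#'   are extracted).
#' @param de_prot Annotation rows of the DE protein-coding transcripts.
#' @param annotation Full annotation (for lncRNA coordinates).
#' @param window Window in bp (default 500000).
#' @return `data.table` of `lnc_transcript_id`, `prot_transcript_id`,
#'   `distance_bp`.
#' @export
pair_lnc_protein <- function(reg_lnc, de_prot, annotation,
                             window = 500000L) {
  lnc_ids <- unique(reg_lnc$lnc_transcript_id)
  lnc_ann <- annotation[transcript_id %in% lnc_ids]
  p <- window_pairs(lnc_ann[, .(id = transcript_id, chrom, start, end)],
                    de_prot[, .(id = transcript_id, chrom, start, end)],
                    window)
  setnames(p, c("left_id", "right_id"),
           c("lnc_transcript_id", "prot_transcript_id"))
  p[]
}

#' Correlate candidate lncRNA-protein pairs and emit the triplet table
#'
#' Keeps candidates with Pearson `r < 0` and raw `p < 0.05` between the
#' two transcripts' normalized expression, then joins each surviving
#' (lncRNA, protein) pair back to every DMR that regulates the lncRNA,
#' producing one row per (DMR, lncRNA, protein) triplet with both
#' correlations, both distances and the DMR direction.
#'
#' @param candidates Output of [pair_lnc_protein()].
#' @param norm_expr Normalized expression matrix.
#' @param reg_lnc Output of [dmr_regulated_lncrnas()].
#' @param dmrs DMR table (for `direction`).
#' @param p_cut Raw p-value threshold (default 0.05).
#' @param method Correlation method (default Pearson).
#' @return Triplet `data.table`: `dmr_id`, `dmr_direction`,
#'   `lnc_transcript_id`, `lnc_de_direction`, `prot_transcript_id`,
#'   `r_meth_lnc`, `p_meth_lnc`, `r_lnc_prot`, `p_lnc_prot`,
#'   `padj_lnc_prot`, `dist_dmr_lnc`, `dist_lnc_prot`.
#' @export
lnc_protein_targets <- function(candidates, norm_expr, reg_lnc, dmrs,
                                p_cut = 0.05, method = "pearson") {
  cp <- correlate_pairs(
    candidates[, .(left_id = lnc_transcript_id,
                   right_id = prot_transcript_id, distance_bp)],
    norm_expr, norm_expr, method = method)
  cp[, padj := bh_adjust(pvalue)]
  keep <- cp[!is.na(r) & r < 0 & pvalue < p_cut]
  setnames(keep,
           c("left_id", "right_id", "r", "pvalue", "padj", "distance_bp"),
           c("lnc_transcript_id", "prot_transcript_id", "r_lnc_prot",
             "p_lnc_prot", "padj_lnc_prot", "dist_lnc_prot"))
  dir_map <- setNames(dmrs$direction, dmrs$dmr_id)
  trip <- merge(
    reg_lnc[, .(dmr_id, lnc_transcript_id, dist_dmr_lnc = distance_bp,
                r_meth_lnc, p_meth_lnc, lnc_de_direction)],
    keep[, .(lnc_transcript_id, prot_transcript_id, r_lnc_prot,
             p_lnc_prot, padj_lnc_prot, dist_lnc_prot)],
    by = "lnc_transcript_id", allow.cartesian = TRUE)
  trip[, dmr_direction := dir_map[dmr_id]]
  setcolorder(trip, c("dmr_id", "dmr_direction", "lnc_transcript_id",
                      "lnc_de_direction", "prot_transcript_id",
                      "r_meth_lnc", "p_meth_lnc", "r_lnc_prot",
                      "p_lnc_prot", "padj_lnc_prot", "dist_dmr_lnc",
                      "dist_lnc_prot"))
  setorder(trip, dmr_id, lnc_transcript_id, prot_transcript_id)
  trip[]
}

#' Tabular per-region report
#'
#' For each DMR appearing in the triplet table, lists every annotated
#' transcript, CpG island and TSS falling within `flank` bp of the region
#' span: the tabular analog of a genome-browser track view.
#'
#' @param triplets Triplet table from [lnc_protein_targets()].
#' @param dmrs DMR table.
#' @param annotation Full annotation.
#' @param cpg_islands,tss Optional BED-like tables (`chrom`, `start`,
#'   `end`).
#' @param flank Window around each DMR, bp (default 20000).
#' @return Long `data.table`: `dmr_id`, `feature_type`, `feature_id`,
#'   `chrom`, `start`, `end`, `distance_bp`.
#' @export
region_report <- function(triplets, dmrs, annotation,
                          cpg_islands = NULL, tss = NULL, flank = 20000L) {
  use <- dmrs[dmr_id %in% unique(triplets$dmr_id)]
  feats <- annotation[, .(feature_id = transcript_id,
                          feature_type = ifelse(biotype == "lncRNA",
                                                "lncRNA_transcript",
                                                ifelse(biotype == "protein_coding",
                                                       "protein_transcript",
                                                       "other_transcript")),
                          chrom, start, end)]
  if (!is.null(cpg_islands)) {
    feats <- rbind(feats, cpg_islands[, .(
      feature_id = paste0("cpg_island_", .I), feature_type = "cpg_island",
      chrom, start, end)])
  }
  if (!is.null(tss)) {
    feats <- rbind(feats, tss[, .(
      feature_id = paste0("tss_", .I), feature_type = "tss",
      chrom, start, end)])
  }
  p <- window_pairs(use[, .(id = dmr_id, chrom, start, end)],
                    feats[, .(id = feature_id, chrom, start, end)], flank)
  setnames(p, c("left_id", "right_id"), c("dmr_id", "feature_id"))
  out <- merge(p, feats, by = "feature_id", sort = FALSE)
  setcolorder(out, c("dmr_id", "feature_type", "feature_id", "chrom",
                     "start", "end", "distance_bp"))
  setorder(out, dmr_id, chrom, start)
  out[]
}
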