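# Recovery metrics against a simulation's truth: match called DMRs to
# planted DMRs by reciprocal overlap, then score triplet recovery and the
# decoy-derived fraction of the output.

#' Match called regions to true regions by reciprocal overlap
#'
#' A called region matches a true region when the overlap covers at least
#' `min_overlap` of BOTH intervals. Each true region takes its best
#' (largest-overlap) match.
#'
#' @param called Called DMR table (`chrom`, `start`, `end`, `dmr_id`).
#' @param truth True region table (same columns).
#' @param min_overlap Reciprocal overlap fraction (default 0.5).
#' @return `data.table`: one row per true region with `true_id`,
#'   `called_id` (`NA` if unrecovered) and `recovered`.
#' @export
region_recovery <- function(called, truth, min_overlap = 0.5) {
  out <- data.table(true_id = truth$dmr_id, called_id = NA_character_,
                    recovered = FALSE)
  if (nrow(called) == 0L) return(out)
  for (i in seq_len(nrow(truth))) {
    same <- called[chrom == truth$chrom[i]]
    if (nrow(same) == 0L) next
    ov <- pmin(same$end, truth$end[i]) - pmax(same$start, truth$start[i])
    frac_true <- ov / (truth$end[i] - truth$start[i])
    frac_called <- ov / (same$end - same$start)
    hit <- which(ov > 0 & frac_true >= min_overlap &
                   frac_called >= min_overlap)
    if (length(hit)) {
      best <- hit[which.max(ov[hit])]
      out[i, `:=`(called_id = same$dmr_id[best], recovered = TRUE)]
    }
  }
  out
}

#' Score a triplet table against the planted truth
#'
#' A planted triplet counts as recovered when some emitted row pairs its
#' lncRNA and protein and its DMR was recovered (reciprocal overlap) by
#' the row's DMR. An emitted row is `decoy_derived` when its lncRNA or
#' protein is a decoy (absent from the truth table's transcript columns);
#' rows built from planted features in a non-planted combination are
#' counted separately as `cross_planted`.
#'
#' @param triplets Emitted triplet table ([lnc_protein_targets()]).
#' @param truth Truth table from the simulation.
#' @param dmr_match Output of [region_recovery()] (called vs true DMRs).
#' @return List: `sensitivity`, `n_recovered`, `n_planted`,
#'   `decoy_fraction` (decoy-derived rows / emitted rows),
#'   `cross_planted_fraction`, `per_triplet` table.
#' @export
triplet_recovery <- function(triplets, truth, dmr_match) {
  called_for <- setNames(dmr_match$called_id, dmr_match$true_id)
  rec <- logical(nrow(truth))
  for (i in seq_len(nrow(truth))) {
    cid <- called_for[[truth$dmr_id[i]]]
    if (is.na(cid)) next
    rec[i] <- any(triplets$dmr_id == cid &
                    triplets$lnc_transcript_id == truth$lnc_transcript_id[i] &
                    triplets$prot_transcript_id == truth$prot_transcript_id[i])
  }
  planted_lnc <- unique(truth$lnc_transcript_id)
  planted_prot <- unique(truth$prot_transcript_id)
  decoy <- !(triplets$lnc_transcript_id %in% planted_lnc) |
    !(triplets$prot_transcript_id %in% planted_prot)
  pair_key <- paste(truth$lnc_transcript_id, truth$prot_transcript_id)
  cross <- !decoy & !(paste(triplets$lnc_transcript_id,
                            triplets$prot_transcript_id) %in% pair_key)
  n_out <- nrow(triplets)
  list(sensitivity = if (nrow(truth)) mean(rec) else NA_real_,
       n_recovered = sum(rec), n_planted = nrow(truth),
       decoy_fraction = if (n_out) sum(decoy) / n_out else 0,
       cross_planted_fraction = if (n_out) sum(cross) / n_out else 0,
       per_triplet = data.table(truth, recovered = rec))
}
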