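# End-to-end driver: from a study directory (cytosine reports, count
# matrix, sample sheet, annotation, reference profiles) through coverage
# filtering, DMR calling, differential expression, the correlation
# cascade, deconvolution and verification, writing every tabular artifact
# along the way.

#' Run the full pipeline on a study directory
#'
#' Expects the layout written by [generate_study()] (or equivalent real
#' data): `meth/*.CpG_report.txt[.gz]`, `counts.tsv`, `samples.tsv`,
#' `annotation.gtf` (or `.bed`) and optionally `reference_profiles.tsv`.
#' Stages: coverage filter (6x in 50% of both groups), permutation DMR
#' caller (or an externally supplied `dmr_bed`), region beta matrix,
#' size-factor NB Wald DE, DE selection (padj < 0.05, |log2FC| > 0.5),
#' 20 kb DMR-lncRNA pairing with negative-correlation filtering, 500 kb
#' lncRNA-protein pairing with negative-correlation filtering,
#' deconvolution of the DMR beta matrix and (optionally) verification
#' against external normalized matrices.
#'
#' @param study_dir Input directory.
#' @param out_dir Output directory (created); omit to skip writing.
#' @param seed Integer seed (drives the permutation caller and any
#'   simulated verification datasets).
#' @param dmr_bed Optional BED of externally called DMRs, bypassing the
#'   caller.
#' @param de_table Optional externally computed DE table TSV, bypassing
#'   the NB Wald stage (columns `transcript_id`, `log2fc`, `pvalue`,
#'   `padj`).
#' @param min_cov,min_frac Coverage filter parameters.
#' @param n_perm Label permutations for the DMR caller.
#' @param q_cut DMR significance threshold.
#' @param lnc_window,prot_window Pairing windows, bp.
#' @param verification_datasets Named list of external normalized
#'   matrices, or `NULL` to skip verification.
#' @param method Correlation method for all correlation stages.
#' @return List with every stage result: `filtered`, `dmrs`, `sig_dmrs`,
#'   `beta`, `de`, `de_sets`, `pairs`, `reg_lnc`, `triplets`,
#'   `fractions`, `fraction_tests`, `verification`, `report`.
#' @export
run_all <- function(study_dir, out_dir = NULL, seed = 1L,
                    dmr_bed = NULL, de_table = NULL,
                    min_cov = 6L, min_frac = 0.5, n_perm = 100L,
                    q_cut = 0.05, lnc_window = 20000L,
                    prot_window = 500000L,
                    verification_datasets = NULL,
                    method = "pearson") {
  set.seed(seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  }
  emit <- function(x, name) {
    if (!is.null(out_dir)) write_table(x, file.path(out_dir, name))
  }
  # --- methylation ---
  reports <- sort(list.files(file.path(study_dir, "meth"),
                             pattern = "\\.CpG_report\\.txt(\\.gz)?$",
                             full.names = TRUE))
  if (length(reports) == 0L) stop("no cytosine reports under ", study_dir)
  sheet <- fread(file.path(study_dir, "samples.tsv"))
  tables <- lapply(reports, read_cytosine_report)
  names(tables) <- vapply(tables, attr, character(1), "sample_id")
  group <- setNames(sheet$group, sheet$sample_id)[names(tables)]
  cpg <- build_cpg_matrix(tables, group)
  filtered <- filter_cpg_coverage(cpg, min_cov = min_cov,
                                  min_frac = min_frac)
  dmrs <- if (is.null(dmr_bed)) {
    call_dmrs(filtered, n_perm = n_perm, q_cut = q_cut)
  } else {
    read_dmr_bed(dmr_bed)
  }
  sig <- if (is.null(dmr_bed)) dmrs[significant == TRUE] else
    dmrs[is.na(qvalue) | qvalue < q_cut]
  beta <- region_beta_matrix(filtered, sig)
  sig <- sig[dmr_id %in% rownames(beta)]
  if (!is.null(out_dir)) {
    write_dmr_bed(dmrs, file.path(out_dir, "dmrs.bed"))
    write_matrix(beta, file.path(out_dir, "beta.tsv"), id_col = "dmr_id")
  }
  # --- expression ---
  cm <- read_count_matrix(file.path(study_dir, "counts.tsv"),
                          file.path(study_dir, "samples.tsv"))
  ann_path <- if (file.exists(file.path(study_dir, "annotation.gtf")))
    file.path(study_dir, "annotation.gtf") else
      file.path(study_dir, "annotation.bed")
  annotation <- read_annotation(ann_path)
  sf <- size_factors(cm)
  norm <- normalize_counts(cm, sf)
  de <- if (is.null(de_table)) nb_wald_de(cm, sf = sf) else
    read_table(de_table)
  de_sets <- select_de(de, annotation)
  emit(de, "de_results.tsv")
  if (!is.null(out_dir)) {
    write_matrix(norm, file.path(out_dir, "normalized.tsv"),
                 id_col = "transcript_id")
  }
  # --- integration ---
  de_lnc_ann <- annotation[transcript_id %in%
                             de_sets$lncRNA$transcript_id]
  de_prot_ann <- annotation[transcript_id %in%
                              de_sets$protein_coding$transcript_id]
  pairs <- pair_lnc_dmr(de_lnc_ann, sig, window = lnc_window)
  reg_lnc <- dmr_regulated_lncrnas(pairs, beta, norm, de, method = method)
  cands <- pair_lnc_protein(reg_lnc, de_prot_ann, annotation,
                            window = prot_window)
  triplets <- lnc_protein_targets(cands, norm, reg_lnc, sig,
                                  method = method)
  emit(pairs, "dmr_lnc_pairs.tsv")
  emit(reg_lnc, "dmr_regulated_lncrnas.tsv")
  emit(triplets, "triplets.tsv")
  report <- region_report(triplets, sig, annotation)
  emit(report, "region_report.tsv")
  # --- deconvolution (optional: needs a reference) ---
  fractions <- fraction_tests <- NULL
  ref_path <- file.path(study_dir, "reference_profiles.tsv")
  if (file.exists(ref_path) && nrow(sig) > 0L) {
    reference <- read_table(ref_path)
    mapped <- tryCatch(map_regions_to_probes(sig, reference),
                       error = function(e) {
                         warning("deconvolution skipped: ",
                                 conditionMessage(e))
                         NULL
                       })
    if (!is.null(mapped)) {
      fractions <- tryCatch(rpc_fractions(beta, mapped$reference),
                            error = function(e) {
                              warning("deconvolution skipped: ",
                                      conditionMessage(e))
                              NULL
                            })
    }
    if (!is.null(fractions)) {
      fraction_tests <- compare_fractions(fractions,
                                          group[rownames(fractions)])
      if (!is.null(out_dir)) {
        write_matrix(fractions, file.path(out_dir, "fractions.tsv"),
                     id_col = "sample_id")
      }
      emit(fraction_tests, "fractions_tests.tsv")
    }
  }
  # --- verification (optional) ---
  verification <- NULL
  if (!is.null(verification_datasets) && nrow(triplets) > 0L) {
    verification <- verify_pairs(triplets, verification_datasets)
    emit(verification$long, "verification_long.tsv")
    emit(verification$by_lnc, "verification_summary.tsv")
  }
  list(filtered = filtered, dmrs = dmrs, sig_dmrs = sig, beta = beta,
       de = de, de_sets = de_sets, norm = norm, annotation = annotation,
       group = group, pairs = pairs, reg_lnc = reg_lnc,
       triplets = triplets, report = report, fractions = fractions,
       fraction_tests = fraction_tests, verification = verification)
}
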