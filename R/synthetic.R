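# Synthetic joint methylation/expression studies with planted regulatory
# structure: beta-binomial CpG methylation with planted DMRs, negative
# binomial expression with lncRNA levels anti-coupled to per-sample DMR
# methylation and protein levels anti-coupled to the realized lncRNA
# counts, plus unlinked decoy transcripts. A machine-readable truth table
# records every planted DMR -> lncRNA -> protein triplet.
#
# Planted cassettes (DMR + linked lncRNA + linked protein) are spaced at
# least ~2x the protein window apart so that cassettes do not overlap each
# other's pairing windows; decoy transcripts ARE placed inside cassette
# windows so that window filtering alone cannot recover the truth.

#' Simulation configuration
#'
#' Defaults describe the emulated study: 11 case vs 13 control samples,
#' planted DMRs averaging 288 bp and 15 CpGs, a group methylation
#' difference of 0.3, Poisson(30) coverage, 30 planted
#' DMR-lncRNA-protein cassettes and 150 + 150 decoy transcripts, with
#' strongly negative methylation-to-lncRNA and lncRNA-to-protein
#' couplings on the log-mean scale.
#'
#' @param n_case,n_control Group sizes.
#' @param genome Named numeric vector of chromosome lengths (bp).
#' @param n_cpg Number of background CpG sites.
#' @param n_planted_dmrs Number of planted DMRs (= cassettes).
#' @param dmr_mean_len Mean planted DMR length, bp.
#' @param dmr_mean_cpgs Mean CpGs per planted DMR.
#' @param delta_beta Case-minus-control methylation difference inside
#'   hyper DMRs (negated for hypo DMRs).
#' @param baseline_beta_range Range of background baseline betas.
#' @param bb_dispersion Beta-binomial overdispersion rho in (0, 1).
#' @param coverage_mean Mean Poisson read coverage per CpG per sample.
#' @param n_lnc_linked,n_prot_linked Planted linked transcripts (cycled
#'   over the planted DMRs if larger).
#' @param n_lnc_decoy,n_prot_decoy Decoy transcripts with
#'   group-independent means.
#' @param coupling_lnc Slope of lncRNA log-mean on per-sample DMR beta
#'   (must be negative for planted links).
#' @param coupling_prot Slope of protein log-mean on the standardized log
#'   lncRNA count (negative).
#' @param nb_dispersion NB dispersion alpha of expression counts.
#' @param lnc_base_mean,prot_base_mean Baseline expression means.
#' @param lnc_window,prot_window Pairing windows, bp.
#' @param seed Integer seed used by [generate_study()].
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_case = 11L, n_control = 13L,
                       genome = c(chr1 = 25e6, chr2 = 25e6),
                       n_cpg = 20000L,
                       n_planted_dmrs = 30L,
                       dmr_mean_len = 288, dmr_mean_cpgs = 15,
                       delta_beta = 0.3,
                       baseline_beta_range = c(0.2, 0.8),
                       bb_dispersion = 0.02,
                       coverage_mean = 30,
                       n_lnc_linked = 30L, n_lnc_decoy = 150L,
                       n_prot_linked = 30L, n_prot_decoy = 150L,
                       coupling_lnc = -4, coupling_prot = -1,
                       nb_dispersion = 0.05,
                       lnc_base_mean = 200, prot_base_mean = 200,
                       lnc_window = 20000L, prot_window = 500000L,
                       seed = 1L) {
  cfg <- list(n_case = as.integer(n_case), n_control = as.integer(n_control),
              genome = genome, n_cpg = as.integer(n_cpg),
              n_planted_dmrs = as.integer(n_planted_dmrs),
              dmr_mean_len = dmr_mean_len, dmr_mean_cpgs = dmr_mean_cpgs,
              delta_beta = delta_beta,
              baseline_beta_range = baseline_beta_range,
              bb_dispersion = bb_dispersion, coverage_mean = coverage_mean,
              n_lnc_linked = as.integer(n_lnc_linked),
              n_lnc_decoy = as.integer(n_lnc_decoy),
              n_prot_linked = as.integer(n_prot_linked),
              n_prot_decoy = as.integer(n_prot_decoy),
              coupling_lnc = coupling_lnc, coupling_prot = coupling_prot,
              nb_dispersion = nb_dispersion,
              lnc_base_mean = lnc_base_mean, prot_base_mean = prot_base_mean,
              lnc_window = as.integer(lnc_window),
              prot_window = as.integer(prot_window),
              seed = as.integer(seed))
  stopifnot(cfg$n_case >= 0, cfg$n_control >= 0, cfg$n_cpg >= 0,
            cfg$n_planted_dmrs >= 0, length(cfg$genome) >= 1,
            all(cfg$genome > 0), cfg$bb_dispersion > 0,
            cfg$bb_dispersion < 1,
            cfg$lnc_window <= 20000L, cfg$prot_window <= 500000L,
            cfg$delta_beta >= 0, cfg$delta_beta <= 1)
  # zero is allowed for null-coupling experiments; positive makes the
  # planted links nonsensical
  if (cfg$n_lnc_linked > 0 && cfg$coupling_lnc > 0) {
    stop("coupling_lnc must be negative (or 0) for planted links")
  }
  if (cfg$n_prot_linked > 0 && cfg$coupling_prot > 0) {
    stop("coupling_prot must be negative (or 0) for planted links")
  }
  structure(cfg, class = "sim_config")
}

# beta-binomial draw: n trials, mean p, overdispersion rho
rbetabinom <- function(n_draws, size, p, rho) {
  p <- pmin(pmax(p, 1e-6), 1 - 1e-6)
  a <- p * (1 - rho) / rho
  b <- (1 - p) * (1 - rho) / rho
  rbinom(n_draws, size, rbeta(n_draws, a, b))
}

# evenly spaced, jittered non-overlapping anchor positions across the
# genome with a minimum separation; used for planted cassettes
place_anchors <- function(genome, n, min_sep) {
  if (n == 0L) return(data.table(chrom = character(), pos = numeric()))
  share <- genome / sum(genome)
  n_per <- diff(round(cumsum(c(0, share * n))))
  names(n_per) <- names(genome)
  out <- list()
  for (ch in names(genome)) {
    k <- n_per[[ch]]
    if (k == 0) next
    spacing <- genome[[ch]] / (k + 1)
    if (spacing < min_sep) {
      stop("cannot place ", n, " cassettes with ", min_sep,
           " bp separation; use a larger genome")
    }
    centers <- spacing * seq_len(k)
    jitter <- runif(k, -0.2, 0.2) * min(spacing - min_sep, 4e5)
    out[[ch]] <- data.table(chrom = ch, pos = round(centers + jitter))
  }
  rbindlist(out)
}

#' Simulate per-CpG methylation with planted DMRs
#'
#' Background CpG positions are placed uniformly at random over the genome
#' and sorted; each planted DMR is a run of about `Poisson(dmr_mean_cpgs)`
#' consecutive CpGs spanning about `Poisson(dmr_mean_len)` bp. Per site
#' and sample, coverage is Poisson and the methylated count is
#' beta-binomial around the site's group mean: background sites share one
#' baseline across groups; inside a hyper (hypo) DMR the case group's mean
#' is shifted by `+delta_beta` (`-delta_beta`), clipped to `[0.05, 0.95]`
#' by construction of the DMR baseline.
#'
#' Uses the current RNG state; seed with `set.seed()` (or via
#' [generate_study()]).
#'
#' @param config A [sim_config()].
#' @return List of class `meth_sim`: `cpg` (a `cpg_matrix`: sites, meth,
#'   cov, group), `true_dmrs` (`chrom`, `start`, `end`, `dmr_id`,
#'   `direction`, `n_cpgs`, 0-based half-open over the CpG extent),
#'   `sample_ids`, `group`, `dmr_site_baseline`.
#' @export
simulate_methylation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  g <- config$genome
  n_dmr <- config$n_planted_dmrs
  sample_ids <- c(sprintf("case_%02d", seq_len(config$n_case)),
                  sprintf("control_%02d", seq_len(config$n_control)))
  group <- rep(c("case", "control"), c(config$n_case, config$n_control))
  # cassette anchors, >= ~2.2x protein window apart so cassettes cannot
  # reach into each other's pairing windows
  anchors <- place_anchors(g, n_dmr, min_sep = 2.2 * config$prot_window)
  dmr_list <- lapply(seq_len(n_dmr), function(i) {
    len <- max(60L, rpois(1L, config$dmr_mean_len))
    ncpg <- max(2L, rpois(1L, config$dmr_mean_cpgs))
    offs <- sort(sample.int(len, min(ncpg, len)))
    pos <- anchors$pos[i] + offs          # 1-based CpG positions
    data.table(chrom = anchors$chrom[i], pos = pos,
               dmr = sprintf("dmr_%03d", i))
  })
  dmr_sites <- rbindlist(dmr_list)
  dmr_dir <- sample(c("hyper", "hypo"), n_dmr, replace = TRUE)
  names(dmr_dir) <- sprintf("dmr_%03d", seq_len(n_dmr))
  # per-DMR baseline leaving room for +/- delta within [0.05, 0.95]
  db <- config$delta_beta
  lo <- pmax(config$baseline_beta_range[1], 0.05)
  hi <- pmin(config$baseline_beta_range[2], 0.95)
  dmr_base <- ifelse(dmr_dir == "hyper",
                     runif(n_dmr, lo, pmin(hi, 0.95 - db)),
                     runif(n_dmr, pmax(lo, 0.05 + db), hi))
  names(dmr_base) <- names(dmr_dir)
  # background CpGs: uniform over the genome, outside planted DMR spans
  chrom_bg <- sample(names(g), config$n_cpg, replace = TRUE,
                     prob = g / sum(g))
  pos_bg <- floor(runif(config$n_cpg, 1, g[chrom_bg])) + 0
  bg <- unique(data.table(chrom = chrom_bg, pos = as.integer(pos_bg)))
  if (nrow(dmr_sites)) {
    spans <- dmr_sites[, .(s = min(pos), e = max(pos)), by = .(chrom, dmr)]
    for (i in seq_len(nrow(spans))) {
      bg <- bg[!(chrom == spans$chrom[i] &
                   pos >= spans$s[i] - 500L & pos <= spans$e[i] + 500L)]
    }
  }
  sites <- rbind(bg[, .(chrom, pos, dmr = NA_character_)],
                 dmr_sites[, .(chrom, pos = as.integer(pos), dmr)])
  setkey(sites, chrom, pos)
  n_sites <- nrow(sites)
  n_samp <- length(sample_ids)
  base_site <- ifelse(is.na(sites$dmr),
                      runif(n_sites, config$baseline_beta_range[1],
                            config$baseline_beta_range[2]),
                      dmr_base[sites$dmr])
  shift <- ifelse(is.na(sites$dmr), 0,
                  ifelse(dmr_dir[sites$dmr] == "hyper", db, -db))
  p_true <- matrix(base_site, n_sites, n_samp) +
    outer(shift, as.numeric(group == "case"))
  cov <- matrix(rpois(n_sites * n_samp, config$coverage_mean),
                n_sites, n_samp, dimnames = list(NULL, sample_ids))
  meth <- matrix(rbetabinom(n_sites * n_samp, as.vector(cov),
                            as.vector(p_true), config$bb_dispersion),
                 n_sites, n_samp, dimnames = list(NULL, sample_ids))
  storage.mode(meth) <- "integer"
  true_dmrs <- if (nrow(dmr_sites)) {
    td <- dmr_sites[, .(chrom = chrom[1L], start = as.integer(min(pos) - 1L),
                        end = as.integer(max(pos)), n_cpgs = .N),
                    by = .(dmr_id = dmr)]
    td[, direction := dmr_dir[dmr_id]]
    setcolorder(td, c("chrom", "start", "end", "dmr_id", "direction",
                      "n_cpgs"))
    setorder(td, chrom, start)[]
  } else {
    data.table(chrom = character(), start = integer(), end = integer(),
               dmr_id = character(), direction = character(),
               n_cpgs = integer())
  }
  cpg <- structure(list(sites = sites[, .(chrom, pos)], meth = meth,
                        cov = cov, group = group),
                   class = "cpg_matrix")
  structure(list(cpg = cpg, true_dmrs = true_dmrs,
                 sample_ids = sample_ids, group = group,
                 dmr_baseline = dmr_base, site_dmr = sites$dmr,
                 config = config),
            class = "meth_sim")
}

# realized per-sample mean beta of each true DMR
true_dmr_betas <- function(meth_sim) {
  region_beta_matrix(meth_sim$cpg, meth_sim$true_dmrs)
}

# place an interval of length len at gap bp from an anchor interval,
# choosing a side at random but flipping if the chromosome boundary is hit
place_near <- function(anchor_start, anchor_end, gap, len, chrom_len) {
  side <- sample(c(-1L, 1L), 1L)
  for (s in c(side, -side)) {
    if (s > 0) {
      st <- anchor_end + gap
      if (st + len <= chrom_len) return(c(st, st + len))
    } else {
      en <- anchor_start - gap
      if (en - len >= 0) return(c(en - len, en))
    }
  }
  stop("window constraint unsatisfiable on this genome; ",
       "increase chromosome lengths")
}

#' Simulate expression counts coupled to simulated methylation
#'
#' One linked lncRNA is planted per planted DMR (cycled if
#' `n_lnc_linked` exceeds the DMR count) within `lnc_window` of the DMR;
#' its counts are negative binomial with
#' `log mean = a_j + coupling_lnc * beta[d, s]`, where `beta[d, s]` is
#' the realized per-sample mean methylation of the DMR. One linked
#' protein-coding transcript is planted per linked lncRNA within
#' `prot_window`, with `log mean = c_k + coupling_prot * z[j, s]`, `z`
#' the standardized log of the realized lncRNA count (so the planted
#' causal chain runs through the lncRNA, not directly from the DMR).
#' Decoy transcripts have group-independent means; half of them are
#' placed inside cassette windows, the rest uniformly.
#'
#' @param config A [sim_config()].
#' @param meth A `meth_sim` from [simulate_methylation()].
#' @return List of class `expr_sim`: `counts` (integer matrix),
#'   `annotation`, `truth` (planted triplets: `dmr_id`,
#'   `lnc_transcript_id`, `prot_transcript_id`, `dmr_direction`,
#'   `planted`), `dmr_beta` (true-DMR beta matrix), `params` (per-feature
#'   intercepts for external replication).
#' @export
simulate_expression <- function(config, meth) {
  stopifnot(inherits(config, "sim_config"), inherits(meth, "meth_sim"))
  g <- config$genome
  td <- meth$true_dmrs
  n_samp <- length(meth$sample_ids)
  grp_case <- meth$group == "case"
  dmr_beta <- true_dmr_betas(meth)
  # fill the (rare) all-missing entries with the group mean so coupling
  # stays defined
  for (i in seq_len(nrow(dmr_beta))) {
    na <- is.na(dmr_beta[i, ])
    if (any(na)) {
      gm <- ifelse(grp_case, mean(dmr_beta[i, grp_case], na.rm = TRUE),
                   mean(dmr_beta[i, !grp_case], na.rm = TRUE))
      dmr_beta[i, na] <- gm[na]
    }
  }
  ann <- list(); counts <- list(); truth <- list()
  a_lnc <- c(); c_prot <- c()
  link_dmr <- character(); link_lnc <- character()
  # linked lncRNAs
  if (config$n_lnc_linked > 0 && nrow(td) == 0L) {
    stop("cannot plant linked lncRNAs without planted DMRs")
  }
  lnc_ids <- sprintf("LNC%04d", seq_len(config$n_lnc_linked))
  for (j in seq_len(config$n_lnc_linked)) {
    d <- ((j - 1L) %% nrow(td)) + 1L
    gap <- round(runif(1, 100, 0.6 * config$lnc_window))
    len <- round(runif(1, 500, 3000))
    iv <- place_near(td$start[d], td$end[d], gap, len, g[[td$chrom[d]]])
    a_j <- log(config$lnc_base_mean) - config$coupling_lnc * 0.5
    mu <- exp(a_j + config$coupling_lnc * dmr_beta[td$dmr_id[d], ])
    cnt <- rnbinom(n_samp, mu = mu, size = 1 / config$nb_dispersion)
    id <- lnc_ids[j]
    ann[[id]] <- data.table(transcript_id = id,
                            gene_id = paste0("G", id), gene_name = id,
                            biotype = "lncRNA", chrom = td$chrom[d],
                            start = as.integer(iv[1]),
                            end = as.integer(iv[2]), strand = "+")
    counts[[id]] <- cnt
    a_lnc[id] <- a_j
    link_dmr[id] <- td$dmr_id[d]
  }
  # linked proteins, anti-coupled to the realized lncRNA counts
  prot_ids <- sprintf("PROT%04d", seq_len(config$n_prot_linked))
  for (k in seq_len(config$n_prot_linked)) {
    j <- ((k - 1L) %% max(config$n_lnc_linked, 1L)) + 1L
    lnc_id <- lnc_ids[j]
    lnc_ann <- ann[[lnc_id]]
    gap <- round(runif(1, 30000, 0.6 * config$prot_window))
    len <- round(runif(1, 2000, 10000))
    iv <- place_near(lnc_ann$start, lnc_ann$end, gap, len,
                     g[[lnc_ann$chrom]])
    z <- as.vector(scale(log(counts[[lnc_id]] + 1)))
    c_k <- log(config$prot_base_mean)
    mu <- exp(c_k + config$coupling_prot * z)
    cnt <- rnbinom(n_samp, mu = mu, size = 1 / config$nb_dispersion)
    id <- prot_ids[k]
    ann[[id]] <- data.table(transcript_id = id,
                            gene_id = paste0("G", id), gene_name = id,
                            biotype = "protein_coding",
                            chrom = lnc_ann$chrom,
                            start = as.integer(iv[1]),
                            end = as.integer(iv[2]), strand = "+")
    counts[[id]] <- cnt
    c_prot[id] <- c_k
    link_lnc[id] <- lnc_id
    truth[[id]] <- data.table(dmr_id = link_dmr[lnc_id],
                              lnc_transcript_id = lnc_id,
                              prot_transcript_id = id,
                              dmr_direction =
                                td$direction[match(link_dmr[lnc_id],
                                                   td$dmr_id)],
                              planted = TRUE)
  }
  # decoys: group-independent means; half inside cassette windows
  add_decoy <- function(i, kind) {
    id <- sprintf("%s%04d", if (kind == "lncRNA") "DLNC" else "DPROT", i)
    len <- if (kind == "lncRNA") round(runif(1, 500, 3000)) else
      round(runif(1, 2000, 10000))
    in_window <- i %% 2L == 0L && nrow(td) > 0L
    if (in_window && kind == "lncRNA") {
      d <- sample.int(nrow(td), 1L)
      gap <- round(runif(1, 100, 0.9 * config$lnc_window))
      iv <- place_near(td$start[d], td$end[d], gap, len, g[[td$chrom[d]]])
      ch <- td$chrom[d]
    } else if (in_window && kind == "protein_coding" &&
               config$n_lnc_linked > 0) {
      lnc_ann <- ann[[sample(lnc_ids, 1L)]]
      gap <- round(runif(1, 10000, 0.9 * config$prot_window))
      iv <- place_near(lnc_ann$start, lnc_ann$end, gap, len,
                       g[[lnc_ann$chrom]])
      ch <- lnc_ann$chrom
    } else {
      ch <- sample(names(g), 1L, prob = g / sum(g))
      st <- floor(runif(1, 0, g[[ch]] - len))
      iv <- c(st, st + len)
    }
    mu <- exp(runif(1, log(20), log(500)))
    cnt <- rnbinom(n_samp, mu = mu, size = 1 / config$nb_dispersion)
    ann[[id]] <<- data.table(transcript_id = id,
                             gene_id = paste0("G", id), gene_name = id,
                             biotype = kind, chrom = ch,
                             start = as.integer(iv[1]),
                             end = as.integer(iv[2]), strand = "+")
    counts[[id]] <<- cnt
  }
  for (i in seq_len(config$n_lnc_decoy)) add_decoy(i, "lncRNA")
  for (i in seq_len(config$n_prot_decoy)) add_decoy(i, "protein_coding")
  annotation <- rbindlist(ann)
  setorder(annotation, chrom, start)
  cmat <- do.call(rbind, counts)[annotation$transcript_id, , drop = FALSE]
  colnames(cmat) <- meth$sample_ids
  storage.mode(cmat) <- "integer"
  truth <- if (length(truth)) rbindlist(truth) else
    data.table(dmr_id = character(), lnc_transcript_id = character(),
               prot_transcript_id = character(),
               dmr_direction = character(), planted = logical())
  structure(list(counts = cmat, annotation = annotation, truth = truth,
                 dmr_beta = dmr_beta,
                 params = list(a_lnc = a_lnc, c_prot = c_prot,
                               link_dmr = link_dmr, link_lnc = link_lnc),
                 group = meth$group, config = config),
            class = "expr_sim")
}

#' Simulate reference profiles and noisy cell-type mixtures
#'
#' Reference betas are Uniform(0, 1) per locus per cell type; mixture
#' weights are uniform on the simplex; each sample's beta vector is the
#' reference matrix times its weights plus Gaussian noise, clipped to
#' `[0, 1]`.
#'
#' @param n_regions Number of reference loci.
#' @param cell_types Character vector of cell-type names (default
#'   epithelial, fibroblast, immune).
#' @param n_samples Number of mixture samples.
#' @param noise_sd Gaussian noise standard deviation.
#' @return List: `reference` (`locus_id`, `chrom`, `pos`, one beta column
#'   per cell type), `mixtures` (loci x samples), `fractions` (samples x
#'   cell types, rows summing to 1).
#' @export
simulate_reference_mixtures <- function(n_regions = 200L,
                                        cell_types = c("epithelial",
                                                       "fibroblast",
                                                       "immune"),
                                        n_samples = 20L,
                                        noise_sd = 0.02) {
  k <- length(cell_types)
  stopifnot(k >= 2L)
  ref <- matrix(runif(n_regions * k), n_regions, k,
                dimnames = list(sprintf("locus_%04d", seq_len(n_regions)),
                                cell_types))
  e <- matrix(stats::rexp(n_samples * k), n_samples, k)
  w <- e / rowSums(e)           # uniform on the simplex
  rownames(w) <- sprintf("mix_%02d", seq_len(n_samples))
  colnames(w) <- cell_types
  mix <- ref %*% t(w) + matrix(rnorm(n_regions * n_samples, 0, noise_sd),
                               n_regions, n_samples)
  mix <- pmin(pmax(mix, 0), 1)
  colnames(mix) <- rownames(w)
  reference <- data.table(locus_id = rownames(ref), chrom = "chrR",
                          pos = as.integer(seq_len(n_regions) * 1000L))
  reference <- cbind(reference, as.data.table(ref))
  list(reference = reference, mixtures = mix, fractions = w)
}

#' Simulate independent verification expression datasets
#'
#' Draws new cohorts from the same planted regulatory chain as an
#' existing study: per-sample DMR betas are Gaussian around the planted
#' group means, linked lncRNAs and proteins reuse the study's intercepts
#' and couplings, and decoys keep group-independent means. With
#' `coupling = FALSE` both coupling slopes are set to zero, giving a null
#' replication cohort. Matrices are returned on the `log2(count + 1)`
#' scale ("normalized matrices").
#'
#' @param expr An `expr_sim` from [simulate_expression()].
#' @param n_datasets Number of datasets.
#' @param n_samples Samples per dataset (split evenly case/control).
#' @param coupling Keep the planted coupling (TRUE) or remove it (FALSE).
#' @return Named list of normalized matrices (features x samples).
#' @export
simulate_external_datasets <- function(expr, n_datasets = 3L,
                                       n_samples = 24L, coupling = TRUE) {
  stopifnot(inherits(expr, "expr_sim"))
  cfg <- expr$config
  meth_base <- rowMeans(expr$dmr_beta[, expr$group == "control",
                                      drop = FALSE])
  td_dir <- setNames(expr$truth$dmr_direction, expr$truth$dmr_id)
  c_lnc <- if (coupling) cfg$coupling_lnc else 0
  c_prot <- if (coupling) cfg$coupling_prot else 0
  ids <- rownames(expr$counts)
  out <- list()
  for (d in seq_len(n_datasets)) {
    n_case <- n_samples %/% 2L
    grp <- rep(c("case", "control"), c(n_case, n_samples - n_case))
    cnt <- matrix(0L, length(ids), n_samples,
                  dimnames = list(ids, sprintf("s%02d", seq_len(n_samples))))
    # new per-sample betas for the planted DMRs
    beta_new <- matrix(NA_real_, nrow(expr$dmr_beta), n_samples,
                       dimnames = list(rownames(expr$dmr_beta), NULL))
    for (r in rownames(beta_new)) {
      dirshift <- if (!r %in% names(td_dir)) 0 else
        if (td_dir[[r]] == "hyper") cfg$delta_beta else -cfg$delta_beta
      m <- meth_base[r] + dirshift * (grp == "case")
      beta_new[r, ] <- pmin(pmax(rnorm(n_samples, m, 0.05), 0), 1)
    }
    lnc_cnt <- list()
    for (id in names(expr$params$a_lnc)) {
      mu <- exp(expr$params$a_lnc[[id]] +
                  c_lnc * beta_new[expr$params$link_dmr[[id]], ])
      lnc_cnt[[id]] <- rnbinom(n_samples, mu = mu,
                               size = 1 / cfg$nb_dispersion)
      cnt[id, ] <- lnc_cnt[[id]]
    }
    for (id in names(expr$params$c_prot)) {
      lnc_id <- expr$params$link_lnc[[id]]
      z <- as.vector(scale(log(lnc_cnt[[lnc_id]] + 1)))
      z[!is.finite(z)] <- 0
      mu <- exp(expr$params$c_prot[[id]] + c_prot * z)
      cnt[id, ] <- rnbinom(n_samples, mu = mu,
                           size = 1 / cfg$nb_dispersion)
    }
    decoys <- setdiff(ids, c(names(expr$params$a_lnc),
                             names(expr$params$c_prot)))
    for (id in decoys) {
      mu <- exp(runif(1, log(20), log(500)))
      cnt[id, ] <- rnbinom(n_samples, mu = mu,
                           size = 1 / cfg$nb_dispersion)
    }
    out[[sprintf("external_%02d", d)]] <- log2(cnt + 1)
  }
  out
}

#' Generate and write a complete synthetic study
#'
#' Seeds the RNG from `config$seed`, simulates methylation and expression
#' and writes every fixture the pipeline consumes:
#' `meth/<sample>.CpG_report.txt.gz`, `true_dmrs.bed`, `counts.tsv`,
#' `samples.tsv`, `annotation.gtf`, `reference_profiles.tsv`,
#' `truth_triplets.tsv` and a `manifest.json` listing every emitted file
#' and the seed. Reference loci are constructed to overlap 70% of the
#' planted DMRs (one probe at the DMR midpoint), plus an equal number of
#' off-DMR loci. Identical configurations (including seed) give
#' byte-identical output trees.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created).
#' @return Invisibly, a list with the in-memory `meth` and `expr`
#'   simulations, the `reference` table and the file `manifest`.
#' @export
generate_study <- function(config = sim_config(), out_dir) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  dir.create(file.path(out_dir, "meth"), recursive = TRUE,
             showWarnings = FALSE)
  meth <- simulate_methylation(config)
  expr <- simulate_expression(config, meth)
  files <- character()
  # per-sample cytosine reports
  for (j in seq_along(meth$sample_ids)) {
    sid <- meth$sample_ids[j]
    tab <- data.table(chrom = meth$cpg$sites$chrom,
                      pos = meth$cpg$sites$pos, strand = "+",
                      meth = meth$cpg$meth[, j],
                      unmeth = meth$cpg$cov[, j] - meth$cpg$meth[, j])
    rel <- file.path("meth", paste0(sid, ".CpG_report.txt.gz"))
    write_cytosine_report(tab, file.path(out_dir, rel))
    files <- c(files, rel)
  }
  td <- meth$true_dmrs
  fwrite(td[, .(chrom, start, end, dmr_id, score = 0, strand = ".",
                qvalue = NA_real_, direction, n_cpgs)],
         file.path(out_dir, "true_dmrs.bed"), sep = "\t",
         col.names = FALSE)
  write_matrix(expr$counts, file.path(out_dir, "counts.tsv"),
               id_col = "transcript_id")
  write_table(data.table(sample_id = meth$sample_ids, group = meth$group),
              file.path(out_dir, "samples.tsv"))
  write_gtf(expr$annotation, file.path(out_dir, "annotation.gtf"))
  reference <- study_reference(td, config)
  write_table(reference, file.path(out_dir, "reference_profiles.tsv"))
  write_table(expr$truth, file.path(out_dir, "truth_triplets.tsv"))
  files <- c(files, "true_dmrs.bed", "counts.tsv", "samples.tsv",
             "annotation.gtf", "reference_profiles.tsv",
             "truth_triplets.tsv")
  manifest <- list(seed = config$seed, n_samples = length(meth$sample_ids),
                   files = sort(files))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(meth = meth, expr = expr, reference = reference,
                 manifest = manifest, out_dir = out_dir))
}

# reference profile overlapping 70% of true DMRs (probe at the DMR
# midpoint) plus an equal number of off-DMR loci
study_reference <- function(true_dmrs,
                            config,
                            cell_types = c("epithelial", "fibroblast",
                                           "immune")) {
  n_on <- floor(0.7 * nrow(true_dmrs))
  on_idx <- if (n_on > 0) sort(sample.int(nrow(true_dmrs), n_on)) else
    integer()
  on <- true_dmrs[on_idx,
                  .(chrom, pos = as.integer(floor((start + end) / 2)))]
  g <- config$genome
  n_off <- max(nrow(true_dmrs) - n_on, 1L)
  off <- data.table(
    chrom = sample(names(g), n_off, replace = TRUE, prob = g / sum(g)),
    pos = as.integer(floor(runif(n_off, 1, min(g)))))
  loci <- rbind(on, off)
  ref <- data.table(locus_id = sprintf("probe_%04d", seq_len(nrow(loci))),
                    chrom = loci$chrom, pos = loci$pos)
  for (ct in cell_types) ref[, (ct) := runif(.N)]
  ref[]
}

# minimal GTF writer (transcript features only, 1-based inclusive)
write_gtf <- function(annotation, path) {
  attrs <- sprintf(
    'gene_id "%s"; transcript_id "%s"; gene_name "%s"; transcript_type "%s";',
    annotation$gene_id, annotation$transcript_id, annotation$gene_name,
    annotation$biotype)
  lines <- paste(annotation$chrom, "dmrlinc_sim", "transcript",
                 annotation$start + 1L, annotation$end, ".",
                 annotation$strand, ".", attrs, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}
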