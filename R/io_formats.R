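# Readers and writers for the external formats the pipeline touches.
#
# Coordinate conventions: all internal intervals are 0-based half-open
# (BED-style). Cytosine positions stay 1-based as read from Bismark-style
# reports and are converted exactly once, at the interval-overlap boundary.
# Strand is carried through but never used in distance or overlap logic.

#' Read a Bismark-style per-cytosine CpG report
#'
#' Parses the seven-column tab-separated cytosine report emitted by Bismark's
#' `--cytosine_report` mode: chromosome, 1-based position, strand, count of
#' methylated reads, count of unmethylated reads, context, trinucleotide
#' context. Only CpG-context records (`context == "CG"`) are returned; input
#' order is preserved within each chromosome. Gzip compression is detected
#' from the file's magic bytes, not its extension.
#'
#' @param path Path to the report (plain text or gzip).
#' @param sample_id Sample identifier attached to the returned table;
#'   defaults to the file name stripped of report suffixes.
#' @return A `data.table` with columns `chrom`, `pos` (1-based), `strand`,
#'   `meth`, `unmeth`, carrying the sample id in attribute `sample_id`.
#'   Coverage is `meth + unmeth`.
#' @export
read_cytosine_report <- function(path, sample_id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(sample_id)) {
    sample_id <- sub("\\.(CpG_report\\.)?txt(\\.gz)?$", "", basename(path))
  }
  lines <- read_lines_maybe_gz(path)
  if (length(lines) == 0L) {
    warning("empty cytosine report: ", path)
    tab <- data.table(chrom = character(), pos = integer(),
                      strand = character(), meth = integer(),
                      unmeth = integer())
    setattr(tab, "sample_id", sample_id)
    return(tab)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 7L)) {
    bad <- which(nf != 7L)[1L]
    stop("malformed cytosine report line ", bad, " in ", path,
         ": expected 7 tab-separated columns, found ", nf[bad])
  }
  m <- matrix(unlist(fields, use.names = FALSE), ncol = 7L, byrow = TRUE)
  pos <- suppressWarnings(as.integer(m[, 2L]))
  meth <- suppressWarnings(as.integer(m[, 4L]))
  unmeth <- suppressWarnings(as.integer(m[, 5L]))
  bad <- which(is.na(pos) | is.na(meth) | is.na(unmeth) |
                 pos < 1L | meth < 0L | unmeth < 0L)
  if (length(bad)) {
    stop("malformed cytosine report line ", bad[1L], " in ", path,
         ": non-numeric position or negative count")
  }
  keep <- m[, 6L] == "CG"
  tab <- data.table(chrom = m[keep, 1L], pos = pos[keep],
                    strand = m[keep, 3L], meth = meth[keep],
                    unmeth = unmeth[keep])
  if (anyDuplicated(tab, by = c("chrom", "pos"))) {
    stop("duplicate (chrom, pos) records in ", path)
  }
  setattr(tab, "sample_id", sample_id)
  tab
}

#' Write a per-cytosine CpG report
#'
#' Inverse of [read_cytosine_report()]: emits the seven-column Bismark-style
#' layout with context `CG` and trinucleotide context `CGG`. A `.gz` suffix
#' selects gzip output (written with a zeroed timestamp, so identical tables
#' give byte-identical files).
#'
#' @param tab Table as returned by [read_cytosine_report()].
#' @param path Output path; gzip-compressed iff it ends in `.gz`.
#' @return `path`, invisibly.
#' @export
write_cytosine_report <- function(tab, path) {
  lines <- paste(tab$chrom, tab$pos, tab$strand, tab$meth, tab$unmeth,
                 "CG", "CGG", sep = "\t")
  write_lines_maybe_gz(lines, path)
  invisible(path)
}

read_lines_maybe_gz <- function(path) {
  magic <- readBin(path, "raw", n = 2L)
  con <- if (length(magic) == 2L && identical(magic, as.raw(c(0x1f, 0x8b)))) {
    gzfile(path, "rt")
  } else {
    file(path, "rt")
  }
  on.exit(close(con))
  readLines(con)
}

write_lines_maybe_gz <- function(lines, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeLines(lines, con)
}

#' Read a transcript annotation from GTF or BED
#'
#' Accepts either a GTF (1-based inclusive coordinates; transcript features
#' with `transcript_id`, `gene_id`, optional `gene_name` and a
#' `transcript_type`/`transcript_biotype`/`gene_type` attribute) or a
#' BED6+1 table whose seventh column is the biotype (already 0-based
#' half-open). All coordinates are normalized to 0-based half-open. Biotypes
#' other than `lncRNA` and `protein_coding` are retained but flagged
#' `other`.
#'
#' @param path Path ending in `.gtf`/`.gff` or `.bed`.
#' @return A `data.table` with columns `transcript_id`, `gene_id`,
#'   `gene_name`, `biotype`, `chrom`, `start`, `end` (0-based half-open),
#'   `strand`.
#' @export
read_annotation <- function(path) {
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  ann <- if (ext %in% c("gtf", "gff")) {
    read_annotation_gtf(path)
  } else if (ext == "bed") {
    read_annotation_bed(path)
  } else {
    stop("unknown annotation format extension '.", ext,
         "' (expected .gtf or .bed): ", path)
  }
  if (anyDuplicated(ann$transcript_id)) {
    stop("duplicated transcript_id in ", path)
  }
  if (any(ann$start >= ann$end)) {
    stop("annotation parse error: transcript with end <= start in ", path)
  }
  ann[!biotype %in% c("lncRNA", "protein_coding"), biotype := "other"]
  ann[]
}

read_annotation_gtf <- function(path) {
  gr <- tryCatch(
    rtracklayer::import(path, format = "gtf"),
    error = function(e) stop("GTF parse error in ", path, ": ",
                             conditionMessage(e))
  )
  md <- as.data.frame(gr)
  if ("type" %in% names(md)) md <- md[md$type == "transcript", , drop = FALSE]
  if (nrow(md) == 0L) stop("no transcript features in GTF: ", path)
  biotype <- md[["transcript_type"]]
  if (is.null(biotype)) biotype <- md[["transcript_biotype"]]
  if (is.null(biotype)) biotype <- md[["gene_type"]]
  if (is.null(biotype)) biotype <- rep("other", nrow(md))
  gene_name <- md[["gene_name"]]
  if (is.null(gene_name)) gene_name <- md[["gene_id"]]
  data.table(
    transcript_id = as.character(md$transcript_id),
    gene_id = as.character(md$gene_id),
    gene_name = as.character(gene_name),
    biotype = as.character(biotype),
    chrom = as.character(md$seqnames),
    start = as.integer(md$start) - 1L,   # 1-based inclusive -> 0-based half-open
    end = as.integer(md$end),
    strand = as.character(md$strand)
  )
}

read_annotation_bed <- function(path) {
  dt <- fread(path, header = FALSE, sep = "\t")
  if (ncol(dt) < 7L) {
    stop("BED annotation needs 7 columns (BED6 + biotype): ", path)
  }
  setnames(dt, 1:7, c("chrom", "start", "end", "transcript_id", "score",
                      "strand", "biotype"))
  dt[, `:=`(gene_id = transcript_id, gene_name = transcript_id)]
  dt[, .(transcript_id = as.character(transcript_id),
         gene_id, gene_name, biotype = as.character(biotype),
         chrom = as.character(chrom), start = as.integer(start),
         end = as.integer(end), strand = as.character(strand))]
}

#' Read a transcript-by-sample count matrix with its sample sheet
#'
#' The matrix is a TSV whose first column holds transcript ids and whose
#' header row holds sample ids; the sample sheet is a TSV mapping
#' `sample_id` to `group` (`case`/`control`). Counts must be non-negative
#' integers; every matrix sample must appear in the sheet.
#'
#' @param path Count matrix TSV.
#' @param sample_sheet Sample sheet TSV.
#' @return A list of class `count_matrix` with elements `counts` (integer
#'   matrix, transcripts x samples) and `group` (named character vector).
#' @export
read_count_matrix <- function(path, sample_sheet) {
  dt <- fread(path, sep = "\t", header = TRUE)
  ids <- as.character(dt[[1L]])
  mat <- as.matrix(dt[, -1L, with = FALSE])
  if (any(is.na(mat))) stop("missing cells in count matrix: ", path)
  if (any(mat < 0) || any(mat != round(mat))) {
    stop("non-integer or negative count in ", path)
  }
  storage.mode(mat) <- "integer"
  rownames(mat) <- ids
  sheet <- fread(sample_sheet, sep = "\t", header = TRUE)
  if (!all(c("sample_id", "group") %in% names(sheet))) {
    stop("sample sheet must have columns sample_id and group: ", sample_sheet)
  }
  missing <- setdiff(colnames(mat), sheet$sample_id)
  if (length(missing)) {
    stop("samples absent from sample sheet: ", paste(missing, collapse = ", "))
  }
  group <- setNames(as.character(sheet$group), sheet$sample_id)[colnames(mat)]
  bad <- setdiff(unique(group), c("case", "control"))
  if (length(bad)) stop("unknown group labels: ", paste(bad, collapse = ", "))
  if (any(table(factor(group, c("case", "control"))) < 2L)) {
    stop("need at least 2 samples per group")
  }
  structure(list(counts = mat, group = group), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "transcripts x",
      ncol(x$counts), "samples (",
      sum(x$group == "case"), "case /", sum(x$group == "control"),
      "control )\n")
  invisible(x)
}

#' Write and read result tables as TSV
#'
#' Plain TSV writers/readers used for every tabular artifact of the
#' pipeline; `read_table(write_table(x))` reproduces `x` field by field.
#'
#' @param x A data.frame or data.table.
#' @param path Output path.
#' @return `write_table` returns `path` invisibly; `read_table` a
#'   `data.table`.
#' @export
write_table <- function(x, path) {
  fwrite(as.data.table(x), path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_table
#' @export
read_table <- function(path) {
  fread(path, sep = "\t", header = TRUE, na.strings = "NA")
}

#' Write DMR calls as BED6+
#'
#' Columns: chrom, start, end, dmr_id, stat, strand (`.`), then qvalue,
#' direction and CpG count.
#'
#' @param dmrs DMR table from [call_dmrs()].
#' @param path Output path.
#' @export
write_dmr_bed <- function(dmrs, path) {
  bed <- data.table(chrom = dmrs$chrom, start = dmrs$start, end = dmrs$end,
                    name = dmrs$dmr_id, score = signif(dmrs$stat, 6),
                    strand = ".", qvalue = dmrs$qvalue,
                    direction = dmrs$direction, n_cpgs = dmrs$n_cpgs)
  fwrite(bed, path, sep = "\t", quote = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a DMR BED6+ file written by [write_dmr_bed()] (or an external
#' caller's regions in the same layout; missing statistic columns default
#' to `NA`).
#'
#' @param path BED path.
#' @return DMR `data.table` (`chrom`, `start`, `end`, `dmr_id`, `stat`,
#'   `qvalue`, `direction`, `n_cpgs`).
#' @export
read_dmr_bed <- function(path) {
  dt <- fread(path, header = FALSE, sep = "\t")
  n <- ncol(dt)
  out <- data.table(chrom = as.character(dt[[1L]]),
                    start = as.integer(dt[[2L]]),
                    end = as.integer(dt[[3L]]))
  out$dmr_id <- if (n >= 4L) as.character(dt[[4L]]) else
    paste0(out$chrom, ".", seq_len(nrow(out)))
  out$stat <- if (n >= 5L) as.numeric(dt[[5L]]) else NA_real_
  out$qvalue <- if (n >= 7L) as.numeric(dt[[7L]]) else NA_real_
  out$direction <- if (n >= 8L) as.character(dt[[8L]]) else NA_character_
  out$n_cpgs <- if (n >= 9L) as.integer(dt[[9L]]) else NA_integer_
  out
}

#' Read a normalized expression matrix (features x samples TSV)
#'
#' First column feature id, remaining columns numeric sample values. Used
#' for external verification datasets.
#'
#' @param path TSV path.
#' @return Numeric matrix with feature rownames.
#' @export
read_expression_matrix <- function(path) {
  dt <- fread(path, sep = "\t", header = TRUE)
  ids <- as.character(dt[[1L]])
  if (anyDuplicated(ids)) {
    stop("identifier collisions in expression matrix: ", path)
  }
  mat <- as.matrix(dt[, -1L, with = FALSE])
  rownames(mat) <- ids
  mat
}

#' Write a numeric matrix as TSV with an id column
#'
#' @param mat Matrix with rownames.
#' @param path Output path.
#' @param id_col Name for the id column.
#' @export
write_matrix <- function(mat, path, id_col = "feature_id") {
  dt <- data.table(id = rownames(mat))
  setnames(dt, "id", id_col)
  out <- cbind(dt, as.data.table(mat))
  fwrite(out, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}
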