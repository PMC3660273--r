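#' Probe-level intensity matrix
#'
#' Container for raw or preprocessed probe-level intensities: a probes x
#' samples matrix of non-negative linear-scale values, the chip geometry
#' (grid coordinates per probe) and a logical exclusion mask of the same
#' shape (`TRUE` = masked).
#'
#' @param values Numeric probes x samples matrix with unique rownames
#'   (probe ids) and colnames (sample ids); values must be non-negative.
#' @param geometry Data frame with columns `probe_id`, `x`, `y`, or `NULL`.
#' @param mask Logical matrix of the same shape (default all `FALSE`).
#' @return An object of class `intensity_matrix`.
#' @export
intensity_matrix <- function(values, geometry = NULL, mask = NULL) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || anyDuplicated(rownames(values))) {
    stop("values must have unique rownames (probe ids)", call. = FALSE)
  }
  if (any(values < 0, na.rm = TRUE)) {
    stop("intensities must be non-negative", call. = FALSE)
  }
  if (!is.null(geometry)) {
    stopifnot(all(c("probe_id", "x", "y") %in% names(geometry)))
    geometry <- geometry[match(rownames(values), geometry$probe_id), ,
                         drop = FALSE]
    rownames(geometry) <- NULL
  }
  if (is.null(mask)) {
    mask <- matrix(FALSE, nrow(values), ncol(values),
                   dimnames = dimnames(values))
  }
  stopifnot(is.logical(mask), identical(dim(mask), dim(values)))
  structure(list(values = values, geometry = geometry, mask = mask),
            class = "intensity_matrix")
}

#' @export
print.intensity_matrix <- function(x, ...) {
  cat(sprintf("intensity_matrix: %d probes x %d samples (%d masked entries)\n",
              nrow(x$values), ncol(x$values), sum(x$mask)))
  invisible(x)
}

#' @export
dim.intensity_matrix <- function(x) dim(x$values)

## ---------------------------------------------------------------------------
## Plain-text readers/writers for the standard artifact formats.

#' Write a reference transcriptome as FASTA
#'
#' Headers follow the `"<transcript_id> gene=<gene_id>"` convention that
#' [read_reference_fasta()] parses back.
#'
#' @param reference A [Biostrings::DNAStringSet] with `gene_id` metadata.
#' @param path Output path.
#' @export
write_reference_fasta <- function(reference, path) {
  out <- reference
  names(out) <- paste0(names(reference), " gene=", reference_gene_ids(reference))
  Biostrings::writeXStringSet(out, path)
  invisible(path)
}

#' Read a reference transcriptome from FASTA
#'
#' The gene id is parsed from the header token `gene=<id>`; headers without
#' one get `gene_id` equal to the transcript id (a genomic-DNA FASTA can be
#' supplied with `gene=GENOMIC` tokens to fold genomic matches into one
#' pseudo-gene).
#'
#' @param path FASTA file path.
#' @return A [Biostrings::DNAStringSet] named by transcript id with a
#'   `gene_id` metadata column.
#' @export
read_reference_fasta <- function(path) {
  ref <- Biostrings::readDNAStringSet(path)
  header <- names(ref)
  tx <- sub("\\s.*$", "", header)
  gid <- ifelse(grepl("gene=", header),
                sub(".*gene=([^[:space:]]+).*", "\\1", header), tx)
  names(ref) <- tx
  S4Vectors::mcols(ref)$gene_id <- gid
  ref
}

#' Write/read the probe design table
#'
#' Tab-separated with columns `probe_id`, `probe_set_id`, `sequence`, `x`,
#' `y`, `d3prime` plus any extra columns present (e.g. the generator's
#' target annotations).
#'
#' @param design Probe design data frame.
#' @param path TSV path.
#' @export
write_design_tsv <- function(design, path) {
  utils::write.table(design, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_design_tsv
#' @export
read_design_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write probe sequences as FASTA
#'
#' @param design Probe design data frame with `probe_id` and `sequence`.
#' @param path FASTA path.
#' @export
write_probe_fasta <- function(design, path) {
  s <- Biostrings::DNAStringSet(design$sequence)
  names(s) <- design$probe_id
  Biostrings::writeXStringSet(s, path)
  invisible(path)
}

#' Write/read a probe-level intensity matrix as TSV
#'
#' Rows are probes (first column `probe_id`), columns samples, linear scale.
#'
#' @param m An `intensity_matrix` (or bare matrix for writing).
#' @param path TSV path.
#' @param geometry Optional geometry data frame to attach when reading.
#' @export
write_intensity_tsv <- function(m, path) {
  v <- if (inherits(m, "intensity_matrix")) m$values else m
  df <- data.frame(probe_id = rownames(v), v, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_intensity_tsv
#' @export
read_intensity_tsv <- function(path, geometry = NULL) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  v <- as.matrix(df[, -1, drop = FALSE])
  rownames(v) <- df$probe_id
  intensity_matrix(v, geometry)
}

#' Write/read the sample sheet
#'
#' Columns `sample_id`, `preparation` (FF/FFPET), `kit`, `er_status`,
#' `pair_id`.
#'
#' @param sheet Sample sheet data frame.
#' @param path TSV path.
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.table(sheet, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sample_sheet
#' @export
read_sample_sheet <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write the ground truth as JSON
#'
#' @param truth A `ground_truth` object.
#' @param path JSON path.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Write a full simulated study to a directory
#'
#' Emits the reference FASTA, probe design TSV and FASTA, one intensity TSV
#' per cohort (`ff.tsv` and `<kit>.tsv`), the sample sheet and the
#' ground-truth JSON under fixed names.
#'
#' @param study Output of [simulate_study()].
#' @param outdir Output directory (created if missing).
#' @return `outdir`, invisibly.
#' @export
write_study <- function(study, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_reference_fasta(study$reference, file.path(outdir, "reference.fa"))
  write_design_tsv(study$design, file.path(outdir, "probes.tsv"))
  write_probe_fasta(study$design, file.path(outdir, "probes.fa"))
  write_intensity_tsv(study$cohort$ff, file.path(outdir, "intensities_ff.tsv"))
  for (k in names(study$cohort$ffpet)) {
    write_intensity_tsv(study$cohort$ffpet[[k]],
                        file.path(outdir, paste0("intensities_", k, ".tsv")))
  }
  write_sample_sheet(study$cohort$sheet, file.path(outdir, "samples.tsv"))
  write_truth_json(study$truth, file.path(outdir, "truth.json"))
  invisible(outdir)
}
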