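## Shared fixtures and independent oracles for the test suite.

suppressPackageStartupMessages({
  library(Biostrings)
})

## A deliberately small cohort so full simulate -> revise -> preprocess
## chains stay fast in unit tests.
small_config <- function(seed = 101, ...) {
  args <- list(
    seed = seed,
    n_genes = 40L,
    n_complete_mismatch_sets = 25L,
    frac_nonmatching_probes = 0.05,
    frac_crosshyb_probes = 0.03,
    control_transcript_length = 1998L,
    control_probe_spacing = 18L
  )
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(sim_config, args)
}

## One cached study + revision + FF expression shared by several test files.
.fixture_env <- new.env(parent = emptyenv())

cached_study <- function() {
  if (is.null(.fixture_env$study)) {
    cfg <- small_config(seed = 314)
    st <- simulate_study(cfg)
    rd <- revise_design(st$design, st$reference)
    rd <- with_complete_mismatch_sets(rd, st$design, st$reference)
    ei <- expression_index(st$cohort$ff, rd)
    .fixture_env$study <- list(config = cfg, study = st, revised = rd,
                               expr_ff = ei$expression, ei_ff = ei)
  }
  .fixture_env$study
}

## ---------------------------------------------------------------------------
## Independent brute-force Hamming matcher (the oracle for match_probe):
## vectorized sliding-window mismatch counting on integer-coded sequences,
## both orientations, no shared code with the package's matcher.

revcomp_chr <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

brute_mismatch_counts <- function(probe, transcript) {
  p <- utf8ToInt(probe)
  s <- utf8ToInt(transcript)
  L <- length(p)
  n <- length(s) - L + 1L
  if (n < 1L) return(integer(0))
  mm <- integer(n)
  for (j in seq_len(L)) {
    mm <- mm + (s[j:(j + n - 1L)] != p[j])
  }
  mm
}

brute_hits <- function(probe, reference, max_mismatches) {
  gene_ids <- S4Vectors::mcols(reference)$gene_id
  out <- list()
  for (t in seq_along(reference)) {
    txt <- as.character(reference[[t]])
    for (strand in c("forward", "revcomp")) {
      p <- if (strand == "forward") probe else revcomp_chr(probe)
      mm <- brute_mismatch_counts(p, txt)
      hit <- which(mm <= max_mismatches)
      if (length(hit)) {
        out[[length(out) + 1L]] <- data.frame(
          transcript_id = names(reference)[t], gene_id = gene_ids[t],
          offset = hit - 1L, strand = strand, mismatches = mm[hit],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(transcript_id = character(0), gene_id = character(0),
                      offset = integer(0), strand = character(0),
                      mismatches = integer(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$transcript_id, res$offset, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

## Random DNA helper for constructed references.
rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

make_reference <- function(seqs, gene_ids = NULL) {
  ref <- Biostrings::DNAStringSet(seqs)
  if (is.null(names(ref))) names(ref) <- sprintf("T%02d", seq_along(ref))
  if (is.null(gene_ids)) gene_ids <- sub("^T", "G", names(ref))
  S4Vectors::mcols(ref)$gene_id <- gene_ids
  ref
}

## Summarize one probe-set log2 matrix by median polish and return the
## pooled two-sample t statistic of ER+ vs ER-.
summ_t <- function(log2_probes, sheet) {
  mp <- median_polish(log2_probes)
  expr <- matrix(mp$overall + mean(mp$row) + mp$col, 1, ncol(log2_probes),
                 dimnames = list("S", sheet$sample_id))
  probe_set_t_test(expr, sheet, "S")$t_statistic
}

## Bare intensity_matrix from a numeric matrix (no chip geometry).
make_im <- function(v, probe_prefix = "p") {
  if (is.null(rownames(v))) rownames(v) <- paste0(probe_prefix, seq_len(nrow(v)))
  if (is.null(colnames(v))) colnames(v) <- paste0("s", seq_len(ncol(v)))
  intensity_matrix(v)
}
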