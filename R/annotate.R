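## In-silico probe re-annotation: map every probe against the reference
## transcriptome, classify probes and probe sets, and emit a revised design
## that keeps only uniquely matching probes, plus the complete-mismatch
## blank control sets used downstream for the limit of blank.

check_probe_sequence <- function(sequence, probe_id = "probe") {
  bad <- regexpr("[^ACGT]", sequence)
  if (bad > 0) {
    stop(sprintf("input error: %s contains non-ACGT character '%s' at position %d",
                 probe_id, substr(sequence, bad, bad), bad), call. = FALSE)
  }
  invisible(sequence)
}

#' Match a probe against a reference transcriptome
#'
#' Reports every window of every transcript, on the forward and
#' reverse-complement orientation, whose Hamming distance to the probe is at
#' most `max_mismatches` (no indels). Offsets are 0-based starts of the
#' aligned window on the transcript's forward strand; results are ordered by
#' (transcript_id, offset, strand).
#'
#' @param probe_sequence Probe sequence over `{A,C,G,T}`.
#' @param reference A [Biostrings::DNAStringSet] with `gene_id` metadata
#'   (see [read_reference_fasta()]).
#' @param max_mismatches Maximum tolerated mismatches (>= 0).
#' @param probe_id Probe name used in error messages.
#' @return Data frame of hits: `transcript_id`, `gene_id`, `offset`,
#'   `strand` (`"forward"`/`"revcomp"`), `mismatches`.
#' @export
match_probe <- function(probe_sequence, reference, max_mismatches = 0L,
                        probe_id = "probe") {
  stopifnot(is.character(probe_sequence), length(probe_sequence) == 1L,
            max_mismatches >= 0)
  check_probe_sequence(probe_sequence, probe_id)
  if (nchar(probe_sequence) > min(Biostrings::width(reference))) {
    stop("input error: probe longer than the shortest reference transcript",
         call. = FALSE)
  }
  gene_ids <- reference_gene_ids(reference)

  one_strand <- function(pat, strand) {
    m <- Biostrings::vmatchPattern(pat, reference,
                                   max.mismatch = max_mismatches,
                                   with.indels = FALSE, fixed = TRUE)
    n_per_tx <- S4Vectors::elementNROWS(m)
    if (sum(n_per_tx) == 0L) return(NULL)
    tx_idx <- rep(seq_along(reference), n_per_tx)
    starts <- unlist(IRanges::start(m), use.names = FALSE)
    mm <- vapply(seq_along(tx_idx), function(i) {
      Biostrings::neditStartingAt(pat, reference[[tx_idx[i]]],
                                  starting.at = starts[i],
                                  with.indels = FALSE, fixed = TRUE)
    }, integer(1))
    data.frame(transcript_id = names(reference)[tx_idx],
               gene_id = gene_ids[tx_idx],
               offset = starts - 1L,
               strand = strand,
               mismatches = mm,
               stringsAsFactors = FALSE)
  }

  pat <- Biostrings::DNAString(probe_sequence)
  hits <- rbind(one_strand(pat, "forward"),
                one_strand(Biostrings::reverseComplement(pat), "revcomp"))
  if (is.null(hits)) {
    hits <- data.frame(transcript_id = character(0), gene_id = character(0),
                       offset = integer(0), strand = character(0),
                       mismatches = integer(0), stringsAsFactors = FALSE)
  }
  hits <- hits[order(hits$transcript_id, hits$offset, hits$strand), ,
               drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Classify a probe from its perfect-match hits
#'
#' @param hits Hit data frame from [match_probe()] run at 0 mismatches.
#' @return `"NO_MATCH"` (no hit), `"MATCH_UNIQUE"` (all hits in one gene) or
#'   `"MATCH_MULTI"` (hits in several genes).
#' @export
classify_probe <- function(hits) {
  if (nrow(hits) == 0L) return("NO_MATCH")
  if (length(unique(hits$gene_id)) == 1L) "MATCH_UNIQUE" else "MATCH_MULTI"
}

## Perfect-match classification of every probe in one pass: a probe is
## MATCH_UNIQUE/MATCH_MULTI according to the number of distinct genes hit at
## 0 mismatches on either orientation, NO_MATCH if none. Returns the class
## and, for unique probes, the matched gene.
classify_probes_bulk <- function(sequences, reference) {
  gene_ids <- reference_gene_ids(reference)
  genes_hit <- vector("list", length(sequences))
  for (str in c("forward", "revcomp")) {
    pd <- Biostrings::DNAStringSet(sequences)
    if (str == "revcomp") pd <- Biostrings::reverseComplement(pd)
    pdict <- Biostrings::PDict(pd)
    for (t in seq_along(reference)) {
      idx <- Biostrings::whichPDict(pdict, reference[[t]])
      if (length(idx)) {
        for (i in idx) genes_hit[[i]] <- c(genes_hit[[i]], gene_ids[t])
      }
    }
  }
  cls <- vapply(genes_hit, function(g) {
    if (is.null(g)) "NO_MATCH"
    else if (length(unique(g)) == 1L) "MATCH_UNIQUE"
    else "MATCH_MULTI"
  }, character(1))
  gene <- vapply(genes_hit, function(g) {
    if (!is.null(g) && length(unique(g)) == 1L) g[1] else NA_character_
  }, character(1))
  data.frame(probe_class = cls, gene_id = gene, stringsAsFactors = FALSE)
}

#' Revise an array design against a reference transcriptome
#'
#' Re-annotates every probe at 0 mismatches and divides the probe sets into
#' three classes, mirroring in-silico probe-set revision of
#' short-oligonucleotide arrays: `unique` sets retain at least
#' `min_retained` uniquely matching probes (only those probes are kept);
#' sets that fall short but contain at least one multi-gene probe are
#' `nonunique`; the rest are `mismatched`. The classes partition all probe
#' sets.
#'
#' @param design Probe design data frame (columns `probe_id`,
#'   `probe_set_id`, `sequence`).
#' @param reference Reference transcriptome ([Biostrings::DNAStringSet]).
#' @param min_retained Minimum number of retained unique probes for a set to
#'   stay usable (default 3; median polish needs at least 2 probes, 3 adds
#'   robustness).
#' @return An object of class `revised_design`: list with `probes` (probe_id,
#'   probe_set_id, probe_class, retained), `sets` (probe_set_id, set_class,
#'   gene_id, n_probes, n_retained) and `complete_mismatch_set_ids`
#'   (filled by [build_complete_mismatch_set()], initially empty).
#' @export
revise_design <- function(design, reference, min_retained = 3L) {
  stopifnot(nrow(design) > 0)
  if (anyDuplicated(design$probe_id)) {
    stop("input error: duplicate probe_id in design", call. = FALSE)
  }
  for (i in seq_len(nrow(design))) {
    check_probe_sequence(design$sequence[i], design$probe_id[i])
  }
  bulk <- classify_probes_bulk(design$sequence, reference)

  probes <- data.frame(probe_id = design$probe_id,
                       probe_set_id = design$probe_set_id,
                       probe_class = bulk$probe_class,
                       gene_id = bulk$gene_id,
                       stringsAsFactors = FALSE)
  sp <- split(probes, probes$probe_set_id)
  sets <- do.call(rbind, lapply(sp, function(p) {
    n_unique <- sum(p$probe_class == "MATCH_UNIQUE")
    set_class <- if (n_unique >= min_retained) "unique"
    else if (any(p$probe_class == "MATCH_MULTI")) "nonunique"
    else "mismatched"
    g <- p$gene_id[p$probe_class == "MATCH_UNIQUE"]
    gene <- if (set_class == "unique" && length(g)) names(which.max(table(g)))
    else NA_character_
    data.frame(probe_set_id = p$probe_set_id[1], set_class = set_class,
               gene_id = gene, n_probes = nrow(p),
               n_retained = if (set_class == "unique") n_unique else 0L,
               stringsAsFactors = FALSE)
  }))
  rownames(sets) <- NULL
  probes$retained <- probes$probe_class == "MATCH_UNIQUE" &
    probes$probe_set_id %in% sets$probe_set_id[sets$set_class == "unique"]

  structure(list(probes = probes, sets = sets,
                 complete_mismatch_set_ids = character(0),
                 min_retained = min_retained),
            class = "revised_design")
}

#' @export
print.revised_design <- function(x, ...) {
  tab <- table(factor(x$sets$set_class,
                      levels = c("unique", "nonunique", "mismatched")))
  cat(sprintf(paste0("revised_design: %d probe sets ",
                     "(%d unique / %d nonunique / %d mismatched), ",
                     "%d of %d probes retained, %d blank control sets\n"),
              nrow(x$sets), tab[["unique"]], tab[["nonunique"]],
              tab[["mismatched"]], sum(x$probes$retained), nrow(x$probes),
              length(x$complete_mismatch_set_ids)))
  invisible(x)
}

#' Identify complete-mismatch (blank) probe sets
#'
#' Returns the probe sets all of whose probes have zero hits in the
#' reference at Hamming distance up to `max_mismatches` on either
#' orientation. These sets measure pure background and provide the blank
#' distribution for the limit of blank.
#'
#' @param design Probe design data frame.
#' @param reference Reference transcriptome.
#' @param max_mismatches Mismatch tolerance for "fails to match" (default 3).
#' @return Character vector of probe-set ids (possibly empty, with a
#'   warning).
#' @export
build_complete_mismatch_set <- function(design, reference, max_mismatches = 3L) {
  hit <- vapply(seq_len(nrow(design)), function(i) {
    count_hits_any(design$sequence[i], reference, max_mismatches) > 0L
  }, logical(1))
  set_hit <- tapply(hit, design$probe_set_id, any)
  ids <- names(set_hit)[!set_hit]
  if (length(ids) == 0L) {
    warning("no complete-mismatch probe sets found; the limit of blank ",
            "cannot be computed downstream", call. = FALSE)
  }
  sort(ids)
}

#' Attach blank control sets to a revised design
#'
#' Convenience wrapper that records the output of
#' [build_complete_mismatch_set()] on the revised design object.
#'
#' @param revised A `revised_design`.
#' @param design,reference,max_mismatches Passed to
#'   [build_complete_mismatch_set()].
#' @return The `revised_design` with `complete_mismatch_set_ids` filled.
#' @export
with_complete_mismatch_sets <- function(revised, design, reference,
                                        max_mismatches = 3L) {
  stopifnot(inherits(revised, "revised_design"))
  revised$complete_mismatch_set_ids <-
    build_complete_mismatch_set(design, reference, max_mismatches)
  revised
}

#' Materialize the revised design as probe records
#'
#' Restricts a design table to the probes retained by the revision (the
#' uniquely matching probes of `unique` sets), e.g. to write the revised
#' probe TSV or to re-run the revision for an idempotence check.
#'
#' @param design Original probe design data frame.
#' @param revised Matching `revised_design`.
#' @return The subset of `design` rows that are retained.
#' @export
retained_probes <- function(design, revised) {
  stopifnot(inherits(revised, "revised_design"))
  keep <- revised$probes$probe_id[revised$probes$retained]
  design[design$probe_id %in% keep, , drop = FALSE]
}

#' Write the revised design tables
#'
#' Emits a probe-set level TSV (`probe_set_id`, `set_class`, `gene_id`,
#' `retained_probe_ids` comma-separated) and a probe-class TSV.
#'
#' @param revised A `revised_design`.
#' @param set_path,probe_path Output TSV paths.
#' @export
write_revised_design_tsv <- function(revised, set_path, probe_path) {
  stopifnot(inherits(revised, "revised_design"))
  kept <- split(revised$probes$probe_id[revised$probes$retained],
                revised$probes$probe_set_id[revised$probes$retained])
  sets <- revised$sets
  sets$retained_probe_ids <- vapply(sets$probe_set_id, function(id) {
    paste(kept[[id]], collapse = ",")
  }, character(1))
  utils::write.table(sets, set_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(revised$probes, probe_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(set_path)
}
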