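## Synthetic matched FF/FFPET cohort generator.
##
## The generator emulates the statistical structure the downstream analysis
## assumes: a reference transcriptome, a short-oligo array design with
## planted flaws (nonmatching and cross-hybridizing probes, whole blank
## "complete mismatch" control sets), and matched fresh-frozen / FFPET
## probe-level intensity cohorts in which the mirrored sections of a tumor
## share one latent expression draw and the FFPET arm is additionally
## degraded per kit (3' bias, attenuation, extra noise, dropout).

DNA_BASES <- c("A", "C", "G", "T")

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

## Total hit count of a probe (both orientations) anywhere in the reference
## at Hamming distance <= max_mismatches.
count_hits_any <- function(seq, reference, max_mismatches) {
  pat <- Biostrings::DNAString(seq)
  n <- sum(Biostrings::vcountPattern(pat, reference,
                                     max.mismatch = max_mismatches,
                                     with.indels = FALSE, fixed = TRUE))
  n + sum(Biostrings::vcountPattern(Biostrings::reverseComplement(pat),
                                    reference,
                                    max.mismatch = max_mismatches,
                                    with.indels = FALSE, fixed = TRUE))
}

## Draw a random probe-length sequence verified absent from the reference at
## Hamming distance <= 3 on both orientations.
random_absent_seq <- function(reference, probe_length, max_tries = 50L) {
  for (i in seq_len(max_tries)) {
    cand <- random_dna(probe_length)
    if (count_hits_any(cand, reference, 3L) == 0L) return(cand)
  }
  stop("generation error: could not find a reference-absent sequence after ",
       max_tries, " tries", call. = FALSE)
}

#' Generate a random reference transcriptome
#'
#' Produces one transcript per gene with i.i.d. uniform base composition and
#' lengths drawn uniformly from `config$transcript_length_range`. Gene ids
#' are `G0001, ...` with transcript ids `T0001, ...`; the FASTA header
#' convention downstream is `"<transcript_id> gene=<gene_id>"`.
#'
#' @param config A [sim_config()] object.
#' @return A [Biostrings::DNAStringSet] named by transcript id, with a
#'   `gene_id` metadata column.
#' @export
generate_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set_sim_seed(config$seed)
  n <- config$n_genes
  rng <- config$transcript_length_range
  lens <- rng[1] + sample.int(rng[2] - rng[1] + 1L, n, replace = TRUE) - 1L
  seqs <- vapply(lens, random_dna, character(1))
  ref <- Biostrings::DNAStringSet(seqs)
  names(ref) <- sprintf("T%04d", seq_len(n))
  S4Vectors::mcols(ref)$gene_id <- sprintf("G%04d", seq_len(n))
  ref
}

reference_gene_ids <- function(reference) {
  gid <- S4Vectors::mcols(reference)$gene_id
  if (is.null(gid)) stop("reference has no gene_id metadata column", call. = FALSE)
  gid
}

## 3'-distance of a probe window: distance from the probe's 3'-most aligned
## base to the transcript 3' end (0 for a probe ending on the last base).
d3prime_of <- function(tx_len, start, probe_length) {
  tx_len - (start + probe_length - 1L)
}

#' Generate a flawed array design with ground truth
#'
#' Tiles each gene with 1-3 probe sets of `probes_per_set` exact-substring
#' probes, then plants the design flaws the probe-set revision is meant to
#' find: a fraction of probes is replaced by random sequences verified
#' absent from the reference at Hamming distance <= 3 (nonmatching), a
#' fraction is made cross-hybridizing by copying the probe's target
#' subsequence into a second gene's transcript (the returned reference is
#' mutated accordingly), and `n_complete_mismatch_sets` whole sets of
#' verified-absent probes are appended as blank controls. A dedicated
#' intact-RNA QC control transcript, densely tiled with probes and excluded
#' from flaw planting and differential expression, is appended to the
#' reference. Chip grid coordinates are assigned by random permutation of a
#' square grid. Planted flaw counts use `round()` of fraction times the
#' number of eligible (non-control) probes.
#'
#' Per-gene expression truth (log2 baseline, ER effect `delta`, silent
#' status) is drawn here so that the same design can be paired with several
#' degradation settings downstream.
#'
#' @param reference Output of [generate_reference()].
#' @param config The [sim_config()] used to generate it.
#' @return A list with elements `design` (data frame: probe_id,
#'   probe_set_id, sequence, x, y, d3prime, target_transcript, target_gene),
#'   `truth` (a `ground_truth` object) and `reference` (the mutated
#'   [Biostrings::DNAStringSet] including the control transcript).
#' @export
generate_array_design <- function(reference, config) {
  stopifnot(inherits(config, "sim_config"))
  if (length(reference) == 0) stop("reference must be non-empty", call. = FALSE)
  set_sim_seed(config$seed + 1L)
  L <- config$probe_length
  pps <- config$probes_per_set

  tx_ids <- names(reference)
  gene_ids <- reference_gene_ids(reference)
  tx_len <- Biostrings::width(reference)

  ## --- control transcript, tiled probes ---------------------------------
  ctrl_len <- config$control_transcript_length
  ctrl_seq <- random_dna(ctrl_len)
  ctrl_tx <- "TQC01"
  ctrl_gene <- "QCCTRL"
  ctrl_starts <- seq(1L, ctrl_len - L + 1L, by = config$control_probe_spacing)

  ## --- per-gene probe sets ----------------------------------------------
  n_sets_per_gene <- as.integer(sample(
    names(config$probe_sets_per_gene), length(reference), replace = TRUE,
    prob = config$probe_sets_per_gene))

  rows <- vector("list", length(reference) + 2L)
  for (g in seq_along(reference)) {
    sets <- lapply(seq_len(n_sets_per_gene[g]), function(s) {
      npos <- tx_len[g] - L + 1L
      starts <- sort(sample.int(npos, pps, replace = npos < pps))
      data.frame(
        probe_set_id = sprintf("PS_%s_%d", gene_ids[g], s),
        probe_index = seq_len(pps),
        start = starts,
        target_transcript = tx_ids[g],
        target_gene = gene_ids[g],
        tx_len = tx_len[g],
        stringsAsFactors = FALSE
      )
    })
    rows[[g]] <- do.call(rbind, sets)
  }
  ## control probe sets: consecutive tiles grouped into sets of pps
  n_ctrl_sets <- length(ctrl_starts) %/% pps
  ctrl_starts <- ctrl_starts[seq_len(n_ctrl_sets * pps)]
  rows[[length(reference) + 1L]] <- data.frame(
    probe_set_id = sprintf("PS_QC_%d", rep(seq_len(n_ctrl_sets), each = pps)),
    probe_index = rep(seq_len(pps), n_ctrl_sets),
    start = ctrl_starts,
    target_transcript = ctrl_tx,
    target_gene = ctrl_gene,
    tx_len = ctrl_len,
    stringsAsFactors = FALSE
  )
  design <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  design$probe_id <- sprintf("%s_p%02d", design$probe_set_id, design$probe_index)
  design$d3prime <- d3prime_of(design$tx_len, design$start, L)

  ## working copy of sequences (character) for mutation and extraction
  seqs <- c(as.character(reference), ctrl_seq)
  names(seqs) <- c(tx_ids, ctrl_tx)
  design$sequence <- substr(seqs[design$target_transcript], design$start,
                            design$start + L - 1L)
  design$class <- "matching-unique"
  design$crosshyb_gene <- NA_character_
  design$crosshyb_transcript <- NA_character_
  design$crosshyb_d3prime <- NA_integer_

  ## --- plant flaws (non-control probes only) ----------------------------
  eligible <- which(design$target_gene != ctrl_gene)
  n_nonmatch <- round(config$frac_nonmatching_probes * length(eligible))
  n_crosshyb <- round(config$frac_crosshyb_probes * length(eligible))

  ## cross-hyb candidates must not share their target window with any other
  ## probe (at >= L-3 overlap another probe would inherit the planted copy)
  overlaps_other <- vapply(eligible, function(i) {
    same_tx <- design$target_transcript == design$target_transcript[i]
    same_tx[i] <- FALSE
    any(abs(design$start[same_tx] - design$start[i]) < L)
  }, logical(1))
  cross_pool <- eligible[!overlaps_other]
  if (length(cross_pool) < n_crosshyb) {
    stop("generation error: too few isolated probe windows for cross-",
         "hybridization planting", call. = FALSE)
  }
  cross_idx <- if (n_crosshyb > 0) sample(cross_pool, n_crosshyb) else integer(0)
  nonmatch_idx <- if (n_nonmatch > 0) {
    sample(setdiff(eligible, cross_idx), n_nonmatch)
  } else integer(0)

  ## cross-hybridization: copy the probe's target 25-mer into a second gene,
  ## at a position not overlapping any existing probe window there
  gene_of_tx <- c(stats::setNames(gene_ids, tx_ids),
                  stats::setNames(ctrl_gene, ctrl_tx))
  for (i in cross_idx) {
    partners <- which(tx_ids != design$target_transcript[i])
    placed <- FALSE
    for (p in sample(partners)) {
      cand <- seq_len(tx_len[p] - L + 1L)
      occupied <- design$start[design$target_transcript == tx_ids[p]]
      ok <- cand[vapply(cand, function(s) all(abs(occupied - s) >= L), logical(1))]
      if (!length(ok)) next
      s2 <- if (length(ok) == 1L) ok else sample(ok, 1L)
      substr(seqs[tx_ids[p]], s2, s2 + L - 1L) <- design$sequence[i]
      design$class[i] <- "crosshyb"
      design$crosshyb_gene[i] <- gene_ids[p]
      design$crosshyb_transcript[i] <- tx_ids[p]
      design$crosshyb_d3prime[i] <- d3prime_of(tx_len[p], s2, L)
      placed <- TRUE
      break
    }
    if (!placed) {
      stop("generation error: no free window for cross-hybridization planting",
           call. = FALSE)
    }
  }

  mutated <- Biostrings::DNAStringSet(seqs)
  S4Vectors::mcols(mutated)$gene_id <- unname(gene_of_tx[names(seqs)])

  ## nonmatching probes: random sequences absent at Hamming <= 3
  for (i in nonmatch_idx) {
    design$sequence[i] <- random_absent_seq(mutated, L)
    design$class[i] <- "nonmatching"
  }

  ## complete-mismatch control sets
  cm <- NULL
  if (config$n_complete_mismatch_sets > 0) {
    cm_ids <- sprintf("PS_CM%03d", seq_len(config$n_complete_mismatch_sets))
    cm <- data.frame(
      probe_set_id = rep(cm_ids, each = pps),
      probe_index = rep(seq_len(pps), config$n_complete_mismatch_sets),
      start = NA_integer_,
      target_transcript = NA_character_,
      target_gene = NA_character_,
      tx_len = NA_integer_,
      stringsAsFactors = FALSE
    )
    cm$probe_id <- sprintf("%s_p%02d", cm$probe_set_id, cm$probe_index)
    cm$d3prime <- NA_integer_
    cm$sequence <- vapply(seq_len(nrow(cm)), function(i) {
      random_absent_seq(mutated, L)
    }, character(1))
    cm$class <- "nonmatching"
    cm$crosshyb_gene <- NA_character_
    cm$crosshyb_transcript <- NA_character_
    cm$crosshyb_d3prime <- NA_integer_
    design <- rbind(design, cm)
  }

  ## chip grid coordinates: random permutation of a square grid
  side <- ceiling(sqrt(nrow(design)))
  cells <- sample.int(side * side, nrow(design)) - 1L
  design$x <- cells %% side
  design$y <- cells %/% side

  ## --- per-gene expression truth ----------------------------------------
  n <- length(reference)
  n_de <- round(config$frac_de_genes * n)
  n_silent <- round(config$frac_silent_genes * n)
  if (n_de + n_silent > n) {
    stop("configuration error: field 'frac_silent_genes' leaves no room for ",
         "the DE fraction", call. = FALSE)
  }
  de_idx <- sample.int(n, n_de)
  silent_idx <- sample(setdiff(seq_len(n), de_idx), n_silent)
  delta <- numeric(n)
  delta[de_idx] <- sample(c(-1, 1), n_de, replace = TRUE) *
    stats::runif(n_de, config$effect_range[1], config$effect_range[2])
  genes <- data.frame(
    gene_id = c(gene_ids, ctrl_gene),
    transcript_id = c(tx_ids, ctrl_tx),
    length = c(tx_len, ctrl_len),
    baseline = stats::rnorm(n + 1L, config$baseline_mean, config$baseline_sd),
    delta = c(delta, 0),
    is_de = c(seq_len(n) %in% de_idx, FALSE),
    silent = c(seq_len(n) %in% silent_idx, FALSE),
    stringsAsFactors = FALSE
  )

  truth <- structure(
    list(
      genes = genes,
      probes = design[, c("probe_id", "probe_set_id", "class", "target_gene",
                          "target_transcript", "d3prime", "crosshyb_gene",
                          "crosshyb_transcript", "crosshyb_d3prime")],
      complete_mismatch_sets = if (is.null(cm)) character(0) else
        unique(cm$probe_set_id),
      control = list(gene_id = ctrl_gene, transcript_id = ctrl_tx,
                     length = ctrl_len)
    ),
    class = "ground_truth"
  )

  design_out <- design[, c("probe_id", "probe_set_id", "sequence", "x", "y",
                           "d3prime", "target_transcript", "target_gene")]
  rownames(design_out) <- NULL
  rownames(truth$probes) <- NULL
  list(design = design_out, truth = truth, reference = mutated)
}

#' Expected probe-set classes implied by the planted ground truth
#'
#' Applies the probe-set revision decision rule (a set stays `unique` if it
#' retains at least `min_retained` uniquely matching probes; otherwise it is
#' `nonunique` if any probe cross-hybridizes and `mismatched` if not) to the
#' generator's planted probe classes, giving the class each probe set should
#' receive from [revise_design()].
#'
#' @param truth A `ground_truth` object.
#' @param min_retained Minimum number of unique probes for a set to stay
#'   usable (default 3, as in [revise_design()]).
#' @return Named character vector of expected classes, one per probe set.
#' @export
truth_set_classes <- function(truth, min_retained = 3L) {
  stopifnot(inherits(truth, "ground_truth"))
  sp <- split(truth$probes$class, truth$probes$probe_set_id)
  vapply(sp, function(cl) {
    if (sum(cl == "matching-unique") >= min_retained) "unique"
    else if (any(cl == "crosshyb")) "nonunique"
    else "mismatched"
  }, character(1))
}

#' Simulate matched FF and FFPET intensity cohorts
#'
#' Each tumor contributes one latent log2 expression draw
#' `e_gs = baseline_g + delta_g * [ER+] + tissue noise`, shared by its
#' mirrored FF and FFPET sections. The FF probe-level log2 signal is
#' `e_gs + affinity_p + N(0, measurement_sd_ff)`; the FFPET signal for kit
#' `k` reuses the same latent components minus
#' `global_attenuation + three_prime_decay * d3prime_p`, times extra log2
#' noise `N(0, extra_noise_sd)`, with probes dropped out at `dropout_prob`
#' replaced by background. Intensities are emitted on the linear scale as
#' `2^signal + background`, floored at 1; nonmatching and complete-mismatch
#' probes (and probes of silent genes) emit background only; a
#' cross-hybridizing probe emits the sum of both source genes' linear
#' signals. The background draw is shared between the FF and FFPET arms of a
#' tumor, so an all-zero degradation profile yields an FFPET matrix
#' identical to FF.
#'
#' @param reference Mutated reference from [generate_array_design()].
#' @param design Design data frame from [generate_array_design()].
#' @param truth Matching `ground_truth` object.
#' @param config The [sim_config()] in force.
#' @return A `sim_cohort` list: `ff` (an `intensity_matrix`), `ffpet` (named
#'   list of `intensity_matrix`, one per kit), `sheet` (sample sheet data
#'   frame: sample_id, preparation, kit, er_status, pair_id).
#' @export
simulate_cohort <- function(reference, design, truth, config) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "ground_truth"))
  if (!all(design$probe_id == truth$probes$probe_id)) {
    stop("design and truth are inconsistent (probe ids differ)", call. = FALSE)
  }
  kits <- names(config$kit_profiles)
  if (length(kits) == 0) stop("configuration error: field 'kit_profiles' is empty",
                              call. = FALSE)

  n_pairs <- 2L * config$n_pairs_per_group
  tumors <- sprintf("P%02d", seq_len(n_pairs))
  er <- rep(c("ER+", "ER-"), each = config$n_pairs_per_group)

  genes <- truth$genes
  np <- nrow(design)

  set_sim_seed(config$seed + 2L)
  tissue <- matrix(stats::rnorm(nrow(genes) * n_pairs, 0, config$tissue_sd),
                   nrow(genes), n_pairs)
  affinity <- stats::rnorm(np, 0, config$probe_affinity_sd)
  eps <- matrix(stats::rnorm(np * n_pairs, 0, config$measurement_sd_ff),
                np, n_pairs)
  bg <- matrix(stats::rnorm(np * n_pairs, config$background_mean,
                            config$background_sd), np, n_pairs)
  bg <- pmax(bg, 0)

  latent <- genes$baseline + outer(genes$delta, as.numeric(er == "ER+")) + tissue

  gi <- match(truth$probes$target_gene, genes$gene_id)
  hi <- match(truth$probes$crosshyb_gene, genes$gene_id)
  silent_gene <- genes$silent[gi]
  silent_gene[is.na(silent_gene)] <- TRUE
  active <- truth$probes$class != "nonmatching" & !silent_gene
  partner_silent <- genes$silent[hi]
  is_cross <- truth$probes$class == "crosshyb" & !is.na(hi) &
    !ifelse(is.na(partner_silent), TRUE, partner_silent)

  s1 <- matrix(0, np, n_pairs)
  s1[active, ] <- latent[gi[active], , drop = FALSE] + affinity[active] +
    eps[active, , drop = FALSE]
  s2 <- matrix(NA_real_, np, n_pairs)
  s2[is_cross, ] <- latent[hi[is_cross], , drop = FALSE] + affinity[is_cross] +
    eps[is_cross, , drop = FALSE]

  lin_ff <- matrix(0, np, n_pairs)
  lin_ff[active, ] <- 2^s1[active, , drop = FALSE]
  lin_ff[is_cross, ] <- lin_ff[is_cross, , drop = FALSE] +
    2^s2[is_cross, , drop = FALSE]

  geometry <- design[, c("probe_id", "x", "y")]
  mk_matrix <- function(lin, suffix) {
    v <- pmax(lin + bg, 1)
    rownames(v) <- design$probe_id
    colnames(v) <- paste0(tumors, "_", suffix)
    intensity_matrix(v, geometry)
  }
  ff <- mk_matrix(lin_ff, "FF")

  d1 <- truth$probes$d3prime
  d1[is.na(d1)] <- 0
  d2 <- truth$probes$crosshyb_d3prime
  d2[is.na(d2)] <- 0

  ffpet <- vector("list", length(kits))
  names(ffpet) <- kits
  for (i in seq_along(kits)) {
    prof <- config$kit_profiles[[kits[i]]]
    set_sim_seed(config$seed + 100L + i)
    eta <- matrix(stats::rnorm(np * n_pairs, 0, prof$extra_noise_sd), np, n_pairs)
    drop <- matrix(stats::runif(np * n_pairs) < prof$dropout_prob, np, n_pairs)
    att1 <- prof$global_attenuation + prof$three_prime_decay * d1
    att2 <- prof$global_attenuation + prof$three_prime_decay * d2
    lin <- matrix(0, np, n_pairs)
    lin[active, ] <- 2^(s1[active, , drop = FALSE] - att1[active])
    lin[is_cross, ] <- lin[is_cross, , drop = FALSE] +
      2^(s2[is_cross, , drop = FALSE] - att2[is_cross])
    lin <- lin * 2^eta
    lin[drop] <- 0
    ffpet[[i]] <- mk_matrix(lin, kits[i])
  }

  sheet <- rbind(
    data.frame(sample_id = paste0(tumors, "_FF"), preparation = "FF",
               kit = "ff", er_status = er, pair_id = tumors,
               stringsAsFactors = FALSE),
    do.call(rbind, lapply(kits, function(k) {
      data.frame(sample_id = paste0(tumors, "_", k), preparation = "FFPET",
                 kit = k, er_status = er, pair_id = tumors,
                 stringsAsFactors = FALSE)
    }))
  )

  structure(list(ff = ff, ffpet = ffpet, sheet = sheet), class = "sim_cohort")
}

#' Run the full generator from a configuration
#'
#' Convenience wrapper chaining [generate_reference()],
#' [generate_array_design()] and [simulate_cohort()].
#'
#' @param config A [sim_config()] object.
#' @return A list with `reference`, `design`, `truth`, `cohort`.
#' @export
simulate_study <- function(config) {
  ref <- generate_reference(config)
  ad <- generate_array_design(ref, config)
  cohort <- simulate_cohort(ad$reference, ad$design, ad$truth, config)
  list(reference = ad$reference, design = ad$design, truth = ad$truth,
       cohort = cohort)
}
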