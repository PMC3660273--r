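## Sample- and design-level quality metrics: limit of blank (LOB) and
## present calls, cross-probe-set consistency, matched-pair correlation,
## and the in-silico 3'/5' degradation ratio.

#' Per-sample limit of blank
#'
#' The LOB is the empirical 95th percentile of the expression of the
#' complete-mismatch (blank) probe sets, computed per sample with linear
#' interpolation between the closest order statistics (R quantile type 7):
#' for blank values `1..20` this convention gives exactly 19.05.
#'
#' @param expr Expression matrix (probe sets x samples, log2).
#' @param blank_set_ids Ids of the complete-mismatch probe sets (>= 20
#'   recommended).
#' @param prob Percentile (default 0.95).
#' @return Named numeric vector, one LOB per sample (log2 units).
#' @export
estimate_lob <- function(expr, blank_set_ids, prob = 0.95) {
  if (length(blank_set_ids) == 0L) {
    stop("LOB undefined: no complete-mismatch probe sets supplied", call. = FALSE)
  }
  missing <- setdiff(blank_set_ids, rownames(expr))
  if (length(missing)) {
    stop("LOB undefined: blank sets absent from expression matrix: ",
         paste(utils::head(missing, 3), collapse = ", "), call. = FALSE)
  }
  apply(expr[blank_set_ids, , drop = FALSE], 2, stats::quantile, probs = prob,
        type = 7, na.rm = TRUE, names = FALSE)
}

#' Present calls against the limit of blank
#'
#' A probe set is "present" in a sample when its expression exceeds the
#' sample's LOB. Blank sets are excluded from both numerator and
#' denominator. The pooled percentage uses one fixed rule: a probe set
#' counts as above-LOB when its median expression across samples exceeds
#' the median LOB.
#'
#' @param expr Expression matrix (probe sets x samples, log2).
#' @param lob Per-sample LOB from [estimate_lob()].
#' @param blank_set_ids Blank set ids to exclude.
#' @return List with `percent_present` (per sample, %) and
#'   `percent_above_lob` (pooled, %).
#' @export
present_calls <- function(expr, lob, blank_set_ids = character(0)) {
  stopifnot(ncol(expr) == length(lob))
  e <- expr[!rownames(expr) %in% blank_set_ids, , drop = FALSE]
  pp <- 100 * colMeans(sweep(e, 2, lob, `>`), na.rm = TRUE)
  med <- apply(e, 1, stats::median, na.rm = TRUE)
  pooled <- 100 * mean(med > stats::median(lob), na.rm = TRUE)
  list(percent_present = pp, percent_above_lob = pooled)
}

#' Cross-probe-set consistency of genes
#'
#' For every gene measured by at least two retained probe sets, computes the
#' Pearson correlation across samples between each pair of its probe-set
#' expression vectors. A gene is inconsistent when the median pairwise
#' correlation does not exceed `r_threshold` (for two sets this reduces to
#' the single pairwise correlation). Zero-variance vectors make a pair's
#' correlation undefined; such pairs are dropped with a warning.
#'
#' @param expr Expression matrix (probe sets x samples, log2), >= 3 samples.
#' @param design A `revised_design` carrying the set-to-gene map, or a data
#'   frame with columns `probe_set_id` and `gene_id`.
#' @param r_threshold Consistency threshold (default 0.5).
#' @return List with `percent_inconsistent` (%), `n_genes` (eligible genes)
#'   and `detail` (per-gene data frame: gene_id, n_sets, median_r,
#'   inconsistent).
#' @export
probe_set_consistency <- function(expr, design, r_threshold = 0.5) {
  if (ncol(expr) < 3L) stop("need >= 3 samples for consistency", call. = FALSE)
  map <- if (inherits(design, "revised_design")) design$sets else design
  map <- map[!is.na(map$gene_id) & map$probe_set_id %in% rownames(expr), ,
             drop = FALSE]
  sets_per_gene <- split(map$probe_set_id, map$gene_id)
  sets_per_gene <- sets_per_gene[lengths(sets_per_gene) >= 2L]
  if (length(sets_per_gene) == 0L) {
    return(list(percent_inconsistent = NA_real_, n_genes = 0L,
                detail = data.frame()))
  }
  dropped <- 0L
  detail <- do.call(rbind, lapply(names(sets_per_gene), function(g) {
    ids <- sets_per_gene[[g]]
    e <- expr[ids, , drop = FALSE]
    pr <- utils::combn(length(ids), 2)
    rs <- apply(pr, 2, function(p) {
      a <- e[p[1], ]
      b <- e[p[2], ]
      ok <- !is.na(a) & !is.na(b)
      if (sum(ok) < 3 || stats::sd(a[ok]) == 0 || stats::sd(b[ok]) == 0) {
        return(NA_real_)
      }
      stats::cor(a[ok], b[ok])
    })
    dropped <<- dropped + sum(is.na(rs))
    med <- stats::median(rs, na.rm = TRUE)
    data.frame(gene_id = g, n_sets = length(ids), median_r = med,
               inconsistent = !is.na(med) & med <= r_threshold,
               stringsAsFactors = FALSE)
  }))
  if (dropped > 0) {
    warning(dropped, " probe-set pair(s) with undefined correlation excluded",
            call. = FALSE)
  }
  ok <- !is.na(detail$median_r)
  list(percent_inconsistent = 100 * mean(detail$inconsistent[ok]),
       n_genes = sum(ok), detail = detail)
}

#' Correlation of expression between matched FF and FFPET samples
#'
#' Pearson correlation of log2 expression over the shared probe sets for
#' every matched pair (same `pair_id`, one FF and one FFPET sample), with
#' missing values dropped pairwise, summarized by the median and quartiles
#' across pairs.
#'
#' @param expr_ff,expr_ffpet Expression matrices for the FF cohort and one
#'   FFPET kit cohort.
#' @param sheet Sample sheet covering both cohorts' samples.
#' @return List with `pairs` (data frame: pair_id, r), `median_r` and
#'   `quartiles` (25%, 75%).
#' @export
pair_correlation <- function(expr_ff, expr_ffpet, sheet) {
  shared <- intersect(rownames(expr_ff), rownames(expr_ffpet))
  if (length(shared) < 3L) stop("too few shared probe sets", call. = FALSE)
  ff <- sheet[sheet$preparation == "FF" & sheet$sample_id %in% colnames(expr_ff), ]
  fp <- sheet[sheet$preparation == "FFPET" &
                sheet$sample_id %in% colnames(expr_ffpet), ]
  pairs <- intersect(ff$pair_id, fp$pair_id)
  unpaired <- setdiff(union(ff$pair_id, fp$pair_id), pairs)
  if (length(unpaired)) {
    warning("excluding unpaired sample(s) for pair id(s): ",
            paste(unpaired, collapse = ", "), call. = FALSE)
  }
  if (length(pairs) == 0L) stop("no matched FF/FFPET pairs found", call. = FALSE)
  r <- vapply(pairs, function(p) {
    a <- expr_ff[shared, ff$sample_id[match(p, ff$pair_id)]]
    b <- expr_ffpet[shared, fp$sample_id[match(p, fp$pair_id)]]
    ok <- !is.na(a) & !is.na(b)
    if (stats::sd(a[ok]) == 0 || stats::sd(b[ok]) == 0) {
      stop("constant expression column for pair ", p, call. = FALSE)
    }
    stats::cor(a[ok], b[ok])
  }, numeric(1))
  list(pairs = data.frame(pair_id = pairs, r = unname(r),
                          stringsAsFactors = FALSE),
       median_r = stats::median(r),
       quartiles = stats::quantile(r, c(0.25, 0.75), names = TRUE))
}

#' In-silico 3'/5' signal ratio of a control transcript
#'
#' The microarray analog of the 3'/5' amplicon ratio used to assess mRNA
#' integrity: per sample, the mean linear intensity of the control
#' transcript's probes lying in its 3'-most third divided by the mean in its
#' 5'-most third. Intact RNA gives a ratio near 1; 3'-biased degradation
#' inflates it — under the linear log2 decay model with rate `lambda` per
#' nt, the expected ratio is about `2^(lambda * Dd)` where `Dd` is the
#' difference in mean 3' distance between the two probe groups.
#'
#' @param m Raw `intensity_matrix` (linear scale).
#' @param design Probe design data frame with `target_transcript` and
#'   `d3prime` columns.
#' @param control_transcript Transcript id of the designated control.
#' @param transcript_length Length of the control transcript (nt); taken
#'   from `reference` if supplied instead.
#' @param reference Optional [Biostrings::DNAStringSet] to look the length
#'   up in.
#' @return Named numeric vector: one ratio per sample (`NA` where the 5'
#'   mean is non-positive, with a warning).
#' @export
three_prime_ratio <- function(m, design, control_transcript,
                              transcript_length = NULL, reference = NULL) {
  stopifnot(inherits(m, "intensity_matrix"))
  if (is.null(transcript_length)) {
    if (is.null(reference) || !control_transcript %in% names(reference)) {
      stop("supply transcript_length or a reference containing the control",
           call. = FALSE)
    }
    transcript_length <- Biostrings::width(reference)[
      match(control_transcript, names(reference))]
  }
  probes <- design[!is.na(design$target_transcript) &
                     design$target_transcript == control_transcript, ,
                   drop = FALSE]
  third <- transcript_length / 3
  p3 <- probes$probe_id[probes$d3prime < third]
  p5 <- probes$probe_id[probes$d3prime >= 2 * third]
  if (length(p3) < 2L || length(p5) < 2L) {
    stop("control transcript needs >= 2 probes in each terminal third",
         call. = FALSE)
  }
  m3 <- colMeans(m$values[p3, , drop = FALSE], na.rm = TRUE)
  m5 <- colMeans(m$values[p5, , drop = FALSE], na.rm = TRUE)
  bad <- !(m5 > 0)
  if (any(bad)) {
    warning("non-positive 5' mean in ", sum(bad), " sample(s); ratio reported ",
            "as missing", call. = FALSE)
  }
  ratio <- ifelse(bad, NA_real_, m3 / m5)
  stats::setNames(ratio, colnames(m$values))
}

#' Assemble a cohort QC report
#'
#' Bundles the sample-level metrics (LOB, percent present, 3'/5' ratio),
#' the pooled metrics (percent probe sets above LOB, percent inconsistent
#' genes) and, when an FF comparison is supplied, the matched-pair
#' correlations, into one list ready for JSON serialization.
#'
#' @param expr Cohort expression matrix (probe sets x samples, log2).
#' @param design A `revised_design` with blank sets attached.
#' @param intensities Raw cohort `intensity_matrix` (for the 3'/5' ratio).
#' @param raw_design Original probe design data frame (for probe positions).
#' @param control_transcript,transcript_length Control transcript spec.
#' @param expr_ff Optional FF expression matrix for pair correlations.
#' @param sheet Sample sheet (required with `expr_ff`).
#' @return List of QC metrics.
#' @export
qc_report <- function(expr, design, intensities = NULL, raw_design = NULL,
                      control_transcript = NULL, transcript_length = NULL,
                      expr_ff = NULL, sheet = NULL) {
  blanks <- design$complete_mismatch_set_ids
  lob <- estimate_lob(expr, blanks)
  pc <- present_calls(expr, lob, blanks)
  cons <- probe_set_consistency(expr, design)
  rep <- list(
    lob = lob,
    percent_present = pc$percent_present,
    percent_above_lob = pc$percent_above_lob,
    percent_inconsistent_genes = cons$percent_inconsistent,
    n_consistency_genes = cons$n_genes
  )
  if (!is.null(intensities) && !is.null(raw_design) &&
      !is.null(control_transcript)) {
    rep$three_prime_ratio <- three_prime_ratio(
      intensities, raw_design, control_transcript, transcript_length)
  }
  if (!is.null(expr_ff) && !is.null(sheet)) {
    pcorr <- pair_correlation(expr_ff, expr, sheet)
    rep$pair_correlation <- list(median = pcorr$median_r,
                                 q25 = unname(pcorr$quartiles[1]),
                                 q75 = unname(pcorr$quartiles[2]))
  }
  rep
}
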