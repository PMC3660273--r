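## FF-versus-FFPET concordance scoring: per-probe-set ER effect sizes,
## relevance-quadrant classification at the 2-fold threshold, global and
## effect-size-binned sensitivity/specificity, probe-set t-tests and a
## Monte-Carlo power estimate.

## The positive group is the level marked "+" (e.g. "ER+"); without such a
## mark the lexicographically first level (C collation) is used.
group_columns <- function(expr, sheet, group_field = "er_status") {
  sheet <- sheet[sheet$sample_id %in% colnames(expr), , drop = FALSE]
  groups <- sheet[[group_field]]
  lv <- sort(unique(groups), method = "radix")
  if (length(lv) != 2L) {
    stop("group field '", group_field, "' must have exactly 2 levels among ",
         "the matrix's samples", call. = FALSE)
  }
  plus <- grepl("\\+$", lv)
  if (any(plus)) lv <- c(lv[plus][1], lv[!plus][1])
  list(pos = sheet$sample_id[groups == lv[1]],
       neg = sheet$sample_id[groups == lv[2]],
       levels = lv)
}

#' Per-probe-set effect sizes
#'
#' The effect size of a probe set is the difference between its mean log2
#' expression in the ER+ samples and in the ER- samples (missing values
#' dropped per probe set). Probe sets with an empty group are reported `NA`
#' and counted.
#'
#' @param expr Expression matrix (probe sets x samples, log2).
#' @param sheet Sample sheet covering the matrix's samples.
#' @param group_field Sheet column holding the two-level contrast (default
#'   `er_status`; the higher-sorting level, ER+, is the positive group).
#' @return Named numeric vector of effects (log2), one per probe set, with
#'   an `n_excluded` attribute.
#' @export
effect_sizes <- function(expr, sheet, group_field = "er_status") {
  g <- group_columns(expr, sheet, group_field)
  if (length(g$pos) < 2L || length(g$neg) < 2L) {
    stop("need >= 2 samples per group", call. = FALSE)
  }
  mp <- rowMeans(expr[, g$pos, drop = FALSE], na.rm = TRUE)
  mn <- rowMeans(expr[, g$neg, drop = FALSE], na.rm = TRUE)
  eff <- mp - mn
  eff[!is.finite(eff)] <- NA_real_
  attr(eff, "n_excluded") <- sum(is.na(eff))
  eff
}

#' Classify FF/FFPET effect pairs into concordance quadrants
#'
#' An effect is "relevant" when its magnitude exceeds `threshold` (1 log2
#' unit = 2-fold by default). Quadrants: `TP` both relevant with the same
#' sign; `WP` (wrong positive) both relevant with opposite signs; `FN`
#' relevant in FF only; `FP` relevant in FFPET only; `TN` neither.
#'
#' @param effect_ff,effect_ffpet Finite effect sizes (vectorized).
#' @param threshold Relevance threshold in log2 units (default 1).
#' @return Character vector of quadrant labels.
#' @export
classify_quadrant <- function(effect_ff, effect_ffpet, threshold = 1.0) {
  stopifnot(length(effect_ff) == length(effect_ffpet))
  na <- is.na(effect_ff) | is.na(effect_ffpet)
  rf <- !na & abs(effect_ff) > threshold
  rp <- !na & abs(effect_ffpet) > threshold
  same <- !na & sign(effect_ff) == sign(effect_ffpet)
  out <- rep("TN", length(effect_ff))
  out[rf & rp & same] <- "TP"
  out[rf & rp & !same] <- "WP"
  out[rf & !rp] <- "FN"
  out[!rf & rp] <- "FP"
  out[na] <- NA_character_
  out
}

#' Build per-probe-set concordance records
#'
#' Computes FF and FFPET effect sizes over the shared probe sets and labels
#' each with its quadrant.
#'
#' @param expr_ff,expr_ffpet Cohort expression matrices.
#' @param sheet Sample sheet covering both cohorts.
#' @param threshold Relevance threshold (log2).
#' @param exclude Probe sets to drop (e.g. blank control sets).
#' @param group_field Contrast column of the sheet.
#' @return Data frame: `probe_set_id`, `effect_ff`, `effect_ffpet`,
#'   `quadrant`.
#' @export
concordance_records <- function(expr_ff, expr_ffpet, sheet, threshold = 1.0,
                                exclude = character(0),
                                group_field = "er_status") {
  shared <- setdiff(intersect(rownames(expr_ff), rownames(expr_ffpet)), exclude)
  eff_ff <- effect_sizes(expr_ff[shared, , drop = FALSE], sheet, group_field)
  eff_fp <- effect_sizes(expr_ffpet[shared, , drop = FALSE], sheet, group_field)
  data.frame(
    probe_set_id = shared,
    effect_ff = unname(eff_ff),
    effect_ffpet = unname(eff_fp),
    quadrant = classify_quadrant(unname(eff_ff), unname(eff_fp), threshold),
    stringsAsFactors = FALSE
  )
}

#' Sensitivity and specificity of an FFPET workflow against FF
#'
#' With FF as the gold standard (100% sensitivity and specificity by
#' assumption), sensitivity is the percentage of FF-relevant probe sets
#' recovered with the same direction in FFPET, `100 * TP / (TP + FN + WP)`,
#' and specificity the percentage of FF-nonrelevant probe sets also
#' nonrelevant in FFPET, `100 * TN / (TN + FP)`. A sign-flipped recovery
#' (WP) counts against sensitivity. Empty denominators give `NA`, not 0.
#'
#' @param records Data frame from [concordance_records()] (rows with `NA`
#'   quadrant are dropped).
#' @return List of class `concordance_summary`: `sensitivity`,
#'   `specificity` (%), `counts` (named TP/TN/FN/FP/WP), `n`.
#' @export
sensitivity_specificity <- function(records) {
  q <- records$quadrant[!is.na(records$quadrant)]
  counts <- table(factor(q, levels = c("TP", "TN", "FN", "FP", "WP")))
  n_rel <- counts[["TP"]] + counts[["FN"]] + counts[["WP"]]
  n_nonrel <- counts[["TN"]] + counts[["FP"]]
  structure(
    list(
      sensitivity = if (n_rel > 0) 100 * counts[["TP"]] / n_rel else NA_real_,
      specificity = if (n_nonrel > 0) 100 * counts[["TN"]] / n_nonrel else NA_real_,
      counts = stats::setNames(as.integer(counts), names(counts)),
      n = length(q)
    ),
    class = "concordance_summary"
  )
}

#' @export
print.concordance_summary <- function(x, ...) {
  cat(sprintf("FFPET vs FF concordance over %d probe sets\n", x$n))
  cat(sprintf("  sensitivity %.1f%%, specificity %.1f%%\n",
              x$sensitivity, x$specificity))
  cat("  counts:", paste(names(x$counts), x$counts, sep = "=",
                         collapse = " "), "\n")
  invisible(x)
}

#' Sensitivity and specificity by FF effect-size bin
#'
#' Recomputes the concordance summary within bins of `|effect_ff|`,
#' reflecting that larger FF effects are easier to recover in FFPET. Bins
#' with fewer than 10 probe sets are flagged low-n.
#'
#' @param records Data frame from [concordance_records()].
#' @param bin_edges Strictly increasing edges applied to `|effect_ff|`
#'   (default `c(0, 1, 1.5, 2.5, Inf)`; intervals are `(lo, hi]`).
#' @return Data frame: bin, n, sensitivity, specificity, low_n.
#' @export
binned_sensitivity <- function(records,
                               bin_edges = c(0, 1, 1.5, 2.5, Inf)) {
  if (any(diff(bin_edges) <= 0)) {
    stop("bin_edges must be strictly increasing", call. = FALSE)
  }
  records <- records[!is.na(records$quadrant), , drop = FALSE]
  bins <- cut(abs(records$effect_ff), bin_edges, include.lowest = TRUE)
  out <- do.call(rbind, lapply(levels(bins), function(b) {
    r <- records[!is.na(bins) & bins == b, , drop = FALSE]
    if (nrow(r) == 0L) {
      return(data.frame(bin = b, n = 0L, sensitivity = NA_real_,
                        specificity = NA_real_, low_n = TRUE,
                        stringsAsFactors = FALSE))
    }
    s <- sensitivity_specificity(r)
    data.frame(bin = b, n = nrow(r), sensitivity = s$sensitivity,
               specificity = s$specificity, low_n = nrow(r) < 10L,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Two-sample t-test on one probe set's expression
#'
#' Pooled-variance two-sample t on the log2 expression of a probe set,
#' ER+ versus ER- (two-sided p from the t distribution with `n1 + n2 - 2`
#' degrees of freedom). Welch's correction is available behind a flag.
#'
#' @param expr Expression matrix (probe sets x samples, log2).
#' @param sheet Sample sheet.
#' @param probe_set_id Probe set to test.
#' @param group_field Contrast column (default `er_status`).
#' @param var_equal Pooled variance (default TRUE).
#' @return List with `t_statistic`, `p_value`, `df`.
#' @export
probe_set_t_test <- function(expr, sheet, probe_set_id,
                             group_field = "er_status", var_equal = TRUE) {
  if (!probe_set_id %in% rownames(expr)) {
    stop("lookup error: unknown probe set id '", probe_set_id, "'", call. = FALSE)
  }
  g <- group_columns(expr, sheet, group_field)
  a <- stats::na.omit(expr[probe_set_id, g$pos])
  b <- stats::na.omit(expr[probe_set_id, g$neg])
  if (length(a) < 2L || length(b) < 2L) {
    stop("need >= 2 samples per group", call. = FALSE)
  }
  if (stats::var(a) + stats::var(b) == 0) {
    stop("zero pooled variance: t statistic undefined", call. = FALSE)
  }
  ht <- stats::t.test(a, b, var.equal = var_equal)
  list(t_statistic = unname(ht$statistic), p_value = ht$p.value,
       df = unname(ht$parameter))
}

#' Monte-Carlo power of the two-group comparison
#'
#' Estimates the power of the pooled-variance two-sample t-test to detect a
#' log2 effect of `effect_log2` at significance `alpha`, by simulating
#' `n_reps` experiments of `n_per_group` normal samples per group with
#' user-supplied SD `sigma_log2` (the within-group variance is a study
#' property and must be provided, not assumed).
#'
#' @param n_per_group Samples per group.
#' @param effect_log2 True group difference (log2 units; 1 = 2-fold).
#' @param sigma_log2 Within-group SD (log2 units).
#' @param alpha Two-sided significance level (default 0.05).
#' @param n_reps Monte-Carlo replicates (default 10000; fewer than 100 gives
#'   a wide confidence interval and warns).
#' @param seed Optional seed for reproducibility.
#' @return Power estimate in [0, 1] with a `mc_se` attribute (binomial SE).
#' @export
power_simulation <- function(n_per_group, effect_log2, sigma_log2,
                             alpha = 0.05, n_reps = 10000L, seed = NULL) {
  stopifnot(n_per_group > 1, sigma_log2 > 0, alpha > 0, alpha < 1, n_reps > 0)
  if (n_reps < 100) warning("n_reps < 100: power estimate has a wide CI",
                            call. = FALSE)
  if (!is.null(seed)) set_sim_seed(seed)
  n <- as.integer(n_per_group)
  a <- matrix(stats::rnorm(n_reps * n, effect_log2, sigma_log2), n_reps, n)
  b <- matrix(stats::rnorm(n_reps * n, 0, sigma_log2), n_reps, n)
  ma <- rowMeans(a)
  mb <- rowMeans(b)
  va <- rowSums((a - ma)^2)
  vb <- rowSums((b - mb)^2)
  sp2 <- (va + vb) / (2 * n - 2)
  tstat <- (ma - mb) / sqrt(sp2 * 2 / n)
  crit <- stats::qt(1 - alpha / 2, df = 2 * n - 2)
  p <- mean(abs(tstat) > crit)
  attr(p, "mc_se") <- sqrt(p * (1 - p) / n_reps)
  p
}

#' Analytically predicted FFPET effect sizes
#'
#' Closed-form prediction of the effect size a degraded FFPET cohort should
#' show for each gene, used to predict which FF-relevant genes become false
#' negatives. The noise-free generative signal of each retained probe
#' (`2^(baseline [+ delta] - global_attenuation - decay * d3prime) +
#' background_mean`) is pushed through the convolution-model posterior mean
#' ([rma_posterior_mean()]) with the generative background parameters; the
#' predicted effect is the mean over the gene's uniquely matching probes of
#' the resulting log2 group difference. Shrinkage of strong effects toward
#' the relevance threshold is driven by the background floor: attenuation
#' alone cancels in the group difference, but once the attenuated signal
#' approaches background the measured expression flattens.
#'
#' Because the compression curve is convex near the floor, the prediction
#' averages it over the generative spread of probe-level log2 signals
#' (probe affinity, tissue and measurement noise) by Gauss-Hermite
#' quadrature rather than evaluating at the mean signal.
#'
#' @param truth A `ground_truth` object.
#' @param profile A [degradation_profile()].
#' @param config The generating [sim_config()].
#' @param gh_nodes Number of Gauss-Hermite nodes for the signal-spread
#'   average (default 9).
#' @return Data frame: `gene_id`, `delta`, `predicted_effect`.
#' @export
predicted_ffpet_effect <- function(truth, profile, config, gh_nodes = 9L) {
  stopifnot(inherits(truth, "ground_truth"),
            inherits(profile, "degradation_profile"))
  genes <- truth$genes
  probes <- truth$probes[truth$probes$class == "matching-unique", , drop = FALSE]
  gi <- match(probes$target_gene, genes$gene_id)
  keep <- !genes$silent[gi]
  probes <- probes[keep, , drop = FALSE]
  gi <- gi[keep]

  att <- profile$global_attenuation + profile$three_prime_decay * probes$d3prime
  s_neg <- genes$baseline[gi] - att
  s_pos <- s_neg + genes$delta[gi]
  ## generative background parameters; exponential rate from the cohort-wide
  ## mean linear signal (half the samples in each ER group)
  mean_signal <- mean(c(2^s_neg, 2^s_pos))
  mu <- config$background_mean
  sigma <- max(config$background_sd, 1e-6)
  alpha <- 1 / mean_signal

  ## Gauss-Hermite nodes/weights (probabilists, via the Hermite recursion on
  ## the Golub-Welsch symmetric tridiagonal eigenproblem)
  J <- matrix(0, gh_nodes, gh_nodes)
  off <- sqrt(seq_len(gh_nodes - 1))
  J[cbind(seq_len(gh_nodes - 1), seq_len(gh_nodes - 1) + 1L)] <- off
  J[cbind(seq_len(gh_nodes - 1) + 1L, seq_len(gh_nodes - 1))] <- off
  eig <- eigen(J, symmetric = TRUE)
  nodes <- eig$values
  weights <- eig$vectors[1, ]^2

  spread <- sqrt(config$probe_affinity_sd^2 + config$tissue_sd^2 +
                   config$measurement_sd_ff^2 + profile$extra_noise_sd^2)
  m_of <- function(s) {
    ## expected measured log2 expression for true log2 signal s
    v <- 0
    for (q in seq_along(nodes)) {
      x <- 2^(s + spread * nodes[q]) + mu
      v <- v + weights[q] * log2(rma_posterior_mean(x, mu, sigma, alpha))
    }
    v
  }
  pred <- tapply(m_of(s_pos) - m_of(s_neg), probes$target_gene, mean)
  out <- data.frame(gene_id = names(pred), stringsAsFactors = FALSE)
  out$delta <- genes$delta[match(out$gene_id, genes$gene_id)]
  out$predicted_effect <- unname(pred)
  out
}
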