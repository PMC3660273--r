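## Probe-level preprocessing: chip-level QC masking, convolution background
## correction, quantile normalization and median-polish summarization over
## the revised design. The triplet is the classic RMA expression index,
## implemented behind a single expression_index() entry point so variants
## can be swapped per cohort.

#' Mask spatial outlier probes
#'
#' Partitions the chip into `zone_grid` x `zone_grid` zones and, per zone
#' and sample, masks probes whose log2 intensity deviates from the zone
#' median by more than `k_mad` zone MADs. Also estimates per-sample optical
#' noise (SD of the lowest 2% of log2 values) and a background-gradient
#' summary (the zone medians).
#'
#' @param m An `intensity_matrix` with geometry.
#' @param zone_grid Zones per chip side (default 4).
#' @param k_mad MAD multiplier for the outlier cut (default 5).
#' @return An `intensity_matrix` copy with the mask updated and a `qc`
#'   attribute: list with `optical_noise` (per sample), `zone_medians`
#'   (zones x samples) and `n_masked` (per sample).
#' @export
mask_spatial_outliers <- function(m, zone_grid = 4L, k_mad = 5) {
  stopifnot(inherits(m, "intensity_matrix"), zone_grid >= 1, k_mad > 0)
  if (is.null(m$geometry)) stop("intensity matrix has no chip geometry", call. = FALSE)
  g <- m$geometry
  zone_of <- function(coord) {
    side <- max(coord) + 1L
    pmin(floor(coord / (side / zone_grid)), zone_grid - 1L)
  }
  zone <- interaction(zone_of(g$x), zone_of(g$y), drop = FALSE)
  ## merge underpopulated zones into the preceding zone along the grid
  counts <- table(zone)
  if (any(counts > 0 & counts < 4)) {
    warning("zones with fewer than 4 probes merged with a neighbor",
            call. = FALSE)
    lev <- levels(zone)
    zl <- as.character(zone)
    for (z in names(counts)[counts > 0 & counts < 4]) {
      donor <- lev[max(1L, match(z, lev) - 1L)]
      zl[zl == z] <- donor
    }
    zone <- factor(zl)
  }
  lv <- log2(pmax(m$values, 1e-12))
  mask <- m$mask
  zms <- matrix(NA_real_, nlevels(zone), ncol(lv),
                dimnames = list(levels(zone), colnames(lv)))
  for (s in seq_len(ncol(lv))) {
    med <- tapply(lv[, s], zone, stats::median)
    md <- tapply(lv[, s], zone, stats::mad)
    zms[, s] <- med[rownames(zms)]
    dev <- abs(lv[, s] - med[as.character(zone)])
    mask[, s] <- mask[, s] | dev > k_mad * md[as.character(zone)]
  }
  noise <- apply(lv, 2, function(v) {
    stats::sd(sort(v)[seq_len(max(2L, floor(0.02 * length(v))))])
  })
  out <- intensity_matrix(m$values, m$geometry, mask)
  attr(out, "qc") <- list(optical_noise = noise, zone_medians = zms,
                          n_masked = colSums(mask))
  out
}

## ---------------------------------------------------------------------------
## Convolution (normal + exponential) background correction.

#' Posterior mean of the true signal under the RMA convolution model
#'
#' For observed intensity `x = s + b` with signal `s ~ Exp(alpha)` truncated
#' to s > 0 and background `b ~ N(mu, sigma)`, returns `E[s | x]` in closed
#' form. This is the adjustment applied by [background_correct()]; it is
#' exposed so the model can be checked against numerical integration.
#'
#' @param x Observed intensities.
#' @param mu,sigma Background mean and SD.
#' @param alpha Exponential rate of the signal prior.
#' @return Posterior expected signal, strictly positive.
#' @export
rma_posterior_mean <- function(x, mu, sigma, alpha) {
  a <- x - mu - sigma^2 * alpha
  num <- stats::dnorm(a / sigma) - stats::dnorm((x - a) / sigma)
  den <- stats::pnorm(a / sigma) + stats::pnorm((x - a) / sigma) - 1
  adj <- a + sigma * num / den
  ## guard the deep lower tail where the truncated-normal ratio degenerates
  bad <- !is.finite(adj) | adj <= 0 | den <= 1e-300
  if (any(bad)) adj[bad] <- .Machine$double.eps
  adj
}

## Background parameter estimation in the style of the classic RMA code:
## mode of the intensity density as the background mean, left-tail spread as
## its SD, right-tail mean as the exponential signal rate.
estimate_bg_parameters <- function(x) {
  d <- stats::density(x, kernel = "epanechnikov", n = 2^14)
  mu <- d$x[which.max(d$y)]
  left <- x[x < mu]
  sigma <- sqrt(sum((left - mu)^2) / max(length(left) - 1, 1)) * sqrt(2)
  right <- x[x > mu]
  alpha <- 1 / mean(right - mu)
  list(mu = mu, sigma = sigma, alpha = alpha)
}

#' Convolution background correction
#'
#' Per sample, fits the normal-plus-exponential convolution model to the
#' unmasked intensities and replaces each value by its posterior expected
#' true signal ([rma_posterior_mean()]). Output values are strictly
#' positive; masked entries are left untouched.
#'
#' @param m An `intensity_matrix` with positive unmasked values.
#' @return A corrected `intensity_matrix`; the fitted parameters are kept in
#'   the `bg_parameters` attribute.
#' @export
background_correct <- function(m) {
  stopifnot(inherits(m, "intensity_matrix"))
  v <- m$values
  pars <- vector("list", ncol(v))
  names(pars) <- colnames(v)
  for (s in seq_len(ncol(v))) {
    use <- !m$mask[, s]
    x <- v[use, s]
    if (stats::sd(x) == 0) {
      warning("degenerate sample ", colnames(v)[s],
              ": falling back to (min - 1) subtraction", call. = FALSE)
      v[use, s] <- x - (min(x) - 1)
      pars[[s]] <- list(mu = min(x) - 1, sigma = 0, alpha = NA_real_)
      next
    }
    p <- estimate_bg_parameters(x)
    if (!is.finite(p$alpha) || p$sigma <= 0) {
      warning("degenerate sample ", colnames(v)[s],
              ": falling back to (min - 1) subtraction", call. = FALSE)
      v[use, s] <- x - (min(x) - 1)
      pars[[s]] <- list(mu = min(x) - 1, sigma = 0, alpha = NA_real_)
      next
    }
    v[use, s] <- rma_posterior_mean(x, p$mu, p$sigma, p$alpha)
    pars[[s]] <- p
  }
  out <- intensity_matrix(v, m$geometry, m$mask)
  attr(out, "bg_parameters") <- pars
  out
}

#' Quantile normalization
#'
#' Replaces each column's sorted values by the across-column mean of order
#' statistics, so that afterwards every column carries one common value
#' multiset. Ties within a column receive the mean of the normalized
#' quantile values assigned to the tied ranks. Masked entries are excluded
#' from the quantile computation and filled by rank interpolation against
#' the unmasked values of their column.
#'
#' @param m An `intensity_matrix` (or bare matrix) with >= 2 samples.
#' @return Normalized object of the same type.
#' @export
quantile_normalize <- function(m) {
  bare <- !inherits(m, "intensity_matrix")
  v <- if (bare) m else m$values
  mask <- if (bare) matrix(FALSE, nrow(v), ncol(v)) else m$mask
  if (ncol(v) < 2L) stop("quantile normalization needs >= 2 samples", call. = FALSE)

  if (!any(mask)) {
    ref <- rowMeans(apply(v, 2, sort))
    out <- apply(v, 2, function(col) {
      stats::approx(seq_along(ref), ref,
                    xout = rank(col, ties.method = "average"))$y
    })
  } else {
    ## reference distribution over unmasked entries, per-column interpolation
    n_ref <- min(colSums(!mask))
    probs <- (seq_len(n_ref) - 1) / (n_ref - 1)
    ref <- rowMeans(vapply(seq_len(ncol(v)), function(s) {
      stats::quantile(v[!mask[, s], s], probs, type = 7, names = FALSE)
    }, numeric(n_ref)))
    out <- v
    for (s in seq_len(ncol(v))) {
      use <- !mask[, s]
      r <- rank(v[use, s], ties.method = "average")
      out[use, s] <- stats::approx((probs * (sum(use) - 1)) + 1, ref, xout = r,
                                   rule = 2)$y
      if (any(!use)) {
        ## masked entries: place by rank against the unmasked distribution
        out[!use, s] <- stats::approx(sort(v[use, s]), sort(out[use, s]),
                                      xout = v[!use, s], rule = 2)$y
      }
    }
  }
  dimnames(out) <- dimnames(v)
  if (bare) out else {
    res <- intensity_matrix(out, m$geometry, mask)
    res
  }
}

## ---------------------------------------------------------------------------
## Median-polish summarization.

#' Median polish of a matrix
#'
#' Iterative row/column median sweeping of `x` into
#' `overall + row + col + residual`, the summarization step of the RMA
#' expression index. Convergence follows the classic criterion: stop when
#' the sum of absolute residuals changes by less than `eps` times itself (or
#' hits zero), or after `max_iter` sweeps. `NA` entries are ignored by the
#' medians and stay `NA` in the residuals.
#'
#' @param x Numeric matrix (probes x samples).
#' @param eps Convergence tolerance (default 1e-6).
#' @param max_iter Maximum number of sweeps (default 100).
#' @return List with `overall`, `row` (per-row effects), `col` (per-column
#'   effects), `residuals`, `iter`.
#' @export
median_polish <- function(x, eps = 1e-6, max_iter = 100L) {
  stopifnot(is.matrix(x))
  r <- x
  t0 <- 0
  re <- numeric(nrow(x))
  ce <- numeric(ncol(x))
  oldsum <- 0
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    rdelta <- apply(r, 1, stats::median, na.rm = TRUE)
    r <- r - rdelta
    re <- re + rdelta
    delta <- stats::median(ce)
    t0 <- t0 + delta
    ce <- ce - delta
    cdelta <- apply(r, 2, stats::median, na.rm = TRUE)
    r <- sweep(r, 2, cdelta)
    ce <- ce + cdelta
    delta <- stats::median(re)
    t0 <- t0 + delta
    re <- re - delta
    newsum <- sum(abs(r), na.rm = TRUE)
    converged <- newsum == 0 || abs(newsum - oldsum) < eps * newsum
    if (converged) break
    oldsum <- newsum
  }
  list(overall = t0, row = re, col = ce, residuals = r, iter = iter)
}

#' Summarize probe sets into expression indices
#'
#' Runs a median polish on the log2 probe x sample submatrix of every
#' retained probe set (the unique sets' retained probes plus all
#' complete-mismatch control sets): the expression value of a sample is the
#' overall plus column effect; the probe affinities are the row effects,
#' re-centered to sum to zero. Masked entries enter as `NA`; a probe set
#' with no unmasked probe in some sample gets `NA` expression there (with
#' the count reported in the `n_missing` attribute).
#'
#' @param m A background-corrected, normalized `intensity_matrix`.
#' @param design A `revised_design` (see [revise_design()],
#'   [with_complete_mismatch_sets()]).
#' @param eps,max_iter Median-polish convergence controls.
#' @return List with `expression` (probe sets x samples matrix, log2) and
#'   `affinity` (named list of per-probe effect vectors, one per set).
#' @export
summarize_probe_sets <- function(m, design, eps = 1e-6, max_iter = 100L) {
  stopifnot(inherits(m, "intensity_matrix"), inherits(design, "revised_design"))
  keep <- design$probes$retained |
    design$probes$probe_set_id %in% design$complete_mismatch_set_ids
  probes <- design$probes[keep, , drop = FALSE]
  missing_probes <- setdiff(probes$probe_id, rownames(m$values))
  if (length(missing_probes)) {
    stop("intensity matrix lacks ", length(missing_probes),
         " probes of the revised design", call. = FALSE)
  }
  lv <- log2(pmax(m$values, .Machine$double.eps))
  lv[m$mask] <- NA_real_

  set_ids <- unique(probes$probe_set_id)
  expr <- matrix(NA_real_, length(set_ids), ncol(lv),
                 dimnames = list(set_ids, colnames(lv)))
  affinity <- vector("list", length(set_ids))
  names(affinity) <- set_ids
  n_missing <- 0L
  for (i in seq_along(set_ids)) {
    pid <- probes$probe_id[probes$probe_set_id == set_ids[i]]
    sub <- lv[pid, , drop = FALSE]
    if (nrow(sub) == 1L) {
      expr[i, ] <- sub[1, ]
      affinity[[i]] <- stats::setNames(0, pid)
    } else {
      mp <- median_polish(sub, eps = eps, max_iter = max_iter)
      ctr <- mean(mp$row)
      expr[i, ] <- mp$overall + ctr + mp$col
      affinity[[i]] <- stats::setNames(mp$row - ctr, pid)
    }
    empty <- colSums(!is.na(sub)) == 0L
    if (any(empty)) {
      expr[i, empty] <- NA_real_
      n_missing <- n_missing + sum(empty)
    }
  }
  structure(list(expression = expr, affinity = affinity),
            n_missing = n_missing)
}

#' RMA-style expression index for one cohort
#'
#' The full preprocessing chain for a single preparation/kit cohort:
#' spatial outlier masking, convolution background correction, quantile
#' normalization and median-polish summarization over the revised design.
#' Cohorts (FF and each FFPET kit) are intended to be processed separately.
#'
#' @param m Raw `intensity_matrix` for one cohort.
#' @param design A `revised_design` with blank sets attached.
#' @param mask_outliers Apply [mask_spatial_outliers()] first (default TRUE
#'   when geometry is present).
#' @param zone_grid,k_mad Masking controls.
#' @return As [summarize_probe_sets()], plus a `qc` element with the masking
#'   report when masking ran.
#' @export
expression_index <- function(m, design,
                             mask_outliers = !is.null(m$geometry),
                             zone_grid = 4L, k_mad = 5) {
  qc <- NULL
  if (mask_outliers) {
    m <- mask_spatial_outliers(m, zone_grid = zone_grid, k_mad = k_mad)
    qc <- attr(m, "qc")
  }
  m <- background_correct(m)
  m <- quantile_normalize(m)
  out <- summarize_probe_sets(m, design)
  out$qc <- qc
  out
}

#' Probe-level signal table behind affinity-profile plots
#'
#' For one probe set, emits the per-probe, per-sample normalized signal
#' component: the log2 probe intensity minus the set's expression value in
#' that sample (i.e. affinity plus residual). With a group map the table is
#' ready for the classic probe-profile plot of a flawed set, where the
#' informative probes separate by group and flawed probes cluster at
#' background.
#'
#' @param m The preprocessed (background-corrected, normalized)
#'   `intensity_matrix` used for summarization.
#' @param design The `revised_design`, or a raw probe design data frame with
#'   `probe_id` and `probe_set_id` columns.
#' @param summary Output of [summarize_probe_sets()] on `m`.
#' @param probe_set_id Probe set to extract.
#' @param groups Optional named vector mapping sample id to group label.
#' @param probe_ids Probes to include (default: all probes of the set in
#'   `m`, including non-retained ones so design flaws stay visible).
#' @return Data frame with `probe_id`, `probe_index`, `sample_id`, `signal`
#'   and (if `groups` is given) `group`.
#' @export
affinity_plot_data <- function(m, design, summary, probe_set_id,
                               groups = NULL, probe_ids = NULL) {
  stopifnot(inherits(m, "intensity_matrix"))
  if (!probe_set_id %in% rownames(summary$expression)) {
    stop("lookup error: unknown probe set id '", probe_set_id, "'",
         call. = FALSE)
  }
  if (is.null(probe_ids)) {
    ptab <- if (inherits(design, "revised_design")) design$probes else design
    probe_ids <- ptab$probe_id[ptab$probe_set_id == probe_set_id]
    probe_ids <- intersect(probe_ids, rownames(m$values))
  }
  lv <- log2(pmax(m$values[probe_ids, , drop = FALSE], .Machine$double.eps))
  expr <- summary$expression[probe_set_id, ]
  out <- data.frame(
    probe_id = rep(probe_ids, times = ncol(lv)),
    probe_index = rep(seq_along(probe_ids), times = ncol(lv)),
    sample_id = rep(colnames(lv), each = length(probe_ids)),
    signal = as.vector(sweep(lv, 2, expr)),
    stringsAsFactors = FALSE
  )
  if (!is.null(groups) && length(groups)) {
    out$group <- unname(groups[out$sample_id])
  }
  out
}
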