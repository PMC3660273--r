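test_that("spatial masking flags planted outliers and nothing on flat chips", {
  set.seed(1)
  n <- 400
  geom <- data.frame(probe_id = paste0("p", 1:n),
                     x = (0:(n - 1)) %% 20, y = (0:(n - 1)) %/% 20)
  flat <- matrix(100, n, 2, dimnames = list(geom$probe_id, c("s1", "s2")))
  m <- intensity_matrix(flat, geom)
  expect_identical(sum(mask_spatial_outliers(m)$mask), 0L)

  v <- matrix(2^rnorm(n * 2, 7, 0.1), n, 2,
              dimnames = list(geom$probe_id, c("s1", "s2")))
  v[17, 1] <- v[17, 1] * 100
  masked <- mask_spatial_outliers(intensity_matrix(v, geom), k_mad = 5)
  expect_identical(which(masked$mask[, 1]), c(p17 = 17L))
  expect_identical(sum(masked$mask[, 2]), 0L)
  qc <- attr(masked, "qc")
  expect_length(qc$optical_noise, 2L)

  ## planted left-to-right gradient is visible in the zone medians
  grad <- matrix(2^(5 + geom$x * 0.2 + rnorm(n, 0, 0.05)), n, 2,
                 dimnames = dimnames(v))
  qg <- attr(mask_spatial_outliers(intensity_matrix(grad, geom)), "qc")
  zx <- as.integer(sub("\\..*", "", rownames(qg$zone_medians)))
  fit <- stats::coef(stats::lm(qg$zone_medians[, 1] ~ zx))
  expect_gt(fit[["zx"]], 0)
})

test_that("posterior mean of the convolution model matches numerical integration", {
  mu <- 50; sigma <- 10; alpha <- 0.01
  ## signal prior Exp(alpha) truncated to (0, x): integrate around the
  ## posterior spike so the quadrature cannot miss it
  oracle <- function(x) {
    a <- x - mu - sigma^2 * alpha
    lo <- max(0, a - 12 * sigma)
    hi <- min(x, max(a, 0) + 12 * sigma)
    f <- function(s) s * dnorm(x - s, mu, sigma) * alpha * exp(-alpha * s)
    g <- function(s) dnorm(x - s, mu, sigma) * alpha * exp(-alpha * s)
    stats::integrate(f, lo, hi, rel.tol = 1e-10)$value /
      stats::integrate(g, lo, hi, rel.tol = 1e-10)$value
  }
  for (x in c(20, 45, 60, 120, 500, 5000)) {
    expect_equal(rma_posterior_mean(x, mu, sigma, alpha), oracle(x),
                 tolerance = 1e-6, label = paste("x =", x))
  }
  ## far above the noise: correction converges to subtracting mu + sigma^2*alpha
  x <- 1e5
  expect_equal(rma_posterior_mean(x, mu, sigma, alpha),
               x - mu - sigma^2 * alpha, tolerance = 1e-2)
})

test_that("background correction is positive, deterministic and near-affine for bright probes", {
  set.seed(2)
  ## realistic chip: 60% background-only probes, 40% expressed
  n <- 6000
  signal <- c(rep(0, 0.6 * n), 2^rnorm(0.4 * n, 9, 1.5))
  bg <- pmax(rnorm(n, 50, 10), 0)
  v <- cbind(s1 = signal + bg, s2 = signal + bg)
  bc <- background_correct(make_im(v))
  expect_true(all(bc$values > 0))
  expect_identical(unname(bc$values[, 1]), unname(bc$values[, 2]))

  ## values >> noise shift by approximately the fitted background mean
  bright <- v[, 1] > 5000
  shift <- v[bright, 1] - bc$values[bright, 1]
  p <- attr(bc, "bg_parameters")$s1
  expect_lt(abs(mean(shift) - (p$mu + p$sigma^2 * p$alpha)) / mean(shift), 0.01)
  ## and the estimated background mean is near the generative one
  expect_lt(abs(p$mu - 50), 15)

  ## adversarial small values stay positive
  tiny <- make_im(cbind(s1 = c(rep(1, 50), 2^runif(200, 0, 10))))
  expect_true(all(background_correct(tiny)$values > 0))

  ## degenerate constant sample falls back with a warning
  expect_warning(
    flatc <- background_correct(make_im(cbind(s1 = rep(10, 100)))),
    "degenerate")
  expect_true(all(flatc$values == 1))
})

test_that("quantile normalization follows the mean-of-order-statistics rule", {
  m <- cbind(a = c(1, 2, 3), b = c(4, 5, 6))
  qn <- quantile_normalize(m)
  expect_equal(unname(qn), cbind(c(2.5, 3.5, 4.5), c(2.5, 3.5, 4.5)))

  ident <- cbind(a = c(2, 9, 4), b = c(2, 9, 4))
  expect_equal(unname(quantile_normalize(ident)), unname(ident))

  ## ties take the mean of their assigned quantile values
  tied <- cbind(a = c(1, 1, 3), b = c(2, 4, 6))
  qt <- quantile_normalize(tied)
  expect_equal(unname(qt[, 1]), c(2, 2, 4.5))
  expect_equal(unname(qt[, 2]), c(1.5, 2.5, 4.5))

  ## columns share one multiset and means agree to 1e-9
  set.seed(3)
  r <- matrix(2^rnorm(500 * 6, 8, 2), 500, 6)
  qr <- quantile_normalize(r)
  for (j in 2:6) expect_equal(sort(qr[, j]), sort(qr[, 1]))
  expect_lt(max(abs(colMeans(qr) - mean(qr))), 1e-9)

  ## independent reference implementation agrees on tie-free data
  skip_if_not_installed("limma")
  expect_equal(unname(qr), unname(limma::normalizeQuantiles(r, ties = TRUE)),
               tolerance = 1e-12)
})

test_that("masked entries are excluded from normalization and rank-interpolated", {
  set.seed(4)
  v <- matrix(2^rnorm(300 * 3, 8, 1), 300, 3,
              dimnames = list(paste0("p", 1:300), paste0("s", 1:3)))
  mask <- matrix(FALSE, 300, 3, dimnames = dimnames(v))
  mask[1:10, 2] <- TRUE
  qn <- quantile_normalize(intensity_matrix(v, mask = mask))
  ## unmasked distributions agree across columns at matched quantiles
  probs <- seq(0.1, 0.9, 0.1)
  q1 <- quantile(qn$values[!mask[, 1], 1], probs)
  q2 <- quantile(qn$values[!mask[, 2], 2], probs)
  expect_equal(unname(q2), unname(q1), tolerance = 0.02)
  ## masked entries stay within the normalized range
  expect_true(all(qn$values[mask] >= min(qn$values[!mask]) - 1e-9))
  expect_true(all(qn$values[mask] <= max(qn$values[!mask]) + 1e-9))
  ## and preserve the rank order they had in the raw column
  expect_identical(order(qn$values[mask[, 2], 2]), order(v[mask[, 2], 2]))
})

test_that("median polish matches the independent reference implementation", {
  set.seed(5)
  for (i in 1:25) {
    x <- matrix(rnorm(11 * 16, 8, 1), 11, 16) +
      outer(rnorm(11, 0, 0.5), rnorm(16, 0, 1), `+`)
    mine <- median_polish(x, eps = 1e-9, max_iter = 200)
    ref <- stats::medpolish(x, eps = 1e-9, maxiter = 200, trace.iter = FALSE)
    expect_equal(mine$overall, ref$overall, tolerance = 1e-6)
    expect_equal(mine$row, ref$row, tolerance = 1e-6)
    expect_equal(mine$col, ref$col, tolerance = 1e-6)
    expect_equal(mine$residuals, ref$residuals, tolerance = 1e-6)
    ## residual rows and columns have median ~ 0
    expect_lt(max(abs(apply(mine$residuals, 1, median))), 1e-6)
    expect_lt(max(abs(apply(mine$residuals, 2, median))), 1e-6)
  }

  ## exactly additive matrix is recovered exactly
  add <- 5 + outer(c(-1, 0, 2), c(3, 1, -2, 0), `+`)
  mp <- median_polish(add)
  expect_equal(mp$residuals, matrix(0, 3, 4), tolerance = 1e-12)
  expect_equal(mp$overall + outer(mp$row, mp$col, `+`), add, tolerance = 1e-12)
})

test_that("summarization returns expression plus zero-centered affinities", {
  set.seed(6)
  ## two clean sets and one single-probe set
  expr_true <- rbind(rnorm(16, 9, 1), rnorm(16, 7, 1))
  aff <- list(rnorm(11, 0, 0.7), 0.3)
  vA <- 2^(matrix(expr_true[1, ], 11, 16, byrow = TRUE) + aff[[1]] +
             matrix(rnorm(11 * 16, 0, 0.05), 11, 16))
  vB <- matrix(2^(expr_true[2, ] + aff[[2]]), 1, 16)
  v <- rbind(vA, vB)
  rownames(v) <- c(sprintf("A_p%02d", 1:11), "B_p01")
  colnames(v) <- paste0("s", 1:16)

  des <- data.frame(probe_id = rownames(v),
                    probe_set_id = c(rep("A", 11), "B"),
                    sequence = replicate(12, rand_seq(25)))
  ref <- make_reference(c(TA = paste0(des$sequence[1:11], collapse = ""),
                          TB = des$sequence[12]), c("GA", "GB"))
  rd <- revise_design(des, ref, min_retained = 1)

  sm <- summarize_probe_sets(make_im(v), rd)
  expect_identical(rownames(sm$expression), c("A", "B"))
  ## single-probe set passes through with zero affinity
  expect_equal(unname(sm$expression["B", ]), unname(log2(v["B_p01", ])))
  expect_identical(unname(sm$affinity$B), 0)
  ## affinities are centered and recover the planted profile shape
  expect_lt(abs(sum(sm$affinity$A)), 1e-6)
  expect_gt(cor(sm$affinity$A, aff[[1]] - mean(aff[[1]])), 0.99)
  ## expression tracks the planted values
  expect_gt(cor(sm$expression["A", ], expr_true[1, ]), 0.99)

  ## fully masked sample for a set -> NA, flagged
  mask <- matrix(FALSE, 12, 16, dimnames = dimnames(v))
  mask[12, 3] <- TRUE
  sm2 <- summarize_probe_sets(intensity_matrix(v, mask = mask), rd)
  expect_true(is.na(sm2$expression["B", 3]))
  expect_identical(attr(sm2, "n_missing"), 1L)
})

test_that("identical input columns give identical expression columns", {
  fx <- cached_study()
  v <- fx$study$cohort$ff$values[, 1:4]
  v[, 2] <- v[, 1]  # duplicate a column
  m <- intensity_matrix(v, fx$study$cohort$ff$geometry)
  ei <- expression_index(m, fx$revised)
  expect_identical(unname(ei$expression[, 1]), unname(ei$expression[, 2]))
})

test_that("raising a gene's signal raises its summarized expression monotonically", {
  fx <- cached_study()
  rd <- fx$revised
  st <- fx$study
  ## pick a clean, expressed, uniquely retained set
  genes <- st$truth$genes
  sets <- rd$sets[rd$sets$set_class == "unique" &
                    !is.na(rd$sets$gene_id), ]
  sets <- sets[!genes$silent[match(sets$gene_id, genes$gene_id)] &
                 sets$gene_id != st$truth$control$gene_id, ]
  target_set <- sets$probe_set_id[1]
  pid <- rd$probes$probe_id[rd$probes$probe_set_id == target_set &
                              rd$probes$retained]

  shifts <- seq(0, 3, length.out = 10)
  out <- vapply(shifts, function(sh) {
    v <- st$cohort$ff$values
    v[pid, ] <- v[pid, ] * 2^sh
    ei <- expression_index(intensity_matrix(v, st$cohort$ff$geometry), rd)
    mean(ei$expression[target_set, ])
  }, numeric(1))
  expect_gt(cor(out, shifts, method = "spearman"), 0.99)
})

test_that("affinity plot data exposes flawed probes at background level", {
  set.seed(9)
  ## 7 informative probes + 4 dead probes, two groups
  groups <- rep(c("ER+", "ER-"), each = 8)
  e <- ifelse(groups == "ER+", 10, 8) + rnorm(16, 0, 0.1)
  v <- rbind(2^(matrix(e, 7, 16, byrow = TRUE) +
                  matrix(rnorm(7 * 16, 0, 0.1), 7, 16)),
             matrix(2^rnorm(4 * 16, 5, 0.3), 4, 16))
  dimnames(v) <- list(sprintf("S_p%02d", 1:11), paste0("t", 1:16))
  des <- data.frame(probe_id = rownames(v), probe_set_id = "S",
                    sequence = replicate(11, rand_seq(25)))
  ref <- make_reference(c(TS = paste0(des$sequence[1:7], collapse = "")), "GS")
  rd <- revise_design(des, ref)
  m <- make_im(v)
  sm <- summarize_probe_sets(m, rd)

  tab <- affinity_plot_data(m, des, sm, "S",
                            groups = setNames(groups, colnames(v)))
  expect_setequal(names(tab),
                  c("probe_id", "probe_index", "sample_id", "signal", "group"))
  expect_identical(nrow(tab), 11L * 16L)
  ## dead probes sit far below the informative ones
  dead <- tab$probe_id %in% sprintf("S_p%02d", 8:11)
  expect_lt(max(tapply(tab$signal[dead], tab$probe_id[dead], mean)),
            min(tapply(tab$signal[!dead], tab$probe_id[!dead], mean)))

  ## single sample, no groups
  m1 <- make_im(v[, 1, drop = FALSE])
  sm1 <- summarize_probe_sets(m1, rd)
  tab1 <- affinity_plot_data(m1, des, sm1, "S")
  expect_identical(nrow(tab1), 11L)
  expect_false("group" %in% names(tab1))

  expect_error(affinity_plot_data(m, des, sm, "NOPE"), "unknown probe set")
})
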