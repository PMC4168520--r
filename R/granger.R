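#' Scalp region map for the 18-channel cognitive montage
#'
#' Five regions: Fronto-Central (F), Left Sensorimotor (L), Central (C),
#' Right Sensorimotor (R) and Occipital (O).  EOG channels are not mapped.
#'
#' @return named list of channel-label vectors, class `region_map`.
#' @export
default_region_map <- function() {
  structure(list(
    F = c("FP1", "FP2", "F7", "F3", "FZ", "F4", "F8"),
    L = c("C3", "P3"),
    C = c("CZ", "PZ"),
    R = c("C4", "P4"),
    O = c("O1", "O2")), class = "region_map")
}

#' Average channels into region signals
#'
#' Replaces the montage by one arithmetic-mean signal per region, the
#' standard reduction before region-level connectivity analysis.
#'
#' @param epochs an [epoched_eeg()] object.
#' @param map named list region -> channel labels ([default_region_map()]).
#' @return an `epoched_eeg` whose channels are the region names.
#' @export
region_average <- function(epochs, map = default_region_map()) {
  stopifnot(inherits(epochs, "epoched_eeg"))
  chans <- toupper(epochs$channels)
  for (rg in names(map)) {
    missing <- setdiff(toupper(map[[rg]]), chans)
    if (length(missing))
      stop(sprintf("region %s: channel %s not present in the montage",
                   rg, missing[1]))
  }
  dims <- dim(epochs$data)
  out <- array(0, c(dims[1], length(map), dims[3]))
  for (ri in seq_along(map)) {
    idx <- match(toupper(map[[ri]]), chans)
    out[, ri, ] <- apply(epochs$data[, idx, , drop = FALSE], c(1, 3), mean)
  }
  epoched_eeg(out, fs = epochs$fs, channels = names(map),
              labels = epochs$labels, subjects = epochs$subjects)
}

## Build the lagged design matrix for least-squares AR fitting.
lag_design <- function(series, p) {
  n <- length(series[[1]])
  do.call(cbind, lapply(series, function(s)
    sapply(seq_len(p), function(j) s[(p - j + 1):(n - j)])))
}

#' Least-squares bivariate VAR(p) fit
#'
#' Fits the two-equation autoregression of demeaned signals
#' `x1`, `x2` by ordinary least squares.  Residual variances use
#' df-corrected divisors (`n_eff - 2p` regressors per equation) so the
#' causality ratio is approximately unbiased under the null.
#'
#' @param x1,x2 numeric signals (equal length > 10 p).
#' @param p model order.
#' @return object of class `var_model`: coefficient array `A`
#'   (2 x 2 x p, `A[k, l, j]` the weight of `x_l(t-j)` in `x_k(t)`),
#'   residual covariance `Sigma`, residuals, `p`, `n_eff`.
#' @export
fit_var_pair <- function(x1, x2, p) {
  if (length(x1) != length(x2)) stop("x1 and x2 must have equal length")
  if (length(x1) <= 10 * p)
    stop("signal too short for the requested order (need length > 10 p)")
  check_finite(x1, "x1"); check_finite(x2, "x2")
  x1 <- x1 - mean(x1); x2 <- x2 - mean(x2)
  n <- length(x1)
  Z <- lag_design(list(x1, x2), p)        # columns: x1 lags 1..p, x2 lags 1..p
  Y <- cbind(x1[(p + 1):n], x2[(p + 1):n])
  qrz <- qr(Z)
  if (qrz$rank < ncol(Z)) stop("rank-deficient VAR regression")
  B <- qr.coef(qrz, Y)                     # (2p) x 2
  E <- Y - Z %*% B
  n_eff <- nrow(Y)
  Sigma <- crossprod(E) / (n_eff - ncol(Z))
  A <- array(0, c(2, 2, p))
  for (j in seq_len(p)) {
    A[1, 1, j] <- B[j, 1];      A[1, 2, j] <- B[p + j, 1]
    A[2, 1, j] <- B[j, 2];      A[2, 2, j] <- B[p + j, 2]
  }
  structure(list(A = A, Sigma = Sigma, residuals = E, p = p,
                 n_eff = n_eff), class = "var_model")
}

#' @describeIn fit_var_pair restricted univariate AR(p) of `x1` alone
#'   (the model omitting the cross coefficients).
#' @export
fit_ar_restricted <- function(x1, p) {
  if (length(x1) <= 10 * p)
    stop("signal too short for the requested order (need length > 10 p)")
  check_finite(x1, "x1")
  x1 <- x1 - mean(x1)
  n <- length(x1)
  Z <- lag_design(list(x1), p)
  yv <- x1[(p + 1):n]
  qrz <- qr(Z)
  if (qrz$rank < ncol(Z)) stop("rank-deficient AR regression")
  b <- qr.coef(qrz, yv)
  e <- yv - as.vector(Z %*% b)
  n_eff <- length(yv)
  structure(list(A = array(b, c(1, 1, p)),
                 Sigma = matrix(sum(e^2) / (n_eff - p), 1, 1),
                 residuals = matrix(e, ncol = 1), p = p, n_eff = n_eff),
            class = "var_model")
}

#' Time-domain Granger causality F(2 -> 1)
#'
#' Log ratio of the restricted to the unrestricted prediction-error
#' variance of `x1`: past values of `x2` Granger-cause `x1` when they
#' reduce its one-step prediction error.
#'
#' @inheritParams fit_var_pair
#' @return scalar `ln(var(e1_restricted) / var(e1_full))`, nonnegative up
#'   to estimation noise.
#' @export
gc_time <- function(x1, x2, p) {
  full <- fit_var_pair(x1, x2, p)
  restr <- fit_ar_restricted(x1, p)
  v_full <- full$Sigma[1, 1]
  v_restr <- restr$Sigma[1, 1]
  if (v_full <= 0 || v_restr <= 0)
    stop("zero residual variance; causality undefined")
  log(v_restr / v_full)
}

## Companion-matrix spectral radius of a (bivariate) VAR.
var_spectral_radius <- function(A) {
  k <- dim(A)[1]; p <- dim(A)[3]
  comp <- matrix(0, k * p, k * p)
  for (j in seq_len(p)) comp[1:k, (j - 1) * k + 1:k] <- A[, , j]
  if (p > 1) comp[(k + 1):(k * p), 1:(k * (p - 1))] <- diag(k * (p - 1))
  max(Mod(eigen(comp, only.values = TRUE)$values))
}

#' Spectral Granger causality I(2 -> 1)(f)
#'
#' Geweke's frequency decomposition for a bivariate VAR: with transfer
#' matrix \eqn{H(f) = (I - \sum_j A_j e^{-2\pi i f j / fs})^{-1}} and
#' spectral matrix \eqn{S(f) = H \Sigma H^*},
#' \deqn{I_{2 \to 1}(f) = -\ln\left(1 - \frac{(\Sigma_{22} -
#'   \Sigma_{12}^2/\Sigma_{11}) |H_{12}(f)|^2}{S_{11}(f)}\right).}
#'
#' @param model a bivariate `var_model` (fitted or constructed).
#' @param freqs frequency grid in Hz; default 0 to fs/2 in 0.5 Hz steps.
#' @param fs sampling rate in Hz.
#' @return data.frame with columns `freq` and `causality`.
#' @export
spectral_gc <- function(model, freqs = NULL, fs) {
  stopifnot(inherits(model, "var_model"), dim(model$A)[1] == 2)
  if (var_spectral_radius(model$A) >= 1)
    stop("unstable VAR: companion spectral radius >= 1")
  freqs <- freqs %||% seq(0, fs / 2, by = 0.5)
  S <- model$Sigma
  s2_partial <- S[2, 2] - S[1, 2]^2 / S[1, 1]
  p <- model$p
  vals <- vapply(freqs, function(f) {
    Af <- diag(2) + 0i
    for (j in seq_len(p))
      Af <- Af - model$A[, , j] * exp(-2i * pi * f * j / fs)
    H <- solve(Af)
    Smat <- H %*% S %*% Conj(t(H))
    S11 <- Re(Smat[1, 1])
    ratio <- s2_partial * Mod(H[1, 2])^2 / S11
    # ratio < 1 in theory; clamp protects against roundoff at sharp peaks
    -log(max(1 - ratio, .Machine$double.eps))
  }, numeric(1))
  data.frame(freq = freqs, causality = vals)
}

#' Minimum-BIC VAR order for a signal pair
#'
#' @inheritParams fit_var_pair
#' @param p_max largest order considered.
#' @return integer order with the smallest Bayesian information criterion.
#' @export
select_var_order <- function(x1, x2, p_max = 20) {
  n <- length(x1)
  p_max <- min(p_max, floor((n - 1) / 10))
  bic <- vapply(seq_len(p_max), function(p) {
    fit <- fit_var_pair(x1, x2, p)
    Sml <- crossprod(fit$residuals) / fit$n_eff
    log(det(Sml)) + log(fit$n_eff) * (4 * p) / fit$n_eff
  }, numeric(1))
  which.min(bic)
}

#' Theta-band directed-connectivity features
#'
#' For every ordered pair of region channels (source -> target) fits a
#' bivariate VAR per trial and averages the spectral causality
#' I(source -> target)(f) over the band (4-8 Hz by default, 0.5 Hz grid).
#' A 5-region montage yields 20 features per trial, in source-major order
#' (`F->L, F->C, ..., O->R`).
#'
#' @param epochs an [epoched_eeg()] of region signals ([region_average()]).
#' @param band frequency band in Hz (length-2 vector).
#' @param p VAR order; `NULL` selects the minimum-BIC order per trial and
#'   pair ([select_var_order()]).
#' @param p_max order search cap when `p` is `NULL`.
#' @return a [feature_matrix()] with the epochs' trial labels.
#' @export
gc_features <- function(epochs, band = c(4, 8), p = 5, p_max = 20) {
  stopifnot(inherits(epochs, "epoched_eeg"))
  regions <- epochs$channels
  n_reg <- length(regions)
  n_tr <- dim(epochs$data)[1]
  pairs <- do.call(rbind, lapply(seq_len(n_reg), function(s)
    cbind(s, setdiff(seq_len(n_reg), s))))
  cn <- paste0(regions[pairs[, 1]], "->", regions[pairs[, 2]])
  fs <- epochs$fs
  freqs <- seq(0, fs / 2, by = 0.5)
  in_band <- freqs >= band[1] & freqs <= band[2]
  vals <- matrix(NA_real_, n_tr, nrow(pairs), dimnames = list(NULL, cn))
  for (tr in seq_len(n_tr)) {
    for (k in seq_len(nrow(pairs))) {
      src <- epochs$data[tr, pairs[k, 1], ]
      tgt <- epochs$data[tr, pairs[k, 2], ]
      ord <- p %||% select_var_order(tgt, src, p_max)
      fit <- fit_var_pair(tgt, src, ord)    # x1 = target, x2 = source
      sp <- spectral_gc(fit, freqs = freqs, fs = fs)
      vals[tr, k] <- mean(sp$causality[in_band])
    }
  }
  feature_matrix(vals, epochs$labels, subjects = epochs$subjects,
                 provenance = sprintf("gc/theta[%g-%g]Hz/p=%s",
                                      band[1], band[2],
                                      if (is.null(p)) "bic" else p))
}

#' Two-sample comparison of connectivity patterns
#'
#' Thin reporting utility (a standard Welch two-sample t-test, not a
#' methodological contribution): per-pair group comparison of directed
#' connectivity features plus an overall test on the per-trial mean
#' connectivity strength.
#'
#' @param features a [feature_matrix()] of connectivity values.
#' @param group vector with two groups, one entry per row (defaults to the
#'   feature labels).
#' @return list with a per-pair data.frame (`pair`, group means, `t`, `p`)
#'   and the overall `htest`.
#' @export
connectivity_group_test <- function(features, group = NULL) {
  group <- group %||% features$labels
  g <- unique(group)
  if (length(g) != 2) stop("exactly two groups required")
  a <- features$values[group == g[1], , drop = FALSE]
  b <- features$values[group == g[2], , drop = FALSE]
  per_pair <- data.frame(
    pair = colnames(features$values),
    mean_1 = colMeans(a), mean_2 = colMeans(b),
    t = NA_real_, p = NA_real_, row.names = NULL)
  for (j in seq_len(ncol(a))) {
    tt <- stats::t.test(a[, j], b[, j])
    per_pair$t[j] <- unname(tt$statistic)
    per_pair$p[j] <- tt$p.value
  }
  overall <- stats::t.test(rowMeans(a), rowMeans(b))
  names(per_pair)[2:3] <- paste0("mean_", g)
  list(per_pair = per_pair, overall = overall, groups = g)
}
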