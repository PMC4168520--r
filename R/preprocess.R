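#' Independent component analysis (fixed-point, log-cosh contrast)
#'
#' Blind source separation by non-Gaussianity maximization: the rows of
#' `X` are centred, whitened by eigen-decomposition of the covariance, and
#' rotated by symmetric fixed-point iterations with the log-cosh
#' nonlinearity.  Deterministic for a given seed.
#'
#' @param X numeric matrix, channels x samples.
#' @param n_components number of components to retain (default: all
#'   channels).
#' @param seed RNG seed for the initial rotation.
#' @param max_iter,tol fixed-point iteration controls.
#' @return object of class `ica_decomposition`: unmixing `W`
#'   (components x channels, includes whitening), mixing `A`
#'   (channels x components, `A %*% W` is the identity on the retained
#'   subspace), sources `S` (components x samples), `center`, `converged`,
#'   `seed`.
#' @export
ica_decompose <- function(X, n_components = NULL, seed = NULL,
                          max_iter = 500L, tol = 1e-6) {
  X <- as.matrix(X)
  check_finite(X, "X")
  nc <- nrow(X); ns <- ncol(X)
  if (ns <= nc) stop("need more samples than channels")
  k <- n_components %||% nc
  if (k < 1 || k > nc) stop("invalid number of components")
  ctr <- rowMeans(X)
  Xc <- X - ctr
  # whitening via eigen-decomposition of the channel covariance
  ev <- eigen(tcrossprod(Xc) / ns, symmetric = TRUE)
  keep <- seq_len(k)
  Kw <- diag(1 / sqrt(pmax(ev$values[keep], .Machine$double.eps)),
             k, k) %*% t(ev$vectors[, keep, drop = FALSE])
  Z <- Kw %*% Xc

  Wr <- with_seed(seed, {
    R <- matrix(stats::rnorm(k * k), k, k)
    qr.Q(qr(R))
  })
  sym_decorrelate <- function(W) {
    s <- eigen(W %*% t(W), symmetric = TRUE)
    s$vectors %*% diag(1 / sqrt(pmax(s$values, .Machine$double.eps)),
                       k, k) %*% t(s$vectors) %*% W
  }
  Wr <- sym_decorrelate(Wr)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    U <- Wr %*% Z
    gU <- tanh(U)
    gpU <- rowMeans(1 - gU^2)
    W_new <- (gU %*% t(Z)) / ns - diag(gpU, k, k) %*% Wr
    W_new <- sym_decorrelate(W_new)
    delta <- max(abs(abs(diag(W_new %*% t(Wr))) - 1))
    Wr <- W_new
    if (delta < tol) { converged <- TRUE; break }
  }
  W <- Wr %*% Kw                          # components x channels
  A <- MASS_ginv(W)                       # channels x components
  structure(list(W = W, A = A, S = W %*% Xc, center = ctr,
                 converged = converged, seed = seed,
                 n_components = k),
            class = "ica_decomposition")
}

## Moore-Penrose pseudoinverse via SVD (small matrices only).
MASS_ginv <- function(M, tol = sqrt(.Machine$double.eps)) {
  s <- svd(M)
  pos <- s$d > tol * s$d[1]
  s$v[, pos, drop = FALSE] %*%
    (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' Back-project retained independent components to channel space
#'
#' @param ica an [ica_decompose()] result.
#' @param keep indices of components to retain (default: components ordered
#'   by explained variance until `var_threshold` is reached).
#' @param var_threshold cumulative explained-variance cutoff used when
#'   `keep` is `NULL`.
#' @return channels x samples matrix reconstructed from the kept sources.
#' @export
ica_backproject <- function(ica, keep = NULL, var_threshold = 0.99) {
  stopifnot(inherits(ica, "ica_decomposition"))
  if (is.null(keep)) {
    contrib <- vapply(seq_len(ica$n_components), function(j)
      sum((ica$A[, j, drop = FALSE] %*%
             ica$S[j, , drop = FALSE])^2), numeric(1))
    ord <- order(contrib, decreasing = TRUE)
    cum <- cumsum(contrib[ord]) / sum(contrib)
    keep <- ord[seq_len(which(cum >= var_threshold)[1])]
  }
  ica$A[, keep, drop = FALSE] %*% ica$S[keep, , drop = FALSE] + ica$center
}

## Upper and lower cubic-spline envelopes through local extrema (endpoints
## anchored at the signal values).
envelope_mean <- function(x) {
  n <- length(x)
  dx <- diff(x)
  s <- sign(dx)
  # indices of strict local maxima / minima
  turn <- which(s[-1] != s[-(n - 1)] & s[-(n - 1)] != 0) + 1
  maxima <- turn[x[turn] > x[pmax(turn - 1, 1)]]
  minima <- setdiff(turn, maxima)
  if (length(maxima) < 2 || length(minima) < 2) return(NULL)
  up <- stats::splinefun(c(1, maxima, n), c(x[1], x[maxima], x[n]),
                         method = "natural")
  lo <- stats::splinefun(c(1, minima, n), c(x[1], x[minima], x[n]),
                         method = "natural")
  (up(seq_len(n)) + lo(seq_len(n))) / 2
}

count_extrema <- function(x) {
  s <- sign(diff(x))
  s <- s[s != 0]
  if (length(s) < 2) 0L else sum(s[-1] != s[-length(s)])
}

#' Empirical mode decomposition by sifting
#'
#' Standard EMD: each intrinsic mode function (IMF) is obtained by
#' repeatedly subtracting the mean of the cubic-spline envelopes of the
#' local maxima and minima until a Cauchy-type criterion
#' (`sum((h_prev - h)^2) / sum(h_prev^2) < sd_tol`) or the sift cap is
#' reached; extraction stops when the residual has fewer than four extrema.
#' The IMFs plus the residual reconstruct the input exactly.
#'
#' @param x numeric signal.
#' @param sd_tol Cauchy stopping tolerance per sift.
#' @param max_sift maximum sifting passes per IMF.
#' @param max_imf maximum number of IMFs.
#' @return object of class `imf_set`: `imfs` (list, fastest oscillation
#'   first), `residual`, `x`, `orthogonalized = FALSE`.
#' @export
emd_sift <- function(x, sd_tol = 0.05, max_sift = 10L, max_imf = 10L) {
  x <- as.numeric(x)
  check_finite(x, "x")
  imfs <- list()
  resid <- x
  while (length(imfs) < max_imf && count_extrema(resid) >= 4) {
    h <- resid
    for (s in seq_len(max_sift)) {
      m <- envelope_mean(h)
      if (is.null(m)) break
      h_new <- h - m
      crit <- sum((h - h_new)^2) / max(sum(h^2), .Machine$double.eps)
      h <- h_new
      if (crit < sd_tol) break
    }
    imfs[[length(imfs) + 1]] <- h
    resid <- resid - h
  }
  structure(list(imfs = imfs, residual = resid, x = x,
                 orthogonalized = FALSE), class = "imf_set")
}

#' Orthogonalize an IMF set (OEMD)
#'
#' Sequential (modified Gram-Schmidt) orthogonalization of the IMFs in
#' extraction order; the residual is recomputed as the difference between
#' the signal and the orthogonalized modes, so completeness
#' (`sum(imfs) + residual == x`) is preserved exactly while the modes
#' become pairwise orthogonal.
#'
#' @param imfset an [emd_sift()] result.
#' @return the orthogonalized `imf_set`.
#' @export
emd_orthogonalize <- function(imfset) {
  stopifnot(inherits(imfset, "imf_set"))
  imfs <- imfset$imfs
  if (length(imfs) > 1) {
    for (k in 2:length(imfs)) {
      v <- imfs[[k]]
      for (j in 1:(k - 1)) {
        u <- imfs[[j]]
        nu <- sum(u^2)
        if (nu > .Machine$double.eps) v <- v - (sum(u * v) / nu) * u
      }
      imfs[[k]] <- v
    }
  }
  resid <- imfset$x - Reduce(`+`, imfs, accumulate = FALSE)
  structure(list(imfs = imfs, residual = resid, x = imfset$x,
                 orthogonalized = TRUE), class = "imf_set")
}
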