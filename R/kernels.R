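#' Kernel specification
#'
#' Describes one basis kernel of the bank the MKL solver combines.  Three
#' families are supported: polynomial \eqn{K(x,y) = ((x \cdot y) + 1)^d},
#' Gaussian RBF \eqn{K(x,y) = \exp(-\|x-y\|^2 / 2\delta^2)} and sigmoid
#' \eqn{K(x,y) = \tanh(k (x \cdot y) + v)}.  The sigmoid family is available
#' for completeness but is not part of the default bank (it is not positive
#' semidefinite in general).
#'
#' @param family one of `"poly"`, `"rbf"`, `"sigmoid"`.
#' @param degree positive integer polynomial degree (poly only).
#' @param width positive Gaussian width \eqn{\delta} (rbf only).
#' @param slope,offset sigmoid parameters \eqn{k}, \eqn{v} (sigmoid only).
#' @return an object of class `kernel_spec`.
#' @examples
#' kernel_spec("poly", degree = 2)
#' kernel_spec("rbf", width = 5)
#' @export
kernel_spec <- function(family = c("poly", "rbf", "sigmoid"),
                        degree = NULL, width = NULL,
                        slope = NULL, offset = NULL) {
  family <- match.arg(family)
  spec <- switch(family,
    poly = {
      if (is.null(degree)) stop("poly kernel requires 'degree'")
      if (!is.null(width) || !is.null(slope) || !is.null(offset))
        stop("poly kernel takes only 'degree'")
      if (degree < 1 || degree != round(degree))
        stop("'degree' must be a positive integer")
      list(family = "poly", degree = as.integer(degree))
    },
    rbf = {
      if (is.null(width)) stop("rbf kernel requires 'width'")
      if (!is.null(degree) || !is.null(slope) || !is.null(offset))
        stop("rbf kernel takes only 'width'")
      if (!is.finite(width) || width <= 0) stop("'width' must be positive")
      list(family = "rbf", width = as.numeric(width))
    },
    sigmoid = {
      if (!is.null(degree) || !is.null(width))
        stop("sigmoid kernel takes only 'slope' and 'offset'")
      list(family = "sigmoid",
           slope = as.numeric(slope %||% 1),
           offset = as.numeric(offset %||% 0))
    })
  structure(spec, class = "kernel_spec")
}

#' @export
format.kernel_spec <- function(x, ...) {
  switch(x$family,
         poly = sprintf("poly(d=%d)", x$degree),
         rbf = sprintf("rbf(width=%g)", x$width),
         sigmoid = sprintf("sigmoid(k=%g,v=%g)", x$slope, x$offset))
}

#' @export
print.kernel_spec <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

#' Default kernel bank: three polynomial and ten RBF kernels
#'
#' Polynomial degrees 1, 2, 3 and RBF widths
#' 0.5, 1, 2, 5, 7, 10, 12, 15, 17, 20 — thirteen kernels in total.
#'
#' @param degrees polynomial degrees.
#' @param widths RBF widths.
#' @return list of [kernel_spec()] objects.
#' @export
default_kernel_bank <- function(degrees = 1:3,
                                widths = c(0.5, 1, 2, 5, 7, 10, 12, 15, 17, 20)) {
  c(lapply(degrees, function(d) kernel_spec("poly", degree = d)),
    lapply(widths, function(w) kernel_spec("rbf", width = w)))
}

#' Evaluate a kernel on a pair of vectors
#'
#' @param spec a [kernel_spec()].
#' @param x,y numeric vectors of equal length.
#' @return scalar kernel value.
#' @examples
#' eval_kernel(kernel_spec("poly", degree = 3), c(1, 1), c(1, 1)) # (2+1)^3 = 27
#' @export
eval_kernel <- function(spec, x, y) {
  stopifnot(inherits(spec, "kernel_spec"))
  if (length(x) != length(y))
    stop("x and y must have the same length")
  check_finite(x, "x"); check_finite(y, "y")
  switch(spec$family,
         poly = (sum(x * y) + 1)^spec$degree,
         rbf = exp(-sum((x - y)^2) / (2 * spec$width^2)),
         sigmoid = tanh(spec$slope * sum(x * y) + spec$offset))
}

## Dense Gram block for one spec; Y = X gives the square training Gram.
gram_block <- function(spec, X, Y = X) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (ncol(X) != ncol(Y)) stop("feature dimension mismatch")
  G <- switch(spec$family,
    poly = (tcrossprod(X, Y) + 1)^spec$degree,
    rbf = {
      d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * tcrossprod(X, Y)
      d2[d2 < 0] <- 0
      exp(-d2 / (2 * spec$width^2))
    },
    sigmoid = tanh(spec$slope * tcrossprod(X, Y) + spec$offset))
  unname(G)
}

#' Build the bank of Gram matrices for a training set
#'
#' Evaluates every kernel in `specs` on all pairs of rows of `X`.  With
#' `normalize = TRUE` (default) each Gram is rescaled to unit mean diagonal
#' (`trace(K)/n = 1`), the usual MKL practice that stops large-scale kernels
#' from dominating the convex combination; the scale constants are stored so
#' rectangular test-vs-train blocks built by [cross_gram()] use the same
#' normalization.
#'
#' @param X numeric matrix, samples in rows.
#' @param specs list of [kernel_spec()] objects.
#' @param normalize rescale each Gram to unit trace/n.
#' @return an object of class `kernel_bank` with elements `specs`, `grams`
#'   (list of n x n matrices), `n`, `scale`.
#' @export
build_bank <- function(X, specs, normalize = TRUE) {
  X <- as.matrix(X)
  if (length(specs) == 0) stop("specs must be non-empty")
  if (nrow(X) < 2) stop("need at least two samples")
  check_finite(X, "X")
  grams <- lapply(specs, function(sp) gram_block(sp, X))
  scale <- vapply(grams, function(G) {
    tr <- mean(diag(G))
    if (tr <= .Machine$double.eps) 1 else 1 / tr
  }, numeric(1))
  if (!normalize) scale[] <- 1
  grams <- Map(function(G, s) G * s, grams, scale)
  structure(list(specs = specs, grams = grams, n = nrow(X),
                 scale = scale, normalized = normalize),
            class = "kernel_bank")
}

#' Rectangular kernel blocks between new samples and the training set
#'
#' @param bank a [build_bank()] result (supplies specs and normalization).
#' @param X_new new samples (rows).
#' @param X_train the training samples the bank was built on.
#' @return list of `nrow(X_new)` x `nrow(X_train)` matrices, one per kernel.
#' @export
cross_gram <- function(bank, X_new, X_train) {
  stopifnot(inherits(bank, "kernel_bank"))
  if (ncol(as.matrix(X_new)) != ncol(as.matrix(X_train)))
    stop("feature dimension mismatch between X_new and X_train")
  Map(function(spec, s) gram_block(spec, X_new, X_train) * s,
      bank$specs, bank$scale)
}

#' Convex combination of the bank's Gram matrices
#'
#' Computes \eqn{K = \sum_m d_m K_m}, the combined kernel of the MKL decision
#' function.
#'
#' @param bank a `kernel_bank` (or plain list of equally sized matrices).
#' @param d weight vector, one weight per kernel.
#' @return the combined Gram matrix.
#' @export
combine_kernels <- function(bank, d) {
  grams <- if (inherits(bank, "kernel_bank")) bank$grams else bank
  if (length(d) != length(grams))
    stop(sprintf("weight length %d does not match bank size %d",
                 length(d), length(grams)))
  K <- grams[[1]] * d[1]
  if (length(grams) > 1)
    for (m in 2:length(grams)) if (d[m] != 0) K <- K + grams[[m]] * d[m]
  K
}

#' @export
print.kernel_bank <- function(x, ...) {
  cat(sprintf("<kernel_bank> M=%d kernels over n=%d samples%s\n",
              length(x$specs), x$n,
              if (x$normalized) " (trace-normalized)" else ""))
  cat(" ", paste(vapply(x$specs, format, character(1)), collapse = ", "), "\n")
  invisible(x)
}
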