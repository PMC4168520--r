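#' Solver settings for the MKL-SVM
#'
#' @param C soft-margin penalty (the degree of tolerated misclassification).
#' @param gap_tol duality-gap tolerance, relative to the combined quadratic
#'   form \eqn{\alpha' Y (\sum_m d_m K_m) Y \alpha}.
#' @param gap_abs absolute duality-gap fallback for degenerate scales.
#' @param max_outer cap on outer (kernel-weight) iterations.
#' @param inner_tol KKT tolerance of the inner SVM solve.
#' @param seed optional seed recorded with the model (the solver itself is
#'   deterministic).
#' @return list of class `mkl_settings`.
#' @export
mkl_settings <- function(C = 100, gap_tol = 0.01, gap_abs = 1e-4,
                         max_outer = 100L, inner_tol = 1e-6, seed = NULL) {
  stopifnot(C > 0, gap_tol > 0, gap_abs >= 0, max_outer >= 1)
  structure(list(C = C, gap_tol = gap_tol, gap_abs = gap_abs,
                 max_outer = as.integer(max_outer),
                 inner_tol = inner_tol, seed = seed),
            class = "mkl_settings")
}

#' Dual objective and kernel-weight gradient
#'
#' For multipliers `alpha` optimal at weights `d`, returns the dual value
#' \eqn{J = \sum_i \alpha_i - \tfrac12 \alpha' Y (\sum_m d_m K_m) Y \alpha}
#' and the gradient
#' \eqn{\partial J / \partial d_m = -\tfrac12 \alpha' Y K_m Y \alpha},
#' which is nonpositive for PSD kernels.  Also returns the per-kernel
#' quadratic forms used by the duality gap.
#'
#' @param dual inner solve result ([svm_dual_solve()]).
#' @param bank the [build_bank()] kernel bank.
#' @param y training labels (-1/+1).
#' @param d current kernel weights.
#' @return list with `J`, `grad` (length M), `quad` (alpha' Y K_m Y alpha).
#' @export
objective_and_gradient <- function(dual, bank, y, d) {
  ay <- dual$alpha * y
  if (length(ay) != bank$n) stop("alpha length does not match bank dimension")
  quad <- vapply(bank$grams, function(K) sum(ay * (K %*% ay)), numeric(1))
  grad <- -0.5 * quad
  J <- sum(dual$alpha) - 0.5 * sum(d * quad)
  list(J = J, grad = grad, quad = quad)
}

#' Reduced-gradient descent direction on the simplex
#'
#' The direction of the kernel-weight update `d <- d + gamma * D`:
#' with mu the index of the largest weight (smallest index on ties) and
#' g the gradient,
#' zero weights whose reduced gradient `g_m - g_mu` is positive stay at
#' zero; every other component moves along `-(g_m - g_mu)`; the mu-th
#' component balances the rest so that `sum(D) = 0` keeps the update on the
#' simplex.
#'
#' @param d current weights (on the unit simplex).
#' @param g gradient of the dual objective in d.
#' @param tol simplex feasibility tolerance.
#' @return direction vector D with `sum(D) = 0`.
#' @export
descent_direction <- function(d, g, tol = 1e-8) {
  if (length(d) != length(g)) stop("d and g must have equal length")
  if (abs(sum(d) - 1) > 1e-6 || min(d) < -1e-10)
    stop("d is not on the unit simplex")
  mu <- which.max(d)                       # ties: smallest index
  red <- g - g[mu]
  D <- -red
  D[d <= tol & red > 0] <- 0               # blocked at the boundary
  D[mu] <- 0
  D[mu] <- -sum(D)
  D
}

#' Duality gap of the current (d, alpha) pair
#'
#' \eqn{\max_m \alpha' Y K_m Y \alpha - \alpha' Y (\sum_m d_m K_m) Y \alpha};
#' zero exactly when all weight rests on a maximal quadratic form (in
#' particular for M = 1).
#'
#' @inheritParams objective_and_gradient
#' @return nonnegative scalar gap.
#' @export
duality_gap <- function(dual, bank, d, y) {
  og <- objective_and_gradient(dual, bank, y, d)
  max(og$quad) - sum(d * og$quad)
}

## Inner evaluation: J(d) with a warm-started SVM solve.
mkl_inner_solve <- function(bank, y, d, settings, alpha0 = NULL) {
  K <- combine_kernels(bank, d)
  svm_dual_solve(K, y, settings$C, tol = settings$inner_tol, alpha0 = alpha0)
}

#' One line-search update of the kernel weights
#'
#' Steps along a descent direction with the largest feasible step
#' `gamma_max` (the step at which the first weight hits zero), backtracking
#' by halving (up to 20 times) until the dual objective decreases, then
#' polishing with a short golden-section search.  Weights below 1e-8 are
#' snapped to zero and the vector renormalized onto the simplex.
#'
#' @param d current weights.
#' @param D descent direction ([descent_direction()]).
#' @param bank kernel bank.
#' @param y labels.
#' @param settings [mkl_settings()].
#' @param dual current inner solution (for warm starts and the reference J).
#' @return list with `d`, `dual`, `J`, `moved` (FALSE when no admissible
#'   decreasing step exists).
#' @export
line_search_update <- function(d, D, bank, y, settings, dual = NULL) {
  if (is.null(dual)) dual <- mkl_inner_solve(bank, y, d, settings)
  J0 <- dual$objective
  if (max(abs(D)) < 1e-12)
    return(list(d = d, dual = dual, J = J0, moved = FALSE))
  neg <- D < -1e-14
  gamma_max <- if (any(neg)) min(-d[neg] / D[neg]) else 1 / max(abs(D))
  if (!is.finite(gamma_max) || gamma_max <= 0)
    return(list(d = d, dual = dual, J = J0, moved = FALSE))

  eval_at <- function(gamma) {
    dn <- d + gamma * D
    dn[dn < 0] <- 0
    dn <- dn / sum(dn)
    sol <- mkl_inner_solve(bank, y, dn, settings, alpha0 = dual$alpha)
    list(d = dn, dual = sol, J = sol$objective)
  }

  gamma <- gamma_max
  best <- NULL
  for (h in seq_len(21)) {
    cand <- eval_at(gamma)
    if (cand$J < J0 - 1e-12) { best <- cand; break }
    gamma <- gamma / 2
  }
  if (is.null(best))
    return(list(d = d, dual = dual, J = J0, moved = FALSE))

  # golden-section polish on [0, min(2*gamma, gamma_max)]
  gr <- (sqrt(5) - 1) / 2
  lo <- 0; hi <- min(2 * gamma, gamma_max)
  x1 <- hi - gr * (hi - lo); x2 <- lo + gr * (hi - lo)
  f1 <- eval_at(x1); f2 <- eval_at(x2)
  for (k in seq_len(8)) {
    if (f1$J < f2$J) {
      hi <- x2; x2 <- x1; f2 <- f1
      x1 <- hi - gr * (hi - lo); f1 <- eval_at(x1)
    } else {
      lo <- x1; x1 <- x2; f1 <- f2
      x2 <- lo + gr * (hi - lo); f2 <- eval_at(x2)
    }
  }
  for (cand in list(f1, f2)) if (cand$J < best$J) best <- cand

  dn <- best$d
  dn[dn < 1e-8] <- 0
  dn <- dn / sum(dn)
  list(d = dn, dual = best$dual, J = best$J, moved = TRUE)
}

#' Fit a binary MKL-SVM by reduced-gradient descent (SimpleMKL)
#'
#' Alternates an exact inner SVM solve on the combined kernel
#' \eqn{K(d) = \sum_m d_m K_m} with a reduced-gradient step on the
#' simplex-constrained kernel weights, starting from uniform weights and
#' terminating when the duality gap falls below tolerance.  The recorded
#' objective sequence is non-increasing.
#'
#' @param X numeric feature matrix (samples in rows).
#' @param y binary labels coded -1/+1.
#' @param specs kernel bank specification (list of [kernel_spec()]);
#'   defaults to the three-poly + ten-RBF bank.
#' @param settings an [mkl_settings()] object.
#' @param standardize z-score the features (statistics stored in the model
#'   and re-applied at prediction time).
#' @param normalize_kernels rescale each Gram to unit trace/n.
#' @return object of class `mkl_model`: weights `d`, inner `dual`
#'   (alpha, b, support vectors), training snapshot, final objective `J`,
#'   objective path `J_path`, final `gap`, `converged` flag.
#' @export
mkl_fit <- function(X, y, specs = default_kernel_bank(),
                    settings = mkl_settings(),
                    standardize = TRUE, normalize_kernels = TRUE) {
  X <- as.matrix(X)
  if (!all(y %in% c(-1, 1))) stop("y must be coded -1/+1")
  if (min(table(y)) < 2) stop("need at least 2 samples per class")
  std <- if (standardize) fit_standardizer(X) else NULL
  Xs <- if (standardize) apply_standardizer(std, X) else X
  bank <- build_bank(Xs, specs, normalize = normalize_kernels)
  M <- length(specs)

  d <- rep(1 / M, M)
  dual <- mkl_inner_solve(bank, y, d, settings)
  J_path <- dual$objective
  gap_path <- numeric(0)
  converged <- FALSE
  iter <- 0L
  repeat {
    og <- objective_and_gradient(dual, bank, y, d)
    qcomb <- sum(d * og$quad)
    gap <- max(og$quad) - qcomb
    gap_path <- c(gap_path, gap)
    gap_tol_eff <- max(settings$gap_tol * qcomb, settings$gap_abs)
    if (gap <= gap_tol_eff) { converged <- TRUE; break }
    if (iter >= settings$max_outer) break
    iter <- iter + 1L
    D <- descent_direction(d, og$grad)
    step <- line_search_update(d, D, bank, y, settings, dual = dual)
    if (!step$moved) { converged <- gap <= gap_tol_eff; break }
    d <- step$d; dual <- step$dual
    J_path <- c(J_path, step$J)
  }
  if (!converged)
    warning("mkl_fit: stopped before reaching the duality-gap tolerance")

  structure(list(
    d = d, dual = dual, specs = specs,
    X_train = Xs, y_train = y,
    standardizer = std, kernel_scale = bank$scale,
    normalize_kernels = normalize_kernels,
    J = dual$objective, J_path = J_path,
    gap = gap_path[length(gap_path)], gap_path = gap_path,
    converged = converged, outer_iterations = iter,
    settings = settings), class = "mkl_model")
}

#' Decision scores of a fitted MKL model
#'
#' \eqn{f(x) = \sum_{i \in sv} \alpha_i y_i \sum_m d_m K_m(x, x_i) + b},
#' evaluated with the training-time standardization and kernel
#' normalization constants.
#'
#' @param model fitted [mkl_fit()] model.
#' @param X_new matrix of new samples (rows).
#' @return numeric vector of real-valued scores.
#' @export
decision_function <- function(model, X_new) {
  stopifnot(inherits(model, "mkl_model"))
  X_new <- as.matrix(X_new)
  if (ncol(X_new) != ncol(model$X_train))
    stop(sprintf("feature dimension mismatch: model has %d, input has %d",
                 ncol(model$X_train), ncol(X_new)))
  Xs <- if (!is.null(model$standardizer))
    apply_standardizer(model$standardizer, X_new) else X_new
  score <- numeric(nrow(Xs))
  ay <- model$dual$alpha * model$y_train
  for (m in seq_along(model$specs)) {
    if (model$d[m] == 0) next
    Kb <- gram_block(model$specs[[m]], Xs, model$X_train) * model$kernel_scale[m]
    score <- score + model$d[m] * as.vector(Kb %*% ay)
  }
  score + model$dual$b
}

#' @describeIn decision_function predicted -1/+1 labels (sign of the score,
#'   with `sign(0)` taken as +1).
#' @param object,... S3 predict method arguments (`newdata` matrix).
#' @param newdata matrix of new samples.
#' @export
predict.mkl_model <- function(object, newdata, ...) {
  ifelse(decision_function(object, newdata) >= 0, 1, -1)
}

#' @export
print.mkl_model <- function(x, ...) {
  cat(sprintf("<mkl_model> M=%d kernels, n=%d, J=%.6g, gap=%.3g, %s\n",
              length(x$specs), length(x$y_train), x$J, x$gap,
              if (x$converged) sprintf("converged in %d outer iterations",
                                       x$outer_iterations)
              else "NOT converged"))
  w <- x$d
  names(w) <- vapply(x$specs, format, character(1))
  print(round(w[w > 0], 4))
  invisible(x)
}
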