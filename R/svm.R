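#' Solve the SVM dual problem on a precomputed Gram matrix
#'
#' Maximizes the soft-margin dual
#' \deqn{\max_\alpha \sum_i \alpha_i - \tfrac12 \sum_{ij} \alpha_i \alpha_j
#'   y_i y_j K_{ij}, \quad 0 \le \alpha_i \le C,\ \sum_i \alpha_i y_i = 0}
#' by sequential minimal optimization with second-order working-set
#' selection.  Termination is on the maximal KKT violation
#' (`m(alpha) - M(alpha) <= tol`), so the returned multipliers satisfy the
#' KKT conditions to `tol`.  Supports warm starts, which the MKL outer loop
#' uses heavily.
#'
#' @param K symmetric n x n Gram matrix.
#' @param y labels in -1/+1.
#' @param C box constraint (> 0).
#' @param tol KKT violation tolerance.
#' @param max_iter iteration cap (warning when hit).
#' @param alpha0 optional feasible warm-start multipliers.
#' @return list with `alpha`, `b`, `objective` (dual value), `sv_index`
#'   (indices with alpha > threshold), `C`, `kkt_violation`, `iterations`.
#' @export
svm_dual_solve <- function(K, y, C, tol = 1e-6, max_iter = NULL, alpha0 = NULL) {
  K <- as.matrix(K)
  n <- nrow(K)
  if (ncol(K) != n) stop("K must be square")
  if (length(y) != n) stop("y length must match K")
  if (!all(y %in% c(-1, 1))) stop("y must be coded -1/+1")
  if (length(unique(y)) < 2) stop("both classes must be present in y")
  if (!is.finite(C) || C <= 0) stop("C must be positive")
  max_iter <- max_iter %||% max(50000L, 300L * n)

  if (is.null(alpha0)) {
    alpha <- numeric(n)
    G <- rep(-1, n)                       # gradient of 1/2 a'Qa - e'a at a=0
  } else {
    alpha <- pmin(pmax(as.numeric(alpha0), 0), C)
    # project onto the equality constraint is not attempted; warm starts come
    # from a feasible previous solve, only box-clipped above.
    ay <- alpha * y
    G <- y * as.vector(K %*% ay) - 1
  }

  eps_a <- 1e-12
  it <- 0L
  repeat {
    it <- it + 1L
    yG <- -y * G
    up <- (y > 0 & alpha < C - eps_a) | (y < 0 & alpha > eps_a)
    lo <- (y > 0 & alpha > eps_a) | (y < 0 & alpha < C - eps_a)
    if (!any(up) || !any(lo)) break
    m_up <- max(yG[up]); M_lo <- min(yG[lo])
    if (m_up - M_lo <= tol || it > max_iter) break

    i <- which(up)[which.max(yG[which(up)])]
    # second-order selection of j among violating candidates
    cand <- which(lo & yG < m_up - .Machine$double.eps)
    if (length(cand) == 0) break
    bset <- m_up - yG[cand]
    aset <- K[i, i] + diag(K)[cand] - 2 * y[i] * y[cand] * K[i, cand]
    aset[aset <= 0] <- 1e-12
    j <- cand[which.max(bset^2 / aset)]

    quad <- K[i, i] + K[j, j] - 2 * K[i, j]
    if (quad <= 0) quad <- 1e-12
    t_step <- (yG[i] - yG[j]) / quad      # >= 0 by construction
    # box limits along the feasible direction (alpha_i += y_i t, alpha_j -= y_j t)
    tmax_i <- if (y[i] > 0) C - alpha[i] else alpha[i]
    tmax_j <- if (y[j] > 0) alpha[j] else C - alpha[j]
    t_step <- min(t_step, tmax_i, tmax_j)
    if (t_step <= 0) break
    alpha[i] <- alpha[i] + y[i] * t_step
    alpha[j] <- alpha[j] - y[j] * t_step
    G <- G + y * (K[, i] - K[, j]) * t_step
  }
  if (it > max_iter)
    warning("svm_dual_solve: iteration cap reached; KKT tolerance not met")

  yG <- -y * G
  up <- (y > 0 & alpha < C - eps_a) | (y < 0 & alpha > eps_a)
  lo <- (y > 0 & alpha > eps_a) | (y < 0 & alpha < C - eps_a)
  viol <- if (any(up) && any(lo)) max(yG[up]) - min(yG[lo]) else 0
  free <- alpha > eps_a & alpha < C - eps_a
  b <- if (any(free)) {
    s <- y * (G + 1)                      # s_i = sum_j alpha_j y_j K_ij
    mean(y[free] - s[free])
  } else if (any(up) && any(lo)) (max(yG[up]) + min(yG[lo])) / 2 else 0
  objective <- sum(alpha) - 0.5 * sum(alpha * (G + 1))

  list(alpha = alpha, b = b, objective = objective,
       sv_index = which(alpha > 1e-8), C = C,
       kkt_violation = viol, iterations = it)
}

#' Decision scores of a plain (single-kernel) SVM dual solution
#'
#' \eqn{f(x) = \sum_i \alpha_i y_i K(x, x_i) + b} evaluated from a
#' rectangular test-vs-train kernel block.
#'
#' @param dual a [svm_dual_solve()] result.
#' @param K_cross n_new x n_train kernel block.
#' @param y training labels.
#' @return numeric score vector.
#' @export
svm_decision <- function(dual, K_cross, y) {
  if (ncol(K_cross) != length(dual$alpha))
    stop("kernel block columns must match training size")
  as.vector(K_cross %*% (dual$alpha * y)) + dual$b
}
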