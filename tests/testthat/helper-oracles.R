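# Independent oracles used across the suite.  These deliberately avoid the
# code paths they check.

# Exhaustive simplex grid search over kernel weights: the MKL objective
# J(d) evaluated with an exact inner QP at every grid point (step `by`),
# then a local refinement pass around the coarse argmin (at large C the
# objective is sharply curved, so the 0.01 grid alone resolves the optimum
# only to a few 1e-3).
grid_search_mkl <- function(bank, y, C, by = 0.01, inner_tol = 1e-8) {
  M <- length(bank$grams)
  eval_J <- function(d)
    svm_dual_solve(combine_kernels(bank, d), y, C, tol = inner_tol)$objective
  if (M == 1) return(eval_J(1))
  best <- Inf; arg <- NULL
  consider <- function(d) {
    J <- eval_J(d)
    if (J < best) { best <<- J; arg <<- d }
  }
  if (M == 2) {
    for (d1 in seq(0, 1, by = by)) consider(c(d1, 1 - d1))
    for (d1 in seq(max(0, arg[1] - by), min(1, arg[1] + by), by = by / 40))
      consider(c(d1, 1 - d1))
  } else if (M == 3) {
    for (d1 in seq(0, 1, by = by))
      for (d2 in seq(0, 1 - d1 + 1e-12, by = by))
        consider(c(d1, d2, max(0, 1 - d1 - d2)))
    c0 <- arg
    for (d1 in seq(max(0, c0[1] - by), min(1, c0[1] + by), by = by / 10))
      for (d2 in seq(max(0, c0[2] - by), min(1 - d1, c0[2] + by), by = by / 10))
        consider(c(d1, d2, max(0, 1 - d1 - d2)))
  } else stop("grid oracle supports M <= 3")
  best
}

# Population time-domain Granger causality of a stable bivariate VAR(1)
# via exact autocovariances (Lyapunov equation) and Levinson-Durbin for
# the restricted AR innovation variance.
yule_walker_F <- function(A, Sigma = diag(2), p_restricted = 50) {
  G0 <- matrix(solve(diag(4) - kronecker(A, A), as.vector(Sigma)), 2)
  gam <- numeric(p_restricted + 1)
  gam[1] <- G0[1, 1]
  Gk <- G0
  for (k in seq_len(p_restricted)) {
    Gk <- A %*% Gk
    gam[k + 1] <- Gk[1, 1]
  }
  # Levinson-Durbin recursion for the order-p innovation variance
  a <- numeric(0)
  v <- gam[1]
  for (k in seq_len(p_restricted)) {
    acc <- gam[k + 1]
    if (k > 1) acc <- acc - sum(a * gam[k:2])
    ref <- acc / v
    a <- c(a - ref * rev(a), ref)
    v <- v * (1 - ref^2)
  }
  log(v / Sigma[1, 1])
}

# Simulate a bivariate VAR(1) trajectory (burn-in discarded).
simulate_var1_pair <- function(A, n, burnin = 500) {
  ntot <- n + burnin
  x <- matrix(0, 2, ntot)
  e <- matrix(rnorm(2 * ntot), 2)
  for (t in 2:ntot) x[, t] <- A %*% x[, t - 1] + e[, t]
  list(x1 = x[1, (burnin + 1):ntot], x2 = x[2, (burnin + 1):ntot])
}

# The worked VAR(1) coupling example: x1 <- 0.5 x1 + 0.4 x2, x2 <- 0.5 x2.
coupled_var1_A <- function(coupling = 0.4)
  matrix(c(0.5, coupling, 0, 0.5), 2, byrow = TRUE)

# Tiny linearly separable multi-class feature set.
gen_separable_features <- function(n_per_class = 10, classes = c("a", "b", "c"),
                                   gap = 6, seed = 1) {
  k <- length(classes)
  vals <- NULL; labs <- character(0)
  set.seed(seed)
  for (i in seq_len(k)) {
    ctr <- c(cos(2 * pi * i / k), sin(2 * pi * i / k)) * gap
    vals <- rbind(vals, sweep(matrix(rnorm(n_per_class * 2, sd = 0.4),
                                     n_per_class), 2, ctr, "+"))
    labs <- c(labs, rep(classes[i], n_per_class))
  }
  feature_matrix(vals, labs, provenance = "separable-fixture")
}

# Random small binary SVM/MKL instance.
random_mkl_instance <- function(n = 16, M = 2, C = 10, seed = 1) {
  set.seed(seed)
  y <- rep(c(1, -1), length.out = n)
  X <- matrix(rnorm(n * 3), n)
  X[y == 1, 1] <- X[y == 1, 1] + runif(1, 0.5, 2)
  fams <- list(kernel_spec("poly", degree = 1),
               kernel_spec("poly", degree = 2),
               kernel_spec("rbf", width = 1),
               kernel_spec("rbf", width = 3),
               kernel_spec("rbf", width = 10))
  specs <- sample(fams, M)
  list(X = X, y = y, specs = specs, C = C)
}
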