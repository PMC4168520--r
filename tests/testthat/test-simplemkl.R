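test_that("objective and gradient match the printed quadratic forms", {
  # alpha = 0: everything vanishes
  bank <- build_bank(matrix(rnorm(8), 4), default_kernel_bank()[1:2],
                     normalize = FALSE)
  y <- c(1, -1, 1, -1)
  og0 <- objective_and_gradient(list(alpha = rep(0, 4)), bank, y,
                                d = c(0.5, 0.5))
  expect_equal(og0$J, 0)
  expect_equal(og0$grad, c(0, 0))

  # n = 2, alpha = (1,1), y = (+1,-1), K = I: g_m = -1/2 (1 + 1) = -1
  bankI <- list(specs = list(kernel_spec("poly", degree = 1)),
                grams = list(diag(2)), n = 2, scale = 1, normalized = FALSE)
  class(bankI) <- "kernel_bank"
  og <- objective_and_gradient(list(alpha = c(1, 1)), bankI, c(1, -1), d = 1)
  expect_equal(og$grad, -1)
  expect_equal(og$J, 2 - 0.5 * 2)

  # gradients are nonpositive for PSD kernels
  set.seed(5)
  X <- matrix(rnorm(20), 10)
  b2 <- build_bank(X, default_kernel_bank())
  a <- runif(10)
  og2 <- objective_and_gradient(list(alpha = a), b2, rep(c(1, -1), 5),
                                d = rep(1 / 13, 13))
  expect_true(all(og2$grad <= 1e-12))
})

test_that("the reduced-gradient direction follows the simplex rules", {
  # equal partials: stationary
  expect_equal(descent_direction(c(0.3, 0.7), c(-2, -2)), c(0, 0))
  # worked 2-kernel case: mu = 1 (largest weight, ties to smallest index)
  expect_equal(descent_direction(c(0.5, 0.5), c(-1, -2)), c(-1, 1))
  # directions always sum to zero; blocked coordinates stay at zero
  set.seed(8)
  for (i in 1:20) {
    M <- sample(2:6, 1)
    d <- runif(M); d[sample(M, 1)] <- 0; d <- d / sum(d)
    g <- -runif(M)
    D <- descent_direction(d, g)
    expect_lt(abs(sum(D)), 1e-12)
    mu <- which.max(d)
    blocked <- d <= 1e-8 & (g - g[mu]) > 0
    expect_true(all(D[blocked] == 0))
  }
  expect_error(descent_direction(c(0.9, 0.9), c(-1, -1)), "simplex")
})

test_that("the duality gap vanishes for single kernels and at the argmax", {
  inst <- random_mkl_instance(n = 12, M = 1, seed = 2)
  bank <- build_bank(inst$X, inst$specs)
  dual <- svm_dual_solve(bank$grams[[1]], inst$y, inst$C)
  expect_equal(duality_gap(dual, bank, 1, inst$y), 0)

  inst3 <- random_mkl_instance(n = 12, M = 3, seed = 3)
  bank3 <- build_bank(inst3$X, inst3$specs)
  d <- rep(1 / 3, 3)
  dual3 <- svm_dual_solve(combine_kernels(bank3, d), inst3$y, inst3$C)
  og <- objective_and_gradient(dual3, bank3, inst3$y, d)
  # gap equals an independent recomputation of the two quadratic forms
  ay <- dual3$alpha * inst3$y
  qf <- vapply(bank3$grams, function(K) drop(t(ay) %*% K %*% ay), numeric(1))
  expect_equal(duality_gap(dual3, bank3, d, inst3$y),
               max(qf) - sum(d * qf), tolerance = 1e-12)
  # putting all weight on the largest quadratic form closes the gap
  ej <- as.numeric(seq_len(3) == which.max(qf))
  dual_j <- svm_dual_solve(combine_kernels(bank3, ej), inst3$y, inst3$C)
  og_j <- objective_and_gradient(dual_j, bank3, inst3$y, ej)
  qj <- og_j$quad
  expect_equal(qj[which.max(qj)] - sum(ej * qj), 0, tolerance = 1e-10)
})

test_that("line search preserves the simplex and never increases J", {
  inst <- random_mkl_instance(n = 16, M = 3, C = 10, seed = 4)
  bank <- build_bank(inst$X, inst$specs)
  st <- mkl_settings(C = 10, inner_tol = 1e-8)
  d <- rep(1 / 3, 3)
  dual <- svm_dual_solve(combine_kernels(bank, d), inst$y, 10, tol = 1e-8)
  og <- objective_and_gradient(dual, bank, inst$y, d)
  D <- descent_direction(d, og$grad)
  up <- line_search_update(d, D, bank, inst$y, st, dual = dual)
  expect_lt(abs(sum(up$d) - 1), 1e-10)
  expect_true(all(up$d >= 0))
  expect_lte(up$J, dual$objective + 1e-9)
  # zero direction: no movement
  same <- line_search_update(d, rep(0, 3), bank, inst$y, st, dual = dual)
  expect_false(same$moved)
  expect_equal(same$d, d)
})

test_that("fitting with one kernel reduces exactly to a plain SVM", {
  inst <- random_mkl_instance(n = 20, M = 1, C = 10, seed = 6)
  st <- mkl_settings(C = 10, inner_tol = 1e-8)
  m <- mkl_fit(inst$X, inst$y, inst$specs, st)
  expect_equal(m$d, 1)
  expect_equal(m$gap, 0)
  bank <- build_bank(m$X_train, inst$specs)
  plain <- svm_dual_solve(bank$grams[[1]], inst$y, 10, tol = 1e-8)
  set.seed(60)
  Xn <- matrix(rnorm(100 * 3), 100)
  Xs <- sweep(sweep(Xn, 2, m$standardizer$center), 2, m$standardizer$scale,
              "/")
  Kc <- cross_gram(bank, Xs, m$X_train)[[1]]
  expect_lt(max(abs(decision_function(m, Xn) -
                      svm_decision(plain, Kc, inst$y))), 1e-6)
})

test_that("an uninformative kernel receives less weight than an informative one", {
  set.seed(12)
  n <- 20
  y <- rep(c(1, -1), each = n / 2)
  X <- cbind(y * 1.2 + rnorm(n, sd = 0.4),   # informative feature
             rnorm(n))                       # pure noise feature
  # kernel 1 sees only the informative column, kernel 2 only the noise
  specs <- list(kernel_spec("rbf", width = 1), kernel_spec("rbf", width = 1))
  bank <- list(
    specs = specs,
    grams = list(
      build_bank(X[, 1, drop = FALSE], specs[1], normalize = FALSE)$grams[[1]],
      build_bank(X[, 2, drop = FALSE], specs[2], normalize = FALSE)$grams[[1]]),
    n = n, scale = c(1, 1), normalized = FALSE)
  class(bank) <- "kernel_bank"
  st <- mkl_settings(C = 10, gap_tol = 1e-4, inner_tol = 1e-8)
  # drive the solver directly on the prebuilt bank
  d <- c(0.5, 0.5)
  dual <- svm_dual_solve(combine_kernels(bank, d), y, 10, tol = 1e-8)
  for (i in 1:30) {
    og <- objective_and_gradient(dual, bank, y, d)
    if (duality_gap(dual, bank, d, y) <= 1e-4 * sum(d * og$quad)) break
    up <- line_search_update(d, descent_direction(d, og$grad), bank, y, st,
                             dual = dual)
    if (!up$moved) break
    d <- up$d; dual <- up$dual
  }
  expect_gt(d[1], d[2])
  # and the final objective matches the exhaustive grid oracle
  expect_lt(abs(dual$objective - grid_search_mkl(bank, y, 10)), 1e-3)
})

test_that("fit objective matches the simplex grid oracle on small instances", {
  st <- function(C) mkl_settings(C = C, gap_tol = 1e-6, gap_abs = 1e-8,
                                 inner_tol = 1e-8, max_outer = 200)
  for (seed in 1:4) {
    inst <- random_mkl_instance(n = 14, M = 2, C = c(1, 10)[seed %% 2 + 1],
                                seed = 20 + seed)
    m <- suppressWarnings(mkl_fit(inst$X, inst$y, inst$specs, st(inst$C)))
    bank <- build_bank(m$X_train, inst$specs)
    J_grid <- grid_search_mkl(bank, inst$y, inst$C)
    expect_lt(abs(m$J - J_grid), 1e-3)
    expect_true(all(diff(m$J_path) <= 1e-9))
    expect_lt(abs(sum(m$d) - 1), 1e-10)
    expect_true(all(m$d >= 0))
  }
})

test_that("margin support vectors score near their labels", {
  inst <- random_mkl_instance(n = 24, M = 2, C = 10, seed = 31)
  m <- suppressWarnings(mkl_fit(inst$X, inst$y, inst$specs,
                                mkl_settings(C = 10, inner_tol = 1e-8)))
  free <- m$dual$alpha > 1e-5 & m$dual$alpha < 10 - 1e-5
  if (any(free)) {
    sc <- decision_function(m, inst$X[free, , drop = FALSE])
    expect_equal(sc, inst$y[free], tolerance = 1e-3)
  }
  expect_error(decision_function(m, matrix(0, 2, 5)), "dimension mismatch")
})
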