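test_that("region averaging reduces the montage to five mean signals", {
  set.seed(1)
  chans <- c("FP1", "FP2", "F7", "F3", "FZ", "F4", "F8", "C3", "P3",
             "CZ", "PZ", "C4", "P4", "O1", "O2")
  data <- array(rnorm(2 * 15 * 128), c(2, 15, 128))
  ep <- epoched_eeg(data, 256, chans, labels = c("x", "y"))
  ra <- region_average(ep)
  expect_equal(ra$channels, c("F", "L", "C", "R", "O"))
  expect_equal(dim(ra$data)[2], 5)
  expect_equal(ra$data[1, 3, ], colMeans(rbind(data[1, 10, ], data[1, 11, ])))
  # Cz = Pz = x gives the region signal x
  data[, 10, ] <- data[, 11, ]
  ep2 <- epoched_eeg(data, 256, chans)
  expect_equal(region_average(ep2)$data[1, 3, ], data[1, 10, ])
  # channel order must not matter
  perm <- sample(15)
  ep3 <- epoched_eeg(data[, perm, , drop = FALSE], 256, chans[perm])
  expect_equal(region_average(ep3)$data, region_average(ep2)$data)
  expect_error(region_average(epoched_eeg(data[, 1:9, , drop = FALSE],
                                          256, chans[1:9])), "not present")
})

test_that("least-squares VAR recovers known coefficients", {
  set.seed(2)
  A <- coupled_var1_A(0.4)
  sim <- simulate_var1_pair(A, 5000)
  fit <- fit_var_pair(sim$x1, sim$x2, 1)
  expect_lt(max(abs(fit$A[, , 1] - A)), 0.05)
  # residuals orthogonal to the regressors (normal equations)
  n <- 5000
  Z <- cbind(sim$x1[1:(n - 1)] - mean(sim$x1),
             sim$x2[1:(n - 1)] - mean(sim$x2))
  expect_lt(max(abs(crossprod(Z, fit$residuals))) / n, 1e-8)
  expect_error(fit_var_pair(rnorm(30), rnorm(30), 5), "too short")
  expect_error(fit_var_pair(rep(1, 100), rnorm(100), 2), "rank-deficient")
})

test_that("time-domain causality matches the Yule-Walker oracle", {
  A <- coupled_var1_A(0.4)
  F_oracle <- yule_walker_F(A)
  set.seed(3)
  sim <- simulate_var1_pair(A, 20000)
  F21 <- gc_time(sim$x1, sim$x2, 5)
  F12 <- gc_time(sim$x2, sim$x1, 5)
  expect_lt(abs(F21 - F_oracle), 0.02)
  expect_lt(F12, 0.01)
  expect_gt(F21, F12)     # directionality
  # independent noise: no causality either way
  set.seed(4)
  expect_lt(gc_time(rnorm(10000), rnorm(10000), 5), 0.01)
})

test_that("spectral causality vanishes without coupling and peaks in theta", {
  m0 <- structure(list(A = array(c(0.5, 0, 0, 0.3), c(2, 2, 1)),
                       Sigma = diag(2), p = 1), class = "var_model")
  sp0 <- spectral_gc(m0, fs = 256)
  expect_lt(max(abs(sp0$causality)), 1e-10)
  expect_error(spectral_gc(structure(list(A = array(c(1.2, 0, 0, 0.3),
                                                    c(2, 2, 1)),
                                          Sigma = diag(2), p = 1),
                                     class = "var_model"), fs = 256),
               "unstable")
  # theta-resonant source driving a target: causality peaks in 4-8 Hz
  rg <- c("S", "T")
  cp <- matrix(c(0, 0.15, 0, 0), 2, 2, byrow = TRUE,
               dimnames = list(rg, rg))
  spec <- connectivity_spec(cp, regions = rg, resonance = 6, pole_r = 0.96)
  ep <- gen_coupled_var(spec, 1, n_samples = 16384, seed = 7)
  fit <- fit_var_pair(ep$data[1, 2, ], ep$data[1, 1, ], 5)
  sp <- spectral_gc(fit, fs = 256)
  pk <- sp$freq[which.max(sp$causality)]
  expect_gte(pk, 4); expect_lte(pk, 8)
  # Geweke consistency: the spectral average approximates the time-domain F
  F_t <- gc_time(ep$data[1, 2, ], ep$data[1, 1, ], 5)
  expect_lt(abs(mean(sp$causality) - F_t) / F_t, 0.15)
})

test_that("connectivity features cover all ordered pairs deterministically", {
  sp <- default_control_spec()
  ep <- gen_coupled_var(sp, 3, n_samples = 768, seed = 5)
  f <- gc_features(ep, p = 5)
  expect_equal(ncol(f$values), 20)
  expect_equal(colnames(f$values)[1:4], c("F->L", "F->C", "F->R", "F->O"))
  expect_true(all(f$values > -1e-10))
  ep$data[2, , ] <- ep$data[1, , ]
  f2 <- gc_features(ep, p = 5)
  expect_equal(f2$values[1, ], f2$values[2, ])
})

test_that("halving designated couplings halves the group-mean connectivity", {
  ctrl <- gen_coupled_var(default_control_spec(), 12, seed = 31)
  pat <- gen_coupled_var(default_patient_spec(), 12, seed = 32)
  fc <- gc_features(ctrl, p = 5)
  fp <- gc_features(pat, p = 5)
  pairs <- c("F->C", "C->F", "L->R")
  ratio <- sum(colMeans(fp$values[, pairs])) /
    sum(colMeans(fc$values[, pairs]))
  expect_lt(ratio, 0.5)
  tt <- connectivity_group_test(
    feature_matrix(rbind(fc$values, fp$values),
                   c(fc$labels, fp$labels)))
  expect_equal(sort(tt$groups), c("control", "patient"))
  expect_equal(nrow(tt$per_pair), 20)
})
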