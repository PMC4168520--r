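test_that("generators are bit-identical under a fixed seed", {
  sp <- list(mental_task_spec("a", band_power = c(1, 1, 2, 1)),
             mental_task_spec("b"))
  e1 <- gen_mental_eeg(sp, 2, seed = 42)
  e2 <- gen_mental_eeg(sp, 2, seed = 42)
  expect_identical(e1$data, e2$data)
  e3 <- gen_mental_eeg(sp, 2, seed = 43)
  expect_false(identical(e1$data, e3$data))
  v1 <- gen_coupled_var(default_control_spec(), 2, n_samples = 512, seed = 9)
  v2 <- gen_coupled_var(default_control_spec(), 2, n_samples = 512, seed = 9)
  expect_identical(v1$data, v2$data)
})

test_that("band carriers concentrate their spectral power in the nominal band", {
  spec <- mental_task_spec("pure", band_power = c(0, 0, 1, 0), noise = 0)
  ep <- gen_mental_eeg(list(spec, mental_task_spec("other", noise = 0)),
                       1, seed = 5)
  x <- ep$data[1, 1, ]
  n <- length(x); fs <- 250
  pw <- Mod(stats::fft(x))^2
  fr <- (seq_len(n) - 1) * fs / n
  sel <- fr <= fs / 2
  share <- sum(pw[sel & fr >= 8 & fr <= 12]) / sum(pw[sel])
  expect_gte(share, 0.9)
})

test_that("mental-task geometry matches the recording conventions", {
  sp <- list(mental_task_spec("a"), mental_task_spec("b"))
  ep <- gen_mental_eeg(sp, 3, seed = 1)
  expect_equal(dim(ep$data), c(6, 6, 2500))   # 10 s at 250 Hz
  expect_equal(ep$fs, 250)
  expect_equal(ep$channels, c("C3", "C4", "P3", "P4", "O1", "O2"))
  expect_equal(table(ep$labels)[["a"]], 3)
  expect_error(gen_mental_eeg(sp, 0, seed = 1), "positive")
  expect_error(gen_mental_eeg(sp[1], 2, seed = 1), "at least 2")
})

test_that("a 4:1 alpha-power contrast separates the alpha entropy columns", {
  specs <- list(mental_task_spec("high_alpha", band_power = c(1, 1, 4, 1)),
                mental_task_spec("low_alpha", band_power = c(1, 1, 1, 1)))
  ep <- gen_mental_eeg(specs, 40, seed = 11)
  fm <- wpe_features(ep, normalized = FALSE)
  alpha <- rowMeans(fm$values[, grep("_alpha$", colnames(fm$values))])
  g1 <- alpha[fm$labels == "high_alpha"]
  g2 <- alpha[fm$labels == "low_alpha"]
  d <- (mean(g1) - mean(g2)) / sqrt((stats::var(g1) + stats::var(g2)) / 2)
  expect_gt(abs(d), 1.5)
})

test_that("identical class specs carry no class information", {
  specs <- list(mental_task_spec("a"), mental_task_spec("b"))
  ep <- gen_mental_eeg(specs, 12, seed = 21)
  fm <- wpe_features(ep, normalized = FALSE)
  cv <- suppressWarnings(
    kfold_cv(fm, k = 4, specs = list(kernel_spec("rbf", width = 5)),
             settings = mkl_settings(C = 10, inner_tol = 1e-3), seed = 3))
  ci_half <- 1.96 * sqrt(0.25 / 24)
  expect_lt(abs(cv$mean_accuracy - 0.5), ci_half + 0.2)
})

test_that("coupled-VAR generation enforces stability and known nulls", {
  rg <- c("A", "B")
  expect_error(connectivity_spec(matrix(c(0, 3, 3, 0), 2), regions = rg),
               "unstable")
  # zero coupling: pairwise causality stays at the estimation floor
  sp0 <- connectivity_spec(matrix(0, 2, 2), regions = rg,
                           resonance = c(6, 5), pole_r = 0.9)
  ep <- gen_coupled_var(sp0, 4, n_samples = 2500, seed = 13)
  for (tr in 1:4) {
    expect_lt(gc_time(ep$data[tr, 1, ], ep$data[tr, 2, ], 5), 0.02)
    expect_lt(gc_time(ep$data[tr, 2, ], ep$data[tr, 1, ], 5), 0.02)
  }
})

test_that("directed coupling dominates its reverse direction across trials", {
  rg <- c("F", "C")
  cp <- matrix(c(0, 0.4, 0, 0), 2, 2, byrow = TRUE,
               dimnames = list(rg, rg))
  spec <- connectivity_spec(cp, regions = rg, resonance = 6, pole_r = 0.96)
  ep <- gen_coupled_var(spec, 40, n_samples = 1024, seed = 17)
  f <- gc_features(ep, p = 5)
  expect_gte(mean(f$values[, "F->C"] > f$values[, "C->F"]), 0.95)
})

test_that("the two-group study is subject-structured and contrast-bearing", {
  st <- gen_two_group_study(subjects_per_group = 13, trials_per_subject = 2,
                            seed = 19)
  expect_equal(length(unique(st$subjects)), 26)
  expect_equal(dim(st$data)[1], 52)
  expect_equal(sort(unique(st$labels)), c("control", "patient"))
  expect_warning(
    gen_two_group_study(default_control_spec(), default_control_spec(),
                        subjects_per_group = 2, trials_per_subject = 1,
                        jitter_sd = 0, seed = 1),
    "degenerate")
})
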