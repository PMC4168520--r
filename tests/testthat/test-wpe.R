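test_that("the packet filter bank reconstructs perfectly and conserves energy", {
  set.seed(1)
  for (len in c(2048, 2500)) {
    x <- rnorm(len)
    tree <- wpt_decompose(x, "db4", 4)
    xr <- Reduce(`+`, lapply(0:15, function(i) wpt_reconstruct_node(tree, 4, i)))
    expect_lt(max(abs(xr - x)), 1e-8)
    energy <- sum(vapply(0:15, function(i) sum(wpt_coef(tree, 4, i)^2),
                         numeric(1)))
    expect_lt(abs(energy - sum(x^2)) / sum(x^2), 1e-6)
  }
  # zero in, zero out; depth and length validation
  z <- wpt_decompose(numeric(64), "db4", 3)
  expect_true(all(abs(wpt_coef(z, 3, 2)) == 0))
  expect_error(wpt_decompose(rnorm(4), "db4", 2), "filter span")
  expect_error(wpt_decompose(rnorm(64), "db9", 2), "unsupported")
})

test_that("packet nodes are ordered by frequency", {
  fs <- 256
  t <- seq_len(4096) / fs
  # tones at increasing frequencies land in increasing level-3 nodes
  for (case in list(c(10, 0), c(40, 2), c(70, 4), c(100, 6), c(120, 7))) {
    x <- sin(2 * pi * case[1] * t)
    tree <- wpt_decompose(x, "db4", 3)
    en <- vapply(0:7, function(i) sum(wpt_coef(tree, 3, i)^2), numeric(1))
    expect_equal(which.max(en) - 1, case[2])
  }
})

test_that("a 6 Hz tone concentrates in the theta band of the edge-aligned map", {
  fs <- 250
  x <- sin(2 * pi * 6 * seq_len(2500) / fs)
  tree <- wpt_decompose(x, "db4", 5)
  map <- band_map(fs, "edges")
  en <- vapply(names(map), function(b) sum(reconstruct_band(tree, b, map)^2),
               numeric(1))
  expect_gte(en[["theta"]] / sum(en), 0.8)
})

test_that("band components sum back to the signal and unknown bands error", {
  set.seed(2)
  x <- rnorm(1600)
  fs <- 250
  map <- band_map(fs, "edges")
  tree <- wpt_decompose(x, "db4", 5)
  mapped <- do.call(rbind, unlist(map, recursive = FALSE))
  unmapped <- setdiff(0:31, mapped[, 2])
  total <- Reduce(`+`, lapply(names(map), function(b)
    reconstruct_band(tree, b, map))) +
    Reduce(`+`, lapply(unmapped, function(i) wpt_reconstruct_node(tree, 5, i)))
  expect_lt(max(abs(total - x)), 1e-8)
  expect_error(reconstruct_band(tree, "gamma", map), "unknown band")
  expect_true(all(abs(reconstruct_band(wpt_decompose(numeric(320), "db4", 5),
                                       "theta", map)) == 0))
})

test_that("band-limited noise is loudest in its own band component", {
  fs <- 250
  map <- band_map(fs, "edges")
  edges <- list(delta = c(0.5, 4), theta = c(4, 8),
                alpha = c(8, 12), beta = c(12, 32))
  set.seed(3)
  for (b in names(edges)) {
    bf <- signal::butter(4, edges[[b]] / (fs / 2), type = "pass")
    x <- signal::filtfilt(bf, rnorm(3000))[251:2750]
    tree <- wpt_decompose(x, "db4", 5)
    en <- vapply(names(map), function(bb)
      sum(reconstruct_band(tree, bb, map)^2), numeric(1))
    expect_equal(names(which.max(en)), b)
  }
})

test_that("Shannon entropy reproduces the worked values in both modes", {
  expect_equal(shannon_entropy(c(1, 0, 0)), 0)
  expect_equal(shannon_entropy(c(1, 0, 0), normalized = FALSE), 0)
  two <- c(sqrt(0.5), sqrt(0.5))
  expect_equal(shannon_entropy(two), log(2))
  expect_equal(shannon_entropy(two, normalized = FALSE), log(2))
  expect_equal(shannon_entropy(numeric(8)), 0)
  # normalized mode is scale-invariant and bounded by log(T)
  set.seed(4)
  f <- rnorm(200)
  expect_equal(shannon_entropy(3.7 * f), shannon_entropy(f))
  expect_lte(shannon_entropy(f), log(200))
  expect_gte(shannon_entropy(f), 0)
  # literal mode scales: SE(cf) = c^2 SE(f) - c^2 log(c^2) E(f)
  c0 <- 1.3
  expect_equal(shannon_entropy(c0 * f, normalized = FALSE),
               c0^2 * shannon_entropy(f, normalized = FALSE) -
                 c0^2 * log(c0^2) * sum(f^2))
})

test_that("feature extraction yields one entropy per channel and band", {
  spec <- mental_task_spec("a", band_power = c(1, 2, 1, 1))
  spec2 <- mental_task_spec("b", band_power = c(1, 1, 1, 2))
  ep <- gen_mental_eeg(list(spec, spec2), 2, seed = 9)
  fm <- wpe_features(ep)
  expect_equal(ncol(fm$values), 24)
  expect_equal(colnames(fm$values)[1:4],
               paste("C3", c("delta", "theta", "alpha", "beta"), sep = "_"))
  expect_equal(fm$labels, ep$labels)
  # identical trials give identical rows
  ep2 <- ep
  ep2$data[2, , ] <- ep2$data[1, , ]
  fm2 <- wpe_features(ep2)
  expect_equal(fm2$values[1, ], fm2$values[2, ])
  # all-zero trial: zero entropies (build by hand; the container forbids NaN)
  ep3 <- epoched_eeg(array(0, c(2, 1, 320)), fs = 250, channels = "CZ",
                     labels = c("a", "b"))
  expect_true(all(wpe_features(ep3)$values == 0))
})
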