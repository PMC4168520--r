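#' Class specification for synthetic mental-task EEG
#'
#' Describes one class of the band-power generator: each trial is a sum of
#' band-limited Gaussian noise carriers (delta 0.5-4, theta 4-8, alpha
#' 8-12, beta 12-32 Hz), scaled per class and channel, plus a broadband
#' noise floor.  Defaults mirror the mental-task recording geometry:
#' 6 channels, 250 Hz, 10 s trials.
#'
#' @param name class label.
#' @param band_power length-4 nonnegative relative power
#'   (delta, theta, alpha, beta).
#' @param channel_gain per-channel gain vector.
#' @param noise broadband noise floor standard deviation.
#' @param fs sampling rate in Hz.
#' @param duration trial length in seconds.
#' @return list of class `mental_task_spec`.
#' @export
mental_task_spec <- function(name, band_power = c(1, 1, 1, 1),
                             channel_gain = rep(1, 6), noise = 0.5,
                             fs = 250, duration = 10) {
  if (length(band_power) != 4 || any(band_power < 0))
    stop("band_power must be four nonnegative values")
  structure(list(name = name, band_power = as.numeric(band_power),
                 channel_gain = as.numeric(channel_gain),
                 noise = noise, fs = fs, duration = duration),
            class = "mental_task_spec")
}

band_edges_hz <- function() list(delta = c(0.5, 4), theta = c(4, 8),
                                 alpha = c(8, 12), beta = c(12, 32))

## Zero-phase band-limited Gaussian noise, unit variance before scaling.
bandlimited_noise <- function(n, fs, band, order = 4) {
  bf <- signal::butter(order, band / (fs / 2), type = "pass")
  x <- signal::filtfilt(bf, stats::rnorm(n + 2 * fs))
  x <- x[(fs + 1):(fs + n)]               # drop filter edge transients
  x / stats::sd(x)
}

#' Generate synthetic mental-task EEG epochs
#'
#' Deterministic for a given seed; same seed, same output bit for bit.
#'
#' @param specs list of [mental_task_spec()] (>= 2 classes).
#' @param trials_per_class trials generated per class.
#' @param seed RNG seed.
#' @param channels channel labels (the 6-electrode montage by default).
#' @return an [epoched_eeg()] with class labels attached.
#' @export
gen_mental_eeg <- function(specs, trials_per_class, seed = 1,
                           channels = c("C3", "C4", "P3", "P4", "O1", "O2")) {
  if (length(specs) < 2) stop("need at least 2 class specs")
  if (trials_per_class < 1) stop("trials_per_class must be positive")
  fs <- specs[[1]]$fs
  n <- round(fs * specs[[1]]$duration)
  n_ch <- length(channels)
  edges <- band_edges_hz()
  n_tot <- length(specs) * trials_per_class
  data <- array(0, c(n_tot, n_ch, n))
  labels <- character(n_tot)
  with_seed(seed, {
    tr <- 0L
    for (sp in specs) {
      if (length(sp$channel_gain) != n_ch)
        stop("channel_gain length must match the montage")
      for (r in seq_len(trials_per_class)) {
        tr <- tr + 1L
        labels[tr] <- sp$name
        for (ch in seq_len(n_ch)) {
          sig <- numeric(n)
          for (b in seq_along(edges))
            if (sp$band_power[b] > 0)
              sig <- sig + sqrt(sp$band_power[b]) *
                bandlimited_noise(n, fs, edges[[b]])
          data[tr, ch, ] <- sp$channel_gain[ch] * sig +
            sp$noise * stats::rnorm(n)
        }
      }
    }
  })
  epoched_eeg(data, fs = fs, channels = channels, labels = labels)
}

#' Coupled vector-autoregression specification for region signals
#'
#' Five coupled regions, each an AR(2) oscillator resonating at
#' `resonance` Hz (poles at radius `pole_r`), with directed lag-1 coupling
#' `coupling[source, target]`.  The generated VAR must be stable
#' (companion spectral radius < 0.98).
#'
#' @param coupling square matrix of directed strengths, rows = source,
#'   columns = target, zero diagonal.
#' @param regions region names.
#' @param resonance oscillator frequency in Hz; a scalar or one value per
#'   region (staggered frequencies keep the coupled network
#'   well-conditioned).
#' @param pole_r pole radius of the oscillators (0 < r < 1).
#' @param noise_sd innovation standard deviation.
#' @param fs sampling rate in Hz.
#' @param group group label carried to generated epochs.
#' @return list of class `connectivity_spec`.
#' @export
connectivity_spec <- function(coupling,
                              regions = c("F", "L", "C", "R", "O"),
                              resonance = 6, pole_r = 0.85,
                              noise_sd = 1, fs = 256, group = "control") {
  coupling <- as.matrix(coupling)
  k <- length(regions)
  if (!all(dim(coupling) == k)) stop("coupling must be regions x regions")
  if (any(diag(coupling) != 0)) stop("coupling diagonal must be zero")
  if (!length(resonance) %in% c(1L, k))
    stop("resonance must be scalar or one value per region")
  spec <- structure(list(coupling = coupling, regions = regions,
                         resonance = resonance, pole_r = pole_r,
                         noise_sd = noise_sd, fs = fs, group = group),
                    class = "connectivity_spec")
  if (var_spectral_radius(spec_var_coefficients(spec)) >= 0.98)
    stop("unstable connectivity spec (companion spectral radius >= 0.98)")
  spec
}

## VAR coefficient array (k x k x 2) implied by a connectivity spec.
spec_var_coefficients <- function(spec) {
  k <- length(spec$regions)
  theta <- 2 * pi * rep_len(spec$resonance, k) / spec$fs
  A <- array(0, c(k, k, 2))
  diag(A[, , 1]) <- 2 * spec$pole_r * cos(theta)
  diag(A[, , 2]) <- -spec$pole_r^2
  A[, , 1] <- A[, , 1] + t(spec$coupling)   # A[target, source] at lag 1
  A
}

#' Default control-group coupling pattern
#'
#' A sparse directed network concentrated on fronto-central interactions
#' (`F->C`, `C->F`, `L->R`, `F->L`, `O->C`, `F->O`).  Region oscillators
#' are staggered inside the theta band (5.2-6.8 Hz) so the coupled network
#' stays well away from the stability margin; because the oscillators are
#' high-Q, these modest lag-1 couplings already produce strong directed
#' theta causality.
#'
#' @param fs sampling rate in Hz.
#' @return a [connectivity_spec()].
#' @export
default_control_spec <- function(fs = 256) {
  rg <- c("F", "L", "C", "R", "O")
  cp <- matrix(0, 5, 5, dimnames = list(rg, rg))
  cp["F", "C"] <- 0.018; cp["C", "F"] <- 0.009; cp["L", "R"] <- 0.018
  cp["F", "L"] <- 0.015; cp["O", "C"] <- 0.015; cp["F", "O"] <- 0.012
  connectivity_spec(cp, regions = rg, fs = fs, group = "control",
                    resonance = c(6.4, 5.6, 6.0, 5.2, 6.8), pole_r = 0.95)
}

#' @describeIn default_control_spec the patient pattern: the designated
#'   couplings (`F->C`, `C->F`, `L->R` by default) reduced by `factor`,
#'   emulating the reduced fronto-central connectivity of the patient
#'   group.
#' @param reduce character vector of `"SRC->TGT"` couplings to reduce.
#' @param factor multiplicative reduction applied to those couplings.
#' @export
default_patient_spec <- function(fs = 256,
                                 reduce = c("F->C", "C->F", "L->R"),
                                 factor = 0.5) {
  sp <- default_control_spec(fs)
  cp <- sp$coupling
  for (edge in reduce) {
    st <- strsplit(edge, "->", fixed = TRUE)[[1]]
    cp[st[1], st[2]] <- cp[st[1], st[2]] * factor
  }
  connectivity_spec(cp, regions = sp$regions, fs = fs, group = "patient",
                    resonance = sp$resonance, pole_r = sp$pole_r,
                    noise_sd = sp$noise_sd)
}

## Simulate one VAR trajectory (n samples after burn-in).
simulate_var <- function(A, noise_sd, n, burnin = 500) {
  k <- dim(A)[1]; p <- dim(A)[3]
  n_tot <- n + burnin
  X <- matrix(0, k, n_tot)
  X[, 1:p] <- stats::rnorm(k * p, sd = noise_sd)
  E <- matrix(stats::rnorm(k * n_tot, sd = noise_sd), k, n_tot)
  for (t in (p + 1):n_tot) {
    acc <- E[, t]
    for (j in seq_len(p)) acc <- acc + A[, , j] %*% X[, t - j]
    X[, t] <- acc
  }
  X[, (burnin + 1):n_tot, drop = FALSE]
}

#' Generate coupled-VAR region epochs
#'
#' Simulates trials from the spec's VAR with >= 500 burn-in samples
#' discarded, so the ground-truth directed-coupling pattern is known
#' exactly.
#'
#' @param spec a [connectivity_spec()].
#' @param trials number of trials.
#' @param n_samples samples per trial (default 4 s at the spec's rate).
#' @param seed RNG seed.
#' @param burnin discarded initial samples per trial.
#' @return an [epoched_eeg()] with 5 region channels, labelled by the
#'   spec's group.
#' @export
gen_coupled_var <- function(spec, trials, n_samples = NULL, seed = 1,
                            burnin = 500) {
  stopifnot(inherits(spec, "connectivity_spec"))
  if (trials < 1) stop("trials must be positive")
  burnin <- max(burnin, 500)
  A <- spec_var_coefficients(spec)
  if (var_spectral_radius(A) >= 0.98)
    stop("unstable connectivity spec (companion spectral radius >= 0.98)")
  n_samples <- n_samples %||% round(4 * spec$fs)
  k <- length(spec$regions)
  data <- array(0, c(trials, k, n_samples))
  with_seed(seed, {
    for (tr in seq_len(trials))
      data[tr, , ] <- simulate_var(A, spec$noise_sd, n_samples, burnin)
  })
  epoched_eeg(data, fs = spec$fs, channels = spec$regions,
              labels = rep(spec$group, trials))
}

#' Generate a two-group connectivity study
#'
#' Emulates a patients-versus-controls design (13 + 13 subjects by
#' default): every subject gets the group coupling matrix perturbed by
#' independent lognormal gains (`exp(rnorm(0, jitter_sd))` per edge), and
#' contributes `trials_per_subject` simulated trials.  Subject identifiers
#' are attached so the cross-validation harness can split by subject.
#'
#' @param control_spec,patient_spec group-level [connectivity_spec()]s.
#' @param subjects_per_group subjects per group.
#' @param trials_per_subject trials per subject.
#' @param seed RNG seed.
#' @param jitter_sd lognormal sigma of the subject-level coupling jitter.
#' @param n_samples samples per trial.
#' @return an [epoched_eeg()] with group labels and subject ids.
#' @export
gen_two_group_study <- function(control_spec = default_control_spec(),
                                patient_spec = default_patient_spec(),
                                subjects_per_group = 13,
                                trials_per_subject = 8,
                                seed = 1, jitter_sd = 0.1,
                                n_samples = NULL) {
  stopifnot(inherits(control_spec, "connectivity_spec"),
            inherits(patient_spec, "connectivity_spec"))
  if (identical(control_spec$coupling, patient_spec$coupling) &&
      jitter_sd == 0)
    warning("identical group specs with zero jitter: degenerate study")
  fs <- control_spec$fs
  n_samples <- n_samples %||% round(4 * fs)
  k <- length(control_spec$regions)
  n_tr <- 2 * subjects_per_group * trials_per_subject
  data <- array(0, c(n_tr, k, n_samples))
  labels <- character(n_tr); subjects <- character(n_tr)
  with_seed(seed, {
    tr <- 0L
    for (grp in list(control_spec, patient_spec)) {
      for (s in seq_len(subjects_per_group)) {
        jitter <- matrix(exp(stats::rnorm(k * k, sd = jitter_sd)), k, k)
        cp <- grp$coupling * jitter
        A <- grp
        A$coupling <- cp
        Av <- spec_var_coefficients(A)
        # keep jittered subjects inside the stability margin
        while (var_spectral_radius(Av) >= 0.98) {
          cp <- cp * 0.9
          A$coupling <- cp
          Av <- spec_var_coefficients(A)
        }
        sid <- sprintf("%s_%02d", grp$group, s)
        for (t in seq_len(trials_per_subject)) {
          tr <- tr + 1L
          data[tr, , ] <- simulate_var(Av, grp$noise_sd, n_samples, 500)
          labels[tr] <- grp$group
          subjects[tr] <- sid
        }
      }
    }
  })
  epoched_eeg(data, fs = fs, channels = control_spec$regions,
              labels = labels, subjects = subjects)
}
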