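#' Semi-Markov simulation parameters
#'
#' The generator is an alternating renewal (semi-Markov) process over
#' Wake/NREM/REM: on entering a state it draws a bout length (>= 2 epochs)
#' from a state-by-phase distribution, then picks the next state from exit
#' transition probabilities. Wake never exits directly to REM, and bout
#' lengths are never 1 epoch, so generated hypnograms are fixpoints of
#' [apply_scoring_rules()] by construction.
#'
#' Defaults describe a nocturnal mouse under LD12:12: longer wake bouts and
#' more frequent REM entries from NREM in the phases where wake/sleep
#' respectively dominate; NREM EEG delta-dominant, REM theta-peaked, Wake
#' broadband; activity concentrated in dark-phase wake; a circadian
#' subcutaneous-temperature rhythm with state offsets and AR(1) noise.
#'
#' @param bout_mean Named 3x2 matrix (rows `W`,`N`,`R`; cols `LIGHT`,`DARK`)
#'   of mean bout lengths in epochs; all > 2.
#' @param bout_family `"geometric"` (shifted to support `{2, 3, ...}`) or
#'   `"lognormal"` (discretized, truncated below at 2).
#' @param bout_sdlog Log-scale SD for the lognormal family.
#' @param trans Named list of exit probabilities: `W` (`c(N=..., R=0)`), `N`
#'   (`c(W=..., R=...)` per phase) and `R` (`c(W=..., N=...)`); each must sum
#'   to 1.
#' @param eeg List: `band_weights` 3x5 matrix (state x band, bands of
#'   [default_bands()]) of amplitude weights for unit-variance band-limited
#'   Gaussian components; `amplitude` overall scale.
#' @param activity Named 3x2 matrix of Poisson rates (counts/min).
#' @param tsc List: `mesor_c`, `amplitude_c`, `acrophase_zt_h`,
#'   `state_offset_c` (named, per state), `ar1_phi`, `sigma_c`.
#' @return Object of class `"sim_params"`.
#' @export
sim_params <- function(
    bout_mean = rbind(W = c(LIGHT = 9, DARK = 24),
                      N = c(LIGHT = 12, DARK = 9),
                      R = c(LIGHT = 7, DARK = 6)),
    bout_family = c("geometric", "lognormal"),
    bout_sdlog = 0.5,
    trans = list(
      W = c(N = 1, R = 0),
      N = list(LIGHT = c(W = 0.65, R = 0.35), DARK = c(W = 0.75, R = 0.25)),
      R = c(W = 0.6, N = 0.4)),
    eeg = list(
      band_weights = rbind(
        W = c(delta = 0.6, theta = 0.8, alpha = 0.6, beta = 0.5, low_gamma = 0.4),
        N = c(delta = 2.0, theta = 0.6, alpha = 0.4, beta = 0.3, low_gamma = 0.2),
        R = c(delta = 0.5, theta = 1.6, alpha = 0.5, beta = 0.3, low_gamma = 0.2)),
      amplitude = 1),
    activity = rbind(W = c(LIGHT = 8, DARK = 20),
                     N = c(LIGHT = 0.5, DARK = 0.5),
                     R = c(LIGHT = 0.2, DARK = 0.2)),
    tsc = list(mesor_c = 36.5, amplitude_c = 0.7, acrophase_zt_h = 18,
               state_offset_c = c(W = 0.2, N = -0.1, R = -0.15),
               ar1_phi = 0.8, sigma_c = 0.05)) {
  bout_family <- match.arg(bout_family)
  if (any(bout_mean < 2)) stop("mean bout lengths must be >= 2 epochs")
  if (abs(sum(trans$W) - 1) > 1e-9) stop("Wake exit probabilities must sum to 1")
  if (trans$W[["R"]] != 0) stop("direct Wake -> REM transitions are not allowed")
  for (ph in c("LIGHT", "DARK"))
    if (abs(sum(trans$N[[ph]]) - 1) > 1e-9)
      stop("NREM exit probabilities must sum to 1 (", ph, ")")
  if (abs(sum(trans$R) - 1) > 1e-9) stop("REM exit probabilities must sum to 1")
  if (any(unlist(trans) < 0) || any(unlist(trans) > 1))
    stop("transition probabilities must lie in [0, 1]")
  if (any(activity < 0)) stop("activity rates must be >= 0")
  structure(list(bout_mean = bout_mean, bout_family = bout_family,
                 bout_sdlog = bout_sdlog, trans = trans, eeg = eeg,
                 activity = activity, tsc = tsc),
            class = "sim_params")
}

#' Apply the standard "mutant" effect preset to simulation parameters
#'
#' Presets mirror the qualitative phenotype of an amyloid knock-in strain:
#' dark-phase wake bouts twice as long, REM entries from NREM reduced (x0.6,
#' giving fewer REM bouts), REM-epoch theta EEG power reduced (amplitude
#' x sqrt(0.7), i.e. power x0.7), and in females a further REM-entry deficit.
#' These are presets for simulation studies, not estimates of any dataset.
#'
#' @param params A [sim_params()].
#' @param sex `"M"` or `"F"`.
#' @param wake_dark_x Multiplier on the dark-phase wake mean bout length.
#' @param rem_entry_x Multiplier on P(NREM -> REM) (renormalized).
#' @param rem_theta_power_x Multiplier on REM theta band *power*.
#' @param female_rem_entry_x Additional REM-entry multiplier for females.
#' @return Modified `"sim_params"` object.
#' @export
mutant_params <- function(params = sim_params(), sex = "M",
                          wake_dark_x = 2, rem_entry_x = 0.6,
                          rem_theta_power_x = 0.7,
                          female_rem_entry_x = 0.8) {
  params$bout_mean["W", "DARK"] <- params$bout_mean["W", "DARK"] * wake_dark_x
  mult <- rem_entry_x * if (identical(sex, "F")) female_rem_entry_x else 1
  for (ph in c("LIGHT", "DARK")) {
    pr <- params$trans$N[[ph]]["R"] * mult
    params$trans$N[[ph]] <- c(W = unname(1 - pr), R = unname(pr))
  }
  params$eeg$band_weights["R", "theta"] <-
    params$eeg$band_weights["R", "theta"] * sqrt(rem_theta_power_x)
  params
}

draw_bout_length <- function(params, state, phase, n = 1L) {
  m <- params$bout_mean[state, phase]
  if (params$bout_family == "geometric") {
    if (m <= 2) return(rep(2L, n))
    2L + stats::rgeom(n, prob = 1 / (m - 1))
  } else {
    mu <- log(m) - params$bout_sdlog^2 / 2
    pmax(2L, as.integer(round(stats::rlnorm(n, mu, params$bout_sdlog))))
  }
}

next_state <- function(params, state, phase) {
  p <- switch(state,
              W = params$trans$W,
              N = params$trans$N[[phase]],
              R = params$trans$R)
  sample(names(p), 1L, prob = p)
}

#' Simulate a semi-Markov hypnogram
#'
#' Alternating renewal process: draw the next state from the exit-transition
#' probabilities of the current state, draw a bout length (>= 2 epochs) from
#' the state-by-phase distribution (phase taken at bout onset), and repeat
#' until `n_days` of epochs are produced. The output is reproducible given
#' `seed` and is a fixpoint of [apply_scoring_rules()].
#'
#' @param params A [sim_params()].
#' @param n_days Days of recording (24 h each).
#' @param seed Optional integer seed.
#' @param epoch_s,zt_start_s,lights_on_h,lights_off_h As in [hypnogram()].
#' @param init_state First state (default `"W"`).
#' @return A [hypnogram()].
#' @export
simulate_hypnogram <- function(params = sim_params(), n_days = 1, seed = NULL,
                               epoch_s = 10, zt_start_s = 0,
                               lights_on_h = 0, lights_off_h = 12,
                               init_state = "W") {
  if (!is.null(seed)) set.seed(seed)
  n_target <- as.integer(round(n_days * 86400 / epoch_s))
  states <- character(0)
  lens <- integer(0)
  state <- init_state
  t_epoch <- 0L
  while (t_epoch < n_target) {
    zt_h <- ((zt_start_s + t_epoch * epoch_s) %% 86400) / 3600
    phase <- if (zt_h >= lights_on_h && zt_h < lights_off_h) "LIGHT" else "DARK"
    L <- draw_bout_length(params, state, phase)
    states <- c(states, state)
    lens <- c(lens, L)
    t_epoch <- t_epoch + L
    state <- next_state(params, state, phase)
  }
  labels <- inverse.rle(list(lengths = lens, values = states))[seq_len(n_target)]
  hypnogram(labels, epoch_s = epoch_s, zt_start_s = zt_start_s,
            lights_on_h = lights_on_h, lights_off_h = lights_off_h)
}

#' Analytic stationary state fractions of the generator
#'
#' For a fixed phase, the long-run fraction of epochs in each state is
#' `pi_i * E[L_i] / sum_j pi_j * E[L_j]`, where `pi` is the stationary
#' distribution of the embedded transition chain and `E[L]` the mean bout
#' length. Used as the renewal-theory oracle in tests.
#'
#' @param params A [sim_params()].
#' @param phase `"LIGHT"` or `"DARK"`.
#' @return Named numeric vector (`W`, `N`, `R`) summing to 1.
#' @export
stationary_state_fractions <- function(params, phase = "LIGHT") {
  st <- c("W", "N", "R")
  P <- matrix(0, 3, 3, dimnames = list(st, st))
  P["W", c("N", "R")] <- params$trans$W[c("N", "R")]
  P["N", c("W", "R")] <- params$trans$N[[phase]][c("W", "R")]
  P["R", c("W", "N")] <- params$trans$R[c("W", "N")]
  e <- eigen(t(P))
  i <- which.min(abs(e$values - 1))
  pi <- Re(e$vectors[, i]); pi <- pi / sum(pi)
  mL <- params$bout_mean[st, phase]
  w <- pi * mL
  stats::setNames(w / sum(w), st)
}

# unit-variance band-limited Gaussian noise, one epoch, frequency-domain
bandlimited_noise <- function(n, fs, lo, hi) {
  f <- (0:(n %/% 2)) * fs / n
  k <- which(f >= lo & f < hi)          # 1-based bin indices (bin 1 = DC)
  k <- k[k > 1L & k < n %/% 2 + 1L]     # skip DC and Nyquist
  if (length(k) == 0L) return(numeric(n))
  X <- complex(length.out = n)
  z <- complex(real = stats::rnorm(length(k)), imaginary = stats::rnorm(length(k)))
  X[k] <- z
  X[n - k + 2L] <- Conj(z)
  x <- Re(stats::fft(X, inverse = TRUE)) / n
  # Var(x) = 2 * m * E|z|^2 / (2 n^2)...: scale empir-free to unit variance
  x * n / sqrt(2 * 2 * length(k))
}

#' Simulate state-dependent EEG for a hypnogram
#'
#' Each epoch is an independent sum of unit-variance band-limited Gaussian
#' noise components weighted by the state's band amplitudes, so the expected
#' power in band b is proportional to `weight_b^2` and band-power ratios
#' have the analytic expectation `(w_num / w_den)^2`. Continuity across
#' epoch boundaries is not enforced (the analysis is strictly per-epoch).
#'
#' @param h A [hypnogram()].
#' @param params A [sim_params()].
#' @param seed Optional integer seed.
#' @param fs Sampling rate (samples/s).
#' @param epochs Optional integer vector (1-based) of epochs to synthesize;
#'   others are zero-filled. Default: all epochs.
#' @return Numeric vector of `n_epochs * epoch_s * fs` samples.
#' @export
simulate_eeg <- function(h, params = sim_params(), seed = NULL, fs = 500,
                         epochs = NULL) {
  if (!is.null(seed)) set.seed(seed)
  spe <- as.integer(round(h$epoch_s * fs))
  n_ep <- n_epochs(h)
  if (is.null(epochs)) epochs <- seq_len(n_ep)
  bands <- default_bands()
  w <- params$eeg$band_weights
  out <- numeric(n_ep * spe)
  for (e in epochs) {
    st <- h$states[e]
    x <- numeric(spe)
    for (b in seq_len(nrow(bands))) {
      wt <- w[st, bands$name[b]]
      if (wt > 0)
        x <- x + wt * bandlimited_noise(spe, fs, bands$lo_hz[b], bands$hi_hz[b])
    }
    out[((e - 1L) * spe + 1L):(e * spe)] <- params$eeg$amplitude * x
  }
  out
}

#' Simulate per-minute activity counts
#'
#' Poisson counts with a state-by-phase rate; the state of each minute is the
#' state of its first epoch.
#'
#' @param h A [hypnogram()].
#' @param params A [sim_params()].
#' @param seed Optional integer seed.
#' @return Data frame `minute`, `zt_s`, `state`, `counts`.
#' @export
simulate_activity <- function(h, params = sim_params(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ep_per_min <- as.integer(round(60 / h$epoch_s))
  n_min <- n_epochs(h) %/% ep_per_min
  first_ep <- (seq_len(n_min) - 1L) * ep_per_min + 1L
  st <- h$states[first_ep]
  ph <- epoch_phase(h)[first_ep]
  rate <- params$activity[cbind(st, ph)]
  data.frame(minute = seq_len(n_min) - 1L,
             zt_s = epoch_zt_s(h)[first_ep],
             state = st,
             counts = stats::rpois(n_min, rate))
}

#' Simulate per-minute subcutaneous body temperature
#'
#' Cosinor rhythm plus state offsets plus AR(1) noise:
#' `T = mesor + amplitude * cos(2*pi*(ZT - acrophase)/24) + offset[state] + e`,
#' `e_t = phi * e_{t-1} + N(0, sigma^2)`.
#'
#' @inheritParams simulate_activity
#' @return Data frame `minute`, `zt_s`, `state`, `tsc_c`.
#' @export
simulate_tsc <- function(h, params = sim_params(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- params$tsc
  ep_per_min <- as.integer(round(60 / h$epoch_s))
  n_min <- n_epochs(h) %/% ep_per_min
  first_ep <- (seq_len(n_min) - 1L) * ep_per_min + 1L
  st <- h$states[first_ep]
  zt_s <- epoch_zt_s(h)[first_ep]
  rhythm <- p$mesor_c +
    p$amplitude_c * cos(2 * pi * (zt_s / 3600 - p$acrophase_zt_h) / 24)
  e <- numeric(n_min)
  if (p$sigma_c > 0) {
    innov <- stats::rnorm(n_min, 0, p$sigma_c)
    e[1] <- innov[1]
    for (t in seq_len(n_min)[-1]) e[t] <- p$ar1_phi * e[t - 1] + innov[t]
  }
  data.frame(minute = seq_len(n_min) - 1L, zt_s = zt_s, state = st,
             tsc_c = rhythm + p$state_offset_c[st] + e)
}

#' Simulate a genotype-by-sex cohort
#'
#' Generates one animal at a time with a deterministic per-animal seed
#' derived from the master seed, storing the exact generator parameters
#' (ground truth) alongside every animal. The default design reproduces a
#' 2x2 genotype-by-sex study with group sizes 8 (KI F), 6 (WT F), 9 (KI M)
#' and 8 (WT M), 31 animals in all.
#'
#' @param design Data frame with columns `genotype` (`"WT"`/`"KI"`), `sex`
#'   (`"M"`/`"F"`) and `n` (animals per group).
#' @param n_days Recording days per animal.
#' @param seed Master integer seed.
#' @param base_params A [sim_params()] used for WT animals; KI animals get
#'   [mutant_params()] applied.
#' @param eeg If `TRUE`, also synthesize EEG (expensive; default `FALSE`).
#' @param activity,tsc If `TRUE`, simulate the respective traces.
#' @param fs EEG sampling rate when `eeg = TRUE`.
#' @return List of class `"sim_cohort"`; each element has `id`, `genotype`,
#'   `sex`, `seed`, `hypnogram`, optional `eeg`/`activity`/`tsc`, and
#'   `truth` (the `"sim_params"` used).
#' @export
simulate_cohort <- function(design = data.frame(
                              genotype = c("KI", "WT", "KI", "WT"),
                              sex = c("F", "F", "M", "M"),
                              n = c(8L, 6L, 9L, 8L)),
                            n_days = 1, seed = 1,
                            base_params = sim_params(),
                            eeg = FALSE, activity = FALSE, tsc = FALSE,
                            fs = 500) {
  stopifnot(all(c("genotype", "sex", "n") %in% names(design)))
  animals <- list()
  idx <- 0L
  for (g in seq_len(nrow(design))) {
    params <- if (design$genotype[g] == "KI")
      mutant_params(base_params, sex = design$sex[g]) else base_params
    for (i in seq_len(design$n[g])) {
      idx <- idx + 1L
      aseed <- (as.integer(seed) + 7919L * idx) %% .Machine$integer.max
      a <- list(id = sprintf("%s_%s_%02d", design$genotype[g], design$sex[g], i),
                genotype = design$genotype[g], sex = design$sex[g],
                seed = aseed,
                hypnogram = simulate_hypnogram(params, n_days, seed = aseed),
                truth = params)
      if (eeg) a$eeg <- simulate_eeg(a$hypnogram, params, seed = aseed + 1L, fs = fs)
      if (activity) a$activity <- simulate_activity(a$hypnogram, params, seed = aseed + 2L)
      if (tsc) a$tsc <- simulate_tsc(a$hypnogram, params, seed = aseed + 3L)
      animals[[idx]] <- a
    }
  }
  structure(animals, class = "sim_cohort")
}
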