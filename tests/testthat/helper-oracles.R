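# Independent oracles used across the suite. Each is a deliberately naive
# implementation kept separate from the package's code paths.

# random state-label sequence
random_labels <- function(n, p = c(W = 0.45, N = 0.4, R = 0.15)) {
  sample(names(p), n, replace = TRUE, prob = p)
}

# run-length-encoding bout oracle: maximal runs >= min_len, scanned by loop
oracle_bouts <- function(labels, min_len = 2L) {
  out <- list()
  i <- 1L
  n <- length(labels)
  while (i <= n) {
    j <- i
    while (j < n && labels[j + 1L] == labels[i]) j <- j + 1L
    if (j - i + 1L >= min_len)
      out[[length(out) + 1L]] <- data.frame(state = labels[i],
                                            onset_epoch = i - 1L,
                                            n_epochs = j - i + 1L)
    i <- j + 1L
  }
  if (length(out) == 0L)
    return(data.frame(state = character(0), onset_epoch = integer(0),
                      n_epochs = integer(0)))
  do.call(rbind, out)
}

# brute-force half-open binning oracle
oracle_histogram <- function(durations, edges) {
  lo <- c(0, edges); hi <- c(edges, Inf)
  vapply(seq_along(lo), function(i) sum(durations >= lo[i] & durations < hi[i]),
         integer(1))
}

# literal step-by-step Holm-Sidak decisions (no vectorized shortcuts)
oracle_holm_sidak_reject <- function(p, alpha = 0.05) {
  m <- length(p)
  ord <- order(p)
  reject <- logical(m)
  for (i in seq_len(m)) {
    thresh <- 1 - (1 - alpha)^(1 / (m - i + 1))
    if (p[ord[i]] <= thresh) reject[ord[i]] <- TRUE else break
  }
  reject
}

# closed-form balanced two-way ANOVA from cell means (equal n per cell)
oracle_balanced_anova <- function(y, A, B) {
  A <- factor(A); B <- factor(B)
  n <- table(A, B)[1, 1]
  a <- nlevels(A); b <- nlevels(B)
  gm <- mean(y)
  mA <- tapply(y, A, mean); mB <- tapply(y, B, mean)
  mAB <- tapply(y, list(A, B), mean)
  ss_a <- n * b * sum((mA - gm)^2)
  ss_b <- n * a * sum((mB - gm)^2)
  ss_ab <- n * sum((mAB - outer(mA - gm, mB - gm, "+") - gm)^2)
  ss_res <- sum((y - mAB[cbind(A, B)])^2)
  list(ss = c(A = ss_a, B = ss_b, AB = ss_ab, res = ss_res),
       df = c(A = a - 1, B = b - 1, AB = (a - 1) * (b - 1), res = a * b * (n - 1)))
}

# direct O(n^2) DFT for tiny spectral cross-checks
oracle_dft_power <- function(x, nfft) {
  xp <- c(x, rep(0, nfft - length(x)))
  k <- 0:(nfft %/% 2)
  power <- vapply(k, function(kk) {
    ph <- -2i * pi * kk * (seq_along(xp) - 1) / nfft
    Mod(sum(xp * exp(ph)))^2 / nfft
  }, numeric(1))
  half <- nfft %/% 2
  if (half >= 2L) power[2:half] <- 2 * power[2:half]
  power
}

# enumeration oracle for transition-epoch exclusion: walk the sequence and
# list 1-based epoch indices that are the (exclusion+1)-th or later epoch of
# a same-state run of the target state
oracle_included_epochs <- function(labels, state, exclusion = 2L) {
  idx <- integer(0)
  i <- 1L
  n <- length(labels)
  while (i <= n) {
    j <- i
    while (j < n && labels[j + 1L] == labels[i]) j <- j + 1L
    len <- j - i + 1L
    if (labels[i] == state && len >= 2L && len > exclusion)
      idx <- c(idx, (i + exclusion):j)
    i <- j + 1L
  }
  idx
}

# small EEG fixture: one sinusoid per epoch at a state-specific frequency
tone_eeg <- function(h, fs = 500, freq = c(W = 20, N = 2, R = 7)) {
  spe <- h$epoch_s * fs
  unlist(lapply(seq_len(n_epochs(h)), function(e) {
    f <- freq[[h$states[e]]]
    sin(2 * pi * f * (0:(spe - 1)) / fs)
  }))
}
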