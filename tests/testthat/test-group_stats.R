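test_that("two-way ANOVA df bookkeeping matches the 2x2 study design", {
  # genotype x sex with group sizes 8, 6, 9, 8 -> error df 27, interaction df 1
  set.seed(31)
  g <- rep(c("KI", "WT", "KI", "WT"), c(8, 6, 9, 8))
  s <- rep(c("F", "F", "M", "M"), c(8, 6, 9, 8))
  at <- twoway_anova(rnorm(31), g, s, names = c("genotype", "sex"))
  expect_equal(at$df[at$effect == "Residuals"], 27)
  expect_equal(at$df[at$effect == "genotype:sex"], 1)
  expect_equal(sum(at$df), 30)
})

test_that("balanced two-way ANOVA matches the closed-form cell-mean oracle", {
  set.seed(32)
  for (i in 1:10) {
    n <- sample(3:6, 1)
    A <- rep(rep(c("a1", "a2"), each = n), 2)
    B <- rep(c("b1", "b2"), each = 2 * n)
    y <- rnorm(4 * n) + ifelse(A == "a1", 0.8, 0) + ifelse(B == "b1", -0.5, 0)
    at <- twoway_anova(y, A, B)
    or <- oracle_balanced_anova(y, A, B)
    expect_equal(at$ss, unname(or$ss), tolerance = 1e-9)
    expect_equal(at$df, unname(or$df))
    Fw <- (or$ss / or$df)[1:3] / (or$ss["res"] / or$df["res"])
    expect_equal(at$F[1:3], unname(Fw), tolerance = 1e-9)
  }
})

test_that("degenerate (constant) responses are reported, not faked", {
  at <- twoway_anova(rep(5, 12), rep(c("a", "b"), 6), rep(c("x", "y"), each = 6))
  expect_true(attr(at, "degenerate"))
  expect_true(all(is.na(at$F[1:3])))
})

test_that("two-way ANOVA validates its design", {
  expect_error(twoway_anova(1:4, c("a", "a", "a", "a"), c("x", "y", "x", "y")),
               "at least 2 levels")
  expect_error(twoway_anova(1:6, c("a", "a", "a", "b", "b", "b"),
                            c("x", "x", "x", "x", "x", "y")),
               "empty design cell: a x y")
})

test_that("repeated-measures ANOVA has the split-plot df structure", {
  # 16 subjects, 2 genotypes, 24 time-of-day levels -> Time df 23
  set.seed(33)
  d <- expand.grid(S = 1:16, W = factor(1:24))
  d$B <- ifelse(d$S <= 8, "WT", "KI")
  d$y <- rnorm(nrow(d)) + as.numeric(d$W) / 10
  at <- repeated_anova(d$y, d$S, d$B, d$W)
  expect_equal(at$df[at$effect == "W"], 23)
  expect_equal(at$df[at$effect == "B:W"], 23)
  expect_equal(at$df[at$effect == "B"], 1)
  expect_equal(at$df[at$effect == "Residuals" & at$stratum == "S"], 14)
  expect_equal(at$df[at$effect == "Residuals" & at$stratum == "Within"],
               14 * 23)
  # constant within-subject responses -> Time F indistinguishable from 0
  d2 <- expand.grid(S = 1:6, W = factor(1:4))
  d2$B <- ifelse(d2$S <= 3, "g1", "g2")
  subj_mean <- stats::rnorm(6)
  d2$y <- subj_mean[d2$S]
  at2 <- suppressWarnings(repeated_anova(d2$y, d2$S, d2$B, d2$W))
  expect_equal(at2$ss[at2$effect == "W"], 0, tolerance = 1e-20)
})

test_that("repeated-measures ANOVA matches a projection-matrix oracle", {
  # small complete split-plot design, SS computed from explicit lm fits
  set.seed(34)
  d <- expand.grid(S = factor(1:8), W = factor(1:3))
  d$B <- factor(ifelse(as.integer(d$S) <= 4, "g1", "g2"))
  d$y <- rnorm(nrow(d)) + ifelse(d$B == "g1", 1, 0) + as.numeric(d$W) / 5
  at <- repeated_anova(d$y, d$S, d$B, d$W)
  ss <- function(fit) sum(stats::resid(fit)^2)
  # between stratum: subject means
  m <- aggregate(y ~ S + B, d, mean)
  ss_b <- 3 * (ss(stats::lm(y ~ 1, m)) - ss(stats::lm(y ~ B, m)))
  ss_s <- 3 * ss(stats::lm(y ~ B, m))
  # within stratum via sequential decomposition of the full model
  f0 <- stats::lm(y ~ S, d)
  f1 <- stats::lm(y ~ S + W, d)
  f2 <- stats::lm(y ~ S + W + B:W, d)
  expect_equal(at$ss[at$effect == "B"], ss_b, tolerance = 1e-9)
  expect_equal(at$ss[at$effect == "Residuals" & at$stratum == "S"], ss_s,
               tolerance = 1e-9)
  expect_equal(at$ss[at$effect == "W"], ss(f0) - ss(f1), tolerance = 1e-9)
  expect_equal(at$ss[at$effect == "B:W"], ss(f1) - ss(f2), tolerance = 1e-9)
  expect_equal(at$ss[at$effect == "Residuals" & at$stratum == "Within"],
               ss(f2), tolerance = 1e-9)
})

test_that("incomplete subjects are dropped with a warning", {
  d <- expand.grid(S = 1:4, W = factor(1:3))
  d$B <- ifelse(d$S <= 2, "g1", "g2")
  d$y <- rnorm(nrow(d))
  d <- d[-1, ]  # subject 1 misses one within level
  expect_warning(at <- repeated_anova(d$y, d$S, d$B, d$W),
                 "incomplete within-factor data: 1")
  expect_equal(at$df[at$effect == "Residuals" & at$stratum == "S"], 1)
})

test_that("Fisher's LSD uses the pooled error term", {
  means <- c(a = 1, b = 1, c = 3)
  ns <- c(a = 5, b = 5, c = 5)
  res <- fishers_lsd(means, ns, ms_error = 2, df_error = 12)
  # identical cell means -> t = 0, p = 1
  r_ab <- res[res$pair == "a vs b", ]
  expect_equal(r_ab$t, 0)
  expect_equal(r_ab$p, 1)
  # swapping the pair flips the sign, same p
  r1 <- fishers_lsd(means, ns, 2, 12, pairs = list(c("a", "c")))
  r2 <- fishers_lsd(means, ns, 2, 12, pairs = list(c("c", "a")))
  expect_equal(r1$t, -r2$t)
  expect_equal(r1$p, r2$p)
  expect_equal(r1$df, 12)
})

test_that("two-group LSD equals the pooled-variance t-test", {
  set.seed(35)
  x <- rnorm(8, 0); y <- rnorm(6, 1)
  g <- rep(c("x", "y"), c(8, 6))
  v <- c(x, y)
  fit <- stats::lm(v ~ g)
  ms_e <- sum(stats::resid(fit)^2) / fit$df.residual
  res <- fishers_lsd(c(x = mean(x), y = mean(y)), c(x = 8, y = 6),
                     ms_e, fit$df.residual)
  tt <- stats::t.test(x, y, var.equal = TRUE)
  expect_equal(res$t, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(res$p, tt$p.value, tolerance = 1e-12)
})

test_that("Holm-Sidak adjusted p-values and decisions are correct", {
  # m = 1: adjusted equals raw
  hs1 <- holm_sidak(0.03)
  expect_equal(hs1$p_adjusted, 0.03)
  expect_true(hs1$reject)
  # canonical example: only the small p rejected
  hs <- holm_sidak(c(0.001, 0.8, 0.9))
  expect_equal(hs$reject, c(TRUE, FALSE, FALSE))
  expect_equal(hs$p_adjusted[1], 1 - (1 - 0.001)^3)
  # adjusted >= raw, monotone in sorted order, permutation-invariant
  set.seed(36)
  for (i in 1:200) {
    p <- runif(sample(2:50, 1))
    hs <- holm_sidak(p)
    expect_true(all(hs$p_adjusted >= p - 1e-15))
    o <- order(p)
    expect_true(all(diff(hs$p_adjusted[o]) >= -1e-15))
    # decisions equal the literal step-down oracle
    expect_equal(hs$reject, oracle_holm_sidak_reject(p))
    # rejection <=> adjusted p <= alpha
    expect_equal(hs$reject, hs$p_adjusted <= 0.05)
    # permutation invariance
    perm <- sample(length(p))
    hs2 <- holm_sidak(p[perm])
    expect_equal(hs2$p_adjusted, hs$p_adjusted[perm])
  }
  expect_error(holm_sidak(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("per-bin comparison rejects nothing on identical spectra", {
  set.seed(37)
  base <- matrix(rexp(6 * 100), nrow = 6)
  res <- per_bin_compare(base, base + 0, freq = seq(0.5, 10, length.out = 100))
  expect_false(any(res$reject))
  expect_equal(nrow(res$ranges), 0)
})

test_that("per-bin comparison finds an injected band difference", {
  set.seed(38)
  freq <- seq(0.5, 15, by = 0.1)
  theta <- freq >= 6 & freq < 9
  mk <- function(n, drop) {
    t(replicate(n, {
      mu <- rep(10, length(freq))
      if (drop) mu[theta] <- mu[theta] * 0.4
      mu * (1 + rnorm(length(freq), 0, 0.05))
    }))
  }
  a <- mk(8, FALSE); b <- mk(8, TRUE)
  res <- per_bin_compare(a, b, freq)
  # the detected contiguous range overlaps the injected theta band
  expect_gt(nrow(res$ranges), 0)
  expect_true(any(res$ranges$lo_hz < 9 & res$ranges$hi_hz >= 6))
  # contiguous-range extraction equals a brute-force scan
  flag <- res$reject
  runs <- list()
  start <- NA
  for (i in seq_along(flag)) {
    if (flag[i] && is.na(start)) start <- i
    if (!flag[i] && !is.na(start)) { runs[[length(runs) + 1]] <- c(start, i - 1); start <- NA }
  }
  if (!is.na(start)) runs[[length(runs) + 1]] <- c(start, length(flag))
  expect_equal(nrow(res$ranges), length(runs))
  for (k in seq_along(runs)) {
    expect_equal(res$ranges$lo_hz[k], res$freq[runs[[k]][1]])
    expect_equal(res$ranges$hi_hz[k], res$freq[runs[[k]][2]])
  }
})

test_that("per-bin comparison supports Welch tests and family restriction", {
  set.seed(39)
  a <- matrix(rnorm(5 * 50, 10), nrow = 5)
  b <- matrix(rnorm(5 * 50, 10, 3), nrow = 5)
  freq <- seq(0.5, 5, length.out = 50)
  rw <- per_bin_compare(a, b, freq, welch = TRUE)
  expect_true(all(rw$df < 8 + 1e-9))  # Welch df below pooled df
  rr <- per_bin_compare(a, b, freq, family_range = c(1, 2))
  expect_true(all(rr$freq >= 1 & rr$freq < 2))
  expect_error(per_bin_compare(a[1, , drop = FALSE], b, freq), "at least 2")
})
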