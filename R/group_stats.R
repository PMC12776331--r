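#' Two-way factorial ANOVA (Type III sums of squares)
#'
#' Crossed two-factor ANOVA for possibly unbalanced designs (e.g. genotype x
#' sex with group sizes 8/6/9/8). Type III sums of squares are computed via
#' sum-to-zero contrasts and single-term deletion from the full model, the
#' convention of the commercial packages used for such designs; on balanced
#' data Type III coincides with sequential sums of squares.
#'
#' @param values Numeric response, one value per animal.
#' @param factorA,factorB Factors (or coercible), same length as `values`.
#' @param names Length-2 character vector naming the factors in the output.
#' @return Data frame of class `"anova_table"` with columns `effect`, `df`,
#'   `ss`, `ms`, `F`, `p`; rows A, B, A:B and Residuals. If the residual mean
#'   square is zero the F and p columns are `NA` and attribute `degenerate`
#'   is set.
#' @export
twoway_anova <- function(values, factorA, factorB,
                         names = c("A", "B")) {
  A <- factor(factorA); B <- factor(factorB)
  if (nlevels(A) < 2 || nlevels(B) < 2)
    stop("each factor needs at least 2 levels")
  if (length(values) != length(A) || length(values) != length(B))
    stop("values and factors must have equal length")
  cells <- table(A, B)
  if (any(cells == 0)) {
    bad <- which(cells == 0, arr.ind = TRUE)[1, ]
    stop("empty design cell: ", levels(A)[bad[1]], " x ", levels(B)[bad[2]])
  }
  dat <- data.frame(y = values, A = A, B = B)
  fit <- stats::lm(y ~ A * B, data = dat,
                   contrasts = list(A = "contr.sum", B = "contr.sum"))
  d1 <- withCallingHandlers(
    stats::drop1(fit, scope = . ~ ., test = "F"),
    warning = function(w) {
      # a perfect fit is reported via the `degenerate` attribute instead
      if (grepl("essentially perfect fit", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  rss <- sum(stats::resid(fit)^2)
  df_res <- fit$df.residual
  ms_res <- rss / df_res
  ss <- d1[c("A", "B", "A:B"), "Sum of Sq"]
  df <- d1[c("A", "B", "A:B"), "Df"]
  ms <- ss / df
  degenerate <- ms_res <= .Machine$double.eps * mean(abs(values))^2 || ms_res == 0
  if (degenerate) {
    Fv <- rep(NA_real_, 3); pv <- rep(NA_real_, 3)
  } else {
    Fv <- ms / ms_res
    pv <- stats::pf(Fv, df, df_res, lower.tail = FALSE)
  }
  out <- data.frame(
    effect = c(names[1], names[2], paste(names, collapse = ":"), "Residuals"),
    df = c(df, df_res),
    ss = c(ss, rss),
    ms = c(ms, ms_res),
    F = c(Fv, NA_real_),
    p = c(pv, NA_real_),
    stringsAsFactors = FALSE)
  attr(out, "degenerate") <- degenerate
  class(out) <- c("anova_table", "data.frame")
  out
}

#' Repeated-measures ANOVA with a within-subject factor
#'
#' Split-plot ANOVA for designs with one or two between-subject factors
#' (e.g. genotype, sex or age) and one within-subject factor (e.g. time of
#' day). This is the complete-case analogue of the REML mixed-effects ANOVA
#' used for such designs: subjects missing any within-factor level are
#' dropped with a warning, and on complete data the two analyses coincide.
#'
#' @param values Numeric responses (long format, one row per subject x
#'   within-level).
#' @param subject Subject identifier, same length as `values`.
#' @param between Factor or data frame of between-subject factors.
#' @param within Within-subject factor (e.g. ZT hour); levels must be shared
#'   across subjects.
#' @return Data frame of class `"anova_table"` with between-subject effects
#'   tested against the subject error stratum and within-subject effects
#'   against the subject-by-within residual stratum; columns `effect`,
#'   `stratum`, `df`, `ss`, `ms`, `F`, `p`.
#' @export
repeated_anova <- function(values, subject, between, within) {
  subject <- factor(subject)
  within <- factor(within)
  if (is.data.frame(between)) {
    bet <- lapply(between, factor)
  } else {
    bet <- list(B = factor(between))
  }
  if (is.null(names(bet)) || any(!nzchar(names(bet))))
    names(bet) <- paste0("B", seq_along(bet))
  dat <- data.frame(y = values, S = subject, W = within, bet,
                    stringsAsFactors = TRUE)
  names(dat)[4:(3 + length(bet))] <- names(bet)
  # complete cases: a subject must carry every within level exactly once
  w_levels <- levels(within)
  tab <- table(dat$S, dat$W)
  ok <- rownames(tab)[apply(tab, 1, function(r) all(r == 1L))]
  if (length(ok) < nlevels(subject)) {
    dropped <- setdiff(levels(subject), ok)
    warning("dropping ", length(dropped),
            " subject(s) with incomplete within-factor data: ",
            paste(dropped, collapse = ", "))
    dat <- dat[dat$S %in% ok, , drop = FALSE]
    dat$S <- droplevels(dat$S)
    for (nm in names(bet)) dat[[nm]] <- droplevels(dat[[nm]])
  }
  if (nlevels(dat$S) < 2L) stop("fewer than 2 complete subjects")
  bterm <- paste(names(bet), collapse = " * ")
  f <- stats::as.formula(paste0("y ~ (", bterm, ") * W + Error(S)"))
  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old))
  fit <- stats::aov(f, data = dat)
  sm <- summary(fit)
  rows <- list()
  for (stratum in names(sm)) {
    t <- sm[[stratum]][[1]]
    eff <- trimws(rownames(t))
    for (i in seq_len(nrow(t))) {
      rows[[length(rows) + 1L]] <- data.frame(
        effect = eff[i], stratum = sub("^Error: ", "", stratum),
        df = t[i, "Df"], ss = t[i, "Sum Sq"], ms = t[i, "Mean Sq"],
        F = if ("F value" %in% colnames(t)) t[i, "F value"] else NA_real_,
        p = if ("Pr(>F)" %in% colnames(t)) t[i, "Pr(>F)"] else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("anova_table", "data.frame")
  out
}

#' Fisher's least significant difference post-hoc tests
#'
#' Pairwise comparisons of cell means using the parent ANOVA's pooled error
#' mean square and error degrees of freedom; p-values are two-sided and
#' unadjusted, as is conventional for LSD.
#'
#' @param means Named numeric vector of cell means.
#' @param ns Named integer vector of cell sizes (same names as `means`).
#' @param ms_error,df_error Residual mean square and df from the parent ANOVA.
#' @param pairs Optional list of length-2 character vectors naming the cells
#'   to compare; default all pairs.
#' @return Data frame: `pair`, `diff`, `se`, `t`, `df`, `p`.
#' @export
fishers_lsd <- function(means, ns, ms_error, df_error, pairs = NULL) {
  if (is.null(names(means)) || is.null(names(ns)))
    stop("means and ns must be named")
  if (!all(names(means) %in% names(ns)))
    stop("means and ns must share names")
  if (is.null(pairs)) {
    cmb <- utils::combn(names(means), 2, simplify = FALSE)
  } else {
    cmb <- pairs
  }
  rows <- lapply(cmb, function(pr) {
    d <- means[[pr[1]]] - means[[pr[2]]]
    se <- sqrt(ms_error * (1 / ns[[pr[1]]] + 1 / ns[[pr[2]]]))
    t <- d / se
    data.frame(pair = paste(pr, collapse = " vs "), diff = d, se = se,
               t = t, df = df_error,
               p = 2 * stats::pt(abs(t), df_error, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Holm-Sidak step-down multiple-comparison procedure
#'
#' Sorts the m p-values ascending and, at step i, compares against the Sidak
#' threshold `1 - (1 - alpha)^(1/(m - i + 1))`, stopping at the first
#' failure. Adjusted p-values are the running maximum of
#' `1 - (1 - p_(i))^(m - i + 1)`, clipped to 1; rejection is equivalent to
#' `adjusted p <= alpha`.
#'
#' @param pvals Numeric p-values in `[0, 1]`.
#' @param alpha Family-wise error rate (default 0.05).
#' @return List with `p_adjusted` and logical `reject`, both in input order,
#'   plus `alpha`.
#' @export
holm_sidak <- function(pvals, alpha = 0.05) {
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1))
    stop("pvals must lie in [0, 1] with no NA")
  m <- length(pvals)
  o <- order(pvals)
  ps <- pvals[o]
  k <- m - seq_len(m) + 1L          # comparisons remaining at each step
  adj_sorted <- cummax(pmin(1, 1 - (1 - ps)^k))
  thresh <- 1 - (1 - alpha)^(1 / k)
  pass <- ps <= thresh
  # step-down: stop at the first failure
  first_fail <- which(!pass)[1]
  reject_sorted <- if (is.na(first_fail)) rep(TRUE, m) else
    seq_len(m) < first_fail
  p_adjusted <- numeric(m); p_adjusted[o] <- adj_sorted
  reject <- logical(m); reject[o] <- reject_sorted
  list(p_adjusted = p_adjusted, reject = reject, alpha = alpha)
}

#' Per-frequency-bin group comparison with Holm-Sidak correction
#'
#' Unpaired t-tests (pooled variance by default, Welch optional) between two
#' groups of per-animal spectra at every frequency bin, corrected across the
#' family of bins by the Holm-Sidak step-down procedure, with contiguous
#' significant frequency ranges extracted.
#'
#' @param spectra_a,spectra_b Numeric matrices, one row per animal and one
#'   column per frequency bin, on the same bin grid.
#' @param freq Numeric vector of bin frequencies (Hz), one per column.
#' @param alpha Family-wise error rate.
#' @param welch If `TRUE`, Welch's t-test instead of pooled variance.
#' @param family_range Optional `c(lo_hz, hi_hz)` restricting the bins tested
#'   (and the correction family); default: all supplied bins.
#' @return List of class `"bin_comparison"`: `freq`, `mean_a`, `mean_b`, `t`,
#'   `p`, `p_adjusted`, `reject`, and `ranges` (data frame `lo_hz`, `hi_hz`
#'   of contiguous rejected runs).
#' @export
per_bin_compare <- function(spectra_a, spectra_b, freq, alpha = 0.05,
                            welch = FALSE, family_range = NULL) {
  if (ncol(spectra_a) != ncol(spectra_b) || ncol(spectra_a) != length(freq))
    stop("both groups and freq must share the same bin grid")
  if (nrow(spectra_a) < 2L || nrow(spectra_b) < 2L)
    stop("need at least 2 animals per group")
  keep <- if (is.null(family_range)) rep(TRUE, length(freq)) else
    freq >= family_range[1] & freq < family_range[2]
  fa <- spectra_a[, keep, drop = FALSE]
  fb <- spectra_b[, keep, drop = FALSE]
  n1 <- nrow(fa); n2 <- nrow(fb)
  m1 <- colMeans(fa); m2 <- colMeans(fb)
  v1 <- apply(fa, 2, stats::var); v2 <- apply(fb, 2, stats::var)
  if (welch) {
    se2 <- v1 / n1 + v2 / n2
    tval <- (m1 - m2) / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    tval <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, length(tval))
  }
  p <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  hs <- holm_sidak(p, alpha)
  ranges <- contiguous_ranges(freq[keep], hs$reject)
  structure(list(freq = freq[keep], mean_a = m1, mean_b = m2,
                 t = tval, df = df, p = p,
                 p_adjusted = hs$p_adjusted, reject = hs$reject,
                 alpha = alpha, welch = welch, ranges = ranges),
            class = "bin_comparison")
}

# contiguous TRUE runs of `flag` -> frequency intervals [lo, hi] (bin centers)
contiguous_ranges <- function(freq, flag) {
  if (!any(flag)) {
    return(data.frame(lo_hz = numeric(0), hi_hz = numeric(0)))
  }
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(lo_hz = freq[starts[keep]], hi_hz = freq[ends[keep]])
}
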