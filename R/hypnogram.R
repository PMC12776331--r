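#' Construct a hypnogram
#'
#' A hypnogram is the central object of the package: an ordered sequence of
#' arousal-state labels, one per fixed-length scoring epoch, aligned to
#' zeitgeber time (ZT; hours since lights-on). States are coded `"W"` (Wake),
#' `"N"` (NREM sleep) and `"R"` (REM sleep).
#'
#' @param states Character vector of state labels. Accepted tokens are
#'   `"W"`/`"N"`/`"R"` or the long forms `"Wake"`/`"NREM"`/`"REM"`
#'   (case-insensitive). Any other token is an error.
#' @param epoch_s Seconds per scoring epoch (default 10).
#' @param zt_start_s Zeitgeber time of the first epoch, in seconds
#'   (0 = lights-on). Must lie in `[0, 86400)`.
#' @param lights_on_h,lights_off_h Light-phase boundaries in ZT hours;
#'   defaults 0 and 12 give the standard LD12:12 cycle. Epochs whose ZT hour
#'   falls in `[lights_on_h, lights_off_h)` are LIGHT, the rest DARK.
#'
#' @return An object of class `"hypnogram"`.
#' @export
hypnogram <- function(states, epoch_s = 10, zt_start_s = 0,
                      lights_on_h = 0, lights_off_h = 12) {
  states <- normalize_states(states)
  if (length(states) < 1L) stop("hypnogram must contain at least one epoch")
  if (!is.numeric(epoch_s) || length(epoch_s) != 1L || epoch_s <= 0)
    stop("epoch_s must be a single positive number")
  if (zt_start_s < 0 || zt_start_s >= 86400)
    stop("zt_start_s must lie in [0, 86400)")
  if (lights_on_h < 0 || lights_off_h <= lights_on_h || lights_off_h > 24)
    stop("phase boundaries must satisfy 0 <= lights_on_h < lights_off_h <= 24")
  structure(
    list(states = states, epoch_s = epoch_s, zt_start_s = zt_start_s,
         lights_on_h = lights_on_h, lights_off_h = lights_off_h),
    class = "hypnogram")
}

# strict label validation; unknown tokens rejected at parse time
normalize_states <- function(states) {
  states <- as.character(states)
  map <- c(W = "W", WAKE = "W", N = "N", NREM = "N", R = "R", REM = "R")
  key <- toupper(states)
  out <- unname(map[key])
  if (anyNA(out)) {
    bad <- unique(states[is.na(out)])
    stop("unknown state label(s): ", paste(bad, collapse = ", "),
         " (expected W/N/R or Wake/NREM/REM)")
  }
  out
}

#' @export
print.hypnogram <- function(x, ...) {
  cat(sprintf("<hypnogram> %d epochs x %gs (%.2f h), ZT start %.2f h, light %g-%g\n",
              n_epochs(x), x$epoch_s, n_epochs(x) * x$epoch_s / 3600,
              x$zt_start_s / 3600, x$lights_on_h, x$lights_off_h))
  tab <- table(factor(x$states, levels = c("W", "N", "R")))
  cat(sprintf("  W %d | N %d | R %d epochs\n", tab[["W"]], tab[["N"]], tab[["R"]]))
  invisible(x)
}

#' Number of epochs in a hypnogram
#' @param h A [hypnogram()].
#' @return Integer epoch count.
#' @export
n_epochs <- function(h) length(h$states)

#' Zeitgeber time of each epoch onset, in seconds (wrapped to one day)
#' @param h A [hypnogram()].
#' @return Numeric vector, one value per epoch, in `[0, 86400)`.
#' @export
epoch_zt_s <- function(h) {
  (h$zt_start_s + (seq_len(n_epochs(h)) - 1) * h$epoch_s) %% 86400
}

#' Light/dark phase of each epoch
#' @param h A [hypnogram()].
#' @return Character vector `"LIGHT"`/`"DARK"` per epoch, assigned from each
#'   epoch's onset ZT.
#' @export
epoch_phase <- function(h) {
  zt_h <- epoch_zt_s(h) / 3600
  ifelse(zt_h >= h$lights_on_h & zt_h < h$lights_off_h, "LIGHT", "DARK")
}

# Resolve a window spec into a logical epoch mask.
# window: "H24", "LIGHT", "DARK", or numeric c(lo_h, hi_h) ZT interval,
# half-open [lo, hi); lo > hi wraps across midnight. Applied across all days.
window_mask <- function(h, window) {
  if (is.character(window) && length(window) == 1L) {
    w <- toupper(window)
    if (w == "H24") return(rep(TRUE, n_epochs(h)))
    if (w %in% c("LIGHT", "DARK")) return(epoch_phase(h) == w)
    stop("unknown window: ", window)
  }
  if (is.numeric(window) && length(window) == 2L) {
    zt_h <- epoch_zt_s(h) / 3600
    lo <- window[1]; hi <- window[2]
    if (lo == hi) stop("empty window [", lo, ", ", hi, ")")
    if (lo < hi) return(zt_h >= lo & zt_h < hi)
    return(zt_h >= lo | zt_h < hi)  # wraps midnight
  }
  stop("window must be \"H24\", \"LIGHT\", \"DARK\" or a numeric ZT interval c(lo, hi)")
}

#' Apply REM-sleep rescoring rules to a scored hypnogram
#'
#' Two rules correct the common failure modes of automated REM scoring:
#' (1) a single isolated REM epoch is rescored as the preceding state
#' (a valid REM bout needs at least two consecutive epochs); (2) REM directly
#' following Wake is rescored as Wake (sleep-onset REM periods are excluded).
#' Rule 2 is applied to the entire contiguous REM run whose first epoch
#' follows Wake, then rule 1; the pair is iterated to a fixpoint. The result
#' is idempotent and conserves the epoch count.
#'
#' If the recording begins with REM there is no previous state to consult;
#' the leading REM run is conservatively rescored as Wake with a warning.
#'
#' @param h A [hypnogram()].
#' @return A rescored [hypnogram()] with identical epoch grid.
#' @export
apply_scoring_rules <- function(h) {
  s <- h$states
  warned_leading <- FALSE
  repeat {
    changed <- FALSE
    r <- rle(s)
    if (r$values[1] == "R") {
      r$values[1] <- "W"
      if (!warned_leading) {
        warning("recording begins with REM; leading REM run rescored as Wake")
        warned_leading <- TRUE
      }
      changed <- TRUE
    }
    # rule 2: whole REM run directly after Wake -> Wake
    after_wake <- which(r$values == "R" &
                          c("", r$values[-length(r$values)]) == "W")
    if (length(after_wake)) {
      r$values[after_wake] <- "W"
      changed <- TRUE
    }
    s <- inverse.rle(r)
    # rule 1: singleton REM -> previous state
    r <- rle(s)
    single <- which(r$values == "R" & r$lengths == 1L)
    single <- single[single > 1L]
    if (length(single)) {
      r$values[single] <- r$values[single - 1L]
      changed <- TRUE
    }
    s <- inverse.rle(r)
    if (!changed) break
  }
  h$states <- s
  h
}

#' Detect bouts in a hypnogram
#'
#' A bout is a maximal run of two or more consecutive epochs of the same
#' state; it ends with a single epoch of any other state. Length-1 runs are
#' not bouts (they still count toward time-in-state).
#'
#' @param h A [hypnogram()], normally already passed through
#'   [apply_scoring_rules()].
#' @return A data frame of class `"bouts"` with columns `state`,
#'   `onset_epoch` (0-based), `n_epochs`, `duration_s`, `onset_zt_s` and
#'   `phase` (light/dark of the onset epoch), ordered by onset.
#' @export
detect_bouts <- function(h) {
  r <- rle(h$states)
  onset0 <- cumsum(c(0L, r$lengths[-length(r$lengths)]))
  keep <- r$lengths >= 2L
  zt <- epoch_zt_s(h)
  phase <- epoch_phase(h)
  out <- data.frame(
    state = r$values[keep],
    onset_epoch = onset0[keep],
    n_epochs = r$lengths[keep],
    duration_s = r$lengths[keep] * h$epoch_s,
    onset_zt_s = zt[onset0[keep] + 1L],
    phase = phase[onset0[keep] + 1L],
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("bouts", "data.frame")
  out
}

#' Time spent in each state within a window
#'
#' Counts every epoch exactly once (singleton runs included; time-in-state is
#' independent of the bout definition). Percentages are over the window's
#' epoch count and sum to 100.
#'
#' @param h A [hypnogram()].
#' @param window `"H24"`, `"LIGHT"`, `"DARK"`, or a numeric ZT-hour interval
#'   `c(lo, hi)` (half-open, applied across all recorded days).
#' @return Data frame with one row per state (`W`, `N`, `R`): `n_epochs`,
#'   `time_min`, `time_pct`.
#' @export
time_in_state <- function(h, window = "H24") {
  mask <- window_mask(h, window)
  total <- sum(mask)
  if (total == 0L) stop("window contains no epochs")
  counts <- vapply(c("W", "N", "R"),
                   function(s) sum(h$states[mask] == s), integer(1))
  data.frame(
    state = c("W", "N", "R"),
    n_epochs = unname(counts),
    time_min = unname(counts) * h$epoch_s / 60,
    time_pct = 100 * unname(counts) / total,
    stringsAsFactors = FALSE)
}

#' Hourly state profile across ZT hours
#'
#' Bins epochs into the 24 ZT hours; multi-day recordings pool epochs per ZT
#' hour, which for complete days equals the mean of the single-day values.
#' Hours only partially covered (epoch count below a full hour per recorded
#' day) are flagged `complete = FALSE`.
#'
#' @param h A [hypnogram()] covering at least one hour.
#' @return Data frame with 24 rows: `zt_hour`, `n_epochs`, `pct_W`, `pct_N`,
#'   `pct_R`, `complete`.
#' @export
hourly_profile <- function(h) {
  if (n_epochs(h) * h$epoch_s < 3600) stop("recording must cover at least 1 h")
  hr <- floor(epoch_zt_s(h) / 3600)
  out <- data.frame(zt_hour = 0:23)
  per_hour_full <- 3600 / h$epoch_s
  counts <- t(vapply(0:23, function(k) {
    sel <- h$states[hr == k]
    c(n = length(sel),
      W = sum(sel == "W"), N = sum(sel == "N"), R = sum(sel == "R"))
  }, numeric(4)))
  out$n_epochs <- counts[, "n"]
  out$pct_W <- ifelse(counts[, "n"] > 0, 100 * counts[, "W"] / counts[, "n"], NA_real_)
  out$pct_N <- ifelse(counts[, "n"] > 0, 100 * counts[, "N"] / counts[, "n"], NA_real_)
  out$pct_R <- ifelse(counts[, "n"] > 0, 100 * counts[, "R"] / counts[, "n"], NA_real_)
  # an hour is "complete" when it holds only whole recorded hours
  out$complete <- counts[, "n"] > 0 & counts[, "n"] %% per_hour_full == 0
  out
}

#' Bout counts and mean bout durations per state within a window
#'
#' A bout belongs to the window of its onset epoch; bouts spanning the
#' light/dark boundary are not split, which makes light + dark counts sum
#' exactly to the 24-h counts. The mean duration is reported as `NA` (never
#' 0) when a state has no bouts in the window.
#'
#' @param bouts A `"bouts"` data frame from [detect_bouts()].
#' @param window As in [time_in_state()]. Numeric windows select by the
#'   bout's onset ZT.
#' @return Data frame with one row per state: `bout_count`,
#'   `mean_bout_duration_s`.
#' @export
bout_stats <- function(bouts, window = "H24") {
  sel <- select_bouts(bouts, window)
  stats <- lapply(c("W", "N", "R"), function(s) {
    d <- sel$duration_s[sel$state == s]
    data.frame(state = s, bout_count = length(d),
               mean_bout_duration_s = if (length(d)) mean(d) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, stats)
}

select_bouts <- function(bouts, window) {
  if (is.character(window) && length(window) == 1L) {
    w <- toupper(window)
    if (w == "H24") return(bouts)
    if (w %in% c("LIGHT", "DARK")) return(bouts[bouts$phase == w, , drop = FALSE])
    stop("unknown window: ", window)
  }
  if (is.numeric(window) && length(window) == 2L) {
    zt_h <- bouts$onset_zt_s / 3600
    lo <- window[1]; hi <- window[2]
    keep <- if (lo < hi) zt_h >= lo & zt_h < hi else zt_h >= lo | zt_h < hi
    return(bouts[keep, , drop = FALSE])
  }
  stop("window must be \"H24\", \"LIGHT\", \"DARK\" or a numeric ZT interval")
}

#' Histogram of bout durations
#'
#' Default edges follow the conventional wake-bout binning: `<60`, `60-100`,
#' `100-140`, `140-180`, `180-220`, `220-260` and `>260` seconds. Bins are
#' half-open on the left edge value: `[0,60), [60,100), ..., [260, Inf)`, so
#' a 60-s bout falls in the second bin.
#'
#' @param bouts A `"bouts"` data frame.
#' @param edges_s Strictly increasing interior bin boundaries in seconds.
#' @param state State whose bouts are binned (default `"W"`).
#' @param window As in [bout_stats()].
#' @return Data frame with columns `bin` (label), `lo_s`, `hi_s`, `count`;
#'   counts sum to the number of selected bouts.
#' @export
bout_histogram <- function(bouts, edges_s = c(60, 100, 140, 180, 220, 260),
                           state = "W", window = "H24") {
  if (length(edges_s) < 1L || any(diff(edges_s) <= 0) || any(edges_s <= 0))
    stop("edges_s must be positive and strictly increasing")
  sel <- select_bouts(bouts, window)
  d <- sel$duration_s[sel$state == state]
  lo <- c(0, edges_s)
  hi <- c(edges_s, Inf)
  count <- vapply(seq_along(lo),
                  function(i) sum(d >= lo[i] & d < hi[i]), integer(1))
  lab <- c(paste0("<", edges_s[1]),
           if (length(edges_s) > 1)
             paste0(edges_s[-length(edges_s)], "-", edges_s[-1]),
           paste0(">", edges_s[length(edges_s)]))
  data.frame(bin = lab, lo_s = lo, hi_s = hi, count = count,
             stringsAsFactors = FALSE)
}

#' Full sleep-architecture summary
#'
#' Composes [time_in_state()] and [bout_stats()] over the three standard
#' windows: the full recording (`H24`), the light phase and the dark phase.
#'
#' @param h A [hypnogram()] (rescore first with [apply_scoring_rules()]).
#' @return Data frame with columns `window`, `state`, `n_epochs`, `time_min`,
#'   `time_pct`, `bout_count`, `mean_bout_duration_s`.
#' @export
summarize_architecture <- function(h) {
  bouts <- detect_bouts(h)
  rows <- lapply(c("H24", "LIGHT", "DARK"), function(w) {
    if (!any(window_mask(h, w))) return(NULL)  # e.g. no dark phase recorded
    tis <- time_in_state(h, w)
    bs <- bout_stats(bouts, w)
    cbind(window = w, merge(tis, bs, by = "state", sort = FALSE))
  })
  out <- do.call(rbind, rows)
  out$state <- factor(out$state, levels = c("W", "N", "R"))
  out <- out[order(match(out$window, c("H24", "LIGHT", "DARK")), out$state), ]
  out$state <- as.character(out$state)
  rownames(out) <- NULL
  out
}
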