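#' Sleep-deprivation protocol definition
#'
#' Defaults encode the standard design: 6 h of total sleep deprivation
#' beginning at light onset (ZT0-6), a 5-h recovery-sleep opportunity over
#' ZT6-11, and the subsequent dark phase (ZT12-24) for delayed REM rebound.
#'
#' @param sd_start_zt_h,sd_duration_h Deprivation start (ZT hours) and length.
#' @param rs_window_h Recovery-sleep ZT interval, half-open.
#' @param dark_window_h Follow-up dark-phase ZT interval, half-open.
#' @return Object of class `"sd_protocol"`.
#' @export
sd_protocol <- function(sd_start_zt_h = 0, sd_duration_h = 6,
                        rs_window_h = c(6, 11), dark_window_h = c(12, 24)) {
  sd_end <- sd_start_zt_h + sd_duration_h
  if (sd_start_zt_h < 0 || sd_end > 24) stop("SD window must lie within one day")
  if (rs_window_h[1] < sd_end && rs_window_h[2] > sd_start_zt_h)
    stop("RS window overlaps the SD window")
  structure(list(sd_window_h = c(sd_start_zt_h, sd_end),
                 rs_window_h = rs_window_h, dark_window_h = dark_window_h),
            class = "sd_protocol")
}

check_full_day <- function(h, what) {
  if (n_epochs(h) * h$epoch_s < 86400)
    stop(what, " hypnogram must cover a full 24-h day (ZT0-24)")
  if (h$zt_start_s != 0)
    stop(what, " hypnogram must start at ZT0")
}

state_minutes_by_hour <- function(h) {
  out <- data.frame(zt_hour = 0:23, W = NA_real_, N = NA_real_, R = NA_real_)
  for (k in 0:23) {
    tis <- time_in_state(h, c(k, k + 1))
    out[k + 1, c("W", "N", "R")] <- tis$time_min
  }
  out
}

#' Sleep-deprivation rebound analysis
#'
#' Compares a baseline day against a sleep-deprivation day: hourly state
#' minutes for both days, cumulative NREM minutes over the recovery-sleep
#' window, dark-phase REM minutes (delayed REM rebound), and - when EEG is
#' supplied for both days - the hourly NREM delta-power (SWA) time course of
#' the recovery window expressed as percent of the baseline day's light-phase
#' NREM delta power.
#'
#' @param baseline_h,sd_h Full-day [hypnogram()]s (ZT0-24) for the baseline
#'   and deprivation days.
#' @param proto An [sd_protocol()].
#' @param baseline_eeg,sd_eeg Optional EEG sample vectors aligned to the two
#'   hypnograms; both must be given for the SWA time course.
#' @param params A [spectral_params()] (used only with EEG).
#' @return Object of class `"rebound_result"`: `hourly` (day, zt_hour, W/N/R
#'   minutes), `rs_cum_nrem_min` and `dark_rem_min` per day with differences,
#'   and `swa_pct` (or `NULL`).
#' @export
rebound_analysis <- function(baseline_h, sd_h, proto = sd_protocol(),
                             baseline_eeg = NULL, sd_eeg = NULL,
                             params = spectral_params()) {
  check_full_day(baseline_h, "baseline")
  check_full_day(sd_h, "SD-day")
  sd_tis <- time_in_state(sd_h, proto$sd_window_h)
  sleep_pct <- sum(sd_tis$time_pct[sd_tis$state %in% c("N", "R")])
  if (sleep_pct > 5)
    warning(sprintf("%.1f%% sleep during the SD window; deprivation may be incomplete",
                    sleep_pct))
  hb <- state_minutes_by_hour(baseline_h)
  hs <- state_minutes_by_hour(sd_h)
  hourly <- rbind(cbind(day = "baseline", hb), cbind(day = "sd", hs))
  rs_hours <- proto$rs_window_h[1]:(proto$rs_window_h[2] - 1)
  rs_cum <- c(baseline = sum(hb$N[hb$zt_hour %in% rs_hours]),
              sd = sum(hs$N[hs$zt_hour %in% rs_hours]))
  dark_hours <- proto$dark_window_h[1]:(proto$dark_window_h[2] - 1)
  dark_rem <- c(baseline = sum(hb$R[hb$zt_hour %in% dark_hours]),
                sd = sum(hs$R[hs$zt_hour %in% dark_hours]))
  swa <- NULL
  if (!is.null(baseline_eeg) && !is.null(sd_eeg)) {
    base <- swa_baseline(baseline_eeg, baseline_h, params)
    tc <- nrem_delta_timecourse(sd_eeg, sd_h, params, hours = rs_hours)
    swa <- data.frame(zt_hour = tc$zt_hour, n_epochs = tc$n_epochs,
                      swa_pct = normalize_to_baseline(tc$power, base))
  }
  structure(list(
    hourly = hourly,
    rs_cum_nrem_min = c(rs_cum, diff = unname(rs_cum["sd"] - rs_cum["baseline"])),
    dark_rem_min = c(dark_rem, diff = unname(dark_rem["sd"] - dark_rem["baseline"])),
    sd_sleep_pct = sleep_pct,
    swa_pct = swa,
    proto = proto), class = "rebound_result")
}

#' Multiple Sleep Latency Test protocol
#'
#' Five 20-min nap opportunities by default. The inter-nap spacing of the
#' murine MSLT is configurable; the default places nap onsets one hour apart
#' starting at ZT2 (20-min nap followed by 40 min of enforced wakefulness).
#'
#' @param nap_starts_zt_s Nap onset times in ZT seconds.
#' @param nap_duration_s Nap-opportunity length in seconds (default 1200).
#' @return Object of class `"mslt_protocol"`.
#' @export
mslt_protocol <- function(nap_starts_zt_s = 7200 + 3600 * (0:4),
                          nap_duration_s = 1200) {
  if (is.unsorted(nap_starts_zt_s, strictly = TRUE))
    stop("nap starts must be strictly increasing")
  if (any(diff(nap_starts_zt_s) < nap_duration_s))
    stop("nap opportunities overlap")
  structure(list(nap_starts_zt_s = nap_starts_zt_s,
                 nap_duration_s = nap_duration_s), class = "mslt_protocol")
}

#' Score a Multiple Sleep Latency Test recording
#'
#' For every nap opportunity: the latency from nap onset to the first epoch
#' of the first valid bout (>= 2 consecutive epochs, counted within the nap)
#' of NREM and of REM sleep, and the accumulated minutes of each state within
#' the nap. When no valid bout occurs, the latency equals the nap duration
#' and is flagged censored. Latency is onset-anchored: measured to the first
#' epoch of the qualifying bout, not the epoch that validates it.
#'
#' Raw (un-rescored) labels containing a singleton REM epoch or a Wake-to-REM
#' transition inside a nap trigger a warning, since such patterns violate the
#' REM scoring rules of [apply_scoring_rules()].
#'
#' @param h A [hypnogram()] covering all naps.
#' @param proto An [mslt_protocol()].
#' @return Data frame of class `"mslt_result"`, one row per nap: `nap`,
#'   `start_zt_s`, `latency_nrem_s`, `censored_nrem`, `latency_rem_s`,
#'   `censored_rem`, `nrem_min`, `rem_min`.
#' @export
mslt_score <- function(h, proto = mslt_protocol()) {
  zt <- epoch_zt_s(h)
  dur <- proto$nap_duration_s
  n_ep_nap <- floor(dur / h$epoch_s)
  rows <- lapply(seq_along(proto$nap_starts_zt_s), function(i) {
    t0 <- proto$nap_starts_zt_s[i]
    first <- which(zt >= t0)[1]
    if (is.na(first) || first + n_ep_nap - 1L > n_epochs(h))
      stop("nap ", i, " is not fully covered by the recording")
    lab <- h$states[first:(first + n_ep_nap - 1L)]
    r <- rle(lab)
    if (any(r$values == "R" & r$lengths == 1L) ||
        any(r$values == "R" & c("", r$values[-length(r$values)]) == "W"))
      warning("nap ", i, " contains REM patterns that violate the scoring rules",
              " (singleton REM or Wake->REM); rescore the hypnogram first")
    lat <- function(state) {
      onset0 <- cumsum(c(0L, r$lengths[-length(r$lengths)]))
      j <- which(r$values == state & r$lengths >= 2L)
      if (length(j) == 0L) return(c(dur, TRUE))
      c(onset0[j[1]] * h$epoch_s, FALSE)
    }
    ln <- lat("N"); lr <- lat("R")
    data.frame(nap = i, start_zt_s = t0,
               latency_nrem_s = ln[1], censored_nrem = as.logical(ln[2]),
               latency_rem_s = lr[1], censored_rem = as.logical(lr[2]),
               nrem_min = sum(lab == "N") * h$epoch_s / 60,
               rem_min = sum(lab == "R") * h$epoch_s / 60)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("mslt_result", "data.frame")
  out
}
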