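#' Read a hypnogram CSV
#'
#' Dialect: comma-separated, UTF-8, mandatory header with columns
#' `epoch_index`, `zt_seconds`, `state`; state tokens `W`/`N`/`R`. The ZT of
#' the first row anchors the recording; rows must be contiguous epochs.
#'
#' @param path File path.
#' @param epoch_s Seconds per epoch; default inferred from the first two rows
#'   (or 10 for single-row files).
#' @param lights_on_h,lights_off_h Phase boundaries (see [hypnogram()]).
#' @return A [hypnogram()].
#' @export
read_hypnogram_csv <- function(path, epoch_s = NULL,
                               lights_on_h = 0, lights_off_h = 12) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("epoch_index", "zt_seconds", "state")
  if (!all(need %in% names(df)))
    stop("hypnogram CSV must have header columns: ", paste(need, collapse = ", "))
  bad <- which(!toupper(df$state) %in% c("W", "N", "R"))
  if (length(bad))
    stop("unknown state token '", df$state[bad[1]], "' at line ", bad[1] + 1L,
         " of ", path)
  if (any(df$epoch_index != seq_len(nrow(df)) - 1L)) {
    bad <- which(df$epoch_index != seq_len(nrow(df)) - 1L)[1]
    stop("non-contiguous epoch_index at line ", bad + 1L, " of ", path)
  }
  if (is.null(epoch_s))
    epoch_s <- if (nrow(df) > 1L) df$zt_seconds[2] - df$zt_seconds[1] else 10
  hypnogram(df$state, epoch_s = epoch_s, zt_start_s = df$zt_seconds[1] %% 86400,
            lights_on_h = lights_on_h, lights_off_h = lights_off_h)
}

#' Write a hypnogram CSV
#'
#' Emits the same dialect [read_hypnogram_csv()] consumes (round-trip
#' identity); rows in epoch order, deterministic formatting.
#'
#' @param h A [hypnogram()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hypnogram_csv <- function(h, path) {
  df <- data.frame(epoch_index = seq_len(n_epochs(h)) - 1L,
                   zt_seconds = epoch_zt_s(h),
                   state = h$states)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and validate a pipeline configuration (YAML or JSON)
#'
#' Recognized top-level keys: `epoch_s`, `lights_on_h`, `lights_off_h`,
#' `spectral` (`fs`, `nfft`, `window`, `f_min`, `f_max`), `sd`
#' (`sd_start_zt_h`, `sd_duration_h`, `rs_window_h`, `dark_window_h`),
#' `mslt` (`nap_starts_zt_s`, `nap_duration_s`), `stats` (`welch`, `alpha`),
#' `seed`. Unknown keys are rejected with a clear message.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return Named list of class `"pipeline_config"` with defaults filled in.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  known <- c("epoch_s", "lights_on_h", "lights_off_h", "spectral", "sd",
             "mslt", "stats", "seed")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         " (known: ", paste(known, collapse = ", "), ")")
  defaults <- list(epoch_s = 10, lights_on_h = 0, lights_off_h = 12,
                   spectral = list(), sd = list(), mslt = list(),
                   stats = list(welch = FALSE, alpha = 0.05), seed = 1L)
  for (k in names(defaults)) if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  check_sub <- function(block, allowed) {
    extra <- setdiff(names(cfg[[block]]), allowed)
    if (length(extra))
      stop("unknown key(s) in config block '", block, "': ",
           paste(extra, collapse = ", "))
  }
  check_sub("spectral", c("fs", "nfft", "window", "f_min", "f_max"))
  check_sub("sd", c("sd_start_zt_h", "sd_duration_h", "rs_window_h", "dark_window_h"))
  check_sub("mslt", c("nap_starts_zt_s", "nap_duration_s"))
  check_sub("stats", c("welch", "alpha"))
  structure(cfg, class = "pipeline_config")
}

config_spectral <- function(cfg) do.call(spectral_params, cfg$spectral)
config_sd <- function(cfg) do.call(sd_protocol, cfg$sd)
config_mslt <- function(cfg) do.call(mslt_protocol, cfg$mslt)

#' Command-line interface to the pipeline
#'
#' Subcommands (first argument), each taking `--key=value` options:
#' \describe{
#'   \item{simulate}{`--out=DIR` `[--seed=N]` `[--days=N]` `[--n=N]` -- write a
#'     2x2 genotype-by-sex cohort (`n` animals/group) as hypnogram CSVs plus a
#'     `ground_truth.json` snapshot.}
#'   \item{architecture}{`--hypnogram=CSV` `--out=CSV` -- rescore, detect
#'     bouts and write the architecture summary.}
#'   \item{spectra}{`--hypnogram=CSV` `--eeg=CSV` `--out=JSON` `[--fs=N]` --
#'     state spectra band powers and ratios.}
#'   \item{rebound}{`--baseline=CSV` `--sd=CSV` `--out=JSON` -- rebound
#'     analysis of two full-day hypnograms.}
#'   \item{mslt}{`--hypnogram=CSV` `--out=CSV` -- score the default five-nap
#'     MSLT.}
#'   \item{compare}{`--a=CSV` `--b=CSV` `--out=CSV` -- per-bin group
#'     comparison of two spectra matrices (rows = animals, header = bin Hz).}
#' }
#' A `--config=FILE` option (YAML/JSON, see [read_config()]) is honored by
#' all subcommands.
#'
#' @param args Character vector of command-line arguments.
#' @return Integer exit code (0 on success); errors print a message and
#'   return 1.
#' @export
sleeparch_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste0(
    "usage: sleeparch <simulate|architecture|spectra|rebound|mslt|compare> [--key=value ...]\n",
    "see ?sleeparch_cli for subcommand options\n")
  if (length(args) == 0L || args[1] %in% c("--help", "-h", "help")) {
    cat(usage)
    return(0L)
  }
  cmd <- args[1]
  opts <- parse_cli_opts(args[-1])
  cfg <- if (!is.null(opts$config)) read_config(opts$config) else
    structure(list(epoch_s = 10, lights_on_h = 0, lights_off_h = 12,
                   spectral = list(), sd = list(), mslt = list(),
                   stats = list(welch = FALSE, alpha = 0.05), seed = 1L),
              class = "pipeline_config")
  res <- tryCatch({
    switch(cmd,
           simulate = cli_simulate(opts, cfg),
           architecture = cli_architecture(opts, cfg),
           spectra = cli_spectra(opts, cfg),
           rebound = cli_rebound(opts, cfg),
           mslt = cli_mslt(opts, cfg),
           compare = cli_compare(opts, cfg),
           stop("unknown subcommand: ", cmd))
    0L
  }, error = function(e) {
    message("sleeparch: ", conditionMessage(e))
    1L
  })
  res
}

parse_cli_opts <- function(args) {
  opts <- list()
  for (a in args) {
    if (!grepl("^--[A-Za-z_]+=", a)) stop("malformed option: ", a)
    key <- sub("^--([A-Za-z_]+)=.*$", "\\1", a)
    val <- sub("^--[A-Za-z_]+=", "", a)
    opts[[key]] <- utils::type.convert(val, as.is = TRUE)
  }
  opts
}

need_opt <- function(opts, key) {
  if (is.null(opts[[key]])) stop("missing required option --", key)
  opts[[key]]
}

cli_simulate <- function(opts, cfg) {
  out <- need_opt(opts, "out")
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  n <- if (is.null(opts$n)) 2L else as.integer(opts$n)
  days <- if (is.null(opts$days)) 1 else as.numeric(opts$days)
  seed <- if (is.null(opts$seed)) cfg$seed else as.integer(opts$seed)
  design <- data.frame(genotype = c("KI", "WT", "KI", "WT"),
                       sex = c("F", "F", "M", "M"), n = n)
  cohort <- simulate_cohort(design, n_days = days, seed = seed)
  truth <- list()
  for (a in cohort) {
    write_hypnogram_csv(a$hypnogram, file.path(out, paste0(a$id, ".csv")))
    truth[[a$id]] <- list(genotype = a$genotype, sex = a$sex, seed = a$seed,
                          bout_mean = as.data.frame(a$truth$bout_mean))
    message("wrote ", a$id, " (", n_epochs(a$hypnogram), " epochs)")
  }
  jsonlite::write_json(truth, file.path(out, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}

cli_architecture <- function(opts, cfg) {
  h <- read_hypnogram_csv(need_opt(opts, "hypnogram"), epoch_s = cfg$epoch_s,
                          lights_on_h = cfg$lights_on_h,
                          lights_off_h = cfg$lights_off_h)
  h <- apply_scoring_rules(h)
  utils::write.csv(summarize_architecture(h), need_opt(opts, "out"),
                   row.names = FALSE, quote = FALSE)
  invisible(NULL)
}

cli_spectra <- function(opts, cfg) {
  h <- read_hypnogram_csv(need_opt(opts, "hypnogram"), epoch_s = cfg$epoch_s)
  h <- apply_scoring_rules(h)
  eeg <- utils::read.csv(need_opt(opts, "eeg"))[[1]]
  sp_args <- cfg$spectral
  if (!is.null(opts$fs)) sp_args$fs <- as.numeric(opts$fs)
  params <- do.call(spectral_params, sp_args)
  out <- list()
  for (st in c("W", "N", "R")) {
    sp <- suppressWarnings(state_spectrum(eeg, h, st, params))
    bands <- default_bands()
    bp <- stats::setNames(
      lapply(bands$name, function(b) band_power(sp, b)), bands$name)
    out[[st]] <- c(list(n_epochs_included = sp$n_epochs_included), bp,
                   list(gamma_delta_ratio = band_ratio(sp, "low_gamma", "delta"),
                        theta_delta_ratio = band_ratio(sp, "theta", "delta")))
  }
  jsonlite::write_json(out, need_opt(opts, "out"), auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(NULL)
}

cli_rebound <- function(opts, cfg) {
  hb <- apply_scoring_rules(read_hypnogram_csv(need_opt(opts, "baseline"),
                                               epoch_s = cfg$epoch_s))
  hs <- apply_scoring_rules(read_hypnogram_csv(need_opt(opts, "sd"),
                                               epoch_s = cfg$epoch_s))
  res <- rebound_analysis(hb, hs, do.call(sd_protocol, cfg$sd))
  jsonlite::write_json(
    list(rs_cum_nrem_min = as.list(res$rs_cum_nrem_min),
         dark_rem_min = as.list(res$dark_rem_min),
         sd_sleep_pct = res$sd_sleep_pct,
         hourly = res$hourly),
    need_opt(opts, "out"), auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}

cli_mslt <- function(opts, cfg) {
  h <- read_hypnogram_csv(need_opt(opts, "hypnogram"), epoch_s = cfg$epoch_s)
  res <- mslt_score(h, do.call(mslt_protocol, cfg$mslt))
  for (i in which(res$censored_nrem))
    message("nap ", res$nap[i], ": no NREM bout; latency censored at nap end")
  utils::write.csv(res, need_opt(opts, "out"), row.names = FALSE, quote = FALSE)
  invisible(NULL)
}

cli_compare <- function(opts, cfg) {
  read_mat <- function(p) as.matrix(utils::read.csv(p, check.names = FALSE))
  a <- read_mat(need_opt(opts, "a"))
  b <- read_mat(need_opt(opts, "b"))
  freq <- as.numeric(colnames(a))
  if (anyNA(freq)) stop("spectra CSV header must be the bin frequencies in Hz")
  res <- per_bin_compare(a, b, freq, alpha = cfg$stats$alpha,
                         welch = isTRUE(cfg$stats$welch))
  df <- data.frame(freq_hz = res$freq, mean_a = res$mean_a, mean_b = res$mean_b,
                   t = res$t, p = res$p, p_adjusted = res$p_adjusted,
                   reject = res$reject)
  utils::write.csv(df, need_opt(opts, "out"), row.names = FALSE, quote = FALSE)
  if (nrow(res$ranges))
    message("significant ranges (Hz): ",
            paste(sprintf("%.2f-%.2f", res$ranges$lo_hz, res$ranges$hi_hz),
                  collapse = ", "))
  invisible(NULL)
}
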