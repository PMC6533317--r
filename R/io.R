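SUMMARY_SCHEMA_VERSION <- "mindchange-trial-set-v1"
TRACE_SCHEMA_VERSION <- "mindchange-traces-v1"

#' Load a model/protocol configuration file
#'
#' Reads a YAML or JSON configuration with two optional top-level blocks:
#' `parameters` (overrides of [model_parameters()] fields) and `protocol`
#' (fields of [trial_config()] plus `epsilon_grid`, `n_trials`,
#' `master_seed`). Unknown keys are rejected by name. A top-level
#' `time_unit: s` declares that the configuration's time constants
#' (`tau_*`, delays, onsets, timeouts, `dt`) are given in seconds and
#' converts them to the internal millisecond convention.
#'
#' @param path file path; an empty file yields the full default profile.
#' @return list with `params` (a `model_parameters`), `protocol` (a
#'   `trial_config`), `epsilon_grid`, `n_trials`, `master_seed`, and
#'   `manifest` (resolved values plus parameter hash).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::yaml.load_file(path)
  if (is.null(raw)) raw <- list()
  allowed_top <- c("parameters", "protocol", "time_unit", "profile")
  unknown <- setdiff(names(raw), allowed_top)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  time_unit <- raw$time_unit %||% "ms"
  if (!time_unit %in% c("ms", "s"))
    stop("time_unit must be 'ms' or 's'")
  k <- if (time_unit == "s") 1000 else 1

  par_ov <- raw$parameters %||% list()
  par_time <- c("tau_s", "tau_mc", "tau_h", "tau_noise")
  for (nm in intersect(names(par_ov), par_time))
    par_ov[[nm]] <- par_ov[[nm]] * k
  # 'd' is already in seconds by convention; never rescaled
  params <- do.call(model_parameters, par_ov)

  pr_ov <- raw$protocol %||% list()
  grid <- pr_ov$epsilon_grid %||% c(0, 3.2, 6.4, 12.8, 25.6, 51.2)
  n_trials <- pr_ov$n_trials %||% 100L
  master_seed <- pr_ov$master_seed %||% 1L
  pr_ov$epsilon_grid <- pr_ov$n_trials <- pr_ov$master_seed <- NULL
  cfg_time <- c("t_stimulus_onset", "t_timeout", "delay_inh", "delay_unc",
                "dt")
  allowed_pr <- c(cfg_time, "epsilon", "correct_side", "seed",
                  "mu_override")
  unknown <- setdiff(names(pr_ov), allowed_pr)
  if (length(unknown))
    stop("unknown protocol key(s): ", paste(unknown, collapse = ", "))
  for (nm in intersect(names(pr_ov), cfg_time))
    pr_ov[[nm]] <- pr_ov[[nm]] * k
  protocol <- do.call(trial_config, pr_ov)

  list(params = params, protocol = protocol, epsilon_grid = grid,
       n_trials = n_trials, master_seed = master_seed,
       manifest = run_manifest(params, list(
         epsilon_grid = grid, n_trials = n_trials,
         master_seed = master_seed, dt = protocol$dt,
         t_stimulus_onset = protocol$t_stimulus_onset,
         t_timeout = protocol$t_timeout,
         delay_inh = protocol$delay_inh,
         delay_unc = protocol$delay_unc)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run manifest
#'
#' Bundles the fully resolved parameter profile (with content hash), the
#' protocol, and the package version, so that a run can be reproduced
#' bit-for-bit from its manifest and seeds.
#'
#' @param params a [model_parameters()] object.
#' @param protocol named list of protocol settings.
#' @return list of class `run_manifest`.
#' @export
run_manifest <- function(params, protocol) {
  structure(list(
    package = "mindchange",
    version = as.character(utils::packageVersion("mindchange")),
    parameter_hash = parameter_hash(params),
    parameters = unclass(params),
    protocol = protocol,
    timestamp = format(Sys.time(), tz = "UTC")
  ), class = "run_manifest")
}

#' Write a trial set to CSV
#'
#' Writes the per-trial summary table (and optionally the full traces, in
#' long format) with a schema-version header line, plus a JSON manifest.
#'
#' @param trials a `trial_set`.
#' @param dir output directory (created if needed).
#' @param traces also write per-trial traces (requires the set to have
#'   been simulated with `keep_traces = TRUE`).
#' @return invisibly, the paths written.
#' @export
write_trial_set <- function(trials, dir, traces = FALSE) {
  stopifnot(inherits(trials, "trial_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(summary = file.path(dir, "trials.csv"),
             manifest = file.path(dir, "manifest.json"))
  con <- file(paths["summary"], "w")
  writeLines(paste0("# ", SUMMARY_SCHEMA_VERSION), con)
  close(con)
  data.table::fwrite(trials$summary, paths["summary"], append = TRUE,
                     col.names = TRUE)
  jsonlite::write_json(
    run_manifest(trials$params, trials$protocol),
    paths["manifest"], auto_unbox = TRUE, digits = NA, pretty = TRUE,
    force = TRUE)
  if (traces) {
    if (is.null(trials$records))
      stop("trial set has no stored traces; simulate with keep_traces = TRUE")
    paths["traces"] <- file.path(dir, "traces.csv")
    long <- data.table::rbindlist(lapply(seq_along(trials$records),
                                         function(i) {
      r <- trials$records[[i]]
      data.table::data.table(trial_id = i, time = r$time, S1 = r$S1,
                             S2 = r$S2, H1 = r$H1, H2 = r$H2,
                             y_inh = r$y_inh, y_U = r$y_U, y_L = r$y_L,
                             y_R = r$y_R, x = r$x)
    }))
    con <- file(paths["traces"], "w")
    writeLines(paste0("# ", TRACE_SCHEMA_VERSION), con)
    close(con)
    data.table::fwrite(long, paths["traces"], append = TRUE,
                       col.names = TRUE)
  }
  invisible(paths)
}

#' Read a trial set written by [write_trial_set()]
#'
#' @param dir directory containing `trials.csv` (and optionally
#'   `traces.csv` and `manifest.json`).
#' @return a `trial_set`; traces, if present, are returned as one long
#'   data frame under `$traces`.
#' @export
read_trial_set <- function(dir) {
  f <- file.path(dir, "trials.csv")
  if (!file.exists(f)) stop("no trials.csv under ", dir)
  hdr <- readLines(f, n = 1)
  if (!identical(hdr, paste0("# ", SUMMARY_SCHEMA_VERSION)))
    stop("unrecognised trial-set schema: ", hdr)
  summ <- as.data.frame(data.table::fread(f, skip = 1))
  man_f <- file.path(dir, "manifest.json")
  protocol <- NULL
  if (file.exists(man_f)) {
    man <- jsonlite::read_json(man_f, simplifyVector = TRUE)
    protocol <- man$protocol
  }
  tr_f <- file.path(dir, "traces.csv")
  traces <- NULL
  if (file.exists(tr_f))
    traces <- as.data.frame(data.table::fread(tr_f, skip = 1))
  structure(list(summary = summ, records = NULL, traces = traces,
                 protocol = protocol, params = NULL),
            class = "trial_set")
}

# seed of the pinned change-of-mind demonstration trial (found once by a
# seed search at epsilon = 3.2 with the default profile, then frozen)
COM_DEMO <- list(seed = 17L, epsilon = 3.2, correct_side = 2L)

#' Generate deterministic test fixtures
#'
#' Writes small, reproducible trial records used by the test suite: two
#' zero-noise trials (an easy and a symmetric one) and one seeded
#' stochastic change-of-mind trial whose seed was found once by search and
#' is pinned in the package. A manifest lists every seed used.
#'
#' @param out_dir output directory.
#' @param kind `"zero-noise"`, `"seeded-stochastic"`, or both (default).
#' @param params a [model_parameters()] object.
#' @return invisibly, the manifest as a list.
#' @export
generate_fixtures <- function(out_dir,
                              kind = c("zero-noise", "seeded-stochastic"),
                              params = model_parameters()) {
  kind <- match.arg(kind, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(schema = "mindchange-fixtures-v1",
                   parameter_hash = parameter_hash(params),
                   fixtures = list())
  write_rec <- function(rec, name) {
    df <- data.frame(time = rec$time, S1 = rec$S1, S2 = rec$S2,
                     H1 = rec$H1, H2 = rec$H2, y_inh = rec$y_inh,
                     y_U = rec$y_U, y_L = rec$y_L, y_R = rec$y_R,
                     x = rec$x)
    f <- file.path(out_dir, paste0(name, ".csv"))
    data.table::fwrite(df, f)
    f
  }
  if ("zero-noise" %in% kind) {
    p0 <- do.call(model_parameters,
                  utils::modifyList(unclass(params),
                                    list(sigma_noise = 0)))
    easy <- run_trial(trial_config(epsilon = 51.2, correct_side = 2), p0)
    symm <- run_trial(trial_config(epsilon = 0, correct_side = 1), p0)
    write_rec(easy, "zero_noise_easy")
    write_rec(symm, "zero_noise_symmetric")
    manifest$fixtures$zero_noise_easy <-
      list(epsilon = 51.2, correct_side = 2, sigma_noise = 0, seed = NULL)
    manifest$fixtures$zero_noise_symmetric <-
      list(epsilon = 0, correct_side = 1, sigma_noise = 0, seed = NULL)
  }
  if ("seeded-stochastic" %in% kind) {
    com <- run_trial(trial_config(epsilon = COM_DEMO$epsilon,
                                  correct_side = COM_DEMO$correct_side,
                                  seed = COM_DEMO$seed), params)
    write_rec(com, "seeded_com")
    manifest$fixtures$seeded_com <- COM_DEMO
  }
  jsonlite::write_json(manifest, file.path(out_dir, "fixtures.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
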