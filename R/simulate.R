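#' Trial protocol configuration
#'
#' Timing constants and stimulus settings for a single simulated trial of
#' the reaction-time task. Times are in ms; the timeout is counted from
#' stimulus onset.
#'
#' @param epsilon evidence quality in percent (0-100).
#' @param correct_side which population/choice is correct, 1 (Left) or 2
#'   (Right).
#' @param t_stimulus_onset stimulus onset time from trial start (ms).
#' @param t_timeout response deadline after stimulus onset (ms).
#' @param delay_inh delay after stimulus onset before the top-down clamp is
#'   released from the inhibitory population (ms).
#' @param delay_unc delay after stimulus onset before the clamp is released
#'   from the uncertainty-encoding population (ms).
#' @param dt Euler-Maruyama integration step (ms).
#' @param seed optional integer seed making the trial reproducible.
#' @param mu_override optional tonic bias (nA) replacing the parameter
#'   profile's `mu_tonic` (used for the second trial of a coupled pair).
#' @return an object of class `trial_config`.
#' @export
trial_config <- function(epsilon = 0, correct_side = 1,
                         t_stimulus_onset = 900, t_timeout = 4000,
                         delay_inh = 400, delay_unc = 500,
                         dt = 0.5, seed = NULL, mu_override = NULL) {
  if (!is.numeric(epsilon) || length(epsilon) != 1L || !is.finite(epsilon) ||
      epsilon < 0 || epsilon > 100)
    stop("epsilon must be a single value in [0, 100]")
  if (!correct_side %in% c(1, 2)) stop("correct_side must be 1 or 2")
  if (dt <= 0) stop("dt must be > 0")
  if (t_timeout <= 0) stop("t_timeout must be > 0")
  if (delay_inh < 0 || delay_unc < 0) stop("delays must be >= 0")
  structure(list(epsilon = epsilon, correct_side = as.integer(correct_side),
                 t_stimulus_onset = t_stimulus_onset, t_timeout = t_timeout,
                 delay_inh = delay_inh, delay_unc = delay_unc, dt = dt,
                 seed = seed, mu_override = mu_override),
            class = "trial_config")
}

#' Simulate a single trial
#'
#' Integrates the full circuit through the trial's event schedule with the
#' forward Euler-Maruyama scheme: top-down clamp on the uncertainty and
#' motor modules from trial start, stimulus on at `t_stimulus_onset`, clamp
#' released from the inhibitory and uncertainty-encoding populations
#' `delay_inh` and `delay_unc` after stimulus onset, decision registered
#' when either sensorimotor rate first reaches `decision_threshold`
#' (response time and initial choice; clamp reinstated at `g_reactivated`
#' on the uncertainty module and released from the motor module), then
#' integration continues with no reset of any state variable until a motor
#' rate reaches `M_th` (final choice) or the timeout elapses (indecision).
#'
#' @param config a [trial_config()].
#' @param params a [model_parameters()] object.
#' @param record keep the full state trace (default `TRUE`).
#' @return an object of class `trial_record`: a list with `time` and traces
#'   (`S1`, `S2`, `H1`, `H2`, `y_inh`, `y_U`, `y_L`, `y_R`, `x`) when
#'   recorded, plus the derived events `rt` (ms from stimulus onset, `NA`
#'   if no decision), `initial_choice`, `final_choice` (0 = none),
#'   `indecision`, `com`, `com_direction`, `uncertainty_peak`,
#'   `uncertainty_area` (Hz*ms), `epsilon`, `correct_side`, `seed`.
#' @examples
#' p <- model_parameters(sigma_noise = 0)  # deterministic trial
#' rec <- run_trial(trial_config(epsilon = 51.2, correct_side = 2), p)
#' rec$final_choice
#' @export
run_trial <- function(config, params, record = TRUE) {
  stopifnot(inherits(config, "trial_config"),
            inherits(params, "model_parameters"))
  if (!is.null(config$seed)) set.seed(config$seed)
  mu_eff <- if (is.null(config$mu_override)) params$mu_tonic else
    config$mu_override
  cfg <- list(epsilon = config$epsilon, correct_side = config$correct_side,
              t_stimulus_onset = config$t_stimulus_onset,
              t_timeout = config$t_timeout, delay_inh = config$delay_inh,
              delay_unc = config$delay_unc, dt = config$dt, mu_eff = mu_eff)
  res <- engine_run_trial(unclass(params), cfg, record)
  ev <- res$events
  if (isTRUE(ev$tie))
    warning("simultaneous threshold crossing; population 1 chosen")
  rec <- list(
    time = if (record) res$trace[, "time"] else NULL,
    S1 = if (record) res$trace[, "S1"] else NULL,
    S2 = if (record) res$trace[, "S2"] else NULL,
    H1 = if (record) res$trace[, "H1"] else NULL,
    H2 = if (record) res$trace[, "H2"] else NULL,
    y_inh = if (record) res$trace[, "y_inh"] else NULL,
    y_U = if (record) res$trace[, "y_U"] else NULL,
    y_L = if (record) res$trace[, "y_L"] else NULL,
    y_R = if (record) res$trace[, "y_R"] else NULL,
    x = if (record) res$trace[, "x"] else NULL,
    rt = ev$rt,
    initial_choice = ev$initial_choice,
    final_choice = ev$final_choice,
    indecision = ev$indecision,
    com = ev$com,
    com_direction = c("none", "error-to-correct",
                      "correct-to-error")[ev$com_direction + 1L],
    first_move_sign = ev$first_move_sign,
    uncertainty_peak = ev$uncertainty_peak,
    uncertainty_area = ev$uncertainty_area,
    t_end = ev$t_end,
    epsilon = config$epsilon,
    correct_side = config$correct_side,
    mu_eff = mu_eff,
    seed = config$seed,
    dt = config$dt,
    t_stimulus_onset = config$t_stimulus_onset
  )
  structure(rec, class = "trial_record")
}

#' @export
print.trial_record <- function(x, ...) {
  cat("<trial_record> epsilon =", x$epsilon, "; correct side =",
      x$correct_side, "\n")
  cat("  rt =", if (is.na(x$rt)) "none" else paste0(x$rt, " ms"),
      "; initial ->", x$initial_choice, "; final ->", x$final_choice,
      if (x$indecision) "(indecision)" else "", "\n")
  cat("  change-of-mind:", x$com,
      if (x$com) paste0("(", x$com_direction, ")") else "", "\n")
  cat(sprintf("  uncertainty: peak = %.3f, area = %.1f Hz*ms\n",
              x$uncertainty_peak, x$uncertainty_area))
  invisible(x)
}

# derive independent, reproducible per-trial seeds from a master seed
derive_seeds <- function(master_seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(master_seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Simulate a block of trials
#'
#' Runs `n_trials` per evidence-quality level with independent,
#' reproducibly derived per-trial seeds, counterbalancing the correct side
#' within each level. Indecision trials (no motor target reached before the
#' timeout) are flagged and retained; the analysis functions exclude them.
#'
#' @param n_trials trials per evidence-quality level.
#' @param epsilon_grid evidence-quality levels in percent.
#' @param params a [model_parameters()] object.
#' @param master_seed integer seed from which all per-trial seeds derive.
#' @param config a [trial_config()] used as protocol template (its
#'   `epsilon`, `correct_side` and `seed` are overridden per trial).
#' @param keep_traces retain full per-trial traces (memory-heavy; default
#'   `FALSE`).
#' @return an object of class `trial_set`: a list with `summary` (one row
#'   per trial), `protocol` metadata, and optionally `records`.
#' @examples
#' ts <- run_block(5, c(0, 51.2), model_parameters(), master_seed = 1)
#' table(ts$summary$final_choice)
#' @export
run_block <- function(n_trials, epsilon_grid = c(0, 3.2, 6.4, 12.8, 25.6,
                                                 51.2),
                      params = model_parameters(), master_seed = 1L,
                      config = trial_config(), keep_traces = FALSE) {
  stopifnot(n_trials >= 1)
  grid <- rep(epsilon_grid, each = n_trials)
  n <- length(grid)
  seeds <- derive_seeds(master_seed, n)
  # counterbalanced correct side within each condition
  side <- rep(rep_len(c(1L, 2L), n_trials), length(epsilon_grid))
  rows <- vector("list", n)
  recs <- if (keep_traces) vector("list", n) else NULL
  for (i in seq_len(n)) {
    cfg <- config
    cfg$epsilon <- grid[i]
    cfg$correct_side <- side[i]
    cfg$seed <- seeds[i]
    rec <- run_trial(cfg, params, record = keep_traces)
    if (keep_traces) recs[[i]] <- rec
    rows[[i]] <- trial_summary_row(rec, i)
  }
  summ <- do.call(rbind, rows)
  rownames(summ) <- NULL
  structure(list(
    summary = summ,
    records = recs,
    protocol = list(epsilon_grid = epsilon_grid, n_trials = n_trials,
                    master_seed = master_seed,
                    t_stimulus_onset = config$t_stimulus_onset,
                    t_timeout = config$t_timeout,
                    delay_inh = config$delay_inh,
                    delay_unc = config$delay_unc, dt = config$dt,
                    parameter_hash = parameter_hash(params)),
    params = params
  ), class = "trial_set")
}

trial_summary_row <- function(rec, id) {
  data.frame(
    trial_id = id,
    epsilon = rec$epsilon,
    correct_side = rec$correct_side,
    rt_ms = if (is.na(rec$rt)) NA_real_ else rec$rt,
    initial_choice = rec$initial_choice,
    final_choice = rec$final_choice,
    correct = if (rec$indecision) NA else rec$final_choice ==
      rec$correct_side,
    com = rec$com,
    com_direction = rec$com_direction,
    uncertainty_peak = rec$uncertainty_peak,
    uncertainty_area = rec$uncertainty_area,
    indecision = rec$indecision,
    mu_eff = rec$mu_eff,
    seed = if (is.null(rec$seed)) NA_integer_ else rec$seed,
    stringsAsFactors = FALSE
  )
}

#' @export
print.trial_set <- function(x, ...) {
  s <- x$summary
  cat("<trial_set>", nrow(s), "trials;", "epsilon grid:",
      paste(x$protocol$epsilon_grid, collapse = ", "), "\n")
  cat(sprintf("  indecision %.1f%%; change-of-mind %.1f%%\n",
              100 * mean(s$indecision), 100 * mean(s$com)))
  invisible(x)
}

#' Simulate pairs of coupled trials
#'
#' In the multi-stage paradigm reward depends on both decisions of a pair,
#' and the decision uncertainty of the first trial carries over: the area
#' read-out `X_n` of the first trial sets a bias `C = alpha * X_n + beta`
#' that is added to the tonic input of the uncertainty-encoding population
#' in the second trial (`mu -> mu + C`), after which the stored bias is
#' reset to zero. The second trial's evidence quality is drawn uniformly
#' from `epsilon_grid`.
#'
#' @param n_pairs number of coupled pairs per first-trial evidence level.
#' @param params a [model_parameters()] object.
#' @param master_seed integer seed.
#' @param epsilon_grid evidence-quality levels; first-trial levels cycle
#'   through the grid, second-trial levels are drawn uniformly from it.
#' @param alpha,beta scaling (nA per Hz*ms) and offset (nA) of the linear
#'   uncertainty-to-bias transformation.
#' @param config protocol template, as in [run_block()].
#' @return a list of two `trial_set` objects (`first`, `second`); the
#'   second set's summary carries `pair_id`, the applied bias `C_bias` and
#'   the first trial's outcome (`first_correct`).
#' @export
run_coupled_pairs <- function(n_pairs, params = model_parameters(),
                              master_seed = 1L,
                              epsilon_grid = c(0, 3.2, 6.4, 12.8, 25.6,
                                               51.2),
                              alpha = 0.008, beta = 0.5,
                              config = trial_config()) {
  stopifnot(n_pairs >= 1)
  eps1 <- rep(epsilon_grid, each = n_pairs)
  n <- length(eps1)
  seeds <- derive_seeds(master_seed, 2L * n + 1L)
  set.seed(seeds[2L * n + 1L])
  eps2 <- sample(epsilon_grid, n, replace = TRUE)
  side1 <- rep(rep_len(c(1L, 2L), n_pairs), length(epsilon_grid))
  side2 <- sample(c(1L, 2L), n, replace = TRUE)
  rows1 <- rows2 <- vector("list", n)
  for (i in seq_len(n)) {
    cfg1 <- config
    cfg1$epsilon <- eps1[i]; cfg1$correct_side <- side1[i]
    cfg1$seed <- seeds[2L * i - 1L]
    r1 <- run_trial(cfg1, params, record = FALSE)
    C <- alpha * r1$uncertainty_area + beta
    cfg2 <- config
    cfg2$epsilon <- eps2[i]; cfg2$correct_side <- side2[i]
    cfg2$seed <- seeds[2L * i]
    cfg2$mu_override <- params$mu_tonic + C   # reset implicitly after pair
    r2 <- run_trial(cfg2, params, record = FALSE)
    rows1[[i]] <- trial_summary_row(r1, i)
    row2 <- trial_summary_row(r2, i)
    row2$pair_id <- i
    row2$C_bias <- C
    row2$first_correct <- if (r1$indecision) NA else
      r1$final_choice == r1$correct_side
    row2$first_epsilon <- eps1[i]
    rows2[[i]] <- row2
  }
  mk <- function(rows) {
    summ <- do.call(rbind, rows)
    rownames(summ) <- NULL
    structure(list(summary = summ, records = NULL,
                   protocol = list(epsilon_grid = epsilon_grid,
                                   n_trials = n_pairs,
                                   master_seed = master_seed,
                                   alpha = alpha, beta = beta,
                                   dt = config$dt,
                                   parameter_hash = parameter_hash(params)),
                   params = params), class = "trial_set")
  }
  list(first = mk(rows1), second = mk(rows2))
}
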