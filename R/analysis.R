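#' Classify a trial as a change-of-mind
#'
#' A change-of-mind is a reversal of the order of dominance of the two
#' motor populations after movement initiation — i.e. a change in the sign
#' of the motor position `x` — provided a choice target is eventually
#' reached before the timeout. Indecision trials are never changes-of-mind.
#' The direction compares the final choice with the correct side.
#'
#' @param record a [run_trial()] result with motor trace retained.
#' @return a list with `com` (logical) and `direction` (one of
#'   `"error-to-correct"`, `"correct-to-error"`, `"none"`).
#' @export
classify_change_of_mind <- function(record) {
  if (is.null(record$x) || is.null(record$time))
    stop("trial record has no motor trace; rerun with record = TRUE")
  if (record$indecision || record$final_choice == 0 || is.na(record$rt))
    return(list(com = FALSE, direction = "none"))
  t_dec <- record$t_stimulus_onset + record$rt
  x <- record$x[record$time >= t_dec]
  sgn <- sign(x[x != 0])
  if (!length(sgn)) return(list(com = FALSE, direction = "none"))
  final_sign <- if (record$final_choice == 1) 1 else -1
  com <- final_sign != sgn[1]
  dir <- if (!com) "none" else if (record$final_choice ==
                                   record$correct_side)
    "error-to-correct" else "correct-to-error"
  list(com = com, direction = dir)
}

#' Uncertainty read-outs of a single trial
#'
#' Two per-trial measures of decision uncertainty from the
#' uncertainty-encoding population activity: its maximum (a real-time
#' read-out) and the area under its curve over the recorded window,
#' computed with the trapezoidal scheme (a proxy for a downstream neural
#' integrator). The area is in Hz*ms (time grid in ms).
#'
#' @param record a [run_trial()] result with the `y_U` trace retained.
#' @return a list with `peak` and `area`.
#' @export
uncertainty_measures <- function(record) {
  if (is.null(record$y_U)) stop("trial record has no y_U trace")
  list(peak = max(record$y_U),
       area = pracma::trapz(record$time, record$y_U))
}

#' Feature scaling to the unit interval
#'
#' `X' = (X - min X) / (max X - min X)`: an affine map sending the minimum
#' to 0 and the maximum to 1, applied across a whole trial set per measure.
#'
#' @param values numeric vector with at least two distinct finite values.
#' @return rescaled vector in \[0, 1\].
#' @export
normalize_feature <- function(values) {
  v <- values[is.finite(values)]
  if (length(v) < 2 || max(v) == min(v))
    stop("feature scaling needs at least two distinct values")
  (values - min(v)) / (max(v) - min(v))
}

#' Fit a Weibull psychometric function
#'
#' Accuracy as a function of evidence quality is fitted with
#' `p(eps) = 1 - 0.5 exp(-(eps/alpha)^beta)`, where `alpha` is the
#' threshold (in percent evidence quality) and `beta` the slope. By default
#' the fit maximises the binomial likelihood of the per-level correct
#' counts; `method = "ls"` minimises squared error of the per-level
#' accuracies instead. Indecision trials must already be excluded.
#'
#' @param accuracy_by_epsilon data frame with columns `epsilon`,
#'   `n_correct`, `n_total` (or `epsilon` and `accuracy` for `method =
#'   "ls"` with equal weights).
#' @param method `"ml"` (binomial maximum likelihood, default) or `"ls"`.
#' @return an object of class `psychometric_fit` with `alpha`, `beta`, the
#'   per-level accuracy table and the fitting method.
#' @examples
#' eps <- c(3.2, 6.4, 12.8, 25.6, 51.2)
#' acc <- 1 - 0.5 * exp(-(eps / 7.32)^1.32)
#' d <- data.frame(epsilon = eps, n_correct = round(1e6 * acc), n_total = 1e6)
#' fit_weibull(d)$alpha
#' @export
fit_weibull <- function(accuracy_by_epsilon, method = c("ml", "ls")) {
  method <- match.arg(method)
  d <- accuracy_by_epsilon
  if (is.null(d$n_total) && !is.null(d$accuracy)) {
    d$n_total <- rep(1L, nrow(d))
    d$n_correct <- d$accuracy
  }
  stopifnot(all(c("epsilon", "n_correct", "n_total") %in% names(d)))
  if (sum(d$epsilon > 0) < 2)
    stop("need at least two non-zero evidence levels to fit")
  pfun <- function(eps, alpha, beta)
    1 - 0.5 * exp(-(eps / alpha)^beta)
  acc <- d$n_correct / d$n_total
  obj <- function(th) {
    alpha <- exp(th[1]); beta <- exp(th[2])
    p <- pfun(d$epsilon, alpha, beta)
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    if (method == "ml")
      -sum(d$n_correct * log(p) + (d$n_total - d$n_correct) * log(1 - p))
    else
      sum((acc - p)^2)
  }
  # crude threshold guess: evidence level nearest 81.6% correct
  i <- which.min(abs(acc - (1 - 0.5 * exp(-1))))
  start <- c(log(max(d$epsilon[i], 1e-2)), log(1.3))
  opt <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  opt2 <- stats::optim(opt$par, obj, method = "Nelder-Mead",
                       control = list(maxit = 2000, reltol = 1e-14))
  if (opt2$convergence != 0)
    stop("Weibull fit did not converge (code ", opt2$convergence, ")")
  alpha <- exp(opt2$par[1]); beta <- exp(opt2$par[2])
  tab <- data.frame(epsilon = d$epsilon, accuracy = acc,
                    n_total = d$n_total,
                    sem = sqrt(acc * (1 - acc) / d$n_total),
                    fitted = pfun(d$epsilon, alpha, beta))
  structure(list(alpha = alpha, beta = beta, table = tab, method = method,
                 value = opt2$value),
            class = "psychometric_fit")
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat(sprintf(
    "<psychometric_fit> p = 1 - 0.5 exp(-(eps/alpha)^beta); alpha = %.3f%%, beta = %.3f (%s)\n",
    x$alpha, x$beta, if (x$method == "ml") "binomial ML" else
      "least squares"))
  invisible(x)
}

# accuracy table from a trial-set summary, excluding indecision trials
accuracy_table <- function(trials) {
  s <- trial_summary(trials)
  s <- s[!s$indecision, ]
  agg <- stats::aggregate(cbind(n_correct = correct) ~ epsilon, data = s,
                          FUN = sum)
  agg$n_total <- as.vector(table(factor(s$epsilon,
                                        levels = sort(unique(s$epsilon)))))
  agg
}

#' Fit the psychometric function of a simulated trial set
#'
#' Convenience wrapper: tabulates per-level accuracy (excluding indecision
#' trials) and calls [fit_weibull()].
#'
#' @param trials a `trial_set` (or its summary data frame).
#' @param method passed to [fit_weibull()].
#' @return a `psychometric_fit`.
#' @export
psychometric_fit <- function(trials, method = "ml") {
  fit_weibull(accuracy_table(trials), method = method)
}

trial_summary <- function(trials) {
  if (inherits(trials, "trial_set")) trials$summary else
    as.data.frame(trials)
}

#' Chronometric summary
#'
#' Mean response time with standard error per evidence level and outcome
#' (correct/error), excluding indecision trials. Cells with fewer than two
#' trials report `NA` standard errors.
#'
#' @param trials a `trial_set` or summary data frame.
#' @return data frame with `epsilon`, `outcome`, `n`, `mean_rt`, `sem_rt`.
#' @export
chronometric_summary <- function(trials) {
  s <- trial_summary(trials)
  s <- s[!s$indecision & !is.na(s$rt_ms), ]
  s$outcome <- ifelse(s$correct, "correct", "error")
  out <- expand.grid(epsilon = sort(unique(s$epsilon)),
                     outcome = c("correct", "error"),
                     stringsAsFactors = FALSE)
  out$n <- NA_integer_; out$mean_rt <- NA_real_; out$sem_rt <- NA_real_
  for (i in seq_len(nrow(out))) {
    v <- s$rt_ms[s$epsilon == out$epsilon[i] & s$outcome == out$outcome[i]]
    out$n[i] <- length(v)
    if (length(v) >= 1) out$mean_rt[i] <- mean(v)
    if (length(v) >= 2) out$sem_rt[i] <- stats::sd(v) / sqrt(length(v))
  }
  out
}

#' Per-condition uncertainty summary
#'
#' Normalised (feature-scaled across the whole trial set, per measure)
#' peak and area uncertainty read-outs, summarised as mean and standard
#' error per evidence level and outcome. This is the summary behind the
#' "<" pattern: uncertainty decreasing with evidence quality for correct
#' choices and increasing for errors.
#'
#' @param trials a `trial_set` or summary data frame.
#' @return data frame keyed by (`epsilon`, `outcome`) with columns
#'   `mean_peak`, `sem_peak`, `mean_area`, `sem_area`, `n`.
#' @export
uncertainty_summary <- function(trials) {
  s <- trial_summary(trials)
  s <- s[!s$indecision, ]
  s$peak_n <- normalize_feature(s$uncertainty_peak)
  s$area_n <- normalize_feature(s$uncertainty_area)
  s$outcome <- ifelse(s$correct, "correct", "error")
  out <- expand.grid(epsilon = sort(unique(s$epsilon)),
                     outcome = c("correct", "error"),
                     stringsAsFactors = FALSE)
  for (col in c("n", "mean_peak", "sem_peak", "mean_area", "sem_area"))
    out[[col]] <- NA_real_
  for (i in seq_len(nrow(out))) {
    k <- s$epsilon == out$epsilon[i] & s$outcome == out$outcome[i]
    out$n[i] <- sum(k)
    if (any(k)) {
      out$mean_peak[i] <- mean(s$peak_n[k])
      out$mean_area[i] <- mean(s$area_n[k])
      if (sum(k) >= 2) {
        out$sem_peak[i] <- stats::sd(s$peak_n[k]) / sqrt(sum(k))
        out$sem_area[i] <- stats::sd(s$area_n[k]) / sqrt(sum(k))
      }
    }
  }
  out
}

#' Accuracy as a function of binned decision uncertainty
#'
#' Bins the normalised peak uncertainty read-out into quantile bins and
#' reports accuracy per bin; accuracy decreases with binned uncertainty.
#'
#' @param trials a `trial_set` or summary data frame.
#' @param n_bins number of quantile bins.
#' @return data frame with bin midpoints, accuracy and counts.
#' @export
accuracy_by_uncertainty <- function(trials, n_bins = 8) {
  s <- trial_summary(trials)
  s <- s[!s$indecision, ]
  u <- normalize_feature(s$uncertainty_peak)
  br <- unique(stats::quantile(u, probs = seq(0, 1, length.out = n_bins +
                                                1)))
  bin <- cut(u, br, include.lowest = TRUE)
  data.frame(
    uncertainty = tapply(u, bin, mean),
    accuracy = tapply(s$correct, bin, mean),
    n = as.vector(table(bin)),
    row.names = NULL
  )
}

#' Change-of-mind probability curve
#'
#' Per evidence level: the probability of any change-of-mind, and split by
#' whether the final choice is correct (error-to-correct) or an error
#' (correct-to-error), with binomial standard errors. Probabilities are
#' computed over the analysed (non-indecision) trials of each level and
#' the total is the sum of the two directional curves.
#'
#' @param trials a `trial_set` or summary data frame.
#' @return an object of class `com_curve` (data frame).
#' @export
com_probability_curve <- function(trials) {
  s <- trial_summary(trials)
  s <- s[!s$indecision, ]
  eps <- sort(unique(s$epsilon))
  out <- data.frame(epsilon = eps, n = NA_real_, p_any = NA_real_,
                    p_to_correct = NA_real_, p_to_error = NA_real_,
                    se_any = NA_real_)
  for (i in seq_along(eps)) {
    k <- s$epsilon == eps[i]
    n <- sum(k)
    out$n[i] <- n
    out$p_any[i] <- mean(s$com[k])
    out$p_to_correct[i] <- mean(s$com[k] & s$com_direction[k] ==
                                  "error-to-correct")
    out$p_to_error[i] <- mean(s$com[k] & s$com_direction[k] ==
                                "correct-to-error")
    out$se_any[i] <- sqrt(out$p_any[i] * (1 - out$p_any[i]) / n)
  }
  class(out) <- c("com_curve", "data.frame")
  out
}

#' Regression of response time on decision uncertainty
#'
#' Ordinary least squares of response time against the peak uncertainty
#' read-out, at two pairing levels: per trial (the Pearson correlation is
#' the headline number) and per evidence-level condition mean (where the
#' R-squared of the 6-point regression is reported). Indecision trials are
#' excluded.
#'
#' @param trials a `trial_set` or summary data frame.
#' @return list with components `trial` and `condition`, each containing
#'   `slope`, `intercept`, `pearson_r`, `r_squared` and `n`.
#' @export
rt_uncertainty_regression <- function(trials) {
  s <- trial_summary(trials)
  s <- s[!s$indecision & !is.na(s$rt_ms), ]
  if (nrow(s) < 3) stop("need at least 3 trials for the regression")
  one <- function(x, y) {
    fit <- stats::lm(y ~ x)
    r <- stats::cor(x, y)
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         pearson_r = r, r_squared = r^2, n = length(x))
  }
  u <- s$uncertainty_peak
  cm_u <- tapply(u, s$epsilon, mean)
  cm_rt <- tapply(s$rt_ms, s$epsilon, mean)
  list(trial = one(u, s$rt_ms),
       condition = one(as.vector(cm_u), as.vector(cm_rt)))
}

#' Normalised second-trial response times of coupled pairs
#'
#' Summarises the sequential effect in coupled pairs: mean second-trial
#' response time per second-trial evidence level, split by the outcome of
#' the first trial, feature-scaled over the condition means.
#'
#' @param pairs result of [run_coupled_pairs()].
#' @return data frame with `epsilon`, `first_outcome`, `n`, `mean_rt`,
#'   `norm_rt`.
#' @export
coupled_rt_summary <- function(pairs) {
  s2 <- pairs$second$summary
  s2 <- s2[!s2$indecision & !is.na(s2$rt_ms) & !is.na(s2$first_correct), ]
  out <- expand.grid(epsilon = sort(unique(s2$epsilon)),
                     first_outcome = c("correct", "error"),
                     stringsAsFactors = FALSE)
  out$n <- NA_integer_; out$mean_rt <- NA_real_
  for (i in seq_len(nrow(out))) {
    k <- s2$epsilon == out$epsilon[i] &
      (s2$first_correct == (out$first_outcome[i] == "correct"))
    out$n[i] <- sum(k)
    if (any(k)) out$mean_rt[i] <- mean(s2$rt_ms[k])
  }
  ok <- is.finite(out$mean_rt)
  out$norm_rt <- NA_real_
  if (sum(ok) >= 2) out$norm_rt[ok] <- normalize_feature(out$mean_rt[ok])
  out
}
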