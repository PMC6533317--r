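#' Right-hand side of the reduced sensorimotor subsystem
#'
#' Deterministic, noise-free dynamics of the two slow synaptic gating
#' variables under constant inputs, with the uncertainty feedback term
#' replaced by a constant current `I_fb` (the bifurcation parameter of the
#' stability analysis):
#' \deqn{\dot S_i = -S_i/\tau_s + (1 - S_i)\,\gamma\,H(x_i)}
#' with `x_i = J_N_self S_i - J_N_cross S_j + I0 + I_i + I_fb` and stimulus
#' currents at evidence quality `epsilon` (signed: positive favours
#' population 1).
#'
#' @param S1,S2 gating variables in \[0, 1\].
#' @param epsilon signed evidence quality in percent (population 1
#'   preferred when positive).
#' @param I_fb constant excitatory feedback current (nA).
#' @param params a [model_parameters()] object.
#' @param stimulus_on logical; include the stimulus currents (default
#'   `TRUE`, as in the within-trial analysis).
#' @return numeric vector `c(dS1, dS2)` in units of 1/s.
#' @export
reduced_rhs <- function(S1, S2, epsilon = 0, I_fb = 0, params,
                        stimulus_on = TRUE) {
  Iext <- if (stimulus_on)
    params$J_A_ext * params$mu0 * c(1 + epsilon / 100, 1 - epsilon / 100)
  else c(0, 0)
  x1 <- params$J_N_self * S1 - params$J_N_cross * S2 + params$I0 +
    Iext[1] + I_fb
  x2 <- params$J_N_self * S2 - params$J_N_cross * S1 + params$I0 +
    Iext[2] + I_fb
  tau_sec <- params$tau_s / 1000
  c(dS1 = -S1 / tau_sec + (1 - S1) * params$gamma *
      transfer_H(x1, params),
    dS2 = -S2 / tau_sec + (1 - S2) * params$gamma *
      transfer_H(x2, params))
}

# vectorised residual field over grids (used by nullclines and the
# brute-force oracle); returns list of dS1, dS2 matrices
rhs_field <- function(S1, S2, epsilon, I_fb, params, stimulus_on = TRUE) {
  G <- expand.grid(S1 = S1, S2 = S2)
  Iext <- if (stimulus_on)
    params$J_A_ext * params$mu0 * c(1 + epsilon / 100, 1 - epsilon / 100)
  else c(0, 0)
  x1 <- params$J_N_self * G$S1 - params$J_N_cross * G$S2 + params$I0 +
    Iext[1] + I_fb
  x2 <- params$J_N_self * G$S2 - params$J_N_cross * G$S1 + params$I0 +
    Iext[2] + I_fb
  H1 <- transfer_H(x1, params)
  H2 <- transfer_H(x2, params)
  tau_sec <- params$tau_s / 1000
  list(dS1 = matrix(-G$S1 / tau_sec + (1 - G$S1) * params$gamma * H1,
                    length(S1), length(S2)),
       dS2 = matrix(-G$S2 / tau_sec + (1 - G$S2) * params$gamma * H2,
                    length(S1), length(S2)))
}

#' Nullclines of the reduced sensorimotor subsystem
#'
#' For each grid value of one gating variable, finds all roots of the
#' other variable's time derivative by sign-change bracketing followed by
#' root polishing, yielding the two nullcline curves whose intersections
#' are the steady states.
#'
#' @inheritParams reduced_rhs
#' @param resolution grid points per axis (>= 50).
#' @return list with data frames `S1_nullcline` (points where dS1/dt = 0)
#'   and `S2_nullcline` (dS2/dt = 0), each with columns `S1`, `S2`.
#' @export
nullclines <- function(epsilon = 0, I_fb = 0, params, resolution = 201,
                       stimulus_on = TRUE) {
  stopifnot(resolution >= 50)
  g <- seq(0, 1, length.out = resolution)
  fld <- rhs_field(g, g, epsilon, I_fb, params, stimulus_on)
  roots_along <- function(M, fixed_is_S2) {
    # M[i, j] = derivative at (S1 = g[i], S2 = g[j]); scan along the
    # varying coordinate for sign changes, then polish each bracket
    pts <- list()
    n <- length(g)
    for (j in seq_len(n)) {
      v <- g[j]
      fv <- if (fixed_is_S2) M[, j] else M[j, ]
      f <- if (fixed_is_S2)
        function(s) reduced_rhs(s, v, epsilon, I_fb, params,
                                stimulus_on)[1]
      else
        function(s) reduced_rhs(v, s, epsilon, I_fb, params,
                                stimulus_on)[2]
      sc <- which(fv[-1] * fv[-n] <= 0 & is.finite(fv[-1]))
      for (k in sc) {
        if (fv[k] == 0 && k > 1 && fv[k - 1] == 0) next
        r <- stats::uniroot(f, c(g[k], g[k + 1]), tol = 1e-12)$root
        pts[[length(pts) + 1]] <- if (fixed_is_S2) c(r, v) else c(v, r)
      }
    }
    if (!length(pts)) return(data.frame(S1 = numeric(), S2 = numeric()))
    m <- do.call(rbind, pts)
    data.frame(S1 = m[, 1], S2 = m[, 2])
  }
  list(S1_nullcline = roots_along(fld$dS1, TRUE),
       S2_nullcline = roots_along(fld$dS2, FALSE))
}

# derivative of the transfer function w.r.t. its current argument (Hz/nA)
transfer_H_prime <- function(x, params) {
  z <- params$a * x - params$b
  u <- params$d * z
  E <- exp(-u)
  out <- (1 - E - params$d * z * E) / (1 - E)^2
  near <- abs(u) < 1e-4
  out[near] <- 0.5 + u[near] / 6
  out[u > 30] <- 1
  out[u < -30] <- 0
  params$a * out
}

# analytic Jacobian of the reduced system (per second)
reduced_jacobian <- function(S1, S2, epsilon, I_fb, params,
                             stimulus_on = TRUE) {
  Iext <- if (stimulus_on)
    params$J_A_ext * params$mu0 * c(1 + epsilon / 100, 1 - epsilon / 100)
  else c(0, 0)
  x1 <- params$J_N_self * S1 - params$J_N_cross * S2 + params$I0 +
    Iext[1] + I_fb
  x2 <- params$J_N_self * S2 - params$J_N_cross * S1 + params$I0 +
    Iext[2] + I_fb
  H1 <- transfer_H(x1, params); H2 <- transfer_H(x2, params)
  dH1 <- transfer_H_prime(x1, params); dH2 <- transfer_H_prime(x2, params)
  tau_sec <- params$tau_s / 1000
  g <- params$gamma
  matrix(c(
    -1 / tau_sec - g * H1 + (1 - S1) * g * dH1 * params$J_N_self,
    -(1 - S2) * g * dH2 * params$J_N_cross,
    -(1 - S1) * g * dH1 * params$J_N_cross,
    -1 / tau_sec - g * H2 + (1 - S2) * g * dH2 * params$J_N_self),
    2, 2)
}

#' Locate the fixed points of the reduced sensorimotor subsystem
#'
#' Dense multi-start Newton root search over the unit square with
#' deduplication; each converged root is classified by the eigenvalues of
#' the numerically differentiated Jacobian and labelled: choice attractors
#' (stable, one population dominant), saddle, or the choice-neutral
#' attractor (stable with `|S1 - S2| <` `neutral_tol`).
#'
#' @inheritParams reduced_rhs
#' @param n_starts starts per axis for the multi-start grid.
#' @param neutral_tol diagonal distance below which a stable point is
#'   labelled choice-neutral.
#' @return data frame of class `fixed_points` with columns `S1`, `S2`,
#'   `H1`, `H2`, `eig1`, `eig2` (real parts), `stability`
#'   (stable-node/stable-focus/saddle/unstable) and `label`.
#' @export
find_fixed_points <- function(epsilon = 0, I_fb = 0, params,
                              n_starts = 17, neutral_tol = 0.05,
                              stimulus_on = TRUE) {
  f <- function(s) reduced_rhs(s[1], s[2], epsilon, I_fb, params,
                               stimulus_on)
  starts <- as.matrix(expand.grid(
    seq(0.005, 0.995, length.out = n_starts),
    seq(0.005, 0.995, length.out = n_starts)))
  sols <- list()
  for (i in seq_len(nrow(starts))) {
    s <- starts[i, ]
    ok <- FALSE
    for (it in 1:80) {
      Fv <- f(s)
      if (max(abs(Fv)) < 1e-11) { ok <- TRUE; break }
      J <- reduced_jacobian(s[1], s[2], epsilon, I_fb, params, stimulus_on)
      step <- tryCatch(solve(J, Fv), error = function(e) NULL)
      if (is.null(step) || !all(is.finite(step))) break
      # damped step, kept near the unit square
      if (max(abs(step)) > 0.25) step <- step * 0.25 / max(abs(step))
      s <- s - step
      if (any(!is.finite(s)) || any(s < -0.2) || any(s > 1.2)) break
    }
    if (ok && all(s >= -1e-9) && all(s <= 1 + 1e-9))
      sols[[length(sols) + 1]] <- pmin(pmax(s, 0), 1)
  }
  if (!length(sols))
    return(structure(data.frame(S1 = numeric(), S2 = numeric(),
                                H1 = numeric(), H2 = numeric(),
                                eig1 = numeric(), eig2 = numeric(),
                                stability = character(),
                                label = character()),
                     class = c("fixed_points", "data.frame")))
  m <- do.call(rbind, sols)
  keep <- rep(TRUE, nrow(m))
  for (i in seq_len(nrow(m)))
    if (keep[i] && i < nrow(m))
      for (j in (i + 1):nrow(m))
        if (keep[j] && max(abs(m[i, ] - m[j, ])) < 1e-6) keep[j] <- FALSE
  m <- m[keep, , drop = FALSE]
  out <- lapply(seq_len(nrow(m)), function(i) {
    S1 <- m[i, 1]; S2 <- m[i, 2]
    J <- reduced_jacobian(S1, S2, epsilon, I_fb, params, stimulus_on)
    ev <- eigen(J, only.values = TRUE)$values
    re <- Re(ev)
    stab <- if (all(re < 0)) {
      if (is.complex(ev) && any(Im(ev) != 0)) "stable-focus" else
        "stable-node"
    } else if (prod(re) < 0 && all(Im(ev) == 0)) "saddle" else "unstable"
    lab <- if (startsWith(stab, "stable")) {
      if (abs(S1 - S2) < neutral_tol) "choice-neutral attractor"
      else if (S1 > S2) "choice-1 attractor" else "choice-2 attractor"
    } else if (stab == "saddle") "saddle" else "other"
    Iext <- if (stimulus_on)
      params$J_A_ext * params$mu0 * c(1 + epsilon / 100,
                                      1 - epsilon / 100) else c(0, 0)
    x1 <- params$J_N_self * S1 - params$J_N_cross * S2 + params$I0 +
      Iext[1] + I_fb
    x2 <- params$J_N_self * S2 - params$J_N_cross * S1 + params$I0 +
      Iext[2] + I_fb
    data.frame(S1 = S1, S2 = S2, H1 = transfer_H(x1, params),
               H2 = transfer_H(x2, params), eig1 = re[1], eig2 = re[2],
               stability = stab, label = lab, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$S1 - out$S2), ]
  rownames(out) <- NULL
  structure(out, class = c("fixed_points", "data.frame"))
}

n_stable <- function(fps) sum(startsWith(fps$stability, "stable"))

#' Bifurcation scan over the uncertainty feedback current
#'
#' Locates the fixed points of the reduced subsystem on a grid of constant
#' feedback currents and refines every change of the fixed-point count by
#' bisection, giving the critical currents (saddle-node points) of the
#' winner-take-all to choice-neutral transition.
#'
#' @inheritParams find_fixed_points
#' @param I_fb_range length-2 numeric range of feedback currents (nA).
#' @param n_steps grid size of the scan.
#' @param tol bisection tolerance on the critical currents (nA).
#' @return object of class `bifurcation_diagram`: list with `branches`
#'   (data frame of fixed points per scanned current, including `S1` and
#'   the corresponding rate `H1`), `counts`, and `critical_currents`.
#' @export
bifurcation_scan <- function(epsilon = 0, I_fb_range = c(0, 0.06), params,
                             n_steps = 41, tol = 1e-4, n_starts = 17,
                             stimulus_on = TRUE) {
  stopifnot(length(I_fb_range) == 2, diff(I_fb_range) != 0)
  grid <- seq(I_fb_range[1], I_fb_range[2], length.out = n_steps)
  fps <- lapply(grid, function(I)
    find_fixed_points(epsilon, I, params, n_starts = n_starts,
                      stimulus_on = stimulus_on))
  counts <- vapply(fps, nrow, 0L)
  branches <- do.call(rbind, lapply(seq_along(grid), function(i)
    cbind(I_fb = grid[i], fps[[i]])))
  crit <- numeric()
  count_at <- function(I) nrow(find_fixed_points(epsilon, I, params,
                                                 n_starts = n_starts,
                                                 stimulus_on = stimulus_on))
  for (i in seq_len(length(grid) - 1)) {
    if (counts[i] != counts[i + 1]) {
      lo <- grid[i]; hi <- grid[i + 1]
      c_lo <- counts[i]
      while (hi - lo > tol) {
        mid <- (lo + hi) / 2
        if (count_at(mid) == c_lo) lo <- mid else hi <- mid
      }
      crit <- c(crit, (lo + hi) / 2)
    }
  }
  structure(list(branches = branches, I_fb = grid, counts = counts,
                 critical_currents = crit, epsilon = epsilon),
            class = "bifurcation_diagram")
}

#' @export
print.bifurcation_diagram <- function(x, ...) {
  cat("<bifurcation_diagram> epsilon =", x$epsilon, "; scan over [",
      min(x$I_fb), ",", max(x$I_fb), "] nA\n")
  cat("  fixed-point counts:", paste(rle(x$counts)$values,
                                     collapse = " -> "), "\n")
  if (length(x$critical_currents))
    cat("  critical current(s):",
        paste(sprintf("%.4f", x$critical_currents), collapse = ", "),
        "nA\n")
  invisible(x)
}

#' Critical uncertainty feedback current
#'
#' The smallest constant feedback current at which the two choice
#' attractors of the reduced subsystem have vanished, leaving a single
#' (choice-neutral) stable steady state, located by bisection on the
#' number of stable fixed points.
#'
#' @inheritParams find_fixed_points
#' @param upper upper bound of the search interval (nA).
#' @param tol bisection tolerance (nA).
#' @return critical current in nA.
#' @export
critical_feedback_current <- function(params, epsilon = 0, upper = 0.1,
                                      tol = 1e-5, stimulus_on = TRUE) {
  multi <- function(I) n_stable(find_fixed_points(epsilon, I, params,
                                                  stimulus_on =
                                                    stimulus_on)) >= 2
  if (!multi(0))
    stop("no winner-take-all regime at I_fb = 0 with these parameters")
  if (multi(upper))
    stop("still multistable at I_fb = ", upper,
         "; increase the search bound")
  lo <- 0; hi <- upper
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (multi(mid)) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Deterministic trajectory of the reduced subsystem
#'
#' Integrates the noise-free 2-D system from a given initial condition
#' (forward Euler), e.g. for basin-of-attraction maps and phase-plane
#' overlays.
#'
#' @inheritParams reduced_rhs
#' @param S0 initial state `c(S1, S2)`.
#' @param t_max duration (ms).
#' @param dt step (ms).
#' @return matrix with columns `time`, `S1`, `S2`.
#' @export
reduced_trajectory <- function(S0, epsilon = 0, I_fb = 0, params,
                               t_max = 3000, dt = 0.5,
                               stimulus_on = TRUE) {
  n <- floor(t_max / dt)
  out <- matrix(NA_real_, n + 1, 3,
                dimnames = list(NULL, c("time", "S1", "S2")))
  s <- S0
  for (i in 0:n) {
    out[i + 1, ] <- c(i * dt, s)
    ds <- reduced_rhs(s[1], s[2], epsilon, I_fb, params, stimulus_on)
    s <- s + dt * ds / 1000   # rhs is per second, dt in ms
  }
  out
}
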