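# shared helpers: small parameter profiles and hand-built trial records

params_default <- model_parameters()
params_nonoise <- model_parameters(sigma_noise = 0)

# a minimal synthetic trial record for analysis-level tests
fake_record <- function(time, x, final_choice, correct_side,
                        rt = 100, indecision = FALSE, y_U = NULL) {
  structure(list(
    time = time, x = x,
    y_U = if (is.null(y_U)) rep(0, length(time)) else y_U,
    rt = rt, initial_choice = 1L, final_choice = final_choice,
    indecision = indecision, com = NA, com_direction = NA,
    uncertainty_peak = NA, uncertainty_area = NA,
    epsilon = 6.4, correct_side = correct_side,
    t_stimulus_onset = 0, t_end = max(time), dt = diff(time[1:2]),
    seed = NULL, mu_eff = 0
  ), class = "trial_record")
}

# brute-force residual-grid oracle for fixed points: cells of an n x n grid
# where both dS1/dt and dS2/dt change sign across the cell's four corners
grid_oracle_cells <- function(epsilon, I_fb, params, n = 500) {
  g <- seq(0, 1, length.out = n)
  f <- mindchange:::rhs_field(g, g, epsilon, I_fb, params)
  corners <- function(M) list(M[-n, -n], M[-1, -n], M[-n, -1], M[-1, -1])
  spans_zero <- function(M) {
    cs <- corners(M)
    lo <- pmin(cs[[1]], cs[[2]], cs[[3]], cs[[4]])
    hi <- pmax(cs[[1]], cs[[2]], cs[[3]], cs[[4]])
    lo < 0 & hi > 0
  }
  hit <- which(spans_zero(f$dS1) & spans_zero(f$dS2), arr.ind = TRUE)
  if (!nrow(hit)) return(NULL)
  # merge 8-connected flagged cells: where the nullclines cross at a
  # shallow angle (the saddle on the diagonal) neighbouring cells are
  # flagged too; each connected component holds one fixed point
  comp <- seq_len(nrow(hit))
  repeat {
    changed <- FALSE
    for (a in seq_len(nrow(hit)))
      for (b in seq_len(nrow(hit)))
        if (comp[b] != comp[a] &&
            abs(hit[a, 1] - hit[b, 1]) <= 1 &&
            abs(hit[a, 2] - hit[b, 2]) <= 1) {
          comp[comp == comp[b]] <- comp[a]
          changed <- TRUE
        }
    if (!changed) break
  }
  out <- NULL
  for (cc in unique(comp)) {
    k <- comp == cc
    out <- rbind(out, c(S1_lo = g[min(hit[k, 1])],
                        S1_hi = g[max(hit[k, 1]) + 1],
                        S2_lo = g[min(hit[k, 2])],
                        S2_hi = g[max(hit[k, 2]) + 1]))
  }
  out
}
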