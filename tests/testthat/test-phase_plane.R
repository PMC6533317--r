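p <- params_default

test_that("reduced dynamics are exchange-symmetric at zero evidence", {
  for (Ifb in c(0, 0.02, 0.05)) {
    d <- reduced_rhs(0.3, 0.3, 0, Ifb, p)
    expect_equal(unname(d[1]), unname(d[2]))
    d1 <- reduced_rhs(0.2, 0.6, 0, Ifb, p)
    d2 <- reduced_rhs(0.6, 0.2, 0, Ifb, p)
    expect_equal(unname(d1), unname(rev(d2)))
  }
  # a common feedback current raises both drives equally
  d0 <- reduced_rhs(0.2, 0.6, 0, 0, p)
  dI <- reduced_rhs(0.2, 0.6, 0, 0.01, p)
  expect_true(all(dI >= d0))
})

test_that("winner-take-all regime has two choice attractors and a saddle", {
  fps <- find_fixed_points(0, 0, p)
  expect_equal(nrow(fps), 3)
  expect_setequal(fps$label, c("choice-1 attractor", "choice-2 attractor",
                               "saddle"))
  # residual contract
  for (i in seq_len(nrow(fps))) {
    res <- reduced_rhs(fps$S1[i], fps$S2[i], 0, 0, p)
    expect_lt(max(abs(res)), 1e-10)
  }
  # symmetric pairing at zero evidence
  a1 <- fps[fps$label == "choice-1 attractor", ]
  a2 <- fps[fps$label == "choice-2 attractor", ]
  expect_equal(a1$S1, a2$S2, tolerance = 1e-8)
  expect_equal(a1$S2, a2$S1, tolerance = 1e-8)
  sd <- fps[fps$label == "saddle", ]
  expect_equal(sd$S1, sd$S2, tolerance = 1e-8)
})

test_that("large feedback current leaves one choice-neutral stable state", {
  fps <- find_fixed_points(0, 0.04, p)
  expect_equal(nrow(fps), 1)
  expect_equal(fps$label, "choice-neutral attractor")
  expect_true(startsWith(fps$stability, "stable"))
})

test_that("fixed points agree with the brute-force residual-grid oracle", {
  for (Ifb in c(0, 0.04)) {
    fps <- find_fixed_points(0, Ifb, p)
    cells <- grid_oracle_cells(0, Ifb, p, n = 500)
    expect_equal(nrow(fps), nrow(cells))
    # each reported point falls in exactly one sign-change cell
    hits <- 0
    for (i in seq_len(nrow(fps))) {
      inside <- fps$S1[i] >= cells[, "S1_lo"] - 1e-9 &
        fps$S1[i] <= cells[, "S1_hi"] + 1e-9 &
        fps$S2[i] >= cells[, "S2_lo"] - 1e-9 &
        fps$S2[i] <= cells[, "S2_hi"] + 1e-9
      hits <- hits + sum(inside)
    }
    expect_equal(hits, nrow(fps))
  }
})

test_that("nullclines are root-accurate, mirror-symmetric, and meet at the
          fixed points", {
  nc <- nullclines(0, 0, p, resolution = 101)
  for (i in seq_len(nrow(nc$S1_nullcline))) {
    d <- reduced_rhs(nc$S1_nullcline$S1[i], nc$S1_nullcline$S2[i], 0, 0, p)
    expect_lt(abs(d[1]), 1e-9)
  }
  # mirror symmetry across the diagonal at zero evidence
  m1 <- nc$S1_nullcline[order(nc$S1_nullcline$S2, nc$S1_nullcline$S1), ]
  m2 <- nc$S2_nullcline[order(nc$S2_nullcline$S1, nc$S2_nullcline$S2), ]
  expect_equal(m1$S1, m2$S2, tolerance = 1e-8)
  expect_equal(m1$S2, m2$S1, tolerance = 1e-8)
  # cross-validation: nullcline intersections reproduce the fixed points
  fps <- find_fixed_points(0, 0, p)
  dmat <- outer(seq_len(nrow(fps)), seq_len(nrow(m1)), function(i, j)
    sqrt((fps$S1[i] - m1$S1[j])^2 + (fps$S2[i] - m1$S2[j])^2))
  expect_lt(max(apply(dmat, 1, min)), 0.02)
})

test_that("bifurcation scan finds the winner-take-all collapse", {
  bd <- bifurcation_scan(0, c(0, 0.05), p, n_steps = 21, tol = 1e-4)
  expect_equal(bd$counts[1], 3L)
  expect_equal(bd$counts[length(bd$counts)], 1L)
  expect_true(length(bd$critical_currents) >= 1)
  # the scan is stateless: a reversed range yields the same branches
  bd_rev <- bifurcation_scan(0, c(0.05, 0), p, n_steps = 21, tol = 1e-4)
  expect_equal(sort(bd_rev$counts), sort(bd$counts))
  expect_equal(sort(bd_rev$branches$S1), sort(bd$branches$S1),
               tolerance = 1e-8)
  # the refined critical current matches the dedicated bisection search
  crit <- critical_feedback_current(p, tol = 1e-5)
  expect_lt(min(abs(bd$critical_currents - crit)), 5e-4)
})

test_that("raising evidence quality shrinks the error attractor basin", {
  starts <- expand.grid(S1 = seq(0.08, 0.92, length.out = 5),
                        S2 = seq(0.08, 0.92, length.out = 5))
  basin_error <- function(eps) {
    n_err <- 0
    for (i in seq_len(nrow(starts))) {
      tr <- reduced_trajectory(c(starts$S1[i], starts$S2[i]), eps, 0, p,
                               t_max = 2500, dt = 2)
      fin <- tr[nrow(tr), ]
      # population 1 is preferred for eps > 0; S2 dominance is the error
      if (fin["S2"] > fin["S1"]) n_err <- n_err + 1
    }
    n_err
  }
  expect_gt(basin_error(3.2), basin_error(25.6))
})
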