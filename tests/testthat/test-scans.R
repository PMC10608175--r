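p <- default_parameter_set()

test_that("energy_profile constructor validates input", {
  expect_error(energy_profile("Q", 1:3, 1:3))
  expect_error(energy_profile("L", c(1, 3, 2), 1:3))
  expect_error(energy_profile("L", 1:3, 1:2))
  pr <- energy_profile("L", 1:3, c(2, 1, 2), reference = 5)
  expect_s3_class(pr, "energy_profile")
  df <- as.data.frame(pr)
  expect_named(df, c("L", "energy"))
  expect_output(print(pr), "energy_profile")
})

test_that("line tension scan finds two symmetric off-center minima", {
  lt <- line_tension_vs_shift(seq(-4, 4, by = 0.25), p)
  ext <- lt$extrema
  expect_equal(nrow(ext), 2)
  pos <- sort(ext$position)
  # leaflet-swap symmetry: minima at +/- the same shift, equal depth
  expect_equal(pos[1], -pos[2], tolerance = 1e-3)
  expect_equal(ext$value[1], ext$value[2], tolerance = 1e-6)
  expect_gt(pos[2], 1.5)
  # the registered state L = 0 is a local maximum between them
  e0 <- lt$energy[lt$grid == 0]
  expect_gt(e0, max(ext$value))
})

test_that("peptide-domain profile has a boundary well and an Lo plateau", {
  pp <- peptide_domain_profile(2.3, X_grid = seq(-6, 9, by = 0.2), params = p)
  d <- pp$details
  expect_gt(d$well_depth, 0)
  # the well sits at the boundary region, not deep in either phase
  expect_gt(d$well_X, 0)
  expect_lt(d$well_X, 2.3 + p$peptide$delta_L)
  # crossing barrier on the ordered side of the well
  expect_lt(d$barrier_X, d$well_X)
  expect_gt(d$crossing_barrier, 0)
  # the tension mode gives the peptide-boundary interaction a ~20 nm decay
  # length, so the true far fields sit at |X| ~ 40 nm, not at the grid ends
  far <- function(X) solve_equilibrium(single_boundary(
    2.3, p, peptide_X = X))$energy - pp$reference
  # far in the disordered phase the reference is recovered
  expect_lt(abs(far(40)), 5e-3)
  # deep in the ordered phase the profile plateaus at the Lo-Ld peptide
  # transfer energy difference
  # transfer energy difference (absolute tolerance: the residual capillary
  # tail at 40 nm is ~1e-3 kBT/nm)
  eLo <- solve_equilibrium(peptide_in_phase("ordered", p))$energy
  eLd <- solve_equilibrium(peptide_in_phase("disordered", p))$energy
  expect_lt(abs(far(-40) - (eLo - eLd)), 5e-3)
})

test_that("joint minimum respects its branch and beats the decoupled optima", {
  jm <- joint_minimum_peptide_shift(p, "positive")
  expect_gte(jm$L, 0)
  e_sep <- solve_equilibrium(single_boundary(jm$L, p))$energy +
    solve_equilibrium(peptide_in_phase("disordered", p))$energy
  expect_lt(jm$energy, e_sep)
  jn <- joint_minimum_peptide_shift(p, "negative")
  expect_lte(jn$L, 0)
})

test_that("basin-restricted line search does not hop over a maximum", {
  # double well: global minimum at x = -1, local at x = +1, maximum at 0
  g <- function(x) (x^2 - 1)^2 + 0.2 * x
  r <- memelastic:::.local_line_min(g, 0.8, -2, 2)
  expect_equal(r$x, stats::optimize(g, c(0.2, 2))$minimum, tolerance = 1e-3)
  expect_gt(r$x, 0)   # stayed in the starting basin
  r2 <- memelastic:::.local_line_min(g, -0.8, -2, 2)
  expect_lt(r2$x, 0)
})

test_that("fusion_barrier edge cases", {
  # monotone decreasing toward contact: no barrier
  pr <- energy_profile("D", seq(1, 15, 0.5), -exp(-seq(1, 15, 0.5)))
  expect_equal(fusion_barrier(pr)$barrier, 0)
  # missing far-field plateau is an error, not silently accepted
  pr2 <- energy_profile("D", seq(1, 15, 0.5), rep(0.1, 29))
  expect_error(fusion_barrier(pr2), "plateau")
  # parabolic hump: refinement recovers the exact off-grid apex
  x <- seq(0.5, 15, 0.5)
  y <- pmax(0, 0.25 - 0.1 * (x - 3.2)^2)
  fb <- fusion_barrier(energy_profile("D", x, y))
  expect_equal(fb$barrier, 0.25, tolerance = 1e-6)
  expect_equal(fb$D_barrier, 3.2, tolerance = 1e-3)
})

test_that("no-peptide interaction profile is smooth and plateaus at large D", {
  tp <- boundary_topologies(0)[1, ]
  Dg <- c(seq(0.5, 8, by = 0.5), seq(9, 15, by = 1), seq(17, 40, by = 3))
  pr <- interaction_profile(tp, p, D_grid = Dg)
  expect_false(pr$details$truncated)
  # adiabatic tracking: no basin hops; the slope near contact is steep but
  # finite, so neighbouring samples stay close
  expect_lt(max(abs(diff(pr$energy))), 0.12)
  expect_lt(abs(pr$energy[length(pr$energy)]), 5e-3)
  fb <- fusion_barrier(pr)
  expect_gt(fb$barrier, 0)
  expect_lt(fb$barrier, 0.2)
})
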