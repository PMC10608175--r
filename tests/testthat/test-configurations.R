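p <- default_parameter_set()

test_that("director jump formula", {
  expect_equal(director_jump(1.3, 1.3), sqrt(2), tolerance = 1e-12)
  expect_equal(director_jump(1.3, 1.8), 1.3 / sqrt(0.65^2 + 0.9^2))
  expect_equal(director_jump(0, 1.3), 0)
})

test_that("mixed jump is a convex combination with validated delta", {
  js <- director_jump(1.3, 1.3); jd <- director_jump(1.3, 1.8)
  expect_equal(mixed_director_jump(1, js, jd), js)
  expect_equal(mixed_director_jump(0, js, jd), jd)
  expect_equal(mixed_director_jump(0.5, js, jd), (js + jd) / 2)
  expect_equal(mixed_director_jump(0.5, js, jd), 1.293, tolerance = 1e-3)
  expect_error(mixed_director_jump(1.2, js, jd), "delta")
  expect_error(mixed_director_jump(-0.1, js, jd), "delta")
})

test_that("strip delta is computed geometrically from the Ld overlap", {
  # boundary at L = 0 (upper edge at 0, ordered toward -x);
  # strip [X-1.3, X] entirely in Ld for X >= 1.3
  cfg <- single_boundary(0, p, peptide_X = 2)
  expect_equal(cfg$strips$delta, 1)
  # 30% of the strip in Ld
  X <- 0.3 * 1.3
  cfg <- single_boundary(0, p, peptide_X = X)
  expect_equal(cfg$strips$delta, 0.3, tolerance = 1e-9)
  # fully inside the ordered phase
  cfg <- single_boundary(0, p, peptide_X = -2)
  expect_equal(cfg$strips$delta, 0)
})

test_that("solved energy is continuous in the peptide position across the edge", {
  E <- function(X) solve_equilibrium(single_boundary(2.3, p, peptide_X = X))$energy
  for (X0 in c(2.3, 2.3 + 1.3)) {   # strip right edge / left edge at the phase edge
    de <- abs(E(X0 + 5e-4) - E(X0 - 5e-4))
    expect_lt(de, 5e-3)
  }
})

test_that("configuration validation errors", {
  expect_error(single_boundary(1, p, peptide_X = c(0, 1)), "overlapping")
  expect_error(domain_pair(-1, params = p), "D must be")
  expect_error(
    membrane_configuration(upper_lo = matrix(c(-Inf, 0), 1),
                           lower_lo = matrix(numeric(0), 0, 2), params = p),
    "infinity")
})

test_that("misregistered width bookkeeping", {
  expect_equal(single_boundary(2.3, p)$misreg_width, 2.3)
  expect_equal(single_boundary(-1.7, p)$misreg_width, 1.7)
  expect_equal(single_boundary(0, p)$misreg_width, 0)
  # domain pair: both shifts contribute, independent of D
  expect_equal(domain_pair(5, 2, 1.5, params = p)$misreg_width, 3.5)
  expect_equal(domain_pair(2, 2, 1.5, params = p)$misreg_width, 3.5)
  # strips are not charged: a peptide covering part of the strip reduces it
  cfg <- single_boundary(2.3, p, peptide_X = 2)
  expect_lt(cfg$misreg_width, 2.3)
})

test_that("topology enumeration: 4, 4 and 3 distinct configurations", {
  expect_equal(nrow(boundary_topologies(0)), 4)
  expect_equal(nrow(boundary_topologies(1)), 4)
  expect_equal(nrow(boundary_topologies(2)), 3)
  expect_error(boundary_topologies(3))
})

test_that("no-peptide domain pair: mirror-class topologies coincide exactly", {
  # z-mirror identity: both-upper == both-lower at the same nearest-edge D
  E <- function(l1, l2, D = 3)
    solve_equilibrium(domain_pair(D, l1, l2, params = p))$energy
  expect_equal(E(2.3, 2.3), E(-2.3, -2.3), tolerance = 1e-10)
  # x-mirror: mixed pair and its reflection
  expect_equal(E(2.3, -2.3), E(-2.3, 2.3), tolerance = 1e-10)
  # cross-class difference is physical but tiny
  expect_lt(abs(E(2.3, 2.3) - E(2.3, -2.3)), 5e-3)
})

test_that("domain pair converges to two isolated boundaries as D grows", {
  e_iso <- solve_equilibrium(single_boundary(2.3, p))$energy
  e_pair <- solve_equilibrium(domain_pair(40, 2.3, 2.3, params = p))$energy
  expect_equal(e_pair, 2 * e_iso, tolerance = 1e-4)
})
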