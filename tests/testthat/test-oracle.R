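# Dual-route validation: the analytic-basis production solver against the
# independent finite-difference variational discretization.

p <- default_parameter_set()

test_that("FD oracle reproduces boundary energies within 1 percent", {
  for (L in c(0, 1.2, 2.3, -2.3, 3.5)) {
    cfg <- single_boundary(L, p)
    ea <- solve_equilibrium(cfg)$energy
    ef <- solve_equilibrium_fd(cfg, h = 0.02, halfwidth = 25)$energy
    expect_lt(abs(ef - ea) / max(abs(ea), 1e-12), 0.01)
  }
})

test_that("FD oracle reproduces peptide energies within 1 percent", {
  # peptide-induced deformations carry a weak long-range tension tail,
  # so the truncated FD box must be wide
  cases <- list(
    peptide_in_phase("disordered", p),
    peptide_in_phase("ordered", p),
    single_boundary(2.3, p, peptide_X = 2.4)
  )
  for (cfg in cases) {
    ea <- solve_equilibrium(cfg)$energy
    ef <- solve_equilibrium_fd(cfg, h = 0.02, halfwidth = 60)$energy
    expect_lt(abs(ef - ea) / abs(ea), 0.01)
  }
})

test_that("FD oracle reproduces a domain-pair energy within 1 percent", {
  cfg <- domain_pair(3, 2.3, 2.3, params = p)
  ea <- solve_equilibrium(cfg)$energy
  ef <- solve_equilibrium_fd(cfg, h = 0.02, halfwidth = 25)$energy
  expect_lt(abs(ef - ea) / abs(ea), 0.01)
})

test_that("FD energies converge toward the analytic value as h shrinks", {
  cfg <- single_boundary(2.3, p)
  ea <- solve_equilibrium(cfg)$energy
  err <- vapply(c(0.08, 0.04, 0.02), function(h)
    abs(solve_equilibrium_fd(cfg, h = h, halfwidth = 25)$energy - ea), 0)
  expect_true(all(diff(err) < 0))
})
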