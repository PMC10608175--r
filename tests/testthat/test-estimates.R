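test_that("effective interaction length 2*sqrt(2*lambda*R)", {
  expect_equal(effective_interaction_length(1, 50), 20)
  expect_equal(effective_interaction_length(1, 5), 2 * sqrt(10))
  # monotone in both arguments
  expect_gt(effective_interaction_length(2, 50),
            effective_interaction_length(1, 50))
  expect_gt(effective_interaction_length(1, 100),
            effective_interaction_length(1, 50))
  expect_error(effective_interaction_length(0, 50))
})

test_that("boundary-saturating peptide concentration", {
  expect_equal(peptide_concentration_full_boundary(R = 5), 2 * 0.6 * 0.3 / (3.5 * 5))
  # the printed ratios: ~1/50, ~1/500, ~1/1000 at R = 5, 50, 100 nm
  expect_equal(peptide_concentration_full_boundary(R = 5), 1 / 50,
               tolerance = 0.03)
  expect_equal(peptide_concentration_full_boundary(R = 50), 1 / 500,
               tolerance = 0.03)
  expect_equal(peptide_concentration_full_boundary(R = 100), 1 / 1000,
               tolerance = 0.03)
  expect_error(peptide_concentration_full_boundary(R = 5, phi_d = 1.2))
})

test_that("absolute well depth and fusion barrier scalings", {
  expect_equal(absolute_well_depth(0.8, 3.5), 0.8 * 1.3 * 3.5)
  expect_equal(absolute_well_depth(0.8, 3.5), 3.64, tolerance = 1e-12)
  expect_equal(absolute_fusion_barrier(0.9, 1, 50), 0.9 * 20)
  expect_equal(absolute_fusion_barrier(0.08, 1, 50), 1.6)
})
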