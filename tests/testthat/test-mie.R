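test_that("Mie series vanishes without contrast and converges", {
  src <- c(16.5, 7.5)
  obs <- c(7.5, 16.5)
  e0 <- mie_cylinder_scattered_field(2.5, 10, 10, 1e9, src, obs)
  expect_lt(Mod(e0), 1e-14)

  e1 <- mie_cylinder_scattered_field(2.5, 20, 10, 1e9, src, obs, n_terms = 25)
  e2 <- mie_cylinder_scattered_field(2.5, 20, 10, 1e9, src, obs, n_terms = 35)
  expect_lt(Mod(e1 - e2) / Mod(e1), 1e-10)
})

test_that("Mie scattering matrix is reciprocal", {
  arr <- antenna_array(n_antennas = 8)
  S <- mie_smatrix(2, 14, 10, arr)
  expect_lt(max(Mod(S - t(S))) / max(Mod(S)), 1e-10)
})

test_that("a small off-calibration cylinder cross-validates MoM at one point", {
  arr <- antenna_array()
  eps <- cylinder_permittivity(108, 1.5, 13 + 0i, 10 + 0i)
  S <- solve_forward(build_contrast(eps, arr, 54), arr)$values
  e <- mie_cylinder_scattered_field(1.5, 13, 10, 1e9,
                                    c(arr$x[1], arr$y[1]),
                                    c(arr$x[10], arr$y[10]))
  expect_lt(Mod(S[10, 1] - e) / Mod(e), 0.02)
})
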