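test_that("contrast construction block-averages and normalizes correctly", {
  arr <- antenna_array()
  # uniform background -> zero contrast everywhere
  eps_bg <- matrix(10 + 0i, 108, 108)
  expect_true(all(build_contrast(eps_bg, arr, 54) == 0))
  # uniform eps = 2*eps_b -> contrast exactly 1
  expect_true(all(build_contrast(eps_bg * 2, arr, 54) == 1))
  # checkerboard of eps_b and 2*eps_b block-averaged 108 -> 54 is uniform 0.5
  idx <- outer(seq_len(108), seq_len(108), "+")
  eps_cb <- matrix(10 + 0i, 108, 108)
  eps_cb[idx %% 2 == 0] <- 20 + 0i
  chi <- build_contrast(eps_cb, arr, 54)
  expect_equal(max(Mod(chi - 0.5)), 0, tolerance = 1e-12)
  expect_error(build_contrast(eps_bg, arr, 32), "divide")
})

test_that("zero contrast yields a numerically zero scattering matrix", {
  arr <- antenna_array()
  S <- solve_forward(matrix(0 + 0i, 36, 36), arr)$values
  expect_equal(dim(S), c(30L, 30L))
  expect_true(all(Mod(S) < 1e-12))
})

test_that("scattering matrices are reciprocal and finite for phantoms", {
  arr <- antenna_array()
  ph <- generate_phantom(21, 3, with_tumor = TRUE)
  S <- solve_forward(build_contrast(ph, arr, 36), arr)$values
  expect_true(all(is.finite(Re(S)) & is.finite(Im(S))))
  expect_lt(max(Mod(S - t(S))) / max(Mod(S)), 1e-6)
})

test_that("solver is linear in the contrast in the Born limit", {
  arr <- antenna_array()
  eps <- cylinder_permittivity(108, 2, 12 + 0i, 10 + 0i)
  chi <- build_contrast(eps, arr, 36)
  # Born reference: single scattering of a vanishing contrast
  S_lin <- solve_forward(chi * 1e-6, arr)$values / 1e-6
  dev <- vapply(c(1e-1, 1e-2, 1e-3), function(alpha) {
    S <- solve_forward(chi * alpha, arr)$values
    sqrt(mean(Mod(S - alpha * S_lin)^2)) / sqrt(mean(Mod(S)^2))
  }, 1)
  expect_true(all(diff(dev) < 0))
  expect_lt(dev[3], 1e-2)
})

test_that("MoM agrees with the Mie-series oracle for a centered cylinder", {
  arr <- antenna_array()
  eps <- cylinder_permittivity(108, 2.5, 15 + 0i, 10 + 0i)
  S <- solve_forward(build_contrast(eps, arr, 54), arr)$values
  Smie <- mie_smatrix(2.5, 15, 10, arr)
  rel <- sqrt(mean(Mod(S - Smie)^2)) / sqrt(mean(Mod(Smie)^2))
  expect_lt(rel, 0.02)
})

test_that("ring-symmetry transforms permute the scattering matrix exactly", {
  # reflecting the phantom across a grid axis (or rotating it 180 degrees)
  # must give the same physics as permuting the antennas
  arr <- antenna_array()
  ph <- generate_phantom(31, 2, with_tumor = TRUE)
  eps <- ph$permittivity_map
  S <- solve_forward(build_contrast(eps, arr, 36), arr)$values
  cases <- list(flip_col = eps[, rev(seq_len(108))],
                flip_row = eps[rev(seq_len(108)), ],
                rot180 = eps[rev(seq_len(108)), rev(seq_len(108))])
  for (tr in names(cases)) {
    St <- solve_forward(build_contrast(cases[[tr]], arr, 36), arr)$values
    q <- mwiseg:::antenna_permutation(30L, tr)
    expect_lt(max(Mod(St - S[q, q])) / max(Mod(S)), 1e-10)
  }
})

test_that("padding to the network tensor is exact and invertible", {
  ones <- matrix(1 + 1i, 30, 30)
  tens <- pad_smatrix(ones)
  expect_equal(dim(tens), c(32L, 32L, 2L))
  expect_true(all(tens[2:31, 2:31, ] == 1))
  border <- tens[c(1, 32), , ] == 0 & TRUE
  expect_true(all(tens[c(1, 32), , ] == 0))
  expect_true(all(tens[, c(1, 32), ] == 0))

  set.seed(4)
  S <- matrix(complex(real = rnorm(900), imaginary = rnorm(900)), 30, 30)
  expect_identical(crop_padded(pad_smatrix(S)), S)
  # standardization rescales and the crop undoes it
  expect_equal(crop_padded(pad_smatrix(S, scale = 2.5), scale = 2.5), S)
  expect_error(pad_smatrix(matrix(0 + 0i, 30, 29)))
})
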