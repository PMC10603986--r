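test_that("phantom generation is deterministic and honors the health state", {
  p1 <- generate_phantom(1, density_class = 1, with_tumor = FALSE)
  p2 <- generate_phantom(1, density_class = 1, with_tumor = FALSE)
  expect_identical(p1, p2)
  expect_equal(sum(p1$tumor_mask), 0)

  p3 <- generate_phantom(7, density_class = 4, with_tumor = TRUE)
  expect_gt(sum(p3$tumor_mask), 0)
  expect_identical(p3, generate_phantom(7, density_class = 4, with_tumor = TRUE))
})

test_that("glandular fraction lands in the declared density band", {
  bands <- list(c(0, 0.10), c(0.10, 0.25), c(0.25, 0.50), c(0.50, 1))
  for (cls in 1:4) {
    for (seed in c(2, 7)) {
      ph <- generate_phantom(seed, cls, with_tumor = (seed == 7))
      g <- sum(ph$label_map %in% 3:4) / sum(ph$label_map >= 1)
      expect_gte(g, bands[[cls]][1])
      expect_lt(g, bands[[cls]][2])
      expect_equal(classify_density(ph$label_map), cls)
    }
  }
})

test_that("phantom structural invariants hold", {
  ph <- generate_phantom(13, 3, with_tumor = TRUE)
  lab <- ph$label_map
  expect_equal(dim(lab), c(108L, 108L))
  expect_equal(ph$pixel_size_cm, 15 / 108)
  expect_equal(round(ph$pixel_size_cm, 3), 0.139)
  expect_identical(ph$tumor_mask, lab == 5L)

  # background pixels carry exactly the background permittivity
  bg <- lab == 0L
  expect_true(all(ph$permittivity_map[bg] == 10 + 0i))
  # lossy-or-lossless convention: imaginary part never positive
  expect_true(all(Im(ph$permittivity_map) <= 0))

  # breast support is one simply connected region (no holes)
  support <- lab >= 1L
  expect_equal(n_components(support, 8), 1)
  expect_equal(n_components(!support, 4), 1)

  # support boundary is closed skin: support pixels adjacent to background
  # are all skin
  n <- nrow(lab)
  inner <- support[2:(n - 1), 2:(n - 1)]
  touches_bg <- !support[1:(n - 2), 2:(n - 1)] | !support[3:n, 2:(n - 1)] |
    !support[2:(n - 1), 1:(n - 2)] | !support[2:(n - 1), 3:n]
  edge_labels <- lab[2:(n - 1), 2:(n - 1)][inner & touches_bg]
  expect_true(all(edge_labels == 1L))
})

test_that("tumor insertion produces perturbed-ellipse components of the expected area", {
  ph <- generate_phantom(5, 2, with_tumor = FALSE)
  target_px <- pi * (0.5 / (15 / 108))^2       # ~41 px for r = 0.5 cm
  for (seed in c(1, 2, 3, 4)) {
    pt <- insert_tumors(ph, rng_seed = seed, n_tumors = 1,
                        radius_range_cm = c(0.5, 0.5))
    area <- sum(pt$tumor_mask)
    expect_gt(area, target_px * 0.5)
    expect_lt(area, target_px * 1.5)
    expect_equal(n_components(pt$tumor_mask, 8), 1)
    # locality: everything outside the tumor component is untouched
    outside <- !pt$tumor_mask
    expect_identical(pt$label_map[outside], ph$label_map[outside])
    expect_identical(pt$permittivity_map[outside], ph$permittivity_map[outside])
    # tumors never overwrite skin or background
    expect_true(all(ph$label_map[pt$tumor_mask] %in% 2:4))
  }
  pt3 <- insert_tumors(ph, rng_seed = 9, n_tumors = 3)
  ncomp <- n_components(pt3$tumor_mask, 8)
  expect_gte(ncomp, 1)
  expect_lte(ncomp, 3)
})

test_that("dielectric assignment respects the table, jitter bounds and background", {
  tab <- tissue_dielectric_table()
  lab <- matrix(0L, 20, 20)
  expect_true(all(assign_dielectrics(lab, tab, 1) == tab$permittivity[1]))

  lab[5:15, 5:15] <- 4L
  tab0 <- tab
  tab0$jitter <- 0
  eps0 <- assign_dielectrics(lab, tab0, 1)
  expect_true(all(eps0[lab == 4L] == tab$permittivity[5]))

  tab1 <- tissue_dielectric_table(jitter_fraction = 0.1)
  eps1 <- assign_dielectrics(lab, tab1, 3)
  ratio <- Mod(eps1[lab == 4L]) / Mod(tab$permittivity[5])
  expect_true(all(ratio >= 0.9 & ratio <= 1.1))
  expect_identical(assign_dielectrics(lab, tab1, 3), eps1)
  # tumor contrast above fibro-glandular by construction
  expect_gt(Re(tab$permittivity[6]), Re(tab$permittivity[5]))
})

test_that("density classification counts glandular pixels against thresholds", {
  m <- matrix(0L, 10, 10)
  m[1:5, 1:10] <- 2L
  expect_equal(classify_density(m), 1L)          # g = 0
  m2 <- matrix(4L, 10, 10)
  expect_equal(classify_density(m2), 4L)         # g = 1
  m3 <- matrix(c(rep(2L, 70), rep(4L, 30)), 10, 10)
  expect_equal(sum(m3 %in% 3:4) / sum(m3 >= 1), 0.3)
  expect_equal(classify_density(m3), 3L)         # 0.25 <= 0.3 < 0.50
  expect_error(classify_density(matrix(0L, 5, 5)), "empty")
})

test_that("dataset generation balances classes, health states and splits", {
  ds <- small_dataset()
  expect_equal(sum(ds$healthy), 40)
  expect_equal(sum(!ds$healthy), 40)
  cell <- table(ds$density_class, ds$healthy)
  expect_true(all(cell == 10))
  expect_equal(as.vector(table(ds$split)[c("train", "val", "test")]),
               c(64L, 8L, 8L))
  # healthy records have empty masks, tumorous at least one pixel
  npix <- apply(ds$tumor_mask, 3, sum)
  expect_true(all(npix[ds$healthy] == 0))
  expect_true(all(npix[!ds$healthy] >= 1))
  # determinism of the full container
  ds2 <- generate_dataset(n_profiles = 80, seed = 11, solver_grid = 27,
                          split = c(0.8, 0.1, 0.1))
  expect_identical(object_checksum(ds), object_checksum(ds2))
  expect_identical(ds$manifest, ds2$manifest)
})

test_that("infeasible balance and bad splits are rejected", {
  expect_error(generate_dataset(10, seed = 1), "divisible")
  expect_error(generate_dataset(12, healthy_fraction = 0.4, seed = 1),
               "balance")
})
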