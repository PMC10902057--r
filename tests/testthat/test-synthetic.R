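# Tissue phantom, region templates and cube simulation.

test_that("phantom labels form a valid lesioned-section geometry", {
  ph <- build_phantom(64, 64, seed = 1)
  codes <- region_codes()
  expect_setequal(unique(as.vector(ph$labels)), unname(codes))
  # ring integrity: no lesion-core pixel touches (8-adjacency) anything
  # but core or ring, so the ring fully encloses the core
  lab <- ph$labels
  core <- which(lab == codes[["lesion_core"]], arr.ind = TRUE)
  for (k in seq_len(nrow(core))) {
    r <- core[k, 1]; c <- core[k, 2]
    nb <- lab[max(1, r - 1):min(nrow(lab), r + 1),
              max(1, c - 1):min(ncol(lab), c + 1)]
    expect_true(all(nb %in% codes[c("lesion_core", "peri_lesion")]))
  }
  # all region areas > 0
  expect_true(all(table(factor(lab, levels = codes)) > 0))
})

test_that("phantom generation is deterministic and degenerates cleanly", {
  expect_identical(build_phantom(32, 32, seed = 7)$labels,
                   build_phantom(32, 32, seed = 7)$labels)
  expect_false(identical(build_phantom(32, 32, seed = 7)$labels,
                         build_phantom(32, 32, seed = 8)$labels))
  # zero lesion axes: no core, no ring
  g0 <- phantom_geometry(lesion_axes = c(0, 0), jitter = 0)
  ph0 <- build_phantom(32, 32, g0)
  codes <- region_codes()
  expect_false(any(ph0$labels %in% codes[c("peri_lesion", "lesion_core")]))
  # lesion placed outside the tissue ellipse is rejected
  bad <- phantom_geometry(lesion_center = c(0.02, 0.02),
                          lesion_axes = c(0.2, 0.2), jitter = 0)
  expect_error(build_phantom(32, 32, bad), "invalid geometry")
  expect_error(build_phantom(8, 8), "width_px")
})

test_that("templates encode the demyelination trend directions", {
  tpl <- default_region_templates()
  for (t in tpl) expect_equal(sum(t$abundance), 1, tolerance = 1e-9)
  ab <- function(region, cls) {
    t <- tpl[[region]]
    sum(t$abundance[t$class %in% cls])
  }
  # monotone class trends white matter -> peri-lesion -> core
  for (cls in c("PC", "PE", "SM")) {   # rising classes
    expect_gt(ab("lesion_core", cls), ab("peri_lesion", cls))
    expect_gt(ab("peri_lesion", cls), ab("white_matter", cls))
  }
  for (cls in c("PC-E", "ST", "PS")) { # falling classes
    expect_lt(ab("lesion_core", cls), ab("peri_lesion", cls))
    expect_lt(ab("peri_lesion", cls), ab("white_matter", cls))
  }
  # PI 38:4 rises steeply; PI is elevated in grey matter
  pi384 <- function(r) tpl[[r]]$abundance[["PI 38:4"]]
  expect_gt(pi384("lesion_core"), pi384("peri_lesion"))
  expect_gt(pi384("peri_lesion"), pi384("white_matter"))
  expect_gt(ab("grey_matter", "PI"), ab("white_matter", "PI"))
  # PE 36:5e peaks in the peri-lesion
  pe365 <- function(r) tpl[[r]]$abundance[["PE 36:5e"]]
  expect_gt(pe365("peri_lesion"), pe365("white_matter"))
  expect_gt(pe365("peri_lesion"), pe365("lesion_core"))
  # effect_scale 0 removes all between-region differences
  tpl0 <- default_region_templates(effect_scale = 0)
  for (r in names(tpl0)) {
    expect_equal(tpl0[[r]]$abundance, tpl0$white_matter$abundance,
                 tolerance = 1e-12)
  }
  # missing class is refused
  lib <- lipid_library()
  expect_error(default_region_templates(lib[lib$class != "SM", ]),
               "missing required lipid class")
})

test_that("noiseless cubes render templates exactly at the species apexes", {
  fix <- noiseless_fixture()
  cube <- fix$cube
  tpl <- fix$templates
  codes <- region_codes()
  apex_idx <- match(round(tpl$white_matter$mz, 6), round(cube$mz, 6))
  expect_false(anyNA(apex_idx))   # axis carries a point at each exact m/z
  for (r in c("white_matter", "lesion_core")) {
    p <- which(cube$truth$labels == codes[[r]])[1]
    apex <- cube$intensity[p, apex_idx]
    expect_equal(apex / sum(apex), unname(tpl[[r]]$abundance),
                 tolerance = 1e-9)
  }
  # background pixels carry no signal when baseline is zero
  bg <- which(cube$truth$labels == codes[["background"]])[1]
  expect_equal(sum(cube$intensity[bg, ]), 0)
})

test_that("cube generation is deterministic and stores its latent truth", {
  ph <- build_phantom(16, 16, mini_geometry())
  tpl <- default_region_templates()
  nm <- noise_model(drift_ppm_sd = 5, seed = 11)
  c1 <- simulate_cube(ph, tpl, nm)
  c2 <- simulate_cube(ph, tpl, nm)
  expect_identical(c1$intensity, c2$intensity)
  c3 <- simulate_cube(ph, tpl, noise_model(drift_ppm_sd = 5, seed = 12))
  expect_false(identical(c1$intensity, c3$intensity))
  # drifted apexes sit at mz * (1 + shift/1e6) within half a grid step
  codes <- region_codes()
  sigma <- nm$peak_fwhm_mz / (2 * sqrt(2 * log(2)))
  p <- which(c1$truth$labels != codes[["background"]] &
               abs(c1$truth$shift_ppm) > 2)[1]
  s <- tpl$white_matter$mz[which.max(tpl$white_matter$abundance)]
  expected_apex <- s * (1 + c1$truth$shift_ppm[p] * 1e-6)
  win <- which(abs(c1$mz - s) < 0.03)
  observed_apex <- c1$mz[win[which.max(c1$intensity[p, win])]]
  expect_lt(abs(observed_apex - expected_apex), sigma / 4)
  # species outside the window are refused by name
  expect_error(simulate_cube(ph, tpl, nm, mz_min = 750, mz_max = 1000),
               "outside the m/z window.*SM 34:1")
})

test_that("intensity noise monotonically erodes within-region correlation", {
  ph <- build_phantom(16, 16, mini_geometry())
  tpl <- default_region_templates()
  codes <- region_codes()
  wm <- which(as.vector(t(ph$labels)) == codes[["white_matter"]])
  mean_cor <- vapply(c(0.05, 0.25, 0.6), function(cv) {
    cube <- simulate_cube(ph, tpl, noise_model(intensity_cv = cv, tic_cv = 0,
                                               drift_ppm_sd = 0, seed = 5))
    fm <- reduce_cube(cube, tpl$white_matter$mz)
    mean(cor(t(fm$values[wm, ]))[upper.tri(diag(length(wm)))])
  }, numeric(1))
  expect_true(all(diff(mean_cor) < 0))
})

test_that("latent TIC factors and drifts are recoverable from the cube", {
  ph <- build_phantom(24, 24, seed = 2)
  tpl <- default_region_templates()
  cube <- simulate_cube(ph, tpl, noise_model(intensity_cv = 0.1,
                                             tic_cv = 0.3, drift_ppm_sd = 8,
                                             seed = 21))
  tissue <- which(cube$truth$labels != 0)
  al <- align_spectra(cube, max_shift_ppm = 25)
  expect_gt(cor(al$shift_ppm[tissue], cube$truth$shift_ppm[tissue]), 0.95)
  tn <- tic_normalize(al$cube)
  expect_gt(cor(tn$tic[tissue], cube$truth$tic_factor[tissue]), 0.95)
})
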