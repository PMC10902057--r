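# Alignment, TIC normalization, average spectrum, peak picking, reduction.

test_that("tic_normalize scales rows to unit sum and flags empty pixels", {
  M <- rbind(c(2, 3, 5), c(0.2, 0.3, 0.5), c(0, 0, 0))
  out <- tic_normalize(M)
  expect_equal(out$data[1, ], c(0.2, 0.3, 0.5))
  expect_equal(out$data[2, ], c(0.2, 0.3, 0.5))   # idempotent on normalized
  expect_equal(out$tic, c(10, 1, 0))
  expect_equal(out$data[3, ], c(0, 0, 0))         # zeros kept, flagged
  expect_equal(out$flagged, c(FALSE, FALSE, TRUE))
  expect_error(tic_normalize(rbind(c(-1, 2))), "negative")
})

test_that("average_spectrum is the pointwise mean over selected pixels", {
  fix <- noiseless_fixture()
  cube <- fix$cube
  # single pixel: average equals that pixel
  p <- which(rowSums(cube$intensity) > 0)[1]
  avg1 <- average_spectrum(cube, pixels = p)
  expect_equal(avg1$intensity, cube$intensity[p, ])
  # linearity: pixels with intensities x and 3x average to 2x
  cube2 <- cube
  cube2$intensity <- rbind(cube$intensity[p, ], 3 * cube$intensity[p, ])
  cube2$coords <- cube$coords[c(p, p), ]
  avg2 <- average_spectrum(cube2)
  expect_equal(avg2$intensity, 2 * cube$intensity[p, ])
  empty <- cube
  empty$intensity <- cube$intensity[0, , drop = FALSE]
  expect_error(average_spectrum(empty), "empty cube")
})

test_that("pick_peaks applies the base-peak threshold to local maxima", {
  # three local maxima of heights 1000, 6, 4: threshold 0.005 cuts at 5
  mz <- seq(700, 700.8, by = 0.01)
  y <- numeric(length(mz))
  for (h in list(c(700.2, 1000), c(700.5, 6), c(700.7, 4))) {
    y <- y + h[2] * exp(-0.5 * ((mz - h[1]) / 0.02)^2)
  }
  pl <- pick_peaks(list(mz = mz, intensity = y), 0.005, smooth = 0)
  expect_equal(length(pl$mz), 2L)
  expect_equal(pl$mz, c(700.2, 700.5), tolerance = 1e-6)
  # threshold 0 keeps every local maximum
  pl0 <- pick_peaks(list(mz = mz, intensity = y), 0, smooth = 0)
  expect_equal(length(pl0$mz), 3L)
  # lowering the threshold returns a superset
  expect_true(all(pl$mz %in% pl0$mz))
  # flat spectrum: no peaks
  flat <- pick_peaks(list(mz = mz, intensity = rep(1, length(mz))), 0.005)
  expect_equal(length(flat$mz), 0L)
})

test_that("reduce_cube takes window maxima with nearest-centre assignment", {
  fix <- noiseless_fixture()
  tpl <- fix$templates
  fm <- reduce_cube(fix$cube, tpl$white_matter$mz, tol_ppm = 5)
  codes <- region_codes()
  ord <- order(tpl$white_matter$mz)   # reduce sorts columns by m/z
  # noiseless: rows are proportional to the region template
  for (r in c("white_matter", "peri_lesion")) {
    p <- which(fix$cube$truth$labels == codes[[r]])[1]
    v <- fm$values[p, ]
    expect_equal(v / sum(v), unname(tpl[[r]]$abundance[ord]),
                 tolerance = 1e-9)
  }
  # background pixel -> all-zero row (no signal within any window)
  bg <- which(fix$cube$truth$labels == codes[["background"]])[1]
  expect_equal(sum(fm$values[bg, ]), 0)
  # widening the tolerance never decreases any entry
  fm2 <- reduce_cube(fix$cube, tpl$white_matter$mz, tol_ppm = 10)
  expect_true(all(fm2$values >= fm$values - 1e-15))
  # overlapping windows fall back to the nearest centre with a warning
  expect_warning(reduce_cube(fix$cube, c(700.00, 700.002), tol_ppm = 10),
                 "overlapping")
})

test_that("alignment recovers injected rigid ppm shifts", {
  fix <- noiseless_fixture()
  cube <- fix$cube
  tissue <- which(cube$truth$labels != 0)
  # zero drift in, zero shift out
  al0 <- align_spectra(cube, max_shift_ppm = 10)
  expect_true(all(al0$shift_ppm == 0))
  # inject +6 / -6 ppm on alternating tissue pixels by resampling
  inj <- rep(c(6, -6), length.out = length(tissue))
  cube6 <- cube
  for (k in seq_along(tissue)) {
    p <- tissue[k]
    cube6$intensity[p, ] <- approx(cube$mz * (1 + inj[k] * 1e-6),
                                   cube$intensity[p, ], xout = cube$mz,
                                   rule = 2)$y
  }
  al <- align_spectra(cube6, max_shift_ppm = 10)
  expect_lt(max(abs(al$shift_ppm[tissue] - inj)), 1)
  # drift beyond the bound saturates and is flagged; only a minority of
  # pixels is drifted so the cohort mean stays an undrifted reference
  drifted_px <- tissue[seq(1, length(tissue), by = 10)]
  cube20 <- cube
  for (p in drifted_px) {
    cube20$intensity[p, ] <- approx(cube$mz * (1 + 20e-6),
                                    cube$intensity[p, ], xout = cube$mz,
                                    rule = 2)$y
  }
  al20 <- align_spectra(cube20, max_shift_ppm = 10)
  expect_true(all(abs(al20$shift_ppm) <= 10 + 1e-9))
  expect_true(all(al20$saturated[drifted_px]))
  expect_false(any(al20$saturated[setdiff(tissue, drifted_px)]))
  # all-zero pixels get shift 0 and a flag
  bg <- which(cube$truth$labels == 0)
  expect_true(all(al0$flagged[bg][rowSums(cube$intensity[bg, ]) == 0]))
})

test_that("feature rows capture at most the full TIC after normalization", {
  fix <- noisy_fixture()
  pp <- fix$pp
  sums <- rowSums(pp$features$values)
  expect_true(all(sums <= 1 + 1e-9))
  expect_true(all(sums >= 0))
})

test_that("normalize/average order changes the average only by a scalar when TICs are equal", {
  fix <- noiseless_fixture()
  cube <- fix$cube
  codes <- region_codes()
  # two pixels from the same region share a TIC in the noiseless cube
  px <- which(cube$truth$labels == codes[["grey_matter"]])[1:2]
  sub <- cube
  sub$intensity <- cube$intensity[px, , drop = FALSE]
  sub$coords <- cube$coords[px, ]
  avg_raw <- average_spectrum(sub)
  avg_norm <- average_spectrum(tic_normalize(sub)$data)
  ratio <- avg_raw$intensity[avg_norm$intensity > 0] /
    avg_norm$intensity[avg_norm$intensity > 0]
  expect_lt(diff(range(ratio)), 1e-9 * mean(ratio))
})

test_that("noiseless phantom fingerprints recover the templates end to end", {
  fix <- noiseless_fixture()
  pp <- fix$pp
  tpl <- fix$templates
  codes <- region_codes()
  expect_equal(length(pp$peaklist$mz), length(tpl$white_matter$mz))
  for (r in c("white_matter", "peri_lesion", "lesion_core", "grey_matter")) {
    rows <- region_pixels(fix, r)
    fp <- colMeans(pp$features$values[rows, , drop = FALSE])
    fp <- fp / sum(fp)
    idx <- vapply(tpl[[r]]$mz,
                  function(m) which.min(abs(pp$peaklist$mz - m)), 1L)
    cosine <- sum(fp[idx] * tpl[[r]]$abundance) /
      sqrt(sum(fp[idx]^2) * sum(tpl[[r]]$abundance^2))
    expect_gt(cosine, 0.999)
    expect_lt(max(abs(fp[idx] - tpl[[r]]$abundance) / tpl[[r]]$abundance),
              1e-6)
  }
})
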