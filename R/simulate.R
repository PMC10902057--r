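# Synthetic MSI datacube generation: render each pixel's region template as
# Gaussian [M-H]- peaks on a shared m/z axis with per-pixel TIC variation,
# ppm mass drift, multiplicative intensity noise, additive baseline and
# optional shot noise. All latent ground truth is returned for recovery
# tests.

#' Instrument noise model for the simulator
#'
#' @param peak_fwhm_mz Gaussian peak full width at half maximum in Da,
#'   constant across the window; the default gives resolution ~60,000 at
#'   m/z 700.
#' @param intensity_cv coefficient of variation of the multiplicative
#'   log-normal noise applied independently per pixel and peak.
#' @param tic_cv CV of the per-pixel log-normal total-signal multiplier.
#' @param drift_ppm_sd standard deviation (ppm) of the per-pixel rigid
#'   mass shift.
#' @param baseline_level additive background level (intensity units of a
#'   unit-total template).
#' @param shot_noise logical; apply Poisson count noise on top
#'   (`shot_scale` counts per intensity unit).
#' @param shot_scale counts per intensity unit when `shot_noise` is TRUE.
#' @param seed RNG seed; generation is reproducible bit-for-bit.
#' @return list of class `noise_model`.
#' @export
noise_model <- function(peak_fwhm_mz = 700 / 60000,
                        intensity_cv = 0.20, tic_cv = 0.20,
                        drift_ppm_sd = 3, baseline_level = 1e-4,
                        shot_noise = FALSE, shot_scale = 1e6, seed = 1) {
  stopifnot(peak_fwhm_mz > 0, intensity_cv >= 0, tic_cv >= 0,
            drift_ppm_sd >= 0, baseline_level >= 0, shot_scale > 0)
  structure(list(peak_fwhm_mz = peak_fwhm_mz, intensity_cv = intensity_cv,
                 tic_cv = tic_cv, drift_ppm_sd = drift_ppm_sd,
                 baseline_level = baseline_level, shot_noise = shot_noise,
                 shot_scale = shot_scale, seed = as.integer(seed)),
            class = "noise_model")
}

# m/z axis: fine, symmetric local grids (exactly centred on each species
# m/z, spacing sigma/2, +-6 sigma) merged with a coarse 1 Da background
# grid over the window.
.build_mz_axis <- function(mz_centers, mz_min, mz_max, sigma) {
  local_grid <- seq(-6 * sigma, 6 * sigma, by = sigma / 2)
  fine <- as.vector(outer(local_grid, mz_centers, `+`))
  axis <- sort(unique(c(fine, seq(mz_min, mz_max, by = 1))))
  axis[axis >= mz_min & axis <= mz_max]
}

#' Simulate an MSI datacube from a phantom and region templates
#'
#' Each tissue pixel's spectrum is its region template rendered as
#' Gaussian peaks at the species' `[M-H]-` m/z (peak height proportional
#' to abundance), multiplied by a per-pixel TIC factor, mass-shifted by a
#' per-pixel ppm drift, perturbed by per-peak log-normal noise and an
#' additive baseline. Background pixels carry baseline only.
#'
#' @param phantom a `tissue_phantom` from [build_phantom()].
#' @param templates named list of `region_template`s covering every
#'   non-background label in the phantom (see
#'   [default_region_templates()]).
#' @param noise a [noise_model()].
#' @param mz_min,mz_max observation window bounds in Da (defaults 550 and
#'   1000, where the glycerophospholipid and sphingolipid classes appear).
#' @return object of class `spectra_cube`: list with `mz` (shared axis),
#'   `intensity` (pixels x m/z matrix, row-major pixel order), `coords`
#'   (0-based row/col per pixel), `pixel_size_um`, `polarity`
#'   (`"negative"`), `mz_range`, `peak_fwhm_mz`, and `truth` (labels
#'   vector, per-pixel `shift_ppm` and `tic_factor`, the templates used,
#'   species m/z).
#' @export
simulate_cube <- function(phantom, templates = default_region_templates(),
                          noise = noise_model(), mz_min = 550, mz_max = 1000) {
  stopifnot(inherits(phantom, "tissue_phantom"), mz_min < mz_max)
  codes <- region_codes()
  labels <- as.vector(t(phantom$labels))  # row-major: row 0 first
  present <- setdiff(sort(unique(labels)), codes[["background"]])
  region_names <- names(codes)[match(present, codes)]
  missing_tpl <- setdiff(region_names, names(templates))
  if (length(missing_tpl) > 0) {
    stop("no template for region(s): ", paste(missing_tpl, collapse = ", "))
  }
  tpl0 <- templates[[region_names[1]]]
  outside <- tpl0$mz < mz_min | tpl0$mz > mz_max
  if (any(outside)) {
    stop("template species outside the m/z window: ",
         paste(tpl0$species[outside], collapse = ", "))
  }

  sigma <- noise$peak_fwhm_mz / (2 * sqrt(2 * log(2)))
  axis <- .build_mz_axis(tpl0$mz, mz_min, mz_max, sigma)
  n_px <- length(labels)
  n_sp <- length(tpl0$mz)

  local_seed(noise$seed, {
    sdlog_t <- sqrt(log(1 + noise$tic_cv^2))
    tic_factor <- stats::rlnorm(n_px, -sdlog_t^2 / 2, sdlog_t)
    shift_ppm <- stats::rnorm(n_px, 0, noise$drift_ppm_sd)
    sdlog_i <- sqrt(log(1 + noise$intensity_cv^2))
    # per pixel-peak noise drawn in one block for reproducibility
    eps <- matrix(stats::rlnorm(n_px * n_sp, -sdlog_i^2 / 2, sdlog_i),
                  n_px, n_sp)
    if (noise$tic_cv == 0) tic_factor[] <- 1
    if (noise$drift_ppm_sd == 0) shift_ppm[] <- 0
    if (noise$intensity_cv == 0) eps[] <- 1

    intensity <- matrix(noise$baseline_level, n_px, length(axis))
    # per-species axis windows (drift << sigma, so undrifted windows +-7
    # sigma always cover the drifted peak)
    win <- lapply(tpl0$mz, function(c0) {
      which(axis >= c0 - 7 * sigma & axis <= c0 + 7 * sigma)
    })
    tissue_idx <- which(labels != codes[["background"]])
    lab_name <- names(codes)[match(labels, codes)]
    for (p in tissue_idx) {
      tp <- templates[[lab_name[p]]]
      centers <- tp$mz * (1 + shift_ppm[p] * 1e-6)
      amp <- tp$abundance * tic_factor[p] * eps[p, ]
      for (s in seq_len(n_sp)) {
        idx <- win[[s]]
        intensity[p, idx] <- intensity[p, idx] +
          amp[s] * exp(-0.5 * ((axis[idx] - centers[s]) / sigma)^2)
      }
    }
    if (noise$shot_noise) {
      intensity[] <- stats::rpois(length(intensity),
                                  intensity * noise$shot_scale) / noise$shot_scale
    }
  })

  coords <- data.frame(
    row = rep(seq_len(phantom$height_px) - 1L, each = phantom$width_px),
    col = rep(seq_len(phantom$width_px) - 1L, times = phantom$height_px))

  structure(list(mz = axis, intensity = intensity, coords = coords,
                 width_px = phantom$width_px, height_px = phantom$height_px,
                 pixel_size_um = phantom$pixel_size_um,
                 polarity = "negative", mz_range = c(mz_min, mz_max),
                 peak_fwhm_mz = noise$peak_fwhm_mz,
                 truth = list(labels = labels, shift_ppm = shift_ppm,
                              tic_factor = tic_factor,
                              templates = templates,
                              species = tpl0$species, species_mz = tpl0$mz)),
            class = "spectra_cube")
}

#' @export
print.spectra_cube <- function(x, ...) {
  cat(sprintf("<spectra_cube> %d pixels (%d x %d), %d m/z points in [%g, %g], %s mode\n",
              nrow(x$intensity), x$height_px, x$width_px, length(x$mz),
              x$mz_range[1], x$mz_range[2], x$polarity))
  invisible(x)
}

#' Simulate a cohort of sections
#'
#' Convenience wrapper generating `n_sections` phantoms and cubes with
#' per-section template jitter (inter-animal variability) and distinct
#' noise realizations, all derived deterministically from one base seed.
#'
#' @param n_sections number of sections (default 9, one per animal).
#' @param width_px,height_px raster size per section.
#' @param templates base region templates.
#' @param noise base noise model (per-section seeds derived from it).
#' @param jitter_cv inter-section template jitter CV (see
#'   [section_templates()]).
#' @param geometry phantom geometry.
#' @param seed base seed.
#' @return list of `n_sections` lists, each with `phantom`, `templates`
#'   (jittered), and `cube`.
#' @export
simulate_cohort <- function(n_sections = 9, width_px = 48, height_px = 48,
                            templates = default_region_templates(),
                            noise = noise_model(), jitter_cv = 0.15,
                            geometry = phantom_geometry(), seed = 1) {
  lapply(seq_len(n_sections), function(i) {
    s <- child_seed(seed, i)
    ph <- build_phantom(width_px, height_px, geometry, seed = s)
    tpl <- section_templates(templates, jitter_cv, seed = s)
    nm <- noise
    nm$seed <- child_seed(s, 1)
    list(phantom = ph, templates = tpl, cube = simulate_cube(ph, tpl, nm))
  })
}
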