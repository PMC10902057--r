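# Shared fixtures, built in code and cached per test session.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, build(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# small phantom whose lesion survives the 16x16 rasterization
mini_geometry <- function() {
  phantom_geometry(lesion_axes = c(0.16, 0.13), ring_thickness = 0.08,
                   jitter = 0)
}

# noiseless 24x24 cube + preprocessing, reused across files
noiseless_fixture <- function() {
  fixture("noiseless24", function() {
    ph <- build_phantom(24, 24, seed = 1)
    tpl <- default_region_templates()
    nm <- noise_model(intensity_cv = 0, tic_cv = 0, drift_ppm_sd = 0,
                      baseline_level = 0, seed = 1)
    cube <- simulate_cube(ph, tpl, nm)
    pp <- preprocess_cube(cube)
    list(phantom = ph, templates = tpl, cube = cube, pp = pp,
         labels = cube$truth$labels[pp$tissue_idx])
  })
}

# default-noise 32x32 cube + preprocessing
noisy_fixture <- function() {
  fixture("noisy32", function() {
    ph <- build_phantom(32, 32, seed = 3)
    tpl <- section_templates(default_region_templates(), 0.15, seed = 3)
    cube <- simulate_cube(ph, tpl, noise_model(seed = 33))
    pp <- preprocess_cube(cube)
    list(phantom = ph, templates = tpl, cube = cube, pp = pp,
         labels = cube$truth$labels[pp$tissue_idx])
  })
}

# brute-force bipartition search over all 2^(n-1)-1 splits, maximizing the
# same objective definition as the walker split (independent search path)
exhaustive_best_split <- function(C) {
  n <- nrow(C)
  best <- -Inf
  best_in_a <- NULL
  for (mask in 0:(2^(n - 1) - 2)) {
    in_a <- c(TRUE, bitwAnd(mask, 2^(0:(n - 2))) > 0)
    a <- which(in_a); b <- which(!in_a)
    sw <- 0; nw <- 0
    if (length(a) > 1) { sw <- sw + sum(C[a, a]) - length(a); nw <- nw + length(a) * (length(a) - 1) }
    if (length(b) > 1) { sw <- sw + sum(C[b, b]) - length(b); nw <- nw + length(b) * (length(b) - 1) }
    o <- (if (nw > 0) sw / nw else 0) - sum(C[a, b]) / (length(a) * length(b))
    if (o > best) { best <- o; best_in_a <- in_a }
  }
  list(objective = best, in_a = best_in_a)
}

region_pixels <- function(fix, region) {
  which(fix$labels == region_codes()[[region]])
}

f1_score <- function(pred_px, truth_px, n_truth) {
  tp <- length(intersect(pred_px, truth_px))
  if (tp == 0) return(0)
  prec <- tp / length(pred_px)
  rec <- tp / n_truth
  2 * prec * rec / (prec + rec)
}
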