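# Region lipid-fingerprint templates: the ground-truth relative-abundance
# vectors each tissue region expresses in the simulator. Trend directions
# from unaffected white matter through the peri-lesion ring to the lesion
# core follow the demyelination signature: PC and PE rise, ether-PC and
# sulfatides fall, SM rises, PS falls, PI (especially PI 38:4, the main
# arachidonate store) rises; grey matter carries elevated PI.

# Species simulated by default: the bundled library minus members of
# close-mass pairs (< 0.1 Da apart), so rendered Gaussian peaks do not
# overlap and noiseless recovery is exact.
.TEMPLATE_EXCLUDE <- c("PC 34:1e", "PC 36:4e", "PC 36:1")

# Baseline white-matter weights (relative, renormalized later).
.WM_BASELINE <- c(
  "PC 32:0" = 0.030, "PC 34:1" = 0.050, "PC 36:4" = 0.020,
  "PC 38:4" = 0.025, "PC 40:6" = 0.020,
  "PC 32:0e" = 0.020, "PC 38:5e" = 0.015,
  "PE 34:1" = 0.025, "PE 36:1" = 0.030, "PE 36:2" = 0.030,
  "PE 38:4" = 0.035, "PE 40:6" = 0.035,
  "PE 36:2e" = 0.030, "PE 36:5e" = 0.012, "PE 38:6e" = 0.020,
  "PE 38:7e" = 0.012, "PE 40:6e" = 0.030, "PE 40:7e" = 0.012,
  "PI 34:1" = 0.008, "PI 36:1" = 0.008, "PI 36:4" = 0.012,
  "PI 37:4" = 0.006, "PI 38:4" = 0.030, "PI 38:5" = 0.010,
  "PI 38:6" = 0.008, "PI 40:6" = 0.008,
  "PS 36:1" = 0.030, "PS 36:2" = 0.020, "PS 38:4" = 0.025, "PS 40:6" = 0.030,
  "PG 34:1" = 0.010, "PG 36:2" = 0.010, "PG 38:4" = 0.008, "PG 40:6" = 0.008,
  "SM 34:1" = 0.020, "SM 36:1" = 0.020, "SM 38:1" = 0.015, "SM 42:2" = 0.015,
  "ST 40:1" = 0.030, "ST 42:1" = 0.035, "ST 42:2" = 0.035, "ST 44:2" = 0.025
)

# White-matter -> lesion-core fold changes. The lesion core is completely
# demyelinated: myelin lipids (sulfatides, ether-PC, the down-trending
# ether-PE, PS) are strongly depleted, while phagocytosis/proliferation
# markers (PC, PE, SM, PI and above all PI 38:4) accumulate.
.CORE_FC <- c(
  "PC 32:0" = 2.2, "PC 34:1" = 2.2, "PC 36:4" = 2.2,
  "PC 38:4" = 2.2, "PC 40:6" = 2.2,
  "PC 32:0e" = 0.40, "PC 38:5e" = 0.40,
  "PE 34:1" = 2.0, "PE 36:1" = 2.0, "PE 36:2" = 2.0,
  "PE 38:4" = 2.0, "PE 40:6" = 2.0,
  "PE 36:2e" = 0.40, "PE 36:5e" = 1.0, "PE 38:6e" = 1.8,
  "PE 38:7e" = 1.8, "PE 40:6e" = 0.40, "PE 40:7e" = 1.8,
  "PI 34:1" = 1.8, "PI 36:1" = 1.8, "PI 36:4" = 1.8,
  "PI 37:4" = 1.8, "PI 38:4" = 3.0, "PI 38:5" = 1.8,
  "PI 38:6" = 1.8, "PI 40:6" = 1.8,
  "PS 36:1" = 0.5, "PS 36:2" = 0.5, "PS 38:4" = 0.5, "PS 40:6" = 0.5,
  "PG 34:1" = 0.7, "PG 36:2" = 1.5, "PG 38:4" = 1.5, "PG 40:6" = 0.7,
  "SM 34:1" = 2.2, "SM 36:1" = 2.2, "SM 38:1" = 2.2, "SM 42:2" = 2.2,
  "ST 40:1" = 0.25, "ST 42:1" = 0.25, "ST 42:2" = 0.25, "ST 44:2" = 0.25
)
# Peri-lesion position of each species along its own white->core
# trajectory, as the exponent t in fc_peri = fc_core^t. Demyelination is
# ACTIVE in the peri-lesion, so loss species are largely depleted there
# already (t = 0.75); the phagocytic accumulation completes in the core,
# so gain species change late (t = 0.30). PE 36:5e peaks in the ring.
.PERI_EXPONENT_LOSS <- 0.75
.PERI_EXPONENT_GAIN <- 0.30
.PERI_MAX <- c("PE 36:5e" = 1.5)

# Grey-matter multipliers relative to white matter (PI-rich, myelin-poor).
.GM_FC <- c(PI = 2.2, ST = 0.50, PC = 1.3, "PE-E" = 0.70, SM = 1.2)

#' Default region lipid templates
#'
#' Builds one `region_template` per tissue region: a relative-abundance
#' vector over the simulated lipid species (normalized to sum 1) encoding
#' the demyelination trend directions described above, plus the
#' fold-change table each region applied to the white-matter baseline.
#'
#' @param species_library library data.frame from [lipid_library()]; must
#'   contain all nine lipid classes (PC, PC-E, PE, PE-E, PI, PS, PG, SM,
#'   ST) among at least 20 species.
#' @param effect_scale scales all log fold changes: 1 is the default
#'   demyelination signature, 0 removes every white/peri/core difference
#'   (grey matter included); useful for power/null experiments.
#' @return named list of `region_template` objects for `grey_matter`,
#'   `white_matter`, `peri_lesion`, `lesion_core`. Each has `region`,
#'   `species` (names), `abundance` (sums to 1), `effect` (fold change vs
#'   white matter, pre-normalization) and `mz` (library `[M-H]-` values).
#' @export
default_region_templates <- function(species_library = lipid_library(),
                                     effect_scale = 1) {
  stopifnot(effect_scale >= 0)
  need <- .LIPID_CLASSES
  have <- unique(species_library$class)
  missing_cls <- setdiff(need, have)
  if (length(missing_cls) > 0) {
    stop("species library missing required lipid class(es): ",
         paste(missing_cls, collapse = ", "))
  }
  if (nrow(species_library) < 20) {
    stop("species library must contain at least 20 species")
  }
  sp <- names(.WM_BASELINE)
  lib_idx <- match(sp, species_library$name)
  if (anyNA(lib_idx)) {
    stop("species library lacks template species: ",
         paste(sp[is.na(lib_idx)], collapse = ", "))
  }
  mz <- species_library$mz_MH[lib_idx]
  cls <- species_library$class[lib_idx]
  names(mz) <- names(cls) <- sp

  base <- .WM_BASELINE / sum(.WM_BASELINE)
  fc_core <- .CORE_FC[sp]^effect_scale
  peri_t <- ifelse(.CORE_FC[sp] < 1, .PERI_EXPONENT_LOSS, .PERI_EXPONENT_GAIN)
  fc_peri <- .CORE_FC[sp]^(effect_scale * peri_t)
  pm <- intersect(names(.PERI_MAX), sp)
  fc_peri[pm] <- .PERI_MAX[pm]^effect_scale

  fc_grey <- stats::setNames(rep(1, length(sp)), sp)
  for (k in names(.GM_FC)) fc_grey[cls == k] <- .GM_FC[[k]]^effect_scale

  mk <- function(region, fc) {
    ab <- base * fc
    structure(list(region = region, species = sp,
                   abundance = ab / sum(ab), effect = fc, mz = mz,
                   class = cls),
              class = "region_template")
  }
  list(grey_matter = mk("grey_matter", fc_grey),
       white_matter = mk("white_matter", stats::setNames(rep(1, length(sp)), sp)),
       peri_lesion = mk("peri_lesion", fc_peri),
       lesion_core = mk("lesion_core", fc_core))
}

#' @export
print.region_template <- function(x, ...) {
  cat(sprintf("<region_template> %s: %d species, sum(abundance)=%.6f\n",
              x$region, length(x$species), sum(x$abundance)))
  invisible(x)
}

#' Per-class rollup of a template or fingerprint vector
#' @param abundance named numeric vector over species shorthand names.
#' @param classes optional character vector of classes (parsed from names
#'   if missing).
#' @return named numeric vector of class totals.
#' @export
class_rollup <- function(abundance, classes = NULL) {
  if (is.null(classes)) {
    classes <- vapply(names(abundance),
                      function(n) parse_shorthand(n)$class, "")
  }
  tapply(abundance, classes, sum)
}

#' Apply inter-section (animal) variability to region templates
#'
#' Multiplies every template abundance by log-normal jitter shared across
#' regions of the same section plus independent per-region jitter, then
#' renormalizes. Emulates biological variability between animals.
#'
#' @param templates list from [default_region_templates()].
#' @param jitter_cv coefficient of variation of the log-normal jitter
#'   (default 0.15).
#' @param seed integer seed; one section per seed.
#' @return list of jittered `region_template` objects.
#' @export
section_templates <- function(templates, jitter_cv = 0.15, seed = 1) {
  stopifnot(jitter_cv >= 0)
  if (jitter_cv == 0) return(templates)
  sdlog <- sqrt(log(1 + jitter_cv^2))
  local_seed(seed, {
    n <- length(templates[[1]]$species)
    shared <- stats::rlnorm(n, -sdlog^2 / 2, sdlog)
    lapply(templates, function(tp) {
      own <- stats::rlnorm(n, -sdlog^2 / 8, sdlog / 2)
      ab <- tp$abundance * shared * own
      tp$abundance <- ab / sum(ab)
      tp
    })
  })
}
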