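# Ground-truth tissue phantom: a parametric label raster emulating a
# coronal spinal-cord section with a focal demyelinating lesion.

#' Region label codes
#'
#' Integer codes used in phantom label rasters and exported masks:
#' background 0, grey_matter 1, white_matter 2, peri_lesion 3,
#' lesion_core 4.
#' @return named integer vector.
#' @export
region_codes <- function() {
  c(background = 0L, grey_matter = 1L, white_matter = 2L,
    peri_lesion = 3L, lesion_core = 4L)
}

#' Phantom geometry parameters
#'
#' All lengths are fractions of the grid dimensions so the same geometry
#' scales to any raster size. The section is an ellipse of tissue; a
#' ventral horizontal band is grey matter and the rest white matter; the
#' lesion core is an ellipse inside the white matter wrapped by a
#' peri-lesion ring of constant thickness.
#'
#' @param tissue_margin fraction of the grid left as background border.
#' @param grey_band_top,grey_band_bottom vertical extent (row fraction) of
#'   the ventral grey-matter band.
#' @param lesion_center (x, y) centre of the lesion core as width/height
#'   fractions.
#' @param lesion_axes (x, y) semi-axes of the lesion core as width/height
#'   fractions; `c(0, 0)` suppresses the lesion entirely.
#' @param ring_thickness peri-lesion ring thickness as a fraction of the
#'   smaller grid dimension.
#' @param jitter relative jitter applied (seeded) to lesion centre and
#'   axes so replicate sections have heterogeneous lesion geometries;
#'   0 disables.
#' @return list of class `phantom_geometry`.
#' @export
phantom_geometry <- function(tissue_margin = 0.06,
                             grey_band_top = 0.62, grey_band_bottom = 0.95,
                             lesion_center = c(0.40, 0.32),
                             lesion_axes = c(0.16, 0.12),
                             ring_thickness = 0.07,
                             jitter = 0.10) {
  stopifnot(tissue_margin >= 0, grey_band_top < grey_band_bottom,
            length(lesion_center) == 2L, length(lesion_axes) == 2L,
            all(lesion_axes >= 0), ring_thickness >= 0, jitter >= 0)
  structure(list(tissue_margin = tissue_margin,
                 grey_band_top = grey_band_top,
                 grey_band_bottom = grey_band_bottom,
                 lesion_center = lesion_center,
                 lesion_axes = lesion_axes,
                 ring_thickness = ring_thickness,
                 jitter = jitter),
            class = "phantom_geometry")
}

# continuous-geometry check that the outer lesion ellipse (core + ring)
# stays inside the tissue ellipse and clear of the grey-matter band
.lesion_fits <- function(g) {
  if (any(g$lesion_axes <= 0)) return(TRUE)
  th <- seq(0, 2 * pi, length.out = 181)
  x <- g$lesion_center[1] + (g$lesion_axes[1] + g$ring_thickness) * cos(th)
  y <- g$lesion_center[2] + (g$lesion_axes[2] + g$ring_thickness) * sin(th)
  ax <- 0.5 - g$tissue_margin
  inside <- all(((x - 0.5) / ax)^2 + ((y - 0.5) / ax)^2 <= 1)
  clear <- max(y) < g$grey_band_top || min(y) > g$grey_band_bottom
  inside && clear
}

#' Build a ground-truth tissue phantom
#'
#' Produces the per-pixel region label raster for one synthetic section.
#' Given the same seed and geometry the raster is reproduced exactly.
#'
#' @param width_px,height_px raster dimensions in pixels (minimum 16).
#' @param geometry a [phantom_geometry()] object.
#' @param pixel_size_um pixel pitch in micrometres (default 10).
#' @param seed integer seed controlling the lesion-geometry jitter.
#' @return object of class `tissue_phantom`: list with `labels`
#'   (height x width integer matrix of [region_codes()]), `width_px`,
#'   `height_px`, `pixel_size_um`, `geometry` (the jittered effective
#'   geometry) and `seed`.
#' @export
build_phantom <- function(width_px = 64, height_px = 64,
                          geometry = phantom_geometry(),
                          pixel_size_um = 10, seed = 1) {
  stopifnot(width_px >= 16, height_px >= 16,
            inherits(geometry, "phantom_geometry"))
  g <- geometry
  if (g$jitter > 0) {
    j <- local_seed(seed, {
      stats::runif(4, -g$jitter, g$jitter)
    })
    # jitter is damped (halved, deterministically) until the jittered
    # lesion fits the tissue, so every seed yields a valid section; an
    # unjittered geometry that cannot fit still errors below
    for (damp in c(1, 0.5, 0.25, 0.125, 0)) {
      g$lesion_center <- geometry$lesion_center * (1 + damp * j[1:2])
      g$lesion_axes <- geometry$lesion_axes * (1 + damp * j[3:4])
      if (.lesion_fits(g)) break
    }
  }
  # pixel centres in unit coordinates
  x <- (matrix(seq_len(width_px), height_px, width_px, byrow = TRUE) - 0.5) / width_px
  y <- (matrix(seq_len(height_px), height_px, width_px) - 0.5) / height_px

  codes <- region_codes()
  labels <- matrix(codes[["background"]], height_px, width_px)

  # tissue ellipse
  tx <- 0.5; ty <- 0.5
  ax <- 0.5 - g$tissue_margin; ay <- 0.5 - g$tissue_margin
  tissue <- ((x - tx) / ax)^2 + ((y - ty) / ay)^2 <= 1
  labels[tissue] <- codes[["white_matter"]]
  grey <- tissue & y >= g$grey_band_top & y <= g$grey_band_bottom
  labels[grey] <- codes[["grey_matter"]]

  if (all(g$lesion_axes > 0)) {
    cx <- g$lesion_center[1]; cy <- g$lesion_center[2]
    lax <- g$lesion_axes[1]; lay <- g$lesion_axes[2]
    rt <- g$ring_thickness
    core <- ((x - cx) / lax)^2 + ((y - cy) / lay)^2 <= 1
    outer <- ((x - cx) / (lax + rt))^2 + ((y - cy) / (lay + rt))^2 <= 1
    ring <- outer & !core
    # the full lesion (core + ring) must sit inside the tissue ellipse and
    # clear of the grey-matter band
    if (any(outer & !tissue)) {
      stop("invalid geometry: lesion (incl. peri-lesion ring) extends outside the tissue area")
    }
    if (any(outer & grey)) {
      stop("invalid geometry: lesion overlaps the grey-matter band")
    }
    labels[ring] <- codes[["peri_lesion"]]
    labels[core] <- codes[["lesion_core"]]
  }

  structure(list(labels = labels, width_px = width_px, height_px = height_px,
                 pixel_size_um = pixel_size_um, geometry = g, seed = seed),
            class = "tissue_phantom")
}

#' @export
print.tissue_phantom <- function(x, ...) {
  tab <- table(factor(x$labels, levels = region_codes(),
                      labels = names(region_codes())))
  cat(sprintf("<tissue_phantom> %d x %d px (%g um/px)\n",
              x$width_px, x$height_px, x$pixel_size_um))
  print(tab)
  invisible(x)
}

#' @export
plot.tissue_phantom <- function(x, ...) {
  pal <- c("grey95", "#8c6bb1", "#e7e1ef", "#636363", "white")
  graphics::image(t(x$labels)[, rev(seq_len(nrow(x$labels)))],
                  col = pal, zlim = c(0, 4), axes = FALSE,
                  main = "tissue phantom", ...)
  invisible(x)
}

#' Write a label raster as a greyscale PNG
#'
#' Region codes are stored directly as 8-bit grey levels (0..4), so the
#' file is a machine-readable mask, not a visualization. The legend is
#' [region_codes()].
#'
#' @param labels integer matrix of region codes, or a `tissue_phantom`.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_label_raster <- function(labels, path) {
  if (inherits(labels, "tissue_phantom")) labels <- labels$labels
  png::writePNG(labels / 255, path)
  invisible(path)
}

#' Read a label raster written by [write_label_raster()]
#' @param path PNG path.
#' @return integer matrix of region codes.
#' @export
read_label_raster <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  matrix(as.integer(round(img * 255)), nrow(img), ncol(img))
}
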