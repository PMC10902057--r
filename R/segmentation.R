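# DHC-RC: divisive hierarchical clustering with rank-competing random
# walkers. The image is split top-down; each split seeds two walkers at a
# minimum-correlation pixel pair and lets them grow competing regions by
# repeatedly claiming the unassigned pixel with the highest mean
# correlation to their current region. Restarts over alternative
# low-correlation seed pairs plus a single-move hill-climbing polish keep
# the bipartition that maximizes mean within-group minus mean
# between-group correlation.

#' Walker configuration for DHC-RC splits
#'
#' @param restarts number of additional seed pairs tried besides the
#'   global minimum-correlation pair: half drawn among the bottom 1%
#'   correlation pairs, half uniformly over all pairs. For small pixel
#'   sets (up to `all_pairs_max` candidate pairs) every pair is tried,
#'   which realizes the "variable number of walkers".
#' @param all_pairs_max if the number of pixel pairs is at most this,
#'   every pair serves as a seed candidate.
#' @param polish logical; run single-move hill climbing on each candidate
#'   bipartition (default TRUE).
#' @param min_size_frac smallest admissible segment size as a fraction of
#'   the pixel set being split (default 0.15); bipartitions below it are
#'   rejected, so small groups of noisy outlier pixels cannot be peeled
#'   off as "segments" (tissue domains are substantial). Sets of up to 20
#'   pixels are split unconstrained. If no admissible bipartition is
#'   found, the best unconstrained one is used.
#' @param max_exact maximum pixel count for exact all-pairs correlation;
#'   above it the split runs on a seeded subsample and remaining pixels
#'   join the nearer group (default 20000).
#' @param standardize standardize each peak across pixels (z-score) before
#'   computing pixel-pixel correlations in [dhc_rc_segment()] (default
#'   TRUE). Raw TIC-scaled fingerprints all correlate strongly through the
#'   shared lipid profile; standardization restores contrast between
#'   tissue domains. Mean fingerprints and colours are always computed on
#'   the unstandardized features.
#' @param select which leaf to split next in [dhc_rc_segment()]:
#'   `"gain"` (default) splits the leaf whose best bipartition attains the
#'   highest objective; `"cohesion"` splits the leaf with the lowest mean
#'   within-segment correlation.
#' @param seed RNG seed making restarts deterministic.
#' @return list of class `walker_config`.
#' @export
walker_config <- function(restarts = 8, all_pairs_max = 200, polish = TRUE,
                          min_size_frac = 0.15, max_exact = 20000,
                          standardize = TRUE, select = c("gain", "cohesion"),
                          seed = 1) {
  stopifnot(restarts >= 0, all_pairs_max >= 1, max_exact >= 2,
            min_size_frac >= 0, min_size_frac < 0.5)
  select <- match.arg(select)
  structure(list(restarts = restarts, all_pairs_max = all_pairs_max,
                 polish = polish, min_size_frac = min_size_frac,
                 max_exact = max_exact, standardize = standardize,
                 select = select, seed = as.integer(seed)),
            class = "walker_config")
}

.feature_values <- function(features) {
  if (inherits(features, "feature_matrix")) features$values
  else if (inherits(features, "preprocessed")) features$features$values
  else as.matrix(features)
}

#' Pearson correlation between two pixel fingerprints
#'
#' @param features feature matrix (pixels x peaks) or `feature_matrix`.
#' @param i,j row indices of the two pixels.
#' @return correlation in `[-1, 1]`.
#' @export
pixel_correlation <- function(features, i, j) {
  X <- .feature_values(features)
  xi <- X[i, ]; xj <- X[j, ]
  if (stats::sd(xi) == 0 || stats::sd(xj) == 0) {
    stop("undefined correlation: constant fingerprint in pixel ",
         if (stats::sd(xi) == 0) i else j,
         " (such pixels should be filtered before segmentation)")
  }
  stats::cor(xi, xj)
}

# Full pixel-pixel Pearson correlation matrix; errors on constant rows.
.correlation_matrix <- function(X) {
  sds <- apply(X, 1, stats::sd)
  if (any(sds == 0)) {
    stop("undefined correlation: ", sum(sds == 0),
         " constant pixel fingerprint(s); filter before segmentation")
  }
  C <- stats::cor(t(X))
  C[!is.finite(C)] <- 0
  C
}

# objective = mean correlation over within-group pairs (pooled across both
# groups; 0 if no such pair) minus mean over between-group pairs
.bipartition_objective <- function(C, in_a) {
  a <- which(in_a); b <- which(!in_a)
  sw <- 0; nw <- 0
  if (length(a) > 1) {
    sw <- sw + sum(C[a, a]) - length(a); nw <- nw + length(a) * (length(a) - 1)
  }
  if (length(b) > 1) {
    sw <- sw + sum(C[b, b]) - length(b); nw <- nw + length(b) * (length(b) - 1)
  }
  within <- if (nw > 0) sw / nw else 0
  between <- sum(C[a, b]) / (length(a) * length(b))
  within - between
}

# Grow two competing walkers from seed pixels (local indices into C).
.grow_walkers <- function(C, seed_a, seed_b) {
  n <- nrow(C)
  grp <- integer(n)           # 0 unassigned, 1 A, 2 B
  grp[seed_a] <- 1L; grp[seed_b] <- 2L
  sum_a <- C[, seed_a]; sum_b <- C[, seed_b]
  n_a <- 1L; n_b <- 1L
  for (step in seq_len(n - 2L)) {
    un <- which(grp == 0L)
    ma <- sum_a[un] / n_a
    mb <- sum_b[un] / n_b
    best <- pmax(ma, mb)
    p <- un[which.max(best)]          # ties: lowest index wins
    if (ma[which.max(best)] >= mb[which.max(best)]) {
      grp[p] <- 1L; n_a <- n_a + 1L; sum_a <- sum_a + C[, p]
    } else {
      grp[p] <- 2L; n_b <- n_b + 1L; sum_b <- sum_b + C[, p]
    }
  }
  grp == 1L
}

# Single-move hill climbing on the bipartition objective, with incremental
# (rank-1) updates so each sweep is O(n) vector work.
.polish_bipartition <- function(C, in_a, min_size = 1L) {
  n <- nrow(C)
  av <- as.numeric(in_a)
  rs_a <- as.vector(C %*% av)            # sum of correlations to group A
  rs_b <- as.vector(C %*% (1 - av))
  a <- sum(in_a); b <- n - a
  Sw <- (sum(rs_a[in_a]) - a) / 2 + (sum(rs_b[!in_a]) - b) / 2
  Sb <- sum(rs_b[in_a])
  comb2 <- function(x) x * (x - 1) / 2
  obj_of <- function(Sw, Sb, a, b) {
    nw <- comb2(a) + comb2(b)
    (if (nw > 0) Sw / nw else 0) - Sb / (a * b)
  }
  obj <- obj_of(Sw, Sb, a, b)
  repeat {
    # candidate objective for moving each pixel to the other group
    s_own <- ifelse(in_a, rs_a - 1, rs_b - 1)     # to own group, minus self
    s_oth <- ifelse(in_a, rs_b, rs_a)
    Sw_new <- Sw - s_own + s_oth
    Sb_new <- Sb - s_oth + s_own
    a_new <- ifelse(in_a, a - 1, a + 1)
    b_new <- ifelse(in_a, b + 1, b - 1)
    nw_new <- comb2(a_new) + comb2(b_new)
    cand <- ifelse(nw_new > 0, Sw_new / nw_new, 0) - Sb_new / (a_new * b_new)
    # never shrink the source group below min_size (and never empty it);
    # groups already below min_size may only gain pixels
    cand[(in_a & a <= max(min_size, 1L)) | (!in_a & b <= max(min_size, 1L))] <- -Inf
    p <- which.max(cand)
    if (cand[p] <= obj + 1e-12) break
    obj <- cand[p]
    Sw <- Sw_new[p]; Sb <- Sb_new[p]; a <- a_new[p]; b <- b_new[p]
    if (in_a[p]) { rs_a <- rs_a - C[, p]; rs_b <- rs_b + C[, p] }
    else { rs_a <- rs_a + C[, p]; rs_b <- rs_b - C[, p] }
    in_a[p] <- !in_a[p]
  }
  list(in_a = in_a, objective = obj)
}

#' Split a pixel set into two by competing random walkers
#'
#' @param features feature matrix (pixels x peaks) or precomputed
#'   correlation matrix (set `is_correlation = TRUE`).
#' @param pixel_set integer indices (rows of `features`) to split; at
#'   least 2.
#' @param config a [walker_config()].
#' @param is_correlation `features` is already a pixel correlation matrix.
#' @return list: `left`, `right` (indices into `features`, each sorted;
#'   `left` contains the lowest index), `objective`.
#' @export
split_segment <- function(features, pixel_set, config = walker_config(),
                          is_correlation = FALSE) {
  pixel_set <- sort(as.integer(pixel_set))
  if (length(pixel_set) < 2) stop("cannot split a segment of fewer than 2 pixels")
  C <- if (is_correlation) features[pixel_set, pixel_set, drop = FALSE]
       else .correlation_matrix(.feature_values(features)[pixel_set, , drop = FALSE])
  n <- nrow(C)

  # candidate seed pairs: global minimum-correlation pair always; all
  # pairs for small sets; otherwise restarts among the bottom 1%
  pairs <- which(upper.tri(C), arr.ind = TRUE)
  ord <- order(C[pairs], pairs[, 1], pairs[, 2])
  pairs <- pairs[ord, , drop = FALSE]
  if (nrow(pairs) <= config$all_pairs_max) {
    cand <- pairs
  } else {
    k <- max(1L, ceiling(0.01 * nrow(pairs)))
    pool <- pairs[seq_len(k), , drop = FALSE]
    cand <- local_seed(config$seed, {
      n_low <- ceiling(config$restarts / 2)
      low <- unique(c(1L, sample.int(nrow(pool), min(n_low, nrow(pool)))))
      wide <- sample.int(nrow(pairs), config$restarts - n_low)
      rbind(pool[low, , drop = FALSE], pairs[wide, , drop = FALSE])
    })
  }

  min_size <- if (n <= 20) 1L else max(1L, ceiling(config$min_size_frac * n))
  best <- NULL; best_any <- NULL
  for (r in seq_len(nrow(cand))) {
    in_a <- .grow_walkers(C, cand[r, 1], cand[r, 2])
    if (config$polish) {
      res <- .polish_bipartition(C, in_a, min_size)
    } else {
      res <- list(in_a = in_a, objective = .bipartition_objective(C, in_a))
    }
    feasible <- min(sum(res$in_a), sum(!res$in_a)) >= min_size
    if (feasible && (is.null(best) || res$objective > best$objective + 1e-12))
      best <- res
    if (is.null(best_any) || res$objective > best_any$objective + 1e-12)
      best_any <- res
  }
  if (is.null(best)) best <- best_any  # no admissible bipartition: fall back
  left_first <- best$in_a[1]
  list(left = pixel_set[if (left_first) best$in_a else !best$in_a],
       right = pixel_set[if (left_first) !best$in_a else best$in_a],
       objective = best$objective)
}

# mean within-segment pairwise correlation (Inf for singletons: never the
# next split target, and unsplittable anyway)
.leaf_cohesion <- function(C, pixels) {
  if (length(pixels) < 2) return(Inf)
  (sum(C[pixels, pixels]) - length(pixels)) /
    (length(pixels) * (length(pixels) - 1))
}

#' Divisive hierarchical segmentation of an MSI feature image
#'
#' Starts from one segment holding every retained pixel and repeatedly
#' splits the leaf with the lowest mean within-segment correlation using
#' [split_segment()], until `n_segments` leaves exist. Segment ids are
#' contiguous from 0; the split history is kept as a tree. Colours come
#' from [assign_colors()].
#'
#' @param features `feature_matrix`, `preprocessed` object, or plain
#'   pixels x peaks matrix.
#' @param n_segments number of leaves requested (1 to number of pixels).
#' @param config a [walker_config()].
#' @return object of class `segment_map`: `assignment` (0-based segment id
#'   per retained pixel; `NA` for excluded pixels), `pixels` (list of row
#'   indices per segment), `tree` (list of nodes: `id`, `parent`,
#'   `children`, `pixels`, `leaf`), `colors`, `means` (per-segment mean
#'   fingerprints), `cohesion`, plus raster geometry when available.
#' @export
dhc_rc_segment <- function(features, n_segments, config = walker_config()) {
  X <- .feature_values(features)
  n <- nrow(X)
  if (n_segments < 1) stop("n_segments must be >= 1")
  if (n_segments > n) {
    stop("n_segments (", n_segments, ") exceeds number of retained pixels (", n, ")")
  }

  sub_assign <- NULL
  if (n > config$max_exact) {
    # medoid approximation: segment a seeded subsample exactly, then
    # attach every remaining pixel to the segment whose mean fingerprint
    # it correlates with best
    keep <- local_seed(config$seed, sort(sample.int(n, config$max_exact)))
    sub_assign <- list(keep = keep, n = n)
    X_full <- X
    X <- X[keep, , drop = FALSE]
    n <- nrow(X)
  }

  Z <- X
  if (isTRUE(config$standardize)) {
    Z <- scale(X)
    Z[, !is.finite(colSums(Z))] <- 0   # constant peaks carry no contrast
  }
  C <- .correlation_matrix(Z)
  tree <- list(list(id = 1L, parent = NA_integer_, children = integer(0),
                    pixels = seq_len(n), leaf = TRUE))
  leaves <- 1L
  splits <- list()   # cached best split per node id
  while (length(leaves) < n_segments) {
    splittable <- leaves[vapply(leaves, function(id)
      length(tree[[id]]$pixels) >= 2, logical(1))]
    if (length(splittable) == 0) stop("no splittable segment left")
    if (config$select == "gain") {
      for (id in splittable) {
        key <- as.character(id)
        if (is.null(splits[[key]])) {
          splits[[key]] <- split_segment(C, tree[[id]]$pixels, config,
                                         is_correlation = TRUE)
        }
      }
      gain <- vapply(splittable, function(id)
        splits[[as.character(id)]]$objective, numeric(1))
      pick <- splittable[which.max(gain)]
      halves <- splits[[as.character(pick)]]
    } else {
      coh <- vapply(splittable, function(id)
        .leaf_cohesion(C, tree[[id]]$pixels), numeric(1))
      pick <- splittable[which.min(coh)]
      halves <- split_segment(C, tree[[pick]]$pixels, config,
                              is_correlation = TRUE)
    }
    id_l <- length(tree) + 1L; id_r <- length(tree) + 2L
    tree[[pick]]$children <- c(id_l, id_r)
    tree[[pick]]$leaf <- FALSE
    tree[[id_l]] <- list(id = id_l, parent = pick, children = integer(0),
                         pixels = halves$left, leaf = TRUE)
    tree[[id_r]] <- list(id = id_r, parent = pick, children = integer(0),
                         pixels = halves$right, leaf = TRUE)
    leaves <- c(setdiff(leaves, pick), id_l, id_r)
  }
  leaves <- sort(leaves)

  assignment <- rep(NA_integer_, n)
  pixels <- vector("list", length(leaves))
  for (k in seq_along(leaves)) {
    px <- tree[[leaves[k]]]$pixels
    assignment[px] <- k - 1L
    pixels[[k]] <- px
  }
  cohesion <- vapply(leaves, function(id) .leaf_cohesion(C, tree[[id]]$pixels),
                     numeric(1))

  if (!is.null(sub_assign)) {
    means_sub <- t(vapply(pixels, function(px) colMeans(X[px, , drop = FALSE]),
                          numeric(ncol(X))))
    full_assign <- rep(NA_integer_, sub_assign$n)
    full_assign[sub_assign$keep] <- assignment
    rest <- setdiff(seq_len(sub_assign$n), sub_assign$keep)
    if (length(rest) > 0) {
      cors <- stats::cor(t(X_full[rest, , drop = FALSE]), t(means_sub))
      full_assign[rest] <- max.col(cors, ties.method = "first") - 1L
    }
    assignment <- full_assign
    pixels <- lapply(seq_along(leaves) - 1L, function(k) which(assignment == k))
    X <- X_full
  }

  means <- t(vapply(pixels, function(px) colMeans(X[px, , drop = FALSE]),
                    numeric(ncol(X))))
  map <- structure(list(assignment = assignment, pixels = pixels,
                        tree = tree, n_segments = length(leaves),
                        means = means, cohesion = cohesion,
                        colors = NULL,
                        coords = if (inherits(features, "feature_matrix"))
                          features$coords else if (inherits(features, "preprocessed"))
                            features$features$coords else NULL,
                        width_px = if (inherits(features, "feature_matrix"))
                          features$width_px else if (inherits(features, "preprocessed"))
                            features$features$width_px else NULL,
                        height_px = if (inherits(features, "feature_matrix"))
                          features$height_px else if (inherits(features, "preprocessed"))
                            features$features$height_px else NULL,
                        config = config),
                   class = "segment_map")
  map$colors <- assign_colors(map)
  map
}

#' Correlation-ordered colour values for segments
#'
#' The two segments whose mean fingerprints correlate least get the two
#' ends of the colour scale (0 and 1); every other segment is placed by a
#' one-dimensional embedding along the line through the two extremes
#' (coordinate `cor(s, a) - cor(s, b)` mapped linearly so the extremes hit
#' 0 and 1), so colour proximity reflects fingerprint similarity. A single
#' segment gets 0.5.
#'
#' @param segment_map a `segment_map`.
#' @param features optional; recompute mean fingerprints from these
#'   features instead of the stored ones.
#' @return numeric vector of colour values in `[0, 1]`, one per segment.
#' @export
assign_colors <- function(segment_map, features = NULL) {
  means <- if (is.null(features)) segment_map$means else
    t(vapply(segment_map$pixels,
             function(px) colMeans(.feature_values(features)[px, , drop = FALSE]),
             numeric(ncol(.feature_values(features)))))
  k <- nrow(means)
  if (k == 1) return(0.5)
  S <- suppressWarnings(stats::cor(t(means)))
  S[!is.finite(S)] <- 0
  if (k == 2) return(c(0, 1))
  pr <- which(S == min(S), arr.ind = TRUE)
  pr <- pr[order(pr[, 1], pr[, 2]), , drop = FALSE]
  a <- pr[1, 1]; b <- pr[1, 2]
  if (a > b) { tmp <- a; a <- b; b <- tmp }
  p <- S[, a] - S[, b]
  cols <- unname((p[a] - p) / (p[a] - p[b]))
  cols <- pmin(pmax(cols, 0), 1)
  # colour values must be unique per segment: break exact ties by nudging
  # later duplicates toward the interior of the scale
  while (anyDuplicated(cols) > 0) {
    d <- duplicated(cols)
    cols[d] <- cols[d] + ifelse(cols[d] < 0.5, 1e-6, -1e-6)
  }
  cols
}

#' Re-segment selected segments
#'
#' Isolates the pixels of the selected segments and reruns the divisive
#' segmentation on them alone, so subtle correlation structure inside a
#' region (e.g. the lesion margin) is no longer masked by the strong
#' lesion/healthy contrast. Pixels outside the selection are marked
#' excluded (`NA` assignment).
#'
#' @param features features the original map was built from.
#' @param segment_map a `segment_map`.
#' @param segment_ids 0-based ids of segments to keep and re-segment.
#' @param n_segments leaves requested within the selection.
#' @param config a [walker_config()].
#' @return new `segment_map` over the selected pixels (other pixels `NA`).
#' @export
resegment <- function(features, segment_map, segment_ids, n_segments,
                      config = walker_config()) {
  segment_ids <- as.integer(segment_ids)
  bad <- setdiff(segment_ids, seq_len(segment_map$n_segments) - 1L)
  if (length(bad) > 0) stop("unknown segment id(s): ", paste(bad, collapse = ", "))
  sel <- sort(unlist(segment_map$pixels[segment_ids + 1L]))
  if (length(sel) == 0) stop("empty segment selection")
  X <- .feature_values(features)
  sub <- dhc_rc_segment(X[sel, , drop = FALSE], n_segments, config)
  assignment <- rep(NA_integer_, nrow(X))
  assignment[sel] <- sub$assignment
  sub$assignment <- assignment
  sub$pixels <- lapply(sub$pixels, function(px) sel[px])
  sub$excluded <- setdiff(seq_len(nrow(X)), sel)
  for (f in c("coords", "width_px", "height_px")) sub[[f]] <- segment_map[[f]]
  sub
}

#' Match segments to ground-truth regions
#'
#' Assigns every segment the region it overlaps most (ties broken toward
#' the lower region code) and reports per-segment purity and per-region
#' recall.
#'
#' @param segment_map a `segment_map` whose pixels index `labels` (via
#'   `pixel_index`, see Details) or directly.
#' @param labels integer vector of ground-truth region codes for exactly
#'   the pixels the map's assignment covers (same length), e.g.
#'   `cube$truth$labels[pp$tissue_idx]`.
#' @return list: `table` (data.frame: segment, region code, region name,
#'   size, purity), `recall` (named vector per region present),
#'   `macro_purity`.
#' @export
map_segments_to_regions <- function(segment_map, labels) {
  if (length(labels) != length(segment_map$assignment)) {
    stop("label raster and segment map cover different pixel grids (",
         length(labels), " vs ", length(segment_map$assignment), " pixels)")
  }
  codes <- region_codes()
  segs <- seq_len(segment_map$n_segments) - 1L
  rows <- lapply(segs, function(s) {
    lab <- labels[which(segment_map$assignment == s)]
    tab <- table(factor(lab, levels = sort(unique(labels))))
    top <- max(tab)
    region <- as.integer(names(tab)[which(tab == top)[1]])  # lower code on tie
    data.frame(segment = s, region = region,
               region_name = names(codes)[match(region, codes)],
               size = length(lab), purity = top / length(lab))
  })
  tab <- do.call(rbind, rows)
  recall <- vapply(sort(unique(labels)), function(r) {
    segs_r <- tab$segment[tab$region == r]
    in_r <- which(labels == r & !is.na(segment_map$assignment))
    if (length(in_r) == 0) return(NA_real_)
    sum(segment_map$assignment[in_r] %in% segs_r) / length(in_r)
  }, numeric(1))
  names(recall) <- names(codes)[match(sort(unique(labels)), codes)]
  list(table = tab, recall = recall, macro_purity = mean(tab$purity))
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items;
#' 1 for identical partitions, ~0 for independent ones.
#'
#' @param a,b vectors of cluster labels (equal length; pairs with `NA` in
#'   either are dropped).
#' @return numeric scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- comb2(length(a))
  expected <- sum_a * sum_b / n
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}

#' @export
print.segment_map <- function(x, ...) {
  cat(sprintf("<segment_map> %d segments over %d pixels\n", x$n_segments,
              sum(!is.na(x$assignment))))
  sizes <- vapply(x$pixels, length, integer(1))
  df <- data.frame(segment = seq_along(sizes) - 1L, size = sizes,
                   cohesion = round(x$cohesion, 4),
                   color = round(x$colors, 3))
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
summary.segment_map <- function(object, labels = NULL, ...) {
  print(object)
  if (!is.null(labels)) {
    m <- map_segments_to_regions(object, labels)
    cat("\nGround-truth overlap:\n")
    print(m$table, row.names = FALSE)
    cat(sprintf("macro purity %.3f\n", m$macro_purity))
  }
  invisible(object)
}

#' Render a segment map as a raster image
#'
#' Colours follow the correlation-ordered scale of [assign_colors()]
#' mapped through a continuous white-to-black colour bar, so segments
#' with similar fingerprints take nearby colours.
#'
#' @param x a `segment_map` with raster geometry.
#' @param ... passed to [graphics::image()].
#' @export
plot.segment_map <- function(x, ...) {
  if (is.null(x$coords)) stop("segment map carries no raster geometry")
  img <- matrix(NA_real_, x$height_px, x$width_px)
  idx <- cbind(x$coords$row + 1L, x$coords$col + 1L)
  img[idx] <- x$colors[x$assignment + 1L]
  pal <- grDevices::colorRampPalette(
    c("white", "#d7301f", "#41ae76", "#807dba", "black"))(256)
  graphics::image(t(img)[, rev(seq_len(nrow(img)))], col = pal,
                  zlim = c(0, 1), axes = FALSE, ...)
  invisible(x)
}

#' Write a segment map as PNG rasters with a JSON sidecar
#'
#' Writes an integer-coded segment raster (`*_ids.png`, segment id stored
#' as grey level, 255 = excluded), a colour rendering following the
#' correlation colour bar, and a JSON sidecar with sizes, colours,
#' cohesion and the split tree.
#'
#' @param map a `segment_map` with raster geometry.
#' @param path_prefix output path prefix.
#' @return invisibly, the files written.
#' @export
write_segment_map <- function(map, path_prefix) {
  if (is.null(map$coords)) stop("segment map carries no raster geometry")
  ids <- matrix(255L, map$height_px, map$width_px)
  idx <- cbind(map$coords$row + 1L, map$coords$col + 1L)
  keep <- !is.na(map$assignment)
  ids[idx[keep, , drop = FALSE]] <- map$assignment[keep]
  f_ids <- paste0(path_prefix, "_ids.png")
  png::writePNG(ids / 255, f_ids)
  img <- matrix(NA_real_, map$height_px, map$width_px)
  img[idx[keep, , drop = FALSE]] <- map$colors[map$assignment[keep] + 1L]
  pal <- grDevices::colorRampPalette(
    c("white", "#d7301f", "#41ae76", "#807dba", "black"))(256)
  rgb <- array(1, c(map$height_px, map$width_px, 3))
  flat <- !is.na(as.vector(img))
  vals <- as.vector(img)[flat]
  cols <- grDevices::col2rgb(pal[pmin(255, floor(vals * 255)) + 1]) / 255
  for (ch in 1:3) {
    plane <- rgb[, , ch]
    plane[flat] <- cols[ch, ]
    rgb[, , ch] <- plane
  }
  f_col <- paste0(path_prefix, "_colors.png")
  png::writePNG(rgb, f_col)
  sidecar <- list(
    n_segments = map$n_segments,
    sizes = vapply(map$pixels, length, integer(1)),
    colors = map$colors,
    cohesion = map$cohesion,
    tree = lapply(map$tree, function(nd)
      list(id = nd$id, parent = nd$parent, children = nd$children,
           n_pixels = length(nd$pixels), leaf = nd$leaf)))
  f_json <- paste0(path_prefix, ".json")
  jsonlite::write_json(sidecar, f_json, auto_unbox = TRUE, digits = NA)
  invisible(c(f_ids, f_col, f_json))
}
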