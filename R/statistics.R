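# Region fingerprint extraction and the downstream statistics: per-species
# Welch t-tests with star coding, PCA of the fingerprint table, and
# random-forest classification of region fingerprints with out-of-fold
# evaluation.

#' Lipid fingerprint of a region
#'
#' Mean over the region's pixels of the annotated-species intensities,
#' renormalized so the relative abundances sum to 1.
#'
#' @param features `feature_matrix` (or matrix) of pixels x peaks.
#' @param region_mask logical or integer vector selecting the region's
#'   pixels (rows).
#' @param species character vector naming each selected peak column; with
#'   `annotations` from [annotate_peaks()] the unique single-match columns
#'   are selected automatically.
#' @param annotations optional annotation table from [annotate_peaks()]
#'   (one row per peak-match, over the same peak list as `features`); used
#'   to pick the annotated columns and name them.
#' @return object of class `region_fingerprint`: named numeric vector of
#'   relative abundances (sums to 1) with attributes `class_rollup` and
#'   `n_pixels`.
#' @export
region_fingerprint <- function(features, region_mask, species = NULL,
                               annotations = NULL) {
  X <- .feature_values(features)
  rows <- if (is.logical(region_mask)) which(region_mask) else as.integer(region_mask)
  if (length(rows) == 0) stop("empty region mask")
  cols <- seq_len(ncol(X))
  if (!is.null(annotations)) {
    ann <- annotations[!is.na(annotations$name), , drop = FALSE]
    ann <- ann[ann$n_matches == 1L, , drop = FALSE]
    mzs <- if (inherits(features, "feature_matrix")) features$mz else NULL
    if (is.null(mzs)) stop("feature matrix without m/z column map")
    cols <- match(ann$peak_mz, mzs)
    species <- ann$name
  }
  if (is.null(species)) species <- as.character(cols)
  v <- colMeans(X[rows, cols, drop = FALSE])
  tot <- sum(v)
  if (tot <= 0) stop("zero total signal in region")
  v <- v / tot
  names(v) <- species
  cls <- tryCatch(class_rollup(v), error = function(e) NULL)
  structure(v, class_rollup = cls, n_pixels = length(rows),
            class = c("region_fingerprint", "numeric"))
}

#' Assemble a fingerprint table over samples and regions
#'
#' @param fingerprints list of `region_fingerprint` vectors (all over the
#'   same species set).
#' @param sample character/integer vector of sample (section) ids.
#' @param region character vector of region labels.
#' @return data.frame with `sample`, `region` and one column per species.
#' @export
fingerprint_table <- function(fingerprints, sample, region) {
  stopifnot(length(fingerprints) == length(sample),
            length(sample) == length(region))
  mat <- do.call(rbind, lapply(fingerprints, as.numeric))
  colnames(mat) <- names(fingerprints[[1]])
  data.frame(sample = sample, region = region, mat,
             check.names = FALSE, stringsAsFactors = FALSE)
}

#' Significance stars for a p value
#'
#' Thresholds as printed alongside the region comparisons:
#' `*` p < 0.05, `**` p < 0.01, `***` p < 0.0001.
#'
#' @param p p value(s) in `[0, 1]`.
#' @param thresholds named cut points; override to use a different
#'   three-star convention.
#' @return character vector of star codes (`""`, `"*"`, `"**"`, `"***"`).
#' @export
star_code <- function(p, thresholds = c("*" = 0.05, "**" = 0.01,
                                        "***" = 0.0001)) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  thresholds <- sort(thresholds, decreasing = TRUE)
  out <- rep("", length(p))
  for (k in seq_along(thresholds)) {
    out[!is.na(p) & p < thresholds[k]] <- names(thresholds)[k]
  }
  out
}

#' Compare species abundance between two regions across samples
#'
#' Two-sided t-test across samples (one fingerprint per sample and
#' region — animals, not pixels, are the unit of replication), Welch by
#' default. Star codes follow [star_code()]. An optional
#' Benjamini-Hochberg adjusted column is appended for transparency; the
#' stars themselves are per-species, unadjusted.
#'
#' @param table fingerprint table from [fingerprint_table()].
#' @param region_pair character vector of two region labels: difference
#'   and t are reported for `region_pair[2] - region_pair[1]`.
#' @param species columns to test (default: all species columns).
#' @param var_equal use the Student (pooled-variance) variant instead of
#'   Welch.
#' @return data.frame of class `comparison_table`: `species`, `mean_1`,
#'   `mean_2`, `mean_diff`, `t`, `df`, `p`, `star`, `p_bh`.
#' @export
compare_regions <- function(table, region_pair, species = NULL,
                            var_equal = FALSE) {
  stopifnot(length(region_pair) == 2)
  if (is.null(species)) species <- setdiff(names(table), c("sample", "region"))
  g1 <- table[table$region == region_pair[1], species, drop = FALSE]
  g2 <- table[table$region == region_pair[2], species, drop = FALSE]
  if (nrow(g1) < 2 || nrow(g2) < 2) {
    stop("insufficient replicates: need >= 2 samples per region, got ",
         nrow(g1), " and ", nrow(g2))
  }
  rows <- lapply(species, function(s) {
    x <- g1[[s]]; y <- g2[[s]]
    if (stats::sd(x) == 0 && stats::sd(y) == 0 && mean(x) == mean(y)) {
      tt <- list(statistic = c(t = 0), parameter = c(df = length(x) + length(y) - 2),
                 p.value = 1)
    } else {
      tt <- stats::t.test(y, x, var.equal = var_equal)
    }
    data.frame(species = s, mean_1 = mean(x), mean_2 = mean(y),
               mean_diff = mean(y) - mean(x),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$star <- star_code(out$p)
  out$p_bh <- stats::p.adjust(out$p, "BH")
  class(out) <- c("comparison_table", "data.frame")
  attr(out, "region_pair") <- region_pair
  out
}

#' PCA of a fingerprint table
#'
#' Mean-centred principal component analysis (no variance scaling by
#' default). The sign of each component is fixed so its largest-magnitude
#' loading is positive. Constant species columns are dropped with a
#' warning.
#'
#' @param table fingerprint table from [fingerprint_table()], or a plain
#'   numeric matrix.
#' @param scale. also scale columns to unit variance.
#' @return object of class `fingerprint_pca`: list with `scores`,
#'   `loadings`, `variance_explained` (fractions, non-increasing),
#'   `center`, `sdev`, plus `sample`/`region` when present in the input.
#' @export
pca_scores <- function(table, scale. = FALSE) {
  if (is.data.frame(table)) {
    meta <- table[intersect(c("sample", "region"), names(table))]
    X <- as.matrix(table[setdiff(names(table), c("sample", "region"))])
  } else {
    meta <- NULL
    X <- as.matrix(table)
  }
  if (nrow(X) < 3) stop("need at least 3 fingerprints for PCA")
  if (ncol(X) < 2) stop("need at least 2 species columns for PCA")
  const <- apply(X, 2, stats::sd) == 0
  if (any(const)) {
    warning("dropping ", sum(const), " constant species column(s): ",
            paste(colnames(X)[const], collapse = ", "))
    X <- X[, !const, drop = FALSE]
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = scale.)
  flip <- vapply(seq_len(ncol(pc$rotation)), function(k) {
    l <- pc$rotation[, k]
    sign(l[which.max(abs(l))])
  }, numeric(1))
  pc$rotation <- sweep(pc$rotation, 2, flip, `*`)
  pc$x <- sweep(pc$x, 2, flip, `*`)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(scores = pc$x, loadings = pc$rotation,
                 variance_explained = ve, center = pc$center,
                 sdev = pc$sdev, sample = meta$sample, region = meta$region),
            class = "fingerprint_pca")
}

#' @export
print.fingerprint_pca <- function(x, ...) {
  cat(sprintf("<fingerprint_pca> %d scores x %d components\n",
              nrow(x$scores), ncol(x$scores)))
  ve <- round(100 * x$variance_explained[seq_len(min(3, length(x$variance_explained)))], 1)
  cat("variance explained (%):", paste(ve, collapse = ", "),
      if (length(x$variance_explained) > 3) "..." else "", "\n")
  invisible(x)
}

#' @export
plot.fingerprint_pca <- function(x, components = c(1, 2), ...) {
  s <- x$scores[, components, drop = FALSE]
  col <- if (!is.null(x$region)) as.integer(factor(x$region)) + 1L else 1L
  ve <- round(100 * x$variance_explained[components], 1)
  graphics::plot(s[, 1], s[, 2], col = col, pch = 19,
                 xlab = sprintf("PC%d (%.1f%%)", components[1], ve[1]),
                 ylab = sprintf("PC%d (%.1f%%)", components[2], ve[2]), ...)
  if (!is.null(x$region)) {
    graphics::legend("topright", legend = levels(factor(x$region)),
                     col = seq_along(levels(factor(x$region))) + 1L, pch = 19,
                     bty = "n")
  }
  invisible(x)
}

#' Classification metrics from a confusion matrix
#'
#' Per-class precision, sensitivity (recall) and one-vs-rest specificity,
#' with macro averages.
#'
#' @param confusion square table/matrix, rows = truth, columns = predicted.
#' @return list: `per_class` data.frame, `macro` named vector, `accuracy`.
#' @export
confusion_metrics <- function(confusion) {
  cm <- as.matrix(confusion)
  stopifnot(nrow(cm) == ncol(cm))
  n <- sum(cm)
  per <- lapply(seq_len(nrow(cm)), function(k) {
    tp <- cm[k, k]
    fn <- sum(cm[k, ]) - tp
    fp <- sum(cm[, k]) - tp
    tn <- n - tp - fn - fp
    data.frame(class = rownames(cm)[k] %||% as.character(k),
               precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
               sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
               specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  list(per_class = per,
       macro = c(precision = mean(per$precision),
                 sensitivity = mean(per$sensitivity),
                 specificity = mean(per$specificity)),
       accuracy = sum(diag(cm)) / n)
}

#' Random-forest classification of region fingerprints
#'
#' Trains a random forest (500 trees, sqrt(p) candidate species per
#' split) and evaluates it strictly out-of-fold: leave-one-sample-out
#' (all regions of one section held out together, the default) or
#' stratified k-fold over samples. Metrics come from the pooled
#' out-of-fold confusion matrix.
#'
#' @param table fingerprint table from [fingerprint_table()] (needs
#'   `sample` and `region` columns).
#' @param scheme `"loso"` (leave-one-sample-out) or `"kfold"`.
#' @param k folds for `scheme = "kfold"`.
#' @param ntree trees per forest.
#' @param seed RNG seed (forest growth and fold assignment).
#' @return object of class `classification_report`: list with `confusion`
#'   (rows = truth), `per_class`, `macro`, `accuracy`, `scheme`, `seed`,
#'   `predictions`.
#' @export
classify_regions <- function(table, scheme = c("loso", "kfold"), k = 3,
                             ntree = 500, seed = 0) {
  scheme <- match.arg(scheme)
  region <- factor(table$region)
  if (nlevels(region) < 2) stop("need at least 2 classes to classify")
  X <- as.matrix(table[setdiff(names(table), c("sample", "region"))])
  samples <- unique(table$sample)
  folds <- local_seed(seed, {
    if (scheme == "loso") {
      stats::setNames(seq_along(samples), samples)
    } else {
      stats::setNames(sample(rep(seq_len(k), length.out = length(samples))),
                      samples)
    }
  })
  fold_of <- folds[as.character(table$sample)]
  pred <- factor(rep(NA_character_, nrow(X)), levels = levels(region))
  skipped <- character(0)
  for (f in sort(unique(fold_of))) {
    test <- fold_of == f
    train_region <- droplevels(region[!test])
    if (nlevels(train_region) < 2) {
      skipped <- c(skipped, as.character(f))
      next
    }
    fit <- local_seed(child_seed(seed, f), {
      randomForest::randomForest(
        x = X[!test, , drop = FALSE], y = train_region, ntree = ntree,
        mtry = max(1, floor(sqrt(ncol(X)))))
    })
    pred[test] <- as.character(stats::predict(fit, X[test, , drop = FALSE]))
  }
  if (length(skipped) > 0) {
    warning("fold(s) without at least 2 training classes skipped: ",
            paste(skipped, collapse = ", "),
            "; metrics cover the remaining folds")
  }
  ok <- !is.na(pred)
  cm <- table(truth = region[ok], predicted = pred[ok])
  m <- confusion_metrics(cm)
  structure(list(confusion = cm, per_class = m$per_class, macro = m$macro,
                 accuracy = m$accuracy, scheme = scheme, seed = seed,
                 predictions = data.frame(sample = table$sample,
                                          region = as.character(region),
                                          predicted = as.character(pred),
                                          stringsAsFactors = FALSE)),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("<classification_report> scheme=%s accuracy=%.3f\n",
              x$scheme, x$accuracy))
  print(x$per_class, row.names = FALSE)
  cat("confusion (rows = truth):\n")
  print(x$confusion)
  invisible(x)
}
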