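# Region fingerprints, Welch comparisons with stars, PCA, random forest.

make_table <- function(n_samples = 6, sep = 4, seed = 42) {
  # three "regions" with mean-shifted species plus noise
  set.seed(seed)
  regions <- c("white_matter", "peri_lesion", "lesion_core")
  rows <- list(); sample <- character(0); region <- character(0)
  for (s in seq_len(n_samples)) {
    for (k in seq_along(regions)) {
      v <- abs(rnorm(8, mean = 10) + sep * (k - 1) * c(1, -1, 1, 0, 0, 1, -1, 0))
      rows <- c(rows, list(v / sum(v)))
      sample <- c(sample, paste0("s", s)); region <- c(region, regions[k])
    }
  }
  mat <- do.call(rbind, rows)
  colnames(mat) <- paste0("sp", 1:8)
  data.frame(sample = sample, region = region, mat)
}

test_that("region_fingerprint averages pixels and renormalizes", {
  X <- rbind(c(2, 2, 4), c(4, 2, 2), c(1, 1, 1))
  # identical pixels: fingerprint equals the renormalized pixel
  fp <- region_fingerprint(rbind(X[1, ], X[1, ]), 1:2,
                           species = c("a", "b", "c"))
  expect_equal(as.numeric(fp), c(0.25, 0.25, 0.5))
  # two pixels a and b: renormalized mean
  fp2 <- region_fingerprint(X, 1:2, species = c("a", "b", "c"))
  m <- (X[1, ] + X[2, ]) / 2
  expect_equal(as.numeric(fp2), m / sum(m))
  expect_equal(sum(fp2), 1)
  expect_error(region_fingerprint(X, integer(0)), "empty region mask")
  expect_error(region_fingerprint(X * 0, 1:2, species = c("a", "b", "c")),
               "zero total signal")
})

test_that("fingerprints equal templates on the noiseless phantom", {
  fix <- noiseless_fixture()
  tpl <- fix$templates
  ann <- annotate_peaks(fix$pp$peaklist, lipid_library(), tol_ppm = 5)
  for (r in c("white_matter", "lesion_core")) {
    fp <- region_fingerprint(fix$pp$features, region_pixels(fix, r),
                             annotations = ann)
    idx <- match(names(fp), tpl[[r]]$species)
    expect_false(anyNA(idx))
    want <- tpl[[r]]$abundance[idx]
    expect_lt(max(abs(fp - want / sum(want)) / (want / sum(want))), 1e-6)
  }
})

test_that("star codes reproduce the printed thresholds exactly", {
  expect_equal(star_code(c(0.9, 0.05, 0.049, 0.01, 0.009, 1e-4, 9.9e-5, 0)),
               c("", "", "*", "*", "**", "**", "***", "***"))
  expect_equal(star_code(0.03), "*")
  # override for the conventional 0.001 three-star rule
  expect_equal(star_code(5e-4, c("*" = 0.05, "**" = 0.01, "***" = 0.001)),
               "***")
})

test_that("compare_regions matches the closed-form Welch t-test", {
  tab <- data.frame(
    sample = rep(paste0("s", 1:3), 2),
    region = rep(c("white_matter", "lesion_core"), each = 3),
    x = c(0.10, 0.11, 0.09, 0.30, 0.31, 0.29))
  out <- compare_regions(tab, c("white_matter", "lesion_core"), "x")
  # hand-computed Welch: d = 0.2, se = sqrt(2 * 1e-4 / 3), df = 4
  se <- sqrt(1e-4 / 3 + 1e-4 / 3)
  t_hand <- 0.2 / se
  p_hand <- 2 * pt(-abs(t_hand), df = 4)
  expect_equal(out$t, t_hand, tolerance = 1e-10)
  expect_equal(out$df, 4, tolerance = 1e-10)
  expect_equal(out$p, p_hand, tolerance = 1e-10)
  expect_equal(out$star, star_code(p_hand))
  expect_equal(out$mean_diff, 0.2)
  # identical groups: t = 0, p = 1, no star
  tab0 <- tab; tab0$x <- rep(c(0.1, 0.2, 0.3), 2)
  out0 <- compare_regions(tab0, c("white_matter", "lesion_core"), "x")
  expect_equal(out0$t, 0)
  expect_equal(out0$p, 1)
  expect_equal(out0$star, "")
  # swapping the pair flips the sign of the difference, not the p value
  rev_out <- compare_regions(tab, c("lesion_core", "white_matter"), "x")
  expect_equal(rev_out$mean_diff, -out$mean_diff)
  expect_equal(rev_out$t, -out$t)
  expect_equal(rev_out$p, out$p)
  expect_error(compare_regions(tab[-(1:2), ], c("white_matter", "lesion_core")),
               "insufficient replicates")
})

test_that("PCA satisfies its conservation and reconstruction contracts", {
  tab <- make_table()
  pca <- pca_scores(tab)
  expect_equal(sum(pca$variance_explained), 1)
  expect_true(all(diff(pca$variance_explained) <= 1e-12))
  # reconstruction with all components reproduces the centred table
  X <- as.matrix(tab[, -(1:2)])
  Xc <- scale(X, center = pca$center, scale = FALSE)
  expect_lt(max(abs(Xc - pca$scores %*% t(pca$loadings))), 1e-9)
  # sign convention: the largest-magnitude loading of each PC is positive
  for (k in seq_len(ncol(pca$loadings))) {
    l <- pca$loadings[, k]
    expect_gt(l[which.max(abs(l))], 0)
  }
  # collinear rows: PC1 carries all variance
  lin <- outer(c(1, 2, 3, 4), c(0.2, 0.3, 0.5))
  colnames(lin) <- c("a", "b", "c")
  p1 <- pca_scores(lin)
  expect_equal(p1$variance_explained[1], 1)
  # constant columns are dropped with a warning
  tab2 <- tab; tab2$sp1 <- 0.5
  expect_warning(pca_scores(tab2), "constant")
  expect_error(pca_scores(tab[1:2, ]), "at least 3")
})

test_that("classification metrics agree with the stored confusion matrix", {
  tab <- make_table(n_samples = 6, sep = 4)
  rep_ <- classify_regions(tab, scheme = "loso", ntree = 100, seed = 1)
  m <- confusion_metrics(rep_$confusion)
  expect_identical(rep_$per_class, m$per_class)
  expect_equal(rep_$accuracy, m$accuracy)
  expect_true(all(unlist(m$per_class[, -1]) >= 0 &
                    unlist(m$per_class[, -1]) <= 1))
  # well-separated classes are classified perfectly out of fold
  expect_equal(rep_$accuracy, 1)
  # metrics recomputed by hand from a known confusion matrix
  cm <- matrix(c(8, 2, 1, 9), 2, byrow = TRUE,
               dimnames = list(c("a", "b"), c("a", "b")))
  mm <- confusion_metrics(cm)
  expect_equal(mm$per_class$precision, c(8 / 9, 9 / 11))
  expect_equal(mm$per_class$sensitivity, c(0.8, 0.9))
  expect_equal(mm$per_class$specificity, c(0.9, 0.8))
  expect_error(classify_regions(within(tab, region <- "x")), "at least 2")
})

test_that("label permutation drives accuracy to chance", {
  tab <- make_table(n_samples = 5, sep = 4)
  set.seed(7)
  # within-section permutation keeps folds class-balanced (the correct
  # exchangeable unit for a leave-one-section-out design)
  acc <- replicate(30, {
    r <- split(tab$region, tab$sample)
    split(tab$region, tab$sample) <- lapply(r, sample)
    classify_regions(tab, ntree = 60, seed = 3)$accuracy
  })
  se <- sd(acc) / sqrt(length(acc))
  expect_lt(abs(mean(acc) - 1 / 3), 3 * max(se, 0.02))
})

test_that("vanishing effect sizes drive stars blank and accuracy to chance", {
  # effect_scale 0: all regions share one template; only jitter and noise
  tpl0 <- default_region_templates(effect_scale = 0)
  fps <- list(); sample <- character(0); region <- character(0)
  for (s in 1:5) {
    tps <- section_templates(tpl0, 0.15, seed = s)
    for (r in c("white_matter", "peri_lesion", "lesion_core")) {
      set.seed(s * 100 + match(r, names(tps)))
      v <- tps[[r]]$abundance * rlnorm(length(tps[[r]]$abundance), 0, 0.02)
      fp <- v / sum(v)
      fps <- c(fps, list(fp))
      sample <- c(sample, paste0("s", s)); region <- c(region, r)
    }
  }
  tab <- fingerprint_table(fps, sample, region)
  cmp <- compare_regions(tab, c("white_matter", "lesion_core"))
  expect_true(mean(cmp$star == "") > 0.9)   # at alpha 0.05, a few false stars allowed
  rep_ <- classify_regions(tab, ntree = 100, seed = 2)
  expect_lt(rep_$accuracy, 0.67)            # far from the separable regime
})
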