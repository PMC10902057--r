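# DHC-RC walker splits, divisive segmentation, colours, region mapping.

test_that("pixel_correlation is Pearson on fingerprints", {
  X <- rbind(a = c(1, 2, 3, 4), b = 2 * c(1, 2, 3, 4), c = c(4, 3, 2, 1))
  expect_equal(pixel_correlation(X, 1, 1), 1)
  expect_equal(pixel_correlation(X, 1, 2), 1)   # scale invariance
  expect_equal(pixel_correlation(X, 1, 3), -1)
  # orthonormal mean-centred fingerprints correlate 0
  Y <- rbind(c(1, -1, 0, 0), c(0, 0, 1, -1))
  expect_equal(pixel_correlation(Y, 1, 2), 0)
  expect_error(pixel_correlation(rbind(c(1, 1, 1), c(1, 2, 3)), 1, 2),
               "constant")
})

test_that("split_segment recovers perfect block structure", {
  set.seed(1)
  X <- rbind(matrix(rep(c(5, 0, 0), 2), 2, byrow = TRUE),
             matrix(rep(c(0, 5, 0), 2), 2, byrow = TRUE)) +
    0.01 * matrix(rnorm(12), 4)
  sp <- split_segment(X, 1:4)
  expect_equal(sp$left, 1:2)
  expect_equal(sp$right, 3:4)
  expect_error(split_segment(X, 2), "fewer than 2")
})

test_that("split_segment equals the exhaustive-search bipartition on small instances", {
  for (s in 1:20) {
    set.seed(s)
    n <- sample(4:10, 1)
    C <- cor(t(matrix(rnorm(n * 8), n)))
    sp <- split_segment(C, seq_len(n), walker_config(seed = s),
                        is_correlation = TRUE)
    oracle <- exhaustive_best_split(C)
    expect_equal(sp$objective, oracle$objective, tolerance = 1e-12)
  }
})

test_that("segmentation output is a valid deterministic partition", {
  fix <- noisy_fixture()
  m <- dhc_rc_segment(fix$pp, 4, walker_config(seed = 9))
  n <- nrow(fix$pp$features$values)
  # leaves are disjoint and cover every retained pixel
  expect_equal(sort(unlist(m$pixels)), seq_len(n))
  expect_equal(m$n_segments, 4L)
  expect_equal(sort(unique(m$assignment)), 0:3)
  expect_equal(vapply(m$pixels, length, 1L),
               as.integer(table(m$assignment)), ignore_attr = TRUE)
  # identical seed and input reproduce the identical map
  m2 <- dhc_rc_segment(fix$pp, 4, walker_config(seed = 9))
  expect_identical(m[c("assignment", "colors", "cohesion")],
                   m2[c("assignment", "colors", "cohesion")])
  # single segment: everything in one leaf
  m1 <- dhc_rc_segment(fix$pp, 1)
  expect_equal(unique(m1$assignment), 0L)
  expect_equal(m1$colors, 0.5)
  expect_error(dhc_rc_segment(fix$pp, n + 1), "exceeds")
})

test_that("relabelling pixel order permutes ids but not the partition", {
  fix <- noisy_fixture()
  X <- fix$pp$features$values[1:60, ]
  m <- dhc_rc_segment(X, 3, walker_config(seed = 4))
  perm <- rev(seq_len(nrow(X)))
  mp <- dhc_rc_segment(X[perm, ], 3, walker_config(seed = 4))
  back <- integer(nrow(X))
  back[perm] <- mp$assignment
  expect_equal(adjusted_rand_index(m$assignment, back), 1)
})

test_that("well-separated regions are recovered exactly without noise", {
  fix <- noiseless_fixture()
  m <- dhc_rc_segment(fix$pp, 4, walker_config(seed = 2))
  expect_equal(adjusted_rand_index(m$assignment, fix$labels), 1)
  mp <- map_segments_to_regions(m, fix$labels)
  expect_equal(mp$macro_purity, 1)
  expect_true(all(mp$recall == 1))
})

test_that("colour assignment follows the correlation-ordered scale", {
  # two segments sit at the scale's ends
  two <- structure(list(means = rbind(c(1, 2, 3), c(3, 2, 1)),
                        n_segments = 2L, pixels = list(1, 2)),
                   class = "segment_map")
  expect_setequal(assign_colors(two), c(0, 1))
  # three segments: 1-D embedding places B strictly nearer its correlate
  means <- rbind(A = c(1, 0.9, 0.8, 0.1), B = c(0.9, 1, 0.7, 0.2),
                 C = c(0.1, 0.3, 0.2, 1))
  fake <- structure(list(means = means, n_segments = 3L,
                         pixels = list(1, 2, 3)), class = "segment_map")
  cols <- assign_colors(fake)
  S <- cor(t(means))
  # oracle: extremes are the min-correlation pair, interior from the
  # embedding coordinate cor(s,a) - cor(s,b) rescaled to [0, 1]
  expect_setequal(cols[c(1, 3)], c(0, 1))
  p <- unname(S[, 1] - S[, 3])
  expect_equal(cols[2], (p[1] - p[2]) / (p[1] - p[3]))
  expect_lt(abs(cols[2] - cols[1]), abs(cols[2] - cols[3]))
  # colours are unique even for duplicated fingerprints
  dup <- structure(list(means = means[c(1, 2, 2), ], n_segments = 3L,
                        pixels = list(1, 2, 3)), class = "segment_map")
  expect_equal(anyDuplicated(assign_colors(dup)), 0L)
})

test_that("resegment isolates the selection and excludes the rest", {
  fix <- noisy_fixture()
  m <- dhc_rc_segment(fix$pp, 3, walker_config(seed = 5))
  # selecting every segment reproduces a fresh segmentation
  all_ids <- seq_len(m$n_segments) - 1L
  rs <- resegment(fix$pp, m, all_ids, 3, walker_config(seed = 5))
  expect_equal(adjusted_rand_index(rs$assignment, m$assignment), 1)
  # partial selection: non-selected pixels are excluded (NA)
  rs1 <- resegment(fix$pp, m, 0L, 2, walker_config(seed = 5))
  sel <- m$pixels[[1]]
  expect_true(all(is.na(rs1$assignment[-sel])))
  expect_true(all(!is.na(rs1$assignment[sel])))
  expect_equal(rs1$excluded, setdiff(seq_along(m$assignment), sel))
  # degenerate selections fail loudly
  expect_error(resegment(fix$pp, m, 7L, 2), "unknown segment")
  one_px <- which(vapply(m$pixels, length, 1L) >= 1)[1]
  expect_error(resegment(fix$pp, m, one_px - 1L,
                         length(m$pixels[[one_px]]) + 1L), "exceeds")
})

test_that("segment-to-region mapping reports purity with the documented tie rule", {
  # segmentation identical to labels: all purities 1
  labels <- c(2L, 2L, 1L, 1L, 4L, 4L)
  sm <- structure(list(assignment = c(0L, 0L, 1L, 1L, 2L, 2L),
                       pixels = list(1:2, 3:4, 5:6), n_segments = 3L),
                  class = "segment_map")
  mp <- map_segments_to_regions(sm, labels)
  expect_true(all(mp$table$purity == 1))
  expect_equal(mp$table$region, c(2L, 1L, 4L))
  # an even split resolves toward the lower region code at purity 0.5
  sm2 <- structure(list(assignment = c(0L, 0L, 0L, 0L),
                        pixels = list(1:4), n_segments = 1L),
                   class = "segment_map")
  mp2 <- map_segments_to_regions(sm2, c(1L, 1L, 3L, 3L))
  expect_equal(mp2$table$region, 1L)
  expect_equal(mp2$table$purity, 0.5)
  expect_error(map_segments_to_regions(sm2, c(1L, 2L)), "different pixel grids")
})

test_that("adjusted Rand index matches its closed form on known cases", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(4, 4, 7, 7)), 1)
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 2, 1, 2)), -0.5)
  a <- c(1, 1, 1, 2, 2, 3)
  b <- c(1, 1, 2, 2, 3, 3)
  # hand-computed: one co-clustered pair; expected (4*3)/15; max (4+3)/2
  expect_equal(adjusted_rand_index(a, b),
               (1 - 4 * 3 / 15) / (3.5 - 4 * 3 / 15))
})
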