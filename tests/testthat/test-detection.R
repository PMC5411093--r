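res_at <- voxel_resolution(100, 70)

test_that("thresholding groups supra-threshold voxels into components", {
  # empty map -> no detections
  zero <- probability_volume(array(0, c(8, 8, 3)), res_at)
  expect_identical(nrow(extract_detections(zero, 0.5)), 0L)
  expect_error(extract_detections(zero, 1.5), "\\(0, 1\\)")

  # two blobs separated by sub-threshold voxels -> two detections whose
  # centroids match the flood-fill oracle
  arr <- array(0, c(16, 16, 4))
  arr[3:5, 3:5, 2] <- 0.9
  arr[10:12, 11:13, 3] <- 0.8
  pv <- probability_volume(arr, res_at)
  det <- extract_detections(pv, 0.5, min_voxels = 2)
  expect_identical(nrow(det), 2L)
  lab <- oracle_flood_fill(arr >= 0.5)
  for (i in 1:2) {
    cen <- c(det$centroid_y[i], det$centroid_x[i], det$centroid_z[i]) + 0.5
    comp <- which(apply(arrayInd(which(lab > 0), dim(arr)), 1, function(p)
      sqrt(sum((p - cen)^2))) < 3)
    expect_gt(length(comp), 0)
  }
  oracle_centroids <- t(sapply(1:2, function(k)
    colMeans(arrayInd(which(lab == k), dim(arr))) - 0.5))
  got <- as.matrix(as.data.frame(det)[, c("centroid_y", "centroid_x",
                                          "centroid_z")])
  expect_equal(got[order(got[, 1]), ], oracle_centroids[order(oracle_centroids[, 1]), ],
               ignore_attr = TRUE)
  # peak probability and micrometre centroids are consistent
  expect_equal(sort(det$peak_probability), c(0.8, 0.9))
  expect_equal(det$centroid_y_um, det$centroid_y * 0.1)
  expect_equal(det$centroid_z_um, det$centroid_z * 0.07)
})

test_that("diagonal contact merges under 26- but not 6-connectivity", {
  arr <- array(0, c(8, 8, 2))
  arr[3, 3, 1] <- 0.9; arr[4, 4, 1] <- 0.9   # corner contact in-plane
  arr[6, 6, 1] <- 0.9; arr[6, 6, 2] <- 0.9   # face contact across slices
  pv <- probability_volume(arr, res_at)
  det26 <- extract_detections(pv, 0.5, min_voxels = 1, connectivity = 26)
  det6 <- extract_detections(pv, 0.5, min_voxels = 1, connectivity = 6)
  expect_identical(nrow(det26), 2L)
  expect_identical(nrow(det6), 3L)
  # agreement with the flood-fill oracle on a random map
  set.seed(8)
  rnd <- array(runif(14 * 14 * 4), c(14, 14, 4))
  for (conn in c(6, 26)) {
    lab <- oracle_flood_fill(rnd >= 0.8, connectivity = conn)
    det <- extract_detections(probability_volume(rnd, res_at), 0.8,
                              min_voxels = 1, connectivity = conn)
    expect_identical(nrow(det), max(lab))
  }
})

test_that("small components are suppressed by the minimum-size rule", {
  arr <- array(0, c(10, 10, 2))
  arr[2, 2, 1] <- 0.9                       # singleton: noise-like
  arr[6:7, 6, 1] <- 0.9                     # two voxels
  pv <- probability_volume(arr, res_at)
  expect_identical(nrow(extract_detections(pv, 0.5)), 1L)         # default 2
  expect_identical(nrow(extract_detections(pv, 0.5, min_voxels = 1)), 2L)
  expect_identical(nrow(extract_detections(pv, 0.5, min_voxels = 3)), 0L)
})

test_that("density curves are monotone and density-targeted thresholds work", {
  # a sparse map of isolated peaks of graded height (the detector's output
  # regime; on percolating noise maps component splitting can locally raise
  # counts, which is why sparsity matters)
  arr <- array(0, c(24, 24, 6))
  peaks <- expand.grid(y = c(4, 12, 20), x = c(4, 12, 20))
  hts <- seq(0.15, 0.95, length.out = nrow(peaks))
  for (i in seq_len(nrow(peaks)))
    arr[peaks$y[i] + (-1:1), peaks$x[i] + (-1:1), 3] <- hts[i]
  pv <- probability_volume(arr, res_at)
  curve <- density_curve(pv, seq(0.2, 0.8, by = 0.2))
  expect_true(all(diff(curve$n_detections) <= 0))
  expect_true(all(diff(curve$density_per_um3) <= 0))
  expect_error(density_curve(pv, numeric(0)), "non-empty")
  expect_error(density_curve(pv, c(0.5, 0.4)), "increasing")
  # threshold above the global maximum -> zero density
  high <- density_curve(probability_volume(arr * 0.3, res_at), c(0.5, 0.9))
  expect_equal(high$n_detections, c(0, 0))

  mk_curve <- function(th, dens) {
    structure(data.frame(threshold = th, n_detections = NA,
                         density_per_um3 = dens),
              class = c("density_curve", "data.frame"))
  }
  expect_equal(choose_threshold_by_density(
    mk_curve(c(0.4, 0.6, 0.8), c(1.5, 0.9, 0.3)), 0.9), 0.6)
  # equidistant densities tie-break towards the higher threshold
  expect_equal(choose_threshold_by_density(
    mk_curve(c(0.5, 0.7), c(1.0, 0.6)), 0.8), 0.7)
  # target below every density -> most conservative threshold available
  expect_equal(choose_threshold_by_density(
    mk_curve(c(0.2, 0.5, 0.8), c(5, 4, 3)), 0.1), 0.8)
})

test_that("greedy matching counts tp/fp/fn per the precision/recall definitions", {
  det <- function(m) data.frame(centroid_y_um = m[, 1], centroid_x_um = m[, 2],
                                centroid_z_um = m[, 3])
  tru <- function(m) data.frame(y_um = m[, 1], x_um = m[, 2], z_um = m[, 3])
  pts <- cbind(runif(10, 0, 5), runif(10, 0, 5), runif(10, 0, 1))

  # perfect one-to-one coverage
  ev <- match_detections(det(pts), tru(pts), tolerance_um = 0.3)
  expect_equal(ev$precision, 1)
  expect_equal(ev$recall, 1)

  # 8 of 10 truths matched plus 2 spurious detections -> P = R = 0.8
  set.seed(99)
  spaced <- cbind(seq(0.5, 9.5, by = 1), rep(2, 10), rep(0.5, 10))
  d8 <- rbind(spaced[1:8, ] + 0.05, cbind(c(50, 60), c(50, 60), c(1, 1)))
  ev2 <- match_detections(det(d8), tru(spaced), tolerance_um = 0.3)
  expect_identical(c(ev2$tp, ev2$fp, ev2$fn), c(8L, 2L, 2L) * 1L)
  expect_equal(ev2$precision, 0.8)
  expect_equal(ev2$recall, 0.8)
  expect_true(ev2$precision >= ev2$precision_ci[1] &&
                ev2$precision <= ev2$precision_ci[2])

  # two detections near one truth: one-to-one matching forces 1 tp + 1 fp
  ev3 <- match_detections(det(rbind(c(1, 1, 0.5), c(1.1, 1, 0.5))),
                          tru(rbind(c(1.05, 1, 0.5))), tolerance_um = 0.3)
  expect_identical(c(ev3$tp, ev3$fp, ev3$fn), c(1L, 1L, 0L) * 1L)
})

test_that("greedy matching achieves the optimal assignment on small scenes", {
  set.seed(123)
  for (rep in 1:20) {
    nd <- sample(0:8, 1); nt <- sample(1:8, 1)
    dm <- cbind(runif(nd, 0, 2), runif(nd, 0, 2), runif(nd, 0, 0.5))
    tm <- cbind(runif(nt, 0, 2), runif(nt, 0, 2), runif(nt, 0, 0.5))
    ev <- match_detections(
      data.frame(centroid_y_um = dm[, 1], centroid_x_um = dm[, 2],
                 centroid_z_um = dm[, 3]),
      data.frame(y_um = tm[, 1], x_um = tm[, 2], z_um = tm[, 3]),
      tolerance_um = 0.5)
    ok <- matrix(FALSE, nd, nt)
    if (nd > 0) for (i in 1:nd) for (j in 1:nt)
      ok[i, j] <- sqrt(sum((dm[i, ] - tm[j, ])^2)) <= 0.5
    expect_identical(ev$tp, as.integer(oracle_max_matching(ok)))
  }
})

test_that("Agresti-Coull intervals match hand evaluation and clip at the edges", {
  # x = 88, n = 100 at 95%: adjusted p ~ 0.8659, half-width ~ 0.0655
  ci <- agresti_coull_interval(88, 100)
  expect_equal(ci[1], 0.800, tolerance = 1e-2)
  expect_equal(ci[2], 0.931, tolerance = 1e-2)
  z <- qnorm(0.975)
  expect_equal(ci, c((88 + z^2 / 2) / (100 + z^2) -
                       z * sqrt((88 + z^2 / 2) / (100 + z^2) *
                                  (1 - (88 + z^2 / 2) / (100 + z^2)) /
                                  (100 + z^2)),
                     (88 + z^2 / 2) / (100 + z^2) +
                       z * sqrt((88 + z^2 / 2) / (100 + z^2) *
                                  (1 - (88 + z^2 / 2) / (100 + z^2)) /
                                  (100 + z^2))),
               tolerance = 1e-12)
  expect_equal(agresti_coull_interval(0, 10)[1], 0)
  expect_equal(agresti_coull_interval(10, 10)[2], 1)
  expect_error(agresti_coull_interval(5, 0), "trials")
  expect_error(agresti_coull_interval(11, 10), "successes")
})

test_that("detections export to CSV and evaluations to JSON", {
  arr <- array(0, c(10, 10, 2)); arr[4:5, 4:5, 1] <- 0.9
  det <- extract_detections(probability_volume(arr, res_at), 0.5)
  td <- withr::local_tempdir()
  f <- write_detections_csv(det, file.path(td, "d.csv"))
  back <- read.csv(f, check.names = FALSE)
  expect_equal(back$n_voxels, det$n_voxels)
  ev <- match_detections(det, data.frame(y_um = 0.4, x_um = 0.4, z_um = 0.05),
                         tolerance_um = 0.3)
  j <- write_evaluation_json(ev, file.path(td, "e.json"))
  parsed <- jsonlite::fromJSON(j)
  expect_identical(parsed$tp + parsed$fp, nrow(det))
})
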