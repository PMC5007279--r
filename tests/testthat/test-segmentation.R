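test_that("segment partitioning follows the plane conventions", {
  sd <- partition_segments(120L, 10, 40, 95)
  expect_identical(sd$cervical, 10:39)
  expect_identical(sd$dorsal, 40:95)
  # conservation: cervical + dorsal = d12 - occiput + 1
  expect_identical(length(sd$cervical) + length(sd$dorsal), 95L - 10L + 1L)
  for (k in 1:20) {
    o <- sample(1:50, 1); c7 <- o + sample(1:30, 1); d <- c7 + sample(0:30, 1)
    s <- partition_segments(120L, o, c7, d)
    expect_identical(length(s$cervical) + length(s$dorsal), d - o + 1L)
  }
  expect_error(partition_segments(120L, 40, 10, 95), "occiput < c7")
  expect_error(partition_segments(120L, 10, 40, 150), "within the volume")
})

test_that("a phantom slice is segmented with accurate masks", {
  ph <- small_phantom()
  cfg <- fast_seg_config()
  fit <- segment_slice(ph$ct$data[, , 5], 1, NULL, cfg)
  expect_identical(fit$status, "ok")
  # canal parameters within one cell of truth
  expect_lte(abs(fit$canal$a - 0.35), 0.02 + 1e-12)
  expect_lte(abs(fit$canal$b - 0.15), 0.02 + 1e-12)
  # mask areas close to the analytic enclosed areas (in px^2)
  canal_true <- curve_area(three_convexity_params(0.35, 0.15)) * 55^2
  cord_true <- pi * 0.11 * 0.07 * 55^2
  expect_lt(abs(sum(fit$canal_mask) - canal_true) / canal_true, 0.05)
  expect_lt(abs(sum(fit$cord_mask) - cord_true) / cord_true, 0.05)
  expect_true(all(fit$canal_mask[fit$cord_mask]))   # nesting
})

test_that("an air slice yields no curve", {
  expect_error(segment_slice(matrix(-1000, 64, 64), 1, NULL,
                             fast_seg_config()),
               class = "no_curve_found")
})

test_that("a circular canal produces a near-circular mask", {
  tr <- small_truth(canal_b = 0)
  ph <- generate_phantom(tr, shape = c(64, 64, 16), spacing = c(1, 1, 2))
  fit <- segment_slice(ph$ct$data[, , 5], 1, NULL, fast_seg_config())
  expect_lte(abs(fit$canal$b), 0.02 + 1e-12)
  # second-moment eccentricity of the canal mask
  idx <- which(fit$canal_mask, arr.ind = TRUE)
  cc <- colMeans(idx)
  mxx <- mean((idx[, 1] - cc[1])^2); myy <- mean((idx[, 2] - cc[2])^2)
  mxy <- mean((idx[, 1] - cc[1]) * (idx[, 2] - cc[2]))
  l <- sort(eigen(matrix(c(mxx, mxy, mxy, myy), 2))$values)
  expect_lt(sqrt(1 - l[1] / l[2]), 0.15)
})

test_that("volume run recovers phantom volumes and properties hold", {
  ph <- small_phantom()
  seg <- small_segmentation()
  # all slices fitted on the noise-free phantom
  expect_true(all(seg$fits$status == "ok"))
  # nesting on every slice
  for (k in seq_along(seg$cord_masks))
    expect_true(all(seg$canal_masks[[k]][seg$cord_masks[[k]]]))
  # volumes within 10% of analytic truth
  tv <- ph$truth_record$volumes
  for (sg in c("cervical", "dorsal")) {
    got <- seg$volumes[seg$volumes$segment == sg, ]
    want <- tv[tv$segment == sg, ]
    expect_lt(abs(got$canal_volume_ml - want$canal_volume_ml) /
                want$canal_volume_ml, 0.10)
    expect_lt(abs(got$cord_volume_ml - want$cord_volume_ml) /
                want$cord_volume_ml, 0.10)
  }
  # per-slice parameter recovery within one cell
  tr <- ph$truth_record$fits
  m <- merge(seg$fits, tr, by = "slice")
  expect_true(all(abs(m$canal_a.x - m$canal_a.y) <= 0.02 + 1e-12))
  expect_true(all(abs(m$canal_b.x - m$canal_b.y) <= 0.02 + 1e-12))
  expect_true(all(abs(m$cord_a.x - m$cord_a.y) <= 0.02 + 1e-12))
  expect_true(all(abs(m$cord_b.x - m$cord_b.y) <= 0.02 + 1e-12))
})

test_that("segmentation is deterministic", {
  ph <- small_phantom()
  segdef <- partition_segments(ph$ct, 2L, 8L, 14L)
  s1 <- small_segmentation()
  s2 <- segment_volume_run(ph$ct, segdef, fast_seg_config())
  expect_identical(s1$fits, s2$fits)
  expect_identical(s1$canal_masks, s2$canal_masks)
  expect_identical(s1$cord_masks, s2$cord_masks)
})

test_that("tidy/glance/autoplot expose the fit table", {
  seg <- small_segmentation()
  td <- tidy(seg)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("slice", "segment", "canal_a", "status") %in% names(td)))
  gl <- glance(seg)
  expect_identical(nrow(gl), 1L)
  expect_equal(gl$fit_rate, 1)
  expect_s3_class(autoplot(seg), "ggplot")
})

test_that("mask volume arithmetic is exact", {
  m <- lapply(1:10, function(i) matrix(TRUE, 10, 10))
  expect_equal(compute_volume(m, c(1, 1, 1)), 1.0)       # 1000 voxels
  expect_equal(compute_volume(list(matrix(FALSE, 5, 5)), c(1, 1, 1)), 0)
  # the reported mean cervical cord volume as a unit check
  arr <- array(FALSE, c(30, 30, 16))
  arr[seq_len(13990)] <- TRUE
  expect_equal(compute_volume(arr, c(1, 1, 1)), 13.99)
  expect_error(compute_volume(list(matrix(TRUE, 2, 2), matrix(TRUE, 3, 3)),
                              c(1, 1, 1)), "shapes differ")
  expect_error(compute_volume(m, c(1, -1, 1)), "spacing")
})
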