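test_that("SUV definition closes on uniform distributions", {
  s <- subject_info(370, 74)
  expect_equal(compute_suv(5, s), 1.0)        # 5 kBq/mL, 370 MBq, 74 kg
  expect_equal(compute_suv(0, s), 0)
  expect_equal(compute_suv(10, s), 2.0)
  expect_error(subject_info(0, 74), "activity")
  expect_error(subject_info(370, -1), "weight")
  expect_error(compute_suv(-1, s), ">= 0")
  # explicit decay correction with the 18F half-life
  s2 <- subject_info(370, 74, decay_corrected = FALSE,
                     uptake_time_min = 109.77)
  expect_equal(compute_suv(2.5, s2), 1.0)
})

test_that("mask-mean SUV averages exactly", {
  s <- subject_info(370, 74)
  pet <- image_volume(array(5, c(4, 4, 3)), c(1, 1, 1), "PET")
  m <- list(`1` = matrix(TRUE, 4, 4), `2` = matrix(FALSE, 4, 4))
  expect_equal(mean_suv_in_mask(pet, m, s), 1.0)
  # two voxels with SUVs 1 and 3 average to 2
  pet$data[1, 1, 2] <- 15
  m2 <- matrix(FALSE, 4, 4); m2[1, 1] <- TRUE
  expect_equal(mean_suv_in_mask(pet, list(`1` = m2, `2` = m2), s), 2.0)
  expect_error(mean_suv_in_mask(pet, list(`1` = matrix(FALSE, 4, 4)), s),
               "empty")
  expect_error(mean_suv_in_mask(pet, list(`1` = matrix(TRUE, 3, 3)), s),
               "grids")
})

test_that("liver normalization behaves as a ratio", {
  expect_equal(normalize_to_liver(2, 2), 1.0)
  expect_equal(normalize_to_liver(1.64, 2.0), 0.82)
  expect_error(normalize_to_liver(1, 0), "> 0")
})

test_that("whole-cord NSUV is the volume-weighted mean of the segments", {
  expect_equal(whole_cord_nsuv(0.7, 0.7, 3, 9), 0.7)
  # the reported group means and volumes combine to 0.8011
  expect_equal(whole_cord_nsuv(0.99, 0.72, 13.99, 32.60),
               (0.99 * 13.99 + 0.72 * 32.60) / (13.99 + 32.60))
  expect_equal(round(whole_cord_nsuv(0.99, 0.72, 13.99, 32.60), 4), 0.8011)
  expect_equal(whole_cord_nsuv(0.9, 0.5, 0, 10), 0.5)
  expect_error(whole_cord_nsuv(1, 1, 0, 0), "zero")
  expect_error(whole_cord_nsuv(1, 1, -1, 2), ">= 0")
})

test_that("whole-cord NSUV is a symmetric convex combination", {
  set.seed(31)
  ok <- sym <- logical(10000)
  for (k in 1:10000) {
    ns <- runif(2, 0.1, 2)
    v <- runif(2, 0.01, 100)
    sc <- whole_cord_nsuv(ns[1], ns[2], v[1], v[2])
    ok[k] <- sc >= min(ns) - 1e-12 && sc <= max(ns) + 1e-12
    sym[k] <- isTRUE(all.equal(sc, whole_cord_nsuv(ns[2], ns[1], v[2], v[1])))
  }
  expect_true(all(ok))
  expect_true(all(sym))
})

test_that("NSUVs are invariant to global scanner scaling", {
  ph <- small_phantom()
  seg <- small_segmentation()
  liver <- 2.37   # arbitrary reference
  r1 <- uptake_report(seg, ph$pet, ph$subject, liver)
  pet_k <- ph$pet; pet_k$data <- pet_k$data * 3.7
  r2 <- uptake_report(seg, pet_k, ph$subject, liver * 3.7)
  expect_equal(r2$table$cord_nsuv, r1$table$cord_nsuv, tolerance = 1e-12)
  expect_equal(r2$sc_nsuv, r1$sc_nsuv, tolerance = 1e-12)
})

test_that("phantom uptake is recovered through the masks within 10%", {
  ph <- small_phantom()
  seg <- small_segmentation()
  liver <- ph$truth_record$liver_suv
  rep <- uptake_report(seg, ph$pet, ph$subject, liver)
  tr <- ph$truth_record
  # dorsal segment (typical contrast) and the whole cord close within 10%;
  # the high-contrast cervical extreme carries a larger partial-volume
  # bias and is characterized in the blur test below
  got_d <- rep$table$cord_nsuv[rep$table$segment == "dorsal"]
  expect_lt(abs(got_d - tr$dorsal_nsuv) / tr$dorsal_nsuv, 0.10)
  truth_sc <- whole_cord_nsuv(tr$cervical_nsuv, tr$dorsal_nsuv,
                              tr$volumes$cord_volume_ml[1],
                              tr$volumes$cord_volume_ml[2])
  expect_lt(abs(rep$sc_nsuv - truth_sc) / truth_sc, 0.10)
  # broom-style accessors
  expect_identical(tidy(rep), rep$table)
  expect_equal(glance(rep)$sc_nsuv, rep$sc_nsuv)
  expect_s3_class(autoplot(rep), "ggplot")
})

test_that("PSF-blurred cord uptake is recovered within 10% at >= 2x FWHM", {
  # cord minor diameter 8.8 mm >= 2 x 4 mm FWHM, typical uptake contrast
  tr <- phantom_truth(nslice = 16L, occiput = 2L, c7 = 8L, d12 = 14L,
                      cord_a = 0.11, cord_b = 0.08, cord_c = 0.01,
                      cord_d = -0.03, cervical_nsuv = 0.82,
                      noise_sd = 0, drift_px = 0)
  ph <- generate_phantom(tr, c(64, 64, 16), c(1, 1, 2))
  px <- cbind(rep(1:64, times = 64), rep(1:64, each = 64))
  fr <- working_frame(c(32.5, 32.5), 55)
  m <- matrix(point_inside(pixel_to_frame(fr, px),
                           ellipse_params(0.11, 0.08, 0.01, -0.03)), 64, 64)
  masks <- setNames(lapply(2:7, function(s) m), 2:7)
  suv <- mean_suv_in_mask(ph$pet, masks, ph$subject)
  u <- tr$cervical_nsuv * tr$liver_suv
  expect_lt(abs(suv - u) / u, 0.10)
})

test_that("ideal body weight follows the published formula", {
  expect_equal(ideal_body_weight("male", 177.8), 71.0)     # 70 in
  expect_equal(ideal_body_weight("female", 152.4), 49.0)   # base case
  expect_equal(ideal_body_weight("female", 165.1), 49 + 1.7 * 5)
  expect_error(ideal_body_weight("male", 100), "undefined")
})
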