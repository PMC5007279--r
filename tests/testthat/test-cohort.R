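test_that("fifth-decile dichotomization uses lower interpolation", {
  d <- dichotomize_fifth_decile(1:10)
  expect_equal(d$threshold, 5)
  expect_length(d$low, 5)
  expect_length(d$high, 5)
  expect_warning(dichotomize_fifth_decile(rep(0.7, 8)), "degenerate")
  expect_error(dichotomize_fifth_decile(1), "at least 2")
  # partition property on random draws
  set.seed(41)
  for (k in 1:20) {
    v <- rnorm(sample(2:50, 1), 0.8, 0.3)
    d <- dichotomize_fifth_decile(v)
    expect_identical(length(d$low) + length(d$high), length(v))
  }
  co <- default_cohort(15, 15, seed = 3L)
  d <- dichotomize_fifth_decile(co$subjects$sc_nsuv)
  expect_identical(length(d$low) + length(d$high), 30L)
})

test_that("mortality rates reproduce the printed contingency arithmetic", {
  expect_identical(mortality_rate(13, 30), 43)   # overall
  expect_identical(mortality_rate(3, 16), 19)    # below-threshold group
  expect_identical(mortality_rate(10, 14), 71)   # above-threshold group
  expect_identical(mortality_rate(0, 7), 0)
  for (n in c(1, 7, 30)) {
    expect_identical(mortality_rate(n, n), 100)
    expect_identical(mortality_rate(0, n), 0)
  }
  expect_error(mortality_rate(1, 0), "> 0")
  expect_error(mortality_rate(5, 4), "\\[0, n\\]")
})

test_that("deaths-by-NSUV-group table reproduces the printed layout", {
  # 16 low values (3 deaths) and 14 high (10 deaths) around threshold 0.67
  set.seed(8)
  low <- c(sort(runif(14, 0.3, 0.66)), 0.67, 0.67)  # 15th and 16th at 0.67
  high <- sort(runif(14, 0.68, 1.6))
  death <- c(rep(1, 3), rep(0, 13), rep(1, 10), rep(0, 4))
  tab <- tibble::tibble(sc_nsuv = c(low, high), death = death)
  out <- mortality_by_nsuv_group(tab)
  expect_equal(out$threshold[1], 0.67)
  expect_identical(out$n, c(16L, 14L, 30L))
  expect_identical(out$mortality_pct, c(19, 71, 43))
})

test_that("group comparison reports means, SDs and a t test", {
  a <- c(1, 2, 3, 4)
  out <- compare_groups(a, a)
  expect_equal(out$p_value, 1)
  expect_equal(out$mean_a, out$mean_b)
  # fully separated groups with tiny jitter
  set.seed(42)
  g1 <- rnorm(4, 0, 1e-6); g2 <- 1 + rnorm(4, 0, 1e-6)
  expect_lt(compare_groups(g1, g2)$p_value, 0.001)
  expect_error(compare_groups(1, c(1, 2)), "at least 2")
  # degenerate equal constants: difference 0, p 1
  expect_equal(compare_groups(rep(1, 3), rep(1, 3))$p_value, 1)
})

test_that("the reported group separation is detectable at n = 30 per arm", {
  # power check at the generating means/SDs: significant in most replicates
  hits <- 0L
  for (seed in 1:20) {
    co <- default_cohort(30, 30, seed = seed)
    p <- compare_groups(co$subjects$sc_nsuv[co$subjects$group == "case"],
                        co$subjects$sc_nsuv[co$subjects$group == "control"])
    hits <- hits + (p$p_value < 0.05)
  }
  expect_gt(hits, 10L)
})

test_that("cohort tables round-trip through delimited text", {
  tab <- tibble::tibble(id = sprintf("P%02d", 1:6),
                        group = rep(c("case", "control"), 3),
                        sc_nsuv = c(0.9, 0.6, 0.7, 0.65, 1.1, 0.72),
                        survival_months = c(12, 36, 36, 30, 8, 36),
                        death = c(1, 0, 0, 1, 1, 0),
                        age = c(61, 70, 55, 66, 72, 58),
                        sex = rep(c("male", "female"), 3),
                        alsfrs_r = c(38, 44, 41, 35, 30, 47),
                        months_to_pet = c(9, 12, 20, 7, 5, 14),
                        riluzole = c(1, 0, 1, 1, 0, 1))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_cohort_table(tab, f)
  back <- read_cohort_table(f)
  expect_equal(as.data.frame(back), as.data.frame(tab))
  bad <- tab; bad$sc_nsuv[1] <- -1
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_cohort_table(bad, f2)
  expect_error(read_cohort_table(f2), "sc_nsuv")
})

test_that("survival hooks run over a cohort table", {
  skip_if_not_installed("survival")
  co <- default_cohort(15, 15, seed = 9L)
  tab <- tibble::tibble(sc_nsuv = co$subjects$sc_nsuv,
                        survival_months = round(runif(30, 6, 36)),
                        death = rbinom(30, 1, 0.4))
  out <- survival_by_nsuv_group(tab)
  expect_s3_class(out$km, "survfit")
  expect_s3_class(out$logrank, "survdiff")
})
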