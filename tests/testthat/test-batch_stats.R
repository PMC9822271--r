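results_of <- function(classes, f_max = NULL) {
  tibble::tibble(curve_index = seq_along(classes),
                 condition_label = "test",
                 n_events = ifelse(classes == "Type1", 0L, 1L),
                 f_max = if (is.null(f_max))
                   ifelse(classes == "Type1", 0, 400) else f_max,
                 class = classes)
}

test_that("type distribution counts and percentages are consistent", {
  dist <- type_distribution(results_of(c("Type1", "Type3")))
  expect_equal(dist$n_total, 2)
  expect_equal(unname(dist$percentages[c("Type1", "Type3")]), c(50, 50))
  expect_equal(sum(dist$counts), dist$n_total)
  expect_equal(sum(dist$percentages), 100, tolerance = 1e-9)

  all4 <- type_distribution(results_of(rep("Type4", 250)))
  expect_equal(unname(all4$percentages["Type4"]), 100)
  expect_error(type_distribution(results_of(character(0))), "empty")
})

test_that("success rate counts Types 3-6 over all recorded curves", {
  expect_equal(success_rate(type_distribution(results_of(c("Type1", "Type3")))),
               0.5)
  expect_equal(success_rate(type_distribution(results_of(rep("Type7", 5)))),
               0)
  # success and failure fractions always partition the batch
  set.seed(71)
  for (i in 1:20) {
    cls <- sample(class_codes(), 97, replace = TRUE)
    dist <- type_distribution(results_of(cls))
    fail <- sum(dist$counts[c("Type1", "Type2", "Type7")]) / dist$n_total
    expect_equal(success_rate(dist) + fail, 1)
  }
})

test_that("adhesion histogram bins half-open and conserves counts", {
  res <- results_of(rep("Type3", 3), f_max = c(100, 420, 430))
  h <- adhesion_histogram(res, bin_width = 50)
  lo <- h$breaks[-length(h$breaks)]
  expect_equal(h$counts[lo == 100], 1)
  expect_equal(h$counts[lo == 400], 2)
  expect_equal(sum(h$counts), 3)

  empty <- adhesion_histogram(results_of(character(0), f_max = numeric(0)))
  expect_true(all(empty$counts == 0))

  # boundary value 200 falls in [200, 250), not [150, 200)
  hb <- adhesion_histogram(results_of("Type2", f_max = 200), bin_width = 50)
  expect_equal(hb$counts[hb$breaks[-length(hb$breaks)] == 200], 1)

  set.seed(72)
  res <- results_of(rep("Type3", 400),
                    f_max = runif(400, 0, 2600))
  expect_equal(sum(adhesion_histogram(res, 50)$counts), 400)
  expect_error(adhesion_histogram(res, 0), "bin_width")
})

test_that("histogram mode of a single-interaction batch sits at ~400 pN", {
  set.seed(73)
  curves <- simulate_curves(preset_pristine(), 120,
                            classes = rep("Type3", 120))
  res <- classify_curves(curves)
  h <- adhesion_histogram(res, bin_width = 50)
  modal_lo <- h$breaks[which.max(h$counts)]
  expect_gte(modal_lo, 300)
  expect_lte(modal_lo, 450)
})

test_that("drift profile matches the hand-computed two-block example", {
  cls <- c(rep("Type1", 50), rep("Type3", 50))
  dp <- drift_profile(results_of(cls), window_size = 50)
  t1 <- dp$delta_pct[dp$class == "Type1"]
  expect_equal(t1, c(50, -50))
  expect_equal(dp$delta_pct[dp$class == "Type3"], c(-50, 50))
  expect_false(any(dp$partial))
})

test_that("window deltas average to zero for every class (identity)", {
  set.seed(74)
  for (i in 1:10) {
    cls <- sample(class_codes(), 250, replace = TRUE)
    dp <- drift_profile(results_of(cls), window_size = 50)
    means <- tapply(dp$delta_pct, dp$class, mean)
    expect_equal(as.vector(means), rep(0, 7), tolerance = 1e-12)
  }
})

test_that("uniform windows give zero drift; partial windows are flagged", {
  cls <- rep(c("Type1", "Type3"), 50)  # identical composition per window
  dp <- drift_profile(results_of(cls), window_size = 20)
  expect_equal(dp$delta_pct, rep(0, nrow(dp)))
  dpp <- drift_profile(results_of(rep("Type3", 55)), window_size = 50)
  expect_true(all(dpp$partial[dpp$window == 2]))
  expect_false(any(dpp$partial[dpp$window == 1]))
  expect_error(drift_profile(results_of(rep("Type3", 10)), 50),
               "window_size")
})

test_that("a stationary series shows no monotone drift trend", {
  set.seed(75)
  curves <- simulate_curves(preset_pristine(), 250)
  res <- classify_curves(curves)
  dp <- drift_profile(res, window_size = 50)
  for (cl in class_codes()) {
    d <- dp[dp$class == cl, ]
    fit <- summary(lm(delta_pct ~ window, data = d))
    tval <- fit$coefficients["window", "t value"]
    if (is.finite(tval)) expect_lt(abs(tval), 3)
  }
})

test_that("RMS roughness: closed forms and known-sigma recovery", {
  expect_equal(rms_roughness(matrix(5, 8, 8)), 0)
  checker <- outer(1:16, 1:16, function(i, j) ifelse((i + j) %% 2 == 0, 1, -1))
  expect_equal(rms_roughness(checker), 1)
  set.seed(76)
  hm <- matrix(rnorm(512 * 512, sd = 2), 512, 512)
  expect_equal(rms_roughness(hm), 2, tolerance = 0.05 / 2)
  # plane correction removes tilt entirely
  tilted <- hm + outer(seq_len(512) * 0.05, seq_len(512) * 0.02, `+`)
  expect_equal(rms_roughness(tilted, plane_correct = TRUE), 2,
               tolerance = 0.05 / 2)
  expect_gt(rms_roughness(tilted, plane_correct = FALSE), 5)
  expect_error(rms_roughness(matrix(c(1, NA, 3, 4), 2, 2)), "non-finite")
  expect_error(rms_roughness(matrix(1)), "2 x 2")
})

test_that("batch report bundles all statistics consistently", {
  set.seed(77)
  cls <- sample(class_codes(), 100, replace = TRUE,
                prob = preset_pristine()$mixture)
  rep <- batch_report(results_of(cls), window_size = 50, bin_width = 100)
  expect_equal(rep$n_total, 100)
  expect_equal(sum(unlist(rep$counts)), 100)
  expect_equal(sum(unlist(rep$histogram$counts)), 100)
  expect_length(rep$drift, 2)
  expect_equal(rep$success_rate,
               sum(cls %in% c("Type3", "Type4", "Type5", "Type6")) / 100)
})
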