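test_that("WLC force matches the interpolation formula at reference points", {
  m <- tether_model()
  expect_equal(wlc_force(0, m), 0)
  expect_equal(wlc_force(25, m), (4.114 / 0.38) * 1.25, tolerance = 1e-10)
  expect_equal(wlc_force(45, m), (4.114 / 0.38) * 25.65, tolerance = 1e-10)
  expect_error(wlc_force(50, m), "x < contour_length")
  expect_error(wlc_force(-1, m), "0 <= x")
})

test_that("WLC force is strictly increasing with the linear low-force limit", {
  m <- tether_model()
  x <- seq(0, 49.9, by = 0.01)
  expect_true(all(diff(wlc_force(x, m)) > 0))
  xs <- seq(0.05, 0.05 * m$contour_length, length.out = 20)
  linear <- 1.5 * m$kT / (m$persistence_length * m$contour_length) * xs
  expect_equal(wlc_force(xs, m) / linear, rep(1, 20), tolerance = 0.05)
})

test_that("WLC inversion is exact within the root-finding tolerance", {
  m <- tether_model()
  expect_equal(wlc_extension_at_force(0, m), 0)
  x_half <- wlc_extension_at_force((4.114 / 0.38) * 1.25, m)
  expect_equal(x_half / m$contour_length, 0.5, tolerance = 1e-4)
  for (f in c(10, 100, 1000)) {
    expect_equal(wlc_force(wlc_extension_at_force(f, m), m), f,
                 tolerance = 1e-6 / f)
  }
  expect_error(wlc_extension_at_force(-5, m), ">= 0")
})

test_that("tether model parameters are validated", {
  expect_error(tether_model(contour_length = 0), "positive")
  expect_error(tether_model(persistence_length = 60), "smaller")
})

test_that("noise-free rendering of each class classifies back to its label", {
  set.seed(81)
  for (cl in class_codes()) {
    for (rep in 1:5) {
      cu <- simulate_curve(cl, noise = FALSE)
      expect_equal(as.character(analyze_curve(cu)$class), cl)
      expect_equal(cu$metadata$true_class, cl)
    }
  }
})

test_that("per-type event structure matches the archetypes", {
  set.seed(82)
  # no interaction: zero events
  ft <- analyze_curve(simulate_curve("Type1", noise = FALSE))$features
  expect_equal(ft$n_events, 0)
  # single interaction: one event in (200, 650]
  ft <- analyze_curve(simulate_curve("Type3", noise = FALSE))$features
  expect_equal(ft$n_events, 1)
  expect_gt(ft$f_max, 200)
  expect_lte(ft$f_max, 650)
  # combined: at least two events with a very high maximum
  ft <- analyze_curve(simulate_curve("Type6", noise = FALSE))$features
  expect_gte(ft$n_events, 2)
  expect_gt(ft$f_max, 650)
  expect_lte(ft$f_max, 2000)
})

test_that("condition presets encode the expected composition constraints", {
  pr <- preset_pristine()$mixture
  bl <- preset_blocked()$mixture
  expect_equal(sum(pr), 1, tolerance = 1e-12)
  expect_equal(sum(bl), 1, tolerance = 1e-12)
  # pristine frequency ordering: T4 > T3 > T5 > T6
  expect_true(pr["Type4"] > pr["Type3"])
  expect_true(pr["Type3"] > pr["Type5"])
  expect_true(pr["Type5"] > pr["Type6"])
  # blocked: inversion of single vs multiple-independent, majority T1+T2
  expect_true(bl["Type3"] > bl["Type4"])
  expect_gt(bl["Type1"] + bl["Type2"], 0.5)
  expect_error(sim_condition("x", c(Type1 = 1)), "named over")
  expect_error(sim_condition("x", stats::setNames(rep(0.2, 7),
                                                  class_codes())),
               "sum to 1")
})

test_that("batch simulation is reproducible and mixture-faithful", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  m1 <- simulate_batch(preset_pristine(), 25, dir1, seed = 83)
  m2 <- simulate_batch(preset_pristine(), 25, dir2, seed = 83)
  expect_identical(m1$true_class, m2$true_class)
  expect_identical(readLines(file.path(dir1, "manifest.csv")),
                   readLines(file.path(dir2, "manifest.csv")))
  f <- m1$filename[7]
  expect_identical(readLines(file.path(dir1, f)),
                   readLines(file.path(dir2, f)))

  # empirical class fraction within 3 binomial sd of the preset weight
  curves <- simulate_curves(preset_blocked(), 400, seed = 84)
  truth <- vapply(curves, function(cu) cu$metadata$true_class, "")
  p <- preset_blocked()$mixture[["Type1"]]
  expect_lt(abs(mean(truth == "Type1") - p), 3 * sqrt(p * (1 - p) / 400))
})

test_that("rupture-force recovery is unbiased for single interactions", {
  curves <- simulate_curves(preset_pristine(), 150, seed = 85,
                            classes = rep("Type3", 150))
  res <- classify_curves(curves)
  truth <- vapply(curves, function(cu) attr(cu, "truth")$tethers$f_rupt,
                  numeric(1))
  # detected maximum adhesion force tracks the sampled bond strength
  expect_lt(mean(res$f_max - truth), 2 * sd(res$f_max - truth) / sqrt(150) + 5)
  expect_equal(mean(res$f_max), mean(truth), tolerance = 0.05)
})

test_that("unknown class codes are rejected", {
  expect_error(simulate_curve("Type9"), "arg")
})
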