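test_that("the decision rule maps the feature partition as defined", {
  cfg <- classifier_config()
  cases <- list(
    list(n = 0, f = 0, code = "Type1"),
    list(n = 1, f = 150, code = "Type2"),
    list(n = 2, f = 150, code = "Type2"),  # low adhesion beats peak count
    list(n = 1, f = 400, code = "Type3"),
    list(n = 3, f = 500, code = "Type4"),
    list(n = 1, f = 1200, code = "Type5"),
    list(n = 2, f = 1500, code = "Type6"),
    list(n = 1, f = 2500, code = "Type7")
  )
  for (cs in cases) {
    expect_equal(as.character(classify_curve(fake_features(cs$n, cs$f), cfg)),
                 cs$code)
  }
})

test_that("upper band limits are inclusive", {
  cfg <- classifier_config()
  expect_equal(as.character(classify_curve(fake_features(1, 200), cfg)),
               "Type2")
  expect_equal(as.character(classify_curve(fake_features(3, 200), cfg)),
               "Type2")
  expect_equal(as.character(classify_curve(fake_features(1, 650), cfg)),
               "Type3")
  expect_equal(as.character(classify_curve(fake_features(2, 650), cfg)),
               "Type4")
  expect_equal(as.character(classify_curve(fake_features(1, 2000), cfg)),
               "Type5")
  expect_equal(as.character(classify_curve(fake_features(2, 2000), cfg)),
               "Type6")
})

test_that("the rule is total: every feature vector gets exactly one class", {
  cfg <- classifier_config()
  grid_f <- c(seq(0.5, 2500, by = 7.3), 200, 650, 2000)
  for (n in 0:4) {
    fs <- if (n == 0) 0 else grid_f
    for (f in fs) {
      cls <- classify_curve(fake_features(n, f), cfg)
      expect_length(cls, 1)
      expect_false(is.na(cls))
      expect_true(as.character(cls) %in% class_codes())
    }
  }
})

test_that("invalid feature combinations are rejected", {
  expect_error(classify_curve(fake_features(0, 100)), "invalid features")
  expect_error(classify_curve(fake_features(2, 0)), "invalid features")
  expect_error(classify_curve(fake_features(-1, 10)), "invalid features")
})

test_that("artifact rules: force ceiling and quality flags", {
  cfg <- classifier_config()
  expect_true(is_artifact(fake_features(1, 2500), cfg))
  expect_false(is_artifact(fake_features(1, 400), cfg))
  for (flag in c("saturated", "overrange", "baseline-jump", "no-contact")) {
    expect_true(is_artifact(fake_features(1, 300, flags = flag), cfg))
    expect_equal(as.character(classify_curve(fake_features(1, 300,
                                                           flags = flag),
                                             cfg)),
                 "Type7")
  }
})

test_that("threshold configuration is validated and tunable", {
  expect_error(classifier_config(650, 200, 2000), "f_nonspecific < f_high")
  cfg <- classifier_config(f_nonspecific = 100, f_high = 300,
                           f_veryhigh = 900)
  expect_equal(as.character(classify_curve(fake_features(1, 250), cfg)),
               "Type3")
  expect_equal(as.character(classify_curve(fake_features(1, 950), cfg)),
               "Type7")
})

test_that("a constructed mini-batch classifies end to end", {
  dir <- withr::local_tempdir()
  curves <- list(
    simulate_curve("Type1", noise = FALSE, curve_index = 1L),
    simulate_single_rupture(400),
    simulate_curve("Type4", noise = FALSE, curve_index = 3L)
  )
  curves[[2]]$metadata$curve_index <- 2L
  for (i in 1:3) {
    write_fd_table(curves[[i]], file.path(dir, sprintf("c%d.tsv", i)))
  }
  write_manifest(data.frame(filename = sprintf("c%d.tsv", 1:3),
                            curve_index = 1:3,
                            condition_label = "test",
                            true_class = NA_character_), dir)
  res <- classify_batch(dir)
  expect_equal(res$class, c("Type1", "Type3", "Type4"))
  expect_equal(attr(res, "n_failed"), 0L)
})

test_that("unreadable curves flag their row but do not stop the batch", {
  dir <- withr::local_tempdir()
  write_fd_table(simulate_single_rupture(400),
                 file.path(dir, "good.tsv"))
  writeLines("garbage", file.path(dir, "bad.tsv"))
  write_manifest(data.frame(filename = c("good.tsv", "bad.tsv"),
                            curve_index = 1:2,
                            condition_label = "test",
                            true_class = NA_character_), dir)
  expect_warning(res <- classify_batch(dir), "could not be analysed")
  expect_equal(nrow(res), 2)
  expect_equal(attr(res, "n_failed"), 1L)
  expect_equal(res$flags[2], "read-error")
  expect_equal(res$class[1], "Type3")
})

test_that("an empty batch yields an empty table with a warning", {
  dir <- withr::local_tempdir()
  write_manifest(data.frame(filename = character(0),
                            curve_index = integer(0),
                            condition_label = character(0),
                            true_class = character(0)), dir)
  expect_warning(res <- classify_batch(dir), "empty batch")
  expect_equal(nrow(res), 0)
})
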