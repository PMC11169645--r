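test_that("confusion metric identities hold exactly for random integer tables", {
  expect_equal(confusion_metrics(3, 2, 1, 2)[, c("acc", "sen", "spe")],
               tibble::tibble(acc = 62.5, sen = 60, spe = 200 / 3))
  set.seed(22)
  for (i in 1:50) {
    counts <- sample(1:40, 4, replace = TRUE)
    m <- confusion_metrics(counts[1], counts[2], counts[3], counts[4])
    expect_equal(m$acc, 100 * (counts[1] + counts[2]) / sum(counts))
    expect_equal(m$sen, 100 * counts[1] / (counts[1] + counts[4]))
    expect_equal(m$spe, 100 * counts[2] / (counts[2] + counts[3]))
  }
})

test_that("zero-denominator ratios warn and report NaN, never silently 0", {
  expect_warning(m <- confusion_metrics(0, 5, 3, 0), "sensitivity")
  expect_true(is.nan(m$sen))
  expect_false(identical(m$sen, 0))
  expect_warning(m2 <- confusion_metrics(4, 0, 0, 2), "specificity")
  expect_true(is.nan(m2$spe))
})

test_that("evaluate matches a hand-tallied confusion table on 20 subjects", {
  spec <- cohort_spec(n_subjects_per_group = 10, n_rois = 6,
                      n_timepoints = 24, window_length = 24, n_states = 1,
                      community_partition = rep(1:2, each = 3),
                      effect_edges = rbind(c(1, 4)), affected_states = 1,
                      seed = 81)
  coh <- generate_cohort(spec)
  cfg <- astnet_config(n_rois = 6, mlp_dims = c(16, 8, 4),
                       head_dims = c(8, 4, 2), batch_size = 5, seed = 9)
  fit <- astnet_train(build_variant("MLP_s", cfg, n_timepoints = 24),
                      coh, epochs = 3)
  pred <- predict(fit, coh)
  tallied <- o_tally(pred$pred, pred$label)
  m <- suppressWarnings(evaluate(fit, coh))
  expect_identical(c(tp = m$tp, tn = m$tn, fp = m$fp, fn = m$fn), tallied)
})

test_that("vectorised Welch test matches stats::t.test to 1e-10", {
  set.seed(23)
  for (i in 1:100) {
    n1 <- sample(3:12, 1); n2 <- sample(3:12, 1)
    x <- matrix(rnorm(n1 * 3, sd = runif(1, 0.5, 2)), n1, 3)
    y <- matrix(rnorm(n2 * 3, mean = runif(1, -1, 1)), n2, 3)
    res <- welch_edge_test(x, y)
    for (j in 1:3) {
      ref <- stats::t.test(x[, j], y[, j])
      expect_equal(res$t[j], unname(ref$statistic), tolerance = 1e-10)
      expect_equal(res$p[j], ref$p.value, tolerance = 1e-10)
    }
  }
})

test_that("copy-identical groups give p = 1 everywhere and an all-ones binarized map", {
  spec <- tiny_spec(seed = 91, effect_size = 0)
  coh <- generate_cohort(spec)
  # make patients exact copies of controls
  for (i in 1:3) {
    coh$subjects[[3 + i]]$data <- coh$subjects[[i]]$data
  }
  maps <- group_difference_maps(coh, source = "pearson", window_length = 8)
  for (m in maps$maps) {
    expect_true(all(m$p_values == 1))
    expect_true(all(m$binarized == 1L))
  }
  expect_true(all(maps$static$binarized == 1L))
})

test_that("group difference maps are calibrated near 5% under the null", {
  spec <- cohort_spec(n_subjects_per_group = 50, n_rois = 12,
                      n_timepoints = 120, window_length = 20,
                      effect_size = 0, seed = 92)
  coh <- generate_cohort(spec)
  maps <- group_difference_maps(coh, source = "pearson", window_length = 20)
  frac <- mean(significant_fraction(maps))
  expect_gt(frac, 0.01)
  expect_lt(frac, 0.10)
})

test_that("group maps require both groups and expose model-derived sources", {
  spec <- tiny_spec(seed = 93)
  coh <- generate_cohort(spec)
  solo <- cohort_subset(coh, c(1, 2, 3, 4))  # 3 controls, 1 patient
  expect_error(group_difference_maps(solo, source = "pearson",
                                     window_length = 8), "at least 2")
  cfg <- tiny_config()
  fit <- astnet_train(astnet(cfg, n_windows = 3), coh, epochs = 2)
  md <- group_difference_maps(coh, fit, source = "connectivity")
  expect_length(md$maps, 3L)
  expect_true(all(md$maps[[1]]$p_values >= 0 & md$maps[[1]]$p_values <= 1))
  ma <- group_difference_maps(coh, fit, source = "adjacency")
  expect_identical(ma$source, "adjacency")
  td <- generics::tidy(md)
  expect_identical(nrow(td), 4L * 10L)  # 3 windows + static, C(5,2) edges
})

test_that("training history and metrics round-trip through CSV", {
  cfg <- tiny_config()
  coh <- generate_cohort(tiny_spec())
  path <- withr::local_tempfile(fileext = ".csv")
  fit <- astnet_train(build_variant("MLP_d", cfg, n_windows = 3), coh,
                      epochs = 3, history_path = path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(as.data.frame(back), as.data.frame(fit$history),
               tolerance = 1e-12)
  mpath <- withr::local_tempfile(fileext = ".csv")
  m <- suppressWarnings(evaluate(fit, coh))
  readr::write_csv(m, mpath)
  expect_equal(as.data.frame(readr::read_csv(mpath, show_col_types = FALSE)),
               as.data.frame(m), tolerance = 1e-12)
})

test_that("trainer rejects empty and single-class cohorts", {
  cfg <- tiny_config()
  m <- astnet(cfg, n_windows = 3)
  coh <- generate_cohort(tiny_spec())
  expect_error(astnet_train(m, cohort_subset(coh, integer(0))), "empty")
  expect_error(astnet_train(m, cohort_subset(coh, 1:3)), "single class")
})

test_that("same seed gives identical training histories; resuming extends them", {
  cfg <- tiny_config()
  coh <- generate_cohort(tiny_spec())
  f1 <- astnet_train(build_variant("MLP_d", cfg, n_windows = 3), coh,
                     epochs = 4)
  f2 <- astnet_train(build_variant("MLP_d", cfg, n_windows = 3), coh,
                     epochs = 4)
  expect_identical(f1$history, f2$history)
  f3 <- astnet_train(f1, coh, epochs = 2)
  expect_identical(nrow(f3$history), 6L)
  expect_identical(f3$history$epoch, 1:6)
})

test_that("window sweep re-partitions, records skips, and reproduces floor arithmetic", {
  spec <- cohort_spec(n_subjects_per_group = 5, n_rois = 6,
                      n_timepoints = 231, window_length = 20, n_states = 1,
                      community_partition = rep(1:2, each = 3),
                      effect_edges = rbind(c(1, 4)), effect_size = 0.5,
                      affected_states = 1, seed = 94)
  coh <- generate_cohort(spec)
  cfg <- astnet_config(n_rois = 6, mlp_dims = c(12, 8, 4),
                       head_dims = c(6, 4, 2), batch_size = 5, seed = 3)
  sw <- window_sweep(coh, coh, window_lengths = c(10, 15, 20, 25, 30, 300),
                     config = cfg, variant = "MLP_d", epochs = 2)
  expect_identical(sw$n_windows[1:5], c(23L, 15L, 11L, 9L, 7L))
  expect_true(sw$skipped[6])
  expect_true(all(!sw$skipped[1:5]))
  expect_identical(nrow(sw), 6L)
  expect_true(all(is.finite(sw$acc[1:5])))
})

test_that("tidiers and plots return the expected classes", {
  cfg <- tiny_config()
  coh <- generate_cohort(tiny_spec())
  fit <- astnet_train(build_variant("MLP_d", cfg, n_windows = 3), coh,
                      epochs = 2)
  td <- generics::tidy(fit)
  expect_named(td, c("epoch", "loss", "value"))
  gl <- generics::glance(fit)
  expect_identical(gl$variant, "MLP_d")
  expect_s3_class(ggplot2::autoplot(fit), "ggplot")
  maps <- group_difference_maps(coh, source = "pearson", window_length = 8)
  expect_s3_class(ggplot2::autoplot(maps), "ggplot")
})
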