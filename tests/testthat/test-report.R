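test_that("a homogeneous population yields a degenerate prevalence interval", {
  d <- simulate_survey_design(2, 4, 10, seed = 81, weight_sd = 0)
  lv <- factor(rep("healthy", 80), levels = c("healthy", "mixed", "unhealthy"))
  pr <- level_prevalence(lv, d, n_boot = 200, seed = 82)
  expect_equal(pr$proportion, c(1, 0, 0))
  expect_equal(pr$ci_low, c(1, 0, 0))
  expect_equal(pr$ci_high, c(1, 0, 0))
  expect_lt(abs(sum(pr$proportion) - 1), 1e-10)
})

test_that("equal weights reproduce the unweighted binomial proportion", {
  set.seed(83)
  d <- simulate_survey_design(5, 8, 30, seed = 84, weight_sd = 0)
  lv <- assign_level(rnorm(nrow(d), 100, 10))
  pr <- level_prevalence(lv, d, n_boot = 400, seed = 85)
  expect_equal(pr$proportion, as.numeric(table(lv) / length(lv)))
  # bootstrap CI roughly matches the analytic binomial interval
  p <- pr$proportion[1]
  half_analytic <- 1.96 * sqrt(p * (1 - p) / length(lv))
  half_boot <- (pr$ci_high[1] - pr$ci_low[1]) / 2
  expect_lt(abs(half_boot - half_analytic), half_analytic)
})

test_that("prevalence estimates respect the weights and the cluster labels", {
  d <- simulate_survey_design(2, 3, 20, seed = 86, weight_sd = 0)
  lv <- factor(c(rep("healthy", 20), rep("mixed", 100)),
               levels = c("healthy", "mixed", "unhealthy"))
  pr0 <- level_prevalence(lv, d, n_boot = 50, seed = 87)
  # doubling the healthy cluster's weight pulls prevalence toward it
  d2 <- d
  d2$weight[1:20] <- 2
  pr2 <- level_prevalence(lv, d2, n_boot = 50, seed = 87)
  expect_gt(pr2$proportion[1], pr0$proportion[1])
  expect_equal(pr2$proportion[1], 40 / 140, tolerance = 1e-12)
  # relabeling clusters leaves point estimates unchanged
  d3 <- d
  d3$cluster <- paste0("relabel_", d3$cluster)
  pr3 <- level_prevalence(lv, d3, n_boot = 50, seed = 87)
  expect_equal(pr3$proportion, pr0$proportion)
})

test_that("single-cluster strata are collapsed with a warning", {
  d <- data.frame(child_id = sprintf("c%02d", 1:40),
                  stratum = rep(c("s1", "s2"), c(10, 30)),
                  cluster = rep(c("c1", "c2", "c3", "c4"), each = 10),
                  weight = 1)
  lv <- assign_level(seq(85, 115, length.out = 40))
  expect_warning(level_prevalence(lv, d, n_boot = 50, seed = 88), "s1")
})

test_that("top foods rank by within-level reporting percentage", {
  rec <- data.frame(
    child_id = c("a", "a", "b", "b", "c"),
    occasion = c("breakfast", "breakfast", "breakfast", "lunch", "breakfast"),
    food = c("bread", "milk", "bread", "rice", "fruit"),
    stringsAsFactors = FALSE)
  lv <- data.frame(child_id = c("a", "b", "c"),
                   level = c("healthy", "healthy", "unhealthy"),
                   stringsAsFactors = FALSE)
  tf <- top_foods(rec, lv)
  bh <- tf[tf$occasion == "breakfast" & tf$level == "healthy", ]
  expect_identical(bh$food[1], "bread")
  expect_identical(bh$pct[1], 100)
  expect_identical(bh$food[2], "milk")
  expect_identical(bh$pct[2], 50)
  # singleton child: 100% blocks; mixed level absent entirely
  expect_false(any(tf$level == "mixed"))
  bu <- tf[tf$occasion == "breakfast" & tf$level == "unhealthy", ]
  expect_identical(bu$food, "fruit")
})

test_that("rank ties break alphabetically and k truncates the list", {
  rec <- data.frame(
    child_id = rep(c("a", "b"), each = 4),
    occasion = "dinner",
    food = c("rice", "beans", "sodas", "pasta",
             "rice", "beans", "sodas", "pasta"),
    stringsAsFactors = FALSE)
  lv <- data.frame(child_id = c("a", "b"), level = c("mixed", "mixed"))
  tf <- top_foods(rec, lv, k = 3)
  expect_identical(tf$food, c("beans", "pasta", "rice"))
  expect_identical(tf$pct, c(100, 100, 100))
})

test_that("the pipeline runs end to end and is reproducible under its seed", {
  cfg <- list(sim = list(n_respondents = 700, seed = 91), seed = 91,
              n_boot = 100,
              design = simulate_survey_design(2, 7, 50, seed = 92))
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  cfg$out_dir <- out1
  r1 <- suppressWarnings(run_pipeline(cfg))
  cfg$out_dir <- out2
  r2 <- suppressWarnings(run_pipeline(cfg))
  need <- c("records.csv", "responses18.csv", "dimensionality.csv",
            "calibration.csv", "model.json", "scores.csv", "dif_report.csv",
            "prevalence.csv", "top_foods.csv", "scale_table.csv")
  for (f in need) {
    expect_true(file.exists(file.path(out1, f)), info = f)
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)), info = f)
  }
  expect_s3_class(r1$fit$model, "ggum_model")
  expect_true(all(r1$scores$level %in% c("healthy", "mixed", "unhealthy")))
})

test_that("the pipeline skips DIF with a warning when groups are missing", {
  fr <- simulate_food_records(simulation_config(n_respondents = 600,
                                                seed = 93))
  w <- capture_warnings(res <- run_pipeline(list(records = fr$records,
                                                 seed = 93)))
  expect_true(any(grepl("DIF stage skipped", w)))
  expect_null(res$dif)
})
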