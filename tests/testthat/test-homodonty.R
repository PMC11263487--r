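test_that("residual stresses are median-normalized ratios", {
  expect_equal(residual_stress(c(1, 2, 3, 4, 5)), c(1, 2, 3, 4, 5) / 3)
  expect_equal(residual_stress(rep(2.5, 6)), rep(1, 6))
  x <- c(0.3, 1.1, 0.9, 4)
  expect_equal(residual_stress(x * 17), residual_stress(x))
  expect_equal(median(residual_stress(c(1, 2, 3, 4, 5))), 1)
  expect_error(residual_stress(c(1, -1, 2)), "positive")
  expect_error(residual_stress(3), "at least 2")
})

test_that("bootstrap null pools half-subsample residuals reproducibly", {
  expect_identical(unique(bootstrap_null(rep(3, 8), reps = 50, seed = 1)), 1)
  p1 <- bootstrap_null(1:10, reps = 100, seed = 42)
  expect_length(p1, 500L)  # reps * floor(n/2)
  expect_identical(p1, bootstrap_null(1:10, reps = 100, seed = 42))
  expect_false(identical(p1, bootstrap_null(1:10, reps = 100, seed = 43)))
  expect_error(bootstrap_null(1:3, seed = 1), "at least 4")
  # for a mildly varying dentition the pool is centered at 1
  stresses <- withr::with_seed(7, rlnorm(20, 0, 0.25))
  pool <- bootstrap_null(stresses, reps = 10000, seed = 7)
  expect_equal(median(pool), 1, tolerance = 0.05)
})

test_that("exact 1-D 2-medoids equals exhaustive medoid-pair search", {
  set.seed(33)
  for (i in 1:50) {
    x <- switch(1 + i %% 3,
                runif(sample(4:12, 1), 0, 3),
                rlnorm(sample(5:12, 1)),
                round(runif(sample(4:12, 1), 0, 2), 1))  # ties included
    exact <- dentition:::medoids2_1d(x)
    oracle <- brute_medoids2(x)
    expect_equal(medoid_cost(x, exact), medoid_cost(x, oracle), tolerance = 1e-12,
                 label = paste("pool", i))
  }
})

test_that("k-medoids thresholding resolves a bimodal pool exactly", {
  pool <- c(rep(0.5, 2500), rep(1.5, 2500))
  th <- kmedoids_threshold(pool, subsample = 5000, repeats = 5, seed = 1)
  expect_identical(th$upper_threshold, 1.0)  # medoids 0.5 and 1.5
  # subsample == pool size: no sampling variability across repeats
  one <- kmedoids_threshold(pool, subsample = 5000, repeats = 1, seed = 9)
  hundred <- kmedoids_threshold(pool, subsample = 5000, repeats = 100, seed = 10)
  expect_identical(one$upper_threshold, hundred$upper_threshold)
  # degenerate all-identical pool
  d <- kmedoids_threshold(rep(1, 100), seed = 1)
  expect_true(d$degenerate)
  expect_identical(d$upper_threshold, 1)
  expect_identical(d$lower_threshold, 1)
})

test_that("two-sided threshold modes behave as documented", {
  set.seed(5)
  pool <- rlnorm(20000, 0, 0.2)
  rec <- kmedoids_threshold(pool, subsample = 5000, repeats = 20, seed = 2,
                            two_sided = "reciprocal")
  expect_lt(rec$lower_threshold, 1)
  expect_gt(rec$upper_threshold, 1)
  mir <- kmedoids_threshold(pool, subsample = 5000, repeats = 20, seed = 2,
                            two_sided = "mirror_log")
  expect_equal(mir$lower_threshold, 1 / mir$upper_threshold)
  off <- kmedoids_threshold(pool, subsample = 5000, repeats = 20, seed = 2,
                            two_sided = "off")
  expect_identical(off$lower_threshold, 0)
})

test_that("classification applies the threshold band and summary metrics", {
  cl <- classify(c(0.9, 1.0, 1.1), upper = 1.5, lower = 0.5)
  expect_identical(cl$class, rep("homodont", 3))
  expect_identical(cl$proportion_heterodont, 0)
  cl2 <- classify(c(0.2, 1.0, 3.0), upper = 1.5, lower = 0.5)
  expect_identical(cl2$class, c("heterodont", "homodont", "heterodont"))
  expect_equal(cl2$proportion_heterodont, 2 / 3)
  expect_equal(classify(c(1, 1, 1), 2, 0.5)$avg_squared_residual, 1.0)
  expect_equal(classify(c(1, 3), 2, 0.5, center = "one")$avg_squared_residual, 2)
})

test_that("run_homodonty is deterministic, scale invariant and respects grouping", {
  traits <- data.frame(tooth = sprintf("t%02d", 1:20),
                       jaw_id = rep(c("A", "B"), each = 10),
                       side = "left",
                       stress = withr::with_seed(21, rlnorm(20, 0, 0.3)))
  r1 <- run_homodonty(traits, reps = 500, subsample = 500, repeats = 10, seed = 11)
  r2 <- run_homodonty(traits, reps = 500, subsample = 500, repeats = 10, seed = 11)
  expect_identical(r1, r2)
  expect_named(r1, c("A/left", "B/left"))
  # scale invariance: stresses x c leave everything unchanged
  sc <- traits; sc$stress <- sc$stress * 123.4
  r3 <- run_homodonty(sc, reps = 500, subsample = 500, repeats = 10, seed = 11)
  for (g in names(r1)) {
    expect_equal(r3[[g]]$residuals, r1[[g]]$residuals)
    expect_equal(r3[[g]]$upper_threshold, r1[[g]]$upper_threshold)
    expect_identical(r3[[g]]$class, r1[[g]]$class)
    expect_equal(r3[[g]]$avg_squared_residual, r1[[g]]$avg_squared_residual)
  }
  # substreams: adding a jaw never perturbs the others' results
  extra <- rbind(traits, data.frame(tooth = sprintf("x%02d", 1:8), jaw_id = "C",
                                    side = "left",
                                    stress = withr::with_seed(5, rlnorm(8, 0, 0.3))))
  r4 <- run_homodonty(extra, reps = 500, subsample = 500, repeats = 10, seed = 11)
  expect_identical(r4[["A/left"]], r1[["A/left"]])
  # a side with < 4 teeth is skipped with a warning
  small <- rbind(traits, data.frame(tooth = "s1", jaw_id = "D", side = "left",
                                    stress = 1))
  expect_warning(r5 <- run_homodonty(small, reps = 500, subsample = 500,
                                     repeats = 10, seed = 11), "skipped")
  expect_named(r5, c("A/left", "B/left"))
})

test_that("an all-equal dentition is always fully homodont", {
  traits <- data.frame(tooth = letters[1:8], stress = rep(2, 8))
  r <- run_homodonty(traits, reps = 200, subsample = 200, repeats = 5, seed = 3)[[1]]
  expect_true(r$degenerate)
  expect_identical(r$proportion_heterodont, 0)
  expect_identical(unique(r$class), "homodont")
  expect_equal(r$avg_squared_residual, 1)
})

test_that("upper threshold is stable across seeds (CV < 2%)", {
  stresses <- withr::with_seed(30, rlnorm(30, 0, 0.25))
  traits <- data.frame(tooth = sprintf("t%d", 1:30), stress = stresses)
  ths <- vapply(1:10, function(s)
    run_homodonty(traits, reps = 10000, subsample = 5000, repeats = 100,
                  seed = s)[[1]]$upper_threshold, numeric(1))
  expect_lt(sd(ths) / mean(ths), 0.02)
  expect_true(all(ths > 1))
})

test_that("a 5x stress outlier is recovered as heterodont (majority over 20 seeds)", {
  spec <- inject_outlier(jaw_spec(n_teeth = 20, segments = 32), 3, 5)
  jaw <- make_jaw(spec)
  traits <- data.frame(tooth = jaw$ground_truth$tooth,
                       stress = jaw$ground_truth$stress)
  hits <- vapply(1:20, function(s) {
    r <- run_homodonty(traits, reps = 2000, subsample = 2000, repeats = 25,
                       seed = s)[[1]]
    r$class[3] == "heterodont"
  }, logical(1))
  expect_gte(sum(hits), 11L)
})

test_that("a 0.2x outlier falls below the lower threshold in two-sided mode", {
  # near-homodont background so the band is meaningful
  spec <- jaw_spec(n_teeth = 20, segments = 32,
                   height_cv = 0.05, radius_cv = 0.05, seed = 2)
  spec <- inject_outlier(spec, 10, 0.2)
  gt <- make_jaw(spec)$ground_truth
  # undo the lever gradient so only size variation remains
  stress <- gt$stress / gt$mechanical_advantage_1
  traits <- data.frame(tooth = gt$tooth, stress = stress)
  r <- run_homodonty(traits, reps = 2000, subsample = 2000, repeats = 25,
                     seed = 4, two_sided = "reciprocal")[[1]]
  expect_lt(r$residuals[10], r$lower_threshold)
  expect_identical(r$class[10], "heterodont")
})
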