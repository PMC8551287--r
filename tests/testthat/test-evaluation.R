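published_cycle_sizes <- c(`2017` = 901, `2018` = 1418, `2019` = 722,
                           `2020` = 486)

test_that("build_scenario reproduces every published training-set size", {
  expected <- rbind(`2017` = c(901, 926, 950, 974),
                    `2018` = c(1418, 1443, 1467, 1491),
                    `2019` = c(722, 747, 771, 795),
                    `2018+2019` = c(2140, 2165, 2189, 2213),
                    `2017+2018+2019` = c(3041, 3066, 3090, 3114))
  ts_sets <- list("2017", "2018", "2019", c("2018", "2019"),
                  c("2017", "2018", "2019"))
  fr <- c(0, 0.05, 0.10, 0.15)
  for (i in seq_along(ts_sets))
    for (j in seq_along(fr)) {
      sc <- build_scenario(published_cycle_sizes, ts_sets[[i]], fr[j],
                           "2020")
      expect_identical(sc$n_TS, as.integer(expected[i, j]))
      expect_identical(sc$n_PS, 413L)
      expect_identical(sc$n_holdout, 73L)
    }
  # augmentation counts 25 / 49 / 73
  expect_identical(build_scenario(published_cycle_sizes, "2017", 0.05,
                                  "2020")$n_aug, 25L)
  expect_identical(build_scenario(published_cycle_sizes, "2017", 0.10,
                                  "2020")$n_aug, 49L)
  expect_identical(build_scenario(published_cycle_sizes, "2017", 0.15,
                                  "2020")$n_aug, 73L)
  expect_error(build_scenario(published_cycle_sizes, "2017", 0.2, "2020"),
               "exceeds the held-out")
  expect_error(build_scenario(published_cycle_sizes,
                              c("2017", "2020"), 0, "2020"),
               "cannot be part")
})

test_that("scenario_partition gives disjoint, nested, deterministic splits", {
  ids <- sprintf("L%03d", 1:300)
  cycles <- rep(c("a", "b"), c(200, 100))
  sizes <- c(a = 200, b = 100)
  parts <- lapply(c(0, 0.05, 0.10, 0.15), function(fr) {
    sc <- build_scenario(sizes, "a", fr, "b", seed = 7)
    scenario_partition(sc, ids, cycles)
  })
  for (p in parts) {
    expect_length(intersect(p$training_ids, p$prediction_ids), 0)
    expect_identical(p$prediction_ids, parts[[1]]$prediction_ids)
  }
  # nested augmentation: 5% subset of 10% subset of 15%
  aug <- lapply(parts, function(p) setdiff(p$training_ids,
                                           ids[cycles == "a"]))
  expect_length(aug[[1]], 0)
  expect_true(all(aug[[2]] %in% aug[[3]]))
  expect_true(all(aug[[3]] %in% aug[[4]]))
  # determinism
  sc <- build_scenario(sizes, "a", 0.1, "b", seed = 7)
  expect_identical(scenario_partition(sc, ids, cycles),
                   scenario_partition(sc, ids, cycles))
})

test_that("accuracy is a validated Pearson correlation", {
  y <- c(1, 2, 3)
  expect_equal(accuracy(y, y), 1)
  expect_equal(accuracy(y, -y), -1)
  # hand-expanded Pearson for (1,2,3) vs (2,2.5,4)
  u <- c(2, 2.5, 4)
  r_hand <- sum((y - 2) * (u - mean(u))) /
    sqrt(sum((y - 2)^2) * sum((u - mean(u))^2))
  expect_equal(accuracy(y, u), r_hand)
  expect_error(accuracy(y, c(1, 1, 1)), "constant")
  expect_error(accuracy(y[1:2], u[1:2]), "at least 3")
  expect_error(accuracy(y, u[1:2]), "length")
})

test_that("gain_statistics follows the printed formulas", {
  expect_equal(gain_statistics(0.5, 0.5, 0.5, 0.5),
               list(gain1 = 0, gain2 = 0))
  expect_equal(gain_statistics(0.50, 0.55)$gain1, 10)
  expect_equal(gain_statistics(0.5, acc_blup = 0.52,
                               acc_ssi = 0.57)$gain2,
               100 * 0.05 / 0.52)
  expect_true(is.na(gain_statistics(0, 0.5)$gain1))
})

test_that("run_experiment bookkeeping, pairing and determinism", {
  pop <- small_population(seed = 30, n_cycles = 3, families = 3, dh = 18,
                          rho_g = 0.4)
  pop$markers <- polymorphic(pop$markers)
  res <- run_experiment(pop, models = "GBLUP",
                        training_cycles = c("1", "2"),
                        prediction_cycle = "3", fractions = 0,
                        n_partitions = 3, base_seed = 11)
  expect_equal(nrow(res), 3)
  expect_equal(res$seed, 11:13)
  expect_true(all(is.na(res$error)))
  # every model sees the same split within a partition: GSSI rows carry
  # the same n_TS/n_PS and their BLUP-equal lambda = 0 case must match
  res2 <- run_experiment(pop, models = c("GBLUP", "GSSI"),
                         training_cycles = c("1", "2"),
                         prediction_cycle = "3", fractions = 0,
                         n_partitions = 2, base_seed = 11,
                         n_lambda_cv = 6, n_folds = 5,
                         min_ratio_cv = 0.05)
  expect_equal(nrow(res2), 4)
  expect_true(all(res2$n_TS == res2$n_TS[1]))
  expect_true(all(!is.na(res2$accuracy)))
  # rerun with the same base seed reproduces the table
  res3 <- run_experiment(pop, models = c("GBLUP", "GSSI"),
                         training_cycles = c("1", "2"),
                         prediction_cycle = "3", fractions = 0,
                         n_partitions = 2, base_seed = 11,
                         n_lambda_cv = 6, n_folds = 5,
                         min_ratio_cv = 0.05)
  expect_identical(res2, res3)
  sm <- summarize_experiment(res2)
  expect_true(all(c("accuracy_mean", "accuracy_sd",
                    "gain_vs_gblup_pct") %in% names(sm)))
  expect_equal(sm$gain_vs_gblup_pct[sm$model == "GBLUP"], 0)
  expect_error(run_experiment(pop, models = character(0),
                              training_cycles = "1",
                              prediction_cycle = "3"),
               "empty")
  expect_error(run_experiment(pop, models = "XBLUP",
                              training_cycles = "1",
                              prediction_cycle = "3", n_partitions = 1),
               "unknown model")
})

test_that("gaussian-kernel models run through the experiment loop", {
  pop <- small_population(seed = 31, n_cycles = 2, families = 3, dh = 15,
                          rho_g = 0.8)
  pop$markers <- polymorphic(pop$markers)
  res <- run_experiment(pop, models = c("K2BLUP", "K2SSI"),
                        training_cycles = "1", prediction_cycle = "2",
                        fractions = 0, n_partitions = 1, base_seed = 5,
                        n_lambda_cv = 5, n_folds = 5,
                        min_ratio_cv = 0.05)
  expect_true(all(!is.na(res$accuracy)))
  expect_true(all(res$h2 >= 0 & res$h2 <= 1))
})
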