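test_that("MAE pools vertices across cases", {
  expect_equal(mae(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(mae(c(1, 2), c(0.5, 1.5)), 0.5)
  # two cases: |e| = 0.2 over 10 vertices, |e| = 0.4 over 30 vertices
  pred <- list(rep(0.2, 10), rep(0.4, 30))
  gt <- list(rep(0, 10), rep(0, 30))
  expect_equal(mae(pred, gt), 0.35)
  expect_error(mae(list(1:3), list(1:4)), "mismatch")
})

test_that("MAE is invariant to case order and consistent vertex permutation", {
  set.seed(1)
  p <- list(rnorm(20), rnorm(15)); g <- list(rnorm(20), rnorm(15))
  expect_equal(mae(p, g), mae(rev(p), rev(g)))
  perm <- sample.int(20)
  expect_equal(mae(list(p[[1]][perm]), list(g[[1]][perm])),
               mae(list(p[[1]]), list(g[[1]])))
})

test_that("TPR at the 90th percentile matches hand-built confusion cases", {
  gt <- c(1, 1, 1, 1, 1, 1, 1, 1, 9, 10)   # two vertices above the threshold
  pred_hit1 <- c(rep(0, 8), 0, 10)         # recovers exactly one positive
  expect_equal(as.numeric(tpr_at_percentile(pred_hit1, gt, 80)), 50)
  expect_equal(as.numeric(tpr_at_percentile(gt, gt)), 100)
  expect_equal(as.numeric(tpr_at_percentile(rep(min(gt), 10), gt)), 0)
  expect_error(tpr_at_percentile(rep(1, 5), rep(1, 5)), "degenerate")
})

test_that("TPR is invariant to a monotone transform applied to both fields", {
  set.seed(2)
  gt <- rlnorm(500); pred <- gt * exp(rnorm(500, sd = 0.3))
  t1 <- as.numeric(tpr_at_percentile(pred, gt))
  t2 <- as.numeric(tpr_at_percentile(log1p(pred), log1p(gt)))
  expect_equal(t1, t2)
})

test_that("fold construction partitions cases evenly and deterministically", {
  f1 <- ecapnet:::make_folds(1:16, 8, seed = 3)
  expect_length(f1, 8)
  expect_true(all(lengths(f1) == 2))
  expect_setequal(unlist(f1), 1:16)
  f2 <- ecapnet:::make_folds(1:16, 8, seed = 3)
  expect_identical(f1, f2)
  expect_error(ecapnet:::make_folds(1:4, 8, seed = 1), "exceeds")
})

test_that("k-fold experiment keeps train and test disjoint and is seeded", {
  d <- cached_dataset(12, seed = 20)
  cfg <- geo_config(local_widths = c(4, 4), global_dim = 8, lift_widths = 8,
                    head_widths = 8, epochs = 3, lr = 0.01, dropout = 0)
  plan <- experiment_plan(arch = "geometric", protocol = "kfold", k = 3,
                          seeds = 1, config = list(geo = cfg))
  res <- run_kfold(d, plan)
  expect_equal(nrow(res), 3)
  expect_true(all(res$mae >= 0))
  expect_true(all(res$tpr >= 0 & res$tpr <= 100))
  expect_true(all(res$n_train + res$n_test < length(d$cases) + 1))
  res2 <- run_kfold(d, plan)
  expect_equal(res$mae, res2$mae)
})

test_that("sequential subsets are nested and honor a baseline cohort", {
  d <- cached_dataset(12, seed = 21)
  cfg <- geo_config(local_widths = c(4, 4), global_dim = 8, lift_widths = 8,
                    head_widths = 8, epochs = 2, lr = 0.01, dropout = 0)
  plan <- experiment_plan(arch = "geometric", protocol = "sequential",
                          k = 4, sizes = c(3, 6), seeds = 1,
                          baseline_ids = 1:2, config = list(geo = cfg))
  res <- run_sequential(d, plan)
  expect_equal(res$condition, c(3, 6))
  expect_true(all(res$n_train >= c(3, 6) * 0.8))
  # nesting is by construction: the shuffled pool is indexed by size
  expect_error(experiment_plan(protocol = "sequential", sizes = c(5, 5)),
               "increasing")
  plan_big <- experiment_plan(arch = "geometric", protocol = "sequential",
                              k = 4, sizes = c(50), seeds = 1,
                              config = list(geo = cfg))
  expect_error(run_sequential(d, plan_big), "exceeds")
})

test_that("summaries aggregate mean and sd per condition", {
  res <- data.frame(arch = "geometric", protocol = "kfold",
                    condition = c(1, 1, 2), seed = c(1, 2, 1),
                    mae = c(0.5, 0.7, 0.4), tpr = c(60, 70, 80),
                    threshold = 1, n_train = 5, n_test = 2)
  class(res) <- c("result_table", class(res))
  agg <- summarize_results(res)
  r1 <- agg[agg$condition == 1, ]
  expect_equal(r1$mae_mean, 0.6)
  expect_equal(r1$mae_sd, sd(c(0.5, 0.7)))
  r2 <- agg[agg$condition == 2, ]
  expect_equal(r2$mae_sd, 0)
  path <- withr::local_tempfile(fileext = ".csv")
  summarize_results(res, file = path)
  back <- read.csv(path)
  expect_named(back, c("arch", "protocol", "condition", "n_runs", "mae_mean",
                       "mae_sd", "tpr_mean", "tpr_sd"))
})
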