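# Evaluation metrics and experiment protocols: vertex-pooled MAE, true
# positive rate above the 90th-percentile ECAP threshold, seeded k-fold
# cross-validation and sequential training-size scaling with nested subsets.

#' Vertex-pooled mean absolute error
#'
#' @param pred,gt numeric vectors or lists of per-case vertex fields.
#' @return scalar MAE pooled over all vertices of all cases.
#' @export
mae <- function(pred, gt) {
  if (is.list(pred)) {
    if (length(pred) != length(gt)) stop("case counts differ")
    for (i in seq_along(pred))
      if (length(pred[[i]]) != length(gt[[i]]))
        stop("shape mismatch in case ", i)
    pred <- unlist(pred); gt <- unlist(gt)
  }
  if (length(pred) != length(gt)) stop("shape mismatch")
  mean(abs(pred - gt))
}

#' True positive rate above a ground-truth percentile threshold
#'
#' The threshold is the empirical percentile (linear interpolation) of the
#' pooled ground-truth vertex values; positives are gt > threshold and the
#' TPR is the percentage of them also predicted above threshold, pooled over
#' vertices of all cases.
#'
#' @param pred,gt numeric vectors or lists of per-case vertex fields.
#' @param percentile threshold percentile (default 90).
#' @return percentage in [0, 100] with the threshold attached as attribute
#'   \code{"threshold"}.
#' @export
tpr_at_percentile <- function(pred, gt, percentile = 90) {
  if (is.list(pred)) { pred <- unlist(pred); gt <- unlist(gt) }
  if (length(pred) != length(gt)) stop("shape mismatch")
  if (!length(gt)) stop("empty fields")
  tau <- stats::quantile(gt, percentile / 100, names = FALSE, type = 7)
  pos <- gt > tau
  if (!any(pos)) stop("degenerate threshold: no positives above percentile")
  out <- 100 * sum(pred > tau & pos) / sum(pos)
  attr(out, "threshold") <- tau
  out
}

#' Experiment plan
#'
#' @param arch surrogate family: \code{"geometric"}, \code{"pca_fcn"},
#'   \code{"unet_bullseye"} or \code{"unet_cartesian"}.
#' @param protocol \code{"kfold"} or \code{"sequential"}.
#' @param k fold count (k-fold protocol).
#' @param sizes strictly increasing training-size ladder (sequential).
#' @param seeds seed list; results are reported per seed and averaged.
#' @param val_fraction fraction of training cases held out for checkpoint
#'   selection (default 0.10).
#' @param percentile classification threshold percentile (default 90).
#' @param ids case indices to use (default: all cases of the dataset).
#' @param baseline_ids case indices always included in every sequential
#'   training set (the synthetic-baseline protocol); default none.
#' @param test_ids fixed test indices for the sequential protocol (default:
#'   the first fold of a seeded k-fold split).
#' @param config model configuration passed to
#'   \code{\link{fit_ecap_surrogate}}.
#' @return a list of class \code{experiment_plan}.
#' @export
experiment_plan <- function(arch = "geometric",
                            protocol = c("kfold", "sequential"),
                            k = 8, sizes = NULL, seeds = 1:3,
                            val_fraction = 0.10, percentile = 90,
                            ids = NULL, baseline_ids = integer(0),
                            test_ids = NULL, config = list()) {
  protocol <- match.arg(protocol)
  if (!is.null(sizes) && any(diff(sizes) <= 0))
    stop("sizes must be strictly increasing")
  if (val_fraction <= 0 || val_fraction >= 1)
    stop("val_fraction must be in (0, 1)")
  structure(list(arch = arch, protocol = protocol, k = k, sizes = sizes,
                 seeds = seeds, val_fraction = val_fraction,
                 percentile = percentile, ids = ids,
                 baseline_ids = baseline_ids, test_ids = test_ids,
                 config = config),
            class = "experiment_plan")
}

# split a shuffled id vector into k folds as equal as possible
make_folds <- function(ids, k, seed) {
  if (k > length(ids)) stop("k exceeds the number of cases")
  set.seed(seed)
  sh <- sample(ids)
  split(sh, rep(seq_len(k), length.out = length(sh)))
}

split_train_val <- function(train_pool, val_fraction) {
  nv <- max(1L, ceiling(val_fraction * length(train_pool)))
  list(val = train_pool[seq_len(nv)],
       train = train_pool[-seq_len(nv)])
}

eval_fit <- function(fit, data, test_ids, percentile) {
  preds <- predict(fit, data, ids = test_ids)
  gts <- lapply(data$cases[test_ids], `[[`, "ecap")
  tpr <- tpr_at_percentile(preds, gts, percentile)
  list(mae = mae(preds, gts), tpr = as.numeric(tpr),
       threshold = attr(tpr, "threshold"))
}

#' Run a k-fold cross-validation experiment
#'
#' Per seed, cases are shuffled into k folds; for each fold the remaining
#' cases are split 90/10 into training and validation (checkpoint
#' selection), the surrogate is fitted and evaluated on the held-out fold.
#'
#' @param data an \code{laa_dataset}.
#' @param plan an \code{experiment_plan} with protocol \code{"kfold"}.
#' @param verbose print per-fold progress.
#' @return a \code{result_table} data frame (one row per fold x seed).
#' @export
run_kfold <- function(data, plan, verbose = FALSE) {
  ids <- plan$ids %||% seq_along(data$cases)
  rows <- list()
  for (seed in plan$seeds) {
    folds <- make_folds(ids, plan$k, seed)
    for (j in seq_along(folds)) {
      test_ids <- folds[[j]]
      pool <- setdiff(unlist(folds[-j]), test_ids)
      tv <- split_train_val(pool, plan$val_fraction)
      fit <- fit_ecap_surrogate(data, arch = plan$arch,
                                train_ids = tv$train, val_ids = tv$val,
                                config = plan$config, seed = seed)
      met <- eval_fit(fit, data, test_ids, plan$percentile)
      rows[[length(rows) + 1L]] <- data.frame(
        arch = plan$arch, protocol = "kfold", condition = j, seed = seed,
        mae = met$mae, tpr = met$tpr, threshold = met$threshold,
        n_train = length(tv$train), n_test = length(test_ids))
      if (verbose)
        message(sprintf("fold %d seed %d: MAE %.4f TPR %.1f%%", j, seed,
                        met$mae, met$tpr))
    }
  }
  res <- do.call(rbind, rows)
  class(res) <- c("result_table", class(res))
  res
}

#' Run a sequential training-size scaling experiment
#'
#' A fixed test fold is held out; nested training subsets of the remaining
#' pool (each size extending the previous) are fitted and evaluated,
#' optionally always including a fixed baseline cohort.
#'
#' @param data an \code{laa_dataset}.
#' @param plan an \code{experiment_plan} with protocol \code{"sequential"}
#'   and a \code{sizes} ladder.
#' @param verbose print progress.
#' @return a \code{result_table} data frame (one row per size x seed).
#' @export
run_sequential <- function(data, plan, verbose = FALSE) {
  if (is.null(plan$sizes)) stop("sequential protocol needs a sizes ladder")
  ids <- plan$ids %||% seq_along(data$cases)
  rows <- list()
  for (seed in plan$seeds) {
    if (is.null(plan$test_ids)) {
      folds <- make_folds(setdiff(ids, plan$baseline_ids), plan$k, seed)
      test_ids <- folds[[1]]
    } else test_ids <- plan$test_ids
    pool <- setdiff(ids, c(test_ids, plan$baseline_ids))
    set.seed(seed + 7L)
    pool <- sample(pool)
    if (max(plan$sizes) > length(pool))
      stop("size ladder exceeds the available training pool (",
           length(pool), ")")
    for (sz in plan$sizes) {
      sub <- c(plan$baseline_ids, pool[seq_len(sz)])
      tv <- split_train_val(sub, plan$val_fraction)
      fit <- fit_ecap_surrogate(data, arch = plan$arch,
                                train_ids = tv$train, val_ids = tv$val,
                                config = plan$config, seed = seed)
      met <- eval_fit(fit, data, test_ids, plan$percentile)
      rows[[length(rows) + 1L]] <- data.frame(
        arch = plan$arch, protocol = "sequential", condition = sz,
        seed = seed, mae = met$mae, tpr = met$tpr,
        threshold = met$threshold,
        n_train = length(tv$train), n_test = length(test_ids))
      if (verbose)
        message(sprintf("size %d seed %d: MAE %.4f TPR %.1f%%", sz, seed,
                        met$mae, met$tpr))
    }
  }
  res <- do.call(rbind, rows)
  class(res) <- c("result_table", class(res))
  res
}

#' Aggregate experiment results
#'
#' @param results a \code{result_table}.
#' @param file optional CSV path for the aggregate table.
#' @return data frame of mean and sd of MAE/TPR per (arch, protocol,
#'   condition).
#' @export
summarize_results <- function(results, file = NULL) {
  key <- interaction(results$arch, results$protocol, results$condition,
                     drop = TRUE)
  agg <- do.call(rbind, lapply(split(results, key), function(g) {
    data.frame(arch = g$arch[1], protocol = g$protocol[1],
               condition = g$condition[1], n_runs = nrow(g),
               mae_mean = mean(g$mae),
               mae_sd = if (nrow(g) > 1) stats::sd(g$mae) else 0,
               tpr_mean = mean(g$tpr),
               tpr_sd = if (nrow(g) > 1) stats::sd(g$tpr) else 0)
  }))
  rownames(agg) <- NULL
  if (!is.null(file)) utils::write.csv(agg, file, row.names = FALSE)
  agg
}

#' Mean-predictor baseline MAE
#'
#' MAE of the constant predictor equal to the vertex-pooled mean of the
#' training targets, evaluated on test targets; the reference against which
#' surrogate learnability is judged.
#'
#' @param train_gt,test_gt lists of per-case ground-truth vertex fields.
#' @return scalar baseline MAE.
#' @export
baseline_mae <- function(train_gt, test_gt) {
  mu <- mean(unlist(train_gt))
  mean(abs(unlist(test_gt) - mu))
}
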