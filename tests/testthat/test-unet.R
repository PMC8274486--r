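test_that("encoder-decoder preserves spatial shape and rejects bad sizes", {
  cfg <- unet_config(depth = 3, base_channels = 4, dropout = 0)
  m <- build_unet(cfg, seed = 1, input_size = 16)
  X <- array(rnorm(16 * 16 * 3), c(16, 16, 3))
  out <- ecapnet:::unet_forward(m, X)$pred
  expect_equal(dim(out), c(16, 16, 1))
  expect_true(all(is.finite(out)))
  expect_error(build_unet(cfg, input_size = 20), "divisible")
})

test_that("halving base channels shrinks the parameter count about fourfold", {
  c8 <- count_parameters(build_unet(unet_config(depth = 3, base_channels = 8),
                                    input_size = 32))
  c4 <- count_parameters(build_unet(unet_config(depth = 3, base_channels = 4),
                                    input_size = 32))
  expect_gt(c8 / c4, 3.5)
  expect_lt(c8 / c4, 4.5)
})

test_that("masked L1 ignores padded pixels exactly", {
  set.seed(2)
  pred <- matrix(rnorm(64), 8, 8)
  target <- matrix(rnorm(64), 8, 8)
  mask <- matrix(runif(64) > 0.4, 8, 8)
  full <- masked_l1(pred, target, matrix(TRUE, 8, 8))
  expect_equal(as.numeric(full), mean(abs(pred - target)))
  l1 <- masked_l1(pred, target, mask)
  pred2 <- pred
  pred2[!mask] <- rnorm(sum(!mask)) * 100
  expect_identical(as.numeric(masked_l1(pred2, target, mask)),
                   as.numeric(l1))
  expect_equal(as.numeric(masked_l1(c(1, 2), c(0, 0), c(TRUE, FALSE))), 1)
  expect_error(masked_l1(pred, target, matrix(FALSE, 8, 8)), "TRUE")
  expect_error(masked_l1(pred, target[1:4, 1:4], mask), "differ")
})

test_that("standardization uses training-mask statistics and a stored record", {
  set.seed(3)
  imgs <- lapply(1:4, function(i) array(rnorm(8 * 8 * 2, mean = i), c(8, 8, 2)))
  masks <- lapply(1:4, function(i) matrix(runif(64) > 0.3, 8, 8))
  std <- standardize_inputs(imgs, masks)
  pooled <- function(ims, ch) unlist(Map(function(im, mk) im[, , ch][mk],
                                         ims, masks))
  for (ch in 1:2) {
    expect_lt(abs(mean(pooled(std$images, ch))), 1e-6)
    expect_lt(abs(sd(pooled(std$images, ch)) - 1), 1e-6)
  }
  # test images reuse the stored record rather than their own statistics
  test_img <- array(rnorm(8 * 8 * 2, mean = 10), c(8, 8, 2))
  out <- apply_standardize(test_img, std$record)
  expect_gt(mean(out), 1)
  # applying the transform twice is not idempotent (guard)
  expect_false(isTRUE(all.equal(apply_standardize(out, std$record), out)))
  expect_error(standardize_inputs(list(array(1, c(4, 4, 1)),
                                       array(1, c(4, 4, 1)))), "variance")
})

test_that("training learns the radial map on synthetic bull's-eyes", {
  set.seed(10)
  S <- 16
  ctr <- (S + 1) / 2
  xs <- (seq_len(S) - ctr) / (S / 2)
  rho <- sqrt(outer(xs^2, xs^2, "+"))
  mask <- rho <= 1
  target <- rho^2
  mk_case <- function(i) {
    mesh <- sample_shape(seed = 400 + i)
    d <- geodesic_distance(mesh, mesh$ostium_ring)
    fl <- build_flat_map(mesh, d, mesh$landmark, R = S, A = S)
    be <- to_bullseye(fl, S = S)
    img <- be$image
    tg <- target; tg[!mask] <- 0
    list(image = img, target = tg, mask = mask)
  }
  cases <- lapply(1:80, mk_case)
  std <- standardize_inputs(lapply(cases[1:64], `[[`, "image"),
                            lapply(cases[1:64], `[[`, "mask"))
  cases <- lapply(cases, function(cs) {
    cs$image <- apply_standardize(cs$image, std$record); cs
  })
  cfg <- unet_config(depth = 2, base_channels = 8, epochs = 25, dropout = 0.1)
  m <- build_unet(cfg, seed = 1, input_size = S)
  m <- train_unet(m, cases[1:64], cases[63:64], seed = 1)
  held <- cases[65:80]
  errs <- vapply(held, function(cs) {
    as.numeric(masked_l1(predict_unet(m, cs$image), cs$target, cs$mask))
  }, numeric(1))
  rng <- diff(range(target[mask]))
  expect_lt(mean(errs) / rng, 0.10)
})

test_that("two images are memorized and training is seed-deterministic", {
  set.seed(5)
  mk <- function() list(image = array(rnorm(8 * 8 * 3), c(8, 8, 3)),
                        target = matrix(rnorm(64), 8, 8),
                        mask = matrix(TRUE, 8, 8))
  cases <- list(mk(), mk())
  cfg <- unet_config(depth = 2, base_channels = 6, epochs = 90, lr = 2e-3,
                     dropout = 0)
  m1 <- train_unet(build_unet(cfg, seed = 2, input_size = 8), cases, seed = 3)
  errs <- vapply(cases, function(cs)
    as.numeric(masked_l1(predict_unet(m1, cs$image), cs$target, cs$mask)),
    numeric(1))
  rng <- diff(range(sapply(cases, function(cs) range(cs$target))))
  expect_lt(mean(errs) / rng, 0.05)
  m2 <- train_unet(build_unet(cfg, seed = 2, input_size = 8), cases, seed = 3)
  expect_identical(m1$history, m2$history)
})

test_that("trained predictions transport back to the mesh without NaNs", {
  d <- cached_dataset(6, seed = 12)
  d <- add_flat_maps(d, R = 8, A = 8)
  cfg <- unet_config(depth = 2, base_channels = 4, epochs = 4, dropout = 0)
  fit <- fit_ecap_surrogate(d, "unet_bullseye", train_ids = 1:4,
                            val_ids = 5:5, config = list(unet = cfg, S = 16),
                            seed = 1)
  preds <- predict(fit, d, ids = 6)
  expect_length(preds[[1]], nrow(d$cases[[6]]$mesh$vertices))
  expect_true(all(is.finite(preds[[1]])))
})
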