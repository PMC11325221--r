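test_that("spearman correlations respect ranks, nulls and hand computation", {
  # monotone transform of a single descriptor gives rho = 1
  set.seed(3)
  x <- matrix(runif(60 * 10, 10, 100), 60, 10,
              dimnames = list(NULL, paste0("S", 1:10)))
  k <- exp(0.05 * x[, 3])          # strictly increasing in S3
  ds <- qspr_dataset(x, k)
  rho <- spearman_matrix(ds)
  expect_equal(unname(rho["S3"]), 1)

  # independent responses stay small at n = 100
  set.seed(4)
  x2 <- matrix(runif(100 * 10), 100, 10, dimnames = list(NULL, paste0("S", 1:10)))
  ds2 <- qspr_dataset(x2, 10^runif(100, -3, 1))
  expect_true(all(abs(spearman_matrix(ds2)) < 0.25))

  # 5-row hand oracle: Pearson correlation of average ranks
  x3 <- matrix(1, 5, 10, dimnames = list(NULL, paste0("S", 1:10)))
  x3[, 1] <- c(3, 1, 4, 1, 5)
  kk <- c(2, 7, 1, 8, 2)
  ds3 <- qspr_dataset(x3, kk)
  rho3 <- spearman_matrix(ds3)
  hand <- cor(rank(x3[, 1]), rank(log10(kk)))
  expect_equal(unname(rho3["S1"]), hand, tolerance = 1e-12)
  # constant columns are flagged and reported as zero
  expect_equal(unname(rho3["S2"]), 0)
  expect_true("S2" %in% attr(rho3, "flagged"))
})

test_that("input selection applies the absolute threshold in order", {
  rho <- c(S1 = 1, S2 = -1, S3 = 1, S4 = 1, S5 = 1, S6 = -1, S7 = 1,
           S8 = 1, S9 = 1, S10 = 1)
  expect_equal(unname(select_inputs(rho, 0.4)), 1:10)
  rho2 <- c(S1 = 0.9, S2 = 0.1, S3 = -0.6, S4 = 0.39, S5 = 0.41,
            S6 = 0, S7 = 0, S8 = 0, S9 = 0, S10 = 0)
  expect_equal(unname(select_inputs(rho2, 0.4)), c(1, 3, 5))
  expect_error(select_inputs(rho2 * 0.01, 0.5), "lower threshold")
  expect_error(select_inputs(rho, 1.2), "threshold")
})

test_that("splits are disjoint, exhaustive, floor-sized and seed-stable", {
  set.seed(5)
  x <- matrix(runif(84 * 10), 84, 10, dimnames = list(NULL, paste0("S", 1:10)))
  ds <- qspr_dataset(x, 10^runif(84, -3, 1))
  sp <- split_spec(calibration = 55, seed = 42)
  s1 <- split_dataset(ds, sp)
  s2 <- split_dataset(ds, sp)
  expect_identical(s1, s2)
  all_idx <- c(unlist(s1$calibration), s1$prediction)
  expect_setequal(all_idx, 1:84)
  expect_equal(length(all_idx), 84)        # disjointness given the setequal
  expect_length(s1$prediction, 29)
  expect_length(s1$calibration$test, floor(0.15 * 55))
  expect_length(s1$calibration$validation, floor(0.15 * 55))
  expect_length(s1$calibration$train, 55 - 2 * floor(0.15 * 55))

  # block sizes are fixed across seeds
  sizes <- t(vapply(1:50, function(sd) {
    s <- split_dataset(ds, split_spec(calibration = 55, seed = sd))
    c(lengths(s$calibration), pred = length(s$prediction))
  }, numeric(4)))
  expect_equal(unname(colMeans(sizes)), c(39, 8, 8, 29))
  expect_true(all(apply(sizes, 2, function(cl) length(unique(cl)) == 1)))

  expect_error(split_spec(calibration = 55, train = 0.5, test = 0.3,
                          validation = 0.3), "sum to 1")
})

test_that("an identity/identity network reaches the linear-model limit", {
  set.seed(6)
  n <- 150
  x <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("S1", "S2")))
  y <- 2 * x[, 1] - x[, 2]
  arch <- mlp_architecture(2, 5, "identity", "identity")
  m <- train_mlp(x[1:100, ], y[1:100], arch, x[101:125, ], y[101:125],
                 seed = 7, transform = "none")
  expect_gte(r2_of(y[1:100], predict(m, x[1:100, ], type = "transformed")),
             0.999)
  expect_gte(r2_of(y[126:150], predict(m, x[126:150, ], type = "transformed")),
             0.999)
})

test_that("zero-epoch training returns the seeded initial network", {
  set.seed(8)
  x <- matrix(rnorm(40 * 3), 40, 3, dimnames = list(NULL, paste0("S", 1:3)))
  y <- rnorm(40)
  arch <- mlp_architecture(3, 4, "tanh", "identity")
  m1 <- train_mlp(x, y, arch, epochs = 0, seed = 99, transform = "none")
  m2 <- train_mlp(x, y, arch, epochs = 0, seed = 99, transform = "none")
  expect_identical(m1$W1, m2$W1)
  expect_identical(predict(m1, x, type = "transformed"),
                   predict(m2, x, type = "transformed"))
})

test_that("the forward pass matches hand arithmetic and nnet on shared weights", {
  # identity/identity network with known weights is affine
  arch <- mlp_architecture(2, 4, "identity", "identity")
  m <- train_mlp(matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("S1", "S2"))),
                 rnorm(10), arch, epochs = 0, seed = 1, transform = "none")
  m$W1 <- matrix(c(1, 0, 0, 1, 1, 1, 0, 0), 4, 2)
  m$b1 <- c(0, 0, 1, 0)
  m$W2 <- matrix(c(1, 2, 3, 4), 1, 4)
  m$b2 <- 0.5
  m$x_center <- c(0, 0); m$x_scale <- c(1, 1); m$y_a <- 0; m$y_b <- 1
  xnew <- matrix(c(2, -1), 1, 2, dimnames = list(NULL, c("S1", "S2")))
  # W1 rows are (1,1), (0,1), (0,0), (1,0), so the hidden layer at x = (2,-1)
  # is (1, -1, 1, 2) and the output 1*1 + 2*(-1) + 3*1 + 4*2 + 0.5 = 10.5
  expect_equal(predict(m, xnew, type = "transformed"), 10.5)

  # logistic-hidden forward pass agrees with nnet given identical weights
  skip_if_not_installed("nnet")
  set.seed(11)
  x <- matrix(rnorm(30 * 3), 30, 3, dimnames = list(NULL, paste0("S", 1:3)))
  y <- rnorm(30)
  arch2 <- mlp_architecture(3, 4, "logistic", "identity")
  mm <- train_mlp(x, y, arch2, epochs = 0, seed = 2, transform = "none")
  mm$x_center <- rep(0, 3); mm$x_scale <- rep(1, 3)
  mm$y_a <- 0; mm$y_b <- 1
  wts <- c(rbind(mm$b1, t(mm$W1)), mm$b2, as.numeric(mm$W2))
  nn <- nnet::nnet(x, y, size = 4, linout = TRUE, Wts = wts, maxit = 0,
                   trace = FALSE)
  expect_equal(predict(mm, x, type = "transformed"),
               as.numeric(predict(nn, x)), tolerance = 1e-10)

  # batch prediction equals row-wise prediction
  rows <- vapply(seq_len(nrow(x)), function(i)
    predict(mm, x[i, , drop = FALSE], type = "transformed"), numeric(1))
  expect_equal(predict(mm, x, type = "transformed"), rows)
})

test_that("stored training fits match re-prediction and survive JSON round trips", {
  set.seed(12)
  x <- matrix(runif(50 * 4, 10, 60), 50, 4, dimnames = list(NULL, paste0("S", 1:4)))
  k <- 10^(0.02 * x[, 2] - 0.03 * x[, 4] + rnorm(50, 0, 0.05))
  arch <- mlp_architecture(4, 6, "tanh", "identity")
  m <- train_mlp(x, log10(k), arch, seed = 13, epochs = 400)
  expect_equal(predict(m, x, type = "transformed"), m$fitted_transformed)
  # rate-scale predictions invert the log transform
  expect_equal(predict(m, x, type = "rate"), 10^m$fitted_transformed)

  path <- tempfile(fileext = ".json")
  save_model(m, path)
  m2 <- load_model(path)
  expect_equal(predict(m2, x, type = "rate"), predict(m, x, type = "rate"))
  expect_identical(m2$architecture$name, m$architecture$name)
})

test_that("training error is non-increasing for a small enough step", {
  set.seed(14)
  x <- matrix(rnorm(60 * 2), 60, 2, dimnames = list(NULL, c("S1", "S2")))
  y <- x[, 1] - 0.5 * x[, 2]
  arch <- mlp_architecture(2, 4, "tanh", "identity")
  m <- train_mlp(x, y, arch, seed = 15, epochs = 300, learn_rate = 0.01,
                 transform = "none")
  expect_true(all(diff(m$history) <= 1e-12))
})

test_that("the random search is seeded, ranked and degenerate-safe", {
  set.seed(16)
  x <- matrix(runif(84 * 10, 20, 100), 84, 10,
              dimnames = list(NULL, paste0("S", 1:10)))
  tr <- synth_qspr_truth(x, family = "linear", seed = 17, sigma_noise = 0.05)
  ds <- tr$dataset
  split <- split_dataset(ds, split_spec(calibration = 55, seed = 18))
  r1 <- random_search(ds, split, n_candidates = 6, seed = 19, epochs = 300)
  r2 <- random_search(ds, split, n_candidates = 6, seed = 19, epochs = 300)
  expect_identical(r1$leaderboard, r2$leaderboard)
  expect_equal(nrow(r1$leaderboard), 6)
  expect_false(is.unsorted(rev(r1$leaderboard$r2_validation)))
  expect_equal(r1$model$metrics$r2_validation,
               max(r1$leaderboard$r2_validation))

  one <- random_search(ds, split, n_candidates = 1, seed = 20, epochs = 200)
  expect_equal(nrow(one$leaderboard), 1)
  expect_s3_class(one$model, "qspr_mlp")
})

test_that("architecture bounds and dataset validation hold", {
  expect_error(mlp_architecture(5, 3), "4, 13")
  expect_error(mlp_architecture(5, 14), "4, 13")
  expect_error(qspr_dataset(matrix(1, 3, 2), c(1, -1, 2)), "positive")
  expect_silent(qspr_dataset(matrix(1:6, 3, 2), c(1, 2, 1), transform = "none"))
  arch <- mlp_architecture(2, 4)
  expect_error(train_mlp(matrix(1, 5, 3), rnorm(5), arch), "columns")
})
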