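test_that("calibration metrics recover the sum-of-squares decomposition", {
  obs <- c(1, 2, 3, 4, 5, 6)
  expect_equal(calibration_metrics(obs, obs)$r2, 1)
  expect_equal(calibration_metrics(obs, obs)$rmse, 0)
  # predicting the mean gives R2 = 0
  expect_equal(calibration_metrics(obs, rep(mean(obs), 6))$r2, 0)

  # 6-point hand case, explicit loops
  pred <- c(1.2, 1.8, 3.3, 3.9, 5.4, 5.7)
  sstot <- 0; ssres <- 0
  for (i in 1:6) {
    sstot <- sstot + (obs[i] - mean(obs))^2
    ssres <- ssres + (obs[i] - pred[i])^2
  }
  got <- calibration_metrics(obs, pred)
  expect_equal(got$r2, 1 - ssres / sstot, tolerance = 1e-12)
  expect_equal(got$rmse, sqrt(ssres / 6), tolerance = 1e-12)

  # per-block computation and the zero-variance flag
  blocks <- rep(c("train", "test"), each = 3)
  per <- calibration_metrics(obs, pred, blocks)
  expect_setequal(per$block, c("train", "test"))
  expect_equal(per$n, c(3, 3))
  expect_warning(calibration_metrics(c(2, 2, 2), c(1, 2, 3)), "zero variance")
})

test_that("prediction metrics separate bias from scatter", {
  obs <- c(1, 2, 3, 4, 5)
  perfect <- prediction_metrics(obs, obs, n_predictors = 2)
  expect_equal(perfect$rmsep, 0)
  expect_equal(perfect$sep, 0)
  expect_equal(perfect$rpd, Inf)
  expect_equal(perfect$rer, Inf)

  # constant residual: all error is bias, none is scatter
  shifted <- prediction_metrics(obs, obs - 0.7, n_predictors = 2)
  expect_equal(shifted$rmsep, 0.7, tolerance = 1e-12)
  expect_equal(shifted$bias, 0.7, tolerance = 1e-12)
  expect_equal(shifted$sep, 0, tolerance = 1e-12)

  # shifting predictions changes RMSEP but not SEP
  set.seed(21)
  pred <- obs + rnorm(5, 0, 0.3)
  a <- prediction_metrics(obs, pred, 2)
  b <- prediction_metrics(obs, pred + 1.3, 2)
  expect_equal(a$sep, b$sep, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(a$rmsep, b$rmsep)))

  # small prediction sets leave the adjusted R2 undefined
  tiny <- prediction_metrics(obs[1:3], pred[1:3], n_predictors = 2)
  expect_true(is.na(tiny$r2_pred_adj))
  expect_true("adjusted_r2_undefined" %in% tiny$flags)
})

test_that("metrics agree with an independently coded formula evaluation", {
  set.seed(22)
  for (i in 1:10) {
    n <- sample(10:40, 1)
    obs <- rnorm(n, 0, 2)
    pred <- obs + rnorm(n, 0.2, 0.5)
    p <- sample(3:8, 1)
    got <- prediction_metrics(obs, pred, n_predictors = p)

    # second route: vectorized stats:: formulations
    e <- obs - pred
    rmsep2 <- sqrt(mean(e^2))
    sep2 <- stats::sd(e)
    rpd2 <- stats::sd(obs) / sep2
    rer2 <- (max(obs) - min(obs)) / sep2
    r2p2 <- 1 - sum(e^2) / ((n - 1) * stats::var(obs))
    r2adj2 <- 1 - (1 - r2p2) * (n - 1) / (n - p - 1)
    expect_equal(got$rmsep, rmsep2, tolerance = 1e-12)
    expect_equal(got$sep, sep2, tolerance = 1e-12)
    expect_equal(got$rpd, rpd2, tolerance = 1e-12)
    expect_equal(got$rer, rer2, tolerance = 1e-12)
    expect_equal(got$r2_pred, r2p2, tolerance = 1e-12)
    expect_equal(got$r2_pred_adj, r2adj2, tolerance = 1e-12)

    # RMSEP-denominator variant rescales RPD and RER consistently
    alt <- prediction_metrics(obs, pred, p, denominator = "rmsep")
    expect_equal(alt$rpd, stats::sd(obs) / rmsep2, tolerance = 1e-12)
  }
})

test_that("RPD and RER decrease as the prediction scatter grows", {
  set.seed(23)
  obs <- rnorm(20, 0, 2)
  noise <- rnorm(20)
  prev_rpd <- Inf; prev_rer <- Inf
  for (s in c(0.1, 0.4, 1.2)) {
    m <- prediction_metrics(obs, obs + s * noise, 3)
    expect_lt(m$rpd, prev_rpd)
    expect_lt(m$rer, prev_rer)
    prev_rpd <- m$rpd; prev_rer <- m$rer
  }
})

test_that("quality and usability bands classify as the validation framework states", {
  # screening-grade examples from the dehydrogenase models
  gdh <- classify_model(rpd = 2.490, rer = 7.749, r2_pred = 0.9021)
  expect_equal(gdh$quality, "excellent")
  expect_equal(gdh$usability, "screening")
  expect_true(gdh$substantial)

  lk <- classify_model(rpd = 1.198, rer = 4.126, r2_pred = 0.8927)
  expect_equal(lk$quality, "non-reliable")   # RPD < 1.4
  expect_equal(lk$usability, "screening")
  expect_true(lk$substantial)

  # band edges: fair is closed on both ends, RER bands are strict
  expect_equal(classify_model(rpd = 1.39, rer = 3)$quality, "non-reliable")
  expect_equal(classify_model(rpd = 1.40, rer = 3)$quality, "fair")
  expect_equal(classify_model(rpd = 2.0, rer = 3)$quality, "fair")
  expect_equal(classify_model(rpd = 2.01, rer = 3)$quality, "excellent")
  expect_equal(classify_model(rpd = 2, rer = 4)$usability, "none")
  expect_equal(classify_model(rpd = 2, rer = 4.001)$usability, "screening")
  expect_equal(classify_model(rpd = 2, rer = 10.5)$usability, "quality-control")
  expect_equal(classify_model(rpd = 2, rer = 15.2)$usability, "quantification")
  expect_equal(classify_model(rpd = 2, rer = 5, r2_pred = 0.75)$substantial,
               FALSE)

  # classification is a pure function of its inputs
  expect_identical(classify_model(rpd = 1.7, rer = 11, r2_pred = 0.8),
                   classify_model(rpd = 1.7, rer = 11, r2_pred = 0.8))
})

test_that("evaluation reports serialize with their classification", {
  set.seed(24)
  obs <- rnorm(12); pred <- obs + rnorm(12, 0, 0.2)
  rep <- prediction_metrics(obs, pred, 4)
  path <- tempfile(fileext = ".json")
  write_evaluation_report(rep, path, network = "MLP 4-6-1")
  back <- jsonlite::read_json(path)
  expect_equal(back$network, "MLP 4-6-1")
  expect_equal(back$rpd, rep$rpd, tolerance = 1e-12)
  expect_true(back$quality %in% c("non-reliable", "fair", "excellent"))
})
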