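# QSPR modelling: Spearman-based input selection, calibration/prediction
# splitting, and single-hidden-layer MLPs trained by batch-gradient
# backpropagation on a sum-of-squares error. Inputs are z-scored on the
# training block; the response is linearly mapped into [0.2, 0.8] of the
# training range so that saturating output activations (logistic, tanh)
# remain usable; both maps are stored in the model and inverted on predict.

#' Assemble a QSPR dataset
#'
#' One row per enzyme-by-DES combination: the ten mixture descriptors and
#' the inactivation rate constant. Rate constants span several decades
#' (1e-4 to ~50 h^-1), which makes raw sum-of-squares training degenerate,
#' so the default training response is log10(k); raw-k mode is retained.
#'
#' @param descriptors Matrix or data frame of descriptor columns (usually
#'   S1..S10), no missing values.
#' @param k Inactivation rate constants (canonical unit h^-1), finite;
#'   strictly positive when `transform = "log10"`.
#' @param enzyme Identifier for the enzyme the responses belong to.
#' @param transform Response transform: `"log10"` (default) or `"none"`.
#' @return Object of class `qspr_dataset` with fields `x` (matrix), `k`,
#'   `y` (transformed response), `enzyme`, `transform`.
#' @export
qspr_dataset <- function(descriptors, k, enzyme = "",
                         transform = c("log10", "none")) {
  transform <- match.arg(transform)
  x <- as.matrix(descriptors)
  storage.mode(x) <- "double"
  if (is.null(colnames(x))) colnames(x) <- paste0("S", seq_len(ncol(x)))
  if (nrow(x) != length(k))
    stop("descriptors and k must have matching row counts")
  if (any(!is.finite(x))) stop("missing or non-finite descriptor values")
  if (any(!is.finite(k))) stop("non-finite responses")
  if (transform == "log10" && any(k <= 0))
    stop("log10 transform requires strictly positive rate constants")
  y <- if (transform == "log10") log10(k) else as.numeric(k)
  structure(list(x = x, k = as.numeric(k), y = y, enzyme = enzyme,
                 transform = transform),
            class = "qspr_dataset")
}

#' Spearman correlations between descriptors and the response
#'
#' Rank correlation (average ranks for ties) of each descriptor column with
#' the transformed response. A constant column has undefined rank
#' correlation and is reported as 0, with its name recorded in the
#' `"flagged"` attribute.
#'
#' @param dataset A [qspr_dataset()] with at least 3 rows.
#' @return Named numeric vector of Spearman rho, one per descriptor, with
#'   attribute `flagged` naming constant columns.
#' @export
spearman_matrix <- function(dataset) {
  stopifnot(inherits(dataset, "qspr_dataset"))
  if (nrow(dataset$x) < 3L) stop("need at least 3 rows")
  rho <- numeric(ncol(dataset$x))
  names(rho) <- colnames(dataset$x)
  flagged <- character(0)
  for (j in seq_len(ncol(dataset$x))) {
    xj <- dataset$x[, j]
    if (stats::sd(xj) == 0) {
      rho[j] <- 0
      flagged <- c(flagged, colnames(dataset$x)[j])
    } else {
      rho[j] <- stats::cor(xj, dataset$y, method = "spearman")
    }
  }
  attr(rho, "flagged") <- flagged
  rho
}

#' Select model inputs from Spearman correlations
#'
#' @param correlations Output of [spearman_matrix()].
#' @param threshold Absolute-correlation cutoff in (0, 1); default 0.4.
#' @return Integer indices (descriptor order) of columns with
#'   `|rho| >= threshold`.
#' @export
select_inputs <- function(correlations, threshold = 0.4) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1)
    stop("threshold must be in (0, 1)")
  idx <- which(abs(correlations) >= threshold)
  if (!length(idx))
    stop("no descriptor reaches |rho| >= ", threshold,
         "; try a lower threshold")
  idx
}

#' Specify a calibration/prediction split
#'
#' The data are first divided into a calibration set and a fully held-out
#' prediction set; the calibration set is subdivided into training, test
#' (early stopping) and validation (model selection) blocks. Within-
#' calibration counts are floor-based with the remainder assigned to
#' training.
#'
#' @param calibration Calibration size: a count (>= 1) or a fraction in
#'   (0, 1) of the dataset.
#' @param train,test,validation Within-calibration fractions, positive and
#'   summing to 1 within 1e-12. Defaults 0.70/0.15/0.15.
#' @param seed Integer seed; the partition is fully reproducible from it.
#' @return Object of class `split_spec`.
#' @export
split_spec <- function(calibration = 0.65, train = 0.70, test = 0.15,
                       validation = 0.15, seed = 1L) {
  fr <- c(train, test, validation)
  if (any(fr <= 0) || abs(sum(fr) - 1) > 1e-12)
    stop("train/test/validation fractions must be positive and sum to 1")
  if (calibration <= 0) stop("calibration must be positive")
  structure(list(calibration = calibration, train = train, test = test,
                 validation = validation, seed = as.integer(seed)),
            class = "split_spec")
}

#' Partition a dataset into calibration blocks and a prediction set
#'
#' @param dataset A [qspr_dataset()] with >= 10 rows.
#' @param spec A [split_spec()].
#' @return List with `calibration` (list of integer index vectors `train`,
#'   `test`, `validation`) and `prediction`; blocks are disjoint and
#'   exhaustive for every seed.
#' @export
split_dataset <- function(dataset, spec) {
  stopifnot(inherits(dataset, "qspr_dataset"), inherits(spec, "split_spec"))
  n <- nrow(dataset$x)
  if (n < 10L) stop("need at least 10 rows to split")
  ncal <- if (spec$calibration < 1) floor(n * spec$calibration)
          else as.integer(spec$calibration)
  if (ncal >= n) stop("calibration set leaves no prediction points")
  ntest <- floor(spec$test * ncal)
  nval <- floor(spec$validation * ncal)
  ntrain <- ncal - ntest - nval
  if (min(ntrain, ntest, nval, n - ncal) < 1L)
    stop("a split block would be empty; adjust fractions or calibration size")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)
  perm <- sample.int(n)
  cal <- perm[seq_len(ncal)]
  list(calibration = list(train = sort(cal[seq_len(ntrain)]),
                          test = sort(cal[ntrain + seq_len(ntest)]),
                          validation = sort(cal[ntrain + ntest + seq_len(nval)])),
       prediction = sort(perm[(ncal + 1L):n]))
}

#' Define an MLP architecture
#'
#' Single hidden layer; 4 to 13 hidden neurons; hidden and output
#' activations drawn from identity, logistic, tanh and exponential.
#'
#' @param n_inputs Number of input descriptors.
#' @param n_hidden Hidden-layer width, integer in \[4, 13\].
#' @param hidden_activation,output_activation One of `"identity"`,
#'   `"logistic"`, `"tanh"`, `"exponential"`.
#' @return Object of class `mlp_architecture`; its `name` follows the
#'   `MLP <inputs>-<hidden>-1` convention.
#' @export
mlp_architecture <- function(n_inputs, n_hidden,
                             hidden_activation = c("identity", "logistic",
                                                   "tanh", "exponential"),
                             output_activation = c("identity", "logistic",
                                                   "tanh", "exponential")) {
  hidden_activation <- match.arg(hidden_activation)
  output_activation <- match.arg(output_activation)
  if (n_hidden < 4L || n_hidden > 13L)
    stop("n_hidden must lie in [4, 13]")
  if (n_inputs < 1L) stop("need at least one input")
  structure(list(n_inputs = as.integer(n_inputs),
                 n_hidden = as.integer(n_hidden),
                 hidden_activation = hidden_activation,
                 output_activation = output_activation,
                 name = sprintf("MLP %d-%d-1", n_inputs, n_hidden)),
            class = "mlp_architecture")
}

# activation and its derivative wrt the pre-activation; the exponential is
# evaluated with pre-activation clipping at +/-30 to prevent overflow
.mlp_act <- function(z, kind) {
  switch(kind,
         identity = z,
         logistic = stats::plogis(z),
         tanh = tanh(z),
         exponential = exp(pmin(pmax(z, -30), 30)),
         stop("unknown activation: ", kind))
}

.mlp_dact <- function(z, a, kind) {
  switch(kind,
         identity = array(1, dim = dim(z)),
         logistic = a * (1 - a),
         tanh = 1 - a^2,
         exponential = a * (abs(z) < 30),
         stop("unknown activation: ", kind))
}

.mlp_forward <- function(xs, W1, b1, W2, b2, arch) {
  z1 <- xs %*% t(W1) + matrix(b1, nrow(xs), length(b1), byrow = TRUE)
  a1 <- .mlp_act(z1, arch$hidden_activation)
  z2 <- a1 %*% t(W2) + b2
  a2 <- .mlp_act(z2, arch$output_activation)
  list(z1 = z1, a1 = a1, z2 = z2, a2 = a2)
}

.mlp_init <- function(arch) {
  # uniform +/- 1/sqrt(fan-in)
  r1 <- 1 / sqrt(arch$n_inputs)
  r2 <- 1 / sqrt(arch$n_hidden)
  list(W1 = matrix(stats::runif(arch$n_hidden * arch$n_inputs, -r1, r1),
                   arch$n_hidden, arch$n_inputs),
       b1 = stats::runif(arch$n_hidden, -r1, r1),
       W2 = matrix(stats::runif(arch$n_hidden, -r2, r2), 1, arch$n_hidden),
       b2 = stats::runif(1, -r2, r2))
}

#' Train a single-hidden-layer MLP by backpropagation
#'
#' Plain batch gradient descent minimizing the sum of squared errors on the
#' training block, with early stopping on the test-block error when a test
#' block is supplied: the weights returned are those of the epoch with the
#' lowest test error, and training stops once `patience` epochs pass
#' without improvement. If the error diverges the optimizer restarts with
#' half the step size, up to `max_restarts` times.
#'
#' @param x_train,y_train Training descriptors (matrix) and responses
#'   (transformed scale).
#' @param architecture An [mlp_architecture()].
#' @param x_test,y_test Optional early-stopping block.
#' @param epochs Maximum training epochs.
#' @param learn_rate Gradient-descent step on the mean squared error.
#' @param patience Early-stopping patience in epochs.
#' @param momentum Classical momentum coefficient; 0 (off) by default.
#' @param max_restarts Restarts (with halved step) after divergence.
#' @param seed Optional integer seed for weight initialization.
#' @param transform Response transform the `y` values are on (stored so
#'   predictions can be inverted back to rate constants).
#' @param input_names Optional column names the model expects at
#'   prediction time; defaults to `colnames(x_train)`.
#' @return Object of class `qspr_mlp`: architecture, weights (`W1`, `b1`,
#'   `W2`, `b2`), standardization constants, response map, per-epoch
#'   training sum-of-squares `history`, and training fits
#'   `fitted_transformed`.
#' @export
train_mlp <- function(x_train, y_train, architecture, x_test = NULL,
                      y_test = NULL, epochs = 2000L, learn_rate = 0.1,
                      patience = 100L, momentum = 0, max_restarts = 5L,
                      seed = NULL, transform = "log10", input_names = NULL) {
  stopifnot(inherits(architecture, "mlp_architecture"))
  x_train <- as.matrix(x_train)
  if (ncol(x_train) != architecture$n_inputs)
    stop("x_train has ", ncol(x_train), " columns but architecture expects ",
         architecture$n_inputs)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(x_train)

  # z-score inputs on the training block (constant columns untouched)
  x_center <- colMeans(x_train)
  x_scale <- apply(x_train, 2L, stats::sd)
  x_scale[x_scale == 0 | !is.finite(x_scale)] <- 1
  xs <- sweep(sweep(x_train, 2L, x_center), 2L, x_scale, "/")

  # map response into [0.2, 0.8] of the training range
  ymin <- min(y_train); ymax <- max(y_train)
  if (ymax > ymin) {
    y_b <- 0.6 / (ymax - ymin)
    y_a <- 0.2 - y_b * ymin
  } else {
    y_b <- 1; y_a <- 0.5 - ymin
  }
  ys <- y_a + y_b * y_train

  ts_avail <- !is.null(x_test) && !is.null(y_test) && length(y_test) > 0
  if (ts_avail) {
    x_test <- as.matrix(x_test)
    xts <- sweep(sweep(x_test, 2L, x_center), 2L, x_scale, "/")
    yts <- y_a + y_b * y_test
  }

  lr <- learn_rate
  result <- NULL
  for (restart in 0:max_restarts) {
    w <- .mlp_init(architecture)
    v <- lapply(w, function(m) m * 0)
    history <- numeric(0)
    best <- list(w = w, err = Inf, epoch = 0L)
    stall <- 0L
    diverged <- FALSE
    epoch <- 0L
    while (epoch < epochs) {
      epoch <- epoch + 1L
      fw <- .mlp_forward(xs, w$W1, w$b1, w$W2, w$b2, architecture)
      res <- fw$a2[, 1L] - ys
      sse <- sum(res^2)
      history[epoch] <- sse
      if (!is.finite(sse)) { diverged <- TRUE; break }
      d2 <- (2 / n) * res *
        .mlp_dact(fw$z2, fw$a2, architecture$output_activation)[, 1L]
      gW2 <- matrix(d2, 1L, n) %*% fw$a1
      gb2 <- sum(d2)
      d1 <- (d2 %*% w$W2) * .mlp_dact(fw$z1, fw$a1, architecture$hidden_activation)
      gW1 <- t(d1) %*% xs
      gb1 <- colSums(d1)
      v$W1 <- momentum * v$W1 - lr * gW1
      v$b1 <- momentum * v$b1 - lr * gb1
      v$W2 <- momentum * v$W2 - lr * gW2
      v$b2 <- momentum * v$b2 - lr * gb2
      w$W1 <- w$W1 + v$W1; w$b1 <- w$b1 + v$b1
      w$W2 <- w$W2 + v$W2; w$b2 <- w$b2 + v$b2
      if (any(!vapply(w, function(m) all(is.finite(m)), TRUE))) {
        diverged <- TRUE; break
      }
      if (ts_avail) {
        ft <- .mlp_forward(xts, w$W1, w$b1, w$W2, w$b2, architecture)
        terr <- sum((ft$a2[, 1L] - yts)^2)
        if (is.finite(terr) && terr < best$err - 1e-12) {
          best <- list(w = w, err = terr, epoch = epoch)
          stall <- 0L
        } else {
          stall <- stall + 1L
          if (stall >= patience) break
        }
      }
    }
    if (!diverged) {
      final_w <- if (ts_avail && is.finite(best$err)) best$w else w
      result <- list(w = final_w, history = history,
                     stopped_epoch = if (ts_avail) best$epoch else epoch)
      break
    }
    lr <- lr / 2
  }
  if (is.null(result))
    stop("MLP training diverged after ", max_restarts,
         " restarts (architecture ", architecture$name, ")")

  model <- structure(
    list(architecture = architecture, W1 = result$w$W1, b1 = result$w$b1,
         W2 = result$w$W2, b2 = result$w$b2,
         x_center = x_center, x_scale = x_scale, y_a = y_a, y_b = y_b,
         transform = transform,
         input_names = if (is.null(input_names)) colnames(x_train) else input_names,
         history = result$history, stopped_epoch = result$stopped_epoch,
         learn_rate = lr, seed = seed, metrics = NULL),
    class = "qspr_mlp")
  model$fitted_transformed <- predict(model, x_train, type = "transformed")
  model
}

#' Predict from a trained QSPR MLP
#'
#' Forward pass with the training-block standardization, inverse response
#' map, and (for `type = "rate"`) inverse log10 transform.
#'
#' @param object A [train_mlp()] model.
#' @param newdata Matrix or data frame of descriptors. If it carries the
#'   model's input columns by name any superset is accepted; otherwise the
#'   column count must match exactly.
#' @param type `"rate"` for rate constants on the original k scale,
#'   `"transformed"` for the training response scale.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.qspr_mlp <- function(object, newdata,
                             type = c("rate", "transformed"), ...) {
  type <- match.arg(type)
  x <- as.matrix(newdata)
  nm <- object$input_names
  if (!is.null(nm) && !is.null(colnames(x)) && all(nm %in% colnames(x))) {
    x <- x[, nm, drop = FALSE]
  } else if (ncol(x) != object$architecture$n_inputs) {
    stop("newdata has ", ncol(x), " columns but the model expects ",
         object$architecture$n_inputs)
  }
  xs <- sweep(sweep(x, 2L, object$x_center), 2L, object$x_scale, "/")
  fw <- .mlp_forward(xs, object$W1, object$b1, object$W2, object$b2,
                     object$architecture)
  y <- (fw$a2[, 1L] - object$y_a) / object$y_b
  if (type == "transformed") return(unname(y))
  if (object$transform == "log10") 10^unname(y) else unname(y)
}

#' @export
print.qspr_mlp <- function(x, ...) {
  cat(sprintf("%s (%s hidden, %s output), trained %d epochs\n",
              x$architecture$name, x$architecture$hidden_activation,
              x$architecture$output_activation, length(x$history)))
  if (!is.null(x$metrics)) {
    m <- x$metrics
    cat(sprintf("  R2 train/test/validation: %.4f / %.4f / %.4f\n",
                m$r2_train, m$r2_test, m$r2_validation))
  }
  invisible(x)
}

#' Randomized architecture search
#'
#' Samples architectures uniformly from the search space (hidden width
#' 4-13, hidden and output activations from identity/logistic/tanh/
#' exponential), trains each on the training block with early stopping on
#' the test block, and ranks candidates by validation R^2 (computed on the
#' transformed response scale). The validation block is untouched during
#' training.
#'
#' @param dataset A [qspr_dataset()].
#' @param split Output of [split_dataset()].
#' @param n_candidates Number of architectures to sample (>= 1).
#' @param seed Integer seed driving architecture sampling and weight
#'   initialization.
#' @param inputs Integer indices of descriptor columns to use; default all.
#' @param ... Further arguments to [train_mlp()] (epochs, learn_rate,
#'   patience, ...).
#' @return List with `model` (the winner, its `metrics` field filled) and
#'   `leaderboard` (one row per candidate, ranked by validation R^2).
#' @export
random_search <- function(dataset, split, n_candidates = 20L, seed = 1L,
                          inputs = NULL, ...) {
  stopifnot(inherits(dataset, "qspr_dataset"), n_candidates >= 1L)
  if (is.null(inputs)) inputs <- seq_len(ncol(dataset$x))
  x <- dataset$x[, inputs, drop = FALSE]
  tr <- split$calibration$train
  te <- split$calibration$test
  va <- split$calibration$validation
  acts <- c("identity", "logistic", "tanh", "exponential")

  set.seed(seed)
  cand <- data.frame(n_hidden = sample(4:13, n_candidates, replace = TRUE),
                     hidden = sample(acts, n_candidates, replace = TRUE),
                     output = sample(acts, n_candidates, replace = TRUE),
                     stringsAsFactors = FALSE)

  models <- vector("list", n_candidates)
  rows <- vector("list", n_candidates)
  for (i in seq_len(n_candidates)) {
    arch <- mlp_architecture(length(inputs), cand$n_hidden[i],
                             cand$hidden[i], cand$output[i])
    m <- tryCatch(
      train_mlp(x[tr, , drop = FALSE], dataset$y[tr], arch,
                x_test = x[te, , drop = FALSE], y_test = dataset$y[te],
                seed = (seed * 1000L + i) %% .Machine$integer.max,
                transform = dataset$transform, ...),
      error = function(e) NULL)
    if (is.null(m)) {
      rows[[i]] <- data.frame(candidate = i, network = arch$name,
                              n_hidden = arch$n_hidden,
                              hidden = arch$hidden_activation,
                              output = arch$output_activation,
                              r2_train = NA_real_, r2_test = NA_real_,
                              r2_validation = NA_real_,
                              stringsAsFactors = FALSE)
      next
    }
    r2b <- function(idx) {
      obs <- dataset$y[idx]
      prd <- predict(m, x[idx, , drop = FALSE], type = "transformed")
      1 - sum((obs - prd)^2) / sum((obs - mean(obs))^2)
    }
    m$metrics <- list(r2_train = r2b(tr), r2_test = r2b(te),
                      r2_validation = r2b(va))
    models[[i]] <- m
    rows[[i]] <- data.frame(candidate = i, network = arch$name,
                            n_hidden = arch$n_hidden,
                            hidden = arch$hidden_activation,
                            output = arch$output_activation,
                            r2_train = m$metrics$r2_train,
                            r2_test = m$metrics$r2_test,
                            r2_validation = m$metrics$r2_validation,
                            stringsAsFactors = FALSE)
  }
  leaderboard <- do.call(rbind, rows)
  ok <- which(is.finite(leaderboard$r2_validation))
  if (!length(ok))
    stop("all ", n_candidates, " candidates failed to train")
  leaderboard <- leaderboard[order(-leaderboard$r2_validation), ]
  rownames(leaderboard) <- NULL
  best_id <- leaderboard$candidate[1L]
  list(model = models[[best_id]], leaderboard = leaderboard)
}

#' Save a trained model to JSON
#'
#' The archive holds the architecture, weights, standardization constants,
#' response map, seed and metrics at full double precision; [load_model()]
#' restores a model whose predictions match the original bitwise.
#'
#' @param model A [train_mlp()] model.
#' @param path Output JSON file.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "qspr_mlp"))
  payload <- list(
    architecture = unclass(model$architecture),
    W1 = model$W1, b1 = model$b1, W2 = model$W2, b2 = model$b2,
    x_center = as.list(model$x_center), x_scale = as.list(model$x_scale),
    y_a = model$y_a, y_b = model$y_b, transform = model$transform,
    input_names = model$input_names, history = model$history,
    stopped_epoch = model$stopped_epoch, learn_rate = model$learn_rate,
    seed = model$seed, metrics = model$metrics)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' Load a model saved by [save_model()]
#'
#' @param path JSON archive.
#' @return A `qspr_mlp` model.
#' @export
load_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  arch <- mlp_architecture(p$architecture$n_inputs, p$architecture$n_hidden,
                           p$architecture$hidden_activation,
                           p$architecture$output_activation)
  model <- structure(
    list(architecture = arch,
         W1 = matrix(as.numeric(p$W1), arch$n_hidden, arch$n_inputs),
         b1 = as.numeric(p$b1),
         W2 = matrix(as.numeric(p$W2), 1L, arch$n_hidden),
         b2 = as.numeric(p$b2),
         x_center = unlist(p$x_center), x_scale = unlist(p$x_scale),
         y_a = p$y_a, y_b = p$y_b, transform = p$transform,
         input_names = p$input_names, history = as.numeric(p$history),
         stopped_epoch = p$stopped_epoch, learn_rate = p$learn_rate,
         seed = p$seed, metrics = p$metrics),
    class = "qspr_mlp")
  model
}
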