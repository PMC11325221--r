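# Chemometric model evaluation: per-block calibration metrics, held-out
# prediction metrics (RMSEP, SEP, RPD, RER, adjusted R2), and the standard
# quality/usability classification bands.

#' Calibration metrics per data block
#'
#' `R2 = 1 - SS_res / SS_tot` (mean-centered) and
#' `RMSE = sqrt(mean(residual^2))`, computed for each block of the
#' calibration data (training / test / validation).
#'
#' @param observed,predicted Numeric vectors on the same scale.
#' @param blocks Optional factor/character vector of block labels; when
#'   omitted a single block `"all"` is assumed.
#' @return Data frame with columns block, n, r2, rmse. A block with zero
#'   variance in `observed` gets `r2 = NA` and a warning.
#' @export
calibration_metrics <- function(observed, predicted, blocks = NULL) {
  if (length(observed) != length(predicted))
    stop("observed and predicted must have the same length")
  if (is.null(blocks)) blocks <- rep("all", length(observed))
  out <- lapply(split(seq_along(observed), blocks), function(idx) {
    if (length(idx) < 2L)
      stop("each block needs at least 2 points")
    o <- observed[idx]; p <- predicted[idx]
    sstot <- sum((o - mean(o))^2)
    ssres <- sum((o - p)^2)
    r2 <- if (sstot == 0) {
      warning("zero variance in observed values; R2 undefined")
      NA_real_
    } else 1 - ssres / sstot
    data.frame(block = blocks[idx[1L]], n = length(idx), r2 = r2,
               rmse = sqrt(mean((o - p)^2)), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Prediction metrics on the held-out set
#'
#' With residuals `e = observed - predicted`:
#' * `RMSEP = sqrt(sum(e^2) / n)`
#' * `bias = mean(e)`
#' * `SEP = sqrt(sum((e - bias)^2) / (n - 1))` (bias-corrected scatter)
#' * `RPD = sd(observed) / SEP`
#' * `RER = range(observed) / SEP`
#' * `R2_pred = 1 - SS_res / SS_tot`
#' * `R2_pred_adj = 1 - (1 - R2_pred) (n - 1) / (n - p - 1)`
#'
#' RPD and RER use the SEP denominator by default (the standard
#' chemometric definition); `denominator = "rmsep"` is available for
#' sensitivity analysis. A zero denominator yields `Inf`.
#'
#' @param observed,predicted Held-out observations and predictions
#'   (>= 3 points).
#' @param n_predictors Number of model inputs p, for the adjusted R2;
#'   `n <= p + 1` leaves it `NA` with a flag.
#' @param denominator `"sep"` (default) or `"rmsep"`.
#' @return Object of class `evaluation_report` (a list): r2_pred,
#'   r2_pred_adj, rmsep, bias, sep, rpd, rer, n_pred, n_predictors,
#'   denominator, flags.
#' @export
prediction_metrics <- function(observed, predicted, n_predictors,
                               denominator = c("sep", "rmsep")) {
  denominator <- match.arg(denominator)
  if (length(observed) != length(predicted))
    stop("observed and predicted must have the same length")
  n <- length(observed)
  if (n < 3L) stop("prediction set needs at least 3 points")
  e <- observed - predicted
  rmsep <- sqrt(sum(e^2) / n)
  bias <- mean(e)
  sep <- sqrt(sum((e - bias)^2) / (n - 1))
  den <- if (denominator == "sep") sep else rmsep
  rpd <- if (den > 0) stats::sd(observed) / den else Inf
  rer <- if (den > 0) diff(range(observed)) / den else Inf
  sstot <- sum((observed - mean(observed))^2)
  r2 <- if (sstot > 0) 1 - sum(e^2) / sstot else NA_real_
  flags <- character(0)
  if (n <= n_predictors + 1L) {
    r2adj <- NA_real_
    flags <- c(flags, "adjusted_r2_undefined")
  } else {
    r2adj <- 1 - (1 - r2) * (n - 1) / (n - n_predictors - 1)
  }
  structure(list(r2_pred = r2, r2_pred_adj = r2adj, rmsep = rmsep,
                 bias = bias, sep = sep, rpd = rpd, rer = rer,
                 n_pred = n, n_predictors = n_predictors,
                 denominator = denominator, flags = flags),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("prediction metrics (n = %d, p = %d, %s denominator):\n",
              x$n_pred, x$n_predictors, x$denominator))
  cat(sprintf("  R2_pred = %.4f (adj %.4f), RMSEP = %.4g, SEP = %.4g\n",
              x$r2_pred, x$r2_pred_adj, x$rmsep, x$sep))
  cat(sprintf("  RPD = %.3f, RER = %.3f\n", x$rpd, x$rer))
  cls <- classify_model(x)
  cat(sprintf("  quality: %s; usability: %s; substantial: %s\n",
              cls$quality, cls$usability, cls$substantial))
  invisible(x)
}

#' Classify model quality from RPD, RER and predictive R2
#'
#' Quality from RPD bands: below 1.4 non-reliable, 1.4 to 2 (both ends
#' included) fair, above 2 excellent. Usability from RER bands with the
#' highest band winning: above 4 screening, above 10 quality control,
#' above 15 quantification (strict inequalities). A model is "substantial"
#' when `R2_pred > 0.75`.
#'
#' @param report An [prediction_metrics()] report, or `NULL` when the
#'   individual values are given.
#' @param rpd,rer,r2_pred Individual values, used when `report` is `NULL`.
#' @return List with `quality` (`"non-reliable"`, `"fair"`,
#'   `"excellent"`), `usability` (`"none"`, `"screening"`,
#'   `"quality-control"`, `"quantification"`) and `substantial` (logical,
#'   `NA` when r2_pred is unavailable).
#' @export
classify_model <- function(report = NULL, rpd = NULL, rer = NULL,
                           r2_pred = NULL) {
  if (!is.null(report)) {
    stopifnot(inherits(report, "evaluation_report"))
    rpd <- report$rpd; rer <- report$rer; r2_pred <- report$r2_pred
  }
  if (is.null(rpd) || is.null(rer))
    stop("rpd and rer are required")
  quality <- if (rpd < 1.4) "non-reliable" else if (rpd <= 2) "fair" else "excellent"
  usability <- if (rer > 15) "quantification" else if (rer > 10) "quality-control" else if (rer > 4) "screening" else "none"
  substantial <- if (is.null(r2_pred) || is.na(r2_pred)) NA else r2_pred > 0.75
  list(quality = quality, usability = usability, substantial = substantial)
}

#' Serialize an evaluation report
#'
#' @param report An [prediction_metrics()] report.
#' @param path Output JSON file.
#' @param calibration Optional [calibration_metrics()] data frame included
#'   under `"calibration"`.
#' @param network Optional network name (e.g. `"MLP 8-6-1"`).
#' @export
write_evaluation_report <- function(report, path, calibration = NULL,
                                    network = NULL) {
  stopifnot(inherits(report, "evaluation_report"))
  cls <- classify_model(report)
  payload <- c(if (!is.null(network)) list(network = network),
               unclass(report), cls,
               if (!is.null(calibration)) list(calibration = calibration))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       dataframe = "rows")
  invisible(path)
}
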