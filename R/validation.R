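#' External-validation metric battery
#'
#' Computes the standard external-validation statistics for one
#' (observed, predicted) pairing of activities:
#' \itemize{
#'   \item `R2` — squared Pearson correlation.
#'   \item `R2_0` — through-origin determination coefficient of the
#'     observed-on-predicted fit: with slope `k = sum(obs*pred)/sum(pred^2)`,
#'     `R2_0 = 1 - sum((obs - k*pred)^2) / sum((obs - mean(obs))^2)`.
#'   \item `R2p_0` — the swapped (predicted-on-observed) analogue.
#'   \item `rm2` / `rm2_prime` — `R2 * (1 - sqrt(R2 - R2_0))` and the primed
#'     analogue; `rm2_avg` is their mean, `rm2_delta` the absolute
#'     difference. When `R2 - R2_0 < 0` (numerically possible), the absolute
#'     value is used under the square root and `rm2_flag` is set.
#'   \item `CCC` — concordance correlation coefficient
#'     `2*cov / (var_obs + var_pred + (mean_obs - mean_pred)^2)` with
#'     population (1/n) moments, the concordance convention.
#'   \item `Q2_F1` / `Q2_F2` — external predictivity referencing the training
#'     mean and the test mean, respectively.
#'   \item `RMSE`, `MAE`; `SD` — the standard deviation of the absolute
#'     residuals, so that `MAE_plus_3SD = MAE + 3*SD` exactly.
#' }
#'
#' @param obs,pred numeric vectors of equal length >= 3.
#' @param train_mean training-set mean activity (required for `Q2_F1`).
#' @return List of class `metric_report`.
#' @examples
#' metric_battery(1:4, c(1.1, 2.1, 2.9, 4.2), train_mean = 2.5)
#' @export
metric_battery <- function(obs, pred, train_mean = NULL) {
  stopifnot(length(obs) == length(pred), length(obs) >= 3)
  obs <- as.numeric(obs); pred <- as.numeric(pred)
  if (stats::var(obs) == 0) stop("observed values have zero variance")

  r2 <- suppressWarnings(stats::cor(obs, pred))^2  # NA for constant pred
  ss_obs <- sum((obs - mean(obs))^2)
  ss_pred <- sum((pred - mean(pred))^2)
  k <- sum(obs * pred) / sum(pred^2)
  r2_0 <- 1 - sum((obs - k * pred)^2) / ss_obs
  kp <- sum(obs * pred) / sum(obs^2)
  r2p_0 <- 1 - sum((pred - kp * obs)^2) / ss_pred

  rm2_flag <- (r2 - r2_0 < 0) || (r2 - r2p_0 < 0)
  rm2 <- r2 * (1 - sqrt(abs(r2 - r2_0)))
  rm2p <- r2 * (1 - sqrt(abs(r2 - r2p_0)))

  ccc <- 2 * mean((obs - mean(obs)) * (pred - mean(pred))) /
    (mean((obs - mean(obs))^2) + mean((pred - mean(pred))^2) +
       (mean(obs) - mean(pred))^2)

  res <- obs - pred
  q2_f1 <- if (is.null(train_mean)) NA_real_ else
    1 - sum(res^2) / sum((obs - train_mean)^2)
  q2_f2 <- 1 - sum(res^2) / ss_obs

  mae <- mean(abs(res))
  sd_abs <- stats::sd(abs(res))
  structure(list(
    n_used = length(obs),
    R2 = r2, R2_0 = r2_0, R2p_0 = r2p_0,
    rm2 = rm2, rm2_prime = rm2p,
    rm2_avg = (rm2 + rm2p) / 2, rm2_delta = abs(rm2 - rm2p),
    rm2_flag = rm2_flag,
    CCC = ccc, Q2_F1 = q2_f1, Q2_F2 = q2_f2,
    RMSE = sqrt(mean(res^2)), MAE = mae, SD = sd_abs,
    MAE_plus_3SD = mae + 3 * sd_abs,
    systematic_error = if (length(obs) >= 5) systematic_error_check(obs, pred) else NA
  ), class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("metric_report (n = %d)\n", x$n_used))
  num <- vapply(x[c("R2", "R2_0", "R2p_0", "rm2_avg", "rm2_delta", "CCC",
                    "Q2_F1", "Q2_F2", "RMSE", "MAE", "SD", "MAE_plus_3SD")],
                identity, 0)
  print(round(num, 4))
  if (!is.na(x$systematic_error))
    cat("systematic error:", if (x$systematic_error) "present" else "absent", "\n")
  invisible(x)
}

#' Remove the records with the largest residuals
#'
#' Drops the `ceiling(fraction * n)` records with the largest absolute
#' residuals (at least one when `fraction > 0`; ties broken by position),
#' mirroring the "95% of the data" variants of validation tables.
#'
#' @param obs,pred numeric vectors.
#' @param fraction fraction to remove, in `[0, 0.5)`; default 0.05.
#' @param ids optional record ids.
#' @return List with `obs`, `pred`, `removed` (ids or indices).
#' @export
trim_high_residuals <- function(obs, pred, fraction = 0.05, ids = NULL) {
  stopifnot(length(obs) == length(pred), fraction >= 0, fraction < 0.5)
  if (is.null(ids)) ids <- seq_along(obs)
  if (fraction == 0) return(list(obs = obs, pred = pred, removed = ids[0]))
  n <- length(obs)
  k <- ceiling(fraction * n)
  drop <- order(-abs(obs - pred), seq_len(n))[seq_len(k)]
  list(obs = obs[-drop], pred = pred[-drop], removed = ids[drop])
}

#' Classify model quality from the metric battery
#'
#' Applies the threshold rules tying prediction errors to the training
#' activity range. A model is \strong{high} quality when MAE and MAE+3SD are
#' both within 10% of the range, `rm2_avg > 0.85` with `rm2_delta < 0.15`,
#' and the determination family (R2, R2_0, R2p_0, CCC) is mutually close
#' (max pairwise gap <= 0.1) with all values >= 0.85. It is \strong{low}
#' quality when MAE exceeds 20% of the range, or MAE+3SD exceeds 25%, or
#' `rm2_avg <= 0.5` with `rm2_delta <= 0.2`, or the whole determination
#' family is <= 0.6. Everything else is \strong{moderate}. The 10%-of-range
#' bound on MAE+3SD is the literal printed rule; `mae3sd_high_frac` allows
#' the common 20% convention instead.
#'
#' @param report a [metric_battery()] result.
#' @param activity_range training-set activity range (log-units), > 0.
#' @param mae3sd_high_frac fraction of the range that MAE+3SD must not exceed
#'   for high quality (default 0.10).
#' @return `"high"`, `"moderate"` or `"low"`.
#' @export
classify_quality <- function(report, activity_range, mae3sd_high_frac = 0.10) {
  stopifnot(inherits(report, "metric_report"), activity_range > 0)
  rfam <- c(report$R2, report$R2_0, report$R2p_0, report$CCC)
  gap <- max(rfam) - min(rfam)
  high <- report$MAE <= 0.10 * activity_range &&
    report$MAE_plus_3SD <= mae3sd_high_frac * activity_range &&
    report$rm2_avg > 0.85 && report$rm2_delta < 0.15 &&
    gap <= 0.1 && all(rfam >= 0.85)
  if (high) return("high")
  low <- report$MAE > 0.20 * activity_range ||
    report$MAE_plus_3SD > 0.25 * activity_range ||
    (report$rm2_avg <= 0.5 && report$rm2_delta <= 0.2) ||
    all(rfam <= 0.6)
  if (low) "low" else "moderate"
}

#' Check predictions for systematic error
#'
#' Flags a systematic (one-sided) error when the mean residual is large
#' relative to the mean absolute residual (`|mean(res)| > 0.5 * MAE`) or when
#' more than 80% of the residuals share one sign.
#'
#' @param obs,pred numeric vectors, length >= 5.
#' @return `TRUE` if a systematic error is detected.
#' @export
systematic_error_check <- function(obs, pred) {
  stopifnot(length(obs) == length(pred), length(obs) >= 5)
  res <- obs - pred
  mae <- mean(abs(res))
  if (mae == 0) return(FALSE)
  same_sign <- max(mean(res > 0), mean(res < 0))
  abs(mean(res)) > 0.5 * mae || same_sign > 0.8
}
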