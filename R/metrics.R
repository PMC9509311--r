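#' Regression error metrics
#'
#' Computes the validation statistics used throughout the package:
#' RMSE, MAE, bias (mean of predicted minus observed), MAPE (computed only
#' over observations above `mape_eps` to avoid division blow-up, with the
#' excluded count reported), Pearson correlation `r`, and the coefficient of
#' determination `r2 = 1 - SS_res/SS_tot`. `r2` may be negative when a model
#' performs worse than the observed mean; `r` is `NA` when either vector is
#' constant.
#'
#' @param pred,obs Numeric vectors of equal length (>= 2).
#' @param mape_eps Observations at or below this value are excluded from
#'   MAPE (default 0.05, in outcome units).
#' @return One-row tibble: `rmse`, `mae`, `bias`, `mape` (percent), `r`,
#'   `r2`, `n`, `n_mape_excluded`.
#' @export
#' @examples
#' regression_metrics(c(2, 2, 2), c(1, 2, 3))
regression_metrics <- function(pred, obs, mape_eps = 0.05) {
  if (length(pred) != length(obs)) {
    stop("pred and obs must have equal length", call. = FALSE)
  }
  ok <- is.finite(pred) & is.finite(obs)
  pred <- pred[ok]; obs <- obs[ok]
  if (length(obs) < 2L) stop("need at least 2 paired values", call. = FALSE)
  err <- pred - obs
  ss_tot <- sum((obs - mean(obs))^2)
  mape_ok <- obs > mape_eps
  tibble::tibble(
    rmse = sqrt(mean(err^2)),
    mae = mean(abs(err)),
    bias = mean(err),
    mape = if (any(mape_ok)) 100 * mean(abs(err[mape_ok]) / obs[mape_ok])
           else NA_real_,
    r = if (stats::sd(obs) > 0 && stats::sd(pred) > 0)
          stats::cor(pred, obs) else NA_real_,
    r2 = if (ss_tot > 0) 1 - sum(err^2) / ss_tot else NA_real_,
    n = length(obs),
    n_mape_excluded = sum(!mape_ok)
  )
}
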