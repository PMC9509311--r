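## Cross-validation harnesses for the LAI model tree.
##
## Two schemes mirror common practice for small ground-sample archives:
## repeated k-fold CV (random splits, repeated because small-sample fits are
## split-sensitive) and leave-one-site-out CV, which probes spatial
## generalization by holding out one vineyard at a time.

# per-fold metrics are NA when a fold holds a single sample (leave-one-out);
# pooled metrics still cover every held-out prediction
metrics_or_na <- function(pred, obs) {
  if (length(obs) < 2L) {
    return(tibble::tibble(rmse = NA_real_, mae = NA_real_, bias = NA_real_,
                          mape = NA_real_, r = NA_real_, r2 = NA_real_,
                          n = length(obs), n_mape_excluded = NA_integer_))
  }
  regression_metrics(pred, obs)
}

fold_assignment <- function(n, k, seed) {
  set.seed(seed)
  # near-equal fold sizes via a seeded shuffle
  sample(rep(seq_len(k), length.out = n))
}

#' Repeated k-fold cross-validation for the model tree
#'
#' For each repetition a fresh seeded shuffle defines `k` near-equal folds;
#' the model is fit on `k - 1` folds and scored on the held-out fold. Test
#' metrics pool all held-out predictions within a repetition and are then
#' averaged across repetitions; train metrics pool each fold model's
#' predictions on its own training rows analogously.
#'
#' @param data Training table (outcome + feature columns, optional `weight`).
#' @param k Number of folds (`k = nrow(data)` gives leave-one-out).
#' @param repeats Number of repetitions (>= 1).
#' @param seed Integer seed; repetition `i` uses `seed + i - 1`.
#' @param ... Passed to [model_tree()] (e.g. `max_rules`, `min_leaf_n`).
#' @return An object of class `cv_report`: list with `folds` (per
#'   repetition/fold/split metric rows), `pooled` (per-split metrics averaged
#'   across repetitions), and `k`, `repeats`, `seed`.
#' @export
cv_kfold <- function(data, k = 5, repeats = 20, seed = 1, ...) {
  n <- nrow(data)
  if (repeats < 1) stop("repeats must be >= 1", call. = FALSE)
  if (n < k) stop("need at least k samples", call. = FALSE)
  outcome <- list(...)$outcome %||% "lai"
  per_rep <- purrr::map(seq_len(repeats), function(rep_i) {
    folds <- fold_assignment(n, k, seed + rep_i - 1L)
    test_pred <- rep(NA_real_, n)
    train_pred <- list(); train_obs <- list()
    fold_rows <- purrr::map_dfr(seq_len(k), function(f) {
      tr <- folds != f
      fit <- model_tree(data[tr, , drop = FALSE], ...)
      p_te <- predict(fit, data[!tr, , drop = FALSE])
      p_tr <- predict(fit, data[tr, , drop = FALSE])
      test_pred[!tr] <<- p_te
      train_pred[[f]] <<- as.numeric(p_tr)
      train_obs[[f]] <<- data[[fit$outcome]][tr]
      dplyr::bind_rows(
        dplyr::mutate(metrics_or_na(p_tr, data[[fit$outcome]][tr]),
                      split = "train", .before = 1),
        dplyr::mutate(metrics_or_na(p_te, data[[fit$outcome]][!tr]),
                      split = "test", .before = 1)
      ) |> dplyr::mutate(rep = rep_i, fold = f, .before = 1)
    })
    obs <- data[[outcome]]
    pooled <- dplyr::bind_rows(
      dplyr::mutate(regression_metrics(unlist(train_pred), unlist(train_obs)),
                    split = "train", .before = 1),
      dplyr::mutate(regression_metrics(test_pred, obs),
                    split = "test", .before = 1)
    ) |> dplyr::mutate(rep = rep_i, .before = 1)
    list(folds = fold_rows, pooled = pooled)
  })
  folds <- purrr::map_dfr(per_rep, "folds")
  pooled_reps <- purrr::map_dfr(per_rep, "pooled")
  pooled <- pooled_reps |>
    dplyr::group_by(.data$split) |>
    dplyr::summarise(dplyr::across(
      c("rmse", "mae", "bias", "mape", "r", "r2"), mean),
      n = dplyr::first(.data$n), .groups = "drop")
  structure(list(folds = folds, pooled_reps = pooled_reps, pooled = pooled,
                 k = k, repeats = repeats, seed = seed),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("Repeated %d-fold CV, %d repetition(s), seed %d\n",
              x$k, x$repeats, x$seed))
  print(x$pooled)
  invisible(x)
}

#' Tidy a cross-validation report
#'
#' @param x A `cv_report` from [cv_kfold()].
#' @param ... Unused.
#' @return The per-repetition, per-fold metric rows as a tibble.
#' @method tidy cv_report
#' @export
tidy.cv_report <- function(x, ...) tibble::as_tibble(x$folds)

#' Glance at a cross-validation report
#'
#' @param x A `cv_report` from [cv_kfold()].
#' @param ... Unused.
#' @return One-row tibble with pooled test metrics plus `k`, `repeats`.
#' @method glance cv_report
#' @export
glance.cv_report <- function(x, ...) {
  dplyr::filter(x$pooled, .data$split == "test") |>
    dplyr::select(-"split") |>
    dplyr::mutate(k = x$k, repeats = x$repeats)
}

#' Leave-one-site-out cross-validation
#'
#' Holds out each site in turn: the model is trained on all other sites and
#' evaluated on the held-out site, probing spatial generalization across
#' vineyards with different canopy architecture. An `"overall"` row pools
#' all held-out predictions.
#'
#' @param data Training table including a `site` column with >= 2 sites.
#' @param ... Passed to [model_tree()].
#' @return Tibble with one train and one test metrics row per site, plus a
#'   pooled `"overall"` test row.
#' @export
cv_leave_site_out <- function(data, ...) {
  if (!"site" %in% names(data)) stop("data needs a 'site' column",
                                     call. = FALSE)
  sites <- unique(data$site)
  if (length(sites) < 2L) stop("need at least 2 distinct sites",
                               call. = FALSE)
  held <- purrr::map(sites, function(s) {
    tr <- data$site != s
    fit <- model_tree(data[tr, , drop = FALSE], ...)
    p_te <- predict(fit, data[!tr, , drop = FALSE])
    p_tr <- predict(fit, data[tr, , drop = FALSE])
    list(
      rows = dplyr::bind_rows(
        dplyr::mutate(regression_metrics(p_tr, data[[fit$outcome]][tr]),
                      site = as.character(s), split = "train", .before = 1),
        dplyr::mutate(regression_metrics(p_te, data[[fit$outcome]][!tr]),
                      site = as.character(s), split = "test", .before = 1)
      ),
      pred = as.numeric(p_te),
      obs = data[[fit$outcome]][!tr]
    )
  })
  overall <- regression_metrics(unlist(purrr::map(held, "pred")),
                                unlist(purrr::map(held, "obs"))) |>
    dplyr::mutate(site = "overall", split = "test", .before = 1)
  dplyr::bind_rows(purrr::map_dfr(held, "rows"), overall)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
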