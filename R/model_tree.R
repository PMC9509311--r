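## Rule-based piecewise-linear regression ("model tree").
##
## The tree is grown greedily: at each step the leaf offering the largest
## score -- the drop from its weighted outcome SD to the pooled residual
## RMSE of side-wise linear fits -- is split at a midpoint between sorted
## unique feature values, until the leaf budget (`max_rules`) is exhausted
## or no admissible split remains.  Each leaf then carries a weighted
## least-squares linear model with backward feature elimination.
## Rules are the ordered root-to-leaf paths, so every point is matched by
## exactly one rule.

weighted_sd <- function(y, w) {
  W <- sum(w)
  m <- sum(w * y) / W
  sqrt(sum(w * (y - m)^2) / W)
}

weighted_rmse <- function(resid, w) sqrt(sum(w * resid^2) / sum(w))

# best (feature, threshold) split of one node, evaluated at every midpoint
# between sorted unique values via cumulative sums. The score is the
# reduction from the leaf's weighted outcome SD to the pooled residual RMSE
# of per-side simple linear fits in the candidate feature: because the
# leaves carry linear models, scoring residuals around side-wise lines (not
# raw outcome spread) is what recovers the breakpoint of a continuous
# piecewise-linear signal exactly. Ties break to the lowest-indexed feature
# then lowest threshold (strict improvement required), so fitting is
# deterministic.
best_split <- function(X, y, w, features, min_leaf_w) {
  parent_sd <- weighted_sd(y, w)
  W <- sum(w)
  best <- NULL
  best_score <- 1e-12
  for (f in features) {
    x <- X[[f]]
    ord <- order(x)
    xs <- x[ord]; ys <- y[ord]; ws <- w[ord]
    n <- length(xs)
    boundary <- which(xs[-n] < xs[-1L])  # split points between distinct xs
    if (length(boundary) == 0L) next
    cw <- cumsum(ws); cwx <- cumsum(ws * xs); cwx2 <- cumsum(ws * xs^2)
    cwy <- cumsum(ws * ys); cwy2 <- cumsum(ws * ys^2)
    cwxy <- cumsum(ws * xs * ys)
    # centred second moments per side; residual SSE of y ~ x on each side
    side_sse <- function(Ws, Sx, Sxx, Sy, Syy, Sxy) {
      sxx <- pmax(Sxx - Sx^2 / Ws, 0)
      syy <- pmax(Syy - Sy^2 / Ws, 0)
      sxy <- Sxy - Sx * Sy / Ws
      pmax(syy - ifelse(sxx > 1e-12, sxy^2 / sxx, 0), 0)
    }
    b <- boundary
    wl <- cw[b]; wr <- W - wl
    sse_l <- side_sse(wl, cwx[b], cwx2[b], cwy[b], cwy2[b], cwxy[b])
    sse_r <- side_sse(wr, cwx[n] - cwx[b], cwx2[n] - cwx2[b],
                      cwy[n] - cwy[b], cwy2[n] - cwy2[b],
                      cwxy[n] - cwxy[b])
    score <- parent_sd - sqrt((sse_l + sse_r) / W)
    score[wl < min_leaf_w | wr < min_leaf_w] <- -Inf
    i <- which.max(score)  # lowest threshold among ties (which.max = first)
    if (score[i] > best_score) {
      best_score <- score[i]
      best <- list(feature = f,
                   threshold = (xs[b[i]] + xs[b[i] + 1L]) / 2,
                   score = score[i])
    }
  }
  best
}

# weighted OLS leaf with backward elimination: a feature is dropped when the
# reduced model's training RMSE stays within 1% of the full model's RMSE
fit_leaf <- function(X, y, w, features, rmse_slack = 0.01) {
  fit_ols <- function(feats) {
    M <- cbind(`(Intercept)` = 1,
               as.matrix(X[, feats, drop = FALSE]))
    fit <- stats::lm.wfit(M, y, w)
    beta <- fit$coefficients
    beta[is.na(beta)] <- 0
    list(beta = beta, rmse = weighted_rmse(y - M %*% beta, w))
  }
  full <- fit_ols(features)
  budget <- full$rmse * (1 + rmse_slack) + 1e-12
  retained <- features
  current <- full
  repeat {
    if (length(retained) == 0L) break
    trial_rmse <- vapply(seq_along(retained), function(i) {
      fit_ols(retained[-i])$rmse
    }, numeric(1))
    i_best <- which.min(trial_rmse)
    if (trial_rmse[i_best] <= budget) {
      retained <- retained[-i_best]
      current <- fit_ols(retained)
    } else break
  }
  coefs <- current$beta[-1L]
  names(coefs) <- retained
  list(intercept = unname(current$beta[1L]),
       coefficients = coefs,
       retained = retained,
       rmse = current$rmse)
}

#' Fit a rule-based piecewise-linear LAI model
#'
#' Fits a model tree: a small set of ordered rules (conjunctions of
#' single-band threshold tests) each ending in a multivariate weighted
#' least-squares linear model. Splits are scored by the reduction from the
#' leaf's weighted outcome standard deviation to the residual RMSE of
#' side-wise linear fits in the split feature (so the breakpoint of a
#' continuous piecewise-linear signal is recovered exactly); growth stops
#' when the number of leaves reaches `max_rules` or no split leaves at least
#' `min_leaf_n` total weight on both sides. Leaf models use backward feature elimination:
#' a band is dropped when removing it degrades the leaf's training RMSE by
#' no more than 1%. With `max_rules = 1` the fit is exactly weighted
#' ordinary least squares.
#'
#' @param data Data frame holding the outcome, the feature columns and
#'   optionally a `weight` column (positive; default 1).
#' @param outcome Name of the outcome column (default `"lai"`).
#' @param features Character vector of feature columns; defaults to all
#'   numeric columns other than the outcome, `weight`, `lai_true` and tags.
#' @param max_rules Maximum number of leaves/rules (>= 1). Two rules suit
#'   ground-sample-only vineyard models; larger budgets (e.g. 30) suit mixed
#'   ground + background training sets.
#' @param min_leaf_n Minimum total sample weight per leaf (default 20).
#' @param weights Optional numeric vector overriding the `weight` column.
#' @return An object of class `model_tree` with elements `rules` (list of
#'   `path` + `leaf`), `features`, `outcome`, `n`, `train_rmse`.
#' @export
#' @examples
#' d <- tibble::tibble(nir = runif(100), lai = 2 * runif(100))
#' d$lai <- 1 + 3 * d$nir
#' fit <- model_tree(d, max_rules = 1)
#' predict(fit, d[1:3, ])
model_tree <- function(data, outcome = "lai", features = NULL,
                       max_rules = 2, min_leaf_n = 20, weights = NULL) {
  if (!is.numeric(max_rules) || max_rules < 1) {
    stop("max_rules must be >= 1", call. = FALSE)
  }
  if (!outcome %in% names(data)) {
    stop("outcome column '", outcome, "' not found", call. = FALSE)
  }
  if (is.null(features)) {
    drop_cols <- c(outcome, "weight", "lai_true", "site", "group", "date")
    features <- names(data)[vapply(data, is.numeric, logical(1))]
    features <- setdiff(features, drop_cols)
  }
  if (length(features) < 1L) stop("no feature columns", call. = FALSE)
  y <- data[[outcome]]
  w <- if (!is.null(weights)) weights
       else if ("weight" %in% names(data)) data[["weight"]]
       else rep(1, nrow(data))
  if (any(!is.finite(w)) || any(w <= 0)) {
    stop("weights must be positive and finite", call. = FALSE)
  }
  X <- tibble::as_tibble(data)[, features, drop = FALSE]
  ok <- stats::complete.cases(X) & is.finite(y)
  X <- X[ok, , drop = FALSE]; y <- y[ok]; w <- w[ok]

  # best-first growth; each leaf caches its own best split so only the two
  # children are re-scored after a split
  new_leaf <- function(idx, path) {
    list(idx = idx, path = path,
         split = best_split(X[idx, , drop = FALSE], y[idx], w[idx],
                            features, min_leaf_n))
  }
  leaves <- list(new_leaf(seq_along(y), list()))
  while (length(leaves) < max_rules) {
    scores <- vapply(leaves, function(lf) {
      if (is.null(lf$split)) -Inf else lf$split$score
    }, numeric(1))
    if (all(!is.finite(scores))) break
    i <- which.max(scores)
    lf <- leaves[[i]]
    sp <- lf$split
    left <- X[[sp$feature]][lf$idx] <= sp$threshold
    child_l <- new_leaf(lf$idx[left],
                        c(lf$path, list(list(feature = sp$feature,
                                             threshold = sp$threshold,
                                             side = "<="))))
    child_r <- new_leaf(lf$idx[!left],
                        c(lf$path, list(list(feature = sp$feature,
                                             threshold = sp$threshold,
                                             side = ">"))))
    leaves <- c(leaves[-i], list(child_l, child_r))
  }

  rules <- lapply(leaves, function(lf) {
    leaf <- fit_leaf(X[lf$idx, , drop = FALSE], y[lf$idx], w[lf$idx], features)
    list(path = lf$path, leaf = leaf,
         n = length(lf$idx), weight = sum(w[lf$idx]),
         mean_lai = sum(w[lf$idx] * y[lf$idx]) / sum(w[lf$idx]))
  })
  obj <- structure(list(rules = rules, features = features, outcome = outcome,
                        n = length(y), max_rules = max_rules,
                        min_leaf_n = min_leaf_n),
                   class = "model_tree")
  pred <- predict(obj, X, clamp = FALSE)
  obj$train_rmse <- weighted_rmse(y - pred, w)
  obj
}

#' Predict from a model tree
#'
#' Each new point is matched by exactly one rule (the root-to-leaf paths
#' partition feature space) and its leaf linear model is evaluated. Negative
#' LAI predictions are clamped to zero; the attribute `"clamped"` flags the
#' affected rows.
#'
#' @param object A [model_tree()] fit.
#' @param newdata Data frame containing the fitted feature columns.
#' @param clamp Clamp negative predictions to 0 (default `TRUE`).
#' @param ... Unused.
#' @return Numeric vector of predictions with attribute `clamped` (logical).
#' @export
predict.model_tree <- function(object, newdata, clamp = TRUE, ...) {
  missing_f <- setdiff(object$features, names(newdata))
  if (length(missing_f)) {
    stop("newdata lacks feature column(s): ",
         paste(missing_f, collapse = ", "), call. = FALSE)
  }
  X <- tibble::as_tibble(newdata)[, object$features, drop = FALSE]
  n <- nrow(X)
  pred <- rep(NA_real_, n)
  assigned <- rep(FALSE, n)
  for (rule in object$rules) {
    ok <- !assigned
    for (cond in rule$path) {
      v <- X[[cond$feature]]
      ok <- ok & (if (cond$side == "<=") v <= cond$threshold
                  else v > cond$threshold)
    }
    if (!any(ok)) next
    Xi <- X[ok, rule$leaf$retained, drop = FALSE]
    p <- rule$leaf$intercept
    if (length(rule$leaf$retained)) {
      p <- p + as.vector(as.matrix(Xi) %*% rule$leaf$coefficients)
    }
    pred[ok] <- p
    assigned[ok] <- TRUE
  }
  clamped <- rep(FALSE, n)
  if (clamp) {
    clamped <- !is.na(pred) & pred < 0
    pred[clamped] <- 0
  }
  attr(pred, "clamped") <- clamped
  pred
}

#' @export
format.model_tree <- function(x, digits = 4, ...) {
  lines <- c(sprintf("Model tree: %d rule(s), %d training samples",
                     length(x$rules), x$n))
  for (j in seq_along(x$rules)) {
    rule <- x$rules[[j]]
    cond <- if (length(rule$path) == 0L) "TRUE" else {
      paste(vapply(rule$path, function(cc) {
        sprintf("%s %s %s", cc$feature, cc$side,
                format(cc$threshold, digits = digits))
      }, character(1)), collapse = " & ")
    }
    eq <- format(rule$leaf$intercept, digits = digits)
    if (length(rule$leaf$retained)) {
      terms <- sprintf("%+g*%s", round(rule$leaf$coefficients, digits),
                       rule$leaf$retained)
      eq <- paste(eq, paste(terms, collapse = " "))
    }
    lines <- c(lines,
               sprintf("Rule %d: if %s  (n = %d)", j, cond, rule$n),
               sprintf("  %s = %s", x$outcome, eq))
  }
  paste(lines, collapse = "\n")
}

#' @export
print.model_tree <- function(x, ...) {
  cat(format(x, ...), "\n")
  invisible(x)
}

#' Tidy a model tree into one row per rule term
#'
#' @param x A [model_tree()] fit.
#' @param ... Unused.
#' @return Tibble with columns `rule`, `condition`, `term`, `estimate`, `n`.
#' @method tidy model_tree
#' @export
tidy.model_tree <- function(x, ...) {
  purrr::map_dfr(seq_along(x$rules), function(j) {
    rl <- x$rules[[j]]
    cond <- if (length(rl$path) == 0L) "TRUE" else {
      paste(vapply(rl$path, function(cc) {
        sprintf("%s %s %.4g", cc$feature, cc$side, cc$threshold)
      }, character(1)), collapse = " & ")
    }
    terms <- c("(Intercept)", rl$leaf$retained)
    estimates <- c(rl$leaf$intercept, unname(rl$leaf$coefficients))
    tibble::tibble(rule = j, condition = cond, term = terms,
                   estimate = estimates, n = rl$n)
  })
}

#' Glance at a model tree
#'
#' @param x A [model_tree()] fit.
#' @param ... Unused.
#' @return One-row tibble with `n_rules`, `n`, `train_rmse`, `max_rules`.
#' @method glance model_tree
#' @export
glance.model_tree <- function(x, ...) {
  tibble::tibble(n_rules = length(x$rules), n = x$n,
                 train_rmse = x$train_rmse, max_rules = x$max_rules)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Hybrid area-fraction sample weights
#'
#' When a small set of ground samples is pooled with a large background
#' sample (e.g. coarse-resolution retrievals over all land covers), each
#' group's total weight is set to the fraction of the domain area it
#' represents: with `N = n_ground + n_background`,
#' `w_ground = f N / n_ground` and `w_background = (1 - f) N / n_background`,
#' so the ground group contributes exactly `100 f` percent of total weight.
#'
#' @param n_ground,n_background Sample counts (>= 1).
#' @param area_fraction Ground-covered area fraction `f` in (0, 1).
#' @return Tibble with one row per group: `group`, `n`, `weight`
#'   (per-sample), `weight_share` (group share of total weight).
#' @export
#' @examples
#' hybrid_weights(260, 50000, 0.03)
hybrid_weights <- function(n_ground, n_background, area_fraction) {
  if (n_ground < 1 || n_background < 1) {
    stop("sample counts must be >= 1", call. = FALSE)
  }
  if (!is.finite(area_fraction) || area_fraction <= 0 || area_fraction >= 1) {
    stop("area_fraction must lie strictly between 0 and 1", call. = FALSE)
  }
  N <- n_ground + n_background
  w_g <- area_fraction * N / n_ground
  w_b <- (1 - area_fraction) * N / n_background
  total <- w_g * n_ground + w_b * n_background
  tibble::tibble(
    group = c("ground", "background"),
    n = c(n_ground, n_background),
    weight = c(w_g, w_b),
    weight_share = c(w_g * n_ground, w_b * n_background) / total
  )
}
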