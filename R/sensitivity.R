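## LAI-error propagation experiment.
##
## For each scenario the solver is run once at baseline and once per grid
## percentage with LAI (and every LAI-derived quantity: cover, interception,
## resistances) scaled -- nothing else changes, in particular not the
## radiometric forcing. Changes in daytime ET and transpiration are
## baseline-relative percentages; soil evaporation, which is often near
## zero, uses the symmetric relative change bounded by +/-200%.

#' Baseline-relative percentage change
#'
#' `100 (value - baseline) / baseline`; `NA` when the baseline is at or
#' below `eps`.
#'
#' @param value,baseline Numeric (vectorised).
#' @param eps Degenerate-baseline tolerance (default 1e-9).
#' @return Signed percentage.
#' @export
#' @examples
#' pct_change(110, 100) # +10
pct_change <- function(value, baseline, eps = 1e-9) {
  ifelse(baseline <= eps, NA_real_, 100 * (value - baseline) / baseline)
}

#' Symmetric relative change
#'
#' `100 (value - baseline) / ((value + baseline)/2)`, bounded by +/-200% by
#' construction; defined as 0 when both values are zero. Suited to
#' quantities that approach zero, such as soil evaporation under a dense
#' canopy.
#'
#' @param value,baseline Non-negative numerics (vectorised).
#' @return Signed percentage in \[-200, 200\].
#' @export
#' @examples
#' sym_rel_change(1, 0) # +200
sym_rel_change <- function(value, baseline) {
  m <- (value + baseline) / 2
  ifelse(m == 0, 0, 100 * (value - baseline) / m)
}

#' Default LAI perturbation grid
#'
#' Signed percentages -50, -45, ..., -5, +5, ..., +50 (zero excluded; the
#' baseline is handled separately).
#'
#' @param step Grid step in percent (default 5).
#' @param max_pct Largest absolute percentage (default 50).
#' @return Numeric vector of signed percentages.
#' @export
perturbation_grid <- function(step = 5, max_pct = 50) {
  p <- seq(step, max_pct, by = step)
  c(-rev(p), p)
}

#' Run the LAI perturbation experiment
#'
#' For every scenario of an ensemble (see [build_iop_ensemble()]) the TSEB
#' solver is run at baseline LAI and at each grid percentage, with
#' fractional cover and all other LAI-derived quantities recomputed
#' consistently and all other inputs unchanged. Daytime aggregates give the
#' percentage change of ET and transpiration ([pct_change()]) and the
#' symmetric relative change of soil evaporation ([sym_rel_change()]).
#'
#' @param ensemble Tibble with `scenario` ids and list-columns `canopy`,
#'   `met` (as from [build_iop_ensemble()]).
#' @param grid Signed percentages (default [perturbation_grid()]).
#' @param surf A [surface_params()].
#' @return A `lai_sensitivity` tibble: `scenario`, `baseline_lai`,
#'   `delta_lai_pct`, `et_mm`, `t_mm`, `e_mm`, `d_et_pct`, `d_t_pct`,
#'   `d_e_sym`, `converged`; the baseline daily aggregates are stored in
#'   `attr(x, "baseline")`. Non-converged runs are kept but flagged (and
#'   their count logged); summaries should exclude them.
#' @export
run_lai_sensitivity <- function(ensemble, grid = perturbation_grid(),
                                surf = surface_params()) {
  stopifnot(all(c("scenario", "canopy", "met") %in% names(ensemble)))
  if (any(grid == 0)) stop("grid must not contain 0", call. = FALSE)
  if (any(abs(grid) > 100)) stop("|grid| must be <= 100", call. = FALSE)
  res <- purrr::map(seq_len(nrow(ensemble)), function(i) {
    canopy0 <- ensemble$canopy[[i]]
    met <- ensemble$met[[i]]
    run_one <- function(scale) {
      cs <- canopy_state(canopy0$lai * scale, hc = canopy0$hc,
                         omega = canopy0$omega,
                         leaf_width = canopy0$leaf_width)
      flux <- run_tseb_day(met, cs, surf)
      dplyr::mutate(daytime_et(flux), converged = all(flux$converged))
    }
    base <- run_one(1)
    pert <- purrr::map_dfr(grid, function(p) {
      d <- run_one(1 + p / 100)
      tibble::tibble(
        scenario = ensemble$scenario[i],
        baseline_lai = canopy0$lai,
        delta_lai_pct = p,
        et_mm = d$et_mm, t_mm = d$t_mm, e_mm = d$e_mm,
        d_et_pct = pct_change(d$et_mm, base$et_mm),
        d_t_pct = pct_change(d$t_mm, base$t_mm),
        d_e_sym = sym_rel_change(d$e_mm, base$e_mm),
        converged = d$converged && base$converged
      )
    })
    list(records = pert,
         baseline = dplyr::mutate(base, scenario = ensemble$scenario[i],
                                  baseline_lai = canopy0$lai, .before = 1))
  })
  records <- purrr::map_dfr(res, "records")
  n_bad <- sum(!records$converged)
  if (n_bad > 0L) {
    vf_log("sensitivity", n_bad, " non-converged run(s) flagged")
  }
  structure(records,
            baseline = purrr::map_dfr(res, "baseline"),
            class = c("lai_sensitivity", class(records)))
}

#' Boxplot summary of sensitivity records
#'
#' Median and quartiles (linear interpolation), whiskers to the furthest
#' point within 1.5 IQR of the box, and the count of outliers beyond the
#' whiskers, per LAI perturbation level. Non-converged records are excluded.
#'
#' @param records A `lai_sensitivity` tibble (or any data frame with
#'   `delta_lai_pct` and the value column).
#' @param value Name of the column to summarize (default `"d_et_pct"`).
#' @return Tibble per `delta_lai_pct`: `median`, `q25`, `q75`,
#'   `whisker_low`, `whisker_high`, `n_outliers`, `n`.
#' @export
summarize_box <- function(records, value = "d_et_pct") {
  if ("converged" %in% names(records)) {
    records <- records[records$converged, , drop = FALSE]
  }
  records |>
    dplyr::group_by(.data$delta_lai_pct) |>
    dplyr::group_modify(function(d, key) {
      v <- d[[value]]
      v <- v[is.finite(v)]
      if (length(v) == 0L) {
        vf_log("sensitivity", "empty group skipped at ",
               key$delta_lai_pct, "%")
        return(tibble::tibble())
      }
      q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
      iqr <- q[3] - q[1]
      lo_fence <- q[1] - 1.5 * iqr
      hi_fence <- q[3] + 1.5 * iqr
      inside <- v[v >= lo_fence & v <= hi_fence]
      tibble::tibble(
        median = q[2], q25 = q[1], q75 = q[3],
        whisker_low = min(inside), whisker_high = max(inside),
        n_outliers = sum(v < lo_fence | v > hi_fence),
        n = length(v)
      )
    }) |>
    dplyr::ungroup()
}

#' Plot sensitivity distributions as boxplots
#'
#' One box per LAI perturbation level, whiskers at 1.5 IQR, outliers drawn
#' individually.
#'
#' @param records A `lai_sensitivity` tibble.
#' @param value Column to plot (default `"d_et_pct"`).
#' @return A ggplot object.
#' @export
plot_sensitivity_box <- function(records, value = "d_et_pct") {
  if ("converged" %in% names(records)) {
    records <- records[records$converged, , drop = FALSE]
  }
  lab <- c(d_et_pct = "Change in daytime ET (%)",
           d_t_pct = "Change in transpiration (%)",
           d_e_sym = "Symmetric change in evaporation (%)")
  ggplot2::ggplot(records,
                  ggplot2::aes(x = factor(.data$delta_lai_pct),
                               y = .data[[value]])) +
    ggplot2::geom_boxplot(coef = 1.5, fill = "grey85") +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey40") +
    ggplot2::labs(x = "LAI change (%)",
                  y = lab[value] %||% value) +
    ggplot2::theme_minimal()
}

#' Plot ET, transpiration and evaporation response curves
#'
#' Daytime water-flux components against the LAI perturbation, one panel per
#' scenario, exposing the rise-then-fall shape of ET in dense canopies.
#'
#' @param records A `lai_sensitivity` tibble.
#' @return A ggplot object.
#' @export
plot_lai_response <- function(records) {
  long <- records |>
    tibble::as_tibble() |>
    tidyr::pivot_longer(c("et_mm", "t_mm", "e_mm"),
                        names_to = "component", values_to = "mm") |>
    dplyr::mutate(component = dplyr::recode(.data$component,
                                            et_mm = "ET", t_mm = "T",
                                            e_mm = "E"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$delta_lai_pct, y = .data$mm,
                                     colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~scenario, scales = "free_y") +
    ggplot2::labs(x = "LAI change (%)", y = "Daytime flux (mm)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Autoplot method for sensitivity experiments
#'
#' @param object A `lai_sensitivity` tibble from [run_lai_sensitivity()].
#' @param type `"box"` (distribution per perturbation level) or
#'   `"response"` (per-scenario flux curves).
#' @param value Column for `type = "box"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot lai_sensitivity
#' @export
autoplot.lai_sensitivity <- function(object, type = c("box", "response"),
                                     value = "d_et_pct", ...) {
  type <- match.arg(type)
  if (type == "box") plot_sensitivity_box(object, value)
  else plot_lai_response(object)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
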