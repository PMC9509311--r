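#' Red-edge inflection point (REIP)
#'
#' Four-band linear approximation of the red-edge inflection wavelength,
#' using reflectance at 665, 705, 740 and 783 nm (Sentinel-2 bands 4-7):
#' \deqn{REIP = 705 + 35 \frac{(\rho_{665}+\rho_{783})/2 - \rho_{705}}
#'                           {\rho_{740}-\rho_{705}}}
#' The ratio is clamped to \[-1, 2\] so the returned wavelength stays within
#' a physically interpretable window; when the denominator is degenerate
#' (|rho740 - rho705| below `tol`) the result is `NA`.
#'
#' @param rho665,rho705,rho740,rho783 Reflectances in \[0, 1\] (vectorised).
#' @param tol Degenerate-denominator tolerance (default 1e-6).
#' @return Wavelength in nanometres, or `NA_real_` where undefined.
#' @export
#' @examples
#' reip(0.05, 0.15, 0.30, 0.40) # 722.5
reip <- function(rho665, rho705, rho740, rho783, tol = 1e-6) {
  num <- (rho665 + rho783) / 2 - rho705
  den <- rho740 - rho705
  ratio <- ifelse(abs(den) < tol, NA_real_, num / den)
  ratio <- pmin(pmax(ratio, -1), 2)
  705 + 35 * ratio
}

safe_ratio <- function(num, den) ifelse(den == 0, NA_real_, num / den)

#' Compute vegetation indices from a reflectance table
#'
#' Appends NDVI, EVI, GCI and NDWI columns (plus REIP when all three red-edge
#' bands are present) to a table of semantic-band reflectances:
#' \itemize{
#'   \item NDVI = (NIR - Red)/(NIR + Red)
#'   \item EVI  = 2.5 (NIR - Red)/(1 + NIR + 6 Red - 7.5 Blue)
#'   \item GCI  = NIR/Green - 1
#'   \item NDWI = (SWIR1 - Red)/(SWIR1 + Red)  (`as_printed`, the default) or
#'         (NIR - SWIR1)/(NIR + SWIR1) (`nir_swir`, the conventional
#'         water-index form)
#'   \item REIP from red, red_edge1, red_edge2, red_edge3 via [reip()]
#' }
#' Zero denominators yield `NA` rather than an error, and `NA`s propagate
#' through downstream tables.
#'
#' @param data Data frame with semantic band columns (see [semantic_bands()]).
#' @param ndwi_convention `"as_printed"` or `"nir_swir"`.
#' @return The input tibble with `ndvi`, `evi`, `gci`, `ndwi` and, when
#'   red-edge bands are available, `reip` columns appended.
#' @export
#' @examples
#' compute_vi(tibble::tibble(blue = 0.05, green = 0.08, red = 0.10,
#'                           nir = 0.40, swir1 = 0.20, swir2 = 0.15))
compute_vi <- function(data, ndwi_convention = c("as_printed", "nir_swir")) {
  ndwi_convention <- match.arg(ndwi_convention)
  need <- c("blue", "green", "red", "nir", "swir1")
  missing_b <- setdiff(need, names(data))
  if (length(missing_b)) {
    stop("compute_vi() needs band column(s): ",
         paste(missing_b, collapse = ", "), call. = FALSE)
  }
  out <- tibble::as_tibble(data)
  out$ndvi <- safe_ratio(out$nir - out$red, out$nir + out$red)
  out$evi <- 2.5 * safe_ratio(out$nir - out$red,
                              1 + out$nir + 6 * out$red - 7.5 * out$blue)
  out$gci <- safe_ratio(out$nir, out$green) - 1
  out$ndwi <- if (ndwi_convention == "as_printed") {
    safe_ratio(out$swir1 - out$red, out$swir1 + out$red)
  } else {
    safe_ratio(out$nir - out$swir1, out$nir + out$swir1)
  }
  if (all(red_edge_bands() %in% names(data))) {
    out$reip <- reip(out$red, out$red_edge1, out$red_edge2, out$red_edge3)
  }
  out
}
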