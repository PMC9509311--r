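#' Semantic band names understood by the package
#'
#' Reflectance tables are keyed by sensor-independent semantic names rather
#' than raw band ids. Landsat-8-like tables must carry the six broad bands;
#' Sentinel-2-like tables may additionally carry the three red-edge bands and
#' the wide NIR band.
#'
#' @return Character vector of the ten semantic band names.
#' @export
semantic_bands <- function() {
  c("blue", "green", "red", "red_edge1", "red_edge2", "red_edge3",
    "nir", "nir_wide", "swir1", "swir2")
}

#' Built-in sensor band maps
#'
#' A band map is a named character vector mapping semantic band names to the
#' column names used in a reflectance CSV. Two maps ship with the package:
#' `"landsat8"` (B2--B7) and `"sentinel2"` (B2--B8A, B11, B12; B8A is the
#' narrow NIR matching the Landsat-8 NIR wavelength, B8 the wide NIR).
#'
#' @param sensor `"landsat8"`, `"sentinel2"`, or a named character vector
#'   giving a custom semantic-name -> column mapping.
#' @return Named character vector (names = semantic bands, values = columns).
#' @export
#' @examples
#' band_map("landsat8")
band_map <- function(sensor = "landsat8") {
  if (is.character(sensor) && length(sensor) > 1L) {
    bad <- setdiff(names(sensor), semantic_bands())
    if (length(bad)) {
      stop("unknown semantic band name(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    return(sensor)
  }
  switch(sensor,
    landsat8 = c(blue = "B2", green = "B3", red = "B4", nir = "B5",
                 swir1 = "B6", swir2 = "B7"),
    sentinel2 = c(blue = "B2", green = "B3", red = "B4",
                  red_edge1 = "B5", red_edge2 = "B6", red_edge3 = "B7",
                  nir_wide = "B8", nir = "B8A", swir1 = "B11", swir2 = "B12"),
    stop("unknown sensor '", sensor, "'; use 'landsat8', 'sentinel2' or a ",
         "named character vector", call. = FALSE)
  )
}

landsat_required_bands <- function() {
  c("blue", "green", "red", "nir", "swir1", "swir2")
}

red_edge_bands <- function() c("red_edge1", "red_edge2", "red_edge3")

#' Read a surface-reflectance table
#'
#' Reads a CSV of per-sample surface reflectance, renames sensor band columns
#' to semantic names via a band map, and drops rows whose reflectance is
#' missing or outside \[0, 1\]. Optional `lai`, `site` and `group` columns are
#' carried through so the result can feed the LAI regression directly.
#'
#' @param path Path to a CSV file.
#' @param band_map Band map as returned by [band_map()].
#' @return A tibble with one row per accepted sample, semantic band columns,
#'   any of `site`, `date`, `lai`, `group` present in the file, and attribute
#'   `n_rejected` giving the number of dropped rows.
#' @export
read_reflectance <- function(path, band_map = vineflux::band_map("landsat8")) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(df) == 0L) stop("empty reflectance table: ", path, call. = FALSE)
  missing_cols <- setdiff(unname(band_map), names(df))
  if (length(missing_cols)) {
    stop("band column(s) missing from ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- df
  names(out)[match(unname(band_map), names(out))] <- names(band_map)
  keep_meta <- intersect(c("site", "date", "lai", "group"), names(out))
  out <- out[, c(keep_meta, names(band_map)), drop = FALSE]
  band_cols <- names(band_map)
  ok <- rep(TRUE, nrow(out))
  for (b in band_cols) {
    v <- out[[b]]
    ok <- ok & is.finite(v) & v >= 0 & v <= 1
  }
  n_rejected <- sum(!ok)
  if (n_rejected > 0L) {
    vf_log("read_reflectance", "rejected ", n_rejected,
           " row(s) with missing or out-of-range reflectance")
  }
  out <- tibble::as_tibble(out[ok, , drop = FALSE])
  attr(out, "n_rejected") <- n_rejected
  out
}

# lightweight structured logging; suppress with options(vineflux.quiet = TRUE)
vf_log <- function(module, ...) {
  if (isTRUE(getOption("vineflux.quiet", FALSE))) return(invisible(NULL))
  message(sprintf("[vineflux:%s] %s", module, paste0(...)))
}
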