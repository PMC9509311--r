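## Synthetic vineyard scenes and forcing.
##
## The generator emulates the statistical structure the analysis assumes:
## three vineyard archetypes whose clumping differences make the same NDVI
## correspond to very different LAI; noisy ground LAI observations; a large
## coarse-resolution "background" sample with saturation bias; and clear-sky
## diurnal forcing for an ensemble of intensive-observation-period (IOP)
## scenarios with prescribed baseline LAI.

band_extinction <- function() {
  c(blue = 0.85, green = 0.85, red = 0.9,
    red_edge1 = 0.85, red_edge2 = 0.65, red_edge3 = 0.55,
    nir = 0.5, nir_wide = 0.5, swir1 = 0.7, swir2 = 0.7)
}

# per-site endmember spectra: each archetype has a distinctive spectral
# signature (dark coastal, intermediate, bright hot-interior), so band
# vectors identify the site and, within a site, the LAI. Soil-red values are
# the once-solved NDVI-window anchor calibration.
leaf_soil_spectra <- function(which = c("dark", "mid", "bright")) {
  which <- match.arg(which)
  switch(which,
    dark = list(
      leaf = c(blue = 0.03, green = 0.08, red = 0.03,
               red_edge1 = 0.06, red_edge2 = 0.30, red_edge3 = 0.45,
               nir = 0.50, nir_wide = 0.50, swir1 = 0.18, swir2 = 0.10),
      soil = c(blue = 0.10, green = 0.13, red = 0.16,
               red_edge1 = 0.17, red_edge2 = 0.19, red_edge3 = 0.20,
               nir = 0.22, nir_wide = 0.22, swir1 = 0.30, swir2 = 0.25)
    ),
    mid = list(
      leaf = c(blue = 0.035, green = 0.09, red = 0.04,
               red_edge1 = 0.07, red_edge2 = 0.315, red_edge3 = 0.465,
               nir = 0.525, nir_wide = 0.525, swir1 = 0.20, swir2 = 0.115),
      soil = c(blue = 0.115, green = 0.15, red = 0.164,
               red_edge1 = 0.215, red_edge2 = 0.235, red_edge3 = 0.245,
               nir = 0.26, nir_wide = 0.26, swir1 = 0.33, swir2 = 0.28)
    ),
    bright = list(
      leaf = c(blue = 0.04, green = 0.10, red = 0.05,
               red_edge1 = 0.08, red_edge2 = 0.33, red_edge3 = 0.48,
               nir = 0.55, nir_wide = 0.55, swir1 = 0.22, swir2 = 0.13),
      soil = c(blue = 0.13, green = 0.17, red = 0.248,
               red_edge1 = 0.26, red_edge2 = 0.28, red_edge3 = 0.29,
               nir = 0.30, nir_wide = 0.30, swir1 = 0.36, swir2 = 0.31)
    )
  )
}

#' Vineyard site archetypes
#'
#' Three synthetic site archetypes with contrasting canopy clumping:
#' `BAR-like` (split canopy, weak clumping, omega 0.85), `SLM-like`
#' (quadrilateral trellis, omega 0.65) and `RIP-like` (double-vertical
#' trellis, strong clumping, omega 0.45). Stronger clumping hides more leaf
#' area per unit cover, so the same NDVI maps to a much higher LAI in
#' RIP-like canopies. Endmember spectra and omegas are tuning constants
#' calibrated once so that the median LAI of samples with NDVI in
#' \[0.60, 0.65\] is near 1.3, 1.7 and 3.4 for the three archetypes.
#'
#' @return Tibble with `site`, `omega`, `lai_min`, `lai_max`, `noise_sd`,
#'   `hc` (canopy height, m) and list-columns `leaf`, `soil` (endmember
#'   reflectance per semantic band).
#' @export
site_archetypes <- function() {
  dark <- leaf_soil_spectra("dark")
  mid <- leaf_soil_spectra("mid")
  hot <- leaf_soil_spectra("bright")
  tibble::tibble(
    site = c("BAR-like", "SLM-like", "RIP-like"),
    omega = c(0.85, 0.65, 0.45),
    lai_min = c(0.8, 0.7, 0.7),
    lai_max = c(2.4, 4.0, 4.0),
    noise_sd = 0.01,
    hc = c(2.2, 2.3, 2.1),
    leaf = list(dark$leaf, mid$leaf, hot$leaf),
    soil = list(dark$soil, mid$soil, hot$soil)
  )
}

#' Simulate one surface-reflectance sample
#'
#' Linear endmember mixing per band: `rho_b = f_b leaf_b + (1 - f_b) soil_b`
#' with `f_b = 1 - exp(-k_b omega lai)` and band-specific extinction `k_b`
#' (red-edge intermediate between red and NIR, so the red-edge inflection
#' shifts with LAI). Gaussian noise is added and the result truncated to
#' \[0, 1\].
#'
#' @param archetype One row of [site_archetypes()].
#' @param lai LAI value within the archetype's range.
#' @param seed Optional integer seed.
#' @param noise_sd Reflectance noise standard deviation; defaults to the
#'   archetype value.
#' @return One-row tibble of semantic band reflectances.
#' @export
simulate_reflectance <- function(archetype, lai, seed = NULL,
                                 noise_sd = NULL) {
  if (lai < archetype$lai_min || lai > archetype$lai_max) {
    stop("lai outside archetype range", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  sd <- noise_sd %||% archetype$noise_sd
  k <- band_extinction()
  leaf <- archetype$leaf[[1]][names(k)]
  soil <- archetype$soil[[1]][names(k)]
  f <- 1 - exp(-k * archetype$omega * lai)
  rho <- f * leaf + (1 - f) * soil + stats::rnorm(length(k), 0, sd)
  rho <- pmin(pmax(rho, 0), 1)
  tibble::as_tibble(as.list(rho))
}

#' Simulate a multi-site LAI--reflectance training set
#'
#' Draws LAI uniformly within each archetype's measured range, simulates the
#' corresponding reflectance, and tags each sample with its site. At default
#' settings the NDVI-window calibration holds: the median true LAI of
#' samples with NDVI between 0.60 and 0.65 is ordered
#' BAR-like < SLM-like < RIP-like, near 1.3 / 1.7 / 3.4.
#'
#' @param archetypes Tibble as from [site_archetypes()].
#' @param n_per_site Samples per site (>= 30).
#' @param seed Integer seed.
#' @param noise_sd Optional reflectance noise override.
#' @return Tibble of labelled samples: band columns, `lai`, `site`, `group`,
#'   `weight` (1).
#' @export
simulate_lai_dataset <- function(archetypes = site_archetypes(),
                                 n_per_site = 200, seed = 1,
                                 noise_sd = NULL) {
  if (nrow(archetypes) == 0L) stop("no archetypes given", call. = FALSE)
  if (n_per_site < 30) stop("n_per_site must be >= 30", call. = FALSE)
  set.seed(seed)
  purrr::map_dfr(seq_len(nrow(archetypes)), function(i) {
    arch <- archetypes[i, ]
    lai <- stats::runif(n_per_site, arch$lai_min, arch$lai_max)
    bands <- purrr::map_dfr(lai, function(l) {
      simulate_reflectance(arch, l, seed = NULL, noise_sd = noise_sd)
    })
    dplyr::mutate(bands, lai = lai, site = arch$site, group = arch$site,
                  weight = 1)
  })
}

#' Simulate background LAI samples with retrieval saturation
#'
#' Emulates a large coarse-resolution training pool covering mixed land
#' covers: true LAI is uniform on \[0, `lai_max`\], the reported label
#' saturates at `l_sat` (`reported = min(true, l_sat) + noise`), and spectra
#' come from a broadened endmember pool (random clumping and endmember
#' jitter).
#'
#' @param n Number of samples.
#' @param seed Integer seed.
#' @param l_sat Saturation level in LAI units (default 4).
#' @param lai_max Upper bound of true LAI (default 6).
#' @param label_noise_sd Noise on the reported label (default 0.3; 0 gives
#'   the pure clamp).
#' @return Tibble with band columns, `lai` (reported label), `lai_true`,
#'   `site = "background"`, `group`, `weight` (1).
#' @export
simulate_background_samples <- function(n, seed = 1, l_sat = 4, lai_max = 6,
                                        label_noise_sd = 0.3) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  set.seed(seed)
  k <- band_extinction()
  std <- leaf_soil_spectra("dark")
  hot <- leaf_soil_spectra("bright")
  lai_true <- stats::runif(n, 0, lai_max)
  omega <- stats::runif(n, 0.5, 1)
  mixw <- stats::runif(n)
  bands <- purrr::map_dfr(seq_len(n), function(i) {
    leaf <- mixw[i] * std$leaf + (1 - mixw[i]) * hot$leaf
    soil <- mixw[i] * std$soil + (1 - mixw[i]) * hot$soil
    f <- 1 - exp(-k * omega[i] * lai_true[i])
    rho <- f * leaf[names(k)] + (1 - f) * soil[names(k)] +
      stats::rnorm(length(k), 0, 0.02)
    tibble::as_tibble(as.list(pmin(pmax(rho, 0), 1)))
  })
  reported <- pmin(lai_true, l_sat) +
    stats::rnorm(n, 0, label_noise_sd)
  dplyr::mutate(bands, lai = pmax(reported, 0), lai_true = lai_true,
                site = "background", group = "background", weight = 1)
}

#' Climate presets for the three site archetypes
#'
#' Stand-in clear-sky climates (no tower data are embedded): a mild coastal
#' site (BAR-like), a moderate one (SLM-like) and a hot interior one
#' (RIP-like).
#'
#' @return Tibble keyed by `site` with `peak_sw` (W/m2), `t_mean` (K),
#'   `t_amp` (K), `e_air` (kPa), `u_mean` (m/s), `pressure` (kPa).
#' @export
climate_presets <- function() {
  tibble::tibble(
    site = c("BAR-like", "SLM-like", "RIP-like"),
    peak_sw = c(850, 900, 950),
    t_mean = c(291, 295, 299),
    t_amp = c(6, 8, 9),
    e_air = c(1.2, 1.4, 1.6),
    u_mean = c(3.0, 2.5, 2.2),
    pressure = c(101.0, 101.3, 101.3)
  )
}

#' Simulate one clear-sky day of hourly forcing
#'
#' Shortwave follows a half-sine between 06:00 and 18:00; air temperature a
#' sinusoid lagging solar noon; incoming longwave a Brutsaert clear-sky
#' emissivity of air temperature and vapor pressure. Radiometric surface
#' temperature is built as
#' `t_rad = t_air + (a0 + a1 s) (sw_in/peak) (1 - 0.5 fc) + noise`, so
#' radiometric heating scales with bare-soil exposure and the stress knob
#' `s`; `fc` uses the *baseline* LAI, making the forcing independent of any
#' later LAI perturbation. Upwelling longwave is emitted consistently so
#' [lst_from_longwave()] round-trips.
#'
#' @param peak_sw Peak shortwave irradiance (W/m2, > 0).
#' @param t_mean,t_amp Mean and diurnal amplitude of air temperature (K).
#' @param e_air Vapor pressure (kPa).
#' @param u_mean Wind speed (m/s).
#' @param pressure Air pressure (kPa).
#' @param lai,omega Baseline canopy state shaping `t_rad`.
#' @param s Stress knob in \[0, 1\] (default 0.3).
#' @param a0,a1 Radiometric heating constants (K; defaults 2 and 8).
#' @param t_rad_noise_sd Gaussian noise on `t_rad` (K, default 0.3).
#' @param seed Integer seed.
#' @return 24-row tibble: `time`, `sw_in`, `lw_in`, `lw_up`, `t_air`,
#'   `e_air`, `u`, `pressure`, `sun_zenith`, `t_rad`.
#' @export
simulate_met_day <- function(peak_sw, t_mean, t_amp, e_air, u_mean,
                             pressure, lai, omega, s = 0.3,
                             a0 = 2, a1 = 8, t_rad_noise_sd = 0.3,
                             seed = 1) {
  if (peak_sw <= 0) stop("peak_sw must be > 0", call. = FALSE)
  set.seed(seed)
  h <- 0:23
  day <- h > 6 & h < 18
  solar <- ifelse(day, sin(pi * (h - 6) / 12), 0)
  sw_in <- peak_sw * solar
  sun_zenith <- acos(pmax(solar, 0.05))
  t_air <- t_mean + t_amp * sin(pi * (h - 8) / 12)
  eps_a <- 1.24 * (10 * e_air / t_air)^(1 / 7)
  lw_in <- eps_a * SIGMA_SB * t_air^4
  fc <- fractional_cover(lai, omega)
  t_rad <- t_air + (a0 + a1 * s) * (sw_in / peak_sw) * (1 - 0.5 * fc) +
    stats::rnorm(24, 0, t_rad_noise_sd)
  eps <- composite_emissivity(fc)
  lw_up <- eps * SIGMA_SB * t_rad^4 + (1 - eps) * lw_in
  tibble::tibble(time = h, sw_in = sw_in, lw_in = lw_in, lw_up = lw_up,
                 t_air = t_air, e_air = e_air, u = u_mean,
                 pressure = pressure, sun_zenith = sun_zenith, t_rad = t_rad)
}

#' Table of IOP scenarios for the sensitivity ensemble
#'
#' The 14 intensive-observation-period scenarios (vineyard, year, IOP,
#' phenological stage) with their measured baseline LAI, spanning bloom
#' (LAI ~ 0.5) through bunch closure in a strongly clumped canopy
#' (LAI ~ 3.9).
#'
#' @return 14-row tibble: `vineyard`, `year`, `iop`, `date`, `stage`,
#'   `lai`, `site` (archetype).
#' @export
iop_table <- function() {
  tibble::tribble(
    ~vineyard, ~year, ~iop, ~date, ~stage, ~lai,
    "BAR012", 2017, "IOP3", "08/07", "Veraison", 1.28,
    "BAR012", 2019, "IOP2", "06/25", "Pea size", 1.91,
    "BAR012", 2019, "IOP3", "07/28", "Veraison", 1.72,
    "SLM001", 2015, "IOP1", "4/23", "Bloom", 0.51,
    "SLM001", 2015, "IOP2", "6/1", "Pea size", 2.50,
    "SLM001", 2015, "IOP3", "7/9", "Veraison", 2.43,
    "SLM001", 2015, "IOP4", "8/15", "Pre Harvest", 2.34,
    "SLM002", 2015, "IOP1", "4/22", "Bloom", 1.04,
    "SLM002", 2015, "IOP2", "5/31", "Pea size", 2.29,
    "SLM002", 2015, "IOP3", "7/8", "Veraison", 1.77,
    "SLM002", 2015, "IOP4", "8/11", "Pre Harvest", 2.56,
    "RIP760", 2018, "IOP1", "6/18", "Bunch Closure", 3.86,
    "RIP760", 2018, "IOP2", "7/11", "Veraison", 3.78,
    "RIP760", 2018, "IOP3", "8/5", "Pre Harvest", 3.82
  ) |>
    dplyr::mutate(site = dplyr::case_when(
      startsWith(.data$vineyard, "BAR") ~ "BAR-like",
      startsWith(.data$vineyard, "SLM") ~ "SLM-like",
      TRUE ~ "RIP-like"
    ))
}

#' Build the 14-scenario IOP ensemble
#'
#' One scenario per [iop_table()] row: the printed measured LAI as baseline,
#' site-appropriate clumping and climate preset, and a deterministic
#' per-scenario sub-seed for the forcing noise.
#'
#' @param seed Integer ensemble seed (default 7).
#' @param s Stress knob passed to [simulate_met_day()] (default 0.3).
#' @param ... Further arguments to [simulate_met_day()] (e.g. `a0`, `a1`).
#' @return Tibble with one row per scenario: ids, `lai`, `omega`, `hc`, and
#'   list-columns `canopy` ([canopy_state()]) and `met` (hourly forcing).
#' @export
build_iop_ensemble <- function(seed = 7, s = 0.3, ...) {
  iops <- iop_table()
  arch <- site_archetypes()
  clim <- climate_presets()
  purrr::map_dfr(seq_len(nrow(iops)), function(i) {
    row <- iops[i, ]
    a <- arch[arch$site == row$site, ]
    cl <- clim[clim$site == row$site, ]
    canopy <- canopy_state(row$lai, hc = a$hc, omega = a$omega)
    met <- simulate_met_day(cl$peak_sw, cl$t_mean, cl$t_amp, cl$e_air,
                            cl$u_mean, cl$pressure,
                            lai = row$lai, omega = a$omega, s = s,
                            seed = seed + 1000L * i, ...)
    tibble::tibble(
      scenario = paste(row$vineyard, row$year, row$iop, sep = "_"),
      vineyard = row$vineyard, year = row$year, iop = row$iop,
      stage = row$stage, site = row$site,
      lai = row$lai, omega = a$omega, hc = a$hc,
      canopy = list(canopy), met = list(met)
    )
  })
}
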