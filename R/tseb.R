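## Priestley-Taylor two-source energy balance (TSEB-PT), series network.
##
## The solver takes radiometric surface temperature, meteorology and canopy
## state, and partitions available energy into canopy and soil sensible and
## latent heat. Canopy transpiration starts at the Priestley-Taylor
## potential rate applied to canopy net radiation; if the implied soil
## evaporation (the energy-balance residual) is negative, the PT coefficient
## is reduced stepwise until soil evaporation is non-negative -- the model's
## representation of canopy stress.

SIGMA_SB <- 5.670374419e-8  # W m-2 K-4
VON_KARMAN <- 0.41
CP_AIR <- 1005              # J kg-1 K-1
LAMBDA_V <- 2.45e6          # J kg-1, latent heat of vaporization (fixed)
GRAV <- 9.81

air_density <- function(pressure_kpa, t_air) {
  1000 * pressure_kpa / (287.04 * t_air)
}

esat_kpa <- function(t_k) {
  tc <- t_k - 273.15
  0.6108 * exp(17.27 * tc / (tc + 237.3))
}

esat_slope_kpa <- function(t_k) {
  tc <- t_k - 273.15
  4098 * esat_kpa(t_k) / (tc + 237.3)^2
}

psychrometric_kpa <- function(pressure_kpa) {
  CP_AIR * pressure_kpa / (0.622 * LAMBDA_V)
}

#' Default TSEB surface parameters
#'
#' @param eps_canopy,eps_soil Component emissivities (canopy 0.99,
#'   soil/cover crop 0.94).
#' @param alpha_pt Initial Priestley-Taylor coefficient (1.26).
#' @param fg Green (transpiring) fraction of the canopy in \[0, 1\].
#' @param g_ratio Soil heat flux as a fraction of soil net radiation (0.35,
#'   a standard daytime value).
#' @param albedo_canopy,albedo_soil Component shortwave albedos (0.20 for a
#'   green vine canopy; 0.25 for the dry bare interrow soil of an irrigated
#'   vineyard in midsummer).
#' @param z_u,z_t Wind and temperature measurement heights (m).
#' @param k_shortwave Nadir shortwave extinction coefficient (scaled by
#'   1/cos(solar zenith) at run time).
#' @param k_longwave Longwave extinction coefficient.
#' @return Named list of surface parameters.
#' @export
surface_params <- function(eps_canopy = 0.99, eps_soil = 0.94,
                           alpha_pt = 1.26, fg = 1, g_ratio = 0.35,
                           albedo_canopy = 0.20, albedo_soil = 0.25,
                           z_u = 5, z_t = 5,
                           k_shortwave = 0.6, k_longwave = 0.95) {
  stopifnot(fg >= 0, fg <= 1, alpha_pt > 0, g_ratio >= 0, g_ratio < 1)
  list(eps_canopy = eps_canopy, eps_soil = eps_soil, alpha_pt = alpha_pt,
       fg = fg, g_ratio = g_ratio, albedo_canopy = albedo_canopy,
       albedo_soil = albedo_soil, z_u = z_u, z_t = z_t,
       k_shortwave = k_shortwave, k_longwave = k_longwave)
}

#' Canopy state for the energy-balance solver
#'
#' @param lai Leaf area index (single-sided, m2/m2, >= 0).
#' @param hc Canopy height (m).
#' @param omega Clumping index in (0, 1\]; < 1 for row/trellis canopies.
#' @param leaf_width Characteristic leaf width (m).
#' @return Named list with `lai`, `hc`, `omega`, `leaf_width`, `fc_nadir`.
#' @export
canopy_state <- function(lai, hc = 2.2, omega = 1, leaf_width = 0.1) {
  stopifnot(lai >= 0, omega > 0, omega <= 1, hc > 0, leaf_width > 0)
  list(lai = lai, hc = hc, omega = omega, leaf_width = leaf_width,
       fc_nadir = fractional_cover(lai, omega))
}

#' Fractional vegetation cover from a gap-fraction law
#'
#' `fc = 1 - exp(-0.5 omega lai / cos(theta))` with view zenith `theta`
#' (0 = nadir).
#'
#' @param lai Leaf area index (>= 0).
#' @param omega Clumping index in (0, 1\].
#' @param view_zenith View zenith angle in radians (< pi/2).
#' @return Cover fraction in \[0, 1\].
#' @export
#' @examples
#' fractional_cover(2) # 1 - exp(-1)
fractional_cover <- function(lai, omega = 1, view_zenith = 0) {
  if (any(view_zenith >= pi / 2)) {
    stop("view zenith must be below 90 degrees", call. = FALSE)
  }
  if (any(lai < 0)) stop("lai must be >= 0", call. = FALSE)
  1 - exp(-0.5 * omega * lai / cos(view_zenith))
}

#' Cover-weighted composite surface emissivity
#'
#' Linear mix of canopy (0.99) and soil/cover-crop (0.94) emissivities by
#' fractional vegetation cover.
#'
#' @param fc Fractional cover in \[0, 1\].
#' @param eps_canopy,eps_soil Component emissivities.
#' @return Composite emissivity.
#' @export
composite_emissivity <- function(fc, eps_canopy = 0.99, eps_soil = 0.94) {
  if (any(fc < 0 | fc > 1)) stop("fc must lie in [0, 1]", call. = FALSE)
  eps_canopy * fc + eps_soil * (1 - fc)
}

#' Radiometric surface temperature from longwave radiation
#'
#' Inverts the surface longwave budget
#' `lw_up = eps sigma T^4 + (1 - eps) lw_in` for the hemispherical
#' radiometric temperature, with the composite emissivity weighted by
#' fractional cover.
#'
#' @param lw_up,lw_in Upwelling and incoming longwave radiation (W/m2).
#' @param fc Fractional vegetation cover in \[0, 1\].
#' @param eps_canopy,eps_soil Component emissivities.
#' @return Radiometric temperature (K).
#' @export
lst_from_longwave <- function(lw_up, lw_in, fc,
                              eps_canopy = 0.99, eps_soil = 0.94) {
  eps <- composite_emissivity(fc, eps_canopy, eps_soil)
  emitted <- lw_up - (1 - eps) * lw_in
  if (any(emitted <= 0)) {
    stop("non-physical longwave: lw_up must exceed (1 - eps) * lw_in",
         call. = FALSE)
  }
  (emitted / (eps * SIGMA_SB))^0.25
}

#' Partition net radiation between canopy and soil
#'
#' Shortwave is split by Beer's-law interception
#' `1 - exp(-K_s omega lai / cos(theta_s))` with component albedos; longwave
#' uses a single-layer exchange with canopy transmittance
#' `exp(-K_L omega lai)`, sky irradiance, and component emission
#' `eps sigma T^4` (reflected longwave neglected). Canopy and soil net
#' radiation sum to total net radiation by construction.
#'
#' @param sw_in,lw_in Incoming short- and longwave radiation (W/m2).
#' @param t_c,t_s Canopy and soil temperatures (K).
#' @param canopy A [canopy_state()].
#' @param surf A [surface_params()].
#' @param sun_zenith Solar zenith angle (radians).
#' @return List with `rn_c`, `rn_s`, `rn`.
#' @export
partition_net_radiation <- function(sw_in, lw_in, t_c, t_s, canopy,
                                    surf = surface_params(),
                                    sun_zenith = 0) {
  mu <- max(cos(sun_zenith), 0.1)
  lai_eff <- canopy$omega * canopy$lai
  f_sw <- 1 - exp(-surf$k_shortwave / mu * lai_eff)
  sn_c <- sw_in * f_sw * (1 - surf$albedo_canopy)
  sn_s <- sw_in * (1 - f_sw) * (1 - surf$albedo_soil)
  tau_l <- exp(-surf$k_longwave * lai_eff)
  em_c <- surf$eps_canopy * SIGMA_SB * t_c^4
  em_s <- surf$eps_soil * SIGMA_SB * t_s^4
  ln_c <- (1 - tau_l) * (lw_in + em_s - 2 * em_c)
  ln_s <- tau_l * lw_in + (1 - tau_l) * em_c - em_s
  rn_c <- sn_c + ln_c
  rn_s <- sn_s + ln_s
  list(rn_c = rn_c, rn_s = rn_s, rn = rn_c + rn_s)
}

# Dyer-Businger diabatic corrections; zeta = z/L capped at |2|
psi_m <- function(zeta) {
  zeta <- pmin(pmax(zeta, -2), 2)
  ifelse(zeta < 0,
         {
           x <- (1 - 16 * pmin(zeta, 0))^0.25
           2 * log((1 + x) / 2) + log((1 + x^2) / 2) - 2 * atan(x) + pi / 2
         },
         -5 * zeta)
}

psi_h <- function(zeta) {
  zeta <- pmin(pmax(zeta, -2), 2)
  ifelse(zeta < 0,
         {
           x <- (1 - 16 * pmin(zeta, 0))^0.25
           2 * log((1 + x^2) / 2)
         },
         -5 * zeta)
}

#' Aerodynamic resistance network (series TSEB)
#'
#' Above-canopy resistance `r_a` from the Monin-Obukhov log profile with
#' `z0m = 0.125 hc`, `d = 0.65 hc`; bulk leaf boundary-layer resistance
#' `r_x = (C'/LAI) sqrt(leaf_width / u_dz)` with `C' = 90` and `u_dz` the
#' wind speed at `d + z0m` from an exponential in-canopy profile; soil
#' surface resistance `r_s = 1/(a + b u_s)` with `a = 0.004`, `b = 0.012`
#' and `u_s` the wind speed just above the soil.
#'
#' @param u Wind speed at `z_u` (m/s, floored at 0.1).
#' @param canopy A [canopy_state()].
#' @param surf A [surface_params()] (uses `z_u`, `z_t`).
#' @param mo_length Monin-Obukhov length (m); `Inf` for neutral.
#' @return List with `r_a`, `r_x`, `r_s` (s/m, all > 0) and `ustar`.
#' @export
aerodynamic_resistances <- function(u, canopy, surf = surface_params(),
                                    mo_length = Inf) {
  if (surf$z_u <= canopy$hc) {
    stop("measurement height z_u must exceed canopy height", call. = FALSE)
  }
  u <- max(u, 0.1)
  hc <- canopy$hc
  d <- 0.65 * hc
  z0m <- 0.125 * hc
  zeta_u <- if (is.finite(mo_length)) (surf$z_u - d) / mo_length else 0
  zeta_t <- if (is.finite(mo_length)) (surf$z_t - d) / mo_length else 0
  log_u <- log((surf$z_u - d) / z0m)
  log_t <- log((surf$z_t - d) / z0m)
  den_u <- max(log_u - psi_m(zeta_u), 0.1)
  den_t <- max(log_t - psi_h(zeta_t), 0.1)
  ustar <- VON_KARMAN * u / den_u
  r_a <- den_u * den_t / (VON_KARMAN^2 * u)
  # in-canopy exponential wind profile (Goudriaan-type decay)
  lai_eff <- max(canopy$omega * canopy$lai, 1e-3)
  u_hc <- ustar / VON_KARMAN * log((hc - d) / z0m)
  u_hc <- max(u_hc, 0.01)
  a_dec <- 0.28 * lai_eff^(2 / 3) * hc^(1 / 3) * canopy$leaf_width^(-1 / 3)
  u_dz <- max(u_hc * exp(-a_dec * (1 - (d + z0m) / hc)), 0.01)
  z_soil <- min(0.05, hc / 2)
  u_s <- max(u_hc * exp(-a_dec * (1 - z_soil / hc)), 0.005)
  r_x <- min(90 / max(canopy$lai, 0.05) * sqrt(canopy$leaf_width / u_dz),
             5000)
  r_s <- 1 / (0.004 + 0.012 * u_s)
  list(r_a = r_a, r_x = r_x, r_s = r_s, ustar = ustar)
}

#' Solve the two-source energy balance for one timestep
#'
#' Iterates the Priestley-Taylor TSEB: canopy latent heat starts at
#' `alpha_pt fg Delta/(Delta + gamma) rn_c`; canopy temperature follows from
#' canopy sensible heat through the series resistance network; soil
#' temperature from the radiometric decomposition
#' `t_rad^4 = f t_c^4 + (1 - f) t_s^4` (nadir cover `f`); soil latent heat
#' is the residual `rn_s - g - h_s`. If soil evaporation is negative the PT
#' coefficient is reduced by 0.05 and the solution recomputed; at
#' `alpha_pt = 0` soil evaporation is forced to zero and soil sensible heat
#' closes the budget. Monin-Obukhov stability corrections are iterated with
#' the fluxes.
#'
#' @param t_rad Radiometric surface temperature (K).
#' @param met One-row data frame or list with `sw_in`, `lw_in`, `t_air`,
#'   `e_air`, `u`, `pressure`, optionally `sun_zenith` (radians).
#' @param canopy A [canopy_state()].
#' @param surf A [surface_params()].
#' @param max_iter Total iteration budget (default 200).
#' @return One-row tibble: `rn`, `rn_c`, `rn_s`, `g`, `h_c`, `h_s`, `le_c`,
#'   `le_s`, `t_c`, `t_s`, `f_theta`, `alpha_pt`, `n_iter`, `converged`.
#'   Energy closes exactly: `(rn - g) - (h_c + h_s + le_c + le_s) = 0`.
#' @export
solve_tseb_pt <- function(t_rad, met, canopy, surf = surface_params(),
                          max_iter = 200) {
  met <- as.list(met)
  t_air <- met$t_air
  sun_zenith <- met$sun_zenith %||% 0
  stopifnot(t_air > 250, t_air < 330)
  delta <- esat_slope_kpa(t_air)
  gamma <- psychrometric_kpa(met$pressure)
  rho_cp <- air_density(met$pressure, t_air) * CP_AIR
  pt_frac <- delta / (delta + gamma)
  f_theta <- min(fractional_cover(canopy$lai, canopy$omega, 0), 0.995)

  alpha <- surf$alpha_pt
  t_c <- t_air
  t_s <- t_rad
  h_s <- 0
  mo_length <- Inf
  n_iter <- 0L
  converged <- FALSE
  state <- NULL

  repeat {
    inner_ok <- FALSE
    for (it in seq_len(50)) {
      n_iter <- n_iter + 1L
      res <- aerodynamic_resistances(met$u, canopy, surf, mo_length)
      rad <- partition_net_radiation(met$sw_in, met$lw_in, t_c, t_s,
                                     canopy, surf, sun_zenith)
      le_c <- max(alpha * surf$fg * pt_frac * rad$rn_c, 0)
      h_c <- rad$rn_c - le_c
      t_ac <- t_air + (h_c + h_s) * res$r_a / rho_cp
      t_c_new <- t_ac + h_c * res$r_x / rho_cp
      ts4 <- (t_rad^4 - f_theta * t_c_new^4) / (1 - f_theta)
      if (ts4 > 0) {
        t_s_new <- ts4^0.25
      } else {
        # canopy implied hotter than the composite allows: pin the soil cool
        # and take the canopy temperature from the decomposition instead
        t_s_new <- max(t_air - 20, 253)
        t_c_new <- ((t_rad^4 - (1 - f_theta) * t_s_new^4) /
                      max(f_theta, 1e-6))^0.25
      }
      h_s <- rho_cp * (t_s_new - t_ac) / res$r_s
      h_tot <- h_c + h_s
      # L = -ustar^3 * t_air * rho_cp / (k g H)
      mo_length <- if (abs(h_tot) > 1e-3) {
        -res$ustar^3 * t_air * rho_cp / (VON_KARMAN * GRAV * h_tot)
      } else Inf
      dT <- max(abs(t_c_new - t_c), abs(t_s_new - t_s))
      t_c <- t_c_new
      t_s <- t_s_new
      if (dT < 0.01) { inner_ok <- TRUE; break }
      if (n_iter >= max_iter) break
    }
    res <- aerodynamic_resistances(met$u, canopy, surf, mo_length)
    rad <- partition_net_radiation(met$sw_in, met$lw_in, t_c, t_s,
                                   canopy, surf, sun_zenith)
    le_c <- max(alpha * surf$fg * pt_frac * rad$rn_c, 0)
    h_c <- rad$rn_c - le_c
    t_ac <- t_air + (h_c + h_s) * res$r_a / rho_cp
    h_s <- rho_cp * (t_s - t_ac) / res$r_s
    g <- surf$g_ratio * rad$rn_s
    le_s <- rad$rn_s - g - h_s
    state <- list(rad = rad, g = g, h_c = h_c, h_s = h_s,
                  le_c = le_c, le_s = le_s)
    if (le_s >= 0) { converged <- inner_ok; break }
    if (alpha <= 0 || n_iter >= max_iter) {
      converged <- inner_ok && n_iter < max_iter
      break
    }
    alpha <- max(alpha - 0.05, 0)
  }

  if (state$le_s < 0) {
    # stressed limit: no soil evaporation; sensible heat closes the budget
    state$le_s <- 0
    state$h_s <- state$rad$rn_s - state$g
  }
  tibble::tibble(
    rn = state$rad$rn, rn_c = state$rad$rn_c, rn_s = state$rad$rn_s,
    g = state$g, h_c = state$h_c, h_s = state$h_s,
    le_c = state$le_c, le_s = state$le_s,
    t_c = t_c, t_s = t_s, f_theta = f_theta,
    alpha_pt = alpha, n_iter = n_iter,
    converged = converged
  )
}

#' Run the TSEB solver over a day of hourly forcing
#'
#' Applies [solve_tseb_pt()] to every daytime row (`sw_in` above
#' `sw_threshold`) of an hourly forcing table that includes a `t_rad`
#' column.
#'
#' @param met Forcing tibble with columns `time`, `sw_in`, `lw_in`, `t_air`,
#'   `e_air`, `u`, `pressure`, `t_rad`, optionally `sun_zenith`.
#' @param canopy A [canopy_state()].
#' @param surf A [surface_params()].
#' @param sw_threshold Daytime shortwave threshold (W/m2, default 25).
#' @return Tibble of flux states, one row per daytime hour, with `time`.
#' @export
run_tseb_day <- function(met, canopy, surf = surface_params(),
                         sw_threshold = 25) {
  day <- dplyr::filter(met, .data$sw_in > sw_threshold)
  if (nrow(day) == 0L) stop("no daytime hours in forcing", call. = FALSE)
  purrr::map_dfr(seq_len(nrow(day)), function(i) {
    row <- day[i, ]
    dplyr::mutate(solve_tseb_pt(row$t_rad, row, canopy, surf),
                  time = row$time, .before = 1)
  })
}

#' Aggregate hourly fluxes to daytime water depths
#'
#' Converts hourly latent heat to water depth with a fixed latent heat of
#' vaporization (2.45 MJ/kg, 1 kg/m2 = 1 mm): `mm = LE * 3600 / lambda`.
#'
#' @param flux Output of [run_tseb_day()].
#' @return One-row tibble: `et_mm`, `t_mm` (canopy transpiration), `e_mm`
#'   (soil evaporation), `hours_used`. `et_mm = t_mm + e_mm`.
#' @export
daytime_et <- function(flux) {
  if (nrow(flux) == 0L) stop("empty flux table", call. = FALSE)
  t_mm <- sum(flux$le_c) * 3600 / LAMBDA_V
  e_mm <- sum(flux$le_s) * 3600 / LAMBDA_V
  tibble::tibble(et_mm = t_mm + e_mm, t_mm = t_mm, e_mm = e_mm,
                 hours_used = nrow(flux))
}

#' Residual energy-balance closure correction
#'
#' Forces closure of eddy-covariance fluxes by assigning the full residual
#' to latent heat: `le_corrected = rn - g - h`.
#'
#' @param rn,g,h,le Net radiation, soil heat flux, sensible and latent heat
#'   (W/m2).
#' @return Corrected latent heat flux (W/m2).
#' @export
residual_closure_correction <- function(rn, g, h, le) {
  rn - g - h
}
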