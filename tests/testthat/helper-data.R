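options(vineflux.quiet = TRUE)

# noiseless two-regime piecewise-linear data: y = 2x below the 0.4 kink,
# y = 5x - 1.2 above (continuous at the kink)
two_regime_data <- function(n = 200, seed = 3) {
  set.seed(seed)
  x <- stats::runif(n, 0, 0.8)
  tibble::tibble(nir = x, lai = ifelse(x < 0.4, 2 * x, 5 * x - 1.2))
}

# small weighted multi-feature linear problem for OLS-equivalence checks;
# every coefficient is large relative to the noise so backward elimination
# keeps all features
weighted_linear_data <- function(n = 80, seed = 4) {
  set.seed(seed)
  d <- tibble::tibble(b_a = stats::runif(n), b_b = stats::runif(n),
                      b_c = stats::runif(n))
  d$lai <- 1 + 2 * d$b_a + 3 * d$b_b - 1.5 * d$b_c + stats::rnorm(n, 0, 0.05)
  d$weight <- stats::runif(n, 0.5, 2)
  d
}

# three synthetic sites with divergent LAI-reflectance slopes (clumping
# archetype contrast) for leave-one-site-out degradation checks
three_site_data <- function(n_per_site = 120, seed = 11) {
  arch <- site_archetypes()
  simulate_lai_dataset(arch, n_per_site = n_per_site, seed = seed)
}

# one-row meteorological record for solver unit tests (midday, clear sky)
midday_met <- function(t_air = 300, sw_in = 850, u = 3, e_air = 1.4,
                       pressure = 101.3) {
  list(time = 13, sw_in = sw_in, lw_in = 370, t_air = t_air, e_air = e_air,
       u = u, pressure = pressure, sun_zenith = 0.3)
}
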