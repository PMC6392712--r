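#' Configuration for the synthetic workforce generator
#'
#' Bundles and validates the parameters of the synthetic prefecture panel
#' generator. Scalars with a documented range form may be given either as a
#' `c(min, max)` range (drawn uniformly per prefecture at simulation time) or
#' as a length-`n_prefectures` vector of fixed values.
#'
#' @param n_prefectures Number of prefectures (>= 2).
#' @param baseline_year,final_year Window of the simulation;
#'   `final_year - baseline_year` annual transitions are simulated.
#' @param initial_stock Per-prefecture practicing-physician stock at
#'   `baseline_year`: a `c(min, max)` range or a vector of length
#'   `n_prefectures`.
#' @param licensing_rates Expected annual newly licensed physicians per
#'   prefecture: range or vector.
#' @param attrition_rate Per-physician annual probability of death or
#'   retirement, in \[0, 1). A scalar applies one national rate (the
#'   estimator's working assumption); a length-`n_prefectures` vector
#'   deliberately violates that assumption for bias experiments.
#' @param gamma0,gamma_newppr,noise_sd Net-migration model: prefecture `i`'s
#'   annual net-outflow propensity (physicians/year) is
#'   `gamma0 + gamma_newppr * newPPR_i + N(0, noise_sd)`, where `newPPR_i` is
#'   the prefecture's newly licensed physicians per 100,000 population.
#'   Propensities are centred across prefectures every year so national net
#'   migration is exactly zero (domestic migration is a closed system).
#' @param populations Synthetic resident populations used to convert
#'   licensing rates to PPRs: range or vector; default 0.5-8 million.
#' @param survey_interval Years between stock observations (default 2,
#'   emulating a biennial survey). The final year is always observed.
#' @param deterministic If `TRUE`, every random draw is replaced by its
#'   expectation (Poisson licensing by the rate, binomial attrition by
#'   `rate * stock`, migration noise by 0), giving an exact-arithmetic panel
#'   for oracle tests.
#' @param seed Default random seed used by [simulate_panel()].
#' @return A validated list of class `"simulation_config"`.
#' @seealso [make_paperlike_config()] for a calibrated 47-prefecture
#'   configuration.
#' @export
simulation_config <- function(n_prefectures = 47,
                              baseline_year = 1994,
                              final_year = 2014,
                              initial_stock = c(1500, 12000),
                              licensing_rates = c(60, 300),
                              attrition_rate = 0.0125,
                              gamma0 = 0,
                              gamma_newppr = 0,
                              noise_sd = 0,
                              populations = c(5e5, 8e6),
                              survey_interval = 2,
                              deterministic = FALSE,
                              seed = 1L) {
  cfg <- list(
    n_prefectures = as.integer(n_prefectures),
    baseline_year = as.integer(baseline_year),
    final_year = as.integer(final_year),
    initial_stock = as.double(initial_stock),
    licensing_rates = as.double(licensing_rates),
    attrition_rate = as.double(attrition_rate),
    gamma0 = as.double(gamma0),
    gamma_newppr = as.double(gamma_newppr),
    noise_sd = as.double(noise_sd),
    populations = as.double(populations),
    survey_interval = as.integer(survey_interval),
    deterministic = isTRUE(deterministic),
    seed = as.integer(seed)
  )
  if (cfg$n_prefectures < 2) {
    stop_physmig("n_prefectures must be >= 2", "validation")
  }
  if (cfg$baseline_year >= cfg$final_year) {
    stop_physmig("baseline_year must precede final_year", "validation")
  }
  if (any(cfg$attrition_rate < 0) || any(cfg$attrition_rate >= 1)) {
    stop_physmig("attrition_rate must lie in [0, 1)", "validation")
  }
  if (!length(cfg$attrition_rate) %in% c(1L, cfg$n_prefectures)) {
    stop_physmig("attrition_rate must be a scalar or one rate per prefecture", "validation")
  }
  if (cfg$survey_interval < 1) {
    stop_physmig("survey_interval must be >= 1", "validation")
  }
  if (cfg$noise_sd < 0) {
    stop_physmig("noise_sd must be non-negative", "validation")
  }
  for (fld in c("initial_stock", "licensing_rates", "populations")) {
    v <- cfg[[fld]]
    if (!length(v) %in% c(2L, cfg$n_prefectures)) {
      stop_physmig(sprintf("%s must be a c(min, max) range or a vector of length %d",
                           fld, cfg$n_prefectures), "validation")
    }
    if (any(v < 0)) stop_physmig(sprintf("%s must be non-negative", fld), "validation")
  }
  structure(cfg, class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("<simulation_config>\n")
  cat(sprintf("  prefectures: %d, window: %d-%d (survey every %d yr)\n",
              x$n_prefectures, x$baseline_year, x$final_year, x$survey_interval))
  cat(sprintf("  attrition rate: %s\n",
              if (length(x$attrition_rate) == 1) format(x$attrition_rate)
              else sprintf("per-prefecture (%.4g-%.4g)", min(x$attrition_rate), max(x$attrition_rate))))
  cat(sprintf("  migration: gamma0 = %g, gamma_newppr = %g, noise_sd = %g\n",
              x$gamma0, x$gamma_newppr, x$noise_sd))
  cat(sprintf("  deterministic: %s, seed: %d\n", x$deterministic, x$seed))
  invisible(x)
}

#' Calibrated 47-prefecture configuration
#'
#' Returns a [simulation_config()] emulating the Japanese physician workforce
#' over 1994-2014: 47 prefectures, biennial stock surveys, annual licensing.
#' The calibration targets the published national magnitudes of that period:
#' licensing rates sum to 7,416 physicians per year, with per-prefecture
#' newly licensed PPR spanning roughly 1.5-16.5 per 100,000 (median about
#' 6.4); the initial national stock is 230,000; and the attrition rate is
#' 3,382 / 270,000 (mean annual national attrition over a stated mean
#' national stock of 270,000), so that the expected mean annual national
#' increase is close to 4,034. Migration follows the licensing gradient
#' (`gamma_newppr = 8` physicians/year per PPR unit, annual noise SD 15), so
#' high-licensing prefectures are net exporters of physicians.
#'
#' The per-prefecture rate, population and stock vectors are built from fixed
#' quantile grids and an internal fixed shuffle: the function is deterministic
#' and takes no arguments.
#'
#' @return A `"simulation_config"` with explicit per-prefecture vectors.
#' @export
make_paperlike_config <- function() {
  n <- 47L
  draws <- with_preserved_seed(20140101L, {
    pops <- qlnorm(stats::ppoints(n), meanlog = log(1.5e6), sdlog = 0.72)
    newppr <- pmin(pmax(qlnorm(stats::ppoints(n), meanlog = log(6.4), sdlog = 0.47),
                        1.5), 16.5)
    list(
      pops = sample(pops),
      newppr = sample(newppr),
      ppr0 = runif(n, 170, 290)
    )
  })
  pops <- draws$pops
  rates <- draws$newppr * pops / 1e5
  scale_pop <- 7416 / sum(rates)
  # rescale populations (not PPRs) so licensing sums to 7416/yr exactly while
  # the newly licensed PPR keeps its 1.5-16.5 span
  pops <- pops * scale_pop
  rates <- draws$newppr * pops / 1e5
  stock0 <- draws$ppr0 * pops / 1e5
  stock0 <- stock0 * 230000 / sum(stock0)
  simulation_config(
    n_prefectures = n,
    baseline_year = 1994L,
    final_year = 2014L,
    initial_stock = stock0,
    licensing_rates = rates,
    attrition_rate = 3382 / 270000,
    gamma0 = 0,
    gamma_newppr = 8,
    noise_sd = 15,
    populations = pops,
    survey_interval = 2L,
    deterministic = FALSE,
    seed = 1L
  )
}

#' Simulate a prefecture panel with known migration ground truth
#'
#' Runs the annual workforce accounting the estimator assumes: each year every
#' prefecture loses attrited physicians (binomial on its start-of-year stock),
#' gains newly licensed physicians (Poisson around its licensing rate) and
#' exchanges net migrants according to the covariate-driven propensity model
#' of [simulation_config()]. Annual net flows are centred so national net
#' migration is exactly zero, and stocks are recorded only at survey years.
#'
#' In deterministic mode with a uniform (scalar) attrition rate, each year's
#' national attrition `rate * S(t)` is allocated across prefectures with
#' constant shares chosen so cumulative per-prefecture attrition is exactly
#' proportional to the survey-mean stock. This makes the estimator's Step-2
#' allocation assumption hold by construction, so [estimate_migration()]
#' recovers the generator's truth to machine precision — the package's
#' exact-arithmetic oracle. With per-prefecture rates (or stochastic draws)
#' attrition is `rate_i * stock_i` per year and the assumption is genuinely
#' violated, which is the point of the bias experiment.
#'
#' If a migration draw would drive a stock negative the outflow is truncated
#' at the available stock and the deficit is redistributed over the remaining
#' prefectures (a message reports it); truth is accumulated from the realised,
#' not the proposed, flows.
#'
#' @param config A [simulation_config()].
#' @param seed Random seed; defaults to `config$seed`. The same seed always
#'   reproduces the identical panel, covariates and truth.
#' @return A list of class `"physmig_sim"`:
#'   \describe{
#'     \item{panel}{long panel tibble (see [read_panel()]) with stocks at
#'       survey years and annual licensing counts,}
#'     \item{covariates}{covariate tibble (see [read_covariates()]);
#'       `new_licensed_ppr` is derived from the licensing rate and the
#'       synthetic population, `practicing_ppr` from the final-year stock,
#'       the remaining six are independent noise on realistic scales,}
#'     \item{truth}{tibble `prefecture, true_net_migrants, true_attrition,
#'       true_migration_ratio` (positive net migrants = outflow),}
#'     \item{flows}{per-year event log `year, prefecture, new_licensed,
#'       attrition, net_out` from which the truth can be re-accumulated,}
#'     \item{config}{the input configuration.}
#'   }
#' @export
#' @examples
#' sim <- simulate_panel(simulation_config(n_prefectures = 3, seed = 7))
#' sim$truth
#' sum(sim$truth$true_net_migrants) # closed system: exactly 0
simulate_panel <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "simulation_config"))
  with_preserved_seed(seed, simulate_panel_impl(config))
}

simulate_panel_impl <- function(cfg) {
  n <- cfg$n_prefectures
  prefs <- sprintf("P%02d", seq_len(n))
  years <- seq(cfg$baseline_year, cfg$final_year - 1L) # transition years
  n_years <- length(years)

  resolve <- function(v) if (length(v) == n) v else runif(n, v[1], v[2])
  pops <- resolve(cfg$populations)
  rates <- resolve(cfg$licensing_rates)
  stock0 <- resolve(cfg$initial_stock)
  r <- if (length(cfg$attrition_rate) == 1) rep(cfg$attrition_rate, n) else cfg$attrition_rate
  uniform_rate <- length(unique(cfg$attrition_rate)) == 1

  newppr <- rates / pops * 1e5
  propensity <- cfg$gamma0 + cfg$gamma_newppr * newppr

  survey_years <- unique(c(seq(cfg$baseline_year, cfg$final_year, by = cfg$survey_interval),
                           cfg$final_year))

  # per-year draws (expectation in deterministic mode), n x n_years matrices
  lic <- matrix(0, n, n_years)
  eps <- matrix(0, n, n_years)
  if (cfg$deterministic) {
    lic[] <- rates
  } else {
    lic[] <- rpois(n * n_years, rep(rates, n_years))
    if (cfg$noise_sd > 0) eps[] <- rnorm(n * n_years, 0, cfg$noise_sd)
  }
  # centred net-outflow proposals, one column per year
  mig <- propensity + eps
  mig <- sweep(mig, 2, colMeans(mig))

  exact_alloc <- cfg$deterministic && uniform_rate
  theta <- NULL
  if (exact_alloc) {
    # attrition-free pre-pass: survey-mean stocks fix the allocation shares
    s <- stock0
    pre <- matrix(NA_real_, n, length(survey_years),
                  dimnames = list(NULL, survey_years))
    obs <- as.character(cfg$baseline_year)
    if (obs %in% colnames(pre)) pre[, obs] <- s
    for (k in seq_len(n_years)) {
      s <- s + lic[, k] - mig[, k]
      obs <- as.character(years[k] + 1L)
      if (obs %in% colnames(pre)) pre[, obs] <- s
    }
    u <- rowMeans(pre)
    theta <- u / sum(u)
    S_nat <- sum(stock0)
  }

  stock <- stock0
  obs_stock <- matrix(NA_real_, n, length(survey_years),
                      dimnames = list(NULL, survey_years))
  if (as.character(cfg$baseline_year) %in% colnames(obs_stock)) {
    obs_stock[, as.character(cfg$baseline_year)] <- stock
  }
  attr_log <- matrix(0, n, n_years)
  out_log <- matrix(0, n, n_years)
  n_truncated <- 0L

  for (k in seq_len(n_years)) {
    a <- if (exact_alloc) {
      theta * (r[1] * S_nat)
    } else if (cfg$deterministic) {
      r * stock
    } else {
      as.double(rbinom(n, round(stock), r))
    }
    a <- pmin(a, stock) # attrition cannot exceed the standing stock
    avail <- stock - a + lic[, k] # max feasible net outflow this year
    m <- mig[, k]
    if (any(m > avail)) {
      m <- redistribute_outflow(m, avail)
      n_truncated <- n_truncated + 1L
    }
    stock <- stock - a + lic[, k] - m
    if (exact_alloc) S_nat <- S_nat + sum(lic[, k]) - r[1] * S_nat
    attr_log[, k] <- a
    out_log[, k] <- m
    obs <- as.character(years[k] + 1L)
    if (obs %in% colnames(obs_stock)) obs_stock[, obs] <- stock
  }
  if (n_truncated > 0L) {
    inform(sprintf("simulate_panel: migration flows truncated in %d year(s) to keep stocks non-negative",
                   n_truncated))
  }

  flows <- tibble(
    year = rep(years, each = n),
    prefecture = rep(prefs, n_years),
    new_licensed = as.vector(lic),
    attrition = as.vector(attr_log),
    net_out = as.vector(out_log)
  )

  lic_total <- rowSums(lic)
  truth <- tibble(
    prefecture = prefs,
    true_net_migrants = rowSums(out_log),
    true_attrition = rowSums(attr_log),
    true_migration_ratio = ifelse(lic_total > 0, rowSums(out_log) / lic_total, NA_real_)
  )

  all_years <- seq(cfg$baseline_year, cfg$final_year)
  panel <- tibble(
    prefecture = rep(prefs, each = length(all_years)),
    year = rep(as.integer(all_years), n),
    stock = NA_real_,
    new_licensed = NA_real_
  )
  sy_idx <- match(paste(panel$prefecture, panel$year),
                  paste(rep(prefs, each = length(survey_years)),
                        rep(survey_years, n)))
  obs_flat <- as.vector(t(obs_stock))
  panel$stock <- obs_flat[sy_idx]
  lic_idx <- match(paste(panel$prefecture, panel$year),
                   paste(rep(prefs, each = n_years), rep(years, n)))
  lic_flat <- as.vector(t(lic))
  panel$new_licensed <- lic_flat[lic_idx]
  panel <- panel[!(is.na(panel$stock) & is.na(panel$new_licensed)), , drop = FALSE]

  covariates <- tibble(
    prefecture = prefs,
    practicing_ppr = obs_stock[, as.character(cfg$final_year)] / pops * 1e5,
    new_licensed_ppr = newppr,
    physician_mean_age = pmin(pmax(rnorm(n, 50.5, 1.5), 45), 57),
    female_ratio = pmin(pmax(rnorm(n, 0.19, 0.03), 0.08), 0.35),
    pop_density = pops / exp(rnorm(n, log(1500), 0.5)),
    unemployment = pmin(pmax(rnorm(n, 0.032, 0.005), 0.015), 0.06),
    aged_ratio = pmin(pmax(rnorm(n, 0.26, 0.03), 0.15), 0.38),
    income = pmax(rnorm(n, 2.9e6, 3.5e5), 1.8e6)
  )

  structure(
    list(panel = validate_panel(panel),
         covariates = validate_covariates(covariates),
         truth = truth,
         flows = flows,
         config = cfg),
    class = "physmig_sim"
  )
}

# Clamp proposed net outflows m (summing to 0) to per-prefecture capacity and
# redistribute the clipped excess over prefectures with headroom, preserving
# the zero national sum. Capacity is the stock available after attrition and
# licensing, so no stock can go negative.
redistribute_outflow <- function(m, avail) {
  for (i in 1:100) {
    over <- m > avail
    if (!any(over)) return(m)
    excess <- sum(m[over] - avail[over])
    m[over] <- avail[over]
    head_room <- avail - m
    head_room[over] <- 0
    if (sum(head_room) < excess) {
      stop_physmig("migration truncation infeasible: no capacity left to absorb flows",
                   "validation")
    }
    m <- m + head_room / sum(head_room) * excess
  }
  stop_physmig("migration truncation did not converge", "validation")
}

#' @export
print.physmig_sim <- function(x, ...) {
  cat("<physmig_sim>\n")
  cat(sprintf("  %d prefectures, %d-%d, %d panel rows\n",
              x$config$n_prefectures, x$config$baseline_year,
              x$config$final_year, nrow(x$panel)))
  cat(sprintf("  total new licensed: %.0f, total attrition: %.0f\n",
              sum(x$flows$new_licensed), sum(x$flows$attrition)))
  cat(sprintf("  net migration range: %.1f to %.1f (sums to %.2g)\n",
              min(x$truth$true_net_migrants), max(x$truth$true_net_migrants),
              sum(x$truth$true_net_migrants)))
  invisible(x)
}

# Run code under a fixed seed, restoring the caller's RNG state afterwards.
with_preserved_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
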