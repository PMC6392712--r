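# Fixtures are built in code; nothing is stored on disk.

tiny_panel <- function() {
  tibble::tibble(
    prefecture = rep(c("aichi", "chiba", "ishikawa"), each = 2),
    year = rep(c(2000L, 2010L), 3),
    stock = c(100, 150, 200, 210, 50, 80),
    new_licensed = c(10, 12, 5, 6, 8, 9)
  )
}

# Two-prefecture panel whose Step 1-3 arithmetic is forced by hand:
# new licensed (100, 100), allocated attrition (40, 60) via mean stocks
# (200, 300), actual increase (30, 70) -> net migrants (+30, -30).
forced_panel <- function() {
  tibble::tibble(
    prefecture = rep(c("a", "b"), each = 2),
    year = rep(c(2000L, 2010L), 2),
    stock = c(185, 215, 265, 335),
    new_licensed = c(100, NA, 100, NA)
  )
}

random_panel <- function(n = 10, seed = 1) {
  cfg <- simulation_config(
    n_prefectures = n,
    baseline_year = 2000L, final_year = 2010L,
    initial_stock = c(500, 5000),
    licensing_rates = c(20, 200),
    attrition_rate = runif(1, 0.005, 0.03),
    gamma_newppr = runif(1, 0, 10),
    noise_sd = runif(1, 0, 20),
    seed = seed
  )
  simulate_panel(cfg)
}

random_covariates <- function(prefs) {
  n <- length(prefs)
  tibble::tibble(
    prefecture = prefs,
    practicing_ppr = runif(n, 150, 320),
    new_licensed_ppr = runif(n, 1.5, 16.5),
    physician_mean_age = runif(n, 46, 56),
    female_ratio = runif(n, 0.1, 0.3),
    pop_density = runif(n, 100, 8000),
    unemployment = runif(n, 0.02, 0.05),
    aged_ratio = runif(n, 0.18, 0.33),
    income = runif(n, 2e6, 4e6)
  )
}
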