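test_that("no-migration limit yields exactly zero net migrants", {
  cfg <- simulation_config(n_prefectures = 5, gamma0 = 0, gamma_newppr = 0,
                           noise_sd = 0, seed = 3)
  sim <- simulate_panel(cfg)
  expect_equal(sim$truth$true_net_migrants, rep(0, 5))
  expect_equal(sim$truth$true_migration_ratio, rep(0, 5))
})

test_that("zero attrition with no migration conserves stock exactly", {
  cfg <- simulation_config(n_prefectures = 4, attrition_rate = 0,
                           gamma_newppr = 0, noise_sd = 0, seed = 11)
  sim <- simulate_panel(cfg)
  by_pref <- split(sim$panel, sim$panel$prefecture)
  for (p in by_pref) {
    first <- p$stock[p$year == min(p$year)]
    last <- p$stock[p$year == max(p$year)]
    lic <- sum(p$new_licensed, na.rm = TRUE)
    expect_equal(last, first + lic)
  }
})

test_that("the same seed reproduces the identical panel and truth", {
  cfg <- simulation_config(n_prefectures = 6, gamma_newppr = 5, noise_sd = 10,
                           seed = 42)
  a <- simulate_panel(cfg)
  b <- simulate_panel(cfg)
  expect_identical(a$panel, b$panel)
  expect_identical(a$truth, b$truth)
  expect_identical(a$covariates, b$covariates)
  c <- simulate_panel(cfg, seed = 43)
  expect_false(identical(a$panel, c$panel))
})

test_that("truth totals equal the re-accumulated per-year event log", {
  cfg <- simulation_config(n_prefectures = 3, baseline_year = 2000,
                           final_year = 2008, initial_stock = c(200, 400),
                           licensing_rates = c(10, 30), attrition_rate = 0.02,
                           gamma_newppr = 3, noise_sd = 4, seed = 9)
  sim <- simulate_panel(cfg)
  relog <- sim$flows |>
    dplyr::group_by(prefecture) |>
    dplyr::summarise(net = sum(net_out), attr = sum(attrition),
                     lic = sum(new_licensed))
  expect_equal(relog$net, sim$truth$true_net_migrants)
  expect_equal(relog$attr, sim$truth$true_attrition)
  expect_equal(relog$net / relog$lic, sim$truth$true_migration_ratio)
})

test_that("every realization is a closed system", {
  for (seed in 1:20) {
    sim <- random_panel(n = 8, seed = seed)
    # net migration sums to zero
    expect_lt(abs(sum(sim$truth$true_net_migrants)), 1e-9)
    # conservation: national stock change = licensing - attrition
    first <- sim$panel |>
      dplyr::filter(!is.na(stock), year == min(year[!is.na(stock)]))
    last <- sim$panel |>
      dplyr::filter(!is.na(stock), year == max(year[!is.na(stock)]))
    expect_equal(sum(last$stock) - sum(first$stock),
                 sum(sim$flows$new_licensed) - sum(sim$flows$attrition))
  }
})

test_that("stocks never go negative even under extreme outflow pressure", {
  cfg <- simulation_config(n_prefectures = 4, initial_stock = c(30, 60),
                           licensing_rates = c(1, 3), attrition_rate = 0.1,
                           gamma0 = 0, gamma_newppr = 50, noise_sd = 30,
                           populations = c(1e4, 1e5), seed = 5)
  expect_message(sim <- simulate_panel(cfg), "truncated")
  expect_true(all(sim$panel$stock >= 0, na.rm = TRUE))
  # truncation preserved the closed-system zero sum
  expect_lt(abs(sum(sim$truth$true_net_migrants)), 1e-9)
})

test_that("config validation rejects out-of-range parameters", {
  expect_error(simulation_config(n_prefectures = 1), class = "physmig_error_validation")
  expect_error(simulation_config(attrition_rate = 1), class = "physmig_error_validation")
  expect_error(simulation_config(survey_interval = 0), class = "physmig_error_validation")
  expect_error(simulation_config(baseline_year = 2010, final_year = 2000),
               class = "physmig_error_validation")
  expect_error(simulation_config(licensing_rates = c(1, 2, 3)),
               class = "physmig_error_validation")
})

test_that("the calibrated national configuration matches its stated targets", {
  cfg <- make_paperlike_config()
  # licensing calibrated to 7416/yr nationally, PPR span 1.5-16.5
  expect_equal(sum(cfg$licensing_rates), 7416, tolerance = 1e-9)
  newppr <- cfg$licensing_rates / cfg$populations * 1e5
  expect_true(all(newppr >= 1.5 - 1e-9 & newppr <= 16.5 + 1e-9))
  expect_equal(sum(cfg$initial_stock), 230000, tolerance = 1e-9)
  # deterministic: two calls agree
  expect_identical(cfg, make_paperlike_config())

  # Monte-Carlo: mean annual national increase within 5% of 4034
  incs <- vapply(1:20, function(s) {
    sim <- simulate_panel(cfg, seed = s)
    obs <- sim$panel[!is.na(sim$panel$stock), ]
    (sum(obs$stock[obs$year == 2014]) - sum(obs$stock[obs$year == 1994])) / 20
  }, numeric(1))
  expect_lt(abs(mean(incs) - 4034) / 4034, 0.05)

  # no-attrition limit: mean annual increase equals the licensing total
  cfg0 <- cfg
  cfg0$attrition_rate <- 0
  sim0 <- simulate_panel(cfg0, seed = 1)
  obs <- sim0$panel[!is.na(sim0$panel$stock), ]
  inc0 <- (sum(obs$stock[obs$year == 2014]) - sum(obs$stock[obs$year == 1994])) / 20
  expect_equal(inc0, 7416, tolerance = 0.02)
})
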