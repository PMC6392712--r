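test_that("national attrition is the licensing-minus-growth residual", {
  # mean-annual national scale of the 1994-2014 Japanese workforce
  expect_identical(estimate_national_attrition(7416, 4034), 3382)
  # no-attrition identity
  for (x in c(0, 1, 1234.5)) expect_equal(estimate_national_attrition(x, x), 0)
  # implausible panel: growth exceeding licensing
  expect_warning(a <- estimate_national_attrition(100, 150), "negative")
  expect_equal(a, -50)
  expect_error(estimate_national_attrition(100, 150, strict = TRUE),
               class = "physmig_error_validation")
  expect_error(estimate_national_attrition(-1, 0), class = "physmig_error_validation")
})

test_that("mean stock averages observed survey years only", {
  two_point <- tibble::tibble(prefecture = "a", year = c(1994L, 2014L),
                              stock = c(100, 300), new_licensed = NA_real_)
  expect_equal(mean_stock(two_point)$mean_stock, 200)

  constant <- tibble::tibble(prefecture = "a", year = seq(1994L, 2014L, 2L),
                             stock = 77, new_licensed = NA_real_)
  expect_equal(mean_stock(constant)$mean_stock, 77)

  # 11 biennial observations of a linear ramp -> the midpoint value
  yrs <- seq(1994L, 2014L, 2L)
  ramp <- tibble::tibble(prefecture = "a", year = yrs,
                         stock = 50 + 7 * (yrs - 1994), new_licensed = NA_real_)
  expect_equal(mean_stock(ramp)$mean_stock, 50 + 7 * (2004 - 1994))

  # window restriction and missing-observation error
  expect_equal(mean_stock(ramp, 1994, 1998)$mean_stock, mean(50 + 7 * c(0, 2, 4)))
  expect_error(mean_stock(ramp, 2015, 2020), class = "physmig_error_validation")
})

test_that("attrition allocation is proportional and conserves the total", {
  expect_equal(allocate_attrition(100, c(a = 1, b = 1))$allocated_attrition,
               c(50, 50))
  expect_equal(allocate_attrition(100, c(a = 3, b = 1))$allocated_attrition,
               c(75, 25))
  withr::with_seed(4, {
    stocks <- runif(47, 500, 12000)
  })
  shares <- allocate_attrition(67640, setNames(stocks, sprintf("p%02d", 1:47)))
  expect_lt(abs(sum(shares$allocated_attrition) - 67640), 1e-6)
  expect_equal(shares$allocated_attrition, 67640 * stocks / sum(stocks))
  expect_error(allocate_attrition(10, c(a = 0, b = 0)),
               class = "physmig_error_validation")
  expect_error(allocate_attrition(-1, c(a = 1)), class = "physmig_error_validation")
})

test_that("the two-prefecture worked panel forces the full chain arithmetic", {
  est <- estimate_migration(forced_panel())
  expect_equal(est$new_licensed_total, c(100, 100))
  expect_equal(est$allocated_attrition, c(40, 60))
  expect_equal(est$adjusted_new_licensed, c(60, 40))
  expect_equal(est$actual_increase, c(30, 70))
  expect_equal(est$net_migrants, c(30, -30)) # zero-sum visible
  expect_equal(est$migration_ratio, c(0.3, -0.3))
  expect_equal(est$label, c("outflow", "inflow"))
})

test_that("net migrants sum to zero and attrition is conserved on random panels", {
  for (seed in 1:25) {
    sim <- random_panel(n = sample(4:12, 1), seed = seed)
    est <- estimate_migration(sim$panel)
    expect_lt(abs(sum(est$net_migrants)), 1e-6)
    nat <- attr(est, "national")
    expect_lt(abs(sum(est$allocated_attrition) - nat$total_attrition), 1e-6)
    # sign convention: outflow iff adjusted licensing exceeds actual increase
    expect_equal(est$net_migrants > 0,
                 est$adjusted_new_licensed > est$actual_increase)
    expect_true(all(est$label[est$net_migrants > 0] == "outflow"))
    expect_true(all(est$label[est$net_migrants < 0] == "inflow"))
  }
})

test_that("estimates are scale equivariant", {
  sim <- random_panel(n = 6, seed = 31)
  est1 <- estimate_migration(sim$panel)
  k <- 3.7
  scaled <- sim$panel
  scaled$stock <- scaled$stock * k
  scaled$new_licensed <- scaled$new_licensed * k
  est2 <- estimate_migration(scaled)
  expect_equal(est2$net_migrants, k * est1$net_migrants)
  expect_equal(est2$migration_ratio, est1$migration_ratio)
})

test_that("deterministic uniform-attrition panels reproduce the generator truth exactly", {
  cfg <- make_paperlike_config()
  cfg$deterministic <- TRUE
  sim <- simulate_panel(cfg)
  est <- estimate_migration(sim$panel)
  expect_equal(est$prefecture, sim$truth$prefecture)
  expect_lt(max(abs(est$net_migrants - sim$truth$true_net_migrants)), 1e-6)
  expect_lt(max(abs(est$migration_ratio - sim$truth$true_migration_ratio)), 1e-9)
  expect_lt(abs(attr(est, "national")$total_attrition - sum(sim$truth$true_attrition)),
            1e-6)
})

test_that("heterogeneous attrition rates bias the estimates but preserve the zero sum", {
  cfg <- simulation_config(
    n_prefectures = 10, baseline_year = 1994, final_year = 2014,
    initial_stock = seq(1000, 10000, length.out = 10),
    licensing_rates = seq(20, 200, length.out = 10),
    attrition_rate = rep(c(0.02, 0.01), 5), # 2:1 violation of the equal-rate assumption
    gamma_newppr = 2, noise_sd = 0, deterministic = TRUE, seed = 8
  )
  sim <- simulate_panel(cfg)
  est <- estimate_migration(sim$panel)
  deviation <- est$net_migrants - sim$truth$true_net_migrants
  expect_gt(max(abs(deviation)), 1) # genuinely biased
  expect_lt(abs(sum(deviation)), 1e-6) # signed deviations cancel nationally
  expect_lt(abs(sum(est$net_migrants)), 1e-6)
})

test_that("missing endpoint stocks are reported by prefecture name", {
  p <- tiny_panel()
  p$stock[p$prefecture == "chiba" & p$year == 2010] <- NA
  expect_error(estimate_migration(p), "chiba", class = "physmig_error_validation")
})

test_that("flow difference spans the extreme outflow and inflow ratios", {
  est <- tibble::tibble(migration_ratio = c(0.68, 0.13, -0.021, -2.45))
  expect_equal(flow_difference(est), 313)
  expect_equal(flow_difference(tibble::tibble(migration_ratio = c(0.2, 0.2, 0.2))), 0)
  for (seed in 1:5) {
    withr::with_seed(seed, r <- rnorm(10))
    expect_gte(flow_difference(tibble::tibble(migration_ratio = r)), 0)
  }
  expect_error(flow_difference(tibble::tibble(migration_ratio = 0.5)),
               class = "physmig_error_validation")
})
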