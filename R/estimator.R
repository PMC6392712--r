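#' Step 1: national attrition by the residual method
#'
#' Deaths and retirements are not observed directly; over a closed national
#' system they must equal the number of newly licensed physicians minus the
#' observed growth of the national stock:
#' `attrition = total_new_licensed - total_increase`.
#'
#' @param total_new_licensed Newly licensed physicians over the window (or
#'   per year — the identity is scale-free), non-negative.
#' @param total_increase Final-year national stock minus baseline-year stock
#'   (may be negative if the workforce shrank).
#' @param strict If `TRUE`, a negative result (more physicians appeared than
#'   were licensed, an implausible panel) raises a validation error instead
#'   of a warning.
#' @return The estimated attrition count.
#' @export
#' @examples
#' estimate_national_attrition(7416, 4034) # mean-annual national scale
estimate_national_attrition <- function(total_new_licensed, total_increase,
                                        strict = FALSE) {
  if (total_new_licensed < 0) {
    stop_physmig("total_new_licensed must be non-negative", "validation")
  }
  attrition <- total_new_licensed - total_increase
  if (attrition < 0) {
    msg <- sprintf(
      "estimated national attrition is negative (%.6g): the stock grew by more than the licensing inflow",
      attrition
    )
    if (strict) stop_physmig(msg, "validation") else warn(msg)
  }
  attrition
}

#' Mean practicing stock per prefecture over the study window
#'
#' Arithmetic mean of the observed survey-year stocks inside
#' `[baseline_year, final_year]`. Only observed years enter the mean; survey
#' gaps are not interpolated.
#'
#' @param panel A panel tibble (see [read_panel()]).
#' @param baseline_year,final_year Window bounds; default to the earliest and
#'   latest year with any observed stock.
#' @return A tibble `prefecture, mean_stock, n_obs`.
#' @export
mean_stock <- function(panel, baseline_year = NULL, final_year = NULL) {
  panel <- validate_panel(panel)
  obs <- panel[!is.na(panel$stock), , drop = FALSE]
  baseline_year <- baseline_year %||% min(obs$year)
  final_year <- final_year %||% max(obs$year)
  obs <- obs[obs$year >= baseline_year & obs$year <= final_year, , drop = FALSE]
  out <- obs |>
    dplyr::group_by(.data$prefecture) |>
    dplyr::summarise(mean_stock = mean(.data$stock), n_obs = dplyr::n(),
                     .groups = "drop")
  missing <- setdiff(unique(panel$prefecture), out$prefecture)
  if (length(missing) > 0) {
    stop_physmig(
      sprintf("no stock observations in [%d, %d] for prefecture(s): %s",
              baseline_year, final_year, paste(missing, collapse = ", ")),
      "validation"
    )
  }
  out
}

#' Step 2: allocate national attrition proportionally to mean stocks
#'
#' Prefecture `i` receives `national_attrition * mean_stock_i / sum(mean_stock)`.
#' Shares stay fractional — no rounding — so they sum to the national total
#' exactly; that conservation is what makes the downstream net-migration
#' estimates sum to zero.
#'
#' @param national_attrition Non-negative national attrition count (Step 1).
#' @param mean_stocks A tibble with columns `prefecture` and `mean_stock`
#'   (see [mean_stock()]), or a named numeric vector.
#' @return A tibble `prefecture, allocated_attrition`.
#' @export
#' @examples
#' allocate_attrition(100, c(A = 3, B = 1))
allocate_attrition <- function(national_attrition, mean_stocks) {
  if (national_attrition < 0) {
    stop_physmig("national_attrition must be non-negative", "validation")
  }
  if (is.numeric(mean_stocks)) {
    mean_stocks <- tibble(prefecture = names(mean_stocks) %||%
                            as.character(seq_along(mean_stocks)),
                          mean_stock = as.double(mean_stocks))
  }
  require_columns(mean_stocks, c("prefecture", "mean_stock"), "mean_stocks")
  total <- sum(mean_stocks$mean_stock)
  if (total <= 0) {
    stop_physmig("cannot allocate attrition: all mean stocks are zero", "validation")
  }
  tibble(
    prefecture = mean_stocks$prefecture,
    allocated_attrition = national_attrition * mean_stocks$mean_stock / total
  )
}

#' Steps 1-3: per-prefecture net migration and migration ratios
#'
#' Chains the full residual method over a panel:
#' \enumerate{
#'   \item national attrition = total new licensed - national stock increase;
#'   \item allocated per prefecture in proportion to mean survey-year stock;
#'   \item `adjusted_new_licensed = new_licensed_total - allocated_attrition`
#'     (the hypothetical stock increase under zero migration),
#'     `net_migrants = adjusted_new_licensed - actual_increase`.
#' }
#' Positive `net_migrants` means the prefecture trained more physicians than
#' it kept — an outflow prefecture; negative means inflow. The migration
#' ratio divides net migrants by the prefecture's total newly licensed count
#' over the window; it is a proportion (0.68 = 68 percent outflow) and can
#' fall below -1 where inflow exceeds local licensing. By construction the
#' net migrant counts sum to zero across prefectures.
#'
#' A negative `adjusted_new_licensed` (attrition exceeding local licensing)
#' is legitimate and propagates; it is flagged in the `label` column logic
#' only through its effect on net migrants.
#'
#' @param panel A panel tibble (see [read_panel()]).
#' @param baseline_year,final_year Window bounds; default to the earliest and
#'   latest observed stock years. Every prefecture must have a stock at both
#'   bounds.
#' @param strict Passed to [estimate_national_attrition()].
#' @param balanced_tol Absolute `net_migrants` at or below which a prefecture
#'   is labelled `"balanced"` rather than outflow/inflow (default 0: any
#'   positive value is outflow).
#' @return A tibble of class `"migration_estimates"` with one row per
#'   prefecture and columns `prefecture, mean_stock, allocated_attrition,
#'   new_licensed_total, adjusted_new_licensed, actual_increase, net_migrants,
#'   migration_ratio, label`; attributes `baseline_year`, `final_year` and
#'   `national` (the Step-1 totals) record the accounting choices.
#' @export
#' @examples
#' sim <- simulate_panel(simulation_config(n_prefectures = 5, seed = 2))
#' estimate_migration(sim$panel)
estimate_migration <- function(panel, baseline_year = NULL, final_year = NULL,
                               strict = FALSE, balanced_tol = 0) {
  panel <- validate_panel(panel)
  obs <- panel[!is.na(panel$stock), , drop = FALSE]
  if (nrow(obs) == 0) stop_physmig("panel has no stock observations", "validation")
  baseline_year <- baseline_year %||% min(obs$year)
  final_year <- final_year %||% max(obs$year)
  if (baseline_year >= final_year) {
    stop_physmig("baseline_year must precede final_year", "validation")
  }

  prefs <- sort(unique(panel$prefecture))
  endpoint <- function(yr, what) {
    s <- obs[obs$year == yr, , drop = FALSE]
    missing <- setdiff(prefs, s$prefecture)
    if (length(missing) > 0) {
      stop_physmig(
        sprintf("missing %s-year (%d) stock for prefecture(s): %s",
                what, yr, paste(missing, collapse = ", ")),
        "validation"
      )
    }
    setNames(s$stock, s$prefecture)[prefs]
  }
  s0 <- endpoint(baseline_year, "baseline")
  s1 <- endpoint(final_year, "final")

  lic <- panel |>
    dplyr::filter(.data$year >= baseline_year, .data$year < final_year) |>
    dplyr::group_by(.data$prefecture) |>
    dplyr::summarise(new_licensed_total = sum(.data$new_licensed, na.rm = TRUE),
                     .groups = "drop")
  lic_total <- setNames(lic$new_licensed_total, lic$prefecture)[prefs]
  lic_total[is.na(lic_total)] <- 0

  national_attrition <- estimate_national_attrition(
    sum(lic_total), sum(s1) - sum(s0), strict = strict
  )
  ms <- mean_stock(panel, baseline_year, final_year)
  alloc <- allocate_attrition(national_attrition, ms)

  est <- tibble(prefecture = prefs) |>
    dplyr::left_join(ms[c("prefecture", "mean_stock")], by = "prefecture") |>
    dplyr::left_join(alloc, by = "prefecture") |>
    dplyr::mutate(
      new_licensed_total = unname(lic_total),
      adjusted_new_licensed = .data$new_licensed_total - .data$allocated_attrition,
      actual_increase = unname(s1 - s0),
      net_migrants = .data$adjusted_new_licensed - .data$actual_increase,
      migration_ratio = ifelse(.data$new_licensed_total > 0,
                               .data$net_migrants / .data$new_licensed_total,
                               NA_real_),
      label = dplyr::case_when(
        .data$net_migrants > balanced_tol ~ "outflow",
        .data$net_migrants < -balanced_tol ~ "inflow",
        TRUE ~ "balanced"
      )
    )
  structure(
    est,
    class = c("migration_estimates", class(est)),
    baseline_year = as.integer(baseline_year),
    final_year = as.integer(final_year),
    national = list(
      total_new_licensed = sum(lic_total),
      total_increase = sum(s1) - sum(s0),
      total_attrition = national_attrition
    )
  )
}

#' Maximum flow difference across prefectures
#'
#' The spread between the strongest outflow and the strongest inflow:
#' `(max(migration_ratio) - min(migration_ratio)) * 100`, in percentage
#' points. With the outflow-positive sign convention this equals the maximum
#' outflow percentage plus the maximum inflow percentage.
#'
#' @param estimates A `"migration_estimates"` tibble (or any data frame with
#'   a `migration_ratio` column holding proportions).
#' @return A single number in percent.
#' @export
#' @examples
#' flow_difference(data.frame(migration_ratio = c(0.68, 0.1, -2.45))) # 313
flow_difference <- function(estimates) {
  require_columns(estimates, "migration_ratio", "estimates")
  r <- estimates$migration_ratio
  r <- r[!is.na(r)]
  if (length(r) < 2) {
    stop_physmig("flow_difference needs at least 2 defined migration ratios",
                 "validation")
  }
  (max(r) - min(r)) * 100
}

#' @export
print.migration_estimates <- function(x, ...) {
  nat <- attr(x, "national")
  cat(sprintf("Migration estimates for %d prefectures, %d-%d\n",
              nrow(x), attr(x, "baseline_year"), attr(x, "final_year")))
  cat(sprintf("  national: new licensed %.0f, increase %.0f, attrition (residual) %.0f\n",
              nat$total_new_licensed, nat$total_increase, nat$total_attrition))
  cat(sprintf("  net migrants sum to %.3g (zero-sum identity)\n",
              sum(x$net_migrants)))
  NextMethod()
}
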