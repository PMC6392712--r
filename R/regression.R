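#' Simple linear regression of migration ratio on one covariate
#'
#' Ordinary least squares of the signed migration ratio (outflow positive) on
#' a single covariate, with intercept. Slope, standard error and the
#' two-sided t-test p-value on n - 2 degrees of freedom are reported on the
#' covariate's native scale.
#'
#' @param data A data frame holding the response and the covariate, one row
#'   per prefecture.
#' @param covariate Name of the covariate column (string).
#' @param response Name of the response column (default `"migration_ratio"`).
#' @param alpha Significance level (default 0.05).
#' @return A one-row tibble `variable, estimate, std_error, statistic,
#'   p_value, significant`.
#' @export
#' @examples
#' d <- data.frame(migration_ratio = c(1, 2, 3, 4, 5) * 2, x = 1:5)
#' fit_simple(d, "x")
fit_simple <- function(data, covariate, response = "migration_ratio",
                       alpha = 0.05) {
  require_columns(data, c(response, covariate), "data")
  d <- data[complete.cases(data[c(response, covariate)]), , drop = FALSE]
  if (nrow(d) < 3) {
    stop_physmig("simple regression needs at least 3 complete observations",
                 "validation")
  }
  x <- d[[covariate]]
  if (length(unique(x)) < 2) {
    stop_physmig(sprintf("covariate '%s' is constant: degenerate design", covariate),
                 "degenerate")
  }
  fit <- lm(stats::reformulate(covariate, response), data = d)
  cf <- summary(fit)$coefficients
  tibble(
    variable = covariate,
    estimate = unname(cf[covariate, "Estimate"]),
    std_error = unname(cf[covariate, "Std. Error"]),
    statistic = unname(cf[covariate, "t value"]),
    p_value = unname(cf[covariate, "Pr(>|t|)"]),
    significant = unname(cf[covariate, "Pr(>|t|)"] < alpha)
  )
}

#' Simple and multiple regression of migration ratios on covariates
#'
#' Mirrors the two-stage association analysis: each covariate is first
#' regressed against the migration ratio on its own, then all covariates
#' enter one joint OLS model with intercept. No multiple-testing correction
#' is applied; significance is raw `p < alpha` in both stages. Prefectures
#' with any missing value are dropped listwise with a warning.
#'
#' @param estimates A `"migration_estimates"` tibble (needs `prefecture` and
#'   `migration_ratio`).
#' @param covariates A covariate tibble (see [read_covariates()]); joined by
#'   `prefecture`.
#' @param alpha Significance level (default 0.05).
#' @param standardize If `TRUE`, covariates are z-scored before fitting so
#'   coefficients are comparable across scales; default reports native
#'   scales.
#' @param variables Covariate columns to use; defaults to the eight standard
#'   socio-demographic covariates present in `covariates`.
#' @return An object of class `"migration_regression"`: a list with `simple`
#'   and `multiple` result tibbles (`variable, estimate, std_error,
#'   statistic, p_value, significant`), `n`, `alpha`, `standardize` and the
#'   underlying `lm` fit (`model`). Use [tidy()] for the side-by-side table
#'   and [glance()] for model-level statistics.
#' @export
#' @examples
#' sim <- simulate_panel(make_paperlike_config())
#' est <- estimate_migration(sim$panel)
#' fit <- fit_multiple(est, sim$covariates)
#' tidy(fit)
fit_multiple <- function(estimates, covariates, alpha = 0.05,
                         standardize = FALSE, variables = NULL) {
  require_columns(estimates, c("prefecture", "migration_ratio"), "estimates")
  require_columns(covariates, "prefecture", "covariates")
  variables <- variables %||% intersect(covariate_names(), names(covariates))
  if (length(variables) == 0) {
    stop_physmig("no covariate columns found", "schema")
  }
  require_columns(covariates, variables, "covariates")

  d <- dplyr::inner_join(
    as_tibble(estimates)[c("prefecture", "migration_ratio")],
    as_tibble(covariates)[c("prefecture", variables)],
    by = "prefecture"
  )
  complete <- complete.cases(d)
  if (any(!complete)) {
    warn(sprintf("dropping %d prefecture(s) with missing values: %s",
                 sum(!complete), paste(d$prefecture[!complete], collapse = ", ")))
    d <- d[complete, , drop = FALSE]
  }
  n <- nrow(d)
  if (n <= length(variables) + 1) {
    stop_physmig(sprintf(
      "need more prefectures (%d) than covariates + 1 (%d) for the joint model",
      n, length(variables) + 1
    ), "validation")
  }
  if (standardize) {
    d[variables] <- lapply(d[variables], function(v) as.numeric(scale(v)))
  }

  X <- stats::model.matrix(stats::reformulate(variables), data = d)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop_physmig(
      sprintf("design matrix is rank deficient; collinear column(s): %s",
              paste(aliased, collapse = ", ")),
      "collinearity"
    )
  }

  model <- lm(stats::reformulate(variables, "migration_ratio"), data = d)
  cf <- summary(model)$coefficients
  multiple <- tibble(
    variable = variables,
    estimate = unname(cf[variables, "Estimate"]),
    std_error = unname(cf[variables, "Std. Error"]),
    statistic = unname(cf[variables, "t value"]),
    p_value = unname(cf[variables, "Pr(>|t|)"]),
    significant = unname(cf[variables, "Pr(>|t|)"] < alpha)
  )
  simple <- purrr::map_dfr(variables, function(v) fit_simple(d, v, alpha = alpha))

  structure(
    list(simple = simple, multiple = multiple, n = n, alpha = alpha,
         standardize = standardize, variables = variables, model = model),
    class = "migration_regression"
  )
}

#' @export
print.migration_regression <- function(x, ...) {
  cat(sprintf("Association analysis over %d prefectures (alpha = %g%s)\n",
              x$n, x$alpha, if (x$standardize) ", standardized covariates" else ""))
  print(tidy(x))
  invisible(x)
}

#' Side-by-side simple/multiple regression table
#'
#' @param x A `"migration_regression"` object.
#' @param ... Unused.
#' @return A tibble `variable, simple_coef, simple_p, multiple_coef,
#'   multiple_p, significant` where `significant` refers to the adjusted
#'   (multiple) model.
#' @export
tidy.migration_regression <- function(x, ...) {
  tibble(
    variable = x$multiple$variable,
    simple_coef = x$simple$estimate,
    simple_p = x$simple$p_value,
    multiple_coef = x$multiple$estimate,
    multiple_p = x$multiple$p_value,
    significant = x$multiple$significant
  )
}

#' Model-level statistics of the joint regression
#'
#' @param x A `"migration_regression"` object.
#' @param ... Unused.
#' @return A one-row tibble with `n`, `alpha`, `r_squared`, `adj_r_squared`,
#'   `sigma`, `df_residual` and `n_significant` (covariates significant in
#'   the joint model).
#' @export
glance.migration_regression <- function(x, ...) {
  s <- summary(x$model)
  tibble(
    n = x$n,
    alpha = x$alpha,
    r_squared = s$r.squared,
    adj_r_squared = s$adj.r.squared,
    sigma = s$sigma,
    df_residual = x$model$df.residual,
    n_significant = sum(x$multiple$significant)
  )
}

#' Coefficient plot for the association analysis
#'
#' Joint-model coefficients with 95 percent confidence intervals; covariates
#' significant at `alpha` are highlighted. Native-scale coefficients are not
#' comparable across covariates unless the fit was standardized.
#'
#' @param object A `"migration_regression"` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.migration_regression <- function(object, ...) {
  m <- object$multiple
  crit <- stats::qt(0.975, object$model$df.residual)
  m$lo <- m$estimate - crit * m$std_error
  m$hi <- m$estimate + crit * m$std_error
  ggplot2::ggplot(m, ggplot2::aes(x = .data$estimate,
                                  y = stats::reorder(.data$variable, .data$estimate),
                                  colour = .data$significant)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$lo, xmax = .data$hi)) +
    ggplot2::labs(x = "Coefficient (joint model, 95% CI)", y = NULL,
                  colour = sprintf("p < %g", object$alpha)) +
    ggplot2::theme_minimal()
}
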