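#' Partition prefectures into four migration groups
#'
#' Sorts prefectures by migration ratio, strongest outflow first, and cuts
#' the ordered list into four consecutive blocks: `high_outflow`,
#' `low_outflow`, `low_inflow`, `high_inflow`. Block sizes are as even as
#' possible; when `n` is not divisible by 4 the shortfall is taken from the
#' high-outflow end (so 47 prefectures split 11/12/12/12 with the 11-member
#' block at the outflow extreme). Ties in the ratio are broken by prefecture
#' id, making the partition deterministic.
#'
#' @param estimates A `"migration_estimates"` tibble (or any data frame with
#'   `prefecture` and `migration_ratio` columns, ratios as proportions).
#' @return A tibble of class `"migration_groups"` with columns `prefecture`,
#'   `migration_ratio`, `rank` (1 = strongest outflow) and `group` (ordered
#'   factor, high_outflow > ... > high_inflow).
#' @export
#' @examples
#' est <- data.frame(prefecture = letters[1:8], migration_ratio = (8:1) / 10)
#' classify_migration(est)
classify_migration <- function(estimates) {
  require_columns(estimates, c("prefecture", "migration_ratio"), "estimates")
  if (any(is.na(estimates$migration_ratio))) {
    stop_physmig("all migration ratios must be defined for classification",
                 "validation")
  }
  n <- nrow(estimates)
  if (n < 4) {
    stop_physmig("need at least 4 prefectures to form 4 groups", "validation")
  }
  sizes <- group_sizes(n)
  ord <- order(-estimates$migration_ratio, estimates$prefecture)
  out <- tibble(
    prefecture = estimates$prefecture[ord],
    migration_ratio = estimates$migration_ratio[ord],
    rank = seq_len(n),
    group = factor(rep(group_levels(), times = sizes),
                   levels = group_levels(), ordered = TRUE)
  )
  structure(out, class = c("migration_groups", class(out)))
}

group_levels <- function() c("high_outflow", "low_outflow", "low_inflow", "high_inflow")

# Even-as-possible block sizes; any deficit is taken from the outflow extreme
# (47 -> 11, 12, 12, 12).
group_sizes <- function(n) {
  k <- n %/% 4L
  r <- n %% 4L
  rev(c(rep(k + 1L, r), rep(k, 4L - r)))
}

#' Group-level median summaries
#'
#' One row per (group, variable) with the median over group members, the
#' reporting convention of the four-group comparison table: the median of an
#' even-sized group is the midpoint of the two central order statistics
#' (R's default [stats::median()]). Variables are the migration ratio plus
#' every covariate supplied.
#'
#' @param groups A `"migration_groups"` tibble from [classify_migration()].
#' @param covariates Optional covariate tibble (see [read_covariates()]);
#'   joined by `prefecture`.
#' @return A long tibble `group, variable, median, n`.
#' @export
group_summary_table <- function(groups, covariates = NULL) {
  require_columns(groups, c("prefecture", "migration_ratio", "group"), "groups")
  data <- as_tibble(groups)[c("prefecture", "group", "migration_ratio")]
  if (!is.null(covariates)) {
    covariates <- validate_covariates(covariates)
    data <- dplyr::left_join(data, covariates, by = "prefecture")
  }
  data |>
    tidyr::pivot_longer(-c("prefecture", "group"),
                        names_to = "variable", values_to = "value") |>
    dplyr::group_by(.data$group, .data$variable) |>
    dplyr::summarise(median = median(.data$value, na.rm = TRUE),
                     n = sum(!is.na(.data$value)), .groups = "drop") |>
    dplyr::arrange(.data$group, .data$variable)
}

#' @export
print.migration_groups <- function(x, ...) {
  cat(sprintf("Four migration groups over %d prefectures (sizes %s)\n",
              nrow(x), paste(table(x$group), collapse = "/")))
  NextMethod()
}

#' Ranked migration-ratio plot coloured by group
#'
#' @param object A `"migration_groups"` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.migration_groups <- function(object, ...) {
  ggplot2::ggplot(
    object,
    ggplot2::aes(x = stats::reorder(.data$prefecture, -.data$migration_ratio),
                 y = 100 * .data$migration_ratio, fill = .data$group)
  ) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_brewer(palette = "RdBu") +
    ggplot2::labs(x = NULL, y = "Migration ratio (%)",
                  title = "Net physician migration by prefecture",
                  subtitle = "positive = outflow of locally licensed physicians") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5,
                                                       size = 6))
}

#' Ranked migration-ratio plot for raw estimates
#'
#' @param object A `"migration_estimates"` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.migration_estimates <- function(object, ...) {
  ggplot2::ggplot(
    as_tibble(object),
    ggplot2::aes(x = stats::reorder(.data$prefecture, -.data$migration_ratio),
                 y = 100 * .data$migration_ratio, fill = .data$label)
  ) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "Migration ratio (%)", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5,
                                                       size = 6))
}
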