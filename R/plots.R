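#' @import ggplot2
NULL

#' Plot the herd-environment gradient
#'
#' Ordered HEG solutions with their scaled covariate, a visual check of the
#' gradient's spread and approximate normality.
#'
#' @param object A `step1_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.step1_fit <- function(object, ...) {
  g <- object$gradient %>% arrange(.data$solution) %>%
    mutate(rank = row_number())
  ggplot(g, aes(x = .data$rank, y = .data$solution)) +
    geom_point(aes(size = .data$n_records), alpha = 0.7) +
    labs(x = "HEG level (ranked)", y = "HEG solution (trait units)",
         size = "records",
         title = "Herd-environment gradient") +
    theme_minimal()
}

#' Plot sire reaction norms
#'
#' One line per sire: EBV as a function of the scaled environment.  Crossing
#' lines are re-ranking; fanning lines are scaling-type GxE.
#'
#' @param object An `rn_fit` with GxE.
#' @param n_sires Number of sires drawn (those with the most extreme
#'   intercepts), to keep the plot readable.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rn_fit <- function(object, n_sires = 30L, ...) {
  stopifnot(object$with_gxe)
  tab <- object$sires %>%
    arrange(dplyr::desc(abs(.data$intercept))) %>%
    dplyr::slice_head(n = n_sires)
  lines <- tidyr::expand_grid(sire_id = tab$sire_id,
                              x = seq(-1, 1, length.out = 21)) %>%
    left_join(tab, by = "sire_id") %>%
    mutate(ebv = .data$intercept + .data$slope * .data$x)
  ggplot(lines, aes(x = .data$x, y = .data$ebv, group = .data$sire_id)) +
    geom_line(alpha = 0.5) +
    labs(x = "scaled environmental gradient", y = "sire EBV",
         title = "Sire reaction norms") +
    theme_minimal()
}

#' Plot the genetic-variance gradient
#'
#' ZGZ' variance and per-level sire heritability along the scaled gradient.
#'
#' @param grad_var A `gradient_variance` tibble from [zgz_gradient()].
#' @return A ggplot object.
#' @export
plot_variance_gradient <- function(grad_var) {
  ggplot(grad_var, aes(x = .data$x)) +
    geom_point(aes(y = .data$zgz), alpha = 0.7) +
    geom_line(aes(y = .data$zgz), stat = "smooth", method = "loess",
              formula = y ~ x, se = FALSE, linewidth = 0.4) +
    labs(x = "scaled environmental gradient", y = "ZGZ' genetic variance",
         title = "Genetic variance along the reaction norm") +
    theme_minimal()
}

#' Plot an EBV re-ranking comparison
#'
#' Rank in evaluation A against rank in evaluation B; points off the
#' diagonal are re-ranked sires.
#'
#' @param comparison Result of [compare_rankings()].
#' @return A ggplot object.
#' @export
plot_rank_comparison <- function(comparison) {
  ggplot(comparison$ranks, aes(x = .data$rank_a, y = .data$rank_b)) +
    geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    geom_point(alpha = 0.6) +
    labs(x = "rank (with GxE)", y = "rank (without GxE)",
         title = sprintf("EBV re-ranking (Spearman r = %.3f)",
                         comparison$spearman)) +
    theme_minimal()
}

#' Heat-map of mean ZGZ' by environmental level
#'
#' @param by_level Output of [average_by_level()] (possibly several
#'   groupings row-bound).
#' @return A ggplot object.
#' @export
plot_zgz_by_level <- function(by_level) {
  ggplot(by_level, aes(x = .data$level, y = .data$grouping,
                       fill = .data$mean_zgz)) +
    geom_tile() +
    geom_text(aes(label = signif(.data$mean_zgz, 3)), size = 3) +
    scale_fill_gradient(low = "#fee8c8", high = "#e34a33") +
    labs(x = "level", y = "environmental category", fill = "mean ZGZ'") +
    theme_minimal()
}

#' Bar chart of per-environment selection responses
#'
#' @param object A tibble from [respond_by_environment()] (columns
#'   `environment`, `trait`, `R_dsi`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_selection_response <- function(object, ...) {
  ggplot(object, aes(x = .data$trait, y = .data$R_dsi,
                     fill = .data$environment)) +
    geom_col(position = "dodge") +
    labs(x = "trait", y = "standardized response per generation",
         title = "Selection response by environment") +
    theme_minimal()
}
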