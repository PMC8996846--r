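#' Genetic variance along the reaction norm (ZGZ')
#'
#' For each herd-environmental-group level at scaled environment `x`, the
#' genetic (sire) variance is the quadratic form `z' G0 z` with
#' z = (P0(x), P1(x)) = (1, x), i.e.
#' `s2_G + 2 x cov(G, GxE) + x^2 s2_GxE`.  The per-level sire heritability
#' uses the residual variance of the level's quantile class:
#' `h2 = 4 zgz / (zgz + [s2_Pe] + [s2_htd|hyc] + s2_e(class))`.
#'
#' @param fit An `rn_fit` with GxE, or a 2x2 `G0` matrix (then `gradient`,
#'   and optionally the other components, must be given explicitly).
#' @param gradient Tibble with `heg_level` and `scaled_x`; defaults to the
#'   fit's gradient.
#' @param sigma2_pe,sigma2_cg Permanent-environment and contemporary-group
#'   variances entering the per-level phenotypic variance (defaulted from
#'   the fit).
#' @param sigma2_e_classes Residual variances per class (defaulted from the
#'   fit); levels are mapped to classes by the quantiles of `scaled_x`.
#' @return A tibble of class `gradient_variance`: `heg_level`, `x`, `zgz`,
#'   `resid_class`, `sigma2_e`, `h2_sire`.
#' @export
zgz_gradient <- function(fit, gradient = NULL, sigma2_pe = NULL,
                         sigma2_cg = NULL, sigma2_e_classes = NULL) {
  if (inherits(fit, "rn_fit")) {
    stopifnot(fit$with_gxe)
    G0 <- fit$G0
    gradient <- gradient %||% fit$gradient
    s <- fit$samples
    sigma2_pe <- sigma2_pe %||%
      (if ("sigma2_pe" %in% names(s)) mean(s$sigma2_pe) else 0)
    sigma2_cg <- sigma2_cg %||%
      mean(s[[if (fit$dataset_kind == "MT") "sigma2_htd" else "sigma2_hyc"]])
    sigma2_e_classes <- sigma2_e_classes %||%
      colMeans(s[grep("^sigma2_e[0-9]+$", names(s))])
  } else {
    G0 <- fit
    stopifnot(is.matrix(G0), all(dim(G0) == 2), !is.null(gradient))
    sigma2_pe <- sigma2_pe %||% 0
    sigma2_cg <- sigma2_cg %||% 0
    sigma2_e_classes <- sigma2_e_classes %||% 0
  }
  ev <- eigen((G0 + t(G0)) / 2, symmetric = TRUE, only.values = TRUE)$values
  x <- gradient$scaled_x
  zgz <- G0[1, 1] + 2 * x * G0[1, 2] + x^2 * G0[2, 2]
  clamped <- zgz < 0
  if (min(ev) < -1e-10 || any(clamped)) {
    warning("G0 is not positive semidefinite; ", sum(clamped),
            " negative ZGZ' value(s) clamped to 0", call. = FALSE)
    zgz <- pmax(zgz, 0)
  }
  cls <- residual_classes(x, length(sigma2_e_classes))
  s2e <- sigma2_e_classes[cls]
  out <- tibble(heg_level = gradient$heg_level, x = x, zgz = zgz,
                resid_class = cls, sigma2_e = s2e,
                h2_sire = 4 * zgz / (zgz + sigma2_pe + sigma2_cg + s2e))
  class(out) <- c("gradient_variance", class(out))
  out
}

# map each HEG level to its herd's level of an EC grouping (or the EG)
heg_grouping <- function(grad_var, env_assignment, grouping) {
  grouping <- match.arg(grouping, c("area", "housing", "feeding", "pasture", "EG"))
  env <- as_tibble(env_assignment)
  key <- if (grouping == "EG") "eg_label" else grouping
  stopifnot(key %in% names(env))
  lv <- tibble(heg_level = grad_var$heg_level,
               herd_id = sub("\\..*$", "", grad_var$heg_level))
  joined <- left_join(lv, select(env, "herd_id", level = all_of(key)),
                      by = "herd_id")
  if (anyNA(joined$level)) {
    stop("HEG level(s) without an environment assignment: ",
         paste(joined$heg_level[is.na(joined$level)], collapse = ", "),
         call. = FALSE)
  }
  joined
}

#' Average ZGZ' variance within environmental levels
#'
#' The genetic variance attributed to a level of an environmental category
#' (or to an environmental group) is the arithmetic mean of the ZGZ'
#' estimates of all HEG levels belonging to herds with that level.
#'
#' @param grad_var A `gradient_variance` tibble from [zgz_gradient()].
#' @param env_assignment Herd-environment tibble (`herd_id`, EC columns,
#'   `eg_label`).
#' @param grouping One of `"area"`, `"housing"`, `"feeding"`, `"pasture"`,
#'   `"EG"`.
#' @return Tibble: `grouping`, `level`, `n_heg`, `mean_zgz`, `mean_h2`.
#'   Grouping levels with no HEG level are absent (reported missing).
#' @export
average_by_level <- function(grad_var, env_assignment, grouping = "area") {
  map <- heg_grouping(grad_var, env_assignment, grouping)
  grad_var %>%
    left_join(map, by = "heg_level") %>%
    group_by(level = .data$level) %>%
    summarise(n_heg = n(), mean_zgz = mean(.data$zgz),
              mean_h2 = mean(.data$h2_sire), .groups = "drop") %>%
    mutate(grouping = grouping, .before = 1)
}

#' Trimmed least-square-means contrasts of ZGZ' across levels
#'
#' Linear-reaction-norm variances are quadratic in `x`, so extreme gradient
#' levels produce extreme ZGZ' values; estimates outside mean +/- 2 SD
#' (computed over all HEG levels of the trait) are discarded before a
#' one-way fixed-effects linear model of ZGZ' on the grouping level.
#' Returns the least-square means, the overall F test, and all pairwise
#' level contrasts with two-tailed p-values (unadjusted by default).
#'
#' @inheritParams average_by_level
#' @param adjust Multiplicity adjustment for the pairwise contrasts:
#'   `"none"` (default) or `"tukey"`.
#' @return List: `lsm` (tibble `level`, `n`, `lsmean`, `se`), `anova`
#'   (tibble `F`, `df1`, `df2`, `p`), `pairwise` (tibble of contrasts),
#'   `n_trimmed`, `trim_window` (`c(lower, upper)`).
#' @export
trim_and_test <- function(grad_var, env_assignment, grouping = "area",
                          adjust = c("none", "tukey")) {
  adjust <- match.arg(adjust)
  map <- heg_grouping(grad_var, env_assignment, grouping)
  dat <- grad_var %>% left_join(map, by = "heg_level")
  m <- mean(dat$zgz); s <- stats::sd(dat$zgz)
  window <- c(m - 2 * s, m + 2 * s)
  trimmed <- filter(dat, .data$zgz >= window[1], .data$zgz <= window[2])
  n_trimmed <- nrow(dat) - nrow(trimmed)
  counts <- count(trimmed, .data$level)
  if (sum(counts$n >= 2) < 2L || dplyr::n_distinct(trimmed$level) < 2L) {
    warning("fewer than 2 levels with >= 2 retained estimates; test skipped",
            call. = FALSE)
    return(list(lsm = trimmed %>% group_by(level = .data$level) %>%
                  summarise(n = n(), lsmean = mean(.data$zgz),
                            se = stats::sd(.data$zgz) / sqrt(n()), .groups = "drop"),
                anova = NULL, pairwise = NULL,
                n_trimmed = n_trimmed, trim_window = window))
  }
  trimmed$level <- factor(trimmed$level)
  lmfit <- stats::lm(zgz ~ level, data = trimmed)
  an <- stats::anova(lmfit)
  em <- emmeans::emmeans(lmfit, "level")
  lsm <- as.data.frame(em) %>%
    as_tibble() %>%
    select(level = "level", lsmean = "emmean", se = "SE") %>%
    left_join(counts, by = "level") %>%
    select("level", "n", "lsmean", "se")
  pw <- as.data.frame(emmeans::contrast(em, "pairwise", adjust = adjust)) %>%
    as_tibble() %>%
    select(contrast = "contrast", estimate = "estimate", se = "SE",
           p = "p.value")
  list(lsm = lsm,
       anova = tibble(F = an$`F value`[1], df1 = an$Df[1], df2 = an$Df[2],
                      p = an$`Pr(>F)`[1]),
       pairwise = pw, n_trimmed = n_trimmed, trim_window = window)
}
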