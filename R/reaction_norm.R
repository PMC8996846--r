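#' Step 1: estimate the herd-environment gradient
#'
#' Fits the repeatability animal model
#' `y = HEG + fixed classes + htd + a + Pe + e` (test-day traits, `"MT"`) or
#' the single-record model `y = HEG + fixed classes + hyc + a + e`
#' (`"FS"`), and returns the fixed herd-environmental-group (HEG) solutions,
#' min-max scaled to \[-1, 1\], as a continuous environmental gradient: good
#' herds get high solutions, poor herds low ones.  Also reports the step-1
#' variance components, the animal-model heritability
#' `h2 = s2_a / (s2_htd|hyc + [s2_Pe] + s2_a + s2_e)`, and normality
#' diagnostics (skewness, kurtosis, Shapiro-Wilk p) of the solutions.
#'
#' @param data Edited phenotype tibble with columns `value` (or
#'   `model$response`), `heg_level`, `htd` (MT) or `hyc` (FS), `animal_id`
#'   and any fixed class columns.
#' @param ped Pedigree data frame covering all `animal_id`s.
#' @param dataset_kind `"MT"` or `"FS"`.
#' @param fixed_class Extra fixed class columns beyond `heg_level`.
#' @param config A [gibbs_config()].
#' @return A `step1_fit`: `gradient` (tibble `heg_level`, `solution`,
#'   `scaled_x`, `n_records`), `components`, `h2`, `h2_se`, `normality`,
#'   `fit` (the underlying `gibbs_fit`).
#' @export
fit_step1 <- function(data, ped, dataset_kind = c("MT", "FS"),
                      fixed_class = intersect("parity_class", names(data)),
                      config = gibbs_config()) {
  dataset_kind <- match.arg(dataset_kind)
  cg_col <- if (dataset_kind == "MT") "htd" else "hyc"
  stopifnot(all(c("heg_level", cg_col, "animal_id") %in% names(data)))

  rand <- list(rand_term(cg_col, structure = "iid"),
               rand_term("animal", column = "animal_id", structure = "pedigree"))
  if (dataset_kind == "MT") {
    rand <- c(rand, list(rand_term("pe", column = "animal_id", structure = "iid")))
  }
  model <- model_spec(response = "value",
                      fixed_class = c("heg_level", fixed_class),
                      random = rand, residual_classes = 1L)
  ainv <- a_inverse(ped)
  fit <- gibbs_sample(model, data, structures = list(animal = ainv),
                      config = config)

  sol <- fit$solutions %>% filter(.data$term == "heg_level")
  heg_levels <- sort(unique(as.character(data$heg_level)))
  gradient <- tibble(heg_level = heg_levels) %>%
    left_join(sol %>% select(level = "level", solution = "estimate"),
              by = c(heg_level = "level")) %>%
    mutate(solution = if_else(is.na(.data$solution), 0, .data$solution))
  if (nrow(gradient) > 1L) {
    gradient$scaled_x <- scale_covariate(gradient$solution)
  } else {
    gradient$scaled_x <- 0
  }
  gradient <- gradient %>%
    left_join(count(data, .data$heg_level, name = "n_records"), by = "heg_level")

  comp <- posterior_summary(fit)
  s <- fit$samples
  h2_chain <- s$sigma2_animal /
    (s[[paste0("sigma2_", cg_col)]] +
       (if (dataset_kind == "MT") s$sigma2_pe else 0) +
       s$sigma2_animal + s$sigma2_e1)
  norm_p <- tryCatch(stats::shapiro.test(gradient$solution)$p.value,
                     error = function(e) NA_real_)
  structure(list(gradient = gradient, components = comp,
                 h2 = mean(h2_chain), h2_se = stats::sd(h2_chain),
                 normality = tibble(skewness = skewness(gradient$solution),
                                    kurtosis = kurtosis(gradient$solution),
                                    shapiro_p = norm_p),
                 dataset_kind = dataset_kind, fit = fit),
            class = "step1_fit")
}

#' Animal-model heritability from variance components
#'
#' `h2 = s2_a / (s2_cg + s2_pe + s2_a + s2_e)` where `s2_cg` is the
#' contemporary-group (herd-test-day or herd-year-classifier) variance and
#' the permanent-environment term enters only for repeated-record traits.
#'
#' @param sigma2_a,sigma2_cg,sigma2_e Variances; `sigma2_pe` defaults to 0.
#' @param sigma2_pe Permanent-environment variance.
#' @return Heritability (vectorized over chains).
#' @export
animal_h2 <- function(sigma2_a, sigma2_cg, sigma2_e, sigma2_pe = 0) {
  sigma2_a / (sigma2_cg + sigma2_pe + sigma2_a + sigma2_e)
}

#' Step 2: fit the reaction-norm sire model
#'
#' Replaces the fixed HEG class effect by a fixed linear (Legendre order
#' 0/1) regression on the scaled gradient, and fits per-sire random
#' reaction norms: with `with_gxe = TRUE`, a correlated (intercept, slope)
#' pair per sire with unstructured 2x2 covariance `G0`; otherwise an
#' intercept-only sire effect.  Residual variance is heterogeneous across
#' five classes defined by the quantiles of each record's herd gradient
#' solution.  The sire term is relationship-structured through the pedigree
#' by default (`sire_structure = "pedigree"`).
#'
#' @param data Edited phenotype tibble (`value`, `heg_level`, `htd`/`hyc`,
#'   `sire_id`, `animal_id`, class columns).
#' @param gradient Gradient tibble from [fit_step1()] (`heg_level`,
#'   `scaled_x`).
#' @param ped Pedigree (used to relate sires); ignored for
#'   `sire_structure = "iid"`.
#' @param with_gxe Fit the random slope (GxE) term?
#' @param dataset_kind `"MT"` (keeps the permanent-environment term) or
#'   `"FS"`.
#' @param fixed_class Extra fixed class columns.
#' @param sire_structure `"pedigree"` or `"iid"`.
#' @param n_residual_classes Number of residual classes (default 5).
#' @param config A [gibbs_config()].
#' @return An `rn_fit`: `components` (posterior summary), `G0` (posterior
#'   mean 2x2, `with_gxe` only), `sires` (tibble of intercept/slope posterior
#'   means and SDs), `samples` (variance chains), `gradient`, `with_gxe`,
#'   `sigma2_e_mean` (average of the residual classes), `fit`.
#' @export
fit_reaction_norm <- function(data, gradient, ped = NULL, with_gxe = TRUE,
                              dataset_kind = c("MT", "FS"),
                              fixed_class = intersect("parity_class", names(data)),
                              sire_structure = c("pedigree", "iid"),
                              n_residual_classes = 5L,
                              config = gibbs_config()) {
  dataset_kind <- match.arg(dataset_kind)
  sire_structure <- match.arg(sire_structure)
  cg_col <- if (dataset_kind == "MT") "htd" else "hyc"
  stopifnot(all(c("heg_level", cg_col, "sire_id") %in% names(data)))

  no_sire <- is.na(data$sire_id) | data$sire_id %in% c("0", "")
  if (any(no_sire)) {
    warning(sum(no_sire), " records without a sire dropped", call. = FALSE)
    data <- data[!no_sire, ]
  }
  data <- data %>%
    inner_join(select(gradient, "heg_level", "scaled_x"), by = "heg_level")
  data$.rclass <- residual_classes(data$scaled_x, n_residual_classes)
  k_eff <- max(data$.rclass)

  structures <- list()
  if (sire_structure == "pedigree") {
    stopifnot(!is.null(ped))
    structures$sire <- sire_relationship_inverse(ped, unique(data$sire_id))
  }
  rand <- list(rand_term(cg_col, structure = "iid"))
  if (dataset_kind == "MT") {
    rand <- c(rand, list(rand_term("pe", column = "animal_id", structure = "iid")))
  }
  rand <- c(rand, list(
    if (with_gxe) {
      rand_term("sire", column = "sire_id", structure = sire_structure,
                order = 1L, covariate = "scaled_x")
    } else {
      rand_term("sire", column = "sire_id", structure = sire_structure)
    }
  ))
  model <- model_spec(response = "value", fixed_class = fixed_class,
                      fixed_covariates = list(scaled_x = 1L),
                      random = rand,
                      residual_classes = k_eff,
                      residual_class_column = ".rclass")
  fit <- gibbs_sample(model, data, structures = structures, config = config)

  s <- fit$samples
  e_cols <- grep("^sigma2_e", names(s), value = TRUE)
  s$sigma2_e_mean <- rowMeans(s[e_cols])

  sire_ids <- sort(unique(as.character(data$sire_id)))
  sol <- fit$solutions
  if (with_gxe) {
    ints <- sol %>% filter(.data$term == "sire",
                           startsWith(.data$level, "P0:"))
    slps <- sol %>% filter(.data$term == "sire",
                           startsWith(.data$level, "P1:"))
    sires <- tibble(sire_id = sub("^P0:", "", ints$level),
                    intercept = ints$estimate, intercept_sd = ints$posterior_sd,
                    slope = slps$estimate, slope_sd = slps$posterior_sd)
    G0 <- matrix(c(mean(s$sire_sigma2_int), mean(s$sire_sigma_int_slope),
                   mean(s$sire_sigma_int_slope), mean(s$sire_sigma2_slope)), 2, 2,
                 dimnames = list(c("intercept", "slope"), c("intercept", "slope")))
  } else {
    ints <- sol %>% filter(.data$term == "sire")
    sires <- tibble(sire_id = ints$level,
                    intercept = ints$estimate, intercept_sd = ints$posterior_sd)
    G0 <- NULL
  }
  sires <- filter(sires, .data$sire_id %in% sire_ids)

  structure(list(components = posterior_summary(s), G0 = G0, sires = sires,
                 samples = s, gradient = gradient, with_gxe = with_gxe,
                 dataset_kind = dataset_kind,
                 sigma2_e_mean = mean(s$sigma2_e_mean),
                 n_residual_classes = k_eff, fit = fit),
            class = "rn_fit")
}

# dense inverse of the sire-block relationship matrix: A over the sires (and
# whatever ancestors connect them) computed by the tabular method on the
# ancestor-closure of the sires, then the sire block inverted
sire_relationship_inverse <- function(ped, sire_ids) {
  px <- ped_index(ped)
  keep <- match(as.character(sire_ids), px$id)
  if (anyNA(keep)) {
    stop("sire(s) not in pedigree: ",
         paste(sire_ids[is.na(keep)], collapse = ", "), call. = FALSE)
  }
  # ancestor closure
  closure <- integer(0)
  frontier <- keep
  while (length(frontier)) {
    closure <- union(closure, frontier)
    par <- unique(c(px$sire[frontier], px$dam[frontier]))
    frontier <- setdiff(par[!is.na(par)], closure)
  }
  sub <- tibble(animal_id = px$id[closure],
                sire_id = ifelse(is.na(px$sire[closure]) |
                                   !(px$sire[closure] %in% closure),
                                 "0", px$id[px$sire[closure]]),
                dam_id = ifelse(is.na(px$dam[closure]) |
                                  !(px$dam[closure] %in% closure),
                                "0", px$id[px$dam[closure]]))
  A <- a_tabular(sub)
  Ass <- A[as.character(sire_ids), as.character(sire_ids)]
  Ainv <- solve(Ass)
  Ainv[abs(Ainv) < 1e-12] <- 0
  methods::as(methods::as(Matrix::Matrix(Ainv, sparse = TRUE), "generalMatrix"),
              "CsparseMatrix")
}

#' Variance ratios of the reaction-norm fit
#'
#' Phenotypic variance is composed as
#' `s2_P = s2_htd|hyc (+ s2_Pe) + s2_G + s2_GxE + 2*cov(G,GxE) + mean s2_e`,
#' and the genetic, GxE and covariance fractions are reported as posterior
#' summaries of the chain-wise ratios.
#'
#' @param fit An `rn_fit` with `with_gxe = TRUE`.
#' @return Tibble (one row per quantity: `sigma2_P`, `G_over_P`,
#'   `GxE_over_P`, `covGxE_over_P`, `h2_sire`) with posterior mean, SE, z, p.
#' @export
variance_ratios <- function(fit) {
  stopifnot(inherits(fit, "rn_fit"))
  if (!fit$with_gxe) stop("variance_ratios() needs a with-GxE fit", call. = FALSE)
  s <- fit$samples
  p_chain <- sigma2_p_chain(fit)
  if (mean(p_chain) <= 0) stop("non-positive phenotypic variance", call. = FALSE)
  chains <- tibble(
    sigma2_P = p_chain,
    G_over_P = s$sire_sigma2_int / p_chain,
    GxE_over_P = s$sire_sigma2_slope / p_chain,
    covGxE_over_P = s$sire_sigma_int_slope / p_chain,
    h2_sire = 4 * s$sire_sigma2_int / p_chain
  )
  posterior_summary(chains)
}

# chain of sigma2_P per the with/without-GxE composition
sigma2_p_chain <- function(fit) {
  s <- fit$samples
  base <- s[[if (fit$dataset_kind == "MT") "sigma2_htd" else "sigma2_hyc"]] +
    (if ("sigma2_pe" %in% names(s)) s$sigma2_pe else 0) + s$sigma2_e_mean
  if (fit$with_gxe) {
    base + s$sire_sigma2_int + s$sire_sigma2_slope + 2 * s$sire_sigma_int_slope
  } else {
    base + s$sigma2_sire
  }
}

#' Sire-model heritability
#'
#' `h2_sire = 4 * s2_G / s2_P`, where `s2_G` is the sire (intercept)
#' variance and `s2_P` follows the with/without-GxE composition of
#' [variance_ratios()].
#'
#' @param fit An `rn_fit`.
#' @return Tibble with posterior mean, SE, z, p of the heritability chain.
#' @export
sire_h2 <- function(fit) {
  stopifnot(inherits(fit, "rn_fit"))
  s <- fit$samples
  g <- if (fit$with_gxe) s$sire_sigma2_int else s$sigma2_sire
  posterior_summary(tibble(h2_sire = 4 * g / sigma2_p_chain(fit)))
}

#' Estimated breeding value along the environmental gradient
#'
#' The sire EBV at environment `x` is `intercept + slope * x` (the order-1
#' Legendre basis is `x` itself); an intercept-only fit returns the
#' intercept for every `x`.
#'
#' @param fit An `rn_fit`.
#' @param sires Sire ids (default: all fitted sires).
#' @param x Environments on the scaled gradient, each in \[-1, 1\].
#' @return Tibble: `sire_id`, `x`, `ebv`.
#' @export
ebv_at_environment <- function(fit, sires = NULL, x = 0) {
  stopifnot(inherits(fit, "rn_fit"), all(abs(x) <= 1 + 1e-8))
  tab <- fit$sires
  if (!is.null(sires)) {
    idx <- match(as.character(sires), tab$sire_id)
    if (anyNA(idx)) stop("unknown sire: ",
                         paste(sires[is.na(idx)], collapse = ", "), call. = FALSE)
    tab <- tab[idx, ]
  }
  tidyr::expand_grid(sire_id = tab$sire_id, x = x) %>%
    left_join(tab, by = "sire_id") %>%
    mutate(ebv = .data$intercept +
             (if (fit$with_gxe) .data$slope * .data$x else 0)) %>%
    select("sire_id", "x", "ebv")
}

#' EBV accuracy
#'
#' `acc = sqrt(1 - PEV / s2_G)`.  By default the prediction-error variance
#' (PEV) of a sire is the posterior variance of its intercept solution, the
#' standard Bayesian PEV; `method = "literal"` instead squares the EBV
#' itself, a published shortcut that ties accuracy to EBV magnitude and can
#' leave the square root undefined (such sires are clamped to 0 and
#' flagged).
#'
#' @param fit An `rn_fit`.
#' @param sires Sire ids (default all).
#' @param method `"posterior"` (default) or `"literal"`.
#' @return Tibble: `sire_id`, `pev`, `accuracy`, `clamped`.
#' @export
ebv_accuracy <- function(fit, sires = NULL, method = c("posterior", "literal")) {
  stopifnot(inherits(fit, "rn_fit"))
  method <- match.arg(method)
  s2g <- if (fit$with_gxe) mean(fit$samples$sire_sigma2_int) else
    mean(fit$samples$sigma2_sire)
  if (s2g <= 0) stop("sire variance is zero; accuracy undefined", call. = FALSE)
  tab <- fit$sires
  if (!is.null(sires)) tab <- tab[match(as.character(sires), tab$sire_id), ]
  pev <- if (method == "posterior") tab$intercept_sd^2 else tab$intercept^2
  ratio <- 1 - pev / s2g
  tibble(sire_id = tab$sire_id, pev = pev,
         accuracy = sqrt(pmax(ratio, 0)),
         clamped = ratio < 0)
}

#' Compare two EBV rankings
#'
#' Spearman rank correlation over the common sires, plus top-k overlap
#' (which sires enter/leave the elite group between the two evaluations)
#' and a per-sire rank-change table.  Ranks are assigned with the best EBV
#' first.
#'
#' @param ebvs_a,ebvs_b Tibbles with `sire_id` and `ebv` columns (e.g. from
#'   [ebv_at_environment()]).
#' @param top_k Size of the elite group examined for re-ranking (default 20).
#' @return List: `spearman`, `top_k`, `top_overlap`, `entered`, `left`,
#'   `ranks` (tibble `sire_id`, `rank_a`, `rank_b`, `rank_change`).
#' @export
compare_rankings <- function(ebvs_a, ebvs_b, top_k = 20L) {
  a <- ebvs_a %>% select("sire_id", ebv_a = "ebv")
  b <- ebvs_b %>% select("sire_id", ebv_b = "ebv")
  common <- inner_join(a, b, by = "sire_id")
  if (nrow(common) == 0L) stop("no common sires between the two EBV sets",
                               call. = FALSE)
  rho <- stats::cor(common$ebv_a, common$ebv_b, method = "spearman")
  ranks <- common %>%
    mutate(rank_a = rank(-.data$ebv_a, ties.method = "average"),
           rank_b = rank(-.data$ebv_b, ties.method = "average"),
           rank_change = .data$rank_b - .data$rank_a) %>%
    select("sire_id", "rank_a", "rank_b", "rank_change")
  top_k <- min(top_k, nrow(common))
  top_a <- ranks$sire_id[order(ranks$rank_a)][seq_len(top_k)]
  top_b <- ranks$sire_id[order(ranks$rank_b)][seq_len(top_k)]
  list(spearman = rho, top_k = top_k,
       top_overlap = length(intersect(top_a, top_b)),
       entered = setdiff(top_b, top_a), left = setdiff(top_a, top_b),
       ranks = ranks)
}

#' @export
tidy.rn_fit <- function(x, ...) x$components

#' @export
glance.rn_fit <- function(x, ...) {
  tibble(with_gxe = x$with_gxe, n_sires = nrow(x$sires),
         n_retained = x$fit$n_retained,
         sigma2_e_mean = x$sigma2_e_mean,
         sigma2_P = mean(sigma2_p_chain(x)),
         h2_sire = sire_h2(x)$mean)
}

#' @export
tidy.step1_fit <- function(x, ...) x$components

#' @export
glance.step1_fit <- function(x, ...) {
  tibble(dataset_kind = x$dataset_kind, n_heg = nrow(x$gradient),
         h2 = x$h2, h2_se = x$h2_se,
         shapiro_p = x$normality$shapiro_p)
}

#' @export
print.step1_fit <- function(x, ...) {
  cat("Step-1 herd-environment gradient (", nrow(x$gradient), " HEG levels), ",
      "animal h2 = ", round(x$h2, 3), " (SE ", round(x$h2_se, 3), ")\n", sep = "")
  invisible(x)
}

#' @export
print.rn_fit <- function(x, ...) {
  cat("Reaction-norm sire model (",
      if (x$with_gxe) "with" else "without", " GxE), ",
      nrow(x$sires), " sires, ", x$n_residual_classes,
      " residual classes\n", sep = "")
  if (x$with_gxe) {
    cat("G0 (intercept, slope):\n")
    print(round(x$G0, 4))
  }
  invisible(x)
}
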