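#' @useDynLib rngxe, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Declare a random term of a mixed model
#'
#' @param name Term label (also the data column holding the level of each
#'   record, unless `column` differs).
#' @param column Data column with the level identifier; defaults to `name`.
#' @param structure `"iid"` (independent levels) or `"pedigree"` (levels
#'   correlated through a relationship-matrix inverse supplied to
#'   [gibbs_sample()]).
#' @param order `NULL` for a plain scalar effect, or `1` for a linear random
#'   regression (Legendre intercept + slope) on `covariate`.
#' @param covariate Data column with the scaled covariate in \[-1, 1\]
#'   (random-regression terms only).
#' @return A `rand_term` list.
#' @export
rand_term <- function(name, column = name, structure = c("iid", "pedigree"),
                      order = NULL, covariate = NULL) {
  structure <- match.arg(structure)
  if (!is.null(order)) {
    stopifnot(order == 1L, !is.null(covariate))
  }
  base::structure(list(name = name, column = column, structure = structure,
                       order = order, covariate = covariate),
                  class = "rand_term")
}

#' Specify a Gaussian mixed model
#'
#' @param response Column holding the trait value.
#' @param fixed_class Character vector of fixed class-effect columns (fitted
#'   with a first-level-zero reference constraint; an intercept is always
#'   included).
#' @param fixed_covariates Named list `column = order` of fixed Legendre
#'   regressions on scaled covariates (order-0 terms are absorbed by the
#'   intercept).
#' @param random List of [rand_term()] objects.
#' @param residual_classes Number of heterogeneous residual classes (1 =
#'   homogeneous).
#' @param residual_class_column Data column with the per-record class index
#'   (required when `residual_classes > 1`).
#' @return A `model_spec` list.
#' @export
model_spec <- function(response, fixed_class = character(),
                       fixed_covariates = list(), random = list(),
                       residual_classes = 1L, residual_class_column = NULL) {
  if (inherits(random, "rand_term")) random <- list(random)
  stopifnot(residual_classes >= 1L)
  if (residual_classes > 1L && is.null(residual_class_column)) {
    stop("residual_class_column required when residual_classes > 1", call. = FALSE)
  }
  structure(list(response = response, fixed_class = fixed_class,
                 fixed_covariates = fixed_covariates, random = random,
                 residual_classes = as.integer(residual_classes),
                 residual_class_column = residual_class_column),
            class = "model_spec")
}

#' Gibbs sampler run configuration
#'
#' Chain bookkeeping follows the usual burn-in/thinning convention: the
#' retained sample count is `floor((n_iter - burn_in) / thin)`, e.g. 220,000
#' iterations with 20,000 burn-in and thinning 100 retain exactly 2,000
#' samples.
#'
#' @param n_iter Total iterations.
#' @param burn_in Iterations discarded (must be `< n_iter`).
#' @param thin Keep every `thin`-th post-burn-in draw.
#' @param seed Integer seed.
#' @param prior_df,prior_scale Scaled-inverse-chi-square prior for scalar
#'   variances; the default `df = -2, scale = 0` is flat on the variance.
#' @param prior_df_G,prior_V_G Inverse-Wishart prior for the 2x2
#'   random-regression covariance.  The default `df = -3, scale = 0` is flat
#'   on G0 (the matrix analogue of the flat scalar-variance prior): an
#'   inverse Wishart with small positive df and near-zero scale is
#'   proportional to a negative power of det(G0) and pulls the posterior
#'   toward singular matrices, which visibly biases slope variances when
#'   per-level slope information is modest.
#' @return A `gibbs_config` list with a `n_retained` field.
#' @export
gibbs_config <- function(n_iter = 20000L, burn_in = 4000L, thin = 10L,
                         seed = 1L, prior_df = -2, prior_scale = 0,
                         prior_df_G = -3, prior_V_G = matrix(0, 2, 2)) {
  n_iter <- as.integer(n_iter); burn_in <- as.integer(burn_in)
  thin <- as.integer(thin)
  stopifnot(burn_in >= 0L, burn_in < n_iter, thin >= 1L)
  structure(list(n_iter = n_iter, burn_in = burn_in, thin = thin,
                 seed = as.integer(seed), prior_df = prior_df,
                 prior_scale = prior_scale, prior_df_G = prior_df_G,
                 prior_V_G = prior_V_G,
                 n_retained = (n_iter - burn_in) %/% thin),
            class = "gibbs_config")
}

# sparse indicator matrix for a factor (all levels)
indicator <- function(f) {
  if (!is.factor(f)) f <- factor(f)
  Matrix::sparseMatrix(i = seq_along(f), j = as.integer(f), x = 1,
                       dims = c(length(f), nlevels(f)),
                       dimnames = list(NULL, levels(f)))
}

# builds the full design and block metadata for the C++ sampler
build_design <- function(model, data, structures = list()) {
  stopifnot(inherits(model, "model_spec"), is.data.frame(data))
  n <- nrow(data)
  mats <- list(Matrix::sparseMatrix(i = seq_len(n), j = rep(1L, n), x = 1,
                                    dims = c(n, 1L),
                                    dimnames = list(NULL, "(Intercept)")))
  meta <- list(tibble(term = "(Intercept)", type = "fixed", level = ""))

  for (tm in model$fixed_class) {
    f <- factor(data[[tm]])
    if (nlevels(f) > 1L) {
      Z <- indicator(f)[, -1L, drop = FALSE]  # reference = first level
      colnames(Z) <- paste0(tm, ":", levels(f)[-1L])
      mats[[length(mats) + 1L]] <- Z
      meta[[length(meta) + 1L]] <-
        tibble(term = tm, type = "fixed", level = levels(f)[-1L])
    }
  }
  for (cv in names(model$fixed_covariates)) {
    ord <- model$fixed_covariates[[cv]]
    P <- legendre_basis(data[[cv]], ord)[, -1L, drop = FALSE]
    colnames(P) <- paste0(cv, ":", colnames(P))
    mats[[length(mats) + 1L]] <- methods::as(P, "CsparseMatrix")
    meta[[length(meta) + 1L]] <-
      tibble(term = cv, type = "fixed", level = paste0("P", seq_len(ord)))
  }
  n_fixed <- sum(vapply(mats, ncol, 0L))

  blocks <- list(list(kind = 0L, start = 0L, q = n_fixed, nb = 1L))
  for (rt in model$random) {
    lev_ids <- NULL
    if (rt$structure == "pedigree") {
      K <- structures[[rt$name]]
      if (is.null(K)) stop("no relationship inverse supplied for pedigree term '",
                           rt$name, "'", call. = FALSE)
      lev_ids <- rownames(K)
    }
    f <- if (is.null(lev_ids)) factor(data[[rt$column]]) else
      factor(data[[rt$column]], levels = lev_ids)
    if (anyNA(f)) stop("levels of '", rt$column, "' missing from the ",
                       "relationship inverse", call. = FALSE)
    Z0 <- indicator(f)
    start <- sum(vapply(mats, ncol, 0L))
    if (is.null(rt$order)) {
      colnames(Z0) <- paste0(rt$name, ":", levels(f))
      mats[[length(mats) + 1L]] <- Z0
      meta[[length(meta) + 1L]] <-
        tibble(term = rt$name, type = rt$structure, level = levels(f))
      blocks[[length(blocks) + 1L]] <-
        list(kind = if (rt$structure == "pedigree") 2L else 1L,
             start = start, q = nlevels(f), nb = 1L,
             K = if (rt$structure == "pedigree") structures[[rt$name]] else NULL,
             term = rt$name)
    } else {
      x <- data[[rt$covariate]]
      Z1 <- Z0 * x
      colnames(Z0) <- paste0(rt$name, ":P0:", levels(f))
      colnames(Z1) <- paste0(rt$name, ":P1:", levels(f))
      mats[[length(mats) + 1L]] <- Z0
      mats[[length(mats) + 1L]] <- Z1
      meta[[length(meta) + 1L]] <-
        tibble(term = rt$name, type = paste0("rr_", rt$structure),
               level = c(paste0("P0:", levels(f)), paste0("P1:", levels(f))))
      blocks[[length(blocks) + 1L]] <-
        list(kind = 3L, start = start, q = nlevels(f), nb = 2L,
             K = if (rt$structure == "pedigree") structures[[rt$name]] else NULL,
             term = rt$name, levels = levels(f))
    }
  }
  W <- do.call(cbind, mats)
  list(W = methods::as(W, "CsparseMatrix"),
       meta = bind_rows(meta), blocks = blocks, n_fixed = n_fixed)
}

# error if the fixed block is rank deficient, naming near-null columns
check_fixed_rank <- function(W, n_fixed) {
  if (n_fixed > 2000L) return(invisible(TRUE)) # skip the dense check at scale
  Xf <- W[, seq_len(n_fixed), drop = FALSE]
  C <- as.matrix(Matrix::crossprod(Xf))
  qr_c <- qr(C)
  if (qr_c$rank < n_fixed) {
    bad <- colnames(Xf)[qr_c$pivot[(qr_c$rank + 1L):n_fixed]]
    stop("fixed effects are rank deficient; confounded column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Fit a Gaussian mixed model by Gibbs sampling
#'
#' Conjugate single-site Gibbs sampler: location parameters are drawn
#' equation-by-equation from their normal full conditionals, scalar variances
#' from scaled inverse chi-square full conditionals, the 2x2
#' random-regression covariance from an inverse Wishart, and each residual
#' class variance from its own scaled inverse chi-square.  Fixed effects are
#' identified by first-level-zero reference constraints, so class solutions
#' are contrasts against the reference level.
#'
#' @param model A [model_spec()].
#' @param data Data frame of records.
#' @param structures Named list of relationship-matrix inverses (from
#'   [a_inverse()]) for pedigree-structured terms; names match term names.
#' @param config A [gibbs_config()].
#' @param start Optional named list of starting variances (`residual`, one
#'   per random term, `G0` for random-regression terms).
#' @param update_variances Set `FALSE` to hold all variances at their
#'   starting values (used for fixed-variance GLS checks).
#' @param keep_coef Optional character vector of coefficient names whose full
#'   chains are stored (posterior means/SDs of all coefficients are always
#'   available).
#' @return A `gibbs_fit` object: `samples` (tibble of variance chains),
#'   `solutions` (tibble of posterior mean/SD per coefficient), `meta`,
#'   `model`, `config`.
#' @export
gibbs_sample <- function(model, data, structures = list(),
                         config = gibbs_config(), start = list(),
                         update_variances = TRUE, keep_coef = NULL) {
  stopifnot(inherits(config, "gibbs_config"))
  if (nrow(data) == 0L) stop("no records to fit", call. = FALSE)
  des <- build_design(model, data, structures)
  check_fixed_rank(des$W, des$n_fixed)
  y <- data[[model$response]]
  stopifnot(is.numeric(y), !anyNA(y))

  vy <- stats::var(y)
  k <- model$residual_classes
  rclass <- if (k > 1L) {
    cl <- data[[model$residual_class_column]]
    stopifnot(all(cl %in% seq_len(k)))
    as.integer(cl) - 1L
  } else rep(0L, nrow(data))

  blocks_cpp <- list()
  var_names <- character()
  for (b in des$blocks) {
    if (b$kind == 0L) {
      blocks_cpp[[length(blocks_cpp) + 1L]] <-
        list(kind = 0L, start = b$start, q = b$q, nb = 1L, K = NULL)
    } else if (b$kind %in% c(1L, 2L)) {
      s2 <- start[[b$term]] %||% (vy / (2 * max(1L, length(des$blocks) - 1L)))
      blocks_cpp[[length(blocks_cpp) + 1L]] <-
        list(kind = b$kind, start = b$start, q = b$q, nb = 1L,
             K = b$K, prior_df = config$prior_df,
             prior_scale = config$prior_scale, sigma2 = s2)
      var_names <- c(var_names, paste0("sigma2_", b$term))
    } else {
      G0 <- start[[paste0(b$term, "_G0")]] %||% diag(vy / 10, 2)
      blocks_cpp[[length(blocks_cpp) + 1L]] <-
        list(kind = 3L, start = b$start, q = b$q, nb = 2L,
             K = b$K, prior_df = config$prior_df_G,
             prior_V = as.numeric(config$prior_V_G), G0 = as.numeric(G0))
      var_names <- c(var_names,
                     paste0(b$term, c("_sigma2_int", "_sigma_int_slope", "_sigma2_slope")))
    }
  }
  var_names <- c(var_names, paste0("sigma2_e", seq_len(k)))
  resid_start <- start$residual %||% rep(vy / 2, k)
  if (length(resid_start) == 1L) resid_start <- rep(resid_start, k)

  keep_idx <- integer(0)
  coef_names <- paste0(des$meta$term,
                       ifelse(des$meta$level == "", "", ":"), des$meta$level)
  if (!is.null(keep_coef)) {
    keep_idx <- match(keep_coef, coef_names)
    if (anyNA(keep_idx)) stop("unknown coefficient in keep_coef", call. = FALSE)
    keep_idx <- keep_idx - 1L
  }

  control <- list(n_iter = config$n_iter, burn_in = config$burn_in,
                  thin = config$thin, update_variances = update_variances,
                  resid_prior_df = config$prior_df,
                  resid_prior_scale = config$prior_scale,
                  resid_start = as.numeric(resid_start),
                  keep_idx = as.integer(keep_idx))

  set.seed(config$seed)
  res <- .gibbs_mme_cpp(des$W, as.numeric(y), rclass, k, blocks_cpp, control)

  samples <- as_tibble(as.data.frame(res$var_chain))
  names(samples) <- var_names
  coef_chains <- NULL
  if (length(keep_idx)) {
    coef_chains <- as_tibble(as.data.frame(res$coef_chain))
    names(coef_chains) <- keep_coef
  }
  solutions <- des$meta %>%
    mutate(coef = coef_names,
           estimate = as.numeric(res$coef_mean),
           posterior_sd = as.numeric(res$coef_sd))

  structure(list(samples = samples, solutions = solutions,
                 coef_chains = coef_chains, model = model, config = config,
                 n_retained = res$n_retained,
                 residual_classes = k),
            class = "gibbs_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Effective sample size of a chain
#'
#' Autocorrelation-based ESS: `n / (1 + 2 * sum(rho_k))` with the sum
#' truncated at the first non-positive autocorrelation.
#'
#' @param x Numeric chain.
#' @return Effective sample size (capped at `length(x)`).
#' @export
effective_size <- function(x) {
  n <- length(x)
  if (n < 3L || stats::sd(x) == 0) return(NA_real_)
  rho <- stats::acf(x, lag.max = min(n - 1L, 200L), plot = FALSE)$acf[-1]
  pos <- which(rho <= 0)
  if (length(pos)) rho <- rho[seq_len(pos[1] - 1L)]
  min(n, n / (1 + 2 * sum(rho)))
}

#' Summarise posterior chains
#'
#' For each parameter: posterior mean, SE (the posterior SD), the z-score
#' `mean / SE`, a two-tailed normal p-value `2 * (1 - pnorm(|z|))`, and the
#' effective sample size.  Chains with zero variance are flagged
#' (`z`, `p` = `NA`) rather than reported as infinitely significant.
#'
#' @param samples A `gibbs_fit`, or a data frame / matrix of chains (one
#'   column per parameter).
#' @return Tibble: `parameter`, `mean`, `se`, `z`, `p`, `ess`.
#' @export
posterior_summary <- function(samples) {
  if (inherits(samples, "gibbs_fit")) samples <- samples$samples
  if (is.numeric(samples) && is.null(dim(samples))) {
    samples <- matrix(samples, ncol = 1, dimnames = list(NULL, "parameter"))
  }
  samples <- as.data.frame(samples)
  if (nrow(samples) == 0L) stop("empty chains", call. = FALSE)
  purrr::map_dfr(names(samples), function(nm) {
    x <- samples[[nm]]
    m <- mean(x); s <- stats::sd(x)
    z <- if (is.na(s) || s == 0) NA_real_ else m / s
    tibble(parameter = nm, mean = m, se = s, z = z,
           p = if (is.na(z)) NA_real_ else 2 * (1 - stats::pnorm(abs(z))),
           ess = effective_size(x))
  })
}

#' @export
print.gibbs_fit <- function(x, ...) {
  cat("Gibbs-sampled mixed model (", x$n_retained, " retained samples)\n",
      sep = "")
  print(posterior_summary(x))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.gibbs_fit <- function(x, ...) posterior_summary(x)

#' @export
glance.gibbs_fit <- function(x, ...) {
  ps <- posterior_summary(x)
  tibble(n_retained = x$n_retained,
         n_parameters = nrow(x$solutions),
         residual_classes = x$residual_classes,
         min_ess = min(ps$ess, na.rm = TRUE))
}
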