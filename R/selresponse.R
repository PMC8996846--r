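#' Truncation-selection intensity
#'
#' The mean standardized superiority of selected parents when the top
#' fraction `p` of a normal distribution is kept:
#' `i = dnorm(qnorm(1 - p)) / p`.  Selecting the best 10% gives i = 1.755.
#'
#' @param p Selected proportion, in (0, 1).
#' @return Selection intensity (vectorized).
#' @examples
#' selection_intensity(0.10)
#' @export
selection_intensity <- function(p) {
  if (any(!is.finite(p) | p <= 0 | p >= 1)) {
    stop("selected proportion must lie strictly between 0 and 1", call. = FALSE)
  }
  stats::dnorm(stats::qnorm(1 - p)) / p
}

#' Selection-index specification
#'
#' Traits, their relative economic emphasis, genetic standard deviations,
#' genetic and phenotypic correlation matrices, and the selected proportion.
#' The default emphasis mirrors a dual-purpose cattle index: 0.65 on milk
#' yield traits split 3:1 between protein and fat yield, 0.20 on the udder
#' factor scores split equally, 0.15 on the performance-test block (0.45 on
#' average daily gain, 0.55 on the fleshiness x dressing composite), and
#' weight 0 on somatic cell score (monitored but not selected on).
#'
#' @param traits Ordered character vector of trait names.
#' @param emphasis Named (or positionally matched) non-negative vector of
#'   relative emphasis, same length as `traits`.
#' @param sigma_a Genetic standard deviations per trait.
#' @param r_a,r_p Genetic and phenotypic correlation matrices (symmetric,
#'   unit diagonal, entries in \[-1, 1\]).
#' @param p Selected proportion (default 0.10).
#' @return A `selection_index_spec` list.
#' @export
selection_index_spec <- function(traits = c("PY", "FY", "UC", "MU", "ADG", "FLxDP", "SCS"),
                                 emphasis = default_emphasis(traits),
                                 sigma_a, r_a, r_p, p = 0.10) {
  nt <- length(traits)
  emphasis <- unname(emphasis[if (!is.null(names(emphasis))) traits else seq_len(nt)])
  stopifnot(length(emphasis) == nt, length(sigma_a) == nt)
  if (any(emphasis < 0)) stop("emphasis entries must be >= 0", call. = FALSE)
  if (any(sigma_a[emphasis > 0] <= 0)) {
    stop("sigma_a must be > 0 for traits with positive emphasis", call. = FALSE)
  }
  check_corr <- function(R, what) {
    if (!is.matrix(R) || any(dim(R) != nt) ||
        any(abs(R - t(R)) > 1e-10) || any(abs(diag(R) - 1) > 1e-10) ||
        any(abs(R) > 1 + 1e-10)) {
      stop(what, " must be a symmetric correlation matrix of dimension ",
           nt, call. = FALSE)
    }
  }
  check_corr(r_a, "r_a"); check_corr(r_p, "r_p")
  if (p <= 0 || p >= 1) stop("p must lie in (0, 1)", call. = FALSE)
  structure(list(traits = traits, emphasis = emphasis, sigma_a = sigma_a,
                 r_a = r_a, r_p = r_p, p = p),
            class = "selection_index_spec")
}

#' Default relative emphasis of the dual-purpose index
#'
#' 0.65 milk block (3:1 protein:fat yield), 0.20 udder factor scores (equal
#' split), 0.15 performance test (0.45 daily gain, 0.55 fleshiness x
#' dressing), 0 on somatic cell score; unrecognized traits get 0.
#'
#' @param traits Trait names.
#' @return Named numeric vector of emphasis values.
#' @export
default_emphasis <- function(traits) {
  tab <- c(PY = 0.65 * 3 / 4, FY = 0.65 * 1 / 4,
           UC = 0.20 / 2, MU = 0.20 / 2,
           ADG = 0.15 * 0.45, FLxDP = 0.15 * 0.55,
           SCS = 0)
  out <- tab[traits]
  out[is.na(out)] <- 0
  names(out) <- traits
  out
}

#' Economic weights from relative emphasis
#'
#' The index weight vector entering the breeder's equation is the relative
#' emphasis scaled by the genetic standard deviation of each trait,
#' `a_s = a * sigma_a`; zero-emphasis traits keep weight 0.
#'
#' @param spec A [selection_index_spec()].
#' @return Named numeric vector `a_s`.
#' @export
economic_weights <- function(spec) {
  stopifnot(inherits(spec, "selection_index_spec"))
  a_s <- spec$emphasis * spec$sigma_a
  a_s[spec$emphasis == 0] <- 0
  names(a_s) <- spec$traits
  a_s
}

#' Build environment-specific G and P matrices
#'
#' Genetic variances of reaction-norm traits are the mean ZGZ' estimates of
#' the HEG levels of the environment; phenotypic variances add the
#' non-genetic components.  Covariances follow
#' `sigma_12 = r_12 * sqrt(sigma2_1 * sigma2_2)` with the supplied genetic
#' and phenotypic correlations.  Performance-test traits use the same fixed
#' variances in every environment (no GxE under standardized testing).
#'
#' @param spec A [selection_index_spec()].
#' @param sigma2_a Named per-trait genetic variances for this environment
#'   (e.g. mean ZGZ' for reaction-norm traits, station-test values for
#'   performance traits).
#' @param sigma2_p Named per-trait phenotypic variances for this
#'   environment.
#' @param repair If `TRUE`, a non-positive-definite matrix is repaired by
#'   clipping eigenvalues at 1e-8 (off by default; the default errors,
#'   naming the offending leading minor).
#' @return List with matrices `G` and `P`.
#' @export
build_matrices <- function(spec, sigma2_a, sigma2_p, repair = FALSE) {
  stopifnot(inherits(spec, "selection_index_spec"))
  nt <- length(spec$traits)
  sigma2_a <- unname(sigma2_a[if (!is.null(names(sigma2_a))) spec$traits else seq_len(nt)])
  sigma2_p <- unname(sigma2_p[if (!is.null(names(sigma2_p))) spec$traits else seq_len(nt)])
  stopifnot(length(sigma2_a) == nt, length(sigma2_p) == nt)
  if (any(sigma2_a <= 0) || any(sigma2_p <= 0)) {
    stop("all variances must be > 0", call. = FALSE)
  }
  outer_sd <- function(v) sqrt(v) %o% sqrt(v)
  G <- spec$r_a * outer_sd(sigma2_a)
  P <- spec$r_p * outer_sd(sigma2_p)
  dimnames(G) <- dimnames(P) <- list(spec$traits, spec$traits)
  check_pd <- function(M, what) {
    for (k in seq_len(nt)) {
      if (det(M[seq_len(k), seq_len(k), drop = FALSE]) <= 0) {
        if (repair) return(nearest_pd(M))
        stop(what, " is not positive definite (leading minor of order ", k,
             ", traits ", paste(spec$traits[seq_len(k)], collapse = ", "), ")",
             call. = FALSE)
      }
    }
    M
  }
  list(G = check_pd(G, "G"), P = check_pd(P, "P"))
}

nearest_pd <- function(M, eps = 1e-8) {
  ev <- eigen((M + t(M)) / 2, symmetric = TRUE)
  d <- pmax(ev$values, eps)
  out <- ev$vectors %*% diag(d, length(d)) %*% t(ev$vectors)
  dimnames(out) <- dimnames(M)
  out
}

#' Multivariate breeder's-equation response to selection
#'
#' Index weights `b = P^-1 G a_s`, index standard deviation
#' `sigma_i = sqrt(b' P b)`, per-generation response
#' `R = (i / sigma_i) G b` in trait units, and the standardized response
#' `R_dsi = R / sigma_P` elementwise.  Positive `R` means the trait mean
#' rises by that amount per generation under truncation selection on the
#' index.
#'
#' @param G,P Genetic and phenotypic (co)variance matrices.
#' @param a_s Economic-weight vector (see [economic_weights()]).
#' @param i Selection intensity (see [selection_intensity()]).
#' @return List of class `selection_response`: `response` (tibble `trait`,
#'   `R`, `R_dsi`), `b`, `sigma_i`, `i`.
#' @export
selection_response <- function(G, P, a_s, i = selection_intensity(0.10)) {
  stopifnot(is.matrix(G), is.matrix(P), all(dim(G) == dim(P)),
            length(a_s) == nrow(P))
  b <- solve(P, G %*% a_s)
  sigma_i2 <- as.numeric(t(b) %*% P %*% b)
  if (sigma_i2 <= .Machine$double.eps) {
    stop("null selection index (sigma_i = 0); response undefined", call. = FALSE)
  }
  sigma_i <- sqrt(sigma_i2)
  R <- as.numeric((i / sigma_i) * (G %*% b))
  traits <- rownames(G) %||% paste0("trait", seq_len(nrow(G)))
  structure(list(response = tibble(trait = traits, R = R,
                                   R_dsi = R / sqrt(diag(P))),
                 b = as.numeric(b), sigma_i = sigma_i, i = i),
            class = "selection_response")
}

#' @export
print.selection_response <- function(x, ...) {
  cat("Selection response (i = ", round(x$i, 3), ", sigma_i = ",
      signif(x$sigma_i, 4), ")\n", sep = "")
  print(x$response)
  invisible(x)
}

#' @export
tidy.selection_response <- function(x, ...) x$response

#' @export
glance.selection_response <- function(x, ...) {
  tibble(i = x$i, sigma_i = x$sigma_i, n_traits = nrow(x$response))
}

#' Per-environment selection responses
#'
#' Convenience wrapper: builds the environment-specific G and P matrices for
#' each row of `env_variances` and evaluates [selection_response()].
#'
#' @param spec A [selection_index_spec()].
#' @param env_variances Tibble with columns `environment`, and per-trait
#'   genetic/phenotypic variances in list-columns `sigma2_a`, `sigma2_p`
#'   (named numeric vectors), or a named list of such pairs.
#' @param i Selection intensity.
#' @return Tibble: `environment`, `trait`, `R`, `R_dsi`.
#' @export
respond_by_environment <- function(spec, env_variances,
                                   i = selection_intensity(spec$p)) {
  purrr::map_dfr(seq_len(nrow(env_variances)), function(r) {
    mats <- build_matrices(spec, env_variances$sigma2_a[[r]],
                           env_variances$sigma2_p[[r]])
    res <- selection_response(mats$G, mats$P, economic_weights(spec), i)
    mutate(res$response, environment = env_variances$environment[[r]],
           .before = 1)
  })
}
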