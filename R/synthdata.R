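#' Somatic cell score transform
#'
#' Log2 transform of somatic cell count, `SCS = 3 + log2(SCC / 100000)`,
#' which normalizes the strongly right-skewed raw counts.  An SCC of
#' 100,000 cells/mL maps to SCS 3; each doubling of SCC adds one score unit.
#'
#' @param scc Somatic cell count in cells/mL; must be strictly positive.
#' @return Numeric vector of somatic cell scores.
#' @examples
#' scs_transform(c(100000, 400000))
#' @export
scs_transform <- function(scc) {
  stopifnot(is.numeric(scc))
  if (any(!is.finite(scc) | scc <= 0)) {
    stop("scs_transform() requires SCC > 0 cells/mL", call. = FALSE)
  }
  3 + log2(scc / 100000)
}

# canonical environmental-category level sets ------------------------------
ec_levels <- function() {
  list(area = c("Plain", "Hill", "Mountain"),
       housing = c("LH", "TS"),        # loose housing vs tie stall
       feeding = c("TMR", "Trad"),     # total mixed ration vs traditional
       pasture = c("Yes", "No"))       # summer pasture
}

#' Enumerate all possible environmental groups
#'
#' The environmental group (EG) of a farm is the joint combination of its
#' four environmental-category levels: geographical area (Plain / Hill /
#' Mountain), housing (loose vs tie stall), feeding (TMR vs traditional) and
#' summer pasture (yes/no) — 3 x 2 x 2 x 2 = 24 possible combinations.
#'
#' @return Tibble of all EG combinations with an `eg_label` column.
#' @export
enumerate_eg <- function() {
  lv <- ec_levels()
  out <- tidyr::expand_grid(area = lv$area, housing = lv$housing,
                            feeding = lv$feeding, pasture = lv$pasture)
  out$eg_label <- paste(out$area, out$housing, out$feeding, out$pasture, sep = "_")
  out
}

# default area-conditional probability tables: lowland farms tend to be
# modernized (loose housing, TMR, no pasture); mountain farms traditional
default_ec_probabilities <- function() {
  list(
    area = c(Plain = 0.45, Hill = 0.15, Mountain = 0.40),
    housing = list(Plain = c(LH = 0.85, TS = 0.15),
                   Hill = c(LH = 0.50, TS = 0.50),
                   Mountain = c(LH = 0.10, TS = 0.90)),
    feeding = list(Plain = c(TMR = 0.85, Trad = 0.15),
                   Hill = c(TMR = 0.35, Trad = 0.65),
                   Mountain = c(TMR = 0.05, Trad = 0.95)),
    pasture = list(Plain = c(Yes = 0.10, No = 0.90),
                   Hill = c(Yes = 0.50, No = 0.50),
                   Mountain = c(Yes = 0.90, No = 0.10))
  )
}

#' Simulation configuration for a synthetic herd-book
#'
#' Bundles the population structure and the true variance architecture of
#' the generator.  `true_G0` is the 2x2 covariance of the sire reaction-norm
#' (intercept, slope) on the transmitting-ability scale, i.e. its (1,1)
#' entry is the sire variance (a quarter of the additive variance).
#'
#' @param n_herds,n_sires Numbers of herds and of sires with daughters.
#' @param daughters_per_sire Mean daughters per sire (Poisson, min 1).
#' @param records_per_cow Mean test-day records per cow (Poisson, min 1,
#'   capped at `n_test_days`).
#' @param n_test_days Test dates available per herd.
#' @param true_G0 2x2 symmetric PSD covariance of (intercept, slope).
#' @param sigma2_pe,sigma2_htd Permanent-environment and herd-test-day
#'   variances.
#' @param sigma2_resid_classes Exactly five residual variances, one per
#'   quintile class of the true herd environmental effect.
#' @param heg_effect_range Interval over which true herd environmental
#'   effects are drawn (uniform).
#' @param fixed_effect_tables Named list of named numeric vectors of true
#'   class-effect values; each phenotyped cow receives one level per table.
#' @param ec_level_probabilities Probability tables for environmental
#'   categories, with housing/feeding/pasture conditioned on area (see
#'   `default_ec_probabilities` in the package source).
#' @param mean_trait Overall trait mean.
#' @param correlate_sires If `TRUE` (default) sire transmitting abilities are
#'   propagated through the pedigree (relatives correlated); if `FALSE` every
#'   animal draws independently from N(0, G0).
#' @param seed Integer seed driving all sampling.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_herds = 60L, n_sires = 100L,
                       daughters_per_sire = 8L, records_per_cow = 10L,
                       n_test_days = 12L,
                       true_G0 = matrix(c(0.06, 0.01, 0.01, 0.04), 2, 2),
                       sigma2_pe = 0.1, sigma2_htd = 0.05,
                       sigma2_resid_classes = c(0.8, 0.9, 1.0, 1.1, 1.2),
                       heg_effect_range = c(-1.5, 1.5),
                       fixed_effect_tables = list(parity_class = c(P1 = 0, P2 = 0.2, P3 = 0.3)),
                       ec_level_probabilities = default_ec_probabilities(),
                       mean_trait = 3,
                       correlate_sires = TRUE,
                       seed = 1L) {
  cfg <- list(n_herds = as.integer(n_herds), n_sires = as.integer(n_sires),
              daughters_per_sire = daughters_per_sire,
              records_per_cow = records_per_cow,
              n_test_days = as.integer(n_test_days),
              true_G0 = true_G0, sigma2_pe = sigma2_pe, sigma2_htd = sigma2_htd,
              sigma2_resid_classes = sigma2_resid_classes,
              heg_effect_range = heg_effect_range,
              fixed_effect_tables = fixed_effect_tables,
              ec_level_probabilities = ec_level_probabilities,
              mean_trait = mean_trait,
              correlate_sires = isTRUE(correlate_sires),
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  G0 <- cfg$true_G0
  if (!is.matrix(G0) || !all(dim(G0) == 2) || abs(G0[1, 2] - G0[2, 1]) > 1e-12) {
    stop("true_G0 must be a symmetric 2x2 matrix", call. = FALSE)
  }
  ev <- eigen(G0, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) stop("true_G0 is not positive semidefinite", call. = FALSE)
  if (cfg$sigma2_pe < 0 || cfg$sigma2_htd < 0 ||
      any(cfg$sigma2_resid_classes < 0)) {
    stop("variances must be non-negative", call. = FALSE)
  }
  if (length(cfg$sigma2_resid_classes) != 5L) {
    stop("sigma2_resid_classes must contain exactly 5 variances", call. = FALSE)
  }
  pr <- cfg$ec_level_probabilities
  check_prob <- function(p, what) {
    if (any(p < 0) || abs(sum(p) - 1) > 1e-8) {
      stop("probabilities for ", what, " must be non-negative and sum to 1",
           call. = FALSE)
    }
  }
  check_prob(pr$area, "area")
  for (ec in c("housing", "feeding", "pasture")) {
    tab <- pr[[ec]]
    if (is.list(tab)) {
      for (a in names(tab)) check_prob(tab[[a]], paste(ec, "|", a))
    } else check_prob(tab, ec)
  }
  if (length(cfg$heg_effect_range) != 2L ||
      diff(cfg$heg_effect_range) <= 0) {
    stop("heg_effect_range must be an increasing interval", call. = FALSE)
  }
  invisible(cfg)
}

#' Assign environmental-category levels and EG labels to herds
#'
#' Samples one level of each environmental category per herd from the
#' configured probability tables.  Housing, feeding and pasture probabilities
#' may be conditioned on the herd's geographical area, which lets category
#' levels cluster realistically (modern lowland farms vs traditional mountain
#' farms).  Reproducible given `config$seed`.
#'
#' @param herds Character or integer vector of herd ids.
#' @param config A [sim_config()].
#' @return Tibble: `herd_id`, `area`, `housing`, `feeding`, `pasture`,
#'   `eg_label`.
#' @export
assign_environments <- function(herds, config) {
  stopifnot(length(herds) > 0L, inherits(config, "sim_config"))
  pr <- config$ec_level_probabilities
  withr_seed(config$seed + 101L, {
    n <- length(herds)
    area <- sample(names(pr$area), n, replace = TRUE, prob = pr$area)
    draw_cond <- function(tab) {
      vapply(area, function(a) {
        p <- if (is.list(tab)) tab[[a]] else tab
        sample(names(p), 1L, prob = p)
      }, character(1), USE.NAMES = FALSE)
    }
    out <- tibble(herd_id = as.character(herds), area = area,
                  housing = draw_cond(pr$housing),
                  feeding = draw_cond(pr$feeding),
                  pasture = draw_cond(pr$pasture))
  })
  out$eg_label <- paste(out$area, out$housing, out$feeding, out$pasture, sep = "_")
  out
}

# run expr under a local RNG state seeded with `seed`
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  eval.parent(substitute(expr))
}

#' Simulate the true population behind a herd-book
#'
#' Builds a pedigree with two ancestral generations behind the sires,
#' assigns herds to environments, draws per-herd true environmental effects
#' uniformly over `heg_effect_range`, and propagates sire reaction-norm
#' transmitting abilities (intercept, slope) through the pedigree: founders
#' are drawn from N(0, G0) and descendants as the parent average plus a
#' Mendelian-sampling deviation, so the sire term of an A-structured sire
#' model is correctly specified.  Dams of phenotyped cows are unrecorded
#' (coded 0), as the analysis models no dam-side structure.
#'
#' @param config A [sim_config()].
#' @return List of class `true_population`: `pedigree`, `sires` (tibble of
#'   true intercept/slope), `herds` (tibble with true environmental effect,
#'   scaled covariate, residual class and EC levels), `cows` (tibble with
#'   sire, herd, parity level, permanent-environment and within-family
#'   deviations), `config`.
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  G0 <- config$true_G0

  env <- assign_environments(paste0("H", seq_len(config$n_herds)), config)

  withr_seed(config$seed, {
    # --- pedigree: founders (GGS/GGD) -> sire parents (GS/GD) -> sires
    n_s <- config$n_sires
    n_gs <- max(4L, ceiling(n_s / 4)); n_gd <- max(8L, ceiling(n_s / 2))
    n_ggs <- max(2L, ceiling(n_gs / 2)); n_ggd <- max(4L, n_gs)
    id_ggs <- paste0("GGS", seq_len(n_ggs)); id_ggd <- paste0("GGD", seq_len(n_ggd))
    id_gs <- paste0("GS", seq_len(n_gs));  id_gd <- paste0("GD", seq_len(n_gd))
    id_sire <- paste0("S", seq_len(n_s))

    ped <- bind_rows(
      tibble(animal_id = c(id_ggs, id_ggd), sire_id = "0", dam_id = "0",
             sex = rep(c("M", "F"), c(n_ggs, n_ggd))),
      tibble(animal_id = id_gs, sire_id = sample(id_ggs, n_gs, TRUE),
             dam_id = sample(id_ggd, n_gs, TRUE), sex = "M"),
      tibble(animal_id = id_gd, sire_id = sample(id_ggs, n_gd, TRUE),
             dam_id = sample(id_ggd, n_gd, TRUE), sex = "F"),
      tibble(animal_id = id_sire, sire_id = sample(id_gs, n_s, TRUE),
             dam_id = sample(id_gd, n_s, TRUE), sex = "M")
    )

    # --- transmitting abilities through the pedigree: t = mean(parents)/... :
    # t_i = 0.5 t_s + 0.5 t_d + m_i, Var(m) = (1 - 0.25 k) G0, k = known parents
    px <- ped_index(ped)
    ord <- ped_toposort(px)
    Lg <- t(chol_psd(G0))
    tval <- matrix(0, nrow(ped), 2)
    for (i in ord) {
      s <- px$sire[i]; d <- px$dam[i]
      mu <- c(0, 0); k <- 0
      if (config$correlate_sires) {
        if (!is.na(s)) { mu <- mu + 0.5 * tval[s, ]; k <- k + 1 }
        if (!is.na(d)) { mu <- mu + 0.5 * tval[d, ]; k <- k + 1 }
      }
      msvar <- 1 - 0.25 * k
      tval[i, ] <- mu + sqrt(msvar) * as.numeric(Lg %*% stats::rnorm(2))
    }
    sires <- tibble(sire_id = id_sire,
                    true_intercept = tval[match(id_sire, px$id), 1],
                    true_slope = tval[match(id_sire, px$id), 2])

    # --- herds: true environmental effects and residual class by quintile
    h_eff <- stats::runif(config$n_herds, config$heg_effect_range[1],
                          config$heg_effect_range[2])
    herds <- env %>%
      mutate(true_env = h_eff,
             true_x = scale_covariate(h_eff),
             resid_class = residual_classes(h_eff, 5L))

    # --- cows: daughters per sire, herd assignment, deviations
    n_daughters <- pmax(1L, stats::rpois(n_s, config$daughters_per_sire))
    cow_sire <- rep(id_sire, n_daughters)
    n_cows <- length(cow_sire)
    sigma2_g <- G0[1, 1]
    cows <- tibble(
      animal_id = paste0("C", seq_len(n_cows)),
      sire_id = cow_sire,
      herd_id = sample(herds$herd_id, n_cows, TRUE),
      pe = stats::rnorm(n_cows, 0, sqrt(config$sigma2_pe)),
      # within-family additive deviation: remaining 3/4 of sigma2_A = 3 sigma2_G
      wf = stats::rnorm(n_cows, 0, sqrt(3 * sigma2_g))
    )
    for (tab in names(config$fixed_effect_tables)) {
      lv <- names(config$fixed_effect_tables[[tab]])
      cows[[tab]] <- sample(lv, n_cows, TRUE)
    }
    ped <- bind_rows(ped, tibble(animal_id = cows$animal_id,
                                 sire_id = cows$sire_id, dam_id = "0",
                                 sex = "F"))
  })

  start <- as.Date("2015-01-01")
  ped$birth_date <- start + rep(c(-3000L, -2200L, -1500L, -700L),
                                c(n_ggs + n_ggd, n_gs + n_gd, n_s, n_cows))
  structure(list(pedigree = ped, sires = sires, herds = herds, cows = cows,
                 config = config),
            class = "true_population")
}

# Cholesky factor tolerant of PSD (rank-deficient) matrices
chol_psd <- function(S) {
  ev <- eigen(S, symmetric = TRUE)
  d <- pmax(ev$values, 0)
  ev$vectors %*% diag(sqrt(d), nrow = length(d)) %*% t(ev$vectors)
}

#' Simulate phenotype records for a true population
#'
#' Each record is the sum of the overall mean, the herd's true environmental
#' effect, a herd-test-day effect, true fixed class effects, the sire's
#' transmitting ability evaluated at the herd's scaled environment
#' (intercept + slope * x), the cow's within-family additive deviation and
#' permanent-environment effect, and a residual drawn from the variance class
#' of the herd's true-environment quintile.
#'
#' @param population A `true_population` from [simulate_population()].
#' @param config Usually `population$config`.
#' @param keep_truth If `TRUE`, adds a `true_mean` column (the record's value
#'   minus its residual draw), so `value - true_mean` recovers the simulated
#'   residuals exactly.
#' @return Tibble of records: `animal_id`, `sire_id`, `herd_id`, `eg_label`,
#'   `heg_level`, `test_day`, `record_date`, class columns, `trait`, `value`.
#' @export
simulate_phenotypes <- function(population, config = population$config,
                                keep_truth = FALSE) {
  stopifnot(inherits(population, "true_population"))
  herds <- population$herds
  cows <- population$cows
  sires <- population$sires

  withr_seed(config$seed + 202L, {
    n_rec_cow <- pmin(config$n_test_days,
                      pmax(1L, stats::rpois(nrow(cows), config$records_per_cow)))
    rec <- cows[rep(seq_len(nrow(cows)), n_rec_cow), ]
    rec$test_day <- unlist(lapply(n_rec_cow, function(m) {
      sort(sample.int(config$n_test_days, m))
    }))
    rec <- left_join(rec, herds, by = "herd_id")
    rec <- left_join(rec, sires, by = "sire_id")

    htd_key <- paste(rec$herd_id, rec$test_day, sep = ":")
    htd_levels <- unique(htd_key)
    htd_eff <- stats::rnorm(length(htd_levels), 0, sqrt(config$sigma2_htd))
    names(htd_eff) <- htd_levels

    fixed <- rep(0, nrow(rec))
    for (tab in names(config$fixed_effect_tables)) {
      fixed <- fixed + unname(config$fixed_effect_tables[[tab]][rec[[tab]]])
    }
    resid_sd <- sqrt(config$sigma2_resid_classes[rec$resid_class])
    true_mean <- unname(config$mean_trait + rec$true_env + htd_eff[htd_key] + fixed) +
      rec$true_intercept + rec$true_slope * rec$true_x +
      rec$wf + rec$pe
    value <- unname(true_mean) + stats::rnorm(nrow(rec), 0, resid_sd)
  })

  class_cols <- names(config$fixed_effect_tables)
  tibble(
    animal_id = rec$animal_id,
    sire_id = rec$sire_id,
    herd_id = rec$herd_id,
    eg_label = rec$eg_label,
    heg_level = paste(rec$herd_id, rec$eg_label, sep = "."),
    test_day = rec$test_day,
    record_date = as.Date("2018-01-15") + 30L * (rec$test_day - 1L),
    htd = paste(rec$herd_id, rec$test_day, sep = ":")
  ) %>%
    bind_cols(rec[, class_cols, drop = FALSE]) %>%
    mutate(trait = "milk", value = value) -> out
  if (keep_truth) out$true_mean <- true_mean
  out
}

#' Simulate a complete synthetic herd-book
#'
#' Convenience wrapper: [simulate_population()] then [simulate_phenotypes()].
#'
#' @param config A [sim_config()].
#' @return List with `population`, `phenotypes`, `env` (herd-environment
#'   tibble) and `pedigree`.
#' @export
simulate_herdbook <- function(config = sim_config()) {
  pop <- simulate_population(config)
  phe <- simulate_phenotypes(pop, config)
  list(population = pop, phenotypes = phe,
       env = pop$herds, pedigree = pop$pedigree)
}

#' Write a synthetic herd-book to CSV files
#'
#' Writes `pedigree.csv` (missing parents coded 0), `phenotypes.csv` and
#' `herd_environment.csv` into `dir`, UTF-8, comma-separated, headered.
#'
#' @param herdbook Result of [simulate_herdbook()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_herdbook <- function(herdbook, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(pedigree = file.path(dir, "pedigree.csv"),
             phenotypes = file.path(dir, "phenotypes.csv"),
             env = file.path(dir, "herd_environment.csv"))
  utils::write.csv(herdbook$pedigree, paths["pedigree"], row.names = FALSE)
  utils::write.csv(herdbook$phenotypes, paths["phenotypes"], row.names = FALSE)
  env_cols <- c("herd_id", "area", "housing", "feeding", "pasture", "eg_label")
  utils::write.csv(herdbook$env[, intersect(env_cols, names(herdbook$env))],
                   paths["env"], row.names = FALSE)
  invisible(paths)
}
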