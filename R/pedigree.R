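#' @import tibble
#' @importFrom dplyr %>% mutate filter select group_by summarise ungroup
#'   arrange left_join inner_join bind_rows bind_cols n count distinct pull
#'   across all_of if_else row_number
#' @importFrom rlang .data
#' @importFrom methods as new
NULL

# internal: canonical pedigree representation ------------------------------

# returns list(id = character ids in input order,
#              sire = integer index or NA, dam = integer index or NA)
ped_index <- function(ped) {
  stopifnot(is.data.frame(ped),
            all(c("animal_id", "sire_id", "dam_id") %in% names(ped)))
  id <- as.character(ped$animal_id)
  if (anyDuplicated(id)) {
    stop("duplicated animal_id in pedigree: ",
         paste(unique(id[duplicated(id)]), collapse = ", "), call. = FALSE)
  }
  code <- function(p) {
    p <- as.character(p)
    p[is.na(p) | p == "0" | p == ""] <- NA_character_
    match(p, id)
  }
  list(id = id, sire = code(ped$sire_id), dam = code(ped$dam_id))
}

# topological order (parents before offspring); errors on cycles
ped_toposort <- function(px) {
  n <- length(px$id)
  # iterative depth computation with explicit cycle detection
  depth <- rep(NA_integer_, n)
  state <- integer(n) # 0 unvisited, 1 in progress, 2 done
  for (root in seq_len(n)) {
    if (state[root] == 2L) next
    stack <- list(root)
    while (length(stack)) {
      j <- stack[[length(stack)]]
      if (state[j] == 2L) { stack[[length(stack)]] <- NULL; next }
      par <- c(px$sire[j], px$dam[j]); par <- par[!is.na(par)]
      pending <- par[state[par] != 2L]
      if (any(state[pending] == 1L) || j %in% pending) {
        stop("pedigree contains a cycle involving animal ", px$id[j],
             call. = FALSE)
      }
      if (length(pending) == 0L) {
        depth[j] <- if (length(par)) max(depth[par]) + 1L else 0L
        state[j] <- 2L
        stack[[length(stack)]] <- NULL
      } else {
        state[j] <- 1L
        stack <- c(stack, as.list(pending))
      }
    }
  }
  order(depth, seq_along(depth))
}

#' Validate a pedigree table
#'
#' Structural quality check of a herd-book pedigree: cycles (an animal its
#' own ancestor), parents recorded as born after their offspring, sex
#' conflicts (an id used both as sire and dam, a sire recorded female, a dam
#' recorded male), and parent ids that do not appear as animals (dangling).
#' A clean pedigree yields a zero-row report.
#'
#' @param ped Data frame with columns `animal_id`, `sire_id`, `dam_id` and
#'   optionally `sex` (`"M"`/`"F"`) and `birth_date` (`Date`).  Missing
#'   parents are coded `0`, `""` or `NA`.
#' @return A tibble with columns `rule`, `animal_id`, `detail`; zero rows
#'   when no issue is found.
#' @export
validate_pedigree <- function(ped) {
  px <- ped_index(ped)
  issues <- list()
  flag <- function(rule, ids, detail) {
    if (length(ids)) {
      issues[[length(issues) + 1L]] <<-
        tibble(rule = rule, animal_id = as.character(ids), detail = detail)
    }
  }

  self_par <- which(px$sire == seq_along(px$id) | px$dam == seq_along(px$id))
  flag("cycle", px$id[self_par], "animal is its own parent")
  no_self <- px
  no_self$sire[self_par] <- NA_integer_
  no_self$dam[self_par] <- NA_integer_
  cyc <- tryCatch({ ped_toposort(no_self); character(0) },
                  error = function(e) sub(".*involving animal ", "", conditionMessage(e)))
  flag("cycle", cyc, "animal is its own ancestor")

  sire_chr <- as.character(ped$sire_id); dam_chr <- as.character(ped$dam_id)
  known <- function(p) !(is.na(p) | p == "0" | p == "")
  dang_s <- unique(sire_chr[known(sire_chr) & is.na(px$sire)])
  dang_d <- unique(dam_chr[known(dam_chr) & is.na(px$dam)])
  flag("dangling_parent", c(dang_s, dang_d),
       "parent id has no animal record")

  if ("sex" %in% names(ped)) {
    sex <- as.character(ped$sex)
    as_sire <- unique(px$sire[!is.na(px$sire)])
    as_dam <- unique(px$dam[!is.na(px$dam)])
    flag("sex_conflict", px$id[intersect(as_sire, as_dam)],
         "id used both as sire and dam")
    flag("sex_conflict", px$id[as_sire[sex[as_sire] %in% "F"]],
         "sire recorded as female")
    flag("sex_conflict", px$id[as_dam[sex[as_dam] %in% "M"]],
         "dam recorded as male")
  }

  if ("birth_date" %in% names(ped)) {
    bd <- as.Date(ped$birth_date)
    for (side in c("sire", "dam")) {
      p <- px[[side]]
      bad <- which(!is.na(p) & !is.na(bd) & !is.na(bd[p]) & bd[p] >= bd)
      flag("date_conflict", px$id[bad],
           paste(side, "born on/after offspring"))
    }
  }

  if (length(issues)) distinct(bind_rows(issues)) else
    tibble(rule = character(), animal_id = character(), detail = character())
}

# internal: list of ancestor index vectors per generation, up to depth
ancestor_generations <- function(px, i, depth) {
  gens <- vector("list", depth)
  current <- i
  for (g in seq_len(depth)) {
    par <- c(px$sire[current], px$dam[current])
    par <- par[!is.na(par)]
    gens[[g]] <- par
    if (length(par) == 0L) {
      for (h in seq(g, depth)) gens[[h]] <- integer(0)
      break
    }
    current <- par
  }
  gens
}

# completeness of one animal's own pedigree over `depth` generations:
# (1/depth) * sum_g known_g / 2^g
own_completeness <- function(px, i, depth) {
  gens <- ancestor_generations(px, i, depth)
  sum(vapply(seq_len(depth), function(g) length(gens[[g]]) / 2^g, 0)) / depth
}

#' Index of pedigree completeness (IPC)
#'
#' The IPC of an animal is the harmonic mean of the pedigree completeness of
#' its two parents, where a parent's completeness over `depth` generations is
#' the average, over generations g = 1..depth, of the proportion of its 2^g
#' ancestors that are known.  An unknown parent has completeness 0, which
#' drives the harmonic mean (and hence the IPC) to 0.
#'
#' @param ped Pedigree data frame (see [validate_pedigree()]).
#' @param animals Character vector of animal ids to evaluate; defaults to all.
#' @param depth Number of ancestral generations considered (default 5; the
#'   metric depends on this choice, so it is always explicit in the output).
#' @return Tibble with columns `animal_id`, `c_sire`, `c_dam`, `ipc`, `depth`.
#' @export
pedigree_completeness <- function(ped, animals = NULL, depth = 5L) {
  stopifnot(depth >= 1L)
  px <- ped_index(ped)
  if (is.null(animals)) animals <- px$id
  idx <- match(as.character(animals), px$id)
  if (anyNA(idx)) {
    stop("animal(s) not in pedigree: ",
         paste(animals[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  res <- purrr::map_dfr(seq_along(idx), function(j) {
    i <- idx[j]
    cs <- if (is.na(px$sire[i])) 0 else own_completeness(px, px$sire[i], depth)
    cd <- if (is.na(px$dam[i])) 0 else own_completeness(px, px$dam[i], depth)
    ipc <- if (cs + cd == 0) 0 else 2 * cs * cd / (cs + cd)
    tibble(animal_id = px$id[i], c_sire = cs, c_dam = cd, ipc = ipc)
  })
  res$depth <- as.integer(depth)
  res
}

#' Generations traced and complete-generation equivalents
#'
#' For each animal, `max_depth` is the longest chain of known ancestors and
#' `cge` (complete-generation equivalents) is the sum over all known
#' ancestors of (1/2)^generation; a fully known g-generation pedigree has
#' `cge = g`.  Returns per-animal values plus their means.
#'
#' @param ped Pedigree data frame.
#' @param animals Animal ids to summarise; defaults to all.
#' @param max_generations Safety cap on the recursion depth (default 30).
#' @return List with `per_animal` (tibble: animal_id, max_depth, cge) and
#'   `summary` (tibble: mean_max_depth, mean_cge, n).
#' @export
generations_traced <- function(ped, animals = NULL, max_generations = 30L) {
  px <- ped_index(ped)
  if (is.null(animals)) animals <- px$id
  idx <- match(as.character(animals), px$id)
  if (anyNA(idx)) {
    stop("animal(s) not in pedigree: ",
         paste(animals[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  per <- purrr::map_dfr(idx, function(i) {
    gens <- ancestor_generations(px, i, max_generations)
    counts <- lengths(gens)
    md <- if (any(counts > 0)) max(which(counts > 0)) else 0L
    cge <- sum(counts * 0.5^seq_along(counts))
    tibble(animal_id = px$id[i], max_depth = as.integer(md), cge = cge)
  })
  list(per_animal = per,
       summary = tibble(mean_max_depth = mean(per$max_depth),
                        mean_cge = mean(per$cge),
                        n = nrow(per)))
}

#' Inverse of the numerator relationship matrix
#'
#' Builds A-inverse directly from the pedigree by Henderson's rules, with
#' Mendelian-sampling variances optionally adjusted for parental inbreeding
#' (inbreeding coefficients computed by the Meuwissen-Luo recursion).  Unknown
#' parents are treated as missing (no unknown-parent groups).
#'
#' @param ped Pedigree data frame.
#' @param use_inbreeding If `TRUE` (default) Mendelian-sampling variances use
#'   parental inbreeding coefficients; if `FALSE` all animals are assumed
#'   non-inbred.
#' @return A sparse symmetric `Matrix` sparse matrix (dgCMatrix) with dimnames equal to the
#'   animal ids, positive definite for any acyclic pedigree.
#' @export
a_inverse <- function(ped, use_inbreeding = TRUE) {
  px <- ped_index(ped)
  ord <- ped_toposort(px)
  n <- length(px$id)
  f <- if (use_inbreeding) inbreeding_ml(px, ord) else rep(0, n)

  trip_i <- vector("list", n); trip_j <- vector("list", n); trip_x <- vector("list", n)
  for (k in seq_len(n)) {
    i <- ord[k]
    s <- px$sire[i]; d <- px$dam[i]
    fs <- if (is.na(s)) -1 else f[s]
    fd <- if (is.na(d)) -1 else f[d]
    # Mendelian sampling variance (as a fraction of sigma2_a)
    dms <- 1 - 0.25 * (1 + fs) - 0.25 * (1 + fd)
    a <- 1 / dms
    ti <- i; tj <- i; tx <- a
    for (p in c(s, d)[!is.na(c(s, d))]) {
      ti <- c(ti, i, p, p); tj <- c(tj, p, i, p)
      tx <- c(tx, -a / 2, -a / 2, a / 4)
    }
    if (!is.na(s) && !is.na(d)) {
      ti <- c(ti, s, d); tj <- c(tj, d, s); tx <- c(tx, a / 4, a / 4)
    }
    trip_i[[k]] <- ti; trip_j[[k]] <- tj; trip_x[[k]] <- tx
  }
  Ainv <- Matrix::sparseMatrix(
    i = unlist(trip_i), j = unlist(trip_j), x = unlist(trip_x),
    dims = c(n, n), dimnames = list(px$id, px$id)
  )
  methods::as(Matrix::drop0(Ainv), "generalMatrix")
}

# Meuwissen & Luo (1992) inbreeding coefficients; px indexed, ord topological
inbreeding_ml <- function(px, ord) {
  n <- length(px$id)
  f <- numeric(n)
  rank_of <- integer(n); rank_of[ord] <- seq_len(n)
  sire <- px$sire; dam <- px$dam
  for (k in seq_len(n)) {
    i <- ord[k]
    s <- sire[i]; d <- dam[i]
    if (is.na(s) || is.na(d)) { f[i] <- 0; next }
    # trace ancestors of i with their contributions L; A_ii = sum L^2 D over
    # the animal itself (L = 1) and all its ancestors
    L <- numeric(n)
    L[s] <- 0.5; L[d] <- 0.5
    # process ancestors in decreasing topological rank
    active <- c(s, d)
    fi <- 0.5 - 0.25 * (f[s] + f[d])
    while (length(active)) {
      j <- active[which.max(rank_of[active])]
      active <- active[active != j]
      sj <- sire[j]; dj <- dam[j]
      fsj <- if (is.na(sj)) -1 else f[sj]
      fdj <- if (is.na(dj)) -1 else f[dj]
      Dj <- 1 - 0.25 * (1 + fsj) - 0.25 * (1 + fdj)
      fi <- fi + L[j]^2 * Dj
      if (!is.na(sj)) { if (L[sj] == 0) active <- c(active, sj); L[sj] <- L[sj] + 0.5 * L[j] }
      if (!is.na(dj)) { if (L[dj] == 0) active <- c(active, dj); L[dj] <- L[dj] + 0.5 * L[j] }
      L[j] <- 0
    }
    f[i] <- fi - 1
  }
  f
}

#' Numerator relationship matrix by the tabular method
#'
#' Dense recursive construction of A; quadratic in pedigree size, intended
#' for small pedigrees and as an independent cross-check of [a_inverse()].
#'
#' @param ped Pedigree data frame.
#' @return Dense symmetric matrix with animal-id dimnames.
#' @export
a_tabular <- function(ped) {
  px <- ped_index(ped)
  ord <- ped_toposort(px)
  n <- length(px$id)
  A <- matrix(0, n, n, dimnames = list(px$id, px$id))
  for (k in seq_len(n)) {
    i <- ord[k]
    s <- px$sire[i]; d <- px$dam[i]
    for (m in seq_len(k - 1L)) {
      j <- ord[m]
      aij <- 0
      if (!is.na(s)) aij <- aij + 0.5 * A[j, s]
      if (!is.na(d)) aij <- aij + 0.5 * A[j, d]
      A[i, j] <- A[j, i] <- aij
    }
    A[i, i] <- 1 + if (!is.na(s) && !is.na(d)) 0.5 * A[s, d] else 0
  }
  A
}

#' Thresholds for the data-editing rules
#'
#' Minimum observations per fixed-effect cell and per-environmental-group
#' retention thresholds, which differ between the repeated-record milk-trait
#' dataset (MT) and the single-record type-trait dataset (FS/LTT).
#'
#' @param min_obs_per_cell Minimum records per fixed-effect cell (default 2).
#' @param eg_min_levels_mt,eg_min_records_mt Minimum herd levels and records
#'   for an environmental group to be retained in an MT analysis (6, 6000).
#' @param eg_min_levels_fs,eg_min_records_fs The same for FS/LTT (5, 300).
#' @return A list of class `edit_thresholds`.
#' @export
edit_thresholds <- function(min_obs_per_cell = 2L,
                            eg_min_levels_mt = 6L, eg_min_records_mt = 6000L,
                            eg_min_levels_fs = 5L, eg_min_records_fs = 300L) {
  th <- list(min_obs_per_cell = as.integer(min_obs_per_cell),
             eg_min_levels_mt = as.integer(eg_min_levels_mt),
             eg_min_records_mt = as.integer(eg_min_records_mt),
             eg_min_levels_fs = as.integer(eg_min_levels_fs),
             eg_min_records_fs = as.integer(eg_min_records_fs))
  if (any(unlist(th) < 1L)) stop("all edit thresholds must be >= 1", call. = FALSE)
  structure(th, class = "edit_thresholds")
}

#' Edit thresholds scaled to a dataset's size
#'
#' The per-group retention thresholds are tied to the size of the study that
#' motivated them (order 10^5 records over ~100 herds).  For smaller
#' datasets this scales the level thresholds by the herd ratio and the
#' record thresholds by the record ratio (floors of 2 levels / 50 records),
#' keeping the per-cell minimum at 2.
#'
#' @param n_herds,n_records Size of the dataset at hand.
#' @param ref_herds,ref_records Reference size the canonical thresholds
#'   were designed for.
#' @return An [edit_thresholds()] object.
#' @export
edit_thresholds_scaled <- function(n_herds, n_records,
                                   ref_herds = 114, ref_records = 163859) {
  sc_l <- n_herds / ref_herds
  sc_r <- n_records / ref_records
  edit_thresholds(
    min_obs_per_cell = 2L,
    eg_min_levels_mt = max(2L, round(6 * sc_l)),
    eg_min_records_mt = max(50L, round(6000 * sc_r)),
    eg_min_levels_fs = max(2L, round(5 * sc_l)),
    eg_min_records_fs = max(50L, round(300 * sc_r))
  )
}

#' Apply the data-editing filters
#'
#' Two rules, applied until stable: (i) any level (cell) of a modelled class
#' effect with fewer than `min_obs_per_cell` records is dropped; (ii) any
#' environmental group failing the dataset-kind-specific minimum number of
#' herd levels and records is dropped entirely.  Because dropping records can
#' empty other cells, rule (i) iterates to a fixed point, which also makes
#' the whole edit idempotent.
#'
#' @param phenotypes Phenotype data frame with an `eg_label` column (or
#'   joinable via `herd_id` to `env_assignment`) plus the class columns.
#' @param env_assignment Optional herd-environment tibble (`herd_id`,
#'   `eg_label`) used to label records lacking `eg_label`.
#' @param thresholds An [edit_thresholds()] object.
#' @param dataset_kind `"MT"` (repeated test-day records) or `"FS"`
#'   (single-record type traits); selects the group-retention thresholds.
#' @param class_terms Character vector of class-effect columns subject to the
#'   per-cell rule (default: all of `heg_level`, `htd`, `parity_class` that
#'   are present).
#' @return List with `data` (filtered tibble) and `audit` (tibble of per-rule
#'   removal counts).
#' @export
edit_data <- function(phenotypes, env_assignment = NULL,
                      thresholds = edit_thresholds(),
                      dataset_kind = c("MT", "FS"),
                      class_terms = NULL) {
  dataset_kind <- tryCatch(match.arg(dataset_kind),
                           error = function(e) stop("unknown dataset_kind; use \"MT\" or \"FS\"",
                                                    call. = FALSE))
  stopifnot(inherits(thresholds, "edit_thresholds"))
  dat <- as_tibble(phenotypes)
  if (!"eg_label" %in% names(dat)) {
    if (is.null(env_assignment)) {
      stop("phenotypes lack eg_label and no env_assignment supplied", call. = FALSE)
    }
    dat <- left_join(dat, select(as_tibble(env_assignment), "herd_id", "eg_label"),
                     by = "herd_id")
  }
  if (is.null(class_terms)) {
    class_terms <- intersect(c("heg_level", "htd", "parity_class"), names(dat))
  }
  audit <- list()
  min_lvl <- if (dataset_kind == "MT") thresholds$eg_min_levels_mt else thresholds$eg_min_levels_fs
  min_rec <- if (dataset_kind == "MT") thresholds$eg_min_records_mt else thresholds$eg_min_records_fs

  # rule (ii): EG retention, on herd counts and record counts
  eg_stats <- dat %>%
    group_by(.data$eg_label) %>%
    summarise(n_levels = dplyr::n_distinct(.data$herd_id), n_records = n(),
              .groups = "drop")
  keep_eg <- eg_stats$eg_label[eg_stats$n_levels >= min_lvl &
                                 eg_stats$n_records >= min_rec]
  removed <- nrow(dat) - sum(dat$eg_label %in% keep_eg)
  audit[["eg_thresholds"]] <- removed
  dat <- filter(dat, .data$eg_label %in% keep_eg)

  # rule (i): per-cell minimum, to a fixed point
  removed_cells <- 0L
  repeat {
    n_before <- nrow(dat)
    for (term in class_terms) {
      counts <- dat %>% count(.data[[term]])
      bad <- counts[[term]][counts$n < thresholds$min_obs_per_cell]
      if (length(bad)) dat <- filter(dat, !(.data[[term]] %in% bad))
    }
    removed_cells <- removed_cells + (n_before - nrow(dat))
    if (nrow(dat) == n_before) break
  }
  audit[["min_obs_per_cell"]] <- removed_cells

  list(data = dat,
       audit = tibble(rule = names(audit), records_removed = unlist(audit, use.names = FALSE)))
}
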