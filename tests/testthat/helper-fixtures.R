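# shared fixtures, built in code and memoized across test files

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, force(expr), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# a small, quickly-fitted herd-book for module-level tests
small_config <- function(seed = 101L, ...) {
  sim_config(n_herds = 30L, n_sires = 40L, daughters_per_sire = 6L,
             records_per_cow = 6L, n_test_days = 8L, seed = seed, ...)
}

small_herdbook <- function() {
  memo("small_herdbook", simulate_herdbook(small_config()))
}

# quick chain settings for module tests (not the recovery protocol)
quick_gibbs <- function(seed = 7L) gibbs_config(3000L, 1000L, 4L, seed = seed)

# a default-scale herd-book plus fitted step-1/step-2 models, shared by the
# pipeline-level tests (whichever test file needs them first builds them)
fixture_hb <- function() {
  memo("step1_hb", simulate_herdbook(sim_config(seed = 401L)))
}

fixture_edited <- function() {
  memo("edited_hb", {
    hb <- fixture_hb()
    th <- edit_thresholds_scaled(60, nrow(hb$phenotypes))
    edit_data(hb$phenotypes, hb$env, th, "MT")
  })
}

fixture_step1 <- function() {
  memo("step1_fit", {
    fit_step1(fixture_edited()$data, fixture_hb()$pedigree, "MT",
              config = quick_gibbs())
  })
}

fixture_rnfit <- function(with_gxe = TRUE) {
  nm <- if (with_gxe) "rnfit_gxe" else "rnfit_nogxe"
  memo(nm, {
    fit_reaction_norm(fixture_edited()$data, fixture_step1()$gradient,
                      fixture_hb()$pedigree, with_gxe = with_gxe,
                      config = quick_gibbs())
  })
}

# random acyclic pedigree generator for property tests
random_pedigree <- function(n, seed) {
  set.seed(seed)
  ped <- data.frame(animal_id = as.character(seq_len(n)),
                    sire_id = "0", dam_id = "0",
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    if (i >= 3 && runif(1) < 0.7) {
      ped$sire_id[i] <- as.character(sample.int(i - 1L, 1))
      d <- sample.int(i - 1L, 1)
      if (as.character(d) != ped$sire_id[i]) ped$dam_id[i] <- as.character(d)
    }
  }
  ped
}

# trio pedigree used in several places
trio_pedigree <- function() {
  data.frame(animal_id = c("S", "D", "O"),
             sire_id = c("0", "0", "S"),
             dam_id = c("0", "0", "D"))
}

# brute-force recursive ancestor enumeration (independent of the package's
# BFS implementation): list of ancestor ids per generation
recurse_ancestors <- function(ped, id, depth) {
  if (depth <= 0) return(list())
  sire <- ped$sire_id[match(id, ped$animal_id)]
  dam <- ped$dam_id[match(id, ped$animal_id)]
  known <- function(p) !is.na(p) && p != "0" && p %in% ped$animal_id
  out <- vector("list", depth)
  parents <- as.character(c(if (known(sire)) sire, if (known(dam)) dam))
  out[[1]] <- parents
  if (depth > 1 && length(parents)) {
    subs <- lapply(parents, function(p) recurse_ancestors(ped, p, depth - 1))
    for (g in seq_len(depth - 1)) {
      out[[g + 1]] <- unlist(lapply(subs, `[[`, g))
    }
  }
  for (g in seq_len(depth)) if (is.null(out[[g]])) out[[g]] <- character(0)
  out
}

# Monte-Carlo truncation-selection oracle: simulate breeding values g and
# phenotypes x = g + e from (G, P), select the top fraction p on the index
# b'x, and average the selected parents' breeding values.
mc_selection_oracle <- function(G, P, a_s, p = 0.10, n = 200000L, seed = 1L) {
  set.seed(seed)
  nt <- nrow(G)
  E <- P - G
  g <- matrix(rnorm(n * nt), n) %*% chol(G)
  x <- g + matrix(rnorm(n * nt), n) %*% chol(E)
  b <- solve(P, G %*% a_s)
  idx <- as.numeric(x %*% b)
  sel <- idx >= quantile(idx, 1 - p)
  colMeans(g[sel, , drop = FALSE])
}

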