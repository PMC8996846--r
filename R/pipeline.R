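#' Pipeline configuration
#'
#' Exactly one of `simulation` (a [sim_config()]) or `inputs` (named list of
#' CSV paths `pedigree`, `phenotypes`, `env`) must be given.  The global
#' `seed` deterministically spawns per-stage seeds, so any stage can be
#' rerun in isolation with identical results.
#'
#' @param simulation Optional [sim_config()] for a simulation-backed run.
#' @param inputs Optional named list of input CSV paths.
#' @param out_dir Output directory for stage artifacts.
#' @param gibbs A [gibbs_config()] shared by both steps.
#' @param thresholds An [edit_thresholds()].
#' @param dataset_kind `"MT"` or `"FS"`.
#' @param index_spec Optional [selection_index_spec()]; when present a
#'   selection-response stage is added.
#' @param pt_variances Optional named list with `sigma2_a`, `sigma2_p` per
#'   non-reaction-norm trait of `index_spec`.
#' @param seed Global integer seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(simulation = NULL, inputs = NULL,
                            out_dir = tempfile("rngxe_run_"),
                            gibbs = gibbs_config(),
                            thresholds = edit_thresholds(),
                            dataset_kind = "MT",
                            index_spec = NULL, pt_variances = NULL,
                            seed = 1L) {
  if (is.null(simulation) == is.null(inputs)) {
    stop("exactly one of `simulation` or `inputs` must be supplied",
         call. = FALSE)
  }
  if (!is.null(inputs)) {
    stopifnot(all(c("pedigree", "phenotypes", "env") %in% names(inputs)))
  }
  structure(list(simulation = simulation, inputs = inputs, out_dir = out_dir,
                 gibbs = gibbs, thresholds = thresholds,
                 dataset_kind = dataset_kind, index_spec = index_spec,
                 pt_variances = pt_variances, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields map directly; `true_G0` is given as a length-4 vector
#' (row-major), `fixed_effect_tables` as named maps.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- NULL
  if (!is.null(y$simulation)) {
    s <- y$simulation
    if (!is.null(s$true_G0)) s$true_G0 <- matrix(as.numeric(s$true_G0), 2, 2, byrow = TRUE)
    if (!is.null(s$fixed_effect_tables)) {
      s$fixed_effect_tables <- lapply(s$fixed_effect_tables, unlist)
    }
    sim <- do.call(sim_config, s)
  }
  gib <- if (is.null(y$gibbs)) gibbs_config() else do.call(gibbs_config, y$gibbs)
  thr <- if (is.null(y$thresholds)) edit_thresholds() else do.call(edit_thresholds, y$thresholds)
  pipeline_config(simulation = sim, inputs = y$inputs,
                  out_dir = y$out_dir %||% tempfile("rngxe_run_"),
                  gibbs = gib, thresholds = thr,
                  dataset_kind = y$dataset_kind %||% "MT",
                  seed = y$seed %||% 1L)
}

stage_seed <- function(config, stage_index) {
  (abs(config$seed) %% 1000003L) * 1000L + stage_index
}

#' Run the full two-step reaction-norm pipeline
#'
#' Executes, in order: data acquisition (simulate or load), data editing,
#' the step-1 gradient model, the step-2 reaction-norm sire model with and
#' without the GxE term, the gradient-variance summaries, and the EBV
#' ranking comparison; optionally a selection-response stage when an index
#' specification is configured.  Each stage writes its tabular outputs under
#' `out_dir` and the run manifest records paths, MD5 checksums, seeds and
#' timings.
#'
#' @param config A [pipeline_config()].
#' @return A `run_manifest` list: `stages` (tibble), `outputs` (named
#'   paths), `results` (in-memory stage results), `seed`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!dir.exists(config$out_dir)) dir.create(config$out_dir, recursive = TRUE)
  stages <- list(); outputs <- character(); results <- list()
  t_all <- Sys.time()
  record <- function(name, paths, t0) {
    stages[[length(stages) + 1L]] <<- tibble(
      stage = name, seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")),
      outputs = paste(basename(paths), collapse = ";"))
    outputs[paths %>% basename()] <<- paths
  }
  save_csv <- function(df, name) {
    p <- file.path(config$out_dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    p
  }
  with_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # stage 1: data
  t0 <- Sys.time()
  dat <- with_stage("data", {
    if (!is.null(config$simulation)) {
      sim <- config$simulation
      sim$seed <- stage_seed(config, 1L)
      simulate_herdbook(sim)
    } else {
      list(pedigree = utils::read.csv(config$inputs$pedigree,
                                      colClasses = "character"),
           phenotypes = as_tibble(utils::read.csv(config$inputs$phenotypes)),
           env = as_tibble(utils::read.csv(config$inputs$env)))
    }
  })
  results$data <- dat
  record("data", c(save_csv(dat$pedigree, "pedigree.csv"),
                   save_csv(dat$env, "herd_environment.csv")), t0)

  # stage 2: edit
  t0 <- Sys.time()
  edited <- with_stage("edit", {
    edit_data(dat$phenotypes, dat$env, config$thresholds,
              config$dataset_kind)
  })
  results$edited <- edited
  record("edit", c(save_csv(edited$data, "phenotypes_edited.csv"),
                   save_csv(edited$audit, "edit_audit.csv")), t0)

  # stage 3: step 1
  t0 <- Sys.time()
  gcfg <- config$gibbs
  gcfg$seed <- stage_seed(config, 3L)
  step1 <- with_stage("step1", {
    fit_step1(edited$data, dat$pedigree, config$dataset_kind, config = gcfg)
  })
  results$step1 <- step1
  record("step1", save_csv(step1$gradient, "gradient.csv"), t0)

  # stages 4-5: step 2 with and without GxE
  fits <- list()
  for (wg in c(TRUE, FALSE)) {
    t0 <- Sys.time()
    nm <- if (wg) "step2_gxe" else "step2_nogxe"
    gcfg$seed <- stage_seed(config, if (wg) 4L else 5L)
    fit <- with_stage(nm, {
      fit_reaction_norm(edited$data, step1$gradient, dat$pedigree,
                        with_gxe = wg, dataset_kind = config$dataset_kind,
                        config = gcfg)
    })
    fits[[nm]] <- fit
    record(nm, c(save_csv(fit$components, paste0(nm, "_components.csv")),
                 save_csv(fit$sires, paste0(nm, "_ebv.csv"))), t0)
  }
  results$step2_gxe <- fits$step2_gxe
  results$step2_nogxe <- fits$step2_nogxe

  # stage 6: gradient-variance summaries
  t0 <- Sys.time()
  summaries <- with_stage("summarize", {
    gv <- zgz_gradient(fits$step2_gxe)
    list(gradient_variance = gv,
         by_level = purrr::map_dfr(c("area", "housing", "feeding", "pasture", "EG"),
                                   ~ average_by_level(gv, dat$env, .x)),
         tests = trim_and_test(gv, dat$env, "area"))
  })
  results$summaries <- summaries
  record("summarize",
         c(save_csv(summaries$gradient_variance, "gradient_variance.csv"),
           save_csv(summaries$by_level, "zgz_by_level.csv")), t0)

  # stage 7: EBV ranking comparison
  t0 <- Sys.time()
  comparison <- with_stage("compare", {
    compare_rankings(ebv_at_environment(fits$step2_gxe, x = 0),
                     ebv_at_environment(fits$step2_nogxe, x = 0))
  })
  results$comparison <- comparison
  record("compare", save_csv(comparison$ranks, "rank_comparison.csv"), t0)

  # optional stage 8: selection response
  if (!is.null(config$index_spec)) {
    t0 <- Sys.time()
    response <- with_stage("respond", {
      pipeline_response(config, summaries$gradient_variance,
                        fits$step2_gxe, dat$env)
    })
    results$response <- response
    record("respond", save_csv(response, "selection_response.csv"), t0)
  }

  manifest <- list(
    stages = bind_rows(stages),
    outputs = outputs,
    checksums = tools::md5sum(unname(outputs)),
    seed = config$seed,
    total_seconds = as.numeric(difftime(Sys.time(), t_all, units = "secs")),
    config = config,
    results = results
  )
  class(manifest) <- "run_manifest"
  manifest
}

# single-trait-per-environment response table built from the ZGZ' summaries;
# non-reaction-norm traits of the index keep their fixed variances
pipeline_response <- function(config, grad_var, fit, env) {
  spec <- config$index_spec
  lev <- average_by_level(grad_var, env, "area")
  s <- fit$samples
  nongen <- mean(s[[if (fit$dataset_kind == "MT") "sigma2_htd" else "sigma2_hyc"]]) +
    (if ("sigma2_pe" %in% names(s)) mean(s$sigma2_pe) else 0)
  rn_trait <- spec$traits[1]
  map <- heg_grouping(grad_var, env, "area")
  mean_e <- grad_var %>%
    left_join(map, by = "heg_level") %>%
    group_by(level = .data$level) %>%
    summarise(mean_e = mean(.data$sigma2_e), .groups = "drop")
  lev <- left_join(lev, mean_e, by = "level")
  env_variances <- tibble(
    environment = lev$level,
    sigma2_a = purrr::map(seq_len(nrow(lev)), function(r) {
      v <- config$pt_variances$sigma2_a
      v[rn_trait] <- lev$mean_zgz[r]
      v[spec$traits]
    }),
    sigma2_p = purrr::map(seq_len(nrow(lev)), function(r) {
      v <- config$pt_variances$sigma2_p
      v[rn_trait] <- lev$mean_zgz[r] + nongen + lev$mean_e[r]
      v[spec$traits]
    })
  )
  respond_by_environment(spec, env_variances)
}

#' Summarise a pipeline run as a report
#'
#' Collects the key result tables of a completed run: variance components
#' with z/p flags, variance-ratio data, the with/without-GxE Spearman
#' correlation and top-k re-ranking, and the environmental-level ZGZ'
#' summaries; writes a Markdown file beside the stage outputs.
#'
#' @param manifest A `run_manifest` from [run_pipeline()].
#' @return List of class `run_report` with the tables and the path of the
#'   Markdown file; errors if the manifest lacks completed stages.
#' @export
make_report <- function(manifest) {
  stopifnot(inherits(manifest, "run_manifest"))
  need <- c("step1", "step2_gxe", "step2_nogxe", "summaries", "comparison")
  missing <- setdiff(need, names(manifest$results))
  if (length(missing)) {
    stop("manifest incomplete; missing stage(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  res <- manifest$results
  ratios <- variance_ratios(res$step2_gxe)
  cmp <- res$comparison
  report <- list(
    components = res$step2_gxe$components,
    ratios = ratios,
    h2 = bind_rows(step1_animal = tibble(mean = res$step1$h2, se = res$step1$h2_se),
                   sire_gxe = sire_h2(res$step2_gxe)[, c("mean", "se")],
                   sire_nogxe = sire_h2(res$step2_nogxe)[, c("mean", "se")],
                   .id = "model"),
    spearman = tibble(comparison = "with vs without GxE",
                      spearman = cmp$spearman, top_k = cmp$top_k,
                      top_overlap = cmp$top_overlap),
    zgz_by_level = res$summaries$by_level,
    response = res$response
  )
  md <- file.path(dirname(manifest$outputs[[1]]), "report.md")
  lines <- c("# Reaction-norm GxE run report", "",
             sprintf("Seed: %d; total runtime: %.1f s", manifest$seed,
                     manifest$total_seconds), "",
             "## Variance components (step 2, with GxE)",
             df_md(report$components),
             "## Variance ratios", df_md(report$ratios),
             "## Heritabilities", df_md(report$h2),
             "## EBV re-ranking", df_md(report$spearman),
             "## ZGZ' by environmental level", df_md(report$zgz_by_level))
  if (!is.null(report$response)) {
    lines <- c(lines, "## Selection response", df_md(report$response))
  }
  writeLines(lines, md)
  report$path <- md
  class(report) <- "run_report"
  report
}

df_md <- function(df) {
  df <- as.data.frame(df)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x) signif(x, 4))
  c(paste("|", paste(names(df), collapse = " | "), "|"),
    paste("|", paste(rep("---", ncol(df)), collapse = " | "), "|"),
    vapply(seq_len(nrow(df)), function(r) {
      paste("|", paste(unlist(df[r, ]), collapse = " | "), "|")
    }, character(1)), "")
}
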