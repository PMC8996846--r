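# a reaction-norm fit object with prescribed constant chains, for exercising
# the ratio/heritability/EBV arithmetic without running the sampler
stub_rn_fit <- function(htd = 1.865, pe = 5.632, g = 0.756, cov = -0.23,
                        gxe = 2.697,
                        e_classes = c(6.3, 6.4, 6.65, 6.8, 7.1),
                        sires = NULL, with_gxe = TRUE, n = 4L) {
  s <- tibble::tibble(
    sigma2_htd = rep(htd, n), sigma2_pe = rep(pe, n))
  if (with_gxe) {
    s$sire_sigma2_int <- rep(g, n)
    s$sire_sigma_int_slope <- rep(cov, n)
    s$sire_sigma2_slope <- rep(gxe, n)
  } else {
    s$sigma2_sire <- rep(g, n)
  }
  for (k in seq_along(e_classes)) s[[paste0("sigma2_e", k)]] <- rep(e_classes[k], n)
  s$sigma2_e_mean <- rowMeans(s[paste0("sigma2_e", seq_along(e_classes))])
  if (is.null(sires)) {
    sires <- tibble::tibble(sire_id = c("s1", "s2"),
                            intercept = c(1, 0.5), intercept_sd = c(0.1, 0.1),
                            slope = c(-1, 1), slope_sd = c(0.2, 0.2))
  }
  structure(list(samples = s, sires = sires, with_gxe = with_gxe,
                 dataset_kind = "MT",
                 G0 = matrix(c(g, cov, cov, gxe), 2, 2),
                 sigma2_e_mean = mean(e_classes),
                 gradient = tibble::tibble(heg_level = paste0("h", 1:5),
                                           scaled_x = seq(-1, 1, length.out = 5)),
                 n_residual_classes = length(e_classes),
                 fit = list(n_retained = n)),
            class = "rn_fit")
}

test_that("phenotypic variance composition and ratios match hand arithmetic", {
  # milk-trait-style components: sigma2_P = htd + Pe + G + GxE + 2cov + mean(e)
  fit <- stub_rn_fit()
  vr <- variance_ratios(fit)
  s2p <- 1.865 + 5.632 + 0.756 + 2.697 + 2 * (-0.23) + 6.65
  expect_equal(s2p, 17.14)
  expect_equal(vr$mean[vr$parameter == "sigma2_P"], s2p)
  expect_equal(vr$mean[vr$parameter == "GxE_over_P"], 2.697 / 17.14,
               tolerance = 1e-12)
  expect_equal(vr$mean[vr$parameter == "G_over_P"], 0.756 / 17.14)
  expect_equal(vr$mean[vr$parameter == "covGxE_over_P"], -0.23 / 17.14)

  # zero covariance: simple sum
  fit0 <- stub_rn_fit(cov = 0)
  vr0 <- variance_ratios(fit0)
  expect_equal(vr0$mean[vr0$parameter == "sigma2_P"],
               1.865 + 5.632 + 0.756 + 2.697 + 6.65)

  # all genetic components zero: ratios zero
  fitz <- stub_rn_fit(g = 0, cov = 0, gxe = 0)
  vrz <- variance_ratios(fitz)
  expect_equal(vrz$mean[vrz$parameter == "G_over_P"], 0)
  expect_equal(vrz$mean[vrz$parameter == "GxE_over_P"], 0)
})

test_that("sire heritability is 4 sigma2_G / sigma2_P", {
  fit <- stub_rn_fit()
  expect_equal(sire_h2(fit)$mean, 4 * 0.756 / 17.14, tolerance = 1e-12)
  # boundary: sigma2_G = sigma2_P / 4 would give 1 (construct via h2 formula)
  expect_equal(animal_h2(1, 1, 1, 1), 0.25)
  expect_equal(animal_h2(0, 1, 1, 1), 0)
  # without GxE the composition excludes slope and covariance mass
  fit_no <- stub_rn_fit(with_gxe = FALSE)
  s2p_no <- 1.865 + 5.632 + 0.756 + 6.65
  expect_equal(sire_h2(fit_no)$mean, 4 * 0.756 / s2p_no)
})

test_that("EBVs along the gradient follow intercept + slope * x", {
  fit <- stub_rn_fit()
  e0 <- ebv_at_environment(fit, "s1", x = 0)
  expect_equal(e0$ebv, 1)
  e1 <- ebv_at_environment(fit, "s1", x = 1)
  expect_equal(e1$ebv, 1 + (-1))
  # re-ranking between environments: (1, -1) vs (0.5, 1) flip
  lo <- ebv_at_environment(fit, x = -1)
  hi <- ebv_at_environment(fit, x = 1)
  expect_equal(order(-lo$ebv), rev(order(-hi$ebv)))
  # midpoint equals the intercept exactly
  mid <- ebv_at_environment(fit, x = 0)
  expect_equal(mid$ebv, fit$sires$intercept)
  # without GxE the intercept is returned for every x
  fit_no <- stub_rn_fit(with_gxe = FALSE)
  expect_equal(ebv_at_environment(fit_no, "s1", x = 0.7)$ebv,
               fit_no$sires$intercept[1])
  expect_error(ebv_at_environment(fit, "nope", x = 0), "unknown sire")
})

test_that("EBV accuracy follows sqrt(1 - PEV / sigma2_G)", {
  sires <- tibble::tibble(sire_id = c("a", "b", "c"),
                          intercept = c(0.5, 0.2, 2),
                          intercept_sd = c(0, sqrt(0.75), 1),
                          slope = 0, slope_sd = 0)
  fit <- stub_rn_fit(g = 1, sires = sires)
  acc <- ebv_accuracy(fit)
  expect_equal(acc$accuracy[1], 1)           # PEV = 0
  expect_equal(acc$accuracy[2], 0.5)         # PEV = 0.75 sigma2_G
  expect_equal(acc$accuracy[3], 0)           # PEV = sigma2_G -> 0
  expect_false(any(acc$clamped[1:2]))

  # PEV > sigma2_G is clamped and flagged
  sires$intercept_sd[3] <- 2
  accc <- ebv_accuracy(stub_rn_fit(g = 1, sires = sires))
  expect_true(accc$clamped[3])
  expect_equal(accc$accuracy[3], 0)

  # literal published shortcut squares the EBV itself
  accl <- ebv_accuracy(stub_rn_fit(g = 1, sires = sires), method = "literal")
  expect_equal(accl$pev, sires$intercept^2)
})

test_that("ranking comparisons: Spearman and top-k bookkeeping", {
  mk <- function(ids, ebv) tibble::tibble(sire_id = ids, ebv = ebv)
  ids <- paste0("s", 1:5)
  same <- compare_rankings(mk(ids, 5:1), mk(ids, 5:1))
  expect_equal(same$spearman, 1)
  rev <- compare_rankings(mk(ids, 1:5), mk(ids, 5:1))
  expect_equal(rev$spearman, -1)
  # one adjacent swap on 5 items: 1 - 6*2/(5*24) = 0.9
  sw <- compare_rankings(mk(ids, c(5, 4, 3, 2, 1)), mk(ids, c(4, 5, 3, 2, 1)))
  expect_equal(sw$spearman, 0.9)
  expect_equal(sw$top_k, 5L)
  expect_equal(sw$top_overlap, 5L)
  expect_error(compare_rankings(mk(ids, 1:5), mk(paste0("t", 1:5), 1:5)),
               "common sires")
})

test_that("step 1 recovers the herd gradient from simulated data", {
  hb <- fixture_hb()
  s1 <- fixture_step1()
  truth <- hb$env$true_env[match(sub("\\..*$", "", s1$gradient$heg_level),
                                 hb$env$herd_id)]
  expect_gte(cor(s1$gradient$solution, truth, method = "spearman"), 0.9)
  expect_equal(range(s1$gradient$scaled_x), c(-1, 1))
  expect_gt(s1$h2, 0)
  expect_lt(s1$h2, 1)
  expect_equal(nrow(s1$normality), 1L)
})

test_that("step 2 structural contracts: slope chains only with GxE", {
  hb <- fixture_hb()
  s1 <- fixture_step1()
  ed <- fixture_edited()
  f_no <- fixture_rnfit(with_gxe = FALSE)
  expect_false("sire_sigma2_slope" %in% names(f_no$samples))
  expect_false("slope" %in% names(f_no$sires))
  expect_true("sigma2_sire" %in% names(f_no$samples))
  expect_equal(f_no$n_residual_classes, 5L)

  f_yes <- fixture_rnfit(with_gxe = TRUE)
  expect_true(all(c("sire_sigma2_int", "sire_sigma_int_slope",
                    "sire_sigma2_slope") %in% names(f_yes$samples)))
  expect_equal(dim(f_yes$G0), c(2L, 2L))
  # averaged residual equals the mean of the class variances
  expect_equal(f_yes$sigma2_e_mean,
               mean(colMeans(f_yes$samples[paste0("sigma2_e", 1:5)])))
  # records without sires are dropped with a warning
  ed_miss <- ed$data
  ed_miss$sire_id[1:5] <- "0"
  expect_warning(
    fit_reaction_norm(ed_miss[1:500, ], s1$gradient, hb$pedigree,
                      with_gxe = FALSE,
                      config = gibbs_config(400, 100, 2, seed = 1)),
    "without a sire")
})

test_that("tidiers expose the fitted quantities as tibbles", {
  f <- fixture_rnfit()
  td <- generics::tidy(f)
  expect_true(all(c("parameter", "mean", "se", "z", "p") %in% names(td)))
  gl <- generics::glance(f)
  expect_equal(gl$with_gxe, TRUE)
  expect_gt(gl$sigma2_P, 0)
})
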