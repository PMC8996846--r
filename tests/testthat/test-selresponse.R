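test_that("selection intensity matches the truncated-normal mean", {
  expect_equal(round(selection_intensity(0.10), 3), 1.755)
  expect_equal(selection_intensity(0.5), dnorm(0) / 0.5)
  expect_equal(round(selection_intensity(0.5), 3), 0.798)
  # numeric integration of the truncated-normal mean as an oracle
  for (p in c(0.05, 0.2, 0.5)) {
    z <- qnorm(1 - p)
    oracle <- integrate(function(u) u * dnorm(u), z, Inf)$value / p
    expect_equal(selection_intensity(p), oracle, tolerance = 1e-6)
  }
  # no selection: intensity tends to 0
  expect_lt(selection_intensity(0.9999), 0.01)
  expect_error(selection_intensity(0), "between 0 and 1")
  expect_error(selection_intensity(1.2), "between 0 and 1")
})

test_that("index specification and economic weights follow the emphasis splits", {
  em <- default_emphasis(c("PY", "FY", "UC", "MU", "ADG", "FLxDP", "SCS"))
  expect_equal(sum(em), 1)
  expect_equal(unname(em["PY"] / em["FY"]), 3)
  expect_equal(unname(em["UC"]), unname(em["MU"]))
  expect_equal(unname(em["ADG"] / 0.15), 0.45)
  expect_equal(unname(em["FLxDP"] / 0.15), 0.55)
  expect_equal(unname(em["SCS"]), 0)

  spec <- selection_index_spec(
    traits = c("PY", "FY", "SCS"),
    emphasis = c(PY = 0.75, FY = 0.25, SCS = 0),
    sigma_a = c(2, 1.5, 0.4),
    r_a = diag(3), r_p = diag(3), p = 0.1)
  a_s <- economic_weights(spec)
  expect_equal(unname(a_s), c(0.75 * 2, 0.25 * 1.5, 0))
  # sigma_a = 1 reduces weights to the emphasis itself
  spec1 <- selection_index_spec(traits = c("A", "B"), emphasis = c(0.5, 0.5),
                                sigma_a = c(1, 1), r_a = diag(2),
                                r_p = diag(2))
  expect_equal(unname(economic_weights(spec1)), c(0.5, 0.5))
  # default PY entry: 0.65 * 3/4 * sigma_a
  em_full <- default_emphasis(c("PY", "FY", "UC", "MU", "ADG", "FLxDP", "SCS"))
  expect_equal(unname(em_full["PY"]), 0.65 * 3 / 4)
})

test_that("G and P build from correlations and variances, with PD checks", {
  spec <- selection_index_spec(
    traits = c("t1", "t2"), emphasis = c(0.6, 0.4), sigma_a = c(2, 3),
    r_a = matrix(c(1, 0.5, 0.5, 1), 2), r_p = diag(2))
  mats <- build_matrices(spec, sigma2_a = c(4, 9), sigma2_p = c(10, 20))
  expect_equal(mats$G[1, 2], 0.5 * sqrt(4 * 9))
  expect_equal(mats$G[1, 2], 3)
  expect_equal(diag(mats$P), c(t1 = 10, t2 = 20))
  expect_equal(mats$P[1, 2], 0)

  # brute-force elementwise oracle on a random valid spec
  set.seed(22)
  nt <- 4
  R <- cov2cor(crossprod(matrix(rnorm(nt * nt), nt)))
  spec4 <- selection_index_spec(traits = paste0("t", 1:nt),
                                emphasis = rep(0.25, nt),
                                sigma_a = runif(nt, 0.5, 2),
                                r_a = R, r_p = R)
  v_a <- runif(nt, 0.2, 3); v_p <- v_a + runif(nt, 1, 3)
  mats4 <- build_matrices(spec4, v_a, v_p)
  for (i in 1:nt) for (j in 1:nt) {
    expect_equal(mats4$G[i, j], R[i, j] * sqrt(v_a[i] * v_a[j]))
    expect_equal(mats4$P[i, j], R[i, j] * sqrt(v_p[i] * v_p[j]))
  }

  # a correlation matrix that is not PD is reported with its minor
  bad_r <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3)
  spec_bad <- selection_index_spec(traits = c("a", "b", "c"),
                                   emphasis = rep(1 / 3, 3),
                                   sigma_a = rep(1, 3),
                                   r_a = bad_r, r_p = diag(3))
  expect_error(build_matrices(spec_bad, rep(1, 3), rep(2, 3)),
               "not positive definite")
})

test_that("single-trait response reduces to R = i h2 sigma_P", {
  h2 <- 0.25; s2p <- 4; i <- selection_intensity(0.10)
  G <- matrix(h2 * s2p, 1, 1); P <- matrix(s2p, 1, 1)
  res <- selection_response(G, P, a_s = 1, i = i)
  expect_equal(res$response$R, i * h2 * sqrt(s2p), tolerance = 1e-12)
  expect_equal(res$response$R, 0.8775, tolerance = 1e-4)
  expect_equal(res$response$R_dsi, i * h2)
  expect_error(selection_response(G, P, a_s = 0), "null selection index")
})

test_that("response is invariant to rescaling the economic weights", {
  set.seed(5)
  R <- cov2cor(crossprod(matrix(rnorm(9), 3)))
  G <- R * (sqrt(c(1, 2, 0.5)) %o% sqrt(c(1, 2, 0.5)))
  P <- R * (sqrt(c(3, 5, 2)) %o% sqrt(c(3, 5, 2)))
  a <- c(0.5, 0.3, 0.2)
  r1 <- selection_response(G, P, a)
  r2 <- selection_response(G, P, 17 * a)
  expect_equal(r1$response$R, r2$response$R, tolerance = 1e-12)
  expect_equal(r2$b, 17 * r1$b)
  expect_equal(r2$sigma_i, 17 * r1$sigma_i)
})

test_that("with proportional matrices the response matches the univariate formula", {
  h2 <- 0.3
  P <- diag(c(4, 9, 2.25))
  G <- h2 * P
  i <- selection_intensity(0.10)
  res <- selection_response(G, P, a_s = c(1, 1, 1), i = i)
  # uncorrelated traits: each behaves like a univariate index on b
  b <- h2 * c(1, 1, 1)
  sigma_i <- sqrt(sum(b^2 * diag(P)))
  expect_equal(res$response$R, (i / sigma_i) * h2 * diag(P) * b)
})

test_that("multi-trait responses agree with the truncation-selection Monte Carlo", {
  set.seed(42)
  for (rep in 1:3) {
    nt <- 3
    Ra <- cov2cor(crossprod(matrix(rnorm(nt * nt), nt)) + diag(nt))
    sa <- runif(nt, 0.5, 1.5)
    G <- Ra * (sa %o% sa)
    P <- G + diag(runif(nt, 1, 2))
    a_s <- runif(nt, 0.2, 1)
    i <- selection_intensity(0.10)
    res <- selection_response(G, P, a_s, i)
    mc <- mc_selection_oracle(G, P, a_s, p = 0.10, n = 200000L, seed = rep)
    # 3 simulation SEs per trait (SE of a selected-group mean)
    n_sel <- 20000
    se <- 3 * sqrt(diag(G)) / sqrt(n_sel) * 2
    expect_true(all(abs(res$response$R - mc) < pmax(se, 0.05 * abs(mc) + 1e-3)))
  }
})

test_that("per-environment wrapper evaluates each environment's matrices", {
  spec <- selection_index_spec(traits = c("milk", "adg"),
                               emphasis = c(0.7, 0.3), sigma_a = c(1, 1),
                               r_a = diag(2), r_p = diag(2))
  env_var <- tibble::tibble(
    environment = c("Plain", "Mountain"),
    sigma2_a = list(c(milk = 1.2, adg = 0.5), c(milk = 0.7, adg = 0.5)),
    sigma2_p = list(c(milk = 3, adg = 2), c(milk = 2.5, adg = 2)))
  out <- respond_by_environment(spec, env_var)
  expect_equal(nrow(out), 4L)
  # more genetic variance in the plain: larger milk response there
  expect_gt(out$R[out$environment == "Plain" & out$trait == "milk"],
            out$R[out$environment == "Mountain" & out$trait == "milk"])
})
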