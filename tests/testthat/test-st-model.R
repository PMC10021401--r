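# build a posterior_draws shell around given per-chain scalar draws so
# the summary/diagnostic machinery can be tested against known chains
fake_draws <- function(alpha_chains, factors = character()) {
  chains <- lapply(alpha_chains, function(a) {
    n <- length(a)
    list(alpha = a, beta = matrix(0, n, 0),
         w = matrix(0, n, 1), nu = matrix(0, n, 1), phi = matrix(0, n, 1),
         sigma_w = rep(1, n), sigma_nu1 = rep(1, n),
         sigma_t = rep(1, n), sigma_nu2 = rep(1, n))
  })
  structure(list(chains = chains, factors = factors, counties = "c01",
                 years = 2003L, spec = model_spec(factors),
                 config = mcmc_config_test()),
            class = "posterior_draws")
}

test_that("posterior summary matches Monte-Carlo oracle on iid chains", {
  set.seed(42)
  d <- fake_draws(list(rnorm(10000), rnorm(10000)))
  sm <- summarize_posterior(d)
  a <- sm[sm$parameter == "alpha", ]
  expect_equal(a$mean, 0, tolerance = 0.05)
  expect_equal(a$sd, 1, tolerance = 0.05)
  expect_equal(a$q2.5, qnorm(0.025), tolerance = 0.1)
  expect_equal(a$q97.5, qnorm(0.975), tolerance = 0.1)
  # iid draws: batch-means MCSE ~ sd/sqrt(N_total)
  expect_equal(a$mc_error, 1 / sqrt(20000), tolerance = 0.5)
})

test_that("identical chains give a Gelman statistic of exactly zero", {
  set.seed(7)
  x <- rnorm(500)
  sm <- summarize_posterior(fake_draws(list(x, x)))
  expect_identical(sm$gelman_pct[sm$parameter == "alpha"], 0)
})

test_that("constant chains give zero SD and zero MC error", {
  sm <- summarize_posterior(fake_draws(list(rep(2, 100), rep(2, 100))))
  a <- sm[sm$parameter == "alpha", ]
  expect_identical(a$sd, 0)
  expect_identical(a$mc_error, 0)
  expect_identical(a$mc_ratio_pct, 0)
  expect_identical(a$gelman_pct, 0)
})

test_that("Gelman statistic agrees with the coda reference", {
  # displaced chains: genuine between-chain variance, PSRF > 1
  set.seed(13)
  c1 <- as.vector(arima.sim(list(ar = 0.6), 2000)) + 0.5
  c2 <- as.vector(arima.sim(list(ar = 0.6), 2000))
  sm <- summarize_posterior(fake_draws(list(c1, c2)))
  ours <- 1 + sm$gelman_pct[sm$parameter == "alpha"] / 100
  ref <- coda::gelman.diag(
    coda::mcmc.list(coda::mcmc(c1), coda::mcmc(c2)),
    autoburnin = FALSE)$psrf[1, 1]
  # coda applies a d.f. correction to the PSRF; agree within a few percent
  expect_equal(ours, unname(ref), tolerance = 0.05)
})

test_that("single-chain summaries are refused", {
  d <- fake_draws(list(rnorm(100), rnorm(100)))
  d$chains <- d$chains[1]
  expect_error(summarize_posterior(d), "single chain")
})

test_that("convergence gate applies both thresholds per parameter", {
  sm <- data.frame(parameter = c("a", "b", "c"),
                   gelman_pct = c(0, 6, 1),
                   mc_ratio_pct = c(0, 1, 7))
  res <- check_convergence(sm)
  expect_false(res$overall)
  expect_equal(res$table$pass, c(TRUE, FALSE, FALSE))
  expect_true(check_convergence(sm, 10, 10)$overall)
})

test_that("fit approaches the OLS solution when random effects vanish", {
  sim <- quick_sim(n = 12, years = 2003:2010, seed = 8,
                   beta = c(f1 = -1.5, f2 = 1), sigma_w = 0.01,
                   sigma_nu = 0, sigma_t = 0.01, sigma_delta = 0.05)
  draws <- fit_st_model(sim$panel, sim$adjacency,
                        model_spec(c("f1", "f2")),
                        mcmc_config_test(n_iter = 2000, burn_in = 500,
                                         seed = 2))
  sm <- summarize_posterior(draws)
  ols <- coef(lm(log(u5m / 1000) ~ f1 + f2, data = sim$panel))
  expect_equal(sm$mean[sm$parameter == "f1"], unname(ols["f1"]),
               tolerance = 0.05)
  expect_equal(sm$mean[sm$parameter == "f2"], unname(ols["f2"]),
               tolerance = 0.05)
})

test_that("draws are deterministic under a fixed seed", {
  sim <- quick_sim(n = 8, years = 2003:2007, seed = 3)
  cfg <- mcmc_config_test(n_iter = 400, burn_in = 100, seed = 5)
  spec <- model_spec(c("f1", "f2"))
  d1 <- fit_st_model(sim$panel, sim$adjacency, spec, cfg)
  d2 <- fit_st_model(sim$panel, sim$adjacency, spec, cfg)
  expect_identical(d1$chains[[1]]$alpha, d2$chains[[1]]$alpha)
  expect_identical(d1$chains[[2]]$beta, d2$chains[[2]]$beta)
  expect_identical(d1$chains[[1]]$sigma_w, d2$chains[[1]]$sigma_w)
})

test_that("structural invariants hold on fitted draws", {
  sim <- quick_sim(n = 10, years = 2003:2008, seed = 6)
  draws <- fit_st_model(sim$panel, sim$adjacency, model_spec(c("f1", "f2")),
                        mcmc_config_test(n_iter = 600, burn_in = 200, seed = 1),
                        store_delta = TRUE)
  # ICAR constraint at every retained iteration
  for (ch in draws$chains) {
    expect_lt(max(abs(rowSums(ch$w))), 1e-10)
    expect_lt(max(abs(rowSums(ch$phi))), 1e-10)
    expect_true(all(ch$sigma_w > 0 & ch$sigma_nu1 > 0 &
                      ch$sigma_t > 0 & ch$sigma_nu2 > 0))
  }
  # pooled mean equals the average of per-chain means exactly
  sm <- summarize_posterior(draws)
  per_chain <- sapply(draws$chains, function(ch) mean(ch$alpha))
  expect_equal(sm$mean[sm$parameter == "alpha"], mean(per_chain),
               tolerance = 1e-12)
})

test_that("fit validates panel completeness and graph connectivity", {
  sim <- quick_sim(n = 6, years = 2003:2006, seed = 2)
  spec <- model_spec(c("f1", "f2"))
  expect_error(fit_st_model(sim$panel[-1, ], sim$adjacency, spec,
                            mcmc_config_test()), "every county-year")
  disconnected <- u5mproj:::new_adjacency(
    6L, matrix(c(1L, 2L, 3L, 4L, 5L, 6L), ncol = 2, byrow = TRUE))
  expect_error(fit_st_model(sim$panel, disconnected, spec,
                            mcmc_config_test()), "connected")
  expect_error(fit_st_model(sim$panel, sim$adjacency,
                            model_spec(c("f1", "zz")), mcmc_config_test()),
               "lacks model factors")
})

test_that("posterior level alpha + mean(X beta) is centering-invariant", {
  sim <- quick_sim(n = 10, years = 2003:2008, seed = 12,
                   beta = c(f1 = -1, f2 = 0.8))
  cfg <- mcmc_config_test(n_iter = 1500, burn_in = 500, seed = 4)
  spec <- model_spec(c("f1", "f2"))
  d_raw <- fit_st_model(sim$panel, sim$adjacency, spec, cfg)
  centred <- sim$panel
  mns <- c(f1 = mean(centred$f1), f2 = mean(centred$f2))
  centred$f1 <- centred$f1 - mns["f1"]
  centred$f2 <- centred$f2 - mns["f2"]
  d_ctr <- fit_st_model(centred, sim$adjacency, spec, cfg)
  level <- function(d, shift) {
    sm <- summarize_posterior(d)
    sm$mean[sm$parameter == "alpha"] +
      sum(shift * sm$mean[match(c("f1", "f2"), sm$parameter)])
  }
  expect_equal(level(d_raw, mns), level(d_ctr, c(0, 0)), tolerance = 0.05)
})

test_that("estimated spatial scale tracks the simulated spatial signal", {
  est_sw <- function(sw, seed) {
    sim <- quick_sim(n = 16, years = 2003:2008, seed = seed, sigma_w = sw,
                     sigma_nu = 0.02, sigma_t = 0.02, sigma_delta = 0.1)
    d <- fit_st_model(sim$panel, sim$adjacency, model_spec(c("f1", "f2")),
                      mcmc_config_test(n_iter = 1200, burn_in = 400,
                                       seed = seed))
    sm <- summarize_posterior(d)
    sm$mean[sm$parameter == "sigma_w"]
  }
  ordered <- vapply(1:5, function(s) est_sw(0.5, s) > est_sw(0.1, s + 100),
                    logical(1))
  expect_gte(sum(ordered), 4)
})

test_that("pruning removes decoy factors and keeps real ones", {
  sim <- quick_sim(n = 14, years = 2003:2010, seed = 9,
                   beta = c(f1 = -1.5, decoy = 0), sigma_w = 0.1,
                   sigma_nu = 0.02, sigma_t = 0.02, sigma_delta = 0.1)
  cfg <- mcmc_config_test(n_iter = 1200, burn_in = 400, seed = 9)
  draws <- fit_st_model(sim$panel, sim$adjacency,
                        model_spec(c("f1", "decoy")), cfg)
  pruned <- prune_nonsignificant(draws, sim$panel, sim$adjacency, cfg)
  expect_true("f1" %in% pruned$factors)
  expect_false("decoy" %in% pruned$factors)
  # already-clean fits come back unchanged
  clean <- prune_nonsignificant(pruned$draws, sim$panel, sim$adjacency, cfg)
  expect_identical(clean$dropped, character(0))
  expect_identical(clean$draws$chains[[1]]$alpha,
                   pruned$draws$chains[[1]]$alpha)
})
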