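test_that("bivariate screen recovers exact slopes on noise-free data", {
  # log(y) = 2x exactly
  x <- seq(0.1, 0.9, length.out = 20)
  panel <- data.frame(u5m = exp(2 * x), x = x)
  # lm warns about the perfect fit; the exactness is the point here
  res <- suppressWarnings(bivariate_screen(panel, "x"))
  expect_equal(res$coefficient, 2, tolerance = 1e-10)
  expect_lt(res$p_value, 1e-12)
  expect_true(res$passes)

  # 3-point closed-form OLS slope
  panel3 <- data.frame(u5m = exp(0:2), x = c(0, 1, 2))
  expect_equal(suppressWarnings(bivariate_screen(panel3, "x"))$coefficient,
               1, tolerance = 1e-12)

  expect_error(bivariate_screen(data.frame(u5m = 1:5, x = rep(1, 5)), "x"),
               "degenerate")
  expect_error(bivariate_screen(panel, "nope"), "unknown factor")
})

test_that("screen type-I rate at p<0.2 matches its nominal level", {
  # pure-noise factor: Monte-Carlo rejection rate ~ Binomial(200, 0.2)
  set.seed(2024)
  hits <- vapply(1:200, function(i) {
    panel <- data.frame(u5m = exp(rnorm(500)), x = runif(500))
    bivariate_screen(panel, "x", 0.2)$passes
  }, logical(1))
  expect_gte(mean(hits), 0.14)
  expect_lte(mean(hits), 0.26)
})

test_that("redundancy exclusions respect umbrella retention and cycles", {
  map <- c(dtp3 = "fully_immunised")
  expect_equal(apply_redundancy_exclusions(c("dtp3", "fully_immunised"), map),
               "fully_immunised")
  expect_equal(apply_redundancy_exclusions(c("a", "b"), c()), c("a", "b"))
  # umbrella absent from the screened set: mapped factor survives
  expect_equal(apply_redundancy_exclusions(c("dtp3", "water"), map),
               c("dtp3", "water"))
  expect_error(apply_redundancy_exclusions("a", c(a = "b", b = "a")), "cycle")
})

test_that("ANC index matches the two-variable eigen closed form", {
  set.seed(9)
  z <- rnorm(120)
  panel <- data.frame(a = z, b = 0.6 * z + 0.8 * rnorm(120))
  idx <- build_anc_index(panel, c("a", "b"))
  # eigenvalues of a 2x2 correlation matrix are 1 +/- |r|
  r <- cor(panel$a, panel$b)
  expect_equal(idx$explained_var, (1 + abs(r)) / 2, tolerance = 1e-10)
  expect_equal(mean(idx$index), 0, tolerance = 1e-12)
  expect_equal(sd(idx$index), 1, tolerance = 1e-12)
  # positively oriented against the component mean
  expect_gt(cor(idx$index, rowMeans(scale(panel))), 0)

  # perfectly correlated pair: index equals either standardised column
  panel2 <- data.frame(a = z, b = 2 * z + 3)
  idx2 <- build_anc_index(panel2, c("a", "b"))
  expect_equal(abs(cor(idx2$index, z)), 1, tolerance = 1e-10)

  # loadings invariant to component order (up to the same permutation)
  idx_rev <- build_anc_index(panel, c("b", "a"))
  expect_equal(idx_rev$loadings[c("a", "b")], idx$loadings[c("a", "b")],
               tolerance = 1e-10)
  expect_error(build_anc_index(data.frame(a = rep(1, 10), b = rnorm(10)),
                               c("a", "b")), "degenerate")
})

test_that("elastic net recovers OLS at zero penalty and shrinks fully", {
  set.seed(21)
  n <- 120
  X <- scale(matrix(rnorm(n * 4), n, 4))
  colnames(X) <- paste0("v", 1:4)
  btrue <- c(1.5, -2, 0.8, 0)
  y <- as.vector(X %*% btrue)   # noise-free: CV must prefer lambda = 0
  cfg <- screening_config(enr_alpha_grid = 1,
                          enr_lambda_grid = c(0.5, 0.1, 0.01, 0),
                          cv_folds = 5)
  set.seed(1)
  fid <- sample(rep(1:5, length.out = n))
  res <- elastic_net_select(X, y, cfg, foldid = fid)
  expect_equal(res$lambda, 0)
  ols <- coef(lm(y ~ X))[-1]
  expect_equal(unname(res$coefficients), unname(ols), tolerance = 1e-6)

  # huge penalty zeroes every slope
  cfg_big <- screening_config(enr_alpha_grid = 1, enr_lambda_grid = c(1e6, 1e5),
                              cv_folds = 5)
  res_big <- elastic_net_select(X, y + rnorm(n), cfg_big, foldid = fid)
  expect_equal(length(res_big$retained), 0)
  expect_error(elastic_net_select(X[1:3, ], y[1:3], cfg), "fewer rows")
})

test_that("lasso on an orthonormal design equals soft-thresholded OLS", {
  set.seed(33)
  n <- 64
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(n * 5), n, 5))))[, -1]
  X <- Q * sqrt(n)                 # crossprod(X)/n = I, columns sum to 0
  colnames(X) <- paste0("v", 1:5)
  btrue <- c(2, -1, 0.4, 0, 0)
  y <- as.vector(X %*% btrue) + rnorm(n, 0, 0.3)
  lam <- 0.3
  cfg <- screening_config(enr_alpha_grid = 1, enr_lambda_grid = c(lam),
                          cv_folds = 4)
  set.seed(2)
  res <- elastic_net_select(X, y, cfg,
                            foldid = sample(rep(1:4, length.out = n)))
  b_ols <- as.vector(crossprod(X, y - mean(y)) / n)
  soft <- sign(b_ols) * pmax(abs(b_ols) - lam, 0)
  expect_equal(unname(res$coefficients), soft, tolerance = 1e-6)
})

test_that("retained set never gains variables as the penalty grows", {
  # orthonormal design: each variable's lasso activity is monotone in
  # lambda, so the retained set can only shrink as the penalty grows
  set.seed(5)
  n <- 60
  X <- qr.Q(qr(cbind(1, matrix(rnorm(n * 2), n, 2))))[, -1] * sqrt(n)
  colnames(X) <- c("v1", "v2")
  y <- as.vector(X %*% c(1.2, 0.15)) + rnorm(n, 0, 0.5)
  lams <- c(2, 1, 0.5, 0.1, 0.01)
  cfg4 <- function(l) screening_config(enr_alpha_grid = 1,
                                       enr_lambda_grid = c(l), cv_folds = 4)
  set.seed(6)
  fid <- sample(rep(1:4, length.out = n))
  active <- t(vapply(lams, function(l) {
    elastic_net_select(X, y, cfg4(l), foldid = fid)$coefficients != 0
  }, logical(2)))
  # once inactive at a small lambda, never active at any larger one
  for (j in 1:2) expect_true(all(diff(as.integer(active[, j])) >= 0))
})

test_that("paired models prefer the index when it drives mortality", {
  make_panel <- function(seed) {
    set.seed(seed)
    n_cty <- 20; T_ <- 6
    id <- rep(sprintf("c%02d", 1:n_cty), each = T_)
    latent <- rnorm(n_cty * T_)            # shared ANC quality signal
    mk <- function(w) plogis(0.3 * latent + rnorm(n_cty * T_, 0, w))
    panel <- data.frame(
      county_id = id, year = rep(2003:2008, n_cty),
      anc4 = mk(0.8), iron_supplement = mk(0.5),
      tetanus_injection = mk(0.5), vitamin_a = mk(0.5),
      other = runif(n_cty * T_), stringsAsFactors = FALSE
    )
    panel$u5m <- 1000 * exp(-3 - 0.8 * latent + rnorm(n_cty * T_, 0, 0.15))
    panel
  }
  cfg <- screening_config(enr_alpha_grid = c(0.5, 1), cv_folds = 5, seed = 3)
  wins <- vapply(1:10, function(s) {
    run_model_pair(make_panel(s), cfg)$chosen_model == 2L
  }, logical(1))
  expect_gte(sum(wins), 7)
})

test_that("paired models keep truly active factors on synthetic panels", {
  active <- c(anc4 = -0.8, fever = -1.2, water = -0.5)
  make_panel <- function(seed) {
    adj <- make_adjacency(30, seed = seed)
    cfg <- synth_config(
      n_counties = 30, years = 2003:2010, seed = seed,
      factor_names = c(names(active), "iron_supplement",
                       "tetanus_injection", "vitamin_a", "d1", "d2"),
      true_beta = c(active, iron_supplement = 0, tetanus_injection = 0,
                    vitamin_a = 0, d1 = 0, d2 = 0),
      sigma_w = 0.1, sigma_nu = 0.02, sigma_t = 0.02, sigma_delta = 0.1,
      overrides = list()
    )
    simulate_panel(cfg, adj)$panel
  }
  cfg <- screening_config(enr_alpha_grid = c(0.5, 1), cv_folds = 5)
  hits <- vapply(1:10, function(s) {
    res <- run_model_pair(make_panel(s), cfg)
    all(names(active) %in% res$retained)
  }, logical(1))
  expect_gte(sum(hits), 8)
  expect_error(
    run_model_pair(data.frame(county_id = "a", year = 1, u5m = 1, x = 1)),
    "ANC columns")
})
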