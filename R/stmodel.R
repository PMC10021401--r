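#' Specification of the spatio-temporal ecological model
#'
#' The model for the log under-five mortality rate is
#' \deqn{\log(U5M_{i,t}/1000) = \alpha + \sum_k \beta_k x_{k,i,t} + w_i +
#'   \nu_i + \phi_t + \delta_{i,t}}
#' with `w` an intrinsic CAR (ICAR) field on the county adjacency graph
#' (structured spatial effect, SD `sigma_w`), `nu` iid county effects
#' (unstructured spatial, SD `sigma_nu1`), `phi` a first-order random
#' walk over years constrained to sum to zero (temporal, SD `sigma_t`),
#' and `delta` the iid space-time interaction which doubles as the
#' residual (SD `sigma_nu2`) — the model carries exactly four variance
#' components and no separate observation noise.
#'
#' Priors: `alpha`, `beta ~ N(0, 10^2)`; each scale parameter is
#' half-Normal with scale `prior_sd_scale`.
#'
#' @param factors Ordered character vector of proportion-scale covariate
#'   columns.
#' @param spatial_structured,spatial_unstructured,temporal Logical flags
#'   switching the corresponding random effect on (default all `TRUE`).
#' @param prior_sd_scale Scale of the half-Normal priors on the SDs.
#' @return A list of class `"model_spec"`.
#' @export
model_spec <- function(factors,
                       spatial_structured = TRUE,
                       spatial_unstructured = TRUE,
                       temporal = TRUE,
                       prior_sd_scale = 5) {
  stopifnot(prior_sd_scale > 0)  # empty `factors` = intercept-only model
  structure(list(factors = factors,
                 spatial_structured = isTRUE(spatial_structured),
                 spatial_unstructured = isTRUE(spatial_unstructured),
                 temporal = isTRUE(temporal),
                 prior_sd_scale = prior_sd_scale),
            class = "model_spec")
}

#' MCMC configuration
#'
#' Defaults mirror the full analysis scale (2 chains of 25,000
#' iterations with 5,000 burn-in); [mcmc_config_test()] gives the
#' reduced scale used throughout the test suite.
#'
#' @param n_chains Number of chains (>= 2 for convergence diagnostics).
#' @param n_iter Total iterations per chain, burn-in included.
#' @param burn_in Iterations discarded per chain (< `n_iter`).
#' @param thin Keep every `thin`-th post-burn-in draw.
#' @param seed Integer seed; chain `c` runs under `seed + c - 1`.
#' @return A list of class `"mcmc_config"`.
#' @export
mcmc_config <- function(n_chains = 2L, n_iter = 25000L, burn_in = 5000L,
                        thin = 1L, seed = 1L) {
  stopifnot(burn_in < n_iter, n_chains >= 1, thin >= 1)
  structure(list(n_chains = as.integer(n_chains),
                 n_iter = as.integer(n_iter),
                 burn_in = as.integer(burn_in),
                 thin = as.integer(thin), seed = as.integer(seed)),
            class = "mcmc_config")
}

#' @rdname mcmc_config
#' @param ... Overrides passed to [mcmc_config()].
#' @export
mcmc_config_test <- function(...) {
  args <- utils::modifyList(list(n_chains = 2L, n_iter = 3000L,
                                 burn_in = 1000L, seed = 1L), list(...))
  do.call(mcmc_config, args)
}

#' Fit the Bayesian spatio-temporal model by MCMC
#'
#' Blocked Metropolis-within-Gibbs sampler. The ICAR and RW1 fields are
#' parameterised in the eigenbasis of their structure matrices (graph
#' Laplacian and path-graph Laplacian), where the improper priors become
#' independent normals on the non-null eigendirections and the
#' sum-to-zero constraints hold exactly by construction. All location
#' parameters — intercept, fixed effects, spatial and temporal
#' coefficients — are then drawn *jointly* from their conjugate
#' multivariate-normal full conditional with the iid county effect
#' integrated out analytically (its covariance contribution is a
#' rank-one block per county), which removes the cross-correlation
#' between fixed and random effects that otherwise dominates the
#' autocorrelation time. The four scale parameters move by random-walk
#' Metropolis on the log scale (the unstructured-county scale with its
#' effects collapsed, avoiding the near-zero funnel), with step sizes
#' adapted during burn-in only.
#'
#' @param panel Complete county-year panel (every county observed in
#'   every year) with `u5m` and all `spec$factors` columns on the
#'   proportion scale.
#' @param adjacency Connected [make_adjacency()] graph.
#' @param spec A [model_spec()].
#' @param config A [mcmc_config()].
#' @param store_delta Keep per-draw residual (interaction) fields;
#'   disable to save memory on long runs.
#' @return Object of class `"posterior_draws"`: per-chain draws of
#'   `alpha`, `beta`, `w`, `nu`, `phi`, the four sigmas and optionally
#'   `delta`, plus index metadata.
#' @export
fit_st_model <- function(panel, adjacency, spec, config = mcmc_config(),
                         store_delta = TRUE) {
  stopifnot(inherits(adjacency, "county_adjacency"),
            inherits(spec, "model_spec"), inherits(config, "mcmc_config"))
  counties <- sort(unique(panel$county_id))
  years <- sort(unique(panel$year))
  n <- length(counties)
  T_ <- length(years)
  if (n != adjacency$n) stop("adjacency does not match panel counties", call. = FALSE)
  if (nrow(panel) != n * T_ ||
      any(table(panel$county_id, panel$year) != 1)) {
    stop("panel must contain every county-year exactly once", call. = FALSE)
  }
  if (max(components_of(adjacency$n, adjacency$edges)) != 1L) {
    stop("adjacency graph must be connected", call. = FALSE)
  }
  missing <- setdiff(spec$factors, names(panel))
  if (length(missing)) {
    stop("panel lacks model factors: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }

  ord <- order(match(panel$county_id, counties), panel$year)
  panel <- panel[ord, , drop = FALSE]
  y <- log(panel$u5m / 1000)
  X <- as.matrix(panel[, spec$factors, drop = FALSE])
  ci <- match(panel$county_id, counties)   # rows grouped by county,
  ti <- match(panel$year, years)           # year fastest within county

  chains <- lapply(seq_len(config$n_chains), function(ch) {
    run_st_chain(y, X, ci, ti, n, T_, adjacency, spec, config,
                 chain_id = ch, store_delta = store_delta)
  })
  structure(list(chains = chains, factors = spec$factors,
                 counties = counties, years = years, spec = spec,
                 config = config),
            class = "posterior_draws")
}

run_st_chain <- function(y, X, ci, ti, n, T_, adjacency, spec, config,
                         chain_id, store_delta) {
  old <- local_seed(config$seed + chain_id - 1L)
  on.exit(restore_seed(old))
  N <- length(y)
  K <- ncol(X)
  ps <- spec$prior_sd_scale
  half_norm_lp <- function(s) -s^2 / (2 * ps^2)

  # eigenbases of the improper priors: ICAR field on the Laplacian's
  # non-null eigendirections, RW1 on the path-graph Laplacian's
  use_w <- spec$spatial_structured
  use_nu <- spec$spatial_unstructured
  use_t <- spec$temporal
  if (use_w) {
    A <- matrix(0, n, n)
    A[adjacency$edges] <- 1
    A <- A + t(A)
    eg <- eigen(diag(rowSums(A)) - A, symmetric = TRUE)
    Vw <- eg$vectors[, seq_len(n - 1L), drop = FALSE]
    lam_w <- eg$values[seq_len(n - 1L)]
  } else {
    Vw <- matrix(0, n, 0); lam_w <- numeric()
  }
  if (use_t) {
    Lt <- diag(c(1, rep(2, T_ - 2L), 1))
    Lt[cbind(seq_len(T_ - 1L), 2:T_)] <- -1
    Lt[cbind(2:T_, seq_len(T_ - 1L))] <- -1
    eg <- eigen(Lt, symmetric = TRUE)
    Vt <- eg$vectors[, seq_len(T_ - 1L), drop = FALSE]
    lam_t <- eg$values[seq_len(T_ - 1L)]
  } else {
    Vt <- matrix(0, T_, 0); lam_t <- numeric()
  }

  # combined location design: intercept, fixed effects, spatial and
  # temporal eigen-coefficients
  U <- cbind(1, X, Vw[ci, , drop = FALSE], Vt[ti, , drop = FALSE])
  p <- ncol(U)
  i_theta <- seq_len(K + 1L)
  i_w <- if (use_w) (K + 1L) + seq_len(n - 1L) else integer()
  i_t <- if (use_t) (K + 1L + length(i_w)) + seq_len(T_ - 1L) else integer()
  UtU <- crossprod(U)
  Uty <- crossprod(U, y)
  Bc <- rowsum(U, ci)        # county-summed design rows (n x p)
  BtB <- crossprod(Bc)
  yc <- as.vector(rowsum(y, ci))
  Bty <- crossprod(Bc, yc)
  Syy_c <- sum(y^2)

  s_w <- if (use_w) 0.2 * chain_id else 0
  s_nu <- if (use_nu) 0.05 * chain_id else 0
  s_t <- if (use_t) 0.05 * chain_id else 0
  s_d <- 0.2 * chain_id
  nu <- rep(0, n)
  b <- rep(0, p)

  step <- c(w = 0.4, nu = 0.6, t = 0.6, d = 0.15)
  acc <- c(w = 0, nu = 0, t = 0, d = 0)

  n_keep <- (config$n_iter - config$burn_in) %/% config$thin
  draws <- list(
    alpha = numeric(n_keep), beta = matrix(NA_real_, n_keep, K),
    w = matrix(NA_real_, n_keep, n), nu = matrix(NA_real_, n_keep, n),
    phi = matrix(NA_real_, n_keep, T_),
    sigma_w = numeric(n_keep), sigma_nu1 = numeric(n_keep),
    sigma_t = numeric(n_keep), sigma_nu2 = numeric(n_keep),
    delta = if (store_delta) matrix(NA_real_, n_keep, N)
  )
  colnames(draws$beta) <- colnames(X)
  kept <- 0L

  # log marginal likelihood of y given the four scales, with the whole
  # location vector b and the iid county effect nu integrated out.
  # Error covariance is block-diagonal per county, s_d^2 I + s_nu^2 J,
  # entering through the rank-one Woodbury correction cc * B'B; the
  # b-integral uses the matrix determinant lemma, so the evidence needs
  # only the same Cholesky factor the conditional b-draw uses.
  evidence <- function(s_w, s_nu, s_t, s_d) {
    cc <- if (use_nu) s_nu^2 / (s_d^2 * (s_d^2 + T_ * s_nu^2)) else 0
    prior_prec <- c(rep(1 / 100, K + 1L),
                    if (use_w) lam_w / s_w^2,
                    if (use_t) lam_t / s_t^2)
    M <- UtU / s_d^2 - cc * BtB
    diag(M) <- diag(M) + prior_prec
    ch <- tryCatch(chol(M), error = function(e) NULL)
    if (is.null(ch)) return(list(lp = -Inf))
    rhs <- Uty / s_d^2 - cc * Bty
    mu <- backsolve(ch, forwardsolve(t(ch), rhs))
    quad <- (Syy_c / s_d^2 - cc * sum(yc^2)) - sum(rhs * mu)
    logdet_Sig <- if (use_nu) {
      n * (T_ - 1) * log(s_d^2) + n * log(s_d^2 + T_ * s_nu^2)
    } else N * log(s_d^2)
    lp <- -0.5 * (logdet_Sig + 2 * sum(log(diag(ch))) -
                    sum(log(prior_prec)) + quad)
    list(lp = lp, ch = ch, mu = mu)
  }

  ev <- evidence(s_w, s_nu, s_t, s_d)

  n_sweeps <- 3L  # scale-block sweeps per iteration; each is one cheap
                  # Cholesky per proposal, and the extra sweeps keep the
                  # scale parameters' Monte Carlo error well below the
                  # diagnostics gate
  for (it in seq_len(config$n_iter)) {
    # marginal Metropolis sweeps over the scales (log-scale random walk,
    # half-Normal priors, Jacobian included)
    for (sw in seq_len(n_sweeps)) {
    if (use_w) {
      prop <- s_w * exp(step["w"] * stats::rnorm(1))
      cand <- evidence(prop, s_nu, s_t, s_d)
      lr <- cand$lp - ev$lp + half_norm_lp(prop) - half_norm_lp(s_w) +
        log(prop) - log(s_w)
      if (log(stats::runif(1)) < lr) { s_w <- prop; ev <- cand; acc["w"] <- acc["w"] + 1 }
    }
    if (use_nu) {
      prop <- s_nu * exp(step["nu"] * stats::rnorm(1))
      cand <- evidence(s_w, prop, s_t, s_d)
      lr <- cand$lp - ev$lp + half_norm_lp(prop) - half_norm_lp(s_nu) +
        log(prop) - log(s_nu)
      if (log(stats::runif(1)) < lr) { s_nu <- prop; ev <- cand; acc["nu"] <- acc["nu"] + 1 }
    }
    if (use_t) {
      prop <- s_t * exp(step["t"] * stats::rnorm(1))
      cand <- evidence(s_w, s_nu, prop, s_d)
      lr <- cand$lp - ev$lp + half_norm_lp(prop) - half_norm_lp(s_t) +
        log(prop) - log(s_t)
      if (log(stats::runif(1)) < lr) { s_t <- prop; ev <- cand; acc["t"] <- acc["t"] + 1 }
    }
    prop <- s_d * exp(step["d"] * stats::rnorm(1))
    cand <- evidence(s_w, s_nu, s_t, prop)
    lr <- cand$lp - ev$lp + half_norm_lp(prop) - half_norm_lp(s_d) +
      log(prop) - log(s_d)
    if (log(stats::runif(1)) < lr) { s_d <- prop; ev <- cand; acc["d"] <- acc["d"] + 1 }
    }

    # b | sigmas, y (nu collapsed): N(mu, M^-1) via the cached Cholesky
    b <- as.vector(ev$mu + backsolve(ev$ch, stats::rnorm(p)))
    eta <- as.vector(U %*% b)      # all effects except nu

    # nu | b, sigmas
    if (use_nu) {
      rc <- yc - as.vector(Bc %*% b)   # per-county residual sums
      prec <- T_ / s_d^2 + 1 / s_nu^2
      nu <- stats::rnorm(n, (rc / s_d^2) / prec, sqrt(1 / prec))
    }
    e <- y - eta - nu[ci]

    # step adaptation in batches of 50 iterations, burn-in only
    if (it <= config$burn_in && it %% 50L == 0L) {
      rate <- acc / (50 * n_sweeps)
      step <- step * ifelse(rate > 0.44, 1.15, 1 / 1.15)
      acc[] <- 0
    }

    if (it > config$burn_in && (it - config$burn_in) %% config$thin == 0L) {
      kept <- kept + 1L
      draws$alpha[kept] <- b[1]
      draws$beta[kept, ] <- b[i_theta][-1]
      draws$w[kept, ] <- if (use_w) as.vector(Vw %*% b[i_w]) else rep(0, n)
      draws$nu[kept, ] <- nu
      draws$phi[kept, ] <- if (use_t) as.vector(Vt %*% b[i_t]) else rep(0, T_)
      draws$sigma_w[kept] <- s_w
      draws$sigma_nu1[kept] <- s_nu
      draws$sigma_t[kept] <- s_t
      draws$sigma_nu2[kept] <- s_d
      if (store_delta) draws$delta[kept, ] <- e
    }
  }
  draws
}

#' @export
print.posterior_draws <- function(x, ...) {
  n_keep <- length(x$chains[[1]]$alpha)
  cat("posterior draws:", length(x$chains), "chains x", n_keep,
      "retained iterations;", length(x$factors), "fixed effects,",
      length(x$counties), "counties,", length(x$years), "years\n")
  invisible(x)
}

# draws of one scalar parameter as an (iterations x chains) matrix
param_matrix <- function(draws, name) {
  sapply(draws$chains, function(chain) {
    if (name %in% names(chain)) return(chain[[name]])
    chain$beta[, name]
  })
}

#' Posterior summary with convergence diagnostics
#'
#' Pooled post-burn-in mean, empirical 2.5/97.5% quantiles and SD per
#' parameter, with the Monte Carlo standard error estimated by batch
#' means (batch size `floor(sqrt(N))` per chain) and the Gelman-Rubin
#' statistic reported on the percentage scale `(PSRF - 1) * 100`
#' (floored at 0, so identical chains give exactly 0%).
#'
#' @param draws A [fit_st_model()] result with >= 2 chains.
#' @return data.frame with one row per parameter (intercept, fixed
#'   effects, four sigmas) and columns `mean`, `q2.5`, `q97.5`, `sd`,
#'   `mc_error`, `mc_ratio_pct`, `gelman_pct`.
#' @export
summarize_posterior <- function(draws) {
  stopifnot(inherits(draws, "posterior_draws"))
  if (length(draws$chains) < 2) {
    stop("Gelman diagnostic undefined for a single chain", call. = FALSE)
  }
  params <- c("alpha", draws$factors,
              "sigma_w", "sigma_nu1", "sigma_t", "sigma_nu2")
  rows <- lapply(params, function(p) {
    m <- param_matrix(draws, p)
    pooled <- as.vector(m)
    mc <- mc_error_batch(m)
    s <- stats::sd(pooled)
    data.frame(parameter = p, mean = mean(pooled),
               q2.5 = unname(stats::quantile(pooled, 0.025)),
               q97.5 = unname(stats::quantile(pooled, 0.975)),
               sd = s, mc_error = mc,
               mc_ratio_pct = if (s > 0) 100 * mc / s else 0,
               gelman_pct = gelman_pct(m),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# batch-means MCSE pooled over chains (pooled mean averages chain means)
mc_error_batch <- function(m) {
  per_chain <- apply(m, 2, function(x) {
    n <- length(x)
    b <- max(2L, floor(sqrt(n)))
    nb <- n %/% b
    bm <- colMeans(matrix(x[seq_len(nb * b)], nrow = b))
    if (stats::sd(x) == 0) return(0)
    stats::sd(bm) / sqrt(nb)
  })
  sqrt(mean(per_chain^2) / length(per_chain))
}

# two-(or m-)chain potential scale reduction factor on the % scale
gelman_pct <- function(m) {
  n <- nrow(m); k <- ncol(m)
  W <- mean(apply(m, 2, stats::var))
  if (!is.finite(W) || W == 0) return(0)
  B_over_n <- stats::var(colMeans(m))
  V <- (n - 1) / n * W + B_over_n
  100 * (max(sqrt(V / W), 1) - 1)
}

#' Apply the convergence gate to a posterior summary
#'
#' A parameter passes when its Gelman statistic and its Monte Carlo
#' error relative to the posterior SD are both below threshold (5% each
#' by default); the fit passes overall when every fixed effect and
#' variance component passes.
#'
#' @param summary Output of [summarize_posterior()].
#' @param gelman_threshold,mc_ratio_threshold Thresholds in percent.
#' @return List with `table` (per-parameter flags) and `overall`.
#' @export
check_convergence <- function(summary, gelman_threshold = 5,
                              mc_ratio_threshold = 5) {
  tab <- data.frame(parameter = summary$parameter,
                    gelman_pct = summary$gelman_pct,
                    mc_ratio_pct = summary$mc_ratio_pct,
                    pass = summary$gelman_pct < gelman_threshold &
                      summary$mc_ratio_pct < mc_ratio_threshold,
                    stringsAsFactors = FALSE)
  list(table = tab, overall = all(tab$pass))
}

#' Iteratively remove factors whose credible interval straddles zero
#'
#' Repeatedly drops the factor whose 95% credible interval contains 0
#' and whose posterior mean is most centred on 0 (smallest |mean|/SD),
#' refitting after each removal, until every retained interval excludes
#' zero or only the intercept remains.
#'
#' @param draws Fitted [fit_st_model()] draws.
#' @param panel,adjacency,config As passed to [fit_st_model()].
#' @return List with `factors` (final retained set), `draws` (final
#'   fit), `dropped` (in removal order).
#' @export
prune_nonsignificant <- function(draws, panel, adjacency,
                                 config = draws$config) {
  dropped <- character()
  repeat {
    sm <- summarize_posterior(draws)
    fx <- sm[sm$parameter %in% draws$factors, , drop = FALSE]
    straddle <- fx[fx$q2.5 <= 0 & fx$q97.5 >= 0, , drop = FALSE]
    if (nrow(straddle) == 0 || length(draws$factors) == 0) break
    z <- abs(straddle$mean) / ifelse(straddle$sd > 0, straddle$sd, Inf)
    victim <- straddle$parameter[which.min(z)]
    dropped <- c(dropped, victim)
    remaining <- setdiff(draws$factors, victim)
    if (length(remaining) == 0) {
      draws$factors <- character()
      break
    }
    spec2 <- draws$spec
    spec2$factors <- remaining
    draws <- fit_st_model(panel, adjacency, spec2, config)
  }
  list(factors = draws$factors, draws = draws, dropped = dropped)
}

#' Extract posterior-mean coefficients for counterfactual prediction
#'
#' @param draws A [fit_st_model()] result.
#' @return List with `alpha` (scalar) and `beta` (named vector of
#'   posterior means per unit proportion), plus `beta_draws` for
#'   interval propagation.
#' @export
coefficient_set <- function(draws) {
  sm <- summarize_posterior(draws)
  beta <- stats::setNames(sm$mean[match(draws$factors, sm$parameter)],
                          draws$factors)
  bd <- do.call(rbind, lapply(draws$chains, function(ch) ch$beta))
  list(alpha = sm$mean[sm$parameter == "alpha"], beta = beta,
       beta_draws = bd)
}
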