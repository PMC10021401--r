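#' Configuration for the synthetic county-panel generator
#'
#' Bundles the parameters of the simulated study: panel dimensions,
#' intervention factors with their true log-linear effects, variance
#' components of the spatio-temporal random effects, and the coverage
#' trajectory law. Defaults emulate the shape of a national county panel:
#' 47 counties observed 2003--2014 with ten intervention-coverage factors
#' whose effects and variance components follow the fitted ecological
#' model this package targets (see `default_true_beta()`).
#'
#' Coverage paths are constant-ARC exponentials: each county-factor draws
#' a 2003 starting proportion and an annual rate of change (percent per
#' year), and the path is clipped to (0.001, 0.999). Per-factor
#' `overrides` replace the start/ARC ranges for factors with a different
#' regime (by default HIV prevalence, a low, declining risk factor rather
#' than a scaled-up intervention).
#'
#' @param n_counties Number of counties (>= 2).
#' @param years Inclusive integer year range (span >= 3).
#' @param factor_names Character vector of factor identifiers.
#' @param seed Integer seed; the panel is deterministic given the config.
#' @param coverage_start_range Interval in (0,1) for 2003 coverage.
#' @param coverage_arc_range Interval (percent/year) for coverage ARC.
#' @param sigma_w ICAR structured spatial SD (log scale).
#' @param sigma_nu Unstructured county SD.
#' @param sigma_t Temporal random-walk SD.
#' @param sigma_delta Space-time interaction / residual SD.
#' @param true_beta Named vector of log-linear effects per unit
#'   proportion, one per factor.
#' @param true_alpha Intercept of the log mortality rate (deaths per
#'   livebirth scale; U5M per 1,000 is `1000 * exp(...)`).
#' @param overrides Named list of per-factor `list(start_range, arc_range)`.
#'
#' @return An object of class `"synth_config"`.
#' @export
synth_config <- function(n_counties = 47L,
                         years = 2003:2014,
                         factor_names = names(default_true_beta()),
                         seed = 1L,
                         coverage_start_range = c(0.10, 0.85),
                         coverage_arc_range = c(-3, 8),
                         sigma_w = 0.5336,
                         sigma_nu = 0.0024,
                         sigma_t = 0.0591,
                         sigma_delta = 0.1398,
                         true_beta = default_true_beta()[factor_names],
                         true_alpha = -0.9273,
                         overrides = list(
                           hiv = list(start_range = c(0.01, 0.12),
                                      arc_range = c(-9, 1))
                         )) {
  if (n_counties < 2) stop("`n_counties` must be >= 2", call. = FALSE)
  years <- as.integer(years)
  if (length(years) < 3) stop("`years` must span at least 3 years", call. = FALSE)
  sig <- c(sigma_w, sigma_nu, sigma_t, sigma_delta)
  if (any(!is.finite(sig)) || any(sig < 0)) {
    stop("all sigmas must be nonnegative", call. = FALSE)
  }
  if (any(coverage_start_range <= 0) || any(coverage_start_range >= 1)) {
    stop("`coverage_start_range` must lie inside (0, 1)", call. = FALSE)
  }
  true_beta <- unlist(true_beta)
  if (is.null(names(true_beta))) names(true_beta) <- factor_names
  if (!setequal(names(true_beta), factor_names)) {
    stop("`true_beta` must be named by `factor_names`", call. = FALSE)
  }
  structure(list(
    n_counties = as.integer(n_counties), years = years,
    factor_names = factor_names, seed = as.integer(seed),
    coverage_start_range = coverage_start_range,
    coverage_arc_range = coverage_arc_range,
    sigma_w = sigma_w, sigma_nu = sigma_nu, sigma_t = sigma_t,
    sigma_delta = sigma_delta,
    true_beta = true_beta[factor_names], true_alpha = true_alpha,
    overrides = overrides
  ), class = "synth_config")
}

#' Reference log-linear effects used as simulation truth
#'
#' Posterior-mean effects (per unit proportion of coverage, or of
#' prevalence for HIV) of the ten retained factors in the fitted
#' ecological model; used as default ground truth by the generator so
#' that recovery tests exercise realistic effect sizes and signs.
#'
#' @return Named numeric vector of length 10.
#' @export
default_true_beta <- function() {
  c(anc4 = -0.7098, antimalarial = -0.0416,
    early_breastfeeding = -0.4162, sanitation = -0.2136,
    facility_delivery = -0.4740, fever_treatment = -1.2550,
    hiv = 6.5930, itn_use = -0.0065,
    fully_immunised = -0.5817, water = -0.3558)
}

#' Simulate a county-year panel with known ground truth
#'
#' Generates intervention coverage as per-county constant-ARC paths and
#' under-five mortality from the log-linear spatio-temporal model
#' \deqn{\log(U5M_{i,t}/1000) = \alpha + \sum_k \beta_k x_{k,i,t} + w_i +
#'   \nu_i + \phi_t + \delta_{i,t}}
#' with `w` an intrinsic CAR (ICAR) field on the county adjacency graph
#' (sum-to-zero), `nu` and `delta` iid Gaussian, and `phi` a centred
#' Gaussian random walk. U5M is returned in deaths per 1,000 livebirths.
#'
#' @param config A [synth_config()].
#' @param adjacency A [make_adjacency()] graph with
#'   `config$n_counties` nodes.
#'
#' @return A list with `panel` (data.frame: `county_id`, `year`, `u5m`,
#'   one proportion column per factor) and `truth` (list with `alpha`,
#'   `beta`, `w`, `nu`, `phi`, `delta`).
#' @export
simulate_panel <- function(config, adjacency) {
  stopifnot(inherits(config, "synth_config"),
            inherits(adjacency, "county_adjacency"))
  if (adjacency$n != config$n_counties) {
    stop("adjacency node count must equal `n_counties`", call. = FALSE)
  }
  n <- config$n_counties
  years <- config$years
  T_ <- length(years)
  K <- length(config$factor_names)

  old <- local_seed(config$seed)
  on.exit(restore_seed(old))

  # coverage: constant-ARC exponential paths, clipped to (0.001, 0.999)
  cov <- array(NA_real_, dim = c(n, T_, K),
               dimnames = list(NULL, years, config$factor_names))
  for (k in seq_len(K)) {
    fac <- config$factor_names[k]
    ov <- config$overrides[[fac]]
    sr <- if (!is.null(ov$start_range)) ov$start_range else config$coverage_start_range
    ar <- if (!is.null(ov$arc_range)) ov$arc_range else config$coverage_arc_range
    x0 <- stats::runif(n, sr[1], sr[2])
    a <- stats::runif(n, ar[1], ar[2])
    for (t in seq_len(T_)) {
      cov[, t, k] <- pmin(pmax(x0 * exp(a / 100 * (t - 1)), 0.001), 0.999)
    }
  }

  w <- simulate_icar(adjacency, config$sigma_w)
  nu <- stats::rnorm(n, 0, config$sigma_nu)
  if (config$sigma_t > 0) {
    phi <- cumsum(stats::rnorm(T_, 0, config$sigma_t))
    phi <- phi - mean(phi)
  } else {
    phi <- rep(0, T_)
  }
  delta <- matrix(stats::rnorm(n * T_, 0, config$sigma_delta), n, T_)

  Xb <- matrix(0, n, T_)
  for (k in seq_len(K)) Xb <- Xb + config$true_beta[k] * cov[, , k]
  lograte <- config$true_alpha + Xb + w + nu +
    matrix(phi, n, T_, byrow = TRUE) + delta

  county_id <- sprintf("c%02d", seq_len(n))
  panel <- data.frame(
    county_id = rep(county_id, times = T_),
    year = rep(years, each = n),
    u5m = 1000 * exp(as.vector(lograte)),
    stringsAsFactors = FALSE
  )
  for (k in seq_len(K)) {
    panel[[config$factor_names[k]]] <- as.vector(cov[, , k])
  }
  panel <- panel[order(panel$county_id, panel$year), , drop = FALSE]
  rownames(panel) <- NULL

  dimnames(delta) <- list(county_id, years)
  truth <- list(alpha = config$true_alpha, beta = config$true_beta,
                w = stats::setNames(w, county_id),
                nu = stats::setNames(nu, county_id),
                phi = stats::setNames(phi, years),
                delta = delta)
  list(panel = panel, truth = truth)
}

# ICAR draw by eigendecomposition of the graph Laplacian: the null
# eigenvector (constant) carries no prior mass and is dropped; the draw
# is centred so it sums to zero exactly.
simulate_icar <- function(adjacency, sigma_w) {
  n <- adjacency$n
  if (sigma_w == 0) return(rep(0, n))
  A <- matrix(0, n, n)
  A[adjacency$edges] <- 1
  A <- A + t(A)
  L <- diag(rowSums(A)) - A
  eig <- eigen(L, symmetric = TRUE)
  keep <- seq_len(n - 1L)  # eigenvalues sorted decreasing; last is null
  z <- stats::rnorm(n - 1L)
  w <- sigma_w * as.vector(eig$vectors[, keep] %*% (z / sqrt(eig$values[keep])))
  w - mean(w)
}

#' Write / read a county-year panel as CSV
#'
#' Factor columns are stored in percent in the file and as proportions in
#' memory; `u5m` stays in deaths per 1,000 livebirths. A `# schema:`
#' comment line precedes the header.
#'
#' @param panel Panel data.frame as produced by [simulate_panel()].
#' @param path File path.
#' @param factor_cols Character vector naming the coverage columns;
#'   defaults to every column other than `county_id`, `year`, `u5m`.
#' @return `write_panel` returns `path` invisibly; `read_panel` the
#'   panel data.frame on the proportion scale.
#' @export
write_panel <- function(panel, path, factor_cols = setdiff(names(panel), c("county_id", "year", "u5m"))) {
  out <- panel
  for (fc in factor_cols) out[[fc]] <- 100 * out[[fc]]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# schema: u5mproj/panel v1", con)
  utils::write.csv(out, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  panel <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  for (fc in setdiff(names(panel), c("county_id", "year", "u5m"))) {
    panel[[fc]] <- panel[[fc]] / 100
  }
  panel
}

#' Write simulation ground truth to a JSON file
#'
#' @param truth Truth list from [simulate_panel()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  out <- truth
  out$delta <- NULL  # per-observation residual field, omitted from the summary file
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
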