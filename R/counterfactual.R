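#' SDG 3.2 evaluation settings
#'
#' @param threshold U5M threshold in deaths per 1,000 livebirths
#'   (default 25; a county attains the target strictly below it).
#' @param evaluation_years Years at which attainment is assessed.
#' @return List of class `"sdg_config"`.
#' @export
sdg_config <- function(threshold = 25, evaluation_years = c(2022L, 2025L)) {
  stopifnot(threshold > 0)
  structure(list(threshold = threshold,
                 evaluation_years = as.integer(evaluation_years)),
            class = "sdg_config")
}

#' Business-as-usual U5M projection
#'
#' Each county's U5M ARC over the 2003--2014 endpoints (11 annual steps)
#' is applied to its 2014 U5M from 2015 through 2025.
#'
#' @param panel County-year panel with `u5m` for 2003 and 2014.
#' @param start_year,base_year Baseline endpoints.
#' @return data.frame `county_id`, `year`, `u5m` for 2015--2025.
#' @export
bau_u5m <- function(panel, start_year = 2003L, base_year = 2014L) {
  u0 <- panel[panel$year == start_year, c("county_id", "u5m")]
  u1 <- panel[panel$year == base_year, c("county_id", "u5m")]
  if (nrow(u0) == 0 || nrow(u1) == 0) {
    stop("panel must include U5M for ", start_year, " and ", base_year,
         call. = FALSE)
  }
  u0 <- u0[order(u0$county_id), ]
  u1 <- u1[order(u1$county_id), ]
  a <- arc(u0$u5m, u1$u5m, base_year - start_year)
  out <- expand.grid(county_id = u1$county_id, year = proj_years,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$u5m <- u1$u5m[match(out$county_id, u1$county_id)] *
    exp(a[match(out$county_id, u1$county_id)] / 100 * (out$year - base_year))
  out[order(out$county_id, out$year), , drop = FALSE]
}

# trajectory long df -> county x year matrix for one factor
traj_factor_matrix <- function(traj, fac) {
  sub <- traj[traj$factor == fac, , drop = FALSE]
  counties <- sort(unique(sub$county_id))
  years <- sort(unique(sub$year))
  m <- matrix(NA_real_, length(counties), length(years),
              dimnames = list(counties, years))
  m[cbind(match(sub$county_id, counties), match(sub$year, years))] <- sub$value
  m
}

#' Counterfactual U5M under a scenario coverage path
#'
#' Under the log-linear model the county-year random effects are common
#' to both coverage paths and cancel in the ratio, so the counterfactual
#' is a multiplicative adjustment of the BAU projection:
#' \deqn{U5M^{scen}_{i,t} = U5M^{BAU}_{i,t} \exp\left(\sum_k \beta_k
#'   (x^{scen}_{k,i,t} - x^{BAU}_{k,i,t})\right)}
#' with coverage on the proportion scale.
#'
#' @param bau A [bau_u5m()] data.frame.
#' @param bau_traj,scen_traj `coverage_trajectory` objects aligned on
#'   county, factor and year.
#' @param coefficients A [coefficient_set()] (or any list with a named
#'   `beta` vector covering every trajectory factor).
#' @return data.frame `county_id`, `year`, `u5m` for the scenario.
#' @export
counterfactual_u5m <- function(bau, bau_traj, scen_traj, coefficients) {
  beta <- coefficients$beta
  facs <- sort(unique(scen_traj$factor))
  absent <- setdiff(facs, names(beta))
  if (length(absent)) {
    stop("no coefficient for trajectory factor(s): ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  out <- bau[order(bau$county_id, bau$year), , drop = FALSE]
  counties <- sort(unique(out$county_id))
  years <- sort(unique(out$year))
  shift <- matrix(0, length(counties), length(years),
                  dimnames = list(counties, years))
  for (fac in facs) {
    mb <- traj_factor_matrix(bau_traj, fac)
    ms <- traj_factor_matrix(scen_traj, fac)
    shift <- shift + beta[fac] * (ms[counties, as.character(years)] -
                                    mb[counties, as.character(years)])
  }
  out$u5m <- out$u5m *
    exp(shift[cbind(match(out$county_id, counties),
                    match(as.character(out$year), as.character(years)))])
  rownames(out) <- NULL
  out
}

#' Percentage change of scenario U5M relative to BAU
#'
#' `100 * (u5m_scen - u5m_bau) / u5m_bau`; negative values are
#' reductions.
#'
#' @param u5m_scen,u5m_bau Numeric vectors (aligned), `u5m_bau > 0`.
#' @return Percent change vector.
#' @export
percent_change <- function(u5m_scen, u5m_bau) {
  if (any(u5m_bau <= 0)) stop("BAU U5M must be positive", call. = FALSE)
  100 * (u5m_scen - u5m_bau) / u5m_bau
}

#' Per-factor counterfactual impacts
#'
#' For each factor, recomputes the counterfactual with only that
#' factor's coverage switched to the scenario path. On the log scale
#' the single-factor effects add exactly to the joint effect.
#'
#' @inheritParams counterfactual_u5m
#' @return data.frame `factor`, `county_id`, `year`, `pct_change`.
#' @export
single_factor_impacts <- function(bau, bau_traj, scen_traj, coefficients) {
  facs <- sort(unique(scen_traj$factor))
  rows <- lapply(facs, function(fac) {
    mini_scen <- scen_traj[scen_traj$factor == fac, , drop = FALSE]
    mini_bau <- bau_traj[bau_traj$factor == fac, , drop = FALSE]
    cf <- counterfactual_u5m(bau, mini_bau, mini_scen, coefficients)
    data.frame(factor = fac, county_id = cf$county_id, year = cf$year,
               pct_change = percent_change(cf$u5m, bau$u5m),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' SDG 3.2 attainment report
#'
#' Flags each county at each evaluation year when projected U5M is
#' strictly below the threshold, and tabulates the count and percent of
#' attaining counties (percent rounded to 1 decimal).
#'
#' @param u5m_map data.frame `county_id`, `year`, `u5m`.
#' @param config An [sdg_config()].
#' @param n_counties Denominator for the attainment percent; defaults to
#'   the number of distinct counties in `u5m_map`.
#' @return List with `flags` (data.frame `county_id`, `year`,
#'   `attained`) and `attainment` (data.frame `year`, `n_attained`,
#'   `pct_attained`).
#' @export
sdg_report <- function(u5m_map, config = sdg_config(),
                       n_counties = length(unique(u5m_map$county_id))) {
  sub <- u5m_map[u5m_map$year %in% config$evaluation_years, , drop = FALSE]
  if (nrow(sub) == 0) stop("evaluation years absent from `u5m_map`", call. = FALSE)
  flags <- data.frame(county_id = sub$county_id, year = sub$year,
                      attained = sub$u5m < config$threshold,
                      stringsAsFactors = FALSE)
  att <- do.call(rbind, lapply(split(flags, flags$year), function(d) {
    data.frame(year = d$year[1], n_attained = sum(d$attained),
               pct_attained = round(100 * sum(d$attained) / n_counties, 1))
  }))
  rownames(att) <- NULL
  list(flags = flags, attainment = att)
}

#' Full projection result across scenarios
#'
#' Convenience wrapper running [bau_u5m()], each requested scenario's
#' counterfactual, percent changes, per-factor impacts and the SDG
#' report in one call.
#'
#' @param panel County-year panel (baseline window).
#' @param coefficients A [coefficient_set()].
#' @param factors Trajectory factors (must be covered by
#'   `coefficients$beta`).
#' @param scenarios Scenario ids to evaluate.
#' @param meta Factor metadata for directions and policy targets.
#' @param sdg An [sdg_config()].
#' @return List of class `"projection_result"`: `u5m` (long data.frame
#'   with `scenario`), `pct_change_vs_bau`, `single_factor_pct_change`,
#'   `attainment`.
#' @export
projection_result <- function(panel, coefficients,
                              factors = names(coefficients$beta),
                              scenarios = c("S1", "S2", "S3", "S4"),
                              meta = default_factor_meta(),
                              sdg = sdg_config()) {
  bau <- bau_u5m(panel)
  bau_traj <- bau_coverage(panel, factors)
  n_cty <- length(unique(bau$county_id))

  u5m_all <- cbind(scenario = "BAU", bau, pct_change_vs_bau = 0)
  sf_all <- NULL
  att_all <- cbind(scenario = "BAU",
                   sdg_report(bau, sdg, n_cty)$attainment)
  for (sc in scenarios) {
    traj <- project_coverage(panel, sc, factors, meta)
    cf <- counterfactual_u5m(bau, bau_traj, traj, coefficients)
    u5m_all <- rbind(u5m_all,
                     cbind(scenario = sc, cf,
                           pct_change_vs_bau = percent_change(cf$u5m, bau$u5m)))
    sf <- single_factor_impacts(bau, bau_traj, traj, coefficients)
    sf_all <- rbind(sf_all, cbind(scenario = sc, sf))
    att_all <- rbind(att_all,
                     cbind(scenario = sc, sdg_report(cf, sdg, n_cty)$attainment))
  }
  rownames(u5m_all) <- rownames(att_all) <- NULL
  structure(list(u5m = u5m_all, single_factor_pct_change = sf_all,
                 attainment = att_all, sdg = sdg),
            class = "projection_result")
}

#' @export
print.projection_result <- function(x, ...) {
  cat("U5M projection result\n")
  print(x$attainment)
  invisible(x)
}
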