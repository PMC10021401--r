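#' Default intervention metadata and national policy targets
#'
#' One row per modelled factor: whether higher coverage is better
#' (prevalence-type factors such as HIV improve downwards), the national
#' 2014 baseline coverage in percent, and the national strategic-plan
#' targets for 2022 and 2025 used by scenario 4.
#'
#' The same table ships as a CSV for file-based workflows:
#' `system.file("extdata", "scenario_targets.csv", package = "u5mproj")`.
#'
#' @return data.frame with columns `factor`, `higher_is_better`,
#'   `baseline_2014_pct`, `target_2022_pct`, `target_2025_pct`.
#' @export
default_factor_meta <- function() {
  data.frame(
    factor = c("anc4", "antimalarial", "early_breastfeeding", "sanitation",
               "facility_delivery", "fever_treatment", "hiv", "itn_use",
               "fully_immunised", "water"),
    higher_is_better = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, TRUE,
                         TRUE, TRUE),
    baseline_2014_pct = c(57.7, 33.5, 62.8, 90.1, 61.5, 72.8, 5.0, 56.0,
                          78.8, 63.4),
    target_2022_pct = c(70, 70, 70, 65, 73, 80, 3.3, 80, 80, 78),
    target_2025_pct = c(80, 90, 80, 70, 75, 90, 2.8, 95, 85, 80),
    stringsAsFactors = FALSE
  )
}

# ---- internal helpers -------------------------------------------------

# county x factor matrix of one year's coverage (proportion scale)
year_matrix <- function(panel, factors, year) {
  sub <- panel[panel$year == year, , drop = FALSE]
  if (nrow(sub) == 0) {
    stop("panel lacks year ", year, " needed for projection", call. = FALSE)
  }
  sub <- sub[order(sub$county_id), , drop = FALSE]
  m <- as.matrix(sub[, factors, drop = FALSE])
  rownames(m) <- sub$county_id
  m
}

# assemble a long trajectory data.frame from a county x factor x year array
as_trajectory <- function(values, scenario) {
  counties <- dimnames(values)[[1]]
  factors <- dimnames(values)[[2]]
  years <- as.integer(dimnames(values)[[3]])
  out <- expand.grid(county_id = counties, factor = factors, year = years,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$value <- as.vector(values)
  out <- out[order(out$county_id, out$factor, out$year), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "scenario") <- scenario
  class(out) <- c("coverage_trajectory", "data.frame")
  out
}

proj_years <- 2015:2025

#' Business-as-usual coverage trajectories
#'
#' Continues each county-factor's own 2003--2014 ARC (11 annual steps)
#' from the 2014 baseline through 2015--2025, clamped to
#' `[0.001, 0.99]`.
#'
#' @param panel County-year panel covering 2003 and 2014 for every
#'   county and factor (proportion scale).
#' @param factors Factor columns to project; defaults to every column
#'   other than `county_id`, `year`, `u5m`.
#' @param base_year,start_year Baseline endpoints (2003 and 2014).
#' @return A long `coverage_trajectory` data.frame (`county_id`,
#'   `factor`, `year`, `value`).
#' @export
bau_coverage <- function(panel,
                         factors = setdiff(names(panel),
                                           c("county_id", "year", "u5m")),
                         start_year = 2003L, base_year = 2014L) {
  x0 <- year_matrix(panel, factors, start_year)
  x1 <- year_matrix(panel, factors, base_year)
  a <- arc(x0, x1, base_year - start_year)
  vals <- array(NA_real_, dim = c(nrow(x1), length(factors), length(proj_years)),
                dimnames = list(rownames(x1), factors, proj_years))
  for (yi in seq_along(proj_years)) {
    vals[, , yi] <- clamp_coverage(x1 * exp(a / 100 * (proj_years[yi] - base_year)))
  }
  as_trajectory(vals, "BAU")
}

#' Scenario 1: scale up to the best-performing county of 2014
#'
#' Per factor the target is the best county's 2014 coverage (maximum,
#' or minimum for prevalence-type factors; ties to the lowest county
#' id). A single national ARC from the national 2014 mean to that target
#' over 8 steps is applied to every county's own baseline. Counties
#' whose projected 2022 value reaches the target switch to an ARC
#' attaining universal coverage (99%) by 2025; all others — and all
#' decreasing-good factors — keep the shared ARC through 2025.
#'
#' @inheritParams bau_coverage
#' @param meta Factor metadata ([default_factor_meta()] layout).
#' @return A `coverage_trajectory`.
#' @export
scenario1 <- function(panel,
                      factors = setdiff(names(panel),
                                        c("county_id", "year", "u5m")),
                      meta = default_factor_meta()) {
  x1 <- year_matrix(panel, factors, 2014L)
  n <- nrow(x1)
  vals <- array(NA_real_, dim = c(n, length(factors), length(proj_years)),
                dimnames = list(rownames(x1), factors, proj_years))
  for (k in seq_along(factors)) {
    hib <- factor_direction(factors[k], meta)
    best <- if (hib) max(x1[, k]) else min(x1[, k])
    national <- mean(x1[, k])
    a <- arc(national, best, 8)
    v22 <- x1[, k] * exp(a / 100 * 8)
    reached <- hib & (v22 >= best - 1e-9)
    for (yi in seq_along(proj_years)) {
      yr <- proj_years[yi]
      base_path <- x1[, k] * exp(a / 100 * (yr - 2014))
      v <- base_path
      if (yr > 2022 && any(reached)) {
        a2 <- arc(v22[reached], 0.99, 3)
        v[reached] <- v22[reached] * exp(a2 / 100 * (yr - 2022))
      }
      vals[, k, yi] <- clamp_coverage(v)
    }
  }
  as_trajectory(vals, "S1")
}

#' Scenario 2: the fastest county ARC observed 2003--2014
#'
#' Per factor, the single fastest improvement-signed county ARC of the
#' baseline period (maximum for coverage factors, most negative for
#' prevalence-type factors) is applied to every county's 2014 baseline
#' across the whole projection period.
#'
#' @inheritParams scenario1
#' @return A `coverage_trajectory`.
#' @export
scenario2 <- function(panel,
                      factors = setdiff(names(panel),
                                        c("county_id", "year", "u5m")),
                      meta = default_factor_meta()) {
  x0 <- year_matrix(panel, factors, 2003L)
  x1 <- year_matrix(panel, factors, 2014L)
  a <- arc(x0, x1, 11)
  vals <- array(NA_real_, dim = c(nrow(x1), length(factors), length(proj_years)),
                dimnames = list(rownames(x1), factors, proj_years))
  for (k in seq_along(factors)) {
    hib <- factor_direction(factors[k], meta)
    fastest <- if (hib) max(a[, k]) else min(a[, k])
    for (yi in seq_along(proj_years)) {
      vals[, k, yi] <- clamp_coverage(
        x1[, k] * exp(fastest / 100 * (proj_years[yi] - 2014)))
    }
  }
  as_trajectory(vals, "S2")
}

#' Scenario 3: converge on the projected national coverage
#'
#' The national (unweighted county-mean) series gives a national
#' 2003--2014 ARC, projected to national targets for 2022 and 2025; the
#' implied period ARCs (2015--2022 and 2022--2025) are then applied to
#' each county's own 2014 baseline, so projected coverage still differs
#' by county.
#'
#' @inheritParams bau_coverage
#' @return A `coverage_trajectory`.
#' @export
scenario3 <- function(panel,
                      factors = setdiff(names(panel),
                                        c("county_id", "year", "u5m"))) {
  x0 <- year_matrix(panel, factors, 2003L)
  x1 <- year_matrix(panel, factors, 2014L)
  nat0 <- colMeans(x0)
  nat1 <- colMeans(x1)
  nat_arc <- arc(nat0, nat1, 11)
  t22 <- project(nat1, nat_arc, 8)
  t25 <- project(nat1, nat_arc, 11)
  period_trajectory(x1, arc(nat1, t22, 8), arc(t22, t25, 3), "S3")
}

#' Scenario 4: national strategic-plan targets
#'
#' National ARCs are computed from the national 2014 baseline to the
#' 2022 policy target (8 steps) and from the 2022 to the 2025 target
#' (3 steps), then applied to each county's own baseline path.
#'
#' @inheritParams scenario1
#' @return A `coverage_trajectory`.
#' @export
scenario4 <- function(panel,
                      factors = setdiff(names(panel),
                                        c("county_id", "year", "u5m")),
                      meta = default_factor_meta()) {
  x1 <- year_matrix(panel, factors, 2014L)
  idx <- match(factors, meta$factor)
  if (anyNA(idx) || anyNA(meta$target_2022_pct[idx]) ||
      anyNA(meta$target_2025_pct[idx])) {
    stop("policy targets missing for: ",
         paste(factors[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  nat1 <- colMeans(x1)
  t22 <- meta$target_2022_pct[idx] / 100
  t25 <- meta$target_2025_pct[idx] / 100
  period_trajectory(x1, arc(nat1, t22, 8), arc(t22, t25, 3), "S4")
}

# shared two-period projection: arc1 to 2022 from the 2014 baseline,
# arc2 onward from the (unclamped) 2022 value
period_trajectory <- function(x1, arc1, arc2, scenario) {
  factors <- colnames(x1)
  vals <- array(NA_real_, dim = c(nrow(x1), length(factors), length(proj_years)),
                dimnames = list(rownames(x1), factors, proj_years))
  for (k in seq_along(factors)) {
    v22 <- x1[, k] * exp(arc1[k] / 100 * 8)
    for (yi in seq_along(proj_years)) {
      yr <- proj_years[yi]
      v <- if (yr <= 2022) {
        x1[, k] * exp(arc1[k] / 100 * (yr - 2014))
      } else {
        v22 * exp(arc2[k] / 100 * (yr - 2022))
      }
      vals[, k, yi] <- clamp_coverage(v)
    }
  }
  as_trajectory(vals, scenario)
}

factor_direction <- function(factor, meta) {
  i <- match(factor, meta$factor)
  if (is.na(i)) TRUE else meta$higher_is_better[i]
}

#' Project coverage under a named scenario
#'
#' Dispatcher over [bau_coverage()], [scenario1()] ... [scenario4()].
#'
#' @inheritParams scenario1
#' @param scenario One of `"BAU"`, `"S1"`, `"S2"`, `"S3"`, `"S4"`
#'   (case-insensitive).
#' @return A `coverage_trajectory`.
#' @export
project_coverage <- function(panel, scenario,
                             factors = setdiff(names(panel),
                                               c("county_id", "year", "u5m")),
                             meta = default_factor_meta()) {
  switch(toupper(scenario),
         BAU = bau_coverage(panel, factors),
         S1 = scenario1(panel, factors, meta),
         S2 = scenario2(panel, factors, meta),
         S3 = scenario3(panel, factors),
         S4 = scenario4(panel, factors, meta),
         stop("unknown scenario: ", scenario, call. = FALSE))
}

#' Write / read a coverage trajectory as CSV (values in percent)
#'
#' @param trajectory A `coverage_trajectory`.
#' @param path File path.
#' @return `write_trajectory` returns `path` invisibly; `read_trajectory`
#'   a `coverage_trajectory` on the proportion scale.
#' @export
write_trajectory <- function(trajectory, path) {
  out <- as.data.frame(trajectory)
  out$value <- 100 * out$value
  out$scenario <- attr(trajectory, "scenario")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# schema: u5mproj/trajectory v1", con)
  utils::write.csv(out, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  scen <- unique(df$scenario)
  df$scenario <- NULL
  df$value <- df$value / 100
  attr(df, "scenario") <- scen
  class(df) <- c("coverage_trajectory", "data.frame")
  df
}
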