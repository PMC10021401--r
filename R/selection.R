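#' Configuration for the factor-selection pipeline
#'
#' @param p_threshold Two-sided p-value threshold of the permissive
#'   bivariate screen (default 0.2).
#' @param redundancy_map Named character vector mapping a factor to the
#'   umbrella factor that captures its contribution (e.g. the individual
#'   vaccines to fully-immunised status); the mapped factor is dropped
#'   whenever its umbrella survives the screen.
#' @param enr_alpha_grid Elastic-net mixing weights in `[0, 1]` to search.
#' @param enr_lambda_grid Penalty grid (decreasing); `NULL` lets glmnet
#'   pick its own data-driven sequence per mixing weight.
#' @param cv_folds Number of cross-validation folds (default 10). Folds
#'   group whole counties so that years of one county never straddle the
#'   train/test split.
#' @param anc_factor Name of the antenatal-visits coverage column.
#' @param anc_components Names of the three interventions delivered
#'   during antenatal visits, combined into a PCA index by model 2.
#' @param seed Seed for the county-to-fold assignment.
#'
#' @return A list of class `"screening_config"`.
#' @export
screening_config <- function(p_threshold = 0.2,
                             redundancy_map = c(dtp3 = "fully_immunised",
                                                polio3 = "fully_immunised",
                                                measles = "fully_immunised",
                                                bcg = "fully_immunised"),
                             enr_alpha_grid = c(0, 0.25, 0.5, 0.75, 1),
                             enr_lambda_grid = NULL,
                             cv_folds = 10L,
                             anc_factor = "anc4",
                             anc_components = c("iron_supplement",
                                                "tetanus_injection",
                                                "vitamin_a"),
                             seed = 1L) {
  stopifnot(p_threshold > 0, p_threshold < 1, length(enr_alpha_grid) >= 1)
  structure(list(p_threshold = p_threshold, redundancy_map = redundancy_map,
                 enr_alpha_grid = enr_alpha_grid,
                 enr_lambda_grid = enr_lambda_grid,
                 cv_folds = as.integer(cv_folds), anc_factor = anc_factor,
                 anc_components = anc_components, seed = as.integer(seed)),
            class = "screening_config")
}

#' Bivariate log-linear screen of one factor
#'
#' Ordinary least squares of `log(U5M)` on a single coverage factor,
#' pooled over county-years. The screen is deliberately permissive
#' (default p < 0.2, two-sided Wald) — it only removes factors with no
#' detectable marginal association.
#'
#' @param panel County-year panel (proportion-scale factors).
#' @param factor Name of the factor column to test.
#' @param p_threshold Significance threshold.
#' @return List with `coefficient`, `p_value`, `passes`.
#' @export
bivariate_screen <- function(panel, factor, p_threshold = 0.2) {
  x <- panel[[factor]]
  if (is.null(x)) stop("unknown factor column: ", factor, call. = FALSE)
  y <- log(panel$u5m)
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3) stop("need >= 3 finite county-year rows", call. = FALSE)
  if (stats::sd(x[ok]) == 0) {
    stop("degenerate design: factor `", factor, "` is constant", call. = FALSE)
  }
  fit <- stats::lm(y[ok] ~ x[ok])
  sm <- summary(fit)$coefficients
  list(coefficient = unname(sm[2, 1]), p_value = unname(sm[2, 4]),
       passes = unname(sm[2, 4]) < p_threshold)
}

#' Drop factors whose contribution an umbrella factor captures
#'
#' @param screened Character vector of factors that passed the screen.
#' @param redundancy_map Named character vector `factor -> umbrella`.
#' @return `screened` with every factor removed whose umbrella is itself
#'   present in `screened`; an umbrella that did not pass the screen
#'   protects nothing.
#' @export
apply_redundancy_exclusions <- function(screened, redundancy_map) {
  if (length(redundancy_map) == 0) return(screened)
  # reject cyclic maps (a factor may not transitively capture itself)
  for (f in names(redundancy_map)) {
    seen <- f
    cur <- f
    while (cur %in% names(redundancy_map)) {
      cur <- unname(redundancy_map[[cur]])
      if (cur %in% seen) {
        stop("cycle in `redundancy_map` involving `", f, "`", call. = FALSE)
      }
      seen <- c(seen, cur)
    }
  }
  drop <- names(redundancy_map)[unname(redundancy_map) %in% screened]
  setdiff(screened, drop)
}

#' Build the antenatal-care intervention index by PCA
#'
#' First principal component of the standardised ANC-delivered
#' intervention columns (iron supplementation, tetanus injection,
#' vitamin A by default), oriented to correlate positively with the mean
#' of its components and rescaled to mean 0, SD 1.
#'
#' @param panel County-year panel.
#' @param components Names of the component columns (>= 2).
#' @return List with `index` (numeric vector, one value per panel row),
#'   `loadings` (named, unit norm) and `explained_var` (share of
#'   variance carried by the first component).
#' @export
build_anc_index <- function(panel,
                            components = c("iron_supplement",
                                           "tetanus_injection",
                                           "vitamin_a")) {
  if (length(components) < 2) stop("need >= 2 component columns", call. = FALSE)
  missing <- setdiff(components, names(panel))
  if (length(missing)) {
    stop("panel lacks ANC component columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  Z <- as.matrix(panel[, components, drop = FALSE])
  sds <- apply(Z, 2, stats::sd)
  if (any(sds == 0)) stop("degenerate: constant ANC component", call. = FALSE)
  Z <- scale(Z)
  pc <- stats::prcomp(Z, center = FALSE, scale. = FALSE)
  idx <- pc$x[, 1]
  load <- pc$rotation[, 1]
  if (stats::cor(idx, rowMeans(Z)) < 0) {
    idx <- -idx
    load <- -load
  }
  list(index = as.vector(scale(idx)),
       loadings = stats::setNames(as.vector(load), components),
       explained_var = pc$sdev[1]^2 / sum(pc$sdev^2))
}

# county-grouped fold assignment: whole counties are shuffled (seeded)
# and dealt round-robin into folds
make_county_folds <- function(county_ids, nfolds, seed = 1L) {
  counties <- sort(unique(county_ids))
  if (length(counties) < nfolds) {
    stop("fewer counties than folds", call. = FALSE)
  }
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  shuffled <- sample(counties)
  fold_of <- stats::setNames(rep(seq_len(nfolds), length.out = length(counties)),
                             shuffled)
  unname(fold_of[county_ids])
}

#' Elastic-net selection over a mixing/penalty grid
#'
#' Penalised least squares of `y` on standardised `X` over every
#' `(alpha, lambda)` pair, scored by k-fold cross-validated mean squared
#' error; returns the factors with non-zero coefficients at the
#' minimising pair (ties broken towards the smaller penalty).
#'
#' @param X Numeric matrix of standardised predictors (columns named).
#' @param y Response vector (`log` U5M rate).
#' @param config A [screening_config()].
#' @param foldid Optional integer fold assignment per row; defaults to
#'   row-shuffled folds (use [make_county_folds()] for grouped folds).
#' @return List with `alpha`, `lambda`, `cv_mse`, `coefficients` (named,
#'   excluding intercept) and `retained` (names of non-zero
#'   coefficients).
#' @export
elastic_net_select <- function(X, y, config = screening_config(),
                               foldid = NULL) {
  X <- as.matrix(X)
  if (nrow(X) < config$cv_folds) {
    stop("fewer rows than cross-validation folds", call. = FALSE)
  }
  if (is.null(foldid)) {
    old <- local_seed(config$seed)
    on.exit(restore_seed(old))
    foldid <- sample(rep(seq_len(config$cv_folds), length.out = nrow(X)))
  }
  best <- NULL
  for (a in config$enr_alpha_grid) {
    # one decreasing penalty sequence per mixing weight: the user grid,
    # or glmnet's data-driven default from the full fit
    lam <- config$enr_lambda_grid
    if (is.null(lam)) {
      lam <- glmnet::glmnet(X, y, alpha = a, standardize = FALSE)$lambda
    }
    lam <- sort(unique(lam), decreasing = TRUE)
    # explicit fold loop (supports grouped folds and penalty grids of
    # any length, including a single fixed lambda)
    sse <- numeric(length(lam))
    for (f in sort(unique(foldid))) {
      tr <- foldid != f
      fit <- glmnet::glmnet(X[tr, , drop = FALSE], y[tr], alpha = a,
                            lambda = lam, standardize = FALSE,
                            thresh = 1e-10)
      pred <- stats::predict(fit, X[!tr, , drop = FALSE], s = lam)
      sse <- sse + colSums((pred - y[!tr])^2)
    }
    cvm <- sse / length(y)
    hits <- which(cvm == min(cvm))
    pick <- hits[which.min(lam[hits])]  # ties -> smaller penalty
    if (is.null(best) || cvm[pick] < best$cv_mse) {
      full <- glmnet::glmnet(X, y, alpha = a, lambda = lam,
                             standardize = FALSE, thresh = 1e-10)
      best <- list(alpha = a, lambda = lam[pick], cv_mse = cvm[pick],
                   fit = full)
    }
  }
  b <- as.vector(stats::coef(best$fit, s = best$lambda, exact = FALSE))[-1]
  names(b) <- colnames(X)
  list(alpha = best$alpha, lambda = best$lambda, cv_mse = best$cv_mse,
       coefficients = b, retained = names(b)[b != 0])
}

#' Run the paired elastic-net models and choose by cross-validated MSE
#'
#' Model 1 regresses `log` U5M on the screened factors including the
#' antenatal-visits factor and each ANC-delivered intervention
#' separately; model 2 replaces the ANC-delivered interventions with
#' their first-principal-component index. The model with the smaller
#' cross-validated MSE supplies the retained factor set (ties go to
#' model 1, which carries no derived variable).
#'
#' @param panel County-year panel containing `u5m`, the ANC factor and
#'   ANC component columns, plus candidate factors.
#' @param config A [screening_config()].
#' @param factors Candidate factor columns; defaults to every column
#'   other than `county_id`, `year`, `u5m`.
#' @return List of class `"selection_result"` with `screened`,
#'   `excluded_redundant`, `anc_index_loadings`, `chosen_model`,
#'   `retained`, `cv_mse` (length-2 vector) and the per-model
#'   elastic-net fits.
#' @export
run_model_pair <- function(panel, config = screening_config(),
                           factors = setdiff(names(panel),
                                             c("county_id", "year", "u5m"))) {
  need <- c(config$anc_factor, config$anc_components)
  missing <- setdiff(need, names(panel))
  if (length(missing)) {
    stop("panel lacks ANC columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  screen <- lapply(factors, function(f) {
    bivariate_screen(panel, f, config$p_threshold)
  })
  screened <- factors[vapply(screen, `[[`, TRUE, "passes")]
  kept <- apply_redundancy_exclusions(screened, config$redundancy_map)
  excluded <- setdiff(screened, kept)

  # ANC factor and its delivered interventions always enter the paired
  # models (their treatment is the point of the pairing)
  m1_factors <- union(kept, need)
  anc_idx <- build_anc_index(panel, config$anc_components)

  y <- log(panel$u5m / 1000)
  std <- function(cols) {
    X <- as.matrix(panel[, cols, drop = FALSE])
    scale(X)
  }
  X1 <- std(m1_factors)
  m2_base <- setdiff(m1_factors, config$anc_components)
  X2 <- cbind(std(m2_base), anc_index = anc_idx$index)

  foldid <- make_county_folds(panel$county_id, config$cv_folds, config$seed)
  fit1 <- elastic_net_select(X1, y, config, foldid)
  fit2 <- elastic_net_select(X2, y, config, foldid)

  chosen <- if (fit2$cv_mse < fit1$cv_mse) 2L else 1L  # tie -> model 1
  retained <- if (chosen == 1L) fit1$retained else fit2$retained
  structure(list(screened = screened, excluded_redundant = excluded,
                 anc_index_loadings = anc_idx$loadings,
                 chosen_model = chosen, retained = retained,
                 cv_mse = c(model1 = fit1$cv_mse, model2 = fit2$cv_mse),
                 model1 = fit1, model2 = fit2),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("factor selection: model", x$chosen_model, "chosen",
      sprintf("(CV MSE %.4g vs %.4g)\n", x$cv_mse[1], x$cv_mse[2]))
  cat("retained:", paste(x$retained, collapse = ", "), "\n")
  invisible(x)
}
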