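# Shared fixture builders: all synthetic, constructed in code.

# minimal panel with exactly the 2003/2014 endpoint years the
# projection code needs; `values` is a named list factor -> matrix with
# rows = counties and columns = c(x2003, x2014) on the proportion scale
endpoint_panel <- function(values, u5m_2003 = NULL, u5m_2014 = NULL) {
  n <- nrow(values[[1]])
  ids <- sprintf("c%02d", seq_len(n))
  if (is.null(u5m_2003)) u5m_2003 <- rep(60, n)
  if (is.null(u5m_2014)) u5m_2014 <- rep(50, n)
  panel <- data.frame(
    county_id = rep(ids, 2),
    year = rep(c(2003L, 2014L), each = n),
    u5m = c(u5m_2003, u5m_2014),
    stringsAsFactors = FALSE
  )
  for (f in names(values)) panel[[f]] <- c(values[[f]][, 1], values[[f]][, 2])
  panel
}

# small full panel + adjacency + truth for quick MCMC runs
quick_sim <- function(n = 12, years = 2003:2010, seed = 1,
                      beta = c(f1 = -1, f2 = 0.8),
                      sigma_w = 0.3, sigma_nu = 0.05, sigma_t = 0.05,
                      sigma_delta = 0.1) {
  adj <- make_adjacency(n, seed = seed)
  cfg <- synth_config(
    n_counties = n, years = years, factor_names = names(beta), seed = seed,
    sigma_w = sigma_w, sigma_nu = sigma_nu, sigma_t = sigma_t,
    sigma_delta = sigma_delta, true_beta = beta, true_alpha = -1,
    overrides = list()
  )
  c(simulate_panel(cfg, adj), list(adjacency = adj, config = cfg))
}

# meta table for toy factors (f1 increasing-good, fbad prevalence-like)
toy_meta <- function(factors, higher = rep(TRUE, length(factors)),
                     t22 = rep(NA_real_, length(factors)),
                     t25 = rep(NA_real_, length(factors))) {
  data.frame(factor = factors, higher_is_better = higher,
             baseline_2014_pct = NA_real_, target_2022_pct = t22,
             target_2025_pct = t25, stringsAsFactors = FALSE)
}
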