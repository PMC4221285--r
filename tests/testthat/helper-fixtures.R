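# Shared fixtures, built in code and cached per test run.

.fixtures <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

small_world <- function(seed = 5) {
  cached(paste0("world", seed),
         generate_landscape(landscape_config(n_rows = 60, n_cols = 60,
                                             seed = seed)))
}

small_stack <- function(seed = 5) {
  cached(paste0("stack", seed), build_covariate_stack(small_world(seed)))
}

# presence tibble with hand-set metadata
presence_tbl <- function(x, y, protocol = "stationary", travel_km = NA,
                         area_ha = NA, date = as.Date("2005-06-15"),
                         species = "sp") {
  n <- max(length(x), length(y))
  tibble::tibble(species = species, x = rep_len(x, n), y = rep_len(y, n),
                 date = rep_len(as.Date(date), n),
                 protocol = rep_len(protocol, n),
                 travel_km = rep_len(as.double(travel_km), n),
                 area_ha = rep_len(as.double(area_ha), n))
}

# toy maxent problem: presences are a subset of the background cells, so the
# unregularized optimum is finite and oracle-checkable
toy_problem <- function(n_bg = 20, n_pres = 6, n_cov = 2, seed = 3) {
  set.seed(seed)
  bg <- tibble::as_tibble(stats::setNames(
    as.data.frame(matrix(stats::runif(n_bg * n_cov), n_bg, n_cov)),
    paste0("v", seq_len(n_cov))))
  pr <- bg[sample.int(n_bg, n_pres, replace = TRUE), , drop = FALSE]
  list(presence = pr, background = bg)
}

# exact penalized maxent objective for oracle checks
maxent_objective <- function(lambda, Fp, Fb, beta = 0) {
  -mean(Fp %*% lambda) + log(sum(exp(Fb %*% lambda))) + sum(beta * abs(lambda))
}

# scaled linear feature matrices matching build_features() scaling
toy_feature_matrices <- function(pr, bg) {
  all <- dplyr::bind_rows(pr, bg)
  sc <- function(v, a) (v - min(a)) / (max(a) - min(a))
  Fp <- vapply(names(all), function(nm) sc(pr[[nm]], all[[nm]]),
               numeric(nrow(pr)))
  Fb <- vapply(names(all), function(nm) sc(bg[[nm]], all[[nm]]),
               numeric(nrow(bg)))
  list(Fp = matrix(Fp, nrow(pr)), Fb = matrix(Fb, nrow(bg)))
}
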