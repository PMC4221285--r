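# The twelve-run simulation design: three contemporary fits with covariate
# subsets, nine future projections of the full model under scenario-specific
# climate-only / LULC-only / combined change, net range change, range-class
# stratification and cross-species summaries.

climate_vars <- c("avg_temp", "avg_precip")
topo_vars <- c("elevation", "slope", "cti")
lulc_vars <- c("cropland_count", "forest_count", "grass_count", "hay_count",
               "shrub_count", "urban_count", "water_count", "wetland_count",
               "lulc_diversity")

covariate_subset <- function(config) {
  switch(config,
    all = c(lulc_vars, climate_vars, topo_vars),
    climate_no_lulc = c(climate_vars, topo_vars),
    lulc_no_climate = c(lulc_vars, topo_vars),
    stop("unknown covariate config: ", config, call. = FALSE))
}

#' Build the per-species twelve-run design
#'
#' Three contemporary runs (all covariates; climate + topography; LULC +
#' topography) and, for each scenario, three future projections of the run-1
#' model (combined change; climate change with static LULC; LULC change with
#' static climate).  Topography is static in every run.
#'
#' @param scenarios Character vector of scenario names (default the three
#'   emissions-storyline presets).
#' @return Tibble of run specs: `run_id`, `epoch`, `config`, `scenario`,
#'   `model_run` (the run whose fitted model a projection uses).
#' @export
build_design <- function(scenarios = c("A1B", "A2", "B1")) {
  base <- tibble::tibble(
    run_id = 1:3, epoch = "contemporary",
    config = c("all", "climate_no_lulc", "lulc_no_climate"),
    scenario = NA_character_, model_run = NA_integer_)
  fut <- purrr::map_dfr(scenarios, function(sc) {
    tibble::tibble(epoch = "future",
                   config = c("both_change", "climate_change_only",
                              "lulc_change_only"),
                   scenario = sc, model_run = 1L)
  })
  fut$run_id <- 3L + seq_len(nrow(fut))
  dplyr::bind_rows(base, fut[, names(base)])
}

# Hybrid projection stack: climate and/or LULC-derived layers from the future
# stack, everything else (always topography) from the contemporary stack.
hybrid_stack <- function(stack_2001, stack_future, config) {
  out <- stack_2001
  take <- switch(config,
    both_change = c(climate_vars, lulc_vars),
    climate_change_only = climate_vars,
    lulc_change_only = lulc_vars,
    stop("unknown projection config: ", config, call. = FALSE))
  for (v in take) out[[v]] <- stack_future[[v]]
  out
}

#' Execute the twelve-run design for one species
#'
#' Fits the three contemporary models on the stated covariate subsets
#' (75/25 presence split, shared background sample), evaluates each (AUC,
#' max-SSS threshold, suitable area), then projects the run-1 model onto the
#' clamped hybrid stacks for every future run and computes net range change
#' relative to the run-1 contemporary range.  The whole suite is reproducible
#' from `seed`.
#'
#' @param presences Filtered presence tibble (`x`, `y`, ...).
#' @param world_2001 Contemporary `synthetic_world` (or any list of aligned
#'   layers accepted by [build_covariate_stack()]).
#' @param worlds_2075 Named list of future worlds, one per scenario in
#'   `design`.
#' @param design Run-spec tibble from [build_design()].
#' @param buffer_km Study-extent buffer (default 500).
#' @param n_background Background points (default 10,000).
#' @param train_frac Training fraction (default 0.75).
#' @param reg_multiplier,max_iter,tol Passed to [fit_maxent()].
#' @param seed Master seed for split and background sampling.
#' @param keep_maps Keep per-run suitability/range rasters (default TRUE).
#' @return An `sdm_run_set`: `results` tibble (one row per run), fitted
#'   `models`, the shared `extent`, and (optionally) `maps` and `ranges`.
#' @export
run_design <- function(presences, world_2001, worlds_2075 = list(),
                       design = build_design(), buffer_km = 500,
                       n_background = 10000, train_frac = 0.75,
                       reg_multiplier = 1.0, max_iter = 500, tol = 1e-5,
                       seed = 1L, keep_maps = TRUE) {
  template <- world_2001$lulc
  extent <- buffer_extent(presences, template, buffer_km = buffer_km)
  bg <- sample_background(extent, n = n_background, seed = seed + 1L)
  split <- split_presences(presences, train_frac = train_frac, seed = seed + 2L)
  stack_2001 <- build_covariate_stack(world_2001)
  stacks_fut <- purrr::map(worlds_2075, build_covariate_stack)

  bg_cov <- extract_covariates(stack_2001, bg)
  train_cov <- extract_covariates(stack_2001, split$train)
  test_cov <- extract_covariates(stack_2001, split$test)

  fut_specs <- design[design$epoch == "future", , drop = FALSE]
  missing_sc <- setdiff(unique(fut_specs$scenario), names(stacks_fut))
  if (length(missing_sc) > 0) {
    warning("no future world for scenario(s) ", paste(missing_sc, collapse = ", "),
            "; those runs are skipped", call. = FALSE)
    design <- design[!(design$epoch == "future" & design$scenario %in% missing_sc), ]
  }

  models <- list(); maps <- list(); ranges <- list()
  rows <- list()
  run1_area <- NA_real_; run1_tau <- NA_real_

  for (i in seq_len(nrow(design))) {
    spec <- design[i, ]
    rid <- as.character(spec$run_id)
    if (spec$epoch == "contemporary") {
      vars <- covariate_subset(spec$config)
      mod <- fit_maxent(train_cov[vars], bg_cov[vars],
                        reg_multiplier = reg_multiplier,
                        max_iter = max_iter, tol = tol)
      ev <- evaluate_model(mod, train_cov[vars], test_cov[vars], bg_cov[vars])
      map <- predict_suitability(mod, stack_2001, extent = extent, clamp = TRUE)
      rng <- apply_threshold(map, ev$tau)
      models[[rid]] <- mod
      if (spec$run_id == 1L) {
        run1_area <- sum(rng$values == 1, na.rm = TRUE)
        run1_tau <- ev$tau
      }
      row <- dplyr::bind_cols(spec, ev,
        tibble::tibble(
          area_extent_pct = suitable_area_pct(rng, "study_extent"),
          area_domain_pct = suitable_area_pct(rng, "full_domain"),
          net_change_pct = NA_real_))
    } else {
      if (is.null(models[["1"]])) stop("run-1 model must be fitted before projections", call. = FALSE)
      stk <- hybrid_stack(stack_2001, stacks_fut[[spec$scenario]], spec$config)
      map <- predict_suitability(models[["1"]], stk, extent = extent, clamp = TRUE)
      rng <- apply_threshold(map, run1_tau)
      a <- sum(rng$values == 1, na.rm = TRUE)
      row <- dplyr::bind_cols(spec,
        tibble::tibble(
          auc_train = NA_real_, auc_test = NA_real_, tau = run1_tau,
          sensitivity = NA_real_, specificity = NA_real_,
          area_extent_pct = suitable_area_pct(rng, "study_extent"),
          area_domain_pct = suitable_area_pct(rng, "full_domain"),
          net_change_pct = 100 * (a - run1_area) / run1_area))
    }
    if (keep_maps) { maps[[rid]] <- map; ranges[[rid]] <- rng }
    rows[[i]] <- row
  }
  structure(list(results = dplyr::bind_rows(rows), models = models,
                 extent = extent, maps = maps, ranges = ranges,
                 background = bg, split = split, seed = seed),
            class = "sdm_run_set")
}

#' @export
print.sdm_run_set <- function(x, ...) {
  cat(sprintf("<sdm_run_set> %d runs (%d fitted models)\n",
              nrow(x$results), length(x$models)))
  print(x$results[, c("run_id", "epoch", "config", "scenario", "auc_test",
                      "area_extent_pct", "net_change_pct")])
  invisible(x)
}

#' Net range change between two epochs
#'
#' `(area_future - area_contemporary) / area_contemporary * 100`, by suitable
#' cell counts.
#'
#' @param range_2001,range_2075 Binary range maps from [apply_threshold()].
#' @return One-row tibble: suitable cell counts and `net_change_pct`.
#' @export
net_range_change <- function(range_2001, range_2075) {
  assert_aligned(range_2001, range_2075)
  a0 <- sum(range_2001$values == 1, na.rm = TRUE)
  a1 <- sum(range_2075$values == 1, na.rm = TRUE)
  tibble::tibble(cells_2001 = a0, cells_2075 = a1,
                 net_change_pct = if (a0 > 0) 100 * (a1 - a0) / a0 else NA_real_)
}

#' Classify a species range against the study-domain boundary
#'
#' `whole_range` when at least `whole_range_frac` of the full (truth) range
#' lies inside the domain; otherwise `double_truncated` when the in-domain
#' range reaches both the northern and southern domain edge rows,
#' `single_truncated` when it reaches exactly one.  A truncated range
#' touching neither edge is labelled `single_truncated` with a warning (the
#' taxonomy has no east/west class).
#'
#' @param range_full Binary [raster_grid()] of the full range on a grid
#'   containing the domain.
#' @param domain_mask Logical matrix on the same grid (TRUE = in-domain).
#' @param whole_range_frac Inside fraction defining `whole_range`.
#' @return One-row tibble: `range_class`, `frac_inside`, `touch_north`,
#'   `touch_south`.
#' @export
classify_range <- function(range_full, domain_mask, whole_range_frac = 0.95) {
  suit <- range_full$values == 1
  total <- sum(suit, na.rm = TRUE)
  if (total == 0) stop("empty range", call. = FALSE)
  inside <- sum(suit & domain_mask, na.rm = TRUE)
  frac <- inside / total
  dom_rows <- which(apply(domain_mask, 1, any))
  north <- min(dom_rows); south <- max(dom_rows)
  touch_n <- any(suit[north, ] & domain_mask[north, ], na.rm = TRUE)
  touch_s <- any(suit[south, ] & domain_mask[south, ], na.rm = TRUE)
  cls <- if (frac >= whole_range_frac) {
    "whole_range"
  } else if (touch_n && touch_s) {
    "double_truncated"
  } else if (touch_n || touch_s) {
    "single_truncated"
  } else {
    warning("truncated range touches neither north nor south edge; ",
            "labelled single_truncated", call. = FALSE)
    "single_truncated"
  }
  tibble::tibble(range_class = cls, frac_inside = frac,
                 touch_north = touch_n, touch_south = touch_s)
}

#' Paired t-test across species
#'
#' Classic paired t on the per-species differences, two-sided p from the t
#' distribution with `n - 1` degrees of freedom.  Degenerate zero-variance
#' differences return `t = 0, p = 1` when the mean difference is zero.
#'
#' @param a,b Numeric vectors of per-species values, same length and order.
#' @return One-row tibble: `estimate` (mean difference), `t`, `df`, `p`.
#' @export
paired_ttest <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  d <- a - b
  if (stats::sd(d) == 0) {
    return(tibble::tibble(estimate = mean(d),
                          t = if (mean(d) == 0) 0 else sign(mean(d)) * Inf,
                          df = length(d) - 1,
                          p = if (mean(d) == 0) 1 else 0))
  }
  ht <- stats::t.test(a, b, paired = TRUE)
  tibble::tibble(estimate = unname(ht$estimate), t = unname(ht$statistic),
                 df = unname(ht$parameter), p = ht$p.value)
}

#' Cross-species summary stratified by range class
#'
#' Per-class arithmetic means of every numeric metric column, computed only
#' over the species in each class.
#'
#' @param results Tibble with a `species` column and numeric metric columns.
#' @param labels Tibble with `species` and `range_class`.
#' @return Tibble of per-class means with an `n_species` column.
#' @export
summarize_by_class <- function(results, labels) {
  dplyr::inner_join(results, labels[, c("species", "range_class")],
                    by = "species") |>
    dplyr::group_by(.data$range_class) |>
    dplyr::summarise(
      n_species = dplyr::n_distinct(.data$species),
      dplyr::across(dplyr::where(is.numeric), ~ mean(.x, na.rm = TRUE)),
      .groups = "drop")
}

#' Scenario-variability summary of net range change
#'
#' Per species and projection config: mean, min and max net change across
#' scenarios (the bar-and-whisker numbers of a scenario-variability figure).
#'
#' @param results A run-result tibble (e.g. `run_design()$results` with a
#'   `species` column added) containing future runs.
#' @return Tibble with per-species/config `mean_change`, `min_change`,
#'   `max_change`.
#' @export
scenario_variability <- function(results) {
  results |>
    dplyr::filter(.data$epoch == "future") |>
    dplyr::group_by(dplyr::across(dplyr::any_of(c("species", "config")))) |>
    dplyr::summarise(mean_change = mean(.data$net_change_pct),
                     min_change = min(.data$net_change_pct),
                     max_change = max(.data$net_change_pct),
                     .groups = "drop")
}
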