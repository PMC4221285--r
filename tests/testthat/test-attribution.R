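test_that("the design holds 3 contemporary and 9 future runs per species", {
  d <- build_design()
  expect_equal(nrow(d), 12)
  expect_equal(sum(d$epoch == "contemporary"), 3)
  expect_equal(sum(d$epoch == "future"), 9)
  expect_true(all(d$model_run[d$epoch == "future"] == 1L))
  expect_equal(nrow(d) * 50, 600)
  d1 <- build_design(scenarios = "A1B")
  expect_equal(nrow(d1), 6)
  expect_equal(d$run_id, 1:12)
  expect_setequal(unique(d$config[d$epoch == "future"]),
                  c("both_change", "climate_change_only", "lulc_change_only"))
})

test_that("net range change matches independent cell arithmetic", {
  a <- raster_grid(matrix(c(rep(1, 40), rep(0, 60)), 10, 10))
  expect_equal(net_range_change(a, a)$net_change_pct, 0)
  b <- raster_grid(matrix(c(rep(1, 20), rep(0, 80)), 10, 10))
  expect_equal(net_range_change(a, b)$net_change_pct, -50)
  set.seed(44)
  r1 <- raster_grid(matrix(rbinom(100, 1, 0.4), 10, 10))
  r2 <- raster_grid(matrix(rbinom(100, 1, 0.3), 10, 10))
  out <- net_range_change(r1, r2)
  expect_equal(out$net_change_pct,
               100 * (sum(r2$values) - sum(r1$values)) / sum(r1$values))
  expect_gte(out$net_change_pct, -100)
})

test_that("range classification separates whole, single- and double-truncated", {
  dom <- matrix(TRUE, 20, 20)
  interior <- matrix(0, 20, 20); interior[8:12, 8:12] <- 1
  expect_equal(classify_range(raster_grid(interior), dom)$range_class,
               "whole_range")
  spanning <- matrix(0, 20, 20); spanning[, 9:11] <- 1
  # spans north to south; pretend most of the range is outside the domain
  expect_equal(
    classify_range(raster_grid(spanning), dom, whole_range_frac = 1.01)$range_class,
    "double_truncated")
  south <- matrix(0, 20, 20); south[15:20, ] <- 1
  expect_equal(
    classify_range(raster_grid(south), dom, whole_range_frac = 1.01)$range_class,
    "single_truncated")
  # truncated but touching neither edge: warned, single_truncated
  mid <- matrix(0, 20, 20); mid[8:12, 1:20] <- 1
  expect_warning(
    out <- classify_range(raster_grid(mid), dom, whole_range_frac = 1.01),
    "neither")
  expect_equal(out$range_class, "single_truncated")
  # a domain-window view: range extends beyond a smaller domain
  dom2 <- matrix(FALSE, 20, 20); dom2[5:15, ] <- TRUE
  tall <- matrix(0, 20, 20); tall[1:20, 3:6] <- 1
  cl <- classify_range(raster_grid(tall), dom2)
  expect_equal(cl$range_class, "double_truncated")
  expect_lt(cl$frac_inside, 0.95)
})

test_that("paired t matches the hand formula and handles degenerate input", {
  a <- c(3, 5, 7); b <- c(2, 3, 4)  # differences 1, 2, 3
  out <- paired_ttest(a, b)
  expect_equal(out$t, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(out$df, 2)
  expect_equal(out$p, 2 * stats::pt(-2 * sqrt(3), df = 2), tolerance = 1e-12)
  # swap flips t, keeps p
  sw <- paired_ttest(b, a)
  expect_equal(sw$t, -out$t)
  expect_equal(sw$p, out$p)
  eq <- paired_ttest(a, a)
  expect_equal(eq$t, 0)
  expect_equal(eq$p, 1)
})

test_that("class summaries are per-class means over member species", {
  res <- tibble::tibble(
    species = c("s1", "s2", "s3", "s4"),
    auc = c(0.9, 0.8, 0.7, 0.6),
    area = c(10, 20, 30, 40))
  labels <- tibble::tibble(
    species = c("s1", "s2", "s3", "s4"),
    range_class = c("whole_range", "whole_range", "single_truncated",
                    "double_truncated"))
  out <- summarize_by_class(res, labels)
  expect_equal(out$auc[out$range_class == "whole_range"], 0.85)
  expect_equal(out$area[out$range_class == "whole_range"], 15)
  expect_equal(out$auc[out$range_class == "single_truncated"], 0.7)
  expect_equal(out$n_species, c(1, 1, 2)[order(c("double_truncated",
                                                 "single_truncated",
                                                 "whole_range"))])
})

test_that("the twelve-run suite attributes change to the family that changed", {
  w <- small_world(seed = 21)
  sp <- virtual_species(temp_optimum = 9, temp_tolerance = 2)
  ps <- sample_presences(w, sp, 350, bias = bias_spec(n_hotspots = 0), seed = 51)
  # climate-only change scenario
  clim_only <- apply_scenario(w, scenario_config("warm", warming_delta = 2.5,
                                                 seed = 3))
  rs <- run_design(ps, w, list(W = clim_only),
                   design = build_design(scenarios = "W"),
                   n_background = 2000, seed = 52, max_iter = 300)
  res <- rs$results
  # identity hybrid: LULC did not change, so lulc_change_only equals run 1
  lulc_row <- res[res$config == "lulc_change_only" & !is.na(res$config), ]
  expect_equal(lulc_row$net_change_pct, 0)
  r1map <- rs$maps[["1"]]
  lulc_map <- rs$maps[[as.character(lulc_row$run_id)]]
  expect_identical(r1map$values, lulc_map$values)
  # climate change moved the range; combined equals climate-only here
  clim_row <- res[res$config == "climate_change_only" & !is.na(res$config), ]
  both_row <- res[res$config == "both_change" & !is.na(res$config), ]
  expect_false(isTRUE(all.equal(clim_row$net_change_pct, 0)))
  expect_equal(both_row$net_change_pct, clim_row$net_change_pct)
  expect_identical(rs$maps[[as.character(both_row$run_id)]]$values,
                   rs$maps[[as.character(clim_row$run_id)]]$values)
})

test_that("projection spot-checks match manual feature evaluation on hybrid stacks", {
  w <- small_world(seed = 21)
  sp <- virtual_species()
  ps <- sample_presences(w, sp, 250, bias = bias_spec(n_hotspots = 0), seed = 61)
  fut <- apply_scenario(w, scenario_preset("A2", seed = 4))
  rs <- run_design(ps, w, list(A2 = fut), design = build_design("A2"),
                   n_background = 1500, seed = 62, max_iter = 200)
  stack_2001 <- build_covariate_stack(w)
  stack_fut <- build_covariate_stack(fut)
  hyb <- avirange:::hybrid_stack(stack_2001, stack_fut, "both_change")
  m1 <- rs$models[["1"]]
  map4 <- rs$maps[["4"]]
  set.seed(63)
  cells <- which(!is.na(map4$values))[sample(sum(!is.na(map4$values)), 10)]
  nr <- nrow(map4$values)
  rows <- ((cells - 1) %% nr) + 1; cols <- ((cells - 1) %/% nr) + 1
  df <- tibble::as_tibble(lapply(hyb[m1$features$bounds$variable],
                                 function(r) r$values[cbind(rows, cols)]))
  manual <- predict(m1, df, type = "logistic", clamp = TRUE)
  expect_equal(unname(map4$values[cbind(rows, cols)]), unname(manual))
})

test_that("scenario variability reports mean/min/max across scenarios", {
  res <- tibble::tibble(
    species = "s", epoch = "future",
    config = rep(c("both_change", "climate_change_only"), each = 3),
    net_change_pct = c(10, 20, 30, -5, 0, 5))
  sv <- scenario_variability(res)
  expect_equal(sv$mean_change[sv$config == "both_change"], 20)
  expect_equal(sv$min_change[sv$config == "climate_change_only"], -5)
  expect_equal(sv$max_change[sv$config == "both_change"], 30)
})
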