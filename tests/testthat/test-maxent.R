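test_that("feature classes activate with presence sample size", {
  train <- tibble::tibble(a = runif(100), b = runif(100))
  f9 <- build_features(train, n_presence = 9)
  expect_setequal(unique(f9$defs$type), "linear")
  f12 <- build_features(train, n_presence = 12)
  expect_setequal(unique(f12$defs$type), c("linear", "quadratic"))
  f20 <- build_features(train, n_presence = 20)
  expect_true(all(c("hinge_fwd", "hinge_rev") %in% f20$defs$type))
  expect_false("threshold" %in% f20$defs$type)
  f100 <- build_features(train, n_presence = 100)
  expect_true(all(c("threshold", "product") %in% f100$defs$type))
})

test_that("a 14-covariate model at n = 100 holds all 91 product pairs", {
  set.seed(9)
  train <- tibble::as_tibble(stats::setNames(
    as.data.frame(matrix(runif(1400), 100)), paste0("v", 1:14)))
  fs <- build_features(train, n_presence = 100)
  expect_equal(sum(fs$defs$type == "product"), choose(14, 2))
})

test_that("features stay in [0, 1] on training data; constants are dropped", {
  set.seed(10)
  train <- tibble::tibble(a = rnorm(50), b = runif(50, -5, 20), k = rep(3, 50))
  expect_warning(fs <- build_features(train, n_presence = 50), "constant")
  expect_false("k" %in% fs$bounds$variable)
  Fm <- avirange:::evaluate_features(fs, train)
  expect_true(all(Fm >= 0 & Fm <= 1))
})

test_that("clamping caps values at the training range and is the identity within", {
  fs <- build_features(tibble::tibble(a = c(0, 10)), n_presence = 50)
  out <- clamp_covariates(fs, tibble::tibble(a = c(-5, 3, 20)))
  expect_equal(out$a, c(0, 3, 10))
  stk <- small_stack()
  m <- list(features = build_features(
    tibble::as_tibble(lapply(stk, function(r) as.vector(r$values))),
    n_presence = 100))
  class(m) <- "maxent_model"
  clamped <- clamp_stack(stk, m)
  for (nm in names(stk)) expect_equal(clamped[[nm]]$values, stk[[nm]]$values)
})

test_that("unregularized fits match a multi-start quasi-grid oracle", {
  for (seed in 1:3) {
    tp <- toy_problem(n_bg = 30, n_pres = 8, n_cov = 3, seed = seed)
    m <- fit_maxent(tp$presence, tp$background, reg_multiplier = 0,
                    feature_classes = "linear", tol = 1e-12, max_iter = 50000)
    fm <- toy_feature_matrices(tp$presence, tp$background)
    obj <- function(l) maxent_objective(l, fm$Fp, fm$Fb)
    # multi-start BFGS stands in for a dense grid search
    starts <- rbind(0, expand.grid(l1 = c(-2, 2), l2 = c(-2, 2),
                                   l3 = c(-2, 2)))
    best <- min(apply(starts, 1, function(s0) {
      stats::optim(as.numeric(s0), obj, method = "BFGS",
                   control = list(reltol = 1e-14, maxit = 2000))$value
    }))
    expect_lt(abs(obj(m$lambda) - best), 1e-4)
    # constraint satisfaction at beta = 0
    q <- exp(fm$Fb %*% m$lambda); q <- q / sum(q)
    expect_true(all(abs(t(fm$Fb) %*% q - colMeans(fm$Fp)) < 1e-3))
  }
})

test_that("a separating binary feature drives the presence expectation to 1", {
  # presences have the feature, most background does not
  pr <- tibble::tibble(a = rep(1, 10))
  bg <- tibble::tibble(a = c(rep(0, 38), 1, 1))
  fs <- build_features(dplyr::bind_rows(pr, bg), n_presence = 10,
                       feature_classes = "linear")
  m <- fit_maxent(pr, bg, feature_space = fs, reg_multiplier = 0,
                  tol = 1e-10, max_iter = 10000)
  q <- exp(m$lambda[1] * bg$a)
  q <- q / sum(q)
  expect_gt(sum(q * bg$a), 0.9)
  expect_gt(m$lambda[1], 0)
})

test_that("null models predict logistic 0.5 and raw sums to 1 over background", {
  tp <- toy_problem(seed = 8)
  m <- fit_maxent(tp$presence, tp$background, max_iter = 0)
  expect_equal(unname(predict(m, tp$background)), rep(0.5, 20))
  m2 <- fit_maxent(tp$presence, tp$background)
  raw <- predict(m2, tp$background, type = "raw")
  expect_equal(sum(raw), 1, tolerance = 1e-9)
  # monotone transform: logistic order matches link order
  eta <- predict(m2, tp$background, type = "link")
  lgs <- predict(m2, tp$background, type = "logistic")
  expect_equal(order(eta), order(lgs))
  expect_true(all(lgs > 0 & lgs < 1))
})

test_that("gain never decreases and regularization shrinks total weight", {
  tp <- toy_problem(n_bg = 40, n_pres = 20, seed = 12)
  m1 <- fit_maxent(tp$presence, tp$background, reg_multiplier = 0.5)
  m2 <- fit_maxent(tp$presence, tp$background, reg_multiplier = 1)
  m4 <- fit_maxent(tp$presence, tp$background, reg_multiplier = 4)
  expect_gte(m1$gain, 0)
  expect_gte(sum(abs(m1$lambda)), sum(abs(m2$lambda)))
  expect_gte(sum(abs(m2$lambda)), sum(abs(m4$lambda)))
})

test_that("percent contributions normalize to 100 and find the one informative variable", {
  set.seed(13)
  n <- 150
  bg <- tibble::tibble(sig = runif(n), noise = runif(n))
  # presences concentrated at high `sig`, indifferent to `noise`
  pr <- tibble::tibble(sig = rbeta(60, 5, 1), noise = runif(60))
  m <- fit_maxent(pr, bg)
  pc <- percent_contribution(m)
  expect_equal(sum(pc$contribution_pct), 100, tolerance = 1e-6)
  expect_equal(pc$variable[1], "sig")
  expect_gt(pc$contribution_pct[1], 60)
  # duplicated covariate: combined share of the two copies stays put
  bg2 <- dplyr::mutate(bg, sig2 = sig)
  pr2 <- dplyr::mutate(pr, sig2 = sig)
  m2 <- fit_maxent(pr2, bg2)
  pc2 <- percent_contribution(m2)
  comb <- sum(pc2$contribution_pct[pc2$variable %in% c("sig", "sig2")])
  expect_lt(abs(comb - pc$contribution_pct[pc$variable == "sig"]), 15)
})

test_that("temperature dominates contributions for a climate-only species", {
  w <- small_world()
  sp <- virtual_species(mixing_weight_climate = 1)
  stk <- small_stack()
  ok <- 0
  for (seed in 1:3) {
    ps <- sample_presences(w, sp, 300, bias = bias_spec(n_hotspots = 0),
                           seed = seed)
    ext <- buffer_extent(ps, w$lulc, buffer_km = 500)
    bg <- sample_background(ext, n = 2000, seed = seed + 50)
    pc <- extract_covariates(stk, ps)[names(stk)]
    bc <- extract_covariates(stk, bg)[names(stk)]
    m <- fit_maxent(pc, bc)
    tab <- percent_contribution(m)
    temp <- tab$contribution_pct[tab$variable == "avg_temp"]
    lulc_max <- max(tab$contribution_pct[tab$category == "lulc"])
    if (temp > lulc_max) ok <- ok + 1
  }
  expect_gte(ok, 2)
})

test_that("tidy and glance expose the fitted structure", {
  tp <- toy_problem(n_bg = 40, n_pres = 20, seed = 14)
  m <- fit_maxent(tp$presence, tp$background)
  td <- tidy(m)
  expect_true(all(c("type", "var1", "lambda", "beta") %in% names(td)))
  expect_true(all(td$lambda != 0))
  gl <- glance(m)
  expect_equal(gl$n_presence, 20)
  expect_equal(gl$n_active, nrow(td))
  expect_error(predict(structure(list(), class = "maxent_model"),
                       tp$background))
})
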