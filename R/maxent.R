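# Presence-only maximum-entropy model, implemented from first principles:
# min-max scaled feature expansion (linear / quadratic / product / hinge /
# threshold), L1-penalized Gibbs density over background points fitted by
# sequential coordinate descent with a closed-form bound-minimizing update
# (best feature per iteration), raw
# and logistic outputs, and percent-contribution accounting from the gain
# trajectory.

# Default regularization multipliers per feature class, linearly interpolated
# in presence sample size and clamped at the table ends. An encoded
# approximation of the defaults popularised by the reference maxent software.
beta_table <- list(
  lqp = list(n = c(10, 30, 100), beta = c(1.0, 0.2, 0.05)),
  hinge = list(n = c(10, 100), beta = c(0.5, 0.5)),
  threshold = list(n = c(10, 100), beta = c(2.0, 1.0))
)

beta_multiplier <- function(class, m) {
  tb <- beta_table[[class]]
  stats::approx(tb$n, tb$beta, xout = m, rule = 2)$y
}

feature_beta_class <- function(type) {
  dplyr::case_when(
    type %in% c("linear", "quadratic", "product") ~ "lqp",
    type %in% c("hinge_fwd", "hinge_rev") ~ "hinge",
    TRUE ~ "threshold"
  )
}

#' Build the maxent feature space
#'
#' Min-max scales every covariate to `[0, 1]` using the training values
#' (presence plus background) and expands features.  Feature classes activate
#' with presence sample size, following the conventional defaults: linear
#' always, quadratic at n >= 10, hinge at n >= 15, threshold and product at
#' n >= 80.  Hinge and threshold knots sit at `n_knots` evenly spaced
#' quantiles of the scaled training values.  Constant covariates are dropped
#' with a warning.  Every feature maps scaled inputs into `[0, 1]`.
#'
#' @param train Data frame of covariate columns (presence and background rows
#'   together).
#' @param n_presence Presence sample size governing feature-class activation.
#' @param n_knots Knots per covariate for hinge/threshold features.
#' @param feature_classes Optional character vector overriding activation,
#'   from `c("linear", "quadratic", "product", "hinge", "threshold")`.
#' @return A `maxent_features` object: covariate `bounds` and a feature
#'   definition tibble.
#' @export
build_features <- function(train, n_presence, n_knots = 50,
                           feature_classes = NULL) {
  train <- tibble::as_tibble(train)
  lo <- vapply(train, min, 0, na.rm = TRUE)
  hi <- vapply(train, max, 0, na.rm = TRUE)
  const <- hi - lo <= 0
  if (any(const)) {
    warning("dropping constant covariate(s): ",
            paste(names(train)[const], collapse = ", "), call. = FALSE)
    train <- train[!const]
    lo <- lo[!const]; hi <- hi[!const]
  }
  vars <- names(train)
  if (length(vars) == 0L) stop("no non-constant covariates", call. = FALSE)
  if (is.null(feature_classes)) {
    feature_classes <- "linear"
    if (n_presence >= 10) feature_classes <- c(feature_classes, "quadratic")
    if (n_presence >= 15) feature_classes <- c(feature_classes, "hinge")
    if (n_presence >= 80) feature_classes <- c(feature_classes, "threshold", "product")
  }
  scaled <- purrr::map2(train, seq_along(vars),
                        function(v, i) (v - lo[i]) / (hi[i] - lo[i]))
  defs <- list(tibble::tibble(type = "linear", var1 = vars, var2 = NA_character_,
                              knot = NA_real_))
  if ("quadratic" %in% feature_classes) {
    defs <- c(defs, list(tibble::tibble(type = "quadratic", var1 = vars,
                                        var2 = NA_character_, knot = NA_real_)))
  }
  if ("product" %in% feature_classes && length(vars) >= 2) {
    prs <- utils::combn(vars, 2)
    defs <- c(defs, list(tibble::tibble(type = "product", var1 = prs[1, ],
                                        var2 = prs[2, ], knot = NA_real_)))
  }
  knot_defs <- function(type_names) {
    purrr::map_dfr(vars, function(v) {
      probs <- seq_len(n_knots) / (n_knots + 1)
      ks <- unique(unname(stats::quantile(scaled[[v]], probs, na.rm = TRUE)))
      ks <- ks[ks > 0 & ks < 1]
      if (length(ks) == 0L) return(NULL)
      purrr::map_dfr(type_names, function(tp) {
        tibble::tibble(type = tp, var1 = v, var2 = NA_character_, knot = ks)
      })
    })
  }
  if ("hinge" %in% feature_classes) {
    defs <- c(defs, list(knot_defs(c("hinge_fwd", "hinge_rev"))))
  }
  if ("threshold" %in% feature_classes) {
    defs <- c(defs, list(knot_defs("threshold")))
  }
  defs <- dplyr::bind_rows(defs)
  defs$name <- paste0(defs$type, ":", defs$var1,
                      ifelse(is.na(defs$var2), "", paste0("*", defs$var2)),
                      ifelse(is.na(defs$knot), "", sprintf("@%.4f", defs$knot)))
  structure(list(bounds = tibble::tibble(variable = vars, min = unname(lo),
                                         max = unname(hi)),
                 defs = defs, n_knots = n_knots,
                 feature_classes = feature_classes),
            class = "maxent_features")
}

#' @export
print.maxent_features <- function(x, ...) {
  cat(sprintf("<maxent_features> %d features over %d covariates (%s)\n",
              nrow(x$defs), nrow(x$bounds),
              paste(x$feature_classes, collapse = ", ")))
  invisible(x)
}

#' Clamp covariates to the training range
#'
#' Replaces each covariate value v by `min(max(v, train_min), train_max)` so
#' projection into novel conditions never extrapolates features beyond the
#' range the model was trained on.
#'
#' @param fs A `maxent_features` or fitted `maxent_model`.
#' @param data Data frame with the model's covariate columns.
#' @return The data frame with clamped covariate columns.
#' @export
clamp_covariates <- function(fs, data) {
  if (inherits(fs, "maxent_model")) fs <- fs$features
  b <- fs$bounds
  data <- tibble::as_tibble(data)
  for (i in seq_len(nrow(b))) {
    v <- b$variable[i]
    data[[v]] <- pmin(pmax(data[[v]], b$min[i]), b$max[i])
  }
  data
}

#' @rdname clamp_covariates
#' @param stack A `covariate_stack`.
#' @param model A fitted `maxent_model`.
#' @return `clamp_stack()`: the stack with each layer clamped to its training
#'   bounds.
#' @export
clamp_stack <- function(stack, model) {
  fs <- if (inherits(model, "maxent_model")) model$features else model
  b <- fs$bounds
  out <- stack
  for (i in seq_len(nrow(b))) {
    v <- b$variable[i]
    if (is.null(out[[v]])) next
    r <- out[[v]]
    r$values <- pmin(pmax(r$values, b$min[i]), b$max[i])
    out[[v]] <- r
  }
  out
}

# Evaluate (a subset of) features on raw covariate data -> matrix in [0, 1].
evaluate_features <- function(fs, data, feature_idx = NULL, clamp = TRUE) {
  if (clamp) data <- clamp_covariates(fs, data)
  b <- fs$bounds
  scaled <- list()
  for (i in seq_len(nrow(b))) {
    v <- b$variable[i]
    z <- (data[[v]] - b$min[i]) / (b$max[i] - b$min[i])
    if (!clamp) z <- pmin(pmax(z, 0), 1)  # features stay in [0, 1] regardless
    scaled[[v]] <- z
  }
  defs <- fs$defs
  if (is.null(feature_idx)) feature_idx <- seq_len(nrow(defs))
  n <- length(scaled[[1]])
  out <- matrix(0, n, length(feature_idx))
  for (k in seq_along(feature_idx)) {
    j <- feature_idx[k]
    z <- scaled[[defs$var1[j]]]
    out[, k] <- switch(defs$type[j],
      linear = z,
      quadratic = z^2,
      product = z * scaled[[defs$var2[j]]],
      hinge_fwd = pmax(0, (z - defs$knot[j]) / (1 - defs$knot[j])),
      hinge_rev = pmax(0, (defs$knot[j] - z) / defs$knot[j]),
      threshold = (z >= defs$knot[j]) * 1
    )
  }
  colnames(out) <- defs$name[feature_idx]
  out
}

#' Fit a presence-only maxent model
#'
#' Minimizes the L1-penalized maxent objective
#' \deqn{J(\lambda) = -\tfrac1m \sum_{presence} \eta(x_i) + \log Z +
#'       \sum_j \beta_j |\lambda_j|,}
#' with \eqn{\eta(x) = \sum_j \lambda_j f_j(x)} and
#' \eqn{Z = \sum_{background} e^{\eta}}, by sequential coordinate descent:
#' each iteration evaluates, for every feature, the closed-form minimizer of
#' a convex upper bound on the one-dimensional objective (exact descent for
#' features in `[0, 1]`) and applies the single most-improving update, as in
#' the reference maxent algorithm.  The regularized training gain therefore
#' never decreases; per-update gain increments are recorded against the
#' feature's parent variable(s) for [percent_contribution()].  Per-feature
#' penalties are \eqn{\beta_j = \Lambda(class, m) \, s_j / \sqrt m \times}
#' `reg_multiplier`, where \eqn{s_j} is the presence-sample sd of the feature
#' and \eqn{\Lambda} the class default interpolated by sample size.
#'
#' @param presence,background Data frames of covariate columns (identical
#'   names); presence needs >= 2 rows.
#' @param feature_space Optional pre-built [build_features()] result; by
#'   default built from the combined training rows.
#' @param reg_multiplier Scales every `beta_j`; 0 disables regularization.
#' @param max_iter Maximum single-feature updates (default 500).
#' @param tol Stop when no update can improve the gain bound by more than this.
#' @param n_knots,feature_classes Passed to [build_features()].
#' @return A fitted `maxent_model`.
#' @export
fit_maxent <- function(presence, background, feature_space = NULL,
                       reg_multiplier = 1.0, max_iter = 500, tol = 1e-5,
                       n_knots = 50, feature_classes = NULL) {
  presence <- tibble::as_tibble(presence)
  background <- tibble::as_tibble(background)
  m <- nrow(presence)
  if (m < 2L) stop("need at least 2 presence points", call. = FALSE)
  if (is.null(feature_space)) {
    feature_space <- build_features(dplyr::bind_rows(presence, background),
                                    n_presence = m, n_knots = n_knots,
                                    feature_classes = feature_classes)
  }
  fs <- feature_space
  Fp <- evaluate_features(fs, presence, clamp = FALSE)
  Fb <- evaluate_features(fs, background, clamp = FALSE)
  p <- ncol(Fb); nb <- nrow(Fb)
  e_tilde <- colMeans(Fp)
  sd_pres <- apply(Fp, 2, stats::sd)
  mult <- beta_multiplier("lqp", m) * (feature_beta_class(fs$defs$type) == "lqp") +
    beta_multiplier("hinge", m) * (feature_beta_class(fs$defs$type) == "hinge") +
    beta_multiplier("threshold", m) * (feature_beta_class(fs$defs$type) == "threshold")
  beta <- reg_multiplier * mult * pmax(sd_pres, 0.01) / sqrt(m)

  lam <- numeric(p)
  w <- rep(1, nb)
  Z <- nb
  mean_eta_p <- 0
  penalty <- 0
  J <- log(Z)
  J0 <- J
  eps <- 1e-12
  contrib <- stats::setNames(numeric(nrow(fs$bounds)), fs$bounds$variable)
  # precompute nonzero supports once for sparse-ish features
  supports <- vector("list", p)
  converged <- FALSE
  iter <- 0L
  # smooth presence expectations away from 0/1 by half a pseudo-count so a
  # feature never observed (or always 1) on presences cannot drive its weight
  # to the step cap; bounds |lambda*| near log(2m)
  et_cl <- pmin(pmax(e_tilde, 1 / (2 * m)), 1 - 1 / (2 * m))
  while (iter < max_iter) {
    iter <- iter + 1L
    q <- w / Z
    e_all <- pmin(pmax(as.vector(crossprod(Fb, q)), eps), 1 - eps)
    # closed-form minimizer of the per-feature upper bound, vectorized
    d1 <- log(pmax(((et_cl - beta) * (1 - e_all)) / ((1 - et_cl + beta) * e_all), 0))
    d2 <- log(pmax(((et_cl + beta) * (1 - e_all)) / ((1 - et_cl - beta) * e_all), 0))
    delta <- ifelse(et_cl - beta > eps & lam + d1 >= 0, d1,
                    ifelse(et_cl + beta < 1 - eps & is.finite(d2) & lam + d2 <= 0,
                           d2, -lam))
    delta <- pmin(pmax(delta, -30), 30)
    # bound on the objective change for each candidate update
    bnd <- -delta * e_tilde + log1p((exp(delta) - 1) * e_all) +
      beta * (abs(lam + delta) - abs(lam))
    j <- which.min(bnd)
    if (!is.finite(bnd[j]) || bnd[j] > -tol) { converged <- TRUE; break }
    dj <- delta[j]
    fbj <- Fb[, j]
    nz <- supports[[j]]
    if (is.null(nz)) {
      nz <- which(fbj != 0)
      if (length(nz) > 0.6 * nb) nz <- seq_len(nb)  # dense: index all rows
      supports[[j]] <- nz
    }
    w_old_nz <- w[nz]
    w[nz] <- w_old_nz * exp(dj * fbj[nz])
    Z_new <- Z + sum(w[nz] - w_old_nz)
    mean_eta_new <- mean_eta_p + dj * e_tilde[j]
    pen_new <- penalty + beta[j] * (abs(lam[j] + dj) - abs(lam[j]))
    J_new <- -mean_eta_new + log(Z_new) + pen_new
    if (J_new > J + 1e-10) {  # numerical guard; the bound guarantees descent
      w[nz] <- w_old_nz
      converged <- TRUE
      break
    }
    gain_inc <- J - J_new
    Z <- Z_new; mean_eta_p <- mean_eta_new; penalty <- pen_new; J <- J_new
    lam[j] <- lam[j] + dj
    v1 <- fs$defs$var1[j]; v2 <- fs$defs$var2[j]
    if (is.na(v2)) {
      contrib[v1] <- contrib[v1] + gain_inc
    } else {
      contrib[v1] <- contrib[v1] + gain_inc / 2
      contrib[v2] <- contrib[v2] + gain_inc / 2
    }
    if (iter %% 100L == 0L) {  # refresh against incremental drift
      eta_b <- as.vector(Fb[, lam != 0, drop = FALSE] %*% lam[lam != 0])
      w <- exp(eta_b)
      Z <- sum(w)
      J <- -mean_eta_p + log(Z) + penalty
    }
  }
  eta_b <- as.vector(Fb[, lam != 0, drop = FALSE] %*% lam[lam != 0])
  mean_eta_p <- sum(e_tilde * lam)
  w <- exp(eta_b)
  Z <- sum(w)
  q <- w / Z
  H <- -sum(q * log(q))
  penalty <- sum(beta * abs(lam))
  J <- -mean_eta_p + log(Z) + penalty
  structure(list(
    features = fs,
    lambda = stats::setNames(lam, fs$defs$name),
    beta = stats::setNames(beta, fs$defs$name),
    log_Z = log(Z),
    entropy = H,
    n_presence = m,
    n_background = nb,
    presence_feature_means = e_tilde,
    gain = J0 - J,
    gain_contributions = contrib,
    reg_multiplier = reg_multiplier,
    converged = converged,
    iterations = iter
  ), class = "maxent_model")
}

#' @export
print.maxent_model <- function(x, ...) {
  cat(sprintf(paste0("<maxent_model> %d presences, %d background, %d/%d active",
                     " features\n  gain %.4f, entropy %.4f, %s in %d cycles\n"),
              x$n_presence, x$n_background, sum(x$lambda != 0),
              length(x$lambda), x$gain, x$entropy,
              if (x$converged) "converged" else "NOT converged", x$iterations))
  invisible(x)
}

#' Predict from a fitted maxent model
#'
#' @param object A fitted `maxent_model`.
#' @param newdata Data frame with the model's covariate columns.
#' @param type `"logistic"` (default): \eqn{c\,q(x) / (1 + c\,q(x))} with
#'   \eqn{c = e^H}, calibrated so typical presence sites score about 0.5 and
#'   a null model scores exactly 0.5; `"raw"`: \eqn{e^{\eta(x)}/Z}, summing to
#'   1 over the training background; `"link"`: \eqn{\eta(x)}.
#' @param clamp Clamp covariates to the training range first (default TRUE;
#'   the identity on training-range data).
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.maxent_model <- function(object, newdata, type = c("logistic", "raw", "link"),
                                 clamp = TRUE, ...) {
  type <- match.arg(type)
  if (is.null(object$lambda) || is.null(object$log_Z)) {
    stop("model is not fitted", call. = FALSE)
  }
  active <- which(object$lambda != 0)
  eta <- if (length(active) == 0L) {
    rep(0, nrow(newdata))
  } else {
    Fm <- evaluate_features(object$features, newdata, feature_idx = active,
                            clamp = clamp)
    as.vector(Fm %*% object$lambda[active])
  }
  switch(type,
    link = eta,
    raw = exp(eta - object$log_Z),
    logistic = {
      cq <- exp(object$entropy + eta - object$log_Z)
      cq / (1 + cq)
    })
}

#' Project a model across a covariate stack
#'
#' Predicts the logistic output at every cell of the study extent (every cell
#' of the grid when `extent` is `NULL`); cells outside the extent are nodata.
#'
#' @param model A fitted `maxent_model`.
#' @param stack A `covariate_stack`.
#' @param extent Optional `study_extent` restricting prediction.
#' @param clamp Clamp covariates to training bounds (default TRUE).
#' @param type Output type as in [predict.maxent_model()].
#' @return A continuous [raster_grid()] suitability map.
#' @export
predict_suitability <- function(model, stack, extent = NULL, clamp = TRUE,
                                type = "logistic") {
  template <- stack[[1]]
  nr <- nrow(template$values); nc <- ncol(template$values)
  inmask <- if (is.null(extent)) rep(TRUE, nr * nc) else as.vector(extent$mask$values == 1)
  cells <- which(inmask)
  rows <- ((cells - 1L) %% nr) + 1L
  cols <- ((cells - 1L) %/% nr) + 1L
  df <- tibble::tibble(
    !!!stats::setNames(
      lapply(stack[model$features$bounds$variable],
             function(r) r$values[cbind(rows, cols)]),
      model$features$bounds$variable))
  pred <- predict.maxent_model(model, df, type = type, clamp = clamp)
  vals <- matrix(NA_real_, nr, nc)
  vals[cbind(rows, cols)] <- pred
  raster_grid(vals, cell_size = template$cell_size, origin = template$origin)
}

#' Percent contribution of each covariate
#'
#' Normalizes the positive regularized-gain increments accumulated per parent
#' variable during fitting (product-feature increments split equally between
#' the two parents) to sum to 100%, and rolls them up by covariate category
#' (climate / LULC / topography).
#'
#' @param model A fitted `maxent_model`.
#' @return Tibble with `variable`, `category`, `contribution_pct`, sorted
#'   decreasing; attribute `"category_rollup"` holds per-category sums.
#' @export
percent_contribution <- function(model) {
  g <- model$gain_contributions
  tot <- sum(g)
  pct <- if (tot > 0) 100 * g / tot else rep(0, length(g))
  out <- tibble::tibble(variable = names(g),
                        category = covariate_category(names(g)),
                        contribution_pct = unname(pct)) |>
    dplyr::arrange(dplyr::desc(.data$contribution_pct))
  rollup <- out |>
    dplyr::group_by(.data$category) |>
    dplyr::summarise(contribution_pct = sum(.data$contribution_pct),
                     .groups = "drop")
  attr(out, "category_rollup") <- rollup
  out
}

#' @method tidy maxent_model
#' @export
tidy.maxent_model <- function(x, ...) {
  dplyr::bind_cols(x$features$defs,
                   tibble::tibble(lambda = unname(x$lambda),
                                  beta = unname(x$beta))) |>
    dplyr::filter(.data$lambda != 0) |>
    dplyr::arrange(dplyr::desc(abs(.data$lambda)))
}

#' @method glance maxent_model
#' @export
glance.maxent_model <- function(x, ...) {
  tibble::tibble(
    n_presence = x$n_presence, n_background = x$n_background,
    n_features = length(x$lambda), n_active = sum(x$lambda != 0),
    gain = x$gain, entropy = x$entropy, log_Z = x$log_Z,
    reg_multiplier = x$reg_multiplier,
    converged = x$converged, iterations = x$iterations
  )
}
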