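# Train/test splitting, rank-based AUC, maximum-sensitivity-plus-specificity
# thresholding, range maps and suitable-area accounting.

#' Random train/test split of presence records
#'
#' Partitions rows into a training set of size `ceiling(train_frac * n)` and
#' a test set of the remainder, under `seed`.
#'
#' @param ps Presence tibble.
#' @param train_frac Training fraction (default 0.75).
#' @param seed RNG seed.
#' @return List with tibbles `train` and `test`.
#' @export
split_presences <- function(ps, train_frac = 0.75, seed = 1L) {
  ps <- tibble::as_tibble(ps)
  n <- nrow(ps)
  n_train <- ceiling(train_frac * n)
  idx <- with_seed(seed, sample.int(n, n_train))
  list(train = ps[sort(idx), , drop = FALSE],
       test = ps[setdiff(seq_len(n), idx), , drop = FALSE])
}

#' Rank-based AUC for presence vs background scores
#'
#' The Mann-Whitney estimate: the probability a randomly chosen presence
#' outscores a randomly chosen background point, ties counting one half.
#'
#' @param presence_scores,background_scores Numeric score vectors.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(presence_scores, background_scores) {
  m <- length(presence_scores); n <- length(background_scores)
  stopifnot(m > 0, n > 0)
  r <- rank(c(presence_scores, background_scores), ties.method = "average")
  (sum(r[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
}

#' Maximum sensitivity-plus-specificity threshold
#'
#' Scans candidate thresholds (the sorted unique scores) and returns the tau
#' maximizing `sensitivity(tau) + specificity(tau)`, with sensitivity the
#' fraction of presence scores >= tau and specificity the fraction of
#' background scores < tau.  Ties break toward the smallest tau, which yields
#' the larger predicted range and favours omission-error control.
#'
#' @param presence_scores,background_scores Numeric score vectors.
#' @return A `sss_threshold`: list with `tau`, `sensitivity`, `specificity`.
#' @export
max_sss_threshold <- function(presence_scores, background_scores) {
  taus <- sort(unique(c(presence_scores, background_scores)))
  sp <- sort(presence_scores); sb <- sort(background_scores)
  m <- length(sp); n <- length(sb)
  sens <- vapply(taus, function(t) mean(sp >= t), 0)
  spec <- vapply(taus, function(t) mean(sb < t), 0)
  best <- which.max(sens + spec)  # which.max takes the first (smallest tau)
  structure(list(tau = taus[best], sensitivity = sens[best],
                 specificity = spec[best]), class = "sss_threshold")
}

#' Binarize a suitability map into a range map
#'
#' A cell is suitable iff its logistic score is >= tau; nodata propagates.
#'
#' @param map Continuous [raster_grid()] of logistic output.
#' @param tau Threshold (a number or an `sss_threshold`).
#' @return A binary [raster_grid()] (1 suitable / 0 unsuitable / NA nodata)
#'   with attribute `"tau"`.
#' @export
apply_threshold <- function(map, tau) {
  if (inherits(tau, "sss_threshold")) tau <- tau$tau
  out <- raster_grid((map$values >= tau) * 1, cell_size = map$cell_size,
                     origin = map$origin)
  attr(out, "tau") <- tau
  out
}

#' Suitable area as a percentage
#'
#' @param rm Binary range map from [apply_threshold()].
#' @param denominator `"study_extent"` (non-nodata cells of the map) or
#'   `"full_domain"` (all grid cells).  Domain-wide percentages are the
#'   conventional reporting unit; extent-restricted percentages are also
#'   informative since prediction only happens inside the buffered extent.
#' @return Percentage in `[0, 100]`.
#' @export
suitable_area_pct <- function(rm, denominator = c("study_extent", "full_domain")) {
  denominator <- match.arg(denominator)
  suit <- sum(rm$values == 1, na.rm = TRUE)
  denom <- switch(denominator,
    study_extent = sum(!is.na(rm$values)),
    full_domain = length(rm$values))
  100 * suit / denom
}

#' Evaluate a fitted model: AUC and threshold
#'
#' Computes training and test AUC against background scores and selects the
#' max-SSS threshold (on the test presences by default; set
#' `threshold_on = "train"` to use training presences).
#'
#' @param model A fitted `maxent_model`.
#' @param train,test Presence covariate tibbles.
#' @param background Background covariate tibble.
#' @param threshold_on `"test"` or `"train"`.
#' @return One-row tibble: `auc_train`, `auc_test`, `tau`, `sensitivity`,
#'   `specificity`.
#' @export
evaluate_model <- function(model, train, test, background,
                           threshold_on = c("test", "train")) {
  threshold_on <- match.arg(threshold_on)
  sb <- predict(model, background)
  st <- predict(model, train)
  se <- if (nrow(test) > 0) predict(model, test) else numeric(0)
  thr_scores <- if (threshold_on == "test" && length(se) > 0) se else st
  thr <- max_sss_threshold(thr_scores, sb)
  tibble::tibble(
    auc_train = auc(st, sb),
    auc_test = if (length(se) > 0) auc(se, sb) else NA_real_,
    tau = thr$tau, sensitivity = thr$sensitivity,
    specificity = thr$specificity)
}
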