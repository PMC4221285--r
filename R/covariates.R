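# Predictor-stack construction: focal LULC counts and diversity, ensemble
# climate means, topographic derivatives, correlation screening.

# Box sum over a centred (2*half+1)^2 window, truncated at edges, via a
# summed-area table. NA treated as 0 (callers mask beforehand).
focal_sum <- function(m, half) {
  nr <- nrow(m); nc <- ncol(m)
  m[is.na(m)] <- 0
  # pad with a leading zero row/col so sat[i+1, j+1] = sum m[1:i, 1:j]
  sat <- rbind(0, apply(m, 2, cumsum))
  sat <- cbind(0, t(apply(sat, 1, cumsum)))
  r1 <- pmax(seq_len(nr) - half, 1L); r2 <- pmin(seq_len(nr) + half, nr)
  c1 <- pmax(seq_len(nc) - half, 1L); c2 <- pmin(seq_len(nc) + half, nc)
  out <- sat[r2 + 1L, c2 + 1L, drop = FALSE] -
    sat[r1, c2 + 1L, drop = FALSE] -
    sat[r2 + 1L, c1, drop = FALSE] +
    sat[r1, c1, drop = FALSE]
  dimnames(out) <- NULL
  out
}

#' Focal neighborhood count of one LULC class
#'
#' Counts cells of `class_id` inside a centred `window` x `window` box around
#' every cell (default 5 x 5, i.e. 1,250 m x 1,250 m at 250-m cells).  Edge
#' cells use the truncated window that fits on the grid, so a corner cell of a
#' uniform raster has count 9, not 25; nodata cells never contribute.
#'
#' @param lulc Categorical [raster_grid()].
#' @param class_id Integer class code to count.
#' @param window Odd window edge length in cells.
#' @return Continuous [raster_grid()] of integer counts.
#' @export
neighborhood_count <- function(lulc, class_id, window = 5) {
  if (lulc$kind != "categorical") stop("`lulc` must be categorical", call. = FALSE)
  if (window %% 2 == 0) stop("`window` must be odd", call. = FALSE)
  ind <- (lulc$values == class_id) * 1
  out <- focal_sum(ind, (window - 1L) %/% 2L)
  raster_grid(out, cell_size = lulc$cell_size, origin = lulc$origin)
}

#' Focal LULC diversity
#'
#' Number of distinct LULC classes present in the centred window around each
#' cell (truncated at edges, nodata excluded).
#'
#' @inheritParams neighborhood_count
#' @param classes Class codes to consider; defaults to the raster's declared
#'   classes, else the codes present.
#' @return Continuous [raster_grid()] with integer values >= 1 wherever the
#'   window holds any data.
#' @export
lulc_diversity <- function(lulc, window = 5, classes = NULL) {
  if (lulc$kind != "categorical") stop("`lulc` must be categorical", call. = FALSE)
  if (window %% 2 == 0) stop("`window` must be odd", call. = FALSE)
  if (is.null(classes)) {
    classes <- lulc$classes %||% sort(unique(lulc$values[!is.na(lulc$values)]))
  }
  half <- (window - 1L) %/% 2L
  div <- matrix(0, nrow(lulc$values), ncol(lulc$values))
  for (cl in classes) {
    div <- div + (focal_sum((lulc$values == cl) * 1, half) > 0)
  }
  raster_grid(div, cell_size = lulc$cell_size, origin = lulc$origin)
}

#' Cell-wise ensemble mean of aligned layers
#'
#' Arithmetic mean across layers (e.g. climate fields from several circulation
#' models, averaged to damp single-model bias).  Nodata propagates: a cell that
#' is nodata in any layer is nodata in the mean.
#'
#' @param layers List of aligned continuous [raster_grid()]s.
#' @return A [raster_grid()].
#' @export
ensemble_mean <- function(layers) {
  if (length(layers) < 1L) stop("need at least one layer", call. = FALSE)
  assert_aligned(layers)
  acc <- Reduce(`+`, lapply(layers, function(r) r$values))
  raster_grid(acc / length(layers),
              cell_size = layers[[1]]$cell_size, origin = layers[[1]]$origin)
}

# Edge-replicated shift of a matrix by (dr, dc).
shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- pmin(pmax(seq_len(nr) + dr, 1L), nr)
  ci <- pmin(pmax(seq_len(nc) + dc, 1L), nc)
  m[ri, ci, drop = FALSE]
}

#' Slope from elevation (Horn's method)
#'
#' Third-order finite difference over the 3 x 3 neighborhood (Horn 1981), the
#' standard GIS slope algorithm; edges use replicated border cells.  Returned
#' in degrees.
#'
#' @param elev Continuous elevation [raster_grid()] in metres.
#' @return Continuous [raster_grid()] of slope in degrees.
#' @export
derive_slope <- function(elev) {
  z <- elev$values
  cs <- elev$cell_size
  dzdx <- ((shift_mat(z, -1, 1) + 2 * shift_mat(z, 0, 1) + shift_mat(z, 1, 1)) -
           (shift_mat(z, -1, -1) + 2 * shift_mat(z, 0, -1) + shift_mat(z, 1, -1))) /
    (8 * cs)
  dzdy <- ((shift_mat(z, 1, -1) + 2 * shift_mat(z, 1, 0) + shift_mat(z, 1, 1)) -
           (shift_mat(z, -1, -1) + 2 * shift_mat(z, -1, 0) + shift_mat(z, -1, 1))) /
    (8 * cs)
  slope <- atan(sqrt(dzdx^2 + dzdy^2)) * 180 / pi
  raster_grid(slope, cell_size = elev$cell_size, origin = elev$origin)
}

#' Compound topographic index from elevation
#'
#' CTI (topographic wetness index) = ln(a / tan(beta)) with contributing area
#' `a` from single-direction (D8) flow accumulation and beta the Horn slope.
#' Flow goes to the steepest-descent neighbor; ties break deterministically to
#' the lowest-index neighbor (row-major order).  `tan(beta)` is floored at
#' `eps` so flats yield large but finite CTI.
#'
#' @param elev Continuous elevation [raster_grid()].
#' @param eps Floor for `tan(beta)` (default 0.001).
#' @return Continuous [raster_grid()]; finite everywhere.
#' @export
derive_cti <- function(elev, eps = 0.001) {
  z <- elev$values
  nr <- nrow(z); nc <- ncol(z); cs <- elev$cell_size
  offs <- list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1),
               c(0, 1), c(1, -1), c(1, 0), c(1, 1))
  dist <- cs * vapply(offs, function(o) sqrt(sum(o^2)), 0)
  n <- nr * nc
  drops <- matrix(-Inf, n, 8)
  targets <- matrix(NA_integer_, n, 8)
  rows <- rep(seq_len(nr), times = nc); cols <- rep(seq_len(nc), each = nr)
  for (k in seq_along(offs)) {
    rr <- rows + offs[[k]][1]; cc <- cols + offs[[k]][2]
    ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
    tgt <- (cc - 1L) * nr + rr
    d <- rep(-Inf, n)
    d[ok] <- (as.vector(z)[ok] - as.vector(z)[tgt[ok]]) / dist[k]
    drops[, k] <- d
    targets[ok, k] <- tgt[ok]
  }
  best <- max.col(drops, ties.method = "first")
  bestdrop <- drops[cbind(seq_len(n), best)]
  down <- targets[cbind(seq_len(n), best)]
  down[!(bestdrop > 0)] <- NA_integer_  # pits and flats drain nowhere
  acc <- rep(1, n)
  ord <- order(as.vector(z), seq_len(n), decreasing = c(TRUE, FALSE), method = "radix")
  for (i in ord) {
    if (!is.na(down[i])) acc[down[i]] <- acc[down[i]] + acc[i]
  }
  a <- acc * cs  # specific catchment area, m
  slope_deg <- derive_slope(elev)$values
  tanb <- pmax(tan(slope_deg * pi / 180), eps)
  cti <- log(matrix(a, nr, nc) / tanb)
  raster_grid(cti, cell_size = elev$cell_size, origin = elev$origin)
}

#' The canonical 14-layer covariate stack
#'
#' Builds the predictor set used throughout the package from a synthetic (or
#' assembled) world: one 5 x 5 neighborhood count per LULC class, focal LULC
#' diversity, annual mean temperature, annual precipitation, and elevation /
#' slope / CTI.  Slope and CTI are derived from the world's elevation when the
#' world does not already carry them.
#'
#' @param world A `synthetic_world` (see [generate_landscape()]) or any list
#'   with aligned `lulc`, `temperature`, `precipitation`, `elevation` layers.
#' @param window Focal window edge length (odd; default 5).
#' @return A `covariate_stack`: named list of aligned [raster_grid()] layers.
#' @export
build_covariate_stack <- function(world, window = 5) {
  lulc <- world$lulc
  cls <- lulc_class_table(lulc)
  counts <- purrr::map(stats::setNames(cls$class_id, cls$layer),
                       ~ neighborhood_count(lulc, .x, window = window))
  slope <- world$slope %||% derive_slope(world$elevation)
  cti <- world$cti %||% derive_cti(world$elevation)
  layers <- c(counts, list(
    lulc_diversity = lulc_diversity(lulc, window = window),
    avg_temp = world$temperature,
    avg_precip = world$precipitation,
    elevation = world$elevation,
    slope = slope,
    cti = cti
  ))
  assert_aligned(layers)
  structure(layers, class = "covariate_stack", window = window)
}

# class id <-> count-layer name mapping for the 8-class legend
lulc_class_table <- function(lulc) {
  ids <- lulc$classes %||% sort(unique(lulc$values[!is.na(lulc$values)]))
  nms <- names(ids)
  if (is.null(nms)) nms <- default_lulc_classes()$name[match(ids, default_lulc_classes()$class_id)]
  layer <- c(water = "water_count", urban = "urban_count",
             cropland = "cropland_count", hay_pasture = "hay_count",
             grassland = "grass_count", forest = "forest_count",
             shrubland = "shrub_count", wetland = "wetland_count")[nms]
  tibble::tibble(class_id = unname(ids), name = nms, layer = unname(layer))
}

#' @export
print.covariate_stack <- function(x, ...) {
  cat(sprintf("<covariate_stack> %d layers: %s\n", length(x),
              paste(names(x), collapse = ", ")))
  invisible(x)
}

#' Covariate category (climate / LULC / topography)
#'
#' @param vars Character vector of covariate names.
#' @return Character vector of categories.
#' @export
covariate_category <- function(vars) {
  dplyr::case_when(
    vars %in% c("avg_temp", "avg_precip") ~ "climate",
    vars %in% c("elevation", "slope", "cti") ~ "topography",
    TRUE ~ "lulc"
  )
}

#' Covariate values at points
#'
#' @param stack A `covariate_stack`.
#' @param points Data frame with `x`, `y` columns (metres).
#' @return The input tibble with one added column per covariate layer.
#' @export
extract_covariates <- function(stack, points) {
  out <- tibble::as_tibble(points)
  for (nm in names(stack)) out[[nm]] <- extract_values(stack[[nm]], points$x, points$y)
  out
}

#' Pairwise Pearson correlation screen
#'
#' Computes Pearson r for every covariate pair over a point sample (the usual
#' multicollinearity check before fitting) and flags pairs whose |r| exceeds a
#' threshold.
#'
#' @param stack A `covariate_stack`.
#' @param points Data frame of sample locations (`x`, `y`), or a data frame
#'   already holding covariate columns.
#' @param flag_threshold Absolute-r flag level (default 0.7).
#' @return A `correlation_report`: list with the symmetric `matrix`, a tibble
#'   of `pairs` ordered by decreasing |r|, and the threshold.
#' @export
correlation_screen <- function(stack, points, flag_threshold = 0.7) {
  vals <- if (all(names(stack) %in% names(points))) {
    dplyr::select(tibble::as_tibble(points), dplyr::all_of(names(stack)))
  } else {
    dplyr::select(extract_covariates(stack, points), dplyr::all_of(names(stack)))
  }
  vals <- vals[stats::complete.cases(vals), , drop = FALSE]
  if (nrow(vals) < 3L) stop("need at least 3 points with finite covariates", call. = FALSE)
  keep <- vapply(vals, function(v) stats::sd(v) > 0, TRUE)
  m <- stats::cor(as.matrix(vals[keep]))
  pairs <- tibble::as_tibble(as.data.frame.table(m, responseName = "r",
                                                 stringsAsFactors = FALSE))
  names(pairs)[1:2] <- c("var1", "var2")
  pairs <- pairs |>
    dplyr::filter(.data$var1 < .data$var2) |>
    dplyr::mutate(abs_r = abs(.data$r),
                  flagged = .data$abs_r > flag_threshold) |>
    dplyr::arrange(dplyr::desc(.data$abs_r))
  structure(list(matrix = m, pairs = pairs, flag_threshold = flag_threshold),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  cat(sprintf("<correlation_report> %d covariates; top pairs:\n", ncol(x$matrix)))
  print(utils::head(x$pairs, 5))
  invisible(x)
}

#' @method tidy correlation_report
#' @export
tidy.correlation_report <- function(x, ...) x$pairs

`%||%` <- function(a, b) if (is.null(a)) b else a
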