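# Per-species study extent (buffered union of presence disks) and uniform
# background sampling within it.

#' Buffered study extent around presence points
#'
#' The study extent is the union of disks of radius `buffer_km` around each
#' presence, intersected with the domain mask: a cell is in-extent iff its
#' centre lies within the radius of at least one presence.  Restricting both
#' background selection and the prediction space to this extent keeps the
#' available environment comparable to where the species was observed.
#'
#' @param presences Presence tibble with planar `x`, `y` (metres).
#' @param template A [raster_grid()] defining the grid.
#' @param buffer_km Buffer radius, km (default 500).
#' @param domain_mask Optional logical matrix (TRUE = in-domain); defaults to
#'   the whole grid.
#' @return A `study_extent`: list with boolean `mask` [raster_grid()],
#'   `buffer_km` and `source_point_count`.
#' @export
buffer_extent <- function(presences, template, buffer_km = 500,
                          domain_mask = NULL) {
  if (nrow(presences) < 1L) stop("need at least one presence", call. = FALSE)
  nr <- nrow(template$values); nc <- ncol(template$values)
  cs <- template$cell_size
  if (is.null(domain_mask)) domain_mask <- matrix(TRUE, nr, nc)
  rad <- buffer_km * 1000
  inmask <- matrix(FALSE, nr, nc)
  cx <- template$origin[1] + (seq_len(nc) - 0.5) * cs
  cy <- template$origin[2] - (seq_len(nr) - 0.5) * cs
  rad_cells <- ceiling(rad / cs) + 1L
  for (i in seq_len(nrow(presences))) {
    px <- presences$x[i]; py <- presences$y[i]
    pc <- floor((px - template$origin[1]) / cs) + 1L
    pr <- floor((template$origin[2] - py) / cs) + 1L
    rr <- max(1L, pr - rad_cells):min(nr, pr + rad_cells)
    ccn <- max(1L, pc - rad_cells):min(nc, pc + rad_cells)
    if (length(rr) == 0L || length(ccn) == 0L) next
    d2 <- outer((cy[rr] - py)^2, (cx[ccn] - px)^2, `+`)
    inmask[rr, ccn] <- inmask[rr, ccn] | (d2 <= rad^2)
  }
  inmask <- inmask & domain_mask
  structure(list(
    mask = raster_grid(inmask * 1, cell_size = cs, origin = template$origin),
    buffer_km = buffer_km,
    source_point_count = nrow(presences)
  ), class = "study_extent")
}

#' @export
print.study_extent <- function(x, ...) {
  cat(sprintf("<study_extent> %d in-mask cells (%.1f%% of grid), buffer %g km, %d source points\n",
              sum(x$mask$values == 1), 100 * mean(x$mask$values == 1),
              x$buffer_km, x$source_point_count))
  invisible(x)
}

#' Sample background points within a study extent
#'
#' Draws `n` cells uniformly without replacement from the in-mask cells (all
#' of them when fewer than `n` are available) and places points at cell
#' centres.  Sampling without replacement avoids duplicated covariate rows;
#' presence cells are not excluded by default because background represents
#' the available environment, which can include occupied sites.
#'
#' @param extent A `study_extent` from [buffer_extent()].
#' @param n Number of background points (default 10,000).
#' @param seed RNG seed.
#' @param exclude Optional tibble of `x`, `y` whose cells are excluded.
#' @return Tibble of background points with `x`, `y`, `row`, `col`.
#' @export
sample_background <- function(extent, n = 10000, seed = 1L, exclude = NULL) {
  mask <- extent$mask
  cells <- which(mask$values == 1)
  if (length(cells) == 0L) stop("study extent mask is empty", call. = FALSE)
  if (!is.null(exclude) && nrow(exclude) > 0) {
    idx <- locate_cells(mask, exclude$x, exclude$y)
    nr <- nrow(mask$values)
    drop <- (idx$col - 1L) * nr + idx$row
    cells <- setdiff(cells, drop[!is.na(drop)])
    if (length(cells) == 0L) stop("no background cells left after exclusion", call. = FALSE)
  }
  picked <- if (length(cells) <= n) cells else with_seed(seed, sample(cells, n))
  nr <- nrow(mask$values)
  rows <- ((picked - 1L) %% nr) + 1L
  cols <- ((picked - 1L) %/% nr) + 1L
  cell_centers(mask, rows, cols)[, c("x", "y", "row", "col")]
}
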