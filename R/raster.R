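#' Lightweight single-band raster on a regular planar grid
#'
#' `raster_grid()` wraps a numeric matrix together with its grid metadata:
#' square cell size in metres, the (x, y) coordinate of the top-left corner,
#' and whether the band is `"continuous"` or `"categorical"`.  Row 1 is the
#' northern edge of the grid; `NA` cells are nodata.  All layers of one world
#' or covariate stack must share shape, cell size and origin
#' (see [assert_aligned()]).
#'
#' @param values Numeric (or integer) matrix of cell values; `NA` = nodata.
#' @param cell_size Cell edge length in metres (> 0).
#' @param origin Length-2 numeric, (x, y) of the top-left grid corner.
#' @param kind `"continuous"` or `"categorical"`.
#' @param classes For categorical grids, the integer codes that may appear.
#'
#' @return An object of class `raster_grid`.
#' @export
#'
#' @examples
#' r <- raster_grid(matrix(1:12, 3, 4), cell_size = 250)
#' dim(r)
raster_grid <- function(values, cell_size = 250, origin = c(0, 0),
                        kind = c("continuous", "categorical"),
                        classes = NULL) {
  kind <- match.arg(kind)
  if (!is.matrix(values)) stop("`values` must be a matrix", call. = FALSE)
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0) {
    stop("`cell_size` must be a single positive number", call. = FALSE)
  }
  if (kind == "categorical") {
    storage.mode(values) <- "integer"
    if (!is.null(classes)) {
      bad <- setdiff(unique(values[!is.na(values)]), classes)
      if (length(bad) > 0) {
        stop("categorical raster contains undeclared codes: ",
             paste(bad, collapse = ", "), call. = FALSE)
      }
    }
  }
  structure(
    list(values = values, cell_size = as.numeric(cell_size),
         origin = as.numeric(origin), kind = kind, classes = classes),
    class = "raster_grid"
  )
}

#' @export
dim.raster_grid <- function(x) dim(x$values)

#' @export
print.raster_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<raster_grid> %d x %d cells (%s), cell %g m, origin (%g, %g)\n",
              d[1], d[2], x$kind, x$cell_size, x$origin[1], x$origin[2]))
  v <- x$values[!is.na(x$values)]
  if (length(v)) {
    cat(sprintf("  values: [%g, %g], nodata cells: %d\n",
                min(v), max(v), sum(is.na(x$values))))
  }
  invisible(x)
}

#' Cell-centre coordinates
#'
#' Returns x/y coordinates of cell centres.  Row 1 is the north edge so y
#' decreases with row index.
#'
#' @param r A [raster_grid()].
#' @param rows,cols Integer vectors of row/column indices (recycled together).
#' @return A tibble with columns `row`, `col`, `x`, `y`.
#' @export
cell_centers <- function(r, rows, cols) {
  tibble::tibble(
    row = as.integer(rows), col = as.integer(cols),
    x = r$origin[1] + (cols - 0.5) * r$cell_size,
    y = r$origin[2] - (rows - 0.5) * r$cell_size
  )
}

#' Locate points on the grid
#'
#' Maps planar point coordinates to the row/column of the containing cell.
#' Points outside the grid get `NA` indices.
#'
#' @param r A [raster_grid()].
#' @param x,y Numeric coordinate vectors in metres.
#' @return A tibble with columns `row`, `col`.
#' @export
locate_cells <- function(r, x, y) {
  d <- dim(r$values)
  col <- floor((x - r$origin[1]) / r$cell_size) + 1L
  row <- floor((r$origin[2] - y) / r$cell_size) + 1L
  bad <- row < 1L | row > d[1] | col < 1L | col > d[2]
  row[bad] <- NA_integer_
  col[bad] <- NA_integer_
  tibble::tibble(row = as.integer(row), col = as.integer(col))
}

#' Raster values at points
#'
#' @param r A [raster_grid()].
#' @param x,y Point coordinates in metres.
#' @return Numeric vector of cell values (`NA` outside the grid / nodata).
#' @export
extract_values <- function(r, x, y) {
  idx <- locate_cells(r, x, y)
  out <- rep(NA_real_, length(x))
  ok <- !is.na(idx$row)
  out[ok] <- r$values[cbind(idx$row[ok], idx$col[ok])]
  out
}

#' Assert that rasters share one grid
#'
#' Checks shape, cell size and origin; errors on mismatch.  Every multi-layer
#' operation in the package calls this before touching cell values.
#'
#' @param ... Two or more [raster_grid()] objects (or a single list of them).
#' @return Invisibly `TRUE`.
#' @export
assert_aligned <- function(...) {
  rs <- list(...)
  if (length(rs) == 1L && !inherits(rs[[1]], "raster_grid")) rs <- rs[[1]]
  if (length(rs) < 2L) return(invisible(TRUE))
  ref <- rs[[1]]
  for (r in rs[-1]) {
    if (!identical(dim(r$values), dim(ref$values)) ||
        !isTRUE(all.equal(r$cell_size, ref$cell_size)) ||
        !isTRUE(all.equal(r$origin, ref$origin))) {
      stop("rasters are not aligned (shape, cell size and origin must match)",
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' Tidy a raster into a long tibble
#'
#' One row per cell with grid indices, cell-centre coordinates and value.
#'
#' @param x A [raster_grid()].
#' @param ... Unused.
#' @return A tibble with columns `row`, `col`, `x`, `y`, `value`.
#' @method as_tibble raster_grid
#' @export
as_tibble.raster_grid <- function(x, ...) {
  d <- dim(x$values)
  rows <- rep(seq_len(d[1]), times = d[2])
  cols <- rep(seq_len(d[2]), each = d[1])
  out <- cell_centers(x, rows, cols)
  out$value <- as.vector(x$values)
  out
}

#' Read / write ESRI ASCII grids
#'
#' Plain-text raster exchange format (`.asc`): a six-line header
#' (ncols, nrows, xllcorner, yllcorner, cellsize, NODATA_value) followed by
#' rows of cell values, north row first.
#'
#' @param r A [raster_grid()].
#' @param path File path.
#' @param nodata Value written for `NA` cells.
#' @return `write_ascii_grid()` returns `path` invisibly; `read_ascii_grid()`
#'   returns a [raster_grid()].
#' @export
write_ascii_grid <- function(r, path, nodata = -9999) {
  d <- dim(r$values)
  hdr <- c(
    sprintf("ncols %d", d[2]),
    sprintf("nrows %d", d[1]),
    sprintf("xllcorner %.10g", r$origin[1]),
    sprintf("yllcorner %.10g", r$origin[2] - d[1] * r$cell_size),
    sprintf("cellsize %.10g", r$cell_size),
    sprintf("NODATA_value %g", nodata)
  )
  v <- r$values
  v[is.na(v)] <- nodata
  body <- apply(v, 1L, function(row) paste(format(row, trim = TRUE), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @param kind Band kind for the grid being read.
#' @export
read_ascii_grid <- function(path, kind = c("continuous", "categorical")) {
  kind <- match.arg(kind)
  lines <- readLines(path)
  hdr <- lines[1:6]
  val <- function(key) {
    ln <- hdr[grepl(paste0("^", key, "\\b"), hdr, ignore.case = TRUE)]
    as.numeric(strsplit(trimws(ln), "\\s+")[[1]][2])
  }
  ncols <- as.integer(val("ncols")); nrows <- as.integer(val("nrows"))
  cs <- val("cellsize"); nodata <- val("NODATA_value")
  xll <- val("xllcorner"); yll <- val("yllcorner")
  body <- strsplit(trimws(lines[-(1:6)]), "\\s+")
  m <- do.call(rbind, lapply(body, as.numeric))
  stopifnot(identical(dim(m), c(nrows, ncols)))
  m[m == nodata] <- NA
  raster_grid(m, cell_size = cs, origin = c(xll, yll + nrows * cs), kind = kind)
}

#' Plot a raster layer
#'
#' @param object A [raster_grid()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot raster_grid
#' @export
autoplot.raster_grid <- function(object, ...) {
  df <- as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)")
  if (object$kind == "categorical") {
    p + ggplot2::geom_raster(ggplot2::aes(fill = factor(.data$value))) +
      ggplot2::labs(fill = "class")
  } else {
    p + ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
      ggplot2::scale_fill_viridis_c(na.value = "grey90")
  }
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom rlang .data
NULL
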