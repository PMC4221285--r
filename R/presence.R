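# Occurrence-record filtering: observation-protocol limits, breeding-season
# window, and 20-km spatial thinning. All functions take a presence tibble
# first and return one, appending to its `filter_log` attribute.

filter_log_append <- function(ps, out, stage) {
  log <- attr(ps, "filter_log")
  if (is.null(log)) log <- tibble::tibble(stage = "original", n = nrow(ps))
  attr(out, "filter_log") <- dplyr::bind_rows(
    log, tibble::tibble(stage = stage, n = nrow(out)))
  out
}

#' Per-stage record counts
#'
#' @param ps A presence tibble as returned by the filtering functions.
#' @return Tibble with columns `stage` and `n`; counts are non-increasing.
#' @export
filter_log <- function(ps) {
  attr(ps, "filter_log") %||% tibble::tibble(stage = "original", n = nrow(ps))
}

#' Filter records by observation protocol
#'
#' Stationary counts are always retained.  Traveling counts are dropped when
#' the travel distance exceeds `max_travel_km` and exhaustive-area counts when
#' the search area exceeds `max_area_ha` — a single recorded coordinate is an
#' unreliable location for a long transect or a large survey block.
#' Comparisons are strict: exactly 2 km / exactly 100 ha are retained.
#' Records with a missing or unknown protocol are rejected with a warning.
#'
#' @param ps Presence tibble with `protocol`, `travel_km`, `area_ha` columns.
#' @param max_travel_km Maximum travel distance, km.
#' @param max_area_ha Maximum search area, hectares.
#' @return Filtered presence tibble; `filter_log` gains a `"protocol"` row.
#' @export
filter_protocol <- function(ps, max_travel_km = 2, max_area_ha = 100) {
  ps <- tibble::as_tibble(ps)
  known <- c("stationary", "traveling", "exhaustive_area")
  bad <- is.na(ps$protocol) | !(ps$protocol %in% known)
  if (any(bad)) {
    warning(sum(bad), " record(s) with missing/unknown protocol rejected",
            call. = FALSE)
  }
  keep <- !bad & (
    ps$protocol == "stationary" |
      (ps$protocol == "traveling" &
         !is.na(ps$travel_km) & ps$travel_km <= max_travel_km) |
      (ps$protocol == "exhaustive_area" &
         !is.na(ps$area_ha) & ps$area_ha <= max_area_ha))
  filter_log_append(ps, ps[keep, , drop = FALSE], "protocol")
}

#' Filter records to the breeding-season window
#'
#' Keeps records whose month-day falls in `[start, end]` inclusive, in any
#' year (default June 1 to July 15, a conservative breeding window for North
#' American species).  Unparseable dates are rejected with a warning.
#'
#' @param ps Presence tibble with a `date` column.
#' @param start,end Window bounds as `"MM-DD"` strings (inclusive).
#' @return Filtered presence tibble; `filter_log` gains a `"season"` row.
#' @export
filter_season <- function(ps, start = "06-01", end = "07-15") {
  ps <- tibble::as_tibble(ps)
  d <- tryCatch(as.Date(ps$date), error = function(e) rep(as.Date(NA), nrow(ps)))
  bad <- is.na(d)
  if (any(bad)) {
    warning(sum(bad), " record(s) with unparseable date rejected", call. = FALSE)
  }
  md <- format(d, "%m-%d")
  keep <- !bad & md >= start & md <= end
  filter_log_append(ps, ps[keep, , drop = FALSE], "season")
}

#' Spatially thin records to a minimum pairwise distance
#'
#' Shuffles the records under `seed`, then greedily accepts each record iff it
#' lies at least `min_dist_km` from every already-accepted record.  The result
#' is a maximal independent set of the proximity graph: all pairwise distances
#' meet the minimum and no rejected record could be added back.  The random
#' shuffle removes order bias; the output is deterministic for a fixed seed.
#'
#' @param ps Presence tibble with planar `x`, `y` in metres.
#' @param min_dist_km Minimum pairwise distance, km.
#' @param seed RNG seed for the shuffle.
#' @param dist_fn Optional distance function `(x1, y1, x2, y2) -> metres`
#'   vectorised over the second pair; defaults to planar Euclidean.
#' @return Thinned presence tibble; `filter_log` gains a `"thin"` row.
#' @export
spatial_thin <- function(ps, min_dist_km = 20, seed = 1L, dist_fn = NULL) {
  ps <- tibble::as_tibble(ps)
  n <- nrow(ps)
  if (n <= 1L) return(filter_log_append(ps, ps, "thin"))
  if (is.null(dist_fn)) {
    dist_fn <- function(x1, y1, x2, y2) sqrt((x1 - x2)^2 + (y1 - y2)^2)
  }
  min_m <- min_dist_km * 1000
  ord <- with_seed(seed, sample.int(n))
  xs <- ps$x[ord]; ys <- ps$y[ord]
  acc <- integer(0)
  for (i in seq_len(n)) {
    if (length(acc) == 0L ||
        min(dist_fn(xs[i], ys[i], xs[acc], ys[acc])) >= min_m) {
      acc <- c(acc, i)
    }
  }
  keep <- sort(ord[acc])
  filter_log_append(ps, ps[keep, , drop = FALSE], "thin")
}

#' Run the standard filtering chain
#'
#' Protocol filter, then season filter, then spatial thinning (the default
#' order; each stage is idempotent and protocol/season commute).
#'
#' @inheritParams filter_protocol
#' @inheritParams filter_season
#' @inheritParams spatial_thin
#' @return Filtered presence tibble with a four-stage `filter_log`.
#' @export
filter_presences <- function(ps, max_travel_km = 2, max_area_ha = 100,
                             start = "06-01", end = "07-15",
                             min_dist_km = 20, seed = 1L) {
  ps |>
    filter_protocol(max_travel_km = max_travel_km, max_area_ha = max_area_ha) |>
    filter_season(start = start, end = end) |>
    spatial_thin(min_dist_km = min_dist_km, seed = seed)
}

#' Read / write presence sets as CSV
#'
#' Columns: `species`, `x`, `y`, `date`, `protocol`, `travel_km`, `area_ha`.
#'
#' @param path File path.
#' @param ps Presence tibble.
#' @return `read_presences()` returns a presence tibble;
#'   `write_presences()` returns `path` invisibly.
#' @export
read_presences <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           species = readr::col_character(),
                           x = readr::col_double(),
                           y = readr::col_double(),
                           date = readr::col_date(),
                           protocol = readr::col_character(),
                           travel_km = readr::col_double(),
                           area_ha = readr::col_double()))
  attr(out, "filter_log") <- tibble::tibble(stage = "original", n = nrow(out))
  out
}

#' @rdname read_presences
#' @export
write_presences <- function(ps, path) {
  readr::write_csv(tibble::as_tibble(ps), path)
  invisible(path)
}
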