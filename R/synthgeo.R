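# Synthetic worlds and virtual species: spatially autocorrelated 8-class LULC
# mosaics, smooth climate gradients, topography, scenario transitions, and
# biased presence sampling from a known truth surface.

# Evaluate code with a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' The 8-class LULC legend
#'
#' @return Tibble with `class_id` (1-8) and `name`.
#' @export
default_lulc_classes <- function() {
  tibble::tibble(
    class_id = 1:8,
    name = c("water", "urban", "cropland", "hay_pasture",
             "grassland", "forest", "shrubland", "wetland")
  )
}

#' Configuration for a synthetic landscape
#'
#' Defaults describe a 200 x 200 grid of 250-m cells (a 50-km planar world):
#' an 8-class LULC mosaic with patch radius `spatial_autocorrelation_range`
#' cells, annual mean temperature increasing linearly from the north edge
#' southwards, annual precipitation increasing west to east, and smooth random
#' topography from which slope and CTI are derived.
#'
#' @param n_rows,n_cols Grid shape (each >= 25 so a full 5 x 5 focal window
#'   has an interior).
#' @param cell_size Cell edge, metres.
#' @param lulc_classes Named integer vector of exactly 8 class codes.
#' @param spatial_autocorrelation_range Typical LULC patch radius, cells.
#' @param climate List: `temp_north` (deg C at the north edge), `temp_gradient`
#'   (total north-to-south increase, deg C), `temp_noise_sd`, `precip_west`
#'   (mm at the west edge), `precip_gradient` (total west-to-east increase,
#'   mm), `precip_noise_sd`.
#' @param elevation List: `smoothing_scale` (cells), `amplitude` (m), `base` (m).
#' @param seed Integer RNG seed; the world is a pure function of the config.
#' @return A `landscape_config`.
#' @export
landscape_config <- function(n_rows = 200, n_cols = 200, cell_size = 250,
                             lulc_classes = NULL,
                             spatial_autocorrelation_range = 10,
                             climate = list(),
                             elevation = list(),
                             seed = 1L) {
  if (n_rows < 25 || n_cols < 25) {
    stop("grid must be at least 25 x 25", call. = FALSE)
  }
  if (cell_size <= 0) stop("cell_size must be positive", call. = FALSE)
  if (is.null(lulc_classes)) {
    leg <- default_lulc_classes()
    lulc_classes <- stats::setNames(leg$class_id, leg$name)
  }
  if (length(lulc_classes) != 8L) stop("exactly 8 LULC classes required", call. = FALSE)
  climate <- utils::modifyList(
    list(temp_north = 5, temp_gradient = 10, temp_noise_sd = 0.3,
         precip_west = 500, precip_gradient = 600, precip_noise_sd = 30),
    climate)
  elevation <- utils::modifyList(
    list(smoothing_scale = 15, amplitude = 300, base = 200),
    elevation)
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 cell_size = cell_size, lulc_classes = lulc_classes,
                 spatial_autocorrelation_range = spatial_autocorrelation_range,
                 climate = climate, elevation = elevation,
                 seed = as.integer(seed)),
            class = "landscape_config")
}

# Smooth ~N(0,1) field: white noise on a coarse lattice, bilinear interpolation.
smooth_field <- function(nr, nc, scale) {
  cnr <- ceiling((nr - 1) / scale) + 2L
  cnc <- ceiling((nc - 1) / scale) + 2L
  g <- matrix(stats::rnorm(cnr * cnc), cnr, cnc)
  u <- (seq_len(nr) - 1) / scale
  v <- (seq_len(nc) - 1) / scale
  i0 <- pmin(floor(u) + 1L, cnr - 1L); fu <- u - (i0 - 1L)
  j0 <- pmin(floor(v) + 1L, cnc - 1L); fv <- v - (j0 - 1L)
  a <- g[i0, j0, drop = FALSE]; b <- g[i0 + 1L, j0, drop = FALSE]
  cc <- g[i0, j0 + 1L, drop = FALSE]; d <- g[i0 + 1L, j0 + 1L, drop = FALSE]
  FU <- matrix(fu, nr, nc); FV <- matrix(fv, nr, nc, byrow = TRUE)
  a * (1 - FU) * (1 - FV) + b * FU * (1 - FV) + cc * (1 - FU) * FV + d * FU * FV
}

#' Generate a synthetic world
#'
#' Builds the contemporary epoch of a synthetic study region: an 8-class LULC
#' mosaic (seeded Voronoi tessellation smoothed by one 3 x 3 majority-filter
#' pass), linear climate gradients with additive noise, smooth elevation, and
#' derived slope and CTI.  Deterministic for a fixed config (the seed is part
#' of the config).
#'
#' @param config A [landscape_config()].
#' @return A `synthetic_world`: aligned layers `lulc`, `temperature`,
#'   `precipitation`, `elevation`, `slope`, `cti`, plus `epoch` and provenance.
#' @export
#'
#' @examples
#' w <- generate_landscape(landscape_config(n_rows = 40, n_cols = 40, seed = 7))
#' table(w$lulc$values)
generate_landscape <- function(config) {
  stopifnot(inherits(config, "landscape_config"))
  nr <- config$n_rows; nc <- config$n_cols; cs <- config$cell_size
  with_seed(config$seed, {
    # --- LULC: seeded Voronoi + one majority pass -------------------------
    rng <- config$spatial_autocorrelation_range
    n_seeds <- max(16L, as.integer(ceiling(nr * nc / (pi * rng^2))))
    idx <- sample.int(nr * nc, n_seeds)
    seed_r <- ((idx - 1L) %% nr) + 1L
    seed_c <- ((idx - 1L) %/% nr) + 1L
    ids <- unname(config$lulc_classes)
    seed_cls <- ids[(sample.int(8L, n_seeds, replace = TRUE) - 1L) %% 8L + 1L]
    # guarantee every class owns at least one seed patch
    seed_cls[seq_len(8L)] <- sample(ids)
    rows <- rep(seq_len(nr), times = nc); cols <- rep(seq_len(nc), each = nr)
    d2 <- outer(rows, seed_r, function(a, b) (a - b)^2) +
      outer(cols, seed_c, function(a, b) (a - b)^2)
    lulc_v <- matrix(seed_cls[max.col(-d2, ties.method = "first")], nr, nc)
    # majority filter: most frequent class in 3 x 3, ties to lowest code
    counts <- lapply(ids, function(cl) focal_sum((lulc_v == cl) * 1, 1L))
    stackm <- do.call(cbind, lapply(counts, as.vector))
    lulc_v <- matrix(ids[max.col(stackm, ties.method = "first")], nr, nc)
    lulc <- raster_grid(lulc_v, cell_size = cs, kind = "categorical",
                        classes = config$lulc_classes)

    # --- climate ----------------------------------------------------------
    cl <- config$climate
    tgrad <- cl$temp_north + cl$temp_gradient * (seq_len(nr) - 1) / (nr - 1)
    temp <- matrix(tgrad, nr, nc) +
      if (cl$temp_noise_sd > 0) smooth_field(nr, nc, 8) * cl$temp_noise_sd else 0
    pgrad <- cl$precip_west + cl$precip_gradient * (seq_len(nc) - 1) / (nc - 1)
    precip <- matrix(pgrad, nr, nc, byrow = TRUE) +
      if (cl$precip_noise_sd > 0) smooth_field(nr, nc, 8) * cl$precip_noise_sd else 0

    # --- topography -------------------------------------------------------
    el <- config$elevation
    elev <- el$base + el$amplitude * smooth_field(nr, nc, el$smoothing_scale)
    elevation <- raster_grid(elev, cell_size = cs)

    structure(list(
      lulc = lulc,
      temperature = raster_grid(temp, cell_size = cs),
      precipitation = raster_grid(precip, cell_size = cs),
      elevation = elevation,
      slope = derive_slope(elevation),
      cti = derive_cti(elevation),
      epoch = "contemporary",
      config = config,
      scenario = NULL
    ), class = "synthetic_world")
  })
}

#' @export
print.synthetic_world <- function(x, ...) {
  d <- dim(x$lulc$values)
  cat(sprintf("<synthetic_world> %d x %d cells, epoch: %s%s\n", d[1], d[2],
              x$epoch,
              if (!is.null(x$scenario)) paste0(" (", x$scenario$name, ")") else ""))
  invisible(x)
}

#' Scenario configuration
#'
#' Coupled climate / land-use storylines.  Rates are per-eligible-cell
#' conversion probabilities applied once between the contemporary and future
#' epochs.  Three presets mirror the qualitative contrasts of the IPCC SRES
#' storylines: `"A1B"` (strong warming, urban and cropland growth), `"A2"`
#' (strongest warming, largest habitat loss), `"B1"` (mild warming,
#' afforestation).
#'
#' @param name Scenario label.
#' @param warming_delta Added to every temperature cell, deg C.
#' @param precip_delta_pct Multiplicative precipitation change, percent.
#' @param urban_growth_rate P(convert) for non-urban, non-water cells adjacent
#'   to urban.
#' @param cropland_expansion_rate P(convert) for grassland/forest cells.
#' @param afforestation_rate P(convert to forest) for cropland/grassland cells.
#' @param seed RNG seed for the stochastic transitions.
#' @return A `scenario_config`.
#' @export
scenario_config <- function(name, warming_delta = 0, precip_delta_pct = 0,
                            urban_growth_rate = 0, cropland_expansion_rate = 0,
                            afforestation_rate = 0, seed = 1L) {
  rates <- c(urban_growth_rate, cropland_expansion_rate, afforestation_rate)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]", call. = FALSE)
  structure(list(name = name, warming_delta = warming_delta,
                 precip_delta_pct = precip_delta_pct,
                 urban_growth_rate = urban_growth_rate,
                 cropland_expansion_rate = cropland_expansion_rate,
                 afforestation_rate = afforestation_rate,
                 seed = as.integer(seed)),
            class = "scenario_config")
}

#' @rdname scenario_config
#' @export
scenario_preset <- function(name = c("A1B", "A2", "B1"), seed = 1L) {
  name <- match.arg(name)
  switch(name,
    A1B = scenario_config("A1B", warming_delta = 3.5, precip_delta_pct = -5,
                          urban_growth_rate = 0.15,
                          cropland_expansion_rate = 0.10,
                          afforestation_rate = 0, seed = seed),
    A2 = scenario_config("A2", warming_delta = 4.5, precip_delta_pct = -10,
                         urban_growth_rate = 0.20,
                         cropland_expansion_rate = 0.20,
                         afforestation_rate = 0, seed = seed),
    B1 = scenario_config("B1", warming_delta = 2.0, precip_delta_pct = 0,
                         urban_growth_rate = 0.05,
                         cropland_expansion_rate = 0,
                         afforestation_rate = 0.10, seed = seed)
  )
}

#' Apply a scenario to a contemporary world
#'
#' Produces the future epoch: temperature shifted by `warming_delta`,
#' precipitation scaled by `precip_delta_pct`, and stochastic LULC transitions
#' drawn under the scenario seed.  Transitions run in a fixed order — urban
#' growth (into non-water cells 8-adjacent to existing urban), cropland
#' expansion (replacing grassland/forest), afforestation (replacing
#' cropland/grassland) — each drawing one uniform per eligible cell in
#' column-major cell order, so a run is exactly replayable from the seed.
#' Topography never changes.
#'
#' @param world A contemporary `synthetic_world`.
#' @param scenario A [scenario_config()].
#' @return A future-epoch `synthetic_world`.
#' @export
apply_scenario <- function(world, scenario) {
  stopifnot(inherits(world, "synthetic_world"), inherits(scenario, "scenario_config"))
  if (world$epoch != "contemporary") {
    stop("scenario can only be applied to a contemporary-epoch world", call. = FALSE)
  }
  cls <- world$lulc$classes
  id <- function(nm) unname(cls[nm])
  lulc <- world$lulc$values
  with_seed(scenario$seed, {
    if (scenario$urban_growth_rate > 0) {
      adj <- focal_sum((lulc == id("urban")) * 1, 1L) - (lulc == id("urban"))
      elig <- which(lulc != id("urban") & lulc != id("water") & adj > 0)
      conv <- elig[stats::runif(length(elig)) < scenario$urban_growth_rate]
      lulc[conv] <- id("urban")
    }
    if (scenario$cropland_expansion_rate > 0) {
      elig <- which(lulc == id("grassland") | lulc == id("forest"))
      conv <- elig[stats::runif(length(elig)) < scenario$cropland_expansion_rate]
      lulc[conv] <- id("cropland")
    }
    if (scenario$afforestation_rate > 0) {
      elig <- which(lulc == id("cropland") | lulc == id("grassland"))
      conv <- elig[stats::runif(length(elig)) < scenario$afforestation_rate]
      lulc[conv] <- id("forest")
    }
  })
  out <- world
  out$lulc <- raster_grid(lulc, cell_size = world$lulc$cell_size,
                          origin = world$lulc$origin, kind = "categorical",
                          classes = cls)
  out$temperature <- raster_grid(world$temperature$values + scenario$warming_delta,
                                 cell_size = world$temperature$cell_size,
                                 origin = world$temperature$origin)
  out$precipitation <- raster_grid(
    world$precipitation$values * (1 + scenario$precip_delta_pct / 100),
    cell_size = world$precipitation$cell_size,
    origin = world$precipitation$origin)
  out$epoch <- "future"
  out$scenario <- scenario
  out
}

#' Virtual species with known suitability
#'
#' A truth model for parameter-recovery experiments: suitability mixes a
#' Gaussian thermal response with a saturating response to the 5 x 5
#' neighborhood count of a preferred LULC class,
#' \deqn{S(x) = w\,e^{-(T(x)-\mu)^2 / 2\sigma^2} +
#'       (1-w)\,\frac{c(x)}{c(x)+h},}
#' optionally zeroed above an elevation limit.
#'
#' @param temp_optimum Thermal optimum, deg C.
#' @param temp_tolerance Gaussian sd, deg C.
#' @param preferred_lulc_class Class id of the preferred habitat.
#' @param lulc_halfsat Half-saturation neighborhood count in `[0, 25]`.
#' @param elevation_limit Metres, or `NULL` for none.
#' @param mixing_weight_climate Weight `w` on the climate term, in `[0, 1]`.
#' @return A `virtual_species`.
#' @export
virtual_species <- function(temp_optimum = 10, temp_tolerance = 2.5,
                            preferred_lulc_class = 6L, lulc_halfsat = 8,
                            elevation_limit = NULL,
                            mixing_weight_climate = 0.5) {
  stopifnot(temp_tolerance > 0, lulc_halfsat >= 0, lulc_halfsat <= 25,
            mixing_weight_climate >= 0, mixing_weight_climate <= 1)
  structure(list(temp_optimum = temp_optimum, temp_tolerance = temp_tolerance,
                 preferred_lulc_class = as.integer(preferred_lulc_class),
                 lulc_halfsat = lulc_halfsat,
                 elevation_limit = elevation_limit,
                 mixing_weight_climate = mixing_weight_climate),
            class = "virtual_species")
}

#' True suitability surface of a virtual species
#'
#' @param world A `synthetic_world`.
#' @param sp A [virtual_species()].
#' @return Continuous [raster_grid()] with values in `[0, 1]`.
#' @export
true_suitability <- function(world, sp) {
  stopifnot(inherits(sp, "virtual_species"))
  tt <- world$temperature$values
  clim <- exp(-(tt - sp$temp_optimum)^2 / (2 * sp$temp_tolerance^2))
  cnt <- neighborhood_count(world$lulc, sp$preferred_lulc_class)$values
  hab <- if (sp$lulc_halfsat == 0) (cnt > 0) * 1 else cnt / (cnt + sp$lulc_halfsat)
  s <- sp$mixing_weight_climate * clim + (1 - sp$mixing_weight_climate) * hab
  if (!is.null(sp$elevation_limit)) {
    s[world$elevation$values > sp$elevation_limit] <- 0
  }
  raster_grid(s, cell_size = world$lulc$cell_size, origin = world$lulc$origin)
}

#' Sampling-bias specification
#'
#' Observation effort modelled as a mixture of Gaussian hotspots centred on
#' randomly chosen urban cells (mimicking population-centred citizen-science
#' effort) over a uniform floor.  `n_hotspots = 0` gives uniform effort.
#'
#' @param n_hotspots Number of hotspots.
#' @param sigma_cells Hotspot Gaussian sd, in cells.
#' @param floor Uniform effort floor relative to a hotspot peak of 1.
#' @return A `bias_spec`.
#' @export
bias_spec <- function(n_hotspots = 5, sigma_cells = 8, floor = 0.2) {
  stopifnot(n_hotspots >= 0, sigma_cells > 0, floor >= 0)
  structure(list(n_hotspots = n_hotspots, sigma_cells = sigma_cells,
                 floor = floor), class = "bias_spec")
}

# Effort surface over the grid (matrix). Hotspot centres are drawn from urban
# cells (any cell if no urban exists).
bias_surface <- function(world, bias) {
  nr <- nrow(world$lulc$values); nc <- ncol(world$lulc$values)
  if (bias$n_hotspots == 0) return(matrix(1, nr, nc))
  urban_id <- unname(world$lulc$classes["urban"])
  cand <- which(world$lulc$values == urban_id)
  if (length(cand) == 0) cand <- seq_len(nr * nc)
  ctr <- sample(cand, min(bias$n_hotspots, length(cand)),
                replace = length(cand) < bias$n_hotspots)
  rows <- rep(seq_len(nr), times = nc); cols <- rep(seq_len(nc), each = nr)
  b <- rep(bias$floor, nr * nc)
  for (k in ctr) {
    kr <- ((k - 1L) %% nr) + 1L; kc <- ((k - 1L) %/% nr) + 1L
    b <- b + exp(-((rows - kr)^2 + (cols - kc)^2) / (2 * bias$sigma_cells^2))
  }
  matrix(b, nr, nc)
}

#' Sample biased presence records from a virtual species
#'
#' Draws `n_raw` occurrence locations with probability proportional to
#' `S(x) * B(x)` (truth suitability times observation effort) and attaches
#' synthetic survey metadata: an observation protocol (stationary / traveling
#' / exhaustive-area), a travel distance for traveling counts, a search area
#' for exhaustive-area counts, and a date uniform over the calendar window,
#' so the downstream protocol / season filters have realistic work to do.
#'
#' @param world A `synthetic_world`.
#' @param sp A [virtual_species()].
#' @param n_raw Number of records to draw (>= 1).
#' @param bias A [bias_spec()].
#' @param seed RNG seed.
#' @param species Species label recorded on each row.
#' @param date_start,date_end Calendar window (month-day strings).
#' @param years Years records may fall in.
#' @return A presence tibble (columns `species`, `x`, `y`, `date`, `protocol`,
#'   `travel_km`, `area_ha`) with a `filter_log` attribute.
#' @export
sample_presences <- function(world, sp, n_raw, bias = bias_spec(), seed = 1L,
                             species = "virtual", date_start = "05-01",
                             date_end = "08-31", years = 1992:2012) {
  if (n_raw < 1) stop("n_raw must be at least 1", call. = FALSE)
  s <- true_suitability(world, sp)$values
  if (all(s <= 0)) stop("no habitable cells", call. = FALSE)
  cs <- world$lulc$cell_size
  nr <- nrow(s); nc <- ncol(s)
  with_seed(seed, {
    b <- bias_surface(world, bias)
    p <- as.vector(s * b)
    cells <- sample.int(nr * nc, n_raw, replace = TRUE, prob = p)
    rows <- ((cells - 1L) %% nr) + 1L
    cols <- ((cells - 1L) %/% nr) + 1L
    ctr <- cell_centers(world$lulc, rows, cols)
    x <- ctr$x + stats::runif(n_raw, -0.5, 0.5) * cs
    y <- ctr$y + stats::runif(n_raw, -0.5, 0.5) * cs
    protocol <- sample(c("stationary", "traveling", "exhaustive_area"),
                       n_raw, replace = TRUE, prob = c(0.40, 0.45, 0.15))
    travel_km <- ifelse(protocol == "traveling", stats::rexp(n_raw, rate = 1 / 1.3), NA_real_)
    area_ha <- ifelse(protocol == "exhaustive_area",
                      stats::rlnorm(n_raw, meanlog = log(40), sdlog = 1), NA_real_)
    yr <- sample(years, n_raw, replace = TRUE)
    d0 <- as.Date(paste0(yr, "-", date_start))
    d1 <- as.Date(paste0(yr, "-", date_end))
    date <- d0 + floor(stats::runif(n_raw) * (as.numeric(d1 - d0) + 1))
    out <- tibble::tibble(species = species, x = x, y = y, date = date,
                          protocol = protocol, travel_km = travel_km,
                          area_ha = area_ha)
    attr(out, "filter_log") <- tibble::tibble(stage = "original", n = n_raw)
    out
  })
}
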