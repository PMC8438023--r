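# Deterministic seeding helpers: every generator call derives its own stream
# from (scenario seed, tag) and restores the caller's RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 7919 + h * 131) %% 2147483629)
}

# per-variable units: temperature-like for bio1..11 (deg C), precipitation
# for bio12..19 (mm, non-negative); `curve` bends the shared gradient so the
# variables are distinct monotone reparameterizations of it
var_units <- function(v) {
  curve <- 0.8 * (((v * 37) %% 17) / 17 - 0.5)
  if (v <= 11) list(offset = -5 - (v %% 3), span = 35 + v, precip = FALSE,
                    curve = curve)
  else list(offset = 0, span = 2500 + 100 * (v %% 4), precip = TRUE,
            curve = curve)
}

# number of discrete levels of the latent gradient and per-variable value step
LATENT_LEVELS <- 120
quantum_of <- function(v) var_units(v)$span / 1000

# shared latent climate gradient, discretized to integer levels: latitude +
# low-frequency sinusoid + seeded noise (one draw per scenario, shared by
# every variable so the variables are strongly collinear, as bioclim
# summaries of one climate system are)
latent_levels <- function(scn) {
  cf <- coord_fields(scn$grid)
  wave <- sin(2 * pi * (1.3 * cf$lon + 0.9 * cf$lat))
  noise <- with_seed(derive_seed(scn$seed, "latent"), {
    matrix(stats::rnorm(length(cf$lon)), nrow(cf$lon), ncol(cf$lon))
  })
  raw <- 0.62 * cf$lat + 0.22 * (wave + 1) / 2 + scn$noise_frac * noise + 0.08
  round(LATENT_LEVELS * raw)
}

# strictly increasing map from latent level to integer lattice ticks of the
# variable's value step; the curvature keeps the map monotone over the
# attainable level range while giving each variable its own nonlinear
# response. Values are materialized as quantum * ticks in one product, so a
# lattice point is bit-identical wherever it occurs (present, shifted
# future, training sample).
level_to_ticks <- function(v, levels) {
  u <- var_units(v)
  t <- levels / LATENT_LEVELS
  g <- t + u$curve * t * (1 - t)
  ticks <- round((u$offset + u$span * g) / quantum_of(v))
  if (u$precip) ticks <- pmax(ticks, 0)
  ticks
}

level_to_value <- function(v, levels) {
  quantum_of(v) * level_to_ticks(v, levels)
}

#' Synthetic study scenario
#'
#' Defines a fully synthetic, seeded stand-in for the study's external
#' inputs: multi-variable climate grids for present and 2070 with per-GCM
#' perturbations, a land mask, occurrences drawn from a known climate
#' envelope, and clustered fine-resolution population rasters. Everything
#' downstream of a scenario is a pure function of its seed.
#'
#' All variables are strictly monotone transforms of one shared latent
#' climate gradient (latitudinal trend + low-frequency sinusoid + seeded
#' noise, discretized to integer levels), so they are strongly collinear,
#' as bioclim summaries of a single climate system are. Values are
#' quantized to a per-variable step (1/1000 of the span); the true envelope
#' is a latent-level band whose per-variable bounds sit half a step off the
#' value lattice, and future shifts and GCM perturbations are lattice
#' multiples -- together this makes dense-sampling parameter recovery exact
#' rather than approximate (see the methods vignette).
#'
#' @param seed integer master seed.
#' @param grid a \code{\link{study_grid}} (default: the full 220 x 120 study
#'   rectangle). Any land mask on it is replaced by the generated one.
#' @param vars bioclim indices to generate (default: the 13 post-selection
#'   variables).
#' @param gcms pseudo-GCM labels (default four, as in the study ensemble).
#' @param rcps future scenario labels to generate.
#' @param envelope_quantiles the true envelope per variable spans these
#'   quantiles of the present field over land.
#' @param shift_frac additive future trend per variable, as a (signed)
#'   fraction of the variable's span: by default temperatures shift up by
#'   6\% and precipitation up by 4\% of span (a warming, monsoon-wetting
#'   trend), so the suitable band migrates and all three change zones are
#'   populated.
#' @param gcm_frac amplitude of the per-GCM smooth perturbation as a
#'   fraction of span.
#' @param noise_frac amplitude of the seeded white-noise term.
#' @param land_fraction fraction of cells that are land.
#' @param n_pop_clusters,pop_factor,pop_peak,pop_growth population model:
#'   number of settlement clusters, fine-grid refinement factor (60 =
#'   30-arc-second equivalent), peak intensity (persons per fine cell), and
#'   per-cluster 2020 to 2070 growth factors (recycled).
#' @return a \code{synthetic_scenario} with the generated land mask on its
#'   grid and the derived \code{true_envelope} (per-variable \code{lo}/
#'   \code{hi} bounds).
#' @export
synthetic_scenario <- function(seed = 1, grid = study_grid(),
                               vars = c(1, 2, 3, 4, 8, 9, 10, 12, 13, 15, 17, 18, 19),
                               gcms = c("CCSM", "CNRM", "MIROC", "MRI"),
                               rcps = "rcp60",
                               envelope_quantiles = c(0.45, 0.80),
                               shift_frac = NULL, gcm_frac = 0.02,
                               noise_frac = 0.06, land_fraction = 0.7,
                               n_pop_clusters = 5, pop_factor = 60,
                               pop_peak = 50, pop_growth = c(1.6, 1.2, 0.9, 1.3, 1.05)) {
  stopifnot(length(vars) >= 1, length(gcms) >= 1,
            envelope_quantiles[1] < envelope_quantiles[2])
  if (is.null(shift_frac))
    shift_frac <- ifelse(vars <= 11, 0.06, 0.04)
  shift_frac <- rep_len(shift_frac, length(vars))
  scn <- structure(
    list(seed = as.integer(seed), grid = grid, vars = vars, gcms = gcms,
         rcps = rcps, envelope_quantiles = envelope_quantiles,
         shift_frac = stats::setNames(shift_frac, paste0("bio", vars)),
         gcm_frac = gcm_frac, noise_frac = noise_frac,
         land_fraction = land_fraction, n_pop_clusters = n_pop_clusters,
         pop_factor = pop_factor, pop_peak = pop_peak,
         pop_growth = rep_len(pop_growth, n_pop_clusters)),
    class = "synthetic_scenario")
  scn$grid$land_mask <- make_land_mask(scn)
  scn$true_envelope <- derive_true_envelope(scn)
  scn
}

#' @export
print.synthetic_scenario <- function(x, ...) {
  cat("synthetic_scenario (seed ", x$seed, "): ", length(x$vars),
      " variables, ", length(x$gcms), " GCMs, ",
      x$grid$n_rows, " x ", x$grid$n_cols, " grid, ",
      sum(x$grid$land_mask), " land cells\n", sep = "")
  invisible(x)
}

# normalized coordinate fields (0..1), row-major matrices
coord_fields <- function(grid) {
  cc <- cell_centers(grid)
  lonn <- (cc$lon - grid$lon_min) / (grid$lon_max - grid$lon_min)
  latn <- (grid$lat_max - cc$lat) / (grid$lat_max - grid$lat_min)  # 0 north
  list(lon = matrix(lonn, grid$n_rows, grid$n_cols, byrow = TRUE),
       lat = matrix(latn, grid$n_rows, grid$n_cols))
}

# present-day field for one variable: the latent gradient mapped through the
# variable's monotone response (already on the value lattice)
present_layer <- function(scn, v, levels = latent_levels(scn)) {
  level_to_value(v, levels)
}

# smooth per-GCM perturbation in lattice ticks
gcm_perturbation_ticks <- function(scn, v, gcm) {
  i <- match(gcm, scn$gcms)
  u <- var_units(v)
  cf <- coord_fields(scn$grid)
  phase <- with_seed(derive_seed(scn$seed, paste0("gcm_", gcm, "_bio", v)),
                     stats::runif(1, 0, 2 * pi))
  f <- sin(2 * pi * ((0.8 + 0.3 * i) * cf$lon + (0.6 + 0.2 * i) * cf$lat) +
             phase)
  round(scn$gcm_frac * u$span * f / quantum_of(v))
}

make_land_mask <- function(scn) {
  cf <- coord_fields(scn$grid)
  noise <- with_seed(derive_seed(scn$seed, "land"), {
    matrix(stats::rnorm(length(cf$lon)), nrow(cf$lon), ncol(cf$lon))
  })
  f <- sin(2 * pi * (2.1 * cf$lon + 1.3 * cf$lat)) +
    0.8 * cos(2 * pi * (0.7 * cf$lon - 1.9 * cf$lat)) + 0.5 * noise
  f >= stats::quantile(f, 1 - scn$land_fraction)
}

# True envelope bounds: a latent-level band [m_lo, m_hi] spanning the
# requested quantiles of the land cells' levels (type-1 quantiles, so both
# band-edge levels are attained on land), mapped to per-variable value
# bounds placed half a value step outside the edge values. Membership
# "strictly inside on every variable" is then exactly the level band, and a
# dense training sample attains the exact edge values of every variable.
derive_true_envelope <- function(scn) {
  lev <- latent_levels(scn)[scn$grid$land_mask]
  m_lo <- stats::quantile(lev, scn$envelope_quantiles[1], type = 1)
  m_hi <- stats::quantile(lev, scn$envelope_quantiles[2], type = 1)
  if (m_hi <= m_lo)
    stop("degenerate true envelope: level band [", m_lo, ", ", m_hi, "]")
  env <- lapply(scn$vars, function(v) {
    q <- quantum_of(v)
    c(lo = unname(level_to_value(v, m_lo) - q / 2),
      hi = unname(level_to_value(v, m_hi) + q / 2))
  })
  stats::setNames(env, paste0("bio", scn$vars))
}

#' Generate the climate stacks of a scenario
#'
#' Present stacks are shared across GCMs (a single observational baseline);
#' each future stack is present + the per-variable additive trend + that
#' GCM's smooth perturbation. Precipitation is clamped at zero.
#'
#' @param scn a \code{\link{synthetic_scenario}}.
#' @return nested list: \code{$present[[gcm]]} and \code{$<rcp>[[gcm]]},
#'   each a \code{climate_stack}.
#' @export
make_climate <- function(scn) {
  levels <- latent_levels(scn)
  ticks <- lapply(scn$vars, function(v) level_to_ticks(v, levels))
  names(ticks) <- paste0("bio", scn$vars)
  present <- lapply(scn$vars, function(v)
    quantum_of(v) * ticks[[paste0("bio", v)]])
  names(present) <- paste0("bio", scn$vars)
  out <- list()
  out$present <- lapply(scn$gcms, function(g)
    climate_stack(present, "present", g, scn$grid))
  names(out$present) <- scn$gcms
  for (rcp in scn$rcps) {
    out[[rcp]] <- lapply(scn$gcms, function(g) {
      layers <- lapply(scn$vars, function(v) {
        u <- var_units(v)
        q <- quantum_of(v)
        shift <- round(scn$shift_frac[[paste0("bio", v)]] * u$span / q)
        tk <- ticks[[paste0("bio", v)]] + shift +
          gcm_perturbation_ticks(scn, v, g)
        if (u$precip) tk <- pmax(tk, 0)
        q * tk
      })
      names(layers) <- paste0("bio", scn$vars)
      climate_stack(layers, rcp, g, scn$grid)
    })
    names(out[[rcp]]) <- scn$gcms
  }
  out
}

# strict membership of a stack's cells in the true envelope
envelope_membership <- function(scn, stack) {
  m <- matrix(TRUE, scn$grid$n_rows, scn$grid$n_cols)
  for (v in names(scn$true_envelope)) {
    b <- scn$true_envelope[[v]]
    m <- m & stack$layers[[v]] > b["lo"] & stack$layers[[v]] < b["hi"]
  }
  m
}

#' Sample occurrences from the true envelope
#'
#' Candidate cells are the land cells whose present climate lies strictly
#' inside the true envelope on every variable. Records are placed at cell
#' centers; \code{n = NULL} takes every candidate cell (dense sampling, the
#' regime in which the fitted envelope recovers the truth exactly).
#'
#' @param scn a \code{\link{synthetic_scenario}}.
#' @param n number of cells to sample without replacement, or \code{NULL}
#'   for all.
#' @param species label for the records.
#' @return an \code{occurrence_set}; the logical truth mask of suitable
#'   present cells is in \code{attr(, "truth_mask")}.
#' @export
make_occurrences <- function(scn, n = NULL, species = "synthetic cobra") {
  climate <- make_climate(scn)
  truth <- envelope_membership(scn, climate$present[[1]]) & scn$grid$land_mask
  cand <- which(truth)
  if (!length(cand))
    stop("no land cell lies strictly inside the true envelope; ",
         "widen envelope_quantiles or the land fraction")
  if (is.null(n)) n <- length(cand)
  if (n > length(cand))
    stop("requested ", n, " occurrences but only ", length(cand),
         " suitable cells exist")
  # a fixed seeded permutation makes samples nested: the n = 30 sample is a
  # subset of the n = 300 sample, so envelope coverage grows monotonically
  perm <- with_seed(derive_seed(scn$seed, "occurrences"), sample(cand))
  pick <- sort(perm[seq_len(n)])
  cc <- cell_centers(scn$grid)
  row <- ((pick - 1) %% scn$grid$n_rows) + 1
  col <- ((pick - 1) %/% scn$grid$n_rows) + 1
  rec <- data.frame(species = species, lon = cc$lon[col], lat = cc$lat[row],
                    source = "synthetic", row = row, col = col,
                    stringsAsFactors = FALSE)
  set <- new_occurrence_set(rec, data.frame(
    species = character(0), lon = numeric(0), lat = numeric(0),
    source = character(0), reason = character(0)))
  attr(set, "truth_mask") <- truth
  set
}

#' Generate a fine-resolution population raster
#'
#' Clustered settlement pattern: Poisson counts around \code{n_pop_clusters}
#' Gaussian intensity peaks on a grid \code{factor} times finer than the
#' study grid. The 2070 raster is the 2020 raster scaled cellwise by the
#' intensity-weighted per-cluster growth factors and rounded, so counts stay
#' integral and a growth factor of 1 reproduces 2020 exactly.
#'
#' @param scn a \code{\link{synthetic_scenario}}.
#' @param epoch \code{"2020"} or \code{"2070"}.
#' @param factor fine-grid refinement factor (defaults to the scenario's).
#' @return integer matrix of person counts,
#'   \code{(n_rows * factor) x (n_cols * factor)}.
#' @export
make_population <- function(scn, epoch = c("2020", "2070"),
                            factor = scn$pop_factor) {
  epoch <- match.arg(epoch)
  nr <- scn$grid$n_rows * factor
  nc <- scn$grid$n_cols * factor
  k <- scn$n_pop_clusters
  centers <- with_seed(derive_seed(scn$seed, "pop_centers"),
                       cbind(row = stats::runif(k, 1, nr),
                             col = stats::runif(k, 1, nc)))
  sigma <- 0.12 * min(nr, nc)
  rows <- seq_len(nr); cols <- seq_len(nc)
  intensity <- matrix(0, nr, nc)
  weighted_growth <- matrix(0, nr, nc)
  for (i in seq_len(k)) {
    ker <- outer(exp(-(rows - centers[i, "row"])^2 / (2 * sigma^2)),
                 exp(-(cols - centers[i, "col"])^2 / (2 * sigma^2)))
    intensity <- intensity + scn$pop_peak * ker
    weighted_growth <- weighted_growth + scn$pop_growth[i] * scn$pop_peak * ker
  }
  pop2020 <- with_seed(derive_seed(scn$seed, "pop_draw"), {
    matrix(stats::rpois(nr * nc, intensity), nr, nc)
  })
  if (epoch == "2020") return(pop2020)
  growth <- ifelse(intensity > 0, weighted_growth / intensity,
                   mean(scn$pop_growth))
  out <- round(pop2020 * growth)
  storage.mode(out) <- "integer"
  out
}

#' Ground-truth accounting of a scenario
#'
#' Computes the exact change zones directly from true-envelope membership
#' (no fitting): the present mask is membership of the shared present
#' climate, the future mask is the union of the per-GCM future memberships
#' (which is what mean-then-threshold consensus yields), both restricted to
#' land. This is the recovery target for end-to-end tests.
#'
#' @param scn a \code{\link{synthetic_scenario}}.
#' @param rcp which generated future scenario to use.
#' @param config an \code{\link{accounting_config}}; defaults to the grid's
#'   cell area.
#' @return list with \code{account} (a \code{\link{species_account}} row),
#'   \code{present_mask}, \code{future_mask}, \code{zones}.
#' @export
ground_truth_accounts <- function(scn, rcp = scn$rcps[1],
                                  config = accounting_config(cell_area = scn$grid$cell_area)) {
  climate <- make_climate(scn)
  land <- scn$grid$land_mask
  present <- envelope_membership(scn, climate$present[[1]]) & land
  future <- matrix(FALSE, scn$grid$n_rows, scn$grid$n_cols)
  for (g in scn$gcms)
    future <- future | envelope_membership(scn, climate[[rcp]][[g]])
  future <- future & land
  zones <- zone_overlay(present * 1, future * 1)
  list(account = species_account(zones, species = "truth", rcp = rcp, config = config),
       present_mask = present, future_mask = future, zones = zones)
}
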