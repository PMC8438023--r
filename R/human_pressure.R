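#' Aggregate a fine population raster to the study grid
#'
#' Block sum: each coarse cell is the sum of its \code{factor x factor}
#' block of fine cells (the 30-arc-second to 0.5-degree downgrade uses
#' factor 60). Total population is conserved exactly. Missing fine cells
#' are treated as zero persons, with a coverage warning.
#'
#' @param fine numeric matrix of per-cell person counts; both dimensions
#'   must be divisible by \code{factor}.
#' @param factor block edge length (default 60).
#' @return matrix of summed counts, \code{nrow(fine)/factor} rows.
#' @export
aggregate_population <- function(fine, factor = 60) {
  stopifnot(is.matrix(fine), factor >= 1, factor == round(factor))
  if (nrow(fine) %% factor != 0 || ncol(fine) %% factor != 0)
    stop("fine grid (", nrow(fine), " x ", ncol(fine),
         ") is not divisible by the aggregation factor ", factor)
  if (anyNA(fine)) {
    warning(sum(is.na(fine)), " missing fine cells treated as 0 persons")
    fine[is.na(fine)] <- 0
  }
  if (any(fine < 0)) stop("population counts must be non-negative")
  block_reduce(fine, as.integer(factor), sum)
}

#' Human population density per change zone
#'
#' For each zone (1 lost, 2 gained, 3 stable): total persons over the
#' zone's cells divided by the zone area. An empty zone has no density --
#' \code{defined} is \code{FALSE} and the density \code{NA} (rendered as a
#' diamond in the published table).
#'
#' @param pop population matrix on the study grid (persons per cell).
#' @param zones zone-coded matrix, same geometry.
#' @param config an \code{\link{accounting_config}} (cell area).
#' @return data.frame with one row per zone: \code{zone}, \code{persons},
#'   \code{cells}, \code{area_km2}, \code{density} (persons/km^2),
#'   \code{defined}.
#' @export
zone_density <- function(pop, zones, config = accounting_config()) {
  if (!identical(dim(pop), dim(zones)))
    stop("population and zone grids disagree on geometry")
  out <- do.call(rbind, lapply(1:3, function(z) {
    inz <- !is.na(zones) & zones == z
    cells <- sum(inz)
    persons <- sum(pop[inz], na.rm = TRUE)
    area <- cells * config$cell_area
    data.frame(zone = z, persons = persons, cells = cells, area_km2 = area,
               density = if (cells > 0) persons / area else NA_real_,
               defined = cells > 0)
  }))
  rownames(out) <- NULL
  out
}

#' Change in zone density between two epochs
#'
#' Both epochs must have been measured over the same zone geometry (the
#' zones are a fixed reference map; only the population changes). Undefined
#' zones stay undefined.
#'
#' @param d2020,d2070 data.frames from \code{\link{zone_density}}.
#' @return data.frame per zone with \code{density_2020}, \code{density_2070},
#'   \code{change}, \code{defined}.
#' @export
density_change <- function(d2020, d2070) {
  stopifnot(identical(d2020$zone, d2070$zone),
            identical(d2020$cells, d2070$cells))
  data.frame(zone = d2020$zone,
             density_2020 = d2020$density,
             density_2070 = d2070$density,
             change = d2070$density - d2020$density,
             defined = d2020$defined & d2070$defined)
}

flag_chr <- function(x) factor(x, levels = c("+", "-", "unknown", "undefined"))

#' Binary risk matrix across species
#'
#' Assembles the per-species threat flags: computed flags come from the
#' accounting and pressure tables (a shrinking suitable niche; rising human
#' density per zone), the temperature/precipitation influence flags from a
#' limiting-variable analysis at the envelope edge (see
#' \code{\link{env_limiting_variable}}), and the remaining flags (declining
#' wild population, trade/overexploitation) are externally sourced inputs
#' (IUCN assessments, CITES listings) passed through verbatim. Flags are
#' \code{"+"}, \code{"-"}, \code{"unknown"} (no published information) or
#' \code{"undefined"} (empty zone).
#'
#' @param accounts data.frame of \code{\link{species_account}} rows.
#' @param pressures named list (by species) of \code{\link{density_change}}
#'   tables.
#' @param external data.frame with \code{species}, \code{population_trend}
#'   (\code{"decreasing"}/\code{"stable"}/\code{"increasing"}/\code{NA}) and
#'   \code{trade_listed} (logical or \code{NA}); optional.
#' @param limiting named list (by species) of character vectors of limiting
#'   variable names at envelope-edge cells; optional.
#' @param edge_fraction minimal fraction of edge cells a variable class must
#'   limit to earn a \code{"+"} (default 0: any cell).
#' @return data.frame, one row per species, flag columns as characters.
#' @export
risk_matrix <- function(accounts, pressures, external = NULL,
                        limiting = NULL, edge_fraction = 0) {
  temp_vars <- paste0("bio", 1:11)
  rows <- lapply(seq_len(nrow(accounts)), function(i) {
    sp <- accounts$species[i]
    niche <- if (accounts$decrease_pct[i] > 0) "+" else "-"

    dens <- rep("unknown", 3)
    pr <- pressures[[sp]]
    if (!is.null(pr)) {
      dens <- ifelse(!pr$defined, "undefined", ifelse(pr$change > 0, "+", "-"))
    }

    infl_t <- infl_p <- "unknown"
    lim <- limiting[[sp]]
    if (!is.null(lim) && length(lim)) {
      ft <- mean(lim %in% temp_vars)
      infl_t <- if (ft > edge_fraction) "+" else "-"
      infl_p <- if ((1 - ft) > edge_fraction) "+" else "-"
    }

    popdec <- trade <- "unknown"
    if (!is.null(external)) {
      ext <- external[external$species == sp, , drop = FALSE]
      if (nrow(ext)) {
        if (!is.na(ext$population_trend[1]))
          popdec <- if (ext$population_trend[1] == "decreasing") "+" else "-"
        if (!is.na(ext$trade_listed[1]))
          trade <- if (isTRUE(ext$trade_listed[1])) "+" else "-"
      }
    }
    data.frame(species = sp,
               population_decrease = popdec,
               decrease_suitable_niche = niche,
               influence_temperature = infl_t,
               influence_precipitation = infl_p,
               density_zone1 = dens[1], density_zone2 = dens[2],
               density_zone3 = dens[3],
               overexploitation_trade = trade,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Render risk flags with the published glyphs
#'
#' \code{unknown} becomes \code{*} (no published information) and
#' \code{undefined} becomes a diamond (empty zone).
#'
#' @param risk data.frame from \code{\link{risk_matrix}}.
#' @return the data.frame with glyph-rendered flag columns.
#' @export
render_risk_glyphs <- function(risk) {
  glyph <- c("+" = "+", "-" = "-", "unknown" = "*", "undefined" = "♦")
  for (col in setdiff(names(risk), "species"))
    risk[[col]] <- unname(glyph[risk[[col]]])
  risk
}
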