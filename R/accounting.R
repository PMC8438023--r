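#' Accounting configuration
#'
#' Parameters for turning change-zone maps into conservation quantities:
#' the projection window (2020 to 2070, a 50-year span), the IUCN Red List
#' criterion B1 extent-of-occurrence gate for Vulnerable status
#' (20,000 km^2), and the constant cell area.
#'
#' @param base_year first year of the window.
#' @param horizon_year projection year.
#' @param vu_threshold Vulnerable EOO threshold in km^2.
#' @param cell_area km^2 per grid cell.
#' @return list of class \code{accounting_config} (with derived \code{span}).
#' @export
accounting_config <- function(base_year = 2020, horizon_year = 2070,
                              vu_threshold = 20000, cell_area = 3600) {
  span <- horizon_year - base_year
  stopifnot(span > 0, vu_threshold > 0, cell_area > 0)
  structure(list(base_year = base_year, horizon_year = horizon_year,
                 span = span, vu_threshold = vu_threshold,
                 cell_area = cell_area),
            class = "accounting_config")
}

#' Zone areas in km^2
#'
#' @param zones zone-coded matrix (already accessibility-masked).
#' @param config an \code{\link{accounting_config}}.
#' @return named vector \code{c(A1, A2, A3)}: lost, gained, stable, each a
#'   multiple of the cell area.
#' @export
zone_areas <- function(zones, config = accounting_config()) {
  cnt <- zone_counts(zones)
  stats::setNames(as.numeric(cnt[c("zone1", "zone2", "zone3")]) * config$cell_area,
                  c("A1", "A2", "A3"))
}

#' Percent decrease of the climatic niche
#'
#' \code{100 * (A1 - A2) / (A1 + A3)}: net loss relative to the current
#' niche (\code{A_cur = A1 + A3}). Algebraically identical to
#' \code{100 * (A_cur - A_fut) / A_cur} with \code{A_fut = A2 + A3}.
#' Negative when gains exceed losses (reported as such, never clamped);
#' undefined (\code{NA}) when the current niche is empty.
#'
#' @param A1,A2,A3 zone areas in km^2 (lost, gained, stable).
#' @return percentage.
#' @export
decrease_pct <- function(A1, A2, A3) {
  cur <- A1 + A3
  ifelse(cur > 0, 100 * (A1 - A2) / cur, NA_real_)
}

#' Mean yearly net loss of niche area
#'
#' \code{(A1 - A2) / span} in km^2 per year; negative for net gain.
#'
#' @inheritParams decrease_pct
#' @param config an \code{\link{accounting_config}}.
#' @return km^2 per year.
#' @export
yearly_rate <- function(A1, A2, config = accounting_config()) {
  (A1 - A2) / config$span
}

#' Year of reaching the Vulnerable extent threshold
#'
#' Linear extrapolation of the yearly net loss until the current accessible
#' niche shrinks to the criterion B1 threshold:
#' \code{base_year + round((A_cur - vu_threshold) / rate)}. A species already
#' at or below the threshold is assigned the base year; a non-positive rate
#' never reaches it (\code{Inf}, rendered "never").
#'
#' @param A_cur current niche area in km^2 (zones 1 + 3).
#' @param rate yearly net loss in km^2/yr.
#' @param config an \code{\link{accounting_config}}.
#' @return calendar year (numeric; \code{Inf} = never).
#' @export
vu_year <- function(A_cur, rate, config = accounting_config()) {
  stopifnot(all(A_cur >= 0))
  out <- numeric(length(A_cur))
  rate <- rep_len(rate, length(A_cur))
  at <- A_cur <= config$vu_threshold
  out[at] <- config$base_year
  never <- !at & rate <= 0
  out[never] <- Inf
  rest <- !at & !never
  out[rest] <- config$base_year +
    round((A_cur[rest] - config$vu_threshold) / rate[rest])
  out
}

#' Full accounting for one species and scenario
#'
#' @param zones accessibility-masked zone grid.
#' @param species,rcp labels.
#' @param config an \code{\link{accounting_config}}.
#' @return one-row data.frame: areas (km^2), \code{A_cur}, \code{A_fut},
#'   \code{decrease_pct}, \code{yearly_rate} (km^2/yr), \code{vu_year}.
#' @export
species_account <- function(zones, species = "species", rcp = "rcp60",
                            config = accounting_config()) {
  a <- zone_areas(zones, config)
  rate <- yearly_rate(a["A1"], a["A2"], config)
  data.frame(species = species, rcp = rcp,
             A1 = unname(a["A1"]), A2 = unname(a["A2"]), A3 = unname(a["A3"]),
             A_cur = unname(a["A1"] + a["A3"]), A_fut = unname(a["A2"] + a["A3"]),
             decrease_pct = decrease_pct(a["A1"], a["A2"], a["A3"]),
             yearly_rate = unname(rate),
             vu_year = vu_year(unname(a["A1"] + a["A3"]), unname(rate), config),
             stringsAsFactors = FALSE)
}

#' Summarize accounts across species
#'
#' @param accounts data.frame of \code{\link{species_account}} rows.
#' @return data.frame per RCP: mean/min/max decrease percentage and zone
#'   area totals.
#' @export
summarize_accounts <- function(accounts) {
  stopifnot(nrow(accounts) >= 1)
  out <- do.call(rbind, lapply(split(accounts, accounts$rcp), function(d) {
    data.frame(rcp = d$rcp[1], n_species = nrow(d),
               mean_decrease_pct = mean(d$decrease_pct, na.rm = TRUE),
               min_decrease_pct = min(d$decrease_pct, na.rm = TRUE),
               max_decrease_pct = max(d$decrease_pct, na.rm = TRUE),
               total_A1 = sum(d$A1), total_A2 = sum(d$A2), total_A3 = sum(d$A3),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' The published per-species accounting table (RCP 6.0)
#'
#' The study's printed values for the ten Asian cobras under RCP 6.0:
#' decrease in niche size (% of the current niche; printed as negative for
#' a decrease), mean yearly decrease (thousand km^2/yr), year to reach the
#' Red List Vulnerable extent, the three zone sizes (million km^2), and the
#' 2020--2070 change in human population density per zone (persons/km^2;
#' \code{NA} where a zone is empty and density is undefined).
#'
#' @return data.frame, one row per species.
#' @export
naja_table1 <- function() {
  data.frame(
    species = c("Naja atra", "Naja kaouthia", "Naja mandalayensis",
                "Naja naja", "Naja oxiana", "Naja philippinensis",
                "Naja samarensis", "Naja siamensis", "Naja sputatrix",
                "Naja sumatrana"),
    decrease_pct = c(-40.14, -27.91, -100.00, -12.15, -13.33, -83.33,
                     -83.72, -86.21, -89.29, -28.37),
    yearly_rate_thousand_km2 = c(-20.09, -39.38, -4.18, -25.99, -15.26,
                                 -2.52, -2.59, -21.60, -3.60, -8.64),
    vu_year = c(2144, 2199, 2065, 2431, 2394, 2072, 2072, 2077, 2070, 2194),
    zone1_Mkm2 = c(1.29, 2.19, 0.21, 1.74, 1.21, 0.13, 0.13, 1.10, 0.18, 0.48),
    zone2_Mkm2 = c(0.28, 0.22, 0.00, 0.44, 0.45, 0.00, 0.00, 0.02, 0.00, 0.05),
    zone3_Mkm2 = c(1.21, 4.86, 0.00, 8.96, 4.51, 0.03, 0.03, 0.15, 0.02, 1.04),
    dpop_zone1 = c(-56, 23, -21, 8, 22, 139, 31, -11, 7, 41),
    dpop_zone2 = c(-55, -16, NA, -33, -1, NA, NA, -2, NA, 41),
    dpop_zone3 = c(-55, -16, NA, -9, 8, 8, 28, -7, -7, 41),
    stringsAsFactors = FALSE)
}

#' The published per-species occurrence counts
#'
#' Occurrence records per species after curation and thinning, as used to
#' train the envelopes (total 1162).
#'
#' @return data.frame with \code{species} and \code{n}.
#' @export
naja_occurrence_counts <- function() {
  data.frame(
    species = c("Naja oxiana", "Naja naja", "Naja kaouthia", "Naja atra",
                "Naja siamensis", "Naja mandalayensis", "Naja sumatrana",
                "Naja sputatrix", "Naja samarensis", "Naja philippinensis"),
    n = c(111L, 354L, 218L, 128L, 76L, 29L, 123L, 54L, 41L, 28L),
    stringsAsFactors = FALSE)
}

#' Recompute the published accounting from its printed inputs
#'
#' Worked-example checker: starting from the printed zone sizes (million
#' km^2) and printed yearly rates, re-derives the decrease percentage
#' (\code{\link{decrease_pct}}), the yearly net-loss rate
#' (\code{\link{yearly_rate}}), and the Vulnerable year
#' (\code{\link{vu_year}}, driven by the printed rate), and reports them
#' next to the printed values. Derived decreases/rates carry a positive
#' sign for a decrease; comparisons use magnitudes. Known residuals (the
#' published table's unrounded intermediates are unrecoverable) appear as
#' small \code{vu_year} offsets for N. atra, N. philippinensis and
#' N. samarensis.
#'
#' @param config an \code{\link{accounting_config}}.
#' @return data.frame with printed and computed columns plus absolute
#'   differences.
#' @export
reproduce_table1 <- function(config = accounting_config()) {
  t1 <- naja_table1()
  A1 <- t1$zone1_Mkm2 * 1e6
  A2 <- t1$zone2_Mkm2 * 1e6
  A3 <- t1$zone3_Mkm2 * 1e6
  dec <- decrease_pct(A1, A2, A3)
  rate <- yearly_rate(A1, A2, config)
  printed_rate <- abs(t1$yearly_rate_thousand_km2) * 1000
  vu <- vu_year(A1 + A3, printed_rate, config)
  data.frame(species = t1$species,
             decrease_pct_printed = abs(t1$decrease_pct),
             decrease_pct_computed = round(dec, 2),
             decrease_abs_diff = abs(abs(t1$decrease_pct) - round(dec, 2)),
             yearly_rate_printed_km2 = printed_rate,
             yearly_rate_computed_km2 = rate,
             vu_year_printed = t1$vu_year,
             vu_year_computed = vu,
             vu_year_diff = vu - t1$vu_year,
             stringsAsFactors = FALSE)
}
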