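#' Materialize a synthetic study directory
#'
#' Writes everything a pipeline run consumes, in the same dialects the real
#' inputs use: occurrence CSV, per-(scenario, GCM, variable) climate ASCII
#' grids, the land mask, fine population rasters for both epochs, and a
#' JSON manifest of the scenario (seed, grid, envelope bounds).
#'
#' @param scn a \code{\link{synthetic_scenario}}.
#' @param dir output directory (created).
#' @param n_occurrences passed to \code{\link{make_occurrences}}.
#' @param pop_factor refinement factor for the emitted population rasters
#'   (the default writes study-grid-resolution sums when 1).
#' @return the directory, invisibly.
#' @export
simulate_study <- function(scn, dir, n_occurrences = NULL,
                           pop_factor = scn$pop_factor) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  occ <- make_occurrences(scn, n_occurrences)
  utils::write.csv(occ$records[c("species", "lon", "lat", "source")],
                   file.path(dir, "occurrences.csv"), row.names = FALSE)
  climate <- make_climate(scn)
  clim_dir <- file.path(dir, "climate")
  for (epoch in names(climate))
    for (g in names(climate[[epoch]]))
      write_climate_stack(climate[[epoch]][[g]], clim_dir)
  write_asc(scn$grid$land_mask * 1, scn$grid, file.path(dir, "land_mask.asc"))
  fine_grid <- study_grid(scn$grid$lon_min, scn$grid$lon_max,
                          scn$grid$lat_min, scn$grid$lat_max,
                          resolution = scn$grid$resolution / pop_factor,
                          cell_area = scn$grid$cell_area / pop_factor^2)
  for (epoch in c("2020", "2070"))
    write_asc(make_population(scn, epoch, factor = pop_factor), fine_grid,
              file.path(dir, sprintf("population_%s.asc", epoch)))
  jsonlite::write_json(
    list(seed = scn$seed, vars = scn$vars, gcms = scn$gcms, rcps = scn$rcps,
         grid = scn$grid[c("lon_min", "lon_max", "lat_min", "lat_max",
                           "resolution", "cell_area")],
         pop_factor = pop_factor,
         true_envelope = scn$true_envelope),
    file.path(dir, "scenario.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Pipeline run configuration
#'
#' Collects paths and parameters for \code{\link{run_pipeline}} and
#' validates them: every referenced path must exist and the scenario list
#' must be non-empty.
#'
#' @param occurrences path to the occurrence CSV.
#' @param climate_dir directory of climate ASCII grids named
#'   \code{<scenario>_<gcm>_bio<k>.asc}.
#' @param out_dir output directory.
#' @param grid a \code{\link{study_grid}}.
#' @param land_mask path to a land-mask ASCII grid, or \code{NULL}.
#' @param population named paths (\code{"2020"}, \code{"2070"}) to fine
#'   population rasters, or \code{NULL} to skip the pressure stage.
#' @param pop_factor aggregation factor for the population rasters.
#' @param vars bioclim indices used for modelling.
#' @param gcms,rcps ensemble members and future scenarios to run.
#' @param ssp SSP identifier labelling the population projection (required
#'   when population rasters are given; there is no default pairing of SSPs
#'   with RCPs).
#' @param accounting an \code{\link{accounting_config}}.
#' @param access_masks optional named list (by species) of accessibility
#'   mask paths.
#' @param seed integer seed recorded in the provenance manifest.
#' @return validated \code{run_config} list.
#' @export
run_config <- function(occurrences, climate_dir, out_dir,
                       grid = study_grid(), land_mask = NULL,
                       population = NULL, pop_factor = 60, vars = NULL,
                       gcms = c("CCSM", "CNRM", "MIROC", "MRI"),
                       rcps = "rcp60", ssp = NULL,
                       accounting = NULL, access_masks = NULL, seed = 1) {
  if (!file.exists(occurrences)) stop("occurrence file not found: ", occurrences)
  if (!dir.exists(climate_dir)) stop("climate directory not found: ", climate_dir)
  if (!is.null(land_mask) && !file.exists(land_mask))
    stop("land mask not found: ", land_mask)
  if (!is.null(population)) {
    if (!all(c("2020", "2070") %in% names(population)))
      stop("population needs paths named \"2020\" and \"2070\"")
    for (p in population) if (!file.exists(p)) stop("population raster not found: ", p)
    if (is.null(ssp)) stop("an SSP identifier is required with population rasters")
  }
  if (!length(gcms)) stop("at least one GCM is required")
  if (!length(rcps)) stop("at least one future scenario is required")
  if (is.null(vars)) vars <- c(1, 2, 3, 4, 8, 9, 10, 12, 13, 15, 17, 18, 19)
  if (is.null(accounting)) accounting <- accounting_config(cell_area = grid$cell_area)
  structure(list(occurrences = occurrences, climate_dir = climate_dir,
                 out_dir = out_dir, grid = grid, land_mask = land_mask,
                 population = population, pop_factor = pop_factor,
                 vars = vars, gcms = gcms, rcps = rcps, ssp = ssp,
                 accounting = accounting, access_masks = access_masks,
                 seed = seed),
            class = "run_config")
}

#' Run the full pipeline
#'
#' One-shot end-to-end execution from on-disk inputs to on-disk outputs:
#' clean and thin occurrences, fit one percentile envelope per species per
#' GCM on the present climate, predict present and each future scenario,
#' average the ensemble into consensus maps, binarize at zero, overlay into
#' change zones, apply land/accessibility masks, account areas and
#' Vulnerable years, and (when population rasters are configured) compute
#' per-zone density change and the risk flags. Stages communicate via the
#' returned in-memory objects \emph{and} on-disk artifacts (CSV + ASCII
#' grids + a provenance manifest), so a run is resumable and reproducible;
#' re-running with the same config writes byte-identical tables.
#'
#' @param config a validated \code{\link{run_config}}.
#' @return invisibly, a list with \code{accounts}, \code{summary},
#'   \code{pressures}, \code{risk}, \code{drop_log} and the output dir.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  grid <- config$grid
  if (!is.null(config$land_mask))
    grid$land_mask <- read_asc(config$land_mask)$data > 0
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  stage <- "occurrences"
  res <- tryCatch({
    occ <- read_occurrences(config$occurrences)
    set <- thin_to_grid(clean_occurrences(occ, grid), grid)
    write_drop_log(set, file.path(config$out_dir, "dropped_records.csv"))
    utils::write.csv(species_counts(set),
                     file.path(config$out_dir, "species_counts.csv"),
                     row.names = FALSE)

    stage <- "climate"
    stacks <- list()
    for (sc in c("present", config$rcps)) {
      stacks[[sc]] <- lapply(config$gcms, function(g)
        read_climate_stack(config$climate_dir, sc, g, grid, vars = config$vars))
      names(stacks[[sc]]) <- config$gcms
    }

    accounts <- list(); pressures <- list(); limiting <- list()
    pop_coarse <- NULL
    if (!is.null(config$population)) {
      stage <- "population"
      pop_coarse <- lapply(config$population, function(p)
        aggregate_population(read_asc(p)$data, config$pop_factor))
    }

    for (sp in unique(set$records$species)) {
      stage <- paste0("species ", sp)
      pts <- set$records[set$records$species == sp, ]
      # fit per GCM on that GCM's present climate, predict, then ensemble
      suit <- list()
      for (sc in c("present", config$rcps)) suit[[sc]] <- list()
      for (g in config$gcms) {
        ex <- extract_values(stacks$present[[g]], pts)
        if (nrow(ex$values) < 2)
          stop("fewer than two usable training points")
        model <- env_fit(ex$values)
        limiting[[sp]] <- edge_limiting_vars(model, stacks$present[[g]])
        for (sc in c("present", config$rcps)) {
          s <- predict(model, stacks[[sc]][[g]])
          suit[[sc]][[g]] <- s
        }
      }
      cons <- lapply(suit, consensus)
      for (sc in names(cons))
        write_asc(cons[[sc]], grid,
                  file.path(config$out_dir,
                            sprintf("consensus_%s_%s.asc", gsub(" ", "_", sp), sc)))
      present_bin <- binarize(cons$present)
      access <- grid$land_mask
      if (!is.null(config$access_masks[[sp]])) {
        am <- read_asc(config$access_masks[[sp]])$data > 0
        access <- if (is.null(access)) am else access & am
      }
      for (rcp in config$rcps) {
        zones <- zone_overlay(present_bin, binarize(cons[[rcp]]))
        zones <- apply_accessibility_mask(zones, access)
        write_asc(zones, grid,
                  file.path(config$out_dir,
                            sprintf("zones_%s_%s.asc", gsub(" ", "_", sp), rcp)))
        accounts[[paste(sp, rcp)]] <-
          species_account(zones, sp, rcp, config$accounting)
        if (!is.null(pop_coarse)) {
          d20 <- zone_density(pop_coarse[["2020"]], zones, config$accounting)
          d70 <- zone_density(pop_coarse[["2070"]], zones, config$accounting)
          pressures[[sp]] <- density_change(d20, d70)
        }
      }
    }

    stage <- "accounting"
    accounts <- do.call(rbind, accounts)
    rownames(accounts) <- NULL
    for (rcp in config$rcps) {
      acc <- accounts[accounts$rcp == rcp, ]
      out <- data.frame(species = acc$species,
                        decrease_pct = acc$decrease_pct,
                        yearly_rate_thousand_km2 = acc$yearly_rate / 1000,
                        vu_year = acc$vu_year,
                        A1_Mkm2 = acc$A1 / 1e6, A2_Mkm2 = acc$A2 / 1e6,
                        A3_Mkm2 = acc$A3 / 1e6)
      utils::write.csv(out, file.path(config$out_dir,
                                      sprintf("accounts_%s.csv", rcp)),
                       row.names = FALSE)
    }
    summary_df <- summarize_accounts(accounts)
    utils::write.csv(summary_df, file.path(config$out_dir, "summary.csv"),
                     row.names = FALSE)

    risk <- NULL
    if (length(pressures)) {
      stage <- "risk"
      risk <- risk_matrix(accounts, pressures, limiting = limiting)
      utils::write.csv(risk, file.path(config$out_dir, "risk_matrix.csv"),
                       row.names = FALSE)
    }

    manifest <- list(seed = config$seed, vars = config$vars,
                     gcms = config$gcms, rcps = config$rcps,
                     ssp = config$ssp,
                     accounting = unclass(config$accounting),
                     n_records = nrow(set$records),
                     n_dropped = nrow(set$dropped))
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    list(accounts = accounts, summary = summary_df, pressures = pressures,
         risk = risk, drop_log = set$dropped, out_dir = config$out_dir)
  }, error = function(e) {
    writeLines(paste("FAILED at stage:", stage, "--", conditionMessage(e)),
               file.path(config$out_dir, "FAILED"))
    stop("pipeline failed at stage [", stage, "]: ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(res)
}

# limiting variables over envelope-edge cells: suitable cells in the lowest
# decile of positive scores
edge_limiting_vars <- function(model, stack, edge_quantile = 0.1) {
  vals <- vapply(model$vars, function(v) as.vector(stack$layers[[v]]),
                 numeric(stack$grid$n_rows * stack$grid$n_cols))
  s <- env_score(model, vals)
  pos <- which(!is.na(s) & s > 0)
  if (!length(pos)) return(character(0))
  edge <- pos[s[pos] <= stats::quantile(s[pos], edge_quantile)]
  if (!length(edge)) edge <- pos[which.min(s[pos])]
  env_limiting_variable(model, vals[edge, , drop = FALSE])
}
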