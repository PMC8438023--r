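#' Read an occurrence table
#'
#' CSV with a header row and at least \code{species,lon,lat} columns
#' (an optional \code{source} tag is carried along).
#'
#' @param path CSV file.
#' @return data.frame with columns \code{species}, \code{lon}, \code{lat},
#'   \code{source}.
#' @export
read_occurrences <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  need <- c("species", "lon", "lat")
  if (!all(need %in% names(df)))
    stop("occurrence tables need columns species,lon,lat; found: ",
         paste(names(df), collapse = ","))
  if (is.null(df$source)) df$source <- NA_character_
  df[c("species", "lon", "lat", "source")]
}

new_occurrence_set <- function(records, dropped) {
  rownames(records) <- NULL
  rownames(dropped) <- NULL
  structure(list(records = records, dropped = dropped),
            class = "occurrence_set")
}

#' @export
print.occurrence_set <- function(x, ...) {
  cat("occurrence_set: ", nrow(x$records), " records, ",
      length(unique(x$records$species)), " species, ",
      nrow(x$dropped), " dropped\n", sep = "")
  invisible(x)
}

as_records <- function(x) {
  if (inherits(x, "occurrence_set")) x$records else x
}

#' Clean occurrence records
#'
#' Mechanical curation with a full audit trail: unparseable rows, exact
#' (species, lon, lat) duplicates, points outside the study extent, and
#' points on non-land cells are removed; every removal is logged with a
#' reason code (\code{unparseable}, \code{duplicate}, \code{outside_extent},
#' \code{not_land}). Dropped + retained always equals the input count.
#'
#' @param records data.frame as from \code{\link{read_occurrences}}.
#' @param grid a \code{\link{study_grid}}; its \code{land_mask} (if any)
#'   defines which cells count as land.
#' @param min_n warn for species retained with fewer than this many records
#'   (small-sample envelopes are legitimate but fragile).
#' @return an \code{occurrence_set}: \code{records} (with \code{row},
#'   \code{col} cell indices) and \code{dropped} (records + \code{reason}).
#' @export
clean_occurrences <- function(records, grid, min_n = 20) {
  records <- as_records(records)
  if (is.null(records$source)) records$source <- NA_character_
  records <- records[c("species", "lon", "lat", "source")]
  n <- nrow(records)
  reason <- rep(NA_character_, n)

  bad <- is.na(records$lon) | is.na(records$lat) |
    is.na(records$species) | !nzchar(trimws(records$species)) |
    abs(records$lon) > 180 | abs(records$lat) > 90
  reason[bad] <- "unparseable"

  dup <- duplicated(records[c("species", "lon", "lat")]) & is.na(reason)
  reason[dup] <- "duplicate"

  loc <- cell_of(grid, records$lon, records$lat)
  out <- !loc$inside & is.na(reason)
  reason[out] <- "outside_extent"

  if (!is.null(grid$land_mask)) {
    onland <- rep(FALSE, n)
    ok <- loc$inside
    onland[ok] <- grid$land_mask[cbind(loc$row[ok], loc$col[ok])]
    water <- !onland & is.na(reason)
    reason[water] <- "not_land"
  }

  keep <- is.na(reason)
  kept <- records[keep, , drop = FALSE]
  kept$row <- loc$row[keep]
  kept$col <- loc$col[keep]
  dropped <- records[!keep, , drop = FALSE]
  dropped$reason <- reason[!keep]

  counts <- table(kept$species)
  lost <- setdiff(unique(records$species[!bad]), names(counts))
  if (length(lost))
    warning("species with no retained records: ", paste(lost, collapse = ", "))
  small <- names(counts)[counts < min_n]
  if (length(small))
    warning("species below ", min_n, " retained records: ",
            paste(sprintf("%s (n=%d)", small, as.integer(counts[small])),
                  collapse = ", "))
  new_occurrence_set(kept, dropped)
}

#' Thin occurrences to one record per grid cell
#'
#' The default spatial-bias filter: at most one record per species per grid
#' cell, the survivor being the first in input order (deterministic).
#' Thinning is idempotent.
#'
#' @param set an \code{occurrence_set} from \code{\link{clean_occurrences}}.
#' @param grid the \code{\link{study_grid}} (used if cell indices are absent).
#' @return an \code{occurrence_set}; removals are appended to the drop log
#'   with reason \code{thinned}.
#' @export
thin_to_grid <- function(set, grid) {
  rec <- as_records(set)
  if (is.null(rec$row) || is.null(rec$col)) {
    loc <- cell_of(grid, rec$lon, rec$lat)
    rec$row <- loc$row; rec$col <- loc$col
  }
  dup <- duplicated(rec[c("species", "row", "col")])
  dropped <- rec[dup, setdiff(names(rec), c("row", "col")), drop = FALSE]
  if (nrow(dropped)) dropped$reason <- "thinned"
  else dropped$reason <- character(0)
  prior <- if (inherits(set, "occurrence_set")) set$dropped else
    data.frame(species = character(0), lon = numeric(0), lat = numeric(0),
               source = character(0), reason = character(0))
  new_occurrence_set(rec[!dup, , drop = FALSE], rbind(prior, dropped))
}

#' Thin occurrences by a minimum great-circle distance
#'
#' Alternative to grid-cell thinning: greedily keeps a record only when it
#' lies at least \code{min_km} from every already-kept record of the same
#' species (haversine distance, first-seen order, deterministic).
#'
#' @param set an \code{occurrence_set} or data.frame of records.
#' @param min_km minimum pairwise distance in kilometres.
#' @return an \code{occurrence_set}.
#' @export
thin_by_distance <- function(set, min_km) {
  rec <- as_records(set)
  keep <- rep(TRUE, nrow(rec))
  for (sp in unique(rec$species)) {
    idx <- which(rec$species == sp)
    kept_idx <- integer(0)
    for (i in idx) {
      if (length(kept_idx) &&
          any(geosphere::distHaversine(
            c(rec$lon[i], rec$lat[i]),
            cbind(rec$lon[kept_idx], rec$lat[kept_idx])) / 1000 < min_km))
        keep[i] <- FALSE
      else kept_idx <- c(kept_idx, i)
    }
  }
  dropped <- rec[!keep, setdiff(names(rec), c("row", "col")), drop = FALSE]
  if (nrow(dropped)) dropped$reason <- "thinned_distance"
  else dropped$reason <- character(0)
  prior <- if (inherits(set, "occurrence_set")) set$dropped else
    data.frame(species = character(0), lon = numeric(0), lat = numeric(0),
               source = character(0), reason = character(0))
  new_occurrence_set(rec[keep, , drop = FALSE], rbind(prior, dropped))
}

#' Per-species record counts
#'
#' @param set an \code{occurrence_set} or data.frame of records.
#' @return data.frame with \code{species} and \code{n}, alphabetical;
#'   counts sum to the number of retained records.
#' @export
species_counts <- function(set) {
  rec <- as_records(set)
  if (nrow(rec) == 0)
    return(data.frame(species = character(0), n = integer(0)))
  tab <- table(rec$species)
  data.frame(species = names(tab), n = as.integer(tab),
             stringsAsFactors = FALSE)
}

#' Write the drop log of an occurrence set
#' @param set an \code{occurrence_set}.
#' @param path CSV output path.
#' @return the path, invisibly.
#' @export
write_drop_log <- function(set, path) {
  utils::write.csv(set$dropped, path, row.names = FALSE)
  invisible(path)
}
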