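#' GCM ensemble consensus
#'
#' Cellwise arithmetic mean of the per-GCM suitability grids for one
#' scenario. Missing members are ignored at each cell (so one model's
#' coastal gaps do not void the ensemble); a cell is missing only where
#' every member is. Because suitabilities are non-negative, the binarized
#' consensus equals the union of the members' envelopes.
#'
#' @param grids list of suitability matrices with identical geometry.
#' @param rule \code{"mean"} (default) or \code{"majority"} (cell suitable
#'   in more than half the non-missing members; sensitivity analyses only).
#' @return matrix; attribute \code{members} lists the GCMs when the inputs
#'   carry \code{gcm} attributes.
#' @export
consensus <- function(grids, rule = c("mean", "majority")) {
  rule <- match.arg(rule)
  stopifnot(length(grids) >= 1)
  d <- dim(grids[[1]])
  for (g in grids)
    if (!identical(dim(g), d))
      stop("consensus members disagree on geometry")
  arr <- array(unlist(grids, use.names = FALSE), dim = c(d, length(grids)))
  navail <- apply(!is.na(arr), c(1, 2), sum)
  if (rule == "mean") {
    tot <- apply(arr, c(1, 2), function(v) sum(v, na.rm = TRUE))
    out <- tot / navail
  } else {
    pos <- apply(arr > 0, c(1, 2), function(v) sum(v, na.rm = TRUE))
    out <- (pos > navail / 2) * 1
  }
  out[navail == 0] <- NA_real_
  members <- vapply(grids, function(g) attr(g, "gcm") %||% NA_character_, "")
  if (!anyNA(members)) attr(out, "members") <- members
  out
}

#' Overlay present and future envelopes into change zones
#'
#' Per-cell code \code{present + 2 * future}: 0 = never suitable, 1 = lost
#' (suitable now, unsuitable by the horizon year), 2 = gained (newly
#' suitable), 3 = stable. Codes partition the analysis cells.
#'
#' @param present,future 0/1 binary grids of identical geometry.
#' @return integer-coded matrix (\code{NA} where either input is missing).
#' @export
zone_overlay <- function(present, future) {
  if (!identical(dim(present), dim(future)))
    stop("present and future grids disagree on geometry")
  if (!all(present %in% c(0, 1, NA)) || !all(future %in% c(0, 1, NA)))
    stop("zone_overlay needs binarized (0/1) grids")
  present + 2 * future
}

#' Mask off inaccessible cells
#'
#' Suitable-but-unreachable climate space (ocean barriers, areas far from
#' the known range, mountain walls) is excluded before any accounting. The
#' mask is applied after zone overlay; the suitable area removed is reported
#' in the \code{masked_off} attribute (cell count of non-zero cells forced
#' to zero).
#'
#' @param x zone or binary grid (matrix).
#' @param mask logical matrix, \code{TRUE} = accessible. \code{NULL} is the
#'   identity.
#' @return the masked grid with attribute \code{masked_off}.
#' @export
apply_accessibility_mask <- function(x, mask) {
  if (is.null(mask)) {
    attr(x, "masked_off") <- 0L
    return(x)
  }
  if (!identical(dim(x), dim(mask)))
    stop("mask geometry does not match the grid")
  off <- !mask & !is.na(x) & x != 0
  x[!mask & !is.na(x)] <- 0
  attr(x, "masked_off") <- sum(off)
  x
}

#' Zone cell counts
#' @param zones zone-coded matrix from \code{\link{zone_overlay}}.
#' @return named integer vector of counts for codes 0--3.
#' @export
zone_counts <- function(zones) {
  stats::setNames(vapply(0:3, function(k) sum(zones == k, na.rm = TRUE),
                         integer(1)),
                  paste0("zone", 0:3))
}
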