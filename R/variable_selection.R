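#' Standardize a value matrix
#'
#' Column-wise z-scoring (mean 0, sample standard deviation 1), the usual
#' preparation before correlation screening and ordination of bioclim
#' variables measured in different units. Constant columns cannot be scaled;
#' they are set to zero and flagged in the \code{"constant_cols"} attribute.
#'
#' @param x numeric matrix (rows = observations) with at least two rows and
#'   no missing values.
#' @return the standardized matrix, with attribute \code{constant_cols}.
#' @export
zscore <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("z-scoring needs at least two rows")
  if (anyNA(x)) stop("z-scoring needs a complete matrix")
  mu <- colMeans(x)
  sdv <- apply(x, 2L, stats::sd)
  const <- sdv == 0
  sdv[const] <- 1
  z <- sweep(sweep(x, 2L, mu, "-"), 2L, sdv, "/")
  z[, const] <- 0
  attr(z, "constant_cols") <- colnames(x)[const] %||% which(const)
  z
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default collinearity priority rules
#'
#' When two bioclim variables are flagged as collinear, these rules decide
#' which one survives; they encode the study's manual choices among the
#' standard bioclim set: annual mean temperature (bio1) over the coldest
#' month/quarter extremes (bio6, bio11); temperature seasonality (bio4) over
#' the derived annual range (bio7); warmest-quarter mean (bio10) over
#' warmest-month max (bio5); annual precipitation (bio12) over
#' wettest-quarter precipitation (bio16); driest-quarter precipitation
#' (bio17) over driest-month (bio14). Pairs not covered by a rule fall back
#' to keeping the lower bioclim index.
#'
#' @return data.frame with integer columns \code{keep} and \code{drop}.
#' @export
default_priority_rules <- function() {
  data.frame(keep = c(1L, 1L, 4L, 10L, 12L, 17L),
             drop = c(6L, 11L, 7L, 5L, 16L, 14L))
}

var_index <- function(x) {
  nm <- colnames(x)
  if (is.null(nm)) return(seq_len(ncol(x)))
  idx <- suppressWarnings(as.integer(sub("^bio", "", nm)))
  if (anyNA(idx)) seq_len(ncol(x)) else idx
}

#' Filter collinear variables by pairwise Pearson correlation
#'
#' Greedy screening: all pairs with \code{|r| > threshold} are visited in
#' descending \code{|r|} (ties broken by variable index, so the result does
#' not depend on column order); if both members of a pair are still alive,
#' one is removed -- the one named by a priority rule when one applies,
#' otherwise the higher bioclim index. Every removal is logged with the
#' surviving partner and the correlation that triggered it.
#'
#' @param x value matrix (ideally standardized; Pearson correlation is
#'   scale-invariant either way), columns named \code{bio<k>}.
#' @param threshold remove one of any pair with \code{|r|} strictly above
#'   this (default 0.9).
#' @param priority_rules data.frame with \code{keep}/\code{drop} columns;
#'   see \code{\link{default_priority_rules}}.
#' @return a \code{selection_result}: \code{kept} (sorted indices),
#'   \code{removed} (data.frame var/partner/r), \code{cor_matrix}.
#' @export
correlation_filter <- function(x, threshold = 0.9,
                               priority_rules = default_priority_rules()) {
  stopifnot(threshold > 0, threshold <= 1)
  x <- as.matrix(x)
  idx <- var_index(x)
  cm <- stats::cor(x)
  cm[is.na(cm)] <- 0  # constant columns correlate with nothing
  dimnames(cm) <- list(paste0("bio", idx), paste0("bio", idx))

  pr <- which(abs(cm) > threshold & upper.tri(cm), arr.ind = TRUE)
  alive <- rep(TRUE, ncol(x))
  removed <- data.frame(var = integer(0), partner = integer(0), r = numeric(0))
  if (nrow(pr)) {
    a <- pmin(idx[pr[, 1]], idx[pr[, 2]])
    b <- pmax(idx[pr[, 1]], idx[pr[, 2]])
    r <- cm[pr]
    ord <- order(-abs(r), a, b)
    pos <- match(idx, idx)  # column position by variable index
    for (k in ord) {
      ia <- which(idx == a[k]); ib <- which(idx == b[k])
      if (!alive[ia] || !alive[ib]) next
      rule <- priority_rules[(priority_rules$keep == a[k] & priority_rules$drop == b[k]) |
                             (priority_rules$keep == b[k] & priority_rules$drop == a[k]), ]
      drop_var <- if (nrow(rule)) rule$drop[1] else max(a[k], b[k])
      keep_var <- if (drop_var == a[k]) b[k] else a[k]
      alive[which(idx == drop_var)] <- FALSE
      removed <- rbind(removed,
                       data.frame(var = drop_var, partner = keep_var, r = r[k]))
    }
  }
  structure(list(kept = sort(idx[alive]), removed = removed,
                 threshold = threshold, cor_matrix = cm),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("selection_result: kept ", length(x$kept), " variable(s) {",
      paste0("bio", x$kept, collapse = ", "), "}\n", sep = "")
  if (nrow(x$removed))
    cat("  removed: ",
        paste(sprintf("bio%d (|r|=%.3f with bio%d)", x$removed$var,
                      abs(x$removed$r), x$removed$partner), collapse = "; "),
        "\n", sep = "")
  invisible(x)
}

#' Save a selection result
#' @param result a \code{selection_result}.
#' @param csv_path decision log (one row per removed variable).
#' @param json_path kept set as JSON.
#' @return invisibly, the paths written.
#' @export
write_selection <- function(result, csv_path, json_path) {
  utils::write.csv(result$removed, csv_path, row.names = FALSE)
  jsonlite::write_json(list(kept = result$kept, threshold = result$threshold),
                       json_path, auto_unbox = TRUE)
  invisible(c(csv_path, json_path))
}

#' Principal-axes ordination of climate space
#'
#' Summarizes the occurrence-point climate matrix by principal components:
#' orthonormal loadings, non-increasing explained-variance fractions summing
#' to one, and per-point scores whose covariance is diagonal. The first two
#' components are the 2-D niche-space summary used to visualize clustering
#' of species into broad climate regimes (arid, insular, humid tropical).
#'
#' @param x standardized value matrix over the kept variables, at least
#'   three rows.
#' @return list with \code{loadings}, \code{explained} (fractions),
#'   \code{cumulative}, \code{scores}.
#' @export
ordination_summary <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 3) stop("ordination needs at least three observations")
  p <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  v <- p$sdev^2
  frac <- v / sum(v)
  list(loadings = p$rotation, explained = frac, cumulative = cumsum(frac),
       scores = p$x)
}
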