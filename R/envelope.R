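#' Fit a percentile climate envelope
#'
#' The BIOCLIM-style presence-only model: the training sample's empirical
#' distribution is stored per variable (as a sorted vector), and a probe is
#' scored by how central its value sits within each distribution. No
#' parameters are estimated; the model is the data.
#'
#' @param x training value matrix: one row per occurrence point, one column
#'   per (kept) bioclim variable, columns named \code{bio<k>}. At least two
#'   rows, no missing values.
#' @return an \code{envelope_model}: \code{vars} (column names),
#'   \code{n_train}, \code{values} (named list of ascending vectors, each of
#'   length \code{n_train}).
#' @export
env_fit <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("envelope fitting needs at least two training rows")
  if (anyNA(x)) stop("envelope fitting needs complete training data")
  if (is.null(colnames(x))) colnames(x) <- paste0("bio", seq_len(ncol(x)))
  values <- lapply(seq_len(ncol(x)), function(j) sort(x[, j]))
  names(values) <- colnames(x)
  structure(list(vars = colnames(x), n_train = nrow(x), values = values),
            class = "envelope_model")
}

#' @export
print.envelope_model <- function(x, ...) {
  cat("envelope_model: ", length(x$vars), " variable(s), n_train = ",
      x$n_train, "\n", sep = "")
  invisible(x)
}

#' Tie-aware empirical percentile
#'
#' \code{p = (# training < x + 0.5 * # training = x) / n_train}. The
#' half-weight on ties guarantees every training value has \code{p >= 0.5/n},
#' strictly inside (0, 1), so sampled climates are never scored as
#' unsuitable. Values strictly outside the training range get 0 or 1.
#'
#' @param model an \code{envelope_model}.
#' @param variable variable name (\code{"bio4"}) or index into
#'   \code{model$vars}.
#' @param x numeric vector of probe values.
#' @return percentiles in [0, 1].
#' @export
env_percentile <- function(model, variable, x) {
  v <- model$values[[variable]]
  if (is.null(v)) stop("unknown variable: ", variable)
  n_le <- findInterval(x, v)
  n_lt <- findInterval(x, v, left.open = TRUE)
  (n_lt + 0.5 * (n_le - n_lt)) / model$n_train
}

#' Score probes against the envelope
#'
#' Per variable the percentile is folded around the median,
#' \code{f = 2 * min(p, 1 - p)}, and the suitability is the minimum of the
#' folded scores across variables: 1 only where every variable sits at its
#' training median, 0 wherever any variable falls strictly outside the
#' training range. Rows with a missing variable score \code{NA}.
#'
#' @param model an \code{envelope_model}.
#' @param newdata matrix or data.frame providing every model variable
#'   (extra columns ignored).
#' @return numeric vector of suitabilities in [0, 1].
#' @export
env_score <- function(model, newdata) {
  newdata <- as.matrix(newdata)
  if (!all(model$vars %in% colnames(newdata)))
    stop("newdata is missing model variable(s): ",
         paste(setdiff(model$vars, colnames(newdata)), collapse = ", "))
  s <- rep(Inf, nrow(newdata))
  for (v in model$vars) {
    p <- env_percentile(model, v, newdata[, v])
    s <- pmin(s, 2 * pmin(p, 1 - p))
  }
  s[apply(is.na(newdata[, model$vars, drop = FALSE]), 1L, any)] <- NA_real_
  s
}

#' Which variable limits the envelope score
#'
#' For each probe row, the variable attaining the minimal folded score (ties
#' broken by model variable order). Used by the risk assessment to decide
#' whether temperature or precipitation constrains a species at the edge of
#' its envelope.
#'
#' @inheritParams env_score
#' @return character vector of variable names (\code{NA} for missing rows).
#' @export
env_limiting_variable <- function(model, newdata) {
  newdata <- as.matrix(newdata)
  f <- sapply(model$vars, function(v) {
    p <- env_percentile(model, v, newdata[, v])
    2 * pmin(p, 1 - p)
  })
  f <- matrix(f, ncol = length(model$vars),
              dimnames = list(NULL, model$vars))
  out <- model$vars[apply(f, 1L, which.min)]
  out[apply(is.na(f), 1L, any)] <- NA_character_
  out
}

#' Predict a suitability grid from a climate stack
#'
#' Applies the envelope cell by cell over the stack; cells with any missing
#' model layer are missing in the output.
#'
#' @param object an \code{envelope_model}.
#' @param stack a \code{climate_stack} providing every model variable.
#' @param ... unused.
#' @return matrix of suitabilities on the grid geometry, with attributes
#'   \code{scenario} and \code{gcm} copied from the stack.
#' @export
predict.envelope_model <- function(object, stack, ...) {
  miss <- setdiff(object$vars, names(stack$layers))
  if (length(miss))
    stop("stack lacks model layer(s): ", paste(miss, collapse = ", "))
  vals <- vapply(object$vars, function(v) as.vector(stack$layers[[v]]),
                 numeric(stack$grid$n_rows * stack$grid$n_cols))
  s <- env_score(object, vals)
  out <- matrix(s, nrow = stack$grid$n_rows, ncol = stack$grid$n_cols)
  attr(out, "scenario") <- stack$scenario
  attr(out, "gcm") <- stack$gcm
  out
}

#' Threshold suitability at zero
#'
#' A cell is suitable (1) iff its score is strictly positive, i.e. strictly
#' inside the training range on every variable (training extremes included
#' via the tie-aware percentile); missing stays missing.
#'
#' @param x suitability grid (matrix) or vector.
#' @return 0/1 object of the same shape, \code{NA} preserved.
#' @export
binarize <- function(x) {
  out <- (x > 0) * 1
  out
}

#' Serialize / restore an envelope model as JSON
#'
#' The sorted training vectors are written in full so a model round-trips
#' exactly.
#'
#' @param model an \code{envelope_model}.
#' @param path JSON file path.
#' @return \code{env_write}: the path, invisibly; \code{env_read}: the model.
#' @export
env_write <- function(model, path) {
  jsonlite::write_json(list(vars = model$vars, n_train = model$n_train,
                            values = model$values),
                       path, digits = I(17), auto_unbox = FALSE)
  invisible(path)
}

#' @rdname env_write
#' @export
env_read <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(vars = obj$vars, n_train = as.integer(obj$n_train),
                 values = lapply(obj$values, as.numeric)),
            class = "envelope_model")
}
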