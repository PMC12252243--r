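#' Composite production index
#'
#' The multifunctionality-style composite quality score: each quality
#' parameter is z-scored across samples (sample standard deviation, `n - 1`
#' denominator) and each sample's index is the arithmetic mean of its
#' z-scores. Parameters therefore contribute on a common scale regardless of
#' units, and the index is invariant to rescaling any parameter by a
#' positive constant.
#'
#' All parameters enter with positive orientation by default; pass `signs`
#' to flip parameters where a larger raw value means worse quality.
#'
#' @param quality data.frame with `sample_id` plus numeric parameters (a
#'   `community_dataset` is also accepted), or a plain numeric matrix.
#' @param signs optional named vector of +1/-1 per parameter.
#' @return List of class `production_index`: `index` (named per-sample
#'   vector), `zscores` (samples x parameters matrix), `dropped`
#'   (zero-variance parameters excluded).
#' @export
production_index <- function(quality, signs = NULL) {
  if (inherits(quality, "community_dataset")) quality <- quality$quality
  if (is.null(quality)) stop("no quality table", call. = FALSE)
  if (is.data.frame(quality) && "sample_id" %in% names(quality)) {
    ids <- quality$sample_id
    mat <- as.matrix(quality[, setdiff(names(quality), "sample_id"),
                             drop = FALSE])
    rownames(mat) <- ids
  } else {
    mat <- as.matrix(quality)
  }
  if (nrow(mat) < 2)
    stop("need at least 2 samples (sd undefined otherwise)", call. = FALSE)
  if (ncol(mat) < 1) stop("need at least 1 parameter", call. = FALSE)
  if (!is.null(signs)) {
    s <- signs[colnames(mat)]
    s[is.na(s)] <- 1
    mat <- sweep(mat, 2, s, `*`)
  }
  sds <- apply(mat, 2, stats::sd)
  dropped <- colnames(mat)[sds == 0]
  if (length(dropped)) {
    warning("zero-variance parameters excluded: ",
            paste(dropped, collapse = ", "), call. = FALSE)
    mat <- mat[, sds > 0, drop = FALSE]
  }
  if (ncol(mat) == 0) {
    # every parameter constant: all z-scores are zero by convention
    z <- matrix(0, nrow(mat), 0, dimnames = list(rownames(mat), NULL))
    idx <- stats::setNames(rep(0, nrow(mat)), rownames(mat))
  } else {
    z <- scale(mat)
    attr(z, "scaled:center") <- attr(z, "scaled:scale") <- NULL
    idx <- rowMeans(z)
  }
  structure(list(index = idx, zscores = z, dropped = dropped),
            class = "production_index")
}

#' Simple linear regression of the production index on a predictor
#'
#' Ordinary least squares with a two-sided t-test on the slope; used to
#' relate the composite quality index to community diversity (an alpha
#' index) or composition (a principal-coordinate axis).
#'
#' @param index numeric response (e.g. `production_index(...)$index`).
#' @param predictor numeric predictor of the same length.
#' @return List with `slope`, `intercept`, `r_squared`, `p_value`, `n`.
#' @export
index_regression <- function(index, predictor) {
  if (inherits(index, "production_index")) index <- index$index
  ok <- is.finite(index) & is.finite(predictor)
  y <- index[ok]
  x <- predictor[ok]
  if (length(y) < 3) stop("need at least 3 finite observations", call. = FALSE)
  if (stats::sd(x) == 0) stop("zero-variance predictor", call. = FALSE)
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = sm$r.squared,
       p_value = sm$coefficients[2, 4],
       n = length(y))
}
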