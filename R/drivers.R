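#' Constrained ordination of a response matrix on predictors
#'
#' The redundancy-analysis core: multivariate least squares of the response
#' on standardized predictors followed by eigen-analysis of the fitted
#' values. The constrained proportion is the fraction of total response
#' variance captured by the fit; significance comes from seeded permutations
#' of the predictor rows.
#'
#' @param response numeric matrix, samples x response variables.
#' @param predictors data.frame or matrix of numeric predictors, same rows.
#' @param n_perm permutations for the significance test.
#' @param seed integer seed.
#' @return List with `constrained_proportion`, `sample_scores`,
#'   `biplot_scores`, `p_value`, `n_perm`.
#' @export
constrained_ordination <- function(response, predictors, n_perm = 999,
                                   seed = NULL) {
  Y <- as.matrix(response)
  X <- as.data.frame(predictors)
  if (ncol(X) < 2) stop("need at least 2 predictor variables", call. = FALSE)
  if (nrow(Y) != nrow(X)) stop("row mismatch", call. = FALSE)
  if (nrow(Y) <= ncol(X))
    stop("need more samples than predictors", call. = FALSE)
  const <- names(X)[vapply(X, function(v) stats::sd(v) == 0, logical(1))]
  if (length(const))
    stop("constant predictors: ", paste(const, collapse = ", "),
         call. = FALSE)
  Xs <- scale(as.matrix(X))
  qrX <- qr(cbind(1, Xs))
  if (qrX$rank < ncol(Xs) + 1) {
    dep <- colnames(Xs)[qrX$pivot[-seq_len(qrX$rank)] - 1]
    stop("rank-deficient predictors; dependent columns: ",
         paste(dep, collapse = ", "), call. = FALSE)
  }
  Xs_df <- as.data.frame(Xs)
  mod <- vegan::rda(Y ~ ., data = Xs_df)
  pval <- with_seed(seed, {
    an <- vegan::anova.cca(mod, permutations = n_perm)
    an$`Pr(>F)`[1]
  })
  list(constrained_proportion =
         unname(mod$CCA$tot.chi / mod$tot.chi),
       sample_scores = vegan::scores(mod, display = "sites",
                                     choices = seq_len(min(2, mod$CCA$rank))),
       biplot_scores = vegan::scores(mod, display = "bp",
                                     choices = seq_len(min(2, mod$CCA$rank))),
       p_value = pval, n_perm = n_perm)
}

#' Redundancy analysis of the community on soil variables
#'
#' Links soil environmental variables to community variation: the community
#' table is converted to Hellinger-transformed relative abundances (square
#' root of relative abundance, the standard transform that makes abundance
#' data suitable for a Euclidean-metric ordination), predictors are
#' standardized, and [constrained_ordination()] is run.
#'
#' @param ds a `community_dataset` with a soil table.
#' @param soil_vars which soil variables to use (default: all).
#' @inheritParams constrained_ordination
#' @return See [constrained_ordination()].
#' @export
rda_drivers <- function(ds, soil_vars = NULL, n_perm = 999, seed = NULL) {
  if (is.null(ds$soil)) stop("no soil table", call. = FALSE)
  soil <- ds$soil[match(rownames(ds$counts), ds$soil$sample_id), ,
                  drop = FALSE]
  vars <- soil_vars %||% setdiff(names(soil), "sample_id")
  X <- soil[, vars, drop = FALSE]
  if (anyNA(X)) stop("soil variables incomplete", call. = FALSE)
  Y <- vegan::decostand(as_relative_abundance(ds$counts), "hellinger")
  constrained_ordination(Y, X, n_perm = n_perm, seed = seed)
}

#' Random-forest ranking of soil drivers
#'
#' Fits a regression forest of a per-sample community response (by default
#' the first principal coordinate of the Bray-Curtis matrix, the axis that
#' separates cultivation modes) on the soil variables, and ranks variables
#' by out-of-bag permutation importance. The out-of-bag R-squared is the
#' honest fit score.
#'
#' @param soil data.frame with `sample_id` plus numeric soil variables, or a
#'   `community_dataset` (then `response` defaults to PCo1).
#' @param response per-sample numeric response aligned to the soil rows;
#'   required when `soil` is a plain table.
#' @param seed integer seed (forest bootstrap and permutation importance).
#' @param n_tree number of trees.
#' @return List of class `driver_ranking`: `importance` (named, descending
#'   permutation importance), `fit_score` (out-of-bag R-squared),
#'   `response`.
#' @export
rf_drivers <- function(soil, response = NULL, seed = NULL, n_tree = 500) {
  if (inherits(soil, "community_dataset")) {
    ds <- soil
    if (is.null(ds$soil)) stop("no soil table", call. = FALSE)
    soil <- ds$soil[match(rownames(ds$counts), ds$soil$sample_id), ,
                    drop = FALSE]
    if (is.null(response)) {
      ord <- pcoa_ordination(bray_curtis(ds))
      response <- ord$coordinates[, 1]
    }
  }
  if (is.null(response)) stop("a response is required", call. = FALSE)
  X <- soil[, setdiff(names(soil), "sample_id"), drop = FALSE]
  if (nrow(X) < 10) stop("need at least 10 samples", call. = FALSE)
  if (length(response) != nrow(X)) stop("row mismatch", call. = FALSE)
  if (stats::sd(response) == 0) stop("constant response", call. = FALSE)
  rf <- with_seed(seed,
    randomForest::randomForest(x = X, y = response, ntree = n_tree,
                               importance = TRUE))
  imp <- randomForest::importance(rf, type = 1, scale = FALSE)[, 1]
  structure(list(importance = sort(imp, decreasing = TRUE),
                 fit_score = rf$rsq[length(rf$rsq)],
                 response = response),
            class = "driver_ranking")
}
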