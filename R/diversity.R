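#' Per-sample alpha diversity
#'
#' Computes one of four alpha-diversity indices per sample: `chao1`
#' (richness estimate from singleton/doubleton counts), `shannon` (entropy,
#' natural log), `pielou` (evenness, Shannon over its maximum `ln S`) and
#' `faith_pd` (total branch length of the rooted subtree spanning the
#' sample's ASVs, root path included).
#'
#' Chao1 uses the bias-corrected form `S_obs + F1(F1-1)/(2(F2+1))`, which
#' stays defined when no doubletons are observed. Pielou is undefined for
#' samples with fewer than two taxa and is returned as `NA` with a warning.
#'
#' @param ds a `community_dataset`. `faith_pd` requires `ds$tree` with every
#'   present ASV as a tip.
#' @param metric one of `"chao1"`, `"shannon"`, `"pielou"`, `"faith_pd"`.
#' @return Named numeric vector, one value per sample.
#' @export
alpha_diversity <- function(ds, metric = c("chao1", "shannon", "pielou",
                                           "faith_pd")) {
  metric <- match.arg(metric)
  counts <- ds$counts
  switch(metric,
    chao1 = apply(counts, 1, function(x) {
      s_obs <- sum(x > 0)
      f1 <- sum(x == 1)
      f2 <- sum(x == 2)
      s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
    }),
    shannon = vegan::diversity(counts, index = "shannon"),
    pielou = {
      h <- vegan::diversity(counts, index = "shannon")
      s <- rowSums(counts > 0)
      if (any(s <= 1))
        warning("Pielou evenness undefined for samples with richness <= 1: ",
                paste(rownames(counts)[s <= 1], collapse = ", "),
                call. = FALSE)
      ifelse(s > 1, h / log(s), NA_real_)
    },
    faith_pd = {
      if (is.null(ds$tree)) stop("faith_pd requires a tree", call. = FALSE)
      present <- colnames(counts)[colSums(counts) > 0]
      missing <- setdiff(present, ds$tree$tip.label)
      if (length(missing))
        stop("ASVs absent from the tree: ",
             paste(missing, collapse = ", "), call. = FALSE)
      pd <- picante::pd(counts, ds$tree, include.root = TRUE)
      stats::setNames(pd$PD, rownames(counts))
    })
}

#' Alpha-diversity table for all four indices
#' @inheritParams alpha_diversity
#' @return data.frame with `sample_id` and one column per index (`faith_pd`
#'   only when a tree is available).
#' @export
alpha_diversity_table <- function(ds) {
  metrics <- c("chao1", "shannon", "pielou")
  if (!is.null(ds$tree)) metrics <- c(metrics, "faith_pd")
  out <- data.frame(sample_id = rownames(ds$counts))
  for (m in metrics) out[[m]] <- unname(alpha_diversity(ds, m))
  out
}

#' Bray-Curtis dissimilarity matrix
#'
#' `BC(x, y) = 1 - 2 * sum(min(x_k, y_k)) / (sum(x) + sum(y))` on the count
#' table; 0 for identical samples, 1 for samples sharing no taxa.
#'
#' @param ds a `community_dataset` (or a plain samples-by-taxa matrix).
#' @return Symmetric numeric matrix with zero diagonal and sample dimnames.
#' @export
bray_curtis <- function(ds) {
  counts <- if (inherits(ds, "community_dataset")) ds$counts else as.matrix(ds)
  if (nrow(counts) < 2) stop("need at least 2 samples", call. = FALSE)
  zero <- rowSums(counts) == 0
  if (any(zero))
    stop("all-zero samples: ", paste(rownames(counts)[zero], collapse = ", "),
         call. = FALSE)
  as.matrix(vegan::vegdist(counts, method = "bray"))
}

#' Principal coordinate analysis
#'
#' Metric embedding of a distance matrix: Gower double-centering of
#' `-d^2/2`, eigendecomposition, coordinates scaled to `sqrt(eigenvalue)` on
#' the positive axes. Negative eigenvalues (non-Euclidean input) are reported
#' but their axes are omitted from the coordinates; no Lingoes/Cailliez
#' correction is applied.
#'
#' @param dm symmetric distance matrix with dimnames.
#' @return List with `coordinates` (samples x positive axes), `eigenvalues`
#'   (all, descending) and `proportion_explained` (positive axes over the sum
#'   of positive eigenvalues).
#' @export
pcoa_ordination <- function(dm) {
  dm <- as.matrix(dm)
  n <- nrow(dm)
  if (n < 2) stop("need at least 2 samples", call. = FALSE)
  fit <- suppressWarnings(
    stats::cmdscale(stats::as.dist(dm), k = n - 1, eig = TRUE))
  eig <- fit$eig
  pos <- which(eig > sqrt(.Machine$double.eps) * max(abs(eig)))
  coords <- fit$points[, seq_along(pos), drop = FALSE]
  colnames(coords) <- paste0("PCo", seq_along(pos))
  rownames(coords) <- rownames(dm)
  if (any(eig < 0))
    message("PCoA: ", sum(eig < 0),
            " negative eigenvalue(s) reported, axes omitted (no correction)")
  list(coordinates = coords,
       eigenvalues = eig,
       proportion_explained = eig[pos] / sum(eig[pos]))
}

#' One-way PERMANOVA
#'
#' Permutational multivariate analysis of variance on a distance matrix
#' (Anderson's pseudo-F from the among/within partition of squared
#' distances), with an unrestricted, seeded label permutation test:
#' `p = (1 + #(F_perm >= F_obs)) / (1 + n_perm)`.
#'
#' @param dm symmetric distance matrix with sample dimnames.
#' @param labels group label per sample, aligned to `dm` rows (names used if
#'   present).
#' @param n_perm number of permutations.
#' @param seed integer seed for the permutation stream.
#' @return List with `pseudo_F`, `R2`, `p_value`, `n_perm`.
#' @export
permanova <- function(dm, labels, n_perm = 999, seed = NULL) {
  dm <- as.matrix(dm)
  labels <- as.character(labels)
  if (length(labels) != nrow(dm))
    stop("labels must match the distance matrix rows", call. = FALSE)
  sizes <- table(labels)
  if (length(sizes) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(sizes < 2))
    stop("groups with a single sample: ",
         paste(names(sizes)[sizes < 2], collapse = ", "), call. = FALSE)
  df <- data.frame(g = labels)
  fit <- with_seed(seed,
    vegan::adonis2(stats::as.dist(dm) ~ g, data = df,
                   permutations = n_perm))
  list(pseudo_F = fit$F[1], R2 = fit$R2[1], p_value = fit$`Pr(>F)`[1],
       n_perm = n_perm)
}

#' Tukey-style pairwise group comparison
#'
#' One-way ANOVA mean-square error with studentized-range adjusted p-values
#' per group pair (Tukey-Kramer harmonic-mean n for unbalanced designs).
#'
#' @param values numeric vector of observations.
#' @param labels group label per observation (>= 2 groups, each n >= 2).
#' @return data.frame with columns `pair`, `difference`, `lwr`, `upr`,
#'   `p_adj`.
#' @export
tukey_groups <- function(values, labels) {
  labels <- as.character(labels)
  ok <- is.finite(values)
  if (!all(ok)) {
    values <- values[ok]
    labels <- labels[ok]
  }
  sizes <- table(labels)
  if (length(sizes) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(sizes < 2))
    stop("groups with fewer than 2 observations: ",
         paste(names(sizes)[sizes < 2], collapse = ", "), call. = FALSE)
  g <- factor(labels)
  fit <- stats::aov(values ~ g)
  mse <- summary(fit)[[1]]["Residuals", "Mean Sq"]
  if (!is.finite(mse) || mse <= .Machine$double.eps * stats::var(values) ||
      isTRUE(all.equal(mse, 0))) {
    # degenerate: no within-group variance anywhere
    warning("zero within-group variance; degenerate Tukey comparison",
            call. = FALSE)
    means <- tapply(values, g, mean)
    pr <- utils::combn(levels(g), 2)
    diffs <- means[pr[2, ]] - means[pr[1, ]]
    return(data.frame(pair = paste(pr[2, ], pr[1, ], sep = "-"),
                      difference = as.numeric(diffs),
                      lwr = as.numeric(diffs), upr = as.numeric(diffs),
                      p_adj = ifelse(diffs == 0, 1, 0)))
  }
  tk <- stats::TukeyHSD(fit)$g
  data.frame(pair = rownames(tk), difference = tk[, "diff"],
             lwr = tk[, "lwr"], upr = tk[, "upr"], p_adj = tk[, "p adj"],
             row.names = NULL)
}

#' Within-group pairwise distances
#'
#' Extracts, per group, all off-diagonal distances among that group's
#' samples -- the within-group dispersion values fed to [tukey_groups()] to
#' compare community variability between cultivation modes.
#'
#' @param dm symmetric distance matrix with sample dimnames.
#' @param labels group label per sample, aligned to `dm` rows.
#' @return Named list of numeric vectors, one per group with >= 2 samples;
#'   size-1 groups are excluded with a warning.
#' @export
within_group_distances <- function(dm, labels) {
  dm <- as.matrix(dm)
  labels <- as.character(labels)
  if (length(labels) != nrow(dm))
    stop("labels must match the distance matrix rows", call. = FALSE)
  out <- list()
  for (grp in unique(labels)) {
    idx <- which(labels == grp)
    if (length(idx) < 2) {
      warning("group '", grp, "' has a single sample; excluded", call. = FALSE)
      next
    }
    sub <- dm[idx, idx]
    out[[grp]] <- sub[upper.tri(sub)]
  }
  out
}
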