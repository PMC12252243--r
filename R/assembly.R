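#' Patristic distances between tree tips
#'
#' Sum of branch lengths along the tree path between every pair of tips.
#'
#' @param tree a `phylo` object with branch lengths.
#' @return Symmetric taxon-by-taxon matrix with zero diagonal.
#' @export
patristic_distances <- function(tree) {
  if (anyDuplicated(tree$tip.label))
    stop("tree has duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "), call. = FALSE)
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths", call. = FALSE)
  ape::cophenetic.phylo(tree)
}

# Core betaMNTD kernel. P: samples x taxa weight matrix whose rows sum to 1
# over present taxa; D: taxa x taxa phylogenetic distances aligned to P's
# columns. For each sample pair the mean (over both directions) of each
# taxon's weighted distance to its nearest taxon in the other sample.
bmntd_kernel <- function(P, D, present_idx = NULL) {
  n <- nrow(P)
  if (is.null(present_idx))
    present_idx <- lapply(seq_len(n), function(i) which(P[i, ] > 0))
  out <- matrix(0, n, n, dimnames = list(rownames(P), rownames(P)))
  for (a in seq_len(n - 1L)) {
    ia <- present_idx[[a]]
    wa <- P[a, ia]
    for (b in (a + 1L):n) {
      ib <- present_idx[[b]]
      sub <- D[ia, ib, drop = FALSE]
      v <- 0.5 * (sum(wa * row_mins(sub)) +
                  sum(P[b, ib] * row_mins(t(sub))))
      out[a, b] <- out[b, a] <- v
    }
  }
  out
}

#' Between-community mean nearest taxon distance (betaMNTD)
#'
#' For each sample pair, the abundance-weighted mean of every taxon's
#' phylogenetic distance to its closest relative in the paired sample,
#' averaged over both directions:
#' `0.5 * (sum_i f_i min_j d(i,j) + sum_j f_j min_i d(j,i))` with `f` the
#' relative abundances. The unweighted variant replaces `f` by `1/S`.
#' Identical samples score zero (each taxon's nearest neighbour is itself).
#'
#' @param ds a `community_dataset`, or a samples-by-taxa count matrix.
#' @param pd_matrix taxon-by-taxon patristic distance matrix covering every
#'   present taxon; computed from `ds$tree` when omitted.
#' @param weighted use relative abundances (default) or presence weights.
#' @return Symmetric sample-by-sample matrix.
#' @export
beta_mntd <- function(ds, pd_matrix = NULL, weighted = TRUE) {
  counts <- if (inherits(ds, "community_dataset")) ds$counts else as.matrix(ds)
  if (is.null(pd_matrix)) {
    if (!inherits(ds, "community_dataset") || is.null(ds$tree))
      stop("pd_matrix required when no tree is available", call. = FALSE)
    pd_matrix <- patristic_distances(ds$tree)
  }
  if (any(rowSums(counts) == 0))
    stop("empty samples: ",
         paste(rownames(counts)[rowSums(counts) == 0], collapse = ", "),
         call. = FALSE)
  present <- colnames(counts)[colSums(counts) > 0]
  missing <- setdiff(present, rownames(pd_matrix))
  if (length(missing))
    stop("taxa absent from the distance matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  counts <- counts[, present, drop = FALSE]
  D <- pd_matrix[present, present, drop = FALSE]
  P <- if (weighted) as_relative_abundance(counts) else {
    pres <- (counts > 0) * 1
    pres / rowSums(pres)
  }
  bmntd_kernel(P, D)
}

#' Beta nearest taxon index (betaNTI)
#'
#' Standardized effect size of betaMNTD against a null distribution obtained
#' by shuffling tip labels across the whole phylogeny (`n_null` independent
#' shuffles; the community matrix is untouched):
#' `betaNTI = (observed - mean_null) / sd_null` per sample pair.
#' `|betaNTI| > 2` is conventionally read as deterministic selection
#' (positive: heterogeneous, negative: homogeneous selection). Pairs whose
#' null distribution has zero spread (e.g. a star phylogeny) are undefined
#' and returned as `NA`.
#'
#' @param ds a `community_dataset` with a tree, or a count matrix (then
#'   `tree` is required).
#' @param tree optional `phylo` overriding `ds$tree`.
#' @param n_null number of tip-shuffle null draws.
#' @param seed integer seed; fixed seed gives bit-identical output.
#' @param weighted abundance-weighted betaMNTD (default) or unweighted.
#' @return List of class `beta_nti_result`: `beta_mntd` (observed matrix),
#'   `null_mean`, `null_sd`, `beta_nti` (matrices, `NA` diagonal and `NA`
#'   where undefined), `n_null`.
#' @export
beta_nti <- function(ds, tree = NULL, n_null = 999, seed = NULL,
                     weighted = TRUE) {
  stop_if_not_scalar_count(n_null, "n_null", min = 1)
  counts <- if (inherits(ds, "community_dataset")) ds$counts else as.matrix(ds)
  tree <- tree %||% (if (inherits(ds, "community_dataset")) ds$tree)
  if (is.null(tree)) stop("a tree is required", call. = FALSE)
  D_full <- patristic_distances(tree)
  present <- colnames(counts)[colSums(counts) > 0]
  missing <- setdiff(present, rownames(D_full))
  if (length(missing))
    stop("taxa absent from the tree: ", paste(missing, collapse = ", "),
         call. = FALSE)
  counts <- counts[, present, drop = FALSE]
  D <- D_full[present, present, drop = FALSE]
  P <- if (weighted) as_relative_abundance(counts) else {
    pres <- (counts > 0) * 1
    pres / rowSums(pres)
  }
  present_idx <- lapply(seq_len(nrow(P)), function(i) which(P[i, ] > 0))
  obs <- bmntd_kernel(P, D, present_idx)

  n <- nrow(P)
  pairs <- pair_index(n)
  null_vals <- matrix(NA_real_, nrow(pairs), n_null)
  m <- ncol(P)
  with_seed(seed, {
    for (k in seq_len(n_null)) {
      perm <- sample.int(m)
      Dk <- D[perm, perm, drop = FALSE]  # tip-label shuffle
      nk <- bmntd_kernel(P, Dk, present_idx)
      null_vals[, k] <- nk[pairs]
    }
  })
  null_mean_v <- rowMeans(null_vals)
  null_sd_v <- apply(null_vals, 1, stats::sd)

  to_mat <- function(v) {
    mmat <- matrix(NA_real_, n, n, dimnames = dimnames(obs))
    mmat[pairs] <- v
    mmat[pairs[, c(2, 1), drop = FALSE]] <- v
    mmat
  }
  bnti_v <- ifelse(null_sd_v > 0, (obs[pairs] - null_mean_v) / null_sd_v,
                   NA_real_)
  structure(list(beta_mntd = obs, null_mean = to_mat(null_mean_v),
                 null_sd = to_mat(null_sd_v), beta_nti = to_mat(bnti_v),
                 n_null = n_null),
            class = "beta_nti_result")
}

# one null draw of a community: S taxa sampled without replacement with
# probability ~ occurrence frequency, each seeded with one individual, the
# remaining N - S individuals multinomial ~ regional relative abundance
rc_null_sample <- function(S, N, freq_w, abund_w, m) {
  taxa <- sample.int(m, S, replace = FALSE, prob = freq_w)
  x <- numeric(m)
  x[taxa] <- 1
  if (N > S) {
    w <- abund_w[taxa]
    if (sum(w) <= 0) w <- rep(1, S)
    x[taxa] <- x[taxa] + stats::rmultinom(1, N - S, prob = w)[, 1]
  }
  x
}

#' Abundance-based Raup-Crick metric (RC-bray)
#'
#' Null-model standardized Bray-Curtis dissimilarity. For each sample pair,
#' `n_null` null community pairs are assembled preserving each sample's
#' observed richness and total count: taxa are drawn without replacement with
#' probability proportional to their occurrence frequency across samples,
#' then individuals are assigned to the drawn taxa with probability
#' proportional to their total relative abundance (each drawn taxon keeps at
#' least one individual so richness is preserved). With
#' `RC_raw = (#(BC_null < BC_obs) + 0.5 #(BC_null = BC_obs)) / n_null`,
#' the reported `RC = 2 (RC_raw - 0.5)` lies in `[-1, 1]`: values near +1
#' mean the observed turnover exceeds the null (dispersal limitation), near
#' -1 that communities are more similar than the null (homogenizing
#' dispersal).
#'
#' @param ds a `community_dataset` or count matrix.
#' @param n_null number of null assemblies per pair.
#' @param seed integer seed.
#' @return Symmetric sample-by-sample matrix of RC values, `NA` diagonal.
#' @export
raup_crick <- function(ds, n_null = 999, seed = NULL) {
  stop_if_not_scalar_count(n_null, "n_null", min = 1)
  counts <- if (inherits(ds, "community_dataset")) ds$counts else as.matrix(ds)
  n <- nrow(counts)
  if (n < 2) stop("need at least 2 samples", call. = FALSE)
  if (any(rowSums(counts) == 0))
    stop("empty samples: ",
         paste(rownames(counts)[rowSums(counts) == 0], collapse = ", "),
         call. = FALSE)
  m <- ncol(counts)
  freq_w <- colSums(counts > 0)          # occurrence frequency
  abund_w <- colSums(as_relative_abundance(counts))  # regional abundance
  freq_w[freq_w == 0] <- .Machine$double.eps  # absent taxa never drawn first
  S <- rowSums(counts > 0)
  N <- round(rowSums(counts))
  obs_bc <- as.matrix(vegan::vegdist(counts, method = "bray"))

  pairs <- pair_index(n)
  rc_v <- numeric(nrow(pairs))
  bc_pair <- function(x, y) {
    1 - 2 * sum(pmin(x, y)) / (sum(x) + sum(y))
  }
  with_seed(seed, {
    for (p in seq_len(nrow(pairs))) {
      a <- pairs[p, 1]; b <- pairs[p, 2]
      obs <- obs_bc[a, b]
      less <- 0; equal <- 0
      for (k in seq_len(n_null)) {
        xa <- rc_null_sample(S[a], N[a], freq_w, abund_w, m)
        xb <- rc_null_sample(S[b], N[b], freq_w, abund_w, m)
        bc <- bc_pair(xa, xb)
        if (bc < obs) less <- less + 1
        else if (bc == obs) equal <- equal + 1
      }
      rc_v[p] <- 2 * ((less + 0.5 * equal) / n_null - 0.5)
    }
  })
  out <- matrix(NA_real_, n, n, dimnames = list(rownames(counts),
                                                rownames(counts)))
  out[pairs] <- rc_v
  out[pairs[, c(2, 1), drop = FALSE]] <- rc_v
  out
}

#' Partition community assembly into five ecological processes
#'
#' Classifies each sample pair by the standard two-step rule: `betaNTI > 2`
#' heterogeneous selection; `betaNTI < -2` homogeneous selection; otherwise
#' (phylogenetically stochastic pairs) `RC > 0.95` dispersal limitation,
#' `RC < -0.95` homogenizing dispersal, `|RC| <= 0.95` drift. Pairs with
#' undefined betaNTI are excluded from the fractions and tallied separately.
#'
#' @param bnti betaNTI matrix (or a `beta_nti_result`).
#' @param rc Raup-Crick matrix from [raup_crick()].
#' @param groups named group label per sample (e.g. from [sample_groups()]);
#'   fractions are computed over the within-group pairs of each label. Use a
#'   single constant label for one overall fraction set.
#' @param bnti_threshold,rc_threshold classification thresholds.
#' @return List with `classification` (data.frame: sample_a, sample_b, group,
#'   beta_nti, raup_crick, process), `fractions` (data.frame: group, process,
#'   fraction, n_pairs), `n_undefined` per group.
#' @export
partition_processes <- function(bnti, rc, groups,
                                bnti_threshold = 2, rc_threshold = 0.95) {
  if (inherits(bnti, "beta_nti_result")) bnti <- bnti$beta_nti
  bnti <- as.matrix(bnti)
  rc <- as.matrix(rc)
  ids <- rownames(bnti)
  if (is.null(names(groups))) names(groups) <- ids
  processes <- c("heterogeneous_selection", "homogeneous_selection",
                 "dispersal_limitation", "homogenizing_dispersal", "drift")
  rows <- list()
  frac_rows <- list()
  undef <- integer(0)
  for (grp in unique(groups)) {
    members <- names(groups)[groups == grp]
    members <- intersect(ids, members)
    if (length(members) < 2)
      stop("group '", grp, "' has no sample pairs", call. = FALSE)
    pr <- utils::combn(members, 2)
    b <- bnti[cbind(pr[1, ], pr[2, ])]
    r <- rc[cbind(pr[1, ], pr[2, ])]
    cls <- ifelse(is.na(b), "undefined",
           ifelse(b > bnti_threshold, "heterogeneous_selection",
           ifelse(b < -bnti_threshold, "homogeneous_selection",
           ifelse(r > rc_threshold, "dispersal_limitation",
           ifelse(r < -rc_threshold, "homogenizing_dispersal", "drift")))))
    rows[[grp]] <- data.frame(sample_a = pr[1, ], sample_b = pr[2, ],
                              group = grp, beta_nti = b, raup_crick = r,
                              process = cls)
    defined <- cls[cls != "undefined"]
    undef[grp] <- sum(cls == "undefined")
    if (length(defined)) {
      tab <- table(factor(defined, levels = processes))
      frac_rows[[grp]] <- data.frame(group = grp, process = processes,
                                     fraction = as.numeric(tab / sum(tab)),
                                     n_pairs = as.integer(tab))
    }
  }
  list(classification = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       fractions = do.call(rbind, c(frac_rows, list(make.row.names = FALSE))),
       n_undefined = undef)
}

#' Full community-assembly analysis
#'
#' Runs [beta_nti()] and [raup_crick()] on a dataset and partitions the
#' within-group pairs into ecological processes.
#'
#' @inheritParams beta_nti
#' @param group_by grouping for the fractions, see [sample_groups()].
#' @param rc_seed separate seed for the Raup-Crick null stream (defaults to
#'   `seed + 1`).
#' @param bnti_threshold,rc_threshold classification thresholds.
#' @return List of class `assembly_result`: the `beta_nti_result` fields,
#'   plus `raup_crick`, `classification`, `fractions`, `n_undefined`.
#' @export
assembly_analysis <- function(ds, n_null = 999, seed = NULL,
                              group_by = "mode_stage", weighted = TRUE,
                              bnti_threshold = 2, rc_threshold = 0.95,
                              rc_seed = NULL) {
  bn <- beta_nti(ds, n_null = n_null, seed = seed, weighted = weighted)
  rc <- raup_crick(ds, n_null = n_null,
                   seed = rc_seed %||% (if (!is.null(seed)) seed + 1))
  groups <- sample_groups(ds, group_by)
  part <- partition_processes(bn, rc, groups,
                              bnti_threshold = bnti_threshold,
                              rc_threshold = rc_threshold)
  structure(c(bn, list(raup_crick = rc,
                       classification = part$classification,
                       fractions = part$fractions,
                       n_undefined = part$n_undefined)),
            class = "assembly_result")
}

#' Fraction of pairs classified as selection
#'
#' Convenience summary: the proportion of defined pairs whose process is
#' heterogeneous or homogeneous selection, either overall or per group.
#'
#' @param x an `assembly_result` (or the `classification` data.frame).
#' @param per_group return one fraction per group instead of the overall one.
#' @return Numeric scalar or named vector.
#' @export
selection_fraction <- function(x, per_group = FALSE) {
  cls <- if (is.data.frame(x)) x else x$classification
  cls <- cls[cls$process != "undefined", , drop = FALSE]
  sel <- cls$process %in% c("heterogeneous_selection", "homogeneous_selection")
  if (!per_group) return(mean(sel))
  res <- tapply(sel, cls$group, mean)
  stats::setNames(as.numeric(res), names(res))
}
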