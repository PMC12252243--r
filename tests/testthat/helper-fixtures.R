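# shared fixtures, all built in code

# 4 samples x 5 ASVs, one fungal contaminant, tree over the protist ASVs
toy_dataset <- function() {
  counts <- matrix(
    c(10, 5, 0, 3, 2,
       8, 0, 4, 3, 1,
       0, 6, 6, 2, 0,
       5, 5, 5, 5, 5),
    nrow = 4, byrow = TRUE,
    dimnames = list(paste0("S", 1:4), paste0("ASV_", 1:5)))
  taxonomy <- data.frame(
    asv_id = paste0("ASV_", 1:5),
    lineage = c(
      "kingdom:Eukaryota;supergroup:Alveolata;division:Ciliophora;genus:Colpoda",
      "kingdom:Eukaryota;supergroup:Archaeplastida;division:Chlorophyta;genus:Scenedesmus",
      "kingdom:Eukaryota;supergroup:Stramenopiles;division:Oomycota;genus:Pythium",
      "kingdom:Eukaryota;supergroup:Rhizaria;division:Cercozoa;genus:Cercomonas",
      "kingdom:Eukaryota;supergroup:Opisthokonta;division:Fungi;genus:Fusarium"))
  tree <- ape::read.tree(text = paste0(
    "((ASV_1:1,ASV_2:1):1,(ASV_3:1.5,(ASV_4:0.5,ASV_5:0.5):1):0.5);"))
  metadata <- data.frame(
    sample_id = paste0("S", 1:4),
    cultivation_mode = c("greenhouse", "greenhouse", "hilly", "hilly"),
    growth_stage = c("flowering", "fruiting", "flowering", "fruiting"))
  soil <- data.frame(sample_id = paste0("S", 1:4),
                     TN = c(1.0, 1.1, 1.8, 1.9),
                     pH = c(6.2, 6.4, 7.8, 7.7))
  quality <- data.frame(sample_id = paste0("S", 1:4),
                        fruit_weight = c(140, 145, 160, 158),
                        seed_number = c(12, 11, 10, 12))
  community_dataset(counts, taxonomy, tree, metadata, soil, quality)
}

# small simulated datasets, cached per test session
.sim_cache <- new.env(parent = emptyenv())
cached_sim <- function(scenario, seed, ...) {
  key <- paste(scenario, seed, ...)
  if (is.null(.sim_cache[[key]])) {
    .sim_cache[[key]] <- simulate_dataset(
      scenario_spec(scenario, seed = seed, ...))
  }
  .sim_cache[[key]]
}

# independent brute-force Faith PD: walk root-to-tip paths and take the
# union of traversed edges
faith_pd_bruteforce <- function(tree, present) {
  root <- length(tree$tip.label) + 1L
  edges <- character(0)
  for (tip in present) {
    path <- ape::nodepath(tree, root, match(tip, tree$tip.label))
    edges <- union(edges, paste(path[-length(path)], path[-1]))
  }
  key <- paste(tree$edge[, 1], tree$edge[, 2])
  sum(tree$edge.length[key %in% edges])
}

# independent brute-force betaMNTD: plain double loop over present taxa
beta_mntd_bruteforce <- function(counts, D, weighted = TRUE) {
  n <- nrow(counts)
  out <- matrix(0, n, n, dimnames = list(rownames(counts), rownames(counts)))
  for (a in seq_len(n)) for (b in seq_len(n)) {
    if (a >= b) next
    ta <- colnames(counts)[counts[a, ] > 0]
    tb <- colnames(counts)[counts[b, ] > 0]
    fa <- counts[a, ta] / sum(counts[a, ])
    fb <- counts[b, tb] / sum(counts[b, ])
    if (!weighted) {
      fa <- rep(1 / length(ta), length(ta))
      fb <- rep(1 / length(tb), length(tb))
      names(fa) <- ta; names(fb) <- tb
    }
    s1 <- 0
    for (i in ta) s1 <- s1 + fa[i] * min(D[i, tb])
    s2 <- 0
    for (j in tb) s2 <- s2 + fb[j] * min(D[j, ta])
    out[a, b] <- out[b, a] <- 0.5 * (s1 + s2)
  }
  out
}

# random count table with guaranteed non-empty samples
random_counts <- function(n_samples, n_taxa, seed, lambda = 3) {
  set.seed(seed)
  m <- matrix(stats::rpois(n_samples * n_taxa, lambda), n_samples, n_taxa,
              dimnames = list(paste0("S", seq_len(n_samples)),
                              paste0("t", seq_len(n_taxa))))
  empty <- rowSums(m) == 0
  m[empty, 1] <- 1
  m
}
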