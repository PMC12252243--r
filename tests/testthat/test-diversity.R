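make_ds <- function(counts, tree = NULL) {
  tax <- data.frame(asv_id = colnames(counts),
                    lineage = rep("kingdom:Eukaryota", ncol(counts)))
  md <- data.frame(sample_id = rownames(counts),
                   cultivation_mode = "hilly", growth_stage = "flowering")
  community_dataset(counts, tax, tree, md)
}

test_that("alpha indices match their closed forms", {
  # uniform community of four taxa
  ds <- make_ds(matrix(c(4, 4, 4, 4), nrow = 2, ncol = 4, byrow = TRUE,
                       dimnames = list(c("U", "V"), paste0("t", 1:4))))
  expect_equal(unname(alpha_diversity(ds, "shannon")[1]), log(4),
               tolerance = 1e-12)
  expect_equal(unname(alpha_diversity(ds, "pielou")[1]), 1, tolerance = 1e-12)
  # Chao1 with S_obs = 10, F1 = 4, F2 = 2 -> 10 + 4*3/(2*3) = 12
  x <- c(rep(1, 4), rep(2, 2), rep(5, 4))
  ds2 <- make_ds(matrix(rep(x, 2), nrow = 2, byrow = TRUE,
                        dimnames = list(c("A", "B"), paste0("t", 1:10))))
  expect_equal(unname(alpha_diversity(ds2, "chao1")[1]), 12)
  # independent cross-check of chao1 against vegan on random tables
  for (seed in 1:5) {
    m <- random_counts(4, 30, seed, lambda = 1)
    got <- alpha_diversity(make_ds(m), "chao1")
    ref <- apply(m, 1, function(r) vegan::estimateR(r)["S.chao1"])
    expect_equal(unname(got), unname(ref), tolerance = 1e-8)
  }
  # pielou undefined at richness <= 1
  ds3 <- make_ds(matrix(c(5, 0, 3, 2), nrow = 2, byrow = TRUE,
                        dimnames = list(c("one", "two"), c("t1", "t2"))))
  expect_warning(p <- alpha_diversity(ds3, "pielou"), "one")
  expect_true(is.na(p["one"]) && !is.na(p["two"]))
})

test_that("alpha diversity invariants hold on random tables", {
  for (seed in 1:10) {
    m <- random_counts(5, 25, seed, lambda = 2)
    ds <- make_ds(m)
    h <- alpha_diversity(ds, "shannon")
    s <- rowSums(m > 0)
    expect_true(all(h <= log(s) + 1e-12))
    expect_true(all(alpha_diversity(ds, "chao1") >= s))
    p <- suppressWarnings(alpha_diversity(ds, "pielou"))
    expect_true(all(p[!is.na(p)] >= 0 & p[!is.na(p)] <= 1 + 1e-12))
  }
})

test_that("Faith PD is root-inclusive and matches the brute-force subtree sum", {
  tree <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  ds <- make_ds(matrix(c(1, 1, 0), nrow = 2, ncol = 3, byrow = TRUE,
                       dimnames = list(c("S1", "S2"), c("A", "B", "C"))),
                tree)
  expect_equal(unname(alpha_diversity(ds, "faith_pd")[1]), 3)
  # brute-force oracle on random trees and random presence sets
  for (seed in 1:5) {
    tr <- simulate_tree(12, seed = seed)
    set.seed(seed + 100)
    m <- matrix(rbinom(3 * 12, 1, 0.5) * rpois(3 * 12, 3), nrow = 3,
                dimnames = list(paste0("S", 1:3), tr$tip.label))
    m[rowSums(m) == 0, 1] <- 1
    got <- alpha_diversity(make_ds(m, tr), "faith_pd")
    ref <- sapply(seq_len(3), function(i)
      faith_pd_bruteforce(tr, colnames(m)[m[i, ] > 0]))
    expect_equal(unname(got), unname(ref), tolerance = 1e-9)
  }
})

test_that("Faith PD is monotone under adding taxa", {
  tr <- simulate_tree(15, seed = 3)
  base_present <- tr$tip.label[1:4]
  m1 <- matrix(0, 1, 15, dimnames = list("S", tr$tip.label))
  m1[, base_present] <- 1
  m2 <- m1
  m2[, tr$tip.label[9]] <- 1
  pd1 <- alpha_diversity(make_ds(rbind(m1, S2 = m1[1, ]), tr), "faith_pd")[1]
  pd2 <- alpha_diversity(make_ds(rbind(m2, S2 = m2[1, ]), tr), "faith_pd")[1]
  expect_gte(pd2, pd1)
})

test_that("Bray-Curtis matches the hand formula and vegan", {
  m <- matrix(c(2, 0, 4,
                2, 2, 0), nrow = 2, byrow = TRUE,
              dimnames = list(c("x", "y"), c("t1", "t2", "t3")))
  bc <- bray_curtis(m)
  expect_equal(bc["x", "y"], 0.6)
  # identity and disjointness
  m2 <- matrix(c(3, 1, 0, 0,
                 3, 1, 0, 0,
                 0, 0, 2, 5), nrow = 3, byrow = TRUE,
               dimnames = list(c("a", "b", "c"), paste0("t", 1:4)))
  bc2 <- bray_curtis(m2)
  expect_equal(bc2["a", "b"], 0)
  expect_equal(bc2["a", "c"], 1)
  # all-zero sample errors by name
  m3 <- m2
  m3["c", ] <- 0
  expect_error(bray_curtis(m3), "c")
})

test_that("PCoA embeds distances correctly", {
  # two samples at distance d -> coordinates +/- d/2
  d2 <- matrix(c(0, 0.8, 0.8, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  ord2 <- pcoa_ordination(d2)
  expect_equal(sort(ord2$coordinates[, 1]), c(-0.4, 0.4), tolerance = 1e-9,
               ignore_attr = TRUE)
  # Euclidean-embeddable input is reproduced exactly
  set.seed(42)
  pts <- matrix(rnorm(6 * 3), 6, 3, dimnames = list(paste0("S", 1:6), NULL))
  dm <- as.matrix(dist(pts))
  ord <- pcoa_ordination(dm)
  rec <- as.matrix(dist(ord$coordinates))
  expect_equal(rec, dm, tolerance = 1e-8)
  # spectral identity: eigenvalue sum equals the trace of the centered matrix
  a <- -0.5 * dm^2
  centered <- sweep(sweep(a, 1, rowMeans(a)), 2, colMeans(a)) + mean(a)
  expect_equal(sum(ord$eigenvalues), sum(diag(centered)), tolerance = 1e-8)
  expect_true(all(diff(ord$eigenvalues) <= 1e-9))
  expect_equal(colSums(ord$coordinates), rep(0, ncol(ord$coordinates)),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("PERMANOVA separates planted clusters and is seeded", {
  set.seed(5)
  pts <- rbind(matrix(rnorm(6 * 2, 0, 1), 6),
               matrix(rnorm(6 * 2, 5, 1), 6))
  rownames(pts) <- paste0("S", 1:12)
  dm <- as.matrix(dist(pts))
  labels <- rep(c("a", "b"), each = 6)
  pm <- permanova(dm, labels, n_perm = 999, seed = 1)
  # mirrored-partition permutations tie with the observed F, so the
  # attainable minimum at 999 permutations is a few thousandths
  expect_lte(pm$p_value, 0.005)
  expect_gte(pm$p_value, 1 / (pm$n_perm + 1))
  expect_true(pm$R2 >= 0 && pm$R2 <= 1)
  pm2 <- permanova(dm, labels, n_perm = 999, seed = 1)
  expect_identical(pm$p_value, pm2$p_value)
  expect_error(permanova(dm, rep("a", 12), n_perm = 99), "2 groups")
  expect_error(permanova(dm, c("a", rep("b", 11)), n_perm = 99), "single")
})

test_that("Tukey comparisons handle planted, identical and degenerate groups", {
  set.seed(9)
  vals <- c(rnorm(6, 0, 0.1), rnorm(6, 10, 0.1))
  tk <- tukey_groups(vals, rep(c("lo", "hi"), each = 6))
  expect_lt(tk$p_adj[1], 0.001)
  # identical groups: zero difference, degenerate p = 1
  same <- rep(c(1, 2, 3), 2)
  expect_warning(tk0 <- tukey_groups(same, rep(c("a", "b"), each = 3)),
                 NA)  # variance within groups is nonzero here, no warning
  expect_equal(tk0$difference, 0)
  expect_equal(tk0$p_adj, 1, tolerance = 1e-9)
  # fully degenerate: all values equal
  expect_warning(tkd <- tukey_groups(rep(1, 8), rep(c("a", "b"), each = 4)),
                 "degenerate")
  expect_equal(tkd$p_adj, 1)
  expect_error(tukey_groups(1:5, rep("a", 5)), "2 groups")
  # unbalanced groups are accepted (Tukey-Kramer)
  tku <- tukey_groups(c(rnorm(3), rnorm(5, 4)), c(rep("a", 3), rep("b", 5)))
  expect_true(is.finite(tku$p_adj))
})

test_that("within-group distances enumerate the right multisets", {
  dm <- matrix(0, 7, 7, dimnames = list(paste0("S", 1:7), paste0("S", 1:7)))
  set.seed(2)
  v <- runif(21)
  dm[upper.tri(dm)] <- v
  dm <- dm + t(dm)
  labels <- c(rep("g1", 3), rep("g2", 4))
  wd <- within_group_distances(dm, labels)
  expect_equal(lengths(wd), c(g1 = 3, g2 = 6))
  expect_true(all(unlist(wd) %in% dm[upper.tri(dm)]))
  # a group of identical samples gives all-zero distances
  dmz <- matrix(0, 3, 3, dimnames = list(paste0("Z", 1:3), paste0("Z", 1:3)))
  expect_equal(within_group_distances(dmz, rep("g", 3))$g, rep(0, 3))
  expect_warning(within_group_distances(dm, c(rep("g1", 6), "lonely")),
                 "lonely")
})
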