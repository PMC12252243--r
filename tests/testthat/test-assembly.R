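test_that("patristic distances match hand values and a graph oracle", {
  tree <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  d <- patristic_distances(tree)
  expect_equal(d["A", "B"], 2)
  expect_equal(d["A", "C"], 4)
  expect_equal(d["B", "C"], 4)
  expect_true(all(diag(d) == 0))
  # independent oracle: shortest paths over the tree's edge graph
  skip_if_not_installed("igraph")
  for (seed in 1:4) {
    tr <- simulate_tree(15, seed = seed)
    g <- igraph::graph_from_edgelist(
      cbind(as.character(tr$edge[, 1]), as.character(tr$edge[, 2])),
      directed = FALSE)
    igraph::E(g)$weight <- tr$edge.length
    sp <- igraph::distances(g)
    tipv <- as.character(seq_along(tr$tip.label))
    ref <- sp[tipv, tipv]
    dimnames(ref) <- list(tr$tip.label, tr$tip.label)
    expect_equal(patristic_distances(tr), ref[tr$tip.label, tr$tip.label],
                 tolerance = 1e-9)
  }
  dup <- tree
  dup$tip.label[2] <- "A"
  expect_error(patristic_distances(dup), "duplicate")
})

test_that("betaMNTD matches hand-worked examples", {
  tree <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  pd <- patristic_distances(tree)
  # {A} vs {B}: 0.5 * (2 + 2) = 2
  m <- matrix(c(1, 0, 0,
                0, 1, 0), nrow = 2, byrow = TRUE,
              dimnames = list(c("s1", "s2"), c("A", "B", "C")))
  expect_equal(beta_mntd(m, pd)["s1", "s2"], 2)
  # {A: .5, C: .5} vs {B: 1}: 0.5 * (.5*2 + .5*4 + 1*2) = 2.5
  m2 <- matrix(c(1, 0, 1,
                 0, 2, 0), nrow = 2, byrow = TRUE,
               dimnames = list(c("s1", "s2"), c("A", "B", "C")))
  expect_equal(beta_mntd(m2, pd)["s1", "s2"], 2.5)
  # identical communities score zero
  m3 <- rbind(s1 = c(A = 3, B = 1, C = 0), s2 = c(A = 3, B = 1, C = 0))
  expect_equal(beta_mntd(m3, pd)["s1", "s2"], 0)
})

test_that("betaMNTD equals brute force and picante on random data", {
  for (seed in 1:5) {
    tr <- simulate_tree(12, seed = seed)
    m <- random_counts(5, 12, seed + 50, lambda = 1.5)
    colnames(m) <- tr$tip.label
    pd <- patristic_distances(tr)
    got_w <- beta_mntd(m, pd, weighted = TRUE)
    got_u <- beta_mntd(m, pd, weighted = FALSE)
    expect_equal(got_w, beta_mntd_bruteforce(m, pd, weighted = TRUE),
                 tolerance = 1e-12)
    expect_equal(got_u, beta_mntd_bruteforce(m, pd, weighted = FALSE),
                 tolerance = 1e-12)
    # independent implementation cross-check
    ref <- as.matrix(picante::comdistnt(m, pd, abundance.weighted = TRUE))
    expect_equal(got_w[rownames(ref), colnames(ref)], ref, tolerance = 1e-9)
    # symmetry and non-negativity
    expect_equal(got_w, t(got_w))
    expect_true(all(got_w >= 0))
  }
})

test_that("unweighted betaMNTD is zero iff taxon sets coincide", {
  tr <- simulate_tree(10, seed = 2)
  pd <- patristic_distances(tr)
  m <- rbind(a = c(rep(1, 4), rep(0, 6)),
             b = c(4, 1, 9, 2, rep(0, 6)),   # same set, different abundances
             c = c(rep(0, 4), rep(1, 6)))
  colnames(m) <- tr$tip.label
  bm <- beta_mntd(m, pd, weighted = FALSE)
  expect_equal(bm["a", "b"], 0)
  expect_gt(bm["a", "c"], 0)
})

test_that("betaNTI is standardized, seeded, and undefined on a star tree", {
  tr <- simulate_tree(14, seed = 4)
  m <- random_counts(6, 14, 77, lambda = 2)
  colnames(m) <- tr$tip.label
  bn1 <- beta_nti(m, tree = tr, n_null = 49, seed = 11)
  bn2 <- beta_nti(m, tree = tr, n_null = 49, seed = 11)
  expect_identical(bn1$beta_nti, bn2$beta_nti)
  # standardization identity where defined
  ok <- !is.na(bn1$beta_nti)
  expect_equal(bn1$beta_nti[ok],
               ((bn1$beta_mntd - bn1$null_mean) / bn1$null_sd)[ok],
               tolerance = 1e-12)
  # star phylogeny: tip shuffling changes nothing, all pairs undefined
  star <- ape::stree(6, type = "star")
  star$edge.length <- rep(1, nrow(star$edge))
  ms <- random_counts(4, 6, 5, lambda = 2)
  colnames(ms) <- star$tip.label
  bstar <- beta_nti(ms, tree = star, n_null = 19, seed = 3)
  offdiag <- bstar$beta_nti[upper.tri(bstar$beta_nti)]
  expect_true(all(is.na(offdiag)))
  expect_true(all(bstar$null_sd[upper.tri(bstar$null_sd)] == 0))
  expect_error(beta_nti(m, tree = tr, n_null = 0), "n_null")
})

test_that("betaNTI is invariant under simultaneous tip relabeling", {
  tr <- simulate_tree(10, seed = 6)
  m <- random_counts(4, 10, 60, lambda = 2)
  colnames(m) <- tr$tip.label
  bn <- beta_nti(m, tree = tr, n_null = 49, seed = 2)
  # swap the names of two tips in both the tree and the table
  swap <- function(x) {
    x[x == "ASV_1"] <- "tmp"
    x[x == "ASV_2"] <- "ASV_1"
    x[x == "tmp"] <- "ASV_2"
    x
  }
  tr2 <- tr
  tr2$tip.label <- swap(tr$tip.label)
  m2 <- m
  colnames(m2) <- swap(colnames(m))
  bn2 <- beta_nti(m2, tree = tr2, n_null = 49, seed = 2)
  expect_equal(bn$beta_nti, bn2$beta_nti, tolerance = 1e-12)
})

test_that("Raup-Crick stays in bounds and is extreme where forced", {
  m <- random_counts(6, 20, 8, lambda = 2)
  # make two samples identical: observed BC = 0 is the attainable minimum
  m[2, ] <- m[1, ]
  rc <- raup_crick(m, n_null = 99, seed = 4)
  offdiag <- rc[upper.tri(rc)]
  expect_true(all(offdiag >= -1 & offdiag <= 1))
  expect_lt(rc[1, 2], -0.95)
  # disjoint samples: observed BC = 1 beats every null that shares taxa
  md <- matrix(0, 3, 8, dimnames = list(paste0("S", 1:3), paste0("t", 1:8)))
  md[1, 1:4] <- c(5, 3, 2, 1)
  md[2, 5:8] <- c(4, 4, 2, 1)
  md[3, ] <- 1
  rcd <- raup_crick(md, n_null = 99, seed = 9)
  # occasional null draws are themselves disjoint and tie with the observed
  # BC of 1, so the value sits at or just under the +1 boundary
  expect_gt(rcd["S1", "S2"], 0.95)
  rc2 <- raup_crick(m, n_null = 99, seed = 4)
  expect_identical(rc, rc2)
  expect_error(raup_crick(m[1, , drop = FALSE], n_null = 9), "2 samples")
})

test_that("process partitioning follows the threshold rules exactly", {
  ids <- paste0("S", 1:3)
  bnti <- matrix(NA_real_, 3, 3, dimnames = list(ids, ids))
  rc <- matrix(NA_real_, 3, 3, dimnames = list(ids, ids))
  bnti[1, 2] <- bnti[2, 1] <- 2.5    # heterogeneous selection
  bnti[1, 3] <- bnti[3, 1] <- -3     # homogeneous selection
  bnti[2, 3] <- bnti[3, 2] <- 1      # stochastic -> consult RC
  rc[2, 3] <- rc[3, 2] <- 0.99       # dispersal limitation
  part <- partition_processes(bnti, rc, setNames(rep("all", 3), ids))
  fr <- part$fractions
  expect_equal(fr$fraction[fr$process == "heterogeneous_selection"], 1 / 3)
  expect_equal(fr$fraction[fr$process == "homogeneous_selection"], 1 / 3)
  expect_equal(fr$fraction[fr$process == "dispersal_limitation"], 1 / 3)
  expect_equal(sum(fr$fraction), 1, tolerance = 1e-9)
  # all-drift case
  b0 <- matrix(0, 3, 3, dimnames = list(ids, ids))
  part0 <- partition_processes(b0, b0, setNames(rep("all", 3), ids))
  expect_equal(part0$fractions$fraction[part0$fractions$process == "drift"], 1)
  # boundary values are stochastic/drift (strict inequalities)
  b2 <- matrix(2, 3, 3, dimnames = list(ids, ids))
  r95 <- matrix(0.95, 3, 3, dimnames = list(ids, ids))
  pb <- partition_processes(b2, r95, setNames(rep("all", 3), ids))
  expect_true(all(pb$classification$process == "drift"))
  # undefined pairs excluded from fractions but tallied
  bu <- bnti
  bu[1, 2] <- bu[2, 1] <- NA
  pu <- partition_processes(bu, rc, setNames(rep("all", 3), ids))
  expect_equal(unname(pu$n_undefined["all"]), 1L)
  expect_equal(sum(pu$fractions$fraction), 1, tolerance = 1e-9)
  expect_error(partition_processes(bnti, rc, setNames(c("a", "a", "b"), ids)),
               "b")
})

test_that("selection_fraction summarizes classifications overall and per group", {
  cls <- data.frame(
    sample_a = "x", sample_b = "y",
    group = c("g1", "g1", "g2", "g2"),
    beta_nti = 0, raup_crick = 0,
    process = c("heterogeneous_selection", "drift",
                "homogeneous_selection", "homogeneous_selection"))
  expect_equal(selection_fraction(cls), 0.75)
  expect_equal(selection_fraction(cls, per_group = TRUE),
               c(g1 = 0.5, g2 = 1))
})
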