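test_that("simulated trees are ultrametric, labelled and reproducible", {
  tr <- simulate_tree(20, seed = 5)
  expect_equal(length(tr$tip.label), 20)
  expect_setequal(tr$tip.label, paste0("ASV_", 1:20))
  depths <- ape::node.depth.edgelength(tr)[1:20]
  expect_true(max(depths) - min(depths) < 1e-9)   # ultrametric
  expect_equal(max(depths), 1, tolerance = 1e-9)  # unit depth
  expect_identical(ape::write.tree(tr), ape::write.tree(simulate_tree(20, seed = 5)))
  expect_error(simulate_tree(2), "n_taxa")
})

test_that("Brownian niches are seeded and phylogenetically conserved", {
  tr <- simulate_tree(16, seed = 1)
  n1 <- simulate_niche(tr, sigma = 1, seed = 9)
  expect_identical(n1, simulate_niche(tr, sigma = 1, seed = 9))
  # sigma -> 0 limit collapses to the root value
  n0 <- simulate_niche(tr, sigma = 1e-8, seed = 9)
  expect_equal(unname(n0), rep(0, 16), tolerance = 1e-6)
  # sister tips are more similar than random tip pairs on average
  sister_vs_random <- sapply(1:50, function(s) {
    tr <- simulate_tree(16, seed = s)
    x <- simulate_niche(tr, sigma = 1, seed = s + 500)
    D <- ape::cophenetic.phylo(tr)
    sisters <- which(D == min(D[D > 0]), arr.ind = TRUE)[1, ]
    sister_diff <- abs(x[sisters[1]] - x[sisters[2]])
    set.seed(s)
    rnd <- sample(16, 2)
    c(sister_diff, abs(x[rnd[1]] - x[rnd[2]]))
  })
  expect_lt(mean(sister_vs_random[1, ]), mean(sister_vs_random[2, ]))
})

test_that("simulated datasets validate, round-trip and are bit-reproducible", {
  spec <- scenario_spec("selection", n_taxa = 15, n_samples_per_cell = 2,
                        depth_mean = 3000, seed = 77)
  ds1 <- simulate_dataset(spec)
  ds2 <- simulate_dataset(spec)
  expect_identical(ds1$counts, ds2$counts)
  expect_identical(ape::write.tree(ds1$tree), ape::write.tree(ds2$tree))
  expect_identical(ds1$soil, ds2$soil)
  expect_identical(ds1$quality, ds2$quality)
  # passes full io validation via a disk round-trip
  dir <- withr::local_tempdir()
  write_community_data(ds1, dir)
  expect_s3_class(read_community_dir(dir), "community_dataset")
  # design shape
  expect_equal(nrow(ds1$counts), 12)
  expect_equal(ncol(ds1$counts), 15 + spec$n_contaminants)
  tab <- table(ds1$metadata$cultivation_mode, ds1$metadata$growth_stage)
  expect_true(all(tab == 2))
})

test_that("the generator plants the documented structure", {
  ds <- cached_sim("selection", seed = 21)
  # contaminant lineages exist and are removed by the standard filter
  expect_true(any(grepl("Fungi|Metazoa|Embryophyta", ds$taxonomy$lineage)))
  flt <- filter_taxa(ds)
  expect_false(any(grepl("Fungi|Metazoa|Embryophyta", flt$taxonomy$lineage)))
  # all three trophic groups occur among the protist ASVs
  traits <- assign_traits(flt)
  expect_true(all(c("consumer", "phototrophic", "parasitic") %in% traits))
  # the nitrogen gradient runs greenhouse < paddy in the soil table
  md <- ds$metadata
  tn <- tapply(ds$soil$TN[match(md$sample_id, ds$soil$sample_id)],
               md$cultivation_mode, mean)
  expect_lt(tn["greenhouse"], tn["paddy"])
  # quality effect: greenhouse mean quality parameters sit lowest
  fw <- tapply(ds$quality$fruit_weight[match(md$sample_id,
                                             ds$quality$sample_id)],
               md$cultivation_mode, mean)
  expect_equal(names(which.min(fw)), "greenhouse")
})

test_that("stronger gradients produce stronger phylogenetic turnover signals", {
  mean_abs_bnti <- function(g, seed) {
    ds <- simulate_dataset(scenario_spec("selection", n_samples_per_cell = 2,
                                         gradient_strength = g, seed = seed))
    bn <- beta_nti(ds, n_null = 49, seed = seed + 7)
    mean(abs(bn$beta_nti), na.rm = TRUE)
  }
  # within the responsive regime; beyond ~2 the mode/microsite positions
  # pass the edge of the niche range and the signal saturates
  levels <- c(0.5, 1, 1.5)
  means <- sapply(levels, function(g)
    mean(sapply(1:10, function(s) mean_abs_bnti(g, 1000 + s))))
  expect_true(all(diff(means) > 0))
})
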