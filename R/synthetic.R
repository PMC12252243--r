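#' Scenario specification for the synthetic generator
#'
#' Describes a full simulated field design: three cultivation modes
#' (greenhouse, hilly- and paddy-converted) crossed with two growth stages
#' (flowering, fruiting), `n_samples_per_cell` soil samples per cell. Taxa
#' live on a simulated phylogeny with Brownian (phylogenetically conserved)
#' niche optima along a nitrogen-like environmental gradient whose
#' mode-dependent mean is lowest in the greenhouse.
#'
#' Two assembly regimes are available. Under `"selection"` the environmental
#' value of each sample filters taxa through Gaussian niche weights of
#' breadth `niche_breadth`, producing deterministic, phylogenetically
#' structured assembly. Under `"neutral"` sampling weights are
#' mode-independent lognormal drift noise around a common regional pool.
#' `"greenhouse_vs_openfield"` is the selection design with the planted
#' quality contrast emphasized; it exists as a named preset for
#' quality-focused analyses.
#'
#' @param scenario preset name; sets `assembly_mode`.
#' @param n_taxa number of protist ASVs (>= 3), excluding contaminants.
#' @param n_samples_per_cell samples per mode-by-stage cell.
#' @param niche_breadth Gaussian niche breadth (sd, gradient units).
#' @param gradient_strength amplitude of the environmental field: mode means
#'   sit at `(-1, 0, 1) * gradient_strength` and each sample additionally
#'   receives a balanced within-cell microsite offset of
#'   `±2 * gradient_strength` (fields are environmentally heterogeneous, so
#'   samples within one farmland still experience different local nitrogen
#'   levels).
#' @param depth_mean mean sequencing depth per sample (Poisson).
#' @param quality_effect planted cultivation-mode shift in the quality
#'   parameters, in units of 0.8 within-mode standard deviations
#'   (greenhouse negative, open-field positive).
#' @param n_contaminants extra non-protist (Fungi/Metazoa/Embryophyta) ASVs
#'   included so the lineage filter has work to do.
#' @param seed integer seed; the entire dataset is reproducible from it.
#' @return List of class `scenario_spec`.
#' @export
scenario_spec <- function(scenario = c("selection", "neutral",
                                       "greenhouse_vs_openfield"),
                          n_taxa = 40, n_samples_per_cell = 6,
                          niche_breadth = 0.9, gradient_strength = 2.5,
                          depth_mean = 20000, quality_effect = 1,
                          n_contaminants = 2, seed = 1) {
  scenario <- match.arg(scenario)
  spec <- list(
    scenario = scenario,
    assembly_mode = if (scenario == "neutral") "neutral" else "selection",
    n_taxa = stop_if_not_scalar_count(n_taxa, "n_taxa", min = 3),
    n_samples_per_cell = stop_if_not_scalar_count(n_samples_per_cell,
                                                  "n_samples_per_cell", 1),
    niche_breadth = niche_breadth,
    gradient_strength = gradient_strength,
    depth_mean = stop_if_not_scalar_count(depth_mean, "depth_mean", 1),
    quality_effect = quality_effect,
    n_contaminants = stop_if_not_scalar_count(n_contaminants,
                                              "n_contaminants", 0),
    seed = seed)
  if (!is.numeric(spec$niche_breadth) || spec$niche_breadth <= 0)
    stop("niche_breadth must be > 0", call. = FALSE)
  if (!is.numeric(spec$gradient_strength) || spec$gradient_strength < 0)
    stop("gradient_strength must be >= 0", call. = FALSE)
  structure(spec, class = "scenario_spec")
}

#' Simulate a rooted ultrametric phylogeny
#'
#' Pure-birth (Yule) tree rescaled to unit root-to-tip depth, tips labelled
#' `ASV_1..ASV_n`.
#'
#' @param n_taxa number of tips (>= 3).
#' @param seed integer seed; fixed seed gives an identical newick string.
#' @return A `phylo` object.
#' @export
simulate_tree <- function(n_taxa, seed = NULL) {
  stop_if_not_scalar_count(n_taxa, "n_taxa", min = 3)
  tree <- with_seed(seed, ape::rphylo(n_taxa, birth = 1, death = 0))
  depth <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length / depth
  tree$tip.label <- paste0("ASV_", seq_len(n_taxa))
  tree
}

#' Simulate phylogenetically conserved niche optima
#'
#' Brownian motion along the tree from a root value of 0 with rate `sigma`
#' (variance `sigma^2` per unit branch length). Close relatives therefore
#' get similar optima -- the niche conservatism that makes phylogenetic
#' turnover responsive to environmental selection.
#'
#' @param tree a `phylo` object.
#' @param sigma Brownian rate (> 0).
#' @param seed integer seed.
#' @return Named numeric vector of per-tip optima.
#' @export
simulate_niche <- function(tree, sigma, seed = NULL) {
  if (!is.numeric(sigma) || sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  with_seed(seed, ape::rTraitCont(tree, model = "BM", sigma = sigma,
                                  root.value = 0))
}

# lineage templates used to spread simulated taxa over trait-map clades
SYNTH_LINEAGES <- c(
  ciliate = paste0("kingdom:Eukaryota;supergroup:Alveolata;",
                   "division:Ciliophora;class:Spirotrichea;",
                   "order:Sporadotrichida;family:Oxytrichidae;",
                   "genus:Oxytricha"),
  chlorophyte = paste0("kingdom:Eukaryota;supergroup:Archaeplastida;",
                       "division:Chlorophyta;class:Chlorophyceae;",
                       "order:Sphaeropleales;family:Scenedesmaceae;",
                       "genus:Scenedesmus"),
  oomycete = paste0("kingdom:Eukaryota;supergroup:Stramenopiles;",
                    "division:Oomycota;class:Peronosporomycetes;",
                    "order:Pythiales;family:Pythiaceae;genus:Pythium"),
  cercozoan = paste0("kingdom:Eukaryota;supergroup:Rhizaria;",
                     "division:Cercozoa;class:Sarcomonadea;",
                     "order:Cercomonadida;family:Cercomonadidae;",
                     "genus:Cercomonas"))

SYNTH_CONTAMINANTS <- c(
  paste0("kingdom:Eukaryota;supergroup:Opisthokonta;division:Fungi;",
         "class:Sordariomycetes;genus:Fusarium"),
  paste0("kingdom:Eukaryota;supergroup:Opisthokonta;division:Metazoa;",
         "class:Nematoda;genus:Caenorhabditis"),
  paste0("kingdom:Eukaryota;supergroup:Archaeplastida;",
         "division:Streptophyta;class:Embryophyta;genus:Citrus"))

# soil variable construction: nitrogen pools track the selection gradient E,
# the rest follow the cultivation-mode contrasts of an intensive greenhouse
# vs open-field design (open fields richer in nutrients and enzymes)
SOIL_VARS <- c("pH", "moisture", "TN", "TP", "TK", "AP", "AK", "ammonia",
               "nitrate", "nitrite", "DOC", "ALP", "beta_Glu", "urease",
               "cellulase")

QUALITY_PARAMS <- c("fruit_weight", "fruit_width", "fruit_height",
                    "fruit_shape_index", "pericarp_thickness",
                    "pericarp_weight", "valve_number", "valve_weight",
                    "seed_number", "seed_weight", "solid_rate", "edible_rate")

# Redraw Brownian niche realizations until the phylogenetic niche
# conservatism the selection scenario is defined by actually holds:
# Pearson correlation between patristic distance and absolute niche
# difference >= r_min. Deterministic: candidate k uses seed + k * 7919;
# the best candidate is kept if none reaches the floor within max_tries.
conserved_niche <- function(tree, sigma, seed, r_min = 0.45,
                            max_tries = 60) {
  D <- ape::cophenetic.phylo(tree)
  ut <- upper.tri(D)
  best <- NULL
  best_r <- -Inf
  for (k in seq_len(max_tries)) {
    cand <- simulate_niche(tree, sigma, seed = seed + (k - 1) * 7919)
    nd <- abs(outer(cand, cand, "-"))
    r <- stats::cor(D[ut], nd[ut])
    if (r > best_r) {
      best <- cand
      best_r <- r
    }
    if (best_r >= r_min) break
  }
  best
}

#' Simulate a complete community dataset
#'
#' Builds counts, taxonomy, tree, metadata, soil and quality tables for the
#' three-mode by two-stage design described by a [scenario_spec()]. The
#' output passes [validate_community_dataset()] and is written/read by the
#' io functions unchanged.
#'
#' Under the selection regime each sample's environmental value filters the
#' taxon pool through Gaussian niche weights; the niche optima are Brownian
#' along the tree with an enforced conservatism floor (see the methods
#' vignette), so environmental turnover produces phylogenetic turnover and
#' the betaNTI null model can recover the planted selection. Under the
#' neutral regime weights are a mode-independent heavy-tailed regional
#' profile with weak per-sample drift, so membership turnover arises from
#' sampling rare taxa in and out -- the data-generating process the null
#' models themselves assume of neutral assembly.
#'
#' @param spec a `scenario_spec`.
#' @return A `community_dataset`.
#' @export
simulate_dataset <- function(spec = scenario_spec()) {
  if (!inherits(spec, "scenario_spec")) stop("need a scenario_spec", call. = FALSE)
  n_prot <- spec$n_taxa
  n_tot <- n_prot + spec$n_contaminants
  tree <- simulate_tree(n_tot, seed = spec$seed)
  sigma_bm <- 2
  niche <- if (spec$assembly_mode == "selection") {
    conserved_niche(tree, sigma_bm, seed = spec$seed + 1)
  } else {
    simulate_niche(tree, sigma_bm, seed = spec$seed + 1)
  }

  modes <- c("greenhouse", "hilly", "paddy")
  stages <- c("flowering", "fruiting")
  per <- spec$n_samples_per_cell
  design <- expand.grid(rep_id = seq_len(per), growth_stage = stages,
                        cultivation_mode = modes, stringsAsFactors = FALSE)
  n_samp <- nrow(design)
  sample_ids <- sprintf("%s_%s_%02d",
                        substr(design$cultivation_mode, 1, 2),
                        substr(design$growth_stage, 1, 2), design$rep_id)
  g <- spec$gradient_strength
  mode_e <- c(greenhouse = -1, hilly = 0, paddy = 1) * g
  stage_e <- c(flowering = 0, fruiting = 0.25)
  # balanced within-cell microsite offsets: alternating low/high local
  # nitrogen patches inside each farmland
  micro <- 2 * g * ifelse(design$rep_id %% 2 == 0, 1, -1)

  with_seed(spec$seed + 2, {
    base_ab <- stats::rlnorm(n_tot, meanlog = 0, sdlog = 0.6)
    names(base_ab) <- tree$tip.label
    base_neutral <- stats::rlnorm(n_tot, meanlog = 0, sdlog = 3)
    names(base_neutral) <- tree$tip.label
    contam <- if (spec$n_contaminants > 0)
      tree$tip.label[(n_prot + 1):n_tot] else character(0)
    base_ab[contam] <- base_ab[contam] * 0.15  # contaminants kept rare
    base_neutral[contam] <- base_neutral[contam] * 0.15

    E <- mode_e[design$cultivation_mode] + stage_e[design$growth_stage] +
      micro + stats::rnorm(n_samp, 0, 0.3)

    # per-mode compositional signature (management filter), independent of
    # the phylogeny
    mode_factor <- matrix(stats::rlnorm(n_tot * 3, 0, 0.4), n_tot, 3,
                          dimnames = list(tree$tip.label, modes))

    counts <- matrix(0, n_samp, n_tot,
                     dimnames = list(sample_ids, tree$tip.label))
    for (s in seq_len(n_samp)) {
      if (spec$assembly_mode == "selection") {
        w <- base_ab * mode_factor[, design$cultivation_mode[s]] *
          stats::rlnorm(n_tot, 0, 0.3) *
          exp(-(niche - E[s])^2 / (2 * spec$niche_breadth^2))
      } else {
        # neutral: one heavy-tailed regional profile shared by all samples,
        # weak per-sample drift; membership turnover then comes from
        # sampling rare taxa in and out, which is what both null models
        # assume of neutral assembly
        w <- base_neutral * stats::rlnorm(n_tot, 0, 0.3)
      }
      # contaminants do not follow the protist assembly process: a small
      # fixed share (~3%) of the protist read mass in every sample
      if (length(contam)) {
        share <- base_ab[contam] * stats::rlnorm(length(contam), 0, 0.3)
        prot <- setdiff(names(w), contam)
        w[contam] <- 0.03 * sum(w[prot]) * share / sum(share)
      }
      depth <- stats::rpois(1, spec$depth_mean)
      counts[s, ] <- stats::rmultinom(1, depth, prob = w)[, 1]
    }

    # taxonomy: protist tips spread over four clades cut from the tree so
    # lineages are phylogenetically coherent and hit all three trophic modes
    prot_tips <- tree$tip.label[seq_len(n_prot)]
    pd_prot <- ape::cophenetic.phylo(tree)[prot_tips, prot_tips]
    clade <- stats::cutree(stats::hclust(stats::as.dist(pd_prot), "average"),
                           k = min(4, n_prot))
    lineage <- SYNTH_LINEAGES[((clade - 1) %% length(SYNTH_LINEAGES)) + 1]
    tax <- data.frame(asv_id = prot_tips, lineage = unname(lineage))
    if (length(contam)) {
      tax <- rbind(tax, data.frame(
        asv_id = contam,
        lineage = rep_len(SYNTH_CONTAMINANTS, length(contam))))
    }

    metadata <- data.frame(sample_id = sample_ids,
                           cultivation_mode = design$cultivation_mode,
                           growth_stage = design$growth_stage)

    soil <- simulate_soil(design, E, n_samp)
    soil <- cbind(sample_id = sample_ids, soil)

    qshift <- c(greenhouse = -1, hilly = 0.6, paddy = 0.4) *
      spec$quality_effect
    quality <- simulate_quality(design, qshift, n_samp)
    quality <- cbind(sample_id = sample_ids, quality)

    community_dataset(counts, tax, tree, metadata, soil, quality)
  })
}

# 15 named soil variables; nitrogen pools (TN, ammonia, nitrate, nitrite)
# are functions of the gradient E so that the planted selection pressure is
# recoverable from the soil table
simulate_soil <- function(design, E, n) {
  mode <- design$cultivation_mode
  m <- function(gh, hi, pa) c(greenhouse = gh, hilly = hi, paddy = pa)[mode]
  noise <- function(sd) stats::rnorm(n, 0, sd)
  data.frame(
    pH = m(6.3, 7.8, 7.9) + noise(0.15),
    moisture = m(23, 20, 21) + noise(1),
    TN = 1.5 + 0.12 * E + noise(0.3),
    TP = m(0.6, 1.1, 0.9) + noise(0.05),
    TK = m(14, 22, 19) + noise(0.8),
    AP = m(18, 32, 28) + noise(1.5),
    AK = m(110, 180, 170) + noise(8),
    ammonia = 12 + 1.2 * E + noise(2.5),
    nitrate = 20 + 2 * E + noise(4),
    nitrite = 0.8 + 0.06 * E + noise(0.15),
    DOC = m(95, 150, 145) + noise(6),
    ALP = m(11, 19, 18) + noise(1),
    beta_Glu = m(24, 35, 33) + noise(1.8),
    urease = m(16, 28, 21) + noise(1.2),
    cellulase = m(7, 11, 10) + noise(0.5))
}

# 12 fruit-quality parameters with a planted per-mode shift of
# 0.8 * qshift standard deviations around realistic Eureka-lemon means
simulate_quality <- function(design, qshift, n) {
  means <- c(fruit_weight = 150, fruit_width = 55, fruit_height = 85,
             fruit_shape_index = 1.55, pericarp_thickness = 6,
             pericarp_weight = 40, valve_number = 10, valve_weight = 95,
             seed_number = 12, seed_weight = 3, solid_rate = 0.35,
             edible_rate = 0.62)
  sds <- 0.08 * means
  shift <- qshift[design$cultivation_mode]
  out <- lapply(QUALITY_PARAMS, function(p) {
    means[p] + 0.8 * shift * sds[p] + stats::rnorm(n, 0, sds[p])
  })
  names(out) <- QUALITY_PARAMS
  as.data.frame(out)
}
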