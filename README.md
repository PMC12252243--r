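# soilprotist

Downstream analysis of soil protistan communities (18S V9 amplicon ASV
tables) surveyed across crop cultivation modes and growth stages, built
around the question the package's motivating field system poses: how does
converting farmland to greenhouse cultivation reshape the soil protistan
community, which ecological processes assemble that community, and does any
of it track the quality of the crop?

The package is aimed at microbial ecologists who have an ASV count table,
a PR2-style taxonomy, a rooted phylogeny and per-sample metadata, and want
the standard downstream battery as tested, seeded, scriptable functions:

- **Preparation** — lineage exclusion (`Fungi`, `Metazoa`, `Embryophyta`),
  singleton removal, seeded rarefaction without replacement (default depth
  18,907).
- **Diversity** — Chao1, Shannon, Pielou, root-inclusive Faith PD;
  Bray–Curtis distances; PCoA; one-way PERMANOVA; Tukey HSD group
  comparisons; within-group dispersion.
- **Community assembly** — the phylogenetic null-model battery. betaMNTD
  (abundance-weighted mean nearest taxon distance), betaNTI from tip-shuffle
  nulls, abundance-based Raup–Crick, and the five-process partition:

  ```
  betaNTI = (betaMNTD_obs − mean_null) / sd_null

  betaNTI >  +2                heterogeneous selection
  betaNTI <  −2                homogeneous selection
  |betaNTI| ≤ 2, RC > +0.95    dispersal limitation
  |betaNTI| ≤ 2, RC < −0.95    homogenizing dispersal
  |betaNTI| ≤ 2, |RC| ≤ 0.95   drift
  ```

- **Trophic traits** — consumer / phototrophic / parasitic assignment from
  lineages with a most-specific-rank-wins rule and a replaceable trait map.
- **Production index** — the multifunctionality-style composite quality
  score: per-parameter z-scores averaged within samples, regressed on
  diversity and composition.
- **Drivers** — Hellinger RDA of the community on soil variables and a
  random-forest ranking of soil drivers by out-of-bag permutation
  importance.
- **Synthetic data** — a generator that emulates the 3-mode × 2-stage field
  design with Brownian (phylogenetically conserved) niches along a
  nitrogen-like gradient, planted quality effects, and contaminant
  lineages, so the whole pipeline is testable without sequencing data.

## Worked example

```r
library(soilprotist)

# a full synthetic survey: 3 modes x 2 stages x 6 samples, 40 protist ASVs
ds <- simulate_dataset(scenario_spec("selection", seed = 7))
ds <- prepare_dataset(ds, depth = 18907, seed = 42)

alpha <- alpha_diversity_table(ds)
bc    <- bray_curtis(ds)
permanova(bc, sample_groups(ds, "mode"), n_perm = 999, seed = 1)

asm <- assembly_analysis(ds, n_null = 199, seed = 3)
selection_fraction(asm)

pi <- production_index(ds)
tapply(pi$index[ds$metadata$sample_id], ds$metadata$cultivation_mode, mean)
```

Output from this exact script:

```
> permanova(bc, sample_groups(ds, "mode"), n_perm = 999, seed = 1)
$pseudo_F  6.1
$R2        0.270
$p_value   0.001

> selection_fraction(asm)
[1] 0.731

> tapply(pi$index[ds$metadata$sample_id], ds$metadata$cultivation_mode, mean)
greenhouse      hilly      paddy
    -0.752      0.388      0.364
```

Reading: cultivation mode explains 27% of the Bray–Curtis variation
(PERMANOVA p = 0.001); about three quarters of within-farmland sample
pairs are classified as assembled by deterministic selection
(|betaNTI| > 2); and the greenhouse carries the planted composite-quality
deficit (lowest group-mean production index).

The whole pipeline also runs as one call with a config, writing per-stage
TSVs and a hash-bearing run manifest:

```r
run_pipeline(list(simulate = "selection", seed = 1, out_dir = "out",
                  n_null = 199, n_perm = 999))
```

or from a shell via the thin wrapper:

```sh
Rscript inst/scripts/pipeline.R --simulate selection --seed 1 --out out
```

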