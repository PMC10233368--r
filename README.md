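# dotscreen

Analysis of pairwise proximity-biotinylation interaction screens read out
on high-density dot-blot membranes — written for groups running
BirA/AviTag ("bait biotinylates prey on contact") screens of two competing
baits, such as the ER translocons Sec61 and Ssh1, against a genome-wide
prey library.

Each membrane carries a 1,536-dot array (32 × 48) spotted from yeast
lysates, imaged in two channels: fluorescent streptavidin (biotinylation
signal, SA) and anti-histone-H3 (loading control, LC). The pipeline:

1. **Quantify** — fit the dot lattice on each membrane image (least-squares
   affine fit to detected spot centroids, tolerant of a few degrees of
   rotation) and measure every dot in both channels, subtracting a local
   annulus background.
2. **Normalize & QC** — per dot compute the SA/LC ratio; per bait–prey set
   take the median of the nine replicates (3 biological × 3 technical);
   exclude sets whose strain was missing pre-lysis (OD600 below floor) or
   whose aggregate sits more than 10 SD *below* the rest of the membrane
   (leave-one-out Z, one-sided); flag replicate SD > 3.
3. **Call preferences** — with aggregates `s_A`, `s_B` and fold change
   `max(s_A, s_B) / min(s_A, s_B)`, a prey *prefers* a bait when the fold
   change is strictly greater than 2; below-floor signals on both sides
   mean no interaction; the result is one of
   `{excluded, no_interaction, both, prefers_A, prefers_B}`.
4. **SP hydropathy** — filter preys to candidate substrates
   ((SP or TMD) and not MTS), and compare per-position Kyte–Doolittle
   profiles of the signal peptides across preference groups
   (mean ± SEM per position, no window smoothing), including 3-residue
   prefix-swap variants and SP-only reporter constructs.

A synthetic screen generator (`screen_config()` / `generate_screen()`)
renders two-channel 16-bit membranes with planted interaction strengths,
replicate noise, missing strains and dropout artifacts, so the whole
pipeline is testable against known ground truth without any external
data. See `vignettes/dotscreen-methods.Rmd` for the model and all
numerical choices.

## Worked example

```r
library(dotscreen)

cfg <- pipeline_config(
  screen = screen_config(n_preys = 96, grid_rows = 16, grid_cols = 24,
                         seed = 5),
  seed = 5)
res <- run_pipeline(cfg)
res
```

```
Proximity-biotinylation screen result
  preys called: 96
    excluded       4
    no_interaction 45
    both           28
    prefers_A      9
    prefers_B      10
  excluded sets: 4 | replicate-SD flags: 0
```

The 96 synthetic preys were planted as 50% non-interactors, 30% equal
interactors and 10% + 10% preferring either bait at a fourfold planted
difference; the screen recovers that partition. The four exclusions are
exactly the four planted missing strains, caught by the pre-lysis OD
rule (`res$pairs$exclusion_reason` names the failing bait side for each).
`res$pairs` holds the per-prey calls with fold changes and exclusion
reasons, `res$sets` the per-bait aggregates with Z-scores, and
`res$profiles` the per-position hydropathy of each preference group's
signal peptides.

A thin command-line front end with `simulate`, `quantify`, `call`,
`sp-profile` and `run` subcommands is installed at
`system.file("cli", "dotscreen", package = "dotscreen")`.

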