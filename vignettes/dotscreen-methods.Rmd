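---
title: "Methods: dot-blot screen quantification and preference calling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dot-blot screen quantification and preference calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The assay and the analysis problem

dotscreen analyses pairwise proximity-biotinylation screens read out on
high-density dot-blot membranes.  Each prey protein carries an N-terminal
AviTag; each of two bait proteins (here the ER translocons Sec61 and Ssh1)
carries the biotin ligase BirA.  When bait and prey come into physical
proximity in vivo, the prey's AviTag is biotinylated, and the biotinylation
level of each strain's lysate — spotted robotically as a 1,536-dot array
(32 × 48) on a nitrocellulose membrane — is read with fluorescent
streptavidin.  A second channel, anti-histone-H3, reports how much protein
was actually spotted and serves as the loading control (LC).  The design
yields nine replicate measurements per bait–prey pair: three biological
replicates, each membrane carrying three technical replicates pinned from
384-position source plates.

The analysis must (i) locate and quantify every dot in both channels,
(ii) normalize the streptavidin signal by the loading control (the SA/LC
ratio), (iii) aggregate the nine replicates with quality control, and
(iv) classify each prey as preferring one bait over the other when its
normalized signal differs by more than twofold.

# Dot quantification

**Grid fitting.** Spots are detected by thresholding each channel at its
median + 5 MAD and labelling connected components (≥ 4 px).  The lattice
is then fitted by least squares: an initial rotation estimate comes from
the median orientation of axially adjacent centroid pairs (pair distances
restricted to 0.8–1.25 × the nearest-neighbour spacing, below √2 × spacing
so diagonal pairs cannot contaminate the estimate), after which integer
lattice indices are assigned and an affine model (origin, per-axis
spacing, rotation) is refitted iteratively.  The fit aborts if the
residual RMS exceeds 0.25 × spacing.  On synthetic membranes the planted
origin and spacing are recovered to well under 0.1 px for rotations up to
2°.

**Measurement.** Each dot is summed over a disk ROI of radius
0.4 × spacing.  The local background per channel is the median of a thin
annulus at 0.45–0.5 × spacing — inside the neighbouring dots at 1,536
density — and `corrected = max(raw − background × area, 0)`.  Summed (not
mean) intensity is the contract; the median-of-annulus estimate is exact
for a locally planar background, which is why a planted planar gradient
does not bias empty positions.  Negative corrected values are clipped at
zero: intensities are physical nonnegatives and downstream ratios must not
change sign.  ROIs that cross the image border are measured on the
available pixels and flagged, never dropped, so every grid position yields
exactly one measurement.

# Normalization, aggregation and exclusion rules

Each dot's SA/LC ratio is `signal_corrected / control_corrected`.  A
control below 5% of the bait's median control intensity marks the dot
invalid (a missing or failed spot) rather than producing an unbounded
ratio; the floor is relative, so channel rescaling does not change
validity calls.

The aggregate per bait–prey set is the **median** of its valid replicate
ratios (robust to a single pin or transfer artifact), with the sample SD
kept for the reproducibility record; fewer than 3 valid replicates refuse
aggregation.  A set is excluded when:

* its strain was missing before lysis (pre-lysis OD600 below 0.2, or the
  strain is absent from the OD table);
* too few valid replicates survived;
* its aggregate lies more than 10 SD **below** the rest of its membrane
  group — the leave-one-out mean and SD over the other QC-passing sets of
  the same bait.  The rule is strictly one-sided: high outliers are the
  strong interactors the screen exists to find.

"Rest of the membrane" is implemented per bait (pooling its three
bio-replicate membranes, which share one layout and normalization) because
the aggregate being tested already spans those membranes.  Sets whose
replicate SD exceeds 3 are flagged for the reproducibility report but not
excluded.

**A known limitation of the Z rule.** On a membrane whose aggregates are a
broad mixture — e.g. half the preys are non-interactors near zero — the
population SD is large and no set can sit 10 SD below the mean; each
additional artifact also inflates the SD and shelters the others.  The
rule is effective exactly where it is meant to act: catching rare
transfer/edge dropouts against an otherwise tight population.  The
validation suite therefore exercises it on all-equal membranes and checks
agreement with an independent leave-one-out oracle, rather than assuming
every planted artifact crosses the threshold.

# Preference calling

With aggregates $s_A$ and $s_B$ for the two baits, the fold change is the
symmetric $\max(s_A, s_B) / \min(s_A, s_B)$, so the threshold acts
identically in both directions, and the rule is **strict**: a preference
requires fold change > 2 (a ratio of exactly 2 is "both").  Both signals
below the detection floor give `no_interaction`.  When exactly one signal
is above the floor the other is indistinguishable from background, so the
fold change is computed against the floor and the same strict rule
applies; this keeps "prefers" synonymous with "fold change > threshold"
everywhere and makes the call monotone in the signals.  A prey whose set
failed QC on either bait is `excluded`.  The five categories are mutually
exclusive and exhaustive, so category counts always sum to the number of
preys.

**Detection floor.** The screen itself never defines how "did not
interact" is scored, so the floor is an explicit parameter.  The default
(`"auto"`) estimates, per bait, the ratio an empty position would produce:
the 95th percentile of background-corrected signal at unmapped grid
positions divided by the median corrected control of mapped dots, pooled
over the bait's membranes.  Because numerator and denominator come from
the same membranes, rescaling either channel rescales the floor
identically — category calls are invariant under (a) a channel gain applied
to all membranes and (b) both channels of one membrane rescaled (an
exposure change).  Scaling one channel of only one bait's membranes
changes A-vs-B fold changes by construction: aggregates are compared
across membranes without cross-membrane scaling, which is the stated
contract.  Grids packed with no empty positions require a numeric floor; a
value of 0.05 sits two orders of magnitude above the empty-position ratio
(~10⁻³ at the default imaging parameters) and far below the ratio of a
genuine interactor (~1).

# The synthetic screen generator

The generator is the package's ground-truth instrument.  Its defaults
reproduce the screen's design: a 32 × 48 array, two baits, 3 × 3
replicates, and a prey panel partitioned into non-interactors (50%),
equal interactors (30%) and preys preferring either bait (10% + 10%) at a
planted fold change of 4.  Per dot, the loading-control intensity is
`control_scale × load` and the signal intensity is
`true_signal × load × e`, with `load` and `e` independent lognormal
factors of mean 1 and CV 0.1 (multiplicative noise is the natural model
for nonnegative blot intensities; `load` is shared between channels
because both see the same spotted material).  Preferring preys carry
`true_signal = 20,000` counts with the preferred bait and `20,000 / 4`
with the other; missing strains (2%) have near-zero OD and 1% load;
dropout sets (1%) have their signal multiplied by 10⁻³.  Spots are 2-D
Gaussians (σ = 1.5 px, truncated at 3σ and renormalized so the rendered
sum equals the planted intensity exactly) at 12 px spacing on a planar
background (500 counts, default slope 0.2 counts/px) with 5-count read
noise, quantized to 16 bits.  Because 3σ = 4.5 px < ROI radius 4.8 px and
the annulus starts at 5.4 px, a noise-free dot is recovered to within
rounding (< 1%), and neighbours cannot bleed into either the ROI or the
annulus.

**Replicate layout.** How three technical replicates map into the
384 → 1,536 pinning pattern is not part of the published design, so the
generator makes it explicit: the default `quadrant` layout places them in
positions 1–3 of each prey's 2 × 2 block and leaves the fourth position
empty — those empties double as the on-membrane blanks that feed the auto
detection floor.  A `rowmajor` layout packs replicates consecutively and
can fill the grid completely (512 preys × 3 = 1,536), which is the
configuration used for the large recovery benchmark (with a numeric
floor, since no blanks remain).

**Synthetic signal peptides.** `generate_sp_set()` draws sequences whose
expected Kyte–Doolittle value at each position equals a target profile
exactly (each residue is sampled from the two scale values bracketing the
target with matching mixture weights), so group profiles converge to their
targets and a target of ±4.5 forces all-Ile/all-Arg sequences.  In fully
synthetic pipeline runs, preys preferring bait A receive SPs with
hydrophobic first three residues (target +3.8), bait-B preys hydrophilic
ones (−3.0), and shared interactors intermediate ones — a deliberately
simple stand-in encoding "the preference information lives in the first
three residues", which is what the prefix-swap and SP-only reporter logic
then recovers (`sp_planted_preference()` scores the mean hydropathy of
residues 1–3).

**What the generator does not emulate** — and hence what passing tests do
not show about real membranes: spot shape irregularity and bleed-over,
dust and scratches, spatially correlated (non-planar) background,
saturation, chemiluminescent film response, plate-position effects
correlated with biology, and real SP sequence composition beyond its
hydropathy profile.  Results on synthetic screens validate the machinery,
not the wet-lab assay.

# Signal-peptide hydropathy analysis

Candidate translocon substrates are preys with a signal peptide or a
transmembrane domain and no predicted mitochondrial targeting signal
(annotations are inputs; prediction tools are out of scope).  Group
profiles average the Kyte–Doolittle value of residue *p* over all SPs of
length ≥ *p* (first 25 positions by default), with SEM = SD/√n and n(p)
reported per position; a single-sequence group reports SEM 0 with n = 1
flagging the convention.  **No window smoothing is applied by default**:
the biological signal of interest is confined to positions 1–3, and a
sliding window would blur exactly that; a window option exists for
conventional hydropathy plots.  `swap_prefix()` exchanges the first k = 3
residues of two SPs (an exact involution), and `build_reporter()` models
the SP-only mCherry/AviTag reporter whose simulated preference follows its
SP donor — swapped constructs follow the prefix donor.

# Numerical choices and degenerate inputs

* Lognormal noise with CV c uses `sdlog = sqrt(log(1 + c²))` and mean 1.
* Category counts are `round(fraction × n)` with the largest class
  absorbing the ±1 rounding drift so the partition is exact.
* The leave-one-out Z uses sample SD over the n − 1 remaining sets
  (denominator n − 2); with duplicated data the SEM of a profile shrinks
  by √((n−1)/(2n−1)), i.e. √2 only asymptotically — the sample-SD
  convention is asserted as such in the tests.
* Blank images, empty ratio lists, zero-length sequences, unknown
  residues, duplicate FASTA ids, missing table columns and non-numeric
  cells all fail fast with messages naming the offending record.
* All randomness flows through a single integer seed; identical
  configurations produce byte-identical screens, images and result files.

# Validation problem sizes

The bundled validation suite generates everything it tests at run time:
16 × 24 / 96-prey screens for quantification, grid-recovery (rotations
0–2°), invariance and IO checks; one 32 × 48 / 512-prey, 6-membrane run
for preference recovery (≥ 95% of planted preferring preys recovered,
≤ 5% false preferences); and one all-equal 384-prey run with planted
missing strains and dropouts for the exclusion rules.  These sizes keep a
full run in a few minutes while exercising every rule at the screen's
true array density and replicate design.
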