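---
title: "Linkage mapping and homeology detection in a pseudo-tetraploid genome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linkage mapping and homeology detection in a pseudo-tetraploid genome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tetramap)
```

## The problem

Salmonid genomes descend from a whole-genome duplication and are still
returning to a diploid state.  Large chromosome segments (homeologs) remain
duplicated and similar enough that a SNP assay often reads the *sum* of two
loci.  Such multisite variants (MSVs) show mixed allelic ratios: with one
segregating paralog the allelic-ratio coordinate theta clusters at
\{0, 1/4, 1/2\} or \{1/2, 3/4, 1\} (MSV-3); with both paralogs segregating it
clusters at all five quarter-grid values (MSV-5).  Standard diploid callers
fail on these markers, and discarding them biases linkage maps exactly in
the duplicated regions one most wants to see.  tetramap implements the full
chain: polyploid-aware genotype calling, sex-specific linkage-map
construction, and detection of homeologous chromosome-arm pairs — plus a
synthetic-data generator that emulates the salmon family material so every
stage can be validated at desk scale against known truth.

## The simulator and what it emulates

`sim_config()` / `simulate_dataset()` generate a genome model, pedigree,
meioses, intensities and sequences.  Design choices:

* **Chromosome axis.** Each chromosome lives on an abstract axis
  $u \in [0,1]$.  Female map positions are $u \cdot L_f$; male positions are
  $L_m F_m(u)$ where $F_m$ is the male crossover-density CDF.  Crossover
  counts are Poisson($L/100$) with no interference, so recombinant
  fractions obey Haldane's map function,
  $r = \tfrac12(1 - e^{-2d/100})$, exactly.  No interference is assumed
  because the downstream mapping functions are two-parameter anyway and
  the source material states none.
* **Male telomeric recombination.** The male density is a mixture of a
  uniform component (weight 0.2 by default) and triangular kernels of
  width 0.1 at the chromosome ends, with per-end weights; a suppressed end
  gets weight 0.  These kernel parameters are free parameters of the
  emulation — the real pattern is known qualitatively (male crossovers
  concentrate near telomeres; some metacentrics show only one elevated
  end) but no published density exists.
* **Defaults are the study conditions**: 29 chromosomes with the published
  sex-specific lengths (shipped as a fixture), overall female:male ratio
  1.37–1.38, 21% MSV markers, four strong homeolog pairs (2p–5q, 3q–6p,
  4p–8q, 7q–17q) at sequence divergence 0.05, 0.5% genotyping error, 2%
  missingness.  The default pedigree is 10 full-sib families in 5
  paternal half-sib groups (100 offspring) — a deliberate desk-scale
  reduction of the ~143-family, ~3300-fish design that the same generator
  reproduces by raising the design counts.
* **Intensities.** theta = class center + Gaussian noise, clamped to
  [0, 1]; MSV noise (0.02) is tighter than SNP noise (0.04), reflecting
  the tighter packing of mixed-ratio clusters; total intensity R is an
  independent log-normal and is used only as an optional QC covariate.
* **Sequences.** Flanks are i.i.d. uniform nucleotides; the substitution
  model replaces each site once, with probability equal to the divergence,
  by a different base, so expected identity is exactly $1 - d$ (no
  multiple-hit correction is needed for this single-round model).  The
  synthetic outgroup genome carries one ancestral copy region per
  homeolog pair, holding mutated copies of both arms' flanks in map order.
* **Validation designs.** Two generator switches exist purely for
  parameter-recovery studies: `testcross` makes one parental sex
  heterozygous (phased 1|0) at every locus and the other homozygous — the
  classical fully-informative design for validating mapping software —
  and `marker_grid` re-spaces markers evenly.  Uniform random placement
  puts some markers well under 1 cM apart, where no finite family set can
  resolve order; the even grid keeps the ordering task well-posed.  The
  outbred defaults stay in force for pipeline demonstrations.
* **Pseudo-linkage** is emulated, not modelled: male gametes of a homeolog
  pair are re-coupled with a configurable probability so that
  grandparental origins at the paired arms agree.  True quadrivalent
  meiosis is out of scope.

What passing tests on these simulations do *not* show: robustness to
two-channel normalization artefacts, batch effects, segregation
distortion, or map expansion from chimeric assemblies — none of which the
generator emulates.

## Genotype calling

`fit_clusters()` fits 1-D Gaussian mixtures with 1..5 components to each
marker's theta values and picks the component count by BIC.  Numerical
choices that matter:

* a **shared component variance** (floored at 0.001) — all clusters of one
  assay share the same noise and a common variance removes the degenerate
  likelihood spikes of free-variance 1-D mixtures;
* **deterministic multi-start**: the quantile grid, an equal-spaced grid,
  and every contiguous window of the canonical quarter and half grids.
  There is no random initialization, so fits are reproducible;
* a **minimum center separation** of 0.1 for a model to be eligible:
  clamping theta at 0/1 leaves boundary point masses that a mixture would
  chase by splitting clusters, while genuine dosage clusters sit at least
  0.25 apart;
* EM tolerance 1e-8, at most 500 iterations.

`classify_marker()` applies the cluster-pattern rules (five clusters →
MSV-5; diploid grid → SNP; tight quarter-grid half → MSV-3 with the fixed
paralog's dosage offset recorded; one cluster → monomorphic; anything else
fails QC).  The MSV-3 tightness gate (`tight_sd = 0.03`) and the center
tolerance (0.08) are configurable; they operationalize the qualitative
observation that mixed-ratio clusters are much more tightly positioned
than diploid ones.  `call_genotypes()` assigns maximum-posterior dosages
(centers map linearly to 0..2 for SNPs, 0..4 for MSVs) and sets calls
below posterior 0.95 missing.  QC thresholds (call rate ≥ 0.9, Mendelian
error rate ≤ 0.02, pedigree-error flag at 10× the cohort median
opposing-homozygote rate) are declared defaults, not published values.

## MSV-5 resolution and its limits

Within a full-sib family, `resolve_msv5()` enumerates all parental
two-locus configurations consistent with the parents' dosages — up to the
joint locus-relabelling symmetry, which is unidentifiable — and scores
them by the multinomial likelihood of the offspring dosage counts with the
two loci unlinked (they lie on different, homeologous chromosomes).
Ambiguity is never guessed: offspring whose dosage admits several locus
splits under the best configuration, or who differ between configurations
within 2 log10 units of the best, are set missing.

Two structural facts shape everything downstream:

1. In a family whose configuration leaves some dosage ambiguous, the
   *retained* offspring are those with extreme dosages, whose two locus
   genotypes are equal — the two locus columns become near copies of each
   other and would fake linkage between one locus and the other's
   neighbourhood.  Only fully determinate ("complete") families therefore
   contribute meioses to the grid.
2. A complete family necessarily segregates at only **one** of the two
   loci (if both varied, dosage sums would collide).  Dual placement of an
   MSV-5 hence combines single-arm placements voted by *different*
   families (`place_msv5_loci()`), which is invariant to the per-family
   label swap and needs no cross-family harmonization.  The pooled grid
   columns used for map integration are additionally harmonized greedily
   by matching phase-folded recombination signatures against SNP columns.

## Two-point estimation

`build_meiosis_grid()` deduces, per parent–offspring meiosis and marker,
the transmitted allele where the parent is heterozygous and the deduction
is unique given the other parent; Mendelian impossibilities are counted
and set unknown.  A deduction that succeeded only because of the other
parent's transmission (other parent heterozygous or unknown) is flagged
*conditional*: at a pair of linked markers the other parent's
transmissions are correlated, so cells conditional at **both** markers are
a biased sample of the focal parent's recombination events (simulations
show ~25% map shrinkage if they are kept) and the pair estimators drop
them.

`estimate_twopoint()` treats each parent's linkage phase as a hidden
variable with prior 1/2 and maximizes the likelihood in r by EM.  This
matters for pedigrees with many small sibships: profiling the phase out
(folded counts) makes a parent with a single doubly-informative meiosis
look perfectly non-recombinant, biasing r downward, whereas under the
mixture such parents are exactly neutral.  The reported LOD is the log10
likelihood ratio against r = 1/2 with phases profiled at the optimum, so
the classical closed forms hold (a fully linked pair of n meioses scores
n·log10 2; with known phase the estimator is the plain count fraction).

`group_markers()` seeds linkage groups from anchor markers (markers with
published chromosome assignments), then attaches the remaining markers
stepwise, most informative first, when pooled LOD ≥ 5 and r ≤ 0.35
(defaults; the r cap prevents chaining through spurious long-range links).
Markers linking two differently-anchored groups are flagged and left
unplaced; markers linking several unanchored groups merge them.  Note that
strong pseudo-linkage can legitimately chain homeologs into one group at
lax thresholds — the reason the original analysis seeded groups with
anchors.  `detect_pseudolinkage()` then reports cross-group pairs with
male LOD ≥ 3 while the female data show free recombination (r ≥ 0.4) —
a declared operationalization; the male-only criterion reflects that
residual tetrasomic pairing is male-specific.

## Ordering, phase strings and sex-specific maps

`build_order()` works on female meioses only (male recombination is too
localized to order by).  The multipoint criterion is the first-order
product of adjacent-interval likelihoods: the sum over adjacent pairs of
the log10 likelihood at the ML recombination fraction.  A tightly linked
adjacency costs ~0 regardless of informativeness; an unlinked one costs
about 0.3 per doubly-informative meiosis.  Markers are inserted at the
best-scoring position, with two unplacement rules: a support margin
(best minus second-best position < 3 log10 units) and a map-expansion cap
(interior insertion expanding the map by > 10 cM beyond the direct
two-point distance).  Deferred markers are retried after the framework
grows; `improve_order()` then slides a window (default 4) over the order
and accepts any permutation improving the combined female+male criterion
until a full pass changes nothing.  Everything is deterministic; ties keep
the incumbent.

`phase_strings()` assigns grandparental-origin symbols per meiosis by
resolving each parent's phase greedily along the order (each marker
oriented to minimize switches against each meiosis's most recent
informative symbol).  `correct_double_recombinants()` blanks the genotype
behind any informative symbol that differs from both flanking informative
symbols when the flanks lie within 10 cM — a double crossover in such a
span is overwhelmingly more likely a genotyping error — in a single pass,
after which maps are re-estimated.

`estimate_sex_maps()` converts per-interval ML recombination fractions to
cM with Kosambi's function by default ($d = 25\ln\frac{1+2r}{1-2r}$, the
CRIMAP convention); Haldane is selectable and is what the package's own
parameter-recovery simulations use, because the simulator is
interference-free.  The mapping function is recorded on the output.
Intervals with no doubly-informative meioses in a sex are imputed 0 and
flagged.  `summarize_maps()` renders the published-table layout (lengths
to 1 decimal, ratios to 2), and `recombination_localization()` indexes the
fraction of male crossovers in the distal 20% of the female span at each
chromosome end, flagging ends above twice the uniform expectation.

## Homeology evidence

Three independent sources are combined by `assert_homeologies()` under the
minimum-of-three rule — a pair of chromosome arms is asserted homeologous
only when at least one *single* source contributes ≥ 3 counts; combined
sub-threshold evidence never asserts (the conservative reading of the
safeguard against false positives):

1. **Dual-locus MSV-5 placements** (`place_msv5_loci()` +
   `msv5_homeologies()`), as above.
2. **Within-genome paralog hits** (`find_paralog_hits()`): an internal
   deterministic k-mer-seeded (k = 16) ungapped aligner, keeping
   cross-arm hits with ≥ 85% identity over ≥ 100 bp.  An adapter
   (`read_tabular_hits()`) accepts 12-column tabular output from an
   external aligner for real-data use.
3. **Outgroup synteny anchors** (`map_anchor_hits()` +
   `anchor_homeologies()`): flanks are anchored on an outgroup genome only
   when the best hit outscores the second best by > 10%; anchors are
   clustered into segments along outgroup chromosomes (gap tolerance
   10 kb) and two arms sharing a segment with ≥ 3 anchors *each* qualify.

Ambiguous multi-arm matches are reported as compound labels, never
resolved by fiat.

## Problem sizes used in validation

The shipped tests and the acceptance script validate at these scales,
chosen as the smallest designs where the statistical claims are
well-powered: interval-r recovery and map-length/ratio recovery use
fully-informative testcross designs with 2000 meioses per sex (100
families of 20); ordering uses 20 evenly spaced markers over 100 cM and
500 female meioses; double-recombinant correction uses 25 markers at 4 cM
spacing, 300 meioses and 1% injected error over 10 replicates; homeology
recovery uses 8 chromosomes, 4 homeolog pairs at divergence 0.05 and 120
markers over 5 seeds.  The genome-wide sex-ratio check sums four
chromosomes because a single chromosome's ratio estimate at 2000 meioses
has a standard error of ~0.04, too wide to test a ±0.05 band.

## Known limitations

* The multipoint criterion is first-order (adjacent intervals only); an
  adjacency with no doubly-informative meioses is scored 0 and order
  around such gaps relies on the window refinement.  A full hidden-state
  chain over all markers would share information across gaps.
* Map ends are invisible: no estimator can see crossovers distal to the
  terminal markers, so male maps with strong telomeric kernels are
  under-covered at the ends, and ratio-recovery simulations use a uniform
  male density for exactly this reason.
* MSV-5 dual placement needs families that segregate at different loci of
  the pair; dosage data alone cannot dual-place a marker within one
  family.
* The published map totals differ slightly between the per-chromosome
  table (2403/1752.9, ratio 1.37) and the abstract (2402.3/1746.2, ratio
  1.38); the package reproduces the table arithmetic and leaves the
  discrepancy as published.
* Real bead-array data need two-channel normalization before theta is
  meaningful; the package starts from theta and does not model batch
  effects.
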