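---
title: "Methods: Ty1 landscapes, divergence and copy-number-control statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Ty1 landscapes, divergence and copy-number-control statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tyland)
```

## The problem this package addresses

Ty1 is a long terminal repeat (LTR) retrotransposon of *Saccharomyces*
yeasts with the structure LTR–*gag*–*pol*–LTR.  Ty1 copy number is held
in check by copy number control (CNC): a truncated Gag product, p22 (and
its processed form p18), encoded in the C-terminal half of *gag*,
represses transposition with a strength that scales with the genomic dose
of compatible *gag* sequence.  Because *S. cerevisiae* carries two
diverged Ty1 subfamilies — the ancestral Ty1′ and the canonical subfamily
typified by the Ty1-H3 tester element, which differ chiefly in *gag* —
a strain's ability to restrict a canonical tester element depends not on
total Ty1 copy number but on how many of its full-length elements carry a
canonical-type *gag*.  Recombination between subfamilies produces mosaic
elements (canonical *gag* joined to Ty1′ *pol* near the *gag*/*pol*
boundary), so classification has to be made region by region, not per
element.

`tyland` implements the complete computational path from raw
repeat-annotation hits to that genotype–phenotype statistic:

1. **Curation** (`annotate_ty()` and its parts): raw RepeatMasker-style
   hits are filtered, repaired and grouped into structurally classified
   Ty elements (full-length / truncated / solo LTR) with BED12 output and
   per-family counts.
2. **Sequence analysis** (`extract_sequences()`, `project_truncated()`,
   `check_orf_capacity()`, MSA utilities): strand-aware element
   extraction, projection of truncated elements onto the Ty1-H3
   reference, and p22/p18 coding-capacity checks.
3. **Divergence and clustering** (`k2p_distance()`,
   `sliding_window_divergence()`, `build_tree()`,
   `bootstrap_supports()`): Kimura 2-parameter distances, windowed
   divergence tracks, NJ/BIONJ clustering with bootstrap supports.
4. **Recombination classification** (`assign_windows()`,
   `call_breakpoints()`, `classify_element()`): windowed assignment of a
   query to the nearer of two subfamily references, breakpoint calling,
   and per-element subfamily calls.
5. **Assay statistics** (`mobility_frequency()`, `fold_change()`,
   `spearman()`, `fisher_exact_2x2()`, `count_substitutions()`,
   `ng86_dnds()`): mobility frequencies with replicate SDs, rank
   correlation of mobility with canonical-*gag* content, and
   substitution/selection summaries.
6. **Synthetic data** (`plant_genome()` and friends): genomes with
   planted elements and full ground truth, used as the oracle for every
   stage above.

## Models and conventions

### Kimura 2-parameter distance

For an aligned pair, with $P$ and $Q$ the proportions of transition and
transversion differences among usable sites,

$$d = -\tfrac12 \ln(1 - 2P - Q) - \tfrac14 \ln(1 - 2Q).$$

Sites where either row carries a gap or an ambiguity code are excluded
*pairwise* (pairwise deletion), not by removing the column from every
pair: the windowed analyses must remain defined over partially gapped
regions, and complete deletion would couple a window's value to rows not
being compared.  The transform is undefined when $1-2P-Q \le 0$ or
$1-2Q \le 0$; such pairs are reported as `NA` with reason `"saturated"`.
Windowed tracks use 50 bp windows with a 10 bp step (the package's
default resolution for element-scale divergence profiles) and require at
least `min_usable = 25` of the 50 sites to be usable; only full-width
windows are emitted, except that an alignment shorter than one window
yields a single truncated window.

### Curation of raw hits

Four editing operations repair the known error modes of library-based
repeat annotation, in this order:

* **(i) divergence filter** — hits with more than 20% divergence to the
  library sequence are removed.  The rule is *strictly greater than*:
  a hit at exactly 20.0% is retained.
* **(ii) LTR relabelling** — within a contiguous cluster of fragments
  (gap ≤ `gap_tolerance`) that contains a Ty1 or Ty2 internal fragment,
  LTR fragments named for the other family are renamed to the internal
  fragment's family.  Contiguity matters: a distal solo LTR that was
  wrongly joined into the group (error iv) is not part of the element's
  cluster and must keep its own name, otherwise it would be mis-assigned
  before the fused-solo split can rescue it.
* **(iii) tandem split** — a group whose fragments read
  LTR–I–LTR–I–LTR is split into component copies, the shared internal
  LTR duplicated into both copies (so per-element BED records may
  overlap at the shared LTR).
* **(iv) fused-solo split** — an LTR fragment outside the element body
  (beyond one flanking LTR per side, or separated by more than
  `gap_tolerance = 100` bp of non-Ty sequence) becomes its own solo-LTR
  record.

Structural classification then calls an element a solo LTR when no
internal fragment is present; otherwise full-length when its **total
length — the sum of aligned fragment lengths, not the genomic span —**
strictly exceeds 95% of the family's canonical length (5918 bp for Ty1,
5960 bp for Ty2), else truncated.  Summed fragment length was chosen over
genomic span because it measures sequence completeness and is insensitive
to nested insertions; the threshold's strict `>` direction follows the
stated full-length definition.  Solo-LTR counts for Ty1 and Ty2 are
pooled, since their LTRs are too similar for reliable family assignment.
Element ids are `<strain>_<f|t|s><serial>` with serials assigned in
ascending (chromosome, start) order, so ids are deterministic.

### Subfamily classification and breakpoints

A query aligned with two references is labelled window by window with the
nearer reference (by K2P distance).  A window is *ambiguous* when either
distance is undefined, the references are locally identical, or the
margin $|d_A - d_B|$ is below `margin_threshold = 0.02` substitutions per
site — roughly one substitution per 50 bp window, so single-substitution
noise cannot flip a label.  Breakpoints are called between maximal runs
of opposite labels after discarding informative runs shorter than
`min_run = 3` windows; ambiguous windows never break a run.  The call
position is the midpoint between the bounding windows, which localises a
planted breakpoint to within about `window/2 + step` = 35 bp (the
simulation suite verifies ≥ 95% recovery at that tolerance, with zero
false calls on pure queries).

Because a breakpoint cannot be localised more finely than that, a
breakpoint only marks a region (gag or pol) as recombinant when it lies
more than `bp_tolerance = window + 2*step` (70 bp) inside the region.
Without this margin, an exchange at the *gag*/*pol* boundary — the
signature of mosaic elements — would be attributed to one of the two
regions by call jitter and the element would never classify as mosaic.
Region types are then majority calls over informative windows
(`fraction_gag_canonical` records the majority fraction); a tie or fewer
than 50% informative windows gives `undetermined` rather than a coin
flip.  Recombinant regions keep their majority group on record, because
strain summaries count gag recombinants with the group contributing the
majority of their *gag*.  The reference pair is arbitrary, so the same
machinery serves canonical-vs-Ty1′ and canonical-vs-*S. paradoxus*
comparisons.

### Trees

Distance clustering uses the classic neighbor-joining reduction or the
variance-weighted BIONJ reduction (via the `ape` implementations), with
pairwise K2P distances and an error on any undefined pair.  Negative
branch lengths, which NJ-family methods can produce, are retained and
flagged in a message rather than clamped — clamping would silently change
path lengths and hide a diagnostic.  Bootstrap supports resample
alignment columns with replacement; the support of each internal
bipartition of the point tree is the percentage of replicate trees
containing it, and a majority-rule consensus is also returned.
Replicates with undefined distances are dropped and counted.

### Mobility statistics

The mobility frequency of a strain is the mean replicate event count per
1 ml culture divided by the viable (Ura+) titer; the SD is the sample SD
(n−1) of the per-replicate frequencies.  Computing dispersion from
per-culture event counts admits two readings — the SD of per-replicate
frequencies, or the SD of the raw counts rescaled by the titer — and the
two differ only by that constant rescaling; the per-replicate-frequency
form is implemented as the default interpretation and flagged here
deliberately.  Detection-limit values ("< x") are carried as bounds:
`fold_change()` marks any ratio using a bound as a lower bound.

`spearman()` uses mid-ranks and reports the two-sided p from the t
approximation $t = \rho\sqrt{(n-2)/(1-\rho^2)}$ when ties are present;
for tie-free data with $n \le 9$ it enumerates the exact permutation
distribution.  The bundled seven-strain *S. cerevisiae* panel contains
ties in the canonical-*gag* counts, so the headline correlation uses the
t branch.

### dN/dS

`ng86_dnds()` is the Nei–Gojobori (1986) counting estimator with equal
pathway weighting and Jukes–Cantor correction.  Mutations creating stop
codons count as nonsynonymous in site counting; pathways through stop
codons are excluded from difference counting when a stop-free pathway
exists.  `pS >= 0.75` is saturated (`dS = NA`), and the ratio is `NA`
whenever `dS` is zero or undefined.  This counting estimator is the
package's self-contained selection summary; it is deliberately not a
maximum-likelihood codon model, so its numbers are not exchangeable with
M0-style estimates on the same data — they answer the same qualitative
question (is *gag* under purifying selection?) with a different
estimator.

## The synthetic-data generator

`plant_genome()` builds a background genome of i.i.d. uniform ACGT — by
construction it has no homology to the Ty library, so every background
hit in the simulation is an injected false positive, never an accident.
Elements are planted with known coordinates, strands, subfamilies,
structural classes and (for mosaics) breakpoints, and the generator
emits the raw hits a homology search would produce, one fragment per
LTR/internal region, with these error modes:

* `p_mislabel_ltr` — an LTR fragment of a full/truncated element is
  emitted under the other family's LTR name;
* `p_merge_tandem` — a tandem array is emitted under a single hit-group
  id sharing the internal LTR hit.  When the merge error does *not*
  fire, the shared LTR hit is emitted once per component copy (the
  already-split representation): a genomic LTR assigned to only one
  copy's group would make the other copy structurally truncated, i.e.
  the generator would plant a ground truth that no curation could
  recover;
* `p_fuse_solo` — a solo LTR planted 150–400 bp from a host element is
  emitted under the host's hit-group id;
* `fp_rate` — false-positive hits per 100 kb, with divergence drawn
  uniformly above the 20% filter threshold (default 25–45%).

Substitutions are simulated by exact per-site multinomial draws from the
K2P transition-probability matrix at the requested distance — the closed
form has the same marginal law as a continuous-time simulation and is
much faster.  Indels default to off, so synthetic alignments are
column-aligned by construction and the MSA-consuming functions can be
tested without an external aligner.  Subfamily references are generated
by evolving one ancestral full-length element to a configured pairwise
divergence of 0.10 in *gag* and 0.02 elsewhere.  These defaults are
deliberate conventions, not measured values — no established point
estimate anchors the canonical-vs-Ty1′ *gag* divergence — so they are
configurable and
the test suite treats them as fixed study conditions, not tunable dials.
Mobility assays are emulated as Poisson replicate counts with mean
`true_frequency × cells_per_ml`.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: sequencing or assembly error (hits come from
exact coordinates, not read mapping), indel evolution and alignment
uncertainty, nested insertions interrupting elements, segmental
duplications of element loci, biological titer variation between
replicate cultures, and any population structure across strains.  The
end-to-end oracle therefore certifies the *logic* of the curation and
classification steps, not their robustness to assembly artefacts.

## Region annotation defaults

The shipped Ty1-H3 region file (`inst/extdata/ty1h3_regions.yaml`)
places the LTRs at 1–334 and 5585–5918, *gag* at 294–1616, *pol* at
1578–5561 (the two ORFs overlap at the +1 frameshift site, heptamer
1571–1577), and the p22 region at 954–1616 — the C-terminal half of
*gag* rounded to the *gag* codon frame, with alternative start codons at
954 and 1020.  Exact p22 start-codon, helix and antisense coordinates
are not published as plain numbers; the helix and antisense intervals in
the file are synthetic placeholders and every entry is overridable via
`load_region_annotation(path)`.

## Problem sizes and determinism

The test suite and the acceptance script run entirely on synthetic data
sized for interactive use: 100 random planted genomes of roughly 20–60 kb
for the end-to-end curation oracle, 100 simulated mosaics (plus 100 pure
controls) for breakpoint recovery, 50 random 8-taxon trees for
NJ/BIONJ bipartition recovery, exhaustive 2×2 tables with margins ≤ 12
for the Fisher check, and 10,000 replicate cultures for
frequency-estimator recovery.  These sizes give the oracles enough cases
to be meaningful while keeping a full run in tens of seconds.  All
randomness flows from explicit seeds: identical `(config, seed)` pairs
give byte-identical genomes, and the acceptance script derives every
sub-seed from its `--seed` argument.

## Known limitations

* The windowed classifier approximates recombination detection; exchanges
  shorter than `min_run × step` windows, or between references diverged
  below the margin threshold, are invisible.  Network-based conflict
  analyses can call pol-region recombinants that windowed assignment
  cannot.
* Maximum-likelihood tree inference, ancestral-state reconstruction and
  phylogenetic networks are out of scope; the distance clustering here
  covers subfamily identification, not deep phylogeny.
* `project_truncated()` localises block edges only to within a handful of
  bp when the flanks of a junction happen to match both reference
  contexts.
* The curation operations assume the hit grouping semantics of
  RepeatMasker-style ids; annotations without grouping ids must be
  pre-grouped by the caller.
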