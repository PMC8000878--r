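---
title: "Hydrogen-bond duplex scoring, site clusters and miRNA-gene associations: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hydrogen-bond duplex scoring, site clusters and miRNA-gene associations: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirsite)
```

## The model

`mirsite` predicts miRNA binding sites (BSs) in mRNAs with a deliberately
simple, fully transparent duplex model in the MirTarget tradition. A
candidate site is a **gapless, antiparallel duplex** over the full miRNA
length: window position $i$ (mRNA, 5'→3') opposes miRNA position
$L - i + 1$ (5'→3'), with no bulges or internal loops. Each base
opposition contributes hydrogen bonds

| pair | bonds | distance (nm) |
|------|-------|---------------|
| G-C  | 3     | 1.03 |
| A-U  | 2     | 1.03 |
| G-U  | 1     | 1.02 |
| A-C  | 1     | 1.04 |

and every other combination contributes none. The two non-Watson-Crick
pairs (G-U, and here also A-C) are treated as *paired* throughout: they
are what lets dinucleotide-repeat tracts bind repeat miRNAs along their
entire length.

The duplex free energy is linear in the bond count,

$$\Delta G = -k_e \sum_i b_i \qquad
  \Delta G_m = -k_e \,(3\,n_{GC} + 2\,n_{AU}),$$

where $\Delta G_m$ is the perfect-complement reference (the miRNA bound to
its exact Watson-Crick complement) and $k_e$ (kJ/mole per hydrogen bond)
is the only energetic constant. Site quality is the ratio
$100\,\Delta G/\Delta G_m$, which cancels $k_e$ exactly; a site is
reported when the ratio reaches the threshold (default **90%,
inclusive**). All filtering therefore survives any recalibration of
$k_e$; absolute energies (the -130/-115 kJ/mole effectiveness criteria
below) are the only consumers of its value.

### Parameters that matter

* `k_e` — energy per hydrogen bond, default **2.4 kJ/mole**. Chosen so
  that a fully complementary mixed-composition 24-nt duplex lands near
  -150 kJ/mole, the magnitude reported for perfect sites in the reference
  tables the package reproduces. Configurable; the ratio-based scan is
  invariant to it (property-tested across random scales).
* `ratio_mode` — `"bonds"` (default; energy ratio) or `"paired"`
  (fraction of positions forming any recognized pair). The paired mode
  reproduces the published family-mismatch calibration exactly: 20 paired
  positions of a 22-nt miRNA give $100\cdot 20/22 = 90.9\% \approx 91\%$.
  Both framings appear in the literature this model follows, so both are
  exposed.
* `threshold_pct` — scan threshold on the ratio, default 90, compared
  with `>=` (a site at exactly 90% is kept).
* Region effectiveness thresholds — `effective_sites()` defaults to
  **-130 kJ/mole** for 5'UTR and CDS sites and **-115 kJ/mole** for
  3'UTR sites ("and stronger", i.e. $\Delta G \le$ threshold), the
  criteria proposed for effective interactions in the source analysis.

### Coordinates and regions

Site starts are **1-based from the first nucleotide of the 5'UTR**,
matching the printed tables; BED output converts to 0-based half-open. A
site's region (5'UTR / CDS / 3'UTR) is decided by its **start position**
alone. Sites can straddle a boundary, and majority-overlap assignment
would be ambiguous for even-split sites; start-based assignment is
deterministic and matches the "start of site" orientation of the tables.
Boundaries are inclusive on the left: with a 100-nt 5'UTR, start 100 is
5'UTR and start 101 is CDS.

### Clusters and compaction

Overlapping sites (any miRNAs) form **clusters**: connected components of
the interval-overlap graph, where intervals are 1-based inclusive and
*touching but disjoint* intervals (e.g. `[1,10]`, `[11,20]`) do **not**
connect. The implementation is a sorted sweep, which for intervals equals
graph components; the test suite cross-checks it against
`igraph::components()` on random interval sets. Per cluster we report the
span (min start to max end, inclusive), the summed member lengths (each
reported start is one interval, so a miRNA with three printed starts
contributes three lengths), and the **compaction ratio** `sum_len /
span_len` — how many times over the member sites would tile the span.
Compaction is 1 exactly for singletons and exceeds 1 whenever members
overlap.

Two span conventions appear in the printed tables this package
reproduces: the printed spans drift by ±1-2 nt from what their own rows
give. `check_cluster_claims()` therefore accepts a printed span within 1
nt of the table-derived one, and accepts a printed compaction that
matches `sum/span` within 0.1 (on the one-decimal reporting scale) under
*either* span. Two printed compaction figures (for the ODC1 5'UTR
cluster and the MAPK1 CDS cluster) are not derivable from their rows
under any counting convention we tried (all printed starts, or one start
per miRNA; printed or derived span); the checker flags them and reports
the table-derived values instead of guessing. This behavior is itself
under test.

Multi-start runs of one miRNA are collapsed only at the reporting layer
(`collapse_ranges()`), never during scanning: the tables list runs of
adjacent starts, so the scan keeps every passing start with no
non-maximum suppression. The run-joining gap defaults to "overlapping"
(successive starts differing by less than the site length); the printed
tables do not state the gap they used, so it is configurable.

### Associations, suppression and competition

From a threshold-filtered site list, `alternatives()` derives the two
association tables — miRNAs with ≥ 2 alternative target genes, and genes
with ≥ 2 alternative miRNAs — deterministically sorted. Translational
suppression as a function of the concentration ratio
$R = [\text{miRNA}]/[\text{mRNA}]$ uses the **occupancy form**

$$s(R) = 100\,\frac{R}{1+R},$$

which satisfies $s(R) + s(1/R) = 100$ exactly and gives ~9.1% at 1:10 and
~90.9% at 10:1 — the "10%" and "90%" round figures of the motivating
description. The literal proportional reading ($s = 100\,\min(R, 1)$) was
rejected because it saturates at 100% for the 10:1 regime and cannot
produce the stated 90%. Within a cluster, `competition_rank()` orders
miRNAs by `rel_expression × |dG|` — the simplest functional combining the
two stated advantage factors (stronger binding, higher concentration).
Only the ranking direction is meaningful; the score is a documented
heuristic and the expression map is caller-supplied.

### Conservation

`flank_identity()`, `substitutions()` and `insert_report()` compare a
cluster region across orthologs. Alignment is an *input* (pre-aligned
multi-FASTA with `-` gaps): the regions compared are short and nearly
identical, and implementing alignment here would duplicate mature tools
without adding anything testable. Substitutions are classified
transition/transversion/indel; when the site's miRNA is supplied, each
record carries $\Delta\Delta G = k_e\,(b_{ref} - b_{alt})$ (positive =
destabilizing) and a `wobble_preserving` flag. The qualitative claim that
C→U substitutions "practically do not affect" binding is operationalized
as: a wobble-preserving substitution moves the paired-mode ratio of a
≥ 20-nt site by < 5 percentage points — a testable rendering, asserted in
the suite.

## The synthetic cosmos

Real inputs for the analysis that motivated this package (candidate-gene
mRNAs, miRBase plus novel miRNAs) are not redistributable from the
printed record alone, so `scenario_gastric_like()` builds a deterministic
benchmark emulating the *shapes* that analysis reports:

* a five-member miRNA family (≤ 2 mutations from a common 22-mer) sharing
  one planted window — a multi-miRNA cluster with compaction 5;
* GU- and CA-dinucleotide-repeat tracts bound by repeat miRNAs, where
  every step-2 phase rebinds — multi-start runs and compactions above 10,
  including all-wobble duplexes (paired ratio 100%, low energy);
* a hub miRNA planted in six genes' 3'UTRs (a 6-gene association) and a
  gene carrying six distinct miRNAs;
* isolated singletons on high-NX genes, mirroring the observation that
  highly expressed genes carry few, separate sites;
* sub-threshold decoys (realized paired ratio ≈ 80%) that the scan must
  *not* report.

Plants write the reverse complement of the miRNA with
$k = \mathrm{round}((1 - \text{target}/100)\,L)$ interior positions
mutated to zero-bond bases, so the realized ratio is exactly computable;
overlapping plants overwrite in order and the truth ledger records every
plant's ratio **recomputed from the final sequence** (both ratio modes).
The recovery guarantees are therefore expressed against realized, not
intended, ratios: every plant at ≥ 90% realized is recovered at its exact
start, and no plant below 85% realized is reported (the 5-point buffer
absorbs overwrite effects, which the ledger makes visible).

What the cosmos does **not** emulate: realistic transcriptome base
composition (background is uniform), genome-scale miRNA sets, isoform
structure, RNA secondary structure or site accessibility, and expression
covariation between miRNAs and hosts. Passing the recovery and property
tests shows the machinery is correct on sequences with planted signal; it
does not validate the biological accuracy of the energy model on real
transcripts.

## Numerical and testing choices

* Degenerate inputs: a transcript shorter than a miRNA yields no sites
  with a warning; a zero-length annotated region is simply never matched;
  an empty site list produces header-only outputs.
* Printed multi-start ranges `a ÷ b (n)` are expanded to `n` evenly
  spaced rounded starts — the inner starts are not individually printed,
  and every cluster statistic used downstream (span, sum, compaction) is
  insensitive to the choice. Printed dG/ratio ranges are linearly
  interpolated across expanded starts and treated as representative only.
* Rounding follows the tables: energies and ratios to integers in the
  sites TSV, compaction to one decimal.
* Problem sizes: the oracle cross-checks run on 100 random
  miRNA/transcript pairs (transcripts 100-250 nt) and 200-250 random
  interval sets in the unit suite, and 1000 pairs / 200 sets in the
  acceptance script — large enough to exercise every branch while keeping
  the default suite fast. The full suite and the acceptance script each
  complete in well under a minute on one CPU.
* All generator randomness flows from a single integer seed; reruns are
  byte-identical (asserted on the emitted FASTA/TSV files).

## Known limitations

The energy model is a bond count, not nearest-neighbor thermodynamics: no
stacking, no loop penalties, no folding or accessibility. It is the model
whose published outputs this package set out to reproduce, and its
absolute energies should be read through the configurable $k_e$ rather
than as physical free energies. The printed tables it reproduces cannot
be regenerated from sequence here because the underlying miRNA sequences
(the proprietary ID-series in particular) are not printed; what the
package verifies end-to-end is every quantity derivable from the printed
rows themselves, plus the full pipeline on synthetic data with known
truth.
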