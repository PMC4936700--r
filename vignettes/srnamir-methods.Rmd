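---
title: "Methods: small RNA miRNA discovery, exact-test expression and degradome target calling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: small RNA miRNA discovery, exact-test expression and degradome target calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srnamir)
```

# The analysis problem

`srnamir` implements the computational core of an unreplicated plant
sRNA-seq study design: four small-RNA libraries from two genotypes (a
diploid and a derived autotetraploid, e.g. of *Paulownia*) under control and
drought conditions — `PA2`, `PA2H`, `PA4`, `PA4H` — plus matched degradome
(PARE) libraries. The pipeline runs from raw reads to biological calls:

1. **Read processing** — adapter trimming, quality and length filtering
   (18–30 nt inserts), collapsing to unique tags, ncRNA class annotation,
   and conserved miRNA matching against a miRBase-style catalog.
2. **Novel miRNA discovery** — hairpin precursor screening of unannotated
   tag clusters with energy (MFE/AMFE/MFEI), duplex-geometry and
   processing-precision criteria.
3. **Differential expression** — the Audic–Claverie exact test between
   unreplicated libraries with RPM normalization and a fold-change gate.
4. **Degradome target calling** — duplex scanning with G:U wobbles,
   cleavage-site detection opposite miRNA positions 10–11, and
   three-category site classification.
5. **Downstream statistics** — hypergeometric GO enrichment and Livak
   2^-ΔΔCt qPCR arithmetic with miRNA–target anticorrelation summaries.

A first-class synthetic-data generator plants all the signal these stages
are meant to find and records a machine-readable truth, so every stage has
recovery tests.

# Read processing

Cleaning assesses removal reasons in a fixed order (quality, adapter,
poly-A, length), so the removal statistics partition the raw reads exactly.
The originating protocol leaves undefined its quality or poly-A thresholds;
the defaults here are a mean Phred of 20 and ≥ 80% A content after
trimming, both configurable. The 3′ adapter is located as the longest read
suffix matching a prefix of the adapter with at most one mismatch per 10
adapter bases compared.

Class annotation assigns each unique tag exactly one class, in the priority
order rRNA > tRNA > snRNA > snoRNA > miRNA > unannotated, mirroring the
usual pipeline order in which ncRNA removal precedes miRNA matching. ncRNA
matching is exact substring containment in user-supplied class reference
sequences; this removes any external-database dependency while preserving
the removal semantics. Conserved miRNA matching is ungapped with a ±2 nt
end-shift scan and at most two mismatches; ungapped matching with a small
end shift is the common convention for ~21-nt queries, where indel handling
is ill-defined.

# Hairpin discovery

Tags are aligned exactly (full-length, ungapped) to the reference
transcripts; tags whose spans overlap or abut within 3 nt form clusters,
and each cluster emits two candidate windows (short/long flank on either
side, defaults 20/200 nt — typical plant pre-miRNA geometry). The dominant
(highest-count) tag of the cluster is the mature candidate.

Because a 220-nt window of transcript sequence usually folds into several
unrelated stems, the screen first folds the whole window, then trims to the
stem anchored on the mature: the span covering the mature and the partners
of its longest contiguous antiparallel pairing run (small bulges up to 6 nt
allowed) plus a 4-nt margin, and refolds the trimmed precursor. Trimming to
the longest run, rather than all partners, prevents a stray mature edge
base recruited by a distant flank helix from dragging the precursor span
across unrelated structure.

Acceptance requires, in order: a successful fold, a single hairpin (exactly
one terminal loop), valid miRNA/miRNA\* duplex geometry, MFE ≤ −18
kcal/mol, mature read count ≥ 5, and processing precision ≥ 0.1. The first
failing criterion is recorded. Overlapping accepted candidates deduplicate
to the lowest-MFE one.

**Duplex geometry.** At least 60% of mature bases must be paired, all into
one opposing arm (so a mature spanning the terminal loop, which pairs with
itself, fails), with antiparallel-monotone partners (a helix, not scattered
pairs). The star strand is inferred from the partners of the mature
(excluding its own 2-nt 3′ overhang) extended by 2 nt at its 3′ end — the
canonical Dicer 2-nt 3′-overhang geometry. The inferred star must fit
inside the precursor, not overlap the mature, and not be grossly asymmetric
(|star length − mature length| ≤ 6 nt). When an observed star span is
supplied it must match the inference exactly, which is why a blunt-ended
duplex fails.

**Processing precision** is the fraction of precursor-mapped reads (by
count, not unique tags) whose 5′ ends lie within ±2 nt of the mature or
star 5′ end. The cited literature does not reproduce the exact formula;
this operationalization is configurable. The boundary case is kept
inclusive: a candidate at precision exactly 0.1 is retained, because the
stated removal rule ("values < 0.1 removed") and the stated retention rule
("> 0.1") disagree and the removal wording is the operational one.

## The bundled energy model

Folding is pluggable. The default backend is an exact dynamic program over
pseudoknot-free structures under a deliberately simple integer energy
model:

* allowed pairs AU, GC, GU; hairpin loops ≥ 3 nt;
* a pair stacked on a paired inner neighbour scores −2 kcal/mol (GC) or −1
  (AU/GU);
* a pair whose inner neighbour is unpaired pays +2 (helix-opening,
  a loop-entropy proxy);
* each hairpin loop costs +3; other loop sizes are free.

The helix-opening and hairpin penalties matter: without them, random
sequence accumulates many scattered two-pair helices and the MFE of random
windows becomes indistinguishable from genuine hairpins. All energies are
integers, so the dynamic program is exact and is verified against
brute-force enumeration of *all* structures for sequences ≤ 18 nt. An
optional `"vienna"` backend shells out to `RNAfold` when available; the
−18 kcal/mol threshold applies to whichever backend is active and the
backend is recorded in every result.

# Differential expression

Abundances are normalized to reads per million of the per-library clean
read total (the stated normalization convention; whether the denominator
should instead be miRNA-mappable reads is not stated in the source
protocol, so the clean-read total is the default and the denominator is a
parameter). Fold change is `log2((rpm_a + 0.01)/(rpm_b + 0.01))`; the
pseudo-RPM guards zero counts and is configurable.

The exact test conditions one count on the other:

$$p(y\mid x) = \left(\frac{N_2}{N_1}\right)^{y}
\frac{(x+y)!}{x!\,y!}\left(1+\frac{N_2}{N_1}\right)^{-(x+y+1)}$$

Both tails include the observed point (`C` sums to `y` inclusive, `D` from
`y` inclusive), following the stated tail limits; the two-sided p-value
doubles the smaller tail, capped at 1 (the standard convention; the source
defines both tails but not their combination). Evaluation is in log-space
via `lgamma`; the upper tail is summed directly as a convergent series
rather than via `1 − C`, which loses all precision when `C ≈ 1`. Calls use
a strict fold-change gate (|log2FC| > 1) and an inclusive p-value gate
(p ≤ 0.05), with no multiple-testing correction for the calls (a
Benjamini–Hochberg column is emitted for reference).

Note that with both tails inclusive the two-sided p is *not* symmetric
under swapping the two counts along with the library sizes (x = 1, y = 0 at
equal sizes gives p = 1/2 one way and 1 the other); the package instead
guarantees and tests the exact identity `C + D − 1 = p(y|x)`.

# Degradome target calling

Candidate sites are scanned ungapped over transcript windows of miRNA
length; penalties are mismatch 1, G:U wobble 0.5, gap 2, doubled at miRNA
positions 2–13, with a score cap of 4 — the scoring convention of the
PairFinder/CleaveLand lineage, of which only the
cap. Any non-match opposite positions 10–11 invalidates the site
regardless of score. The cleavage coordinate is the transcript base paired
to miRNA position 10.

Degradome tags (fixed 20 nt, the MmeI tag length) align exact-match only;
per-transcript profiles count tag 5′ ends. Site abundance is the maximum
profile count within ±1 nt of the cleavage coordinate. Categories: **I**
abundance equals the transcript maximum; **II** strictly between the
maximum and the median of positions with ≥ 1 count; **III** at or below
that median. The cited category systems use up to five classes; this
three-way max/median operationalization is a documented design choice, not
a claim about the original authors' exact rules. Pooling across libraries
keeps each site's best category, and each target gene's best site category.

# Downstream statistics

GO enrichment uses the upper-tail hypergeometric probability per term (the
standard choice; the source names only the p ≤ 0.05 threshold), with terms
taken as given (no ontology-graph propagation). qPCR relative expression is
Livak 2^-ΔΔCt with replicate Ct values averaged per sample; the calibrator
sample is 1 by construction. Anticorrelation summaries report the sign of
the Spearman correlation between matched miRNA and target expression
vectors, with |ρ| < 0.3 labelled flat.

# The synthetic study design

The generator's defaults are the study conditions the tests run under:

* four libraries at 10^6 reads each; 20 planted 21-nt miRNAs on
  50 transcripts of 400–1200 nt (one host and one perfectly complementary
  target transcript per miRNA);
* precursors constructed, not sampled: mature + 12-nt loop + star, where
  the star is the reverse complement of the mature's first 19 nt plus a
  2-nt tail — criterion-compliant 2-nt 3′-overhang geometry by
  construction. Loop bases come from {A,C} and the two bases at the helix
  junction are chosen so the fold cannot extend the helix into the loop;
  the mature is redrawn until the planted helix scores ≤ −21 kcal/mol under
  the bundled model, so the MFE criterion holds with margin;
* true fold changes (stressed over control, both genotype pairs) default to
  the cycle (+2, −2, 0, 0) over the planted miRNAs: half differential at
  the 4-fold level, half null;
* counts are negative binomial with variance μ + dμ²; the default
  dispersion d = 0.01 reflects technical-replication-level variation in an
  unreplicated design (each condition is one library), and is the level at
  which the planted-null fold-change spread stays below 0.2 at depth;
  d = 0 gives Poisson for analytic checks;
* class composition (miRNA 20%, rRNA 5%, tRNA 5%, snRNA 0.2%,
  snoRNA 0.1%, unannotated 69.7%) follows the magnitude of real library
  annotation tables, as do the per-class mean reads per unique tag
  (rRNA ≈ 10, tRNA ≈ 50, snRNA/snoRNA ≈ 2.5, unannotated ≈ 3): most
  degradation tags are near-singletons while tRNA fragments are few but
  abundant. The unique-tag counts scale with depth accordingly. Half the
  unannotated tags are genuine transcript degradation fragments (sampled
  away from planted precursors with a 5-nt guard so planted processing
  precision stays interpretable); half are unmappable random tags. Tag
  lengths follow a 24-nt-dominant, then 21-nt, profile;
* degradome libraries plant a Poisson peak (mean 50 reads/library) of
  20-nt tags starting exactly at each planted cleavage position over a
  uniform Poisson background (mean 1 read per transcript position).

What the generator does **not** emulate: sequencing errors and quality
dropoff, multi-mapping ambiguity across paralogues, isomiR 5′/3′
heterogeneity, genuine siRNA phasing, and hairpins from repeat elements.
Recovery results on this design therefore demonstrate that the
implementation finds what its criteria define, not that the criteria are
sufficient on arbitrary real libraries.

# Numerical and scale choices

* Coordinates are 0-based half-open everywhere; the internal alphabet is
  DNA (U converted on input, folding converts back).
* Candidate windows longer than 400 nt are clipped around the cluster
  before folding (the dynamic program is cubic).
* Screen, DE and degradome recovery tests use these problem sizes: the
  20-precursor design at depth 10^6 for discovery; 100 simulated designs
  with a coarsened background (the exact test sees only miRNA counts and
  library totals, so background granularity is irrelevant there) for DE
  recovery; 100 seeded 10-miRNA designs for degradome recovery; 200 random
  sequences ≤ 18 nt for the folding oracle. The null calibration of the
  exact test uses 10,000 Poisson draws with rates log-uniform in
  [5, 500].
* All generators derive their RNG streams from a single recorded seed and
  are byte-identical on repeat calls.

# Known limitations

* The bundled energy model ranks hairpins sensibly and is exact and fast,
  but its absolute energies are not ViennaRNA's; the −18 kcal/mol
  criterion is meaningful relative to the active backend.
* With one library per condition the exact test measures sampling
  variation only; biological replication is out of scope by design, and
  significance calls on real data inherit that caveat.
* Degradome category boundaries (max/median) are one defensible reading of
  the three-category scheme; sites near the boundaries can switch
  categories under other readings.
* Conserved-miRNA matching is ungapped; a catalog entry differing from the
  tag by an indel will not match.
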