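---
title: "Methods and design of wbatk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of wbatk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wbatk)
```

wbatk implements the analytical workflow around a high-density SNP
genotyping array for hexaploid bread wheat: selecting an informative marker
panel from a large candidate pool, building biparental linkage maps and a
consensus map, scanning for segregation distortion, computing germplasm
diversity and differentiation statistics, and profiling copy-number
variation from probe intensities. This vignette explains the models and the
design decisions behind each stage, and what the synthetic-data module does
and does not emulate.

## Data model

A genotype table is a wide tibble (`marker_id` + one column per sample)
over the four-call alphabet `AA`, `AB`, `BB`, `NC`. The alphabet is fixed:
array pipelines that emit additional cluster states (hemizygous, off-target)
are expected to collapse them to `NC` upstream. Dominant assays — those that
cannot separate the heterozygote cluster from one homozygote — keep the same
alphabet; dominance is *metadata* on the marker, not a different call code.
Downstream frequency computations treat dominant markers under a two-state
convention, which biases their allele frequencies towards the collapse
class; this is documented rather than corrected, because the correction
would require knowing the collapse direction, which real arrays do not
report.

On read, the missing tokens `NC`, `NoCall`, `NN` and `-` all map to `NC`;
any other token is an error naming the offending cell — a silent no-call
would corrupt every statistic computed afterwards. VCF export is provided
for interoperability, with one loud caveat: genetic-map positions are not
physical coordinates, so `POS` holds the marker's *rank* within its
chromosome and the cM position travels in the `CM` INFO key. The VCF header
says so.

## Synthetic data: what it emulates

The generator exists so that every analysis in the package can be tested
against known truth without any array data. Three generators cover the
three data regimes:

**Biparental populations** (`simulate_biparental()`). Gametes form under
Haldane's no-interference model: per meiosis the crossover count on a
chromosome of length $L$ cM is Poisson($L/100$) with uniform positions.
Doubled haploids fix a single gamete; RIL and SSD designs iterate
single-seed selfing to the design generation, so residual per-locus
heterozygosity is $0.5^{g-1}$ at generation $g$ (0.0625 at F5, 0.03125 at
F6). Haldane was chosen because the two-point estimators used downstream
assume no interference; crossover interference is explicitly out of scope.
Segregation distortion is implemented as viability selection: an individual
homozygous for the disfavoured allele at a distortion locus survives with
probability $1-s$. Selection is applied by rejection sampling on
final-generation individuals rather than per generation — for the
transmission-ratio magnitudes of interest the two are equivalent at the
level of marginal genotype ratios, and the single-pass form keeps the
generator simple and exactly reproducible. Defaults mirror a breeders'
array screen: 56.2% of markers dominant, 25% of markers polymorphic
between any two parents, 5% missing data (the data model tolerates up to
20%), and a 68.8/31.2 transition/transversion mix.

**Structured collections** (`simulate_collections()`). Ancestral minor
allele frequencies are Uniform(0.05, 0.5) — which qualitatively reproduces
the flat-with-spike MAF histograms seen in real elite collections — scaled
per subgenome by a multiplier (default D = 0.5, reflecting the D-genome
diversity bottleneck of conventional hexaploid germplasm; a synthetic
hexaploid scenario uses a D multiplier above 1). Collection frequencies
follow the Balding–Nichols model: for differentiation target $F$, the
collection frequency is Beta$(p(1-F)/F,\,(1-p)(1-F)/F)$, with mean $p$ and
variance $Fp(1-p)$, so Weir–Cockerham $\theta$ between collections
estimates $F$ analytically. Individuals are inbred lines: heterozygous at a
residual 1% rate, otherwise homozygous by the collection frequency
(allele-frequency preserving). Balding–Nichols was chosen because it gives
an exact recovery target for the FST estimator; the real study had no
generative model, it had data.

**Intensity matrices** (`simulate_intensities()`). Marker baselines are
lognormal; a sample's intensity is the baseline scaled by
$\text{copy}/2$ with multiplicative noise $2^{\mathcal N(0,\sigma)}$, and a
panel of at least 20 unaffected reference samples is appended. Zero-copy
regions are floored at a relative intensity of $2^{-5}$ rather than zero,
mimicking background hybridization.

What the generators do **not** emulate: linkage disequilibrium beyond
map-based recombination, pedigree structure beyond a single biparental
cross, genotyping-error processes other than missingness, homoeologous
cross-hybridization between subgenomes, and sequence-level variation.
Passing tests therefore demonstrate correctness of the estimators under
their stated models, not robustness to every artefact of real array data.

## Panel selection

The selection procedure reduces a candidate pool to one SNP per contig by a
preference lattice: a contig's single SNP is taken as is; otherwise
candidates are restricted to genetically mapped SNPs if any exist, then to
codominant SNPs if any exist, and the marker with the highest polymorphic
information content wins. PIC uses the standard biallelic Botstein form

$$\mathrm{PIC} = 1 - (p^2 + q^2) - 2p^2q^2,$$

which is symmetric in $p \leftrightarrow q$, maximal (0.375) at $p = 0.5$
and monotone in MAF — so the ranking is robust to reasonable alternative
informativeness scores. PIC ties break lexicographically by marker id,
making selection invariant to input order. Genetic-map spacing is treated
as a property of the candidate set; an optional greedy thinning
(`thin_panel()`, minimum cM gap) is provided but off by default.

## Linkage mapping

The mapping engine is deliberately two-point: binning, pairwise
recombination-fraction estimation, graph-based grouping, and seriation
ordering. Proprietary multipoint-likelihood engines used in production map
building are not reimplemented; the two-point pipeline reproduces the same
concepts (bins, skeleton markers, inflation control) while remaining fully
verifiable against simulation truth.

*Filtering and binning.* Markers with more than 20% missing data are
removed (a marker exactly at 20% is kept), then monomorphic markers are
dropped. Markers are binned when their segregation patterns are identical
on every co-called individual (with at least one such individual) — with
numeric coding this coincides with a pairwise correlation of 1, and the
identical-on-co-called formulation avoids undefined correlations under
missing data. Binning is greedy first-fit so that every bin is a clique;
the representative is the member with fewest no-calls (ties by id).

*Two-point estimation.* For DH data, $\hat r$ is the recombinant fraction.
For RILs, the observed homozygote discordance $R$ is mapped back through
the selfing attractor $R = 2r/(1+2r)$, i.e. $\hat r = R/(2-2R)$, capped at
0.49. For F5 data, the package computes the exact two-locus genotype
distribution of the selfing chain (ten diplotype states iterated four
generations from the coupling F1) and maximises the nine-class multinomial
likelihood numerically; a grid search serves the all-pairs matrix and
Brent optimisation the single-pair estimator. Direct numerical maximum
likelihood was preferred over an EM formulation — the likelihood is
one-dimensional and unimodal on $(0, 0.5)$, so EM adds machinery without
adding accuracy. LOD is the base-10 likelihood ratio against $r = 0.5$.

*Grouping and ordering.* Linkage groups are connected components of the
graph with edges where $\hat r \le 0.35$ and LOD $\ge 3$. Within a group,
ordering seeds the path with the most distant linked pair (largest
$\hat r \le 0.35$ — the presumptive chromosome ends), adds markers by
cheapest insertion (smallest increase in the adjacent-$\hat r$ sum; pure
end-extension cannot place interior markers between the seed ends), and
polishes with 2-opt segment reversals until no reversal improves the
adjacent sum. Positions are cumulative map-function distances of adjacent
$\hat r$; Haldane and Kosambi are both available. The package default is
Haldane, matching the generator's recombination model so that map lengths
are comparable to simulation truth; Kosambi is selectable for real data
where interference is expected.

*Skeleton and inflation control.* Representatives of multi-marker bins
form the skeleton ordered first; remaining unique-pattern markers are then
inserted at their best position while the total map length stays below
`inflation_limit` (default 1.2) times the skeleton length — markers whose
insertion would inflate the map beyond the budget are dropped and logged,
since isolated pattern errors manifest exactly as local map inflation. In
sparse data (large populations, well-spaced markers) most patterns are
unique and multi-marker bins cannot frame a chromosome; when they cover
less than half of a group's representatives, all representatives are
treated as skeleton. Chromosome orientation is arbitrary; maps are
canonically oriented so the end marker with the lexicographically smaller
id comes first.

*Distortion scan.* Homozygote counts are tested against 50:50 with a
1-df chi-square without continuity correction,
$X^2 = (n_1-n_2)^2/(n_1+n_2)$; heterozygotes and no-calls are excluded.
Significance defaults to $P < 0.005$ and the favoured parent is the larger
count. The export carries both $-\log_{10} p$ and $\log_{10} X^2$ so either
Manhattan-plot convention can be drawn.

*Consensus merging.* Component maps sharing a chromosome nomenclature
(see `anchor_chromosomes()` for de novo maps) are merged per chromosome by
a precedence-graph heuristic: each component contributes directed edges
between consecutive markers; antiparallel edges resolve by majority
multiplicity, ties by the larger supporting population, then
lexicographically; residual cycles are broken by deleting the
minimum-multiplicity edge inside each strongly connected component. The
acyclic graph is ordered by Kahn's algorithm with ties broken by mean
rescaled component position, and consensus positions are the unweighted
mean of linearly rescaled component positions, monotonised by isotonic
regression and anchored at zero. No weighting is applied across component
maps. Distorted markers and markers mapped to different chromosomes in
different components must be excluded beforehand; a cross-chromosome
conflict is an error, not a silent repair.

## Diversity statistics

Allele frequencies count the `A` allele over called genotypes only (AA = 2,
AB = 1, BB = 0). Per collection the package reports:

* `%P` — the percentage of *all panel markers* polymorphic in the
  collection ($0 < p < 1$);
* `He` — mean expected heterozygosity, $1 - \sum_i p_i^2 = 2pq$ per
  biallelic marker;
* `MAF` — mean minor allele frequency;
* `RI` — the rarity index $\frac{1}{I}\sum_i p_{ij}/p_i$, the mean ratio of
  the collection's allele frequency to the pooled frequency.

`He` and `MAF` average over all panel markers with a defined frequency, so
monomorphic markers contribute zero — the convention that keeps `%P` and
`He` mutually consistent in a single table; whether published tables
excluded monomorphic markers is generally unstated, so the convention is
declared here rather than asserted as universal. For RI, markers with
pooled $p_i = 0$ are excluded (the ratio is undefined) and the effective
marker count is reported; the pooled dataset against itself gives RI = 1
exactly, which is asserted by test.

Pairwise differentiation uses the Weir–Cockerham moment estimator
$\hat\theta$, accumulated as a ratio of sums of the variance components
across markers. Negative estimates are reported as computed — they are a
routine feature of this estimator for weakly differentiated pairs, and
truncating them at zero would bias averages. The estimator is validated by
parameter recovery on Balding–Nichols simulations ($F = 0.15$ recovered
within $\pm 0.02$; $F = 0$ within $\pm 0.01$).

Identity-by-state similarity is strict call equality over co-called
markers (AB vs AA counts as a mismatch), matching the similarity definition
used for germplasm relationship matrices on this array class. Principal
coordinates come from classical metric MDS (`stats::cmdscale`: double-centred
$-d^2/2$, eigendecomposition, coordinates scaled by the square roots of the
positive eigenvalues) on $d = 1 - \text{similarity}$. A Euclidean-embeddable
distance matrix is reproduced to numerical precision, which the test suite
checks on a 3-4-5 triangle.

Rarefaction of `%P` versus collection size samples without replacement
(mandatory seed), reporting mean and SD over replicates.

## Copy-number profiling

Log2R is $\log_2(\text{sample}/\text{reference median})$ per marker,
floored at $-5$, median-centred per sample (absorbing array-brightness
differences, so calls are invariant to uniform scaling of a sample — an
asserted test), and smoothed with a running median of 15 markers along each
chromosome. Calls are maximal runs of at least 10 consecutive markers
beyond the thresholds, classed whole-chromosome (≥ 90% of the chromosome's
markers), arm/telomeric (anchored at an end, ≥ 25%) or segmental.

The production tool used for such arrays does not document its thresholds,
so all parameters here are explicit engineering choices: the loss threshold
$-0.5$ and gain threshold $+0.4$ sit at the midpoints separating the
expected Log2R of copy states 1 ($-1$), 2 ($0$) and 3 ($+0.585$); the
15-marker median window suppresses single-marker noise while preserving
runs of 8 or more markers; the 10-marker minimum run keeps the false-call
rate per sample negligible at realistic noise ($\sigma = 0.15$). In a
hexaploid, "copy state" refers to the assayed locus dosage (2 = disomic
normal); homoeologous cross-hybridization is treated as noise, not
modelled. Rye-introgression signals are detected simply as loss runs of
wheat-specific probes — no alien-genome genotype model is attempted. No
segmentation by HMM or circular binary segmentation is performed;
breakpoints are marker-resolution.

## Pipeline and reproducibility

`run_pipeline()` wires the stages (simulate → panel → map → diversity →
cnv) from a single flat configuration list with one master seed; per-stage
streams are derived offsets of it. There is no workflow engine:
reproducibility comes from mandatory seeds plus a JSON manifest recording
the package version, a configuration hash and the MD5 checksum of every
output file — reruns with the same configuration are bit-identical, which
the test suite asserts. `report_summary()` renders a run directory as a
markdown report; regeneration is idempotent. The package's interface is
its functions; `scripts/acceptance.R` is a thin script over them that
recomputes the headline quantities end to end.

## Numerical choices and degenerate inputs

* Chi-square p-values use the asymptotic 1-df upper tail; with the
  population sizes involved (60+) the approximation error is far below
  reporting precision.
* $\hat r$ is capped at 0.49 before map functions are applied
  (Haldane distance diverges at 0.5); unestimable pairs (too few co-called
  individuals, default minimum 10) are treated as unlinked.
* A group of one marker yields a trivial one-marker map at 0 cM. A sample
  with no calls reports `NA` het rate. All-NC markers within a collection
  have absent (not zero) frequencies. Markers with no homozygous calls are
  an error in the distortion scan rather than a silent skip.
* Rarefaction allows subsamples of size 1 (a single inbred line is never
  polymorphic, giving 0%), which anchors the curve at its floor.
* All tie-breaks (PIC ties, bin representatives, seed pairs, consensus
  edges, topological order) are lexicographic, so every result is
  deterministic given the seed.

## Problem sizes used in the test suite

The suite validates on sizes chosen to give tight sampling bands while
keeping the default run fast: two 200 cM chromosomes with 100 markers each
at DH $n = 200$ for map recovery (Kendall $\tau \ge 0.95$, length within
15%); 5,000 markers across 250 sparse chromosomes at DH $n = 128$ for null
distortion calibration; two collections of 50 at 5,000 markers for FST
recovery; 50 simulated aberration lines at $\sigma = 0.15$ over 1,260
markers for CNV recall and false-call rate; 100 random 100-contig
instances for panel-selection oracle equivalence.

## Known limitations

Two-point ordering cannot resolve marker order within tight clusters below
the recombination resolution of the population (bins are the honest
representation of that limit). The consensus heuristic optimises order
consistency, not a global likelihood; with heavily conflicting components
it prefers the majority and logs nothing about minority support beyond
provenance. Diversity statistics inherit the two-state bias at dominant
markers. CNV calling assumes a trustworthy reference panel; systematic
probe effects shared by the panel cancel, but batch effects between sample
and panel do not.
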