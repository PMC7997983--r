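---
title: "Methods: from display-library reads to IgOme profiles and mimicry candidates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from display-library reads to IgOme profiles and mimicry candidates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(igome)
```

`igome` analyses serum antibody epitope repertoires captured by a bacterial
surface-display library of random 12-residue peptides. Pooled case and
control immunoglobulins are panned competitively against the library; clones
surviving the depletion/enrichment rounds are deep-sequenced through the
36-bp DNA variance region that encodes each displayed peptide. This vignette
documents the models and procedures the package implements, the parameters
that matter, the numerical choices made where the method description leaves
room, and what the synthetic-data tests do and do not demonstrate.

## Read processing

Each read is `flank5 + 36-nt insert + flank3`; the default flanks are the
display vector's forward PCR primer and the reverse complement of its
reverse primer. `extract_inserts()` takes the first occurrence of the 5'
flank and the first occurrence of the 3' flank after it, each tolerating
`max_mismatches` substitutions (default 0), and accepts the insert only if
it is exactly 36 nt and free of `N`. Unparseable reads are tallied, never an
error: at display depth, losing a malformed read is the correct behaviour.
With paired ends, a failed first mate is retried on the reverse complement
of the second; mates carry the same insert, so nothing more is needed from
read 2.

Translation is always frame 1 of the extracted insert — the display
construct fixes the reading frame, so no 3-frame search is performed. A
premature stop truncates the peptide and is flagged; roughly 13–14% of
inserts carry one. Truncated peptides of at least 6 residues are *kept* in
the epitope table (they satisfy the retrieval length floor and are genuine
display products); whether to drop them instead is exposed through the
`min_len` argument for sensitivity analysis.

## The 10-σ-99 noise floor

Distinct sequences are ranked by ascending read count, ties broken
lexicographically so the ranking is a total order and reruns are
byte-identical. The bottom set *B* holds the first `floor(0.99 n)`
sequences; the threshold is `mean(B) + 10 * sd(B)` with the *population*
standard deviation, and only counts strictly greater than the threshold are
retained — so a degenerate pool in which every count is equal retains
nothing. "10 standard deviations above the lowest 99%" admits two readings:
a location+scale summary of the bottom-99% counts (used here, because a
"noise floor" is a property of the noise mass), or 10 σ above the 99th
percentile; the second is available as `stat = "quantile"`. The bottom set
must hold at least 2 sequences for the spread to exist; smaller tables are
an error rather than a silent pass-through.

## Epitope set partitioning

Epitopes present in exactly one pool form the unique sets (the symmetric
difference). Epitopes present in both pools are assigned by fold change on
reads-per-million frequencies, because real pools differ several-fold in
sequencing depth; a raw-count mode exists for equal-depth designs. The
threshold is ≥ 5-fold in either direction; shared epitopes reaching neither
direction stay `unassigned` — retained for audit, excluded from downstream
enrichment sets. There are deliberately no pseudocounts: a zero count in one
pool makes an epitope "unique", never an infinite fold change. Downstream
annotation uses the ≥ 10-residue members of the four enriched sets.

## Annotation and the significance surrogate

Because annotation demands 100% identity over the matched span, a k-mer
seed index (default k = 10, the annotation length floor) with maximal
bidirectional extension finds *exactly* the matches of a naive substring
scan — the tests assert this equivalence — while staying fast. When a full
epitope has no occurrence, maximal exact sub-matches of ≥ 10 residues are
reported, several per protein if need be (dis-contiguous matches). A relaxed
mode reports the best gapless alignment per protein above an identity
threshold; it exists for deliberately widened screens (e.g. collecting all
epitopes ≥ 50% identical to a protein family before phylogenetics).

Each hit receives a significance in [0, 1], lower = more specific:
`sig = 1 − exp(−E·m)` with `E = total_positions × Π background(residue)`
over the matched residues and `m` the number of distinct proteins hit by the
epitope. The score is parameter-free, strictly decreasing in match length
for fixed composition, saturates at 1 for unspecific matches, and penalises
multi-protein ambiguity. It is composition-based by construction: residue
order does not change `E`. It is a surrogate for database-scale E-values
(no substitution-matrix scoring, no Karlin–Altschul statistics) and should
be read as a relative ranking device, with thresholds (e.g. a mean
significance below ≈ 0.58 for "high specificity") supplied by the analyst.
An epitope's full read count is credited to every protein and species it
hits (set semantics), with ambiguity penalised only through the
significance; fractional splitting is available. Isoform redundancy
collapses to the best hit per isoform group — lowest significance, then
longest match, then lexicographic protein id. Spans are 0-based, half-open
throughout.

## Taxonomic profiling

Per species: `NGSR_e-norm = n_reads / n_epitopes`, reads per distinct mapped
epitope. Species are ranked by decreasing NGSR_e-norm with deterministic
tie-breaks (more reads, then name); the dominant set is the top
`floor(0.10 N)` species (the rounding is a package choice; at least 10
species are required so the set is non-empty), and each group's
representation is the percentage of its members inside that set — a group
with no members reports `NA`, not 0. Viral genome-type composition is each
type's share of the summed viral NGSR_e-norm and always totals 100%. Family
profiles use richness (species per family) and the Z-transform of family
mean NGSR_e-norm with the *sample* (n−1) standard deviation; families at
z ≥ 1 are flagged as outliers. Lineages come from a TSV (taxid,
superkingdom…species, genome type); genome type must be supplied — it is
curated information, not derivable from a taxid.

## Autoantibody triage

Human hits are summarised per protein (distinct epitopes, total reads, mean
significance, mean log10 read intensity) and split at a configurable mean
significance threshold. Pool overlap is `100·shared/union`. Gene-set
coverage takes an explicit membership map and an explicit universe — the
enrichment universe is a parameter, not a hidden default — and tests
enrichment with a one-sided hypergeometric tail, BH-adjusted across sets.
Union coverage of a set collection is the share of the query inside the
membership union. The shared-target matrix lists proteins in at least
`min_membership` of the enriched sets. Where published percentages were
printed truncated rather than rounded, the reporting helpers echo that
convention.

## Epitope phylogenetics and mimicry detection

Pairwise global alignment uses affine gaps, open 10.0 / extension 1.0, with
BLOSUM62 (the substitution matrix is configurable; the gap costs are the
documented screen settings). The Kimura protein distance
`d = −ln(1 − D − 0.2 D²)` is computed on both-non-gap columns (pairwise
deletion; complete deletion is a config switch). The transform saturates
near D ≈ 0.854: `kimura_distance()` raises an error there, while the
matrix/phylogeny builders cap such pairs at a common ceiling of 2. The cap
value is a deliberate numerical choice: beyond D ≈ 0.75 short peptides are
effectively unrelated, and mapping all of them to one ceiling keeps the
neighbour-joining rate terms from absorbing saturation noise — with a large
cap, genuinely mimicking pairs can have their cherry branch lengths pushed
past the reporting threshold by fluctuations among unrelated background
distances.

Trees are neighbour-joining; negative branch estimates are clamped to zero
and counted. Two taxa yield the degenerate single-edge tree. Bootstrap
supports resample the columns of a star-progressive multiple alignment
(every epitope aligned to the centre sequence, gaps merged by
"once a gap, always a gap") — adequate for short, similar-length peptides,
not a general MSA — and report the percentage of replicate trees containing
each internal bipartition; the resampling is seeded and the seed is recorded.

Mimicry candidates are the *maximal* clades whose leaf branches are all
shorter than 0.1 and whose leaves span both a human and a microbial kingdom
flag. Every human–microbial pair inside a reported clade is emitted with its
Kimura distance and aligned mismatch positions. Triangle inequality is not
assumed or asserted anywhere — Kimura distances need not satisfy it.

## Pool comparison statistics

Counts are log10-transformed (the transform refuses non-positive values).
For two groups, Shapiro–Wilk at α = 0.05 on each group gates between the
unpaired t test (with an F test choosing pooled vs Welch variances) and the
two-tailed Mann–Whitney test. Mann–Whitney is exact by full enumeration of
all labelings when the combined n is at most 12 (924 labelings at 6+6 —
cheap, and ties are handled by the enumeration itself); above that, the
normal approximation with tie correction. The two-tailed p is the
probability of a U at least as far from its null mean as observed. For three
or more groups, Kruskal–Wallis (tie-corrected) is followed by Dunn's
pairwise z with the documented tie term; the multiple-comparison adjustment
is Bonferroni-style multiplication capped at 1, switchable to Šidák — the
adjustment used by the original graphing software is not documented, so the
most conservative standard choice is the default. Median CIs are
order-statistic (distribution-free): the narrowest `(x_(j), x_(n+1−j))`
interval with binomial coverage ≥ 95% (n ≥ 6 required). Because figure
legends can annotate either centre, `compare_groups()` emits both the median
with its order-statistic CI and the mean with its t-based CI.

## The synthetic generator: what it emulates, and what it does not

`sim_config()` defaults describe the emulated study: two cohorts at two
pooling depths (`case_P10/P20`, `control_P10/P20`); 12-mer inserts between
the display vector's primer flanks; a premature-stop insert rate of 13.5%
(the reported pools showed just under 13% and 14%); 40 planted epitopes per
pool of which 12 are shared between cohorts at target fold changes
(10, 8, 6, 2 recycled — the 2 plants deliberate "unassigned" epitopes);
5,000 noise peptides per pool; log-normal planted counts
(meanlog = log 500, sdlog = 0.8) over geometric noise counts (mean 1.5) —
the enrichment distribution is not documented anywhere, so these are chosen
to produce the qualitative regime the noise floor presumes: a heavy right
tail well separated from a dense low-count floor, at a desk-scale problem
size (≈ 40k reads and ≈ 5.8k distinct sequences per pool, versus millions
in a real screen). Epitopes from viral proteins get a 3× read-depth boost,
emulating the virus-dominated enrichment after competitive panning; this is
what makes the top-decile dominance test directional. Three human–viral
mimicry 12-mers are planted with exactly one mismatch, mirroring the
published single-substitution examples. The reference holds 60 microbial
species (40% viruses with genome types, families of ~3 species) plus a
human partition with a TRIM-like paralog family (≥ 60% pairwise identity)
and an isoform group.

Reverse translation draws synonymous codons uniformly (no codon-usage
bias); stop corruption replaces one uniformly chosen codon per affected
read, so per-pool read totals always equal the sum of intended counts and
full-length recovery of a planted epitope is Binomial(intended, 1 − rate) —
the oracle used by the distribution tests. The generator does *not* emulate
base-quality error profiles, PCR duplicates, biopanning round dynamics, or
codon bias; quality strings are constant. Consequently, passing tests show
that the pipeline's logic is correct under the stated statistical structure
— they do not validate behaviour under platform-specific artefacts, and the
recovery/removal rates measured on simulations should not be quoted as
expected performance on real screens.

## Problem sizes and determinism

The test suite and the acceptance script run the full pipeline at the
generator's default scale (four pools, ≈ 160k reads total), annotate against
a ≈ 33k-window proteome index, bootstrap with up to 100 replicates over ≤ 20
epitopes, and estimate the Mann–Whitney null rejection rate from 2,000
seeded replicates at n = 6 + 6 on the exact path. Every stochastic step is
seeded; identical configuration and seed reproduce byte-identical FASTA,
FASTQ, tables and trees.

## Known limitations

* The significance surrogate ranks specificity but is not calibrated against
  database-scale E-values; thresholds ported from other pipelines need
  re-tuning.
* The star-progressive MSA is built for 12-mer epitopes; for longer or
  length-heterogeneous sequences a profile-based aligner should replace it.
* Mimicry detection reads clades off the stored (arbitrary) rooting of the
  unrooted NJ tree; tight mixed clades are robust to this, but borderline
  clades near the root may shift with rooting.
* Multi-pool (> 2) designs are handled by running the two-pool partition per
  depth and comparing results, not by a joint model.
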