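---
title: "Methods: domain triage, Pfam mapping and ECOD-style accession"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: domain triage, Pfam mapping and ECOD-style accession}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(domaintriage)
```

This vignette documents the models and procedures behind
`domaintriage`, the reasoning for its tunable parameters, what the
synthetic-data generator does and does not emulate, and the numerical
and design choices a maintainer would want written down.

## The annotation problem

A domain parser applied to predicted structures emits, per domain: a
segmented residue range on its protein (1-based inclusive; discontinuous
domains have several non-abutting segments), an assignment probability
against a structural reference, the reference domain hit and its
position in an ECOD-style hierarchy (A > X > H > T > F), a DSSP-style
secondary-structure string, per-residue pLDDT, and the source organism.
The package turns that raw output into classification-ready annotation
in five stages: quality triage, sequence clustering statistics,
taxonomic diversity, Pfam mapping, and accession with gap analysis.

## Judge categorization

Domains are triaged into four mutually exclusive classes from three
quantities: assignment probability $p$, reference coverage $c$, and the
secondary-structure element count $k$.

* `simple_topology` iff $k < 3$, regardless of $p$ and $c$ — with fewer
  than three elements the fold carries too little topological signal
  for the other distinctions to be meaningful;
* otherwise `good_domain` iff $p \ge p_{high}$ and $c \ge c_{good}$;
* `partial_domain` iff $p \ge p_{high}$ and $c < c_{good}$ (a confident
  but incomplete match, typically a fragment);
* `low_confidence` otherwise.

An SSE is a maximal run of helix states (H/G/I) of length at least 3 or
strand states (E/B) of length at least 2; T, S, C, `-` and space are
coil, and any other character is an error. These run-length minima are
the common DSSP reduction (a one- or two-residue "helix" is not a
helix; a two-residue strand can pair).

Defaults: $p_{high} = 0.85$, the probability above which well-assigned
domains dominate in this kind of data; $c_{good} = 0.70$, the
conventional domain-coverage cutoff. Both are exposed in
`judge_thresholds()` because upstream parsers calibrate their
probabilities differently. Domains with an empty secondary-structure
string cannot be judged; they are excluded with a warning rather than
guessed (fail-visible).

## Clustering statistics

Large runs cluster domain sequences with CD-HIT at 99/70/40 % identity
and import the `.clstr` files. For desk-scale work and testing the
package ships `greedy_cluster()`, a transparent stand-in with CD-HIT's
greedy incremental shape: sequences sorted longest-first (ties by id),
each joining the first cluster whose representative it matches at or
above the threshold, else founding a new cluster. Identity is matches
divided by alignment columns of a global affine-gap alignment (BLOSUM62,
open 10, extend 1). CD-HIT's word-filter heuristics are speed
optimizations, not semantics, and are deliberately not reproduced; we
claim planted-partition recovery, never cluster-for-cluster equivalence
with CD-HIT on real data. Tie-breaking is fixed by the sort order, so
clustering is reproducible without seeds.

Singleton statistics are reported both as a fraction of clusters and as
a fraction of domains — the two differ by an order of magnitude in
redundant data and answer different questions. Cross-threshold
singleton consistency (the fraction of 40 %-singletons still singletons
at 70 %) distinguishes genuinely unique sequences from borderline
threshold cases; an empty denominator is an error, not a zero.

## Weighted taxonomic diversity

For a cluster of $n$ members the score is

$$D = \sum_r w_r \frac{t_r}{n}, \qquad
  r \in \{\text{species, family, order, class, phylum}\}$$

where $t_r$ is the number of distinct resolved taxa at rank $r$ and the
weights are 0.30/0.25/0.20/0.15/0.10 (finer ranks weighted higher, sum
exactly 1). The score ranges over $(0, 1]$: homogeneous clusters score
$1/n$, clusters pairwise distinct at every rank score exactly 1. The
nominal lower end 0 of the scale is not attainable for finite clusters;
we note this rather than rescale. Only clusters of at least three
members are scored — smaller denominators make the ratios
uninformative — and clusters scoring strictly above 0.7 are flagged
"highly diverse" (the boundary itself is not).

Unresolved ranks: a member with an "unresolved" label still counts in
the denominator, but unresolved labels are never counted as distinct
taxa and two unresolved members never share a taxon. This avoids
inflating diversity from missing annotation; the alternative
(renormalizing weights when a rank is missing cluster-wide) silently
changes the score's meaning across clusters, so we do not do it.

## Pfam mapping

Hits come from `hmmscan --cut_ga` domtblout tables; gathering-threshold
filtering is delegated to the search tool (synthetic hits carry a
planted pass/fail flag). Hit extent on the query uses the envelope
coordinates — HMMER's inclusive estimate of the homologous region — a
deliberate choice recorded here because alignment coordinates would
also have been defensible.

Per domain, the mapping is the best series of non-overlapping hits:
the subset of envelopes, pairwise sharing at most `overlap_tolerance`
residues (default 0), maximizing summed bit score. This is solved
exactly by weighted interval scheduling dynamic programming; ties break
toward fewer hits, then the lexicographically smallest accession set.
The test suite checks the DP against exhaustive subset enumeration on a
thousand random instances.

Confidence tiers are evaluated in order and partition all mappings:
high requires coverage ≥ 0.80 and bit score strictly > 50; the
unpublished lower tiers default to medium (≥ 0.60, > 35) and low
(≥ 0.40, > 20), with uncertain as fallback, all configurable in
`confidence_rules()`. Coverage is model coverage,
$(\mathrm{hmm_{to}} - \mathrm{hmm_{from}} + 1)/\mathrm{model\_len}$:
the high tier gates family completeness, which is a property of how
much of the family model is matched, not of the query. A composite
mapping is tiered by its weakest family — a chain is as strong as its
weakest link. Hits are tiled per domain (domain sequences are the
queries), not per protein.

## Gap analysis and temporal capture

Unmapped well-assigned domains partition into three classes by their
T-group context: `unrepresented_tgroup` (no domain of the T-group maps
to Pfam), `sensitivity_gap` (the domain's structural reference is also
hit by Pfam-mapped siblings — an appropriate family exists but misses
this sequence), and `underspecified_subgroup` (its reference is used by
no mapped sibling — a structurally resolved sub-group with no sequence
family yet).

The temporal rescan orders release tags as version numbers, finds the
first release whose GA-passing hits capture each domain, and labels the
capture `new_family` when every capturing family's numeric accession is
at or above the floor (default 25159, i.e. PF25159 and above — families
created after Pfam 38.0), else `improved_model`. The floor is parsed
from accession digits and configurable.

Novel-family candidate clusters require all members unmapped, size
strictly over 100, and at least 15 distinct resolved phyla.

## Accession

Only well-assigned domains are accessioned. A candidate is deferred
when an existing classified domain on the same protein shares at least
`min_overlap` of the shorter domain's residues (default 0.50 — the
field speaks of "overlapping" domains without a number; half the
shorter domain is the point at which two parses are clearly claiming
the same structural unit). Deferral diagnostics report both exact range
identity and identity within a two-residue boundary jitter, because range-identity
statistics in practice often tolerate small boundary differences;
emitting both numbers costs nothing and avoids a silent choice.

Retained domains are assigned under their T-group: an exact Pfam-set
match joins the existing F-group; unseen sets found new F-groups
(simple for singleton sets, composite for larger ones, one new group
per distinct T-group × set, numbered after the largest existing F
suffix); unmapped domains are placed at the T-group level ('.0').
Each new F-group promotes as representative its member with the highest
assignment probability, ties broken by higher mean pLDDT then smaller
id — "highest quality" needs a total order, and this one is
reproducible. After a run, no two accessioned domains on one protein
exceed the overlap criterion; the tests scan for this invariant
directly.

## The synthetic-data generator

`simulate_dataset()` emulates the statistical structure of a
proteome-scale study at desk scale: a domains-per-protein distribution
with a point mass at one domain and a declining tail, judge classes at
80.3/4.1/6.4/9.2 %, 14.4 % discontinuous domains, per-class Pfam mapped
fractions 93.65/88/81.1/40.5 % (the partial-domain rate is a package
choice; the others are typical of proteome-scale classification of
curated protein sets), a gap-class
mix of 85.7/13.3/1.0 %, capture of 16.7 % of unmapped well-assigned
domains by later releases (91 % of captures via new families), and
deferral pressure on 20.6 % of well-assigned domains (79 % identical
ranges, 97 % matching T-groups).

All class attributes are planted by quota — exact largest-remainder
counts, shuffled — rather than Bernoulli sampling, so recovery tests
compare equal, not approximately equal. Attributes are generated to
satisfy their class deterministically: probabilities and coverages are
drawn strictly inside the class's region, secondary-structure strings
are built with exactly the planted number of countable elements (the
generator's strings are verified against the judge module's own
counter), hit tables are written in genuine domtblout layout so the
real parser is exercised, and cluster families are seed sequences with
an exact number of point substitutions (no indels, keeping identity
bookkeeping exact). Default scale is 550 proteins (~1,020 domains),
with 5 planted sequence families of 11 members at 2 % divergence and a
withheld-correspondence plan that forces exactly 2 simple and 1
composite new F-group at accession.

What the generator does not emulate: 3-D coordinates and PAE matrices,
realistic pLDDT autocorrelation (only a domain-high/linker-low
contrast, enough to reproduce the direction of the parsing "smoothing
effect"), indels within cluster families, biased taxon sampling, and
hit-score distributions of real HMM searches. Passing tests therefore
demonstrate the correctness of the bookkeeping and algorithms under
controlled conditions, not the field behaviour of CD-HIT or HMMER on
real proteomes.

## Numerical choices and degenerate inputs

* Coordinates are 1-based inclusive everywhere; half-open arithmetic is
  internal only. Range strings reject overlapping and abutting
  segments rather than merging them.
* Score arithmetic is double precision; diversity equality is tested at
  1e-12; bit-score ties in the DP at 1e-9.
* Empty cluster sets, empty denominators and unknown taxids are errors,
  never silent zeros or drops.
* TSV writers emit a canonical form (tab-separated, no quoting, fixed
  numeric formatting), so read → write → read is byte-stable and
  pipeline manifests can hash outputs meaningfully.
* The test suite and the acceptance script run on generated data only;
  problem sizes (≤ ~1,000 domains, 55-sequence clustering instances,
  1,000 DP-oracle instances of ≤ 12 hits) were chosen as the smallest
  scales at which every planted structure is still present.

## Known limitations

* The greedy clusterer is quadratic in the number of founded clusters
  and aligns with full dynamic programming; it is a correctness
  reference, not a CD-HIT replacement.
* `ref_coverage` is taken from the upstream parser as-is; whether it is
  alignment or envelope coverage is the producer's convention, and the
  judge thresholds should be calibrated accordingly.
* Deferral compares domains by residue overlap on the same protein
  accession; matching by accession alone (without ranges) is not
  implemented as a separate mode — callers can pass whole-protein
  ranges to emulate it.
* The '.0' pseudo-group placement does not create F nodes in the
  hierarchy table; it is a per-domain status, mirroring how such
  placements await future family definition.
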