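---
title: "Methods: diagnostic RFLP design and DNA-barcoding diet analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diagnostic RFLP design and DNA-barcoding diet analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rflpdiet)
```

rflpdiet implements two workflows that together turn dissected predator
stomachs into quantitative diet estimates: (1) the molecular design side —
screening a species-labelled COI barcode voucher library for restriction
enzymes that diagnose one prey species, in-silico PCR with degenerate primer
cocktails, and an outcome model for dual-priming-oligonucleotide (DPO)
blocking primers that suppress predator DNA; and (2) the analysis side —
index-of-relative-importance diet tables, Hill-number diversity profiles,
trophic position from nitrogen isotope ratios, and body-condition indices.
This vignette records the models, the conventions and defaults, and the
choices made where the design was genuinely open.

## Sequence model and coordinates

Every residue is one of the 15 IUPAC nucleotide codes plus inosine (`I`),
stored internally as a 4-bit set over {A, C, G, T}. Inosine is a synthesis
base that pairs promiscuously: it expands to the universal set, is allowed
only in primers, and templates containing it are rejected at ingestion.
`U` is mapped to `T` and case is folded once, at ingestion, so one canonical
alphabet flows through every scan.

Coordinates are 0-based and half-open. A backbone cut falling between
template positions *k*−1 and *k* is stored as `cut_coord = k`, so fragment
lengths are plain coordinate differences and a digest's fragment lengths
always sum to the template length. Cuts landing exactly on a template end
are dropped rather than emitting zero-length fragments.

## Restriction-site scanning and the two match modes

An ambiguity code in a template is a set of possible bases, and a diagnostic
claim has to survive that uncertainty in both directions. `find_cut_sites()`
therefore supports two modes:

* **conservative** — a position matches only when the template's base set is
  a subset of the motif's base set: *every* resolution of the template is
  cut. Used for the target species ("cuts all target vouchers").
* **liberal** — the base sets merely intersect: *some* resolution is cut.
  Used for non-targets ("cuts no non-target voucher, even in the worst
  case").

Both strands are scanned (the reverse complement of the motif on the forward
strand); for palindromic motifs the redundant minus-strand hit is
suppressed. Conservative hits are a subset of liberal hits by construction,
and both modes are property-tested against a brute-force oracle that
enumerates every full resolution of small ambiguous templates.

Fragment sizes are reported from the top strand only (`cut_top`), matching
how a gel sizes duplex DNA and how published fragment arithmetic is done
(e.g. a 709-bp amplicon with a single cut at coordinate 228 gives
228 + 481). One consequence worth recording: the mirror identity
`digest(revcomp(s)) == rev(digest(s))` holds exactly for blunt palindromic
cutters (`cut_top == cut_bottom`, e.g. SspI AAT^ATT); for sticky-end
palindromes such as NsiI (ATGCA^T) the mirrored pattern corresponds to the
bottom-strand cut and shifts by the overhang length. Only within-site type
II cutters are accepted at catalog load; enzymes cutting outside their
recognition site would be untested surface and are rejected.

## The diagnostic predicate and parallel digests

`cut_matrix()` counts, per species × enzyme, the vouchers carrying at least
one site under each mode. An enzyme is **diagnostic** for a target species
when it cuts *all* target vouchers conservatively and *no* voucher of any
other species liberally — the asymmetric, worst-case-safe predicate. Enzymes
failing exactly one half of the predicate are reported as near-misses with
their offending counts, since a practitioner will want to see how close the
next candidate was. No ranking heuristic beyond the strict predicate is
applied; when several enzymes qualify, catalog order is preserved and
`gel_distinguishable()` lets the user compare predicted band patterns at a
chosen gel resolution (sorted fragment lists matched one-to-one; any pair
differing by more than the resolution, or differing band counts, are
distinguishable).

For multi-species targets (screening out two predator species at once),
`parallel_digest_sets()` enumerates enzyme subsets in which every target is
fully covered by at least one member and no member touches a non-target.
Enzymes cutting any non-target are pruned first; enumeration is exhaustive
up to `max_set_size` (default 2, the practical parallel-digest case — a
~263-enzyme catalog makes size-2 enumeration trivial), and only minimal sets
are returned. Both searches are tested for equality with independent
brute-force enumeration on random cut matrices.

## In-silico PCR

Primers are matched through the same base-set algebra: a primer position
matches a template position when the sets intersect (inosine matches
anything). A binding site is reported when the total mismatch count is at
most `max_mismatch` *and* the 3'-most `seed_len` positions are
mismatch-free, reflecting that polymerase extension requires a matched 3'
end. The defaults, `max_mismatch = 2` and `seed_len = 5`, are this package's
choice: no thresholds are published for the original mitogenome alignments,
and PCR is empirically tolerant of a couple of internal mismatches while a
3'-terminal mismatch is strongly disfavoured.

The M13-tailed cocktail primers carry 5' sequencing tails (18 nt on the
forward M13F tail, 17 nt on the reverse M13R tail, as printed) that do not
bind the template. Tails are excluded from matching but included verbatim in
the extracted amplicon, because product sizes — and therefore predicted
fragment patterns — include primer sequence: the same cut site yields
242 + 496 in a 738-bp tailed-cocktail product but 228 + 481 in the 709-bp
untailed product. Every compatible forward/reverse site pair within the
product-length bounds yields one amplicon.

## The DPO blocking-primer outcome model

A DPO blocker is two specificity segments joined by a poly-deoxyinosine
linker (the single run of ≥ 3 `I`; multi-linker oligos are rejected): a long
**stabilizer** that anchors annealing and a short **determiner**. A 3' C3
spacer (trailing `3` in the printed sequence) makes the oligo
non-extendable; blockers without a spacer would themselves prime and are
rejected as unsupported. Segment orientation follows the naming convention
of the printed blockers (plain `DPO` = 5' stabilizer / 3' determiner;
`DPOr` = reversed) and can be overridden explicitly.

Blockers act through full hybridization, so segment matching is exact
(per-position set intersection, inosine universal) rather than
mismatch-tolerant; the best-matching window on the template is located
first (fewest mismatches, leftmost tie-break). With S = "stabilizer segment
fully matched" and D = "determiner fully matched":

| orientation | S | D | outcome |
|---|---|---|---|
| conventional (5' stab, 3' det) | yes | any | blocked |
| conventional | no | any | unaffected |
| reversed (5' det, 3' stab) | yes | yes | blocked |
| reversed | yes | no | arrest_only |
| reversed | no | any | unaffected |

A mismatched 3' determiner on a conventional blocker acts like the C3
spacer itself — annealing without extension — so the stabilizer alone
blocks. On a reversed blocker the stabilizer sits 3', so a template matching
only the stabilizer truncates extension without preventing amplification
(elongation arrest). Non-DPO spacer blockers block only on a full-length
match. All eight orientation × S × D combinations are tested against
engineered templates, and an engineered four-species panel reproduces the
qualitative contrast that motivates reversed DPOs: the conventional blocker
suppresses every template whose stabilizer window matches (predator and
prey alike), while the reversed and plain blockers suppress only the
predator template.

## Diet metrics and their denominators

For prey species *i*, the index of relative importance is
IRI\_i = %O\_i × (%W\_i + %N\_i), normalized to %IRI across identified
species. Two denominator conventions are deliberately explicit because the
published numbers pin them down:

* **%O** defaults to occurrence out of *non-empty* stomachs. For the
  embedded Smallmouth Bass table, 144 occurrences over 264 − 97 = 167
  non-empty stomachs gives 86%, matching the reported frequency; dividing by
  all 264 does not. The all-predators denominator remains selectable, and
  %IRI is invariant to the choice (a uniform rescaling of %O cancels in the
  normalization — property-tested).
* **%W and %N** default to totals *including* unidentifiable remains (the
  coarse Fish/Crayfish class rows): 81.6 g of Round Goby over 285.7 g of
  total Largemouth stomach contents reproduces the reported 29% by weight.
  Identified-only denominators are selectable.

Aggregate tables follow the published layout, where the coarse rows are
class totals that already include the identified species
(`coarse_are_totals = TRUE`); record-level tables aggregate coarse rows
from the unidentified remains only, and the including-unidentified
denominators are then the sums over all rows. Coarse classes never receive
IRI rows. Machine outputs carry unrounded values; display rounding is left
to the caller.

Descriptive stomach summaries (items per stomach with empty stomachs
counting zero, weight per item, weight per stomach, percent empty) use the
n − 1 sample standard deviation over √n for standard errors.

## Hill diversity

The diversity profile reports the Hill number
^qD = (Σ p\_i^q)^(1/(1−q)) of the identified-prey numerical composition
over a grid of orders (default 0 to 3 by 0.1), with the Shannon limit
exp(−Σ p\_i ln p\_i) substituted within 10^-12 of q = 1. ^0D is species
richness, ^2D inverse Simpson concentration; the profile is non-increasing
in q and equals richness for uniform compositions (both property-tested,
and q = 1 / q = 2 values are cross-checked against vegan's independent
implementation). The **plug-in** (empirical) estimator is used throughout;
no small-sample bias correction is applied. For strongly dominated
compositions the plug-in exponential-Shannon value is slightly smaller than
asymptotic coverage-based estimators, so published diversities computed with
a corrected estimator can sit a few percent above the plug-in value at
q = 1; only values reproducible from the embedded composition tables by the
plug-in form are asserted in the test suite. Proportions must be strictly
positive and sum to 1 within 10^-9.

## Isotopes and body condition

Trophic position is the linear map TP = (δ15N − baseline)/enrichment + 2
with defaults baseline = 8.5 ‰ and enrichment = 3.4 ‰ per trophic level: the
baseline organism sits at TP 2 and each enrichment step adds one level.
Relative weight is Wr = 100 · W / Ws(L) with the species' standard-weight
power law log10 Ws = a + b·log10 L (L in mm, Ws in g; a = −5.528, b = 3.273
for Largemouth and a = −5.329, b = 3.200 for Smallmouth Bass, as printed).
Fulton's condition factor is K = c · W / L³; the source cites its condition
factor reference without printing the formula, so the conventional constant
c = 100 for grams and centimetres is the default and c is configurable
(the unit identity c' = c · (length factor)³ / (weight factor) is tested).

## Synthetic data: what it emulates and what it does not

The generators exist so every stage is testable offline against known
ground truth; each returns a machine-readable truth record and is
seed-deterministic to the byte (one RNG stream per call via `withr`, no
global state).

* `simulate_voucher_set()` plants the diagnostic structure the design search
  must recover: one random ancestor per species, per-base mutated vouchers
  (default 2% divergence within species — typical of intraspecific COI
  variation), the target enzyme's site written at one fixed locus in every
  target voucher, and site absence (liberal mode, both strands) enforced in
  all non-target vouchers by bounded redraws. Optional ambiguity injection
  replaces positions with compatible IUPAC codes without violating the
  plant. Passing `scrub_enzymes` additionally removes the decoy catalog's
  sites from every voucher, making the planted enzyme the unique diagnostic
  by construction; without it the plant is still always recovered, but a
  decoy can qualify by chance when the target ancestor happens to carry its
  site.
* `simulate_pcr_template()` builds templates with exact cocktail binding
  sites around a random interior, plants restriction sites at requested
  amplicon cut coordinates (verifying afterwards that the digest cuts
  exactly there), and writes blocker windows whose stabilizer/determiner
  segments match or mismatch on demand (about 40% of a mismatched segment's
  positions, at least two, are flipped to non-pairing bases, leaving the
  window the best-matching locus).
* `simulate_stomach_table()` emulates the statistical structure of the
  dissection data: empty stomachs at a fixed probability (default 97/264),
  1 + Poisson items otherwise (default mean 287/167 items per non-empty
  stomach), multinomial prey composition (default the embedded Smallmouth
  number column), lognormal wet weights (default mean ≈ 4.25 g, σ_log = 0.8
  — strictly positive and right-skewed like gut-content masses), and
  rank-dependent identification failure that coarsens the taxon to its
  class, with the generating truth logged.

None of this is a model of molecular evolution, annealing thermodynamics or
digestion kinetics: vouchers mutate uniformly with no substitution model,
primer binding has no melting-temperature component (printed
melting temperatures are not reproduced, by design), and digestion ranks are
sampled independently of item weight. Passing tests therefore demonstrate
that the algorithms recover planted structure under realistic sampling
noise — not that the defaults describe any particular lake's food web.

## Numerical choices and degenerate inputs

* Proportion sum tolerance 10^-9; q = 1 switch at |q − 1| < 10^-12; the
  q → 1 continuity of the Hill profile is asserted to 10^-6.
* Empty error-rate denominators yield `NA` ("not applicable"), never 0: a
  corroboration set with no true non-targets cannot estimate a
  false-positive rate.
* Zero diet denominators (no non-empty stomachs, zero total weight) are
  errors, not NaN propagation.
* Blocker window location breaks ties leftmost; site scans report
  overlapping occurrences individually; catalog and species orders are
  preserved end-to-end so reports are deterministic.
* Test problem sizes are deliberately desk-scale: voucher sets of 5 species
  × 10 vouchers × 652 bp across 20 seeds for recovery properties, 100
  random small cut matrices against brute-force enumeration, and one
  Monte-Carlo stomach table at the study's n = 264 checked within binomial
  sampling error (±3 percentage points on the dominant species' %IRI).

## Known limitations

The enzyme catalog shipped is a small fixture (the three assay enzymes plus
common decoys); the full commercial catalog used originally is not
redistributed, and any user catalog in the same CSV format is accepted. The
packaged Round Goby voucher set is a synthetic stand-in generated by
`simulate_voucher_set()` (the real reference records live in public barcode
repositories and are not bundled), so design-search results on it validate
the algorithm, not the biology. Melting temperatures, methylation
sensitivity, star activity, partial digestion and circular templates are out
of scope, as are inferential comparisons between predators (standard t/ANOVA
machinery applies directly to the descriptive outputs if wanted).
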