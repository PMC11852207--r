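---
title: "Modelling and decoding shufflon recombination assays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and decoding shufflon recombination assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shufflonr)
```

## The system being modelled

A shufflon is a multiple DNA inversion system: $n$ invertible segments
("modules") separated and flanked by $n+1$ copies of a recombination
site in alternating orientation, all recombined by one site-specific
tyrosine-family invertase. The site (called *sfx* in the canonical
R64 *pil* system) is 31 nt: a 12-bp variable left arm, a 7-bp core and a
12-bp conserved right arm. The arm asymmetry restricts the enzyme to
inversions — excisions require artificially symmetric sites — which is
what makes shufflons attractive as in-vivo DNA barcoding devices: the
module arrangement is a barcode that diversifies over time without
losing sequence.

`shufflonr` implements the quantitative machinery needed to design,
simulate and analyse reporter assays built on this system: the
configuration model and its combinatorics, a synthetic library and
noisy long-read generator, two independent read decoders, the library
statistics, and a k-mer screen for discovering candidate sites in
flanking DNA.

## The parity-constrained permutation model

Because sites alternate in orientation, a single inversion acts between
two junctions an **odd** distance apart (an even distance would pair
two sites of equal orientation, which cannot recombine by inversion).
Reversing an odd-length block of modules maps odd positions to odd
positions, so module ids and positions are conserved modulo 2: odd
modules visit only odd positions, even modules only even positions,
and every module can be inverted in place. The number of configurations
is therefore

$$N(n) = \lceil n/2\rceil!\;\lfloor n/2\rfloor!\;2^n,$$

giving $N(5) = 3!\,2!\,2^5 = 384$ and $N(11) = 6!\,5!\,2^{11} =
176{,}947{,}200$.

```{r}
count_configurations(5)
count_configurations(11)
```

The package validates this count two independent ways: by full
enumeration of signed permutations under the parity rule, and by
breadth-first closure of the reference configuration under the
mechanistic inversion-event model (`reachable_set()`), which also
yields each configuration's minimal event count. That the closure
equals the enumerated set for every $n$ tested is itself one of the
test-suite invariants.

## The reporter design and its defaults

`default_design()` builds a synthetic five-module reporter with module
lengths 143, 237, 332, 426 and 521 bp. Only the length range (143 to
521 bp, increasing) is fixed by the assayed construct; the three
interior lengths are an evenly spaced interpolation chosen so lengths
are unique and monotone. Anchors default to 1250 bp per side. The
described flanking was "about 2 kb" of anchor around the shufflon and
a size selection at about 4.5 kb; reading 2 kb as the *total* anchor
contribution makes the default amplicon 4345 bp, consistent with the
4.5 kb gel band, whereas 2 kb per side would overshoot it. Both
choices are configurable.

Module, anchor and site sequences are generated pseudo-randomly from a
fixed seed and screened so that **no 15-mer is shared between any two
design sequences on either strand** and no module contains the site.
This screen is what makes the marker decoder well-posed; real dummy
sequences would be designed the same way. Site copies are rendered at
fixed junction positions in fixed alternating orientation for every
configuration: recombination between identical sites regenerates the
sites, so only module content and orientation distinguish references.
One consequence worth noting: the reference set models a single sfx
sequence per reporter. Hybrid sites (differing left arms recombined
together) do not arise in a single-site reporter and are not modelled.

## The synthetic data generator

`simulate_library()` draws, per member, $k \sim \text{Poisson}(\lambda)$
inversion events (memoryless recombination during incubation) and
applies them sequentially; `fixed_events` provides a deterministic mode
for tests. Event weights default to uniform over the valid odd-span
junction pairs; whether all pairs recombine equally in vivo is unknown
(the assayed libraries show positional bias), so the weights are an
explicit parameter and a `positional_bias` preset down-weights events
that involve a terminal junction, mimicking the observation that
terminal modules shuffle less.

`simulate_reads()` applies independent per-base substitutions,
insertions and deletions (defaults 2%/2%/2%, the magnitude of
R9.4-era nanopore reads; no error figures were reported for the
original data) and reverse-complements each read with probability 0.5.
What the generator deliberately does **not** emulate: quality-score
structure, homopolymer-specific error enrichment, chimeric or
truncated reads, and carry-over between barcodes. A green decoding
test therefore establishes correctness of the decoding logic under
i.i.d. noise of realistic magnitude, not robustness to every ONT
artefact.

Because every uniform-weight event is an involution, the one-step
transition matrix of the configuration chain is symmetric and doubly
stochastic, so its stationary distribution is uniform — heavily
shuffled libraries approach the uniform law over all 384 states. The
explicit chain (`transition_matrix()`, `expected_shuffling_rate()`)
is the analytic oracle the simulator is tested against: the expected
shuffling rate at rate $\lambda$ is
$1 - \sum_k \text{Pois}(k;\lambda)\,(P^k)_{\text{ref},\text{ref}}$.
Tests run this comparison at 2000–3000 members and a 3-standard-error
band; the stationary-law check is run on the 16-state three-module
chain rather than the full 384-state one to keep the suite fast — the
algebraic argument does not depend on $n$.

## Decoding reads

Two decoders are implemented and kept deliberately independent:

* `classify_read()` (production): k-mer markers unique to one design
  sequence and strand locate each module; the median marker position
  gives the module's position, the majority marker strand its
  orientation, anchor markers fix the global strand. A call must find
  all $n$ modules, satisfy the parity invariant and reach a
  marker-consistency score of `min_score` (default 0.6); anything else
  is `unclassified`. Defaults $k = 15$ and 10 markers minimum per
  module: a 15-mer survives ~6% error with probability
  $0.94^{15} \approx 0.40$, so even the shortest 143-bp module
  (~129 markers) retains dozens of intact markers per read.
* `classify_read_exhaustive()` (oracle): global Levenshtein distance
  from the read and its reverse complement to every reference, via a
  multi-word bit-parallel algorithm in C++ with best-so-far early
  abandonment (pruned comparisons are provably worse than the minimum,
  so tie semantics are unaffected). The original pipeline filtered
  alignments at an aligner-specific score (AS > 7500); that cutoff is
  translated to a scale-free identity floor of 0.80. Any tie at the
  minimum distance is returned unclassified rather than broken
  arbitrarily, because misassignment inflates diversity estimates.

The size filter (default ±15% around the expected amplicon length)
mirrors the "approximate 4.5 kb" selection; "approximate" is all the
description gives, and ±15% comfortably passes 6%-error reads while
rejecting half-length molecules.

## Statistics

The shuffling rate is the fraction of **classified** reads not in the
reference configuration; unclassified reads never enter the
denominator (the reported rates were fractions of analysed reads).
Occupancy is the per-position distribution over signed modules;
parity-forbidden cells are structural zeros. Replicate pooling is
always explicit (`pool_summaries()`), matching the distinction between
averaging per-replicate rates and pooling members before occupancy.

Diversity under subsampling draws members **with replacement**
proportional to counts; the original 4000-member analysis does not say
whether replacement was used, and with-replacement sampling stays
well-defined when the subsample exceeds the library. Against a uniform
library the mean unique count has the closed form
$384\,(1 - (1 - 1/384)^m)$, which the implementation is tested
against.

The inversion-frequency table restricts to reads whose unsigned module
order is the reference order and measures, per module, the frequency
of the inverted orientation — and the regression of that frequency on
module length (continuous) plus invertase identity (categorical,
treatment coding against a stated reference level) reproduces the
analysis of whether longer modules invert less often. The exact factor
encoding used originally is unstated; treatment coding with a
user-selectable baseline is documented here as this package's choice.
Routine group-comparison tests (Welch ANOVA, Dunnett's C, Welch
t-tests) are intentionally out of scope: they are off-the-shelf and
carry no assay-specific logic.

## Mining flanking DNA for candidate sites

`find_repeats()` tabulates every k-mer (default $k = 13$, the longest
conserved stretch of the canonical site) with reverse-complement
canonicalisation and reports those occurring at least twice on one
strand (direct repeat) or on both strands (inverted repeat).
Overlapping occurrences are counted — the source description does not
say, and counting them is the more complete choice; reports note it.
Each flanking record is scanned independently. A 13-mer, being of odd
length, can never equal its own reverse complement, so palindromy is
assessed at the 31-nt site level instead: identity between the left
arm and the reverse complement of the right arm, threshold 0.75, with
fully palindromic candidates excluded from representative picking the
way palindromic homologues were excluded from the screen.
`reconstruct_sites()` places the conserved 13-mer flush with the right
end of the 31-nt window by default (offset 18), because the conserved
portion lies in core + right arm; the exact register is not printed
anywhere, so the offset is a parameter. The upstream protein-homology
search that produces flanking regions requires a live sequence
database and is out of scope; mining starts from user-provided FASTA.

## Numerical and engineering choices

* Coordinates are 0-based half-open internally, 1-based only in
  reports. Orientation `+` is the forward strand of the reference.
* The configuration string (`"+1-4+3-2+5"`) is the canonical key in
  every table, file and JSON object.
* All randomness flows through explicit integer seeds; library calls
  restore the caller's RNG state. Pipeline child seeds derive from the
  master seed by fixed offsets and stay below $2^{31}$.
* The bit-parallel edit distance treats `N` as matching nothing and is
  verified against `utils::adist` over random and structured cases,
  including multi-word patterns.
* Enumeration (and hence exhaustive classification and the explicit
  chain) is capped at $n = 7$ by default; beyond that the analytic
  count is the supported route.

## Known limitations

* The marker decoder requires globally unique k-mers across the
  design; highly repetitive custom modules will be rejected at
  index-building time rather than mis-decoded.
* The exhaustive decoder is quadratic per read and meant for oracles
  and small batches.
* The error model is i.i.d.; systematic ONT artefacts are not
  represented, so decoder accuracy on real flowcell data may differ
  from the simulated figures.
* Wet-lab shuffling rates and mining yields from the original study
  depend on unreleased sequencing data and a live database; they are
  covered here by property-based and closed-form checks, not by
  numeric reproduction.
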