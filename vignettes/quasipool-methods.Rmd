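---
title: "Methods: quasispecies pool analysis for aptamer selections from homopolymeric seeds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quasispecies pool analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quasipool)
```

## The setting

In a conventional SELEX experiment an aptamer is fished out of a vast random
pool. The opposite regime — starting from a *single*, informationally poor
seed molecule and letting error-prone replication generate the diversity —
produces a quasispecies: a cloud of genotypes radiating from the seed, shaped
each round by selection for ligand binding. quasipool implements the
computational side of such a campaign: pool input/output, a stochastic
simulator of the error-prone replication/selection loop, diversity and
mutation-rate statistics, structural motif search, folding-energy profiles,
sequence-space embeddings, and the one-site binding isotherm used to
characterize the selected aptamers by isothermal titration calorimetry (ITC).

The canonical construct is 69 nt: a central 39 nt homopolymer (poly-A or
poly-T/U) flanked by two different 15 nt primer-binding sites that are
conserved during amplification. `seed_construct()` models this decomposition
and accepts arbitrary cores; `validate_seed()` enforces the 15 + 39 + 15
geometry.

### Synthetic stand-in seeds

The five classic campaign seeds (T4–T8) are published only in supplementary
material not redistributed here. `synthetic_seed()` therefore ships
*synthetic* constructs: correct geometry and core composition, arbitrary
fixed primers with roughly balanced base usage. Every pool-level statistic in
this package (distances, mutation rates, motif frequencies, calibrations) is
insensitive to the precise primer sequences; sequence-specific quantities —
notably the folding free energies of the real seeds (−7.3 kcal/mol for the
T5-type seed, −2.3 for T8) — are **not** reproduced by the stand-ins, and the
package makes no attempt to imitate them.

## The replication simulator

One call to `replicate_pool()` represents one full diversification step
(biologically: reverse transcription, error-prone PCR and sequencing are one
aggregate error channel — the three sources cannot be separated by
sequencing the output, so no attempt is made to model them separately).
Events per molecule, in order:

1. **Homopolymer slippage** — each base run of length ≥ `min_run_len`
   (default 4) suffers at most one slippage event with probability
   `slippage_rate`; the signed run-length change is drawn from
   `slippage_step_dist`. The shipped distribution (`slippage_steps()`) is a
   truncated geometric over magnitudes 1–6 with a 0.8 contraction bias:
   polymerases stutter on homopolymers and predominantly shorten them, which
   is how heavily truncated inserts come to dominate early pools.
2. **Substitutions** — per-base probability `sub_rate`; a substituted base
   becomes its transition partner with odds `ts_tv_ratio` (default 0.8,
   the near-equal transition/transversion ratio characteristic of
   Mn^2+^-driven error-prone PCR) against the two transversions.
3. **Indels** — per-base probability `indel_rate`, split evenly between
   deleting the base and inserting a random base before it.
4. **Recombination** — with probability `recomb_rate` per molecule,
   `recombine()` joins a uniform prefix of the molecule to a uniform suffix
   of an independently drawn partner. Because cut points are independent,
   products can carry duplications (e.g. a partial second copy of a primer,
   the kind of event that creates a bulged-G motif out of flank sequence) or
   internal deletions. Only single crossovers are modelled.

Primer flanks are excluded from mutation (`protect_prefix`/`protect_suffix`),
because the primer-binding sites are conserved by the amplification design;
recombination may still duplicate flank fragments. Adjacent transpositions
are *not* an explicit mutation channel — swap-like changes arise through
indel pairs — but the distance metric (below) counts a transposition as one
operation, because the analysis measures, rather than mechanistically
models, them.

Template choice is weighted by `count * exp(-truncation_bias * length)`:
shorter molecules replicate better, the "tyranny of the short motif" that
lets parasitic truncated inserts take over a pool.

**Selection** (`select_pool()`) retains each molecule independently with
probability `min(1, background_capture + capture_scale * score /
stringency)`. The score is a named rule: an indicator for the degenerate
recognition loop, an indicator for a full structural descriptor hit, or a
constant. `stringency` (scalar or per-round schedule) emulates harsher
elution in late rounds. Total reads never increase across selection.

**Round structure** (`run_campaign()`): round 0 is one replication step
applied to a seed-only pool (the initial standard-plus-error-prone PCR is
collapsed into the same parameterized step as every other round); each later
round is select-then-replicate back up to `molecules_per_round`. Everything
is driven by the single `rng_seed`, so a configuration reproduces its pools
bit for bit.

**Calibration.** The default `replication_params()` were chosen so that a
diversified round-0 pool sits at a mean Damerau-Levenshtein distance of
roughly 4–7 from its seed — the observed regime for poly-A seed campaigns,
corresponding to average per-base mutation rates of 10–18% over the 39 nt
core (`rate_from_distance(c(4, 7), 39)`). The defaults are fixed constants
of the package, not tuning knobs; the test suite verifies the band over ten
replicate simulations of 600 molecules each.

## Diversity statistics

`damerau_levenshtein()` implements the *restricted* (optimal string
alignment) Damerau-Levenshtein distance: the Wagner-Fischer dynamic program
extended with one adjacent-transposition row, unit cost per substitution,
insertion, deletion or transposition. The restricted variant never edits a
transposed pair again; it can therefore exceed the unrestricted Damerau
distance and does not satisfy the triangle inequality — acceptable here
because distances are always taken to a fixed reference, never chained.
U and T are identified before comparison, so DNA and RNA views of one
molecule are at distance zero. Plain `levenshtein()` (via `utils::adist`) is
exposed as a cross-check: transpositions can only lower the distance.

Distances are computed on full constructs by default (primers included,
matching how reads are prepared for the embedding workflow); pass trimmed
pools and the core as reference for insert-only distances.
`pool_distance_distribution()` summarises per unique sequence by default —
round-by-round reporting in this field counts unique sequences — with
abundance weighting behind a flag.

`random_pool_baseline()` generates the classic comparison pool: the seed's
own primers around uniform-random inserts. For a 39 nt homopolymer core the
expected distance is 39 × 3/4 = 29.25 — each uniform base differs from the
core base with probability 3/4 and costs one substitution; primers are
shared and contribute nothing. The simulated mean (~29.2) sits marginally
below the analytic value because rare alignments share indel savings across
the insert boundary.

`positionwise_mutation_rate()` implements the per-position rate
M~i~ = 1 − C~i~/T~i~, with C~i~ the count of reads carrying the reference
base at core position i and T~i~ the reads covering i. Since the source
analysis does not state how reads were mapped onto positions, two modes are
provided: the default `"full_length"` counts only inserts of exactly the
core length (no alignment ambiguity); `"leftmost"` lets shorter inserts
contribute to the positions they cover under a leftmost mapping. Positions
with T~i~ = 0 are undefined (`NA`) and excluded from the mean; the suite
checks the conservation identity Σ T~i~M~i~ = total mismatches.

## Motif search

Two layers, matching how nucleotide-aptamer motifs are actually hunted:

* `scan_iupac()` — degenerate consensus scanning (the 11 nt purine-rich
  recognition loop `GGNAGANNNTG`, of which 7 positions are conserved —
  `conserved_position_count()`). All overlapping match positions are
  reported; frequencies are given as % of unique sequences (and
  abundance-weighted). Scanning is U/T-agnostic.
* `parse_descriptor()` / `match_descriptor()` — the helix/strand structural
  descriptor dialect: an element-order line (`h1 s1 h2 s2 h2' s3 h1'`)
  followed by per-element definitions. Interpretation choices, each
  documented because the dialect's printed examples do not exercise them:
  * the bounded repeat `X[k]` expands to 0–k copies, so the spacer `N[30]N`
    spans 1–31 nt (the convention of the descriptor tool family this dialect
    comes from);
  * a helix mismatch pair `a:b` allows `a` pattern mismatches across both
    halves and `b` non-Watson-Crick pairings between them (the printed
    motifs use `0:0`, so the choice is inert there);
  * helix complementarity is strict Watson-Crick by default; G:T/G:U wobble
    sits behind a flag;
  * the `"reverse"` orientation swaps the first and last strand of the
    topology — bulge before loop — mirroring the reverse arrangement of the
    canonical ATP motif.

  Matching enumerates *every* placement consistent with the constraints
  (backtracking over element spans, 1-based inclusive coordinates in the
  output); an independent exhaustive span-enumeration oracle pins the
  matcher down in the tests. `canonical_atp_descriptor()` ships the strict
  and relaxed canonical ATP motifs (relaxed frees loop position 9), and the
  suite verifies that deleting the essential bulged G (`s3`) abolishes the
  hit.

## Folding and embedding

`fold()` hides two engines behind one interface. The external engine shells
out to ViennaRNA's `RNAfold` for thermodynamic minimum-free-energy structures
(kcal/mol, 37 °C default). The fallback is a self-contained maximum
base-pair folder (Nussinov-style dynamic program, hairpin loops ≥ 3,
Watson-Crick + wobble) whose surrogate "energy" is −(pair count). The
surrogate is for engine-free testing and relative comparisons only; results
carry an engine tag and `pool_energy_distribution()` never mixes the two
scales in one distribution. If the external engine is absent the error says
so explicitly — there is no silent substitution.

`encode_pool()` one-hot encodes sequences into `pad_len × 4` binary rows
(zero-padded; default pad 50 for insert-level reads — the pipeline uses a
larger pad because full constructs with indels and duplications run longer).
The literature phrase "binary triplet encoding" is ambiguous (three channels
cannot one-hot four bases); the package defaults to standard 4-channel
one-hot and offers a compact 3-channel binary code behind a flag — the
embedding's qualitative behaviour, not the channel count, is the contract.
Encoding is exactly invertible via stored lengths.

`embed_rounds()` fits **one** model on the merged, collapsed encoding of all
rounds and *transforms* each round through it, so per-round coordinate sets
live in a single space and shared sequences coincide. The engine is a
fit/transform adapter; `pca_engine()` (first two principal components) is
the always-available implementation, and a t-SNE-style engine with the same
contract can be dropped in (recorded `params` such as perplexity are for
that use). Implementing embedding internals is out of scope by design.
In the pipeline, rare recombinants longer than the pad are excluded from the
embedding stage and counted, rather than aborting the analysis.

## The one-site ITC model

`predict_heats()` implements the standard single-set-of-sites isotherm with
displacement-cell bookkeeping. With cell volume V₀ and injection volume dV,
concentrations dilute by (1 − dV/V₀) per injection while the syringe adds
titrant; the bound-site concentration B is the admissible root of

  B² − (nM + X + K~d~)B + nMX = 0,

bounded by both total sites nM and total titrant X, and the heat of
injection i is ΔH·V₀·(B~i~ − B~i−1~(1 − dV/V₀)) + offset (µcal; ΔH in
kcal/mol, concentrations µM, volumes µL). `simulate_itc()` generates curves
under this model — default protocol: a 0.5 µL pre-injection flagged excluded,
then 14 × 2.8 µL, cell 6 µM, syringe 200 µM — and `fit_one_site()` recovers
the free parameters among {K~d~, n, ΔH, offset} by Levenberg-Marquardt least
squares on the non-excluded heats. Auto-initialisation uses ΔH from the
first informative heat and a coarse multi-start over K~d~ (0.05×, 0.5×, 5×
the cell concentration, best residual wins), which keeps near-stoichiometric
curves (K~d~ ≪ cell concentration) out of the K~d~ → 0 local minimum.
Fixing parameters (`fixed = list(n = 0.5)`) reproduces constrained-
stoichiometry fitting — the practical recourse when active concentrations
are uncertain. An all-zero titration is reported as "no detectable binding"
with an unidentifiable K~d~ rather than a number.

Because the original raw thermograms are not available, the module's
validation surface is simulate-and-recover: noise-free closed loops are
exact to ≥ 6 significant digits across K~d~ ∈ {0.5, 7, 50} µM × n ∈
{0.5, 1} (spanning the reported low-micromolar affinities), the median of
noisy replicates recovers K~d~ within 15%, and parameter standard errors
grow with noise.

## Numerical and testing choices

* Determinism: all stochastic components draw from the R session RNG;
  campaign and pipeline configurations carry an `rng_seed` and reproduce
  outputs identically.
* Collapsing sorts by descending abundance with lexicographic tie-breaks,
  so pool order is deterministic.
* Problem sizes in the test suite are chosen for statistical resolution at
  interactive runtimes: exhaustive distance checks over two-letter strings
  to length 6, 10⁴-sequence random baselines, 600–1200-molecule simulated
  rounds, 60-replicate Monte-Carlo recovery. The synthetic generator's
  *parameters* are the study conditions; only cohort sizes are scaled.
* Degenerate inputs are first-class: empty pools read and collapse cleanly,
  empty inserts survive trimming (truncation parasites are a finding, not an
  error), zero-length random inserts give the forced-deletion distance, and
  sub-minimum titrations are rejected with a clear message.

## What passing tests do and do not show

The simulator emulates the *statistical structure* the analyses assume —
substitution/indel/slippage spectra, truncation takeover, motif enrichment
under selection, round-0 distance calibration. It does not model
thermocycler-resolved PCR, polymerase-specific error spectra, RNA/DNA strand
bookkeeping, or multi-crossover recombination; real pools additionally carry
sequencing artefacts and round-to-round protocol drift that no aggregate
channel reproduces. Motif-frequency trajectories and embedding geometries
obtained on simulated pools therefore validate the *analysis code*, not any
particular biological claim; and because the bundled seeds are synthetic
stand-ins, sequence-specific published values (seed folding energies, real
aptamer affinities) are deliberately outside what this package can or does
reproduce.
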