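---
title: "Designing and scoring deterministic deep-mutagenesis libraries with midaskit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and scoring deterministic deep-mutagenesis libraries with midaskit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(midaskit)
```

## The problem midaskit addresses

Microbe-independent deep assembly and screening (MIDAS) constructs protein
variant libraries deterministically: every desired variant of a gene is
assembled as a linear PCR product in its own well of a multiwell block and
transfected directly into mammalian cells, so variant identity is tracked
by well position rather than by sequencing. The approach replaces both
plasmid cloning and degenerate-oligo libraries, and its construction step
is pure bookkeeping — exact oligo sequences, segmented PCR plans, plate
maps — which is what this package automates. The same experiments produce
site-by-substitution activity tables, so the package also implements the
downstream scoring: normalization, mutational-tolerance aggregation,
substrate-specificity analysis with censoring, and dose-response fitting.

Four scheme variants are covered, named by their two design axes:

* **polytemplated vs monotemplated** — whether the left-most and right-most
  primary PCRs use plasmids with distinct backbone priming sites, or a
  single template plasmid. In the monotemplated case the secondary PCR
  would re-amplify residual plasmid carried over from unpurified mutagenic
  primaries; the package therefore attaches 5' *tag* extensions (sequences
  absent from the template) to the outer primers and emits nested primers
  that prime only on the tags.
* **monofocal vs polyfocal** — mutagenesis at one target region (TR) or at
  several TRs spread over the coding sequence, assembled from `i + 1`
  overlapping segments for `i` TRs.

## Primer design rules

A mutagenic forward primer for a TR is built as
`5'-flank | payload | 3'-flank`: the 5' flank copies the template
immediately upstream of the TR, the payload replaces the TR span (a codon
substitution from the active codon table, an insertion, a deletion, or a
whole-segment replacement), and the 3' flank anneals immediately
downstream. Its non-mutagenic counter primer is the reverse complement of
the template window ending just before the TR, so the counter's 5' region
is reverse-complementary to the shared 5' flank of every member of a
saturation array — this overlap is what lets the upstream segment extend
across the junction in the secondary PCR. A mirror-symmetric
reverse-mutagenic mode puts the payload on the reverse primer.

Flank lengths are either explicit (to reproduce a published array exactly)
or chosen automatically: start at 18 nt and grow one base at a time until
the flank's duplex melting temperature reaches 60 °C, warn beyond 24 nt,
hard-stop at 40 nt. The 18–24 nt window and the 60–66 °C overlap window are
the protocol's standard bounds; the growth rule exists because AT-rich
contexts genuinely need longer arms (one published 3' arm is 30 nt), so the
upper bound is advisory rather than hard. Exceeding 66 °C at the minimum
length warns but never shortens a flank below 18 nt.

### Melting temperature

No installed R package computes oligo nearest-neighbor melting
temperatures, so `melting_temperature()` implements the two-state
nearest-neighbor model with the unified 1998 parameter set: per-dinucleotide
enthalpy/entropy terms, terminal A·T / G·C initiation corrections, a
symmetry correction for self-complementary oligos, and the entropic
monovalent-salt correction `ΔS += 0.368 · (N−1) · ln[Na+]`. Defaults are
50 mM monovalent salt and 500 nM total strand concentration (CT/4 in the
two-state formula); the protocol literature does not state buffer
conditions for its Tm window, so both are explicit `tm_params()` fields
recorded in run metadata. The implementation is verified in the test suite
against frozen values computed with an independent implementation of the
same parameter set; agreement is within 0.01 °C.

### Tags

Monotemplated designs need a tag that the template cannot prime on.
`generate_tag()` draws seeded random 23-mers with 40–60 % GC and accepts
the first whose longest exact shared substring with the template (either
strand) is below 12 nt — long enough below the 15-nt in-silico priming
seed that nested primers cannot find a foothold. `validate_tag()` exposes
the same exhaustive scan as a report, and is also applied to user-supplied
tags.

## Assembly planning and in-silico verification

Two combinatorial schemes cover the polyfocal case:

* **per-segment** — one mutagenic primary PCR per variant per TR plus one
  constant left segment; secondaries are the cross product of per-TR
  amplicon choices (`Σᵢ |variantsᵢ|` mutagenic primaries, `Πᵢ |variantsᵢ|`
  secondaries).
* **per-permutation** — the middle segment carries both payloads (TR1 on
  its forward, TR2 on its mutagenic reverse primer), giving one primary
  per full permutation and one-to-one secondary transfer (`i × j`
  primaries). This trades more primaries for simpler liquid handling. The
  package implements it for up to two TRs — the layout it mirrors is the
  two-site case, and its generalization to more sites is ambiguous — while
  the per-segment scheme is fully general.

TRs closer than 60 nt cannot be separated by distinct amplicons (the
overlap and annealing arms would collide), so such pairs are merged into a
single TR-carrying primer when their combined span stays within the 12-nt
TR cap, and rejected with guidance otherwise. The 12-nt cap itself reflects
what a single oligo payload can carry; it is a hard limit with an override
argument because the underlying constraint is approximate.

`simulate_pcr()` models priming as an exact match of a primer's 3'-terminal
`k = 15` bases (configurable); mismatch-tolerant priming is deliberately out
of scope because every primer in these designs is template-exact outside
its payload. Products carry the primer's full 5' portion, which is how
payloads and tags enter amplicons. `simulate_assembly()` joins a
secondary's amplicons by unique maximal exact overlap (≥ 18 nt, mirroring
the counter/mutagenic overlap rule) and then applies the secondary primer
pair to *every* template in the mix. Setting `residual_template = TRUE`
adds the original plasmid to the mix, reproducing the re-amplification
hazard: untagged outer primers then return both the mutant and the parental
product, while tag-nested primers return only the mutant. Multi-site
priming yields multiple products rather than a silent choice.

## Library economics

`epcr_recovery()` implements the standard estimate of how often a specific
multi-nucleotide change is recovered from an error-prone PCR library:
`(rate × functional)^n × Π(aᵢ/4) × m`, where `rate` is the per-nucleotide
mutagenesis rate, `functional` the fraction of clones still active at that
rate, `n` the number of required base changes, `aᵢ` the number of
acceptable bases at change `i`, and `m` the number of mutually exclusive
codon paths. The `aᵢ/4` convention (rather than `aᵢ/3`, which would condition
on the base having changed) matches how these figures are conventionally
quoted; a strict `aᵢ/3` mode is available for sensitivity analysis and is
labelled as such. Reciprocals are reported as "1 in N" with one significant
figure below 10⁵ and two above, again matching quoting convention; the
exact value is always returned alongside. `degenerate_library_samples()`
(32^P × oversampling, default ×10) and `midas_sample_count()` (product for
combinatorial screens, sum for independent sites) complete the comparison
between degenerate, random, and arrayed construction.

## Screen scoring

Scoring proceeds in explicit stages so each assumption is visible:

1. `expression_normalize()` divides the reporter signal by a co-expressed
   reference (e.g. a second luciferase translated from the same amplicon),
   cancelling per-well transfection efficiency. This assumes the reference
   is unaffected by the perturbation being screened.
2. `normalize_response()` converts to fold or percent increase over the
   vehicle control; the two modes satisfy `percent = (fold − 1) × 100`.
3. `screen_score_matrix()` averages technical replicates (retaining
   per-variant CVs for diagnostics) and divides by parent activity.
4. `tolerance_scores()` aggregates each site's substitutions as both a sum
   and a mean of parent-relative activities. The mean is the headline score
   because it is scale-free when substitutions are missing; the sum over
   all 20 is reported alongside. The wild-type identity substitution is
   part of enumerated arrays and is included by default; whether to exclude
   it is genuinely a convention choice, so a flag (`include_wt`) supports
   both.
5. `specificity_matrix()` censors any variant whose activity falls
   *strictly* below 0.25 × parent on any substrate — dim wells have high
   CVs, and censoring prevents that error from propagating into
   preference ratios. Preference for substrate X over Y is the ratio of
   parent-relative activities (antisymmetric by construction); a ratio was
   chosen over a difference because it is invariant to per-substrate
   scale, with the difference available as an alternative statistic.
6. `fit_dose_response()` fits the four-parameter logistic on log dose
   (variable-slope model) by bounded Levenberg–Marquardt least squares.
   The initializer takes bottom/top from the response extremes, EC50 from
   the dose nearest the half-range crossing, and hill = 1; log-EC50 is
   bounded to the tested dose range extended one decade each way.
   Non-convergence is reported with the optimizer's message, never
   silently.

## What the synthetic generators emulate — and what they do not

`synthetic_unit()` produces seeded random templates with
promoter/CDS/polyA annotation, a clean reading frame, and optional embedded
local template fragments so the packaged primer arrays can be regenerated
from a full transcription unit; templates are rejection-sampled to share no
12-nt run with the packaged tag so tag-uniqueness checks are meaningful.
`synthetic_screen_truth()` and `simulate_screen()` plant known structure —
a fully tolerant site, a fully intolerant site, substrate-preferring
variants, censorable variants — under lognormal multiplicative noise
(default 5 % CV, 3 technical replicates, matching typical plate-reader
repeatability) with per-well transfection multipliers that the expression
normalization must cancel.

Passing recovery tests on these simulations shows that the scoring
pipeline inverts its own generative model at realistic noise levels. It
does not show robustness to features real screens have and the generator
does not: plate-position effects and reader drift, photon-counting
statistics at low signal, cross-well contamination, or biological
replicate variation. Published per-well screen data are not available in
machine-readable form, so reported biological constants (e.g. a dissociation
constant of 898 µM used in the dose-response scenarios) enter only as
generator inputs, never as asserted outputs.

## Problem sizes and numerical choices

The test suite and the acceptance script run, among others: regeneration of
both packaged 20-member primer arrays; contamination simulations on a
900-nt-CDS synthetic template; scheme-equivalence checks over 3 × 3 designs;
full fidelity verification of all 400 products of a 20 × 20 combinatorial
design on a 630-codon synthetic fusion (residues 560 and 610); and screen
recovery on 6 sites × 20 substitutions × 3 substrates. These sizes match
the scales the protocol itself uses, and every simulated quantity is
recomputed at run time from the stated seeds. Ties in `layout_plates()`
are avoided by construction (row-major deterministic fill); all generators
take explicit seeds; degenerate inputs (empty payload lists, zero-reaction
layouts, empty sequences) are exercised in the tests.

## Known limitations

* Primer-dimer and hairpin screening are out of scope; designs are
  enumerated and template-exact, but thermodynamically pathological flanks
  are only caught indirectly through the Tm window.
* The in-silico PCR model is exact-match; it cannot represent polymerase
  errors or mispriming below the `k`-mer threshold.
* Only forward-strand, intron-free CDS features are supported.
* The per-permutation scheme is limited to two TRs.
* GenBank parsing covers simple forward `start..end` features only, which
  is sufficient for transcription-unit templates but not arbitrary records.
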