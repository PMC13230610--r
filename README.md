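# midaskit

Design and analysis toolkit for deterministic deep mutagenesis by PCR
assembly (MIDAS: microbe-independent deep assembly and screening).

## What it is for

MIDAS builds protein variant libraries without microbial cloning: every
variant gene — promoter, coding sequence, polyadenylation signal — is
assembled as a linear PCR product in its own well and transfected directly
into mammalian cells, so variant identity is tracked by well position.
The construction step is deterministic bookkeeping, and that is what this
package automates for people running such screens:

* **Primer design** — enumerated saturation-mutagenesis arrays (one exact
  oligo per amino acid, no NNS/NNK degeneracy): mutagenic primers built as
  `5'-flank | payload codon | 3'-flank`, non-mutagenic counter primers
  whose 5' region is reverse-complementary to the array's shared flank,
  outer primers bracketing the transcription unit, and — for
  single-template (monotemplated) designs — 5' tag extensions absent from
  the template plus nested primers that prime only on the tags, which
  prevents the secondary PCR from re-amplifying residual plasmid.
  Flank lengths follow the 18–24 nt / 60–66 °C overlap-Tm rules, with a
  nearest-neighbor melting-temperature model (unified parameter set,
  entropic salt correction) built in.
* **Assembly planning** — for `i` target regions, segmented plans with
  `i + 1` overlapping primary PCRs under two combinatorial schemes:
  *per-segment* (Σ variants mutagenic primaries, cross-product
  secondaries) or *per-permutation* (`i × j` primaries, one-to-one
  secondaries), plus 96/384-well plate layouts.
* **In-silico verification** — exact-match PCR simulation
  (3'-terminal 15-mer priming) and overlap-extension joining, including
  the plasmid re-amplification hazard: untagged designs yield mixed
  mutant + parental product sets, tag-nested designs yield only the
  intended variant.
* **Library economics** — error-prone PCR recovery frequencies
  `(rate × functional)^n × Π(aᵢ/4) × m`, degenerate-library sizing
  `32^P × oversampling`, arrayed well counts, responsivity folds.
* **Screen scoring** — expression normalization against a co-expressed
  reference, vehicle normalization (fold / percent increase), per-site
  mutational tolerance (mean and sum of parent-relative activities),
  substrate-specificity matrices with strict <25 %-of-parent censoring,
  and four-parameter logistic (variable-slope) dose-response fits.

Seeded synthetic generators (templates with annotated features, multiwell
screens with planted truth) make every stage testable without external
data; published primer arrays are packaged as fixtures and regenerated
byte-for-byte by the design functions.

## Worked example

Design a 20-amino-acid saturation array at residue 108 of a luciferase
CDS, plan a single-template assembly, and verify the products in silico:

```r
library(midaskit)

unit <- fixture_unit("d108", seed = 1)       # synthetic template carrying
tr   <- resolve_target_region(unit, 108)     # the packaged D108 fragment
tr
#> <target_region> residues 108..108 (CDS 1), span [551,554), wt GAC (D)

arr <- design_saturation_array(unit, tr, flanks = c(19, 19))
arr$D108N
#> <primer_spec NanoLuc-D108N-F> [F_mut] 41 nt
#>   ggttacgccgaacatgatcAACtatttcggacggccgtatg

design_counter_primer(unit, tr, arr[[1]], length = 19)
#> <primer_spec NanoLuc-D108-R> [R_counter] 19 nt
#>   gatcatgttcggcgtaacc

plan <- plan_assembly(unit, list(saturation_set(tr)),
                      mode = "monotemplated",
                      tags = list(fo = midas_fixtures()$tag))
plan
#> <assembly_plan per-segment/monotemplated> 1 TR(s); 21 primary (20 mutagenic + 1 constant); 20 secondary

# tag-nested secondary primers cannot re-amplify residual plasmid:
length(simulate_assembly(plan, "D108S", residual_template = TRUE))
#> [1] 1
```

The mutagenic primer shows the payload codon uppercase between its
template-matching flanks; the counter primer is the reverse complement of
the shared 19-nt 5' flank. The assembly plan runs 21 primary PCRs (20
mutagenic right-side segments plus one constant left segment) and 20
secondaries, one per variant well. With residual plasmid in the mix the
tag-nested design still returns exactly one product — the intended
variant — whereas the same design with untagged outer primers would
return a mutant/parental mixture.

How rare would one of these variants be in a random library? A
substitution needing two adjacent base changes reachable by two codon
paths, at a 0.5 % mutagenesis rate that leaves 6.7 % of clones functional:

```r
rec <- epcr_recovery(epcr_model(0.005, 0.067, n = 2, acceptable = c(1, 1), paths = 2))
#> 1 in 7.13e+07 (reported 1 in 7.1e+07)
```

— which is why the 20-well arrayed screen is the practical route.

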