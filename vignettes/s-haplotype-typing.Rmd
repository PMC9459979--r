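---
title: "In-silico S-haplotype typing at the radish S locus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{In-silico S-haplotype typing at the radish S locus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stype)
```

## The problem

Radish (*Raphanus sativus*) carries a sporophytic self-incompatibility
(SSI) system: the highly polymorphic S locus (with the tightly linked
genes *SRK*, *SLG* and *SCR/SP11*) determines whether a stigma accepts or
rejects pollen. Because the pollen phenotype is set by the diploid pollen
parent, two lines that share an *expressed* S haplotype cannot set hybrid
seed at the flowering stage. Hybrid radish breeding therefore depends on
knowing which S haplotype each parental line carries, and on a nomenclature
in which alleles named independently by different research groups can be
compared at all.

`stype` implements the desk half of an S-haplotype identification system
built around the kinase domain (exons 4–7) of the stigma receptor gene
*SRK*:

1. **Nomenclature unification.** Published radish S-allele names from four
   naming schools are declared equivalent row-wise in a cross-reference
   table; transitive closure over those links yields non-redundant classes
   renumbered `NAU-S1`, `NAU-S2`, … The packaged table unifies to 52
   classes.
2. **Class typing by virtual PCR.** Two degenerate primer pairs amplify the
   kinase domain of Class I haplotypes (product ≈ 1200 nt) and Class II
   haplotypes (≈ 1000 nt). Which pair yields a product classifies a
   genotype as Class I, Class II, or a Class I/II heterozygote.
3. **PCR-RFLP.** Class I products digested with HinfI (recognition
   `GANTC`, cut after the G) produce allele-specific fragment patterns; a
   resolution-limited gel model groups genotypes into electrophoretic
   profiles without sequencing.
4. **Identity-based typing.** A global-alignment percent identity against a
   reference panel assigns each allele to a known haplotype or flags it as
   novel; novel alleles receive the next free `NAU-S` number.
5. **Cross prediction.** Under Class I > Class II dominance, a flowering-
   stage cross is predicted incompatible exactly when the parents share an
   expressed haplotype; field pollination outcomes are summarised by the
   compatibility index (seeds per pollinated flower) and classified by the
   0.5 / 2.0 thresholds.

## Nomenclature unification

Each row of the alias table declares all of its non-empty cells mutually
equivalent (the published equivalences rest on BLAST comparison of the
underlying allele sequences; the table encodes the conclusion, not the
evidence, so unification uses the declared links rather than a similarity
threshold). A parenthesized token inside a cell, as in `S22 (S7)`, is a
synonym used by the same group for the same allele, not a cross-team link.

```{r registry}
reg <- radish_registry()
reg
s_lookup(reg, "okamoto", "S30")
s_lookup(reg, "lim", "S6")
```

Classes are numbered deterministically: components are ordered by the
highest-priority naming school present (Okamoto, then Lim, then Kim D,
then other groups), then by the numeric part of the smallest primary label
of that school. This regenerates the published numbering for every entry
anchored on a school serial number. For the six entries known only from
"other group" identifiers the published order follows publication history,
which no property of the table reproduces; those six receive the
deterministic numeric order instead. Shuffling the input rows changes
nothing.

Novel haplotypes extend the registry monotonically and idempotently:

```{r novel}
register_novel(reg, "NAU-Rs46")$nau_name
```

## Virtual PCR model

Primer binding uses IUPAC set matching: a primer position with symbol `R`
accepts A or G, and so on. The default mismatch tolerance is 0 — the
degenerate codes already absorb the intended variation, and every planted
binding site in the synthetic data is embedded intact. When a nonzero
tolerance is requested, the three bases at the primer's 3′ end must still
match exactly, because polymerase extension requires a paired 3′ terminus.

Products are enumerated by pairing every forward site with every
downstream reverse site. The product-size window defaults to the pair's
expected length ± 20% (Class I 960–1440 nt, Class II 800–1200 nt), since
the reported band sizes are approximate; pairings whose primer footprints
would overlap are discarded as physically unamplifiable. Coordinates are
0-based, half-open, on the top strand throughout.

```{r pcr}
cfg <- sim_config(rng_seed = 7)
refs <- simulate_reference_panel(cfg)
pair_I <- primer_pair(kd_primers(), "class_I")
virtual_pcr(refs$panel$sequence[1], pair_I, template_id = refs$panel$nau_name[1])
```

## Gel model and profile grouping

Digestion is complete (one-hour incubation is modelled as full cleavage at
every site) and fragment sizes are double-stranded lengths, so only the
top-strand cut position matters. The gel model has two parameters:

* `resolution_pct` (default 2): fragments within 2% of a longer fragment
  co-migrate and merge into its band — roughly the resolving power of a 6%
  non-denaturing polyacrylamide gel with silver staining;
* `min_detect` (default 50 nt): shorter fragments run off the gel.

Band-level equality at a tolerance is not transitive, so
`profile_table()` groups profiles by single-linkage (connected components
of the pairwise-equality graph). This makes profile identity deterministic
and independent of input order; the ids are numbered by first appearance.

## Identity-based typing

`percent_identity()` is a global Needleman–Wunsch alignment (match +1,
mismatch −1, linear gap cost 2 per base) whose identity is computed over
aligned columns excluding terminal-gap columns, so a clean overhang does
not count against two otherwise identical sequences. The same-haplotype
threshold defaults to 98.5%: the smallest published within-class
similarity is 98.7%, and between-class identities sit far lower, so 98.5
sits just under the observed within-class floor. Two references from
different classes tying within 0.1 percentage points of the maximum give
an `ambiguous` call, which is reported and never silently resolved.

## The dominance model and compatibility scoring

Dominance is applied identically on the stigma and pollen sides: Class I
over Class II in heterozygotes, co-dominance within a class. This is the
simplest symmetric model consistent with the reported genetics, and it
reproduces every compatibility relationship in the published crossing
data. The compatibility index classifier uses closed boundaries for the
weak class (`[0.5, 2.0]`), consistent with published calls of 0.47 as
incompatible and 2.05 as compatible. The binary shared-haplotype model
cannot predict *weak* incompatibility, so concordance scoring collapses
observed strong/weak incompatibility into one incompatible category; on
the published trial table exactly one of eleven crosses (a
between-haplotype combination with index 1.85) disagrees with the model,
and the report flags it.

```{r trials}
trials <- pollination_trials()
preds <- predict_trials(trials[trials$cross_type == "cross", ])
outc <- data.frame(female_id = preds$female_id, male_id = preds$male_id,
                   observed_class = classify_index(
                     trials$compatibility_index[trials$cross_type == "cross"]))
concordance(preds, outc)[c("n", "n_agree", "agreement")]
```

## What the synthetic data emulates — and what it does not

No kinase-domain sequences are shipped with the package, so all
sequence-level validation runs on panels from `simulate_reference_panel()`
and `simulate_genotype_panel()`. The generator's defaults are the study
conditions: 23 reference haplotypes (19 Class I, 4 Class II) of 1400 nt;
a panel of 79 genotypes — 48 homozygous Class I (with haplotype
multiplicities 8, 7, 5, 4, 4, 3, 3, 2, 2 and ten singletons), 13
homozygous Class II (5, 4, 3, 1), 17 Class I/II heterozygotes, and one
line amplifiable by neither primer system (the published class partition
counts 48 + 13 + 17 typed lines but uses the 79-line denominator for its
frequencies).

Mechanically, every reference embeds one concrete realization of its
class's degenerate primer pair at fixed offsets; cores diverge from a
common ancestor by 10% substitutions (so pairwise divergence between
haplotypes comfortably exceeds the 5% floor the typing threshold assumes);
allele copies carried by genotypes are re-mutated at 0.5%. Class I
haplotypes get planted HinfI maps: explicit `GANTC` motifs at lattice
positions inside the amplicon, accidental motifs scrubbed elsewhere, and
maps re-drawn until all haplotypes are pairwise distinguishable under the
configured gel model. One HinfI site is constitutive — the reverse
complement of the Class I reverse primer contains `GATTC` — so every
Class I amplicon shares one cut in the primer footprint; distinctness
rests entirely on the planted maps. Pollination counts are Poisson seeds
(means 0.2 and 3.0 per flower for incompatible and compatible crosses) and
Bernoulli pods (rates 20% and 75%), matching the ranges of the published
trials; a zero-variance mode gives exact expectations.

The model is deliberately idealized: substitution-only mutation (no
indels by default), no partial digestion, no heteroduplex bands, no
primer-annealing thermodynamics, and no molecular evolution at the S
locus. Passing tests therefore demonstrate that the pipeline's logic
recovers planted truth under realistic divergences — not that wet-lab
artifacts (failed amplifications, partial digests, comigration on a real
gel) are handled.

## Numerical and degenerate-input choices

* Frequencies print with half-up rounding to 2 decimals, matching the
  published tables (one published entry, 10.41 for 5/48, reflects
  truncation of 10.4167 and differs from half-up rounding in the last
  digit).
* Cut positions falling on a sequence boundary are dropped — they release
  no fragment — preserving the invariant that fragment lengths are
  positive and sum to the sequence length.
* Fragment sizes follow the standard RFLP convention of top-strand cut
  positions (G^ANTC). Because that cut sits 3 nt from its mirror image
  (HinfI leaves a 5′ overhang), digesting the reverse complement reverses
  the fragment list only up to a ±3 nt stagger per junction — invisible at
  gel resolution but real in exact arithmetic.
* An empty query set runs the whole workflow successfully and reports
  zero counts; a genotype amplifying with neither pair lands in the
  `none` bucket without affecting others.
* Identity of two sequences with no aligned columns is reported as 0.

## Problem sizes

The test suite and the acceptance script run the simulation at the study
scale (79 genotypes, 96 allele sequences, 23 references): a full workflow
pass aligns every allele against its class's reference panel in about a
minute on one core. Property suites use 1000 random sequences for the
digestion/site-scan oracles and graphs of up to 100 nodes for the
unification oracle — sizes at which the brute-force oracles themselves
stay instantaneous.

## Known limitations

* The registry's numbering for other-group-only entries is deterministic
  but not the published historical order (see above).
* PCR-RFLP discrimination is only as good as the site maps: real alleles
  with identical `GANTC` layouts are indistinguishable on the gel, exactly
  as in the laboratory assay; sequence typing is the arbiter.
* Heterozygote gel lanes superimpose two allele patterns and are not
  profiled; like the laboratory protocol, RFLP profiling is restricted to
  Class I homozygotes.
* The cross model is binary; compatibility indices in the weak band
  (0.5–2.0) arise in the field from partial breakdown of SI that the
  shared-haplotype rule cannot represent.
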