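---
title: "Founder-mutation amplicon panels: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Founder-mutation amplicon panels: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(founderpanel)
library(dplyr)
```

## The problem

In populations with strong founder effects, a short list of recurrent
disease alleles explains a large fraction of cases of a heterogeneous
Mendelian disease group such as inherited retinal disease. Screening that
list first — by multiplex PCR of a few dozen amplicons, dual-index
barcoding of up to 96 samples, and deep short-read sequencing — costs a
small fraction of exome sequencing and resolves the easy cases before any
comprehensive test is ordered.

`founderpanel` implements that screen end to end as testable software:
panel design, a simulator standing in for the wet lab, concentration
calibration, pileup genotyping, and diagnostic-category reporting. This
vignette records the models behind each stage and the choices made where
the underlying protocol leaves the design open.

## Coordinates and core quantities

Target mutations and VCF records are 1-based; amplicon intervals (BED) are
0-based half-open, spanning the forward primer's 5' end through the
reverse primer's 5' end. A mutation's *offset* is its distance from the
forward primer's 3' end (offset 1 = the next base); primer-footprint
polymorphisms are located by their distance from the primer's 3' end
(distance 1 = the terminal base), so a variant at 5'-counted position 14
of a 20-mer sits at distance 7.

The panel's detection logic rests on one inequality, encoded in
`panel_config()`: with a target average coverage of 1000 reads and a
100-read floor, a heterozygote carrying only 25% mutant reads is still
supported by `min_expected_alt_reads(100, 0.25) = 25` reads at the floor
and 500 at the average. Reads are single-end, forward-primer-anchored, and
150 bases long, so every mutation must sit within read range of the
forward primer and a 47-amplicon panel screens
`panel_covered_bases(47, 150) = 7050` bases.

## Primer design

`design_primer_pair()` enumerates every placement of both primers inside a
±300 bp window around the mutation and returns the global optimum of a
documented additive penalty

\[ |T_{m,f}-T_{opt}| + |T_{m,r}-T_{opt}| + |T_{m,f}-T_{m,r}|
   + 20\,(|GC_f-0.5| + |GC_r-0.5|) + 0.5\,D(f,r), \]

subject to hard constraints (`design_constraints()`): core length 18–25,
Tm in [57, 63] °C, pair Tm difference ≤ 3 °C, GC in [0.35, 0.65], unique
3'-terminal 15-mer in the reference (both strands), cross-dimer score
≤ 12, mutation offset in [1, 150] with the full allele inside the read,
and amplicon length between one and two read lengths (a shorter amplicon
would let the read run into adapter; a longer one would put the reverse
primer beyond a paired 150-cycle strategy). The original protocol used a
desktop design program with unstated parameter values; every default here
is therefore the package's own and is overridable. Because the search is
exhaustive over the candidate grid with deterministic tie-breaking
(leftmost, then shortest), the optimum is reproducible and can be checked
against a brute-force enumerator, which the test suite does.

Melting temperatures use the unified nearest-neighbor thermodynamics
(SantaLucia 1998) with terminal initiation terms, the self-complementarity
correction, an entropic salt correction at 50 mM monovalent cation and a
500 nM oligo concentration — the community-standard model, chosen
precisely because any independent calculator at the same conditions can
verify it. The cross-dimer score `dimer_score()` is the maximum weighted
run of Watson–Crick matches over all antiparallel ungapped alignments,
counting matches at either 3' terminus twice, since 3'-anchored duplexes
prime extension. Hairpins and genome-wide off-target search are out of
scope; 3'-15-mer uniqueness against the supplied reference is the
desk-scale specificity surrogate.

After design, every amplicon is annotated with *all* panel mutations its
forward read can genotype — neighboring mutations ride along with their
founder host — and `deoverlap_panel()` resolves mutations covered by two
overlapping amplicons by keeping the lower-penalty one, mirroring the
manual removal of a redundant overlapping fragment during panel bring-up.

## The simulator

`simulate_run()` is the package's stand-in for PCR and sequencer.
`total_reads` reads are allocated multinomially over
(sample × amplicon × haplotype) cells with weight
`concentration × efficiency × dropout`; per-amplicon base efficiencies are
drawn once per pool from a log-normal distribution. σ = 1 by default,
chosen so an uncalibrated pool shows the several-fold coverage dispersion
that the calibration loop exists to fix; a calibrated pool corresponds to
σ ≈ 0.3. Autosomal cells carry two equally weighted haplotypes
(heterozygous alternates are phased together — the panel does no phasing,
so nothing downstream depends on it); X-linked amplicons in males carry
one. Errors are i.i.d. substitutions at 0.1% per base; indel errors are
omitted as irrelevant to substitution pileups at 1000×. Barcodes travel in
the FASTQ header (`... i7+i5`, the Illumina dialect) rather than as
inline bases, which preserves the 96-sample pooling semantics while
keeping demultiplexing exact. The same seed reproduces a run byte for
byte.

The dropout model maps a primer-site mismatch's 3'-distance to the
carrying haplotype's efficiency multiplier: 1 beyond distance 10, 0.05 at
4–10, 0 at ≤ 3. The source observation ("wild-type reads extremely low or
even absent" for a mid-primer polymorphism at distance 7) bounds but does
not quantify this curve, so the default is the package's own and is
explicitly replaceable; at distance 7 it yields an alternate-allele
fraction of ≈ 0.95, which the caller sees as homozygous.

## Calibration

`coverage_profile()` converts per-amplicon read counts to mean per-base
coverage per sample, and scores a run by the *population* standard
deviation of those means (the amplicons are the whole population of
interest; the trace also reports the variance since "variance" and "SD"
are used interchangeably when such runs are described).
`propose_adjustment()` multiplies each concentration by
`target / observed`, clipped to [0.25, 4] per round to model pipetting
practicality; zero-coverage amplicons cannot be rescued by scaling, so
they are flagged for redesign instead of adjusted, matching the six
dead primer sets that had to be redesigned during bring-up.
`run_calibration_loop()` alternates simulation, profiling and adjustment;
convergence is judged on the coefficient of variation (depth-invariant,
tolerance 0.15 by default). In the noiseless surrogate
(`noiseless = TRUE`, expected counts instead of multinomial draws) a
single unclipped round equalizes coverage exactly — the share law is
multiplicative, so one proportional correction cancels the efficiencies.
With multinomial noise at 10^5 reads per round, five rounds typically
leave the SD at a few percent of its starting value; the package asserts
≤ 10% rather than any run-specific figure, because the published
reduction is a property of one physical dataset.

## Genotyping

Reads are demultiplexed by exact dual-index match, then assigned to the
unique amplicon whose forward-primer core matches the read prefix with at
most 2 mismatches. General alignment is deliberately replaced by this
anchored match: every template is a known amplicon, so alignment adds
cost without information. Pileups count reads matching the reference and
alternate allele patterns at each covered offset (patterns, not single
bases, so multi-base and length-changing alleles count correctly), and
optionally tally full per-offset base composition.

Calls follow fixed allele-fraction bands at or above the 100-read floor:
hom_ref below 0.10, het within [0.25, 0.75], hom_alt above 0.90. The 0.25
lower heterozygous bound and the 100-read floor come from the protocol's
stated operating point; the 0.10/0.90 homozygous margins and the
treatment of the gap zones — assign the nearer band and flag
`needs_confirmation` — are the package's own, since the protocol verifies
every positive by Sanger sequencing anyway (every het/hom_alt/hemi_alt
call carries `needs_confirmation` for that reason). X-linked sites in
males report `hemi_alt`; with unknown sex, apparent homozygotes stay
`hom_alt` with a warning. `scan_non_target_variants()` emits any
non-target offset whose non-reference fraction reaches 0.10 at ≥ 100
reads — at a 0.1% error rate the binomial tail makes false sites
vanishingly rare, which the tests confirm over seeded replicates — and
`detect_dropout()` flags homozygous-looking calls on amplicons whose
footprints overlap known polymorphisms, leaving the genotype itself
untouched because resolution requires orthogonal evidence. The
population-frequency filter threshold defaults to 0.01 (the criterion is
stated upstream, the cutoff is not); filters annotate rather than delete.

## Case reporting

`classify_case()` maps one sample's passing calls to one of four
categories: *solved* (AR homozygote, presumed compound heterozygote —
two AR hets in one gene, flagged since no phasing is done — AD positive,
or X-linked hemizygote), *partially solved* (one AR het completed by an
externally supplied in-trans allele; the external tools themselves are
out of scope, so the evidence is an input column), *one AR variant*, and
*unsolved*. Hypomorphic alleles participate only in trans with a
pathogenic call of the same gene; alone they are excluded from the logic
entirely. Printed percentages use half-away-from-zero integer rounding,
matching how such results are conventionally reported.

## The synthetic study and what passing tests mean

`simulate_reference()` / `simulate_targets()` / `simulate_truth()`
generate the test-bed: uniform-random mini-chromosomes (three autosomes
plus an X), a 49-target table with 2 structural variants, a few
neighboring mutations placed within read range of their founder hosts,
one hypomorphic AR allele, X-linked targets, and a decaying family-count
distribution; genotypes are drawn independently per site (15% carrier, 5%
homozygote by default). Problem sizes in the test and acceptance runs —
a 10-target/8-amplicon study for pipeline checks, 96-sample plates at
500× for concordance over 25 seeds, a 47-amplicon pool at 10^5
reads/round for calibration — were chosen so the full loop runs
comfortably on a laptop while keeping every binomial margin enormous
(at 500×, a heterozygote's allele fraction is 11 standard deviations from
the nearest band edge).

The generator emulates read-share physics, dropout, barcoding and
substitution noise. It does not emulate real genomic context (repeats, GC
bias, homopolymers), PCR chimeras, index hopping, quality-score
variation, or indel sequencing errors. Passing tests therefore
demonstrate that the algorithms are correct under the stated model, not
that the laboratory protocol achieves these numbers on real DNA.

## Known limitations

Structural variants are excluded by flag, not detected. The simulator's
truth model is per-site independent rather than haplotype-frequency
based. Specificity checking is exact-15-mer counting against the supplied
reference, not genome-scale alignment. The caller does no indel
realignment or base-quality modeling. Clinical pathogenicity assessment
is out of scope end to end.
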