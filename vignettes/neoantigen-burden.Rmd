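---
title: "Neoantigen burden modeling: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neoantigen burden modeling: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neoburden)
```

## The problem

Tumors accumulate somatic mutations, and a mutation that changes protein
sequence can create a *neoantigen*: a peptide absent from the germ line that
the immune system may recognize as foreign. Only a small minority of
predicted neoantigens are *authentic* — naturally processed, presented on
MHC class I, and recognized by autologous CD8 T cells. For tumor types with
intermediate mutation burden (ovarian high-grade serous carcinoma, HGSC,
with a median around 40 missense mutations) the question of whether a given
patient harbors *any* authentic neoantigen is therefore genuinely open,
whereas highly mutated tumors (lung carcinomas) almost certainly do.

`neoburden` implements the desk side of that analysis: from an annotated
somatic mutation table to (i) a vaccine candidate panel with designed long
peptides for a single tumor, and (ii) per-sample predicted-neoantigen counts
and authenticity probabilities for a cohort.

## The filtering funnel

Candidate mutations pass four rules in a fixed order, each stage recorded in
an audit so alternative orders can be compared:

1. **somatic** — present in tumor but not matched normal;
2. **not in dbSNP** — removes residual germline polymorphisms;
3. **expressed** — at least `min_alt_reads` (default 1) RNA-seq reads
   carrying the mutant allele. Only mutant-allele support is gated: zero
   wild-type reads are permitted (mutant-only expression is biologically
   real, e.g. through allelic imbalance);
4. **eligible class** — missense, in-frame indel, or frameshift. Nonsense
   mutations are dropped by default because a premature stop is not expected
   to yield a presented epitope; the class set is configurable.

Expression evidence arrives as precomputed read counts; re-deriving counts
from alignments is out of scope (the package consumes an annotated table,
not BAMs).

## Mutant contexts, windows, and vaccine peptides

`apply_mutation()` builds the mutant protein sequence and the set of *novel
positions* — residues that differ from wild type or are newly created:

* missense: one substituted residue;
* in-frame indel: the inserted residues plus one flanking residue on each
  side of the junction. The flanks are included by convention so that
  junction-spanning windows are always enumerated even for pure deletions,
  where no inserted residue exists;
* frameshift: the wild-type prefix up to the first affected residue followed
  by the novel C-terminal tail, every tail residue novel. The tail is taken
  from the record when precomputed; otherwise it is translated from the
  shifted reading frame of the coding sequence until the first stop codon
  (`translate_frameshift()`). When only a coding sequence is available and
  the DNA-level event is unknown, a single-base deletion at the first
  affected codon is assumed — the minimal frameshift — since the mutation
  record carries no nucleotide-level description. Tails longer than a
  configurable cap (default 50 residues) are truncated with a warning.

`enumerate_class1_windows()` lists every 8–11mer of the mutant sequence that
overlaps at least one novel position — the candidate set for MHC class I
binding prediction. An interior missense mutation yields exactly
8 + 9 + 10 + 11 = 38 windows; a mutation at residue 1 yields 4. Lengths
outside 8–11 require an explicit override, because the class I groove does
not accommodate them.

`design_vaccine_peptide()` returns the long synthetic peptide used for
vaccination: `flank` (default 14) wild-type residues on each side of the
novel region, so an interior missense gives a 29mer with the mutant residue
at offset 15. At protein termini the peptide is **clipped, not padded** — a
mutation at residue 4 yields an 18mer — and a frameshift peptide is the
upstream flank plus the entire novel tail. No minimum output length is
enforced.

## Binding predictions

The package never reimplements a binding predictor. External predictor
output (NetMHCpan-style columnar text or a minimal TSV) is parsed into
(peptide, allele, IC50 nM) calls; affinities are carried in nM throughout,
never percentile ranks. Classification is strict: a peptide binds iff
IC50 < threshold, so boundary values are non-binders. Three conventional
thresholds matter: 100 nM (high affinity, used for cohort burden), 500 nM
(intermediate), and 1500 nM (relaxed, used to admit candidates to a vaccine
panel). Per mutation, the single best epitope is the minimum IC50 over all
windows and typed alleles; exact ties break toward the lexicographically
smallest (length, start) window so results are reproducible.

For tests and simulations, `synthetic_predict()` supplies a deterministic
stand-in: each (peptide, allele, seed) triple is hashed — a polynomial
rolling hash with multiplicative mixing — onto a log-uniform IC50. Hashing
rather than sequential random draws makes the predictor order-independent
and parallelizable by contract: a peptide's affinity never depends on what
else was scored in the same call. Peptides containing a planted anchor
motif map into a designated strong range instead, which is how simulations
plant known binders.

### Background affinity range

The background range defaults to [1, 50000] nM, the span of typical
predictor output. The simulators deliberately restrict it: `simulate_cohort`
uses [150, 50000] and the single-tumor fixture [1600, 50000]. A log-uniform
background over the full range would fall below any threshold for a large
fraction of windows, drowning the planted composition in background
binders; raising the floor above the working threshold makes the planted
windows *exactly* the sub-threshold set, so the emitted truth record matches
a recount of the emitted files with no sampling noise. This is a property
of the generators, not of the predictor interface.

## The authenticity model

Empirical studies of viral epitopes found that only about 8% of peptides
binding MHC I with IC50 < 100 nM are authentic epitopes. Treating a
sample's `N` predicted neoantigens as independent trials with authenticity
rate `a`:

* expected authentic neoantigens: `E = a·N`;
* probability of at least one: `P = 1 − (1 − a)^N`.

With `a = 0.08`, `N = 6` gives `E = 0.48` and `P ≈ 39%`; `N = 27` gives
`E = 2.16` and `P ≈ 89%`. The smallest integer `N` reaching `P ≥ 0.90` is
28 (`min_n_for_likelihood()`). Reported percentages round half-up to
integers, reproducing 39 and 89 from 0.3936 and 0.8948; R's default
banker's rounding would not.

When only a subset of class I loci is typed (e.g. HLA-A of A/B/C), counts
are extrapolated by `total_loci / typed_loci` (the ×3 rule for one typed
locus of three) *before* the probability model is applied, and the power is
evaluated for real-valued `N` so fractional scaled counts are admitted. The
`a = 0.08` constant is literature-derived and exposed as a parameter for
sensitivity sweeps, as is the likelihood cutoff.

Two counting modes are first-class because the two workflows genuinely
differ: cohort burden counts distinct sub-threshold window *sequences*
(`per_peptide`), while a vaccine panel counts *mutations* with at least one
sub-threshold window (`per_mutation`). `per_peptide ≥ per_mutation` always.
Whether the independence assumption of the binomial model is better read
per peptide or per mutation is not decidable from first principles; both
interpretations are supported and reported.

Cohort medians use the midpoint convention for even cohorts, and the median
is taken over the *scaled* `N` (scaling before summarizing); both
conventions are stated here because the alternatives are defensible.

## The synthetic cohorts

`simulate_cohort()` emulates the statistical structure of tumor cohorts
without any sequencing data. Per sample:

* the somatic non-synonymous mutation count is drawn from a negative
  binomial (overdispersed counts are typical of tumor mutation burden; a
  log-normal family is offered for even heavier tails);
* each mutation is independently transcribed with probability 42/92 ≈ 0.457
  (the transcribed fraction observed in a mouse ovarian tumor line);
* each transcribed mutation independently harbors one sub-threshold binding
  window with probability 0.10, planted through the predictor's anchor-motif
  mechanism as a single 11mer containing the mutant residue;
* mutant-allele read counts for transcribed mutations follow a geometric
  tail capped at 2000, matching observed RNA-seq support in order of
  magnitude only.

The raw predicted-neoantigen count of a sample with `n` mutations is then
Binomial(`n`, 0.457 × 0.10), and `cohort_analytics()` marginalizes this
over the burden distribution to give the exact median of the scaled count
and the exact fraction of samples with `P ≥ 0.90` — the values empirical
cohorts converge to, used by the parameter-recovery tests.

Preset parameters were calibrated **once**, analytically, against two
anchors — median scaled `N` of 6 (intermediate burden) and 27 (high
burden) — by a calibration script, and then frozen:

* `hgsc_like`: NB(size 10, mean 45) — median ≈ 43 total mutations, narrow
  spread (HGSC lacks a hypermutated subtype);
* `lung_like`: NB(size 1.2, mean 270) — median ≈ 200 with a spread over
  orders of magnitude.

The implied analytic fraction of samples with `P ≥ 0.90` is ≈ 0.0004
(hgsc_like) and ≈ 0.48 (lung_like); these follow from the calibration, they
were not targets.

What the simulation does **not** capture: mutation hotspots and signatures,
linkage between burden and expression, allele-frequency structure, HLA
population frequencies, immune editing, and real binding-motif biology
(affinities are hashes, not chemistry). Passing recovery tests therefore
demonstrates that the pipeline's counting, scaling and probability logic is
correct — not that the presets describe any particular real cohort.

### The single-tumor fixture

`make_id8_fixture()` plants a 92-mutation mouse-style mutanome whose funnel
is fixed by construction: 42 transcribed, 39 of eligible class (three
transcribed nonsense mutations are planted, plus one frameshift and one
in-frame deletion among the eligible), and 17 carrying a planted window
with IC50 in the intermediate 103–1160 nM range, every other window above
1500 nM. Running the real pipeline on the fixture must recover
92 → 42 → 39 → 17 at the relaxed 1500 nM cutoff and an empty panel at
100 nM. The real funnel of the tumor line this emulates depends on archived
sequencing data; the fixture asserts the pipeline's filtering and threshold
logic, not the biology.

## Numerical and interface choices

* Protein coordinates are 1-based throughout; window coordinates refer to
  the mutant sequence.
* Variant-class spellings are normalized through an explicit MAF dialect
  map; unknown spellings are errors, never silently dropped.
* Duplicate FASTA identifiers, residues outside the 20 standard amino acids
  plus `X`, non-positive affinities, and coverage gaps (a window–allele
  pair with no binding call) are all hard errors naming the offender.
* All generators take explicit integer seeds and are byte-reproducible;
  the hash predictor is additionally independent of batch composition.
* Problem sizes in the test-suite recovery checks — 200 samples per preset,
  1000 random protein–mutation pairs for the window oracle, 1000 random
  cohorts for the threshold-equivalence check — were chosen as the smallest
  sizes at which binomial sampling error is well below the assertion
  tolerances.

## Known limitations

* No proteome-wide uniqueness screen of mutant peptides, no MHC class II
  (> 11mer) enumeration, no percentile-rank calibration, no HLA typing —
  allele calls and binding predictions are consumed, not produced.
* Contexts are built one mutation at a time; overlapping mutations in one
  gene are not co-applied.
* The authenticity model treats predicted binders as exchangeable
  independent trials; clonality, expression level and immune editing are
  ignored.
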