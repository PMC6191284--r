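---
title: "Detecting and dating gene loss in coding alignments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and dating gene loss in coding alignments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genelossr)
```

## The problem

When a gene becomes dispensable, selection on its coding sequence relaxes
and the gene decays into a pseudogene: frameshifting indels, premature
stop codons, splice-site disruptions and whole-exon deletions accumulate,
and the ratio of nonsynonymous to synonymous substitution rates (dN/dS,
written $\omega$) drifts from the small value typical of purifying
selection toward the neutral value of 1.  Comparative studies of such
losses ask three questions that this package answers as a pipeline:

1. **Which species have lost the gene?**  Scan each species' aligned
   coding sequence for inactivating mutations, validate candidates
   against unassembled sequencing reads, and classify each species as
   intact, lost, or missing (too much of the locus behind assembly gaps
   to decide).
2. **Where on the phylogeny did loss happen?**  Inactivating mutations
   shared with identical breakpoints by related species arose once in
   their common ancestor (Dollo parsimony: a lesion is never reverted),
   so the minimal set of loss events consistent with the statuses can be
   placed on branches.
3. **When did loss happen?**  The branch on which the gene died carries a
   mixture of constrained and neutral evolution; its branch-wide
   $\omega$, estimated under a codon branch model, can be inverted into
   the time the gene spent functional versus pseudogenic.

Every stage can be exercised end to end on synthetic data with known
ground truth, produced by the package's codon substitution simulator.

## The dating model

A loss branch of duration $T$ splits into a functional span $T_f$ and a
pseudogenic span $T_p = T - T_f$.  While functional, the gene evolves
with $\omega = \omega_f < 1$; after loss it evolves neutrally with
$\omega = 1$.  Synonymous sites of a functional gene are not fully
neutral either (splicing and translational constraints), so the
functional regime's synonymous rate is a fraction $c$ of the fully
neutral rate; the default $c = 0.7$ encodes the assumption that a
functional gene's synonymous rate is 70% of the neutral rate.  Both the
synonymous and nonsynonymous rates of the functional regime carry the
factor $c$; the nonsynonymous rate carries the additional factor
$\omega_f$.  Substitutions then accumulate as

$$ dS \propto c\,T_f + T_p, \qquad dN \propto c\,\omega_f\,T_f + T_p, $$

so the branch-wide ratio is

$$ \omega_{\text{mixed}} \;=\; \frac{c\,\omega_f\,T_f + T_p}{c\,T_f + T_p}, $$

which is `mixed_omega_forward()`.  Solving for the pseudogenic span
gives the closed-form inversion used by `date_loss()`:

$$ T_p \;=\; T\,\frac{c\,(\omega_{\text{mixed}} - \omega_f)}
  {(1 - \omega_{\text{mixed}}) + c\,(\omega_{\text{mixed}} - \omega_f)}. $$

The fraction $T_p/T$ is scale-free, so divergence-time uncertainty
propagates by evaluating the loss date
$k\cdot t_{\text{start}} + (1-k)\cdot t_{\text{end}}$ (with
$k = T_p/T$) at the older and younger bound pair of the branch's end
dates; the resulting interval always lies within the branch span.  An
observed $\omega_{\text{mixed}} \ge 1$ dates the loss at the branch
start; $\omega_{\text{mixed}} < \omega_f$ means the branch shows
stronger selection than the functional class and is undateable.  When
shared inactivating mutations prove the gene was already dead at a
descendant split, `apply_parsimony_constraint()` clamps the younger
bound of the interval up to that split date.

The mixed $\omega$ itself comes from `fit_branch_model()`: a codon
substitution model (Muse–Gaut style: the rate of a single-nucleotide
codon change is the position-specific F3x4 frequency of the target
nucleotide, times $\kappa$ for transitions, times the class $\omega$
for nonsynonymous changes) with one $\omega$ class per loss branch, a
`pseudogene` class fixed at $\omega = 1$ for branches entirely below a
loss, and a `background` class for all functional branches.  Branch
lengths, $\kappa$ and the free $\omega$s are estimated by maximum
likelihood with Felsenstein's pruning algorithm (compiled kernel),
multi-start over spread initial $\omega$ values.  The functional-class
estimate $\hat\omega_f$ and the loss-branch estimate
$\hat\omega_{\text{mixed}}$ feed the inversion above.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `syn_scaling` ($c$) | 0.7 | functional-to-neutral synonymous rate ratio |
| `missing_threshold` | 0.2 | fraction of ambiguous coding bases above which a species is `missing` |
| `min_reads` | 30 | reads required to confirm a mutation (with zero ancestral support) |
| `het_band` | [0.35, 0.65] | derived-read fraction interval called heterozygous ("~50:50") |
| `flank` | 50 bp | genomic context extracted on each side of a mutation for read probes |
| `breakpoint_tolerance` | 2 columns | slack when deciding two species share "the same" lesion |
| `neutral_rate` | 0.002 /site/Myr | simulator's fully neutral nucleotide substitution rate |
| `omega_functional` | 0.16 | simulator's functional-class dN/dS (strong purifying selection) |
| `kappa` | 2 | transition/transversion rate ratio |

The heterozygote band operationalizes a "roughly 50:50" read split; the
confirmation rule takes "no support for the ancestral allele" literally
(an `ancestral_tolerance` parameter exists, default 0).  The
breakpoint tolerance exists because alignment ambiguity at indel edges
can shift apparent breakpoints by a column or two even for a genuinely
shared deletion.  The neutral rate of 0.002 substitutions per site per
Myr is a typical mammalian germline average; individual lineages range
from roughly half to over twice this value.

## The synthetic-data generator

`simulate_alignment()` evolves a coding sequence (plus short introns
with pinned GT/GC–AG splice dinucleotides) along a time-calibrated tree
under the same Muse–Gaut parameterization the estimator uses, by
exact per-site Gillespie simulation, logging every substitution.  On a
branch carrying a loss event the process switches at the loss time from
the constrained regime ($c$-scaled rates, $\omega_f$, stop codons
unreachable) to the neutral regime (unscaled rates, $\omega = 1$, stop
codons reachable and retained).  The event log yields per-branch
realized dN/dS with mutational-opportunity normalization, which is the
oracle for parameter-recovery tests: a pure pseudogene branch realizes
$\omega \approx 1$, and a mixed branch realizes the forward formula
above (a cross-module consistency check in the test suite).

`inject_lesions()` then stamps gene-inactivating lesions onto post-loss
lineage segments: Poisson counts per class per Myr of post-loss time,
placed uniformly with conflict avoidance; a lesion placed on an
ancestral segment appears with identical coordinates and alleles in all
descendant species — the shared-breakpoint signal that Dollo parsimony
exploits.  Frameshift indel lengths are geometric (multiples of 3
rejected); exon deletions remove exactly one exon; splice lesions
rewrite a donor or acceptor dinucleotide.  Assembly gaps are emulated
by stamping `N` runs over the output — over gap characters too, since a
real assembly gap hides whatever lies underneath.

Ground truth is finalized from the generator's own edit records by
ungapped arithmetic (cumulative frame shifts, translation of the edited
exon sequence), deliberately independent of the scanner's
alignment-column code path.  Two consequences deserve emphasis:
neutral drift alone creates in-frame stop codons, which are genuine
nonsense mutations and belong in the truth set; and an injected lesion
can be invisible in a given species because a larger deletion removed
it or an assembly gap covers it, in which case it is dropped from that
species' truth.  Frameshift-induced stops whose codon is identical to
the ancestral sequence (the stop exists only because of the upstream
indel) are real mutations but carry no allele-discriminating site, so
read validation classifies them as unsupported/other — the frameshift
itself is the validatable lesion there.

What the simulator does **not** emulate: alignment error (sequences are
aligned by construction), paralogous or processed-pseudogene
contamination, context-dependent mutation (CpG), rate variation among
sites or lineages beyond the two-regime switch, and power-law indel
lengths.  Passing tests therefore demonstrate correctness of the
machinery under the stated model, not robustness to real-data artifacts
such as misalignment — which the upstream alignment pipeline must
handle.

## Numerical choices

* The codon likelihood works on the 61 sense codons; in-frame stops are
  masked to missing.  By default a column with a gap, `N` or masked
  stop in some species is kept and that species marginalized
  (`missing = "mask"`); `missing = "complete"` drops the whole column.
  The two options were benchmarked on the dating scenario and give
  nearly identical estimates; masking retains more data when pseudogene
  sequences are stop-rich.
* Each class's rate matrix is normalized to one expected substitution
  per codon site, symmetrized with respect to the F3x4 stationary
  frequencies, and eigendecomposed; decompositions are cached across
  optimizer moves that only change branch lengths.
* Optimization is `nlminb` over branch lengths (bounds
  $[10^{-7}, 20]$), $\kappa$ ($[0.05, 100]$) and free $\omega$s
  ($[10^{-4}, 50]$), convergence tolerance $10^{-6}$ on the
  log-likelihood.  Start 1 optimizes everything from data-derived
  initial values; starts 2–3 probe other $\omega$ basins with branch
  lengths held at the incumbent optimum and trigger a full refit only
  when they improve the likelihood — guarding against local optima at a
  fraction of the cost of three full fits.  The alternative model of
  `relaxation_test()` is warm-started from the null optimum, which also
  enforces the nesting inequality.
* Nei–Gojobori counting (`count_dn_ds()`) averages over equally
  weighted mutational pathways, skips pathways through stop codons
  (falling back to all pathways if none avoids a stop), counts
  stop-creating changes as nonsynonymous, and applies the Jukes–Cantor
  correction.  It is the independent cross-check for the ML estimator,
  never its replacement.
* Read assignment matches the allele-discriminating window (mutation
  core ± 12 bp) against each read on both strands with a mismatch
  budget of 1 per 50 bp of window; ties count as `other`.  When an
  allele's core is longer than a read could span — the restored side of
  an exon-scale deletion — a read supports that allele by matching
  either breakpoint-edge window instead.  Degenerate inputs: an empty
  read set is `low_coverage`; identical probes (no discriminating site)
  can only produce ties.
* `scan_species()` calls a deletion only when the gap run borders no
  `N` (an assembly gap could mimic or hide a deletion), calls an
  insertion only when both host bases are real, never calls a codon or
  dinucleotide containing `N`, and reads stop codons in the frame
  implied by all upstream indels of that species.  The native terminal
  stop of the reference is excluded.

## Design choices where the design was open

* **Dollo placement from statuses, not only shared lesions.**  One loss
  event is placed per maximal clade whose non-missing members are all
  lost; `missing` species are compatible with either state and never
  found their own event.  Shared-lesion groups attach as supporting
  evidence; a species lacking a shared lesion is excused if one of its
  larger deletions demonstrably removed the site; a lesion shared
  across disjoint lost clades is a homoplasy warning.  This yields the
  minimal event count even when post-loss erosion has erased the shared
  lesions in some descendants.
* **Relaxed selection as a two-ratio LRT.**  The foreground/background
  contrast is tested by a likelihood-ratio test with one extra free
  $\omega$ against $\chi^2_1$, reporting relaxation when
  $\hat\omega_{fg} > \hat\omega_{bg}$.  A selection-intensity parameter
  acting on an $\omega$ distribution would answer a subtler question;
  the directional contrast is what the downstream dating consumes.
* **Dating uses time-calibrated branch spans** (with both older and
  younger divergence bounds propagated), not substitution-scaled
  lengths; the $c$ correction enters through the forward formula.
  Sampling error of $\hat\omega_{\text{mixed}}$ is not propagated into
  the printed interval — the interval reflects divergence-time bounds,
  as is conventional for this style of dating; the end-to-end recovery
  test quantifies the total error empirically instead.

## Problem sizes used in the checks

The test suite exercises the scanner on a 50-species, 400-codon
simulation with all six lesion classes (recall must be exact with zero
false positives); read validation on 100 simulated pileups each for the
fixed-allele and heterozygous cases; $\omega$ recovery on ten
2000-codon, 8-species replicates at $\omega_f = 0.16$; end-to-end
dating on ten 5000-codon replicates of a 6-taxon tree whose 14-Myr loss
branch (34 to 20 Mya) carries a mid-branch loss at 27 Mya; and LRT
calibration on 200 null replicates of a 4-taxon, 150-codon alignment.
The dating geometry matters: absolute date error scales like
$T\cdot\delta\omega$ while $\delta\omega$ shrinks only like
$T^{-1/2}$, so shorter loss branches date more precisely, and long
neutral tails below the loss degrade the ancestral-state reconstruction
that the branch estimate rests on.  With the default neutral rate the
chosen scenario recovers the loss date with a median absolute error of
about 1.5 Myr.

## Known limitations

* The two-regime switch is abrupt; gradual relaxation of selection
  would bias $T_p$ estimates in a direction the model cannot see.
* $\hat\omega_{\text{mixed}}$ on short or data-poor loss branches is
  noisy, and the date transform is steep as
  $\omega_{\text{mixed}} \to 1$: losses near the start of a long branch
  carry wide effective uncertainty that the printed interval (which
  only reflects divergence-time bounds) understates.
* The scanner assumes the reference gene model is correct and the
  alignment is trustworthy; exon-boundary refinement and alignment
  cleaning are upstream concerns.
* Read validation uses exact-window matching with a small mismatch
  budget, not quality-aware genotyping; heavily diverged or repetitive
  contexts can leave reads uninformative.
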