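---
title: "Models and design choices in pedpanel"
author: "pedpanel authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in pedpanel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(pedpanel)
```

`pedpanel` re-creates, as reusable and tested components, the
computational procedures of a hierarchical-coverage pedigree WGS study:
coverage design by greedy ranking, in-silico down-sampling, unit-wise
genotype refinement with consensus haplotypes, staged variant QC,
IBD-based sample QC with parentage assignment, and LD thinning into
mapping panels. This vignette records the underlying models, the
parameters that matter, and the places where the design was genuinely
open and a choice had to be made.

## The synthetic cohort

Every stage is exercised on data from a gene-dropping simulator, because
the package's claims must be checkable against known truth.

* **Pedigree** (`simulate_pedigree`): a founder set (the motivating
  colony descends from 57 wild-caught founders over nine generations;
  desk-scale defaults use 8–60 founders over 2–4 generations) expands by
  mating within adjacent generations. Each female has a Poisson number
  of offspring by a primary mate, with 30 % extra-pair paternity, so
  full sibs, maternal and paternal half sibs all occur. Sexes are
  balanced within generations; birth years advance 8 ± 2 years per
  generation, placing parent–offspring age gaps in 4–12 years.
* **Genome** (`simulate_sites`, `simulate_genetic_map`): 2–8 autosomes;
  biallelic SNPs with founder MAF ~ Uniform(0.05, 0.5) so MAF filters are
  exercised on both sides of their thresholds; STR-style anchors define
  100 cM (default) per chromosome. The study's true map length is not
  known here; it is a configuration parameter, not a claim.
* **Transmission** (`gene_drop`): founder haplotype alleles are i.i.d.
  per site; each meiosis recombines between adjacent sites with Haldane's
  map function `r = (1 - exp(-2 d / 100)) / 2` (no interference — the
  simplest defensible model). Output is Mendelian-consistent by
  construction, which the tests assert.
* **Reads** (`simulate_reads`): depth per site per individual is Poisson
  at the individual's planned mean — a deliberate choice over fixed
  depth, since achieved coverage in real projects is a continuum around
  the plan — and each read reports a uniformly chosen haplotype's allele
  flipped with probability `base_error` (default 0.01). Reads are
  per-site allele counts; alignment, base-quality structure, indels and
  multi-allelic variation are *not* modelled (a handful of literal
  multi-allelic decoy records is spliced into pipeline panels purely as
  input for the structural filter). Consequently, passing tests show the
  *procedures* behave as specified; they say nothing about
  alignment-driven artifacts in real data.

## Coverage design

`greedy_rank` restricts the pedigree graph to sequencing candidates and
repeatedly picks the individual whose direct (one-generation) descendants
add the most new ids to a growing offspring-set. Interpretive choices:

* *Direct descendants* means immediate children. The marginal-gain
  semantics ("no identical ids are stored") make the offspring-set a set;
  a candidate whose children are all covered has gain 0.
* The initial "child-set" and the later "offspring-set" are treated as
  one and the same accumulator.
* Ties break by *older first* (ascending birth year); unknown birth
  years sort last; remaining ties break by id. Rank 1 is sequenced
  deepest.

`evaluate_scheme` thins each trio member's reads by binomial sampling of
depth with a matching hypergeometric draw of alt reads (reads are
exchangeable, so the alt fraction is preserved in expectation), re-calls
genotypes, and reports the trio Mendelian inconsistency rate and
per-role concordance against the full-depth calls, averaged over
replicates (3 by default, following the three-repetition design of the
original experiment). One measurement choice is important: **the
Mendelian rate is computed on the single-sample maximum-posterior calls,
before trio refinement** — the trio-constrained refiner enforces
Mendelian consistency by construction, so coverage-driven inconsistency
is only observable pre-constraint. Concordance, by contrast, is measured
on the refined calls, where parental information actually helps.

## Genotype refinement

`call_naive` computes genotype likelihoods Binomial(depth, p) with
p ∈ {e, 1/2, 1−e} and a Hardy–Weinberg prior; zero depth is missing;
posterior ties resolve to the lower dosage.

`refine_trio` replaces the study's population-scale phasing/imputation
machinery with a defined, exactly solvable stand-in: the joint posterior
over the 27 trio genotype configurations (Hardy–Weinberg priors on
parents, Mendelian transmission to the child, member read likelihoods),
maximized per site. A duo or singleton is the same model with the absent
parent marginalized as an unrelated population member (its likelihood is
flat), which collapses to the 9-configuration duo, or single-sample,
posterior. Design choices:

* **Zero-depth members are imputed, not left missing.** A member with no
  reads has a flat likelihood, so the argmax configuration fills in its
  genotype from the other members and the prior. This mirrors what
  pedigree-aware imputation does, and it is what makes the downstream
  consensus haplotypes and the final 5 % missing-rate filter meaningful
  (under a missing-at-zero-depth convention, low-coverage samples would
  void nearly every site). The naive caller retains the
  missing-at-zero-depth convention; refinement returns complete calls.
* Phase: the paternal haplotype is listed first; the child's phase is
  derived from transmitted alleles where a parent is homozygous;
  an unresolvable heterozygote deterministically places the alt allele
  in the paternal slot. Parent haplotypes are ordered
  (transmitted, untransmitted) with the same alt-first tie rule.
* Configuration ties resolve to the smallest index in the fixed
  (father-major) enumeration, making refinement fully deterministic.

`build_consensus` pools an individual's replicated haplotype pairs from
every unit containing it, splits the 2k haplotypes into two clusters —
one per chromosome copy — constrained to one haplotype per pair per
cluster, minimizing total within-cluster pairwise Hamming distance
(exact enumeration for k ≤ 6, greedy seeded by the first pair beyond),
and takes the per-locus majority within each cluster. A majority *tie*
becomes a missing consensus allele: the conservative reading, since the
source procedure is silent. This is the main source of residual
missingness entering the Stage 4 missing-rate filter.

## Filter cascades and ledgers

Filters apply in a frozen order and every cascade carries a ledger
(`filter_report`) obeying conservation: start − Σ removed = end.
Boundary conventions, chosen where the printed procedures leave room:

* "Twofold range of the global median" is the closed interval
  [m/2, 2m]; boundary sites are retained. The reference median is the
  per-site cumulative-depth median of the panel entering the step, so
  re-running a cascade on its own output removes nothing on well-behaved
  (unimodal) depth distributions — the suite asserts this — though a
  pathological depth distribution could shift the median enough to
  violate strict idempotence.
* "Within 5 bp" means |Δpos| ≤ 5 on the same chromosome, assessed among
  the sites that survived the preceding steps, and removes *both*
  members of a close pair.
* MAF is computed from called genotypes (allele counts over non-missing
  calls), not dosages; thresholds are strict (`< 0.25`, `< 0.10`), as
  are heterozygosity (`> 0.6`) and missingness (`> 0.5`, `> 0.05`);
  the Mendel-error site filter uses `>= 5` violating units.
* The Stage 2 read-level caller-filter row is a structural pass-through
  (removes 0): synthetic panels have no alignment layer, but the ledger
  keeps the row so its shape matches the full cascade. Alignment
  masking, liftover and assembly-specific rows are out of scope.
* Stage 4 order: Mendel-site removal, heterozygosity, masking of the
  remaining sporadic Mendelian-error genotypes (only the child's call is
  set missing), then the 5 % missing-rate gate.
* Filter order is not commutative (the suite demonstrates
  missingness-before-proximity differs from the reverse); the printed
  order is frozen.

A transcribed published ledger may carry a stated total that differs
from its row sum (the Stage 2 table's rows over-count its printed total
by 32); `filter_report` keeps the stated total for the conservation
identity and exposes the discrepancy via `report_discrepancy` rather
than repairing it.

## Relatedness and parentage

`estimate_ibd_all` implements the classical method-of-moments IBS→IBD
decomposition: per-site expected IBS-state probabilities given allele
frequencies under IBD ∈ {0,1,2} are summed over each pair's jointly
called sites, solved sequentially for (Z0, Z1, Z2), and projected onto
the simplex; π̂ = Z1/2 + Z2. Allele frequencies are sample frequencies
from the supplied (LD-pruned) panel, and no small-sample bias correction
is applied — on a strongly structured cohort this leaves a visible
upward drift in π̂ for unrelated pairs (a few hundredths with thousands
of pruned markers, worse with few founders or few markers). Two
consequences are handled explicitly:

* `flag_sample_issues` interprets "frequently involved in discordant
  pairs" as a **top-tail** rule: a sample is flagged when its count of
  pairs with |π̂ − 2φ| > 0.15 exceeds the *cohort median count* by at
  least 10. The excess-over-median form absorbs panel-wide
  miscalibration of the moment estimator (an absolute count would flag
  entire cohorts whenever the drift approaches the discordance
  threshold) while leaving genuine outliers — swapped or contaminated
  samples discordant with all their relatives — clearly above the tail.
* Parentage candidates require π̂ in [0.35, 0.65] *and* Z0 < 0.1; the
  window is an artifact default for "parent-offspring-level sharing"
  (the source states no numbers), and the Z0 ceiling is what separates
  parent-offspring from full sibs at equal π̂.

The remaining parentage rules are: at most one surviving candidate per
sex (otherwise unresolved); behavioral-record compatibility for mothers
and housing-record compatibility for fathers, reduced to boolean
membership in a (child, candidate, type) table since the real colony
records are unavailable; and a parent-minus-child age difference within
4–15 years. A candidate not strictly older than the child is never
assigned, whatever the genetic evidence. Absent record tables demote
calls to "provisional".

## Panel thinning and maps

`ld_thin` is sliding-window greedy pruning: windows of 50 SNPs shifted
by 20 over the retained list, the later member of any pair with
r² > threshold removed, passes repeated to a fixpoint. r² is the squared
Pearson correlation of genotype dosages over pairwise-complete samples
(composite LD) — the haplotype-phase alternative would require phased
data and the upstream pruning convention is dosage-based. Monomorphic
sites have undefined correlation and are never removed on its account.
Two structural points:

* **The linkage set is produced by thinning the association set** at
  r² ≤ 0.4, so it nests inside the r² ≤ 0.9 set by construction.
  Sequential windowed greedy pruning is *not* threshold-monotone on a
  common input in general (removing a site at the stricter threshold can
  rescue a later site the laxer run would have discarded), so nestedness
  is obtained structurally rather than assumed.
* `verify_ld_thinning` certifies a thinned set by exhaustively checking
  all pairs inside every sliding window of the retained list — the same
  window/shift grid the pruner uses. Pairs that never share a window
  (possible beyond the 30-SNP overlap of adjacent windows) are outside
  the windowed design and not constrained, exactly as in the standard
  windowed pruning tools.

`pedigree_mendel_check` is nuclear-family consistency: for biallelic
sites, per-unit parent–child legality is a complete level-1 check
(sibling-joint constraints add nothing at two alleles).
`interpolate_map` is piecewise-linear bp→cM through the anchors, with
terminal-slope extrapolation floored at 0 cM and monotonicity enforced.
Panel summaries use the span between first and last retained marker for
per-Mb density, and non-overlapping 5-marker windows for the mean
pairwise r².

## Problem sizes and numerical conventions

The test suite and the acceptance script run desk-scale versions of each
experiment, chosen to estimate every quantity stably: trios with 2,500
sites and ~22 down-sampling replicates for the coverage comparison;
a ~130-member pedigree with 1,600 sites (several hundred after MAF
filtering and pruning) for parentage recovery; a 60-founder,
~4,000-site cohort for flagging calibration; 200 random pedigrees and
500 random bundles for the exhaustive-oracle equivalences. Monte-Carlo
assertions use 3-standard-error bands. All stochastic functions take
explicit integer seeds and the pipeline derives per-stage seeds from one
master seed, so reruns are byte-identical.

## Known limitations

* Reads are exchangeable allele counts: no alignment error, mapping
  bias, base-quality variation or indel realignment, so the coverage
  ledger rows tied to those layers are structural pass-throughs here.
* The trio refiner is site-independent: it uses no linkage information
  within a chromosome, unlike HMM-based phasing/imputation, and will
  under-perform it at very low depth; it is a defined, exactly solvable
  stand-in, not a reimplementation.
* Method-of-moments IBD inherits its known biases under inbreeding and
  structured allele frequencies; thresholds around it are exposed as
  configuration rather than asserted as universal.
* Sex chromosomes are excluded throughout; the simulator produces
  autosomes only.
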