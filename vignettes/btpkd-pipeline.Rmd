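---
title: "Hunting a dominant mutation: the BTPKD analysis chain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hunting a dominant mutation: the BTPKD analysis chain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pkdscan)
```

## The problem

Bull Terrier Polycystic Kidney Disease (BTPKD) is an autosomal dominant
cystic kidney disease of English Bull Terriers, the canine counterpart of
human ADPKD. Its causal mutation is a G>A transition at coding position
9772 in exon 29 of the canine *Pkd1* orthologue, producing the
charge-reversing substitution E3258K in Polycystin 1. `pkdscan`
re-implements, as reusable and tested components, the computational chain
by which such a mutation is isolated from a candidate-gene resequencing
survey:

1. a site-by-sample genotype table (with VCF-lite export),
2. the dominant-model segregation filter and its exclusion taxonomy,
3. exact minimum-haplotype parsimony phasing,
4. cDNA-to-protein consequence mapping,
5. Grantham GV/GD pathogenicity scoring with the seven-class grade,
6. in-silico allelic-discrimination (TaqMan-style) genotyping, and
7. a synthetic cohort generator that emulates the study design so every
   stage is testable without external downloads.

The packaged fixture (`btpkd_variants()`) transcribes the published
37-site survey of four dogs (two affected, two unaffected). The published
two-base exon 17 variant (positions 85–86) is stored as two
single-nucleotide sites, matching the two slots it occupies in the
published haplotype strings; both classify as pattern P1, so the filter's
outcome is unchanged by this representation.

## The segregation filter

Under a fully penetrant dominant model with embryonic-lethal homozygotes,
the disease allele must appear in **exactly one copy in every affected**
individual and in **no copy in any unaffected** individual. For a site
with genotype calls $g_1,\dots,g_n$ and statuses $s_i$, allele $a$ is a
candidate iff

$$\forall i: s_i = \text{affected} \Rightarrow \#\{a \in g_i\} = 1
\quad\text{and}\quad
s_i = \text{unaffected} \Rightarrow \#\{a \in g_i\} = 0.$$

Candidacy is decided purely on the genotype configuration; the database
reference alleles are never consulted for it. Sites that fail are
labelled with a five-pattern exclusion taxonomy (P1 all-homozygous, P2
all-identically-heterozygous, P3/P5 a single heterozygous affected with
everyone else homozygous for a non-database / database allele, P4 a
single heterozygous unaffected). The P3-versus-P5 split is the only place
the database reference is used, and an ambiguous two-allele reference
containing the shared homozygous allele resolves to P5; these labels are
descriptive and never change candidacy. On the packaged survey the filter
retains exactly one candidate — the exon 29 site, allele A — and excludes
the other 36 sites.

If two or more alleles qualify at one site (possible only with three or
more alleles), `dominant_candidate()` returns the lexicographically
smallest with a `multi` flag, and the site is classed `OTHER` rather than
`CANDIDATE`: the data then do not single out one allele, and we prefer to
surface that instead of inventing a ranking.

### Specificity of the rule

For a biallelic site *unlinked to disease* with alt-allele frequency $p$
under Hardy–Weinberg, the alt allele survives the rule with probability

$$\big(2p(1-p)\big)^{n_A}\,\big((1-p)^2\big)^{n_U},$$

implemented as `expected_null_pass_rate()`. Two subtleties matter when
checking this by simulation. First, the closed form is the rate for the
*designated* alt allele; near $p = 0.5$ the reference allele can also
qualify at other sites, so the Monte-Carlo counts only sites where the
candidate equals the designated alt. Second, the cohort generator's
founder-haplotype sharing (below) deliberately links background sites to
the causal chromosome — affected carriers share one chromosome
identically by descent, which inflates the per-site rate to
$p(1-p)^{n_A+2n_U-1}$-type forms. The specificity check therefore
simulates with `causal_on_founder_haplotype = FALSE`, which makes every
site independent of disease as the formula assumes. The test suite
verifies agreement within three binomial standard errors over 10,000
sites at $p \in \{0.1, 0.25, 0.5\}$.

## Parsimony phasing

`min_parsimony_phase()` finds a phasing of all samples minimizing the
number of distinct haplotypes across chromosomes — the natural parsimony
criterion for a handful of closely related individuals in one gene, where
recombination and recurrent mutation are negligible on the observed
scale. Alleles (including indel and run-length tokens) are opaque symbols
during phasing; there is no frequency model, no pedigree constraint and
no recombination model, which is why the method should not be used for
large unrelated cohorts (statistical phasers exist for that).

The search is exact:

* **Pattern collapsing.** Sites with identical genotype-pattern across
  samples are collapsed to one representative column first. Identical
  columns can be phased identically in some optimum, so the minimal
  count is invariant; the suite confirms this by comparing against the
  uncollapsed exhaustive search on random tables.
* **Branch-and-bound.** Samples are processed most-heterozygous first, so
  the widest branching happens once at the root; each sample contributes
  $2^{k-1}$ phasings for $k$ heterozygous columns. Haplotypes are
  interned to integer ids, partial solutions are pruned when their
  distinct-haplotype count exceeds the incumbent, and a greedy descent
  provides the initial incumbent.
* **Determinism.** Ties among equally parsimonious solutions are broken
  by lexicographic order of the sorted rendered haplotypes, so output is
  reproducible run to run.
* **Guard rails.** A `max_het_columns` cap (default 24 per sample after
  collapsing) turns a combinatorial blow-up into an informative error
  rather than an open-ended search.

On the packaged survey the optimum is five haplotypes, and the published
five-haplotype assignment (`btpkd_haplotypes()`) verifies against every
genotype with `check_phasing()`. Note that equally parsimonious optima
may differ in which haplotype carries the disease allele in which dog; in
every consistent phasing, though, each affected dog carries the exon 29 A
on exactly one chromosome and no unaffected chromosome carries it.

## Consequence mapping

Coding positions are numbered from the first base of the initiation
codon, so position $p$ lands in residue $\lceil p/3 \rceil$ at codon
offset $((p-1) \bmod 3)+1$; 9772 is the first base of codon 3258, and
GAG→AAG replaces glutamic acid with lysine. Charges at neutral pH are
taken as $-1$ for D/E, $+1$ for K/R and 0 otherwise — histidine is
treated as neutral, which matches the conventional "charge reversal"
description of E→K ($\Delta = +2$). The reference codon passed to
`annotate_substitution()` must carry the stated reference base at the
computed offset; a mismatch raises an error, which in practice catches
off-by-one coordinate bookkeeping early. Non-exonic sites are reported as
"non-coding: not assessed": splice-site and regulatory prediction needs a
transcript model this package does not carry. The exon 29 site sits at
feature position 42 while the substitution is at coding position 9772,
which implies a coding start of 9731 for that exon; the package records
this only as contextual arithmetic, since no transcript model is shipped
to assert it against.

## Grantham distance, GV/GD and the seven classes

The Grantham distance combines side-chain composition $c$, polarity $p$
and molecular volume $v$:

$$D(a, b) = \rho\sqrt{\alpha\,\Delta c^2 + \beta\,\Delta p^2 +
\gamma\,\Delta v^2},\qquad
\alpha = 1.833,\ \beta = 0.1018,\ \gamma = 0.000399.$$

The scale $\rho$ is meant to normalize the mean of the 190 unordered
residue-pair distances to 100. The package ships the published constant
$\rho = 50.723$, which exactly reproduces the rounded distance matrix in
canonical use and the unrounded E–K distance of 56.87. Recomputing the
calibration from the unrounded property values gives
$\rho = 50.790$ (i.e., the published constant leaves the mean at 99.87,
normalized "to 100" only to rounding) and would shift E–K to 56.94. We
treat the published constant as the definition — it is what every
downstream user of these scores compares against — and expose the strict
recalibration as `grantham_rho(calibrate = TRUE)`; a test pins the two
within 0.2%.

For an alignment column, **GV** is the property-space *range* of the
observed residues (zero iff the column is invariant; equal to the
pairwise distance for a two-residue column), and **GD** is the distance
of the variant from that range: per property, the deviation is zero
inside the observed $[\min,\max]$ interval and the distance to the nearer
bound outside it. The seven-grade classifier assigns Cx for the largest
$x \in \{15,25,35,45,55,65\}$ with

$$GD \ge x + \tan(10^\circ)\cdot GV^{2},$$

else C0. Two readings of the printed boundary rule were possible —
degrees versus radians for the tangent, and the placement of the
exponent; we read "Tan(10)" as tangent of ten degrees and "GV∧2.0" as
$GV^2$, the parameterization under which the rule behaves sensibly
(a radian-10 tangent is negative, which would invert the ordering). For
an invariant column ($GV = 0$) the boundary term vanishes, so the E3258K
grade — $GV = 0$, $GD = 56.87$, class C55 — is insensitive to this
reading. The boundaries for the six classes other than C55 reuse the same
functional form at their thresholds, as the seven-class scheme defines.

Column "homology" figures are implemented as the fraction of alignment
columns at which all sequences carry the identical non-gap symbol (the
asterisk convention of printed alignments), not average pairwise
identity. Reproducing the published cross-species percentages (74%
nucleotide identity in exon 29, 84%/89% over protein regions) requires
downloading species sequences and is deliberately out of scope for the
packaged tests; `conservation_fraction()` plus `read_alignment()` perform
the computation on any alignment you supply.

## In-silico allelic discrimination

The genotyping assay is modeled computationally: a chromosome is scored
by exact string containment of the wild-type (`TGGCCGAGCTGCAG`) and
mutant (`TGGCCAAGCTGCAG`) probes on either strand — the probes differ at
exactly the variant base, so exact matching reproduces the competitive
hybridization logic. A chromosome matching both probes or neither is
ambiguous and forces a `no-call`; the call is symmetric in chromosome
order and strand. There is no thermodynamic, mismatch-tolerance or
fluorescence model: melting behaviour and real-time curve analysis are
instrument concerns outside the computational scope, and since the two
probes differ at one base, exact containment is the faithful abstraction.
`extract_amplicon()` models PCR delimitation by the printed primer pair
and errors on templates containing multiple candidate amplicons rather
than guessing. `cosegregation_summary()` tallies carrier category against
affection status; concordance counts affected heterozygous carriers and
unaffected non-carriers over all called samples, with no-calls reported
separately and excluded from the denominator.

## The synthetic cohort generator

`simulate_cohort()` emulates the statistical structure the analyses
assume, not the biology of any particular gene:

* every affected individual is a heterozygous carrier whose carrier
  chromosome is one **founder haplotype shared identically by descent**
  (the study's cases all descend from two affected half-siblings, and the
  disease allele rides one background haplotype);
* unaffected individuals never carry the causal allele at penetrance 1;
  at penetrance $f < 1$ each unaffected is a silent heterozygous carrier
  with probability $1 - f$ (the simplest generative reading of reduced
  penetrance given fixed cohort sizes);
* **no individual is ever causal-homozygous** (embryonic lethality), by
  construction and double-checked as a hard invariant;
* background sites are biallelic, mutually independent, and drawn under
  Hardy–Weinberg at a fixed frequency (default 0.25) or per-site
  Beta-distributed frequencies; linkage to disease arises only through
  the founder haplotype;
* genotyping error is a per-allele symmetric flip at a stated rate —
  the simplest mechanism that exercises the filter's failure modes (a
  single flipped allele in the wrong dog destroys candidacy);
* one master seed feeds fixed-offset per-stage streams (site parameters,
  founder, chromosomes, silent carriers, errors, amplicon flanks), so the
  same seed is bit-reproducible and adding a stage never perturbs earlier
  ones.

What it does **not** emulate: pedigree structure beyond the single shared
founder chromosome, recombination, mutation-rate heterogeneity,
multi-allelic or indel background sites, hemizygosity, or missing calls.
Passing tests on these cohorts therefore demonstrate correctness of the
algorithms under the stated model, not robustness to every artefact of
real resequencing data — a deliberately sharp boundary.

Default sizes mirror the study design: two affected and two unaffected
sequenced individuals over 36 background sites plus the causal site, and
a 47-affected / 102-unaffected confirmation cohort for the assay.

## Problem sizes and numerical choices in the test suite

The suite runs entirely on synthetic or packaged data: the 37-site
survey; 10,000-site cohorts for the null-rate comparison (three allele
frequencies, three-standard-error bands); 1,000 seeded cohorts for
planted-variant recovery (sensitivity exactly 1 at penetrance 1 and error
0); 200 random small tables comparing branch-and-bound phasing against
exhaustive enumeration (tables whose raw enumeration exceeds $2^{14}$
combinations are skipped by a deterministic rule); 10,000 simulated
individuals for the lethality invariant; and a 149-dog error-free assay
cohort whose concordance is exactly 1. Degenerate inputs are exercised
throughout: empty tables, empty haplotypes, all-gap columns, zero-length
cohorts, ambiguous templates.

## Known limitations

* The phaser is exponential in heterozygous pattern-columns per sample;
  it is built for small related panels, not population cohorts.
* VCF export is lossy for run-length and unknown-sequence deletion
  alleles (they are emitted as literal expansions / N-runs); only
  SNV-only tables round-trip.
* The GV/GD implementation scores prebuilt alignments; it does not build
  alignments, and alignment choice (species set, depth) dominates the
  scores in practice.
* External predictor scores (PolyPhen-2, SIFT) are carried as metadata
  via `external_prediction_metadata()` and are never recomputed: both
  depend on trained models and databases outside this package's scope.
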