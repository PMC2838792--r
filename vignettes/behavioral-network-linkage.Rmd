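---
title: "Behavioral symptom networks and clade-conditioned linkage: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Behavioral symptom networks and clade-conditioned linkage: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model behind `cladelink`, the
choices made where the method leaves room, and what the synthetic-data
module does and does not establish about real data.

## The phenotypic model

Diagnostic categories in psychiatry are coarse summaries of a symptom
continuum. The framework implemented here treats the **individual symptom
vector** as the unit of analysis. Individuals are taxa; each symptom is a
character. A dichotomous symptom is an unordered two-state character; the
four-state severity scales (absent, minimal, moderate, severe) are scored
as **ordered** characters with step cost $|i-j|$. Ordering is a modeling
choice: a severity scale has a natural progression, and jumping
absent→severe should cost more than absent→minimal. Because the choice is
debatable, `ordered_ordinal = FALSE` scores them unordered instead.
Missing states are treated as unknown — free to take whatever state
minimizes tree length, excluded from prevalence and count statistics.

The behavioral network is the set of shortest (most parsimonious) trees:
arrangements that minimize total symptom gains and losses. The score of a
tree is computed by dynamic programming (generalized Sankoff recursion,
exact for multifurcating trees and for both cost regimes; implemented in
C++). Tree space is searched with the parsimony ratchet: hill-climbing is
alternated between the original character weights and a randomly
up-weighted subset, which lets the search hop between islands of local
optimality. Defaults are the classical ratchet settings — 200 iterations,
25% of characters up-weighted ×2 — with SPR rearrangements; for leaf sets
in the hundreds the cheaper NNI neighborhood (`move = "nni"`) is the
practical choice, and identical symptom profiles are collapsed to a single
leaf during search (provably score-neutral) and re-expanded afterwards.
Equally parsimonious trees (deduplicated by bipartition fingerprint,
capped at 1000) are summarized by a majority-rule consensus retaining
bipartitions supported by strictly more than 51% of trees.

**Rooting.** Nesting requires direction. The default policy appends an
artificial all-zero "asymptomatic" pseudo-individual before the search,
roots the consensus at it, and removes it; symptom-free individuals then
sit at the base of the network. All trait-scored individuals — including
unaffected relatives — are network leaves, since the continuum hypothesis
is precisely about sub-clinical symptom carriers.

## Nesting and clade labels

Every internal node of the rooted consensus defines a clade of its
descendant leaves. Levels are numbered so the children of the root carry
the largest level (most inclusive) and deeper nodes smaller ones:
$\mathrm{level}(v) = d_{\max} + 1 - d(v)$ with $d$ the root distance and
$d_{\max}$ the deepest non-trivial internal node. Indices within a level
follow preorder. The published analyses use structurally equivalent labels
but their exact index assignment is tool-internal and unknowable; only the
structural semantics (laminar nesting, level = inclusiveness) are
reproduced here. Multifurcations contribute one clade per child subtree;
no artificial resolution is introduced.

Clades spanning fewer than `min_families = 40` distinct families are
discarded **before** any linkage test — an a priori constraint limiting
tests with little power. For a clade under test, members are *affected*,
family members outside the clade *unaffected*, and family members without
trait data *unknown* (unscored is not asymptomatic); families without any
member in the clade are excluded from that clade's scan.

## Two-point linkage with heterogeneity

For each clade × marker × model the pedigree likelihood is computed
exactly by Elston–Stewart peeling over the joint disease–marker state
space: a person's state is an ordered pair of haplotypes (disease allele ×
marker allele, $H = 2A$ haplotypes). Founders carry Hardy–Weinberg priors
at the disease locus (frequency $q$) and the marker (map frequencies, or
founder-estimated); transmission recombines with fraction $\theta$;
penetrances $(f_0, f_1, f_2)$ apply to the affection coding with unknown
contributing a factor 1; untyped genotypes are summed over. Nuclear units
are peeled along the tree of units; messages are max-normalized with the
scale tracked exactly, so likelihood ratios are exact to machine
precision. Pedigrees with loops are rejected outright — peeling without
loop-breaking is exact and testable, and the simulated designs are
loop-free. Families whose likelihood is zero at every $\theta$ (a
Mendelian inconsistency, or an affection pattern impossible under a fully
penetrant model — e.g. an affected child of two unaffected parents under
the fully penetrant dominant) are excluded from that single test, counted,
and reported via `attr(result, "excluded")`.

The LOD grid is $\{0, 0.01, 0.05, 0.10, \dots, 0.5\}$ (sex-averaged
$\theta$); the admixture HLOD is maximized over $\alpha \in [0,1]$ on a
0.01 grid with golden-section refinement inside the bracketing cells.
These grids are numerical choices, not model content; the refinement makes
the reported $\alpha$ accurate to ~1e-4 at negligible cost. `Z_max` per
clade is the maximum over the four genetic models, all markers and both
analysis schemes (homogeneity LOD and HLOD); since
$\max_\alpha \mathrm{HLOD} \ge \mathrm{HLOD}(\alpha{=}1) = \mathrm{LOD}$,
this equals the maximal HLOD.

## Empirical significance

Gene dropping redraws founder genotypes from the observed (founder-
estimated) allele frequencies, mates individuals along the pedigree, and
recombines between adjacent markers with Haldane's map function on the cM
gaps (Kosambi available as an option); the observed missingness mask is
re-applied. Phenotypes, the network and the clade set are **held fixed**
across replicates — only genotypes are randomized — so the replicates
embody "no linkage anywhere" while preserving the full multiple-testing
structure. With $R$ replicates,
$p_M = (\#\{Z^{rep}_{clade} \ge Z^{obs}_{clade}\} + 1)/(R + 1)$ within a
clade (maxima over models and markers) and $p_G$ uses replicate maxima
across all clades as well. The add-one convention avoids zero p-values and
reproduces the $1/(R+1)$ floor (with the conventional $R = 100$, a maximum
beating every replicate reports ≤ 0.01). Defining $p_G$ per clade against
the replicate *global* maximum guarantees $p_M \le p_G$. The $p_G$
denominator includes only clades that passed the family filter — the tests
actually performed.

## The four-group symptom LRT

For one clade, one diagnostic category and one trait, the scored cohort is
partitioned into group 2 (category minus clade), group 3 (clade minus
category), group 4 (intersection) and group 1 (the rest). With $x_i$
symptom-present counts of $n_i$, the null $p_2 = p_3 = p_4$ is tested
against $p_2 \ne p_3 = p_4$ using plug-in binomial MLEs (pooled
$\hat p = (x_2{+}x_3{+}x_4)/(n_2{+}n_3{+}n_4)$ under H₀;
$\hat p_2 = x_2/n_2$, $\hat p_{34} = (x_3{+}x_4)/(n_3{+}n_4)$ under H_A);
group 1 cancels. When the clade is contained in the category (group 3
empty) $p_2$ is compared with $p_4$; when they are disjoint (group 4
empty) with $p_3$; if the applicable comparison has an empty group the
test is flagged undefined rather than reported as $p = 1$. Significance is
empirical: clade membership is permuted within the scored cohort, holding
the clade size and diagnostic labels fixed — the minimal exchangeable null
for H₀ (the permutations deliberately ignore family structure, matching
the test's independence assumption; see Limitations). Ordinal traits count
as present at any severity ≥ 1. Per-trait p-values are reported unadjusted
at the 0.05 level, with a Benjamini–Hochberg column added purely as a
convenience.

## What the synthetic KPD study emulates

`simulate_kpd_study()` mirrors the structure of the GAW14 "Kofendred
Personality Disorder" benchmark: three populations (Aipotu: ≥2 members
with any of P1–P3; Karangar: ≥2 with P2/P3; Danacaa: ≥2 with P1), 100
families per population by default, microsatellite panels at 7.5 cM, four
disease loci with epistasis and two penetrance modifiers, and latent
phenotypes expressed as overlapping trait sets (P1 = {b,e,f,h},
P2 = {c..h} without b, P3 = {c..h} plus b — so P2 and P3 differ by the
single trait b). The exact GAW14 generating tables are not public, so the
quantitative settings are this package's own documented choices: P1
requires D1-recessive and a D2 carrier; P2 requires D2-recessive and a D3
carrier, or alternatively D4-recessive (two genetic routes to one
phenotype); P3 requires a D2 carrier and D3-recessive; disease-allele
frequencies 0.2–0.35 keep rejection-sampled ascertainment tractable; base
penetrance 0.9, multiplied by 0.6 in carriers of the relevant modifier
(D5 modifies P1, D6 modifies P2/P3); each trait of an expressed phenotype
appears with probability 1 and every trait has a 0.02 background rate in
everyone, which produces the sub-clinical symptom carriers the continuum
view predicts. Families default to two parents and four children.

What passing tests on these data **do** show: the search recovers planted
symptom structure through realistic noise; the nesting, filtering and
affection coding behave as specified; the linkage engine localizes planted
loci through ascertainment and epistasis; the empirical p-values are
calibrated under a true null. What they do **not** show: robustness to
real-world phenotype measurement error structure (correlated symptom
scoring, informative missingness), to genotyping error, to loops or very
large pedigrees, or to trait sets whose true generating process is not
tree-like at all — on real data the network is a grouping heuristic, not a
claim that symptoms evolved along a tree.

## Problem sizes used in the shipped checks

The test-suite and acceptance script run at desk scale, chosen so the full
battery completes in minutes on one core while leaving each property
statistically sharp: exhaustive parsimony oracles on ≤7 leaves (up to 945
topologies), brute-force likelihood enumeration on ≤6-member pedigrees
with 2-allele markers, the KS uniformity check on 200 null studies at
R = 25 replicates, and an end-to-end KPD study scaled to 3 × 30 families
on four 60 cM chromosomes (32 markers, 4 alleles) with the family filter
scaled proportionally (12 of 90 families, matching 40 of 300). The
generator's defaults remain the full-size conditions (3 × 100 families,
416 markers on 10 chromosomes).

## Known limitations

* Two-point analysis only; no multipoint, no X chromosome, no
  sex-specific maps.
* Pedigree loops are rejected rather than broken.
* The LRT and its permutation null treat individuals as independent;
  related individuals share symptoms for familial reasons, so within-family
  correlation is not corrected (the permutation p-values are exact for the
  stated exchangeable null, which ignores families).
* The parsimony search is heuristic; optimality is only guaranteed where
  the exhaustive oracle can verify it (small leaf sets), elsewhere the
  ratchet's escape behavior is relied upon.
* Symptom exclusion lists (e.g. dropping rarely scored items) are the
  user's responsibility; no automatic pruning is applied.
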