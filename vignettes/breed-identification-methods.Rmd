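---
title: "Breed identification from SNP and InDel genotypes: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Breed identification: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(breedkit)
```

## The problem

Given genome-wide genotypes for animals from a set of candidate breeds,
we want to (a) verify that reference animals really are purebreds of
their labeled breed, (b) find a small panel of markers that carries most
of the between-breed information, and (c) assign new animals to breeds
from that panel alone. `breedkit` implements this workflow for biallelic
SNPs and short InDels coded as ALT-allele dosages (0/1/2), and ships a
simulator so every stage can be exercised and tested end to end.

## The simulator: what it emulates and what it does not

`simulate_dataset()` draws breed allele frequencies from the
Balding–Nichols model: for ancestral frequency $p$ and differentiation
parameter $F$, each breed's frequency is
$\mathrm{Beta}\!\left(p\tfrac{1-F}{F},\,(1-p)\tfrac{1-F}{F}\right)$,
so $F$ is the expected Wright's $F_{ST}$ between breeds and an explicit
knob. Genotypes are then independent binomial draws,
$g_{im} \sim \mathrm{Bin}(2, \sum_k q_{ik} f_{km})$ — exactly the
generative model the supervised admixture likelihood assumes.

Default design (chosen once, as the study conditions the package
targets): 13 breeds with 17–39 animals each, markers at a 5.3:1
SNP:InDel ratio laid out over 26 autosome-labeled chromosomes of 100 Mb
(so the 500-kb LD window is a meaningful physical scale), $F = 0.1$,
ancestral frequencies uniform on (0.1, 0.9), breed frequencies clamped
to [0.01, 0.99] to avoid degenerate markers, and a 10% minority of
admixed individuals. Admixed ancestry is Dirichlet(0.5, 0.5) over the
labeled breed and one random second source, with the labeled breed
assigned the larger component: an animal whose label is a minority of
its genome is a mislabel, which the tests plant explicitly instead.

What the simulator does **not** emulate: linkage (markers are
independent by construction — LD-pruning tests therefore plant
duplicated/correlated columns explicitly), realistic site-frequency
spectra, genotyping error, relatedness within breeds, and any real
breed phylogeny (breeds are exchangeable). Passing tests on this
generator show the estimators are correct under their assumed model
and well-behaved at realistic sample sizes; they do not certify
performance on real data with structure the model lacks.

## Quality control

Variant-level hard filters follow the GATK convention, with separate
rulesets: SNPs fail on QD < 2, MQ < 40, FS > 60, SOR > 3,
MQRankSum < −12.5 or ReadPosRankSum < −8; InDels on QD < 2, FS > 200,
SOR > 10, MQRankSum < −12.5 or ReadPosRankSum < −8. A record with an
absent annotation passes that rule (the VariantFiltration behavior);
this matters for sites where rank-sum statistics are undefined.

Marker QC keeps biallelic, fully genotyped, autosomal markers and
InDels shorter than 50 bp, measured as
$\max(|\mathrm{ref}|, |\mathrm{alt}|) - 1$. The autosome whitelist is
configurable and defaults to "1"–"26" (the sheep autosome count).
Downstream estimators require complete data, which is why a 100%
genotyping rate is enforced rather than imputed around.

LD pruning uses composite LD: the squared Pearson correlation of dosage
vectors, with $r^2 \ge 0.2$ within a physical 500-kb window on the same
chromosome. The threshold and window are standard; the *victim* rule is
not dictated by them, so we chose the common heuristic: scan pairs in
position order and drop the member with the lower minor-allele
frequency (ties drop the later marker). The post-condition — no
retained within-window pair at or above the threshold — is verified in
tests by exhaustive all-pairs scans, independently of the scan order.
Zero-variance markers get $r^2 = 0$ with a warning rather than NaN. The
merged SI set is the column-concatenation of the pruned SNP and InDel
sets, re-sorted and re-pruned with the same parameters.

## The mislabel screen

VCF2Dis-style p-distance between individuals,
$d_{ij} = \frac{1}{2M}\sum_m |g_{im} - g_{jm}|$ (a scaled Manhattan
metric in [0, 1]), feeds Saitou–Nei neighbor joining (`ape::nj`;
negative branch lengths, possible on non-additive input, are clamped to
zero with the deficit moved to the sibling edge). The published
procedure removes individuals "grouped in a branch of another breed" by
visual inspection; we operationalize it as: flag an individual when the
majority breed among its $k = 5$ cophenetically nearest leaves differs
from its own label, with ties resolved in favor of the label. This is a
proxy, not a reconstruction of the visual call; $k$ is configurable and
is reduced automatically when a breed has fewer than $k + 1$ members.
On simulated 5-breed data ($F_{ST} \ge 0.1$, 500 markers) it recovers
planted single-label swaps in over 95% of datasets while flagging
nothing on clean data.

## Genomic breed composition

The supervised admixture model: given breed allele frequencies
$f_{km}$, an individual's genotype likelihood is

$$\ell(q) = \sum_m \left[ g_m \log\textstyle\sum_k q_k f_{km} +
  (2 - g_m) \log\sum_k q_k (1 - f_{km}) \right]$$

maximized over the simplex. Two engines are provided.

**Projection** (`estimate_gbc`): frequencies fixed at the reference
estimates, per-individual EM from a uniform start. The multiplicative
EM update keeps $q$ on the simplex and the log-likelihood
non-decreasing (asserted in tests). This is exact when frequencies are
known — e.g. against the simulator's true frequencies — and is the
right tool for panel-vs-full comparisons at fixed reference.

**Joint supervised** (`estimate_gbc_supervised`, the default engine of
`gbc_crossval`): reference individuals keep one-hot ancestry, test
individuals get free $q$, and the frequencies are re-estimated jointly
— the behavior of ADMIXTURE's supervised mode. This matters
quantitatively: reference panels of 20–40 animals carry sampling noise
of the same order as the between-breed differentiation at
$F_{ST} = 0.1$, and a fixed-frequency projection absorbs that noise
into spurious foreign ancestry, deflating purebred GBC to ~0.85 on
average and breaking the 90% purity screen for a third of true
purebreds. Joint re-estimation removes most of this shrinkage (purebred
own-breed GBC ≥ 0.9 for ≥ 95% of animals under the default design).
Because reference ancestry is one-hot, the reference contribution to
the EM frequency update collapses to fixed allele counts, so each
iteration costs only $O(TKM)$ for $T$ test individuals.

Numerical choices: frequencies clamped to $[10^{-4}, 1 - 10^{-4}]$ so
the likelihood stays finite for any genotype; uniform simplex
initialization (deterministic); convergence when the total
log-likelihood gains less than $10^{-6}$, capped at 2000 iterations.
The EM tail is slow near simplex vertices, so the cap is the effective
stop for near-purebred individuals; the attained $q$ is stable to well
below the 0.90 screen's resolution. Clamping can in principle perturb
strict monotonicity at the $10^{-8}$ level; tests assert
non-decreasing log-likelihood to that tolerance.

The tenfold GBC cross-validation splits every breed into ten subsets
(sizes within one of each other) and estimates each subset against the
remaining nine of every breed, so no individual informs its own
reference. The purebred screen then retains individuals with
labeled-breed GBC ≥ 90% (inclusive) **and** no mislabel flag — the
conjunction of both criteria defines the training population.

Panel-vs-full GBC agreement is summarized as the Pearson correlation of
the flattened individuals × breeds composition matrices (optionally on
the purebred or non-purebred subset). Per-breed column-wise
correlations averaged would be an alternative reading; the flattened
form is our documented choice, and at near-one-hot compositions the two
are close.

## Marker informativeness

For breeds $a, b$ with ALT frequencies $p_a, p_b$ at a marker:

- **Delta**: $|p_a - p_b|$.
- **Wright's $F_{ST}$**: $(H_T - H_S)/H_T$ with
  $\bar p = (p_a + p_b)/2$, $H_T = 2\bar p(1 - \bar p)$,
  $H_S = p_a(1-p_a) + p_b(1-p_b)$; defined 0 when $H_T = 0$. The
  classic Wright formulation is used (not Weir–Cockerham) because the
  pairwise statistic, not an estimator of a population parameter, is
  what ranks markers here.
- **Rosenberg's $I_n$**: over the two alleles $j$,
  $\sum_j (-\bar p_j \ln \bar p_j + \frac1K \sum_i p_{ij} \ln p_{ij})$
  with $0 \ln 0 = 0$; natural logs, range $[0, \ln K]$.
- **Mutual information**: empirical MI of the dosage-category × breed
  contingency table, in nats, on raw categories {0, 1, 2} (no binning).
- **MDA / MDG**: permutation and impurity importances of a 500-tree
  random forest (`ranger`, mtry $=\lfloor\sqrt M\rfloor$, fixed seed).

Delta and $F_{ST}$ are two-population statistics; with $K$ breeds they
are aggregated over the $\binom K2$ pairs by the **maximum** (default):
a marker diagnostic for even one breed pair is assignment-relevant.
Mean-over-pairs is available (`aggregate = "mean"`); the max emphasizes
pair-specific markers, the mean genome-wide differentiation. All four
closed-form statistics are checked against independent brute-force
implementations to $10^{-12}$.

## DFI panels

Rankings use the score order with ties broken by (chromosome, position)
ascending, making every ranking a deterministic permutation.

`dfi_union` finds the smallest common per-method depth $k$ such that
the union of the three top-$k$ lists holds at least $N$ unique markers,
orders the union by each marker's best (minimum) rank across the three
methods (ties by position), and keeps the first $N$. "Equal depth per
method" is our reading of merging equal numbers of top markers from
each method; incrementing depths jointly rather than per-method keeps
the three methods symmetric.

`dfi_inter` finds (by binary search over the monotone intersection
size) the smallest depth $t$ at which the three top-$t$ lists share at
least $N$ markers, then orders members by entry depth (the maximum of
the three ranks), breaking ties by rank sum and then position, and
keeps the first $N$. Ordering by entry depth first — rather than by
rank sum over the whole depth-$t$ intersection — is deliberate: it is
what makes panels *nested* ($N \le N' \Rightarrow$ panel($N$) ⊆
panel($N'$)), a property the workflow relies on when comparing panel
sizes, and which a pure rank-sum trim cannot guarantee because a marker
entering the intersection late can carry a smaller rank sum than an
early entrant. Rank sum still decides among markers entering at the
same depth. Both combiners are verified against linear depth-scan
oracles and for nesting across a size ladder.

With full rankings over a common universe the depth-$M$ intersection is
the whole universe, so `dfi_inter` can only fail when $N$ exceeds the
number of markers; the error reports that bound.

## Classification and the KSR rule

Base learners on raw dosages (no standardization — dosages share one
scale, and standardizing would reweight markers by frequency): KNN with
$k = 1$, linear-kernel C-classification SVM with cost 1, and a
500-tree random forest with mtry $=\lfloor\sqrt M\rfloor$. KNN's $k$,
the SVM cost and the tree count are configurable; the defaults are the
conventional ones for this task. The forests and CV use `ranger` (the
same Breiman random-forest algorithm as the classic `randomForest`
package, substantially faster single-threaded).

KSR integrates the three: the breed predicted by at least two methods
wins; if all three disagree, KNN's call stands. Equivalently — and this
is how it is implemented — SVM's call wins exactly when SVM and RF
agree, otherwise KNN's: any pair involving KNN already returns KNN's
call. The full 27-case truth table is asserted in tests. Note KSR is
not guaranteed to beat its best base method; what is guaranteed (and
asserted) is that it equals the pairwise majority whenever one exists.

Evaluation is replicated, breed-stratified tenfold cross-validation:
each breed is split into ten folds differing by at most one animal;
each fold in turn is the validation set. Replicates re-randomize both
the fold assignment and the learners' seeds ("different random sampling
procedures" covers both sources). Accuracy is
$\frac{1}{R}\sum_{i=1}^{R} \frac{N_T}{N_T + N_F} \times 100\%$ over $R$
replicates, with per-breed accuracies and a mean confusion matrix
(true × assigned, rows summing to breed test sizes) alongside. The
package default is $R = 50$; the acceptance script and the heavier
tests use $R = 10$ at the 13-breed design, which already yields
replicate-stable estimates on simulated data (problem sizes: 375
individuals × 1000-marker panels).

## Pipeline and reproducibility

`run_pipeline()` composes the stages (simulate/load → QC → per-type
pruning and SI merge → tree screen → cross-validated GBC → purebred
screen → panel selection → CV classification), logging marker and
individual counts per stage and writing every artifact (QC table,
newick tree, flagged ids, GBC report, panels, accuracy tables) into the
run directory. Stage seeds are derived from the root seed by drawing
child seeds from a seeded stream, so stages are independently
reproducible and a rerun with the same config is byte-identical. All
randomness in the package flows through caller-supplied seeds; the
global RNG state is saved and restored around every seeded operation.

## Known limitations

- The mislabel screen is a proxy for a visual tree call; its $k$ and
  the majority rule are choices, and borderline introgressed animals
  can be flagged or missed near the threshold.
- GBC estimates shrink toward the interior when reference panels are
  tiny even with joint re-estimation; the 90% screen is calibrated for
  panels of roughly 15+ animals per breed.
- The simulator's independence assumptions (markers, individuals) make
  classification easier than on real data with family structure; the
  headline accuracies here characterize the method under its model, not
  field performance.
- EM convergence near simplex vertices is slow; results are reported at
  a 2000-iteration cap with a $10^{-6}$ log-likelihood tolerance.
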