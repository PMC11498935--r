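---
title: "Models and methods behind somatree"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind somatree}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somatree)
```

# The biological model

Shoot meristems carry no sequestered germ line, so a mutation arising in
a growing stem is inherited by every branch that later develops distal
to it. Across one individual, somatic SNVs therefore form nested
presence/absence patterns over the branch tips, anchored by a basal
cambium sample that defines the reference genotype. Two clocks compete
to explain how many mutations accumulate: a replication clock (mutations
per cell division, hence per unit of growth) and a time clock
(replication-independent damage, hence per year). `somatree` implements
the full chain from noisy per-replicate call tables to the rate
estimates, the architecture comparison, the spectrum, the selection
test, and the two-clock decomposition.

## Mutation accumulation

Along a branch segment of length $\ell$ meters, mutations arise as a
Poisson process with mean $2 G \mu \ell$, where $G$ is the (diploid
factor 2) number of sites and $\mu$ the per-nucleotide per-meter rate.
A mutation on the path between two tips is carried by exactly one of
them, so the pairwise SNV difference between tips $i,j$ is Poisson with
mean $2 G \mu d_{ij}$ — the linear distance law the rate estimator
exploits. At each branching, a daughter meristem may fail to inherit a
mutant cell lineage; the simulator models this as an independent loss
with probability `loss_prob` per daughter branch, which produces the
non-nested "lost" patterns seen in real crowns.

## Rate estimation

`fit_mutation_rates()` regresses the pairwise SNV counts on the pairwise
physical distances over all $\binom{7}{2} = 21$ unordered tip pairs with
a zero intercept, $b = \sum x y / \sum x^2$, and reports
$\mu_g = b / (2R)$ for $R$ callable sites, plus per-tip
$\mu_y = M / (2RA)$ at age $A$ with a t-based mean interval across tips.
All unordered pairs enter once; the regression design is the
conventional pairwise presentation.

**Confidence intervals.** The 21 pairs are not independent: every edge
of the architecture contributes its mutation count to every pair whose
path crosses it. The classical single-regression t interval
(`regress_through_origin()`, and `ci_method = "pairs"`) ignores this and
substantially understates the slope variance — in our simulations it
covers the generating rate in only roughly a third to a half of runs.
Because the estimator knows the architecture, the default
`ci_method = "edge"` instead treats the slope as what it algebraically
is: a fixed weighted sum $b = \sum_e w_e c_e$ of the independent Poisson
edge counts $c_e$, with plug-in variance
$\widehat{\mathrm{Var}}(b) = \sum_e w_e^2\, \hat b\, \ell_e$. This
interval attains close to nominal coverage (~95–96% empirically) and is
the one the package reports by default; the pairwise interval remains
available for comparability with the conventional presentation.

## Discovery pipeline

The discovery logic mirrors a dual-caller, two-replicate,
three-threshold design:

1. hard filters per record — removal conditions are strict inequalities
   (`QD < 2.0` removed, `QD = 2.0` retained; likewise QUAL 30, SOR 4,
   FS 60, MQ 40, MQRankSum −12.5, ReadPosRankSum −8). A missing
   annotation fails its filter (conservative hard-filter semantics) and
   is counted;
2. intersection of the two biological replicates, keyed on
   (contig, position, ref, alt, genotype). Genotype is part of the key:
   a het call in one replicate and a hom call in the other are not
   "identical" calls and do not intersect;
3. intersection of the two callers, same key;
4. pooling of the three calling thresholds (key-level union with
   provenance);
5. support filters across all samples: a site needs ≥ 5 high-quality
   reads in every sample and replicate, and every carrier needs ≥ 2
   alt-supporting reads in both replicates;
6. homozygous collapsing: a homozygous call is one mutation event, not
   two — at realistic rates a genotyping error is far more likely than
   two hits at one site.

Every stage only removes records, so the pipeline is monotone; on
noiseless input it is the identity, which the end-to-end tests assert
exactly.

For inter-individual SNVs the filters run in order: removal within
151 bp (inclusive) of an indel; removal within 151 bp of any site in a
run of more than ten consecutive zero-depth sites; removal at depth
below 5 or above an upper bound computed from the mean depth $d$ of the
whole track before any removal. The upper bound defaults to
$d + 3\sqrt d$ — the mean plus three standard deviations of a
Poisson-like depth — with $4d$ available as `depth_upper = "linear"`;
the source description of this bound is ambiguous and we treat the
Poisson reading as the sensible default.

## Neighbor joining and congruence

`neighbor_joining()` is a from-scratch Saitou–Nei implementation:
join the pair minimising $Q(i,j) = (n-2)d_{ij} - r_i - r_j$, standard
limb lengths, distance update $d_{uk} = (d_{ik}+d_{jk}-d_{ij})/2$, and
the closed-form three-point solution at the end. Two conventions make
it deterministic and robust: ties in $Q$ break by the lexicographically
smallest sorted label pair, and negative limb lengths are clamped to
zero with the deficit moved to the sister limb (total preserved). On any
additive matrix the induced tree distances reproduce the input to
machine precision, which the tests verify against an independent
implementation. The base sample is an all-zero column; it is excluded
from NJ by default (it carries no variant information beyond rooting)
and congruence is computed on the seven tips. Congruence is the
Robinson–Foulds distance — the symmetric difference of non-trivial
bipartition sets, normalised by its maximum $2(n-3)$.

## Spectrum

Substitutions are classified into the 96 pyrimidine-centered
trinucleotide classes (purine-centered contexts are
reverse-complemented; the mapping from the 192 strand-specific contexts
is an exact 2-to-1 surjection, asserted exhaustively). Two
normalisations are provided because the convention is genuinely
ambiguous: `"opportunity"` (default) divides each class count by the
genome count of its reference triplet and renormalises — appropriate for
comparing genomes with different composition — while `"raw"` uses plain
class fractions, the scale on which the published human signature
matrices are defined. Both the raw counts and the opportunity vector are
kept on the object so either view can be recomputed. Sites with a
non-ACGT or missing flank are excluded and counted.

CpG enrichment is the fraction of SNVs whose mutated base sits in a CpG
dinucleotide (either strand) over the fraction of genome positions in
CpG context. Note a bookkeeping consequence of weighting *sites*: with a
site-level weight $m$ on CpG positions and CpG genomic fraction $c$, the
realised enrichment fold is $m / (1 + (m-1)c)$, slightly below $m$ —
about 3.2 for $m = 4$ at $c \approx 0.07$. The recovery tests use the
corresponding band.

## Selection test

For every CDS position and each of the three alternative bases the
mutated codon is classified synonymous / missense / nonsense with the
standard nuclear code, binned by the six pyrimidine-collapsed
substitution classes; the table totals exactly $3 L_{cds}$. The terminal
stop codon is excluded from the enumeration and from $L_{cds}$: stop
mutations have no category in the three-way scheme (a stop-to-sense
change is neither missense nor nonsense), and excluding them is the only
convention under which the $3 L_{cds}$ identity holds exactly.

Background rates come from the intergenic complement — outside all gene
territories extended 1 kbp upstream of the start codon and 500 bp
downstream of the stop, strand-aware — as class counts over eligible
bases (C:G for C>\*, A:T for T>\*); a whole-genome alternative is
provided. The neutral expectation is
$p_N = \lambda_N / (\lambda_S + \lambda_N)$ with
$\lambda = \sum_{\text{class}} \text{rate} \times \text{opportunity}$;
despite sometimes being labelled a "synonymous" rate in the field, this
quantity with $\lambda_N$ in the numerator is the expected
*non-synonymous* fraction, and that is what the package calls it. The
test is the standard exact two-sided binomial test; its discrete size at
the simulation's operating point measures 0.03–0.05, within the nominal
band.

## The two-clock growth model

The per-division rate decomposes as $\mu = \alpha + \beta\tau$
(replication-dependent $\alpha$ per division; replication-independent
$\beta$ per year over a cell cycle of $\tau$ years), giving the per-year
rate $r\mu = \alpha/\tau + \beta$ and accumulation
$m(t) = (\alpha/\tau + \beta)t$. For two species sharing $\alpha,\beta$
but differing in cell-cycle duration, the per-meter rate ratio
$(\alpha+\beta\tau_S)/(\alpha+\beta\tau_F)$ runs monotonically from 1
($\beta = 0$) to $\tau_S/\tau_F$ ($\beta \gg \alpha$).
`assess_consistency()` inverts this: an observed ratio strictly inside
$(1, \tau_S/\tau_F)$ has the exact solution
$x = \beta\tau_F/\alpha = (\rho-1)/(\tau_S/\tau_F - \rho)$; a ratio at
or above the supremum has no finite nonnegative solution and is reported
explicitly as the $\beta \gg \alpha$ limit with its gap, rather than
silently clipped — an observed 3.7 against a cell-cycle ratio of 3.2 is
such a case. The cell-cycle ratio itself is taken as inversely
proportional to the growth increment when not supplied directly. The
package parameterises $\alpha,\beta$ per model object; cross-species
comparisons assume they are shared, which is the model's own assumption,
not a fact about the data.

# The synthetic-data generator

The generator emulates the study design the analysis assumes: one
individual, a base sample plus seven branch tips (defaults), an
annotated single-contig diploid genome, Poisson mutation accumulation
per branch with a configurable CpG C>T excess, independent loss at
branch points, a configurable homozygous fraction (default 46/1136),
and two biological replicates per sample with per-site false-negative
and false-positive call probabilities, Poisson depths, and hard-filter
annotations drawn from pass/fail mixtures. Both callers and all three
thresholds see the same site evidence by default — caller disagreement
is representable through the error rates, not mechanistically.

Deliberate simplifications, hence what passing tests do and do not show:
sites are mutated under an infinite-sites approximation (collisions are
resampled with a warning); genes are single-exon with clean ORFs; no
reads are simulated, so mapping artefacts, allele-frequency effects and
manual curation have no counterpart; depth is Poisson, not overdispersed;
replicate errors are independent, which is exactly the assumption the
replicate-intersection filter exploits. Recovery on this generator
validates the pipeline's logic and statistics, not the behaviour of
upstream callers on real reads.

Defaults follow the study conditions where those are stated (7 tips +
base; ~40 m architectures; 2 replicates; the 46/1136 homozygous
fraction; three thresholds; two callers) and otherwise use round,
field-plausible values: 30× mean depth, GC 0.37, 200 kb default genome
with 20 genes of mean CDS 900 bp. Simulation problem sizes in the tests
and the acceptance script (genomes of 30–200 kb, per-meter rates of
2×10⁻⁵–3×10⁻⁴, 100–200 seeds, 1000 calibration replicates) were chosen
once so that every targeted property has adequate resolution — e.g.
≥ 50 expected SNVs per pair for coverage, ≥ 20 SNVs per tip for
congruence, ≥ 2000 SNVs for enrichment — while the whole suite stays
fast; rates this high per meter simply compress the per-base rate scale
and leave every estimator's geometry unchanged.

# Numerical conventions

* Boundary convention everywhere: removal conditions are strict
  inequalities; values exactly at a threshold pass. The indel window is
  inclusive (distance ≤ 151 bp removed).
* NJ tie-break: lexicographic smallest label pair; negative limbs
  clamped with transfer. Newick output quotes labels and prints lengths
  to 6 significant digits (the tree object itself keeps full precision).
* Spectrum classes are ordered substitution-major (C>A, C>G, C>T, T>A,
  T>C, T>G), then 5′ and 3′ flank alphabetically — the conventional
  signature-matrix row order.
* The interior solution of the ratio equation is returned to full
  precision; round-trips through `predicted_rate_ratio()` recover
  $\beta\tau_F/\alpha$ to 10⁻⁹.
* Reporting precision follows the field's presentation: rates to 3
  significant figures, fold-ratios to 2.

# Known limitations

* Callable-site counts $R$ are inputs, not computed from alignments.
* The NJ implementation is $O(n^3)$ — ample for crown-scale problems,
  not for hundreds of taxa.
* CIs for $\mu_y$ treat the seven tips as independent replicates; tips
  sharing long trunk paths are positively correlated, so that interval
  is approximate (the paired-sample design of the per-meter estimator
  does not apply to it).
* The selection test uses six substitution classes, not 96-context
  opportunities; with hundreds rather than thousands of coding SNVs the
  finer weighting is not identifiable, which is also why the package
  does not attempt signature refitting.
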