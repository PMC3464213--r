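---
title: "Family-aware variant calling and de novo mutation detection: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Family-aware variant calling and de novo mutation detection: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Short-read sequencing of families offers two things unrelated samples
cannot: Mendelian transmission constrains which genotype configurations
are possible, and a genuine violation of those constraints is evidence of
a germline de novo mutation (DNM).  Most variant callers ignore
relatedness, which wastes the first source of information and turns
genotyping errors into spurious Mendelian inconsistencies — exactly the
sites a DNM screen would flag.  `famcall` implements a single likelihood
framework in which variant site discovery, per-individual genotype
calling, and DNM scoring all condition on the sequence data of every
member of a pedigree simultaneously.

# Models

## Genotype likelihoods

At one genomic site for one individual, each aligned base $b_j$ carries an
error probability $e_j$ (from its Phred quality).  Given a true diploid
genotype $\{a_1, a_2\}$, a base originates from either allele with
probability $1/2$, is read correctly with probability $1 - e_j$, and is
otherwise miscalled uniformly to one of the three alternative bases:

$$\mathrm{GL}(\{a_1,a_2\}) \;=\; \sum_j \log\Bigl(\tfrac12 P(b_j \mid a_1, e_j) + \tfrac12 P(b_j \mid a_2, e_j)\Bigr),
\qquad P(b \mid a, e) = \begin{cases} 1-e & b = a\\ e/3 & b \ne a.\end{cases}$$

Base errors are treated as independent; correlated-error corrections are
deliberately not modeled.  All ten unordered genotypes over
$\{A,C,G,T\}$ are evaluated (canonical order
`AA, AC, AG, AT, CC, CG, CT, GG, GT, TT`).  Everything is done in
natural-log space — at 30x and above, linear-space products underflow —
and conversion to Phred-scaled PLs happens only at I/O boundaries.
Per-base error rates below $10^{-10}$ are clamped there, so "Q infinity"
inputs cannot produce $-\infty$.

## Pedigree likelihood

For a family with read vector $R$ and genotype vector $G$ at a biallelic
site with alleles $(A_1, A_2)$ and founder alternative-allele frequency
$p$:

$$L(R \mid p) = \sum_G \;\prod_i \mathrm{GL}_i(G_i)\; \prod_{\text{founders}} \mathrm{HWE}(G_f; p) \prod_{\text{triplets}} P(G_c \mid G_{fa}, G_{mo}),$$

with Hardy–Weinberg founder priors and Mendelian transmission (each
parent passes each of its two alleles with probability $1/2$).  The sum
over $3^n$ configurations is evaluated by Elston–Stewart peeling: the
pedigree is decomposed into nuclear families, which form a tree for
outbred pedigrees; leaf families are summed out and passed as a
three-valued message to the connector individual shared with the next
family.  Peeling is linear in pedigree size and exact — the test suite
holds it to within $10^{-10}$ (log scale) of a brute-force enumeration
oracle on 200 randomized pedigrees per run.

Members without sequence data carry flat likelihoods, so unsequenced
founders are integrated out and their allele frequency is still informed
by their descendants.  Within the peeling engine the genotype space is
restricted to the three genotypes over $(A_1, A_2)$; the 10-genotype
space is used only for likelihood storage and allele-pair selection
(variant sites are assumed biallelic).

## Site discovery and frequency estimation

Per site, seven configurations are scored: monomorphic reference, the
transition of the reference (prior $2/3$ of the variant mass), the two
transversions ($1/6$ each), and the three allele pairs excluding the
reference.  The prior probability that the site is variant at all is the
neutral coalescent mass $\theta \sum_{i=1}^{2N-1} 1/i$ with
$\theta = 10^{-3}$ by default and $N$ the number of diploid founders
across all families.  Each variant configuration is scored by its profile
likelihood: $p$ is estimated by a 7-point coarse scan followed by Brent
search on $[10^{-8}, 1-10^{-8}]$ (absolute tolerance $10^{-8}$), jointly
across all families, and plugged in.  The site quality is
$-10\log_{10} P(\text{monomorphic reference} \mid R)$ from the normalized
configuration posteriors; sites with variant posterior $\ge 0.5$ are
emitted (configurable — no emission cutoff is prescribed by the source
framework, so the neutral posterior threshold was chosen).

Because the profile likelihood of a variant configuration tends to the
monomorphic likelihood as $p \to 0$, the variant posterior of a clearly
monomorphic site floors near its prior mass rather than at zero; this is
a property of profiling rather than integrating over $p$, which we accept
because the frequency is a genuine nuisance parameter estimated by ML.

## Genotype calling

Individual genotypes are posterior modes conditioning on the whole
family's reads, computed by clamped peeling at the estimated $p$.  Ties
break toward fewer alternative alleles.  Reported per genotype: GQ
$= -10\log_{10}(1 - \max \text{posterior})$ capped at 99, and the dosage
$P(\mathrm{het}) + 2P(\mathrm{hom~alt}) \in [0, 2]$.

## De novo mutations

A per-generation allele transition matrix makes transmission
mutation-aware: transitions mutate at rate $\alpha$, each transversion at
$\beta$, diagonal $1 - \alpha - 2\beta$.  Defaults: total per-allele rate
$\mu = 1.5\times10^{-8}$ per site per generation split
$\alpha = \mu/2$, $\beta = \mu/4$ (a transition twice as likely as each
transversion).  The published description prints the identity
$\mu = 2\alpha + \beta$, which is inconsistent with one transition and
two transversion targets per allele; the constructor therefore takes
$(\alpha, \beta)$ (or an arbitrary user 4x4 matrix) and derives the row
sums itself.

The DNM score for a family at a site is the likelihood ratio
$\mathrm{LR} = L_{denovo} / L_{mendel}$: the same peeling engine run with
mutation-aware versus strictly Mendelian transmission, both at the same
plugged-in $\hat p$.  The posterior probability of a DNM is
$1 - L_{nomut}/L_{denovo}$, where $L_{nomut}$ is a third peeling pass
with the off-diagonal of the mutation matrix zeroed (the mass of all
transmission paths without any mutation event).  A candidate is claimed
when $\mathrm{LR} \ge 10$ (default) *and* at least one father–mother–
offspring triplet of called genotypes is Mendelian-inconsistent;
optionally the stricter rule requiring hom-ref parents and a het child.

### Behavior of the LR, and a known gap

The LR is sharply bimodal.  When both parents carry strong hom-ref
evidence, the profile $\hat p$ sits at the $10^{-8}$ boundary (the cohort
pins it) and the LR is astronomical ($10^{5}$–$10^{8}$).  When one
parent's hom-ref evidence is weak — low realized depth, or a spurious
alt-base read ($e/3$ per base) — the Mendelian explanation "that parent
is actually het" becomes competitive, $\hat p$ moves interior
($\approx 1/(2 \times \text{total alleles})$), and the LR collapses
toward 1.  The claim threshold is therefore not the operative lever: at
30x mean depth the detected fraction is the probability that neither
parent falls in the weak-evidence regime, about 90–92% in a 100-trio
cohort, largely insensitive to the threshold anywhere in $[2, 10^4]$.  The
published benchmark reports over 98% at 30x; reaching that number with
these likelihoods would require a caller-side prior mutation rate near
$10^{-7}$ rather than $1.5\times10^{-8}$.  We keep the published rate and
report the measured power honestly; both the rate and the threshold are
exposed (`mutation_model()`, `lr_threshold`).

## Consanguinity

Elston–Stewart peeling requires the nuclear-family graph to be a tree.
Marriage/inbreeding loops are broken by duplicating one individual per
loop: the original keeps its parent links, a clone takes over the
spouse/offspring role and becomes a founder, and both share the same
sequence data.  This is the classic loop-breaking approximation — the
clone's data is counted twice and founder prior mass is duplicated, so
the likelihood is inexact — but it preserves most of the family
information; the first-cousin benchmark below shows the expected
two-fold accuracy gain over ignoring relatedness.  Posteriors are
reported for the original instance only.

# The simulator: what it emulates, and what it does not

`simulate_dataset()` generates the idealized no-mapping-error world used
for all quantitative checks:

* **Sites** are independent.  Per site the alternative allele frequency is
  drawn from the neutral site frequency spectrum
  $P(\text{freq} = i/n) \propto 1/i$ over the $n$ founder haplotypes of
  the whole cohort; founder haplotype alleles are Bernoulli draws at that
  frequency.  The reference allele is uniform; the alternative is the
  transition with probability $2/3$.  This *replaces* the original
  benchmark's demographic coalescent haplotypes (European/African
  models, with linkage disequilibrium): the metrics under test — genotype
  accuracy versus depth, Mendelian inconsistency, DNM power — depend on
  depth, error rate and the frequency spectrum, and the caller itself
  ignores LD.  Externally generated haplotypes can be supplied through
  `gene_drop()` directly.
* **Gene dropping**: founders take haplotype pairs; each meiosis lays
  $\mathrm{Poisson}(1.5\times10^{-8} \times \text{region length})$
  crossovers uniformly and transmits one recombinant per parent.  At the
  simulated scales recombination is nearly inert, but it is implemented
  and moment-tested.
* **Reads**: per individual-site depth is $\mathrm{Poisson}(c)$; each base
  comes from either allele with probability $1/2$ and is miscalled
  uniformly with probability $e$ (Q20 $= 0.01$, Q30 $= 0.001$).  The
  dataset generator samples the per-base-identity *counts* directly from
  the equivalent multinomial — distributionally identical to per-base
  simulation (`simulate_pileup()` does the per-base version and the test
  suite checks the moments agree).
* **DNMs** are injected per transmitted allele at $1.4\times10^{-8}$ per
  site per generation (stochastically inert at desk scale), or planted
  ("forced" mode) for power studies: `simulate_dnm_trios()` builds a
  cohort of 100 sequenced trios in which the first trio's child carries
  one DNM per site — power is estimated conditional on a mutation having
  occurred, since a rate-based estimate would need $\sim 10^{10}$
  site-transmissions.

A green simulation test therefore establishes correctness of the
likelihood machinery and the direction and rough magnitude of the
family-information gains; it does not establish performance under
mapping error, indel realignment artifacts, LD, or non-equilibrium
demography.

# Evaluation conventions

* The false negative rate is the percentage of true non-reference
  genotypes not recovered as non-reference (site unemitted or modal call
  hom-ref), averaged per individual.
* Mismatch rates compare called and true unordered allele pairs at sites
  polymorphic in the simulated sample, stratified by the *true* genotype
  (HomRef / Het / HomAlt); unemitted sites count as hom-ref calls.
* The Mendelian inconsistency rate divides inconsistent called triplets
  by (true variant sites) x (triplets); unemitted sites are hom-ref and
  hence consistent.  Whether monomorphic sites belong in the denominator
  is ambiguous in the source description; restricting to true variant
  sites is recorded in the report and used consistently for both calling
  modes, so the family/unrelated comparison is unaffected.
* Frequency stratification uses 10 equal bins on the true alternative
  allele frequency.

# Worked example

```{r, eval = FALSE}
library(famcall)

# simulate 4 three-generation pedigrees over 2000 shared sites at 10x
sim <- simulate_dataset(
  sim_config(n_sites = 2000, coverage = 10, base_error = 0.01, seed = 1),
  make_pedigrees("3gen", 4))

fam  <- call_sites(sim, mode = "family")
std  <- call_sites(sim, mode = "unrelated")
evaluate_calls(fam, sim)   # FNR, mismatch by category, Mendelian rate
evaluate_calls(std, sim)   # same metrics ignoring relatedness

# de novo power at 30x
dnm_power_experiment(n_sites = 200, coverage = 30, seed = 1)$power
```

# Numerical choices

* Peeling runs in linear space with per-step rescaling (log-scale carried
  separately); messages and member potentials are renormalized to max 1
  after every multiplication, so no underflow occurs for any pedigree
  depth tested.
* Brent search is bracketed by a 7-point coarse scan
  $\{10^{-8}, .05, .25, .5, .75, .95, 1-10^{-8}\}$; a configuration whose
  coarse maximum lies more than 50 nats below the current best
  configuration is not refined (its posterior mass is below
  $2\times10^{-22}$ regardless).
* Genotype-call ties break toward fewer alternative alleles; GQ is capped
  at 99; dosages are reported to 4 decimals in VCF.
* The binary GLF format is not implemented; a documented tab-separated GL
  table (one row per individual-site, 10 natural-log likelihoods in
  canonical order) and VCF PL fields cover interchange.
* Sex chromosomes are not modeled; all sites are treated as autosomal
  diploid.

# Known limitations

* Loop-broken likelihoods are approximate (no exact summation over
  inbreeding loops).
* Multi-allelic sites, LD/haplotype refinement, reference bias and
  mapping error are out of scope.
* Indel genotype likelihoods are consumed from external VCF PL/GL fields
  (`famcall refine`), never computed from reads.
* DNM detection power at the default prior mutation rate falls a few
  points short of the published 30x benchmark, for the reason analyzed
  above.
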