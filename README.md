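# famcall

Family-aware variant calling, genotype calling and de novo mutation
detection from next-generation sequencing genotype likelihoods.

## Who this is for

Statistical geneticists and sequencing-pipeline developers analysing
short-read data for **related individuals** — trios, nuclear families,
multi-generation pedigrees, including consanguineous ones.  Standard
callers treat samples as unrelated, which discards Mendelian
transmission information and turns genotyping errors into spurious
Mendelian inconsistencies (false de novo candidates).  `famcall` models
the whole family jointly and emits better variant lists, better
genotypes, and a calibrated de novo mutation score; it also ships the
simulator and metrics needed to verify every one of those claims without
external data.

## The model in brief

Per individual and site, 10-genotype likelihoods come from the
independent-error pileup model
`GL(a1,a2) = Σ_j log(½·P(b_j|a1,e_j) + ½·P(b_j|a2,e_j))` with
`P(b|a,e) = 1−e` on a match and `e/3` per miscall.  The family
likelihood at a biallelic site with founder alt frequency *p* is

```
L(R|p) = Σ_G Π_i GL_i(G_i) · Π_founders HWE(G_f; p) · Π_triplets P(G_c | G_fa, G_mo)
```

evaluated exactly by Elston–Stewart peeling (linear in pedigree size;
loops broken by individual duplication).  Site discovery scores seven
allele configurations under a neutral coalescent prior
`θ·Σ_{i=1}^{2N−1} 1/i` (θ = 1/1000), each with *p* profiled out by Brent
search jointly across families.  Genotypes are family-conditional
posterior modes with GQ and dosage.  De novo evidence is the likelihood
ratio `L_denovo / L_mendel` between mutation-aware transmission (4×4
allele transition matrix, default total rate 1.5e-8 per site per
generation) and strict Mendelian transmission; a candidate needs
`LR ≥ 10` plus a Mendelian-inconsistent called triplet.

See `vignettes/famcall-methods.Rmd` for the full account, assumptions
and limitations.

## Worked example

```r
library(famcall)

## 3 ten-person 3-generation pedigrees, 2000 shared polymorphic sites,
## 5x coverage, Q20 bases (1% error)
sim <- simulate_dataset(
  sim_config(n_sites = 2000, coverage = 5, base_error = 0.01, seed = 7),
  make_pedigrees("3gen", 3))

fam <- call_sites(sim, mode = "family")     # model the pedigrees
std <- call_sites(sim, mode = "unrelated")  # standard approach

evaluate_calls(fam, sim)
#> <famcall metrics>
#>   FNR per individual (%): 3.988
#>   mismatch (%): All=3.501  HomRef=0.875  Het=9.157  HomAlt=2.628
#>   Mendelian inconsistency rate: 0.000219
#>   Ts/Tv: 2.002
evaluate_calls(std, sim)
#> <famcall metrics>
#>   FNR per individual (%): 5.646
#>   mismatch (%): All= 4.98  HomRef= 1.17  Het=13.32  HomAlt= 3.45
#>   Mendelian inconsistency rate: 0.0435
#>   Ts/Tv: 1.998
```

Reading: at 5x, family-aware calling misses 4.0% of true non-reference
genotypes per individual versus 5.6% when relatedness is ignored, halves
the heterozygote error excess, and cuts Mendelian inconsistencies
~200-fold — the error-driven inconsistencies that would otherwise flood
a de novo screen.  (At the benchmark scale of 30 pedigrees × 20,000
sites these numbers tighten to ≈3.2% vs ≈5.6%.)

De novo power, conditional on a planted mutation, in a 100-trio cohort
at 30x:

```r
dnm_power_experiment(n_sites = 200, coverage = 30, seed = 11)$power
#> [1] 90
```

(The published benchmark reports over 98% here; the vignette analyses why
these likelihoods top out near 90–92% at the default prior mutation rate,
and which knobs control it.)

## Command line

```sh
famcall simulate --config sim.json --out-prefix sim     # GL table + PED + truth
famcall call     --gl sim.gl.tsv --ped sim.ped --denovo --out out.vcf
famcall call     --gl sim.gl.tsv --ped sim.ped --unrelated --out std.vcf
famcall denovo   --vcf out.vcf --ped sim.ped --lr-threshold 10
famcall evaluate --calls out.vcf --truth sim.truth.tsv --ped sim.ped \
                 --report report.json
famcall refine   --vcf external.vcf --ped fam.ped   # family-aware
                 # re-genotyping from external PL/GL (e.g. indels)
```

The executable lives at
`system.file("cli", "famcall", package = "famcall")`; equivalently call
`famcall_cli(c("call", ...))` from R.

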