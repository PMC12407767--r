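# demuxamb

Genotype-based demultiplexing and ambient-contamination estimation for
pooled single-cell RNA+ATAC multiome droplets.

## What problem this solves

Pooling genetically distinct donors in one multiome channel is the
standard way to scale single-cell experiments: the donors' SNPs act as
natural barcodes and each droplet can be assigned back to its donor
from the alleles observed in its reads. But droplets — especially from
nuclei isolated out of solid or frozen tissue — also contain cell-free
**ambient** molecules from the loading suspension, which carry the
pooled average genotype rather than one donor's. Ambient contamination
degrades naive demultiplexing; modeled explicitly, it becomes
estimable per droplet.

demuxamb is a likelihood-based method for exactly that joint task. For
every droplet barcode it

- classifies the droplet as **empty / singlet / doublet** (no prior
  barcode filtering needed — empty droplets are a first-class
  hypothesis),
- assigns singlets and doublets to **donors**, and
- estimates a per-droplet **ambient molecule fraction** α separately
  for the RNA and the ATAC modality.

It is aimed at analysts of pooled 10x-style multiome experiments with
donor genotypes (VCF) available, and at methodologists who want a
simulator with known ground truth for this setting.

## The model in brief

A droplet has `H ∈ {0,1,2}` nuclei (categorical, proportions λ) and
donor composition `S` (singlet donor `i` w.p. `π_c[i]`; doublet `{i,j}`
∝ `π_c[i]·π_c[j]` over unordered distinct pairs). Each deduplicated
molecule (RNA UMI group / ATAC fragment) is ambient with probability
`α` — the droplet's per-modality ambient fraction, fixed at 1 for
empty droplets — or else comes from the hypothesis' donor(s), doublet
donors contributing equally. A molecule from origin `i` emits at every
overlapping SNP `v` a base call that is, with sequencing error
probability τ (Phred), uniform over the four bases, and otherwise
Bernoulli in the origin's alternate-allele frequency `γ[v,i]`:

    p(b | origin i) = (1 − τ) · Bern(b; γ[v,i]) + τ/4

Donor `γ` come from the VCF (0, 0.5, 1); the ambient pool's allele
frequency is the mixture `γ_a[v] = Σ_i π_a[i]·γ[v,i]`, with ambient
donor proportions `π_a` estimated once from the sub-threshold
("fixed-empty", < 100 molecules in both modalities) droplets by
projected gradient ascent and then frozen. Per-droplet α's are fitted
by safeguarded Newton–Raphson with a weak Beta-like prior; λ and π_c by
EM; the prior center β is reset each round to the weighted average
singlet α. Droplet types are called when their posterior mass reaches
0.90 (otherwise ambiguous). See the methods vignette
(`vignettes/ambient-demultiplexing.Rmd`) for the full account.

The package also ships the matching droplet **simulator** (abstract
molecule-table mode, plus a sequence mode that writes FASTQ/SAM against
a synthetic genome) and the **evaluation** metrics (singlet
precision/recall, ambient-fraction MAE, error-versus-coverage curves).

## Worked example

Simulate a 4-donor experiment with medium contamination (per-droplet
ambient fractions ~ Beta(4,16), mean 0.2), fit, call, and score:

```r
library(demuxamb)

cfg <- simConfig(n_cellular = 500, n_empty = 1500, n_donors = 4,
                 n_variants = 20000, coverage_mean = 1000,
                 ambient = "medium")
sim  <- simulateExperiment(cfg, seed = 1)
fit  <- demuxFit(sim$molecules, sim$pool$genotypes)
fit
#> DemuxFit: 501 test droplets, 664 fixed-empty, 11 hypotheses, 4 donors
#>   converged: TRUE after 6 iterations
#>   lambda: 0.5722, 0.4119, 0.0159

calls <- callDroplets(fit, threshold = 0.90)
head(calls[, .(barcode, call, donor1, p_sng, alpha_rna, alpha_atac)], 3)
#>      barcode   call  donor1     p_sng alpha_rna alpha_atac
#> 1: BC0000001    SNG donor01 0.9971065 0.3516733  0.5173616
#> 2: BC0000002    SNG donor04 1.0000000 0.1937626  0.1201581
#> 3: BC0000003    AMB    <NA> 0.8191010 0.5666788  0.6485951

ev <- evaluateCalls(fit, sim$truth)
ev$pr[threshold == 0.9]
#>    threshold n_called n_correct precision    recall
#> 1:       0.9      470       468 0.9957447 0.9894292
round(ev$mae_correct_singlets, 4)
#>    RNA   ATAC
#> 0.0857 0.0785
```

Reading this: of the 501 barcodes with ≥ 100 molecules, 470 were called
singlets at the 0.90 posterior threshold and 468 of them got the right
donor (precision 0.996); 98.9% of all true singlets were recovered.
The fitted per-droplet ambient fractions are within ~0.08 of the truth
on average at this moderate coverage (≈ 110 informative molecules per
modality); the error shrinks roughly with the square root of the
informative-molecule count (see `errorByCoverage()`).

Real data enter through `readGenotypes()` (VCF) and either
`pileupBam()` (indexed BAM per modality, `CB`/`UB` tags, optional peaks
BED for intra/inter-peak ATAC labels) or `readMoleculeTable()` (the
TSV interchange format). A command-line wrapper with `simulate`, `fit`,
`evaluate`, and `pileup` subcommands is installed at `exec/demuxamb`.

`assignments.tsv` columns: `barcode`, `call` (EMPTY/SNG/DBL/AMB),
`donor1`/`donor2`, type posterior masses `p_empty`/`p_sng`/`p_dbl`,
best-hypothesis masses `p_best_sng`/`p_best_dbl`, fitted `alpha_rna`/
`alpha_atac` at the reported hypothesis (1 for EMPTY), a `tie` flag,
and per-modality coverage (`n_rna`, `n_atac`, `inf_rna`, `inf_atac`).
`summary.json` records call counts, λ, π_c, π_a, β, and convergence.

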