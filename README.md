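# zwmarkers

In-silico evaluation of PCR sexing markers on avian ZW genomes.

Birds carry ZW sex chromosomes (females ZW, males ZZ), and many species —
turacos (Musophagiformes) almost without exception — cannot be sexed by
looking at them. Molecular sexing uses PCR markers built on conserved genes
(*CHD1*, *NIPBL*, *SPIN*) whose Z and W gametolog copies differ in the
length of an intron: one primer pair, two bands in females (Z + W product),
one band in males. Whether such a marker works for a given species is
largely computable from genome sequence, and this package computes it:

* **gene structure** — spliced mapping of an mRNA onto genomic sequence to
  recover exon/intron coordinates (`map_exons()`, `intron_table()`,
  GFF3 export);
* **in-silico PCR** — IUPAC-degenerate primer binding-site scanning with a
  3'-exact rule, exhaustive product enumeration, and exon/intron
  composition per product (`scan_primer()`, `enumerate_amplicons()`,
  `annotate_composition()`);
* **homology search** — k-mer seeded, banded, affine-gap local alignment
  (fixed scoring +1/−2, gap −5/−2) to find second genomic copies of an
  amplicon and classify gene locations (`local_search()`, `chain_hits()`,
  `locate_gene()`, `presence_matrix()`);
* **copy comparison** — pairing the Z amplicon with its best second copy
  and computing the length polymorphism ΔL = |len(Z) − len(second)|
  (`pair_copies()`, `species_summary()`);
* **gel model** — a calibrated log-linear band-migration law
  d = t·V·exp(α(g) − β(g)·ln L) with band width, lane run-off, and
  smallest-resolving-gel search (`gel_config()`, `resolvable()`,
  `min_gel_percent()`, `render_gel()`);
* **marker evaluation** — per-marker sexing verdicts (informative /
  z_only / unresolvable / partial / not_found / confounded), per-individual
  sex calls that are correct or indeterminate but never confidently wrong,
  and ranked marker panels (`evaluate_marker()`, `sex_call()`,
  `recommend_panel()`);
* **synthetic data** — a seeded ZW genome generator with planted gene
  models, primer sites, gametolog divergence and intron indels, plus full
  ground truth (`simulate_zw()`, `random_sim_config()`,
  `recovery_report()`), and a deterministic synthetic reference landscape
  engineered to the marker geometry reported for the published turaco
  genome assemblies (`turaco_reference_fixture()`).

The methods vignette (`vignettes/zwmarkers-methods.Rmd`) describes the
models, parameters and design choices in detail.

## Worked example

Simulate a ZW genome pair with a planted 43 bp intron length polymorphism
and run the full pipeline:

```r
library(zwmarkers)

sim <- simulate_zw(sim_config(seed = 42))
run <- run_marker_pipeline(sim, sim$primers, species_id = "demo")

run$z_amplicons[, c("marker_id", "length", "composition")]
#>     marker_id length           composition
#> MZ1       MZ1    520 E1(60)/I1(400)/E2(60)

run$reports[, c("marker_id", "z_length", "second_length",
                "second_location", "delta_L", "z_longer")]
#>   marker_id z_length second_length second_location delta_L z_longer
#> 1       MZ1      520           477               W      43     TRUE

run$verdicts[, c("marker_id", "verdict", "gel_pct_required", "delta_L")]
#>   marker_id     verdict gel_pct_required delta_L
#> 1       MZ1 informative                1      43
```

The 520 bp Z product spans 60 bp of exon 1, the whole 400 bp intron and
60 bp of exon 2; its W copy is 477 bp (the planted 43 bp deletion), so the
marker is informative, separating on a 1% gel after an hour. A female lane
shows both bands, a male lane one:

```r
v <- run$verdicts[1, ]
sex_call(c(520, 477), v)$call   # "female"
sex_call(520, v)$call           # "male"
print(render_gel(list(male = 520, female = c(520, 477)),
                 gel_config(1), 60))
```

The scripted analyses in `analysis/` (01–07) run the same machinery over
the packaged reference landscape: gene structure of the CHD1- and
NIPBL-like genes (intron 9 = 2852 bp, intron 16 = 335 bp, intron 22 =
185 bp, NIPBL intron 17 = 801 bp), the six locatable markers' amplicons
(367, 258, 2997, 504, 464, 923 bp with their exon/intron compositions),
their second copies (378, 269, 623, 461, 421, 510 bp; ΔL = 11, 11, 2374,
43, 43, 413, with Z shorter only for the intron-22 markers), gel
resolvability per marker, verdicts and panels, and a 100-genome synthetic
validation study. Each script prints what it found and writes tables under
`results/`.

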