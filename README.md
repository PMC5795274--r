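# tfanno: target-gene-based functional annotation of transcription factors

Most human transcription factors (TFs) are poorly characterised: we often
know *that* a protein binds DNA, but not *which* biology it controls. One
productive route around this is indirect — a TF inherits the functions of
the genes it regulates. `tfanno` implements that idea as a tested pipeline
for systems biologists working with ChIP-seq-derived regulatory networks:

1. **Target-gene calling** (TIP-style). From a genes × bins matrix of
   binding signal in a window centred on each transcription start site, the
   TF's characteristic profile is the normalised mean signal
   `w_i = s̄_i / Σ_i s̄_i`, each gene is scored by the weighted sum
   `g_j = Σ_i w_i s_ji`, scores are standardised to
   `z_j = (g_j − ḡ)/sd(g)`, converted to one-sided upper-tail normal
   p-values, and targets are called at a Benjamini–Hochberg FDR (default
   0.01, window 6,000 bp with a 20,000 bp alternative).
2. **A TF→target-gene compendium** merged across evidence sources
   (low-throughput literature, ENCODE, other ChIP-seq) with GMT
   serialisation, degree statistics and master-regulator detection.
3. **Target-function detection**: for each TF × functional term, a 2×2
   table of target-gene versus term-membership status restricted to an
   explicitly chosen *gene universe*, tested by Fisher's exact test (and a
   G-test approximation, `G = 2 Σ O ln(O/E)`), with the phi coefficient

   `φ = (n11·n00 − n10·n01) / √((n10+n11)(n00+n10)(n01+n11)(n00+n01))`

   giving the direction, and BH control applied per annotation source.
   Curated sources (OMIM/PharmGKB/Reactome/GO-like) are tested against a
   conservative "literature-rich" universe (coding genes with at least one
   curated annotation); machine-derived sources (GWAS-like) against all
   coding genes. The universe matters: inflating it with irrelevant genes
   strictly inflates the odds ratio.
4. **A randomized-compendium null model**: fake TFs with matched target
   counts sampled uniformly from the universe; pairing real vs fake
   p-values per TF × term estimates the number of true associations
   (`n_upper − n_lower`) and the empirical FDR at a cutoff
   (`n_fake / n_real`).
5. **Similarity networks**: TF–TF target-gene sharing (phi, Fisher, BH;
   neighbors at FDR 0.01), target-function and known-function sharing, the
   discordance analysis of function-similar but target-dissimilar TF
   pairs, and function–function regulator sharing (functions linked by
   identical regulators without shared member genes).
6. **Diversity / pleiotropy indices**: each entity's uniqueness
   `u_t = 1/Σ_{t'} φ²_{tt'}` down-weights redundant TFs or terms, and the
   effective number of regulators or functions is `π = Σ u_t` over the
   members. Regulator diversity is related to functional pleiotropy by an
   OLS Wald test controlling for the number of targets per TF, with a
   PageRank control for network position.
7. **A synthetic-data generator** with planted TF–function structure, so
   every stage is testable end to end without external data.

The package is Bioconductor-style S4: `BindingProfile` (a
`SummarizedExperiment`), `Compendium`, `AnnotationCollection`,
`SimulationConfig`, with accessors and validity methods.

## Worked example

```r
library(tfanno)

cfg <- simulationConfig(seed = 42)   # the default synthetic study
sp  <- generateGeneSpace(cfg)        # 2,000 genes, 6 annotation sources
cm  <- generateCompendium(cfg, sp$genes, sp$collections)
cm$compendium
#> Compendium: 1315 TF->TG edges, 20 TFs, 935 target genes
#>   evidence labels: other_high_throughput

a   <- annotateTFs(cm$compendium, sp$collections, sp$genes, fdr = 0.05)
sig <- a[a$significant & a$direction == "positive", ]
nrow(sig)
#> [1] 30
head(sig[order(sig$p_two_sided),
         c("tf", "term", "source", "n11", "odds_ratio", "phi", "q")], 3)
#>           tf          term   source n11 odds_ratio   phi        q
#> 1059 G000521     GOBP_T009     GOBP  33       54.3 0.532 6.57e-30
#> 735  G000254 Reactome_T015 Reactome  35       52.5 0.505 7.14e-30
#> 307  G000660     GWAS_T007     GWAS  24       75.0 0.495 1.01e-25
```

Each row says: of the TF's target genes inside the source's universe,
`n11` are members of the term — far more than the universe-conditioned
expectation (odds ratio ≫ 1, positive phi), so the term is called a target
function of that TF at FDR 0.05. Against the generator's planted truth
(30 TF–term links), this run recovers 29/30 with one extra call
(recall 0.97, precision 0.97).

`runPipeline(cfg, "out/")` executes all seven stages
(simulate → call-targets → merge → annotate → nullfdr → similarity →
diversity), writes every artifact as GMT/TSV plus a `manifest.json` with
md5 digests, and is byte-identical on rerun with the same seed.

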