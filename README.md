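# panrec

Comparative pangenomics and biogeography for prokaryotic genome
collections — written for microbial ecologists working with cultured
genomes, MAGs and SAGs (the motivating system is ammonia-oxidizing
archaea, but nothing is taxon-specific). The package covers the
computations such a study chains together:

* **Orthogroups** from all-vs-all protein comparison at ≥ 50% identity
  and ≥ 50% pairwise coverage (exact local alignment, single-linkage
  components), and the orthogroup × genome presence/absence matrix.
* **Core/pan-genome rarefaction**: for each subset size *m* of *n*
  genomes, all C(*n*, *m*) = *n*!/[*m*!·(*n*−*m*)!] combinations are
  evaluated, or up to 5000 distinct random combinations when there are
  more; pan(*m*) counts orthogroups in ≥ 1 selected genome, core(*m*)
  those in all of them. A closed-form oracle
  E[pan(*m*)] = Σ_g (1 − C(*n*−*k_g*, *m*)/C(*n*, *m*)) validates the
  sampler.
* **Heaps'-law openness**: log–log least squares of
  P(N) = κ·N^γ and n_new(N) = κ′·N^(−α); α ≤ 1 calls the pan-genome
  open. Plus the average number of new orthogroups per Mbp of added
  genome over random addition orders.
* **Lineage-enriched orthogroups**: prevalent (≥ 0.8) in a focal
  lineage, absent or scarce (≤ 0.1) elsewhere.
* **Genome identity**: fragment-based ANI (ANIb dialect: 1020 bp
  fragments, BLASTn, 30%/70% retention, two-direction mean) and
  reciprocal-best-hit AAI; GC content.
* **Marker supermatrix**: best-hit marker extraction, Gblocks-style
  conserved-block trimming, partitioned concatenation.
* **Fragment recruitment**: hit filtering at ≥ 80% identity / ≥ 100 bp
  / E ≤ 1e-10, deterministic best-hit read assignment, lineage
  abundances normalized by mean lineage genome size (Mb), identity
  screens (97/95/90% cutoffs) and IUPAC primer-mismatch counting.
* **Synthetic data with ground truth**: pangenomes with a specified
  core, accessory spectrum and unique-gene rate; sequences diverged at
  an exact expected identity 1−d; read communities with known
  composition and error rate; alignments with planted conserved blocks.
  Every analysis stage is tested against these truths or an independent
  oracle.

See `vignettes/panrec-methods.Rmd` for the models, parameter defaults
and numerical conventions.

## Worked example

A synthetic 8-genome pangenome with 6 core families, a 6-family
accessory spectrum, ~2 unique genes per genome and 20% within-family
divergence, pushed through orthology and rarefaction:

```r
library(panrec)

spec <- pangenome_spec(
  n_genomes = 8, core_size = 6,
  accessory_pool = data.frame(family = sprintf("acc%d", 1:6),
                              p = c(0.2, 0.3, 0.4, 0.5, 0.6, 0.7)),
  unique_rate = 2, gene_length = 300, divergence = 0.2, seed = 11)
pg <- simulate_pangenome(spec)

hits  <- all_vs_all_hits(pg$proteins)
ogs   <- cluster_orthogroups(filter_ortho_hits(hits), pg$proteins)
M     <- build_presence_matrix(ogs, unique(pg$proteins$genome_id))
curve <- pangenome_curve(M, cap = 5000, seed = 1)
curve
#> Pan/core rarefaction: 25 orthogroups x 8 genomes (cap 5000)
#>  m pan_mean pan_sd core_mean core_sd n_combos exhaustive
#>  1   10.875 1.1659   10.8750 1.16592        8       TRUE
#>  2   13.643 1.7158    8.1071 0.67291       28       TRUE
#>  3   15.804 1.8363    7.5000 0.65465       56       TRUE
#>  4   17.771 1.8219    7.0857 0.64902       70       TRUE
#>  5   19.643 1.7053    6.7679 0.62653       56       TRUE
#>  6   21.464 1.4756    6.5000 0.56695       28       TRUE
#>  7   23.250 1.0897    6.2500 0.43301        8       TRUE
#>  8   25.000 0.0000    6.0000 0.00000        1       TRUE

fit_heaps(curve)
#> Heaps'-law fit
#>   pan:  P(N) = 10.49 * N^0.4000   (RSS 0.00506, 8 points)
#>   new:  n(N) = 3.197 * N^-0.3116  (RSS 0.0143, 7 points)
#>   pan-genome OPEN (alpha <= 1)

aai(pg$proteins[pg$proteins$genome_id == "g01", ],
    pg$proteins[pg$proteins$genome_id == "g02", ],
    name_a = "g01", name_b = "g02")
#> AAI g01 vs g02: 79.99% (support 8)
```

Reading the output: the 25 gene families the generator planted across
these 8 genomes (6 core, 6 accessory realised in subsets, 13
genome-private uniques) come back as exactly 25 orthogroups — 6 of them
fully shared, matching `core_mean` at `m = 8`, the rest the
accessory/unique tail that keeps the pan curve rising. The
fitted γ ≈ 0.4 with α < 1 calls this small pan-genome open, and the AAI
between two genomes recovers the planted 20% proteome divergence
(≈ 80% identity) from 8 reciprocal best hits.

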