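---
title: "Methods: pangenome rarefaction, genome identity and fragment recruitment"
author: "panrec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pangenome rarefaction, genome identity and fragment recruitment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panrec)
```

panrec implements the comparative-genomics computations used to
characterise a newly delineated order of ammonia-oxidizing archaea (AOA)
and, more generally, any collection of prokaryotic genomes, MAGs and
SAGs: orthogroup construction, core/pan-genome rarefaction with
Heaps'-law openness, genome identity (ANI/AAI), lineage-enriched gene
detection, marker supermatrix assembly, and competitive metagenomic
fragment recruitment with genome-size-normalized lineage abundances.
This vignette records the models, parameter choices and numerical
conventions, and what the synthetic-data generator does and does not
emulate.

## Orthogroups

Proteins are compared all-vs-all by exact local alignment
(Smith--Waterman, BLOSUM62, affine gaps: opening 10, extension 4 per
residue) behind a k-mer prefilter (`k = 4`, at least one shared k-mer;
`prefilter = FALSE` disables it). Identity is identical columns divided
by all alignment columns, *including internal gap columns*, times 100 --
the common local-alignment reporting convention; terminal overhangs are
excluded. Coverage is the aligned span over the sequence length,
computed for query and subject separately.

Hits survive at identity >= 50% and coverage >= 50% *on both sides*
(all thresholds inclusive). The literature the thresholds come from does
not say which side coverage applies to; the symmetric rule is our
choice, because one-sided coverage lets short fragments chain unrelated
full-length proteins into one cluster.

Orthogroups are the connected components of the surviving similarity
graph (single linkage). Popular orthology tools default to MCL
inflation-based clustering instead; components were chosen because they
are deterministic, parameter-free, and exactly checkable against a
brute-force transitive-closure oracle, which the test suite does for
every instance up to 50 proteins. Proteins without edges become
singleton orthogroups, so orthogroups always partition the protein set.
Orthogroup ids are assigned by each component's lexicographically
smallest member, making output order reproducible.

The internal aligner reports no E-value (we do not fabricate score
statistics); E-value thresholds apply only to imported 12-column tabular
hit files.

## Core/pan-genome rarefaction

From the orthogroup-by-genome presence/absence matrix, for every subset
size $m$ of the $n$ genomes the pan-genome is the number of orthogroups
present in at least one selected genome and the core is the number
present in all of them. There are $\binom{n}{m}$ subsets; all are
enumerated when there are at most `cap` (default 5000, applied per $m$),
otherwise `cap` *distinct* subsets are sampled uniformly without
replacement (rejection sampling on canonical keys). Sampling without
replacement guarantees consistency at the cap boundary: at
$\binom{n}{m} = \mathrm{cap}$ the sampled and exhaustive regimes
coincide. Binomial coefficients are computed exactly with an internal
base-$10^7$ big-integer running product (no floating-point overflow for
$n \le 200$), so the exhaustive/sampled decision is never corrupted by
rounding.

Per-$m$ standard deviations use the population denominator $N$: the
evaluated combination set is itself the object of interest.

The closed-form expectations
$$E[\mathrm{pan}(m)] = \sum_g \left(1 - \binom{n-k_g}{m}\Big/\binom{n}{m}\right),
\qquad
E[\mathrm{core}(m)] = \sum_g \binom{k_g}{m}\Big/\binom{n}{m},$$
with $k_g$ the number of genomes carrying orthogroup $g$, are evaluated
as running products of rational terms (never forming large binomials)
and serve as the independent oracle: exhaustive curve means must agree
to $10^{-12}$.

## Heaps' law and openness

The pan curve is fitted as $P(N) = \kappa N^{\gamma}$ and the new-gene
decay as $n_{\mathrm{new}}(N) = \kappa' N^{-\alpha}$ with
$n_{\mathrm{new}}(N) = P(N) - P(N-1)$, both by ordinary least squares on
the log-log scale -- deterministic, closed-form, and standard for
pan-genome openness analyses. Non-positive increments (possible in noisy
sampled curves) are excluded with a warning; fewer than three usable
points is an error. Following the classical criterion, $\alpha \le 1$
declares the pan-genome open.

The second openness statistic is the average number of new orthogroups
per Mbp of added genome: genomes are added in random order and each
genome after the first contributes (orthogroups unseen so far) / (its
size in Mbp); the statistic pools contributions over positions and
orders (default 100 random orders, seeded). The first genome contributes
no term -- the statistic measures what each *new* genome adds. Whether
the original analysis averaged one or many orders is not stated;
averaging is our choice and the exhaustive-permutation oracle in the
tests confirms the sampled mean converges to the order-average.

## Lineage-enriched orthogroups

"Enriched in the focal lineage but absent or scarce elsewhere" is
quantified as prevalence >= 0.8 among focal genomes and <= 0.1 among all
others (inclusive, both configurable). These two numbers are our
quantification of a qualitative phrase and are deliberately exposed as
arguments.

Completeness-based genome filtering ("over 50%") is strict at the
boundary: 50.0 is excluded. Completeness estimation itself is an
external input.

## ANI and AAI

ANI follows the ANIb fragment dialect: the query genome is cut into
consecutive 1020 bp fragments (remainder kept), each fragment is aligned
to the subject genome with BLASTn (`-task blastn -reward 1 -penalty -1
-gapopen 3 -gapextend 2 -xdrop_gap_final 150 -dust no -evalue 1e-15` --
permissive settings that keep fragment alignments full-length at
moderate divergence), and the best hit per fragment is retained when its
identity is >= 30% and it covers >= 70% of the fragment. Directional ANI
is the mean identity of retained hits; the reported value is the mean of
the two directions (both exposed), and coverage is retained aligned
bases over query length. A pair with no retained fragments yields
support 0 and an undefined (`NA`) value, not an error. Self-comparison
gives exactly 100.

AAI uses reciprocal best hits: best local alignment per protein in each
direction; mutual best pairs passing identity >= 40% and both-sided
coverage >= 0.5 (the cited tool's defaults, configurable) are RBHs, and
AAI is their mean identity. Support is the RBH count, bounded by the
smaller proteome.

GC content is $100(G+C)/(A+C+G+T)$ with ambiguous bases excluded from
numerator and denominator, reported to one decimal.

## Marker supermatrix

Marker extraction searches each reference marker against each genome's
proteins (exact local alignment) and keeps the best-scoring hit with
identity >= 30% and >= 50% coverage *of the marker reference*; ties
break by score, then protein length, then lexicographic id. Multiple
sequence alignment is an input, not reimplemented: a progressive aligner
adds nothing to the contribution this package packages.

Conserved-block selection reimplements the classical trimmer's column
classification, fully specified here because the original binary's edge
handling has undocumented corner cases: a column with any gap is
nonconserved (`gaps = none` behaviour); otherwise with $c$ the count of
the most frequent residue, $c < IS$ is nonconserved, $c \ge FS$ highly
conserved, else conserved. Defaults: $IS = \lfloor n/2\rfloor + 1$,
$FS = \lceil 0.85\,n\rceil$, maximum nonconserved run $CP = 8$, minimum
block length $BL = 10$, fewer than 4 sequences is an error. Runs of more
than $CP$ nonconserved columns are rejected and split the alignment;
each candidate block is trimmed to its outermost *highly conserved*
columns; blocks shorter than $BL$ are dropped. Selection is idempotent
on its own output.

Concatenation joins each marker's kept columns in sorted marker order,
gap-fills genomes absent from a marker, drops genomes missing more than
half of the total columns (configurable), and emits a 1-based inclusive
partition table that must tile the supermatrix exactly (asserted).
Downstream likelihood inference, model selection and bootstrapping are
out of scope.

## Fragment recruitment

Recruitment hit filtering keeps identity >= 80%, alignment length >=
100 bp, E-value <= 1e-10 (all inclusive). "100 bp coverage" is read as a
minimum alignment length in bp -- the natural reading of a read-mapping
filter -- not a fraction; it is configurable. Each read is assigned to
the subject of its single best hit, ranked by bitscore, then E-value,
then identity, then lexicographic subject id; determinism was preferred
over random tie-breaking for reproducibility. Lineage counts are
normalized by the mean genome size (Mb) over *all database genomes* of
the lineage (not the per-sample detected ones -- our documented reading)
and relative abundances are the normalized values rescaled to sum to 1.

Identity screens assign a query its best reference's lineage when the
best local alignment reaches the cutoff (inclusive): 97% for amplicon
screens, 95%/90% for 16S/amoA database screens in the original use.
Internal screening is nucleotide-level. Degenerate-primer mismatch
counting treats a position as matching when the template base falls in
the primer position's IUPAC set; reverse primers are compared after
reverse-complementation, and a sliding search exposes the best window.

## The synthetic-data generator

The generator stands in for the study-scale genome and metagenome
downloads, producing inputs with *known ground truth*:

* **Pangenomes** -- core families in every genome, accessory families
  present independently with per-family probabilities (optionally
  restricted to a genome subset, which is how lineage-specific families
  are planted), and per-genome Poisson-distributed unique genes drawn as
  fresh random sequences, whose expected identity to anything else is
  alphabet background and therefore far below the 50% clustering
  threshold. Genome sequences are the genes joined by short random
  spacers, so genome sizes used in normalization come from the actual
  sequences.
* **Divergence** -- point substitutions only, each hit position changed
  to a uniformly chosen *different* residue, so expected identity is
  exactly $1-d$ with no back-substitution algebra. The pangenome spec's
  `divergence` is the expected *pairwise* divergence between family
  members; the per-member rate $x$ is derived from
  $(1-x)^2 + x^2/(k-1) = 1-d$ (alphabet size $k$), so recovery targets
  for ANI/AAI/orthology are exact.
* **Read communities** -- sources drawn from a stated composition,
  uniform starts, forward strand, per-base substitution errors.
* **Marker alignments** -- planted blocks are gap-free and unanimous;
  outside columns carry random residues and gaps (default rate 0.5).
  Blocks separated by fewer than $CP+1$ columns merge during selection
  by design, so recovery fixtures plant blocks further apart.

All generators are pure functions of (spec, seed): the global RNG state
is saved and restored, and equal seeds give byte-identical output.

What the generator does *not* emulate -- and hence what green tests do
not certify about real data: indels and rearrangements, codon structure
and GC skew, paralogy and horizontal transfer inside families,
non-uniform read sampling, chimeric reads, and assembly artefacts. The
recovery results (e.g. ANI within 0.5 of $100(1-d)$) are statements
about the substitution-only regime.

## Problem sizes and numerical conventions

The test suite and the acceptance script run at desk scale, chosen so
the complete battery finishes in a few minutes while keeping every
statistical check at three-sigma binomial resolution: 20 replicate
30-orthogroup x 8-genome matrices for the rarefaction oracle; 20
replicate 30-genome synthetic pangenomes (~400 families) for Heaps
recovery, with the sampled curve capped at a few hundred combinations
per $m$; 200 kb genome pairs at $d \in \{0, 0.05, 0.1, 0.2\}$ for ANI;
15-protein proteomes for AAI; 10 000-read communities for recruitment;
50 random fixtures for block recovery.

Degenerate inputs are handled explicitly: empty FASTA files and empty
sequences are errors naming the record; a presence matrix with a
genome-less orthogroup cannot arise (orthogroups partition proteins); an
ANI/AAI pair with no support returns a flagged undefined value; an empty
supermatrix is an error; rejection sampling of combinations remains
exact at the cap boundary because the binomial decision is exact.

## Known limitations

Single-linkage components can chain two families through one spurious
bridge hit where MCL would split them; counts of orthogroups on real
data are therefore not expected to match inflation-based tools.
The BLASTn-based ANI inherits the slight upward identity bias of
best-HSP trimming (about +0.1--0.2 at $d = 0.2$), visible in but within
the tolerance of the recovery checks. The recruitment module consumes
any 12-column hit table but performs no protein-level search of its
own; whether identity in the original protein-vs-genome mapping was
amino-acid- or nucleotide-level is ambiguous, and internal screening
here is nucleotide-level. Fragment recruitment against references closer
than ~85% ANI becomes ambiguous and is not modelled.
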