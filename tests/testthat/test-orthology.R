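proteins_df <- function(seqs, genomes = NULL) {
  if (is.null(genomes)) genomes <- sprintf("G%d", seq_along(seqs))
  data.frame(gene_id = names(seqs), genome_id = genomes,
             seq = unname(seqs), stringsAsFactors = FALSE)
}

test_that("identical proteins align at 100% identity and full coverage", {
  set.seed(21)
  s <- random_protein(100)
  h <- all_vs_all_hits(proteins_df(c(p1 = s, p2 = s)))
  expect_equal(nrow(h), 1)
  expect_equal(h$pident, 100)
  expect_equal(h$qcov, 1)
  expect_equal(h$scov, 1)
  expect_true(is.na(h$evalue))  # internal aligner reports no E-value
})

test_that("the k-mer prefilter suppresses pairs sharing no k-mers", {
  # disjoint alphabets guarantee zero shared 4-mers
  a <- paste(rep("ACDEF", 10), collapse = "")
  b <- paste(rep("GHIKL", 10), collapse = "")
  h <- all_vs_all_hits(proteins_df(c(p1 = a, p2 = b)))
  expect_equal(nrow(h), 0)
  expect_error(all_vs_all_hits(proteins_df(c(p1 = a, p2 = ""))),
               "empty sequence")
})

test_that("alignment scores match the exhaustive DP oracle", {
  set.seed(22)
  sm <- blosum62()
  # constructed pair sharing a 60-aa exact repeat inside 120-aa sequences
  core <- random_protein(60)
  a <- paste0(random_protein(30), core, random_protein(30))
  b <- paste0(random_protein(30), core, random_protein(30))
  h <- all_vs_all_hits(proteins_df(c(p1 = a, p2 = b)), prefilter = FALSE)
  expect_equal(nrow(h), 1)
  expect_gte(h$length, 60)
  expect_gte(h$qcov, 0.5)
  expect_gte(h$scov, 0.5)
  expect_equal(h$bitscore, sw_score_oracle(a, b, sm))

  # random pairs, scores equal the DP oracle exactly
  for (i in 1:5) {
    x <- random_protein(sample(40:80, 1))
    y0 <- random_protein(sample(40:80, 1))
    y <- paste0(substr(x, 10, 35), y0)  # share a region so a hit exists
    h <- all_vs_all_hits(proteins_df(c(p1 = x, p2 = y)), prefilter = FALSE)
    if (nrow(h) == 1)
      expect_equal(h$bitscore, sw_score_oracle(x, y, sm))
  }
})

test_that("orthology filter enforces inclusive 50/50 thresholds both-sided", {
  base <- all_vs_all_hits(proteins_df(c(p1 = "MKVLATGW", p2 = "MKVLATGW")))
  mk <- function(pident, qcov, scov) {
    h <- base
    h$pident <- pident; h$qcov <- qcov; h$scov <- scov
    h
  }
  expect_equal(nrow(filter_ortho_hits(mk(49.9, 0.9, 0.9))), 0)
  expect_equal(nrow(filter_ortho_hits(mk(50.0, 0.5, 0.5))), 1)
  expect_equal(nrow(filter_ortho_hits(mk(90, 0.4, 0.9))), 0)
  expect_equal(nrow(filter_ortho_hits(mk(90, 0.9, 0.4))), 0)
})

test_that("clustering is single-linkage over the surviving graph", {
  prot <- proteins_df(c(p1 = "AAAA", p2 = "AAAA", p3 = "AAAA", p4 = "CCCC"),
                      genomes = c("g1", "g2", "g3", "g1"))
  hits <- data.frame(qseqid = c("p1", "p2"), sseqid = c("p2", "p3"))
  ogs <- cluster_orthogroups(hits, prot)
  expect_setequal(unique(ogs$og_id), c("OG00001", "OG00002"))
  expect_equal(canonical_partition(split(ogs$gene_id, ogs$og_id)),
               c("p1,p2,p3", "p4"))

  # no edges at all -> all singletons
  ogs <- cluster_orthogroups(hits[0, ], prot)
  expect_equal(length(unique(ogs$og_id)), 4)

  expect_error(cluster_orthogroups(
    data.frame(qseqid = "p1", sseqid = "zz"), prot), "unknown protein")
})

test_that("clustering equals the brute-force transitive-closure oracle", {
  set.seed(23)
  for (rep in 1:10) {
    n <- sample(5:20, 1)
    ids <- sprintf("p%02d", 1:n)
    prot <- proteins_df(setNames(replicate(n, random_protein(30)), ids))
    n_edges <- sample(0:(2 * n), 1)
    edges <- data.frame(qseqid = sample(ids, n_edges, replace = TRUE),
                        sseqid = sample(ids, n_edges, replace = TRUE))
    edges <- edges[edges$qseqid != edges$sseqid, , drop = FALSE]
    ogs <- cluster_orthogroups(edges, prot)
    expect_equal(canonical_partition(split(ogs$gene_id, ogs$og_id)),
                 closure_partition(ids, edges))
  }
})

test_that("raising the identity threshold only splits orthogroups", {
  set.seed(24)
  pg <- simulate_pangenome(pangenome_spec(4, 5, unique_rate = 1,
                                          gene_length = 300,
                                          divergence = 0.3, seed = 31))
  hits <- all_vs_all_hits(pg$proteins)
  part_of <- function(min_id) {
    ogs <- cluster_orthogroups(filter_ortho_hits(hits, min_id), pg$proteins)
    split(ogs$gene_id, ogs$og_id)
  }
  loose <- part_of(50)
  strict <- part_of(70)
  # every strict cluster is contained in some loose cluster (refinement)
  for (s in strict) {
    container <- Filter(function(l) all(s %in% l), loose)
    expect_length(container, 1)
  }
})

test_that("planted families are recovered exactly from diverged proteomes", {
  pg <- simulate_pangenome(pangenome_spec(5, 3, unique_rate = 1,
                                          gene_length = 300,
                                          divergence = 0.2, seed = 32))
  hits <- all_vs_all_hits(pg$proteins)
  ogs <- cluster_orthogroups(filter_ortho_hits(hits), pg$proteins)
  truth <- split(pg$truth$gene_table$gene_id, pg$truth$gene_table$family)
  expect_equal(canonical_partition(split(ogs$gene_id, ogs$og_id)),
               canonical_partition(truth))
  # partition property
  expect_equal(sort(ogs$gene_id), sort(pg$proteins$gene_id))
})

test_that("presence matrix reflects orthogroup occupancy", {
  ogs <- data.frame(og_id = c("OG1", "OG1", "OG2"),
                    gene_id = c("p1", "p2", "p3"),
                    genome_id = c("g1", "g2", "g1"))
  m <- build_presence_matrix(ogs, c("g1", "g2", "g3"))
  expect_equal(unname(m["OG1", ]), c(1L, 1L, 0L))
  expect_equal(sum(m["OG2", ]), 1)
  # conservation: total cells = sum of distinct genomes per orthogroup
  expect_equal(sum(m), 3)
  expect_error(build_presence_matrix(ogs, c("g1", "g3")), "not in genome_ids")
})
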