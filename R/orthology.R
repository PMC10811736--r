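# Orthogroup construction: all-vs-all protein comparison, the 50% identity /
# 50% pairwise-coverage filter, single-linkage graph clustering, and the
# presence/absence matrix that all pangenome statistics consume.

#' All-vs-all local protein alignment
#'
#' Computes the optimal local alignment for every unordered protein pair
#' that shares at least `min_kmer_shared` k-mers (the prefilter; disable
#' with `prefilter = FALSE` to force full all-vs-all). Self-hits are
#' excluded. Identity is identical columns / alignment columns (internal
#' gaps included) x 100; coverages are the aligned span divided by each
#' sequence's length. The internal aligner reports no E-value (`NA`);
#' E-value thresholds apply only to imported tabular hit files.
#'
#' @param proteins data.frame with columns `gene_id`, `genome_id`, `seq`
#'   (amino-acid); gene ids must be unique across the collection.
#' @param min_kmer_shared Minimum shared k-mers for a pair to be aligned.
#' @param k k-mer size for the prefilter.
#' @param prefilter Set `FALSE` to align every pair.
#' @return Hit data.frame (one row per aligned unordered pair, query =
#'   the earlier protein in input order) with the 12 standard hit columns
#'   plus `qcov`, `scov`.
#' @export
all_vs_all_hits <- function(proteins, min_kmer_shared = 1L, k = 4L,
                            prefilter = TRUE) {
  if (!is.data.frame(proteins) ||
      !all(c("gene_id", "genome_id", "seq") %in% names(proteins)))
    stop("proteins must have columns gene_id, genome_id, seq")
  if (nrow(proteins) < 2L) stop("need at least 2 proteins")
  if (anyDuplicated(proteins$gene_id))
    stop("duplicate gene_id: ",
         proteins$gene_id[anyDuplicated(proteins$gene_id)])
  if (any(!nzchar(proteins$seq))) {
    bad <- proteins$gene_id[!nzchar(proteins$seq)][1]
    stop("empty sequence for protein ", bad)
  }
  n <- nrow(proteins)
  sets <- if (prefilter) .kmer_sets(proteins$seq, k) else NULL
  out <- vector("list", n)
  for (j in 2:n) {
    cand <- seq_len(j - 1L)
    if (prefilter)
      cand <- cand[vapply(cand, function(i)
        .shared_kmers(sets[[i]], sets[[j]]) >= min_kmer_shared, logical(1))]
    if (length(cand) == 0L) next
    h <- .align_local(proteins$seq[cand], proteins$seq[j], "protein")
    h <- data.frame(qseqid = proteins$gene_id[cand],
                    sseqid = proteins$gene_id[j],
                    h[c("pident", "length", "mismatch", "gapopen",
                        "qstart", "qend", "sstart", "send")],
                    evalue = NA_real_, bitscore = h$score,
                    qcov = h$qcov, scov = h$scov,
                    stringsAsFactors = FALSE)
    out[[j]] <- h
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L) {
    h <- .empty_hits()
    h$qcov <- h$scov <- numeric(0)
    return(h)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Filter hits for orthogroup construction
#'
#' Keeps hits with identity >= `min_identity` percent and coverage >=
#' `min_coverage` percent on *both* query and subject (thresholds
#' inclusive). The both-sided coverage rule prevents short fragments from
#' chaining unrelated full-length proteins.
#'
#' @param hits Hit data.frame carrying `qcov` and `scov` (fractions).
#' @param min_identity Percent identity threshold (default 50).
#' @param min_coverage Percent coverage threshold applied to both sides
#'   (default 50).
#' @return The surviving subset, same columns.
#' @export
filter_ortho_hits <- function(hits, min_identity = 50, min_coverage = 50) {
  if (!all(c("qcov", "scov") %in% names(hits)))
    stop("hits must carry qcov and scov columns")
  keep <- hits$pident >= min_identity &
    hits$qcov >= min_coverage / 100 &
    hits$scov >= min_coverage / 100
  hits[keep, , drop = FALSE]
}

#' Cluster proteins into orthogroups
#'
#' Single-linkage clustering: orthogroups are the connected components of
#' the undirected graph whose edges are the surviving hits (either
#' direction). Proteins with no edges form singleton orthogroups, so the
#' orthogroups always partition the protein set. Orthogroup ids are
#' assigned deterministically in order of each component's
#' lexicographically smallest member.
#'
#' @param hits Filtered hit data.frame (see [filter_ortho_hits()]).
#' @param proteins The full protein data.frame (`gene_id`, `genome_id`,
#'   `seq`); every hit must reference a known protein.
#' @return data.frame with columns `og_id`, `gene_id`, `genome_id`.
#' @export
cluster_orthogroups <- function(hits, proteins) {
  ids <- proteins$gene_id
  unknown <- setdiff(unique(c(hits$qseqid, hits$sseqid)), ids)
  if (length(unknown))
    stop("hit references unknown protein: ", unknown[1])
  g <- igraph::graph_from_data_frame(
    hits[, c("qseqid", "sseqid"), drop = FALSE],
    directed = FALSE, vertices = data.frame(name = ids))
  comp <- igraph::components(g)$membership
  members <- split(names(comp), comp)
  members <- members[order(vapply(members, min, ""))]
  og_ids <- sprintf("OG%05d", seq_along(members))
  df <- data.frame(
    og_id = rep(og_ids, lengths(members)),
    gene_id = unlist(members, use.names = FALSE),
    stringsAsFactors = FALSE)
  df$genome_id <- proteins$genome_id[match(df$gene_id, ids)]
  df <- df[order(df$og_id, df$gene_id), ]
  rownames(df) <- NULL
  df
}

#' Build the orthogroup presence/absence matrix
#'
#' @param orthogroups Membership data.frame from [cluster_orthogroups()]
#'   (`og_id`, `gene_id`, `genome_id`).
#' @param genome_ids All genomes the matrix should cover (columns);
#'   genomes with no genes yield all-zero columns are not allowed -- every
#'   membership genome must be listed, but listed genomes may be empty.
#' @return Integer 0/1 matrix, orthogroup rows x genome columns, both
#'   sorted; cell 1 iff the orthogroup has >= 1 member in that genome.
#' @export
build_presence_matrix <- function(orthogroups, genome_ids) {
  missing <- setdiff(unique(orthogroups$genome_id), genome_ids)
  if (length(missing))
    stop("orthogroup references genome not in genome_ids: ", missing[1])
  ogs <- sort(unique(orthogroups$og_id))
  gs <- sort(genome_ids)
  m <- matrix(0L, length(ogs), length(gs), dimnames = list(ogs, gs))
  m[cbind(match(orthogroups$og_id, ogs),
          match(orthogroups$genome_id, gs))] <- 1L
  m
}
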