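# Pairwise genome identity: fragment-based ANI (ANIb dialect, BLASTn
# engine) and reciprocal-best-hit AAI, plus GC content.

#' Cut a genome into consecutive fragments
#'
#' Non-overlapping fragments of `fragment_length` bp per contig, final
#' shorter remainder kept; concatenating the fragments reproduces the
#' input. 1020 bp is the classical ANIb fragment size.
#'
#' @param genome Sequence-record data.frame (one row per contig) or a
#'   named character vector.
#' @param fragment_length Fragment size in bp (default 1020).
#' @return data.frame with columns `id` (`<contig>_frag<k>`), `contig`,
#'   `start`, `end` (0-based half-open source coordinates), `seq`.
#' @export
fragment_genome <- function(genome, fragment_length = 1020L) {
  genome <- .as_records(genome, "genome")
  if (!.is_count(fragment_length) || fragment_length < 1)
    stop("fragment_length must be >= 1")
  out <- lapply(seq_len(nrow(genome)), function(i) {
    len <- nchar(genome$seq[i])
    starts <- seq(0L, len - 1L, by = fragment_length)
    ends <- pmin(starts + fragment_length, len)
    data.frame(id = sprintf("%s_frag%d", genome$id[i], seq_along(starts)),
               contig = genome$id[i], start = starts, end = ends,
               seq = substring(genome$seq[i], starts + 1L, ends),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# ---- BLAST+ plumbing -------------------------------------------------------

.require_tool <- function(tool) {
  path <- Sys.which(tool)
  if (!nzchar(path))
    stop("external tool '", tool, "' not found on PATH ",
         "(NCBI BLAST+ is required for this operation)")
  path
}

.make_blast_db <- function(records, dbtype = "nucl") {
  .require_tool("makeblastdb")
  fa <- tempfile(fileext = ".fa")
  write_fasta(records, fa)
  db <- tempfile()
  out <- system2(Sys.which("makeblastdb"),
                 c("-in", fa, "-dbtype", dbtype, "-out", db),
                 stdout = TRUE, stderr = TRUE)
  if (!is.null(attr(out, "status")))
    stop("makeblastdb failed: ", paste(out, collapse = "\n"))
  db
}

.run_blastn <- function(query_records, db, extra = character(0)) {
  .require_tool("blastn")
  qf <- tempfile(fileext = ".fa")
  write_fasta(query_records, qf)
  of <- tempfile(fileext = ".tsv")
  out <- system2(Sys.which("blastn"),
                 c("-query", qf, "-db", db, "-outfmt", "6", "-out", of,
                   extra),
                 stdout = TRUE, stderr = TRUE)
  if (!is.null(attr(out, "status")))
    stop("blastn failed: ", paste(out, collapse = "\n"))
  if (file.size(of) == 0) return(.empty_hits())
  read_hits_table(of)
}

# ANIb-style blastn settings: permissive extension through mismatches so
# fragment alignments stay full-length at moderate divergence.
.ANIB_BLASTN_OPTS <- c("-task", "blastn", "-reward", "1", "-penalty", "-1",
                       "-gapopen", "3", "-gapextend", "2",
                       "-xdrop_gap_final", "150", "-dust", "no",
                       "-evalue", "1e-15")

# Best hit per query: bitscore desc, evalue asc, pident desc, subject lex.
.best_hit_per_query <- function(hits) {
  if (nrow(hits) == 0L) return(hits)
  o <- order(hits$qseqid, -hits$bitscore, hits$evalue, -hits$pident,
             hits$sseqid)
  h <- hits[o, , drop = FALSE]
  h[!duplicated(h$qseqid), , drop = FALSE]
}

.ani_one_direction <- function(genome_q, genome_s, fragment_length,
                               min_frag_identity, min_frag_coverage) {
  frags <- fragment_genome(genome_q, fragment_length)
  db <- .make_blast_db(genome_s, "nucl")
  hits <- .run_blastn(frags, db, .ANIB_BLASTN_OPTS)
  best <- .best_hit_per_query(hits)
  if (nrow(best)) {
    flen <- nchar(frags$seq)[match(best$qseqid, frags$id)]
    span <- best$qend - best$qstart + 1
    keep <- best$pident >= min_frag_identity &
      span / flen >= min_frag_coverage
    best <- best[keep, , drop = FALSE]
    span <- span[keep]
  } else span <- numeric(0)
  list(ani = if (nrow(best)) mean(best$pident) else NA_real_,
       coverage = sum(span) / sum(nchar(genome_q$seq)),
       support = nrow(best))
}

#' Fragment-based average nucleotide identity (ANIb)
#'
#' The query genome is cut into 1020 bp fragments, each fragment is
#' aligned to the subject genome with BLASTn (permissive ANIb settings),
#' and the best hit per fragment is retained when its identity is at
#' least `min_frag_identity` percent and it covers at least
#' `min_frag_coverage` of the fragment. ANI in one direction is the mean
#' identity of retained hits; the reported value is the mean of the two
#' directions. Coverage is the retained aligned bases divided by the
#' query genome length.
#'
#' @param genome_a,genome_b Sequence-record data.frames (contigs).
#' @param name_a,name_b Genome labels for the result.
#' @param fragment_length Fragment size in bp (default 1020).
#' @param min_frag_identity Fragment identity threshold, percent
#'   (default 30).
#' @param min_frag_coverage Fragment coverage threshold, fraction
#'   (default 0.7).
#' @return Object of class `pairwise_identity` with elements `value`
#'   (two-direction mean, `NA` when no fragment is retained in either
#'   direction), `ani_ab`, `ani_ba`, `coverage_ab`, `coverage_ba`,
#'   `support` (total retained fragments, with per-direction breakdown).
#' @export
anib <- function(genome_a, genome_b, name_a = "genome_a",
                 name_b = "genome_b", fragment_length = 1020L,
                 min_frag_identity = 30, min_frag_coverage = 0.7) {
  genome_a <- .as_records(genome_a, "genome_a")
  genome_b <- .as_records(genome_b, "genome_b")
  ab <- .ani_one_direction(genome_a, genome_b, fragment_length,
                           min_frag_identity, min_frag_coverage)
  ba <- .ani_one_direction(genome_b, genome_a, fragment_length,
                           min_frag_identity, min_frag_coverage)
  vals <- c(ab$ani, ba$ani)
  structure(list(genome_a = name_a, genome_b = name_b, metric = "ANI",
                 value = if (all(is.na(vals))) NA_real_ else
                   mean(vals, na.rm = TRUE),
                 ani_ab = ab$ani, ani_ba = ba$ani,
                 coverage_ab = ab$coverage, coverage_ba = ba$coverage,
                 support = ab$support + ba$support,
                 support_ab = ab$support, support_ba = ba$support),
            class = "pairwise_identity")
}

#' Reciprocal-best-hit average amino-acid identity
#'
#' Every protein of each proteome is locally aligned against the other
#' proteome (exact Smith-Waterman with a k-mer prefilter); a protein pair
#' is a reciprocal best hit (RBH) when each is the other's best-scoring
#' hit and the alignment passes the identity and (both-sided) coverage
#' thresholds. AAI is the mean identity over RBHs.
#'
#' @param proteome_a,proteome_b Sequence-record data.frames (or protein
#'   tables with a `gene_id` column).
#' @param name_a,name_b Genome labels.
#' @param min_identity Percent identity threshold (default 40).
#' @param min_coverage Coverage threshold, fraction, applied to both
#'   proteins (default 0.5).
#' @param k Prefilter k-mer size.
#' @return Object of class `pairwise_identity` with `value` (`NA` when
#'   there are no RBHs), `coverage_ab`/`coverage_ba` (mean RBH coverage
#'   per side), `support` (RBH count) and the RBH pair table `rbh`.
#' @export
aai <- function(proteome_a, proteome_b, name_a = "genome_a",
                name_b = "genome_b", min_identity = 40, min_coverage = 0.5,
                k = 4L) {
  norm <- function(p, what) {
    if (is.data.frame(p) && "gene_id" %in% names(p) && !("id" %in% names(p)))
      p$id <- p$gene_id
    .as_records(p, what)
  }
  pa <- norm(proteome_a, "proteome_a")
  pb <- norm(proteome_b, "proteome_b")
  sets_a <- .kmer_sets(pa$seq, k)
  sets_b <- .kmer_sets(pb$seq, k)
  # hits[i, j]: alignment of a-protein i against b-protein j
  best <- function(px, sets_x, py, sets_y) {
    res <- vector("list", nrow(px))
    for (j in seq_len(nrow(py))) {
      cand <- which(vapply(sets_x, function(s)
        .shared_kmers(s, sets_y[[j]]) >= 1L, logical(1)))
      if (length(cand) == 0L) next
      h <- .align_local(px$seq[cand], py$seq[j], "protein")
      for (ii in seq_along(cand)) {
        i <- cand[ii]
        if (is.null(res[[i]]) || h$score[ii] > res[[i]]$score ||
            (h$score[ii] == res[[i]]$score && py$id[j] < res[[i]]$id))
          res[[i]] <- list(id = py$id[j], score = h$score[ii],
                           pident = h$pident[ii], qcov = h$qcov[ii],
                           scov = h$scov[ii])
      }
    }
    res
  }
  ab <- best(pa, sets_a, pb, sets_b)
  ba <- best(pb, sets_b, pa, sets_a)
  names(ab) <- pa$id
  names(ba) <- pb$id
  rbh <- list()
  for (i in seq_len(nrow(pa))) {
    h <- ab[[i]]
    if (is.null(h)) next
    back <- ba[[h$id]]
    if (is.null(back) || back$id != pa$id[i]) next
    if (h$pident < min_identity || h$qcov < min_coverage ||
        h$scov < min_coverage) next
    rbh[[length(rbh) + 1L]] <- data.frame(
      protein_a = pa$id[i], protein_b = h$id, pident = h$pident,
      cov_a = h$qcov, cov_b = h$scov, stringsAsFactors = FALSE)
  }
  rbh <- if (length(rbh)) do.call(rbind, rbh) else
    data.frame(protein_a = character(0), protein_b = character(0),
               pident = numeric(0), cov_a = numeric(0), cov_b = numeric(0))
  structure(list(genome_a = name_a, genome_b = name_b, metric = "AAI",
                 value = if (nrow(rbh)) mean(rbh$pident) else NA_real_,
                 coverage_ab = if (nrow(rbh)) mean(rbh$cov_a) else NA_real_,
                 coverage_ba = if (nrow(rbh)) mean(rbh$cov_b) else NA_real_,
                 support = nrow(rbh), rbh = rbh),
            class = "pairwise_identity")
}

#' @export
print.pairwise_identity <- function(x, ...) {
  val <- if (is.na(x$value)) "undefined (no support)" else
    sprintf("%.2f%%", x$value)
  cat(sprintf("%s %s vs %s: %s (support %d)\n", x$metric, x$genome_a,
              x$genome_b, val, x$support))
  invisible(x)
}

#' GC content of a nucleotide sequence
#'
#' `100 * (G + C) / (A + C + G + T)`; ambiguous bases are excluded from
#' both numerator and denominator. Reported to one decimal.
#'
#' @param genome Sequence-record data.frame, named character vector, or a
#'   single sequence string (all contigs are pooled).
#' @return GC percentage, rounded to 1 decimal.
#' @export
gc_content <- function(genome) {
  seqs <- if (is.character(genome) && is.null(names(genome)) &&
              length(genome) == 1L) genome else .as_records(genome)$seq
  chars <- unlist(strsplit(seqs, "", fixed = TRUE))
  n_gc <- sum(chars %in% c("G", "C"))
  n_at <- sum(chars %in% c("A", "T"))
  if (n_gc + n_at == 0L) stop("no unambiguous bases in sequence")
  round(100 * n_gc / (n_gc + n_at), 1)
}
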