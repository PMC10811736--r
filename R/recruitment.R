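# Competitive fragment recruitment: hit filtering, best-hit read
# assignment, genome-size-normalized lineage abundances, identity screens
# against marker references, and degenerate-primer mismatch counting.

#' Filter fragment-recruitment hits
#'
#' Keeps hits with identity >= `min_identity` percent, alignment length
#' >= `min_align_len` bp and E-value <= `max_evalue` (all thresholds
#' inclusive). "100 bp coverage" is read as a minimum alignment length in
#' bp, the natural reading for a read-mapping filter.
#'
#' @param hits Hit data.frame ([read_hits_table()] columns).
#' @param min_identity Percent identity (default 80).
#' @param min_align_len Minimum alignment length in bp (default 100).
#' @param max_evalue Maximum E-value (default 1e-10).
#' @return The surviving subset. Idempotent.
#' @export
filter_recruitment_hits <- function(hits, min_identity = 80,
                                    min_align_len = 100,
                                    max_evalue = 1e-10) {
  keep <- hits$pident >= min_identity &
    hits$length >= min_align_len &
    hits$evalue <= max_evalue
  hits[keep, , drop = FALSE]
}

#' Competitively assign reads to genomes
#'
#' Each read goes to the subject of its single best surviving hit,
#' ranked by bitscore (desc), then E-value (asc), then identity (desc),
#' then lexicographic subject id -- a fully deterministic tie-break.
#'
#' @param hits Filtered hit data.frame; query ids are read ids, subject
#'   ids are genome ids.
#' @param read_ids Optional vector of all read ids; reads without hits
#'   are then reported with `genome_id = NA` (unassigned).
#' @return data.frame with columns `read_id`, `genome_id`.
#' @export
competitive_assign <- function(hits, read_ids = NULL) {
  best <- .best_hit_per_query(hits)
  out <- data.frame(read_id = best$qseqid, genome_id = best$sseqid,
                    stringsAsFactors = FALSE)
  if (!is.null(read_ids)) {
    missing <- setdiff(read_ids, out$read_id)
    if (length(missing))
      out <- rbind(out, data.frame(read_id = missing,
                                   genome_id = NA_character_))
    out <- out[match(read_ids, out$read_id), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Genome-size-normalized lineage abundances
#'
#' Assigned reads are aggregated per lineage; each lineage's count is
#' normalized by the mean genome size in Mb over *all database genomes*
#' of that lineage (not only the genomes hit), and relative abundances
#' are the normalized values rescaled to sum to 1.
#'
#' @param assignments data.frame from [competitive_assign()]; `NA`
#'   genome ids count as unassigned.
#' @param lineage_map data.frame from [read_lineage_map()] covering every
#'   assigned genome.
#' @return Object of class `recruitment_profile`: `per_genome` (counts),
#'   `per_lineage` (data.frame `lineage`, `reads`, `mean_genome_mb`,
#'   `per_mb`, `relative`, `read_fraction`), `n_assigned`, `n_unassigned`.
#' @export
lineage_abundance <- function(assignments, lineage_map) {
  assigned <- assignments[!is.na(assignments$genome_id), , drop = FALSE]
  unknown <- setdiff(unique(assigned$genome_id), lineage_map$genome_id)
  if (length(unknown))
    stop("assigned genome missing from lineage map: ", unknown[1])
  per_genome <- table(assigned$genome_id)
  lin_of <- setNames(lineage_map$lineage, lineage_map$genome_id)
  lins <- sort(unique(lineage_map$lineage))
  reads <- vapply(lins, function(l)
    sum(per_genome[names(per_genome) %in%
                     lineage_map$genome_id[lineage_map$lineage == l]]),
    numeric(1))
  mean_mb <- vapply(lins, function(l)
    mean(lineage_map$genome_size_bp[lineage_map$lineage == l]) / 1e6,
    numeric(1))
  per_mb <- reads / mean_mb
  relative <- if (sum(per_mb) > 0) per_mb / sum(per_mb) else
    rep(NA_real_, length(lins))
  read_fraction <- if (nrow(assigned) > 0) reads / nrow(assigned) else
    rep(NA_real_, length(lins))
  structure(list(
    per_genome = as.data.frame(per_genome, responseName = "reads",
                               stringsAsFactors = FALSE),
    per_lineage = data.frame(lineage = lins, reads = unname(reads),
                             mean_genome_mb = unname(mean_mb),
                             per_mb = unname(per_mb),
                             relative = unname(relative),
                             read_fraction = unname(read_fraction),
                             stringsAsFactors = FALSE),
    n_assigned = nrow(assigned),
    n_unassigned = sum(is.na(assignments$genome_id))),
    class = "recruitment_profile")
}

#' @export
print.recruitment_profile <- function(x, ...) {
  cat(sprintf("Recruitment profile: %d assigned, %d unassigned reads\n",
              x$n_assigned, x$n_unassigned))
  print.data.frame(x$per_lineage, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Screen query sequences against lineage-labeled references
#'
#' Each query is locally aligned (nucleotide level) against every
#' reference; the best-scoring alignment decides the assignment: the
#' reference's lineage when its identity is at least `min_identity`
#' percent (inclusive), otherwise `"unassigned"`.
#'
#' @param queries Sequence-record data.frame of query sequences.
#' @param references Sequence-record data.frame of reference genes
#'   (non-empty).
#' @param ref_lineages Named character vector: reference id -> lineage.
#' @param min_identity Percent identity threshold (e.g. 97 for 16S
#'   amplicon screens, 95/90 for 16S/amoA database screens).
#' @return data.frame with columns `query_id`, `best_reference`,
#'   `identity`, `lineage`, `threshold`.
#' @export
screen_sequences <- function(queries, references, ref_lineages,
                             min_identity) {
  queries <- .as_records(queries, "queries")
  references <- .as_records(references, "references")
  if (nrow(references) == 0L) stop("empty reference set")
  if (!all(references$id %in% names(ref_lineages)))
    stop("every reference needs a lineage label")
  if (min_identity <= 0 || min_identity > 100)
    stop("min_identity must be in (0, 100]")
  out <- lapply(seq_len(nrow(queries)), function(qi) {
    h <- .align_local(references$seq, queries$seq[qi], "dna")
    o <- order(-h$score, references$id)
    b <- o[1]
    id <- h$pident[b]
    data.frame(query_id = queries$id[qi],
               best_reference = references$id[b],
               identity = id,
               lineage = if (id >= min_identity)
                 unname(ref_lineages[references$id[b]]) else "unassigned",
               threshold = min_identity, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Map reads against a genome database with BLASTn
#'
#' Convenience wrapper producing the 12-column hit table the recruitment
#' filters consume: builds a BLAST database from the reference genomes
#' (subject ids are the record ids) and searches the reads with
#' `blastn -task blastn -outfmt 6`.
#'
#' @param reads Sequence-record data.frame of reads.
#' @param genomes Sequence-record data.frame of reference genome
#'   sequences.
#' @param max_target_seqs Hits kept per read before competitive
#'   assignment (default 25).
#' @return Hit data.frame as from [read_hits_table()].
#' @export
map_reads_blastn <- function(reads, genomes, max_target_seqs = 25L) {
  reads <- .as_records(reads, "reads")
  genomes <- .as_records(genomes, "genomes")
  db <- .make_blast_db(genomes, "nucl")
  .run_blastn(reads, db, c("-task", "blastn", "-dust", "no",
                           "-max_target_seqs",
                           as.character(max_target_seqs)))
}

# IUPAC nucleotide sets, primer position -> allowed target bases
.iupac_set <- function(code) {
  map <- Biostrings::IUPAC_CODE_MAP
  if (!code %in% names(map)) stop("not an IUPAC nucleotide code: ", code)
  strsplit(map[[code]], "", fixed = TRUE)[[1]]
}

#' Count primer-template mismatches under IUPAC degeneracy
#'
#' A position mismatches when the target base is not in the primer
#' position's IUPAC set. Reverse primers should be compared after
#' reverse-complementation (`reverse_complement = TRUE`).
#'
#' @param primer Primer sequence (IUPAC nucleotide codes).
#' @param target Template sequence (concrete bases).
#' @param start 1-based start of the comparison window on the target; the
#'   window must be at least as long as the primer.
#' @param reverse_complement Reverse-complement the primer first.
#' @return Integer mismatch count.
#' @seealso [best_primer_window()] for the minimum-mismatch placement.
#' @export
count_primer_mismatches <- function(primer, target, start = 1L,
                                    reverse_complement = FALSE) {
  if (reverse_complement)
    primer <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(primer)))
  np <- nchar(primer)
  if (start < 1 || start + np - 1L > nchar(target))
    stop("target window shorter than primer")
  p <- strsplit(toupper(primer), "", fixed = TRUE)[[1]]
  t <- strsplit(toupper(substring(target, start, start + np - 1L)),
                "", fixed = TRUE)[[1]]
  sum(vapply(seq_len(np), function(i) !(t[i] %in% .iupac_set(p[i])),
             logical(1)))
}

#' Best primer placement on a template
#'
#' Slides the primer over every target offset and returns the placement
#' with the fewest IUPAC mismatches (earliest such window on ties).
#'
#' @inheritParams count_primer_mismatches
#' @return List with `start` (1-based) and `mismatches`.
#' @export
best_primer_window <- function(primer, target, reverse_complement = FALSE) {
  if (reverse_complement)
    primer <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(primer)))
  np <- nchar(primer)
  if (np > nchar(target)) stop("target shorter than primer")
  offsets <- seq_len(nchar(target) - np + 1L)
  mm <- vapply(offsets, function(s)
    count_primer_mismatches(primer, target, s), integer(1))
  b <- which.min(mm)
  list(start = offsets[b], mismatches = mm[b])
}
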