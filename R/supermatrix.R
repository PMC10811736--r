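# Concatenated marker supermatrix: marker extraction by best-hit search,
# Gblocks-style conserved-block selection, partitioned concatenation.

#' Extract marker proteins from proteomes by best-hit search
#'
#' Each marker reference is locally aligned against every protein of each
#' genome; the best-scoring hit passing the identity and reference-coverage
#' thresholds is selected. Ties are broken by higher score, then longer
#' protein, then lexicographic gene id. Genomes where a marker passes no
#' threshold are recorded as missing; genomes with zero markers found
#' raise a warning but are retained.
#'
#' @param proteomes data.frame with columns `gene_id`, `genome_id`, `seq`.
#' @param marker_refs Sequence-record data.frame of reference marker
#'   proteins (one per marker; `id` is the marker id).
#' @param min_identity Percent identity threshold (default 30).
#' @param min_coverage Minimum aligned fraction of the marker reference
#'   (default 0.5).
#' @return data.frame with columns `marker_id`, `genome_id`, `gene_id`,
#'   `pident`, `score` (one row per marker found in a genome).
#' @export
extract_markers <- function(proteomes, marker_refs, min_identity = 30,
                            min_coverage = 0.5) {
  marker_refs <- .as_records(marker_refs, "marker_refs")
  if (nrow(marker_refs) == 0L) stop("empty marker reference set")
  genomes <- unique(proteomes$genome_id)
  rows <- list()
  for (g in genomes) {
    sub <- proteomes[proteomes$genome_id == g, , drop = FALSE]
    found <- 0L
    for (mi in seq_len(nrow(marker_refs))) {
      # one batched call: all proteins of the genome vs the marker ref;
      # scov is then the aligned fraction of the marker reference
      a <- .align_local(sub$seq, marker_refs$seq[mi], "protein")
      scores <- a$score; pident <- a$pident
      ok <- which(pident >= min_identity & a$scov >= min_coverage)
      if (length(ok) == 0L) next
      o <- ok[order(-scores[ok], -nchar(sub$seq[ok]), sub$gene_id[ok])]
      b <- o[1]
      rows[[length(rows) + 1L]] <- data.frame(
        marker_id = marker_refs$id[mi], genome_id = g,
        gene_id = sub$gene_id[b], pident = pident[b], score = scores[b],
        stringsAsFactors = FALSE)
      found <- found + 1L
    }
    if (found == 0L)
      warning("no markers found in genome ", g, " (retained)")
  }
  if (length(rows) == 0L)
    return(data.frame(marker_id = character(0), genome_id = character(0),
                      gene_id = character(0), pident = numeric(0),
                      score = numeric(0)))
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Select conserved alignment blocks (Gblocks-style)
#'
#' Column classification and block assembly in the spirit of the classical
#' conserved-block trimmer, fully specified: a column containing any gap
#' is nonconserved; otherwise, with `c` the count of its most frequent
#' residue, it is nonconserved when `c < IS`, highly conserved when
#' `c >= FS`, and conserved in between. Runs of more than `CP` contiguous
#' nonconserved columns are rejected and split the alignment into
#' candidate blocks; each candidate is trimmed at both edges to its
#' outermost highly-conserved columns; blocks shorter than `BL` are
#' dropped. This is a faithful-in-spirit reimplementation, not
#' bit-compatible with the original binary, whose edge handling has
#' undocumented corner cases.
#'
#' @param alignment Sequence-record data.frame of aligned, equal-width
#'   rows (>= 4).
#' @param IS Minimum count of the dominant residue for a conserved
#'   position (default `floor(n/2) + 1`).
#' @param FS Minimum count for a highly conserved / flank position
#'   (default `ceiling(0.85 * n)`).
#' @param CP Maximum run of contiguous nonconserved positions kept inside
#'   a block (default 8).
#' @param BL Minimum block length in columns (default 10).
#' @return List of class `conserved_blocks`: `intervals` (data.frame
#'   `start`, `end`, 0-based half-open, disjoint and sorted), `params`,
#'   `n_seqs`, `alignment_length`.
#' @export
select_conserved_blocks <- function(alignment, IS = NULL, FS = NULL,
                                    CP = 8L, BL = 10L) {
  alignment <- .as_records(alignment, "alignment")
  n <- nrow(alignment)
  if (n < 4L) stop("need >= 4 sequences (conservation thresholds degenerate)")
  L <- unique(nchar(alignment$seq))
  if (length(L) != 1L) stop("alignment rows differ in length")
  if (is.null(IS)) IS <- floor(n / 2) + 1L
  if (is.null(FS)) FS <- ceiling(0.85 * n)
  m <- do.call(rbind, strsplit(alignment$seq, "", fixed = TRUE))
  # 0 = nonconserved, 1 = conserved, 2 = highly conserved
  cls <- apply(m, 2, function(col) {
    if (any(col == "-")) return(0L)
    c_max <- max(table(col))
    if (c_max < IS) 0L else if (c_max >= FS) 2L else 1L
  })
  # reject runs of > CP contiguous nonconserved columns
  r <- rle(cls == 0L)
  rejected <- rep(r$values & r$lengths > CP, r$lengths)
  seg <- rle(!rejected)
  pos <- cumsum(c(0L, seg$lengths))
  intervals <- list()
  for (i in which(seg$values)) {
    s <- pos[i] + 1L
    e <- pos[i + 1L]
    hc <- which(cls[s:e] == 2L)
    if (length(hc) == 0L) next
    s2 <- s + hc[1] - 1L
    e2 <- s + hc[length(hc)] - 1L
    if (e2 - s2 + 1L < BL) next
    intervals[[length(intervals) + 1L]] <- c(s2 - 1L, e2)  # to 0-based
  }
  iv <- if (length(intervals))
    data.frame(start = vapply(intervals, `[`, 0L, 1),
               end = vapply(intervals, `[`, 0L, 2)) else
    data.frame(start = integer(0), end = integer(0))
  structure(list(intervals = iv,
                 params = list(IS = IS, FS = FS, CP = CP, BL = BL),
                 n_seqs = n, alignment_length = L),
            class = "conserved_blocks")
}

#' @export
print.conserved_blocks <- function(x, ...) {
  kept <- sum(x$intervals$end - x$intervals$start)
  cat(sprintf("Conserved blocks: %d block(s), %d / %d columns kept (IS %d, FS %d, CP %d, BL %d)\n",
              nrow(x$intervals), kept, x$alignment_length,
              x$params$IS, x$params$FS, x$params$CP, x$params$BL))
  if (nrow(x$intervals))
    cat(paste(sprintf("  [%d, %d)", x$intervals$start, x$intervals$end),
              collapse = "\n"), "\n")
  invisible(x)
}

#' Concatenate conserved marker blocks into a supermatrix
#'
#' Markers are processed in sorted marker-id order; for each genome the
#' kept columns of every marker are joined, genomes absent from a marker
#' are gap-filled across its partition, and genomes missing more than
#' `max_missing` of the total columns are dropped with a warning. A
#' 1-based inclusive partition table records the marker boundaries.
#'
#' @param blocksets Named list (marker id -> [select_conserved_blocks()]
#'   result).
#' @param alignments Named list (marker id -> aligned sequence-record
#'   data.frame); row ids are genome ids.
#' @param genome_universe Genomes to include (default: union over
#'   alignments).
#' @param max_missing Maximum tolerated missing-column fraction per
#'   genome (default 0.5).
#' @return Object of class `supermatrix`: `rows` (sequence-record
#'   data.frame), `partitions` (data.frame `name`, `start`, `end`),
#'   `length`.
#' @export
concatenate_markers <- function(blocksets, alignments,
                                genome_universe = NULL, max_missing = 0.5) {
  markers <- sort(names(alignments))
  if (!all(markers %in% names(blocksets)))
    stop("every alignment needs a matching blockset")
  if (is.null(genome_universe))
    genome_universe <- sort(unique(unlist(
      lapply(alignments, function(a) a$id))))
  pieces <- list()
  parts <- list()
  off <- 0L
  for (mk in markers) {
    aln <- .as_records(alignments[[mk]], mk)
    iv <- blocksets[[mk]]$intervals
    w <- sum(iv$end - iv$start)
    if (w == 0L) next
    kept <- vapply(aln$seq, function(s)
      paste(substring(s, iv$start + 1L, iv$end), collapse = ""),
      "", USE.NAMES = FALSE)
    col <- setNames(rep(strrep("-", w), length(genome_universe)),
                    genome_universe)
    col[aln$id[aln$id %in% genome_universe]] <-
      kept[aln$id %in% genome_universe]
    pieces[[mk]] <- col
    parts[[mk]] <- data.frame(name = mk, start = off + 1L, end = off + w,
                              stringsAsFactors = FALSE)
    off <- off + w
  }
  if (off == 0L) stop("empty supermatrix: no kept columns in any marker")
  rows <- vapply(genome_universe, function(g)
    paste(vapply(pieces, `[[`, "", g), collapse = ""), "")
  stopifnot(all(nchar(rows) == off))  # partition tiling assertion
  miss_frac <- vapply(genome_universe, function(g) {
    gapped <- sum(vapply(names(pieces), function(mk)
      if (grepl("^-+$", pieces[[mk]][[g]]))
        nchar(pieces[[mk]][[g]]) else 0L, numeric(1)))
    gapped / off
  }, numeric(1))
  drop <- genome_universe[miss_frac > max_missing]
  if (length(drop))
    warning("dropping genome(s) missing > ", max_missing * 100,
            "% of columns: ", paste(drop, collapse = ", "))
  keep <- setdiff(genome_universe, drop)
  structure(list(
    rows = data.frame(id = keep, desc = "", seq = unname(rows[keep]),
                      stringsAsFactors = FALSE),
    partitions = do.call(rbind, parts),
    length = off), class = "supermatrix")
}

#' @export
print.supermatrix <- function(x, ...) {
  cat(sprintf("Supermatrix: %d genomes x %d columns, %d partition(s)\n",
              nrow(x$rows), x$length, nrow(x$partitions)))
  invisible(x)
}
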