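# Exact local alignment (Smith-Waterman via Biostrings::pairwiseAlignment)
# plus the k-mer prefilter used before all-vs-all comparisons.
#
# Identity convention (used everywhere in the package): identical columns /
# alignment columns x 100, where alignment columns include internal gap
# columns; terminal overhangs outside the local alignment are excluded.
# Coverage = aligned span on the original sequence / sequence length.

.blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- get("BLOSUM62", envir = e)
    }
    cache
  }
})

.dna_submat <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- Biostrings::nucleotideSubstitutionMatrix(
        match = 2, mismatch = -3, baseOnly = FALSE)
    cache
  }
})

.count_gap_opens <- function(s) {
  vapply(gregexpr("-+", s, perl = TRUE), function(g)
    if (g[1] == -1L) 0L else length(g), integer(1))
}

# Align each of `queries` (character vector) locally against one `subject`;
# returns one row per query with score, identity, coverage and 1-based
# coordinates on the original sequences.
.align_local <- function(queries, subject, type = c("protein", "dna")) {
  type <- match.arg(type)
  if (type == "protein") {
    pat <- Biostrings::AAStringSet(queries)
    sub <- Biostrings::AAString(subject)
    aln <- Biostrings::pairwiseAlignment(
      pat, sub, type = "local", substitutionMatrix = .blosum62(),
      gapOpening = 10, gapExtension = 4)
  } else {
    pat <- Biostrings::DNAStringSet(queries)
    sub <- Biostrings::DNAString(subject)
    aln <- Biostrings::pairwiseAlignment(
      pat, sub, type = "local", substitutionMatrix = .dna_submat(),
      gapOpening = 5, gapExtension = 2)
  }
  pal <- Biostrings::pattern(aln)
  sal <- Biostrings::subject(aln)
  pstr <- as.character(pal)
  sstr <- as.character(sal)
  alen <- nchar(pstr)
  nmat <- Biostrings::nmatch(aln)
  prng <- methods::slot(pal, "range")
  srng <- methods::slot(sal, "range")
  qstart <- methods::slot(prng, "start")
  qend <- qstart + methods::slot(prng, "width") - 1L
  sstart <- methods::slot(srng, "start")
  send <- sstart + methods::slot(srng, "width") - 1L
  data.frame(
    score = methods::slot(aln, "score"),
    pident = ifelse(alen > 0, 100 * nmat / alen, 0),
    length = alen,
    mismatch = Biostrings::nmismatch(aln),
    gapopen = .count_gap_opens(pstr) + .count_gap_opens(sstr),
    qstart = qstart, qend = qend, sstart = sstart, send = send,
    qcov = (qend - qstart + 1) / nchar(queries),
    scov = (send - sstart + 1) / nchar(subject),
    stringsAsFactors = FALSE)
}

# k-mer sets for the prefilter.
.kmer_sets <- function(seqs, k) {
  lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    unique(substring(s, seq_len(n - k + 1L), k:n))
  })
}

.shared_kmers <- function(set_a, set_b) {
  sum(set_a %in% set_b)
}
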