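# Synthetic pangenomes, diverged sequences, read communities and alignments
# with planted ground truth. All generators are pure functions of their
# arguments plus `seed`: the global RNG state is saved and restored.

.random_seq <- function(n, alphabet) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Point-substitution under the current RNG: each position replaced with
# probability d by a uniformly chosen DIFFERENT residue, so expected
# identity to the input is exactly 1 - d.
# Per-member substitution rate x such that two independent copies of an
# ancestor, each mutated at x under the "always change" model over an
# alphabet of size k, have expected pairwise identity 1 - d:
# (1-x)^2 + x^2/(k-1) = 1 - d.
.pairwise_to_member_rate <- function(d, k) {
  if (d == 0) return(0)
  a <- k / (k - 1)
  if (d > 1 / a)
    stop("pairwise divergence ", d, " unreachable over a ", k,
         "-letter alphabet (max ", format(1 / a), ")")
  (1 - sqrt(1 - a * d)) / a
}

.mutate_chars <- function(chars, d, alphabet) {
  hit <- which(runif(length(chars)) < d)
  if (length(hit)) {
    k <- length(alphabet)
    pos <- match(chars[hit], alphabet)
    if (anyNA(pos)) stop("residue outside alphabet: ",
                         chars[hit][which(is.na(pos))[1]])
    off <- sample.int(k - 1L, length(hit), replace = TRUE)
    chars[hit] <- alphabet[(pos - 1L + off) %% k + 1L]
  }
  chars
}

#' Evolve a sequence by point substitution at a fixed divergence
#'
#' Each position is independently replaced with probability `d` by a
#' uniformly chosen *different* residue (no indels), so the expected
#' identity between input and output is exactly `1 - d`. Used to plant
#' known ANI/AAI/orthology recovery targets.
#'
#' @param seq Residue string (nucleotide or amino-acid).
#' @param d Per-site substitution probability in `[0, 1]`.
#' @param seed Integer seed; the global RNG is left untouched.
#' @param alphabet `"auto"` (default), `"dna"` or `"protein"`.
#' @return The diverged sequence as a character string.
#' @export
evolve_sequence <- function(seq, d, seed, alphabet = "auto") {
  if (!is.numeric(d) || length(d) != 1L || is.na(d) || d < 0 || d > 1)
    stop("d must be a single value in [0, 1]")
  alphabet <- match.arg(alphabet, c("auto", "dna", "protein"))
  if (alphabet == "auto") alphabet <- .guess_alphabet(seq)
  alpha <- if (alphabet == "dna") .DNA_BASES else .AA_RESIDUES
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  withr::with_seed(seed,
    paste(.mutate_chars(chars, d, alpha), collapse = ""))
}

#' Specify a synthetic pangenome
#'
#' Describes a multi-genome pangenome with a fixed core, an accessory pool
#' with per-family presence probabilities, and per-genome unique genes --
#' the structure that pangenome rarefaction operates on.
#'
#' @param n_genomes Number of genomes (>= 2).
#' @param core_size Number of gene families present in every genome.
#' @param accessory_pool data.frame with columns `family` and `p`
#'   (presence probability in `(0, 1)`); optional column `genomes`, a list
#'   of integer vectors restricting a family to a genome subset (it can
#'   then only occur there) -- used to plant lineage-specific families.
#' @param unique_rate Mean number of unique (genome-private, unrelated)
#'   genes per genome; per-genome counts are Poisson.
#' @param gene_length Mean gene length in nucleotides (protein length is
#'   `gene_length / 3` residues).
#' @param divergence Expected *pairwise* per-site divergence `d` between
#'   any two members of a family, so within-family expected identity is
#'   `1 - d`. Each genome's copy is the family ancestor evolved at the
#'   per-member rate `x` solving `(1-x)^2 + x^2/(k-1) = 1 - d` (alphabet
#'   size `k`), which makes the pairwise expectation exact.
#' @param seed Integer seed.
#' @return Object of class `pangenome_spec`.
#' @export
pangenome_spec <- function(n_genomes, core_size, accessory_pool = NULL,
                           unique_rate = 0, gene_length = 900,
                           divergence = 0.1, seed = 1L) {
  if (!.is_count(n_genomes) || n_genomes < 2) stop("n_genomes must be >= 2")
  if (!.is_count(core_size)) stop("core_size must be a count")
  if (is.null(accessory_pool))
    accessory_pool <- data.frame(family = character(0), p = numeric(0))
  if (!all(c("family", "p") %in% names(accessory_pool)))
    stop("accessory_pool needs columns 'family' and 'p'")
  if (nrow(accessory_pool) &&
      (any(accessory_pool$p <= 0) || any(accessory_pool$p >= 1)))
    stop("accessory presence probabilities must lie in (0, 1)")
  if (core_size == 0 && nrow(accessory_pool) == 0L && unique_rate == 0)
    stop("empty pangenome: no core, accessory pool or unique genes")
  if (unique_rate < 0) stop("unique_rate must be >= 0")
  if (divergence < 0 || divergence > 1) stop("divergence must be in [0, 1]")
  structure(list(n_genomes = as.integer(n_genomes),
                 core_size = as.integer(core_size),
                 accessory_pool = accessory_pool,
                 unique_rate = unique_rate,
                 gene_length = gene_length,
                 divergence = divergence,
                 seed = as.integer(seed)),
            class = "pangenome_spec")
}

#' Simulate a pangenome with known family structure
#'
#' Generates genomes (gene sequences joined by short random spacers),
#' proteomes, and a ground-truth table mapping every gene to its family.
#' Core families appear in all genomes; accessory family `f` appears in
#' genome `g` independently with probability `p_f` (optionally restricted
#' to a genome subset); unique genes are fresh random sequences, unrelated
#' to everything else. Within a family, each genome's copy is the family
#' ancestor evolved at the spec's divergence, both at the nucleotide and
#' the protein level.
#'
#' @param spec A [pangenome_spec()].
#' @return List with elements
#'   `genomes` (sequence-record data.frame, one record per genome),
#'   `proteins` (data.frame `gene_id`, `genome_id`, `seq`),
#'   `genes` (nucleotide data.frame, same shape),
#'   `genome_sizes` (named vector, bp, from the actual sequences),
#'   `truth` (list: `gene_table` with `gene_id`/`genome_id`/`family`/`type`,
#'   `presence` family-by-genome 0/1 matrix, `divergence`).
#' @export
simulate_pangenome <- function(spec) {
  stopifnot(inherits(spec, "pangenome_spec"))
  withr::with_seed(spec$seed, .simulate_pangenome_impl(spec))
}

.simulate_pangenome_impl <- function(spec) {
  n <- spec$n_genomes
  gids <- sprintf("g%02d", seq_len(n))
  fams <- character(0)
  fam_restrict <- list()
  if (spec$core_size > 0) {
    core_ids <- sprintf("core%04d", seq_len(spec$core_size))
    fams <- c(fams, core_ids)
    fam_restrict[core_ids] <- list(seq_len(n))
  }
  acc <- spec$accessory_pool
  acc_ids <- as.character(acc$family)
  for (i in seq_along(acc_ids)) {
    fam_restrict[[acc_ids[i]]] <-
      if (!is.null(acc$genomes)) acc$genomes[[i]] else seq_len(n)
  }
  fams <- c(fams, acc_ids)
  if (anyDuplicated(fams)) stop("duplicate family ids")

  # Family ancestors: paired nucleotide gene and protein sequence.
  aa_len <- max(20L, round(spec$gene_length / 3))
  anc_nt <- lapply(fams, function(f)
    strsplit(.random_seq(max(60L, rpois(1, spec$gene_length)), .DNA_BASES),
             "", fixed = TRUE)[[1]])
  anc_aa <- lapply(fams, function(f)
    strsplit(.random_seq(max(20L, rpois(1, aa_len)), .AA_RESIDUES),
             "", fixed = TRUE)[[1]])
  names(anc_nt) <- names(anc_aa) <- fams

  is_core <- fams %in% if (spec$core_size > 0)
    sprintf("core%04d", seq_len(spec$core_size)) else character(0)
  p_fam <- setNames(rep(1, length(fams)), fams)
  p_fam[acc_ids] <- acc$p

  rows <- list()
  genome_seq <- character(n)
  d_nt <- .pairwise_to_member_rate(spec$divergence, 4L)
  d_aa <- .pairwise_to_member_rate(spec$divergence, 20L)
  for (g in seq_len(n)) {
    present <- vapply(fams, function(f) {
      if (!(g %in% fam_restrict[[f]])) return(FALSE)
      if (is_core[match(f, fams)]) TRUE else runif(1) < p_fam[[f]]
    }, logical(1))
    fam_here <- fams[present]
    nt <- lapply(fam_here, function(f)
      .mutate_chars(anc_nt[[f]], d_nt, .DNA_BASES))
    aa <- lapply(fam_here, function(f)
      .mutate_chars(anc_aa[[f]], d_aa, .AA_RESIDUES))
    fam_label <- fam_here
    type <- ifelse(is_core[match(fam_here, fams)], "core", "accessory")
    n_uni <- rpois(1, spec$unique_rate)
    if (n_uni > 0) {
      ufam <- sprintf("uniq_%s_%03d", gids[g], seq_len(n_uni))
      nt <- c(nt, lapply(ufam, function(f)
        strsplit(.random_seq(max(60L, rpois(1, spec$gene_length)),
                             .DNA_BASES), "", fixed = TRUE)[[1]]))
      aa <- c(aa, lapply(ufam, function(f)
        strsplit(.random_seq(max(20L, rpois(1, aa_len)), .AA_RESIDUES),
                 "", fixed = TRUE)[[1]]))
      fam_label <- c(fam_label, ufam)
      type <- c(type, rep("unique", n_uni))
    }
    gene_ids <- sprintf("%s_%s", gids[g], fam_label)
    rows[[g]] <- data.frame(gene_id = gene_ids,
                            genome_id = rep(gids[g], length(gene_ids)),
                            family = fam_label, type = type,
                            nt = vapply(nt, paste, "", collapse = ""),
                            aa = vapply(aa, paste, "", collapse = ""),
                            stringsAsFactors = FALSE)
    spacers <- vapply(seq_len(length(nt) + 1L), function(i)
      .random_seq(sample(20:100, 1), .DNA_BASES), "")
    pieces <- character(2L * length(nt) + 1L)
    pieces[seq(1, length(pieces), by = 2)] <- spacers
    if (length(nt))
      pieces[seq(2, length(pieces) - 1, by = 2)] <- rows[[g]]$nt
    genome_seq[g] <- paste(pieces, collapse = "")
  }
  tab <- do.call(rbind, rows)
  all_fams <- sort(unique(tab$family))
  presence <- matrix(0L, length(all_fams), n,
                     dimnames = list(all_fams, gids))
  presence[cbind(match(tab$family, all_fams), match(tab$genome_id, gids))] <- 1L
  list(genomes = data.frame(id = gids, desc = "", seq = genome_seq,
                            stringsAsFactors = FALSE),
       proteins = data.frame(gene_id = tab$gene_id, genome_id = tab$genome_id,
                             seq = tab$aa, stringsAsFactors = FALSE),
       genes = data.frame(gene_id = tab$gene_id, genome_id = tab$genome_id,
                          seq = tab$nt, stringsAsFactors = FALSE),
       genome_sizes = setNames(nchar(genome_seq), gids),
       truth = list(gene_table = tab[, c("gene_id", "genome_id",
                                         "family", "type")],
                    presence = presence,
                    divergence = spec$divergence))
}

#' Simulate a metagenomic read community with known composition
#'
#' Reads are drawn from source genomes according to `composition`, with
#' uniform start positions (forward strand) and independent per-base
#' substitution errors.
#'
#' @param genomes Sequence-record data.frame (one record per genome) or a
#'   named character vector of genome sequences.
#' @param composition Named numeric vector of per-read source
#'   probabilities; names must match genome ids; must sum to 1 (within
#'   1e-9).
#' @param read_length Read length in bp (<= shortest genome).
#' @param n_reads Number of reads.
#' @param error_rate Per-base substitution error probability.
#' @param seed Integer seed.
#' @return List `reads` (sequence-record data.frame) and `truth`
#'   (data.frame `read_id`, `genome_id`, `start` 1-based).
#' @export
simulate_reads <- function(genomes, composition, read_length, n_reads,
                           error_rate = 0, seed = 1L) {
  genomes <- .as_records(genomes, "genomes")
  if (is.null(names(composition)) ||
      !all(names(composition) %in% genomes$id))
    stop("composition must be named by genome ids")
  if (abs(sum(composition) - 1) > 1e-9)
    stop("composition must sum to 1 (got ", sum(composition), ")")
  if (read_length > min(nchar(genomes$seq)))
    stop("read_length exceeds the shortest genome")
  if (error_rate < 0 || error_rate > 1) stop("error_rate must be in [0, 1]")
  withr::with_seed(seed, {
    src <- sample(names(composition), n_reads, replace = TRUE,
                  prob = composition)
    glen <- setNames(nchar(genomes$seq), genomes$id)
    start <- floor(runif(n_reads) * (glen[src] - read_length + 1)) + 1L
    seqs <- substring(genomes$seq[match(src, genomes$id)],
                      start, start + read_length - 1L)
    if (error_rate > 0)
      seqs <- vapply(seqs, function(s)
        paste(.mutate_chars(strsplit(s, "", fixed = TRUE)[[1]],
                            error_rate, .DNA_BASES), collapse = ""),
        "", USE.NAMES = FALSE)
    ids <- sprintf("read%06d", seq_len(n_reads))
    list(reads = data.frame(id = ids, desc = "", seq = seqs,
                            stringsAsFactors = FALSE),
         truth = data.frame(read_id = ids, genome_id = unname(src),
                            start = as.integer(unname(start)),
                            stringsAsFactors = FALSE))
  })
}

#' Simulate a marker alignment with planted conserved blocks
#'
#' Columns inside the planted blocks are gap-free and unanimous (one
#' residue per column shared by all rows); columns outside carry
#' independent random residues and gaps at rate `gap_rate`. With
#' `gap_rate >= 0.5` the planted blocks are, with overwhelming
#' probability, exactly the conserved blocks a Gblocks-style trimmer
#' selects. Blocks closer together than the trimmer's allowed
#' nonconserved-run length merge during selection, so plant them further
#' apart when exact recovery is the goal.
#'
#' @param n_seqs Number of rows (>= 4 for downstream block selection).
#' @param length Alignment length in columns.
#' @param blocks data.frame with columns `start`, `end`: disjoint 0-based
#'   half-open column intervals.
#' @param gap_rate Per-cell gap probability outside blocks.
#' @param seed Integer seed.
#' @return List `alignment` (sequence-record data.frame, equal-width rows)
#'   and `truth` (the planted block intervals).
#' @export
simulate_marker_alignment <- function(n_seqs, length, blocks,
                                      gap_rate = 0.5, seed = 1L) {
  stopifnot(.is_count(n_seqs), n_seqs >= 2, .is_count(length))
  b <- blocks[order(blocks$start), , drop = FALSE]
  if (any(b$start < 0) || any(b$end > length) || any(b$end <= b$start))
    stop("blocks must be non-empty intervals within [0, length)")
  if (nrow(b) > 1L && any(b$start[-1] < b$end[-nrow(b)]))
    stop("overlapping blocks")
  withr::with_seed(seed, {
    m <- matrix("", n_seqs, length)
    in_block <- logical(length)
    for (i in seq_len(nrow(b)))
      in_block[(b$start[i] + 1L):b$end[i]] <- TRUE
    for (j in which(in_block)) m[, j] <- sample(.AA_RESIDUES, 1)
    out <- which(!in_block)
    if (length(out)) {
      cells <- matrix(sample(.AA_RESIDUES, n_seqs * length(out),
                             replace = TRUE), n_seqs)
      gaps <- matrix(runif(n_seqs * length(out)) < gap_rate, n_seqs)
      cells[gaps] <- "-"
      m[, out] <- cells
    }
    aln <- data.frame(id = sprintf("s%02d", seq_len(n_seqs)), desc = "",
                      seq = apply(m, 1, paste, collapse = ""),
                      stringsAsFactors = FALSE)
    list(alignment = aln,
         truth = data.frame(start = b$start, end = b$end))
  })
}
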