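#' Read a FASTA file into a sequence-record table
#'
#' Sequence records are represented throughout the package as a data.frame
#' with columns `id` (header token before the first whitespace), `desc`
#' (remainder of the header line, `""` if absent) and `seq` (upper-case
#' residue string with line wrapping removed).
#'
#' @param path Path to a FASTA file (nucleotide or amino-acid).
#' @return data.frame with columns `id`, `desc`, `seq`, in file order.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">a x", "AC", "GT"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("empty FASTA file: ", path)
  hdr <- names(ss)
  id <- sub("\\s.*$", "", hdr)
  desc <- ifelse(grepl("\\s", hdr), sub("^\\S+\\s+", "", hdr), "")
  seq <- toupper(unname(as.character(ss)))
  if (any(!nzchar(id)))
    stop("FASTA record ", which(!nzchar(id))[1], " has an empty id")
  empty <- which(!nzchar(seq))
  if (length(empty))
    stop("FASTA record '", id[empty[1]], "' has an empty sequence")
  data.frame(id = id, desc = desc, seq = seq, stringsAsFactors = FALSE)
}

#' Write sequence records to FASTA
#'
#' `read_fasta(write_fasta(x, path))` reproduces `x` exactly.
#'
#' @param records Sequence-record data.frame (`id`, optional `desc`, `seq`)
#'   or a named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width in residues (>= 1).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  if (!.is_count(width) || width < 1) stop("width must be >= 1")
  if ((is.data.frame(records) && nrow(records) == 0L) ||
      (!is.data.frame(records) && length(records) == 0L)) {
    file.create(path)
    return(invisible(path))
  }
  records <- .as_records(records)
  ss <- Biostrings::BStringSet(records$seq)
  names(ss) <- ifelse(nzchar(records$desc),
                      paste(records$id, records$desc), records$id)
  Biostrings::writeXStringSet(ss, path, width = as.integer(width))
  invisible(path)
}

.HIT_COLS <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
               "qstart", "qend", "sstart", "send", "evalue", "bitscore")

#' Read a 12-column tabular sequence-search hit file
#'
#' The standard tab-separated hit format (qseqid sseqid pident length
#' mismatch gapopen qstart qend sstart send evalue bitscore), as written by
#' BLAST+ `-outfmt 6` and compatible aligners. Lines beginning with `#` are
#' skipped. Coordinates stay 1-based inclusive, as in the format itself.
#'
#' @param path Path to the hit table.
#' @return data.frame with the 12 standard columns; numeric fields parsed
#'   (scientific-notation E-values accepted).
#' @export
read_hits_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- which(!grepl("^#", lines) & nzchar(lines))
  if (length(keep) == 0L) return(.empty_hits())
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 12L)) {
    i <- which(nf != 12L)[1]
    stop(sprintf("line %d: expected 12 columns, found %d", keep[i], nf[i]))
  }
  m <- matrix(unlist(parts), ncol = 12L, byrow = TRUE)
  hits <- data.frame(qseqid = m[, 1], sseqid = m[, 2],
                     stringsAsFactors = FALSE)
  for (j in 3:12) {
    v <- suppressWarnings(as.numeric(m[, j]))
    if (anyNA(v)) {
      i <- which(is.na(v))[1]
      stop(sprintf("line %d: unparseable numeric value '%s' in column %s",
                   keep[i], m[i, j], .HIT_COLS[j]))
    }
    hits[[.HIT_COLS[j]]] <- v
  }
  if (any(hits$pident < 0 | hits$pident > 100))
    stop("percent identity outside [0, 100]")
  if (any(hits$evalue < 0)) stop("negative E-value")
  hits
}

.empty_hits <- function() {
  h <- data.frame(qseqid = character(0), sseqid = character(0),
                  stringsAsFactors = FALSE)
  for (j in 3:12) h[[.HIT_COLS[j]]] <- numeric(0)
  h
}

#' Read a genome lineage map
#'
#' TSV with columns `genome_id`, `lineage`, `genome_size_bp` (a header row
#' with these names is recognised and skipped). Genome sizes are kept in bp;
#' normalisation routines convert to Mb (bp / 1e6).
#'
#' @param path Path to the TSV.
#' @return data.frame with columns `genome_id`, `lineage`, `genome_size_bp`.
#' @export
read_lineage_map <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                   comment.char = "#")
  if (ncol(df) != 3L) stop("lineage map must have 3 columns, found ", ncol(df))
  if (nrow(df) > 0 && identical(as.character(df[1, 1]), "genome_id"))
    df <- df[-1, , drop = FALSE]
  names(df) <- c("genome_id", "lineage", "genome_size_bp")
  df$genome_id <- as.character(df$genome_id)
  df$lineage <- as.character(df$lineage)
  df$genome_size_bp <- suppressWarnings(as.numeric(df$genome_size_bp))
  if (anyNA(df$genome_size_bp)) stop("unparseable genome size")
  dup <- df$genome_id[duplicated(df$genome_id)]
  if (length(dup)) stop("duplicate genome_id: ", dup[1])
  if (any(df$genome_size_bp <= 0))
    stop("genome_size_bp must be > 0 (genome ",
         df$genome_id[which(df$genome_size_bp <= 0)[1]], ")")
  rownames(df) <- NULL
  df
}

#' @rdname read_presence_matrix
#' @param matrix Binary integer matrix, orthogroup rows x genome columns,
#'   with dimnames.
#' @export
write_presence_matrix <- function(matrix, path) {
  if (is.null(rownames(matrix)) || is.null(colnames(matrix)))
    stop("presence matrix needs row (orthogroup) and column (genome) names")
  if (!all(matrix %in% c(0L, 1L))) stop("non-binary cell in presence matrix")
  df <- data.frame(og_id = rownames(matrix), matrix, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a presence/absence matrix
#'
#' TSV with first column `og_id`, remaining columns one per genome, cells 0
#' or 1. Round-trips exactly.
#'
#' @param path Path to the TSV.
#' @return Integer matrix with orthogroup rownames and genome colnames.
#' @export
read_presence_matrix <- function(path) {
  df <- read.delim(path, header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("presence matrix needs >= 1 genome column")
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!all(m %in% c(0, 1))) {
    bad <- which(!(m %in% c(0, 1)))[1]
    stop("non-binary cell '", m[bad], "' in presence matrix")
  }
  storage.mode(m) <- "integer"
  rownames(m) <- as.character(df[[1]])
  m
}

#' Write a phylogenomic partition file
#'
#' One line per marker in the `"<type>, <name> = <start>-<end>"` dialect,
#' 1-based inclusive coordinates. Partitions must tile `1..L` contiguously.
#'
#' @param partitions data.frame with columns `name`, `start`, `end`
#'   (1-based inclusive).
#' @param path Output path.
#' @param type Data-type label written before each partition (default "AA").
#' @return `path`, invisibly.
#' @export
write_partition_file <- function(partitions, path, type = "AA") {
  p <- partitions[order(partitions$start), , drop = FALSE]
  if (nrow(p) == 0L) stop("no partitions")
  if (p$start[1] != 1L) stop("partitions must start at 1")
  if (any(p$end < p$start)) stop("partition end before start")
  if (nrow(p) > 1L) {
    nxt <- p$start[-1]
    prev_end <- p$end[-nrow(p)]
    if (any(nxt != prev_end + 1L))
      stop("gap or overlap between partitions at position ",
           prev_end[which(nxt != prev_end + 1L)[1]])
  }
  writeLines(sprintf("%s, %s = %d-%d", type, p$name, p$start, p$end), path)
  invisible(path)
}
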