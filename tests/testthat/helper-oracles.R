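# Independent oracles and small fixtures used across the suite.

DNA <- c("A", "C", "G", "T")
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_dna <- function(n) paste(sample(DNA, n, replace = TRUE), collapse = "")
random_protein <- function(n) paste(sample(AA20, n, replace = TRUE),
                                    collapse = "")

# Worked presence/absence matrix: genomes g1..g3, orthogroup rows
# A:111 B:111 C:110 D:100 E:001.
m0_matrix <- function() {
  matrix(c(1, 1, 1,
           1, 1, 1,
           1, 1, 0,
           1, 0, 0,
           0, 0, 1), 5, 3, byrow = TRUE,
         dimnames = list(LETTERS[1:5], c("g1", "g2", "g3")))
}

# Pascal-triangle binomial oracle (exact for values below 2^53).
pascal_choose <- function(n, m) {
  row <- 1
  for (i in seq_len(n)) row <- c(1, head(row, -1) + row[-1], 1)[seq_len(i + 1)]
  row[m + 1]
}

# Brute-force transitive closure: partition of `ids` induced by `edges`
# (2-column matrix/data.frame), via boolean reachability matrix powers.
# Returns a canonical character vector (sorted comma-joined components).
closure_partition <- function(ids, edges) {
  n <- length(ids)
  R <- diag(n) > 0
  if (nrow(edges) > 0) {
    i <- match(edges[[1]], ids)
    j <- match(edges[[2]], ids)
    R[cbind(i, j)] <- TRUE
    R[cbind(j, i)] <- TRUE
  }
  repeat {
    R2 <- (R %*% R) > 0
    if (identical(R2, R)) break
    R <- R2
  }
  comps <- unique(apply(R, 1, function(r) paste(sort(ids[r]), collapse = ",")))
  sort(comps)
}

canonical_partition <- function(members_by_group) {
  sort(unname(vapply(members_by_group,
                     function(x) paste(sort(x), collapse = ","), "")))
}

# Affine-gap Smith-Waterman oracle (gap of length L costs open + ext * L),
# plain dynamic programming, no prefilter. Returns the optimal local score.
sw_score_oracle <- function(a, b, submat, open = 10, ext = 4) {
  a <- strsplit(a, "", fixed = TRUE)[[1]]
  b <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(a); m <- length(b)
  M <- Ix <- Iy <- matrix(-Inf, n + 1, m + 1)
  M[1, ] <- 0; M[, 1] <- 0
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- submat[a[i - 1], b[j - 1]]
      M[i, j] <- max(0, M[i - 1, j - 1], Ix[i - 1, j - 1],
                     Iy[i - 1, j - 1]) + s
      Ix[i, j] <- max(M[i - 1, j] - open - ext, Ix[i - 1, j] - ext)
      Iy[i, j] <- max(M[i, j - 1] - open - ext, Iy[i, j - 1] - ext)
      best <- max(best, M[i, j])
    }
  }
  best
}

blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  get("BLOSUM62", envir = e)
}

# Exhaustive-permutation oracle for the openness statistic: pooled mean of
# new-orthogroups-per-Mbp contributions over ALL genome orders.
openness_oracle <- function(M, sizes_bp) {
  M <- M != 0
  n <- ncol(M)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  contribs <- c()
  for (ord in perms(seq_len(n))) {
    seen <- M[, ord[1]]
    for (g in ord[-1]) {
      contribs <- c(contribs, sum(M[, g] & !seen) / (sizes_bp[g] / 1e6))
      seen <- seen | M[, g]
    }
  }
  mean(contribs)
}

has_blast <- function() nzchar(Sys.which("blastn")) &&
  nzchar(Sys.which("makeblastdb"))
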