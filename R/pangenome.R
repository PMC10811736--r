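# Core/pan-genome rarefaction by combinatorial genome sampling, Heaps'-law
# openness fitting, the new-genes-per-Mbp statistic, and lineage-enriched
# orthogroup detection.

# ---- exact big-integer binomials -------------------------------------------
# C(n, m) for n up to 200 far exceeds 2^53, so an exact little-endian
# base-1e7 limb representation is used internally (multiply and divide by
# small integers only, which is all the running-product formula needs).

.BIGBASE <- 1e7

.big_mul_small <- function(x, f) {
  x <- x * f
  carry <- 0
  for (i in seq_along(x)) {
    v <- x[i] + carry
    carry <- floor(v / .BIGBASE)
    x[i] <- v - carry * .BIGBASE
  }
  while (carry > 0) {
    x <- c(x, carry %% .BIGBASE)
    carry <- floor(carry / .BIGBASE)
  }
  x
}

.big_div_small <- function(x, f) {
  rem <- 0
  for (i in rev(seq_along(x))) {
    v <- rem * .BIGBASE + x[i]
    x[i] <- floor(v / f)
    rem <- v - x[i] * f
  }
  if (rem != 0) stop("non-exact big-integer division")  # cannot happen here
  while (length(x) > 1L && x[length(x)] == 0) x <- x[-length(x)]
  x
}

.big_to_value <- function(x) {
  if (length(x) <= 3L) {
    v <- sum(x * .BIGBASE^(seq_along(x) - 1L))
    if (v <= 2^53) return(v)  # terms and sum below 2^53: exact in a double
  }
  paste0(format(x[length(x)], scientific = FALSE),
         paste(sprintf("%07.0f", rev(x[-length(x)])), collapse = ""))
}

#' Exact number of genome combinations
#'
#' Computes `n! / (m! (n - m)!)` exactly by a running product with exact
#' integer division, without floating-point overflow for `n <= 200`.
#'
#' @param n Number of genomes.
#' @param m Sample size, `0 <= m <= n`.
#' @return The exact count: a numeric when representable exactly in a
#'   double (< 2^53), otherwise a decimal digit string.
#' @examples
#' count_combinations(5, 2)   # 10
#' count_combinations(23, 12) # 1352078
#' @export
count_combinations <- function(n, m) {
  if (!.is_count(n) || !.is_count(m)) stop("n and m must be counts")
  if (m > n) stop("m must not exceed n")
  m <- min(m, n - m)
  x <- 1
  for (k in seq_len(m)) {
    x <- .big_mul_small(x, n - m + k)
    x <- .big_div_small(x, k)
  }
  .big_to_value(x)
}

# TRUE iff C(n, m) <= cap, decided exactly.
.choose_at_most <- function(n, m, cap) {
  v <- count_combinations(n, m)
  is.numeric(v) && v <= cap
}

#' Sample genome combinations
#'
#' If the exact number of m-subsets of `1..n` is at most `cap`, all of
#' them are returned (exhaustive); otherwise `cap` *distinct* subsets are
#' sampled uniformly without replacement. Deterministic under `seed`.
#'
#' @param n,m Universe size and subset size (`0 < m <= n`).
#' @param cap Maximum number of combinations (default 5000).
#' @param seed Integer seed.
#' @return List of sorted integer vectors, with attributes `exhaustive`
#'   (logical) and `n_combos`.
#' @export
sample_combinations <- function(n, m, cap = 5000L, seed = 1L) {
  if (!.is_count(n) || !.is_count(m) || m < 1 || m > n)
    stop("need 0 < m <= n")
  if (!.is_count(cap) || cap < 1) stop("cap must be >= 1")
  if (.choose_at_most(n, m, cap)) {
    combos <- utils::combn(n, m, simplify = FALSE)
    attr(combos, "exhaustive") <- TRUE
    attr(combos, "n_combos") <- length(combos)
    return(combos)
  }
  combos <- withr::with_seed(seed, {
    seen <- new.env(hash = TRUE, parent = emptyenv())
    res <- vector("list", cap)
    got <- 0L
    while (got < cap) {
      s <- sort(sample.int(n, m))
      key <- paste(s, collapse = ",")
      if (is.null(seen[[key]])) {
        seen[[key]] <- TRUE
        got <- got + 1L
        res[[got]] <- s
      }
    }
    res
  })
  attr(combos, "exhaustive") <- FALSE
  attr(combos, "n_combos") <- length(combos)
  combos
}

#' Core/pan-genome rarefaction curve
#'
#' For each subset size `m` in `1..n`, samples genome combinations (all of
#' them when there are at most `cap`, else `cap` distinct random ones) and
#' records the mean and standard deviation of the pan-genome size
#' (orthogroups present in at least one selected genome) and the core
#' size (orthogroups present in all selected genomes). The sd uses the
#' population denominator (the evaluated combination set is the object of
#' interest, not a sample from a larger one).
#'
#' @param matrix Presence/absence matrix (orthogroups x genomes, 0/1).
#' @param cap Per-m combination cap (default 5000).
#' @param seed Integer seed; each m uses a seed derived from it.
#' @return Object of class `pangenome_curve`: a data.frame with columns
#'   `m`, `pan_mean`, `pan_sd`, `core_mean`, `core_sd`, `n_combos`,
#'   `exhaustive`.
#' @export
pangenome_curve <- function(matrix, cap = 5000L, seed = 1L) {
  if (is.null(dim(matrix)) || nrow(matrix) == 0L || ncol(matrix) == 0L)
    stop("presence matrix is empty")
  M <- matrix != 0
  storage.mode(M) <- "double"
  n <- ncol(M)
  rows <- lapply(seq_len(n), function(m) {
    combos <- sample_combinations(n, m, cap = cap, seed = seed + m)
    ind <- matrix(0, length(combos), n)
    ind[cbind(rep(seq_along(combos), each = m), unlist(combos))] <- 1
    counts <- ind %*% t(M)           # combos x orthogroups
    pan <- rowSums(counts > 0)
    core <- rowSums(counts == m)
    pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
    data.frame(m = m, pan_mean = mean(pan), pan_sd = pop_sd(pan),
               core_mean = mean(core), core_sd = pop_sd(core),
               n_combos = length(combos),
               exhaustive = attr(combos, "exhaustive"))
  })
  out <- do.call(rbind, rows)
  structure(out, class = c("pangenome_curve", "data.frame"),
            n_genomes = n, n_ogs = nrow(matrix), cap = cap, seed = seed)
}

#' @export
print.pangenome_curve <- function(x, ...) {
  cat(sprintf("Pan/core rarefaction: %d orthogroups x %d genomes (cap %d)\n",
              attr(x, "n_ogs"), attr(x, "n_genomes"), attr(x, "cap")))
  print.data.frame(x, row.names = FALSE, digits = 5)
  invisible(x)
}

#' @export
plot.pangenome_curve <- function(x, ...) {
  graphics::plot(x$m, x$pan_mean, type = "b", pch = 19,
                 ylim = range(c(x$pan_mean, x$core_mean)),
                 xlab = "genomes sampled (m)", ylab = "orthogroups", ...)
  graphics::lines(x$m, x$core_mean, type = "b", pch = 1)
  graphics::legend("right", legend = c("pan", "core"), pch = c(19, 1),
                   bty = "n")
  invisible(x)
}

#' Closed-form expected pan and core sizes
#'
#' Exact expectation of the rarefaction statistics over all m-subsets:
#' `E[pan(m)] = sum_g (1 - C(n - k_g, m) / C(n, m))` and
#' `E[core(m)] = sum_g C(k_g, m) / C(n, m)`, where `k_g` is the number of
#' genomes carrying orthogroup `g`. The binomial ratios are evaluated as
#' running products of exact rationals, so no large binomials are formed.
#' Serves as the independent oracle for [pangenome_curve()] in the
#' exhaustive regime.
#'
#' @param matrix Presence/absence matrix.
#' @param m Subset size, `1 <= m <=` number of genomes.
#' @return Named numeric vector `c(pan = ..., core = ...)`.
#' @export
expected_pan_core_exact <- function(matrix, m) {
  n <- ncol(matrix)
  if (!.is_count(m) || m < 1 || m > n) stop("need 1 <= m <= n")
  k <- rowSums(matrix != 0)
  ratio_absent <- function(kk) {   # C(n - kk, m) / C(n, m)
    if (n - kk < m) return(0)
    prod((n - kk - seq_len(m) + 1) / (n - seq_len(m) + 1))
  }
  ratio_core <- function(kk) {     # C(kk, m) / C(n, m)
    if (kk < m) return(0)
    prod((kk - seq_len(m) + 1) / (n - seq_len(m) + 1))
  }
  tab <- table(k)
  kv <- as.numeric(names(tab))
  cnt <- as.numeric(tab)
  c(pan = sum(cnt * (1 - vapply(kv, ratio_absent, numeric(1)))),
    core = sum(cnt * vapply(kv, ratio_core, numeric(1))))
}

#' Fit Heaps' law to a rarefaction curve
#'
#' Two log-log least-squares fits: the pan-genome model
#' `P(N) = kappa * N^gamma` on the pan means, and the new-gene decay
#' `n_new(N) = kappa' * N^(-alpha)` on the successive pan-mean increments
#' `P(N) - P(N - 1)` for `N >= 2`. Non-positive increments are excluded
#' with a warning. By the classical openness criterion the pan-genome is
#' called open when `alpha <= 1`.
#'
#' @param curve A [pangenome_curve()] or any data.frame with columns `m`
#'   and `pan_mean` (>= 3 rows, positive pan means).
#' @return Object of class `heaps_fit` with elements `kappa_pan`, `gamma`,
#'   `kappa_new`, `alpha`, `rss_pan`, `rss_new` (residual sums of squares
#'   on the log scale), `open` and `n_points`.
#' @export
fit_heaps <- function(curve) {
  if (!all(c("m", "pan_mean") %in% names(curve)))
    stop("curve must have columns m and pan_mean")
  if (nrow(curve) < 3L) stop("need >= 3 curve points")
  if (any(curve$pan_mean <= 0)) stop("pan means must be positive")
  fit_pan <- lm(log(pan_mean) ~ log(m), data = curve)
  new_df <- data.frame(m = curve$m[-1], n_new = diff(curve$pan_mean))
  bad <- new_df$n_new <= 0
  if (any(bad)) {
    warning(sum(bad), " non-positive new-gene increment(s) excluded ",
            "from the decay fit")
    new_df <- new_df[!bad, , drop = FALSE]
  }
  if (nrow(new_df) < 3L)
    stop("fewer than 3 usable new-gene points for the decay fit")
  fit_new <- lm(log(n_new) ~ log(m), data = new_df)
  alpha <- -unname(coef(fit_new)[2])
  structure(list(
    kappa_pan = exp(unname(coef(fit_pan)[1])),
    gamma = unname(coef(fit_pan)[2]),
    kappa_new = exp(unname(coef(fit_new)[1])),
    alpha = alpha,
    rss_pan = sum(fit_pan$residuals^2),
    rss_new = sum(fit_new$residuals^2),
    open = alpha <= 1,
    n_points = c(pan = nrow(curve), new = nrow(new_df))),
    class = "heaps_fit")
}

#' @export
print.heaps_fit <- function(x, ...) {
  cat("Heaps'-law fit\n")
  cat(sprintf("  pan:  P(N) = %.4g * N^%.4f   (RSS %.3g, %d points)\n",
              x$kappa_pan, x$gamma, x$rss_pan, x$n_points["pan"]))
  cat(sprintf("  new:  n(N) = %.4g * N^-%.4f  (RSS %.3g, %d points)\n",
              x$kappa_new, x$alpha, x$rss_new, x$n_points["new"]))
  cat(sprintf("  pan-genome %s (alpha %s 1)\n",
              if (x$open) "OPEN" else "closed",
              if (x$open) "<=" else ">"))
  invisible(x)
}

#' @export
coef.heaps_fit <- function(object, ...) {
  c(kappa_pan = object$kappa_pan, gamma = object$gamma,
    kappa_new = object$kappa_new, alpha = object$alpha)
}

#' Average new genes per Mbp of added genome
#'
#' Genomes are added in random order; every genome after the first
#' contributes `(orthogroups not seen in any earlier genome) / (its
#' genome size in Mbp)`. The statistic is the mean contribution pooled
#' over positions and orders. The first genome of an order contributes no
#' term: the statistic measures what each *new* genome adds.
#'
#' @param matrix Presence/absence matrix.
#' @param genome_sizes Named vector of genome sizes in bp covering every
#'   matrix column.
#' @param n_orders Number of random addition orders to average (default
#'   100).
#' @param seed Integer seed.
#' @return Object of class `openness_result`: list with `value` (mean new
#'   orthogroups per Mbp), `per_order` (per-order means), `n_orders`,
#'   `seed`.
#' @export
openness_new_genes_per_mbp <- function(matrix, genome_sizes,
                                       n_orders = 100L, seed = 1L) {
  gs <- colnames(matrix)
  if (is.null(gs)) stop("matrix needs genome column names")
  missing <- setdiff(gs, names(genome_sizes))
  if (length(missing)) stop("missing genome size for ", missing[1])
  sizes_mb <- genome_sizes[gs] / 1e6
  M <- matrix != 0
  n <- ncol(M)
  contribs <- withr::with_seed(seed, {
    lapply(seq_len(n_orders), function(o) {
      ord <- sample.int(n)
      seen <- M[, ord[1]]
      out <- numeric(n - 1L)
      for (i in seq_len(n - 1L)) {
        g <- ord[i + 1L]
        out[i] <- sum(M[, g] & !seen) / sizes_mb[g]
        seen <- seen | M[, g]
      }
      out
    })
  })
  structure(list(value = mean(unlist(contribs)),
                 per_order = vapply(contribs, mean, numeric(1)),
                 n_orders = n_orders, seed = seed),
            class = "openness_result")
}

#' @export
print.openness_result <- function(x, ...) {
  cat(sprintf("New orthogroups per Mbp of added genome: %.3f (mean of %d random orders)\n",
              x$value, x$n_orders))
  invisible(x)
}

#' Detect lineage-enriched orthogroups
#'
#' Orthogroups enriched in a focal lineage but absent or scarce
#' elsewhere: prevalence >= `min_focal_prev` among focal genomes and <=
#' `max_other_prev` among all other genomes (both inclusive).
#'
#' @param matrix Presence/absence matrix.
#' @param lineage_map data.frame from [read_lineage_map()] covering every
#'   matrix genome.
#' @param focal Focal lineage label.
#' @param min_focal_prev Minimum focal prevalence (fraction, default 0.8).
#' @param max_other_prev Maximum non-focal prevalence (default 0.1).
#' @return Sorted character vector of enriched orthogroup ids.
#' @export
detect_enriched_ogs <- function(matrix, lineage_map, focal,
                                min_focal_prev = 0.8, max_other_prev = 0.1) {
  if (!focal %in% lineage_map$lineage) stop("unknown lineage: ", focal)
  gs <- colnames(matrix)
  missing <- setdiff(gs, lineage_map$genome_id)
  if (length(missing)) stop("genome not in lineage map: ", missing[1])
  lin <- lineage_map$lineage[match(gs, lineage_map$genome_id)]
  fc <- which(lin == focal)
  if (length(fc) == 0L) stop("no matrix genomes belong to lineage ", focal)
  oc <- which(lin != focal)
  M <- matrix != 0
  prev_focal <- rowMeans(M[, fc, drop = FALSE])
  prev_other <- if (length(oc)) rowMeans(M[, oc, drop = FALSE]) else
    rep(0, nrow(M))
  sort(rownames(matrix)[prev_focal >= min_focal_prev &
                          prev_other <= max_other_prev])
}

#' Filter genomes by assembly completeness
#'
#' Keeps genomes whose completeness is strictly greater than
#' `min_completeness` percent ("over 50%"). Completeness estimates are an
#' external input.
#'
#' @param genomes Character vector of genome ids.
#' @param completeness Named numeric vector (percent, 0-100) covering
#'   every genome.
#' @param min_completeness Strict lower bound (default 50).
#' @return The surviving genome ids, in input order.
#' @export
filter_genomes_by_completeness <- function(genomes, completeness,
                                           min_completeness = 50) {
  missing <- setdiff(genomes, names(completeness))
  if (length(missing)) stop("missing completeness for ", missing[1])
  vals <- completeness[genomes]
  if (any(is.na(vals) | vals < 0 | vals > 100))
    stop("completeness values must lie in [0, 100]")
  keep <- genomes[vals > min_completeness]
  if (length(keep) == 0L)
    warning("no genome exceeds ", min_completeness, "% completeness")
  keep
}
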