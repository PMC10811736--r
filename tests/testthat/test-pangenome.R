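test_that("count_combinations is exact, including beyond double precision", {
  expect_equal(count_combinations(5, 2), 10)
  expect_equal(count_combinations(7, 0), 1)
  expect_equal(count_combinations(7, 7), 1)
  expect_equal(count_combinations(23, 12), pascal_choose(23, 12))
  expect_equal(count_combinations(23, 12), 1352078)
  expect_error(count_combinations(5, 6), "exceed")
  # largest Pascal-checkable case that is still exact in a double
  expect_equal(count_combinations(56, 28), pascal_choose(56, 28))
  v200 <- count_combinations(200, 100)
  expect_type(v200, "character")
  expect_equal(nchar(v200), 59)  # ~9.05e58
})

test_that("sample_combinations is exhaustive below the cap, capped above", {
  all6 <- sample_combinations(4, 2, cap = 5000, seed = 1)
  expect_length(all6, 6)
  expect_true(attr(all6, "exhaustive"))
  expect_equal(all6, utils::combn(4, 2, simplify = FALSE),
               ignore_attr = TRUE)

  s <- sample_combinations(30, 15, cap = 100, seed = 2)
  expect_length(s, 100)
  expect_false(attr(s, "exhaustive"))
  keys <- vapply(s, paste, "", collapse = ",")
  expect_equal(anyDuplicated(keys), 0)

  expect_identical(sample_combinations(30, 15, cap = 100, seed = 2), s)
  expect_error(sample_combinations(4, 2, cap = 0), "cap")
})

test_that("rarefaction on the worked matrix matches hand enumeration", {
  cv <- pangenome_curve(m0_matrix(), seed = 1)
  expect_true(all(cv$exhaustive))
  # m=1: means are the per-genome orthogroup counts (4+3+3)/3
  expect_equal(cv$pan_mean[1], 10 / 3)
  expect_equal(cv$core_mean[1], 10 / 3)
  # m=2: pans 4,5,4 and cores 3,2,2 over the three pairs
  expect_equal(cv$pan_mean[2], 13 / 3)
  expect_equal(cv$core_mean[2], 7 / 3)
  # m=n: pan = all orthogroups, core = fully shared ones
  expect_equal(cv$pan_mean[3], 5)
  expect_equal(cv$core_mean[3], 2)
})

test_that("closed-form expectations match their algebraic identities", {
  M0 <- m0_matrix()
  expect_equal(expected_pan_core_exact(M0, 2),
               c(pan = 13 / 3, core = 7 / 3))
  expect_equal(expected_pan_core_exact(M0, 3), c(pan = 5, core = 2))
  k <- rowSums(M0)
  expect_equal(expected_pan_core_exact(M0, 1),
               c(pan = sum(k) / 3, core = sum(k) / 3))
  expect_error(expected_pan_core_exact(M0, 4), "m <= n")
})

test_that("exhaustive curve means equal the exact expectation", {
  set.seed(41)
  for (rep in 1:5) {
    M <- matrix(rbinom(30 * 6, 1, runif(1, 0.2, 0.8)), 30, 6,
                dimnames = list(sprintf("OG%02d", 1:30),
                                sprintf("g%d", 1:6)))
    cv <- pangenome_curve(M, seed = rep)
    for (m in 1:6) {
      ex <- expected_pan_core_exact(M, m)
      expect_lt(abs(cv$pan_mean[m] - ex["pan"]), 1e-12)
      expect_lt(abs(cv$core_mean[m] - ex["core"]), 1e-12)
    }
    expect_true(all(diff(cv$pan_mean) >= -1e-12))
    expect_true(all(diff(cv$core_mean) <= 1e-12))
  }
})

test_that("sampled curves stay near the closed-form expectation", {
  set.seed(42)
  M <- matrix(rbinom(50 * 16, 1, 0.5), 50, 16,
              dimnames = list(sprintf("OG%02d", 1:50),
                              sprintf("g%02d", 1:16)))
  cv <- pangenome_curve(M, cap = 400, seed = 7)
  for (m in which(!cv$exhaustive)) {
    ex <- expected_pan_core_exact(M, m)
    se <- cv$pan_sd[m] / sqrt(cv$n_combos[m])
    expect_lt(abs(cv$pan_mean[m] - ex["pan"]), 4 * max(se, 1e-6) + 0.05)
  }
})

test_that("Heaps fits recover noiseless power laws", {
  cur <- data.frame(m = 1:10, pan_mean = 10 * (1:10)^0.5)
  f <- fit_heaps(cur)
  expect_equal(f$gamma, 0.5, tolerance = 1e-9)
  expect_equal(f$kappa_pan, 10, tolerance = 1e-9)

  # exact new-gene decay n_new(N) = 50 * N^-0.8
  N <- 2:12
  cur2 <- data.frame(m = 1:12, pan_mean = cumsum(c(100, 50 * N^-0.8)))
  f2 <- fit_heaps(cur2)
  expect_equal(f2$alpha, 0.8, tolerance = 1e-9)
  expect_equal(f2$kappa_new, 50, tolerance = 1e-7)
  expect_true(f2$open)

  # non-positive increments are excluded with a warning; too few -> error
  cur3 <- data.frame(m = 1:4, pan_mean = c(10, 12, 12, 13))
  expect_warning(expect_error(fit_heaps(cur3), "usable"), "excluded")
  expect_error(fit_heaps(cur[1:2, ]), ">= 3")
})

test_that("openness statistic matches the worked example and the oracle", {
  M <- matrix(c(1, 0,
                1, 1,
                0, 1,
                0, 1), 4, 2, byrow = TRUE,
              dimnames = list(c("A", "B", "C", "D"), c("g1", "g2")))
  sizes <- c(g1 = 2e6, g2 = 1e6)
  # orders contribute 2/1 = 2.0 and 1/2 = 0.5; pooled mean 1.25
  op <- openness_new_genes_per_mbp(M, sizes, n_orders = 2000, seed = 1)
  expect_equal(op$value, openness_oracle(M, sizes), tolerance = 0.06)
  expect_equal(openness_oracle(M, sizes), 1.25)

  # identical genomes contribute nothing
  M2 <- matrix(1L, 5, 3, dimnames = list(sprintf("OG%d", 1:5),
                                         c("a", "b", "c")))
  expect_equal(openness_new_genes_per_mbp(
    M2, c(a = 1e6, b = 1e6, c = 1e6), n_orders = 10, seed = 1)$value, 0)

  # exhaustive-permutation oracle at n = 4
  set.seed(43)
  M3 <- matrix(rbinom(40, 1, 0.5), 10, 4,
               dimnames = list(sprintf("OG%02d", 1:10),
                               sprintf("g%d", 1:4)))
  sizes3 <- setNames(runif(4, 1e6, 4e6), colnames(M3))
  op3 <- openness_new_genes_per_mbp(M3, sizes3, n_orders = 4000, seed = 2)
  expect_equal(op3$value, openness_oracle(M3, sizes3), tolerance = 0.05)

  expect_error(openness_new_genes_per_mbp(M, c(g1 = 2e6)), "missing")
  expect_identical(openness_new_genes_per_mbp(M, sizes, seed = 5),
                   openness_new_genes_per_mbp(M, sizes, seed = 5))
})

test_that("lineage enrichment uses inclusive prevalence thresholds", {
  m <- matrix(c(1, 1, 0, 0,
                1, 1, 1, 1,
                1, 0, 0, 0), 3, 4, byrow = TRUE,
              dimnames = list(c("OGfocal", "OGall", "OGhalf"),
                              c("f1", "f2", "o1", "o2")))
  lmap <- data.frame(genome_id = c("f1", "f2", "o1", "o2"),
                     lineage = c("F", "F", "O", "O"),
                     genome_size_bp = 1e6)
  expect_equal(detect_enriched_ogs(m, lmap, "F"), "OGfocal")
  # prevalence 0.5 in focal is below the 0.8 default; all-genome OGs fail
  # the scarcity rule
  expect_equal(detect_enriched_ogs(m, lmap, "F", min_focal_prev = 0.5),
               c("OGfocal", "OGhalf"))
  expect_error(detect_enriched_ogs(m, lmap, "X"), "unknown lineage")
})

test_that("completeness filter is strict at its boundary", {
  comp <- c(g1 = 50.0, g2 = 50.1, g3 = 80)
  expect_equal(filter_genomes_by_completeness(names(comp), comp),
               c("g2", "g3"))
  expect_warning(
    out <- filter_genomes_by_completeness(c("g1"), comp),
    "no genome")
  expect_length(out, 0)
  expect_error(filter_genomes_by_completeness(c("g1", "gX"), comp),
               "missing completeness")
})
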