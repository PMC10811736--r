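test_that("marker extraction picks the best passing hit with fixed tie-breaks", {
  set.seed(61)
  ref <- random_protein(150)
  prots <- data.frame(
    gene_id = c("pexact", "pnoise"),
    genome_id = "g1",
    seq = c(ref, random_protein(150)))
  res <- extract_markers(prots, data.frame(id = "m1", desc = "", seq = ref))
  expect_equal(res$gene_id, "pexact")
  expect_equal(res$pident, 100)

  # two identical candidates: equal score, equal length -> lexicographic id
  prots2 <- data.frame(gene_id = c("pb", "pa"), genome_id = "g1",
                       seq = c(ref, ref))
  res2 <- extract_markers(prots2, data.frame(id = "m1", desc = "", seq = ref))
  expect_equal(res2$gene_id, "pa")

  # tie on score, different lengths -> longer protein wins
  longer <- paste0(ref, random_protein(40))
  prots3 <- data.frame(gene_id = c("pshort", "plong"), genome_id = "g1",
                       seq = c(ref, longer))
  res3 <- extract_markers(prots3, data.frame(id = "m1", desc = "", seq = ref))
  expect_equal(res3$gene_id, "plong")

  # genome with no passing marker -> warning, absent from table
  prots4 <- rbind(prots,
                  data.frame(gene_id = "q1", genome_id = "g2",
                             seq = paste(rep("GHIKL", 30), collapse = "")))
  expect_warning(res4 <- extract_markers(
    prots4, data.frame(id = "m1", desc = "", seq = ref)), "no markers")
  expect_false("g2" %in% res4$genome_id)
})

test_that("planted markers are selected correctly at 20% divergence", {
  set.seed(62)
  refs <- data.frame(id = sprintf("m%d", 1:5), desc = "",
                     seq = replicate(5, random_protein(180)))
  rows <- list()
  for (g in c("g1", "g2", "g3")) {
    for (i in 1:5)
      rows[[length(rows) + 1]] <- data.frame(
        gene_id = sprintf("%s_m%d", g, i), genome_id = g,
        seq = evolve_sequence(refs$seq[i], 0.2,
                              1000 + 10 * i + match(g, c("g1", "g2", "g3")),
                              alphabet = "protein"))
    for (i in 1:3)
      rows[[length(rows) + 1]] <- data.frame(
        gene_id = sprintf("%s_x%d", g, i), genome_id = g,
        seq = random_protein(180))
  }
  prots <- do.call(rbind, rows)
  res <- extract_markers(prots, refs)
  expect_equal(nrow(res), 15)
  expect_true(all(res$gene_id == sprintf("%s_%s", res$genome_id,
                                         res$marker_id)))
})

test_that("conserved-block selection follows the stated column rules", {
  # planted [10, 40): gap-free unanimous inside, half-gaps outside
  sim <- simulate_marker_alignment(8, 100, data.frame(start = 10, end = 40),
                                   seed = 63)
  bs <- select_conserved_blocks(sim$alignment)
  expect_equal(bs$intervals, data.frame(start = 10L, end = 40L))

  # all-unanimous alignment of length 50 -> one full-range block
  uni <- data.frame(id = sprintf("s%d", 1:6), desc = "",
                    seq = rep(strrep("ACDEF", 10), 6))
  expect_equal(select_conserved_blocks(uni)$intervals,
               data.frame(start = 0L, end = 50L))

  # unanimous run of 9 with BL = 10 -> nothing survives
  sim9 <- simulate_marker_alignment(8, 60, data.frame(start = 20, end = 29),
                                    seed = 64)
  expect_equal(nrow(select_conserved_blocks(sim9$alignment)$intervals), 0)

  expect_error(select_conserved_blocks(uni[1:3, ]), ">= 4")
})

test_that("block selection is idempotent on its own output", {
  set.seed(65)
  for (rep in 1:5) {
    sim <- simulate_marker_alignment(
      8, 150, data.frame(start = c(15, 70), end = c(45, 110)),
      seed = 650 + rep)
    bs <- select_conserved_blocks(sim$alignment)
    kept <- vapply(sim$alignment$seq, function(s)
      paste(substring(s, bs$intervals$start + 1, bs$intervals$end),
            collapse = ""), "", USE.NAMES = FALSE)
    proj <- data.frame(id = sim$alignment$id, desc = "", seq = kept)
    bs2 <- select_conserved_blocks(proj)
    expect_equal(bs2$intervals,
                 data.frame(start = 0L, end = nchar(kept[1])))
  }
})

test_that("supermatrix concatenation tiles partitions and gap-fills", {
  s1 <- simulate_marker_alignment(6, 80, data.frame(start = 10, end = 40),
                                  seed = 66)
  s2 <- simulate_marker_alignment(6, 60, data.frame(start = 20, end = 40),
                                  seed = 67)
  b1 <- select_conserved_blocks(s1$alignment)
  b2 <- select_conserved_blocks(s2$alignment)
  # drop genome s06 from marker m2 -> it gets gap-filled there
  a2 <- s2$alignment[s2$alignment$id != "s06", ]
  sm <- concatenate_markers(list(m1 = b1, m2 = b2),
                            list(m1 = s1$alignment, m2 = a2))
  expect_equal(sm$length, 30 + 20)
  expect_equal(sm$partitions$name, c("m1", "m2"))
  expect_equal(sm$partitions$start, c(1L, 31L))
  expect_equal(sm$partitions$end, c(30L, 50L))
  expect_true(all(nchar(sm$rows$seq) == sm$length))
  row6 <- sm$rows$seq[sm$rows$id == "s06"]
  expect_equal(substring(row6, 31, 50), strrep("-", 20))
  # its partition table passes the io validator
  tf <- withr::local_tempfile()
  write_partition_file(sm$partitions, tf)
  expect_length(readLines(tf), 2)

  # a genome missing too much is dropped with a warning
  a2b <- s2$alignment[s2$alignment$id %in% c("s01", "s02", "s03", "s04"), ]
  a1b <- s1$alignment[s1$alignment$id %in% c("s01", "s02", "s03", "s04",
                                             "s05"), ]
  expect_warning(
    sm2 <- concatenate_markers(list(m1 = b1, m2 = b2),
                               list(m1 = a1b, m2 = a2b),
                               genome_universe = sprintf("s%02d", 1:6)),
    "dropping")
  expect_false("s06" %in% sm2$rows$id)

  # zero kept columns overall -> error
  empty <- structure(list(intervals = data.frame(start = integer(0),
                                                 end = integer(0))),
                     class = "conserved_blocks")
  expect_error(concatenate_markers(list(m1 = empty),
                                   list(m1 = s1$alignment)),
               "empty supermatrix")
})
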