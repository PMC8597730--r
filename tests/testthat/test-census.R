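test_that("copy counts pool vnf/anf with their nifD/nifK counterparts", {
  g1 <- make_genome("C1", data.frame(gene = c("nifH", "nifD", "nifK"),
                                     strand = "+", stringsAsFactors = FALSE))
  expect_equal(nitrogenase_copy_counts(g1),
               c(n_H = 1L, n_Dlike = 1L, n_Klike = 1L))

  g2 <- make_genome("C2", data.frame(gene = c("nifH", "vnfD"),
                                     strand = "+", stringsAsFactors = FALSE))
  expect_equal(nitrogenase_copy_counts(g2),
               c(n_H = 1L, n_Dlike = 1L, n_Klike = 0L))

  # two nifH copies split over chromosome and plasmid
  g3 <- make_genome("C3", data.frame(gene = c("nifH", "nifH"),
                                     strand = "+",
                                     replicon = c("chr", "plasmid1"),
                                     stringsAsFactors = FALSE))
  expect_equal(nitrogenase_copy_counts(g3)[["n_H"]], 2L)
})

test_that("copy-balance categories partition all count vectors", {
  cb <- function(h, d, k) copy_balance_category(c(n_H = h, n_Dlike = d, n_Klike = k))
  expect_equal(cb(1, 1, 1)$category, "EQUAL")
  expect_equal(cb(2, 1, 1)$category, "H_EXCESS")
  expect_false(cb(2, 1, 1)$only_H)
  expect_equal(cb(3, 0, 0)$category, "H_EXCESS")
  expect_true(cb(3, 0, 0)$only_H)
  expect_equal(cb(0, 1, 0)$category, "NO_H")
  expect_equal(cb(1, 2, 1)$category, "OTHER_IMBALANCE")
  expect_error(cb(0, 0, 0))

  # total partition + only_H implies H_EXCESS, fuzzed
  set.seed(9)
  for (i in 1:200) {
    h <- sample(0:4, 1); d <- sample(0:4, 1); k <- sample(0:4, 1)
    if (h + d + k == 0) next
    r <- cb(h, d, k)
    expect_true(r$category %in% c("EQUAL", "H_EXCESS", "NO_H", "OTHER_IMBALANCE"))
    if (r$only_H) expect_equal(r$category, "H_EXCESS")
  }
})

test_that("nifH typing follows the same-strand neighborhood rule", {
  # nifD adjacent, same strand -> T1
  t1 <- make_genome("T1g", data.frame(gene = c("nifH", "nifD"), strand = "+",
                                      stringsAsFactors = FALSE))
  expect_equal(classify_nifh(t1)$nifh_type, "T1")

  # nifD 11 same-strand CDSs away on the same replicon -> T2
  plan <- data.frame(gene = c("nifH", rep("recA", 10), "nifD"), strand = "+",
                     stringsAsFactors = FALSE)
  t2 <- make_genome("T2g", plan)
  expect_equal(classify_nifh(t2)$nifh_type, "T2")
  # ... and exactly at the radius (10 positions) -> T1
  plan10 <- data.frame(gene = c("nifH", rep("recA", 9), "nifD"), strand = "+",
                       stringsAsFactors = FALSE)
  expect_equal(classify_nifh(make_genome("T1b", plan10))$nifh_type, "T1")

  # sole nifH -> T3
  t3 <- make_genome("T3g", data.frame(gene = c("nifH", "recA"), strand = "+",
                                      stringsAsFactors = FALSE))
  expect_equal(classify_nifh(t3)$nifh_type, "T3")

  # vnfK three CDSs away -> T1
  plan_v <- data.frame(gene = c("nifH", "recA", "gyrB", "vnfK"), strand = "+",
                       stringsAsFactors = FALSE)
  expect_equal(classify_nifh(make_genome("T1v", plan_v))$nifh_type, "T1")

  # opposite-strand nifD does not count as a neighbor (but makes T2)
  plan_o <- data.frame(gene = c("nifH", "nifD"), strand = c("+", "-"),
                       stringsAsFactors = FALSE)
  call_o <- classify_nifh(make_genome("T2o", plan_o))
  expect_equal(call_o$nifh_type, "T2")
  expect_equal(call_o$n_neighborhood_hits, 0L)

  # opposite-strand CDSs do not consume neighborhood distance
  plan_s <- data.frame(gene = c("nifH", rep("recA", 15), "nifD"),
                       strand = c("+", rep("-", 15), "+"),
                       stringsAsFactors = FALSE)
  expect_equal(classify_nifh(make_genome("T1s", plan_s))$nifh_type, "T1")

  # neighborhood never spans replicons
  plan_r <- data.frame(gene = c("nifH", "nifD"), strand = "+",
                       replicon = c("chr", "plasmid1"),
                       stringsAsFactors = FALSE)
  expect_equal(classify_nifh(make_genome("T2r", plan_r))$nifh_type, "T2")
})

test_that("typing agrees with the brute-force coordinate oracle on fuzzed genomes", {
  set.seed(1234)
  for (i in 1:200) {
    g <- random_fuzz_genome(sprintf("F%04d", i))
    got <- classify_nifh(g)
    want <- oracle_classify_nifh(g)
    expect_equal(got$nifh_type, want$nifh_type, info = g$genome_id)
    # mutual exclusion: T3 never coexists with T1/T2 on a genome
    if (nrow(got) > 0 && any(got$nifh_type == "T3")) {
      expect_true(all(got$nifh_type == "T3"), info = g$genome_id)
    }
  }
})

test_that("a shared nifD is evidence for two nifH copies", {
  plan <- data.frame(gene = c("nifH", "nifD", "nifH"), strand = "+",
                     stringsAsFactors = FALSE)
  calls <- classify_nifh(make_genome("SH", plan))
  expect_equal(calls$nifh_type, c("T1", "T1"))
})

test_that("percentage reproduces printed ratios with half-even rounding", {
  expect_equal(percentage(1457, 6529), 22.3)
  expect_equal(percentage(96, 1457, 2), 6.59)
  expect_equal(percentage(0, 100), 0)
  expect_error(percentage(1, 0))
  expect_error(percentage(5, 4))
})

test_that("census summary counts genomes once per type flag", {
  g_t1 <- lapply(1:10, function(i) {
    make_genome(paste0("A", i), data.frame(gene = c("nifH", "nifD"),
                                           strand = "+", stringsAsFactors = FALSE))
  })
  g_t3 <- lapply(1:5, function(i) {
    make_genome(paste0("B", i), data.frame(gene = "nifH", strand = "+",
                                           stringsAsFactors = FALSE))
  })
  s <- census_summary(setNames(c(g_t1, g_t3), c(paste0("A", 1:10), paste0("B", 1:5))))
  expect_equal(s$types$n_genomes, c(10L, 0L, 5L))

  # a genome carrying both T1 and T2 counts once in each flag
  plan <- data.frame(gene = c("nifH", "nifD", "nifK", rep("recA", 12), "nifH"),
                     strand = "+", stringsAsFactors = FALSE)
  g_both <- make_genome("AB", plan)
  s2 <- census_summary(list(AB = g_both))
  f <- s2$flags
  expect_true(f$has_T1 && f$has_T2)
  expect_equal(s2$types$n_genomes, c(1L, 0L, 0L))

  # empty input: all-zero summary
  s3 <- census_summary(list())
  expect_true(all(s3$types$n_genomes == 0))
})
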