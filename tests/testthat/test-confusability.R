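test_that("greedy clustering collapses identical and separates distant sequences", {
  set.seed(14)
  s <- rand_protein(120)
  five <- setNames(rep(s, 5), paste0("s", 1:5))
  cl <- cluster_greedy(five, 0.95)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$size, 5L)

  # two families at ~50% identity stay apart (checked against all-pairs identities)
  a <- rand_protein(150); b <- rand_protein(150)
  fams <- setNames(c(a, a, b, b), c("a1", "a2", "b1", "b2"))
  expect_lt(global_identity(a, b), 0.95)
  expect_equal(nrow(cluster_greedy(fams, 0.95)), 2L)

  one <- setNames(rand_protein(100), "solo")
  expect_equal(cluster_greedy(one, 0.95)$rep_id, "solo")
  expect_equal(nrow(cluster_greedy(character(0), 0.95)), 0L)
})

test_that("fragment sampling respects lengths, counts and the skip rule", {
  set.seed(15)
  rep300 <- rand_protein(300)
  fr <- sample_subsequences(rep300, "r1", seed = 2)
  expect_equal(nrow(fr), 40L)  # 4 lengths x 10
  expect_equal(as.integer(table(fr$length)), rep(10L, 4))
  expect_true(all(nchar(fr$sequence) == fr$length))

  rep90 <- rand_protein(90)
  expect_warning(fr90 <- sample_subsequences(rep90, "r2", seed = 2), "skip")
  expect_setequal(unique(fr90$length), c(40L, 60L, 80L))

  expect_identical(sample_subsequences(rep300, "r1", seed = 2), fr)
})

test_that("partial mapping verdicts follow the opposite-label rule", {
  set.seed(16)
  t12_ref <- rand_protein(300)
  t3_ref <- rand_protein(300)
  refs <- setNames(c(t12_ref, t3_ref), c("r_t12", "r_t3"))
  labels <- c("T12", "T3")

  q <- data.frame(query_id = "q1", sequence = substr(t12_ref, 50, 129),
                  origin = "T12", stringsAsFactors = FALSE)
  expect_equal(map_partials(q, refs, labels, 0.95)$verdict, "correct")

  # a query identical to references of both labels is incorrect
  both <- setNames(c(t12_ref, t12_ref), c("r_t12", "r_imposter_t3"))
  expect_equal(map_partials(q, both, c("T12", "T3"), 0.95)$verdict, "incorrect")

  gib <- data.frame(query_id = "g", sequence = rand_protein(80),
                    origin = "T12", stringsAsFactors = FALSE)
  expect_equal(map_partials(gib, refs, labels, 0.95)$verdict, "unmapped")
})

test_that("incorrect-mapping rates exclude unmapped and handle empty cells", {
  res <- data.frame(
    query_id = paste0("q", 1:5), origin = "T12",
    length = c(40, 40, 40, 40, 60),
    n_hits = c(1, 1, 1, 0, 0), n_opposite = c(1, 0, 0, 0, 0),
    verdict = c("incorrect", "correct", "correct", "correct", "unmapped"),
    threshold = 0.95, stringsAsFactors = FALSE)
  r <- incorrect_mapping_rate(res)
  expect_equal(r$rate[r$length == 40], 0.25)
  expect_true(is.na(r$rate[r$length == 60]))
  expect_equal(r$n_unmapped[r$length == 60], 1L)
})

test_that("removing opposite-label references eliminates incorrect verdicts", {
  fam <- gen_protein_family(sim_family_spec(6, 6, 200, 0.05, 0.10, seed = 18))
  refs <- setNames(fam$sequence, fam$seq_id)
  labels <- fam$label
  q <- do.call(rbind, lapply(1:3, function(k) {
    d <- sample_subsequences(refs[[k]], names(refs)[k],
                             lengths = c(40L, 60L), n_per_length = 5L,
                             seed = k)
    d$origin <- labels[k]
    d
  }))
  only_t12 <- map_partials(q, refs[labels == "T12"],
                           labels[labels == "T12"], 0.90)
  expect_true(all(only_t12$verdict %in% c("correct", "unmapped")))

  # hit sets nest across thresholds: rate at 0.95 cannot exceed rate at 0.90
  r90 <- map_partials(q, refs, labels, 0.90)
  r95 <- map_partials(q, refs, labels, 0.95)
  rates <- incorrect_mapping_rate(rbind(r90, r95))
  for (len in unique(rates$length)) {
    sub <- rates[rates$length == len, ]
    if (all(!is.na(sub$rate))) {
      expect_lte(sub$rate[sub$threshold == 0.95],
                 sub$rate[sub$threshold == 0.90])
    }
  }
})

test_that("MSA windows degap, exclude gappy rows, and skip overruns", {
  base <- rand_protein(340)
  msa <- c(s1 = base,
           s2 = paste0(substr(base, 1, 40),
                       strrep("-", 10), substr(base, 51, 340)),
           s3 = paste0(strrep("-", 70), substr(base, 71, 340)))
  cfg <- nif_config(msa_starts = c(31L), msa_window = 40L)
  w <- msa_windows(msa, cfg)[["31-70"]]
  expect_equal(w$n_residues[w$seq_id == "s1"], 40L)
  expect_equal(w$n_residues[w$seq_id == "s2"], 30L)  # 10 gaps in window
  expect_false("s3" %in% w$seq_id)                   # all-gap window excluded
  expect_equal(attr(w, "n_excluded"), 1L)

  cfg2 <- nif_config(msa_starts = c(331L), msa_window = 40L)
  expect_warning(out <- msa_windows(msa, cfg2), "skipped")
  expect_length(out, 0L)

  # row order does not change per-sequence outcomes
  w2 <- msa_windows(msa[c(3, 1, 2)], cfg)[["31-70"]]
  expect_setequal(w$seq_id, w2$seq_id)
  expect_equal(w2$n_residues[match(w$seq_id, w2$seq_id)], w$n_residues)
})

test_that("window networks classify confusing nodes like the pairwise oracle", {
  set.seed(19)
  # two well-separated cliques: nothing confusing
  a <- rand_protein(40); b <- rand_protein(40)
  sub <- data.frame(seq_id = c("a1", "a2", "b1", "b2"),
                    subseq = c(a, a, b, b), stringsAsFactors = FALSE)
  lab <- c("T12", "T12", "T3", "T3")
  wc <- window_confusion(sub, lab, 0.95)
  expect_true(all(wc$nodes$class == "distinct"))
  expect_equal(unname(wc$proportions), c(0, 0))

  # an identical cross-label pair is confusing on both sides
  sub2 <- data.frame(seq_id = c("x", "y"), subseq = c(a, a),
                     stringsAsFactors = FALSE)
  wc2 <- window_confusion(sub2, c("T12", "T3"), 0.95)
  expect_true(all(wc2$nodes$class == "confusing"))

  # fuzzed agreement with the independent double-loop oracle
  fam <- gen_protein_family(sim_family_spec(8, 8, 150, 0.03, 0.08, seed = 20))
  msa <- setNames(fam$sequence, fam$seq_id)  # equal-length, gap-free
  cfg <- nif_config(msa_starts = c(31L, 71L), msa_window = 40L)
  wins <- msa_windows(msa, cfg)
  labels <- setNames(fam$label, fam$seq_id)
  for (w in wins) {
    for (th in c(0.90, 0.95)) {
      wc <- window_confusion(w, labels[w$seq_id], th)
      want <- oracle_confusing(setNames(w$subseq, w$seq_id),
                               labels[w$seq_id], th)
      expect_equal(wc$nodes$class == "confusing", unname(want))
    }
  }

  expect_warning(window_confusion(sub[1:2, ], c("T12", "T12"), 0.95),
                 "single-label")
})
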