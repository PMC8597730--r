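test_that("stage-1 screen recovers nitrogenase-derived reads and rejects noise", {
  set.seed(22)
  pan <- make_screen_panel(seed = 23, n_per_clade = 3)
  # error-free read cut from a nifD reference
  dna <- withr::with_seed(24, back_translate(pan$refs[["nifD_ref"]]))
  reads <- data.frame(read_id = "r1", seq = substr(dna, 101, 350),
                      stringsAsFactors = FALSE)
  cand <- screen_stage1(reads, pan$refs)
  expect_equal(cand$read_id, "r1")

  # a read with one substitution stays a candidate
  mut <- reads
  substr(mut$seq, 60, 60) <- if (substr(mut$seq, 60, 60) == "A") "C" else "A"
  expect_equal(nrow(screen_stage1(mut, pan$refs)), 1L)

  # random background reads are never candidates at default thresholds
  bg <- data.frame(read_id = sprintf("b%04d", 1:1000),
                   seq = vapply(1:1000, function(i) {
                     paste(sample(c("A", "C", "G", "T"), 250, TRUE),
                           collapse = "")
                   }, ""), stringsAsFactors = FALSE)
  expect_equal(nrow(screen_stage1(bg, pan$refs)), 0L)
})

test_that("gene assignment picks the best group and filters decoys", {
  pan <- make_screen_panel(seed = 25, n_per_clade = 3)
  h_dna <- withr::with_seed(26, back_translate(pan$true_seqs[[1]]))
  d_dna <- withr::with_seed(27, back_translate(pan$refs[["nifD_ref"]]))
  dec_dna <- withr::with_seed(28, back_translate(pan$decoys[[1]]))
  cand <- data.frame(read_id = c("h", "d", "x"),
                     seq = c(substr(h_dna, 1, 250), substr(d_dna, 1, 250),
                             substr(dec_dna, 1, 250)),
                     stringsAsFactors = FALSE)
  panel <- c(pan$refs, pan$decoys)
  groups <- c(pan$groups, rep("decoy", length(pan$decoys)))
  got <- assign_gene(cand, panel, groups)
  expect_equal(got$assigned_gene, c("nifH", "nifD_like", "none"))

  # exact tie between two references resolves deterministically by ref id
  dup_panel <- setNames(c(pan$true_seqs[[1]], pan$true_seqs[[1]]), c("b", "a"))
  got2 <- assign_gene(cand[1, ], dup_panel, c("nifH", "nifH"))
  expect_equal(got2$best_ref, "a")
})

test_that("hit retention arithmetic drives the read verdict trichotomy", {
  cfg <- nif_config()
  # 0.94 >= 0.95 * 0.98 = 0.931 -> T3 hit retained -> ambiguous
  v1 <- pseudonif:::verdict_from_identities(
    c(t1 = 0.98, t3 = 0.94), c("T1", "T3"), cfg)
  expect_equal(v1$verdict, "ambiguous")
  # 0.92 < 0.931 -> T3 hit dropped -> true
  v2 <- pseudonif:::verdict_from_identities(
    c(t1 = 0.98, t3 = 0.92), c("T1", "T3"), cfg)
  expect_equal(v2$verdict, "true_nifH")
  # all retained hits T3 -> pseudo; T2 counts as a true anchor
  expect_equal(pseudonif:::verdict_from_identities(
    c(t3 = 0.97), "T3", cfg)$verdict, "pseudo_nifH")
  expect_equal(pseudonif:::verdict_from_identities(
    c(t2 = 0.97), "T2", cfg)$verdict, "true_nifH")

  # trichotomy is total and exclusive over fuzzed identity profiles
  set.seed(29)
  for (i in 1:300) {
    n <- sample(2:6, 1)
    ids <- setNames(runif(n, 0.5, 1), paste0("r", 1:n))
    types <- sample(c("T1", "T2", "T3"), n, replace = TRUE)
    v <- pseudonif:::verdict_from_identities(ids, types, cfg)
    expect_true(v$verdict %in% c("true_nifH", "pseudo_nifH", "ambiguous", "n/a"))
    if (v$verdict != "n/a") {
      kept <- types[v$retained]
      expect_true(length(kept) > 0)
      if (v$verdict == "true_nifH") expect_true(all(kept %in% c("T1", "T2")))
      if (v$verdict == "pseudo_nifH") expect_true(all(kept == "T3"))
      if (v$verdict == "ambiguous") {
        expect_true(any(kept == "T3") && any(kept %in% c("T1", "T2")))
      }
    }
  }
})

test_that("raising the retention factor shrinks the retained set monotonically", {
  set.seed(30)
  for (i in 1:100) {
    ids <- runif(6, 0.6, 1)
    lo <- pseudonif:::retained_hits(ids, max(ids), nif_config(hit_retention_factor = 0.90))
    hi <- pseudonif:::retained_hits(ids, max(ids), nif_config(hit_retention_factor = 0.97))
    expect_true(all(which(hi) %in% which(lo)))
  }
})

test_that("classify_nifh_read works end-to-end on a single read", {
  pan <- make_screen_panel(seed = 31, n_per_clade = 3)
  dna <- withr::with_seed(32, back_translate(pan$true_seqs[[1]]))
  v <- classify_nifh_read(substr(dna, 101, 350),
                          c(pan$true_seqs, pan$pseudo_seqs),
                          unname(pan$types))
  expect_equal(v$verdict, "true_nifH")
  expect_warning(classify_nifh_read("AAATTTAAATTTAAATTTAAAGGGTTTAAATTTAAATTTAAATTTAAATTTAAATTTAAATTTAAA",
                                    pan$true_seqs[1], "T1"), "n/a")
})

test_that("overestimation factor is the reciprocal of the true proportion", {
  expect_equal(overestimation_factor(c(true_nifH = 10, pseudo_nifH = 0,
                                       ambiguous = 0)), 1.0)
  expect_equal(overestimation_factor(c(true_nifH = 25, pseudo_nifH = 25,
                                       ambiguous = 50)), 4.0)
  expect_message(
    f <- overestimation_factor(c(true_nifH = 0, pseudo_nifH = 5, ambiguous = 0)))
  expect_true(is.na(f))
  expect_error(overestimation_factor(c(true_nifH = 0, pseudo_nifH = 0,
                                       ambiguous = 0)))
})

test_that("the Poisson proportionality test matches its worked examples", {
  # both counts zero: the origin lies on every line through the origin
  expect_equal(proportionality_test(0, 0, 894, 1497)$verdict, "consistent")
  # zero nifD against 1000 nifH: far off the length ratio
  expect_equal(proportionality_test(0, 1000, 894, 1497)$verdict, "deviating")
  # 597 vs 1000 sits on the 0.597 length-ratio line
  expect_equal(proportionality_test(597, 1000, 894, 1497)$verdict, "consistent")
  # CI shape: exact chi-square bounds, lower 0 at x = 0
  ci0 <- poisson_ci(0, 0.99)
  expect_equal(ci0[["lower"]], 0)
  expect_equal(ci0[["upper"]], qchisq(0.995, 2) / 2)
  ci5 <- poisson_ci(5, 0.99)
  expect_equal(ci5[["lower"]], qchisq(0.005, 10) / 2)
  expect_equal(ci5[["upper"]], qchisq(0.995, 12) / 2)
})

test_that("qc + screen handles tiny in-memory samples", {
  pan <- make_screen_panel(seed = 33, n_per_clade = 3)
  mg <- gen_metagenome(sim_metagenome_spec(
    150, 150, mix = c(true_nifH = 0.4, pseudo_nifH = 0.2, nifD = 0, nifK = 0,
                      background = 0.4), insert_length = 250, seed = 34),
    sources = list(true_nifH = pan$true_seqs, pseudo_nifH = pan$pseudo_seqs))
  expect_error(qc_reads(mg$r1, list(ids = mg$r2$ids[-1], seqs = mg$r2$seqs[-1],
                                    quals = mg$r2$quals[-1])), "unequal")
  res <- screen_metagenome(mg$r1, mg$r2, pan$refs, pan$groups, pan$types,
                           decoys = pan$decoys, sample_id = "tiny")
  s <- res$summary
  expect_equal(s$n_nifD_like + s$n_nifK_like, 0L)
  expect_gt(s$n_nifH, 0L)
  # proportions over classified nifH reads sum to one
  expect_equal(s$prop_true + s$prop_pseudo + s$prop_ambiguous, 1.0)
  # verdicts only on nifH-assigned reads
  expect_true(all(is.na(res$per_read$verdict[res$per_read$assigned_gene != "nifH"])))

  # background-only sample: zero counts everywhere
  bg <- gen_metagenome(sim_metagenome_spec(
    60, 150, mix = c(true_nifH = 0, pseudo_nifH = 0, nifD = 0, nifK = 0,
                     background = 1), insert_length = 250, seed = 35))
  res_bg <- screen_metagenome(bg$r1, bg$r2, pan$refs, pan$groups, pan$types,
                              sample_id = "bg")
  expect_equal(res_bg$summary$n_nifH, 0L)
  expect_equal(res_bg$summary$n_true, 0L)

  # determinism of the whole pipeline
  res2 <- screen_metagenome(mg$r1, mg$r2, pan$refs, pan$groups, pan$types,
                            decoys = pan$decoys, sample_id = "tiny")
  expect_identical(res$summary, res2$summary)
})

test_that("merged reads below the length floor are dropped and the cap binds", {
  cfg <- nif_config(min_merged_length = 200L)
  # insert of 180 bases: merged read trims below 200 -> dropped
  mg <- gen_metagenome(sim_metagenome_spec(
    30, 120, mix = c(true_nifH = 0, pseudo_nifH = 0, nifD = 0, nifK = 0,
                     background = 1), insert_length = 180, seed = 36))
  out <- qc_reads(mg$r1, mg$r2, cfg)
  expect_equal(nrow(out), 0L)

  # cap: only the first reads_cap filtered reads are retained
  mg2 <- gen_metagenome(sim_metagenome_spec(
    40, 150, mix = c(true_nifH = 0, pseudo_nifH = 0, nifD = 0, nifK = 0,
                     background = 1), insert_length = 250, seed = 37))
  out2 <- qc_reads(mg2$r1, mg2$r2, nif_config(reads_cap = 10L))
  expect_equal(nrow(out2), 10L)
  st <- attr(out2, "stats")
  expect_equal(st[["n_retained"]], 10L)
  expect_equal(st[["below_cap"]], 0L)
})
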