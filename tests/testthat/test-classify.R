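test_that("consequence classification follows the transcript rules", {
  # most severe across transcripts governs outside the known-gene list
  expect_identical(
    classify_consequence(c(t1 = "stop gained", t2 = "intronic")),
    "functional")
  # for known genes only the clinically relevant transcript counts
  expect_identical(
    classify_consequence(c(t1 = "synonymous coding",
                           t2 = "non synonymous coding"),
                         known_gene = TRUE,
                         clinically_relevant_transcript = "t1"),
    "synonymous")
  expect_identical(
    classify_consequence(c(t1 = "synonymous coding",
                           t2 = "synonymous coding")),
    "synonymous")
  expect_identical(classify_consequence(c(t1 = "intronic")), "other")
  expect_error(classify_consequence(character()), "at least one")
  expect_error(
    classify_consequence(c(t1 = "stop gained"), known_gene = TRUE),
    "clinically")
})

test_that("rarity thresholds and novelty follow the panel rules", {
  # pooled internal MAF 2% -> excluded
  rows <- make_panel_rows(int_ac = rep(7L, 13), int_an = rep(320L, 13))
  expect_identical(classify_rarity(rows), "excluded")
  # pooled 0.5% but one internal panel at 12% -> excluded
  ac <- rep(0L, 13); ac[4] <- 38L
  rows <- make_panel_rows(int_ac = ac)
  expect_identical(classify_rarity(rows), "excluded")
  # external panel above 1% -> excluded
  rows <- make_panel_rows(int_ac = c(1L, rep(0L, 12)),
                          ext_ac = c(60L, rep(0L, 6)))
  expect_identical(classify_rarity(rows), "excluded")
  # seen once in one panel only -> rare
  rows <- make_panel_rows(int_ac = c(1L, rep(0L, 12)))
  expect_identical(classify_rarity(rows), "rare")
  # unobserved everywhere -> novel
  expect_identical(classify_rarity(make_panel_rows()), "novel")
  # missing panels are a configuration error
  expect_error(classify_rarity(make_panel_rows()[-1, ]), "panels")
})

test_that("relaxing any MAF threshold never shrinks the rare set", {
  withr::with_seed(20, {
    for (rep in 1:20) {
      ac <- as.integer(rbinom(13, 320, runif(1, 0, 0.05)))
      ec <- as.integer(rbinom(7, 2000, runif(1, 0, 0.02)))
      rows <- make_panel_rows(int_ac = ac, ext_ac = ec)
      base <- classify_rarity(rows)
      relaxed <- classify_rarity(rows, maf_internal_pooled = 0.05,
                                 maf_internal_single = 0.2,
                                 maf_external = 0.05)
      if (base == "rare") expect_identical(relaxed, "rare")
      if (base == "novel") expect_identical(relaxed, "novel")
    }
  })
})

test_that("deleteriousness strata use the exact accepted label sets", {
  expect_identical(deleteriousness_stratum("deleterious", "benign",
                                           "neutral"), "one_plus")
  expect_identical(deleteriousness_stratum("deleterious",
                                           "probably damaging",
                                           "deleterious"), "all_three")
  # "possibly damaging" is not an accepted PolyPhen label
  expect_identical(deleteriousness_stratum(NA, "possibly damaging", NA),
                   "none")
  expect_identical(deleteriousness_stratum(NA, NA, NA), "none")
})

test_that("scenario selection nests and partitions as stated", {
  cls <- random_classified(120, seed = 31)
  for (r in c("rare", "novel")) {
    f <- select_scenario_variants(cls, r, "functional")
    f1 <- select_scenario_variants(cls, r, "functional_1plus_del")
    fa <- select_scenario_variants(cls, r, "functional_all_del")
    syn <- select_scenario_variants(cls, r, "synonymous")
    expect_true(all(fa %in% f1))
    expect_true(all(f1 %in% f))
    expect_length(intersect(f, syn), 0)
  }
  # rare and novel strata are disjoint
  expect_length(intersect(select_scenario_variants(cls, "rare", "functional"),
                          select_scenario_variants(cls, "novel", "functional")),
                0)
  expect_error(select_scenario_variants(cls, "common", "functional"),
               "rarity")
  expect_error(select_scenario_variants(cls, "rare", "weird"), "function")
  # an impossible stratum yields an empty set, not an error
  cls$del_stratum <- "none"
  expect_length(select_scenario_variants(cls, "rare", "functional_all_del"),
                0)
})

test_that("the cascade matches an independent brute-force oracle", {
  pool <- simulate_haplotype_pool(2000, 2500, seed = 32)
  m <- length(pool$positions)
  vids <- sprintf("1:%d:%s:%s", pool$positions, pool$ref, pool$alt)
  genes <- rep(c("K1", "N1"), length.out = m)
  ann <- simulate_annotations(data.frame(variant_id = vids, gene = genes),
                              seed = 33)
  panels <- simulate_reference_panels(pool, seed = 34)
  cls <- classify_variants(ann, panels, known_genes = "K1")
  expect_identical(nrow(cls), m)
  # partition property over observed variants
  expect_true(all(cls$rarity %in% c("rare", "novel", "excluded")))
  for (v in vids[seq_len(min(m, 50))]) {
    a <- ann[ann$variant_id == v, ]
    pr <- panels[panels$variant_id == v, ]
    known <- a$gene[1] == "K1"
    crt <- if (known) "K1.t1" else NULL
    want <- oracle_classify(a, pr, known, crt)
    got <- cls[cls$variant_id == v, ]
    expect_identical(got$function_class, want$function_class)
    expect_identical(got$rarity, want$rarity)
    expect_identical(got$del_stratum, want$del_stratum)
  }
})

test_that("clinical triage keeps novel functional and rare pathogenic only", {
  cls <- data.frame(
    variant_id = c("v1", "v2", "v3", "v4", "v5"),
    gene = "G",
    function_class = c("functional", "functional", "functional",
                       "synonymous", "functional"),
    rarity = c("novel", "rare", "rare", "novel", "excluded"),
    del_stratum = "none",
    clinvar_status = c(NA, "Benign", "Likely pathogenic", NA,
                       "Pathogenic"),
    stringsAsFactors = FALSE)
  kept <- clinvar_triage(cls)
  expect_setequal(kept$variant_id, c("v1", "v3"))
  expect_identical(kept$triage_reason[kept$variant_id == "v1"],
                   "novel_functional")
})

test_that("triage counts add up on a cohort-scale fixture", {
  # 321 novel functional + 11 rare pathogenic/likely-pathogenic = 332
  n_novel <- 321; n_rare_path <- 11
  withr::local_seed(40)
  cls <- data.frame(
    variant_id = sprintf("v%04d", 1:800),
    gene = "G",
    function_class = c(rep("functional", n_novel),
                       rep("functional", n_rare_path),
                       sample(c("functional", "synonymous"),
                              800 - n_novel - n_rare_path, replace = TRUE)),
    rarity = c(rep("novel", n_novel), rep("rare", n_rare_path),
               rep("rare", 800 - n_novel - n_rare_path)),
    del_stratum = "none",
    clinvar_status = c(rep(NA, n_novel),
                       rep(c("Pathogenic", "Likely pathogenic"),
                           length.out = n_rare_path),
                       rep(c(NA, "Benign"),
                           length.out = 800 - n_novel - n_rare_path)),
    stringsAsFactors = FALSE)
  expect_identical(nrow(clinvar_triage(cls)), 332L)
})
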