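test_that("similarity and coverage filters are strict, as printed in the protocol", {
  boundary <- dplyr::bind_rows(
    make_hit(subject_id = "s1", similarity_pct = 30.0, coverage_pct = 90),
    make_hit(subject_id = "s2", similarity_pct = 30.1, coverage_pct = 90),
    make_hit(subject_id = "s3", similarity_pct = 90, coverage_pct = 70.0),
    make_hit(subject_id = "s4", similarity_pct = 90, coverage_pct = 70.1)
  )
  kept <- filter_hits(boundary)
  expect_setequal(kept$subject_id, c("s2", "s4"))
})

test_that("top-k capping ranks by score with lexicographic tie-break", {
  set.seed(21)
  hits <- random_hits(300)
  hits$similarity_pct <- 90
  hits$coverage_pct <- 90
  p <- screen_params(top_k = 250)
  kept <- filter_hits(hits, p)
  expect_equal(nrow(kept), 250)
  # idempotence
  expect_equal(filter_hits(kept, p), kept)
  # explicit tie: equal scores resolved by subject id
  ties <- dplyr::bind_rows(
    make_hit(subject_id = "zz", rank_score = 50),
    make_hit(subject_id = "aa", rank_score = 50),
    make_hit(subject_id = "mm", rank_score = 60)
  )
  kept2 <- filter_hits(ties, screen_params(top_k = 2))
  expect_equal(kept2$subject_id, c("mm", "aa"))
})

test_that("filtered set matches the brute-force oracle on random hits", {
  set.seed(99)
  hits <- random_hits(800)
  got <- filter_hits(hits, screen_params())
  want <- oracle_filter(hits)
  expect_equal(got$subject_id, want$subject_id)
  expect_equal(got$rank_score, want$rank_score)
})

test_that("mixed query ids are rejected", {
  hits <- dplyr::bind_rows(make_hit(query_id = "q1"), make_hit(query_id = "q2"))
  expect_error(filter_hits(hits), "single query",
               class = "proteosig_usage_error")
})

test_that("NTE calls follow the minimum-start rule with a full-coverage veto", {
  retained <- dplyr::bind_rows(lapply(1:12, function(i) {
    make_hit(subject_id = sprintf("s%02d", i), query_start = 26L)
  }))
  call <- call_nte(retained = retained, query_id = "q1", query_length = 225)
  expect_equal(call$nte_length, 25L)
  expect_true(call$is_nte)
  expect_equal(call$status, "ok")

  veto <- dplyr::bind_rows(retained[-1, ],
                           make_hit(subject_id = "s13", query_start = 1L))
  call2 <- call_nte(retained = veto, query_id = "q1", query_length = 225)
  expect_equal(call2$nte_length, 0L)
  expect_false(call2$is_nte)
})

test_that("support and anchoring gate the call without erroring", {
  few <- dplyr::bind_rows(lapply(1:3, function(i) {
    make_hit(subject_id = sprintf("s%02d", i), query_start = 26L)
  }))
  call <- call_nte(retained = few, query_id = "q", query_length = 200)
  expect_equal(call$status, "insufficient-support")
  expect_false(call$is_nte)
  expect_equal(call$nte_length, 25L)

  # hits that truncate the subject N-terminus are not boundary evidence
  trunc <- dplyr::bind_rows(lapply(1:12, function(i) {
    make_hit(subject_id = sprintf("s%02d", i), query_start = 26L,
             subject_start = 40L)
  }))
  call2 <- call_nte(retained = trunc, query_id = "q", query_length = 200)
  expect_equal(call2$status, "no-anchored-hits")
  expect_false(call2$is_nte)

  mixed <- dplyr::bind_rows(trunc,
                            make_hit(subject_id = "s99", query_start = 11L,
                                     subject_start = 2L))
  call3 <- call_nte(retained = mixed, query_id = "q", query_length = 200)
  expect_equal(call3$nte_length, 10L)
  expect_true(call3$is_nte)
})

test_that("adding a retained hit never increases the called extension", {
  set.seed(5)
  for (rep in 1:20) {
    n <- sample(10:30, 1)
    hits <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
      make_hit(subject_id = sprintf("s%03d", i),
               query_start = sample(1:60, 1), subject_start = 1L)
    }))
    base <- call_nte(retained = hits, query_id = "q", query_length = 300)
    more <- dplyr::bind_rows(hits, make_hit(subject_id = "sZZZ",
                                            query_start = sample(1:60, 1),
                                            subject_start = 1L))
    grown <- call_nte(retained = more, query_id = "q", query_length = 300)
    expect_lte(grown$nte_length, base$nte_length)
  }
})

test_that("out-of-range extensions are flagged but still reported", {
  retained <- dplyr::bind_rows(lapply(1:12, function(i) {
    make_hit(subject_id = sprintf("s%02d", i), query_start = 81L)
  }))
  call <- call_nte(retained = retained, query_id = "q", query_length = 300,
                   params = screen_params(max_nte_len = 73))
  expect_true(call$is_nte)
  expect_true(call$out_of_range)
  expect_equal(call$nte_length, 80L)
})

test_that("screening a simulated family recovers the planted extension", {
  fam <- simulate_family(family_spec(12, 200, 0, c("1" = 25), seed = 1))
  calls <- screen_proteome(fam$proteome, subjects = fam$proteome)
  expect_equal(calls$nte_length[calls$query_id == "fam_m01"], 25L)
  expect_true(calls$is_nte[calls$query_id == "fam_m01"])
  expect_false(any(calls$is_nte[-1]))
})

test_that("mixing in-house and parsed hits in one screen is rejected", {
  prot <- make_proteome_tbl("q1", strrep("MKV", 40))
  mixed <- dplyr::bind_rows(make_hit(hit_source = "blast"),
                            make_hit(subject_id = "s2", hit_source = "inhouse"))
  expect_error(screen_proteome(prot, hits = mixed), "not comparable",
               class = "proteosig_usage_error")
  expect_error(screen_proteome(prot), "exactly one",
               class = "proteosig_usage_error")
  expect_error(screen_proteome(prot, hits = mixed, subjects = prot),
               "exactly one", class = "proteosig_usage_error")
})

test_that("conservation scan lists exactly the other NTE-bearing genomes", {
  # four genomes, orthologous protein planted with an NTE in three
  calls <- tibble::tibble(
    query_id = paste0("g", 1:4, "_p1"),
    genome_id = paste0("g", 1:4),
    query_length = 220L, n_hits_retained = 12L,
    min_query_start = c(21L, 21L, 21L, 1L),
    nte_length = c(20L, 20L, 20L, 0L),
    is_nte = c(TRUE, TRUE, TRUE, FALSE),
    status = "ok", out_of_range = FALSE
  )
  combos <- utils::combn(4, 2)
  orthologs <- tibble::tibble(
    protein_a = paste0("g", combos[1, ], "_p1"),
    protein_b = paste0("g", combos[2, ], "_p1"),
    genome_a = paste0("g", combos[1, ]),
    genome_b = paste0("g", combos[2, ]),
    score_ab = 100, score_ba = 100
  )
  ann <- conservation_scan(calls, orthologs)
  expect_equal(ann$conserved_in[[1]], c("g2", "g3"))
  expect_equal(ann$conserved_in[[2]], c("g1", "g3"))
  expect_equal(ann$conserved_in[[3]], c("g1", "g2"))
  expect_equal(ann$conserved_in[[4]], character())
})

test_that("dual conventional/NTE paralog families are detected", {
  families <- tibble::tibble(
    protein_id = c("ftsZ1", "ftsZ2", "x1", "x2", "solo"),
    family_id = c("famA", "famA", "famB", "famB", "famC")
  )
  calls <- tibble::tibble(
    query_id = families$protein_id,
    query_length = 300L, n_hits_retained = 12L,
    min_query_start = c(1L, 18L, 15L, 12L, 1L),
    nte_length = c(0L, 17L, 14L, 11L, 0L),
    is_nte = c(FALSE, TRUE, TRUE, TRUE, FALSE),
    status = "ok", out_of_range = FALSE
  )
  pairs <- paralog_nte_pairs(families, calls)
  # famA: one conventional + one NTE member; famB has no conventional copy
  expect_equal(nrow(pairs), 1)
  expect_equal(pairs$conventional_id, "ftsZ1")
  expect_equal(pairs$nte_id, "ftsZ2")
  expect_equal(pairs$nte_length, 17L)
})

test_that("single-linkage families from in-house hits recover planted paralogs", {
  specs <- lapply(1:3, function(k) family_spec(2, 120, 0, c("1" = 15), seed = 100 + k))
  sims <- lapply(seq_along(specs), function(k) {
    simulate_family(specs[[k]], family_id = paste0("f", k))
  })
  proteome <- dplyr::bind_rows(lapply(sims, `[[`, "proteome"))
  proteome$genome_id <- "g1"
  fams <- cluster_families(proteome)
  expect_equal(dplyr::n_distinct(fams$family_id), 3)
  params <- screen_params(min_support = 1)
  calls <- screen_proteome(proteome, subjects = proteome, params = params)
  pairs <- paralog_nte_pairs(fams, calls)
  expect_equal(nrow(pairs), 3)
  expect_setequal(pairs$nte_id, c("f1_m01", "f2_m01", "f3_m01"))
})
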