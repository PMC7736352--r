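# Recompute an alignment score from its gapped columns: substitution scores
# plus affine gap costs (open + extend per residue, per gap run).
recompute_score <- function(aln, params) {
  q <- strsplit(aln$aligned_query, "")[[1]]
  s <- strsplit(aln$aligned_subject, "")[[1]]
  gap_runs <- function(x) {
    r <- rle(x == "-")
    r$lengths[r$values]
  }
  subst <- sum(params$substitution_matrix[cbind(q[q != "-" & s != "-"],
                                                s[q != "-" & s != "-"])])
  runs <- c(gap_runs(q), gap_runs(s))
  subst - sum(ifelse(runs > 0, params$gap_open + runs * params$gap_extend, 0))
}

test_that("identical sequences align end to end with full identity", {
  aln <- align_pair("MKV", "MKV")
  expect_equal(aln$identity_pct, 100)
  expect_equal(aln$query_start, 1)
  expect_equal(aln$query_end, 3)
  expect_equal(aln$score, 14)  # M:5 + K:5 + V:4 under BLOSUM62
  expect_true(aln$is_hit)
})

test_that("a pair with no positive-scoring cell is a no-hit", {
  aln <- align_pair("AAAA", "CCCC")
  expect_false(aln$is_hit)
  expect_equal(aln$score, 0)
  expect_true(is.na(aln$query_start))
  expect_equal(nrow(hits_from_alignment(aln, 4, "q", "s")), 0)
})

test_that("empty sequences are rejected", {
  expect_error(align_pair("", "MKV"), "empty",
               class = "proteosig_usage_error")
})

test_that("scores match the independent affine-gap DP oracle", {
  bl <- proteosig:::blosum62()
  for (s in c(3, 17, 101, 202)) {
    set.seed(s)
    a <- random_protein(sample(8:35, 1))
    b <- random_protein(sample(8:35, 1))
    for (mode in c("local", "global")) {
      p <- align_params(mode = mode)
      expect_equal(align_pair(a, b, p)$score,
                   oracle_align_score(a, b, bl, mode = mode),
                   info = sprintf("seed %d mode %s", s, mode))
    }
  }
})

test_that("reported score equals its column-wise recomputation", {
  set.seed(9)
  for (k in 1:20) {
    a <- random_protein(sample(10:60, 1))
    b <- random_protein(sample(10:60, 1))
    p <- align_params()
    aln <- align_pair(a, b, p)
    if (aln$is_hit) {
      expect_equal(aln$score, recompute_score(aln, p))
    }
  }
})

test_that("alignment score is symmetric and monotone under extension", {
  set.seed(13)
  for (k in 1:10) {
    a <- random_protein(25)
    b <- random_protein(25)
    expect_equal(align_pair(a, b)$score, align_pair(b, a)$score)
    # appending residues can only add local alignment options
    expect_gte(align_pair(paste0(a, random_protein(5)), b)$score,
               align_pair(a, b)$score)
    expect_gte(align_pair(a, paste0(b, random_protein(5)))$score,
               align_pair(a, b)$score)
  }
})

test_that("hits_from_alignment computes the screen operands", {
  seq100 <- random_protein(100)
  full <- align_pair(seq100, seq100)
  h <- hits_from_alignment(full, 100, "q", "s")
  expect_equal(h$coverage_pct, 100)
  expect_equal(h$similarity_pct, 100)

  part <- tibble::tibble(
    score = 80, query_start = 26L, query_end = 100L, subject_start = 1L,
    subject_end = 75L, identity_pct = 80, positives_pct = 92,
    n_columns = 75L, aligned_query = "", aligned_subject = "", is_hit = TRUE
  )
  h2 <- hits_from_alignment(part, 100, "q", "s")
  expect_equal(h2$coverage_pct, 75)
  expect_equal(h2$similarity_pct, 92)
  expect_equal(h2$rank_score, 80)
})

test_that("in-house hits agree with parsing the equivalent tabular line", {
  set.seed(31)
  core <- random_protein(120)
  query <- paste0(random_protein(20), core)
  aln <- align_pair(query, core)
  inhouse <- hits_from_alignment(aln, nchar(query), "q1", "s1")
  tab <- withr::local_tempfile()
  writeLines(paste(c("q1", "s1", sprintf("%.2f", aln$identity_pct), aln$n_columns,
                     "0", "0", aln$query_start, aln$query_end, aln$subject_start,
                     aln$subject_end, "1e-30", aln$score,
                     sprintf("%.2f", aln$positives_pct)), collapse = "\t"), tab)
  parsed <- read_blast_hits(tab, setNames(nchar(query), "q1"))
  expect_equal(parsed$coverage_pct, inhouse$coverage_pct)
  expect_equal(parsed$similarity_pct, inhouse$similarity_pct, tolerance = 1e-4)
  expect_equal(parsed$query_start, inhouse$query_start)
})

test_that("reciprocal best hits pair identical proteomes completely", {
  set.seed(7)
  seqs <- vapply(1:4, function(i) random_protein(60), character(1))
  a <- make_proteome_tbl(paste0("a", 1:4), seqs, "gA")
  b <- make_proteome_tbl(paste0("b", 1:4), seqs, "gB")
  pairs <- reciprocal_best_hits(a, b)
  expect_equal(nrow(pairs), 4)
  expect_equal(sort(paste(pairs$protein_a, pairs$protein_b)),
               sort(paste(paste0("a", 1:4), paste0("b", 1:4))))

  b_missing <- b[-2, ]
  pairs2 <- reciprocal_best_hits(a, b_missing)
  expect_false("a2" %in% pairs2$protein_a)
  expect_equal(nrow(pairs2), 3)
})

test_that("reciprocal best hits match an exhaustive all-vs-all check", {
  set.seed(11)
  a <- make_proteome_tbl(paste0("a", 1:3),
                         vapply(1:3, function(i) random_protein(50), character(1)), "gA")
  b <- make_proteome_tbl(paste0("b", 1:3),
                         vapply(1:3, function(i) random_protein(50), character(1)), "gB")
  score_mat <- outer(seq_len(3), seq_len(3), Vectorize(function(i, j) {
    align_pair(a$sequence[i], b$sequence[j])$score
  }))
  expected <- list()
  for (i in 1:3) {
    j <- which.max(score_mat[i, ])
    if (score_mat[i, j] > 0 && which.max(score_mat[, j]) == i) {
      expected[[length(expected) + 1]] <- c(a$protein_id[i], b$protein_id[j])
    }
  }
  got <- suppressWarnings(reciprocal_best_hits(a, b))
  expect_equal(nrow(got), length(expected))
  for (e in expected) {
    expect_true(any(got$protein_a == e[1] & got$protein_b == e[2]))
  }
})

test_that("NCBI-format substitution matrices load correctly", {
  path <- withr::local_tempfile()
  writeLines(c("# comment", "   A  R  N", "A  4 -1 -2", "R -1  5  0",
               "N -2  0  6"), path)
  m <- read_substitution_matrix(path)
  expect_equal(m["A", "A"], 4)
  expect_equal(m["R", "N"], 0)
  expect_equal(m, t(m))
  bl <- proteosig:::blosum62()
  expect_equal(m["A", "R"], bl["A", "R"])
})
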