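# Small in-code fixtures shared across test files.

write_fasta_lines <- function(lines) {
  path <- withr::local_tempfile(fileext = ".faa", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

make_proteome_tbl <- function(ids, seqs, genome_id = "g1") {
  tibble::tibble(protein_id = ids, genome_id = genome_id,
                 sequence = seqs, description = "")
}

# One synthetic hit row with sensible defaults.
make_hit <- function(query_id = "q1", subject_id = "s1", similarity_pct = 90,
                     coverage_pct = 90, query_start = 1L, query_end = 100L,
                     subject_start = 1L, rank_score = 100,
                     hit_source = "blast") {
  tibble::tibble(
    query_id = query_id, subject_id = subject_id,
    similarity_pct = similarity_pct, coverage_pct = coverage_pct,
    query_start = as.integer(query_start), query_end = as.integer(query_end),
    subject_start = as.integer(subject_start), rank_score = rank_score,
    similarity_source = "pident", hit_source = hit_source
  )
}

random_hits <- function(n, queries = "q1") {
  tibble::tibble(
    query_id = sample(queries, n, replace = TRUE),
    subject_id = sprintf("s%04d", sample.int(n * 2, n)),
    similarity_pct = round(runif(n, 0, 100), 1),
    coverage_pct = round(runif(n, 0, 100), 1),
    query_start = sample.int(50, n, replace = TRUE),
    query_end = sample(60:100, n, replace = TRUE),
    subject_start = sample.int(10, n, replace = TRUE),
    rank_score = sample(seq(20, 500, by = 5), n, replace = TRUE),
    similarity_source = "pident",
    hit_source = "blast"
  )
}
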