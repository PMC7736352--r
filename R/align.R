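#' Alignment parameters
#'
#' Parameter bundle for the built-in affine-gap protein aligner, mirroring
#' BLASTP defaults (BLOSUM62, gap open 11, gap extend 1). A gap of length
#' `k` costs `gap_open + k * gap_extend`, i.e. the opening penalty is charged
#' in addition to the extension cost of the first gap residue.
#'
#' @param substitution_matrix Named symmetric integer substitution matrix;
#'   default BLOSUM62.
#' @param gap_open Positive gap-opening cost (default 11).
#' @param gap_extend Positive per-residue gap-extension cost (default 1);
#'   must not exceed `gap_open`.
#' @param mode `"local"` (Smith-Waterman) or `"global"` (Needleman-Wunsch).
#' @return A list of class `align_params`.
#' @export
align_params <- function(substitution_matrix = NULL, gap_open = 11,
                         gap_extend = 1, mode = c("local", "global")) {
  mode <- match.arg(mode)
  if (is.null(substitution_matrix)) {
    substitution_matrix <- blosum62()
  }
  if (!isTRUE(all.equal(substitution_matrix, t(substitution_matrix)))) {
    usage_error("substitution matrix must be symmetric")
  }
  if (gap_open <= 0 || gap_extend <= 0 || gap_extend > gap_open) {
    usage_error("need 0 < gap_extend <= gap_open")
  }
  structure(
    list(substitution_matrix = substitution_matrix, gap_open = gap_open,
         gap_extend = gap_extend, mode = mode),
    class = "align_params"
  )
}

blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

#' Read an NCBI-format substitution matrix
#'
#' Parses the plain-text matrix layout distributed with BLAST (comment lines
#' starting with `#`, a header row of residue labels, one labelled row per
#' residue).
#'
#' @param path Path to the matrix file.
#' @return A named numeric matrix.
#' @export
read_substitution_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")])
  cols <- strsplit(lines[1], "\\s+")[[1]]
  rows <- strsplit(lines[-1], "\\s+")
  m <- do.call(rbind, lapply(rows, function(r) as.numeric(r[-1])))
  rownames(m) <- vapply(rows, `[[`, "", 1)
  colnames(m) <- cols
  m
}

#' Align two protein sequences with affine gap penalties
#'
#' Optimal affine-gap dynamic-programming alignment (Smith-Waterman local or
#' Needleman-Wunsch global), the built-in substitute for an external BLASTP
#' search. Backed by `Biostrings::pairwiseAlignment()`.
#'
#' @param query,subject Non-empty amino-acid strings.
#' @param params An [align_params()] bundle.
#' @return A one-row tibble with columns `score`, `query_start`, `query_end`,
#'   `subject_start`, `subject_end`, `identity_pct`, `positives_pct`
#'   (columns with positive matrix score over all alignment columns),
#'   `n_columns`, `aligned_query`, `aligned_subject` and `is_hit`. A local
#'   alignment with no positive-scoring cell is reported as a no-hit row
#'   (`is_hit = FALSE`, score 0, coordinates `NA`).
#' @examples
#' align_pair("MKV", "MKV")
#' @export
align_pair <- function(query, subject, params = align_params()) {
  if (!nzchar(query) || !nzchar(subject)) {
    usage_error("cannot align an empty sequence")
  }
  type <- if (params$mode == "local") "local" else "global"
  pa <- Biostrings::pairwiseAlignment(
    query, subject, type = type,
    substitutionMatrix = params$substitution_matrix,
    gapOpening = params$gap_open, gapExtension = params$gap_extend
  )
  aq <- as.character(Biostrings::alignedPattern(pa))
  as_ <- as.character(Biostrings::alignedSubject(pa))
  sc <- Biostrings::score(pa)
  if (params$mode == "local" && (sc <= 0 || nchar(aq) == 0)) {
    return(tibble(
      score = 0, query_start = NA_integer_, query_end = NA_integer_,
      subject_start = NA_integer_, subject_end = NA_integer_,
      identity_pct = NA_real_, positives_pct = NA_real_,
      n_columns = 0L, aligned_query = "", aligned_subject = "",
      is_hit = FALSE
    ))
  }
  stats <- alignment_column_stats(aq, as_, params$substitution_matrix)
  tibble(
    score = sc,
    query_start = BiocGenerics::start(Biostrings::pattern(pa)),
    query_end = BiocGenerics::end(Biostrings::pattern(pa)),
    subject_start = BiocGenerics::start(Biostrings::subject(pa)),
    subject_end = BiocGenerics::end(Biostrings::subject(pa)),
    identity_pct = stats$identity_pct,
    positives_pct = stats$positives_pct,
    n_columns = stats$n_columns,
    aligned_query = aq,
    aligned_subject = as_,
    is_hit = TRUE
  )
}

# Column-wise identity and positives over a gapped alignment; the positives
# denominator counts every alignment column, as BLAST does.
alignment_column_stats <- function(aligned_query, aligned_subject, matrix) {
  qc <- seq_chars(aligned_query)
  sc <- seq_chars(aligned_subject)
  stopifnot(length(qc) == length(sc))
  nongap <- qc != "-" & sc != "-"
  pos <- logical(length(qc))
  pos[nongap] <- matrix[cbind(qc[nongap], sc[nongap])] > 0
  list(
    identity_pct = sum(qc == sc & nongap) / length(qc) * 100,
    positives_pct = sum(pos) / length(qc) * 100,
    n_columns = length(qc)
  )
}

#' Convert an alignment result into a homolog hit
#'
#' Derives the similarity/coverage statistics the NTE screen filters on from
#' a built-in alignment, on the same scale as hits parsed from BLAST tabular
#' files: similarity is the positives percentage, coverage is the aligned
#' query span over the query length.
#'
#' @param aln One-row alignment tibble from [align_pair()].
#' @param query_length Full query length in residues.
#' @param query_id,subject_id Identifiers recorded on the hit.
#' @return A one-row hits tibble (zero rows for a no-hit alignment), with
#'   `hit_source = "inhouse"` and `rank_score` equal to the raw alignment
#'   score.
#' @export
hits_from_alignment <- function(aln, query_length, query_id, subject_id) {
  if (!isTRUE(aln$is_hit[1])) {
    return(empty_hits())
  }
  tibble(
    query_id = query_id,
    subject_id = subject_id,
    similarity_pct = aln$positives_pct[1],
    coverage_pct = (aln$query_end[1] - aln$query_start[1] + 1) / query_length * 100,
    query_start = as.integer(aln$query_start[1]),
    query_end = as.integer(aln$query_end[1]),
    subject_start = as.integer(aln$subject_start[1]),
    rank_score = aln$score[1],
    similarity_source = "positives",
    hit_source = "inhouse"
  )
}

#' Align one query against a set of subjects
#'
#' Runs the built-in aligner for one query against every subject in a
#' proteome and returns the homolog hits (no-hits dropped, self-hits
#' excluded).
#'
#' @param query_record One-row proteome tibble (the query).
#' @param subjects Proteome tibble of subject sequences.
#' @param params An [align_params()] bundle.
#' @return A hits tibble as from [read_blast_hits()].
#' @export
align_against <- function(query_record, subjects, params = align_params()) {
  check_proteome(subjects)
  qid <- query_record$protein_id[1]
  qseq <- query_record$sequence[1]
  subjects <- filter(subjects, .data$protein_id != qid)
  rows <- purrr::map(seq_len(nrow(subjects)), function(i) {
    aln <- align_pair(qseq, subjects$sequence[i], params)
    hits_from_alignment(aln, nchar(qseq), qid, subjects$protein_id[i])
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) empty_hits() else out
}

#' Reciprocal best hits between two proteomes
#'
#' Ortholog heuristic supporting the cross-genome NTE conservation scan: a
#' pair `(a, b)` is reported iff `b` is `a`'s highest-scoring hit in the
#' second proteome and `a` is `b`'s highest-scoring hit in the first.
#'
#' @param proteome_a,proteome_b Proteome tibbles.
#' @param params An [align_params()] bundle.
#' @return A tibble with columns `protein_a`, `protein_b`, `genome_a`,
#'   `genome_b`, `score_ab`, `score_ba`. Score ties for the best hit are
#'   broken lexicographically by subject id and surfaced as a warning.
#' @export
reciprocal_best_hits <- function(proteome_a, proteome_b, params = align_params()) {
  check_proteome(proteome_a)
  check_proteome(proteome_b)
  best_ab <- best_hits_oneway(proteome_a, proteome_b, params)
  best_ba <- best_hits_oneway(proteome_b, proteome_a, params)
  pairs <- dplyr::inner_join(
    best_ab, rename(best_ba, query_id = "subject_id", subject_id = "query_id"),
    by = c("query_id", "subject_id"), suffix = c("_ab", "_ba")
  )
  tibble(
    protein_a = pairs$query_id,
    protein_b = pairs$subject_id,
    genome_a = proteome_a$genome_id[1],
    genome_b = proteome_b$genome_id[1],
    score_ab = pairs$best_score_ab,
    score_ba = pairs$best_score_ba
  )
}

best_hits_oneway <- function(queries, subjects, params) {
  rows <- purrr::map(seq_len(nrow(queries)), function(i) {
    scores <- vapply(subjects$sequence, function(s) {
      align_pair(queries$sequence[i], s, params)$score
    }, numeric(1), USE.NAMES = FALSE)
    ok <- scores > 0
    if (!any(ok)) {
      return(NULL)
    }
    top <- max(scores)
    cand <- sort(subjects$protein_id[scores == top])
    if (length(cand) > 1) {
      warn(sprintf(
        "best-hit tie for '%s' (%s); broken lexicographically",
        queries$protein_id[i], paste(cand, collapse = ", ")
      ), class = "proteosig_tie_warning")
    }
    tibble(query_id = queries$protein_id[i], subject_id = cand[1],
           best_score = top)
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    tibble(query_id = character(), subject_id = character(),
           best_score = numeric())
  } else {
    out
  }
}
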