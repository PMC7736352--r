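#' Read a proteome from a FASTA file
#'
#' Reads one protein FASTA file into a normalized proteome table: one row per
#' record, identifiers taken from the first whitespace-delimited header token,
#' sequences uppercased, and a single terminal `*` stop symbol stripped.
#'
#' @param path Path to a FASTA file (wrapped or unwrapped sequence lines).
#' @param genome_id Genome identifier attached to every record. Defaults to
#'   the file name without extension.
#' @return A tibble with columns `protein_id`, `genome_id`, `sequence`,
#'   `description`. The number of rows is the ORF count used as the
#'   denominator of all census proportions.
#' @details Errors on an empty file, on duplicated `protein_id` (the offending
#'   id is named), and on any residue outside the 20-letter alphabet plus `X`
#'   (the offending file line is named). Internal `*` symbols are an error;
#'   only a single trailing `*` is treated as a stop codon and removed.
#' @examples
#' fa <- tempfile(fileext = ".faa")
#' writeLines(c(">a desc", "MKV", ">b", "MA", "GW"), fa)
#' read_proteome(fa, genome_id = "g1")
#' @export
read_proteome <- function(path, genome_id = NULL) {
  if (!file.exists(path)) {
    usage_error("FASTA file does not exist: %s", path)
  }
  genome_id <- genome_id %||% sub("\\.[^.]*$", "", basename(path))
  aas <- Biostrings::readBStringSet(path)
  if (length(aas) == 0) {
    processing_error("no records in FASTA file %s", path)
  }
  headers <- names(aas)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)][1]
    processing_error("duplicate protein_id '%s' in %s", dup, path)
  }
  seqs <- toupper(as.character(aas))
  seqs <- sub("\\*$", "", seqs)
  bad <- !grepl(paste0("^[", paste(AA_ALPHABET20, collapse = ""), "X]+$"), seqs)
  if (any(bad)) {
    .report_bad_residue(path, ids[bad][1])
  }
  if (any(!nzchar(seqs))) {
    processing_error("empty sequence for protein '%s' in %s",
                     ids[!nzchar(seqs)][1], path)
  }
  tibble(
    protein_id = unname(ids),
    genome_id = genome_id,
    sequence = unname(seqs),
    description = unname(desc)
  )
}

# Locate the first offending residue line for an informative parse error.
.report_bad_residue <- function(path, protein_id) {
  lines <- readLines(path, warn = FALSE)
  in_rec <- FALSE
  body_line <- 0L
  ok <- paste0("^[", paste(AA_ALPHABET20, collapse = ""), "X*]*$")
  for (i in seq_along(lines)) {
    if (startsWith(lines[i], ">")) {
      in_rec <- identical(sub("\\s.*$", "", sub("^>", "", lines[i])), protein_id)
      next
    }
    if (in_rec && !grepl(ok, toupper(lines[i]))) {
      body_line <- i
      break
    }
    if (in_rec && grepl("\\*.", lines[i])) {
      body_line <- i
      break
    }
  }
  processing_error(
    "invalid amino-acid character in record '%s' (%s line %d)",
    protein_id, path, if (body_line > 0) body_line else NA_integer_
  )
}

#' Write a proteome table to FASTA
#'
#' Inverse of [read_proteome()]: writing then re-reading a normalized proteome
#' is the identity.
#'
#' @param proteome Proteome tibble as returned by [read_proteome()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_proteome <- function(proteome, path) {
  check_proteome(proteome)
  set <- Biostrings::AAStringSet(setNames(proteome$sequence, ifelse(
    nzchar(proteome$description),
    paste(proteome$protein_id, proteome$description),
    proteome$protein_id
  )))
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

# Validate the proteome contract shared by every downstream operation.
check_proteome <- function(proteome) {
  need <- c("protein_id", "genome_id", "sequence")
  if (!is.data.frame(proteome) || !all(need %in% names(proteome))) {
    usage_error("proteome must be a data frame with columns %s",
                paste(need, collapse = ", "))
  }
  if (nrow(proteome) < 1) usage_error("proteome has no records")
  if (anyDuplicated(proteome$protein_id)) {
    usage_error("duplicate protein_id '%s' in proteome",
                proteome$protein_id[duplicated(proteome$protein_id)][1])
  }
  invisible(proteome)
}

#' Parse BLAST tabular output into homolog hits
#'
#' Reads standard 12-column BLAST tabular output (`-outfmt 6`: query, subject,
#' pident, length, mismatch, gapopen, qstart, qend, sstart, send, evalue,
#' bitscore), optionally with a 13th `ppos` column. Produces one homolog hit
#' per query/subject pair, the scale on which the `>30%` similarity and
#' `>70%` coverage screen filters operate.
#'
#' @param path Path to the tabular file.
#' @param query_lengths Named numeric vector mapping `query_id` to query
#'   length, or a proteome tibble from which lengths are taken.
#' @return A tibble of hits with columns `query_id`, `subject_id`,
#'   `similarity_pct`, `coverage_pct`, `query_start`, `query_end`,
#'   `subject_start`, `rank_score`, `similarity_source`, `hit_source`.
#' @details Similarity is the `ppos` (BLAST positives) column when present,
#'   else `pident`; `similarity_source` records which. Coverage is
#'   `(qend - qstart + 1) / query_length * 100` for a single HSP; when a
#'   query/subject pair has several HSPs only the best by `rank_score`
#'   (bitscore) is retained, ties going to the first occurrence. Self-hits
#'   (query == subject) are dropped. A query id absent from `query_lengths`,
#'   a malformed column count, or coverage over 100% is an error.
#' @export
read_blast_hits <- function(path, query_lengths) {
  if (!file.exists(path)) usage_error("BLAST tabular file does not exist: %s", path)
  if (is.data.frame(query_lengths)) {
    check_proteome(query_lengths)
    query_lengths <- setNames(nchar(query_lengths$sequence),
                              query_lengths$protein_id)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) {
    return(empty_hits())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  bad <- which(!(ncols %in% c(12L, 13L)))
  if (length(bad) > 0) {
    processing_error("malformed BLAST tabular line %d in %s: %d columns",
                     bad[1], path, ncols[bad[1]])
  }
  m <- do.call(rbind, lapply(fields, function(f) f[1:13][seq_len(13)]))
  has_ppos <- ncols == 13L
  query_id <- m[, 1]
  unknown <- setdiff(unique(query_id), names(query_lengths))
  if (length(unknown) > 0) {
    processing_error("query id '%s' absent from query_lengths", unknown[1])
  }
  qlen <- unname(query_lengths[query_id])
  pident <- as.numeric(m[, 3])
  qstart <- as.integer(m[, 7])
  qend <- as.integer(m[, 8])
  sstart <- as.integer(m[, 9])
  bitscore <- as.numeric(m[, 12])
  ppos <- ifelse(has_ppos, suppressWarnings(as.numeric(m[, 13])), NA_real_)
  hits <- tibble(
    query_id = query_id,
    subject_id = m[, 2],
    similarity_pct = ifelse(has_ppos, ppos, pident),
    coverage_pct = (qend - qstart + 1) / qlen * 100,
    query_start = qstart,
    query_end = qend,
    subject_start = sstart,
    rank_score = bitscore,
    similarity_source = ifelse(has_ppos, "ppos", "pident"),
    hit_source = "blast"
  )
  hits <- filter(hits, .data$query_id != .data$subject_id)
  over <- hits$coverage_pct > 100 + 1e-9
  if (any(over)) {
    processing_error("coverage over 100%% for query '%s' (qend beyond query length?)",
                     hits$query_id[over][1])
  }
  # Best HSP per query/subject pair, ties to first occurrence.
  hits |>
    mutate(.ord = row_number()) |>
    group_by(.data$query_id, .data$subject_id) |>
    arrange(desc(.data$rank_score), .data$.ord, .by_group = TRUE) |>
    slice(1) |>
    ungroup() |>
    arrange(.data$.ord) |>
    select(-".ord")
}

empty_hits <- function() {
  tibble(
    query_id = character(), subject_id = character(),
    similarity_pct = numeric(), coverage_pct = numeric(),
    query_start = integer(), query_end = integer(),
    subject_start = integer(), rank_score = numeric(),
    similarity_source = character(), hit_source = character()
  )
}

#' Parse TMHMM-style short-format transmembrane predictions
#'
#' Reads the one-line-per-protein short format produced by TMHMM v2 (and by
#' [write_tm_predictions()]): tab-separated fields including `len=`,
#' `PredHel=` and `Topology=`.
#'
#' @param path Path to the predictions file.
#' @return A tibble with columns `protein_id`, `seq_length`, `n_helices` and
#'   a list-column `helix_spans` of tibbles with 1-based closed `start`/`end`
#'   intervals.
#' @details A missing `PredHel=` field or a protein listed twice is an error.
#'   Spans are parsed from the topology string and are sorted and
#'   non-overlapping by construction of the format.
#' @export
read_tm_predictions <- function(path) {
  if (!file.exists(path)) usage_error("TM predictions file does not exist: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parse_one <- function(line, i) {
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    id <- f[1]
    predhel <- grep("^PredHel=", f, value = TRUE)
    if (length(predhel) == 0) {
      processing_error("missing PredHel= field on line %d of %s", i, path)
    }
    lenf <- grep("^len=", f, value = TRUE)
    topo <- grep("^Topology=", f, value = TRUE)
    spans <- parse_topology(if (length(topo)) sub("^Topology=", "", topo[1]) else "")
    tibble(
      protein_id = id,
      seq_length = if (length(lenf)) as.integer(sub("^len=", "", lenf[1])) else NA_integer_,
      n_helices = as.integer(sub("^PredHel=", "", predhel[1])),
      helix_spans = list(spans)
    )
  }
  out <- bind_rows(purrr::imap(lines, parse_one))
  if (nrow(out) > 0 && anyDuplicated(out$protein_id)) {
    processing_error("protein '%s' listed twice in %s",
                     out$protein_id[duplicated(out$protein_id)][1], path)
  }
  out
}

parse_topology <- function(topology) {
  m <- regmatches(topology, gregexpr("\\d+-\\d+", topology))[[1]]
  if (length(m) == 0) {
    return(tibble(start = integer(), end = integer()))
  }
  parts <- do.call(rbind, strsplit(m, "-", fixed = TRUE))
  tibble(start = as.integer(parts[, 1]), end = as.integer(parts[, 2]))
}

#' Write transmembrane predictions in TMHMM-style short format
#'
#' @param tm Predictions tibble as returned by [read_tm_predictions()] or
#'   [predict_tm()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tm_predictions <- function(tm, path) {
  lines <- purrr::pmap_chr(
    list(tm$protein_id, tm$seq_length, tm$n_helices, tm$helix_spans),
    function(id, len, nh, spans) {
      topo <- if (nrow(spans) == 0) {
        "o"
      } else {
        sides <- rep(c("i", "o"), length.out = nrow(spans) + 1)
        paste0(paste0(sides[seq_len(nrow(spans))], spans$start, "-", spans$end,
                      collapse = ""), sides[nrow(spans) + 1])
      }
      sprintf("%s\tlen=%d\tExpAA=%.2f\tFirst60=%.2f\tPredHel=%d\tTopology=%s",
              id, len, sum(spans$end - spans$start + 1), 0, nh, topo)
    }
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read signal-peptide predictions from a two-column summary file
#'
#' Reads the tab-separated summary dialect used for both predictor regimes:
#' `protein_id`, `YES`/`NO`, and an optional third column with the 1-based
#' cleavage position for secreted proteins.
#'
#' @param path Path to the summary file.
#' @param regime Predictor regime tag, `"v4like"` or `"v5like"`.
#' @return A tibble with columns `protein_id`, `regime`, `is_secreted`,
#'   `cleavage_pos`.
#' @export
read_sp_predictions <- function(path, regime = c("v5like", "v4like")) {
  regime <- match.arg(regime)
  if (!file.exists(path)) usage_error("SP predictions file does not exist: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(!(lengths(fields) %in% c(2L, 3L)))
  if (length(bad) > 0) {
    processing_error("malformed SP summary line %d in %s", bad[1], path)
  }
  out <- tibble(
    protein_id = purrr::map_chr(fields, 1),
    regime = regime,
    is_secreted = purrr::map_chr(fields, 2) == "YES",
    cleavage_pos = purrr::map_int(fields, function(f) {
      if (length(f) == 3 && f[2] == "YES") as.integer(f[3]) else NA_integer_
    })
  )
  if (nrow(out) > 0 && anyDuplicated(out$protein_id)) {
    processing_error("protein '%s' listed twice in %s",
                     out$protein_id[duplicated(out$protein_id)][1], path)
  }
  out
}

#' Write signal-peptide predictions in the two-column summary dialect
#'
#' @param sp Predictions tibble as returned by [read_sp_predictions()] or
#'   [predict_sp()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sp_predictions <- function(sp, path) {
  lines <- purrr::pmap_chr(
    list(sp$protein_id, sp$is_secreted, sp$cleavage_pos),
    function(id, sec, cp) {
      if (isTRUE(sec) && !is.na(cp)) {
        sprintf("%s\tYES\t%d", id, cp)
      } else if (isTRUE(sec)) {
        sprintf("%s\tYES", id)
      } else {
        sprintf("%s\tNO", id)
      }
    }
  )
  writeLines(lines, path)
  invisible(path)
}
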