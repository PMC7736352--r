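#' NTE screen parameters
#'
#' Thresholds for calling unique N-terminal extensions from filtered homolog
#' hits. Defaults follow the published protocol: homolog hits are kept when
#' similarity exceeds 30% and query coverage exceeds 70% (both strictly),
#' capped at the top 250 hits by score, and an extension must be at least 10
#' residues long.
#'
#' @param min_similarity_pct Similarity threshold, strict `>` (default 30).
#' @param min_coverage_pct Query-coverage threshold, strict `>` (default 70).
#' @param top_k Maximum retained hits per query (default 250).
#' @param min_nte_len Minimum extension length in residues to call an NTE
#'   (default 10).
#' @param max_nte_len Optional upper length; longer calls are flagged
#'   `out_of_range` but still reported (default `NULL`, report only).
#' @param min_support Minimum retained hits needed to attempt a call
#'   (default 10): with fewer informative homologs a "unique" extension is
#'   unfalsifiable. Set to 1 for the most permissive reading.
#' @param start_quantile Quantile of retained query starts used as the
#'   N-terminal boundary (default 0 = minimum, i.e. a single homolog
#'   covering the query N-terminus vetoes uniqueness; larger values give a
#'   majority rule).
#' @param anchor_check When `TRUE` (default) and subject start coordinates
#'   are available, a hit counts as boundary evidence only if its alignment
#'   begins within `max_subject_start` residues of the subject's N-terminus
#'   or of the query's N-terminus — guarding against local-alignment
#'   truncation mimicking an extension while keeping full-N-terminus veto
#'   hits whose subject carries its own extension.
#' @param max_subject_start Anchor tolerance in residues (default 5).
#' @return A list of class `screen_params`.
#' @export
screen_params <- function(min_similarity_pct = 30, min_coverage_pct = 70,
                          top_k = 250, min_nte_len = 10, max_nte_len = NULL,
                          min_support = 10, start_quantile = 0,
                          anchor_check = TRUE, max_subject_start = 5) {
  if (min_similarity_pct < 0 || min_similarity_pct > 100 ||
      min_coverage_pct < 0 || min_coverage_pct > 100) {
    usage_error("thresholds must lie in [0, 100]")
  }
  if (top_k < 1 || min_nte_len < 1 || min_support < 1) {
    usage_error("top_k, min_nte_len and min_support must be >= 1")
  }
  if (start_quantile < 0 || start_quantile > 1) {
    usage_error("start_quantile must lie in [0, 1]")
  }
  structure(
    list(min_similarity_pct = min_similarity_pct,
         min_coverage_pct = min_coverage_pct, top_k = top_k,
         min_nte_len = min_nte_len, max_nte_len = max_nte_len,
         min_support = min_support, start_quantile = start_quantile,
         anchor_check = anchor_check, max_subject_start = max_subject_start),
    class = "screen_params"
  )
}

#' Filter and rank homolog hits for one query
#'
#' Applies the similarity/coverage filter (strict inequalities, so boundary
#' hits at exactly 30% similarity or 70% coverage are excluded) and keeps the
#' `top_k` hits by `rank_score`, ties broken lexicographically by subject id.
#' Idempotent: re-filtering retained hits returns them unchanged.
#'
#' @param hits Hits tibble for a single query (mixed query ids are an error).
#' @param params A [screen_params()] bundle.
#' @return The retained hits, ranked.
#' @export
filter_hits <- function(hits, params = screen_params()) {
  if (nrow(hits) > 0 && dplyr::n_distinct(hits$query_id) > 1) {
    usage_error("filter_hits expects hits for a single query, got %d",
                dplyr::n_distinct(hits$query_id))
  }
  hits |>
    filter(.data$similarity_pct > params$min_similarity_pct,
           .data$coverage_pct > params$min_coverage_pct) |>
    arrange(desc(.data$rank_score), .data$subject_id) |>
    head(params$top_k)
}

#' Call a unique N-terminal extension for one query
#'
#' The core verdict: the extension length is the number of query residues
#' before the earliest aligned query position over the retained homolog hits
#' (`nte_length = min_query_start - 1`), so any homolog covering the query
#' N-terminus vetoes a call. An NTE is called when the extension reaches
#' `min_nte_len` and enough hits support the comparison.
#'
#' @param query_record One-row proteome tibble for the query, or `NULL` if
#'   `query_id`/`query_length` are given directly.
#' @param retained Hits tibble already passed through [filter_hits()].
#' @param params A [screen_params()] bundle.
#' @param query_id,query_length Used when `query_record` is `NULL`.
#' @return A one-row tibble with `query_id`, `query_length`,
#'   `n_hits_retained`, `min_query_start`, `nte_length`, `is_nte`, `status`
#'   (`"ok"`, `"insufficient-support"` or `"no-anchored-hits"`) and
#'   `out_of_range`.
#' @export
call_nte <- function(query_record = NULL, retained, params = screen_params(),
                     query_id = NULL, query_length = NULL) {
  if (!is.null(query_record)) {
    query_id <- query_record$protein_id[1]
    query_length <- nchar(query_record$sequence[1])
  }
  n_ret <- nrow(retained)
  anchored <- retained
  if (params$anchor_check && n_ret > 0 && "subject_start" %in% names(retained) &&
      !all(is.na(retained$subject_start))) {
    # A hit is boundary evidence if it starts near the subject's N-terminus
    # (the subject's own start is represented, so a large query_start is
    # real) or near the query's N-terminus (it cannot inflate the call and
    # vetoes uniqueness directly).
    anchored <- filter(retained, is.na(.data$subject_start) |
                         .data$subject_start <= params$max_subject_start |
                         .data$query_start <= params$max_subject_start)
  }
  if (nrow(anchored) > 0) {
    starts <- sort(anchored$query_start)
    min_start <- as.integer(stats::quantile(starts, probs = params$start_quantile,
                                            type = 1, names = FALSE))
    nte_len <- min_start - 1L
  } else {
    min_start <- NA_integer_
    nte_len <- NA_integer_
  }
  status <- if (n_ret < params$min_support) {
    "insufficient-support"
  } else if (nrow(anchored) == 0) {
    "no-anchored-hits"
  } else {
    "ok"
  }
  is_nte <- status == "ok" && !is.na(nte_len) && nte_len >= params$min_nte_len
  out_of_range <- is_nte && !is.null(params$max_nte_len) &&
    nte_len > params$max_nte_len
  tibble(
    query_id = query_id,
    query_length = as.integer(query_length),
    n_hits_retained = as.integer(n_ret),
    min_query_start = min_start,
    nte_length = nte_len,
    is_nte = is_nte,
    status = status,
    out_of_range = out_of_range
  )
}

#' Screen a proteome for unique N-terminal extensions
#'
#' Runs [filter_hits()] and [call_nte()] for every query in a proteome,
#' against either precomputed BLAST tabular hits or subject proteomes
#' searched with the built-in aligner. Mixing the two hit sources in one
#' screen is rejected: raw alignment scores and bitscores are not on the
#' same scale, so their top-k rankings are not comparable.
#'
#' @param proteome Query proteome tibble.
#' @param hits Optional precomputed hits tibble (all queries together).
#' @param subjects Optional subject proteome (or list of proteomes) to search
#'   with the built-in aligner when `hits` is not supplied.
#' @param params A [screen_params()] bundle.
#' @param aln_params An [align_params()] bundle for the built-in route.
#' @return A calls tibble with one row per query (columns as [call_nte()]
#'   plus `genome_id`), queries in input order.
#' @export
screen_proteome <- function(proteome, hits = NULL, subjects = NULL,
                            params = screen_params(),
                            aln_params = align_params()) {
  check_proteome(proteome)
  if (is.null(hits) == is.null(subjects)) {
    usage_error("supply exactly one of 'hits' (parsed tabular) or 'subjects' (built-in alignment)")
  }
  if (!is.null(hits) && nrow(hits) > 0 &&
      dplyr::n_distinct(hits$hit_source) > 1) {
    usage_error("hits mix sources %s: in-house scores and bitscores are not comparable",
                paste(unique(hits$hit_source), collapse = "/"))
  }
  if (!is.null(subjects) && is.data.frame(subjects)) {
    subjects <- list(subjects)
  }
  calls <- purrr::map(seq_len(nrow(proteome)), function(i) {
    rec <- proteome[i, ]
    qh <- if (!is.null(hits)) {
      filter(hits, .data$query_id == rec$protein_id)
    } else {
      bind_rows(purrr::map(subjects, align_against,
                           query_record = rec, params = aln_params))
    }
    retained <- filter_hits(qh, params)
    call_nte(rec, retained, params)
  })
  bind_rows(calls) |>
    mutate(genome_id = proteome$genome_id[match(.data$query_id, proteome$protein_id)],
           .after = "query_id")
}

#' Annotate NTE calls with cross-genome conservation
#'
#' For every positive NTE call, lists the other genomes whose reciprocal-best
#' -hit ortholog also carries a called NTE.
#'
#' @param calls Calls tibble covering several genomes (needs `genome_id`).
#' @param orthologs Ortholog pairs from [reciprocal_best_hits()], possibly
#'   row-bound over several genome pairs.
#' @return `calls` with a `conserved_in` list-column of genome id vectors
#'   (empty for non-NTE calls and unpaired proteins).
#' @export
conservation_scan <- function(calls, orthologs) {
  edges <- bind_rows(
    select(orthologs, from = "protein_a", to = "protein_b",
           to_genome = "genome_b"),
    select(orthologs, from = "protein_b", to = "protein_a",
           to_genome = "genome_a")
  )
  nte_ids <- calls$query_id[calls$is_nte]
  conserved <- purrr::map2(calls$query_id, calls$is_nte, function(id, pos) {
    if (!pos) {
      return(character())
    }
    partners <- edges[edges$from == id & edges$to %in% nte_ids, ]
    sort(unique(partners$to_genome))
  })
  mutate(calls, conserved_in = conserved)
}

#' Cluster proteins into families by single-linkage over homolog hits
#'
#' Builds within-proteome protein families as connected components of the
#' graph whose edges are hits passing the same strict similarity/coverage
#' filters used by the screen, so the paralog analysis reuses the published
#' thresholds rather than introducing new ones.
#'
#' @param proteome Proteome tibble.
#' @param params A [screen_params()] bundle (filters reused).
#' @param aln_params An [align_params()] bundle.
#' @param hits Optional precomputed all-vs-all hits; computed with the
#'   built-in aligner when absent.
#' @return A tibble with columns `protein_id`, `family_id`; singletons get
#'   their own family.
#' @export
cluster_families <- function(proteome, params = screen_params(),
                             aln_params = align_params(), hits = NULL) {
  check_proteome(proteome)
  if (is.null(hits)) {
    hits <- bind_rows(purrr::map(seq_len(nrow(proteome)), function(i) {
      align_against(proteome[i, ], proteome, aln_params)
    }))
  }
  passing <- filter(hits,
                    .data$similarity_pct > params$min_similarity_pct,
                    .data$coverage_pct > params$min_coverage_pct)
  g <- igraph::graph_from_data_frame(
    d = select(passing, "query_id", "subject_id"),
    directed = FALSE,
    vertices = proteome$protein_id
  )
  comp <- igraph::components(g)
  tibble(
    protein_id = names(comp$membership),
    family_id = paste0("fam", unname(comp$membership))
  )
}

#' Detect conventional/NTE paralog pairs
#'
#' Reports, per family, every pairing of a conventional member (no extension:
#' `nte_length == 0`) with an NTE-bearing member — the dual-FtsZ pattern of a
#' genome keeping one canonical copy and one copy carrying a unique
#' N-terminal extension.
#'
#' @param families Tibble with columns `protein_id`, `family_id`.
#' @param calls Calls tibble from [screen_proteome()].
#' @return A tibble with columns `family_id`, `conventional_id`, `nte_id`,
#'   `nte_length`.
#' @export
paralog_nte_pairs <- function(families, calls) {
  joined <- dplyr::inner_join(families, calls,
                              by = c(protein_id = "query_id"))
  fams <- split(joined, joined$family_id)
  rows <- purrr::map(fams, function(f) {
    conv <- f$protein_id[!is.na(f$nte_length) & f$nte_length == 0]
    nte <- f[f$is_nte, , drop = FALSE]
    if (length(conv) == 0 || nrow(nte) == 0) {
      return(NULL)
    }
    tidyr::crossing(conventional_id = conv,
                    nte_id = nte$protein_id) |>
      mutate(family_id = f$family_id[1],
             nte_length = nte$nte_length[match(.data$nte_id, nte$protein_id)]) |>
      select("family_id", "conventional_id", "nte_id", "nte_length")
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    tibble(family_id = character(), conventional_id = character(),
           nte_id = character(), nte_length = integer())
  } else {
    out
  }
}
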