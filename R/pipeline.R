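#' Read a pipeline configuration
#'
#' Configurations are YAML mappings (or plain R lists) whose keys mirror the
#' arguments of [run_screen()] and [run_memsig()]; parameter sub-maps
#' (`screen`, `align`, `moment`, `tm_scan`) override the corresponding
#' parameter-bundle defaults. Values supplied directly to the run functions
#' override the file.
#'
#' @param config A YAML file path or a named list.
#' @param overrides Named list merged over the file contents.
#' @return A named list.
#' @export
read_run_config <- function(config, overrides = list()) {
  cfg <- if (is.character(config)) {
    if (!file.exists(config)) usage_error("config file does not exist: %s", config)
    yaml::read_yaml(config)
  } else if (is.list(config)) {
    config
  } else {
    usage_error("config must be a file path or a list")
  }
  utils::modifyList(cfg, overrides)
}

run_metadata <- function(cfg) {
  list(
    package = "proteosig",
    version = as.character(utils::packageVersion("proteosig")),
    seed = cfg$seed %||% NA,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = cfg[setdiff(names(cfg), c("out_dir"))]
  )
}

log_msg <- function(level, msg, ...) {
  message(sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%S"), level,
                  sprintf(msg, ...)))
}

#' Run the NTE screen end to end
#'
#' Orchestrates the full screen: read query proteome(s), gather homolog hits
#' (from a BLAST tabular file or by built-in alignment against a subject
#' database), filter and rank, call extensions, annotate amphipathic
#' character, and — when several query genomes are given — annotate
#' cross-genome conservation via reciprocal best hits. Writes
#' `screen_report.tsv` and `screen_report.json` to the output directory.
#'
#' @param config YAML path or list with keys: `query_fastas` (character
#'   vector of proteome FASTA paths), exactly one of `hits_tab` (BLAST
#'   tabular path; single query genome only) or `db_fasta` (subject FASTA
#'   for the built-in aligner), `out_dir`, optional `seed`, optional
#'   `ss_annotations` (TSV path), and optional `screen`/`align`/`moment`
#'   parameter maps.
#' @param ... Overrides merged over the config.
#' @return The annotated calls tibble, invisibly.
#' @export
run_screen <- function(config, ...) {
  cfg <- read_run_config(config, list(...))
  if (is.null(cfg$query_fastas) || is.null(cfg$out_dir)) {
    usage_error("config needs 'query_fastas' and 'out_dir'")
  }
  if (is.null(cfg$hits_tab) == is.null(cfg$db_fasta)) {
    usage_error("config needs exactly one of 'hits_tab' or 'db_fasta'")
  }
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  sp <- do.call(screen_params, cfg$screen %||% list())
  ap <- do.call(align_params, cfg$align %||% list())
  mp <- do.call(moment_params, cfg$moment %||% list())
  if (length(cfg$query_fastas) == 0) {
    # an empty query set is a valid (empty) screen, not an error
    empty <- tibble(query_id = character(), genome_id = character(),
                    query_length = integer(), n_hits_retained = integer(),
                    min_query_start = integer(), nte_length = integer(),
                    is_nte = logical(), status = character(),
                    out_of_range = logical(), conserved_in = character())
    readr::write_tsv(empty, file.path(cfg$out_dir, "screen_report.tsv"))
    jsonlite::write_json(list(metadata = run_metadata(cfg), calls = empty),
                         file.path(cfg$out_dir, "screen_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    log_msg("INFO", "screen finished: empty query set")
    return(invisible(empty))
  }
  proteomes <- purrr::map(cfg$query_fastas, read_proteome)
  log_msg("INFO", "screening %d genome(s)", length(proteomes))
  calls_by_genome <- purrr::map(proteomes, function(prot) {
    if (!is.null(cfg$hits_tab)) {
      if (length(proteomes) > 1) {
        usage_error("'hits_tab' supports a single query genome")
      }
      hits <- read_blast_hits(cfg$hits_tab, prot)
      screen_proteome(prot, hits = hits, params = sp)
    } else {
      db <- read_proteome(cfg$db_fasta, genome_id = "db")
      screen_proteome(prot, subjects = db, params = sp, aln_params = ap)
    }
  })
  calls <- bind_rows(calls_by_genome)
  if (length(proteomes) > 1) {
    log_msg("INFO", "computing reciprocal best hits for conservation scan")
    pairs <- utils::combn(length(proteomes), 2, simplify = FALSE)
    orthologs <- bind_rows(purrr::map(pairs, function(ij) {
      reciprocal_best_hits(proteomes[[ij[1]]], proteomes[[ij[2]]], ap)
    }))
    calls <- conservation_scan(calls, orthologs)
  } else {
    calls <- mutate(calls, conserved_in = list(character()))
  }
  ss <- if (!is.null(cfg$ss_annotations)) read_ss_annotations(cfg$ss_annotations)
  all_prot <- bind_rows(proteomes)
  calls <- annotate_amphipathic(calls, all_prot, mp, ss_annotations = ss)
  flat <- mutate(calls,
                 conserved_in = purrr::map_chr(.data$conserved_in, paste, collapse = ","))
  readr::write_tsv(flat, file.path(cfg$out_dir, "screen_report.tsv"))
  jsonlite::write_json(
    list(metadata = run_metadata(cfg),
         params = sp[!vapply(sp, is.null, logical(1))],
         calls = flat),
    file.path(cfg$out_dir, "screen_report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  log_msg("INFO", "screen finished: %d queries, %d NTE call(s)",
          nrow(calls), sum(calls$is_nte))
  invisible(calls)
}

#' Run the membrane-signature census end to end
#'
#' Computes per-genome signatures (from supplied predictor files or the
#' built-in rule-based predictors), fits the reference confidence ellipses,
#' classifies every genome, and writes `signatures.tsv`, `outliers.tsv`,
#' `scatter.tsv` (plot-ready points plus ellipse boundaries) and
#' `memsig_report.json`.
#'
#' @param config YAML path or list. Either `panel_tsv` (a precomputed
#'   signature table with columns `genome_id`, `frac_tm_pct`, `sec_ratio`
#'   and optional `group`) or `genomes` — a list of maps with keys `fasta`,
#'   optional `tm`/`sp_v4`/`sp_v5` prediction paths, optional `group`; set
#'   `builtin_predictors: true` to use the rule-based predictors instead of
#'   files. Optional: `levels` (default 0.95, 0.999), `reference_group`
#'   (group fitted as the reference panel; default the largest group),
#'   `out_dir`, `seed`.
#' @param ... Overrides merged over the config.
#' @return A list with `signatures`, `model` and `outliers`, invisibly.
#' @export
run_memsig <- function(config, ...) {
  cfg <- read_run_config(config, list(...))
  if (is.null(cfg$out_dir)) usage_error("config needs 'out_dir'")
  if (is.null(cfg$panel_tsv) && is.null(cfg$genomes)) {
    usage_error("config needs 'panel_tsv' or 'genomes'")
  }
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  levels <- as.numeric(cfg$levels %||% c(0.95, 0.999))
  signatures <- tibble()
  if (!is.null(cfg$panel_tsv)) {
    signatures <- readr::read_tsv(cfg$panel_tsv, show_col_types = FALSE,
                                  progress = FALSE)
    if (!"group" %in% names(signatures)) signatures$group <- "reference"
    if (!"sec_ratio_defined" %in% names(signatures)) {
      signatures$sec_ratio_defined <- !is.na(signatures$sec_ratio)
    }
  }
  if (!is.null(cfg$genomes)) {
    tmp <- do.call(tm_scan_params, cfg$tm_scan %||% list())
    sigs <- purrr::map(cfg$genomes, function(g) {
      prot <- read_proteome(g$fasta, genome_id = g$genome_id %||% NULL)
      if (isTRUE(cfg$builtin_predictors)) {
        tm <- predict_tm(prot, tmp)
        s4 <- predict_sp(prot, sp_rule_params("v4like"))
        s5 <- predict_sp(prot, sp_rule_params("v5like"))
      } else {
        if (is.null(g$tm) || is.null(g$sp_v4) || is.null(g$sp_v5)) {
          usage_error("genome '%s': predictor files missing and builtin_predictors not set",
                      prot$genome_id[1])
        }
        tm <- read_tm_predictions(g$tm)
        s4 <- read_sp_predictions(g$sp_v4, "v4like")
        s5 <- read_sp_predictions(g$sp_v5, "v5like")
      }
      sig <- genome_signature(prot, tm, s4, s5, quiet = TRUE)
      sig$group <- g$group %||% "query"
      sig$predictor <- if (isTRUE(cfg$builtin_predictors)) "builtin" else "external"
      if (!sig$sec_ratio_defined) {
        log_msg("WARN", "genome '%s': zero v4-like Sec calls, sec_ratio undefined",
                sig$genome_id)
      }
      sig
    })
    signatures <- bind_rows(signatures, bind_rows(sigs))
  }
  ref_group <- cfg$reference_group %||%
    names(sort(table(signatures$group), decreasing = TRUE))[1]
  reference <- filter(signatures, .data$group == ref_group)
  log_msg("INFO", "fitting reference ellipses on group '%s' (%d genomes)",
          ref_group, nrow(reference))
  model <- fit_reference_ellipse(reference, levels = levels)
  outliers <- classify_genome(signatures, model)
  bounds <- bind_rows(purrr::map(levels, ellipse_boundary, model = model))
  readr::write_tsv(signatures, file.path(cfg$out_dir, "signatures.tsv"))
  readr::write_tsv(outliers, file.path(cfg$out_dir, "outliers.tsv"))
  readr::write_tsv(
    bind_rows(
      mutate(select(signatures, "genome_id", "frac_tm_pct", "sec_ratio",
                    "group"), kind = "point", level = NA_real_),
      mutate(select(bounds, "frac_tm_pct", "sec_ratio", "level"),
             genome_id = NA_character_, group = "ellipse", kind = "boundary")
    ),
    file.path(cfg$out_dir, "scatter.tsv")
  )
  jsonlite::write_json(
    list(metadata = run_metadata(cfg),
         model = list(mean = model$mean, covariance = model$covariance,
                      levels = model$levels,
                      chi2_quantiles = model$chi2_quantiles,
                      n_reference = model$n, reference_group = ref_group),
         outliers = outliers),
    file.path(cfg$out_dir, "memsig_report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, matrix = "rowmajor"
  )
  log_msg("INFO", "memsig finished: %d genome(s) classified", nrow(outliers))
  invisible(list(signatures = signatures, model = model, outliers = outliers))
}
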