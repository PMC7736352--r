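#' Hydrophobic-moment parameters
#'
#' Settings for Eisenberg hydrophobic-moment scanning of N-terminal
#' extensions, the sequence-based score for amphipathic alpha-helix
#' character: residues are placed around an ideal helix at 100 degrees per
#' residue and the vector sum of their hydrophobicities measures how
#' segregated the hydrophobic face is.
#'
#' @param scale Named per-residue hydrophobicity vector, or the name of a
#'   built-in scale (default `"eisenberg"`, the Eisenberg consensus scale).
#' @param delta_deg Helical rotation per residue in degrees (default 100,
#'   the canonical alpha-helix twist); must lie in (0, 360).
#' @param window Window length in residues (default 18, about five helix
#'   turns); must be at least 4.
#' @param mu_threshold Minimum mean hydrophobic moment per residue for an
#'   amphipathic call (default 0.4, the classical surface-seeking region).
#' @param h_max Maximum mean hydrophobicity of the best window (default
#'   0.4): uniformly hydrophobic windows are transmembrane-like, not
#'   amphipathic.
#' @return A list of class `moment_params`.
#' @export
moment_params <- function(scale = "eisenberg", delta_deg = 100, window = 18,
                          mu_threshold = 0.4, h_max = 0.4) {
  if (is.character(scale)) {
    scale <- hydrophobicity_scale(scale)
  }
  if (delta_deg <= 0 || delta_deg >= 360) {
    usage_error("delta_deg must lie strictly between 0 and 360")
  }
  if (window < 4) usage_error("window must be at least 4 residues")
  structure(
    list(scale = scale, delta_deg = delta_deg, window = window,
         mu_threshold = mu_threshold, h_max = h_max),
    class = "moment_params"
  )
}

#' Mean hydrophobic moment of one window
#'
#' Classical Eisenberg moment: with per-residue hydrophobicities `H_i` and
#' helical twist `delta`,
#' `mu_H = sqrt((sum H_i sin(i delta))^2 + (sum H_i cos(i delta))^2) / N`.
#'
#' @param window_sequence Amino-acid string scored as one window.
#' @param params A [moment_params()] bundle (only `scale` and `delta_deg`
#'   are used; the window length is taken from the sequence).
#' @return The mean hydrophobic moment per residue (non-negative scalar).
#' @examples
#' hydrophobic_moment("LLKKLLKKLLKKLLKKLL", moment_params())
#' @export
hydrophobic_moment <- function(window_sequence, params = moment_params()) {
  res <- seq_chars(window_sequence)
  missing <- setdiff(res, names(params$scale))
  if (length(missing) > 0) {
    processing_error("residue '%s' absent from hydrophobicity scale", missing[1])
  }
  h <- unname(params$scale[res])
  delta <- params$delta_deg * pi / 180
  i <- seq_along(h)
  sqrt(sum(h * sin(i * delta))^2 + sum(h * cos(i * delta))^2) / length(h)
}

#' Scan a sequence for its most amphipathic window
#'
#' Slides the moment window along the sequence one residue at a time and
#' reports the window with the largest mean hydrophobic moment (leftmost on
#' ties). Sequences shorter than the window are scored as a single
#' full-length window. The amphipathic call requires a high moment and a
#' moderate mean hydrophobicity (`mu_h >= mu_threshold` and
#' `mean_h <= h_max`).
#'
#' @param sequence Amino-acid string, at least 4 residues.
#' @param params A [moment_params()] bundle.
#' @param ss Optional per-residue secondary-structure string (`H`/`E`/`C`,
#'   same length as `sequence`), e.g. from an external structure predictor;
#'   when given, only windows lying entirely in helical (`H`) runs are
#'   scored, and a sequence with no qualifying window is reported
#'   non-amphipathic.
#' @return A one-row tibble with `best_window_start`, `window_length`,
#'   `mu_h`, `mean_h`, `is_amphipathic`.
#' @export
scan_amphipathic <- function(sequence, params = moment_params(), ss = NULL) {
  n <- nchar(sequence)
  if (n < 4) usage_error("sequence must be at least 4 residues, got %d", n)
  w <- min(params$window, n)
  starts <- seq_len(n - w + 1)
  if (!is.null(ss)) {
    if (nchar(ss) != n) {
      usage_error("secondary-structure string length (%d) != sequence length (%d)",
                  nchar(ss), n)
    }
    helical <- seq_chars(ss) == "H"
    starts <- starts[vapply(starts, function(s) all(helical[s:(s + w - 1)]),
                            logical(1))]
    if (length(starts) == 0) {
      return(tibble(best_window_start = NA_integer_, window_length = w,
                    mu_h = NA_real_, mean_h = NA_real_,
                    is_amphipathic = FALSE))
    }
  }
  mus <- vapply(starts, function(s) {
    hydrophobic_moment(substr(sequence, s, s + w - 1), params)
  }, numeric(1))
  best <- starts[which.max(mus)]
  mu <- max(mus)
  res <- seq_chars(substr(sequence, best, best + w - 1))
  mean_h <- mean(unname(params$scale[res]))
  tibble(
    best_window_start = as.integer(best),
    window_length = as.integer(w),
    mu_h = mu,
    mean_h = mean_h,
    is_amphipathic = mu >= params$mu_threshold && mean_h <= params$h_max
  )
}

#' Annotate NTE calls with amphipathic-helix character
#'
#' For each positive NTE call, scores the extension itself (the first
#' `nte_length` residues of the query) with [scan_amphipathic()].
#'
#' @param calls Calls tibble from [screen_proteome()].
#' @param proteome Proteome tibble holding the query sequences.
#' @param params A [moment_params()] bundle.
#' @param ss_annotations Optional tibble (`protein_id`, `ss`) of per-residue
#'   secondary-structure strings for the full proteins; the NTE-spanning
#'   prefix is used.
#' @return `calls` with added columns `amphipathic`, `amph_mu_h`,
#'   `amph_mean_h`, `amph_window_start` (NA for non-NTE calls and for
#'   extensions shorter than 4 residues).
#' @export
annotate_amphipathic <- function(calls, proteome, params = moment_params(),
                                 ss_annotations = NULL) {
  check_proteome(proteome)
  score_one <- function(id, is_nte, len) {
    if (!isTRUE(is_nte) || is.na(len) || len < 4) {
      return(tibble(amphipathic = NA, amph_mu_h = NA_real_,
                    amph_mean_h = NA_real_, amph_window_start = NA_integer_))
    }
    seq <- proteome$sequence[match(id, proteome$protein_id)]
    nte_seq <- substr(seq, 1, len)
    ss <- NULL
    if (!is.null(ss_annotations) && id %in% ss_annotations$protein_id) {
      ss <- substr(ss_annotations$ss[match(id, ss_annotations$protein_id)], 1, len)
    }
    r <- scan_amphipathic(nte_seq, params, ss = ss)
    tibble(amphipathic = r$is_amphipathic, amph_mu_h = r$mu_h,
           amph_mean_h = r$mean_h, amph_window_start = r$best_window_start)
  }
  ann <- bind_rows(purrr::pmap(
    list(calls$query_id, calls$is_nte, calls$nte_length), score_one
  ))
  dplyr::bind_cols(calls, ann)
}

#' Read per-protein secondary-structure annotations
#'
#' Two-column TSV: `protein_id` and an `H`/`E`/`C` string, one residue per
#' character — the route for using externally predicted helix annotations
#' instead of the hydrophobic-moment heuristic alone.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `protein_id`, `ss`.
#' @export
read_ss_annotations <- function(path) {
  readr::read_tsv(path, col_names = c("protein_id", "ss"),
                  col_types = readr::cols(.default = readr::col_character()),
                  progress = FALSE)
}
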