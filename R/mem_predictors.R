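# Residues counted as hydrophobic by the rule-based predictors (positive
# Kyte-Doolittle hydropathy, plus tryptophan).
HYDROPHOBIC_SET <- c("A", "C", "F", "I", "L", "M", "V", "W")

#' Transmembrane-scan parameters
#'
#' Settings for the rule-based sliding-window transmembrane scanner used
#' when external helix predictions are not supplied. A window whose mean
#' Kyte-Doolittle hydropathy reaches the threshold marks a candidate
#' membrane-spanning segment.
#'
#' @param scale Hydropathy table or built-in scale name (default
#'   `"kyte_doolittle"`).
#' @param window Odd window length in residues (default 19, a typical
#'   membrane-spanning helix).
#' @param threshold Mean-hydropathy cutoff at window centers (default 1.6).
#' @param min_gap Segments whose qualifying centers are separated by fewer
#'   than this many positions are merged (default 5).
#' @return A list of class `tm_scan_params`.
#' @export
tm_scan_params <- function(scale = "kyte_doolittle", window = 19,
                           threshold = 1.6, min_gap = 5) {
  if (is.character(scale)) scale <- hydrophobicity_scale(scale)
  if (window %% 2 == 0) usage_error("window must be odd")
  if (!is.finite(threshold)) usage_error("threshold must be finite")
  structure(list(scale = scale, window = window, threshold = threshold,
                 min_gap = min_gap),
            class = "tm_scan_params")
}

#' Predict transmembrane segments with a hydropathy scan
#'
#' Rule-based substitute predictor (reported downstream as
#' `predictor = "builtin"`): segments are maximal runs of window centers
#' with mean hydropathy at or above the threshold, merged across short
#' gaps, and reported as full window extents. Proteins shorter than the
#' window get zero helices. Deterministic and independent of protein order.
#'
#' @param proteome Proteome tibble.
#' @param params A [tm_scan_params()] bundle.
#' @return A predictions tibble in the same shape as
#'   [read_tm_predictions()]: `protein_id`, `seq_length`, `n_helices`,
#'   `helix_spans`.
#' @export
predict_tm <- function(proteome, params = tm_scan_params()) {
  check_proteome(proteome)
  half <- (params$window - 1L) / 2L
  rows <- purrr::map2(proteome$protein_id, proteome$sequence, function(id, s) {
    n <- nchar(s)
    spans <- tibble(start = integer(), end = integer())
    if (n >= params$window) {
      h <- unname(params$scale[seq_chars(s)])
      h[is.na(h)] <- 0
      cs <- c(0, cumsum(h))
      win_means <- (cs[(params$window + 1):(n + 1)] - cs[1:(n - params$window + 1)]) /
        params$window
      centers <- which(win_means >= params$threshold) + half
      if (length(centers) > 0) {
        breaks <- which(diff(centers) - 1L >= params$min_gap)
        run_start <- pmax(centers[c(1, breaks + 1)] - half, 1L)
        run_end <- pmin(centers[c(breaks, length(centers))] + half, n)
        # trim window overhang back to residues that are themselves
        # hydrophobic at the threshold, so the span is the planted run
        for (k in seq_along(run_start)) {
          while (run_start[k] < run_end[k] && h[run_start[k]] < params$threshold) {
            run_start[k] <- run_start[k] + 1L
          }
          while (run_end[k] > run_start[k] && h[run_end[k]] < params$threshold) {
            run_end[k] <- run_end[k] - 1L
          }
        }
        spans <- tibble(start = as.integer(run_start),
                        end = as.integer(run_end))
      }
    }
    tibble(protein_id = id, seq_length = n,
           n_helices = nrow(spans), helix_spans = list(spans))
  })
  bind_rows(rows)
}

#' Signal-peptide rule parameters
#'
#' Settings for the rule-based Sec signal-peptide caller. The two regimes
#' emulate the strictness relationship between two generations of
#' signal-peptide predictors: `v4like` demands a longer hydrophobic core
#' than `v5like` and is therefore, by construction, at most as permissive —
#' every `v4like` call is also a `v5like` call.
#'
#' @param regime `"v4like"` or `"v5like"`.
#' @param n_region Number of leading residues whose net charge (K/R = +1,
#'   D/E = -1) must be at least +1 (default 5).
#' @param h_min Minimum hydrophobic run length within the first 25 residues
#'   (default 10 for `v4like`, 8 for `v5like`); at least 4.
#' @param c_allowed Residues allowed at the -3 and -1 positions relative to
#'   cleavage (default A, G, S, C, T).
#' @param min_cleavage,max_cleavage Cleavage-site search window, 1-based
#'   position of the first mature residue (defaults 10 and 35); identical
#'   for both regimes so regime containment holds structurally.
#' @return A list of class `sp_rule_params`.
#' @export
sp_rule_params <- function(regime = c("v5like", "v4like"), n_region = 5,
                           h_min = NULL, c_allowed = c("A", "G", "S", "C", "T"),
                           min_cleavage = 10, max_cleavage = 35) {
  regime <- match.arg(regime)
  h_min <- h_min %||% switch(regime, v4like = 10, v5like = 8)
  if (h_min < 4) usage_error("h_min must be at least 4")
  structure(list(regime = regime, n_region = n_region, h_min = h_min,
                 c_allowed = c_allowed, min_cleavage = min_cleavage,
                 max_cleavage = max_cleavage),
            class = "sp_rule_params")
}

#' Predict Sec signal peptides with sequence rules
#'
#' Rule-based substitute predictor: a protein is called secreted iff (1) the
#' net charge of the first `n_region` residues is at least +1, (2) a
#' hydrophobic run of at least `h_min` residues occurs within the first 25
#' residues, and (3) a cleavage position with small residues at -3/-1
#' exists within the search window. The reported cleavage position is the
#' earliest compliant one. Proteins shorter than 20 residues are never
#' called.
#'
#' @param proteome Proteome tibble.
#' @param params An [sp_rule_params()] bundle.
#' @return A predictions tibble in the same shape as
#'   [read_sp_predictions()]: `protein_id`, `regime`, `is_secreted`,
#'   `cleavage_pos`.
#' @export
predict_sp <- function(proteome, params = sp_rule_params()) {
  check_proteome(proteome)
  rows <- purrr::map2(proteome$protein_id, proteome$sequence, function(id, s) {
    res <- seq_chars(s)
    n <- length(res)
    secreted <- FALSE
    cpos <- NA_integer_
    if (n >= 20) {
      nr <- res[seq_len(min(params$n_region, n))]
      charge <- sum(nr %in% c("K", "R")) - sum(nr %in% c("D", "E"))
      run_ok <- max_run(res[seq_len(min(25, n))] %in% HYDROPHOBIC_SET) >= params$h_min
      if (charge >= 1 && run_ok) {
        for (p in seq(params$min_cleavage, min(params$max_cleavage, n))) {
          if (res[p - 3] %in% params$c_allowed && res[p - 1] %in% params$c_allowed) {
            secreted <- TRUE
            cpos <- as.integer(p)
            break
          }
        }
      }
    }
    tibble(protein_id = id, regime = params$regime,
           is_secreted = secreted, cleavage_pos = cpos)
  })
  bind_rows(rows)
}

max_run <- function(x) {
  if (!any(x)) return(0L)
  r <- rle(x)
  max(r$lengths[r$values])
}
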