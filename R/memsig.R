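#' Compute a genome's membrane signature
#'
#' The per-genome coordinates of the membrane-signature plane: the
#' percentage of proteins with at least one predicted transmembrane helix
#' (x axis) and, on the y axis, the ratio of the Sec signal-peptide call
#' percentages under the two predictor regimes. All percentages are taken
#' out of the total number of ORFs in the proteome.
#'
#' @param proteome Proteome tibble (the census denominator).
#' @param tm Transmembrane predictions tibble ([read_tm_predictions()] or
#'   [predict_tm()]).
#' @param sp_v4,sp_v5 Signal-peptide predictions per regime.
#' @param quiet Suppress the message about proteins lacking predictions
#'   (which count as negative).
#' @return A one-row tibble with `genome_id`, `n_orfs`, `frac_tm_pct`,
#'   `frac_sec_v4_pct`, `frac_sec_v5_pct`, `sec_ratio` and
#'   `sec_ratio_defined` (`FALSE`, with `sec_ratio = NA`, when no protein
#'   is called under the v4-like regime).
#' @examples
#' prot <- tibble::tibble(protein_id = paste0("p", 1:10), genome_id = "g",
#'                        sequence = strrep("MKTAYIAKQR", 25), description = "")
#' tm <- predict_tm(prot)
#' sig <- genome_signature(prot, tm, predict_sp(prot, sp_rule_params("v4like")),
#'                         predict_sp(prot, sp_rule_params("v5like")))
#' @export
genome_signature <- function(proteome, tm, sp_v4, sp_v5, quiet = FALSE) {
  check_proteome(proteome)
  n_orfs <- nrow(proteome)
  ids <- proteome$protein_id
  for (preds in list(tm, sp_v4, sp_v5)) {
    if (anyDuplicated(preds$protein_id)) {
      usage_error("prediction table lists protein '%s' more than once",
                  preds$protein_id[duplicated(preds$protein_id)][1])
    }
  }
  missing_any <- unique(c(setdiff(ids, tm$protein_id),
                          setdiff(ids, sp_v4$protein_id),
                          setdiff(ids, sp_v5$protein_id)))
  if (length(missing_any) > 0 && !quiet) {
    message(sprintf("%d protein(s) lack a prediction and count as negative",
                    length(missing_any)))
  }
  n_tm <- sum(ids %in% tm$protein_id[tm$n_helices >= 1])
  n_v4 <- sum(ids %in% sp_v4$protein_id[sp_v4$is_secreted])
  n_v5 <- sum(ids %in% sp_v5$protein_id[sp_v5$is_secreted])
  f_v4 <- n_v4 / n_orfs * 100
  f_v5 <- n_v5 / n_orfs * 100
  tibble(
    genome_id = proteome$genome_id[1],
    n_orfs = n_orfs,
    frac_tm_pct = n_tm / n_orfs * 100,
    frac_sec_v4_pct = f_v4,
    frac_sec_v5_pct = f_v5,
    sec_ratio = if (n_v4 > 0) f_v5 / f_v4 else NA_real_,
    sec_ratio_defined = n_v4 > 0
  )
}

#' Fit a bivariate-normal confidence-ellipse model to a reference panel
#'
#' Fits the reference distribution in the (TM-fraction, Sec-ratio) plane
#' with the sample mean and unbiased sample covariance; confidence-ellipse
#' boundaries lie at squared Mahalanobis distance equal to the chi-square
#' quantile with 2 degrees of freedom at each level.
#'
#' @param signatures Signature tibble with columns `frac_tm_pct` and
#'   `sec_ratio` (rows with undefined `sec_ratio` are dropped with a
#'   warning); at least 3 usable rows.
#' @param levels Confidence levels (default `c(0.95, 0.999)`).
#' @return An object of class `ellipse_model` with elements `mean`,
#'   `covariance`, `levels`, `chi2_quantiles`, `n` and the reference
#'   `frac_tm_pct` values (used for percentiles).
#' @export
fit_reference_ellipse <- function(signatures, levels = c(0.95, 0.999)) {
  if (any(levels <= 0 | levels >= 1)) usage_error("levels must lie in (0, 1)")
  levels <- sort(unique(levels))
  usable <- signatures
  if ("sec_ratio_defined" %in% names(usable)) {
    usable <- filter(usable, .data$sec_ratio_defined)
  }
  usable <- filter(usable, !is.na(.data$sec_ratio), !is.na(.data$frac_tm_pct))
  if (nrow(usable) < nrow(signatures)) {
    warn(sprintf("%d signature(s) with undefined sec_ratio dropped from the fit",
                 nrow(signatures) - nrow(usable)))
  }
  if (nrow(usable) < 3) {
    usage_error("need at least 3 signatures with a defined sec_ratio, got %d",
                nrow(usable))
  }
  x <- cbind(frac_tm_pct = usable$frac_tm_pct, sec_ratio = usable$sec_ratio)
  mu <- colMeans(x)
  sigma <- stats::cov(x)
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-12 * max(abs(ev), 1)) {
    ax <- if (sigma["frac_tm_pct", "frac_tm_pct"] <= sigma["sec_ratio", "sec_ratio"]) {
      "frac_tm_pct"
    } else {
      "sec_ratio"
    }
    processing_error(
      "singular covariance: no variation (or collinear panel) along '%s'", ax)
  }
  structure(
    list(mean = mu, covariance = sigma, levels = levels,
         chi2_quantiles = setNames(qchisq(levels, df = 2), format(levels)),
         n = nrow(usable), reference_frac_tm = usable$frac_tm_pct),
    class = "ellipse_model"
  )
}

#' @export
print.ellipse_model <- function(x, ...) {
  cat(sprintf("Bivariate confidence-ellipse model (n = %d reference genomes)\n", x$n))
  cat(sprintf("  mean: frac_tm_pct = %.3f, sec_ratio = %.3f\n",
              x$mean[1], x$mean[2]))
  cat("  levels:", paste(sprintf("%g%% (chi2 = %.3f)", 100 * x$levels,
                                 x$chi2_quantiles), collapse = ", "), "\n")
  invisible(x)
}

#' Classify genomes against a fitted reference ellipse
#'
#' Computes each genome's squared Mahalanobis distance from the reference
#' mean and whether it falls inside the confidence ellipse at every fitted
#' level, plus the percentile of its TM fraction among the reference
#' genomes (strictly-smaller share, so "greater than 99.7% of strains"
#' reads literally).
#'
#' @param signatures Signature tibble (one or more rows) to classify.
#' @param model An `ellipse_model` from [fit_reference_ellipse()].
#' @param reference Optional signature tibble whose `frac_tm_pct` defines
#'   the percentile; defaults to the panel the model was fitted on.
#' @return A tibble with `genome_id`, `mahalanobis_sq`, one logical
#'   `inside_<level>` column per level, `frac_tm_percentile` and `reason`
#'   (`"undefined-sec-ratio"` rows get `NA` distances and inside flags).
#' @export
classify_genome <- function(signatures, model, reference = NULL) {
  if (!inherits(model, "ellipse_model")) usage_error("model must be an ellipse_model")
  ref_tm <- if (is.null(reference)) model$reference_frac_tm else reference$frac_tm_pct
  inside_names <- paste0("inside_", level_label(model$levels))
  rows <- purrr::map(seq_len(nrow(signatures)), function(i) {
    sig <- signatures[i, ]
    pctl <- mean(ref_tm < sig$frac_tm_pct) * 100
    defined <- !is.na(sig$sec_ratio)
    if (!defined) {
      d2 <- NA_real_
      inside <- rep(NA, length(model$levels))
      reason <- "undefined-sec-ratio"
    } else {
      d2 <- mahalanobis(c(sig$frac_tm_pct, sig$sec_ratio),
                        center = model$mean, cov = model$covariance)
      inside <- unname(d2 <= model$chi2_quantiles)
      reason <- ""
    }
    out <- tibble(genome_id = sig$genome_id, mahalanobis_sq = d2)
    for (k in seq_along(inside_names)) out[[inside_names[k]]] <- inside[k]
    out$frac_tm_percentile <- pctl
    out$reason <- reason
    out
  })
  bind_rows(rows)
}

#' Boundary points of a fitted confidence ellipse
#'
#' @param model An `ellipse_model`.
#' @param level One of the model's confidence levels.
#' @param n Number of boundary points.
#' @return A tibble with `frac_tm_pct`, `sec_ratio`, `level`.
#' @export
ellipse_boundary <- function(model, level = model$levels[1], n = 181) {
  r2 <- qchisq(level, df = 2)
  eg <- eigen(model$covariance, symmetric = TRUE)
  theta <- seq(0, 2 * pi, length.out = n)
  circ <- rbind(cos(theta), sin(theta)) * sqrt(r2)
  pts <- t(eg$vectors %*% (sqrt(pmax(eg$values, 0)) * circ) + model$mean)
  tibble(frac_tm_pct = pts[, 1], sec_ratio = pts[, 2], level = level)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted ellipse model
#'
#' @param x An `ellipse_model`.
#' @param ... Unused.
#' @return One row per model parameter (`term`, `estimate`).
#' @method tidy ellipse_model
#' @export
tidy.ellipse_model <- function(x, ...) {
  tibble(
    term = c("mean_frac_tm_pct", "mean_sec_ratio", "var_frac_tm_pct",
             "cov_frac_tm_sec_ratio", "var_sec_ratio"),
    estimate = unname(c(x$mean[1], x$mean[2], x$covariance[1, 1],
                        x$covariance[1, 2], x$covariance[2, 2]))
  )
}

#' One-row summary of a fitted ellipse model
#'
#' @param x An `ellipse_model`.
#' @param ... Unused.
#' @return A one-row tibble with the panel size, correlation and the
#'   chi-square boundary values per level.
#' @method glance ellipse_model
#' @export
glance.ellipse_model <- function(x, ...) {
  out <- tibble(
    n = x$n,
    correlation = stats::cov2cor(x$covariance)[1, 2],
    log_det_covariance = determinant(x$covariance, logarithm = TRUE)$modulus[1]
  )
  for (k in seq_along(x$levels)) {
    out[[paste0("chi2_", level_label(x$levels[k]))]] <- x$chi2_quantiles[k]
  }
  out
}

# "0.95" -> "95", "0.999" -> "999": percentage with the decimal point dropped.
level_label <- function(levels) {
  vapply(levels, function(l) {
    gsub("\\.", "", sub("0+$", "", sub("\\.$", "", sprintf("%.4f", 100 * l))))
  }, character(1))
}

#' Plot a membrane-signature map with confidence ellipses
#'
#' @param object An `ellipse_model`.
#' @param signatures Optional signature tibble to overlay as points (a
#'   `group` column, when present, maps to colour).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ellipse_model
#' @export
autoplot.ellipse_model <- function(object, signatures = NULL, ...) {
  bounds <- bind_rows(purrr::map(object$levels, ellipse_boundary, model = object)) |>
    mutate(level = factor(paste0(100 * .data$level, "%")))
  p <- ggplot2::ggplot() +
    ggplot2::geom_path(
      data = bounds,
      ggplot2::aes(x = .data$frac_tm_pct, y = .data$sec_ratio,
                   linetype = .data$level, group = .data$level)
    ) +
    ggplot2::labs(
      x = "Proteins with transmembrane helices (% of ORFs)",
      y = "Sec signal-peptide call ratio (v5-like / v4-like)",
      linetype = "Confidence"
    ) +
    ggplot2::theme_minimal()
  if (!is.null(signatures)) {
    aes_pts <- if ("group" %in% names(signatures)) {
      ggplot2::aes(x = .data$frac_tm_pct, y = .data$sec_ratio,
                   colour = .data$group)
    } else {
      ggplot2::aes(x = .data$frac_tm_pct, y = .data$sec_ratio)
    }
    p <- p + ggplot2::geom_point(data = signatures, aes_pts)
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
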