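# Run code under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# sample() that never interprets a length-1 vector as 1:n.
resample <- function(x, size) x[sample.int(length(x), size)]

# Polar/charged residues used as simulation background: none is hydrophobic,
# so planted transmembrane segments and signal peptides are the only
# membrane-like features a rule-based predictor can find.
POLAR_BACKGROUND <- c("D", "E", "K", "R", "N", "Q", "S", "T", "G", "H", "P")

#' Specify a synthetic homolog family
#'
#' Describes a family of homologs sharing one ancestral core domain, with
#' selected members carrying a planted N-terminal extension of known
#' length — the ground-truth input regime of the NTE screen (observed
#' extensions in the motivating genome span 10-73 residues).
#'
#' @param n_homologs Number of family members.
#' @param core_length Ancestral core length in residues.
#' @param substitution_rate Per-site substitution probability applied
#'   independently to every member's core (0 to 0.3). Substitutions only:
#'   no indels, so planted extension lengths are exactly recoverable.
#' @param nte_lengths Named integer vector mapping 1-based member indices to
#'   planted extension lengths (e.g. `c("1" = 25)`), all at least 1.
#' @param nte_composition `"random"` (uniform residues) or `"amphipathic"`
#'   (periodic hydrophobic/polar pattern at the helical repeat).
#' @param seed Mandatory integer seed; generation is a pure function of the
#'   spec.
#' @return A list of class `family_spec`.
#' @export
family_spec <- function(n_homologs, core_length, substitution_rate = 0,
                        nte_lengths = integer(),
                        nte_composition = c("random", "amphipathic"),
                        seed) {
  nte_composition <- match.arg(nte_composition)
  if (substitution_rate < 0 || substitution_rate > 0.3) {
    usage_error("substitution_rate must lie in [0, 0.3]")
  }
  if (length(nte_lengths) > 0 && any(nte_lengths < 1)) {
    usage_error("planted NTE lengths must be >= 1")
  }
  structure(list(n_homologs = n_homologs, core_length = core_length,
                 substitution_rate = substitution_rate,
                 nte_lengths = nte_lengths,
                 nte_composition = nte_composition, seed = seed),
            class = "family_spec")
}

#' Simulate a homolog family with planted N-terminal extensions
#'
#' Draws one random ancestral core, derives each member by independent
#' per-site substitution, and prepends the planted extension to the
#' designated members. Deterministic under the spec's seed: identical specs
#' give byte-identical output.
#'
#' @param spec A [family_spec()].
#' @param family_id Identifier prefix for member ids and the genome id.
#' @return A list with `proteome` (a proteome tibble; member ids
#'   `<family_id>_m01`, ...) and `truth` (tibble `protein_id`,
#'   `planted_nte_length`, 0 for members without an extension).
#' @export
simulate_family <- function(spec, family_id = "fam") {
  with_seed(spec$seed, {
    core <- sample(AA_ALPHABET20, spec$core_length, replace = TRUE)
    ids <- sprintf("%s_m%02d", family_id, seq_len(spec$n_homologs))
    planted <- setNames(rep(0L, spec$n_homologs), as.character(seq_len(spec$n_homologs)))
    planted[names(spec$nte_lengths)] <- as.integer(spec$nte_lengths)
    seqs <- vapply(seq_len(spec$n_homologs), function(i) {
      member <- core
      if (spec$substitution_rate > 0) {
        hit <- runif(length(member)) < spec$substitution_rate
        if (any(hit)) {
          member[hit] <- vapply(member[hit], function(a) {
            sample(setdiff(AA_ALPHABET20, a), 1)
          }, character(1))
        }
      }
      len <- planted[[as.character(i)]]
      if (len > 0) {
        nte <- switch(spec$nte_composition,
          random = sample(AA_ALPHABET20, len, replace = TRUE),
          amphipathic = amphipathic_stretch(len)
        )
        member <- c(nte, member)
      }
      paste(member, collapse = "")
    }, character(1))
    list(
      proteome = tibble(protein_id = ids, genome_id = family_id,
                        sequence = unname(seqs), description = ""),
      truth = tibble(protein_id = ids, planted_nte_length = unname(planted))
    )
  })
}

# Residues laid around an ideal helix (100 degrees/residue): hydrophobic on
# one face, charged/polar on the other, giving a high Eisenberg moment.
amphipathic_stretch <- function(len) {
  hydro <- c("L", "F", "I", "V")
  polar <- c("K", "E", "Q", "S")
  angle <- (seq_len(len) * 100) %% 360
  on_face <- angle <= 90 | angle >= 270
  ifelse(on_face, sample(hydro, len, replace = TRUE),
         sample(polar, len, replace = TRUE))
}

#' Specify a synthetic proteome with planted membrane features
#'
#' Describes a proteome in which known fractions of proteins carry one
#' strongly hydrophobic transmembrane segment and/or a compliant Sec signal
#' peptide, with the v4-like positives a subset of the v5-like positives
#' (the v4-like regime demands a longer hydrophobic core).
#'
#' @param n_proteins Number of proteins.
#' @param length_min,length_max Uniform protein-length bounds (residues).
#' @param frac_tm Planted fraction of transmembrane proteins, in `[0, 1]`.
#' @param frac_sp_v4,frac_sp_v5 Planted Sec fractions per regime; the
#'   v5-like rate must be at least the v4-like rate.
#' @param fp_rate,fn_rate False-positive/false-negative rates applied when
#'   emitting mock predictor tables (0 = mocks reflect truth exactly).
#' @param seed Mandatory integer seed.
#' @return A list of class `proteome_spec`.
#' @export
proteome_spec <- function(n_proteins, length_min = 200, length_max = 400,
                          frac_tm = 0, frac_sp_v4 = 0, frac_sp_v5 = 0,
                          fp_rate = 0, fn_rate = 0, seed) {
  rates <- c(frac_tm, frac_sp_v4, frac_sp_v5, fp_rate, fn_rate)
  if (any(rates < 0 | rates > 1)) usage_error("all rates must lie in [0, 1]")
  if (frac_sp_v4 > frac_sp_v5) {
    usage_error("frac_sp_v4 (%.3f) must not exceed frac_sp_v5 (%.3f)",
                frac_sp_v4, frac_sp_v5)
  }
  if (length_min < 80 || length_max < length_min) {
    usage_error("need 80 <= length_min <= length_max")
  }
  structure(list(n_proteins = n_proteins, length_min = length_min,
                 length_max = length_max, frac_tm = frac_tm,
                 frac_sp_v4 = frac_sp_v4, frac_sp_v5 = frac_sp_v5,
                 fp_rate = fp_rate, fn_rate = fn_rate, seed = seed),
            class = "proteome_spec")
}

#' Simulate a proteome with planted TM segments and signal peptides
#'
#' Background residues are drawn from a polar alphabet, so the planted
#' features are the only membrane-like signals present. Planted
#' transmembrane proteins receive one 19-residue strongly hydrophobic
#' segment; planted Sec proteins receive a charged n-region, a hydrophobic
#' h-region (12 residues for v4-planted, 9 for v5-only, so the rule-based
#' regimes recover the planted strictness split) and a compliant A-x-A
#' cleavage site. Planted counts are `round(rate * n)`, so planted rates
#' are reproduced exactly by zero-error mocks.
#'
#' @param spec A [proteome_spec()].
#' @param genome_id Genome identifier.
#' @return A list with `proteome`, `truth` (per-protein planted flags and
#'   coordinates), and mock predictor tables `tm_mock`, `sp_mock_v4`,
#'   `sp_mock_v5` reflecting truth with the spec's error rates.
#' @export
simulate_proteome <- function(spec, genome_id = "sim") {
  with_seed(spec$seed, {
    n <- spec$n_proteins
    lens <- sample(seq(spec$length_min, spec$length_max), n, replace = TRUE)
    ids <- sprintf("%s_p%05d", genome_id, seq_len(n))
    n_tm <- round(spec$frac_tm * n)
    n_v5 <- round(spec$frac_sp_v5 * n)
    n_v4 <- round(spec$frac_sp_v4 * n)
    tm_idx <- sample(n, n_tm)
    sp_v5_idx <- sample(n, n_v5)
    sp_v4_idx <- if (n_v4 > 0) resample(sp_v5_idx, n_v4) else integer()
    truth <- tibble(
      protein_id = ids,
      is_tm = seq_len(n) %in% tm_idx,
      tm_start = NA_integer_, tm_end = NA_integer_,
      is_sp_v4 = seq_len(n) %in% sp_v4_idx,
      is_sp_v5 = seq_len(n) %in% sp_v5_idx,
      planted_cleavage = NA_integer_
    )
    seqs <- character(n)
    for (i in seq_len(n)) {
      res <- c("M", sample(POLAR_BACKGROUND, lens[i] - 1, replace = TRUE))
      if (truth$is_sp_v5[i]) {
        h_len <- if (truth$is_sp_v4[i]) 12L else 9L
        prefix <- c("M", "K", "K", sample(c("N", "Q"), 2, replace = TRUE),
                    rep_len(c("L", "A", "A"), h_len), "S", "N", "S")
        res[seq_along(prefix)] <- prefix
        truth$planted_cleavage[i] <- length(prefix) + 1L
      }
      if (truth$is_tm[i]) {
        start <- resample(seq(41, lens[i] - 19 - 5), 1)
        res[start:(start + 18)] <- sample(c("I", "L", "V", "F"), 19, replace = TRUE)
        truth$tm_start[i] <- start
        truth$tm_end[i] <- start + 18L
      }
      seqs[i] <- paste(res, collapse = "")
    }
    proteome <- tibble(protein_id = ids, genome_id = genome_id,
                       sequence = seqs, description = "")
    flip <- function(truth_pos) {
      obs <- truth_pos
      obs[truth_pos] <- runif(sum(truth_pos)) >= spec$fn_rate
      obs[!truth_pos] <- runif(sum(!truth_pos)) < spec$fp_rate
      obs
    }
    tm_obs <- flip(truth$is_tm)
    tm_mock <- tibble(
      protein_id = ids, seq_length = lens,
      n_helices = as.integer(tm_obs),
      helix_spans = purrr::map(seq_len(n), function(i) {
        if (!tm_obs[i]) {
          tibble(start = integer(), end = integer())
        } else if (truth$is_tm[i]) {
          tibble(start = truth$tm_start[i], end = truth$tm_end[i])
        } else {
          tibble(start = 41L, end = 59L)
        }
      })
    )
    sp_mock <- function(truth_pos, regime) {
      obs <- flip(truth_pos)
      tibble(protein_id = ids, regime = regime, is_secreted = obs,
             cleavage_pos = ifelse(obs & truth_pos, truth$planted_cleavage,
                                   ifelse(obs, 22L, NA_integer_)))
    }
    list(proteome = proteome, truth = truth, tm_mock = tm_mock,
         sp_mock_v4 = sp_mock(truth$is_sp_v4, "v4like"),
         sp_mock_v5 = sp_mock(truth$is_sp_v5, "v5like"))
  })
}

#' Specify a synthetic reference panel of genome signatures
#'
#' @param n_genomes Number of background genomes drawn from a bivariate
#'   normal over (TM-fraction %, Sec ratio).
#' @param mean Length-2 mean vector.
#' @param covariance 2x2 positive-definite covariance matrix.
#' @param planted_outliers Optional tibble/data frame with columns
#'   `frac_tm_pct` and `sec_ratio`: outlier genomes appended to the panel
#'   and flagged in the truth column.
#' @param seed Mandatory integer seed.
#' @return A list of class `panel_spec`.
#' @export
panel_spec <- function(n_genomes, mean = c(20, 1.1),
                       covariance = diag(c(9, 0.04)),
                       planted_outliers = NULL, seed) {
  covariance <- as.matrix(covariance)
  ev <- eigen(covariance, symmetric = TRUE, only.values = TRUE)$values
  if (length(mean) != 2 || any(dim(covariance) != 2) || min(ev) <= 0) {
    usage_error("mean must have length 2 and covariance must be 2x2 positive-definite")
  }
  structure(list(n_genomes = n_genomes, mean = mean, covariance = covariance,
                 planted_outliers = planted_outliers, seed = seed),
            class = "panel_spec")
}

#' Simulate a reference signature panel with planted outliers
#'
#' @param spec A [panel_spec()].
#' @return A signature tibble with columns `genome_id`, `frac_tm_pct`,
#'   `sec_ratio`, `sec_ratio_defined`, `group` (`"background"` or
#'   `"outlier"`) and `planted_outlier`.
#' @export
simulate_panel <- function(spec) {
  with_seed(spec$seed, {
    bg <- if (spec$n_genomes > 0) {
      draws <- MASS::mvrnorm(spec$n_genomes, mu = spec$mean,
                             Sigma = spec$covariance)
      draws <- matrix(draws, ncol = 2)
      tibble(
        genome_id = sprintf("bg%04d", seq_len(spec$n_genomes)),
        frac_tm_pct = draws[, 1], sec_ratio = draws[, 2],
        sec_ratio_defined = TRUE, group = "background",
        planted_outlier = FALSE
      )
    } else {
      tibble(genome_id = character(), frac_tm_pct = numeric(),
             sec_ratio = numeric(), sec_ratio_defined = logical(),
             group = character(), planted_outlier = logical())
    }
    out <- spec$planted_outliers
    if (!is.null(out) && nrow(out) > 0) {
      bg <- bind_rows(bg, tibble(
        genome_id = sprintf("outlier%02d", seq_len(nrow(out))),
        frac_tm_pct = out$frac_tm_pct, sec_ratio = out$sec_ratio,
        sec_ratio_defined = TRUE, group = "outlier", planted_outlier = TRUE
      ))
    }
    bg
  })
}
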