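sig_tbl <- function(tm, ratio, id = sprintf("g%04d", seq_along(tm))) {
  tibble::tibble(genome_id = id, frac_tm_pct = tm, sec_ratio = ratio,
                 sec_ratio_defined = !is.na(ratio))
}

test_that("genome signatures are straight census arithmetic", {
  prot <- make_proteome_tbl(paste0("p", 1:10),
                            rep(strrep("MKTAY", 30), 10))
  tm <- tibble::tibble(protein_id = paste0("p", 1:10), seq_length = 150L,
                       n_helices = c(rep(1L, 3), rep(0L, 7)),
                       helix_spans = replicate(10, tibble::tibble(
                         start = integer(), end = integer()), simplify = FALSE))
  spx <- function(ids_yes, regime) {
    tibble::tibble(protein_id = paste0("p", 1:10), regime = regime,
                   is_secreted = paste0("p", 1:10) %in% ids_yes,
                   cleavage_pos = NA_integer_)
  }
  sig <- genome_signature(prot, tm, spx("p1", "v4like"),
                          spx(c("p1", "p2"), "v5like"))
  expect_equal(sig$frac_tm_pct, 30)
  expect_equal(sig$frac_sec_v4_pct, 10)
  expect_equal(sig$frac_sec_v5_pct, 20)
  expect_equal(sig$sec_ratio, 2)
  expect_equal(sig$n_orfs, 10)
})

test_that("missing predictions count as negative; zero v4 calls flag the ratio", {
  prot <- make_proteome_tbl(paste0("p", 1:4), rep(strrep("MKTAY", 30), 4))
  none <- tibble::tibble(protein_id = character(), regime = character(),
                         is_secreted = logical(), cleavage_pos = integer())
  tm1 <- tibble::tibble(protein_id = "p1", seq_length = 150L, n_helices = 1L,
                        helix_spans = list(tibble::tibble(start = 10L, end = 28L)))
  expect_message(
    sig <- genome_signature(prot, tm1, none, none),
    "count as negative"
  )
  expect_equal(sig$frac_tm_pct, 25)
  expect_false(sig$sec_ratio_defined)
  expect_true(is.na(sig$sec_ratio))
})

test_that("ellipse fitting uses chi-square boundaries and rejects degenerate panels", {
  set.seed(3)
  panel <- sig_tbl(rnorm(40, 20, 3), rnorm(40, 1.1, 0.2))
  m <- fit_reference_ellipse(panel)
  expect_s3_class(m, "ellipse_model")
  expect_equal(unname(m$chi2_quantiles[1]), 5.991465, tolerance = 1e-6)
  expect_equal(unname(m$chi2_quantiles[2]), 13.81551, tolerance = 1e-6)
  expect_equal(m$mean[["frac_tm_pct"]], mean(panel$frac_tm_pct))
  expect_equal(m$covariance[1, 2], cov(panel$frac_tm_pct, panel$sec_ratio))

  dup <- sig_tbl(rep(20, 5), rep(1.1, 5))
  expect_error(fit_reference_ellipse(dup), "singular",
               class = "proteosig_processing_error")
  expect_error(fit_reference_ellipse(panel[1:2, ]), "at least 3",
               class = "proteosig_usage_error")
})

test_that("classification is exact at the mean and monotone across levels", {
  set.seed(14)
  panel <- sig_tbl(rnorm(60, 20, 3), rnorm(60, 1.1, 0.2))
  m <- fit_reference_ellipse(panel)
  at_mean <- sig_tbl(m$mean[[1]], m$mean[[2]], id = "center")
  rep0 <- classify_genome(at_mean, m)
  expect_equal(rep0$mahalanobis_sq, 0)
  expect_true(rep0$inside_95 && rep0$inside_999)

  # random points: inside flags must match the chi-square rule and nest
  pts <- sig_tbl(rnorm(50, 20, 8), rnorm(50, 1.1, 0.6))
  reps <- classify_genome(pts, m)
  expect_equal(reps$inside_95, reps$mahalanobis_sq <= qchisq(0.95, 2))
  expect_equal(reps$inside_999, reps$mahalanobis_sq <= qchisq(0.999, 2))
  expect_true(all(reps$inside_999[reps$inside_95]))
})

test_that("a point between the two chi-square radii is outside 95% but inside 99.9%", {
  set.seed(15)
  panel <- sig_tbl(rnorm(200, 20, 3), rnorm(200, 1.1, 0.2))
  m <- fit_reference_ellipse(panel)
  # place a point at squared Mahalanobis radius 9 along the first eigenvector
  eg <- eigen(m$covariance, symmetric = TRUE)
  pt <- m$mean + 3 * sqrt(eg$values[1]) * eg$vectors[, 1]
  rep1 <- classify_genome(sig_tbl(pt[1], pt[2], id = "mid"), m)
  expect_equal(rep1$mahalanobis_sq, 9, tolerance = 1e-8)
  expect_false(rep1$inside_95)
  expect_true(rep1$inside_999)
})

test_that("undefined sec ratios yield a reason code, not an error", {
  set.seed(16)
  panel <- sig_tbl(rnorm(30, 20, 3), rnorm(30, 1.1, 0.2))
  m <- fit_reference_ellipse(panel)
  rep2 <- classify_genome(sig_tbl(35, NA, id = "nosec"), m)
  expect_true(is.na(rep2$mahalanobis_sq))
  expect_true(is.na(rep2$inside_95))
  expect_equal(rep2$reason, "undefined-sec-ratio")
  expect_equal(rep2$frac_tm_percentile, 100)
})

test_that("Mahalanobis classification is affine-equivariant under translation", {
  set.seed(17)
  panel <- sig_tbl(rnorm(50, 20, 3), rnorm(50, 1.1, 0.2))
  test_pt <- sig_tbl(28, 1.9, id = "t")
  d1 <- classify_genome(test_pt, fit_reference_ellipse(panel))$mahalanobis_sq
  shifted <- dplyr::mutate(panel, frac_tm_pct = frac_tm_pct + 7,
                           sec_ratio = sec_ratio - 0.5)
  shifted_pt <- sig_tbl(28 + 7, 1.9 - 0.5, id = "t")
  d2 <- classify_genome(shifted_pt, fit_reference_ellipse(shifted))$mahalanobis_sq
  expect_equal(d1, d2, tolerance = 1e-9)
})

test_that("percentiles are strict, bounded, and shrink when the genome joins the panel", {
  panel <- sig_tbl(c(10, 15, 20, 25, 30), c(1.0, 1.3, 0.9, 1.2, 1.1))
  m <- fit_reference_ellipse(panel)
  r <- classify_genome(sig_tbl(26, 1.2, id = "x"), m)
  expect_equal(r$frac_tm_percentile, 80)  # 4 of 5 strictly smaller
  with_self <- dplyr::bind_rows(panel, sig_tbl(26, 1.2, id = "x"))
  r2 <- classify_genome(sig_tbl(26, 1.2, id = "x"), m, reference = with_self)
  expect_lte(r2$frac_tm_percentile, r$frac_tm_percentile)
  expect_true(all(dplyr::between(
    classify_genome(sig_tbl(c(0, 50), c(1, 3)), m)$frac_tm_percentile, 0, 100)))
})

test_that("ellipse boundaries lie exactly on their chi-square radius", {
  set.seed(18)
  panel <- sig_tbl(rnorm(40, 20, 3), rnorm(40, 1.1, 0.2))
  m <- fit_reference_ellipse(panel)
  for (lv in m$levels) {
    b <- ellipse_boundary(m, lv, n = 60)
    d2 <- mahalanobis(cbind(b$frac_tm_pct, b$sec_ratio), m$mean, m$covariance)
    expect_equal(d2, rep(qchisq(lv, 2), 60), tolerance = 1e-8)
  }
})

test_that("tidy, glance and autoplot expose the fitted model", {
  set.seed(19)
  panel <- sig_tbl(rnorm(40, 20, 3), rnorm(40, 1.1, 0.2))
  m <- fit_reference_ellipse(panel)
  td <- tidy(m)
  expect_equal(td$estimate[td$term == "mean_frac_tm_pct"],
               mean(panel$frac_tm_pct))
  gl <- glance(m)
  expect_equal(gl$n, 40)
  expect_named(gl, c("n", "correlation", "log_det_covariance",
                     "chi2_95", "chi2_999"))
  p <- autoplot(m, signatures = dplyr::mutate(panel, group = "background"))
  expect_s3_class(p, "ggplot")
})
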