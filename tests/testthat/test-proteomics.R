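test_that("abundance tables validate their design", {
  m <- matrix(2^rnorm(40, 20), 10, 4,
              dimnames = list(sprintf("P%02d", 1:10), NULL))
  design <- tibble::tibble(
    sample_id = c("m1", "m2", "p1", "p2"),
    fraction = c("monosome", "monosome", "polysome", "polysome"),
    treatment = "CHX", replicate = c(1, 2, 1, 2))
  colnames(m) <- design$sample_id
  tab <- abundance_table(m, design)
  expect_s3_class(tab, "abundance_table")
  long <- tidy(tab)
  expect_equal(nrow(long), 40)

  expect_error(abundance_table(m, design[1:3, ]), class = "design_error")
  bad <- design; bad$replicate <- 1
  m2 <- m; colnames(m2)[2] <- "zz"
  expect_error(abundance_table(m2, design), class = "design_error")
})

test_that("normalisation removes pure per-sample scale factors", {
  tab <- simulate_proteomics(n_proteins = 400, n_rep = 2, seed = 2)
  m <- tab$intensities
  scaled <- m
  fac <- c(1, 3, 0.5, 2, 1.7, 0.8, 1, 1, 2.2, 0.6, 1.4, 1)[seq_len(ncol(m))]
  scaled <- sweep(m, 2, fac, "*")
  tab2 <- abundance_table(scaled, tab$design)
  n1 <- vsn_normalize(tab)
  n2 <- vsn_normalize(tab2)
  # per-protein between-sample differences are restored (a global shift of
  # the transformed scale is immaterial)
  ctr <- function(x) x - rowMeans(x)
  expect_lt(median(abs(ctr(n1$intensities) - ctr(n2$intensities))), 0.05)

  # identical samples: differences vanish
  dup <- abundance_table(cbind(extra = m[, 1], m),
                         dplyr::bind_rows(
                           tibble::tibble(sample_id = "extra",
                                          fraction = "monosome",
                                          treatment = "CHX", replicate = 99),
                           tab$design))
  nd <- vsn_normalize(dup)
  expect_lt(max(abs(nd$intensities[, "extra"] - nd$intensities[, 2])), 1e-9)

  # rank order within each sample is preserved
  for (j in 1:3) {
    expect_identical(order(n1$intensities[, j]), order(m[, j]))
  }

  sparse <- m; sparse[1:380, 1] <- NA
  expect_error(vsn_normalize(abundance_table(sparse, tab$design)),
               class = "normalization_error")
})

test_that("the glog transform flattens additive-noise heteroscedasticity", {
  # additive floor dominates the low-intensity end; plain log2 leaves a
  # strong SD-vs-rank trend that the calibrated glog must flatten >= 5-fold
  tab <- simulate_proteomics(n_proteins = 3000, n_rep = 3, base_meanlog2 = 18,
                             additive_sd = 2^16, seed = 5)
  norm <- vsn_normalize(tab)
  slope_of <- function(m) {
    mu <- rowMeans(m)
    s <- apply(m, 1, sd)
    abs(unname(stats::coef(stats::lm(s ~ rank(mu)))[2]))
  }
  ratio <- slope_of(log2(tab$intensities)) / slope_of(norm$intensities)
  expect_gte(ratio, 5)
})

test_that("mixed imputation applies the MNAR/MAR rules", {
  tab <- simulate_proteomics(n_proteins = 120, n_rep = 3, seed = 6)
  norm <- vsn_normalize(tab)

  # no missing values: identity
  imp0 <- impute_mixed(norm)
  expect_identical(imp0$intensities, norm$intensities)
  expect_identical(imp0$stage, "imputed")

  # protein absent in all HRN-polysome replicates -> MNAR at scale minimum
  n2 <- norm
  des <- n2$design
  hrn_poly <- des$fraction == "polysome" & des$treatment == "HRN"
  n2$intensities[3, hrn_poly] <- NA
  n2$intensities[5, which(!hrn_poly)[1]] <- NA  # a lone MAR hole elsewhere
  imp <- impute_mixed(n2)
  expect_equal(unname(imp$intensities[3, hrn_poly]),
               rep(min(n2$intensities, na.rm = TRUE), sum(hrn_poly)))
  # MAR entry imputed from neighbours, not at the scale minimum
  expect_gt(imp$intensities[5, which(!hrn_poly)[1]],
            min(n2$intensities, na.rm = TRUE))

  # protein missing everywhere is dropped with a warning
  n3 <- norm
  n3$intensities[7, ] <- NA
  expect_warning(imp3 <- impute_mixed(n3), "dropping")
  expect_equal(nrow(imp3$intensities), nrow(norm$intensities) - 1)
})

test_that("knn imputation beats single-value imputation on a MAR mask", {
  tab <- simulate_proteomics(n_proteins = 300, n_rep = 3, seed = 7)
  norm <- vsn_normalize(tab)
  truth <- norm$intensities
  set.seed(8)
  mask <- matrix(runif(length(truth)) < 0.10, nrow(truth))
  # keep at least one observation per protein per condition so all masked
  # entries are MAR by the classifier
  mask[, c(1, 4, 7, 10)] <- FALSE
  masked <- norm
  masked$intensities[mask] <- NA
  imp <- impute_mixed(masked)
  rmse_knn <- sqrt(mean((imp$intensities[mask] - truth[mask])^2))
  single <- min(truth, na.rm = TRUE)
  rmse_single <- sqrt(mean((single - truth[mask])^2))
  expect_lt(rmse_knn, rmse_single)
})

test_that("moderated test handles exact ties and the classic-t limit", {
  m <- matrix(rnorm(60, 20), 10, 6,
              dimnames = list(sprintf("P%02d", 1:10), sprintf("s%d", 1:6)))
  design <- tibble::tibble(sample_id = sprintf("s%d", 1:6),
                           fraction = rep(c("polysome", "monosome"), each = 3),
                           treatment = "CHX",
                           replicate = rep(1:3, 2))
  # identical groups: t = 0, p = 1
  m_id <- cbind(m[, 1:3], m[, 1:3])
  colnames(m_id) <- design$sample_id
  tab_id <- structure(list(intensities = m_id, design = design,
                           stage = "imputed"), class = "abundance_table")
  d_id <- moderated_test(tab_id, c("polysome.CHX", "monosome.CHX"))
  expect_equal(d_id$log2fc, rep(0, 10))
  expect_equal(d_id$moderated_t, rep(0, 10))
  expect_equal(d_id$p_value, rep(1, 10))

  # d0 = 0 recovers the classic equal-variance two-sample t exactly
  tab <- structure(list(intensities = m, design = design, stage = "imputed"),
                   class = "abundance_table")
  d0fit <- moderated_test(tab, c("polysome.CHX", "monosome.CHX"), d0 = 0)
  classic <- apply(m, 1, function(r) {
    tt <- t.test(r[1:3], r[4:6], var.equal = TRUE)
    c(t = unname(tt$statistic), p = tt$p.value)
  })
  expect_equal(d0fit$moderated_t, unname(classic["t", ]), tolerance = 1e-10)
  expect_equal(d0fit$p_value, unname(classic["p", ]), tolerance = 1e-10)

  # d0 -> Inf gives the fully pooled z-like statistic, |t| between the limits
  dinf <- moderated_test(tab, c("polysome.CHX", "monosome.CHX"), d0 = Inf)
  dmid <- moderated_test(tab, c("polysome.CHX", "monosome.CHX"), d0 = 4)
  s0 <- attr(dmid, "s0_sq")
  for (i in 1:10) {
    lims <- sort(c(abs(d0fit$moderated_t[i]), abs(dinf$moderated_t[i])))
    expect_gte(abs(dmid$moderated_t[i]), lims[1] - 1e-9)
    expect_lte(abs(dmid$moderated_t[i]), lims[2] + 1e-9)
  }
})

test_that("moderated test agrees with the established empirical-Bayes oracle", {
  tab <- simulate_proteomics(n_proteins = 500, n_rep = 3, seed = 19)
  imp <- impute_mixed(vsn_normalize(tab))
  d <- moderated_test(imp, c("polysome.CHX", "monosome.CHX"))
  grp <- paste(imp$design$fraction, imp$design$treatment, sep = ".")
  keep <- grp %in% c("polysome.CHX", "monosome.CHX")
  dmat <- cbind(1, grp[keep] == "polysome.CHX")
  fitl <- limma::eBayes(limma::lmFit(imp$intensities[, keep], dmat))
  expect_equal(attr(d, "d0"), fitl$df.prior, tolerance = 0.02)
  expect_equal(attr(d, "s0_sq"), fitl$s2.prior, tolerance = 0.05)
  expect_gt(cor(d$moderated_t, fitl$t[, 2]), 0.999)
  expect_equal(d$log2fc, unname(fitl$coefficients[, 2]), tolerance = 1e-9)
})

test_that("BH adjustment matches a brute-force step-up on random inputs", {
  set.seed(33)
  for (i in 1:20) {
    p <- runif(sample(5:200, 1))^sample(1:3, 1)
    expect_equal(p.adjust(p, "BH"), bh_stepup(p), tolerance = 1e-12)
  }
  # monotone in p and bounded by 1
  p <- runif(500)
  adj <- p.adjust(p, "BH")
  expect_true(all(adj[order(p)] == cummax(adj[order(p)])))
  expect_lte(max(adj), 1)
  # q-values are BH scaled by pi0 <= 1
  q <- storey_qvalue(p)
  expect_true(all(q <= adj + 1e-12))
})

test_that("null simulation yields calibrated p-values and controlled FDR", {
  tab <- simulate_proteomics(n_proteins = 2000, n_rep = 3, seed = 11)
  imp <- impute_mixed(vsn_normalize(tab))
  d <- moderated_test(imp, c("polysome.CHX", "monosome.CHX"))
  expect_gt(stats::ks.test(d$p_value, "punif")$p.value, 0.01)
  r <- apply_rejections(d, alpha = 0.05, lfc = log2(1.5))
  expect_lte(mean(r$significant), 0.07)
})

test_that("rejection thresholds implement the alpha/lfc rule exactly", {
  d <- tibble::tibble(protein_id = sprintf("P%d", 1:4),
                      log2fc = c(1.0, 0.3, -0.8, 0.7),
                      moderated_t = 0, p_value = c(0.01, 0.01, 0.2, 0.001),
                      adj_p = c(0.04, 0.04, 0.3, 0.049))
  class(d) <- c("diff_result", class(d))
  r <- apply_rejections(d)
  expect_equal(r$significant, c(TRUE, FALSE, FALSE, TRUE))

  # threshold sweep agrees with brute-force set filtering
  set.seed(12)
  d2 <- tibble::tibble(protein_id = sprintf("P%d", 1:300),
                       log2fc = rnorm(300), moderated_t = 0,
                       p_value = runif(300), adj_p = runif(300))
  class(d2) <- c("diff_result", class(d2))
  for (alpha in c(0.01, 0.05, 0.2)) {
    for (lfc in c(0, log2(1.5), 1)) {
      r2 <- apply_rejections(d2, alpha, lfc)
      brute <- d2$protein_id[d2$adj_p < alpha & abs(d2$log2fc) > lfc]
      expect_identical(r2$protein_id[r2$significant], brute)
    }
  }
})

test_that("shift classification follows the two-contrast rules", {
  mk <- function(ids, fc, sig) {
    d <- tibble::tibble(protein_id = ids, log2fc = fc, moderated_t = 0,
                        p_value = 0.5, adj_p = 0.5, significant = sig)
    class(d) <- c("diff_result", class(d))
    d
  }
  ids <- c("A", "B", "C", "D")
  c1 <- mk(ids, c(2, 1, -1, 2), c(TRUE, TRUE, TRUE, TRUE))
  c2 <- mk(ids, c(-2, 1.5, -2, 0), c(TRUE, TRUE, TRUE, FALSE))
  cl <- classify_fraction_shifts(list(poly_vs_mono_chx = c1,
                                      hrn_vs_chx_poly = c2))
  expect_setequal(cl$chx_polysome_enriched, c("A", "B", "D"))
  expect_setequal(cl$shifted_to_monosome, "A")
  expect_setequal(cl$hrn_polysome_elevated, "B")
  expect_length(intersect(cl$hrn_polysome_elevated, cl$shifted_to_monosome), 0)
  expect_true(all(cl$shifted_to_monosome %in% cl$chx_polysome_enriched))

  none <- mk(ids, c(0, 0, 0, 0), rep(FALSE, 4))
  cl0 <- classify_fraction_shifts(list(poly_vs_mono_chx = none,
                                       hrn_vs_chx_poly = none))
  expect_length(cl0$chx_polysome_enriched, 0)
  expect_error(classify_fraction_shifts(list(poly_vs_mono_chx = c1)),
               class = "design_error")
})

test_that("planted fraction shifts are recovered with high power", {
  hits_shift <- hits_enr <- integer(20)
  for (s in 1:20) {
    planted <- tibble::tibble(
      protein_id = sprintf("P%04d", 1:10),
      poly_enrichment_log2 = 2,
      runoff_shift_log2 = -2
    )
    tab <- simulate_proteomics(n_proteins = 300, n_rep = 3, planted = planted,
                               seed = 1000 + s)
    res <- analyze_fraction_shifts(tab)
    hits_enr[s] <- sum(planted$protein_id %in% res$classes$chx_polysome_enriched)
    hits_shift[s] <- sum(planted$protein_id %in% res$classes$shifted_to_monosome)
  }
  expect_gte(mean(hits_enr) / 10, 0.9)
  expect_gte(mean(hits_shift) / 10, 0.9)
})

test_that("both adjustment modes run the full reanalysis deterministically", {
  planted <- tibble::tibble(protein_id = sprintf("P%04d", 1:15),
                            poly_enrichment_log2 = 2.2,
                            runoff_shift_log2 = c(rep(-2, 8), rep(0, 7)))
  tab <- simulate_proteomics(n_proteins = 400, n_rep = 3, planted = planted,
                             mar_rate = 0.02, mnar_quantile = 0.02, seed = 23)
  res_bh <- suppressWarnings(analyze_fraction_shifts(tab, adjust = "BH"))
  res_q <- suppressWarnings(analyze_fraction_shifts(tab, adjust = "qvalue"))
  expect_gte(res_q$summary$n_chx_polysome_enriched,
             res_bh$summary$n_chx_polysome_enriched)
  # repeat run is bit-identical (no RNG after simulation)
  res_bh2 <- suppressWarnings(analyze_fraction_shifts(tab, adjust = "BH"))
  expect_identical(res_bh$summary, res_bh2$summary)
  expect_identical(res_bh$diffs$poly_vs_mono_chx$adj_p,
                   res_bh2$diffs$poly_vs_mono_chx$adj_p)
  # the planted enrichment magnitude is recovered in the summary
  expect_equal(res_bh$summary$mean_log2fc_enriched, 2.2, tolerance = 0.25)
})
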