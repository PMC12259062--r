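# a small simulated group with no sample-level variance, used for the
# ordinary-least-squares limit checks
zero_u_dataset <- function(seed = 2, eta2 = 0.4) {
  simulate_citeseq(sim_config(
    n_samples = c(healthy = 4), cells_per_sample = 75, n_ict = 3,
    n_background = 0, eta1 = 0.5, eta2 = c(eta2, 0, 0),
    sigma_u = 0, sigma_e = 1, seed = seed))
}

test_that("fixed effects match OLS when the random intercept is absent", {
  sim <- zero_u_dataset()
  ds <- sim$dataset
  fit <- fit_trio(ds, c(m = "P1", g = "G1", t = "ICT1"), group = "healthy")
  ols <- lm(ds$adt[, "P1"] ~ ds$rna[, "G1"] + ds$rna[, "ICT1"])
  expect_equal(unname(fit$coefficients),
               unname(coef(ols)), tolerance = 1e-4)
  expect_true(fit$sigma_u2 < 0.02)
  expect_gt(fit$r2, 0)
})

test_that("degenerate predictors and too few samples are rejected", {
  sim <- zero_u_dataset()
  ds <- sim$dataset
  ds$rna[, "ICT2"] <- 1
  expect_error(fit_trio(ds, c(m = "P1", g = "G1", t = "ICT2"),
                        group = "healthy"),
               "degenerate predictor")
  ds1 <- subset_cells_for_test(ds, ds$meta$sample_id == "s1")
  expect_error(fit_trio(ds1, c(m = "P1", g = "G1", t = "ICT1")),
               "at least 2 samples")
  expect_error(fit_trio(ds, c(m = "P1", g = "G1", t = "NOPE")),
               "not in RNA matrix")
})

test_that("trio scan flags the planted trio and only that one", {
  sim <- make_fixture("one-strong-trio")
  ds <- sim$dataset
  catalog <- build_trios(data.frame(m = "P1", g = "G1"),
                         sim$truth$ict_genes, colnames(ds$rna))
  tab <- scan_trios(ds, catalog, group = "healthy")
  expect_s3_class(tab, "ptt_table")
  expect_equal(nrow(tab), 10)
  expect_true(tab$is_ptt[tab$t == "ICT1"])
  expect_equal(sum(tab$is_ptt), 1)
  # adjusted p-values agree with the independent step-up reference
  ok <- tab$converged
  expect_equal(tab$fdr[ok], bh_reference(tab$p[ok]), tolerance = 1e-12)

  empty <- scan_trios(ds, catalog[0, ], group = "healthy")
  expect_equal(nrow(empty), 0)
  expect_s3_class(empty, "ptt_table")
})

test_that("failed trios stay in the table but out of the FDR family", {
  sim <- zero_u_dataset()
  ds <- sim$dataset
  ds$rna[, "ICT3"] <- 0   # constant -> per-trio failure
  catalog <- build_trios(data.frame(m = "P1", g = "G1"),
                         c("ICT1", "ICT2", "ICT3"), colnames(ds$rna))
  tab <- scan_trios(ds, catalog, group = "healthy")
  expect_equal(nrow(tab), 3)
  bad <- tab[tab$t == "ICT3", ]
  expect_false(bad$converged)
  expect_true(is.na(bad$fdr))
  expect_match(bad$note, "degenerate")
  expect_equal(sum(!is.na(tab$fdr)), 2)
})

test_that("full-vs-reduced comparison aggregates per pair as specified", {
  sim <- zero_u_dataset(seed = 9)
  ds <- sim$dataset
  catalog <- build_trios(data.frame(m = "P1", g = "G1"),
                         c("ICT1", "ICT2", "ICT3"), colnames(ds$rna))
  tab <- scan_trios(ds, catalog, group = "healthy")
  cmp <- compare_reduced(ds, catalog, group = "healthy", ptt = tab)
  expect_equal(nrow(cmp), 1)
  expect_equal(cmp$eta1_full, max(tab$eta1))
  expect_equal(cmp$p_full, min(tab$p1))
  expect_equal(cmp$r2_full, mean(tab$r2))
  # with the ICT term present the fit can only explain more variance
  expect_gt(cmp$r2_full, cmp$r2_reduced - 1e-6)

  # single-trio pair: max = min = mean of the one fit
  cat1 <- catalog[catalog$t == "ICT1", ]
  tab1 <- scan_trios(ds, cat1, group = "healthy")
  cmp1 <- compare_reduced(ds, cat1, group = "healthy", ptt = tab1)
  expect_equal(cmp1$eta1_full, tab1$eta1)
  expect_equal(cmp1$r2_full, tab1$r2)
})

test_that("cross-group PTT summaries count distinct ICT genes and overlap", {
  tab <- function(ts, flag = TRUE) {
    structure(data.frame(m = "P1", g = "G1", t = ts, is_ptt = flag),
              class = c("ptt_table", "data.frame"))
  }
  a <- tab(c("T1", "T2", "T3"))
  s <- summarize_ptt(list(healthy = a, severe = a))
  expect_equal(unname(s$ict_counts[, "healthy"]), 3)
  expect_equal(s$n_shared, 3)             # identical tables: full overlap
  b <- tab(c("T4", "T5"))
  s2 <- summarize_ptt(list(healthy = a, severe = b))
  expect_equal(s2$n_shared, 0)            # disjoint: empty intersection
  s3 <- summarize_ptt(list(h = a, s = b),
                      protein_abundance = c(P1 = 1.5))
  expect_true(all(is.na(s3$abundance_cor)))  # one protein: undefined
})

test_that("Satterthwaite option gives p-values close to Wald on large groups", {
  sim <- zero_u_dataset(seed = 4)
  ds <- sim$dataset
  fw <- fit_trio(ds, c(m = "P1", g = "G1", t = "ICT1"), group = "healthy")
  fs <- fit_trio(ds, c(m = "P1", g = "G1", t = "ICT1"), group = "healthy",
                 df = "satterthwaite")
  expect_equal(unname(fs$coefficients), unname(fw$coefficients),
               tolerance = 1e-6)
  expect_equal(fs$p[["eta2"]], fw$p[["eta2"]], tolerance = 0.01)
})
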