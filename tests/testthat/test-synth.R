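test_that("the generator is deterministic in its seed", {
  cf <- sim_config(n_samples = c(h = 2, s = 2), cells_per_sample = 30,
                   n_ict = 5, seed = 13)
  a <- simulate_citeseq(cf)
  b <- simulate_citeseq(cf)
  expect_identical(a$dataset$rna, b$dataset$rna)
  expect_identical(a$dataset$adt, b$dataset$adt)
  expect_identical(a$truth$u, b$truth$u)
  cf2 <- cf; cf2$seed <- 14
  c <- simulate_citeseq(cf2)
  expect_false(identical(a$dataset$rna, c$dataset$rna))
})

test_that("the noiseless limit reproduces the protein equation exactly", {
  cf <- sim_config(n_samples = c(h = 2), cells_per_sample = 40, n_ict = 1,
                   n_background = 0, eta0 = 0.7, eta1 = 0.5, eta2 = 1,
                   sigma_u = 0, sigma_e = 0, seed = 5)
  sim <- simulate_citeseq(cf)
  ds <- sim$dataset
  lhs <- ds$adt[, "P1"] - 0.7 - 0.5 * ds$rna[, "G1"]
  expect_equal(unname(lhs), unname(ds$rna[, "ICT1"]), tolerance = 1e-12)
})

test_that("latent transcription is standard normal at scale", {
  sim <- simulate_citeseq(sim_config(n_samples = c(h = 10),
                                     cells_per_sample = 1000, n_ict = 3,
                                     n_background = 0, seed = 8))
  X <- sim$dataset$rna
  expect_lt(max(abs(colMeans(X))), 0.05)
  expect_lt(max(abs(apply(X, 2, sd) - 1)), 0.05)
})

test_that("binary mode shifts the case group as configured", {
  sim <- simulate_citeseq(sim_config(
    n_samples = c(healthy = 3, severe = 3), cells_per_sample = 400,
    n_ict = 2, n_background = 0, xt_shift = c(1, 0), e_shift = 2,
    sigma_u = 0, seed = 9))
  ds <- sim$dataset
  case <- ds$meta$phenotype == "severe"
  expect_equal(mean(ds$rna[case, "ICT1"]) - mean(ds$rna[!case, "ICT1"]),
               1, tolerance = 0.1)
  expect_equal(mean(ds$rna[case, "ICT2"]) - mean(ds$rna[!case, "ICT2"]),
               0, tolerance = 0.1)
  expect_equal(mean(ds$adt[case, "P1"]) - mean(ds$adt[!case, "P1"]),
               2, tolerance = 0.2)
})

test_that("continuous mode implies the documented mediation classes", {
  cf <- sim_config(n_samples = c(all = 4), cells_per_sample = 50, n_ict = 4,
                   outcome = "continuous_latent",
                   eta2 = c(0.4, 0.4, 0, 0), delta = c(0, 0.4, 0.4, 0),
                   beta = 0.5, seed = 2)
  sim <- simulate_citeseq(cf)
  expect_equal(unname(sim$truth$implied_class),
               c("full", "partial", "null", "dropped"))
  expect_setequal(sim$truth$true_support, c("ICT1", "ICT2", "ICT3"))
  expect_true("D_latent" %in% names(sim$dataset$meta))
})

test_that("negative-binomial emission produces QC-able counts", {
  sim <- simulate_citeseq(sim_config(n_samples = c(h = 2), n_ict = 3,
                                     cells_per_sample = 50, seed = 4,
                                     emission = "negative_binomial"))
  ds <- sim$dataset
  expect_identical(ds$rna_layer, "counts")
  expect_true(all(ds$rna >= 0) && all(ds$rna == round(ds$rna)))
  norm <- normalize_adt(normalize_rna(qc_filter(ds, min_genes = 1,
                                                min_cells = 1)))
  expect_identical(norm$rna_layer, "lognorm.z")
  expect_identical(norm$adt_layer, "clr.z")
})

test_that("the fixture registry matches its documentation", {
  tn <- make_fixture("tiny-null")
  expect_equal(nrow(tn$dataset$rna), 200)
  expect_equal(length(unique(tn$dataset$meta$sample_id)), 4)
  expect_true(all(tn$truth$config$eta2 == 0))

  ot <- make_fixture("one-strong-trio")
  expect_equal(sum(ot$truth$config$eta2 != 0), 1)
  expect_equal(ot$truth$config$eta2[1, 1], 1)

  sm <- make_fixture("sparse-mediation-20")
  expect_equal(nrow(sm$dataset$rna), 2000)
  expect_equal(length(sm$truth$ict_genes), 20)
  expect_length(sm$truth$true_support, 3)
  expect_error(make_fixture("no-such-fixture"))
})

test_that("ground truth serializes to YAML and TSV", {
  sim <- make_fixture("sparse-mediation-20")
  dir <- file.path(tempdir(), "gt")
  paths <- write_ground_truth(sim$truth, dir)
  expect_true(all(file.exists(paths)))
  y <- yaml::read_yaml(paths[1])
  expect_equal(y$true_support, c("ICT1", "ICT2", "ICT3"))
  expect_equal(y$config$seed, 1)
})
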