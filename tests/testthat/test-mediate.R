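test_that("effect decomposition is exact and matches the total-effect slope", {
  for (s in 1:10) {
    set.seed(200 + s)
    n <- 150 + 50 * (s %% 3)
    x <- rnorm(n)
    m <- 0.3 * s / 10 * x + rnorm(n)
    d <- 0.2 * m - 0.1 * x + rnorm(n)
    fit <- mediate(x, m, d)
    co <- coef(fit)
    expect_identical(fit$total, co[["delta"]] + co[["alpha"]] * co[["beta"]])
    slope <- unname(coef(lm(d ~ x))[2])
    expect_equal(fit$total, slope, tolerance = 1e-8)
  }
})

test_that("mediation is equivariant under exposure sign flips", {
  set.seed(7)
  x <- rnorm(300); m <- 0.5 * x + rnorm(300); d <- 0.4 * m + 0.2 * x + rnorm(300)
  f1 <- mediate(x, m, d)
  f2 <- mediate(-x, m, d)
  # alpha and delta flip with x; beta is untouched; so indirect and total
  # flip sign while their magnitudes and p-values are invariant
  expect_equal(coef(f2)[["alpha"]], -coef(f1)[["alpha"]], tolerance = 1e-10)
  expect_equal(coef(f2)[["delta"]], -coef(f1)[["delta"]], tolerance = 1e-10)
  expect_equal(coef(f2)[["beta"]], coef(f1)[["beta"]], tolerance = 1e-10)
  expect_equal(f2$indirect, -f1$indirect, tolerance = 1e-10)
  expect_equal(f2$total, -f1$total, tolerance = 1e-10)
  expect_equal(f2$p_indirect, f1$p_indirect, tolerance = 1e-10)
  expect_equal(f2$p_delta, f1$p_delta, tolerance = 1e-10)
})

test_that("a null indirect effect stays within its Sobel error bars", {
  inside <- 0
  for (s in 1:200) {
    set.seed(300 + s)
    x <- rnorm(250)
    m <- rnorm(250)                   # alpha = 0: x does not move m
    d <- 0.4 * m + rnorm(250)
    f <- mediate(x, m, d)
    if (abs(f$indirect) < 3 * f$se[["indirect"]]) inside <- inside + 1
  }
  expect_gte(inside / 200, 0.99)
})

test_that("planted indirect effects are recovered without bias", {
  est <- vapply(1:100, function(s) {
    set.seed(400 + s)
    x <- rnorm(1000)
    m <- 0.5 * x + rnorm(1000)
    d <- 0.4 * m + rnorm(1000)        # delta = 0
    mediate(x, m, d)$indirect
  }, 0)
  expect_equal(mean(est), 0.20, tolerance = 0.01)
})

test_that("mediation classes follow the significance pattern", {
  stub <- function(pi, pd) structure(list(p_indirect = pi, p_delta = pd),
                                     class = "mediation")
  expect_equal(classify_mediation(stub(0.01, 0.40)), "full")
  expect_equal(classify_mediation(stub(0.01, 0.01)), "partial")
  expect_equal(classify_mediation(stub(0.40, 0.01)), "none")
  expect_equal(classify_mediation(stub(0.40, 0.40)), "not_daICT")
  expect_equal(classify_mediation(stub(0.06, 0.04), level = 0.1), "partial")
})

test_that("bootstrap and Sobel inference agree on well-powered fits", {
  agree <- 0
  for (s in 1:20) {
    set.seed(500 + s)
    x <- rnorm(600)
    strong <- s %% 2 == 0
    m <- (if (strong) 0.5 else 0) * x + rnorm(600)
    d <- 0.4 * m + rnorm(600)
    fs <- mediate(x, m, d)
    fb <- mediate(x, m, d, boot = 399, seed = s)
    if ((fs$p_indirect < 0.05) == (fb$p_indirect < 0.05)) agree <- agree + 1
  }
  expect_gte(agree / 20, 0.9)
})

test_that("dataset-level mediation uses the 0/1 contrast coding", {
  sim <- simulate_citeseq(sim_config(
    n_samples = c(healthy = 3, severe = 3), cells_per_sample = 100,
    n_ict = 4, n_background = 0, eta2 = c(0.6, 0, 0, 0), e_shift = 1,
    sigma_u = 0.2, seed = 21))
  ds <- sim$dataset
  f <- fit_single_mediation(ds, c(m = "P1", t = "ICT1"),
                            case = "severe", ref = "healthy")
  expect_gt(coef(f)[["alpha"]], 0.3)
  expect_gt(coef(f)[["beta"]], 0)
  expect_equal(f$contrast, "severe vs healthy")
  expect_error(fit_single_mediation(ds, c(m = "P1", t = "ICT1"),
                                    case = "critical", ref = "healthy"),
               "empty")
})

test_that("the mediation scan recovers planted mediators", {
  # 10 candidate ICT genes; 4 truly move the protein, which is shifted in
  # cases, so those 4 carry real indirect effects
  sim <- simulate_citeseq(sim_config(
    n_samples = c(healthy = 4, severe = 4), cells_per_sample = 100,
    n_ict = 10, n_background = 0,
    eta2 = c(rep(0.6, 4), rep(0, 6)), e_shift = 1, sigma_u = 0.2,
    seed = 31))
  ds <- sim$dataset
  ptt <- structure(data.frame(m = "P1", g = "G1",
                              t = paste0("ICT", 1:10), is_ptt = TRUE),
                   class = c("ptt_table", "data.frame"))
  tab <- scan_mediation(ds, ptt, case = "severe", ref = "healthy")
  expect_equal(nrow(tab), 10)
  recall <- sum(tab$daICT[tab$t %in% paste0("ICT", 1:4)])
  expect_gte(recall, 3)

  empty <- scan_mediation(ds, ptt[ptt$t == "none", ],
                          case = "severe", ref = "healthy")
  expect_equal(nrow(empty), 0)
})

test_that("prediction and simulation methods are consistent with the fit", {
  set.seed(9)
  x <- rnorm(400); m <- 0.5 * x + rnorm(400); d <- 0.4 * m + 0.1 * x + rnorm(400)
  fit <- mediate(x, m, d)
  pr <- predict(fit, x = c(-1, 0, 1))
  expect_equal(diff(pr$m_hat), rep(coef(fit)[["alpha"]], 2))
  sims <- simulate(fit, nsim = 2, seed = 1)
  expect_length(sims, 2)
  refit <- mediate(sims[[1]]$x, sims[[1]]$m, sims[[1]]$d)
  expect_equal(coef(refit)[["alpha"]], coef(fit)[["alpha"]], tolerance = 0.2)
})
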