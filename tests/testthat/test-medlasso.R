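make_med_data <- function(n = 400, r = 8, seed = 1, beta = 0.5) {
  set.seed(seed)
  X <- matrix(rnorm(n * r), n, r, dimnames = list(NULL, paste0("ICT", 1:r)))
  m <- 0.5 * X[, 1] + 0.4 * X[, 2] + rnorm(n)
  d <- beta * m + 0.3 * X[, 2] + 0.4 * X[, 3] + rnorm(n)
  list(X = X, m = m, d = d)
}

test_that("the unpenalized fit equals the two-equation least-squares oracle", {
  dd <- make_med_data()
  fit <- medlasso(dd$X, dd$m, dd$d, lambda = 0, standardize = FALSE)
  o1 <- lm(dd$m ~ dd$X)
  o2 <- lm(dd$d ~ dd$X + dd$m)
  expect_equal(unname(fit$alpha), unname(coef(o1)[-1]), tolerance = 1e-6)
  expect_equal(unname(fit$delta), unname(coef(o2)[2:(1 + ncol(dd$X))]),
               tolerance = 1e-6)
  expect_equal(fit$beta, unname(coef(o2)[["dd$m"]]), tolerance = 1e-6)
  expect_equal(fit$phi0, unname(coef(o1)[1]), tolerance = 1e-6)
})

test_that("a dominating penalty zeroes every exposure but never beta", {
  dd <- make_med_data(seed = 2)
  fit <- medlasso(dd$X, dd$m, dd$d, lambda = 10)
  expect_true(all(fit$alpha == 0))
  expect_true(all(fit$delta == 0))
  # with all delta_t at zero the outcome equation collapses to d ~ m alone
  ms <- as.vector(scale(dd$m))
  expect_equal(fit$beta, unname(coef(lm(dd$d ~ ms))[2]), tolerance = 1e-6)
  expect_equal(fit$nnz, 0)
})

test_that("penalty weights follow the quartic-root rule", {
  expect_equal(penalty_weight(1), 1)
  expect_equal(penalty_weight(16), 2)
  expect_equal(penalty_weight(81), 3)
})

test_that("coordinate descent matches glmnet on the mediator equation", {
  dd <- make_med_data(n = 500, seed = 3)
  Xs <- scale(dd$X) * sqrt(500 / 499)   # unit 1/n column norms
  ms <- as.vector(scale(dd$m))
  for (lam in c(0.01, 0.05, 0.2)) {
    mine <- medlasso(Xs, ms, dd$d, lambda = lam, weight = 1,
                     standardize = FALSE)
    ref <- glmnet::glmnet(Xs, ms, lambda = lam, standardize = FALSE,
                          thresh = 1e-12)
    expect_equal(unname(mine$alpha), as.vector(ref$beta), tolerance = 1e-5)
  }
})

test_that("the objective never increases across sweeps", {
  dd <- make_med_data(n = 300, seed = 4)
  fit <- medlasso(dd$X, dd$m, dd$d, lambda = 0.02, debug = TRUE)
  for (tr in fit$objective) {
    expect_true(all(diff(tr) <= 1e-12))
  }
  expect_true(fit$converged)
})

test_that("sparsity is monotone along the path and BIC selects within it", {
  dd <- make_med_data(n = 600, seed = 5)
  path <- medlasso_path(dd$X, dd$m, dd$d,
                        grid = seq(0.001, 0.2, length.out = 12))
  expect_true(all(diff(path$nnz) <= 0))
  expect_equal(min(path$bic),
               path$fits[[which(path$grid == path$lambda_star)]]$bic)
  # warm-started path fits agree with cold restarts
  cold <- medlasso(dd$X, dd$m, dd$d, lambda = path$grid[6])
  expect_equal(path$fits[[6]]$alpha, cold$alpha, tolerance = 1e-5)
  # single-value grid selects that lambda
  one <- medlasso_path(dd$X, dd$m, dd$d, grid = 0.01)
  expect_equal(one$lambda_star, 0.01)
})

test_that("classification reads the sparsity pattern exactly", {
  fit <- structure(list(alpha = c(A = 0.3, B = 0, C = 0.2, D = 0),
                        delta = c(A = 0, B = 0.1, C = -0.1, D = 0),
                        beta = 0.5), class = "medlasso")
  cls <- classify_multi(fit)
  expect_equal(cls$class, c("full", "null", "partial", "dropped"))
  # a zero beta kills every indirect pathway
  fit$beta <- 0
  cls0 <- classify_multi(fit)
  expect_equal(cls0$class[cls0$t == "A"], "dropped")
})

test_that("strong-effect filtering applies a strict threshold", {
  tab <- structure(data.frame(m = "P1", g = "G1", t = c("T1", "T2", "T3"),
                              eta2 = c(0.05, 0.11, -0.3), is_ptt = TRUE),
                   class = c("ptt_table", "data.frame"))
  expect_setequal(filter_strong_effects(tab, "P1"), c("T2", "T3"))
  expect_setequal(filter_strong_effects(tab, "P1", threshold = 0),
                  c("T1", "T2", "T3"))
  tab$eta2 <- c(0.1, 0.1, 0.1)
  expect_warning(out <- filter_strong_effects(tab, "P1"), "no ICT gene")
  expect_length(out, 0)
  expect_error(filter_strong_effects(tab, "P9"), "no PTT rows")
})

test_that("planted sparse coefficients are recovered near their values", {
  set.seed(6)
  n <- 2000; r <- 10
  X <- matrix(rnorm(n * r), n, r, dimnames = list(NULL, paste0("T", 1:r)))
  alpha_true <- c(rep(0.4, 3), rep(0, 7))
  delta_true <- c(0, 0.4, 0.4, rep(0, 7))
  m <- drop(X %*% alpha_true) + rnorm(n)
  d <- 0.5 * m + drop(X %*% delta_true) + rnorm(n)
  path <- medlasso_path(X, m, d, standardize = FALSE)
  fit <- path$fit
  err <- c(abs(fit$alpha[alpha_true != 0] - 0.4),
           abs(fit$delta[delta_true != 0] - 0.4))
  expect_lt(mean(err), 0.15)
  # optional debiasing refit moves the estimates toward the truth
  path_r <- medlasso_path(X, m, d, standardize = FALSE, refit = TRUE)
  err_r <- c(abs(path_r$fit$alpha[alpha_true != 0] - 0.4),
             abs(path_r$fit$delta[delta_true != 0] - 0.4))
  expect_lte(mean(err_r), mean(err) + 1e-8)
})

test_that("module transition matrices cross-tabulate correctly", {
  m2 <- data.frame(t = c("A", "B", "C", "D"),
                   class = c("full", "partial", "none", "full"),
                   indirect = c(0.2, 0.1, 0.01, 0.15),
                   delta = c(0.01, 0.2, 0.3, 0.0))
  m3 <- data.frame(t = c("A", "B", "C", "D"),
                   class = c("full", "partial", "null", "dropped"))
  tr <- compare_modules(m2, m3)
  expect_equal(unname(tr$matrix["full", "full"]), 1)
  expect_equal(unname(tr$matrix["partial", "partial"]), 1)
  expect_equal(unname(tr$matrix["none", "null"]), 1)
  expect_equal(unname(tr$matrix["full", "NA"]), 1)   # dropped gene
  expect_equal(tr$effects$n, c(3, 1))
  expect_error(compare_modules(m2, data.frame(t = "Z", class = "full")),
               "no shared")
})
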