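# Coordinate-descent solver for a penalized least-squares problem
#   (1/2n) || y - b0 - X b ||^2  +  sum_j penalty_j |b_j|
# with an unpenalized intercept handled by centering. `penalty` is a
# per-column vector; zero entries leave that coefficient unpenalized.
cd_lasso <- function(X, y, penalty, tol = 1e-7, max_sweeps = 1e4,
                     init = NULL, debug = FALSE) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(penalty) == p, all(penalty >= 0))
  xm <- colMeans(X); ym <- mean(y)
  Xc <- sweep(X, 2, xm, "-")
  yc <- y - ym
  nrm2 <- colSums(Xc^2) / n            # (x_j' x_j) / n
  b <- init %||% numeric(p)
  r <- yc - drop(Xc %*% b)
  obj <- function() sum(r^2) / (2 * n) + sum(penalty * abs(b))
  trace <- if (debug) obj() else NULL
  sweeps <- 0L; converged <- FALSE
  active <- which(nrm2 > 0)            # constant columns stay at zero
  repeat {
    sweeps <- sweeps + 1L
    delta_max <- 0
    for (j in active) {
      zj <- sum(Xc[, j] * r) / n + nrm2[j] * b[j]
      bj <- soft_threshold(zj, penalty[j]) / nrm2[j]
      if (bj != b[j]) {
        r <- r - Xc[, j] * (bj - b[j])
        delta_max <- max(delta_max, abs(bj - b[j]))
        b[j] <- bj
      }
    }
    if (debug) trace <- c(trace, obj())
    if (delta_max < tol) { converged <- TRUE; break }
    if (sweeps >= max_sweeps) break
  }
  list(b = b, intercept = ym - sum(xm * b), rss = sum(r^2),
       sweeps = sweeps, converged = converged, objective = trace)
}

#' Penalty weight for multiple exposures
#'
#' `w(1, r) = r^(1/4)`: the factor balancing the L1 penalty against the
#' number `r` of ICT exposures entering the model, so that the same lambda
#' grid remains usable as exposures accumulate. `w(1, 1) = 1`,
#' `w(1, 16) = 2`.
#'
#' @param r number of exposures.
#' @return Numeric weight.
#' @export
penalty_weight <- function(r) r^(1 / 4)

#' L1-regularized multi-exposure mediation
#'
#' Joint sparse mediation of many ICT-gene exposures through one
#' surface-protein mediator onto a phenotype outcome:
#'
#'   `m = phi0  + sum_t alpha_t x_t                 + sigma`
#'   `d = omega0 + sum_t delta_t x_t + beta * m     + xi`
#'
#' estimated by minimizing
#'
#'   `(1/2n)||m - phi0 - X alpha||^2 + (1/2n)||d - omega0 - X delta - beta m||^2
#'      + lambda * w(1, r) * (sum|alpha_t| + sum|delta_t|)`
#'
#' The mediator coefficient `beta` and the intercepts are never penalized,
#' so the mediator-to-outcome link is always retained. Because the first
#' term involves only `alpha` and the second only `(delta, beta)`, the joint
#' minimizer decouples into two penalized least-squares problems, each solved
#' by coordinate descent to a stationary point (largest coefficient update
#' below `tol`, default 1e-7, or `max_sweeps` sweeps).
#'
#' Exposures and the mediator are z-scored before fitting by default so that
#' one lambda is scale-free; coefficients are reported on that standardized
#' scale.
#'
#' @param X numeric matrix of exposures, cells x r (ICT-gene transcription).
#' @param m mediator vector (protein abundance).
#' @param d outcome vector (phenotype, 0/1).
#' @param lambda non-negative regularization strength.
#' @param weight penalty weight; default [penalty_weight()] of `ncol(X)`.
#' @param standardize z-score `X` columns and `m` before fitting (default
#'   TRUE).
#' @param tol,max_sweeps coordinate-descent stopping rule.
#' @param init optional warm start: list with `alpha` and `deltabeta`.
#' @param debug record the objective after every sweep (it must be
#'   non-increasing; used by the test suite).
#' @return A `medlasso` object: `alpha`, `delta` (sparse vectors), `beta`,
#'   intercepts, residual sums of squares of both equations, nonzero support
#'   sets, BIC, and solver diagnostics.
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(2000), 200, 10); colnames(X) <- paste0("ICT", 1:10)
#' m <- 0.5 * X[, 1] + rnorm(200)
#' d <- 0.4 * m + 0.3 * X[, 2] + rnorm(200)
#' fit <- medlasso(X, m, d, lambda = 0.02)
#' fit
#' @export
medlasso <- function(X, m, d, lambda, weight = NULL, standardize = TRUE,
                     tol = 1e-7, max_sweeps = 1e4, init = NULL,
                     debug = FALSE) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  r <- ncol(X); n <- nrow(X)
  stopifnot(length(m) == n, length(d) == n, lambda >= 0)
  weight <- weight %||% penalty_weight(r)
  if (standardize) {
    X <- zscore_cols(X); attr(X, "constant") <- NULL
    if (stats::sd(m) > 0) m <- as.vector(scale(m))
  }
  pen <- lambda * weight
  f1 <- cd_lasso(X, m, penalty = rep(pen, r), tol = tol,
                 max_sweeps = max_sweeps, init = init$alpha, debug = debug)
  f2 <- cd_lasso(cbind(X, ..mediator.. = m), d,
                 penalty = c(rep(pen, r), 0), tol = tol,
                 max_sweeps = max_sweeps, init = init$deltabeta,
                 debug = debug)
  alpha <- stats::setNames(f1$b, colnames(X))
  delta <- stats::setNames(f2$b[seq_len(r)], colnames(X))
  beta <- unname(f2$b[r + 1])
  nnz <- sum(alpha != 0) + sum(delta != 0)
  bic <- n * log(f1$rss / n) + n * log(f2$rss / n) + (nnz + 3) * log(n)
  structure(list(alpha = alpha, delta = delta, beta = beta,
                 phi0 = f1$intercept, omega0 = f2$intercept,
                 lambda = lambda, weight = weight, n = n, r = r,
                 rss = c(mediator = f1$rss, outcome = f2$rss),
                 nnz = nnz, bic = bic,
                 support = list(alpha = names(alpha)[alpha != 0],
                                delta = names(delta)[delta != 0]),
                 converged = f1$converged && f2$converged,
                 sweeps = c(f1$sweeps, f2$sweeps),
                 objective = list(mediator = f1$objective,
                                  outcome = f2$objective),
                 standardized = standardize),
            class = "medlasso")
}

#' @export
print.medlasso <- function(x, ...) {
  cat(sprintf("penalized mediation fit: r = %d exposures, n = %d, lambda = %g (w = %.3f)\n",
              x$r, x$n, x$lambda, x$weight))
  cat(sprintf("  nonzero alpha: %d  nonzero delta: %d  beta = %.4f  BIC = %.1f%s\n",
              sum(x$alpha != 0), sum(x$delta != 0), x$beta, x$bic,
              if (!x$converged) "  [NOT CONVERGED]" else ""))
  invisible(x)
}

#' @export
coef.medlasso <- function(object, ...) {
  data.frame(t = names(object$alpha), alpha = unname(object$alpha),
             delta = unname(object$delta), beta = object$beta)
}

#' Select ICT exposures with strong trio effects
#'
#' From a PTT table, the ICT genes whose trio coefficient passes
#' `|eta2| > threshold` (strict) in at least one contributing PTT for the
#' protein; these form the exposure set for the multi-exposure model.
#'
#' @param ptt_table a `ptt_table`.
#' @param protein surface protein name.
#' @param threshold strict absolute-effect cutoff (default 0.1).
#' @param ptt_only consider only rows flagged `is_ptt` (default TRUE).
#' @return Character vector of ICT gene names.
#' @export
filter_strong_effects <- function(ptt_table, protein, threshold = 0.1,
                                  ptt_only = TRUE) {
  sub <- ptt_table[ptt_table$m == protein &
                     (!ptt_only | ptt_table$is_ptt), , drop = FALSE]
  if (nrow(sub) == 0) stop("no PTT rows for protein ", protein)
  genes <- unique(sub$t[!is.na(sub$eta2) & abs(sub$eta2) > threshold])
  if (length(genes) == 0)
    warning("no ICT gene passes |eta2| > ", threshold, " for ", protein)
  genes
}

#' Fit the multi-exposure mediation model from a dataset
#'
#' Convenience wrapper assembling the exposure matrix (ICT-gene
#' transcription), mediator (protein abundance) and 0/1 phenotype for a
#' contrast, then fitting [medlasso()] at one lambda or, with a grid,
#' [medlasso_path()].
#'
#' @param ds a normalized `citeseq` object.
#' @param protein surface protein (mediator).
#' @param exposures character vector of ICT genes (e.g. from
#'   [filter_strong_effects()]).
#' @param case,ref phenotype labels coded 1 / 0.
#' @param lambda single value (returns a `medlasso`) or vector / `NULL`
#'   (returns a `medlasso_path` over [lambda_grid()]).
#' @param ... passed to [medlasso()] / [medlasso_path()].
#' @return A `medlasso` or `medlasso_path` object.
#' @export
fit_multi_mediation <- function(ds, protein, exposures, case, ref,
                                lambda = NULL, ...) {
  missing <- setdiff(exposures, colnames(ds$rna))
  if (length(missing)) stop("exposures not in RNA matrix: ",
                            paste(missing, collapse = ", "))
  ic <- cells_in_groups(ds, case)
  ir <- cells_in_groups(ds, ref)
  if (!any(ic) || !any(ir)) stop("a contrast group is empty")
  keep <- ic | ir
  X <- ds$rna[keep, exposures, drop = FALSE]
  m <- ds$adt[keep, protein]
  d <- as.numeric(ic[keep])
  if (is.null(lambda) || length(lambda) > 1)
    medlasso_path(X, m, d, grid = lambda %||% lambda_grid(), ...)
  else
    medlasso(X, m, d, lambda = lambda, ...)
}

#' Default lambda grid
#'
#' Eleven evenly spaced values on `[0.005, 0.03]`, the range searched when
#' selecting the regularization strength by BIC.
#'
#' @param from,to,length.out grid parameters.
#' @return Numeric vector, ascending.
#' @export
lambda_grid <- function(from = 0.005, to = 0.03, length.out = 11) {
  seq(from, to, length.out = length.out)
}

#' Lambda path with BIC model selection
#'
#' Fits [medlasso()] at every grid value (ascending, warm-started from the
#' previous solution) and scores each fit with
#' `BIC = n log(RSS_m / n) + n log(RSS_d / n) + k log(n)`, where `k` counts
#' the nonzero penalized coefficients plus three always-present parameters
#' (`beta` and the two intercepts). The selected `lambda*` minimizes BIC;
#' ties go to the smaller lambda, keeping the less sparse candidate.
#'
#' @inheritParams medlasso
#' @param grid ascending lambda values (default [lambda_grid()]).
#' @param refit refit an unpenalized model on the selected support before
#'   classification (default FALSE).
#' @param ... passed to [medlasso()].
#' @return A `medlasso_path` object: per-lambda fits, the BIC vector,
#'   `lambda_star`, the selected `fit`, and the per-gene
#'   [classify_multi()] table at `lambda*`.
#' @export
medlasso_path <- function(X, m, d, grid = lambda_grid(), weight = NULL,
                          refit = FALSE, ...) {
  stopifnot(length(grid) >= 1)
  grid <- sort(grid)
  fits <- vector("list", length(grid))
  warm <- NULL
  for (i in seq_along(grid)) {
    fits[[i]] <- medlasso(X, m, d, lambda = grid[i], weight = weight,
                          init = warm, ...)
    warm <- list(alpha = unname(fits[[i]]$alpha),
                 deltabeta = c(unname(fits[[i]]$delta), fits[[i]]$beta))
  }
  ok <- vapply(fits, function(f) f$converged, TRUE)
  if (!any(ok)) stop("all penalized fits failed to converge")
  bic <- vapply(fits, function(f) f$bic, 0)
  bic_sel <- ifelse(ok, bic, Inf)
  i_star <- which.min(bic_sel)          # ties -> first = smallest lambda
  best <- fits[[i_star]]
  if (refit) best <- refit_support(X, m, d, best)
  structure(list(grid = grid, fits = fits, bic = bic,
                 nnz = vapply(fits, function(f) f$nnz, 0),
                 lambda_star = grid[i_star], fit = best,
                 classification = classify_multi(best), refit = refit),
            class = "medlasso_path")
}

# unpenalized least-squares refit restricted to the selected support
refit_support <- function(X, m, d, fit) {
  X <- as.matrix(X)
  if (fit$standardized) {
    X <- zscore_cols(X); attr(X, "constant") <- NULL
    if (stats::sd(m) > 0) m <- as.vector(scale(m))
  }
  sa <- fit$support$alpha; sd_ <- fit$support$delta
  alpha <- fit$alpha * 0
  if (length(sa)) {
    cf <- stats::lm.fit(cbind(1, X[, sa, drop = FALSE]), m)$coefficients
    alpha[sa] <- cf[-1]; fit$phi0 <- cf[1]
  }
  delta <- fit$delta * 0
  cf2 <- stats::lm.fit(cbind(1, X[, sd_, drop = FALSE], m), d)$coefficients
  if (length(sd_)) delta[sd_] <- cf2[1 + seq_along(sd_)]
  fit$omega0 <- cf2[1]
  fit$beta <- unname(cf2[length(cf2)])
  fit$alpha <- alpha; fit$delta <- delta
  fit
}

#' @export
print.medlasso_path <- function(x, ...) {
  cat(sprintf("lambda path: %d values on [%g, %g]; lambda* = %g (min BIC = %.1f)\n",
              length(x$grid), min(x$grid), max(x$grid), x$lambda_star,
              min(x$bic)))
  print(table(class = x$classification$class))
  invisible(x)
}

#' @export
coef.medlasso_path <- function(object, ...) coef(object$fit)

#' @export
plot.medlasso_path <- function(x, ...) {
  graphics::plot(x$grid, x$bic, type = "b", xlab = "lambda", ylab = "BIC", ...)
  graphics::abline(v = x$lambda_star, lty = 2)
  invisible(x)
}

#' Classify exposures from the sparsity pattern of a penalized fit
#'
#' At the selected lambda each ICT gene is labeled from the exact zeros of
#' its coefficients: `"full"` mediation when `alpha_t * beta != 0` and
#' `delta_t == 0`; `"partial"` when `alpha_t * beta != 0` and
#' `delta_t != 0`; `"null"` when `alpha_t * beta == 0` and `delta_t != 0`;
#' `"dropped"` when both pathways vanish. The labels are exhaustive and
#' disjoint; the regularized model produces no p-values, so sparsity takes
#' the role significance plays in the single-exposure model.
#'
#' @param fit a `medlasso` object.
#' @return data.frame with columns `t`, `alpha`, `delta`, `class`.
#' @export
classify_multi <- function(fit) {
  ind <- fit$alpha * fit$beta
  cls <- ifelse(ind != 0 & fit$delta == 0, "full",
                ifelse(ind != 0 & fit$delta != 0, "partial",
                       ifelse(ind == 0 & fit$delta != 0, "null", "dropped")))
  data.frame(t = names(fit$alpha), alpha = unname(fit$alpha),
             delta = unname(fit$delta), beta = fit$beta,
             class = unname(cls))
}

#' Cross-tabulate single- and multi-exposure classifications
#'
#' Builds the transition matrix between the single-exposure labels (full /
#' partial / none / not_daICT) and the multi-exposure labels at `lambda*`
#' (full / partial / null / dropped, the last reported as `NA` since the
#' gene leaves the model), plus mean absolute effect sizes of the
#' single-exposure fit for retained versus dropped genes.
#'
#' @param m2_table a `mediation_table` from [scan_mediation()], restricted to
#'   one protein.
#' @param m3 a `medlasso_path` or its `classification` data.frame.
#' @return A `module_transition` list: `matrix` (4 x 4 counts), and
#'   `effects` summarizing |indirect| and |delta| for retained vs dropped.
#' @export
compare_modules <- function(m2_table, m3) {
  cls3 <- if (inherits(m3, "medlasso_path")) m3$classification else m3
  common <- intersect(m2_table$t, cls3$t)
  if (length(common) == 0) stop("no shared (protein, ICT gene) keys")
  lab2 <- factor(m2_table$class[match(common, m2_table$t)],
                 levels = c("full", "partial", "none", "not_daICT"))
  lab3r <- cls3$class[match(common, cls3$t)]
  lab3 <- factor(ifelse(lab3r == "dropped", "NA", lab3r),
                 levels = c("full", "partial", "null", "NA"))
  tm <- table(module2 = lab2, module3 = lab3)
  retained <- lab3 != "NA"
  idx <- match(common, m2_table$t)
  eff <- data.frame(
    set = c("retained", "dropped"),
    n = c(sum(retained), sum(!retained)),
    mean_abs_indirect = c(mean(abs(m2_table$indirect[idx][retained])),
                          mean(abs(m2_table$indirect[idx][!retained]))),
    mean_abs_delta = c(mean(abs(m2_table$delta[idx][retained])),
                       mean(abs(m2_table$delta[idx][!retained]))))
  structure(list(matrix = tm, effects = eff, n = length(common)),
            class = "module_transition")
}

#' @export
print.module_transition <- function(x, ...) {
  cat(sprintf("single- vs multi-exposure classification (%d shared genes):\n",
              x$n))
  print(x$matrix)
  print(x$effects, digits = 3)
  invisible(x)
}
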