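#' Single-exposure linear mediation
#'
#' The core mediation estimator: for an exposure `x` (ICT-gene
#' transcription), mediator `m` (surface-protein abundance) and outcome `d`
#' (phenotype, usually coded 0/1), fits the two least-squares equations
#'
#'   `m = phi0  + alpha * x             + sigma`
#'   `d = omega0 + beta * m + delta * x + xi`
#'
#' The indirect (mediated) effect is `alpha * beta`, the direct effect
#' `delta`, and the total effect `delta + alpha * beta`, which in the
#' no-covariate linear case equals the simple-regression slope of `d` on
#' `x` exactly. Inference on the indirect effect uses the Sobel
#' (delta-method) standard error
#' `sqrt(alpha^2 se(beta)^2 + beta^2 se(alpha)^2)` by default, with a
#' seeded percentile bootstrap as an option.
#'
#' The outcome equation is linear even for a binary `d` (a linear-probability
#' reading with Gaussian errors); that choice is what makes the effect
#' decomposition exact. No random effects enter here: the sample structure is
#' handled upstream when trios are screened.
#'
#' @param x,m,d numeric vectors of equal length (cells).
#' @param boot number of bootstrap resamples for the indirect-effect p-value
#'   (0 = Sobel only; 999 is a common choice).
#' @param seed optional seed for the bootstrap.
#' @return A `mediation` object with coefficients, standard errors,
#'   `indirect`, `total`, `p_indirect`, `p_delta`, residuals of both
#'   equations, and bootstrap draws when requested.
#' @examples
#' set.seed(1)
#' x <- rnorm(500); m <- 0.5 * x + rnorm(500); d <- 0.4 * m + rnorm(500)
#' fit <- mediate(x, m, d)
#' fit
#' classify_mediation(fit)
#' @export
mediate <- function(x, m, d, boot = 0, seed = NULL) {
  n <- length(x)
  stopifnot(length(m) == n, length(d) == n)
  if (stats::sd(x) == 0) stop("constant exposure x")
  if (stats::sd(d) == 0) stop("constant outcome d (one group empty?)")

  f1 <- stats::lm(m ~ x)
  f2 <- stats::lm(d ~ m + x)
  s1 <- summary(f1)$coefficients
  s2 <- summary(f2)$coefficients

  alpha <- s1["x", "Estimate"]; se_alpha <- s1["x", "Std. Error"]
  beta <- s2["m", "Estimate"]; se_beta <- s2["m", "Std. Error"]
  delta <- s2["x", "Estimate"]; se_delta <- s2["x", "Std. Error"]
  p_delta <- s2["x", "Pr(>|t|)"]

  indirect <- alpha * beta
  se_ind <- sqrt(alpha^2 * se_beta^2 + beta^2 * se_alpha^2)
  p_ind <- if (se_ind > 0) 2 * stats::pnorm(-abs(indirect / se_ind)) else 1

  out <- list(coefficients = c(phi0 = unname(stats::coef(f1)[1]), alpha = alpha,
                               omega0 = unname(stats::coef(f2)[1]),
                               beta = beta, delta = delta),
              indirect = indirect, total = delta + indirect,
              se = c(alpha = se_alpha, beta = se_beta, delta = se_delta,
                     indirect = se_ind),
              p_indirect = p_ind, p_delta = p_delta, n = n,
              method = "sobel",
              residuals = list(mediator = stats::resid(f1),
                               outcome = stats::resid(f2)))
  if (boot > 0) {
    if (!is.null(seed)) set.seed(seed)
    draws <- replicate(boot, {
      i <- sample.int(n, n, replace = TRUE)
      a <- stats::cov(x[i], m[i]) / stats::var(x[i])
      cf <- stats::lm.fit(cbind(1, m[i], x[i]), d[i])$coefficients
      a * cf[2]
    })
    # percentile bootstrap two-sided p with add-one smoothing
    p_boot <- 2 * min((1 + sum(draws <= 0)) / (boot + 1),
                      (1 + sum(draws >= 0)) / (boot + 1))
    out$p_indirect <- min(p_boot, 1)
    out$method <- "bootstrap"
    out$boot <- draws
  }
  class(out) <- "mediation"
  out
}

#' @export
print.mediation <- function(x, ...) {
  co <- x$coefficients
  cat(sprintf("mediation fit (n = %d, %s inference)\n", x$n, x$method))
  cat(sprintf("  alpha = %.4f  beta = %.4f  delta = %.4f\n",
              co["alpha"], co["beta"], co["delta"]))
  cat(sprintf("  indirect = %.4f (p = %.3g)  direct = %.4f (p = %.3g)  total = %.4f\n",
              x$indirect, x$p_indirect, co["delta"], x$p_delta, x$total))
  invisible(x)
}

#' @export
coef.mediation <- function(object, ...) object$coefficients

#' @export
residuals.mediation <- function(object,
                                equation = c("outcome", "mediator"), ...) {
  object$residuals[[match.arg(equation)]]
}

#' @export
summary.mediation <- function(object, ...) {
  data.frame(effect = c("indirect", "direct", "total"),
             estimate = c(object$indirect, object$coefficients["delta"],
                          object$total),
             se = c(object$se["indirect"], object$se["delta"], NA),
             p = c(object$p_indirect, object$p_delta, NA))
}

#' @export
predict.mediation <- function(object, x, ...) {
  co <- object$coefficients
  m_hat <- co["phi0"] + co["alpha"] * x
  d_hat <- co["omega0"] + co["beta"] * m_hat + co["delta"] * x
  data.frame(x = x, m_hat = unname(m_hat), d_hat = unname(d_hat))
}

#' @export
simulate.mediation <- function(object, nsim = 1, seed = NULL, x = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  co <- object$coefficients
  s_m <- stats::sd(object$residuals$mediator)
  s_d <- stats::sd(object$residuals$outcome)
  lapply(seq_len(nsim), function(i) {
    xi <- x %||% stats::rnorm(object$n)
    m <- co["phi0"] + co["alpha"] * xi + stats::rnorm(length(xi), 0, s_m)
    d <- co["omega0"] + co["beta"] * m + co["delta"] * xi +
      stats::rnorm(length(xi), 0, s_d)
    data.frame(x = xi, m = unname(m), d = unname(d))
  })
}

#' Fit single-exposure mediation for one trio and one phenotype contrast
#'
#' Pulls the exposure (ICT-gene transcription), mediator (protein abundance)
#' and binary-coded phenotype out of the dataset for the cells of the two
#' contrasted groups, then calls [mediate()]. The case group is coded 1 and
#' the reference 0; either side may pool several labels (e.g. severe vs
#' healthy plus mild).
#'
#' @param ds a normalized `citeseq` object.
#' @param trio named vector / one-row data.frame with `m` and `t` (the coding
#'   gene plays no role in the mediation equations).
#' @param case,ref phenotype label(s) coded 1 and 0.
#' @inheritParams mediate
#' @return A `mediation` object (see [mediate()]) with `m`, `t` and the
#'   contrast recorded.
#' @export
fit_single_mediation <- function(ds, trio, case, ref, boot = 0, seed = NULL) {
  trio <- as.list(trio)
  ic <- cells_in_groups(ds, case)
  ir <- cells_in_groups(ds, ref)
  if (!any(ic) || !any(ir)) stop("constant outcome: a contrast group is empty")
  keep <- ic | ir
  fit <- mediate(x = ds$rna[keep, trio$t],
                 m = ds$adt[keep, trio$m],
                 d = as.numeric(ic[keep]),
                 boot = boot, seed = seed)
  fit$m <- trio$m; fit$t <- trio$t
  fit$contrast <- paste(paste(case, collapse = "+"), "vs",
                        paste(ref, collapse = "+"))
  fit
}

#' Classify a mediation fit
#'
#' Labels the exposure gene by which effects are significant at `level`:
#' `"full"` mediation when only the indirect effect is non-zero, `"partial"`
#' when both indirect and direct are, `"none"` when only the direct effect
#' is, and `"not_daICT"` when neither — a gene with any of the first three
#' labels is a disease-associated ICT (daICT) gene.
#'
#' @param fit a `mediation` object.
#' @param level significance level (default 0.05, nominal — no
#'   multiple-testing correction by default; apply [stats::p.adjust()] to a
#'   scan table for an FDR-controlled variant).
#' @return One of `"full"`, `"partial"`, `"none"`, `"not_daICT"`.
#' @export
classify_mediation <- function(fit, level = 0.05) {
  sig_ind <- fit$p_indirect < level
  sig_dir <- fit$p_delta < level
  if (sig_ind && !sig_dir) "full"
  else if (sig_ind && sig_dir) "partial"
  else if (!sig_ind && sig_dir) "none"
  else "not_daICT"
}

#' Mediation scan over the PTTs of a contrast
#'
#' Runs [fit_single_mediation()] for every distinct (protein, ICT gene) pair
#' flagged as a PTT in the supplied table and classifies each fit. When the
#' PTT table mixes several phenotype groups, the union of flagged pairs is
#' used.
#'
#' @param ds a normalized `citeseq` object.
#' @param ptt_table a `ptt_table` (or any data.frame with `m`, `t` and
#'   `is_ptt`); rows with `is_ptt == FALSE` are ignored.
#' @param case,ref contrast labels as in [fit_single_mediation()].
#' @param protein optional: restrict to one surface protein.
#' @param level classification level (default 0.05).
#' @param boot,seed bootstrap options passed through.
#' @return A `mediation_table` data.frame: one row per (m, t) with all
#'   coefficients, effects, standard errors, p-values, class and daICT flag.
#' @export
scan_mediation <- function(ds, ptt_table, case, ref, protein = NULL,
                           level = 0.05, boot = 0, seed = NULL) {
  keys <- unique(as.data.frame(ptt_table)[ptt_table$is_ptt, c("m", "t")])
  if (!is.null(protein)) keys <- keys[keys$m %in% protein, , drop = FALSE]
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    f <- tryCatch(fit_single_mediation(ds, keys[i, ], case, ref,
                                       boot = boot, seed = seed),
                  error = function(e) NULL)
    if (is.null(f)) return(NULL)
    cls <- classify_mediation(f, level)
    data.frame(m = keys$m[i], t = keys$t[i], contrast = f$contrast,
               alpha = f$coefficients[["alpha"]],
               beta = f$coefficients[["beta"]],
               delta = f$coefficients[["delta"]],
               indirect = f$indirect, total = f$total,
               se_alpha = f$se[["alpha"]], se_beta = f$se[["beta"]],
               se_delta = f$se[["delta"]], se_indirect = f$se[["indirect"]],
               p_indirect = f$p_indirect, p_delta = f$p_delta,
               class = cls, daICT = cls != "not_daICT")
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(m = character(0), t = character(0),
                      contrast = character(0), alpha = numeric(0),
                      beta = numeric(0), delta = numeric(0),
                      indirect = numeric(0), total = numeric(0),
                      se_alpha = numeric(0), se_beta = numeric(0),
                      se_delta = numeric(0), se_indirect = numeric(0),
                      p_indirect = numeric(0), p_delta = numeric(0),
                      class = character(0), daICT = logical(0))
  rownames(out) <- NULL
  class(out) <- c("mediation_table", "data.frame")
  attr(out, "level") <- level
  out
}

#' @export
print.mediation_table <- function(x, ...) {
  cat(sprintf("mediation scan: %d (protein, ICT gene) pairs, %d daICT\n",
              nrow(x), sum(x$daICT)))
  if (nrow(x)) print(table(class = x$class))
  invisible(x)
}

#' Write a mediation table as TSV
#' @param tab a `mediation_table`.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_mediation <- function(tab, path) {
  write_tsv(as.data.frame(tab), path)
}
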