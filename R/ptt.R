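#' Fit the trio mixed-effects model
#'
#' For one trio (protein m, coding gene g, ICT gene t) and one phenotype
#' group, fits by restricted maximum likelihood
#'
#'   `E_mc = eta0 + eta1 * X_gc + eta2 * X_tc + sum(zeta * V) + (1 | sample) + eps`
#'
#' where `E` is the normalized ADT abundance of the protein, `X_g` and `X_t`
#' the normalized transcription of the coding gene and the ICT gene, `V`
#' optional per-cell covariates, and the random intercept absorbs the
#' non-independence of cells from the same sample. The coefficient of
#' interest is `eta2`, the effect of ICT-gene transcription on surface
#' abundance after accounting for the protein's own transcription; its
#' p-value is a Wald z-test by default.
#'
#' @param ds a normalized `citeseq` object.
#' @param trio named character vector or one-row data.frame with entries
#'   `m`, `g`, `t`.
#' @param group phenotype label(s) to subset cells to; `NULL` uses all cells.
#' @param covariates character vector of numeric metadata columns (`V`).
#' @param df `"wald"` (z-test, default) or `"satterthwaite"` (requires the
#'   lmerTest package).
#' @return A `trio_fit` object: coefficients (`eta0`, `eta1`, `eta2`,
#'   covariate `zeta`s), standard errors, p-values for `eta1` and `eta2`,
#'   variance components `sigma_u2` (sample intercept) and `sigma_e2`
#'   (residual), `r2` (squared correlation of fitted vs observed),
#'   cell/sample counts, and convergence/singularity flags.
#' @examples
#' ds <- make_fixture("one-strong-trio")$dataset
#' fit <- fit_trio(ds, c(m = "P1", g = "G1", t = "ICT1"), group = "healthy")
#' fit
#' @export
fit_trio <- function(ds, trio, group = NULL, covariates = NULL,
                     df = c("wald", "satterthwaite")) {
  df <- match.arg(df)
  trio <- as.list(trio)
  dat <- trio_frame(ds, trio, group, covariates)
  fit_trio_frame(dat, trio, group, covariates, df, reduced = FALSE)
}

# assemble the per-cell model frame for one trio
trio_frame <- function(ds, trio, group, covariates) {
  for (nm in c("m", "g", "t"))
    if (is.null(trio[[nm]])) stop("trio must provide m, g and t")
  if (!trio$m %in% colnames(ds$adt)) stop("protein not in ADT matrix: ", trio$m)
  if (!trio$g %in% colnames(ds$rna)) stop("coding gene not in RNA matrix: ", trio$g)
  if (!is.na(trio$t) && !trio$t %in% colnames(ds$rna))
    stop("ICT gene not in RNA matrix: ", trio$t)
  keep <- if (is.null(group)) rep(TRUE, nrow(ds$rna)) else cells_in_groups(ds, group)
  dat <- data.frame(E = ds$adt[keep, trio$m],
                    Xg = ds$rna[keep, trio$g],
                    sample = factor(ds$meta$sample_id[keep]))
  if (!is.na(trio$t)) dat$Xt <- ds$rna[keep, trio$t]
  for (v in covariates) dat[[v]] <- ds$meta[[v]][keep]
  dat
}

fit_trio_frame <- function(dat, trio, group, covariates, df, reduced = FALSE) {
  if (nlevels(droplevels(dat$sample)) < 2)
    stop("need at least 2 samples in the group")
  if (stats::sd(dat$Xg) == 0 || (!reduced && stats::sd(dat$Xt) == 0))
    stop("degenerate predictor: constant within group")

  rhs <- c("Xg", if (!reduced) "Xt", covariates, "(1 | sample)")
  fml <- stats::as.formula(paste("E ~", paste(rhs, collapse = " + ")))

  use_satt <- df == "satterthwaite"
  if (use_satt && !requireNamespace("lmerTest", quietly = TRUE)) {
    warning("lmerTest not available; falling back to Wald z")
    use_satt <- FALSE
  }
  fitter <- if (use_satt) lmerTest::lmer else lme4::lmer

  warn <- character(0)
  fit <- withCallingHandlers(
    fitter(fml, data = dat, REML = TRUE),
    warning = function(w) {
      warn <<- c(warn, conditionMessage(w))
      invokeRestart("muffleWarning")
    },
    message = function(m) invokeRestart("muffleMessage"))
  msgs <- fit@optinfo$conv$lme4$messages %||% character(0)
  msgs <- msgs[!grepl("boundary (singular)", msgs, fixed = TRUE)]
  converged <- length(msgs) == 0 &&
    !any(grepl("failed to converge|unable to evaluate", warn))
  singular <- lme4::isSingular(fit)

  sm <- summary(fit)
  ct <- sm$coefficients
  est <- ct[, "Estimate"]
  se <- ct[, "Std. Error"]
  pvals <- if (use_satt) ct[, "Pr(>|t|)"] else 2 * stats::pnorm(-abs(est / se))

  vc <- as.data.frame(lme4::VarCorr(fit))
  sigma_u2 <- vc$vcov[vc$grp == "sample"]
  sigma_e2 <- vc$vcov[vc$grp == "Residual"]

  coefs <- c(eta0 = unname(est["(Intercept)"]), eta1 = unname(est["Xg"]),
             eta2 = if (!reduced) unname(est["Xt"]) else NA_real_)
  zeta <- if (length(covariates)) est[covariates] else numeric(0)

  structure(list(
    m = trio$m, g = trio$g, t = if (reduced) NA_character_ else trio$t,
    group = paste(group %||% "all", collapse = "+"),
    coefficients = coefs, zeta = zeta,
    se = c(eta1 = unname(se["Xg"]),
           eta2 = if (!reduced) unname(se["Xt"]) else NA_real_),
    p = c(eta1 = unname(pvals["Xg"]),
          eta2 = if (!reduced) unname(pvals["Xt"]) else NA_real_),
    sigma_u2 = sigma_u2, sigma_e2 = sigma_e2,
    r2 = stats::cor(stats::fitted(fit), dat$E)^2,
    n_cells = nrow(dat), n_samples = nlevels(droplevels(dat$sample)),
    converged = converged, singular = singular, df_method = df,
    reduced = reduced),
    class = "trio_fit")
}

#' @export
print.trio_fit <- function(x, ...) {
  cat(sprintf("trio fit [%s]: %s ~ %s + %s  (group %s, %d cells / %d samples)\n",
              if (x$reduced) "reduced" else "full",
              x$m, x$g, if (x$reduced) "-" else x$t, x$group,
              x$n_cells, x$n_samples))
  cat(sprintf("  eta1 = %.4f  eta2 = %s (se %s, p %s)\n",
              x$coefficients["eta1"],
              formatC(x$coefficients["eta2"], format = "g", digits = 4),
              formatC(x$se["eta2"], format = "g", digits = 3),
              formatC(x$p["eta2"], format = "g", digits = 3)))
  cat(sprintf("  sigma_u^2 = %.4f  sigma_e^2 = %.4f  R^2 = %.3f%s\n",
              x$sigma_u2, x$sigma_e2, x$r2,
              if (!x$converged) "  [NOT CONVERGED]" else ""))
  invisible(x)
}

#' @export
coef.trio_fit <- function(object, ...) {
  c(object$coefficients, object$zeta)
}

#' Scan a trio catalog for putative transport trios (PTTs)
#'
#' Fits [fit_trio()] for every trio in the catalog within one phenotype
#' group, adjusts the `eta2` p-values of all converged fits by
#' Benjamini-Hochberg, and flags trios with FDR below `level` as putative
#' transport trios. Trios whose fit fails (degenerate predictors,
#' non-convergence) are retained in the table with `converged = FALSE` but
#' excluded from the FDR family, since invalid p-values would distort it.
#'
#' @param ds a normalized `citeseq` object.
#' @param catalog a `trio_catalog` (or data.frame with `m`, `g`, `t`).
#' @param group phenotype label(s) defining the analysis group.
#' @param covariates optional covariate column names.
#' @param level FDR threshold for the `is_ptt` flag (default 0.05).
#' @param df p-value method passed to [fit_trio()].
#' @return A `ptt_table` data.frame, one row per trio: coefficients, se and
#'   p for `eta2` (plus `eta1` stats for model comparison), FDR, `is_ptt`,
#'   variance components, `r2`, counts and convergence flag.
#' @export
scan_trios <- function(ds, catalog, group, covariates = NULL, level = 0.05,
                       df = "wald") {
  if (nrow(catalog) == 0) {
    out <- empty_ptt_table()
    return(out)
  }
  rows <- vector("list", nrow(catalog))
  for (i in seq_len(nrow(catalog))) {
    trio <- catalog[i, ]
    f <- tryCatch(fit_trio(ds, trio, group = group, covariates = covariates,
                           df = df),
                  error = function(e) e)
    if (inherits(f, "error")) {
      rows[[i]] <- data.frame(m = trio$m, g = trio$g, t = trio$t,
                              group = paste(group, collapse = "+"),
                              eta0 = NA_real_, eta1 = NA_real_, eta2 = NA_real_,
                              se1 = NA_real_, se2 = NA_real_,
                              p1 = NA_real_, p = NA_real_,
                              sigma_u2 = NA_real_, sigma_e2 = NA_real_,
                              r2 = NA_real_, n_cells = NA_integer_,
                              n_samples = NA_integer_, converged = FALSE,
                              note = conditionMessage(f))
    } else {
      rows[[i]] <- data.frame(m = f$m, g = f$g, t = f$t, group = f$group,
                              eta0 = f$coefficients[["eta0"]],
                              eta1 = f$coefficients[["eta1"]],
                              eta2 = f$coefficients[["eta2"]],
                              se1 = f$se[["eta1"]], se2 = f$se[["eta2"]],
                              p1 = f$p[["eta1"]], p = f$p[["eta2"]],
                              sigma_u2 = f$sigma_u2, sigma_e2 = f$sigma_e2,
                              r2 = f$r2, n_cells = f$n_cells,
                              n_samples = f$n_samples, converged = f$converged,
                              note = "")
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$fdr <- NA_real_
  ok <- out$converged & !is.na(out$p)
  out$fdr[ok] <- stats::p.adjust(out$p[ok], method = "BH")
  out$is_ptt <- !is.na(out$fdr) & out$fdr < level
  class(out) <- c("ptt_table", "data.frame")
  attr(out, "level") <- level
  out
}

empty_ptt_table <- function() {
  out <- data.frame(m = character(0), g = character(0), t = character(0),
                    group = character(0), eta0 = numeric(0), eta1 = numeric(0),
                    eta2 = numeric(0), se1 = numeric(0), se2 = numeric(0),
                    p1 = numeric(0), p = numeric(0), sigma_u2 = numeric(0),
                    sigma_e2 = numeric(0), r2 = numeric(0),
                    n_cells = integer(0), n_samples = integer(0),
                    converged = logical(0), note = character(0),
                    fdr = numeric(0), is_ptt = logical(0))
  class(out) <- c("ptt_table", "data.frame")
  out
}

#' @export
print.ptt_table <- function(x, ...) {
  cat(sprintf("PTT table: %d trios, %d converged, %d PTTs (FDR < %s)\n",
              nrow(x), sum(x$converged), sum(x$is_ptt),
              format(attr(x, "level") %||% 0.05)))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x)[
    order(x$fdr), c("m", "g", "t", "group", "eta1", "eta2", "p", "fdr", "is_ptt")]),
    digits = 3)
  invisible(x)
}

#' @export
summary.ptt_table <- function(object, ...) {
  by_protein <- tapply(object$t[object$is_ptt], object$m[object$is_ptt],
                       function(t) length(unique(t)))
  list(n_trios = nrow(object), n_converged = sum(object$converged),
       n_ptt = sum(object$is_ptt),
       ict_per_protein = by_protein)
}

#' Write a PTT table as TSV
#' @param tab a `ptt_table`.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_ptt <- function(tab, path) {
  write_tsv(as.data.frame(tab), path)
}

#' Compare the full trio model with a reduced model without the ICT gene
#'
#' For every (protein, coding gene) pair the full model's statistics are
#' aggregated across that pair's trios — the maximum `eta1`, the minimum
#' `eta1` p-value, the mean `r2` — and set against a reduced model
#' `E ~ Xg + V + (1 | sample)` fitted once per pair. The comparison measures
#' how much including ICT transcription strengthens the apparent link
#' between coding-gene transcription and surface abundance.
#'
#' @param ds a normalized `citeseq` object.
#' @param catalog trio catalog.
#' @param group phenotype label(s).
#' @param covariates optional covariate column names.
#' @param ptt optional precomputed [scan_trios()] table for this group, to
#'   avoid refitting the full models.
#' @return A `model_comparison` data.frame, one row per pair, with
#'   `eta1_full`, `p_full`, `r2_full`, `eta1_reduced`, `p_reduced`,
#'   `r2_reduced`.
#' @export
compare_reduced <- function(ds, catalog, group, covariates = NULL, ptt = NULL) {
  if (is.null(ptt)) ptt <- scan_trios(ds, catalog, group, covariates)
  ok <- ptt[ptt$converged, , drop = FALSE]
  if (nrow(ok) == 0) stop("no converged trios to compare")
  keys <- unique(ok[, c("m", "g")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- ok[ok$m == keys$m[i] & ok$g == keys$g[i], ]
    dat <- trio_frame(ds, list(m = keys$m[i], g = keys$g[i], t = NA),
                      group, covariates)
    red <- fit_trio_frame(dat, list(m = keys$m[i], g = keys$g[i], t = NA),
                          group, covariates, df = "wald", reduced = TRUE)
    data.frame(m = keys$m[i], g = keys$g[i], n_trios = nrow(sub),
               eta1_full = max(sub$eta1), p_full = min(sub$p1),
               r2_full = mean(sub$r2),
               eta1_reduced = red$coefficients[["eta1"]],
               p_reduced = red$p[["eta1"]], r2_reduced = red$r2)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("model_comparison", "data.frame")
  out
}

#' @export
summary.model_comparison <- function(object, ...) {
  tt <- function(a, b) if (nrow(object) > 1 && stats::sd(a - b) > 0)
    stats::t.test(a, b, paired = TRUE)$p.value else NA_real_
  data.frame(
    statistic = c("eta1", "min_p", "mean_r2"),
    full = c(mean(object$eta1_full), mean(object$p_full), mean(object$r2_full)),
    reduced = c(mean(object$eta1_reduced), mean(object$p_reduced),
                mean(object$r2_reduced)),
    paired_t_p = c(tt(object$eta1_full, object$eta1_reduced),
                   tt(object$p_full, object$p_reduced),
                   tt(object$r2_full, object$r2_reduced)))
}

#' Summarize PTT tables across phenotype groups
#'
#' Counts the distinct ICT genes recruited per protein in each group, the
#' trios shared by all groups, and — when mean protein abundances are
#' supplied — the Pearson correlation between a protein's abundance and the
#' number of ICT genes it recruits.
#'
#' @param tables named list of `ptt_table`s, one per phenotype group.
#' @param protein_abundance optional named numeric vector of mean protein
#'   abundance (names matching proteins).
#' @return A `ptt_summary` list: `ict_counts` (protein x group matrix of
#'   distinct ICT genes), `shared_trios` (keys flagged in every group),
#'   `per_group` PTT totals, and `abundance_cor` per group when abundances
#'   were given.
#' @export
summarize_ptt <- function(tables, protein_abundance = NULL) {
  stopifnot(length(tables) >= 1)
  if (is.null(names(tables)))
    names(tables) <- paste0("group", seq_along(tables))
  proteins <- sort(unique(unlist(lapply(tables, function(t) t$m))))
  counts <- sapply(tables, function(tab) {
    sapply(proteins, function(p)
      length(unique(tab$t[tab$is_ptt & tab$m == p])))
  })
  counts <- matrix(counts, nrow = length(proteins),
                   dimnames = list(proteins, names(tables)))
  keysets <- lapply(tables, function(tab)
    unique(paste(tab$m, tab$g, tab$t, sep = "\r")[tab$is_ptt]))
  shared <- Reduce(intersect, keysets)
  res <- list(ict_counts = counts,
              per_group = vapply(tables, function(t) sum(t$is_ptt), 0L),
              n_shared = length(shared),
              shared_trios = if (length(shared)) {
                parts <- do.call(rbind, strsplit(shared, "\r", fixed = TRUE))
                data.frame(m = parts[, 1], g = parts[, 2], t = parts[, 3])
              } else data.frame(m = character(0), g = character(0),
                                t = character(0)))
  if (!is.null(protein_abundance)) {
    res$abundance_cor <- apply(counts, 2, function(cnt) {
      ab <- protein_abundance[rownames(counts)]
      if (sum(!is.na(ab)) >= 3 && stats::sd(cnt) > 0 &&
          stats::sd(ab, na.rm = TRUE) > 0)
        stats::cor(ab, cnt, use = "complete.obs") else NA_real_
    })
  }
  class(res) <- "ptt_summary"
  res
}

#' @export
print.ptt_summary <- function(x, ...) {
  cat("PTTs per group:\n"); print(x$per_group)
  cat(sprintf("shared across all groups: %d trios\n", x$n_shared))
  if (!is.null(x$abundance_cor)) {
    cat("abundance vs ICT-count correlation:\n"); print(round(x$abundance_cor, 3))
  }
  invisible(x)
}

#' @export
plot.ptt_summary <- function(x, group = colnames(x$ict_counts)[1],
                             protein_abundance = NULL, ...) {
  cnt <- x$ict_counts[, group]
  if (is.null(protein_abundance)) {
    graphics::barplot(sort(cnt, decreasing = TRUE), las = 2,
                      ylab = "distinct ICT genes", main = group, ...)
  } else {
    ab <- protein_abundance[names(cnt)]
    graphics::plot(ab, cnt, xlab = "mean protein abundance",
                   ylab = "distinct ICT genes", main = group, ...)
  }
  invisible(x)
}
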