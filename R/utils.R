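# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Soft-thresholding operator
#'
#' `sign(z) * max(|z| - gamma, 0)`, the proximal operator of the absolute
#' value; the elementary step of the coordinate-descent lasso solver.
#'
#' @param z numeric vector.
#' @param gamma non-negative threshold.
#' @return numeric vector of the same length as `z`.
#' @keywords internal
soft_threshold <- function(z, gamma) {
  sign(z) * pmax(abs(z) - gamma, 0)
}

# column z-score; constant columns become all-zero and are reported
zscore_cols <- function(x, tol = 1e-12) {
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  constant <- sdv < tol
  sdv[constant] <- 1
  z <- sweep(sweep(x, 2, mu, "-"), 2, sdv, "/")
  z[, constant] <- 0
  attr(z, "constant") <- colnames(x)[constant] %||% which(constant)
  z
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}

stop_if_missing_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(sprintf("%s is missing required column(s): %s",
                 what, paste(miss, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}
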