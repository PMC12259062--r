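#' Paired RNA/ADT single-cell dataset
#'
#' Container for CITE-seq-style data: a cell x gene RNA matrix and a cell x
#' protein ADT (antibody-derived tag) matrix measured on the same cells, plus
#' per-cell metadata. Both matrices share one cell ordering; each cell carries
#' a sample identifier (the grouping unit for random intercepts downstream), a
#' phenotype label, and zero or more numeric covariates.
#'
#' @param rna numeric matrix, cells in rows and genes in columns. Row names are
#'   cell identifiers, column names gene symbols.
#' @param adt numeric matrix, cells in rows and surface proteins in columns,
#'   same cell ordering as `rna`.
#' @param meta data.frame with columns `cell_id`, `sample_id`, `phenotype`;
#'   any additional numeric columns are available as covariates.
#' @param rna_layer,adt_layer tags recording what the values are:
#'   `"counts"`, `"lognorm"`, `"lognorm.z"` for RNA; `"counts"`, `"clr"`,
#'   `"clr.z"` for ADT.
#' @return An object of class `citeseq`.
#' @examples
#' rna <- matrix(rpois(60, 5), 6, 10,
#'               dimnames = list(paste0("c", 1:6), paste0("g", 1:10)))
#' adt <- matrix(rpois(12, 50), 6, 2,
#'               dimnames = list(paste0("c", 1:6), c("CD3", "CD69")))
#' meta <- data.frame(cell_id = paste0("c", 1:6),
#'                    sample_id = rep(c("s1", "s2"), each = 3),
#'                    phenotype = rep(c("healthy", "severe"), each = 3))
#' ds <- citeseq_dataset(rna, adt, meta)
#' ds
#' @export
citeseq_dataset <- function(rna, adt, meta,
                            rna_layer = "counts", adt_layer = "counts") {
  rna <- as.matrix(rna)
  adt <- as.matrix(adt)
  stop_if_missing_cols(meta, c("cell_id", "sample_id", "phenotype"), "metadata")
  meta$cell_id <- as.character(meta$cell_id)

  if (is.null(rownames(rna)) || is.null(rownames(adt)))
    stop("matrices must carry cell identifiers as row names")
  if (nrow(rna) != nrow(adt) || !identical(rownames(rna), rownames(adt)))
    stop("dimension mismatch: RNA and ADT matrices must cover the same cells in the same order")
  if (anyDuplicated(rownames(rna))) stop("duplicate cell ids")
  if (anyDuplicated(colnames(rna))) stop("duplicate gene names")
  if (anyDuplicated(colnames(adt))) stop("duplicate protein names")

  missing_meta <- setdiff(rownames(rna), meta$cell_id)
  if (length(missing_meta))
    stop(sprintf("unannotated cells: %d cell(s) absent from metadata (e.g. %s)",
                 length(missing_meta), missing_meta[1]))
  extra <- setdiff(meta$cell_id, rownames(rna))
  if (length(extra)) {
    warning(sprintf("dropping %d metadata row(s) without matrix cells", length(extra)))
  }
  meta <- meta[match(rownames(rna), meta$cell_id), , drop = FALSE]
  rownames(meta) <- NULL

  if (any(is.na(meta$sample_id)) || any(!nzchar(as.character(meta$sample_id))))
    stop("sample_id must be non-empty for every cell")
  meta$sample_id <- as.character(meta$sample_id)
  meta$phenotype <- as.character(meta$phenotype)

  structure(list(rna = rna, adt = adt, meta = meta,
                 rna_layer = rna_layer, adt_layer = adt_layer,
                 constant_genes = character(0)),
            class = "citeseq")
}

#' @export
print.citeseq <- function(x, ...) {
  cat(sprintf("citeseq dataset: %d cells, %d genes [%s], %d proteins [%s]\n",
              nrow(x$rna), ncol(x$rna), x$rna_layer, ncol(x$adt), x$adt_layer))
  cat(sprintf("  samples: %d  phenotypes: %s\n",
              length(unique(x$meta$sample_id)),
              paste(names(table(x$meta$phenotype)), table(x$meta$phenotype),
                    sep = "=", collapse = ", ")))
  invisible(x)
}

#' @export
dim.citeseq <- function(x) c(cells = nrow(x$rna), genes = ncol(x$rna),
                             proteins = ncol(x$adt))

# subset by logical/integer cell index, keeping matrices and metadata aligned
subset_cells <- function(ds, idx) {
  ds$rna <- ds$rna[idx, , drop = FALSE]
  ds$adt <- ds$adt[idx, , drop = FALSE]
  ds$meta <- ds$meta[idx, , drop = FALSE]
  rownames(ds$meta) <- NULL
  ds
}

# cells belonging to one or more phenotype labels
cells_in_groups <- function(ds, groups) {
  ds$meta$phenotype %in% groups
}

read_matrix_any <- function(path, format) {
  if (format == "mtx") {
    mtx <- file.path(path, "matrix.mtx")
    feat <- file.path(path, "features.tsv")
    bc <- file.path(path, "barcodes.tsv")
    for (f in c(mtx, feat, bc))
      if (!file.exists(f)) stop("missing MTX component: ", f)
    m <- as.matrix(Matrix::readMM(mtx))        # features x cells on disk
    features <- utils::read.delim(feat, header = FALSE)[[1]]
    barcodes <- utils::read.delim(bc, header = FALSE)[[1]]
    dimnames(m) <- list(features, barcodes)
    t(m)                                       # cells x features internally
  } else if (format == "tsv") {
    df <- utils::read.delim(path, check.names = FALSE, row.names = 1)
    as.matrix(df)
  } else {
    stop("unknown format: ", format)
  }
}

guess_format <- function(path) {
  if (dir.exists(path)) "mtx" else "tsv"
}

#' Load a paired RNA/ADT dataset from disk
#'
#' Reads either Matrix Market triplets (a directory containing `matrix.mtx`,
#' `features.tsv`, `barcodes.tsv`, stored features x cells as is conventional)
#' or dense TSV files (cells in rows, first column cell ids, header row of
#' feature names), together with a metadata TSV carrying `cell_id`,
#' `sample_id` and `phenotype` columns.
#'
#' @param rna_path,adt_path directory (MTX) or file (TSV) per matrix.
#' @param metadata_path metadata TSV path.
#' @param format `"auto"` (directory means MTX), `"mtx"` or `"tsv"`.
#' @param rna_layer,adt_layer layer tags for the values being read.
#' @return A [citeseq_dataset()].
#' @seealso [write_citeseq()]
#' @export
load_citeseq <- function(rna_path, adt_path, metadata_path,
                         format = c("auto", "mtx", "tsv"),
                         rna_layer = "counts", adt_layer = "counts") {
  format <- match.arg(format)
  fr <- if (format == "auto") guess_format(rna_path) else format
  fa <- if (format == "auto") guess_format(adt_path) else format
  rna <- read_matrix_any(rna_path, fr)
  adt <- read_matrix_any(adt_path, fa)
  meta <- read_tsv(metadata_path)
  adt <- adt[match(rownames(rna), rownames(adt)), , drop = FALSE]
  if (any(is.na(rownames(adt))))
    stop("dimension mismatch: ADT matrix does not cover all RNA cells")
  citeseq_dataset(rna, adt, meta, rna_layer = rna_layer, adt_layer = adt_layer)
}

write_matrix_any <- function(m, path, format) {
  if (format == "mtx") {
    dir.create(path, recursive = TRUE, showWarnings = FALSE)
    # write the triplet by hand at full precision (features x cells)
    tm <- t(m)
    sp <- methods::as(methods::as(Matrix::Matrix(tm, sparse = TRUE),
                                  "generalMatrix"), "TsparseMatrix")
    con <- file(file.path(path, "matrix.mtx"), "w")
    writeLines("%%MatrixMarket matrix coordinate real general", con)
    writeLines(sprintf("%d %d %d", nrow(tm), ncol(tm), length(sp@x)), con)
    writeLines(sprintf("%d %d %.17g", sp@i + 1L, sp@j + 1L, sp@x), con)
    close(con)
    utils::write.table(data.frame(rownames(tm)), file.path(path, "features.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
    utils::write.table(data.frame(colnames(tm)), file.path(path, "barcodes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  } else if (format == "tsv") {
    df <- data.frame(cell_id = rownames(m),
                     format(m, digits = 17, trim = TRUE, scientific = TRUE),
                     check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else stop("unknown format: ", format)
  invisible(path)
}

#' Write a paired dataset to disk
#'
#' Inverse of [load_citeseq()]; the write/read round trip preserves values to
#' near machine precision in both supported encodings.
#'
#' @param ds a `citeseq` object.
#' @param dir output directory (created if needed).
#' @param format `"mtx"` writes `rna/` and `adt/` triplet directories;
#'   `"tsv"` writes dense `rna.tsv` and `adt.tsv`.
#' @return The paths written, invisibly.
#' @export
write_citeseq <- function(ds, dir, format = c("mtx", "tsv")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (format == "mtx") {
    rp <- file.path(dir, "rna"); ap <- file.path(dir, "adt")
  } else {
    rp <- file.path(dir, "rna.tsv"); ap <- file.path(dir, "adt.tsv")
  }
  write_matrix_any(ds$rna, rp, format)
  write_matrix_any(ds$adt, ap, format)
  mp <- file.path(dir, "metadata.tsv")
  write_tsv(ds$meta, mp)
  invisible(c(rna = rp, adt = ap, metadata = mp))
}

#' Quality-control filtering of cells and genes
#'
#' Applies, in this order: (1) remove cells with fewer than `min_genes`
#' detected genes; (2) remove genes detected in fewer than `min_cells` of the
#' remaining cells; (3) remove cells whose mitochondrial fraction exceeds
#' `max_mito`. All thresholds follow the strict-inequality convention: a cell
#' with exactly `min_genes` detected genes is retained, a cell with a
#' mitochondrial fraction of exactly `max_mito` is retained. The order
#' matters — the gene filter sees only cells that survived step 1 — and is
#' fixed.
#'
#' @param ds a `citeseq` object holding raw counts.
#' @param min_genes minimum detected genes per cell (default 100).
#' @param min_cells minimum cells a gene must be detected in (default 5).
#' @param max_mito maximum mitochondrial count fraction (default 0.05).
#' @param mito_prefix gene-name prefix identifying mitochondrial genes.
#' @return Filtered `citeseq` object.
#' @export
qc_filter <- function(ds, min_genes = 100, min_cells = 5, max_mito = 0.05,
                      mito_prefix = "MT-") {
  if (ds$rna_layer != "counts")
    stop("qc_filter requires the raw-count layer, got ", ds$rna_layer)
  detected <- rowSums(ds$rna > 0)
  ds <- subset_cells(ds, detected >= min_genes)
  if (nrow(ds$rna) == 0) stop("all cells removed by the detected-gene filter")

  gene_cells <- colSums(ds$rna > 0)
  ds$rna <- ds$rna[, gene_cells >= min_cells, drop = FALSE]

  mito <- startsWith(colnames(ds$rna), mito_prefix)
  tot <- rowSums(ds$rna)
  frac <- if (any(mito)) rowSums(ds$rna[, mito, drop = FALSE]) / tot else rep(0, nrow(ds$rna))
  ds <- subset_cells(ds, frac <= max_mito)
  if (nrow(ds$rna) == 0) stop("all cells removed by the mitochondrial filter")
  ds
}

#' Log-normalize and z-transform the RNA matrix
#'
#' Per cell, counts are divided by the cell total, multiplied by
#' `scale_factor`, and `log1p`-transformed; each gene is then z-transformed
#' (mean 0, sd 1 across all cells). Genes with zero variance after log
#' normalization are set to all-zero and recorded in `ds$constant_genes`.
#'
#' @param ds a `citeseq` object with raw RNA counts.
#' @param scale_factor library-size scaling target (default 10000).
#' @param z apply the per-gene z-transform (default TRUE). With `z = FALSE`
#'   the layer stops at `"lognorm"`.
#' @param group_by optional metadata column name: z-transform within each
#'   level of that column instead of across the whole dataset.
#' @return The dataset with `rna_layer` set to `"lognorm.z"` (or `"lognorm"`).
#' @export
normalize_rna <- function(ds, scale_factor = 1e4, z = TRUE, group_by = NULL) {
  if (ds$rna_layer != "counts")
    stop("normalize_rna expects raw counts, got layer ", ds$rna_layer)
  tot <- rowSums(ds$rna)
  if (any(tot == 0)) stop("cell(s) with zero total counts: ",
                          paste(head(rownames(ds$rna)[tot == 0], 3), collapse = ", "))
  ln <- log1p(ds$rna / tot * scale_factor)
  if (!z) {
    ds$rna <- ln
    ds$rna_layer <- "lognorm"
    return(ds)
  }
  if (is.null(group_by)) {
    zm <- zscore_cols(ln)
    constant <- attr(zm, "constant")
  } else {
    g <- ds$meta[[group_by]]
    zm <- ln
    constant <- character(0)
    for (lev in unique(g)) {
      sub <- zscore_cols(ln[g == lev, , drop = FALSE])
      zm[g == lev, ] <- sub
      constant <- union(constant, attr(sub, "constant"))
    }
  }
  if (length(constant))
    warning(sprintf("%d constant gene(s) set to zero after normalization",
                    length(constant)))
  attr(zm, "constant") <- NULL
  ds$rna <- zm
  ds$constant_genes <- constant
  ds$rna_layer <- "lognorm.z"
  ds
}

#' Centered-log-ratio normalize and z-transform the ADT matrix
#'
#' ADT counts are compositional within a cell, so the default margin is the
#' cell: `clr_i = log(x_i + 1) - mean_j log(x_j + 1)` across the proteins of
#' that cell. The `+1` pseudocount handles zeros. Each protein is then
#' z-transformed across cells. A per-protein CLR margin is provided as an
#' alternative for panels where the compositional assumption is doubtful.
#'
#' @param ds a `citeseq` object with raw ADT counts.
#' @param z apply the per-protein z-transform (default TRUE); with
#'   `z = FALSE` the layer stops at `"clr"`, whose rows sum to zero.
#' @param margin `"cell"` (default) or `"protein"`.
#' @return The dataset with `adt_layer` set to `"clr.z"` (or `"clr"`).
#' @export
normalize_adt <- function(ds, z = TRUE, margin = c("cell", "protein")) {
  margin <- match.arg(margin)
  if (ds$adt_layer != "counts")
    stop("normalize_adt expects raw counts, got layer ", ds$adt_layer)
  lg <- log1p(ds$adt)
  clr <- if (margin == "cell") lg - rowMeans(lg) else sweep(lg, 2, colMeans(lg), "-")
  if (!z) {
    ds$adt <- clr
    ds$adt_layer <- "clr"
    return(ds)
  }
  ds$adt <- zscore_cols(clr)
  attr(ds$adt, "constant") <- NULL
  ds$adt_layer <- "clr.z"
  ds
}

#' Wilcoxon rank-sum differential test between two phenotype groups
#'
#' Two-sided rank-sum test per feature, with Benjamini-Hochberg adjustment
#' across the tested features. For small groups without ties the exact null
#' distribution is used; otherwise the normal approximation with tie
#' correction (the default behaviour of [stats::wilcox.test()]).
#'
#' @param ds a `citeseq` object (normalized layers recommended).
#' @param layer `"adt"` for surface proteins or `"rna"` for genes.
#' @param group_a,group_b phenotype labels (each may name several labels).
#' @param features feature names to test; default all in the layer.
#' @param level FDR threshold for the `significant` flag (default 0.05).
#' @return A `de_table` data.frame: feature, group means, difference of means
#'   (`lfc` on the normalized scale), W statistic, nominal p, BH-adjusted FDR,
#'   significance flag.
#' @export
wilcoxon_de <- function(ds, layer = c("adt", "rna"), group_a, group_b,
                        features = NULL, level = 0.05) {
  layer <- match.arg(layer)
  m <- if (layer == "adt") ds$adt else ds$rna
  features <- features %||% colnames(m)
  missing <- setdiff(features, colnames(m))
  if (length(missing)) stop("unknown feature(s): ", paste(missing, collapse = ", "))
  ia <- cells_in_groups(ds, group_a)
  ib <- cells_in_groups(ds, group_b)
  if (sum(ia) < 2 || sum(ib) < 2)
    stop("each group needs at least 2 cells")
  res <- lapply(features, function(f) {
    a <- m[ia, f]; b <- m[ib, f]
    wt <- suppressWarnings(stats::wilcox.test(a, b, alternative = "two.sided"))
    pv <- wt$p.value
    if (is.nan(pv)) pv <- 1   # every value tied: no rank separation
    data.frame(feature = f, mean_a = mean(a), mean_b = mean(b),
               lfc = mean(a) - mean(b), statistic = unname(wt$statistic),
               p = pv)
  })
  out <- do.call(rbind, res)
  out$fdr <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$fdr < level
  class(out) <- c("de_table", "data.frame")
  out
}
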