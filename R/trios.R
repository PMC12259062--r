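#' Load the intracellular-transport (ICT) gene list
#'
#' Reads a TSV with a `gene_symbol` column (or, failing that, its first
#' column) and returns the deduplicated set of symbols. The ICT list is an
#' input to the analysis — typically genes annotated to protein-trafficking
#' processes (ER-to-Golgi transport, vesicle-mediated transport,
#' endocytic/lysosomal routing) — curated upstream.
#'
#' @param path TSV file path.
#' @param case_normalize uppercase all symbols (default FALSE; matching is
#'   case-sensitive by default).
#' @return Character vector of unique gene symbols.
#' @export
load_ict_genes <- function(path, case_normalize = FALSE) {
  df <- read_tsv(path)
  if (nrow(df) == 0) stop("empty ICT gene list: ", path)
  col <- if ("gene_symbol" %in% names(df)) "gene_symbol" else names(df)[1]
  genes <- unique(as.character(df[[col]]))
  genes <- genes[nzchar(genes)]
  if (length(genes) == 0) stop("empty ICT gene list: ", path)
  if (case_normalize) genes <- unique(toupper(genes))
  message(sprintf("loaded %d unique ICT gene symbols", length(genes)))
  genes
}

#' Load the surface-protein to coding-gene map
#'
#' One row per (protein, subunit gene): multi-subunit proteins such as CD3
#' (CD3D/CD3G/CD3E), HLA-DR (HLA-DRA/DRB1/DRB5) and CD16
#' (FCGR1A/2A/3A/1B/2B/3B) map to several coding genes.
#'
#' @param path TSV with columns `protein` and `gene_symbol`.
#' @return Named list: protein name -> character vector of coding genes.
#' @export
load_protein_map <- function(path) {
  df <- read_tsv(path)
  stop_if_missing_cols(df, c("protein", "gene_symbol"), "protein map")
  split(as.character(df$gene_symbol), as.character(df$protein))
}

#' Expand measured proteins into (protein, coding gene) pairs
#'
#' Each measured protein contributes one pair per subunit coding gene. With
#' the standard 30-protein panel, where CD3, HLA-DR and CD16 carry 3, 3 and 6
#' subunit genes and the remaining 27 proteins one each, this yields 39 pairs.
#'
#' @param protein_map named list from [load_protein_map()].
#' @param measured_proteins proteins present in the ADT matrix.
#' @return data.frame with columns `m` (protein) and `g` (coding gene).
#' @export
build_pairs <- function(protein_map, measured_proteins) {
  unmapped <- setdiff(measured_proteins, names(protein_map))
  if (length(unmapped))
    stop("protein(s) missing from the map: ", paste(unmapped, collapse = ", "))
  rows <- lapply(measured_proteins, function(p) {
    genes <- unique(protein_map[[p]])
    data.frame(m = p, g = genes)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Build the trio catalog
#'
#' A trio is the unit of analysis: a surface protein `m`, one of its coding
#' genes `g`, and an ICT gene `t`. The catalog is the cartesian product of
#' the (m, g) pairs with the ICT genes measured in the RNA matrix, minus —
#' when `exclude_self` — trios whose ICT gene equals the coding gene (a gene
#' should not appear as its own transport regulator).
#'
#' @param pairs data.frame from [build_pairs()].
#' @param ict_genes character vector of ICT gene symbols.
#' @param rna_gene_names genes measured in the RNA matrix; ICT genes absent
#'   from it are dropped before the product. `NULL` skips the intersection.
#' @param exclude_self drop trios with `t == g` (default TRUE).
#' @return A `trio_catalog` data.frame with columns `m`, `g`, `t` and
#'   attributes recording the usable ICT genes.
#' @export
build_trios <- function(pairs, ict_genes, rna_gene_names = NULL,
                        exclude_self = TRUE) {
  usable <- unique(ict_genes)
  if (!is.null(rna_gene_names)) usable <- intersect(usable, rna_gene_names)
  grid <- expand.grid(pair = seq_len(nrow(pairs)), t = usable,
                      stringsAsFactors = FALSE)
  out <- data.frame(m = pairs$m[grid$pair], g = pairs$g[grid$pair], t = grid$t)
  if (exclude_self) out <- out[out$t != out$g, , drop = FALSE]
  out <- unique(out)
  rownames(out) <- NULL
  if (nrow(out) == 0) warning("empty trio catalog")
  attr(out, "n_ict_usable") <- length(usable)
  attr(out, "exclude_self") <- exclude_self
  class(out) <- c("trio_catalog", "data.frame")
  out
}

#' @export
print.trio_catalog <- function(x, ...) {
  cat(sprintf("trio catalog: %d trios (%d proteins, %d coding genes, %d ICT genes)\n",
              nrow(x), length(unique(x$m)), length(unique(x$g)),
              length(unique(x$t))))
  invisible(x)
}

#' Write a trio catalog as TSV
#' @param catalog a `trio_catalog`.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_trios <- function(catalog, path) {
  write_tsv(as.data.frame(catalog)[, c("m", "g", "t")], path)
}
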