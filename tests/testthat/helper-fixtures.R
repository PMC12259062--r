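# shared helpers for the test suite; all fixtures are built in code

# independent Benjamini-Hochberg step-up reference: O(n^2) literal
# implementation of adj_i = min(1, min_{j: p_j >= p_i} n * p_j / rank_j)
bh_reference <- function(p) {
  n <- length(p)
  r <- rank(p, ties.method = "first")
  vapply(seq_len(n), function(i) {
    cand <- n * p[r >= r[i]] / r[r >= r[i]]
    min(1, min(cand))
  }, 0)
}

# subset a citeseq dataset by cell index without touching internals elsewhere
subset_cells_for_test <- function(ds, idx) {
  ds$rna <- ds$rna[idx, , drop = FALSE]
  ds$adt <- ds$adt[idx, , drop = FALSE]
  ds$meta <- ds$meta[idx, , drop = FALSE]
  ds
}

# random mediation classification table for network tests
random_classification <- function(n, seed) {
  set.seed(seed)
  cls <- sample(c("full", "partial", "null", "dropped"), n, replace = TRUE)
  data.frame(t = sprintf("ICT%d", seq_len(n)),
             alpha = round(stats::rnorm(n), 3),
             delta = round(stats::rnorm(n), 3),
             class = cls)
}

# tiny deterministic count dataset with known QC edge cases:
#   cell2 has 99 detected genes (removed), cell3 exactly 100 (kept),
#   cell4 has a 7/120 mitochondrial fraction (removed), cell5 exactly
#   6/120 = 5% (kept); MT-ND1 stays detected in >= 5 surviving cells so the
#   gene filter does not interfere with the mitochondrial step
qc_edge_dataset <- function() {
  genes <- c(paste0("GENE", seq_len(118)), "MT-ND1", "MT-CO1")
  m <- matrix(0, nrow = 6, ncol = 120,
              dimnames = list(paste0("cell", 1:6), genes))
  m["cell1", ] <- 1; m["cell1", "MT-CO1"] <- 0          # 119 detected
  m["cell2", c(paste0("GENE", 1:98), "MT-ND1")] <- 1    # 99 detected
  m["cell3", c(paste0("GENE", 1:99), "MT-ND1")] <- 1    # exactly 100
  m["cell4", c(paste0("GENE", 1:99), "MT-ND1")] <- 1
  m["cell4", "GENE1"] <- 15; m["cell4", "MT-ND1"] <- 7  # 7/120 mito
  m["cell5", c(paste0("GENE", 1:99), "MT-ND1")] <- 1
  m["cell5", "GENE1"] <- 16; m["cell5", "MT-ND1"] <- 6  # 6/120 = 5% mito
  m["cell6", ] <- 1; m["cell6", "MT-CO1"] <- 0
  adt <- matrix(20, nrow = 6, ncol = 2,
                dimnames = list(rownames(m), c("CD3", "CD69")))
  meta <- data.frame(cell_id = rownames(m),
                     sample_id = rep(c("s1", "s2"), 3),
                     phenotype = rep("healthy", 6))
  citeseq_dataset(m, adt, meta)
}

# the standard 30-protein panel map: CD3, HLA-DR, CD16 multi-subunit,
# 27 singleton proteins
panel_30_map <- function() {
  multi <- list(
    "CD3" = c("CD3D", "CD3G", "CD3E"),
    "HLA-DR" = c("HLA-DRA", "HLA-DRB1", "HLA-DRB5"),
    "CD16" = c("FCGR1A", "FCGR2A", "FCGR3A", "FCGR1B", "FCGR2B", "FCGR3B"))
  singles <- paste0("CD", 100 + seq_len(27))
  c(multi, stats::setNames(as.list(paste0("G", seq_len(27))), singles))
}
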