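#' Configuration for the CITE-seq simulator
#'
#' Describes a synthetic multi-sample, multi-phenotype paired RNA/ADT
#' dataset with planted trio and mediation structure. The generative model
#' mirrors the modeling assumptions downstream: ICT-gene, coding-gene and
#' background transcription are standard normal per cell; each sample
#' carries a Gaussian random intercept `u_s` with sd `sigma_u`; protein
#' abundance is
#' `E = eta0 + eta1 * X_g + sum_t eta2[t] * X_t + u_s + eps`.
#'
#' Two outcome modes are supported. In `"binary_sample"` mode the phenotype
#' is assigned at the sample level (as in a real multi-donor study) and
#' effect sizes are realized as group shifts: `xt_shift` moves the mean of
#' selected ICT transcripts and `e_shift` the protein abundance in the case
#' group. In `"continuous_latent"` mode a per-cell outcome
#' `D = omega0 + sum_t delta[t] * X_t + beta * E + xi` is emitted alongside
#' the group labels; exact coefficient recovery by the mediation models is
#' only well-posed there.
#'
#' By default latent values are emitted directly (already on the normalized,
#' z-scored scale the models expect); `emission = "negative_binomial"` maps
#' them through `mu = exp(a + b * latent)` into overdispersed counts so that
#' the QC and normalization steps can be exercised.
#'
#' @param n_samples named integer vector: samples per phenotype group. The
#'   default mirrors a small multi-donor disease study (5 healthy, 3 mild,
#'   4 severe).
#' @param cells_per_sample mean cells per sample.
#' @param cell_dispersion 0 for exactly `cells_per_sample` cells; otherwise
#'   the negative-binomial dispersion of the per-sample cell count.
#' @param n_proteins,n_ict,n_background panel sizes.
#' @param eta0,eta1 intercept and coding-gene effect (recycled per protein).
#' @param eta2 matrix (proteins x ICT genes) of planted transport effects;
#'   a vector is treated as the first protein's row.
#' @param sigma_u,sigma_e random-intercept and residual sd of the protein
#'   equation.
#' @param outcome `"binary_sample"` or `"continuous_latent"`.
#' @param case_group group receiving the shifts in binary mode (default the
#'   last group).
#' @param xt_shift length-`n_ict` mean shift of ICT transcripts in the case
#'   group (binary mode).
#' @param e_shift protein-abundance shift in the case group (binary mode,
#'   recycled per protein).
#' @param omega0,delta,beta,sigma_xi outcome-equation parameters
#'   (continuous mode; `delta` has length `n_ict`, `beta` applies to the
#'   first protein).
#' @param emission `"gaussian"` (latent values as-is) or
#'   `"negative_binomial"` (counts).
#' @param nb_dispersion NB dispersion of the count emission (default 0.5).
#' @param seed integer seed fixing the full output.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_samples = c(healthy = 5, mild = 3, severe = 4),
                       cells_per_sample = 100, cell_dispersion = 0,
                       n_proteins = 1, n_ict = 10, n_background = 20,
                       eta0 = 0, eta1 = 0.5, eta2 = NULL,
                       sigma_u = 0.5, sigma_e = 1,
                       outcome = c("binary_sample", "continuous_latent"),
                       case_group = NULL, xt_shift = 0, e_shift = 0,
                       omega0 = 0, delta = 0, beta = 0, sigma_xi = 1,
                       emission = c("gaussian", "negative_binomial"),
                       nb_dispersion = 0.5, seed = 1) {
  outcome <- match.arg(outcome)
  emission <- match.arg(emission)
  if (is.null(names(n_samples)))
    names(n_samples) <- paste0("group", seq_along(n_samples))
  stopifnot(all(n_samples >= 1), cells_per_sample >= 1,
            sigma_u >= 0, sigma_e >= 0, sigma_xi >= 0, nb_dispersion > 0)
  e2 <- matrix(0, n_proteins, n_ict)
  if (!is.null(eta2)) {
    if (is.matrix(eta2)) e2[] <- eta2 else e2[1, seq_along(eta2)] <- eta2
  }
  structure(list(
    n_samples = n_samples, cells_per_sample = cells_per_sample,
    cell_dispersion = cell_dispersion, n_proteins = n_proteins,
    n_ict = n_ict, n_background = n_background,
    eta0 = rep_len(eta0, n_proteins), eta1 = rep_len(eta1, n_proteins),
    eta2 = e2, sigma_u = sigma_u, sigma_e = sigma_e,
    outcome = outcome,
    case_group = case_group %||% names(n_samples)[length(n_samples)],
    xt_shift = rep_len(xt_shift, n_ict),
    e_shift = rep_len(e_shift, n_proteins),
    omega0 = omega0, delta = rep_len(delta, n_ict), beta = beta,
    sigma_xi = sigma_xi, emission = emission,
    nb_dispersion = nb_dispersion, seed = seed), class = "sim_config")
}

#' Simulate a paired RNA/ADT dataset with planted structure
#'
#' Draws a dataset from a [sim_config()]; the same seed reproduces the same
#' output exactly. Ground truth — planted coefficients, per-sample random
#' intercepts, the latent outcome, and the mediation class each ICT gene's
#' planted effects imply — is returned alongside the data.
#'
#' @param config a [sim_config()].
#' @return List with elements `dataset` (a [citeseq_dataset()]) and `truth`
#'   (a `ground_truth` list).
#' @examples
#' sim <- simulate_citeseq(sim_config(n_samples = c(healthy = 2, severe = 2),
#'                                    cells_per_sample = 30, seed = 7))
#' sim$dataset
#' @export
simulate_citeseq <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cf <- config
  set.seed(cf$seed)

  groups <- rep(names(cf$n_samples), cf$n_samples)
  sample_ids <- paste0("s", seq_along(groups))
  ncell_s <- if (cf$cell_dispersion > 0)
    pmax(1L, stats::rnbinom(length(sample_ids), mu = cf$cells_per_sample,
                            size = 1 / cf$cell_dispersion))
  else rep(cf$cells_per_sample, length(sample_ids))
  if (sum(ncell_s) == 0) stop("infeasible config: 0 cells")

  cell_sample <- rep(sample_ids, ncell_s)
  cell_group <- rep(groups, ncell_s)
  n <- length(cell_sample)
  cell_ids <- paste0("c", seq_len(n))
  is_case <- cell_group == cf$case_group

  genes_g <- paste0("G", seq_len(cf$n_proteins))
  genes_t <- paste0("ICT", seq_len(cf$n_ict))
  genes_b <- if (cf$n_background > 0) paste0("BG", seq_len(cf$n_background)) else character(0)
  proteins <- paste0("P", seq_len(cf$n_proteins))

  X <- matrix(stats::rnorm(n * (cf$n_proteins + cf$n_ict + length(genes_b))),
              nrow = n, dimnames = list(cell_ids, c(genes_g, genes_t, genes_b)))
  if (cf$outcome == "binary_sample" && any(cf$xt_shift != 0))
    X[is_case, genes_t] <- sweep(X[is_case, genes_t, drop = FALSE], 2,
                                 cf$xt_shift, "+")

  u <- matrix(stats::rnorm(length(sample_ids) * cf$n_proteins, 0, cf$sigma_u),
              nrow = length(sample_ids),
              dimnames = list(sample_ids, proteins))
  E <- matrix(0, n, cf$n_proteins, dimnames = list(cell_ids, proteins))
  for (p in seq_len(cf$n_proteins)) {
    E[, p] <- cf$eta0[p] + cf$eta1[p] * X[, genes_g[p]] +
      drop(X[, genes_t, drop = FALSE] %*% cf$eta2[p, ]) +
      u[cell_sample, p] + stats::rnorm(n, 0, cf$sigma_e)
    if (cf$outcome == "binary_sample" && cf$e_shift[p] != 0)
      E[is_case, p] <- E[is_case, p] + cf$e_shift[p]
  }

  meta <- data.frame(cell_id = cell_ids, sample_id = cell_sample,
                     phenotype = cell_group)
  D_latent <- NULL
  if (cf$outcome == "continuous_latent") {
    D_latent <- cf$omega0 + drop(X[, genes_t, drop = FALSE] %*% cf$delta) +
      cf$beta * E[, 1] + stats::rnorm(n, 0, cf$sigma_xi)
    meta$D_latent <- D_latent
  }

  if (cf$emission == "negative_binomial") {
    rna <- matrix(stats::rnbinom(length(X), mu = exp(1 + 0.7 * X),
                                 size = 1 / cf$nb_dispersion),
                  nrow = n, dimnames = dimnames(X))
    adt <- matrix(stats::rnbinom(length(E), mu = exp(3 + 0.7 * E),
                                 size = 1 / cf$nb_dispersion),
                  nrow = n, dimnames = dimnames(E))
    ds <- citeseq_dataset(rna, adt, meta)
  } else {
    ds <- citeseq_dataset(X, E, meta,
                          rna_layer = "lognorm.z", adt_layer = "clr.z")
  }

  indirect <- cf$eta2[1, ] * cf$beta
  implied <- ifelse(indirect != 0 & cf$delta == 0, "full",
                    ifelse(indirect != 0 & cf$delta != 0, "partial",
                           ifelse(indirect == 0 & cf$delta != 0, "null",
                                  "dropped")))
  truth <- structure(list(
    config = cf, proteins = proteins, coding_genes = genes_g,
    ict_genes = genes_t, background_genes = genes_b,
    protein_map = stats::setNames(as.list(genes_g), proteins),
    u = u, D_latent = D_latent,
    implied_class = stats::setNames(implied, genes_t),
    true_support = genes_t[cf$eta2[1, ] != 0 | cf$delta != 0]),
    class = "ground_truth")
  list(dataset = ds, truth = truth)
}

#' Write simulation ground truth to disk
#'
#' YAML for the configuration and planted coefficients, TSV for per-cell
#' latent values.
#'
#' @param truth a `ground_truth` object.
#' @param dir output directory.
#' @return Paths written, invisibly.
#' @export
write_ground_truth <- function(truth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cf <- truth$config
  ypath <- file.path(dir, "ground_truth.yaml")
  yaml::write_yaml(list(
    config = lapply(unclass(cf), function(x) if (is.matrix(x)) as.vector(t(x)) else x),
    proteins = truth$proteins, coding_genes = truth$coding_genes,
    ict_genes = truth$ict_genes,
    implied_class = as.list(truth$implied_class),
    true_support = truth$true_support,
    sample_intercepts = as.list(stats::setNames(truth$u[, 1], rownames(truth$u)))),
    ypath)
  paths <- ypath
  if (!is.null(truth$D_latent)) {
    tpath <- file.path(dir, "latent_outcome.tsv")
    write_tsv(data.frame(cell = seq_along(truth$D_latent),
                         D_latent = truth$D_latent), tpath)
    paths <- c(paths, tpath)
  }
  invisible(paths)
}

#' Named simulation fixtures used across the test suite
#'
#' A small registry of deterministic datasets:
#' \describe{
#'   \item{`"tiny-null"`}{4 samples (2 healthy, 2 severe) x 50 cells, no
#'     planted effects.}
#'   \item{`"one-strong-trio"`}{6 healthy + 2 severe samples x 100 cells,
#'     exactly one trio planted with `eta2 = 1` (ICT1 -> P1), coding-gene
#'     effect 0.5, sample-intercept sd 0.5.}
#'   \item{`"sparse-mediation-20"`}{continuous-outcome design, 10 samples x
#'     200 cells (n = 2000), 20 ICT exposures of which 3 are active
#'     (`alpha = delta = 0.4`, `beta = 0.5`).}
#' }
#'
#' @param name fixture name.
#' @param seed optional seed overriding the registry default (1).
#' @return As [simulate_citeseq()]: list with `dataset` and `truth`.
#' @export
make_fixture <- function(name = c("tiny-null", "one-strong-trio",
                                  "sparse-mediation-20"), seed = NULL) {
  name <- match.arg(name)
  cf <- switch(name,
    "tiny-null" = sim_config(
      n_samples = c(healthy = 2, severe = 2), cells_per_sample = 50,
      n_ict = 5, n_background = 10, eta1 = 0.5, sigma_u = 0.3, seed = 1),
    "one-strong-trio" = sim_config(
      n_samples = c(healthy = 6, severe = 2), cells_per_sample = 100,
      n_ict = 10, n_background = 10, eta1 = 0.5, eta2 = c(1, rep(0, 9)),
      sigma_u = 0.5, seed = 1),
    "sparse-mediation-20" = sim_config(
      n_samples = c(all = 10), cells_per_sample = 200,
      n_ict = 20, n_background = 5, eta1 = 0.5,
      eta2 = c(rep(0.4, 3), rep(0, 17)),
      sigma_u = 0.2, outcome = "continuous_latent",
      delta = c(rep(0.4, 3), rep(0, 17)), beta = 0.5, seed = 1))
  if (!is.null(seed)) cf$seed <- seed
  simulate_citeseq(cf)
}
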