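#' Build and validate a workflow configuration
#'
#' Collects everything one end-to-end run needs: input paths (or a fixture
#' name to simulate instead), the phenotype groups and the case/reference
#' contrast, the thresholds, the lambda grid, and a seed. Thresholds are
#' validated eagerly so a bad value fails before any fitting starts.
#'
#' @param rna_path,adt_path,metadata_path,ict_path,protein_map_path input
#'   files for [load_citeseq()], [load_ict_genes()], [load_protein_map()].
#'   Ignored when `fixture` is set.
#' @param fixture optional [make_fixture()] name; simulates the inputs.
#' @param groups phenotype labels to analyze separately in the trio scan
#'   (`NULL` = all labels present).
#' @param case,ref contrast labels for the mediation modules.
#' @param protein protein for the multi-exposure model (`NULL` = the protein
#'   with most PTTs).
#' @param fdr PTT FDR threshold (default 0.05).
#' @param mediation_level mediation significance level (default 0.05).
#' @param eta2_threshold strong-effect cutoff for Module III exposures
#'   (default 0.1).
#' @param lambda grid for [medlasso_path()] (default [lambda_grid()]).
#' @param covariates optional covariate column names for the trio model.
#' @param normalize run QC + normalization (set FALSE when the inputs are
#'   already normalized, e.g. gaussian-emission simulations).
#' @param seed integer seed.
#' @return A validated `run_config` list.
#' @export
run_config <- function(rna_path = NULL, adt_path = NULL, metadata_path = NULL,
                       ict_path = NULL, protein_map_path = NULL,
                       fixture = NULL, groups = NULL, case = NULL, ref = NULL,
                       protein = NULL, fdr = 0.05, mediation_level = 0.05,
                       eta2_threshold = 0.1, lambda = lambda_grid(),
                       covariates = NULL, normalize = is.null(fixture),
                       seed = 1) {
  for (nm in c("fdr", "mediation_level")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || v <= 0 || v >= 1)
      stop(sprintf("invalid %s: must be a number in (0, 1), got %s",
                   nm, format(v)), call. = FALSE)
  }
  if (any(lambda < 0)) stop("invalid lambda: grid values must be >= 0")
  if (is.null(fixture)) {
    paths <- c(rna_path = rna_path, adt_path = adt_path,
               metadata_path = metadata_path, ict_path = ict_path,
               protein_map_path = protein_map_path)
    missing <- paths[!file.exists(paths)]
    if (length(missing))
      stop("missing input file(s): ", paste(missing, collapse = ", "))
  }
  structure(list(rna_path = rna_path, adt_path = adt_path,
                 metadata_path = metadata_path, ict_path = ict_path,
                 protein_map_path = protein_map_path, fixture = fixture,
                 groups = groups, case = case, ref = ref, protein = protein,
                 fdr = fdr, mediation_level = mediation_level,
                 eta2_threshold = eta2_threshold, lambda = sort(lambda),
                 covariates = covariates, normalize = normalize, seed = seed),
            class = "run_config")
}

#' Read a workflow configuration from YAML
#'
#' @param path YAML file whose keys match the arguments of [run_config()].
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  do.call(run_config, vals)
}

#' Run the four-module workflow end to end
#'
#' Loads (or simulates) the paired dataset, applies QC and normalization
#' when asked, builds the trio catalog, scans trios per phenotype group,
#' runs the single-exposure mediation scan on the pooled PTTs for the
#' configured contrast, fits the multi-exposure lambda path for the chosen
#' protein, and builds the regulatory network. Every table is written as
#' TSV under `output_dir`, the network as GraphML and edge list, and a JSON
#' run manifest records the package version, the configuration, its file
#' hash, the seed, and the row counts of every output. Reruns with the same
#' configuration and seed produce identical files.
#'
#' @param config a `run_config` (or path to a YAML file).
#' @param output_dir directory for outputs (created if needed).
#' @return Invisibly, a list with the in-memory results and the manifest.
#' @export
run_workflow <- function(config, output_dir) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)

  if (!is.null(config$fixture)) {
    sim <- make_fixture(config$fixture, seed = config$seed)
    ds <- sim$dataset
    ict <- sim$truth$ict_genes
    pmap <- sim$truth$protein_map
  } else {
    ds <- load_citeseq(config$rna_path, config$adt_path, config$metadata_path)
    ict <- load_ict_genes(config$ict_path)
    pmap <- load_protein_map(config$protein_map_path)
  }
  if (config$normalize) {
    ds <- qc_filter(ds)
    ds <- normalize_rna(ds)
    ds <- normalize_adt(ds)
  }

  pairs <- build_pairs(pmap, intersect(colnames(ds$adt), names(pmap)))
  catalog <- build_trios(pairs, ict, colnames(ds$rna))
  write_trios(catalog, file.path(output_dir, "trios.tsv"))

  groups <- config$groups %||% unique(ds$meta$phenotype)
  ptt <- lapply(groups, function(g)
    scan_trios(ds, catalog, group = g, covariates = config$covariates,
               level = config$fdr))
  names(ptt) <- groups
  for (g in groups)
    write_ptt(ptt[[g]], file.path(output_dir, paste0("ptt_", g, ".tsv")))
  pooled <- do.call(rbind, lapply(ptt, as.data.frame))
  class(pooled) <- c("ptt_table", "data.frame")

  case <- config$case %||% groups[length(groups)]
  ref <- config$ref %||% groups[1]
  med2 <- scan_mediation(ds, pooled, case = case, ref = ref,
                         level = config$mediation_level)
  write_mediation(med2, file.path(output_dir, "mediation_single.tsv"))

  results <- list(dataset = ds, catalog = catalog, ptt = ptt,
                  mediation = med2)
  protein <- config$protein
  if (is.null(protein) && any(pooled$is_ptt)) {
    tab <- table(pooled$m[pooled$is_ptt])
    protein <- names(tab)[which.max(tab)]
  }
  if (!is.null(protein)) {
    exposures <- tryCatch(
      filter_strong_effects(pooled, protein, config$eta2_threshold),
      error = function(e) character(0))
    if (length(exposures) >= 1) {
      path <- fit_multi_mediation(ds, protein, exposures, case = case,
                                  ref = ref, lambda = config$lambda)
      write_tsv(data.frame(lambda = path$grid, bic = path$bic, k = path$nnz),
                file.path(output_dir, "lambda_path.tsv"))
      write_tsv(path$classification,
                file.path(output_dir, "mediation_multi.tsv"))
      g_stats <- list(gene = pairs$g[match(protein, pairs$m)],
                      eta1 = mean(pooled$eta1[pooled$m == protein],
                                  na.rm = TRUE),
                      significant = any(pooled$p1[pooled$m == protein] < 0.05,
                                        na.rm = TRUE))
      net <- build_network(protein, path$classification,
                           beta = path$fit$beta, coding_gene_stats = g_stats,
                           contrast = paste(case, "vs", ref))
      export_network(net, file.path(output_dir, "network.graphml"), "graphml")
      export_network(net, file.path(output_dir, "network_edges.tsv"), "edgelist")
      results$multi <- path
      results$network <- net
    }
  }

  cfg_path <- file.path(output_dir, "config.yaml")
  yaml::write_yaml(lapply(unclass(config), function(x) x), cfg_path)
  outputs <- setdiff(list.files(output_dir), "manifest.json")
  manifest <- list(
    package = "surfmed",
    version = as.character(utils::packageVersion("surfmed")),
    seed = config$seed,
    config_hash = unname(tools::md5sum(cfg_path)),
    n_cells = nrow(ds$rna), n_trios = nrow(catalog),
    n_ptt = vapply(ptt, function(t) sum(t$is_ptt), 0L),
    n_daICT = sum(med2$daICT),
    outputs = outputs)
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  results$manifest <- manifest
  invisible(results)
}
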