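#' Pipeline parameters with defaults
#'
#' One bag of knobs for the full per-phenotype run. All thresholds echo
#' into the run manifest.
#'
#' @param network_top_k Edges retained per ranked network.
#' @param community_top_k Strongest edges used for community detection.
#' @param cutoffs Cis-curve cutoff grid (default
#'   [default_cutoff_grid()] on the retained edges).
#' @param mi_bins MI discretization override (default `round(sqrt(n))`).
#' @param n_permutations,pairs_per_permutation Pooled permutation null
#'   size.
#' @param community_method Score ranking used for communities
#'   (`"spearman"` or `"mi"`).
#' @param resolutions Louvain resolution sweep.
#' @param jaccard_threshold,min_persistence Persistence filtering.
#' @param enrich_padj Enrichment call threshold (adjusted p).
#' @param classify_padj DE classification threshold (adjusted p).
#' @param biotype_top_k Edges counted for biotype-pair fractions.
#' @param seed Master seed for every stochastic stage.
#' @return Named list of parameters.
#' @export
pipeline_params <- function(network_top_k = 20000L,
                            community_top_k = 10000L,
                            cutoffs = NULL,
                            mi_bins = NULL,
                            n_permutations = 20L,
                            pairs_per_permutation = 5000L,
                            community_method = c("spearman", "mi"),
                            resolutions = default_resolutions(),
                            jaccard_threshold = 0.75,
                            min_persistence = 5L,
                            enrich_padj = 1e-10,
                            classify_padj = 0.05,
                            biotype_top_k = 5000L,
                            seed = 1L) {
  list(network_top_k = network_top_k, community_top_k = community_top_k,
       cutoffs = cutoffs, mi_bins = mi_bins,
       n_permutations = n_permutations,
       pairs_per_permutation = pairs_per_permutation,
       community_method = match.arg(community_method),
       resolutions = resolutions,
       jaccard_threshold = jaccard_threshold,
       min_persistence = min_persistence,
       enrich_padj = enrich_padj, classify_padj = classify_padj,
       biotype_top_k = biotype_top_k, seed = seed)
}

build_networks <- function(em, params, label) {
  n <- ncol(em$values)
  sp <- spearman_matrix(em)
  null_sp <- permutation_null(em, "spearman",
                              n_permutations = params$n_permutations,
                              pairs_per_permutation = params$pairs_per_permutation,
                              seed = params$seed)
  edges_sp <- rank_edges(sp, null = null_sp, top_k = params$network_top_k)
  mi <- mutual_information_matrix(em, n_bins = params$mi_bins)
  null_mi <- permutation_null(em, "mi",
                              n_permutations = params$n_permutations,
                              pairs_per_permutation = params$pairs_per_permutation,
                              n_bins = params$mi_bins, seed = params$seed)
  edges_mi <- rank_edges(mi, null = null_mi, top_k = params$network_top_k)
  list(spearman = edges_sp, mi = edges_mi, label = label)
}

topk_jaccard <- function(edges_a, edges_b, k) {
  key <- function(d, k) {
    top <- d[order(d$rank)[seq_len(min(k, nrow(d)))], ]
    paste(top$gene_a, top$gene_b, sep = "\r")
  }
  a <- key(edges_a, k); b <- key(edges_b, k)
  length(intersect(a, b)) / length(union(a, b))
}

#' Run the full analysis for one cancer phenotype against control
#'
#' Mirrors the study design: the cancer cohort is pre-processed jointly
#' with the control cohort, networks are then inferred separately for the
#' cancer and the control samples, and topology, community, differential
#' expression and enrichment stages follow.
#'
#' @param cancer,control Raw-count `expression_matrix` objects.
#' @param annotation Annotation table.
#' @param gene_sets Optional `gene_set_collection` for enrichment.
#' @param params [pipeline_params()].
#' @param out_dir Optional directory; when given every artifact is
#'   written there along with a JSON run manifest.
#' @param phenotype Label for the cancer cohort.
#' @return A bundle list: normalized matrices, edge lists (MI and
#'   Spearman, cancer and control), cis profiles and their KS comparison,
#'   biotype tables, component spectra, community hierarchy, DE table,
#'   enrichment and trend tables, method-agreement Jaccard, manifest.
#' @export
run_phenotype <- function(cancer, control, annotation, gene_sets = NULL,
                          params = pipeline_params(), out_dir = NULL,
                          phenotype = "cancer") {
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", what, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  joint <- stage("preprocess", {
    em <- expression_matrix(cbind(cancer$values, control$values),
                            phenotype = c(stats::setNames(cancer$phenotype, cancer$sample_ids),
                                          stats::setNames(control$phenotype, control$sample_ids)))
    preprocess_counts(em, annotation)
  })
  canc_samples <- joint$matrix$sample_ids[
    joint$matrix$phenotype %in% unique(cancer$phenotype)]
  ctrl_samples <- setdiff(joint$matrix$sample_ids, canc_samples)
  norm_cancer <- subset_expression(joint$matrix, samples = canc_samples)
  norm_control <- subset_expression(joint$matrix, samples = ctrl_samples)

  nets_cancer <- stage("networks_cancer",
                       build_networks(norm_cancer, params, phenotype))
  nets_control <- stage("networks_control",
                        build_networks(norm_control, params, "control"))
  method_agreement <- topk_jaccard(nets_cancer$spearman, nets_cancer$mi,
                                   params$community_top_k)

  cutoffs <- params$cutoffs
  if (is.null(cutoffs))
    cutoffs <- default_cutoff_grid(min(nrow(nets_cancer$spearman),
                                       nrow(nets_control$spearman)),
                                   from = 1000)
  topo <- stage("topology", {
    primary <- params$community_method
    list(
      cis_cancer = cis_fraction_curve(nets_cancer[[primary]], annotation,
                                      cutoffs, network_id = phenotype),
      cis_control = cis_fraction_curve(nets_control[[primary]], annotation,
                                       cutoffs, network_id = "control"),
      biotype_cancer = biotype_pair_fractions(nets_cancer[[primary]],
                                              annotation,
                                              params$biotype_top_k),
      biotype_control = biotype_pair_fractions(nets_control[[primary]],
                                               annotation,
                                               params$biotype_top_k),
      components_cancer = component_spectrum(nets_cancer[[primary]],
                                             params$community_top_k,
                                             annotation),
      components_control = component_spectrum(nets_control[[primary]],
                                              params$community_top_k,
                                              annotation))
  })
  ks <- ks_compare(topo$cis_cancer, topo$cis_control)

  hierarchy <- stage("communities", {
    edges <- nets_cancer[[params$community_method]]
    top <- edges[order(edges$rank)[
      seq_len(min(params$community_top_k, nrow(edges)))], ]
    persistence_filter(
      resolution_sweep(top, params$resolutions, seed = params$seed),
      jaccard_threshold = params$jaccard_threshold,
      min_persistence = params$min_persistence)
  })

  de <- stage("differential_expression", {
    nb_wald_de(subset_expression(joint$counts, samples = canc_samples),
               subset_expression(joint$counts, samples = ctrl_samples),
               classify_padj = params$classify_padj)
  })

  enrichment <- NULL
  trends <- NULL
  if (!is.null(gene_sets) && length(hierarchy$communities)) {
    enrichment <- stage("enrichment",
                        hypergeom_enrich(hierarchy, gene_sets,
                                         universe = joint$matrix$gene_ids,
                                         padj_threshold = params$enrich_padj))
    trends <- stage("trends", community_trends(hierarchy, de))
  }

  bundle <- list(
    phenotype = phenotype,
    normalized = joint$matrix, counts = joint$counts,
    report = joint$report,
    networks_cancer = nets_cancer, networks_control = nets_control,
    method_agreement_jaccard = method_agreement,
    topology = topo, ks = ks,
    communities = hierarchy,
    de = de, enrichment = enrichment, trends = trends,
    params = params)
  if (!is.null(out_dir)) bundle$manifest <- write_bundle(bundle, out_dir)
  bundle
}

write_tsv_plain <- function(df, path, digits = 10) {
  num <- vapply(df, is.numeric, logical(1))
  for (col in names(df)[num]) {
    v <- df[[col]]
    if (!is.integer(v)) df[[col]] <- sprintf(paste0("%.", digits, "g"), v)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a phenotype bundle to disk with a run manifest
#'
#' @param bundle Result of [run_phenotype()].
#' @param out_dir Output directory (created if needed).
#' @return The manifest list, invisibly written as `manifest.json`.
#' @export
write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  put <- function(name, writer) {
    p <- file.path(out_dir, name)
    writer(p)
    paths[[length(paths) + 1]] <<- p
    p
  }
  put("edges_cancer_spearman.tsv",
      function(p) write_edge_list(bundle$networks_cancer$spearman, p))
  put("edges_cancer_mi.tsv",
      function(p) write_edge_list(bundle$networks_cancer$mi, p))
  put("edges_control_spearman.tsv",
      function(p) write_edge_list(bundle$networks_control$spearman, p))
  put("edges_control_mi.tsv",
      function(p) write_edge_list(bundle$networks_control$mi, p))
  put("cis_profile_cancer.tsv",
      function(p) write_tsv_plain(as.data.frame(bundle$topology$cis_cancer), p))
  put("cis_profile_control.tsv",
      function(p) write_tsv_plain(as.data.frame(bundle$topology$cis_control), p))
  put("biotype_fractions_cancer.tsv",
      function(p) write_tsv_plain(bundle$topology$biotype_cancer, p))
  put("biotype_fractions_control.tsv",
      function(p) write_tsv_plain(bundle$topology$biotype_control, p))
  put("components_cancer.tsv",
      function(p) write_tsv_plain(bundle$topology$components_cancer$components, p))
  put("de_table.tsv", function(p) write_tsv_plain(bundle$de, p))
  comm_paths <- write_community_tables(bundle$communities, out_dir)
  paths <- c(paths, comm_paths)
  if (!is.null(bundle$enrichment))
    put("enrichment.tsv", function(p) write_tsv_plain(bundle$enrichment, p))
  if (!is.null(bundle$trends))
    put("trends.tsv", function(p) write_tsv_plain(bundle$trends, p))
  paths <- unlist(paths)
  checksums <- tools::md5sum(paths)
  names(checksums) <- basename(names(checksums))
  manifest <- list(
    schema_version = "1.0",
    package_version = as.character(utils::packageVersion("hemonet")),
    phenotype = bundle$phenotype,
    parameters = bundle$params[setdiff(names(bundle$params), "resolutions")],
    resolutions = unname(bundle$params$resolutions),
    ks = bundle$ks[c("statistic", "p_value")],
    method_agreement_jaccard = bundle$method_agreement_jaccard,
    n_communities = length(bundle$communities$communities),
    filter_report = bundle$report$genes_removed_by_rule,
    size_factors = as.list(bundle$report$size_factors),
    checksums = as.list(checksums))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Cross-phenotype comparison
#'
#' Intersects the strongest cancer edges across phenotypes, detects
#' persistent communities on the intersection network, collects the KS
#' comparison of every cancer cis-profile against its control, and builds
#' the shared-biological-process trend matrix.
#'
#' @param bundles Named list (phenotype -> [run_phenotype()] bundle), at
#'   least 2.
#' @param gene_sets Optional `gene_set_collection`.
#' @param top_k Edges per network entering the intersection.
#' @param params [pipeline_params()].
#' @return List with `intersection` (edges + nodes),
#'   `intersection_communities`, `ks_tests`, `shared_trends`,
#'   `enrichment` (on intersection communities, when gene sets given).
#' @export
run_comparison <- function(bundles, gene_sets = NULL, top_k = 100000L,
                           params = pipeline_params()) {
  if (length(bundles) < 2) stop("need at least 2 phenotype bundles")
  phenos <- names(bundles)
  universes <- lapply(bundles, function(b) sort(b$normalized$gene_ids))
  if (length(unique(vapply(universes, paste, character(1), collapse = ","))) > 1) {
    all_u <- Reduce(union, universes)
    common <- Reduce(intersect, universes)
    stop("gene universes differ across phenotypes; symmetric difference: ",
         paste(utils::head(setdiff(all_u, common), 10), collapse = ", "))
  }
  edge_lists <- lapply(bundles, function(b)
    b$networks_cancer[[params$community_method]])
  inter <- intersect_networks(edge_lists, top_k = top_k)
  comm <- NULL
  enr <- NULL
  if (nrow(inter$edges)) {
    comm <- persistence_filter(
      resolution_sweep(inter$edges, params$resolutions, seed = params$seed),
      jaccard_threshold = params$jaccard_threshold,
      min_persistence = params$min_persistence)
    if (!is.null(gene_sets) && length(comm$communities))
      enr <- hypergeom_enrich(comm, gene_sets,
                              universe = universes[[1]],
                              padj_threshold = params$enrich_padj)
  }
  ks_tests <- lapply(bundles, `[[`, "ks")
  shared <- NULL
  if (all(vapply(bundles, function(b) !is.null(b$enrichment), logical(1)))) {
    shared <- shared_bp_matrix(
      lapply(bundles, `[[`, "enrichment"),
      lapply(bundles, `[[`, "communities"),
      lapply(bundles, `[[`, "de"))
  }
  list(intersection = inter, intersection_communities = comm,
       enrichment = enr, ks_tests = ks_tests, shared_trends = shared)
}

#' Build a gene-set collection from planted study truth
#'
#' One set per planted module (the ground-truth "processes") plus a
#' number of random decoy sets drawn from the annotation, so enrichment
#' has both true and null targets.
#'
#' @param study A [generate_study()] result.
#' @param n_random Number of decoy sets.
#' @param random_size Genes per decoy set.
#' @param seed Integer seed.
#' @return A `gene_set_collection`.
#' @export
truth_gene_sets <- function(study, n_random = 20L, random_size = 50L,
                            seed = 1L) {
  mods <- c(study$modules_control, study$modules_cancer)
  sets <- stats::setNames(lapply(mods, `[[`, "member_genes"),
                          paste0("MODULE_", vapply(mods, `[[`, character(1),
                                                   "module_id")))
  decoys <- withr::with_seed(seed, {
    lapply(seq_len(n_random), function(i)
      sort(sample(study$annotation$gene_id, random_size)))
  })
  names(decoys) <- sprintf("RANDOM_%02d", seq_len(n_random))
  all <- c(sets, decoys)
  structure(all,
            descriptions = stats::setNames(
              c(rep("planted co-expression module", length(sets)),
                rep("random decoy set", length(decoys))), names(all)),
            class = "gene_set_collection")
}

#' One-command synthetic end-to-end demo
#'
#' Generates the default synthetic study (paired cancer/control cohorts
#' with planted cis modules and a pseudogene cluster), runs the full
#' per-phenotype pipeline and returns the bundle together with the
#' ground truth.
#'
#' @param out_dir Optional output directory for all artifacts.
#' @param seed Master seed.
#' @param n_genes,n_samples Cohort scale.
#' @param params [pipeline_params()] (its seed is overridden by `seed`).
#' @param ... Further arguments to [generate_study()].
#' @return List with `study`, `gene_sets`, `bundle`.
#' @export
run_demo <- function(out_dir = NULL, seed = 1L, n_genes = 2000L,
                     n_samples = 100L, params = pipeline_params(), ...) {
  params$seed <- seed
  study <- generate_study(n_genes = n_genes, n_samples = n_samples,
                          seed = seed, ...)
  gene_sets <- truth_gene_sets(study, seed = seed + 10L)
  bundle <- run_phenotype(study$cancer$matrix, study$control$matrix,
                          study$annotation, gene_sets = gene_sets,
                          params = params, out_dir = out_dir)
  if (!is.null(out_dir)) {
    write_truth(study$cancer$truth, file.path(out_dir, "truth_cancer"))
    write_truth(study$control$truth, file.path(out_dir, "truth_control"))
    write_gmt(gene_sets, file.path(out_dir, "gene_sets.gmt"))
  }
  list(study = study, gene_sets = gene_sets, bundle = bundle)
}

#' Load a pipeline configuration from YAML
#'
#' Expected fields: `annotation` (TSV path), `control` (counts TSV),
#' `cohorts` (named map phenotype -> counts TSV), optional `gene_sets`
#' (GMT path), optional `params` (any [pipeline_params()] field),
#' optional `out_dir`.
#'
#' @param path YAML file path.
#' @return Config list with paths validated.
#' @export
load_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (f in c("annotation", "control"))
    if (is.null(cfg[[f]])) stop("config lacks required field: ", f)
  if (is.null(cfg$cohorts) || !length(cfg$cohorts))
    stop("config lacks cancer cohorts")
  paths <- c(cfg$annotation, cfg$control, unlist(cfg$cohorts), cfg$gene_sets)
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("config references missing file(s): ",
         paste(missing, collapse = ", "))
  cfg
}

#' Run the full study from a YAML configuration
#'
#' Pairs every cancer cohort with the control cohort (joint
#' normalization per pairing), runs each phenotype and, when two or more
#' phenotypes are configured, the cross-phenotype comparison.
#'
#' @param config Path to a YAML file or a config list.
#' @return List with per-phenotype `bundles` and `comparison` (or NULL).
#' @export
run_config <- function(config) {
  if (is.character(config)) config <- load_pipeline_config(config)
  params <- do.call(pipeline_params,
                    config$params[intersect(names(config$params),
                                            names(formals(pipeline_params)))])
  annotation <- read_gene_annotation(config$annotation)
  control <- read_expression_matrix(config$control)
  control$phenotype[] <- "control"
  gene_sets <- if (!is.null(config$gene_sets)) read_gmt(config$gene_sets)
  bundles <- list()
  for (ph in names(config$cohorts)) {
    cancer <- read_expression_matrix(config$cohorts[[ph]])
    cancer$phenotype[] <- ph
    odir <- if (!is.null(config$out_dir)) file.path(config$out_dir, ph)
    bundles[[ph]] <- run_phenotype(cancer, control, annotation, gene_sets,
                                   params, out_dir = odir, phenotype = ph)
  }
  comparison <- if (length(bundles) >= 2)
    run_comparison(bundles, gene_sets, params = params)
  list(bundles = bundles, comparison = comparison)
}
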