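#' Specification of one planted co-expression module
#'
#' @param module_id Character id.
#' @param member_genes Character vector of gene ids (a clique of planted
#'   co-expression).
#' @param latent_correlation Exchangeable latent correlation in `[0, 1)`
#'   shared by every within-module gene pair.
#' @param chromosome_restricted Logical; if `TRUE` all members must sit on
#'   one chromosome (a "cis" module).
#' @param biotype_restricted Optional biotype label all members must carry.
#' @return A `module_spec` list.
#' @export
module_spec <- function(module_id, member_genes, latent_correlation,
                        chromosome_restricted = FALSE,
                        biotype_restricted = NULL) {
  if (latent_correlation < 0 || latent_correlation >= 1)
    stop("latent_correlation must lie in [0, 1): block correlation matrix ",
         "is only positive semidefinite on that range")
  if (anyDuplicated(member_genes))
    stop("module ", module_id, " has duplicated members")
  structure(list(module_id = as.character(module_id),
                 member_genes = as.character(member_genes),
                 latent_correlation = latent_correlation,
                 chromosome_restricted = isTRUE(chromosome_restricted),
                 biotype_restricted = biotype_restricted),
            class = "module_spec")
}

# Deterministic apportionment of n into integer counts proportional to
# `props` (largest-remainder / Hamilton rounding; ties broken by order).
largest_remainder <- function(n, props) {
  if (abs(sum(props) - 1) > 1e-9) stop("proportions must sum to 1")
  raw <- n * props
  base <- floor(raw)
  short <- n - sum(base)
  if (short > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(short)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(as.integer(base), names(props))
}

#' Generate a synthetic gene annotation table
#'
#' Genes are laid out contiguously along each chromosome with random sizes
#' and GC content; biotypes are apportioned by deterministic
#' largest-remainder rounding and assigned by a seeded shuffle. Pseudogenes
#' receive a `parent_gene_id` drawn from the protein-coding genes.
#'
#' @param n_genes Total number of genes.
#' @param chromosome_sizes Named integer vector: chromosome label to number
#'   of genes; must sum to `n_genes`.
#' @param biotype_proportions Named numeric vector of biotype fractions
#'   summing to 1 (e.g. protein_coding, pseudogene, lncRNA).
#' @param seed Integer seed; same seed, same table.
#' @return Annotation data.frame as from [read_gene_annotation()].
#' @export
generate_annotation <- function(n_genes,
                                chromosome_sizes,
                                biotype_proportions = c(protein_coding = 0.75,
                                                        pseudogene = 0.15,
                                                        lncRNA = 0.10),
                                seed = 1L) {
  if (is.null(names(chromosome_sizes)))
    stop("chromosome_sizes must be named by chromosome label")
  if (n_genes < length(chromosome_sizes))
    stop("n_genes is smaller than the number of chromosomes")
  if (sum(chromosome_sizes) != n_genes)
    stop("chromosome_sizes must sum to n_genes")
  counts <- largest_remainder(n_genes, biotype_proportions)
  withr::with_seed(seed, {
    biotype <- sample(rep(names(counts), counts))
    chrom <- rep(names(chromosome_sizes), chromosome_sizes)
    gene_id <- sprintf("G%05d", seq_len(n_genes))
    glen <- round(stats::runif(n_genes, 500, 50000))
    start <- unlist(lapply(split(glen, factor(chrom, levels = unique(chrom))),
                           function(l) cumsum(c(1, utils::head(l + 1000, -1)))),
                    use.names = FALSE)
    gc <- round(stats::runif(n_genes, 30, 70), 2)
    parent <- rep(NA_character_, n_genes)
    pc <- gene_id[biotype == "protein_coding"]
    is_pg <- grepl("pseudogene", biotype)
    if (any(is_pg) && length(pc))
      parent[is_pg] <- sample(pc, sum(is_pg), replace = TRUE)
    validate_annotation(data.frame(
      gene_id = gene_id, chromosome = chrom, biotype = biotype,
      gc_percent = gc, start_position = start, end_position = start + glen,
      parent_gene_id = parent, stringsAsFactors = FALSE))
  })
}

#' Default planted-module layouts for the two cohort modes
#'
#' Control mode plants `n_modules` trans-mixed modules: members sampled
#' across all chromosomes, so planted edges are mostly inter-chromosomal.
#' Cancer mode plants `n_modules` chromosome-restricted modules (each on a
#' distinct chromosome) plus one dense pseudogene module mixing
#' chromosomes, mirroring the cis-dominated topology and the pseudogene
#' cluster reported for hematopoietic cancer networks.
#'
#' @param annotation Annotation table.
#' @param mode `"control"` or `"cancer"`.
#' @param n_modules Number of (non-pseudogene) modules.
#' @param module_size Genes per module.
#' @param latent_correlation Planted latent correlation for every module.
#' @param pseudogene_module_size Size of the cancer-mode pseudogene module
#'   (0 disables it).
#' @param seed Integer seed.
#' @return List of [module_spec()] objects.
#' @export
default_module_specs <- function(annotation, mode = c("control", "cancer"),
                                 n_modules = 8L, module_size = 50L,
                                 latent_correlation = 0.8,
                                 pseudogene_module_size = 50L,
                                 seed = 1L) {
  mode <- match.arg(mode)
  withr::with_seed(seed, {
    specs <- list()
    used <- character(0)
    if (mode == "cancer") {
      chroms <- names(sort(table(annotation$chromosome), decreasing = TRUE))
      if (length(chroms) < n_modules)
        stop("need at least ", n_modules, " chromosomes for cancer mode")
      for (i in seq_len(n_modules)) {
        pool <- annotation$gene_id[annotation$chromosome == chroms[i] &
                                     !grepl("pseudogene", annotation$biotype) &
                                     !(annotation$gene_id %in% used)]
        if (length(pool) < module_size)
          stop("chromosome ", chroms[i], " has too few free genes for a module")
        members <- sort(sample(pool, module_size))
        used <- c(used, members)
        specs[[i]] <- module_spec(sprintf("cis%02d", i), members,
                                  latent_correlation,
                                  chromosome_restricted = TRUE)
      }
      if (pseudogene_module_size > 0) {
        pg_pool <- annotation$gene_id[grepl("pseudogene", annotation$biotype) &
                                        !(annotation$gene_id %in% used)]
        if (length(pg_pool) < pseudogene_module_size)
          stop("too few pseudogenes for the pseudogene module")
        members <- sort(sample(pg_pool, pseudogene_module_size))
        specs[[n_modules + 1L]] <- module_spec(
          "pgclust", members, latent_correlation,
          chromosome_restricted = FALSE, biotype_restricted = "pseudogene")
      }
    } else {
      for (i in seq_len(n_modules)) {
        pool <- setdiff(annotation$gene_id, used)
        members <- sort(sample(pool, module_size))
        used <- c(used, members)
        specs[[i]] <- module_spec(sprintf("mix%02d", i), members,
                                  latent_correlation,
                                  chromosome_restricted = FALSE)
      }
    }
    specs
  })
}

check_modules <- function(modules, annotation) {
  all_members <- unlist(lapply(modules, `[[`, "member_genes"))
  if (anyDuplicated(all_members))
    stop("module member sets must be disjoint")
  missing <- setdiff(all_members, annotation$gene_id)
  if (length(missing))
    stop("module members absent from annotation: ",
         paste(utils::head(missing, 5), collapse = ", "))
  chrom <- stats::setNames(annotation$chromosome, annotation$gene_id)
  for (m in modules) {
    if (m$chromosome_restricted &&
        length(unique(chrom[m$member_genes])) != 1L)
      stop("module ", m$module_id,
           " is chromosome_restricted but spans several chromosomes")
  }
  invisible(TRUE)
}

# Baseline per-gene NB means: log-spaced across nb_mean_range in gene order.
# Deterministic (no RNG) so that control and cancer cohorts generated in
# separate calls share the same baseline and differ only by the planted
# fold changes.
baseline_means <- function(annotation, nb_mean_range) {
  n <- nrow(annotation)
  mu <- exp(seq(log(nb_mean_range[1]), log(nb_mean_range[2]), length.out = n))
  # fixed interleave so mean is not confounded with chromosome order
  idx <- order(rep_len(seq_len(17L), n), seq_len(n))
  stats::setNames(mu[order(idx)], annotation$gene_id)
}

#' Generate one synthetic count cohort with planted co-expression
#'
#' Counts are drawn by a Gaussian copula: each gene's latent profile is
#' standard normal, with an exchangeable block correlation
#' `latent_correlation` inside each planted module (implemented as a shared
#' per-sample module factor), then mapped through the negative-binomial
#' quantile function at the gene's mean and dispersion (NB2:
#' `variance = mean + mean^2 * dispersion`). Cancer mode multiplies each
#' gene's mean by `2^log2FC` for genes named in `de_spec`.
#'
#' @param annotation Annotation table; defines the gene universe.
#' @param modules List of [module_spec()] objects (members must be
#'   annotated and disjoint).
#' @param mode `"control"` or `"cancer"`; `de_spec` is applied only in
#'   cancer mode.
#' @param n_samples Number of samples to draw.
#' @param nb_mean_range Range of baseline NB means, log-spaced over genes.
#' @param nb_dispersion NB2 dispersion (common to all genes).
#' @param de_spec Named numeric vector of true log2 fold changes
#'   (gene id -> log2FC), applied in cancer mode.
#' @param seed Integer seed; same seed and config give byte-identical
#'   output.
#' @return List with `matrix` (an `expression_matrix`) and `truth` (planted
#'   edge data.frame, `log2fc_true`, `module_assignment`, `config`).
#' @export
generate_cohort <- function(annotation, modules, mode = c("control", "cancer"),
                            n_samples = 100L,
                            nb_mean_range = c(20, 500),
                            nb_dispersion = 0.1,
                            de_spec = NULL, seed = 1L) {
  mode <- match.arg(mode)
  if (nb_dispersion <= 0) stop("nb_dispersion must be > 0 (NB2 model)")
  check_modules(modules, annotation)
  genes <- annotation$gene_id
  n_genes <- length(genes)
  mu <- baseline_means(annotation, nb_mean_range)
  log2fc <- stats::setNames(rep(0, n_genes), genes)
  if (!is.null(de_spec) && mode == "cancer") {
    unknown <- setdiff(names(de_spec), genes)
    if (length(unknown))
      stop("de_spec names absent from annotation: ",
           paste(utils::head(unknown, 5), collapse = ", "))
    log2fc[names(de_spec)] <- de_spec
  }
  mu_mode <- mu * 2^log2fc

  module_of <- stats::setNames(rep(NA_character_, n_genes), genes)
  for (m in modules) module_of[m$member_genes] <- m$module_id

  z <- withr::with_seed(seed, {
    zz <- matrix(stats::rnorm(n_samples * n_genes), nrow = n_samples,
                 dimnames = list(NULL, genes))
    for (m in modules) {
      rho <- m$latent_correlation
      if (rho > 0) {
        f <- stats::rnorm(n_samples)
        idx <- m$member_genes
        zz[, idx] <- sqrt(rho) * f + sqrt(1 - rho) * zz[, idx]
      }
    }
    zz
  })
  u <- stats::pnorm(z)
  size <- 1 / nb_dispersion
  counts <- matrix(0L, nrow = n_genes, ncol = n_samples,
                   dimnames = list(genes,
                                   sprintf("%s_s%03d", mode, seq_len(n_samples))))
  for (j in seq_len(n_genes)) {
    counts[j, ] <- stats::qnbinom(u[, genes[j]], size = size, mu = mu_mode[j])
  }
  storage.mode(counts) <- "double"

  planted <- do.call(rbind, lapply(modules, function(m) {
    g <- sort(m$member_genes)
    if (length(g) < 2) return(NULL)
    idx <- utils::combn(length(g), 2)
    data.frame(gene_a = g[idx[1, ]], gene_b = g[idx[2, ]],
               module_id = m$module_id, stringsAsFactors = FALSE)
  }))
  if (is.null(planted))
    planted <- data.frame(gene_a = character(0), gene_b = character(0),
                          module_id = character(0))

  em <- expression_matrix(counts,
                          phenotype = rep(mode, n_samples))
  truth <- list(
    planted_edges = planted,
    log2fc_true = log2fc,
    module_assignment = module_of,
    config = list(mode = mode, n_samples = n_samples,
                  nb_mean_range = nb_mean_range,
                  nb_dispersion = nb_dispersion,
                  de_spec = de_spec, seed = seed,
                  modules = lapply(modules, unclass)))
  list(matrix = em, truth = truth)
}

#' Generate the full default study: annotation plus paired cohorts
#'
#' One call that emulates the study design: a control cohort whose planted
#' modules mix chromosomes and a cancer cohort whose strongest modules are
#' chromosome-restricted plus one dense pseudogene cluster, with known
#' per-gene fold changes between modes (the pseudogene module is planted as
#' overexpressed).
#'
#' @param n_genes,n_chromosomes,n_samples Cohort dimensions.
#' @param n_modules,module_size,latent_correlation,pseudogene_module_size
#'   Module layout (see [default_module_specs()]).
#' @param nb_mean_range,nb_dispersion NB marginal parameters.
#' @param de_log2fc Log2 fold change planted on the pseudogene-module genes
#'   and on a matched number of random non-module genes (half up, half
#'   down).
#' @param seed Master seed; sub-seeds are derived from it.
#' @return List with `annotation`, `control`, `cancer` (each a
#'   `generate_cohort()` result), `modules_control`, `modules_cancer`.
#' @export
generate_study <- function(n_genes = 2000L, n_chromosomes = 10L,
                           n_samples = 100L, n_modules = 8L,
                           module_size = 50L, latent_correlation = 0.8,
                           pseudogene_module_size = 50L,
                           nb_mean_range = c(20, 500), nb_dispersion = 0.1,
                           de_log2fc = 2, seed = 1L) {
  per <- largest_remainder(n_genes,
                           stats::setNames(rep(1 / n_chromosomes, n_chromosomes),
                                           as.character(seq_len(n_chromosomes))))
  annotation <- generate_annotation(n_genes, per, seed = seed)
  mod_ctrl <- default_module_specs(annotation, "control", n_modules,
                                   module_size, latent_correlation,
                                   seed = seed + 1L)
  mod_canc <- default_module_specs(annotation, "cancer", n_modules,
                                   module_size, latent_correlation,
                                   pseudogene_module_size, seed = seed + 2L)
  pg_members <- if (pseudogene_module_size > 0)
    mod_canc[[length(mod_canc)]]$member_genes else character(0)
  de_spec <- withr::with_seed(seed + 3L, {
    free <- setdiff(annotation$gene_id,
                    unlist(lapply(c(mod_ctrl, mod_canc), `[[`, "member_genes")))
    extra <- sample(free, min(length(pg_members), length(free)))
    up <- utils::head(extra, ceiling(length(extra) / 2))
    down <- utils::tail(extra, floor(length(extra) / 2))
    c(stats::setNames(rep(de_log2fc, length(pg_members)), pg_members),
      stats::setNames(rep(de_log2fc, length(up)), up),
      stats::setNames(rep(-de_log2fc, length(down)), down))
  })
  control <- generate_cohort(annotation, mod_ctrl, "control", n_samples,
                             nb_mean_range, nb_dispersion, seed = seed + 4L)
  cancer <- generate_cohort(annotation, mod_canc, "cancer", n_samples,
                            nb_mean_range, nb_dispersion, de_spec = de_spec,
                            seed = seed + 5L)
  list(annotation = annotation, control = control, cancer = cancer,
       modules_control = mod_ctrl, modules_cancer = mod_canc,
       de_spec = de_spec, seed = seed)
}

#' Write a cohort's ground truth to plain-text files
#'
#' @param truth The `truth` element of a [generate_cohort()] result.
#' @param dir Output directory.
#' @return Paths written, invisibly.
#' @export
write_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  edge_path <- file.path(dir, "planted_edges.tsv")
  utils::write.table(truth$planted_edges, edge_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cfg_path <- file.path(dir, "truth_config.json")
  jsonlite::write_json(truth$config, cfg_path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(c(edge_path, cfg_path))
}
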