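#' Median-of-ratios size factors
#'
#' DESeq-style size factors on a joint count matrix: per-gene geometric
#' means over all samples (genes with a zero anywhere are excluded from
#' the reference), then the per-sample median ratio to that reference.
#'
#' @param counts Numeric count matrix (genes x samples) or an
#'   `expression_matrix`.
#' @return Named positive numeric vector, one factor per sample.
#' @export
median_of_ratios_size_factors <- function(counts) {
  x <- if (inherits(counts, "expression_matrix")) counts$values else counts
  loggeo <- rowMeans(log(x))
  usable <- is.finite(loggeo)
  if (!any(usable))
    stop("no gene is positive in every sample; cannot form the reference")
  sf <- apply(x[usable, , drop = FALSE], 2, function(col) {
    exp(stats::median(log(col[col > 0]) - loggeo[usable][col > 0]))
  })
  if (any(!is.finite(sf) | sf <= 0))
    stop("degenerate size factor(s) for sample(s): ",
         paste(colnames(x)[!is.finite(sf) | sf <= 0], collapse = ", "))
  stats::setNames(sf, colnames(x))
}

#' Negative-binomial Wald differential expression (simplified)
#'
#' A deliberately compact NB2 Wald test for a two-group comparison:
#' median-of-ratios size factors on the joint matrix, per-gene
#' method-of-moments dispersion (`variance = mean + mean^2 * dispersion`,
#' averaged over the two groups and floored at 1e-8), log2 fold change of
#' normalized group means with a 0.5 pseudo-mean floor, delta-method
#' standard error, normal two-sided p-value and Benjamini-Hochberg
#' adjustment. There is no dispersion shrinkage toward a trend, no
#' outlier filtering and no independent filtering; the downstream use is
#' sign/threshold classification, for which sign and approximate
#' magnitude suffice.
#'
#' @param cancer,control `expression_matrix` objects of raw counts over
#'   the same gene universe, at least 3 samples each.
#' @param classify_padj Adjusted-p threshold for the over/under
#'   classification (default 0.05); genes above it are `unclassified`.
#' @return Data.frame with gene_id, base_mean, log2FoldChange, lfcSE,
#'   stat, p_value, padj, class (`over`/`under`/`unclassified`);
#'   attribute `excluded_genes` lists genes zero in every sample.
#' @export
nb_wald_de <- function(cancer, control, classify_padj = 0.05) {
  stopifnot(inherits(cancer, "expression_matrix"),
            inherits(control, "expression_matrix"))
  if (!identical(sort(cancer$gene_ids), sort(control$gene_ids)))
    stop("cancer and control must share one gene universe")
  if (ncol(cancer$values) < 3 || ncol(control$values) < 3)
    stop("need at least 3 samples per group")
  x1 <- cancer$values
  x0 <- control$values[cancer$gene_ids, , drop = FALSE]
  joint <- cbind(x1, x0)
  all_zero <- rowSums(joint) == 0
  excluded <- rownames(joint)[all_zero]
  x1 <- x1[!all_zero, , drop = FALSE]
  x0 <- x0[!all_zero, , drop = FALSE]
  sf <- median_of_ratios_size_factors(cbind(x1, x0))
  n1 <- ncol(x1); n0 <- ncol(x0)
  y1 <- sweep(x1, 2, sf[seq_len(n1)], "/")
  y0 <- sweep(x0, 2, sf[n1 + seq_len(n0)], "/")
  m1 <- rowMeans(y1); m0 <- rowMeans(y0)
  v1 <- apply(y1, 1, stats::var); v0 <- apply(y0, 1, stats::var)
  disp_g <- function(v, m) ifelse(m > 0, (v - m) / m^2, 0)
  disp <- pmax((disp_g(v1, m1) + disp_g(v0, m0)) / 2, 1e-8)
  m1p <- m1 + 0.5; m0p <- m0 + 0.5
  lfc <- log2(m1p / m0p)
  se <- sqrt((1 / m1p + disp) / n1 + (1 / m0p + disp) / n0) / log(2)
  stat <- lfc / se
  p <- 2 * stats::pnorm(-abs(stat))
  padj <- bh_adjust(p)
  class <- rep("unclassified", length(lfc))
  class[padj < classify_padj & lfc > 0] <- "over"
  class[padj < classify_padj & lfc < 0] <- "under"
  structure(data.frame(
    gene_id = rownames(x1), base_mean = (n1 * m1 + n0 * m0) / (n1 + n0),
    log2FoldChange = lfc, lfcSE = se, stat = stat,
    p_value = p, padj = padj, class = class,
    stringsAsFactors = FALSE, row.names = NULL),
    excluded_genes = excluded, classify_padj = classify_padj)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement
#' (via [stats::p.adjust()]), after validating the inputs lie in [0, 1].
#'
#' @param p Numeric vector of p-values.
#' @return Adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p) | p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

as_community_list <- function(communities) {
  if (inherits(communities, "community_hierarchy")) {
    tab <- community_table(communities)
    return(stats::setNames(lapply(tab$members, identity), tab$community_id))
  }
  if (is.data.frame(communities)) {
    if (!all(c("community_id", "members") %in% names(communities)))
      stop("community table needs community_id and a members list-column")
    return(stats::setNames(lapply(communities$members, identity),
                           communities$community_id))
  }
  if (is.list(communities) && !is.null(names(communities)))
    return(communities)
  stop("cannot interpret `communities`")
}

#' Hypergeometric over-representation of communities in gene sets
#'
#' One-sided (upper-tail) hypergeometric test of the overlap between each
#' community and each gene set against a fixed universe, with
#' Benjamini-Hochberg adjustment across all (community, set) pairs and an
#' enriched flag at `padj < padj_threshold`.
#'
#' @param communities A `community_hierarchy`, community table or named
#'   list of member vectors.
#' @param sets A `gene_set_collection` or named list of member vectors.
#' @param universe Character vector of background genes (community
#'   members must be a subset; sets are intersected with it).
#' @param padj_threshold Enrichment call threshold (default 1e-10).
#' @return Data.frame with community_id, set_id, community_size, set_size,
#'   overlap_count, p_value, padj, enriched.
#' @export
hypergeom_enrich <- function(communities, sets, universe,
                             padj_threshold = 1e-10) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  comm <- as_community_list(communities)
  outside <- setdiff(unique(unlist(comm)), universe)
  if (length(outside))
    stop("community member(s) outside the universe: ",
         paste(utils::head(outside, 5), collapse = ", "))
  sets <- lapply(sets, intersect, universe)
  N <- length(universe)
  grid <- expand.grid(community_id = names(comm), set_id = names(sets),
                      stringsAsFactors = FALSE)
  res <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    cm <- comm[[grid$community_id[i]]]
    st <- sets[[grid$set_id[i]]]
    ov <- length(intersect(cm, st))
    data.frame(community_id = grid$community_id[i],
               set_id = grid$set_id[i],
               community_size = length(cm), set_size = length(st),
               overlap_count = ov,
               p_value = stats::phyper(ov - 1, length(st), N - length(st),
                                       length(cm), lower.tail = FALSE),
               stringsAsFactors = FALSE)
  }))
  res$padj <- bh_adjust(res$p_value)
  res$enriched <- res$padj < padj_threshold
  res[order(res$p_value), , drop = FALSE]
}

#' Differential-expression trend of a gene community
#'
#' The proportion of overexpressed members minus the proportion of
#' underexpressed members, in `[-1, 1]`: +1 when every member tends to
#' overexpression, -1 when every member tends to underexpression, 0 when
#' the two proportions balance. Members not scored in the DE table (or
#' not significant) count in the denominator as unclassified.
#'
#' @param members Character vector of community member genes (non-empty).
#' @param de_table Result of [nb_wald_de()].
#' @return One-row data.frame: trend, n_over, n_under, n_unclassified,
#'   n_total.
#' @export
de_trend <- function(members, de_table) {
  if (!length(members)) stop("empty community")
  cls <- stats::setNames(de_table$class, de_table$gene_id)[members]
  cls[is.na(cls)] <- "unclassified"
  n_over <- sum(cls == "over")
  n_under <- sum(cls == "under")
  n_total <- length(members)
  data.frame(trend = (n_over - n_under) / n_total,
             n_over = n_over, n_under = n_under,
             n_unclassified = n_total - n_over - n_under,
             n_total = n_total)
}

#' Trend table for every community
#'
#' @param communities A `community_hierarchy`, community table or named
#'   list of member vectors.
#' @param de_table Result of [nb_wald_de()].
#' @return Data.frame with community_id plus the [de_trend()] columns.
#' @export
community_trends <- function(communities, de_table) {
  comm <- as_community_list(communities)
  do.call(rbind, lapply(names(comm), function(id) {
    cbind(data.frame(community_id = id, stringsAsFactors = FALSE),
          de_trend(comm[[id]], de_table))
  }))
}

#' Trend matrix of biological processes shared across phenotypes
#'
#' Restricts to gene sets (biological processes) enriched in every
#' phenotype and reports, per phenotype and process, the differential
#' expression trend of the union of genes across all communities that
#' enrich that process in that phenotype.
#'
#' @param enrichment_tables Named list (phenotype -> [hypergeom_enrich()]
#'   table).
#' @param communities_list Named list (phenotype -> communities, any form
#'   accepted by [hypergeom_enrich()]).
#' @param de_tables Named list (phenotype -> [nb_wald_de()] table).
#' @return Numeric matrix, phenotypes x shared processes, of trend
#'   values; empty (0 columns) with a warning when no process is shared.
#' @export
shared_bp_matrix <- function(enrichment_tables, communities_list, de_tables) {
  phenos <- names(enrichment_tables)
  if (length(phenos) < 2) stop("need at least 2 phenotypes")
  if (!identical(sort(phenos), sort(names(de_tables))) ||
      !identical(sort(phenos), sort(names(communities_list))))
    stop("enrichment, community and DE lists must cover the same phenotypes")
  enriched_ids <- lapply(enrichment_tables, function(tab)
    unique(tab$set_id[tab$enriched]))
  shared <- Reduce(intersect, enriched_ids)
  if (!length(shared)) {
    warning("no biological process is enriched in every phenotype")
    return(matrix(numeric(0), nrow = length(phenos), ncol = 0,
                  dimnames = list(phenos, character(0))))
  }
  shared <- sort(shared)
  out <- matrix(NA_real_, length(phenos), length(shared),
                dimnames = list(phenos, shared))
  for (ph in phenos) {
    comm <- as_community_list(communities_list[[ph]])
    tab <- enrichment_tables[[ph]]
    for (bp in shared) {
      cids <- tab$community_id[tab$enriched & tab$set_id == bp]
      genes <- sort(unique(unlist(comm[cids])))
      out[ph, bp] <- de_trend(genes, de_tables[[ph]])$trend
    }
  }
  out
}
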