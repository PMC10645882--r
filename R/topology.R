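#' Default cutoff grid for cis-fraction curves
#'
#' Logarithmic grid of top-k cutoffs from 1e4 up to `min(1e7, n_edges)`,
#' 30 points, deduplicated after rounding.
#'
#' @param n_edges Total number of edges available.
#' @param from,to,length_out Grid parameters.
#' @return Strictly increasing integer vector of cutoffs.
#' @export
default_cutoff_grid <- function(n_edges, from = 1e4, to = 1e7,
                                length_out = 30L) {
  to <- min(to, n_edges)
  if (to < from) from <- max(1, min(from, to))
  unique(round(exp(seq(log(from), log(to), length.out = length_out))))
}

annotate_edges_chromosome <- function(edges, annotation) {
  chrom <- stats::setNames(annotation$chromosome, annotation$gene_id)
  missing <- setdiff(unique(c(edges$gene_a, edges$gene_b)), names(chrom))
  if (length(missing))
    stop("edge gene(s) missing from annotation: ",
         paste(utils::head(missing, 5), collapse = ", "))
  chrom[edges$gene_a] == chrom[edges$gene_b]
}

#' Cis-fraction curve over top-k cutoffs
#'
#' For each cutoff k, the fraction of the k strongest edges whose two
#' genes share a chromosome label ("cis", intra-chromosomal).
#'
#' @param edges Ranked edge list.
#' @param annotation Annotation table covering every edge gene.
#' @param cutoffs Ascending top-k cutoffs (default
#'   [default_cutoff_grid()]).
#' @param network_id Optional label stored with the profile.
#' @return A `cis_profile` data.frame with columns `cutoff` and
#'   `cis_fraction`, attribute `network_id`.
#' @export
cis_fraction_curve <- function(edges, annotation, cutoffs = NULL,
                               network_id = NULL) {
  E <- nrow(edges)
  if (is.null(cutoffs)) cutoffs <- default_cutoff_grid(E)
  cutoffs <- as.integer(cutoffs)
  if (any(diff(cutoffs) <= 0)) stop("cutoffs must be strictly increasing")
  if (any(cutoffs < 1 | cutoffs > E))
    stop("cutoffs must lie in [1, ", E, "]")
  cis <- annotate_edges_chromosome(edges, annotation)
  cum <- cumsum(cis[order(edges$rank)])
  out <- data.frame(cutoff = cutoffs,
                    cis_fraction = cum[cutoffs] / cutoffs)
  structure(out, network_id = network_id, class = c("cis_profile", "data.frame"))
}

#' Kolmogorov-Smirnov comparison of two cis-fraction profiles
#'
#' Two-sample KS on the two sets of cis-fraction values:
#' `D = sup |ECDF_a - ECDF_b|`, with an asymptotic p-value from the
#' Kolmogorov distribution. The cis-fraction values across cutoffs are
#' serially dependent (each top-k set nests the previous one), so the
#' nominal p-value is reported together with that caveat.
#'
#' @param profile_a,profile_b `cis_profile` objects (or plain numeric
#'   vectors of at least 2 values each).
#' @return List with `statistic` (D), `p_value`, `n_a`, `n_b`, `caveat`.
#' @export
ks_compare <- function(profile_a, profile_b) {
  xa <- if (is.data.frame(profile_a)) profile_a$cis_fraction else profile_a
  xb <- if (is.data.frame(profile_b)) profile_b$cis_fraction else profile_b
  if (length(xa) < 2 || length(xb) < 2)
    stop("each profile needs at least 2 points")
  kt <- suppressWarnings(stats::ks.test(xa, xb, exact = FALSE))
  list(statistic = unname(kt$statistic),
       p_value = unname(kt$p.value),
       n_a = length(xa), n_b = length(xb),
       caveat = paste("profile points are serially dependent across nested",
                      "cutoffs; the KS iid assumption does not hold strictly"))
}

#' Default biotype coarsening into figure-legend families
#'
#' Any biotype containing "pseudogene" maps to `"pseudogene"`, `IG_*` to
#' `"IG"`, `TR_*` to `"TR"`; everything else is kept verbatim.
#'
#' @param biotypes Character vector.
#' @return Coarsened character vector.
#' @export
coarsen_biotype <- function(biotypes) {
  out <- as.character(biotypes)
  out[grepl("pseudogene", out)] <- "pseudogene"
  out[startsWith(out, "IG_")] <- "IG"
  out[startsWith(out, "TR_")] <- "TR"
  out
}

#' Biotype interaction fractions among the strongest edges
#'
#' Counts unordered biotype-family pairs over the top-k edges and
#' normalizes to fractions (summing to 1).
#'
#' @param edges Ranked edge list.
#' @param annotation Annotation table.
#' @param top_k Number of strongest edges to count (default: all).
#' @param coarsen Function mapping fine biotypes to families (default
#'   [coarsen_biotype()]).
#' @return Data.frame with `biotype_pair` (label "A:B", alphabetical),
#'   `count`, `fraction`, sorted by fraction descending; attribute
#'   `top_k`.
#' @export
biotype_pair_fractions <- function(edges, annotation, top_k = NULL,
                                   coarsen = coarsen_biotype) {
  if (is.null(top_k)) top_k <- nrow(edges)
  top_k <- min(top_k, nrow(edges))
  top <- edges[order(edges$rank)[seq_len(top_k)], , drop = FALSE]
  bio <- stats::setNames(coarsen(annotation$biotype), annotation$gene_id)
  missing <- setdiff(unique(c(top$gene_a, top$gene_b)), names(bio))
  if (length(missing))
    stop("edge gene(s) missing from annotation: ",
         paste(utils::head(missing, 5), collapse = ", "))
  ba <- bio[top$gene_a]
  bb <- bio[top$gene_b]
  pair <- ifelse(ba <= bb, paste(ba, bb, sep = ":"), paste(bb, ba, sep = ":"))
  tab <- sort(table(pair), decreasing = TRUE)
  out <- data.frame(biotype_pair = names(tab),
                    count = as.integer(tab),
                    fraction = as.numeric(tab) / top_k,
                    stringsAsFactors = FALSE)
  structure(out, top_k = top_k)
}

#' Connected-component spectrum of the top-k network
#'
#' Component sizes (descending) of the graph formed by the top-k edges,
#' with per-component chromosome purity (fraction of members on the modal
#' chromosome) when an annotation is supplied.
#'
#' @param edges Ranked edge list.
#' @param top_k Number of strongest edges to use (default: all).
#' @param annotation Optional annotation table for purity.
#' @return List with `components` (data.frame: component_id, size,
#'   modal_chromosome, purity) and `membership` (named vector gene ->
#'   component_id).
#' @export
component_spectrum <- function(edges, top_k = NULL, annotation = NULL) {
  if (is.null(top_k)) top_k <- nrow(edges)
  top_k <- min(top_k, nrow(edges))
  top <- edges[order(edges$rank)[seq_len(top_k)], , drop = FALSE]
  g <- igraph::graph_from_data_frame(top[, c("gene_a", "gene_b")],
                                     directed = FALSE)
  comp <- igraph::components(g)
  ord <- order(comp$csize, decreasing = TRUE)
  relabel <- match(seq_along(comp$csize), ord)
  membership <- stats::setNames(relabel[comp$membership],
                                igraph::V(g)$name)
  sizes <- comp$csize[ord]
  df <- data.frame(component_id = seq_along(sizes), size = sizes)
  if (!is.null(annotation)) {
    chrom <- stats::setNames(annotation$chromosome, annotation$gene_id)
    stats_by <- lapply(seq_along(sizes), function(i) {
      members <- names(membership)[membership == i]
      tab <- sort(table(chrom[members]), decreasing = TRUE)
      c(modal = names(tab)[1], purity = as.numeric(tab[1]) / length(members))
    })
    df$modal_chromosome <- vapply(stats_by, `[[`, character(1), "modal")
    df$purity <- as.numeric(vapply(stats_by, `[[`, character(1), "purity"))
  }
  list(components = df, membership = membership)
}

#' Intersect the strongest edges of several networks
#'
#' Exact set intersection of the top-`top_k` edge sets of two or more
#' ranked edge lists (canonical gene_a < gene_b ordering makes the set
#' comparison exact). The node set is the endpoints of surviving edges.
#'
#' @param edge_lists List of >= 2 ranked edge lists.
#' @param top_k Edges taken from each network (default 100000, the
#'   strongest-interaction cutoff used for cross-phenotype intersection).
#' @return List with `edges` (data.frame gene_a/gene_b, sorted), `nodes`
#'   (character vector), `n_networks`.
#' @export
intersect_networks <- function(edge_lists, top_k = 100000L) {
  if (length(edge_lists) < 2)
    stop("need at least 2 networks to intersect")
  keys <- lapply(edge_lists, function(el) {
    if (any(el$gene_a >= el$gene_b))
      stop("edge list not canonical (gene_a < gene_b required)")
    k <- min(top_k, nrow(el))
    top <- el[order(el$rank)[seq_len(k)], , drop = FALSE]
    paste(top$gene_a, top$gene_b, sep = "\r")
  })
  common <- Reduce(intersect, keys)
  common <- sort(common)
  parts <- strsplit(common, "\r", fixed = TRUE)
  edges <- data.frame(
    gene_a = vapply(parts, `[[`, character(1), 1L),
    gene_b = vapply(parts, `[[`, character(1), 2L),
    stringsAsFactors = FALSE)
  list(edges = edges,
       nodes = sort(unique(c(edges$gene_a, edges$gene_b))),
       n_networks = length(edge_lists))
}
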