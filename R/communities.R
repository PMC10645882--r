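#' Default resolution sweep
#'
#' 20 values of the Louvain resolution parameter, log-spaced in
#' `[0.25, 4]` (bracketing the standard resolution 1 symmetrically).
#'
#' @param from,to,length_out Sweep parameters.
#' @return Increasing numeric vector of resolutions.
#' @export
default_resolutions <- function(from = 0.25, to = 4, length_out = 20L) {
  exp(seq(log(from), log(to), length.out = length_out))
}

as_network_graph <- function(x) {
  if (igraph::is_igraph(x)) return(x)
  if (is.data.frame(x)) {
    if (!all(c("gene_a", "gene_b") %in% names(x)))
      stop("edge data.frame needs gene_a and gene_b columns")
    return(igraph::simplify(igraph::graph_from_data_frame(
      x[, c("gene_a", "gene_b")], directed = FALSE)))
  }
  stop("expected an igraph graph or an edge data.frame")
}

#' Louvain partitions across a resolution sweep
#'
#' One modularity-based Louvain partition per resolution, deterministic
#' for a fixed seed (the seed is re-applied before each resolution so
#' partitions do not depend on sweep order).
#'
#' @param graph An igraph graph or canonical edge data.frame.
#' @param resolutions Numeric vector of resolution parameters (default
#'   [default_resolutions()]).
#' @param seed Integer seed.
#' @return List of partitions; each is a named integer membership vector
#'   (gene -> community index). Attribute `resolutions` carries the sweep.
#' @export
resolution_sweep <- function(graph, resolutions = default_resolutions(),
                             seed = 1L) {
  g <- as_network_graph(graph)
  if (igraph::vcount(g) == 0) stop("empty graph")
  parts <- lapply(resolutions, function(res) {
    withr::with_seed(seed, {
      cl <- igraph::cluster_louvain(g, resolution = res)
      stats::setNames(igraph::membership(cl), igraph::V(g)$name)
    })
  })
  structure(parts, resolutions = resolutions)
}

partition_to_sets <- function(membership) {
  split(names(membership), membership)
}

jaccard_sets <- function(a, b) {
  length(intersect(a, b)) / length(union(a, b))
}

# Greedy one-to-one matching between the communities of two adjacent
# partitions: pairs are taken in decreasing Jaccard order, each community
# used at most once, and only matches at or above the threshold survive.
match_adjacent <- function(sets_a, sets_b, threshold) {
  if (!length(sets_a) || !length(sets_b)) return(integer(0))
  jac <- outer(seq_along(sets_a), seq_along(sets_b),
               Vectorize(function(i, j) jaccard_sets(sets_a[[i]], sets_b[[j]])))
  match_of <- stats::setNames(integer(0), character(0))
  used_a <- logical(length(sets_a))
  used_b <- logical(length(sets_b))
  ord <- order(jac, decreasing = TRUE)
  out <- integer(length(sets_a)); out[] <- NA_integer_
  for (k in ord) {
    if (jac[k] < threshold) break
    i <- (k - 1) %% length(sets_a) + 1
    j <- (k - 1) %/% length(sets_a) + 1
    if (used_a[i] || used_b[j]) next
    used_a[i] <- TRUE; used_b[j] <- TRUE
    out[i] <- j
  }
  out
}

#' Persistence filtering of a resolution sweep into a community hierarchy
#'
#' Communities from adjacent resolutions are matched one-to-one when the
#' Jaccard similarity of their member sets reaches `jaccard_threshold`;
#' maximal chains of matched communities are collapsed to one
#' representative (the genes present in at least half of the chain's
#' snapshots), with persistence equal to the chain length. Chains shorter
#' than `min_persistence` are dropped. Containment links connect every
#' retained pair where one member set is a proper subset of the other.
#'
#' @param partitions Result of [resolution_sweep()] (list of named
#'   membership vectors with a `resolutions` attribute, or a plain list
#'   plus the `resolutions` argument).
#' @param jaccard_threshold Match threshold in `(0, 1]` (default 0.75).
#' @param min_persistence Minimum chain length to retain (default 5).
#' @param resolutions Optional explicit resolution values.
#' @return A `community_hierarchy` list: `communities` (list of records
#'   with community_id, members, persistence, resolution_range),
#'   `containment` (data.frame parent/child), `resolutions`.
#' @export
persistence_filter <- function(partitions, jaccard_threshold = 0.75,
                               min_persistence = 5L, resolutions = NULL) {
  if (jaccard_threshold <= 0 || jaccard_threshold > 1)
    stop("jaccard_threshold must lie in (0, 1]")
  if (is.null(resolutions)) resolutions <- attr(partitions, "resolutions")
  if (is.null(resolutions)) resolutions <- seq_along(partitions)
  R <- length(partitions)
  if (R < min_persistence)
    stop("need at least min_persistence (", min_persistence, ") partitions")
  sets <- lapply(partitions, partition_to_sets)

  # chain id per (resolution, community); start new chains where unmatched
  chain_id <- vector("list", R)
  chains <- list()
  next_id <- 0L
  chain_id[[1]] <- integer(length(sets[[1]]))
  for (i in seq_along(sets[[1]])) {
    next_id <- next_id + 1L
    chain_id[[1]][i] <- next_id
    chains[[next_id]] <- list(snapshots = sets[[1]][i], res_idx = 1L)
  }
  for (r in seq_len(R - 1L)) {
    m <- match_adjacent(sets[[r]], sets[[r + 1L]], jaccard_threshold)
    chain_id[[r + 1L]] <- integer(length(sets[[r + 1L]]))
    matched_b <- m[!is.na(m)]
    for (i in seq_along(m)) {
      if (!is.na(m[i])) {
        id <- chain_id[[r]][i]
        chain_id[[r + 1L]][m[i]] <- id
        chains[[id]]$snapshots <- c(chains[[id]]$snapshots,
                                    sets[[r + 1L]][m[i]])
        chains[[id]]$res_idx <- c(chains[[id]]$res_idx, r + 1L)
      }
    }
    for (j in seq_along(sets[[r + 1L]])) {
      if (chain_id[[r + 1L]][j] == 0L) {
        next_id <- next_id + 1L
        chain_id[[r + 1L]][j] <- next_id
        chains[[next_id]] <- list(snapshots = sets[[r + 1L]][j],
                                  res_idx = r + 1L)
      }
    }
  }

  retained <- list()
  for (ch in chains) {
    len <- length(ch$snapshots)
    if (len < min_persistence) next
    counts <- table(unlist(lapply(ch$snapshots, unique)))
    members <- sort(names(counts)[2 * as.integer(counts) >= len])
    if (!length(members)) next
    retained[[length(retained) + 1L]] <- list(
      members = members, persistence = len,
      resolution_range = range(resolutions[ch$res_idx]))
  }

  # merge duplicate representatives, keeping the larger persistence
  if (length(retained)) {
    keys <- vapply(retained, function(x) paste(x$members, collapse = "\r"),
                   character(1))
    keep <- !duplicated(keys)
    for (k in unique(keys[duplicated(keys)])) {
      ids <- which(keys == k)
      retained[[ids[1]]]$persistence <- max(vapply(retained[ids],
                                                   `[[`, numeric(1),
                                                   "persistence"))
      retained[[ids[1]]]$resolution_range <-
        range(unlist(lapply(retained[ids], `[[`, "resolution_range")))
    }
    retained <- retained[keep]
  }
  ord <- order(-vapply(retained, function(x) length(x$members), numeric(1)),
               vapply(retained, function(x) x$members[1], character(1)))
  retained <- retained[ord]
  for (i in seq_along(retained))
    retained[[i]]$community_id <- sprintf("C%03d", i)

  containment <- data.frame(parent = character(0), child = character(0),
                            stringsAsFactors = FALSE)
  if (length(retained) > 1) {
    for (i in seq_along(retained)) {
      for (j in seq_along(retained)) {
        if (i == j) next
        a <- retained[[i]]$members; b <- retained[[j]]$members
        if (length(b) < length(a) && all(b %in% a))
          containment <- rbind(containment, data.frame(
            parent = retained[[i]]$community_id,
            child = retained[[j]]$community_id,
            stringsAsFactors = FALSE))
      }
    }
  }
  structure(list(communities = retained, containment = containment,
                 resolutions = resolutions,
                 params = list(jaccard_threshold = jaccard_threshold,
                               min_persistence = min_persistence)),
            class = "community_hierarchy")
}

#' @export
print.community_hierarchy <- function(x, ...) {
  cat(sprintf("community_hierarchy: %d communities over %d resolutions\n",
              length(x$communities), length(x$resolutions)))
  invisible(x)
}

#' Flatten a community hierarchy into a table
#'
#' @param hierarchy A `community_hierarchy`.
#' @return Data.frame with community_id, size, persistence,
#'   resolution_min, resolution_max and a `members` list-column.
#' @export
community_table <- function(hierarchy) {
  stopifnot(inherits(hierarchy, "community_hierarchy"))
  if (!length(hierarchy$communities))
    return(data.frame(community_id = character(0), size = integer(0),
                      persistence = integer(0), resolution_min = numeric(0),
                      resolution_max = numeric(0)))
  df <- data.frame(
    community_id = vapply(hierarchy$communities, `[[`, character(1),
                          "community_id"),
    size = vapply(hierarchy$communities,
                  function(x) length(x$members), integer(1)),
    persistence = vapply(hierarchy$communities, function(x)
      as.integer(x$persistence), integer(1)),
    resolution_min = vapply(hierarchy$communities, function(x)
      x$resolution_range[1], numeric(1)),
    resolution_max = vapply(hierarchy$communities, function(x)
      x$resolution_range[2], numeric(1)),
    stringsAsFactors = FALSE)
  df$members <- I(lapply(hierarchy$communities, `[[`, "members"))
  df
}

#' Write a community table (and containment links) to TSV
#'
#' @param hierarchy A `community_hierarchy`.
#' @param dir Output directory.
#' @return Paths written, invisibly.
#' @export
write_community_tables <- function(hierarchy, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tab <- community_table(hierarchy)
  flat <- tab
  flat$members <- vapply(tab$members, paste, character(1), collapse = ";")
  p1 <- file.path(dir, "communities.tsv")
  utils::write.table(flat, p1, sep = "\t", quote = FALSE, row.names = FALSE)
  p2 <- file.path(dir, "containment.tsv")
  utils::write.table(hierarchy$containment, p2, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(p1, p2))
}
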