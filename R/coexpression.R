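#' Equal-frequency discretization of one expression profile
#'
#' Bins a numeric profile into `B` near-equal-occupancy bins by rank,
#' with ties broken by order of appearance. A constant profile has no
#' informative discretization; callers detect that case, force the gene
#' into one bin and flag it.
#'
#' @param x Numeric vector.
#' @param B Number of bins.
#' @return Integer vector of bin codes in `1..B`.
#' @export
discretize_equal_frequency <- function(x, B) {
  n <- length(x)
  if (B < 2) stop("need at least 2 bins")
  r <- rank(x, ties.method = "first")
  as.integer(floor((r - 1) * B / n) + 1L)
}

default_mi_bins <- function(n_samples) max(2L, as.integer(round(sqrt(n_samples))))

#' All-pairs mutual information matrix
#'
#' Plug-in (maximum-likelihood) mutual information in bits between every
#' gene pair, on equal-frequency discretized profiles with
#' `B = max(2, round(sqrt(n)))` bins by default. Symmetric; the diagonal
#' is excluded (set to 0). Constant genes cannot be discretized
#' informatively: their pairs score 0 and the gene ids are flagged in the
#' `flagged_genes` attribute.
#'
#' @param em An `expression_matrix` of normalized expression (>= 8
#'   samples).
#' @param n_bins Optional bin-count override.
#' @return Gene x gene numeric matrix with attributes `method = "mi"`,
#'   `n_bins`, `n_samples`, `flagged_genes`.
#' @export
mutual_information_matrix <- function(em, n_bins = NULL) {
  stopifnot(inherits(em, "expression_matrix"))
  n <- ncol(em$values)
  if (n < 8) stop("mutual information needs at least 8 samples")
  B <- if (is.null(n_bins)) default_mi_bins(n) else as.integer(n_bins)
  constant <- apply(em$values, 1, function(v) max(v) == min(v))
  D <- apply(em$values, 1, discretize_equal_frequency, B = B) # n x G
  # a constant profile would get spread over bins by rank ties; force it
  # into one bin so its entropy, and thus all its MIs, are exactly 0
  if (any(constant)) D[, constant] <- 1L
  M <- mi_all_pairs_cpp(D, B)
  dimnames(M) <- list(em$gene_ids, em$gene_ids)
  structure(M, method = "mi", n_bins = B, n_samples = n,
            flagged_genes = em$gene_ids[constant])
}

#' All-pairs Spearman correlation matrix
#'
#' Rank correlation with average ranks for ties (Pearson on ranks).
#' Constant genes are flagged and their correlations set to 0.
#'
#' @param em An `expression_matrix` (>= 4 samples).
#' @return Gene x gene numeric matrix with attributes `method =
#'   "spearman"`, `n_samples`, `flagged_genes`; diagonal set to 0.
#' @export
spearman_matrix <- function(em) {
  stopifnot(inherits(em, "expression_matrix"))
  n <- ncol(em$values)
  if (n < 4) stop("Spearman correlation needs at least 4 samples")
  R <- apply(em$values, 1, rank, ties.method = "average") # n x G
  constant <- apply(em$values, 1, function(v) max(v) == min(v))
  S <- suppressWarnings(stats::cor(R))
  S[is.na(S)] <- 0
  diag(S) <- 0
  dimnames(S) <- list(em$gene_ids, em$gene_ids)
  structure(S, method = "spearman", n_samples = n,
            flagged_genes = em$gene_ids[constant])
}

#' Pooled permutation null for co-expression scores
#'
#' Builds a pooled null distribution by repeatedly drawing random gene
#' pairs and scoring them after permuting one profile's sample order,
#' breaking any dependence while preserving both marginals. Edge p-values
#' against this null use the add-one rule
#' `p = (1 + #(null >= score)) / (1 + N_null)`.
#'
#' @param em An `expression_matrix`.
#' @param method `"mi"` or `"spearman"`.
#' @param n_permutations Number of sample-order permutations.
#' @param pairs_per_permutation Random pairs scored per permutation.
#' @param n_bins MI bin override (default as in
#'   [mutual_information_matrix()]).
#' @param seed Integer seed.
#' @return A `null_distribution` list: `method`, `n_permutations`,
#'   `pairs_per_permutation`, `null_scores` (absolute scores), `seed`.
#' @export
permutation_null <- function(em, method = c("spearman", "mi"),
                             n_permutations = 20L,
                             pairs_per_permutation = 10000L,
                             n_bins = NULL, seed = 1L) {
  method <- match.arg(method)
  stopifnot(inherits(em, "expression_matrix"))
  if (n_permutations < 1) stop("need at least one permutation")
  n <- ncol(em$values)
  G <- nrow(em$values)
  if (G < 2) stop("need at least two genes")
  if (method == "mi") {
    B <- if (is.null(n_bins)) default_mi_bins(n) else as.integer(n_bins)
    D <- apply(em$values, 1, discretize_equal_frequency, B = B)
  } else {
    Rk <- apply(em$values, 1, rank, ties.method = "average")
  }
  scores <- withr::with_seed(seed, {
    unlist(lapply(seq_len(n_permutations), function(p) {
      perm <- sample.int(n)
      ia <- sample.int(G, pairs_per_permutation, replace = TRUE)
      ib <- sample.int(G, pairs_per_permutation, replace = TRUE)
      same <- ia == ib
      if (any(same)) ib[same] <- (ib[same] %% G) + 1L
      if (method == "mi") {
        mi_paired_cols_cpp(D[, ia, drop = FALSE],
                           D[perm, ib, drop = FALSE], B)
      } else {
        A <- Rk[, ia, drop = FALSE]
        Bm <- Rk[perm, ib, drop = FALSE]
        A <- sweep(A, 2, colMeans(A))
        Bm <- sweep(Bm, 2, colMeans(Bm))
        num <- colSums(A * Bm)
        den <- sqrt(colSums(A^2) * colSums(Bm^2))
        r <- num / den
        r[!is.finite(r)] <- 0
        r
      }
    }), use.names = FALSE)
  })
  structure(list(method = method, n_permutations = n_permutations,
                 pairs_per_permutation = pairs_per_permutation,
                 null_scores = abs(scores), seed = seed),
            class = "null_distribution")
}

#' Empirical p-values against a pooled null
#'
#' @param abs_scores Numeric vector of absolute co-expression scores.
#' @param null The `null_distribution` from [permutation_null()] (or a
#'   numeric vector of null scores).
#' @param alpha Optional significance target; a warning attribute is set
#'   when the null is too small to ever reach `alpha`.
#' @return Numeric vector of p-values in `(0, 1]`, add-one rule.
#' @export
edge_p_values <- function(abs_scores, null, alpha = NULL) {
  ns <- if (inherits(null, "null_distribution")) null$null_scores else null
  ns <- sort(ns)
  N <- length(ns)
  n_ge <- N - findInterval(abs_scores, ns, left.open = TRUE)
  p <- (1 + n_ge) / (1 + N)
  if (!is.null(alpha) && 1 / (1 + N) > alpha)
    attr(p, "warning") <- sprintf(
      "null has %d values; minimum attainable p %.3g exceeds alpha %.3g",
      N, 1 / (1 + N), alpha)
  p
}

#' Rank all gene pairs into a canonical edge list
#'
#' Upper-triangle pairs sorted by absolute score descending, ties broken
#' lexicographically by (gene_a, gene_b); ranks are contiguous from 1.
#' Within each row `gene_a < gene_b`.
#'
#' @param score_matrix Symmetric gene x gene score matrix (as from
#'   [mutual_information_matrix()] or [spearman_matrix()]).
#' @param null Optional `null_distribution` for p-values.
#' @param top_k Optional truncation; if larger than the number of pairs,
#'   all pairs are returned with a warning.
#' @return A ranked edge list data.frame (gene_a, gene_b, score,
#'   abs_score, rank, p_value) with attributes `method` and `n_samples`
#'   copied from the score matrix.
#' @export
rank_edges <- function(score_matrix, null = NULL, top_k = NULL) {
  g <- rownames(score_matrix)
  if (is.null(g)) stop("score matrix must carry gene dimnames")
  if (nrow(score_matrix) != ncol(score_matrix))
    stop("score matrix must be square")
  ut <- upper.tri(score_matrix)
  idx <- which(ut, arr.ind = TRUE)
  ga <- g[idx[, 1]]
  gb <- g[idx[, 2]]
  swap <- ga > gb
  if (any(swap)) { tmp <- ga[swap]; ga[swap] <- gb[swap]; gb[swap] <- tmp }
  s <- score_matrix[ut]
  a <- abs(s)
  ord <- order(-a, ga, gb, method = "radix")
  E <- length(ord)
  if (!is.null(top_k)) {
    if (top_k > E) {
      warning("top_k (", top_k, ") exceeds available pairs (", E,
              "); returning all")
      top_k <- E
    }
    ord <- ord[seq_len(top_k)]
  }
  edges <- data.frame(gene_a = ga[ord], gene_b = gb[ord],
                      score = s[ord], abs_score = a[ord],
                      rank = seq_along(ord),
                      p_value = NA_real_, stringsAsFactors = FALSE)
  if (!is.null(null))
    edges$p_value <- as.numeric(edge_p_values(edges$abs_score, null))
  structure(edges,
            method = attr(score_matrix, "method"),
            n_samples = attr(score_matrix, "n_samples"))
}

#' Precision of a ranking against planted edges
#'
#' Precision at `k` (default: the number of planted edges): the fraction
#' of the top-`k` ranked pairs that are planted.
#'
#' @param edges Ranked edge list (canonical).
#' @param planted Data.frame with gene_a/gene_b (canonical) of true pairs.
#' @param k Cutoff (default `nrow(planted)`).
#' @return Precision in `[0, 1]`.
#' @export
edge_precision <- function(edges, planted, k = nrow(planted)) {
  if (k < 1) stop("k must be positive")
  key <- function(d) paste(d$gene_a, d$gene_b, sep = "\r")
  top <- utils::head(edges, k)
  mean(key(top) %in% key(planted))
}
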