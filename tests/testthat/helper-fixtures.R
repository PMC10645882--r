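# Shared fixture builders; everything is generated in code.

make_em <- function(values, phenotype = NULL) {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("g%02d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("s%02d", seq_len(ncol(values)))
  expression_matrix(values, phenotype = phenotype, require_counts = FALSE)
}

make_annotation <- function(gene_ids, chromosome, biotype = "protein_coding",
                            gc = 50, len = 1000) {
  n <- length(gene_ids)
  validate_annotation(data.frame(
    gene_id = gene_ids,
    chromosome = rep_len(chromosome, n),
    biotype = rep_len(biotype, n),
    gc_percent = rep_len(gc, n),
    start_position = seq_len(n) * 10000,
    end_position = seq_len(n) * 10000 + rep_len(len, n),
    stringsAsFactors = FALSE))
}

# canonical edge list straight from gene pairs + scores (rank by |score|)
make_edges <- function(gene_a, gene_b, score) {
  swap <- gene_a > gene_b
  tmp <- gene_a[swap]; gene_a[swap] <- gene_b[swap]; gene_b[swap] <- tmp
  ord <- order(-abs(score), gene_a, gene_b)
  data.frame(gene_a = gene_a[ord], gene_b = gene_b[ord],
             score = score[ord], abs_score = abs(score)[ord],
             rank = seq_along(score), p_value = NA_real_,
             stringsAsFactors = FALSE)
}

# two-sample KS oracle: brute-force sup over pooled evaluation points
ks_oracle <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  max(abs(vapply(pts, function(t) mean(x <= t) - mean(y <= t), numeric(1))))
}

# upper-tail hypergeometric by complete enumeration of overlap counts
hyper_oracle <- function(overlap, set_size, universe_size, draw_size) {
  js <- overlap:min(set_size, draw_size)
  sum(choose(set_size, js) *
        choose(universe_size - set_size, draw_size - js)) /
    choose(universe_size, draw_size)
}

# a small planted two-clique graph with one bridging edge
two_clique_edges <- function(k = 6) {
  cl <- function(prefix) {
    g <- sprintf("%s%02d", prefix, seq_len(k))
    idx <- utils::combn(k, 2)
    data.frame(gene_a = g[idx[1, ]], gene_b = g[idx[2, ]],
               stringsAsFactors = FALSE)
  }
  rbind(cl("a"), cl("b"),
        data.frame(gene_a = "a01", gene_b = "b01", stringsAsFactors = FALSE))
}
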