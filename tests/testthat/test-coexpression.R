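test_that("MI of a profile with itself equals log2(B) on balanced bins", {
  x <- as.numeric(1:12)
  vals <- rbind(g1 = x, g2 = x + 100)  # strictly monotone copies
  em <- make_em(vals)
  mi <- mutual_information_matrix(em, n_bins = 3)
  expect_equal(mi["g1", "g2"], log2(3), tolerance = 1e-12)
  mi2 <- mutual_information_matrix(em, n_bins = 2)
  expect_equal(mi2["g1", "g2"], 1, tolerance = 1e-12)
})

test_that("MI matches the plug-in formula on a hand-evaluated 2-bin joint", {
  # equal-frequency 2-bin discretization of these 10 samples puts the
  # first five in bin 1 for both genes: joint counts [[5,0],[0,5]]
  vals <- rbind(g1 = as.numeric(1:10), g2 = as.numeric(11:20))
  mi <- mutual_information_matrix(make_em(vals), n_bins = 2)
  manual <- sum(rep(0.5, 2) * log2(0.5 / (0.5 * 0.5)))
  expect_equal(mi["g1", "g2"], manual)
  expect_equal(manual, 1)
})

test_that("MI is symmetric, non-negative and bounded by marginal entropy", {
  set.seed(10)
  vals <- matrix(rnorm(8 * 40), nrow = 8,
                 dimnames = list(sprintf("g%d", 1:8), NULL))
  colnames(vals) <- sprintf("s%02d", 1:40)
  em <- make_em(vals)
  B <- 5
  mi <- mutual_information_matrix(em, n_bins = B)
  expect_identical(mi, t(mi))
  expect_true(all(mi >= 0))
  ent <- apply(vals, 1, function(v) {
    tab <- tabulate(discretize_equal_frequency(v, B), B)
    p <- tab[tab > 0] / length(v)
    -sum(p * log2(p))
  })
  for (i in 1:7) for (j in (i + 1):8)
    expect_lte(mi[i, j], min(ent[i], ent[j]) + 1e-12)
})

test_that("constant genes are flagged and score zero", {
  vals <- rbind(g1 = as.numeric(1:20), g2 = rep(5, 20), g3 = rnorm(20))
  em <- make_em(vals)
  mi <- mutual_information_matrix(em, n_bins = 4)
  expect_equal(attr(mi, "flagged_genes"), "g2")
  expect_equal(unname(mi["g2", c("g1", "g3")]), c(0, 0))
  sp <- spearman_matrix(em)
  expect_equal(attr(sp, "flagged_genes"), "g2")
  expect_equal(unname(sp["g2", c("g1", "g3")]), c(0, 0))
})

test_that("Spearman handles monotone and tied profiles correctly", {
  up <- as.numeric(1:10); down <- as.numeric(10:1)
  vals <- rbind(g1 = up, g2 = down, g3 = up^3)
  sp <- spearman_matrix(make_em(vals))
  expect_equal(sp["g1", "g2"], -1)
  expect_equal(sp["g1", "g3"], 1)

  a <- c(1, 2, 2, 4); b <- c(3, 1, 1, 2)
  sp2 <- spearman_matrix(make_em(rbind(gA = a, gB = b)))
  oracle <- cor(rank(a, ties.method = "average"),
                rank(b, ties.method = "average"))
  expect_equal(sp2["gA", "gB"], oracle, tolerance = 1e-12)
})

test_that("Spearman and MI are invariant under strictly monotone transforms", {
  set.seed(11)
  vals <- matrix(rgamma(6 * 30, 2, 1), nrow = 6,
                 dimnames = list(sprintf("g%d", 1:6), sprintf("s%02d", 1:30)))
  em <- make_em(vals)
  trans <- vals; trans[1, ] <- exp(trans[1, ]); trans[2, ] <- log(trans[2, ] + 1)
  em_t <- expression_matrix(trans, require_counts = FALSE)
  expect_equal(spearman_matrix(em)[1:6, 1:6],
               spearman_matrix(em_t)[1:6, 1:6], tolerance = 1e-12)
  expect_equal(mutual_information_matrix(em, 5)[1:6, 1:6],
               mutual_information_matrix(em_t, 5)[1:6, 1:6],
               tolerance = 1e-12)
})

test_that("pooled-null p-values follow the add-one rule at the extremes", {
  null <- structure(list(method = "spearman", n_permutations = 1,
                         pairs_per_permutation = 99,
                         null_scores = seq(0.01, 0.99, by = 0.01), seed = 1),
                    class = "null_distribution")
  N <- 99
  expect_equal(edge_p_values(1.5, null), 1 / (N + 1))
  expect_equal(edge_p_values(0.005, null), 1)
  expect_equal(edge_p_values(0.01, null), 1)      # score == min(null)
  expect_equal(edge_p_values(0.985, null), 2 / (N + 1))
  p <- edge_p_values(0.5, null, alpha = 1e-5)
  expect_match(attr(p, "warning"), "minimum attainable")
})

test_that("permutation null yields uniform p-values under independence", {
  set.seed(12)
  vals <- matrix(rnorm(60 * 100), nrow = 60,
                 dimnames = list(sprintf("g%02d", 1:60), sprintf("s%03d", 1:100)))
  em <- make_em(vals)
  null <- permutation_null(em, "spearman", n_permutations = 10,
                           pairs_per_permutation = 2000, seed = 77)
  sp <- spearman_matrix(em)
  p <- edge_p_values(abs(sp[upper.tri(sp)]), null)
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("edge ranking is a canonical permutation with lexicographic ties", {
  scores <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  scores["A", "B"] <- scores["B", "A"] <- 0.9
  scores["A", "C"] <- scores["C", "A"] <- 0.5
  scores["B", "C"] <- scores["C", "B"] <- 0.7
  edges <- rank_edges(scores)
  expect_equal(paste(edges$gene_a, edges$gene_b), c("A B", "B C", "A C"))
  expect_equal(edges$rank, 1:3)

  tied <- scores; tied["A", "C"] <- tied["C", "A"] <- 0.9
  edges2 <- rank_edges(tied)
  expect_equal(paste(edges2$gene_a, edges2$gene_b)[1:2], c("A B", "A C"))

  # negative scores rank by absolute value
  neg <- scores; neg["A", "B"] <- neg["B", "A"] <- -0.95
  expect_equal(rank_edges(neg)$score[1], -0.95)

  expect_warning(rank_edges(scores, top_k = 10), "exceeds available")
  # every retained pair appears exactly once
  set.seed(13)
  big <- matrix(rnorm(20 * 20), 20, 20); big <- big + t(big)
  dimnames(big) <- list(sprintf("g%02d", 1:20), sprintf("g%02d", 1:20))
  e <- rank_edges(big)
  expect_equal(nrow(e), choose(20, 2))
  expect_false(any(duplicated(paste(e$gene_a, e$gene_b))))
  expect_equal(e$rank, seq_len(nrow(e)))
})

test_that("planted modules are recovered with high precision at modest n", {
  study <- generate_study(n_genes = 300, n_chromosomes = 6, n_samples = 100,
                          n_modules = 3, module_size = 15,
                          pseudogene_module_size = 10, seed = 17)
  canc <- study$cancer$matrix
  planted <- study$cancer$truth$planted_edges
  sp <- rank_edges(spearman_matrix(canc), top_k = nrow(planted))
  expect_gte(edge_precision(sp, planted), 0.9)
  mi <- rank_edges(mutual_information_matrix(canc), top_k = nrow(planted))
  expect_gte(edge_precision(mi, planted), 0.9)
})
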