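fake_de <- function(ids, classes) {
  data.frame(gene_id = ids, log2FoldChange = ifelse(classes == "over", 1,
                                                    ifelse(classes == "under", -1, 0)),
             p_value = 0.5, padj = 0.5, class = classes,
             stringsAsFactors = FALSE)
}

test_that("BH adjustment matches hand-computed step-up values", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(c(0.01, 0.04)), c(0.02, 0.04))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(40)
  p <- runif(50)
  adj <- bh_adjust(p)
  ord <- order(p)
  expect_true(all(diff(adj[ord]) >= -1e-12))
  expect_true(all(adj <= 1 & adj >= p))
})

test_that("hypergeometric p matches complete enumeration on small urns", {
  # universe 20, set 5, community 5, full overlap: 1 / C(20,5)
  universe <- sprintf("u%02d", 1:20)
  comm <- list(c1 = universe[1:5])
  sets <- list(S = universe[1:5])
  res <- hypergeom_enrich(comm, sets, universe, padj_threshold = 1e-3)
  expect_equal(res$p_value, 1 / choose(20, 5), tolerance = 1e-12)
  # set == universe -> p = 1 for any community
  res2 <- hypergeom_enrich(comm, list(S = universe), universe)
  expect_equal(res2$p_value, 1)
  # zero overlap, small set -> p ~ 1, never enriched
  res3 <- hypergeom_enrich(list(c1 = universe[1:5]),
                           list(S = universe[16:18]), universe)
  expect_gt(res3$p_value, 0.5)
  expect_false(res3$enriched)

  set.seed(41)
  for (i in 1:30) {
    N <- sample(8:25, 1)
    uni <- sprintf("x%02d", seq_len(N))
    K <- sample(1:N, 1); n <- sample(1:N, 1)
    st <- sample(uni, K); cm <- sample(uni, n)
    ov <- length(intersect(st, cm))
    got <- hypergeom_enrich(list(c = cm), list(S = st), uni)$p_value
    expect_equal(got, hyper_oracle(ov, K, N, n), tolerance = 1e-12)
  }
  expect_error(hypergeom_enrich(list(c = "zz"), list(S = "zz"), character(0)),
               "empty universe")
  expect_error(hypergeom_enrich(list(c = "zz"), list(S = "u01"),
                                sprintf("u%02d", 1:5)), "outside the universe")
})

test_that("trend endpoints follow the definition exactly", {
  de <- fake_de(sprintf("g%d", 1:6),
                c("over", "over", "over", "under", "under", "under"))
  expect_equal(de_trend(sprintf("g%d", 1:3), de)$trend, 1)
  expect_equal(de_trend(sprintf("g%d", 4:6), de)$trend, -1)
  expect_equal(de_trend(sprintf("g%d", 1:6), de)$trend, 0)
  # unscored genes count as unclassified in the denominator
  half <- de_trend(c("g1", "g2", "unknown1", "unknown2"), de)
  expect_equal(half$trend, 0.5)
  expect_equal(half$n_unclassified, 2)
  expect_error(de_trend(character(0), de), "empty community")
})

test_that("trend is antisymmetric under sign flip on fuzzed communities", {
  set.seed(42)
  ids <- sprintf("g%03d", 1:200)
  for (i in 1:100) {
    classes <- sample(c("over", "under", "unclassified"), 200, replace = TRUE)
    flipped <- ifelse(classes == "over", "under",
                      ifelse(classes == "under", "over", classes))
    members <- sample(ids, sample(2:50, 1))
    t1 <- de_trend(members, fake_de(ids, classes))$trend
    t2 <- de_trend(members, fake_de(ids, flipped))$trend
    expect_equal(t1, -t2)
    expect_lte(abs(t1), 1)
  }
})

test_that("median-of-ratios size factors recover scalings", {
  set.seed(43)
  base <- matrix(rnbinom(400 * 4, mu = 80, size = 8), nrow = 400) + 1
  dimnames(base) <- list(sprintf("g%03d", 1:400), sprintf("s%d", 1:4))
  expect_equal(unname(median_of_ratios_size_factors(cbind(base[, 1], base[, 1]))),
               c(1, 1))
  scaled <- cbind(a = base[, 1], b = 3 * base[, 1])
  sf <- median_of_ratios_size_factors(scaled)
  expect_equal(unname(sf["b"] / sf["a"]), 3, tolerance = 1e-9)
})

test_that("NB Wald recovers a planted fold change of 4 within tolerance", {
  set.seed(44)
  n_genes <- 600; n <- 50
  mu <- rep(100, n_genes)
  up <- 1:30; down <- 31:60
  mu1 <- mu; mu1[up] <- 400; mu1[down] <- 25
  mk <- function(mu_vec, tag) {
    m <- matrix(rnbinom(n_genes * n, size = 10, mu = mu_vec), nrow = n_genes)
    dimnames(m) <- list(sprintf("g%03d", seq_len(n_genes)), paste0(tag, 1:n))
    m
  }
  canc <- expression_matrix(mk(mu1, "x"), phenotype = rep("cancer", n))
  ctrl <- expression_matrix(mk(mu, "c"), phenotype = rep("control", n))
  de <- nb_wald_de(canc, ctrl)
  est <- de$log2FoldChange[match(sprintf("g%03d", up), de$gene_id)]
  expect_lt(abs(mean(est) - 2), 0.2)
  expect_true(all(de$class[match(sprintf("g%03d", up), de$gene_id)] == "over"))
  expect_true(all(de$class[match(sprintf("g%03d", down), de$gene_id)] == "under"))
  expect_true(all(de$padj >= de$p_value))
})

test_that("NB Wald input validation and all-zero exclusion work", {
  set.seed(45)
  mk <- function(tag) {
    m <- matrix(rnbinom(50 * 4, mu = 30, size = 5), nrow = 50)
    dimnames(m) <- list(sprintf("g%02d", 1:50), paste0(tag, 1:4))
    m
  }
  a <- mk("a"); b <- mk("b")
  a["g01", ] <- 0; b["g01", ] <- 0
  de <- nb_wald_de(expression_matrix(a, phenotype = rep("x", 4)),
                   expression_matrix(b, phenotype = rep("c", 4)))
  expect_equal(attr(de, "excluded_genes"), "g01")
  expect_false("g01" %in% de$gene_id)
  expect_error(nb_wald_de(expression_matrix(a[, 1:2], phenotype = rep("x", 2)),
                          expression_matrix(b[, 1:2], phenotype = rep("c", 2))),
               "at least 3 samples")
})

test_that("shared-process trend matrix intersects enriched sets correctly", {
  mk_enr <- function(sets_enriched) {
    data.frame(community_id = "c1", set_id = c("BP1", "BP2", "BP3"),
               community_size = 3, set_size = 3, overlap_count = 3,
               p_value = 1e-20, padj = 1e-20,
               enriched = c("BP1", "BP2", "BP3") %in% sets_enriched,
               stringsAsFactors = FALSE)
  }
  comm <- list(c1 = c("g1", "g2"))
  de_over <- fake_de(c("g1", "g2"), c("over", "over"))
  de_under <- fake_de(c("g1", "g2"), c("under", "under"))
  m <- shared_bp_matrix(
    list(A = mk_enr(c("BP1", "BP2")), B = mk_enr(c("BP1", "BP3"))),
    list(A = comm, B = comm),
    list(A = de_over, B = de_under))
  expect_equal(colnames(m), "BP1")   # only BP1 shared
  expect_equal(unname(m[, "BP1"]), c(1, -1))

  expect_warning(
    m0 <- shared_bp_matrix(
      list(A = mk_enr("BP1"), B = mk_enr("BP2")),
      list(A = comm, B = comm),
      list(A = de_over, B = de_under)),
    "no biological process")
  expect_equal(ncol(m0), 0)

  # three-phenotype brute-force set intersection
  enr3 <- list(A = mk_enr(c("BP1", "BP2")), B = mk_enr(c("BP1", "BP3")),
               C = mk_enr(c("BP1", "BP2", "BP3")))
  oracle <- Reduce(intersect, lapply(enr3, function(t) t$set_id[t$enriched]))
  m3 <- shared_bp_matrix(enr3, list(A = comm, B = comm, C = comm),
                         list(A = de_over, B = de_under, C = de_over))
  expect_setequal(colnames(m3), oracle)
})
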