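test_that("annotation generator honours chromosome and biotype layout", {
  ann <- generate_annotation(100, c(A = 50, B = 50), seed = 3)
  expect_equal(as.vector(table(ann$chromosome)[c("A", "B")]), c(50, 50))
  expect_true(all(ann$end_position >= ann$start_position))
  # deterministic for fixed seed
  expect_identical(ann, generate_annotation(100, c(A = 50, B = 50), seed = 3))
  expect_false(identical(ann, generate_annotation(100, c(A = 50, B = 50),
                                                  seed = 4)))
  expect_error(generate_annotation(2, c(A = 1, B = 0, C = 1), seed = 1),
               "smaller than the number of chromosomes")
})

test_that("biotype counts follow deterministic largest-remainder rounding", {
  ann <- generate_annotation(
    1000, c(A = 1000),
    biotype_proportions = c(protein_coding = 0.8, pseudogene = 0.2), seed = 1)
  expect_equal(sum(ann$biotype == "pseudogene"), 200)
  expect_equal(sum(ann$biotype == "protein_coding"), 800)
  # fractional case: 0.335/0.335/0.33 of 10 -> remainders decide ties
  ann2 <- generate_annotation(
    10, c(A = 10),
    biotype_proportions = c(x = 0.335, y = 0.335, z = 0.33), seed = 1)
  expect_equal(as.vector(table(ann2$biotype)[c("x", "y", "z")]), c(4, 3, 3))
  # pseudogenes carry a protein-coding parent
  pg <- ann[ann$biotype == "pseudogene", ]
  expect_true(all(pg$parent_gene_id %in%
                    ann$gene_id[ann$biotype == "protein_coding"]))
})

test_that("module specs validate their invariants", {
  expect_error(module_spec("m", c("g1", "g2"), 1.0), "positive semidefinite")
  expect_error(module_spec("m", c("g1", "g1"), 0.5), "duplicated")
  ann <- make_annotation(c("g1", "g2", "g3"), c("1", "2", "2"))
  bad <- list(module_spec("m", c("g1", "g2"), 0.5, chromosome_restricted = TRUE))
  expect_error(generate_cohort(ann, bad, "control", 10, seed = 1),
               "spans several chromosomes")
  overlapping <- list(module_spec("m1", c("g1", "g2"), 0.5),
                      module_spec("m2", c("g2", "g3"), 0.5))
  expect_error(generate_cohort(ann, overlapping, "control", 10, seed = 1),
               "disjoint")
})

test_that("zero latent correlation gives near-independent profiles", {
  ann <- make_annotation(sprintf("g%02d", 1:10), "1")
  mods <- list(module_spec("m", ann$gene_id, 0))
  coh <- generate_cohort(ann, mods, "control", n_samples = 500, seed = 5)
  sp <- spearman_matrix(coh$matrix)
  offdiag <- sp[upper.tri(sp)]
  expect_lt(abs(median(offdiag)), 0.05)
})

test_that("planted latent correlation reproduces the copula-induced Spearman", {
  # independent Monte-Carlo oracle: the same copula construction written
  # out directly at large n, for a single NB pair
  rho <- 0.9; mu <- c(50, 200); disp <- 0.1
  set.seed(99)
  n_big <- 50000
  f <- rnorm(n_big)
  z1 <- sqrt(rho) * f + sqrt(1 - rho) * rnorm(n_big)
  z2 <- sqrt(rho) * f + sqrt(1 - rho) * rnorm(n_big)
  x1 <- qnbinom(pnorm(z1), size = 1 / disp, mu = mu[1])
  x2 <- qnbinom(pnorm(z2), size = 1 / disp, mu = mu[2])
  oracle <- cor(x1, x2, method = "spearman")

  ann <- make_annotation(c("gA", "gB"), "1")
  mods <- list(module_spec("m", c("gA", "gB"), rho))
  coh <- generate_cohort(ann, mods, "control", n_samples = 500,
                         nb_mean_range = c(50, 200), nb_dispersion = disp,
                         seed = 11)
  got <- cor(coh$matrix$values["gA", ], coh$matrix$values["gB", ],
             method = "spearman")
  expect_lt(abs(got - oracle), 0.1)
})

test_that("planted fold changes shift cancer means by the NB ratio", {
  ann <- make_annotation(sprintf("g%02d", 1:20), "1")
  de <- c(g01 = 2)
  ctrl <- generate_cohort(ann, list(), "control", n_samples = 500, seed = 21)
  canc <- generate_cohort(ann, list(), "cancer", n_samples = 500,
                          de_spec = de, seed = 22)
  ratio <- mean(canc$matrix$values["g01", ]) / mean(ctrl$matrix$values["g01", ])
  expect_gt(ratio, 3.4)
  expect_lt(ratio, 4.7)
  expect_equal(unname(canc$truth$log2fc_true["g01"]), 2)
  expect_equal(unname(canc$truth$log2fc_true["g02"]), 0)
})

test_that("cohorts are reproducible and truth edges are the module cliques", {
  ann <- make_annotation(sprintf("g%02d", 1:12), rep(c("1", "2"), each = 6))
  mods <- list(module_spec("m1", c("g01", "g02", "g03"), 0.7),
               module_spec("m2", c("g07", "g08"), 0.7))
  a <- generate_cohort(ann, mods, "cancer", n_samples = 30, seed = 8)
  b <- generate_cohort(ann, mods, "cancer", n_samples = 30, seed = 8)
  expect_identical(a$matrix$values, b$matrix$values)
  expect_equal(nrow(a$truth$planted_edges), choose(3, 2) + choose(2, 2))
  expect_true(all(a$truth$planted_edges$gene_a < a$truth$planted_edges$gene_b))
  expect_equal(unname(a$truth$module_assignment[c("g01", "g07", "g12")]),
               c("m1", "m2", NA))
})

test_that("NB marginals are recovered by method of moments within 10%", {
  ann <- make_annotation(sprintf("g%02d", 1:10), "1")
  coh <- generate_cohort(ann, list(), "control", n_samples = 1000,
                         nb_mean_range = c(50, 400), nb_dispersion = 0.15,
                         seed = 31)
  x <- coh$matrix$values
  mu_target <- exp(seq(log(50), log(400), length.out = 10))
  for (g in c(1, 5, 10)) {
    m <- mean(x[g, ]); v <- var(x[g, ])
    mu_true <- sort(mu_target)[rank(rowMeans(x))[g]] # identify by rank
    expect_lt(abs(m - mu_true) / mu_true, 0.10)
    disp_hat <- (v - m) / m^2
    expect_lt(abs(disp_hat - 0.15) / 0.15, 0.10)
  }
})

test_that("default study layout plants the advertised architecture", {
  study <- generate_study(n_genes = 400, n_chromosomes = 8, n_samples = 10,
                          n_modules = 4, module_size = 10,
                          pseudogene_module_size = 10, seed = 2)
  chrom <- setNames(study$annotation$chromosome, study$annotation$gene_id)
  for (m in study$modules_cancer[1:4])
    expect_length(unique(chrom[m$member_genes]), 1)
  n_chrom_ctrl <- vapply(study$modules_control, function(m)
    length(unique(chrom[m$member_genes])), integer(1))
  expect_true(all(n_chrom_ctrl > 1))
  pg <- study$modules_cancer[[5]]
  bio <- setNames(study$annotation$biotype, study$annotation$gene_id)
  expect_true(all(grepl("pseudogene", bio[pg$member_genes])))
  expect_equal(unname(study$de_spec[pg$member_genes]), rep(2, 10))
})
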