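#' Remove low-count genes
#'
#' A gene is removed if it hits ANY of three rules, evaluated on the joint
#' (cancer + control) matrix:
#' \itemize{
#'   \item `low_quantile`: mean expression at or below the
#'     `quantile_cut` quantile of all gene means;
#'   \item `zero_majority`: zero in more than `zero_majority_fraction` of
#'     the samples;
#'   \item `low_mean`: mean expression strictly less than `mean_cut`.
#' }
#'
#' @param em An `expression_matrix` of raw counts.
#' @param quantile_cut Quantile of gene means below which genes are
#'   dropped (default 0.25).
#' @param zero_majority_fraction Zero-fraction above which a gene is
#'   dropped (default 0.5, i.e. a strict majority of zeros).
#' @param mean_cut Minimum mean expression (strict; a gene with mean
#'   exactly `mean_cut` is kept).
#' @param quantile_type Quantile convention passed to [stats::quantile()]
#'   (default 7, linear interpolation).
#' @return List with `matrix` (filtered `expression_matrix`) and `report`
#'   (a `NormalizationReport`-style list: `genes_removed_by_rule` counts a
#'   gene once per rule it hits, `n_removed` counts distinct genes,
#'   `removed_by_rule` lists ids).
#' @export
filter_low_expression <- function(em, quantile_cut = 0.25,
                                  zero_majority_fraction = 0.5,
                                  mean_cut = 10, quantile_type = 7) {
  stopifnot(inherits(em, "expression_matrix"))
  x <- em$values
  means <- rowMeans(x)
  zfrac <- rowMeans(x == 0)
  # quantile_cut = 0 disables the relative rule; being relative to its
  # input, it tightens under repeated application, unlike the two
  # absolute rules
  if (quantile_cut > 0) {
    qcut <- stats::quantile(means, quantile_cut, type = quantile_type,
                            names = FALSE)
    low_q <- means <= qcut
  } else {
    qcut <- NA_real_
    low_q <- rep(FALSE, length(means))
  }
  hit <- list(
    low_quantile = low_q,
    zero_majority = zfrac > zero_majority_fraction,
    low_mean = means < mean_cut)
  drop <- Reduce(`|`, hit)
  if (all(drop))
    stop("all genes removed by low-expression filters")
  keep <- rownames(x)[!drop]
  report <- list(
    genes_in = nrow(x),
    genes_out = length(keep),
    n_removed = sum(drop),
    genes_removed_by_rule = vapply(hit, sum, integer(1)),
    removed_by_rule = lapply(hit, function(h) rownames(x)[h]),
    params = list(quantile_cut = quantile_cut,
                  quantile_value = qcut,
                  zero_majority_fraction = zero_majority_fraction,
                  mean_cut = mean_cut, quantile_type = quantile_type),
    steps_applied = "filter_low_expression")
  list(matrix = subset_expression(em, genes = keep), report = report)
}

#' TMM effective size factors
#'
#' Trimmed-mean-of-M-values scaling via [edgeR::calcNormFactors()]. The
#' returned factor per sample is the library size times the TMM
#' normalization factor, rescaled to geometric mean 1, i.e. the effective
#' scaling to divide counts by.
#'
#' @param em An `expression_matrix` (or numeric count matrix).
#' @param reference_sample Optional sample id (or column index) to use as
#'   TMM reference; default lets edgeR pick the sample whose upper quartile
#'   is closest to the mean upper quartile.
#' @param trim_m Trim fraction on log-ratios (M-values), default 0.30.
#' @param trim_a Trim fraction on absolute intensities (A-values), default
#'   0.05.
#' @return Named numeric vector of positive size factors, geometric mean 1.
#' @export
tmm_size_factors <- function(em, reference_sample = NULL,
                             trim_m = 0.30, trim_a = 0.05) {
  x <- if (inherits(em, "expression_matrix")) em$values else em
  if (ncol(x) < 2) stop("TMM needs at least 2 samples")
  lib <- colSums(x)
  if (any(lib == 0))
    stop("sample(s) with all-zero counts: ",
         paste(colnames(x)[lib == 0], collapse = ", "))
  ref <- reference_sample
  if (is.character(ref)) ref <- match(ref, colnames(x))
  f <- edgeR::calcNormFactors(x, method = "TMM", refColumn = ref,
                              logratioTrim = trim_m, sumTrim = trim_a)
  eff <- lib * f
  eff <- eff / exp(mean(log(eff)))
  stats::setNames(eff, colnames(x))
}

# Map each bin's values, per sample, onto the sample-wide empirical
# distribution at the bin-internal rank grid (type-7 quantiles at
# (rank-1)/(m-1)).  A single bin therefore maps to itself exactly; several
# bins end up with matched distributions while within-bin rank order is
# preserved.
quantile_map_bins <- function(x, bins) {
  out <- x
  for (b in split(seq_along(x), bins)) {
    m <- length(b)
    r <- rank(x[b], ties.method = "average")
    p <- if (m == 1L) 0.5 else (r - 1) / (m - 1)
    out[b] <- stats::quantile(x, probs = p, type = 7, names = FALSE)
  }
  out
}

equal_frequency_bins <- function(v, n_bins) {
  n <- length(v)
  n_bins <- max(1L, min(n_bins, n))
  r <- rank(v, ties.method = "first")
  as.integer(floor((r - 1) * n_bins / n) + 1L)
}

#' Correct GC-content and gene-length expression bias
#'
#' Within each sample, genes are split into `n_bins` equal-frequency bins
#' by GC content and the bin value distributions are equalized by a
#' full-quantile map onto the sample-wide distribution; the same is then
#' done for gene length. Within-bin rank order per sample is preserved.
#'
#' @param em An `expression_matrix`.
#' @param annotation Annotation table covering every gene in `em`.
#' @param n_bins Number of equal-frequency bins (default 10).
#' @return A corrected `expression_matrix`.
#' @export
gc_length_correct <- function(em, annotation, n_bins = 10L) {
  stopifnot(inherits(em, "expression_matrix"))
  idx <- match(em$gene_ids, annotation$gene_id)
  missing <- em$gene_ids[is.na(idx)]
  if (length(missing))
    stop("gene(s) missing from annotation: ",
         paste(utils::head(missing, 5), collapse = ", "))
  gc <- annotation$gc_percent[idx]
  len <- annotation$length[idx]
  if (anyNA(gc) || anyNA(len))
    stop("gene(s) with missing GC or length: ",
         paste(utils::head(em$gene_ids[is.na(gc) | is.na(len)], 5),
               collapse = ", "))
  gc_bins <- equal_frequency_bins(gc, n_bins)
  len_bins <- equal_frequency_bins(len, n_bins)
  vals <- em$values
  for (j in seq_len(ncol(vals))) {
    vals[, j] <- quantile_map_bins(vals[, j], gc_bins)
    vals[, j] <- quantile_map_bins(vals[, j], len_bins)
  }
  expression_matrix(vals, phenotype = stats::setNames(em$phenotype, em$sample_ids),
                    require_counts = FALSE)
}

#' Between-lane full-quantile normalization
#'
#' Makes every sample's value distribution identical (the mean empirical
#' distribution), via [limma::normalizeQuantiles()].
#'
#' @param em An `expression_matrix`.
#' @return A normalized `expression_matrix`.
#' @export
between_lane_quantile <- function(em) {
  stopifnot(inherits(em, "expression_matrix"))
  if (ncol(em$values) == 0 || nrow(em$values) == 0)
    stop("empty expression matrix")
  vals <- limma::normalizeQuantiles(em$values)
  dimnames(vals) <- dimnames(em$values)
  expression_matrix(vals, phenotype = stats::setNames(em$phenotype, em$sample_ids),
                    require_counts = FALSE)
}

#' Full pre-processing pipeline on a joint cancer + control matrix
#'
#' Order: low-expression filtering, GC/length full-quantile correction,
#' between-lane full-quantile normalization, TMM scaling. A PCA separation
#' diagnostic on the final matrix is attached in place of a multivariate
#' noise-reduction step.
#'
#' @param em Joint raw-count `expression_matrix` (phenotype labels set).
#' @param annotation Annotation table.
#' @param quantile_cut,zero_majority_fraction,mean_cut Filter thresholds,
#'   see [filter_low_expression()].
#' @param n_bins GC/length bin count.
#' @param trim_m,trim_a TMM trim fractions.
#' @return List with `matrix` (normalized `expression_matrix`), `counts`
#'   (filtered raw counts, for count-based differential expression),
#'   `report` (filter report, `size_factors`, `steps_applied`,
#'   `pca_diagnostic`).
#' @export
preprocess_counts <- function(em, annotation, quantile_cut = 0.25,
                              zero_majority_fraction = 0.5, mean_cut = 10,
                              n_bins = 10L, trim_m = 0.30, trim_a = 0.05) {
  filt <- filter_low_expression(em, quantile_cut, zero_majority_fraction,
                                mean_cut)
  corrected <- gc_length_correct(filt$matrix, annotation, n_bins)
  lane <- between_lane_quantile(corrected)
  sf <- tmm_size_factors(lane, trim_m = trim_m, trim_a = trim_a)
  vals <- sweep(lane$values, 2, sf, "/")
  norm <- expression_matrix(vals,
                            phenotype = stats::setNames(em$phenotype, em$sample_ids),
                            require_counts = FALSE)
  report <- filt$report
  report$size_factors <- sf
  report$steps_applied <- c("filter_low_expression", "gc_length_correct",
                            "between_lane_quantile", "tmm_scaling")
  report$pca_diagnostic <- pca_phenotype_diagnostic(norm)
  list(matrix = norm, counts = filt$matrix, report = report)
}

#' PCA phenotype-separation diagnostic
#'
#' Principal components of log2(x + 1) expression with a simple separation
#' summary: the ratio of between-phenotype to total variance on each of
#' the leading components. Emitted as a table so that phenotype mixing
#' after normalization can be audited.
#'
#' @param em An `expression_matrix` with phenotype labels.
#' @param n_components Number of leading components to report.
#' @return List with `scores` (samples x components data.frame incl.
#'   phenotype) and `separation` (per-component between/total variance
#'   ratio).
#' @export
pca_phenotype_diagnostic <- function(em, n_components = 3L) {
  stopifnot(inherits(em, "expression_matrix"))
  lx <- t(log2(em$values + 1))
  keep <- which(apply(lx, 2, stats::sd) > 0)
  p <- stats::prcomp(lx[, keep, drop = FALSE], center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(p$x))
  scores <- data.frame(sample_id = em$sample_ids,
                       phenotype = em$phenotype,
                       p$x[, seq_len(k), drop = FALSE],
                       stringsAsFactors = FALSE, check.names = FALSE)
  sep <- vapply(seq_len(k), function(i) {
    v <- p$x[, i]
    grand <- mean(v)
    between <- sum(tapply(v, em$phenotype, function(g) length(g) * (mean(g) - grand)^2))
    between / sum((v - grand)^2)
  }, numeric(1))
  list(scores = scores,
       separation = stats::setNames(sep, colnames(p$x)[seq_len(k)]))
}
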