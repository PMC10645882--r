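#' Construct an expression matrix object
#'
#' Lightweight container for a genes x samples expression matrix together
#' with a per-sample phenotype label (a cancer name or `"control"`).
#'
#' @param values Numeric matrix, genes in rows, samples in columns. Must
#'   carry unique rownames (gene ids) and colnames (sample ids).
#' @param phenotype Optional character vector of per-sample labels, either
#'   named by sample id or in column order. Defaults to `"unlabelled"`.
#' @param require_counts If `TRUE`, values must be non-negative.
#' @return An object of class `expression_matrix`: a list with elements
#'   `values`, `gene_ids`, `sample_ids`, `phenotype`.
#' @export
expression_matrix <- function(values, phenotype = NULL, require_counts = TRUE) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have gene rownames and sample colnames")
  dup_g <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup_g))
    stop("duplicated gene id(s): ", paste(dup_g, collapse = ", "))
  dup_s <- unique(colnames(values)[duplicated(colnames(values))])
  if (length(dup_s))
    stop("duplicated sample id(s): ", paste(dup_s, collapse = ", "))
  if (anyNA(values))
    stop("expression values contain NA")
  if (require_counts && any(values < 0))
    stop("negative values in a count matrix")
  storage.mode(values) <- "double"
  if (is.null(phenotype)) {
    phenotype <- rep("unlabelled", ncol(values))
    names(phenotype) <- colnames(values)
  } else {
    if (is.null(names(phenotype))) {
      if (length(phenotype) != ncol(values))
        stop("phenotype length does not match number of samples")
      names(phenotype) <- colnames(values)
    }
    missing <- setdiff(colnames(values), names(phenotype))
    if (length(missing))
      stop("phenotype missing for sample(s): ", paste(missing, collapse = ", "))
    phenotype <- phenotype[colnames(values)]
  }
  structure(
    list(values = values,
         gene_ids = rownames(values),
         sample_ids = colnames(values),
         phenotype = as.character(stats::setNames(phenotype, colnames(values)))),
    class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  tab <- table(x$phenotype)
  cat("phenotypes:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Subset an expression matrix by genes and/or samples
#'
#' @param em An `expression_matrix`.
#' @param genes,samples Character vectors of ids to keep (default: all).
#' @return A new `expression_matrix`.
#' @export
subset_expression <- function(em, genes = NULL, samples = NULL) {
  stopifnot(inherits(em, "expression_matrix"))
  g <- if (is.null(genes)) em$gene_ids else genes
  s <- if (is.null(samples)) em$sample_ids else samples
  missing_g <- setdiff(g, em$gene_ids)
  if (length(missing_g))
    stop("unknown gene id(s): ", paste(utils::head(missing_g, 5), collapse = ", "))
  missing_s <- setdiff(s, em$sample_ids)
  if (length(missing_s))
    stop("unknown sample id(s): ", paste(utils::head(missing_s, 5), collapse = ", "))
  expression_matrix(em$values[g, s, drop = FALSE],
                    phenotype = stats::setNames(em$phenotype, em$sample_ids)[s],
                    require_counts = FALSE)
}

#' Read an expression matrix from TSV
#'
#' Expects a tab-separated file whose header row holds sample ids and whose
#' first column holds gene ids.
#'
#' @param path Path to the TSV file.
#' @param phenotype_map Optional named character vector mapping sample id to
#'   phenotype label.
#' @param require_counts Passed to [expression_matrix()].
#' @return An `expression_matrix`.
#' @export
read_expression_matrix <- function(path, phenotype_map = NULL,
                                   require_counts = TRUE) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character")
  if (ncol(raw) < 2) stop("expression TSV needs a gene-id column plus samples: ", path)
  gene_ids <- raw[[1L]]
  dup <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup))
    stop("duplicated gene id(s) in ", path, ": ", paste(dup, collapse = ", "))
  vals <- as.matrix(raw[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals)))
  if (anyNA(num)) {
    bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)[1L, , drop = TRUE]
    stop(sprintf("non-numeric value at gene '%s', sample '%s' in %s",
                 gene_ids[bad[1L]], colnames(vals)[bad[2L]], path))
  }
  dimnames(num) <- list(gene_ids, colnames(vals))
  expression_matrix(num, phenotype = phenotype_map, require_counts = require_counts)
}

#' Write an expression matrix to TSV
#'
#' @param em An `expression_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(em, path) {
  stopifnot(inherits(em, "expression_matrix"))
  df <- data.frame(gene_id = em$gene_ids, em$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Normalize chromosome labels
#'
#' Strips a leading `"chr"` prefix (any case) and upper-cases the X, Y and
#' MT labels; anything else is kept verbatim. Cis/trans classification only
#' needs label equality, so no assembly-specific renaming is attempted.
#'
#' @param x Character vector of chromosome labels.
#' @return Normalized character vector.
#' @export
normalize_chromosome <- function(x) {
  x <- sub("^[Cc][Hh][Rr]", "", as.character(x))
  sexmt <- toupper(x) %in% c("X", "Y", "MT", "M")
  x[sexmt] <- toupper(x[sexmt])
  x[x == "M"] <- "MT"
  x
}

#' Read a BioMart-style gene annotation table
#'
#' Required tab-separated columns: `gene_id`, `chromosome`, `biotype`,
#' `gc_percent`, `start_position`, `end_position`; optional
#' `parent_gene_id` (pseudogene parent). A `length` column is derived as
#' end minus start, and chromosome labels are normalized with
#' [normalize_chromosome()].
#'
#' @param path Path to the annotation TSV.
#' @return A `data.frame` with one row per gene.
#' @export
read_gene_annotation <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  required <- c("gene_id", "chromosome", "biotype", "gc_percent",
                "start_position", "end_position")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("annotation file ", path, " lacks column(s): ",
         paste(missing, collapse = ", "))
  validate_annotation(df)
}

#' Validate (and finish deriving) an annotation table
#'
#' @param df A data.frame carrying at least the required annotation columns.
#' @return The validated data.frame with `length` derived and chromosome
#'   labels normalized.
#' @export
validate_annotation <- function(df) {
  dup <- unique(df$gene_id[duplicated(df$gene_id)])
  if (length(dup))
    stop("duplicated gene id(s) in annotation: ", paste(dup, collapse = ", "))
  df$chromosome <- normalize_chromosome(df$chromosome)
  df$gc_percent <- as.numeric(df$gc_percent)
  if (any(df$gc_percent < 0 | df$gc_percent > 100, na.rm = TRUE))
    stop("gc_percent outside [0, 100]")
  df$start_position <- as.numeric(df$start_position)
  df$end_position <- as.numeric(df$end_position)
  bad <- df$gene_id[df$end_position < df$start_position]
  if (length(bad))
    stop("end_position < start_position for gene(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  df$length <- df$end_position - df$start_position
  if (!"parent_gene_id" %in% names(df)) df$parent_gene_id <- NA_character_
  rownames(df) <- NULL
  df
}

#' Write an annotation table to TSV
#' @param annotation Annotation data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_annotation <- function(annotation, path) {
  utils::write.table(annotation, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' One set per line: set id, description, then member gene ids, all
#' tab-separated. Lines with fewer than three fields are rejected with the
#' offending line number.
#'
#' @param path Path to the GMT file.
#' @return A `gene_set_collection`: named list of character member vectors,
#'   with a `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop("malformed GMT line ", which(nf < 3L)[1L], " in ", path,
         " (needs id, description and at least one member)")
  ids <- vapply(fields, `[[`, character(1), 1L)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicated set id(s) in ", path, ": ", paste(dup, collapse = ", "))
  members <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(members) <- ids
  structure(members,
            descriptions = stats::setNames(vapply(fields, `[[`, character(1), 2L), ids),
            class = "gene_set_collection")
}

#' Write a gene-set collection to GMT
#' @param sets A `gene_set_collection` or named list of member vectors.
#' @param path Output path.
#' @param descriptions Optional named descriptions (default taken from the
#'   object's attribute, else the set id).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- attr(sets, "descriptions")
  if (is.null(descriptions))
    descriptions <- stats::setNames(names(sets), names(sets))
  lines <- vapply(names(sets), function(id) {
    paste(c(id, descriptions[[id]], sets[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a ranked edge list to TSV
#'
#' Canonical form: within each row `gene_a < gene_b` lexicographically, rows
#' sorted by rank. Columns: gene_a, gene_b, score, abs_score, rank, p_value.
#'
#' @param edges A ranked edge list data.frame (see [rank_edges()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(edges, path) {
  required <- c("gene_a", "gene_b", "score", "abs_score", "rank")
  missing <- setdiff(required, names(edges))
  if (length(missing))
    stop("edge list lacks column(s): ", paste(missing, collapse = ", "))
  if (any(edges$gene_a >= edges$gene_b))
    stop("edge list not canonical: gene_a must sort before gene_b")
  if (!"p_value" %in% names(edges)) edges$p_value <- NA_real_
  out <- data.frame(
    gene_a = edges$gene_a, gene_b = edges$gene_b,
    score = sprintf("%.10g", edges$score),
    abs_score = sprintf("%.10g", edges$abs_score),
    rank = edges$rank,
    p_value = ifelse(is.na(edges$p_value), "NA", sprintf("%.10g", edges$p_value)),
    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a ranked edge list from TSV
#'
#' @param path Path written by [write_edge_list()].
#' @return A data.frame with columns gene_a, gene_b, score, abs_score,
#'   rank, p_value.
#' @export
read_edge_list <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  required <- c("gene_a", "gene_b", "score", "abs_score", "rank")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("edge list ", path, " lacks column(s): ", paste(missing, collapse = ", "))
  if (any(df$gene_a >= df$gene_b))
    stop("edge list ", path, " not canonical (gene_a must sort before gene_b)")
  if (is.unsorted(df$rank)) df <- df[order(df$rank), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Export a network with node attributes as GraphML
#'
#' @param edges Edge data.frame with gene_a/gene_b (score kept as an edge
#'   attribute when present).
#' @param node_attributes Optional data.frame with a `gene_id` column plus
#'   attribute columns (chromosome, biotype, log2FC class, ...).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_graphml_network <- function(edges, path, node_attributes = NULL) {
  g <- igraph::graph_from_data_frame(
    edges[, c("gene_a", "gene_b", intersect("score", names(edges)))],
    directed = FALSE)
  if (!is.null(node_attributes)) {
    stopifnot("gene_id" %in% names(node_attributes))
    idx <- match(igraph::V(g)$name, node_attributes$gene_id)
    for (col in setdiff(names(node_attributes), "gene_id")) {
      g <- igraph::set_vertex_attr(g, col, value = node_attributes[[col]][idx])
    }
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
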