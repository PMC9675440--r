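#' Annotated cell x gene count matrix
#'
#' A sparse (or dense) nonnegative cells x genes matrix with per-cell
#' metadata carrying a cluster label. Metadata rows correspond one-to-one to
#' matrix rows; gene lookup is case-sensitive exact match (with an optional
#' alias map, see [subset_by_cluster_and_gene()]).
#'
#' @param matrix Cells x genes matrix (base or `Matrix` sparse),
#'   nonnegative.
#' @param meta Data frame with columns `cell_id` and `cluster`, one row per
#'   matrix row.
#' @param genes Character vector of gene identifiers, one per matrix column.
#' @return An object of class `arc_counts`.
#' @export
count_matrix <- function(matrix, meta, genes) {
  if (!all(c("cell_id", "cluster") %in% names(meta))) {
    abort("metadata must have columns cell_id and cluster")
  }
  meta <- as_tibble(meta)
  if (nrow(meta) != nrow(matrix)) {
    abort(sprintf("metadata has %d row(s) for a %d-cell matrix",
                  nrow(meta), nrow(matrix)))
  }
  if (length(genes) != ncol(matrix)) {
    abort(sprintf("%d gene name(s) for a %d-gene matrix",
                  length(genes), ncol(matrix)))
  }
  if (any(!nzchar(as.character(meta$cluster))) || anyNA(meta$cluster)) {
    abort("cluster labels must be non-empty strings")
  }
  if (length(matrix) && min(matrix) < 0) {
    abort("expression values must be nonnegative")
  }
  meta$cluster <- as.character(meta$cluster)
  meta$cell_id <- as.character(meta$cell_id)
  structure(list(matrix = matrix, meta = meta, genes = as.character(genes)),
            class = "arc_counts")
}

#' @export
print.arc_counts <- function(x, ...) {
  cat(sprintf("<arc_counts> %d cells x %d genes, %d cluster(s)\n",
              nrow(x$matrix), ncol(x$matrix),
              length(unique(x$meta$cluster))))
  invisible(x)
}

#' @export
dim.arc_counts <- function(x) dim(x$matrix)

#' Read a cell x gene count matrix with cluster metadata
#'
#' Supports MatrixMarket (`.mtx`, cells x genes, with a separate gene list
#' file) and dense delimited text (genes as named columns; an optional
#' `cell_id` column is used as cell identifier). Metadata is delimited text
#' with a `cell_id` column and a cluster column.
#'
#' @param matrix_path `.mtx` or dense delimited file.
#' @param metadata_path Delimited metadata with `cell_id` + cluster column.
#' @param genes_path Gene list (one identifier per line); required for MTX.
#' @param cluster_col Name of the metadata cluster column.
#' @return An `arc_counts` object.
#' @export
read_count_matrix <- function(matrix_path, metadata_path, genes_path = NULL,
                              cluster_col = "cluster") {
  if (!file.exists(matrix_path)) {
    abort(paste0("matrix file not found: ", matrix_path))
  }
  if (!file.exists(metadata_path)) {
    abort(paste0("metadata file not found: ", metadata_path))
  }
  if (grepl("\\.mtx$", matrix_path, ignore.case = TRUE)) {
    if (is.null(genes_path)) abort("genes_path is required for MTX input")
    m <- Matrix::readMM(matrix_path)
    genes <- readLines(genes_path, warn = FALSE)
    genes <- genes[nzchar(genes)]
  } else {
    d <- readr::read_delim(matrix_path, show_col_types = FALSE,
                           progress = FALSE)
    if ("cell_id" %in% names(d)) d <- d[setdiff(names(d), "cell_id")]
    genes <- names(d)
    m <- as.matrix(d)
  }
  meta <- readr::read_delim(metadata_path, show_col_types = FALSE,
                            progress = FALSE)
  if (!cluster_col %in% names(meta)) {
    abort(paste0("metadata has no '", cluster_col, "' column; found: ",
                 paste(names(meta), collapse = ", ")))
  }
  if (!"cell_id" %in% names(meta)) {
    abort("metadata has no 'cell_id' column")
  }
  meta <- dplyr::rename(meta, cluster = dplyr::all_of(cluster_col))
  count_matrix(m, meta[c("cell_id", "cluster")], genes)
}

#' @rdname read_count_matrix
#' @param counts An `arc_counts` object.
#' @param dir Output directory; writes `matrix.mtx`, `genes.txt`,
#'   `metadata.csv`.
#' @export
write_count_matrix <- function(counts, dir) {
  stopifnot(inherits(counts, "arc_counts"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(methods::as(methods::as(counts$matrix, "CsparseMatrix"),
                              "generalMatrix"),
                  file.path(dir, "matrix.mtx"))
  writeLines(counts$genes, file.path(dir, "genes.txt"))
  readr::write_csv(counts$meta, file.path(dir, "metadata.csv"))
  invisible(dir)
}

# gene column index with exact, case-sensitive matching and alias support
gene_index <- function(counts, gene, aliases = NULL) {
  g <- gene
  if (!g %in% counts$genes && !is.null(aliases) && g %in% names(aliases)) {
    g <- aliases[[g]]
  }
  i <- which(counts$genes == g)
  if (length(i) != 1) {
    abort(paste0("gene '", gene, "' not found (exact match); available: ",
                 paste(head(counts$genes, 20), collapse = ", "),
                 if (length(counts$genes) > 20) ", ..."))
  }
  i
}

#' Subset cells by cluster membership and a gating gene
#'
#' Keeps cells whose cluster label is in `clusters` and whose expression of
#' `gate_gene` satisfies the positivity rule (default: value > 0 on the
#' stored matrix). This is the "all cells in the listed clusters that
#' express the gate gene" operation used to pull somatostatin neurons out of
#' an annotated hypothalamic single-cell deposit.
#'
#' @param counts An `arc_counts` object.
#' @param clusters Character vector of cluster labels (empty = empty subset).
#' @param gate_gene Gene whose expression gates the subset; `NULL` for
#'   cluster-only subsetting.
#' @param min_expr Positivity rule: expression strictly greater than this.
#' @param aliases Optional named character vector mapping query names to the
#'   deposit's identifiers (e.g. `c(Vgat = "Slc32a1")`).
#' @return An `arc_counts` with the selected cells.
#' @export
subset_by_cluster_and_gene <- function(counts, clusters, gate_gene = NULL,
                                       min_expr = 0, aliases = NULL) {
  stopifnot(inherits(counts, "arc_counts"))
  known <- unique(counts$meta$cluster)
  bad <- setdiff(clusters, known)
  if (length(bad)) {
    abort(paste0("unknown cluster(s): ", paste(bad, collapse = ", "),
                 "; valid clusters: ", paste(known, collapse = ", ")))
  }
  keep <- counts$meta$cluster %in% clusters
  if (!is.null(gate_gene)) {
    j <- gene_index(counts, gate_gene, aliases)
    keep <- keep & as.numeric(counts$matrix[, j]) > min_expr
  }
  count_matrix(counts$matrix[keep, , drop = FALSE],
               counts$meta[keep, , drop = FALSE], counts$genes)
}

#' Percentage of cells expressing a gene
#'
#' `100 * #(expression > min_expr) / n` over the cells of `counts`.
#'
#' @inheritParams subset_by_cluster_and_gene
#' @param gene Gene to query.
#' @return The percentage (full precision; round for reporting).
#' @export
percent_expressing <- function(counts, gene, min_expr = 0, aliases = NULL) {
  stopifnot(inherits(counts, "arc_counts"))
  if (!nrow(counts$matrix)) abort("empty cell subset")
  j <- gene_index(counts, gene, aliases)
  100 * mean(as.numeric(counts$matrix[, j]) > min_expr)
}

#' Cluster-subset coexpression report
#'
#' Convenience wrapper: subset to `clusters` gated on `gate_gene`, then
#' report the percent of subset cells expressing each query gene.
#'
#' @inheritParams subset_by_cluster_and_gene
#' @param query_genes Genes to report percent-positive for.
#' @return A list of class `arc_subset_report`: `clusters`,
#'   `n_in_clusters`, `n_filtered` (cells passing the gate), and `per_gene`,
#'   a tibble (`gene`, `n_positive`, `pct`).
#' @export
subset_report <- function(counts, clusters, gate_gene, query_genes,
                          min_expr = 0, aliases = NULL) {
  in_cl <- subset_by_cluster_and_gene(counts, clusters, gate_gene = NULL)
  sub <- subset_by_cluster_and_gene(counts, clusters, gate_gene = gate_gene,
                                    min_expr = min_expr, aliases = aliases)
  per_gene <- purrr::map_dfr(query_genes, function(g) {
    p <- percent_expressing(sub, g, min_expr = min_expr, aliases = aliases)
    tibble(gene = g, n_positive = as.integer(round(p / 100 * nrow(sub$matrix))),
           pct = p)
  })
  structure(
    list(clusters = clusters, n_in_clusters = nrow(in_cl$matrix),
         n_filtered = nrow(sub$matrix), gate_gene = gate_gene,
         per_gene = per_gene),
    class = "arc_subset_report"
  )
}

#' @export
print.arc_subset_report <- function(x, ...) {
  cat(sprintf("clusters: %s\n", paste(x$clusters, collapse = ", ")))
  cat(sprintf("%d cells in clusters; %d express %s\n",
              x$n_in_clusters, x$n_filtered, x$gate_gene))
  print(x$per_gene)
  invisible(x)
}
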