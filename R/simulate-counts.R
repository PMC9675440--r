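#' Simulate a sparse labelled count matrix with programmed coexpression
#'
#' Per cluster and gene, each cell is positive with the programmed Bernoulli
#' fraction; positive cells receive a shifted-Poisson count
#' (`1 + Poisson(lambda)`), negatives 0. The realised per-cluster fractions
#' are returned as ground truth. This emulates the structure the
#' cluster-subset coexpression counter assumes: a sparse cells x genes
#' matrix, a cluster label per cell, and known marker-positivity fractions.
#'
#' @param cluster_sizes Named integer vector: cells per cluster.
#' @param fractions Tibble with columns `cluster`, `gene`, `fraction`
#'   (in `[0, 1]`); missing (cluster, gene) pairs default to fraction 0.
#' @param lambda Poisson mean of the positive-count distribution minus 1.
#' @param seed Integer seed.
#' @return A list: `counts` (an `arc_counts`, sparse) and `truth` (tibble
#'   `cluster`, `gene`, `fraction`, `fraction_realized`, `n_cells`).
#' @export
simulate_count_matrix <- function(cluster_sizes, fractions, lambda = 2,
                                  seed = 1) {
  if (any(fractions$fraction < 0 | fractions$fraction > 1)) {
    abort("fractions must lie in [0, 1]")
  }
  clusters <- names(cluster_sizes)
  if (is.null(clusters)) abort("cluster_sizes must be a named vector")
  genes <- unique(fractions$gene)
  n_total <- sum(cluster_sizes)
  cluster_of <- rep(clusters, cluster_sizes)

  withr::with_seed(seed, {
    m <- Matrix::Matrix(0, n_total, length(genes), sparse = TRUE)
    truth <- list()
    for (cl in clusters) {
      rows <- which(cluster_of == cl)
      for (gi in seq_along(genes)) {
        fr <- fractions$fraction[fractions$cluster == cl &
                                   fractions$gene == genes[gi]]
        fr <- if (length(fr)) fr[1] else 0
        pos <- rows[runif(length(rows)) < fr]
        if (length(pos)) {
          m[pos, gi] <- 1 + rpois(length(pos), lambda)
        }
        truth[[length(truth) + 1]] <- tibble(
          cluster = cl, gene = genes[gi], fraction = fr,
          fraction_realized = length(pos) / length(rows),
          n_cells = length(rows)
        )
      }
    }
    meta <- tibble(cell_id = sprintf("c%05d", seq_len(n_total)),
                   cluster = cluster_of)
    list(counts = count_matrix(m, meta, genes),
         truth = dplyr::bind_rows(truth))
  })
}
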