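toy_counts <- function() {
  m <- matrix(c(0, 1, 2,
                5, 0, 0), nrow = 3,
              dimnames = NULL)  # 3 cells x 2 genes (Sst, Th)
  meta <- tibble::tibble(cell_id = c("c1", "c2", "c3"),
                         cluster = c("Agrp/Sst", "Agrp/Sst", "Sst/Nts"))
  count_matrix(m, meta, c("Sst", "Th"))
}

test_that("count matrices validate metadata alignment and cluster labels", {
  cm <- toy_counts()
  expect_equal(dim(cm), c(3L, 2L))
  meta2 <- tibble::tibble(cell_id = c("c1", "c2"), cluster = c("a", "b"))
  expect_error(count_matrix(matrix(0, 3, 2), meta2, c("g1", "g2")),
               "2 row")
  meta3 <- tibble::tibble(cell_id = c("c1", "c2", "c3"),
                          cluster = c("a", "", "b"))
  expect_error(count_matrix(matrix(0, 3, 2), meta3, c("g1", "g2")),
               "non-empty")
  expect_error(count_matrix(matrix(-1, 3, 2),
                            tibble::tibble(cell_id = paste0("c", 1:3),
                                           cluster = "a"),
                            c("g1", "g2")), "nonnegative")
})

test_that("MTX and dense encodings load to identical values", {
  cm <- toy_counts()
  dir <- withr::local_tempdir()
  write_count_matrix(cm, dir)
  sparse <- read_count_matrix(file.path(dir, "matrix.mtx"),
                              file.path(dir, "metadata.csv"),
                              file.path(dir, "genes.txt"))
  expect_equal(dim(sparse), c(3L, 2L))
  # dense delimited encoding of the same matrix
  dense_path <- file.path(dir, "dense.csv")
  readr::write_csv(tibble::tibble(cell_id = cm$meta$cell_id,
                                  Sst = as.numeric(cm$matrix[, 1]),
                                  Th = as.numeric(cm$matrix[, 2])),
                   dense_path)
  dense <- read_count_matrix(dense_path, file.path(dir, "metadata.csv"))
  expect_equal(as.matrix(sparse$matrix), unname(as.matrix(dense$matrix)))
  expect_equal(sparse$genes, dense$genes)

  # metadata row-count mismatch is an error
  readr::write_csv(cm$meta[1:2, ], file.path(dir, "short.csv"))
  expect_error(read_count_matrix(file.path(dir, "matrix.mtx"),
                                 file.path(dir, "short.csv"),
                                 file.path(dir, "genes.txt")),
               "2 row")
})

test_that("cluster/gene subsetting applies the expression-positive gate", {
  cm <- toy_counts()
  # Sst values [0, 1, 2] across the listed clusters: 2 cells pass > 0
  sub <- subset_by_cluster_and_gene(cm, c("Agrp/Sst", "Sst/Nts"), "Sst")
  expect_equal(nrow(sub$matrix), 2L)
  expect_equal(sub$meta$cell_id, c("c2", "c3"))

  expect_equal(nrow(subset_by_cluster_and_gene(cm, character(0),
                                               "Sst")$matrix), 0L)
  expect_error(subset_by_cluster_and_gene(cm, "Nope", "Sst"),
               "unknown cluster.*Agrp/Sst")
  expect_error(subset_by_cluster_and_gene(cm, "Agrp/Sst", "Pomc"),
               "not found")
  # positivity threshold: subset size monotone non-increasing
  sizes <- vapply(c(0, 1, 2, 5), function(th) {
    nrow(subset_by_cluster_and_gene(cm, c("Agrp/Sst", "Sst/Nts"), "Sst",
                                    min_expr = th)$matrix)
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("percent expressing counts strict positives", {
  cm <- toy_counts()
  sub <- subset_by_cluster_and_gene(cm, c("Agrp/Sst", "Sst/Nts"), "Sst")
  # Th values in subset: [0, 0] -> 0%; Sst: [1, 2] -> 100%
  expect_equal(percent_expressing(sub, "Th"), 0)
  expect_equal(percent_expressing(sub, "Sst"), 100)
  # two cells, one positive -> 50%
  half <- count_matrix(matrix(c(0, 5), 2, 1),
                       tibble::tibble(cell_id = c("a", "b"), cluster = "x"),
                       "g")
  expect_equal(percent_expressing(half, "g"), 50)
  empty <- subset_by_cluster_and_gene(cm, character(0), "Sst")
  expect_error(percent_expressing(empty, "Sst"), "empty")

  # invariant to cell order and to extra genes
  cm2 <- count_matrix(cm$matrix[3:1, ], cm$meta[3:1, ], cm$genes)
  expect_equal(percent_expressing(cm2, "Sst"), percent_expressing(cm, "Sst"))
  cm3 <- count_matrix(cbind(cm$matrix, 9), cm$meta,
                      c(cm$genes, "Extra"))
  expect_equal(percent_expressing(cm3, "Sst"), percent_expressing(cm, "Sst"))
})

test_that("gene aliases map to deposit identifiers", {
  cm <- toy_counts()
  expect_equal(percent_expressing(cm, "Vgat", aliases = c(Vgat = "Sst")),
               percent_expressing(cm, "Sst"))
})

test_that("subset reports count cluster cells and gate survivors", {
  fr <- tibble::tibble(cluster = rep(c("Agrp/Sst", "Sst/Nts", "Other"), 2),
                       gene = rep(c("Sst", "Th"), each = 3),
                       fraction = c(0.9, 0.8, 0.1, 0.2, 0.1, 0.5))
  sim <- simulate_count_matrix(c("Agrp/Sst" = 150, "Sst/Nts" = 100,
                                 "Other" = 80), fr, seed = 3)
  rep <- subset_report(sim$counts, c("Agrp/Sst", "Sst/Nts"), "Sst", "Th")
  expect_equal(rep$n_in_clusters, 250L)
  # independent recount on the dense matrix
  dm <- as.matrix(sim$counts$matrix)
  in_cl <- sim$counts$meta$cluster %in% c("Agrp/Sst", "Sst/Nts")
  expect_equal(rep$n_filtered, sum(in_cl & dm[, 1] > 0))
  expect_equal(rep$per_gene$pct,
               100 * mean(dm[in_cl & dm[, 1] > 0, 2] > 0))
})
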