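toy_logcpm <- function(n_genes = 6, n_cells = 120, seed = 41) {
  set.seed(seed)
  m <- matrix(rexp(n_genes * n_cells), nrow = n_genes,
              dimnames = list(paste0("G", seq_len(n_genes)), NULL))
  Matrix::Matrix(m, sparse = TRUE)
}

test_that("interaction statistic is the mean of cluster means with filters", {
  lc <- Matrix::Matrix(rbind(G1 = c(rep(2, 30), rep(0.5, 30)),
                             G2 = c(rep(0.2, 30), rep(1, 30))),
                       sparse = TRUE)
  cells <- tibble::tibble(cluster = rep(c("A", "B"), each = 30))
  got <- interaction_statistic(lc, cells, "G1", "G2", "A", "B")
  expect_true(got$passes_expression_filter)
  expect_equal(got$statistic, (2 + 1) / 2)
  expect_error(interaction_statistic(lc, cells, "NOPE", "G2", "A", "B"),
               "NOPE")
})

test_that("expression filters are strict at 10% and require 20 cells", {
  base <- matrix(1, nrow = 2, ncol = 60,
                 dimnames = list(c("L", "R"), NULL))
  base["L", ] <- c(rep(1, 3), rep(0, 27), rep(1, 30))  # 3/30 = 10% exactly
  cells <- tibble::tibble(cluster = rep(c("A", "B"), each = 30))
  got <- interaction_statistic(Matrix::Matrix(base, sparse = TRUE),
                               cells, "L", "R", "A", "B")
  expect_false(got$passes_expression_filter)
  expect_true(is.na(got$statistic))
  # 19-cell receiver excluded
  cells19 <- tibble::tibble(cluster = rep(c("A", "B"), c(41, 19)))
  m <- matrix(1, 2, 60, dimnames = list(c("L", "R"), NULL))
  got19 <- interaction_statistic(Matrix::Matrix(m, sparse = TRUE),
                                 cells19, "L", "R", "A", "B")
  expect_false(got19$passes_expression_filter)
})

test_that("constant expression makes every permutation tie at p = 1", {
  m <- matrix(1, nrow = 2, ncol = 80,
              dimnames = list(c("L", "R"), NULL))
  cells <- tibble::tibble(cluster = rep(c("A", "B"), each = 40))
  res <- permutation_test(Matrix::Matrix(m, sparse = TRUE), cells,
                          tibble::tibble(ligand = "L", receptor = "R"),
                          B = 50, seed = 1)
  expect_true(all(res$empirical_p == 1))
})

test_that("empirical p-values obey the add-one bounds and the B boundary", {
  lc <- toy_logcpm()
  cells <- tibble::tibble(cluster = rep(c("A", "B"), each = 60))
  pairs <- tibble::tibble(ligand = "G1", receptor = "G2")
  res <- permutation_test(lc, cells, pairs, B = 99, seed = 2)
  expect_true(all(res$empirical_p >= 1 / 100 & res$empirical_p <= 1))
  # minimum attainable p at B = 999 is 1/1000 = 0.001, which fails the
  # strict < 0.001 rule
  expect_false(0.001 < 0.001)
  expect_error(permutation_test(lc, cells, pairs, B = 0), "B")
})

test_that("seeded permutations reproduce the table and ignore cell order", {
  lc <- toy_logcpm(seed = 5)
  cells <- tibble::tibble(cluster = rep(c("A", "B"), each = 60))
  pairs <- tibble::tibble(ligand = c("G1", "G3"),
                          receptor = c("G2", "G4"))
  a <- permutation_test(lc, cells, pairs, B = 200, seed = 7)
  b <- permutation_test(lc, cells, pairs, B = 200, seed = 7)
  expect_identical(a, b)
})

test_that("a planted strong pair attains the minimal empirical p", {
  wins <- 0
  for (seed in 1:10) {
    set.seed(seed)
    n_cells <- 200
    cells <- tibble::tibble(cluster = rep(c("A", "B", "C"),
                                          length.out = n_cells))
    m <- matrix(rexp(5 * n_cells, rate = 2), nrow = 5,
                dimnames = list(paste0("G", 1:5), NULL))
    m["G1", cells$cluster == "A"] <- m["G1", cells$cluster == "A"] + 3
    m["G2", cells$cluster == "B"] <- m["G2", cells$cluster == "B"] + 3
    res <- permutation_test(Matrix::Matrix(m, sparse = TRUE), cells,
                            tibble::tibble(ligand = c("G1", "G3"),
                                           receptor = c("G2", "G4")),
                            B = 200, seed = seed)
    planted <- res[res$ligand == "G1" & res$sender == "A" &
                     res$receiver == "B", ]
    # the planted pair must sit at the permutation floor with the
    # largest observed statistic of the whole scan
    if (planted$empirical_p == min(res$empirical_p) &&
        planted$statistic == max(res$statistic, na.rm = TRUE)) {
      wins <- wins + 1
    }
  }
  expect_gte(wins, 9)
})

test_that("final calls require DE, abundance, and curation jointly", {
  res <- tibble::tibble(
    ligand = c("L1", "L1", "L2"), receptor = c("R1", "R1", "R2"),
    sender = c("A", "C", "A"), receiver = c("B", "B", "B"),
    statistic = 1, empirical_p = c(0.0005, 0.0005, 0.0005),
    passes_expression_filter = TRUE, passes_significance = TRUE
  )
  de <- tibble::tibble(gene = "L1", subset = "A", fdr = 0.01)
  curated <- tibble::tibble(ligand = c("L1", "L2"),
                            receptor = c("R1", "R2"))
  got <- filter_interactions(res, de, enriched_clusters = "A", curated)
  expect_equal(got$final_call, c(TRUE, FALSE, FALSE))
  # row 2 fails DE (L1 not DE in sender C) and abundance; row 3 fails DE
  expect_false(got$passes_de_filter[3])
  expect_error(filter_interactions(res, de, "A", curated[0, ]),
               "mandatory")
})

test_that("label-shuffled data give calibrated empirical p-values", {
  set.seed(43)
  lc <- toy_logcpm(n_genes = 2, n_cells = 300, seed = 43)
  rownames(lc) <- c("L", "R")
  p_vals <- replicate(30, {
    cells <- tibble::tibble(cluster = sample(rep(c("A", "B"), each = 150)))
    res <- permutation_test(lc, cells,
                            tibble::tibble(ligand = "L", receptor = "R"),
                            B = 99, seed = sample.int(1e6, 1))
    res$empirical_p[res$sender == "A" & res$receiver == "B"]
  })
  # under the exchangeable null the p-values should not pile up at the
  # extremes
  expect_gt(mean(p_vals <= 0.25), 0.1)
  expect_gt(mean(p_vals > 0.5), 0.25)
  expect_lt(mean(p_vals <= 0.05), 0.25)
})
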