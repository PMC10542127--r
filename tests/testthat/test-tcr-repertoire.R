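clone_tab <- function(counts) {
  tibble::tibble(clone_key = paste0("K", seq_along(counts)),
                 count = as.integer(counts))
}

test_that("expansion requires both the strict frequency and count rules", {
  tab <- clone_tab(c(6, 5, 989))
  got <- call_expanded(tab)          # total 1000
  expect_equal(got$expanded, c(TRUE, FALSE, TRUE))  # 0.6% in; 0.5% out
  one_read <- call_expanded(clone_tab(c(1, 99)))    # 1% but count 1
  expect_false(one_read$expanded[1])
  expect_error(call_expanded(clone_tab(integer())), "empty")
})

test_that("fisher 2x2 reproduces the printed fatal-sharing comparison", {
  p <- fisher_exact_2x2(matrix(c(3, 1, 1, 8), nrow = 2,
                               byrow = TRUE))$p_two_sided
  expect_equal(round(p, 3), 0.052)
  expect_equal(fisher_exact_2x2(matrix(c(0, 5, 0, 5), 2))$p_two_sided, 1)
  p_diag <- fisher_exact_2x2(diag(c(10, 10)))$p_two_sided
  expect_equal(p_diag, 2 / 184756, tolerance = 1e-10)
})

test_that("fisher 2x2 equals the enumeration oracle over small margins", {
  for (a in 0:5) for (b in 0:4) for (c in 0:4) for (d in 0:5) {
    tab <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
    if (sum(tab) == 0) next
    mine <- fisher_exact_2x2(tab)
    oracle <- enumerate_fisher(tab)
    expect_equal(mine$p_two_sided, oracle$p_two_sided, tolerance = 1e-9)
    expect_equal(mine$p_greater, oracle$p_greater, tolerance = 1e-9)
  }
})

test_that("tissue enrichment tests expanded candidates one-sidedly", {
  tissue <- clone_tab(c(50, 50, 6, 894))
  ctrl <- clone_tab(c(1, 50, 6, 943))
  res <- tissue_enrichment(tissue, ctrl, tissue = "heart")
  # every clone here passes the expansion rule, so all are candidates
  expect_setequal(res$clone_key, c("K1", "K2", "K3", "K4"))
  # K4 is *less* frequent in tissue than control: not enriched one-sidedly
  expect_false(res$enriched[res$clone_key == "K4"])
  k1 <- res[res$clone_key == "K1", ]
  expect_equal(k1$fisher_p,
               enumerate_fisher(matrix(c(50, 950, 1, 999), 2,
                                       byrow = TRUE))$p_greater,
               tolerance = 1e-9)
  expect_lt(k1$fisher_p, 1e-10)
  expect_true(k1$enriched)
  # equal frequencies are not enriched
  k2 <- res[res$clone_key == "K2", ]
  expect_gte(k2$fisher_p, 0.5)
  expect_false(k2$enriched)
})

test_that("control-absent clones use the pseudo denominator in the ratio only", {
  tissue <- clone_tab(c(20, 980))
  ctrl <- tibble::tibble(clone_key = "K2", count = 1000L)
  res <- tissue_enrichment(tissue, ctrl)
  expect_equal(res$freq_control[res$clone_key == "K1"], 0)
  expect_equal(res$normalized_ratio[res$clone_key == "K1"],
               0.02 / (0.5 / 1000))
  # the test itself used the true zero
  expect_equal(res$fisher_p[res$clone_key == "K1"],
               enumerate_fisher(matrix(c(20, 980, 0, 1000), 2,
                                       byrow = TRUE))$p_greater,
               tolerance = 1e-9)
})

test_that("Hill diversity matches closed forms", {
  uniform <- clone_tab(rep(10, 10))  # 100 sequences
  qd <- hill_diversity(uniform, q_grid = 0:4)
  expect_equal(qd$qD, rep(10, 5), tolerance = 1e-10)
  skewed <- clone_tab(c(200, 100, 100))
  qd2 <- hill_diversity(skewed, q_grid = c(0, 1, 2))
  expect_equal(qd2$qD, c(3, 2^1.5, 8 / 3), tolerance = 1e-10)
  expect_error(hill_diversity(clone_tab(c(50, 49))), "99")
})

test_that("Hill profile is continuous at q = 1 and non-increasing in q", {
  set.seed(21)
  for (rep in 1:10) {
    counts <- rmultinom(1, 500, prop.table(rexp(30)))[, 1]
    counts <- counts[counts > 0]
    p <- counts / sum(counts)
    q_grid <- c(1 - 1e-4, 1, 1 + 1e-4, seq(0, 4, by = 0.25))
    qd <- hill_diversity(clone_tab(counts), q_grid = q_grid)
    expect_lt(abs(qd$qD[1] - qd$qD[2]), 1e-3)
    expect_lt(abs(qd$qD[3] - qd$qD[2]), 1e-3)
    ordered <- qd[order(qd$q), ]
    expect_true(all(diff(ordered$qD) <= 1e-9))
    # definition cross-check
    expect_equal(qd$qD[qd$q == 2], brute_hill(p, 2), tolerance = 1e-12)
  }
})

test_that("Hill numbers agree with vegan's renyi profile", {
  skip_if_not_installed("vegan")
  set.seed(22)
  counts <- rmultinom(1, 1000, prop.table(rexp(40)))[, 1]
  counts <- counts[counts > 0]
  qd <- hill_diversity(clone_tab(counts), q_grid = c(0, 0.5, 1, 2, 4))
  ref <- exp(as.numeric(vegan::renyi(counts,
                                     scales = c(0, 0.5, 1, 2, 4))))
  expect_equal(qd$qD, ref, tolerance = 1e-8)
})

test_that("rarefied diversity is seeded and depth-checked", {
  tab <- clone_tab(c(300, 200, 100, 50, 50))
  a <- hill_diversity(tab, q_grid = c(0, 2), rarefy_depth = 200, seed = 9)
  b <- hill_diversity(tab, q_grid = c(0, 2), rarefy_depth = 200, seed = 9)
  expect_identical(a, b)
  expect_lt(a$qD[a$q == 0], 5 + 1e-9)  # rarefaction cannot raise richness
  expect_error(hill_diversity(tab, rarefy_depth = 10000), "exceeds")
})

test_that("overlap summaries reproduce printed and degenerate cases", {
  got <- overlap_from_counts(19, 28, 5)
  expect_equal(got$pct_of_heart_display, "26%")
  expect_equal(got$pct_of_tumor_display, "18%")
  enr <- function(keys, called) {
    tibble::tibble(clone_key = keys, enriched = called)
  }
  none <- heart_tumor_overlap(enr(c("a", "b"), TRUE),
                              enr(c("c", "d"), TRUE))
  expect_equal(none$n_shared, 0L)
  expect_equal(none$pct_of_heart, 0)
  same <- heart_tumor_overlap(enr(letters[1:7], TRUE),
                              enr(letters[1:7], TRUE))
  expect_equal(same$n_shared, 7L)
  expect_equal(same$pct_of_tumor, 100)
})

test_that("enrichment recovers the generator's planted clone sets", {
  hits <- 0; total_called <- 0; false_called <- 0; total_truth <- 0
  for (seed in 1:5) {
    st <- simulate_study(small_sim_config(seed = seed))
    for (don in names(st$truth$repertoire$enriched)) {
      truth_h <- st$truth$repertoire$enriched[[don]]$heart_enriched
      tt <- st$clone_tables[st$clone_tables$donor_id == don &
                              st$clone_tables$tissue == "heart", ]
      ct <- st$clone_tables[st$clone_tables$donor_id == don &
                              st$clone_tables$tissue == "control_tissue", ]
      res <- tissue_enrichment(tt, ct)
      called <- res$clone_key[res$enriched]
      hits <- hits + sum(truth_h %in% called)
      total_truth <- total_truth + length(truth_h)
      total_called <- total_called + length(called)
      false_called <- false_called + sum(!(called %in% truth_h))
    }
  }
  expect_gte(hits / total_truth, 0.9)
  expect_lte(false_called / max(total_called, 1), 0.1)
})
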