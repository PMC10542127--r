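test_that("AUROC matches brute-force pair counting and handles ties", {
  lc <- function(vals) {
    m <- matrix(vals, nrow = 1)
    rownames(m) <- "G1"
    m
  }
  cells_in_out <- tibble::tibble(cluster = rep(c("A", "B"), each = 3))
  # perfect separation
  expect_equal(auroc_scan(lc(c(5, 6, 7, 1, 2, 3)), cells_in_out, "A")$auroc,
               1.0)
  # all ties
  expect_equal(auroc_scan(lc(rep(2, 6)), cells_in_out, "A")$auroc, 0.5)
  # in (3,1) vs out (2,0): 3 of 4 pairs concordant
  cells4 <- tibble::tibble(cluster = c("A", "A", "B", "B"))
  expect_equal(auroc_scan(lc(c(3, 1, 2, 0)), cells4, "A")$auroc, 0.75)
  # brute force on random data
  set.seed(1)
  v <- rnorm(40); cl <- tibble::tibble(cluster = sample(c("A", "B"), 40,
                                                        replace = TRUE))
  pairs <- expand.grid(i = which(cl$cluster == "A"),
                       j = which(cl$cluster == "B"))
  brute <- mean(ifelse(v[pairs$i] > v[pairs$j], 1,
                       ifelse(v[pairs$i] == v[pairs$j], 0.5, 0)))
  expect_equal(auroc_scan(lc(v), cl, "A")$auroc, brute)
  expect_error(auroc_scan(lc(v), tibble::tibble(cluster = rep("A", 40)),
                          "A"),
               "complement")
})

test_that("AUROC is invariant under strictly monotone transforms", {
  set.seed(2)
  m <- matrix(rexp(200), nrow = 5,
              dimnames = list(paste0("G", 1:5), NULL))
  cl <- tibble::tibble(cluster = sample(c("A", "B"), 40, replace = TRUE))
  a1 <- auroc_scan(m, cl, "A")$auroc
  a2 <- auroc_scan(log1p(m * 7), cl, "A")$auroc
  expect_equal(a1, a2)
})

test_that("variance prior recovers simulated hyperparameters", {
  set.seed(3)
  d0 <- 4; s0 <- 1; d <- 8
  s2 <- s0 * d0 / stats::rchisq(5000, d0) * stats::rchisq(5000, d) / d
  prior <- estimate_variance_prior(s2, d)
  expect_lt(abs(prior$d0 - d0) / d0, 0.2)
  expect_lt(abs(prior$s0_sq - s0) / s0, 0.1)
  # identical variances -> infinite prior df
  flat <- estimate_variance_prior(rep(2.5, 100), 4)
  expect_true(is.infinite(flat$d0))
  expect_equal(flat$s0_sq, 2.5, tolerance = 1e-6)
  expect_error(estimate_variance_prior(c(1, 2), 4), ">= 10 genes")
  expect_error(estimate_variance_prior(rep(0, 50), 4), "zero")
})

make_pb <- function(counts, clusters) {
  list(counts = counts,
       units = tibble::tibble(
         unit = colnames(counts),
         sample_id = colnames(counts),
         cluster = clusters,
         n_cells = 10L))
}

test_that("posterior variance follows the moderation formula", {
  # plug-in check: s2 = 4, d = 4, prior (d0 = 4, s0 = 1) -> 2.5
  set.seed(4)
  counts <- matrix(rpois(8 * 20, 40), nrow = 20,
                   dimnames = list(paste0("G", 1:20), paste0("u", 1:8)))
  pb <- make_pb(counts, rep(c("A", "B"), each = 4))
  res <- ova_moderated_t(pb, "A", prior = list(d0 = 4, s0_sq = 1))
  y <- icimyo:::log2_cpm(counts)
  in_cl <- rep(c(TRUE, FALSE), each = 4)
  g <- 5
  s2 <- (sum((y[g, in_cl] - mean(y[g, in_cl]))^2) +
           sum((y[g, !in_cl] - mean(y[g, !in_cl]))^2)) / 6
  s2_post <- (4 * 1 + 6 * s2) / (4 + 6)
  expect_equal(res$t_mod[g],
               (mean(y[g, in_cl]) - mean(y[g, !in_cl])) /
                 sqrt(s2_post * (1 / 4 + 1 / 4)))
  expect_equal((4 * 1 + 4 * 4) / 8, 2.5)
})

test_that("moderated t interpolates between ordinary and fixed-variance t", {
  set.seed(5)
  counts <- matrix(rpois(10 * 30, 60), nrow = 30,
                   dimnames = list(paste0("G", 1:30), paste0("u", 1:10)))
  counts[1:5, 1:5] <- counts[1:5, 1:5] + 40
  pb <- make_pb(counts, rep(c("A", "B"), each = 5))
  est <- attr(ova_moderated_t(pb, "A"), "prior")
  t_none <- ova_moderated_t(pb, "A", prior = list(d0 = 0,
                                                  s0_sq = est$s0_sq))$t_mod
  t_inf <- ova_moderated_t(pb, "A", prior = list(d0 = Inf,
                                                 s0_sq = est$s0_sq))$t_mod
  t_mid <- ova_moderated_t(pb, "A",
                           prior = list(d0 = 4, s0_sq = est$s0_sq))$t_mod
  between <- (abs(t_mid) >= pmin(abs(t_none), abs(t_inf)) - 1e-9) &
    (abs(t_mid) <= pmax(abs(t_none), abs(t_inf)) + 1e-9)
  expect_true(all(between))
  # d0 = 0 equals the ordinary two-sample equal-variance t
  g <- 3
  y <- icimyo:::log2_cpm(counts)
  tt <- stats::t.test(y[g, 1:5], y[g, 6:10], var.equal = TRUE)
  expect_equal(t_none[g], unname(tt$statistic), tolerance = 1e-8)
})

test_that("a constant gene gets zero effect and p = 1", {
  counts <- matrix(50, nrow = 12, ncol = 6,
                   dimnames = list(paste0("G", 1:12), paste0("u", 1:6)))
  pb <- make_pb(counts, rep(c("A", "B"), each = 3))
  res <- ova_moderated_t(pb, "A", prior = list(d0 = Inf, s0_sq = 1))
  expect_true(all(res$log2fc == 0))
  expect_true(all(res$p == 1))
})

test_that("moderated t agrees with limma on a shared pseudobulk fixture", {
  skip_if_not_installed("limma")
  set.seed(6)
  counts <- matrix(rnbinom(50 * 12, mu = 80, size = 10), nrow = 50,
                   dimnames = list(paste0("G", 1:50), paste0("u", 1:12)))
  counts[1:8, 1:6] <- counts[1:8, 1:6] * 3
  pb <- make_pb(counts, rep(c("A", "B"), each = 6))
  mine <- ova_moderated_t(pb, "A")
  y <- icimyo:::log2_cpm(counts)
  design <- cbind(1, rep(c(1, 0), each = 6))
  fit <- limma::eBayes(limma::lmFit(y, design))
  expect_equal(mine$t_mod, unname(fit$t[, 2]), tolerance = 1e-6)
  expect_equal(mine$p, unname(fit$p.value[, 2]), tolerance = 1e-6)
  expect_equal(attr(mine, "prior")$d0, fit$df.prior, tolerance = 1e-4)
  expect_equal(attr(mine, "prior")$s0_sq, fit$s2.prior, tolerance = 1e-4)
})

test_that("marker scan flags planted cluster markers by both rules", {
  set.seed(7)
  st <- simulate_study(small_sim_config(seed = 7))
  f <- qc_filter(st$cell_table, st$counts)
  hx <- which(f$cell_table$compartment == "heart")
  cells <- f$cell_table[hx, ]
  lc <- log_normalize(f$counts[, hx])
  pb <- pseudobulk_sum(f$counts[, hx], cells)
  mk <- marker_scan(lc, cells, pb, clusters = "C1")
  # the generator elevates a leading gene block in each cluster; C1's
  # block must surface as markers
  block_genes <- rownames(st$counts)[1:3]
  hits <- mk[mk$gene %in% block_genes, ]
  expect_true(all(hits$is_ova_marker | hits$is_auroc_marker))
  expect_true(all(mk$auroc >= 0 & mk$auroc <= 1))
  expect_true(all(mk$fdr >= mk$p, na.rm = TRUE))
})
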