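test_that("heart-expanded flags respect the within-donor rule", {
  blood <- tibble::tibble(
    donor_id = c("d1", "d1", "d2", "d3"),
    barcode = paste0("b", 1:4),
    cluster = "C1",
    clone_key = c("A", "B", "A", NA)
  )
  sets <- list(d1 = c("A"), d2 = c("Z"), d3 = c("A", "B"))
  got <- mark_heart_expanded_in_blood(blood, sets)
  # d1 cell with A flagged; d2 cell with A NOT flagged (different donor's
  # set); NA clone never flagged
  expect_equal(got$myo_clone, c(1L, 0L, 0L, 0L))
  # donors without heart data are dropped with a message
  expect_message(
    dropped <- mark_heart_expanded_in_blood(blood, sets["d1"]),
    "skipping")
  expect_equal(unique(dropped$donor_id), "d1")
})

test_that("bulk and sc expanded sets are analyzed as a union", {
  blood <- tibble::tibble(donor_id = "d1", barcode = paste0("b", 1:3),
                          cluster = "C1", clone_key = c("A", "B", "C"))
  union_set <- list(d1 = c("A", "B"))   # bulk {A} united with sc {B}
  got <- mark_heart_expanded_in_blood(blood, union_set)
  expect_equal(got$myo_clone, c(1L, 1L, 0L))
})

test_that("subset logistic equals the 2x2 closed-form odds ratio", {
  # table: flagged in-subset 20, flagged out 30; unflagged in 80, out 870
  d <- tibble::tibble(
    donor_id = "d1",
    cluster = rep(c("S", "O", "S", "O"), c(20, 30, 80, 870)),
    clone_key = rep(c("K", NA), c(50, 950)),
    myo_clone = rep(c(1L, 0L), c(50, 950))
  )
  res <- subset_sharing_test(d)
  s_row <- res[res$blood_subset == "S", ]
  or_2x2 <- (20 * 870) / (30 * 80)
  expect_equal(s_row$OR, or_2x2, tolerance = 1e-6)
  expect_equal(s_row$beta1, log(7.25), tolerance = 1e-6)
  expect_equal(s_row$n_total_shared_cells, 50L)
  expect_equal(s_row$n_unique_shared_clones, 1L)
})

test_that("null sharing flags give roughly uniform LRT p-values", {
  set.seed(31)
  p_vals <- replicate(200, {
    d <- tibble::tibble(
      donor_id = "d1",
      cluster = sample(c("S", "O"), 400, replace = TRUE,
                       prob = c(0.2, 0.8)),
      clone_key = "K",
      myo_clone = rbinom(400, 1, 0.1)
    )
    res <- subset_sharing_test(d)
    res$lrt_p[res$blood_subset == "S"]
  })
  # discrete data tie occasionally; the KS distance is still informative
  ks <- suppressWarnings(stats::ks.test(p_vals, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_gt(mean(p_vals > 0.05), 0.85)
})

test_that("zero flagged cells yield undefined rows with a reason", {
  d <- tibble::tibble(donor_id = "d1", cluster = c("S", "O"),
                      clone_key = NA_character_, myo_clone = 0L)
  res <- subset_sharing_test(d)
  expect_true(all(is.na(res$lrt_p)))
  expect_match(res$reason[1], "no heart-expanded")
})

test_that("complete-separation subsets are flagged unstable but reported", {
  d <- tibble::tibble(
    donor_id = "d1",
    cluster = rep(c("S", "O"), c(10, 90)),
    clone_key = rep(c("K", NA), c(10, 90)),
    myo_clone = rep(c(1L, 0L), c(10, 90))
  )
  res <- subset_sharing_test(d)
  s_row <- res[res$blood_subset == "S", ]
  expect_true(s_row$unstable)
  expect_false(is.na(s_row$lrt_p))
})

test_that("fatal association reproduces printed and enumerated tables", {
  # 3 of 4 fatal vs 1 of 9 non-fatal donors with significant sharing
  sharing <- c(rep(TRUE, 3), FALSE, TRUE, rep(FALSE, 8))
  fatal <- c(rep(TRUE, 4), rep(FALSE, 9))
  got <- fatal_association_test(sharing, fatal)
  expect_equal(round(got$p, 3), 0.052)
  expect_equal(got$table["fatal", "sharing"], 3)
  # identical rates -> p = 1
  even <- fatal_association_test(c(TRUE, TRUE, FALSE, FALSE,
                                   rep(c(TRUE, FALSE), each = 4)),
                                 rep(c(TRUE, FALSE), c(4, 8)))
  expect_equal(even$p, 1)
  # 4/4 vs 0/9: hypergeometric enumeration gives 1/715
  extreme <- fatal_association_test(rep(c(TRUE, FALSE), c(4, 9)),
                                    rep(c(TRUE, FALSE), c(4, 9)))
  expect_equal(extreme$p, 1 / 715, tolerance = 1e-9)
  expect_equal(round(extreme$p, 4), 0.0014)
})

test_that("shared clones map onto heart subsets with the low-evidence screen", {
  heart <- tibble::tibble(
    donor_id = rep(c("d1", "d2"), c(30, 8)),
    cluster = c(rep(c("T1", "T2"), 15), rep("T1", 8)),
    clone_key = c(rep("K", 30), rep("K", 8))
  )
  got <- map_shared_clones_to_heart_subsets(
    heart, list(d1 = "K", d2 = "K"))
  d1 <- got[got$donor_id == "d1", ]
  expect_false(any(d1$low_evidence))
  expect_equal(sum(d1$n_shared_cells), 30L)
  d2 <- got[got$donor_id == "d2", ]        # 8 cells <= 10
  expect_true(all(d2$low_evidence))
  expect_equal(d2$pct_of_donor_shared, 100)
  empty <- map_shared_clones_to_heart_subsets(heart,
                                              list(d1 = character()))
  expect_true(all(empty$n_shared_cells == 0))
})

test_that("permuting flags within donor destroys planted significance", {
  set.seed(32)
  st <- simulate_study(sim_config(seed = 32, cells_per_donor = 400,
                                  n_genes = 40))
  expanded <- st$clone_tables |>
    dplyr::filter(tissue == "heart") |>
    dplyr::group_by(donor_id) |>
    dplyr::group_modify(~ call_expanded(.x)) |>
    dplyr::ungroup() |>
    dplyr::filter(expanded)
  sets <- split(expanded$clone_key, expanded$donor_id)
  blood <- st$cell_table[st$cell_table$compartment == "blood", ]
  flagged <- suppressMessages(mark_heart_expanded_in_blood(blood, sets))
  fatal <- st$truth$donor$fatal_donors
  fatal_flagged <- flagged[flagged$donor_id %in% fatal, ]
  res <- subset_sharing_test(fatal_flagged)
  des <- res[res$blood_subset == "C3", ]
  perm_p <- replicate(20, {
    perm <- fatal_flagged |>
      dplyr::group_by(donor_id) |>
      dplyr::mutate(myo_clone = sample(myo_clone)) |>
      dplyr::ungroup()
    pr <- subset_sharing_test(perm)
    median(pr$lrt_p[pr$blood_subset == "C3"], na.rm = TRUE)
  })
  expect_gt(median(perm_p), 0.2)
  # the designated subset carries real signal before permutation
  expect_lt(median(des$lrt_p, na.rm = TRUE), median(perm_p))
})
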