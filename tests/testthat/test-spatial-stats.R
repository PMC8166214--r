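# hand-built world for the accuracy metric: two touching cells plus one
# distant cell, with a controllable grouping
accuracy_toy <- function() {
  labels <- array(0L, c(12, 6, 4))
  labels[2:5, 2:5, 2:3] <- 1L   # cell 1
  labels[6:9, 2:5, 2:3] <- 2L   # cell 2, touching cell 1
  labels[11:12, 1:2, 1:2] <- 3L # cell 3, isolated
  nucvol <- array(0L, dim(labels))
  nucvol[3, 3, 2] <- 1L; nucvol[7, 3, 2] <- 2L; nucvol[11, 1, 1] <- 3L
  nuc <- nuclei_seeds(nucvol, c(1, 1, 1))
  g <- structure(list(origin = c(0, 0, 0), pixel_size = 1,
                      dims = dim(labels)), class = "jsta_grid")
  # linkage: types A and B merge at 0.3, C joins at 0.9
  hc <- list(merge = rbind(c(-1L, -2L), c(1L, -3L)),
             height = c(0.3, 0.9), order = 1:3,
             labels = c("A", "B", "C"), method = "average")
  class(hc) <- "hclust"
  tax <- synthetic_taxonomy(3, 9, seed = 1)
  tax$linkage <- hc
  tax$types <- c("A", "B", "C")
  list(labels = labels, nuclei = nuc, grid = g, taxonomy = tax)
}

test_that("assignment accuracy scores a manual toy at both granularities", {
  w <- accuracy_toy()
  panel <- gene_panel("g1")
  # 10 spots: 8 truly from cell 1 inside cell 1's territory, 2 truly from
  # cell 2 but placed inside cell 1 (misassigned to cell 1 by any method)
  sp <- spot_table(x = c(seq(2.2, 4.3, length.out = 8), 4.6, 4.7),
                   y = rep(3.0, 10), z = rep(2.0, 10),
                   gene = rep(1, 10), panel,
                   true_cell = c(rep(1L, 8), 2L, 2L))
  truth <- list(labels = w$labels, nuclei = w$nuclei, spots = sp,
                true_types = c(`1` = "A", `2` = "B", `3` = "C"),
                taxonomy = w$taxonomy)
  class(truth) <- "jsta_truth"
  pred <- jsta:::make_state(w$labels, w$grid, w$nuclei,
                            cell_type = c("A", "B", "C"))

  # fine level (height 0): A and B are different groups: 8/10
  acc0 <- assignment_accuracy(pred, truth, heights = 0)
  expect_equal(unname(acc0$per_cell["1", 1]), 0.8)
  # at height 0.5, A and B share a group: neighbor misassignment forgiven
  acc5 <- assignment_accuracy(pred, truth, heights = 0.5)
  expect_equal(unname(acc5$per_cell["1", 1]), 1.0)
  # the mean is over cells with spots; cells 2 and 3 are empty here
  expect_equal(acc0$n_empty, 2)
  expect_equal(unname(acc0$mean_accuracy), 0.8)
})

test_that("perfect segmentation scores 1 at every granularity", {
  tt <- small_tissue()
  pred <- jsta:::make_state(tt$labels, build_grid(tt$spots, tt$nuclei, 1),
                            tt$nuclei,
                            cell_type = tt$true_types)
  # align the state grid to the truth frame: rebuild labels on that grid
  g <- pred$grid
  tr <- array(0L, g$dims)
  off <- round(-g$origin / g$pixel_size)
  td <- dim(tt$labels)
  tr[off[1] + 1:td[1], off[2] + 1:td[2], off[3] + 1:td[3]] <- tt$labels
  pred$labels <- tr
  acc <- assignment_accuracy(pred, tt)
  expect_true(all(abs(acc$mean_accuracy - 1) < 1e-12))
})

test_that("accuracy is non-decreasing in granularity height on real runs", {
  tt <- small_tissue()
  g <- build_grid(tt$spots, tt$nuclei, 1)
  E_p <- knn_density(tt$spots, g, K = 5)
  wb <- watershed_baseline(g, tt$nuclei, E_p)
  acc <- assignment_accuracy(wb, tt)
  expect_true(all(diff(acc$mean_accuracy) >= -1e-12))
})

test_that("type correlation recovers identity, sign flips and a closed form", {
  set.seed(91)
  E <- matrix(rpois(40 * 12, 8), 40)
  colnames(E) <- paste0("g", 1:12)
  Tl <- rep(c("A", "B", "C", "D"), each = 10)
  ref <- list(E_ref = E, T_ref = Tl)
  r_id <- type_correlation(E, Tl, ref, min_mean_counts = 5)
  expect_equal(unname(r_id), rep(1, 4), tolerance = 1e-12)

  r_neg <- type_correlation(max(E) - E, Tl, ref, min_mean_counts = 0)
  expect_true(all(r_neg < 0))

  # closed form on 4 types x 3 genes: correlation of scaled type means
  A <- rbind(c(10, 0, 5), c(0, 10, 5), c(5, 5, 10), c(10, 10, 0))
  B <- rbind(c(9, 1, 5), c(1, 9, 6), c(6, 4, 9), c(9, 9, 1))
  EA <- A[rep(1:4, each = 2), ]; EB <- B[rep(1:4, each = 2), ]
  colnames(EA) <- colnames(EB) <- paste0("g", 1:3)
  Tl4 <- rep(c("w", "x", "y", "z"), each = 2)
  r <- type_correlation(EA, Tl4, list(E_ref = EB, T_ref = Tl4),
                        min_mean_counts = 0)
  sa <- scale(A); sb <- scale(B)
  oracle <- sapply(1:4, function(i) cor(sa[i, ], sb[i, ]))
  expect_equal(unname(r), oracle, tolerance = 1e-12)

  expect_error(type_correlation(E[, 1:2], Tl,
                                list(E_ref = E[, 1:2], T_ref = Tl),
                                min_mean_counts = 1e6), "fewer than 3")
})

test_that("colocalization flags segregated types and is order-invariant", {
  set.seed(101)
  # two fully segregated clouds of 100 cells each
  xy <- rbind(cbind(runif(100, 0, 20), runif(100, 0, 20)),
              cbind(runif(100, 50, 70), runif(100, 0, 20)))
  Tl <- rep(c("A", "B"), each = 100)
  res <- colocalization_test(xy, Tl, k_neighbors = 20, n_perm = 200,
                             seed = 5)
  expect_lt(res$q["A", "A"], 0.05)
  expect_lt(res$q["B", "B"], 0.05)
  expect_equal(unname(rowSums(res$observed)), c(1, 1), tolerance = 1e-12)

  # permuting the input order leaves the observed matrix unchanged
  o <- sample(200)
  res2 <- colocalization_test(xy[o, ], Tl[o], k_neighbors = 20,
                              n_perm = 10, seed = 5)
  expect_equal(res2$observed, res$observed)

  expect_error(colocalization_test(xy[1:10, ], Tl[1:10], k_neighbors = 20),
               "more than k_neighbors")
})

test_that("spDEG p-values respect the add-one floor and find a gradient", {
  set.seed(111)
  n <- 100
  xy <- cbind(runif(n, 0, 50), runif(n, 0, 50))
  # gene 1: strong spatial gradient; genes 2-3: spatially unstructured
  noise_sd <- 1
  E <- cbind(3 * (xy[, 1] / 50) * 3 + rnorm(n, 0, noise_sd),
             rnorm(n, 5, noise_sd), rnorm(n, 5, noise_sd))
  colnames(E) <- c("grad", "flat1", "flat2")
  Tl <- rep("T1", n)
  res <- spdeg_test(xy, E, Tl, min_cells = 40, k_local = 9, n_perm = 100,
                    seed = 7)
  tab <- res$table
  expect_equal(min(tab$p), 1 / 101, tolerance = 1e-12)
  expect_lt(tab$q[tab$gene == "grad"], 0.05)
  expect_true(all(tab$p > 0 & tab$p <= 1))

  # types at or below min_cells are skipped but recorded
  Tl2 <- c(rep("big", 60), rep("small", 40))
  res2 <- spdeg_test(xy, E, Tl2, min_cells = 40, n_perm = 20, seed = 3)
  expect_equal(res2$tested_types, "big")
  expect_equal(res2$skipped_types, "small")
})

test_that("permutation tests are reproducible under a fixed seed", {
  set.seed(121)
  xy <- cbind(runif(60, 0, 30), runif(60, 0, 30))
  Tl <- sample(c("A", "B"), 60, replace = TRUE)
  E <- matrix(rpois(60 * 4, 6), 60)
  colnames(E) <- paste0("g", 1:4)
  a <- colocalization_test(xy, Tl, k_neighbors = 10, n_perm = 50, seed = 9)
  b <- colocalization_test(xy, Tl, k_neighbors = 10, n_perm = 50, seed = 9)
  expect_identical(a$p, b$p)
  c1 <- spdeg_test(xy, E, rep("t", 60), min_cells = 40, n_perm = 30, seed = 4)
  c2 <- spdeg_test(xy, E, rep("t", 60), min_cells = 40, n_perm = 30, seed = 4)
  expect_identical(c1$table, c2$table)
})

test_that("the BH correction agrees with a brute-force implementation", {
  set.seed(131)
  for (i in 1:20) {
    p <- runif(sample(3:50, 1))
    expect_equal(stats::p.adjust(p, "BH"), oracle_bh(p), tolerance = 1e-12)
  }
})
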