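# a minimal hand-built world: two 8-voxel nuclei in a 20 x 10 x 6 volume
two_nuclei <- function(gap = 10) {
  vol <- array(0L, c(20, 10, 6))
  vol[3:4, 4:5, 3:4] <- 1L
  vol[(3:4) + gap, 4:5, 3:4] <- 2L
  nuclei_seeds(vol, c(1, 1, 1))
}

test_that("watershed initialization caps assignment at the distance threshold", {
  nuc <- two_nuclei(gap = 10)
  g <- build_grid(NULL, nuc, 1)
  st <- watershed_initialize(g, nuc, max_dist = 2)
  expect_s3_class(st, "jsta_state")
  expect_setequal(sort(unique(st$labels[st$labels > 0])), c(1L, 2L))

  # every assigned pixel lies within 2 um of its nucleus' voxels
  centers <- jsta:::grid_centers(g)
  for (cid in 1:2) {
    pix <- which(st$labels == cid)
    nuc_idx <- which(nuc$labels == cid)
    nijk <- jsta:::array_index(nuc_idx, dim(nuc$labels))
    nxyz <- jsta:::voxel_center_aniso(nijk, nuc$origin, nuc$voxel_size)
    d <- apply(centers[pix, , drop = FALSE], 1, function(q)
      min(sqrt(colSums((t(nxyz) - q)^2))))
    expect_true(all(d <= 2 + 1e-9))
  }

  # nuclei 10 um apart leave a background gap between the two cells
  adj <- jsta:::label_adjacency(st$labels)
  expect_true(is.null(adj[["1"]]) || !(2 %in% adj[["1"]]))

  expect_error(watershed_initialize(g, nuclei_seeds(array(0L, c(4, 4, 2)),
                                                    c(1, 1, 1))),
               "no nuclei")
})

test_that("density watershed masks empty space and splits a uniform field", {
  nuc <- two_nuclei(gap = 8)
  g <- build_grid(NULL, nuc, 1)
  n_p <- prod(g$dims)
  # uniform high density near the nuclei plane, empty elsewhere
  centers <- jsta:::grid_centers(g)
  E_p <- matrix(0, n_p, 1)
  infield <- centers[, 1] > 0 & centers[, 1] < 18 &
    centers[, 2] > 1 & centers[, 2] < 9 & centers[, 3] > 0 & centers[, 3] < 6
  E_p[infield, 1] <- 4 # log2(4) = 2 >= 1 passes the mask
  st <- watershed_baseline(g, nuc, E_p, compactness = 10)

  # the cell-free (masked) region stays background
  expect_true(all(st$labels[which(!infield)] == 0))

  # two seeds in a uniform field bisect it near-equally (compactness rules)
  sizes <- table(st$labels[st$labels > 0])
  expect_equal(length(sizes), 2)
  expect_lt(abs(sizes[1] - sizes[2]) / sum(sizes), 0.2)

  # the watershed line: the two cells never touch face-on
  adj <- jsta:::label_adjacency(st$labels)
  expect_true(is.null(adj[["1"]]) || !(2 %in% adj[["1"]]))
})

test_that("border pixels obey the 5-foreign / 2-own neighbor rule", {
  # one 4x4x3 cell block against a 4x4x3 block of a different type
  labels <- array(0L, c(10, 6, 5))
  labels[2:5, 2:5, 2:4] <- 1L
  labels[6:9, 2:5, 2:4] <- 2L
  nucvol <- array(0L, dim(labels))
  nucvol[3, 3, 3] <- 1L
  nucvol[8, 3, 3] <- 2L
  nuc <- nuclei_seeds(nucvol, c(1, 1, 1))
  g <- list(origin = c(0, 0, 0), pixel_size = 1, dims = dim(labels))
  class(g) <- "jsta_grid"
  st <- jsta:::make_state(labels, g, nuc,
                          cell_type = c("A", "B"))

  bp <- border_pixels(st)
  ijk <- jsta:::array_index(bp$lin, dim(labels))

  # interface pixels (x = 5 and x = 6 faces) are borders
  expect_true(any(ijk[, 1] == 5) && any(ijk[, 1] == 6))
  # the cells' interior voxels are never borders
  expect_false(any(ijk[, 1] %in% c(3, 8) & ijk[, 2] %in% 3:4 & ijk[, 3] == 3))

  # same-type neighbors are frozen: retype both cells as A
  st2 <- st
  st2$cell_type[] <- c("A", "A")
  bp2 <- border_pixels(st2)
  # no candidate pairs across the 1|2 interface remain
  expect_true(all(bp2$pair_cell == 0 | bp2$own[bp2$pair_pt] == 0 |
                    bp2$pair_cell != ifelse(bp2$own[bp2$pair_pt] == 1, 2, 1)))
  ijk2 <- jsta:::array_index(bp2$lin[bp2$own > 0], dim(labels))
  # labeled borders now exist only at the background interface, where a
  # pixel still has >= 5 background neighbors; the x = 5/6 inner columns
  # with 2-deep same-type backing are gone
  expect_false(any(ijk2[, 1] %in% c(5, 6) & ijk2[, 2] %in% 3:4 &
                     ijk2[, 3] == 3))
})

test_that("probability rescaling follows the distance-decay algebra", {
  q <- c(0.2, 0.5, 0.3)
  # a type within d dominates regardless of q
  rs <- rescale_pixel_probabilities(q, c(1, 10, 10), d = 2, prob_floor = 0.01)
  expect_false(rs$background)
  expect_gt(rs$q[1], 0.5)

  # at r = 6d the decay factor is exactly 1/2: with two candidates of equal
  # classifier probability, one at the unit-factor distance (r = 3.5d,
  # where 5d / (2(r-d)) = 1) and one at 6d, the rescaled ratio is 2:1
  d <- 2
  rs2 <- rescale_pixel_probabilities(c(0.5, 0.5, 0), c(3.5 * d, 6 * d, Inf),
                                     d = d, prob_floor = 0.01)
  expect_equal(rs2$q[1] / rs2$q[2], 2, tolerance = 1e-12)
  # and the exponential alternative halves at the same point (factor 1 at
  # r = d, 1/2 at r = 6d)
  rs2e <- rescale_pixel_probabilities(c(0.5, 0.5, 0), c(d, 6 * d, Inf),
                                      d = d, prob_floor = 0.01,
                                      decay = "exponential")
  expect_equal(rs2e$q[2] / rs2e$q[1], 0.5, tolerance = 1e-6)

  # no neighboring types at all: background
  rs3 <- rescale_pixel_probabilities(q, c(Inf, Inf, Inf), d = 2,
                                     prob_floor = 0.01)
  expect_true(rs3$background)

  # the floor prunes weak candidates after renormalization
  rs4 <- rescale_pixel_probabilities(c(0.97, 0.03, 0), c(10, 10, Inf),
                                     d = 2, prob_floor = 0.05)
  expect_equal(rs4$q[2], 0)
  expect_equal(sum(rs4$q), 1)

  expect_error(rescale_pixel_probabilities(q, c(-1, 2, 3), d = 2), "negative")
})

test_that("vectorized rescaling matches the scalar operation row by row", {
  set.seed(61)
  k <- 5
  for (i in 1:50) {
    q <- as.vector(stats::rgamma(k, 1)); q <- q / sum(q)
    r <- ifelse(runif(k) < 0.3, Inf, runif(k, 0, 30))
    fl <- sample(c(0.01, 0.05), 1)
    a <- rescale_pixel_probabilities(q, r, d = 2, prob_floor = fl)
    b <- jsta:::rescale_rows(matrix(q, 1), matrix(r, 1), d = 2,
                             prob_floor = fl, decay = "rational")
    expect_equal(a$q, as.vector(b$Q), tolerance = 1e-12)
    expect_equal(a$background, unname(b$background))
  }
})

test_that("annealed sampling interpolates between multinomial and argmax", {
  # one-hot rows always return their type
  expect_equal(anneal_and_sample(c(0, 1, 0), iteration = 0), 2L)

  # iteration 0: plain multinomial frequencies
  set.seed(71)
  draws <- replicate(20000, anneal_and_sample(c(0.7, 0.3), 0))
  p_hat <- mean(draws == 1)
  se <- sqrt(0.7 * 0.3 / 20000)
  expect_lt(abs(p_hat - 0.7), 3 * se)

  # large iteration count: argmax almost surely
  draws2 <- replicate(500, anneal_and_sample(c(0.6, 0.4), 1e6))
  expect_true(all(draws2 == 1))

  # the boost at iteration t multiplies the max entry by (1 + 0.05 t)
  set.seed(72)
  t <- 10
  boosted <- 0.7 * (1 + 0.05 * t) / (0.7 * (1 + 0.05 * t) + 0.3)
  draws3 <- replicate(20000, anneal_and_sample(c(0.7, 0.3), t))
  expect_lt(abs(mean(draws3 == 1) - boosted),
            3 * sqrt(boosted * (1 - boosted) / 20000))
})

test_that("counts from segmentation enumerate a hand-built toy exactly", {
  labels <- array(0L, c(6, 4, 2))
  labels[1:3, , ] <- 1L
  labels[4:6, 1:2, ] <- 2L
  nucvol <- array(0L, dim(labels)); nucvol[2, 2, 1] <- 1L; nucvol[5, 1, 1] <- 2L
  nuc <- nuclei_seeds(nucvol, c(1, 1, 1))
  g <- list(origin = c(0, 0, 0), pixel_size = 1, dims = dim(labels))
  class(g) <- "jsta_grid"
  st <- jsta:::make_state(labels, g, nuc)

  panel <- gene_panel(c("g1", "g2"))
  sp <- spot_table(x = c(0.5, 1.5, 2.5, 4.5, 4.5, 5.5),
                   y = c(0.5, 1.5, 3.5, 0.5, 1.5, 3.5),
                   z = rep(0.5, 6),
                   gene = c(1, 1, 2, 1, 2, 2), panel)
  E_c <- counts_from_segmentation(st, sp)
  # spots 1-3 in cell 1 (g1,g1,g2); spots 4-5 in cell 2 (g1,g2);
  # spot 6 at (5.5, 3.5) is over background
  expect_equal(unname(E_c), rbind(c(2L, 1L), c(1L, 1L)))

  # conservation: cell counts + background = all spots per gene
  asg <- spot_assignments(st, sp)
  expect_equal(colSums(E_c) + c(sum(asg == 0 & sp$gene == 1),
                                sum(asg == 0 & sp$gene == 2)),
               c(g1 = 3, g2 = 3), ignore_attr = TRUE)

  # a spot outside the grid counts as background, with a warning
  sp_out <- spot_table(c(0.5, 100), c(0.5, 100), c(0.5, 100), c(1, 1), panel)
  expect_warning(asg2 <- spot_assignments(st, sp_out), "outside the grid")
  expect_equal(asg2[2], 0L)
})

test_that("the EM run conserves spots and cells and pins nuclei", {
  tt <- small_tissue()
  st <- run_jsta(tt$spots, tt$nuclei, tt$taxonomy, pixel_size = 1,
                 params = reassignment_params("simulation", seed = 9,
                                              n_train_rounds = 2,
                                              n_reassign_iters = 3))
  # no cell ids created or destroyed
  expect_setequal(st$cell_ids, tt$nuclei$ids)
  expect_setequal(sort(unique(st$labels[st$labels > 0])), st$cell_ids)

  # nucleus pixels never flip
  pin <- which(st$nucleus_pixel > 0)
  expect_equal(st$labels[pin], st$nucleus_pixel[pin])

  # spot conservation across the run
  expect_equal(sum(st$counts) +
                 sum(spot_assignments(st, tt$spots) == 0),
               nrow(tt$spots))

  # diagnostics report finite flip counts per iteration
  expect_true(all(is.finite(st$diagnostics$flips)))
  expect_true(all(st$diagnostics$flips <= st$diagnostics$n_border))
})

test_that("a single-type tissue reduces to the watershed initialization", {
  tax1 <- synthetic_taxonomy(2, 8, seed = 81)
  tt <- simulate_tissue(tax1, sim_params(extent = c(20, 20, 8), seed = 82))
  # force one type everywhere: a reference whose cells are all one label
  # cannot train, so run_jsta must keep the watershed boundaries
  tax_uni <- sample_reference_cells(tax1, 30, seed = 83)
  uni <- tt
  st <- suppressWarnings(
    run_jsta(uni$spots, uni$nuclei, {
      t2 <- tax_uni
      # make the classifier see a single dominant type by collapsing labels
      t2$T_ref <- rep(t2$types[1], length(t2$T_ref))
      t2$T_ref[1:2] <- t2$types[2] # minimum to satisfy training contract
      t2
    }, pixel_size = 1, params = reassignment_params("simulation", seed = 84))
  )
  init <- watershed_initialize(st$grid, uni$nuclei, max_dist = 2)
  if (length(unique(st$cell_type)) < 2) {
    expect_identical(st$labels, init$labels)
  } else {
    succeed("classifier produced two types; degenerate path not exercised")
  }
})

test_that("same-type interfaces stay exactly as initialized", {
  tt <- small_tissue()
  st <- run_jsta(tt$spots, tt$nuclei, tt$taxonomy, pixel_size = 1,
                 params = reassignment_params("simulation", seed = 19,
                                              n_train_rounds = 2,
                                              n_reassign_iters = 3))
  init <- watershed_initialize(st$grid, tt$nuclei, max_dist = 2)
  # pixels on interfaces between same-type cells: assigned in init to cell a
  # with a 26-neighbor in cell b of the same (final) type
  nb <- jsta:::neighbor_labels(init$labels)
  lab <- as.integer(init$labels)
  ty <- st$cell_type
  moved <- which(lab > 0 & as.integer(st$labels) != lab)
  if (length(moved)) {
    # any moved pixel must have had a differently-typed or background
    # neighbor at some point; at minimum it cannot sit strictly between
    # same-type cells with no background contact in the initial map
    strictly_same <- vapply(moved, function(i) {
      v <- nb[i, ]
      v <- v[v >= 0]
      others <- setdiff(unique(v[v > 0]), lab[i])
      length(others) > 0 && !any(v == 0) &&
        all(ty[as.character(others)] == ty[as.character(lab[i])])
    }, logical(1))
    expect_false(any(strictly_same))
  } else {
    succeed("no pixels moved")
  }
})

test_that("pixel classification confidence trends upward over the EM", {
  # mean max pixel probability over three checkpoints (first, middle and
  # last third of the reassignment iterations), allowing one non-monotone
  # step: the first checkpoint is scored on the easy initial borders near
  # the nuclei, so a single early dip is expected before the rise
  reps <- accept_replicates()
  for (r in reps) {
    d <- r$jsta$diagnostics
    thirds <- split(d$mean_max_prob, cut(seq_len(nrow(d)), 3))
    ck <- vapply(thirds, mean, numeric(1), na.rm = TRUE)
    expect_length(ck, 3)
    expect_lte(sum(diff(ck) < 0), 1)
  }
})
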