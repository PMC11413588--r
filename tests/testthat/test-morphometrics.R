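# Cluster labeling, diameters, ratios, and radial core-shell profiles.

test_that("face connectivity defines clusters", {
  two <- make_fixture("two-cube-contact")
  expect_equal(find_clusters(two, "all-matter")$n_clusters, 1)

  # separate the cubes by one medium voxel
  apart <- create_lattice(c(14, 12, 12))
  off <- as.matrix(expand.grid(0:2, 0:2, 0:2))
  apart <- add_compartment(apart, sweep(off, 2, c(3, 5, 5), "+"), "Cell")
  apart <- add_compartment(apart, sweep(off, 2, c(7, 5, 5), "+"), "Cell")
  expect_equal(find_clusters(apart, "all-matter")$n_clusters, 2)

  empty <- create_lattice(c(5, 5, 5))
  rep0 <- find_clusters(empty, "all-matter")
  expect_equal(rep0$n_clusters, 0)
  expect_equal(nrow(rep0$clusters), 0)
})

test_that("cluster labeling matches the naive flood-fill oracle", {
  for (seed in c(3, 8)) {
    st <- make_fixture("random-dispersion", n = 40, dims = c(18, 18, 18),
                       seed = seed)
    st <- run_mcs(st, 3)
    for (mode in c("all-matter", "cells-only")) {
      rep <- find_clusters(st, mode)
      oracle <- oracle_flood_fill(state_mask(st, mode))
      expect_equal(rep$n_clusters, oracle$n)
      # same partition up to component relabeling
      pairs <- unique(cbind(as.integer(rep$comp), as.integer(oracle$comp)))
      pairs <- pairs[pairs[, 1] > 0 | pairs[, 2] > 0, , drop = FALSE]
      expect_equal(anyDuplicated(pairs[, 1]), 0)
      expect_equal(anyDuplicated(pairs[, 2]), 0)
    }
  }

  # freshly seeded state, all-matter mode
  st <- make_fixture("mini-seeding", n = 60, seed = 5)
  rep <- find_clusters(st, "all-matter")
  expect_equal(rep$n_clusters, oracle_flood_fill(state_mask(st, "all-matter"))$n)
})

test_that("every non-medium voxel is counted in exactly one cluster", {
  st <- make_fixture("mini-seeding", n = 50, seed = 6)
  st <- run_mcs(st, 5)
  rep <- find_clusters(st, "all-matter")
  expect_equal(sum(rep$clusters$n_voxels), sum(st$comps$volume))
  expect_true(all(!is.na(rep$membership$cluster)))
  # cells-only mode assigns no ECM compartment
  co <- find_clusters(st, "cells-only")
  ecm <- st$comps$type != "Cell"
  expect_true(all(is.na(co$membership$cluster[ecm])))
  expect_equal(sum(co$clusters$n_voxels),
               sum(st$comps$volume[st$comps$type == "Cell"]))
})

test_that("projected diameter is the footprint-equivalent circle diameter", {
  cube <- make_fixture("isolated-cube")
  rep <- find_clusters(cube, "all-matter")
  expect_equal(rep$clusters$projected_diameter, 2 * sqrt(9 / pi),
               tolerance = 1e-12)
  expect_equal(projected_diameter(cluster_voxels(rep, 1)), 2 * sqrt(9 / pi))

  # translation invariance
  vox <- cluster_voxels(rep, 1)
  expect_equal(projected_diameter(sweep(vox, 2, c(3, -2, 1), "+")),
               projected_diameter(vox))

  # a 1-voxel-thick disk of radius r has projected diameter ~ 2r
  r <- 9
  g <- as.matrix(expand.grid(x = 1:25, y = 1:25, z = 13))
  disk <- g[(g[, 1] - 13)^2 + (g[, 2] - 13)^2 <= r^2, ]
  expect_lt(abs(projected_diameter(disk) - 2 * r), 1)

  expect_error(projected_diameter(disk[0, ]), "empty")
  expect_equal(equivalent_diameter(pi / 6), 1)
})

test_that("diameter ratios compare the largest clusters across snapshots", {
  st <- make_fixture("two-cube-contact")
  rep <- find_clusters(st, "all-matter")
  expect_equal(diameter_ratio(rep, rep), 1.0)

  # doubling every linear dimension doubles the projected diameter
  vox <- cluster_voxels(rep, 1)
  dbl <- unique(rbind(
    cbind(2 * vox[, 1], 2 * vox[, 2], 2 * vox[, 3]),
    cbind(2 * vox[, 1] - 1, 2 * vox[, 2], 2 * vox[, 3]),
    cbind(2 * vox[, 1], 2 * vox[, 2] - 1, 2 * vox[, 3]),
    cbind(2 * vox[, 1] - 1, 2 * vox[, 2] - 1, 2 * vox[, 3]),
    cbind(2 * vox[, 1], 2 * vox[, 2], 2 * vox[, 3] - 1),
    cbind(2 * vox[, 1] - 1, 2 * vox[, 2], 2 * vox[, 3] - 1),
    cbind(2 * vox[, 1], 2 * vox[, 2] - 1, 2 * vox[, 3] - 1),
    cbind(2 * vox[, 1] - 1, 2 * vox[, 2] - 1, 2 * vox[, 3] - 1)))
  expect_equal(projected_diameter(dbl) / projected_diameter(vox), 2,
               tolerance = 1e-12)

  empty <- find_clusters(create_lattice(c(4, 4, 4)), "all-matter")
  expect_error(diameter_ratio(rep, empty), "empty")
})

test_that("radial profiles resolve core-shell composition", {
  st <- make_fixture("cell-shell-around-ecm")
  rep <- find_clusters(st, "all-matter")
  expect_equal(rep$n_clusters, 1)
  prof <- radial_profile(st, rep, n_shells = 6)
  expect_equal(nrow(prof), 6)
  # fractions sum to one in every populated shell
  sums <- rowSums(prof[, c("medium", "cell", "ecmst", "ecmv")])
  expect_equal(sums[prof$n_voxels > 0], rep(1, sum(prof$n_voxels > 0)),
               tolerance = 1e-12)
  # ECM dominates the innermost shell, cells the outer shells
  expect_gt(prof$ecmv[1], prof$ecmv[6])
  expect_gt(prof$cell[5], prof$cell[1])

  # homogeneous ball: a single type everywhere inside the cluster radius
  ball <- create_lattice(c(15, 15, 15))
  g <- as.matrix(expand.grid(1:15, 1:15, 1:15))
  inside <- (g[, 1] - 8)^2 + (g[, 2] - 8)^2 + (g[, 3] - 8)^2 <= 5^2
  ball <- add_compartment(ball, g[inside, ], "Cell",
                          target_volume = sum(inside))
  repb <- find_clusters(ball, "all-matter")
  profb <- radial_profile(ball, repb, n_shells = 4)
  inner <- profb$shell < 4   # the outermost shell clips the ball's corners
  expect_true(all(profb$cell[inner] > 0.9))

  expect_error(radial_profile(st, rep, n_shells = 1), "n_shells")
})

test_that("summary timeseries aggregates snapshots consistently", {
  st <- make_fixture("mini-seeding", n = 30, seed = 9)
  res <- run_simulation(st, mcs = 20, snapshot_every = 10)
  m <- res$metrics
  expect_equal(nrow(m), 3)
  expect_equal(m$mcs, c(0, 10, 20))
  expect_equal(m$day, 1 + m$mcs / 240)
  counts <- as.matrix(m[, c("n_clusters_all_matter", "n_clusters_cells_only",
                            "cell_voxels", "ecmst_voxels", "ecmv_voxels",
                            "n_cell", "n_ecmst", "n_ecmv", "mitoses",
                            "secretions", "deletions")])
  expect_true(all(counts >= 0))
  expect_true(all(counts == round(counts)))
  # cells-only clusters refine the cell-containing all-matter clusters:
  # each all-matter cluster with cells splits into >= 1 cells-only cluster
  for (s in res$snapshots) {
    am <- find_clusters(s, "all-matter")
    co <- find_clusters(s, "cells-only")
    expect_gte(co$n_clusters, sum(am$clusters$n_cells > 0))
  }

  single <- summary_timeseries(list(st))
  expect_equal(nrow(single), 1)
})
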