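# The Hamiltonian: contact term, volume term, and the local delta-H.

test_that("contact energy matches hand-derived values on cube fixtures", {
  empty <- create_lattice(c(6, 6, 6))
  expect_equal(contact_energy(empty), 0)

  # isolated 3x3x3 SZ cell, order 1: 54 medium faces x J(medium-cell)=5
  cube <- make_fixture("isolated-cube")
  expect_equal(contact_energy(cube, order = 1), 270)

  # two cubes sharing a 3x3 face: 90 medium faces x 5 + 9 cell-cell x 5
  two <- make_fixture("two-cube-contact")
  expect_equal(contact_energy(two, order = 1), 495)
})

test_that("contact energy agrees with the brute-force pair enumeration", {
  for (seed in 1:4) {
    st <- random_messy_state(seed, dims = c(5, 5, 5),
                             boundary = if (seed %% 2) "fixed-medium"
                                        else "periodic",
                             order = if (seed > 2) 2 else 1)
    expect_equal(contact_energy(st), oracle_contact_energy(st),
                 tolerance = 1e-12)
  }
})

test_that("volume energy is the quadratic constraint over non-medium compartments", {
  cube <- make_fixture("isolated-cube")  # V = 27, target V_Cell = 30, lambda 10
  expect_equal(volume_energy(cube), 90)
  expect_equal(total_energy(cube), 360)

  # at target, the term vanishes
  st <- create_lattice(c(8, 8, 8))
  st <- add_compartment(st, cbind(2:4, 2, 2), "ECMst", target_volume = 3)
  st <- add_compartment(st, cbind(2:4, 5, 2), "ECMv", target_volume = 3)
  expect_equal(volume_energy(st), 0)
})

test_that("total energy is invariant under compartment id relabeling", {
  st <- make_fixture("two-cube-contact")
  h0 <- total_energy(st)
  relab <- st
  relab$labels[relab$labels == 1L] <- 99L
  relab$comps$id[relab$comps$id == 1] <- 99L
  expect_equal(total_energy(relab), h0)
})

test_that("local delta_H equals the full-recompute energy difference", {
  # the module's primary oracle: randomized states x randomized moves
  n_checked <- 0
  for (seed in 1:40) {
    st <- random_messy_state(seed,
                             order = if (seed %% 2) 1 else 2,
                             boundary = if (seed %% 3) "fixed-medium"
                                        else "periodic")
    h0 <- total_energy(st)
    for (k in 1:30) {
      mv <- random_move(st)
      dh <- delta_h(st, mv$source, mv$target)
      after <- apply_index_copy(st, mv$source, mv$target)
      expect_lt(abs(dh - (total_energy(after) - h0)), 1e-9)
      n_checked <- n_checked + 1
    }
  }
  expect_gte(n_checked, 1000)
})

test_that("delta_H volume part has its closed form and is antisymmetric", {
  # shrinking a cell at V = V_target by one voxel costs lambda * 1^2 = 10
  st <- make_fixture("isolated-cube")
  st$comps$target_volume <- 27
  dh <- delta_h(st, source_voxel = c(4, 5, 5), target_voxel = c(5, 5, 5))
  dc <- {  # contact part, brute force
    after <- apply_index_copy(st, c(4, 5, 5), c(5, 5, 5))
    oracle_contact_energy(after) - oracle_contact_energy(st)
  }
  expect_equal(dh, 10 + dc, tolerance = 1e-9)

  # a copy followed by its exact reverse has the opposite delta-H
  checked <- 0
  for (seed in 1:10) {
    sti <- random_messy_state(seed)
    mv <- random_move(sti)
    fwd <- delta_h(sti, mv$source, mv$target)
    after <- apply_index_copy(sti, mv$source, mv$target)
    # reverse: restore the overwritten label by copying it back from any
    # neighbor (virtual medium sites included) that still carries it
    old_label <- sti$labels[mv$target[1], mv$target[2], mv$target[3]]
    nb <- neighbor_voxels(after, mv$target)
    j <- which(nb$label == old_label)
    if (!length(j)) next
    rev <- delta_h(after, c(nb$x[j[1]], nb$y[j[1]], nb$z[j[1]]), mv$target)
    expect_equal(rev, -fwd, tolerance = 1e-9)
    checked <- checked + 1
  }
  expect_gte(checked, 3)
})

test_that("a cube at its target volume is a strict local energy minimum", {
  st <- make_fixture("isolated-cube")
  st$comps$target_volume <- 27
  # every admissible single-voxel perturbation raises the energy
  # (labels differ only near the cube at 5:7, so scan its neighborhood)
  for (x in 4:8) for (y in 4:8) for (z in 4:8) {
    nb <- neighbor_voxels(st, c(x, y, z), order = 1)
    tgt_label <- st$labels[x, y, z]
    for (j in seq_len(nrow(nb))) {
      if (nb$label[j] == tgt_label) next
      dh <- delta_h(st, c(nb$x[j], nb$y[j], nb$z[j]), c(x, y, z))
      expect_gt(dh, 0)
    }
  }
})

test_that("at near-zero temperature the energy relaxes monotonically", {
  st <- make_fixture("random-dispersion", n = 12, order = 2, seed = 7)
  p <- unclass(st$params)
  p$table$Tm <- 1e-6
  p$flags$lifecycle <- FALSE
  st$params <- structure(p, class = "cpm_params")
  h <- total_energy(st)
  for (i in 1:10) {
    st <- run_mcs(st, 1)
    h2 <- total_energy(st)
    expect_lte(h2, h + 1e-9)
    h <- h2
  }
})

test_that("the energy audit decomposes H and counts bonds", {
  st <- make_fixture("two-cube-contact")
  a <- energy_audit(st)
  expect_equal(a$H_total, a$H_contact + a$H_volume)
  expect_equal(a$H_total, total_energy(st))
  expect_equal(unname(a$bond_counts["Cell", "Cell"]), 9)   # shared face
  expect_equal(unname(a$bond_counts["Medium", "Cell"]), 90)
})
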