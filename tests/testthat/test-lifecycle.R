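# The cyclic cell/ECM behavior: growth, action gating, mitosis, secretion,
# death, ECM decay and deletion.

test_that("cells below the action threshold only grow their target volume", {
  st <- create_lattice(c(9, 9, 9))
  # a 15-voxel cell: below V_A = 20, so no action can fire
  vox <- as.matrix(expand.grid(3:7, 4:6, 4))
  st <- add_compartment(st, vox, "Cell", target_volume = 15)
  set.seed(1)
  for (i in 1:50) st <- update_cell(st, 1)
  expect_equal(nrow(st$comps), 1)                      # no mitosis, no ECM
  expect_equal(st$comps$target_volume, 15 + 50 * 0.08) # SZ growth speed
  expect_equal(st$comps$volume, 15)                    # realized volume untouched
})

test_that("cells above V_Death are deleted and their voxels become medium", {
  st <- create_lattice(c(12, 12, 12))
  vox <- as.matrix(expand.grid(3:7, 3:7, 3:5))  # 75 voxels > V_Death = 60
  st <- add_compartment(st, vox, "Cell")
  set.seed(1)
  st2 <- update_cell(st, 1)
  expect_equal(nrow(st2$comps), 0)
  expect_equal(medium_volume(st2), prod(dim(st2$labels)))
  expect_equal(unname(st2$counters["cell_death"]), 1)
})

test_that("with all action probabilities zero the cell population is constant", {
  ov <- list(P_M = 0, P_ECMst = 0, P_ECMv = 0)
  st <- make_fixture("mini-seeding", n = 20, seed = 2)
  p <- unclass(build_parameter_set("SZ", ov))
  p$domain$dims <- dim(st$labels)
  st$params <- structure(p, class = "cpm_params")
  st <- run_mcs(st, 30)
  expect_equal(sum(st$comps$type == "Cell"), 20)
  expect_equal(unname(st$counters["mitosis"]), 0)
  expect_equal(unname(st$counters[c("secrete_ECMst", "secrete_ECMv")]),
               c(0, 0))
})

test_that("division partitions the parent nearly in half with targets V_Cell/2", {
  set.seed(7)
  st <- create_lattice(c(12, 12, 12))
  vox <- as.matrix(expand.grid(4:8, 4:9, 5:6))[1:30, ]  # a 30-voxel slab
  st <- add_compartment(st, vox, "Cell")
  for (i in 1:10) {
    r <- divide_cell(st, 1)
    s2 <- r$state
    expect_equal(nrow(s2$comps), 2)
    expect_equal(sum(s2$comps$volume), 30)              # partition, no loss
    expect_equal(s2$comps$target_volume, c(15, 15))     # V_parent = V_daughter
    expect_lte(abs(diff(s2$comps$volume)), 1)           # median split balance
    expect_silent(validate_state(s2))
  }
  # offspring start below the action threshold: 15 < V_A = 20
  r <- divide_cell(st, 1)
  expect_true(all(r$state$comps$volume < 20))

  # a 1-voxel cell cannot divide
  st1 <- create_lattice(c(5, 5, 5))
  st1 <- add_compartment(st1, matrix(c(3, 3, 3), 1), "Cell")
  expect_error(divide_cell(st1, 1), "cannot divide")
})

test_that("repeated division with growth disabled conserves cell voxels", {
  ov <- list(P_M = 20, P_ECMst = 0, P_ECMv = 0, v_g = 0)
  st <- make_fixture("mini-seeding", n = 12, seed = 3)
  p <- unclass(build_parameter_set("SZ", ov))
  p$domain$dims <- dim(st$labels)
  p$domain$attempts_per_mcs <- 0  # isolate the lifecycle from the dynamics
  st$params <- structure(p, class = "cpm_params")
  v0 <- sum(st$comps$volume[st$comps$type == "Cell"])
  set.seed(4)
  st <- run_mcs(st, 20)
  expect_equal(sum(st$comps$volume[st$comps$type == "Cell"]), v0)
  expect_gt(unname(st$counters["mitosis"]), 0)
  expect_silent(validate_state(st))
})

test_that("secretion creates an adjacent ECM compartment with target V_ECMInit", {
  st <- make_fixture("isolated-cube")
  set.seed(5)
  r <- secrete_ecm(st, 1, "ECMv")
  expect_false(is.na(r$ecm_id))
  s2 <- r$state
  i <- match(r$ecm_id, s2$comps$id)
  expect_equal(s2$comps$type[i], "ECMv")
  expect_equal(s2$comps$target_volume[i], 30)
  expect_lte(s2$comps$volume[i], 8)   # seeded as up to a 2x2x2 block
  expect_gte(s2$comps$volume[i], 1)
  expect_gt(contact_area(s2, 1, r$ecm_id, order = 1), 0)  # pericellular
  expect_silent(validate_state(s2))
})

test_that("a fully enclosed cell cannot secrete (blocked, logged)", {
  st <- create_lattice(c(9, 9, 9))
  st <- add_compartment(st, as.matrix(expand.grid(4:6, 4:6, 4:6)), "Cell")
  # enclose the cell completely with one ECMst husk
  husk <- as.matrix(expand.grid(3:7, 3:7, 3:7))
  inner <- husk[, 1] >= 4 & husk[, 1] <= 6 & husk[, 2] >= 4 & husk[, 2] <= 6 &
    husk[, 3] >= 4 & husk[, 3] <= 6
  st <- add_compartment(st, husk[!inner, ], "ECMst", target_volume = 98)
  set.seed(6)
  r <- secrete_ecm(st, 1, "ECMst")
  expect_true(is.na(r$ecm_id))
  expect_equal(unname(r$state$counters["secretion_blocked"]), 1)
  expect_equal(nrow(r$state$comps), 2)
})

test_that("ECM decay moves the target at v_d and deletion clears small ECM", {
  # DZ decay arithmetic: 30 - 100 * 0.097 = 20.3 after 100 updates
  st <- create_lattice(c(10, 10, 10),
                       params = build_parameter_set("DZ"))
  st <- add_compartment(st, as.matrix(expand.grid(4:6, 4:6, 4:6)), "ECMst",
                        target_volume = 30)
  for (i in 1:100) st <- update_ecm(st, 1)
  expect_equal(st$comps$target_volume, 30 - 100 * 0.097)

  # v_d = 0 keeps the target forever
  st0 <- create_lattice(c(10, 10, 10),
                        params = build_parameter_set("SZ", list(v_d = 0)))
  st0 <- add_compartment(st0, as.matrix(expand.grid(4:6, 4:6, 4:6)), "ECMv",
                         target_volume = 30)
  for (i in 1:50) st0 <- update_ecm(st0, 1)
  expect_equal(st0$comps$target_volume, 30)

  # an ECM at volume 2 < V_Delete = 3 is deleted; voxels return to medium
  st2 <- create_lattice(c(6, 6, 6))
  st2 <- add_compartment(st2, rbind(c(3, 3, 3), c(4, 3, 3)), "ECMv",
                         target_volume = 2)
  st2 <- update_ecm(st2, 1)
  expect_equal(nrow(st2$comps), 0)
  expect_equal(medium_volume(st2), 216)
  expect_equal(unname(st2$counters["ecm_deleted"]), 1)
})

test_that("realized ECM deletion times track the decay law (quiescent lattice)", {
  # expected lifetime (V_ECMInit - V_Delete) / v_d: 1000 MCS for MZ, ~278 DZ;
  # deletion runs a little early because the contact term holds the realized
  # volume below its target (order-1 neighborhood keeps that lag smallest)
  for (zone in c("MZ", "DZ")) {
    params <- build_parameter_set(zone, list(neighborhood_order = 1))
    expected <- (30 - 3) / unclass(params)$table$v_d
    times <- vapply(1:4, function(s) {
      set.seed(s)
      st <- create_lattice(c(14, 14, 14), params = params)
      st <- add_compartment(st, as.matrix(expand.grid(5:7, 5:7, 5:7)), "ECMst",
                            target_volume = 30)
      st <- run_mcs(st, ceiling(expected * 1.4), record_events = TRUE)
      del <- st$events[st$events$event == "ecm_deleted", ]
      expect_equal(nrow(del), 1)
      del$mcs
    }, 0)
    expect_lt(abs(mean(times) - expected) / expected, 0.15)
  }
})

test_that("mitosis and secretion draws are Binomial(N, p) at 3 sigma", {
  # one lifecycle sweep over N always-eligible cells; per-zone probabilities
  set.seed(9)
  st0 <- make_fixture("random-dispersion", n = 2000, types = "Cell",
                      dims = c(54, 54, 54), order = 2, seed = 9)
  check_binomial <- function(observed, n, p, slack = 0) {
    expect_lt(abs(observed - n * p), 3 * sqrt(n * p * (1 - p)) + slack + 1e-9)
  }
  for (zone in c("SZ", "MZ", "DZ")) {
    params <- build_parameter_set(zone)
    t <- unclass(params)$table
    st <- st0
    p <- unclass(params)
    p$domain$dims <- dim(st$labels)
    p$domain$attempts_per_mcs <- 0
    st$params <- structure(p, class = "cpm_params")
    st <- run_mcs(st, 1)
    check_binomial(unname(st$counters["mitosis"]), 2000, t$P_M / 100)
    # mitosis preempts secretion, so only non-dividing cells draw secretion;
    # a blocked placement is a fired draw that placed no compartment, so it
    # widens the band by at most the blocked count
    n_eligible <- 2000 - unname(st$counters["mitosis"])
    blocked <- unname(st$counters["secretion_blocked"])
    check_binomial(unname(st$counters["secrete_ECMst"]) + blocked / 2,
                   n_eligible, t$P_ECMst / 100, slack = blocked / 2)
    check_binomial(unname(st$counters["secrete_ECMv"]) + blocked / 2,
                   n_eligible, t$P_ECMv / 100, slack = blocked / 2)
  }
})

test_that("raising the ECM decay speed never raises the ECM content", {
  # paired seeds, SZ conditions vs the same with the DZ decay speed
  ecm_voxels <- function(v_d, seed) {
    params <- build_parameter_set("SZ", list(v_d = v_d))
    st <- seed_zone(params, n_cells = 24, seed = seed)
    st <- run_mcs(st, 120)
    sum(st$comps$volume[st$comps$type %in% c("ECMst", "ECMv")])
  }
  lo <- vapply(1:10, function(s) ecm_voxels(0.003, s), 0)
  hi <- vapply(1:10, function(s) ecm_voxels(0.097, s), 0)
  expect_lte(mean(hi), mean(lo))
})

test_that("lifecycle updates never create or destroy voxels", {
  st <- make_fixture("mini-seeding", n = 40, seed = 10)
  n_total <- prod(dim(st$labels))
  set.seed(10)
  for (i in 1:5) {
    st <- run_mcs(st, 10)
    expect_equal(sum(st$comps$volume) + medium_volume(st), n_total)
    expect_silent(validate_state(st))
  }
})
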