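# Shared reduced-scale simulation runs for the acceptance checks (computed
# once per test session and reused across blocks).

.run_cache <- new.env(parent = emptyenv())

# reduced surrogate of a zone culture: 100 cells, proportionally scaled
# cylinder, 720 MCS (the day-4 mark, where aggregation is established)
reduced_run <- function(zone, seed, n_cells = 100, mcs = 720,
                        overrides = list()) {
  key <- paste(zone, seed, n_cells, mcs,
               paste(names(overrides), unlist(overrides), collapse = "_"),
               sep = "|")
  if (!is.null(.run_cache[[key]])) return(.run_cache[[key]])
  params <- build_parameter_set(zone, overrides)
  st0 <- seed_zone(params, n_cells = n_cells, seed = seed)
  st <- run_mcs(st0, mcs)
  out <- list(initial = st0, final = st)
  .run_cache[[key]] <- out
  out
}

# periodic two-compartment state engineered so that *every* admissible move
# has delta-H exactly Tm: J = 0 everywhere, lambda = Tm/2, and both
# compartments sit half a voxel above target (growing one costs
# lambda * (2 * 0.5 + 1) = Tm, shrinking the other costs 0)
.engineered_state <- function(Tm = 37) {
  zero_j <- list(J_medium_medium = 0, J_cell_cell = 0, J_medium_cell = 0,
                 J_medium_ECM = 0, J_cell_ECM = 0, J_ECM_ECM = 0,
                 lambda_vol = Tm / 2, Tm = Tm, boundary = "periodic",
                 neighborhood_order = 1, lifecycle = FALSE)
  params <- build_parameter_set("SZ", overrides = zero_j)
  st <- create_lattice(c(6, 6, 6), boundary = "periodic", params = params)
  labels <- array(1L, dim = c(6, 6, 6))
  labels[, , 4:6] <- 2L
  st$labels <- labels
  st$comps <- data.frame(id = 1:2, type = "Cell", zone = "SZ",
                         volume = c(108, 108),
                         target_volume = c(107.5, 107.5),
                         stringsAsFactors = FALSE)
  st
}
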