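## The Hamiltonian H = H_contact + H_volume and the local delta-H that drives
## acceptance of index copies.
##
## H_contact sums the contact energy J(type_i, type_j) once per unordered
## neighbor pair whose voxels belong to *different* compartments (the
## (1 - delta(sigma_i, sigma_j)) factor). H_volume is the quadratic penalty
## lambda_vol * (V - V_target)^2 over volume-constrained compartments; the
## medium carries no volume term.

#' Total contact energy of a state
#'
#' @param state a `cpm_state`.
#' @param order neighborhood order (default: the state's own).
#' @return contact energy (one count per unordered neighbor pair of distinct
#'   compartments; bonds to virtual medium sites outside a fixed-medium
#'   lattice are included).
#' @export
contact_energy <- function(state, order = NULL) {
  order <- order %||% unclass(state$params)$domain$neighborhood_order
  a <- .state_args(state)
  .cpm_contact_energy(a$labels, a$ids, a$types, .j_matrix(state$params),
                      as.integer(order),
                      identical(unclass(state$params)$domain$boundary, "periodic"))
}

#' Total volume-constraint energy of a state
#'
#' `sum(lambda_vol * (V - V_target)^2)` over constrained compartments (cells,
#' plus ECM unless the `ecm_constrained` flag is off); the medium is excluded.
#'
#' @param state a `cpm_state`.
#' @return volume energy.
#' @export
volume_energy <- function(state) {
  p <- unclass(state$params)
  lambda <- p$table$lambda_vol
  constrained <- state$comps$type == "Cell" |
    (state$comps$type %in% c("ECMst", "ECMv") & isTRUE(p$flags$ecm_constrained))
  sum(lambda * (state$comps$volume[constrained] -
                  state$comps$target_volume[constrained])^2)
}

#' Total energy H = H_contact + H_volume
#' @param state a `cpm_state`.
#' @param order neighborhood order for the contact term (default: the state's).
#' @return total energy.
#' @export
total_energy <- function(state, order = NULL) {
  contact_energy(state, order) + volume_energy(state)
}

#' Local energy change of one index copy
#'
#' Energy difference H(after) - H(before) for copying the source voxel's label
#' onto the target voxel, computed locally: only the target voxel's neighbor
#' bonds and the two affected compartments' volume terms change.
#'
#' @param state a `cpm_state`.
#' @param source_voxel,target_voxel 1-based voxel coordinates; must be
#'   neighbors with distinct labels. Under the fixed-medium boundary the
#'   source may be an out-of-lattice virtual medium site.
#' @return the energy difference (a scalar).
#' @export
delta_h <- function(state, source_voxel, target_voxel) {
  d <- dim(state$labels)
  source_voxel <- as.integer(source_voxel)
  target_voxel <- as.integer(target_voxel)
  if (!.in_lattice(d, target_voxel)) stop("target voxel outside lattice")
  order <- unclass(state$params)$domain$neighborhood_order
  if (max(abs(source_voxel - target_voxel)) > 1 ||
      sum(abs(source_voxel - target_voxel)) > order) {
    stop("source and target voxels are not neighbors at order ", order)
  }
  periodic <- identical(unclass(state$params)$domain$boundary, "periodic")
  if (.in_lattice(d, source_voxel)) {
    src <- state$labels[matrix(source_voxel, 1)]
  } else if (periodic) {
    sv <- ((source_voxel - 1) %% d) + 1
    src <- state$labels[matrix(sv, 1)]
  } else {
    src <- 0L
  }
  a <- .state_args(state)
  .cpm_delta_h(a$labels, a$ids, a$types, a$volumes, a$targets,
               .cpp_par(state$params), as.integer(src),
               .vox_index(d, target_voxel))
}

#' Energy audit of a state
#'
#' Decomposes the Hamiltonian: contact term, volume term, total, and the
#' per-type-pair boundary bond counts behind the contact term.
#'
#' @param state a `cpm_state`.
#' @return list with `H_contact`, `H_volume`, `H_total` and `bond_counts`
#'   (an upper-triangular 4x4 matrix over Medium/Cell/ECMst/ECMv).
#' @export
energy_audit <- function(state) {
  a <- .state_args(state)
  p <- unclass(state$params)
  counts <- .cpm_bond_counts(a$labels, a$ids, a$types,
                             as.integer(p$domain$neighborhood_order),
                             identical(p$domain$boundary, "periodic"))
  dimnames(counts) <- list(.TYPE_NAMES, .TYPE_NAMES)
  hc <- contact_energy(state)
  hv <- volume_energy(state)
  list(H_contact = hc, H_volume = hv, H_total = hc + hv, bond_counts = counts)
}
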