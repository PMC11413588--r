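## Single-compartment lifecycle operations. These call the same C++ routines
## used inside the per-MCS sweep of run_mcs(), so behavior in isolation and in
## a full run is identical.

.lifecycle_op <- function(state, id, op, kind = -1L) {
  a <- .state_args(state)
  res <- .cpm_lifecycle_op(a$labels, a$ids, a$types, a$volumes, a$targets,
                           .cpp_par(state$params), as.integer(id), op,
                           as.integer(kind))
  list(state = .absorb_cpp(state, res), result_id = res$result_id)
}

#' One lifecycle update of a cell compartment
#'
#' Grows the cell's target volume by `v_g`. A cell whose realized volume
#' exceeds `V_Death` is deleted (its voxels become medium). Otherwise, if the
#' realized volume exceeds the action threshold `V_A`, the cell draws its
#' stochastic actions for this MCS: mitosis with probability `P_M`, then —
#' unless a division fired and `mitosis_preempts` is on — ECMst secretion with
#' `P_ECMst` and ECMv secretion with `P_ECMv` (independent draws).
#'
#' @param state a `cpm_state`.
#' @param id id of a live cell compartment.
#' @return the updated state.
#' @export
update_cell <- function(state, id) {
  .lifecycle_op(state, id, "update_cell")$state
}

#' One lifecycle update of an ECM compartment
#'
#' Decays the ECM's target volume by `v_d`; an ECM compartment whose realized
#' volume has fallen below `V_Delete` is deleted and its voxels replaced by
#' medium.
#'
#' @param state a `cpm_state`.
#' @param id id of a live ECMst or ECMv compartment.
#' @return the updated state.
#' @export
update_ecm <- function(state, id) {
  .lifecycle_op(state, id, "update_ecm")$state
}

#' Divide a cell compartment
#'
#' Splits the cell along a random-orientation plane: voxels are ordered by
#' their projection onto a random unit normal and cut at the median, so the
#' plane passes through the centroid for symmetric bodies and the two halves
#' differ by at most one voxel. The parent keeps its id; the daughter gets a
#' fresh id; both get target volume `V_parent = V_daughter = V_Cell / 2`.
#'
#' @param state a `cpm_state`.
#' @param id id of a live cell with at least 2 voxels.
#' @return list with `state`, `parent_id`, `daughter_id`.
#' @export
divide_cell <- function(state, id) {
  r <- .lifecycle_op(state, id, "divide")
  list(state = r$state, parent_id = as.integer(id), daughter_id = r$result_id)
}

#' Secrete a new ECM compartment from a cell
#'
#' Creates a new ECM compartment of the requested kind at medium voxels
#' face-adjacent to the cell: a random adjacent medium voxel anchors an (up
#' to) 2x2x2 seed block of medium voxels, and the new compartment's target
#' volume `V_ECMInit` lets the volume constraint grow it toward full size. If
#' the cell has no adjacent medium voxel, secretion fails silently (counted
#' under `counters["secretion_blocked"]`).
#'
#' @param state a `cpm_state`.
#' @param id id of a live cell compartment.
#' @param kind `"ECMst"` or `"ECMv"`.
#' @return list with `state` and `ecm_id` (NA if secretion was blocked).
#' @export
secrete_ecm <- function(state, id, kind = c("ECMst", "ECMv")) {
  kind <- match.arg(kind)
  r <- .lifecycle_op(state, id, "secrete", kind = .type_code(kind))
  list(state = r$state, ecm_id = r$result_id)
}
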