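## Voxel lattice, compartment registry, neighborhoods, and the elementary
## index-copy with exact volume bookkeeping.

.empty_comps <- function() {
  data.frame(id = integer(), type = character(), zone = character(),
             volume = numeric(), target_volume = numeric(),
             stringsAsFactors = FALSE)
}

.zero_counters <- function() {
  c(attempts = 0, accepted = 0, mitosis = 0, secrete_ECMst = 0,
    secrete_ECMv = 0, ecm_deleted = 0, cell_death = 0,
    secretion_blocked = 0, annihilated = 0)
}

.empty_events <- function() {
  data.frame(mcs = integer(), event = character(), id = integer(),
             zone = character(), stringsAsFactors = FALSE)
}

.new_state <- function(labels, comps, params, mcs = 0L) {
  structure(
    list(labels = labels, comps = comps, zone = unclass(params)$zone,
         params = params, mcs = as.integer(mcs),
         counters = .zero_counters(), events = .empty_events()),
    class = "cpm_state"
  )
}

#' Create an all-medium voxel lattice
#'
#' Every voxel starts as medium (compartment id 0). The returned simulation
#' state carries the given parameter set; compartments are added either by
#' [seed_zone()], [make_fixture()], or manually via [add_compartment()].
#'
#' @param dims integer vector `(nx, ny, nz)`, all >= 1.
#' @param boundary `"fixed-medium"` (out-of-lattice sites behave as medium,
#'   the default, matching a culture well) or `"periodic"`.
#' @param params a [build_parameter_set()] object (default: SZ).
#' @return A `cpm_state` with `prod(dims)` medium voxels.
#' @examples
#' st <- create_lattice(c(4, 4, 4))
#' medium_volume(st)  # 64
#' @export
create_lattice <- function(dims, boundary = c("fixed-medium", "periodic"),
                           params = build_parameter_set("SZ")) {
  boundary <- match.arg(boundary)
  dims <- as.integer(dims)
  if (length(dims) != 3 || anyNA(dims) || any(dims < 1)) {
    stop("dims must be three positive integers")
  }
  stopifnot(inherits(params, "cpm_params"))
  p <- unclass(params)
  p$domain$dims <- dims
  p$domain$boundary <- boundary
  params <- structure(p, class = "cpm_params")
  labels <- array(0L, dim = dims)
  .new_state(labels, .empty_comps(), params)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Number of medium voxels in a state
#' @param state a `cpm_state`.
#' @return integer count of voxels labeled 0.
#' @export
medium_volume <- function(state) {
  prod(dim(state$labels)) - sum(state$comps$volume)
}

#' Register a new compartment occupying a block of voxels
#'
#' Low-level constructor used by the seeding routines and fixtures: claims the
#' given voxels (which must currently be medium) for a fresh compartment id.
#'
#' @param state a `cpm_state`.
#' @param voxels n x 3 matrix of 1-based voxel coordinates.
#' @param type `"Cell"`, `"ECMst"` or `"ECMv"`.
#' @param target_volume target volume; defaults to the parameter set's
#'   `V_Cell` for cells and `V_ECMInit` for ECM.
#' @return the updated state, with the new id in `attr(, "new_id")`.
#' @export
add_compartment <- function(state, voxels, type, target_volume = NULL) {
  stopifnot(inherits(state, "cpm_state"))
  type <- match.arg(type, c("Cell", "ECMst", "ECMv"))
  voxels <- matrix(as.integer(voxels), ncol = 3)
  d <- dim(state$labels)
  if (any(voxels < 1) || any(voxels[, 1] > d[1]) || any(voxels[, 2] > d[2]) ||
      any(voxels[, 3] > d[3])) {
    stop("voxel coordinates outside the lattice")
  }
  idx <- voxels[, 1] + d[1] * (voxels[, 2] - 1L + d[2] * (voxels[, 3] - 1L))
  if (any(state$labels[idx] != 0L)) stop("voxels are not all medium")
  if (anyDuplicated(idx)) stop("duplicate voxels")
  if (is.null(target_volume)) {
    t <- unclass(state$params)$table
    target_volume <- if (type == "Cell") t$V_Cell else t$V_ECMInit
  }
  id <- if (nrow(state$comps)) max(state$comps$id) + 1L else 1L
  state$labels[idx] <- id
  state$comps <- rbind(state$comps, data.frame(
    id = id, type = type, zone = state$zone, volume = nrow(voxels),
    target_volume = target_volume, stringsAsFactors = FALSE))
  attr(state, "new_id") <- id
  state
}

# linear (1-based) index of voxel coordinates
.vox_index <- function(dims, voxel) {
  voxel[1] + dims[1] * (voxel[2] - 1 + dims[2] * (voxel[3] - 1))
}

.in_lattice <- function(dims, voxel) {
  all(voxel >= 1) && all(voxel <= dims)
}

# neighbor displacement matrix for a neighborhood order (L1 norm <= order)
.nbr_offsets <- function(order) {
  stopifnot(order %in% 1:3)
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  l1 <- rowSums(abs(g))
  g[l1 >= 1 & l1 <= order, , drop = FALSE]
}

#' Neighbor voxels of a lattice site
#'
#' Returns the neighborhood of a voxel: 6 face neighbors at order 1, +12 edge
#' neighbors at order 2, +8 corner neighbors at order 3 (the full Moore
#' neighborhood). Under the fixed-medium boundary, out-of-lattice neighbors
#' are reported as virtual medium sites (`label` 0, `virtual` TRUE); under the
#' periodic boundary coordinates are wrapped.
#'
#' @param state a `cpm_state`.
#' @param voxel 1-based voxel coordinates `(x, y, z)`, inside the lattice.
#' @param order neighborhood order (1, 2 or 3); default: the state's own.
#' @return data.frame with columns `x`, `y`, `z`, `label`, `virtual`.
#' @export
neighbor_voxels <- function(state, voxel, order = NULL) {
  d <- dim(state$labels)
  voxel <- as.integer(voxel)
  if (!.in_lattice(d, voxel)) stop("voxel outside lattice")
  order <- order %||% unclass(state$params)$domain$neighborhood_order
  off <- .nbr_offsets(order)
  nb <- sweep(off, 2, voxel, "+")
  periodic <- identical(unclass(state$params)$domain$boundary, "periodic")
  if (periodic) {
    nb <- ((nb - 1) %% matrix(d, nrow(nb), 3, byrow = TRUE)) + 1
  }
  inside <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
    nb[, 3] >= 1 & nb[, 3] <= d[3]
  label <- integer(nrow(nb))
  label[inside] <- state$labels[nb[inside, , drop = FALSE]]
  data.frame(x = nb[, 1], y = nb[, 2], z = nb[, 3], label = label,
             virtual = !inside)
}

#' Apply one index copy (label rewrite) with exact bookkeeping
#'
#' Copies the source voxel's compartment id onto the target voxel. The two
#' voxels must be neighbors (within the state's neighborhood order) and carry
#' different labels. Under the fixed-medium boundary the source may lie
#' outside the lattice, in which case it is a virtual medium site. A
#' compartment whose last voxel is overwritten is removed from the registry
#' (counted under `counters["annihilated"]`).
#'
#' @param state a `cpm_state`.
#' @param source_voxel,target_voxel 1-based voxel coordinates.
#' @return the updated state.
#' @export
apply_index_copy <- function(state, source_voxel, target_voxel) {
  d <- dim(state$labels)
  source_voxel <- as.integer(source_voxel)
  target_voxel <- as.integer(target_voxel)
  if (!.in_lattice(d, target_voxel)) stop("target voxel outside lattice")
  order <- unclass(state$params)$domain$neighborhood_order
  if (max(abs(source_voxel - target_voxel)) > 1 ||
      sum(abs(source_voxel - target_voxel)) > order ||
      all(source_voxel == target_voxel)) {
    stop("source and target voxels are not neighbors at order ", order)
  }
  periodic <- identical(unclass(state$params)$domain$boundary, "periodic")
  if (.in_lattice(d, source_voxel)) {
    src <- state$labels[matrix(source_voxel, 1)]
  } else if (periodic) {
    sv <- ((source_voxel - 1) %% d) + 1
    src <- state$labels[matrix(sv, 1)]
  } else {
    src <- 0L  # virtual medium site
  }
  tgt <- state$labels[matrix(target_voxel, 1)]
  if (src == tgt) stop("source and target voxels carry the same label (no-op)")
  state$labels[matrix(target_voxel, 1)] <- src
  if (src != 0L) {
    i <- match(src, state$comps$id)
    state$comps$volume[i] <- state$comps$volume[i] + 1
  }
  if (tgt != 0L) {
    i <- match(tgt, state$comps$id)
    state$comps$volume[i] <- state$comps$volume[i] - 1
    if (state$comps$volume[i] == 0) {
      state$comps <- state$comps[-i, , drop = FALSE]
      state$counters["annihilated"] <- state$counters["annihilated"] + 1
    }
  }
  state
}

#' Contact area between two compartments
#'
#' Number of unordered neighbor voxel pairs whose labels are `id_a` and
#' `id_b`. Id 0 is the medium; under the fixed-medium boundary, bonds to
#' virtual out-of-lattice medium sites are included. `id_a == id_b` returns 0
#' (pairs inside one compartment are not boundary pairs).
#'
#' @param state a `cpm_state`.
#' @param id_a,id_b compartment ids (0 = medium).
#' @param order neighborhood order; default: the state's own.
#' @return integer pair count.
#' @export
contact_area <- function(state, id_a, id_b, order = NULL) {
  for (id in c(id_a, id_b)) {
    if (id != 0 && !(id %in% state$comps$id)) stop("unknown compartment id ", id)
  }
  order <- order %||% unclass(state$params)$domain$neighborhood_order
  periodic <- identical(unclass(state$params)$domain$boundary, "periodic")
  .cpm_contact_area(state$labels, as.integer(id_a), as.integer(id_b),
                    as.integer(order), periodic)
}

#' Check state bookkeeping against the label field
#'
#' Recounts every compartment's voxels from the lattice and compares with the
#' registry; verifies that volumes (medium included) sum to the lattice size.
#'
#' @param state a `cpm_state`.
#' @return TRUE invisibly; stops with a message on any inconsistency.
#' @export
validate_state <- function(state) {
  lab <- as.integer(state$labels)
  n <- length(lab)
  counts <- tabulate(lab + 1L, nbins = max(lab, state$comps$id, 0L) + 1L)
  for (i in seq_len(nrow(state$comps))) {
    id <- state$comps$id[i]
    found <- if (id + 1L <= length(counts)) counts[id + 1L] else 0L
    if (found != state$comps$volume[i]) {
      stop("volume mismatch for compartment ", id, ": registry ",
           state$comps$volume[i], ", lattice ", found)
    }
  }
  extra <- setdiff(unique(lab), c(0L, state$comps$id))
  if (length(extra)) stop("unregistered label(s) on lattice: ",
                          paste(extra, collapse = ", "))
  if (sum(state$comps$volume) + medium_volume(state) != n) {
    stop("volumes do not sum to the lattice size")
  }
  invisible(TRUE)
}

# arguments for the C++ engine
.state_args <- function(state) {
  list(labels = state$labels,
       ids = as.integer(state$comps$id),
       types = .type_code(state$comps$type),
       volumes = as.numeric(state$comps$volume),
       targets = as.numeric(state$comps$target_volume))
}

.EVENT_NAMES <- c("mitosis", "secrete_ECMst", "secrete_ECMv", "ecm_deleted",
                  "cell_death", "secretion_blocked")

# fold a C++ result back into the R state
.absorb_cpp <- function(state, res) {
  state$labels <- res$labels
  state$comps <- if (length(res$ids)) {
    data.frame(id = res$ids, type = .type_name(res$types), zone = state$zone,
               volume = res$volumes, target_volume = res$targets,
               stringsAsFactors = FALSE)
  } else {
    .empty_comps()
  }
  state$mcs <- res$mcs
  state$counters <- state$counters + res$counters[names(state$counters)]
  if (length(res$ev_mcs)) {
    state$events <- rbind(state$events, data.frame(
      mcs = res$ev_mcs, event = .EVENT_NAMES[res$ev_code], id = res$ev_id,
      zone = state$zone, stringsAsFactors = FALSE))
  }
  state
}
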