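## Morphometric readouts: connected clusters, projected and equivalent
## diameters, diameter ratios, and radial core-shell profiles.

#' Find connected clusters of compartments
#'
#' Labels face-connected (order-1) components of the voxel lattice over
#' non-medium voxels (`"all-matter"` mode: a *spheroid* of cells plus ECM) or
#' cell voxels only (`"cells-only"` mode: *cell clusters*). Every compartment
#' is assigned to the component containing the majority of its voxels.
#'
#' @param state a `cpm_state`.
#' @param mode `"all-matter"` or `"cells-only"`.
#' @return a `cluster_report`: list with `mcs`, `mode`, `n_clusters`,
#'   `clusters` (one row per cluster: voxel count, member compartment counts
#'   by type, centroid, projected and equivalent diameters), `membership`
#'   (data.frame id -> cluster) and `comp` (the per-voxel component array).
#' @export
find_clusters <- function(state, mode = c("all-matter", "cells-only")) {
  mode <- match.arg(mode)
  a <- .state_args(state)
  res <- .cpm_components(a$labels, a$ids, a$types,
                         if (mode == "all-matter") 0L else 1L)
  K <- res$n_components
  comp <- res$comp
  membership <- data.frame(id = state$comps$id, cluster = res$majority)
  clusters <- data.frame(cluster = integer(), n_voxels = integer(),
                         n_cells = integer(), n_ecmst = integer(),
                         n_ecmv = integer(), centroid_x = numeric(),
                         centroid_y = numeric(), centroid_z = numeric(),
                         projected_diameter = numeric(),
                         equivalent_diameter = numeric())
  if (K > 0) {
    d <- dim(state$labels)
    cv <- as.integer(comp)
    sel <- which(cv > 0L)
    k <- cv[sel]
    x <- ((sel - 1L) %% d[1]) + 1L
    y <- (((sel - 1L) %/% d[1]) %% d[2]) + 1L
    z <- ((sel - 1L) %/% (d[1] * d[2])) + 1L
    n_vox <- tabulate(k, K)
    cx <- rowsum(as.numeric(x), k)[, 1] / n_vox
    cy <- rowsum(as.numeric(y), k)[, 1] / n_vox
    cz <- rowsum(as.numeric(z), k)[, 1] / n_vox
    # projected XY footprint area: distinct (x, y) columns per cluster
    key <- x + d[1] * as.numeric(y)
    area <- vapply(split(key, k), function(u) length(unique(u)), 0)
    area <- area[as.character(seq_len(K))]
    memb_type <- state$comps$type
    cnt <- function(tp) {
      m <- membership$cluster[memb_type == tp]
      tabulate(m[!is.na(m)], K)
    }
    clusters <- data.frame(
      cluster = seq_len(K), n_voxels = n_vox,
      n_cells = cnt("Cell"), n_ecmst = cnt("ECMst"), n_ecmv = cnt("ECMv"),
      centroid_x = cx, centroid_y = cy, centroid_z = cz,
      projected_diameter = 2 * sqrt(area / pi),
      equivalent_diameter = (6 * n_vox / pi)^(1 / 3))
  }
  structure(list(mcs = state$mcs, mode = mode, n_clusters = K,
                 clusters = clusters, membership = membership, comp = comp),
            class = "cluster_report")
}

#' @export
print.cluster_report <- function(x, ...) {
  cat(sprintf("cluster report (MCS %d, %s): %d cluster(s)\n",
              x$mcs, x$mode, x$n_clusters))
  if (x$n_clusters > 0) {
    ord <- order(-x$clusters$n_voxels)
    print(utils::head(x$clusters[ord, ], 10), row.names = FALSE)
  }
  invisible(x)
}

#' Voxel coordinates of one cluster
#' @param report a [find_clusters()] report.
#' @param cluster cluster index.
#' @return n x 3 matrix of 1-based voxel coordinates.
#' @export
cluster_voxels <- function(report, cluster) {
  d <- dim(report$comp)
  sel <- which(as.integer(report$comp) == as.integer(cluster))
  if (!length(sel)) stop("cluster ", cluster, " is empty or unknown")
  cbind(x = ((sel - 1L) %% d[1]) + 1L,
        y = (((sel - 1L) %/% d[1]) %% d[2]) + 1L,
        z = ((sel - 1L) %/% (d[1] * d[2])) + 1L)
}

#' Projected equivalent circular diameter of a voxel set
#'
#' The diameter `2 * sqrt(A / pi)` of the circle with the same area as the
#' voxel set's footprint on the XY plane (A = number of distinct `(x, y)`
#' columns), matching how spheroid diameters are measured on inverted
#' microscope images (XY projections).
#'
#' @param voxels n x 3 matrix of voxel coordinates (e.g. [cluster_voxels()]).
#' @return diameter in voxels.
#' @export
projected_diameter <- function(voxels) {
  voxels <- matrix(as.numeric(voxels), ncol = 3)
  if (!nrow(voxels)) stop("empty voxel set")
  a <- nrow(unique(voxels[, 1:2, drop = FALSE]))
  2 * sqrt(a / pi)
}

#' Equivalent-sphere diameter of a voxel count
#' @param n_voxels cluster volume in voxels.
#' @return `(6 V / pi)^(1/3)`, the diameter of the sphere of equal volume.
#' @export
equivalent_diameter <- function(n_voxels) (6 * n_voxels / pi)^(1 / 3)

# largest cluster by voxel count; ties broken by the lowest centroid z
# (closest to the substrate)
.largest_cluster <- function(report) {
  cl <- report$clusters
  if (!nrow(cl)) stop("cluster report is empty")
  cl <- cl[order(-cl$n_voxels, cl$centroid_z), ]
  cl[1, ]
}

#' Diameter ratio between two snapshots
#'
#' Ratio of the projected diameters of the largest cluster (by voxel count)
#' at the later and the earlier snapshot — the growth readout used to compare
#' simulated spheroids with their culture counterparts (day 14 vs day 1).
#'
#' @param report_t2,report_t1 [find_clusters()] reports at the later and
#'   earlier time.
#' @return `projected_diameter(largest at t2) / projected_diameter(largest at
#'   t1)`.
#' @export
diameter_ratio <- function(report_t2, report_t1) {
  .largest_cluster(report_t2)$projected_diameter /
    .largest_cluster(report_t1)$projected_diameter
}

#' Radial composition profile of a cluster
#'
#' Splits the ball around the cluster centroid (up to the cluster's maximum
#' voxel radius) into `n_shells` concentric equal-width shells and reports the
#' voxel-type composition of each shell. Fractions include medium voxels, so
#' each shell's fractions sum to 1; shells are clipped to the lattice.
#'
#' @param state the `cpm_state` the report was computed from.
#' @param report a [find_clusters()] report.
#' @param cluster cluster index (default: the largest cluster).
#' @param n_shells number of shells, >= 2.
#' @return data.frame with `shell`, `r_inner`, `r_outer`, `n_voxels` and
#'   fractions `medium`, `cell`, `ecmst`, `ecmv`.
#' @export
radial_profile <- function(state, report, cluster = NULL, n_shells = 6) {
  n_shells <- as.integer(n_shells)
  if (n_shells < 2) stop("n_shells must be >= 2")
  cluster <- cluster %||% .largest_cluster(report)$cluster
  vox <- cluster_voxels(report, cluster)
  if (nrow(vox) < 2) stop("degenerate single-voxel cluster")
  cl <- report$clusters[report$clusters$cluster == cluster, ]
  ctr <- c(cl$centroid_x, cl$centroid_y, cl$centroid_z)
  rmax <- sqrt(max((vox[, 1] - ctr[1])^2 + (vox[, 2] - ctr[2])^2 +
                     (vox[, 3] - ctr[3])^2))
  d <- dim(state$labels)
  idx <- seq_len(prod(d)) - 1L
  x <- (idx %% d[1]) + 1L
  y <- ((idx %/% d[1]) %% d[2]) + 1L
  z <- (idx %/% (d[1] * d[2])) + 1L
  r <- sqrt((x - ctr[1])^2 + (y - ctr[2])^2 + (z - ctr[3])^2)
  keep <- r <= rmax
  shell <- pmin(floor(r[keep] / (rmax / n_shells)) + 1L, n_shells)
  code_by_id <- integer(max(state$comps$id, 1L) + 1L)
  code_by_id[state$comps$id + 1L] <- .type_code(state$comps$type)
  code <- code_by_id[as.integer(state$labels)[keep] + 1L]
  n <- tabulate(shell, n_shells)
  frac <- function(tc) {
    cnt <- tabulate(shell[code == tc], n_shells)
    ifelse(n > 0, cnt / n, NA_real_)
  }
  w <- rmax / n_shells
  data.frame(shell = seq_len(n_shells), r_inner = (seq_len(n_shells) - 1) * w,
             r_outer = seq_len(n_shells) * w, n_voxels = n,
             medium = frac(0L), cell = frac(1L), ecmst = frac(2L),
             ecmv = frac(3L))
}

#' Per-snapshot morphometric summary table
#'
#' One row per snapshot: MCS, culture-day equivalent, cluster counts in both
#' connectivity modes, the largest all-matter cluster's diameters, voxel
#' totals per compartment type, compartment counts, and the cumulative
#' lifecycle counters.
#'
#' @param snapshots list of `cpm_state` snapshots (e.g. from
#'   [run_simulation()]).
#' @return data.frame with one row per snapshot.
#' @export
summary_timeseries <- function(snapshots) {
  if (!length(snapshots)) stop("at least one snapshot is required")
  rows <- lapply(snapshots, function(st) {
    am <- find_clusters(st, "all-matter")
    co <- find_clusters(st, "cells-only")
    big <- if (am$n_clusters > 0) .largest_cluster(am) else NULL
    vol_by <- function(tp) sum(st$comps$volume[st$comps$type == tp])
    n_by <- function(tp) sum(st$comps$type == tp)
    data.frame(
      mcs = st$mcs, day = day_for_mcs(st$mcs, st$params$clock),
      n_clusters_all_matter = am$n_clusters,
      n_clusters_cells_only = co$n_clusters,
      largest_projected_diameter = if (is.null(big)) NA_real_
                                   else big$projected_diameter,
      largest_equivalent_diameter = if (is.null(big)) NA_real_
                                    else big$equivalent_diameter,
      cell_voxels = vol_by("Cell"), ecmst_voxels = vol_by("ECMst"),
      ecmv_voxels = vol_by("ECMv"),
      n_cell = n_by("Cell"), n_ecmst = n_by("ECMst"), n_ecmv = n_by("ECMv"),
      mitoses = unname(st$counters["mitosis"]),
      secretions = unname(st$counters["secrete_ECMst"] +
                            st$counters["secrete_ECMv"]),
      deletions = unname(st$counters["ecm_deleted"] +
                           st$counters["cell_death"]))
  })
  do.call(rbind, rows)
}
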