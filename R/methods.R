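## S3 methods for simulation states.

#' @export
print.cpm_state <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("CPM state: %dx%dx%d lattice, zone %s, MCS %d (day %.2f)\n",
              d[1], d[2], d[3], x$zone, x$mcs,
              day_for_mcs(x$mcs, x$params$clock)))
  tp <- table(factor(x$comps$type, levels = c("Cell", "ECMst", "ECMv")))
  cat(sprintf("  compartments: %d cells, %d ECMst, %d ECMv; medium %d voxels\n",
              tp["Cell"], tp["ECMst"], tp["ECMv"], medium_volume(x)))
  invisible(x)
}

#' @export
summary.cpm_state <- function(object, ...) {
  print(object)
  am <- find_clusters(object, "all-matter")
  co <- find_clusters(object, "cells-only")
  cat(sprintf("  clusters: %d all-matter, %d cells-only\n",
              am$n_clusters, co$n_clusters))
  if (am$n_clusters > 0) {
    big <- .largest_cluster(am)
    cat(sprintf("  largest spheroid: %d voxels, projected diameter %.1f\n",
                big$n_voxels, big$projected_diameter))
  }
  cnt <- object$counters
  cat(sprintf("  events: %d mitoses, %d + %d secretions, %d ECM deletions\n",
              cnt["mitosis"], cnt["secrete_ECMst"], cnt["secrete_ECMv"],
              cnt["ecm_deleted"]))
  invisible(list(all_matter = am, cells_only = co))
}

#' Plot a mid-plane slice of the lattice
#'
#' Shows one z-slice of the label field colored by compartment type (white
#' medium, steel-blue cells, salmon ECMst, pale-green ECMv) — the in silico
#' analogue of a spheroid section.
#'
#' @param x a `cpm_state`.
#' @param z slice index (default: the matter-weighted mid-plane).
#' @param ... ignored.
#' @return the slice's type-code matrix, invisibly.
#' @export
plot.cpm_state <- function(x, z = NULL, ...) {
  d <- dim(x$labels)
  code_by_id <- integer(max(x$comps$id, 1L) + 1L)
  if (nrow(x$comps)) code_by_id[x$comps$id + 1L] <- .type_code(x$comps$type)
  if (is.null(z)) {
    zw <- vapply(seq_len(d[3]), function(k) sum(x$labels[, , k] != 0L), 0)
    z <- if (sum(zw) > 0) round(sum(seq_len(d[3]) * zw) / sum(zw)) else
      ceiling(d[3] / 2)
  }
  slice <- matrix(code_by_id[x$labels[, , z] + 1L], d[1], d[2])
  cols <- c("white", "steelblue", "salmon", "palegreen3")
  graphics::image(seq_len(d[1]), seq_len(d[2]), slice, zlim = c(0, 3),
                  col = cols, xlab = "x", ylab = "y", useRaster = TRUE,
                  main = sprintf("zone %s, MCS %d, z = %d", x$zone, x$mcs, z))
  invisible(slice)
}
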