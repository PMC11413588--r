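## Snapshot persistence, determinism hashing, and exports.

.SNAPSHOT_FORMAT <- "spheroidCPM-snapshot-v1"

# md5 of a serialized object (via a scratch file; no external digest dependency)
.md5_of <- function(object) {
  raw <- serialize(object, NULL, version = 2)
  f <- tempfile()
  on.exit(unlink(f))
  writeBin(raw, f)
  unname(tools::md5sum(f))
}

#' Hash of a state's label field and registry
#'
#' md5 over the serialized label array, compartment registry and MCS counter;
#' two states with identical trajectories hash identically, which is the
#' package's determinism contract.
#'
#' @param state a `cpm_state`.
#' @return md5 string.
#' @export
state_hash <- function(state) {
  .md5_of(list(labels = state$labels, comps = state$comps, mcs = state$mcs))
}

#' Write a snapshot archive
#'
#' Stores the full simulation state plus the current RNG state, a format
#' version tag and a checksum, so that a run resumed from the snapshot is
#' bit-identical to an uninterrupted one.
#'
#' @param state a `cpm_state`.
#' @param path file to write (an RDS container).
#' @return `path`, invisibly.
#' @export
write_snapshot <- function(state, path) {
  rng <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  payload <- list(state = state, rng = rng)
  saveRDS(list(format = .SNAPSHOT_FORMAT, payload = payload,
               checksum = .md5_of(payload)), path)
  invisible(path)
}

#' Read a snapshot archive
#'
#' @param path file written by [write_snapshot()].
#' @param restore_rng if TRUE (default), restore the archived RNG state so the
#'   resumed trajectory continues exactly where the original left off.
#' @return the archived `cpm_state`.
#' @export
read_snapshot <- function(path, restore_rng = TRUE) {
  arch <- readRDS(path)
  if (!identical(arch$format, .SNAPSHOT_FORMAT)) {
    stop("unknown snapshot format: ",
         if (is.null(arch$format)) "<missing tag>" else arch$format)
  }
  if (!identical(.md5_of(arch$payload), arch$checksum)) {
    stop("snapshot checksum mismatch: archive is corrupt")
  }
  if (restore_rng && !is.null(arch$payload$rng)) {
    assign(".Random.seed", arch$payload$rng, envir = globalenv())
  }
  arch$payload$state
}

#' Export the label field as an ASCII VTK structured-points file
#'
#' Legacy "STRUCTURED_POINTS" format readable by ParaView and similar viewers;
#' writes two scalar fields, the compartment id and the compartment type code
#' (0 medium, 1 cell, 2 ECMst, 3 ECMv).
#'
#' @param state a `cpm_state`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_vtk <- function(state, path) {
  d <- dim(state$labels)
  lab <- as.integer(state$labels)
  code_by_id <- integer(max(state$comps$id, 1L) + 1L)
  if (nrow(state$comps)) {
    code_by_id[state$comps$id + 1L] <- .type_code(state$comps$type)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               sprintf("spheroidCPM lattice, MCS %d, zone %s",
                       state$mcs, state$zone),
               "ASCII", "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", d[1], d[2], d[3]),
               "ORIGIN 0 0 0", "SPACING 1 1 1",
               sprintf("POINT_DATA %d", prod(d)),
               "SCALARS compartment_id int 1", "LOOKUP_TABLE default"), con)
  writeLines(paste(lab, collapse = " "), con)
  writeLines(c("SCALARS type_code int 1", "LOOKUP_TABLE default"), con)
  writeLines(paste(code_by_id[lab + 1L], collapse = " "), con)
  invisible(path)
}

#' Write the lifecycle event log as CSV
#' @param state a `cpm_state` run with `record_events = TRUE`.
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_event_log <- function(state, path) {
  write.csv(state$events, path, row.names = FALSE)
  invisible(path)
}
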