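## Run configuration: a YAML file carrying the zone, run length, seed and any
## parameter overrides (every parameter-table symbol is addressable by name).

.CONFIG_KEYS <- c("zone", "total_mcs", "snapshot_every", "seed", "n_cells",
                  "out_dir", "overrides")

#' Assemble a run configuration
#'
#' @param zone `"SZ"`, `"MZ"` or `"DZ"`.
#' @param total_mcs run length in MCS (default 3120, the 14-day mark).
#' @param snapshot_every snapshot interval in MCS.
#' @param seed RNG seed.
#' @param n_cells seeded cell count (default: geometry default, 1,000).
#' @param out_dir output directory for the CLI.
#' @param overrides named parameter overrides (validated against
#'   [build_parameter_set()]; unknown names are an error).
#' @return a `cpm_config` list.
#' @export
run_config <- function(zone = "SZ", total_mcs = 3120, snapshot_every = 240,
                       seed = 1, n_cells = NULL, out_dir = ".",
                       overrides = list()) {
  zone <- match.arg(zone, .ZONES)
  params <- build_parameter_set(zone, overrides)  # validates override names
  structure(list(zone = zone, total_mcs = as.integer(total_mcs),
                 snapshot_every = as.integer(snapshot_every),
                 seed = as.integer(seed),
                 n_cells = if (is.null(n_cells)) NULL else as.integer(n_cells),
                 out_dir = out_dir, overrides = overrides, params = params),
            class = "cpm_config")
}

#' Save a run configuration as YAML
#' @param config a [run_config()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "cpm_config"))
  x <- unclass(config)
  x$params <- NULL
  x <- x[!vapply(x, is.null, TRUE)]
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Load a run configuration from YAML
#'
#' Unknown top-level keys and unknown parameter-override names are rejected
#' with the offending key named. The returned configuration carries the fully
#' built zone parameter set (`$params`), overrides applied.
#'
#' @param path YAML file written by [save_config()] or by hand.
#' @return a `cpm_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  x <- yaml::read_yaml(path)
  unknown <- setdiff(names(x), .CONFIG_KEYS)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  run_config(zone = x$zone %||% "SZ",
             total_mcs = x$total_mcs %||% 3120,
             snapshot_every = x$snapshot_every %||% 240,
             seed = x$seed %||% 1,
             n_cells = x$n_cells,
             out_dir = x$out_dir %||% ".",
             overrides = x$overrides %||% list())
}
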