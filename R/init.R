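## Building the 0-MCS state: cylindrical seeding of cells and ECM at the
## zone-specific ratios, plus small deterministic test fixtures.
##
## Seeding places non-overlapping 3x3x3 compartments on a slot grid (slots are
## 3 voxels on a side) inside a cylinder resting on the substrate plane z = 1.
## Under the default unit_mode "cell-slot" the printed cylinder dimensions are
## read in slot units (1 unit = 3 voxels), which is the only reading with the
## capacity to hold 1,000 cells of 27 voxels plus ECM at the stated ratios;
## unit_mode "voxel" takes them literally and errors with a capacity report
## when the compartments do not fit.

# lattice dimensions giving the seeding cylinder lateral margin and the
# spheroid vertical headroom; used when params$domain$dims is NULL
.auto_dims <- function(d_vox, h_vox) {
  nxy <- as.integer(ceiling(1.5 * d_vox))
  nz <- as.integer(h_vox + max(ceiling(d_vox / 2), 16))
  c(nxy, nxy, nz)
}

# origins (1-based, step 3) of 3x3x3 blocks lying entirely inside a circle of
# radius r_vox (voxels) centered at (cx, cy)
.slot_origins_xy <- function(nx, ny, cx, cy, r_vox) {
  x0c <- round(cx) - 1
  y0c <- round(cy) - 1
  xs <- seq(x0c - 3 * ceiling(r_vox / 3), x0c + 3 * ceiling(r_vox / 3), by = 3)
  ys <- seq(y0c - 3 * ceiling(r_vox / 3), y0c + 3 * ceiling(r_vox / 3), by = 3)
  xs <- xs[xs >= 1 & xs + 2 <= nx]
  ys <- ys[ys >= 1 & ys + 2 <= ny]
  g <- expand.grid(x0 = xs, y0 = ys)
  # farthest corner of the block from the axis must be inside the circle
  dx <- pmax(abs(g$x0 - cx), abs(g$x0 + 2 - cx))
  dy <- pmax(abs(g$y0 - cy), abs(g$y0 + 2 - cy))
  g[dx^2 + dy^2 <= r_vox^2, , drop = FALSE]
}

#' Seed the 0-MCS state for one depth zone
#'
#' Distributes `n_cells` cell compartments plus ECMst/ECMv compartments at the
#' zone's cell:ECMst:ECMv ratio over random non-overlapping slots of a
#' cylindrical region resting on the substrate plane. Every compartment is a
#' 3x3x3 voxel block (27 voxel^3); cells get target volume `V_Cell`, ECM
#' compartments `V_ECMInit`. ECM counts are `round(n_cells * r/r_cell)` for
#' the ratio triple `(r_cell, r_st, r_v)`.
#'
#' When `n_cells` differs from the geometry's default (1,000), the cylinder
#' diameter is rescaled by `sqrt(n_cells / 1000)` so the seeding density is
#' preserved (the cylinder height is kept).
#'
#' @param params a [build_parameter_set()] parameter set.
#' @param n_cells number of cells to seed (default: the geometry's n_cells).
#' @param dims lattice dimensions; default: derived from the cylinder size
#'   (or `params$domain$dims` when set).
#' @param seed optional integer passed to `set.seed()` for a reproducible
#'   placement.
#' @return a `cpm_state` at MCS 0.
#' @examples
#' \donttest{
#' st <- seed_zone(build_parameter_set("SZ"), n_cells = 100, seed = 1)
#' table(st$comps$type)
#' }
#' @export
seed_zone <- function(params, n_cells = NULL, dims = NULL, seed = NULL) {
  stopifnot(inherits(params, "cpm_params"))
  if (!is.null(seed)) set.seed(seed)
  p <- unclass(params)
  g <- p$geometry
  n_cells <- as.integer(n_cells %||% g$n_cells)
  if (n_cells < 1) stop("n_cells must be >= 1")
  unit <- if (identical(g$unit_mode, "cell-slot")) 3 else 1

  diameter <- g$cylinder_diameter
  if (n_cells != g$n_cells) {
    diameter <- ceiling(diameter * sqrt(n_cells / g$n_cells))
  }
  d_vox <- diameter * unit
  h_vox <- g$cylinder_height * unit
  n_layers <- if (unit == 3) g$cylinder_height else g$cylinder_height %/% 3L
  r_vox <- d_vox / 2

  ratio <- g$ratio
  n_st <- as.integer(round(n_cells * ratio[2] / ratio[1]))
  n_v <- as.integer(round(n_cells * ratio[3] / ratio[1]))
  n_total <- n_cells + n_st + n_v

  dims <- as.integer(dims %||% p$domain$dims %||% .auto_dims(d_vox, h_vox))
  if (any(dims < c(d_vox, d_vox, h_vox))) {
    stop("lattice dims ", paste(dims, collapse = "x"),
         " cannot contain the seeding cylinder (", d_vox, " voxels across, ",
         h_vox, " high)")
  }
  cx <- (dims[1] + 1) / 2
  cy <- (dims[2] + 1) / 2
  xy <- .slot_origins_xy(dims[1], dims[2], cx, cy, r_vox)
  capacity <- nrow(xy) * n_layers
  if (capacity < n_total) {
    stop("seeding cylinder capacity insufficient: ", n_total,
         " compartments requested (", n_cells, " cells + ", n_st, " ECMst + ",
         n_v, " ECMv) but only ", capacity, " non-overlapping 27-voxel slots",
         " fit a ", diameter, " x ", g$cylinder_height, " cylinder in '",
         g$unit_mode, "' units; use unit_mode = \"cell-slot\" or enlarge the",
         " cylinder")
  }

  slot <- sample.int(capacity, n_total)       # distinct slots, random order
  layer <- (slot - 1L) %/% nrow(xy)           # 0-based layer
  rowi <- (slot - 1L) %% nrow(xy) + 1L
  x0 <- xy$x0[rowi]
  y0 <- xy$y0[rowi]
  z0 <- 1L + 3L * layer
  type <- c(rep("Cell", n_cells), rep("ECMst", n_st), rep("ECMv", n_v))

  labels <- array(0L, dim = dims)
  off <- as.matrix(expand.grid(0:2, 0:2, 0:2))
  for (i in seq_len(n_total)) {
    vox <- cbind(x0[i] + off[, 1], y0[i] + off[, 2], z0[i] + off[, 3])
    labels[vox] <- i
  }
  t <- p$table
  comps <- data.frame(
    id = seq_len(n_total), type = type, zone = p$zone, volume = 27,
    target_volume = ifelse(type == "Cell", t$V_Cell, t$V_ECMInit),
    stringsAsFactors = FALSE)

  p$domain$dims <- dims
  p$geometry$n_cells <- n_cells
  p$geometry$cylinder_diameter <- diameter
  params <- structure(p, class = "cpm_params")
  .new_state(labels, comps, params)
}

#' Deterministic test fixtures with known ground truth
#'
#' Small states whose energies, cluster counts or profile orderings are known
#' in closed form, used throughout the test-suite:
#'
#' * `"isolated-cube"`: one 3x3x3 cell (volume 27, target 30) centered in a
#'   12x12x12 medium lattice, order-1 neighborhood. Under SZ parameters its
#'   energy is `H_contact = 54 * 5 = 270`, `H_volume = 10 * 3^2 = 90`.
#' * `"two-cube-contact"`: two 3x3x3 cells sharing a full 3x3 face; a single
#'   all-matter cluster with 9 cell-cell boundary pairs.
#' * `"cell-shell-around-ecm"`: an ECMv ball (radius 4) wrapped in a
#'   spherical cell shell (radius 4 to 7): the canonical core-shell profile.
#' * `"random-dispersion"`: `n` 3x3x3 compartments of random types placed on
#'   random non-overlapping slots of the whole lattice.
#' * `"mini-seeding"`: [seed_zone()] scaled down to `n_cells`.
#'
#' @param family fixture family name (above).
#' @param zone zone parameters to attach (default SZ).
#' @param n compartments for `"random-dispersion"` / cells for
#'   `"mini-seeding"`.
#' @param types optional compartment types for `"random-dispersion"`
#'   (recycled to length `n`; default: drawn at random).
#' @param dims optional lattice dims override.
#' @param order neighborhood order of the attached parameter set (default 1,
#'   the hand-checkable case).
#' @param seed optional `set.seed()` seed.
#' @return a `cpm_state`.
#' @export
make_fixture <- function(family = c("isolated-cube", "two-cube-contact",
                                    "cell-shell-around-ecm",
                                    "random-dispersion", "mini-seeding"),
                         zone = "SZ", n = 100, types = NULL, dims = NULL,
                         order = 1, seed = NULL) {
  family <- match.arg(family)
  if (!is.null(seed)) set.seed(seed)
  params <- build_parameter_set(zone,
                                overrides = list(neighborhood_order = order))
  block <- function(origin) {
    off <- as.matrix(expand.grid(0:2, 0:2, 0:2))
    cbind(origin[1] + off[, 1], origin[2] + off[, 2], origin[3] + off[, 3])
  }
  if (family == "isolated-cube") {
    st <- create_lattice(dims %||% c(12, 12, 12), params = params)
    return(add_compartment(st, block(c(5, 5, 5)), "Cell"))
  }
  if (family == "two-cube-contact") {
    st <- create_lattice(dims %||% c(14, 12, 12), params = params)
    st <- add_compartment(st, block(c(4, 5, 5)), "Cell")
    return(add_compartment(st, block(c(7, 5, 5)), "Cell"))
  }
  if (family == "cell-shell-around-ecm") {
    d <- dims %||% c(21, 21, 21)
    st <- create_lattice(d, params = params)
    ctr <- (d + 1) / 2
    g <- as.matrix(expand.grid(x = 1:d[1], y = 1:d[2], z = 1:d[3]))
    r <- sqrt((g[, 1] - ctr[1])^2 + (g[, 2] - ctr[2])^2 + (g[, 3] - ctr[3])^2)
    core <- g[r <= 4, , drop = FALSE]
    shell <- g[r > 4 & r <= 7, , drop = FALSE]
    st <- add_compartment(st, core, "ECMv", target_volume = nrow(core))
    return(add_compartment(st, shell, "Cell", target_volume = nrow(shell)))
  }
  if (family == "random-dispersion") {
    d <- dims %||% c(24, 24, 24)
    nslots <- floor(d / 3)
    total <- prod(nslots)
    if (n > total) stop("lattice holds at most ", total, " slots")
    slots <- sample.int(total, n)
    sx <- (slots - 1) %% nslots[1]
    sy <- ((slots - 1) %/% nslots[1]) %% nslots[2]
    sz <- (slots - 1) %/% (nslots[1] * nslots[2])
    if (is.null(types)) types <- sample(c("Cell", "ECMst", "ECMv"), n,
                                        replace = TRUE)
    types <- rep_len(types, n)
    labels <- array(0L, dim = as.integer(d))
    off <- as.matrix(expand.grid(0:2, 0:2, 0:2))
    for (i in seq_len(n)) {
      vox <- cbind(3 * sx[i] + 1 + off[, 1], 3 * sy[i] + 1 + off[, 2],
                   3 * sz[i] + 1 + off[, 3])
      labels[vox] <- i
    }
    t <- unclass(params)$table
    comps <- data.frame(
      id = seq_len(n), type = types, zone = zone, volume = 27,
      target_volume = ifelse(types == "Cell", t$V_Cell, t$V_ECMInit),
      stringsAsFactors = FALSE)
    p <- unclass(params)
    p$domain$dims <- as.integer(d)
    return(.new_state(labels, comps, structure(p, class = "cpm_params")))
  }
  # mini-seeding
  seed_zone(params, n_cells = n, dims = dims)
}
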