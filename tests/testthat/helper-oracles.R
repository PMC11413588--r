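# Independent pure-R oracles the fast engine is checked against, plus
# generators for small randomized states.

# brute-force contact energy: enumerate every neighbor pair once
oracle_contact_energy <- function(state, order = NULL) {
  p <- unclass(state$params)
  order <- if (is.null(order)) p$domain$neighborhood_order else order
  periodic <- identical(p$domain$boundary, "periodic")
  J <- spheroidCPM:::.j_matrix(state$params)
  d <- dim(state$labels)
  type_of <- function(l) {
    if (l == 0) return("Medium")
    state$comps$type[match(l, state$comps$id)]
  }
  off <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  off <- off[rowSums(abs(off)) >= 1 & rowSums(abs(off)) <= order, ]
  H <- 0
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    l <- state$labels[x, y, z]
    for (k in seq_len(nrow(off))) {
      nb <- c(x, y, z) + as.numeric(off[k, ])
      positive_half <- off$dz[k] > 0 ||
        (off$dz[k] == 0 && (off$dy[k] > 0 || (off$dy[k] == 0 && off$dx[k] > 0)))
      if (periodic) {
        nb <- ((nb - 1) %% d) + 1
        if (!positive_half) next
        ln <- state$labels[nb[1], nb[2], nb[3]]
      } else if (any(nb < 1) || any(nb > d)) {
        ln <- 0L                      # virtual medium site: count every bond once
        if (l == 0) next              # same compartment as the medium
        H <- H + J[type_of(l), "Medium"]
        next
      } else {
        if (!positive_half) next
        ln <- state$labels[nb[1], nb[2], nb[3]]
      }
      if (ln == l) next
      H <- H + J[type_of(l), type_of(ln)]
    }
  }
  H
}

oracle_volume_energy <- function(state) {
  p <- unclass(state$params)
  lam <- p$table$lambda_vol
  keep <- state$comps$type == "Cell" |
    (state$comps$type %in% c("ECMst", "ECMv") & isTRUE(p$flags$ecm_constrained))
  sum(lam * (state$comps$volume[keep] - state$comps$target_volume[keep])^2)
}

oracle_total_energy <- function(state, order = NULL) {
  oracle_contact_energy(state, order) + oracle_volume_energy(state)
}

# naive 3D flood fill over a voxel mask (face connectivity)
oracle_flood_fill <- function(mask) {
  d <- dim(mask)
  comp <- array(0L, d)
  k <- 0L
  idx <- which(mask)
  for (s in idx) {
    if (comp[s] != 0L) next
    k <- k + 1L
    queue <- s
    comp[s] <- k
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      x <- ((v - 1) %% d[1]) + 1
      y <- (((v - 1) %/% d[1]) %% d[2]) + 1
      z <- ((v - 1) %/% (d[1] * d[2])) + 1
      for (o in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                     c(0, 0, 1), c(0, 0, -1))) {
        nb <- c(x, y, z) + o
        if (any(nb < 1) || any(nb > d)) next
        w <- nb[1] + d[1] * (nb[2] - 1 + d[2] * (nb[3] - 1))
        if (mask[w] && comp[w] == 0L) {
          comp[w] <- k
          queue <- c(queue, w)
        }
      }
    }
  }
  list(comp = comp, n = k)
}

# voxel type mask for flood-fill oracles
state_mask <- function(state, mode) {
  code <- integer(max(state$comps$id, 1L) + 1L)
  code[state$comps$id + 1L] <- spheroidCPM:::.type_code(state$comps$type)
  m <- array(code[state$labels + 1L], dim(state$labels))
  if (mode == "all-matter") m > 0 else m == 1
}

# irregular random state: every voxel gets a random label; volumes can be
# anything, compartments are typically disconnected
random_messy_state <- function(seed, dims = c(7, 7, 7), n_comp = 5,
                               order = 2, boundary = "fixed-medium",
                               min_volume = 2) {
  set.seed(seed)
  params <- build_parameter_set(sample(c("SZ", "MZ", "DZ"), 1),
                                overrides = list(neighborhood_order = order,
                                                 boundary = boundary))
  repeat {
    labels <- array(sample(0:n_comp, prod(dims), replace = TRUE), dims)
    vols <- tabulate(labels, nbins = n_comp)
    if (all(vols >= min_volume)) break
  }
  comps <- data.frame(
    id = seq_len(n_comp),
    type = sample(c("Cell", "ECMst", "ECMv"), n_comp, replace = TRUE),
    zone = unclass(params)$zone,
    volume = vols,
    target_volume = runif(n_comp, 10, 40),
    stringsAsFactors = FALSE)
  p <- unclass(params)
  p$domain$dims <- as.integer(dims)
  spheroidCPM:::.new_state(labels, comps, structure(p, class = "cpm_params"))
}

# admissible (distinct-label, non-annihilating) random move in a state;
# source coordinates are raw neighbor offsets (possibly outside the lattice:
# virtual medium under the fixed boundary, wrapped under the periodic one)
random_move <- function(state) {
  d <- dim(state$labels)
  p <- unclass(state$params)
  order <- p$domain$neighborhood_order
  periodic <- identical(p$domain$boundary, "periodic")
  off <- spheroidCPM:::.nbr_offsets(order)
  for (i in 1:500) {
    tgt <- c(sample(d[1], 1), sample(d[2], 1), sample(d[3], 1))
    src <- tgt + as.integer(off[sample(nrow(off), 1), ])
    if (all(src >= 1) && all(src <= d)) {
      src_label <- state$labels[src[1], src[2], src[3]]
    } else if (periodic) {
      w <- ((src - 1) %% d) + 1
      src_label <- state$labels[w[1], w[2], w[3]]
    } else {
      src_label <- 0L
    }
    tgt_label <- state$labels[tgt[1], tgt[2], tgt[3]]
    if (src_label == tgt_label) next
    if (tgt_label > 0) {  # skip annihilating moves: the compartment's volume
      v <- state$comps$volume[match(tgt_label, state$comps$id)]
      if (v <= 1) next    # term leaves H when the registry drops it
    }
    return(list(source = as.integer(src), target = tgt,
                source_label = src_label))
  }
  stop("no admissible move found")
}
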