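## Dendrite representations.
##
## linear mode: a 1-D branch of length L (um), optionally with periodic
## boundary conditions (as in the two-synapse and branch-clustering setups).
## tree mode: a rooted acyclic set of ~10-um segments with parent links and
## 3-D endpoint coordinates; synapse positions are (segment, offset) pairs
## and all distances are path distances along the cable.

#' Linear dendritic branch
#'
#' @param length branch length L in um.
#' @param periodic use periodic boundary conditions (distance
#'   `min(|dx|, L - |dx|)`).
#' @return A `dendrite` object (mode `"linear"`).
#' @export
linear_dendrite <- function(length = 150, periodic = TRUE) {
  if (length <= 0) stop("length must be positive")
  structure(list(mode = "linear", L = length, periodic = periodic),
            class = "dendrite")
}

#' @export
print.dendrite <- function(x, ...) {
  if (x$mode == "linear") {
    cat(sprintf("<dendrite> linear, L = %g um%s\n", x$L,
                if (x$periodic) " (periodic)" else ""))
  } else {
    cat(sprintf("<dendrite> tree, %d segments, total cable %.0f um, max path %.0f um\n",
                nrow(x$segments), total_length(x),
                max(x$segments$d1)))
  }
  invisible(x)
}

#' Total cable length of a dendrite (um)
#' @param dendrite a `dendrite` object.
#' @export
total_length <- function(dendrite) {
  if (dendrite$mode == "linear") dendrite$L else sum(dendrite$segments$length)
}

## build a tree dendrite from a segment table: id, parent (0 = soma/root),
## length, and endpoint coords (x0..z1).  d0/d1 = path distance of the
## proximal/distal end to the soma.
.make_tree <- function(segments) {
  n <- nrow(segments)
  segments$id <- seq_len(n)
  d0 <- numeric(n)
  ## parents always precede children (construction guarantees it)
  for (i in seq_len(n)) {
    p <- segments$parent[i]
    d0[i] <- if (p == 0) 0 else d0[p] + segments$length[p]
  }
  segments$d0 <- d0
  segments$d1 <- d0 + segments$length
  structure(list(mode = "tree", segments = segments), class = "dendrite")
}

## ancestor chain (segment ids, self first) for LCA-based path distances
.anc_chain <- function(segments, i) {
  out <- integer(0)
  while (i != 0) { out <- c(out, i); i <- segments$parent[i] }
  out
}

#' Synthetic dendritic tree
#'
#' Generates a random binary-branching tree: a trunk followed by `depth`
#' generations of paired daughter branches whose lengths shrink by
#' `taper` per generation, each resampled into ~`step`-um segments and given
#' random 3-D directions so it can be written as a valid SWC file.  A stand-in
#' for reconstructed morphologies when no download is wanted.
#'
#' @param depth number of branching generations (>= 1).
#' @param trunk trunk length in um.
#' @param taper multiplicative length factor per generation.
#' @param length_sd relative jitter of branch lengths.
#' @param step segment resampling step (um).
#' @param seed integer seed.
#' @return A `dendrite` object (mode `"tree"`).
#' @export
synthetic_tree <- function(depth = 4, trunk = 100, taper = 0.75,
                           length_sd = 0.15, step = 10, seed = 1) {
  if (depth < 1) stop("depth must be >= 1")
  set.seed(seed)
  segs <- list()
  ## queue of open tips: (parent segment id, generation, origin coords, dir)
  add_branch <- function(parent, gen, origin) {
    len <- max(2 * step, trunk * taper^gen * exp(rnorm(1, 0, length_sd)))
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    if (gen == 0) u <- c(0, 1, 0)           # trunk grows along +y
    nseg <- max(1, round(len / step))
    sl <- len / nseg
    last <- parent
    pos <- origin
    for (j in seq_len(nseg)) {
      nxt <- pos + u * sl
      segs[[length(segs) + 1]] <<- data.frame(
        parent = last, length = sl,
        x0 = pos[1], y0 = pos[2], z0 = pos[3],
        x1 = nxt[1], y1 = nxt[2], z1 = nxt[3])
      last <- length(segs)
      pos <- nxt
    }
    list(tip = last, pos = pos)
  }
  tips <- list(add_branch(0L, 0, c(0, 0, 0)))
  for (g in seq_len(depth)) {
    tips <- unlist(lapply(tips, function(t)
      list(add_branch(t$tip, g, t$pos), add_branch(t$tip, g, t$pos))),
      recursive = FALSE)
  }
  .make_tree(do.call(rbind, segs))
}

#' Read an SWC morphology
#'
#' Standard 7-column SWC (`id type x y z radius parent`, `#` comments).  The
#' soma is the root node; each child-parent link becomes a cable segment.
#' Multi-root or cyclic files are rejected.
#'
#' @param path SWC file path.
#' @return A `dendrite` object (mode `"tree"`).
#' @export
load_swc <- function(path) {
  tab <- utils::read.table(path, comment.char = "#",
                           col.names = c("id", "type", "x", "y", "z",
                                         "radius", "parent"))
  if (sum(tab$parent == -1) != 1) stop("SWC must have exactly one root")
  idx <- match(tab$parent, tab$id)
  if (any(is.na(idx) & tab$parent != -1)) stop("SWC has dangling parents")
  ord <- order(tab$id)          # ids may be arbitrary; remap to 1..n
  tab <- tab[ord, ]
  remap <- match(tab$parent, tab$id)
  remap[is.na(remap)] <- 0L
  ## detect cycles / ensure parents precede children by topological pass
  n <- nrow(tab)
  depth <- rep(NA_integer_, n)
  depth[remap == 0L] <- 0L
  for (pass in seq_len(n)) {
    pd <- rep(NA_integer_, n)
    pd[remap > 0L] <- depth[remap[remap > 0L]]
    todo <- which(is.na(depth) & !is.na(pd))
    if (!length(todo)) break
    depth[todo] <- pd[todo] + 1L
  }
  if (any(is.na(depth))) stop("SWC is cyclic or disconnected")
  ord2 <- order(depth)
  tab <- tab[ord2, ]
  remap <- match(tab$parent, tab$id); remap[is.na(remap)] <- 0L
  segs <- data.frame(
    parent = 0L, length = 0,
    x0 = 0, y0 = 0, z0 = 0, x1 = 0, y1 = 0, z1 = 0)[0, ]
  node2seg <- integer(nrow(tab))   # segment ending at node i
  for (i in seq_len(nrow(tab))) {
    p <- remap[i]
    if (p == 0L) { node2seg[i] <- 0L; next }
    len <- sqrt(sum((unlist(tab[i, c("x", "y", "z")]) -
                     unlist(tab[p, c("x", "y", "z")]))^2))
    segs[nrow(segs) + 1L, ] <- c(node2seg[p], len,
                                 tab$x[p], tab$y[p], tab$z[p],
                                 tab$x[i], tab$y[i], tab$z[i])
    node2seg[i] <- nrow(segs)
  }
  segs$parent <- as.integer(segs$parent)
  .make_tree(segs)
}

#' Write a dendrite tree as SWC
#'
#' Canonical 7-column format (dendrite type code 3, soma node type 1, radius
#' 0.5); write -> read -> write is byte-stable.
#'
#' @param dendrite a tree `dendrite`.
#' @param path output file.
#' @export
write_swc <- function(dendrite, path) {
  if (dendrite$mode != "tree") stop("write_swc needs a tree dendrite")
  s <- dendrite$segments
  lines <- c("# generated by dendroclust",
             sprintf("%d 1 %.4f %.4f %.4f 0.5 -1", 1L, s$x0[1], s$y0[1], s$z0[1]))
  ## node i+1 is the distal end of segment i; parent node = parent segment + 1
  for (i in seq_len(nrow(s))) {
    lines <- c(lines, sprintf("%d 3 %.4f %.4f %.4f 0.5 %d",
                              i + 1L, s$x1[i], s$y1[i], s$z1[i],
                              s$parent[i] + 1L))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Resample a tree into equal segments
#'
#' Splits each unbranched cable section into equal pieces of approximately
#' `step` um (n = max(1, round(len/step))), preserving topology and cumulative
#' path length.  Idempotent on segment count.
#'
#' @param dendrite tree `dendrite`.
#' @param step target segment length (um), default 10.
#' @export
resample_dendrite <- function(dendrite, step = 10) {
  if (dendrite$mode != "tree") return(dendrite)
  s <- dendrite$segments
  nchild <- tabulate(s$parent[s$parent > 0], nbins = nrow(s))
  ## walk sections: a section runs from a segment whose parent is root or a
  ## branch point (or the root itself) down to the next branch point/tip
  starts <- which(s$parent == 0 | nchild[pmax(s$parent, 1)] > 1 & s$parent > 0)
  out <- list(); secmap <- integer(nrow(s))  # new tip-seg id per old segment
  for (st in starts) {
    chain <- st
    while (nchild[chain[length(chain)]] == 1) {
      chain <- c(chain, which(s$parent == chain[length(chain)]))
    }
    len <- sum(s$length[chain])
    nseg <- max(1L, round(len / step))
    sl <- len / nseg
    ## linear interpolation of coordinates along the chain
    pts <- rbind(unlist(s[chain[1], c("x0", "y0", "z0")]),
                 as.matrix(s[chain, c("x1", "y1", "z1")]))
    cum <- c(0, cumsum(s$length[chain]))
    at <- seq(0, len, length.out = nseg + 1)
    co <- apply(pts, 2, function(v) approx(cum, v, xout = at)$y)
    parent0 <- if (s$parent[st] == 0) 0L else secmap[s$parent[st]]
    last <- parent0
    for (j in seq_len(nseg)) {
      out[[length(out) + 1]] <- data.frame(
        parent = last, length = sl,
        x0 = co[j, 1], y0 = co[j, 2], z0 = co[j, 3],
        x1 = co[j + 1, 1], y1 = co[j + 1, 2], z1 = co[j + 1, 3])
      last <- length(out)
    }
    secmap[chain[length(chain)]] <- last
  }
  .make_tree(do.call(rbind, out))
}

#' Place synapses on a dendrite
#'
#' Distributes `N = floor(total_length * nu)` synapses uniformly over the
#' dendrite with initial efficacy 0.5.
#'
#' @param dendrite a `dendrite`.
#' @param nu synaptic density per um (> 0).
#' @param seed integer seed.
#' @param type synapse type label.
#' @return Data frame (`synapse_set`): id, position (linear coordinate or
#'   segment/offset), efficacy, type, birth time.
#' @export
place_synapses <- function(dendrite, nu = 0.2, seed = 1, type = "excitatory") {
  if (nu <= 0) stop("nu must be positive")
  N <- floor(total_length(dendrite) * nu)
  if (N < 1) stop("density too low: no synapses to place")
  set.seed(seed)
  if (dendrite$mode == "linear") {
    syn <- data.frame(id = seq_len(N), pos = runif(N, 0, dendrite$L),
                      segment = NA_integer_, offset = NA_real_)
  } else {
    s <- dendrite$segments
    seg <- sample.int(nrow(s), N, replace = TRUE, prob = s$length)
    syn <- data.frame(id = seq_len(N), pos = NA_real_, segment = seg,
                      offset = runif(N) * s$length[seg])
  }
  syn$efficacy <- 0.5
  syn$type <- type
  syn$birth_ms <- 0
  class(syn) <- c("synapse_set", "data.frame")
  syn
}

#' Pairwise path distances between synapse positions
#'
#' Linear periodic branches use `min(|dx|, L - |dx|)`; non-periodic use
#' `|dx|`; trees use the shortest path through the segment graph (offsets
#' interpolate within segments).
#'
#' @param dendrite a `dendrite`.
#' @param synapses a synapse set from [place_synapses()] (or a numeric vector
#'   of linear positions).
#' @return Symmetric distance matrix in um.
#' @export
pairwise_distance <- function(dendrite, synapses) {
  if (dendrite$mode == "linear") {
    pos <- if (is.numeric(synapses)) synapses else synapses$pos
    if (any(pos < 0 | pos > dendrite$L)) stop("position off the dendrite")
    dx <- abs(outer(pos, pos, "-"))
    if (dendrite$periodic) dx <- pmin(dx, dendrite$L - dx)
    return(dx)
  }
  s <- dendrite$segments
  seg <- synapses$segment; off <- synapses$offset
  if (any(seg < 1 | seg > nrow(s)) || any(off < 0 | off > s$length[seg] + 1e-9))
    stop("position off the dendrite")
  n <- length(seg)
  chains <- lapply(seq_len(nrow(s)), function(i) .anc_chain(s, i))
  dsoma <- s$d0[seg] + off
  D <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(max(i - 1, 0))) {
    if (seg[i] == seg[j]) {
      D[i, j] <- abs(off[i] - off[j])
    } else {
      common <- intersect(chains[[seg[i]]], chains[[seg[j]]])
      if (!length(common)) {
        D[i, j] <- dsoma[i] + dsoma[j]          # meet only at the soma
      } else if (common[1] == seg[i]) {         # chains are self-first
        D[i, j] <- dsoma[j] - dsoma[i]          # j lies below i's segment
      } else if (common[1] == seg[j]) {
        D[i, j] <- dsoma[i] - dsoma[j]
      } else {
        D[i, j] <- dsoma[i] + dsoma[j] - 2 * s$d1[common[1]]
      }
    }
    D[j, i] <- D[i, j]
  }
  D
}

#' Path distance of each synapse to the soma (um)
#' @inheritParams pairwise_distance
#' @export
soma_distance <- function(dendrite, synapses) {
  if (dendrite$mode == "linear") {
    ## linear branches have no soma; measure from coordinate origin
    return(if (is.numeric(synapses)) synapses else synapses$pos)
  }
  s <- dendrite$segments
  s$d0[synapses$segment] + synapses$offset
}

#' Gaussian proximity matrix
#'
#' `s_kl = exp(-d_kl^2 / (2*sigma^2))`, zeroed beyond `cutoff*sigma` to keep
#' updates sparse (error < 4e-6 per pair at the default 5-sigma cutoff).
#'
#' @param distances distance matrix (um).
#' @param sigma calcium spread (um, > 0).
#' @param cutoff cutoff in multiples of sigma.
#' @export
proximity_matrix <- function(distances, sigma = 6, cutoff = 5) {
  if (sigma <= 0) stop("sigma must be positive")
  S <- exp(-distances^2 / (2 * sigma^2))
  S[distances > cutoff * sigma] <- 0
  S
}

#' Structural plasticity: synapse turnover
#'
#' Replaces every synapse whose efficacy is below `W_thr` by a new synapse at
#' a random position with a fresh receptive field (uniform orientation,
#' Gaussian-spread center) and efficacy 0.5; the total count is preserved and
#' each replacement is logged.
#'
#' @param synapses synapse set (must carry `theta`, `cx`, `cy` columns if RFs
#'   are attached).
#' @param dendrite the dendrite they live on.
#' @param W_thr turnover threshold.
#' @param rf_sampler function(n) returning a data frame with columns
#'   `x`, `y`, `theta` (e.g. a closure over [sample_receptive_fields()]);
#'   may be NULL when synapses carry no receptive fields.
#' @param time_ms simulation time stamp for the log.
#' @return List with updated `synapses` and a `log` data frame
#'   (time_ms, old_id, new_position_um, new_theta_deg).
#' @export
apply_turnover <- function(synapses, dendrite, W_thr = 0.02,
                           rf_sampler = NULL, time_ms = 0) {
  dead <- which(synapses$efficacy < W_thr & synapses$type == "excitatory")
  log <- data.frame(time_ms = numeric(0), old_id = integer(0),
                    new_position_um = numeric(0), new_theta_deg = numeric(0))
  if (!length(dead)) return(list(synapses = synapses, log = log))
  n <- length(dead)
  if (dendrite$mode == "linear") {
    newpos <- runif(n, 0, dendrite$L)
    synapses$pos[dead] <- newpos
  } else {
    s <- dendrite$segments
    seg <- sample.int(nrow(s), n, replace = TRUE, prob = s$length)
    synapses$segment[dead] <- seg
    synapses$offset[dead] <- runif(n) * s$length[seg]
    newpos <- s$d0[seg] + synapses$offset[dead]
  }
  th <- rep(NA_real_, n)
  if (!is.null(rf_sampler)) {
    rf <- rf_sampler(n)
    synapses$theta[dead] <- rf$theta
    synapses$cx[dead] <- rf$x
    synapses$cy[dead] <- rf$y
    th <- rf$theta
  }
  synapses$efficacy[dead] <- 0.5
  synapses$birth_ms[dead] <- time_ms
  list(synapses = synapses,
       log = data.frame(time_ms = time_ms, old_id = synapses$id[dead],
                        new_position_um = newpos, new_theta_deg = th))
}

#' Density-ramp schedule
#'
#' Schedule for raising synaptic density from `nu_start` to `nu_end` over
#' `duration_days` by inserting one synapse every `add_interval_min` minutes,
#' while scaling the calcium spread and the per-event calcium increment so
#' that the total neighborhood calcium (proportional to
#' `sigma_c * increment * nu`) is conserved.
#'
#' @param L branch length (um).
#' @param nu_start,nu_end densities (per um), `nu_end > nu_start`.
#' @param duration_days ramp duration.
#' @param add_interval_min insertion interval (minutes).
#' @param sigma_c0 initial calcium spread (um).
#' @return Data frame of insertion events: time_ms, nu (density after the
#'   insertion), sigma_c and drive_scale to apply from that time on.
#' @export
density_ramp <- function(L = 150, nu_start = 0.2, nu_end = 0.8,
                         duration_days = 4, add_interval_min = 64,
                         sigma_c0 = 6) {
  if (nu_end <= nu_start) stop("nu_end must exceed nu_start")
  n_add <- round((nu_end - nu_start) * L)
  times <- seq_len(n_add) * add_interval_min * 60000
  nu <- nu_start + seq_len(n_add) / L
  frac <- (nu - nu_start) / (nu_end - nu_start)
  ## split the conservation between spread and increment: both shrink as
  ## sqrt(nu0/nu) so sigma_c * increment * nu stays constant
  shrink <- sqrt(nu_start / nu)
  data.frame(time_ms = times, nu = nu,
             sigma_c = sigma_c0 * shrink,
             drive_scale = shrink)
}
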