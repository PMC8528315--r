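#' Specification of a synthetic vascular phantom
#'
#' Parameters of the seeded ground-truth network generator used to exercise
#' and evaluate the pipeline: branching, tortuous vessel trees with tapering
#' radii and optional capillary-style anastomoses, confined to a rectangular
#' tissue domain.
#'
#' @param domain_um length-3 physical domain size (um), `(z, y, x)`.
#' @param n_trees number of independent vessel trees.
#' @param n_branches exact number of bifurcation events across the phantom;
#'   each event splits a growing tip in two, so the phantom has
#'   `n_trees + 2 * n_branches` tree strands and, absent loops, exactly
#'   `n_branches` bifurcations.
#' @param radius_range root vessel radius range (um); radii taper toward
#'   the leaves.
#' @param taper multiplicative radius factor applied at each branching
#'   generation (in (0, 1]).
#' @param loop_prob probability that a terminal tip is joined to a nearby
#'   terminal of another strand, forming an anastomotic loop.
#' @param tortuosity amplitude of the random direction perturbation per
#'   growth step (0 = straight vessels).
#' @param step_um centerline sampling step (um).
#' @param strand_length_range length range (um) of an unbranched strand.
#' @param min_radius_um smallest radius a taper may reach (um).
#' @param seed integer seed making the phantom reproducible.
#' @return List of class `phantom_spec`.
#' @export
phantom_spec <- function(domain_um = c(128, 128, 128), n_trees = 4L,
                         n_branches = 6L, radius_range = c(3, 8),
                         taper = 0.8, loop_prob = 0.2, tortuosity = 0.25,
                         step_um = 2, strand_length_range = c(30, 80),
                         min_radius_um = 2, seed = 1L) {
  if (any(domain_um <= 0) || length(domain_um) != 3L)
    stop("`domain_um` must be 3 positive extents", call. = FALSE)
  if (n_trees < 1L) stop("need at least one tree", call. = FALSE)
  structure(list(domain_um = as.numeric(domain_um),
                 n_trees = as.integer(n_trees),
                 n_branches = as.integer(n_branches),
                 radius_range = radius_range, taper = taper,
                 loop_prob = loop_prob, tortuosity = tortuosity,
                 step_um = step_um,
                 strand_length_range = strand_length_range,
                 min_radius_um = min_radius_um, seed = as.integer(seed)),
            class = "phantom_spec")
}

unit3 <- function(v) v / sqrt(sum(v^2))

#' Generate a seeded ground-truth phantom network
#'
#' Grows tortuous vessel trees by a random walk with momentum: tips advance
#' in steps, directions perturbed by the tortuosity amplitude and steered
#' away from the domain boundary; each strand ends either in a bifurcation
#' (two child tips at a tapered radius) until the branch budget is spent, or
#' in a terminal tip, which may be joined to a nearby terminal to form a
#' loop. Radii taper linearly along each strand toward the child radius.
#' The result is a `vessel_network` whose bulk statistics are computable
#' with [to_cylinders()] and [bulk_stats()] and which can be rendered and
#' imaged with [render_binary()] and [simulate_image()].
#'
#' @param spec a [phantom_spec()].
#' @return A `vessel_network` with attribute `domain_um`; strand energies
#'   are set to -1 (synthetic ground truth carries no filter response).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  seed_keep <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(seed_keep))
    assign(".Random.seed", seed_keep, .GlobalEnv), add = TRUE)
  set.seed(spec$seed)
  dom <- spec$domain_um
  margin <- max(spec$radius_range) + 2
  rand_pos <- function() margin + stats::runif(3) * (dom - 2 * margin)
  node_pos <- NULL # special vertex positions, one row per node id
  new_node <- function(p) {
    node_pos <<- rbind(node_pos, matrix(p, 1))
    nrow(node_pos)
  }
  strands <- list()
  add_strand <- function(pts, radii, from, to) {
    strands[[length(strands) + 1L]] <<-
      list(points = pts, radii_um = radii,
           energies = rep(-1, nrow(pts)), end_vertices = c(from, to))
  }
  grow <- function(pos, dir, r0, r1) {
    len <- stats::runif(1, spec$strand_length_range[1],
                        spec$strand_length_range[2])
    n_step <- max(2L, ceiling(len / spec$step_um))
    pts <- matrix(0, n_step + 1L, 3L)
    pts[1, ] <- pos
    for (i in seq_len(n_step)) {
      dir <- unit3(dir + spec$tortuosity * stats::rnorm(3))
      ## steer away from the walls
      nxt <- pts[i, ] + spec$step_um * dir
      low <- nxt < margin; high <- nxt > dom - margin
      if (any(low | high)) {
        dir[low] <- abs(dir[low]); dir[high] <- -abs(dir[high])
        dir <- unit3(dir)
        nxt <- pts[i, ] + spec$step_um * dir
      }
      pts[i + 1L, ] <- nxt
    }
    list(points = pts, radii = seq(r0, r1, length.out = n_step + 1L),
         dir = dir)
  }
  tips <- lapply(seq_len(spec$n_trees), function(i) {
    p <- rand_pos()
    list(pos = p, dir = unit3(stats::rnorm(3)),
         radius = stats::runif(1, spec$radius_range[1],
                               spec$radius_range[2]),
         node = new_node(p))
  })
  branches_left <- spec$n_branches
  open_ends <- list() # terminal tips eligible for loop closure
  while (length(tips)) {
    tip <- tips[[1]]; tips <- tips[-1]
    r_next <- max(spec$min_radius_um, tip$radius * spec$taper)
    g <- grow(tip$pos, tip$dir, tip$radius, r_next)
    end <- g$points[nrow(g$points), ]
    if (branches_left > 0L) {
      branches_left <- branches_left - 1L
      node <- new_node(end)
      add_strand(g$points, g$radii, tip$node, node)
      for (k in 1:2) {
        perp <- unit3(stats::rnorm(3))
        child_dir <- unit3(g$dir + 0.8 * (perp - sum(perp * g$dir) * g$dir) *
                             (if (k == 1) 1 else -1))
        tips[[length(tips) + 1L]] <-
          list(pos = end, dir = child_dir, radius = r_next, node = node)
      }
    } else {
      node <- new_node(end)
      add_strand(g$points, g$radii, tip$node, node)
      open_ends[[length(open_ends) + 1L]] <-
        list(node = node, pos = end, radius = r_next)
    }
  }
  ## anastomotic loops between nearby open terminals
  if (length(open_ends) >= 2L && spec$loop_prob > 0) {
    used <- rep(FALSE, length(open_ends))
    for (i in seq_along(open_ends)) {
      if (used[i] || stats::runif(1) > spec$loop_prob) next
      pi_ <- open_ends[[i]]$pos
      d <- vapply(open_ends, function(o) sqrt(sum((o$pos - pi_)^2)),
                  numeric(1))
      d[used] <- Inf; d[i] <- Inf
      d[d > max(spec$strand_length_range)] <- Inf
      if (all(is.infinite(d))) next
      j <- which.min(d)
      n_step <- max(2L, ceiling(d[j] / spec$step_um))
      tt <- seq(0, 1, length.out = n_step + 1L)
      pts <- outer(1 - tt, pi_) + outer(tt, open_ends[[j]]$pos)
      add_strand(pts, seq(open_ends[[i]]$radius, open_ends[[j]]$radius,
                          length.out = n_step + 1L),
                 open_ends[[i]]$node, open_ends[[j]]$node)
      used[i] <- used[j] <- TRUE
    }
  }
  ends <- do.call(rbind, lapply(strands, function(s) s$end_vertices))
  deg <- tabulate(ends, nbins = nrow(node_pos))
  vertices <- data.frame(id = seq_len(nrow(node_pos)),
                         z_um = node_pos[, 1], y_um = node_pos[, 2],
                         x_um = node_pos[, 3])
  structure(list(strands = strands,
                 bifurcations = which(deg >= 3L),
                 endpoints = which(deg == 1L),
                 vertices = vertices,
                 n_edges = length(strands)),
            class = "vessel_network", domain_um = dom)
}
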