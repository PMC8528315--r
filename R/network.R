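#' Organize vertices and edges into strands, bifurcations and endpoints
#'
#' Bifurcations are vertices of degree 3 or more; endpoints have degree 1.
#' A strand is a maximal chain of consecutive edges connecting exactly two
#' such special vertices, passing only through degree-2 interior vertices.
#' Pure cycles of degree-2 vertices become loop strands whose two end
#' vertices coincide. Isolated vertices are dropped.
#'
#' @param vertices vertex data frame from [extract_vertices()].
#' @param edges cleaned edge list (after [deduplicate_mutual()] and
#'   [remove_small_cycles()]).
#' @param spacing,origin physical geometry of the source grid, used to
#'   convert trace voxels to um positions. Default unit spacing.
#' @return Object of class `vessel_network`: list with `strands` (each a
#'   list of `points` (n x 3 um), `radii_um`, `energies`, `end_vertices`),
#'   `bifurcations` and `endpoints` (vertex ids), `vertices` (the input
#'   rows in use), `n_edges`.
#' @export
identify_network <- function(vertices, edges, spacing = c(1, 1, 1),
                             origin = c(0, 0, 0)) {
  if (length(edges) == 0L)
    return(structure(list(strands = list(), bifurcations = integer(),
                          endpoints = integer(), vertices = vertices[0, ],
                          n_edges = 0L), class = "vessel_network"))
  a <- vapply(edges, `[[`, numeric(1), "vertex_a")
  b <- vapply(edges, `[[`, numeric(1), "vertex_b")
  ids <- sort(unique(c(a, b)))
  deg <- table(factor(c(a, b), levels = ids))
  deg <- stats::setNames(as.integer(deg), ids)
  special <- ids[deg[as.character(ids)] != 2L]
  used <- rep(FALSE, length(edges))
  incident <- lapply(ids, function(v) which(a == v | b == v))
  names(incident) <- as.character(ids)
  strands <- list()

  ## oriented per-point quantities for an edge walked starting at vertex v
  orient_edge <- function(e, from) {
    tr <- e$trace; r <- e$radii_um; en <- e$energies
    if (from == e$vertex_b) list(trace = tr, radii = r, energies = en,
                                 to = e$vertex_a)
    else list(trace = tr[rev(seq_len(nrow(tr))), , drop = FALSE],
              radii = rev(r), energies = rev(en), to = e$vertex_b)
  }

  walk_strand <- function(start, first_edge) {
    chain <- list(); cur <- start; eidx <- first_edge
    repeat {
      used[eidx] <<- TRUE
      oe <- orient_edge(edges[[eidx]], cur)
      chain[[length(chain) + 1L]] <- oe
      cur <- oe$to
      if (cur %in% special || cur == start) break
      nxt <- incident[[as.character(cur)]]
      nxt <- nxt[!used[nxt]]
      if (!length(nxt)) break # open chain ending at an exhausted vertex
      eidx <- nxt[1]
    }
    tr <- chain[[1]]$trace; r <- chain[[1]]$radii; en <- chain[[1]]$energies
    if (length(chain) > 1) for (k in 2:length(chain)) {
      tr <- rbind(tr, chain[[k]]$trace[-1, , drop = FALSE])
      r <- c(r, chain[[k]]$radii[-1]); en <- c(en, chain[[k]]$energies[-1])
    }
    pts <- sweep(sweep(tr - 1, 2L, spacing, "*"), 2L, origin, "+")
    list(points = pts, radii_um = r, energies = en,
         end_vertices = c(start, cur), n_edges = length(chain))
  }

  for (s in special) for (eidx in incident[[as.character(s)]]) {
    if (used[eidx]) next
    strands[[length(strands) + 1L]] <- walk_strand(s, eidx)
  }
  ## remaining edges form pure degree-2 cycles
  while (any(!used)) {
    eidx <- which(!used)[1]
    start <- min(edges[[eidx]]$vertex_a, edges[[eidx]]$vertex_b)
    strands[[length(strands) + 1L]] <- walk_strand(start, eidx)
  }
  structure(list(
    strands = strands,
    bifurcations = as.integer(ids[deg[as.character(ids)] >= 3L]),
    endpoints = as.integer(ids[deg[as.character(ids)] == 1L]),
    vertices = vertices[vertices$id %in% ids, , drop = FALSE],
    n_edges = length(edges)), class = "vessel_network")
}

#' @export
print.vessel_network <- function(x, ...) {
  cat(sprintf(
    "<vessel_network> %d strands, %d bifurcations, %d endpoints, %d edges\n",
    length(x$strands), length(x$bifurcations), length(x$endpoints),
    x$n_edges))
  invisible(x)
}

#' Smooth strand geometry with radius-adaptive, energy-weighted kernels
#'
#' Interior strand points are replaced by Gaussian kernel averages along the
#' unsmoothed arc length: at point `i` the kernel standard deviation equals
#' the local (unsmoothed) radius, truncated at three standard deviations,
#' and each contributing point is additionally weighted by its energy
#' magnitude, favouring the more probable, lower-energy locations. All five
#' local quantities (three position components, radius, energy) are
#' averaged in a single pass; the two strand end points are returned
#' untouched.
#'
#' @param network a `vessel_network`.
#' @param energy_aware multiply kernel weights by `|energy|` (default TRUE;
#'   requires negative energies along strands).
#' @return The network with smoothed strand geometry.
#' @export
smooth_strands <- function(network, energy_aware = TRUE) {
  network$strands <- lapply(network$strands, function(st) {
    n <- nrow(st$points)
    if (n <= 2L) return(st)
    seg <- sqrt(rowSums((st$points[-1, , drop = FALSE] -
                         st$points[-n, , drop = FALSE])^2))
    s <- c(0, cumsum(seg))
    w_e <- if (energy_aware) abs(st$energies) else rep(1, n)
    pts <- st$points; rad <- st$radii_um; en <- st$energies
    for (i in 2:(n - 1L)) {
      sd_i <- st$radii_um[i]
      if (!is.finite(sd_i) || sd_i <= 0) next
      sel <- which(abs(s - s[i]) <= 3 * sd_i)
      w <- w_e[sel] * exp(-(s[sel] - s[i])^2 / (2 * sd_i^2))
      W <- sum(w)
      if (W <= 0) next
      pts[i, ] <- colSums(st$points[sel, , drop = FALSE] * w) / W
      rad[i] <- sum(st$radii_um[sel] * w) / W
      en[i] <- sum(st$energies[sel] * w) / W
    }
    st$points <- pts; st$radii_um <- rad; st$energies <- en
    st
  })
  network
}
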