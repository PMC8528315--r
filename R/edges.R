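#' Limits on the edge exploration
#'
#' Caps that keep the per-vertex exploration finite: the number of edges a
#' seed vertex may find, and the trace length as a multiple of the seed
#' radius.
#'
#' @param max_edges_per_vertex maximum edges found per origin vertex
#'   (default 4).
#' @param max_trace_factor trace-length cap as a multiple of the seed vertex
#'   radius (default 30; sensible values lie roughly in 20-100).
#' @param max_explored hard cap on explored voxels per origin (memory guard).
#' @return List of class `extraction_limits`.
#' @export
extraction_limits <- function(max_edges_per_vertex = 4L,
                              max_trace_factor = 30,
                              max_explored = 200000L) {
  if (max_edges_per_vertex < 1 || max_trace_factor <= 0)
    stop("limits must be positive", call. = FALSE)
  structure(list(max_edges_per_vertex = as.integer(max_edges_per_vertex),
                 max_trace_factor = max_trace_factor,
                 max_explored = as.integer(max_explored)),
            class = "extraction_limits")
}

#' Trace edges between vertices through the energy field
#'
#' For each origin vertex an independent best-first ("watershed")
#' exploration expands the lowest-energy frontier voxel of its
#' 26-neighbourhood, with write-once back-pointers, until it reaches another
#' vertex; the connecting centerline is then back-traced through the pointer
#' map. Exploration never crosses the facing plane of an already-found
#' terminal (the half-space through that terminal with outward normal away
#' from the origin), never revisits a pointered voxel, stops at non-negative
#' energy, and respects the edge-count and trace-length limits. Centerline
#' stretches shared between two traces from one origin are retained only in
#' the first-extracted (lower-energy) edge.
#'
#' @param vertices vertex data frame from [extract_vertices()].
#' @param fields an `energy_fields` object.
#' @param limits an [extraction_limits()] object.
#' @return List of edges, each a list with `vertex_a` (origin id),
#'   `vertex_b` (terminal id), `trace` (n x 3 voxel indices, terminal to
#'   origin order), `radii_um`, `energies`, `max_energy`. Per origin, edges
#'   appear in extraction order.
#' @export
extract_edges <- function(vertices, fields, limits = extraction_limits()) {
  if (nrow(vertices) < 2L) return(list())
  d <- dim(fields$energy$values)
  lin <- vertices$z + (vertices$y - 1L) * d[1] +
    (vertices$x - 1L) * d[1] * d[2]
  cap <- limits$max_trace_factor * vertices$radius_um
  raw <- cpp_trace_edges(as.numeric(fields$energy$values), as.integer(d),
                         fields$energy$spacing, as.integer(lin),
                         limits$max_edges_per_vertex, as.numeric(cap),
                         limits$max_explored)
  lapply(raw, function(ed) {
    tr <- arrayInd(ed$trace, d)
    en <- fields$energy$values[ed$trace]
    list(vertex_a = vertices$id[ed$origin],
         vertex_b = vertices$id[ed$terminal], trace = tr,
         radii_um = fields$size$values[ed$trace], energies = en,
         max_energy = max(en))
  })
}

edge_pair_key <- function(edges) {
  vapply(edges, function(e)
    paste(min(e$vertex_a, e$vertex_b), max(e$vertex_a, e$vertex_b)),
    character(1))
}

#' Drop the weaker trace of mutually-discovered vertex pairs
#'
#' When two vertices discover each other (reciprocal traces over the same
#' unordered pair), only the more probable trace - the one with the lower
#' maximum energy - is kept.
#'
#' @param edges edge list from [extract_edges()].
#' @return Filtered edge list.
#' @export
deduplicate_mutual <- function(edges) {
  if (length(edges) < 2L) return(edges)
  key <- edge_pair_key(edges)
  maxe <- vapply(edges, `[[`, numeric(1), "max_energy")
  keep <- rep(TRUE, length(edges))
  for (k in unique(key[duplicated(key)])) {
    idx <- which(key == k)
    best <- idx[which.min(maxe[idx])]
    keep[setdiff(idx, best)] <- FALSE
  }
  edges[keep]
}

#' Eliminate small cycles of three fully-connected vertices
#'
#' Two vertices are adjacent by a small cycle if they can reach each other
#' both in one edge and in two edges (i.e. they share a triangle). The
#' connected components of that adjacency are computed and the least
#' probable (highest maximum energy) triangle edge is removed from each
#' component; adjacency is recomputed and the removal repeated until no
#' small-cycle adjacency remains.
#'
#' @param vertices vertex data frame (ids referenced by the edges).
#' @param edges edge list (after [deduplicate_mutual()]).
#' @return Edge list with no remaining triangle.
#' @export
remove_small_cycles <- function(vertices, edges) {
  repeat {
    if (length(edges) < 3L) return(edges)
    a <- vapply(edges, `[[`, numeric(1), "vertex_a")
    b <- vapply(edges, `[[`, numeric(1), "vertex_b")
    ids <- sort(unique(c(a, b)))
    n <- length(ids)
    ai <- match(a, ids); bi <- match(b, ids)
    A <- matrix(0L, n, n)
    A[cbind(ai, bi)] <- 1L
    A[cbind(bi, ai)] <- 1L
    two <- (A %*% A) > 0
    S <- (A == 1L) & two
    if (!any(S)) return(edges)
    g <- igraph::graph_from_adjacency_matrix(S, mode = "undirected")
    comp <- igraph::components(g)$membership
    maxe <- vapply(edges, `[[`, numeric(1), "max_energy")
    drop <- integer(0)
    for (cc in unique(comp[rowSums(S) > 0])) {
      in_comp <- comp[ai] == cc & comp[bi] == cc & S[cbind(ai, bi)]
      cand <- which(in_comp)
      if (length(cand))
        drop <- c(drop, cand[which.max(maxe[cand])])
    }
    if (!length(drop)) return(edges) # defensive; should not happen
    edges <- edges[-drop]
  }
}
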