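#' Extract seed vertices from energy and size fields
#'
#' Vertex centres are strict local minima of the energy field over the
#' 26-neighbourhood (exact ties broken toward the lexicographically earlier
#' voxel, so the output is deterministic). Candidates are processed from
#' lowest to highest energy and greedily painted onto a blank canvas: a
#' candidate is accepted only if its centre voxel is not inside the masked
#' ball (physical radius, anisotropy-aware) of a previously accepted vertex.
#' Radii are read from the size field at the centre voxel.
#'
#' @param fields an `energy_fields` object (see [energy_fields()]).
#' @return Data frame with one row per accepted vertex, in acceptance
#'   (ascending energy) order: `id`, voxel indices `z`, `y`, `x` (1-based),
#'   physical `z_um`, `y_um`, `x_um`, `radius_um`, `energy`. Empty if the
#'   energy field is non-negative everywhere.
#' @export
extract_vertices <- function(fields) {
  e <- fields$energy$values
  d <- dim(e)
  cand <- cpp_local_minima(as.numeric(e), as.integer(d))
  if (length(cand) == 0L) return(empty_vertex_df())
  en <- e[cand]
  ord <- order(en, cand)
  cand <- cand[ord]
  en <- en[ord]
  rad <- fields$size$values[cand]
  keep <- cpp_paint_vertices(as.integer(cand), as.numeric(rad),
                             as.integer(d), fields$energy$spacing)
  cand <- cand[keep]; en <- en[keep]; rad <- rad[keep]
  sub <- arrayInd(cand, d)
  pos <- voxel_to_um(fields$energy, sub)
  data.frame(id = seq_along(cand),
             z = sub[, 1], y = sub[, 2], x = sub[, 3],
             z_um = pos[, 1], y_um = pos[, 2], x_um = pos[, 3],
             radius_um = rad, energy = en)
}

empty_vertex_df <- function() {
  data.frame(id = integer(), z = integer(), y = integer(), x = integer(),
             z_um = numeric(), y_um = numeric(), x_um = numeric(),
             radius_um = numeric(), energy = numeric())
}
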