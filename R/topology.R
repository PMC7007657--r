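#' Topology report for a structure mask
#'
#' Counts 6-connected components and computes the Euler characteristic of
#' the cubical complex spanned by the occupied voxels (vertices - edges +
#' faces - cubes). For a solid, cavity-free body the Euler characteristic
#' equals the number of components minus the total genus, so a "pinhole"
#' structure (a delineation with a tunnel through it, the donut that
#' deformable propagation engines notoriously fail on) is flagged by
#' `has_handle`. The flag assumes no fully enclosed internal cavities,
#' which delineated organ masks do not have in practice; a cavity would
#' raise the Euler characteristic and could hide a handle.
#'
#' Topology is used to tag metric records, never to exclude them.
#'
#' @param mask a non-empty [structure_mask()].
#' @return list with `n_components`, `euler_characteristic`, `has_handle`.
#' @export
check_topology <- function(mask) {
  if (is_empty_mask(mask)) stop("mask is empty")
  lab <- label_components_cpp(as.logical(mask$occupancy), mask$grid$shape)
  ncomp <- attr(lab, "n_components")
  chi <- euler_characteristic(mask$occupancy)
  list(n_components = as.integer(ncomp),
       euler_characteristic = as.integer(chi),
       has_handle = chi < ncomp)
}

# Euler characteristic V - E + F - C of the cubical complex of the occupied
# voxels: each occupied voxel contributes its cube, 6 faces, 12 edges and 8
# vertices, shared cells counted once (see euler_char_cpp).
euler_characteristic <- function(occ) {
  euler_char_cpp(as.logical(occ), dim(occ))
}
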