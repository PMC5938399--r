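# Dendritic and axonal summary metrics. Edge compartment follows the child
# node (SWC convention), so the edge from a soma node to the first neurite
# node counts toward the neurite and soma-internal cable is never counted.

#' Total cable length of a compartment
#'
#' Sum over all parent-child edges whose child node has the given compartment
#' of the Euclidean distance between the two nodes, in mm. Soma-internal
#' edges are excluded.
#'
#' @param n a `neuron_recon`.
#' @param compartment one of `"axon"`, `"dendrite"`, `"apical_dendrite"`,
#'   `"other"`, `"dendrite_all"` (basal + apical pooled) or `"all"` (all
#'   neurite compartments).
#' @return cable length in mm.
#' @export
cable_length <- function(n, compartment = "axon") {
  stopifnot(inherits(n, "neuron_recon"))
  if (identical(compartment, "all")) {
    et <- edge_table(n)
    return(sum(et$length[et$type != 1L]))
  }
  if (identical(compartment, "soma"))
    stop_pq("soma-internal cable is not a neurite length; see ?cable_length",
            "projquant_argument_error")
  et <- edge_table(n)
  sum(et$length[.types_match(et$type, compartment)])
}

#' Number of stems emanating from the soma
#'
#' Counts edges from a soma node to a node of the given compartment, i.e.
#' the number of neurite trees attached to the cell body.
#'
#' @inheritParams cable_length
#' @return non-negative integer count.
#' @export
count_stems <- function(n, compartment = "dendrite_all") {
  stopifnot(inherits(n, "neuron_recon"))
  et <- edge_table(n)
  sum(et$parent_type == 1L & .types_match(et$type, compartment))
}

#' Number of branch points
#'
#' Counts nodes of the given compartment with two or more children of that
#' compartment. A trifurcation counts once (branch points are nodes, not
#' child pairs).
#'
#' @inheritParams cable_length
#' @return non-negative integer count.
#' @export
count_branch_points <- function(n, compartment = "dendrite_all") {
  stopifnot(inherits(n, "neuron_recon"))
  nodes <- n$nodes
  mask <- .types_match(nodes$type, compartment)
  in_comp <- nodes$id[mask]
  child_parents <- nodes$parent[mask & nodes$parent != -1L]
  child_parents <- child_parents[child_parents %in% in_comp]
  sum(table(child_parents) >= 2L)
}

#' Morphometry summary of a reconstruction
#'
#' The standard per-neuron metrics: total dendritic length, number of
#' dendritic stems, number of dendritic branch points (basal and apical
#' dendrites pooled) and total axonal length.
#'
#' @param n a `neuron_recon` or a list of them.
#' @return a data.frame of class `morphometry_summary` with one row per
#'   neuron and columns `neuron_id`, `dendritic_length`, `n_stems`,
#'   `n_branch_points`, `axonal_length` (lengths in mm).
#' @export
summarize_morphometry <- function(n) {
  if (inherits(n, "neuron_recon")) n <- list(n)
  rows <- lapply(n, function(x) {
    data.frame(
      neuron_id = x$neuron_id,
      dendritic_length = cable_length(x, "dendrite_all"),
      n_stems = count_stems(x, "dendrite_all"),
      n_branch_points = count_branch_points(x, "dendrite_all"),
      axonal_length = cable_length(x, "axon")
    )
  })
  out <- do.call(rbind, rows)
  class(out) <- c("morphometry_summary", "data.frame")
  out
}
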