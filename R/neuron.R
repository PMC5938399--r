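# Neuron reconstructions are rooted trees of 3D sample points. Internally all
# coordinates are millimetres in one of three frames:
#   bregma    - ml: signed mm, midline = 0, left hemisphere negative;
#               ap: signed mm, anterior to Bregma positive;
#               dv: depth from the pia in mm, increasing ventrally.
#   injection - ml/ap offsets from the injection site, same conventions.
#   section   - per-section local coordinates prior to stitching.
# Radii are carried in micrometres, as in SWC files.

.SWC_TYPES <- c(soma = 1L, axon = 2L, dendrite = 3L, apical_dendrite = 4L)

#' Map SWC structure-type codes to compartment names
#'
#' Codes 1-4 follow the SWC convention (soma, axon, basal dendrite, apical
#' dendrite); any other code maps to `"other"`.
#'
#' @param type integer vector of SWC type codes.
#' @return character vector of compartment names.
#' @export
compartment_name <- function(type) {
  out <- rep("other", length(type))
  for (nm in names(.SWC_TYPES)) out[type == .SWC_TYPES[[nm]]] <- nm
  out
}

# logical mask: which SWC type codes belong to the named compartment group
.types_match <- function(type, compartment) {
  switch(compartment,
    soma = type == 1L,
    axon = type == 2L,
    dendrite = type == 3L,
    apical_dendrite = type == 4L,
    dendrite_all = type %in% c(3L, 4L),
    other = !(type %in% 1:4),
    stop_pq(sprintf("unknown compartment '%s'", compartment),
            "projquant_argument_error")
  )
}

#' Construct a neuron reconstruction
#'
#' @param nodes data.frame with columns `id` (positive integer, unique),
#'   `type` (SWC structure code), `ml`, `ap`, `dv` (mm), `radius`
#'   (micrometres, may be `NA`) and `parent` (id of the parent node, `-1` for
#'   the root).
#' @param neuron_id character label, e.g. `"AP049"`.
#' @param frame coordinate frame, one of `"bregma"`, `"injection"`,
#'   `"section"`.
#' @param provenance free-form list of metadata (tracer target, section
#'   thickness, source file, ...).
#' @param validate check the structural invariants (single soma-rooted tree,
#'   acyclic, parents resolvable). Nodes are reordered so that every parent
#'   precedes its children.
#' @return object of class `neuron_recon`.
#' @export
neuron_reconstruction <- function(nodes, neuron_id = "neuron", frame = "bregma",
                                  provenance = list(), validate = TRUE) {
  stopifnot(is.data.frame(nodes))
  req <- c("id", "type", "ml", "ap", "dv", "radius", "parent")
  missing_cols <- setdiff(req, names(nodes))
  if (length(missing_cols))
    stop_pq(paste("nodes is missing columns:", paste(missing_cols, collapse = ", ")),
            "projquant_argument_error")
  frame <- match.arg(frame, c("bregma", "injection", "section"))
  nodes <- nodes[, req]
  nodes$id <- as.integer(nodes$id)
  nodes$type <- as.integer(nodes$type)
  nodes$parent <- as.integer(nodes$parent)
  n <- structure(
    list(neuron_id = neuron_id, nodes = nodes, frame = frame,
         provenance = provenance),
    class = "neuron_recon"
  )
  if (validate) n <- validate_neuron(n)
  n
}

#' Validate a neuron reconstruction
#'
#' Checks the structural invariants: unique positive ids, exactly one root
#' (parent `-1`), every parent id resolvable, the graph a single connected
#' acyclic tree, and soma nodes forming a connected subgraph that contains
#' the root. Finite coordinates are required. On success the nodes are
#' returned in topological (parent-before-child) order.
#'
#' @param n a `neuron_recon`.
#' @return the validated (possibly reordered) `neuron_recon`.
#' @export
validate_neuron <- function(n) {
  nodes <- n$nodes
  if (nrow(nodes) == 0L)
    stop_pq("reconstruction has no nodes", "projquant_structural_error")
  if (anyDuplicated(nodes$id))
    stop_pq("duplicate node ids", "projquant_structural_error")
  if (any(nodes$id <= 0L))
    stop_pq("node ids must be positive", "projquant_structural_error")
  if (!all(is.finite(as.matrix(nodes[, c("ml", "ap", "dv")]))))
    stop_pq("non-finite coordinates", "projquant_structural_error")
  roots <- nodes$id[nodes$parent == -1L]
  if (length(roots) == 0L)
    stop_pq("no root node (parent -1)", "projquant_structural_error")
  if (length(roots) > 1L)
    stop_pq(sprintf("multiple roots: node ids %s", paste(roots, collapse = ", ")),
            "projquant_structural_error")
  known <- c(-1L, nodes$id)
  orphans <- setdiff(nodes$parent, known)
  if (length(orphans))
    stop_pq(sprintf("parent id(s) %s refer to no node",
                    paste(orphans, collapse = ", ")),
            "projquant_structural_error")

  # BFS from root to get topological order; anything unreached is either a
  # disconnected component or part of a cycle.
  idx <- match(nodes$parent, nodes$id)             # NA for root
  kids <- split(seq_len(nrow(nodes)), idx)
  order_out <- integer(nrow(nodes))
  order_out[1L] <- which(nodes$parent == -1L)
  head <- 1L; tail <- 1L
  while (head <= tail) {
    ch <- kids[[as.character(order_out[head])]]
    if (!is.null(ch)) {
      order_out[(tail + 1L):(tail + length(ch))] <- ch
      tail <- tail + length(ch)
    }
    head <- head + 1L
  }
  if (tail < nrow(nodes))
    stop_pq("reconstruction is not a single connected acyclic tree",
            "projquant_structural_error")
  nodes <- nodes[order_out, , drop = FALSE]
  rownames(nodes) <- NULL

  soma_rows <- which(nodes$type == 1L)
  if (length(soma_rows)) {
    if (nodes$type[1L] != 1L)
      stop_pq("root node is not a soma node", "projquant_structural_error")
    soma_ids <- nodes$id[soma_rows]
    ok <- nodes$parent[soma_rows] %in% c(-1L, soma_ids)
    if (!all(ok))
      stop_pq("soma nodes do not form a connected subgraph containing the root",
              "projquant_structural_error")
  }
  n$nodes <- nodes
  n
}

#' Soma location of a reconstruction
#'
#' @param n a `neuron_recon`.
#' @return named numeric `(ml, ap, dv)` in mm of the root node.
#' @export
soma_location <- function(n) {
  r <- n$nodes[n$nodes$parent == -1L, ]
  c(ml = r$ml[1], ap = r$ap[1], dv = r$dv[1])
}

# Edge table: one row per non-root node, with parent coordinates attached.
# Edge compartment follows the child node (SWC convention).
edge_table <- function(n) {
  nodes <- n$nodes
  child <- which(nodes$parent != -1L)
  pidx <- match(nodes$parent[child], nodes$id)
  data.frame(
    child_id = nodes$id[child], parent_id = nodes$parent[child],
    type = nodes$type[child], parent_type = nodes$type[pidx],
    ml0 = nodes$ml[pidx], ap0 = nodes$ap[pidx], dv0 = nodes$dv[pidx],
    ml1 = nodes$ml[child], ap1 = nodes$ap[child], dv1 = nodes$dv[child],
    length = sqrt((nodes$ml[child] - nodes$ml[pidx])^2 +
                  (nodes$ap[child] - nodes$ap[pidx])^2 +
                  (nodes$dv[child] - nodes$dv[pidx])^2)
  )
}

#' @export
print.neuron_recon <- function(x, ...) {
  nn <- nrow(x$nodes)
  cat(sprintf("Neuron reconstruction '%s' (%s frame)\n", x$neuron_id, x$frame))
  cat(sprintf("  %d nodes; soma at (ml %.3f, ap %.3f, dv %.3f) mm\n",
              nn, soma_location(x)[1], soma_location(x)[2], soma_location(x)[3]))
  tab <- table(compartment_name(x$nodes$type))
  cat("  nodes by compartment:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.neuron_recon <- function(object, ...) {
  summarize_morphometry(object)
}

#' Plot a 2D projection of a reconstruction
#'
#' Coronal projections show ml against depth (pia up); horizontal
#' projections show the dorsal view (ml against ap). Axon is drawn in red,
#' dendrites in black, the soma as a filled dot.
#'
#' @param x a `neuron_recon`.
#' @param plane `"coronal"` or `"horizontal"`.
#' @param ... further arguments passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.neuron_recon <- function(x, plane = c("coronal", "horizontal"), ...) {
  plane <- match.arg(plane)
  et <- edge_table(x)
  if (plane == "coronal") {
    a0 <- et$ml0; b0 <- -et$dv0; a1 <- et$ml1; b1 <- -et$dv1
    ylab <- "depth (mm)"
  } else {
    a0 <- et$ml0; b0 <- et$ap0; a1 <- et$ml1; b1 <- et$ap1
    ylab <- "ap (mm)"
  }
  graphics::plot(range(c(a0, a1)), range(c(b0, b1)), type = "n",
                 xlab = "ml (mm)", ylab = ylab, asp = 1,
                 main = x$neuron_id, ...)
  dend <- et$type %in% c(3L, 4L)
  ax <- et$type == 2L
  graphics::segments(a0[dend], b0[dend], a1[dend], b1[dend], col = "black")
  graphics::segments(a0[ax], b0[ax], a1[ax], b1[ax], col = "#cc3333")
  s <- soma_location(x)
  graphics::points(s[1], if (plane == "coronal") -s[3] else s[2],
                   pch = 19, col = "#119933", cex = 1.2)
  invisible(x)
}
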