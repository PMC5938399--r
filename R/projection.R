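# Per-neuron projection profiles, the thresholded projection matrix,
# S2p/M1p classification and group summaries.
#
# "Branching axon" in a region is operationalized as intra-region axonal
# cable belonging to a connected intra-region piece of the axonal tree that
# contains at least one axonal branch point inside the region. Intra-region
# cable of unbranched pass-through (or terminating) fibers is tallied
# separately as passing cable, so users can sum the two if they prefer a
# total-cable reading.

#' Construct a projection profile
#'
#' @param neuron_id character label.
#' @param region_lengths named numeric, branching-axon cable (mm) per region.
#' @param passing_lengths named numeric, non-branching (pass-through) axon
#'   cable (mm) per region; same names as `region_lengths`.
#' @param elsewhere_length axonal cable (mm) in no modelled region.
#' @param total_axon_length total axonal cable (mm). Must equal the sum of
#'   the other components to 1e-9 relative.
#' @return object of class `projection_profile`.
#' @export
projection_profile <- function(neuron_id, region_lengths, passing_lengths,
                               elsewhere_length, total_axon_length) {
  stopifnot(identical(names(region_lengths), names(passing_lengths)))
  if (any(c(region_lengths, passing_lengths, elsewhere_length,
            total_axon_length) < -1e-12))
    stop_pq("cable lengths must be non-negative", "projquant_argument_error")
  s <- sum(region_lengths) + sum(passing_lengths) + elsewhere_length
  tol <- 1e-9 * max(1, total_axon_length)
  if (abs(s - total_axon_length) > tol)
    stop_pq(sprintf(
      "cable conservation violated: components sum to %.12g, total is %.12g",
      s, total_axon_length), "projquant_conservation_error")
  structure(list(neuron_id = neuron_id,
                 region_lengths = region_lengths,
                 passing_lengths = passing_lengths,
                 elsewhere_length = elsewhere_length,
                 total_axon_length = total_axon_length),
            class = "projection_profile")
}

#' @export
print.projection_profile <- function(x, ...) {
  cat(sprintf("Projection profile '%s': total axon %.1f mm (%.1f mm unassigned)\n",
              x$neuron_id, x$total_axon_length, x$elsewhere_length))
  df <- data.frame(region = names(x$region_lengths),
                   branching_mm = round(unname(x$region_lengths), 2),
                   passing_mm = round(unname(x$passing_lengths), 2))
  print.data.frame(df[df$branching_mm > 0 | df$passing_mm > 0, ],
                   row.names = FALSE)
  invisible(x)
}

#' Quantify the regional projection of a single neuron
#'
#' Clips every axonal edge against the region model, then splits each
#' region's intra-region cable into branching and passing components: a
#' connected intra-region piece of the axonal tree counts as branching if it
#' contains at least one axonal branch point (node with >= 2 axonal
#' children) inside the region, and as passing otherwise. The components
#' plus unassigned (`elsewhere`) cable conserve the total axonal length.
#'
#' @param n a `neuron_recon` in the bregma frame.
#' @param model a [region_model()].
#' @return a [projection_profile()].
#' @export
quantify_projection <- function(n, model) {
  stopifnot(inherits(n, "neuron_recon"))
  if (!identical(n$frame, "bregma"))
    stop_pq("reconstruction must be in the bregma frame", "projquant_frame_error")
  nodes <- n$nodes
  et <- edge_table(n)
  ax <- et[et$type == 2L, , drop = FALSE]
  region_names <- model$regions$name
  zero <- stats::setNames(numeric(length(region_names)), region_names)
  total <- sum(ax$length)
  if (nrow(ax) == 0L)
    return(projection_profile(n$neuron_id, zero, zero, 0, 0))

  p0 <- as.matrix(ax[, c("ml0", "ap0", "dv0")])
  p1 <- as.matrix(ax[, c("ml1", "ap1", "dv1")])
  pieces <- .clip_edges(p0, p1, model)
  elsewhere <- sum(pieces$length[pieces$region == "elsewhere"])

  # node-level region assignment and axonal branch points
  axon_node <- nodes$type == 2L
  node_region <- rep("", nrow(nodes))
  node_region[axon_node] <- locate_point(
    as.matrix(nodes[axon_node, c("ml", "ap", "dv")]), model)
  ax_children_parent <- nodes$parent[nodes$type == 2L & nodes$parent != -1L]
  # parents that are themselves axon nodes, with >= 2 axonal children
  ax_ids <- nodes$id[axon_node]
  tabp <- table(ax_children_parent[ax_children_parent %in% ax_ids])
  branch_ids <- as.integer(names(tabp)[tabp >= 2L])

  branching <- zero; passing <- zero

  for (rg in region_names) {
    in_pieces <- pieces[pieces$region == rg, , drop = FALSE]
    if (!nrow(in_pieces)) next
    in_ids <- nodes$id[axon_node & node_region == rg]
    # connected components (union-find) of the axonal tree restricted to
    # nodes inside rg; edges with both endpoints inside connect them
    comp <- seq_along(in_ids)
    find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
    ppos <- match(ax$parent_id, in_ids)
    cpos <- match(ax$child_id, in_ids)
    for (k in which(!is.na(ppos) & !is.na(cpos))) {
      a <- find(ppos[k]); b <- find(cpos[k])
      if (a != b) comp[b] <- a
    }
    roots <- vapply(seq_along(in_ids), find, integer(1))
    br_comps <- unique(roots[match(intersect(branch_ids, in_ids), in_ids)])
    # component ownership per piece: the child end if inside rg, else the
    # parent end; a piece with neither endpoint inside is a standalone
    # pass-through (it cannot contain a branch point of rg)
    pc <- cpos[in_pieces$edge]; pp <- ppos[in_pieces$edge]
    owner <- ifelse(!is.na(pc), roots[pc], ifelse(!is.na(pp), roots[pp], NA))
    is_br <- !is.na(owner) & owner %in% br_comps
    branching[rg] <- sum(in_pieces$length[is_br])
    passing[rg] <- sum(in_pieces$length[!is_br])
  }
  projection_profile(n$neuron_id, branching, passing, elsewhere, total)
}

#' Threshold projection profiles into a cell-by-region class matrix
#'
#' Classes follow strict thresholds on branching-axon length: `dark` for
#' length > `dark_mm`, `light` for `light_mm` < length <= `dark_mm`, `none`
#' otherwise. Boundary values fall to the lower class.
#'
#' @param profiles a `projection_profile` or list of them.
#' @param light_mm,dark_mm class thresholds in mm (defaults 1 and 10).
#' @return object of class `projection_matrix`: list with `classes`
#'   (neurons x regions character matrix), `lengths` (numeric matrix) and
#'   `thresholds`.
#' @export
threshold_matrix <- function(profiles, light_mm = 1, dark_mm = 10) {
  if (inherits(profiles, "projection_profile")) profiles <- list(profiles)
  if (!length(profiles))
    stop_pq("profiles must be non-empty", "projquant_argument_error")
  if (light_mm < 0 || dark_mm < 0 || light_mm >= dark_mm)
    stop_pq("thresholds must satisfy 0 <= light < dark", "projquant_argument_error")
  lens <- do.call(rbind, lapply(profiles, function(p) p$region_lengths))
  rownames(lens) <- vapply(profiles, function(p) p$neuron_id, character(1))
  classes <- matrix("none", nrow(lens), ncol(lens), dimnames = dimnames(lens))
  classes[lens > light_mm] <- "light"
  classes[lens > dark_mm] <- "dark"
  structure(list(classes = classes, lengths = lens,
                 thresholds = c(light_mm = light_mm, dark_mm = dark_mm)),
            class = "projection_matrix")
}

#' @export
print.projection_matrix <- function(x, ...) {
  cat(sprintf("Projection matrix: %d neurons x %d regions (light > %g mm, dark > %g mm)\n",
              nrow(x$classes), ncol(x$classes),
              x$thresholds["light_mm"], x$thresholds["dark_mm"]))
  print(x$classes, quote = FALSE)
  invisible(x)
}

#' Classify a neuron by its dominant long-range cortical target
#'
#' `"S2p"` if the branching-axon length in wS2 exceeds that in wM1/2,
#' `"M1p"` if the reverse, `"unclassified"` on an exact tie (including both
#' zero).
#'
#' @param p a `projection_profile`, or a list of them.
#' @param s2 name of the wS2 entry in the profile (default `"wS2"`).
#' @param m1 name of the wM1/2 entry (default `"wM1/2"`).
#' @return character vector of class labels.
#' @export
classify_projection_class <- function(p, s2 = "wS2", m1 = "wM1/2") {
  if (inherits(p, "projection_profile")) p <- list(p)
  vapply(p, function(pr) {
    if (!all(c(s2, m1) %in% names(pr$region_lengths)))
      stop_pq(sprintf("profile lacks '%s'/'%s' entries", s2, m1),
              "projquant_argument_error")
    a <- pr$region_lengths[[s2]]; b <- pr$region_lengths[[m1]]
    if (a > b) "S2p" else if (b > a) "M1p" else "unclassified"
  }, character(1))
}

#' Core fraction of branching axon
#'
#' Fraction of the total branching-axon cable that lies in the three core
#' regions wS1, wS2 and wM1/2.
#'
#' @param p a `projection_profile` or list of them.
#' @param core names of the core regions.
#' @return numeric in `[0, 1]`.
#' @export
core_fraction <- function(p, core = c("wS1", "wS2", "wM1/2")) {
  if (inherits(p, "projection_profile")) p <- list(p)
  vapply(p, function(pr) {
    tot <- sum(pr$region_lengths)
    if (tot <= 0)
      stop_pq("total branching axon is zero; core fraction undefined",
              "projquant_undefined_result")
    sum(pr$region_lengths[core]) / tot
  }, numeric(1))
}

#' Group summaries (mean and SD) of morphometrics and projection lengths
#'
#' @param profiles list of `projection_profile`.
#' @param summaries optional [summarize_morphometry()] data.frame aligned
#'   with `profiles`.
#' @param labels character vector of group labels, one per profile.
#' @return data.frame of class `group_summary` with columns `group`,
#'   `metric`, `mean`, `sd` (sample SD, `NA` for n = 1) and `n`.
#' @export
group_summary <- function(profiles, summaries = NULL, labels) {
  if (length(labels) != length(profiles))
    stop_pq("labels must match profiles", "projquant_argument_error")
  if (!length(profiles))
    stop_pq("profiles must be non-empty", "projquant_argument_error")
  vals <- do.call(rbind, lapply(profiles, function(p)
    c(p$region_lengths, total_axon = p$total_axon_length)))
  if (!is.null(summaries)) {
    stopifnot(nrow(summaries) == length(profiles))
    vals <- cbind(vals, dendritic_length = summaries$dendritic_length,
                  n_stems = summaries$n_stems,
                  n_branch_points = summaries$n_branch_points)
  }
  out <- do.call(rbind, lapply(split(seq_along(labels), labels), function(ix) {
    m <- vals[ix, , drop = FALSE]
    data.frame(group = labels[ix[1]], metric = colnames(m),
               mean = colMeans(m),
               sd = if (length(ix) >= 2) apply(m, 2, stats::sd) else NA_real_,
               n = length(ix), row.names = NULL)
  }))
  rownames(out) <- NULL
  class(out) <- c("group_summary", "data.frame")
  out
}

#' Tabulate projection profiles
#'
#' @param profiles list of `projection_profile`.
#' @return data.frame: `neuron_id`, one `branch_*` column per region, one
#'   `pass_*` column per region, `elsewhere`, `total_axon`.
#' @export
profiles_to_df <- function(profiles) {
  if (inherits(profiles, "projection_profile")) profiles <- list(profiles)
  do.call(rbind, lapply(profiles, function(p) {
    row <- data.frame(neuron_id = p$neuron_id)
    b <- as.list(p$region_lengths); names(b) <- paste0("branch_", names(b))
    s <- as.list(p$passing_lengths); names(s) <- paste0("pass_", names(s))
    cbind(row, as.data.frame(b, check.names = FALSE),
          as.data.frame(s, check.names = FALSE),
          data.frame(elsewhere = p$elsewhere_length,
                     total_axon = p$total_axon_length))
  }))
}

#' Rebuild projection profiles from a table written by [profiles_to_df()]
#'
#' @param df data.frame in the [profiles_to_df()] layout.
#' @return list of `projection_profile`.
#' @export
df_to_profiles <- function(df) {
  bcols <- grep("^branch_", names(df), value = TRUE)
  pcols <- grep("^pass_", names(df), value = TRUE)
  regions <- sub("^branch_", "", bcols)
  lapply(seq_len(nrow(df)), function(i) {
    projection_profile(
      df$neuron_id[i],
      stats::setNames(as.numeric(df[i, bcols]), regions),
      stats::setNames(as.numeric(df[i, pcols]), regions),
      df$elsewhere[i], df$total_axon[i])
  })
}
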