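# Synthetic reconstructions and multi-animal density volumes with known
# ground truth. The generator emulates the statistical structure of layer
# 2/3 pyramidal projection neurons of the whisker barrel cortex: a soma
# 200-250 um deep in wS1, ~8 mm of dendrite on ~8 stems with ~64 branch
# nodes, ~40 mm of dense local axon in wS1, and long-range collaterals
# placing prescribed amounts of branching (or unbranched passing) cable in
# named target regions. Geometry is deliberately schematic - collateral
# trunks descend to a deep fiber corridor below every modelled region and
# rise into the target from below - because only the quantities the
# pipeline measures (cable lengths per region, branch counts, topology) are
# controlled; tortuosity and radii are not.
#
# The ground-truth projection profile is computed analytically from the
# construction (trunk bookkeeping), never via quantify_projection, so the
# generator can serve as an independent oracle for the analyzer.

#' Specification of one synthetic neuron
#'
#' @param neuron_id character label.
#' @param soma optional `c(ml, ap, dv)` (mm, bregma frame); default is the
#'   wS1 center at a depth drawn uniformly in 0.200-0.250 mm.
#' @param dendrite_length_mm total dendritic length (default 8.1).
#' @param n_stems dendritic trees from the soma (default 8; the first stem
#'   is written as apical dendrite, the rest as basal).
#' @param n_dendrite_branch_points total dendritic branch nodes (default 64).
#' @param local_axon_mm axonal cable placed in wS1, including the trunk
#'   plumbing that crosses wS1 (default 41.7).
#' @param collaterals data.frame(`region`, `length_mm`, `include_branch`):
#'   long-range collaterals placing `length_mm` of cable strictly inside
#'   the target region; with `include_branch = TRUE` (the default) the
#'   intra-region cable arborizes (counts as branching axon), otherwise it
#'   is an unbranched fiber (counts as passing).
#' @param passing_fibers data.frame(`region`, `length_mm`): shorthand for
#'   unbranched collaterals.
#' @param seed integer RNG seed; the same seed yields a bit-identical
#'   reconstruction.
#' @return object of class `synthetic_neuron_spec`.
#' @export
synthetic_neuron_spec <- function(neuron_id = "SYN001", soma = NULL,
                                  dendrite_length_mm = 8.1, n_stems = 8,
                                  n_dendrite_branch_points = 64,
                                  local_axon_mm = 41.7,
                                  collaterals = NULL, passing_fibers = NULL,
                                  seed = 1L) {
  collaterals <- collaterals %||%
    data.frame(region = character(), length_mm = numeric(),
               include_branch = logical())
  if (is.null(collaterals$include_branch)) collaterals$include_branch <- TRUE
  if (!is.null(passing_fibers) && nrow(passing_fibers)) {
    collaterals <- rbind(collaterals,
                         data.frame(region = passing_fibers$region,
                                    length_mm = passing_fibers$length_mm,
                                    include_branch = FALSE))
  }
  if (any(collaterals$length_mm < 0) || dendrite_length_mm < 0 ||
      local_axon_mm < 0)
    stop_pq("lengths must be non-negative", "projquant_spec_error")
  if (n_stems < 1 || n_dendrite_branch_points < 0)
    stop_pq("need >= 1 stem and >= 0 branch points", "projquant_spec_error")
  structure(list(neuron_id = neuron_id, soma = soma,
                 dendrite_length_mm = dendrite_length_mm,
                 n_stems = as.integer(n_stems),
                 n_dendrite_branch_points = as.integer(n_dendrite_branch_points),
                 local_axon_mm = local_axon_mm,
                 collaterals = collaterals, seed = as.integer(seed)),
            class = "synthetic_neuron_spec")
}

# ---- internal geometry helpers ------------------------------------------

# Random binary tree of exactly n_branch branch nodes realized as a
# fixed-step random walk confined to an axis-aligned box. Returns a local
# table: point matrix, parent index (0 = attach externally), with total
# length exactly `total_len` and, if n_branch > 0, exactly n_branch nodes
# with two children.
.grow_arbor <- function(origin, total_len, n_branch, box_lo, box_hi,
                        step_target = 0.05) {
  n_seg <- max(2L * n_branch + 1L, ceiling(total_len / step_target))
  step <- total_len / n_seg
  ctr <- (box_lo + box_hi) / 2
  pts <- matrix(0, n_seg + 64L, 3)
  par <- integer(n_seg + 64L)
  n_pts <- 0L
  add_pt <- function(p, parent) {
    n_pts <<- n_pts + 1L
    if (n_pts > nrow(pts)) {
      pts <<- rbind(pts, matrix(0, nrow(pts), 3))
      par <<- c(par, integer(length(par)))
    }
    pts[n_pts, ] <<- p
    par[n_pts] <<- parent
    n_pts
  }
  walk_step <- function(from) {
    for (try in 1:8) {
      u <- unit_vec(stats::rnorm(3))
      cand <- from + step * u
      if (all(cand >= box_lo & cand <= box_hi)) return(cand)
    }
    from + step * unit_vec(ctr - from + stats::rnorm(3) * 1e-6)
  }
  # task stack: (attach point index or 0, position, segments, branches)
  tasks <- list(list(parent = 0L, pos = origin, n_seg = n_seg,
                     n_branch = n_branch))
  while (length(tasks)) {
    tk <- tasks[[length(tasks)]]; tasks[[length(tasks)]] <- NULL
    parent <- tk$parent; pos <- tk$pos
    segs <- tk$n_seg; brs <- tk$n_branch
    # chain until the next branch node (or to the end)
    chain <- if (brs == 0L) segs
             else sample.int(segs - 2L * brs, 1L)
    for (s in seq_len(chain)) {
      pos <- walk_step(pos)
      parent <- add_pt(pos, parent)
    }
    if (brs > 0L) {
      rem_seg <- segs - chain
      b1 <- sample.int(brs, 1L) - 1L          # 0 .. brs-1
      b2 <- brs - 1L - b1
      smin1 <- 2L * b1 + 1L; smin2 <- 2L * b2 + 1L
      s1 <- smin1 + sample.int(rem_seg - smin1 - smin2 + 1L, 1L) - 1L
      s2 <- rem_seg - s1
      tasks[[length(tasks) + 1L]] <- list(parent = parent, pos = pos,
                                          n_seg = s1, n_branch = b1)
      tasks[[length(tasks) + 1L]] <- list(parent = parent, pos = pos,
                                          n_seg = s2, n_branch = b2)
    }
  }
  list(points = pts[seq_len(n_pts), , drop = FALSE],
       parent = par[seq_len(n_pts)], length = total_len)
}

# Search the region's footprint for an anchor column: an (ml, ap) point
# whose +-probe_half box is owned by the region over its depth range and
# owned by nothing between the region's floor and the fiber corridor.
# Returns c(ml, ap) or NULL.
.find_anchor_column <- function(model, region_name, corridor_dv,
                                probe_half = 0.12, prefer = NULL) {
  regs <- model$regions
  r <- regs[regs$name == region_name, ]
  if (!nrow(r))
    stop_pq(sprintf("region '%s' not in model", region_name),
            "projquant_spec_error")
  prefer <- prefer %||% c(r$center_ml, r$center_ap)
  mls <- seq(r$center_ml - r$half_ml + probe_half,
             r$center_ml + r$half_ml - probe_half, by = 0.04)
  aps <- seq(r$center_ap - r$half_ap + probe_half,
             r$center_ap + r$half_ap - probe_half, by = 0.04)
  cand <- expand.grid(ml = mls, ap = aps)
  cand <- cand[order((cand$ml - prefer[1])^2 + (cand$ap - prefer[2])^2), ]
  dv_in <- seq(r$dv_min + 0.02, r$dv_max - 0.02, length.out = 6)
  dv_below <- if (r$dv_max < corridor_dv)
    seq(r$dv_max + 0.02, corridor_dv, length.out = 5) else numeric(0)
  corners <- rbind(c(0, 0), c(-1, -1), c(-1, 1), c(1, -1), c(1, 1)) * probe_half
  for (i in seq_len(nrow(cand))) {
    p <- c(cand$ml[i], cand$ap[i])
    pts_in <- cbind(rep(p[1] + corners[, 1], each = length(dv_in)),
                    rep(p[2] + corners[, 2], each = length(dv_in)),
                    rep(dv_in, nrow(corners)))
    if (!all(locate_point(pts_in, model) == region_name)) next
    if (length(dv_below)) {
      pts_bel <- cbind(p[1], p[2], dv_below)
      if (!all(locate_point(pts_bel, model) == "elsewhere")) next
    }
    return(p)
  }
  NULL
}

# anchors for every region plus the wS1 descent shaft; cached on the model
.model_anchors <- function(model) {
  cached <- attr(model, "pq_anchors")
  if (!is.null(cached)) return(cached)
  corridor_dv <- max(model$regions$dv_max) + 0.5
  anchors <- lapply(model$regions$name, function(nm)
    .find_anchor_column(model, nm, corridor_dv))
  names(anchors) <- model$regions$name
  local_ws1 <- if ("wS1" %in% model$regions$name)
    .find_anchor_column(model, "wS1", corridor_dv, probe_half = 0.22)
  else NULL
  list(anchors = anchors, corridor_dv = corridor_dv, local_ws1 = local_ws1)
}

#' Precompute generator anchor columns for a region model
#'
#' The neuron generator routes collateral trunks through per-region anchor
#' columns found by grid search; computing them once and attaching them to
#' the model avoids repeating the search for every neuron of a cohort.
#'
#' @param model a [region_model()].
#' @return the model with anchors attached as an attribute.
#' @export
prepare_model <- function(model) {
  attr(model, "pq_anchors") <- .model_anchors(model)
  model
}

# ---- neuron generation ---------------------------------------------------

#' Generate a synthetic neuron with known ground truth
#'
#' Builds a reconstruction meeting the spec exactly: dendritic length, stem
#' and branch-point counts are hit exactly; each collateral places exactly
#' `length_mm` of cable strictly inside its target region (branching cable
#' if `include_branch`, unbranched passing cable otherwise); `local_axon_mm`
#' of axon lies in wS1. The returned ground-truth profile is derived from
#' the construction bookkeeping, independent of [quantify_projection()].
#'
#' @param spec a [synthetic_neuron_spec()].
#' @param model a [region_model()]; must contain every target region.
#' @return list with elements `neuron` (a `neuron_recon`) and `truth`
#'   (a [projection_profile()]).
#' @export
generate_neuron <- function(spec, model = default_region_model()) {
  stopifnot(inherits(spec, "synthetic_neuron_spec"))
  anc <- .model_anchors(model)
  corridor_dv <- anc$corridor_dv
  regs <- model$regions
  ws1 <- regs[regs$name == "wS1", ]
  if (!nrow(ws1))
    stop_pq("model must contain a 'wS1' region", "projquant_spec_error")
  unknown <- setdiff(spec$collaterals$region, regs$name)
  if (length(unknown))
    stop_pq(paste("collateral target(s) not in model:",
                  paste(unknown, collapse = ", ")), "projquant_spec_error")

  with_seed(spec$seed, {
    soma <- spec$soma %||% c(ws1$center_ml, ws1$center_ap,
                             stats::runif(1, 0.200, 0.250))
    nodes_pts <- matrix(soma, 1, 3)
    nodes_type <- 1L
    nodes_parent <- 0L                        # row index of parent; 0 = root
    add_nodes <- function(points, parent_rows, type) {
      n0 <- nrow(nodes_pts)
      nodes_pts <<- rbind(nodes_pts, points)
      nodes_type <<- c(nodes_type, rep(type, nrow(points)))
      nodes_parent <<- c(nodes_parent, parent_rows)
      n0 + seq_len(nrow(points))
    }
    attach_arbor <- function(arb, attach_row, type) {
      rows <- add_nodes(arb$points,
                        rep(0L, nrow(arb$points)), type)
      # fix parents: local parent 0 -> attach_row
      loc_par <- arb$parent
      mapped <- rows[pmax(loc_par, 1L)]
      nodes_parent[rows] <<- ifelse(loc_par == 0L, attach_row, mapped)
      rows
    }

    # dendrites: exact stem count, branch-point and length targets
    n_st <- spec$n_stems
    b_tot <- spec$n_dendrite_branch_points
    b_per <- rep(b_tot %/% n_st, n_st)
    extra <- b_tot %% n_st
    if (extra > 0) b_per[seq_len(extra)] <- b_per[seq_len(extra)] + 1L
    len_per <- spec$dendrite_length_mm / n_st
    dend_lo <- c(soma[1] - 0.25, soma[2] - 0.25, 0.02)
    dend_hi <- c(soma[1] + 0.25, soma[2] + 0.25, 0.60)
    for (s in seq_len(n_st)) {
      arb <- .grow_arbor(soma, len_per, b_per[s], dend_lo, dend_hi,
                         step_target = 0.04)
      attach_arbor(arb, 1L, if (s == 1L) 4L else 3L)
    }

    # axon root (zero-length edge at the soma)
    a0 <- add_nodes(matrix(soma, 1, 3), 1L, 2L)

    # wS1 descent shaft: a column owned by wS1 down to the cortical floor
    # and by nothing below it, as close to the soma as possible
    shaft <- .find_anchor_column(model, "wS1", corridor_dv,
                                 prefer = soma[1:2])
    if (is.null(shaft))
      stop_pq("no feasible trunk shaft inside wS1", "projquant_spec_error")
    jog_len <- sqrt(sum((shaft - soma[1:2])^2))
    plumbing_ws1 <- jog_len + (ws1$dv_max - soma[3])
    jog_row <- add_nodes(matrix(c(shaft, soma[3]), 1, 3), a0, 2L)
    hub_row <- add_nodes(matrix(c(shaft, corridor_dv), 1, 3), jog_row, 2L)

    # local wS1 arbor; its budget absorbs the trunk plumbing so that total
    # wS1 axon equals local_axon_mm exactly
    loc_box_ctr <- anc$local_ws1
    if (is.null(loc_box_ctr))
      stop_pq("no feasible local-axon territory inside wS1",
              "projquant_spec_error")
    loc_lo <- c(loc_box_ctr - 0.20, max(ws1$dv_min + 0.05, 0.05))
    loc_hi <- c(loc_box_ctr + 0.20, ws1$dv_max - 0.65)
    loc_ctr3 <- (loc_lo + loc_hi) / 2
    attach_len <- sqrt(sum((loc_ctr3 - soma)^2))
    loc_budget <- spec$local_axon_mm - plumbing_ws1 - attach_len
    if (loc_budget < 0.5)
      stop_pq("local_axon_mm too small to cover trunk plumbing",
              "projquant_spec_error")
    loc_attach <- add_nodes(matrix(loc_ctr3, 1, 3), a0, 2L)
    n_loc_branch <- max(5L, min(40L, as.integer(loc_budget %/% 1)))
    loc_arb <- .grow_arbor(loc_ctr3, loc_budget, n_loc_branch,
                           loc_lo, loc_hi, step_target = 0.05)
    loc_rows <- attach_arbor(loc_arb, loc_attach, 2L)

    # collaterals
    region_names <- regs$name
    truth_branch <- stats::setNames(numeric(length(region_names)), region_names)
    truth_pass <- truth_branch
    truth_branch["wS1"] <- spec$local_axon_mm
    elsewhere <- (corridor_dv - ws1$dv_max)            # descent below wS1
    col_check <- list()
    if (nrow(spec$collaterals)) for (ci in seq_len(nrow(spec$collaterals))) {
      cl <- spec$collaterals[ci, ]
      if (cl$length_mm <= 0) next
      rr <- regs[regs$name == cl$region, ]
      tanchor <- anc$anchors[[cl$region]]
      if (is.null(tanchor))
        stop_pq(sprintf("no feasible anchor column in region '%s'", cl$region),
                "projquant_spec_error")
      run_len <- sqrt(sum((tanchor - shaft)^2))
      run_row <- add_nodes(matrix(c(tanchor, corridor_dv), 1, 3), hub_row, 2L)
      entry_row <- add_nodes(matrix(c(tanchor, rr$dv_max), 1, 3), run_row, 2L)
      elsewhere <- elsewhere + run_len + (corridor_dv - rr$dv_max)
      box_lo <- c(tanchor - 0.10, max(rr$dv_min + 0.05, rr$dv_max - 0.45))
      box_hi <- c(tanchor + 0.10, rr$dv_max - 0.05)
      if (cl$include_branch) {
        entry_step <- 0.05
        budget <- cl$length_mm - entry_step
        if (budget < 0.02)
          stop_pq(sprintf(
            "collateral to '%s' too short (%.3f mm) to arborize",
            cl$region, cl$length_mm), "projquant_spec_error")
        apt <- c(tanchor, rr$dv_max - entry_step)
        arow <- add_nodes(matrix(apt, 1, 3), entry_row, 2L)
        nb <- max(1L, min(30L, as.integer(budget %/% 0.8)))
        arb <- .grow_arbor(apt, budget, nb, box_lo, box_hi,
                           step_target = 0.05)
        rows <- attach_arbor(arb, arow, 2L)
        truth_branch[cl$region] <- truth_branch[cl$region] + cl$length_mm
        col_check[[length(col_check) + 1L]] <-
          list(region = cl$region, rows = c(arow, rows))
      } else {
        arb <- .grow_arbor(c(tanchor, rr$dv_max), cl$length_mm, 0L,
                           box_lo, box_hi, step_target = 0.05)
        rows <- attach_arbor(arb, entry_row, 2L)
        truth_pass[cl$region] <- truth_pass[cl$region] + cl$length_mm
        col_check[[length(col_check) + 1L]] <-
          list(region = cl$region, rows = rows)
      }
    }

    # verify the construction's ownership assumptions with the containment
    # oracle (generation fails loudly rather than returning a wrong truth)
    jog_mid <- (soma + c(shaft, soma[3])) / 2
    att_mid <- (soma + loc_ctr3) / 2
    ver_pts <- rbind(nodes_pts[c(loc_rows, loc_attach), , drop = FALSE],
                     jog_mid, att_mid)
    if (!all(locate_point(ver_pts, model) == "wS1"))
      stop_pq("local axon escaped wS1 territory; adjust the region model",
              "projquant_spec_error")
    for (chk in col_check) {
      lab2 <- locate_point(nodes_pts[chk$rows, , drop = FALSE], model)
      if (!all(lab2 == chk$region))
        stop_pq(sprintf("collateral cable escaped region '%s'", chk$region),
                "projquant_spec_error")
    }

    nodes <- data.frame(
      id = seq_len(nrow(nodes_pts)), type = nodes_type,
      ml = nodes_pts[, 1], ap = nodes_pts[, 2], dv = nodes_pts[, 3],
      radius = ifelse(nodes_type == 1L, 5.0, 0.5),
      parent = ifelse(nodes_parent == 0L, -1L, nodes_parent)
    )
    neuron <- neuron_reconstruction(nodes, neuron_id = spec$neuron_id,
                                    frame = "bregma",
                                    provenance = list(synthetic = TRUE,
                                                      seed = spec$seed))
    total_axon <- cable_length(neuron, "axon")
    analytic <- sum(truth_branch) + sum(truth_pass) + elsewhere
    if (abs(total_axon - analytic) > 1e-6 * max(1, total_axon))
      stop_pq(sprintf(
        "generator bookkeeping mismatch: built %.9f mm, accounted %.9f mm",
        total_axon, analytic), "projquant_spec_error")
    truth <- projection_profile(spec$neuron_id, truth_branch, truth_pass,
                                elsewhere_length = total_axon -
                                  sum(truth_branch) - sum(truth_pass),
                                total_axon_length = total_axon)
    list(neuron = neuron, truth = truth)
  })
}

# ---- cohorts -------------------------------------------------------------

#' Default cohort specification
#'
#' Study conditions for a two-class cohort: 6 wS2-projecting (S2p) and 9
#' wM1/2-projecting (M1p) neurons. Dendritic parameters and the wS1, wS2
#' and wM1/2 cable distributions use the reported group means and SDs;
#' occasional additional targets (striatum, TeA, PM, CM, PL1/2) are drawn
#' from zero-inflated truncated normals whose rates reflect how often
#' individual reconstructed neurons showed those projections.
#'
#' @param n_s2p,n_m1p group sizes.
#' @param seed cohort RNG seed.
#' @return object of class `synthetic_cohort_spec`.
#' @export
default_cohort_spec <- function(n_s2p = 6, n_m1p = 9, seed = 1L) {
  reg <- function(region, mean, sd, p_zero)
    data.frame(region = region, mean = mean, sd = sd, p_zero = p_zero)
  s2p <- list(
    dendrite = c(mean = 8.1, sd = 0.8), stems = c(mean = 8.3, sd = 1.6),
    branch_points = c(mean = 64, sd = 10),
    local_axon = c(mean = 41.7, sd = 1.1),
    regions = rbind(
      reg("wS2", 12.2, 7.4, 0),
      reg("wM1/2", 0, 0, 1),
      reg("Striatum", 12.5, 3.0, 5 / 6),
      reg("PM", 3.0, 2.0, 0.5),
      reg("PL2", 4.0, 2.0, 5 / 6)
    )
  )
  m1p <- list(
    dendrite = c(mean = 8.5, sd = 0.7), stems = c(mean = 8.0, sd = 1.4),
    branch_points = c(mean = 63, sd = 4),
    local_axon = c(mean = 40.0, sd = 3.8),
    regions = rbind(
      reg("wM1/2", 20.8, 11.7, 0),
      reg("wS2", 1.6, 2.7, 5 / 9),
      reg("Striatum", 16.9, 4.0, 8 / 9),
      reg("TeA", 7.7, 2.0, 8 / 9),
      reg("CM", 5.0, 3.0, 2 / 3),
      reg("PM", 5.0, 3.0, 2 / 3)
    )
  )
  structure(list(classes = list(S2p = list(n = n_s2p, params = s2p),
                                M1p = list(n = n_m1p, params = m1p)),
                 seed = as.integer(seed)),
            class = "synthetic_cohort_spec")
}

# zero-inflated truncated (at 0) normal draw; draws below `floor_mm` are
# treated as no projection
.rztnorm <- function(n, mean, sd, p_zero, floor_mm = 0.1) {
  mean <- rep_len(mean, n); sd <- rep_len(sd, n); p_zero <- rep_len(p_zero, n)
  out <- numeric(n)
  nz <- stats::runif(n) >= p_zero
  for (i in which(nz)) {
    x <- -1
    for (try in 1:100) {
      x <- stats::rnorm(1, mean[i], sd[i])
      if (x > 0) break
    }
    out[i] <- max(x, 0)
  }
  out[out < floor_mm] <- 0
  out
}

#' Generate a synthetic cohort with planted ground truth
#'
#' Draws per-neuron parameters from the class distributions of `spec`,
#' generates each neuron with [generate_neuron()], and returns the planted
#' ground truth: per-neuron profiles, the thresholded projection matrix of
#' the planted branching lengths, and the projection class implied by each
#' planted profile.
#'
#' @param spec a [default_cohort_spec()]-style object.
#' @param model a [region_model()].
#' @return list with `neurons` (list of `neuron_recon`), `truth` (list of
#'   planted [projection_profile()]), `labels` (class labels used for the
#'   draws), `planted_classes` (classification of the planted profiles),
#'   `planted_matrix` (a [threshold_matrix()] of the planted lengths) and
#'   `specs`.
#' @export
generate_cohort <- function(spec = default_cohort_spec(),
                            model = default_region_model()) {
  stopifnot(inherits(spec, "synthetic_cohort_spec"))
  model <- prepare_model(model)
  neurons <- list(); truth <- list(); labels <- character(0); specs <- list()
  with_seed(spec$seed, {
    idx <- 0L
    for (cls in names(spec$classes)) {
      cfg <- spec$classes[[cls]]
      for (i in seq_len(cfg$n)) {
        idx <- idx + 1L
        p <- cfg$params
        dend <- max(2, stats::rnorm(1, p$dendrite["mean"], p$dendrite["sd"]))
        stems <- max(3L, min(14L, as.integer(round(
          stats::rnorm(1, p$stems["mean"], p$stems["sd"])))))
        bps <- max(10L, as.integer(round(
          stats::rnorm(1, p$branch_points["mean"], p$branch_points["sd"]))))
        laxon <- max(10, stats::rnorm(1, p$local_axon["mean"],
                                      p$local_axon["sd"]))
        draws <- p$regions
        lens <- .rztnorm(nrow(draws), draws$mean, draws$sd, draws$p_zero)
        coll <- data.frame(region = draws$region, length_mm = lens,
                           include_branch = TRUE)
        coll <- coll[coll$length_mm > 0, , drop = FALSE]
        nspec <- synthetic_neuron_spec(
          neuron_id = sprintf("%s%03d", toupper(substr(cls, 1, 2)), idx),
          dendrite_length_mm = dend, n_stems = stems,
          n_dendrite_branch_points = bps, local_axon_mm = laxon,
          collaterals = coll,
          seed = sample.int(.Machine$integer.max, 1L))
        g <- generate_neuron(nspec, model)
        neurons[[idx]] <- g$neuron
        truth[[idx]] <- g$truth
        labels[idx] <- cls
        specs[[idx]] <- nspec
      }
    }
  })
  if (!length(neurons))
    return(list(neurons = list(), truth = list(), labels = character(0),
                planted_classes = character(0), planted_matrix = NULL,
                specs = list()))
  list(neurons = neurons, truth = truth, labels = labels,
       planted_classes = classify_projection_class(truth),
       planted_matrix = threshold_matrix(truth),
       specs = specs)
}

# ---- sectioning ----------------------------------------------------------

#' Cut a reconstruction into serial coronal sections
#'
#' Every edge is split analytically where it crosses a section plane
#' (multiples of `thickness` in dv), so the fragments' total cable equals
#' the original exactly. Each section receives an independent in-plane
#' (ml, ap) jitter drawn uniformly from `[-jitter, jitter]`, recorded in
#' the manifest so that stitching can invert it.
#'
#' @param n a `neuron_recon`.
#' @param thickness section thickness in mm (0.080 for single-cell
#'   material, 0.100 for viral material).
#' @param jitter in-plane misalignment amplitude in mm (default 0).
#' @param seed RNG seed for the jitter.
#' @return object of class `section_stack`: list with `sections` (each
#'   `index`, `nodes` (section-local coordinates), `shift`), `thickness`
#'   and `manifest` (data.frame `section_index`, `shift_ml_mm`,
#'   `shift_ap_mm`).
#' @export
split_into_sections <- function(n, thickness = 0.080, jitter = 0, seed = NULL) {
  stopifnot(inherits(n, "neuron_recon"), thickness > 0)
  nodes <- n$nodes
  # augmented node list: original nodes plus cut points inserted on edges
  pts <- as.matrix(nodes[, c("ml", "ap", "dv")])
  type <- nodes$type
  radius <- nodes$radius
  parent_row <- match(nodes$parent, nodes$id)      # NA for root
  new_pts <- list(); new_type <- integer(0); new_rad <- numeric(0)
  edges_from <- integer(0); edges_to <- integer(0)
  n_orig <- nrow(pts)
  next_row <- n_orig
  eps <- 1e-9
  for (ch in seq_len(n_orig)) {
    pr <- parent_row[ch]
    if (is.na(pr)) next
    dv0 <- pts[pr, 3]; dv1 <- pts[ch, 3]
    k0 <- ceiling(min(dv0, dv1) / thickness + eps)
    k1 <- floor(max(dv0, dv1) / thickness - eps)
    chain <- pr
    if (k1 >= k0 && abs(dv1 - dv0) > eps) {
      planes <- (k0:k1) * thickness
      tcut <- sort((planes - dv0) / (dv1 - dv0))
      tcut <- tcut[tcut > eps & tcut < 1 - eps]
      for (tc in tcut) {
        next_row <- next_row + 1L
        new_pts[[length(new_pts) + 1L]] <- pts[pr, ] + (pts[ch, ] - pts[pr, ]) * tc
        new_type <- c(new_type, type[ch])
        new_rad <- c(new_rad, radius[ch])
        chain <- c(chain, next_row)
      }
    }
    chain <- c(chain, ch)
    edges_from <- c(edges_from, chain[-length(chain)])
    edges_to <- c(edges_to, chain[-1])
  }
  if (length(new_pts)) {
    pts <- rbind(pts, do.call(rbind, new_pts))
    type <- c(type, new_type)
    radius <- c(radius, new_rad)
  }
  mid_dv <- (pts[edges_from, 3] + pts[edges_to, 3]) / 2
  sec_of_edge <- pmax(0L, as.integer(floor(mid_dv / thickness)))
  root_row <- which(is.na(parent_row))
  sec_ids <- sort(unique(c(sec_of_edge, floor(pts[root_row, 3] / thickness))))
  sec_ids <- seq(min(sec_ids), max(sec_ids))       # contiguous indices
  shifts <- if (jitter > 0) {
    with_seed(seed, matrix(stats::runif(2 * length(sec_ids), -jitter, jitter),
                           ncol = 2))
  } else matrix(0, length(sec_ids), 2)
  sections <- vector("list", length(sec_ids))
  next_id <- 0L
  for (si in seq_along(sec_ids)) {
    s <- sec_ids[si]
    es <- which(sec_of_edge == s)
    rows <- sort(unique(c(edges_from[es], edges_to[es])))
    if (s == floor(pts[root_row, 3] / thickness))
      rows <- sort(unique(c(rows, root_row)))
    if (!length(rows)) {
      sections[[si]] <- list(index = s,
                             nodes = data.frame(id = integer(0)),
                             shift = shifts[si, ])
      next
    }
    loc <- match(rows, rows)
    id_map <- next_id + seq_along(rows)
    next_id <- next_id + length(rows)
    # parent within this section: via an edge assigned to this section
    par_loc <- rep(-1L, length(rows))
    for (e in es) {
      ci <- match(edges_to[e], rows)
      pi <- match(edges_from[e], rows)
      par_loc[ci] <- id_map[pi]
    }
    sections[[si]] <- list(
      index = s,
      nodes = data.frame(
        id = id_map, type = type[rows],
        ml = pts[rows, 1] + shifts[si, 1],
        ap = pts[rows, 2] + shifts[si, 2],
        dv = pts[rows, 3] - s * thickness,
        radius = radius[rows],
        parent = par_loc
      ),
      shift = shifts[si, ]
    )
  }
  manifest <- data.frame(section_index = sec_ids,
                         shift_ml_mm = shifts[, 1],
                         shift_ap_mm = shifts[, 2])
  structure(list(sections = sections, thickness = thickness,
                 manifest = manifest, neuron_id = n$neuron_id),
            class = "section_stack")
}

#' @export
print.section_stack <- function(x, ...) {
  cat(sprintf("Section stack '%s': %d sections of %.0f um\n",
              x$neuron_id %||% "?", length(x$sections), x$thickness * 1e3))
  invisible(x)
}

# ---- bulk-labeling densities --------------------------------------------

#' Simulate multi-animal bulk-labeling density volumes
#'
#' For each animal and each region of the hotspot table, deposits an
#' isotropic Gaussian blob of cable mass at a center drawn from
#' `Normal(mean, SD)` per axis (the table's bregma-frame columns). The
#' drawn (planted) centers are returned for recovery tests. Mass is placed
#' in a thin dorso-ventral slab; per-pixel deposition uses the integrated
#' (pixel-averaged) Gaussian so the blob is symmetric about its center.
#'
#' @param n_animals number of simulated animals (default 5).
#' @param table hotspot table ([default_hotspot_table()] layout); columns
#'   `region`, `ml`, `ml_sd`, `ap`, `ap_sd` are used.
#' @param mass_mm cable mass per blob (recycled over regions).
#' @param blob_sigma SD of the blob itself in mm (default 0.05: a compact
#'   hotspot core).
#' @param voxel voxel size in mm.
#' @param margin grid margin beyond the extreme table centers in mm.
#' @param seed RNG seed.
#' @return list with `volumes` (list of [density_volume()]) and `centers`
#'   (list of per-animal data.frames `region`, `ml`, `ap`).
#' @export
generate_bulk_density <- function(n_animals = 5, table = default_hotspot_table(),
                                  mass_mm = 10, blob_sigma = 0.05,
                                  voxel = 0.05, margin = 1.0, seed = NULL) {
  stopifnot(n_animals >= 1)
  if (any(table$ml_sd < 0 | table$ap_sd < 0))
    stop_pq("SDs must be non-negative", "projquant_spec_error")
  mass_mm <- rep_len(mass_mm, nrow(table))
  ml_rng <- range(table$ml) + c(-margin, margin)
  ap_rng <- range(table$ap) + c(-margin, margin)
  origin <- c(ml_rng[1], ap_rng[1], 0)
  dims <- c(ceiling(diff(ml_rng) / voxel), ceiling(diff(ap_rng) / voxel), 2L)
  xs <- origin[1] + (0:dims[1]) * voxel           # pixel edges
  ys <- origin[2] + (0:dims[2]) * voxel
  with_seed(seed, {
    volumes <- vector("list", n_animals)
    centers <- vector("list", n_animals)
    for (a in seq_len(n_animals)) {
      vals <- array(0, dims)
      cml <- stats::rnorm(nrow(table), table$ml, table$ml_sd)
      cap <- stats::rnorm(nrow(table), table$ap, table$ap_sd)
      for (i in seq_len(nrow(table))) {
        if (mass_mm[i] <= 0) next
        px <- diff(stats::pnorm(xs, cml[i], blob_sigma))
        py <- diff(stats::pnorm(ys, cap[i], blob_sigma))
        vals[, , 1] <- vals[, , 1] + mass_mm[i] * outer(px, py)
      }
      volumes[[a]] <- density_volume(vals, origin, voxel)
      centers[[a]] <- data.frame(region = table$region, ml = cml, ap = cap)
    }
    list(volumes = volumes, centers = centers)
  })
}
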