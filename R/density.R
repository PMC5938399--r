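# Voxelized axon-density volumes and hotspot-center estimation. A density
# volume is a computational stand-in for bulk-labeling fluorescence: a 3D
# grid holding cable length (mm) per voxel in the bregma frame.

#' Construct a density volume
#'
#' @param values 3D numeric array, dimensions (ml, ap, dv), cable mm per
#'   voxel.
#' @param origin numeric `c(ml, ap, dv)`: the low corner of voxel
#'   `[1, 1, 1]` in bregma-frame mm.
#' @param voxel isotropic voxel edge length in mm.
#' @return object of class `density_volume`.
#' @export
density_volume <- function(values, origin, voxel = 0.05) {
  stopifnot(length(dim(values)) == 3L, length(origin) == 3L, voxel > 0)
  if (any(values < 0))
    stop_pq("density values must be non-negative", "projquant_argument_error")
  structure(list(values = values, origin = as.numeric(origin), voxel = voxel),
            class = "density_volume")
}

#' @export
print.density_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "Density volume %dx%dx%d voxels (%.3g mm), origin (%.2f, %.2f, %.2f), total %.3g mm cable\n",
    d[1], d[2], d[3], x$voxel, x$origin[1], x$origin[2], x$origin[3],
    sum(x$values)))
  invisible(x)
}

#' Voxelize axonal cable into a density volume
#'
#' Each edge's length is distributed over the voxels it traverses by
#' analytic clipping of the segment against the voxel grid planes, so the
#' volume total equals the voxelized cable length exactly (up to floating
#' point). Cable outside the grid accrues to an out-of-bounds counter
#' (attribute `oob_mm`) with a warning.
#'
#' @param x a `neuron_recon` (bregma frame) or an n x 3 matrix of polyline
#'   points; lists of either are concatenated as independent polylines.
#' @param origin low corner `c(ml, ap, dv)` of the grid in mm.
#' @param dim integer `c(n_ml, n_ap, n_dv)` voxel counts.
#' @param voxel voxel edge length in mm (default 0.05).
#' @param compartment compartment to voxelize when `x` is a reconstruction
#'   (default `"axon"`).
#' @return a [density_volume()].
#' @export
voxelize <- function(x, origin, dim, voxel = 0.05, compartment = "axon") {
  segs <- .as_segments(x, compartment)
  vals <- array(0, dim = dim)
  oob <- 0
  p0 <- segs$p0; p1 <- segs$p1
  n_edges <- nrow(p0)
  hi <- origin + dim * voxel
  for (e in seq_len(n_edges)) {
    a <- p0[e, ]; b <- p1[e, ]
    len <- sqrt(sum((b - a)^2))
    if (len == 0) next
    ts <- c(0, 1)
    for (ax in 1:3) {
      d <- b[ax] - a[ax]
      if (abs(d) < 1e-15) next
      lo_k <- ceiling((min(a[ax], b[ax]) - origin[ax]) / voxel)
      hi_k <- floor((max(a[ax], b[ax]) - origin[ax]) / voxel)
      if (hi_k >= lo_k) {
        planes <- origin[ax] + (lo_k:hi_k) * voxel
        ts <- c(ts, (planes - a[ax]) / d)
      }
    }
    ts <- sort(unique(pmin(1, pmax(0, ts))))
    t0 <- ts[-length(ts)]; t1 <- ts[-1]
    tm <- (t0 + t1) / 2
    mids <- cbind(a[1] + (b[1] - a[1]) * tm,
                  a[2] + (b[2] - a[2]) * tm,
                  a[3] + (b[3] - a[3]) * tm)
    idx <- floor(sweep(mids, 2, origin) / voxel) + 1
    piece_len <- (t1 - t0) * len
    inside <- idx[, 1] >= 1 & idx[, 1] <= dim[1] &
              idx[, 2] >= 1 & idx[, 2] <= dim[2] &
              idx[, 3] >= 1 & idx[, 3] <= dim[3]
    oob <- oob + sum(piece_len[!inside])
    if (any(inside)) {
      flat <- (idx[inside, 3] - 1) * dim[1] * dim[2] +
              (idx[inside, 2] - 1) * dim[1] + idx[inside, 1]
      for (j in seq_along(flat)) vals[flat[j]] <- vals[flat[j]] + piece_len[inside][j]
    }
  }
  if (oob > 0)
    warning(sprintf("%.3g mm of cable fell outside the grid", oob))
  v <- density_volume(vals, origin, voxel)
  attr(v, "oob_mm") <- oob
  v
}

.as_segments <- function(x, compartment) {
  if (inherits(x, "neuron_recon")) {
    et <- edge_table(x)
    et <- et[.types_match(et$type, compartment), , drop = FALSE]
    return(list(p0 = as.matrix(et[, c("ml0", "ap0", "dv0")]),
                p1 = as.matrix(et[, c("ml1", "ap1", "dv1")])))
  }
  if (is.matrix(x) || is.data.frame(x)) {
    m <- as.matrix(x)
    return(list(p0 = m[-nrow(m), , drop = FALSE], p1 = m[-1, , drop = FALSE]))
  }
  if (is.list(x)) {
    parts <- lapply(x, .as_segments, compartment = compartment)
    return(list(p0 = do.call(rbind, lapply(parts, `[[`, "p0")),
                p1 = do.call(rbind, lapply(parts, `[[`, "p1"))))
  }
  stop_pq("cannot interpret input as polylines", "projquant_argument_error")
}

#' Project a density volume to 2D
#'
#' Coronal projections collapse the antero-posterior axis (result ml x dv);
#' horizontal projections collapse depth (result ml x ap). Mass is
#' conserved.
#'
#' @param v a [density_volume()].
#' @param plane `"coronal"` or `"horizontal"`.
#' @return matrix of class `density_map` with attributes `origin`, `voxel`,
#'   `axes`.
#' @export
project2d <- function(v, plane = c("horizontal", "coronal")) {
  stopifnot(inherits(v, "density_volume"))
  plane <- match.arg(plane)
  if (plane == "horizontal") {
    m <- apply(v$values, c(1, 2), sum)
    axes <- c("ml", "ap"); origin <- v$origin[c(1, 2)]
  } else {
    m <- apply(v$values, c(1, 3), sum)
    axes <- c("ml", "dv"); origin <- v$origin[c(1, 3)]
  }
  structure(m, origin = origin, voxel = v$voxel, axes = axes,
            class = c("density_map", "matrix"))
}

#' @export
plot.density_map <- function(x, main = NULL, ...) {
  ax <- attr(x, "axes"); o <- attr(x, "origin"); vx <- attr(x, "voxel")
  xs <- o[1] + (seq_len(nrow(x)) - 0.5) * vx
  ys <- o[2] + (seq_len(ncol(x)) - 0.5) * vx
  graphics::image(xs, ys, unclass(x), xlab = paste0(ax[1], " (mm)"),
                  ylab = paste0(ax[2], " (mm)"),
                  main = main %||% "axon density",
                  col = grDevices::hcl.colors(64, "inferno", rev = TRUE), ...)
  invisible(x)
}

# separable Gaussian smoothing of a matrix, sigma in pixels, zero padding
.smooth2d <- function(m, sigma_px) {
  if (sigma_px <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma_px))
  k <- stats::dnorm(-r:r, sd = sigma_px)
  k <- k / sum(k)
  pass <- function(mm) {            # smooth along rows (first index)
    out <- matrix(0, nrow(mm), ncol(mm))
    for (o in -r:r) {
      w <- k[o + r + 1]
      src_rows <- seq_len(nrow(mm)) - o
      ok <- src_rows >= 1 & src_rows <= nrow(mm)
      out[ok, ] <- out[ok, ] + w * mm[src_rows[ok], ]
    }
    out
  }
  t(pass(t(pass(m))))
}

# 8-connected component of 'keep' pixels containing (i0, j0)
.connected_component <- function(keep, i0, j0) {
  comp <- matrix(FALSE, nrow(keep), ncol(keep))
  queue <- matrix(c(i0, j0), ncol = 2)
  comp[i0, j0] <- TRUE
  while (nrow(queue)) {
    cur <- queue[1, , drop = FALSE]; queue <- queue[-1, , drop = FALSE]
    for (di in -1:1) for (dj in -1:1) {
      i <- cur[1] + di; j <- cur[2] + dj
      if (i >= 1 && i <= nrow(keep) && j >= 1 && j <= ncol(keep) &&
          keep[i, j] && !comp[i, j]) {
        comp[i, j] <- TRUE
        queue <- rbind(queue, c(i, j))
      }
    }
  }
  comp
}

#' Estimate the center of an axon-density hotspot
#'
#' Collapses depth (horizontal projection), smooths with an isotropic
#' Gaussian, restricts to the search window, and returns the
#' density-weighted centroid of the pixels at or above `support` times the
#' window peak. With `connected = TRUE` the support set is restricted to
#' the 8-connected pixel component containing the peak, which separates a
#' hotspot from near neighbours whose tails enter the window; with the
#' default `connected = FALSE` two equal blobs inside one window yield the
#' midway centroid (narrow the window to separate them).
#'
#' @param v a [density_volume()] or a horizontal `density_map`.
#' @param window numeric `c(ml_min, ml_max, ap_min, ap_max)` in mm.
#' @param sigma Gaussian smoothing SD in mm (default 0.1).
#' @param support support threshold as a fraction of the window peak
#'   (default 0.5).
#' @param connected restrict the support set to the peak's connected
#'   component.
#' @return numeric `c(ml, ap)` of the estimated center in mm.
#' @export
find_hotspot_center <- function(v, window, sigma = 0.1, support = 0.5,
                                connected = FALSE) {
  m <- if (inherits(v, "density_volume")) project2d(v, "horizontal") else v
  o <- attr(m, "origin"); vx <- attr(m, "voxel")
  sm <- .smooth2d(unclass(m), sigma / vx)
  xs <- o[1] + (seq_len(nrow(sm)) - 0.5) * vx
  ys <- o[2] + (seq_len(ncol(sm)) - 0.5) * vx
  ii <- which(xs >= window[1] & xs <= window[2])
  jj <- which(ys >= window[3] & ys <= window[4])
  if (!length(ii) || !length(jj))
    stop_pq("search window does not overlap the grid", "projquant_argument_error")
  w <- sm[ii, jj, drop = FALSE]
  if (sum(w) <= 0)
    stop_pq("no signal in the search window", "projquant_no_signal")
  peak <- which(w == max(w), arr.ind = TRUE)[1, ]
  keep <- w >= support * max(w)
  if (connected) keep <- .connected_component(keep, peak[1], peak[2])
  wt <- w * keep
  c(ml = sum(outer(xs[ii], rep(1, length(jj))) * wt) / sum(wt),
    ap = sum(outer(rep(1, length(ii)), ys[jj]) * wt) / sum(wt))
}

# Second-pass center estimate on a pre-smoothed map: density-weighted
# centroid of the pixels >= support * (window peak) that are 8-connected to
# the peak AND nearer to the chosen local maximum than to any other local
# maximum found in the first pass. The nearest-maximum restriction keeps
# the support from bleeding across the saddle toward a close neighbouring
# hotspot, which would otherwise bias the centroid systematically.
.refined_center <- function(sm, xs, ys, win, support, lm_ml, lm_ap, pick) {
  ii <- which(xs >= win[1] & xs <= win[2])
  jj <- which(ys >= win[3] & ys <= win[4])
  w <- sm[ii, jj, drop = FALSE]
  if (sum(w) <= 0) return(c(NA_real_, NA_real_))
  peak <- which(w == max(w), arr.ind = TRUE)[1, ]
  keep <- w >= support * max(w)
  keep <- .connected_component(keep, peak[1], peak[2])
  if (length(lm_ml) > 1L) {
    px <- outer(xs[ii], rep(1, length(jj)))
    py <- outer(rep(1, length(ii)), ys[jj])
    d_pick <- (px - lm_ml[pick])^2 + (py - lm_ap[pick])^2
    d_other <- Reduce(pmin, lapply(seq_along(lm_ml)[-pick], function(k)
      (px - lm_ml[k])^2 + (py - lm_ap[k])^2))
    keep <- keep & d_pick <= d_other
  }
  wt <- w * keep
  if (sum(wt) <= 0) return(c(NA_real_, NA_real_))
  c(sum(outer(xs[ii], rep(1, length(jj))) * wt) / sum(wt),
    sum(outer(rep(1, length(ii)), ys[jj]) * wt) / sum(wt))
}

# all local maxima (8-neighbourhood, strictly positive) of a matrix subset
.local_maxima <- function(w) {
  n <- nrow(w); m <- ncol(w)
  if (n == 0 || m == 0) return(matrix(integer(0), ncol = 2))
  pad <- matrix(-Inf, n + 2, m + 2)
  pad[2:(n + 1), 2:(m + 1)] <- w
  best <- matrix(-Inf, n, m)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    best <- pmax(best, pad[(2:(n + 1)) + di, (2:(m + 1)) + dj])
  }
  which(w > 0 & w >= best, arr.ind = TRUE)
}

#' Aggregate hotspot centers across animals
#'
#' For each region of the model and each animal: smooth the horizontal
#' density map, search a window around the region's nominal center for the
#' local maximum nearest that center, then re-estimate the center with
#' [find_hotspot_center()] in a tight window around that maximum
#' (`connected = TRUE`). Per region the centers are averaged across animals
#' (mean and sample SD) and reported in both the bregma and the
#' injection-site frame; because averaging is linear the two frames' means
#' differ exactly by the injection-site coordinates.
#'
#' @param volumes list of [density_volume()], one per animal.
#' @param model a [region_model()]; its injection site anchors the
#'   offset frame.
#' @param sigma smoothing SD in mm.
#' @param support support threshold for the centroid.
#' @param search_pad widening (mm) of the region box for the first-pass
#'   local-maximum search.
#' @param refine_half half-width (mm) of the second-pass window around the
#'   located maximum.
#' @param seeds optional data.frame (`region`, `ml`, `ap`) of nominal
#'   hotspot locations used to seed the local-maximum search; defaults to
#'   the region centers of `model`. Useful when a region's geometric box
#'   center is not where its density peak is expected. Optional `ml_sd`,
#'   `ap_sd` columns widen the per-region search window to cover the
#'   expected across-animal scatter (3 SD beyond the region box).
#' @return data.frame of class `hotspot_table`: `region`, `n_animals`,
#'   `ml`, `ml_sd`, `ap`, `ap_sd` (bregma frame), `off_ml`, `off_ml_sd`,
#'   `off_ap`, `off_ap_sd` (injection frame). Per-animal centers are in
#'   attribute `centers`. Regions without signal in any animal are omitted
#'   with a warning.
#' @export
aggregate_centers <- function(volumes, model, sigma = 0.1, support = 0.5,
                              search_pad = 0.2, refine_half = 0.18,
                              seeds = NULL) {
  if (!length(volumes))
    stop_pq("need at least one animal", "projquant_argument_error")
  site <- model$injection_site
  maps <- lapply(volumes, project2d, plane = "horizontal")
  regs <- model$regions
  n_reg <- nrow(regs)
  seed_pos <- cbind(regs$center_ml, regs$center_ap)
  win_half <- cbind(regs$half_ml + search_pad, regs$half_ap + search_pad)
  # per-axis scatter scale of each seed: used to score seed-to-maximum
  # matches in Mahalanobis units (the MAP matching under a Gaussian
  # scatter model); defaults to an isotropic 0.1 mm scale
  seed_scale <- matrix(0.1, n_reg, 2)
  if (!is.null(seeds)) {
    hit <- match(regs$name, seeds$region)
    ok <- !is.na(hit)
    seed_pos[ok, 1] <- seeds$ml[hit[ok]]
    seed_pos[ok, 2] <- seeds$ap[hit[ok]]
    if (all(c("ml_sd", "ap_sd") %in% names(seeds))) {
      seed_scale[ok, 1] <- pmax(seeds$ml_sd[hit[ok]], 0.05)
      seed_scale[ok, 2] <- pmax(seeds$ap_sd[hit[ok]], 0.05)
      win_half[ok, 1] <- pmax(win_half[ok, 1],
                              regs$half_ml[ok] + 3 * seeds$ml_sd[hit[ok]])
      win_half[ok, 2] <- pmax(win_half[ok, 2],
                              regs$half_ap[ok] + 3 * seeds$ap_sd[hit[ok]])
    }
  }

  per_animal <- array(NA_real_, c(length(volumes), n_reg, 2))
  for (a in seq_along(maps)) {
    m <- maps[[a]]
    o <- attr(m, "origin"); vx <- attr(m, "voxel")
    sm <- .smooth2d(unclass(m), sigma / vx)
    xs <- o[1] + (seq_len(nrow(sm)) - 0.5) * vx
    ys <- o[2] + (seq_len(ncol(sm)) - 0.5) * vx
    lm <- .local_maxima(sm)
    if (!nrow(lm)) next
    # discard numerically tiny ripples
    hts <- sm[lm]
    lm <- lm[hts > 1e-6 * max(hts), , drop = FALSE]
    lm_ml <- xs[lm[, 1]]; lm_ap <- ys[lm[, 2]]
    # one-to-one assignment of region seeds to maxima, feasible within each
    # region's search window, minimizing the total squared Mahalanobis
    # distance under the seeds' scatter scales
    cost <- outer(seq_len(n_reg), seq_along(lm_ml), function(i, k)
      ((seed_pos[i, 1] - lm_ml[k]) / seed_scale[i, 1])^2 +
      ((seed_pos[i, 2] - lm_ap[k]) / seed_scale[i, 2])^2)
    feas <- outer(seq_len(n_reg), seq_along(lm_ml), function(i, k)
      abs(seed_pos[i, 1] - lm_ml[k]) <= win_half[i, 1] &
      abs(seed_pos[i, 2] - lm_ap[k]) <= win_half[i, 2])
    cost[!feas] <- Inf
    assign <- .assign_seeds(cost)
    # a seed without its own maximum (its hotspot merged into a
    # neighbour's at this resolution) falls back to the most plausible
    # shared maximum, provided the match is within ~5 combined SDs;
    # regions with genuinely no signal stay unassigned
    for (i in which(is.na(assign))) {
      if (any(is.finite(cost[i, ])) && min(cost[i, ]) <= 25)
        assign[i] <- which.min(cost[i, ])
    }
    for (i in which(!is.na(assign))) {
      pick <- assign[i]
      win2 <- c(lm_ml[pick] - refine_half, lm_ml[pick] + refine_half,
                lm_ap[pick] - refine_half, lm_ap[pick] + refine_half)
      per_animal[a, i, ] <- .refined_center(sm, xs, ys, win2, support,
                                            lm_ml, lm_ap, pick)
    }
  }

  rows <- list(); centers_attr <- list()
  for (i in seq_len(n_reg)) {
    ok <- !is.na(per_animal[, i, 1])
    if (!any(ok)) {
      warning(sprintf("region '%s': no signal in any animal; omitted",
                      regs$name[i]))
      next
    }
    pa <- per_animal[ok, i, , drop = FALSE]
    dim(pa) <- c(sum(ok), 2)
    n_a <- nrow(pa)
    sds <- if (n_a >= 2) apply(pa, 2, stats::sd) else c(NA_real_, NA_real_)
    rows[[length(rows) + 1L]] <- data.frame(
      region = regs$name[i], n_animals = n_a,
      ml = mean(pa[, 1]), ml_sd = sds[1],
      ap = mean(pa[, 2]), ap_sd = sds[2],
      off_ml = mean(pa[, 1]) - site$ml, off_ml_sd = sds[1],
      off_ap = mean(pa[, 2]) - site$ap, off_ap_sd = sds[2]
    )
    centers_attr[[regs$name[i]]] <- pa
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "centers") <- centers_attr
  class(out) <- c("hotspot_table", "data.frame")
  out
}

# One-to-one assignment of rows (seeds) to columns (maxima) minimizing the
# total cost, with a large fixed penalty for leaving a row unassigned so
# that every seed claims a maximum whenever feasible. Infeasible pairs
# carry Inf cost. Greedy seeding followed by local-improvement passes
# (relocation, eviction, pairwise swap); problems here are tiny (a dozen
# seeds, a few dozen maxima), and near-separable, so this reaches the
# optimum in practice.
.assign_seeds <- function(cost, penalty = 1e3) {
  n <- nrow(cost); m <- ncol(cost)
  assign <- rep(NA_integer_, n)
  used <- logical(m)
  ord <- order(apply(cost, 1, min))
  for (i in ord) {
    cands <- which(!used & is.finite(cost[i, ]))
    if (!length(cands)) next
    k <- cands[which.min(cost[i, cands])]
    assign[i] <- k; used[k] <- TRUE
  }
  rowcost <- function(i) if (is.na(assign[i])) penalty else cost[i, assign[i]]
  improved <- TRUE
  guard <- 0L
  while (improved && guard < 100L) {
    improved <- FALSE; guard <- guard + 1L
    # relocation: any row to its best free feasible column
    for (i in seq_len(n)) {
      free <- which(!used & is.finite(cost[i, ]))
      if (!length(free)) next
      k <- free[which.min(cost[i, free])]
      if (cost[i, k] < rowcost(i) - 1e-15) {
        if (!is.na(assign[i])) used[assign[i]] <- FALSE
        assign[i] <- k; used[k] <- TRUE
        improved <- TRUE
      }
    }
    # eviction: an unassigned row takes an occupied column whose holder can
    # relocate (to a free column or to unassigned) at lower total cost
    for (j in which(is.na(assign))) {
      best_delta <- -1e-15; best <- NULL
      for (k in which(is.finite(cost[j, ]) & used)) {
        i <- which(assign == k)
        free_i <- which(!used & is.finite(cost[i, ]))
        relo <- if (length(free_i)) min(cost[i, free_i]) else penalty
        delta <- (cost[j, k] - penalty) + (relo - cost[i, k])
        if (delta < best_delta) {
          best_delta <- delta
          best <- list(i = i, k = k,
                       k2 = if (length(free_i))
                         free_i[which.min(cost[i, free_i])] else NA_integer_)
        }
      }
      if (!is.null(best)) {
        assign[j] <- best$k
        assign[best$i] <- best$k2
        if (!is.na(best$k2)) used[best$k2] <- TRUE
        improved <- TRUE
      }
    }
    # pairwise swap
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i >= j) next
      ki <- assign[i]; kj <- assign[j]
      if (is.na(ki) && is.na(kj)) next
      c_cur <- rowcost(i) + rowcost(j)
      c_i_kj <- if (is.na(kj)) penalty else cost[i, kj]
      c_j_ki <- if (is.na(ki)) penalty else cost[j, ki]
      if (is.finite(c_i_kj + c_j_ki) && c_i_kj + c_j_ki < c_cur - 1e-15) {
        assign[i] <- kj; assign[j] <- ki
        improved <- TRUE
      }
    }
  }
  assign
}

#' Write / read a density volume as plain text
#'
#' Dense-array container: a CSV of nonzero voxels (`i`, `j`, `k`, `value`)
#' plus a JSON sidecar holding `origin_mm`, `voxel_mm` and `dim`.
#'
#' @param v a [density_volume()].
#' @param path CSV path; the sidecar is written next to it as
#'   `<path>.json`.
#' @return the path, invisibly.
#' @export
write_density <- function(v, path) {
  nz <- which(v$values != 0, arr.ind = TRUE)
  df <- data.frame(i = nz[, 1], j = nz[, 2], k = nz[, 3],
                   value = v$values[nz])
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(
    list(origin_mm = v$origin, voxel_mm = v$voxel, dim = dim(v$values),
         axes_order = c("ml", "ap", "dv")),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_density
#' @export
read_density <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  df <- utils::read.csv(path)
  vals <- array(0, dim = meta$dim)
  vals[cbind(df$i, df$j, df$k)] <- df$value
  density_volume(vals, meta$origin_mm, meta$voxel_mm)
}
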