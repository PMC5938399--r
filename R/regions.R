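# Bregma-referenced region model. Projection targets are modelled as named
# axis-aligned domains: cortical columns spanning the full cortical depth and
# a subcortical box for the dorsolateral striatum. The model only fixes the
# hotspot centers; the extents are configuration, because the underlying
# data constrain the centers of the projection zones much better than their
# boundaries. Overlaps are resolved by priority (lower number wins), with
# wS1 given the lowest priority among cortical regions so that the
# dysgranular subregions win where they abut the barrel field.

#' Reference table of projection-hotspot centers
#'
#' Mean and SD (mm) of the centers of the long-range axonal projection
#' hotspots of wS1 layer 2/3 neurons, in two frames: offsets relative to the
#' wS1 injection site (C2 barrel column, left hemisphere) and absolute
#' bregma-referenced coordinates. ml is negative on the left hemisphere; ap
#' is positive anterior to Bregma. Estimated across 5 mice.
#'
#' @return data.frame with columns `region`, `off_ml`, `off_ml_sd`,
#'   `off_ap`, `off_ap_sd`, `ml`, `ml_sd`, `ap`, `ap_sd`.
#' @export
default_hotspot_table <- function() {
  data.frame(
    region    = c("wS1", "wS2", "wM1/2", "PL1", "PL2", "AM", "CM", "PM",
                  "PP", "TeA", "Striatum"),
    off_ml    = c(0, -0.82, 2.21, -1.12, -0.66, 0.48, 0.70, 0.51, -0.49, -1.43, 0.18),
    off_ml_sd = c(0, 0.06, 0.12, 0.06, 0.07, 0.09, 0.10, 0.06, 0.04, 0.04, 0.14),
    off_ap    = c(0, 0.02, 2.70, -0.36, -0.36, 0.93, 0.19, -0.38, -1.49, -0.36, 0.29),
    off_ap_sd = c(0, 0.05, 0.09, 0.00, 0.00, 0.31, 0.14, 0.05, 0.22, 0.00, 0.07),
    ml        = c(-3.02, -3.83, -0.81, -4.13, -3.67, -2.54, -2.32, -2.51,
                  -3.51, -4.45, -2.83),
    ml_sd     = c(0.06, 0.06, 0.09, 0.09, 0.08, 0.05, 0.09, 0.10, 0.03, 0.06, 0.12),
    ap        = c(-1.65, -1.63, 1.04, -2.01, -2.01, -0.72, -1.46, -2.04,
                  -3.14, -2.01, -1.36),
    ap_sd     = c(0.07, 0.11, 0.09, 0.07, 0.07, 0.35, 0.12, 0.05, 0.25, 0.07, 0.10)
  )
}

#' Injection site
#'
#' @param ml,ap bregma-frame coordinates of the tracer injection site in mm.
#'   Defaults are the left wS1 C2 barrel column.
#' @return object of class `injection_site`.
#' @export
injection_site <- function(ml = -3.02, ap = -1.65) {
  stopifnot(is.finite(ml), is.finite(ap))
  structure(list(ml = ml, ap = ap), class = "injection_site")
}

#' Construct a region model
#'
#' @param regions data.frame with columns `name`, `shape`
#'   (`"cortical_column"` or `"box"`), `center_ml`, `center_ap`, `half_ml`,
#'   `half_ap`, `dv_min`, `dv_max` (mm, bregma frame) and `priority`
#'   (integer; lower wins where regions overlap).
#' @param site an [injection_site()].
#' @return object of class `region_model`.
#' @export
region_model <- function(regions, site = injection_site()) {
  req <- c("name", "shape", "center_ml", "center_ap", "half_ml", "half_ap",
           "dv_min", "dv_max", "priority")
  missing_cols <- setdiff(req, names(regions))
  if (length(missing_cols))
    stop_pq(paste("regions is missing columns:", paste(missing_cols, collapse = ", ")),
            "projquant_argument_error")
  if (anyDuplicated(regions$name))
    stop_pq("region names must be unique", "projquant_argument_error")
  if ("elsewhere" %in% regions$name)
    stop_pq("'elsewhere' is a reserved region name", "projquant_argument_error")
  if (!all(regions$shape %in% c("cortical_column", "box")))
    stop_pq("shape must be 'cortical_column' or 'box'", "projquant_argument_error")
  if (any(regions$half_ml <= 0 | regions$half_ap <= 0))
    stop_pq("half extents must be positive", "projquant_argument_error")
  if (any(regions$dv_min >= regions$dv_max))
    stop_pq("dv_min must be smaller than dv_max", "projquant_argument_error")
  regions <- regions[order(regions$priority), , drop = FALSE]
  rownames(regions) <- NULL
  structure(list(regions = regions, injection_site = site),
            class = "region_model")
}

#' Default region model
#'
#' Axis-aligned domains centered on the reference hotspot centers
#' ([default_hotspot_table()]). Cortical columns span the full cortical
#' depth (`dv` 0 to `cortical_depth`); default in-plane half-extents are
#' 0.4 mm, except wS1 which is sized to the barrel field (1.0 x 1.0 mm),
#' wM1/2 which is elongated antero-posteriorly (half-extent 0.85 mm) and TeA
#' (half-extent 0.35 mm). The striatum is a subcortical box (dv 1.5-3.5 mm)
#' spanning ap 0.30-1.70 mm posterior to Bregma. All extents are meant to be
#' overridden where better boundary information is available.
#'
#' @param half_default default in-plane half-extent (mm) of a cortical column.
#' @param cortical_depth depth of the cortical columns (mm from the pia).
#' @param site an [injection_site()].
#' @return a [region_model()].
#' @export
default_region_model <- function(half_default = 0.4, cortical_depth = 2.0,
                                 site = injection_site()) {
  tab <- default_hotspot_table()
  regions <- data.frame(
    name = tab$region,
    shape = ifelse(tab$region == "Striatum", "box", "cortical_column"),
    center_ml = tab$ml, center_ap = tab$ap,
    half_ml = half_default, half_ap = half_default,
    dv_min = 0, dv_max = cortical_depth,
    priority = NA_integer_
  )
  rownames(regions) <- regions$name
  regions["wS1", c("half_ml", "half_ap")] <- c(1.0, 1.0)
  regions["wM1/2", "half_ap"] <- 0.85
  regions["TeA", "half_ap"] <- 0.35
  regions["Striatum", c("center_ap", "half_ap")] <- c(-1.0, 0.7)
  regions["Striatum", c("dv_min", "dv_max")] <- c(1.5, 3.5)
  # Specific targets win over wS1 (the dysgranular subregions abut the
  # barrel field); the striatum is depth-separated but still beats wS1.
  regions$priority <- seq_len(nrow(regions)) + 1L
  regions["wS1", "priority"] <- 99L
  rownames(regions) <- NULL
  region_model(regions, site)
}

#' Convert injection-site offsets to bregma coordinates
#'
#' The two frames are related by a rigid translation:
#' `bregma = injection_site + offset`.
#'
#' @param p numeric vector `c(ml, ap)` or a 2-column matrix/data.frame of
#'   (ml, ap) offsets in mm relative to the injection site.
#' @param site an [injection_site()].
#' @return same shape as `p`, in bregma-frame mm.
#' @export
injection_to_bregma <- function(p, site = injection_site()) {
  if (is.data.frame(p)) p <- as.matrix(p)
  if (is.matrix(p)) {
    p[, 1] <- p[, 1] + site$ml
    p[, 2] <- p[, 2] + site$ap
    p
  } else {
    stopifnot(length(p) == 2L)
    c(ml = unname(p[1]) + site$ml, ap = unname(p[2]) + site$ap)
  }
}

#' @rdname injection_to_bregma
#' @export
bregma_to_injection <- function(p, site = injection_site()) {
  if (is.data.frame(p)) p <- as.matrix(p)
  if (is.matrix(p)) {
    p[, 1] <- p[, 1] - site$ml
    p[, 2] <- p[, 2] - site$ap
    p
  } else {
    stopifnot(length(p) == 2L)
    c(ml = unname(p[1]) - site$ml, ap = unname(p[2]) - site$ap)
  }
}

# logical vector: which points fall inside region r (row of model$regions)
.region_contains <- function(r, ml, ap, dv) {
  ml >= r$center_ml - r$half_ml & ml <= r$center_ml + r$half_ml &
  ap >= r$center_ap - r$half_ap & ap <= r$center_ap + r$half_ap &
  dv >= r$dv_min & dv <= r$dv_max
}

#' Assign points to regions
#'
#' Returns, for each point, the name of the highest-priority region whose
#' domain contains it, or `"elsewhere"` if none does.
#'
#' @param p numeric vector `c(ml, ap, dv)` or an n x 3 matrix/data.frame of
#'   bregma-frame coordinates in mm.
#' @param model a [region_model()].
#' @param frame frame tag of the points; must be `"bregma"`.
#' @return character vector of region names.
#' @export
locate_point <- function(p, model, frame = "bregma") {
  if (!identical(frame, "bregma"))
    stop_pq("points must be in the bregma frame", "projquant_frame_error")
  if (is.null(dim(p))) p <- matrix(p, ncol = 3, byrow = TRUE)
  p <- as.matrix(p)
  out <- rep("elsewhere", nrow(p))
  todo <- rep(TRUE, nrow(p))
  regs <- model$regions
  for (i in seq_len(nrow(regs))) {          # already sorted by priority
    if (!any(todo)) break
    r <- regs[i, ]
    hit <- todo & .region_contains(r, p[, 1], p[, 2], p[, 3])
    out[hit] <- r$name
    todo <- todo & !hit
  }
  out
}

# Parametric interval [t0, t1] (clipped to [0,1]) where segment p0->p1 lies
# inside the axis-aligned domain of region r; c(NA, NA) if empty.
# Vectorized over edges: p0, p1 are n x 3 matrices. Returns n x 2 matrix.
.slab_interval <- function(r, p0, p1) {
  lo <- c(r$center_ml - r$half_ml, r$center_ap - r$half_ap, r$dv_min)
  hi <- c(r$center_ml + r$half_ml, r$center_ap + r$half_ap, r$dv_max)
  t0 <- rep(0, nrow(p0)); t1 <- rep(1, nrow(p0))
  for (a in 1:3) {
    d <- p1[, a] - p0[, a]
    par <- abs(d) < 1e-15
    inside_par <- p0[, a] >= lo[a] & p0[, a] <= hi[a]
    ta <- (lo[a] - p0[, a]) / d
    tb <- (hi[a] - p0[, a]) / d
    tmin <- pmin(ta, tb); tmax <- pmax(ta, tb)
    tmin[par] <- ifelse(inside_par[par], -Inf, Inf)
    tmax[par] <- ifelse(inside_par[par], Inf, -Inf)
    t0 <- pmax(t0, tmin); t1 <- pmin(t1, tmax)
  }
  empty <- t0 > t1
  t0[empty] <- NA_real_; t1[empty] <- NA_real_
  cbind(t0, t1)
}

# Split every edge at region boundary crossings and label each piece with
# the region owning its midpoint. p0, p1: n x 3 matrices (bregma mm).
# Returns data.frame(edge, region, length, t0, t1).
.clip_edges <- function(p0, p1, model) {
  n_edges <- nrow(p0)
  if (n_edges == 0L)
    return(data.frame(edge = integer(), region = character(),
                      length = numeric(), t0 = numeric(), t1 = numeric()))
  elen <- seg_lengths(p0, p1)
  # collect breakpoints per edge
  bps <- vector("list", n_edges)
  for (e in seq_len(n_edges)) bps[[e]] <- c(0, 1)
  regs <- model$regions
  for (i in seq_len(nrow(regs))) {
    iv <- .slab_interval(regs[i, ], p0, p1)
    hit <- which(!is.na(iv[, 1]))
    for (e in hit) bps[[e]] <- c(bps[[e]], iv[e, 1], iv[e, 2])
  }
  pieces_edge <- integer(0); pieces_t0 <- numeric(0); pieces_t1 <- numeric(0)
  for (e in seq_len(n_edges)) {
    ts <- sort(unique(pmin(1, pmax(0, bps[[e]]))))
    if (length(ts) < 2L) ts <- c(0, 1)
    k <- length(ts) - 1L
    pieces_edge <- c(pieces_edge, rep(e, k))
    pieces_t0 <- c(pieces_t0, ts[-length(ts)])
    pieces_t1 <- c(pieces_t1, ts[-1])
  }
  tm <- (pieces_t0 + pieces_t1) / 2
  mids <- p0[pieces_edge, , drop = FALSE] +
    (p1[pieces_edge, , drop = FALSE] - p0[pieces_edge, , drop = FALSE]) * tm
  lab <- locate_point(mids, model)
  data.frame(edge = pieces_edge, region = lab,
             length = (pieces_t1 - pieces_t0) * elen[pieces_edge],
             t0 = pieces_t0, t1 = pieces_t1)
}

#' Clip a polyline against the region model
#'
#' Each edge of the chain is split analytically at region boundary
#' crossings and each resulting sub-segment's length accrues to the region
#' owning its midpoint (priority rule), or to `"elsewhere"`. The returned
#' lengths sum to the total chain length exactly (up to floating point).
#'
#' @param chain an n x 3 matrix/data.frame of bregma-frame points (mm),
#'   n >= 2, interpreted as an ordered polyline.
#' @param model a [region_model()].
#' @return named numeric vector of cable length (mm) per region, including
#'   an `"elsewhere"` entry; regions with no cable are present with 0.
#' @export
clip_polyline_to_regions <- function(chain, model) {
  chain <- as.matrix(chain)
  if (nrow(chain) < 2L)
    stop_pq("chain must have at least 2 points", "projquant_argument_error")
  p0 <- chain[-nrow(chain), , drop = FALSE]
  p1 <- chain[-1, , drop = FALSE]
  pieces <- .clip_edges(p0, p1, model)
  out <- stats::setNames(numeric(nrow(model$regions) + 1L),
                         c(model$regions$name, "elsewhere"))
  agg <- tapply(pieces$length, pieces$region, sum)
  out[names(agg)] <- agg
  out
}

#' @export
print.region_model <- function(x, ...) {
  cat(sprintf("Region model: %d regions; injection site (ml %.2f, ap %.2f) mm\n",
              nrow(x$regions), x$injection_site$ml, x$injection_site$ap))
  print.data.frame(x$regions, row.names = FALSE, digits = 3)
  invisible(x)
}
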