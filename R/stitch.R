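# Serial-section assembly. Tracings made section by section are re-assembled
# into one 3D reconstruction: each fragment's depth is offset by its section
# index times the section thickness, the recorded in-plane shift is
# inverted, and cut neurite endpoints facing each other across a section
# boundary are joined parent -> child. Registration is rigid per-section
# in-plane translation only; the shifts come from the stitching manifest.

#' Write a section stack to disk
#'
#' One SWC fragment file per section (section-local coordinates,
#' micrometres) plus a CSV manifest (`section_index`, `filename`,
#' `shift_ml_mm`, `shift_ap_mm`).
#'
#' @param stack a `section_stack` from [split_into_sections()].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return path of the manifest, invisibly.
#' @export
write_section_stack <- function(stack, dir, prefix = "section") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0); idx <- integer(0)
  for (sec in stack$sections) {
    if (!nrow(sec$nodes)) next
    fn <- sprintf("%s_%03d.swc", prefix, sec$index)
    write_swc_fragment(sec$nodes, file.path(dir, fn))
    files <- c(files, fn); idx <- c(idx, sec$index)
  }
  sh <- stack$manifest[match(idx, stack$manifest$section_index), ]
  manifest <- data.frame(section_index = idx, filename = files,
                         shift_ml_mm = sh$shift_ml_mm,
                         shift_ap_mm = sh$shift_ap_mm)
  mp <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mp, row.names = FALSE)
  invisible(mp)
}

#' Read a section stack from a manifest
#'
#' @param manifest_path CSV with columns `section_index`, `filename`,
#'   `shift_ml_mm`, `shift_ap_mm`; file names are resolved relative to the
#'   manifest's directory.
#' @param thickness section thickness in mm.
#' @param neuron_id label for the stitched reconstruction.
#' @return a `section_stack`.
#' @export
read_section_stack <- function(manifest_path, thickness,
                               neuron_id = "stitched") {
  man <- utils::read.csv(manifest_path)
  base <- dirname(manifest_path)
  sections <- lapply(seq_len(nrow(man)), function(i) {
    nodes <- read_swc_fragment(file.path(base, man$filename[i]))
    list(index = man$section_index[i], nodes = nodes,
         shift = c(man$shift_ml_mm[i], man$shift_ap_mm[i]))
  })
  structure(list(sections = sections, thickness = thickness,
                 manifest = man, neuron_id = neuron_id),
            class = "section_stack")
}

#' Stitch section fragments into one reconstruction
#'
#' Un-shifts and depth-offsets every fragment, then joins cut neurite
#' endpoints: a fragment root lying on a section face is connected under
#' the nearest node on the matching face of the adjacent section, provided
#' it lies within the merge tolerance. Among several candidates the nearest
#' wins; an exact distance tie is an error (no silent choice). If more than
#' one root remains after merging, the operation raises an error of class
#' `projquant_unmerged_error` reporting the unmerged endpoints. A cyclic
#' result raises a structural error.
#'
#' @param stack a `section_stack`.
#' @param tolerance_um merge tolerance in micrometres (default 5).
#' @return a `neuron_recon` in the frame the sections were cut from.
#' @export
stitch_sections <- function(stack, tolerance_um = 5) {
  th <- stack$thickness
  tol <- tolerance_um * 1e-3
  secs <- Filter(function(s) nrow(s$nodes) > 0, stack$sections)
  if (!length(secs))
    stop_pq("empty section stack", "projquant_argument_error")
  tabs <- lapply(secs, function(sec) {
    nd <- sec$nodes
    data.frame(
      sec = sec$index, lid = nd$id, type = nd$type,
      ml = nd$ml - sec$shift[1], ap = nd$ap - sec$shift[2],
      dv = nd$dv + sec$index * th,
      radius = nd$radius, lparent = nd$parent
    )
  })
  gtab <- do.call(rbind, tabs)
  gtab$gid <- seq_len(nrow(gtab))
  # local parent -> global id (local ids are unique within a section)
  key <- paste(gtab$sec, gtab$lid)
  pkey <- paste(gtab$sec, gtab$lparent)
  gtab$gparent <- gtab$gid[match(pkey, key)]
  gtab$gparent[gtab$lparent == -1L] <- NA_integer_

  near_plane <- abs(gtab$dv / th - round(gtab$dv / th)) * th <= tol
  roots <- which(is.na(gtab$gparent))
  face_roots <- roots[near_plane[roots]]
  # candidate partners: non-root face nodes
  cand <- setdiff(which(near_plane), roots)

  pairs <- NULL
  for (r in face_roots) {
    cc <- cand[abs(gtab$sec[cand] - gtab$sec[r]) == 1L]
    if (!length(cc)) next
    d <- sqrt((gtab$ml[cc] - gtab$ml[r])^2 + (gtab$ap[cc] - gtab$ap[r])^2 +
              (gtab$dv[cc] - gtab$dv[r])^2)
    keep <- d <= tol
    if (!any(keep)) next
    cc <- cc[keep]; d <- d[keep]
    if (length(cc) > 1L && sum(d == min(d)) > 1L)
      stop_pq(sprintf(
        "ambiguous merge for endpoint at (%.4f, %.4f, %.4f): candidates at equal distance",
        gtab$ml[r], gtab$ap[r], gtab$dv[r]), "projquant_ambiguous_merge")
    pairs <- rbind(pairs, data.frame(root = r, partner = cc, dist = d))
  }
  if (!is.null(pairs)) {
    pairs <- pairs[order(pairs$dist), ]
    done_root <- logical(nrow(gtab)); used_partner <- logical(nrow(gtab))
    for (i in seq_len(nrow(pairs))) {
      r <- pairs$root[i]; p <- pairs$partner[i]
      if (done_root[r] || used_partner[p]) next
      gtab$gparent[r] <- p
      done_root[r] <- TRUE; used_partner[p] <- TRUE
    }
  }
  remaining <- which(is.na(gtab$gparent))
  if (length(remaining) > 1L) {
    rep_df <- data.frame(ml = gtab$ml[remaining], ap = gtab$ap[remaining],
                         dv = gtab$dv[remaining], section = gtab$sec[remaining])
    stop_pq(sprintf(
      "%d fragment endpoints could not be merged (tolerance %.1f um); first at (%.4f, %.4f, %.4f)",
      length(remaining) - 1L, tolerance_um,
      rep_df$ml[1], rep_df$ap[1], rep_df$dv[1]),
      "projquant_unmerged_error", data = rep_df)
  }
  nodes <- data.frame(
    id = gtab$gid, type = gtab$type, ml = gtab$ml, ap = gtab$ap, dv = gtab$dv,
    radius = gtab$radius,
    parent = ifelse(is.na(gtab$gparent), -1L, gtab$gparent)
  )
  neuron_reconstruction(nodes, neuron_id = stack$neuron_id %||% "stitched",
                        frame = "bregma",
                        provenance = list(stitched = TRUE,
                                          thickness = th,
                                          tolerance_um = tolerance_um))
}
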