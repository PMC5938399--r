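# SWC input/output. The canonical on-disk format is standard 7-column SWC
# (id, type, x, y, z, radius, parent), whitespace-delimited, '#' comments.
# Column mapping: x -> ml, y -> ap, z -> dv. The default file unit is
# micrometres (the Neurolucida / NeuroMorpho convention); coordinates are
# converted to millimetres on read. A header comment "# UNITS <um|mm>"
# overrides the default.

#' Read a neuron reconstruction from an SWC file
#'
#' @param path path to an SWC file.
#' @param unit file coordinate unit: `"auto"` (use a `# UNITS` header comment
#'   if present, micrometres otherwise), `"um"` or `"mm"`. Radii are assumed
#'   to be in the same unit and are stored in micrometres.
#' @param neuron_id label for the reconstruction; defaults to the file name
#'   without extension.
#' @param frame coordinate frame tag to attach (default `"bregma"`).
#' @return a [neuron_reconstruction()].
#' @export
read_swc <- function(path, unit = c("auto", "um", "mm"), neuron_id = NULL,
                     frame = "bregma") {
  unit <- match.arg(unit)
  if (!file.exists(path))
    stop_pq(sprintf("file not found: %s", path), "projquant_io_error")
  lines <- readLines(path, warn = FALSE)
  if (unit == "auto") {
    hdr <- grep("^#\\s*UNITS\\b", lines, value = TRUE, ignore.case = TRUE)
    unit <- "um"
    if (length(hdr)) {
      u <- tolower(sub("^#\\s*UNITS\\s+", "", hdr[1], ignore.case = TRUE))
      u <- trimws(u)
      if (u %in% c("mm", "millimetres", "millimeters")) unit <- "mm"
      else if (u %in% c("um", "micrometres", "micrometers", "microns")) unit <- "um"
      else stop_pq(sprintf("unrecognized UNITS header '%s'", u), "projquant_parse_error")
    }
  }
  body_idx <- which(!grepl("^\\s*(#|$)", lines))
  if (!length(body_idx))
    stop_pq("SWC file has no data lines", "projquant_parse_error")
  fields <- strsplit(trimws(lines[body_idx]), "\\s+")
  nf <- lengths(fields)
  if (any(nf != 7L)) {
    bad <- body_idx[which(nf != 7L)[1]]
    stop_pq(sprintf("malformed SWC line %d: expected 7 fields, found %d",
                    bad, nf[which(nf != 7L)[1]]), "projquant_parse_error")
  }
  vals <- suppressWarnings(matrix(as.numeric(unlist(fields)), ncol = 7, byrow = TRUE))
  if (anyNA(vals)) {
    bad <- body_idx[which(rowSums(is.na(vals)) > 0)[1]]
    stop_pq(sprintf("malformed SWC line %d: non-numeric field", bad),
            "projquant_parse_error")
  }
  scale <- if (unit == "um") 1e-3 else 1
  rscale <- if (unit == "um") 1 else 1e3
  nodes <- data.frame(
    id = as.integer(vals[, 1]), type = as.integer(vals[, 2]),
    ml = vals[, 3] * scale, ap = vals[, 4] * scale, dv = vals[, 5] * scale,
    radius = vals[, 6] * rscale, parent = as.integer(vals[, 7])
  )
  if (is.null(neuron_id))
    neuron_id <- sub("\\.[sS][wW][cC]$", "", basename(path))
  neuron_reconstruction(nodes, neuron_id = neuron_id, frame = frame,
                        provenance = list(source = path, unit = unit))
}

#' Write a neuron reconstruction to an SWC file
#'
#' Emits standard 7-column SWC in micrometres with a `# UNITS um` header.
#' Missing radii are written with the sentinel 1.0 micrometre. Reading the
#' file back yields identical topology and coordinates to within 1e-9 mm.
#'
#' @param n a `neuron_recon`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_swc <- function(n, path) {
  stopifnot(inherits(n, "neuron_recon"))
  nodes <- n$nodes
  radius <- ifelse(is.na(nodes$radius), 1.0, nodes$radius)
  hdr <- c(
    sprintf("# SWC reconstruction '%s' written by projquant", n$neuron_id),
    "# UNITS um",
    sprintf("# FRAME %s", n$frame),
    "# id type x(ml) y(ap) z(dv) radius parent"
  )
  body <- sprintf("%d %d %.6f %.6f %.6f %.6f %d",
                  nodes$id, nodes$type,
                  nodes$ml * 1e3, nodes$ap * 1e3, nodes$dv * 1e3,
                  radius, nodes$parent)
  ok <- tryCatch({
    writeLines(c(hdr, body), path)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    stop_pq(sprintf("cannot write '%s': %s", path, conditionMessage(ok)),
            "projquant_io_error")
  invisible(path)
}

# Relaxed SWC reader for per-section fragments: returns a plain node table
# and allows multiple roots (a section typically holds several disconnected
# pieces of one neuron).
read_swc_fragment <- function(path, unit = "um") {
  lines <- readLines(path, warn = FALSE)
  body_idx <- which(!grepl("^\\s*(#|$)", lines))
  fields <- strsplit(trimws(lines[body_idx]), "\\s+")
  vals <- matrix(as.numeric(unlist(fields)), ncol = 7, byrow = TRUE)
  scale <- if (unit == "um") 1e-3 else 1
  data.frame(
    id = as.integer(vals[, 1]), type = as.integer(vals[, 2]),
    ml = vals[, 3] * scale, ap = vals[, 4] * scale, dv = vals[, 5] * scale,
    radius = vals[, 6] * (if (unit == "um") 1 else 1e3),
    parent = as.integer(vals[, 7])
  )
}

write_swc_fragment <- function(nodes, path) {
  radius <- ifelse(is.na(nodes$radius), 1.0, nodes$radius)
  body <- sprintf("%d %d %.6f %.6f %.6f %.6f %d",
                  nodes$id, nodes$type,
                  nodes$ml * 1e3, nodes$ap * 1e3, nodes$dv * 1e3,
                  radius, nodes$parent)
  writeLines(c("# UNITS um", "# section fragment"), con = path)
  cat(body, file = path, sep = "\n", append = TRUE)
  invisible(path)
}
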