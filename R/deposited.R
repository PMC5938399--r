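# Full-cohort analysis over a directory of reconstructions, as used for
# deposited single-cell datasets (after one-time conversion of Neurolucida
# files to SWC; see the package README). Produces the standard group
# statistics: morphometrics, per-region branching-axon lengths, the
# thresholded projection matrix, S2p/M1p classes and core fractions.

#' Analyze a directory of SWC reconstructions
#'
#' Reads every `*.swc` file in `dir`, computes morphometry and projection
#' profiles against the region model, classifies each neuron by its
#' dominant long-range target, and returns group summaries.
#'
#' @param dir directory containing SWC files (bregma-frame coordinates).
#' @param model a [region_model()].
#' @param labels optional named character vector mapping neuron ids to
#'   group labels; by default neurons are grouped by their computed
#'   S2p/M1p class.
#' @param unit SWC coordinate unit passed to [read_swc()].
#' @return list with `summaries` (morphometry data.frame), `profiles`
#'   (list of [projection_profile()]), `matrix` (a [threshold_matrix()]),
#'   `classes`, `core_fractions` and `groups` (a [group_summary()]).
#' @export
reproduce_deposited_stats <- function(dir, model = default_region_model(),
                                      labels = NULL, unit = "auto") {
  files <- sort(list.files(dir, pattern = "\\.[sS][wW][cC]$",
                           full.names = TRUE))
  if (!length(files))
    stop_pq(sprintf("no SWC files found under '%s'", dir),
            "projquant_io_error")
  neurons <- lapply(files, read_swc, unit = unit)
  summaries <- summarize_morphometry(neurons)
  profiles <- lapply(neurons, quantify_projection, model = model)
  classes <- classify_projection_class(profiles)
  grp <- if (is.null(labels)) classes
         else unname(labels[summaries$neuron_id])
  list(
    summaries = summaries,
    profiles = profiles,
    matrix = threshold_matrix(profiles),
    classes = classes,
    core_fractions = core_fraction(profiles),
    groups = group_summary(profiles, summaries, grp)
  )
}
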