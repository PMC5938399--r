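# Shared fixtures, built in code.

# a minimal hand-built neuron: soma at origin, straight axon down, one
# dendrite stem with a bifurcation
tiny_neuron <- function() {
  nodes <- data.frame(
    id = 1:6,
    type = c(1L, 2L, 2L, 3L, 3L, 3L),
    ml = c(0, 0, 0, 0.01, 0.02, 0.02),
    ap = c(0, 0, 0, 0, 0.01, -0.01),
    dv = c(0.2, 0.3, 0.4, 0.2, 0.2, 0.2),
    radius = 1,
    parent = c(-1L, 1L, 2L, 1L, 4L, 4L)
  )
  neuron_reconstruction(nodes, neuron_id = "tiny")
}

# random tree node table for round-trip tests (single soma root, mixed
# compartments), n nodes
random_tree_nodes <- function(n, seed) {
  set.seed(seed)
  parent <- c(-1L, vapply(2:n, function(i) sample.int(i - 1L, 1L), integer(1)))
  data.frame(
    id = seq_len(n),
    type = c(1L, sample(c(2L, 2L, 3L, 4L), n - 1L, replace = TRUE)),
    ml = c(0, stats::runif(n - 1, -4, 0)),
    ap = c(0, stats::runif(n - 1, -3, 2)),
    dv = c(0.2, stats::runif(n - 1, 0, 2)),
    radius = stats::runif(n, 0.3, 3),
    parent = parent
  )
}

# simple single-region model for geometry tests: one 1x1x1 mm box ("cube")
# centered at (-2, -1), dv 0.5..1.5, plus an "amygdala"-style deep box
two_box_model <- function() {
  regions <- data.frame(
    name = c("cube", "deep"),
    shape = c("box", "box"),
    center_ml = c(-2, -2), center_ap = c(-1, 1),
    half_ml = c(0.5, 0.5), half_ap = c(0.5, 0.5),
    dv_min = c(0.5, 2.0), dv_max = c(1.5, 3.0),
    priority = c(1L, 2L)
  )
  region_model(regions, injection_site(-2, -1))
}

expect_profile_equal <- function(p, q, tol = 1e-6) {
  expect_equal(p$region_lengths, q$region_lengths, tolerance = tol)
  expect_equal(p$passing_lengths, q$passing_lengths, tolerance = tol)
  expect_equal(p$elsewhere_length, q$elsewhere_length, tolerance = tol)
  expect_equal(p$total_axon_length, q$total_axon_length, tolerance = tol)
}
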