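# Sectioning and serial-section reassembly.

test_that("a straight vertical axon split into two sections stitches back", {
  nodes <- data.frame(
    id = 1:3, type = c(1L, 2L, 2L),
    ml = -3, ap = -1.6, dv = c(0.01, 0.075, 0.155),
    radius = 1, parent = c(-1L, 1L, 2L)
  )
  n <- neuron_reconstruction(nodes, "straight")
  st <- split_into_sections(n, thickness = 0.08)
  expect_length(st$sections, 2L)
  out <- stitch_sections(st, tolerance_um = 5)
  expect_equal(cable_length(out, "axon"), cable_length(n, "axon"),
               tolerance = 1e-6)
})

test_that("a neuron within one section round-trips as the identity", {
  nodes <- data.frame(
    id = 1:3, type = c(1L, 2L, 2L),
    ml = c(-3, -3.01, -3.02), ap = -1.6, dv = c(0.01, 0.02, 0.03),
    radius = 1, parent = c(-1L, 1L, 2L)
  )
  n <- neuron_reconstruction(nodes, "one_sec")
  st <- split_into_sections(n, thickness = 0.08)
  expect_length(Filter(function(s) nrow(s$nodes) > 0, st$sections), 1L)
  out <- stitch_sections(st)
  expect_equal(cable_length(out, "all"), cable_length(n, "all"),
               tolerance = 1e-9)
})

test_that("sectioning conserves fragment cable exactly", {
  m <- prepare_model(default_region_model())
  g <- generate_neuron(synthetic_neuron_spec(
    collaterals = data.frame(region = "wS2", length_mm = 10,
                             include_branch = TRUE), seed = 21), m)
  st <- split_into_sections(g$neuron, thickness = 0.08, jitter = 0.01,
                            seed = 4)
  frag_total <- sum(vapply(st$sections, function(sec) {
    nd <- sec$nodes
    if (!nrow(nd)) return(0)
    pid <- match(nd$parent, nd$id)
    ok <- !is.na(pid)
    sum(sqrt((nd$ml[ok] - nd$ml[pid[ok]])^2 + (nd$ap[ok] - nd$ap[pid[ok]])^2 +
             (nd$dv[ok] - nd$dv[pid[ok]])^2))
  }, numeric(1)))
  expect_equal(frag_total, cable_length(g$neuron, "all"), tolerance = 1e-9)
})

test_that("split + stitch with recorded jitter recovers cable and branches", {
  m <- prepare_model(default_region_model())
  for (seed in c(1, 2)) {
    g <- generate_neuron(synthetic_neuron_spec(
      collaterals = data.frame(region = c("wS2", "Striatum"),
                               length_mm = c(12, 6),
                               include_branch = TRUE), seed = seed), m)
    st <- split_into_sections(g$neuron, thickness = 0.08, jitter = 0.02,
                              seed = seed + 100)
    out <- stitch_sections(st, tolerance_um = 5)
    expect_lt(abs(cable_length(out, "axon") - cable_length(g$neuron, "axon")) /
              cable_length(g$neuron, "axon"), 0.005)
    expect_equal(count_branch_points(out, "axon"),
                 count_branch_points(g$neuron, "axon"))
    expect_equal(count_branch_points(out, "dendrite_all"),
                 count_branch_points(g$neuron, "dendrite_all"))
    # region quantification survives the round trip
    expect_profile_equal(quantify_projection(out, m), g$truth, tol = 1e-5)
  }
})

test_that("endpoints farther apart than the tolerance are reported, not joined", {
  # two fragments whose cut faces are 20 um apart in-plane
  sec0 <- list(index = 0L, shift = c(0, 0), nodes = data.frame(
    id = 1:2, type = c(1L, 2L), ml = c(-3, -3), ap = c(-1.6, -1.6),
    dv = c(0.01, 0.08), radius = 1, parent = c(-1L, 1L)))
  sec1 <- list(index = 1L, shift = c(0, 0), nodes = data.frame(
    id = 3:4, type = c(2L, 2L), ml = c(-3.02, -3.02), ap = c(-1.6, -1.6),
    dv = c(0.0, 0.05), radius = 1, parent = c(-1L, 3L)))
  stack <- structure(list(sections = list(sec0, sec1), thickness = 0.08,
                          manifest = data.frame(section_index = 0:1,
                                                shift_ml_mm = 0,
                                                shift_ap_mm = 0),
                          neuron_id = "gap"),
                     class = "section_stack")
  err <- tryCatch(stitch_sections(stack, tolerance_um = 5), error = identity)
  expect_s3_class(err, "projquant_unmerged_error")
  expect_true(is.data.frame(err$data))
  # a 25 um tolerance closes the same gap
  out <- stitch_sections(stack, tolerance_um = 25)
  expect_s3_class(out, "neuron_recon")
})

test_that("stitching is invariant to relabeling fragment node ids", {
  m <- prepare_model(default_region_model())
  g <- generate_neuron(synthetic_neuron_spec(seed = 33), m)
  st <- split_into_sections(g$neuron, thickness = 0.08)
  st2 <- st
  st2$sections <- lapply(st$sections, function(sec) {
    if (!nrow(sec$nodes)) return(sec)
    shift <- 1000L
    sec$nodes$id <- sec$nodes$id + shift
    sec$nodes$parent <- ifelse(sec$nodes$parent == -1L, -1L,
                               sec$nodes$parent + shift)
    sec
  })
  a <- stitch_sections(st)
  b <- stitch_sections(st2)
  expect_equal(cable_length(a, "all"), cable_length(b, "all"),
               tolerance = 1e-12)
  expect_equal(count_branch_points(a, "axon"), count_branch_points(b, "axon"))
})

test_that("section stacks round-trip through the on-disk manifest format", {
  m <- prepare_model(default_region_model())
  g <- generate_neuron(synthetic_neuron_spec(seed = 8), m)
  st <- split_into_sections(g$neuron, thickness = 0.08, jitter = 0.015,
                            seed = 5)
  dir <- withr::local_tempdir()
  mp <- write_section_stack(st, dir)
  st2 <- read_section_stack(mp, thickness = 0.08, neuron_id = "rt")
  out <- stitch_sections(st2)
  expect_lt(abs(cable_length(out, "all") - cable_length(g$neuron, "all")),
            1e-4)
})
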