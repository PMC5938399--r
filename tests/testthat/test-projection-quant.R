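# Projection profiles, thresholded matrix, classification, group summaries.

test_that("a planted wS2 collateral is recovered exactly as branching axon", {
  m <- prepare_model(default_region_model())
  spec <- synthetic_neuron_spec(
    "P1", collaterals = data.frame(region = "wS2", length_mm = 12.0,
                                   include_branch = TRUE), seed = 5)
  g <- generate_neuron(spec, m)
  p <- quantify_projection(g$neuron, m)
  expect_equal(unname(p$region_lengths["wS2"]), 12.0, tolerance = 1e-6)
  expect_equal(unname(p$region_lengths["wS1"]), 41.7, tolerance = 1e-6)
  expect_profile_equal(p, g$truth)
})

test_that("an unbranched fiber through a region counts as passing, not branching", {
  m <- two_box_model()
  # straight unbranched axon crossing the deep box (dv 2..3) vertically
  nodes <- data.frame(
    id = 1:4, type = c(1L, 2L, 2L, 2L),
    ml = -2, ap = 1, dv = c(0.2, 1.0, 3.5, 4.0),
    radius = 1, parent = c(-1L, 1L, 2L, 3L)
  )
  n <- neuron_reconstruction(nodes, "pass")
  p <- quantify_projection(n, m)
  expect_equal(unname(p$passing_lengths["deep"]), 1.0, tolerance = 1e-9)
  expect_equal(unname(p$region_lengths["deep"]), 0)
  # same geometry with a side branch inside the box -> branching
  nodes2 <- rbind(nodes, data.frame(id = 5L, type = 2L, ml = -1.9, ap = 1,
                                    dv = 2.5, radius = 1, parent = 2L))
  nodes2$dv[3] <- 2.5  # put a real node (with 2 children) inside the box
  nodes2$parent[4] <- 3L
  nodes2$parent[5] <- 3L
  n2 <- neuron_reconstruction(nodes2, "branch")
  p2 <- quantify_projection(n2, m)
  expect_gt(unname(p2$region_lengths["deep"]), 0)
  expect_equal(unname(p2$passing_lengths["deep"]), 0)
})

test_that("a generated passing fiber lands in the passing tally", {
  m <- prepare_model(default_region_model())
  spec <- synthetic_neuron_spec(
    "P2", passing_fibers = data.frame(region = "TeA", length_mm = 5.0),
    seed = 9)
  g <- generate_neuron(spec, m)
  p <- quantify_projection(g$neuron, m)
  expect_equal(unname(p$passing_lengths["TeA"]), 5.0, tolerance = 1e-6)
  expect_equal(unname(p$region_lengths["TeA"]), 0)
  expect_profile_equal(p, g$truth)
})

test_that("profiles conserve cable and reject violations", {
  zero <- stats::setNames(numeric(2), c("a", "b"))
  expect_error(projection_profile("x", zero + c(1, 0), zero, 0, 2),
               class = "projquant_conservation_error")
  expect_error(projection_profile("x", zero - 1, zero, 0, -2),
               class = "projquant_argument_error")
  p <- projection_profile("x", zero + c(1, 0), zero + c(0, 0.5), 0.5, 2)
  expect_s3_class(p, "projection_profile")
})

test_that("threshold classes follow the strict 1/10 mm boundaries", {
  mk <- function(len) projection_profile(
    paste0("n", len),
    stats::setNames(c(len, 0, 0), c("X", "wS2", "wM1/2")),
    stats::setNames(numeric(3), c("X", "wS2", "wM1/2")), 0, len)
  lens <- c(0, 0.5, 1, 1.0001, 5, 10, 10.0001, 12.5, 40)
  mat <- threshold_matrix(lapply(lens, mk))
  got <- mat$classes[, "X"]
  expect_equal(unname(got),
               c("none", "none", "none", "light", "light", "light",
                 "dark", "dark", "dark"))
  expect_error(threshold_matrix(list(mk(1)), light_mm = -1),
               class = "projquant_argument_error")
  expect_error(threshold_matrix(list()), class = "projquant_argument_error")
})

test_that("threshold_matrix is monotone in length", {
  rank_of <- c(none = 1L, light = 2L, dark = 3L)
  mk <- function(len) projection_profile(
    "n", stats::setNames(len, "X"), stats::setNames(0, "X"), 0, len)
  set.seed(8)
  lens <- sort(stats::runif(50, 0, 20))
  cls <- vapply(lens, function(l) threshold_matrix(mk(l))$classes[1, 1],
                character(1))
  expect_true(all(diff(rank_of[cls]) >= 0))
})

test_that("S2p/M1p classification follows the wS2-vs-wM1/2 rule", {
  mk <- function(s2, m1) projection_profile(
    "n", stats::setNames(c(s2, m1), c("wS2", "wM1/2")),
    stats::setNames(c(0, 0), c("wS2", "wM1/2")), 0, s2 + m1)
  expect_equal(classify_projection_class(mk(12.2, 0)), "S2p")
  expect_equal(classify_projection_class(mk(1.6, 20.8)), "M1p")
  expect_equal(classify_projection_class(mk(0, 0)), "unclassified")
  expect_equal(classify_projection_class(mk(3, 3)), "unclassified")
  # scale invariance
  set.seed(2)
  for (i in 1:20) {
    s2 <- stats::runif(1, 0, 30); m1 <- stats::runif(1, 0, 30)
    c1 <- classify_projection_class(mk(s2, m1))
    c2 <- classify_projection_class(mk(s2 * 7.3, m1 * 7.3))
    expect_identical(c1, c2)
  }
  bad <- projection_profile("n", stats::setNames(1, "A"),
                            stats::setNames(0, "A"), 0, 1)
  expect_error(classify_projection_class(bad),
               class = "projquant_argument_error")
})

test_that("core_fraction computes the wS1+wS2+wM1/2 share", {
  mk <- function(v) projection_profile(
    "n", v, stats::setNames(numeric(length(v)), names(v)), 0, sum(v))
  all_ws1 <- mk(stats::setNames(c(40, 0, 0, 0),
                                c("wS1", "wS2", "wM1/2", "Striatum")))
  expect_equal(core_fraction(all_ws1), 1.0)
  mixed <- mk(stats::setNames(c(40, 12, 0, 8),
                              c("wS1", "wS2", "wM1/2", "Striatum")))
  expect_equal(core_fraction(mixed), 52 / 60, tolerance = 1e-12)
  zero <- mk(stats::setNames(numeric(4), c("wS1", "wS2", "wM1/2", "Striatum")))
  expect_error(core_fraction(zero), class = "projquant_undefined_result")
})

test_that("group_summary recovers planted distribution moments", {
  set.seed(31)
  n <- 100
  lens <- pmax(0, stats::rnorm(n, 12, 7))
  profiles <- lapply(seq_len(n), function(i) projection_profile(
    paste0("n", i), stats::setNames(c(lens[i], 30), c("wS2", "wS1")),
    stats::setNames(c(0, 0), c("wS2", "wS1")), 0, lens[i] + 30))
  gs <- group_summary(profiles, labels = rep("G", n))
  mu <- gs$mean[gs$metric == "wS2"]
  se <- stats::sd(lens) / sqrt(n)
  expect_lt(abs(mu - mean(lens)), 1e-12)       # summary is exact on its input
  expect_lt(abs(mu - 12), 2 * se + 7 * 0.05)   # and close to the target
  # single-neuron group: SD flagged as NA
  gs1 <- group_summary(profiles[1], labels = "solo")
  expect_true(all(is.na(gs1$sd)))
  expect_error(group_summary(profiles, labels = rep("G", n - 1)),
               class = "projquant_argument_error")
})
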