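# Voxelization, 2D projections, hotspot center estimation.

test_that("an axis-aligned 1 mm segment splits uniformly over 20 voxels", {
  seg <- rbind(c(0.0, 0.025, 0.025), c(1.0, 0.025, 0.025))
  v <- voxelize(seg, origin = c(0, 0, 0), dim = c(20L, 1L, 1L), voxel = 0.05)
  expect_equal(as.numeric(v$values), rep(0.05, 20), tolerance = 1e-12)
})

test_that("voxelization conserves cable mass", {
  m <- prepare_model(default_region_model())
  g <- generate_neuron(synthetic_neuron_spec(
    collaterals = data.frame(region = "wM1/2", length_mm = 15,
                             include_branch = TRUE), seed = 12), m)
  v <- voxelize(g$neuron, origin = c(-6, -5, -0.1), dim = c(130, 160, 90),
                voxel = 0.05)
  expect_lt(abs(sum(v$values) - cable_length(g$neuron, "axon")) /
            cable_length(g$neuron, "axon"), 1e-6)
  # empty neuron -> all-zero volume
  soma <- neuron_reconstruction(data.frame(
    id = 1L, type = 1L, ml = -3, ap = -1.6, dv = 0.2, radius = 5,
    parent = -1L), "soma")
  v0 <- voxelize(soma, origin = c(-6, -5, 0), dim = c(10, 10, 10))
  expect_equal(sum(v0$values), 0)
})

test_that("cable outside the grid is counted and warned about", {
  seg <- rbind(c(-0.5, 0.025, 0.025), c(0.5, 0.025, 0.025))
  expect_warning(
    v <- voxelize(seg, origin = c(0, 0, 0), dim = c(20L, 1L, 1L), voxel = 0.05),
    "outside")
  expect_equal(attr(v, "oob_mm"), 0.5, tolerance = 1e-9)
  expect_equal(sum(v$values), 0.5, tolerance = 1e-9)
})

test_that("project2d collapses the right axis and conserves mass", {
  vals <- array(0, c(4, 5, 3))
  vals[2, 3, 1] <- 2; vals[2, 3, 2] <- 1; vals[4, 1, 3] <- 5
  v <- density_volume(vals, origin = c(0, 0, 0), voxel = 0.1)
  h <- project2d(v, "horizontal")
  expect_equal(dim(h), c(4, 5))
  expect_equal(h[2, 3], 3)
  expect_equal(sum(h), sum(vals))
  co <- project2d(v, "coronal")
  expect_equal(dim(co), c(4, 3))
  expect_equal(sum(co), sum(vals))
  # volumes differing only along the collapsed axis project identically
  vals2 <- vals; vals2[2, 3, ] <- c(1, 2, 0)
  h2 <- project2d(density_volume(vals2, c(0, 0, 0), 0.1), "horizontal")
  expect_equal(unclass(h2), unclass(h), ignore_attr = TRUE)
  expect_error(project2d(v, "sagittal"))
})

test_that("find_hotspot_center recovers a planted Gaussian blob center", {
  tab <- data.frame(region = "wS2", ml = -3.83, ml_sd = 0, ap = -1.63,
                    ap_sd = 0)
  sim <- generate_bulk_density(n_animals = 1, table = tab, seed = 1)
  ctr <- find_hotspot_center(sim$volumes[[1]],
                             window = c(-4.3, -3.3, -2.1, -1.1))
  expect_lt(max(abs(ctr - c(-3.83, -1.63))), 0.02)
  # single nonzero pixel -> that pixel's center
  vals <- array(0, c(10, 10, 1))
  vals[3, 7, 1] <- 1
  v <- density_volume(vals, origin = c(0, 0, 0), voxel = 0.05)
  ctr2 <- find_hotspot_center(v, window = c(0, 0.5, 0, 0.5), sigma = 0)
  expect_equal(unname(ctr2), c(0.125, 0.325), tolerance = 1e-9)
  expect_error(find_hotspot_center(v, window = c(0.4, 0.5, 0, 0.2), sigma = 0),
               class = "projquant_no_signal")
})

test_that("two equal blobs in one window give the midway centroid", {
  xs <- seq(0.025, 0.975, by = 0.05)
  vals <- array(0, c(20, 20, 1))
  px1 <- diff(stats::pnorm(seq(0, 1, by = 0.05), 0.3, 0.04))
  px2 <- diff(stats::pnorm(seq(0, 1, by = 0.05), 0.7, 0.04))
  py <- diff(stats::pnorm(seq(0, 1, by = 0.05), 0.5, 0.04))
  vals[, , 1] <- outer(px1, py) + outer(px2, py)
  v <- density_volume(vals, origin = c(0, 0, 0), voxel = 0.05)
  ctr <- find_hotspot_center(v, window = c(0, 1, 0, 1), sigma = 0.05)
  expect_equal(unname(ctr[1]), 0.5, tolerance = 0.02)
  # connected = TRUE instead picks one blob
  ctr2 <- find_hotspot_center(v, window = c(0, 1, 0, 1), sigma = 0.05,
                              connected = TRUE)
  expect_gt(abs(ctr2[1] - 0.5), 0.15)
})

test_that("aggregate_centers recovers planted multi-animal means", {
  m <- default_region_model()
  # SD 0: every animal at the table mean; recovered SD ~ 0
  tab0 <- default_hotspot_table()
  tab0$ml_sd[] <- 0; tab0$ap_sd[] <- 0
  sim0 <- generate_bulk_density(n_animals = 3, table = tab0, seed = 2)
  out0 <- aggregate_centers(sim0$volumes, m, sigma = 0.05, seeds = tab0)
  expect_equal(nrow(out0), 11L)
  expect_lt(max(out0$ml_sd, out0$ap_sd), 1e-9)
  ref <- tab0[match(out0$region, tab0$region), ]
  expect_lt(max(abs(out0$ml - ref$ml)), 0.02)
  expect_lt(max(abs(out0$ap - ref$ap)), 0.02)
  # frame duality: bregma mean minus site = injection-frame mean, exactly
  expect_equal(out0$ml - injection_site()$ml, out0$off_ml, tolerance = 1e-12)
  expect_equal(out0$ap - injection_site()$ap, out0$off_ap, tolerance = 1e-12)
})

test_that("a region with zero mass is omitted with a warning", {
  tab <- default_hotspot_table()
  masses <- rep(10, nrow(tab))
  masses[tab$region == "PP"] <- 0
  sim <- generate_bulk_density(n_animals = 2, table = tab, mass_mm = masses,
                               seed = 6)
  expect_warning(
    out <- aggregate_centers(sim$volumes, default_region_model(),
                             sigma = 0.05, seeds = tab),
    "PP")
  expect_false("PP" %in% out$region)
})

test_that("density volumes round-trip through the text container", {
  sim <- generate_bulk_density(n_animals = 1, seed = 3)
  v <- sim$volumes[[1]]
  path <- file.path(withr::local_tempdir(), "vol.csv")
  write_density(v, path)
  v2 <- read_density(path)
  expect_equal(v2$origin, v$origin)
  expect_equal(v2$voxel, v$voxel)
  expect_equal(v2$values, v$values, tolerance = 1e-12)
})
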