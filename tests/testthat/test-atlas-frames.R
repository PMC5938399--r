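# Frame transforms, point-to-region assignment, polyline clipping.

test_that("injection/bregma transforms are exact inverses", {
  site <- injection_site()
  set.seed(1)
  p <- cbind(stats::runif(50, -5, 5), stats::runif(50, -5, 5))
  back <- bregma_to_injection(injection_to_bregma(p, site), site)
  expect_lt(max(abs(back - p)), 1e-12)
  expect_equal(unname(injection_to_bregma(c(0, 0), site)),
               c(site$ml, site$ap))
})

test_that("reference offsets map onto the printed bregma coordinates", {
  tab <- default_hotspot_table()
  b <- injection_to_bregma(cbind(tab$off_ml, tab$off_ap))
  expect_equal(b[tab$region == "wM1/2", 1], -0.81, tolerance = 0.005)
  expect_equal(b[tab$region == "TeA", 1], -4.45, tolerance = 0.005)
  expect_lt(max(abs(b - cbind(tab$ml, tab$ap))), 0.015)
})

test_that("locate_point honours containment and priority", {
  m <- default_region_model()
  expect_equal(locate_point(c(-3.83, -1.63, 0.5), m), "wS2")
  expect_equal(locate_point(c(0, 0, 0.5), m), "elsewhere")
  # wS1 has lowest priority: a point in the CM box that also lies in the
  # wS1 box goes to CM
  expect_equal(locate_point(c(-2.32, -1.46, 0.5), m), "CM")
  # depth separation: striatum below the cortical column
  expect_equal(locate_point(c(-2.83, -1.0, 2.5), m), "Striatum")
  expect_equal(locate_point(c(-2.83, -1.0, 4.0), m), "elsewhere")
  expect_error(locate_point(c(0, 0, 0), m, frame = "injection"),
               class = "projquant_frame_error")
})

test_that("locate_point agrees with a brute-force containment check", {
  m <- default_region_model()
  set.seed(42)
  pts <- cbind(stats::runif(10000, -5.5, 0.5), stats::runif(10000, -4.5, 3),
               stats::runif(10000, 0, 4.5))
  got <- locate_point(pts, m)
  # oracle: test each region independently, then resolve by priority
  regs <- m$regions[order(m$regions$priority), ]
  oracle <- rep("elsewhere", nrow(pts))
  decided <- rep(FALSE, nrow(pts))
  for (i in seq_len(nrow(regs))) {
    r <- regs[i, ]
    inside <- pts[, 1] >= r$center_ml - r$half_ml &
              pts[, 1] <= r$center_ml + r$half_ml &
              pts[, 2] >= r$center_ap - r$half_ap &
              pts[, 2] <= r$center_ap + r$half_ap &
              pts[, 3] >= r$dv_min & pts[, 3] <= r$dv_max
    oracle[inside & !decided] <- r$name
    decided <- decided | inside
  }
  expect_identical(got, oracle)
})

test_that("clip_polyline_to_regions conserves length and splits analytically", {
  m <- two_box_model()
  # wholly inside the cube
  seg <- rbind(c(-2.4, -1, 1), c(-1.6, -1, 1))
  out <- clip_polyline_to_regions(seg, m)
  expect_equal(unname(out["cube"]), 0.8, tolerance = 1e-12)
  expect_equal(unname(out["elsewhere"]), 0)
  # entering the box exactly halfway
  seg2 <- rbind(c(-3.0, -1, 1), c(-2.0, -1, 1))
  out2 <- clip_polyline_to_regions(seg2, m)
  expect_equal(unname(out2["cube"]), 0.5, tolerance = 1e-12)
  expect_equal(unname(out2["elsewhere"]), 0.5, tolerance = 1e-12)
  expect_error(clip_polyline_to_regions(rbind(c(0, 0, 0)), m),
               class = "projquant_argument_error")
})

test_that("clip agrees with a dense-resampling oracle on random chains", {
  m <- default_region_model()
  set.seed(7)
  for (rep in 1:5) {
    k <- 12
    chain <- cbind(stats::runif(k, -4.5, -0.5), stats::runif(k, -3.5, 1.5),
                   stats::runif(k, 0, 4))
    got <- clip_polyline_to_regions(chain, m)
    # oracle: subdivide every edge into 1 um pieces, label midpoints
    acc <- stats::setNames(numeric(length(got)), names(got))
    for (e in seq_len(k - 1)) {
      a <- chain[e, ]; b <- chain[e + 1, ]
      len <- sqrt(sum((b - a)^2))
      np <- max(2L, ceiling(len / 1e-3))
      tm <- (seq_len(np) - 0.5) / np
      mids <- cbind(a[1] + (b[1] - a[1]) * tm, a[2] + (b[2] - a[2]) * tm,
                    a[3] + (b[3] - a[3]) * tm)
      lab <- locate_point(mids, m)
      agg <- tapply(rep(len / np, np), lab, sum)
      acc[names(agg)] <- acc[names(agg)] + agg
    }
    expect_equal(sum(got), sum(acc), tolerance = 1e-9)
    expect_lt(max(abs(got - acc)) / sum(got), 1e-3)
    # exact conservation of the total
    total <- sum(sqrt(rowSums((chain[-1, ] - chain[-k, ])^2)))
    expect_equal(sum(got), total, tolerance = 1e-12)
  }
})

test_that("region assignment is translation-equivariant", {
  m <- default_region_model()
  shift <- c(0.37, -0.91)
  regs <- m$regions
  regs$center_ml <- regs$center_ml + shift[1]
  regs$center_ap <- regs$center_ap + shift[2]
  m2 <- region_model(regs, m$injection_site)
  set.seed(3)
  pts <- cbind(stats::runif(2000, -5, 0), stats::runif(2000, -4, 3),
               stats::runif(2000, 0, 4))
  pts2 <- pts
  pts2[, 1] <- pts2[, 1] + shift[1]
  pts2[, 2] <- pts2[, 2] + shift[2]
  expect_identical(locate_point(pts, m), locate_point(pts2, m2))
})

test_that("region model validation rejects bad configurations", {
  regs <- default_region_model()$regions
  expect_error(region_model(rbind(regs, regs[1, ])),
               class = "projquant_argument_error")
  bad <- regs; bad$name[1] <- "elsewhere"
  expect_error(region_model(bad), class = "projquant_argument_error")
  bad2 <- regs; bad2$half_ml[2] <- 0
  expect_error(region_model(bad2), class = "projquant_argument_error")
  bad3 <- regs; bad3$dv_min[3] <- bad3$dv_max[3]
  expect_error(region_model(bad3), class = "projquant_argument_error")
})
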