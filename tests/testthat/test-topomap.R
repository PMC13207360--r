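test_that("Welch band powers have 2 Hz bins and concentrate a pure alpha tone", {
  sp <- welch_psd(sin(2 * pi * 10 * (0:2559) / 256), 256)
  expect_equal(diff(sp$freq)[1], 2)
  bp <- band_power_welch(sine_window(10))
  expect_gt(bp["F3", "alpha"] / sum(bp["F3", ]), 0.9)
  expect_error(band_power_welch(sine_window(10)["samples"]), "tg_window")
  short <- raw_window(matrix(rnorm(100), 1), 0, "F3", 256)
  expect_error(band_power_welch(short), "needs")
})

test_that("white-noise density is flat across bands within 5%", {
  set.seed(3)
  dens <- replicate(1000, {
    bp <- band_power_welch(raw_window(matrix(rnorm(256), 1), 0, "Cz", 256))
    # band measure = bin count x 2 Hz resolution: theta 2, alpha 3, beta 9
    c(bp[1, "theta"] / 4, bp[1, "alpha"] / 6, bp[1, "beta"] / 18)
  })
  m <- rowMeans(dens)     # per-Hz density per band
  expect_lt(max(abs(m / mean(m) - 1)), 0.05)
})

test_that("FAA is the F4/F3 log alpha ratio with its symmetries", {
  bp <- matrix(c(2, 2, 1, 1, 3, 3), 2, dimnames = list(c("F3", "F4"),
                                                       c("theta", "alpha", "beta")))
  expect_equal(compute_faa(bp), 0)
  bp["F4", "alpha"] <- exp(1) * bp["F3", "alpha"]
  expect_equal(compute_faa(bp), 1)
  swapped <- bp[c(2, 1), ]; rownames(swapped) <- c("F3", "F4")
  expect_equal(compute_faa(swapped), -1)
  bp["F3", "alpha"] <- 0
  expect_error(compute_faa(bp), "positive")
})

test_that("azimuthal equidistant projection preserves arc length and azimuth", {
  expect_equal(as.vector(project_layout(matrix(c(0, 0, 1), 1))), c(0, 0))
  # two electrodes at the same polar angle project to the same radius
  p <- project_layout(rbind(c(sin(1), 0, cos(1)), c(0, sin(1), cos(1))))
  expect_equal(sqrt(sum(p[1, ]^2)), sqrt(sum(p[2, ]^2)))
  # planar radius equals great-circle distance from the vertex
  lay <- electrode_layout()
  arc <- acos(pmin(1, lay$z))
  expect_equal(sqrt(lay$px^2 + lay$py^2), arc, tolerance = 1e-9)
  expect_error(project_layout(matrix(c(0, 0, -1), 1)), "antipode")
})

test_that("layout mirrors homolog pairs across the midline", {
  lay <- electrode_layout()
  pairs <- rbind(c("F3", "F4"), c("F7", "F8"), c("T7", "T8"),
                 c("P7", "P8"), c("O1", "O2"), c("AF3", "AF4"), c("FC5", "FC6"))
  for (i in seq_len(nrow(pairs))) {
    a <- lay[pairs[i, 1], ]; b <- lay[pairs[i, 2], ]
    expect_equal(a$px, b$px, tolerance = 1e-12)
    expect_equal(a$py, -b$py, tolerance = 1e-12)
  }
})

test_that("thin-plate interpolation reproduces constants, sites, and affine fields", {
  lay <- electrode_layout()
  interp <- fit_topo_interpolator(lay)
  m <- interpolate_topomap(rep(3.5, 14), interp)
  expect_lt(max(abs(m[matrix(interp$mask, 32)] - 3.5)), 1e-6)
  set.seed(2)
  v <- rnorm(14)
  at_sites <- eval_topo_interpolator(interp, v, cbind(lay$px, lay$py))
  expect_lt(max(abs(at_sites - v)), 1e-6)
  aff <- 2 + 1.3 * lay$px - 0.7 * lay$py
  maff <- interpolate_topomap(aff, interp)
  gx <- rep(interp$grid_axis, times = 32); gy <- rep(interp$grid_axis, each = 32)
  want <- 2 + 1.3 * gx - 0.7 * gy
  expect_lt(max(abs(as.vector(maff)[interp$mask] - want[interp$mask])), 1e-6)
  expect_error(fit_topo_interpolator(rbind(lay, lay)), "duplicate")
})

test_that("maps are permutation-safe, monotone at the boosted site, mirror-consistent", {
  lay <- electrode_layout()
  interp <- fit_topo_interpolator(lay)
  set.seed(4)
  v <- rnorm(14); names(v) <- lay$label
  m1 <- interpolate_topomap(v, interp)
  perm <- sample(14)
  m2 <- interpolate_topomap(v[perm], interp)   # named: matched by label
  expect_equal(m1, m2)
  # scaling one electrode up does not decrease the value at its own site
  v2 <- v; v2["O1"] <- v2["O1"] + 2
  site <- cbind(lay["O1", "px"], lay["O1", "py"])
  expect_gt(eval_topo_interpolator(interp, v2, site),
            eval_topo_interpolator(interp, v, site))
  # mirrored input values produce mirrored maps
  pairs <- c(AF3 = "AF4", F7 = "F8", F3 = "F4", FC5 = "FC6", T7 = "T8",
             P7 = "P8", O1 = "O2")
  vm <- v
  for (l in names(pairs)) { vm[l] <- v[pairs[l]]; vm[pairs[l]] <- v[l] }
  mm <- interpolate_topomap(vm, interp)
  expect_equal(mm, m1[, 32:1], tolerance = 1e-6)
})

test_that("map stacks are 32x32x4 with a constant FAA plane", {
  set.seed(5)
  lay <- electrode_layout()
  interp <- fit_topo_interpolator(lay)
  x <- matrix(rnorm(14 * 256), 14, dimnames = list(lay$label, NULL))
  w <- normalize_window(raw_window(x, 0, lay$label, 256))
  st <- build_map_stack(w, interp)
  expect_equal(dim(st), c(32L, 32L, 4L))
  expect_equal(sd(st[, , 4]), 0)
})

test_that("sequences need K contiguous stacks and span 1.9 s", {
  lay <- electrode_layout()
  interp <- fit_topo_interpolator(lay)
  set.seed(6)
  mk <- function(t0) {
    x <- matrix(rnorm(14 * 256), 14, dimnames = list(lay$label, NULL))
    build_map_stack(normalize_window(raw_window(x, t0, lay$label, 256)), interp)
  }
  stacks <- lapply(seq(0, by = 0.1, length.out = 11), mk)
  expect_length(build_sequence(stacks[1:9]), 0)
  seqs <- build_sequence(stacks)
  expect_length(seqs, 2)
  expect_equal(attr(seqs[[2]], "start_time_s") - attr(seqs[[1]], "start_time_s"),
               0.1)
  # span = W + (K-1) * stride = 1.9 s
  expect_equal(attr(seqs[[1]], "start_time_s") + 0.9 + 1, 1.9)
  expect_error(build_sequence(stacks[c(1:5, 7:11)]), "gap")
})
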