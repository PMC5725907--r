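test_that("a blank field yields zero beads, and zero beads is not an error", {
  img <- image_from_planes(actin = matrix(0, 200, 200))
  bs <- detect_beads(img)
  expect_equal(bs$n_beads, 0L)
  expect_true(all(bs$mask == 0L))
})

test_that("well-separated beads are recovered with accurate centers and radii", {
  spec <- scene_spec(seed = 2, field_um = c(700, 700), pixel_size = 1,
                     beads = list(list(center = c(170, 170), radius_um = 90),
                                  list(center = c(170, 520), radius_um = 90),
                                  list(center = c(520, 350), radius_um = 90)),
                     roles = "actin")
  sc <- render_scene(spec)
  bs <- detect_beads(sc$image)
  expect_equal(bs$n_beads, 3L)
  truth <- sc$truth$bead_centers_px
  for (k in seq_len(3)) {
    d <- sqrt((bs$beads$row - truth[k, 1])^2 + (bs$beads$col - truth[k, 2])^2)
    expect_lt(min(d), 2)                                   # centers within 2 px
    expect_rel_error(bs$beads$equivalent_radius_um[which.min(d)], 90, 0.05)
  }
  expect_true(all(bs$beads$circularity >= 0.6))
})

test_that("the radius gate rejects undersized disks", {
  spec <- scene_spec(seed = 2, field_um = c(700, 700), pixel_size = 1,
                     beads = list(list(center = c(170, 170), radius_um = 90),
                                  list(center = c(170, 520), radius_um = 90),
                                  list(center = c(520, 350), radius_um = 90),
                                  list(center = c(520, 120), radius_um = 20)),
                     roles = "actin")
  bs <- detect_beads(render_scene(spec)$image)   # min_radius_um = 50 default
  expect_equal(bs$n_beads, 3L)
})

test_that("bead count is invariant under global intensity scaling (auto threshold)", {
  sc <- render_scene(one_bead_spec(seed = 9, radius = 85))
  img2 <- sc$image
  img2$planes$actin <- img2$planes$actin * 3.7
  expect_equal(detect_beads(sc$image)$n_beads, detect_beads(img2)$n_beads)
  expect_equal(detect_beads(sc$image)$mask, detect_beads(img2)$mask)
})

test_that("touching beads are split by the distance-transform watershed", {
  spec <- scene_spec(seed = 4, field_um = c(600, 600), pixel_size = 1,
                     beads = list(list(center = c(300, 215), radius_um = 85),
                                  list(center = c(300, 375), radius_um = 85)),
                     roles = "actin")   # centers 160 um apart: disks overlap
  bs <- detect_beads(render_scene(spec)$image)
  expect_equal(bs$n_beads, 2L)
})

test_that("bead masks are hole-filled (simply connected)", {
  plane <- matrix(0, 300, 300)
  Rm <- matrix(1:300, 300, 300); Cm <- t(Rm)
  d2 <- (Rm - 150)^2 + (Cm - 150)^2
  plane[d2 <= 80^2] <- 100
  plane[d2 <= 20^2] <- 0                       # dark core
  img <- image_from_planes(actin = plane)
  p <- analysis_params(bead = list(threshold_method = "manual",
                                   manual_threshold = 50))
  bs <- detect_beads(img, p)
  expect_equal(bs$n_beads, 1L)
  expect_true(all(bs$mask[d2 <= 20^2] == 1L))  # core reclaimed by filling
})

test_that("the perimeter band matches its analytic area and a brute-force oracle", {
  sc <- render_scene(one_bead_spec(seed = 6, field = 500, radius = 80))
  bs <- detect_beads(sc$image)
  w <- 25
  band <- bead_perimeter_band(bs, w)
  r <- bs$beads$equivalent_radius_um[1]
  analytic <- pi * ((r + w)^2 - r^2)
  expect_rel_error(sum(band), analytic, 0.10)

  # overlapping annuli of two nearby beads merge without double counting
  spec <- scene_spec(seed = 4, field_um = c(500, 500), pixel_size = 1,
                     beads = list(list(center = c(250, 160), radius_um = 70),
                                  list(center = c(250, 340), radius_um = 70)),
                     roles = "actin")
  bs2 <- detect_beads(render_scene(spec)$image)
  band2 <- bead_perimeter_band(bs2, 30)
  # oracle: per-pixel distance to the nearest bead pixel, by explicit loop
  bead_idx <- which(bs2$mask > 0)
  br <- (bead_idx - 1) %% nrow(bs2$mask) + 1
  bc <- (bead_idx - 1) %/% nrow(bs2$mask) + 1
  samp <- which(matrix(TRUE, nrow(bs2$mask), ncol(bs2$mask)))
  set.seed(1); samp <- sample(samp, 4000)
  for (i in samp) {
    ri <- (i - 1) %% nrow(bs2$mask) + 1
    ci <- (i - 1) %/% nrow(bs2$mask) + 1
    dmin <- sqrt(min((br - ri)^2 + (bc - ci)^2))
    expect_equal(band2[i], dmin <= 30 && bs2$mask[i] == 0L)
  }

  expect_equal(sum(bead_perimeter_band(detect_beads(
    image_from_planes(actin = matrix(0, 50, 50))), 10)), 0)
})
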