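test_that("empty masks give an empty skeleton and missing averages", {
  img <- image_from_planes(actin = matrix(0, 150, 150))
  beads <- detect_beads(img)
  sm <- segment_sprouts(img, beads)
  sk <- skeletonize_sprouts(sm, beads)
  expect_equal(sum(sk$skeleton), 0L)
  len <- measure_lengths(sk)
  expect_equal(len$total_sprout_length_um, 0)
  expect_true(is.na(len$avg_sprout_length_um))
  expect_true(is.na(measure_width(sm, sk)))
  expect_true(is.na(count_branch_points(sk)$avg_branch_points))
})

test_that("straight and diagonal tube lengths are recovered within 5%", {
  for (ang in c(0, 45)) {
    sc <- render_scene(one_bead_spec(
      seed = 21, field = 800, radius = 90,
      sprouts = radial_sprouts(1, length_um = 300, angles = ang)))
    r <- analyze_image(sc$image)
    expect_rel_error(r$total_sprout_length, 300, 0.05)
  }
})

test_that("skeletonization is idempotent after pruning", {
  sc <- render_scene(one_bead_spec(
    seed = 22, field = 800, radius = 90,
    sprouts = c(radial_sprouts(2, length_um = 250),
                branched_sprout(angle = 200, trunk = 220))))
  beads <- detect_beads(sc$image)
  sm <- segment_sprouts(sc$image, beads)
  sk <- skeletonize_sprouts(sm, beads)
  expect_equal(sproutr:::thin_mask(sk$skeleton), sk$skeleton)
})

test_that("every skeleton pixel lies inside the sprout mask", {
  sc <- render_scene(one_bead_spec(
    seed = 23, field = 700, radius = 90,
    sprouts = radial_sprouts(3, length_um = 200)))
  beads <- detect_beads(sc$image)
  sm <- segment_sprouts(sc$image, beads)
  sk <- skeletonize_sprouts(sm, beads)
  expect_equal(sum(sk$skeleton & !sm$mask), 0L)
})

test_that("per-sprout length arithmetic follows the drawn geometry", {
  # two tubes 200 and 400 um on one bead: total ~600, avg ~300
  sc <- render_scene(one_bead_spec(
    seed = 24, field = 1000, radius = 90,
    sprouts = list(list(bead = 1, angle_deg = 0, length_um = 400, width_um = 24,
                        wiggle_um = numeric(), branches = list()),
                   list(bead = 1, angle_deg = 180, length_um = 200,
                        width_um = 24, wiggle_um = numeric(), branches = list()))))
  r <- analyze_image(sc$image)
  expect_equal(r$n_sprouts, 2)
  expect_rel_error(r$total_sprout_length, 600, 0.05)
  expect_rel_error(r$avg_sprout_length, 300, 0.05)

  # a bifurcating sprout: trunk 150 plus two 100 um branches, one sprout
  scY <- render_scene(one_bead_spec(
    seed = 25, field = 800, radius = 90,
    sprouts = branched_sprout(trunk = 150, branches = list(
      list(at_frac = 1, angle_offset_deg = 35, length_um = 100),
      list(at_frac = 1, angle_offset_deg = -35, length_um = 100)))))
  rY <- analyze_image(scY$image)
  expect_equal(rY$n_sprouts, 1)
  expect_rel_error(rY$total_sprout_length, 350, 0.10)
  expect_equal(rY$avg_sprout_length, rY$total_sprout_length)
})

test_that("width = area / length recovers drawn widths and survives rescaling", {
  sc <- render_scene(one_bead_spec(
    seed = 26, field = 800, radius = 90,
    sprouts = radial_sprouts(1, length_um = 300, width_um = 30)))
  r <- analyze_image(sc$image)
  expect_rel_error(r$avg_sprout_width, 30, 0.10)

  # same geometry at double resolution: calibrated width within 2%
  spec <- one_bead_spec(seed = 26, field = 800, radius = 90,
                        sprouts = radial_sprouts(1, length_um = 300,
                                                 width_um = 30))
  spec$pixel_size <- 0.5
  spec$optics$psf_sigma_um <- 2
  r2 <- analyze_image(render_scene(spec)$image)
  expect_lt(abs(r2$avg_sprout_width / r$avg_sprout_width - 1), 0.02)
})

test_that("branch points count junction clusters once and average per sprout", {
  straight <- render_scene(one_bead_spec(
    seed = 27, field = 800, sprouts = radial_sprouts(1, length_um = 250)))
  expect_equal(analyze_image(straight$image)$avg_branch_points, 0)

  y <- render_scene(one_bead_spec(
    seed = 28, field = 800, sprouts = branched_sprout(trunk = 250)))
  expect_equal(analyze_image(y$image)$avg_branch_points, 1)

  yy <- render_scene(one_bead_spec(
    seed = 29, field = 800,
    sprouts = branched_sprout(trunk = 260, branches = list(
      list(at_frac = 0.45, angle_offset_deg = 40, length_um = 130),
      list(at_frac = 0.75, angle_offset_deg = -45, length_um = 110)))))
  expect_equal(analyze_image(yy$image)$avg_branch_points, 2)

  # one Y plus one straight sprout: 1 junction / 2 sprouts
  mix <- render_scene(one_bead_spec(
    seed = 30, field = 900,
    sprouts = c(branched_sprout(angle = 0, trunk = 250),
                radial_sprouts(1, length_um = 250, angles = 180))))
  expect_equal(analyze_image(mix$image)$avg_branch_points, 0.5)
})

test_that("junction clusters never exceed the count of high-degree pixels", {
  sc <- render_scene(one_bead_spec(
    seed = 31, field = 800,
    sprouts = c(branched_sprout(angle = 30, trunk = 240),
                branched_sprout(angle = 200, trunk = 230))))
  beads <- detect_beads(sc$image)
  sm <- segment_sprouts(sc$image, beads)
  sk <- skeletonize_sprouts(sm, beads)
  n_high <- sum(sk$skeleton & sproutr:::nbcount8(sk$skeleton) >= 3)
  expect_lte(nrow(sk$junctions), n_high)
  expect_gte(nrow(sk$junctions), 2)
})

test_that("total skeleton length is invariant under scene rotation", {
  spec <- random_scene(seed = 32, n_beads = 1, field_um = c(1000, 1000),
                       sprouts_per_bead = 3, sprout_length_um = c(150, 280),
                       roles = "actin")
  lens <- vapply(c(0, 45, 90), function(ang)
    analyze_image(render_scene(rotate_scene(spec, ang))$image)$total_sprout_length,
    numeric(1))
  expect_lt(max(abs(lens / lens[1] - 1)), 0.05)
})
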