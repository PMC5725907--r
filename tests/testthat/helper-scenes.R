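# Scene builders shared across the suite. Small fields keep tests fast;
# geometry is chosen so ground truth is unambiguous.

# a single bead at the field center
one_bead_spec <- function(seed = 1, field = 700, radius = 90, sprouts = list(),
                          roles = "actin", ...) {
  scene_spec(seed = seed, field_um = c(field, field), pixel_size = 1,
             beads = list(list(center = c(field / 2, field / 2),
                               radius_um = radius)),
             sprouts = sprouts, roles = roles, ...)
}

# n straight tubes drawn radially from the central bead
radial_sprouts <- function(n, length_um = 250, width_um = 24,
                           angles = seq(0, 360, length.out = n + 1)[-1]) {
  lapply(seq_len(n), function(i)
    list(bead = 1, angle_deg = angles[i], length_um = length_um,
         width_um = width_um, wiggle_um = numeric(), branches = list()))
}

# Y-shaped sprout: trunk with one or more side branches
branched_sprout <- function(angle = 0, trunk = 250, width = 24,
                            branches = list(list(at_frac = 0.55,
                                                 angle_offset_deg = 40,
                                                 length_um = 120))) {
  list(list(bead = 1, angle_deg = angle, length_um = trunk, width_um = width,
            wiggle_um = numeric(), branches = branches))
}

# a flat (noise-free, unblurred) multi-channel image built from matrices
image_from_planes <- function(..., pixel_size = 1) {
  multichannel_image(list(...), pixel_size = pixel_size, source_id = "manual")
}

expect_rel_error <- function(measured, truth, tol) {
  expect_lt(abs(measured / truth - 1), tol)
}
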