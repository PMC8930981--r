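# Fixtures built in code.

# Minimal bilateral toy: one mirrored bundle pair pulling straight dorsal
# at in-lever `r_in` with total (both sides) force `total_force` N at
# 30 N/cm^2, bite point `r_out` mm anterior of the hinge. Closed-pose
# lever-law force = total_force * r_in / r_out.
toy_vertical_pair <- function(r_in = 10, r_out = 40, total_force = 10,
                              h = 20, half_width = 5,
                              bite_label = "jaw_tip") {
  acsa <- total_force / (2 * 30)
  mu <- data.frame(name = "pair", group = "external_adductor", side = "left",
                   origin_x = r_in, origin_y = half_width, origin_z = h,
                   insertion_x = r_in, insertion_y = half_width,
                   insertion_z = 0,
                   acsa = acsa, volume = NA_real_, fiber_length = NA_real_,
                   stringsAsFactors = FALSE)
  bp <- data.frame(label = bite_label, x = r_out, y = 0, z = 0,
                   stringsAsFactors = FALSE)
  mirror_unilateral(jaw_model(c(0, half_width, 0), c(0, -half_width, 0),
                              mu, bp))
}

# Unilateral (left-only) model for mirroring tests.
toy_unilateral <- function() {
  mu <- data.frame(name = c("a", "b"),
                   group = c("external_adductor", "pterygoideus"),
                   side = "left",
                   origin_x = c(5, 3), origin_y = c(4, 5),
                   origin_z = c(15, 12),
                   insertion_x = c(10, 8), insertion_y = c(5, 5),
                   insertion_z = c(0, 1),
                   acsa = c(0.4, 0.3), volume = c(0.8, 0.6),
                   fiber_length = c(2, 2),
                   stringsAsFactors = FALSE)
  bp <- data.frame(label = c("jaw_tip", "posterior_most"),
                   x = c(35, 14), y = 0, z = 0, stringsAsFactors = FALSE)
  jaw_model(c(0, 5, 0), c(0, -5, 0), mu, bp)
}

path_planar_toy <- function() {
  p <- system.file("extdata", "planar_toy.json", package = "jawstatics")
  if (!nzchar(p)) p <- testthat::test_path("..", "..", "inst", "extdata",
                                           "planar_toy.json")
  p
}

# The published bite-force table: the per-(bite point, gape) maxima the
# percent-of-max report is checked against.
printed_force_table <- function() {
  data.frame(
    bite_point = rep(c("posterior_most", "jaw_tip", "posterior_caniniform",
                       "anterior_caniniform"), each = 3),
    gape_deg = rep(c(10, 30, 60), times = 4),
    bite_force_N = c(256, 229, 159,
                     143, 128, 89,
                     178, 159, 110,
                     172, 154, 107),
    stringsAsFactors = FALSE)
}
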