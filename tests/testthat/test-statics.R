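test_that("moment about an axis is the axial torque component", {
  expect_equal(moment_about_axis(c(0, 0, 10), c(10, 0, 0), c(0, 0, 0),
                                 c(0, 1, 0)), -100)
  # force applied on the axis, or parallel to its position vector: no moment
  expect_equal(moment_about_axis(c(3, 0, 1), c(0, 5, 0), c(0, 0, 0),
                                 c(0, 1, 0)), 0)
  expect_equal(moment_about_axis(c(2, 0, 2), c(1, 0, 1), c(0, 0, 0),
                                 c(0, 1, 0)), 0)
  expect_error(moment_about_axis(c(1, 0, 0), c(0, 0, 1), c(0, 0, 0),
                                 c(0, 2, 0)), "unit")
})

test_that("the solver reproduces the scalar lever law on the planar toy", {
  m <- toy_vertical_pair(r_in = 10, r_out = 40, total_force = 10)
  expect_equal(solve_bite_force(m, "jaw_tip", 0, 0, 30)$bite_force, 2.5,
               tolerance = 1e-12)
  m2 <- toy_vertical_pair(r_in = 10, r_out = 20, total_force = 10)
  expect_equal(solve_bite_force(m2, "jaw_tip", 0, 0, 30)$bite_force, 5,
               tolerance = 1e-12)

  # out-lever law: force x out-lever constant across collinear bite points
  fr <- vapply(c(15, 20, 30, 40), function(r)
    solve_bite_force(toy_vertical_pair(r_out = r), "jaw_tip",
                     0, 0, 30)$bite_force * r, numeric(1))
  expect_equal(max(fr) - min(fr), 0, tolerance = 1e-9)
})

test_that("solver matches the brute-force equilibrium oracle on seeded random jaws", {
  worst <- 0
  for (s in 1:100) {
    m <- make_random_jaw(seed = s)
    gape <- c(10, 30, 60)[(s %% 3) + 1]
    orient <- c(-25, -10, 0, 10, 25)[(s %% 5) + 1]
    lab <- m$bite_points$label[(s %% 4) + 1]
    got <- suppressWarnings(solve_bite_force(m, lab, gape, orient, 30))
    ref <- oracle_solve(m, lab, gape, orient, 30)
    if (ref$bite_force < 0) {
      # an orientation the jaw cannot resist: solver clamps by design
      expect_true(got$clamped)
      expect_identical(got$bite_force, 0)
      next
    }
    worst <- max(worst,
                 abs(got$bite_force - ref$bite_force) /
                   max(abs(ref$bite_force), 1e-12),
                 max(abs(got$joint_force - ref$joint_force)) /
                   max(sqrt(sum(ref$joint_force^2)), 1e-12))
  }
  expect_lt(worst, 1e-9)
})

test_that("every solution is in exact force and hinge-moment balance", {
  for (s in c(2, 17, 123)) {
    m <- make_random_jaw(seed = s)
    for (g in c(10, 30, 60)) for (o in c(-30, 0, 30)) {
      sol <- suppressWarnings(
        solve_bite_force(m, "anterior_caniniform", g, o, 30))
      pose <- open_jaw(m, g)
      ja <- joint_axis(pose)
      mf <- jawstatics:::muscle_forces(pose, 30)
      fmus <- colSums(mf$direction * mf$magnitude)
      resid <- fmus - sol$bite_force * sol$bite_direction + sol$joint_force
      expect_lt(max(abs(resid)), 1e-9)
      if (sol$clamped) next  # a clamped zero force cannot balance the moment
      bp <- jawstatics:::bite_point_position(pose, "anterior_caniniform")
      mom <- sol$muscle_moment +
        moment_about_axis(-sol$bite_force * sol$bite_direction, bp,
                          ja$center, ja$axis)
      expect_lt(abs(mom), 1e-9)
    }
  }
})

test_that("bite force is linear in stress and area, invariant to geometric scale", {
  m <- make_random_jaw(seed = 5)
  f1 <- solve_bite_force(m, "jaw_tip", 30, 10, 30)$bite_force
  expect_equal(solve_bite_force(m, "jaw_tip", 30, 10, 60)$bite_force, 2 * f1,
               tolerance = 1e-12)
  m2 <- m; m2$muscles$acsa <- 2 * m2$muscles$acsa
  expect_equal(solve_bite_force(m2, "jaw_tip", 30, 10, 30)$bite_force, 2 * f1,
               tolerance = 1e-12)
  m3 <- m
  for (cols in list(c("origin_x", "origin_y", "origin_z"),
                    c("insertion_x", "insertion_y", "insertion_z")))
    m3$muscles[, cols] <- 3 * m3$muscles[, cols]
  m3$bite_points[, c("x", "y", "z")] <- 3 * m3$bite_points[, c("x", "y", "z")]
  m3$joint_left <- 3 * m3$joint_left; m3$joint_right <- 3 * m3$joint_right
  expect_equal(solve_bite_force(m3, "jaw_tip", 30, 10, 30)$bite_force, f1,
               tolerance = 1e-12)
})

test_that("degenerate and jaw-opening reaction orientations are handled", {
  m <- toy_vertical_pair()
  # at gape 0 a bite point on the x-axis has a vanishing arm near +/-90,
  # but those orientations are rejected by the domain check
  expect_error(solve_bite_force(m, "jaw_tip", 0, 90, 30), "orientation")
  # orientation past the perpendicular at high gape flips the arm sign:
  # clamped to zero with a warning, not an error
  m60 <- open_jaw(m, 60)
  expect_warning(s <- solve_bite_force(m, "jaw_tip", 60, -40, 30),
                 "clamped")
  expect_identical(s$bite_force, 0)
  expect_true(s$clamped)
  # a unilateral model is accepted with a warning
  expect_warning(solve_bite_force(toy_unilateral(), "jaw_tip", 10, 0, 30),
                 "unilateral")
})

test_that("the sweep enumerates gape x bite point x orientation and flags cell maxima", {
  m <- toy_vertical_pair()
  res <- run_simulation(m, simulation_config())
  expect_equal(nrow(res), 3 * 1 * 13)
  expect_equal(sum(res$is_max), 3)
  expect_true(all(res$status %in% c("ok", "clamped", "unsolvable")))

  # doubling all areas doubles every solvable force
  m2 <- m; m2$muscles$acsa <- 2 * m2$muscles$acsa
  res2 <- run_simulation(m2, simulation_config())
  expect_equal(res2$bite_force_N, 2 * res$bite_force_N, tolerance = 1e-12)

  # per-row failures are recorded and the run continues: at gape 30 the
  # -60 deg reaction acts along the jaw-to-bite-point line (zero arm)
  res3 <- run_simulation(m, simulation_config(
    gapes_deg = 30, orientation_min = -60, orientation_max = 0,
    orientation_step = 30))
  expect_equal(nrow(res3), 3)
  expect_equal(res3$status, c("unsolvable", "ok", "ok"))
  expect_true(is.na(res3$bite_force_N[1]))
})

test_that("planar-toy vertical bite force is non-increasing in gape", {
  # at a vertical (orientation-0) food reaction the above-joint-origin toy
  # loses force monotonically as the jaw opens; a max over a sweep that
  # includes near-singular reaction orientations (arm -> 0) would not,
  # which is why the headline sweep stays clear of +/-90 deg
  pj <- make_planar_jaw(seed = 0)
  res <- run_simulation(pj$model, simulation_config(
    orientation_min = 0, orientation_max = 0, orientation_step = 5))
  for (bp in unique(res$bite_point)) {
    f <- res$bite_force_N[res$bite_point == bp][order(c(10, 30, 60))]
    expect_true(all(diff(f) <= 1e-9))
  }
  # and the generator's closed form says the same at every gape
  for (bp in unique(pj$expected$bite_point)) {
    e <- pj$expected[pj$expected$bite_point == bp, ]
    expect_true(all(diff(e$bite_force_N[order(e$gape_deg)]) < 0))
  }
})

test_that("percent-of-max annotates forces relative to the global maximum", {
  tab <- data.frame(bite_point = c("posterior_most", "jaw_tip"),
                    gape_deg = 10,
                    bite_force_N = c(256, 143))
  p <- percent_of_max(tab)
  expect_equal(p$pct_of_max, c(100L, 56L))

  tab2 <- data.frame(bite_force_N = c(256, 229))
  expect_equal(percent_of_max(tab2)$pct_of_max, c(100L, 89L))

  expect_equal(percent_of_max(data.frame(bite_force_N = 7))$pct_of_max, 100L)
  expect_error(percent_of_max(data.frame(bite_force_N = numeric(0))),
               "non-empty")

  # round-half-up, not banker's rounding: 50.5% of max reads 51
  expect_equal(percent_of_max(
    data.frame(bite_force_N = c(200, 101)))$pct_of_max, c(100L, 51L))
})
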