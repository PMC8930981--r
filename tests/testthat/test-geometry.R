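test_that("joint axis is the right-to-left unit line through the joint midpoint", {
  m <- toy_vertical_pair()
  ja <- joint_axis(m)
  expect_equal(ja$center, c(0, 0, 0))
  expect_equal(ja$axis, c(0, 1, 0))

  m2 <- toy_vertical_pair()
  m2$joint_left <- c(3, 6, 2); m2$joint_right <- c(1, -4, 2)
  ja2 <- joint_axis(m2)
  expect_equal(ja2$center, c(2, 1, 2))
  expect_equal(ja2$axis, c(2, 10, 0) / sqrt(104))

  m2$joint_right <- m2$joint_left
  expect_error(joint_axis(m2), "degenerate")
})

test_that("Rodrigues rotation follows the right-hand rule and is an isometry", {
  expect_equal(rotate_about_axis(c(10, 0, 0), c(0, 0, 0), c(0, 1, 0), 90),
               c(0, 0, -10))
  # point on the axis and zero angle are fixed points
  expect_equal(rotate_about_axis(c(0, 3, 0), c(0, 0, 0), c(0, 1, 0), 57),
               c(0, 3, 0))
  p <- c(4, -2, 7)
  expect_equal(rotate_about_axis(p, c(1, 1, 1), c(0, 0, 1), 0), p)
  expect_error(rotate_about_axis(p, c(0, 0, 0), c(0, 2, 0), 30), "unit")

  # distance to the axis preserved for random cases
  set.seed(42)
  for (i in 1:20) {
    ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
    ctr <- rnorm(3); p <- rnorm(3) * 10; ang <- runif(1, -180, 180)
    q <- rotate_about_axis(p, ctr, ax, ang)
    dist_axis <- function(x) {
      r <- x - ctr; sqrt(sum((r - sum(r * ax) * ax)^2))
    }
    expect_equal(dist_axis(q), dist_axis(p), tolerance = 1e-12)
  }
})

test_that("opening the jaw lowers the tip, preserves axis distances, and is a group action", {
  m <- toy_vertical_pair()
  tip0 <- bite_point_z <- m$bite_points$z[1]
  m30 <- open_jaw(m, 30)
  expect_lt(m30$bite_points$z[1], tip0)     # ventral motion
  expect_identical(open_jaw(m, 0), m)       # gape == reference: unchanged
  expect_error(open_jaw(m, 95), "90")
  expect_error(open_jaw(m, -5), "90")

  # insertion distance to the hinge axis is invariant
  ja <- joint_axis(m)
  d_axis <- function(mm) {
    ins <- as.matrix(mm$muscles[, c("insertion_x", "insertion_y", "insertion_z")])
    apply(ins, 1, function(p) {
      r <- p - ja$center; sqrt(sum((r - sum(r * ja$axis) * ja$axis)^2))
    })
  }
  expect_equal(d_axis(m30), d_axis(m), tolerance = 1e-12)

  # group action: opening to a then to b equals opening straight to b
  m_ab <- open_jaw(open_jaw(m, 20), 55)
  m_b <- open_jaw(m, 55)
  expect_equal(as.matrix(m_ab$bite_points[, c("x", "y", "z")]),
               as.matrix(m_b$bite_points[, c("x", "y", "z")]),
               tolerance = 1e-9)
  expect_equal(m_ab$muscles$insertion_z, m_b$muscles$insertion_z,
               tolerance = 1e-9)
  # cranial side untouched
  expect_equal(m_b$muscles$origin_z, m$muscles$origin_z)
})

test_that("mirroring reflects across the sagittal plane exactly once", {
  u <- toy_unilateral()
  b <- mirror_unilateral(u)
  expect_equal(nrow(b$muscles), 2 * nrow(u$muscles))
  right <- b$muscles[b$muscles$side == "right", ]
  expect_equal(right$insertion_y, -u$muscles$insertion_y)
  expect_equal(right$origin_y, -u$muscles$origin_y)
  expect_equal(right$acsa, u$muscles$acsa)     # areas and groups preserved
  expect_equal(right$group, u$muscles$group)
  expect_error(mirror_unilateral(b), "bilateral")

  # symmetric geometry: mirrored model's hinge moment doubles
  ja <- joint_axis(b)
  mom <- function(mm) {
    mf <- jawstatics:::muscle_forces(mm, 30)
    sum(vapply(seq_len(nrow(mf$application)), function(i)
      moment_about_axis(mf$direction[i, ] * mf$magnitude[i],
                        mf$application[i, ], ja$center, ja$axis),
      numeric(1)))
  }
  expect_equal(mom(b), 2 * mom(u), tolerance = 1e-12)
})

test_that("model validation collects all invariant violations", {
  mu <- data.frame(name = "m", group = "external_adductor", side = "left",
                   origin_x = 1, origin_y = 1, origin_z = 1,
                   insertion_x = 1, insertion_y = 1, insertion_z = 1,
                   acsa = -1, volume = NA_real_, fiber_length = NA_real_)
  bp <- data.frame(label = "jaw_tip", x = 0, y = 0, z = 0)  # on the axis
  err <- tryCatch(jaw_model(c(0, 5, 0), c(0, -5, 0), mu, bp),
                  error = function(e) conditionMessage(e))
  expect_match(err, "acsa")
  expect_match(err, "origin equals insertion")
  expect_match(err, "hinge axis")
})

test_that("geometry files load, validate, convert units and round-trip", {
  p <- path_planar_toy()
  m <- load_jaw_model(p)
  expect_s3_class(m, "jaw_model")
  expect_equal(nrow(m$muscles), 2)
  expect_equal(m$bite_points$label, "jaw_tip")

  # write -> load round-trips every schema field bit-identically
  tmp <- withr::local_tempfile(fileext = ".json")
  write_jaw_model(m, tmp)
  m2 <- load_jaw_model(tmp)
  expect_identical(m2$joint_left, m$joint_left)
  expect_identical(m2$muscles, m$muscles)
  expect_identical(m2$bite_points, m$bite_points)
  expect_identical(m2$gape_reference_deg, m$gape_reference_deg)

  # unknown top-level keys survive the round trip
  j <- jsonlite::fromJSON(p, simplifyVector = FALSE)
  j$provenance <- list(specimen = "synthetic toy", digitizer = "none")
  tmp2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(j, tmp2, auto_unbox = TRUE, digits = NA)
  m3 <- load_jaw_model(tmp2)
  expect_equal(m3$extra$provenance$specimen, "synthetic toy")
  tmp3 <- withr::local_tempfile(fileext = ".json")
  write_jaw_model(m3, tmp3)
  expect_equal(load_jaw_model(tmp3)$extra, m3$extra)

  # cm lengths and mm^2 areas are converted to mm / cm^2
  j2 <- jsonlite::fromJSON(p, simplifyVector = FALSE)
  j2$units <- list(length = "cm", area = "mm2")
  tmp4 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(j2, tmp4, auto_unbox = TRUE, digits = NA)
  m4 <- load_jaw_model(tmp4)
  expect_equal(m4$joint_left, 10 * m$joint_left)
  expect_equal(m4$muscles$acsa, m$muscles$acsa / 100)

  # schema violations name the offending field
  j3 <- jsonlite::fromJSON(p, simplifyVector = FALSE)
  j3$muscles[[1]]$acsa <- -1
  tmp5 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(j3, tmp5, auto_unbox = TRUE, digits = NA)
  expect_error(load_jaw_model(tmp5), "acsa")
  expect_error(load_jaw_model("no/such/file.json"), "not found")
})

test_that("the packaged planar toy solves to its closed-form lever value", {
  m <- load_jaw_model(path_planar_toy())
  # one mirrored pair, 30 N total, in-lever 10 mm, out-lever 40 mm
  s <- solve_bite_force(m, "jaw_tip", 0, 0, 30)
  expect_equal(s$bite_force, sum(m$muscles$acsa) * 30 * 10 / 40,
               tolerance = 1e-12)
})
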