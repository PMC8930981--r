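# Static force equilibrium of the mandible, treated as a rigid body on an
# ideal hinge (both quadrate-articular joints collapsed to one axis). Three
# force systems act on it: the adductor muscle forces, the food reaction at
# the bite point, and the joint reaction. The scalar moment balance about
# the hinge axis yields the bite force; the vector force balance then yields
# the joint reaction.

#' Moment of a force about an axis
#'
#' Scalar moment `((p - center) x force) . axis` in N.mm: the component of
#' the torque about `center` along the (unit) hinge axis.
#'
#' @param force 3-vector, N.
#' @param application_point 3-vector, mm.
#' @param center point on the axis, mm.
#' @param axis unit 3-vector.
#' @return signed scalar moment, N.mm.
#' @export
moment_about_axis <- function(force, application_point, center, axis) {
  force <- as_point3(force, "force")
  application_point <- as_point3(application_point, "application_point")
  center <- as_point3(center, "center")
  axis <- as_point3(axis, "axis")
  if (abs(vec_norm(axis) - 1) > 1e-8)
    stop("'axis' must be unit length", call. = FALSE)
  sum(cross3(application_point - center, force) * axis)
}

# Direction of the bite force (jaw on food) for a reaction orientation.
# Orientation 0 is "vertical" in the closed-skull frame (+z, perpendicular
# to the occlusal plane of the closed jaw); the angle rotates that direction
# within the plane perpendicular to the hinge axis, right-hand rule about
# +axis. The food sets this direction, so it does not rotate with gape.
reaction_direction <- function(axis, angle_deg) {
  if (!is.finite(angle_deg) || angle_deg <= -90 || angle_deg >= 90)
    stop("reaction orientation must lie in (-90, 90) degrees", call. = FALSE)
  up <- c(0, 0, 1)
  up_perp <- up - sum(up * axis) * axis   # project into plane perp. to axis
  if (vec_norm(up_perp) < 1e-9)
    stop("hinge axis is vertical; reaction orientation undefined", call. = FALSE)
  base <- up_perp / vec_norm(up_perp)
  th <- angle_deg * pi / 180
  v <- base * cos(th) + cross3(axis, base) * sin(th)
  v / vec_norm(v)
}

#' Simulation configuration
#'
#' @param gapes_deg gape angles in degrees (default 10, 30, 60).
#' @param bite_points bite-point labels to solve at; `NULL` means every
#'   bite point present in the model.
#' @param orientation_min,orientation_max,orientation_step sweep of the
#'   food-reaction orientation, degrees (default -30 to +30 by 5).
#' @param muscle_stress muscle stress, N/cm^2 (default 30).
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(gapes_deg = c(10, 30, 60), bite_points = NULL,
                              orientation_min = -30, orientation_max = 30,
                              orientation_step = 5, muscle_stress = 30) {
  if (any(!is.finite(gapes_deg) | gapes_deg < 0 | gapes_deg >= 90))
    stop("gape angles must lie in [0, 90)", call. = FALSE)
  if (!is.finite(orientation_step) || orientation_step <= 0)
    stop("orientation_step must be > 0", call. = FALSE)
  if (orientation_min > orientation_max)
    stop("orientation_min must not exceed orientation_max", call. = FALSE)
  if (!is.finite(muscle_stress) || muscle_stress <= 0)
    stop("muscle_stress must be > 0", call. = FALSE)
  structure(list(gapes_deg = gapes_deg, bite_points = bite_points,
                 orientation_min = orientation_min,
                 orientation_max = orientation_max,
                 orientation_step = orientation_step,
                 muscle_stress = muscle_stress),
            class = "simulation_config")
}

#' Solve the static bite force at one condition
#'
#' Poses the model at `gape_deg`, sets every adductor maximally active
#' (force = acsa x stress along the straight insertion -> origin line),
#' sums their moments about the hinge axis, and solves the moment balance
#' for the bite-force magnitude along the chosen food-reaction direction.
#' The joint reaction is whatever force closes the vector balance
#' (muscles + bite reaction + joint = 0).
#'
#' A reaction orientation whose moment arm at the bite point vanishes
#' (< 1e-9 mm) is unsolvable and raises an error; an orientation the jaw
#' cannot resist (negative solved force) is clamped to zero with
#' `clamped = TRUE` and a warning.
#'
#' @param model a bilateral `jaw_model` (a unilateral model is accepted
#'   with a warning).
#' @param bite_point_label which bite point to load.
#' @param gape_deg gape angle, degrees.
#' @param orientation_deg food-reaction orientation, degrees in (-90, 90);
#'   0 is a vertical bite.
#' @param stress muscle stress, N/cm^2.
#' @return object of class `bite_solution`: `bite_force` (N), `joint_force`
#'   (3-vector, N), `joint_force_magnitude`, `joint_force_orientation`
#'   (degrees from vertical in the sagittal projection, positive tipped
#'   anteriorly), `muscle_moment` (N.mm about the hinge axis), `clamped`,
#'   and the condition labels.
#' @export
solve_bite_force <- function(model, bite_point_label, gape_deg,
                             orientation_deg = 0, stress = 30) {
  if (length(unique(model$muscles$side)) < 2L)
    warning("model is unilateral; forces reflect one side's muscles only",
            call. = FALSE)
  pose <- open_jaw(model, gape_deg)
  ja <- joint_axis(pose)
  mf <- muscle_forces(pose, stress)

  fvec <- mf$direction * mf$magnitude          # n x 3 force vectors
  rel <- sweep(mf$application, 2L, ja$center)  # moment arms about center
  # torque_i = r_i x F_i ; component along axis
  tx <- rel[, 2L] * fvec[, 3L] - rel[, 3L] * fvec[, 2L]
  ty <- rel[, 3L] * fvec[, 1L] - rel[, 1L] * fvec[, 3L]
  tz <- rel[, 1L] * fvec[, 2L] - rel[, 2L] * fvec[, 1L]
  muscle_moment <- sum(tx * ja$axis[1L] + ty * ja$axis[2L] + tz * ja$axis[3L])

  u <- reaction_direction(ja$axis, orientation_deg)
  bp <- bite_point_position(pose, bite_point_label)
  arm <- moment_about_axis(u, bp, ja$center, ja$axis)
  if (abs(arm) < 1e-9)
    stop(sprintf(
      "unsolvable reaction orientation %g deg at '%s': moment arm below 1e-9 mm",
      orientation_deg, bite_point_label), call. = FALSE)

  f <- muscle_moment / arm
  clamped <- FALSE
  if (f < 0) {
    clamped <- TRUE
    f <- 0
    warning(sprintf(
      "reaction orientation %g deg at '%s' would open the jaw; bite force clamped to 0",
      orientation_deg, bite_point_label), call. = FALSE)
  }

  bite_reaction <- -f * u                       # food pushing on the jaw
  joint <- -(colSums(fvec) + bite_reaction)
  structure(list(
    bite_point = bite_point_label,
    gape_deg = gape_deg,
    orientation_deg = orientation_deg,
    bite_force = f,
    bite_direction = u,
    joint_force = joint,
    joint_force_magnitude = vec_norm(joint),
    joint_force_orientation = atan2(joint[1L], joint[3L]) * 180 / pi,
    muscle_moment = muscle_moment,
    bite_moment_arm = arm,
    clamped = clamped
  ), class = "bite_solution")
}

#' @export
print.bite_solution <- function(x, ...) {
  cat(sprintf("<bite_solution> %s @ gape %g deg, orientation %g deg\n",
              x$bite_point, x$gape_deg, x$orientation_deg))
  cat(sprintf("  bite force: %.3f N%s\n", x$bite_force,
              if (x$clamped) " (clamped)" else ""))
  cat(sprintf("  joint force: %.3f N at %.1f deg from vertical (sagittal)\n",
              x$joint_force_magnitude, x$joint_force_orientation))
  invisible(x)
}

#' Sweep gapes, bite points and reaction orientations
#'
#' One solved condition per row of the gape x bite point x orientation
#' grid. Solver failures for single rows (e.g. an unsolvable orientation)
#' are recorded in the `status` column and the sweep continues. The row
#' with the largest bite force within each (gape, bite point) cell is
#' flagged `is_max`; that maximum is the headline force for the cell.
#'
#' @param model a `jaw_model`.
#' @param config a [simulation_config()].
#' @return data frame with columns `bite_point`, `gape_deg`,
#'   `orientation_deg`, `bite_force_N`, `joint_force_N`, `joint_angle_deg`,
#'   `status` (`ok`/`clamped`/`unsolvable`), `is_max`.
#' @export
run_simulation <- function(model, config = simulation_config()) {
  labels <- config$bite_points
  if (is.null(labels)) labels <- model$bite_points$label
  orient <- seq(config$orientation_min, config$orientation_max,
                by = config$orientation_step)
  grid <- expand.grid(orientation_deg = orient, bite_point = labels,
                      gape_deg = config$gapes_deg,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    sol <- tryCatch(
      withCallingHandlers(
        solve_bite_force(model, g$bite_point, g$gape_deg, g$orientation_deg,
                         stress = config$muscle_stress),
        warning = function(w) invokeRestart("muffleWarning")),
      error = function(e) NULL)
    if (is.null(sol)) {
      data.frame(bite_point = g$bite_point, gape_deg = g$gape_deg,
                 orientation_deg = g$orientation_deg,
                 bite_force_N = NA_real_, joint_force_N = NA_real_,
                 joint_angle_deg = NA_real_, status = "unsolvable",
                 stringsAsFactors = FALSE)
    } else {
      data.frame(bite_point = g$bite_point, gape_deg = g$gape_deg,
                 orientation_deg = g$orientation_deg,
                 bite_force_N = sol$bite_force,
                 joint_force_N = sol$joint_force_magnitude,
                 joint_angle_deg = sol$joint_force_orientation,
                 status = if (sol$clamped) "clamped" else "ok",
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  out$is_max <- FALSE
  cells <- split(seq_len(nrow(out)),
                 list(out$bite_point, out$gape_deg), drop = TRUE)
  for (idx in cells) {
    f <- out$bite_force_N[idx]
    if (all(is.na(f))) next
    out$is_max[idx[which.max(f)]] <- TRUE
  }
  out
}

#' Percent-of-maximum report
#'
#' Annotates every solved condition with its bite force as a percentage of
#' the global maximum, rounded half-up to integer percent (the maximum row
#' reads 100).
#'
#' @param results data frame with a `bite_force_N` column (e.g. from
#'   [run_simulation()]).
#' @return `results` with an integer `pct_of_max` column.
#' @export
percent_of_max <- function(results) {
  results <- as.data.frame(results)
  if (!nrow(results) || !"bite_force_N" %in% names(results))
    stop("'results' must be a non-empty table with a bite_force_N column",
         call. = FALSE)
  mx <- suppressWarnings(max(results$bite_force_N, na.rm = TRUE))
  if (!is.finite(mx) || mx <= 0)
    stop("no positive bite force in 'results'", call. = FALSE)
  results$pct_of_max <- ifelse(
    is.na(results$bite_force_N), NA_integer_,
    as.integer(floor(100 * results$bite_force_N / mx + 0.5)))
  results
}
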