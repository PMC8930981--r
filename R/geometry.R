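#' @keywords internal
"_PACKAGE"

#' @importFrom stats lm coef confint predict runif rnorm setNames aggregate
#' @importFrom jsonlite fromJSON write_json
NULL

# Recognised muscle groups and bite-point labels. Coordinate frame throughout:
# right-handed, millimetres, +x anterior, +y toward the animal's left,
# +z dorsal. Areas in cm^2, volumes cm^3, fiber lengths cm.
MUSCLE_GROUPS <- c("external_adductor", "pseudotemporalis", "pterygoideus",
                   "posterior_adductor")
BITE_POINT_LABELS <- c("jaw_tip", "anterior_caniniform",
                       "posterior_caniniform", "posterior_most")

as_point3 <- function(p, what = "point") {
  p <- suppressWarnings(as.numeric(unlist(p)))
  if (length(p) != 3L || anyNA(p) || !all(is.finite(p)))
    stop(sprintf("'%s' must be a finite numeric 3-vector", what), call. = FALSE)
  unname(p)
}

vec_norm <- function(v) sqrt(sum(v * v))

unit_vector <- function(v, what = "vector") {
  n <- vec_norm(v)
  if (n < 1e-12)
    stop(sprintf("cannot normalise zero-length %s", what), call. = FALSE)
  v / n
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Construct a jaw model
#'
#' A `jaw_model` bundles the rigid geometry the static bite solver needs:
#' the two quadrate-articular joint centers (whose connecting line is the
#' hinge axis), the adductor muscle bundles with their origins (cranium),
#' insertions (mandible) and cross-sectional areas, and the bite points
#' along the tooth row. Coordinates are millimetres in a right-handed frame
#' with +x anterior, +y toward the animal's left and +z dorsal; areas are
#' cm^2.
#'
#' @param joint_left,joint_right numeric 3-vectors, joint centers (mm).
#' @param muscles data frame with columns `name`, `group` (one of
#'   `r paste(MUSCLE_GROUPS, collapse = ", ")`), `side` (`left`/`right`),
#'   `origin_x/y/z`, `insertion_x/y/z` (mm), `acsa` (cm^2) and optionally
#'   `volume` (cm^3) and `fiber_length` (cm).
#' @param bite_points data frame with columns `label` (one of
#'   `r paste(BITE_POINT_LABELS, collapse = ", ")`) and `x`, `y`, `z` (mm).
#' @param gape_reference_deg gape angle (degrees) of the digitized pose;
#'   0 means the jaw was digitized closed.
#' @param extra named list of unknown top-level keys from a geometry file,
#'   preserved on write.
#' @return validated object of class `jaw_model`.
#' @seealso [load_jaw_model()], [open_jaw()], [solve_bite_force()]
#' @export
jaw_model <- function(joint_left, joint_right, muscles, bite_points,
                      gape_reference_deg = 0, extra = list()) {
  m <- structure(list(
    joint_left = as_point3(joint_left, "joint_left"),
    joint_right = as_point3(joint_right, "joint_right"),
    muscles = as.data.frame(muscles, stringsAsFactors = FALSE),
    bite_points = as.data.frame(bite_points, stringsAsFactors = FALSE),
    gape_reference_deg = as.numeric(gape_reference_deg),
    extra = extra
  ), class = "jaw_model")
  validate_jaw_model(m)
}

#' Validate a jaw model
#'
#' Checks every structural invariant (distinct joints, at least one muscle
#' and bite point, positive areas, origin distinct from insertion, unique
#' bite-point labels, no bite point on the hinge axis) and throws a single
#' error listing all violations.
#'
#' @param model a `jaw_model`.
#' @return the model, invisibly usable in pipelines (returned visibly).
#' @export
validate_jaw_model <- function(model) {
  bad <- character(0)
  mu <- model$muscles
  bp <- model$bite_points

  if (vec_norm(model$joint_left - model$joint_right) < 1e-9)
    bad <- c(bad, "joint_left and joint_right coincide (degenerate hinge axis)")
  if (!is.finite(model$gape_reference_deg) ||
      model$gape_reference_deg < 0 || model$gape_reference_deg >= 90)
    bad <- c(bad, "gape_reference_deg must lie in [0, 90)")

  need_mu <- c("name", "group", "side", "origin_x", "origin_y", "origin_z",
               "insertion_x", "insertion_y", "insertion_z", "acsa")
  if (nrow(mu) < 1L) {
    bad <- c(bad, "model needs at least one muscle bundle")
  } else if (!all(need_mu %in% names(mu))) {
    bad <- c(bad, sprintf("muscles missing column(s): %s",
                          paste(setdiff(need_mu, names(mu)), collapse = ", ")))
  } else {
    if (!all(mu$group %in% MUSCLE_GROUPS))
      bad <- c(bad, sprintf("unknown muscle group(s): %s",
                            paste(unique(setdiff(mu$group, MUSCLE_GROUPS)),
                                  collapse = ", ")))
    if (!all(mu$side %in% c("left", "right")))
      bad <- c(bad, "muscle side must be 'left' or 'right'")
    if (any(!is.finite(mu$acsa) | mu$acsa <= 0))
      bad <- c(bad, sprintf("acsa must be > 0 (offending bundle(s): %s)",
                            paste(mu$name[!is.finite(mu$acsa) | mu$acsa <= 0],
                                  collapse = ", ")))
    ori <- as.matrix(mu[, c("origin_x", "origin_y", "origin_z")])
    ins <- as.matrix(mu[, c("insertion_x", "insertion_y", "insertion_z")])
    if (!all(is.finite(ori)) || !all(is.finite(ins)))
      bad <- c(bad, "muscle coordinates must all be finite")
    else {
      zero <- sqrt(rowSums((ori - ins)^2)) < 1e-9
      if (any(zero))
        bad <- c(bad, sprintf("origin equals insertion for bundle(s): %s",
                              paste(mu$name[zero], collapse = ", ")))
    }
  }

  if (nrow(bp) < 1L) {
    bad <- c(bad, "model needs at least one bite point")
  } else if (!all(c("label", "x", "y", "z") %in% names(bp))) {
    bad <- c(bad, "bite_points must have columns label, x, y, z")
  } else {
    if (anyDuplicated(bp$label))
      bad <- c(bad, "bite point labels must be unique")
    if (!all(bp$label %in% BITE_POINT_LABELS))
      bad <- c(bad, sprintf("unknown bite point label(s): %s",
                            paste(setdiff(bp$label, BITE_POINT_LABELS),
                                  collapse = ", ")))
    if (vec_norm(model$joint_left - model$joint_right) >= 1e-9) {
      ja <- joint_axis(model)
      pos <- as.matrix(bp[, c("x", "y", "z")])
      d <- vapply(seq_len(nrow(pos)), function(i) {
        r <- pos[i, ] - ja$center
        vec_norm(r - sum(r * ja$axis) * ja$axis)
      }, numeric(1))
      if (any(d < 1e-9))
        bad <- c(bad, sprintf("bite point(s) on the hinge axis: %s",
                              paste(bp$label[d < 1e-9], collapse = ", ")))
    }
  }

  if (length(bad))
    stop("invalid jaw model:\n  - ", paste(bad, collapse = "\n  - "),
         call. = FALSE)
  model
}

#' @export
print.jaw_model <- function(x, ...) {
  cat("<jaw_model>\n")
  cat(sprintf("  joints: L(%s)  R(%s)  [hinge span %.2f mm]\n",
              paste(signif(x$joint_left, 4), collapse = ", "),
              paste(signif(x$joint_right, 4), collapse = ", "),
              vec_norm(x$joint_left - x$joint_right)))
  cat(sprintf("  muscles: %d bundle(s), sides {%s}, total acsa %.3f cm^2\n",
              nrow(x$muscles), paste(unique(x$muscles$side), collapse = ","),
              sum(x$muscles$acsa)))
  cat(sprintf("  bite points: %s\n", paste(x$bite_points$label, collapse = ", ")))
  cat(sprintf("  gape reference: %g deg\n", x$gape_reference_deg))
  invisible(x)
}

#' Hinge axis of a jaw model
#'
#' The two quadrate-articular joint centers define the hinge: the center is
#' their midpoint and the axis the unit vector pointing from the right joint
#' to the left joint.
#'
#' @param model a `jaw_model`.
#' @return list with `center` (3-vector, mm) and `axis` (unit 3-vector).
#' @export
joint_axis <- function(model) {
  v <- model$joint_left - model$joint_right
  if (vec_norm(v) < 1e-9)
    stop("degenerate hinge axis: joint centers coincide", call. = FALSE)
  list(center = (model$joint_left + model$joint_right) / 2,
       axis = v / vec_norm(v))
}

#' Rotate a point about an axis (Rodrigues rotation)
#'
#' Right-hand-rule rotation of `p` by `angle_deg` about the line through
#' `center` with unit direction `axis`. Distances to the axis are preserved.
#'
#' @param p numeric 3-vector.
#' @param center point on the rotation axis.
#' @param axis unit 3-vector.
#' @param angle_deg rotation angle in degrees.
#' @return rotated 3-vector.
#' @export
rotate_about_axis <- function(p, center, axis, angle_deg) {
  p <- as_point3(p, "p"); center <- as_point3(center, "center")
  axis <- as_point3(axis, "axis")
  if (abs(vec_norm(axis) - 1) > 1e-8)
    stop("'axis' must be unit length", call. = FALSE)
  drop(rotate_points(matrix(p, nrow = 1L), center, axis, angle_deg))
}

# Vectorised Rodrigues rotation of an n x 3 matrix of points.
rotate_points <- function(pts, center, axis, angle_deg) {
  th <- angle_deg * pi / 180
  v <- sweep(pts, 2L, center)
  kx <- cbind(axis[2L] * v[, 3L] - axis[3L] * v[, 2L],
              axis[3L] * v[, 1L] - axis[1L] * v[, 3L],
              axis[1L] * v[, 2L] - axis[2L] * v[, 1L])
  kdv <- drop(v %*% axis)
  r <- v * cos(th) + kx * sin(th) +
    tcrossprod(kdv, axis) * (1 - cos(th))
  sweep(r, 2L, center, `+`)
}

# Sense (+1/-1) of rotation about the hinge axis that OPENS the jaw, i.e.
# moves the jaw tip ventrally (-z). Determined from the geometry, never
# hard-coded: the reference point is the jaw_tip bite point when present,
# otherwise the bite point farthest from the hinge axis.
opening_sense <- function(model) {
  ja <- joint_axis(model)
  bp <- model$bite_points
  if ("jaw_tip" %in% bp$label) {
    ref <- as_point3(bp[bp$label == "jaw_tip", c("x", "y", "z")], "jaw_tip")
  } else {
    pos <- as.matrix(bp[, c("x", "y", "z")])
    d <- vapply(seq_len(nrow(pos)), function(i) {
      r <- pos[i, ] - ja$center
      vec_norm(r - sum(r * ja$axis) * ja$axis)
    }, numeric(1))
    ref <- pos[which.max(d), ]
  }
  dz <- rotate_about_axis(ref, ja$center, ja$axis, 1)[3L] - ref[3L]
  if (abs(dz) < 1e-12)
    stop("cannot determine jaw-opening sense: reference bite point does not move vertically",
         call. = FALSE)
  if (dz < 0) 1 else -1
}

#' Pose a jaw model at a gape angle
#'
#' Rigidly rotates every mandibular point (muscle insertions and bite
#' points) about the hinge axis so that the model's gape becomes
#' `gape_deg`; cranial points (muscle origins, joints) are fixed. The
#' opening sense is the rotation direction that moves the jaw tip
#' ventrally, derived from the geometry.
#'
#' @param model a `jaw_model`.
#' @param gape_deg target gape angle, degrees, in `[0, 90)`.
#' @return a `jaw_model` posed at `gape_deg` (its `gape_reference_deg`
#'   is updated accordingly).
#' @export
open_jaw <- function(model, gape_deg) {
  if (!is.finite(gape_deg) || gape_deg < 0 || gape_deg >= 90)
    stop("'gape_deg' must lie in [0, 90)", call. = FALSE)
  delta <- gape_deg - model$gape_reference_deg
  if (abs(delta) < 1e-15) return(model)
  ja <- joint_axis(model)
  ang <- opening_sense(model) * delta
  ins <- as.matrix(model$muscles[, c("insertion_x", "insertion_y", "insertion_z")])
  model$muscles[, c("insertion_x", "insertion_y", "insertion_z")] <-
    rotate_points(ins, ja$center, ja$axis, ang)
  pos <- as.matrix(model$bite_points[, c("x", "y", "z")])
  model$bite_points[, c("x", "y", "z")] <-
    rotate_points(pos, ja$center, ja$axis, ang)
  model$gape_reference_deg <- gape_deg
  model
}

#' Mirror a unilateral jaw model to bilateral
#'
#' Holotype muscles are often digitized on one side only; under bilateral
#' symmetry each bundle is duplicated and reflected across the sagittal
#' plane (the plane through the hinge-axis midpoint normal to y), with its
#' `side` flipped. Area, group and name are preserved.
#'
#' @param model a `jaw_model` whose muscles all lie on one side.
#' @return a bilateral `jaw_model` with twice the bundle count.
#' @export
mirror_unilateral <- function(model) {
  sides <- unique(model$muscles$side)
  if (length(sides) > 1L)
    stop("model is already bilateral; skip mirroring", call. = FALSE)
  yc <- (model$joint_left[2L] + model$joint_right[2L]) / 2
  mir <- model$muscles
  mir$origin_y <- 2 * yc - mir$origin_y
  mir$insertion_y <- 2 * yc - mir$insertion_y
  mir$side <- ifelse(mir$side == "left", "right", "left")
  model$muscles <- rbind(model$muscles, mir)
  rownames(model$muscles) <- NULL
  validate_jaw_model(model)
}

# Fetch one bite point's coordinates by label.
bite_point_position <- function(model, label) {
  bp <- model$bite_points
  i <- match(label, bp$label)
  if (is.na(i))
    stop(sprintf("no bite point labelled '%s' (have: %s)", label,
                 paste(bp$label, collapse = ", ")), call. = FALSE)
  as_point3(bp[i, c("x", "y", "z")], label)
}
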