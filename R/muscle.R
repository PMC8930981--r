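# Muscle architecture: force generation from cross-sectional area.
# No pennation correction anywhere: anatomical and physiological
# cross-sectional area coincide in this model, so a single `acsa` field
# (cm^2) drives force = acsa * muscle stress (N/cm^2).

#' Cross-sectional area from volume and fiber length
#'
#' @param volume muscle volume, cm^3.
#' @param fiber_length fiber length, cm.
#' @return cross-sectional area, cm^2 (`volume / fiber_length`). Vectorised.
#' @export
acsa_from_volume <- function(volume, fiber_length) {
  if (any(!is.finite(volume) | volume <= 0))
    stop("'volume' must be > 0", call. = FALSE)
  if (any(!is.finite(fiber_length) | fiber_length <= 0))
    stop("'fiber_length' must be > 0", call. = FALSE)
  volume / fiber_length
}

#' Force generated by a maximally active muscle bundle
#'
#' Magnitude is `acsa * stress`; the line of action runs from the insertion
#' toward the origin (a straight line, no wrapping) and the force is applied
#' at the insertion on the mandible.
#'
#' @param bundle one muscle bundle: a one-row data frame (or list) with
#'   `origin_x/y/z`, `insertion_x/y/z` and `acsa`.
#' @param stress muscle stress in N/cm^2 (default 30).
#' @return list with `name`, `application_point` (mm), `direction` (unit
#'   3-vector insertion -> origin) and `magnitude` (N).
#' @export
muscle_force <- function(bundle, stress = 30) {
  if (!is.finite(stress) || stress <= 0)
    stop("'stress' must be > 0", call. = FALSE)
  b <- as.list(bundle)
  o <- c(b$origin_x, b$origin_y, b$origin_z)
  i <- c(b$insertion_x, b$insertion_y, b$insertion_z)
  d <- o - i
  if (vec_norm(d) < 1e-9)
    stop("zero-length line of action (origin equals insertion)", call. = FALSE)
  list(name = if (is.null(b$name)) NA_character_ else b$name,
       application_point = i,
       direction = d / vec_norm(d),
       magnitude = b$acsa * stress)
}

# All bundle forces of a model at once: list of matrices/vectors the solver
# consumes. Directions are unit insertion -> origin rows.
muscle_forces <- function(model, stress = 30) {
  if (!is.finite(stress) || stress <= 0)
    stop("'stress' must be > 0", call. = FALSE)
  mu <- model$muscles
  ori <- as.matrix(mu[, c("origin_x", "origin_y", "origin_z")])
  ins <- as.matrix(mu[, c("insertion_x", "insertion_y", "insertion_z")])
  d <- ori - ins
  len <- sqrt(rowSums(d^2))
  if (any(len < 1e-9))
    stop("zero-length line of action for bundle(s): ",
         paste(mu$name[len < 1e-9], collapse = ", "), call. = FALSE)
  list(application = ins, direction = d / len, magnitude = mu$acsa * stress)
}

#' Centroid of an attachment area
#'
#' Broad origin/insertion areas are reduced to a single effective point:
#' the (optionally area-weighted) arithmetic mean of the digitized points.
#'
#' @param points n x 3 numeric matrix (or a list of 3-vectors).
#' @param weights optional positive weights (e.g. facet areas), length n.
#' @return 3-vector centroid.
#' @export
attachment_centroid <- function(points, weights = NULL) {
  if (is.list(points)) points <- do.call(rbind, lapply(points, as_point3))
  points <- as.matrix(points)
  if (!nrow(points)) stop("need at least one point", call. = FALSE)
  if (ncol(points) != 3L) stop("'points' must be n x 3", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, nrow(points))
  if (length(weights) != nrow(points) || any(!is.finite(weights) | weights <= 0))
    stop("'weights' must be positive, one per point", call. = FALSE)
  drop(crossprod(points, weights) / sum(weights))
}

#' Volume fraction of each adductor group
#'
#' Reports the share of total adductor volume per muscle group, the way
#' segmentation studies summarise jaw musculature (e.g. the external
#' adductor complex exceeding half of total adductor volume).
#'
#' @param muscles muscle data frame with `name`, `group` and `volume` (cm^3).
#' @return named numeric vector of fractions summing to 1.
#' @export
group_volume_fractions <- function(muscles) {
  mu <- as.data.frame(muscles)
  if (!all(c("group", "volume") %in% names(mu)))
    stop("'muscles' must have columns group and volume", call. = FALSE)
  miss <- !is.finite(mu$volume) | mu$volume <= 0
  if (any(miss))
    stop("missing or non-positive volume for bundle(s): ",
         paste(if (!is.null(mu$name)) mu$name[miss] else which(miss),
               collapse = ", "), call. = FALSE)
  tot <- tapply(mu$volume, mu$group, sum)
  fr <- tot / sum(tot)
  setNames(as.numeric(fr), names(fr))
}
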