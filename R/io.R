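# Geometry file format: JSON with top-level keys
#   units        {"length": "mm"|"cm", "area": "cm2"|"mm2"}
#   joints       {"left": [x,y,z], "right": [x,y,z]}
#   gape_reference_deg
#   muscles      [{name, group, side, origin:[...], insertion:[...],
#                  acsa, volume?, fiber_length?}, ...]
#   bite_points  [{label, position:[x,y,z]}, ...]
# Unknown top-level keys are preserved on a load -> write round trip.

KNOWN_TOPLEVEL_KEYS <- c("units", "joints", "gape_reference_deg",
                         "muscles", "bite_points")

fail_field <- function(field, msg) {
  stop(sprintf("geometry file field '%s': %s", field, msg), call. = FALSE)
}

num_or_fail <- function(x, field) {
  v <- suppressWarnings(as.numeric(unlist(x)))
  if (!length(v) || anyNA(v) || !all(is.finite(v)))
    fail_field(field, "must be finite numeric")
  v
}

#' Load a jaw geometry file
#'
#' Reads the JSON geometry schema, checks it field by field (errors name the
#' offending field), converts lengths to millimetres and areas to cm^2, and
#' returns a fully validated [jaw_model()]. Unknown top-level keys are kept
#' in `$extra` and written back by [write_jaw_model()]; unknown keys inside
#' individual muscle or bite-point entries are dropped.
#'
#' @param path path to a geometry JSON file.
#' @return a validated `jaw_model`.
#' @export
load_jaw_model <- function(path) {
  if (!file.exists(path))
    stop(sprintf("geometry file not found: %s", path), call. = FALSE)
  j <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!is.list(j)) stop("geometry file is not a JSON object", call. = FALSE)

  units <- j$units
  len_unit <- if (is.null(units$length)) "mm" else units$length
  area_unit <- if (is.null(units$area)) "cm2" else units$area
  if (!len_unit %in% c("mm", "cm"))
    fail_field("units.length", "must be 'mm' or 'cm'")
  if (!area_unit %in% c("cm2", "mm2"))
    fail_field("units.area", "must be 'cm2' or 'mm2'")
  len_scale <- if (len_unit == "cm") 10 else 1
  area_scale <- if (area_unit == "mm2") 0.01 else 1

  if (is.null(j$joints)) fail_field("joints", "missing")
  if (is.null(j$joints$left)) fail_field("joints.left", "missing")
  if (is.null(j$joints$right)) fail_field("joints.right", "missing")
  jl <- num_or_fail(j$joints$left, "joints.left") * len_scale
  jr <- num_or_fail(j$joints$right, "joints.right") * len_scale
  if (length(jl) != 3L) fail_field("joints.left", "must have 3 coordinates")
  if (length(jr) != 3L) fail_field("joints.right", "must have 3 coordinates")

  gref <- if (is.null(j$gape_reference_deg)) 0 else
    num_or_fail(j$gape_reference_deg, "gape_reference_deg")

  if (is.null(j$muscles) || !length(j$muscles))
    fail_field("muscles", "missing or empty")
  mu <- lapply(seq_along(j$muscles), function(i) {
    m <- j$muscles[[i]]
    tag <- sprintf("muscles[%d]", i)
    for (k in c("name", "group", "side", "origin", "insertion", "acsa"))
      if (is.null(m[[k]])) fail_field(paste0(tag, ".", k), "missing")
    o <- num_or_fail(m$origin, paste0(tag, ".origin")) * len_scale
    s <- num_or_fail(m$insertion, paste0(tag, ".insertion")) * len_scale
    if (length(o) != 3L) fail_field(paste0(tag, ".origin"), "must have 3 coordinates")
    if (length(s) != 3L) fail_field(paste0(tag, ".insertion"), "must have 3 coordinates")
    acsa <- num_or_fail(m$acsa, paste0(tag, ".acsa")) * area_scale
    if (acsa <= 0) fail_field(paste0(tag, ".acsa"), "must be > 0")
    data.frame(name = as.character(m$name), group = as.character(m$group),
               side = as.character(m$side),
               origin_x = o[1L], origin_y = o[2L], origin_z = o[3L],
               insertion_x = s[1L], insertion_y = s[2L], insertion_z = s[3L],
               acsa = acsa,
               volume = if (is.null(m$volume)) NA_real_ else
                 num_or_fail(m$volume, paste0(tag, ".volume")),
               fiber_length = if (is.null(m$fiber_length)) NA_real_ else
                 num_or_fail(m$fiber_length, paste0(tag, ".fiber_length")),
               stringsAsFactors = FALSE)
  })
  mu <- do.call(rbind, mu)

  if (is.null(j$bite_points) || !length(j$bite_points))
    fail_field("bite_points", "missing or empty")
  bp <- lapply(seq_along(j$bite_points), function(i) {
    b <- j$bite_points[[i]]
    tag <- sprintf("bite_points[%d]", i)
    if (is.null(b$label)) fail_field(paste0(tag, ".label"), "missing")
    if (is.null(b$position)) fail_field(paste0(tag, ".position"), "missing")
    p <- num_or_fail(b$position, paste0(tag, ".position")) * len_scale
    if (length(p) != 3L) fail_field(paste0(tag, ".position"), "must have 3 coordinates")
    data.frame(label = as.character(b$label), x = p[1L], y = p[2L], z = p[3L],
               stringsAsFactors = FALSE)
  })
  bp <- do.call(rbind, bp)

  extra <- j[setdiff(names(j), KNOWN_TOPLEVEL_KEYS)]
  jaw_model(jl, jr, mu, bp, gape_reference_deg = gref, extra = extra)
}

#' Write a jaw model to a geometry file
#'
#' Emits the same JSON schema [load_jaw_model()] reads (lengths mm, areas
#' cm^2, full double precision), including any unknown top-level keys kept
#' in `$extra`, so load -> write -> load round-trips every schema field.
#'
#' @param model a `jaw_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_jaw_model <- function(model, path) {
  mu <- model$muscles
  muscles <- lapply(seq_len(nrow(mu)), function(i) {
    m <- as.list(mu[i, ])
    out <- list(name = m$name, group = m$group, side = m$side,
                origin = c(m$origin_x, m$origin_y, m$origin_z),
                insertion = c(m$insertion_x, m$insertion_y, m$insertion_z),
                acsa = m$acsa)
    if (!is.na(m$volume)) out$volume <- m$volume
    if (!is.na(m$fiber_length)) out$fiber_length <- m$fiber_length
    out
  })
  bp <- model$bite_points
  bite_points <- lapply(seq_len(nrow(bp)), function(i)
    list(label = bp$label[i], position = c(bp$x[i], bp$y[i], bp$z[i])))
  doc <- c(list(
    units = list(length = "mm", area = "cm2"),
    joints = list(left = model$joint_left, right = model$joint_right),
    gape_reference_deg = model$gape_reference_deg,
    muscles = muscles,
    bite_points = bite_points
  ), model$extra)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
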