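# Seeded synthetic-data generators. Every input the pipeline needs can be
# generated here: jaw geometries with hand-derived closed-form lever
# solutions (the solver's independent oracle), comparative in vivo bite
# force datasets emulating the max-of-five-trials field protocol, and crab
# exoskeleton hardness records. All generators are pure functions of their
# parameters and seed; the caller's RNG state is left untouched.

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

#' Planar toy jaw with closed-form bite forces
#'
#' Builds a sagittal-plane jaw whose solved bite force has a hand-derived
#' closed form at every gape, for use as an independent oracle. The hinge
#' axis is +y through the origin; insertions sit on the mandible at
#' horizontal in-levers r_i; bite points on the midline tooth row at
#' out-levers R. Two origin placements:
#'
#' * `"above_joint"` (default): all origins at (0, +/-w, h), dorsal to the
#'   joint. The perpendicular muscle arm at gape theta is
#'   `r h / sqrt(r^2 + h^2 + 2 h r sin(theta))` per unit force and the
#'   vertical-reaction out-lever is `R cos(theta)`, giving
#'   `F(theta) = sum_i F_i r_i h / (R sqrt(r_i^2 + h^2 + 2 h r_i sin(theta)))`
#'   - strictly decreasing in gape, like a real adductor whose advantage
#'   degrades as the jaw opens.
#' * `"vertical"`: each origin directly dorsal to its insertion, so every
#'   bundle pulls straight dorsally at the closed pose and the closed-pose
#'   force is the textbook lever law `sum_i F_i r_i / R`. At gape theta the
#'   closed form is
#'   `F(theta) = sum_i F_i r_i (r_i sin + h cos) / (L_i R cos)` with
#'   `L_i = sqrt(r_i^2 (1-cos)^2 + (h + r_i sin)^2)`.
#'
#' Expected values assume a vertical (orientation 0) food reaction.
#'
#' @param n_bundles_per_side bundles per side.
#' @param in_lever_range range (mm) the in-levers are drawn from.
#' @param out_levers named vector of bite-point out-levers (mm), labels from
#'   `jaw_tip, anterior_caniniform, posterior_caniniform, posterior_most`;
#'   anterior points must be farther from the joint.
#' @param total_acsa summed cross-sectional area per side, cm^2.
#' @param origin_elevation dorsal height h of the origins, mm.
#' @param half_width half the hinge span, mm.
#' @param gapes_deg gapes the expected table is evaluated at.
#' @param origin_mode `"above_joint"` or `"vertical"` (see above).
#' @param seed RNG seed.
#' @return list with `model` (bilateral `jaw_model`), `expected` (data
#'   frame `bite_point`, `gape_deg`, `bite_force_N` from the closed form)
#'   and `params`.
#' @export
make_planar_jaw <- function(n_bundles_per_side = 3,
                            in_lever_range = c(4, 12),
                            out_levers = c(jaw_tip = 35,
                                           anterior_caniniform = 30,
                                           posterior_caniniform = 22,
                                           posterior_most = 14),
                            total_acsa = 4,
                            origin_elevation = 15,
                            half_width = 5,
                            gapes_deg = c(0, 10, 30, 60),
                            origin_mode = c("above_joint", "vertical"),
                            seed = 0) {
  origin_mode <- match.arg(origin_mode)
  if (n_bundles_per_side < 1) stop("need at least one bundle", call. = FALSE)
  if (any(out_levers <= 0) || any(in_lever_range <= 0) ||
      total_acsa <= 0 || origin_elevation <= 0)
    stop("levers, areas and elevation must be positive", call. = FALSE)
  labs <- names(out_levers)
  if (is.null(labs) || !all(labs %in% BITE_POINT_LABELS))
    stop("out_levers must be named with valid bite point labels", call. = FALSE)
  ord <- intersect(BITE_POINT_LABELS, labs)  # anterior-most first
  if (is.unsorted(rev(out_levers[ord])))
    stop("out_levers must decrease from jaw_tip to posterior_most",
         call. = FALSE)

  with_seed(seed, {
    r <- sort(runif(n_bundles_per_side, in_lever_range[1L], in_lever_range[2L]))
    w <- runif(n_bundles_per_side)
    acsa <- total_acsa * w / sum(w)
    h <- origin_elevation
    mu <- data.frame(
      name = sprintf("bundle_%02d", seq_len(n_bundles_per_side)),
      group = rep_len(MUSCLE_GROUPS[1:3], n_bundles_per_side),
      side = "left",
      origin_x = if (origin_mode == "above_joint") 0 else r,
      origin_y = half_width,
      origin_z = h,
      insertion_x = r, insertion_y = half_width, insertion_z = 0,
      acsa = acsa, volume = NA_real_, fiber_length = NA_real_,
      stringsAsFactors = FALSE)
    bp <- data.frame(label = labs, x = unname(out_levers), y = 0, z = 0,
                     stringsAsFactors = FALSE)
    model <- mirror_unilateral(
      jaw_model(c(0, half_width, 0), c(0, -half_width, 0), mu, bp))

    fmus <- 2 * acsa * 30           # bilateral bundle force at 30 N/cm^2
    expected <- do.call(rbind, lapply(gapes_deg, function(g) {
      th <- g * pi / 180
      per_bundle <- if (origin_mode == "above_joint") {
        fmus * r * h / sqrt(r^2 + h^2 + 2 * h * r * sin(th))
      } else {
        L <- sqrt(r^2 * (1 - cos(th))^2 + (h + r * sin(th))^2)
        fmus * r * (r * sin(th) + h * cos(th)) / (L * cos(th))
      }
      data.frame(bite_point = labs, gape_deg = g,
                 bite_force_N = sum(per_bundle) / unname(out_levers),
                 stringsAsFactors = FALSE)
    }))
    rownames(expected) <- NULL
    list(model = model, expected = expected,
         params = list(in_levers = r, acsa = acsa, h = h,
                       out_levers = out_levers, origin_mode = origin_mode,
                       seed = seed))
  })
}

#' Random anatomically plausible jaw model
#'
#' Draws a bilateral jaw with origins dorsal and posterior to their
#' insertions, insertions on the mandible between joint and tip, four bite
#' points ordered along the tooth row, and positive areas. Deterministic
#' for a given seed; every generated model passes [validate_jaw_model()].
#'
#' @param seed RNG seed.
#' @param n_bundles_per_side bundles per side (default drawn in 3..6).
#' @return a validated bilateral `jaw_model`.
#' @export
make_random_jaw <- function(seed = 1, n_bundles_per_side = NULL) {
  with_seed(seed, {
    if (is.null(n_bundles_per_side))
      n_bundles_per_side <- sample(3:6, 1L)
    w <- runif(1, 8, 14)                     # hinge span
    jaw_len <- runif(1, 25, 40)
    ins_x <- runif(n_bundles_per_side, 0.10, 0.45) * jaw_len
    ins_y <- runif(n_bundles_per_side, 0.7, 1.0) * (w / 2)
    ins_z <- runif(n_bundles_per_side, -1, 2)
    # origins in the temporal region: dorsal to and just around the joint,
    # always posterior to the coronoid-region insertions
    ori_x <- runif(n_bundles_per_side, -3, 0.08 * jaw_len)
    ori_y <- ins_y + runif(n_bundles_per_side, -2, 2)
    ori_z <- ins_z + runif(n_bundles_per_side, 8, 18)    # dorsal
    mu <- data.frame(
      name = sprintf("bundle_%02d", seq_len(n_bundles_per_side)),
      group = sample(MUSCLE_GROUPS, n_bundles_per_side, replace = TRUE),
      side = "left",
      origin_x = ori_x, origin_y = ori_y, origin_z = ori_z,
      insertion_x = ins_x, insertion_y = ins_y, insertion_z = ins_z,
      acsa = runif(n_bundles_per_side, 0.05, 0.6),
      volume = NA_real_, fiber_length = NA_real_,
      stringsAsFactors = FALSE)
    frac <- sort(runif(4, 0.3, 1), decreasing = TRUE)
    bp <- data.frame(label = BITE_POINT_LABELS,
                     x = frac * jaw_len,
                     y = 0,
                     z = runif(4, -0.5, 0.5),
                     stringsAsFactors = FALSE)
    mirror_unilateral(
      jaw_model(c(0, w / 2, 0), c(0, -w / 2, 0), mu, bp))
  })
}

#' Synthetic comparative in vivo bite-force dataset
#'
#' Emulates a multi-species field dataset: species mean head widths are
#' log-spaced across `hw_range`; each specimen's true (log10) bite
#' capacity is `intercept + slope * log10(head_width)` plus a species-level
#' and a specimen-level Gaussian effect on the log10 scale. The recorded
#' force is the maximum of `trials_per_individual` trials with
#' multiplicative lognormal noise (coefficient of variation `trial_cv`),
#' emulating a max-of-trials transducer protocol. Trials model submaximal
#' efforts: their location is calibrated so that the recorded maximum is
#' log-unbiased for the animal's capacity (the protocol's premise is that
#' the best of five trials is the animal's maximum, so the emulated
#' records must not drift above the generating allometry as the trial
#' count grows).
#'
#' @param n_species number of species (default 44).
#' @param n_specimens total specimens (default 332), spread as evenly as
#'   possible across species.
#' @param slope,intercept generating allometry on log10-log10 axes
#'   (defaults 2.0 and -1.0).
#' @param species_sd,specimen_sd random-effect standard deviations, log10
#'   scale.
#' @param trials_per_individual trials per animal (default 5).
#' @param trial_cv coefficient of variation of one trial.
#' @param hw_range species mean head-width range, mm.
#' @param seed RNG seed.
#' @return data frame with columns `species`, `head_width` (mm),
#'   `bite_force` (N) and `svl` (mm).
#' @export
make_comparative_dataset <- function(n_species = 44, n_specimens = 332,
                                     slope = 2.0, intercept = -1.0,
                                     species_sd = 0.08, specimen_sd = 0.05,
                                     trials_per_individual = 5,
                                     trial_cv = 0.1,
                                     hw_range = c(4, 38), seed = 1) {
  if (n_specimens < n_species)
    stop("n_specimens must be >= n_species", call. = FALSE)
  if (species_sd < 0 || specimen_sd < 0 || trial_cv < 0)
    stop("standard deviations must be >= 0", call. = FALSE)
  with_seed(seed, {
    hw_sp <- 10^seq(log10(hw_range[1L]), log10(hw_range[2L]),
                    length.out = n_species)
    base <- n_specimens %/% n_species
    extra <- n_specimens %% n_species
    per_sp <- rep(base, n_species) + rep(c(1L, 0L), c(extra, n_species - extra))
    sp_eff <- rnorm(n_species, 0, species_sd)
    sigma_log <- sqrt(log(1 + trial_cv^2))
    # E[max of k standard normals]; shifting trials down by sigma * this
    # makes log(max of k trials) unbiased for log capacity
    k <- trials_per_individual
    e_max_k <- if (k == 1L) 0 else
      stats::integrate(function(z) z * k * stats::dnorm(z) *
                         stats::pnorm(z)^(k - 1), -Inf, Inf)$value
    rows <- lapply(seq_len(n_species), function(s) {
      m <- per_sp[s]
      hw <- hw_sp[s] * exp(rnorm(m, 0, 0.05))
      cap <- 10^(intercept + slope * log10(hw) + sp_eff[s] +
                   rnorm(m, 0, specimen_sd))
      rec <- vapply(cap, function(ci)
        max(ci * exp(rnorm(k, 0, sigma_log) - sigma_log * e_max_k)),
        numeric(1))
      data.frame(species = sprintf("species_%02d", s),
                 head_width = hw, bite_force = rec,
                 svl = 7 * hw * exp(rnorm(m, 0, 0.05)),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Synthetic crab exoskeleton hardness dataset
#'
#' Carapace widths drawn uniformly over `width_range` (adult land crabs of
#' the modelled genus reach about 6 cm); failure force is linear in width
#' plus Gaussian noise, floored at 0.1 N; mass scales roughly with the cube
#' of width.
#'
#' @param slope N per cm of carapace width (default 30).
#' @param intercept N (default 0).
#' @param sd Gaussian noise sd, N.
#' @param n number of crabs.
#' @param width_range cm (default 2 to 6).
#' @param seed RNG seed.
#' @return data frame with `carapace_width` (cm), `mass` (g),
#'   `failure_force` (N).
#' @export
make_hardness_dataset <- function(slope = 30, intercept = 0, sd = 10,
                                  n = 30, width_range = c(2, 6), seed = 1) {
  if (n < 1) stop("need n >= 1", call. = FALSE)
  with_seed(seed, {
    wd <- runif(n, width_range[1L], width_range[2L])
    ff <- pmax(intercept + slope * wd + rnorm(n, 0, sd), 0.1)
    data.frame(carapace_width = wd,
               mass = 0.23 * wd^3 * exp(rnorm(n, 0, 0.1)),
               failure_force = ff,
               stringsAsFactors = FALSE)
  })
}
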