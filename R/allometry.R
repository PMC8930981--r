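# Comparative layer: log10-log10 allometry of in vivo bite force against
# head width across species, placement of a model-estimated species on that
# line, and prey (crab exoskeleton) hardness against carapace size on
# untransformed axes.

#' Fit the bite force ~ head width allometry
#'
#' Ordinary least squares of `log10(bite_force)` on `log10(head_width)`.
#' Specimens are treated as exchangeable points (no phylogenetic
#' correction), matching how specimen-level comparative bite-force plots
#' are drawn; set `species_means = TRUE` to fit per-species mean log10
#' values instead (one point per species, which removes within-species
#' pseudo-replication when the fit's standard errors matter).
#'
#' @param records data frame with columns `species`, `head_width` (mm) and
#'   `bite_force` (N).
#' @param species_means fit species means instead of specimens.
#' @return object of class `allometric_fit`: `slope`, `intercept` (log10 N
#'   at log10 mm = 0), `r2`, `residual_sd`, `n`, standard errors, the 95%
#'   confidence intervals and the underlying `lm` fit.
#' @export
fit_loglog <- function(records, species_means = FALSE) {
  d <- as.data.frame(records)
  need <- c("species", "head_width", "bite_force")
  if (!all(need %in% names(d)))
    stop("'records' must have columns species, head_width, bite_force",
         call. = FALSE)
  if (any(!is.finite(d$head_width) | d$head_width <= 0))
    stop("head_width must be positive", call. = FALSE)
  if (any(!is.finite(d$bite_force) | d$bite_force <= 0))
    stop("bite_force must be positive", call. = FALSE)
  x <- log10(d$head_width)
  y <- log10(d$bite_force)
  if (species_means) {
    x <- tapply(x, d$species, mean)
    y <- tapply(y, d$species, mean)[names(x)]
  }
  if (length(x) < 3L)
    stop("need at least 3 records (or species) to fit", call. = FALSE)
  if (diff(range(x)) < 1e-12)
    stop("zero variance in head width; cannot fit", call. = FALSE)
  fit <- lm(y ~ x, data = data.frame(x = as.numeric(x), y = as.numeric(y)))
  # noiseless power-law input makes lm warn about a perfect fit; the fit
  # itself is exact and welcome
  sm <- suppressWarnings(summary(fit))
  ci <- suppressWarnings(confint(fit, level = 0.95))
  structure(list(
    slope = unname(coef(fit)[2L]),
    intercept = unname(coef(fit)[1L]),
    slope_se = sm$coefficients["x", "Std. Error"],
    intercept_se = sm$coefficients["(Intercept)", "Std. Error"],
    slope_ci = unname(ci["x", ]),
    intercept_ci = unname(ci["(Intercept)", ]),
    r2 = sm$r.squared,
    residual_sd = sm$sigma,
    n = length(x),
    species_means = species_means,
    lm = fit
  ), class = "allometric_fit")
}

#' @export
print.allometric_fit <- function(x, ...) {
  cat(sprintf(
    "<allometric_fit> log10(F) = %.4f + %.4f log10(HW)  (n = %d%s)\n",
    x$intercept, x$slope, x$n,
    if (x$species_means) " species means" else " specimens"))
  cat(sprintf("  r2 = %.4f, residual sd = %.4f (log10 N)\n",
              x$r2, x$residual_sd))
  invisible(x)
}

#' Signed log10 residual of a point from the allometric line
#'
#' Where does an animal sit relative to the regression line? Positive means
#' above the line (stronger bite than its head width predicts).
#'
#' @param fit an `allometric_fit`.
#' @param head_width mm, positive.
#' @param bite_force N, positive.
#' @return `log10(bite_force) - (intercept + slope * log10(head_width))`.
#' @export
residual_position <- function(fit, head_width, bite_force) {
  if (any(!is.finite(head_width) | head_width <= 0))
    stop("'head_width' must be positive", call. = FALSE)
  if (any(!is.finite(bite_force) | bite_force <= 0))
    stop("'bite_force' must be positive", call. = FALSE)
  log10(bite_force) - (fit$intercept + fit$slope * log10(head_width))
}

#' Fit exoskeleton failure force against carapace size
#'
#' OLS of failure force (N) on carapace width (cm), untransformed: prey
#' hardness is modelled as increasing linearly with size.
#'
#' @param records data frame with columns `carapace_width` (cm) and
#'   `failure_force` (N).
#' @return object of class `hardness_fit` with `slope` (N/cm),
#'   `intercept` (N), standard errors, `r2`, `residual_sd`, `n` and the
#'   underlying `lm`.
#' @export
fit_hardness_vs_size <- function(records) {
  d <- as.data.frame(records)
  if (!all(c("carapace_width", "failure_force") %in% names(d)))
    stop("'records' must have columns carapace_width, failure_force",
         call. = FALSE)
  if (nrow(d) < 3L) stop("need at least 3 hardness records", call. = FALSE)
  if (any(!is.finite(d$carapace_width) | d$carapace_width <= 0) ||
      any(!is.finite(d$failure_force) | d$failure_force <= 0))
    stop("carapace_width and failure_force must be positive", call. = FALSE)
  if (diff(range(d$carapace_width)) < 1e-12)
    stop("zero variance in carapace width; cannot fit", call. = FALSE)
  fit <- lm(failure_force ~ carapace_width, data = d)
  sm <- suppressWarnings(summary(fit))
  structure(list(
    slope = unname(coef(fit)[2L]),
    intercept = unname(coef(fit)[1L]),
    slope_se = sm$coefficients["carapace_width", "Std. Error"],
    r2 = sm$r.squared,
    residual_sd = sm$sigma,
    n = nrow(d),
    lm = fit
  ), class = "hardness_fit")
}

#' Predicted hardness at a carapace width
#'
#' @param fit a `hardness_fit`.
#' @param carapace_width cm.
#' @return predicted failure force, N.
#' @export
predict_hardness <- function(fit, carapace_width) {
  fit$intercept + fit$slope * carapace_width
}

#' Does a bite force exceed a prey hardness?
#'
#' @param bite_force N, positive.
#' @param predicted_hardness N, positive.
#' @return list with `exceeds` (bite force >= hardness), `margin`
#'   (bite - hardness, N) and `ratio` (bite / hardness).
#' @export
exceeds_hardness <- function(bite_force, predicted_hardness) {
  if (!is.finite(bite_force) || bite_force <= 0 ||
      !is.finite(predicted_hardness) || predicted_hardness <= 0)
    stop("forces must be positive", call. = FALSE)
  list(exceeds = bite_force >= predicted_hardness,
       margin = bite_force - predicted_hardness,
       ratio = bite_force / predicted_hardness)
}
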