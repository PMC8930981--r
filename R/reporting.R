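# Report layer: headline summaries of a simulation sweep and the combined
# comparative report (placement on the allometric line + prey-hardness
# verdict). In vivo comparative forces are measured at the jaw tip at a
# gape of about 30 degrees, so placement on the allometric line defaults to
# the model force solved under that same condition, never the global
# maximum.

#' Summarise a simulation sweep
#'
#' @param results table from [run_simulation()].
#' @return list with `max_force` (N), `max_at` (bite point, gape of the
#'   global maximum) and `cell_maxima`, a data frame of the per-(gape,
#'   bite point) maximum over reaction orientations with its percent of
#'   the global maximum.
#' @export
simulation_summary <- function(results) {
  results <- as.data.frame(results)
  ok <- results[!is.na(results$bite_force_N), , drop = FALSE]
  if (!nrow(ok)) stop("no solvable conditions in 'results'", call. = FALSE)
  cells <- ok[ok$is_max, , drop = FALSE]
  cells <- percent_of_max(cells)
  i <- which.max(cells$bite_force_N)
  list(max_force = cells$bite_force_N[i],
       max_at = list(bite_point = cells$bite_point[i],
                     gape_deg = cells$gape_deg[i]),
       cell_maxima = cells[order(cells$gape_deg,
                                 -cells$bite_force_N), , drop = FALSE])
}

# Maximum-over-orientations force at one (bite point, gape) cell.
cell_max_force <- function(results, bite_point, gape_deg) {
  r <- results[results$bite_point == bite_point &
                 results$gape_deg == gape_deg &
                 !is.na(results$bite_force_N), , drop = FALSE]
  if (!nrow(r))
    stop(sprintf("no solved condition for '%s' at %g deg", bite_point,
                 gape_deg), call. = FALSE)
  max(r$bite_force_N)
}

#' Combined bite-performance report
#'
#' Places a model-estimated animal on the comparative allometric line and,
#' when a hardness fit is supplied, compares its maximum bite force with
#' the predicted prey hardness at a chosen carapace width.
#'
#' @param results sweep table from [run_simulation()].
#' @param fit comparative `allometric_fit`.
#' @param focal_head_width head width (mm) of the modelled animal.
#' @param hardness_fit optional `hardness_fit`; omit to skip the hardness
#'   section.
#' @param crab_width carapace width (cm) the hardness is predicted at
#'   (default 6, full adult size).
#' @param placement_bite_point,placement_gape condition whose
#'   max-over-orientations force is placed on the line (defaults `jaw_tip`
#'   at 30 degrees, matching the in vivo measurement protocol).
#' @return list with `placement` (condition, force, signed log10 residual,
#'   above-line flag) and, when `hardness_fit` is given, `hardness`
#'   (predicted hardness, max model force, [exceeds_hardness()] verdict).
#' @export
bite_performance_report <- function(results, fit, focal_head_width,
                                    hardness_fit = NULL, crab_width = 6,
                                    placement_bite_point = "jaw_tip",
                                    placement_gape = 30) {
  f_place <- cell_max_force(results, placement_bite_point, placement_gape)
  res <- residual_position(fit, focal_head_width, f_place)
  out <- list(placement = list(
    bite_point = placement_bite_point,
    gape_deg = placement_gape,
    bite_force = f_place,
    head_width = focal_head_width,
    log10_residual = res,
    above_line = res > 0
  ))
  if (!is.null(hardness_fit)) {
    hmax <- predict_hardness(hardness_fit, crab_width)
    fmax <- max(results$bite_force_N, na.rm = TRUE)
    out$hardness <- c(list(crab_width = crab_width,
                           predicted_hardness = hmax,
                           max_bite_force = fmax),
                      exceeds_hardness(fmax, hmax))
  }
  out
}
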