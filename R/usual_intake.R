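#' Specify how the within/between variance ratio is obtained
#'
#' The usual-intake adjustment needs the ratio of within-person (day-to-day)
#' to between-person variance on the transformed scale. With repeated recall
#' days per subject the ratio can be estimated internally from the data
#' ([estimate_variance_components()]); with a single recall day an external
#' ratio from a comparable survey must be supplied.
#'
#' The shipped external default of 2.0 (log scale) is an order-of-magnitude
#' placeholder only — nutrient- and survey-specific ratios differ — and a
#' warning is emitted whenever it is used; set `ratio` explicitly for any
#' real analysis.
#'
#' @param mode `"internal"` (estimate from repeated days) or `"external"`
#'   (use `ratio`).
#' @param ratio Positive within/between variance ratio on the transformed
#'   scale; required meaningfully only for external mode.
#' @return An object of class `"variance_ratio_spec"`.
#' @export
variance_ratio_spec <- function(mode = c("internal", "external"), ratio = NULL) {
  mode <- match.arg(mode)
  placeholder <- FALSE
  if (mode == "external") {
    if (is.null(ratio)) {
      ratio <- 2.0
      placeholder <- TRUE
    }
    if (!is.numeric(ratio) || length(ratio) != 1 || !is.finite(ratio) || ratio <= 0) {
      abort_calfort("external variance ratio must be a single positive number",
                    "calfort_config_error")
    }
  }
  structure(
    list(mode = mode, ratio = ratio, placeholder = placeholder),
    class = "variance_ratio_spec"
  )
}

#' Transformations between the intake and adjustment scales
#'
#' The adjustment operates on a transformed scale on which daily intakes are
#' approximately symmetric. The default is the natural log with a small
#' additive offset so that zero intakes (possible in sparse recalls, though
#' biologically implausible for a full day) remain finite; `"identity"`
#' disables the transformation.
#'
#' @param x Numeric vector of intakes (mg/day) or transformed values.
#' @param transformation `"log"` or `"identity"`.
#' @param offset Additive offset used by the log transformation (mg).
#' @return Transformed (`intake_transform`) or back-transformed, non-negative
#'   (`intake_backtransform`) numeric vector.
#' @export
intake_transform <- function(x, transformation = c("log", "identity"), offset = 1) {
  transformation <- match.arg(transformation)
  if (any(x < 0, na.rm = TRUE)) {
    abort_calfort("intakes must be non-negative", "calfort_validation_error")
  }
  switch(transformation, log = log(x + offset), identity = x)
}

#' @rdname intake_transform
#' @export
intake_backtransform <- function(x, transformation = c("log", "identity"), offset = 1) {
  transformation <- match.arg(transformation)
  out <- switch(transformation, log = exp(x) - offset, identity = x)
  pmax(out, 0)
}

#' Estimate within- and between-person variance components
#'
#' One-way random-effects decomposition of transformed daily intakes:
#' the within-person variance is the (weighted) mean over subjects with at
#' least two recall days of the per-subject sample variance; the
#' between-person variance is the weighted variance of subject means minus
#' `within_var / mean_days`, floored at zero (subject means of few days still
#' carry within-person noise).
#'
#' @param values Numeric vector of daily intakes on the *transformed* scale.
#' @param subject_id Subject identifier for each value.
#' @param weights Optional positive survey weight per value (constant within
#'   subject); default 1.
#' @return An object of class `"variance_components"`: a list with
#'   `between_var`, `within_var`, `n_subjects`, `n_repeat_subjects`,
#'   `mean_days`.
#' @export
estimate_variance_components <- function(values, subject_id, weights = NULL) {
  if (length(values) != length(subject_id)) {
    abort_calfort("values and subject_id must have the same length",
                  "calfort_validation_error")
  }
  if (is.null(weights)) weights <- rep(1, length(values))
  d <- tibble::tibble(v = values, id = as.character(subject_id), w = weights) |>
    dplyr::group_by(.data$id) |>
    dplyr::summarise(
      m = mean(.data$v),
      s2 = if (dplyr::n() >= 2) var(.data$v) else NA_real_,
      k = dplyr::n(),
      w = .data$w[1],
      .groups = "drop"
    )
  if (nrow(d) < 2) {
    abort_calfort("at least 2 subjects are required to estimate variance components",
                  "calfort_validation_error")
  }
  rep_sub <- !is.na(d$s2)
  if (!any(rep_sub)) {
    abort_calfort(
      paste0(
        "no subject has repeated recall days; within-person variance cannot be ",
        "estimated internally - supply an external variance ratio ",
        "(variance_ratio_spec(mode = 'external', ratio = ...))"
      ),
      "calfort_data_error"
    )
  }
  within <- wtd_mean(d$s2[rep_sub], d$w[rep_sub])
  mean_days <- wtd_mean(d$k, d$w)
  between <- max(0, wtd_sd(d$m, d$w)^2 - within / mean_days)
  structure(
    list(
      between_var = between,
      within_var = within,
      n_subjects = nrow(d),
      n_repeat_subjects = sum(rep_sub),
      mean_days = mean_days
    ),
    class = "variance_components"
  )
}

#' @export
print.variance_components <- function(x, ...) {
  cat("Variance components (transformed scale)\n")
  cat(sprintf("  between-person: %.4f\n", x$between_var))
  cat(sprintf("  within-person:  %.4f\n", x$within_var))
  cat(sprintf("  subjects: %d (%d with repeated days; mean days %.2f)\n",
              x$n_subjects, x$n_repeat_subjects, x$mean_days))
  invisible(x)
}

#' Adjust a one-day intake distribution toward the usual-intake distribution
#'
#' A single recall day overstates the spread of habitual intake because it
#' mixes between-person differences with within-person day-to-day noise. The
#' adjustment shrinks each transformed day-1 intake toward the weighted group
#' mean,
#' \deqn{t_i' = m + (t_i - m)\sqrt{1/(1 + r)},}
#' where `r` is the within/between variance ratio, then back-transforms. This
#' preserves the weighted mean on the transformed scale exactly, multiplies
#' the transformed-scale SD by `sqrt(1/(1+r))`, and is strictly monotone (no
#' re-ranking of subjects) whenever `r` is finite.
#'
#' @param intakes_mg Day-1 intakes in mg/day (non-negative).
#' @param weights Optional positive survey weights (default 1).
#' @param variance A [variance_ratio_spec()].
#' @param components A `"variance_components"` object; required for internal
#'   mode.
#' @param transformation,offset See [intake_transform()].
#' @param subject_id,group_label Optional identifiers carried into the result
#'   for export and plotting.
#' @return An object of class `"usual_intake"`: a list with `values_mg`
#'   (adjusted usual intakes, one per subject), `weights`, `subject_id`,
#'   `group_label`, `ratio`, `transformation`, `offset`.
#' @export
adjust_distribution <- function(intakes_mg, weights = NULL,
                                variance = variance_ratio_spec("external", 2),
                                components = NULL,
                                transformation = c("log", "identity"),
                                offset = 1,
                                subject_id = NULL, group_label = NULL) {
  transformation <- match.arg(transformation)
  if (length(intakes_mg) == 0) {
    abort_calfort("cannot adjust an empty intake distribution", "calfort_validation_error")
  }
  if (is.null(weights)) weights <- rep(1, length(intakes_mg))
  if (length(weights) != length(intakes_mg) || any(weights <= 0)) {
    abort_calfort("weights must be positive and match intakes in length",
                  "calfort_validation_error")
  }
  if (!inherits(variance, "variance_ratio_spec")) {
    abort_calfort("variance must be a variance_ratio_spec()", "calfort_config_error")
  }

  degenerate <- FALSE
  if (variance$mode == "external") {
    if (isTRUE(variance$placeholder) && !isFALSE(attr(variance, "warned"))) {
      warning(
        "using the shipped placeholder external variance ratio (2.0); ",
        "set variance_ratio_spec(mode = 'external', ratio = ...) from a ",
        "comparable survey for any real analysis",
        call. = FALSE
      )
    }
    ratio <- variance$ratio
  } else {
    if (!inherits(components, "variance_components")) {
      abort_calfort(
        "internal mode requires variance components from estimate_variance_components()",
        "calfort_config_error"
      )
    }
    if (components$between_var == 0) {
      warning(
        "between-person variance is zero; the adjusted distribution is ",
        "degenerate at the group mean",
        call. = FALSE
      )
      degenerate <- TRUE
      ratio <- Inf
    } else {
      ratio <- components$within_var / components$between_var
    }
  }

  t <- intake_transform(intakes_mg, transformation, offset)
  m <- wtd_mean(t, weights)
  lambda <- if (is.infinite(ratio)) 0 else sqrt(1 / (1 + ratio))
  t_adj <- m + (t - m) * lambda
  values <- intake_backtransform(t_adj, transformation, offset)

  structure(
    list(
      values_mg = values,
      weights = weights,
      subject_id = subject_id,
      group_label = group_label,
      ratio = ratio,
      lambda = lambda,
      degenerate = degenerate,
      transformation = transformation,
      offset = offset
    ),
    class = "usual_intake"
  )
}

#' @export
print.usual_intake <- function(x, ...) {
  cat("Usual-intake distribution")
  if (!is.null(x$group_label)) cat(" [", x$group_label, "]", sep = "")
  cat("\n")
  cat(sprintf(
    "  n = %d, mean = %.1f mg/day, SD = %.1f mg/day (ratio = %s, %s scale)\n",
    length(x$values_mg),
    wtd_mean(x$values_mg, x$weights),
    wtd_sd(x$values_mg, x$weights),
    format(round(x$ratio, 3)), x$transformation
  ))
  invisible(x)
}

#' Weighted percentile with linear interpolation
#'
#' Continuous generalization of the standard sample quantile (R's type 7) to
#' weighted data: values are placed at cumulative-weight positions and the
#' percentile `p` is read off at position `1 + (W - 1) * p / 100` (total
#' weight `W`), interpolating linearly between adjacent positions. With
#' integer weights this is identical to expanding each value into that many
#' copies and taking the ordinary type-7 quantile.
#'
#' @param x Numeric vector.
#' @param w Positive weights (default 1).
#' @param p Percentiles in `[0, 100]` (vectorized).
#' @return Numeric vector, one value per element of `p`.
#' @export
#' @examples
#' weighted_percentile(c(100, 200, 300, 400), p = 50) # 250
#' weighted_percentile(c(1, 2, 3), w = c(1, 1, 2), p = 50) # 2.5
weighted_percentile <- function(x, w = NULL, p) {
  if (length(x) == 0) {
    abort_calfort("cannot take percentiles of an empty distribution",
                  "calfort_validation_error")
  }
  if (any(!is.finite(p)) || any(p < 0) || any(p > 100)) {
    abort_calfort("percentiles must lie in [0, 100]", "calfort_validation_error")
  }
  if (is.null(w)) w <- rep(1, length(x))
  o <- order(x)
  x <- x[o]
  w <- w[o]
  cw <- cumsum(w)
  W <- cw[length(cw)]
  value_at <- function(pos) {
    pos <- min(pos, W)
    x[which(cw >= pos - 1e-9)[1]]
  }
  vapply(p, function(pp) {
    h <- 1 + (W - 1) * pp / 100
    lo <- floor(h)
    f <- h - lo
    if (f == 0) value_at(lo) else (1 - f) * value_at(lo) + f * value_at(lo + 1)
  }, numeric(1))
}

#' Percentiles of a usual-intake distribution
#'
#' @param dist A `"usual_intake"` object from [adjust_distribution()], or a
#'   numeric vector (then `weights` applies).
#' @param p Percentiles in `[0, 100]`.
#' @param weights Optional weights when `dist` is a plain numeric vector.
#' @return Intake in mg/day at each requested percentile; monotone in `p`.
#' @export
percentile <- function(dist, p, weights = NULL) {
  if (inherits(dist, "usual_intake")) {
    weighted_percentile(dist$values_mg, dist$weights, p)
  } else {
    weighted_percentile(dist, weights, p)
  }
}

#' Export a usual-intake distribution as CSV for audit
#'
#' @param dist A `"usual_intake"` object.
#' @param path Output CSV path (columns `subject_id`, `usual_mg`, `weight`).
#' @return The path, invisibly.
#' @export
write_usual_intake <- function(dist, path) {
  stopifnot(inherits(dist, "usual_intake"))
  out <- tibble::tibble(
    subject_id = dist$subject_id %||% as.character(seq_along(dist$values_mg)),
    usual_mg = dist$values_mg,
    weight = dist$weights
  )
  readr::write_csv(out, path)
  invisible(path)
}
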