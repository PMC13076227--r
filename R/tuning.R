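# Orientation tuning: wrapped two-Gaussian fits, OSI and tuning width.

# wrapped angular difference in [-180, 180)
ang_diff <- function(x) ((x + 180) %% 360) - 180

two_gaussian <- function(theta, baseline, r_pref, r_opp, theta_pref, sigma) {
  baseline +
    r_pref * exp(-ang_diff(theta - theta_pref)^2 / (2 * sigma^2)) +
    r_opp * exp(-ang_diff(theta - theta_pref - 180)^2 / (2 * sigma^2))
}

#' Screen visual responsiveness and orientation selectivity
#'
#' Two Kruskal-Wallis tests on per-trial response amplitudes:
#' `p_responsive` over nine groups (eight directions plus the blank
#' condition) and `p_selective` over the eight direction groups only.
#' When all responses are identical there is no variation to test and both
#' p-values are 1.
#'
#' @param response Numeric vector of per-trial response amplitudes.
#' @param direction Direction of each trial in degrees, with `NA` (or
#'   `"blank"`) marking blank trials.
#' @return Named numeric vector `c(p_responsive, p_selective)`.
#' @export
screen_responsiveness <- function(response, direction) {
  if (is.character(direction) || is.factor(direction)) {
    direction <- suppressWarnings(as.numeric(as.character(direction)))
  }
  is_blank <- is.na(direction)
  grp_all <- ifelse(is_blank, "blank", as.character(direction))
  counts <- table(grp_all)
  if (any(counts < 2)) abort("every condition needs at least 2 trials.")
  p_resp <- kw_p(response, grp_all)
  p_sel <- kw_p(response[!is_blank], as.character(direction[!is_blank]))
  c(p_responsive = p_resp, p_selective = p_sel)
}

kw_p <- function(x, g) {
  if (length(unique(x)) == 1) return(1)
  kruskal.test(x, factor(g))$p.value
}

#' Fit a wrapped two-Gaussian orientation tuning curve
#'
#' Least-squares fit of
#' `R(theta) = B + Rp * exp(-d(theta - theta_p)^2 / (2 sigma^2))
#'           + Ro * exp(-d(theta - theta_p - 180)^2 / (2 sigma^2))`
#' where `d()` is the wrapped angular difference, the two lobes share one
#' width `sigma`, and the amplitudes are constrained nonnegative with
#' `Rp >= Ro` enforced by relabelling (shifting `theta_p` by 180 deg). The
#' optimiser is Levenberg-Marquardt, multi-started from each sampled
#' direction; the best fit by residual sum of squares wins. Flat response
#' profiles are flagged rather than fitted.
#'
#' @param directions Stimulus directions in degrees (typically 0-315 in
#'   45-degree steps).
#' @param responses Mean response per direction (same length).
#' @return A `tuning_fit` object: list with `coef` (named vector
#'   `baseline`, `r_pref`, `r_opp`, `theta_pref`, `sigma`), `rss`,
#'   `converged`, `flat`, plus the data.
#' @seealso [compute_osi()], [compute_tuning_width()], [predict.tuning_fit()]
#' @export
#' @examples
#' th <- seq(0, 315, by = 45)
#' r <- two_gaussian_response(th, 0.1, 1, 0.5, 45, 25)
#' fit <- fit_two_gaussian_tuning(th, r)
#' coef(fit)
fit_two_gaussian_tuning <- function(directions, responses) {
  stopifnot(length(directions) == length(responses))
  if (length(directions) < 5) {
    abort("need at least 5 directions to fit 5 parameters.")
  }
  spread <- max(responses) - min(responses)
  if (spread == 0) {
    return(new_tuning_fit(
      coef = c(baseline = responses[1], r_pref = 0, r_opp = 0,
               theta_pref = NA_real_, sigma = NA_real_),
      rss = 0, converged = FALSE, flat = TRUE,
      directions = directions, responses = responses))
  }
  resid_fn <- function(p) {
    two_gaussian(directions, p[1], p[2], p[3], p[4], p[5]) - responses
  }
  lower <- c(-Inf, 0, 0, -Inf, 1)
  upper <- c(Inf, Inf, Inf, Inf, 180)
  best <- NULL
  for (th0 in directions) {
    start <- c(min(responses), spread,
               max(0, responses[which.min(abs(ang_diff(directions - th0 - 180)))] -
                     min(responses)),
               th0, 30)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = start, fn = resid_fn, lower = lower,
                         upper = upper,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss) {
      best <- list(par = fit$par, rss = rss,
                   converged = fit$info %in% 1:4)
    }
  }
  if (is.null(best)) {
    return(new_tuning_fit(
      coef = c(baseline = NA_real_, r_pref = NA_real_, r_opp = NA_real_,
               theta_pref = NA_real_, sigma = NA_real_),
      rss = NA_real_, converged = FALSE, flat = FALSE,
      directions = directions, responses = responses))
  }
  p <- best$par
  if (p[3] > p[2]) {  # relabel so the preferred lobe is the larger
    p <- c(p[1], p[3], p[2], p[4] + 180, p[5])
  }
  p[4] <- p[4] %% 360
  new_tuning_fit(
    coef = c(baseline = p[1], r_pref = p[2], r_opp = p[3],
             theta_pref = p[4], sigma = p[5]),
    rss = best$rss, converged = best$converged, flat = FALSE,
    directions = directions, responses = responses)
}

new_tuning_fit <- function(coef, rss, converged, flat, directions,
                           responses) {
  structure(list(coef = coef, rss = rss, converged = converged, flat = flat,
                 directions = directions, responses = responses),
            class = "tuning_fit")
}

#' Evaluate the wrapped two-Gaussian tuning model
#'
#' @param theta Directions in degrees.
#' @param baseline,r_pref,r_opp,theta_pref,sigma Model parameters
#'   (amplitudes in response units, angles in degrees).
#' @return Model responses at `theta`.
#' @export
two_gaussian_response <- function(theta, baseline, r_pref, r_opp,
                                  theta_pref, sigma) {
  two_gaussian(theta, baseline, r_pref, r_opp, theta_pref, sigma)
}

#' @export
coef.tuning_fit <- function(object, ...) object$coef

#' @export
print.tuning_fit <- function(x, ...) {
  if (x$flat) {
    cat("<tuning_fit> flat response profile (flagged; no preferred direction)\n")
  } else {
    cat(sprintf(
      "<tuning_fit> theta_pref = %.1f deg, sigma = %.1f deg, Rp = %.3g, Ro = %.3g, B = %.3g (rss %.3g)\n",
      x$coef["theta_pref"], x$coef["sigma"], x$coef["r_pref"],
      x$coef["r_opp"], x$coef["baseline"], x$rss))
  }
  invisible(x)
}

#' Predict from a tuning fit
#'
#' @param object A `tuning_fit`.
#' @param newdata Directions in degrees (default: the fitted directions).
#' @param ... Unused.
#' @return Fitted responses.
#' @export
predict.tuning_fit <- function(object, newdata = NULL, ...) {
  theta <- newdata %||% object$directions
  p <- object$coef
  if (object$flat) return(rep(p[["baseline"]], length(theta)))
  two_gaussian(theta, p[["baseline"]], p[["r_pref"]], p[["r_opp"]],
               p[["theta_pref"]], p[["sigma"]])
}

#' Tidy a tuning fit
#'
#' @param x A `tuning_fit`.
#' @param ... Unused.
#' @return Tibble of `term`, `estimate`.
#' @export
tidy.tuning_fit <- function(x, ...) {
  tibble(term = names(x$coef), estimate = unname(x$coef))
}

#' Glance at a tuning fit
#'
#' @param x A `tuning_fit`.
#' @param ... Unused.
#' @return One-row tibble with fit summaries including OSI and widths.
#' @export
glance.tuning_fit <- function(x, ...) {
  w <- compute_tuning_width(x)
  tibble(rss = x$rss, converged = x$converged, flat = x$flat,
         osi = compute_osi(x), sigma = w[["sigma"]], fwhm = w[["fwhm"]],
         n = length(x$responses))
}

#' Orientation selectivity index
#'
#' `OSI = (Rpref - Rortho) / (Rpref + Rortho)`: the depth of modulation
#' from the preferred orientation to its orthogonal orientation
#' (theta_ortho = theta_pref + 90 deg). From a fit, `Rpref` is the fitted,
#' baseline-subtracted response at the preferred direction and `Rortho`
#' averages the two orthogonal directions, rectified at zero (a negative
#' fitted orthogonal response counts as 0). May also be called directly
#' with two amplitudes.
#'
#' @param fit A `tuning_fit`, or the numeric `Rpref`.
#' @param r_ortho When `fit` is numeric: `Rortho`.
#' @return OSI in \[0, 1\] for nonnegative rectified amplitudes; `NA`
#'   (flagged via attribute `reason`) when undefined.
#' @export
#' @examples
#' compute_osi(2, 1)  # 1/3
compute_osi <- function(fit, r_ortho = NULL) {
  if (is.numeric(fit)) {
    stopifnot(!is.null(r_ortho))
    r_pref <- fit
  } else {
    stopifnot(inherits(fit, "tuning_fit"))
    if (fit$flat || !is.finite(fit$coef[["theta_pref"]])) {
      return(structure(NA_real_, reason = "flat or unidentified fit"))
    }
    th <- fit$coef[["theta_pref"]]
    b <- fit$coef[["baseline"]]
    r_pref <- predict(fit, th) - b
    r_ortho <- max(0, mean(predict(fit, c(th + 90, th - 90)) - b))
  }
  if (r_pref + r_ortho <= 0) {
    return(structure(NA_real_, reason = "zero denominator"))
  }
  (r_pref - r_ortho) / (r_pref + r_ortho)
}

#' Tuning width: sigma and full width at half maximum
#'
#' The tuning width of the principal lobe, reported both as the fitted
#' Gaussian `sigma` and as the full width at half maximum,
#' `FWHM = 2 * sqrt(2 * ln 2) * sigma` (about 2.355 sigma).
#'
#' @param fit A `tuning_fit`, or a numeric `sigma` in degrees.
#' @return Named vector `c(sigma, fwhm)` in degrees.
#' @export
#' @examples
#' compute_tuning_width(25)  # fwhm 58.87
compute_tuning_width <- function(fit) {
  sigma <- if (is.numeric(fit)) fit else fit$coef[["sigma"]]
  c(sigma = sigma, fwhm = 2 * sqrt(2 * log(2)) * sigma)
}

#' Maximum response at the direction nearest the preferred one
#'
#' The measured (not fitted) mean response at the sampled direction
#' closest to the preferred direction; ties go to the smaller angle.
#'
#' @param fit A `tuning_fit`.
#' @param directions Sampled directions (degrees); default those in `fit`.
#' @param responses Mean responses per direction; default those in `fit`.
#' @return The mean response at the nearest sampled direction.
#' @export
max_response <- function(fit, directions = NULL, responses = NULL) {
  directions <- directions %||% fit$directions
  responses <- responses %||% fit$responses
  th <- fit$coef[["theta_pref"]]
  if (!is.finite(th)) return(NA_real_)
  d <- abs(ang_diff(directions - th))
  nearest <- which(d == min(d))
  if (length(nearest) > 1) nearest <- nearest[which.min(directions[nearest])]
  responses[nearest]
}

#' Fit tuning curves for a table of trials
#'
#' The tidy entry point for the orientation-tuning analysis: takes a
#' per-trial table, screens each cell for responsiveness and orientation
#' selectivity (Kruskal-Wallis), fits the wrapped two-Gaussian model to
#' the per-direction mean responses, and summarises OSI, tuning width and
#' maximum response.
#'
#' @param trials Tibble with columns `cell_id`, `direction_deg` (`NA` for
#'   blank trials) and `response`.
#' @return Tibble with one row per cell: `cell_id`, `theta_pref`, `osi`,
#'   `sigma`, `fwhm`, `max_response`, `p_responsive`, `p_selective`,
#'   `converged`, `flat`.
#' @export
fit_tuning <- function(trials) {
  stopifnot(all(c("cell_id", "direction_deg", "response") %in% names(trials)))
  trials |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::group_modify(function(df, key) {
      scr <- screen_responsiveness(df$response, df$direction_deg)
      tuned <- df[!is.na(df$direction_deg), ]
      means <- tuned |>
        dplyr::group_by(.data$direction_deg) |>
        dplyr::summarise(m = mean(.data$response), .groups = "drop")
      fit <- fit_two_gaussian_tuning(means$direction_deg, means$m)
      w <- compute_tuning_width(fit)
      tibble(
        theta_pref = unname(fit$coef["theta_pref"]),
        osi = as.numeric(compute_osi(fit)),
        sigma = unname(w[["sigma"]]), fwhm = unname(w[["fwhm"]]),
        max_response = max_response(fit, means$direction_deg, means$m),
        p_responsive = unname(scr["p_responsive"]),
        p_selective = unname(scr["p_selective"]),
        converged = fit$converged, flat = fit$flat)
    }) |>
    dplyr::ungroup()
}

#' Simulate an orientation-tuning dataset
#'
#' Draws per-trial response amplitudes from the wrapped two-Gaussian model
#' plus Gaussian noise, over eight directions (by default) and a blank
#' condition, together with the generating parameters per cell.
#'
#' @param n_cells Number of cells (default 50).
#' @param directions Evenly spaced stimulus directions in degrees.
#' @param repeats Trials per condition (default 15; must be >= 1).
#' @param true_params Optional tibble with columns `cell_id`, `baseline`,
#'   `r_pref`, `r_opp`, `theta_pref`, `sigma`; drawn at random when
#'   omitted (theta_pref uniform, sigma 15-40 deg, r_pref 0.5-2,
#'   r_opp/r_pref 0-0.8, baseline 0-0.1).
#' @param noise_sd Per-trial noise SD; default 10% of each cell's
#'   `r_pref`. A scalar applies to all cells (0 gives noiseless trials).
#' @param seed Integer seed.
#' @return List with `trials` (tibble: `cell_id`, `direction_deg` with
#'   `NA` for blanks, `trial`, `response`) and `params` (the generating
#'   parameters, including the realised `noise_sd`).
#' @export
simulate_tuning_dataset <- function(n_cells = 50,
                                    directions = seq(0, 315, by = 45),
                                    repeats = 15, true_params = NULL,
                                    noise_sd = NULL, seed = 1) {
  if (repeats < 1) abort("`repeats` must be >= 1.")
  steps <- diff(sort(directions))
  if (length(unique(round(steps, 9))) > 1) {
    abort("`directions` must be evenly spaced.")
  }
  withr::with_seed(seed, {
    if (is.null(true_params)) {
      true_params <- tibble(
        cell_id = sprintf("cell_%03d", seq_len(n_cells)),
        baseline = runif(n_cells, 0, 0.1),
        r_pref = runif(n_cells, 0.5, 2),
        r_opp = NA_real_,
        theta_pref = runif(n_cells, 0, 360),
        sigma = runif(n_cells, 15, 40))
      true_params$r_opp <- true_params$r_pref * runif(n_cells, 0, 0.8)
    } else {
      true_params <- as_tibble(true_params)
      n_cells <- nrow(true_params)
    }
    sdv <- noise_sd %||% (0.1 * true_params$r_pref)
    if (length(sdv) == 1) sdv <- rep(sdv, n_cells)
    true_params$noise_sd <- sdv

    conds <- c(directions, NA_real_)  # NA = blank
    trials <- tidyr::expand_grid(
      cell = seq_len(n_cells),
      direction_deg = conds,
      trial = seq_len(repeats))
    p <- true_params[trials$cell, ]
    mu <- ifelse(
      is.na(trials$direction_deg),
      p$baseline,
      two_gaussian(ifelse(is.na(trials$direction_deg), 0,
                          trials$direction_deg),
                   p$baseline, p$r_pref, p$r_opp, p$theta_pref, p$sigma))
    trials$response <- mu + rnorm(nrow(trials), 0, p$noise_sd)
    trials <- tibble(cell_id = true_params$cell_id[trials$cell],
                     direction_deg = trials$direction_deg,
                     trial = trials$trial, response = trials$response)
    list(trials = trials, params = true_params)
  })
}
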