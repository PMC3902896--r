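#' Scaling factors linking binding curves to cellular dose-response curves
#'
#' Three global factors map an in vitro binding isotherm onto a cellular
#' fold-activation dose-response curve:
#' \itemize{
#'   \item \code{d}: y-axis amplitude (unitless) — the rise from baseline to
#'     plateau, absorbing the action of all other transcription factors;
#'   \item \code{e}: y-axis baseline fold-activation (unitless, > 0) — the
#'     plateau is \code{e + d};
#'   \item \code{f}: x-axis conversion from ng of receptor expression vector
#'     to molar free receptor (molar per ng), assuming expression is linear
#'     in vector dose.
#' }
#' Alternate conventions exist (e.g. treating the amplitude parameter as the
#' plateau itself); with this parameterization plateau = \code{e + d}, so any
#' such reading maps onto these factors by \code{d' = plateau - e}.
#'
#' @param d amplitude, \code{>= 0}.
#' @param e baseline, \code{> 0}.
#' @param f molar-per-ng dose conversion, \code{> 0}.
#' @return object of class \code{scaling_parameters}.
#' @export
scaling_parameters <- function(d, e, f) {
  if (!is.numeric(d) || length(d) != 1L || !is.finite(d) || d < 0) {
    stop("invalid parameter: 'd' must be a single non-negative number",
         call. = FALSE)
  }
  check_positive(e, "e")
  check_positive(f, "f")
  structure(list(d = d, e = e, f = f), class = "scaling_parameters")
}

#' @export
print.scaling_parameters <- function(x, ...) {
  cat("Scaling parameters: d =", format(x$d, digits = 4),
      " e =", format(x$e, digits = 4),
      " f =", format(x$f, digits = 4), "M/ng\n")
  invisible(x)
}

#' Predicted fold-activation at a given expression-vector dose
#'
#' The thermodynamic dose-response model: fold-activation is a rescaled
#' dimer-binding isotherm,
#' \deqn{FA(D) = e + d \cdot \bar{Y}_{dimer}(f D, k_{tot})}
#' so FA runs from the baseline \code{e} at zero dose to the plateau
#' \code{e + d} at saturating dose, with midpoint where
#' \code{f * D = sqrt(k_tot)}.
#'
#' @param dose expression-vector dose in ng, non-negative; vectorized.
#' @param k_tot total dissociation constant (molar^2) of the HRE.
#' @param s [scaling_parameters()].
#' @return predicted fold-activation, same length as \code{dose}.
#' @export
predict_fold_activation <- function(dose, k_tot, s) {
  stopifnot(inherits(s, "scaling_parameters"))
  check_conc(dose, "dose")
  s$e + s$d * ybar_dimer(s$f * dose, k_tot)
}

#' Global fit of shared scaling factors across dose-response curves
#'
#' Fits a single set of scaling factors (d, e, f) to all curves at once by
#' pooled least squares, with each curve's \code{k_tot} held fixed at its
#' independently measured value. Because d, e and f are common to every
#' curve, all binding isotherms are rescaled identically; the only per-HRE
#' input is its binding affinity. Recovering the data this way is the direct
#' test of whether DNA binding energetics account for sequence-specific
#' activation.
#'
#' Optimization is multi-start: f is initialized on a log-spaced grid
#' (1 fM/ng to 1 uM/ng), d and e from the observed activity range, and each
#' start is refined with \code{stats::nlminb} on log-transformed parameters;
#' the best converged start wins. Least squares is unweighted by default;
#' \code{weight_by_sem = TRUE} weights each point by \code{1/sem^2}.
#'
#' @param curves data.frame with columns \code{hre}, \code{dose_ng},
#'   \code{fold_activation} (and optionally \code{sem}, \code{n_rep});
#'   several HREs stacked.
#' @param hres HRE table (see [hre_table()]) providing \code{k_tot} (molar^2)
#'   for every HRE present in \code{curves}.
#' @param weight_by_sem logical; weight residuals by 1/sem^2.
#' @return object of class \code{scaling_fit}: list with \code{s}
#'   ([scaling_parameters()]), \code{fit_sd} (pooled RMS residual on N - 3
#'   df), \code{per_curve_sd} (named RMS residual per HRE, no df correction),
#'   \code{n_points}, \code{converged}.
#' @export
fit_scaling_global <- function(curves, hres, weight_by_sem = FALSE) {
  curves <- validate_curves(curves)
  if (length(unique(curves$hre)) < 1L || nrow(curves) < 5L) {
    stop("insufficient data: need at least 5 points", call. = FALSE)
  }
  missing <- setdiff(unique(curves$hre), hres$hre)
  if (length(missing) > 0) {
    stop("configuration error: no k_tot for HRE(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  ktot <- hres$k_tot[match(curves$hre, hres$hre)]
  dose <- curves$dose_ng
  fa <- curves$fold_activation
  w <- if (weight_by_sem) {
    if (!("sem" %in% names(curves)) || any(curves$sem <= 0)) {
      stop("configuration error: positive 'sem' column required for weighting",
           call. = FALSE)
    }
    1 / curves$sem^2
  } else {
    rep(1, length(fa))
  }

  obj <- function(theta) {
    p <- exp(theta)  # (d, e, f) > 0
    pred <- p[2L] + p[1L] * (p[3L] * dose)^2 / (ktot + (p[3L] * dose)^2)
    sum(w * (fa - pred)^2)
  }

  d0 <- max(max(fa) - min(fa), 1e-3)
  e0 <- max(min(fa), 1e-3)
  f_starts <- log_grid(1e-15, 1e-6, 10)
  best <- NULL
  for (f0 in f_starts) {
    fit <- tryCatch(
      stats::nlminb(log(c(d0, e0, f0)), obj,
                    control = list(iter.max = 500, eval.max = 1000)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$objective < best$objective)) {
      best <- fit
    }
  }
  if (is.null(best)) {
    stop("global scaling fit failed from every start", call. = FALSE)
  }
  p <- exp(best$par)
  s <- scaling_parameters(p[1L], p[2L], p[3L])
  pred <- s$e + s$d * (s$f * dose)^2 / (ktot + (s$f * dose)^2)
  resid <- fa - pred

  converged <- best$convergence == 0
  # f is unidentifiable when the fitted response never leaves its baseline
  if (diff(range(pred)) < 1e-6 || stats::sd(fa) < 1e-10) {
    warning("dose-response data are flat; scaling factor f is not ",
            "identifiable", call. = FALSE)
    converged <- FALSE
  }

  per_curve <- vapply(split(resid, curves$hre),
                      function(r) sqrt(mean(r^2)), numeric(1))
  structure(
    list(s = s,
         fit_sd = fit_sd(resid, n_params = 3L),
         per_curve_sd = per_curve,
         n_points = length(fa),
         converged = converged),
    class = "scaling_fit")
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat("Global dose-response fit (shared d, e, f; per-HRE k_tot fixed)\n")
  print(x$s)
  cat("  pooled fit SD:", format(x$fit_sd, digits = 4),
      " (n =", x$n_points, ", converged =", x$converged, ")\n")
  invisible(x)
}

#' Predict the dose-response curve of a new HRE
#'
#' Pure prediction with no refitting: given an HRE's measured \code{k_tot}
#' and scaling factors resolved on other response elements, evaluate the
#' model on a dose grid. A 100-fold weaker \code{k_tot} shifts the predicted
#' half-maximal dose 10-fold to the right (midpoint at
#' \code{f * D = sqrt(k_tot)}).
#'
#' @param k_tot total dissociation constant (molar^2).
#' @param s [scaling_parameters()], typically from [fit_scaling_global()].
#' @param doses dose grid in ng (may be empty).
#' @param hre label for the returned curve.
#' @return data.frame with columns \code{hre}, \code{dose_ng},
#'   \code{fold_activation}.
#' @export
predict_new_hre <- function(k_tot, s, doses, hre = "predicted") {
  check_positive(k_tot, "k_tot")
  if (length(doses) == 0) {
    return(data.frame(hre = character(), dose_ng = numeric(),
                      fold_activation = numeric()))
  }
  data.frame(hre = hre, dose_ng = doses,
             fold_activation = predict_fold_activation(doses, k_tot, s))
}

validate_curves <- function(curves) {
  stopifnot(is.data.frame(curves))
  if (!all(c("hre", "dose_ng", "fold_activation") %in% names(curves))) {
    stop("curves need columns 'hre', 'dose_ng', 'fold_activation'",
         call. = FALSE)
  }
  if (any(!is.finite(curves$dose_ng)) || any(curves$dose_ng < 0)) {
    stop("invalid parameter: doses must be non-negative and finite",
         call. = FALSE)
  }
  if (any(!is.finite(curves$fold_activation))) {
    stop("invalid parameter: fold-activation must be finite", call. = FALSE)
  }
  curves
}
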