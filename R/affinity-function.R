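#' Cross-section through a family of dose-response curves
#'
#' The traditional affinity-vs-function plot is a cross-section: pick one
#' expression-vector dose, read off each HRE's fold-activation at that dose,
#' and pair it with the HRE's binding affinity. Fold-activation is
#' interpolated linearly between adjacent tabulated doses; doses outside a
#' curve's grid raise an error (no extrapolation).
#'
#' @param curves data.frame of dose-response curves (\code{hre},
#'   \code{dose_ng}, \code{fold_activation}).
#' @param dose single dose (ng) at which to take the cross-section.
#' @param hres HRE table supplying affinities.
#' @param affinity which affinity to report: \code{"k_app"} (molar) or
#'   \code{"k_tot"} (molar^2).
#' @return data.frame with columns \code{hre}, \code{affinity}, \code{fa},
#'   one row per HRE.
#' @export
cross_section <- function(curves, dose, hres, affinity = c("k_app", "k_tot")) {
  affinity <- match.arg(affinity)
  curves <- validate_curves(curves)
  if (length(dose) != 1L || !is.finite(dose) || dose < 0) {
    stop("invalid parameter: 'dose' must be a single non-negative number",
         call. = FALSE)
  }
  by_hre <- split(curves, curves$hre)
  fa <- vapply(by_hre, function(cv) {
    if (dose < min(cv$dose_ng) || dose > max(cv$dose_ng)) {
      stop("extrapolation error: dose ", dose, " ng outside the grid of HRE '",
           cv$hre[1L], "'", call. = FALSE)
    }
    stats::approx(cv$dose_ng, cv$fold_activation, xout = dose,
                  ties = mean)$y
  }, numeric(1))
  name <- names(by_hre)
  aff <- hres[[affinity]][match(name, hres$hre)]
  if (any(is.na(aff))) {
    stop("configuration error: missing affinity for HRE(s): ",
         paste(name[is.na(aff)], collapse = ", "), call. = FALSE)
  }
  data.frame(hre = name, affinity = aff, fa = unname(fa),
             row.names = NULL)
}

#' Ordinary least-squares regression of activity on affinity
#'
#' Regresses fold-activation on binding affinity, either on the raw scale or
#' after base-10 log transformation of both variables. Log transformation
#' linearizes the intrinsically non-linear affinity-function relationship and
#' is the standard way to test for correlation; the raw linear fit is kept
#' because it is what the traditional analysis reports. Significance is the
#' F-test of the regression slope: P is the probability that the observed
#' R-squared arises from two uncorrelated variables, from the F distribution
#' with (1, n - 2) degrees of freedom.
#'
#' @param pairs data.frame with columns \code{affinity} and \code{fa} (one
#'   row per HRE), e.g. from [cross_section()].
#' @param scale \code{"linear"} or \code{"log10"} (both variables
#'   transformed).
#' @return object of class \code{regression_result}: list with \code{scale},
#'   \code{slope}, \code{intercept}, \code{r_squared}, \code{f_stat},
#'   \code{p_value}, \code{n}.
#' @examples
#' tab <- hre_table()
#' regress(data.frame(affinity = tab$k_app, fa = tab$fold_activation), "log10")
#' @export
regress <- function(pairs, scale = c("linear", "log10")) {
  scale <- match.arg(scale)
  stopifnot(is.data.frame(pairs),
            all(c("affinity", "fa") %in% names(pairs)))
  n <- nrow(pairs)
  if (n < 3L) {
    stop("insufficient data: regression needs at least 3 pairs", call. = FALSE)
  }
  x <- pairs$affinity
  y <- pairs$fa
  if (scale == "log10") {
    if (any(x <= 0) || any(y <= 0)) {
      stop("invalid parameter: log10 scale requires positive values",
           call. = FALSE)
    }
    x <- log10(x)
    y <- log10(y)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("degenerate regression: a variable has zero variance", call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  r2 <- sm$r.squared
  f_stat <- unname(sm$fstatistic[1L])
  structure(
    list(scale = scale,
         slope = unname(stats::coef(fit)[2L]),
         intercept = unname(stats::coef(fit)[1L]),
         r_squared = r2,
         f_stat = f_stat,
         p_value = stats::pf(f_stat, 1, n - 2, lower.tail = FALSE),
         n = n),
    class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat("Affinity-function regression [", x$scale, " scale]\n", sep = "")
  cat("  slope = ", format(x$slope, digits = 4),
      ", intercept = ", format(x$intercept, digits = 4), "\n", sep = "")
  cat("  R^2 = ", format(x$r_squared, digits = 3),
      ", P = ", format(x$p_value, digits = 3),
      " (F = ", format(x$f_stat, digits = 4),
      ", n = ", x$n, ")\n", sep = "")
  invisible(x)
}

#' P-value for an observed R-squared under the no-correlation null
#'
#' Survival function of \eqn{F = R^2 (n-2) / (1 - R^2)} at (1, n - 2)
#' degrees of freedom: the probability that an R-squared at least this large
#' arises from two uncorrelated variables.
#'
#' @param r_squared coefficient of determination in \code{[0, 1]}.
#' @param n number of pairs (at least 3).
#' @return p-value in \code{(0, 1]}; \code{r_squared = 1} returns 0 with a
#'   warning.
#' @export
regression_pvalue <- function(r_squared, n) {
  if (!is.finite(r_squared) || r_squared < 0 || r_squared > 1) {
    stop("invalid parameter: r_squared must lie in [0, 1]", call. = FALSE)
  }
  if (n < 3) {
    stop("insufficient data: need n >= 3", call. = FALSE)
  }
  if (r_squared == 1) {
    warning("r_squared = 1: p-value is degenerate at 0", call. = FALSE)
    return(0)
  }
  f <- r_squared * (n - 2) / (1 - r_squared)
  stats::pf(f, 1, n - 2, lower.tail = FALSE)
}

#' Fold-range (max/min) of a set of positive values
#'
#' Summary used to express the dynamic range of an affinity column: the
#' apparent affinities of the reference HRE panel span ~60-fold, while the
#' total affinities reveal a true range of nearly 700-fold.
#'
#' @param values positive numeric vector.
#' @return max(values) / min(values).
#' @examples
#' fold_range(hre_table()$k_app)  # 62.5
#' @export
fold_range <- function(values) {
  if (length(values) < 1L || any(!is.finite(values)) || any(values <= 0)) {
    stop("invalid parameter: values must be positive and finite",
         call. = FALSE)
  }
  max(values) / min(values)
}

#' Specify a simulated global perturbation
#'
#' Two perturbations that mimic common experiments: uniformly weakening every
#' HRE's binding affinity (e.g. a receptor or DNA mutation), or uniformly
#' reducing the maximal fold-activity of every HRE (e.g. a coactivator
#' knockdown).
#'
#' @param kind \code{"affinity_fold_reduction"} (multiply every dissociation
#'   \code{k_tot} by \code{factor}) or \code{"max_activity_fold_reduction"}
#'   (divide the plateau \code{e + d} by \code{factor}, keeping the baseline).
#' @param factor fold change, \code{>= 1}.
#' @return object of class \code{perturbation_spec}.
#' @export
perturbation_spec <- function(kind = c("affinity_fold_reduction",
                                       "max_activity_fold_reduction"),
                              factor) {
  kind <- match.arg(kind)
  if (!is.numeric(factor) || length(factor) != 1L || !is.finite(factor) ||
      factor < 1) {
    stop("invalid parameter: 'factor' must be a single finite number >= 1",
         call. = FALSE)
  }
  structure(list(kind = kind, factor = factor), class = "perturbation_spec")
}

#' Apply a perturbation to the model inputs
#'
#' Returns modified HRE records and scaling parameters. An affinity
#' reduction multiplies every dissociation-scale \code{k_tot} by the factor
#' (weaker binding); a max-activity reduction rescales the amplitude so the
#' plateau \code{e + d} is divided by the factor while the baseline \code{e}
#' is unchanged. A perturbation that would drive the amplitude negative
#' (plateau below baseline) is an error.
#'
#' @param hres HRE table.
#' @param s [scaling_parameters()].
#' @param spec [perturbation_spec()].
#' @return list with elements \code{hres} and \code{s}, perturbed.
#' @export
apply_perturbation <- function(hres, s, spec) {
  stopifnot(inherits(spec, "perturbation_spec"),
            inherits(s, "scaling_parameters"))
  if (spec$kind == "affinity_fold_reduction") {
    hres$k_tot <- hres$k_tot * spec$factor
    hres$k_tot_fM2 <- hres$k_tot / 1e-15
  } else {
    new_d <- (s$e + s$d) / spec$factor - s$e
    if (new_d < 0) {
      stop("invalid perturbation: plateau would fall below the baseline",
           call. = FALSE)
    }
    s <- scaling_parameters(new_d, s$e, s$f)
  }
  list(hres = hres, s = s)
}

#' Simulated perturbation experiment with replicate noise and significance
#'
#' Simulates, at one expression dose, a perturbation experiment the way it
#' would be scored at the bench: noisy replicate activities for wild-type
#' and perturbed conditions for every HRE, the mean perturbed/wild-type
#' activity ratio, and a Welch two-sample t-test of perturbed vs wild-type
#' replicates with significance flags at P < 0.05 (\code{*}) and P < 0.005
#' (\code{**}).
#'
#' Noise is relative Gaussian (each replicate is the model activity times
#' \code{1 + N(0, cv)}). With zero noise and factor 1 all ratios are exactly
#' 1 and nothing is flagged.
#'
#' @param hres HRE table.
#' @param s [scaling_parameters()].
#' @param spec [perturbation_spec()].
#' @param dose expression-vector dose (ng).
#' @param n_rep replicates per condition (at least 2).
#' @param noise_cv relative noise SD per replicate.
#' @param seed RNG seed.
#' @return data.frame with one row per HRE: \code{hre}, \code{ratio} (mean
#'   perturbed/wild-type), \code{ratio_sem}, \code{p_value},
#'   \code{significance} ("", "*", "**").
#' @export
perturbation_report <- function(hres, s, spec, dose, n_rep = 3,
                                noise_cv = 0.08, seed = NULL) {
  if (n_rep < 2) {
    stop("insufficient data: need at least 2 replicates to test",
         call. = FALSE)
  }
  pert <- apply_perturbation(hres, s, spec)
  with_seed(seed, {
    rows <- lapply(seq_len(nrow(hres)), function(i) {
      mu_wt <- predict_fold_activation(dose, hres$k_tot[i], s)
      mu_pt <- predict_fold_activation(dose, pert$hres$k_tot[i], pert$s)
      wt <- mu_wt * (1 + stats::rnorm(n_rep, 0, noise_cv))
      pt <- mu_pt * (1 + stats::rnorm(n_rep, 0, noise_cv))
      ratios <- pt / mean(wt)
      p <- if (noise_cv == 0) {
        if (isTRUE(all.equal(mu_wt, mu_pt))) 1 else 0
      } else {
        stats::t.test(pt, wt)$p.value
      }
      data.frame(hre = hres$hre[i],
                 ratio = mean(ratios),
                 ratio_sem = if (noise_cv == 0) 0 else
                   stats::sd(ratios) / sqrt(n_rep),
                 p_value = p,
                 significance = if (p < 0.005) "**" else
                   if (p < 0.05) "*" else "")
    })
    do.call(rbind, rows)
  })
}
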