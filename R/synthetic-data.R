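#' Specify a noise model for synthetic data
#'
#' Three noise kinds cover the data types the analyses consume:
#' \itemize{
#'   \item \code{"additive_gaussian"}: saturation-scale noise
#'     \code{y + N(0, sd)}; footprint titration scatter is well described by
#'     an additive SD of about 0.087.
#'   \item \code{"relative_gaussian"}: multiplicative noise
#'     \code{y * (1 + N(0, cv))}, for reporter activities.
#'   \item \code{"per_hre_sem"}: relative noise calibrated per HRE from the
#'     reference table's fold-activation SEMs: relative SD =
#'     \code{sqrt(n) * SEM / FA} with n = 3 transfection replicates.
#' }
#'
#' @param kind one of the above.
#' @param sd_or_cv noise magnitude (ignored for \code{"per_hre_sem"}).
#' @param n_rep number of replicates to generate.
#' @param seed RNG seed; the same seed always reproduces the same data.
#' @param sd deprecated-style convenience alias for \code{sd_or_cv}.
#' @return object of class \code{noise_model}.
#' @export
noise_model <- function(kind = c("additive_gaussian", "relative_gaussian",
                                 "per_hre_sem"),
                        sd_or_cv = 0.087, n_rep = 2, seed = NULL, sd = NULL) {
  kind <- match.arg(kind)
  if (!is.null(sd)) sd_or_cv <- sd
  if (!is.numeric(sd_or_cv) || sd_or_cv < 0) {
    stop("invalid parameter: noise magnitude must be non-negative",
         call. = FALSE)
  }
  if (n_rep < 1) stop("invalid parameter: n_rep must be >= 1", call. = FALSE)
  structure(list(kind = kind, sd_or_cv = sd_or_cv, n_rep = as.integer(n_rep),
                 seed = seed),
            class = "noise_model")
}

#' Generate synthetic footprint-titration isotherms
#'
#' Simulates replicate binding isotherms from the dimer-assembly model:
#' \code{ybar = ybar_dimer(x, k_tot) + e} with additive Gaussian noise, the
#' data shape produced by quantitative footprint titration. Noisy values are
#' clipped to \code{[-0.2, 1.2]} (the same bounds the fitters accept); any
#' clipping is reported via a message. A grid that does not bracket the
#' transition midpoint \code{sqrt(k_tot)} triggers an identifiability
#' warning.
#'
#' @param k_tot generating total dissociation constant (molar^2).
#' @param grid free monomer concentrations (molar); default 12 log-spaced
#'   points from 1 nM to 3 uM.
#' @param noise [noise_model()]; \code{n_rep} replicates are generated with
#'   independent noise.
#' @param hre label stored with the isotherm.
#' @return data.frame with columns \code{hre}, \code{replicate},
#'   \code{conc_molar}, \code{ybar}.
#' @examples
#' make_isotherm(0.800e-15, noise = noise_model(sd = 0.087, seed = 1))
#' @export
make_isotherm <- function(k_tot, grid = log_grid(1e-9, 3e-6, 12),
                          noise = noise_model(), hre = "synthetic") {
  check_positive(k_tot, "k_tot")
  check_conc(grid, "grid")
  mid <- sqrt(k_tot)
  if (min(grid) > mid || max(grid) < mid) {
    warning("concentration grid does not bracket the midpoint sqrt(k_tot); ",
            "the constant may not be identifiable", call. = FALSE)
  }
  mu <- ybar_dimer(grid, k_tot)
  with_seed(noise$seed, {
    reps <- lapply(seq_len(noise$n_rep), function(r) {
      y <- mu + stats::rnorm(length(grid), 0, noise$sd_or_cv)
      clipped <- y < -0.2 | y > 1.2
      if (any(clipped)) {
        message(sum(clipped), " synthetic saturation value(s) clipped to ",
                "[-0.2, 1.2]")
        y <- pmin(pmax(y, -0.2), 1.2)
      }
      data.frame(hre = hre, replicate = paste0("rep", r),
                 conc_molar = grid, ybar = y)
    })
    do.call(rbind, reps)
  })
}

#' Default expression-vector dose grid
#'
#' Ten log-spaced doses from 3 to 1500 ng, the span over which reporter
#' dose-response curves are typically measured and simulated.
#'
#' @return numeric vector of doses (ng).
#' @export
default_dose_grid <- function() log_grid(3, 1500, 10)

#' Simulate a noise-free dose-response family from binding energetics
#'
#' The "energetics-only" model family: every HRE produces the same maximal
#' fold increase \code{f_max}, and activity at each dose is governed purely
#' by dimer-model occupancy at that HRE's \code{k_tot}:
#' \deqn{FA_i(D) = 1 + (f_{max} - 1)\, \bar{Y}_{dimer}(f D, k_{tot,i})}
#' Each curve is a binding isotherm rescaled into dose/fold-activation
#' units; at the dose where \code{f * D = sqrt(k_tot_i)} every curve passes
#' through \code{(1 + f_max) / 2}.
#'
#' @param hres HRE table with \code{k_tot} (molar^2).
#' @param f_max maximal fold-activation at saturation (>= 1); default 5, the
#'   standard choice for illustrating cross-section non-linearity.
#' @param f molar free receptor per ng of expression vector; default 1 nM/ng.
#' @param doses dose grid (ng).
#' @return data.frame with columns \code{hre}, \code{dose_ng},
#'   \code{fold_activation} (noise-free).
#' @export
simulate_dose_response_family <- function(hres, f_max = 5, f = 1e-9,
                                          doses = default_dose_grid()) {
  if (!is.numeric(f_max) || f_max < 1) {
    stop("invalid parameter: f_max must be >= 1", call. = FALSE)
  }
  if (!("k_tot" %in% names(hres)) || any(is.na(hres$k_tot))) {
    stop("configuration error: every HRE needs a k_tot", call. = FALSE)
  }
  s <- scaling_parameters(d = f_max - 1, e = 1, f = f)
  rows <- lapply(seq_len(nrow(hres)), function(i) {
    predict_new_hre(hres$k_tot[i], s, doses, hre = hres$hre[i])
  })
  do.call(rbind, rows)
}

#' Error-perturb dose-response curves with replicate structure
#'
#' Adds noise to simulated curves the way transfection assays scatter:
#' \code{n_rep} independent replicate activities per point, summarized as
#' mean and SEM. Under \code{"per_hre_sem"} the relative SD of each HRE is
#' calibrated from the reference table (\code{sqrt(n) * fa_sem /
#' fold_activation}, n = 3), so simulated scatter matches the measured
#' per-sequence scatter; \code{"relative_gaussian"} applies one common CV;
#' \code{"additive_gaussian"} adds saturation-scale noise directly.
#'
#' @param curves noise-free curves (\code{hre}, \code{dose_ng},
#'   \code{fold_activation}).
#' @param noise [noise_model()].
#' @param hres HRE table; required for \code{kind = "per_hre_sem"}.
#' @return list with \code{curves}: data.frame \code{hre}, \code{dose_ng},
#'   \code{fold_activation} (replicate mean), \code{sem}, \code{n_rep}; and
#'   \code{replicates}: the long per-replicate table.
#' @export
error_perturb <- function(curves, noise, hres = NULL) {
  curves <- validate_curves(curves)
  stopifnot(inherits(noise, "noise_model"))
  rel_sd <- switch(
    noise$kind,
    relative_gaussian = ,
    additive_gaussian = rep(noise$sd_or_cv, nrow(curves)),
    per_hre_sem = {
      if (is.null(hres)) {
        stop("configuration error: per_hre_sem noise needs the HRE table",
             call. = FALSE)
      }
      idx <- match(curves$hre, hres$hre)
      if (any(is.na(idx))) {
        stop("configuration error: missing SEM entries for HRE(s): ",
             paste(unique(curves$hre[is.na(idx)]), collapse = ", "),
             call. = FALSE)
      }
      sqrt(3) * hres$fa_sem[idx] / hres$fold_activation[idx]
    })

  with_seed(noise$seed, {
    reps <- lapply(seq_len(noise$n_rep), function(r) {
      eps <- stats::rnorm(nrow(curves), 0, rel_sd)
      fa <- if (noise$kind == "additive_gaussian") {
        curves$fold_activation + eps
      } else {
        curves$fold_activation * (1 + eps)
      }
      data.frame(hre = curves$hre, dose_ng = curves$dose_ng,
                 replicate = paste0("rep", r), fold_activation = fa)
    })
    long <- do.call(rbind, reps)
    key <- interaction(long$hre, long$dose_ng, drop = TRUE)
    mean_fa <- tapply(long$fold_activation, key, mean)
    sem_fa <- tapply(long$fold_activation, key,
                     function(v) stats::sd(v) / sqrt(length(v)))
    kk <- interaction(curves$hre, curves$dose_ng, drop = TRUE)
    out <- data.frame(hre = curves$hre, dose_ng = curves$dose_ng,
                      fold_activation = as.numeric(mean_fa[as.character(kk)]),
                      sem = as.numeric(sem_fa[as.character(kk)]),
                      n_rep = noise$n_rep)
    list(curves = out, replicates = long)
  })
}
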