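tab <- hre_table()

test_that("log-log regression of the reference panel reproduces the known
           correlation; the linear scale hides it", {
  pairs <- data.frame(affinity = tab$k_app, fa = tab$fold_activation)
  ll <- regress(pairs, "log10")
  expect_equal(round(ll$r_squared, 2), 0.73)
  expect_equal(ll$p_value, 0.0137, tolerance = 1e-2)
  expect_lt(ll$slope, 0)

  lin <- regress(pairs, "linear")
  expect_equal(lin$r_squared, 0.4406, tolerance = 1e-3)

  # the log-scale correlation barely changes between the two affinity scales
  lt <- regress(data.frame(affinity = tab$k_tot, fa = tab$fold_activation),
                "log10")
  expect_equal(lt$r_squared, 0.75, tolerance = 1e-2)
  expect_lt(abs(lt$r_squared - ll$r_squared), 0.05)
})

test_that("regression internals are consistent and degenerate cases error", {
  pairs <- data.frame(affinity = 1:6, fa = 2 * (1:6) + 3)
  perfect <- suppressWarnings(regress(pairs, "linear"))  # collinear by design
  expect_equal(perfect$r_squared, 1)
  expect_equal(perfect$slope, 2)

  r <- regress(data.frame(affinity = tab$k_app, fa = tab$fold_activation),
               "log10")
  # r_squared, F and P must be mutually consistent at df (1, n - 2)
  expect_equal(r$f_stat, r$r_squared * (r$n - 2) / (1 - r$r_squared),
               tolerance = 1e-12)
  expect_equal(regression_pvalue(r$r_squared, r$n), r$p_value,
               tolerance = 1e-12)

  expect_error(regress(pairs[1:2, ], "linear"), "insufficient data")
  expect_error(regress(data.frame(affinity = c(1, 1, 1), fa = c(1, 2, 3)),
                       "linear"), "degenerate")
  expect_error(regress(data.frame(affinity = c(-1, 1, 2), fa = c(1, 2, 3)),
                       "log10"), "positive")
})

test_that("regress is equivariant under unit changes", {
  pairs <- data.frame(affinity = tab$k_app, fa = tab$fold_activation)
  # linear R^2 invariant under affine rescaling of the affinity axis
  r1 <- regress(pairs, "linear")
  r2 <- regress(transform(pairs, affinity = affinity * 1e9), "linear")
  expect_equal(r1$r_squared, r2$r_squared, tolerance = 1e-12)
  # log-scale slope/R^2 invariant under multiplicative unit change
  l1 <- regress(pairs, "log10")
  l2 <- regress(transform(pairs, affinity = affinity * 1e9), "log10")
  expect_equal(l1$r_squared, l2$r_squared, tolerance = 1e-12)
  expect_equal(l1$slope, l2$slope, tolerance = 1e-12)
})

test_that("regression_pvalue matches the F survival function", {
  expect_equal(regression_pvalue(0, 7), 1)
  expect_equal(regression_pvalue(0.734, 7), 0.0138, tolerance = 1e-2)
  expect_gt(regression_pvalue(0.99, 7), regression_pvalue(0.9999, 7))
  expect_warning(p1 <- regression_pvalue(1, 7), "degenerate")
  expect_equal(p1, 0)
  expect_error(regression_pvalue(0.5, 2), "insufficient data")
  expect_error(regression_pvalue(1.5, 7), "invalid parameter")
})

test_that("fold ranges of the reference affinity columns", {
  expect_equal(fold_range(tab$k_app), 62.5)
  expect_equal(fold_range(tab$k_tot), 697.5)
  expect_equal(fold_range(rep(3.2, 5)), 1)
  expect_error(fold_range(c(1, 0)), "invalid parameter")
})

test_that("cross-sections interpolate linearly and refuse to extrapolate", {
  fam <- simulate_dose_response_family(tab, f_max = 5, f = 1e-9)
  doses <- sort(unique(fam$dose_ng))

  # at a grid point the cross-section is the tabulated value
  cs <- cross_section(fam, doses[4], tab, "k_app")
  tabulated <- fam$fold_activation[fam$dose_ng == doses[4]]
  expect_equal(sort(cs$fa), sort(tabulated), tolerance = 1e-12)

  # between grid points: exact linear interpolation
  mid <- (doses[4] + doses[5]) / 2
  cs_mid <- cross_section(fam, mid, tab, "k_app")
  pal4 <- fam$fold_activation[fam$hre == "Pal" & fam$dose_ng == doses[4]]
  pal5 <- fam$fold_activation[fam$hre == "Pal" & fam$dose_ng == doses[5]]
  expect_equal(cs_mid$fa[cs_mid$hre == "Pal"], (pal4 + pal5) / 2,
               tolerance = 1e-12)

  expect_error(cross_section(fam, 1e6, tab), "extrapolation")

  # dose 0: every HRE sits at the shared baseline
  fam0 <- rbind(data.frame(hre = unique(fam$hre), dose_ng = 0,
                           fold_activation = 1), fam)
  cs0 <- cross_section(fam0, 0, tab)
  expect_true(all(cs0$fa == 1))
})

test_that("the affinity-function relation from the energetics-only family is
           decreasing and strongly convex", {
  fam <- simulate_dose_response_family(tab, f_max = 5, f = 1e-9)
  # convex in k_tot at the mid-sensitivity dose (exact model algebra)
  cs <- cross_section(fam, 100, tab, "k_tot")
  cs <- cs[order(cs$affinity), ]
  expect_true(all(diff(cs$fa) < 0))
  slopes <- diff(cs$fa) / diff(cs$affinity)
  expect_true(all(diff(slopes) > 0))
  # still decreasing and convex against the apparent affinity at a lower dose
  cs2 <- cross_section(fam, 32, tab, "k_app")
  cs2 <- cs2[order(cs2$affinity), ]
  expect_true(all(diff(cs2$fa) < 0))
  expect_true(all(diff(diff(cs2$fa) / diff(cs2$affinity)) > 0))
  # any family sharing (d, e, f): FA vs k_tot non-increasing at every dose
  for (dose in c(10, 316, 1000)) {
    csd <- cross_section(fam, dose, tab, "k_tot")
    csd <- csd[order(csd$affinity), ]
    expect_true(all(diff(csd$fa) <= 1e-12))
  }
})

test_that("perturbations transform the model inputs as specified", {
  s <- scaling_parameters(4, 1, 1e-9)

  ident <- apply_perturbation(tab, s, perturbation_spec("affinity_fold_reduction", 1))
  expect_equal(ident$hres$k_tot, tab$k_tot)
  expect_equal(ident$s$d, s$d)

  aff <- apply_perturbation(tab, s, perturbation_spec("affinity_fold_reduction", 10))
  expect_equal(aff$hres$k_tot[tab$hre == "Pal"], 8.00e-15)

  # plateau 5 halves to 2.5, so d drops from 4 to 1.5 with e = 1 untouched
  act <- apply_perturbation(tab, s, perturbation_spec("max_activity_fold_reduction", 2))
  expect_equal(act$s$d, 1.5)
  expect_equal(act$s$e, 1)
  expect_error(
    apply_perturbation(tab, s, perturbation_spec("max_activity_fold_reduction", 10)),
    "invalid perturbation")
  expect_error(perturbation_spec("affinity_fold_reduction", 0.5),
               "invalid parameter")
})

test_that("perturbation reports expose the dose-dependence of apparent
           effects", {
  s <- scaling_parameters(1.4, 1, 1e-9)
  ten <- perturbation_spec("affinity_fold_reduction", 10)

  # no noise, factor 1: ratios exactly 1, nothing flagged
  null <- perturbation_report(tab, s, perturbation_spec("affinity_fold_reduction", 1),
                              dose = 100, noise_cv = 0)
  expect_true(all(null$ratio == 1))
  expect_true(all(null$significance == ""))

  # low dose reveals changes at high-affinity sites...
  low <- perturbation_report(tab, s, ten, dose = 100, noise_cv = 0)
  expect_lt(low$ratio[low$hre == "Pal"], low$ratio[low$hre == "TAT4"])
  # ...high dose at low-affinity sites
  high <- perturbation_report(tab, s, ten, dose = 1000, noise_cv = 0)
  expect_lt(high$ratio[high$hre == "TAT4"], high$ratio[high$hre == "Pal"])

  # halving the maximal activity at a saturating dose hits all HREs equally
  sat <- perturbation_report(tab, s,
                             perturbation_spec("max_activity_fold_reduction", 2),
                             dose = 1e5, noise_cv = 0)
  expect_equal(sat$ratio, rep(0.5, nrow(tab)), tolerance = 1e-3)

  # with noise the test machinery flags large effects and is reproducible
  noisy1 <- perturbation_report(tab, s, ten, dose = 100, n_rep = 3,
                                noise_cv = 0.08, seed = 9)
  noisy2 <- perturbation_report(tab, s, ten, dose = 100, n_rep = 3,
                                noise_cv = 0.08, seed = 9)
  expect_identical(noisy1, noisy2)
  expect_true(noisy1$significance[noisy1$hre == "Pal"] %in% c("*", "**"))
  expect_error(perturbation_report(tab, s, ten, dose = 100, n_rep = 1),
               "insufficient data")
})
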