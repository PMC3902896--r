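test_that("state counting follows the per-site choice structure", {
  trio <- trio_species()
  one_pal <- enumerate_microstates(promoter_architecture("palindrome"),
                                   trio[3])
  expect_equal(nrow(one_pal), 2)           # empty; dimer-bound

  two_sites <- enumerate_microstates(
    promoter_architecture(c("half", "palindrome")), trio)
  expect_equal(nrow(two_sites), (3 + 1)^2) # independent per-site choices

  both <- enumerate_microstates(promoter_architecture(c("half", "half")),
                                trio[1])
  w <- both$weight_expr[both$state == "red|red"]
  expect_match(w, "\\(x_red/k_half\\)\\^2")
  expect_match(w, "k_c_red\\^1")

  expect_error(promoter_architecture(rep("half", 13)), "size error")
})

test_that("enumeration matches hand-derived closed forms for every
           architecture of up to 3 sites and 3 species", {
  trio <- trio_species()
  site_types <- c("half", "palindrome")
  totals_of <- function(n) c(50e-9, 300e-9, 2e-6)[seq_len(n)]
  for (L in 1:3) {
    archs <- expand.grid(rep(list(site_types), L), stringsAsFactors = FALSE)
    for (a in seq_len(nrow(archs))) {
      sites <- unlist(archs[a, ], use.names = FALSE)
      for (ns in 1:3) {
        species <- trio[seq_len(ns)]
        got <- prob_fully_ligated(promoter_architecture(sites), species,
                                  totals_of(ns))
        want <- oracle_prob_full(sites, species, totals_of(ns))
        expect_equal(as.numeric(got), as.numeric(want), tolerance = 1e-10)
      }
    }
  }
})

test_that("state probabilities normalize to one at every concentration", {
  trio <- trio_species()
  arch <- promoter_architecture(c("half", "palindrome", "half"))
  for (conc in c(0, 1e-9, 1e-7, 1e-5)) {
    p <- prob_fully_ligated(arch, trio, rep(conc, 3), details = TRUE)
    states <- attr(p, "states")
    expect_equal(sum(states$probability), 1, tolerance = 1e-10)
    expect_true(all(states$probability >= 0 & states$probability <= 1))
    expect_equal(sum(p) + attr(p, "p_empty") + attr(p, "p_other"), 1,
                 tolerance = 1e-10)
  }
})

test_that("unit cooperativity factorizes joint occupancy into independent
           sites", {
  sp <- receptor_species("GR", k_dim = 16e-9, k_half = 1e-6, k_pal = 10e-9,
                         k_c = 1)
  single <- prob_fully_ligated(promoter_architecture("half"), list(sp), 100e-9)
  joint <- prob_fully_ligated(promoter_architecture(c("half", "half")),
                              list(sp), 100e-9)
  expect_equal(joint[["GR"]], single[["GR"]]^2, tolerance = 1e-10)

  mix <- prob_fully_ligated(promoter_architecture(c("half", "palindrome")),
                            list(sp), 100e-9)
  pal <- prob_fully_ligated(promoter_architecture("palindrome"), list(sp),
                            100e-9)
  expect_equal(mix[["GR"]], single[["GR"]] * pal[["GR"]], tolerance = 1e-10)
})

test_that("identical species are exchangeable and split the homotypic
           probability equally", {
  a <- receptor_species("A", k_dim = 1e-6, k_half = 1e-6, k_pal = 10e-9,
                        k_c = 50)
  b <- receptor_species("B", k_dim = 1e-6, k_half = 1e-6, k_pal = 10e-9,
                        k_c = 50)
  arch <- promoter_architecture(c("palindrome", "half"))
  p_ab <- prob_fully_ligated(arch, list(a, b), c(200e-9, 200e-9))
  p_ba <- prob_fully_ligated(arch, list(b, a), c(200e-9, 200e-9))
  expect_equal(p_ab[["A"]], p_ab[["B"]], tolerance = 1e-12)
  expect_equal(p_ab[["A"]], p_ba[["A"]], tolerance = 1e-12)
})

test_that("a species' full occupancy is monotone in its own concentration", {
  trio <- trio_species()
  arch <- promoter_architecture(c("half", "palindrome"))
  grid <- 10^seq(-9, -5, length.out = 15)
  p_blue <- vapply(grid, function(conc) {
    prob_fully_ligated(arch, trio, c(100e-9, conc, 100e-9))[["blue"]]
  }, numeric(1))
  expect_true(all(diff(p_blue) > -1e-12))
})

test_that("single-species anchors: measured-affinity palindrome occupancy and
           saturation", {
  gr <- receptor_species("GR", k_dim = 16e-9, k_half = 1e-6, k_pal = 10e-9)
  arch <- promoter_architecture("palindrome")
  expect_equal(prob_fully_ligated(arch, list(gr), 0)[["GR"]], 0)
  # at 100 nM total: x = 24.57 nM, [M2] = 37.7 nM, P = 37.7/(10 + 37.7)
  expect_equal(prob_fully_ligated(arch, list(gr), 100e-9)[["GR"]], 0.790,
               tolerance = 1e-3)
  expect_gt(prob_fully_ligated(arch, list(gr), 1)[["GR"]], 0.9999)
})

test_that("non-dimerizing species cannot use the pre-formed-dimer pathway,
           and the single-monomer palindrome mode is switchable", {
  nod <- receptor_species("AR", k_dim = NA, k_half = 1e-6, k_pal = 10e-9)
  arch <- promoter_architecture("palindrome")
  expect_equal(prob_fully_ligated(arch, list(nod), 1e-6)[["AR"]], 0)

  st <- enumerate_microstates(arch, list(nod),
                              include_single_palindrome = TRUE)
  expect_equal(nrow(st), 3)  # empty, dimer (weight 0 here), single monomer
  p <- prob_fully_ligated(arch, list(nod), 1e-6,
                          include_single_palindrome = TRUE)
  expect_equal(p[["AR"]], 0)                    # monomer mode is partial
  expect_gt(attr(p, "p_other"), 0.5)            # 2x/k_half = 2 at 1 uM
})

test_that("competitive sweeps reproduce the architecture-dependent hierarchy
           of the three-species benchmark", {
  trio <- trio_species()
  grid <- 10^seq(-10, -4, length.out = 31)

  # isolated half-site: weak dimerization wins everywhere (most free monomer)
  half <- sweep_by_species(
    occupancy_sweep(promoter_architecture("half"), trio, grid))
  expect_true(all(half$red$probability >= half$blue$probability - 1e-12))
  expect_true(all(half$blue$probability >= half$green$probability - 1e-12))

  # isolated palindrome: the ordering reverses
  pal <- sweep_by_species(
    occupancy_sweep(promoter_architecture("palindrome"), trio, grid))
  expect_true(all(pal$green$probability >= pal$blue$probability - 1e-12))
  expect_true(all(pal$blue$probability >= pal$red$probability - 1e-12))

  # a sweep at one grid point reproduces prob_fully_ligated
  one <- occupancy_sweep(promoter_architecture("half"), trio, grid[5])
  direct <- prob_fully_ligated(promoter_architecture("half"), trio,
                               rep(grid[5], 3))
  expect_equal(one$probability[one$state_class == "homotypic_full"],
               as.numeric(direct), tolerance = 1e-12)

  expect_error(occupancy_sweep(promoter_architecture("half"), trio,
                               numeric(0)), "empty")
})

test_that("multi-site promoters hand preferential occupancy to different
           species", {
  trio <- trio_species()
  grid <- 10^seq(-10, -4, length.out = 31)

  two_pal <- sweep_by_species(occupancy_sweep(
    promoter_architecture(c("palindrome", "palindrome")), trio, grid))
  blue_top <- two_pal$blue$probability >
    pmax(two_pal$red$probability, two_pal$green$probability)
  expect_true(any(blue_top))

  two_half <- sweep_by_species(occupancy_sweep(
    promoter_architecture(c("half", "half")), trio, grid))
  red_top <- two_half$red$probability >
    pmax(two_half$blue$probability, two_half$green$probability)
  expect_true(any(red_top))
})
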