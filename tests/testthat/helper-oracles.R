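# Hand-derived closed forms used as independent oracles for the occupancy
# simulator, plus the standard three-species parameter set.

# Solution monomer/dimer from total receptor, independent of the package:
# 2x^2/k + x = R  =>  x = (-k + sqrt(k^2 + 8 k R)) / 4;  [M2] = (R - x)/2.
oracle_solution <- function(r_total, k_dim) {
  if (is.na(k_dim)) {
    return(list(x = r_total, m2 = 0))
  }
  x <- (-k_dim + sqrt(k_dim^2 + 8 * k_dim * r_total)) / 4
  list(x = x, m2 = (r_total - x) / 2)
}

# Per-site binding factor for species sp at a site of given type.
oracle_site_factor <- function(sp, site, sol) {
  if (site == "half") sol$x / sp$k_half else sol$m2 / sp$k_pal
}

# Homotypic full-occupancy probabilities from explicit 1/2/3-site partition
# functions (sums written out by hand; cooperativity only between adjacent
# sites occupied by the same species).
oracle_prob_full <- function(sites, species, totals) {
  ns <- length(species)
  sol <- lapply(seq_len(ns), function(s) {
    oracle_solution(totals[s], species[[s]]$k_dim)
  })
  a <- sapply(seq_along(sites), function(i) {
    vapply(seq_len(ns), function(s) {
      oracle_site_factor(species[[s]], sites[i], sol[[s]])
    }, numeric(1))
  })
  a <- matrix(a, nrow = ns)  # a[s, i]: factor for species s at site i
  kc <- vapply(species, `[[`, numeric(1), "k_c")
  L <- length(sites)
  if (L == 1) {
    z <- 1 + sum(a[, 1])
    full <- a[, 1] / z
  } else if (L == 2) {
    z <- 1 + sum(a[, 1]) + sum(a[, 2])
    for (s in 1:ns) for (t in 1:ns) {
      z <- z + a[s, 1] * a[t, 2] * if (s == t) kc[s] else 1
    }
    full <- a[, 1] * a[, 2] * kc / z
  } else if (L == 3) {
    z <- 1 + sum(a[, 1]) + sum(a[, 2]) + sum(a[, 3])
    for (s in 1:ns) for (t in 1:ns) {
      z <- z + a[s, 1] * a[t, 2] * if (s == t) kc[s] else 1  # sites 1,2
      z <- z + a[s, 2] * a[t, 3] * if (s == t) kc[s] else 1  # sites 2,3
      z <- z + a[s, 1] * a[t, 3]                              # 1,3 not adjacent
    }
    for (s in 1:ns) for (t in 1:ns) for (u in 1:ns) {
      w <- a[s, 1] * a[t, 2] * a[u, 3]
      if (s == t) w <- w * kc[s]
      if (t == u) w <- w * kc[t]
      z <- z + w
    }
    full <- a[, 1] * a[, 2] * a[, 3] * kc^2 / z
  } else {
    stop("oracle only covers 1-3 sites")
  }
  names(full) <- vapply(species, `[[`, character(1), "name")
  full
}

# The standard competitive trio: identical site affinities, energetics
# partitioned differently between dimerization and cooperativity.
trio_species <- function() {
  list(
    receptor_species("red", k_dim = 10e-6, k_half = 1e-6, k_pal = 10e-9,
                     k_c = 200),
    receptor_species("blue", k_dim = 1e-6, k_half = 1e-6, k_pal = 10e-9,
                     k_c = 50),
    receptor_species("green", k_dim = 16e-9, k_half = 1e-6, k_pal = 10e-9,
                     k_c = 1))
}

sweep_by_species <- function(sweep) {
  full <- sweep[sweep$state_class == "homotypic_full", ]
  split(full, full$species)
}
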