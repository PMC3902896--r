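#' Define a receptor species by its interaction energetics
#'
#' A receptor species is characterized by four microscopic constants
#' (dissociation scale, so smaller = tighter):
#' \itemize{
#'   \item \code{k_dim}: solution dimerization constant (molar), or \code{NA}
#'     for a species with no detectable dimerization. Published values for
#'     such species are lower limits; to use a printed lower limit as if it
#'     were the true constant, simply supply it as \code{k_dim}.
#'   \item \code{k_half}: monomer binding to a half-site (molar).
#'   \item \code{k_pal}: pre-formed dimer binding to a palindrome (molar).
#'   \item \code{k_c}: unitless nearest-neighbor cooperativity multiplying
#'     the weight of adjacent sites jointly occupied by this species;
#'     \code{k_c = 1} means no cooperativity.
#' }
#' Dimers bind palindromes only as pre-formed solution dimers, so a species
#' with \code{k_dim = NA} cannot occupy a palindrome (unless single-monomer
#' palindrome occupancy is enabled in the simulator).
#'
#' @param name species label.
#' @param k_dim molar, positive, or \code{NA}/\code{NULL}.
#' @param k_half molar, positive.
#' @param k_pal molar, positive.
#' @param k_c unitless, positive (default 1).
#' @return object of class \code{receptor_species}.
#' @export
receptor_species <- function(name, k_dim = NA, k_half = 1e-6, k_pal = 10e-9,
                             k_c = 1) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (is.null(k_dim)) k_dim <- NA_real_
  if (!is.na(k_dim)) check_positive(k_dim, "k_dim")
  check_positive(k_half, "k_half")
  check_positive(k_pal, "k_pal")
  check_positive(k_c, "k_c")
  structure(list(name = name, k_dim = as.numeric(k_dim), k_half = k_half,
                 k_pal = k_pal, k_c = k_c),
            class = "receptor_species")
}

#' @export
print.receptor_species <- function(x, ...) {
  cat("Receptor species '", x$name, "': k_dim = ",
      if (is.na(x$k_dim)) "none" else format(x$k_dim, digits = 3),
      " M, k_half = ", format(x$k_half, digits = 3),
      " M, k_pal = ", format(x$k_pal, digits = 3),
      " M, k_c = ", format(x$k_c, digits = 3), "\n", sep = "")
  invisible(x)
}

#' Define a promoter architecture as an ordered list of sites
#'
#' @param sites character vector over \code{{"half", "palindrome"}}, in
#'   promoter order; 1 to 12 sites (the exhaustive-enumeration bound).
#' @return object of class \code{promoter_architecture}.
#' @examples
#' promoter_architecture(c("half", "palindrome"))
#' @export
promoter_architecture <- function(sites) {
  if (!is.character(sites) || !all(sites %in% c("half", "palindrome"))) {
    stop("sites must be a character vector over {\"half\", \"palindrome\"}",
         call. = FALSE)
  }
  if (length(sites) < 1L || length(sites) > 12L) {
    stop("size error: architectures are limited to 1-12 sites", call. = FALSE)
  }
  structure(list(sites = sites), class = "promoter_architecture")
}

#' Enumerate promoter microstates and their statistical weights
#'
#' Builds the full configurational state space of a promoter: every site is
#' either empty or occupied by one species (a monomer on a half-site, a
#' pre-formed dimer on a palindrome). The statistical weight of a state,
#' relative to the empty promoter (weight 1), is
#' \deqn{\prod_{occupied\ sites} c_s \times \prod_{adjacent\ same-species\ pairs} k_{c,s}}
#' where the per-site factor \eqn{c_s} is \code{x_s / k_half_s} for a
#' half-site and \code{[M2]_s / k_pal_s} for a palindrome. Cooperativity is
#' microscopic: one factor of \code{k_c} per nearest-neighbor pair of sites
#' occupied by the same species, regardless of the two site types;
#' heterotypic adjacent pairs receive no cooperativity.
#'
#' @param arch [promoter_architecture()].
#' @param species list of [receptor_species()].
#' @param include_single_palindrome logical; if \code{TRUE}, a palindrome may
#'   also be occupied by a single monomer at one of its two half-sites
#'   (per-site factor \code{2 x_s / k_half_s}); such states count as partial,
#'   not fully ligated. Default \code{FALSE}: palindromes take pre-formed
#'   dimers only.
#' @return data.frame with one row per microstate: columns \code{state}
#'   (string such as \code{"red.GR"} with \code{"."} = empty), per-species
#'   occupancy counts, and \code{weight_expr}, a human-readable expression
#'   for the weight. The exponent bookkeeping needed to evaluate weights
#'   numerically is attached as attributes and consumed by
#'   [prob_fully_ligated()].
#' @export
enumerate_microstates <- function(arch, species,
                                  include_single_palindrome = FALSE) {
  stopifnot(inherits(arch, "promoter_architecture"))
  species <- as_species_list(species)
  n_sites <- length(arch$sites)
  n_sp <- length(species)
  if ((n_sp + 1)^n_sites > 2^22) {
    stop("size error: state space too large to enumerate", call. = FALSE)
  }

  # per-site occupancy options: 0 = empty, j = species j in its default mode,
  # n_sp + j = species j as a single monomer on a palindrome (optional)
  opts <- lapply(arch$sites, function(st) {
    o <- 0:n_sp
    if (st == "palindrome" && include_single_palindrome) {
      o <- c(o, n_sp + seq_len(n_sp))
    }
    o
  })
  states <- as.matrix(expand.grid(opts, KEEP.OUT.ATTRS = FALSE))
  colnames(states) <- paste0("site", seq_len(n_sites))

  sp_of <- function(code) ifelse(code == 0L, 0L,
                                 ifelse(code > n_sp, code - n_sp, code))
  mono_pal <- states > n_sp  # single-monomer-on-palindrome flag
  sp_idx <- matrix(sp_of(states), nrow = nrow(states))

  # sufficient statistics per state and species:
  #   h[s]  - half-site monomers (incl. single monomers on palindromes)
  #   p[s]  - dimer-occupied palindromes
  #   cc[s] - adjacent same-species occupied pairs
  is_pal <- matrix(rep(arch$sites == "palindrome", each = nrow(states)),
                   nrow = nrow(states))
  h <- p <- cc <- matrix(0L, nrow(states), n_sp)
  for (s in seq_len(n_sp)) {
    occ_s <- sp_idx == s
    h[, s] <- rowSums(occ_s & (!is_pal | mono_pal))
    p[, s] <- rowSums(occ_s & is_pal & !mono_pal)
    if (n_sites > 1) {
      for (j in seq_len(n_sites - 1L)) {
        cc[, s] <- cc[, s] + (occ_s[, j] & occ_s[, j + 1L])
      }
    }
  }
  # number of single-monomer palindrome occupancies (statistical factor 2)
  n_mono_pal <- rowSums(mono_pal)

  sp_names <- vapply(species, `[[`, character(1), "name")
  lab <- apply(states, 1L, function(row) {
    paste(ifelse(row == 0L, ".",
                 ifelse(row > n_sp,
                        paste0(sp_names[row - n_sp], "(mono)"),
                        sp_names[row])),
          collapse = "|")
  })
  expr <- vapply(seq_len(nrow(states)), function(i) {
    terms <- character(0)
    for (s in seq_len(n_sp)) {
      if (h[i, s] > 0) terms <- c(terms, sprintf("(x_%s/k_half)^%d",
                                                 sp_names[s], h[i, s]))
      if (p[i, s] > 0) terms <- c(terms, sprintf("(M2_%s/k_pal)^%d",
                                                 sp_names[s], p[i, s]))
      if (cc[i, s] > 0) terms <- c(terms, sprintf("k_c_%s^%d",
                                                  sp_names[s], cc[i, s]))
    }
    if (n_mono_pal[i] > 0) terms <- c(terms, sprintf("2^%d", n_mono_pal[i]))
    if (length(terms) == 0) "1" else paste(terms, collapse = " * ")
  }, character(1))

  out <- data.frame(state = lab, stringsAsFactors = FALSE)
  for (s in seq_len(n_sp)) {
    out[[paste0("n_", sp_names[s])]] <- h[, s] + p[, s]
  }
  out$weight_expr <- expr
  attr(out, "stats") <- list(h = h, p = p, cc = cc, n_mono_pal = n_mono_pal,
                             sp_idx = sp_idx, n_sites = n_sites)
  attr(out, "species") <- species
  out
}

#' Probability that each species fully occupies the promoter
#'
#' Computes, for each receptor species, the equilibrium probability of the
#' homotypic fully ligated state: every promoter site occupied by that one
#' species. Solution-phase monomer and dimer concentrations are first
#' resolved from each species' total concentration via [free_monomer()] and
#' [dimer_conc()] (promoter DNA is assumed to be at trace concentration and
#' does not deplete the receptor pool). State probabilities are weights
#' normalized by the partition function Z (the sum over all microstates).
#'
#' @param arch [promoter_architecture()].
#' @param species list of [receptor_species()].
#' @param totals numeric vector of total receptor concentrations (molar, in
#'   monomer units), one per species.
#' @param include_single_palindrome see [enumerate_microstates()].
#' @param details logical; if \code{TRUE} return the full state table with a
#'   \code{probability} column as attribute \code{"states"}.
#' @return named numeric vector of homotypic full-occupancy probabilities,
#'   one per species, with attributes \code{p_empty} (empty-promoter
#'   probability) and \code{p_other} (all partial/mixed states).
#' @examples
#' gr <- receptor_species("GR", k_dim = 16e-9, k_half = 1e-6, k_pal = 10e-9)
#' prob_fully_ligated(promoter_architecture("palindrome"), list(gr), 100e-9)
#' @export
prob_fully_ligated <- function(arch, species, totals,
                               include_single_palindrome = FALSE,
                               details = FALSE) {
  species <- as_species_list(species)
  if (length(totals) != length(species)) {
    stop("invalid parameter: one total concentration per species",
         call. = FALSE)
  }
  check_conc(totals, "totals")

  st <- enumerate_microstates(arch, species,
                              include_single_palindrome =
                                include_single_palindrome)
  stats <- attr(st, "stats")
  n_sp <- length(species)
  x <- m2 <- numeric(n_sp)
  for (s in seq_len(n_sp)) {
    kd <- species[[s]]$k_dim
    x[s] <- free_monomer(totals[s], if (is.na(kd)) NULL else kd)
    m2[s] <- if (is.na(kd)) 0 else dimer_conc(x[s], kd)
  }

  # log-free weight evaluation; 0^0 = 1 handled by exponent masks
  w <- rep(1, nrow(st))
  for (s in seq_len(n_sp)) {
    sp <- species[[s]]
    w <- w * (x[s] / sp$k_half)^stats$h[, s] *
      (m2[s] / sp$k_pal)^stats$p[, s] *
      sp$k_c^stats$cc[, s]
  }
  w <- w * 2^stats$n_mono_pal
  z <- sum(w)
  prob <- w / z

  full <- vapply(seq_len(n_sp), function(s) {
    # every site occupied by species s in its default (non-mono-pal) mode
    sum(prob[rowSums(stats$sp_idx == s) == stats$n_sites &
               stats$n_mono_pal == 0])
  }, numeric(1))
  names(full) <- vapply(species, `[[`, character(1), "name")
  p_empty <- prob[rowSums(stats$sp_idx) == 0][1L]
  res <- full
  attr(res, "p_empty") <- p_empty
  attr(res, "p_other") <- 1 - sum(full) - p_empty
  if (details) {
    st$probability <- prob
    attr(res, "states") <- st
  }
  res
}

#' Competitive occupancy over a concentration sweep
#'
#' Sweeps total receptor concentration over a grid with every species held
#' at the same total at each grid point (the competitive setup: all species
#' present at equal totals, competing for identical sites), and records each
#' species' homotypic full-occupancy probability plus the aggregate
#' empty and mixed/partial probabilities.
#'
#' @param arch [promoter_architecture()].
#' @param species list of [receptor_species()].
#' @param grid total concentrations (molar), e.g. \code{log_grid}-spaced.
#' @param totals optional function(conc) returning the per-species totals at
#'   a grid point; defaults to equal totals for all species.
#' @param include_single_palindrome see [enumerate_microstates()].
#' @return data.frame in long format: \code{conc_molar}, \code{species},
#'   \code{probability}, \code{state_class} (\code{"homotypic_full"},
#'   \code{"empty"}, \code{"mixed_or_partial"}).
#' @export
occupancy_sweep <- function(arch, species, grid, totals = NULL,
                            include_single_palindrome = FALSE) {
  species <- as_species_list(species)
  if (length(grid) < 1L) {
    stop("invalid parameter: empty concentration grid", call. = FALSE)
  }
  check_conc(grid, "grid")
  if (is.null(totals)) {
    totals <- function(conc) rep(conc, length(species))
  }
  rows <- lapply(grid, function(conc) {
    p <- prob_fully_ligated(arch, species, totals(conc),
                            include_single_palindrome =
                              include_single_palindrome)
    rbind(
      data.frame(conc_molar = conc, species = names(p),
                 probability = as.numeric(p),
                 state_class = "homotypic_full"),
      data.frame(conc_molar = conc, species = "any",
                 probability = c(attr(p, "p_empty"), attr(p, "p_other")),
                 state_class = c("empty", "mixed_or_partial")))
  })
  out <- do.call(rbind, rows)
  row.names(out) <- NULL
  out
}

as_species_list <- function(species) {
  if (inherits(species, "receptor_species")) species <- list(species)
  if (!is.list(species) || length(species) == 0 ||
      !all(vapply(species, inherits, logical(1), "receptor_species"))) {
    stop("'species' must be a receptor_species or a list of them",
         call. = FALSE)
  }
  nm <- vapply(species, `[[`, character(1), "name")
  if (anyDuplicated(nm)) {
    stop("invalid parameter: species names must be unique", call. = FALSE)
  }
  species
}
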