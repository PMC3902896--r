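# Readers and writers for the package's CSV/JSON/YAML dialects. Column names
# carry explicit unit suffixes (conc_molar, dose_ng); provenance is written as
# '#' comment lines so every writer's output round-trips through its reader.

#' Read isotherms from CSV
#'
#' Expects header columns \code{hre}, \code{replicate}, \code{conc_molar},
#' \code{ybar}; lines starting with \code{#} are ignored.
#'
#' @param path CSV file.
#' @return validated isotherm data.frame.
#' @export
read_isotherms <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  validate_isotherms(df)
}

#' Write isotherms to CSV
#'
#' @param isotherms isotherm data.frame.
#' @param path output file.
#' @param provenance optional named list written as \code{#} header comments.
#' @return \code{path}, invisibly.
#' @export
write_isotherms <- function(isotherms, path, provenance = NULL) {
  write_csv_with_header(isotherms, path, provenance)
}

#' Read dose-response curves from CSV
#'
#' Expects columns \code{hre}, \code{dose_ng}, \code{fold_activation} and
#' optionally \code{sem}, \code{n_rep}.
#'
#' @param path CSV file.
#' @return validated curve data.frame.
#' @export
read_dose_response <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  validate_curves(df)
}

#' Write dose-response curves to CSV
#'
#' @param curves curve data.frame.
#' @param path output file.
#' @param provenance optional named list written as \code{#} header comments.
#' @return \code{path}, invisibly.
#' @export
write_dose_response <- function(curves, path, provenance = NULL) {
  write_csv_with_header(curves, path, provenance)
}

#' Write a fit object to JSON
#'
#' Serializes \code{binding_fit}, \code{scaling_fit} or
#' \code{regression_result} objects (residual vectors are dropped) together
#' with optional provenance.
#'
#' @param fit fit object.
#' @param path output file.
#' @param provenance optional named list stored under \code{"provenance"}.
#' @return \code{path}, invisibly.
#' @export
write_fit_json <- function(fit, path, provenance = NULL) {
  x <- unclass(fit)
  x$residuals <- NULL
  if (inherits(fit$s, "scaling_parameters")) x$s <- unclass(fit$s)
  if (!is.null(provenance)) x$provenance <- provenance
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(path)
}

#' Read receptor species and promoter architecture from a config file
#'
#' JSON or YAML (by extension). Layout, with explicit unit suffixes:
#' \preformatted{
#' species:
#'   - name: green
#'     k_dim_molar: 1.6e-8   # omit or null for no dimerization
#'     k_half_molar: 1.0e-6
#'     k_pal_molar: 1.0e-8
#'     k_c: 1
#' architecture: [half, palindrome]
#' }
#'
#' @param path config file (\code{.json}, \code{.yaml} or \code{.yml}).
#' @return list with \code{species} (list of [receptor_species()]) and
#'   \code{architecture} ([promoter_architecture()] or \code{NULL}).
#' @export
read_species_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    stop("unit mismatch: species config must be .json or .yaml", call. = FALSE)
  }
  if (is.null(cfg$species)) {
    stop("configuration error: config has no 'species' entry", call. = FALSE)
  }
  species <- lapply(cfg$species, function(sp) {
    receptor_species(
      name = sp$name,
      k_dim = if (is.null(sp$k_dim_molar)) NA else sp$k_dim_molar,
      k_half = sp$k_half_molar,
      k_pal = sp$k_pal_molar,
      k_c = if (is.null(sp$k_c)) 1 else sp$k_c)
  })
  arch <- if (!is.null(cfg$architecture)) {
    promoter_architecture(unlist(cfg$architecture))
  }
  list(species = species, architecture = arch)
}

write_csv_with_header <- function(df, path, provenance = NULL) {
  con <- file(path, open = "w")
  on.exit(close(con))
  if (!is.null(provenance)) {
    for (nm in names(provenance)) {
      writeLines(paste0("# ", nm, ": ",
                        paste(format(provenance[[nm]]), collapse = " ")), con)
    }
  }
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
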