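#' Reference table of HRE binding affinities and fold-activation
#'
#' Returns the bundled reference panel of seven glucocorticoid response
#' elements: name, sequence (hexamer-spacer-hexamer), apparent affinity
#' \code{k_app} from the Langmuir model, total affinity \code{k_tot} from the
#' dimer-assembly model, and ligand-induced fold-activation at a 100 ng dose
#' of receptor expression vector (mean of 3 transfection replicates, +/- SEM).
#'
#' Affinities are dissociation-scale. The printed-unit columns
#' (\code{k_app_nM}, \code{k_tot_fM2}) are kept alongside canonical molar
#' columns: \code{k_app} in M, \code{k_tot} in M^2 (1 fM^2 = 1e-15 M^2; see
#' [ybar_dimer()] for why this is the only self-consistent reading).
#'
#' @param path CSV file to read instead of the bundled fixture; must follow
#'   the same column layout.
#' @return a \code{data.frame} with one row per HRE and columns \code{hre},
#'   \code{sequence}, \code{k_app_nM}, \code{k_app_sd_nM}, \code{k_tot_fM2},
#'   \code{k_tot_sd_fM2}, \code{fold_activation}, \code{fa_sem}, plus derived
#'   molar-scale \code{k_app}, \code{k_app_sd}, \code{k_tot}, \code{k_tot_sd}.
#' @examples
#' hre_table()
#' @export
hre_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "hre_table1.csv", package = "hrebind",
                        mustWork = TRUE)
  }
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  needed <- c("hre", "sequence", "k_app_nM", "k_app_sd_nM", "k_tot_fM2",
              "k_tot_sd_fM2", "fold_activation", "fa_sem")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0) {
    stop("HRE table is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df$k_app    <- df$k_app_nM * 1e-9
  df$k_app_sd <- df$k_app_sd_nM * 1e-9
  df$k_tot    <- df$k_tot_fM2 * 1e-15
  df$k_tot_sd <- df$k_tot_sd_fM2 * 1e-15
  validate_hres(df)
  df
}

#' Validate an HRE record table
#'
#' Checks the invariants every HRE record must satisfy: positive dissociation
#' constants, positive fold-activation, and a non-empty sequence over
#' \{A, C, G, T\} (case-insensitive; lower case conventionally marks the
#' spacer between hexamer half-sites).
#'
#' @param hres data.frame as returned by [hre_table()].
#' @return the table, invisibly, if valid; otherwise an error.
#' @export
validate_hres <- function(hres) {
  stopifnot(is.data.frame(hres))
  if (any(hres$k_app <= 0) || any(hres$k_tot <= 0)) {
    stop("invalid HRE record: affinities must be positive", call. = FALSE)
  }
  if (any(hres$fold_activation <= 0)) {
    stop("invalid HRE record: fold-activation must be positive", call. = FALSE)
  }
  ok_seq <- nzchar(hres$sequence) &
    grepl("^[ACGTacgt]+$", hres$sequence)
  if (any(!ok_seq)) {
    stop("invalid HRE record: sequences must be non-empty over {A,C,G,T}",
         call. = FALSE)
  }
  if (anyDuplicated(hres$hre)) {
    stop("invalid HRE record: duplicate HRE names", call. = FALSE)
  }
  invisible(hres)
}
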