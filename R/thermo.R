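R_KCAL <- 1.987e-3  # gas constant, kcal/(mol K)

#' log10 computed relative potency from relative binding free energies
#'
#' The computed relative sweetness (a potency ratio proxy) of a compound
#' against a reference is `CRS = exp(-(ddF - ddF_ref)/RT)`, treating potency
#' as a direct readout of the dissociation constant. This function returns
#' `log10(CRS)`.
#'
#' The default temperature is 310 K (physiological); potency comparisons at
#' room temperature should pass `temperature_K = 298.15`.
#'
#' @param ddF Relative binding free energy of the compound, kcal/mol
#'   (vectorized).
#' @param ddF_ref Relative binding free energy of the reference compound.
#' @param temperature_K Absolute temperature, > 0.
#' @return `log10(CRS)` as a numeric vector.
#' @examples
#' log_crs(-11.7, -6.9)  # ~3.38
#' @export
log_crs <- function(ddF, ddF_ref, temperature_K = 310) {
  if (any(temperature_K <= 0)) stop("temperature must be positive", call. = FALSE)
  rt <- R_KCAL * temperature_K
  -(ddF - ddF_ref) / (rt * log(10))
}

#' Potency table with computed log10 relative potency and propagated error
#'
#' @param records Data frame with columns `name`, `ddF` (kcal/mol), `ddF_err`
#'   (standard deviation, kcal/mol) and optionally `log_rs` (log10 of the
#'   experimental relative potency).
#' @param reference Name of the reference compound (a row of `records`).
#' @param temperature_K Absolute temperature.
#' @return Tibble: input columns plus `log_crs` and `log_crs_err`
#'   (errors of compound and reference combined in quadrature; the reference
#'   row gets 0 for both).
#' @export
crs_table <- function(records, reference, temperature_K = 310) {
  stopifnot(all(c("name", "ddF", "ddF_err") %in% names(records)))
  i <- match(reference, records$name)
  if (is.na(i)) stop("reference compound '", reference, "' not in records", call. = FALSE)
  rt <- R_KCAL * temperature_K
  out <- tibble::as_tibble(records)
  out$log_crs <- log_crs(out$ddF, out$ddF[i], temperature_K)
  out$log_crs_err <- sqrt(out$ddF_err^2 + out$ddF_err[i]^2) / (rt * log(10))
  out$log_crs[i] <- 0
  out$log_crs_err[i] <- 0
  out
}

#' Fold change in potency implied by a binding free-energy change
#'
#' `exp(-ddF_change / RT)`: a modification that strengthens binding by
#' 2.4 kcal/mol (`ddF_change = -2.4`) at 298.15 K makes the compound about
#' 57 times more potent. Fold factors multiply when free-energy changes add.
#'
#' @param ddF_change Binding free-energy change of the modification, kcal/mol
#'   (negative = stronger binding).
#' @param temperature_K Absolute temperature, > 0 (default 298.15 K).
#' @return Fold improvement (numeric, vectorized).
#' @examples
#' fold_improvement(-2.4)  # ~57
#' fold_improvement(-3.8)  # ~600 to one significant figure
#' @export
fold_improvement <- function(ddF_change, temperature_K = 298.15) {
  if (any(temperature_K <= 0)) stop("temperature must be positive", call. = FALSE)
  exp(-ddF_change / (R_KCAL * temperature_K))
}

#' Reference free-energy table for the T1R2 sweetener case study
#'
#' Relative binding free energies (vs a chargeless ethane probe) and
#' experimental relative-sweetness values for sucrose, 4R-Cl-sucrose,
#' sucralose, dulcin and an isovanillyl sweetener, shipped as a CSV under
#' `extdata`.
#'
#' @return Tibble with columns `name`, `log_rs`, `ddF`, `ddF_err`.
#' @export
sweetener_table <- function() {
  path <- system.file("extdata", "sweetener_free_energies.csv",
                      package = "moietyrank", mustWork = TRUE)
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
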