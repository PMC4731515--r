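#' Marker presets for endosome populations
#'
#' Literature-derived default parameters for the five fluorescent endosomal
#' markers the analysis supports. Early endosomes (TGN-associated;
#' GFP-RabA1d, YFP-VTI12) are small, mostly continuously moving and render
#' as Gaussian spots; late endosomes (MVB; YFP-RabF2a, YFP-RabF2b,
#' GFP-2xFYVE) are larger, mostly discontinuous, render as ring-like
#' structures under SIM, and engage in dancing and clustering/fusion
#' interactions.
#'
#' Columns:
#' \describe{
#'   \item{name}{marker name.}
#'   \item{endosome_class}{"early" or "late".}
#'   \item{continuous_fraction}{fraction of the population moving
#'     continuously (straight constant-speed excursions).}
#'   \item{v_max, v_sd}{go-phase / continuous speed: population mean and
#'     between-particle SD, um/s (individual particles draw their speed
#'     from this distribution).}
#'   \item{apparent_diameter_mean, apparent_diameter_sd}{apparent
#'     (measured-FWHM) diameter distribution, nm.}
#'   \item{rendering}{"gaussian_spot" or "ring" (SIM modality).}
#'   \item{dancing_rate, fusion_rate}{pairwise event rates, events/s, used
#'     to derive default event counts in simulations.}
#'   \item{tip_enrichment}{multiplicative enrichment of initial particle
#'     density at the root-hair tip (1 = uniform).}
#' }
#'
#' @return A tibble with one row per marker.
#' @export
#' @examples
#' marker_presets()
marker_presets <- function() {
  tibble::tribble(
    ~name,     ~endosome_class, ~continuous_fraction, ~v_max, ~v_sd, ~apparent_diameter_mean, ~apparent_diameter_sd, ~rendering,      ~dancing_rate, ~fusion_rate, ~tip_enrichment,
    "RabA1d",  "early",         0.80,                 8.7,    1.1,   197,                     20.7,                  "gaussian_spot", 0,             0,            1.5,
    "VTI12",   "early",         0.50,                 6.5,    0.9,   197,                     20.7,                  "gaussian_spot", 0,             0,            1.5,
    "RabF2a",  "late",          0.40,                 5.6,    0.9,   339.7,                   79,                    "ring",          0.02,          0.01,         2.0,
    "RabF2b",  "late",          0.40,                 5.7,    1.1,   339.7,                   79,                    "ring",          0.02,          0.01,         2.0,
    "FYVE",    "late",          0.40,                 5.5,    1.2,   336.2,                   72,                    "ring",          0.02,          0.01,         2.0
  )
}

#' Look up a single marker preset
#'
#' @param name One of `"RabA1d"`, `"VTI12"`, `"RabF2a"`, `"RabF2b"`,
#'   `"FYVE"`.
#' @return A one-row tibble (see [marker_presets()]).
#' @export
get_preset <- function(name) {
  p <- marker_presets()
  row <- p[p$name == name, ]
  if (nrow(row) == 0) {
    rlang::abort(paste0("Unknown marker preset '", name, "'. Available: ",
                        paste(p$name, collapse = ", ")))
  }
  row
}
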