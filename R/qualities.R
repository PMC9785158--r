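#' Radiation qualities of the microbeam experiment
#'
#' Metadata for the four ion beams used to irradiate cell nuclei: particle
#' type, nominal beam energy, and the estimated energy and unrestricted
#' linear energy transfer (LET) at the centre of the cell nucleus.  LET is
#' consumed as metadata only (it labels the beams and orders them by
#' ionisation density); it enters no computation in this package.
#'
#' @return A tibble with one row per radiation quality and columns
#'   `quality` (label used throughout the package), `particle`,
#'   `beam_energy_MeV`, `energy_at_center_MeV`, `energy_at_center_sd`,
#'   `let_keV_um`, `let_sd`.
#' @export
#' @examples
#' radiation_qualities()
radiation_qualities <- function() {
  tibble::tibble(
    quality = c("protons_3MeV", "alpha_20MeV", "alpha_10MeV", "alpha_8MeV"),
    particle = c("proton", "alpha", "alpha", "alpha"),
    beam_energy_MeV = c(3, 20, 10, 8),
    energy_at_center_MeV = c(1.6, 17.8, 5.5, 1.9),
    energy_at_center_sd = c(0.2, 0.2, 0.4, 0.6),
    let_keV_um = c(19, 36, 85, 170),
    let_sd = c(2, 1, 4, 40)
  )
}
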