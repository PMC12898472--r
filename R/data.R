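#' Published TNBC risk-model gene panels
#'
#' Loads the bundled GMT of published gene panels: `SPSM` (the 10-gene
#' stress-response tumor cell / plasmacytoid-dendritic-cell prognostic
#' panel), `SPSM_IPSM_SHARED` (the 5 genes shared between the SPSM and IPSM
#' panels) and `IPSM_PARTIAL` (the published members of the 8-gene IPSM
#' panel; the full list was not released, so this set is incomplete).
#'
#' @return named list of character gene vectors.
#' @examples
#' sigs <- riskSignatures()
#' lengths(sigs)
#' @export
riskSignatures <- function() {
  readGeneSets(system.file("extdata", "tnbc_risk_signatures.gmt",
                           package = "tumorImmuneRisk", mustWork = TRUE))
}
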