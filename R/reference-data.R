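#' @include accessors.R
NULL

#' Published reference coupling-control ratios
#'
#' Group-mean linearized respiratory control ratios (L/P, leak over OXPHOS
#' capacity in the NADH-linked pathway, rox-corrected) for five reference
#' tissue and cell models assayed with the SUIT reference protocols: mouse
#' heart isolated mitochondria, human PBMCs, human platelets, mouse brain
#' homogenate and HEK 293T cells. L/P is the statistically usable
#' linearization of the respiratory control ratio P/L; the P-L control
#' efficiency follows as 1 - L/P.
#'
#' @return data.frame with columns \code{model}, \code{species},
#'   \code{preparation}, \code{n}, \code{L_over_P_mean}, \code{L_over_P_sd}.
#' @export
couplingControlReference <- function() {
  path <- system.file("extdata", "coupling_control_reference.csv",
                      package = "oxygraphR", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
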