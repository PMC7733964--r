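## Population parameter defaults and ground-truth presets.

#' Default population parameters for a phenotype
#'
#' Documented defaults for the 38 population parameters of the unified
#' model.  The two phenotypes share every parameter except the four that
#' differ across the epithelial-mesenchymal transition: the input magnitudes
#' I1 (ERK pathway, 5.3 vs 1.9) and I2 (AKT pathway, 8.1 vs 55), the
#' pGSK3B dephosphorylation kinetic order h5 (0.3 vs 0.05), and the
#' AKT-branch S6 activation rate k13 (10^-7.8 vs 10^-9.5).
#'
#' Shared values are chosen so that, with the default synthetic totals and
#' baseline fractions, all deactivation-rate closures land in the
#' 0.1-1 / min range and the stimulated responses double to triple the
#' baseline phospho levels over the 50-minute horizon.
#'
#' @param phenotype "epithelial" or "mesenchymal".
#' @return A \linkS4class{ParameterSet}.
#' @export
#' @examples
#' defaultParameters("epithelial")["I1"]
defaultParameters <- function(phenotype = c("epithelial", "mesenchymal")) {
  phenotype <- match.arg(phenotype)
  shared <- c(
    tau1 = 0.5, d1 = 0.10,
    tau2 = 0.5, d2 = 0.08,
    kR = 0.03, gR = 1.2, gc1 = 0.4, hR = 1.0, gammaR = 0.3, RT = 10,
    kP = 0.5, gP = 1.0, hP = 2.0, gammaP = 0.25,
    k1 = 0.075, g1 = 1.0, h1 = 1.0,
    k2 = 3e-4, g2 = 1.3, h2 = 1.0,
    k3 = 2e-3, g3 = 1.0, h3 = 1.0,
    k4 = 0.03, g4 = 1.0, h4 = 1.0,
    k5 = 1.5e-3, g5 = 1.0, k12 = 8e-3, g12 = 1.0,
    k6 = 5e-3, g6 = 1.0, g13 = 3.0, h6 = 1.0)
  pheno <- if (phenotype == "epithelial") {
    c(I1 = 5.3, I2 = 8.1, h5 = 0.3, k13 = 10^-7.8)
  } else {
    c(I1 = 1.9, I2 = 55, h5 = 0.05, k13 = 10^-9.5)
  }
  ParameterSet(c(shared, pheno))
}

#' The four parameters that differ across the transition
#'
#' @return Character vector of the differing parameter names.
#' @export
differingParameterNames <- function() c("I1", "I2", "h5", "k13")

#' Ground-truth parameter presets for the two phenotypes
#'
#' Returns the paired epithelial/mesenchymal parameter sets used as ground
#' truth by the synthetic-data generator.  The two sets agree on every
#' parameter except \code{I1}, \code{I2}, \code{h5} and \code{k13}.
#'
#' @return List with elements \code{theta_epithelial},
#'   \code{theta_mesenchymal} (both \linkS4class{ParameterSet}) and
#'   \code{differing_parameters}.
#' @export
#' @examples
#' gt <- groundTruthPresets()
#' gt$theta_epithelial["I1"]   # 5.3
#' gt$theta_mesenchymal["I1"]  # 1.9
groundTruthPresets <- function() {
  list(theta_epithelial = defaultParameters("epithelial"),
       theta_mesenchymal = defaultParameters("mesenchymal"),
       differing_parameters = differingParameterNames())
}

## ---- model specification ---------------------------------------------------

#' ModelSpec: fixed reaction structure of the unified model
#'
#' @slot species All model species (two unmeasured modifiers followed by the
#'   six measured phosphoproteins).
#' @slot parameters Canonical parameter names (the template slots).
#' @slot edges data.frame of directed activation edges, including the two
#'   crosstalk links (PI3K -> pRAF and pRSK -> pGSK3B).
#' @export
setClass("ModelSpec",
         representation(species = "character", parameters = "character",
                        edges = "data.frame"))

#' Build the unified reaction-network model
#'
#' Constructs the fixed structure of the power-law (canonical / generalized
#' mass action) model: an aggregated delayed, decaying input per pathway,
#' the unmeasured modifiers pRAF (finite capacity) and PI3K, the
#' RAF-MEK-ERK-RSK and PI3K-AKT-GSK3B chains converging on S6, and the two
#' crosstalk links (PI3K to RAF activation, RSK to GSK3B phosphorylation).
#'
#' @return A \linkS4class{ModelSpec} with exactly 38 named parameter slots.
#' @export
#' @examples
#' parameterCount(buildModel())  # 38
buildModel <- function() {
  edges <- data.frame(
    from = c("EGF1", "EGF2", "PI3K", "pRAF", "pMEK", "ppERK", "PI3K",
             "pAKT", "pRSK", "pRSK", "pAKT"),
    to = c("pRAF", "PI3K", "pRAF", "pMEK", "ppERK", "pRSK", "pAKT",
           "pGSK3B", "pGSK3B", "pS6", "pS6"),
    type = c("input", "input", "crosstalk", "cascade", "cascade", "cascade",
             "cascade", "cascade", "crosstalk", "cascade", "cascade"))
  new("ModelSpec",
      species = c("pRAF", "PI3K", measuredSpecies()),
      parameters = modelParameterNames(),
      edges = edges)
}

#' Number of population-level parameters of a model specification
#'
#' @param spec A \linkS4class{ModelSpec}.
#' @return Integer parameter count.
#' @export
parameterCount <- function(spec) length(spec@parameters)

setMethod("show", "ModelSpec", function(object) {
  cat("ModelSpec:", length(object@species), "species,",
      length(object@parameters), "population parameters,",
      nrow(object@edges), "directed edges\n")
})

## ---- search ranges ---------------------------------------------------------

#' Default parameter search ranges
#'
#' Log-uniform sampling ranges for the global search stage, set from
#' physical reasoning: input magnitudes span no stimulation (1) to strong
#' stimulation (100); delays a fraction of a minute to several minutes;
#' decay rates give transients lasting one minute to the full horizon;
#' activation rate constants span roughly two orders of magnitude either
#' side of rates that relax in minutes at the panel's intensity scales; and
#' kinetic orders cover the canonical near-zero-order to cooperative range.
#'
#' @return Named list of c(lower, upper) per parameter.
#' @export
defaultSearchRanges <- function() {
  r <- list(
    I1 = c(1, 100), tau1 = c(0.1, 5), d1 = c(0.01, 1),
    I2 = c(1, 100), tau2 = c(0.1, 5), d2 = c(0.01, 1),
    kR = c(1e-3, 1), gR = c(0.1, 3), gc1 = c(0.05, 2), hR = c(0.1, 3),
    gammaR = c(0.01, 3), RT = c(1, 100),
    kP = c(0.01, 10), gP = c(0.1, 3), hP = c(0.1, 3), gammaP = c(0.01, 3),
    k1 = c(1e-3, 1), g1 = c(0.1, 3), h1 = c(0.1, 3),
    k2 = c(1e-5, 0.1), g2 = c(0.1, 3), h2 = c(0.1, 3),
    k3 = c(1e-4, 1), g3 = c(0.1, 3), h3 = c(0.1, 3),
    k4 = c(1e-3, 1), g4 = c(0.1, 3), h4 = c(0.1, 3),
    k5 = c(1e-5, 0.1), g5 = c(0.1, 3),
    k12 = c(1e-4, 1), g12 = c(0.1, 3), h5 = c(0.01, 3),
    k6 = c(1e-4, 1), g6 = c(0.1, 3),
    k13 = c(1e-11, 1e-5), g13 = c(1, 4), h6 = c(0.1, 3))
  r[modelParameterNames()]
}
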