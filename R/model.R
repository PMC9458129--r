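#' The packaged calcium-TRAIL apoptosis model
#'
#' Loads the synthetic, calibrated mass-action network of calcium-modulated
#' TRAIL-mediated apoptosis that ships with the package
#' (`inst/extdata/ca_trail_synthetic/`). The mechanism is the extrinsic
#' apoptosis cascade of the EARM family: TRAIL binds death receptor to form a
#' DISC that activates caspase-8; caspase-8 truncates Bid; tBid activates Bax,
#' which is buffered stoichiometrically by Bcl-2 until free active Bax
#' dimerises into mitochondrial pores; pores release Smac and cytochrome c;
#' cytochrome c nucleates the apoptosome, which activates caspase-3; XIAP
#' sequesters caspase-3 and is antagonised by released Smac; caspase-3 cleaves
#' PARP. Cytosolic calcium (clamped, in uM) acts through a calcium-activated
#' protease (calpain) held in check stoichiometrically by its endogenous
#' inhibitor calpastatin; once free, calpain truncates Bid and degrades XIAP.
#' The inhibitor titration makes the calcium response sharply ultrasensitive:
#' saturated at and above 1 uM, negligible at resting (~0.1 uM) calcium.
#'
#' Rate constants and initial amounts are NOT transcribed from any published
#' table; they were calibrated once against the printed single-cell event
#' hours and population viabilities of the source study and then frozen (see
#' the methods vignette). The tabulated TRAIL amount corresponds to the
#' reference dose of 50 ng/mL.
#'
#' @return A validated `reaction_network`.
#' @examples
#' net <- ca_trail_model()
#' net$species
#' @export
ca_trail_model <- function() {
  dir <- system.file("extdata", "ca_trail_synthetic", package = "camapop",
                     mustWork = TRUE)
  read_network(file.path(dir, "species.csv"), file.path(dir, "reactions.csv"))
}
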