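#' Analyte feature names used throughout the simulator
#'
#' Liquid compositions and sensor affinities are expressed over six
#' dissolved-analyte features (ethanol enters separately through the
#' bulk refractive index): sugars, divalent cations, monovalent
#' cations, macromolecules (proteins / polysaccharides), organic acids
#' and aroma compounds (volatile congeners, botanicals).
#'
#' @return Character vector of the six feature names, in canonical order.
#' @export
analyte_features <- function() {
  c("sugars", "divalent_cations", "monovalent_cations",
    "macromolecules", "organic_acids", "aroma_compounds")
}

# Half-saturation constants per feature (g/L). Shared across chemistries;
# per-element selectivity lives in the affinity matrix.
.default_half_saturation <- c(
  sugars = 20, divalent_cations = 0.2, monovalent_cations = 0.5,
  macromolecules = 2, organic_acids = 3, aroma_compounds = 0.3
)

#' Default cross-reactive chemistry catalogue for the 24 sensor elements
#'
#' Each sensor element carries a distinct self-assembled monolayer that
#' gates which dissolved molecules enter the plasmonic sensing volume.
#' This catalogue is a synthetic stand-in for the measured surface
#' chemistries: the affinity matrix (maximum Langmuir saturation shift
#' per analyte feature, nm) is hand-set so that the qualitative
#' behaviour of the array holds — carboxylate elements (13-15) and the
#' cation receptor (22) respond strongly to divalent cations,
#' cyclodextrin cavitands (23, 24) to aroma compounds and sugars, and
#' macromolecule-binding elements develop slowly (base rate about
#' 1/180 s^-1, so beer-like responses stabilise after roughly 8 min).
#' No affinity value is a measurement.
#'
#' Each element's nominal resonance in water is drawn once per chip as
#' 709 nm + Gaussian noise with sd 4/sqrt(2) nm, honouring the stated
#' 709 +/- 4 nm spread across elements.
#'
#' @param seed integer seed fixing the per-element water resonances.
#' @return A data.frame of class `chemistry_profile` with one row per
#'   sensor (columns `sensor_id`, `label`, `kinetic_rate`,
#'   `resonance_water`, and `aff_<feature>` / `k_<feature>` pairs).
#' @export
default_chemistries <- function(seed = 1L) {
  labels <- c(
    "bare gold control",              # 1
    "mercaptohexanol (hydroxyl)",     # 2
    "hidden quaternary ammonium",     # 3  hydrophobic chain over fixed +
    "mercaptoethanesulfonate",        # 4
    "aminoethanethiol (amine)",       # 5
    "thiophenol (pi-aromatic)",       # 6
    "perfluorodecanethiol",           # 7
    "PEG-thiol (antifouling)",        # 8
    "mercaptophenylboronic acid",     # 9  diol/sugar binder
    "glutathione (zwitterion)",       # 10
    "thioglucose (glycoside)",        # 11
    "mercaptohexadecane (alkyl)",     # 12
    "mercaptopropionate (C3 carboxylate)",   # 13
    "mercaptooctanoate (C8 carboxylate)",    # 14
    "mercaptoundecanoate (C11 carboxylate)", # 15
    "long-chain neutral ester",       # 16
    "imidazole thiol",                # 17
    "pyridyl thiol",                  # 18
    "mixed amine/hydroxyl",           # 19
    "sulfobetaine zwitterion",        # 20
    "cholesterol-mimetic thiol",      # 21
    "aza-crown cation receptor",      # 22
    "alpha-cyclodextrin cavitand",    # 23
    "beta-cyclodextrin cavitand"      # 24
  )

  # Affinity matrix, nm at saturation, rows = sensors, cols = features
  # (sugars, divalent, monovalent, macromolecules, organic_acids, aroma).
  aff <- matrix(c(
    0.3, 0.4, 0.15, 1.2, 0.3, 0.4,   # 1  bare gold: sticky to most things
    0.4, 0.2, 0.10, 0.5, 0.3, 0.2,   # 2
    0.1, 0.1, 0.05, 0.8, 1.6, 1.0,   # 3  anion / hydrophobe capture
    0.1, 0.9, 0.40, 0.3, 0.1, 0.1,   # 4  sulfonate: cations
    0.2, 0.1, 0.05, 0.7, 1.2, 0.3,   # 5  amine: acids
    0.1, 0.1, 0.05, 0.6, 0.4, 1.1,   # 6  pi-stacking aromatics
    0.05, 0.05, 0.02, 0.3, 0.1, 0.9, # 7  fluorophilic/hydrophobic
    0.1, 0.05, 0.02, 0.1, 0.05, 0.1, # 8  antifouling: near-inert
    1.5, 0.2, 0.10, 0.4, 0.5, 0.2,   # 9  boronate: sugars
    0.3, 0.8, 0.30, 0.9, 0.6, 0.2,   # 10
    0.9, 0.3, 0.10, 0.5, 0.2, 0.3,   # 11 sugar-sugar interactions
    0.05, 0.05, 0.02, 0.8, 0.2, 1.2, # 12 alkyl: hydrophobes, proteins
    0.1, 1.8, 0.30, 0.4, 0.3, 0.1,   # 13 carboxylate: divalent cations
    0.1, 1.5, 0.25, 0.6, 0.3, 0.3,   # 14
    0.1, 1.2, 0.20, 0.9, 0.3, 0.5,   # 15
    0.2, 0.1, 0.05, 1.3, 0.4, 1.4,   # 16 ester: macromolecules, aroma
    0.2, 0.7, 0.20, 0.5, 0.9, 0.3,   # 17
    0.2, 0.5, 0.15, 0.5, 0.7, 0.6,   # 18
    0.3, 0.3, 0.10, 0.6, 0.8, 0.2,   # 19
    0.1, 0.3, 0.15, 0.2, 0.2, 0.1,   # 20 zwitterion: weakly fouling
    0.1, 0.05, 0.02, 1.0, 0.2, 1.3,  # 21 sterol pocket: hydrophobes
    0.1, 2.2, 0.60, 0.3, 0.4, 0.2,   # 22 crown: strong cation receptor
    0.8, 0.4, 0.10, 0.7, 0.3, 1.8,   # 23 alpha-CD cavitand
    1.0, 0.5, 0.10, 0.8, 0.3, 2.2    # 24 beta-CD cavitand
  ), nrow = 24, byrow = TRUE,
  dimnames = list(NULL, analyte_features()))

  # Fast intrinsic rates for small-molecule adsorption; macromolecule
  # binding is slow and handled by slow_rate in effective_rate().
  base_rate <- rep(0.08, 24)

  res_water <- withr::with_seed(as.integer(seed), {
    709 + stats::rnorm(24, 0, 4 / sqrt(2))
  })

  out <- data.frame(
    sensor_id = 1:24,
    label = labels,
    kinetic_rate = base_rate,
    resonance_water = res_water,
    stringsAsFactors = FALSE
  )
  for (f in analyte_features()) {
    out[[paste0("aff_", f)]] <- aff[, f]
    out[[paste0("k_", f)]] <- .default_half_saturation[[f]]
  }
  stopifnot(all(is.finite(aff)), all(.default_half_saturation > 0),
            all(base_rate > 0))
  class(out) <- c("chemistry_profile", "data.frame")
  out
}

#' Extract the affinity and half-saturation matrices from a chemistry table
#'
#' @param chem a `chemistry_profile` data.frame.
#' @return List with numeric matrices `affinity` and `half_saturation`
#'   (24 x 6, columns in `analyte_features()` order).
#' @export
chemistry_matrices <- function(chem) {
  feats <- analyte_features()
  aff <- as.matrix(chem[paste0("aff_", feats)])
  ks <- as.matrix(chem[paste0("k_", feats)])
  colnames(aff) <- colnames(ks) <- feats
  list(affinity = aff, half_saturation = ks)
}

#' Instrument response model
#'
#' Collects the optical and noise parameters of the simulated
#' instrument: the bulk refractive-index sensitivity of the plasmonic
#' resonance, the Lorentzian dip shape rendered into frames, and the
#' instrument noise. Defaults are simulator choices at physically
#' typical magnitudes, not measured values: 250 nm/RIU bulk
#' sensitivity, 80 nm dip FWHM, 0.5 fractional dip depth, 0.5 %
#' multiplicative intensity noise.
#'
#' `lambda_noise_sd` is the wavelength-domain equivalent of the
#' intensity noise after spline extraction (used by the fast
#' signal-level simulator); its default (0.04 nm) was measured once by
#' pushing the default 0.5 % intensity noise through the full
#' render-section-normalise-spline pipeline (observed sd 0.037 nm).
#' Baseline drift and carryover default to zero and are opt-in.
#'
#' @param bulk_sensitivity nm per refractive-index unit (> 0).
#' @param dip_depth fractional transmission loss at resonance, in (0,1).
#' @param dip_fwhm full width at half maximum of the dip, nm (> 0).
#' @param intensity_noise_sd relative sd of multiplicative intensity noise.
#' @param lambda_noise_sd sd (nm) of extracted-minimum noise in
#'   signal-level simulation.
#' @param baseline_drift_rate resonance drift, nm per hour.
#' @param carryover_fraction fraction of a sample's equilibrium shift
#'   that persists after rinsing, in [0, 1).
#' @return An object of class `response_model` (a list).
#' @export
response_model <- function(bulk_sensitivity = 250, dip_depth = 0.5,
                           dip_fwhm = 80, intensity_noise_sd = 0.005,
                           lambda_noise_sd = 0.04,
                           baseline_drift_rate = 0,
                           carryover_fraction = 0) {
  stopifnot(bulk_sensitivity > 0, dip_fwhm > 0,
            dip_depth > 0, dip_depth < 1,
            intensity_noise_sd >= 0, lambda_noise_sd >= 0,
            carryover_fraction >= 0, carryover_fraction < 1)
  structure(
    list(bulk_sensitivity = bulk_sensitivity, dip_depth = dip_depth,
         dip_fwhm = dip_fwhm, intensity_noise_sd = intensity_noise_sd,
         lambda_noise_sd = lambda_noise_sd,
         baseline_drift_rate = baseline_drift_rate,
         carryover_fraction = carryover_fraction),
    class = "response_model"
  )
}
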