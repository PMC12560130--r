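#' Refractive index of pure water at 25 degrees C (sodium D line)
#' @export
RI_WATER_25C <- 1.33250

# Refractive index of ethanol-water mixtures at 25 C versus ethanol
# volume fraction (%). Values are a smooth digitisation of standard
# 25 C mixture data (sodium D line); the curve is non-monotone, peaking
# near 90 % v/v before relaxing to the pure-ethanol value.
.ethanol_ri_table <- data.frame(
  abv = seq(0, 100, by = 10),
  ri  = c(1.33250, 1.33620, 1.34040, 1.34500, 1.34920,
          1.35300, 1.35600, 1.35830, 1.35960, 1.36000, 1.35940)
)

# RI increment per g/L of dissolved solid, by analyte feature.
# Magnitudes follow typical dn/dc values: sucrose ~1.4e-4, salts
# ~1.8e-4, proteins ~1.9e-4 RIU per g/L.
.solid_ri_increment <- c(
  sugars = 1.44e-4, divalent_cations = 1.9e-4,
  monovalent_cations = 1.7e-4, macromolecules = 1.9e-4,
  organic_acids = 1.3e-4, aroma_compounds = 1.2e-4
)

#' Construct an analyte composition
#'
#' @param abv ethanol content, percent by volume, in [0, 100].
#' @param sugars,divalent_cations,monovalent_cations,macromolecules,organic_acids,aroma_compounds
#'   nonnegative concentrations (g/L).
#' @return Named numeric vector of class `analyte_composition` with
#'   elements `abv` plus the six features of [analyte_features()].
#' @export
analyte_composition <- function(abv = 0, sugars = 0, divalent_cations = 0,
                                monovalent_cations = 0, macromolecules = 0,
                                organic_acids = 0, aroma_compounds = 0) {
  x <- c(abv = abv, sugars = sugars, divalent_cations = divalent_cations,
         monovalent_cations = monovalent_cations,
         macromolecules = macromolecules, organic_acids = organic_acids,
         aroma_compounds = aroma_compounds)
  if (abv < 0 || abv > 100) stop("abv must lie in [0, 100]")
  if (any(x < 0)) stop("concentrations must be nonnegative")
  structure(x, class = "analyte_composition")
}

#' Bulk refractive index of a liquid from its composition
#'
#' The ethanol contribution is interpolated (monotone cubic) from an
#' embedded 25 C ethanol-water refractive-index table; each dissolved
#' solid then adds a documented linear increment per g/L. The result is
#' monotone nondecreasing in every dissolved-solid feature.
#'
#' @param composition an [analyte_composition()].
#' @return Refractive index (dimensionless), at least that of pure water.
#' @examples
#' composition_to_ri(analyte_composition())          # pure water, 1.3325
#' composition_to_ri(analyte_composition(abv = 40))  # a 40 % v/v spirit
#' @export
composition_to_ri <- function(composition) {
  x <- unclass(composition)
  abv <- x[["abv"]]
  if (is.na(abv) || abv < 0 || abv > 100) stop("abv must lie in [0, 100]")
  ri <- stats::splinefun(.ethanol_ri_table$abv, .ethanol_ri_table$ri,
                         method = "monoH.FC")(abv)
  feats <- analyte_features()
  ri <- ri + sum(.solid_ri_increment[feats] * x[feats])
  unname(ri)
}

#' Construct a liquid sample
#'
#' @param sample_id identifier string.
#' @param class_label one of `mineral_water`, `beer`, `white_wine`,
#'   `whiskey`, `vodka`, `gin`, `di_water`, `custom`.
#' @param composition an [analyte_composition()].
#' @return A `liquid_sample` list with the derived `refractive_index`.
#' @export
liquid_sample <- function(sample_id, class_label, composition) {
  classes <- c("mineral_water", "beer", "white_wine", "whiskey",
               "vodka", "gin", "di_water", "custom")
  class_label <- match.arg(class_label, classes)
  if (class_label == "di_water" && any(unclass(composition) != 0))
    stop("di_water must have an all-zero composition")
  ri <- composition_to_ri(composition)
  stopifnot(ri >= RI_WATER_25C - 1e-12)
  structure(
    list(sample_id = sample_id, class_label = class_label,
         composition = composition, refractive_index = ri),
    class = "liquid_sample"
  )
}

#' @export
print.liquid_sample <- function(x, ...) {
  cat(sprintf("<liquid_sample> %s [%s]  RI = %.5f  ABV = %.1f%%\n",
              x$sample_id, x$class_label, x$refractive_index,
              x$composition[["abv"]]))
  invisible(x)
}

# Class-conditional composition distributions: lognormal with the
# medians below (meanlog = log(median)). A zero median means the
# feature is absent for that class. Values are simulator choices at
# realistic beverage magnitudes (g/L; abv in % v/v).
.class_composition_spec <- list(
  mineral_water = list(
    median = c(abv = 0, sugars = 0, divalent_cations = 0.08,
               monovalent_cations = 0.03, macromolecules = 0,
               organic_acids = 0.005, aroma_compounds = 0),
    sdlog = c(abv = 0, sugars = 0, divalent_cations = 0.8,
              monovalent_cations = 0.8, macromolecules = 0,
              organic_acids = 0.5, aroma_compounds = 0)),
  beer = list(
    median = c(abv = 5, sugars = 25, divalent_cations = 0.05,
               monovalent_cations = 0.05, macromolecules = 3,
               organic_acids = 1.5, aroma_compounds = 0.05),
    sdlog = c(abv = 0.15, sugars = 0.4, divalent_cations = 0.4,
              monovalent_cations = 0.4, macromolecules = 0.3,
              organic_acids = 0.3, aroma_compounds = 0.5)),
  white_wine = list(
    median = c(abv = 12, sugars = 5, divalent_cations = 0.08,
               monovalent_cations = 0.02, macromolecules = 0.3,
               organic_acids = 6, aroma_compounds = 0.1),
    sdlog = c(abv = 0.08, sugars = 0.9, divalent_cations = 0.4,
              monovalent_cations = 0.4, macromolecules = 0.4,
              organic_acids = 0.2, aroma_compounds = 0.4)),
  whiskey = list(
    median = c(abv = 43, sugars = 2, divalent_cations = 0.002,
               monovalent_cations = 0.002, macromolecules = 0.02,
               organic_acids = 1.5, aroma_compounds = 0.15),
    sdlog = c(abv = 0.05, sugars = 0.5, divalent_cations = 0.5,
              monovalent_cations = 0.5, macromolecules = 0.5,
              organic_acids = 0.4, aroma_compounds = 0.4)),
  vodka = list(
    median = c(abv = 40, sugars = 0.05, divalent_cations = 0.001,
               monovalent_cations = 0.001, macromolecules = 0,
               organic_acids = 0.01, aroma_compounds = 0.005),
    sdlog = c(abv = 0.02, sugars = 0.6, divalent_cations = 0.5,
              monovalent_cations = 0.5, macromolecules = 0,
              organic_acids = 0.5, aroma_compounds = 0.6)),
  gin = list(
    median = c(abv = 41, sugars = 0.2, divalent_cations = 0.002,
               monovalent_cations = 0.002, macromolecules = 0,
               organic_acids = 0.05, aroma_compounds = 0.6),
    sdlog = c(abv = 0.06, sugars = 0.6, divalent_cations = 0.5,
              monovalent_cations = 0.5, macromolecules = 0,
              organic_acids = 0.5, aroma_compounds = 0.4))
)

# number of commercial examples per class, fixed by the study design
.class_counts <- c(mineral_water = 6L, beer = 6L, white_wine = 8L,
                   whiskey = 5L, vodka = 4L, gin = 6L)

#' Default catalogue of liquid samples
#'
#' Draws the study roster — 35 commercial beverages over six classes
#' (mineral water 6, beer 6, white wine 8, whiskey 5, vodka 4, gin 6)
#' — plus one deionised-water standard. Compositions are drawn from
#' class-conditional lognormal distributions with documented medians;
#' the same seed always yields the identical catalogue.
#'
#' @param seed integer seed.
#' @return List of 36 `liquid_sample` objects: 35 beverages then the
#'   `DI` standard.
#' @examples
#' cat35 <- default_catalog(seed = 42)
#' table(vapply(cat35, function(s) s$class_label, ""))
#' @export
default_catalog <- function(seed = 42L) {
  withr::with_seed(as.integer(seed), {
    samples <- list()
    for (cls in names(.class_counts)) {
      spec <- .class_composition_spec[[cls]]
      for (i in seq_len(.class_counts[[cls]])) {
        vals <- vapply(names(spec$median), function(f) {
          m <- spec$median[[f]]
          if (m <= 0) return(0)
          stats::rlnorm(1, meanlog = log(m), sdlog = spec$sdlog[[f]])
        }, numeric(1))
        vals["abv"] <- min(vals[["abv"]], 100)
        comp <- do.call(analyte_composition, as.list(vals))
        sid <- sprintf("%s_%d", cls, i)
        samples[[sid]] <- liquid_sample(sid, cls, comp)
      }
    }
    samples[["DI"]] <- liquid_sample("DI", "di_water", analyte_composition())
    samples
  })
}

#' Export a sample catalogue as a data.frame / CSV
#'
#' @param catalog list of `liquid_sample` objects.
#' @param file optional path; when given the table is also written as CSV.
#' @return data.frame with one row per sample (id, class, RI, composition).
#' @export
catalog_table <- function(catalog, file = NULL) {
  rows <- lapply(catalog, function(s) {
    data.frame(sample_id = s$sample_id, class_label = s$class_label,
               refractive_index = s$refractive_index,
               as.list(unclass(s$composition)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  if (!is.null(file)) utils::write.csv(out, file, row.names = FALSE)
  out
}
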