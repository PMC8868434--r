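# Seeded simulators for compositional FA profiles and sigmoidal
# dose-response plates, plus the packaged diatom reference dataset.

# The 24 species of the packaged diatom dataset: ten saturates, seven
# monounsaturates (one trans isomer), seven polyunsaturates with both
# omega-3 (EPA, DHA) and omega-6 members. This is the default species list
# for simulate_fa_profile().
default_species <- function() {
  c("C6:0", "C10:0", "C12:0", "C14:0", "C15:0", "C16:0", "C17:0", "C18:0",
    "C22:0", "C24:0",
    "C14:1", "C16:1", "C17:1", "C18:1n9t", "C18:1n9c", "C22:1n9", "C24:1n9",
    "C18:3n6", "C18:2n6c", "C20:4n6", "C20:5n3", "C20:3n6", "C20:2n6",
    "C22:6n3")
}

#' Simulate a compositional fatty-acid profile
#'
#' Draws a random composition over a species list from a Dirichlet
#' distribution (independent gamma draws normalised to 100%), then zeroes
#' each species independently with probability `nd_probability` to emulate
#' not-detected calls. Percentages sum to exactly 100 before the N.D. step.
#' Fully reproducible under a fixed seed; a seed is mandatory — there is no
#' global-random-state mode.
#'
#' @param species character vector of shorthand codes (default: the 24
#'   species of the packaged diatom dataset).
#' @param concentration positive Dirichlet weights, recycled to the species
#'   length; the default weight 1 gives a flat composition prior.
#' @param nd_probability probability in \[0, 1\] that a species is zeroed
#'   (default 0.15, the not-detected rate of the packaged dataset).
#' @param seed integer seed (mandatory).
#' @param sample_id label for the simulated sample.
#' @return An [fa_profile()]. Profiles that lose mass to N.D. zeroing may
#'   total below 95% and then carry the usual low-total warning.
#' @export
simulate_fa_profile <- function(species = default_species(),
                                concentration = 1,
                                nd_probability = 0.15,
                                seed,
                                sample_id = "sim") {
  if (length(species) == 0L) stop_assay("species list is empty")
  if (missing(seed)) stop("a seed is required for simulation", call. = FALSE)
  alpha <- rep_len(as.numeric(concentration), length(species))
  if (any(!is.finite(alpha)) || any(alpha <= 0)) {
    stop_assay("concentration weights must be positive")
  }
  if (!is.finite(nd_probability) || nd_probability < 0 || nd_probability > 1) {
    stop_assay("nd_probability must lie in [0, 1]")
  }
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  g <- stats::rgamma(length(species), shape = alpha, rate = 1)
  pct <- 100 * g / sum(g)
  nd <- stats::runif(length(species)) < nd_probability
  pct[nd] <- NA_real_   # fa_profile() records these as N.D. (0 with flag)
  suppressWarnings(
    fa_profile(codes = species, percentages = pct, sample_id = sample_id))
}

#' Simulate a four-parameter logistic dose-response series
#'
#' Generates `activity(x) = bottom + (top - bottom) / (1 + (ic50/x)^hill)`
#' at the given doses, plus optional additive Gaussian noise in percentage
#' points. The ground-truth IC50 makes the output suitable for
#' parameter-recovery testing of [estimate_ic50()].
#'
#' @param doses strictly increasing positive concentrations.
#' @param ic50 true midpoint concentration (> 0).
#' @param hill Hill slope (> 0; the curve increases with dose; pass
#'   decreasing activities through 100 - activity if an inverted series is
#'   wanted).
#' @param bottom,top asymptotes in percent, `bottom < top` (defaults 0 and
#'   100, a full-range assay).
#' @param noise_sd standard deviation of additive Gaussian noise, percentage
#'   points (default 0).
#' @param seed integer seed (mandatory when `noise_sd > 0`).
#' @param unit concentration unit tag.
#' @return A [dose_response()].
#' @export
simulate_dose_response <- function(doses, ic50, hill = 1, bottom = 0,
                                   top = 100, noise_sd = 0, seed = NULL,
                                   unit = "mg/mL") {
  if (any(doses <= 0)) stop_assay("doses must be positive")
  if (ic50 <= 0) stop_assay("ic50 must be positive")
  if (hill <= 0) stop_assay("hill slope must be positive")
  if (bottom >= top) stop_assay("bottom must be below top")
  act <- bottom + (top - bottom) / (1 + (ic50 / doses)^hill)
  if (noise_sd > 0) {
    if (is.null(seed)) stop("a seed is required when noise_sd > 0", call. = FALSE)
    old <- get_rng_state()
    on.exit(restore_rng_state(old))
    set.seed(as.integer(seed))
    act <- act + stats::rnorm(length(doses), sd = noise_sd)
  }
  dose_response(doses, act, unit = unit)
}

#' Packaged reference FA profiles of two freshwater diatoms
#'
#' Returns the bundled GC-MS FAME compositions of the benthic diatom
#' isolates *Anomoeoneis* sp. AARL D039 ("Ano") and *Rhopalodia* sp.
#' AARL D020 ("Rho"): 24 fatty-acid species each (percent of total FA,
#' triplicate SDs as metadata, N.D. entries zero-flagged) plus total lipid
#' content in percent of dry weight. These two profiles are the canonical
#' worked example for the index pipeline.
#'
#' @return named list of two [fa_profile()] objects, `Ano` and `Rho`.
#' @examples
#' ref <- diatom_reference_profiles()
#' nutritional_indices(ref$Ano)
#' @export
diatom_reference_profiles <- function() {
  path <- system.file("extdata", "diatom_fa_profiles.csv", package = "lipidqi",
                      mustWork = TRUE)
  list(Ano = read_profile_csv(path, sample_id = "Ano"),
       Rho = read_profile_csv(path, sample_id = "Rho"))
}

# save/restore .Random.seed so simulators never disturb the caller's RNG
get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng_state <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
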