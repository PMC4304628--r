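#' Synthetic registry-style incidence table
#'
#' Generates SEER-like age-binned incidence from the multistage onset
#' model itself: bin rates are the bin-averaged model hazard per 100,000
#' person-years, optionally with Poisson count noise at a stated
#' exposure. Because the generator is the model, fitting the table back
#' is a parameter-recovery exercise with known truth.
#'
#' @param params generating `onset_parameters`.
#' @param age_breaks bin edges (years), e.g. `seq(40, 85, by = 5)`.
#' @param person_years exposure per bin (scalar or vector); required for
#'   Poisson noise.
#' @param noise `"none"` or `"poisson"`.
#' @param seed seed for the noise draw.
#' @return an `incidence_table` (with `person_years` filled).
#' @export
synthetic_incidence <- function(params, age_breaks = seq(40, 85, by = 5),
                                person_years = 1e7,
                                noise = c("none", "poisson"), seed = 1L) {
  noise <- match.arg(noise)
  stopifnot(length(age_breaks) >= 2)
  tbl <- incidence_table(utils::head(age_breaks, -1), age_breaks[-1],
                         rate_per_100k = 0,
                         person_years = rep_len(person_years,
                                                length(age_breaks) - 1L))
  rates <- model_bin_rates(params, tbl)
  if (noise == "poisson") {
    stopifnot(all(tbl$person_years > 0))
    counts <- local_seed(seed,
                         stats::rpois(length(rates),
                                      rates / 1e5 * tbl$person_years))
    rates <- counts / tbl$person_years * 1e5
  }
  tbl$rate_per_100k <- rates
  tbl
}

#' Planted-signal labeled ensemble
#'
#' Test double for the trial-outcome ensemble: `n_features` log10
#' features drawn uniform on \[-6, 6\] (mirroring rate-constant bounds of
#' 1e-6 to 1e6), with a binary label that depends only on a small set of
#' informative features — positive when every informative feature falls
#' below its empirical quantile threshold, the quantile chosen so the
#' positive fraction hits `positive_fraction`. Used to verify that the
#' classification/influence machinery recovers known drivers.
#'
#' @param n records.
#' @param n_features total features (named `f1`..`fn` by default).
#' @param informative indices of informative features.
#' @param positive_fraction target share of positive labels.
#' @param noise_rate probability of flipping each label (0 = separable).
#' @param seed seed.
#' @param feature_names optional feature names.
#' @return tibble with feature columns and a logical `beneficial` label;
#'   attribute `informative` holds the planted feature names.
#' @export
planted_ensemble <- function(n = 500L, n_features = 18L,
                             informative = 1:4, positive_fraction = 0.05,
                             noise_rate = 0, seed = 1L,
                             feature_names = paste0("f", seq_len(n_features))) {
  stopifnot(all(informative >= 1), all(informative <= n_features),
            positive_fraction > 0, positive_fraction < 1)
  if (positive_fraction * n < 1)
    stop("positive-fraction target infeasible at this n", call. = FALSE)
  local_seed(seed, {
    X <- matrix(stats::runif(n * n_features, -6, 6), nrow = n,
                dimnames = list(NULL, feature_names))
    if (length(informative) == 0) {
      lab <- stats::runif(n) < positive_fraction
    } else {
      ## positive iff every informative feature is below a common
      ## empirical-quantile cutoff, the cutoff set so the positive count
      ## lands on the target
      U <- vapply(informative, function(j) rank(X[, j]) / n, numeric(n))
      s <- apply(U, 1, max)
      lab <- s <= stats::quantile(s, positive_fraction, type = 1)
    }
    if (noise_rate > 0)
      lab <- xor(lab, stats::runif(n) < noise_rate)
    out <- tibble::as_tibble(as.data.frame(X))
    out$beneficial <- lab
    attr(out, "informative") <- feature_names[informative]
    out
  })
}

#' Write small SBML fixtures
#'
#' Minimal valid (and deliberately invalid) SBML files for exercising the
#' importer: `"mass_action"` (one first-order reaction A -> B),
#' `"michaelis_menten"` (saturating conversion), `"no_reactions"` (valid
#' XML, empty reaction list), and `"unsupported_law"` (a kinetic law
#' outside the supported subset).
#'
#' @param path output file.
#' @param variant which fixture to write.
#' @return `path`, invisibly.
#' @export
toy_sbml <- function(path, variant = c("mass_action", "michaelis_menten",
                                       "no_reactions", "unsupported_law")) {
  variant <- match.arg(variant)
  head <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">',
    '<model id="toy">',
    '<listOfCompartments><compartment id="c" size="1"/></listOfCompartments>',
    '<listOfSpecies>',
    '<species id="A" compartment="c" initialConcentration="2"/>',
    '<species id="B" compartment="c" initialConcentration="0"/>',
    '</listOfSpecies>',
    '<listOfParameters><parameter id="k0" value="0.5"/>',
    '<parameter id="k1" value="1.5"/></listOfParameters>')
  rx <- switch(variant,
    no_reactions = character(),
    mass_action = c(
      '<listOfReactions><reaction id="J1" reversible="false">',
      '<listOfReactants><speciesReference species="A"/></listOfReactants>',
      '<listOfProducts><speciesReference species="B"/></listOfProducts>',
      '<kineticLaw><math xmlns="http://www.w3.org/1998/Math/MathML">',
      '<apply><times/><ci>k0</ci><ci>A</ci></apply>',
      '</math></kineticLaw></reaction></listOfReactions>'),
    michaelis_menten = c(
      '<listOfReactions><reaction id="J1" reversible="false">',
      '<listOfReactants><speciesReference species="A"/></listOfReactants>',
      '<listOfProducts><speciesReference species="B"/></listOfProducts>',
      '<kineticLaw><math xmlns="http://www.w3.org/1998/Math/MathML">',
      '<apply><divide/><apply><times/><ci>k0</ci><ci>A</ci></apply>',
      '<apply><plus/><ci>k1</ci><ci>A</ci></apply></apply>',
      '</math></kineticLaw></reaction></listOfReactions>'),
    unsupported_law = c(
      '<listOfReactions><reaction id="J1" reversible="false">',
      '<listOfReactants><speciesReference species="A"/></listOfReactants>',
      '<listOfProducts><speciesReference species="B"/></listOfProducts>',
      '<kineticLaw><math xmlns="http://www.w3.org/1998/Math/MathML">',
      '<apply><power/><ci>A</ci><cn>2</cn></apply>',
      '</math></kineticLaw></reaction></listOfReactions>'))
  writeLines(c(head, rx, '</model>', '</sbml>'), path)
  invisible(path)
}
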