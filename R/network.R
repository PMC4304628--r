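#' Reaction networks for selenium metabolism modelling
#'
#' A `reaction_network` couples a species table to a list of reactions with
#' one of three rate-law kinds:
#'
#' * `mass_action`: rate = k0 * prod(reactant^stoich) * prod(modifier);
#'   a reaction with no reactants and no modifiers is a constant source.
#' * `saturating`: one species enters through a Michaelis–Menten factor
#'   k0 * S / (k1 + S); every other reactant/modifier enters linearly.
#' * `amplified`: composite damage law
#'   (k0 * L + k2 * L * A / (k1 + A)) * prod(reactant^stoich), where L is a
#'   linear driver (peroxide) and A an amplifying species (selenide).
#'
#' Concentrations are in mM, time in years; the genomic pool is a
#' dimensionless fraction so DNA + dmDNA is conserved at 1.
#'
#' @param species tibble with columns `name`, `initial_concentration`,
#'   `clamped` (logical: held fixed during integration, e.g. extracellular
#'   selenium).
#' @param reactions list of reactions built with [reaction()].
#' @param parameter_names ordered character vector of all rate-constant
#'   names; each must be used by exactly one reaction.
#' @param dose_species name of the clamped species representing the
#'   extracellular selenium level, or `NA` if none.
#' @param damage_species name of the damaged-DNA pool, or `NA`.
#' @return an object of class `reaction_network`.
#' @export
reaction_network <- function(species, reactions, parameter_names,
                             dose_species = NA_character_,
                             damage_species = NA_character_,
                             topology = NA_character_) {
  species <- tibble::as_tibble(species)
  stopifnot(all(c("name", "initial_concentration", "clamped") %in%
                  names(species)))
  if (anyDuplicated(species$name) > 0)
    stop("species names must be unique", call. = FALSE)
  if (any(species$initial_concentration < 0))
    stop("initial concentrations must be non-negative", call. = FALSE)
  net <- structure(
    list(species = species, reactions = reactions,
         parameter_names = parameter_names,
         dose_species = dose_species, damage_species = damage_species,
         topology = topology),
    class = "reaction_network")
  validate_network(net)
  net
}

#' Define one reaction
#'
#' @param id reaction identifier (e.g. `"R3"`).
#' @param reactants,products named integer vectors: species -> stoichiometric
#'   count. Empty (`NULL`) for source/sink ends.
#' @param modifiers character vector of species appearing in the rate law
#'   without being consumed.
#' @param rate_law one of `"mass_action"`, `"saturating"`, `"amplified"`.
#' @param constants character vector of rate-constant names, in role order:
#'   mass_action `k0`; saturating `(k0, k1)`; amplified `(k0, k1, k2)`.
#' @param sat species the saturating factor acts on (saturating law), or the
#'   amplifying species (amplified law).
#' @param lin linear driver species (amplified law only).
#' @export
reaction <- function(id, reactants = NULL, products = NULL,
                     modifiers = character(), rate_law = "mass_action",
                     constants, sat = NA_character_, lin = NA_character_) {
  rate_law <- match.arg(rate_law, c("mass_action", "saturating", "amplified"))
  n_expected <- c(mass_action = 1L, saturating = 2L, amplified = 3L)[[rate_law]]
  if (length(constants) != n_expected)
    stop(sprintf("reaction %s: rate law '%s' takes %d constants, got %d",
                 id, rate_law, n_expected, length(constants)), call. = FALSE)
  to_stoich <- function(x) {
    if (is.null(x)) return(integer())
    storage.mode(x) <- "integer"
    if (any(x < 0)) stop("stoichiometric coefficients must be >= 0",
                         call. = FALSE)
    x
  }
  structure(list(id = id, reactants = to_stoich(reactants),
                 products = to_stoich(products), modifiers = modifiers,
                 rate_law = rate_law, constants = constants,
                 sat = sat, lin = lin),
            class = "reaction")
}

validate_network <- function(net) {
  sp <- net$species$name
  all_constants <- character()
  for (rx in net$reactions) {
    refd <- c(names(rx$reactants), names(rx$products), rx$modifiers,
              stats::na.omit(c(rx$sat, rx$lin)))
    missing <- setdiff(refd, sp)
    if (length(missing) > 0)
      stop(sprintf("reaction %s references unknown species: %s",
                   rx$id, paste(missing, collapse = ", ")), call. = FALSE)
    all_constants <- c(all_constants, rx$constants)
  }
  if (anyDuplicated(all_constants) > 0)
    stop("a rate constant is shared between reactions", call. = FALSE)
  if (!setequal(all_constants, net$parameter_names) ||
      length(all_constants) != length(net$parameter_names))
    stop("parameter_names must list each reaction constant exactly once",
         call. = FALSE)
  invisible(net)
}

#' @export
print.reaction_network <- function(x, ...) {
  cat(sprintf("<reaction_network: %d species, %d reactions, %d parameters>\n",
              nrow(x$species), length(x$reactions),
              length(x$parameter_names)))
  invisible(x)
}

#' Net stoichiometry matrix (species x reactions)
#'
#' @param net a `reaction_network`.
#' @return numeric matrix of products-minus-reactants counts.
#' @export
stoichiometry_matrix <- function(net) {
  sp <- net$species$name
  S <- matrix(0, nrow = length(sp), ncol = length(net$reactions),
              dimnames = list(sp, vapply(net$reactions, `[[`, "", "id")))
  for (j in seq_along(net$reactions)) {
    rx <- net$reactions[[j]]
    if (length(rx$reactants))
      S[names(rx$reactants), j] <- S[names(rx$reactants), j] - rx$reactants
    if (length(rx$products))
      S[names(rx$products), j] <- S[names(rx$products), j] + rx$products
  }
  S
}

## Michaelis-Menten occupancy c/(km + c); the empty-pool limit c = km = 0
## is 0 (no substrate, no flux), not NaN.
mm_frac <- function(c, km) if (c <= 0) 0 else c / (km + c)

## Evaluate all reaction rates at a named concentration vector.
reaction_rates <- function(net, conc, params) {
  vapply(net$reactions, function(rx) {
    k <- params[rx$constants]
    ## linear factors; the saturating/amplifying species enter only through
    ## their dedicated factors below
    skip <- switch(rx$rate_law, saturating = rx$sat,
                   amplified = c(rx$sat, rx$lin), character())
    lin_factor <- 1
    for (s in setdiff(names(rx$reactants), skip))
      lin_factor <- lin_factor * conc[[s]]^rx$reactants[[s]]
    for (s in setdiff(rx$modifiers, skip))
      lin_factor <- lin_factor * conc[[s]]
    switch(rx$rate_law,
      mass_action = k[[1]] * lin_factor,
      saturating = {
        cs <- conc[[rx$sat]]
        if (rx$sat %in% names(rx$reactants) && rx$reactants[[rx$sat]] > 1L)
          lin_factor <- lin_factor * cs^(rx$reactants[[rx$sat]] - 1L)
        k[[1]] * mm_frac(cs, k[[2]]) * lin_factor
      },
      amplified = {
        L <- conc[[rx$lin]]
        A <- conc[[rx$sat]]
        (k[[1]] * L + k[[3]] * L * mm_frac(A, k[[2]])) * lin_factor
      })
  }, numeric(1))
}

check_params <- function(net, params) {
  missing <- setdiff(net$parameter_names, names(params))
  if (length(missing) > 0)
    stop(sprintf("missing rate constants: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  if (any(params[net$parameter_names] < 0))
    stop("rate constants must be non-negative", call. = FALSE)
  params[net$parameter_names]
}

#' The bundled selenium-metabolism network
#'
#' A six-species, eleven-reaction reconstruction of simplified selenium
#' metabolism and its effect on genomic DNA damage, with 18 rate constants.
#' Selenide (HSe) damages DNA directly (R1) and amplifies peroxide-mediated
#' damage through redox cycling (R3, R10), while methylselenol (MeSeH),
#' produced by methylation of selenide (R4), is protective by catalysing
#' peroxide reduction (R2). Extracellular selenium is clamped and enters the
#' cell as selenide through saturating transport (R8). Damaged DNA is
#' repaired back to the intact pool by a saturating repair reaction (R7), so
#' DNA + dmDNA is conserved by every reaction.
#'
#' Reactions and constants:
#' \describe{
#'   \item{R1 (2)}{selenide-mediated DNA damage, saturating in selenide}
#'   \item{R2 (2)}{methylselenol-catalysed peroxide reduction, saturating in
#'     peroxide}
#'   \item{R3 (3)}{peroxide-mediated DNA damage: linear term `R3_k0` plus a
#'     selenide-amplified term `R3_k2` with half-saturation `R3_k1`}
#'   \item{R4 (2)}{methylation of selenide to methylselenol, saturating}
#'   \item{R5 (1)}{methylselenol clearance}
#'   \item{R6 (1)}{constitutive peroxide production}
#'   \item{R7 (2)}{saturating repair of dmDNA to DNA}
#'   \item{R8 (2)}{saturating transport of extracellular selenium into the
#'     cell as selenide}
#'   \item{R9 (1)}{selenide clearance into selenoprotein synthesis}
#'   \item{R10 (1)}{selenide redox cycling producing peroxide}
#'   \item{R11 (1)}{basal peroxide decay}
#' }
#'
#' @param baseline_selenium initial (clamped) extracellular selenium, mM.
#' @return a `reaction_network` with 18 parameters.
#' @export
reference_selenium_network <- function(baseline_selenium = 1.7) {
  species <- tibble::tibble(
    name = c("Se_ext", "HSe", "MeSeH", "H2O2", "DNA", "dmDNA"),
    initial_concentration = c(baseline_selenium, 0, 0, 0, 1, 0),
    clamped = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE))
  reactions <- list(
    reaction("R1", reactants = c(DNA = 1L), products = c(dmDNA = 1L),
             modifiers = "HSe", rate_law = "saturating",
             constants = c("R1_k0", "R1_k1"), sat = "HSe"),
    reaction("R2", reactants = c(H2O2 = 1L), modifiers = "MeSeH",
             rate_law = "saturating", constants = c("R2_k0", "R2_k1"),
             sat = "H2O2"),
    reaction("R3", reactants = c(DNA = 1L), products = c(dmDNA = 1L),
             modifiers = c("H2O2", "HSe"), rate_law = "amplified",
             constants = c("R3_k0", "R3_k1", "R3_k2"),
             sat = "HSe", lin = "H2O2"),
    reaction("R4", reactants = c(HSe = 1L), products = c(MeSeH = 1L),
             rate_law = "saturating", constants = c("R4_k0", "R4_k1"),
             sat = "HSe"),
    reaction("R5", reactants = c(MeSeH = 1L), constants = "R5_k0"),
    reaction("R6", products = c(H2O2 = 1L), constants = "R6_k0"),
    reaction("R7", reactants = c(dmDNA = 1L), products = c(DNA = 1L),
             rate_law = "saturating", constants = c("R7_k0", "R7_k1"),
             sat = "dmDNA"),
    reaction("R8", products = c(HSe = 1L), modifiers = "Se_ext",
             rate_law = "saturating", constants = c("R8_k0", "R8_k1"),
             sat = "Se_ext"),
    reaction("R9", reactants = c(HSe = 1L), constants = "R9_k0"),
    reaction("R10", products = c(H2O2 = 1L), modifiers = "HSe",
             constants = "R10_k0"),
    reaction("R11", reactants = c(H2O2 = 1L), constants = "R11_k0"))
  parameter_names <- unlist(lapply(reactions, `[[`, "constants"))
  reaction_network(species, reactions, parameter_names,
                   dose_species = "Se_ext", damage_species = "dmDNA",
                   topology = "selenium_reference")
}

## Exact steady state for the reference topology: the network is a feed-
## forward cascade (Se_ext -> HSe -> MeSeH, H2O2 -> dmDNA) whose balance at
## each layer is monotone in one unknown, so each layer is a bracketed
## scalar root-find. Orders of magnitude faster than integrating, and used
## heavily by the constrained ensemble sampler.
reference_steady_state <- function(params, selenium_level, dna_total = 1) {
  p <- as.list(params)
  root <- function(f, upper) {
    if (f(0) <= 0) return(0)
    ## the analytic upper bound can be non-negative by one ulp under
    ## cancellation; expand until the bracket is genuinely negative
    for (i in 1:64) {
      if (f(upper) < 0) break
      upper <- upper * 4
    }
    stats::uniroot(f, c(0, upper), tol = 1e-14,
                   maxiter = 2000L)$root
  }
  i8 <- p$R8_k0 * mm_frac(selenium_level, p$R8_k1)
  h <- root(function(h) i8 - p$R4_k0 * mm_frac(h, p$R4_k1) - p$R9_k0 * h,
            upper = 2 * i8 / p$R9_k0 + 1)
  m <- p$R4_k0 * mm_frac(h, p$R4_k1) / p$R5_k0
  prod_x <- p$R6_k0 + p$R10_k0 * h
  x <- root(function(x) prod_x - p$R2_k0 * mm_frac(x, p$R2_k1) * m -
              p$R11_k0 * x,
            upper = 2 * prod_x / p$R11_k0 + 1)
  a <- damage_rate_per_DNA(p, h, x)
  d <- if (a <= 0) 0 else
    stats::uniroot(function(d) a * (dna_total - d) -
                     p$R7_k0 * mm_frac(d, p$R7_k1),
                   c(0, dna_total), tol = 1e-14, maxiter = 2000L)$root
  c(Se_ext = selenium_level, HSe = h, MeSeH = m, H2O2 = x,
    DNA = dna_total - d, dmDNA = d)
}

## first-order damage rate acting on the intact DNA pool
damage_rate_per_DNA <- function(p, hse, h2o2) {
  p$R1_k0 * mm_frac(hse, p$R1_k1) + p$R3_k0 * h2o2 +
    p$R3_k2 * h2o2 * mm_frac(hse, p$R3_k1)
}

#' Default rate-constant bounds
#'
#' Lower/upper bounds for every rate constant. All constants default to the
#' one printed range, \eqn{10^{-6}} to \eqn{10^6}: rates must be positive
#' and bounded above by diffusion limits.
#'
#' @param net a `reaction_network`.
#' @param lower,upper shared bounds applied to every constant.
#' @return tibble with columns `name`, `lower`, `upper`.
#' @export
default_parameter_bounds <- function(net = reference_selenium_network(),
                                     lower = 1e-6, upper = 1e6) {
  stopifnot(lower > 0, upper >= lower)
  tibble::tibble(name = net$parameter_names, lower = lower, upper = upper)
}

#' Nominal parameter set: geometric mean of the bounds
#'
#' @param bounds tibble as from [default_parameter_bounds()].
#' @return named numeric vector of rate constants.
#' @export
nominal_parameters <- function(bounds = default_parameter_bounds()) {
  stats::setNames(sqrt(bounds$lower * bounds$upper), bounds$name)
}

network_rhs <- function(net, params) {
  S <- stoichiometry_matrix(net)
  S[net$species$clamped, ] <- 0
  force(params)
  function(t, y, p) {
    rates <- reaction_rates(net, y, params)
    list(as.numeric(S %*% rates))
  }
}

#' Integrate a reaction network
#'
#' Deterministic mass-action/saturating kinetics via a stiff ODE solver.
#' Clamped species are held at their (possibly overridden) initial values.
#'
#' @param net a `reaction_network`.
#' @param params named numeric vector covering `net$parameter_names`.
#' @param t_end final time (years).
#' @param initial_override named numeric vector replacing selected initial
#'   concentrations (e.g. the clamped selenium dose).
#' @param times optional explicit output time grid (overrides `t_end`).
#' @param rtol,atol solver tolerances.
#' @return tibble with a `time` column and one column per species.
#' @export
simulate_network <- function(net, params, t_end, initial_override = NULL,
                             times = NULL, rtol = 1e-10, atol = 1e-12) {
  params <- check_params(net, params)
  y0 <- stats::setNames(net$species$initial_concentration, net$species$name)
  if (!is.null(initial_override)) {
    unknown <- setdiff(names(initial_override), names(y0))
    if (length(unknown) > 0)
      stop("initial_override names unknown species: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    y0[names(initial_override)] <- initial_override
  }
  if (is.null(times)) {
    stopifnot(t_end > 0)
    times <- seq(0, t_end, length.out = 201)
  }
  sol <- deSolve::ode(y = y0, times = times, func = network_rhs(net, params),
                      parms = NULL, method = "lsoda",
                      rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0) {
    last <- sol[nrow(sol), ]
    stop(sprintf(
      "integration failed at t = %.4g; last state: %s", last[[1]],
      paste(sprintf("%s=%.4g", names(y0), last[-1]), collapse = ", ")),
      call. = FALSE)
  }
  out <- tibble::as_tibble(as.data.frame(sol))
  out[out < 0 & out > -1e-9] <- 0
  out
}

#' Steady state of a reaction network
#'
#' Integrates to quasi-equilibrium over geometrically growing horizons until
#' every non-clamped derivative satisfies
#' \eqn{|dC/dt| < tol \times \max(C)}, then polishes with damped Newton
#' iterations on the derivative vector (in the integrator's basin, so the
#' conserved-moiety null direction is harmless: Newton steps are solved by
#' least squares).
#'
#' For the bundled reference topology the network is a feed-forward cascade
#' and the steady state is instead computed exactly by bracketed scalar
#' root-finding per layer (`method = "cascade"`); `method = "auto"` picks
#' the cascade when available. The two routes agree to solver tolerance and
#' are cross-checked in the test suite.
#'
#' @param net,params as in [simulate_network()].
#' @param initial_override optional named overrides of initial state.
#' @param tol relative derivative tolerance (default 1e-9).
#' @param t_max maximum integration horizon before giving up.
#' @param method `"auto"`, `"cascade"` or `"integrate"`.
#' @return named numeric vector of steady-state concentrations.
#' @export
steady_state <- function(net, params, initial_override = NULL,
                         tol = 1e-9, t_max = 1e12,
                         method = c("auto", "cascade", "integrate")) {
  params <- check_params(net, params)
  method <- match.arg(method)
  if (method != "integrate" &&
      identical(net$topology, "selenium_reference")) {
    y0 <- stats::setNames(net$species$initial_concentration,
                          net$species$name)
    if (!is.null(initial_override))
      y0[names(initial_override)] <- initial_override
    return(reference_steady_state(params, selenium_level = y0[["Se_ext"]],
                                  dna_total = y0[["DNA"]] + y0[["dmDNA"]]))
  }
  if (method == "cascade")
    stop("cascade solver is only available for the reference topology",
         call. = FALSE)
  y <- stats::setNames(net$species$initial_concentration, net$species$name)
  if (!is.null(initial_override)) y[names(initial_override)] <- initial_override
  rhs <- network_rhs(net, params)
  free <- !net$species$clamped
  resid <- function(y) rhs(0, y, NULL)[[1]]
  scale_of <- function(y) max(abs(y), 1e-12)
  t_hi <- 100
  repeat {
    sol <- deSolve::ode(y = y, times = c(0, t_hi), func = rhs, parms = NULL,
                        method = "lsoda", rtol = 1e-11, atol = 1e-13)
    y <- sol[nrow(sol), -1]
    r <- resid(y)
    if (max(abs(r[free])) < tol * scale_of(y)) break
    t_hi <- t_hi * 100
    if (t_hi > t_max)
      stop(sprintf(
        "no steady state within t = %.3g; residual derivatives: %s", t_max,
        paste(sprintf("%s=%.3g", names(y)[free], r[free]), collapse = ", ")),
        call. = FALSE)
  }
  ## Newton polish on the free coordinates (least-squares step tolerates the
  ## conservation-law null space)
  idx <- which(free)
  for (it in seq_len(8)) {
    r <- resid(y)[idx]
    if (max(abs(r)) < 1e-13 * scale_of(y)) break
    J <- matrix(0, length(idx), length(idx))
    h <- pmax(abs(y[idx]), 1e-8) * 1e-7
    for (j in seq_along(idx)) {
      yp <- y; yp[idx[j]] <- yp[idx[j]] + h[j]
      J[, j] <- (resid(yp)[idx] - r) / h[j]
    }
    step <- tryCatch(stats::lm.fit(J, -r)$coefficients,
                     error = function(e) rep(0, length(idx)))
    step[is.na(step)] <- 0
    y_new <- y
    y_new[idx] <- y[idx] + step
    if (any(y_new < 0) ||
        max(abs(resid(y_new)[idx])) >= max(abs(r))) break
    y <- y_new
  }
  pmax(y, 0)
}

#' Steady-state damaged-DNA level at a given selenium dose
#'
#' @param net a `reaction_network` whose `dose_species`/`damage_species`
#'   are set (as in [reference_selenium_network()]).
#' @param params named rate-constant vector.
#' @param selenium_level extracellular selenium (mM), clamped during the
#'   solve.
#' @param ... passed to [steady_state()].
#' @return scalar steady-state dmDNA concentration.
#' @export
steady_state_dmDNA <- function(net, params, selenium_level, ...) {
  stopifnot(selenium_level > 0)
  if (is.na(net$dose_species) || is.na(net$damage_species))
    stop("network does not declare dose/damage species", call. = FALSE)
  ov <- stats::setNames(selenium_level, net$dose_species)
  ss <- steady_state(net, params, initial_override = ov, ...)
  unname(ss[net$damage_species])
}

#' Dose-response curve of relative mutation rate versus selenium level
#'
#' Steady-state damaged DNA at each selenium level, normalized to the
#' baseline level so the curve passes through 1 at baseline by construction.
#'
#' @param net,params as in [steady_state_dmDNA()].
#' @param selenium_grid numeric vector of selenium levels (mM).
#' @param baseline baseline selenium level (mM), default 1.7.
#' @return tibble with columns `selenium_mM`, `relative_mutation_rate`.
#' @export
dose_response <- function(net, params, selenium_grid, baseline = 1.7) {
  ref <- steady_state_dmDNA(net, params, baseline)
  vals <- vapply(selenium_grid, function(lv) {
    tryCatch(steady_state_dmDNA(net, params, lv),
             error = function(e) stop(sprintf(
               "steady state failed at selenium level %.4g mM: %s",
               lv, conditionMessage(e)), call. = FALSE))
  }, numeric(1))
  rel <- if (ref > 0) vals / ref else ifelse(vals == 0, 1, Inf)
  rel[selenium_grid == baseline] <- 1
  tibble::tibble(selenium_mM = selenium_grid, relative_mutation_rate = rel)
}
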