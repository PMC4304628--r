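# shared fixtures built in code

ref_net <- reference_selenium_network()
ref_nominal <- nominal_parameters()

# single irreversible conversion A -> B with mass-action constant k
two_species_network <- function(k_name = "k") {
  reaction_network(
    species = tibble::tibble(name = c("A", "B"),
                             initial_concentration = c(2, 0),
                             clamped = c(FALSE, FALSE)),
    reactions = list(reaction("J1", reactants = c(A = 1L),
                              products = c(B = 1L), constants = k_name)),
    parameter_names = k_name)
}

# constant-hazard curve (exponential onset) for sampling tests
constant_hazard_curve <- function(lambda, horizon, n_grid = 400L) {
  ages <- seq(0, horizon, length.out = n_grid)
  structure(tibble::tibble(age = ages, hazard = lambda,
                           survival = exp(-lambda * ages)),
            class = c("hazard_curve", class(tibble::tibble())))
}

# small multistage parameter set used for solver cross-checks
small_onset_params <- function() {
  onset_parameters(nu = 1, mu = 0.05, beta = 1, delta = 1, K = 3L)
}
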