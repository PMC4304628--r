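test_that("reference network has the expected structure", {
  expect_length(ref_net$parameter_names, 18)
  expect_setequal(
    c("R3_k0", "R3_k2", "R4_k0", "R8_k0"),
    intersect(ref_net$parameter_names,
              c("R3_k0", "R3_k2", "R4_k0", "R8_k0")))
  expect_true(ref_net$species$clamped[ref_net$species$name == "Se_ext"])
  # every reaction conserves the genomic pool DNA + dmDNA
  S <- stoichiometry_matrix(ref_net)
  expect_true(all(S["DNA", ] + S["dmDNA", ] == 0))
})

test_that("network validation rejects inconsistent definitions", {
  sp <- tibble::tibble(name = c("A", "B"), initial_concentration = c(1, 0),
                       clamped = FALSE)
  expect_error(
    reaction_network(sp, list(reaction("J1", reactants = c(C = 1L),
                                       constants = "k")), "k"),
    "unknown species")
  expect_error(
    reaction_network(sp, list(reaction("J1", reactants = c(A = 1L),
                                       constants = "k")), c("k", "k2")),
    "exactly once")
  expect_error(reaction("J1", reactants = c(A = 1L), constants = c("a", "b")),
               "takes 1 constants")
  sp_dup <- tibble::tibble(name = c("A", "A"),
                           initial_concentration = c(1, 0), clamped = FALSE)
  expect_error(reaction_network(sp_dup, list(), character()), "unique")
})

test_that("zero rate constants freeze the trajectory", {
  p <- ref_nominal
  p[] <- 0
  tr <- simulate_network(ref_net, p, t_end = 10)
  for (sp in ref_net$species$name)
    expect_equal(tr[[sp]],
                 rep(ref_net$species$initial_concentration[
                   ref_net$species$name == sp], nrow(tr)))
})

test_that("single mass-action reaction matches the closed form", {
  net <- two_species_network()
  k <- 0.37
  tr <- simulate_network(net, c(k = k), t_end = 12)
  expect_lt(max(abs(tr$B - 2 * (1 - exp(-k * tr$time)))), 1e-6)
  expect_lt(max(abs(tr$A + tr$B - 2)), 1e-9)
})

test_that("trajectories conserve the genomic pool and stay non-negative", {
  tr <- simulate_network(ref_net, ref_nominal, t_end = 60)
  total <- tr$DNA + tr$dmDNA
  expect_lt(max(abs(total - total[1])) / total[1], 1e-6)
  expect_true(all(as.matrix(tr[, -1]) >= -1e-9))
})

test_that("steady state is idempotent across initial conditions", {
  ov1 <- c(Se_ext = 1.7)
  ov2 <- c(Se_ext = 1.7, HSe = 0.9, MeSeH = 0.4, H2O2 = 2.1,
           DNA = 0.3, dmDNA = 0.7)
  s1 <- steady_state(ref_net, ref_nominal, ov1, method = "integrate")
  s2 <- steady_state(ref_net, ref_nominal, ov2, method = "integrate")
  expect_lt(max(abs(s1 - s2) / pmax(abs(s1), 1e-12)), 1e-4)
})

test_that("cascade and integration steady states agree", {
  set.seed(71)
  for (i in 1:4) {
    p <- stats::setNames(10^runif(18, -3, 3), ref_net$parameter_names)
    a <- steady_state(ref_net, p, c(Se_ext = 1.7))
    b <- steady_state(ref_net, p, c(Se_ext = 1.7), method = "integrate")
    expect_lt(max(abs(a - b) / pmax(abs(b), 1e-9)), 1e-5)
  }
})

test_that("long integration endpoint reproduces the steady state", {
  ss <- steady_state_dmDNA(ref_net, ref_nominal, 1.7)
  tr <- simulate_network(ref_net, ref_nominal, t_end = 500,
                         initial_override = c(Se_ext = 1.7))
  expect_lt(abs(tr$dmDNA[nrow(tr)] / ss - 1), 1e-6)
})

test_that("dmDNA vanishes without damage sources or with huge repair", {
  p <- ref_nominal
  p[c("R1_k0", "R3_k0", "R3_k2")] <- 0
  expect_equal(steady_state_dmDNA(ref_net, p, 1.7), 0)
  p2 <- ref_nominal
  p2["R7_k0"] <- 1e12
  expect_lt(steady_state_dmDNA(ref_net, p2, 1.7), 1e-9)
})

test_that("dose-response is normalized at baseline and >= 0", {
  dr <- dose_response(ref_net, ref_nominal, c(1.0, 1.7, 2.5, 4.0))
  expect_identical(dr$relative_mutation_rate[dr$selenium_mM == 1.7], 1)
  expect_true(all(dr$relative_mutation_rate >= 0))
  # consistency with direct two-point steady states
  r25 <- steady_state_dmDNA(ref_net, ref_nominal, 2.5) /
    steady_state_dmDNA(ref_net, ref_nominal, 1.7)
  expect_equal(dr$relative_mutation_rate[dr$selenium_mM == 2.5], r25,
               tolerance = 1e-9)
})

test_that("blocking selenium transport flattens the dose-response", {
  p <- ref_nominal
  p["R8_k0"] <- 0
  dr <- dose_response(ref_net, p, c(1.0, 1.7, 2.5, 4.0))
  expect_equal(dr$relative_mutation_rate, rep(1, 4), tolerance = 1e-9)
})

test_that("bounds and nominal parameters are consistent", {
  b <- default_parameter_bounds(ref_net)
  expect_equal(nrow(b), 18)
  nom <- nominal_parameters(b)
  expect_true(all(nom >= b$lower & nom <= b$upper))
  expect_equal(unname(nom), rep(1, 18)) # geometric mean of 1e-6..1e6
})
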