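test_that("extinction profile matches closed forms", {
  # no mutation: no route to malignancy, lineages never produce K-mutants
  p0 <- onset_parameters(nu = 1, mu = 0, beta = 2, delta = 1, K = 4L)
  ep0 <- extinction_profile(p0, seq(0, 10, 1))
  expect_true(all(abs(as.matrix(ep0[, -1]) - 1) < 1e-8))
  # K = 2, beta = delta = 0: pure waiting time, u1 = exp(-mu tau)
  p1 <- onset_parameters(nu = 1, mu = 0.3, beta = 0, delta = 0, K = 2L)
  ep1 <- extinction_profile(p1, seq(0, 5, 0.25))
  expect_lt(max(abs(ep1$u1 - exp(-0.3 * ep1$tau))), 1e-8)
  # invariants: u(0) = 1, non-increasing, in [0, 1]
  ep <- extinction_profile(small_onset_params(), seq(0, 20, 0.5))
  expect_equal(unlist(ep[1, -1], use.names = FALSE), rep(1, 2))
  expect_true(all(diff(ep$u1) <= 1e-10))
  expect_true(all(ep$u1 >= 0 & ep$u1 <= 1))
})

test_that("hazard handles degenerate stage counts and zero mutation", {
  ages <- seq(0, 50, 0.5)
  h0 <- onset_hazard(onset_parameters(2, 0, 1, 1, 3L), ages)
  expect_true(all(abs(h0$hazard) < 1e-8))
  expect_true(all(abs(h0$survival - 1) < 1e-8))
  # K = 1: every seeded cell is malignant -> constant hazard nu
  h1 <- onset_hazard(onset_parameters(0.02, 0.5, 1, 1, 1L), ages)
  expect_equal(h1$hazard, rep(0.02, length(ages)))
  expect_equal(h1$survival, exp(-0.02 * ages), tolerance = 1e-12)
})

test_that("hazard approaches the Armitage-Doll form without clonal expansion", {
  p <- onset_parameters(nu = 100, mu = 1e-4, beta = 0, delta = 0, K = 4L)
  ages <- seq(0, 100, 1) # mu * t <= 0.01 throughout
  hc <- onset_hazard(p, ages)
  ad <- p$nu * (p$mu * ages)^(p$K - 1) / factorial(p$K - 1)
  idx <- ages >= 10
  expect_lt(max(abs(hc$hazard[idx] / ad[idx] - 1)), 0.01)
})

test_that("hazard is monotone in the mutation rate", {
  ages <- seq(0, 60, 1)
  mus <- c(0.01, 0.02, 0.05, 0.1)
  hs <- lapply(mus, function(m)
    onset_hazard(onset_parameters(1, m, 1, 1, 3L), ages)$hazard)
  for (i in seq_len(length(mus) - 1))
    expect_true(all(hs[[i + 1]] - hs[[i]] >= -1e-9))
})

test_that("survival curve is consistent: S non-increasing, S(0) = 1", {
  hc <- onset_hazard(small_onset_params(), seq(0, 30, 0.25))
  expect_equal(hc$survival[1], 1)
  expect_true(all(diff(hc$survival) <= 1e-12))
  expect_true(all(hc$hazard >= 0))
})

test_that("onset-age sampling reproduces the exponential distribution", {
  lambda <- 0.2
  curve <- constant_hazard_curve(lambda, horizon = 150)
  set.seed(101)
  x <- sample_onset_age(curve, entry_age = 0, n = 100000)
  x <- x[!is.na(x)]
  se <- (1 / lambda) / sqrt(length(x))
  expect_lt(abs(mean(x) - 1 / lambda), 3 * se)
})

test_that("constant-hazard sampling is memoryless under left truncation", {
  lambda <- 0.15
  curve <- constant_hazard_curve(lambda, horizon = 250)
  a <- 40
  # a single 10k-draw KS at alpha 0.01 fails by chance for ~1% of draws;
  # require the property to hold for the majority of sub-draws
  pv <- vapply(1:3, function(s) {
    set.seed(102 + s)
    x0 <- sample_onset_age(curve, entry_age = 0, n = 10000)
    xa <- sample_onset_age(curve, entry_age = a, n = 10000)
    suppressWarnings(
      stats::ks.test(x0[!is.na(x0)], xa[!is.na(xa)] - a))$p.value
  }, numeric(1))
  expect_gte(sum(pv > 0.01), 2)
})

test_that("conditional sampling equals unconditional sampling plus rejection", {
  hc <- onset_hazard(small_onset_params(), seq(0, 40, 0.1))
  set.seed(103)
  a <- 5
  cond <- sample_onset_age(hc, entry_age = a, n = 8000)
  uncond <- sample_onset_age(hc, entry_age = 0, n = 40000)
  kept <- uncond[!is.na(uncond) & uncond > a]
  ks <- suppressWarnings(stats::ks.test(cond[!is.na(cond)], kept))
  expect_gt(ks$p.value, 0.01)
})

test_that("zero hazard always returns none-within-horizon", {
  curve <- constant_hazard_curve(0, horizon = 50)
  expect_true(all(is.na(sample_onset_age(curve, 0, n = 100))))
})

test_that("sampling errors when survival is exhausted at entry", {
  curve <- constant_hazard_curve(10, horizon = 400)
  expect_error(sample_onset_age(curve, entry_age = 390, n = 1),
               "conditioning impossible")
})

test_that("Gillespie oracle matches Poisson seeding for K = 1", {
  p <- onset_parameters(nu = 0.5, mu = 0, beta = 0, delta = 0, K = 1L)
  set.seed(104)
  t <- stochastic_onset_oracle(p, t_end = 60, n = 20000)
  t <- t[!is.na(t)]
  se <- (1 / p$nu) / sqrt(length(t))
  expect_lt(abs(mean(t) - 1 / p$nu), 3 * se)
})

test_that("Gillespie oracle never fires without mutation (K > 1)", {
  p <- onset_parameters(nu = 2, mu = 0, beta = 1, delta = 1.2, K = 3L)
  set.seed(105)
  expect_true(all(is.na(stochastic_onset_oracle(p, t_end = 5, n = 200))))
  expect_false(any(lineage_onset_oracle(p, tau = 5, n = 200)))
})

test_that("Gillespie draws are reproducible under set.seed", {
  p <- small_onset_params()
  set.seed(106); a <- stochastic_onset_oracle(p, t_end = 5, n = 50)
  set.seed(106); b <- stochastic_onset_oracle(p, t_end = 5, n = 50)
  expect_identical(a, b)
})

test_that("ODE extinction probabilities agree with lineage simulation", {
  p <- small_onset_params()
  set.seed(107)
  n <- 20000
  hit <- lineage_onset_oracle(p, tau = 5, n = n)
  u_mc <- 1 - mean(hit)
  u_ode <- extinction_profile(p, c(0, 5))$u1[2]
  se <- sqrt(u_mc * (1 - u_mc) / n)
  expect_lt(abs(u_mc - u_ode), 3 * se)
})
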