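base_params <- onset_reference_parameters()

test_that("zero hazard censors every subject at follow-up", {
  p0 <- onset_parameters(nu = 0, mu = 0, beta = 1, delta = 1, K = 4L)
  design <- trial_design(n_per_arm = 200, n_replicates = 2)
  curve <- onset_hazard(p0, seq(0, 85, 0.5))
  surf <- onset_switch_surface(p0, p0, age_max = 78, tau_max = 7)
  set.seed(31)
  subj <- simulate_trial(design, curve, surf)
  expect_true(all(subj$event == 0))
  expect_true(all(subj$time == design$follow_up))
})

test_that("an at-entry switch to identical rates is exactly homogeneous", {
  surf <- onset_switch_surface(base_params, base_params, age_max = 78,
                               tau_max = 7)
  curve <- onset_hazard(base_params, seq(0, 85, 0.25))
  for (a in c(58, 62, 66)) {
    H <- switch_cum_hazard(surf, a)
    logS <- stats::approx(curve$age, log(curve$survival),
                          xout = a + surf$tau_grid)$y
    H_hom <- -(logS - logS[1])
    expect_lt(max(abs(H[1, ] - H_hom)), 0.005 * max(H_hom))
  }
})

test_that("event times with zero lag follow the exponential oracle", {
  lambda <- 0.05
  design <- trial_design(n_per_arm = 25000, follow_up = 60,
                         entry_age_mean = 30, entry_age_sd = 0.5,
                         lag_mean = 0, n_replicates = 1)
  curve <- constant_hazard_curve(lambda, horizon = 200)
  pk1 <- onset_parameters(nu = lambda, mu = 0, beta = 0, delta = 0, K = 1L)
  surf <- onset_switch_surface(pk1, pk1, age_max = 40, tau_max = 60)
  set.seed(32)
  subj <- simulate_trial(design, curve, surf)
  ev <- subj$time[subj$event == 1]
  # moment check against the censored-exponential mean
  m_theory <- (1 - (1 + lambda * 60) * exp(-lambda * 60)) /
    (lambda * (1 - exp(-lambda * 60)))
  expect_lt(abs(mean(ev) - m_theory), 3 * sd(ev) / sqrt(length(ev)))
})

test_that("cox_fit matches survival::coxph on regular data", {
  set.seed(33)
  n <- 400
  arm <- rep(c("control", "supplement"), each = n)
  time <- c(rexp(n, 0.1), rexp(n, 0.07))
  event <- as.integer(time < 8)
  time <- pmin(time, 8)
  res <- cox_fit(time, event, arm)
  ref <- survival::coxph(
    survival::Surv(time, event) ~ I(arm == "supplement"),
    ties = "breslow")
  expect_equal(log(res$hazard_ratio), unname(coef(ref)), tolerance = 1e-8)
  expect_false(res$monotone)
  expect_true(res$p_value > 0 && res$p_value < 1)
})

test_that("monotone partial likelihood is capped with a score-test p", {
  # two subjects, one per arm; the treated subject fails first, then the
  # control: L(b) = e^b / (e^b + 1), maximized at the cap
  res <- cox_fit(time = c(2, 1), event = c(1, 1),
                 arm = c("control", "supplement"))
  expect_true(res$monotone)
  expect_true(is.finite(res$p_value))
  expect_gt(res$hazard_ratio, 1e6)
  # and the mirrored case caps below 1
  res2 <- cox_fit(time = c(1, 2), event = c(1, 1),
                  arm = c("control", "supplement"))
  expect_lt(res2$hazard_ratio, 1e-6)
  expect_error(cox_fit(c(1, 1), c(0, 0), c("control", "supplement")),
               "no events")
})

test_that("planted hazard ratio is recovered by the Cox fit", {
  set.seed(34)
  fits <- replicate(200, {
    n <- 600
    time <- c(rexp(n, 0.1), rexp(n, 0.07))
    event <- as.integer(time < 10)
    cox_fit(pmin(time, 10), event,
            rep(c("control", "supplement"), each = n))$hazard_ratio
  })
  lhr <- log(fits)
  expect_lt(abs(mean(lhr) - log(0.7)),
            3 * sd(lhr) / sqrt(length(lhr)))
})

test_that("identical arms reject at close to the nominal rate", {
  set.seed(35)
  pvals <- replicate(300, {
    n <- 500
    time <- rexp(2 * n, 0.1)
    event <- as.integer(time < 8)
    cox_fit(pmin(time, 8), event,
            rep(c("control", "supplement"), each = n))$p_value
  })
  expect_gt(mean(pvals < 0.05), 0.01)
  expect_lt(mean(pvals < 0.05), 0.10)
})

test_that("replicates share biology but differ in population draws", {
  design <- trial_design(n_per_arm = 500, n_replicates = 3)
  curve <- onset_hazard(base_params, seq(0, 85, 0.25))
  supp <- onset_parameters(base_params$nu, base_params$mu * 0.4,
                           base_params$beta, base_params$delta,
                           base_params$K)
  surf <- onset_switch_surface(base_params, supp, age_max = 78,
                               tau_max = 7)
  r1 <- run_replicates(design, curve, surf, seed = 11)
  r2 <- run_replicates(design, curve, surf, seed = 11)
  expect_equal(r1, r2) # same seed, identical results
  expect_equal(nrow(r1), 3)
  expect_false(isTRUE(all.equal(r1$hazard_ratio[1], r1$hazard_ratio[2])))
})

test_that("a flat dose-response yields a null hazard ratio on average", {
  design <- trial_design(n_per_arm = 2000, n_replicates = 10)
  curve <- onset_hazard(base_params, seq(0, 85, 0.25))
  surf <- onset_switch_surface(base_params, base_params, age_max = 78,
                               tau_max = 7)
  res <- run_replicates(design, curve, surf, seed = 12)
  lhr <- log(res$hazard_ratio)
  expect_lt(abs(mean(lhr)), 3 * sd(lhr) / sqrt(length(lhr)) + 0.02)
})

test_that("outcome classification follows the two-significant rule", {
  mk <- function(p, hr) tibble::tibble(p_value = p, hazard_ratio = hr)
  expect_identical(
    classify_outcome(mk(c(0.01, 0.02, 0.8), c(0.7, 0.8, 1.0)))$label,
    "beneficial")
  expect_identical(
    classify_outcome(mk(c(0.01, 0.02), c(1.1, 1.15)))$label, "harmful")
  expect_identical(
    classify_outcome(mk(c(0.04, 0.2, 0.3), c(0.5, 0.6, 0.7)))$label,
    "insignificant")
  # boundary: exactly two significant replicates suffice
  expect_identical(
    classify_outcome(mk(c(0.049, 0.049, 0.9), c(0.8, 0.9, 1.0)))$label,
    "beneficial")
  expect_error(classify_outcome(mk(0.01, 0.5)), "at least 2")
})

test_that("power never decreases with arm size at a fixed true effect", {
  curve <- onset_hazard(base_params, seq(0, 85, 0.25))
  supp <- onset_parameters(base_params$nu, base_params$mu * 0.3,
                           base_params$beta, base_params$delta,
                           base_params$K)
  surf <- onset_switch_surface(base_params, supp, age_max = 78,
                               tau_max = 7)
  rates <- vapply(c(500, 2000, 8000), function(n) {
    design <- trial_design(n_per_arm = n, n_replicates = 8)
    res <- run_replicates(design, curve, surf, seed = 13)
    mean(res$p_value < 0.05)
  }, numeric(1))
  expect_true(all(diff(rates) >= -0.15)) # monotone up to replicate noise
  expect_gt(rates[3], rates[1])
})
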