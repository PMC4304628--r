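#' Two-arm prevention trial design
#'
#' @param n_per_arm subjects per arm.
#' @param entry_age_mean,entry_age_sd normal entry-age distribution (years).
#' @param follow_up follow-up length (years).
#' @param baseline_selenium,supplement_selenium selenium levels (mM) in the
#'   control and supplement arms.
#' @param n_replicates replicated trials per parameter set.
#' @param alpha significance level for the outcome classification.
#' @param lag_mean mean of the exponential onset-to-diagnosis lag (years);
#'   the natural-history waiting-time model.
#' @return object of class `trial_design`.
#' @export
trial_design <- function(n_per_arm = 10000L, entry_age_mean = 62.0,
                         entry_age_sd = 2.0, follow_up = 7,
                         baseline_selenium = 1.7, supplement_selenium = 2.5,
                         n_replicates = 3L, alpha = 0.05, lag_mean = 5) {
  stopifnot(n_per_arm >= 1, entry_age_sd > 0, follow_up > 0,
            alpha > 0, alpha < 1, n_replicates >= 1, lag_mean >= 0)
  structure(list(n_per_arm = as.integer(n_per_arm),
                 entry_age_mean = entry_age_mean,
                 entry_age_sd = entry_age_sd, follow_up = follow_up,
                 baseline_selenium = baseline_selenium,
                 supplement_selenium = supplement_selenium,
                 n_replicates = as.integer(n_replicates), alpha = alpha,
                 lag_mean = lag_mean),
            class = "trial_design")
}

#' Post-entry onset distribution under an at-entry mutation-rate switch
#'
#' In the supplement arm the cellular mutation rate switches from its
#' baseline value to the supplemented value at trial entry, so lineages
#' seeded before entry evolve under baseline rates and then under
#' supplemented rates. Writing the extinction system's flow map as
#' \eqn{\phi_\tau}, the lineage survival for seeding time s < a < t is
#' \eqn{u(s,t) = \phi^{base}_{a-s}(\phi^{supp}_{t-a}(1))}. The cumulative
#' post-entry onset hazard for a subject entering at age a is then
#' \deqn{H(\tau | a) = \nu [Q_s(\tau) + \Phi_2(a, \tau) - Q_b(a)]}
#' with \eqn{Q_s, Q_b} the homogeneous quadratures under the two rate
#' sets and \eqn{\Phi_2(a,\tau) = \int_0^a (1 - [\phi^{base}_\sigma(w)]_1)
#' d\sigma}, \eqn{w = \phi^{supp}_\tau(1)}. One backward solve per
#' tau-grid point yields \eqn{\Phi_2} for every entry age at once.
#' When the two parameter sets are identical this reduces exactly to the
#' time-homogeneous conditional distribution.
#'
#' @param base_params,supp_params `onset_parameters` before/after entry
#'   (same `nu` and `K`).
#' @param age_max largest supported entry age (years).
#' @param tau_max post-entry horizon (years), typically the follow-up.
#' @param n_tau,age_step grid resolutions.
#' @return object of class `onset_switch_surface`.
#' @export
onset_switch_surface <- function(base_params, supp_params,
                                 age_max = 80, tau_max = 7,
                                 n_tau = 36L, age_step = 0.5) {
  stopifnot(inherits(base_params, "onset_parameters"),
            inherits(supp_params, "onset_parameters"),
            base_params$K == supp_params$K,
            base_params$nu == supp_params$nu)
  tau_grid <- seq(0, tau_max, length.out = n_tau)
  age_grid <- seq(0, age_max, by = age_step)
  K <- base_params$K
  if (K == 1L) {
    ## seeded cells are malignant immediately; the switch is irrelevant
    surf <- list(K = 1L, nu = base_params$nu, tau_grid = tau_grid,
                 age_grid = age_grid)
    class(surf) <- "onset_switch_surface"
    return(surf)
  }
  Km1 <- K - 1L
  ## all flows run in the complement v = 1 - u (see extinction_rhs)
  sup <- solve_extinction(supp_params, tau_grid, quadrature = TRUE)
  Vs <- matrix(pmin(pmax(sup[, 1 + seq_len(Km1), drop = FALSE], 0), 1),
               ncol = Km1)
  Qs <- sup[, ncol(sup)]
  base0 <- solve_extinction(base_params, age_grid, quadrature = TRUE)
  Qb <- base0[, ncol(base0)]
  Phi2 <- matrix(0, nrow = length(age_grid), ncol = n_tau)
  Phi2[, 1] <- Qb # v = 0 at tau = 0
  for (j in 2:n_tau) {
    solj <- solve_extinction(base_params, age_grid, v0 = Vs[j, ],
                             quadrature = TRUE)
    Phi2[, j] <- solj[, ncol(solj)]
  }
  surf <- list(K = K, nu = base_params$nu, tau_grid = tau_grid,
               age_grid = age_grid, Qs = Qs, Qb = Qb, Phi2 = Phi2)
  class(surf) <- "onset_switch_surface"
  surf
}

## Cumulative post-entry hazard matrix H[i, j] = H(tau_j | a_i) for a
## vector of entry ages; rows are non-decreasing in tau by construction
## (enforced against interpolation wiggle).
switch_cum_hazard <- function(surface, entry_ages) {
  tg <- surface$tau_grid
  if (surface$K == 1L)
    return(outer(rep(surface$nu, length(entry_ages)), tg))
  ag <- surface$age_grid
  i0 <- pmin(pmax(findInterval(entry_ages, ag), 1L), length(ag) - 1L)
  wt <- (entry_ages - ag[i0]) / (ag[i0 + 1L] - ag[i0])
  Phi2_a <- surface$Phi2[i0, , drop = FALSE] * (1 - wt) +
    surface$Phi2[i0 + 1L, , drop = FALSE] * wt
  Qb_a <- surface$Qb[i0] * (1 - wt) + surface$Qb[i0 + 1L] * wt
  H <- surface$nu * (matrix(surface$Qs, nrow = length(entry_ages),
                            ncol = length(tg), byrow = TRUE) +
                       Phi2_a - Qb_a)
  H[, 1] <- 0
  t(apply(H, 1, cummax))
}

## Inverse-transform sample of post-entry onset times from a cumulative
## hazard matrix: returns tau (NA when onset exceeds the grid horizon).
sample_from_cum_hazard <- function(H, tau_grid, u) {
  target <- -log(u)
  j <- rowSums(H < target)
  n_tau <- length(tau_grid)
  tau <- rep(NA_real_, nrow(H))
  in_range <- j >= 1 & j < n_tau
  jj <- j[in_range]
  rows <- which(in_range)
  H0 <- H[cbind(rows, jj)]
  H1 <- H[cbind(rows, jj + 1L)]
  frac <- (target[in_range] - H0) / pmax(H1 - H0, 1e-300)
  tau[in_range] <- tau_grid[jj] + frac * (tau_grid[jj + 1L] - tau_grid[jj])
  tau[j == 0] <- 0 # only possible if H starts above target; H[,1]=0 forbids
  tau
}

## Conditional onset sampling from a homogeneous hazard curve for a vector
## of entry ages (the control arm). Piecewise-exponential interpolation.
sample_onset_vec <- function(curve, entry_ages, u) {
  logS <- log(pmax(curve$survival, .Machine$double.xmin))
  logS_entry <- stats::approx(curve$age, logS, xout = entry_ages)$y
  target <- logS_entry + log(u)
  if (diff(range(logS)) == 0) return(rep(NA_real_, length(entry_ages)))
  ages <- stats::approx(logS, curve$age, xout = target, ties = min)$y
  ages[target < min(logS)] <- NA_real_
  pmax(ages, entry_ages, na.rm = FALSE)
}

#' Simulate one randomized two-arm prevention trial
#'
#' Entry ages are drawn normal; onset ages are sampled left-truncated at
#' entry (control arm from the homogeneous baseline hazard, supplement arm
#' from the at-entry mutation-rate switch surface); diagnosis trails onset
#' by an exponential lag; events beyond follow-up are censored.
#'
#' @param design a [trial_design()].
#' @param control_curve `hazard_curve` under baseline mutation rate.
#' @param switch_surface `onset_switch_surface` for the supplement arm.
#' @return tibble of subjects: `arm`, `entry_age`, `time` (years on
#'   study), `event` (0/1).
#' @export
simulate_trial <- function(design, control_curve, switch_surface) {
  n <- design$n_per_arm
  entry <- stats::rnorm(2L * n, design$entry_age_mean, design$entry_age_sd)
  arm <- rep(c("control", "supplement"), each = n)
  onset <- rep(NA_real_, 2L * n)
  u <- stats::runif(2L * n)
  onset[1:n] <- sample_onset_vec(control_curve, entry[1:n], u[1:n])
  idx <- (n + 1L):(2L * n)
  H <- switch_cum_hazard(switch_surface, entry[idx])
  tau <- sample_from_cum_hazard(H, switch_surface$tau_grid, u[idx])
  onset[idx] <- entry[idx] + tau
  lag <- if (design$lag_mean > 0)
    stats::rexp(2L * n, rate = 1 / design$lag_mean) else 0
  diag_time <- onset - entry + lag # time on study at diagnosis
  event <- !is.na(diag_time) & diag_time <= design$follow_up
  time <- ifelse(event, diag_time, design$follow_up)
  tibble::tibble(arm = arm, entry_age = entry, time = pmax(time, 1e-9),
                 event = as.integer(event))
}

#' Cox proportional-hazards fit for a two-arm trial
#'
#' Single binary covariate (supplement vs control), Breslow tie handling,
#' Wald p-value. With events in only one arm the partial likelihood is
#' monotone: the hazard ratio is reported at a bounded cap and the
#' p-value from the score test, with `monotone = TRUE`.
#'
#' @param time event/censor times on study.
#' @param event 1 = event, 0 = censored.
#' @param arm factor or character; `"supplement"` is the exposed level.
#' @param hr_cap bound on the reported hazard ratio under monotone
#'   likelihood.
#' @return tibble: `hazard_ratio`, `p_value`, `events_control`,
#'   `events_supplement`, `n_control`, `n_supplement`, `monotone`.
#' @export
cox_fit <- function(time, event, arm, hr_cap = exp(15)) {
  exposed <- as.integer(arm == "supplement")
  ev_c <- sum(event[exposed == 0])
  ev_s <- sum(event[exposed == 1])
  if (ev_c + ev_s == 0)
    stop("no events in either arm; hazard ratio undefined", call. = FALSE)
  fit <- suppressWarnings(
    survival::coxph(survival::Surv(time, event) ~ exposed,
                    ties = "breslow"))
  s <- summary(fit)
  ## monotone partial likelihood: one arm without events, or a diverging
  ## coefficient (e.g. all exposed failures precede all control ones)
  monotone <- ((ev_c == 0) != (ev_s == 0)) ||
    !is.finite(s$coefficients[1, "Pr(>|z|)"]) ||
    abs(fit$coefficients) > log(hr_cap)
  if (monotone) {
    hr <- if (fit$coefficients < 0) 1 / hr_cap else hr_cap
    p <- unname(s$sctest["pvalue"])
  } else {
    hr <- unname(exp(fit$coefficients))
    p <- unname(s$coefficients[1, "Pr(>|z|)"])
  }
  tibble::tibble(hazard_ratio = hr, p_value = p,
                 events_control = ev_c, events_supplement = ev_s,
                 n_control = sum(exposed == 0),
                 n_supplement = sum(exposed == 1), monotone = monotone)
}

#' Run replicated trials for one parameter set
#'
#' All replicates share the same biology (hazard curve and switch
#' surface); each replicate redraws its virtual population. Replicates
#' use derived sub-seeds so the whole set is reproducible.
#'
#' @param design a [trial_design()].
#' @param control_curve,switch_surface as in [simulate_trial()].
#' @param seed integer seed.
#' @return tibble of per-replicate results with a `replicate` column.
#' @export
run_replicates <- function(design, control_curve, switch_surface, seed) {
  purrr::map_dfr(seq_len(design$n_replicates), function(r) {
    res <- local_seed(derive_seed(seed, paste0("replicate", r)), {
      subj <- simulate_trial(design, control_curve, switch_surface)
      cox_fit(subj$time, subj$event, subj$arm)
    })
    dplyr::bind_cols(tibble::tibble(replicate = r), res)
  })
}

#' Classify a parameter set's trial outcome
#'
#' Beneficial: at least two replicated trials with p-value below `alpha`
#' and a mean hazard ratio below 1; harmful: the same significance rule
#' with mean hazard ratio above 1; otherwise insignificant.
#'
#' @param results tibble with `hazard_ratio` and `p_value` columns
#'   (one row per replicate; at least two).
#' @param alpha significance level.
#' @return tibble: `label`, `n_significant`, `mean_hr`.
#' @export
classify_outcome <- function(results, alpha = 0.05) {
  if (nrow(results) < 2)
    stop("outcome classification requires at least 2 replicates",
         call. = FALSE)
  n_sig <- sum(results$p_value < alpha)
  mean_hr <- mean(results$hazard_ratio)
  label <- if (n_sig >= 2 && mean_hr < 1) "beneficial"
  else if (n_sig >= 2 && mean_hr > 1) "harmful"
  else "insignificant"
  tibble::tibble(label = label, n_significant = n_sig, mean_hr = mean_hr)
}
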