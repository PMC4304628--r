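#' Multistage cancer-onset model parameters
#'
#' The onset model is a birth-death-mutation branching process: cells with
#' k mutations divide symmetrically at rate `beta`, die at rate `delta`,
#' and divide with mutation at rate `mu` (moving a daughter to stage
#' k + 1); first-mutation cells are seeded from the healthy pool as a
#' Poisson process of rate `nu`, and the first cell to accumulate `K`
#' mutations is the first tumor cell. All rates are per year.
#'
#' @param nu seeding rate of first-mutation cells (events/year).
#' @param mu per-cell mutation rate (events/cell/year).
#' @param beta per-cell symmetric division rate (events/cell/year).
#' @param delta per-cell death rate (events/cell/year).
#' @param K integer number of mutations defining the first tumor cell.
#' @return an object of class `onset_parameters`.
#' @export
onset_parameters <- function(nu, mu, beta, delta, K = 4L) {
  stopifnot(nu >= 0, mu >= 0, beta >= 0, delta >= 0, K >= 1)
  structure(list(nu = nu, mu = mu, beta = beta, delta = delta,
                 K = as.integer(K)),
            class = "onset_parameters")
}

#' @export
print.onset_parameters <- function(x, ...) {
  cat(sprintf(
    "<onset_parameters: nu=%.4g, mu=%.4g, beta=%.4g, delta=%.4g, K=%d>\n",
    x$nu, x$mu, x$beta, x$delta, x$K))
  invisible(x)
}

#' Reference fitted onset parameters for prostate cancer
#'
#' The registry-fitted values used throughout as defaults: mutation rate
#' 3.65e-5, division rate 762.2 and death rate 762.0 events per cell per
#' year with K = 4 — cell divisions about twice per day and roughly 1e-7
#' mutations per generation. The seeding rate `nu` is not separately
#' reported; the default here is chosen so the model hazard is of
#' registry prostate-cancer magnitude in the trial-age range (several
#' hundred cases per 100,000 person-years in the seventh decade).
#'
#' @param nu seeding rate override (events/year).
#' @return `onset_parameters`.
#' @export
onset_reference_parameters <- function(nu = 280) {
  onset_parameters(nu = nu, mu = 3.65e-5, beta = 762.2, delta = 762.0,
                   K = 4L)
}

## The lineage extinction system, solved in the complement
## v_k = 1 - u_k (the probability that one k-mutant cell's lineage HAS
## produced a K-mutant within lineage age tau). The textbook form
##   du_k/dtau = beta u_k^2 + delta + mu u_k u_{k+1} - (beta+delta+mu) u_k
## is algebraically equivalent to
##   dv_k/dtau = (beta - delta) v_k - beta v_k^2 + mu v_{k+1} (1 - v_k)
## with v_K identically 1, but in the near-critical regime u_1 sits
## within ~1e-5 of 1 and the hazard nu*(1 - u_1) would be computed as a
## catastrophic cancellation; tracking v directly keeps full relative
## precision. An optional quadrature state accumulates integral(v_1).
extinction_rhs <- function(params, quadrature = FALSE) {
  b <- params$beta; d <- params$delta; m <- params$mu
  Km1 <- params$K - 1L
  function(t, v, p) {
    vv <- v[seq_len(Km1)]
    vp1 <- c(vv[-1], 1)
    dv <- (b - d) * vv - b * vv^2 + m * vp1 * (1 - vv)
    if (quadrature) list(c(dv, vv[1])) else list(dv)
  }
}

## v0 = 0 corresponds to a fresh lineage (u = 1).
solve_extinction <- function(params, tau_grid, v0 = NULL,
                             quadrature = FALSE) {
  Km1 <- params$K - 1L
  if (is.null(v0)) v0 <- rep(0, Km1)
  y0 <- if (quadrature) c(v0, 0) else v0
  sol <- deSolve::ode(y = y0, times = tau_grid,
                      func = extinction_rhs(params, quadrature),
                      parms = NULL, method = "lsoda",
                      rtol = 1e-10, atol = 1e-16, maxsteps = 100000L)
  if (attr(sol, "istate")[1] < 0)
    stop(sprintf("extinction solver failed (%d stages, last tau %.4g)",
                 Km1, sol[nrow(sol), 1]), call. = FALSE)
  sol
}

#' Lineage extinction probabilities
#'
#' For each stage k = 1..K-1, the probability \eqn{u_k(\tau)} that the
#' lineage of a single k-mutant cell produces no K-mutant cell within
#' lineage age \eqn{\tau}.
#'
#' @param params `onset_parameters` with `K >= 2`.
#' @param tau_grid increasing grid starting at 0 (years).
#' @return tibble with columns `tau` and `u1` .. `u{K-1}`.
#' @export
extinction_profile <- function(params, tau_grid) {
  stopifnot(inherits(params, "onset_parameters"))
  if (params$K < 2)
    stop("extinction profile requires K >= 2", call. = FALSE)
  stopifnot(tau_grid[1] == 0, !is.unsorted(tau_grid, strictly = TRUE))
  sol <- solve_extinction(params, tau_grid)
  sol[, -1] <- 1 - sol[, -1] # back to extinction probabilities u = 1 - v
  out <- tibble::as_tibble(as.data.frame(sol))
  names(out) <- c("tau", paste0("u", seq_len(params$K - 1L)))
  dplyr::mutate(out, dplyr::across(-tau, ~ pmin(pmax(.x, 0), 1)))
}

#' Age-dependent onset hazard and survival
#'
#' The hazard of cancer onset at age t under Poisson seeding of
#' first-mutation cells is \eqn{h(t) = \nu (1 - u_1(t))}, with onset-free
#' survival \eqn{S(t) = \exp(-\int_0^t h)}. The cumulative hazard is
#' accumulated inside the ODE solve rather than by quadrature of the
#' output grid.
#'
#' @param params `onset_parameters`.
#' @param ages increasing age grid starting at 0 (years).
#' @return tibble of class `hazard_curve` with columns `age`, `hazard`
#'   (events/year) and `survival`.
#' @export
onset_hazard <- function(params, ages) {
  stopifnot(inherits(params, "onset_parameters"))
  stopifnot(ages[1] == 0, !is.unsorted(ages, strictly = TRUE))
  if (params$K == 1L) {
    ## every seeded cell is already malignant
    out <- tibble::tibble(age = ages, hazard = params$nu,
                          survival = exp(-params$nu * ages))
  } else {
    sol <- solve_extinction(params, ages, quadrature = TRUE)
    v1 <- pmin(pmax(sol[, 2], 0), 1)
    Q <- sol[, ncol(sol)]
    out <- tibble::tibble(age = ages, hazard = params$nu * v1,
                          survival = exp(-params$nu * Q))
  }
  class(out) <- c("hazard_curve", class(out))
  out
}

#' Sample onset ages from a hazard curve, left-truncated at study entry
#'
#' Inverse-transform sampling from the conditional onset distribution
#' given no onset by `entry_age`. The survival curve is interpolated
#' log-linearly (piecewise-exponential hazard). Draws whose conditional
#' quantile falls beyond the curve horizon are returned as `NA`
#' (none-within-horizon).
#'
#' @param curve a `hazard_curve` from [onset_hazard()].
#' @param entry_age entry age (years), within the curve domain.
#' @param n number of draws.
#' @return numeric vector of onset ages, `NA` where onset does not occur
#'   within the curve horizon.
#' @export
sample_onset_age <- function(curve, entry_age, n = 1L) {
  stopifnot(inherits(curve, "hazard_curve"))
  stopifnot(entry_age >= min(curve$age), entry_age <= max(curve$age))
  logS <- log(pmax(curve$survival, .Machine$double.xmin))
  logS_entry <- stats::approx(curve$age, logS, xout = entry_age)$y
  if (!is.finite(logS_entry) || logS_entry <= log(.Machine$double.xmin) / 2)
    stop("survival is zero at entry age; conditioning impossible",
         call. = FALSE)
  target <- logS_entry + log(stats::runif(n))
  if (diff(range(logS)) == 0) # zero hazard everywhere: nothing ever occurs
    return(rep(NA_real_, n))
  ## logS is non-increasing in age; invert by interpolation
  ages <- stats::approx(logS, curve$age, xout = target, ties = min)$y
  ages[target < min(logS)] <- NA_real_
  idx <- which(ages <= entry_age)
  ages[idx] <- entry_age + 1e-9 # guard numeric ties at entry
  ages
}

#' Stochastic multistage-onset oracle
#'
#' Exact Gillespie simulation of the seeded birth-death-mutation process;
#' returns the age of the first K-mutant cell, or `NA` when none arises
#' by `t_end`. Used as an independent cross-check of [onset_hazard()].
#'
#' @param params `onset_parameters`.
#' @param t_end simulation horizon (years).
#' @param n number of independent realizations.
#' @param max_events event budget per realization (error when exceeded).
#' @return numeric vector of onset times with `NA` for no onset.
#' @export
stochastic_onset_oracle <- function(params, t_end, n = 1L,
                                    max_events = 1e8) {
  stopifnot(inherits(params, "onset_parameters"), t_end > 0, n >= 1)
  cpp_gillespie_onset(params$nu, params$mu, params$beta, params$delta,
                      params$K, t_end, as.integer(n), max_events)
}

#' Stochastic lineage-extinction oracle
#'
#' Fraction of single k-mutant founder lineages that produce no K-mutant
#' within `tau`; the Monte-Carlo counterpart of [extinction_profile()].
#'
#' @param params `onset_parameters` with `K >= 2`.
#' @param tau lineage age (years).
#' @param n number of lineages.
#' @param k0 founder stage (default 1).
#' @param max_events event budget per lineage.
#' @return logical vector, `TRUE` where the lineage produced a K-mutant.
#' @export
lineage_onset_oracle <- function(params, tau, n, k0 = 1L,
                                 max_events = 1e8) {
  stopifnot(inherits(params, "onset_parameters"))
  cpp_gillespie_lineage(params$mu, params$beta, params$delta, params$K,
                        as.integer(k0), tau, as.integer(n), max_events)
}
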