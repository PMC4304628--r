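#' Build or read an age-binned incidence table
#'
#' Registry-style (SEER-like) age-specific incidence: non-overlapping,
#' ordered age bins `[age_low, age_high)` with rates per 100,000
#' person-years and optional person-year exposures.
#'
#' @param age_low,age_high bin edges (years).
#' @param rate_per_100k incidence rate per 100,000 person-years.
#' @param person_years optional exposure per bin.
#' @return tibble of class `incidence_table`.
#' @export
incidence_table <- function(age_low, age_high, rate_per_100k,
                            person_years = NA_real_) {
  tbl <- tibble::tibble(age_low = age_low, age_high = age_high,
                        rate_per_100k = rate_per_100k,
                        person_years = person_years)
  if (any(tbl$age_high <= tbl$age_low))
    stop("age bins must have age_high > age_low", call. = FALSE)
  if (is.unsorted(tbl$age_low, strictly = TRUE) ||
      any(utils::head(tbl$age_high, -1) > tbl$age_low[-1]))
    stop("age bins must be ordered and non-overlapping", call. = FALSE)
  if (any(tbl$rate_per_100k < 0))
    stop("rates must be non-negative", call. = FALSE)
  class(tbl) <- c("incidence_table", class(tbl))
  tbl
}

#' @rdname incidence_table
#' @param path CSV file with columns `age_low`, `age_high`,
#'   `rate_per_100k` and optionally `person_years`.
#' @export
read_incidence_csv <- function(path) {
  df <- utils::read.csv(path)
  incidence_table(df$age_low, df$age_high, df$rate_per_100k,
                  if ("person_years" %in% names(df)) df$person_years
                  else NA_real_)
}

#' @rdname incidence_table
#' @param table an `incidence_table`.
#' @export
write_incidence_csv <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

## Model-predicted rate per 100k for each bin: hazard averaged over the
## bin on a fine sub-grid (how registry person-year rates are tabulated).
model_bin_rates <- function(params, table, points_per_bin = 9L) {
  grids <- lapply(seq_len(nrow(table)), function(i)
    seq(table$age_low[i], table$age_high[i], length.out = points_per_bin))
  ages <- sort(unique(c(0, unlist(grids))))
  curve <- onset_hazard(params, ages)
  h <- stats::approx(curve$age, curve$hazard, xout = unlist(grids))$y
  idx <- rep(seq_len(nrow(table)), each = points_per_bin)
  as.numeric(tapply(h, idx, mean)) * 1e5
}

#' Declare which onset parameters an incidence fit may vary
#'
#' The fit works in log10 space over the seeding rate `nu`, mutation rate
#' `mu`, net growth `growth` = beta - delta, and division rate `beta`
#' (with delta recovered as beta - growth). Any subset can be frozen at
#' fixed values, e.g. to fit only the cell-level rates while holding the
#' seeding rate.
#'
#' @param free character subset of `c("nu","mu","growth","beta")`.
#' @param fixed named list of fixed values for the non-free quantities.
#' @export
onset_fit_spec <- function(free = c("nu", "mu", "growth", "beta"),
                           fixed = list()) {
  all <- c("nu", "mu", "growth", "beta")
  free <- match.arg(free, all, several.ok = TRUE)
  need <- setdiff(all, free)
  if (!all(need %in% names(fixed)))
    stop("fixed values required for: ",
         paste(setdiff(need, names(fixed)), collapse = ", "), call. = FALSE)
  structure(list(free = free, fixed = fixed), class = "onset_fit_spec")
}

#' Fit multistage onset parameters to an incidence table
#'
#' Minimizes the person-year-weighted sum of squared differences between
#' the bin-averaged model hazard (per 100,000 person-years) and the
#' observed rates, by derivative-free local search from a fixed number of
#' log-space multi-starts. The seeding/mutation composite
#' \eqn{\nu \mu^{K-1}} and the net growth rate \eqn{\beta - \delta} are
#' well identified; \eqn{\beta} and \eqn{\delta} individually sit on a
#' near-flat ridge, which the returned `ridge` profile makes explicit
#' rather than hiding behind a single point estimate.
#'
#' @param table an `incidence_table` with at least 3 bins.
#' @param K number of mutation stages (fixed during the fit).
#' @param fit_spec an [onset_fit_spec()].
#' @param n_starts number of log-space multi-starts.
#' @param seed seed making the multi-start draw deterministic.
#' @param maxit Nelder-Mead iteration cap per start.
#' @param n_polish restarted-simplex polish rounds applied to the best
#'   start (each restart re-expands the collapsed simplex; more rounds
#'   buy precision in the objective's flat directions).
#' @return object of class `onset_fit`: fitted `params`, `objective`,
#'   per-bin `residuals`, multi-start table `starts`, and `ridge`
#'   diagnostic (objective along beta + c, delta + c).
#' @export
fit_to_incidence <- function(table, K = 4L, fit_spec = onset_fit_spec(),
                             n_starts = 16L, seed = 1L, maxit = 400L,
                             n_polish = 10L) {
  stopifnot(inherits(table, "incidence_table"))
  if (nrow(table) < 3)
    stop("incidence table needs at least 3 bins", call. = FALSE)
  weights <- if (all(is.finite(table$person_years)))
    table$person_years / sum(table$person_years)
  else rep(1, nrow(table))

  ## The seeding rate nu enters the hazard multiplicatively, so when it
  ## is free its weighted-least-squares optimum is closed-form for any
  ## shape parameters ("profiling"); this removes the exactly-degenerate
  ## amplitude direction from the search and identifies the composite
  ## nu * mu^(K-1) through the amplitude.
  profile_nu <- "nu" %in% fit_spec$free
  opt_names <- setdiff(fit_spec$free, if (profile_nu) "nu" else character())
  y <- table$rate_per_100k
  assemble <- function(theta, nu_value = NULL) {
    vals <- as.list(10^theta)
    names(vals) <- opt_names
    vals <- c(vals, fit_spec$fixed)
    if (profile_nu) vals$nu <- if (is.null(nu_value)) 1 else nu_value
    delta <- vals$beta - vals$growth
    if (delta < 0) return(NULL)
    onset_parameters(vals$nu, vals$mu, vals$beta, delta, K)
  }
  profiled_scale <- function(pred1) {
    den <- sum(weights * pred1^2)
    if (den <= 0) return(0)
    max(0, sum(weights * pred1 * y) / den)
  }
  objective <- function(theta) {
    p <- assemble(theta)
    if (is.null(p)) return(1e12)
    pred <- tryCatch(model_bin_rates(p, table), error = function(e) NULL)
    if (is.null(pred)) return(1e12)
    if (profile_nu) pred <- profiled_scale(pred) * pred
    sum(weights * (pred - y)^2)
  }

  ranges <- list(mu = c(-7, -3), growth = c(-2, 0.5), beta = c(0, 4))
  starts <- local_seed(seed, {
    m <- vapply(opt_names, function(q)
      stats::runif(n_starts, ranges[[q]][1], ranges[[q]][2]), numeric(n_starts))
    matrix(m, nrow = n_starts, dimnames = list(NULL, opt_names))
  })

  if (length(opt_names) == 0) {
    best <- list(par = numeric(0), value = objective(numeric(0)))
    values <- best$value
  } else {
    runs <- lapply(seq_len(n_starts), function(i) {
      fit <- stats::optim(starts[i, ], objective, method = "Nelder-Mead",
                          control = list(maxit = maxit, reltol = 1e-12))
      list(par = fit$par, value = fit$value, convergence = fit$convergence)
    })
    values <- vapply(runs, `[[`, numeric(1), "value")
    best <- runs[[which.min(values)]]
    ## polish the winner with restarted simplices: single Nelder-Mead
    ## runs collapse prematurely in this objective's flat directions
    ## improvements arrive in bursts as the re-expanded simplex re-orients
    ## down the valley, so run every round rather than stopping at the
    ## first stall
    for (i in seq_len(n_polish)) {
      prev <- best
      best <- stats::optim(best$par, objective, method = "Nelder-Mead",
                           control = list(maxit = 800, reltol = 1e-16))
      if (best$value >= prev$value && i > 2 &&
          identical(best$par, prev$par)) break
    }
  }
  params <- assemble(best$par)
  if (profile_nu) {
    s <- profiled_scale(model_bin_rates(params, table))
    params <- assemble(best$par, nu_value = s)
  }
  pred <- model_bin_rates(params, table)

  ## ridge profile: shift beta and delta together, net growth unchanged
  offsets <- c(-0.05, -0.02, 0, 0.02, 0.05) * params$beta
  offsets <- offsets[params$delta + offsets >= 0]
  ridge <- tibble::tibble(
    offset = offsets,
    objective = vapply(offsets, function(c0) {
      p2 <- onset_parameters(params$nu, params$mu, params$beta + c0,
                             params$delta + c0, K)
      sum(weights * (model_bin_rates(p2, table) - table$rate_per_100k)^2)
    }, numeric(1)))
  ## flat relative to the magnitude of the data, not the (possibly
  ## near-zero) best objective: a few-percent joint shift of beta and
  ## delta changes the fit by a vanishing fraction of the signal
  data_scale <- sum(weights * table$rate_per_100k^2)
  ridge_flat <- diff(range(ridge$objective)) <= 0.01 * data_scale

  structure(list(
    params = params,
    objective = best$value,
    residuals = tibble::tibble(
      age_low = table$age_low, age_high = table$age_high,
      observed = table$rate_per_100k, fitted = pred,
      weight = weights, residual = pred - table$rate_per_100k),
    starts = tibble::tibble(start = seq_along(values), value = values),
    ridge = ridge, ridge_flat = ridge_flat,
    fit_spec = fit_spec, K = as.integer(K), seed = seed),
    class = "onset_fit")
}

#' @export
print.onset_fit <- function(x, ...) {
  cat(sprintf("<onset_fit: objective %.6g%s>\n", x$objective,
              if (x$ridge_flat) ", beta/delta ridge nearly flat" else ""))
  print(x$params)
  invisible(x)
}
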