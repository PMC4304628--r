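#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an incidence fit
#'
#' @param x an `onset_fit`.
#' @param ... unused.
#' @return tibble of parameter estimates (one row per rate, plus the
#'   identifiable composites: seeding-mutation composite
#'   nu * mu^(K-1) and net growth beta - delta).
#' @export
tidy.onset_fit <- function(x, ...) {
  p <- x$params
  tibble::tibble(
    term = c("nu", "mu", "beta", "delta", "K",
             "nu_mu_composite", "net_growth"),
    estimate = c(p$nu, p$mu, p$beta, p$delta, p$K,
                 p$nu * p$mu^(p$K - 1L), p$beta - p$delta))
}

#' @rdname tidy.onset_fit
#' @export
glance.onset_fit <- function(x, ...) {
  tibble::tibble(objective = x$objective, n_bins = nrow(x$residuals),
                 ridge_flat = x$ridge_flat, K = x$K,
                 n_starts = nrow(x$starts), seed = x$seed)
}

#' Tidy a boosted-tree trial classifier
#'
#' @param x a `trial_classifier`.
#' @param ... unused.
#' @return the relative-influence table (see [relative_influence()]).
#' @export
tidy.trial_classifier <- function(x, ...) relative_influence(x)

#' @rdname tidy.trial_classifier
#' @export
glance.trial_classifier <- function(x, ...) {
  tibble::tibble(n_features = length(x$features),
                 nrounds = x$config$nrounds,
                 max_depth = x$config$max_depth, eta = x$config$eta,
                 class_weight = x$config$class_weight,
                 threshold = x$threshold)
}
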