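#' Marginal log-likelihood of replicate counts at one site
#'
#' The N-mixture observation model for one species, site, and period: latent
#' abundance `N ~ Poisson(lambda)` and each within-period replicate count an
#' independent `Binomial(N, p)` thinning of the same N. The discrete latent
#' abundance is summed out over `N = max(y), ..., nmax` in log space:
#' `log sum_N Poisson(N; lambda) prod_k Binomial(y_k; N, p)`.
#'
#' For a single replicate this equals the Poisson thinning identity
#' `log Poisson(y; lambda * p)` up to truncation error.
#'
#' @param y integer vector of replicate counts.
#' @param lambda positive Poisson mean of the latent abundance.
#' @param p detection probability in (0, 1].
#' @param nmax truncation bound for the latent abundance; must be >= max(y).
#' @return the marginal log-likelihood (a scalar).
#' @export
marginal_loglik_site <- function(y, lambda, p, nmax) {
  stopifnot(length(lambda) == 1L, lambda > 0, p > 0, p <= 1, all(y >= 0))
  ymax <- max(y)
  if (nmax < ymax)
    stop("nmax must be at least max(y)", call. = FALSE)
  N <- ymax:nmax
  terms <- stats::dpois(N, lambda, log = TRUE)
  for (k in seq_along(y))
    terms <- terms + stats::dbinom(y[k], N, p, log = TRUE)
  logsumexp(terms)
}

#' Expected abundance from the linear predictor
#'
#' Evaluates `lambda = exp(alpha + sum_m beta_m E_m + phi)` for one species,
#' site, and period. Under the `"fixed50"` compositional parametrization the
#' land-cover proportions must sum to one (closure) and there is no
#' intercept, so each `beta_m` is the log expected abundance were type m to
#' cover the whole buffer; supplying a nonzero `alpha` is an error there.
#' The drift term `phi` applies in Period 2 only (pass `phi = 0` for
#' Period 1).
#'
#' @param beta numeric vector of habitat effects for this species (length M).
#' @param E land-cover proportions (length M) at the radius relevant to the
#'   variant.
#' @param alpha species intercept (multiscale variant only).
#' @param phi species drift term (Period 2 only).
#' @param variant `"multiscale"` or `"fixed50"`.
#' @param tol closure tolerance for the fixed50 composition check.
#' @return lambda, the Poisson mean.
#' @export
linear_predictor <- function(beta, E, alpha = 0, phi = 0,
                             variant = c("multiscale", "fixed50"),
                             tol = 1e-6) {
  variant <- match.arg(variant)
  stopifnot(length(beta) == length(E))
  if (variant == "fixed50") {
    if (alpha != 0)
      stop("fixed50 variant has no intercept (compositional parametrization)",
           call. = FALSE)
    if (abs(sum(E) - 1) > tol)
      stop("fixed50 requires a closed composition: proportions must sum to 1",
           call. = FALSE)
  }
  exp(alpha + sum(beta * E) + phi)
}
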