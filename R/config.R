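#' Pipeline configuration
#'
#' Bundles the tunables shared across pipeline stages: scale-selection method,
#' MCMC settings, latent-abundance truncation used by the marginal likelihood,
#' the credible-interval level, the tie-break rule for scale selection, and
#' the master random seed. Values can be loaded from a YAML-like key:value
#' text file and overridden by arguments.
#'
#' @param method scale-selection method: `"pearson"`, `"spearman"`, `"brt"`,
#'   or `"fixed50"` (always the smallest radius).
#' @param chains,warmup,sampling MCMC settings; defaults 4 chains, 1500
#'   warmup, 500 sampling iterations per chain.
#' @param nmax_extra latent-abundance truncation margin: `Nmax = max(y) +
#'   nmax_extra` in [marginal_loglik_site()] checks.
#' @param cri_level credible-interval mass, default 0.89.
#' @param tie_break `"smallest"` radius wins ties (most local scale).
#' @param seed master seed.
#' @return a list of class `sft_config`.
#' @export
sft_config <- function(method = c("pearson", "spearman", "brt", "fixed50"),
                       chains = 4L, warmup = 1500L, sampling = 500L,
                       nmax_extra = 50L, cri_level = 0.89,
                       tie_break = "smallest", seed = 1L) {
  method <- match.arg(method)
  stopifnot(chains >= 1, warmup >= 0, sampling >= 1,
            cri_level > 0, cri_level < 1, nmax_extra >= 0)
  structure(list(method = method, chains = as.integer(chains),
                 warmup = as.integer(warmup), sampling = as.integer(sampling),
                 nmax_extra = as.integer(nmax_extra), cri_level = cri_level,
                 tie_break = tie_break, seed = as.integer(seed)),
            class = "sft_config")
}

#' @export
print.sft_config <- function(x, ...) {
  cat("sft_config:\n")
  for (nm in names(x)) cat(sprintf("  %-10s %s\n", nm, x[[nm]]))
  invisible(x)
}
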