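#' Rate constants of the phage-lysogen community model
#'
#' Bundles the five rate constants shared by every strain of the community
#' (per-strain heterogeneity is layered on top via [jitter_parameters()] or
#' per-strain overrides in [community_config()]). Time is measured in
#' bacterial generations, so `alpha = 1` means lysogens double their
#' (exponential-growth) biomass scale once per unit time.
#'
#' @param alpha Lysogen growth rate (1/generation).
#' @param gamma Spontaneous prophage induction rate (1/generation).
#' @param delta Phage death or outflow rate (1/generation).
#' @param k Adsorption (infection) rate constant
#'   (volume cell^-1 generation^-1).
#' @param b Burst size: phage released per lysis event (dimensionless, >= 1).
#' @param allow_nongrowing If `TRUE`, permit `alpha <= gamma` (a community
#'   whose lysogens cannot grow) with a warning instead of an error.
#'
#' @return An object of class `"model_parameters"`: a named list with fields
#'   `alpha`, `gamma`, `delta`, `k`, `b`.
#' @seealso [default_parameters()] for the package defaults.
#' @export
#' @examples
#' p <- model_parameters(alpha = 1, gamma = 1e-3, delta = 1, k = 1e-9, b = 10)
#' p$b
model_parameters <- function(alpha, gamma, delta, k, b,
                             allow_nongrowing = FALSE) {
  vals <- c(alpha = alpha, gamma = gamma, delta = delta, k = k, b = b)
  if (!all(is.finite(vals)))
    stop("all model parameters must be finite numbers", call. = FALSE)
  if (any(vals <= 0))
    stop("all model parameters must be strictly positive; got ",
         paste(names(vals)[vals <= 0], collapse = ", "), " <= 0",
         call. = FALSE)
  if (b < 1)
    stop("burst size b must be >= 1", call. = FALSE)
  if (alpha <= gamma) {
    msg <- sprintf(
      "alpha (%g) <= gamma (%g): lysogen populations cannot grow", alpha, gamma)
    if (allow_nongrowing) warning(msg, call. = FALSE)
    else stop(msg, "; set allow_nongrowing = TRUE to override", call. = FALSE)
  }
  structure(list(alpha = alpha, gamma = gamma, delta = delta, k = k, b = b),
            class = "model_parameters")
}

#' Default model parameters
#'
#' The package default rate constants, in generation-based units:
#' `alpha = 1`, `gamma = 1e-3`, `delta = 1`, `k = 1e-9`, `b = 10`.
#'
#' These describe a temperate-phage community under conditions of modest
#' burst size and slow spontaneous induction, and place the
#' symmetric-fixed-point densities near 1e8-1e9 cells per unit volume.
#' Under these defaults a community of three immunity classes with a
#' single temperate strain each exhibits sustained chaos (largest Lyapunov
#' exponent around +0.05 per generation), the phage-to-lysogen ratios of
#' temperate strains bunch at troughs about a factor 2 below
#' `b*gamma/delta`, and the obligate lytic member of a two-class community
#' usually - but not always - fluctuates to effective extinction. Note
#' that `k` only sets the density
#' scale: substituting `P -> k P`, `L -> k L` removes `k` from the equations,
#' so the qualitative dynamics depend only on `(alpha, gamma, delta, b)`.
#'
#' @return A [model_parameters()] object; identical on every call.
#' @export
#' @examples
#' default_parameters()
default_parameters <- function() {
  model_parameters(alpha = 1, gamma = 1e-3, delta = 1, k = 1e-9, b = 10)
}

#' @export
print.model_parameters <- function(x, ...) {
  cat("Phage-lysogen model parameters (per generation):\n")
  cat(sprintf("  alpha = %g  (lysogen growth)\n", x$alpha))
  cat(sprintf("  gamma = %g  (spontaneous induction)\n", x$gamma))
  cat(sprintf("  delta = %g  (phage death/outflow)\n", x$delta))
  cat(sprintf("  k     = %g  (adsorption, volume/cell/generation)\n", x$k))
  cat(sprintf("  b     = %g  (burst size)\n", x$b))
  invisible(x)
}

is_model_parameters <- function(x) inherits(x, "model_parameters")
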