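#' Parameters of the ancestral-change-plus-split demographic model
#'
#' Backward in time: two populations of relative sizes `nu1F` and `nu2Y`
#' merge at time `Td` into an ancestral population of relative size `nua`,
#' which reverts to the reference size `Na` at time `Ta`. Times are in units
#' of 2*Na generations; relative sizes are multiples of `Na`.
#'
#' @param nua relative ancestral size between `Ta` and `Td`.
#' @param Ta time the ancestral size change started (2*Na generations).
#' @param Td split (divergence) time; must satisfy `Ta > Td >= 0`.
#' @param nu1F,nu2Y relative sizes of the two daughter populations.
#' @param Na reference ancestral effective size in diploid individuals.
#' @param mu mutation rate per generation per site.
#' @param g generation time in years.
#' @return An object of class `demographic_params`.
#' @export
demographic_params <- function(nua = 1, Ta = 0.5, Td = 0.05,
                               nu1F = 1, nu2Y = 1,
                               Na = 22727, mu = 1.1e-8, g = 5) {
  if (any(c(nua, nu1F, nu2Y, Na) <= 0)) stop("population sizes must be > 0")
  if (Td < 0) stop("Td must be >= 0")
  if (Ta <= Td) stop("size change must predate the split: Ta > Td required")
  if (mu < 0 || g <= 0) stop("mu >= 0 and g > 0 required")
  structure(list(nua = nua, Ta = Ta, Td = Td, nu1F = nu1F, nu2Y = nu2Y,
                 Na = Na, mu = mu, g = g),
            class = "demographic_params")
}

#' @export
print.demographic_params <- function(x, ...) {
  cat(sprintf(
    "demography: Na=%g diploids; nua=%g on [Td,Ta)=[%g,%g); split sizes nu1F=%g nu2Y=%g\n",
    x$Na, x$nua, x$Td, x$Ta, x$nu1F, x$nu2Y))
  cat(sprintf("  mu=%g /gen/site, g=%g y; theta/site = %g\n",
              x$mu, x$g, 4 * x$Na * x$mu))
  invisible(x)
}
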