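#' Reference variance components of the homoscedastic base model
#'
#' Derives the homogeneous ("reference") variance components implied by a
#' trait mean, a coefficient of variation and a heritability. The phenotypic
#' variance is fixed by the constant-CV assumption,
#' \eqn{\sigma_p^2 = (CV \cdot \mu)^2}, and is split into an additive genetic
#' part \eqn{\sigma_u^2 = h^2 \sigma_p^2} and a residual part
#' \eqn{\sigma_e^2 = (1 - h^2)\sigma_p^2}. These components parameterise the
#' homoscedastic base draw before any scale-effect transformation is applied.
#'
#' @param mu Trait mean, in trait units. Must be strictly positive.
#' @param cv Coefficient of variation (dimensionless, > 0).
#' @param h2 Heritability, strictly between 0 and 1.
#'
#' @return A one-row tibble with columns `sigma_p2`, `sigma_u2`, `sigma_e2`
#'   (variances, trait units squared) and `sigma_p`, `sigma_u`, `sigma_e`
#'   (their square roots, trait units).
#'
#' @examples
#' derive_variance_components(mu = 100, cv = 0.15, h2 = 0.15)
#' @export
derive_variance_components <- function(mu, cv, h2) {
  check_positive(mu, "mu")
  check_positive(cv, "cv")
  check_proportion(h2, "h2")
  sigma_p2 <- (cv * mu)^2
  sigma_u2 <- h2 * sigma_p2
  sigma_e2 <- (1 - h2) * sigma_p2
  tibble(
    sigma_p2 = sigma_p2,
    sigma_u2 = sigma_u2,
    sigma_e2 = sigma_e2,
    sigma_p = sqrt(sigma_p2),
    sigma_u = sqrt(sigma_u2),
    sigma_e = sqrt(sigma_e2)
  )
}
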