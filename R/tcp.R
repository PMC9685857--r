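#' Radiobiological parameters for the Poisson TCP model
#'
#' Linear-quadratic cell kill delivered in equal fractions, with clonogens
#' distributed at uniform density. The defaults (`alpha` 0.15 /Gy,
#' `alpha/beta` 1.5 Gy, 1e7 clonogens/cc) are literature-typical prostate
#' values supplied as documented placeholders — they are not calibrated to
#' any specific clinical dataset, and absolute TCP values depend strongly on
#' them; comparisons across plans evaluated with one fixed set are the
#' intended use. Set `sigma_alpha > 0` to average the TCP over a normal
#' population distribution of `alpha` (discretized, renormalized).
#'
#' @param alpha LQ alpha in 1/Gy; > 0.
#' @param alpha_beta Alpha/beta ratio in Gy (sets `beta = alpha/alpha_beta`);
#'   `Inf` for a pure linear model.
#' @param n_fractions Number of equal fractions; >= 1.
#' @param clonogen_density Clonogens per cc; > 0.
#' @param sigma_alpha Population SD of alpha in 1/Gy; 0 disables averaging.
#' @return An object of class `tcp_parameters`.
#' @export
tcp_parameters <- function(alpha = 0.15, alpha_beta = 1.5, n_fractions = 27,
                           clonogen_density = 1e7, sigma_alpha = 0) {
  if (!(alpha > 0)) stop("alpha must be positive")
  if (!(alpha_beta > 0)) stop("alpha_beta must be positive")
  if (n_fractions < 1) stop("n_fractions must be >= 1")
  if (!(clonogen_density > 0)) stop("clonogen_density must be positive")
  if (sigma_alpha < 0) stop("sigma_alpha must be >= 0")
  structure(list(alpha = alpha, beta = if (is.finite(alpha_beta)) alpha / alpha_beta else 0,
                 alpha_beta = alpha_beta, n_fractions = as.integer(n_fractions),
                 clonogen_density = clonogen_density, sigma_alpha = sigma_alpha),
            class = "tcp_parameters")
}

#' @export
print.tcp_parameters <- function(x, ...) {
  cat(sprintf("<tcp_parameters> alpha %.3g /Gy, beta %.3g /Gy^2 (a/b %.3g Gy), %d fractions, rho %.3g /cc",
              x$alpha, x$beta, x$alpha_beta, x$n_fractions, x$clonogen_density))
  if (x$sigma_alpha > 0) cat(sprintf(", sigma_alpha %.3g", x$sigma_alpha))
  cat("\n  (defaults are literature-typical placeholders, not fit to any cohort)\n")
  invisible(x)
}

#' Linear-quadratic surviving fraction under fractionated delivery
#'
#' `SF(D) = exp(-alpha*D - beta*d*D)` with dose per fraction
#' `d = D / n_fractions`: 1 at zero dose, strictly decreasing in `D`, and
#' independent of fractionation when `beta = 0`.
#'
#' @param total_dose Total dose in Gy; >= 0 (vectorized).
#' @param params A [tcp_parameters()].
#' @param alpha Optional override of `params$alpha` (used for population
#'   averaging).
#' @return Surviving fraction(s) in (0, 1].
#' @export
surviving_fraction <- function(total_dose, params = tcp_parameters(), alpha = NULL) {
  stopifnot(inherits(params, "tcp_parameters"))
  if (any(total_dose < 0)) stop("total_dose must be >= 0")
  a <- if (is.null(alpha)) params$alpha else alpha
  d_frac <- total_dose / params$n_fractions
  exp(-a * total_dose - params$beta * d_frac * total_dose)
}

#' Poisson tumour control probability from a differential DVH
#'
#' The expected number of surviving clonogens is accumulated over dose bins,
#' `N = sum_b rho * v_b * SF(D_b)` with `v_b` the absolute bin volume (cc)
#' and `D_b` the bin-centre dose, and `TCP = exp(-N)`. With
#' `sigma_alpha > 0` the TCP is averaged over a discretized normal
#' distribution of `alpha` (49 nodes over +/- 3.5 SD, weights renormalized,
#' negative alphas truncated).
#'
#' @param dvh A [compute_dvh()] result (absolute volumes in cc).
#' @param params A [tcp_parameters()].
#' @param n0 Optional total clonogen count for the structure; overrides
#'   `clonogen_density * volume`.
#' @return An object of class `tcp_result`: `tcp`, `expected_survivors`,
#'   and a per-bin contribution table.
#' @export
tcp_poisson <- function(dvh, params = tcp_parameters(), n0 = NULL) {
  stopifnot(inherits(dvh, "dvh"), inherits(params, "tcp_parameters"))
  occ <- dvh$diff_cc > 0
  if (!any(occ)) stop("empty DVH")
  d_b <- (dvh$bin_lo[occ] + dvh$bin_hi[occ]) / 2
  v_b <- dvh$diff_cc[occ]
  rho <- if (is.null(n0)) params$clonogen_density else {
    if (!(n0 > 0)) stop("n0 must be positive")
    n0 / dvh$total_cc
  }
  survivors_for <- function(a) sum(rho * v_b * surviving_fraction(d_b, params, alpha = a))
  if (params$sigma_alpha > 0) {
    z <- seq(-3.5, 3.5, length.out = 49)
    alphas <- params$alpha + params$sigma_alpha * z
    keep <- alphas > 0
    w <- stats::dnorm(z)[keep]
    w <- w / sum(w)
    n_exp <- vapply(alphas[keep], survivors_for, numeric(1))
    tcp <- sum(w * exp(-n_exp))
    n_mean <- sum(w * n_exp)
  } else {
    n_mean <- survivors_for(params$alpha)
    tcp <- exp(-n_mean)
  }
  structure(list(
    structure = dvh$structure, tcp = tcp, expected_survivors = n_mean,
    bins = data.frame(dose_gy = d_b, volume_cc = v_b,
                      sf = surviving_fraction(d_b, params),
                      survivors = rho * v_b * surviving_fraction(d_b, params)),
    params = params
  ), class = "tcp_result")
}

#' @export
print.tcp_result <- function(x, ...) {
  cat(sprintf("<tcp_result> %s: TCP = %.4f (expected survivors %.3g)\n",
              x$structure, x$tcp, x$expected_survivors))
  invisible(x)
}
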