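## Diffusion engine.
##
## All integrals factor as (Beta kernel) x (smooth exponential of a
## quadratic in pa) and are evaluated with the Gauss-Jacobi rule of
## quadrature.R.  With c = 2(2 - alpha) N mtilde, the fixation kernel is
##   G(pa) = pa^(-c Qa) (1 - pa)^(-c QA) * exp(B2 pa^2 + B1 pa)
## where B2 = 2 (1-alpha)(1-2h) N sd and
##       B1 = 2 N ((alpha + 2(1-alpha) h) sd - 2 (1-alpha) sh_signed),
## and the stationary density is
##   phi(pa) proportional to pa^(c Qa - 1) (1 - pa)^(c QA - 1)
##                           * exp(-B2 pa^2 - B1 pa).
## G is integrable iff c * max(Qa, QA) < 1; phi is normalisable iff
## c > 0 (i.e. mtilde > 0).

## shared coefficients
diffusion_coefs <- function(object) {
  p <- object$params
  c_mig <- 2 * (2 - p$alpha) * p$N * object$derived$mtilde
  B2 <- 2 * (1 - p$alpha) * (1 - 2 * p$h) * p$N * p$sd
  B1 <- 2 * p$N * ((p$alpha + 2 * (1 - p$alpha) * p$h) * p$sd -
                     2 * (1 - p$alpha) * object$sh_signed)
  list(c = c_mig, aQ = c_mig * p$Qa, bQ = c_mig * (1 - p$Qa),
       B2 = B2, B1 = B1)
}

check_integrable <- function(object) {
  k <- diffusion_coefs(object)
  if (k$aQ >= 1 || k$bQ >= 1) {
    end <- if (k$aQ >= 1 && k$bQ >= 1) "both endpoints"
    else if (k$aQ >= 1) "pa = 0" else "pa = 1"
    stop("nonintegrable kernel: 2(2-alpha)*N*mtilde*Q reaches ",
         signif(max(k$aQ, k$bQ), 4), " >= 1 at ", end,
         "; reduce migration (the fixation integrals diverge)",
         call. = FALSE)
  }
  invisible(k)
}

#' Diffusion kernel G(pa)
#'
#' The kernel `G(pa) = exp(-2 int M/V dpa)` of the fixation-probability
#' diffusion, where `M` is the systematic allele-frequency change
#' ([systematic_change()]) and `V = pa(1-pa)/(2 Ne)` the drift variance.
#' In closed form,
#' `G(pa) = pa^{-c Qa} (1-pa)^{-c QA} exp(B2 pa^2 + B1 pa)` with
#' `c = 2(2-alpha) N mtilde`,
#' `B2 = 2(1-alpha)(1-2h) N sd` and
#' `B1 = 2N((alpha + 2(1-alpha)h) sd - 2(1-alpha) sh)`
#' (`sh` signed by scheme).  Without migration the power-law factors are
#' 1 and `G` is a pure exponential of a quadratic.
#'
#' @param pa Allele frequency in `(0, 1)` (vectorised).
#' @param object A [phasesel] model.
#' @return `G(pa)`, same length as `pa`.
#' @export
g_kernel <- function(pa, object) {
  k <- diffusion_coefs(object)
  pa^(-k$aQ) * (1 - pa)^(-k$bQ) * exp(k$B2 * pa^2 + k$B1 * pa)
}

#' Fixation probability of the mutant allele
#'
#' `phi(p0) = int_0^p0 G / int_0^1 G` for the mutant allele starting at
#' frequency `p0`, under the model's selection scheme, mating system and
#' migration.  With `mtilde = 0` and no selection this reduces to `p0`.
#'
#' @param p0 Initial mutant frequency; defaults to the model's `p0`.
#' @param object A [phasesel] model.
#' @param n Quadrature nodes.
#' @return The fixation probability in `[0, 1]`.
#' @examples
#' fixation_probability(object = phasesel(sh = 0.03, N = 30, p0 = 1/60))
#' @export
fixation_probability <- function(p0 = object$params$p0, object, n = 120) {
  stopifnot(p0 >= 0, p0 <= 1)
  if (p0 == 0) return(0)
  if (p0 == 1) return(1)
  k <- check_integrable(object)
  ## rescale the exponential to avoid overflow for large |B1| + |B2|
  shift <- max(k$B1 + k$B2, 0)
  smooth_s <- function(t) exp(k$B2 * t^2 + k$B1 * t - shift)
  num <- beta_kernel_integral_partial(smooth_s, -k$aQ, -k$bQ, p0, n = n)
  den <- beta_kernel_integral(smooth_s, -k$aQ, -k$bQ, n = n)
  val <- num / den
  min(max(val, 0), 1)
}

#' Neutral fixation probability
#'
#' `phi0(p0)` for a neutral allele (`sh = sd = 0`) under the same mating
#' system and migration.  With migration the kernel is a Beta kernel and
#' `phi0` is evaluated exactly through the regularised incomplete Beta
#' function `pbeta(p0, 1 - c Qa, 1 - c QA)`; without migration
#' `phi0(p0) = p0`.
#'
#' @inheritParams fixation_probability
#' @return The neutral fixation probability in `[0, 1]`.
#' @export
neutral_fixation_probability <- function(p0 = object$params$p0, object) {
  stopifnot(p0 >= 0, p0 <= 1)
  k <- check_integrable(object)
  if (k$c == 0) return(p0)
  stats::pbeta(p0, 1 - k$aQ, 1 - k$bQ)
}

#' Substitution rates and the Ka/Ks ratio
#'
#' Assembles `Ka = 2 Ne u phi(p0)`, `Ks = 2 Ne mu phi0(p0)` and
#' `Ka/Ks = (phi/phi0) (u/mu)` from the diffusion fixation
#' probabilities.  In an isolated population with `p0 = 1/(2N)`...`Ks`
#' reduces to the mutation rate `mu` scaled by `Ne/N` (the selfing
#' discount of the effective number of new mutants).
#'
#' @param object A [phasesel] model.
#' @param n Quadrature nodes.
#' @return A list of class `"phasesel_rates"` with components `phi`,
#'   `phi0`, `Ka`, `Ks` and `ka_ks`.
#' @examples
#' ka_ks(phasesel("antagonistic", sh = 0.03, sd = 0.06, alpha = 0,
#'                N = 30))$ka_ks   # complete offset: 1
#' @export
ka_ks <- function(object, n = 120) {
  p <- object$params
  Ne <- object$derived$Ne
  phi <- fixation_probability(p$p0, object, n = n)
  phi0 <- neutral_fixation_probability(p$p0, object)
  out <- list(phi = phi, phi0 = phi0,
              Ka = 2 * Ne * p$u * phi,
              Ks = 2 * Ne * p$mu * phi0,
              ka_ks = (phi / phi0) * (p$u / p$mu))
  class(out) <- "phasesel_rates"
  out
}

#' @export
print.phasesel_rates <- function(x, digits = 6, ...) {
  cat(sprintf("phi = %.*g, phi0 = %.*g\nKa = %.*g, Ks = %.*g, Ka/Ks = %.*g\n",
              digits, x$phi, digits, x$phi0, digits, x$Ka, digits, x$Ks,
              digits, x$ka_ks))
  invisible(x)
}

#' Closed-form Ka/Ks special cases
#'
#' Closed forms of the Ka/Ks ratio in an isolated population
#' (`mtilde = 0`) with additive sporophytic selection (`h = 1/2`), all of
#' the shape `(1 - e^{k p0}) / ((1 - e^k) p0)` for a case-specific
#' exponent rate `k`:
#' \describe{
#'   \item{`"gametophytic"`}{`sd = 0`, antagonistic:
#'     `k = -4 N (1-alpha) sh`.}
#'   \item{`"sporophytic"`}{`sh = 0`: `k = 2 N sd` (purifying).}
#'   \item{`"sporophytic_Ne"`}{the `p0 = 1/(2N)` linearisation of the
#'     sporophytic case in terms of `Ne`: `x/(e^x - 1)` with
#'     `x = 4 Ne sd / (2 - alpha)`.}
#'   \item{`"antagonistic"`}{biphasic antagonistic:
#'     `k = 2 N (sd - 2 (1-alpha) sh)`.}
#'   \item{`"synergistic"`}{biphasic synergistic:
#'     `k = 2 N (sd + 2 (1-alpha) sh)`.}
#' }
#' The removable singularity at `k = 0` (complete offset or neutrality)
#' returns the analytic limit 1.
#'
#' @param case One of the labels above.
#' @param object A [phasesel] model satisfying the case's conditions
#'   (`h = 0.5`, `mtilde = 0`, and the relevant zero coefficient).
#' @return The closed-form Ka/Ks value.
#' @export
closed_form_ka_ks <- function(case = c("gametophytic", "sporophytic",
                                       "sporophytic_Ne", "antagonistic",
                                       "synergistic"),
                              object) {
  case <- match.arg(case)
  p <- object$params
  d <- object$derived
  if (d$mtilde != 0)
    stop("closed forms require an isolated population (mtilde = 0)",
         call. = FALSE)
  if (p$h != 0.5)
    stop("closed forms require additive sporophytic selection (h = 0.5)",
         call. = FALSE)
  need <- function(cond, msg) if (!cond) stop(msg, call. = FALSE)
  switch(case,
         gametophytic = need(p$sd == 0 && p$scheme == "antagonistic",
                             "'gametophytic' case requires sd = 0, antagonistic scheme"),
         sporophytic = need(p$sh == 0, "'sporophytic' case requires sh = 0"),
         sporophytic_Ne = need(p$sh == 0, "'sporophytic_Ne' case requires sh = 0"),
         antagonistic = need(p$scheme == "antagonistic",
                             "'antagonistic' case requires the antagonistic scheme"),
         synergistic = need(p$scheme == "synergistic",
                            "'synergistic' case requires the synergistic scheme"))
  if (case == "sporophytic_Ne") {
    x <- 4 * d$Ne * p$sd / (2 - p$alpha)
    return(if (abs(x) < 1e-6) 1 - x / 2 else x / (exp(x) - 1))
  }
  k <- switch(case,
              gametophytic = -4 * p$N * (1 - p$alpha) * p$sh,
              sporophytic = 2 * p$N * p$sd,
              antagonistic = 2 * p$N * (p$sd - 2 * (1 - p$alpha) * p$sh),
              synergistic = 2 * p$N * (p$sd + 2 * (1 - p$alpha) * p$sh))
  expm1_ratio(k, p$p0)
}

## (1 - e^{k p0}) / ((1 - e^k) p0), with the k -> 0 limit handled by
## expm1 (itself accurate) and the exact limit 1 at k = 0
expm1_ratio <- function(k, p0) {
  if (k == 0) return(1)
  expm1(k * p0) / (expm1(k) * p0)
}

#' Selfing rate of complete selective balance
#'
#' Under antagonistic biphasic selection with additive dominance the
#' gametophytic and sporophytic pressures offset exactly when
#' `sd = 2 (1 - alpha) sh`, i.e. at the selfing rate
#' `alpha* = 1 - sd / (2 sh)`, where Ka/Ks = 1 and the polymorphism
#' `pi_a` turns over.
#'
#' @param object A [phasesel] model (antagonistic, `h = 0.5`, `sh > 0`).
#' @return A list with `alpha_star` and logical `attainable` (whether the
#'   turning point falls inside `[0, 1]`).
#' @export
balancing_selfing_rate <- function(object) {
  p <- object$params
  if (p$scheme != "antagonistic" || p$h != 0.5 || p$sh <= 0)
    stop("balancing selfing rate applies to antagonistic selection with ",
         "h = 0.5 and sh > 0", call. = FALSE)
  a_star <- 1 - p$sd / (2 * p$sh)
  list(alpha_star = a_star, attainable = a_star >= 0 && a_star <= 1)
}

#' Stationary allele-frequency density
#'
#' Wright's stationary density under migration--selection--drift balance,
#' `phi(pa) = C / V(pa) / G(pa)`, which in closed form is proportional to
#' `pa^{c Qa - 1} (1-pa)^{c QA - 1} exp(-B2 pa^2 - B1 pa)` with the
#' coefficients of [g_kernel()].  Requires `mtilde > 0`; without
#' migration polymorphism is transient (absorbed at the boundaries) and
#' no stationary density exists.
#'
#' @param object A [phasesel] model with `mtilde > 0`.
#' @param n Quadrature nodes.
#' @return A list of class `"phasesel_density"` with the normalised
#'   `density` function, the normalisation constant `C` (such that
#'   `phi(pa) = C * kernel(pa)`), the neutral density `density0`
#'   (a Beta(`c Qa`, `c QA`) density), and the Beta exponents.
#' @examples
#' m <- phasesel("antagonistic", sh = 0.03, sd = 0.05, alpha = 0.05,
#'               mP = 0.01, N = 30)
#' d <- stationary_density(m)
#' integrate(d$density, 0, 1)$value  # 1
#' @export
stationary_density <- function(object, n = 120) {
  k <- diffusion_coefs(object)
  if (k$c <= 0)
    stop("no stationary density without migration (mtilde = 0): ",
         "polymorphism is transient", call. = FALSE)
  shift <- min(k$B1 + k$B2, 0)
  smooth <- function(t) exp(-(k$B2 * t^2 + k$B1 * t) + shift)
  Z <- beta_kernel_integral(smooth, k$aQ - 1, k$bQ - 1, n = n)
  dens <- function(pa)
    pa^(k$aQ - 1) * (1 - pa)^(k$bQ - 1) * smooth(pa) / Z
  dens0 <- function(pa) stats::dbeta(pa, k$aQ, k$bQ)
  structure(list(density = dens, density0 = dens0, C = 1 / (Z * exp(-shift)),
                 a = k$aQ, b = k$bQ, coefs = k, n = n, model = object),
            class = "phasesel_density")
}

#' @export
print.phasesel_density <- function(x, ...) {
  cat("Stationary allele-frequency density: Beta exponents (",
      signif(x$a, 4), ", ", signif(x$b, 4),
      ") x exp(-", signif(x$coefs$B2, 4), " pa^2 - ",
      signif(x$coefs$B1, 4), " pa), normalised\n", sep = "")
  invisible(x)
}

## moments of the stationary density: E[pa], E[pa^2] via the same rule
density_moments <- function(dobj) {
  k <- dobj$coefs
  n <- dobj$n
  shift <- min(k$B1 + k$B2, 0)
  smooth <- function(t) exp(-(k$B2 * t^2 + k$B1 * t) + shift)
  Z <- beta_kernel_integral(smooth, k$aQ - 1, k$bQ - 1, n = n)
  m1 <- beta_kernel_integral(smooth, k$aQ, k$bQ - 1, n = n) / Z
  m2 <- beta_kernel_integral(function(t) t^2 * smooth(t),
                             k$aQ - 1, k$bQ - 1, n = n) / Z
  list(m1 = m1, m2 = m2)
}

#' Nonsynonymous polymorphism pi_a
#'
#' Mean heterozygosity at the selected (nonsynonymous) site at
#' stationarity, `pi_a = int 2 pa (1 - pa) phi(pa) dpa`, together with
#' the mean allele frequency `p_bar` and its variance `Vp` under the
#' stationary density; the moment identity
#' `pi_a = 2 (p_bar_A p_bar_a - Vp)` holds by construction and is
#' verified to quadrature tolerance.
#'
#' @param object A [phasesel] model with `mtilde > 0`.
#' @param n Quadrature nodes.
#' @return A list of class `"phasesel_poly"` with `pi_a`, `p_bar`, `Vp`
#'   and `pi_a_moment` (the moment-identity evaluation).
#' @export
pi_a <- function(object, n = 120) {
  d <- stationary_density(object, n = n)
  k <- d$coefs
  shift <- min(k$B1 + k$B2, 0)
  smooth <- function(t) exp(-(k$B2 * t^2 + k$B1 * t) + shift)
  Z <- beta_kernel_integral(smooth, k$aQ - 1, k$bQ - 1, n = n)
  pia <- 2 * beta_kernel_integral(smooth, k$aQ, k$bQ, n = n) / Z
  mom <- density_moments(d)
  Vp <- mom$m2 - mom$m1^2
  out <- list(pi_a = pia, p_bar = mom$m1, Vp = Vp,
              pi_a_moment = 2 * ((1 - mom$m1) * mom$m1 - Vp))
  class(out) <- "phasesel_poly"
  out
}

#' @export
print.phasesel_poly <- function(x, digits = 6, ...) {
  cat(sprintf("pi_a = %.*g (mean freq %.*g, variance %.*g)\n",
              digits, x$pi_a, digits, x$p_bar, digits, x$Vp))
  invisible(x)
}

#' Synonymous polymorphism pi_s
#'
#' Mean heterozygosity at the neutral site at stationarity, in closed
#' form `pi_s = 2 QA Qa (1 - 1/(1 + c))` with `c = 2 (2 - alpha) N
#' mtilde` (the Beta-moment of the neutral stationary density).  Without
#' migration the neutral site is only transiently polymorphic and
#' `pi_s = 0` is returned with `transient = TRUE`.
#'
#' @param object A [phasesel] model.
#' @return A list with `pi_s` and logical `transient`.
#' @export
pi_s <- function(object) {
  k <- diffusion_coefs(object)
  Qa <- object$params$Qa
  if (k$c == 0)
    return(list(pi_s = 0, transient = TRUE))
  list(pi_s = 2 * (1 - Qa) * Qa * (1 - 1 / (1 + k$c)), transient = FALSE)
}

#' Sensitivity of Ka/Ks to a model parameter
#'
#' Central finite-difference derivative of the quadrature Ka/Ks ratio
#' with respect to one parameter, refined by one step of Richardson
#' extrapolation (steps `h` and `h/2` combined to fourth order).
#'
#' @param object A [phasesel] model.
#' @param target One of `"sh"`, `"sd"`, `"alpha"`, `"N"`.
#' @param rel_step Relative step size (absolute step for parameters at
#'   0).
#' @return The derivative `d(Ka/Ks)/d(target)`.
#' @examples
#' kaks_sensitivity(phasesel(sh = 0.03, alpha = 0.3, N = 30), "alpha")
#' @export
kaks_sensitivity <- function(object, target = c("sh", "sd", "alpha", "N"),
                             rel_step = 1e-3) {
  target <- match.arg(target)
  x0 <- object$params[[target]]
  ## rebuild the perturbed model without the constructor's integer-N and
  ## sign checks: the diffusion formulas are continuous in every parameter
  f <- function(x) {
    m <- object
    m$params[[target]] <- x
    m$derived <- derive_params(m)
    m$fitness <- fitness_scheme(m)
    m$sh_signed <- signed_sh(m)
    ka_ks(m)$ka_ks
  }
  h <- if (x0 != 0) abs(x0) * rel_step else rel_step
  if (target == "N") h <- max(h, 1e-3 * object$params$N)
  cd <- function(h) (f(x0 + h) - f(x0 - h)) / (2 * h)
  d1 <- cd(h)
  d2 <- cd(h / 2)
  (4 * d2 - d1) / 3
}
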