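#' Selection model for a haploid--diploid plant life cycle
#'
#' Constructs a model of one biallelic autosomal site in a hermaphrodite
#' plant population on an island receiving unidirectional pollen and seed
#' flow from a large, stable mainland.  Natural selection may act in the
#' haploid gametophyte phase (coefficient `sh`), in the diploid sporophyte
#' phase (coefficient `sd`, dominance `h`), or in both.  Two schemes are
#' supported: under *antagonistic* selection the mutant allele `a` is
#' favoured in gametophytes (gamete fitnesses `wA = 1 - sh`, `wa = 1`) but
#' deleterious in sporophytes (`WAA = 1`, `WAa = 1 - h*sd`,
#' `Waa = 1 - sd`); under *synergistic* selection `a` is deleterious in
#' both phases (`wA = 1`, `wa = 1 - sh`, same sporophyte fitnesses).
#'
#' Mixed mating with selfing rate `alpha` implies the single-locus
#' equilibrium inbreeding coefficient `F = alpha / (2 - alpha)`, effective
#' population size `Ne = N / (1 + F) = (1 - alpha/2) * N`, and composite
#' migration rate `mtilde = mS + (1 - alpha)/2 * mP` (alien pollen is
#' discounted by the outcrossing fraction).  These derived quantities are
#' stored on the returned object.
#'
#' @param scheme Selection scheme, `"antagonistic"` or `"synergistic"`.
#' @param sh Gametophytic selection coefficient (dimensionless, >= 0).
#' @param sd Sporophytic selection coefficient (dimensionless, >= 0).
#' @param h Degree of dominance in the sporophyte phase, in `[0, 1]`;
#'   `0.5` is additive, `0` fully masks the mutant in heterozygotes,
#'   `1` is complete dominance of the mutant.
#' @param alpha Selfing rate, in `[0, 1]`.
#' @param N Actual (census) population size of the island, integer >= 2.
#' @param mP,mS Pollen and seed migration rates from the mainland,
#'   proportions in `[0, 1]`.
#' @param Qa Frequency of the mutant allele `a` among migrants
#'   (`QA = 1 - Qa`).
#' @param p0 Initial frequency of the mutant allele; defaults to a single
#'   new copy, `1/(2N)`.
#' @param u,mu Nonsynonymous and synonymous per-site per-generation
#'   mutation rates; only their ratio enters Ka/Ks.  Default `1e-8` each.
#'
#' @return An object of class `"phasesel"`: a list with components
#'   `params` (the validated inputs), `derived` (`F`, `Ne`, `mtilde`),
#'   `fitness` (`wA`, `wa`, `WAA`, `WAa`, `Waa`) and `sh_signed` (the
#'   signed gametophytic coefficient that carries the scheme through every
#'   diffusion formula: `+sh` antagonistic, `-sh` synergistic).
#'
#' @examples
#' m <- phasesel("antagonistic", sh = 0.03, sd = 0.05, h = 0.5,
#'               alpha = 0, N = 30)
#' coef(m)
#' summary(m)
#' @seealso [ka_ks()], [stationary_density()], [wf_fixation()],
#'   [run_sweep()]
#' @export
phasesel <- function(scheme = c("antagonistic", "synergistic"),
                     sh = 0, sd = 0, h = 0.5, alpha = 0, N = 30,
                     mP = 0, mS = 0, Qa = 0.5, p0 = 1 / (2 * N),
                     u = 1e-8, mu = u) {
  scheme <- match.arg(scheme)
  params <- list(scheme = scheme, sh = sh, sd = sd, h = h, alpha = alpha,
                 N = N, mP = mP, mS = mS, Qa = Qa, p0 = p0, u = u, mu = mu)
  validate_params(params)
  obj <- structure(list(params = params), class = "phasesel")
  obj$derived <- derive_params(obj)
  obj$fitness <- fitness_scheme(obj)
  obj$sh_signed <- signed_sh(obj)
  obj
}

validate_params <- function(p) {
  num1 <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      stop("'", nm, "' must be a single finite number", call. = FALSE)
  }
  for (nm in c("sh", "sd", "h", "alpha", "N", "mP", "mS", "Qa", "p0",
               "u", "mu"))
    num1(p[[nm]], nm)
  prop <- c(h = p$h, alpha = p$alpha, mP = p$mP, mS = p$mS, Qa = p$Qa)
  bad <- prop < 0 | prop > 1
  if (any(bad))
    stop("parameter(s) ", paste(names(prop)[bad], collapse = ", "),
         " must lie in [0, 1]", call. = FALSE)
  if (p$sh < 0 || p$sd < 0)
    stop("selection coefficients 'sh' and 'sd' must be >= 0", call. = FALSE)
  if (p$N < 2 || p$N != round(p$N))
    stop("'N' must be an integer >= 2", call. = FALSE)
  if (p$p0 <= 0 || p$p0 >= 1)
    stop("'p0' must lie strictly in (0, 1)", call. = FALSE)
  if (p$u < 0 || p$mu < 0)
    stop("mutation rates must be >= 0", call. = FALSE)
  if (p$sh > 0.1 || p$sd > 0.1)
    warning("selection coefficient above 0.1: the weak-selection ",
            "diffusion approximation may be inaccurate", call. = FALSE)
  invisible(p)
}

#' Selfing and migration algebra
#'
#' Derived quantities of the mixed-mating mainland--island model: the
#' equilibrium inbreeding coefficient `F = alpha/(2 - alpha)`, the
#' effective population size `Ne = N/(1 + F) = (1 - alpha/2) N` (complete
#' selfing halves `Ne`), and the composite migration rate
#' `mtilde = mS + (1 - alpha)/2 * mP`.
#'
#' @param object A [phasesel] model.
#' @return A list with components `F`, `Ne` and `mtilde`.
#' @examples
#' derive_params(phasesel(alpha = 1, N = 30))$Ne  # N/2
#' @export
derive_params <- function(object) {
  p <- object$params
  Fcoef <- p$alpha / (2 - p$alpha)
  list(F = Fcoef,
       Ne = p$N / (1 + Fcoef),
       mtilde = p$mS + (1 - p$alpha) / 2 * p$mP)
}

#' Phase-specific fitness scheme
#'
#' Gamete and genotype fitnesses for the model's selection scheme.  The
#' sporophyte fitnesses are identical between schemes; the gamete
#' fitnesses swap which allele is penalised.
#'
#' @inheritParams derive_params
#' @return A list with components `wA`, `wa` (gamete fitnesses) and
#'   `WAA`, `WAa`, `Waa` (genotype fitnesses).
#' @export
fitness_scheme <- function(object) {
  p <- object$params
  gam <- switch(p$scheme,
                antagonistic = c(wA = 1 - p$sh, wa = 1),
                synergistic  = c(wA = 1, wa = 1 - p$sh),
                stop("unknown selection scheme: ", p$scheme, call. = FALSE))
  list(wA = unname(gam["wA"]), wa = unname(gam["wa"]),
       WAA = 1, WAa = 1 - p$h * p$sd, Waa = 1 - p$sd)
}

#' Signed gametophytic selection coefficient
#'
#' The single sign that carries the selection scheme through every
#' diffusion formula: `+sh` for antagonistic selection (mutant favoured in
#' gametophytes), `-sh` for synergistic (mutant deleterious in both
#' phases).
#'
#' @inheritParams derive_params
#' @return A single number.
#' @export
signed_sh <- function(object) {
  p <- object$params
  switch(p$scheme, antagonistic = p$sh, synergistic = -p$sh)
}

#' @export
print.phasesel <- function(x, digits = 4, ...) {
  p <- x$params
  d <- x$derived
  cat("Haploid-diploid selection model (", p$scheme, " scheme)\n", sep = "")
  cat(sprintf("  gametophytic sh = %g, sporophytic sd = %g, dominance h = %g\n",
              p$sh, p$sd, p$h))
  cat(sprintf("  selfing alpha = %g  (F = %.4g, Ne = %.4g of N = %d)\n",
              p$alpha, d$F, d$Ne, as.integer(p$N)))
  cat(sprintf("  migration: mP = %g, mS = %g, Qa = %g  (mtilde = %.4g)\n",
              p$mP, p$mS, p$Qa, d$mtilde))
  cat(sprintf("  initial mutant frequency p0 = %.4g; u/mu = %g\n",
              p$p0, p$u / p$mu))
  invisible(x)
}

#' @export
coef.phasesel <- function(object, ...) {
  p <- object$params
  d <- object$derived
  c(sh = p$sh, sd = p$sd, h = p$h, alpha = p$alpha, N = p$N,
    mP = p$mP, mS = p$mS, Qa = p$Qa, p0 = p$p0, u = p$u, mu = p$mu,
    F = d$F, Ne = d$Ne, mtilde = d$mtilde)
}

#' Summarise a phasesel model
#'
#' Evaluates the model's headline quantities: the diffusion fixation
#' probabilities `phi(p0)` and `phi0(p0)`, the substitution rates and
#' their ratio Ka/Ks, and -- when the composite migration rate is positive
#' so a stationary allele-frequency distribution exists -- the
#' polymorphism measures `pi_a`, `pi_s` and their ratio.
#'
#' @param object A [phasesel] model.
#' @param ... Unused.
#' @return An object of class `"summary.phasesel"`.
#' @export
summary.phasesel <- function(object, ...) {
  rate <- ka_ks(object)
  poly <- if (object$derived$mtilde > 0) pi_a(object) else NULL
  pis <- pi_s(object)
  out <- list(model = object, rate = rate, poly = poly, pi_s = pis)
  class(out) <- "summary.phasesel"
  out
}

#' @export
print.summary.phasesel <- function(x, digits = 6, ...) {
  print(x$model)
  r <- x$rate
  cat("\nDiffusion results:\n")
  cat(sprintf("  phi(p0)  = %.*g   phi0(p0) = %.*g\n",
              digits, r$phi, digits, r$phi0))
  cat(sprintf("  Ka = %.*g   Ks = %.*g   Ka/Ks = %.*g\n",
              digits, r$Ka, digits, r$Ks, digits, r$ka_ks))
  if (!is.null(x$poly)) {
    cat(sprintf("  pi_a = %.*g   pi_s = %.*g   pi_a/pi_s = %.*g\n",
                digits, x$poly$pi_a, digits, x$pi_s$pi_s,
                digits, x$poly$pi_a / x$pi_s$pi_s))
  } else {
    cat("  mtilde = 0: polymorphism is transient (pi_s = 0 after",
        "absorption); no stationary density\n")
  }
  invisible(x)
}

## Rebuild a model with some parameters replaced; revalidates and rederives.
modify_model <- function(object, ...) {
  repl <- list(...)
  p <- object$params
  for (nm in names(repl)) {
    if (!nm %in% names(p)) stop("unknown parameter: ", nm, call. = FALSE)
    p[[nm]] <- repl[[nm]]
  }
  do.call(phasesel, p)
}
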