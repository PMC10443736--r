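# Shared model fixtures: the N = 30, p0 = 1/(2N) settings used throughout
# the numerical examples.

mod <- function(scheme = "antagonistic", sh = 0, sd = 0, h = 0.5,
                alpha = 0, N = 30, mP = 0, mS = 0, Qa = 0.5,
                p0 = 1 / (2 * N), ...) {
  phasesel(scheme, sh = sh, sd = sd, h = h, alpha = alpha, N = N,
           mP = mP, mS = mS, Qa = Qa, p0 = p0, ...)
}

# genotype state at single-locus inbreeding equilibrium for frequency pa
ib_state <- function(pa, Fcoef) {
  pA <- 1 - pa
  genotype_state(pA^2 + Fcoef * pA * pa,
                 2 * pA * pa * (1 - Fcoef),
                 pa^2 + Fcoef * pA * pa)
}
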