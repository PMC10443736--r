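#' Genotype-frequency state at a life-cycle stage
#'
#' A light container for genotype frequencies `(pAA, pAa, paa)` at a named
#' stage of the life cycle.  All three arguments may be vectors of equal
#' length, in which case the state holds a batch of populations (used by
#' the Wright--Fisher simulator to advance many replicates at once).
#'
#' @param pAA,pAa,paa Genotype frequencies; each vector must sum to 1
#'   componentwise within `1e-9`.
#' @param stage Stage label, one of `"adults"`, `"post-pollen-flow"`,
#'   `"seeds"`, `"post-seed-flow"`, `"post-sporophytic-selection"`.
#' @return An object of class `"genotype_state"` with fields `pAA`,
#'   `pAa`, `paa`, the implied allele frequencies `pA`, `pa`, and `stage`.
#' @examples
#' genotype_state(0.25, 0.5, 0.25)$pa
#' @export
genotype_state <- function(pAA, pAa, paa, stage = "adults") {
  stopifnot(length(pAA) == length(pAa), length(pAa) == length(paa))
  tot <- pAA + pAa + paa
  if (any(pAA < -1e-12 | pAa < -1e-12 | paa < -1e-12) ||
      any(abs(tot - 1) > 1e-9))
    stop("genotype frequencies must be nonnegative and sum to 1",
         call. = FALSE)
  stages <- c("adults", "post-pollen-flow", "seeds", "post-seed-flow",
              "post-sporophytic-selection")
  stage <- match.arg(stage, stages)
  pA <- pAA + pAa / 2
  structure(list(pAA = pAA, pAa = pAa, paa = paa,
                 pA = pA, pa = 1 - pA, stage = stage),
            class = "genotype_state")
}

#' @export
print.genotype_state <- function(x, ...) {
  cat("genotype_state [", x$stage, "]\n", sep = "")
  print(data.frame(pAA = x$pAA, pAa = x$pAa, paa = x$paa, pa = x$pa))
  invisible(x)
}

#' @export
as.data.frame.genotype_state <- function(x, ...) {
  data.frame(stage = x$stage, pAA = x$pAA, pAa = x$pAa, paa = x$paa,
             pa = x$pa)
}

#' Pollen flow
#'
#' Mixes the island pollen pool with mainland pollen at rate `mP`:
#' `pa* = (1 - mP) pa + mP Qa`.  Ovules do not migrate, so the ovule pool
#' keeps the adult allele frequencies.  The genotype frequencies carried
#' on the state are unchanged (pollen flow acts on the gamete pool only);
#' the pollen-pool allele frequency is attached as `pa_pollen`.
#'
#' @param adults A [genotype_state] at stage `"adults"`.
#' @param object A [phasesel] model.
#' @return The state relabelled `"post-pollen-flow"` with fields
#'   `pA_pollen`, `pa_pollen`.
#' @export
pollen_flow <- function(adults, object) {
  p <- object$params
  pa_pol <- (1 - p$mP) * adults$pa + p$mP * p$Qa
  out <- adults
  out$stage <- "post-pollen-flow"
  out$pa_pollen <- pa_pol
  out$pA_pollen <- 1 - pa_pol
  out
}

#' Gametophytic selection and mixed mating
#'
#' Produces seed genotype frequencies from the post-pollen-flow state.
#' With probability `1 - alpha` (outcrossing) gametes are selected in both
#' the pollen pool (allele frequencies `pA*`, `pa*`, fitness weights `wA`,
#' `wa`, mean `wP`) and the ovule pool (adult frequencies, mean `wO`), and
#' seeds form by random union of the two selected pools.  With probability
#' `alpha` (selfing) each maternal plant selfs with its own pollen:
#' homozygotes breed true, and within heterozygous parents gametophytic
#' selection sets the gamete ratio to `wA : wa` (normalised), offspring
#' following the squared selected ratios; the parental mean gamete fitness
#' is `1 - sh/2`.  The two parts are combined by their weights.
#'
#' @param state A [genotype_state] at stage `"post-pollen-flow"` (or
#'   `"adults"`, in which case pollen flow with `mP` is applied first).
#' @param object A [phasesel] model.
#' @return A [genotype_state] at stage `"seeds"`.
#' @export
mate_and_select_gametes <- function(state, object) {
  if (state$stage == "adults") state <- pollen_flow(state, object)
  stopifnot(state$stage == "post-pollen-flow")
  p <- object$params
  w <- object$fitness

  ## outcrossing: selected pollen and ovule pools
  wP <- w$wA * state$pA_pollen + w$wa * state$pa_pollen
  wO <- w$wA * state$pA + w$wa * state$pa
  if (any(wP <= 0) || any(wO <= 0))
    stop("mean gamete fitness is non-positive", call. = FALSE)
  pA_pol <- w$wA * state$pA_pollen / wP
  pa_pol <- w$wa * state$pa_pollen / wP
  pA_ov <- w$wA * state$pA / wO
  pa_ov <- w$wa * state$pa / wO
  out_AA <- pA_ov * pA_pol
  out_Aa <- pA_ov * pa_pol + pa_ov * pA_pol
  out_aa <- pa_ov * pa_pol

  ## selfing: gametophytic selection acts only within heterozygous parents
  gA <- w$wA / (w$wA + w$wa)
  ga <- w$wa / (w$wA + w$wa)
  self_AA <- state$pAA + state$pAa * gA^2
  self_Aa <- state$pAa * 2 * gA * ga
  self_aa <- state$paa + state$pAa * ga^2

  a <- p$alpha
  genotype_state((1 - a) * out_AA + a * self_AA,
                 (1 - a) * out_Aa + a * self_Aa,
                 (1 - a) * out_aa + a * self_aa,
                 stage = "seeds")
}

#' Seed flow
#'
#' Mixes seed genotype frequencies with mainland seeds at rate `mS`.
#' Migrant seeds carry Hardy--Weinberg genotype proportions
#' `(QA^2, 2 QA Qa, Qa^2)` at the mainland allele frequency.
#'
#' @param seeds A [genotype_state] at stage `"seeds"`.
#' @param object A [phasesel] model.
#' @return A [genotype_state] at stage `"post-seed-flow"`.
#' @export
seed_flow <- function(seeds, object) {
  stopifnot(seeds$stage == "seeds")
  p <- object$params
  QA <- 1 - p$Qa
  genotype_state((1 - p$mS) * seeds$pAA + p$mS * QA^2,
                 (1 - p$mS) * seeds$pAa + p$mS * 2 * QA * p$Qa,
                 (1 - p$mS) * seeds$paa + p$mS * p$Qa^2,
                 stage = "post-seed-flow")
}

#' Sporophytic (viability) selection
#'
#' Reweights genotype frequencies by the sporophyte fitnesses
#' `(WAA, WAa, Waa)` normalised by the population mean fitness
#' `Wbar = WAA pAA + WAa pAa + Waa paa`.
#'
#' @param state A [genotype_state] at stage `"post-seed-flow"`.
#' @param object A [phasesel] model.
#' @return A [genotype_state] at stage `"post-sporophytic-selection"`.
#' @export
sporophytic_selection <- function(state, object) {
  stopifnot(state$stage == "post-seed-flow")
  w <- object$fitness
  Wbar <- w$WAA * state$pAA + w$WAa * state$pAa + w$Waa * state$paa
  if (any(Wbar <= 0))
    stop("mean sporophyte fitness is non-positive", call. = FALSE)
  genotype_state(w$WAA * state$pAA / Wbar,
                 w$WAa * state$pAa / Wbar,
                 w$Waa * state$paa / Wbar,
                 stage = "post-sporophytic-selection")
}

#' One full deterministic generation
#'
#' Composes the life-cycle events in their fixed order: pollen flow,
#' gametophytic selection with mixed mating, seed flow, sporophytic
#' selection.  The resulting allele-frequency change agrees with the
#' first-order systematic change of [systematic_change()] up to terms of
#' second order in `(sh, sd, mtilde)`.
#'
#' @param adults A [genotype_state] at stage `"adults"`.
#' @param object A [phasesel] model.
#' @return A [genotype_state] at stage `"post-sporophytic-selection"`.
#' @examples
#' m <- phasesel("antagonistic", sh = 0.03, sd = 0.05, N = 30)
#' st <- genotype_state(0.25, 0.5, 0.25)
#' full_generation(st, m)$pa - st$pa
#' @export
full_generation <- function(adults, object) {
  stopifnot(adults$stage == "adults")
  st <- pollen_flow(adults, object)
  st <- mate_and_select_gametes(st, object)
  st <- seed_flow(st, object)
  sporophytic_selection(st, object)
}

#' First-order systematic change of the mutant-allele frequency
#'
#' The per-generation deterministic change `M(pa) = pa*** - pa` to first
#' order in the selection and migration parameters:
#' \deqn{M = \tilde m (Q_a - p_a)
#'   + s_h p_A p_a \left(1 - \tfrac{\alpha}{2}(1+F)\right)
#'   - s_d p_A p_a \left(p_a + \tfrac{\alpha}{2} p_A (1+F)
#'   + h (p_A - p_a)\left(1 - \tfrac{\alpha}{2}(1+F)\right)\right)}
#' with `F = alpha/(2 - alpha)` and the scheme carried by the sign of
#' `sh` (negative under synergistic selection).  The change for the
#' ancestral allele is `-M`.
#'
#' @param pa Mutant allele frequency (vectorised).
#' @param object A [phasesel] model.
#' @return The systematic change, same length as `pa`.
#' @export
systematic_change <- function(pa, object) {
  p <- object$params
  d <- object$derived
  sh <- object$sh_signed
  pA <- 1 - pa
  half_a1F <- p$alpha / 2 * (1 + d$F)   # = alpha/(2 - alpha)
  d$mtilde * (p$Qa - pa) +
    sh * pA * pa * (1 - half_a1F) -
    p$sd * pA * pa * (pa + half_a1F * pA + p$h * (pA - pa) * (1 - half_a1F))
}

## Genotype state at the single-locus inbreeding equilibrium for allele
## frequency pa and inbreeding coefficient F:
##   pAA = pA^2 + F pA pa, pAa = 2 pA pa (1 - F), paa = pa^2 + F pA pa.
inbreeding_equilibrium_state <- function(pa, Fcoef, stage = "adults") {
  pA <- 1 - pa
  genotype_state(pA^2 + Fcoef * pA * pa,
                 2 * pA * pa * (1 - Fcoef),
                 pa^2 + Fcoef * pA * pa,
                 stage = stage)
}
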