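## Forward Wright-Fisher simulator of the identical life cycle.
##
## Each generation applies the deterministic recursion (pollen flow ->
## gametophytic selection & mixed mating -> seed flow -> sporophytic
## selection) and then samples N adult genotypes multinomially from the
## post-selection frequencies.  The multinomial draw is decomposed into
## two vectorised binomials so thousands of replicate populations advance
## in parallel.  Selfing-induced reduction of the effective size emerges
## from the mating structure itself; it is not imposed.

## one multinomial draw of size N per replicate, vectorised
sample_genotypes <- function(state, N) {
  k <- length(state$pAA)
  nAA <- stats::rbinom(k, N, state$pAA)
  rest <- N - nAA
  pcond <- ifelse(rest > 0, state$pAa / (1 - state$pAA), 0)
  pcond <- pmin(pmax(pcond, 0), 1)
  nAa <- stats::rbinom(k, rest, pcond)
  naa <- N - nAA - nAa
  genotype_state(nAA / N, nAa / N, naa / N, stage = "adults")
}

## advance a batch of replicate populations one generation
wf_step <- function(state, object) {
  det <- full_generation(state, object)
  sample_genotypes(det, object$params$N)
}

## starting state: mutant copies placed as heterozygotes at frequency p0
## (a count of round(2 N p0) copies, at least 1), matching the diffusion's
## initial frequency convention
wf_initial_state <- function(object, replicates) {
  p <- object$params
  copies <- max(1L, round(2 * p$N * p$p0))
  naa <- max(0L, copies - p$N)        # heterozygotes first, then aa
  nAa <- copies - 2L * naa
  nAA <- p$N - nAa - naa
  genotype_state(rep(nAA / p$N, replicates), rep(nAa / p$N, replicates),
                 rep(naa / p$N, replicates), stage = "adults")
}

#' Simulate Wright--Fisher trajectories of the life cycle
#'
#' Forward stochastic simulation: each generation runs the deterministic
#' life-cycle recursion and then one multinomial draw of `N` adult
#' genotypes.  Absorbing states (without migration) are loss and
#' fixation of the mutant allele.
#'
#' @param object A [phasesel] model.
#' @param nsim Number of independent replicate trajectories.
#' @param seed Optional integer seed (applied via `set.seed`).
#' @param generations Number of generations to record.
#' @param ... Unused.
#' @return A data frame with columns `rep`, `generation`, `pAA`, `pAa`,
#'   `paa`, `pa`.
#' @examples
#' m <- phasesel(sh = 0.03, N = 30, p0 = 1/60)
#' head(simulate(m, nsim = 3, seed = 1, generations = 5))
#' @export
simulate.phasesel <- function(object, nsim = 1, seed = NULL,
                              generations = 100, ...) {
  if (!is.null(seed)) set.seed(seed)
  st <- wf_initial_state(object, nsim)
  out <- vector("list", generations + 1)
  out[[1]] <- cbind(rep = seq_len(nsim), generation = 0,
                    as.data.frame(st)[-1])
  for (g in seq_len(generations)) {
    st <- wf_step(st, object)
    out[[g + 1]] <- cbind(rep = seq_len(nsim), generation = g,
                          as.data.frame(st)[-1])
  }
  res <- do.call(rbind, out)
  res[order(res$rep, res$generation), , drop = FALSE]
}

#' Monte-Carlo fixation probability from the Wright--Fisher oracle
#'
#' Runs replicate trajectories until absorption (mutant lost or fixed)
#' or a generation cap, and reports the fixation fraction with its exact
#' binomial standard error.  Requires an isolated population
#' (`mtilde = 0`) for absorption to be guaranteed; with migration the
#' cap applies and unabsorbed replicates are reported, never dropped.
#'
#' @param object A [phasesel] model.
#' @param replicates Number of independent trajectories.
#' @param max_generations Absorption cap per trajectory.
#' @param seed Optional integer seed.
#' @return A list of class `"wf_summary"` with `fixed`, `lost`,
#'   `unabsorbed`, `fixation_fraction`, `se` (binomial standard error
#'   among absorbed replicates) and `replicates`.
#' @examples
#' wf_fixation(phasesel(sh = 0.03, N = 30, p0 = 1/60),
#'             replicates = 2000, seed = 1)
#' @export
wf_fixation <- function(object, replicates = 10000,
                        max_generations = 100 * object$params$N,
                        seed = NULL) {
  stopifnot(replicates >= 1)
  if (!is.null(seed)) set.seed(seed)
  st <- wf_initial_state(object, replicates)
  fixed <- 0L
  lost <- 0L
  gen <- 0L
  while (length(st$pa) > 0 && gen < max_generations) {
    st <- wf_step(st, object)
    gen <- gen + 1L
    done_fix <- st$paa == 1
    done_loss <- st$pAA == 1
    fixed <- fixed + sum(done_fix)
    lost <- lost + sum(done_loss)
    keep <- !(done_fix | done_loss)
    if (!all(keep))
      st <- genotype_state(st$pAA[keep], st$pAa[keep], st$paa[keep],
                           stage = "adults")
  }
  unabsorbed <- length(st$pa)
  absorbed <- fixed + lost
  frac <- if (absorbed > 0) fixed / absorbed else NA_real_
  se <- if (absorbed > 1 && !is.na(frac))
    sqrt(max(frac * (1 - frac), 0) / absorbed) else NA_real_
  structure(list(fixed = fixed, lost = lost, unabsorbed = unabsorbed,
                 fixation_fraction = frac, se = se,
                 replicates = replicates, generations_run = gen),
            class = "wf_summary")
}

#' @export
print.wf_summary <- function(x, ...) {
  if (!is.null(x$fixed))
    cat(sprintf(
      "WF oracle: %d replicates, %d fixed / %d lost / %d unabsorbed\n",
      x$replicates, x$fixed, x$lost, x$unabsorbed))
  if (!is.null(x$fixation_fraction) && !is.na(x$fixation_fraction))
    cat(sprintf("fixation fraction = %.6g (SE %.3g)\n",
                x$fixation_fraction, x$se))
  if (!is.null(x$mean_het))
    cat(sprintf("mean heterozygosity = %.6g (SE %.3g), mean freq = %.6g\n",
                x$mean_het, x$se_het, x$mean_freq))
  invisible(x)
}

#' Stationary moments from the Wright--Fisher oracle
#'
#' Long-run time averages of the mutant frequency and heterozygosity
#' `2 pa (1 - pa)` under migration--drift(--selection) balance, from
#' independent replicate chains with burn-in and thinning.  Standard
#' errors come from the between-replicate spread of replicate means
#' (replicates are independent), so they remain valid despite
#' within-chain autocorrelation.
#'
#' @param object A [phasesel] model with `mtilde > 0`.
#' @param replicates Independent chains.
#' @param burn_in Generations discarded before recording (default
#'   `10 N`).
#' @param record Number of recorded (thinned) samples per chain.
#' @param thin Generations between records (default `N`).
#' @param seed Optional integer seed.
#' @return A list of class `"wf_summary"` with `mean_het`, `se_het`,
#'   `mean_freq`, `se_freq`, and the settings used.
#' @export
wf_stationary <- function(object, replicates = 200,
                          burn_in = 10 * object$params$N, record = 50,
                          thin = object$params$N, seed = NULL) {
  if (object$derived$mtilde <= 0)
    stop("stationary moments require migration (mtilde > 0)", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  st <- wf_initial_state(object, replicates)
  for (g in seq_len(burn_in)) st <- wf_step(st, object)
  het <- matrix(0, nrow = replicates, ncol = record)
  freq <- matrix(0, nrow = replicates, ncol = record)
  for (r in seq_len(record)) {
    for (g in seq_len(thin)) st <- wf_step(st, object)
    het[, r] <- 2 * st$pa * (1 - st$pa)
    freq[, r] <- st$pa
  }
  het_rep <- rowMeans(het)
  freq_rep <- rowMeans(freq)
  ess <- replicates
  if (ess < 100)
    warning("fewer than 100 independent replicate chains; standard ",
            "errors may be unstable", call. = FALSE)
  structure(list(mean_het = mean(het_rep),
                 se_het = stats::sd(het_rep) / sqrt(replicates),
                 mean_freq = mean(freq_rep),
                 se_freq = stats::sd(freq_rep) / sqrt(replicates),
                 replicates = replicates, burn_in = burn_in,
                 record = record, thin = thin),
            class = "wf_summary")
}
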