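test_that("the G kernel matches its defining integral of -2M/V", {
  m <- mod("antagonistic", sh = 0.03, sd = 0.05, h = 0.5, alpha = 0)
  expect_equal(g_kernel(0.5, m), exp(-0.3), tolerance = 1e-12)
  # neutral and exactly-offset kernels are identically 1
  expect_equal(g_kernel(seq(0.1, 0.9, 0.2), mod()), rep(1, 5))
  moff <- mod("antagonistic", sh = 0.03, sd = 0.06, h = 0.5, alpha = 0)
  expect_equal(g_kernel(seq(0.1, 0.9, 0.2), moff), rep(1, 5))
  # independent oracle: numeric integration of -2 M / V from 1/2 to pa
  for (mm in list(m, mod("synergistic", sh = 0.02, sd = 0.03, h = 0.3,
                         alpha = 0.4, mP = 0.005, mS = 0.002))) {
    V <- function(pa) pa * (1 - pa) / (2 * mm$derived$Ne)
    lg <- function(pa) integrate(function(q)
      -2 * systematic_change(q, mm) / V(q), 0.5, pa,
      rel.tol = 1e-12)$value
    for (pa in c(0.2, 0.6, 0.9))
      expect_equal(g_kernel(pa, mm) / g_kernel(0.5, mm), exp(lg(pa)),
                   tolerance = 1e-8)
  }
})

test_that("fixation probability behaves as a probability and hits limits", {
  m <- mod("antagonistic", sh = 0.03, sd = 0, alpha = 0, p0 = 1 / 60)
  expect_equal(fixation_probability(0, m), 0)
  expect_equal(fixation_probability(1, m), 1)
  ps <- vapply(seq(0.05, 0.95, 0.1), fixation_probability, 0, object = m)
  expect_true(all(diff(ps) > 0))
  expect_true(all(ps >= 0 & ps <= 1))
  # neutral: phi equals the initial frequency
  expect_equal(fixation_probability(0.3, mod()), 0.3, tolerance = 1e-12)
  expect_equal(fixation_probability(1 / 60, mod()), 1 / 60,
               tolerance = 1e-12)
})

test_that("neutral fixation probability is the incomplete-Beta closed form", {
  expect_equal(neutral_fixation_probability(0.3, mod()), 0.3)
  expect_equal(neutral_fixation_probability(1 / 60, mod(N = 30)), 1 / 60)
  # quadrature path (fixation_probability of a neutral model) agrees with
  # the regularised incomplete Beta over a parameter grid
  for (N in c(20, 30)) for (a in c(0, 0.05, 0.5))
    for (mP in c(0.002, 0.005)) for (Qa in c(0.3, 0.5)) {
      mm <- mod(N = N, alpha = a, mP = mP, Qa = Qa)
      c_mig <- 2 * (2 - a) * N * mm$derived$mtilde
      ib <- pbeta(1 / (2 * N), 1 - c_mig * Qa, 1 - c_mig * (1 - Qa))
      expect_equal(neutral_fixation_probability(1 / (2 * N), mm), ib)
      expect_equal(fixation_probability(1 / (2 * N), mm), ib,
                   tolerance = 1e-8)
    }
})

test_that("a nonintegrable kernel raises a structured error, not a number", {
  # 2(2-alpha) N mtilde Q reaches 1 near mP ~ 0.036 at these settings
  m_bad <- mod(alpha = 0.05, mP = 0.05, Qa = 0.5, sh = 0.03)
  expect_error(fixation_probability(1 / 60, m_bad), "nonintegrable")
  expect_error(neutral_fixation_probability(1 / 60, m_bad),
               "nonintegrable")
  expect_error(ka_ks(m_bad), "nonintegrable")
  m_ok <- mod(alpha = 0.05, mP = 0.03, Qa = 0.5, sh = 0.03)
  expect_silent(ka_ks(m_ok))
})

test_that("closed-form special cases match quadrature and frozen references", {
  # gametophytic-only positive selection
  m14 <- mod("antagonistic", sh = 0.03, sd = 0, alpha = 0, p0 = 1 / 60)
  r14 <- closed_form_ka_ks("gametophytic", m14)
  expect_equal(r14, 3.5923, tolerance = 1e-4)
  expect_equal(ka_ks(m14)$ka_ks, r14, tolerance = 1e-6)

  # sporophytic-only purifying selection, and its Ne-linearised variant
  m16 <- mod("antagonistic", sh = 0, sd = 0.05, alpha = 0, p0 = 1 / 60)
  r16 <- closed_form_ka_ks("sporophytic", m16)
  r17 <- closed_form_ka_ks("sporophytic_Ne", m16)
  expect_equal(r16, 0.161183, tolerance = 1e-5)
  expect_equal(r17, 3 / (exp(3) - 1), tolerance = 1e-12)
  expect_equal(ka_ks(m16)$ka_ks, r16, tolerance = 1e-6)
  expect_false(isTRUE(all.equal(r16, r17, tolerance = 1e-3)))

  # antagonistic biphasic: gametophytic positive selection dominates
  # (ratio > 1) exactly when sd < 2(1-alpha) sh
  m18 <- mod("antagonistic", sh = 0.03, sd = 0.05, alpha = 0, p0 = 1 / 60)
  r18 <- closed_form_ka_ks("antagonistic", m18)
  expect_equal(r18, 1.32317, tolerance = 1e-4)
  expect_gt(r18, 1)
  expect_equal(ka_ks(m18)$ka_ks, r18, tolerance = 1e-6)

  # synergistic biphasic: cumulative purging
  m20 <- mod("synergistic", sh = 0.03, sd = 0.05, alpha = 0, p0 = 1 / 60)
  r20 <- closed_form_ka_ks("synergistic", m20)
  expect_equal(r20, 0.009503, tolerance = 1e-3)
  expect_equal(ka_ks(m20)$ka_ks, r20, tolerance = 1e-6)

  # agreement holds across the selfing range in every regime
  for (a in c(0, 0.25, 0.7)) {
    for (case in c("gametophytic", "antagonistic")) {
      mm <- mod("antagonistic", sh = 0.02,
                sd = if (case == "gametophytic") 0 else 0.03,
                alpha = a, p0 = 1 / 60)
      expect_equal(ka_ks(mm)$ka_ks, closed_form_ka_ks(case, mm),
                   tolerance = 1e-6)
    }
    ms <- mod("synergistic", sh = 0.02, sd = 0.03, alpha = a, p0 = 1 / 60)
    expect_equal(ka_ks(ms)$ka_ks, closed_form_ka_ks("synergistic", ms),
                 tolerance = 1e-6)
  }

  # case-condition errors
  expect_error(closed_form_ka_ks("gametophytic", m18), "sd = 0")
  expect_error(closed_form_ka_ks("sporophytic", m18), "sh = 0")
  expect_error(closed_form_ka_ks("antagonistic", m20), "antagonistic")
  expect_error(closed_form_ka_ks("antagonistic",
                                 mod("antagonistic", sh = 0.01, h = 0)),
               "h = 0.5")
  expect_error(closed_form_ka_ks("antagonistic",
                                 mod("antagonistic", sh = 0.01, mS = 0.01)),
               "isolated")
})

test_that("ka_ks carries the u/mu factor and the neutral Ks identity", {
  r <- ka_ks(mod(u = 2e-8, mu = 1e-8))
  expect_equal(r$ka_ks, 2, tolerance = 1e-12)
  # isolated outcrossing population, p0 = 1/(2N): Ks equals mu
  r0 <- ka_ks(mod(alpha = 0, N = 30, mu = 1e-8, u = 1e-8))
  expect_equal(r0$Ks, 1e-8, tolerance = 1e-12)
  expect_equal(r0$Ka, r0$Ks)
})

test_that("the balancing selfing rate sits at 1 - sd/(2 sh)", {
  b <- balancing_selfing_rate(mod("antagonistic", sh = 0.03, sd = 0.05))
  expect_equal(b$alpha_star, 1 / 6, tolerance = 1e-12)
  expect_true(b$attainable)
  expect_equal(balancing_selfing_rate(
    mod("antagonistic", sh = 0.03, sd = 0.06))$alpha_star, 0)
  expect_equal(balancing_selfing_rate(
    mod("antagonistic", sh = 0.03, sd = 0))$alpha_star, 1)
  out <- balancing_selfing_rate(mod("antagonistic", sh = 0.01, sd = 0.05))
  expect_false(out$attainable)
  expect_error(balancing_selfing_rate(mod("synergistic", sh = 0.03)),
               "antagonistic")
})

test_that("the stationary density normalises and has the neutral Beta limit", {
  mn <- mod(alpha = 0.05, mP = 0.01, N = 30)
  d <- stationary_density(mn)
  expect_equal(integrate(d$density, 0, 1, rel.tol = 1e-10)$value, 1,
               tolerance = 1e-8)
  pa <- seq(0.05, 0.95, 0.1)
  c_mig <- 2 * 1.95 * 30 * mn$derived$mtilde
  expect_equal(d$density(pa), dbeta(pa, c_mig * 0.5, c_mig * 0.5),
               tolerance = 1e-8)
  ms <- mod("antagonistic", sh = 0.03, sd = 0.05, alpha = 0.05, mP = 0.01)
  ds <- stationary_density(ms)
  expect_equal(integrate(ds$density, 0, 1, rel.tol = 1e-10)$value, 1,
               tolerance = 1e-8)
  expect_error(stationary_density(mod()), "migration")
})

test_that("pi_a satisfies the moment identity and the neutral closed form", {
  ms <- mod("antagonistic", sh = 0.03, sd = 0.05, alpha = 0.05, mP = 0.01)
  pa <- pi_a(ms)
  expect_equal(pa$pi_a, pa$pi_a_moment, tolerance = 1e-8)
  expect_equal(pa$pi_a, 2 * ((1 - pa$p_bar) * pa$p_bar - pa$Vp),
               tolerance = 1e-8)
  # direct-quadrature cross-check against integrate() on the density
  dens <- stationary_density(ms)$density
  ref <- integrate(function(q) 2 * q * (1 - q) * dens(q), 0, 1,
                   rel.tol = 1e-11)$value
  expect_equal(pa$pi_a, ref, tolerance = 1e-8)
  # neutral model: pi_a collapses to pi_s
  mn <- mod(alpha = 0.05, mP = 0.01)
  expect_equal(pi_a(mn)$pi_a, pi_s(mn)$pi_s, tolerance = 1e-8)
})

test_that("pi_s follows the Beta-moment closed form across a grid", {
  for (N in c(20, 30, 60)) for (a in c(0, 0.05, 0.5))
    for (mv in list(c(0.01, 0), c(0, 0.004), c(0.01, 0.002)))
      for (Qa in c(0.3, 0.5)) {
        mm <- mod(N = N, alpha = a, mP = mv[1], mS = mv[2], Qa = Qa)
        c_mig <- 2 * (2 - a) * N * mm$derived$mtilde
        # oracle: E[2p(1-p)] under Beta(c Qa, c QA), by integrate()
        ref <- integrate(function(q) 2 * q * (1 - q) *
                           dbeta(q, c_mig * Qa, c_mig * (1 - Qa)),
                         0, 1, rel.tol = 1e-12)$value
        expect_equal(pi_s(mm)$pi_s, ref, tolerance = 1e-8)
      }
  mn <- mod(alpha = 0.05, mP = 0.01, N = 30, Qa = 0.5)
  # c = 2(2 - 0.05) * 30 * 0.00475 = 0.55575
  expect_equal(pi_s(mn)$pi_s, 2 * 0.25 * (1 - 1 / 1.55575),
               tolerance = 1e-9)
  # migration-dominated limit 2 QA Qa; transient flag without migration
  expect_equal(pi_s(mod(mS = 1, Qa = 0.3, N = 500))$pi_s, 2 * 0.7 * 0.3,
               tolerance = 1e-2)
  z <- pi_s(mod())
  expect_identical(z$pi_s, 0)
  expect_true(z$transient)
})

test_that("Ka/Ks sensitivities obey the closed-form relations and signs", {
  for (a in c(0, 0.5)) {
    mm <- mod("antagonistic", sh = 0.03, sd = 0.05, alpha = a, p0 = 1 / 60)
    dsh <- kaks_sensitivity(mm, "sh")
    dsd <- kaks_sensitivity(mm, "sd")
    expect_equal(dsh, -2 * (1 - a) * dsd, tolerance = 1e-4)
    ms <- mod("synergistic", sh = 0.03, sd = 0.05, alpha = a, p0 = 1 / 60)
    dsh_s <- kaks_sensitivity(ms, "sh")
    dsd_s <- kaks_sensitivity(ms, "sd")
    expect_equal(dsh_s, (1 - a) * 2 * dsd_s, tolerance = 1e-4)
  }
  expect_gt(kaks_sensitivity(
    mod("antagonistic", sh = 0.03, alpha = 0, p0 = 1 / 60), "sh"), 0)
  expect_lt(kaks_sensitivity(
    mod("antagonistic", sh = 0.03, alpha = 0.3, p0 = 1 / 60), "alpha"), 0)
  expect_gt(kaks_sensitivity(
    mod("synergistic", sh = 0.03, sd = 0.05, alpha = 0.5, p0 = 1 / 60),
    "alpha"), 0)
  expect_gt(kaks_sensitivity(
    mod("antagonistic", sh = 0.03, alpha = 0.3, p0 = 1 / 60), "N"), 0)
  expect_lt(kaks_sensitivity(
    mod("antagonistic", sd = 0.05, alpha = 0, p0 = 1 / 60), "N"), 0)
  expect_lt(kaks_sensitivity(
    mod("antagonistic", sd = 0.05, alpha = 0, p0 = 1 / 60), "sd"), 0)
})

test_that("dominance orders purifying strength: h = 1 < 1/2 < 0", {
  r <- vapply(c(0, 0.5, 1), function(h)
    ka_ks(mod("antagonistic", sd = 0.05, h = h, alpha = 0,
              p0 = 1 / 60))$ka_ks, 0)
  expect_true(r[3] < r[2] && r[2] < r[1])
})

test_that("seed flow outweighs pollen flow at equal rates under selfing", {
  for (a in c(0.05, 0.5, 0.9)) {
    seeds <- mod(alpha = a, mS = 0.01, mP = 0)$derived$mtilde
    pollen <- mod(alpha = a, mS = 0, mP = 0.01)$derived$mtilde
    expect_gt(seeds, pollen)
  }
})

test_that("summary assembles rates and polymorphism coherently", {
  s <- summary(mod("antagonistic", sh = 0.03, sd = 0.05, alpha = 0.05,
                   mP = 0.01))
  expect_s3_class(s, "summary.phasesel")
  expect_equal(s$rate$ka_ks, s$rate$phi / s$rate$phi0, tolerance = 1e-12)
  expect_false(is.null(s$poly))
  expect_output(print(s), "pi_a")
  s0 <- summary(mod(sh = 0.03))
  expect_true(is.null(s0$poly))
  expect_output(print(s0), "transient")
})
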