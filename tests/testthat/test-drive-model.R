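# Analytic poison-antidote model: survival, tetrad expectations, MLE.

test_that("spore survival follows the poison-antidote rules", {
  k1 <- killerAllele("cw9", "k")
  expect_equal(sporeSurvivalProbability(c(k = "+"), list(k1)), 0)
  expect_equal(sporeSurvivalProbability(c(k = "cw9"), list(k1)), 1)

  # mutual killing: carrying one of two non-cross-resistant killers does not
  # protect against the other
  ka <- killerAllele("cw9", "a"); kb <- killerAllele("cw27", "b")
  expect_equal(
    sporeSurvivalProbability(c(a = "cw9", b = "+"), list(ka, kb)), 0)
  expect_equal(
    sporeSurvivalProbability(c(a = "cw9", b = "cw27"), list(ka, kb)), 1)

  # a killing-dead but protection-proficient allele (Td-like) harms no one
  td <- killerPreset("Td", "cw9-Td", "k")
  expect_equal(sporeSurvivalProbability(c(k = "+"), list(td)), 1)
  expect_equal(sporeSurvivalProbability(c(k = "cw9-Td"), list(td)), 1)

  # partial penetrance and partial protection multiply
  kp <- killerAllele("x", "k", kappa = 0.6, pi = 0.75)
  expect_equal(sporeSurvivalProbability(c(k = "+"), list(kp)), 0.4)
  expect_equal(sporeSurvivalProbability(c(k = "x"), list(kp)),
               1 - 0.6 * 0.25)

  expect_error(sporeSurvivalProbability(c(z = "+"), list(k1)), "locus 'k'")
})

test_that("tetrad outcome distributions match exact expectations", {
  # single fully penetrant het killer: every tetrad is 2 carriers viable,
  # 2 non-carriers dead
  d <- tetradOutcomeDistribution(hetKillerCross())
  expect_equal(unname(d), c(0, 0, 1, 0, 0))

  # no killers: all four spores viable
  noKiller <- crossConfig(
    data.frame(id = "m", chromosome = "I", position = 1e5),
    parent1 = c(m = "A"), parent2 = c(m = "B"))
  expect_equal(unname(tetradOutcomeDistribution(noKiller)),
               c(0, 0, 0, 0, 1))

  # two killers at the same locus in repulsion: every spore carries exactly
  # one killer and is killed by the other
  d0 <- tetradOutcomeDistribution(mutualKillerCross(linked = TRUE, r = 0))
  expect_equal(unname(d0), c(1, 0, 0, 0, 0))

  # distributions sum to 1 for an assortment of configurations
  for (cfg in assortedKillerConfigs())
    expect_lt(abs(sum(tetradOutcomeDistribution(cfg)) - 1), 1e-12)
})

test_that("expected viability matches enumeration-derived values", {
  expect_equal(expectedViability(hetKillerCross()), 0.5)
  # two unlinked het killers in repulsion: only double carriers survive
  expect_equal(expectedViability(mutualKillerCross()), 0.25)
  # both parents carry the same killer: viability normal
  sameKiller <- crossConfig(
    data.frame(id = "k", chromosome = "III", position = 1e6),
    parent1 = c(k = "cw9"), parent2 = c(k = "cw9"),
    killers = list(killerAllele("cw9", "k")))
  expect_equal(expectedViability(sameKiller), 1.0)
})

test_that("survival is monotone in kappa and pi over random configurations", {
  set.seed(101)
  for (rep in 1:25) {
    kap <- runif(1); pii <- runif(1)
    geno <- c(k = sample(c("+", "cw9"), 1))
    base <- sporeSurvivalProbability(
      geno, list(killerAllele("cw9", "k", kappa = kap, pi = pii)))
    upK <- sporeSurvivalProbability(
      geno, list(killerAllele("cw9", "k", kappa = min(kap + 0.2, 1), pi = pii)))
    upP <- sporeSurvivalProbability(
      geno, list(killerAllele("cw9", "k", kappa = kap, pi = min(pii + 0.2, 1))))
    expect_lte(upK, base + 1e-12)
    expect_gte(upP, base - 1e-12)
  }
})

test_that("expected viable allele frequency matches closed forms", {
  # marker unlinked to the killer stays at 50%
  loci <- data.frame(id = c("k", "m"), chromosome = c("III", "I"),
                     position = c(1e6, 1e6))
  cfg <- crossConfig(loci, parent1 = c(k = "+", m = "A"),
                     parent2 = c(k = "cw9", m = "B"),
                     killers = list(killerAllele("cw9", "k")))
  expect_equal(expectedViableAlleleFrequency(cfg, "m", "A"), 0.5)
  # at the killer locus all survivors are carriers
  expect_equal(expectedViableAlleleFrequency(cfg, "k", "+"), 0)
  # partial penetrance: carriers survive w.p. 1, non-carriers w.p. 1-kappa
  cfg6 <- hetKillerCross(kappa = 0.6)
  expect_equal(expectedViableAlleleFrequency(cfg6, "k", "+"),
               (1 - 0.6) / (2 - 0.6))
  # degenerate: nobody survives
  expect_error(
    expectedViableAlleleFrequency(mutualKillerCross(linked = TRUE, r = 0),
                                  "a", "cw9"),
    "no viable spores")
})

test_that("parent swap leaves expected viability unchanged", {
  for (cfg in assortedKillerConfigs()[c(1, 4, 7, 10)]) {
    swapped <- crossConfig(lociTable(cfg), cfg@parent2, cfg@parent1,
                           killers = cfg@killers)
    expect_equal(expectedViability(swapped), expectedViability(cfg))
  }
})

test_that("maximum-likelihood fitting recovers killer parameters", {
  # boundary MLE: all carriers viable, all non-carriers dead
  tt <- simulateMeiosisTetrads(hetKillerCross(), 100, seed = 3)
  fit <- fitKillerParameters(tt, list(killerAllele("cw9", "k")))
  expect_equal(fit$estimates$kappa, 1)
  expect_equal(fit$estimates$pi, 1)
  expect_true(fit$estimates$boundary)

  # recovery at interior values (parameter-recovery property at one point;
  # the full grid runs in the acceptance suite)
  cfg <- hetKillerCross(kappa = 0.8, pi = 1)
  tt <- simulateMeiosisTetrads(cfg, 500, seed = 4)
  fit <- fitKillerParameters(tt, list(killerAllele("cw9", "k")))
  expect_lt(abs(fit$estimates$kappa - 0.8), 0.05)

  # Tb-like data: carriers partially dying implies pi < 1, kappa near 1
  cfgTb <- hetKillerCross(kappa = 1, pi = 0.75)
  tt <- simulateMeiosisTetrads(cfgTb, 500, seed = 5)
  fit <- fitKillerParameters(tt, list(killerAllele("cw9", "k")))
  expect_lt(fit$estimates$pi, 1)
  expect_gt(fit$estimates$kappa, 0.9)

  # non-identifiable: when both parents carry the killer there are no
  # exposed non-carriers, so kappa is flagged
  sameKiller <- crossConfig(
    data.frame(id = "k", chromosome = "III", position = 1e6),
    parent1 = c(k = "cw9"), parent2 = c(k = "cw9"),
    killers = list(killerAllele("cw9", "k")))
  tt <- simulateMeiosisTetrads(sameKiller, 50, seed = 6)
  fit <- fitKillerParameters(tt, list(killerAllele("cw9", "k")))
  expect_false(fit$estimates$kappaIdentifiable)
  expect_true(fit$estimates$piIdentifiable)
})
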