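# Cross builders shared across tests.

# single heterozygous killer at one locus
hetKillerCross <- function(kappa = 1, pi = 1, id = "cw9") {
  crossConfig(
    loci = data.frame(id = "k", chromosome = "III", position = 1e6),
    parent1 = c(k = "+"), parent2 = c(k = id),
    killers = list(killerAllele(id, "k", kappa = kappa, pi = pi)))
}

# two killers with disjoint resistance sets, one per parent
mutualKillerCross <- function(linked = FALSE, r = 0.5,
                              kappa = c(1, 1), pi = c(1, 1)) {
  loci <- if (linked)
    data.frame(id = c("a", "b"), chromosome = "II", position = c(1e6, 1e6 + 1),
               recombFractionToNext = c(r, NA))
  else
    data.frame(id = c("a", "b"), chromosome = c("I", "II"),
               position = c(1e6, 1e6))
  crossConfig(loci,
              parent1 = c(a = "cw9", b = "+"), parent2 = c(a = "+", b = "cw27"),
              killers = list(
                killerAllele("cw9", "a", kappa = kappa[1], pi = pi[1]),
                killerAllele("cw27", "b", kappa = kappa[2], pi = pi[2])))
}

# killers from one parent on opposite arms of a chromosome III analog
twoArmKillerCross <- function(positions = c(0.45e6, 1.8e6),
                              chromLength = 2.4e6) {
  cfg <- crossConfig(
    data.frame(id = c("kL", "kR"), chromosome = "III", position = positions),
    parent1 = c(kL = "+", kR = "+"), parent2 = c(kL = "cwL", kR = "cwR"),
    killers = list(killerAllele("cwL", "kL"), killerAllele("cwR", "kR")))
  attr(cfg, "chromLengths") <- c(III = chromLength)
  cfg
}

# a deterministic assortment of killer configurations for property tests
assortedKillerConfigs <- function() {
  list(
    hetKillerCross(),
    hetKillerCross(kappa = 0.6),
    hetKillerCross(kappa = 0.8, pi = 0.5),
    hetKillerCross(kappa = 1, pi = 0.75),       # Tb-like
    hetKillerCross(kappa = 0, pi = 1),          # Td-like
    hetKillerCross(kappa = 1, pi = 0.5),        # Te-like
    mutualKillerCross(),
    mutualKillerCross(linked = TRUE, r = 0),
    mutualKillerCross(linked = TRUE, r = 0.2),
    mutualKillerCross(kappa = c(0.7, 0.9), pi = c(1, 0.8)),
    twoArmKillerCross())
}
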