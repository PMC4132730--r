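test_that("zero intensities yield no events and obligate CO then refuses", {
  cfg <- simulationConfig(lambda1 = 0, lambda2 = 0)
  set.seed(1)
  ev <- placeCrossovers(cfg, 500)
  expect_identical(nrow(ev), 0L)
  expect_error(simulationConfig(lambda1 = 0, lambda2 = 0, obligateCo = TRUE),
               "obligateCo")
  expect_error(simulationConfig(lambda1 = -1), "lambda1")
  expect_error(simulationConfig(nu = 0), "nu")
  expect_error(simulationConfig(markerPositions = c(0.2, 0.2, 0.3)),
               "increasing")
})

test_that("class I placement is Poisson at nu = 1 and more regular at larger nu", {
  set.seed(11)
  cfg <- simulationConfig(lambda1 = 2, lambda2 = 0, nu = 1)
  ev <- placeCrossovers(cfg, 10000)
  counts <- tabulate(ev$meiosis, 10000)
  # mean count within 3 SE of lambda1 = 2 (Poisson variance)
  expect_lt(abs(mean(counts) - 2), 3 * sqrt(2 / 10000))

  # pooled inter-event spacings on a long window are exponential(rate 2)
  long <- simulationConfig(markerPositions = c(1, 2, 3), chromLength = 100,
                           lambda1 = 200, lambda2 = 0, nu = 1)
  evl <- placeCrossovers(long, 50)
  gaps1 <- unlist(tapply(evl$position, evl$meiosis, diff), use.names = FALSE)
  expect_gt(ks.test(gaps1, "pexp", 2)$p.value, 0.01)

  # gamma-renewal spacing CV at nu = 10 is below the Poisson CV
  long10 <- simulationConfig(markerPositions = c(1, 2, 3), chromLength = 100,
                             lambda1 = 200, lambda2 = 0, nu = 10)
  evl10 <- placeCrossovers(long10, 50)
  gaps10 <- unlist(tapply(evl10$position, evl10$meiosis, diff),
                   use.names = FALSE)
  expect_lt(sd(gaps10) / mean(gaps10), sd(gaps1) / mean(gaps1))
  # theoretical CV is 1/sqrt(nu)
  expect_lt(abs(sd(gaps10) / mean(gaps10) - 1 / sqrt(10)), 0.05)
})

test_that("event positions are stationary (uniform) for Poisson and gamma shapes", {
  set.seed(12)
  for (nuVal in c(1, 10, 2.5)) {
    cfg <- simulationConfig(lambda1 = 2, lambda2 = 0, nu = nuVal)
    ev <- placeCrossovers(cfg, 10000)
    expect_gt(ks.test(ev$position, "punif", 0, 1)$p.value, 0.01)
    expect_lt(abs(nrow(ev) / 10000 - 2), 3 * sqrt(2 / 10000) * max(1, nuVal))
  }
})

test_that("chromatid choice is uniform over the four pairs and independent between events", {
  set.seed(13)
  ev <- data.frame(meiosis = 1:10000, position = 0.5, pathway = "class_I")
  ev <- resolveChromatids(ev)
  tab <- table(ev$chromatidM, ev$chromatidP)
  expect_true(all(abs(tab / 10000 - 0.25) < 3 * sqrt(0.25 * 0.75 / 10000)))

  ev2 <- data.frame(meiosis = rep(1:10000, each = 2),
                    position = rep(c(0.3, 0.7), 10000),
                    pathway = "class_I")
  ev2 <- resolveChromatids(ev2)
  pair <- paste0(ev2$chromatidM, ev2$chromatidP)
  first <- pair[seq(1, length(pair), by = 2)]
  second <- pair[seq(2, length(pair), by = 2)]
  expect_gt(chisq.test(table(first, second))$p.value, 0.01)

  expect_identical(nrow(resolveChromatids(ev[0, ])), 0L)
})

test_that("generated tetrads show Mendelian 2:2 segregation at every locus", {
  for (s in 1:3) {
    cfg <- simulationConfig(nu = c(1, 7, 2.5)[s], lambda1 = 2, lambda2 = 1,
                            nMeioses = 2000, seed = s,
                            markerPhase = if (s == 2) "repulsion"
                                          else "coupling")
    al <- sporeAlleles(simulateTetrads(cfg))
    perLocus <- apply(al, c(2, 3), sum)
    expect_true(all(perLocus == 2L))
  }
})

test_that("chromatid tracing matches hand-traced single-crossover diagrams", {
  cfg <- simulationConfig(nMeioses = 1)
  # no events: parental ditype, two fluorescent and two dark spores
  tet0 <- generateTetrads(cfg, data.frame(meiosis = integer(),
                                          position = numeric(),
                                          chromatidM = integer(),
                                          chromatidP = integer()), 1)
  al0 <- sporeAlleles(tet0)[, , 1]
  expect_identical(colSums(al0), c(2, 2, 2))
  expect_identical(sum(rowSums(al0) == 3), 2L)

  # one CO between markers 1 and 2 on (maternal 1, paternal 1):
  # tetratype in the first interval, parental ditype in the second
  ev <- data.frame(meiosis = 1L, position = 0.45,
                   chromatidM = 1L, chromatidP = 1L)
  tet1 <- generateTetrads(cfg, ev, 1)
  expect_identical(as.character(intervalType(tet1, 1)), "TT")
  expect_identical(as.character(intervalType(tet1, 2)), "PD")

  # unsorted events are rejected
  ev2 <- data.frame(meiosis = c(1L, 1L), position = c(0.6, 0.45),
                    chromatidM = c(1L, 1L), chromatidP = c(1L, 2L))
  expect_error(generateTetrads(cfg, ev2, 1), "sorted")
  expect_error(generateTetrads(cfg, ev[, c("meiosis", "position")], 1),
               "chromatid")
})

test_that("vectorised tracer agrees with an independent molecule-following oracle", {
  set.seed(14)
  cfg <- simulationConfig(nu = 3, lambda1 = 3, lambda2 = 1, nMeioses = 400)
  ev <- resolveChromatids(placeCrossovers(cfg, 400))
  tet <- generateTetrads(cfg, ev, 400)
  for (i in seq_len(400)) {
    evm <- ev[ev$meiosis == i, , drop = FALSE]
    expect_identical(unname(sporeAlleles(tet)[, , i]),
                     oracleTetradAlleles(evm, cfg@markerPositions))
  }
})

test_that("population simulation is deterministic under the config seed", {
  cfg <- simulationConfig(nMeioses = 500, seed = 99, lambda2 = 0.5)
  t1 <- simulateTetrads(cfg)
  t2 <- simulateTetrads(cfg)
  expect_identical(sporeAlleles(t1), sporeAlleles(t2))
  expect_identical(serialize(t1, NULL), serialize(t2, NULL))
  m1 <- simulateMeiocytes(cfg)
  m2 <- simulateMeiocytes(cfg)
  expect_identical(m1, m2)
})

test_that("Perkins estimate recovers small marker distances and grows with lambda2", {
  cfg <- simulationConfig(markerPositions = c(0.40, 0.45, 0.55),
                          nu = 1, lambda1 = 2, lambda2 = 0,
                          nMeioses = 50000, seed = 21)
  d <- mapDistances(tallyTetrads(simulateTetrads(cfg)))
  expect_lt(abs(cM(d[[1]]) - 5), 3 * sqrt(mapVar(d[[1]])))
  expect_lt(abs(cM(d[[2]]) - 10), 3 * sqrt(mapVar(d[[2]])))

  base <- simulationConfig(nu = 5, lambda1 = 1, lambda2 = 1,
                           nMeioses = 50000, seed = 22)
  dbl <- simulationConfig(nu = 5, lambda1 = 1, lambda2 = 2,
                          nMeioses = 50000, seed = 23)
  d1 <- cM(mapDistances(tallyTetrads(simulateTetrads(base)))[[1]])
  d2 <- cM(mapDistances(tallyTetrads(simulateTetrads(dbl)))[[1]])
  expect_gt(d2, d1)
})

test_that("obligate-CO rejection sampling equals conditioning on at least one event", {
  set.seed(15)
  cfgFree <- simulationConfig(lambda1 = 0.3, lambda2 = 0, nu = 1)
  cfgObl <- simulationConfig(lambda1 = 0.3, lambda2 = 0, nu = 1,
                             obligateCo = TRUE)
  evF <- placeCrossovers(cfgFree, 20000)
  evO <- placeCrossovers(cfgObl, 20000)
  expect_identical(sum(tabulate(evO$meiosis, 20000) == 0L), 0L)
  # conditional sampling: keep meioses that happened to draw >= 1 event
  expect_gt(ks.test(evO$position, evF$position)$p.value, 0.01)
  cntO <- tabulate(evO$meiosis, 20000)
  cntF <- tabulate(evF$meiosis, 20000)
  tabO <- table(factor(cntO, levels = 1:6))
  tabF <- table(factor(cntF[cntF > 0], levels = 1:6))
  keep <- tabO + tabF > 5
  expect_gt(suppressWarnings(
    chisq.test(rbind(tabO[keep], tabF[keep]))$p.value), 0.01)
})

test_that("meiocyte bivalent counts follow the Poisson void probability", {
  obl <- simulationConfig(lambda1 = 1.8, lambda2 = 0.2, nu = 7,
                          obligateCo = TRUE, nChromPairs = 5L,
                          nMeioses = 1000, seed = 30)
  mc <- simulateMeiocytes(obl)
  expect_true(all(mc$bivalents == 5L))
  expect_true(all(mc$bivalents + mc$univalentPairs == 5L))

  none <- simulationConfig(lambda1 = 0, lambda2 = 0, nMeioses = 200,
                           seed = 31)
  expect_true(all(simulateMeiocytes(none)$bivalents == 0L))

  lam <- 0.8
  cfg <- simulationConfig(lambda1 = lam / 2, lambda2 = lam / 2, nu = 1,
                          nMeioses = 20000, seed = 32)
  mc2 <- simulateMeiocytes(cfg)
  expected <- 5 * (1 - exp(-lam))
  se <- sd(mc2$bivalents) / sqrt(20000)
  expect_lt(abs(mean(mc2$bivalents) - expected), 3 * se)
})

test_that("coefficient of coincidence is 1 without interference and below 1 with", {
  recBoth <- function(cc) {
    jc <- jointCounts(cc)
    r1 <- c(FALSE, TRUE, TRUE)
    n <- sum(jc)
    p11 <- sum(jc[r1, r1]) / n
    p1 <- sum(jc[r1, ]) / n
    p2 <- sum(jc[, r1]) / n
    list(coc = p11 / (p1 * p2),
         chisqP = suppressWarnings(chisq.test(rbind(
           c(sum(jc[r1, r1]), sum(jc[r1, !r1])),
           c(sum(jc[!r1, r1]), sum(jc[!r1, !r1]))))$p.value))
  }
  free <- recBoth(tallyTetrads(simulateTetrads(
    simulationConfig(nu = 1, lambda1 = 2, lambda2 = 0,
                     nMeioses = 50000, seed = 40))))
  expect_gt(free$chisqP, 0.001)
  expect_lt(abs(free$coc - 1), 0.2)

  interf <- recBoth(tallyTetrads(simulateTetrads(
    simulationConfig(nu = 10, lambda1 = 2, lambda2 = 0,
                     nMeioses = 50000, seed = 41))))
  expect_lt(interf$coc, 1)
  expect_lt(interf$chisqP, 0.001)
})
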