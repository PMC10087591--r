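# Forward-time metapopulation simulator: construction contracts,
# transmission genetics, dispersal bookkeeping, conservation and closure.

test_that("simulation parameters are validated field by field", {
  expect_s3_class(sim_params(), "sim_params")
  expect_error(sim_params(subpop_size = 11), "even")
  expect_error(sim_params(subpop_size = 2), ">= 4")
  expect_error(sim_params(d = 1.5), "`d`")
  expect_error(sim_params(r = 0.7), "`r`")
  expect_error(sim_params(q0 = -0.1), "`q0`")
  expect_error(sim_params(beta = Inf), "finite")
  expect_error(sim_params(generations = 0), "generations")
  expect_error(sim_params(perception = "psychic"), "arg")
})

test_that("initialisation fills subpopulations with balanced sexes and unlinked loci", {
  p <- sim_params(n_subpop = 4, subpop_size = 10, q0 = 0.3, seed = 1)
  set.seed(1)
  m <- init_metapopulation(p)
  expect_length(m$subpop, 40)
  expect_equal(sum(m$male), 20)
  expect_equal(as.vector(table(m$subpop)), rep(10, 4))
  for (s in 1:4) expect_equal(sum(m$male[m$subpop == s]), 5)

  # q0 = 0 boundary: no conformity allele anywhere
  set.seed(2)
  m0 <- init_metapopulation(sim_params(n_subpop = 4, subpop_size = 10, q0 = 0))
  expect_true(all(m0$pref == 0L))

  # expected 50:50 trait allocation over many independent initialisations
  set.seed(test_seed(20))
  freqs <- replicate(400, mean(init_metapopulation(p)$trait))
  se <- sd(freqs) / sqrt(length(freqs))
  expect_lt(abs(mean(freqs) - 0.5), 4 * se)
})

test_that("perceived frequency counts males or realised matings", {
  set.seed(3)
  m <- init_metapopulation(sim_params(n_subpop = 2, subpop_size = 10))
  m$trait[m$subpop == 1 & m$male] <- c(1L, 1L, 1L, 0L, 0L)
  expect_equal(perceived_frequency(m, 1, "male-frequency"), 0.6)
  expect_equal(perceived_frequency(m, 1, "mating-observation",
                                   matings = c(1L, 1L, 0L)), 2 / 3)
  # first chooser falls back to the standing male frequency
  expect_equal(perceived_frequency(m, 1, "mating-observation"), 0.6)
  m$trait[m$subpop == 2 & m$male] <- 1L
  expect_equal(perceived_frequency(m, 2, "male-frequency"), 1)
})

test_that("mate choice follows the conformist rule and falls back gracefully", {
  males <- c(1L, 0L) # one male of each display trait
  rule <- logistic_rule(2.8)

  set.seed(test_seed(21))
  n <- 2e4
  # non-conformist females: uniform over males
  picks <- replicate(n, choose_mate(FALSE, males, 0.6, rule))
  expect_lt(abs(mean(picks == 1L) - 0.5), 4 * sqrt(0.25 / n))

  # conformist at the symmetry point: trait A targeted half the time
  picks <- replicate(n, choose_mate(TRUE, males, 0.5, rule))
  expect_lt(abs(mean(picks == 1L) - 0.5), 4 * sqrt(0.25 / n))

  # conformist at q = 0.6, beta = 2.8: A targeted with the logistic probability
  pA <- 0.6^2.8 / (0.6^2.8 + 0.4^2.8)
  picks <- replicate(n, choose_mate(TRUE, males, 0.6, rule))
  expect_lt(abs(mean(picks == 1L) - pA), 4 * sqrt(pA * (1 - pA) / n))

  # no male of the target trait: uniform fallback never errors
  picks <- replicate(200, choose_mate(TRUE, c(0L, 0L, 0L), 0.9, rule))
  expect_true(all(picks %in% 1:3))
  expect_error(choose_mate(TRUE, integer(0), 0.5, rule), "no males")
})

test_that("two-locus transmission has the stated haplotype probabilities", {
  # no segregating variation: offspring equal the parents whatever r is
  set.seed(test_seed(22))
  for (r in c(0, 0.2, 0.5)) {
    kids <- reproduce(c(1L, 1L), c(1L, 1L), r)
    expect_equal(unname(kids$son), c(1L, 1L))
    expect_equal(unname(kids$daughter), c(1L, 1L))
  }

  # full linkage: offspring haplotype is always one parental haplotype
  for (i in 1:200) {
    kids <- reproduce(c(0L, 1L), c(1L, 0L), r = 0)
    expect_true(all(sum(kids$son) != 1 | identical(unname(kids$son), c(0L, 1L)) |
                      identical(unname(kids$son), c(1L, 0L))))
    expect_true(identical(unname(kids$son), c(0L, 1L)) ||
                  identical(unname(kids$son), c(1L, 0L)))
  }

  # mother (B, C), father (A, c), r = 0.2: haplotype law
  # (B,C) 0.4, (A,c) 0.4, (B,c) 0.1, (A,C) 0.1
  n <- 4e4
  hap <- character(n)
  for (i in seq_len(n)) {
    k <- reproduce(c(0L, 1L), c(1L, 0L), r = 0.2)$son
    hap[i] <- paste0(k[1L], k[2L])
  }
  emp <- table(factor(hap, levels = c("01", "10", "00", "11"))) / n
  expected <- c(`01` = 0.4, `10` = 0.4, `00` = 0.1, `11` = 0.1)
  for (h in names(expected)) {
    tol <- 4 * sqrt(expected[[h]] * (1 - expected[[h]]) / n)
    expect_lt(abs(emp[[h]] - expected[[h]]), tol)
  }
})

test_that("dispersal conserves subpopulation sizes and the flagged-migrant rate", {
  p <- sim_params(n_subpop = 20, subpop_size = 50, d = 0.02)
  set.seed(test_seed(23))
  m <- init_metapopulation(p)

  # d = 0: membership untouched
  m0 <- disperse(m, 0)
  expect_identical(m0$subpop, m$subpop)

  # d = 1: everyone is a migrant, but sizes and sex counts are conserved
  m1 <- disperse(m, 1)
  expect_equal(attr(m1, "n_migrants"), 1000L)
  expect_equal(as.vector(table(m1$subpop)), rep(50, 20))
  for (s in 1:20) expect_equal(sum(m1$male[m1$subpop == s]), 25)

  # expected migrants N*d over many draws, within binomial tolerance
  mig <- replicate(300, attr(disperse(m, 0.02), "n_migrants"))
  se <- sqrt(1000 * 0.02 * 0.98 / 300)
  expect_lt(abs(mean(mig) - 20), 4 * se)
})

test_that("a generation step conserves size and sex ratio and respects closure", {
  p <- sim_params(n_subpop = 5, subpop_size = 12, beta = 2.8, d = 0.1,
                  q0 = 0.3, generations = 1)
  set.seed(test_seed(24))
  m <- init_metapopulation(p)
  for (t in 1:20) {
    m <- step_generation(m, p)
    expect_equal(as.vector(table(m$subpop)), rep(12, 5))
    for (s in 1:5) expect_equal(sum(m$male[m$subpop == s]), 6)
    expect_equal(m$generation, t)
  }

  # closure: q0 = 0 means C can never appear
  p0 <- sim_params(n_subpop = 3, subpop_size = 10, q0 = 0, generations = 1)
  m <- init_metapopulation(p0)
  for (t in 1:15) {
    m <- step_generation(m, p0)
    expect_true(all(m$pref == 0L))
  }

  # closure: a fixed display trait stays fixed
  m <- init_metapopulation(p)
  m$trait[] <- 1L
  for (t in 1:10) {
    m <- step_generation(m, p)
    expect_true(all(m$trait == 1L))
  }
})

test_that("simulations are reproducible and record every generation and subpopulation", {
  p <- sim_params(n_subpop = 3, subpop_size = 8, generations = 25, seed = 77)
  r1 <- run_simulation(p)
  r2 <- run_simulation(p)
  expect_identical(r1$records, r2$records)
  expect_equal(nrow(r1$records), 25 * 3)
  expect_true(all(r1$records$freq_A_males >= 0 & r1$records$freq_A_males <= 1))
  expect_true(all(r1$records$freq_C_females >= 0 & r1$records$freq_C_females <= 1))

  # a different seed gives a different trajectory
  p2 <- p
  p2$seed <- 78L
  expect_false(identical(run_simulation(p2)$records, r1$records))

  # the caller's RNG stream is left untouched
  set.seed(5)
  before <- .Random.seed
  invisible(run_simulation(p))
  expect_identical(.Random.seed, before)

  # mating-observation perception runs and conserves too
  pm <- sim_params(n_subpop = 3, subpop_size = 8, generations = 10,
                   perception = "mating-observation", seed = 5)
  rm_ <- run_simulation(pm)
  expect_identical(run_simulation(pm)$records, rm_$records)
})

test_that("summaries compute end-state statistics from the records", {
  fake <- structure(list(records = data.frame(
    generation = c(1, 1, 2, 2),
    subpop = c(1, 2, 1, 2),
    freq_A_males = c(0.5, 0.5, 0, 1),
    freq_C_females = c(0.2, 0.4, 0.3, 0.5),
    cov_trait_pref = 0), params = NULL, seed = 1), class = "sim_result")
  s <- summary(fake)
  expect_equal(s$final_freq_C, 0.4)
  expect_equal(s$final_freq_A_by_subpop, c(0, 1))
  expect_equal(s$var_among_subpop_freq_A, 0.25)
  expect_equal(s$n_polymorphic_subpops, 0)

  one <- fake
  one$records <- data.frame(generation = 1, subpop = 1, freq_A_males = 1,
                            freq_C_females = 0.1, cov_trait_pref = 0)
  s1 <- summary(one)
  expect_equal(s1$var_among_subpop_freq_A, 0)
  expect_equal(s1$n_polymorphic_subpops, 0)
})

test_that("sweeps derive distinct reproducible seeds per cell and replicate", {
  base <- sim_params(n_subpop = 2, subpop_size = 8, generations = 10)
  sw <- run_sweep(2, 0.1, replicates = 3, base_params = base, base_seed = 13)
  expect_s3_class(sw, "sweep_result")
  expect_equal(nrow(sw), 3)
  expect_equal(length(unique(sw$seed)), 3)
  sw2 <- run_sweep(2, 0.1, replicates = 3, base_params = base, base_seed = 13)
  expect_identical(as.data.frame(sw), as.data.frame(sw2))

  sw3 <- run_sweep(c(1, 2), c(0.1, 0.4), replicates = 2, base_params = base,
                   base_seed = 13)
  expect_equal(nrow(sw3), 8)
  expect_equal(length(unique(sw3$seed)), 8)
  expect_error(run_sweep(2, 0.1, 0, base, 1), ">= 1")
})
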