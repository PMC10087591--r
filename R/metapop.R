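#' Simulation parameters for the gene-culture metapopulation model
#'
#' Bundles and validates the parameters of the two-locus forward-time
#' simulator. Individuals are haploid carriers of two unlinked diallelic
#' loci: a male-expressed, selectively neutral display trait (alleles A/B)
#' and a female-expressed mate-choice locus (alleles C/c). Females carrying
#' `c` mate with a uniformly random local male; females carrying `C` choose
#' the display trait by the logistic conformist rule with strength `beta`
#' (and error rate `alpha`), then mate with a random local male of that
#' trait. Each female leaves exactly one son and one daughter;
#' non-overlapping generations; a fraction `d` of offspring then disperses
#' among subpopulations, sex-balanced.
#'
#' @param n_subpop Number of subpopulations (>= 1).
#' @param subpop_size Individuals per subpopulation (even, >= 4; half of
#'   each sex).
#' @param beta Conformity strength of C females (any finite real).
#' @param d Dispersal fraction in \eqn{[0, 1]}.
#' @param r Recombination rate in \eqn{[0, 0.5]}: the probability that an
#'   offspring inherits its trait allele and its preference allele from
#'   different parents.
#' @param q0 Initial frequency of the conformity allele C in \eqn{[0, 1]}.
#' @param alpha Choice error rate of C females in \eqn{[0, 1]} (default 0).
#' @param generations Number of generations to simulate (>= 1).
#' @param perception How a conformist female perceives the trait frequency
#'   `q`: `"male-frequency"` (default; the standing frequency of A among her
#'   subpopulation's adult males) or `"mating-observation"` (the frequency
#'   of A among matings already realised this generation in her
#'   subpopulation, falling back to the male frequency for the first
#'   chooser).
#' @param seed Integer seed; the whole run is reproducible from it.
#' @return A validated list of class `sim_params`.
#' @export
sim_params <- function(n_subpop = 20, subpop_size = 50, beta = 2.8,
                       d = 0.02, r = 0.2, q0 = 0.2, alpha = 0,
                       generations = 500,
                       perception = c("male-frequency", "mating-observation"),
                       seed = 1) {
  n_subpop <- check_count(n_subpop, "n_subpop", 1)
  subpop_size <- check_count(subpop_size, "subpop_size", 4)
  if (subpop_size %% 2L != 0L) {
    stop("`subpop_size` must be even (equal numbers of males and females); got ",
         subpop_size, call. = FALSE)
  }
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta)) {
    stop("`beta` must be a single finite number", call. = FALSE)
  }
  d <- check_unit_interval(d, "d")
  if (!is.numeric(r) || length(r) != 1L || !is.finite(r) || r < 0 || r > 0.5) {
    stop("`r` must be in [0, 0.5]; got ", format(r), call. = FALSE)
  }
  q0 <- check_unit_interval(q0, "q0")
  alpha <- check_unit_interval(alpha, "alpha")
  generations <- check_count(generations, "generations", 1)
  perception <- match.arg(perception)
  seed <- check_count(seed, "seed", 0)
  structure(list(n_subpop = n_subpop, subpop_size = subpop_size, beta = beta,
                 d = d, r = r, q0 = q0, alpha = alpha,
                 generations = generations, perception = perception,
                 seed = seed),
            class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat(sprintf(
    "Metapopulation parameters: %d subpops x %d, beta = %g, d = %g, r = %g, q0 = %g, alpha = %g, %d generations, perception = %s, seed = %d\n",
    x$n_subpop, x$subpop_size, x$beta, x$d, x$r, x$q0, x$alpha,
    x$generations, x$perception, x$seed))
  invisible(x)
}

#' Initialise a metapopulation
#'
#' Creates the founding generation: each subpopulation gets exactly half
#' males and half females; trait alleles A/B are allocated independently at
#' expected 50:50 metapopulation-wide; the conformity allele C is allocated
#' independently with probability `q0` — the two loci start neither
#' physically nor statistically linked. Draws from the current R random
#' stream (seed the stream, or use [run_simulation()] which seeds it from
#' `params$seed`).
#'
#' @param params A [sim_params()] object.
#' @return A `metapopulation` object: parallel vectors `subpop`, `male`
#'   (logical), `trait` (1 = A, 0 = B), `pref` (1 = C, 0 = c), plus the
#'   generation counter.
#' @export
init_metapopulation <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  n <- params$n_subpop * params$subpop_size
  half <- params$subpop_size %/% 2L
  structure(list(
    subpop = rep(seq_len(params$n_subpop), each = params$subpop_size),
    male = rep(rep(c(TRUE, FALSE), each = half), times = params$n_subpop),
    trait = stats::rbinom(n, 1L, 0.5),
    pref = stats::rbinom(n, 1L, params$q0),
    n_subpop = params$n_subpop,
    subpop_size = params$subpop_size,
    generation = 0L), class = "metapopulation")
}

#' @export
print.metapopulation <- function(x, ...) {
  cat(sprintf(
    "Metapopulation: %d subpops x %d individuals, generation %d\n  freq(A) among males = %.3f, freq(C) among females = %.3f\n",
    x$n_subpop, x$subpop_size, x$generation,
    mean(x$trait[x$male]), mean(x$pref[!x$male])))
  invisible(x)
}

#' Trait frequency perceived by a conformist female
#'
#' Returns the frequency of display trait A that a conformist female in
#' subpopulation `subpop_id` observes. In `"male-frequency"` mode this is
#' the standing proportion of A among the subpopulation's adult males; in
#' `"mating-observation"` mode it is the proportion of A among the father
#' traits in `matings` (the matings already realised this generation in
#' this subpopulation), falling back to the male frequency when no mating
#' has happened yet.
#'
#' @param metapop A `metapopulation`.
#' @param subpop_id Subpopulation index.
#' @param mode `"male-frequency"` or `"mating-observation"`.
#' @param matings Integer vector of father trait values (1 = A, 0 = B) of
#'   realised matings this generation.
#' @return The perceived frequency of A, in \eqn{[0, 1]}.
#' @export
perceived_frequency <- function(metapop, subpop_id,
                                mode = c("male-frequency", "mating-observation"),
                                matings = integer(0)) {
  mode <- match.arg(mode)
  male_traits <- metapop$trait[metapop$male & metapop$subpop == subpop_id]
  if (length(male_traits) == 0L) {
    stop("subpopulation ", subpop_id, " has no males", call. = FALSE)
  }
  if (mode == "mating-observation" && length(matings) > 0L) {
    mean(matings)
  } else {
    mean(male_traits)
  }
}

#' Mate choice of a single female
#'
#' A non-conformist (c) female picks a uniformly random male. A conformist
#' (C) female first draws a target display trait — A with probability
#' [logistic_prob()] of the perceived frequency `q` under `rule` — then
#' picks a uniformly random male of that trait; if no male of the target
#' trait is present she falls back to a uniformly random male. When `q` is
#' 0 or 1, only one display trait is on offer and the choice reduces to a
#' uniform draw among the available males (the conformist target, or its
#' error-driven alternative, cannot be distinguished or is absent). Males
#' may mate any number of times.
#'
#' @param conformist `TRUE` for a C female, `FALSE` for a c female.
#' @param male_traits Integer vector of the local males' display traits
#'   (1 = A, 0 = B).
#' @param q Perceived frequency of A.
#' @param rule A [logistic_rule()].
#' @return The index of the chosen male within `male_traits`.
#' @export
choose_mate <- function(conformist, male_traits, q, rule) {
  nm <- length(male_traits)
  if (nm == 0L) stop("no males to choose from", call. = FALSE)
  if (!conformist || q <= 0 || q >= 1) {
    return(sample.int(nm, 1L))
  }
  target <- as.integer(stats::runif(1L) < logistic_prob(q, rule))
  cand <- which(male_traits == target)
  if (length(cand) == 0L) return(sample.int(nm, 1L))
  cand[sample.int(length(cand), 1L)]
}

## Vectorised two-locus transmission for n matings -> n offspring.
## Each offspring independently: with prob 1-r both alleles from one
## uniformly chosen parent; with prob r the trait allele from one uniformly
## chosen parent and the preference allele from the other.
transmit <- function(t_mother, p_mother, t_father, p_father, r) {
  n <- length(t_mother)
  recomb <- stats::runif(n) < r
  from_mother <- stats::runif(n) < 0.5
  trait <- ifelse(from_mother, t_mother, t_father)
  pref <- ifelse(from_mother != recomb, p_mother, p_father)
  list(trait = as.integer(trait), pref = as.integer(pref))
}

#' Reproduction of one mated pair
#'
#' Produces exactly one son and one daughter. Each offspring independently
#' inherits, with probability `1 - r`, both alleles from one uniformly
#' chosen parent (a parental haplotype) and, with probability `r`, the
#' trait allele from one uniformly chosen parent and the preference allele
#' from the other (a recombinant haplotype).
#'
#' @param mother,father Length-2 integer vectors `c(trait, pref)` with
#'   1 = A/C and 0 = B/c.
#' @param r Recombination rate in \eqn{[0, 0.5]}.
#' @return A list with elements `son` and `daughter`, each `c(trait, pref)`.
#' @export
reproduce <- function(mother, father, r) {
  stopifnot(length(mother) == 2L, length(father) == 2L, r >= 0, r <= 0.5)
  kids <- transmit(rep(mother[1L], 2L), rep(mother[2L], 2L),
                   rep(father[1L], 2L), rep(father[2L], 2L), r)
  list(son = c(trait = kids$trait[1L], pref = kids$pref[1L]),
       daughter = c(trait = kids$trait[2L], pref = kids$pref[2L]))
}

#' Sex-balanced dispersal among subpopulations
#'
#' Every individual is independently flagged as a migrant with probability
#' `d`; within each sex, migrants are then randomly permuted across all the
#' slots vacated by migrants of that sex metapopulation-wide (males take
#' male slots, females female slots), so subpopulation sizes and sex ratios
#' are conserved exactly. A migrant may land back in its origin
#' subpopulation with probability of order 1 over the number of
#' subpopulations.
#'
#' @param metapop A `metapopulation`.
#' @param d Dispersal fraction in \eqn{[0, 1]}.
#' @return The metapopulation with reassigned subpopulation labels; the
#'   number of flagged migrants is attached as attribute `n_migrants`.
#' @export
disperse <- function(metapop, d) {
  if (d <= 0 || metapop$n_subpop == 1L) {
    attr(metapop, "n_migrants") <- 0L
    return(metapop)
  }
  migrant <- stats::runif(length(metapop$subpop)) < d
  for (sex in c(TRUE, FALSE)) {
    idx <- which(migrant & metapop$male == sex)
    if (length(idx) > 1L) {
      metapop$subpop[idx] <- metapop$subpop[idx][sample.int(length(idx))]
    }
  }
  attr(metapop, "n_migrants") <- sum(migrant)
  metapop
}

#' Advance the metapopulation by one generation
#'
#' Runs one full life cycle: in each subpopulation every female chooses a
#' mate ([choose_mate()]) using her perceived trait frequency
#' ([perceived_frequency()]), produces one son and one daughter
#' ([reproduce()] semantics, vectorised), the offspring generation replaces
#' the parents entirely, and offspring then disperse ([disperse()]). Under
#' `"mating-observation"` perception, females choose sequentially in a
#' uniformly shuffled order, each observing the matings realised before
#' hers.
#'
#' @param metapop A `metapopulation`.
#' @param params The [sim_params()] of the run.
#' @return The next-generation `metapopulation`.
#' @export
step_generation <- function(metapop, params) {
  rule <- logistic_rule(params$beta, params$alpha)
  n <- length(metapop$subpop)
  half <- params$subpop_size %/% 2L
  mother_t <- integer(0); mother_p <- integer(0)
  father_t <- integer(0); father_p <- integer(0)
  kid_subpop <- integer(0)
  for (s in seq_len(params$n_subpop)) {
    in_s <- metapop$subpop == s
    midx <- which(in_s & metapop$male)
    fidx <- which(in_s & !metapop$male)
    mt <- metapop$trait[midx]
    q <- mean(mt)
    conf <- metapop$pref[fidx] == 1L
    nf <- length(fidx)
    fathers <- integer(nf) # indices into midx
    if (params$perception == "male-frequency") {
      rnd <- !conf | q <= 0 | q >= 1
      if (any(rnd)) fathers[rnd] <- sample.int(length(midx), sum(rnd), replace = TRUE)
      if (any(!rnd)) {
        pA <- logistic_prob(q, rule)
        target <- as.integer(stats::runif(sum(!rnd)) < pA)
        a_males <- which(mt == 1L)
        b_males <- which(mt == 0L)
        pick <- integer(sum(!rnd))
        is_a <- target == 1L
        if (any(is_a)) pick[is_a] <- a_males[sample.int(length(a_males), sum(is_a), replace = TRUE)]
        if (any(!is_a)) pick[!is_a] <- b_males[sample.int(length(b_males), sum(!is_a), replace = TRUE)]
        fathers[!rnd] <- pick
      }
    } else {
      order_f <- sample.int(nf)
      seen <- integer(0)
      for (j in order_f) {
        qj <- if (length(seen) > 0L) mean(seen) else q
        fathers[j] <- choose_mate(conf[j], mt, qj, rule)
        seen <- c(seen, mt[fathers[j]])
      }
    }
    fg <- midx[fathers]
    mother_t <- c(mother_t, metapop$trait[fidx])
    mother_p <- c(mother_p, metapop$pref[fidx])
    father_t <- c(father_t, metapop$trait[fg])
    father_p <- c(father_p, metapop$pref[fg])
    kid_subpop <- c(kid_subpop, rep.int(s, nf))
  }
  sons <- transmit(mother_t, mother_p, father_t, father_p, params$r)
  daughters <- transmit(mother_t, mother_p, father_t, father_p, params$r)
  nf_tot <- length(kid_subpop)
  offspring <- list(
    subpop = c(kid_subpop, kid_subpop),
    male = rep(c(TRUE, FALSE), each = nf_tot),
    trait = c(sons$trait, daughters$trait),
    pref = c(sons$pref, daughters$pref),
    n_subpop = metapop$n_subpop,
    subpop_size = metapop$subpop_size,
    generation = metapop$generation + 1L)
  class(offspring) <- "metapopulation"
  # restore canonical ordering by subpopulation for readability
  ord <- order(offspring$subpop, !offspring$male)
  offspring$subpop <- offspring$subpop[ord]
  offspring$male <- offspring$male[ord]
  offspring$trait <- offspring$trait[ord]
  offspring$pref <- offspring$pref[ord]
  disperse(offspring, params$d)
}
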