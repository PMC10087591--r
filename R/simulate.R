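#' Run a metapopulation simulation
#'
#' Initialises a metapopulation from `params`, iterates [step_generation()]
#' for `params$generations` generations, and records, for every generation
#' and subpopulation, the frequency of display allele A among males, the
#' frequency of conformity allele C among females, and the within-
#' subpopulation covariance between the trait and preference alleles (the
#' statistical linkage disequilibrium that fuels the Fisher runaway). The
#' run is fully reproducible from `params` (including `params$seed`) and
#' leaves the caller's random stream untouched.
#'
#' @param params A [sim_params()] object.
#' @return An object of class `sim_result`: a list with `records` (a
#'   `data.frame` with columns `generation`, `subpop`, `freq_A_males`,
#'   `freq_C_females`, `cov_trait_pref`), `params`, and `seed`.
#' @examples
#' res <- run_simulation(sim_params(n_subpop = 4, subpop_size = 10,
#'                                  generations = 20, seed = 7))
#' summary(res)
#' @export
run_simulation <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  with_preserved_seed(params$seed, {
    metapop <- init_metapopulation(params)
    ns <- params$n_subpop
    g <- params$generations
    freq_a <- matrix(NA_real_, g, ns)
    freq_c <- matrix(NA_real_, g, ns)
    cov_tp <- matrix(NA_real_, g, ns)
    for (t in seq_len(g)) {
      metapop <- step_generation(metapop, params)
      for (s in seq_len(ns)) {
        in_s <- metapop$subpop == s
        freq_a[t, s] <- mean(metapop$trait[in_s & metapop$male])
        freq_c[t, s] <- mean(metapop$pref[in_s & !metapop$male])
        ts <- metapop$trait[in_s]
        ps <- metapop$pref[in_s]
        cov_tp[t, s] <- mean(ts * ps) - mean(ts) * mean(ps)
      }
    }
    records <- data.frame(
      generation = rep(seq_len(g), times = ns),
      subpop = rep(seq_len(ns), each = g),
      freq_A_males = as.vector(freq_a),
      freq_C_females = as.vector(freq_c),
      cov_trait_pref = as.vector(cov_tp))
    structure(list(records = records, params = params, seed = params$seed),
              class = "sim_result")
  })
}

#' @export
print.sim_result <- function(x, ...) {
  s <- summary(x)
  cat(sprintf(
    "Simulation result: %d generations, %d subpops\n  final freq(C) = %.3f, mean final freq(A) = %.3f, among-subpop var(A) = %.4f, polymorphic subpops = %d\n",
    x$params$generations, x$params$n_subpop, s$final_freq_C,
    s$mean_final_freq_A, s$var_among_subpop_freq_A, s$n_polymorphic_subpops))
  invisible(x)
}

#' Summarise the end state of a simulation
#'
#' Computes, from the final generation of a [run_simulation()] result: the
#' metapopulation frequency of the conformity allele C among females, the
#' per-subpopulation frequencies of display allele A among males, their
#' among-subpopulation variance (population variance, i.e. mean squared
#' deviation), and the number of subpopulations still polymorphic for the
#' display trait.
#'
#' @param object A `sim_result`.
#' @param ... Unused.
#' @return A list with `final_freq_C`, `final_freq_A_by_subpop`,
#'   `mean_final_freq_A`, `var_among_subpop_freq_A`,
#'   `n_polymorphic_subpops`.
#' @export
summary.sim_result <- function(object, ...) {
  rec <- object$records
  if (nrow(rec) == 0L) stop("empty simulation result", call. = FALSE)
  fin <- rec[rec$generation == max(rec$generation), , drop = FALSE]
  fin <- fin[order(fin$subpop), , drop = FALSE]
  fa <- fin$freq_A_males
  list(final_freq_C = mean(fin$freq_C_females),
       final_freq_A_by_subpop = fa,
       mean_final_freq_A = mean(fa),
       var_among_subpop_freq_A = mean((fa - mean(fa))^2),
       n_polymorphic_subpops = sum(fa > 0 & fa < 1))
}

#' Sweep conformity strength and dispersal rate
#'
#' Runs `replicates` independent simulations for every cell of the
#' `betas` x `ds` grid, holding all other parameters at `base_params`.
#' Per-cell, per-replicate seeds are derived deterministically from
#' `base_seed` by a counter scheme, so any subset of the sweep is
#' reproducible in isolation.
#'
#' @param betas,ds Non-empty grids of conformity strengths and dispersal
#'   fractions.
#' @param replicates Simulation runs per grid cell (>= 1).
#' @param base_params A [sim_params()] giving all non-swept parameters.
#' @param base_seed Integer base seed.
#' @return A `data.frame` of class `sweep_result` with one row per
#'   replicate: `beta`, `d`, `replicate`, `seed`, `final_freq_C`,
#'   `mean_final_freq_A`, `var_among_subpop_freq_A`,
#'   `n_polymorphic_subpops`.
#' @export
run_sweep <- function(betas, ds, replicates, base_params, base_seed) {
  stopifnot(length(betas) >= 1, length(ds) >= 1,
            inherits(base_params, "sim_params"))
  replicates <- check_count(replicates, "replicates")
  rows <- vector("list", length(betas) * length(ds) * replicates)
  k <- 0L
  cell <- 0L
  for (b in betas) {
    for (d in ds) {
      cell <- cell + 1L
      for (rep_i in seq_len(replicates)) {
        seed <- derive_seed(base_seed, cell, rep_i)
        p <- base_params
        p$beta <- b
        p$d <- d
        p$seed <- seed
        s <- summary(run_simulation(p))
        k <- k + 1L
        rows[[k]] <- data.frame(
          beta = b, d = d, replicate = rep_i, seed = seed,
          final_freq_C = s$final_freq_C,
          mean_final_freq_A = s$mean_final_freq_A,
          var_among_subpop_freq_A = s$var_among_subpop_freq_A,
          n_polymorphic_subpops = s$n_polymorphic_subpops)
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("sweep_result", "data.frame")
  out
}

#' Write and read simulator outputs as CSV
#'
#' Time series are written with header
#' `run_id,generation,subpop,freq_A_males,freq_C_females,cov_trait_pref`;
#' sweep tables with header
#' `beta,d,replicate,seed,final_freq_C,mean_final_freq_A,var_among_subpop_freq_A,n_polymorphic_subpops`.
#'
#' @param result A `sim_result` or `sweep_result`.
#' @param path File path.
#' @param run_id Identifier stamped on every time-series row (default
#'   `"run1"`).
#' @return Writers return `path` invisibly; readers return a `data.frame`
#'   (`read_sweep_result()` restores the `sweep_result` class).
#' @export
write_sim_result <- function(result, path, run_id = "run1") {
  stopifnot(inherits(result, "sim_result"))
  out <- cbind(run_id = run_id, result$records)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_sim_result
#' @export
read_sim_result <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname write_sim_result
#' @export
write_sweep_result <- function(result, path) {
  stopifnot(inherits(result, "sweep_result"))
  utils::write.csv(as.data.frame(result), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_sim_result
#' @export
read_sweep_result <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(out) <- c("sweep_result", "data.frame")
  out
}
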