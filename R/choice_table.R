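#' Build a validated choice table
#'
#' A choice table holds grouped frequency-dependent adoption data: for each
#' group of observers, the demonstrator frequency of every trait and the
#' number of observers that adopted it. It is the input to the conformity
#' estimators ([fit_beta_binary()], [fit_beta_multitrait()],
#' [fit_error_mixture()]).
#'
#' Validation enforces: demonstrator frequencies within each group sum to 1;
#' adoption counts are non-negative and no larger than the group's observer
#' count; the observer count is constant across a group's trait rows.
#' Adoption counts may be non-integer so that exact (infinite-observer)
#' proportions can be represented.
#'
#' @param group Group identifiers (coerced to character).
#' @param trait Trait identifiers within groups (coerced to character).
#' @param freq Demonstrator frequency of each trait in its group, in
#'   \eqn{[0, 1]}.
#' @param observers Number of observers per group (positive; repeated on
#'   every trait row of the group).
#' @param adoptions Number (possibly fractional) of observers adopting each
#'   trait.
#' @return A `data.frame` with class `choice_table` and columns
#'   `group`, `trait`, `freq`, `observers`, `adoptions`.
#' @examples
#' choice_table(group = c(1, 1, 2, 2), trait = c("A", "B", "A", "B"),
#'              freq = c(0.6, 0.4, 0.3, 0.7), observers = 10,
#'              adoptions = c(8, 2, 2, 8))
#' @export
choice_table <- function(group, trait, freq, observers, adoptions) {
  tab <- data.frame(group = as.character(group),
                    trait = as.character(trait),
                    freq = as.numeric(freq),
                    observers = as.numeric(observers),
                    adoptions = as.numeric(adoptions),
                    stringsAsFactors = FALSE)
  validate_choice_table(tab)
}

validate_choice_table <- function(tab, freq_tol = 1e-9) {
  need <- c("group", "trait", "freq", "observers", "adoptions")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols)) {
    stop("choice table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  tab <- tab[need]
  check_freq(tab$freq, "freq")
  if (any(tab$observers <= 0)) stop("`observers` must be positive", call. = FALSE)
  if (any(tab$adoptions < 0)) stop("`adoptions` must be non-negative", call. = FALSE)
  if (any(tab$adoptions > tab$observers + 1e-9)) {
    stop("`adoptions` cannot exceed `observers`", call. = FALSE)
  }
  by_group <- split(tab, tab$group)
  for (g in by_group) {
    if (abs(sum(g$freq) - 1) > freq_tol) {
      stop("demonstrator frequencies in group '", g$group[1],
           "' sum to ", format(sum(g$freq), digits = 12), ", not 1",
           call. = FALSE)
    }
    if (length(unique(g$observers)) != 1L) {
      stop("`observers` differs across trait rows of group '", g$group[1],
           "'", call. = FALSE)
    }
    if (anyDuplicated(g$trait)) {
      stop("duplicated trait id in group '", g$group[1], "'", call. = FALSE)
    }
  }
  class(tab) <- c("choice_table", "data.frame")
  tab
}

#' Read / write a choice table as CSV
#'
#' The on-disk format is plain comma-separated text with header
#' `group,trait,freq,observers,adoptions`. `read_choice_table()` validates
#' on load.
#'
#' @param path File path.
#' @param tab A [choice_table()].
#' @return `read_choice_table()` returns a validated `choice_table`;
#'   `write_choice_table()` returns `path` invisibly.
#' @export
read_choice_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(group = "character", trait = "character"))
  validate_choice_table(tab)
}

#' @rdname read_choice_table
#' @export
write_choice_table <- function(tab, path) {
  stopifnot(inherits(tab, "choice_table"))
  utils::write.csv(as.data.frame(tab), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Simulate binary choice data from a logistic learning rule
#'
#' Generates a synthetic two-trait [choice_table()] for validating the
#' conformity estimators: at each design frequency `q` in each group,
#' adoptions of trait `"A"` are drawn `Binomial(observers, p'(q))` with
#' `p'` from [logistic_prob()] under `rule`; trait `"B"` receives the
#' remaining observers. Deterministic given `seed`.
#'
#' @param rule A [logistic_rule()].
#' @param freq_levels Demonstrator frequencies of trait `"A"`, one group per
#'   level per replicate group.
#' @param observers Observers per group.
#' @param groups Number of replicate groups per frequency level (default 1).
#' @param seed Integer seed.
#' @return A `choice_table` with `length(freq_levels) * groups` groups.
#' @export
simulate_choices <- function(rule, freq_levels, observers, groups = 1, seed) {
  stopifnot(inherits(rule, "logistic_rule"))
  if (length(freq_levels) == 0L || groups < 1 || observers < 1) {
    stop("empty design: need at least one frequency level, one group and one observer",
         call. = FALSE)
  }
  check_freq(freq_levels, "freq_levels")
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  q <- rep(freq_levels, times = groups)
  p <- logistic_prob(q, rule)
  adopt_A <- with_preserved_seed(seed,
    stats::rbinom(length(q), size = observers, prob = p))
  gid <- sprintf("g%03d", seq_along(q))
  choice_table(group = rep(gid, each = 2L),
               trait = rep(c("A", "B"), times = length(q)),
               freq = as.vector(rbind(q, 1 - q)),
               observers = observers,
               adoptions = as.vector(rbind(adopt_A, observers - adopt_A)))
}
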