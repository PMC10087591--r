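# Fixture builders used across the test files. All expected adoption
# probabilities are computed here with direct power arithmetic
# (q^beta / sum q^beta), independent of the package's logit-form
# implementation.

direct_logistic <- function(q, beta, alpha = 0) {
  alpha / 2 + (1 - alpha) * q^beta / (q^beta + (1 - q)^beta)
}

# Two-trait table whose adoption counts lie exactly on the logistic curve
# (fractional counts represent the infinite-observer limit).
exact_binary_table <- function(beta, qs, alpha = 0, observers = 1000) {
  p <- direct_logistic(qs, beta, alpha)
  choice_table(group = rep(seq_along(qs), each = 2L),
               trait = rep(c("A", "B"), length(qs)),
               freq = as.vector(rbind(qs, 1 - qs)),
               observers = observers,
               adoptions = as.vector(rbind(observers * p, observers * (1 - p))))
}

# K-trait table with exact multi-logistic adoption counts; freq_mat has one
# row per group, one column per trait, rows summing to 1.
exact_multi_table <- function(beta, freq_mat, observers = 1000) {
  k <- ncol(freq_mat)
  rows <- lapply(seq_len(nrow(freq_mat)), function(g) {
    q <- freq_mat[g, ]
    p <- q^beta / sum(q^beta)
    data.frame(group = as.character(g), trait = LETTERS[seq_len(k)],
               freq = q, observers = observers, adoptions = observers * p)
  })
  do.call(rbind, rows) |> validate_ct()
}

validate_ct <- function(df) {
  choice_table(df$group, df$trait, df$freq, df$observers, df$adoptions)
}

# Deterministic sub-seed helper mirroring the package's counter scheme,
# kept local so tests control their own streams.
test_seed <- function(i, j = 0L) conformity:::derive_seed(20260924L, i, j)
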