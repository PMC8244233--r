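# Shared test fixtures, built in code.

# Small cohort config with overridable generative parameters.
test_config <- function(n = 2393, seed = 1L, ...) {
  simulation_config(n_individuals = n, seed = seed, ...)
}

# A minimal hand-built phenotyped table for analyses that only need an
# outcome and an exposure coding (no genotypes).
tiny_table <- function(y, group) {
  data.frame(y = y, grp = factor(group), stringsAsFactors = FALSE)
}

# Expand 2x2 cell counts (exposed-case, exposed-noncase, unexposed-case,
# unexposed-noncase) into individual rows.
expand_2x2 <- function(a, b, c, d) {
  data.frame(
    y = c(rep(1, a), rep(0, b), rep(1, c), rep(0, d)),
    x = c(rep(1, a + b), rep(0, c + d)))
}
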