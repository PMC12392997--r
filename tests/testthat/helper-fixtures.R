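# Shared fixtures built in code.

default_ps <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- synth_parameter_set(synthetic_spec(seed = 42))
    cache
  }
})

# A parameter set with all disease transitions and mortality zeroed:
# nothing ever happens, so the cohort sits in its initial distribution.
inert_ps <- function(init = NULL) {
  ps <- default_ps()
  ps$transitions <- ps$transitions[0, ]
  ps$mortality$other$prob[] <- 0
  ps$mortality$ugc$prob[] <- 0
  ps$mortality$advanced <- lapply(ps$mortality$advanced, function(x) x * 0)
  if (!is.null(init)) {
    states <- default_state_space()$state
    full <- setNames(numeric(length(states)), states)
    full[names(init)] <- init
    ps$initial_distribution <- full
  }
  ps
}

# Published cumulative screening counts per strategy code.
published_schedule_counts <- c(
  y40_nf_i1 = 31, y40_nf_i2 = 16, y40_nf_i5 = 7, y40_nf_i10 = 4,
  y40_nf_i15 = 3, y40_nf_in = 1, y40_f_i5 = 7, y40_f_i10 = 4,
  y40_f_i15 = 3, y40_f_in = 1,
  y45_nf_i1 = 26, y45_nf_i2 = 13, y45_nf_i5 = 6, y45_nf_i10 = 3,
  y45_nf_i15 = 2, y45_nf_in = 1, y45_f_i5 = 6, y45_f_i10 = 3,
  y45_f_i15 = 2, y45_f_in = 1,
  y50_nf_i1 = 21, y50_nf_i2 = 11, y50_nf_i5 = 5, y50_nf_i10 = 3,
  y50_nf_i15 = 2, y50_nf_in = 1, y50_f_i5 = 5, y50_f_i10 = 3,
  y50_f_i15 = 2, y50_f_in = 1,
  y55_nf_i1 = 16, y55_nf_i2 = 8, y55_nf_i5 = 4, y55_nf_i10 = 2,
  y55_nf_i15 = 2, y55_nf_in = 1, y55_f_i5 = 4, y55_f_i10 = 2,
  y55_f_i15 = 2, y55_f_in = 1)

# Printed cost/QALY table for the eight reference arms (baseline plus the
# seven dominant strategies), bundled with the package.
published_outcomes <- function() {
  read.csv(system.file("extdata", "published_outcomes.csv",
                       package = "ugcscreen"),
           stringsAsFactors = FALSE)
}

random_outcomes <- function(n, seed) {
  set.seed(seed)
  data.frame(code = sprintf("s%02d", seq_len(n)),
             cost = runif(n, 1e6, 1e9),
             qalys = runif(n, 1e5, 3e6), stringsAsFactors = FALSE)
}

# Exhaustive dominance search used as the independent frontier oracle:
# a point is excluded iff some other point strongly dominates it, or some
# pair's convex combination does (extended dominance).
brute_force_frontier <- function(df) {
  n <- nrow(df)
  dominated <- logical(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (df$cost[j] <= df$cost[i] && df$qalys[j] >= df$qalys[i] &&
          (df$cost[j] < df$cost[i] || df$qalys[j] > df$qalys[i])) {
        dominated[i] <- TRUE
      }
    }
  }
  ext <- logical(n)
  for (i in seq_len(n)) {
    if (dominated[i]) next
    for (j in seq_len(n)) {
      for (k in seq_len(n)) {
        if (i %in% c(j, k) || j == k) next
        if (dominated[j] || dominated[k]) next
        dq <- df$qalys[k] - df$qalys[j]
        if (dq == 0) next
        w <- (df$qalys[i] - df$qalys[j]) / dq
        if (w < 0 || w > 1) next
        mix_cost <- (1 - w) * df$cost[j] + w * df$cost[k]
        if (mix_cost < df$cost[i] - 1e-9) ext[i] <- TRUE
      }
    }
  }
  sort(df$code[!dominated & !ext])
}
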