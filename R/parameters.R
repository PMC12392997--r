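#' Convert a multi-year transition probability to an annual probability
#'
#' Uses constant-hazard compounding: `p1 = 1 - (1 - pT)^(1/T)`, so that
#' compounding the annual probability over `T` years recovers the input.
#'
#' @param p_T Probability observed over a `T`-year period, in `[0, 1]`.
#' @param T_years Period length in whole years, `>= 1`.
#' @return Annual probability in `[0, 1]`.
#' @examples
#' annualize_probability(0.75, 2)  # 0.5
#' @export
annualize_probability <- function(p_T, T_years) {
  if (any(p_T < 0 | p_T > 1)) stop("p_T must lie in [0, 1]", call. = FALSE)
  if (any(T_years < 1) || any(T_years != floor(T_years)))
    stop("T_years must be an integer >= 1", call. = FALSE)
  1 - (1 - p_T)^(1 / T_years)
}

#' Convert an annual event rate to an annual probability
#'
#' Standard exponential conversion `p = 1 - exp(-rate)` for mortality series
#' supplied as rates rather than probabilities.
#'
#' @param rate Non-negative annual rate.
#' @return Probability in `[0, 1)`.
#' @export
rate_to_probability <- function(rate) {
  if (any(rate < 0)) stop("rate must be non-negative", call. = FALSE)
  1 - exp(-rate)
}

#' Duration-dependent annual death probabilities from 5-year survival
#'
#' Advanced cancer mortality is duration-dependent: the annual probability
#' for post-diagnosis years 1-5 is derived from the stage's 5-year survival
#' under a constant-hazard split, `q = 1 - S5^(1/5)`, and held at the
#' first-year value beyond year 5.
#'
#' @param S5 Five-year survival fraction, in `(0, 1]`.
#' @return Numeric vector of length 6: annual death probabilities for
#'   duration years 1..5 and the constant 6+ tail.
#' @examples
#' derive_advanced_mortality(0.32768)  # 0.2 each year
#' @export
derive_advanced_mortality <- function(S5) {
  if (length(S5) != 1L || S5 <= 0 || S5 > 1)
    stop("S5 must be a single value in (0, 1]", call. = FALSE)
  q <- 1 - S5^(1 / 5)
  rep(q, 6L)
}

# ---------------------------------------------------------------------------
# ParameterSet

#' Construct and validate a full model parameter set
#'
#' Bundles every input the cohort model needs: the state space, the annual
#' transition table, the initial state distribution, age-indexed mortality
#' series, state utilities, screening/treatment costs, test characteristics,
#' compliance rates, the discount rate, cohort size, age span and the
#' willingness-to-pay threshold.  Validation aggregates all violations into
#' a single error message.
#'
#' @param state_space Data frame from [default_state_space()].
#' @param transitions Data frame with columns `from`, `to`, `prob` and
#'   optionally `period_years` (converted to annual on construction).
#' @param initial_distribution Named numeric over core states, summing to 1.
#' @param mortality List with elements `other` and `ugc` (each a data frame
#'   `age`, `prob` covering the age span) and `advanced` (named list per
#'   organ prefix of length-6 duration series, see
#'   [derive_advanced_mortality()]).
#' @param utilities Named list of [param_value()] keyed by disease state.
#' @param costs List: `screening_total` ([param_value()]),
#'   `screening_components` (named numerics), `treatment` (per organ prefix a
#'   list `sdcis`, `early`, `advanced_clinical`, `advanced_screen` of
#'   [param_value()]), optional `fp` per-false-positive cost.
#' @param test List of [param_value()]: `sensitivity`, `specificity`.
#' @param compliance List of [param_value()]: `screening`, `follow_up`.
#' @param discount_rate A [param_value()].
#' @param cohort_size Cohort size (default 100000).
#' @param age_span Entry and final attained age (default `c(40, 80)`).
#' @param wtp Willingness-to-pay threshold in yuan per QALY (default 70653,
#'   one-time per-capita GDP).
#' @param options List of switches: `beta_gamma_mode` (`"recentered"` or
#'   `"raw"`), `fp_cost`, `surveillance_interval`, `half_cycle`,
#'   `psa_transitions` (`"fixed"` or `"uniform20"`).
#' @return A validated object of class `ugc_parameter_set`.
#' @export
parameter_set <- function(state_space, transitions, initial_distribution,
                          mortality, utilities, costs, test, compliance,
                          discount_rate, cohort_size = 100000L,
                          age_span = c(40L, 80L), wtp = 70653,
                          options = list()) {
  defaults <- list(beta_gamma_mode = "recentered", fp_cost = 0,
                   surveillance_interval = 1L, half_cycle = FALSE,
                   psa_transitions = "fixed")
  options <- utils::modifyList(defaults, options)

  tr <- as.data.frame(transitions, stringsAsFactors = FALSE)
  if (!"period_years" %in% names(tr)) tr$period_years <- 1
  conv <- tr$period_years > 1
  tr$prob[conv] <- annualize_probability(tr$prob[conv], tr$period_years[conv])
  tr$period_years <- 1

  ps <- structure(list(
    state_space = state_space, transitions = tr,
    initial_distribution = unlist(initial_distribution),
    mortality = mortality, utilities = utilities, costs = costs,
    test = test, compliance = compliance, discount_rate = discount_rate,
    cohort_size = as.integer(cohort_size), age_span = as.integer(age_span),
    wtp = as.numeric(wtp), options = options), class = "ugc_parameter_set")
  validate_parameter_set(ps)
  ps
}

#' Validate a parameter set, aggregating every violated invariant
#' @param ps A `ugc_parameter_set`.
#' @return Invisibly `TRUE`; errors with the full violation list otherwise.
#' @export
validate_parameter_set <- function(ps) {
  bad <- character()
  note <- function(msg) bad <<- c(bad, msg)
  ss <- ps$state_space
  if (sum(ss$state == "healthy") != 1L) note("state_space: need exactly one 'healthy' state")
  if (sum(ss$grade == "death") < 2L) note("state_space: need >= 2 death states")
  if (any(ss$pre_intramucosal & ss$grade != "precancer"))
    note("state_space: pre_intramucosal flagged outside precancer grades")

  states <- ss$state
  tr <- ps$transitions
  if (!all(tr$from %in% states)) note(paste0(
    "transitions: unknown from-states: ",
    paste(setdiff(tr$from, states), collapse = ", ")))
  if (!all(tr$to %in% states)) note(paste0(
    "transitions: unknown to-states: ",
    paste(setdiff(tr$to, states), collapse = ", ")))
  if (any(tr$prob < 0 | tr$prob > 1)) note("transitions: probabilities outside [0, 1]")
  rs <- tapply(tr$prob, tr$from, sum)
  over <- names(rs)[rs > 1 + 1e-12]
  if (length(over)) note(paste0("transitions: row sums exceed 1 for: ",
                                paste(over, collapse = ", ")))
  dead <- ss$state[ss$grade == "death"]
  if (any(tr$from %in% dead)) note("transitions: transition out of an absorbing state")
  # no regression past intramucosal carcinoma
  rank_of <- state_rank()
  post <- ss$state[ss$grade %in% c("early_cancer", "advanced_cancer")]
  reg <- tr$from %in% post &
    rank_of[tr$to] <= rank_of[tr$from] & !is.na(rank_of[tr$to]) & tr$to != tr$from
  if (any(reg, na.rm = TRUE)) note("transitions: regression edge out of a post-intramucosal state")

  init <- ps$initial_distribution
  if (abs(sum(init) - 1) > 1e-9) note("initial_distribution: does not sum to 1")
  if (any(init < 0)) note("initial_distribution: negative entries")
  if (!all(names(init) %in% states)) note("initial_distribution: unknown states")

  for (series in c("other", "ugc")) {
    m <- ps$mortality[[series]]
    if (is.null(m)) { note(paste0("mortality: missing series '", series, "'")); next }
    if (any(m$prob < 0 | m$prob > 1)) note(paste0("mortality$", series, ": probabilities outside [0, 1]"))
    if (min(m$age) > ps$age_span[1] || max(m$age) < ps$age_span[2])
      note(paste0("mortality$", series, ": ages do not cover the model age span"))
  }
  for (org in names(ORGANS)) {
    d <- ps$mortality$advanced[[org]]
    if (is.null(d) || length(d) != 6L)
      note(paste0("mortality$advanced$", org, ": need a length-6 duration series"))
    else if (any(d < 0 | d > 1))
      note(paste0("mortality$advanced$", org, ": probabilities outside [0, 1]"))
  }

  for (nm in names(ps$utilities)) {
    u <- ps$utilities[[nm]]
    if (!nm %in% states) note(paste0("utilities: unknown state '", nm, "'"))
    if (u$base < -1 || u$base > 1) note(paste0("utilities$", nm, ": outside [-1, 1]"))
  }
  ustates <- setdiff(states, ss$state[ss$grade %in% c("healthy", "death")])
  miss <- setdiff(ustates, names(ps$utilities))
  if (length(miss)) note(paste0("utilities: missing states: ", paste(miss, collapse = ", ")))

  if (ps$costs$screening_total$base < 0) note("costs$screening_total: negative")
  for (org in names(ORGANS)) {
    tc <- ps$costs$treatment[[org]]
    need <- c("sdcis", "early", "advanced_clinical", "advanced_screen")
    miss <- setdiff(need, names(tc))
    if (length(miss)) note(paste0("costs$treatment$", org, ": missing ",
                                  paste(miss, collapse = ", ")))
    for (k in intersect(need, names(tc)))
      if (tc[[k]]$base < 0) note(paste0("costs$treatment$", org, "$", k, ": negative"))
  }
  for (nm in c("sensitivity", "specificity"))
    if (ps$test[[nm]]$base < 0 || ps$test[[nm]]$base > 1)
      note(paste0("test$", nm, ": outside [0, 1]"))
  for (nm in c("screening", "follow_up"))
    if (ps$compliance[[nm]]$base < 0 || ps$compliance[[nm]]$base > 1)
      note(paste0("compliance$", nm, ": outside [0, 1]"))

  if (length(bad))
    stop("invalid parameter set:\n  - ", paste(bad, collapse = "\n  - "),
         call. = FALSE)
  invisible(TRUE)
}

# Grade ordering within each organ ladder, for regression checks.
state_rank <- function() {
  r <- c(healthy = 0, post_tx = 0)
  for (p in names(ORGANS)) {
    lad <- organ_states(p)
    r[lad] <- seq_along(lad)
  }
  r[c("death_ugc", "death_other")] <- NA
  r
}

#' @export
print.ugc_parameter_set <- function(x, ...) {
  cat("<ugc_parameter_set>\n")
  cat(sprintf("  states: %d (16 disease + healthy/post-treatment + 2 death)\n",
              nrow(x$state_space)))
  cat(sprintf("  cohort: %d entering at age %d, horizon age %d\n",
              x$cohort_size, x$age_span[1], x$age_span[2]))
  cat(sprintf("  screening: Se %.2f, Sp %.2f, compliance %.2f (follow-up %.2f)\n",
              x$test$sensitivity$base, x$test$specificity$base,
              x$compliance$screening$base, x$compliance$follow_up$base))
  cat(sprintf("  discount %.3f, WTP %s CNY/QALY\n", x$discount_rate$base,
              format(x$wtp, big.mark = ",")))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Parameter addressing (used by DSA and PSA)

# A parameter path is e.g. "compliance.screening", "test.sensitivity",
# "discount_rate", "costs.screening_total", "utilities.es_SDCIS",
# "costs.treatment.es.sdcis".
get_param <- function(ps, path) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  node <- ps
  for (p in parts) {
    node <- node[[p]]
    if (is.null(node)) stop("unknown parameter: ", path, call. = FALSE)
  }
  if (!inherits(node, "param_value"))
    stop("not a parameter leaf: ", path, call. = FALSE)
  node
}

set_param_ <- function(ps, path, pv) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  expr <- Reduce(function(acc, p) call("[[", acc, p), parts, quote(ps))
  if (!inherits(eval(expr), "param_value"))
    stop("not a parameter leaf: ", path, call. = FALSE)
  eval(call("<-", expr, quote(pv)))
  ps
}

set_param_base <- function(ps, path, value) {
  pv <- get_param(ps, path)
  pv$base <- value
  set_param_(ps, path, pv)
}

# All sampleable / sweepable parameter paths with their domain kind.
parameter_paths <- function(ps) {
  paths <- c(
    "compliance.screening", "compliance.follow_up",
    "test.sensitivity", "test.specificity", "discount_rate")
  kinds <- rep("probability", 4)
  kinds <- c(kinds, "generic")
  for (u in names(ps$utilities)) {
    paths <- c(paths, paste0("utilities.", u)); kinds <- c(kinds, "utility")
  }
  paths <- c(paths, "costs.screening_total"); kinds <- c(kinds, "cost")
  for (org in names(ORGANS))
    for (k in c("sdcis", "early", "advanced_clinical", "advanced_screen")) {
      paths <- c(paths, paste0("costs.treatment.", org, ".", k))
      kinds <- c(kinds, "cost")
    }
  data.frame(path = paths, kind = kinds, stringsAsFactors = FALSE)
}

#' Resolved parameter table
#'
#' Flat table of every tunable parameter: name, base, range and sampling
#' family — convenient for CSV export and as the DSA sweep inventory.
#'
#' @param ps A `ugc_parameter_set`.
#' @return Data frame with columns `name`, `base`, `low`, `high`, `family`,
#'   `params`, `units`.
#' @export
parameter_table <- function(ps) {
  pp <- parameter_paths(ps)
  rows <- lapply(pp$path, function(p) {
    pv <- get_param(ps, p)
    data.frame(name = p, base = pv$base, low = pv$low, high = pv$high,
               family = pv$dist$family,
               params = paste(format(pv$dist$params, trim = TRUE),
                              collapse = ";"),
               units = pv$units, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# ---------------------------------------------------------------------------
# PSA sampling

#' Draw one probabilistic-sensitivity-analysis variant of a parameter set
#'
#' Samples every parameter that carries a non-fixed distribution
#' (compliances, test characteristics, discount rate, utilities, costs)
#' jointly and independently; utilities are capped at 1, probabilities kept
#' in `[0, 1]`, costs kept non-negative.  Structural inputs (state space,
#' transition table, mortality) are unchanged by default; with
#' `options$psa_transitions = "uniform20"` transition probabilities are
#' additionally perturbed by independent U(0.8, 1.2) factors.
#'
#' @param base A `ugc_parameter_set`.
#' @param seed Integer seed; identical seeds give identical samples.
#' @return A new validated `ugc_parameter_set` with sampled base values.
#' @export
sample_parameter_set <- function(base, seed) {
  with_seed_(seed, {
    ps <- base
    mode <- ps$options$beta_gamma_mode
    pp <- parameter_paths(ps)
    for (i in seq_len(nrow(pp))) {
      pv <- get_param(ps, pp$path[i])
      if (pv$dist$family == "fixed") next
      ps <- set_param_base(ps, pp$path[i],
                           sample_param(pv, mode = mode, kind = pp$kind[i]))
    }
    if (identical(ps$options$psa_transitions, "uniform20")) {
      f <- stats::runif(nrow(ps$transitions), 0.8, 1.2)
      ps$transitions$prob <- pmin(ps$transitions$prob * f, 1)
    }
    validate_parameter_set(ps)
    ps
  })
}

# Evaluate an expression under a temporary RNG seed, restoring the caller's
# RNG state afterwards.
with_seed_ <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
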