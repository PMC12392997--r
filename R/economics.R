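#' Discount multiplier for a cycle
#'
#' @param t Cycle index (0 at model entry).
#' @param r Annual real discount rate (`> -1`).
#' @return `(1 + r)^(-t)`.
#' @examples
#' discount_factor(1, 0.03)  # 0.9709
#' @export
discount_factor <- function(t, r) {
  stopifnot(all(t >= 0), r > -1)
  (1 + r)^(-t)
}

# Expanded-space utility vector: healthy and post-treatment carry utility 1,
# surveillance and tunnel copies inherit the underlying state's utility,
# death states contribute 0.
utility_vector <- function(ps) {
  ex <- expanded_states()
  u <- stats::setNames(numeric(length(ex)), ex)
  u["healthy"] <- 1
  u["post_tx"] <- 1
  for (s in c(precancer_states(), early_states())) {
    pv <- ps$utilities[[s]]
    if (is.null(pv)) stop("state lacks a utility: ", s, call. = FALSE)
    u[s] <- pv$base
    u[paste0("s_", s)] <- pv$base
  }
  for (s in advanced_states()) {
    pv <- ps$utilities[[s]]
    if (is.null(pv)) stop("state lacks a utility: ", s, call. = FALSE)
    u[paste0(s, "_d", seq_len(N_TUNNEL))] <- pv$base
  }
  u
}

#' Discounted cost and QALY totals for one screening strategy
#'
#' Runs the cohort under the strategy's schedule and management policy and
#' accrues cycle costs (screening, follow-up, treatment) and
#' occupancy-weighted utilities, discounted from model entry (`t = 0` at
#' the entry age).  No half-cycle correction by default
#' (`options$half_cycle = TRUE` averages adjacent cycle occupancies).
#'
#' @param ps A `ugc_parameter_set`.
#' @param strategy A `ugc_strategy`, or `NULL` for the no-screening arm.
#' @param engine Optional precomputed operator set (internal reuse).
#' @return An object of class `ugc_outcome`: a one-row data frame with
#'   `code`, `cost` (CNY, cohort scale, discounted), `qalys` (discounted),
#'   `cost_undisc`, `qalys_undisc`, `cases`, `ugc_deaths`, `life_years`.
#' @export
evaluate_strategy <- function(ps, strategy = NULL, engine = NULL) {
  trace <- run_cohort(ps, strategy, engine = engine)
  accrue_trace(trace, ps)
}

#' Accrue one cycle's discounted cost and QALYs
#'
#' @param v Expanded occupancy vector at the cycle.
#' @param cycle_cost Undiscounted per-capita cost incurred during the cycle.
#' @param ps A `ugc_parameter_set` (utilities, cohort size, discount rate).
#' @param t Cycle index (0 at entry).
#' @return List with `cost` and `qaly`, cohort scale, discounted.
#' @export
accrue_cycle <- function(v, cycle_cost, ps, t) {
  d <- discount_factor(t, ps$discount_rate$base)
  u <- utility_vector(ps)
  list(cost = cycle_cost * ps$cohort_size * d,
       qaly = sum(v * u[names(v)]) * ps$cohort_size * d)
}

# Accrual over a completed trace; split out so tests can audit cycle sums.
accrue_trace <- function(trace, ps) {
  r <- ps$discount_rate$base
  n_cyc <- nrow(trace$occupancy)
  tvec <- seq_len(n_cyc) - 1
  disc <- discount_factor(tvec, r)
  u <- utility_vector(trace_states_check(trace, ps))
  occ <- trace$occupancy
  if (isTRUE(ps$options$half_cycle)) {
    occ <- (occ + rbind(occ[-1, , drop = FALSE],
                        occ[n_cyc, , drop = FALSE])) / 2
  }
  q_cycle <- drop(occ %*% u) * ps$cohort_size
  c_cycle <- (trace$events$cost_screening + trace$events$cost_followup +
                trace$events$cost_treatment) * ps$cohort_size
  s <- tally_events(trace)
  structure(data.frame(
    code = trace$strategy,
    cost = sum(c_cycle * disc),
    qalys = sum(q_cycle * disc),
    cost_undisc = sum(c_cycle),
    qalys_undisc = sum(q_cycle),
    cases = s$cases, ugc_deaths = s$ugc_deaths,
    life_years = s$life_years,
    stringsAsFactors = FALSE), class = c("ugc_outcome", "data.frame"))
}

trace_states_check <- function(trace, ps) {
  if (!identical(colnames(trace$occupancy), expanded_states()))
    stop("trace state space does not match the parameter set", call. = FALSE)
  ps
}

#' Evaluate a set of strategies plus the no-screening reference
#'
#' @param ps A `ugc_parameter_set`.
#' @param strategies Named list of `ugc_strategy` (default the full
#'   40-strategy grid); a `NULL` element denotes the no-screening arm.
#' @param include_reference Prepend the no-screening reference arm.
#' @return A data frame with one row per arm (classes as in
#'   [evaluate_strategy()]).
#' @export
evaluate_strategies <- function(ps, strategies = enumerate_strategies(),
                                include_reference = TRUE) {
  engine <- build_engine(ps)
  rows <- list()
  if (include_reference)
    rows[["no_screening"]] <- evaluate_strategy(ps, NULL, engine)
  for (s in strategies) {
    if (is.null(s)) {
      if (!"no_screening" %in% names(rows))
        rows[["no_screening"]] <- evaluate_strategy(ps, NULL, engine)
      next
    }
    rows[[s$code]] <- evaluate_strategy(ps, s, engine)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
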