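# Cost-utility comparison: CUR, pairwise ICUR, efficient frontier with
# strong and extended dominance, and net monetary benefit.

#' Construct a strategy outcome point
#'
#' The minimal (cost, QALY) pair used by the comparison layer; full model
#' outcomes from [evaluate_strategy()] coerce automatically.
#'
#' @param code Strategy code.
#' @param cost Total discounted cost (CNY, cohort scale).
#' @param qalys Total discounted QALYs.
#' @return A one-row data frame of class `ugc_outcome_point`.
#' @export
strategy_outcome <- function(code, cost, qalys) {
  stopifnot(is.finite(cost), is.finite(qalys), cost >= 0, qalys > 0)
  structure(data.frame(code = code, cost = cost, qalys = qalys,
                       stringsAsFactors = FALSE),
            class = c("ugc_outcome_point", "data.frame"))
}

as_outcome_frame <- function(outcomes) {
  df <- as.data.frame(outcomes)[, c("code", "cost", "qalys")]
  if (anyDuplicated(df$code)) stop("duplicate strategy codes", call. = FALSE)
  df
}

#' Cost-utility ratio of one strategy
#'
#' @param outcome A row with `cost` and `qalys` (or the two numbers).
#' @return Cost per QALY (CNY/QALY).
#' @export
cost_utility_ratio <- function(outcome) {
  if (any(outcome$qalys <= 0)) stop("QALYs must be positive", call. = FALSE)
  outcome$cost / outcome$qalys
}

#' Incremental cost-utility ratio between two strategies
#'
#' Returns the ICUR `(cost_a - cost_b) / (qalys_a - qalys_b)` together with
#' a dominance verdict: `"a_dominates"` when a is cheaper and more
#' effective, `"a_dominated"` for the reverse, `"tie"` when both
#' differences vanish, otherwise `"icur"`.
#'
#' @param a,b Outcome rows with `cost` and `qalys`.
#' @return List with `delta_cost`, `delta_qalys`, `icur` (`NA` for ties)
#'   and `verdict`.
#' @export
incremental_ratio <- function(a, b) {
  dc <- a$cost - b$cost
  dq <- a$qalys - b$qalys
  verdict <- if (dc == 0 && dq == 0) "tie"
    else if (dc <= 0 && dq >= 0) "a_dominates"
    else if (dc >= 0 && dq <= 0) "a_dominated"
    else "icur"
  list(delta_cost = dc, delta_qalys = dq,
       icur = if (dq != 0) dc / dq else NA_real_, verdict = verdict)
}

#' Efficient frontier with strong and extended dominance
#'
#' Orders outcomes by ascending cost, removes strongly dominated strategies
#' (at least as costly and no more effective than another, with one strict
#' inequality), then iteratively removes extended-dominated strategies
#' (whose ICUR versus the previous frontier member exceeds the ICUR of the
#' next) until neighbor ICURs are strictly increasing.
#'
#' Cost ties keep the higher-QALY strategy; exact ties in both dimensions
#' keep the lexicographically smallest code.
#'
#' @param outcomes Data frame of outcomes (`code`, `cost`, `qalys`).
#' @param baseline Code of the comparator for the vs-baseline increments
#'   (default `"no_screening"`); it need not be on the frontier.
#' @return A `ugc_frontier`: list with `frontier` (ordered data frame with
#'   incremental cost/QALYs/ICUR versus the neighboring frontier member and
#'   versus the baseline) and `excluded` (data frame tagging each removed
#'   strategy `strongly_dominated` or `extended_dominated`).
#' @export
efficient_frontier <- function(outcomes, baseline = "no_screening") {
  df <- as_outcome_frame(outcomes)
  # deterministic ordering: cost ascending, then qalys descending, then code
  df <- df[order(df$cost, -df$qalys, df$code), , drop = FALSE]

  excluded <- data.frame(code = character(), reason = character(),
                         stringsAsFactors = FALSE)
  # exact ties in both dimensions: keep lexicographically smallest code
  dup <- duplicated(df[, c("cost", "qalys")])
  if (any(dup)) {
    excluded <- rbind(excluded, data.frame(code = df$code[dup],
                                           reason = "strongly_dominated"))
    df <- df[!dup, , drop = FALSE]
  }
  strong <- vapply(seq_len(nrow(df)), function(i) {
    any(df$cost <= df$cost[i] & df$qalys >= df$qalys[i] &
          (df$cost < df$cost[i] | df$qalys > df$qalys[i]))
  }, logical(1))
  if (any(strong))
    excluded <- rbind(excluded, data.frame(code = df$code[strong],
                                           reason = "strongly_dominated"))
  keep <- df[!strong, , drop = FALSE]

  repeat {
    if (nrow(keep) < 3L) break
    icur <- c(NA, diff(keep$cost) / diff(keep$qalys))
    bad <- which(icur[-length(icur)] >= icur[-1]) + 0L  # icur[i] >= icur[i+1]
    bad <- bad[bad > 1]   # first member has no previous ICUR
    if (!length(bad)) break
    drop_i <- bad[1]
    excluded <- rbind(excluded, data.frame(code = keep$code[drop_i],
                                           reason = "extended_dominated"))
    keep <- keep[-drop_i, , drop = FALSE]
  }

  base_row <- df[df$code == baseline, , drop = FALSE]
  fr <- keep
  fr$inc_cost_neighbor <- c(NA, diff(fr$cost))
  fr$inc_qalys_neighbor <- c(NA, diff(fr$qalys))
  fr$icur_neighbor <- fr$inc_cost_neighbor / fr$inc_qalys_neighbor
  if (nrow(base_row) == 1L) {
    fr$inc_cost_baseline <- fr$cost - base_row$cost
    fr$inc_qalys_baseline <- fr$qalys - base_row$qalys
    fr$icur_baseline <- ifelse(fr$code == baseline, NA,
                               fr$inc_cost_baseline / fr$inc_qalys_baseline)
  }
  fr$cur <- cost_utility_ratio(fr)
  rownames(fr) <- NULL
  structure(list(frontier = fr, excluded = excluded, baseline = baseline),
            class = "ugc_frontier")
}

#' @export
print.ugc_frontier <- function(x, ...) {
  cat(sprintf("<ugc_frontier> %d frontier members, %d excluded\n",
              nrow(x$frontier), nrow(x$excluded)))
  print(x$frontier[, c("code", "cost", "qalys", "icur_neighbor")], digits = 8)
  invisible(x)
}

#' Net monetary benefit of an outcome versus a baseline
#'
#' `NMB = lambda * (qalys - qalys_baseline) - (cost - cost_baseline)`; the
#' argmax over strategies at a willingness-to-pay `lambda` identifies the
#' optimal strategy.
#'
#' @param outcome Outcome row(s) with `cost` and `qalys`.
#' @param lambda Willingness-to-pay (CNY/QALY), `>= 0`.
#' @param baseline Baseline outcome row.
#' @return Numeric NMB (CNY), vectorised over rows of `outcome`.
#' @export
net_monetary_benefit <- function(outcome, lambda, baseline) {
  stopifnot(lambda >= 0)
  lambda * (outcome$qalys - baseline$qalys) - (outcome$cost - baseline$cost)
}

#' Optimal strategy at a willingness-to-pay threshold
#'
#' @param outcomes Outcome data frame.
#' @param lambda Willingness-to-pay (CNY/QALY).
#' @param baseline Baseline code (default `"no_screening"`).
#' @return The code of the NMB-maximising strategy.
#' @export
optimal_strategy <- function(outcomes, lambda, baseline = "no_screening") {
  df <- as_outcome_frame(outcomes)
  b <- df[df$code == baseline, , drop = FALSE]
  if (nrow(b) != 1L) stop("baseline not found: ", baseline, call. = FALSE)
  nmb <- net_monetary_benefit(df, lambda, b)
  df$code[which.max(nmb)]
}

#' Classify a strategy's ICUR against GDP-multiple thresholds
#'
#' High cost-utility is an ICUR below one-time per-capita GDP; 2x and 3x
#' thresholds are reported for context.
#'
#' @param icur ICUR value (CNY/QALY).
#' @param gdp_per_capita Per-capita GDP (default 70653 CNY).
#' @return One of `"high_cost_utility"` (`< 1x`), `"within_2x"`,
#'   `"within_3x"`, `"not_cost_effective"`.
#' @export
classify_icur <- function(icur, gdp_per_capita = 70653) {
  ifelse(icur < gdp_per_capita, "high_cost_utility",
    ifelse(icur < 2 * gdp_per_capita, "within_2x",
      ifelse(icur < 3 * gdp_per_capita, "within_3x", "not_cost_effective")))
}
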