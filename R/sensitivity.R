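# One-way deterministic sensitivity analysis, tornado ranking, threshold
# location, probabilistic sensitivity analysis and CEAC construction.

#' One-way parameter sweep
#'
#' Re-evaluates every strategy at each grid point of one parameter, holding
#' all other parameters at base.
#'
#' @param ps A `ugc_parameter_set`.
#' @param param Parameter path, e.g. `"compliance.screening"`,
#'   `"discount_rate"`, `"costs.screening_total"`,
#'   `"costs.treatment.es.sdcis"`, `"utilities.ga_HGIN"` (see
#'   [parameter_table()] for the inventory).
#' @param values Grid of values; defaults to the parameter's deterministic
#'   range endpoints `c(low, high)`.
#' @param strategies Named list of strategies (default the full grid).
#' @return Data frame: `param`, `value`, plus one outcome row per strategy
#'   and grid point.
#' @export
one_way_sweep <- function(ps, param, values = NULL,
                          strategies = enumerate_strategies()) {
  pv <- get_param(ps, param)  # errors on unknown parameter
  if (is.null(values)) values <- c(pv$low, pv$high)
  out <- lapply(values, function(x) {
    psx <- set_param_base(ps, param, x)
    res <- evaluate_strategies(psx, strategies)
    res$param <- param
    res$value <- x
    res
  })
  do.call(rbind, out)
}

#' Tornado table over a set of parameters
#'
#' For each parameter, evaluates the net monetary benefit of the base-case
#' optimal strategy (versus the baseline arm, at willingness-to-pay
#' `lambda`) with the parameter at its low and high range end, and ranks
#' parameters by the absolute NMB spread.
#'
#' @param ps A `ugc_parameter_set`.
#' @param params Character vector of parameter paths (default: every
#'   parameter with a non-degenerate range).
#' @param lambda Willingness-to-pay (default `ps$wtp`).
#' @param strategies Strategy list used to determine the base-case optimum.
#' @param baseline Baseline code.
#' @return Data frame sorted by descending `spread`: `param`, `low`,
#'   `high`, `nmb_low`, `nmb_high`, `spread`.
#' @export
tornado_table <- function(ps, params = NULL, lambda = ps$wtp,
                          strategies = enumerate_strategies(),
                          baseline = "no_screening") {
  if (is.null(params)) {
    pt <- parameter_table(ps)
    params <- pt$name[pt$high > pt$low]
  }
  base_res <- evaluate_strategies(ps, strategies)
  opt <- optimal_strategy(base_res, lambda, baseline)
  nmb_at <- function(res) {
    b <- res[res$code == baseline, , drop = FALSE]
    net_monetary_benefit(res[res$code == opt, , drop = FALSE], lambda, b)
  }
  rows <- lapply(params, function(p) {
    pv <- get_param(ps, p)
    lo_res <- evaluate_strategies(set_param_base(ps, p, pv$low), strategies)
    hi_res <- evaluate_strategies(set_param_base(ps, p, pv$high), strategies)
    nl <- nmb_at(lo_res); nh <- nmb_at(hi_res)
    data.frame(param = p, low = pv$low, high = pv$high,
               nmb_low = nl, nmb_high = nh, spread = abs(nh - nl),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$spread, out$param), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "optimal_strategy") <- opt
  out
}

#' Locate the parameter value at which the optimal strategy switches
#'
#' Scans the parameter's range on a coarse grid for a change in the
#' NMB-argmax strategy, then bisects the first bracketing interval to the
#' requested tolerance.  Returns `NULL` when the optimum is constant over
#' the whole range; when several switches exist the lowest is returned and
#' flagged.
#'
#' @param ps A `ugc_parameter_set`.
#' @param param Parameter path.
#' @param lambda Willingness-to-pay (default `ps$wtp`).
#' @param tolerance Bracket width at which bisection stops.
#' @param strategies Strategy list.
#' @param baseline Baseline code.
#' @param n_scan Coarse-scan grid size (default 8).
#' @return `NULL`, or a list `param`, `switch_value`, `below`, `above`,
#'   `multiple` (logical).
#' @export
threshold_locate <- function(ps, param, lambda = ps$wtp, tolerance = 1e-3,
                             strategies = enumerate_strategies(),
                             baseline = "no_screening", n_scan = 8L) {
  stopifnot(tolerance > 0)
  pv <- get_param(ps, param)
  if (pv$high <= pv$low) return(NULL)
  opt_at <- function(x) {
    res <- evaluate_strategies(set_param_base(ps, param, x), strategies)
    optimal_strategy(res, lambda, baseline)
  }
  grid <- seq(pv$low, pv$high, length.out = n_scan)
  opts <- vapply(grid, opt_at, "")
  ch <- which(opts[-1] != opts[-length(opts)])
  if (!length(ch)) return(NULL)
  lo <- grid[ch[1]]; hi <- grid[ch[1] + 1]
  o_lo <- opts[ch[1]]
  while (hi - lo > tolerance) {
    mid <- (lo + hi) / 2
    if (opt_at(mid) == o_lo) lo <- mid else hi <- mid
  }
  list(param = param, switch_value = (lo + hi) / 2,
       below = o_lo, above = opt_at(hi), multiple = length(ch) > 1L)
}

#' Probabilistic sensitivity analysis
#'
#' Draws `n` parameter-set variants (each parameter from its distribution,
#' jointly and independently) and evaluates every strategy under each.
#' Iteration `i` uses the child seed `seed + i`, so any subset of
#' iterations is reproducible.
#'
#' @param ps Base `ugc_parameter_set`.
#' @param n Number of Monte-Carlo iterations (study default 1000).
#' @param seed Root integer seed.
#' @param strategies Strategy list (default the full grid).
#' @return Data frame `iteration`, `code`, `cost`, `qalys`, with attribute
#'   `seed`.
#' @export
run_psa <- function(ps, n = 1000L, seed = 1L,
                    strategies = enumerate_strategies()) {
  stopifnot(n >= 1)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    psi <- sample_parameter_set(ps, seed + i)
    res <- evaluate_strategies(psi, strategies)
    rows[[i]] <- data.frame(iteration = i, code = res$code,
                            cost = res$cost, qalys = res$qalys,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "seed") <- seed
  out
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the fraction of PSA iterations in
#' which each strategy attains the maximal net monetary benefit (ties split
#' equally).
#'
#' @param psa Output of [run_psa()].
#' @param lambdas Willingness-to-pay grid (default 0 to 3x per-capita GDP
#'   in steps of 5000 CNY).
#' @param baseline Baseline code used in the NMB (the argmax is invariant
#'   to the baseline; it fixes the NMB scale only).
#' @return Data frame `wtp`, `code`, `probability`; probabilities over
#'   strategies sum to 1 at each `wtp`.
#' @export
compute_ceac <- function(psa, lambdas = seq(0, 3 * 70653, by = 5000),
                         baseline = NULL) {
  stopifnot(length(lambdas) > 0, nrow(psa) > 0)
  codes <- sort(unique(psa$code))
  iters <- sort(unique(psa$iteration))
  cost <- matrix(NA_real_, length(iters), length(codes),
                 dimnames = list(iters, codes))
  qaly <- cost
  idx <- cbind(match(psa$iteration, iters), match(psa$code, codes))
  cost[idx] <- psa$cost
  qaly[idx] <- psa$qalys
  out <- lapply(lambdas, function(l) {
    nmb <- l * qaly - cost
    wins <- numeric(length(codes))
    mx <- apply(nmb, 1, max)
    for (i in seq_along(iters)) {
      w <- which(nmb[i, ] >= mx[i] - 1e-9)
      wins[w] <- wins[w] + 1 / length(w)
    }
    data.frame(wtp = l, code = codes, probability = wins / length(iters),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
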