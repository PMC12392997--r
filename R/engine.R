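# Deterministic annual-cycle cohort engine.
#
# The engine works on an expanded state space: surveillance copies (prefix
# "s_") of the precancerous and early-cancer states for follow-up arms, and
# six duration-indexed tunnel copies ("_d1".."_d6") of each advanced-cancer
# state carrying duration-dependent death probabilities.  Within a cycle,
# other-cause death is applied first at the attained-age probability; the
# disease transitions then act on survivors (competing-risk ordering fixed
# for reproducibility).

mortality_at <- function(tab, age) {
  i <- match(age, tab$age)
  if (is.na(i))
    stop("age ", age, " outside mortality table coverage (",
         min(tab$age), "-", max(tab$age), ")", call. = FALSE)
  tab$prob[i]
}

# Age-independent disease-transition distributions over the expanded space:
# a list of (row state -> named target probabilities, stay implicit).
core_disease_rows <- function(ps) {
  ex <- expanded_states()
  tr <- ps$transitions
  by_from <- split(tr[c("to", "prob")], tr$from)
  get_row <- function(state) {
    r <- by_from[[state]]
    if (is.null(r)) return(stats::setNames(numeric(0), character(0)))
    stats::setNames(r$prob, r$to)
  }
  healthy_row <- get_row("healthy")
  post_row <- if ("post_tx" %in% names(by_from)) get_row("post_tx") else healthy_row

  # target remapping for the surveillance layer: lesions under surveillance
  # stay flagged while they remain pre-intramucosal or early; regression to
  # healthy exits surveillance; progression to advanced presents clinically.
  map_surv <- function(targets) {
    nm <- names(targets)
    nm <- ifelse(nm %in% c(precancer_states(), early_states()),
                 paste0("s_", nm), nm)
    stats::setNames(as.numeric(targets), nm)
  }
  map_adv_entry <- function(targets) {
    nm <- names(targets)
    nm <- ifelse(nm %in% advanced_states(), paste0(nm, "_d1"), nm)
    stats::setNames(as.numeric(targets), nm)
  }

  rows <- list()
  rows[["healthy"]] <- map_adv_entry(healthy_row)
  rows[["post_tx"]] <- map_adv_entry(post_row)
  for (s in c(precancer_states(), early_states())) {
    rows[[s]] <- map_adv_entry(get_row(s))
    rows[[paste0("s_", s)]] <- map_adv_entry(map_surv(get_row(s)))
  }
  rows
}

#' Assemble the full one-cycle transition operator at an attained age
#'
#' Composes the annual disease transitions with age-specific other-cause
#' mortality (applied competitively to every live state), age-specific
#' upper-GI-cancer mortality on early-cancer states, and duration-specific
#' advanced-cancer death probabilities on the tunnel states.  Rows sum to 1
#' exactly (the residual is the stay probability).
#'
#' @param ps A `ugc_parameter_set`.
#' @param age Attained age; must be covered by the mortality tables.
#' @return A stochastic matrix over the expanded engine state space.
#' @export
assemble_cycle_matrix <- function(ps, age, rows = NULL) {
  if (age < ps$age_span[1] || age > ps$age_span[2])
    stop("age ", age, " outside the model age span", call. = FALSE)
  if (is.null(rows)) rows <- core_disease_rows(ps)
  ex <- expanded_states()
  n <- length(ex)
  M <- matrix(0, n, n, dimnames = list(ex, ex))
  q_o <- mortality_at(ps$mortality$other, age)
  q_u <- mortality_at(ps$mortality$ugc, age)

  early_all <- c(early_states(), paste0("s_", early_states()))
  for (s in names(rows)) {
    d <- rows[[s]]
    stay <- 1 - sum(d)
    if (stay < -1e-12)
      stop("transition row for '", s, "' sums to more than 1", call. = FALSE)
    surv <- 1 - q_o
    M[s, "death_other"] <- q_o
    if (s %in% early_all) {
      M[s, "death_ugc"] <- surv * q_u
      surv <- surv * (1 - q_u)
    }
    if (length(d)) M[s, names(d)] <- M[s, names(d)] + surv * d
    M[s, s] <- M[s, s] + surv * max(stay, 0)
  }
  for (org in names(ORGANS)) {
    qd <- ps$mortality$advanced[[org]]
    for (k in seq_len(N_TUNNEL)) {
      s <- sprintf("%s_adv_d%d", org, k)
      nxt <- sprintf("%s_adv_d%d", org, min(k + 1L, N_TUNNEL))
      M[s, "death_other"] <- q_o
      M[s, "death_ugc"] <- (1 - q_o) * qd[k]
      M[s, nxt] <- M[s, nxt] + (1 - q_o) * (1 - qd[k])
    }
  }
  M["death_ugc", "death_ugc"] <- 1
  M["death_other", "death_other"] <- 1
  M
}

#' Advance a cohort occupancy vector through one cycle
#'
#' @param v Named occupancy vector (entries `>= 0`, summing to 1).
#' @param operator A transition matrix whose rows match `v`.
#' @return The occupancy vector after one cycle.
#' @export
advance_cohort <- function(v, operator) {
  if (length(v) != nrow(operator))
    stop("dimension mismatch between state vector and operator", call. = FALSE)
  drop(v %*% operator)
}

# ---------------------------------------------------------------------------
# Screening and follow-up rounds

#' Default lesion-management policy for a strategy
#'
#' On screen detection: severe dysplasia/CIS and HGIN are endoscopically
#' treated and move to the post-treatment state; early cancers are treated
#' (curative endoscopic resection) and move to post-treatment; advanced
#' cancers are tagged screen-detected for costing; lower-grade precancer
#' enters annual surveillance in follow-up arms and is left untouched
#' otherwise.
#'
#' @param strategy A `ugc_strategy` (or `NULL` for no screening).
#' @return An object of class `ugc_policy`.
#' @export
management_policy <- function(strategy) {
  follow_up <- !is.null(strategy) && strategy$follow_up
  lower <- setdiff(precancer_states(), treatable_precancer())
  actions <- c(
    stats::setNames(rep("treat_revert", length(treatable_precancer())),
                    treatable_precancer()),
    stats::setNames(rep("treat_early", length(early_states())), early_states()),
    stats::setNames(rep("advanced_screen_cost", length(advanced_states())),
                    advanced_states()),
    stats::setNames(rep(if (follow_up) "surveil" else "none", length(lower)),
                    lower))
  structure(list(follow_up = follow_up, actions = actions,
                 surveillance_interval = 1L),
            class = "ugc_policy")
}

# organ prefix of a core state id
state_org <- function(s) substr(s, 1, 2)

#' Apply one population screening round to an occupancy vector
#'
#' A fraction `compliance` of every live, undiagnosed state attends
#' (screening cost per attendance); within attenders, detectable lesion
#' mass is found with probability `Se` and managed per the policy, and
#' healthy attenders are flagged false-positive with probability `1 - Sp`
#' (costed at `options$fp_cost`, 0 by default).  Mass is conserved exactly.
#'
#' @param v Expanded occupancy vector.
#' @param ps A `ugc_parameter_set`.
#' @param policy A [management_policy()].
#' @return `list(v = updated vector, report = round report)` where the
#'   report carries attendances, true positives by state, false-positive
#'   mass, screen-detected advanced mass by organ, and accrued costs
#'   (per-capita CNY, undiscounted).
#' @export
apply_screening_round <- function(v, ps, policy) {
  cs <- ps$compliance$screening$base
  se <- ps$test$sensitivity$base
  sp <- ps$test$specificity$base
  detectable <- c(precancer_states(), early_states())
  adv_d1 <- paste0(advanced_states(), "_d1")
  screened <- c("healthy", "post_tx", detectable, adv_d1)

  occupied <- detectable[v[detectable] > 0]
  missing <- setdiff(occupied, names(policy$actions))
  if (length(missing))
    stop("management policy lacks an action for occupied state(s): ",
         paste(missing, collapse = ", "), call. = FALSE)

  attend <- cs * v[screened]
  names(attend) <- screened
  det <- se * attend[detectable]
  tp <- det

  cost_treat <- 0
  for (s in treatable_precancer()) {
    if (policy$actions[[s]] != "treat_revert") next
    m <- det[[s]]
    v[s] <- v[s] - m
    v["post_tx"] <- v["post_tx"] + m
    cost_treat <- cost_treat + m * ps$costs$treatment[[state_org(s)]]$sdcis$base
  }
  for (s in early_states()) {
    m <- det[[s]]
    v[s] <- v[s] - m
    v["post_tx"] <- v["post_tx"] + m
    cost_treat <- cost_treat + m * ps$costs$treatment[[state_org(s)]]$early$base
  }
  lower <- setdiff(precancer_states(), treatable_precancer())
  for (s in lower) {
    if (policy$actions[[s]] != "surveil") next
    m <- det[[s]]
    v[s] <- v[s] - m
    v[paste0("s_", s)] <- v[paste0("s_", s)] + m
  }
  # advanced cancer in its first (undiagnosed) tunnel year: detected mass is
  # costed at the screen-detected rate; it stays in its tunnel.
  adv_det <- stats::setNames(se * cs * v[adv_d1], names(ORGANS))
  cost_adv <- sum(vapply(names(ORGANS), function(org)
    adv_det[[org]] * ps$costs$treatment[[org]]$advanced_screen$base, 0))

  fp <- (1 - sp) * (attend[["healthy"]] + attend[["post_tx"]])
  costs <- list(
    screening = sum(attend) * ps$costs$screening_total$base,
    treatment = cost_treat + cost_adv,
    fp = fp * ps$options$fp_cost)
  list(v = v, report = list(attendances = sum(attend), tp = tp, fp = fp,
                            adv_screen_detected = adv_det, costs = costs))
}

#' Apply one annual follow-up surveillance round
#'
#' A fraction `follow-up compliance` of the surveilled lesion mass receives
#' an endoscopy (screening cost per attendance); detection with `Se` routes
#' high-grade lesions and early cancers to endoscopic treatment, while
#' lower-grade lesions remain under surveillance.
#'
#' @inheritParams apply_screening_round
#' @return `list(v, report)` as for [apply_screening_round()].
#' @export
apply_follow_up_round <- function(v, ps, policy) {
  if (!policy$follow_up)
    stop("follow-up round invoked for a strategy without follow-up",
         call. = FALSE)
  cf <- ps$compliance$follow_up$base
  se <- ps$test$sensitivity$base
  surv_states <- paste0("s_", c(precancer_states(), early_states()))
  attend <- cf * v[surv_states]
  det <- se * attend

  cost_treat <- 0
  for (s in paste0("s_", treatable_precancer())) {
    m <- det[[s]]
    v[s] <- v[s] - m
    v["post_tx"] <- v["post_tx"] + m
    org <- state_org(sub("^s_", "", s))
    cost_treat <- cost_treat + m * ps$costs$treatment[[org]]$sdcis$base
  }
  for (s in paste0("s_", early_states())) {
    m <- det[[s]]
    v[s] <- v[s] - m
    v["post_tx"] <- v["post_tx"] + m
    org <- state_org(sub("^s_", "", s))
    cost_treat <- cost_treat + m * ps$costs$treatment[[org]]$early$base
  }
  costs <- list(screening = sum(attend) * ps$costs$screening_total$base,
                treatment = cost_treat, fp = 0)
  list(v = v, report = list(attendances = sum(attend), tp = det, fp = 0,
                            adv_screen_detected = stats::setNames(
                              numeric(length(ORGANS)), names(ORGANS)),
                            costs = costs))
}

# ---------------------------------------------------------------------------
# Cohort propagation

# Precompute the age-indexed cycle operators once per parameter set.
build_engine <- function(ps) {
  rows <- core_disease_rows(ps)
  ages <- seq(ps$age_span[1], ps$age_span[2])
  mats <- lapply(ages, function(a) assemble_cycle_matrix(ps, a, rows))
  names(mats) <- as.character(ages)
  list(ages = ages, matrices = mats)
}

#' Run the cohort through the full horizon under a screening strategy
#'
#' Deterministic fraction-flow propagation from entry age to the horizon
#' with a 1-year cycle.  With `strategy = NULL` this is the pure natural
#' history (the no-screening reference arm).  Screening rounds occur at the
#' start of a cycle, before the natural-history transition; follow-up
#' surveillance rounds run annually from the cycle after the first
#' screening round in follow-up arms.
#'
#' Treatment-cost timing: mass entering an advanced state is undiagnosed
#' for one cycle; if a screening round occurs in that cycle it is
#' screen-detected with probability compliance x Se (screen-detected
#' treatment cost) and the remainder presents clinically (clinical
#' treatment cost).  Early-cancer and high-grade-precancer treatment costs
#' accrue on screen/follow-up detection only.
#'
#' @param ps A `ugc_parameter_set`.
#' @param strategy A `ugc_strategy`, or `NULL` for no screening.
#' @param engine Optional precomputed operator set (internal reuse).
#' @return A `ugc_trace`: start-of-cycle occupancy matrix (one row per age),
#'   per-cycle event tallies and undiscounted per-capita cost components.
#' @export
run_cohort <- function(ps, strategy = NULL, engine = NULL) {
  if (is.null(engine)) engine <- build_engine(ps)
  policy <- management_policy(strategy)
  schedule <- if (is.null(strategy)) integer(0) else build_schedule(strategy)
  ex <- expanded_states()
  ages <- engine$ages
  n_cyc <- length(ages)
  adv_d1 <- paste0(advanced_states(), "_d1")
  cancer_entry <- c(early_states(), paste0("s_", early_states()), adv_d1)
  noncancer <- c("healthy", "post_tx", precancer_states(),
                 paste0("s_", precancer_states()))

  occ <- matrix(0, n_cyc, length(ex), dimnames = list(ages, ex))
  ev <- data.frame(age = ages, new_cases_es = 0, new_cases_ca = 0,
                   new_cases_ga = 0, ugc_deaths = 0, other_deaths = 0,
                   detections = 0, attendances = 0,
                   cost_screening = 0, cost_followup = 0, cost_treatment = 0)

  cs <- ps$compliance$screening$base
  se <- ps$test$sensitivity$base
  v <- expand_initial(ps$initial_distribution)

  for (t in seq_len(n_cyc)) {
    age <- ages[t]
    occ[t, ] <- v
    d1_start <- v[adv_d1]   # undiagnosed advanced mass at cycle start

    screen_now <- age %in% schedule
    if (screen_now) {
      r <- apply_screening_round(v, ps, policy)
      v <- r$v
      ev$detections[t] <- ev$detections[t] + sum(r$report$tp) +
        sum(r$report$adv_screen_detected)
      ev$attendances[t] <- ev$attendances[t] + r$report$attendances
      ev$cost_screening[t] <- ev$cost_screening[t] +
        r$report$costs$screening + r$report$costs$fp
      ev$cost_treatment[t] <- ev$cost_treatment[t] + r$report$costs$treatment
    }
    # clinical presentation of the remaining newly-advanced mass
    sd_frac <- if (screen_now) cs * se else 0
    for (org in names(ORGANS)) {
      clin <- d1_start[[paste0(org, "_adv_d1")]] * (1 - sd_frac)
      ev$cost_treatment[t] <- ev$cost_treatment[t] +
        clin * ps$costs$treatment[[org]]$advanced_clinical$base
    }
    if (policy$follow_up && age > strategy$start_age &&
        (age - strategy$start_age) %% policy$surveillance_interval == 0) {
      r <- apply_follow_up_round(v, ps, policy)
      v <- r$v
      ev$detections[t] <- ev$detections[t] + sum(r$report$tp)
      ev$attendances[t] <- ev$attendances[t] + r$report$attendances
      ev$cost_followup[t] <- ev$cost_followup[t] + r$report$costs$screening
      ev$cost_treatment[t] <- ev$cost_treatment[t] + r$report$costs$treatment
    }
    if (t < n_cyc) {
      M <- engine$matrices[[t]]
      flows_in <- v[noncancer] %*% M[noncancer, cancer_entry, drop = FALSE]
      fl <- stats::setNames(drop(flows_in), cancer_entry)
      for (org in names(ORGANS)) {
        col <- paste0("new_cases_", org)
        ev[[col]][t] <- fl[[paste0(org, "_early")]] +
          fl[[paste0("s_", org, "_early")]] + fl[[paste0(org, "_adv_d1")]]
      }
      ev$ugc_deaths[t] <- sum(v * M[, "death_ugc"]) - v[["death_ugc"]]
      ev$other_deaths[t] <- sum(v * M[, "death_other"]) - v[["death_other"]]
      v <- advance_cohort(v, M)
    }
  }
  structure(list(occupancy = occ, events = ev,
                 cohort_size = ps$cohort_size,
                 strategy = if (is.null(strategy)) "no_screening" else strategy$code),
            class = "ugc_trace")
}

#' @export
print.ugc_trace <- function(x, ...) {
  s <- tally_events(x)
  cat(sprintf("<ugc_trace> %s: %d cycles, cohort %d\n", x$strategy,
              nrow(x$occupancy), x$cohort_size))
  cat(sprintf("  cumulative cases %.0f (es %.0f, ca %.0f, ga %.0f), UGC deaths %.0f\n",
              s$cases, s$cases_by_organ[["es"]], s$cases_by_organ[["ca"]],
              s$cases_by_organ[["ga"]], s$ugc_deaths))
  invisible(x)
}

#' Summarise cumulative events along a cohort trace
#'
#' @param trace A `ugc_trace` from [run_cohort()].
#' @return List with `cases` (cumulative first entries into cancer states,
#'   cohort scale), `cases_by_organ`, `ugc_deaths`, `other_deaths`,
#'   `life_years` (undiscounted live person-years), `detections`.
#' @export
tally_events <- function(trace) {
  ev <- trace$events
  n <- trace$cohort_size
  live <- setdiff(colnames(trace$occupancy), c("death_ugc", "death_other"))
  by_org <- c(es = sum(ev$new_cases_es), ca = sum(ev$new_cases_ca),
              ga = sum(ev$new_cases_ga)) * n
  list(cases = sum(by_org),
       cases_by_organ = by_org,
       ugc_deaths = sum(ev$ugc_deaths) * n,
       other_deaths = sum(ev$other_deaths) * n,
       life_years = sum(trace$occupancy[, live]) * n,
       detections = sum(ev$detections) * n)
}
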