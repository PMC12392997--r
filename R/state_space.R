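#' Default health-state space for the upper-GI natural history model
#'
#' Sixteen disease states across three anatomical tracks — esophagus
#' (mild dysplasia, moderate dysplasia, severe dysplasia/carcinoma in situ,
#' early cancer, advanced cancer), cardia (intestinal metaplasia, low- and
#' high-grade intraepithelial neoplasia, early, advanced) and gastric
#' (chronic atrophic gastritis, intestinal metaplasia, LGIN, HGIN, early,
#' advanced) — plus a healthy state, a post-endoscopic-treatment state that
#' shares the healthy state's utilities and onset transitions, and two
#' absorbing death states (upper-GI-cancer death, other-cause death).
#'
#' `pre_intramucosal` flags the precancerous grades, among which regression
#' is biologically permitted; once a lesion reaches intramucosal carcinoma
#' (the early-cancer states) progression is forward-only.
#'
#' @return A data frame with one row per state and columns `state`, `organ`
#'   (`esophagus`/`cardia`/`gastric`/`none`), `grade` (`healthy`,
#'   `precancer`, `early_cancer`, `advanced_cancer`, `death`),
#'   `pre_intramucosal` and `screen_detectable`.
#' @examples
#' ss <- default_state_space()
#' sum(!ss$grade %in% c("healthy", "death"))  # 16 disease states + post_tx
#' @export
default_state_space <- function() {
  row <- function(state, organ, grade, pre, det)
    data.frame(state = state, organ = organ, grade = grade,
               pre_intramucosal = pre, screen_detectable = det,
               stringsAsFactors = FALSE)
  rbind(
    row("healthy",  "none", "healthy", FALSE, FALSE),
    row("post_tx",  "none", "healthy", FALSE, FALSE),
    row("es_mD",    "esophagus", "precancer", TRUE, TRUE),
    row("es_MD",    "esophagus", "precancer", TRUE, TRUE),
    row("es_SDCIS", "esophagus", "precancer", TRUE, TRUE),
    row("es_early", "esophagus", "early_cancer", FALSE, TRUE),
    row("es_adv",   "esophagus", "advanced_cancer", FALSE, TRUE),
    row("ca_IM",    "cardia", "precancer", TRUE, TRUE),
    row("ca_LGIN",  "cardia", "precancer", TRUE, TRUE),
    row("ca_HGIN",  "cardia", "precancer", TRUE, TRUE),
    row("ca_early", "cardia", "early_cancer", FALSE, TRUE),
    row("ca_adv",   "cardia", "advanced_cancer", FALSE, TRUE),
    row("ga_CAG",   "gastric", "precancer", TRUE, TRUE),
    row("ga_IM",    "gastric", "precancer", TRUE, TRUE),
    row("ga_LGIN",  "gastric", "precancer", TRUE, TRUE),
    row("ga_HGIN",  "gastric", "precancer", TRUE, TRUE),
    row("ga_early", "gastric", "early_cancer", FALSE, TRUE),
    row("ga_adv",   "gastric", "advanced_cancer", FALSE, TRUE),
    row("death_ugc",   "none", "death", FALSE, FALSE),
    row("death_other", "none", "death", FALSE, FALSE)
  )
}

# Organ prefixes and per-organ state ladders used throughout the engine.
ORGANS <- c(es = "esophagus", ca = "cardia", ga = "gastric")

organ_states <- function(prefix) {
  switch(prefix,
    es = c("es_mD", "es_MD", "es_SDCIS", "es_early", "es_adv"),
    ca = c("ca_IM", "ca_LGIN", "ca_HGIN", "ca_early", "ca_adv"),
    ga = c("ga_CAG", "ga_IM", "ga_LGIN", "ga_HGIN", "ga_early", "ga_adv"))
}

precancer_states <- function() {
  c("es_mD", "es_MD", "es_SDCIS", "ca_IM", "ca_LGIN", "ca_HGIN",
    "ga_CAG", "ga_IM", "ga_LGIN", "ga_HGIN")
}

# Precancer grades treated endoscopically on detection (one per organ:
# the organ's highest pre-intramucosal grade, costed at its SD/CIS-grade
# treatment row).
treatable_precancer <- function() c("es_SDCIS", "ca_HGIN", "ga_HGIN")

early_states <- function() c("es_early", "ca_early", "ga_early")
advanced_states <- function() c("es_adv", "ca_adv", "ga_adv")

N_TUNNEL <- 6L  # advanced-cancer duration years 1..5 plus a 6+ bucket

# Expanded (engine) state space: surveillance copies of precancer and early
# states for follow-up arms, and duration-indexed tunnel copies of the
# advanced states.
expanded_states <- function() {
  adv <- unlist(lapply(advanced_states(),
                       function(s) paste0(s, "_d", seq_len(N_TUNNEL))))
  c("healthy", "post_tx",
    precancer_states(),
    paste0("s_", precancer_states()),
    early_states(),
    paste0("s_", early_states()),
    adv,
    "death_ugc", "death_other")
}

# Map a core-state occupancy vector onto the expanded space (advanced mass
# enters the first tunnel year; no surveilled mass initially).
expand_initial <- function(init) {
  ex <- expanded_states()
  v <- stats::setNames(numeric(length(ex)), ex)
  for (s in names(init)) {
    tgt <- if (s %in% advanced_states()) paste0(s, "_d1") else s
    if (!tgt %in% ex) stop("unknown state in initial distribution: ", s,
                           call. = FALSE)
    v[tgt] <- v[tgt] + init[[s]]
  }
  v
}

live_states <- function() setdiff(expanded_states(), c("death_ugc", "death_other"))
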