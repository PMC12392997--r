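#' Specification for the synthetic natural-history generator
#'
#' The transition probabilities, initial state distribution and mortality
#' schedules that drive the cohort model are location-specific registry and
#' yearbook inputs; this generator produces structurally faithful, seeded
#' stand-ins so the whole pipeline runs end-to-end.  Generated tables make
#' no claim of clinical accuracy — they exist to exercise the model
#' structure (three organ ladders with bidirectional precancer transitions,
#' forward-only progression after intramucosal carcinoma, age-increasing
#' background mortality, duration-dependent advanced-cancer survival).
#'
#' @param seed Integer seed controlling the jitter applied to the baseline
#'   transition intensities.
#' @param progression_intensity Multiplier on all forward (progression)
#'   probabilities; `>= 0`.
#' @param regression_intensity Multiplier on all backward (regression)
#'   probabilities among pre-intramucosal states; `>= 0`.
#' @param onset_scale Multiplier on healthy-to-first-lesion onset
#'   probabilities; `>= 0`.
#' @param jitter_sd Standard deviation of the lognormal jitter on each edge
#'   (0 disables jitter).
#' @param mortality_40,mortality_80 Annual other-cause death probability at
#'   ages 40 and 80; the curve is exponential in age between them
#'   (defaults 0.003 and 0.065, a realistic adult schedule).
#' @param ugc_mortality_40,ugc_mortality_slope Base and exponential slope of
#'   the age-indexed upper-GI-cancer mortality series applied to
#'   early-cancer states.
#' @param survival_5yr Named list of 5-year survival by organ prefix for
#'   advanced cancer (default 0.20 at every site, the survival of
#'   late-stage diagnosis).
#' @return An object of class `ugc_synthetic_spec`.
#' @export
synthetic_spec <- function(seed = 42L,
                           progression_intensity = 1,
                           regression_intensity = 1,
                           onset_scale = 1,
                           jitter_sd = 0.1,
                           mortality_40 = 0.003, mortality_80 = 0.065,
                           ugc_mortality_40 = 0.02, ugc_mortality_slope = 0.01,
                           survival_5yr = list(es = 0.20, ca = 0.20, ga = 0.20)) {
  stopifnot(progression_intensity >= 0, regression_intensity >= 0,
            onset_scale >= 0, jitter_sd >= 0,
            mortality_40 > 0, mortality_80 > 0)
  structure(list(seed = as.integer(seed),
                 progression_intensity = progression_intensity,
                 regression_intensity = regression_intensity,
                 onset_scale = onset_scale, jitter_sd = jitter_sd,
                 mortality_40 = mortality_40, mortality_80 = mortality_80,
                 ugc_mortality_40 = ugc_mortality_40,
                 ugc_mortality_slope = ugc_mortality_slope,
                 survival_5yr = survival_5yr),
            class = "ugc_synthetic_spec")
}

# Baseline annual intensities before scaling/jitter.  Forward edges follow
# each organ's grade ladder; regressions exist only among pre-intramucosal
# grades (and back to healthy from the first grade).
synth_edge_template <- function() {
  e <- function(from, to, prob, kind)
    data.frame(from = from, to = to, prob = prob, kind = kind,
               stringsAsFactors = FALSE)
  rbind(
    # onsets out of healthy (mirrored for post-treatment)
    e("healthy", "es_mD",  0.0090, "onset"),
    e("healthy", "ca_IM",  0.0070, "onset"),
    e("healthy", "ga_CAG", 0.0140, "onset"),
    # esophagus ladder
    e("es_mD",    "es_MD",    0.060, "forward"),
    e("es_MD",    "es_SDCIS", 0.050, "forward"),
    e("es_SDCIS", "es_early", 0.120, "forward"),
    e("es_early", "es_adv",   0.350, "forward"),
    e("es_mD",    "healthy",  0.050, "backward"),
    e("es_MD",    "es_mD",    0.040, "backward"),
    e("es_SDCIS", "es_MD",    0.020, "backward"),
    # cardia ladder
    e("ca_IM",    "ca_LGIN",  0.040, "forward"),
    e("ca_LGIN",  "ca_HGIN",  0.040, "forward"),
    e("ca_HGIN",  "ca_early", 0.100, "forward"),
    e("ca_early", "ca_adv",   0.350, "forward"),
    e("ca_IM",    "healthy",  0.050, "backward"),
    e("ca_LGIN",  "ca_IM",    0.040, "backward"),
    e("ca_HGIN",  "ca_LGIN",  0.020, "backward"),
    # gastric ladder
    e("ga_CAG",   "ga_IM",    0.060, "forward"),
    e("ga_IM",    "ga_LGIN",  0.050, "forward"),
    e("ga_LGIN",  "ga_HGIN",  0.045, "forward"),
    e("ga_HGIN",  "ga_early", 0.100, "forward"),
    e("ga_early", "ga_adv",   0.350, "forward"),
    e("ga_CAG",   "healthy",  0.050, "backward"),
    e("ga_IM",    "ga_CAG",   0.040, "backward"),
    e("ga_LGIN",  "ga_IM",    0.030, "backward")
  )
}

#' Generate a seeded synthetic annual transition table
#'
#' @param spec A [synthetic_spec()].
#' @return Data frame `from`, `to`, `prob`, `period_years` obeying the
#'   structural invariants (row sums `<= 1`, no regression out of
#'   post-intramucosal states).
#' @export
synth_transition_table <- function(spec) {
  stopifnot(inherits(spec, "ugc_synthetic_spec"))
  tab <- synth_edge_template()
  scale <- c(onset = spec$onset_scale,
             forward = spec$progression_intensity,
             backward = spec$regression_intensity)
  tab$prob <- tab$prob * scale[tab$kind]
  if (spec$jitter_sd > 0) {
    tab$prob <- with_seed_(spec$seed,
      tab$prob * exp(stats::rnorm(nrow(tab), 0, spec$jitter_sd)))
  }
  rs <- tapply(tab$prob, tab$from, sum)
  over <- names(rs)[rs > 1]
  if (length(over))
    stop("intensities produce row sums > 1 for: ",
         paste(over, collapse = ", "), call. = FALSE)
  tab$kind <- NULL
  tab$period_years <- 1
  tab
}

synth_mortality <- function(spec, age_span = c(40L, 80L)) {
  ages <- seq(age_span[1], age_span[2])
  slope <- log(spec$mortality_80 / spec$mortality_40) / 40
  other <- spec$mortality_40 * exp(slope * (ages - 40))
  ugc <- spec$ugc_mortality_40 * exp(spec$ugc_mortality_slope * (ages - 40))
  list(
    other = data.frame(age = ages, prob = pmin(other, 1)),
    ugc = data.frame(age = ages, prob = pmin(ugc, 1)),
    advanced = lapply(spec$survival_5yr, derive_advanced_mortality)
  )
}

# Initial state distribution emulating lesion detection rates in a
# 40-44-year-old population: ~98% healthy, small precancer fractions
# shrinking with grade, trace early cancer, no prevalent advanced cancer.
synth_initial_distribution <- function() {
  init <- c(
    es_mD = 0.0040, es_MD = 0.0015, es_SDCIS = 0.0005,
    ca_IM = 0.0030, ca_LGIN = 0.0010, ca_HGIN = 0.0003,
    ga_CAG = 0.0060, ga_IM = 0.0030, ga_LGIN = 0.0010, ga_HGIN = 0.0003,
    es_early = 0.0001, ca_early = 0.0001, ga_early = 0.0001)
  c(healthy = 1 - sum(init), init)
}

# Printed base-case utilities, costs, test characteristics, compliances and
# discount rate with their deterministic ranges and PSA families.
printed_parameters <- function() {
  tri <- function(a, c, b) dist_spec("triangular", c(a, c, b))
  pv <- param_value
  utilities <- list(
    es_mD    = pv("utilities.es_mD",    0.944, 0.940, 1.000, tri(0.94, 0.98, 1.00)),
    es_MD    = pv("utilities.es_MD",    0.939, 0.930, 1.000, tri(0.93, 0.98, 1.00)),
    es_SDCIS = pv("utilities.es_SDCIS", 0.921, 0.881, 0.961, dist_spec("beta", c(0.929, 0.145))),
    es_early = pv("utilities.es_early", 0.889, 0.849, 0.929, dist_spec("beta", c(0.904, 0.180))),
    es_adv   = pv("utilities.es_adv",   0.804, 0.764, 0.844, dist_spec("beta", c(0.838, 0.223))),
    ca_IM    = pv("utilities.ca_IM",    0.960, 0.920, 1.000, dist_spec("beta", c(0.972, 0.035))),
    ca_LGIN  = pv("utilities.ca_LGIN",  0.941, 0.940, 1.000, tri(0.94, 0.98, 1.00)),
    ca_HGIN  = pv("utilities.ca_HGIN",  0.927, 0.887, 0.967, dist_spec("beta", c(0.936, 0.09))),
    ca_early = pv("utilities.ca_early", 0.863, 0.823, 0.903, dist_spec("beta", c(0.894, 0.221))),
    ca_adv   = pv("utilities.ca_adv",   0.724, 0.684, 0.764, dist_spec("beta", c(0.757, 0.303))),
    ga_CAG   = pv("utilities.ga_CAG",   0.969, 0.929, 1.000, dist_spec("beta", c(0.972, 0.035))),
    ga_IM    = pv("utilities.ga_IM",    0.960, 0.920, 1.000, dist_spec("beta", c(0.972, 0.035))),
    ga_LGIN  = pv("utilities.ga_LGIN",  0.930, 0.930, 1.000, tri(0.93, 0.98, 1.00)),
    ga_HGIN  = pv("utilities.ga_HGIN",  0.922, 0.882, 0.962, dist_spec("beta", c(0.937, 0.150))),
    ga_early = pv("utilities.ga_early", 0.828, 0.788, 0.868, dist_spec("beta", c(0.939, 0.139))),
    ga_adv   = pv("utilities.ga_adv",   0.773, 0.733, 0.803, dist_spec("beta", c(0.803, 0.286))))
  g <- function(a, b) dist_spec("gamma", c(a, b))
  tc <- function(name, base, lo, hi, d)
    pv(name, base, lo, hi, d, units = "CNY")
  costs <- list(
    screening_total = tc("costs.screening_total", 651.36, 521.09, 781.63, g(2.16, 0.003)),
    screening_components = c(direct_medical = 629.70, direct_nonmedical = 13.59,
                             indirect = 7.97),
    treatment = list(
      es = list(
        sdcis = tc("costs.treatment.es.sdcis", 21950.52, 17560.42, 26340.62, g(20.43, 0.001)),
        early = tc("costs.treatment.es.early", 44891.14, 35912.91, 53869.37, g(12.23, 0.0003)),
        advanced_clinical = tc("costs.treatment.es.advanced_clinical",
                               76138.39, 60910.71, 91366.07, g(26.85, 0.0004)),
        advanced_screen = tc("costs.treatment.es.advanced_screen",
                             45683.03, 36546.43, 54819.64, g(17.13, 0.0004))),
      ca = list(
        sdcis = tc("costs.treatment.ca.sdcis", 25568.31, 20454.65, 30681.97, g(4.15, 0.0002)),
        early = tc("costs.treatment.ca.early", 35162.11, 28129.69, 42194.53, g(11.04, 0.0004)),
        advanced_clinical = tc("costs.treatment.ca.advanced_clinical",
                               64760.92, 51808.74, 77713.10, g(22.30, 0.0004)),
        advanced_screen = tc("costs.treatment.ca.advanced_screen",
                             38856.55, 31085.24, 46627.86, g(8.10, 0.0002))),
      ga = list(
        sdcis = tc("costs.treatment.ga.sdcis", 26891.98, 21513.58, 32270.38, g(5.45, 0.0002)),
        early = tc("costs.treatment.ga.early", 44221.23, 35376.98, 53065.48, g(10.13, 0.0002)),
        advanced_clinical = tc("costs.treatment.ga.advanced_clinical",
                               67278.45, 53822.76, 80734.14, g(23.85, 0.0004)),
        advanced_screen = tc("costs.treatment.ga.advanced_screen",
                             40367.07, 32293.66, 48440.48, g(4.41, 0.0001)))))
  list(
    utilities = utilities, costs = costs,
    test = list(
      sensitivity = pv("test.sensitivity", 0.96, 0.90, 0.99, tri(0.90, 0.96, 0.99)),
      specificity = pv("test.specificity", 0.90, 0.80, 0.95, tri(0.80, 0.90, 0.95))),
    compliance = list(
      screening = pv("compliance.screening", 0.60, 0.30, 0.80, tri(0.30, 0.60, 0.80)),
      follow_up = pv("compliance.follow_up", 0.75, 0.50, 0.90, tri(0.50, 0.75, 0.90))),
    discount_rate = pv("discount_rate", 0.03, 0.02, 0.05, tri(0.02, 0.03, 0.05)))
}

#' Assemble a complete synthetic parameter set
#'
#' Combines seeded synthetic structural tables (transitions, initial
#' distribution, mortality) with the published base-case utilities, costs,
#' test characteristics, compliance rates and discount rate.
#'
#' @param spec A [synthetic_spec()]; defaults to the package default.
#' @param ... Passed to [parameter_set()] (e.g. `cohort_size`, `options`).
#' @return A validated `ugc_parameter_set`.
#' @examples
#' ps <- synth_parameter_set(synthetic_spec(seed = 1))
#' ps$test$sensitivity$base  # 0.96
#' @export
synth_parameter_set <- function(spec = synthetic_spec(), ...) {
  printed <- printed_parameters()
  parameter_set(
    state_space = default_state_space(),
    transitions = synth_transition_table(spec),
    initial_distribution = synth_initial_distribution(),
    mortality = synth_mortality(spec),
    utilities = printed$utilities,
    costs = printed$costs,
    test = printed$test,
    compliance = printed$compliance,
    discount_rate = printed$discount_rate,
    ...)
}
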