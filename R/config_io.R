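# Structured-text (YAML) parameter configuration, format "ugc-cea/1".
# A config written by write_parameter_config() round-trips through
# load_parameter_set(); synthetic and hand-edited inputs are interchangeable.

pv_to_list <- function(pv) {
  out <- list(base = pv$base, range = c(pv$low, pv$high),
              dist = list(family = pv$dist$family,
                          params = pv$dist$params))
  if (!is.null(pv$dist$truncation)) out$dist$truncation <- pv$dist$truncation
  if (nzchar(pv$units)) out$units <- pv$units
  out
}

pv_from_list <- function(name, x) {
  if (is.numeric(x) && length(x) == 1L)       # shorthand: bare number = fixed
    return(param_value(name, x))
  if (is.null(x$base)) stop("parameter '", name, "': missing 'base'", call. = FALSE)
  d <- if (is.null(x$dist)) NULL else
    dist_spec(x$dist$family, unlist(x$dist$params),
              truncation = if (is.null(x$dist$truncation)) NULL else
                unlist(x$dist$truncation))
  rng <- if (is.null(x$range)) c(x$base, x$base) else unlist(x$range)
  param_value(name, x$base, rng[1], rng[2], dist = d,
              units = if (is.null(x$units)) "" else x$units)
}

#' Write a parameter set to a structured-text configuration file
#'
#' @param ps A `ugc_parameter_set`.
#' @param path Destination file path.
#' @return Invisibly, `path`.
#' @export
write_parameter_config <- function(ps, path) {
  tr <- ps$transitions
  doc <- list(
    format = "ugc-cea/1",
    cohort_size = ps$cohort_size,
    age_span = ps$age_span,
    wtp = ps$wtp,
    options = ps$options,
    discount_rate = pv_to_list(ps$discount_rate),
    compliance = lapply(ps$compliance, pv_to_list),
    test = lapply(ps$test, pv_to_list),
    utilities = lapply(ps$utilities, pv_to_list),
    costs = list(
      screening_total = pv_to_list(ps$costs$screening_total),
      screening_components = as.list(ps$costs$screening_components),
      treatment = lapply(ps$costs$treatment, function(org)
        lapply(org, pv_to_list))),
    initial_distribution = as.list(ps$initial_distribution),
    transitions = lapply(seq_len(nrow(tr)), function(i)
      list(from = tr$from[i], to = tr$to[i], prob = tr$prob[i],
           period_years = tr$period_years[i])),
    mortality = list(
      input_type = "probability",
      other = list(age = ps$mortality$other$age,
                   value = ps$mortality$other$prob),
      ugc = list(age = ps$mortality$ugc$age,
                 value = ps$mortality$ugc$prob),
      advanced = lapply(ps$mortality$advanced, as.numeric)))
  yaml::write_yaml(doc, path, precision = 12)
  invisible(path)
}

#' Load and validate a parameter set from a configuration file
#'
#' Reads a `ugc-cea/1` structured-text document.  Missing optional blocks
#' take documented defaults: cohort size 100,000, ages 40-80, discount rate
#' 0.03, willingness-to-pay 70,653 CNY/QALY.  Mortality series declared
#' with `input_type: rate` are converted with [rate_to_probability()];
#' advanced-cancer mortality may be given either as explicit length-6
#' duration series or as 5-year survivals (key `advanced_survival_5yr`),
#' expanded with [derive_advanced_mortality()].
#'
#' @param path Path to the configuration file.
#' @return A validated `ugc_parameter_set`.
#' @export
load_parameter_set <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  doc <- yaml::read_yaml(path)
  if (is.null(doc$format) || !identical(doc$format, "ugc-cea/1"))
    stop("config schema error: key 'format' must be \"ugc-cea/1\"", call. = FALSE)
  need <- function(key) {
    if (is.null(doc[[key]]))
      stop("config schema error: missing key '", key, "'", call. = FALSE)
    doc[[key]]
  }
  tr_raw <- need("transitions")
  tr <- do.call(rbind, lapply(tr_raw, function(e) {
    if (is.null(e$from) || is.null(e$to) || is.null(e$prob))
      stop("config schema error: transition entry missing from/to/prob",
           call. = FALSE)
    data.frame(from = e$from, to = e$to, prob = e$prob,
               period_years = if (is.null(e$period_years)) 1 else e$period_years,
               stringsAsFactors = FALSE)
  }))
  mo <- need("mortality")
  conv <- if (identical(mo$input_type, "rate")) rate_to_probability else identity
  series <- function(key) {
    s <- mo[[key]]
    if (is.null(s)) stop("config schema error: missing mortality '", key, "'",
                         call. = FALSE)
    data.frame(age = unlist(s$age), prob = conv(unlist(s$value)))
  }
  adv <- if (!is.null(mo$advanced)) lapply(mo$advanced, unlist)
         else if (!is.null(mo$advanced_survival_5yr))
           lapply(mo$advanced_survival_5yr, derive_advanced_mortality)
         else stop("config schema error: mortality needs 'advanced' or ",
                   "'advanced_survival_5yr'", call. = FALSE)
  co <- need("costs")
  utilities <- need("utilities")
  parameter_set(
    state_space = default_state_space(),
    transitions = tr,
    initial_distribution = unlist(need("initial_distribution")),
    mortality = list(other = series("other"), ugc = series("ugc"),
                     advanced = adv),
    utilities = stats::setNames(
      lapply(names(utilities), function(n)
        pv_from_list(paste0("utilities.", n), utilities[[n]])),
      names(utilities)),
    costs = list(
      screening_total = pv_from_list("costs.screening_total", co$screening_total),
      screening_components = unlist(co$screening_components),
      treatment = stats::setNames(
        lapply(names(co$treatment), function(org)
          stats::setNames(
            lapply(names(co$treatment[[org]]), function(k)
              pv_from_list(paste0("costs.treatment.", org, ".", k),
                           co$treatment[[org]][[k]])),
            names(co$treatment[[org]]))),
        names(co$treatment))),
    test = list(
      sensitivity = pv_from_list("test.sensitivity", need("test")$sensitivity),
      specificity = pv_from_list("test.specificity", need("test")$specificity)),
    compliance = list(
      screening = pv_from_list("compliance.screening", need("compliance")$screening),
      follow_up = pv_from_list("compliance.follow_up", need("compliance")$follow_up)),
    discount_rate = if (is.null(doc$discount_rate))
      param_value("discount_rate", 0.03, 0.02, 0.05,
                  dist_spec("triangular", c(0.02, 0.03, 0.05)))
      else pv_from_list("discount_rate", doc$discount_rate),
    cohort_size = if (is.null(doc$cohort_size)) 100000L else doc$cohort_size,
    age_span = if (is.null(doc$age_span)) c(40L, 80L) else unlist(doc$age_span),
    wtp = if (is.null(doc$wtp)) 70653 else doc$wtp,
    options = if (is.null(doc$options)) list() else doc$options)
}
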