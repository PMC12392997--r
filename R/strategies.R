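#' Define a single endoscopic screening strategy
#'
#' Strategies are coded `y<start>_<f|nf>_i<interval>`: screening start age
#' (40/45/50/55), precancer follow-up (`f`) or not (`nf`), and screening
#' interval in years (`i1`, `i2`, `i5`, `i10`, `i15`) or `in` for
#' once-in-a-lifetime.  Screening stops after age 70.
#'
#' @param start_age Screening start age, one of 40, 45, 50, 55.
#' @param interval Interval in years (1, 2, 5, 10, 15) or `"once"`.
#' @param follow_up Logical; annual endoscopic surveillance of detected
#'   lower-grade precancerous lesions.
#' @param end_age Last eligible screening age (default 70).
#' @return An object of class `ugc_strategy` with fields `code`,
#'   `start_age`, `end_age`, `interval`, `follow_up`.
#' @examples
#' screening_strategy(40, 1, FALSE)$code  # "y40_nf_i1"
#' @export
screening_strategy <- function(start_age, interval, follow_up,
                               end_age = 70L) {
  stopifnot(start_age %in% c(40L, 45L, 50L, 55L),
            identical(interval, "once") || interval %in% c(1, 2, 5, 10, 15),
            is.logical(follow_up), start_age <= end_age)
  code <- sprintf("y%d_%s_i%s", start_age, if (follow_up) "f" else "nf",
                  if (identical(interval, "once")) "n" else interval)
  structure(list(code = code, start_age = as.integer(start_age),
                 end_age = as.integer(end_age), interval = interval,
                 follow_up = follow_up),
            class = "ugc_strategy")
}

#' @export
print.ugc_strategy <- function(x, ...) {
  cat(sprintf("<ugc_strategy> %s: ages %d-%d, every %s year(s), %s follow-up\n",
              x$code, x$start_age, x$end_age,
              if (identical(x$interval, "once")) "once per lifetime, no"
              else as.character(x$interval),
              if (x$follow_up) "with" else "without"))
  invisible(x)
}

#' Parse a strategy code back into a strategy object
#' @param code A code such as `"y45_f_i10"` or `"y50_f_in"`.
#' @return A `ugc_strategy`.
#' @export
parse_strategy <- function(code) {
  m <- regmatches(code, regexec("^y(\\d+)_(f|nf)_i(\\d+|n)$", code))[[1]]
  if (length(m) != 4L) stop("unrecognised strategy code: ", code, call. = FALSE)
  screening_strategy(as.integer(m[2]),
                     if (m[4] == "n") "once" else as.numeric(m[4]),
                     m[3] == "f")
}

#' Enumerate the 40 combined screening strategies
#'
#' The full grid: start ages 40/45/50/55 crossed with intervals 1, 2, 5,
#' 10, 15 years and once-per-lifetime without follow-up, and intervals 5,
#' 10, 15 and once with follow-up (annual surveillance is redundant under
#' 1- and 2-yearly screening, so those arms have no follow-up variant).
#'
#' @param include_reference If `TRUE`, append the no-screening reference
#'   (`NULL` policy) as a final `"no_screening"` entry.
#' @return A named list of `ugc_strategy` objects (40 of them), optionally
#'   followed by `no_screening = NULL`.
#' @export
enumerate_strategies <- function(include_reference = FALSE) {
  out <- list()
  for (age in c(40L, 45L, 50L, 55L)) {
    for (iv in list(1, 2, 5, 10, 15, "once"))
      out[[length(out) + 1L]] <- screening_strategy(age, iv, FALSE)
    for (iv in list(5, 10, 15, "once"))
      out[[length(out) + 1L]] <- screening_strategy(age, iv, TRUE)
  }
  names(out) <- vapply(out, `[[`, "", "code")
  if (include_reference) out <- c(out, list(no_screening = NULL))
  out
}

#' Screening ages implied by a strategy
#'
#' @param strategy A `ugc_strategy`.
#' @return Integer vector of ages `start, start + interval, ... <= end_age`
#'   (a single age for once-per-lifetime strategies).
#' @examples
#' build_schedule(screening_strategy(55, 15, FALSE))  # 55 70
#' @export
build_schedule <- function(strategy) {
  stopifnot(inherits(strategy, "ugc_strategy"))
  if (identical(strategy$interval, "once")) return(strategy$start_age)
  seq(strategy$start_age, strategy$end_age, by = strategy$interval)
}
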