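#' Age-interval scheme
#'
#' Defines the ordered chronological-age intervals used to anchor irregularly
#' timed longitudinal assessments. The default is the four intervals
#' 51-55, 56-60, 61-65 and 66-72 years commonly used for mid-to-late-life
#' twin assessments spanning ages 51-72.
#'
#' Interval membership is decided on completed years: an assessment at age
#' 55.9 belongs to 51-55 because `floor(55.9) = 55`.
#'
#' @param breaks Data frame (or tibble) with columns `label`, `min`, `max`
#'   (integer years, inclusive). If `NULL`, the default four-interval scheme.
#' @return A tibble of class `age_interval_scheme` with columns `label`,
#'   `min`, `max`.
#' @examples
#' age_interval_scheme()
#' @export
age_interval_scheme <- function(breaks = NULL) {
  if (is.null(breaks)) {
    breaks <- tibble(
      label = c("51-55", "56-60", "61-65", "66-72"),
      min   = c(51L, 56L, 61L, 66L),
      max   = c(55L, 60L, 65L, 72L)
    )
  }
  breaks <- as_tibble(breaks)
  stopifnot(all(c("label", "min", "max") %in% names(breaks)))
  breaks <- arrange(breaks, .data$min)
  if (any(breaks$min > breaks$max))
    abort("each interval must satisfy min <= max")
  if (nrow(breaks) > 1) {
    gaps <- breaks$min[-1] - breaks$max[-nrow(breaks)]
    if (any(gaps != 1))
      abort("intervals must be ordered, non-overlapping and contiguous in whole years")
  }
  class(breaks) <- c("age_interval_scheme", class(breaks))
  breaks
}

#' Assign an age to its interval
#'
#' Maps ages (in years) to interval labels by completed years:
#' `floor(age)` must fall inside an interval's `[min, max]`.
#'
#' @param age Numeric vector of ages in years.
#' @param scheme An [age_interval_scheme()].
#' @return Character vector of interval labels; `NA` where the age is outside
#'   the scheme (callers decide whether to drop or error).
#' @examples
#' assign_interval(c(55.9, 56.0, 71.7))
#' @export
assign_interval <- function(age, scheme = age_interval_scheme()) {
  fl <- floor(age)
  idx <- rep(NA_integer_, length(age))
  for (i in seq_len(nrow(scheme))) {
    idx[fl >= scheme$min[i] & fl <= scheme$max[i]] <- i
  }
  scheme$label[idx]
}

#' Predicted brain-age difference (PBAD)
#'
#' PBAD is chronological age minus predicted brain age (PBA). A negative PBAD
#' means the brain is predicted to be older than the person's chronological
#' age; a positive PBAD means it is predicted younger.
#'
#' @param pba Predicted brain age in years.
#' @param age Chronological age at assessment in years.
#' @return `age - pba`, in years.
#' @examples
#' derive_pbad(pba = 65, age = 60) # -5: brain-age older
#' @export
derive_pbad <- function(pba, age) {
  if (any(!is.finite(pba)) || any(!is.finite(age)))
    abort("pba and age must be finite")
  age - pba
}
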