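#' Anchor longitudinal assessments onto age intervals
#'
#' Converts a long per-assessment table into one wide row per twin pair with
#' one phenotype slot per age interval and twin. Each subject's score at a
#' wave is re-coded to the interval containing the age at that assessment;
#' when a subject is assessed twice inside the same interval only the first
#' (earliest-wave) observation is kept. Records whose age falls outside the
#' scheme are dropped and tallied. The resulting structured missingness is
#' what the raw-data FIML engine is designed to absorb.
#'
#' @param long Long table with columns `family_id`, `twin` (1/2),
#'   `zygosity` (`"MZ"`/`"DZ"`), `wave`, `age`, `phenotype`, and optionally
#'   covariate columns `scanner`, `ethnicity`, `birth_year`.
#' @param scheme An [age_interval_scheme()].
#' @return A wide tibble (`family_id`, `zygosity`, `t1_a`..`tT_a`,
#'   `t1_b`..`tT_b`) with attributes:
#'   * `report` — tallies, see [anchor_report()];
#'   * `covariates` — per kept observation (`family_id`, `twin`, `interval`,
#'     `age`, plus any covariate columns present), aligned with the wide cells
#'     and consumed by [residualize()].
#' @seealso [residualize()], [fiml_loglik()]
#' @export
age_anchor <- function(long, scheme = age_interval_scheme()) {
  long <- as_tibble(long)
  req <- c("family_id", "twin", "zygosity", "wave", "age", "phenotype")
  miss <- setdiff(req, names(long))
  if (length(miss)) abort(paste0("long table lacks columns: ", paste(miss, collapse = ", ")))

  Tn <- nrow(scheme)
  if (nrow(long) == 0) {
    wide <- empty_wide(Tn)
    attr(wide, "report") <- anchor_report_new(Tn)
    attr(wide, "covariates") <- tibble()
    return(wide)
  }

  dup_wave <- long %>%
    dplyr::count(.data$family_id, .data$twin, .data$wave) %>%
    filter(.data$n > 1)
  if (nrow(dup_wave) > 0)
    abort(paste0("duplicate records for the same subject and wave (e.g. family ",
                 dup_wave$family_id[1], ", twin ", dup_wave$twin[1], ")"))

  long <- mutate(long, interval = assign_interval(.data$age, scheme))
  n_out_of_range <- sum(is.na(long$interval))
  kept <- filter(long, !is.na(.data$interval))

  # first-observation rule inside an interval
  kept <- kept %>%
    arrange(.data$family_id, .data$twin, .data$interval, .data$wave) %>%
    group_by(.data$family_id, .data$twin, .data$interval) %>%
    mutate(.dup = row_number() > 1) %>%
    ungroup()
  n_dropped_dup <- sum(kept$.dup)
  kept <- filter(kept, !.data$.dup) %>% select(-".dup")

  per_subject <- kept %>%
    group_by(.data$family_id, .data$twin) %>%
    summarise(k = dplyr::n_distinct(.data$interval), .groups = "drop")
  tallies <- vapply(seq_len(Tn), function(k) sum(per_subject$k == k), integer(1))

  zyg <- kept %>% distinct(.data$family_id, .data$zygosity)
  if (anyDuplicated(zyg$family_id))
    abort("inconsistent zygosity within a family")

  idx <- match(kept$interval, scheme$label)
  kept$.col <- paste0("t", idx, "_", ifelse(kept$twin == 1, "a", "b"))
  wide <- kept %>%
    select("family_id", ".col", "phenotype") %>%
    tidyr::pivot_wider(names_from = ".col", values_from = "phenotype")
  all_cols <- wide_value_cols(Tn)
  for (cl in setdiff(all_cols, names(wide))) wide[[cl]] <- NA_real_
  wide <- wide %>%
    left_join(zyg, by = "family_id") %>%
    select("family_id", "zygosity", dplyr::all_of(all_cols)) %>%
    arrange(.data$family_id)

  cov_cols <- intersect(c("scanner", "ethnicity", "birth_year"), names(kept))
  covars <- kept %>%
    select("family_id", "twin", "interval", "age", dplyr::all_of(cov_cols))

  rep <- anchor_report_new(Tn)
  rep$subjects_by_n_intervals <- setNames(as.integer(tallies), paste0("n", seq_len(Tn)))
  rep$dropped_duplicates <- as.integer(n_dropped_dup)
  rep$dropped_out_of_range <- as.integer(n_out_of_range)
  rep$n_pairs <- nrow(wide)
  attr(wide, "report") <- rep
  attr(wide, "covariates") <- covars
  wide
}

anchor_report_new <- function(Tn) {
  structure(list(
    subjects_by_n_intervals = setNames(integer(Tn), paste0("n", seq_len(Tn))),
    dropped_duplicates = 0L,
    dropped_out_of_range = 0L,
    n_pairs = 0L
  ), class = "anchor_report")
}

wide_value_cols <- function(Tn) {
  c(paste0("t", seq_len(Tn), "_a"), paste0("t", seq_len(Tn), "_b"))
}

empty_wide <- function(Tn) {
  out <- tibble(family_id = character(0), zygosity = character(0))
  for (cl in wide_value_cols(Tn)) out[[cl]] <- numeric(0)
  out
}

#' Anchoring report
#'
#' Extracts the tallies recorded by [age_anchor()]: how many subjects
#' contributed data in exactly 1, 2, ... intervals, how many within-interval
#' duplicate observations were dropped (first-observation rule), and how many
#' records fell outside the interval scheme.
#'
#' @param wide A wide table produced by [age_anchor()].
#' @return A list of class `anchor_report`.
#' @export
anchor_report <- function(wide) {
  rep <- attr(wide, "report")
  if (is.null(rep)) abort("no anchor report attached; was this table produced by age_anchor()?")
  rep
}

#' @export
print.anchor_report <- function(x, ...) {
  cat("Age-anchoring report\n")
  cat("  pairs:", x$n_pairs, "\n")
  cat("  subjects by number of intervals:",
      paste(sprintf("%s=%d", names(x$subjects_by_n_intervals), x$subjects_by_n_intervals),
            collapse = ", "), "\n")
  cat("  dropped within-interval duplicates:", x$dropped_duplicates, "\n")
  cat("  dropped out-of-range records:", x$dropped_out_of_range, "\n")
  invisible(x)
}

#' Per-observation covariates attached by age_anchor
#'
#' @param wide A wide table produced by [age_anchor()].
#' @return Tibble with one row per kept observation.
#' @export
anchor_covariates <- function(wide) {
  cv <- attr(wide, "covariates")
  if (is.null(cv)) abort("no covariates attached; was this table produced by age_anchor()?")
  cv
}
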