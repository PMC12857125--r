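#' Exclusion rules for cohort filtering
#'
#' An exclusion rule pairs a name (its tally bucket) with a vectorized
#' predicate over a cohort data frame returning `TRUE` for records to remove.
#' Rules are applied jointly: the kept set is the set matching no rule, so it
#' does not depend on rule order. When a record matches several rules its
#' removal is attributed to the first matching rule in declared order, so
#' tallies (but never the kept set) can depend on ordering.
#'
#' `rule_min_age(21)` drops records below the legal drinking age using
#' `age_years` where present, otherwise any age-group label is accepted.
#' `rule_missing(field)` drops records with `NA` (or empty-string) values.
#' `rule_disallowed(field, values)` drops disallowed category labels such as
#' an unusable "other" race code. `rule_year_range(min, max)` keeps only
#' surveys in an inclusive year window (the sensitivity-analysis filter).
#' `rule_nondrinker()` and `rule_inconsistent_gpd()` build the drinker-only
#' analytic sample: the latter's default flags records claiming drinker
#' status with missing or zero grams-per-day, a stand-in predicate that can
#' be replaced by any function of the data.
#'
#' @param name Tally-bucket name for the rule.
#' @param predicate Function of a data frame returning a logical vector
#'   (`TRUE` = exclude). `NA` results are treated as `FALSE`.
#' @return An object of class `exclusion_rule`.
#' @examples
#' r <- exclusion_rule("under_age", function(d) d$age_years < 21)
#' @export
exclusion_rule <- function(name, predicate) {
  stopifnot(is.character(name), length(name) == 1L, is.function(predicate))
  structure(list(name = name, predicate = predicate), class = "exclusion_rule")
}

#' @rdname exclusion_rule
#' @param min_age Minimum age in whole years (inclusive).
#' @export
rule_min_age <- function(min_age = 21) {
  exclusion_rule("under_age", function(d) {
    if (is.null(d$age_years)) rep(FALSE, nrow(d)) else d$age_years < min_age
  })
}

#' @rdname exclusion_rule
#' @param field Column name the rule inspects.
#' @export
rule_missing <- function(field) {
  exclusion_rule(paste0("missing_", field), function(d) {
    x <- d[[field]]
    is.na(x) | (is.character(x) & !is.na(x) & x == "")
  })
}

#' @rdname exclusion_rule
#' @param values Disallowed labels for `field`.
#' @export
rule_disallowed <- function(field, values) {
  exclusion_rule(paste0("disallowed_", field), function(d) {
    !is.na(d[[field]]) & d[[field]] %in% values
  })
}

#' @rdname exclusion_rule
#' @param min,max Inclusive survey-year bounds.
#' @export
rule_year_range <- function(min, max) {
  exclusion_rule("outside_year_range", function(d) {
    d$survey_year < min | d$survey_year > max
  })
}

#' @rdname exclusion_rule
#' @export
rule_nondrinker <- function() {
  exclusion_rule("nondrinker", function(d) !is.na(d$drinker) & d$drinker == 0)
}

#' @rdname exclusion_rule
#' @export
rule_missing_gpd <- function() {
  exclusion_rule("missing_gpd", function(d) is.na(d$gpd))
}

#' @rdname exclusion_rule
#' @export
rule_inconsistent_gpd <- function(predicate = NULL) {
  if (is.null(predicate))
    predicate <- function(d) !is.na(d$drinker) & d$drinker == 1 & (is.na(d$gpd) | d$gpd == 0)
  exclusion_rule("inconsistent_gpd", predicate)
}

#' Apply exclusion rules to a cohort
#'
#' Partitions records into kept and excluded sets and tallies removals per
#' rule. The kept set is invariant to rule order; attribution of overlapping
#' removals follows the declared order (first matching rule wins).
#'
#' @param data Cohort data frame.
#' @param rules List of [exclusion_rule()] objects (possibly empty).
#' @return List with `kept` and `excluded` data frames and an integer `tally`
#'   named by rule.
#' @examples
#' cohort <- data.frame(age_years = c(18, 30), survey_year = 2009,
#'                      drinker = 1, gpd = 5)
#' apply_exclusions(cohort, list(rule_min_age(21)))$tally
#' @export
apply_exclusions <- function(data, rules = list()) {
  stopifnot(is.data.frame(data))
  if (inherits(rules, "exclusion_rule")) rules <- list(rules)
  n <- nrow(data)
  tally <- integer(length(rules))
  names(tally) <- vapply(rules, `[[`, character(1L), "name")
  if (!length(rules) || n == 0L) {
    return(list(kept = data, excluded = data[integer(0L), , drop = FALSE], tally = tally))
  }
  attributed <- integer(n) # 0 = kept, k = removed by rule k
  for (k in seq_along(rules)) {
    hit <- rules[[k]]$predicate(data)
    if (length(hit) != n) stop("rule '", names(tally)[k], "' returned wrong length")
    hit[is.na(hit)] <- FALSE
    tally[k] <- sum(hit & attributed == 0L)
    attributed[hit & attributed == 0L] <- k
  }
  list(kept = data[attributed == 0L, , drop = FALSE],
       excluded = data[attributed != 0L, , drop = FALSE],
       tally = tally)
}

#' Default analytic filters
#'
#' Convenience rule sets for the two analytic samples: `drinking_status_rules()`
#' (all adults 21+, usable race code, non-missing education and drinker
#' status) and `gpd_rules()` (additionally current drinkers with usable
#' grams-per-day).
#'
#' @param min_age Minimum age (years).
#' @param other_race_labels Race labels treated as unusable.
#' @return List of [exclusion_rule()] objects.
#' @export
drinking_status_rules <- function(min_age = 21, other_race_labels = "Other") {
  list(rule_min_age(min_age),
       rule_disallowed("race_ethnicity", other_race_labels),
       rule_missing("education"),
       rule_missing("drinker"))
}

#' @rdname drinking_status_rules
#' @export
gpd_rules <- function(min_age = 21, other_race_labels = "Other") {
  c(drinking_status_rules(min_age, other_race_labels),
    list(rule_nondrinker(), rule_missing_gpd(), rule_inconsistent_gpd()))
}

#' Cap grams-per-day at a plausibility ceiling
#'
#' Heavy self-reported intakes are top-coded at `cap` grams of pure alcohol
#' per day (the default 200 g is roughly 14 US standard drinks) to tame
#' implausible outliers before log-transformation. Idempotent.
#'
#' @param gpd Non-negative numeric vector (NA passed through).
#' @param cap Ceiling in grams/day.
#' @return `pmin(gpd, cap)`.
#' @examples
#' cap_gpd(c(15, 350)) # 15 200
#' @export
cap_gpd <- function(gpd, cap = 200) {
  if (any(gpd < 0, na.rm = TRUE)) stop("gpd must be non-negative")
  if (length(cap) != 1L || cap <= 0) stop("cap must be a positive scalar")
  pmin(gpd, cap)
}

#' Natural-log transform of consumption
#'
#' The drinker-only grams-per-day outcome is strongly right-skewed; the
#' linear model is fitted to its natural log. Requires strictly positive
#' input: zero consumption denotes a non-drinker, removed upstream.
#'
#' @param gpd Positive numeric vector (NA passed through).
#' @return `log(gpd)`.
#' @examples
#' log_gpd(exp(1)) # 1
#' @export
log_gpd <- function(gpd) {
  if (any(gpd <= 0, na.rm = TRUE)) stop("gpd must be strictly positive for log transform")
  log(gpd)
}

#' Group exact ages into design age bands
#'
#' Closed integer bins 21-24, 25-59 and 60+; ages of 85 and over are treated
#' as 85 (the survey's top-code). Ages below 21 return `NA` (they are
#' excluded by [rule_min_age()]).
#'
#' @param age_years Integer vector of ages.
#' @return Character vector of age-group labels.
#' @export
age_to_group <- function(age_years) {
  age_years <- pmin(age_years, 85L)
  out <- rep(NA_character_, length(age_years))
  out[age_years >= 21 & age_years <= 24] <- "21-24"
  out[age_years >= 25 & age_years <= 59] <- "25-59"
  out[age_years >= 60] <- "60+"
  out
}

#' Read or write a cohort CSV
#'
#' Cohort files are plain CSV with header columns `sex`, `race_ethnicity`,
#' `age_group`, `education`, `survey_year`, `drinker`, `gpd` (extra columns
#' such as `age_years` or `stratum` are preserved). Missing values are
#' encoded as empty fields.
#'
#' @param file Path to a CSV file.
#' @param data Cohort data frame.
#' @return `read_cohort()` returns a data frame; `write_cohort()` returns
#'   `file` invisibly.
#' @export
read_cohort <- function(file) {
  d <- utils::read.csv(file, stringsAsFactors = FALSE, na.strings = "")
  req <- c("sex", "race_ethnicity", "age_group", "education", "survey_year")
  missing_cols <- setdiff(req, names(d))
  if (length(missing_cols))
    stop("cohort file lacks column(s): ", paste(missing_cols, collapse = ", "))
  d
}

#' @rdname read_cohort
#' @export
write_cohort <- function(data, file) {
  utils::write.csv(data, file, row.names = FALSE, na = "")
  invisible(file)
}
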