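#' Define a social category axis
#'
#' A category axis is one dimension of the intersectional cross-classification
#' (for example sex, race/ethnicity, age group, or educational attainment).
#' The reference level is the one absorbed into the intercept when the axis
#' enters a main-effects design matrix.
#'
#' @param name Identifier for the axis (e.g. `"sex"`). Must match the column
#'   name carrying this axis in individual-level data.
#' @param levels Character vector of unique, non-empty category labels, in the
#'   order used for stratum enumeration.
#' @param reference Label used as the fixed-effect baseline; defaults to the
#'   first level.
#' @param short_codes Optional named character vector mapping levels to the
#'   short codes used in canonical stratum labels (e.g. `c(Men = "M")`).
#'   Levels without a short code print as themselves.
#' @return An object of class `category_axis`.
#' @examples
#' category_axis("sex", c("Men", "Women"), short_codes = c(Men = "M", Women = "F"))
#' @export
category_axis <- function(name, levels, reference = levels[1L], short_codes = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  levels <- as.character(levels)
  if (length(levels) < 1L || anyNA(levels) || any(!nzchar(levels)))
    stop("axis '", name, "': levels must be non-empty strings")
  if (anyDuplicated(levels))
    stop("axis '", name, "': duplicate level labels")
  if (!reference %in% levels)
    stop("axis '", name, "': reference level '", reference, "' is not a level")
  codes <- levels
  names(codes) <- levels
  if (!is.null(short_codes)) {
    bad <- setdiff(names(short_codes), levels)
    if (length(bad)) stop("short_codes name unknown levels: ", paste(bad, collapse = ", "))
    codes[names(short_codes)] <- short_codes
  }
  structure(
    list(name = name, levels = levels, reference = reference, short_codes = codes),
    class = "category_axis"
  )
}

#' Build a crossed strata design
#'
#' Enumerates every combination of levels across the supplied axes as an
#' intersectional stratum. Enumeration is deterministic and lexicographic:
#' the first axis varies slowest, the last axis fastest, levels in declared
#' order, so stratum indices are reproducible across runs and platforms.
#'
#' @param axes List of [category_axis()] objects (at least one).
#' @param label_order Optional character vector of axis names giving the order
#'   in which levels are pasted into the canonical stratum label. Defaults to
#'   axis order. This only affects display labels, never indices.
#' @return An object of class `strata_design` with components `axes` (named
#'   list) and `strata` (data frame with `index`, one column per axis, and
#'   `label`, the canonical label).
#' @examples
#' d <- strata_design(list(
#'   category_axis("sex", c("Men", "Women")),
#'   category_axis("education", c("low", "high"))
#' ))
#' nrow(d$strata) # 4
#' @seealso [nhis_design()] for the default 108-stratum design.
#' @export
strata_design <- function(axes, label_order = NULL) {
  if (!length(axes)) stop("at least one axis is required")
  if (!all(vapply(axes, inherits, logical(1L), "category_axis")))
    stop("all axes must be category_axis objects")
  nm <- vapply(axes, `[[`, character(1L), "name")
  if (anyDuplicated(nm)) stop("duplicate axis names")
  names(axes) <- nm
  if (is.null(label_order)) label_order <- nm
  if (!setequal(label_order, nm)) stop("label_order must be a permutation of axis names")

  lev <- lapply(axes, `[[`, "levels")
  # expand.grid varies the first factor fastest; reverse so the first axis
  # varies slowest (lexicographic over axis order, then level order)
  grid <- expand.grid(rev(lev), KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[, rev(seq_along(lev)), drop = FALSE]
  names(grid) <- nm

  label <- .canonical_labels(grid, axes, label_order)
  if (anyDuplicated(label)) stop("stratum labels are not unique")
  strata <- cbind(data.frame(index = seq_len(nrow(grid))), grid,
                  data.frame(label = label, stringsAsFactors = FALSE))
  structure(list(axes = axes, strata = strata, label_order = label_order),
            class = "strata_design")
}

.canonical_labels <- function(grid, axes, label_order) {
  parts <- lapply(label_order, function(a) {
    unname(axes[[a]]$short_codes[grid[[a]]])
  })
  do.call(paste, c(parts, sep = ", "))
}

#' @export
print.strata_design <- function(x, ...) {
  sizes <- vapply(x$axes, function(a) length(a$levels), integer(1L))
  cat("Strata design: ", paste(sizes, collapse = " x "), " = ",
      nrow(x$strata), " strata\n", sep = "")
  for (a in x$axes)
    cat("  ", a$name, ": ", paste(a$levels, collapse = ", "),
        " (ref: ", a$reference, ")\n", sep = "")
  invisible(x)
}

#' Default NHIS-like intersectional design
#'
#' The 2 x 6 x 3 x 3 = 108 stratum cross-classification of US adults used
#' throughout the package: sex (Men/Women), race and ethnicity (non-Hispanic
#' White, Black, Asian, Mixed-race, American Indian/Alaska Native, and
#' Hispanic), age group (21-24, 25-59, 60+), and educational attainment
#' (low = high school or less, medium = some college, high = 4+ years of
#' college). Reference categories are Men, White, 21-24, and low education.
#' Canonical labels read sex, age, race, education, e.g. `"M, 21-24, White, high"`.
#'
#' @return A `strata_design` with 108 strata.
#' @examples
#' nrow(nhis_design()$strata)
#' @export
nhis_design <- function() {
  strata_design(
    list(
      category_axis("sex", c("Men", "Women"),
                    short_codes = c(Men = "M", Women = "F")),
      category_axis("race_ethnicity",
                    c("White", "Black", "Asian", "Mixed-race", "AI/AN", "Hispanic")),
      category_axis("age_group", c("21-24", "25-59", "60+")),
      category_axis("education", c("low", "medium", "high"))
    ),
    label_order = c("sex", "age_group", "race_ethnicity", "education")
  )
}

#' Assign individuals to strata
#'
#' Maps each record's category labels to its stratum index in the design.
#' The mapping is a bijection between in-design label tuples and indices
#' `1..J`; any missing or out-of-design label is an error (such records
#' should have been removed by [apply_exclusions()] first).
#'
#' @param data Data frame with one column per design axis (matching axis
#'   names), or a single-row list.
#' @param design A [strata_design()].
#' @return Integer vector of stratum indices, one per row of `data`.
#' @examples
#' d <- nhis_design()
#' rec <- data.frame(sex = "Men", race_ethnicity = "White",
#'                   age_group = "21-24", education = "high")
#' d$strata$label[stratum_index(rec, d)] # "M, 21-24, White, high"
#' @export
stratum_index <- function(data, design) {
  stopifnot(inherits(design, "strata_design"))
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  nm <- names(design$axes)
  missing_cols <- setdiff(nm, names(data))
  if (length(missing_cols))
    stop("data lacks axis column(s): ", paste(missing_cols, collapse = ", "))
  idx <- rep(0L, nrow(data))
  for (a in nm) {
    li <- match(as.character(data[[a]]), design$axes[[a]]$levels)
    if (anyNA(li)) {
      bad <- unique(data[[a]][is.na(li)])
      stop("axis '", a, "': label(s) not in design or missing: ",
           paste(utils::head(bad, 5L), collapse = ", "))
    }
    idx <- idx * length(design$axes[[a]]$levels) + (li - 1L)
  }
  idx + 1L
}

#' Recover category labels from stratum indices
#'
#' Inverse of [stratum_index()].
#'
#' @param index Integer vector of stratum indices.
#' @param design A [strata_design()].
#' @return Data frame of axis labels, one row per index.
#' @export
stratum_labels <- function(index, design) {
  stopifnot(inherits(design, "strata_design"))
  if (any(index < 1L | index > nrow(design$strata)))
    stop("stratum index out of range")
  design$strata[index, names(design$axes), drop = FALSE]
}
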