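# Serology utilities: ImmunoCAP class assignment, sensitization and
# dust-mite eligibility rules.

#' ImmunoCAP class of a specific-IgE concentration
#'
#' Seven ordinal classes over kU/l concentrations: class 0 below 0.35;
#' class 1 \[0.35, 0.71); class 2 \[0.71, 3.51); class 3 \[3.51, 7.6);
#' class 4 \[7.6, 17.6); class 5 \[17.6, 50\]; class 6 above 50. The printed
#' class table leaves small gaps between upper and lower bounds
#' (0.70 / 0.71 etc.); bounds are treated as half-open intervals anchored at
#' the printed lower bounds, with class 5 closed at 50, giving exhaustive
#' gap-free coverage consistent with every printed breakpoint.
#'
#' @param sige Numeric vector of specific-IgE concentrations (kU/l), >= 0.
#' @return Integer vector of classes 0-6.
#' @examples
#' cap_class(c(0.2, 0.35, 2, 50, 50.001))
#' @export
cap_class <- function(sige) {
  if (any(is.na(sige)) || any(sige < 0)) {
    abort("specific-IgE concentrations must be non-negative")
  }
  cls <- findInterval(sige, c(0.35, 0.71, 3.51, 7.6, 17.6))
  cls[sige > 50] <- 6L
  as.integer(cls)
}

#' Is a subject sensitized to an allergen?
#'
#' Sensitization threshold: specific IgE at or above 0.35 kU/l (class >= 1).
#'
#' @param serology Serology tibble from [read_serology()].
#' @param allergen Name of the allergen concentration column; an unknown
#'   column is an error.
#' @return Logical vector, one element per subject.
#' @export
is_sensitized <- function(serology, allergen) {
  if (!allergen %in% names(serology)) {
    abort(paste0("unknown allergen column: ", allergen))
  }
  serology[[allergen]] >= 0.35
}

#' Dust-mite eligibility with reasons
#'
#' A subject is eligible when both Der f and Der p specific IgE reach at
#' least CAP class 2 and no exclusion flag is set (co-morbid asthma, eczema
#' or other allergic disease; hypertension/diabetes/other chronic disease;
#' inflammatory nasal disease). Total IgE > 100 kU/l is reported as an
#' annotation flag (`total_ige_positive`), not an eligibility criterion.
#' Eligibility is monotone in the IgE concentrations: raising either value
#' never turns an eligible subject ineligible.
#'
#' @param serology Serology tibble with `der_f` and `der_p` columns (their
#'   absence is an error) and optional 0/1 flag columns.
#' @param conjunctive Require both allergens at class >= 2 (default); set
#'   `FALSE` for the disjunctive sensitivity-analysis variant.
#' @return Tibble: `subject_id`, `eligible`, `reasons` (list-column of
#'   failed criteria), `total_ige_positive`.
#' @export
dm_eligible <- function(serology, conjunctive = TRUE) {
  assert_columns(serology, c("subject_id", "der_f", "der_p"), "serology table")
  flag_cols <- c(asthma = "co-morbid asthma", eczema = "co-morbid eczema",
                 other_allergic = "other allergic disease",
                 chronic_disease = "hypertension/diabetes/chronic disease",
                 nasal_disease = "inflammatory nasal disease")
  cf <- cap_class(serology$der_f)
  cp <- cap_class(serology$der_p)
  rows <- map(seq_len(nrow(serology)), function(i) {
    reasons <- character()
    if (cf[i] < 2) reasons <- c(reasons, "Der f below class 2")
    if (cp[i] < 2) reasons <- c(reasons, "Der p below class 2")
    if (conjunctive) {
      sens_fail <- cf[i] < 2 || cp[i] < 2
    } else {
      sens_fail <- cf[i] < 2 && cp[i] < 2
      if (!sens_fail) reasons <- setdiff(reasons, c("Der f below class 2",
                                                    "Der p below class 2"))
    }
    for (col in names(flag_cols)) {
      if (col %in% names(serology) &&
          isTRUE(serology[[col]][i] %in% c(1, TRUE))) {
        reasons <- c(reasons, unname(flag_cols[col]))
      }
    }
    tibble(subject_id = serology$subject_id[i],
           eligible = length(reasons) == 0,
           reasons = list(reasons))
  })
  out <- bind_rows(rows)
  out$total_ige_positive <- if ("total_ige" %in% names(serology)) {
    serology$total_ige > 100
  } else {
    NA
  }
  out
}
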