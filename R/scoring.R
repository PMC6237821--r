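#' The internal CMT2A severity rule table
#'
#' Point values for the rule-based severity scale: the age-at-onset base
#' term (early < 6 years: 1.5; classical 6--20 years: 1; late > 20
#' years: 0.5), the major features (pyramidal signs 2, mild pyramidal
#' signs 1.5, sudden visual loss 1.5, optic atrophy 1, mental
#' retardation / developmental delay 1, wheelchair dependency 1,
#' subcortical MRI lesions 0.5) and the minor "other symptoms" that each
#' add 0.5 (hearing impairment/deafness, sensorineural hearing loss,
#' cerebellar ataxia, vasomotor troubles, tremor, cataracts, learning
#' difficulties, mitochondrial myopathy, microcephaly, periventricular
#' leukomalacia, proximal weakness, markedly reduced motor nerve
#' conduction velocity, plus a generic `other_minor` token for a minor
#' symptom reported without identity).
#'
#' @param file optional path to an override rule table (same columns:
#'   `feature_id`, `points`, `category`).
#' @return data frame with columns `feature_id`, `points`, `category`
#'   (one of `onset`, `major`, `minor`).
#' @export
severity_rules <- function(file = NULL) {
  if (is.null(file)) {
    file <- system.file("extdata", "score_rules.csv", package = "mfn2sev",
                        mustWork = TRUE)
  }
  rules <- read_delimited(file)
  stopifnot(all(c("feature_id", "points", "category") %in% names(rules)))
  if (anyDuplicated(rules$feature_id)) stop("duplicate feature_id in rule table")
  if (!all(rules$category %in% c("onset", "major", "minor"))) {
    stop("rule categories must be onset/major/minor")
  }
  rules$points <- as.numeric(rules$points)
  rules
}

#' Onset categories implied by an age or age range
#'
#' Maps an age at onset (years) to the onset categories of the severity
#' scale: `early` for onset before age 6, `classical` for 6--20,
#' `late` for onset after 20. An age range spanning a boundary yields
#' the union of the categories it covers.
#'
#' @param age a single non-negative age, or a length-2 range `c(min, max)`.
#' @return character vector of categories, subset of
#'   `c("early", "classical", "late")`.
#' @examples
#' onset_category(1.5)      # early
#' onset_category(c(1, 10)) # early + classical
#' onset_category(25)       # late
#' @export
onset_category <- function(age) {
  if (is.null(age) || all(is.na(age))) {
    stop("missing onset age: supply explicit onset categories instead")
  }
  age <- as.numeric(age)
  if (any(age < 0)) stop("onset age must be non-negative")
  if (length(age) == 1L) age <- c(age, age)
  if (length(age) != 2L || age[1] > age[2]) stop("age must be a value or c(min, max)")
  out <- character(0)
  if (age[1] < 6) out <- c(out, "early")
  if (age[2] >= 6 && age[1] <= 20) out <- c(out, "classical")
  if (age[2] > 20) out <- c(out, "late")
  out
}

#' Construct a structured clinical record
#'
#' @param mutation_label canonical protein-change label the record
#'   belongs to (e.g. `"p.Arg274Trp"`).
#' @param onset_age optional age at onset (years) or range `c(min, max)`;
#'   used to derive onset categories when `onset_categories` is `NULL`.
#' @param onset_categories explicit onset category alternatives (subset of
#'   `early`, `classical`, `late`); alternatives model reports such as
#'   "early or classical".
#' @param major character vector of major-feature keys (see
#'   [severity_rules()]).
#' @param minor character vector of minor-feature keys; each distinct key
#'   counts once.
#' @param asymptomatic logical; a confirmed healthy carrier scores 0
#'   (the onset base term is suppressed).
#' @param cmap_mV optional numeric CMAP amplitudes, stored verbatim.
#' @param cmtns,fds optional standard-scale integers, stored verbatim.
#' @return list of class `clinical_record`.
#' @export
clinical_record <- function(mutation_label, onset_age = NULL,
                            onset_categories = NULL,
                            major = character(0), minor = character(0),
                            asymptomatic = FALSE,
                            cmap_mV = NULL, cmtns = NA_integer_,
                            fds = NA_integer_) {
  if (is.null(onset_categories) && !asymptomatic) {
    onset_categories <- onset_category(onset_age)
  }
  if (!asymptomatic) {
    if (length(onset_categories) == 0L) stop("onset_categories must be non-empty")
    bad <- setdiff(onset_categories, c("early", "classical", "late"))
    if (length(bad)) stop("unknown onset category: ", paste(bad, collapse = ", "))
  }
  structure(
    list(mutation_label = mutation_label,
         onset_age = onset_age,
         onset_categories = unique(onset_categories),
         major = unique(as.character(major)),
         minor = unique(as.character(minor)),
         asymptomatic = isTRUE(asymptomatic),
         cmap_mV = cmap_mV, cmtns = cmtns, fds = fds),
    class = "clinical_record")
}

#' Severity score interval
#'
#' A closed interval of points on the severity scale; degenerate
#' (`min == max`) unless the record lists onset-category alternatives.
#'
#' @param min_points,max_points non-negative multiples of 0.5.
#' @return numeric vector `c(min, max)` of class `severity_score`.
#' @export
severity_score <- function(min_points, max_points = min_points) {
  stopifnot(min_points >= 0, max_points >= min_points)
  if (any(abs(c(min_points, max_points) * 2 - round(c(min_points, max_points) * 2)) > 1e-9)) {
    stop("scores must be multiples of 0.5")
  }
  structure(c(min = min_points, max = max_points), class = "severity_score")
}

#' @export
format.severity_score <- function(x, ...) {
  if (x[1] == x[2]) format_num(x[1]) else paste0(format_num(x[1]), "-", format_num(x[2]))
}

#' @export
print.severity_score <- function(x, ...) {
  cat("<severity_score>", format(x), "\n"); invisible(x)
}

format_num <- function(x) sub("\\.0+$", "", sprintf("%.1f", x))

score_midpoint <- function(s) (s[[1]] + s[[2]]) / 2

#' Score one clinical record on the severity scale
#'
#' The score is the onset base term plus the sum of major-feature points
#' plus 0.5 per distinct minor feature. When a record carries several
#' onset-category alternatives the result is the interval spanned by the
#' alternatives; asymptomatic carriers score 0.
#'
#' @param record a [clinical_record()].
#' @param rules rule table, see [severity_rules()].
#' @return a [severity_score()].
#' @examples
#' r <- clinical_record("p.His277Tyr", onset_categories = "classical",
#'                      major = "pyramidal_signs", minor = "vasomotor_troubles")
#' score_record(r)  # 3.5
#' @export
score_record <- function(record, rules = severity_rules()) {
  stopifnot(inherits(record, "clinical_record"))
  if (record$asymptomatic) return(severity_score(0))
  onset_pts <- rules$points[rules$category == "onset"]
  names(onset_pts) <- sub("^onset_", "", rules$feature_id[rules$category == "onset"])
  majors <- rules[rules$category == "major", ]
  minors <- rules[rules$category == "minor", ]
  unknown <- c(setdiff(record$major, majors$feature_id),
               setdiff(record$minor, minors$feature_id))
  if (length(unknown)) {
    stop("unknown feature key(s): ", paste(unknown, collapse = ", "),
         "\nvalid keys: ", paste(rules$feature_id, collapse = ", "))
  }
  feat <- sum(majors$points[match(record$major, majors$feature_id)]) +
    sum(minors$points[match(record$minor, minors$feature_id)])
  totals <- onset_pts[record$onset_categories] + feat
  severity_score(min(totals), max(totals))
}

#' Score a set of clinical records, aggregated per mutation
#'
#' Applies [score_record()] to each record; when several records describe
#' the same mutation the reported interval is the hull of the per-record
#' intervals, with the contributing records noted in the `provenance`
#' column.
#'
#' @param records list of [clinical_record()]s.
#' @param rules rule table.
#' @return data frame with columns `mutation`, `score_min`, `score_max`,
#'   `n_records`, `provenance`.
#' @export
score_table <- function(records, rules = severity_rules()) {
  if (length(records) == 0L) {
    return(data.frame(mutation = character(0), score_min = numeric(0),
                      score_max = numeric(0), n_records = integer(0),
                      provenance = character(0), stringsAsFactors = FALSE))
  }
  scored <- lapply(records, score_record, rules = rules)
  labels <- vapply(records, `[[`, character(1), "mutation_label")
  rows <- lapply(split(seq_along(records), factor(labels, levels = unique(labels))),
                 function(idx) {
    mins <- vapply(scored[idx], `[[`, numeric(1), 1L)
    maxs <- vapply(scored[idx], `[[`, numeric(1), 2L)
    data.frame(mutation = labels[idx[1]],
               score_min = min(mins), score_max = max(maxs),
               n_records = length(idx),
               provenance = if (length(idx) > 1L) "interval hull over records" else "single record",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read structured clinical records from delimited text
#'
#' Expects columns `mutation`, `onset_age` (free text, may be empty),
#' `onset_categories` (`;`-joined), `asymptomatic` (0/1),
#' `major_features` and `minor_features` (`;`-joined controlled
#' vocabulary keys).
#'
#' @param file path to the delimited file.
#' @return list of [clinical_record()]s.
#' @export
read_clinical_records <- function(file) {
  df <- read_delimited(file)
  need <- c("mutation", "onset_categories", "asymptomatic",
            "major_features", "minor_features")
  if (!all(need %in% names(df))) {
    stop("clinical record file must have columns: ", paste(need, collapse = ", "))
  }
  split_set <- function(x) {
    if (is.na(x) || !nzchar(x)) character(0) else strsplit(x, ";", fixed = TRUE)[[1]]
  }
  lapply(seq_len(nrow(df)), function(i) {
    clinical_record(
      mutation_label = df$mutation[i],
      onset_age = if ("onset_age" %in% names(df)) df$onset_age[i] else NULL,
      onset_categories = split_set(as.character(df$onset_categories[i])),
      major = split_set(as.character(df$major_features[i])),
      minor = split_set(as.character(df$minor_features[i])),
      asymptomatic = as.integer(df$asymptomatic[i]) == 1L)
  })
}
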