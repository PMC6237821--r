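#' Bundled mutation catalogue (26 GTPase-domain missense variants)
#'
#' @return catalogue data frame, see [read_catalog()].
#' @export
mfn2_table1_catalog <- function() {
  read_catalog(system.file("extdata", "table1_catalog.csv",
                           package = "mfn2sev", mustWork = TRUE))
}

#' Bundled structured clinical records for the catalogue
#'
#' One record per mutation: explicit onset-category alternatives (as the
#' clinical literature assigned them, which takes precedence over the
#' raw printed age range), major and minor feature keys, and the
#' published reference score interval in columns `score_min`/`score_max`
#' of the `"published_scores"` attribute.
#'
#' @return list of [clinical_record()]s with a `published_scores`
#'   attribute (data frame `mutation`, `score_min`, `score_max`).
#' @export
mfn2_table1_clinical <- function() {
  file <- system.file("extdata", "table1_clinical.csv", package = "mfn2sev",
                      mustWork = TRUE)
  records <- read_clinical_records(file)
  df <- read_delimited(file)
  attr(records, "published_scores") <-
    data.frame(mutation = df$mutation, score_min = as.numeric(df$score_min),
               score_max = as.numeric(df$score_max), stringsAsFactors = FALSE)
  records
}

#' Bundled per-position ordering annotations
#'
#' The published clinical and structural severity chains for the 11
#' analyzed positions. The structural chains summarise the
#' molecular-modelling severity assessment and are consumed here as
#' annotations; they are not recomputed.
#'
#' @return data frame with columns `position`, `wt`, `clinical`,
#'   `structural` (chain strings, see [parse_chain()]).
#' @export
mfn2_table2 <- function() {
  df <- read_delimited(system.file("extdata", "table2_orderings.tsv",
                                   package = "mfn2sev", mustWork = TRUE))
  df$position <- as.integer(df$position)
  df
}

# derive one clinical chain per group from a per-mutation score table
derive_group_chains <- function(groups, scores) {
  subs <- ungroup_positions(groups)
  missing <- setdiff(subs$label, scores$mutation)
  if (length(missing)) {
    stop("no score for: ", paste(missing, collapse = ", "))
  }
  chains <- lapply(seq_len(nrow(groups)), function(i) {
    g <- subs[subs$position == groups$position[i], ]
    idx <- match(g$label, scores$mutation)
    derive_clinical_chain(data.frame(alt = g$alt,
                                     score_min = scores$score_min[idx],
                                     score_max = scores$score_max[idx],
                                     stringsAsFactors = FALSE))
  })
  names(chains) <- as.character(groups$position)
  chains
}

run_pipeline <- function(catalog, records, structural = NULL,
                         range = domain_range(), exclusions = character(0),
                         rules = severity_rules()) {
  in_domain <- filter_domain(catalog, range)
  kept <- apply_exclusions(in_domain, exclusions)
  groups <- group_by_position(kept)
  scores <- score_table(records, rules)
  subs <- ungroup_positions(groups)
  scores_grouped <- scores[scores$mutation %in% subs$label, , drop = FALSE]
  chains <- if (nrow(groups)) derive_group_chains(groups, scores) else list()
  comparisons <- NULL
  summary <- NULL
  notice <- character(0)
  if (!is.null(structural) && nrow(groups)) {
    idx <- match(groups$position, structural$position)
    if (anyNA(idx)) {
      stop("no structural chain for position(s): ",
           paste(groups$position[is.na(idx)], collapse = ", "))
    }
    comparisons <- lapply(seq_len(nrow(groups)), function(i)
      compare_chains(chains[[i]], parse_chain(structural$structural[idx[i]]),
                     position = groups$position[i]))
    summary <- concordance_summary(comparisons)
  } else if (nrow(groups) == 0L) {
    notice <- "no position groups: concordance skipped"
  } else {
    notice <- "no structural chains supplied: concordance skipped"
  }
  structure(
    list(counts = c(n_input = nrow(catalog), n_in_domain = nrow(in_domain),
                    n_after_exclusions = nrow(kept),
                    n_grouped = sum(groups$n_alts), n_groups = nrow(groups)),
         groups = groups, scores = scores, clinical_chains = chains,
         comparisons = comparisons, summary = summary, notice = notice,
         version = as.character(utils::packageVersion("mfn2sev"))),
    class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> mfn2sev", x$version, "\n")
  cat(sprintf("  records: %d in -> %d in domain -> %d after exclusions -> %d in %d groups\n",
              x$counts["n_input"], x$counts["n_in_domain"],
              x$counts["n_after_exclusions"], x$counts["n_grouped"],
              x$counts["n_groups"]))
  if (!is.null(x$summary)) {
    cat(sprintf("  concordance: %d/%d groups (%d%%), %d partial, %d discordant\n",
                x$summary$n_concordant, x$summary$n_groups,
                x$summary$agreement_percent, x$summary$n_partial,
                x$summary$n_discordant))
  }
  for (n in x$notice) cat("  note:", n, "\n")
  invisible(x)
}

#' Comparison table of a run report
#'
#' @param report a `run_report`.
#' @return data frame with one row per group: `position`, `clinical`,
#'   `structural`, `status`, `n_mismatched`.
#' @export
comparison_table <- function(report) {
  stopifnot(inherits(report, "run_report"))
  if (is.null(report$comparisons)) {
    return(data.frame(position = integer(0), clinical = character(0),
                      structural = character(0), status = character(0),
                      n_mismatched = integer(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(report$comparisons, function(cmp) {
    data.frame(position = cmp$position, clinical = format(cmp$clinical),
               structural = format(cmp$structural), status = cmp$status,
               n_mismatched = nrow(cmp$mismatched_pairs),
               stringsAsFactors = FALSE)
  }))
}

#' Reproduce the bundled genotype-phenotype analysis end to end
#'
#' Runs the full pipeline on the bundled fixtures: parses the
#' 26-mutation catalogue, applies the GTPase-domain filter and the
#' exclusion list, groups by position (11 groups), scores the clinical
#' records on the internal scale, derives the clinical severity chain of
#' every group and compares it against the bundled
#' structural-impairment chains. The run is deterministic.
#'
#' @return a `run_report`; see [comparison_table()] for the per-group
#'   view.
#' @examples
#' rep <- run_paper_reproduction()
#' rep$summary$agreement_percent  # 73
#' @export
run_paper_reproduction <- function() {
  catalog <- mfn2_table1_catalog()
  records <- mfn2_table1_clinical()
  rec_labels <- vapply(records, `[[`, character(1), "mutation_label")
  if (!setequal(rec_labels, catalog$label)) {
    stop("bundled fixtures inconsistent: clinical records do not match the catalogue")
  }
  run_pipeline(catalog, records, structural = mfn2_table2(),
               range = domain_range(), exclusions = mfn2_exclusions())
}

#' Run the pipeline on user-supplied inputs
#'
#' @param config list with elements `catalog_file` (required),
#'   `clinical_file` (required), `structural_file` (optional chain
#'   annotations, columns `position`, `wt`, `clinical`, `structural`),
#'   `exclusions_file` (optional), `rules_file` (optional rule
#'   override), `domain` (length-2 range, default 95--339) and `out_dir`
#'   (optional; stage outputs are written there as delimited text).
#' @return a `run_report`.
#' @export
run_custom <- function(config) {
  need <- c("catalog_file", "clinical_file")
  miss <- setdiff(need, names(config))
  if (length(miss)) stop("config is missing: ", paste(miss, collapse = ", "))
  for (f in intersect(c("catalog_file", "clinical_file", "structural_file",
                        "exclusions_file", "rules_file"), names(config))) {
    if (!file.exists(config[[f]])) stop("config path does not exist: ", config[[f]])
  }
  catalog <- read_catalog(config$catalog_file, strict = FALSE)
  records <- read_clinical_records(config$clinical_file)
  structural <- if (!is.null(config$structural_file)) {
    df <- read_delimited(config$structural_file)
    df$position <- as.integer(df$position)
    df
  }
  exclusions <- if (!is.null(config$exclusions_file)) {
    x <- readLines(config$exclusions_file)
    trimws(x[nzchar(trimws(x)) & !startsWith(trimws(x), "#")])
  } else character(0)
  rules <- severity_rules(config$rules_file)
  range <- if (!is.null(config$domain)) {
    domain_range(config$domain[1], config$domain[2])
  } else domain_range()
  report <- run_pipeline(catalog, records, structural, range, exclusions, rules)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(report$groups,
                     file.path(config$out_dir, "groups.csv"), row.names = FALSE)
    utils::write.csv(report$scores,
                     file.path(config$out_dir, "scores.csv"), row.names = FALSE)
    utils::write.csv(comparison_table(report),
                     file.path(config$out_dir, "comparisons.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(counts = as.list(report$counts),
           summary = if (!is.null(report$summary)) unclass(report$summary),
           version = report$version, notice = report$notice),
      file.path(config$out_dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  }
  report
}
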