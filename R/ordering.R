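#' Construct a severity ordering chain
#'
#' A chain ranks the alternative substitutions at one residue position,
#' joining adjacent labels with relations from `>` (strictly more
#' severe), `>=` (at least as severe) and `=` (equally severe).
#'
#' @param labels character vector of distinct amino-acid labels (>= 1).
#' @param relations character vector from `c(">", ">=", "=")`, length
#'   `length(labels) - 1`.
#' @return list of class `ordering_chain`.
#' @export
ordering_chain <- function(labels, relations = character(0)) {
  labels <- as.character(labels)
  relations <- as.character(relations)
  relations[relations == "≥"] <- ">="
  if (length(labels) < 1L) stop("a chain needs at least one label")
  if (anyDuplicated(labels)) stop("repeated label in chain: ",
                                  paste(labels[duplicated(labels)], collapse = ", "))
  if (length(relations) != length(labels) - 1L) {
    stop("need exactly ", length(labels) - 1L, " relations for ",
         length(labels), " labels")
  }
  bad <- setdiff(relations, c(">", ">=", "="))
  if (length(bad)) stop("unknown relation symbol: ", paste(bad, collapse = ", "))
  structure(list(labels = labels, relations = relations),
            class = "ordering_chain")
}

#' Parse a severity chain from text
#'
#' Accepts the row format of the bundled ordering annotations, e.g.
#' `"Asp > Arg > Leu = Tyr"`; the unicode `≥` is accepted as `>=`.
#'
#' @param text a single chain string.
#' @return an [ordering_chain()].
#' @export
parse_chain <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- gsub("≥", ">=", text)
  tokens <- strsplit(trimws(text), "\\s+")[[1]]
  tokens <- tokens[nzchar(tokens)]
  if (length(tokens) == 0L) stop("empty chain")
  if (length(tokens) %% 2L == 0L) stop("dangling relation in chain: '", text, "'")
  labels <- tokens[seq(1L, length(tokens), by = 2L)]
  relations <- if (length(tokens) > 1L) tokens[seq(2L, length(tokens), by = 2L)] else character(0)
  if (any(labels %in% c(">", ">=", "="))) stop("misplaced relation token in '", text, "'")
  ordering_chain(labels, relations)
}

#' @export
format.ordering_chain <- function(x, ...) {
  if (length(x$labels) == 1L) return(x$labels)
  paste(c(rbind(x$labels[-length(x$labels)], x$relations), x$labels[length(x$labels)]),
        collapse = " ")
}

#' @export
print.ordering_chain <- function(x, ...) {
  cat("<ordering_chain>", format(x), "\n"); invisible(x)
}

#' @export
`==.ordering_chain` <- function(e1, e2) {
  identical(e1$labels, e2$labels) && identical(e1$relations, e2$relations)
}

#' Derive the clinical severity chain from a group's scores
#'
#' Alternatives are ranked by decreasing score-interval midpoint (ties in
#' midpoint broken alphabetically before assigning `=`). Adjacent
#' relations: equal midpoints give `=`; two degenerate (point) scores
#' exactly 0.5 apart give `>=`; any other positive gap gives `>`.
#'
#' @param group_scores data frame with columns `alt`, `score_min`,
#'   `score_max` (one row per alternative), or a named list of
#'   [severity_score()]s keyed by alternative.
#' @return an [ordering_chain()].
#' @examples
#' derive_clinical_chain(data.frame(alt = c("Leu", "Met"),
#'                                  score_min = c(2, 1.5),
#'                                  score_max = c(2, 1.5)))  # Leu >= Met
#' @export
derive_clinical_chain <- function(group_scores) {
  if (is.list(group_scores) && !is.data.frame(group_scores)) {
    group_scores <- data.frame(
      alt = names(group_scores),
      score_min = vapply(group_scores, `[[`, numeric(1), 1L),
      score_max = vapply(group_scores, `[[`, numeric(1), 2L),
      stringsAsFactors = FALSE)
  }
  stopifnot(nrow(group_scores) >= 1L)
  mid <- (group_scores$score_min + group_scores$score_max) / 2
  ord <- order(-mid, group_scores$alt)
  g <- group_scores[ord, , drop = FALSE]
  mid <- mid[ord]
  n <- nrow(g)
  relations <- character(max(0L, n - 1L))
  for (i in seq_len(n - 1L)) {
    dmid <- mid[i] - mid[i + 1L]
    point_i <- g$score_min[i] == g$score_max[i]
    point_j <- g$score_min[i + 1L] == g$score_max[i + 1L]
    relations[i] <- if (abs(dmid) < 1e-9) "="
      else if (point_i && point_j && abs(dmid - 0.5) < 1e-9) ">="
      else ">"
  }
  ordering_chain(g$alt, relations)
}

# relation from label a to label b implied by a chain; one of
# ">", ">=", "=", "<", "<=". Combining relations along the path:
# any ">" makes it strict; else any ">=" makes it ">="; else "=".
chain_relation <- function(chain, a, b) {
  ia <- match(a, chain$labels); ib <- match(b, chain$labels)
  if (is.na(ia) || is.na(ib)) stop("label not in chain: ", if (is.na(ia)) a else b)
  if (ia == ib) return("=")
  flip <- ia > ib
  lo <- min(ia, ib); hi <- max(ia, ib)
  rels <- chain$relations[lo:(hi - 1L)]
  rel <- if (any(rels == ">")) ">" else if (any(rels == ">=")) ">=" else "="
  if (!flip) rel else switch(rel, ">" = "<", ">=" = "<=", "=" = "=")
}

#' Compare a clinical chain against a structural-impairment chain
#'
#' For every adjacent pair of the clinical chain, the clinical relation
#' is checked against the relation the structural chain implies for the
#' same pair. A pair matches when the relations are equal, or when the
#' clinical relation is `>=` and the structural one is `>` or `=`
#' (the weak clinical claim subsumes both). A strictness disagreement
#' (`>` vs `=`, either direction) makes the pair — and, absent any
#' reversal, the group — `partial`; a rank reversal makes the group
#' `discordant`.
#'
#' @param clinical,structural [ordering_chain()]s over the same label set.
#' @param position optional residue position, carried into the result.
#' @return list of class `group_comparison` with elements `position`,
#'   `clinical`, `structural`, `status` (`concordant`, `partial` or
#'   `discordant`) and `mismatched_pairs` (data frame).
#' @export
compare_chains <- function(clinical, structural, position = NA_integer_) {
  stopifnot(inherits(clinical, "ordering_chain"),
            inherits(structural, "ordering_chain"))
  if (!setequal(clinical$labels, structural$labels)) {
    stop("label sets differ: {", paste(clinical$labels, collapse = ","),
         "} vs {", paste(structural$labels, collapse = ","), "}")
  }
  mism <- data.frame(a = character(0), b = character(0),
                     clinical = character(0), structural = character(0),
                     kind = character(0), stringsAsFactors = FALSE)
  for (i in seq_len(length(clinical$labels) - 1L)) {
    a <- clinical$labels[i]; b <- clinical$labels[i + 1L]
    rc <- clinical$relations[i]
    rs <- chain_relation(structural, a, b)
    ok <- rc == rs || (rc == ">=" && rs %in% c(">", "="))
    if (!ok) {
      kind <- if (rs %in% c("<", "<=")) "reversal" else "strictness"
      mism <- rbind(mism, data.frame(a = a, b = b, clinical = rc,
                                     structural = rs, kind = kind,
                                     stringsAsFactors = FALSE))
    }
  }
  status <- if (nrow(mism) == 0L) "concordant"
    else if (any(mism$kind == "reversal")) "discordant"
    else "partial"
  structure(list(position = position, clinical = clinical,
                 structural = structural, status = status,
                 mismatched_pairs = mism),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> pos %s: '%s' vs '%s' -> %s\n",
              ifelse(is.na(x$position), "?", x$position),
              format(x$clinical), format(x$structural), x$status))
  invisible(x)
}

#' Summarise concordance over a set of group comparisons
#'
#' Only fully concordant groups count toward the agreement percentage;
#' partial groups (strictness-only mismatch, "incomplete but not
#' discordant") are reported separately. The percentage is rounded
#' half-up to an integer.
#'
#' @param comparisons list of [compare_chains()] results.
#' @return list of class `concordance_summary` with `n_groups`,
#'   `n_concordant`, `n_partial`, `n_discordant`, `agreement_percent`.
#' @export
concordance_summary <- function(comparisons) {
  if (length(comparisons) == 0L) stop("no comparisons to summarise")
  status <- vapply(comparisons, `[[`, character(1), "status")
  n <- length(status)
  nc <- sum(status == "concordant")
  structure(list(n_groups = n, n_concordant = nc,
                 n_partial = sum(status == "partial"),
                 n_discordant = sum(status == "discordant"),
                 agreement_percent = round_half_up(100 * nc / n)),
            class = "concordance_summary")
}

round_half_up <- function(x) floor(x + 0.5)

#' @export
print.concordance_summary <- function(x, ...) {
  cat(sprintf("<concordance_summary> %d/%d concordant (%d%%), %d partial, %d discordant\n",
              x$n_concordant, x$n_groups, x$agreement_percent,
              x$n_partial, x$n_discordant))
  invisible(x)
}

#' Concordance of external predictor scores with clinical chains
#'
#' For each tool, the alternatives of every group are ranked by
#' decreasing predictor score (exact ties give `=`, otherwise `>`) and
#' the resulting chain is compared against the group's clinical chain;
#' the reported number is the percentage of fully concordant groups.
#' The procedure mirrors the in-house structural comparison and is
#' methodology-dependent: predictors rank variants genome-wide, not
#' within positions, so results should be read as compatibility rather
#' than accuracy.
#'
#' @param predictor_scores data frame with columns `mutation`, `tool`,
#'   `score` (higher = predicted more deleterious).
#' @param groups group table from [group_by_position()].
#' @param clinical_chains named list of [ordering_chain()]s keyed by
#'   position (as character).
#' @return data frame with columns `tool`, `n_groups`, `n_concordant`,
#'   `percent`.
#' @export
predictor_compatibility <- function(predictor_scores, groups, clinical_chains) {
  stopifnot(all(c("mutation", "tool", "score") %in% names(predictor_scores)))
  subs <- ungroup_positions(groups)
  tools <- unique(predictor_scores$tool)
  rows <- lapply(tools, function(tl) {
    sc <- predictor_scores[predictor_scores$tool == tl, ]
    missing <- setdiff(subs$label, sc$mutation)
    if (length(missing)) {
      stop("missing ", tl, " score for: ", paste(missing, collapse = ", "))
    }
    comps <- lapply(seq_len(nrow(groups)), function(i) {
      g <- subs[subs$position == groups$position[i], ]
      s <- sc$score[match(g$label, sc$mutation)]
      ord <- order(-s, g$alt)
      alts <- g$alt[ord]; s <- s[ord]
      rels <- ifelse(abs(diff(s)) < 1e-12, "=", ">")
      tool_chain <- ordering_chain(alts, rels)
      compare_chains(clinical_chains[[as.character(groups$position[i])]],
                     tool_chain, position = groups$position[i])
    })
    summ <- concordance_summary(comps)
    data.frame(tool = tl, n_groups = summ$n_groups,
               n_concordant = summ$n_concordant,
               percent = summ$agreement_percent, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
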