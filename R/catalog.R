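#' Parse an HGVS-like protein change into a mutation record
#'
#' Parses strings such as `"p.Arg274Trp"` or `"p.R274W"` into a missense
#' mutation record. Compound annotations joined by `"+"` (e.g. a nonsense
#' change reported in cis, or a co-occurring diagnosis) are kept as
#' annotations on the missense component: nonsense and frameshift
#' components are recorded but never scored. A string whose *first*
#' component is not a simple missense substitution (frameshift, stop,
#' silent) is rejected.
#'
#' @param text a single HGVS-like protein change string.
#' @param nt_change optional nucleotide-level change, free text.
#' @return a list of class `mutation_record` with elements `position`,
#'   `wt`, `alt` (canonical 3-letter codes), `label` (canonical
#'   `p.<Wt3><pos><Alt3>`), `nt_change` and `annotations`.
#' @examples
#' parse_protein_change("p.Arg274Trp")
#' parse_protein_change("p.H165Y")
#' @export
parse_protein_change <- function(text, nt_change = NA_character_) {
  stopifnot(is.character(text), length(text) == 1L)
  parts <- trimws(strsplit(text, "+", fixed = TRUE)[[1]])
  parts <- parts[nzchar(parts)]
  if (length(parts) == 0L) stop("empty protein change string")
  main <- parts[1]
  core <- sub("^p\\.", "", main)
  if (grepl("fs|\\*|Ter|X\\d*$", core)) {
    stop("not a missense substitution (frameshift/stop): '", main, "'")
  }
  m <- regmatches(core, regexec("^([A-Za-z]{1}|[A-Za-z]{3})([0-9]+)([A-Za-z]{1}|[A-Za-z]{3})$", core))[[1]]
  if (length(m) != 4L) {
    stop("malformed protein change: '", main, "' (expected p.<wt><pos><alt>)")
  }
  wt <- aa_canonical(m[2])
  alt <- aa_canonical(m[4])
  position <- as.integer(m[3])
  if (position < 1L) stop("residue position must be >= 1: ", position)
  if (wt == alt) stop("silent substitution (wt == alt) in '", main, "'")
  structure(
    list(position = position, wt = wt, alt = alt,
         label = paste0("p.", wt, position, alt),
         nt_change = nt_change,
         annotations = if (length(parts) > 1L) parts[-1] else character(0)),
    class = "mutation_record")
}

#' @export
format.mutation_record <- function(x, ...) x$label

#' @export
print.mutation_record <- function(x, ...) {
  extra <- if (length(x$annotations)) paste0(" [+ ", paste(x$annotations, collapse = ", "), "]") else ""
  cat(sprintf("<mutation_record> %s (%s%d%s)%s\n", x$label, x$wt, x$position, x$alt, extra))
  invisible(x)
}

#' Build a mutation catalogue from protein-change labels
#'
#' Parses a character vector of protein changes into a catalogue
#' data frame, one row per missense record. Exact duplicate records
#' (same canonical label) are de-duplicated with a warning, reflecting
#' multiple literature reports of one variant. Entries that fail to parse
#' are an error unless `strict = FALSE`, in which case they are dropped
#' and reported in the `"dropped"` attribute.
#'
#' @param protein_change character vector of HGVS-like protein changes.
#' @param nt_change optional character vector of nucleotide changes.
#' @param strict error on unparseable entries (default) or drop them.
#' @return data frame with columns `position`, `wt`, `alt`, `label`,
#'   `nt_change`, `annotations` (`;`-joined).
#' @export
mutation_catalog <- function(protein_change, nt_change = NULL, strict = TRUE) {
  n <- length(protein_change)
  if (is.null(nt_change)) nt_change <- rep(NA_character_, n)
  stopifnot(length(nt_change) == n)
  recs <- vector("list", n)
  dropped <- character(0)
  for (i in seq_len(n)) {
    rec <- tryCatch(parse_protein_change(protein_change[i], nt_change[i]),
                    error = function(e) e)
    if (inherits(rec, "error")) {
      if (strict) stop(conditionMessage(rec))
      dropped <- c(dropped, protein_change[i])
    } else {
      recs[[i]] <- rec
    }
  }
  recs <- recs[!vapply(recs, is.null, logical(1))]
  out <- data.frame(
    position = vapply(recs, `[[`, integer(1), "position"),
    wt = vapply(recs, `[[`, character(1), "wt"),
    alt = vapply(recs, `[[`, character(1), "alt"),
    label = vapply(recs, `[[`, character(1), "label"),
    nt_change = vapply(recs, `[[`, character(1), "nt_change"),
    annotations = vapply(recs, function(r) paste(r$annotations, collapse = ";"), character(1)),
    stringsAsFactors = FALSE)
  if (anyDuplicated(out$label)) {
    dup <- unique(out$label[duplicated(out$label)])
    warning("duplicate records de-duplicated: ", paste(dup, collapse = ", "))
    out <- out[!duplicated(out$label), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "dropped") <- dropped
  out
}

#' Read a mutation catalogue from delimited text
#'
#' Expects a header with at least a `protein_change` column; `nt_change`
#' and `refs` columns are optional. Comma- and tab-delimited files are
#' both accepted.
#'
#' @param file path to the delimited file.
#' @param strict passed to [mutation_catalog()].
#' @return catalogue data frame (see [mutation_catalog()]).
#' @export
read_catalog <- function(file, strict = TRUE) {
  df <- read_delimited(file)
  if (!"protein_change" %in% names(df)) {
    stop("catalogue file must have a 'protein_change' column: ", file)
  }
  nt <- if ("nt_change" %in% names(df)) as.character(df$nt_change) else NULL
  mutation_catalog(as.character(df$protein_change), nt, strict = strict)
}

# sniff comma vs tab on the header line
read_delimited <- function(file) {
  header <- readLines(file, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  utils::read.table(file, header = TRUE, sep = sep, quote = "\"",
                    stringsAsFactors = FALSE, comment.char = "",
                    check.names = TRUE)
}

#' Inclusive GTPase-domain residue range
#'
#' The mitofusin 2 GTPase domain spans residues 95 to 339 (1-based,
#' inclusive on both ends) in the structural model underlying the
#' bundled annotations.
#'
#' @param start,end integer residue bounds.
#' @return length-2 integer vector `c(start, end)`.
#' @export
domain_range <- function(start = 95L, end = 339L) {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start > end) {
    stop("invalid domain range: start must be <= end")
  }
  c(start = start, end = end)
}

#' Keep catalogue records inside a residue range
#'
#' @param catalog catalogue data frame from [mutation_catalog()].
#' @param range inclusive residue range, see [domain_range()].
#' @return the filtered catalogue, input order preserved.
#' @export
filter_domain <- function(catalog, range = domain_range()) {
  keep <- catalog$position >= range[1] & catalog$position <= range[2]
  out <- catalog[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Default exclusion list for the bundled catalogue
#'
#' Variants excluded for lack of clinical data (p.Arg104Leu, p.Thr105Ala)
#' and the double mutation in cis (p.Thr105LeufsX2 + p.Phe223Tyr).
#'
#' @return character vector of labels to drop before grouping.
#' @export
mfn2_exclusions <- function() {
  path <- system.file("extdata", "exclusions.txt", package = "mfn2sev",
                      mustWork = TRUE)
  x <- readLines(path)
  trimws(x[nzchar(trimws(x)) & !startsWith(trimws(x), "#")])
}

#' Drop excluded records from a catalogue
#'
#' Membership is tested on the canonical missense label and, for compound
#' entries, on the original `"+"`-joined form. The removed records are
#' reported in the `"removal_log"` attribute (label and reason).
#'
#' @param catalog catalogue data frame.
#' @param exclusions character vector of labels (default bundled list).
#' @return filtered catalogue with a `removal_log` attribute.
#' @export
apply_exclusions <- function(catalog, exclusions = mfn2_exclusions()) {
  full <- ifelse(nzchar(catalog$annotations),
                 paste(catalog$label,
                       gsub(";", " + ", catalog$annotations, fixed = TRUE),
                       sep = " + "),
                 catalog$label)
  drop <- catalog$label %in% exclusions | full %in% exclusions
  out <- catalog[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removal_log") <- data.frame(
    label = catalog$label[drop],
    reason = rep("on exclusion list", sum(drop)),
    stringsAsFactors = FALSE)
  out
}

#' Group catalogue records by residue position
#'
#' One group per position carrying at least `min_alts` distinct
#' substitutions; positions with fewer are dropped and reported in the
#' `"dropped_singletons"` attribute. Groups are sorted by position.
#' Conflicting wild-type residues at one position are an error.
#'
#' @param catalog catalogue data frame (already domain- and
#'   exclusion-filtered).
#' @param min_alts minimum number of distinct substitutions per group.
#' @return data frame with columns `position`, `wt`, `n_alts`, `alts`
#'   (`;`-joined, catalogue order).
#' @export
group_by_position <- function(catalog, min_alts = 2L) {
  if (nrow(catalog) == 0L) {
    out <- data.frame(position = integer(0), wt = character(0),
                      n_alts = integer(0), alts = character(0),
                      stringsAsFactors = FALSE)
    attr(out, "dropped_singletons") <- out$position
    return(out)
  }
  split_idx <- split(seq_len(nrow(catalog)), catalog$position)
  rows <- lapply(split_idx, function(idx) {
    wt <- unique(catalog$wt[idx])
    if (length(wt) > 1L) {
      stop("conflicting wild-type residues at position ",
           catalog$position[idx[1]], ": ", paste(wt, collapse = ", "))
    }
    alts <- unique(catalog$alt[idx])
    data.frame(position = catalog$position[idx[1]], wt = wt,
               n_alts = length(alts),
               alts = paste(alts, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$position), , drop = FALSE]
  rownames(out) <- NULL
  dropped <- out$position[out$n_alts < min_alts]
  out <- out[out$n_alts >= min_alts, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped_singletons") <- dropped
  out
}

#' Expand a group table back into per-substitution rows
#'
#' @param groups group table from [group_by_position()].
#' @return data frame with one row per (position, alt), columns
#'   `position`, `wt`, `alt`, `label`.
#' @export
ungroup_positions <- function(groups) {
  if (nrow(groups) == 0L) {
    return(data.frame(position = integer(0), wt = character(0),
                      alt = character(0), label = character(0),
                      stringsAsFactors = FALSE))
  }
  rows <- lapply(seq_len(nrow(groups)), function(i) {
    alts <- strsplit(groups$alts[i], ";", fixed = TRUE)[[1]]
    data.frame(position = groups$position[i], wt = groups$wt[i], alt = alts,
               label = paste0("p.", groups$wt[i], groups$position[i], alts),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
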