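# Idealized residue templates for fixture construction. Local coordinates,
# anchor (first functional atom) at the origin, body extending towards +x;
# bond geometry is approximate except at the anchor, which is what the
# detectors measure. Coordinates are kept to 3 decimals so a PDB
# round-trip is exact.
RES_TEMPLATES <- list(
  Asp = list(anchor = "OD1", atoms = rbind(
    OD1 = c(0, 0, 0), CG = c(1.0, -0.75, 0), OD2 = c(1.0, -2.0, 0),
    CB = c(2.5, -0.75, 0), CA = c(4.0, -0.75, 0), N = c(4.5, 0.6, 0),
    C = c(5.0, -1.9, 0), O = c(6.2, -1.7, 0))),
  Glu = list(anchor = "OE1", atoms = rbind(
    OE1 = c(0, 0, 0), CD = c(1.0, -0.75, 0), OE2 = c(1.0, -2.0, 0),
    CG = c(2.5, -0.75, 0), CB = c(3.9, -0.2, 0), CA = c(5.3, -0.75, 0),
    N = c(5.8, 0.6, 0), C = c(6.3, -1.9, 0), O = c(7.5, -1.7, 0))),
  Arg = list(anchor = "NH1", atoms = rbind(
    NH1 = c(0, 0, 0), CZ = c(1.0, 0.75, 0), NH2 = c(1.0, 2.0, 0),
    NE = c(2.2, 0.25, 0), CD = c(3.6, 0.75, 0), CG = c(5.0, 0.25, 0),
    CB = c(6.4, 0.75, 0), CA = c(7.8, 0.25, 0), N = c(8.3, 1.6, 0),
    C = c(8.8, -0.9, 0), O = c(10.0, -0.7, 0))),
  Lys = list(anchor = "NZ", atoms = rbind(
    NZ = c(0, 0, 0), CE = c(1.5, 0.3, 0), CD = c(2.9, -0.2, 0),
    CG = c(4.3, 0.3, 0), CB = c(5.7, -0.2, 0), CA = c(7.1, 0.3, 0),
    N = c(7.6, 1.6, 0), C = c(8.1, -0.9, 0), O = c(9.3, -0.7, 0))),
  His = list(anchor = "ND1", atoms = rbind(
    ND1 = c(0, 0, 0), CE1 = c(0.802, 1.103, 0), NE2 = c(2.098, 0.682, 0),
    CD2 = c(2.098, -0.682, 0), CG = c(0.802, -1.103, 0),
    CB = c(2.3, -2.0, 0), CA = c(3.7, -1.6, 0), N = c(4.2, -0.3, 0),
    C = c(4.7, -2.8, 0), O = c(5.9, -2.6, 0))),
  Trp = list(anchor = "centroid", atoms = rbind(  # 6-ring centred at origin
    CE3 = c(-1.4, 0, 0), CD2 = c(-0.7, 1.212, 0), CE2 = c(0.7, 1.212, 0),
    CZ2 = c(1.4, 0, 0), CH2 = c(0.7, -1.212, 0), CZ3 = c(-0.7, -1.212, 0),
    NE1 = c(1.6, 2.4, 0), CD1 = c(0.4, 3.2, 0), CG = c(-0.9, 2.5, 0),
    CB = c(-1.7, 3.7, 0), CA = c(-3.1, 3.3, 0), N = c(-3.6, 2.0, 0),
    C = c(-4.1, 4.5, 0), O = c(-5.3, 4.3, 0))),
  Phe = list(anchor = "centroid", atoms = rbind(
    CG = c(-1.4, 0, 0), CD1 = c(-0.7, 1.212, 0), CE1 = c(0.7, 1.212, 0),
    CZ = c(1.4, 0, 0), CE2 = c(0.7, -1.212, 0), CD2 = c(-0.7, -1.212, 0),
    CB = c(-2.8, 0.5, 0), CA = c(-4.2, 0, 0), N = c(-4.7, 1.3, 0),
    C = c(-5.2, -1.2, 0), O = c(-6.4, -1.0, 0))),
  Tyr = list(anchor = "OH", atoms = rbind(
    OH = c(0, 0, 0), CZ = c(1.36, 0, 0), CE1 = c(2.06, 1.212, 0),
    CD1 = c(3.46, 1.212, 0), CG = c(4.16, 0, 0), CD2 = c(3.46, -1.212, 0),
    CE2 = c(2.06, -1.212, 0), CB = c(5.56, 0.5, 0), CA = c(6.96, 0, 0),
    N = c(7.46, 1.3, 0), C = c(7.96, -1.2, 0), O = c(9.16, -1.0, 0))),
  Val = list(anchor = "CG1", atoms = rbind(
    CG1 = c(0, 0, 0), CB = c(1.3, 0.8, 0), CG2 = c(1.8, 2.0, 0),
    CA = c(2.8, 0.3, 0), N = c(3.3, 1.6, 0), C = c(3.8, -0.9, 0),
    O = c(5.0, -0.7, 0))),
  Leu = list(anchor = "CD1", atoms = rbind(
    CD1 = c(0, 0, 0), CG = c(1.3, 0.8, 0), CD2 = c(1.8, 2.0, 0),
    CB = c(2.8, 0.3, 0), CA = c(4.2, 0.8, 0), N = c(4.7, 2.1, 0),
    C = c(5.2, -0.4, 0), O = c(6.4, -0.2, 0))),
  Met = list(anchor = "CE", atoms = rbind(
    CE = c(0, 0, 0), SD = c(1.8, 0, 0), CG = c(3.2, 0.5, 0),
    CB = c(4.6, 0, 0), CA = c(6.0, 0.5, 0), N = c(6.5, 1.8, 0),
    C = c(7.0, -0.7, 0), O = c(8.2, -0.5, 0))),
  Ala = list(anchor = "CB", atoms = rbind(
    CB = c(0, 0, 0), CA = c(1.5, 0, 0), N = c(2.0, 1.3, 0),
    C = c(2.5, -1.2, 0), O = c(3.7, -1.0, 0))),
  Ser = list(anchor = "OG", atoms = rbind(
    OG = c(0, 0, 0), CB = c(1.4, 0.3, 0), CA = c(2.8, -0.2, 0),
    N = c(3.3, 1.1, 0), C = c(3.8, -1.4, 0), O = c(5.0, -1.2, 0))),
  Gly = list(anchor = "CA", atoms = rbind(
    CA = c(0, 0, 0), N = c(0.5, 1.3, 0), C = c(1.5, -0.7, 0),
    O = c(2.7, -0.5, 0))),
  Gln = list(anchor = "NE2", atoms = rbind(
    NE2 = c(0, 0, 0), CD = c(1.0, -0.75, 0), OE1 = c(1.0, -2.0, 0),
    CG = c(2.5, -0.75, 0), CB = c(3.9, -0.2, 0), CA = c(5.3, -0.75, 0),
    N = c(5.8, 0.6, 0), C = c(6.3, -1.9, 0), O = c(7.5, -1.7, 0))),
  Asn = list(anchor = "ND2", atoms = rbind(
    ND2 = c(0, 0, 0), CG = c(1.0, -0.75, 0), OD1 = c(1.0, -2.0, 0),
    CB = c(2.5, -0.75, 0), CA = c(4.0, -0.75, 0), N = c(4.5, 0.6, 0),
    C = c(5.0, -1.9, 0), O = c(6.2, -1.7, 0))),
  Thr = list(anchor = "OG1", atoms = rbind(
    OG1 = c(0, 0, 0), CB = c(1.4, 0.3, 0), CG2 = c(1.9, 1.5, 0),
    CA = c(2.8, -0.2, 0), N = c(3.3, 1.1, 0), C = c(3.8, -1.4, 0),
    O = c(5.0, -1.2, 0))),
  Ile = list(anchor = "CD1", atoms = rbind(
    CD1 = c(0, 0, 0), CG1 = c(1.4, 0.5, 0), CB = c(2.8, 0, 0),
    CG2 = c(3.3, 1.2, 0), CA = c(4.2, 0.5, 0), N = c(4.7, 1.8, 0),
    C = c(5.2, -0.7, 0), O = c(6.4, -0.5, 0))),
  Pro = list(anchor = "CG", atoms = rbind(
    CG = c(0, 0, 0), CB = c(1.2, 0.8, 0), CD = c(1.2, -0.9, 0),
    CA = c(2.5, 0.4, 0), N = c(2.5, -0.9, 0), C = c(3.7, -0.4, 0),
    O = c(4.9, -0.6, 0))),
  Cys = list(anchor = "SG", atoms = rbind(
    SG = c(0, 0, 0), CB = c(1.8, 0, 0), CA = c(3.2, 0.5, 0),
    N = c(3.7, 1.8, 0), C = c(4.2, -0.7, 0), O = c(5.4, -0.5, 0))))

template_atoms <- function(code, chain, resno, origin, mirror = FALSE,
                           rot_x_deg = 0) {
  tmpl <- RES_TEMPLATES[[code]]
  if (is.null(tmpl)) stop("no fixture template for residue code: ", code)
  X <- tmpl$atoms
  if (mirror) X[, 1] <- -X[, 1]
  if (rot_x_deg != 0) {
    th <- rot_x_deg * pi / 180
    R <- rbind(c(1, 0, 0), c(0, cos(th), -sin(th)), c(0, sin(th), cos(th)))
    X <- X %*% t(R)
  }
  X <- sweep(X, 2, -origin)
  data.frame(chain = chain, resno = as.integer(resno), resid = code,
             elety = rownames(tmpl$atoms),
             x = round(X[, 1], 3), y = round(X[, 2], 3), z = round(X[, 3], 3),
             stringsAsFactors = FALSE)
}

#' Specify one placed interaction for a structure fixture
#'
#' @param kind one of `salt_bridge`, `stacking`, `hydrophobic`,
#'   `pair` (two residues with apposed functional atoms, no interaction
#'   guarantee) or `isolated` (single residue; `res_b` ignored).
#' @param res_a,res_b length-3 vectors `c(code, chain, resno)`.
#' @param distance target anchor-anchor (or centroid-centroid) distance
#'   in Angstrom.
#' @param angle interplanar angle in degrees (stacking only).
#' @return list of class `placement`.
#' @export
placement <- function(kind, res_a, res_b = NULL, distance = 3.5, angle = 0) {
  stopifnot(kind %in% c("salt_bridge", "stacking", "hydrophobic", "pair",
                        "isolated"))
  if (distance <= 0) stop("requested distance must be positive")
  parse_res <- function(r) {
    if (is.null(r)) return(NULL)
    list(code = aa_canonical(r[[1]]), chain = as.character(r[[2]]),
         resno = as.integer(r[[3]]))
  }
  structure(list(kind = kind, res_a = parse_res(res_a),
                 res_b = parse_res(res_b), distance = distance,
                 angle = angle), class = "placement")
}

build_placement <- function(p, origin) {
  a <- p$res_a; b <- p$res_b
  if (p$kind == "isolated") {
    return(template_atoms(a$code, a$chain, a$resno, origin))
  }
  if (is.null(b)) stop("placement kind '", p$kind, "' needs res_b")
  if (p$kind == "stacking") {
    at_a <- template_atoms(a$code, a$chain, a$resno, origin)
    at_b <- template_atoms(b$code, b$chain, b$resno,
                           origin + c(0, 0, p$distance),
                           rot_x_deg = p$angle)
    return(rbind(at_a, at_b))
  }
  if (p$kind == "salt_bridge") {
    acid_first <- a$code %in% names(ACID_ATOMS)
    if (!acid_first && !b$code %in% names(ACID_ATOMS)) {
      stop("salt_bridge placement needs one Asp/Glu residue")
    }
    if (!acid_first) { tmp <- a; a <- b; b <- tmp }
    if (!b$code %in% names(BASE_ATOMS)) {
      stop("salt_bridge placement needs one Arg/Lys/His residue")
    }
  }
  at_a <- template_atoms(a$code, a$chain, a$resno, origin, mirror = TRUE)
  at_b <- template_atoms(b$code, b$chain, b$resno,
                         origin + c(p$distance, 0, 0))
  rbind(at_a, at_b)
}

#' Generate an idealized structure fixture
#'
#' Places the requested interactions at exact geometries, each in its
#' own region of space (regions are 25 Angstrom apart, so placements
#' never interact with each other), and optionally writes the result as
#' a PDB file. Anchors are positioned so the placed distance is exactly
#' the minimum relevant inter-atom (or centroid) distance the detectors
#' measure. Any two residues closer than the 1.5 Angstrom clash limit
#' are an error.
#'
#' @param placements list of [placement()]s.
#' @param file optional output PDB path.
#' @return list with elements `structure` (a `protein_structure`) and
#'   `file` (path or `NULL`).
#' @export
gen_structure_fixture <- function(placements, file = NULL) {
  if (inherits(placements, "placement")) placements <- list(placements)
  parts <- lapply(seq_along(placements), function(i)
    build_placement(placements[[i]], origin = c(0, 25 * (i - 1), 0)))
  atoms <- do.call(rbind, parts)
  s <- as_structure(atoms)
  res <- structure_residues(s)
  if (nrow(res) > 1L) {
    key <- paste(s$chain, s$resno)
    for (i in seq_len(nrow(res) - 1L)) {
      for (j in seq((i + 1L), nrow(res))) {
        A <- coords(s[key == paste(res$chain[i], res$resno[i]), ])
        B <- coords(s[key == paste(res$chain[j], res$resno[j]), ])
        if (min(cross_dist(A, B)) < 1.5) {
          stop("placement violates the 1.5 Angstrom clash limit between ",
               res$resid[i], res$resno[i], " and ", res$resid[j], res$resno[j])
        }
      }
    }
  }
  if (!is.null(file)) write_structure(s, file)
  list(structure = s, file = file)
}

#' Generate a random mutation catalogue
#'
#' Deterministic for a given seed: draws distinct positions inside the
#' domain range, a wild-type residue per position, and 2--4 (by default)
#' distinct substitutions at group positions plus optional
#' single-substitution positions.
#'
#' @param n_positions number of multi-substitution positions.
#' @param n_singletons number of single-substitution positions.
#' @param alts_range inclusive range of substitutions per group position.
#' @param range domain residue range, see [domain_range()].
#' @param seed mandatory integer seed.
#' @return catalogue data frame (see [mutation_catalog()]).
#' @export
gen_catalog <- function(n_positions = 11, n_singletons = 0,
                        alts_range = c(2, 4), range = domain_range(),
                        seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (alts_range[2] > 19) stop("at most 19 distinct substitutions per position")
  withr::with_seed(seed, {
    total <- n_positions + n_singletons
    positions <- sort(sample(seq(range[1], range[2]), total))
    n_alts <- c(sample(seq(alts_range[1], alts_range[2]), n_positions,
                       replace = TRUE),
                rep(1L, n_singletons))
    n_alts <- n_alts[sample.int(total)]
    labels <- unlist(lapply(seq_len(total), function(i) {
      wt <- sample(AA3, 1)
      alts <- sample(setdiff(AA3, wt), n_alts[i])
      paste0("p.", wt, positions[i], alts)
    }))
    mutation_catalog(labels)
  })
}

# greedy composition of a target score: largest feasible onset base,
# then majors in decreasing point order, then 0.5-point minors
compose_record <- function(label, target, rules) {
  if (target < 0.5 || abs(target * 2 - round(target * 2)) > 1e-9) {
    stop("target score must be a multiple of 0.5 and >= 0.5: ", target)
  }
  onset <- rules[rules$category == "onset", ]
  onset <- onset[order(-onset$points), ]
  majors <- rules[rules$category == "major", ]
  majors <- majors[order(-majors$points, majors$feature_id), ]
  minors <- rules[rules$category == "minor", ]
  minor_budget <- 0.5 * nrow(minors)
  for (k in seq_len(nrow(onset))) {
    base <- onset$points[k]
    rest <- target - base
    if (rest < -1e-9) next
    take <- character(0)
    for (m in seq_len(nrow(majors))) {
      if (rest - majors$points[m] >= -1e-9) {
        take <- c(take, majors$feature_id[m])
        rest <- rest - majors$points[m]
      }
    }
    n_min <- round(rest / 0.5)
    if (abs(rest - 0.5 * n_min) < 1e-9 && n_min <= nrow(minors)) {
      cat_name <- sub("^onset_", "", onset$feature_id[k])
      return(clinical_record(label, onset_categories = cat_name,
                             major = take,
                             minor = minors$feature_id[seq_len(n_min)]))
    }
  }
  stop("target score ", target, " is unreachable under the vocabulary limits")
}

#' Generate a synthetic clinical cohort with known target scores
#'
#' For every substitution in `groups`, draws a target score and composes
#' a clinical record whose rule-based score equals it exactly (greedy
#' deterministic composition: the largest feasible onset base, then
#' majors, then 0.5-point minors). The emitted truth table supports
#' round-trip testing.
#'
#' @param groups group table from [group_by_position()].
#' @param score_range inclusive range (multiples of 0.5) to draw target
#'   scores from.
#' @param rules severity rule table.
#' @param seed mandatory integer seed.
#' @return list with `records` (list of [clinical_record()]s) and
#'   `truth` (data frame `mutation`, `target_score`).
#' @export
gen_cohort <- function(groups, score_range = c(0.5, 7), rules = severity_rules(),
                       seed) {
  if (missing(seed)) stop("seed is mandatory")
  subs <- ungroup_positions(groups)
  withr::with_seed(seed, {
    targets <- sample(seq(score_range[1], score_range[2], by = 0.5),
                      nrow(subs), replace = TRUE)
  })
  records <- lapply(seq_len(nrow(subs)), function(i)
    compose_record(subs$label[i], targets[i], rules))
  list(records = records,
       truth = data.frame(mutation = subs$label, target_score = targets,
                          stringsAsFactors = FALSE))
}

#' Generate chain pairs with known comparison statuses
#'
#' Builds a structural chain per group (random labels, relations drawn
#' from `>` and `=` with at least one `>`), then derives the clinical
#' chain by perturbation: identity for concordant truth, one strictness
#' flip for partial, one adjacent swap across a strict relation for
#' discordant.
#'
#' @param n_groups number of chain pairs.
#' @param p_concordant,p_partial status probabilities (discordant takes
#'   the remainder).
#' @param labels_range inclusive range of chain lengths (>= 2).
#' @param seed mandatory integer seed.
#' @return list with `clinical` and `structural` (lists of
#'   [ordering_chain()]s) and `truth` (character vector of statuses).
#' @export
gen_concordance_scenario <- function(n_groups, p_concordant = 0.6,
                                     p_partial = 0.25, labels_range = c(2, 4),
                                     seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (p_concordant + p_partial > 1 + 1e-9) stop("probabilities sum above 1")
  withr::with_seed(seed, {
    statuses <- sample(c("concordant", "partial", "discordant"), n_groups,
                       replace = TRUE,
                       prob = c(p_concordant, p_partial,
                                1 - p_concordant - p_partial))
    clinical <- vector("list", n_groups)
    structural <- vector("list", n_groups)
    for (g in seq_len(n_groups)) {
      k <- sample(seq(labels_range[1], labels_range[2]), 1)
      labs <- sample(AA3, k)
      rels <- sample(c(">", "="), k - 1L, replace = TRUE)
      rels[sample.int(k - 1L, 1)] <- ">"  # guarantee a strict relation
      structural[[g]] <- ordering_chain(labs, rels)
      cl <- structural[[g]]
      if (statuses[g] == "partial") {
        i <- sample.int(k - 1L, 1)
        cl$relations[i] <- if (cl$relations[i] == ">") "=" else ">"
      } else if (statuses[g] == "discordant") {
        strict <- which(cl$relations == ">")
        i <- strict[sample.int(length(strict), 1)]
        cl$labels[c(i, i + 1L)] <- cl$labels[c(i + 1L, i)]
      }
      clinical[[g]] <- cl
    }
    list(clinical = clinical, structural = structural, truth = statuses)
  })
}
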