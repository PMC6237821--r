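# atom-set definitions used by the detectors
ACID_ATOMS <- list(Asp = c("OD1", "OD2"), Glu = c("OE1", "OE2"))
# His is treated as protonatable and counts as cationic; an approximation
# appropriate for physiological-pH contact analysis.
BASE_ATOMS <- list(Arg = c("NE", "NH1", "NH2"), Lys = "NZ",
                   His = c("ND1", "NE2"))
RING_ATOMS <- list(Phe = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
                   Tyr = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
                   # Trp uses the 6-membered-ring centroid
                   Trp = c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
                   His = c("CG", "ND1", "CD2", "CE1", "NE2"))
APOLAR_RESIDUES <- c("Ala", "Val", "Leu", "Ile", "Met", "Pro", "Phe", "Trp")

#' Build a structure object from an atom table
#'
#' @param atoms data frame with columns `chain`, `resno`, `resid`
#'   (3-letter residue code), `elety` (atom name), `x`, `y`, `z`.
#' @return the validated atom table, class `protein_structure`.
#' @export
as_structure <- function(atoms) {
  need <- c("chain", "resno", "resid", "elety", "x", "y", "z")
  stopifnot(all(need %in% names(atoms)))
  atoms <- as.data.frame(atoms)[need]
  atoms$resno <- as.integer(atoms$resno)
  if (nrow(atoms) == 0L) stop("structure has no atoms")
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    stop("non-finite coordinates")
  }
  key <- paste(atoms$chain, atoms$resno, atoms$elety)
  if (anyDuplicated(key)) {
    stop("duplicate (chain, residue, atom) triples: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  }
  canon <- atoms$resid %in% toupper(AA3) | atoms$resid %in% AA3
  atoms$resid[canon] <- aa_canonical(substr(atoms$resid[canon], 1, 3))
  rownames(atoms) <- NULL
  class(atoms) <- c("protein_structure", "data.frame")
  atoms
}

#' Read protein coordinates from a PDB file
#'
#' Thin wrapper over `bio3d::read.pdb()`. Only ATOM records are kept;
#' for multi-model files the first model is used with a warning;
#' insertion codes are rejected; alternate locations are resolved by
#' highest occupancy, then altloc `A`.
#'
#' @param file path to a PDB file.
#' @return a `protein_structure` (see [as_structure()]).
#' @export
read_structure <- function(file) {
  if (!file.exists(file)) stop("no such file: ", file)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(file, multi = FALSE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop("unreadable PDB file: ", file, " (",
                             conditionMessage(e), ")"))
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L) stop("no ATOM records in ", file)
  if (any(grepl("MODEL", readLines(file), fixed = TRUE)) &&
      sum(grepl("^MODEL", readLines(file))) > 1L) {
    warning("multi-model file: using the first model only")
  }
  if (any(!is.na(at$insert) & nzchar(at$insert))) {
    stop("insertion codes are not supported: ", file)
  }
  at$alt[is.na(at$alt)] <- ""
  if (any(nzchar(at$alt))) {
    key <- paste(at$chain, at$resno, at$elety)
    keep <- unlist(lapply(split(seq_len(nrow(at)), key), function(idx) {
      if (length(idx) == 1L) return(idx)
      occ <- at$o[idx]; occ[is.na(occ)] <- 1
      best <- idx[occ == max(occ)]
      if (length(best) > 1L) {
        a <- best[at$alt[best] %in% c("A", "")]
        best <- if (length(a)) a[1] else best[1]
      }
      best[1]
    }), use.names = FALSE)
    at <- at[sort(keep), , drop = FALSE]
  }
  at$chain[is.na(at$chain)] <- "A"
  as_structure(data.frame(chain = at$chain, resno = at$resno,
                          resid = at$resid, elety = at$elety,
                          x = at$x, y = at$y, z = at$z,
                          stringsAsFactors = FALSE))
}

#' Write a structure to a PDB file
#'
#' @param structure a `protein_structure`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_structure <- function(structure, file) {
  stopifnot(inherits(structure, "protein_structure"))
  bio3d::write.pdb(file = file,
                   xyz = as.numeric(t(as.matrix(structure[, c("x", "y", "z")]))),
                   resno = structure$resno,
                   resid = toupper(structure$resid),
                   chain = structure$chain,
                   elety = structure$elety,
                   eleno = seq_len(nrow(structure)))
  invisible(file)
}

# unique residues of a structure, ordered by chain then index
structure_residues <- function(structure) {
  r <- unique(structure[, c("chain", "resno", "resid")])
  r <- r[order(r$chain, r$resno), , drop = FALSE]
  rownames(r) <- NULL
  r
}

empty_edges <- function() {
  data.frame(kind = character(0), chain_a = character(0), res_a = integer(0),
             code_a = character(0), atom_a = character(0),
             chain_b = character(0), res_b = integer(0),
             code_b = character(0), atom_b = character(0),
             distance = numeric(0), angle = numeric(0),
             same_chain = logical(0), stringsAsFactors = FALSE)
}

res_atoms <- function(structure, chain, resno, names = NULL) {
  sel <- structure$chain == chain & structure$resno == resno
  if (!is.null(names)) sel <- sel & structure$elety %in% names
  structure[sel, , drop = FALSE]
}

# squared-distance matrix between two n x 3 coordinate matrices
cross_dist <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  sqrt(pmax(d2, 0))
}

coords <- function(df) as.matrix(df[, c("x", "y", "z"), drop = FALSE])

# order edge endpoints canonically by (chain, residue index)
make_edge <- function(kind, ra, rb, atom_a, atom_b, distance, angle = NA_real_) {
  swap <- (rb$chain < ra$chain) || (rb$chain == ra$chain && rb$resno < ra$resno)
  if (swap) { tmp <- ra; ra <- rb; rb <- tmp; tmpa <- atom_a; atom_a <- atom_b; atom_b <- tmpa }
  data.frame(kind = kind, chain_a = ra$chain, res_a = ra$resno,
             code_a = ra$resid, atom_a = atom_a,
             chain_b = rb$chain, res_b = rb$resno, code_b = rb$resid,
             atom_b = atom_b, distance = distance, angle = angle,
             same_chain = ra$chain == rb$chain, stringsAsFactors = FALSE)
}

finish_edges <- function(rows) {
  if (length(rows) == 0L) return(empty_edges())
  out <- do.call(rbind, rows)
  out <- out[order(out$kind, out$chain_a, out$res_a, out$chain_b, out$res_b), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect salt bridges
#'
#' Reports one edge for every (Asp/Glu carboxylate oxygen) --
#' (Arg/Lys/His side-chain nitrogen) residue pair whose minimum
#' heavy-atom distance is at or below `cutoff`; the reported distance
#' and atoms are those of the closest pair. Charged residues missing
#' their side-chain atoms are skipped with a warning.
#'
#' @param structure a `protein_structure`.
#' @param cutoff distance cutoff in Angstrom.
#' @return edge data frame (kind `salt_bridge`).
#' @export
detect_salt_bridges <- function(structure, cutoff = 4.0) {
  res <- structure_residues(structure)
  acids <- res[res$resid %in% names(ACID_ATOMS), , drop = FALSE]
  bases <- res[res$resid %in% names(BASE_ATOMS), , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(acids))) {
    ra <- acids[i, ]
    A <- res_atoms(structure, ra$chain, ra$resno, ACID_ATOMS[[ra$resid]])
    if (nrow(A) == 0L) {
      warning("skipping ", ra$resid, ra$resno, " (", ra$chain,
              "): carboxylate atoms missing")
      next
    }
    for (j in seq_len(nrow(bases))) {
      rb <- bases[j, ]
      B <- res_atoms(structure, rb$chain, rb$resno, BASE_ATOMS[[rb$resid]])
      if (nrow(B) == 0L) {
        warning("skipping ", rb$resid, rb$resno, " (", rb$chain,
                "): side-chain nitrogens missing")
        next
      }
      D <- cross_dist(coords(A), coords(B))
      k <- which(D == min(D), arr.ind = TRUE)[1, ]
      if (D[k[1], k[2]] <= cutoff) {
        rows[[length(rows) + 1L]] <- make_edge(
          "salt_bridge", ra, rb, A$elety[k[1]], B$elety[k[2]], D[k[1], k[2]])
      }
    }
  }
  finish_edges(rows)
}

ring_geometry <- function(structure, chain, resno, resid) {
  atoms <- res_atoms(structure, chain, resno, RING_ATOMS[[resid]])
  if (nrow(atoms) < length(RING_ATOMS[[resid]])) return(NULL)
  X <- coords(atoms)
  centroid <- colMeans(X)
  sv <- svd(sweep(X, 2, centroid))
  list(centroid = centroid, normal = sv$v[, 3])
}

#' Detect parallel aromatic stacking
#'
#' Edges between aromatic residues (Phe/Tyr/Trp/His) whose ring
#' centroids are within `centroid_cutoff` and whose interplanar angle is
#' at most `angle_max` degrees (parallel geometry). Trp uses the
#' centroid of its six-membered ring; residues with incomplete ring
#' atoms are skipped with a warning.
#'
#' @param structure a `protein_structure`.
#' @param centroid_cutoff ring-centroid distance cutoff, Angstrom.
#' @param angle_max maximum interplanar angle, degrees.
#' @return edge data frame (kind `stacking`, `angle` column filled).
#' @export
detect_stacking <- function(structure, centroid_cutoff = 5.5, angle_max = 30) {
  res <- structure_residues(structure)
  arom <- res[res$resid %in% names(RING_ATOMS), , drop = FALSE]
  geoms <- vector("list", nrow(arom))
  for (i in seq_len(nrow(arom))) {
    g <- ring_geometry(structure, arom$chain[i], arom$resno[i], arom$resid[i])
    if (is.null(g)) {
      warning("skipping ", arom$resid[i], arom$resno[i], " (", arom$chain[i],
              "): incomplete ring")
    }
    geoms[[i]] <- g
  }
  keep <- !vapply(geoms, is.null, logical(1))
  arom <- arom[keep, , drop = FALSE]; geoms <- geoms[keep]
  rows <- list()
  n <- nrow(arom)
  for (i in seq_len(max(0L, n - 1L))) {
    for (j in seq((i + 1L), n)) {
      d <- sqrt(sum((geoms[[i]]$centroid - geoms[[j]]$centroid)^2))
      if (d > centroid_cutoff) next
      cosang <- abs(sum(geoms[[i]]$normal * geoms[[j]]$normal))
      ang <- acos(pmin(1, cosang)) * 180 / pi
      if (ang <= angle_max) {
        rows[[length(rows) + 1L]] <- make_edge(
          "stacking", arom[i, ], arom[j, ], "ring", "ring", d, angle = ang)
      }
    }
  }
  finish_edges(rows)
}

sidechain_carbons <- function(structure, chain, resno) {
  a <- res_atoms(structure, chain, resno)
  a[startsWith(a$elety, "C") & !a$elety %in% c("C", "CA"), , drop = FALSE]
}

#' Detect hydrophobic side-chain contacts
#'
#' One edge per pair of apolar residues (Ala, Val, Leu, Ile, Met, Pro,
#' Phe, Trp) with any side-chain carbon pair within `cutoff`, collapsed
#' to the minimum-distance atom pair.
#'
#' @param structure a `protein_structure`.
#' @param cutoff carbon-carbon distance cutoff, Angstrom.
#' @return edge data frame (kind `hydrophobic`).
#' @export
detect_hydrophobic <- function(structure, cutoff = 4.5) {
  res <- structure_residues(structure)
  apolar <- res[res$resid %in% APOLAR_RESIDUES, , drop = FALSE]
  carb <- lapply(seq_len(nrow(apolar)), function(i)
    sidechain_carbons(structure, apolar$chain[i], apolar$resno[i]))
  keep <- vapply(carb, nrow, integer(1)) > 0L
  apolar <- apolar[keep, , drop = FALSE]; carb <- carb[keep]
  rows <- list()
  n <- nrow(apolar)
  for (i in seq_len(max(0L, n - 1L))) {
    for (j in seq((i + 1L), n)) {
      D <- cross_dist(coords(carb[[i]]), coords(carb[[j]]))
      k <- which(D == min(D), arr.ind = TRUE)[1, ]
      if (D[k[1], k[2]] <= cutoff) {
        rows[[length(rows) + 1L]] <- make_edge(
          "hydrophobic", apolar[i, ], apolar[j, ],
          carb[[i]]$elety[k[1]], carb[[j]]$elety[k[2]], D[k[1], k[2]])
      }
    }
  }
  finish_edges(rows)
}

#' All interaction edges of a structure
#'
#' Runs the three detectors and binds their edge tables.
#'
#' @param structure a `protein_structure`.
#' @param salt_cutoff,stack_cutoff,stack_angle_max,hydrophobic_cutoff
#'   detector cutoffs (Angstrom / degrees).
#' @return combined edge data frame.
#' @export
detect_interactions <- function(structure, salt_cutoff = 4.0,
                                stack_cutoff = 5.5, stack_angle_max = 30,
                                hydrophobic_cutoff = 4.5) {
  out <- rbind(detect_salt_bridges(structure, salt_cutoff),
               detect_stacking(structure, stack_cutoff, stack_angle_max),
               detect_hydrophobic(structure, hydrophobic_cutoff))
  rownames(out) <- NULL
  out
}

#' Interaction profile of one residue
#'
#' Union of all detector edges touching the residue, ordered by kind and
#' partner index.
#'
#' @param structure a `protein_structure`.
#' @param chain chain identifier.
#' @param position residue index.
#' @param ... cutoffs passed to [detect_interactions()].
#' @return edge data frame restricted to the residue.
#' @export
residue_profile <- function(structure, chain, position, ...) {
  res <- structure_residues(structure)
  if (!any(res$chain == chain & res$resno == position)) {
    stop("no residue ", position, " in chain ", chain)
  }
  edges <- detect_interactions(structure, ...)
  touch <- (edges$chain_a == chain & edges$res_a == position) |
    (edges$chain_b == chain & edges$res_b == position)
  prof <- edges[touch, , drop = FALSE]
  partner <- ifelse(prof$chain_a == chain & prof$res_a == position,
                    prof$res_b, prof$res_a)
  prof <- prof[order(prof$kind, partner), , drop = FALSE]
  rownames(prof) <- NULL
  prof
}

#' The long-range electrostatic pairs maintaining MFN2 closure
#'
#' The curated set of six interdomain contacts holding the closed,
#' diamond-shaped conformation: Asp210(GTPase)--Arg476(HR2),
#' Lys243(GTPase)--Asp480(HR2), Arg250(GTPase)--Glu598(HR2),
#' Glu542(HR2)--Lys732(HR1), Asp377/Glu370(HR1)--Arg564(HR2) (either
#' acidic partner satisfies the contact) and Glu359(HR1)--Arg575(HR2).
#'
#' @param file optional path to an override pair table.
#' @return data frame with columns `pair_id`, `pos_a`, `code_a`,
#'   `domain_a`, `pos_b`, `code_b`, `domain_b`, `note` (`pos_a`/`code_a`
#'   may hold `;`-joined alternatives).
#' @export
closure_pairs <- function(file = NULL) {
  if (is.null(file)) {
    file <- system.file("extdata", "closure_pairs.csv", package = "mfn2sev",
                        mustWork = TRUE)
  }
  read_delimited(file)
}

#' Audit the closure network in a structure
#'
#' Marks each curated closure pair present when a salt-bridge edge links
#' the two positions (any chain); listed residues absent from the
#' structure are reported as missing rather than raising an error.
#'
#' @param structure a `protein_structure`.
#' @param pairs pair table, see [closure_pairs()].
#' @param cutoff salt-bridge cutoff in Angstrom.
#' @return data frame `pair_id`, `label`, `present`, `note`, with the
#'   fraction present in attribute `"fraction_present"`.
#' @export
check_closure_network <- function(structure, pairs = closure_pairs(),
                                  cutoff = 4.0) {
  edges <- detect_salt_bridges(structure, cutoff)
  res <- structure_residues(structure)
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    pa <- as.integer(strsplit(as.character(pairs$pos_a[i]), ";")[[1]])
    ca <- strsplit(as.character(pairs$code_a[i]), ";")[[1]]
    pb <- as.integer(pairs$pos_b[i])
    label <- paste0(paste0(ca, pa, collapse = "/"), "-", pairs$code_b[i], pb)
    have_a <- pa %in% res$resno
    have_b <- pb %in% res$resno
    if (!any(have_a) || !have_b) {
      return(data.frame(pair_id = pairs$pair_id[i], label = label,
                        present = FALSE, note = "missing residue",
                        stringsAsFactors = FALSE))
    }
    hit <- any((edges$res_a %in% pa & edges$res_b == pb) |
                 (edges$res_b %in% pa & edges$res_a == pb))
    data.frame(pair_id = pairs$pair_id[i], label = label, present = hit,
               note = if (hit) "salt bridge detected" else "no contact",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "fraction_present") <- mean(out$present)
  out
}

#' The curated mechanism map for the analyzed positions
#'
#' Assigns each of the 11 analyzed GTPase-domain positions to the fusion
#' step its mutations impair: rearrangement of the GTP binding site
#' (His277), dimerization (Arg104, His165, Arg259, Arg274, Gln276), GTP
#' hydrolysis (Gly127, which positions His128 and the catalytic water),
#' closure (Asp210, Arg250) and yet-unknown mechanisms (Val244, Pro251).
#'
#' @param file optional path to an override map (columns `position`,
#'   `category`).
#' @return data frame with columns `position`, `category`.
#' @export
mechanism_map <- function(file = NULL) {
  if (is.null(file)) {
    file <- system.file("extdata", "mechanism_map.csv", package = "mfn2sev",
                        mustWork = TRUE)
  }
  m <- read_delimited(file)
  m$position <- as.integer(m$position)
  m
}

#' Classify mutated positions into mechanism categories
#'
#' @param position integer vector of residue positions.
#' @param map mechanism map, see [mechanism_map()].
#' @return data frame with columns `position`, `category` (`unknown` for
#'   unmapped positions), `mapped` (FALSE flags positions absent from
#'   the map).
#' @export
classify_mechanism <- function(position, map = mechanism_map()) {
  idx <- match(as.integer(position), map$position)
  data.frame(position = as.integer(position),
             category = ifelse(is.na(idx), "unknown", map$category[idx]),
             mapped = !is.na(idx), stringsAsFactors = FALSE)
}

#' Interaction-profile difference between wild-type and mutant
#'
#' Static surrogate for a trajectory comparison: edges keyed by
#' (kind, partner chain, partner index) that appear only in the
#' wild-type profile are reported as lost, those only in the mutant as
#' gained. The structures must agree on residue identity everywhere
#' except the mutated position.
#'
#' @param wild,mutant `protein_structure`s sharing residue numbering.
#' @param chain chain identifier of the mutated residue.
#' @param position mutated residue index.
#' @param ... cutoffs passed to the detectors.
#' @return list with edge data frames `lost` and `gained`.
#' @export
diff_profiles <- function(wild, mutant, chain, position, ...) {
  rw <- structure_residues(wild); rm_ <- structure_residues(mutant)
  kw <- paste(rw$chain, rw$resno); km <- paste(rm_$chain, rm_$resno)
  common <- intersect(kw, km)
  cw <- rw$resid[match(common, kw)]; cm <- rm_$resid[match(common, km)]
  off <- common != paste(chain, position) & cw != cm
  if (any(off)) {
    stop("residue identity differs away from the mutated position: ",
         paste(common[off], collapse = ", "))
  }
  pw <- residue_profile(wild, chain, position, ...)
  pm <- residue_profile(mutant, chain, position, ...)
  key <- function(p, ch, pos) {
    partner_chain <- ifelse(p$chain_a == ch & p$res_a == pos, p$chain_b, p$chain_a)
    partner_res <- ifelse(p$chain_a == ch & p$res_a == pos, p$res_b, p$res_a)
    paste(p$kind, partner_chain, partner_res)
  }
  kw2 <- key(pw, chain, position); km2 <- key(pm, chain, position)
  list(lost = pw[!kw2 %in% km2, , drop = FALSE],
       gained = pm[!km2 %in% kw2, , drop = FALSE])
}
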