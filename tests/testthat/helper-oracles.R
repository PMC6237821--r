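# Brute-force oracles, kept independent of the package internals:
# they re-derive the same quantities by exhaustive scans with their own
# constant tables.

oracle_group <- function(catalog, min_alts = 2L) {
  positions <- sort(unique(catalog$position))
  out <- list()
  for (p in positions) {
    rows <- catalog[catalog$position == p, ]
    alts <- unique(rows$alt)
    if (length(alts) >= min_alts) {
      out[[length(out) + 1L]] <- data.frame(
        position = p, wt = rows$wt[1], n_alts = length(alts),
        alts = paste(alts, collapse = ";"), stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(position = integer(0), wt = character(0),
                      n_alts = integer(0), alts = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

# exhaustive atom-pair scans; own atom tables
.oracle_acid <- list(Asp = c("OD1", "OD2"), Glu = c("OE1", "OE2"))
.oracle_base <- list(Arg = c("NE", "NH1", "NH2"), Lys = "NZ",
                     His = c("ND1", "NE2"))
.oracle_ring <- list(Phe = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
                     Tyr = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
                     Trp = c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
                     His = c("CG", "ND1", "CD2", "CE1", "NE2"))
.oracle_apolar <- c("Ala", "Val", "Leu", "Ile", "Met", "Pro", "Phe", "Trp")

oracle_salt_bridges <- function(s, cutoff = 4.0) {
  res <- unique(s[, c("chain", "resno", "resid")])
  hits <- character(0)
  for (i in seq_len(nrow(res))) for (j in seq_len(nrow(res))) {
    ri <- res[i, ]; rj <- res[j, ]
    if (!ri$resid %in% names(.oracle_acid)) next
    if (!rj$resid %in% names(.oracle_base)) next
    A <- s[s$chain == ri$chain & s$resno == ri$resno &
             s$elety %in% .oracle_acid[[ri$resid]], ]
    B <- s[s$chain == rj$chain & s$resno == rj$resno &
             s$elety %in% .oracle_base[[rj$resid]], ]
    if (nrow(A) == 0 || nrow(B) == 0) next
    dmin <- Inf
    for (p in seq_len(nrow(A))) for (q in seq_len(nrow(B))) {
      d <- sqrt((A$x[p] - B$x[q])^2 + (A$y[p] - B$y[q])^2 + (A$z[p] - B$z[q])^2)
      dmin <- min(dmin, d)
    }
    if (dmin <= cutoff) {
      k <- sort(c(paste(ri$chain, ri$resno), paste(rj$chain, rj$resno)))
      hits <- c(hits, paste(k, collapse = "|"))
    }
  }
  sort(unique(hits))
}

oracle_stacking <- function(s, cutoff = 5.5, angle_max = 30) {
  res <- unique(s[, c("chain", "resno", "resid")])
  res <- res[res$resid %in% names(.oracle_ring), , drop = FALSE]
  geom <- vector("list", nrow(res))
  for (i in seq_len(nrow(res))) {
    a <- s[s$chain == res$chain[i] & s$resno == res$resno[i] &
             s$elety %in% .oracle_ring[[res$resid[i]]], ]
    if (nrow(a) < length(.oracle_ring[[res$resid[i]]])) next
    X <- as.matrix(a[, c("x", "y", "z")])
    cen <- colMeans(X)
    n <- svd(sweep(X, 2, cen))$v[, 3]
    geom[[i]] <- list(cen = cen, n = n)
  }
  hits <- character(0)
  for (i in seq_len(nrow(res))) for (j in seq_len(nrow(res))) {
    if (j <= i || is.null(geom[[i]]) || is.null(geom[[j]])) next
    d <- sqrt(sum((geom[[i]]$cen - geom[[j]]$cen)^2))
    ang <- acos(min(1, abs(sum(geom[[i]]$n * geom[[j]]$n)))) * 180 / pi
    if (d <= cutoff && ang <= angle_max) {
      k <- sort(c(paste(res$chain[i], res$resno[i]),
                  paste(res$chain[j], res$resno[j])))
      hits <- c(hits, paste(k, collapse = "|"))
    }
  }
  sort(unique(hits))
}

oracle_hydrophobic <- function(s, cutoff = 4.5) {
  res <- unique(s[, c("chain", "resno", "resid")])
  res <- res[res$resid %in% .oracle_apolar, , drop = FALSE]
  hits <- character(0)
  for (i in seq_len(nrow(res))) for (j in seq_len(nrow(res))) {
    if (j <= i) next
    a <- s[s$chain == res$chain[i] & s$resno == res$resno[i], ]
    a <- a[grepl("^C", a$elety) & !a$elety %in% c("C", "CA"), ]
    b <- s[s$chain == res$chain[j] & s$resno == res$resno[j], ]
    b <- b[grepl("^C", b$elety) & !b$elety %in% c("C", "CA"), ]
    if (nrow(a) == 0 || nrow(b) == 0) next
    dmin <- Inf
    for (p in seq_len(nrow(a))) for (q in seq_len(nrow(b))) {
      d <- sqrt((a$x[p] - b$x[q])^2 + (a$y[p] - b$y[q])^2 + (a$z[p] - b$z[q])^2)
      dmin <- min(dmin, d)
    }
    if (dmin <= cutoff) {
      k <- sort(c(paste(res$chain[i], res$resno[i]),
                  paste(res$chain[j], res$resno[j])))
      hits <- c(hits, paste(k, collapse = "|"))
    }
  }
  sort(unique(hits))
}

edge_keys <- function(edges) {
  if (nrow(edges) == 0) return(character(0))
  sort(mapply(function(ca, ra, cb, rb) {
    paste(sort(c(paste(ca, ra), paste(cb, rb))), collapse = "|")
  }, edges$chain_a, edges$res_a, edges$chain_b, edges$res_b,
  USE.NAMES = FALSE))
}

# random structure built from the package's residue templates at random
# placements; used for oracle-equivalence and invariance properties
random_structure <- function(seed, n_res = 15, box = 18) {
  codes <- names(mfn2sev:::RES_TEMPLATES)
  withr::with_seed(seed, {
    parts <- lapply(seq_len(n_res), function(i) {
      mfn2sev:::template_atoms(sample(codes, 1),
                               chain = sample(c("A", "B"), 1), resno = i,
                               origin = runif(3, 0, box),
                               rot_x_deg = runif(1, 0, 360))
    })
    as_structure(do.call(rbind, parts))
  })
}

rigid_motion <- function(s, seed) {
  withr::with_seed(seed, {
    M <- matrix(rnorm(9), 3)
    R <- qr.Q(qr(M))
    if (det(R) < 0) R[, 1] <- -R[, 1]
    t <- runif(3, -50, 50)
  })
  X <- as.matrix(s[, c("x", "y", "z")]) %*% t(R)
  s$x <- X[, 1] + t[1]; s$y <- X[, 2] + t[2]; s$z <- X[, 3] + t[3]
  s
}

random_chain <- function(seed, k_max = 5) {
  withr::with_seed(seed, {
    k <- sample(1:k_max, 1)
    labs <- sample(c("Ala", "Arg", "Asp", "Cys", "Gln", "His", "Leu", "Met",
                     "Trp", "Tyr", "Val"), k)
    rels <- if (k > 1) sample(c(">", ">=", "="), k - 1, replace = TRUE) else character(0)
    ordering_chain(labs, rels)
  })
}
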