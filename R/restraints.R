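#' Select the top x*L contacts by probability
#'
#' Takes the `round(x * L)` highest-probability predictions (all of them if
#' fewer are available). Ties in probability are broken by (i, j)
#' lexicographic order, so selection is stable across runs.
#'
#' @param preds contact data.frame (columns i, j, p, optionally d0).
#' @param x selection ratio (> 0; the protocol sweeps 0.1 to 4).
#' @param L protein length.
#' @return the selected rows, ordered by decreasing p then (i, j).
#' @export
selectTopContacts <- function(preds, x, L) {
  if (x <= 0) stop("x must be positive")
  if (L < 1) stop("L must be >= 1")
  n <- min(round(x * L), nrow(preds))
  ord <- order(-preds$p, preds$i, preds$j)
  out <- preds[ord, , drop = FALSE][seq_len(n), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Bounded distance-restraint potential
#'
#' The flat-bottomed contact energy used with the fragment-assembly engines:
#' zero on `[lb, ub]`, quadratic walls `((d - lb)/sd)^2` below `lb` and
#' `((d - ub)/sd)^2` just above `ub`, switching at `d = ub + 0.5 sd` to a
#' linear tail of slope `1/sd` matched for continuity
#' (`(d - (ub + 0.5 sd))/sd + 0.25`). Defaults `lb = 3.5`, `ub = 8`,
#' `sd = 0.5` Angstrom. Vectorised over `d`.
#'
#' @param d distance(s), Angstrom, >= 0.
#' @param lb,ub lower/upper bound (0 < lb < ub).
#' @param sd restraint width (> 0).
#' @return energy value(s) >= 0.
#' @export
boundedPotential <- function(d, lb = 3.5, ub = 8, sd = 0.5) {
  if (any(d < 0)) stop("d must be non-negative")
  if (lb <= 0 || lb >= ub) stop("need 0 < lb < ub")
  if (sd <= 0) stop("sd must be positive")
  knee <- ub + 0.5 * sd
  ifelse(d < lb, ((d - lb) / sd)^2,
    ifelse(d <= ub, 0,
      ifelse(d <= knee, ((d - ub) / sd)^2,
        (d - knee) / sd + (0.5 * sd / sd)^2)))
}

#' Square-well contact potential with exponential decay
#'
#' The contact distance energy used with the united-residue conformation
#' sampler: a constant reward `-P` for distances below `d0` and
#' `-P exp(-(d - d0)^2) + P (d - d0)/d` beyond it (continuous at `d0`).
#' For `P = 0` the potential is identically zero. Vectorised over `d`.
#'
#' @param d distance(s), Angstrom, >= 0.
#' @param P predicted contact probability in [0, 1].
#' @param d0 well edge, Angstrom (> 0; default 8).
#' @return energy value(s).
#' @export
squareWellPotential <- function(d, P, d0 = 8) {
  if (any(d < 0)) stop("d must be non-negative")
  if (P < 0 || P > 1) stop("P must be in [0,1]")
  if (d0 <= 0) stop("d0 must be positive")
  ifelse(d < d0, -P, -P * exp(-(d - d0)^2) + P * (d - d0) / pmax(d, 1e-12))
}

.rep_atom <- function(sequence, idx) {
  ifelse(substring(sequence, idx, idx) == "G", "CA", "CB")
}

#' Translate contact predictions into distance restraints
#'
#' One restraint per contact between CB atoms (CA for glycine), with bounds
#' `lb = 3.5`, `ub = 8` Angstrom, width `sd = 0.5`, weight equal to the
#' predicted probability and source tag "contact". Duplicate pairs keep the
#' maximum weight.
#'
#' @param contacts contact data.frame (i, j, p).
#' @param sequence the target amino-acid sequence.
#' @return distance-restraint data.frame (see [RestraintSet-class]).
#' @export
contactsToRestraints <- function(contacts, sequence) {
  L <- nchar(sequence)
  if (!nrow(contacts)) return(emptyDistanceRestraints())
  if (any(contacts$i < 1 | contacts$j > L))
    stop("contact index out of range 1..", L)
  df <- data.frame(
    i = contacts$i, j = contacts$j,
    atom_i = .rep_atom(sequence, contacts$i),
    atom_j = .rep_atom(sequence, contacts$j),
    lb = 3.5, ub = 8.0, sd = 0.5,
    weight = contacts$p, source = "contact",
    stringsAsFactors = FALSE)
  df <- df[order(df$i, df$j, -df$weight), ]
  df <- df[!duplicated(paste(df$i, df$j)), ]
  rownames(df) <- NULL
  df
}

#' Secondary-structure-derived restraints
#'
#' For every helix run of length >= 4: per-residue phi/psi torsion
#' restraints (-57/-47 +/- 20 degrees) and CA(i)-CA(i+4) distance
#' restraints of 5.4-6.4 Angstrom (source "ss_local"). For every strand run
#' of length >= 3: phi/psi restraints (-120/+120 +/- 30 degrees). Coil
#' positions are unrestrained.
#'
#' @param ss secondary-structure string over \{H,E,C\}.
#' @param sequence amino-acid sequence of the same length.
#' @return a [RestraintSet-class].
#' @export
ssToRestraints <- function(ss, sequence) {
  if (nchar(ss) != nchar(sequence))
    stop("ss length != sequence length")
  if (!grepl("^[HEC]*$", ss)) stop("ss must be over {H,E,C}")
  st <- strsplit(ss, "")[[1]]
  tors <- list()
  dists <- list()
  hr <- .runs_of(st == "H", 4L)
  for (k in seq_len(nrow(hr))) {
    run <- hr$start[k]:hr$end[k]
    tors[[length(tors) + 1L]] <- data.frame(
      residue = rep(run, each = 2L),
      angle = rep(c("phi", "psi"), length(run)),
      target = rep(c(-57, -47), length(run)),
      tol = 20, weight = 1, stringsAsFactors = FALSE)
    if (length(run) >= 5L) {
      i4 <- run[seq_len(length(run) - 4L)]
      dists[[length(dists) + 1L]] <- data.frame(
        i = i4, j = i4 + 4L, atom_i = "CA", atom_j = "CA",
        lb = 5.4, ub = 6.4, sd = 0.5, weight = 1, source = "ss_local",
        stringsAsFactors = FALSE)
    }
  }
  er <- .runs_of(st == "E", 3L)
  for (k in seq_len(nrow(er))) {
    run <- er$start[k]:er$end[k]
    tors[[length(tors) + 1L]] <- data.frame(
      residue = rep(run, each = 2L),
      angle = rep(c("phi", "psi"), length(run)),
      target = rep(c(-120, 120), length(run)),
      tol = 30, weight = 1, stringsAsFactors = FALSE)
  }
  RestraintSet(
    distances = if (length(dists)) do.call(rbind, dists)
                else emptyDistanceRestraints(),
    torsions = if (length(tors)) do.call(rbind, tors)
               else emptyTorsionRestraints(),
    meta = list(ss = ss))
}

.restraint_dist <- function(model, df) {
  get_atom <- function(r, atom) {
    m <- atomCoords(model, atom)
    if (is.null(m)) return(rep(NA_real_, 3))
    m[r, ]
  }
  vapply(seq_len(nrow(df)), function(k) {
    a <- get_atom(df$i[k], df$atom_i[k])
    b <- get_atom(df$j[k], df$atom_j[k])
    sqrt(sum((a - b)^2))
  }, numeric(1))
}

#' Check distance-restraint satisfaction in a model
#'
#' A distance restraint is satisfied iff `lb <= d <= ub` (inclusive bounds).
#'
#' @param model a [StructureModel-class] covering all restrained residues.
#' @param rs a [RestraintSet-class] (only distance restraints are checked).
#' @return list with `fraction` (in [0, 1]; 1 for an empty set) and
#'   `unrealized` (the violated restraint rows, input order preserved).
#' @export
restraintSatisfaction <- function(model, rs) {
  df <- rs@distances
  if (!nrow(df)) return(list(fraction = 1, unrealized = df))
  if (any(df$j > nres(model)))
    stop("restrained residue beyond model length")
  d <- .restraint_dist(model, df)
  if (any(!is.finite(d))) {
    bad <- which(!is.finite(d))[1]
    stop(sprintf("missing restrained atom %s for residue %d",
                 df$atom_i[bad], df$i[bad]))
  }
  sat <- d >= df$lb & d <= df$ub
  list(fraction = mean(sat), unrealized = df[!sat, , drop = FALSE])
}

#' Detect beta-strand pairings across round-1 models
#'
#' Finds pairs of strand (E) runs whose best-register mean CA-CA distance is
#' below 5.5 Angstrom in at least half of the supplied models, together with
#' the pairing orientation (parallel when both runs progress in the same
#' sequence direction at the optimal register, antiparallel otherwise).
#'
#' @param models list of [StructureModel-class] with assigned secondary
#'   structure (assigned on the fly with [assignSS()] where missing).
#' @return list of pairings, each a list with `run_i`, `run_j` (integer
#'   residue vectors), `orientation` ("parallel"/"antiparallel") and
#'   `pairs` (2-column matrix of aligned residue indices).
#' @export
detectBetaPairings <- function(models) {
  if (!length(models)) stop("need at least one model")
  sss <- lapply(models, function(m) {
    s <- secondaryStructure(m)
    if (is.na(s)) s <- assignSS(m)
    strsplit(s, "")[[1]]
  })
  # strand runs from the consensus of per-model assignments
  L <- nres(models[[1]])
  efrac <- rowMeans(vapply(sss, function(s) s == "E", logical(L)))
  runs <- .runs_of(efrac >= 0.5, 3L)
  if (nrow(runs) < 2L) return(list())
  score_pair <- function(ca, ra, rb, rev_b) {
    rb_use <- if (rev_b) rev(rb) else rb
    la <- length(ra); lb <- length(rb_use)
    best <- Inf; best_pairs <- NULL
    for (off in -(lb - 1):(la - 1)) {
      ia <- seq_len(la)
      ib <- ia - off
      ok <- ib >= 1 & ib <= lb
      if (sum(ok) < 3L) next
      pa <- ra[ia[ok]]; pb <- rb_use[ib[ok]]
      d <- sqrt(rowSums((ca[pa, , drop = FALSE] - ca[pb, , drop = FALSE])^2))
      if (mean(d) < best) {
        best <- mean(d)
        best_pairs <- cbind(pa, pb)
      }
    }
    list(dist = best, pairs = best_pairs)
  }
  out <- list()
  for (a in seq_len(nrow(runs) - 1L)) {
    for (b in (a + 1L):nrow(runs)) {
      ra <- runs$start[a]:runs$end[a]
      rb <- runs$start[b]:runs$end[b]
      votes_par <- votes_anti <- 0L
      sum_par <- sum_anti <- 0
      pairs_par <- pairs_anti <- NULL
      for (m in models) {
        ca <- caCoords(m)
        sp <- score_pair(ca, ra, rb, FALSE)
        sa <- score_pair(ca, ra, rb, TRUE)
        if (is.finite(sp$dist) && sp$dist < 5.5) {
          votes_par <- votes_par + 1L; sum_par <- sum_par + sp$dist
          pairs_par <- sp$pairs
        }
        if (is.finite(sa$dist) && sa$dist < 5.5) {
          votes_anti <- votes_anti + 1L; sum_anti <- sum_anti + sa$dist
          pairs_anti <- sa$pairs
        }
      }
      need <- ceiling(length(models) / 2)
      if (max(votes_par, votes_anti) >= need) {
        anti <- votes_anti > votes_par ||
          (votes_anti == votes_par && sum_anti <= sum_par)
        out[[length(out) + 1L]] <- list(
          run_i = ra, run_j = rb,
          orientation = if (anti) "antiparallel" else "parallel",
          pairs = if (anti) pairs_anti else pairs_par)
      }
    }
  }
  out
}

#' Restraints reinforcing detected beta-strand pairings
#'
#' For every aligned residue pair of each pairing: a CA-CA distance
#' restraint of 4.5-5.5 Angstrom (sd 0.5) and, for the implied hydrogen-bond
#' ladder (every second aligned pair), an N-O restraint of 2.6-3.2 Angstrom.
#' All restraints carry source "beta_pairing".
#'
#' @param pairings output of [detectBetaPairings()].
#' @return distance-restraint data.frame.
#' @export
betaPairingRestraints <- function(pairings) {
  if (!length(pairings)) return(emptyDistanceRestraints())
  rows <- list()
  for (p in pairings) {
    pr <- p$pairs
    for (k in seq_len(nrow(pr))) {
      i <- min(pr[k, ]); j <- max(pr[k, ])
      rows[[length(rows) + 1L]] <- data.frame(
        i = i, j = j, atom_i = "CA", atom_j = "CA",
        lb = 4.5, ub = 5.5, sd = 0.5, weight = 1, source = "beta_pairing",
        stringsAsFactors = FALSE)
      if (k %% 2L == 1L) {  # hydrogen-bond ladder on alternating rungs
        rows[[length(rows) + 1L]] <- data.frame(
          i = i, j = j, atom_i = "N", atom_j = "O",
          lb = 2.6, ub = 3.2, sd = 0.2, weight = 1, source = "beta_pairing",
          stringsAsFactors = FALSE)
      }
    }
  }
  df <- do.call(rbind, rows)
  df <- df[!duplicated(paste(df$i, df$j, df$atom_i, df$atom_j)), ]
  rownames(df) <- NULL
  df
}

#' Merge distance-restraint tables without duplicating (i, j, atom) keys
#'
#' Earlier tables take precedence: a restraint on an (i, j, atom_i, atom_j)
#' key already present is dropped.
#'
#' @param ... distance-restraint data.frames.
#' @return merged data.frame.
#' @export
mergeRestraints <- function(...) {
  df <- do.call(rbind, list(...))
  if (!nrow(df)) return(emptyDistanceRestraints())
  df <- df[!duplicated(paste(df$i, df$j, df$atom_i, df$atom_j)), ]
  rownames(df) <- NULL
  df
}
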