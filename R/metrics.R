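#' Kabsch superposition
#'
#' Least-squares optimal rigid superposition of point set `coordsA` onto
#' `coordsB` (n x 3 matrices, n >= 3). Reflections are excluded: the
#' returned rotation is proper (det = +1), so mirror-image point sets do
#' not superpose to zero RMSD.
#'
#' @param coordsA,coordsB n x 3 numeric matrices.
#' @return list with elements `rotation` (3 x 3, det +1), `translation`
#'   (length-3), `rmsd` (Angstrom). The fitted coordinates are
#'   `coordsA %*% t(rotation) + translation` (rows).
#' @export
kabschSuperpose <- function(coordsA, coordsB) {
  coordsA <- as.matrix(coordsA)
  coordsB <- as.matrix(coordsB)
  if (!all(dim(coordsA) == dim(coordsB)))
    stop("coordinate sets must have equal dimensions")
  if (nrow(coordsA) < 3L) stop("need at least 3 points")
  res <- .kabsch_cpp(coordsA, coordsB)
  res$translation <- as.numeric(res$translation)
  res
}

.ca_of <- function(m) if (is(m, "StructureModel")) caCoords(m) else as.matrix(m)

#' GDT-TS of a model against a reference
#'
#' Mean over distance cutoffs 1, 2, 4 and 8 Angstrom of the maximal fraction
#' of CA atoms superposable within the cutoff, searched by the standard
#' iterative seed-extension heuristic (seed fragments of lengths 3, 5 and 7
#' at every position, iterative superpose-and-include to convergence, best
#' over seeds). Reported on the 1-point scale; multiply by 100 for the
#' 100-point scale.
#'
#' @param model,reference [StructureModel-class] objects (or L x 3 CA
#'   matrices) of equal length.
#' @return GDT-TS in [0, 1].
#' @export
gdtTS <- function(model, reference) {
  a <- .ca_of(model)
  b <- .ca_of(reference)
  if (nrow(a) != nrow(b)) stop("length mismatch: ", nrow(a), " vs ", nrow(b))
  fr <- .gdt_fractions_cpp(a, b, c(1, 2, 4, 8))
  mean(fr)
}

#' Per-cutoff GDT fractions
#' @inheritParams gdtTS
#' @param cutoffs distance cutoffs in Angstrom.
#' @return numeric vector of maximal superposable fractions, one per cutoff.
#' @export
gdtFractions <- function(model, reference, cutoffs = c(1, 2, 4, 8)) {
  a <- .ca_of(model)
  b <- .ca_of(reference)
  if (nrow(a) != nrow(b)) stop("length mismatch")
  as.numeric(.gdt_fractions_cpp(a, b, cutoffs))
}

#' Length-dependent TM-score normalisation distance
#' @param L protein length (>= 16).
#' @return d0 in Angstrom: `1.24 * (L - 15)^(1/3) - 1.8`.
#' @export
tmD0 <- function(L) {
  if (L < 16) stop("d0 formula requires L >= 16")
  1.24 * (L - 15)^(1 / 3) - 1.8
}

#' TM-score of a model against a reference
#'
#' TM-score with the standard length-dependent normalisation
#' `d0 = 1.24 (L - 15)^(1/3) - 1.8`, maximised over an iterative
#' superposition search seeded from chain fragments. Scores above 0.5
#' indicate a correctly folded topology.
#'
#' @inheritParams gdtTS
#' @return TM-score in [0, 1].
#' @export
tmScore <- function(model, reference) {
  a <- .ca_of(model)
  b <- .ca_of(reference)
  if (nrow(a) != nrow(b)) stop("length mismatch: ", nrow(a), " vs ", nrow(b))
  d0 <- tmD0(nrow(a))
  .tm_score_cpp(a, b, d0)
}

#' Correct-fold classification
#' @inheritParams gdtTS
#' @return TRUE iff TM-score > 0.5.
#' @export
classifyFold <- function(model, reference) tmScore(model, reference) > 0.5

#' Extract contacts realised in a model
#'
#' All residue pairs i < j with sequence separation `|i - j| >=
#' min_separation` whose representative atoms (CB, or CA for glycine) lie
#' strictly closer than `threshold` Angstrom.
#'
#' @param model a [StructureModel-class].
#' @param threshold distance threshold in Angstrom (default 8).
#' @param min_separation minimum sequence separation (default 6).
#' @return data.frame with columns i, j (sorted by i then j).
#' @export
extractContacts <- function(model, threshold = 8, min_separation = 6) {
  stopifnot(threshold > 0, min_separation >= 1)
  xyz <- repCoords(model)
  L <- nrow(xyz)
  d <- as.matrix(stats::dist(xyz))
  idx <- which(upper.tri(d), arr.ind = TRUE)
  sep_ok <- (idx[, 2] - idx[, 1]) >= min_separation
  close_ok <- d[idx] < threshold
  keep <- idx[sep_ok & close_ok, , drop = FALSE]
  out <- data.frame(i = keep[, 1], j = keep[, 2])
  out[order(out$i, out$j), , drop = FALSE]
}

.dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  c1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  c2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  x <- sum(c1 * c2)
  cc <- c(c1[2] * c2[3] - c1[3] * c2[2], c1[3] * c2[1] - c1[1] * c2[3],
          c1[1] * c2[2] - c1[2] * c2[1])
  y <- sum(cc * b2) / sqrt(sum(b2^2))
  atan2(y, x) * 180 / pi
}

#' Backbone phi/psi angles
#' @param model StructureModel with N, CA and C atoms.
#' @return data.frame with columns phi, psi (degrees; NA at chain termini).
#' @export
phiPsi <- function(model) {
  N <- atomCoords(model, "N"); CA <- atomCoords(model, "CA")
  C <- atomCoords(model, "C")
  if (is.null(N) || is.null(C)) stop("backbone N and C atoms required")
  L <- nres(model)
  phi <- psi <- rep(NA_real_, L)
  for (i in seq_len(L)) {
    if (i > 1 && all(is.finite(c(C[i - 1, ], N[i, ], CA[i, ], C[i, ]))))
      phi[i] <- .dihedral(C[i - 1, ], N[i, ], CA[i, ], C[i, ])
    if (i < L && all(is.finite(c(N[i, ], CA[i, ], C[i, ], N[i + 1, ]))))
      psi[i] <- .dihedral(N[i, ], CA[i, ], C[i, ], N[i + 1, ])
  }
  data.frame(phi = phi, psi = psi)
}

#' CA pseudo-torsions along the chain
#'
#' Dihedral over CA(i-1), CA(i), CA(i+1), CA(i+2), anchored at residue i
#' (NA where undefined). Right-handed helices give values near +50 degrees,
#' extended strands near -170 degrees.
#'
#' @param ca L x 3 CA coordinate matrix or a StructureModel.
#' @return numeric vector of length L (degrees).
#' @export
caPseudoTorsions <- function(ca) {
  if (is(ca, "StructureModel")) ca <- caCoords(ca)
  L <- nrow(ca)
  out <- rep(NA_real_, L)
  if (L >= 4) {
    for (i in 2:(L - 2))
      out[i] <- .dihedral(ca[i - 1, ], ca[i, ], ca[i + 1, ], ca[i + 2, ])
  }
  out
}

.runs_of <- function(mask, min_len) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_len
  data.frame(start = starts[keep], end = ends[keep])
}

#' Assign 3-state secondary structure from coordinates
#'
#' A simplified, deterministic 3-state assignment. When backbone N and C
#' atoms are present, helix and strand states come from phi/psi windows
#' (helix: phi in [-90, -30] and psi in [-77, -17] over runs of >= 4;
#' strand: phi in [-180, -45] and psi in [45, 225 mod 360] over runs of
#' >= 3) plus a CA-distance strand-pairing check. For coarse CA-only
#' models the equivalent CA pseudo-geometry windows are used (pseudo-torsion
#' in [30, 70] with CA(i)..CA(i+3) < 6.5 A for helix; |pseudo-torsion| > 120
#' with extended CA(i)..CA(i+3) > 9.2 A for strand). Everything else is coil;
#' chains shorter than 4 residues are all coil. Strand states are only kept
#' where a partner strand lies within 5.5 A (mean CA-CA over the run),
#' mirroring sheet pairing.
#'
#' @param model a [StructureModel-class].
#' @return character scalar over \{H,E,C\} of length L.
#' @export
assignSS <- function(model) {
  L <- nres(model)
  if (L < 4L) return(strrep("C", L))
  has_bb <- !is.null(atomCoords(model, "N")) && !is.null(atomCoords(model, "C"))
  ca <- caCoords(model)
  helix_mask <- strand_mask <- rep(FALSE, L)
  if (has_bb) {
    pp <- phiPsi(model)
    helix_mask <- !is.na(pp$phi) & !is.na(pp$psi) &
      pp$phi >= -90 & pp$phi <= -30 & pp$psi >= -77 & pp$psi <= -17
    psi_wrap <- ifelse(!is.na(pp$psi) & pp$psi < -90, pp$psi + 360, pp$psi)
    strand_mask <- !is.na(pp$phi) & !is.na(psi_wrap) &
      pp$phi >= -180 & pp$phi <= -45 & psi_wrap >= 45 & psi_wrap <= 225
  } else {
    tor <- caPseudoTorsions(ca)
    d13 <- c(sqrt(rowSums((ca[seq_len(L - 3), , drop = FALSE] -
                             ca[4:L, , drop = FALSE])^2)), rep(NA, 3))
    helix_mask <- !is.na(tor) & tor >= 30 & tor <= 70 &
      !is.na(d13) & d13 < 6.5
    strand_mask <- !is.na(tor) & abs(tor) > 120 & !is.na(d13) & d13 > 9.2
  }
  strand_mask <- strand_mask & !helix_mask
  ss <- rep("C", L)
  hr <- .runs_of(helix_mask, 4L)
  for (k in seq_len(nrow(hr))) ss[hr$start[k]:hr$end[k]] <- "H"
  er <- .runs_of(strand_mask & ss == "C", 3L)
  # keep a strand run only if some other strand run pairs with it
  if (nrow(er) >= 1L) {
    keep <- rep(FALSE, nrow(er))
    if (nrow(er) >= 2L) {
      for (a in seq_len(nrow(er) - 1L)) {
        for (b in (a + 1L):nrow(er)) {
          ra <- er$start[a]:er$end[a]
          rb <- er$start[b]:er$end[b]
          dmat <- as.matrix(stats::dist(ca[c(ra, rb), , drop = FALSE]))
          cross <- dmat[seq_along(ra), length(ra) + seq_along(rb), drop = FALSE]
          if (min(apply(cross, 1, min)) < 5.5 &&
              mean(apply(cross, 1, min) < 6.5) >= 0.5) {
            keep[a] <- TRUE
            keep[b] <- TRUE
          }
        }
      }
    }
    for (k in which(keep)) ss[er$start[k]:er$end[k]] <- "E"
  }
  paste(ss, collapse = "")
}

#' APOLLO-style pairwise consensus ranking
#'
#' Scores each model by its mean GDT-TS to all other models in the pool and
#' ranks by descending score; structurally central models rank first.
#'
#' @param models list of equal-length [StructureModel-class] objects (>= 2).
#' @return data.frame (model_id, score) sorted by descending score, ties
#'   broken by model_id.
#' @export
pairwiseConsensusRank <- function(models) {
  if (length(models) < 2L) stop("need at least 2 models")
  Ls <- vapply(models, nres, integer(1))
  if (length(unique(Ls)) != 1L) stop("models must have equal length")
  coords <- lapply(models, caCoords)
  M <- .gdt_matrix_cpp(coords)
  n <- length(models)
  score <- (rowSums(M) - 1) / (n - 1)
  ids <- vapply(models, modelId, character(1))
  out <- data.frame(model_id = ids, score = score)
  out[order(-out$score, out$model_id), , drop = FALSE]
}
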