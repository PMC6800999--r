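#' @useDynLib ContactFold, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
#' @importFrom stats cor runif rnorm sd setNames p.adjust aggregate
#' @importFrom utils read.delim write.table head tail
NULL

AA3TO1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V"
)
AA1TO3 <- setNames(names(AA3TO1), unname(AA3TO1))

#' StructureModel: a single-chain protein model
#'
#' Coarse-grained container for one protein structural model: the amino-acid
#' sequence, per-residue atomic coordinates (CA always present; CB present
#' except for glycine; N, C, O optional) and an optional 3-state secondary
#' structure string over \{H, E, C\}. Residues are numbered sequentially from
#' 1 regardless of the numbering in any source PDB file.
#'
#' @slot modelId character scalar identifier.
#' @slot aaSequence character scalar over the 20-letter amino-acid alphabet.
#' @slot atoms named list of L x 3 numeric matrices (Angstrom), keyed by atom
#'   name ("CA", "CB", "N", "C", "O"). Rows of "CB" are NA for glycine.
#' @slot ss character scalar over \{H,E,C\} of length L, or NA if unassigned.
#'
#' @export
setClass("StructureModel",
  representation(
    modelId = "character",
    aaSequence = "character",
    atoms = "list",
    ss = "character"
  ),
  prototype(modelId = "model", aaSequence = "", atoms = list(), ss = NA_character_)
)

setValidity("StructureModel", function(object) {
  L <- nchar(object@aaSequence)
  msgs <- character()
  if (L < 1L) msgs <- c(msgs, "sequence must be non-empty")
  if (!grepl("^[ACDEFGHIKLMNPQRSTVWY]*$", object@aaSequence))
    msgs <- c(msgs, "sequence contains non-standard amino-acid letters")
  if (is.null(object@atoms[["CA"]]))
    msgs <- c(msgs, "CA coordinates are required")
  for (nm in names(object@atoms)) {
    m <- object@atoms[[nm]]
    if (!is.matrix(m) || ncol(m) != 3L || nrow(m) != L)
      msgs <- c(msgs, sprintf("atom matrix '%s' must be L x 3", nm))
  }
  ca <- object@atoms[["CA"]]
  if (is.matrix(ca) && any(!is.finite(ca)))
    msgs <- c(msgs, "CA coordinates must all be finite")
  cb <- object@atoms[["CB"]]
  if (!is.null(cb) && is.matrix(cb) && nrow(cb) == L) {
    gly <- strsplit(object@aaSequence, "")[[1]] == "G"
    bad <- !gly & !stats::complete.cases(cb)
    if (any(bad))
      msgs <- c(msgs, sprintf("CB missing for non-glycine residue(s) %s",
                              paste(which(bad)[1:min(3, sum(bad))], collapse = ",")))
  }
  if (!is.na(object@ss)) {
    if (nchar(object@ss) != L) msgs <- c(msgs, "ss length != sequence length")
    if (!grepl("^[HEC]*$", object@ss)) msgs <- c(msgs, "ss must be over {H,E,C}")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a StructureModel
#'
#' @param modelId identifier string.
#' @param sequence amino-acid sequence (one-letter codes).
#' @param ca L x 3 matrix of CA coordinates (Angstrom).
#' @param cb optional L x 3 matrix of CB coordinates; rows for glycine may be
#'   NA. If omitted, pseudo-CB positions are constructed from the CA trace
#'   (glycine rows set to NA).
#' @param n,c,o optional L x 3 backbone coordinate matrices.
#' @param ss optional secondary-structure string over \{H,E,C\}.
#' @return a validated [StructureModel-class] object.
#' @export
StructureModel <- function(modelId, sequence, ca, cb = NULL,
                           n = NULL, c = NULL, o = NULL, ss = NA_character_) {
  ca <- as.matrix(ca)
  dimnames(ca) <- NULL
  storage.mode(ca) <- "double"
  atoms <- list(CA = ca)
  gly <- strsplit(sequence, "")[[1]] == "G"
  if (is.null(cb)) {
    cb <- .pseudo_cb_cpp(ca)
    cb[gly, ] <- NA_real_
  } else {
    cb <- as.matrix(cb)
    dimnames(cb) <- NULL
    storage.mode(cb) <- "double"
  }
  atoms$CB <- cb
  for (nm in c("N", "C", "O")) {
    v <- switch(nm, N = n, C = c, O = o)
    if (!is.null(v)) {
      v <- as.matrix(v)
      dimnames(v) <- NULL
      storage.mode(v) <- "double"
      atoms[[nm]] <- v
    }
  }
  new("StructureModel", modelId = as.character(modelId),
      aaSequence = sequence, atoms = atoms, ss = ss)
}

#' Empty restraint tables
#'
#' Zero-row data.frames with the distance- and torsion-restraint schemas used
#' by [RestraintSet-class].
#' @return a zero-row data.frame.
#' @export
emptyDistanceRestraints <- function() {
  data.frame(i = integer(), j = integer(), atom_i = character(),
             atom_j = character(), lb = numeric(), ub = numeric(),
             sd = numeric(), weight = numeric(), source = character(),
             stringsAsFactors = FALSE)
}

#' @rdname emptyDistanceRestraints
#' @export
emptyTorsionRestraints <- function() {
  data.frame(residue = integer(), angle = character(), target = numeric(),
             tol = numeric(), weight = numeric(), stringsAsFactors = FALSE)
}

#' RestraintSet: distance and torsion restraints for folding
#'
#' @slot distances data.frame with columns i, j, atom_i, atom_j, lb, ub, sd,
#'   weight, source (one of contact, ss_pair, ss_local, hbond, beta_pairing).
#' @slot torsions data.frame with columns residue, angle ("phi"/"psi"),
#'   target (degrees in (-180, 180]), tol (degrees > 0), weight.
#' @slot meta list of provenance fields (e.g. x ratio, round number).
#' @export
setClass("RestraintSet",
  representation(distances = "data.frame", torsions = "data.frame",
                 meta = "list"),
  prototype(distances = emptyDistanceRestraints(),
            torsions = emptyTorsionRestraints(), meta = list())
)

setValidity("RestraintSet", function(object) {
  d <- object@distances
  msgs <- character()
  need <- c("i", "j", "atom_i", "atom_j", "lb", "ub", "sd", "weight", "source")
  if (!all(need %in% names(d)))
    return("distance table lacks required columns")
  if (nrow(d)) {
    if (any(d$i == d$j)) msgs <- c(msgs, "distance restraint with i == j")
    if (any(d$lb <= 0 | d$lb >= d$ub)) msgs <- c(msgs, "need 0 < lb < ub")
    if (any(d$sd <= 0)) msgs <- c(msgs, "sd must be positive")
    if (any(d$weight < 0)) msgs <- c(msgs, "weights must be non-negative")
    key <- paste(d$i, d$j, d$atom_i, d$atom_j)
    if (anyDuplicated(key)) msgs <- c(msgs, "duplicate (i,j,atom pair) restraint")
  }
  tt <- object@torsions
  if (nrow(tt)) {
    if (any(tt$target <= -180 | tt$target > 180))
      msgs <- c(msgs, "torsion target outside (-180, 180]")
    if (any(tt$tol <= 0)) msgs <- c(msgs, "torsion tolerance must be positive")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a RestraintSet
#' @param distances distance-restraint data.frame (see [RestraintSet-class]).
#' @param torsions torsion-restraint data.frame.
#' @param meta provenance list.
#' @return a validated RestraintSet.
#' @export
RestraintSet <- function(distances = emptyDistanceRestraints(),
                         torsions = emptyTorsionRestraints(),
                         meta = list()) {
  rownames(distances) <- NULL
  rownames(torsions) <- NULL
  new("RestraintSet", distances = distances, torsions = torsions, meta = meta)
}

#' DecoySet: a pool of structural decoys with provenance
#'
#' @slot models list of [StructureModel-class] objects sharing one sequence.
#' @slot provenance data.frame with one row per model: model_id, x, round,
#'   seed, energy.
#' @export
setClass("DecoySet",
  representation(models = "list", provenance = "data.frame"),
  prototype(models = list(),
            provenance = data.frame(model_id = character(), x = numeric(),
                                    round = integer(), seed = integer(),
                                    energy = numeric()))
)

setValidity("DecoySet", function(object) {
  if (!length(object@models)) return(TRUE)
  seqs <- vapply(object@models, function(m) m@aaSequence, character(1))
  if (length(unique(seqs)) != 1L)
    return("all decoys must share one sequence")
  if (nrow(object@provenance) != length(object@models))
    return("provenance rows must match number of models")
  TRUE
})

#' @rdname DecoySet-class
#' @param models list of StructureModel objects.
#' @param provenance per-model provenance data.frame.
#' @export
DecoySet <- function(models, provenance) {
  rownames(provenance) <- NULL
  new("DecoySet", models = models, provenance = provenance)
}

#' QAEnsemble: the two-level model quality-assessment ensemble
#'
#' Ten level-1 feed-forward regressors (one per target-wise cross-validation
#' fold, each with its own input standardisation statistics and an
#' architecture selected by validation selection loss) plus one level-2
#' combiner trained on the ten level-1 scores concatenated with the original
#' features.
#'
#' @slot level1 list of 10 fitted networks (weights, normalisation, arch).
#' @slot level2 fitted combiner network.
#' @slot featureNames character vector naming the input feature columns.
#' @slot config list: architecture grid, seed, training options.
#' @export
setClass("QAEnsemble",
  representation(level1 = "list", level2 = "list",
                 featureNames = "character", config = "list")
)

setValidity("QAEnsemble", function(object) {
  if (length(object@level1) != 10L)
    return("ensemble must contain exactly 10 level-1 members")
  TRUE
})

setMethod("show", "StructureModel", function(object) {
  L <- nchar(object@aaSequence)
  cat(sprintf("StructureModel '%s': %d residues, atoms: %s%s\n",
              object@modelId, L, paste(names(object@atoms), collapse = ","),
              if (is.na(object@ss)) "" else ", ss assigned"))
})

setMethod("show", "RestraintSet", function(object) {
  cat(sprintf("RestraintSet: %d distance, %d torsion restraints\n",
              nrow(object@distances), nrow(object@torsions)))
  if (nrow(object@distances))
    print(table(object@distances$source))
})

setMethod("show", "DecoySet", function(object) {
  cat(sprintf("DecoySet: %d decoys (L = %d)\n", length(object@models),
              if (length(object@models)) nres(object@models[[1]]) else 0L))
})

setMethod("show", "QAEnsemble", function(object) {
  cat(sprintf("QAEnsemble: 10 level-1 + 1 level-2 networks over %d features\n",
              length(object@featureNames)))
})

setMethod("length", "DecoySet", function(x) length(x@models))

#' Accessors for StructureModel and friends
#'
#' `nres` returns the residue count L; `caCoords`/`cbCoords` return L x 3
#' coordinate matrices; `repCoords` returns the contact representative atom
#' per residue (CB, or CA for glycine / residues lacking CB); `modelId`,
#' `aaSequence` and `secondaryStructure` return the corresponding fields;
#' `decoyModels` and `decoyProvenance` unpack a [DecoySet-class].
#'
#' @param x a StructureModel (or DecoySet where noted).
#' @return see individual descriptions.
#' @name accessors
NULL

#' @rdname accessors
#' @export
nres <- function(x) nchar(x@aaSequence)

#' @rdname accessors
#' @export
modelId <- function(x) x@modelId

#' @rdname accessors
#' @export
aaSequence <- function(x) x@aaSequence

#' @rdname accessors
#' @export
secondaryStructure <- function(x) x@ss

#' @rdname accessors
#' @export
caCoords <- function(x) x@atoms[["CA"]]

#' @rdname accessors
#' @export
cbCoords <- function(x) x@atoms[["CB"]]

#' @rdname accessors
#' @param atom atom name such as "N" or "C".
#' @export
atomCoords <- function(x, atom) x@atoms[[atom]]

#' @rdname accessors
#' @export
repCoords <- function(x) {
  ca <- caCoords(x)
  cb <- cbCoords(x)
  if (is.null(cb)) return(ca)
  use_ca <- !stats::complete.cases(cb)
  out <- cb
  out[use_ca, ] <- ca[use_ca, ]
  out
}

#' @rdname accessors
#' @export
decoyModels <- function(x) x@models

#' @rdname accessors
#' @export
decoyProvenance <- function(x) x@provenance

`%||%` <- function(a, b) if (is.null(a)) b else a
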