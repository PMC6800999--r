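#' Read a single-chain PDB file into a StructureModel
#'
#' Parses ATOM records (via bio3d) from a single-model, single-chain PDB
#' file. Residues are renumbered sequentially from 1 in file order; the
#' original author numbering is kept in the returned object's
#' `meta` attribute (`attr(model, "resseq_map")`). Files with insertion
#' codes, multiple chains, or any residue lacking a CA atom are rejected.
#'
#' @param path path to a PDB file (ATOM records, UTF-8 text).
#' @param modelId identifier; defaults to the file name without extension.
#' @return a [StructureModel-class].
#' @export
readPDB <- function(path, modelId = NULL) {
  if (is.null(modelId))
    modelId <- sub("\\.[^.]*$", "", basename(path))
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE))
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (!nrow(at)) stop("no ATOM records in ", path)
  if (length(unique(at$chain[!is.na(at$chain)])) > 1L)
    stop("multi-chain PDB input is not supported: ", path)
  ins <- at$insert
  if (any(!is.na(ins) & ins != ""))
    stop("insertion codes are not supported: ", path)
  if (any(!is.finite(at$x) | !is.finite(at$y) | !is.finite(at$z)))
    stop("non-numeric coordinate in ", path)
  resseq <- at$resno
  ridx <- cumsum(!duplicated(resseq))[match(resseq, resseq)]
  # file-order residue index (resno may restart; rely on order of change)
  change <- c(TRUE, resseq[-1] != resseq[-length(resseq)])
  ridx <- cumsum(change)
  L <- max(ridx)
  resnames <- at$resid[change]
  aa <- AA3TO1[resnames]
  if (any(is.na(aa)))
    stop("non-standard residue(s): ",
         paste(unique(resnames[is.na(aa)]), collapse = ","))
  sequence <- paste(aa, collapse = "")
  atoms <- list()
  for (nm in c("CA", "CB", "N", "C", "O")) {
    sel <- at$elety == nm
    if (!any(sel) && nm != "CA") next
    m <- matrix(NA_real_, L, 3)
    m[ridx[sel], ] <- cbind(at$x[sel], at$y[sel], at$z[sel])
    atoms[[nm]] <- m
  }
  ca <- atoms[["CA"]]
  if (is.null(ca) || any(!stats::complete.cases(ca))) {
    bad <- if (is.null(ca)) seq_len(L) else which(!stats::complete.cases(ca))
    stop("missing CA for residue ", bad[1], " in ", path)
  }
  gly <- aa == "G"
  cb <- atoms[["CB"]]
  if (is.null(cb)) {
    cb <- matrix(NA_real_, L, 3)
  }
  missing_cb <- !stats::complete.cases(cb) & !gly
  if (any(missing_cb)) {
    # fill from CA pseudo-construction so invariants hold for stripped files
    pc <- .pseudo_cb_cpp(ca)
    cb[missing_cb, ] <- pc[missing_cb, ]
  }
  cb[gly, ] <- NA_real_
  m <- StructureModel(modelId, sequence, ca, cb = cb,
                      n = atoms[["N"]], c = atoms[["C"]], o = atoms[["O"]])
  attr(m, "resseq_map") <- data.frame(internal = seq_len(L),
                                      resseq = resseq[change])
  m
}

#' Write a StructureModel as a PDB file
#'
#' Emits fixed-width ATOM records (3-decimal coordinates) for all atoms held
#' in the model, chain A, sequential residue numbering. Round-tripping
#' through [readPDB()] reproduces coordinates to 3 decimals.
#'
#' @param model a [StructureModel-class].
#' @param path output file path.
#' @return invisibly, the path.
#' @export
writePDB <- function(model, path) {
  stopifnot(is(model, "StructureModel"))
  L <- nres(model)
  if (L < 1L) stop("cannot write a 0-residue model")
  aa <- strsplit(aaSequence(model), "")[[1]]
  lines <- character()
  serial <- 0L
  order_atoms <- intersect(c("N", "CA", "C", "O", "CB"), names(model@atoms))
  for (i in seq_len(L)) {
    for (nm in order_atoms) {
      xyz <- model@atoms[[nm]][i, ]
      if (any(!is.finite(xyz))) next
      serial <- serial + 1L
      lines <- c(lines, sprintf(
        "ATOM  %5d  %-3s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00",
        serial, nm, AA1TO3[aa[i]], i, xyz[1], xyz[2], xyz[3]))
    }
  }
  writeLines(c(lines, "TER", "END"), path)
  invisible(path)
}

#' Read CASP RR-format contact predictions
#'
#' Whitespace-separated records `i j d_low d_high probability`; header and
#' sequence lines that do not parse as five numeric fields are skipped with
#' a warning. Pairs are normalised to i < j, duplicates keep the maximum
#' probability, and the result is sorted by decreasing probability with ties
#' broken by (i, j) lexicographic order.
#'
#' @param path path to an RR file.
#' @param L protein length; indices greater than L are an error.
#' @return data.frame with columns i, j, p, d0 (contact records).
#' @export
readRR <- function(path, L) {
  raw <- readLines(path, warn = FALSE)
  raw <- trimws(raw)
  raw <- raw[nzchar(raw)]
  toks <- strsplit(raw, "\\s+")
  ok <- vapply(toks, function(tk) {
    length(tk) == 5L && !anyNA(suppressWarnings(as.numeric(tk)))
  }, logical(1))
  if (any(!ok)) {
    skipped <- sum(!ok)
    warning(sprintf("skipped %d non-record line(s) in %s", skipped, path))
  }
  toks <- toks[ok]
  if (!length(toks))
    return(data.frame(i = integer(), j = integer(), p = numeric(),
                      d0 = numeric()))
  m <- do.call(rbind, lapply(toks, as.numeric))
  i <- as.integer(pmin(m[, 1], m[, 2]))
  j <- as.integer(pmax(m[, 1], m[, 2]))
  p <- m[, 5]
  d0 <- m[, 4]
  if (any(i < 1L) || any(j > L)) stop("contact index out of range 1..", L)
  if (any(i == j)) stop("self-contact record (i == j)")
  if (any(p < 0 | p > 1)) stop("contact probability outside [0,1]")
  df <- data.frame(i = i, j = j, p = p, d0 = d0)
  # duplicates keep max P
  key <- paste(df$i, df$j)
  if (anyDuplicated(key)) {
    df <- df[order(key, -df$p), ]
    df <- df[!duplicated(paste(df$i, df$j)), ]
  }
  df <- df[order(-df$p, df$i, df$j), ]
  rownames(df) <- NULL
  df
}

#' Write contacts in CASP RR format
#' @param contacts contact data.frame (i, j, p, d0).
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeRR <- function(contacts, path) {
  lines <- sprintf("%d %d 0 %g %.6f", contacts$i, contacts$j,
                   contacts$d0, contacts$p)
  writeLines(lines, path)
  invisible(path)
}

#' Read a FASTA file and return the first sequence
#' @param path FASTA file path.
#' @return character scalar (upper-case one-letter codes).
#' @export
readFastaSeq <- function(path) {
  fa <- bio3d::read.fasta(path)
  toupper(paste(fa$ali[1, ], collapse = ""))
}

#' Read a one-line string file (secondary structure or solvent accessibility)
#'
#' The file holds a plain string (optionally under a FASTA-style header);
#' the first non-header line is returned.
#'
#' @param path file path.
#' @return character scalar.
#' @export
readStringFile <- function(path) {
  ln <- readLines(path, warn = FALSE)
  ln <- trimws(ln)
  ln <- ln[nzchar(ln) & !startsWith(ln, ">")]
  if (!length(ln)) stop("no string found in ", path)
  ln[1]
}

#' Read a TSV feature table keyed by (target_id, model_id)
#'
#' TSV with a header; the first two columns must be `target_id` and
#' `model_id`, remaining columns numeric (NA allowed). Rows with any NA are
#' flagged via the logical `complete` attribute column.
#'
#' @param path TSV path.
#' @return data.frame with attribute column `.complete`.
#' @export
readFeatureTable <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 2L || !identical(names(df)[1:2], c("target_id", "model_id")))
    stop("feature table must start with target_id, model_id columns")
  key <- paste(df$target_id, df$model_id)
  if (anyDuplicated(key))
    stop("duplicate (target_id, model_id) row: ",
         key[duplicated(key)][1])
  for (cn in names(df)[-(1:2)]) df[[cn]] <- as.numeric(df[[cn]])
  df$.complete <- stats::complete.cases(df[, -(1:2), drop = FALSE])
  df
}

#' Write a feature table in the TSV dialect read by [readFeatureTable()]
#' @param df data.frame whose first two columns are target_id, model_id.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeFeatureTable <- function(df, path) {
  df <- df[, setdiff(names(df), ".complete"), drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize / read a RestraintSet distance table as TSV
#' @param rs a [RestraintSet-class].
#' @param path file path.
#' @return `writeRestraints`: invisibly the path; `readRestraints`: a
#'   RestraintSet (distance restraints only).
#' @export
writeRestraints <- function(rs, path) {
  utils::write.table(rs@distances, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeRestraints
#' @export
readRestraints <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  RestraintSet(distances = df)
}
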