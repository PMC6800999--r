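#' 1D secondary-structure match score
#'
#' Fraction of positions where the secondary structure predicted from the
#' sequence agrees with the one assigned from the model.
#'
#' @param pred_ss,model_ss equal-length strings over \{H,E,C\}.
#' @return agreement fraction in [0, 1].
#' @export
ssMatch <- function(pred_ss, model_ss) {
  if (!nchar(pred_ss) || !nchar(model_ss)) stop("empty string")
  if (nchar(pred_ss) != nchar(model_ss)) stop("length mismatch")
  a <- strsplit(pred_ss, "")[[1]]
  b <- strsplit(model_ss, "")[[1]]
  mean(a == b)
}

#' 1D solvent-accessibility match score
#'
#' Fraction of positions where the 2-state (B = buried, E = exposed)
#' accessibility predicted from the sequence agrees with the state derived
#' from the model.
#'
#' @param pred_sa,model_sa equal-length strings over \{B,E\}.
#' @return agreement fraction in [0, 1].
#' @export
saMatch <- function(pred_sa, model_sa) {
  if (!nchar(pred_sa) || !nchar(model_sa)) stop("empty string")
  if (nchar(pred_sa) != nchar(model_sa)) stop("length mismatch")
  a <- strsplit(pred_sa, "")[[1]]
  b <- strsplit(model_sa, "")[[1]]
  mean(a == b)
}

#' 2-state solvent exposure from a model
#'
#' Sphere-count exposure proxy: a residue is exposed ("E") if at most 14
#' other CA atoms lie within 10 Angstrom of its CA, buried ("B") otherwise.
#' This approximates a 25 percent relative-accessibility threshold without a
#' full solvent-accessible-surface computation.
#'
#' @param model a [StructureModel-class].
#' @return string over \{B,E\} of length L.
#' @export
solventExposure <- function(model) {
  ca <- caCoords(model)
  d <- as.matrix(stats::dist(ca))
  counts <- rowSums(d < 10) - 1L
  paste(ifelse(counts <= 14, "E", "B"), collapse = "")
}

#' 2D contact-match features
#'
#' For each sequence-separation class (short 6-11, medium 12-23, long >= 24)
#' the top `ceiling(L/5)` predictions in that class by probability are
#' checked against the contacts realised in the model (representative atoms
#' within 8 Angstrom); the feature is the realised fraction. A class with no
#' predictions scores 0 and clears the completeness flag.
#'
#' @param preds contact prediction data.frame (i, j, p).
#' @param model a [StructureModel-class].
#' @return named numeric vector (f_con_short, f_con_medium, f_con_long) with
#'   logical attribute "complete".
#' @export
contactMatchFeatures <- function(preds, model) {
  L <- nres(model)
  n_top <- ceiling(L / 5)
  realised <- extractContacts(model, threshold = 8, min_separation = 6)
  rkey <- paste(realised$i, realised$j)
  sep <- preds$j - preds$i
  classes <- list(short = sep >= 6 & sep <= 11,
                  medium = sep >= 12 & sep <= 23,
                  long = sep >= 24)
  complete <- TRUE
  out <- vapply(classes, function(msk) {
    sub <- preds[msk, , drop = FALSE]
    if (!nrow(sub)) {
      complete <<- FALSE
      return(0)
    }
    sub <- sub[order(-sub$p, sub$i, sub$j), , drop = FALSE]
    sub <- sub[seq_len(min(n_top, nrow(sub))), , drop = FALSE]
    mean(paste(sub$i, sub$j) %in% rkey)
  }, numeric(1))
  names(out) <- paste0("f_con_", names(classes))
  attr(out, "complete") <- complete
  out
}

#' Assemble per-model QA feature vectors for one target
#'
#' Computes the own 1D/2D features for every model and appends the external
#' 3D score columns from `external_table` (matched by model_id). Missing
#' external scores are imputed with the per-target column mean and flag the
#' model incomplete; external columns are then min-max normalised to [0, 1]
#' within the target (constant columns map to 0.5).
#'
#' @param models list of [StructureModel-class] objects for one target.
#' @param pred_ss predicted secondary-structure string.
#' @param pred_sa predicted 2-state accessibility string.
#' @param preds contact predictions (data.frame i, j, p).
#' @param external_table optional data.frame with columns model_id plus
#'   numeric score columns (a [readFeatureTable()] slice).
#' @param target_id target identifier recorded in the output.
#' @return data.frame: target_id, model_id, f_ss, f_sa, f_con_short,
#'   f_con_medium, f_con_long, external columns, complete (logical).
#' @export
assembleFeatures <- function(models, pred_ss, pred_sa, preds,
                             external_table = NULL, target_id = "T0") {
  if (!length(models)) stop("no models supplied")
  rows <- lapply(models, function(m) {
    mss <- secondaryStructure(m)
    if (is.na(mss)) mss <- assignSS(m)
    cf <- contactMatchFeatures(preds, m)
    data.frame(target_id = target_id, model_id = modelId(m),
               f_ss = ssMatch(pred_ss, mss),
               f_sa = saMatch(pred_sa, solventExposure(m)),
               f_con_short = cf[["f_con_short"]],
               f_con_medium = cf[["f_con_medium"]],
               f_con_long = cf[["f_con_long"]],
               complete = attr(cf, "complete"),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  if (!is.null(external_table) && nrow(external_table)) {
    ext_cols <- setdiff(names(external_table),
                        c("target_id", "model_id", ".complete"))
    idx <- match(df$model_id, external_table$model_id)
    for (cn in ext_cols) {
      v <- as.numeric(external_table[[cn]])[idx]
      if (any(is.na(v))) {
        df$complete[is.na(v)] <- FALSE
        v[is.na(v)] <- mean(v, na.rm = TRUE)
      }
      rng <- range(v)
      v <- if (diff(rng) < 1e-12) rep(0.5, length(v))
           else (v - rng[1]) / diff(rng)
      df[[cn]] <- v
    }
  }
  # keep `complete` as the last column
  df <- df[, c(setdiff(names(df), "complete"), "complete")]
  df
}

#' Names of the feature columns in an assembled feature table
#' @param df output of [assembleFeatures()].
#' @return character vector of feature column names.
#' @export
featureColumns <- function(df) {
  setdiff(names(df), c("target_id", "model_id", "complete", "gdt"))
}
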