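#' Filter a model pool: completeness and per-group duplicates
#'
#' Removes models covering less than `length_min_fraction` of the target
#' length, then scans each source group in input order and drops any model
#' whose GDT-TS to an already-retained model of the same group exceeds
#' `dup_threshold` (near-duplicates). Models from different groups are never
#' compared. The filter is idempotent.
#'
#' @param models list of [StructureModel-class] objects.
#' @param groups character vector of source-group labels (one per model);
#'   defaults to a single group.
#' @param target_length full target length; defaults to the maximum model
#'   length in the pool.
#' @param length_min_fraction completeness cutoff (default 0.8).
#' @param dup_threshold GDT-TS duplicate cutoff (default 0.95).
#' @return list with elements `models` and `groups` (the survivors).
#' @export
filterPool <- function(models, groups = NULL, target_length = NULL,
                       length_min_fraction = 0.8, dup_threshold = 0.95) {
  if (!length(models)) stop("empty model pool")
  if (is.null(groups)) groups <- rep("g1", length(models))
  stopifnot(length(groups) == length(models))
  Ls <- vapply(models, nres, integer(1))
  if (is.null(target_length)) target_length <- max(Ls)
  keep <- Ls >= length_min_fraction * target_length
  models <- models[keep]
  groups <- groups[keep]
  Ls <- Ls[keep]
  retained <- logical(length(models))
  for (k in seq_along(models)) {
    dup <- FALSE
    for (r in which(retained)) {
      if (groups[r] != groups[k] || Ls[r] != Ls[k]) next
      if (gdtTS(models[[k]], models[[r]]) > dup_threshold) {
        dup <- TRUE
        break
      }
    }
    retained[k] <- !dup
  }
  if (!any(retained)) stop("no models survive filtering")
  list(models = models[retained], groups = groups[retained])
}

#' Consensus combination of a top-ranked model with similar pool members
#'
#' Models with GDT-TS above `similarity_threshold` to the top model are each
#' superposed onto it and their CA coordinates averaged into a consensus
#' model. If the consensus stays structurally close to the initial top model
#' (GDT-TS > 0.88) it is kept as the final model; otherwise the unmodified
#' top model is returned flagged "refine_needed" (external refinement is a
#' downstream step).
#'
#' @param top_model the selected [StructureModel-class].
#' @param ranked_pool list of StructureModels (including the top model).
#' @param similarity_threshold GDT-TS similarity cutoff (default 0.6).
#' @return list with `model` (the final StructureModel), `decision`
#'   ("kept" or "refine_needed") and `n_combined`.
#' @export
consensusCombine <- function(top_model, ranked_pool,
                             similarity_threshold = 0.6) {
  ca_top <- caCoords(top_model)
  sims <- vapply(ranked_pool, function(m) {
    if (nres(m) != nres(top_model)) return(-1)
    gdtTS(m, top_model)
  }, numeric(1))
  similar <- ranked_pool[sims > similarity_threshold]
  if (!length(similar)) similar <- list(top_model)
  acc <- matrix(0, nrow(ca_top), 3)
  for (m in similar) {
    sup <- kabschSuperpose(caCoords(m), ca_top)
    fitted <- caCoords(m) %*% t(sup$rotation)
    fitted <- sweep(fitted, 2, sup$translation, "+")
    acc <- acc + fitted
  }
  consensus <- StructureModel(paste0(modelId(top_model), "_consensus"),
                              aaSequence(top_model), acc / length(similar))
  if (gdtTS(consensus, top_model) > 0.88) {
    list(model = consensus, decision = "kept", n_combined = length(similar))
  } else {
    list(model = top_model, decision = "refine_needed",
         n_combined = length(similar))
  }
}
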