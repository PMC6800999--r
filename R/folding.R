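#' Folding protocol configuration
#'
#' @param x_grid strictly increasing contact-selection ratios (> 0);
#'   default the full sweep 0.1, 0.2, ..., 4.0.
#' @param models_per_x decoys built per ratio (default 5).
#' @param anneal_steps Metropolis proposals per decoy; default
#'   `min(20000 * L, 2e6)`, resolved at fold time.
#' @param T_start,T_end temperature schedule endpoints (T_start > T_end > 0).
#'   Equal temperatures degenerate to greedy descent.
#' @param step_size proposal displacement scale, Angstrom.
#' @param seed base seed; per-decoy seeds are derived deterministically.
#' @param round2_enabled run the second (beta-sheet augmented) round.
#' @param n_select final models to keep after clustering.
#' @param cluster_threshold TM-score threshold for greedy clustering.
#' @return a validated list of class "FoldingConfig".
#' @export
foldingConfig <- function(x_grid = seq(0.1, 4, by = 0.1), models_per_x = 5,
                          anneal_steps = NULL, T_start = 2, T_end = 0.01,
                          step_size = 0.6, seed = 1, round2_enabled = TRUE,
                          n_select = 5, cluster_threshold = 0.6) {
  if (any(x_grid <= 0) || is.unsorted(x_grid, strictly = TRUE))
    stop("x_grid must be strictly increasing and positive")
  if (models_per_x < 1) stop("models_per_x must be >= 1")
  if (!is.null(anneal_steps) && anneal_steps < 1)
    stop("anneal_steps must be >= 1")
  if (!(T_start >= T_end && T_end > 0))
    stop("need T_start >= T_end > 0")
  structure(list(x_grid = x_grid, models_per_x = models_per_x,
                 anneal_steps = anneal_steps, T_start = T_start,
                 T_end = T_end, step_size = step_size, seed = seed,
                 round2_enabled = round2_enabled, n_select = n_select,
                 cluster_threshold = cluster_threshold),
            class = "FoldingConfig")
}

.embed_bounds <- function(rs, L) {
  df <- rs@distances
  big <- 3.8 * (L - 1)
  lb <- matrix(3.5, L, L)
  ub <- matrix(big, L, L)
  idx <- seq_len(L)
  for (k in idx) {
    off <- abs(idx - k)
    ub[k, ] <- pmin(ub[k, ], 3.8 * off)
  }
  diag(lb) <- 0
  diag(ub) <- 0
  sub <- cbind(idx[-L], idx[-1])
  lb[sub] <- 3.8; lb[sub[, 2:1]] <- 3.8
  ub[sub] <- 3.8; ub[sub[, 2:1]] <- 3.8
  restrained <- matrix(FALSE, L, L)
  if (nrow(df)) {
    cb_slack <- ifelse(df$atom_i == "CB" | df$atom_j == "CB", 1.0, 0)
    rlb <- matrix(-Inf, L, L)
    rub <- matrix(Inf, L, L)
    for (k in seq_len(nrow(df))) {
      i <- df$i[k]; j <- df$j[k]
      if (df$lb[k] > df$ub[k])
        stop(sprintf("infeasible bounds for pair (%d,%d): lb %.2f > ub %.2f",
                     i, j, df$lb[k], df$ub[k]))
      lo <- max(2.5, df$lb[k] - cb_slack[k])
      hi <- df$ub[k] + cb_slack[k]
      rlb[i, j] <- rlb[j, i] <- max(rlb[i, j], lo)
      rub[i, j] <- rub[j, i] <- min(rub[i, j], hi)
      restrained[i, j] <- restrained[j, i] <- TRUE
    }
    # restraints replace the generic chain defaults on their pairs
    lb[restrained] <- pmin(rlb[restrained], rub[restrained])
    ub[restrained] <- rub[restrained]
  }
  # triangle-inequality smoothing of upper bounds
  for (k in idx) {
    uk <- ub[, k]
    cand <- outer(uk, ub[k, ], "+")
    ub <- pmin(ub, cand)
  }
  bad <- which(lb > ub + 1e-9 & upper.tri(lb), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("infeasible bounds after smoothing for pair (%d,%d)",
                 bad[1, 1], bad[1, 2]))
  list(lb = lb, ub = ub, restrained = restrained)
}

.helix_anchors <- function(rs) {
  tt <- rs@torsions
  if (!nrow(tt)) return(integer())
  phi <- tt[tt$angle == "phi", , drop = FALSE]
  sort(unique(phi$residue[abs(phi$target + 57) < 15]))
}

#' Metric-matrix distance-geometry embedding
#'
#' Builds a full distance matrix from the restraint bounds (restrained pairs
#' at their interval midpoint, chain neighbours at 3.8 Angstrom, all other
#' pairs drawn uniformly from their triangle-smoothed bounds), embeds it by
#' classical metric-matrix scaling (top three eigenvectors) and fixes
#' chirality so that the mean CA pseudo-torsion over helix-restrained
#' residues (or over the whole chain when no helix restraints exist) is
#' non-negative. Deterministic given `seed`.
#'
#' @param rs a [RestraintSet-class] with at least one distance restraint.
#' @param L chain length (>= 8).
#' @param seed integer seed for the metrization draw.
#' @param sequence optional amino-acid sequence (defaults to poly-alanine).
#' @return a coarse-grained (CA + pseudo-CB) [StructureModel-class].
#' @export
embedDistanceGeometry <- function(rs, L, seed, sequence = NULL) {
  if (!nrow(rs@distances)) stop("restraint set has no distance restraints")
  if (L < 8) stop("L must be >= 8")
  if (is.null(sequence)) sequence <- strrep("A", L)
  b <- .embed_bounds(rs, L)
  set.seed(seed)
  u <- matrix(runif(L * L), L, L)
  u[lower.tri(u)] <- t(u)[lower.tri(u)]
  D <- ifelse(b$restrained, (b$lb + b$ub) / 2, b$lb + u * (b$ub - b$lb))
  D[abs(row(D) - col(D)) == 1] <- 3.8
  diag(D) <- 0
  D2 <- D^2
  J <- diag(L) - matrix(1 / L, L, L)
  G <- -0.5 * J %*% D2 %*% J
  eg <- eigen(G, symmetric = TRUE)
  ev <- pmax(eg$values[1:3], 0)
  X <- eg$vectors[, 1:3, drop = FALSE] %*% diag(sqrt(ev), 3)
  anchors <- .helix_anchors(rs)
  tor <- caPseudoTorsions(X)
  ref <- if (length(anchors)) {
    mean(tor[anchors[anchors >= 2 & anchors <= L - 2]], na.rm = TRUE)
  } else mean(tor, na.rm = TRUE)
  if (is.finite(ref) && ref < 0) X[, 3] <- -X[, 3]
  StructureModel(sprintf("embed_s%d", seed), sequence, X)
}

.anneal_inputs <- function(model, rs) {
  L <- nres(model)
  df <- rs@distances
  gly <- strsplit(aaSequence(model), "")[[1]] == "G"
  keep <- df$atom_i %in% c("CA", "CB") & df$atom_j %in% c("CA", "CB")
  df <- df[keep, , drop = FALSE]
  cbi <- as.integer(df$atom_i == "CB" & !gly[df$i])
  cbj <- as.integer(df$atom_j == "CB" & !gly[df$j])
  tt <- rs@torsions
  tor <- data.frame(idx = integer(), target = numeric(), tol = numeric(),
                    weight = numeric())
  if (nrow(tt)) {
    phi <- tt[tt$angle == "phi", , drop = FALSE]
    cls <- ifelse(abs(phi$target + 57) < 15, "H", "E")
    keep_t <- phi$residue >= 2 & phi$residue <= L - 2
    tor <- data.frame(
      idx = phi$residue[keep_t],
      target = ifelse(cls[keep_t] == "H", 50, -170),
      tol = ifelse(cls[keep_t] == "H", 20, 35),
      weight = phi$weight[keep_t])
  }
  list(df = df, cbi = cbi, cbj = cbj, tor = tor)
}

#' Simulated annealing refinement against a restraint set
#'
#' Metropolis annealing over single-residue Cartesian perturbations of the
#' CA trace. The objective sums weighted [boundedPotential()] terms for all
#' CA/CB distance restraints (CB evaluated at pseudo-CB positions rebuilt
#' from the CA geometry), a chain-bond term (3.8 +/- 0.1 Angstrom), CA
#' pseudo-torsion penalties derived from the phi/psi restraints (helix
#' +50 deg, strand -170 deg) and a soft-sphere clash term. The best-energy
#' snapshot is returned; with `T_start == T_end` the schedule degenerates to
#' greedy descent. Deterministic given `seed`.
#'
#' @param model starting [StructureModel-class] (CA required).
#' @param rs a [RestraintSet-class].
#' @param config a [foldingConfig()] list.
#' @param seed integer seed.
#' @return the refined StructureModel with attribute `energy` (best total
#'   energy) and `acceptance` (acceptance rate).
#' @export
annealModel <- function(model, rs, config = foldingConfig(), seed = 1) {
  L <- nres(model)
  ai <- .anneal_inputs(model, rs)
  steps <- config$anneal_steps
  if (is.null(steps)) steps <- min(20000 * L, 2e6)
  set.seed(seed)
  res <- .anneal_cpp(caCoords(model), ai$df$i, ai$df$j, ai$cbi, ai$cbj,
                     ai$df$lb, ai$df$ub, ai$df$sd, ai$df$weight,
                     ai$tor$idx, ai$tor$target, ai$tor$tol, ai$tor$weight,
                     as.integer(steps), config$T_start, config$T_end,
                     config$step_size, 5.0, 2.0, 1.0)
  out <- StructureModel(modelId(model), aaSequence(model), res$coords)
  attr(out, "energy") <- res$energy
  attr(out, "acceptance") <- res$acceptance
  out
}

.derive_seed <- function(base, ...) {
  parts <- c(base, unlist(list(...)))
  as.integer(sum(parts * seq_along(parts) * 7919) %% 2147483629L)
}

.build_round_restraints <- function(contacts, ssr, sequence, x, L,
                                    prune_keep = NULL, extra = NULL,
                                    round = 1L) {
  sel <- selectTopContacts(contacts, x, L)
  cr <- contactsToRestraints(sel, sequence)
  if (!is.null(prune_keep) && nrow(cr))
    cr <- cr[paste(cr$i, cr$j) %in% prune_keep, , drop = FALSE]
  dist <- mergeRestraints(cr, if (is.null(extra)) emptyDistanceRestraints()
                          else extra, ssr@distances)
  RestraintSet(distances = dist, torsions = ssr@torsions,
               meta = list(x = x, round = round))
}

#' Two-round contact-driven folding protocol
#'
#' Round 1: for every ratio `x` in the grid, the top `x * L` contacts are
#' translated into CB-level distance restraints, merged with the
#' secondary-structure restraints, embedded by distance geometry and refined
#' by simulated annealing (`models_per_x` decoys per ratio). Round 2 (when
#' enabled): beta-strand pairings are detected on the round-1 cluster
#' representatives, contact restraints unrealized in at least half of the
#' representatives are pruned, strand-pairing restraints are added, and
#' embedding plus annealing is repeated. The returned pool is the union of
#' both rounds with per-decoy provenance.
#'
#' @param contacts predicted contacts (data.frame i, j, p).
#' @param ss predicted 3-state secondary-structure string.
#' @param sequence amino-acid sequence.
#' @param config a [foldingConfig()].
#' @return a [DecoySet-class].
#' @export
confold2Fold <- function(contacts, ss, sequence, config = foldingConfig()) {
  L <- nchar(sequence)
  ssr <- ssToRestraints(ss, sequence)
  models <- list()
  prov <- list()
  add_decoy <- function(m, x, round, seed, energy) {
    models[[length(models) + 1L]] <<- m
    prov[[length(prov) + 1L]] <<- data.frame(
      model_id = modelId(m), x = x, round = round, seed = seed,
      energy = energy)
  }
  run_round <- function(round, prune_keep = NULL, extra = NULL) {
    for (x in config$x_grid) {
      rs <- .build_round_restraints(contacts, ssr, sequence, x, L,
                                    prune_keep, extra, round)
      if (!nrow(rs@distances)) next
      for (m in seq_len(config$models_per_x)) {
        sd_m <- .derive_seed(config$seed, round * 1000, round(x * 10), m)
        emb <- embedDistanceGeometry(rs, L, sd_m, sequence)
        dec <- annealModel(emb, rs, config, sd_m + 1L)
        dec@modelId <- sprintf("r%d_x%s_m%d", round, format(x), m)
        add_decoy(dec, x, round, sd_m, attr(dec, "energy"))
      }
    }
  }
  run_round(1L)
  if (config$round2_enabled && length(models)) {
    r1 <- DecoySet(models, do.call(rbind, prov))
    sel <- clusterAndSelect(r1, n_select = min(config$n_select, length(models)),
                            threshold = config$cluster_threshold)
    reps <- sel$models
    pairings <- detectBetaPairings(reps)
    extra <- betaPairingRestraints(pairings)
    # prune contact restraints unrealized in >= half of the representatives
    all_cr <- contactsToRestraints(
      selectTopContacts(contacts, max(config$x_grid), L), sequence)
    if (nrow(all_cr)) {
      cr_set <- RestraintSet(distances = all_cr)
      unreal <- vapply(reps, function(rmod) {
        s <- restraintSatisfaction(rmod, cr_set)
        paste(all_cr$i, all_cr$j) %in%
          paste(s$unrealized$i, s$unrealized$j)
      }, logical(nrow(all_cr)))
      unreal <- matrix(unreal, nrow = nrow(all_cr))
      frac_unreal <- rowMeans(unreal)
      prune_keep <- paste(all_cr$i, all_cr$j)[frac_unreal < 0.5]
    } else prune_keep <- character()
    run_round(2L, prune_keep = prune_keep, extra = extra)
  }
  DecoySet(models, do.call(rbind, prov))
}

#' Greedy TM-score clustering and representative selection
#'
#' Greedy clustering at a TM-score threshold: the model with most neighbours
#' above the threshold seeds the first (largest) cluster, its members are
#' removed, and the scan repeats. Each cluster's representative is the
#' member with the lowest restraint-satisfaction energy recorded in the
#' decoy provenance (the cluster centre when no energies are available).
#' Representatives are returned ordered by cluster size; no padding when
#' fewer clusters than `n_select` exist.
#'
#' @param decoys a [DecoySet-class] (or list of StructureModels).
#' @param n_select maximum number of representatives to return (>= 1).
#' @param threshold TM-score clustering threshold (default 0.6).
#' @return list with `models` (representatives), `clusters` (list of integer
#'   index vectors into the input pool) and `sizes`.
#' @export
clusterAndSelect <- function(decoys, n_select = 5, threshold = 0.6) {
  if (n_select < 1) stop("n_select must be >= 1")
  if (is(decoys, "DecoySet")) {
    models <- decoyModels(decoys)
    energies <- decoyProvenance(decoys)$energy
  } else {
    models <- decoys
    energies <- rep(NA_real_, length(models))
  }
  n <- length(models)
  if (!n) stop("empty decoy pool")
  if (n == 1L)
    return(list(models = models, clusters = list(1L), sizes = 1L))
  L <- nres(models[[1]])
  M <- .tm_matrix_cpp(lapply(models, caCoords), tmD0(L))
  remaining <- seq_len(n)
  clusters <- list()
  while (length(remaining)) {
    sub <- M[remaining, remaining, drop = FALSE]
    counts <- rowSums(sub > threshold)
    centre <- remaining[which.max(counts)]
    memb <- remaining[M[centre, remaining] > threshold]
    if (!length(memb)) memb <- centre
    clusters[[length(clusters) + 1L]] <- memb
    remaining <- setdiff(remaining, memb)
  }
  sizes <- lengths(clusters)
  ord <- order(-sizes)
  clusters <- clusters[ord]
  sizes <- sizes[ord]
  reps <- lapply(clusters, function(idx) {
    if (all(is.na(energies[idx]))) idx[1]
    else idx[which.min(energies[idx])]
  })
  keep <- seq_len(min(n_select, length(clusters)))
  list(models = lapply(unlist(reps[keep]), function(i) models[[i]]),
       clusters = clusters, sizes = sizes)
}
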