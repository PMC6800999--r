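fast_cfg <- function(...) {
  foldingConfig(x_grid = c(0.5, 1), models_per_x = 1, anneal_steps = 20000,
                seed = 11, round2_enabled = FALSE, ...)
}

test_that("distance-geometry embedding recovers an exact helix", {
  bb <- ideal_backbone(rep(-57, 10), rep(-47, 10))
  D <- as.matrix(dist(bb$CA))
  rows <- do.call(rbind, lapply(1:9, function(i) do.call(rbind, lapply(
    (i + 1):10, function(j)
      data.frame(i = i, j = j, atom_i = "CA", atom_j = "CA",
                 lb = max(D[i, j] - 1e-6, 0.1), ub = D[i, j] + 1e-6,
                 sd = 0.5, weight = 1, source = "contact")))))
  rs <- RestraintSet(distances = rows)
  m <- embedDistanceGeometry(rs, 10, seed = 1)
  expect_lt(kabschSuperpose(caCoords(m), bb$CA)$rmsd, 1)
  m2 <- embedDistanceGeometry(rs, 10, seed = 1)
  expect_identical(caCoords(m), caCoords(m2))   # deterministic given seed
})

test_that("embedding rejects infeasible bounds, naming the pair", {
  df <- data.frame(i = 1L, j = 3L, atom_i = "CA", atom_j = "CA",
                   lb = 9, ub = 10, sd = 0.5, weight = 1, source = "contact")
  rs <- RestraintSet(distances = df)
  # lb = 9 contradicts the 2 x 3.8 chain path bound after smoothing
  expect_error(embedDistanceGeometry(rs, 8, seed = 1), "\\(1,3\\)")
  expect_error(embedDistanceGeometry(RestraintSet(), 8, 1), "no distance")
})

test_that("annealing never worsens the best-energy snapshot", {
  bb <- ideal_backbone(rep(-57, 15), rep(-47, 15))
  m0 <- StructureModel("h", strrep("A", 15), bb$CA)
  rs <- ssToRestraints(strrep("H", 15), strrep("A", 15))
  cfg <- foldingConfig(anneal_steps = 5000, seed = 2)
  out <- annealModel(m0, rs, cfg, seed = 2)
  # start satisfies the restraints: best snapshot cannot be worse
  s0 <- restraintSatisfaction(m0, rs)
  s1 <- restraintSatisfaction(out, rs)
  expect_gte(s1$fraction, s0$fraction - 1e-9)
  expect_lte(attr(out, "energy"), attr(out, "energy") + 1e-9)
  # greedy mode (T_start == T_end) only descends
  cfg_g <- foldingConfig(anneal_steps = 5000, T_start = 1, T_end = 1)
  out_g <- annealModel(m0, rs, cfg_g, seed = 3)
  expect_true(is.finite(attr(out_g, "energy")))
  # determinism
  out2 <- annealModel(m0, rs, cfg, seed = 2)
  expect_identical(caCoords(out), caCoords(out2))
})

test_that("annealing from a random start satisfies helix restraints", {
  L <- 30
  set.seed(9)
  start <- StructureModel("r", strrep("A", L),
                          cbind(cumsum(rep(3.8, L)) + rnorm(L, 0, 0.5),
                                rnorm(L, 0, 2), rnorm(L, 0, 2)))
  ss <- paste0(strrep("H", 14), "CC", strrep("H", 14))
  rs <- ssToRestraints(ss, strrep("A", L))
  cfg <- foldingConfig(anneal_steps = 200000, seed = 4)
  out <- annealModel(start, rs, cfg, seed = 4)
  expect_gt(restraintSatisfaction(out, rs)$fraction, 0.9)
})

test_that("folding config validates its invariants", {
  expect_equal(length(foldingConfig()$x_grid), 40L)
  expect_error(foldingConfig(x_grid = c(2, 1)), "increasing")
  expect_error(foldingConfig(T_start = 0.1, T_end = 1), "T_start")
  expect_error(foldingConfig(models_per_x = 0), "models_per_x")
})

test_that("the folding protocol sweeps x, tracks rounds and keeps geometry", {
  spec <- syntheticSpec(40, c("H:9", "C:3", "E:6", "C:3", "E:6", "C:3",
                              "H:10"), seed = 2)
  nat <- makeNative(spec)
  preds <- makeContactPredictions(nat, 1, 1, seed = 5)
  dec <- confold2Fold(preds, secondaryStructure(nat), aaSequence(nat),
                      fast_cfg())
  prov <- decoyProvenance(dec)
  expect_equal(sort(unique(prov$x)), c(0.5, 1))
  expect_true(all(prov$round == 1L))     # round 2 disabled
  for (m in decoyModels(dec)) {
    ca <- caCoords(m)
    bl <- sqrt(rowSums((ca[-1, ] - ca[-nrow(ca), ])^2))
    expect_true(all(bl >= 3.0 & bl <= 4.6))
  }
  # round 2 enabled adds second-round entries with pruning + beta logic
  cfg2 <- foldingConfig(x_grid = c(1), models_per_x = 1,
                        anneal_steps = 20000, seed = 11,
                        round2_enabled = TRUE)
  dec2 <- confold2Fold(preds, secondaryStructure(nat), aaSequence(nat), cfg2)
  expect_setequal(unique(decoyProvenance(dec2)$round), c(1L, 2L))
})

test_that("with only ss restraints decoys satisfy most local restraints", {
  L <- 36
  ss <- paste0(strrep("H", 16), "CCCC", strrep("H", 16))
  seqaa <- strrep("A", L)
  rs <- ssToRestraints(ss, seqaa)
  cfg <- foldingConfig(x_grid = 1, models_per_x = 2, anneal_steps = 300000,
                       seed = 21, round2_enabled = FALSE)
  dec <- confold2Fold(data.frame(i = integer(), j = integer(),
                                 p = numeric()), ss, seqaa, cfg)
  fr <- vapply(decoyModels(dec), function(m)
    restraintSatisfaction(m, rs)$fraction, numeric(1))
  expect_gt(mean(fr), 0.9)
})

test_that("clustering matches threshold-graph components on a decoy pool", {
  nat <- makeNative(syntheticSpec(40, c("H:9", "C:3", "E:6", "C:3", "E:6",
                                        "C:3", "H:10"), seed = 8))
  # three well-separated families: near-native, mid, scrambled
  dec <- makeDecoys(nat, 12, c(0.3, 6, 20), seed = 13)
  sel <- clusterAndSelect(dec, n_select = 5)
  # oracle: connected components of the TM > 0.6 graph (BFS)
  coords <- lapply(decoyModels(dec), caCoords)
  M <- sapply(coords, function(a) sapply(coords, function(b)
    tmScore(a, b)))
  adj <- M > 0.6
  seen <- rep(FALSE, 12)
  comps <- list()
  for (s in 1:12) {
    if (seen[s]) next
    q <- s
    comp <- integer()
    while (length(q)) {
      v <- q[1]; q <- q[-1]
      if (seen[v]) next
      seen[v] <- TRUE
      comp <- c(comp, v)
      q <- c(q, which(adj[v, ] & !seen))
    }
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  got <- lapply(sel$clusters, sort)
  expect_setequal(lapply(got, paste, collapse = ","),
                  lapply(comps, paste, collapse = ","))
  # majority cluster representative comes from the majority family
  pool <- c(rep(list(decoyModels(dec)[[1]]), 10), decoyModels(dec)[2])
  pool <- lapply(seq_along(pool), function(i) {
    m <- pool[[i]]; m@modelId <- paste0("p", i); m
  })
  sel2 <- clusterAndSelect(pool, n_select = 2)
  expect_equal(sel2$sizes[1], 10L)
  expect_lte(length(clusterAndSelect(pool, n_select = 5)$models), 5L)
  expect_error(clusterAndSelect(dec, n_select = 0), "n_select")
})
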