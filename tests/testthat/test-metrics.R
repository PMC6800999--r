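test_that("Kabsch superposition handles rigid motions and excludes mirrors", {
  set.seed(1)
  a <- matrix(rnorm(30), 10, 3)
  fit <- kabschSuperpose(a, sweep(a, 2, c(5, 0, 0), "+"))
  expect_lt(fit$rmsd, 1e-9)
  fit2 <- kabschSuperpose(a, a)
  expect_equal(fit2$rotation, diag(3), tolerance = 1e-8)
  expect_equal(fit2$translation, c(0, 0, 0), tolerance = 1e-8)
  expect_true(abs(det(fit$rotation) - 1) < 1e-8)
  # mirror image of a chiral 4-point set cannot reach rmsd 0 under proper
  # rotations; no sampled proper rotation does better than the Kabsch fit
  chiral <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1.3, 0), c(0.2, 0.4, 1.7))
  mirror <- chiral %*% diag(c(1, 1, -1))
  fitm <- kabschSuperpose(chiral, mirror)
  expect_gt(fitm$rmsd, 0.1)
  set.seed(42)
  best_sampled <- Inf
  cm <- scale(chiral, scale = FALSE)
  mm <- scale(mirror, scale = FALSE)
  for (k in 1:2000) {
    R <- qr.Q(qr(matrix(rnorm(9), 3)))
    if (det(R) < 0) R[, 1] <- -R[, 1]
    best_sampled <- min(best_sampled,
                        sqrt(mean(rowSums((cm %*% t(R) - mm)^2))))
  }
  expect_lte(fitm$rmsd, best_sampled + 1e-9)
  expect_error(kabschSuperpose(a[1:2, ], a[1:2, ]), "3 points")
})

test_that("GDT-TS matches identity and the displaced-residue case", {
  m <- ideal_helix_model(12)
  expect_equal(gdtTS(m, m), 1.0)
  # 3 of 4 residues exactly superposable, 1 displaced far: every cutoff
  # fraction is 3/4 (checked against the exhaustive subset oracle)
  a <- rbind(c(0, 0, 0), c(3.8, 0, 0), c(7.6, 0, 0), c(11.4, 0, 0))
  b <- a
  b[4, ] <- b[4, ] + c(0, 100, 0)
  expect_equal(gdtFractions(a, b), rep(0.75, 4))
  expect_equal(gdtFractions(a, b), gdt_oracle(a, b))
  expect_equal(mean(gdt_oracle(a, b)), gdtTS(a, b))
})

test_that("GDT-TS equals the exhaustive oracle on small instances", {
  set.seed(7)
  for (rep in 1:3) {
    a <- matrix(runif(18, 0, 10), 6, 3)
    b <- a + matrix(rnorm(18, 0, c(0.2, 0.2, 3)[rep]), 6, 3)
    expect_equal(gdtFractions(a, b), gdt_oracle(a, b), tolerance = 1e-9)
  }
  # incoherently scattered points: no common rigid motion, score < 0.25
  set.seed(8)
  a <- matrix(runif(18, 0, 60), 6, 3)
  b <- matrix(runif(18, 0, 60), 6, 3) + 100
  expect_equal(gdtFractions(a, b, 8), gdt_oracle(a, b, 8), tolerance = 1e-9)
  expect_lt(gdtTS(a, b), 0.6)  # only trivial 3-point seeds can match
})

test_that("TM-score: identity, d0 formula, and fold classification", {
  m <- ideal_helix_model(21)
  expect_equal(tmScore(m, m), 1.0)
  expect_true(classifyFold(m, m))
  expect_equal(tmD0(21), 1.24 * 6^(1 / 3) - 1.8, tolerance = 1e-12)
  expect_equal(tmD0(21), 0.4531, tolerance = 1e-3)
  expect_error(tmD0(15), "L >= 16")
  # a scrambled chain scores below the 0.5 correct-fold threshold
  set.seed(3)
  bad <- StructureModel("bad", aaSequence(m),
                        matrix(runif(63, 0, 30), 21, 3))
  expect_lt(tmScore(bad, m), 0.5)
  expect_false(classifyFold(bad, m))
})

test_that("scores are invariant under rigid motion and symmetric", {
  spec <- syntheticSpec(40, c("H:9", "C:3", "E:6", "C:3", "E:6", "C:3",
                              "H:10"), seed = 2)
  nat <- makeNative(spec)
  dec <- decoyModels(makeDecoys(nat, 1, 4, seed = 5))[[1]]
  g0 <- gdtTS(dec, nat)
  t0 <- tmScore(dec, nat)
  for (s in 1:3) {
    moved <- apply_rigid(dec, seed = s)
    expect_equal(gdtTS(moved, nat), g0, tolerance = 1e-6)
    expect_equal(tmScore(moved, nat), t0, tolerance = 1e-6)
  }
  expect_equal(gdtTS(nat, dec), g0, tolerance = 1e-6)
  expect_equal(tmScore(nat, dec), t0, tolerance = 1e-6)
  # scores hit 1 only for congruent inputs
  expect_lt(gdtTS(dec, nat), 1)
  expect_equal(gdtTS(apply_rigid(nat, 9), nat), 1.0)
})

test_that("extractContacts applies the strict-< convention and separation", {
  ca <- rbind(c(0, 0, 0), c(3.8, 0, 0), c(7.6, 0, 0), c(11.4, 0, 0),
              c(15.2, 0, 0), c(19, 0, 0), c(22.8, 0, 0), c(26.6, 0, 0),
              c(30.4, 0, 0), c(34.2, 0, 0), c(38, 0, 0))
  # residues 1 and 11 are glycine-free; place CBs at controlled distance
  cb <- ca + 0.01
  cb[11, ] <- cb[1, ] + c(7.9, 0, 0)
  m <- StructureModel("t", strrep("A", 11), ca, cb = cb)
  got <- extractContacts(m, threshold = 8, min_separation = 10)
  expect_equal(nrow(got), 1L)
  expect_equal(c(got$i, got$j), c(1L, 11L))
  cb[11, ] <- cb[1, ] + c(8.0, 0, 0)   # exactly at the threshold: excluded
  m2 <- StructureModel("t", strrep("A", 11), ca, cb = cb)
  expect_equal(nrow(extractContacts(m2, 8, 10)), 0L)
  # glycine pairs are measured CA-CA
  seq_g <- paste0("G", strrep("A", 9), "G")
  cbg <- cb
  cbg[c(1, 11), ] <- NA
  mg <- StructureModel("t", seq_g, ca, cb = cbg)
  d_ca <- sqrt(sum((ca[1, ] - ca[11, ])^2))
  got_g <- extractContacts(mg, threshold = d_ca + 0.01, min_separation = 10)
  expect_equal(nrow(got_g), 1L)
})

test_that("extractContacts is monotone in the threshold", {
  nat <- makeNative(syntheticSpec(40, c("H:9", "C:3", "E:6", "C:3", "E:6",
                                        "C:3", "H:10"), seed = 4))
  prev <- NULL
  for (thr in c(6, 7.5, 8, 8.5, 10)) {
    cur <- paste(extractContacts(nat, thr, 6)$i,
                 extractContacts(nat, thr, 6)$j)
    if (!is.null(prev)) expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("assignSS labels ideal helices, paired strands and short chains", {
  h <- ideal_helix_model(20)
  ss <- strsplit(assignSS(h), "")[[1]]
  expect_gte(sum(ss == "H"), 16)
  hp <- hairpin_model(5)
  ssh <- strsplit(assignSS(hp), "")[[1]]
  expect_true(all(ssh[c(2:4, 10:12)] == "E"))
  short <- StructureModel("s", "AAA", rbind(c(0, 0, 0), c(3.8, 0, 0),
                                            c(7.6, 0, 0)))
  expect_equal(assignSS(short), "CCC")
})

test_that("pairwise consensus ranking equals the all-pairs mean", {
  nat <- makeNative(syntheticSpec(40, c("H:9", "C:3", "E:6", "C:3", "E:6",
                                        "C:3", "H:10"), seed = 6))
  pool <- decoyModels(makeDecoys(nat, 10, c(0.5, 2, 5, 9), seed = 3))
  rk <- pairwiseConsensusRank(pool)
  # brute-force double-loop oracle
  ids <- vapply(pool, modelId, character(1))
  oracle <- vapply(seq_along(pool), function(i)
    mean(vapply(seq_along(pool)[-i], function(j)
      gdtTS(pool[[i]], pool[[j]]), numeric(1))), numeric(1))
  expect_equal(rk$score[match(ids, rk$model_id)], oracle, tolerance = 1e-9)
  expect_true(all(diff(rk$score) <= 1e-12))
  # identical models all score 1
  same <- list(pool[[1]], pool[[1]], pool[[1]])
  same <- lapply(1:3, function(i) {
    m <- same[[i]]; m@modelId <- paste0("m", i); m
  })
  expect_equal(pairwiseConsensusRank(same)$score, rep(1, 3))
  # pool {A, A, B}: score(A) = (1 + g)/2, score(B) = g
  A <- pool[[1]]; B <- pool[[8]]
  g <- gdtTS(A, B)
  ab_pool <- list(A, A, B)
  ab_pool <- lapply(1:3, function(i) {
    m <- ab_pool[[i]]; m@modelId <- c("a1", "a2", "b")[i]; m
  })
  rk2 <- pairwiseConsensusRank(ab_pool)
  expect_equal(rk2$score[rk2$model_id == "b"], g, tolerance = 1e-9)
  expect_equal(rk2$score[rk2$model_id == "a1"], (1 + g) / 2,
               tolerance = 1e-9)
  expect_error(pairwiseConsensusRank(list(A)), "at least 2")
})
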