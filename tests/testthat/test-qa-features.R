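test_that("1D match scores are positional agreement fractions", {
  expect_equal(ssMatch("HHHH", "HHHH"), 1.0)
  expect_equal(ssMatch("HHHH", "HHHC"), 0.75)
  expect_error(ssMatch("", ""), "empty")
  expect_error(ssMatch("HH", "HHH"), "length")
  expect_equal(saMatch("BEBE", "BEBE"), 1.0)
  expect_equal(saMatch("BEBE", "EBEB"), 0.0)
  # independent random strings agree at chance level
  set.seed(31)
  a <- paste(sample(c("B", "E"), 1000, TRUE), collapse = "")
  b <- paste(sample(c("B", "E"), 1000, TRUE), collapse = "")
  expect_lt(abs(saMatch(a, b) - 0.5), 0.05)
})

test_that("contact-match features count realised top-L/5 predictions", {
  nat <- makeNative(syntheticSpec(40, c("H:9", "C:3", "E:6", "C:3", "E:6",
                                        "C:3", "H:10"), seed = 2))
  preds <- makeContactPredictions(nat, 1, 1, seed = 3)
  cf <- contactMatchFeatures(preds, nat)
  # noise-free predictions are all realised in the generating native
  sep <- preds$j - preds$i
  populated <- c(any(sep >= 6 & sep <= 11), any(sep >= 12 & sep <= 23),
                 any(sep >= 24))
  expect_true(all(cf[populated] == 1))
  expect_true(all(cf[!populated] == 0))
  expect_equal(attr(cf, "complete"), all(populated))
  # hand-counted fixture: known realised subset
  realised <- extractContacts(nat, 8, 6)
  fake <- data.frame(i = c(realised$i[1:3], 1, 1),
                     j = c(realised$j[1:3], 39, 40),
                     p = c(0.9, 0.8, 0.7, 0.6, 0.5))
  cf2 <- contactMatchFeatures(fake, nat)
  rkey <- paste(realised$i, realised$j)
  for (cls in list(c(6, 11, "f_con_short"), c(12, 23, "f_con_medium"),
                   c(24, Inf, "f_con_long"))) {
    sub <- fake[fake$j - fake$i >= as.numeric(cls[1]) &
                  fake$j - fake$i <= as.numeric(cls[2]), ]
    if (!nrow(sub)) next
    sub <- head(sub[order(-sub$p), ], ceiling(40 / 5))
    expect_equal(cf2[[cls[3]]], mean(paste(sub$i, sub$j) %in% rkey))
  }
})

test_that("contact features are invariant under rigid motion", {
  nat <- makeNative(syntheticSpec(40, c("H:9", "C:3", "E:6", "C:3", "E:6",
                                        "C:3", "H:10"), seed = 4))
  preds <- makeContactPredictions(nat, 0.8, 1, seed = 5)
  cf0 <- contactMatchFeatures(preds, nat)
  moved <- apply_rigid(nat, seed = 6)
  cf1 <- contactMatchFeatures(preds, moved)
  expect_equal(as.numeric(cf1), as.numeric(cf0), tolerance = 1e-9)
  expect_equal(solventExposure(moved), solventExposure(nat))
})

test_that("mean long/medium contact match decreases with decoy perturbation", {
  nat <- makeNative(syntheticSpec(48, c("E:6", "C:3", "E:6", "C:3", "H:11",
                                        "C:3", "E:8", "C:8"), seed = 3))
  preds <- makeContactPredictions(nat, 1, 1, seed = 4)
  mags <- c(1, 5, 15)
  means <- vapply(mags, function(m) {
    dec <- makeDecoys(nat, 6, m, seed = 40 + m)
    mean(vapply(decoyModels(dec), function(d) {
      cf <- contactMatchFeatures(preds, d)
      mean(cf[c("f_con_medium", "f_con_long")])
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) <= 0))
})

test_that("assembleFeatures builds per-model rows with normalised externals", {
  nat <- makeNative(syntheticSpec(40, c("H:9", "C:3", "E:6", "C:3", "E:6",
                                        "C:3", "H:10"), seed = 5))
  dec <- decoyModels(makeDecoys(nat, 3, c(1, 3), seed = 6))
  preds <- makeContactPredictions(nat, 0.8, 1, seed = 7)
  fv <- assembleFeatures(dec, secondaryStructure(nat), solventExposure(nat),
                         preds, target_id = "T1")
  expect_equal(nrow(fv), 3L)
  expect_setequal(featureColumns(fv),
                  c("f_ss", "f_sa", "f_con_short", "f_con_medium",
                    "f_con_long"))
  expect_true(all(vapply(featureColumns(fv), function(cn)
    all(fv[[cn]] >= 0 & fv[[cn]] <= 1), logical(1))))
  ext <- data.frame(target_id = "T1",
                    model_id = vapply(dec, modelId, character(1)),
                    s1 = c(10, 20, 30), s2 = c(0.5, NA, 0.7))
  fv2 <- assembleFeatures(dec, secondaryStructure(nat),
                          solventExposure(nat), preds, ext, "T1")
  expect_equal(fv2$s1, c(0, 0.5, 1))         # min-max normalisation
  expect_false(fv2$complete[2])              # imputed NA flags the row
  # row 1 keeps whatever the contact-feature completeness says (a class
  # with no predictions clears it)
  expect_equal(fv2$complete[1],
               attr(contactMatchFeatures(preds, dec[[1]]), "complete"))
  expect_error(assembleFeatures(list(), "H", "B", preds), "no models")
})
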