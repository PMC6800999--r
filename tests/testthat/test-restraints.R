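test_that("selectTopContacts takes round(x*L) by probability with stable ties", {
  set.seed(2)
  preds <- data.frame(i = 1:25, j = 31:55, p = runif(25))
  got <- selectTopContacts(preds, 0.2, 50)
  expect_equal(nrow(got), 10L)
  expect_equal(sort(got$p, decreasing = TRUE),
               sort(preds$p, decreasing = TRUE)[1:10])
  expect_equal(nrow(selectTopContacts(preds[1:5, ], 4, 50)), 5L)
  ties <- data.frame(i = c(9, 2, 2), j = c(20, 30, 21), p = 0.5)
  got2 <- selectTopContacts(ties, 2 / 50, 50)
  expect_equal(c(got2$i, got2$j), c(2, 2, 21, 30))
  expect_identical(got2, selectTopContacts(ties, 2 / 50, 50))
  expect_error(selectTopContacts(preds, 0, 50), "positive")
  for (x in c(0.1, 0.5, 1, 2.5, 4))
    expect_equal(nrow(selectTopContacts(preds, x, 50)),
                 min(round(x * 50), 25))
})

test_that("bounded potential reproduces all four printed branches", {
  expect_equal(boundedPotential(3.0), 1.0)        # ((3-3.5)/0.5)^2
  expect_equal(boundedPotential(5.0), 0)
  expect_equal(boundedPotential(3.5), 0)
  expect_equal(boundedPotential(8.0), 0)
  expect_equal(boundedPotential(8.2), 0.16)       # ((8.2-8)/0.5)^2
  expect_equal(boundedPotential(9.0), 2 * (9 - 8.25) + 0.25)
  # slope of the linear tail is 1/sd (finite differences)
  d <- seq(8.5, 12, by = 0.01)
  slopes <- diff(boundedPotential(d)) / 0.01
  expect_equal(slopes, rep(2, length(slopes)), tolerance = 1e-6)
  expect_error(boundedPotential(-1), "non-negative")
  expect_error(boundedPotential(5, lb = 9, ub = 8), "lb < ub")
})

test_that("bounded potential is continuous, flat on [lb,ub], rising outside", {
  # two-sided limits agree at every breakpoint
  for (b in c(3.5, 8, 8.25)) {
    expect_equal(boundedPotential(b - 1e-9), boundedPotential(b + 1e-9),
                 tolerance = 1e-6)
  }
  d <- seq(0, 15, by = 1e-3)
  f <- boundedPotential(d)
  expect_true(all(f[d >= 3.5 & d <= 8] == 0))
  inside_up <- diff(f[d > 8])
  expect_true(all(inside_up > 0))
  inside_dn <- diff(f[d < 3.5])
  expect_true(all(inside_dn < 0))
})

test_that("square-well potential matches the printed equation", {
  expect_equal(squareWellPotential(5, 0.9), -0.9)
  expect_equal(squareWellPotential(10, 1), -exp(-4) + 2 / 10)
  # continuity at d0 and the P = 0 degenerate case
  expect_equal(squareWellPotential(8 + 1e-9, 1), -1, tolerance = 1e-6)
  d <- seq(0, 15, by = 1e-3)
  expect_true(all(squareWellPotential(d, 0) == 0))
  f <- squareWellPotential(d, 0.7)
  expect_true(all(f[d < 8] == -0.7))
  expect_lt(max(abs(diff(f))), 0.01)
  expect_error(squareWellPotential(5, 1.5), "P must be")
})

test_that("contacts become CB restraints with the stated parameters", {
  contacts <- data.frame(i = c(2, 5, 5), j = c(40, 30, 30),
                         p = c(0.8, 0.6, 0.9))
  sequence <- strrep("A", 40)
  rs <- contactsToRestraints(contacts, sequence)
  expect_equal(nrow(rs), 2L)   # duplicate keeps max weight
  r1 <- rs[rs$i == 2, ]
  expect_equal(c(r1$lb, r1$ub, r1$sd), c(3.5, 8.0, 0.5))
  expect_equal(c(r1$atom_i, r1$atom_j), c("CB", "CB"))
  expect_equal(r1$weight, 0.8)
  expect_equal(rs$weight[rs$i == 5], 0.9)
  seq_g <- paste0("AG", strrep("A", 38))
  rg <- contactsToRestraints(data.frame(i = 2, j = 30, p = 0.5), seq_g)
  expect_equal(rg$atom_i, "CA")   # glycine end measured at CA
  expect_equal(rg$atom_j, "CB")
  expect_error(contactsToRestraints(data.frame(i = 2, j = 99, p = 0.5),
                                    sequence), "out of range")
})

test_that("secondary-structure restraints follow the emission rules", {
  expect_equal(nrow(ssToRestraints("CCCC", "AAAA")@distances), 0L)
  expect_equal(nrow(ssToRestraints("CCCC", "AAAA")@torsions), 0L)
  rs <- ssToRestraints("CHHHHHHCCC", strrep("A", 10))
  expect_equal(nrow(rs@torsions), 12L)     # phi+psi per helix residue
  expect_equal(nrow(rs@distances), 2L)     # i,i+4 pairs in a 6-residue run
  expect_equal(rs@distances$lb, c(5.4, 5.4))
  expect_equal(rs@distances$ub, c(6.4, 6.4))
  expect_true(all(rs@torsions$target %in% c(-57, -47)))
  rs_e <- ssToRestraints("EEEECCC", strrep("A", 7))
  expect_equal(nrow(rs_e@torsions), 8L)
  expect_true(all(rs_e@torsions$target %in% c(-120, 120)))
  expect_error(ssToRestraints("HH", "AAA"), "length")
  expect_error(ssToRestraints("HHX", "AAA"), "H,E,C")
})

test_that("restraint satisfaction uses inclusive bounds and reports violators", {
  ca <- cbind(seq(0, by = 3.8, length.out = 10), 0, 0)
  m <- StructureModel("chain", strrep("G", 10), ca)
  df <- data.frame(i = c(1, 1, 2), j = c(2, 3, 10),
                   atom_i = "CA", atom_j = "CA",
                   lb = c(3.5, 7.0, 3.5), ub = c(3.8, 8.0, 8.0),
                   sd = 0.5, weight = 1, source = "contact")
  rs <- RestraintSet(distances = df)
  got <- restraintSatisfaction(m, rs)
  # d(1,2)=3.8 satisfied at the boundary; d(1,3)=7.6 in; d(2,10)=30.4 out
  expect_equal(got$fraction, 2 / 3)
  expect_equal(nrow(got$unrealized), 1L)
  expect_equal(got$unrealized$j, 10)
  # brute-force recount oracle
  dmat <- as.matrix(dist(ca))
  sat <- mapply(function(i, j, lb, ub) dmat[i, j] >= lb & dmat[i, j] <= ub,
                df$i, df$j, df$lb, df$ub)
  expect_equal(got$fraction, mean(sat))
  rs_cb <- RestraintSet(distances = transform(df, atom_i = "CB"))
  expect_error(restraintSatisfaction(m, rs_cb), "missing restrained atom")
})

test_that("beta pairings are detected with orientation", {
  anti <- hairpin_model(5, parallel = FALSE)
  anti@ss <- assignSS(anti)
  got <- detectBetaPairings(list(anti))
  expect_equal(length(got), 1L)
  expect_equal(got[[1]]$orientation, "antiparallel")
  par <- hairpin_model(5, parallel = TRUE)
  par@ss <- assignSS(par)
  got_p <- detectBetaPairings(list(par))
  expect_equal(length(got_p), 1L)
  expect_equal(got_p[[1]]$orientation, "parallel")
  helix <- ideal_helix_model(20)
  helix@ss <- assignSS(helix)
  expect_equal(detectBetaPairings(list(helix)), list())
})

test_that("beta-pairing restraints follow the ladder emission rule", {
  anti <- hairpin_model(5)
  anti@ss <- assignSS(anti)
  pairings <- detectBetaPairings(list(anti))
  rs <- betaPairingRestraints(pairings)
  ca_rows <- rs[rs$atom_i == "CA", ]
  no_rows <- rs[rs$atom_i == "N", ]
  n_pairs <- nrow(pairings[[1]]$pairs)
  expect_equal(nrow(ca_rows), n_pairs)
  expect_equal(nrow(no_rows), ceiling(n_pairs / 2))
  expect_true(all(ca_rows$lb == 4.5 & ca_rows$ub == 5.5))
  expect_true(all(no_rows$lb == 2.6 & no_rows$ub == 3.2))
  expect_true(all(rs$source == "beta_pairing"))
  expect_equal(betaPairingRestraints(list()), emptyDistanceRestraints())
  # merging never duplicates an (i, j, atom) key
  merged <- mergeRestraints(rs, rs)
  expect_equal(nrow(merged), nrow(rs))
})
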