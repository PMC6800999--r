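# Shared fixtures, built in code at test time.

# Ideal-geometry backbone fragment from phi/psi (degrees); full backbone.
ideal_backbone <- function(phi, psi) {
  ContactFold:::.build_backbone(phi, psi)
}

ideal_helix_model <- function(n = 20, id = "helix") {
  bb <- ideal_backbone(rep(-57, n), rep(-47, n))
  StructureModel(id, strrep("A", n), bb$CA, cb = bb$CB, n = bb$N, c = bb$C)
}

# Two paired extended strands (antiparallel by default) as one chain with a
# connecting loop; returns a StructureModel with full backbone.
hairpin_model <- function(strand_len = 5, parallel = FALSE, id = "hairpin") {
  bb1 <- ideal_backbone(rep(-120, strand_len), rep(120, strand_len))
  # align strand 1 along +z with its pleat in the xy-plane
  axis <- bb1$CA[strand_len, ] - bb1$CA[1, ]
  R <- ContactFold:::.rot_align(axis, c(0, 0, 1))
  b1 <- lapply(bb1, function(m) m %*% t(R))
  off1 <- -b1$CA[1, ]
  b1 <- lapply(b1, function(m) sweep(m, 2, off1, "+"))
  # partner strand: a parallel partner is a pure translation; an
  # antiparallel partner is a proper 180-degree rotation about y, which
  # flips the chain direction while keeping the pleat in phase
  # partner strand: parallel is a pure translation; antiparallel tries the
  # two proper 180-degree flips (about x and about y) and picks the one
  # that registers best. The z-offset is optimised for a tight register.
  flips <- if (parallel) list(diag(3)) else
    list(diag(c(-1, 1, -1)), diag(c(1, -1, -1)))
  reg_cost <- function(ca2) {
    d <- sqrt(outer(rowSums(b1$CA^2), rowSums(ca2^2), "+") -
                2 * b1$CA %*% t(ca2))
    mean(apply(d, 1, min))
  }
  best <- NULL
  for (Rf in flips) {
    cand <- lapply(b1, function(m) m %*% t(Rf))
    z0 <- b1$CA[ceiling(strand_len / 2), 3] -
      cand$CA[ceiling(strand_len / 2), 3]
    for (dz in seq(-4, 4, by = 0.1)) {
      ca2 <- sweep(cand$CA, 2, c(4.8, 0, z0 + dz), "+")
      cost <- reg_cost(ca2)
      if (is.null(best) || cost < best$cost)
        best <- list(cost = cost, Rf = Rf, shift = c(4.8, 0, z0 + dz))
    }
  }
  b2 <- lapply(b1, function(m)
    sweep(m %*% t(best$Rf), 2, best$shift, "+"))
  P <- b1$CA[strand_len, ]
  Q <- b2$CA[1, ]
  chord <- sqrt(sum((Q - P)^2))
  loop_n <- max(3L, ceiling(chord / 3.8) + 1L)   # parallel needs a long loop
  loop <- ContactFold:::.loop_arc(P, Q, loop_n, c(0, 1, 0))
  L <- 2L * strand_len + loop_n
  CA <- rbind(b1$CA, loop, b2$CA)
  N <- rbind(b1$N, loop - 1.2, b2$N)
  C <- rbind(b1$C, loop + 1.2, b2$C)
  CB <- rbind(b1$CB, loop + 0.5, b2$CB)
  StructureModel(id, strrep("A", L), CA, cb = CB, n = N, c = C)
}

# Random rigid motion applied to a coordinate matrix (seeded by caller).
random_rigid <- function(xyz) {
  q <- matrix(rnorm(9), 3, 3)
  qr_R <- qr.Q(qr(q))
  if (det(qr_R) < 0) qr_R[, 1] <- -qr_R[, 1]
  sweep(xyz %*% t(qr_R), 2, runif(3, -20, 20), "+")
}

apply_rigid <- function(model, seed = 1) {
  set.seed(seed)
  q <- matrix(rnorm(9), 3, 3)
  R <- qr.Q(qr(q))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  tr <- runif(3, -20, 20)
  move <- function(m) if (is.null(m)) NULL else sweep(m %*% t(R), 2, tr, "+")
  StructureModel(modelId(model), aaSequence(model),
                 move(caCoords(model)), cb = move(cbCoords(model)),
                 n = move(atomCoords(model, "N")),
                 c = move(atomCoords(model, "C")),
                 ss = secondaryStructure(model))
}

# Exhaustive GDT oracle for tiny instances: maximise, over every subset of
# >= 3 residues used as the superposition set, the fraction of residues
# within the cutoff after that superposition.
gdt_oracle <- function(a, b, cutoffs = c(1, 2, 4, 8)) {
  L <- nrow(a)
  subsets <- unlist(lapply(3:L, function(k)
    utils::combn(L, k, simplify = FALSE)), recursive = FALSE)
  vapply(cutoffs, function(cut) {
    best <- 0
    for (ss in subsets) {
      fit <- kabschSuperpose(a[ss, , drop = FALSE], b[ss, , drop = FALSE])
      moved <- sweep(a %*% t(fit$rotation), 2, fit$translation, "+")
      d <- sqrt(rowSums((moved - b)^2))
      best <- max(best, mean(d <= cut + 1e-9))
    }
    best
  }, numeric(1))
}

# Minimal PDB text for a short peptide; coords is a list of per-residue
# named lists of atom -> xyz.
write_mini_pdb <- function(path, resnames, coords) {
  lines <- character()
  serial <- 0L
  for (i in seq_along(resnames)) {
    for (nm in names(coords[[i]])) {
      serial <- serial + 1L
      xyz <- coords[[i]][[nm]]
      lines <- c(lines, sprintf(
        "ATOM  %5d  %-3s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00",
        serial, nm, resnames[i], i, xyz[1], xyz[2], xyz[3]))
    }
  }
  writeLines(c(lines, "END"), path)
  path
}

toy_qa_noise <- function(...) {
  utils::modifyList(list(contact_precision = 0.8), list(...))
}
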