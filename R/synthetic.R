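# Synthetic fixture generators: ideal-geometry toy natives, graded decoys,
# precision-controlled contact predictions and full QA training datasets.
# Every generator is a pure function of its arguments and seed.

# --- internal: ideal backbone construction (NeRF) -------------------------

.BOND <- c(N_CA = 1.458, CA_C = 1.525, C_N = 1.329)
.ANGLE <- c(N_CA_C = 111.2, CA_C_N = 116.2, C_N_CA = 121.7)

.nerf_place <- function(a, b, c, bond, angle_deg, torsion_deg) {
  ang <- angle_deg * pi / 180
  tor <- torsion_deg * pi / 180
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2], ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2], n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- c(-bond * cos(ang), bond * sin(ang) * cos(tor),
          bond * sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

# Build an ideal-backbone fragment from phi/psi vectors; returns N, CA, C
# matrices (n x 3) and CB from the standard tetrahedral construction.
.build_backbone <- function(phi, psi, gly = NULL) {
  n <- length(phi)
  if (is.null(gly)) gly <- rep(FALSE, n)
  N <- CA <- C <- matrix(NA_real_, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(.BOND["N_CA"], 0, 0)
  ang <- .ANGLE["N_CA_C"] * pi / 180
  C[1, ] <- CA[1, ] + .BOND["CA_C"] * c(-cos(ang), sin(ang), 0)
  for (i in seq_len(n)[-1]) {
    N[i, ] <- .nerf_place(N[i - 1, ], CA[i - 1, ], C[i - 1, ],
                          .BOND["C_N"], .ANGLE["CA_C_N"], psi[i - 1])
    CA[i, ] <- .nerf_place(CA[i - 1, ], C[i - 1, ], N[i, ],
                           .BOND["N_CA"], .ANGLE["C_N_CA"], 180)
    C[i, ] <- .nerf_place(C[i - 1, ], N[i, ], CA[i, ],
                          .BOND["CA_C"], .ANGLE["N_CA_C"], phi[i])
  }
  CB <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    if (gly[i]) next
    b <- CA[i, ] - N[i, ]
    cc <- C[i, ] - CA[i, ]
    a <- c(b[2] * cc[3] - b[3] * cc[2], b[3] * cc[1] - b[1] * cc[3],
           b[1] * cc[2] - b[2] * cc[1])
    CB[i, ] <- -0.58273431 * a + 0.56802827 * b - 0.54067466 * cc + CA[i, ]
  }
  list(N = N, CA = CA, C = C, CB = CB)
}

.rot_align <- function(v, target) {
  # rotation matrix taking unit vector v onto unit vector target
  v <- v / sqrt(sum(v^2))
  target <- target / sqrt(sum(target^2))
  cr <- c(v[2] * target[3] - v[3] * target[2],
          v[3] * target[1] - v[1] * target[3],
          v[1] * target[2] - v[2] * target[1])
  s <- sqrt(sum(cr^2))
  cth <- sum(v * target)
  if (s < 1e-10) {
    if (cth > 0) return(diag(3))
    ref <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    axis <- c(v[2] * ref[3] - v[3] * ref[2], v[3] * ref[1] - v[1] * ref[3],
              v[1] * ref[2] - v[2] * ref[1])
    axis <- axis / sqrt(sum(axis^2))
    return(2 * outer(axis, axis) - diag(3))
  }
  K <- matrix(c(0, -cr[3], cr[2], cr[3], 0, -cr[1], -cr[2], cr[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + K + K %*% K * ((1 - cth) / s^2)
}

.parse_topology <- function(topology) {
  parts <- strsplit(topology, ":")
  data.frame(type = vapply(parts, `[`, "", 1),
             len = as.integer(vapply(parts, `[`, "", 2)))
}

#' Specification for a synthetic protein
#'
#' @param L chain length; must equal the sum of element lengths.
#' @param topology character vector of elements in chain order, each
#'   "H:len", "E:len" or "C:len" (helix, strand, coil/loop).
#' @param n_decoys default decoy count for [makeDecoys()].
#' @param quality_grid default perturbation magnitudes (Angstrom).
#' @param contact_precision,contact_coverage defaults for
#'   [makeContactPredictions()].
#' @param seed integer seed.
#' @return a validated list of class "SyntheticSpec".
#' @export
syntheticSpec <- function(L, topology, n_decoys = 20,
                          quality_grid = c(1, 3, 6, 10),
                          contact_precision = 1.0, contact_coverage = 2.0,
                          seed = 1) {
  el <- .parse_topology(topology)
  if (!all(el$type %in% c("H", "E", "C"))) stop("topology types must be H/E/C")
  if (sum(el$len) != L)
    stop("element lengths sum to ", sum(el$len), ", not L = ", L)
  if (contact_precision <= 0 || contact_precision > 1)
    stop("contact_precision must be in (0, 1]")
  structure(list(L = L, topology = topology, elements = el,
                 n_decoys = n_decoys, quality_grid = quality_grid,
                 contact_precision = contact_precision,
                 contact_coverage = contact_coverage, seed = seed),
            class = "SyntheticSpec")
}

.ss_string <- function(el) {
  paste(rep(el$type, el$len), collapse = "")
}

#' Build an ideal-geometry toy native structure
#'
#' Helices and strands are built with ideal backbone geometry
#' (phi/psi -57/-47 and -120/+120) and placed rigidly: strands side by side
#' 4.6 Angstrom apart with in-phase pleats forming a sheet, helices packed
#' on the sheet faces 7.6 Angstrom away, consecutive elements running in
#' alternating directions.
#' Coil elements become connecting loops laid out along circular arcs with
#' 3.8 Angstrom CA spacing. Placement is jittered and retried (deterministic
#' in the seed) until the chain is self-avoiding (no non-bonded CA pair
#' closer than 3.5 Angstrom); an error is raised if no feasible packing is
#' found.
#'
#' @param spec a [syntheticSpec()].
#' @return a [StructureModel-class] with full backbone for secondary
#'   structure elements and the true ss string attached.
#' @export
makeNative <- function(spec) {
  el <- spec$elements
  L <- spec$L
  ss <- .ss_string(el)
  seqaa <- strrep("A", L)
  for (attempt in seq_len(25L)) {
    set.seed(spec$seed + 1000L * (attempt - 1L))
    out <- try(.place_native(el, L), silent = TRUE)
    if (!inherits(out, "try-error")) {
      ca <- out$CA
      d <- as.matrix(stats::dist(ca))
      d[abs(row(d) - col(d)) <= 1] <- Inf
      if (min(d) >= 3.5) {
        m <- StructureModel("native", seqaa, ca, cb = out$CB,
                            n = out$N, c = out$C, ss = ss)
        return(m)
      }
    }
  }
  stop("no self-avoiding packing found for topology ",
       paste(spec$topology, collapse = ","))
}

.place_native <- function(el, L) {
  N <- CA <- C <- CB <- matrix(NA_real_, L, 3)
  struct_idx <- which(el$type %in% c("H", "E"))
  # slot layout: strands in a sheet (y = 0), helices on a layer at y = 10
  n_e <- 0L; n_h <- 0L
  dir_sign <- 1
  prev_e_res <- integer()
  starts <- cumsum(c(1L, el$len[-nrow(el)]))
  for (k in seq_len(nrow(el))) {
    len <- el$len[k]
    idx <- starts[k]:(starts[k] + len - 1L)
    type <- el$type[k]
    if (type == "C") next
    if (type == "H") {
      bb <- .build_backbone(rep(-57, len), rep(-47, len))
      n_h <- n_h + 1L
      # helices pack on alternating faces of the sheet, centred over it
      side <- if (n_h %% 2L == 1L) 1 else -1
      n_strands <- sum(el$type == "E")
      sheet_mid <- max(0, (n_strands - 1)) * 4.6 / 2
      x0 <- c(sheet_mid + ((n_h - 1L) %/% 2L) * 8.6 + runif(1, -1.2, 1.2),
              side * (7.6 + runif(1, -0.5, 0.5)), 0)
    } else {
      bb <- .build_backbone(rep(-120, len), rep(120, len))
      n_e <- n_e + 1L
      x0 <- c((n_e - 1) * 4.6 + runif(1, -0.3, 0.3), runif(1, -0.5, 0.5), 0)
    }
    axis <- bb$CA[len, ] - bb$CA[1, ]
    R <- .rot_align(axis, c(0, 0, dir_sign))
    if (type == "E") {
      # spin the strand about its axis so the backbone pleat points out of
      # the sheet plane (y), keeping adjacent strands 4.6 A apart laterally
      ca_r0 <- bb$CA %*% t(R)
      resid <- sweep(ca_r0[, 1:2, drop = FALSE], 2,
                     colMeans(ca_r0[, 1:2, drop = FALSE]), "-")
      pc <- eigen(crossprod(resid))$vectors[, 1]
      th <- pi / 2 - atan2(pc[2], pc[1])
      S <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
                  3, 3, byrow = TRUE)
      R <- S %*% R
    }
    span <- sqrt(sum(axis^2))
    z0 <- if (dir_sign > 0) 0 else span
    shift <- c(x0[1], x0[2], z0)
    if (type == "E" && n_e >= 2L && length(prev_e_res)) {
      # choose the pleat phase in-phase with the previous strand (real
      # sheets pleat together): of the two spins 180 deg apart, keep the
      # one whose closest approach to the previous strand is larger
      flipZ <- diag(c(-1, -1, 1))
      cand <- list(R, flipZ %*% R)
      score <- vapply(cand, function(Rc) {
        ca_c <- bb$CA %*% t(Rc)
        ca_c <- sweep(ca_c, 2, shift - ca_c[1, ], "+")
        min(as.matrix(stats::dist(rbind(ca_c, CA[prev_e_res, ])))[
          seq_len(len), len + seq_along(prev_e_res)])
      }, numeric(1))
      R <- cand[[which.max(score)]]
    }
    # anchor: first CA at shift, axis along +/- z
    ca_r <- bb$CA %*% t(R)
    off <- shift - ca_r[1, ]
    place <- function(m) sweep(m %*% t(R), 2, off, "+")
    N[idx, ] <- place(bb$N)
    CA[idx, ] <- place(bb$CA)
    C[idx, ] <- place(bb$C)
    CB[idx, ] <- place(bb$CB)
    if (type == "E") prev_e_res <- idx
    dir_sign <- -dir_sign
  }
  # loops: circular arcs between placed neighbours (and free ends)
  for (k in seq_len(nrow(el))) {
    if (el$type[k] != "C") next
    len <- el$len[k]
    idx <- starts[k]:(starts[k] + len - 1L)
    pre <- if (k > 1L) starts[k] - 1L else NA
    post <- if (k < nrow(el)) starts[k] + len else NA
    if (is.na(pre)) {
      # N-terminal tail: step backwards from the first placed residue
      v <- CA[post, ] - CA[post + 1L, ]
      v <- v / sqrt(sum(v^2))
      pos <- CA[post, ]
      for (t in rev(seq_along(idx))) {
        stp <- v + runif(3, -0.08, 0.08)
        pos <- pos + 3.8 * stp / sqrt(sum(stp^2))
        CA[idx[t], ] <- pos
      }
    } else if (is.na(post)) {
      v <- CA[pre, ] - CA[pre - 1L, ]
      v <- v / sqrt(sum(v^2))
      pos <- CA[pre, ]
      for (t in seq_along(idx)) {
        stp <- v + runif(3, -0.08, 0.08)
        pos <- pos + 3.8 * stp / sqrt(sum(stp^2))
        CA[idx[t], ] <- pos
      }
    } else {
      CA[idx, ] <- .loop_arc(CA[pre, ], CA[post, ], len,
                             bulge_hint = CA[pre, ] - colMeans(CA, na.rm = TRUE))
    }
  }
  # approximate backbone for loop residues from the CA tangent so that
  # phi/psi are defined everywhere (loops are coil; exact values irrelevant)
  for (i in which(!stats::complete.cases(N))) {
    tgt <- if (i < L) CA[i + 1L, ] - CA[i, ] else CA[i, ] - CA[i - 1L, ]
    tgt <- tgt / sqrt(sum(tgt^2))
    N[i, ] <- CA[i, ] - 1.458 * tgt
    C[i, ] <- CA[i, ] + 1.525 * tgt
  }
  cbp <- .pseudo_cb_cpp(CA)
  miss <- !stats::complete.cases(CB)
  CB[miss, ] <- cbp[miss, ]
  list(N = N, CA = CA, C = C, CB = CB)
}

.loop_arc <- function(P, Q, n, bulge_hint) {
  chord <- sqrt(sum((Q - P)^2))
  s <- 3.8 * (n + 1)
  if (s < chord) stop("loop of ", n, " residues cannot span ", round(chord, 1),
                      " Angstrom")
  # solve sin(a/2)/(a/2) = chord/s for the arc angle a
  f <- function(a) sin(a / 2) / (a / 2) - chord / s
  a <- if (f(1e-6) * f(2 * pi - 1e-6) < 0)
    stats::uniroot(f, c(1e-6, 2 * pi - 1e-6))$root else 1e-6
  R <- s / a
  u <- (Q - P) / chord
  w <- bulge_hint - sum(bulge_hint * u) * u
  if (sqrt(sum(w^2)) < 1e-8) {
    w <- c(u[2], -u[1], 0)
    if (sqrt(sum(w^2)) < 1e-8) w <- c(0, u[3], -u[2])
  }
  w <- w / sqrt(sum(w^2))
  mid <- (P + Q) / 2
  h <- R * cos(a / 2)
  centre <- mid - h * w
  vP <- P - centre
  vQ <- Q - centre
  # rotation axis: sweep vP onto vQ through the arc of angle a (the major
  # arc when a > pi); verified numerically and flipped if needed
  axis <- c(vP[2] * vQ[3] - vP[3] * vQ[2], vP[3] * vQ[1] - vP[1] * vQ[3],
            vP[1] * vQ[2] - vP[2] * vQ[1])
  if (sqrt(sum(axis^2)) < 1e-8)
    axis <- c(u[2] * w[3] - u[3] * w[2], u[3] * w[1] - u[1] * w[3],
              u[1] * w[2] - u[2] * w[1])
  axis <- axis / sqrt(sum(axis^2))
  if (a > pi) axis <- -axis
  rodrigues <- function(axis, th) {
    K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                  -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
    diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
  }
  err_fwd <- sqrt(sum((as.numeric(rodrigues(axis, a) %*% vP) - vQ)^2))
  err_rev <- sqrt(sum((as.numeric(rodrigues(-axis, a) %*% vP) - vQ)^2))
  if (err_rev < err_fwd) axis <- -axis
  out <- matrix(NA_real_, n, 3)
  for (t in seq_len(n)) {
    th <- a * t / (n + 1)
    out[t, ] <- centre + as.numeric(rodrigues(axis, th) %*% vP)
  }
  out
}

# Hinge + correlated-jitter perturbation of a CA trace; uses caller's RNG.
.perturb_ca <- function(ca0, hinge_deg_sd, jitter_sd) {
  L <- nrow(ca0)
  ca <- ca0
  if (hinge_deg_sd > 0) {
    for (h in seq_len(sample(1:2, 1))) {
      hinge <- sample(5:(L - 5), 1)
      axis <- rnorm(3)
      axis <- axis / sqrt(sum(axis^2))
      ang <- rnorm(1, 0, hinge_deg_sd) * pi / 180
      K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                    -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
      Rm <- diag(3) + sin(ang) * K + (1 - cos(ang)) * K %*% K
      pivot <- ca[hinge, ]
      seg <- (hinge + 1L):L
      ca[seg, ] <- sweep(sweep(ca[seg, , drop = FALSE], 2, pivot, "-") %*%
                           t(Rm), 2, pivot, "+")
    }
  }
  if (jitter_sd > 0) {
    eps <- matrix(0, L, 3)
    for (cc in 1:3) {
      e <- rnorm(L, 0, jitter_sd)
      eps[, cc] <- as.numeric(stats::filter(e, 0.85, method = "recursive"))
    }
    ca <- ca + eps * sqrt(1 - 0.85^2)
  }
  ca
}

# Topology-breaker decoy: a large hinge rotation with minimal jitter --
# a model whose secondary-structure elements are individually intact but
# whose global fold is wrong. Local 1D features and locally-biased 3D
# scores cannot distinguish such models from good ones; contact-match
# features can, because contacts across the hinge are destroyed. Uses the
# caller's RNG.
.break_topology_ca <- function(native) {
  ca <- caCoords(native)
  L <- nrow(ca)
  # single hinge in the middle third so the rotation always reorients one
  # half of the fold relative to the other
  h <- sample(floor(L / 3):ceiling(2 * L / 3), 1)
  axis <- rnorm(3)
  axis <- axis / sqrt(sum(axis^2))
  ang <- sample(c(-1, 1), 1) * (22 + runif(1, 0, 10)) * pi / 180
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  Rm <- diag(3) + sin(ang) * K + (1 - cos(ang)) * K %*% K
  pivot <- ca[h, ]
  seg <- (h + 1L):L
  ca[seg, ] <- sweep(sweep(ca[seg, , drop = FALSE], 2, pivot, "-") %*%
                       t(Rm), 2, pivot, "+")
  ca + matrix(rnorm(length(ca), 0, 0.2), L, 3)
}

#' Generate graded decoys from a native structure
#'
#' Each decoy applies one or two random hinge rotations (angle scale
#' proportional to the magnitude) plus serially correlated Gaussian jitter
#' to the native CA trace, so decoys keep realistic partially correct
#' substructure. True labels are the GDT-TS of each decoy against the
#' native; mean label decreases with magnitude. Magnitude 0 reproduces the
#' native exactly.
#'
#' @param native a [StructureModel-class].
#' @param n number of decoys.
#' @param magnitudes perturbation magnitudes in Angstrom, recycled over
#'   decoys in round-robin order.
#' @param seed integer seed.
#' @return a [DecoySet-class] whose provenance holds model_id, magnitude
#'   and the true `gdt` label.
#' @export
makeDecoys <- function(native, n, magnitudes, seed = 1) {
  if (any(magnitudes < 0)) stop("magnitudes must be >= 0")
  set.seed(seed)
  L <- nres(native)
  ca0 <- caCoords(native)
  mags <- rep(magnitudes, length.out = n)
  models <- vector("list", n)
  gdt <- numeric(n)
  for (d in seq_len(n)) {
    m <- mags[d]
    ca <- if (m > 0) .perturb_ca(ca0, 2.5 * m, 0.3 * m) else ca0
    mod <- StructureModel(sprintf("decoy_%03d", d), aaSequence(native), ca)
    gdt[d] <- gdtTS(mod, native)
    models[[d]] <- mod
  }
  DecoySet(models, data.frame(model_id = sprintf("decoy_%03d", seq_len(n)),
                              magnitude = mags, gdt = gdt))
}

#' Generate contact predictions at a controlled precision
#'
#' Mixes true contacts of the native (representative atoms within 8
#' Angstrom, separation >= 6) with sampled non-contact pairs so that every
#' rank of the returned list is a true contact with probability
#' `precision`; in particular the measured top-L/5 precision has expectation
#' `precision`. Probabilities decay with rank
#' (`0.95 exp(-r / (coverage L))` plus small noise) so that only the
#' ordering matters downstream.
#'
#' @param native a [StructureModel-class].
#' @param precision target precision in (0, 1].
#' @param coverage list size as a multiple of L.
#' @param seed integer seed.
#' @return contact data.frame (i, j, p, d0) sorted by decreasing p.
#' @export
makeContactPredictions <- function(native, precision, coverage, seed = 1) {
  if (precision <= 0 || precision > 1) stop("precision must be in (0, 1]")
  L <- nres(native)
  n_total <- max(1L, round(coverage * L))
  truth <- extractContacts(native, 8, 6)
  set.seed(seed)
  is_true <- runif(n_total) < precision
  n_true <- sum(is_true)
  if (n_true > nrow(truth))
    stop("native has only ", nrow(truth), " true contacts; cannot reach ",
         "precision ", precision, " at coverage ", coverage)
  pick_true <- truth[sample(nrow(truth), n_true), , drop = FALSE]
  # sample false pairs (separation >= 6, not a true contact)
  all_pairs <- which(upper.tri(matrix(0, L, L)), arr.ind = TRUE)
  all_pairs <- all_pairs[all_pairs[, 2] - all_pairs[, 1] >= 6, , drop = FALSE]
  keys <- paste(all_pairs[, 1], all_pairs[, 2])
  false_pool <- all_pairs[!(keys %in% paste(truth$i, truth$j)), , drop = FALSE]
  n_false <- n_total - n_true
  if (n_false > nrow(false_pool))
    stop("not enough non-contact pairs for coverage ", coverage)
  pick_false <- false_pool[sample(nrow(false_pool), n_false), , drop = FALSE]
  ij <- matrix(NA_integer_, n_total, 2)
  ij[is_true, ] <- cbind(pick_true$i, pick_true$j)
  ij[!is_true, ] <- pick_false
  r <- seq_len(n_total)
  p <- 0.95 * exp(-r / (coverage * L)) + runif(n_total, 0, 0.01)
  p <- sort(pmin(p, 1), decreasing = TRUE)
  df <- data.frame(i = ij[, 1], j = ij[, 2], p = p, d0 = 8)
  rownames(df) <- NULL
  df
}

.corrupt_string <- function(s, alphabet, rate) {
  if (rate <= 0) return(s)
  ch <- strsplit(s, "")[[1]]
  flip <- runif(length(ch)) < rate
  ch[flip] <- vapply(ch[flip], function(c0)
    sample(setdiff(alphabet, c0), 1), character(1))
  paste(ch, collapse = "")
}

.topology_library <- function(L) {
  # templates scaled to length L; loops absorb the remainder
  mk <- function(types, fracs) {
    lens <- pmax(ifelse(types == "C", 3L, 5L), round(fracs * L))
    lens[length(lens)] <- lens[length(lens)] + (L - sum(lens))
    if (lens[length(lens)] < 1L) return(NULL)
    paste(types, lens, sep = ":")
  }
  tpl <- list(
    mk(c("H", "C", "E", "C", "E", "C", "H"),
       c(0.22, 0.08, 0.14, 0.08, 0.14, 0.08, 0.26)),
    mk(c("E", "C", "E", "C", "H", "C", "E"),
       c(0.15, 0.08, 0.15, 0.08, 0.28, 0.08, 0.18)),
    mk(c("E", "C", "H", "C", "E", "C", "H"),
       c(0.16, 0.08, 0.24, 0.08, 0.16, 0.08, 0.2)),
    mk(c("H", "C", "E", "C", "E", "C", "E"),
       c(0.3, 0.08, 0.14, 0.08, 0.14, 0.08, 0.18)))
  tpl[!vapply(tpl, is.null, logical(1))]
}

#' Generate a labelled synthetic QA dataset
#'
#' For each target: a toy native (topology drawn from a small template
#' library, infeasible templates skipped deterministically), a model pool,
#' contact predictions at the stated precision, and assembled feature
#' vectors. The pool mixes graded decoys (two thirds clustered in the
#' hard-to-rank 0.75-0.95 GDT region, the rest clearly wrong) with
#' hinge-rotated topology breakers (locally intact, globally wrong).
#' External 3D score columns emulate single-model quality methods:
#' `(1 - b) gdt + b local + noise` with local-plausibility bias `b`
#' (`noise_spec$local_bias`), one column per entry of `noise_spec$sigma`,
#' clipped to [0, 1]; plus one adversarial anti-correlated column and, if
#' `noise_spec$oracle`, one exact oracle column. Predicted 1D strings are
#' corrupted at realistic error rates. Labels (`gdt`) are the true GDT-TS
#' of each model against its native.
#'
#' @param n_targets number of targets (>= 10 for downstream ensemble
#'   training).
#' @param models_per_target models per target.
#' @param noise_spec list with fields `sigma` (numeric vector of external
#'   noise SDs), `local_bias` (in [0, 1]), `oracle` (logical),
#'   `adversarial` (logical), `contact_precision`, `contact_coverage`,
#'   `include_contacts` (logical; drop the 2D features when FALSE), `L`
#'   (target length), `ss_error`, `sa_error` (1D corruption rates).
#' @param seed integer seed.
#' @return QA data.frame: target_id, model_id, feature columns, complete,
#'   gdt.
#' @export
makeQADataset <- function(n_targets, models_per_target = 12,
                          noise_spec = list(), seed = 1) {
  ns <- utils::modifyList(list(sigma = c(0.15, 0.2, 0.25, 0.3),
                               oracle = FALSE,
                               adversarial = TRUE, contact_precision = 0.8,
                               contact_coverage = 1.0,
                               include_contacts = TRUE, L = 40L,
                               ss_error = 0.15, sa_error = 0.2,
                               local_bias = 0.4), noise_spec)
  out <- vector("list", n_targets)
  for (t in seq_len(n_targets)) {
    tseed <- seed * 1000L + t
    set.seed(tseed)
    tpl <- .topology_library(ns$L)
    order_try <- (sample(length(tpl), 1) + seq_along(tpl) - 2L) %%
      length(tpl) + 1L
    native <- NULL
    for (ti in order_try) {
      topo <- tpl[[ti]]
      lens <- as.integer(sub(".*:", "", topo))
      spec <- syntheticSpec(sum(lens), topo, seed = tseed)
      native <- tryCatch(makeNative(spec), error = function(e) NULL)
      if (!is.null(native)) break
    }
    if (is.null(native))
      stop("no feasible topology for target ", t, " at L = ", ns$L)
    # pool composition mirrors server-model pools: half clusters near the
    # native (hard-to-rank top region), a quarter spreads to clearly wrong
    # models, and a quarter are hinge-only "topology breakers" -- locally
    # well-formed models with a wrong global fold, which 1D features cannot
    # distinguish from good models but contact features can
    n_break <- max(1L, floor(models_per_target / 3))
    n_grad <- models_per_target - n_break
    n_top <- ceiling(n_grad * 2 / 3)
    mags <- c(runif(n_top, 2, 4.5), runif(n_grad - n_top, 4.5, 9))
    dec <- makeDecoys(native, n_grad, mags, seed = tseed + 1L)
    set.seed(tseed + 7L)
    breakers <- lapply(seq_len(n_break), function(b) {
      ca <- .break_topology_ca(native)
      StructureModel(sprintf("decoy_%03d", n_grad + b),
                     aaSequence(native), ca)
    })
    models <- c(decoyModels(dec), breakers)
    g <- c(decoyProvenance(dec)$gdt,
           vapply(breakers, gdtTS, numeric(1), reference = native))
    # local-quality score of each model: single-model QA methods reward
    # local plausibility, which overrates topologically wrong but locally
    # clean models -- the bias that contact-match features correct
    lam <- vapply(models, function(m)
      ssMatch(secondaryStructure(native), assignSS(m)), numeric(1))
    preds <- makeContactPredictions(native, ns$contact_precision,
                                    ns$contact_coverage, seed = tseed + 2L)
    # predicted 1D features are imperfect, as secondary-structure and
    # accessibility predictors are (~82% / ~80% 2- and 3-state accuracy)
    set.seed(tseed + 4L)
    pred_ss <- .corrupt_string(secondaryStructure(native), c("H", "E", "C"),
                               ns$ss_error)
    pred_sa <- .corrupt_string(solventExposure(native), c("B", "E"),
                               ns$sa_error)
    fv <- assembleFeatures(models, pred_ss, pred_sa, preds,
                           target_id = sprintf("T%03d", t))
    set.seed(tseed + 3L)
    beta <- ns$local_bias
    for (sidx in seq_along(ns$sigma)) {
      v <- (1 - beta) * g + beta * lam + rnorm(length(g), 0, ns$sigma[sidx])
      fv[[sprintf("ext_%d", sidx)]] <- pmin(pmax(v, 0), 1)
    }
    if (isTRUE(ns$adversarial))
      fv$ext_adv <- pmin(pmax(1 - g + rnorm(length(g), 0, 0.05), 0), 1)
    if (isTRUE(ns$oracle)) fv$ext_oracle <- g
    fv$gdt <- g
    if (!isTRUE(ns$include_contacts))
      fv <- fv[, setdiff(names(fv),
                         c("f_con_short", "f_con_medium", "f_con_long"))]
    out[[t]] <- fv
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}
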