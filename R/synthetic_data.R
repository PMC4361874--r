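# Synthetic 7TM ensemble generator: heptahelical N/CA/C backbones built from
# ideal alpha-helix internal coordinates, with per-helix rigid-body jitter
# (optionally coupled across helices), per-residue torsion and coordinate
# noise, optional kinks and missing positions. Deterministic given a seed.

# ideal backbone internal coordinates (bond lengths A, angles deg)
.BOND <- c(N_CA = 1.458, CA_C = 1.525, C_N = 1.329)
.ANGLE <- c(N_CA_C = 111.2, CA_C_N = 116.2, C_N_CA = 121.7)
.OMEGA <- 180

# NeRF placement: D such that |CD| = bond, angle(B,C,D) = ang (deg) and
# dihedral(A,B,C,D) = tor (deg)
place_atom <- function(A, B, C, bond, ang, tor) {
  ang <- ang * pi / 180
  tor <- tor * pi / 180
  bc <- C - B
  bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- bond * c(-cos(ang), sin(ang) * cos(tor), sin(ang) * sin(tor))
  C + d2[1] * bc + d2[2] * m + d2[3] * n
}

# build an L-residue backbone from phi/psi vectors (phi[1], psi[L] unused);
# returns list of L x 3 matrices n, ca, c
build_backbone <- function(phi, psi, omega = .OMEGA) {
  L <- length(phi)
  stopifnot(length(psi) == L, L >= 2)
  N <- CA <- C <- matrix(0, L, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(.BOND["N_CA"], 0, 0)
  a <- .ANGLE["N_CA_C"] * pi / 180
  C[1, ] <- CA[1, ] + .BOND["CA_C"] * c(-cos(a), sin(a), 0)
  for (i in 2:L) {
    N[i, ] <- place_atom(N[i - 1, ], CA[i - 1, ], C[i - 1, ],
                         .BOND["C_N"], .ANGLE["CA_C_N"], psi[i - 1])
    CA[i, ] <- place_atom(CA[i - 1, ], C[i - 1, ], N[i, ],
                          .BOND["N_CA"], .ANGLE["C_N_CA"], omega)
    C[i, ] <- place_atom(C[i - 1, ], N[i, ], CA[i, ],
                         .BOND["CA_C"], .ANGLE["N_CA_C"], phi[i])
  }
  list(n = N, ca = CA, c = C)
}

# Rodrigues rotation matrix about unit axis u by angle deg
rot_about <- function(u, deg) {
  th <- deg * pi / 180
  u <- u / sqrt(sum(u^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# rotation mapping unit vector a onto unit vector b
rot_between <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  v <- c(a[2] * b[3] - a[3] * b[2],
         a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  s <- sqrt(sum(v^2)); cc <- sum(a * b)
  if (s < 1e-12) {
    if (cc > 0) return(diag(3))
    # opposite: rotate 180 about any perpendicular
    p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    v <- c(a[2] * p[3] - a[3] * p[2], a[3] * p[1] - a[1] * p[3],
           a[1] * p[2] - a[2] * p[1])
    return(rot_about(v, 180))
  }
  K <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + K + K %*% K * ((1 - cc) / s^2)
}

#' Specification for a synthetic 7TM ensemble
#'
#' Controls the conservation structure of a generated ensemble. Members share
#' one ideal-geometry template per helix (alpha-helical backbone built from
#' internal coordinates with base torsions `phi0`/`psi0`, giving a helix with
#' approximately 1.5 A rise/residue, 100 deg twist/residue and 2.3 A C-alpha
#' radius) and differ only by the stochastic terms: per-helix rigid-body
#' jitter (translation sigma in A, rotation sigma in degrees), per-residue
#' torsion noise (degrees) and per-atom isotropic coordinate noise (A).
#' Helices listed together in a `couplings` group receive an identical
#' rigid-body draw in every member, so their mutual distances stay conserved
#' while distances to independently jittered helices vary.
#'
#' @param n_members ensemble size (default 20).
#' @param seed integer seed; fully determines the output.
#' @param phi0,psi0 base backbone torsions in degrees (defaults -57, -47).
#' @param rise,twist,radius nominal helix geometry implied by the base
#'   torsions (A/residue, deg/residue, A); used by the generator's geometric
#'   self-checks.
#' @param layout_radius radius (A) of the ellipse on which the seven helix
#'   axes are placed (default 11).
#' @param tilt per-helix axis tilt in degrees (scalar or length 7).
#' @param trans_sigma per-helix rigid translation sigma, A (scalar or 7).
#' @param rot_sigma per-helix rigid rotation sigma, degrees (scalar or 7).
#' @param coord_sigma per-helix per-atom isotropic coordinate noise sigma, A
#'   (scalar or 7).
#' @param torsion_sigma per-helix per-residue torsion noise sigma, degrees
#'   (scalar or 7); may also be a 7 x 5 matrix for per-section control.
#' @param couplings list of integer vectors of helix numbers drawing their
#'   rigid-body jitter jointly (e.g. `list(c(1, 6))`).
#' @param kinks optional data.frame with columns `helix`, `index`, `angle`
#'   bending the template at a BW index by `angle` degrees.
#' @param missing optional named list: member index -> character vector of BW
#'   positions (`"h.ii"`) omitted from that member.
#' @param bfactor_base,bfactor_helix,bfactor_member temperature-factor model:
#'   B = base + helix offset + member offset (scalars or length 7 / n_members).
#' @return An object of class `generator_spec`.
#' @seealso [preset()] for ready-made scenarios, [generate_ensemble()].
#' @export
generator_spec <- function(n_members = 20L, seed = 1L,
                           phi0 = -57, psi0 = -47,
                           rise = 1.5, twist = 100, radius = 2.3,
                           layout_radius = 11, tilt = 0,
                           trans_sigma = 0.4, rot_sigma = 2,
                           coord_sigma = 0.08, torsion_sigma = 0,
                           couplings = list(), kinks = NULL,
                           missing = list(),
                           bfactor_base = 30, bfactor_helix = 0,
                           bfactor_member = 0) {
  rec7 <- function(x) {
    x <- rep_len(as.numeric(x), 7L)
    if (any(x < 0)) stop("noise sigmas must be >= 0")
    x
  }
  if (is.matrix(torsion_sigma)) {
    stopifnot(nrow(torsion_sigma) == 7L, ncol(torsion_sigma) == 5L,
              all(torsion_sigma >= 0))
  } else {
    torsion_sigma <- matrix(rep_len(as.numeric(torsion_sigma), 7L), 7L, 5L)
    if (any(torsion_sigma < 0)) stop("noise sigmas must be >= 0")
  }
  if (length(couplings) > 0) {
    all_h <- unlist(couplings)
    stopifnot(all(all_h %in% 1:7), !anyDuplicated(all_h))
  }
  if (!is.null(kinks)) {
    stopifnot(is.data.frame(kinks),
              all(c("helix", "index", "angle") %in% names(kinks)))
  }
  if (length(missing) > 0 && is.null(names(missing))) {
    stop("'missing' must be a named list keyed by member index")
  }
  structure(list(
    n_members = as.integer(n_members), seed = as.integer(seed),
    phi0 = phi0, psi0 = psi0, rise = rise, twist = twist, radius = radius,
    layout_radius = layout_radius, tilt = rep_len(as.numeric(tilt), 7L),
    trans_sigma = rec7(trans_sigma), rot_sigma = rec7(rot_sigma),
    coord_sigma = rec7(coord_sigma), torsion_sigma = torsion_sigma,
    couplings = couplings, kinks = kinks, missing = missing,
    bfactor_base = bfactor_base,
    bfactor_helix = rep_len(as.numeric(bfactor_helix), 7L),
    bfactor_member = rep_len(as.numeric(bfactor_member), n_members)
  ), class = "generator_spec")
}

#' @export
print.generator_spec <- function(x, ...) {
  cat(sprintf("synthetic 7TM generator spec: %d members, seed %d\n",
              x$n_members, x$seed))
  cat("  trans sigma (A):", paste(format(x$trans_sigma), collapse = " "), "\n")
  cat("  coord sigma (A):", paste(format(x$coord_sigma), collapse = " "), "\n")
  if (length(x$couplings)) {
    cat("  coupled helices:",
        paste(vapply(x$couplings, function(g)
          paste(roman_helix(g), collapse = "+"), ""), collapse = ", "), "\n")
  }
  if (length(x$missing)) {
    cat("  gapped members:", paste(names(x$missing), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Ready-made generator scenarios
#'
#' * `"rhodopsin_like"`: a homogeneous family-like set — helix III internally
#'   quiet, helices IV and VII noisy, helices I and VI rigid-jitter coupled.
#' * `"mixed_family"`: the same conservation pattern with all noise scaled up
#'   1.8x and 19 members, emulating a heterogeneous multi-family set.
#' * `"gapped"`: `mixed_family` plus missing positions — member 1 lacks 4.39
#'   and member 2 lacks 2.66, 2.67, 6.59, 6.60 — so the common-position pair
#'   universe is 18,915.
#'
#' @param name preset name.
#' @param n_members,seed overrides passed through to [generator_spec()].
#' @return A [generator_spec()].
#' @export
preset <- function(name = c("rhodopsin_like", "mixed_family", "gapped"),
                   n_members = NULL, seed = 1L) {
  if (!is.character(name) || length(name) != 1L ||
      !name %in% c("rhodopsin_like", "mixed_family", "gapped")) {
    stop("unknown preset '", paste(name, collapse = ","),
         "'; available: rhodopsin_like, mixed_family, gapped")
  }
  # per-helix conservation pattern: III quiet, IV and VII noisy, I+VI coupled
  trans <- c(0.35, 0.35, 0.15, 0.80, 0.45, 0.35, 0.80)
  rot <- c(1.5, 1.5, 0.8, 3.0, 2.0, 1.5, 3.0)
  coord <- c(0.10, 0.12, 0.05, 0.35, 0.15, 0.10, 0.35)
  scale <- if (name == "rhodopsin_like") 1 else 1.8
  nm <- if (!is.null(n_members)) n_members
        else if (name == "rhodopsin_like") 20L else 19L
  miss <- if (name == "gapped") {
    list(`1` = "4.39", `2` = c("2.66", "2.67", "6.59", "6.60"))
  } else list()
  generator_spec(n_members = nm, seed = seed,
                 trans_sigma = trans * scale, rot_sigma = rot * scale,
                 coord_sigma = coord * scale,
                 couplings = list(c(1L, 6L)),
                 missing = miss,
                 bfactor_base = 30, bfactor_helix = c(0, 2, -5, 8, 3, 0, 8))
}

# canonical noiseless helix template in the bundle layout frame
.helix_template <- function(h, defn, spec, phi, psi, apply_kinks = TRUE) {
  hrow <- defn$helices[h, ]
  L <- hrow$end - hrow$start + 1L
  bb <- build_backbone(phi, psi)
  # canonical frame: CA centroid at origin, helix axis along z with the
  # first residue at +z when its end is extracellular
  ctr <- colMeans(bb$ca)
  X <- sweep(bb$ca, 2, ctr)
  v <- svd(X, nu = 0, nv = 1)$v[, 1]
  if (sum(v * (bb$ca[L, ] - bb$ca[1, ])) < 0) v <- -v  # v points 1st -> last
  target <- if (hrow$ec_end == "first") c(0, 0, -1) else c(0, 0, 1)
  R <- rot_between(v, target)
  tf <- function(m) t(R %*% (t(m) - ctr))
  bb <- lapply(bb, tf)
  # optional kink: bend the part following the kink position about an axis
  # perpendicular to the helix axis, through the kink CA
  if (apply_kinks && !is.null(spec$kinks)) {
    kk <- spec$kinks[spec$kinks$helix == h, , drop = FALSE]
    for (q in seq_len(nrow(kk))) {
      at <- kk$index[q] - hrow$start + 1L
      if (at < 1L || at > L) next
      pivot <- bb$ca[at, ]
      Rk <- rot_about(c(1, 0, 0), kk$angle[q])
      bend <- function(m) {
        sel <- seq_len(nrow(m)) > at
        m[sel, ] <- t(Rk %*% (t(m[sel, , drop = FALSE]) - pivot) + pivot)
        m
      }
      bb <- lapply(bb, bend)
    }
  }
  # layout: tilt about a horizontal axis, then move to the bundle ellipse
  ang <- (h - 1) * 2 * pi / 7
  centre <- spec$layout_radius * c(cos(ang), sin(ang), 0)
  Rt <- rot_about(c(-sin(ang), cos(ang), 0), spec$tilt[h])
  lapply(bb, function(m) t(Rt %*% t(m)) +
           matrix(centre, nrow(m), 3, byrow = TRUE))
}

# one-off geometric self-check of the noiseless template
.check_template <- function(ca) {
  d1 <- sqrt(rowSums((ca[-1, , drop = FALSE] -
                        ca[-nrow(ca), , drop = FALSE])^2))
  if (any(abs(d1 - 3.8) > 0.1)) {
    stop("generator self-check failed: consecutive CA spacing ",
         paste(round(range(d1), 3), collapse = "-"), " A (expected 3.8 +/- 0.1)")
  }
  if (nrow(ca) > 4) {
    d4 <- sqrt(rowSums((ca[-(1:4), , drop = FALSE] -
                          ca[seq_len(nrow(ca) - 4), , drop = FALSE])^2))
    if (any(abs(d4 - 6.2) > 0.4)) {
      stop("generator self-check failed: i,i+4 CA spacing ",
           paste(round(range(d4), 3), collapse = "-"),
           " A (expected 6.2 +/- 0.4)")
    }
  }
  invisible(TRUE)
}

#' Generate a synthetic 7TM ensemble
#'
#' Builds `spec$n_members` aligned bundles over the bundle definition,
#' deterministically from `spec$seed`. Per member the random draws are made
#' in a fixed, documented order: first one rigid-body draw per coupling group
#' (3 translation normals, 3 rotation-axis normals, 1 rotation-angle normal),
#' then one per uncoupled helix in helix order, then per helix the torsion
#' noise (phi then psi, residue order) and the per-atom coordinate noise
#' (N, CA, C per residue). Coupled helices receive the identical rigid
#' transform (rotation about the bundle centre plus translation), scaled by
#' the sigmas of the group's first helix; uncoupled helices rotate about
#' their own axis centre.
#'
#' @param spec a [generator_spec()].
#' @param defn the governing [bundle_definition()].
#' @param dir optional directory: when given, one PDB file per member plus
#'   `alignment.tsv` and `sets.tsv` manifests (the inputs consumed by
#'   [read_chain()] / [read_alignment_table()]) are written there.
#' @param name set name of the returned ensemble.
#' @return A [build_set()] ensemble; when `dir` is given it carries a
#'   `files` attribute listing the PDB paths.
#' @export
generate_ensemble <- function(spec, defn = default_bundle(), dir = NULL,
                              name = "synthetic") {
  stopifnot(inherits(spec, "generator_spec"),
            inherits(defn, "bundle_definition"))
  set.seed(spec$seed, kind = "Mersenne-Twister")
  pos <- defn$positions
  hrows <- defn$helices
  lens <- hrows$end - hrows$start + 1L

  # noiseless templates, checked once
  base_phi <- lapply(lens, function(L) rep(spec$phi0, L))
  base_psi <- lapply(lens, function(L) rep(spec$psi0, L))
  templates <- lapply(1:7, function(h)
    .helix_template(h, defn, spec, base_phi[[h]], base_psi[[h]]))
  # geometric self-check on the ideal (un-kinked) geometry
  for (h in 1:7) {
    tm <- if (is.null(spec$kinks) || !h %in% spec$kinks$helix) templates[[h]]
          else .helix_template(h, defn, spec, base_phi[[h]], base_psi[[h]],
                               apply_kinks = FALSE)
    .check_template(tm$ca)
  }

  # clash advisory on the noiseless layout
  allca <- do.call(rbind, lapply(templates, `[[`, "ca"))
  hel <- rep(1:7, lens)
  dmin <- Inf
  for (h in 1:6) {
    a <- allca[hel == h, , drop = FALSE]
    b <- allca[hel > h, , drop = FALSE]
    for (i in seq_len(nrow(a))) {
      dmin <- min(dmin, sqrt(min(rowSums((b - matrix(a[i, ], nrow(b), 3,
                                                     byrow = TRUE))^2))))
    }
  }
  if (dmin < 2) {
    warning(sprintf("layout places inter-helix C-alphas %.2f A apart (< 2 A)",
                    dmin))
  }

  grouped <- if (length(spec$couplings)) unlist(spec$couplings) else integer(0)
  free_h <- setdiff(1:7, grouped)
  need_rebuild <- any(spec$torsion_sigma > 0)

  members <- vector("list", spec$n_members)
  for (m in seq_len(spec$n_members)) {
    # rigid-body draws, documented order
    draw_rigid <- function() list(tr = stats::rnorm(3),
                                  ax = stats::rnorm(3),
                                  an = stats::rnorm(1))
    gdraw <- lapply(spec$couplings, function(g) draw_rigid())
    fdraw <- stats::setNames(lapply(free_h, function(h) draw_rigid()),
                             free_h)
    ca_m <- n_m <- c_m <- NULL
    ids_m <- integer(0)
    for (h in 1:7) {
      L <- lens[h]
      # torsion noise (phi then psi) in residue order
      tn_sec <- spec$torsion_sigma[h, pos$section[pos$helix == h]]
      phi <- base_phi[[h]]; psi <- base_psi[[h]]
      if (need_rebuild) {
        phi <- phi + stats::rnorm(L) * tn_sec
        psi <- psi + stats::rnorm(L) * tn_sec
        bb <- .helix_template(h, defn, spec, phi, psi)
      } else {
        bb <- templates[[h]]
      }
      # rigid transform
      gi <- which(vapply(spec$couplings, function(g) h %in% g, TRUE))
      if (length(gi) == 1L) {
        d <- gdraw[[gi]]
        lead <- spec$couplings[[gi]][1]
        pivot <- c(0, 0, 0)  # coupled: rotate jointly about the bundle centre
        ts <- spec$trans_sigma[lead]; rs <- spec$rot_sigma[lead]
      } else {
        d <- fdraw[[as.character(h)]]
        ang <- (h - 1) * 2 * pi / 7
        pivot <- spec$layout_radius * c(cos(ang), sin(ang), 0)
        ts <- spec$trans_sigma[h]; rs <- spec$rot_sigma[h]
      }
      ax <- d$ax / sqrt(sum(d$ax^2))
      R <- rot_about(ax, d$an * rs)
      tr <- d$tr * ts
      rigid <- function(mt) t(R %*% (t(mt) - pivot) + pivot) +
        matrix(tr, nrow(mt), 3, byrow = TRUE)
      bb <- lapply(bb, rigid)
      # per-atom coordinate noise, N/CA/C per residue
      cs <- spec$coord_sigma[h]
      if (cs > 0) {
        noise <- matrix(stats::rnorm(3L * L * 3L), 3L * L, 3) * cs
        bb$n <- bb$n + noise[seq(1, by = 3, length.out = L), ]
        bb$ca <- bb$ca + noise[seq(2, by = 3, length.out = L), ]
        bb$c <- bb$c + noise[seq(3, by = 3, length.out = L), ]
      }
      ids <- bw_id(h, seq.int(hrows$start[h], hrows$end[h]))
      rownames(bb$n) <- rownames(bb$ca) <- rownames(bb$c) <- ids
      ca_m <- rbind(ca_m, bb$ca); n_m <- rbind(n_m, bb$n)
      c_m <- rbind(c_m, bb$c); ids_m <- c(ids_m, ids)
    }
    # drop this member's missing positions
    miss <- spec$missing[[as.character(m)]]
    if (!is.null(miss)) {
      drop <- bw_parse(miss)
      keep <- !ids_m %in% drop
      ca_m <- ca_m[keep, , drop = FALSE]
      n_m <- n_m[keep, , drop = FALSE]
      c_m <- c_m[keep, , drop = FALSE]
      ids_m <- ids_m[keep]
    }
    b <- spec$bfactor_base + spec$bfactor_helix[bw_helix(ids_m)] +
      spec$bfactor_member[m]
    names(b) <- ids_m
    members[[m]] <- aligned_bundle(ca_m, defn, n = n_m, c = c_m, b = b,
                                   source_id = sprintf("SYN%02d", m),
                                   chain_id = "A")
  }
  ens <- build_set(members, name = name, defn = defn)
  if (!is.null(dir)) {
    attr(ens, "files") <- write_ensemble_fixtures(ens, dir, name = name)
  }
  ens
}

#' Write an ensemble as PDB fixtures with alignment and set manifests
#'
#' One PDB file per member (`<source_id>.pdb`, chain A, residue number =
#' helix x 100 + BW index, B-factor column populated), an `alignment.tsv`
#' mapping residue numbers to BW positions, and a `sets.tsv` manifest listing
#' the members.
#'
#' @param ensemble a [build_set()] ensemble.
#' @param dir output directory (created if needed).
#' @param name set name recorded in the manifest.
#' @return character vector of the PDB paths, invisibly named by source id.
#' @export
write_ensemble_fixtures <- function(ensemble, dir, name = ensemble$name) {
  stopifnot(inherits(ensemble, "bundle_ensemble"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  align <- NULL
  for (mem in ensemble$members) {
    ids <- mem$present
    with_n <- !is.null(mem$n)
    per_res <- if (with_n) 3L else 1L
    xyz <- matrix(NA_real_, length(ids) * per_res, 3)
    elety <- character(length(ids) * per_res)
    for (k in seq_along(ids)) {
      r <- (k - 1L) * per_res
      if (with_n) {
        xyz[r + 1L, ] <- mem$n[as.character(ids[k]) == rownames(mem$n), ]
        xyz[r + 2L, ] <- mem$ca[k, ]
        xyz[r + 3L, ] <- mem$c[as.character(ids[k]) == rownames(mem$c), ]
        elety[r + (1:3)] <- c("N", "CA", "C")
      } else {
        xyz[r + 1L, ] <- mem$ca[k, ]
        elety[r + 1L] <- "CA"
      }
    }
    resno <- rep(ids, each = per_res)
    bvals <- if (is.null(mem$b)) rep(0, length(ids)) else mem$b
    path <- file.path(dir, paste0(mem$source_id, ".pdb"))
    bio3d::write.pdb(file = path, xyz = as.numeric(t(xyz)),
                     resno = resno, resid = rep("ALA", length(resno)),
                     chain = rep(mem$chain_id, length(resno)),
                     elety = elety, o = rep(1, length(resno)),
                     b = rep(bvals, each = per_res))
    paths[mem$source_id] <- path
    align <- rbind(align, data.frame(source_id = mem$source_id,
                                     chain_id = mem$chain_id,
                                     residue = ids,
                                     bw_position = bw_chr(ids)))
  }
  utils::write.table(align, file.path(dir, "alignment.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  manifest <- do.call(rbind, lapply(ensemble$members, function(mem)
    data.frame(source_id = mem$source_id, chain_id = mem$chain_id,
               set_name = name)))
  utils::write.table(manifest, file.path(dir, "sets.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}
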