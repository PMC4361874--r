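# Backbone phi/psi torsions per BW position and their circular deviations
# across an ensemble, averaged over the 35 helix sections.

#' Signed dihedral angle of four points
#'
#' IUPAC convention: looking down the 2-3 bond, the angle from the 1-2 bond
#' to the 3-4 bond, positive clockwise; result in (-180, 180] degrees.
#'
#' @param p1,p2,p3,p4 numeric 3-vectors (Angstrom).
#' @return angle in degrees.
#' @export
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  if (sum(n1^2) < 1e-12 || sum(n2^2) < 1e-12) {
    stop("collinear points: dihedral undefined")
  }
  n1xn2 <- c(n1[2] * n2[3] - n1[3] * n2[2],
             n1[3] * n2[1] - n1[1] * n2[3],
             n1[1] * n2[2] - n1[2] * n2[1])
  x <- sum(n1 * n2)
  y <- sum(n1xn2 * b2) / sqrt(sum(b2^2))
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Backbone phi/psi angles of a bundle
#'
#' phi(i) is the C(i-1)-N(i)-CA(i)-C(i) dihedral and psi(i) the
#' N(i)-CA(i)-C(i)-N(i+1) dihedral, where i-1 and i+1 are the sequence
#' neighbours (consecutive BW indices within the same helix). Helices are
#' separate segments — the loop residues are not part of the bundle — so phi
#' is undefined at each helix's first position and psi at its last, as well
#' as wherever a neighbour or a backbone atom is missing.
#'
#' @param bundle an [aligned_bundle()] carrying N and C coordinates.
#' @param defn the governing [bundle_definition()].
#' @return data.frame with `id`, `bw`, `phi`, `psi` (degrees, `NA` where
#'   undefined), one row per present position.
#' @export
torsions_for_bundle <- function(bundle, defn = default_bundle()) {
  stopifnot(inherits(bundle, "aligned_bundle"))
  if (is.null(bundle$n) || is.null(bundle$c)) {
    stop("bundle lacks N/C backbone coordinates; torsions need N, CA and C")
  }
  ids <- bundle$present
  getrow <- function(m, id) {
    i <- match(as.character(id), rownames(m))
    if (is.na(i)) NULL else m[i, ]
  }
  phi <- psi <- rep(NA_real_, length(ids))
  for (k in seq_along(ids)) {
    id <- ids[k]
    prev <- id - 1L; nxt <- id + 1L
    same_helix_prev <- bw_helix(prev) == bw_helix(id) && prev %in% ids
    same_helix_next <- bw_helix(nxt) == bw_helix(id) && nxt %in% ids
    N <- getrow(bundle$n, id); CA <- getrow(bundle$ca, id)
    C <- getrow(bundle$c, id)
    if (is.null(N) || is.null(C)) next
    if (same_helix_prev) {
      Cp <- getrow(bundle$c, prev)
      if (!is.null(Cp)) phi[k] <- dihedral(Cp, N, CA, C)
    }
    if (same_helix_next) {
      Nn <- getrow(bundle$n, nxt)
      if (!is.null(Nn)) psi[k] <- dihedral(N, CA, C, Nn)
    }
  }
  data.frame(id = ids, bw = bw_chr(ids), phi = phi, psi = psi)
}

#' Circular deviation of a set of angles
#'
#' `"sd"` (default) is the circular standard deviation
#' `sqrt(-2 log Rbar) * 180 / pi`, where `Rbar` is the mean resultant length;
#' `"range"` is the minimal arc containing all the angles (360 minus the
#' largest gap). Both respect wrap-around: -179 and +179 degrees deviate by
#' 2 degrees, not 358.
#'
#' @param deg numeric vector of angles in degrees (`NA` dropped).
#' @param method `"sd"` or `"range"`.
#' @return non-negative deviation in degrees (`NA` if fewer than 2 angles).
#' @export
circ_dev <- function(deg, method = c("sd", "range")) {
  method <- match.arg(method)
  deg <- deg[!is.na(deg)]
  if (length(deg) < 2L) return(NA_real_)
  if (method == "sd") {
    rad <- deg * pi / 180
    rbar <- sqrt(mean(cos(rad))^2 + mean(sin(rad))^2)
    rbar <- min(rbar, 1)
    sqrt(-2 * log(max(rbar, .Machine$double.xmin))) * 180 / pi
  } else {
    a <- sort(deg %% 360)
    gaps <- diff(c(a, a[1] + 360))
    360 - max(gaps)
  }
}

#' Cross-ensemble torsion deviation per position and per section
#'
#' Computes phi and psi for every member, then for each BW position the
#' circular deviation of each angle across the members, and finally the
#' arithmetic mean of those per-position deviations within each of the 35
#' helix sections. Positions with the angle defined in fewer than 2 members
#' are excluded from their section mean.
#'
#' @param ensemble a [build_set()] ensemble whose members carry N/C atoms.
#' @param defn the governing [bundle_definition()].
#' @param method deviation statistic, see [circ_dev()].
#' @return An object of class `torsion_dev`: list with `positions`
#'   (`bw`, `n_phi`, `n_psi`, `dev_phi`, `dev_psi`) and `sections`
#'   (35 rows: `helix`, `section`, `label`, `n_positions_phi`,
#'   `n_positions_psi`, `dev_phi`, `dev_psi`).
#' @export
torsion_deviation <- function(ensemble, defn = default_bundle(),
                              method = c("sd", "range")) {
  stopifnot(inherits(ensemble, "bundle_ensemble"))
  method <- match.arg(method)
  tors <- lapply(ensemble$members, torsions_for_bundle, defn = defn)
  ids <- sort(Reduce(union, lapply(tors, `[[`, "id")))
  PHI <- sapply(tors, function(t) t$phi[match(ids, t$id)])
  PSI <- sapply(tors, function(t) t$psi[match(ids, t$id)])
  if (is.null(dim(PHI))) { PHI <- matrix(PHI, nrow = 1); PSI <- matrix(PSI, nrow = 1) }
  n_phi <- rowSums(!is.na(PHI))
  n_psi <- rowSums(!is.na(PSI))
  dev_phi <- apply(PHI, 1, circ_dev, method = method)
  dev_psi <- apply(PSI, 1, circ_dev, method = method)
  pos <- data.frame(id = ids, bw = bw_chr(ids), n_phi = n_phi, n_psi = n_psi,
                    dev_phi = dev_phi, dev_psi = dev_psi)
  pd <- defn$positions
  pos$helix <- pd$helix[match(ids, pd$id)]
  pos$section <- pd$section[match(ids, pd$id)]
  pos$section_label <- pd$section_label[match(ids, pd$id)]
  secs <- unique(pd[, c("helix", "section", "section_label")])
  secs <- secs[order(secs$helix, secs$section), ]
  agg <- function(dev, n) {
    vapply(seq_len(nrow(secs)), function(i) {
      sel <- pos$helix == secs$helix[i] & pos$section == secs$section[i] &
        n >= 2 & !is.na(dev)
      if (!any(sel)) return(NA_real_)
      mean(dev[sel])
    }, 0)
  }
  cnt <- function(n) {
    vapply(seq_len(nrow(secs)), function(i) {
      sum(pos$helix == secs$helix[i] & pos$section == secs$section[i] & n >= 2)
    }, 0L)
  }
  sections <- data.frame(helix = secs$helix, section = secs$section,
                         label = secs$section_label,
                         n_positions_phi = cnt(n_phi),
                         n_positions_psi = cnt(n_psi),
                         dev_phi = agg(dev_phi, n_phi),
                         dev_psi = agg(dev_psi, n_psi))
  rownames(sections) <- NULL
  structure(list(positions = pos, sections = sections,
                 method = method, n_members = length(ensemble$members),
                 set_name = ensemble$name),
            class = "torsion_dev")
}

#' @export
print.torsion_dev <- function(x, ...) {
  cat(sprintf("Backbone torsion deviation (%s): set '%s', %d members\n",
              x$method, x$set_name, x$n_members))
  s <- x$sections[!is.na(x$sections$dev_phi), ]
  s <- s[order(s$dev_phi + s$dev_psi), ]
  cat("  most regular sections (lowest phi+psi deviation):\n")
  print(utils::head(s[, c("label", "dev_phi", "dev_psi")], 3),
        row.names = FALSE, digits = 3)
  invisible(x)
}

#' @export
summary.torsion_dev <- function(object, ...) object$sections
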