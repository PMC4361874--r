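# Independent oracles and small fixture builders used across the suite.

# brute-force per-pair statistics: explicit loops and textbook formulas,
# population SD; independent of the vectorised implementation
oracle_pair_stats <- function(coords_list, pairs) {
  n <- length(coords_list)
  out <- data.frame(a = pairs$a, b = pairs$b, mean = NA_real_, sd = NA_real_,
                    min = NA_real_, max = NA_real_, score = NA_real_)
  for (r in seq_len(nrow(pairs))) {
    d <- numeric(n)
    for (k in seq_len(n)) {
      pa <- coords_list[[k]][as.character(pairs$a[r]), ]
      pb <- coords_list[[k]][as.character(pairs$b[r]), ]
      d[k] <- sqrt((pa[1] - pb[1])^2 + (pa[2] - pb[2])^2 + (pa[3] - pb[3])^2)
    }
    m <- sum(d) / n
    s <- sqrt(sum((d - m)^2) / n)
    out$mean[r] <- m; out$sd[r] <- s
    out$min[r] <- min(d); out$max[r] <- max(d)
    out$score[r] <- if (s > 0) m / s else Inf
  }
  out
}

# random rigid motion built from base-R Euler rotations (independent of the
# package's Rodrigues helpers)
random_rigid <- function() {
  ang <- stats::runif(3, -pi, pi)
  rx <- matrix(c(1, 0, 0, 0, cos(ang[1]), sin(ang[1]),
                 0, -sin(ang[1]), cos(ang[1])), 3, 3)
  ry <- matrix(c(cos(ang[2]), 0, -sin(ang[2]), 0, 1, 0,
                 sin(ang[2]), 0, cos(ang[2])), 3, 3)
  rz <- matrix(c(cos(ang[3]), sin(ang[3]), 0, -sin(ang[3]), cos(ang[3]),
                 0, 0, 0, 1), 3, 3)
  list(R = rx %*% ry %*% rz, t = stats::runif(3, -20, 20))
}

apply_rigid <- function(m, rigid) {
  t(rigid$R %*% t(m)) + matrix(rigid$t, nrow(m), 3, byrow = TRUE)
}

# bundle with CA coordinates given as a named list "h.ii" -> c(x, y, z)
make_ca_bundle <- function(coords, defn, source_id = "T", chain_id = "A",
                           b = NULL) {
  ids <- bw_parse(names(coords))
  m <- do.call(rbind, coords)
  rownames(m) <- ids
  aligned_bundle(m, defn, b = b, source_id = source_id, chain_id = chain_id)
}

# small ensemble over `ids` with coordinates drawn once and jittered per
# member; returns list(ensemble, coords_list) for oracle comparison
random_small_ensemble <- function(defn, n_members = 5, n_positions = 12,
                                  seed = 42) {
  set.seed(seed)
  ids <- sort(sample(bw_positions(defn), n_positions))
  base <- matrix(stats::runif(n_positions * 3, -15, 15), n_positions, 3)
  coords_list <- list()
  members <- list()
  for (k in seq_len(n_members)) {
    m <- base + matrix(stats::rnorm(n_positions * 3, sd = 0.5),
                       n_positions, 3)
    rownames(m) <- ids
    coords_list[[k]] <- m
    members[[k]] <- aligned_bundle(m, defn, source_id = sprintf("R%02d", k))
  }
  list(ensemble = build_set(members, "tiny"), coords = coords_list,
       ids = ids)
}

# minimal hand-written PDB text (for altloc and gap fixtures)
pdb_atom_line <- function(serial, elety, resno, x, y, z, alt = " ",
                          chain = "A", b = 30, resid = "ALA") {
  sprintf("ATOM  %5d  %-3s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
          serial, elety, alt, resid, chain, resno, x, y, z, 1.00, b)
}
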