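defn <- default_bundle()

test_that("dihedral follows the IUPAC convention and matches bio3d", {
  # planar cis arrangement -> 0; trans -> 180
  expect_equal(dihedral(c(1, 1, 0), c(0, 1, 0), c(0, 0, 0), c(1, 0, 0)), 0)
  expect_equal(abs(dihedral(c(-1, 1, 0), c(0, 1, 0), c(0, 0, 0),
                            c(1, 0, 0))), 180)
  set.seed(6)
  for (i in 1:25) {
    p <- matrix(stats::rnorm(12, sd = 3), 4, 3)
    ref <- bio3d::torsion.xyz(as.numeric(t(p)))
    ref <- ref[!is.na(ref)][1]
    expect_equal(dihedral(p[1, ], p[2, ], p[3, ], p[4, ]), ref,
                 tolerance = 1e-6)
  }
  expect_error(dihedral(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0)),
               "collinear")
})

test_that("generated backbones return their construction angles", {
  ens <- generate_ensemble(generator_spec(n_members = 2, seed = 4,
                                          trans_sigma = 0.3, rot_sigma = 2,
                                          coord_sigma = 0), defn)
  for (mem in ens$members) {
    tor <- torsions_for_bundle(mem, defn)
    expect_equal(stats::median(tor$phi, na.rm = TRUE), -57, tolerance = 0.5)
    expect_equal(stats::median(tor$psi, na.rm = TRUE), -47, tolerance = 0.5)
    expect_lt(max(abs(tor$phi + 57), na.rm = TRUE), 0.5)
    expect_lt(max(abs(tor$psi + 47), na.rm = TRUE), 0.5)
  }
})

test_that("phi/psi are undefined at helix termini and across junctions", {
  ens <- generate_ensemble(generator_spec(n_members = 2, seed = 4), defn)
  tor <- torsions_for_bundle(ens$members[[1]], defn)
  pos <- defn$positions
  firsts <- pos$id[pos$index == defn$helices$start[pos$helix]]
  lasts <- pos$id[pos$index == defn$helices$end[pos$helix]]
  expect_true(all(is.na(tor$phi[tor$id %in% firsts])))
  expect_true(all(is.na(tor$psi[tor$id %in% lasts])))
  # everything else defined: 200 - 7 of each
  expect_equal(sum(!is.na(tor$phi)), 193L)
  expect_equal(sum(!is.na(tor$psi)), 193L)
})

test_that("torsions match an independent bio3d recomputation", {
  ens <- generate_ensemble(generator_spec(n_members = 2, seed = 9,
                                          coord_sigma = 0.3), defn)
  mem <- ens$members[[1]]
  tor <- torsions_for_bundle(mem, defn)
  # helix III residues as one continuous backbone for bio3d
  ids <- mem$present[bw_helix(mem$present) == 3]
  xyz <- NULL
  for (id in ids) {
    key <- as.character(id)
    xyz <- rbind(xyz, mem$n[key == rownames(mem$n), ], mem$ca[key == rownames(mem$ca), ],
                 mem$c[key == rownames(mem$c), ])
  }
  flat <- as.numeric(t(xyz))
  for (k in 2:(length(ids) - 1)) {
    at <- (k - 1) * 3  # index of N(k) among atoms
    phi_ref <- bio3d::torsion.xyz(flat[(3 * (at - 1) + 1):(3 * (at + 3))])
    phi_ref <- phi_ref[!is.na(phi_ref)][1]
    expect_equal(tor$phi[tor$id == ids[k]], phi_ref, tolerance = 1e-6)
  }
})

test_that("circular deviation respects wrap-around and 360-degree shifts", {
  expect_equal(circ_dev(c(-179, 179)), 1, tolerance = 0.01)
  expect_equal(circ_dev(c(-179, 179), method = "range"), 2, tolerance = 1e-9)
  set.seed(2)
  a <- stats::rnorm(30, mean = 170, sd = 8)
  shifted <- a + 360 * rbinom(30, 1, 0.5)
  expect_equal(circ_dev(a), circ_dev(shifted), tolerance = 1e-9)
  expect_equal(circ_dev(a, "range"), circ_dev(shifted, "range"),
               tolerance = 1e-9)
  expect_identical(circ_dev(c(10)), NA_real_)
  expect_equal(circ_dev(c(42, 42, 42)), 0)
})

test_that("identical members give zero torsion deviation everywhere", {
  ens <- generate_ensemble(generator_spec(n_members = 3, seed = 1,
                                          trans_sigma = 0, rot_sigma = 0,
                                          coord_sigma = 0), defn)
  td <- torsion_deviation(ens, defn)
  expect_true(all(td$sections$dev_phi < 1e-6, na.rm = TRUE))
  expect_true(all(td$sections$dev_psi < 1e-6, na.rm = TRUE))
})

test_that("dihedrals are invariant under rigid motion of a member", {
  ens <- generate_ensemble(generator_spec(n_members = 2, seed = 10,
                                          coord_sigma = 0.2), defn)
  mem <- ens$members[[1]]
  t1 <- torsions_for_bundle(mem, defn)
  set.seed(123)
  rg <- random_rigid()
  mv <- function(m) { out <- apply_rigid(m, rg); rownames(out) <- rownames(m); out }
  moved <- aligned_bundle(mv(mem$ca), defn, n = mv(mem$n), c = mv(mem$c),
                          source_id = "M")
  t2 <- torsions_for_bundle(moved, defn)
  expect_equal(t1$phi, t2$phi, tolerance = 1e-6)
  expect_equal(t1$psi, t2$psi, tolerance = 1e-6)
})

test_that("section averages stay within the per-position deviation range", {
  ens <- generate_ensemble(generator_spec(n_members = 6, seed = 11,
                                          coord_sigma = 0.25), defn)
  td <- torsion_deviation(ens, defn)
  pos <- td$positions
  for (i in seq_len(nrow(td$sections))) {
    sel <- pos$helix == td$sections$helix[i] &
      pos$section == td$sections$section[i] & pos$n_phi >= 2 &
      !is.na(pos$dev_phi)
    if (!any(sel)) next
    expect_gte(td$sections$dev_phi[i], min(pos$dev_phi[sel]) - 1e-12)
    expect_lte(td$sections$dev_phi[i], max(pos$dev_phi[sel]) + 1e-12)
  }
})

test_that("injected section-level angle noise is recovered", {
  ts <- matrix(0, 7, 5)
  ts[3, 4] <- 5  # 5 degrees of phi/psi noise in section III.4 only
  ens <- generate_ensemble(generator_spec(n_members = 20, seed = 17,
                                          coord_sigma = 0,
                                          torsion_sigma = ts), defn)
  td <- torsion_deviation(ens, defn)
  hit <- td$sections[td$sections$label == "III.4", ]
  expect_equal(hit$dev_phi, 5, tolerance = 1.5)
  expect_equal(hit$dev_psi, 5, tolerance = 1.5)
  quiet <- td$sections[td$sections$label %in% c("III.2", "V.3", "I.1"), ]
  expect_true(all(quiet$dev_phi < 1, na.rm = TRUE))
})
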