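defn <- default_bundle()

test_that("PDB fixtures round-trip through read_chain/apply_alignment", {
  dir <- withr::local_tempdir()
  spec <- generator_spec(n_members = 3, seed = 7)
  ens <- generate_ensemble(spec, defn, dir = dir)
  align <- read_alignment_table(file.path(dir, "alignment.tsv"))
  for (k in 1:3) {
    mem <- ens$members[[k]]
    rec <- read_chain(file.path(dir, paste0(mem$source_id, ".pdb")), "A")
    al <- align[align$source_id == mem$source_id, ]
    bun <- apply_alignment(rec, setNames(al$bw, al$residue), defn,
                           source_id = mem$source_id)
    expect_identical(bun$present, mem$present)
    # PDB prints 3 decimals
    expect_equal(bun$ca, mem$ca, tolerance = 1e-3)
    expect_equal(unname(bun$b), unname(mem$b), tolerance = 1e-2)
    expect_equal(bun$n, mem$n, tolerance = 1e-3)
  }
})

test_that("altloc conformer A wins regardless of record order", {
  lines_a_first <- c(
    pdb_atom_line(1, "CA", 10, 1, 1, 1, alt = "A"),
    pdb_atom_line(2, "CA", 10, 9, 9, 9, alt = "B"),
    pdb_atom_line(3, "CA", 11, 2, 2, 2),
    "END")
  lines_b_first <- c(
    pdb_atom_line(1, "CA", 10, 9, 9, 9, alt = "B"),
    pdb_atom_line(2, "CA", 10, 1, 1, 1, alt = "A"),
    pdb_atom_line(3, "CA", 11, 2, 2, 2),
    "END")
  f1 <- withr::local_tempfile(fileext = ".pdb")
  f2 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines_a_first, f1)
  writeLines(lines_b_first, f2)
  r1 <- read_chain(f1, "A")
  r2 <- read_chain(f2, "A")
  r1 <- r1[order(r1$resno), ]
  r2 <- r2[order(r2$resno), ]
  expect_equal(r1$x, c(1, 2))
  expect_equal(r2$x, c(1, 2))
})

test_that("missing chains and residues are handled explicitly", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(pdb_atom_line(1, "CA", 10, 1, 1, 1), "END"), f)
  expect_error(read_chain(f, "B"), "available: A")
  expect_error(read_chain("/nonexistent/file.pdb", "A"), "no such")

  # a residue mapped in the alignment but absent from the file lands in
  # the missing set
  rec <- read_chain(f, "A")
  bun <- apply_alignment(rec, c(`10` = bw_id(4, 39), `11` = bw_id(4, 40)),
                         defn)
  expect_true(bw_id(4, 40) %in% bun$missing)
  expect_false(bw_id(4, 39) %in% bun$missing)
  expect_equal(length(bun$missing), 199L)
})

test_that("apply_alignment rejects double-mapped BW positions", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(pdb_atom_line(1, "CA", 10, 1, 1, 1),
               pdb_atom_line(2, "CA", 11, 2, 2, 2), "END"), f)
  rec <- read_chain(f, "A")
  expect_error(apply_alignment(rec, c(`10` = bw_id(3, 50),
                                      `11` = bw_id(3, 50)), defn),
               "one BW position")
})

test_that("serial extension from the *.50 anchors matches explicit tables", {
  # serial-extension rule: residue numbers map onto consecutive BW indices in
  # both directions from each anchor, no gap insertion
  anchor_res <- c(150L, 250L, 350L, 450L, 550L, 650L, 750L)
  serial <- integer(0)
  keys <- character(0)
  for (h in 1:7) {
    hrow <- defn$helices[h, ]
    idx <- seq.int(hrow$start, hrow$end)
    res <- anchor_res[h] + (idx - 50L)
    serial <- c(serial, bw_id(h, idx))
    keys <- c(keys, as.character(res))
  }
  explicit <- setNames(serial, keys)
  # equivalent table built independently by offset arithmetic
  spec <- generator_spec(n_members = 2, seed = 1)
  ens <- generate_ensemble(spec, defn)
  mem <- ens$members[[1]]
  m <- mem$ca
  rownames(m) <- keys[match(mem$present, serial)]
  rec <- data.frame(resno = as.integer(rownames(m)), insert = "",
                    elety = "CA", x = m[, 1], y = m[, 2], z = m[, 3], b = 30)
  bun <- apply_alignment(rec, explicit, defn)
  expect_identical(bun$present, mem$present)
})

test_that("mean C-alpha B-factor and chain selection by lower mean", {
  b1 <- make_ca_bundle(list(`3.50` = c(0, 0, 0), `3.52` = c(5, 0, 0),
                            `3.54` = c(10, 0, 0)), defn,
                       b = setNames(c(10, 20, 30),
                                    bw_parse(c("3.50", "3.52", "3.54"))))
  expect_equal(mean_ca_bfactor(b1), 20)
  b2 <- make_ca_bundle(list(`3.50` = c(0, 0, 0), `3.52` = c(5, 0, 0),
                            `3.54` = c(10, 0, 0)), defn,
                       b = setNames(c(30, 30, 30),
                                    bw_parse(c("3.50", "3.52", "3.54"))))
  expect_equal(mean_ca_bfactor(b2), 30)
  chains <- list(b1, b2)
  best <- chains[[which.min(vapply(chains, mean_ca_bfactor, 0))]]
  expect_identical(best, b1)
  b3 <- make_ca_bundle(list(`3.50` = c(0, 0, 0), `3.52` = c(5, 0, 0)), defn)
  expect_error(mean_ca_bfactor(b3), "no B-factors")
})

test_that("ensemble common positions shrink with gapped members", {
  spec <- preset("gapped", seed = 3)
  ens <- generate_ensemble(spec, defn)
  expect_equal(length(ens$common), 195L)
  expect_equal(nrow(enumerate_pairs(defn, ens$common)), 18915L)
  # one gap only
  spec1 <- generator_spec(n_members = 4, seed = 3,
                          missing = list(`2` = "4.39"))
  ens1 <- generate_ensemble(spec1, defn)
  expect_equal(nrow(enumerate_pairs(defn, ens1$common)), 19701L)
  # complete members: full universe
  ens0 <- generate_ensemble(generator_spec(n_members = 3, seed = 3), defn)
  expect_equal(nrow(enumerate_pairs(defn, ens0$common)), 19900L)

  # monotonicity: adding a member never grows the intersection
  grown <- build_set(c(ens0$members, ens1$members), "grown")
  expect_true(all(grown$common %in% ens0$common))
  expect_lte(length(grown$common), length(ens0$common))

  expect_error(build_set(ens0$members[1]), "at least 2")
})
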