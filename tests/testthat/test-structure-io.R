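test_that("structures round-trip through PDB with coordinates preserved", {
  st <- make_cylinder_structure(inner_radius = 2, length = 10,
                                atoms_per_ring = 8)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(st, f)
  st2 <- read_structure(f, dialect = "pdb")
  expect_equal(nrow(st2$atoms), nrow(st$atoms))
  expect_lt(max(abs(coords(st2) - coords(st))), 1e-3)
  expect_equal(st2$atoms$resno, st$atoms$resno)
})

test_that("a single-ATOM PDB file yields a one-atom structure", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1       1.000   2.000   3.000  1.00 10.00           N",
    "END"), f)
  st <- read_structure(f)
  expect_equal(nrow(st$atoms), 1L)
  expect_equal(unname(unlist(st$atoms[1, c("x", "y", "z")])), c(1, 2, 3))
  expect_equal(st$atoms$vdw, 1.55)  # nitrogen from the documented table
})

test_that("multi-model files return only the requested model's atoms", {
  f <- withr::local_tempfile(fileext = ".pdb")
  atom_line <- function(serial, x)
    sprintf("ATOM  %5d  CA  GLY A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
            serial, serial, x, 0, 0)
  writeLines(c("MODEL        1",
               vapply(1:4, function(i) atom_line(i, i), character(1)),
               "ENDMDL",
               "MODEL        2",
               vapply(1:4, function(i) atom_line(i, i + 100), character(1)),
               "ENDMDL", "END"), f)
  m1 <- read_structure(f, model = 1)
  m2 <- read_structure(f, model = 2)
  expect_equal(nrow(m1$atoms), 4L)
  expect_equal(nrow(m2$atoms), 4L)
  expect_equal(m2$atoms$x, m1$atoms$x + 100)
  expect_error(read_structure(f, model = 3), "model")
})

test_that("mmCIF input parses atom_site records", {
  f <- withr::local_tempfile(fileext = ".cif")
  writeLines(c(
    "data_test", "loop_",
    paste0("_atom_site.", c("group_PDB", "id", "type_symbol",
                            "label_atom_id", "label_alt_id", "label_comp_id",
                            "label_asym_id", "label_entity_id",
                            "label_seq_id", "pdbx_PDB_ins_code", "Cartn_x",
                            "Cartn_y", "Cartn_z", "occupancy",
                            "B_iso_or_equiv", "pdbx_formal_charge",
                            "auth_seq_id", "auth_comp_id", "auth_asym_id",
                            "auth_atom_id", "pdbx_PDB_model_num")),
    "ATOM 1 N N . ALA A 1 1 ? 1.000 2.000 3.000 1.00 10.00 ? 1 ALA A N 1",
    "ATOM 2 C CA . ALA A 1 1 ? 2.000 2.500 3.000 1.00 10.00 ? 1 ALA A CA 1"),
    f)
  st <- read_structure(f, dialect = "mmcif")
  expect_equal(nrow(st$atoms), 2L)
  expect_equal(st$atoms$x, c(1, 2))
  expect_equal(st$atoms$name, c("N", "CA"))
})

test_that("alternate locations keep the highest-occupancy conformer", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA AGLY A   1       0.000   0.000   0.000  0.40  0.00           C",
    "ATOM      2  CA BGLY A   1       5.000   0.000   0.000  0.60  0.00           C",
    "END"), f)
  st <- read_structure(f)
  expect_equal(nrow(st$atoms), 1L)
  expect_equal(st$atoms$x, 5)
})

test_that("unknown elements get the default radius with a warning", {
  atoms <- data.frame(name = "Q1", element = "QQ", resname = "UNK",
                      resno = 1, chain = "A", x = 0, y = 0, z = 0)
  expect_warning(st <- as_structure(atoms), "unknown element")
  expect_equal(st$atoms$vdw, 1.70)
})

test_that("duplicate atom identities are rejected", {
  atoms <- data.frame(name = c("CA", "CA"), element = "C", resname = "GLY",
                      resno = 1, chain = "A", x = 0:1, y = 0, z = 0)
  expect_error(as_structure(atoms), "duplicated")
})

test_that("superposition is exact for rigid motions and matches Kabsch", {
  st <- make_cylinder_structure(inner_radius = 2, length = 10,
                                atoms_per_ring = 8)
  # self-superposition
  expect_equal(superpose(st, st)$rmsd, 0, tolerance = 1e-10)
  # 90 degrees about z plus translation is recovered exactly
  moved <- transform_structure(st, rot_z(pi / 2), c(3, -2, 7))
  fit <- superpose(moved, st)
  expect_lt(fit$rmsd, 1e-8)
  expect_lt(max(abs(coords(fit$structure) - coords(st))), 1e-6)
  # 4-atom toy with one displaced atom: rmsd equals closed-form Kabsch
  ref <- matrix(c(0, 0, 0, 1, 0, 0, 0, 1, 0, 0, 0, 1), 4, 3, byrow = TRUE)
  mob <- ref; mob[4, ] <- mob[4, ] + c(1, 0, 0)
  mk <- function(m, id) as_structure(
    data.frame(name = paste0("C", 1:4), element = "C", resname = "UNK",
               resno = 1:4, chain = "A", x = m[, 1], y = m[, 2], z = m[, 3]),
    id = id)
  fit <- superpose(mk(mob, "mob"), mk(ref, "ref"))
  expect_equal(fit$rmsd, kabsch_rmsd(mob, ref), tolerance = 1e-6)
  # no random rigid motion of the mobile set does better than the optimum
  set.seed(7)
  best_random <- min(vapply(1:100, function(i) {
    ax <- rnorm(3); R <- aqpscope:::rotation_about(ax, runif(1, 0, 2 * pi))
    m <- sweep(mob %*% t(R), 2, rnorm(3, sd = 0.3), "+")
    # optimal translation for this rotation: align centroids
    m <- sweep(m, 2, colMeans(m) - colMeans(ref))
    sqrt(mean(rowSums((m - ref)^2)))
  }, numeric(1)))
  expect_gte(best_random, fit$rmsd - 1e-9)
})

test_that("superposition rejects degenerate pairings", {
  line <- as_structure(data.frame(
    name = paste0("C", 1:4), element = "C", resname = "UNK", resno = 1:4,
    chain = "A", x = 1:4, y = 0, z = 0), id = "line")
  expect_error(superpose(line, line), "collinear")
  two <- as_structure(data.frame(
    name = paste0("C", 1:2), element = "C", resname = "UNK", resno = 1:2,
    chain = "A", x = 1:2, y = 0, z = 1), id = "two")
  expect_error(superpose(two, two), "at least 3")
})

test_that("FASTA records round-trip and enforce the amino-acid alphabet", {
  rec <- tip2_like_sequence()
  f <- withr::local_tempfile(fileext = ".fa")
  write_fasta(rec, f)
  back <- read_fasta(f)
  expect_length(back, 1L)
  expect_equal(back[[1]]$residues, rec$residues)
  expect_error(sequence_record("bad", "ACDEFZ"), "invalid residue")
})
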