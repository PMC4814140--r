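test_that("NPA motifs are located with the relaxed-pattern fallback", {
  seq <- tip2_like_sequence()
  npa <- locate_npa(seq)
  expect_equal(as.numeric(npa), c(83, 197))
  # second motif degraded to NPS: both still found, with a warning
  rel <- mutate_sequence(seq, 199, "S")
  expect_warning(npa2 <- locate_npa(rel), "relaxed")
  expect_equal(as.numeric(npa2), c(83, 197))
  # no motif at all
  none <- sequence_record("none", strsplit(paste(rep("ACDEFGIKLM", 12),
                                                 collapse = ""), "")[[1]] |>
                            paste(collapse = ""))
  expect_error(locate_npa(none), "ambiguous")
})

test_that("sequence annotation resolves the five filter positions", {
  ann <- annotate_filter_sequence(tip2_like_sequence())
  pos <- ann$positions
  expect_equal(pos$resno[match(c("H2P", "LCP", "H5P", "LEP", "HEP"),
                               pos$position)],
               c(63, 131, 185, 194, 200))
  expect_equal(pos$aa[match(c("H2P", "LCP", "H5P", "LEP", "HEP"),
                            pos$position)],
               c("H", "H", "I", "G", "R"))
  expect_equal(unclass(filter_code(ann)), "HHIGR")
  expect_equal(ann$npa1, 83)
  expect_equal(ann$npa2, 197)
  # planted LCP substitution flows into the code
  mut <- mutate_sequence(tip2_like_sequence(), 131, "F")
  expect_equal(unclass(filter_code(annotate_filter_sequence(mut))), "HFIGR")
  # a scrambled non-channel sequence fails at anchoring
  set.seed(3)
  scram <- sequence_record("scrambled", paste(
    sample(strsplit(tip2_like_sequence()$residues, "")[[1]]), collapse = ""))
  expect_error(annotate_filter_sequence(scram))
})

test_that("specificity classification follows the documented rules", {
  expect_equal(classify_specificity("HHIGR")$call, "aquaammoniaporin")
  expect_equal(classify_specificity("HFIGR")$call, "aquaammoniaporin")
  expect_equal(classify_specificity("FNHCR")$call, "water_specific")
  expect_equal(classify_specificity("WGGFR")$call, "glycerol_like")
  un <- classify_specificity("FHHCR")
  expect_equal(un$call, "unknown")
  expect_match(un$rationale, "need")
  expect_error(classify_specificity("HH1GR"), "invalid")
  expect_error(classify_specificity("HHGR"), "5 letters")
  # purity: repeated calls agree
  codes <- c("HHIGR", "FNHCR", "HHICR", "FHICR")
  expect_identical(vapply(codes, function(cd)
    classify_specificity(cd)$call, character(1)),
    vapply(codes, function(cd) classify_specificity(cd)$call, character(1)))
})

test_that("dual-permeability requirement is flagged for hydrophobic H5P with bulky LEP", {
  expect_true(classify_specificity("HHICR")$flags[["requires_dual_permeability"]])
  expect_true(classify_specificity("FNICR")$flags[["requires_dual_permeability"]])
  expect_false(classify_specificity("HHIGR")$flags[["requires_dual_permeability"]])
})

test_that("classification matches growth complementation for the 14 assayed codes", {
  cc <- reference_complementation()
  expect_equal(nrow(cc), 14L)
  pred <- predict_complementation(cc$code)
  exceptions <- cc$in_vivo_exception
  expect_equal(sum(exceptions), 3L)
  # all exceptions carry the dual-permeability flag
  expect_true(all(pred$flagged[exceptions]))
  # outside the documented exceptions, prediction equals the assay outcome
  expect_equal(pred$predicted[!exceptions], cc$complementation[!exceptions])
})

test_that("structure annotation finds pore-facing residues geometrically", {
  st <- make_cylinder_structure(inner_radius = 4, length = 24,
                                atoms_per_ring = 16)
  ax <- attr(st, "truth")$axis
  # lone histidine protruding into the SF window lands at LCP
  st1 <- add_filter_residue(st, 500, "HIS", z = 5, axial_distance = 2,
                            tip_atom = "NE2")
  ann1 <- annotate_filter_structure(st1, ax)
  expect_equal(ann1$positions$resno[ann1$positions$position == "LCP"], 500)
  # residues at known axial distances: exactly those within 4.5 A qualify
  st2 <- add_filter_residue(st1, 501, "ARG", z = 7, axial_distance = 3,
                            tip_atom = "NH1", angle = pi / 2)
  st2 <- add_filter_residue(st2, 502, "ILE", z = 6, axial_distance = 6,
                            tip_atom = "CD1", angle = pi)
  ann2 <- annotate_filter_structure(st2, ax)
  cand <- attr(ann2, "candidates")
  expect_true(all(c(500, 501) %in% cand$resno))
  expect_false(502 %in% cand$resno)
  expect_equal(ann2$positions$resno[ann2$positions$position == "HEP"], 501)
  # reversing the axis direction with the mirrored window keeps the residues
  axr <- channel_axis(ax$origin, -ax$direction, ax$z_min, ax$z_max)
  ann3 <- annotate_filter_structure(st2, axr, z_window = c(-12, -1))
  expect_setequal(attr(ann3, "candidates")$resno, cand$resno)
  # empty window errors
  expect_error(annotate_filter_structure(st, ax), "no filter candidates")
})

test_that("structure and sequence annotation agree on synthetic channels", {
  st <- make_cylinder_structure(inner_radius = 4, length = 24,
                                atoms_per_ring = 16)
  ax <- attr(st, "truth")$axis
  st <- add_filter_residue(st, 63, "HIS", z = 4, axial_distance = 2.5,
                           tip_atom = "NE2", angle = 0)
  st <- add_filter_residue(st, 131, "HIS", z = 6, axial_distance = 2,
                           tip_atom = "NE2", angle = pi / 2)
  st <- add_filter_residue(st, 185, "ILE", z = 5, axial_distance = 3,
                           tip_atom = "CD1", angle = pi)
  st <- add_filter_residue(st, 194, "GLY", z = 7, axial_distance = 2.5,
                           mode = "carbonyl", angle = 3 * pi / 2)
  st <- add_filter_residue(st, 200, "ARG", z = 8, axial_distance = 2.2,
                           tip_atom = "NH1", angle = pi / 4)
  ann <- annotate_filter_structure(st, ax, sequence = tip2_like_sequence())
  seq_ann <- annotate_filter_sequence(tip2_like_sequence())
  expect_equal(ann$positions$resno, seq_ann$positions$resno)
  expect_length(ann$conflicts, 0)
})

test_that("carbonyl spatial group follows the LCP-asparagine hydrogen bond", {
  toy <- function(lcp_res, nd2_dist) {
    atoms <- rbind(
      data.frame(name = "O", element = "O", resname = "GLY", resno = 194,
                 chain = "A", x = 0, y = 0, z = 0),
      data.frame(name = "CA", element = "C", resname = "GLY", resno = 194,
                 chain = "A", x = 1.5, y = 0, z = 0),
      data.frame(name = if (lcp_res == "ASN") "ND2" else "NE2",
                 element = "N", resname = lcp_res, resno = 131,
                 chain = "A", x = nd2_dist, y = 0, z = 0))
    as_structure(atoms, id = "toy")
  }
  ann <- structure(list(positions = data.frame(
    position = c("LCP", "LEP"),
    resno = c(131, 194),
    aa = c("N", "G"))), class = "filter_annotation")
  g1 <- carbonyl_group(toy("ASN", 3.0), ann)
  expect_equal(g1$group, "II")
  expect_equal(g1$hbond_distance, 3.0)
  g2 <- carbonyl_group(toy("ASN", 4.2), ann)
  expect_equal(g2$group, "I")
  ann_his <- ann
  ann_his$positions$aa[1] <- "H"
  g3 <- carbonyl_group(toy("HIS", 3.0), ann_his)
  expect_equal(g3$group, "I")
  expect_true(is.na(g3$hbond_distance))
  # missing atom is reported by name
  broken <- toy("ASN", 3.0)
  broken$atoms <- broken$atoms[broken$atoms$name != "ND2", ]
  expect_error(carbonyl_group(broken, ann), "ND2")
})
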