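# Extended selectivity-filter annotation and specificity classification.
#
# Aquaporin substrate specificity is read from five pore-lining positions:
# H2P (helix 2), LCP (loop C), H5P (helix 5), LEP (loop E, backbone
# carbonyl) and HEP (the conserved helix E arginine).  In AtTIP2;1 these are
# His63, His131, Ile185, Gly194 and Arg200, with the NPA asparagines at
# residues 83 and 197.  Sequence annotation anchors the positions to the two
# NPA motifs; structure annotation reads them geometrically from pore-facing
# side chains.

.filter_positions <- c("H2P", "LCP", "H5P", "LEP", "HEP")

#' Locate the two NPA motifs of an aquaporin sequence
#'
#' Finds the asparagines of the two Asn-Pro-Ala signature motifs, the first
#' in the N-terminal half and the second in the C-terminal half of the
#' sequence.  When fewer than two strict NPA matches exist, the relaxed
#' pattern N-P-[AST] is also considered, with a warning.
#'
#' @param record A \code{sequence_record} (length >= 100).
#' @return Integer vector \code{c(npa1, npa2)} of the 1-based indices of the
#'   two motif asparagines, with all candidate positions as attribute
#'   \code{candidates}.
#' @export
locate_npa <- function(record) {
  stopifnot(inherits(record, "sequence_record"))
  s <- record$residues
  n <- nchar(s)
  if (n < 100) stop("sequence too short for NPA anchoring (need >= 100 aa)")
  find <- function(pat) {
    m <- gregexpr(pat, s, perl = TRUE)[[1]]
    if (m[1] == -1L) integer(0) else as.integer(m)
  }
  strict <- find("NPA")
  cand <- strict
  if (length(strict) < 2) {
    relaxed <- setdiff(find("NP[AST]"), strict)
    if (length(relaxed)) {
      warning("relaxed NPA motif (N-P-[AST]) used at position(s) ",
              paste(relaxed, collapse = ", "))
      cand <- sort(c(strict, relaxed))
    }
  }
  first <- cand[cand <= n / 2]
  second <- cand[cand > n / 2]
  if (length(first) != 1 || length(second) != 1)
    stop("ambiguous NPA anchoring: candidate motifs at [",
         paste(cand, collapse = ", "), "] (need exactly one per half)")
  structure(c(npa1 = first, npa2 = second), candidates = cand)
}

#' Default NPA-relative offsets of the selectivity-filter positions
#'
#' Offsets calibrated on AtTIP2;1 (NPA asparagines 83/197; filter residues
#' His63, Ile185, Gly194, Arg200): H2P = npa1 - 20, H5P = npa2 - 12,
#' LEP = npa2 - 3, HEP = npa2 + 3.  LCP is not offset-anchorable and is
#' located by a motif search in loop C (see
#' \code{\link{annotate_filter_sequence}}).
#'
#' @return Named numeric vector of offsets with names H2P, H5P, LEP, HEP and
#'   attribute \code{anchor} naming the NPA motif each offset counts from.
#' @export
default_filter_offsets <- function() {
  structure(c(H2P = -20, H5P = -12, LEP = -3, HEP = 3),
            anchor = c(H2P = "npa1", H5P = "npa2", LEP = "npa2", HEP = "npa2"))
}

aa_at <- function(s, i) substr(s, i, i)

#' Annotate the extended selectivity filter in a sequence
#'
#' Anchors H2P, H5P, LEP and HEP at fixed offsets from the NPA motifs
#' (\code{\link{default_filter_offsets}}, overridable) and locates LCP as the
#' His/Phe/Asn in the loop C segment (between H2P and H5P) nearest to
#' npa1 + 48, unless an explicit \code{lcp} residue number is supplied (e.g.
#' from a curated alignment).
#'
#' @param record A \code{sequence_record}.
#' @param offsets Named offset vector as in
#'   \code{\link{default_filter_offsets}}.
#' @param lcp Optional explicit residue number for LCP.
#' @param lcp_types Amino acids eligible for the LCP motif search.
#' @param lcp_target_offset Offset from npa1 the LCP search centres on.
#' @return Object of class \code{filter_annotation}: list with
#'   \code{positions} (data frame position/resno/aa), \code{npa1},
#'   \code{npa2}, \code{source} and \code{flags}.
#' @export
annotate_filter_sequence <- function(record, offsets = default_filter_offsets(),
                                     lcp = NULL, lcp_types = c("H", "F", "N"),
                                     lcp_target_offset = 48) {
  npa <- locate_npa(record)
  s <- record$residues
  n <- nchar(s)
  anchor <- attr(default_filter_offsets(), "anchor")
  resno <- setNames(integer(4), names(offsets))
  for (p in names(offsets)) {
    base <- if (anchor[[p]] == "npa1") npa[["npa1"]] else npa[["npa2"]]
    resno[[p]] <- base + offsets[[p]]
  }
  if (any(resno < 1 | resno > n))
    stop("filter offsets fall outside the sequence (length ", n, ")")
  if (is.null(lcp)) {
    lo <- resno[["H2P"]] + 1L
    hi <- resno[["H5P"]] - 1L
    seg <- strsplit(substr(s, lo, hi), "")[[1]]
    hits <- lo - 1L + which(seg %in% lcp_types)
    if (!length(hits))
      stop("no LCP candidate (", paste(lcp_types, collapse = "/"),
           ") found in loop C segment [", lo, ", ", hi, "]")
    target <- npa[["npa1"]] + lcp_target_offset
    lcp <- hits[which.min(abs(hits - target))]
  }
  pos <- data.frame(
    position = .filter_positions,
    resno = c(resno[["H2P"]], lcp, resno[["H5P"]], resno[["LEP"]],
              resno[["HEP"]]),
    stringsAsFactors = FALSE)
  pos$aa <- vapply(pos$resno, function(i) aa_at(s, i), character(1))
  flags <- character(0)
  if (pos$aa[pos$position == "HEP"] != "R")
    flags <- c(flags, "hep_not_arginine")
  structure(list(positions = pos, npa1 = unname(npa[["npa1"]]),
                 npa2 = unname(npa[["npa2"]]), source = "sequence",
                 flags = flags, id = record$id),
            class = "filter_annotation")
}

#' @export
print.filter_annotation <- function(x, ...) {
  cat("<filter_annotation>", x$id, "(", x$source, ") code:",
      tryCatch(filter_code(x), error = function(e) "incomplete"), "\n")
  print(x$positions, row.names = FALSE)
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Five-letter filter code
#'
#' The one-letter filter code in the order H2P, LCP, H5P, LEP, HEP (e.g.
#' HHIGR for AtTIP2;1, FNHCR for human AQP1).
#'
#' @param x A \code{filter_annotation} or a 5-letter string.
#' @return Character scalar of class \code{filter_code}.
#' @export
filter_code <- function(x) {
  if (inherits(x, "filter_annotation")) {
    aa <- x$positions$aa[match(.filter_positions, x$positions$position)]
    if (anyNA(aa)) stop("annotation has unresolved positions")
    code <- paste(aa, collapse = "")
  } else {
    code <- toupper(as.character(x))
  }
  if (nchar(code) != 5) stop("filter code must have exactly 5 letters")
  aa <- strsplit(code, "")[[1]]
  bad <- setdiff(aa, .aa_alphabet)
  if (length(bad)) stop("invalid amino-acid letter(s) in code: ",
                        paste(bad, collapse = ", "))
  structure(code, class = "filter_code")
}

.hydrophobic_h5 <- c("I", "V", "L", "A", "G")
.aromatic_lcp <- c("H", "F", "W", "Y")
.small_lep <- c("G", "A", "S", "C", "T")

#' Classify substrate specificity from a filter code
#'
#' A pure rule-based classifier on the 5-letter code (order H2P, LCP, H5P,
#' LEP, HEP), applied in order:
#' \enumerate{
#'   \item H5P = H and LCP = N: \code{water_specific} (the helix-5 histidine
#'     of water channels, with the loop-C asparagine that pins the LEP
#'     carbonyl);
#'   \item H2P = H, LCP aromatic (H/F/W/Y), and either H5P small/hydrophobic
#'     (I/V/L/A/G) or H5P = H compensated by a small loop-E residue (G/A,
#'     whose carbonyl can still reach the substrate):
#'     \code{aquaammoniaporin} (the TIP2/AQP8 pattern);
#'   \item H2P in (W, F), H5P in (G, A, S) and a bulky LEP:
#'     \code{glycerol_like};
#'   \item otherwise \code{unknown}, with a rationale naming the failed
#'     clauses.
#' }
#' A separate flag \code{requires_dual_permeability} marks codes with a
#' hydrophobic H5P and an LEP outside (G, A): such channels can be
#' ammonia-selective in vitro yet fail ammonia-uptake growth complementation,
#' presumably because efficient uptake in vivo also needs water permeability
#' (restored by a small LEP residue).
#'
#' @param code A \code{filter_code} or 5-letter string.
#' @return Object of class \code{specificity_call}: list with \code{call},
#'   \code{rationale} and logical \code{flags}.
#' @export
classify_specificity <- function(code) {
  code <- filter_code(code)
  aa <- strsplit(unclass(code), "")[[1]]
  names(aa) <- .filter_positions
  flags <- c(requires_dual_permeability =
               unname(aa["H5P"] %in% c("I", "V", "L", "M", "F") &&
                      !aa["LEP"] %in% c("G", "A")))
  mk <- function(call, rationale)
    structure(list(call = call, rationale = rationale, code = code,
                   flags = flags), class = "specificity_call")
  if (aa["H5P"] == "H" && aa["LCP"] == "N")
    return(mk("water_specific",
              "helix-5 histidine with loop-C asparagine (water-channel pattern)"))
  if (aa["H2P"] == "H" && aa["LCP"] %in% .aromatic_lcp &&
      (aa["H5P"] %in% .hydrophobic_h5 ||
       (aa["H5P"] == "H" && aa["LEP"] %in% c("G", "A"))))
    return(mk("aquaammoniaporin",
              "helix-2 histidine, aromatic loop C, and a small/hydrophobic helix 5 or a helix-5 histidine offset by a small loop-E residue (TIP2/AQP8 pattern)"))
  if (aa["H2P"] %in% c("W", "F") && aa["H5P"] %in% c("G", "A", "S") &&
      !aa["LEP"] %in% .small_lep)
    return(mk("glycerol_like",
              "aromatic helix 2, small helix 5, bulky loop E (aquaglyceroporin pattern)"))
  failed <- c(
    sprintf("water rule: H5P=%s (need H) & LCP=%s (need N)", aa["H5P"], aa["LCP"]),
    sprintf("aquaammoniaporin rule: H2P=%s (need H) & LCP=%s (need H/F/W/Y) & H5P=%s (need I/V/L/A/G)",
            aa["H2P"], aa["LCP"], aa["H5P"]),
    sprintf("glycerol rule: H2P=%s (need W/F) & H5P=%s (need G/A/S) & LEP=%s (need bulky)",
            aa["H2P"], aa["H5P"], aa["LEP"]))
  mk("unknown", paste(failed, collapse = "; "))
}

#' @export
print.specificity_call <- function(x, ...) {
  cat("<specificity_call>", unclass(x$code), "->", x$call, "\n ",
      x$rationale, "\n")
  if (any(x$flags)) cat("  flags:",
                        paste(names(x$flags)[x$flags], collapse = ", "), "\n")
  invisible(x)
}

.backbone_names <- c("N", "CA", "C", "O", "OXT", "H", "HA", "HA2", "HA3",
                     "H1", "H2", "H3")

residue_table <- function(structure) {
  a <- structure$atoms
  key <- paste(a$chain, a$resno, a$insert)
  first <- !duplicated(key)
  data.frame(chain = a$chain[first], resno = a$resno[first],
             insert = a$insert[first], resname = a$resname[first],
             key = key[first], stringsAsFactors = FALSE)
}

aa3to1 <- function(resname) {
  out <- suppressWarnings(bio3d::aa321(resname))
  out[is.na(out) | out == ""] <- "X"
  out
}

#' Annotate the selectivity filter geometrically from a structure
#'
#' Candidate filter residues are those with a side-chain atom (or, for LEP,
#' the backbone carbonyl oxygen) within \code{cutoff} of the channel axis in
#' the selectivity-filter window (between the NPA region at z = 0 and the
#' non-cytosolic mouth).  When a sequence annotation is supplied as prior,
#' geometric candidates are reconciled with the sequence positions,
#' preferring geometry on conflict and recording the conflict; without a
#' prior, candidates are assigned by residue chemistry (arginine to HEP,
#' the pore-nearest aromatic to LCP, a second aromatic to H2P, hydrophobics
#' to H5P, backbone-carbonyl-only candidates to LEP).
#'
#' @param structure An \code{aqp_structure}.
#' @param axis A \code{channel_axis} with z = 0 at the NPA region.
#' @param sequence Optional \code{sequence_record} prior.
#' @param cutoff Axial distance cutoff in Angstrom (default 4.5).
#' @param z_window Length-2 axial window; default \code{c(1, axis$z_max)}.
#' @return A \code{filter_annotation} (source \code{"structure"}) with the
#'   candidate table as attribute \code{candidates} and any
#'   sequence/geometry conflicts in \code{$conflicts}.
#' @export
annotate_filter_structure <- function(structure, axis, sequence = NULL,
                                      cutoff = 4.5, z_window = NULL) {
  if (is.null(z_window)) z_window <- c(1, axis$z_max)
  z_window <- sort(z_window)
  a <- structure$atoms
  loc <- axis_local(coords(structure), axis)
  r <- sqrt(loc[, 1]^2 + loc[, 2]^2)
  inwin <- loc[, 3] >= z_window[1] & loc[, 3] <= z_window[2]
  near <- r <= cutoff & inwin
  sidechain <- !(a$name %in% .backbone_names)
  key <- paste(a$chain, a$resno, a$insert)
  res <- residue_table(structure)
  agg <- function(sel) {
    if (!any(sel)) return(setNames(numeric(0), character(0)))
    tapply(r[sel], key[sel], min)
  }
  sc_near <- agg(near & sidechain)
  bb_near <- agg(near & a$name == "O")
  cand <- res[res$key %in% union(names(sc_near), names(bb_near)), ]
  if (!nrow(cand))
    stop("no filter candidates within ", cutoff,
         " A of the axis in the z window [", z_window[1], ", ", z_window[2], "]")
  cand$aa <- aa3to1(cand$resname)
  cand$r_sidechain <- unname(sc_near[cand$key])
  cand$r_carbonyl <- unname(bb_near[cand$key])
  conflicts <- character(0)

  if (!is.null(sequence)) {
    seq_ann <- annotate_filter_sequence(sequence)
    pos <- seq_ann$positions
    for (i in seq_len(nrow(pos))) {
      p <- pos$position[i]
      ok_keys <- if (p == "LEP") cand$key[!is.na(cand$r_carbonyl) |
                                         !is.na(cand$r_sidechain)]
                 else cand$key[!is.na(cand$r_sidechain)]
      hit <- res$key[match(pos$resno[i], res$resno)]
      if (is.na(hit) || !(hit %in% ok_keys)) {
        alt <- cand[cand$aa == pos$aa[i], ]
        if (nrow(alt)) {
          conflicts <- c(conflicts, sprintf(
            "%s: sequence residue %d not at the pore; geometric candidate %d used",
            p, pos$resno[i], alt$resno[1]))
          pos$resno[i] <- alt$resno[1]
        } else {
          conflicts <- c(conflicts, sprintf(
            "%s: sequence residue %d has no pore-facing atoms within cutoff",
            p, pos$resno[i]))
        }
      }
    }
    out <- seq_ann
    out$positions <- pos
    out$source <- "structure"
    out$conflicts <- conflicts
    out$id <- structure$id
    attr(out, "candidates") <- cand
    return(out)
  }

  assign_one <- function(keys) {
    if (!length(keys)) return(NA_integer_)
    cand$resno[match(keys[1], cand$key)]
  }
  by_r <- function(sel) {
    k <- cand$key[sel]
    k[order(cand$r_sidechain[sel])]
  }
  arg_keys <- by_r(cand$aa == "R" & !is.na(cand$r_sidechain))
  hep <- assign_one(arg_keys)
  arom <- by_r(cand$aa %in% .aromatic_lcp & !is.na(cand$r_sidechain))
  lcp <- assign_one(arom)
  h2p <- if (length(arom) > 1) assign_one(arom[-1]) else NA_integer_
  hyd <- by_r(cand$aa %in% c("I", "V", "L", "M") & !is.na(cand$r_sidechain))
  h5p <- assign_one(hyd)
  bbonly <- cand$key[!is.na(cand$r_carbonyl) & is.na(cand$r_sidechain)]
  bbonly <- bbonly[order(cand$r_carbonyl[match(bbonly, cand$key)])]
  lep <- assign_one(bbonly)
  resno <- c(H2P = h2p, LCP = lcp, H5P = h5p, LEP = lep, HEP = hep)
  pos <- data.frame(position = .filter_positions,
                    resno = unname(resno[.filter_positions]),
                    stringsAsFactors = FALSE)
  pos$aa <- ifelse(is.na(pos$resno), NA_character_,
                   cand$aa[match(pos$resno, cand$resno)])
  out <- structure(list(positions = pos, npa1 = NA_integer_,
                        npa2 = NA_integer_, source = "structure",
                        flags = if (any(is.na(pos$resno))) "unresolved"
                                else character(0),
                        conflicts = conflicts, id = structure$id),
                   class = "filter_annotation")
  attr(out, "candidates") <- cand
  out
}

#' Spatial group of the LEP backbone carbonyl
#'
#' Water-specific aquaporins carry an asparagine at LCP whose side-chain
#' amide can hydrogen-bond the LEP backbone carbonyl, pinning it toward the
#' pore centre (group II).  Channels without that asparagine (TIP2-like,
#' aquaglyceroporins, AQP4) leave the carbonyl in the relaxed orientation
#' (group I).  The call is: group II iff the LCP residue is Asn and its ND2
#' nitrogen lies within \code{cutoff} of the LEP carbonyl oxygen.
#'
#' @param structure An \code{aqp_structure}.
#' @param annotation A \code{filter_annotation} with LCP and LEP resolved.
#' @param cutoff Hydrogen-bond distance cutoff in Angstrom (default 3.5).
#' @return Object of class \code{carbonyl_group_call}: list with
#'   \code{group} ("I" or "II") and \code{hbond_distance} (Angstrom, NA when
#'   LCP is not asparagine).
#' @export
carbonyl_group <- function(structure, annotation, cutoff = 3.5) {
  pos <- annotation$positions
  lcp <- pos[pos$position == "LCP", ]
  lep <- pos[pos$position == "LEP", ]
  if (!nrow(lcp) || is.na(lcp$resno) || !nrow(lep) || is.na(lep$resno))
    stop("annotation must resolve LCP and LEP")
  a <- structure$atoms
  o_idx <- which(a$resno == lep$resno & a$name == "O")
  if (!length(o_idx))
    stop("missing atom: backbone O of LEP residue ", lep$resno)
  if (lcp$aa != "N") {
    return(structure(list(group = "I", hbond_distance = NA_real_,
                          lcp_aa = lcp$aa), class = "carbonyl_group_call"))
  }
  nd2_idx <- which(a$resno == lcp$resno & a$name == "ND2")
  if (!length(nd2_idx))
    stop("missing atom: ND2 of LCP asparagine ", lcp$resno)
  d <- sqrt(sum((c(a$x[o_idx[1]], a$y[o_idx[1]], a$z[o_idx[1]]) -
                 c(a$x[nd2_idx[1]], a$y[nd2_idx[1]], a$z[nd2_idx[1]]))^2))
  structure(list(group = if (d <= cutoff) "II" else "I",
                 hbond_distance = d, lcp_aa = "N"),
            class = "carbonyl_group_call")
}

#' Predicted growth-complementation outcome for a filter code
#'
#' Maps the mechanistic specificity call onto the +/- outcome of an
#' ammonia-uptake yeast growth assay: \code{aquaammoniaporin} predicts
#' complementation ("+"), all other calls predict failure ("-").  Codes
#' flagged \code{requires_dual_permeability} are marked: for those, in-vivo
#' growth can deviate from the in-vitro specificity (ammonia-specific
#' channels with too little water permeability fail to complement).
#'
#' @param codes Character vector of 5-letter filter codes.
#' @return Data frame with columns \code{code}, \code{call},
#'   \code{predicted} ("+"/"-") and \code{flagged}.
#' @export
predict_complementation <- function(codes) {
  calls <- lapply(codes, classify_specificity)
  data.frame(
    code = as.character(codes),
    call = vapply(calls, `[[`, character(1), "call"),
    predicted = vapply(calls, function(x)
      if (x$call == "aquaammoniaporin") "+" else "-", character(1)),
    flagged = vapply(calls, function(x)
      unname(x$flags["requires_dual_permeability"]), logical(1)),
    stringsAsFactors = FALSE)
}
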