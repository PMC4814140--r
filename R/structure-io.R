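#' @importFrom stats approx coef cor lm median optim rnorm runif sd setNames var
#' @importFrom utils head read.csv tail write.csv
NULL

# -- van der Waals radii -----------------------------------------------------

#' Element to van der Waals radius table
#'
#' Returns the element -> vdW radius map (in Angstrom) used when assigning
#' radii to atoms read from coordinate files.  The default table covers the
#' elements found in protein/nucleic structures; it can be replaced or
#' extended via a two-column CSV file (columns \code{element}, \code{radius}).
#'
#' @param path Optional path to a CSV file with columns \code{element} and
#'   \code{radius} overriding/extending the built-in table.
#' @return Named numeric vector of radii in Angstrom, names are upper-case
#'   element symbols.
#' @export
vdw_radius_table <- function(path = NULL) {
  tab <- c(H = 1.09, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
           P = 1.80, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98,
           SE = 1.90, FE = 1.94, ZN = 1.39, MG = 1.73, CA = 2.31,
           "NA" = 2.27, K = 2.75, MN = 1.97, CU = 1.40)
  if (!is.null(path)) {
    usr <- read.csv(path, stringsAsFactors = FALSE)
    if (!all(c("element", "radius") %in% names(usr)))
      stop("radius table must have columns 'element' and 'radius'")
    tab[toupper(usr$element)] <- usr$radius
  }
  tab
}

.default_vdw <- 1.70

assign_vdw <- function(element, table = vdw_radius_table()) {
  el <- toupper(trimws(element))
  r <- unname(table[el])
  unknown <- is.na(r)
  if (any(unknown)) {
    warning("unknown element(s) ", paste(unique(el[unknown]), collapse = ", "),
            "; assigned default radius ", .default_vdw, " A")
    r[unknown] <- .default_vdw
  }
  r
}

# -- Structure container -----------------------------------------------------

.atom_cols <- c("serial", "name", "element", "resname", "resno", "insert",
                "chain", "x", "y", "z", "occupancy", "b", "vdw")

#' Build a structure object from an atom table
#'
#' The structure container used throughout the package: a data frame of atoms
#' with coordinates in Angstrom, residue identity (chain, residue number,
#' insertion code), occupancy/B-factor and an assigned van der Waals radius.
#'
#' @param atoms Data frame with (at least) columns \code{name},
#'   \code{element}, \code{resname}, \code{resno}, \code{chain}, \code{x},
#'   \code{y}, \code{z}.  Missing \code{serial}, \code{insert},
#'   \code{occupancy}, \code{b} and \code{vdw} columns are filled with
#'   defaults (vdW radii from \code{\link{vdw_radius_table}}).
#' @param id Identifier string for the structure.
#' @param model_number Model number the atoms belong to (multi-model files).
#' @param radius_table Element radius map, see \code{\link{vdw_radius_table}}.
#' @return Object of class \code{aqp_structure}: a list with elements
#'   \code{atoms}, \code{id}, \code{model_number}.
#' @export
as_structure <- function(atoms, id = "structure", model_number = 1L,
                         radius_table = vdw_radius_table()) {
  stopifnot(is.data.frame(atoms))
  need <- c("name", "element", "resname", "resno", "chain", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss))
    stop("atom table lacks column(s): ", paste(miss, collapse = ", "))
  n <- nrow(atoms)
  if (is.null(atoms$serial)) atoms$serial <- seq_len(n)
  if (is.null(atoms$insert)) atoms$insert <- ""
  atoms$insert[is.na(atoms$insert)] <- ""
  if (is.null(atoms$occupancy)) atoms$occupancy <- 1
  if (is.null(atoms$b)) atoms$b <- 0
  if (is.null(atoms$vdw)) atoms$vdw <- assign_vdw(atoms$element, radius_table)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) stop("non-finite atom coordinates")
  if (any(atoms$vdw <= 0)) stop("vdw radii must be positive")
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$name)
  if (anyDuplicated(key))
    stop("duplicated (chain, residue, atom name) identity: ",
         key[duplicated(key)][1])
  structure(list(atoms = atoms[, .atom_cols], id = id,
                 model_number = as.integer(model_number)),
            class = "aqp_structure")
}

#' @export
print.aqp_structure <- function(x, ...) {
  cat("<aqp_structure>", x$id, "\n  atoms:", nrow(x$atoms),
      " chains:", paste(unique(x$atoms$chain), collapse = ","),
      " model:", x$model_number, "\n")
  invisible(x)
}

#' Atom coordinates of a structure
#'
#' @param structure An \code{aqp_structure}.
#' @return Numeric matrix (n x 3) of coordinates in Angstrom.
#' @export
coords <- function(structure) {
  as.matrix(structure$atoms[, c("x", "y", "z")])
}

infer_element <- function(name) {
  nm <- gsub("[0-9']", "", trimws(name))
  two <- toupper(substr(nm, 1, 2))
  tab <- vdw_radius_table()
  ifelse(two %in% names(tab) & nchar(nm) > 1 & two %in%
           c("CL", "BR", "SE", "FE", "ZN", "MG", "MN", "CU"),
         two, toupper(substr(nm, 1, 1)))
}

# -- Readers / writers -------------------------------------------------------

#' Read a structure from PDB or mmCIF
#'
#' Parses ATOM/HETATM records, resolves alternate locations by keeping the
#' highest-occupancy conformer, and assigns van der Waals radii by element.
#' Coordinates are treated as orthogonal Angstrom; no crystal-symmetry
#' expansion is performed.
#'
#' @param path Path to the coordinate file.
#' @param dialect One of \code{"auto"} (by file extension), \code{"pdb"},
#'   \code{"mmcif"}.
#' @param model Model number to extract from multi-model files (default 1).
#' @param radius_table Element radius map, see \code{\link{vdw_radius_table}}.
#' @return An \code{aqp_structure}.
#' @export
read_structure <- function(path, dialect = c("auto", "pdb", "mmcif"),
                           model = 1L, radius_table = vdw_radius_table()) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "auto") {
    ext <- tolower(tools::file_ext(path))
    dialect <- if (ext %in% c("cif", "mmcif")) "mmcif" else "pdb"
  }
  pdb <- tryCatch(
    if (dialect == "pdb") {
      bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE)
    } else {
      suppressWarnings(bio3d::read.cif(path))
    },
    error = function(e) stop("failed to parse ", path, " as ", dialect, ": ",
                             conditionMessage(e), call. = FALSE))
  at <- pdb$atom
  nmod <- if (is.matrix(pdb$xyz)) nrow(pdb$xyz) else 1L
  if (model > nmod)
    stop("model ", model, " requested but file has ", nmod, " model(s)")
  xyz <- if (is.matrix(pdb$xyz)) pdb$xyz[model, ] else as.numeric(pdb$xyz)
  xyz <- matrix(xyz, ncol = 3, byrow = TRUE)
  at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
  el <- at$elesy
  bad <- is.na(el) | el == ""
  el[bad] <- infer_element(at$elety[bad])
  atoms <- data.frame(
    serial = at$eleno, name = at$elety, element = el,
    resname = at$resid, resno = at$resno,
    insert = ifelse(is.na(at$insert), "", at$insert),
    chain = ifelse(is.na(at$chain), "A", at$chain),
    x = at$x, y = at$y, z = at$z,
    occupancy = ifelse(is.na(at$o), 1, at$o),
    b = ifelse(is.na(at$b), 0, at$b),
    stringsAsFactors = FALSE)
  # alternate locations: keep highest-occupancy conformer per atom identity
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$name)
  if (anyDuplicated(key)) {
    ord <- order(key, -atoms$occupancy)
    atoms <- atoms[ord, ][!duplicated(sort(key)), ]
    atoms <- atoms[order(atoms$serial), ]
  }
  as_structure(atoms, id = basename(path), model_number = model,
               radius_table = radius_table)
}

#' Write a structure as PDB
#'
#' @param structure An \code{aqp_structure}.
#' @param path Output file path.
#' @return Invisibly, \code{path}.
#' @export
write_structure <- function(structure, path) {
  a <- structure$atoms
  bio3d::write.pdb(file = path,
                   xyz = as.vector(t(as.matrix(a[, c("x", "y", "z")]))),
                   resno = a$resno, resid = a$resname, chain = a$chain,
                   eleno = a$serial, elety = a$name, insert = a$insert,
                   o = a$occupancy, b = a$b, elesy = a$element)
  invisible(path)
}

# -- Sequences ---------------------------------------------------------------

.aa_alphabet <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X")

#' Construct a protein sequence record
#'
#' @param id Sequence identifier.
#' @param residues One-letter amino-acid string (20 standard letters plus X).
#' @return Object of class \code{sequence_record}.
#' @export
sequence_record <- function(id, residues) {
  residues <- toupper(gsub("[-\\s]", "", residues, perl = TRUE))
  aa <- strsplit(residues, "")[[1]]
  bad <- setdiff(unique(aa), .aa_alphabet)
  if (length(bad))
    stop("invalid residue letter(s): ", paste(bad, collapse = ", "))
  structure(list(id = id, residues = residues), class = "sequence_record")
}

#' @export
print.sequence_record <- function(x, ...) {
  cat("<sequence_record>", x$id, "-", nchar(x$residues), "aa\n")
  invisible(x)
}

#' Read sequences from a FASTA file
#'
#' @param path Path to a FASTA file.
#' @return List of \code{sequence_record} objects.
#' @export
read_fasta <- function(path) {
  fa <- bio3d::read.fasta(path, rm.dup = FALSE)
  lapply(seq_along(fa$id), function(i) {
    res <- paste(fa$ali[i, fa$ali[i, ] != "-"], collapse = "")
    sequence_record(fa$id[i], res)
  })
}

#' Write sequence records to FASTA
#'
#' @param records A \code{sequence_record} or list of them.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_fasta <- function(records, path) {
  if (inherits(records, "sequence_record")) records <- list(records)
  lines <- unlist(lapply(records, function(r) c(paste0(">", r$id), r$residues)))
  writeLines(lines, path)
  invisible(path)
}

# -- Superposition -----------------------------------------------------------

#' Least-squares rigid-body superposition
#'
#' Superposes \code{mobile} onto \code{reference} using a Kabsch
#' least-squares fit over paired atoms, and applies the resulting rigid
#' transform to all atoms of \code{mobile}.
#'
#' @param mobile,reference \code{aqp_structure} objects.
#' @param pairing Optional data frame with columns \code{chain},
#'   \code{resno}, \code{name} naming the atoms used for the fit.  By default
#'   all atoms whose (chain, resno, name) identity occurs in both structures
#'   are paired.
#' @return List with \code{structure} (the transformed mobile) and
#'   \code{rmsd} (Angstrom, over the paired atoms).
#' @export
superpose <- function(mobile, reference, pairing = NULL) {
  key <- function(s) paste(s$atoms$chain, s$atoms$resno, s$atoms$name)
  km <- key(mobile); kr <- key(reference)
  if (is.null(pairing)) {
    common <- intersect(km, kr)
    im <- match(common, km); ir <- match(common, kr)
  } else {
    kp <- paste(pairing$chain, pairing$resno, pairing$name)
    im <- match(kp, km); ir <- match(kp, kr)
    if (anyNA(im) || anyNA(ir))
      stop("pairing names atoms absent from mobile or reference")
  }
  if (length(im) < 3)
    stop("superposition needs at least 3 paired atoms, got ", length(im))
  xr <- coords(reference)[ir, , drop = FALSE]
  xm <- coords(mobile)[im, , drop = FALSE]
  sv <- svd(scale(xr, scale = FALSE))$d
  if (sv[2] < 1e-8 * max(sv[1], 1))
    stop("paired atoms are collinear; superposition is underdetermined")
  fixed <- as.vector(t(xr))
  mob_all <- as.vector(t(coords(mobile)))
  inds_fit_fixed <- seq_along(fixed)
  inds_fit_mobile <- as.vector(t(outer(im, 1:3, function(i, k) 3 * (i - 1) + k)))
  moved <- bio3d::fit.xyz(fixed = fixed, mobile = mob_all,
                          fixed.inds = inds_fit_fixed,
                          mobile.inds = inds_fit_mobile)
  newxyz <- matrix(as.numeric(moved), ncol = 3, byrow = TRUE)
  out <- mobile
  out$atoms$x <- newxyz[, 1]; out$atoms$y <- newxyz[, 2]
  out$atoms$z <- newxyz[, 3]
  d <- newxyz[im, , drop = FALSE] - xr
  list(structure = out, rmsd = sqrt(mean(rowSums(d^2))))
}

#' Apply a rigid transform to a structure
#'
#' @param structure An \code{aqp_structure}.
#' @param rotation 3x3 rotation matrix.
#' @param translation Length-3 translation vector (applied after rotation).
#' @return Transformed \code{aqp_structure}.
#' @export
transform_structure <- function(structure, rotation = diag(3),
                                translation = c(0, 0, 0)) {
  xyz <- coords(structure) %*% t(rotation)
  xyz <- sweep(xyz, 2, translation, "+")
  structure$atoms$x <- xyz[, 1]
  structure$atoms$y <- xyz[, 2]
  structure$atoms$z <- xyz[, 3]
  structure
}
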