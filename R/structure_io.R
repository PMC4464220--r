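## structure_io: minimal multi-model PDB reading/writing, loop selection and
## the loop-loop centre-of-mass distance collective variable.

.atomic_masses <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, P = 30.973762,
  S = 32.06, MG = 24.305, K = 39.0983, NA. = 22.98977, CL = 35.45,
  F = 18.998, BR = 79.904, ZN = 65.38, MN = 54.938
)

.mass_for_element <- function(element) {
  m <- .atomic_masses[ifelse(element == "NA", "NA.", element)]
  m[is.na(m)] <- 12.011  # unknown elements get a generic heavy-atom mass
  unname(m)
}

## Guess an element symbol from a PDB atom name ("OP1" -> O, "C4'" -> C).
.element_from_name <- function(name) {
  s <- gsub("[0-9'*\"]", "", name)
  two <- toupper(substr(s, 1, 2))
  one <- toupper(substr(s, 1, 1))
  ifelse(two %in% c("MG", "CL", "NA", "ZN", "MN", "BR"), two, one)
}

.nuc_resname_map <- c(
  A = "A", ADE = "A", RA = "A", RA3 = "A", RA5 = "A", A3 = "A", A5 = "A", AN = "A",
  C = "C", CYT = "C", RC = "C", RC3 = "C", RC5 = "C", C3 = "C", C5 = "C", CN = "C",
  G = "G", GUA = "G", RG = "G", RG3 = "G", RG5 = "G", G3 = "G", G5 = "G", GN = "G",
  U = "U", URA = "U", URI = "U", RU = "U", RU3 = "U", RU5 = "U", U3 = "U", U5 = "U", UN = "U"
)

#' Default backbone atom selection
#'
#' The RNA backbone atoms used for loop centre-of-mass computation. Whether
#' the non-bridging phosphate oxygens OP1/OP2 belong to "the backbone" is a
#' modelling choice; both variants are offered.
#'
#' @param include_phosphate_oxygens include OP1/OP2 (default `TRUE`).
#' @return character vector of atom names.
#' @export
backbone_atoms <- function(include_phosphate_oxygens = TRUE) {
  base <- c("P", "O5'", "C5'", "C4'", "C3'", "O3'")
  if (include_phosphate_oxygens) base <- c("P", "OP1", "OP2", base[-1])
  base
}

#' Construct a structure model
#'
#' A light-weight container for one coordinate set (one PDB MODEL): a
#' data frame of atoms with names, residue indices/names, coordinates (in
#' Angstrom), element and mass. Residue names of ribonucleotides are
#' normalized to A, C, G, U; other residues (ligands, ions, water) are
#' retained but flagged `nucleotide = FALSE`.
#'
#' @param atoms data frame with columns `name`, `resname`, `resid`, `chain`,
#'   `x`, `y`, `z` (and optionally `element`, `mass`).
#' @param model_id integer model identifier.
#' @return object of class `StructureModel`.
#' @export
structure_model <- function(atoms, model_id = 1L) {
  need <- c("name", "resname", "resid", "chain", "x", "y", "z")
  if (!all(need %in% names(atoms))) {
    stop("atoms must have columns: ", paste(need, collapse = ", "))
  }
  atoms$name <- trimws(atoms$name)
  atoms$resname <- trimws(atoms$resname)
  if (is.null(atoms$element)) atoms$element <- .element_from_name(atoms$name)
  if (is.null(atoms$mass)) atoms$mass <- .mass_for_element(atoms$element)
  norm <- .nuc_resname_map[toupper(atoms$resname)]
  atoms$nucleotide <- !is.na(norm)
  atoms$resname[atoms$nucleotide] <- unname(norm[atoms$nucleotide])
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stop("non-finite coordinates in structure model")
  }
  if (any(atoms$mass <= 0)) stop("non-positive atomic mass")
  ## residue order must be non-decreasing per chain for nucleotides
  for (ch in unique(atoms$chain[atoms$nucleotide])) {
    r <- atoms$resid[atoms$nucleotide & atoms$chain == ch]
    firsts <- r[!duplicated(r)]
    if (is.unsorted(firsts, strictly = TRUE)) {
      stop("nucleotide residue indices not strictly increasing in chain '", ch, "'")
    }
  }
  structure(list(model_id = as.integer(model_id), atoms = atoms),
            class = "StructureModel")
}

#' @export
print.StructureModel <- function(x, ...) {
  nres <- length(unique(x$atoms$resid[x$atoms$nucleotide]))
  cat(sprintf("<StructureModel %d: %d atoms, %d nucleotide residues>\n",
              x$model_id, nrow(x$atoms), nres))
  invisible(x)
}

#' Define a loop by an inclusive residue range
#'
#' @param label loop label, e.g. `"L2"`.
#' @param from,to inclusive residue index range (PDB numbering).
#' @return object of class `LoopDefinition`.
#' @export
loop_definition <- function(label, from, to) {
  from <- as.integer(from); to <- as.integer(to)
  if (to < from) stop("empty loop range: ", from, "-", to)
  structure(list(label = label, from = from, to = to), class = "LoopDefinition")
}

.loops_disjoint <- function(a, b) (a$to < b$from) || (b$to < a$from)

#' Read a (multi-model) PDB file
#'
#' Parses ATOM/HETATM records into one [structure_model()] per MODEL block
#' (a single model if the file has no MODEL records). Only the first
#' alternate location indicator is kept; insertion codes raise an error.
#'
#' @param path path to a PDB file.
#' @return list of `StructureModel` objects.
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  if (!any(is_atom)) stop("no ATOM/HETATM records in ", path)
  model_no <- cumsum(rec == "MODEL ")
  model_no[model_no == 0] <- 1L

  idx <- which(is_atom)
  ln <- lines[idx]
  parse_num <- function(from, to, what) {
    v <- suppressWarnings(as.numeric(substr(ln, from, to)))
    bad <- which(!is.finite(v))
    if (length(bad)) {
      stop("unparseable ", what, " in PDB line ", idx[bad[1]], ": ",
           lines[idx[bad[1]]])
    }
    v
  }
  name <- trimws(substr(ln, 13, 16))
  altloc <- substr(ln, 17, 17)
  resname <- trimws(substr(ln, 18, 20))
  chain <- substr(ln, 22, 22)
  resid <- suppressWarnings(as.integer(substr(ln, 23, 26)))
  if (anyNA(resid)) {
    bad <- which(is.na(resid))[1]
    stop("unparseable residue number in PDB line ", idx[bad])
  }
  icode <- substr(ln, 27, 27)
  if (any(icode != " ")) {
    stop("insertion codes are not supported (line ",
         idx[which(icode != " ")[1]], ")")
  }
  x <- parse_num(31, 38, "x coordinate")
  y <- parse_num(39, 46, "y coordinate")
  z <- parse_num(47, 54, "z coordinate")
  element <- trimws(toupper(substr(ln, 77, 78)))
  element[element == ""] <- .element_from_name(name[element == ""])

  keep <- altloc %in% c(" ", "A")  # first altloc only
  df <- data.frame(name = name, resname = resname, resid = resid,
                   chain = chain, x = x, y = y, z = z, element = element,
                   mass = .mass_for_element(element),
                   stringsAsFactors = FALSE)[keep, , drop = FALSE]
  mno <- model_no[idx][keep]

  models <- lapply(sort(unique(mno)), function(m) {
    structure_model(df[mno == m, , drop = FALSE], model_id = m)
  })
  n_nuc <- sum(models[[1]]$atoms$nucleotide)
  if (n_nuc == 0) stop("no nucleotide residues found in ", path)
  models
}

#' Write structure models to a PDB file
#'
#' @param models a `StructureModel` or list of them.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(models, path) {
  if (inherits(models, "StructureModel")) models <- list(models)
  con <- file(path, "w")
  on.exit(close(con))
  multi <- length(models) > 1
  for (m in models) {
    if (multi) writeLines(sprintf("MODEL     %4d", m$model_id), con)
    a <- m$atoms
    nm <- ifelse(nchar(a$name) < 4, paste0(" ", a$name), a$name)
    recs <- sprintf("ATOM  %5d %-4s %-3s%2s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
                    seq_len(nrow(a)), nm, a$resname, a$chain, a$resid,
                    a$x, a$y, a$z, a$element)
    writeLines(recs, con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

.residue_atoms <- function(model, resid, chain = NULL) {
  a <- model$atoms
  sel <- a$resid == resid
  if (!is.null(chain)) sel <- sel & a$chain == chain
  a[sel, , drop = FALSE]
}

#' Centre of mass of loop backbone atoms
#'
#' Mass-weighted (default) or geometric mean position of the selected
#' backbone atoms of all residues in the loop range.
#'
#' @param model a `StructureModel`.
#' @param loop a [loop_definition()].
#' @param atom_set atom names to select; default [backbone_atoms()].
#' @param weighting `"mass"` (centre of mass) or `"geometric"` (centroid).
#' @return numeric length-3 position, Angstrom.
#' @export
backbone_com <- function(model, loop, atom_set = backbone_atoms(),
                         weighting = c("mass", "geometric")) {
  weighting <- match.arg(weighting)
  a <- model$atoms
  in_loop <- a$nucleotide & a$resid >= loop$from & a$resid <= loop$to
  sel <- in_loop & a$name %in% atom_set
  present <- unique(a$resid[sel])
  wanted <- loop$from:loop$to
  missing <- setdiff(intersect(wanted, unique(a$resid[a$nucleotide])), present)
  absent <- setdiff(wanted, unique(a$resid[a$nucleotide]))
  if (length(absent)) {
    stop("loop ", loop$label, ": residues absent from model: ",
         paste(absent, collapse = ", "))
  }
  if (length(missing)) {
    stop("loop ", loop$label, ": no atoms from the selection in residues: ",
         paste(missing, collapse = ", "))
  }
  s <- a[sel, , drop = FALSE]
  w <- if (weighting == "mass") s$mass else rep(1, nrow(s))
  c(sum(w * s$x), sum(w * s$y), sum(w * s$z)) / sum(w)
}

#' Loop-loop distance collective variable
#'
#' Euclidean distance between the backbone centres of mass of two loops;
#' the collective variable L of the umbrella-sampling design.
#'
#' @inheritParams backbone_com
#' @param loopA,loopB two disjoint [loop_definition()]s.
#' @return distance L in Angstrom.
#' @export
loop_distance <- function(model, loopA, loopB, atom_set = backbone_atoms(),
                          weighting = c("mass", "geometric")) {
  if (!.loops_disjoint(loopA, loopB)) {
    stop("loop definitions overlap: ", loopA$label, " and ", loopB$label)
  }
  ca <- backbone_com(model, loopA, atom_set, weighting)
  cb <- backbone_com(model, loopB, atom_set, weighting)
  sqrt(sum((ca - cb)^2))
}
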