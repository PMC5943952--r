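# Molecular data model: a light-weight 2D connection-table graph.
#
# Atoms carry an element symbol, a formal charge and an implicit hydrogen
# count; hydrogens are never graph nodes.  Bond orders are the SDF codes
# 1 (single), 2 (double), 3 (triple) and 4 (aromatic).

BOND_SINGLE   <- 1L
BOND_DOUBLE   <- 2L
BOND_TRIPLE   <- 3L
BOND_AROMATIC <- 4L

#' Construct a molecular graph
#'
#' The substrate for group perception: heavy atoms with formal charges and
#' implicit hydrogen counts, and bonds with order single/double/triple/
#' aromatic (stored as the V2000 codes 1, 2, 3, 4).  Hydrogen atoms are
#' materialised as per-atom counts, never as graph nodes.
#'
#' @param atoms data frame with columns `element` (symbol), `charge`
#'   (integer formal charge) and optionally `hcount` (implicit hydrogens;
#'   computed from a standard valence model when `NA` or absent).
#' @param bonds data frame with columns `i`, `j` (1-based atom indices) and
#'   `order` (1, 2, 3 or 4).
#' @param name,id molecule name and identifier.
#' @param props named character vector of SDF data fields, if any.
#' @return an object of class `molgraph`.
#' @export
molgraph <- function(atoms, bonds = NULL, name = "", id = name, props = character()) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  stopifnot(nrow(atoms) >= 1, "element" %in% names(atoms))
  if (is.null(atoms$charge)) atoms$charge <- 0L
  atoms$charge <- as.integer(atoms$charge)
  if (is.null(atoms$hcount)) atoms$hcount <- NA_integer_
  atoms$hcount <- as.integer(atoms$hcount)
  unknown <- setdiff(unique(atoms$element), KNOWN_ELEMENTS)
  if (length(unknown))
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))

  if (is.null(bonds) || nrow(as.data.frame(bonds)) == 0) {
    bonds <- data.frame(i = integer(), j = integer(), order = integer())
  } else {
    bonds <- as.data.frame(bonds, stringsAsFactors = FALSE)
    stopifnot(all(c("i", "j", "order") %in% names(bonds)))
    bonds$i <- as.integer(bonds$i); bonds$j <- as.integer(bonds$j)
    bonds$order <- as.integer(bonds$order)
    n <- nrow(atoms)
    if (any(bonds$i < 1 | bonds$i > n | bonds$j < 1 | bonds$j > n))
      stop("bond endpoint out of range")
    if (any(bonds$i == bonds$j)) stop("self-bond")
    key <- paste(pmin(bonds$i, bonds$j), pmax(bonds$i, bonds$j))
    if (anyDuplicated(key)) stop("duplicate bond")
    if (!all(bonds$order %in% 1:4)) stop("bond order must be 1, 2, 3 or 4")
  }
  m <- structure(list(atoms = atoms, bonds = bonds,
                      name = name, id = id, props = props),
                 class = "molgraph")
  if (anyNA(m$atoms$hcount)) m <- fill_hcounts(m)
  m
}

#' @export
print.molgraph <- function(x, ...) {
  cat(sprintf("<molgraph> %s (%d heavy atoms, %d bonds)\n",
              if (nzchar(x$id)) x$id else "<unnamed>",
              nrow(x$atoms), nrow(x$bonds)))
  invisible(x)
}

n_atoms <- function(mol) nrow(mol$atoms)

# Incidence list: for each atom, the indices of rows of mol$bonds touching it.
incident_bonds <- function(mol) {
  n <- n_atoms(mol)
  out <- vector("list", n)
  b <- mol$bonds
  if (nrow(b)) {
    for (k in seq_len(nrow(b))) {
      out[[b$i[k]]] <- c(out[[b$i[k]]], k)
      out[[b$j[k]]] <- c(out[[b$j[k]]], k)
    }
  }
  out
}

# Heavy-atom neighbours of atom a, with the order of the connecting bond.
atom_neighbors <- function(mol, a, inc = incident_bonds(mol)) {
  ks <- inc[[a]]
  if (!length(ks)) return(data.frame(j = integer(), order = integer()))
  b <- mol$bonds[ks, , drop = FALSE]
  data.frame(j = ifelse(b$i == a, b$j, b$i), order = b$order)
}

# Explicit bond-order sum of one atom (aromatic counts 1.5, rounded down
# over the total, which for a ring atom with two aromatic bonds gives 3).
# Exception: the aromatic C-N bonds of a normalised amidinium center are
# formally single bonds carrying the delocalised charge, so they count 1
# (an imidazolium C2 with two such bonds can still bear a hydrogen).
bond_order_sum <- function(mol, a, inc) {
  nb <- atom_neighbors(mol, a, inc)
  if (!nrow(nb)) return(0L)
  o <- as.numeric(nb$order)
  o[o == BOND_AROMATIC] <- 1.5
  if (mol$atoms$element[a] == "C" && mol$atoms$charge[a] == 1L)
    o[nb$order == BOND_AROMATIC &
        mol$atoms$element[nb$j] == "N"] <- 1
  as.integer(floor(sum(o)))
}

# Materialise implicit hydrogen counts from the valence model for atoms
# with hcount == NA.  `extra` adds already-folded explicit hydrogens.
fill_hcounts <- function(mol, extra = integer(n_atoms(mol))) {
  inc <- incident_bonds(mol)
  for (a in seq_len(n_atoms(mol))) {
    if (!is.na(mol$atoms$hcount[a])) next
    el <- mol$atoms$element[a]
    chg <- mol$atoms$charge[a]
    s <- bond_order_sum(mol, a, inc) + extra[a]
    v <- element_valence(el, chg)
    if (is.null(v)) { mol$atoms$hcount[a] <- extra[a]; next }
    v <- v[v >= s]
    mol$atoms$hcount[a] <- if (length(v)) as.integer(v[1] - s + extra[a]) else extra[a]
  }
  mol
}

#' Check a molecule against the supported element set
#'
#' The parameter tables are restricted to molecules containing H, B, C, N,
#' O, P, S, Si and/or halogens.  Any other element makes the molecule
#' ineligible for group perception and prediction.
#'
#' @param mol a [molgraph].
#' @return a list with `eligible` (logical) and `offending` (character
#'   vector of unsupported elements, empty iff eligible).
#' @export
validate_elements <- function(mol) {
  off <- sort(unique(setdiff(mol$atoms$element, ELEMENT_WHITELIST)))
  list(eligible = length(off) == 0, offending = off)
}

#' Read a molecule from a SMILES string
#'
#' The SMILES is converted to a V2000 molblock with OpenBabel (via
#' ChemmineOB), then parsed into a [molgraph].  Input aromatic bonds are
#' kekulised and re-perceived under the package's fixed aromaticity
#' convention (six-membered C/N rings plus the amidinium motif); the
#' amidinium/imidazolium/guanidinium charge convention is applied unless
#' `normalize = FALSE`.
#'
#' @param smiles SMILES string over the supported elements.
#' @param name,id molecule name / identifier (default: the SMILES itself).
#' @param normalize apply [normalize_amidinium()] after reading.
#' @return a [molgraph].
#' @export
read_smiles <- function(smiles, name = smiles, id = name, normalize = TRUE) {
  if (!requireNamespace("ChemmineOB", quietly = TRUE))
    stop("read_smiles() requires the ChemmineOB package (OpenBabel)")
  sdf <- tryCatch(
    ChemmineOB::convertFormat("SMI", "SDF", paste0(smiles, "\n")),
    error = function(e) "")
  lines <- strsplit(sdf, "\n", fixed = TRUE)[[1]]
  if (length(lines) < 4 || !grepl("V2000", lines[4]))
    stop("SMILES parse failure for input: ", smiles)
  mol <- parse_molblock(lines, name = name, id = id)
  finalize_molgraph(mol, normalize = normalize)
}

# Shared post-read pipeline: kekulise input aromatic bonds, materialise
# implicit hydrogens, apply the amidinium charge convention, re-aromatise
# six-membered C/N rings.
finalize_molgraph <- function(mol, normalize = TRUE) {
  extra <- mol$hextra %||% integer(n_atoms(mol))
  mol$hextra <- NULL
  mol <- kekulize(mol)
  if (anyNA(mol$atoms$hcount)) mol <- fill_hcounts(mol, extra = extra)
  if (normalize) mol <- normalize_amidinium(mol)
  mol <- aromatize_six_rings(mol)
  mol
}

old_charge_code <- function(code) {
  # V2000 atom-block charge column: 0 none, 1 +3, 2 +2, 3 +1, 5 -1, 6 -2, 7 -3
  c(`0` = 0L, `1` = 3L, `2` = 2L, `3` = 1L, `4` = 0L, `5` = -1L,
    `6` = -2L, `7` = -3L)[as.character(code)]
}

# Parse one V2000 molblock (character vector of lines, first line = title).
# Explicit hydrogen atoms are folded into the implicit counts of their
# heavy neighbour.
parse_molblock <- function(lines, name = NULL, id = NULL) {
  if (length(lines) < 4) stop("truncated molblock")
  title <- trimws(lines[1])
  counts <- lines[4]
  na <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  nb <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(na) || is.na(nb)) stop("unreadable counts line: ", counts)
  if (length(lines) < 4 + na + nb) stop("truncated atom/bond block")

  at <- lines[5:(4 + na)]
  element <- trimws(substr(at, 32, 34))
  badel <- setdiff(unique(element), KNOWN_ELEMENTS)
  if (length(badel)) stop("unknown element symbol(s): ",
                          paste(badel, collapse = ", "))
  charge <- old_charge_code(suppressWarnings(as.integer(substr(at, 37, 39))))
  charge[is.na(charge)] <- 0L

  bonds <- data.frame(i = integer(), j = integer(), order = integer())
  if (nb > 0) {
    bl <- lines[(5 + na):(4 + na + nb)]
    bonds <- data.frame(
      i = as.integer(substr(bl, 1, 3)),
      j = as.integer(substr(bl, 4, 6)),
      order = as.integer(substr(bl, 7, 9)))
    if (anyNA(bonds)) stop("unreadable bond block")
    if (!all(bonds$order %in% 1:4))
      stop("unsupported bond type(s): ",
           paste(setdiff(bonds$order, 1:4), collapse = ", "))
  }

  rest <- if (length(lines) > 4 + na + nb) lines[(5 + na + nb):length(lines)] else character()
  # M CHG supersedes the atom-block charge column entirely
  chg_lines <- grep("^M  CHG", rest, value = TRUE)
  if (length(chg_lines)) {
    charge[] <- 0L
    for (ln in chg_lines) {
      f <- as.integer(strsplit(trimws(substring(ln, 7)), "\\s+")[[1]])
      npairs <- f[1]
      for (p in seq_len(npairs)) charge[f[2 * p]] <- f[2 * p + 1]
    }
  }

  # data fields ("> <field>" blocks) after M  END
  props <- character()
  hdr <- grep("^> ", rest)
  for (h in hdr) {
    field <- sub("^> *<([^>]*)>.*$", "\\1", rest[h])
    val <- character()
    k <- h + 1
    while (k <= length(rest) && nzchar(trimws(rest[k])) && !startsWith(rest[k], "$$$$")) {
      val <- c(val, rest[k]); k <- k + 1
    }
    props[field] <- paste(val, collapse = "\n")
  }

  atoms <- data.frame(element = element, charge = charge,
                      hcount = NA_integer_, stringsAsFactors = FALSE)

  # fold explicit hydrogens into counts
  isH <- atoms$element == "H"
  extra <- integer(na)
  if (any(isH)) {
    if (any(atoms$charge[isH] != 0L))
      stop("charged explicit hydrogen not supported")
    for (a in which(isH)) {
      ks <- which(bonds$i == a | bonds$j == a)
      if (length(ks) != 1 || bonds$order[ks] != BOND_SINGLE)
        stop("explicit hydrogen with irregular bonding (atom ", a, ")")
      nbr <- if (bonds$i[ks] == a) bonds$j[ks] else bonds$i[ks]
      if (atoms$element[nbr] == "H") stop("H-H bond not supported")
      extra[nbr] <- extra[nbr] + 1L
    }
    keep <- which(!isH)
    remap <- match(seq_len(na), keep)
    bonds <- bonds[!(bonds$i %in% which(isH) | bonds$j %in% which(isH)), , drop = FALSE]
    bonds$i <- remap[bonds$i]; bonds$j <- remap[bonds$j]
    atoms <- atoms[keep, , drop = FALSE]
    extra <- extra[keep]
    rownames(atoms) <- NULL; rownames(bonds) <- NULL
  }

  if (is.null(name)) name <- title
  if (is.null(id) || !nzchar(id %||% "")) id <- if (nzchar(title)) title else ""
  m <- structure(list(atoms = atoms, bonds = bonds, name = name,
                      id = id, props = props),
                 class = "molgraph")
  # implicit hydrogens are materialised in finalize_molgraph(), after
  # kekulisation, so that input aromatic bonds do not skew the valence sums
  m$hextra <- extra
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read molecules from a V2000 SDF file
#'
#' Records are parsed independently: a corrupt record yields a per-record
#' error (collected in the `"errors"` attribute of the result and reported
#' as a warning) while the remaining records are still returned.  Records
#' containing elements outside the supported set are kept but flagged via
#' their `offending_elements` field rather than dropped.
#'
#' @param path path to an SDF (V2000) file.
#' @param id_field optional name of a data field to use as compound id;
#'   by default the title line is used.
#' @param normalize apply the amidinium charge convention.
#' @return list of [molgraph] objects with attribute `errors`, a data frame
#'   with columns `record` and `message`.
#' @export
read_sdf <- function(path, id_field = NULL, normalize = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  ends <- grep("^\\$\\$\\$\\$", lines)
  starts <- c(1L, head(ends, -1) + 1L)
  if (!length(ends)) { starts <- 1L; ends <- length(lines) + 1L }
  mols <- list()
  errors <- data.frame(record = integer(), message = character())
  for (r in seq_along(starts)) {
    rec <- lines[starts[r]:(ends[r] - 1L)]
    if (!any(nzchar(trimws(rec)))) next
    m <- tryCatch({
      mol <- parse_molblock(rec)
      if (!is.null(id_field) && id_field %in% names(mol$props))
        mol$id <- mol$props[[id_field]]
      ver <- validate_elements(mol)
      mol$offending_elements <- ver$offending
      if (ver$eligible) {
        mol <- finalize_molgraph(mol, normalize = normalize)
      } else {
        extra <- mol$hextra %||% integer(n_atoms(mol))
        mol$hextra <- NULL
        mol <- fill_hcounts(mol, extra = extra)
      }
      mol
    }, error = function(e) e)
    if (inherits(m, "error")) {
      errors <- rbind(errors,
                      data.frame(record = r, message = conditionMessage(m)))
    } else {
      mols[[length(mols) + 1L]] <- m
    }
  }
  if (nrow(errors))
    warning(sprintf("%d record(s) could not be read: %s", nrow(errors),
                    paste(sprintf("record %d (%s)", errors$record,
                                  errors$message), collapse = "; ")))
  attr(mols, "errors") <- errors
  mols
}

#' Write molecules to a V2000 SDF file
#'
#' Bond orders (including aromatic, type 4) are written as stored; formal
#' charges are emitted as `M  CHG` lines; implicit hydrogens are not
#' materialised.  Data fields in `props` are written as `> <field>` blocks.
#'
#' @param mols a [molgraph] or list of them.
#' @param path output file path.
#' @export
write_sdf <- function(mols, path) {
  if (inherits(mols, "molgraph")) mols <- list(mols)
  con <- file(path, "w")
  on.exit(close(con))
  for (mol in mols) {
    na <- n_atoms(mol); nb <- nrow(mol$bonds)
    writeLines(c(mol$name, "  groupadd          2D", "",
                 sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", na, nb)), con)
    for (a in seq_len(na))
      writeLines(sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                         0, 0, 0, mol$atoms$element[a]), con)
    if (nb)
      writeLines(sprintf("%3d%3d%3d  0  0  0  0",
                         mol$bonds$i, mol$bonds$j, mol$bonds$order), con)
    chg <- which(mol$atoms$charge != 0L)
    if (length(chg)) {
      for (grp in split(chg, ceiling(seq_along(chg) / 8)))
        writeLines(paste0("M  CHG", sprintf("%3d", length(grp)),
                          paste0(sprintf("%4d%4d", grp, mol$atoms$charge[grp]),
                                 collapse = "")), con)
    }
    writeLines("M  END", con)
    for (f in names(mol$props))
      writeLines(c(sprintf("> <%s>", f), mol$props[[f]], ""), con)
    writeLines("$$$$", con)
  }
  invisible(path)
}
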