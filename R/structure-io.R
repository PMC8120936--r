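# Chain-level PDB input/output.
#
# A `chain` is a light S3 container: one polypeptide chain as a data frame of
# heavy atoms. Author residue numbering is kept (`res_seq`/`icode`) but all
# sequence-separation logic downstream uses `ordinal`, the rank of the residue
# within the chain, so numbering gaps and insertion codes cannot corrupt it.

#' Construct a chain object
#'
#' @param atoms data.frame with columns `res_type` (3-letter code), `res_seq`
#'   (author numbering, integer), `icode` (insertion code, "" if none),
#'   `ordinal` (1-based residue rank within the chain), `atom_name`,
#'   `element`, `x`, `y`, `z`, `occupancy`.
#' @param chain_id single chain identifier string.
#' @return object of class `chain`.
#' @export
new_chain <- function(atoms, chain_id = "A") {
  needed <- c("res_type", "res_seq", "icode", "ordinal", "atom_name",
              "element", "x", "y", "z", "occupancy")
  missing <- setdiff(needed, names(atoms))
  if (length(missing))
    stop("chain atoms lack columns: ", paste(missing, collapse = ", "))
  if (nrow(atoms) == 0L) stop("chain must contain at least one atom")
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("non-finite coordinates in chain")
  rownames(atoms) <- NULL
  structure(list(chain_id = as.character(chain_id)[1L],
                 atoms = atoms[needed]),
            class = "chain")
}

#' Number of residues in a chain
#' @param chain a `chain` object.
#' @export
n_residues <- function(chain) {
  stopifnot(inherits(chain, "chain"))
  length(unique(chain$atoms$ordinal))
}

#' Residue types of a chain in order
#' @param chain a `chain` object.
#' @return character vector of 3-letter codes, one per residue.
#' @export
chain_sequence <- function(chain) {
  stopifnot(inherits(chain, "chain"))
  a <- chain$atoms
  a$res_type[!duplicated(a$ordinal)]
}

#' @export
print.chain <- function(x, ...) {
  cat(sprintf("<chain %s: %d residues, %d heavy atoms>\n",
              x$chain_id, n_residues(x), nrow(x$atoms)))
  invisible(x)
}

# ---- PDB parsing ------------------------------------------------------------

pdb_field <- function(lines, from, to) substr(lines, from, to)

#' Read one chain from a PDB file
#'
#' Parses ATOM records (plus HETATM MSE, mapped to MET) of the first model.
#' Hydrogens/deuteriums, waters and other heteroatoms, OXT termini and
#' non-standard residues are removed; one alternate-location conformer is kept
#' per atom (highest occupancy, ties broken by altloc code order).
#'
#' @param path PDB file path.
#' @param chain_id chain identifier to extract; `NULL` takes the first chain
#'   that survives filtering.
#' @return a `chain` object. The attribute `completeness` reports, per
#'   residue, how many of the expected heavy atoms were found.
#' @export
read_structure <- function(path, chain_id = NULL) {
  if (!file.exists(path)) stop("cannot read PDB file: ", path)
  lines <- readLines(path, warn = FALSE)
  endmdl <- which(startsWith(lines, "ENDMDL"))
  if (length(endmdl)) lines <- lines[seq_len(endmdl[1L] - 1L)]  # first model
  rec <- pdb_field(lines, 1, 6)
  keep <- rec == "ATOM  " | rec == "HETATM"
  lines <- lines[keep]
  rec <- rec[keep]
  if (!length(lines)) stop("no ATOM records found in ", path)

  atom_name <- trimws(pdb_field(lines, 13, 16))
  altloc    <- trimws(pdb_field(lines, 17, 17))
  res_type  <- trimws(pdb_field(lines, 18, 20))
  ch        <- trimws(pdb_field(lines, 22, 22))
  res_seq   <- suppressWarnings(as.integer(pdb_field(lines, 23, 26)))
  icode     <- trimws(pdb_field(lines, 27, 27))
  x <- as.numeric(pdb_field(lines, 31, 38))
  y <- as.numeric(pdb_field(lines, 39, 46))
  z <- as.numeric(pdb_field(lines, 47, 54))
  occ <- suppressWarnings(as.numeric(pdb_field(lines, 55, 60)))
  occ[is.na(occ)] <- 1
  element <- toupper(trimws(pdb_field(lines, 77, 78)))
  noel <- element == "" | is.na(element)
  element[noel] <- toupper(guess_element(atom_name[noel]))

  df <- data.frame(rec = rec, atom_name = atom_name, altloc = altloc,
                   res_type = res_type, ch = ch, res_seq = res_seq,
                   icode = icode, x = x, y = y, z = z, occupancy = occ,
                   element = element, stringsAsFactors = FALSE)

  # selenomethionine is the one mapped heteroresidue
  mse <- df$rec == "HETATM" & df$res_type == "MSE"
  df$res_type[mse] <- "MET"
  df$atom_name[mse & df$atom_name == "SE"] <- "SD"
  df$element[mse & df$element == "SE"] <- "S"
  df <- df[df$rec == "ATOM  " | mse, , drop = FALSE]

  df <- df[!(df$element %in% c("H", "D")), , drop = FALSE]
  df <- df[df$atom_name != "OXT", , drop = FALSE]

  if (is.null(chain_id)) {
    if (!nrow(df)) stop("chain empty after filtering in ", path)
    chain_id <- df$ch[1L]
  } else if (!any(df$ch == chain_id)) {
    stop("chain '", chain_id, "' not found in ", path)
  }
  df <- df[df$ch == chain_id, , drop = FALSE]

  bad <- !(df$res_type %in% STANDARD_AA)
  if (any(bad)) {
    warning("dropping non-standard residue(s): ",
            paste(unique(df$res_type[bad]), collapse = ", "))
    df <- df[!bad, , drop = FALSE]
  }
  if (!nrow(df)) stop("chain empty after filtering in ", path)

  # altloc resolution: per residue+atom keep highest occupancy, tie -> altloc order
  rid <- paste(df$res_seq, df$icode, sep = "_")
  keykey <- paste(rid, df$atom_name, sep = "|")
  ord <- order(match(rid, unique(rid)), df$atom_name,
               -df$occupancy, df$altloc)
  df <- df[ord, , drop = FALSE]
  df <- df[!duplicated(paste(df$res_seq, df$icode, df$atom_name, sep = "|")), ,
           drop = FALSE]
  # restore file residue order, atoms in name order within residue
  rid <- paste(df$res_seq, df$icode, sep = "_")
  df$ordinal <- match(rid, unique(rid))
  df <- df[order(df$ordinal), , drop = FALSE]

  chain <- new_chain(
    data.frame(res_type = df$res_type, res_seq = df$res_seq,
               icode = df$icode, ordinal = df$ordinal,
               atom_name = df$atom_name, element = df$element,
               x = df$x, y = df$y, z = df$z, occupancy = df$occupancy,
               stringsAsFactors = FALSE),
    chain_id = chain_id)
  attr(chain, "completeness") <- chain_completeness(chain)
  chain
}

# Expected vs found heavy atoms per residue (missing-atom report).
chain_completeness <- function(chain) {
  a <- chain$atoms
  res <- a[!duplicated(a$ordinal), c("ordinal", "res_type")]
  found <- vapply(res$ordinal, function(o) sum(a$ordinal == o), 0L)
  expected <- vapply(res$res_type, function(rt)
    length(BACKBONE_ATOMS) + length(AA_SIDECHAIN_ATOMS[[rt]]), 0L)
  data.frame(ordinal = res$ordinal, res_type = res$res_type,
             n_found = found, n_expected = expected,
             stringsAsFactors = FALSE)
}

#' Write a chain to a PDB file
#'
#' @param chain a `chain` object.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_structure <- function(chain, path) {
  stopifnot(inherits(chain, "chain"))
  a <- chain$atoms
  if (!nrow(a)) stop("refusing to write an empty chain")
  # PDB atom-name column convention: 1-2 letter elements start in column 14
  fmt_name <- function(nm, el) {
    ifelse(nchar(el) >= 2L | nchar(nm) >= 4L,
           sprintf("%-4s", nm), sprintf(" %-3s", nm))
  }
  lines <- sprintf(
    "ATOM  %5d %s %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(a)), fmt_name(a$atom_name, a$element), a$res_type,
    chain$chain_id, a$res_seq, ifelse(a$icode == "", " ", a$icode),
    a$x, a$y, a$z, a$occupancy, 0, a$element)
  writeLines(c(lines, "TER", "END"), path)
  invisible(path)
}

# Coordinates of a chain as an n_atoms x 3 matrix.
chain_coords <- function(chain) {
  as.matrix(chain$atoms[, c("x", "y", "z")])
}

# Replace coordinates (same atom order) returning a new chain.
set_chain_coords <- function(chain, coords) {
  stopifnot(nrow(coords) == nrow(chain$atoms), ncol(coords) == 3L)
  a <- chain$atoms
  a$x <- coords[, 1L]; a$y <- coords[, 2L]; a$z <- coords[, 3L]
  out <- new_chain(a, chain$chain_id)
  out
}

#' Apply a rigid-body transform to a chain
#' @param chain a `chain` object.
#' @param rotation 3x3 rotation matrix.
#' @param translation length-3 translation vector (Angstrom).
#' @export
transform_chain <- function(chain, rotation = diag(3), translation = c(0, 0, 0)) {
  xyz <- chain_coords(chain) %*% t(rotation)
  xyz <- sweep(xyz, 2L, translation, "+")
  set_chain_coords(chain, xyz)
}
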