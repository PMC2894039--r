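res_key <- function(chain, resno, insert) {
  insert <- ifelse(is.na(insert) | insert == " ", "", insert)
  sprintf("%s:%d%s", chain, as.integer(resno), insert)
}

#' Read a protein structure from a PDB file
#'
#' Parses ATOM (and optionally HETATM) records into a structure model holding
#' heavy atoms grouped into residues and chains. For alternate-location
#' atoms, only the highest-occupancy conformer is kept (ties broken by the
#' first altloc code alphabetically). Waters and non-polymer het-groups are
#' excluded by default; hydrogens are always excluded.
#'
#' @param path Path to a PDB file.
#' @param model_index Which model of a multi-model file to use (default 1).
#' @param keep_het Keep HETATM records (waters still excluded)? Default FALSE.
#' @return An object of class `structure_model`: a list with element `atoms`,
#'   a data frame with columns chain, resno, insert, resid, elety, elesym,
#'   x, y, z, o, mass, key; and `chains`, the ordered chain identifiers.
#' @export
read_structure <- function(path, model_index = 1L, keep_het = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE)
  atoms <- pdb$atom
  nmod <- nrow(pdb$xyz)
  if (is.null(nmod) || nmod < 1L) stop("no coordinates in model: ", path)
  if (model_index > nmod) {
    stop("model_index ", model_index, " but file has ", nmod, " model(s)")
  }
  xyz <- matrix(pdb$xyz[model_index, ], ncol = 3, byrow = TRUE)
  atoms$x <- xyz[, 1]; atoms$y <- xyz[, 2]; atoms$z <- xyz[, 3]
  if (!keep_het) atoms <- atoms[atoms$type == "ATOM", , drop = FALSE]
  atoms <- atoms[!(atoms$resid %in% c("HOH", "DOD", "WAT")), , drop = FALSE]
  if (nrow(atoms) == 0L) stop("empty model after filtering: ", path)
  structure_model(chain = atoms$chain, resno = atoms$resno,
                  insert = atoms$insert, resid = atoms$resid,
                  elety = atoms$elety, elesym = atoms$elesym,
                  x = atoms$x, y = atoms$y, z = atoms$z,
                  o = atoms$o, alt = atoms$alt)
}

#' Build a structure model from atom vectors
#'
#' Low-level constructor used by [read_structure()] and the fixture
#' generators. Hydrogens are dropped; alternate locations resolved by
#' occupancy; atom masses assigned from the element.
#'
#' @param chain,resno,insert,resid,elety,elesym,x,y,z,o,alt Per-atom vectors.
#' @return A `structure_model` object.
#' @export
structure_model <- function(chain, resno, insert = "", resid, elety,
                            elesym = NULL, x, y, z, o = 1, alt = "") {
  n <- length(x)
  insert <- rep_len(ifelse(is.na(insert) | insert == " ", "", insert), n)
  alt <- rep_len(ifelse(is.na(alt), "", alt), n)
  o <- rep_len(ifelse(is.na(o), 1, o), n)
  if (is.null(elesym)) elesym <- guess_element(elety)
  elesym <- toupper(ifelse(is.na(elesym) | elesym == "", guess_element(elety),
                           elesym))
  atoms <- data.frame(chain = as.character(chain), resno = as.integer(resno),
                      insert = as.character(insert),
                      resid = as.character(resid),
                      elety = as.character(elety),
                      elesym = elesym, x = x, y = y, z = z, o = o,
                      alt = alt, stringsAsFactors = FALSE)
  atoms <- atoms[!(atoms$elesym %in% c("H", "D")), , drop = FALSE]
  if (nrow(atoms) == 0L) stop("structure has no heavy atoms")
  if (any(!is.finite(atoms$x + atoms$y + atoms$z))) {
    stop("non-finite atomic coordinates")
  }
  atoms$key <- res_key(atoms$chain, atoms$resno, atoms$insert)
  # resolve alternate locations: keep the highest-occupancy conformer per atom
  if (any(atoms$alt != "")) {
    id <- paste(atoms$key, atoms$elety)
    ord <- order(id, -atoms$o, atoms$alt)
    atoms <- atoms[ord, , drop = FALSE]
    atoms <- atoms[!duplicated(paste(atoms$key, atoms$elety)), , drop = FALSE]
    atoms <- atoms[order(match(atoms$key, unique(atoms$key))), , drop = FALSE]
  }
  atoms$alt <- NULL
  masses <- element_masses()
  m <- masses[atoms$elesym]
  if (any(is.na(m))) {
    stop("no mass/radius entry for element(s): ",
         paste(unique(atoms$elesym[is.na(m)]), collapse = ", "))
  }
  atoms$mass <- unname(m)
  rownames(atoms) <- NULL
  out <- list(atoms = atoms, chains = unique(atoms$chain))
  class(out) <- "structure_model"
  out
}

guess_element <- function(elety) {
  e <- gsub("[^A-Za-z]", "", as.character(elety))
  two <- toupper(substr(e, 1, 2))
  one <- toupper(substr(e, 1, 1))
  ifelse(two %in% c("SE", "CL", "BR", "FE", "ZN", "MG", "MN"), two, one)
}

#' @export
print.structure_model <- function(x, ...) {
  cat("structure_model:", nrow(x$atoms), "heavy atoms,",
      length(unique(x$atoms$key)), "residues,",
      length(x$chains), "chain(s) [", paste(x$chains, collapse = ", "), "]\n")
  invisible(x)
}

#' Subset a structure model by chain
#'
#' @param structure A `structure_model`.
#' @param chains Character vector of chain identifiers to keep.
#' @return A `structure_model` restricted to the requested chains.
#' @export
subset_chains <- function(structure, chains) {
  stopifnot(inherits(structure, "structure_model"))
  missing <- setdiff(chains, structure$chains)
  if (length(missing)) {
    stop("chain(s) not in structure: ", paste(missing, collapse = ", "))
  }
  atoms <- structure$atoms[structure$atoms$chain %in% chains, , drop = FALSE]
  out <- list(atoms = atoms, chains = unique(atoms$chain))
  class(out) <- "structure_model"
  out
}

#' Residue keys of a structure, in order of appearance
#'
#' @param structure A `structure_model`.
#' @return Character vector of unique residue keys ("chain:resno[icode]").
#' @export
residue_keys <- function(structure) unique(structure$atoms$key)

#' Centre of a residue's heavy atoms
#'
#' The default scheme is the mass-weighted mean (centre of mass) of the
#' heavy-atom coordinates; `"geometric"` gives the unweighted mean.
#'
#' @param atoms Data frame of atoms (rows of `structure$atoms`).
#' @param scheme `"mass"` (default) or `"geometric"`.
#' @return Numeric length-3 vector (Angstrom).
#' @export
residue_center <- function(atoms, scheme = c("mass", "geometric")) {
  scheme <- match.arg(scheme)
  if (nrow(atoms) == 0L) stop("empty atom set")
  w <- if (scheme == "mass") atoms$mass else rep(1, nrow(atoms))
  c(sum(w * atoms$x), sum(w * atoms$y), sum(w * atoms$z)) / sum(w)
}

#' Centres of mass for residues of a structure
#'
#' @param structure A `structure_model`.
#' @param keys Residue keys to compute (default all).
#' @param scheme Passed to [residue_center()].
#' @return Numeric matrix, one row per key (rownames = keys), columns x,y,z.
#' @export
residue_centers <- function(structure, keys = NULL,
                            scheme = c("mass", "geometric")) {
  scheme <- match.arg(scheme)
  a <- structure$atoms
  if (is.null(keys)) keys <- unique(a$key)
  w <- if (scheme == "mass") a$mass else rep(1, nrow(a))
  sw <- rowsum(w, a$key)
  cx <- rowsum(w * a$x, a$key) / sw
  cy <- rowsum(w * a$y, a$key) / sw
  cz <- rowsum(w * a$z, a$key) / sw
  if (any(!keys %in% rownames(sw))) {
    stop("unknown residue key(s): ",
         paste(setdiff(keys, rownames(sw)), collapse = ", "))
  }
  out <- cbind(x = cx[keys, 1], y = cy[keys, 1], z = cz[keys, 1])
  rownames(out) <- keys
  out
}

#' One-letter sequence of a chain, in residue order
#'
#' @param structure A `structure_model`.
#' @param chain Chain identifier.
#' @return Named character vector of 1-letter codes, names are residue keys.
#' @export
chain_sequence <- function(structure, chain) {
  a <- structure$atoms[structure$atoms$chain == chain, , drop = FALSE]
  if (nrow(a) == 0L) stop("chain not in structure: ", chain)
  keys <- unique(a$key)
  resid <- a$resid[match(keys, a$key)]
  seq1 <- bio3d::aa321(resid)
  names(seq1) <- keys
  seq1
}

# residue names (3-letter) for a set of keys
residue_names <- function(structure, keys) {
  a <- structure$atoms
  out <- a$resid[match(keys, a$key)]
  if (any(is.na(out))) {
    stop("unknown residue key(s): ", paste(keys[is.na(out)], collapse = ", "))
  }
  names(out) <- keys
  out
}

#' Write a structure model to a PDB file
#'
#' @param structure A `structure_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(structure, path) {
  a <- structure$atoms
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   type = rep("ATOM", nrow(a)),
                   resno = a$resno, resid = a$resid, insert = a$insert,
                   chain = a$chain, elety = a$elety, eleno = seq_len(nrow(a)),
                   o = a$o, b = rep(0, nrow(a)),
                   elesy = a$elesym)
  invisible(path)
}
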