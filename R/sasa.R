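# deterministic quasi-uniform points on the unit sphere (golden-spiral)
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Per-atom solvent-accessible surface area
#'
#' Numerical SASA by the Shrake-Rupley sphere-sampling scheme: each atom's
#' solvent sphere (van der Waals radius + probe radius) is sampled at
#' `n_points` deterministic quasi-uniform points; a point is accessible if it
#' lies outside every other atom's solvent sphere. The result is exactly
#' reproducible for a fixed point count.
#'
#' @param structure A `structure_model`.
#' @param probe_radius Solvent probe radius in Angstrom (default 1.4).
#' @param n_points Sample points per atom (default 960, minimum 100).
#' @param radii Named vector of van der Waals radii per element symbol.
#' @return Numeric vector of per-atom areas (Angstrom^2), one per row of
#'   `structure$atoms`.
#' @export
compute_sasa <- function(structure, probe_radius = 1.4, n_points = 960L,
                         radii = vdw_radii()) {
  stopifnot(inherits(structure, "structure_model"),
            probe_radius > 0, n_points >= 100L)
  a <- structure$atoms
  r <- radii[a$elesym]
  if (any(is.na(r))) {
    stop("no van der Waals radius for element(s): ",
         paste(unique(a$elesym[is.na(r)]), collapse = ", "))
  }
  R <- unname(r) + probe_radius
  xyz <- as.matrix(a[, c("x", "y", "z")])
  n <- nrow(xyz)
  pts <- sphere_points(n_points)
  out <- numeric(n)
  # neighbour prefilter on squared distances
  maxR <- max(R)
  for (i in seq_len(n)) {
    d2 <- (xyz[, 1] - xyz[i, 1])^2 + (xyz[, 2] - xyz[i, 2])^2 +
      (xyz[, 3] - xyz[i, 3])^2
    nb <- which(d2 < (R[i] + R)^2 & d2 > 0)
    if (length(nb) == 0L) {
      out[i] <- 4 * pi * R[i]^2
      next
    }
    p <- pts * R[i]
    p[, 1] <- p[, 1] + xyz[i, 1]
    p[, 2] <- p[, 2] + xyz[i, 2]
    p[, 3] <- p[, 3] + xyz[i, 3]
    acc <- rep(TRUE, n_points)
    for (j in nb[order(d2[nb])]) {
      if (!any(acc)) break
      keep <- acc
      dj2 <- (p[keep, 1] - xyz[j, 1])^2 + (p[keep, 2] - xyz[j, 2])^2 +
        (p[keep, 3] - xyz[j, 3])^2
      acc[keep] <- dj2 > R[j]^2
    }
    out[i] <- 4 * pi * R[i]^2 * sum(acc) / n_points
  }
  out
}

# sum per-atom SASA into per-residue totals (named by residue key)
residue_sasa <- function(structure, atom_sasa) {
  v <- rowsum(atom_sasa, structure$atoms$key)
  out <- v[, 1]
  names(out) <- rownames(v)
  out[unique(structure$atoms$key)]
}

#' Surface residues of a chain group by relative accessibility
#'
#' Relative accessibility is the residue's SASA divided by the reference
#' maximal accessibility of its residue type (extended-tripeptide reference,
#' see [max_accessibility()]). Residues at or above `rel_threshold` (default
#' 5 percent) are classified as surface.
#'
#' @param structure A `structure_model` for the isolated chain group.
#' @param rel_threshold Relative accessibility cutoff (default 0.05).
#' @param reference Named vector of per-residue-type maximal areas.
#' @param probe_radius,n_points Passed to [compute_sasa()].
#' @return An object of class `surface_set`: data frame with columns key,
#'   chain, resno, insert, resid, sasa, rel_acc, restricted to surface
#'   residues; the full (unfiltered) table is kept in attribute `"all"`.
#' @export
surface_residues <- function(structure, rel_threshold = 0.05,
                             reference = max_accessibility(),
                             probe_radius = 1.4, n_points = 960L) {
  stopifnot(inherits(structure, "structure_model"))
  sasa <- residue_sasa(structure, compute_sasa(structure, probe_radius,
                                               n_points))
  keys <- names(sasa)
  a <- structure$atoms
  idx <- match(keys, a$key)
  resid <- a$resid[idx]
  ref <- reference[resid]
  if (any(is.na(ref))) {
    stop("residue type(s) missing from reference table: ",
         paste(unique(resid[is.na(ref)]), collapse = ", "))
  }
  tab <- data.frame(key = keys, chain = a$chain[idx], resno = a$resno[idx],
                    insert = a$insert[idx], resid = resid,
                    sasa = unname(sasa), rel_acc = unname(sasa / ref),
                    stringsAsFactors = FALSE)
  out <- tab[tab$rel_acc >= rel_threshold, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "all") <- tab
  attr(out, "rel_threshold") <- rel_threshold
  class(out) <- c("surface_set", "data.frame")
  out
}

#' Identify interface residues between two chain groups
#'
#' Computes the solvent-accessible surface area of each chain group in
#' isolation and in the complex; residues whose summed atomic buried area
#' (isolated minus complexed SASA) exceeds `burial_threshold` belong to the
#' interface.
#'
#' @param structure A `structure_model` containing both groups.
#' @param group_a,group_b Disjoint, non-empty character vectors of chain ids.
#' @param burial_threshold Minimum buried area per residue in Angstrom^2
#'   (default 0.1).
#' @param probe_radius,n_points Passed to [compute_sasa()].
#' @return An object of class `interface_record`: list with `partner_a`,
#'   `partner_b` (residue keys), `delta_asa` (named, Angstrom^2 buried, both
#'   partners), and `chain_partition`.
#' @export
identify_interface <- function(structure, group_a, group_b,
                               burial_threshold = 0.1,
                               probe_radius = 1.4, n_points = 960L) {
  stopifnot(inherits(structure, "structure_model"))
  if (length(group_a) == 0L || length(group_b) == 0L) {
    stop("both chain groups must be non-empty")
  }
  if (length(intersect(group_a, group_b))) stop("chain groups must be disjoint")
  sub_a <- subset_chains(structure, group_a)
  sub_b <- subset_chains(structure, group_b)
  both <- subset_chains(structure, c(group_a, group_b))
  sasa_cplx <- residue_sasa(both, compute_sasa(both, probe_radius, n_points))
  sasa_a <- residue_sasa(sub_a, compute_sasa(sub_a, probe_radius, n_points))
  sasa_b <- residue_sasa(sub_b, compute_sasa(sub_b, probe_radius, n_points))
  iso <- c(sasa_a, sasa_b)
  delta <- iso - sasa_cplx[names(iso)]
  sel <- delta > burial_threshold
  keys <- names(delta)[sel]
  in_a <- keys %in% names(sasa_a)
  out <- list(partner_a = keys[in_a], partner_b = keys[!in_a],
              delta_asa = delta[sel],
              chain_partition = list(a = group_a, b = group_b),
              burial_threshold = burial_threshold)
  class(out) <- "interface_record"
  out
}

#' @export
print.interface_record <- function(x, ...) {
  cat("interface_record: ", length(x$partner_a), " residue(s) on [",
      paste(x$chain_partition$a, collapse = ","), "], ",
      length(x$partner_b), " on [",
      paste(x$chain_partition$b, collapse = ","), "]; buried area ",
      sprintf("%.1f", sum(x$delta_asa)), " A^2\n", sep = "")
  invisible(x)
}

#' Atoms belonging to the interface residues
#'
#' @param structure The `structure_model` the interface was derived from.
#' @param interface An `interface_record`.
#' @param side `"both"` (default), `"a"`, or `"b"`.
#' @return Data frame of atoms (rows of `structure$atoms`).
#' @export
interface_atoms <- function(structure, interface, side = c("both", "a", "b")) {
  side <- match.arg(side)
  keys <- switch(side, both = c(interface$partner_a, interface$partner_b),
                 a = interface$partner_a, b = interface$partner_b)
  structure$atoms[structure$atoms$key %in% keys, , drop = FALSE]
}

#' Write an interface report as TSV
#'
#' Columns: chain, resnum, icode, resname, delta_asa, partner.
#'
#' @param interface An `interface_record`.
#' @param structure The originating `structure_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_interface_tsv <- function(interface, structure, path) {
  keys <- c(interface$partner_a, interface$partner_b)
  a <- structure$atoms
  idx <- match(keys, a$key)
  df <- data.frame(chain = a$chain[idx], resnum = a$resno[idx],
                   icode = a$insert[idx], resname = a$resid[idx],
                   delta_asa = unname(interface$delta_asa[keys]),
                   partner = rep(c("a", "b"),
                                 c(length(interface$partner_a),
                                   length(interface$partner_b))))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
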