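# centres of mass for surface-set members, as a keyed matrix
surface_centers <- function(structure, surface) {
  residue_centers(structure, surface$key)
}

new_patch <- function(center, members) {
  list(center = center, members = members, rho = NA_real_, too_few = NA)
}

#' Construct a surface patch by hand
#'
#' Mostly useful for scoring an arbitrary residue set (e.g. the true
#' interface) with the same machinery as generated patches.
#'
#' @param center Central residue key (must be among `members`, or `NA` for a
#'   set without a designated centre).
#' @param members Character vector of residue keys.
#' @return A patch list as produced by the `generate_patches_*` functions.
#' @export
surface_patch <- function(center, members) {
  if (!is.na(center) && !center %in% members) {
    stop("center must be one of the patch members")
  }
  new_patch(center, members)
}

#' Surface patches by a fixed radius (Method 1)
#'
#' One patch per surface residue: the central residue plus every other
#' surface residue whose centre of mass lies within `radius` of the centre
#' residue's centre of mass. Conventional radii: 15 A for heterocomplexes,
#' 22 A for homodimers.
#'
#' @param structure A `structure_model` (single chain group).
#' @param surface A `surface_set` from [surface_residues()].
#' @param radius Patch radius in Angstrom.
#' @return List of patches; each is a list with `center` (key) and
#'   `members` (keys).
#' @export
generate_patches_fixed <- function(structure, surface, radius) {
  stopifnot(radius > 0)
  ctr <- surface_centers(structure, surface)
  d <- as.matrix(stats::dist(ctr))
  lapply(seq_len(nrow(ctr)), function(i) {
    new_patch(rownames(ctr)[i], rownames(ctr)[d[i, ] <= radius])
  })
}

# half the maximum inter-atom distance of an atom data frame
half_max_atom_distance <- function(atoms) {
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (nrow(xyz) < 2L) stop("interface has fewer than 2 atoms")
  max(stats::dist(xyz)) / 2
}

#' Surface patches with an interface-adapted radius (Method 2)
#'
#' As Method 1, but the radius is set per protein to half the maximum
#' distance between any two atoms of its true interface, so patch sizes
#' track the actual interface size.
#'
#' @param structure A `structure_model`.
#' @param surface A `surface_set`.
#' @param interface_atoms Data frame of interface atoms (e.g. from
#'   [interface_atoms()]), >= 2 rows.
#' @return List of patches; the derived radius is stored in attribute
#'   `"radius"`.
#' @export
generate_patches_adaptive <- function(structure, surface, interface_atoms) {
  radius <- half_max_atom_distance(interface_atoms)
  out <- generate_patches_fixed(structure, surface, radius)
  attr(out, "radius") <- radius
  out
}

#' Solvent vectors for surface residues
#'
#' For each surface residue, the centre of gravity of its `k_neighbors`
#' nearest surface-residue neighbours is computed; the solvent vector is the
#' unit vector opposite to residue-centre -> neighbour-centroid, i.e. it
#' points away from the local protein body into the solvent.
#'
#' @param structure A `structure_model`.
#' @param surface A `surface_set` with more than `k_neighbors` members.
#' @param k_neighbors Number of nearest neighbours (default 10).
#' @return Numeric matrix of unit vectors, one row per surface residue
#'   (rownames = keys).
#' @export
compute_solvent_vectors <- function(structure, surface, k_neighbors = 10L) {
  ctr <- surface_centers(structure, surface)
  n <- nrow(ctr)
  if (n <= k_neighbors) {
    stop("need more than ", k_neighbors, " surface residues, have ", n)
  }
  d <- as.matrix(stats::dist(ctr))
  out <- matrix(NA_real_, n, 3, dimnames = list(rownames(ctr), NULL))
  for (i in seq_len(n)) {
    nb <- order(d[i, ])[2:(k_neighbors + 1L)]
    centroid <- colMeans(ctr[nb, , drop = FALSE])
    v <- ctr[i, ] - centroid
    nv <- sqrt(sum(v^2))
    if (nv == 0) stop("degenerate solvent vector for residue ",
                      rownames(ctr)[i])
    out[i, ] <- v / nv
  }
  out
}

#' Surface patches with radius and solvent-vector constraints (Method 3)
#'
#' As Method 2, but a residue joins a patch only if the angle between its
#' solvent vector and the central residue's solvent vector is below
#' `angle_cutoff` (default 110 degrees). This prevents patches from wrapping
#' around to the opposite face of the molecule.
#'
#' @param structure A `structure_model`.
#' @param surface A `surface_set`.
#' @param interface_atoms Interface atoms for the adaptive radius; or supply
#'   `radius` directly.
#' @param radius Optional explicit radius (overrides `interface_atoms`).
#' @param angle_cutoff Maximum solvent-vector angle in degrees (default 110).
#' @param k_neighbors Passed to [compute_solvent_vectors()].
#' @return List of patches; attributes `"radius"` and `"solvent_vectors"`.
#' @export
generate_patches_vector <- function(structure, surface,
                                    interface_atoms = NULL, radius = NULL,
                                    angle_cutoff = 110, k_neighbors = 10L) {
  if (is.null(radius)) {
    if (is.null(interface_atoms)) {
      stop("supply either interface_atoms or radius")
    }
    radius <- half_max_atom_distance(interface_atoms)
  }
  ctr <- surface_centers(structure, surface)
  sv <- compute_solvent_vectors(structure, surface, k_neighbors)
  d <- as.matrix(stats::dist(ctr))
  cos_cut <- cos(angle_cutoff * pi / 180)
  cosang <- sv %*% t(sv)
  out <- lapply(seq_len(nrow(ctr)), function(i) {
    ok <- d[i, ] <= radius & cosang[i, ] > cos_cut
    ok[i] <- TRUE  # centre always belongs to its own patch
    new_patch(rownames(ctr)[i], rownames(ctr)[ok])
  })
  attr(out, "radius") <- radius
  attr(out, "solvent_vectors") <- sv
  out
}

#' Score conserved-residue clustering within each patch
#'
#' For every patch, residues with undefined entropy are dropped, the
#' conserved subset is selected relative to the patch's own entropy mean
#' (same criterion machinery as for interfaces), and rho = M_s(conserved) /
#' M_s(patch) is computed. Patches with fewer than 2 conserved residues or
#' fewer than 2 scored residues are marked `too_few` instead of receiving a
#' number.
#'
#' @param patches List of patches (from a `generate_patches_*` function, or
#'   a single hand-built patch list).
#' @param structure A `structure_model`.
#' @param profile An `entropy_profile` covering the patch residues.
#' @param criterion,measure Passed to [select_conserved()].
#' @return The patch list with `rho`, `too_few`, `n_conserved`, `n_scored`
#'   filled in per patch.
#' @export
score_patches <- function(patches, structure, profile,
                          criterion = "mean", measure = "plain") {
  centers_all <- residue_centers(structure)
  lapply(patches, function(p) {
    score_one_patch(p, centers_all, profile, criterion, measure)
  })
}

score_one_patch <- function(p, centers_all, profile, criterion, measure) {
  vals <- if (measure == "plain") profile$s else -profile$s_relative
  keys <- p$members[p$members %in% profile$key[!is.na(vals)]]
  p$n_scored <- length(keys)
  if (length(keys) < 2L) {
    p$too_few <- TRUE; p$rho <- NA_real_; p$n_conserved <- 0L
    return(p)
  }
  cons <- select_conserved(profile, keys, criterion, measure)
  p$n_conserved <- length(cons$members)
  if (p$n_conserved < 2L) {
    p$too_few <- TRUE; p$rho <- NA_real_
    return(p)
  }
  cr <- clustering_ratio(centers_all[cons$members, , drop = FALSE],
                         centers_all[keys, , drop = FALSE])
  p$too_few <- FALSE
  p$rho <- cr$rho
  p$m_s_cons <- cr$m_s_subset
  p$m_s_patch <- cr$m_s_whole
  p$conserved <- cons$members
  p
}

#' Percentage overlap between a patch and the true interface
#'
#' 100 times the number of residues common to the patch and the interface,
#' divided by the number of interface residues.
#'
#' @param patch A patch (list with `members`) or a character vector of keys.
#' @param interface Character vector of interface residue keys (non-empty).
#' @return Percentage in \[0, 100\].
#' @export
patch_overlap_percent <- function(patch, interface) {
  if (length(interface) == 0L) stop("empty interface")
  members <- if (is.list(patch)) patch$members else patch
  100 * length(intersect(members, interface)) / length(interface)
}

#' Rank the true interface among scored surface patches
#'
#' Patches are ordered by descending rho. The interface's rank is 1 plus the
#' number of comparison patches with strictly greater rho; patches without a
#' numeric rho (too few conserved residues) rank below every numeric one but
#' stay in the denominator. The decile bins the rank over all ranked patches
#' plus the interface; the Z-score is (rho_int - mean(rho)) / sd(rho) over
#' the numeric comparison patches, with Z > 1.64 the conventional 95th
#' percentile significance threshold.
#'
#' @param patches Scored comparison patches (from [score_patches()]).
#' @param interface_patch The true interface, scored identically (a single
#'   patch as produced by [score_patches()] on a one-element list).
#' @return An object of class `patch_ranking`: list with `patches` (data
#'   frame sorted by descending rho), `interface_rank`, `decile`,
#'   `rho_interface`, `z_score`, `n_patches`, `interface_too_few`.
#' @export
rank_interface <- function(patches, interface_patch) {
  if (length(patches) == 0L) stop("no comparison patches")
  tab <- data.frame(
    center = vapply(patches, `[[`, "", "center"),
    size = vapply(patches, function(p) length(p$members), 1L),
    n_conserved = vapply(patches, function(p) as.integer(p$n_conserved), 1L),
    rho = vapply(patches, function(p) as.numeric(p$rho), 1),
    stringsAsFactors = FALSE)
  tab <- tab[order(-ifelse(is.na(tab$rho), -Inf, tab$rho)), , drop = FALSE]
  rownames(tab) <- NULL
  rho_num <- tab$rho[!is.na(tab$rho)]
  n_total <- nrow(tab) + 1L
  if (isTRUE(interface_patch$too_few) || is.na(interface_patch$rho)) {
    out <- list(patches = tab, interface_rank = n_total,
                decile = 10L, rho_interface = NA_real_, z_score = NA_real_,
                n_patches = nrow(tab), interface_too_few = TRUE)
    class(out) <- "patch_ranking"
    return(out)
  }
  rho_int <- interface_patch$rho
  rank <- 1L + sum(rho_num > rho_int)
  decile <- as.integer(ceiling(10 * rank / n_total))
  z <- if (length(rho_num) >= 2L && stats::sd(rho_num) > 0) {
    (rho_int - mean(rho_num)) / stats::sd(rho_num)
  } else NA_real_
  out <- list(patches = tab, interface_rank = rank, decile = decile,
              rho_interface = rho_int, z_score = z, n_patches = nrow(tab),
              interface_too_few = FALSE)
  class(out) <- "patch_ranking"
  out
}

#' @export
print.patch_ranking <- function(x, ...) {
  cat("patch_ranking:", x$n_patches, "surface patches\n")
  if (x$interface_too_few) {
    cat("  interface had too few conserved residues to score;",
        "reported in the worst decile\n")
  } else {
    cat(sprintf("  interface rho = %.4f, rank %d / %d (decile %d), Z = %s\n",
                x$rho_interface, x$interface_rank, x$n_patches + 1L,
                x$decile,
                if (is.na(x$z_score)) "NA" else sprintf("%.2f", x$z_score)))
    if (!is.na(x$z_score)) {
      cat("  Z > 1.64 marks clustering significant at the 95th percentile:",
          if (x$z_score > 1.64) "significant\n" else "not significant\n")
    }
  }
  invisible(x)
}

#' @export
plot.patch_ranking <- function(x, ...) {
  rho <- x$patches$rho[!is.na(x$patches$rho)]
  graphics::hist(rho, breaks = 20, col = "grey80", border = "white",
                 main = "Conserved-residue clustering across surface patches",
                 xlab = expression(rho))
  if (!x$interface_too_few) {
    graphics::abline(v = x$rho_interface, col = "red3", lwd = 2)
    graphics::legend("topright", legend = "true interface", col = "red3",
                     lwd = 2, bty = "n")
  }
  invisible(x)
}
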