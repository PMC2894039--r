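# Synthetic structures, alignments and annotations with recorded ground
# truth. Pseudo-residues are two beads: a backbone carbon ("CA") and a
# side-chain carbon ("CB"); geometry is chosen so that exactly the designed
# contact set crosses the buried-area threshold with a comfortable margin.

#' Specification for a synthetic fixture
#'
#' @param n_residues_per_chain Residues per chain (default 100).
#' @param interface_size Designed contact residues per chain (default 24,
#'   the typical per-chain interface size of heterocomplexes).
#' @param conserved_fraction Fraction of the analysed interface that is
#'   conserved (default 0.5).
#' @param placement `"clustered"` (conserved residues confined to a tight
#'   sub-region of the interface) or `"scattered"` (uniform over the
#'   interface).
#' @param cluster_count Number of planted conserved blobs for clustered
#'   placement (default 1).
#' @param geometry `"two-slab"` or `"sphere-contact"`.
#' @param msa_depth Rows in the generated alignment (default 100, >= 2).
#' @param noise_entropy Target class entropy (nats) of non-conserved
#'   columns (default ln 2; must be <= ln 7).
#' @param seed Integer seed; all generators are reproducible from it.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_residues_per_chain = 100L, interface_size = 24L,
                         conserved_fraction = 0.5,
                         placement = c("clustered", "scattered"),
                         cluster_count = 1L,
                         geometry = c("two-slab", "sphere-contact"),
                         msa_depth = 100L, noise_entropy = log(2),
                         seed = 1L) {
  placement <- match.arg(placement)
  geometry <- match.arg(geometry)
  if (conserved_fraction <= 0 || conserved_fraction >= 1) {
    stop("conserved_fraction must be in (0, 1)")
  }
  if (msa_depth < 2L) stop("msa_depth must be >= 2")
  if (noise_entropy > log(7) + 1e-12) {
    stop("noise_entropy cannot exceed ln 7 = ", round(log(7), 4))
  }
  if (interface_size > n_residues_per_chain) {
    stop("interface_size exceeds chain size")
  }
  out <- list(n_residues_per_chain = as.integer(n_residues_per_chain),
              interface_size = as.integer(interface_size),
              conserved_fraction = conserved_fraction,
              placement = placement, cluster_count = as.integer(cluster_count),
              geometry = geometry, msa_depth = as.integer(msa_depth),
              noise_entropy = noise_entropy, seed = as.integer(seed))
  class(out) <- "fixture_spec"
  out
}

# random standard-amino-acid sequence (3-letter codes)
random_sequence <- function(n) {
  aa3 <- names(max_accessibility())
  sample(aa3, n, replace = TRUE)
}

slab_grid <- function(n, spacing = 6) {
  ncol <- ceiling(sqrt(n))
  i <- seq_len(n) - 1L
  cbind(x = (i %% ncol) * spacing, y = (i %/% ncol) * spacing)
}

# compact block of k grid positions nearest the grid centroid
central_block <- function(grid, k) {
  ctr <- colMeans(grid)
  order((grid[, 1] - ctr[1])^2 + (grid[, 2] - ctr[2])^2)[seq_len(k)]
}

build_chain_atoms <- function(chain, grid3_ca, grid3_cb, resid) {
  n <- nrow(grid3_ca)
  data.frame(chain = chain, resno = rep(seq_len(n), each = 2L),
             insert = "", resid = rep(resid, each = 2L),
             elety = rep(c("CA", "CB"), n), elesym = "C",
             x = as.vector(rbind(grid3_ca[, 1], grid3_cb[, 1])),
             y = as.vector(rbind(grid3_ca[, 2], grid3_cb[, 2])),
             z = as.vector(rbind(grid3_ca[, 3], grid3_cb[, 3])),
             o = 1, alt = "", stringsAsFactors = FALSE)
}

#' Generate a toy two-chain complex with a designed interface
#'
#' Two-slab geometry: both chains are planar grids of two-bead residues
#' (6 A spacing); over the designed contact block the second chain
#' approaches to van der Waals contact (4.2 A between facing backbone
#' beads), elsewhere it stays 25 A away, so exactly the designed residues
#' bury surface area on complexation. Sphere-contact geometry: two
#' sphere-shell chains juxtaposed; the contact set is recorded from the
#' realised geometry. Conserved residues are planted within the interface
#' according to `spec$placement`.
#'
#' @param spec A [fixture_spec()].
#' @return List with `structure` (a `structure_model`), and `truth`: list
#'   with `interface_a`, `interface_b` (keys), `conserved` (keys on chain
#'   A), `conserved_blobs` (list of key sets, the planted sub-clusters).
#' @export
make_complex <- function(spec) {
  old <- local_seed(spec$seed)
  on.exit(restore_seed(old))
  n <- spec$n_residues_per_chain
  if (spec$geometry == "two-slab") {
    grid <- slab_grid(n)
    contact <- central_block(grid, spec$interface_size)
    ca_a <- cbind(grid, z = 0); cb_a <- cbind(grid, z = -2.5)
    zb <- ifelse(seq_len(n) %in% contact, 4.2, 25)
    ca_b <- cbind(grid, z = zb); cb_b <- cbind(grid, z = zb + 2.5)
  } else {
    R <- sqrt(n * 36 / (4 * pi))
    pts <- sphere_points(n) # unit sphere, deterministic
    ca_a <- pts * R
    cb_a <- pts * (R - 2.5)
    # second sphere along +z, brought to van der Waals contact at the poles
    ca_b <- sweep(-pts * R, 2, c(0, 0, 2 * R + 4.2), "+")
    cb_b <- sweep(-pts * (R - 2.5), 2, c(0, 0, 2 * R + 4.2), "+")
    colnames(ca_a) <- colnames(cb_a) <- colnames(ca_b) <- colnames(cb_b) <-
      c("x", "y", "z")
  }
  atoms <- rbind(build_chain_atoms("A", ca_a, cb_a, random_sequence(n)),
                 build_chain_atoms("B", ca_b, cb_b, random_sequence(n)))
  st <- structure_model(chain = atoms$chain, resno = atoms$resno,
                        insert = atoms$insert, resid = atoms$resid,
                        elety = atoms$elety, elesym = atoms$elesym,
                        x = atoms$x, y = atoms$y, z = atoms$z, o = atoms$o)
  if (spec$geometry == "two-slab") {
    int_a <- res_key("A", contact, "")
    int_b <- res_key("B", contact, "")
  } else {
    # record the realised contact set: backbone beads within the burial
    # cutoff distance (r_i + r_j + 2 * probe = 6.2 A) of any partner atom
    keep_a <- apply_contact(ca_a, rbind(ca_b, cb_b), 6.2)
    keep_b <- apply_contact(ca_b, rbind(ca_a, cb_a), 6.2)
    int_a <- res_key("A", which(keep_a), "")
    int_b <- res_key("B", which(keep_b), "")
  }
  cons <- plant_conserved(st, int_a, spec)
  truth <- list(interface_a = int_a, interface_b = int_b,
                conserved = unlist(cons), conserved_blobs = cons)
  list(structure = st, truth = truth)
}

apply_contact <- function(from, to, cutoff) {
  vapply(seq_len(nrow(from)), function(i) {
    min(sqrt((to[, 1] - from[i, 1])^2 + (to[, 2] - from[i, 2])^2 +
               (to[, 3] - from[i, 3])^2)) < cutoff
  }, logical(1))
}

# choose the conserved residue keys inside the interface per the placement
plant_conserved <- function(st, interface_keys, spec) {
  n_cons <- max(2L, round(spec$conserved_fraction * length(interface_keys)))
  ctr <- residue_centers(st, interface_keys)
  if (spec$placement == "scattered") {
    return(list(sample(interface_keys, n_cons)))
  }
  k <- spec$cluster_count
  per <- diff(round(seq(0, n_cons, length.out = k + 1)))
  taken <- character(0); blobs <- list()
  # one blob: anchor anywhere in the interface; several: well-spread anchors
  seeds <- if (k == 1L) sample.int(nrow(ctr), 1L) else farthest_points(ctr, k)
  for (b in seq_len(k)) {
    d <- sqrt(colSums((t(ctr) - ctr[seeds[b], ])^2))
    cand <- interface_keys[order(d)]
    cand <- setdiff(cand, taken)
    sel <- cand[seq_len(min(per[b], length(cand)))]
    blobs[[b]] <- sel
    taken <- c(taken, sel)
  }
  # keep each blob within a ball of radius extent/4 around its seed where
  # the interface allows it; with a single blob this always holds
  blobs
}

# greedy farthest-point seeds for multi-blob placement
farthest_points <- function(ctr, k) {
  n <- nrow(ctr)
  if (k == 1L) return(which.min(rowSums(sweep(ctr, 2, colMeans(ctr))^2)))
  idx <- which.max(rowSums(sweep(ctr, 2, colMeans(ctr))^2))
  while (length(idx) < k) {
    d <- apply(ctr, 1, function(p) {
      min(sqrt(colSums((t(ctr[idx, , drop = FALSE]) - p)^2)))
    })
    idx <- c(idx, which.max(d))
  }
  idx
}

#' Generate a single-chain sphere-shell fixture for patch scanning
#'
#' Residues sit on a sphere shell (two beads each, side chain pointing
#' inward), so every residue is surface-exposed. A polar cap of
#' `interface_size` residues is designated the true interface; conserved
#' residues are planted inside it (clustered placement confines them to a
#' ball of a quarter of the cap extent around the pole).
#'
#' @param spec A [fixture_spec()].
#' @return List with `structure`, `truth` (`interface`, `conserved`).
#' @export
make_chain_sphere <- function(spec) {
  old <- local_seed(spec$seed)
  on.exit(restore_seed(old))
  n <- spec$n_residues_per_chain
  R <- sqrt(n * 36 / (4 * pi))
  pts <- sphere_points(n)
  ca <- pts * R; cb <- pts * (R - 2.5)
  colnames(ca) <- colnames(cb) <- c("x", "y", "z")
  atoms <- build_chain_atoms("A", ca, cb, random_sequence(n))
  st <- structure_model(chain = atoms$chain, resno = atoms$resno,
                        insert = atoms$insert, resid = atoms$resid,
                        elety = atoms$elety, elesym = atoms$elesym,
                        x = atoms$x, y = atoms$y, z = atoms$z, o = atoms$o)
  # cap of interface_size residues nearest the +z pole
  pole_order <- order(-pts[, 3])
  cap <- pole_order[seq_len(spec$interface_size)]
  int_keys <- res_key("A", cap, "")
  n_cons <- max(2L, round(spec$conserved_fraction * length(int_keys)))
  all_keys <- res_key("A", seq_len(n), "")
  # clustered: a tight sub-cap of the interface around the pole, with
  # background conservation scattered at the same density over the rest of
  # the surface (so every patch has conserved residues, but only the
  # interface has them clustered); scattered: conservation spread uniformly
  # over the whole surface (a no-signal control)
  if (spec$placement == "clustered") {
    blob <- int_keys[seq_len(n_cons)]
    rest <- setdiff(all_keys, int_keys)
    scatter <- sample(rest, round(spec$conserved_fraction * length(rest)))
    cons <- c(blob, scatter)
  } else {
    cons <- sample(all_keys, max(2L, round(spec$conserved_fraction * n)))
  }
  list(structure = st,
       truth = list(interface = int_keys, conserved = cons))
}

#' Generate a thin two-faced slab chain
#'
#' Two parallel residue layers 8 A apart; solvent vectors of interior
#' residues of the two faces are anti-parallel, so patches built with the
#' solvent-vector constraint must never reach the interior of the opposite
#' face. Rim residues (slab edges) face sideways and belong to neither
#' face. Used to exercise the 110-degree rule.
#'
#' @param nx,ny Grid dimensions per face.
#' @param seed Integer seed (residue identities only).
#' @return List with `structure` and `truth` (`face`: named vector, +1 for
#'   interior residues of the top face, -1 for the bottom face interior,
#'   0 for rim residues).
#' @export
make_two_faced_slab <- function(nx = 6L, ny = 6L, seed = 1L) {
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  n <- nx * ny
  i <- seq_len(n) - 1L
  grid <- cbind(x = (i %% nx) * 6, y = (i %/% nx) * 6)
  ca_bot <- cbind(grid, z = 0); cb_bot <- cbind(grid, z = 2.5)
  ca_top <- cbind(grid, z = 8); cb_top <- cbind(grid, z = 5.5)
  ca <- rbind(ca_bot, ca_top); cb <- rbind(cb_bot, cb_top)
  atoms <- build_chain_atoms("A", ca, cb, random_sequence(2L * n))
  st <- structure_model(chain = atoms$chain, resno = atoms$resno,
                        insert = atoms$insert, resid = atoms$resid,
                        elety = atoms$elety, elesym = atoms$elesym,
                        x = atoms$x, y = atoms$y, z = atoms$z, o = atoms$o)
  ix <- i %% nx; iy <- i %/% nx
  interior <- ix > 0L & ix < nx - 1L & iy > 0L & iy < ny - 1L
  face <- c(ifelse(interior, -1L, 0L), ifelse(interior, 1L, 0L))
  names(face) <- res_key("A", seq_len(2L * n), "")
  list(structure = st, truth = list(face = face))
}

#' Planted blobs of residue points for sub-cluster recovery
#'
#' Generates `n_blobs` Gaussian point clouds with centres at least
#' `separation` apart (placed on a line), each of `per_blob` points with
#' the given spatial `spread` (sd per axis).
#'
#' @param n_blobs Number of blobs.
#' @param per_blob Points per blob.
#' @param separation Distance between adjacent blob centres (Angstrom).
#' @param spread Standard deviation of points around their centre
#'   (default 2).
#' @param seed Integer seed.
#' @return List with `points` (keyed matrix) and `truth` (list of key sets,
#'   one per blob).
#' @export
make_blob_points <- function(n_blobs, per_blob, separation, spread = 2,
                             seed = 1L) {
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  pts <- NULL; truth <- list()
  for (b in seq_len(n_blobs)) {
    ctr <- c((b - 1) * separation, 0, 0)
    blob <- sweep(matrix(stats::rnorm(3 * per_blob, sd = spread),
                         ncol = 3), 2, ctr, "+")
    keys <- sprintf("A:%d", (b - 1) * per_blob + seq_len(per_blob))
    rownames(blob) <- keys
    pts <- rbind(pts, blob)
    truth[[b]] <- keys
  }
  colnames(pts) <- c("x", "y", "z")
  list(points = pts, truth = truth)
}

# invert the k-class entropy target: probabilities (p, (1-p)/(k-1), ...)
# with -sum p ln p = target
entropy_target_probs <- function(target) {
  if (target <= 1e-12) return(1)
  k <- 2L
  while (log(k) < target - 1e-12) k <- k + 1L
  if (abs(log(k) - target) < 1e-12) return(rep(1 / k, k))
  h <- function(p) {
    q <- (1 - p) / (k - 1)
    -(p * log(p) + (k - 1) * q * log(q))
  }
  p <- stats::uniroot(function(p) h(p) - target, c(1 / k + 1e-9, 1 - 1e-9),
                      tol = 1e-12)$root
  c(p, rep((1 - p) / (k - 1), k - 1))
}

#' Generate a controlled alignment for a fixture chain
#'
#' The query row is the chain's observed sequence. Columns of planted
#' conserved residues are drawn entirely within the query residue's
#' amino-acid class (class entropy exactly 0); every other column mixes the
#' query's class with other classes in deterministic proportions chosen so
#' its class entropy is as close to `spec$noise_entropy` as rounding to
#' `msa_depth` rows permits.
#'
#' @param spec A [fixture_spec()].
#' @param truth Truth list from a generator (uses `conserved`).
#' @param structure The fixture `structure_model`.
#' @param chain Chain to build the alignment for (default "A").
#' @return An `msa` object.
#' @export
make_alignment <- function(spec, truth, structure, chain = "A") {
  old <- local_seed(spec$seed + 1L)
  on.exit(restore_seed(old))
  cseq <- chain_sequence(structure, chain)
  keys <- names(cseq)
  depth <- spec$msa_depth
  scheme <- class_scheme()
  by_class <- split(names(scheme), scheme)
  probs <- entropy_target_probs(spec$noise_entropy)
  mat <- matrix("", nrow = depth, ncol = length(keys))
  conserved <- keys %in% truth$conserved
  for (j in seq_along(keys)) {
    qcls <- scheme[[cseq[j]]]
    if (conserved[j]) {
      letters_j <- sample(by_class[[qcls]], depth, replace = TRUE)
      letters_j[1] <- cseq[j]
    } else {
      k <- length(probs)
      other <- sample(setdiff(seq_len(n_classes(scheme)), qcls), k - 1L)
      cls_seq <- c(qcls, other)
      # query row keeps the observed residue; homologue rows are drawn
      # independently from the target class distribution
      col_cls <- sample(cls_seq, depth - 1L, replace = TRUE, prob = probs)
      letters_j <- c(cseq[j], vapply(col_cls, function(cl) {
        sample(by_class[[cl]], 1L)
      }, ""))
    }
    mat[, j] <- letters_j
  }
  new_alignment(mat, ids = c("query", sprintf("hom%03d", seq_len(depth - 1L))),
                query = 1L)
}

#' Synthetic alanine-scanning annotations with planted localisation
#'
#' Assigns ddG >= 2 kcal/mol to `n_hot` interface residues, an exact
#' `inside_fraction` of them drawn from the planted conserved set; all
#' remaining interface residues receive ddG in [0, 1).
#'
#' @param truth Truth list with `interface_a` (or `interface`) and
#'   `conserved`.
#' @param structure The fixture structure (for residue names).
#' @param inside_fraction Fraction of hot residues inside the conserved set
#'   (0..1).
#' @param n_hot Number of hot residues.
#' @param seed Integer seed.
#' @return Data frame with columns key, resname, ddg.
#' @export
make_hotspot_annotations <- function(truth, structure, inside_fraction,
                                     n_hot, seed = 1L) {
  if (inside_fraction < 0 || inside_fraction > 1) {
    stop("inside_fraction must be in [0, 1]")
  }
  interface <- if (!is.null(truth$interface_a)) truth$interface_a else
    truth$interface
  if (n_hot > length(interface)) stop("n_hot exceeds interface size")
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  n_in <- round(inside_fraction * n_hot)
  inside <- sample(intersect(truth$conserved, interface), n_in)
  outside <- sample(setdiff(interface, truth$conserved), n_hot - n_in)
  hot <- c(inside, outside)
  cold <- setdiff(interface, hot)
  key <- c(hot, cold)
  ddg <- c(2 + stats::runif(length(hot)), stats::runif(length(cold), 0, 0.99))
  data.frame(key = key, resname = unname(residue_names(structure, key)),
             ddg = ddg, stringsAsFactors = FALSE)
}

#' Write a fixture to disk (PDB, aligned FASTA, truth JSON)
#'
#' @param fixture List with `structure` and `truth`.
#' @param alignment Optional `msa` to write alongside.
#' @param dir Output directory (created if needed).
#' @param name Base file name (default "fixture").
#' @return Named character vector of the files written.
#' @export
write_fixture <- function(fixture, alignment = NULL, dir, name = "fixture") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(pdb = file.path(dir, paste0(name, ".pdb")),
             truth = file.path(dir, paste0(name, "_truth.json")))
  write_structure(fixture$structure, paths[["pdb"]])
  jsonlite::write_json(fixture$truth, paths[["truth"]], auto_unbox = FALSE,
                       pretty = TRUE)
  if (!is.null(alignment)) {
    paths[["msa"]] <- file.path(dir, paste0(name, ".fasta"))
    write_alignment(alignment, paths[["msa"]])
  }
  paths
}
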