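sphere_fixture <- function(seed = 2, n = 80L, cap = 20L) {
  fx <- make_chain_sphere(fixture_spec(n_residues_per_chain = n,
                                       interface_size = cap, seed = seed))
  surf <- surface_residues(fx$structure)
  list(fx = fx, surf = surf)
}

test_that("fixed-radius patches equal a brute-force distance filter", {
  sf <- sphere_fixture()
  ctr <- residue_centers(sf$fx$structure, sf$surf$key)
  patches <- generate_patches_fixed(sf$fx$structure, sf$surf, 15)
  expect_length(patches, nrow(ctr))
  expect_setequal(vapply(patches, `[[`, "", "center"), rownames(ctr))
  for (p in patches[c(1, 10, 40)]) {
    d <- sqrt(colSums((t(ctr) - ctr[p$center, ])^2))
    expect_setequal(p$members, rownames(ctr)[d <= 15])
    expect_true(p$center %in% p$members)
  }
})

test_that("patch radius extremes: singleton and whole-surface patches", {
  st <- structure_model(chain = "A", resno = 1:3, resid = "ALA", elety = "CA",
                        elesym = "C", x = c(0, 100, 200), y = 0, z = 0)
  surf <- surface_residues(st)
  small <- generate_patches_fixed(st, surf, 5)
  expect_true(all(vapply(small, function(p) length(p$members), 1L) == 1L))
  big <- generate_patches_fixed(st, surf, 1e4)
  expect_true(all(vapply(big, function(p) length(p$members), 1L) == 3L))
})

test_that("adaptive radius is half the maximum interface atom distance", {
  atoms30 <- data.frame(x = c(0, 30, 5), y = 0, z = 0)
  expect_equal(ppiclust:::half_max_atom_distance(atoms30), 15)
  atoms44 <- data.frame(x = c(0, 44), y = 0, z = 0)
  expect_equal(ppiclust:::half_max_atom_distance(atoms44), 22)
  sf <- sphere_fixture()
  ia <- sf$fx$structure$atoms[
    sf$fx$structure$atoms$key %in% sf$fx$truth$interface, ]
  adaptive <- generate_patches_adaptive(sf$fx$structure, sf$surf, ia)
  fixed <- generate_patches_fixed(sf$fx$structure, sf$surf,
                                  attr(adaptive, "radius"))
  expect_equal(lapply(adaptive, `[[`, "members"),
               lapply(fixed, `[[`, "members"))
  expect_error(generate_patches_adaptive(sf$fx$structure, sf$surf,
                                         atoms44[1, , drop = FALSE]),
               "fewer than 2")
})

test_that("solvent vectors are unit length and point outward on a sphere", {
  # shell small enough that the 10 nearest neighbours span a wide solid
  # angle: their centroid then sits well inside the body and the inverted
  # vector is close to the outward radial direction
  sf <- sphere_fixture(n = 24L, cap = 6L)
  sv <- compute_solvent_vectors(sf$fx$structure, sf$surf, 10)
  norms <- sqrt(rowSums(sv^2))
  expect_equal(norms, rep(1, nrow(sv)), tolerance = 1e-9, ignore_attr = TRUE)
  ctr <- residue_centers(sf$fx$structure, rownames(sv))
  radial <- ctr / sqrt(rowSums(ctr^2))
  ang <- acos(pmin(1, rowSums(sv * radial))) * 180 / pi
  expect_true(all(ang < 15))
  # unit-norm contract holds on an irregular dense shell too
  sf2 <- sphere_fixture(n = 120L, cap = 20L)
  sv2 <- compute_solvent_vectors(sf2$fx$structure, sf2$surf, 10)
  expect_equal(sqrt(rowSums(sv2^2)), rep(1, nrow(sv2)), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("a residue above a symmetric ring points along the ring axis", {
  th <- seq(0, 2 * pi, length.out = 11)[-11]
  st <- structure_model(chain = "A", resno = 1:11, resid = "ALA",
                        elety = "CA", elesym = "C",
                        x = c(0, 6 * cos(th)), y = c(0, 6 * sin(th)),
                        z = c(3, rep(0, 10)))
  surf <- surface_residues(st)
  sv <- compute_solvent_vectors(st, surf, 10)
  expect_equal(unname(sv["A:1", ]), c(0, 0, 1), tolerance = 1e-9)
})

test_that("too few surface neighbours is an error", {
  st <- structure_model(chain = "A", resno = 1:4, resid = "ALA", elety = "CA",
                        elesym = "C", x = (1:4) * 8, y = 0, z = 0)
  surf <- surface_residues(st)
  expect_error(compute_solvent_vectors(st, surf, 10), "surface residues")
})

test_that("the solvent-vector constraint keeps patches off the far face", {
  slab <- make_two_faced_slab(6, 6, seed = 1)
  surf <- surface_residues(slab$structure)
  patches <- generate_patches_vector(slab$structure, surf, radius = 30,
                                     angle_cutoff = 110)
  face <- slab$truth$face
  violations <- 0L
  for (p in patches) {
    if (face[p$center] == 0L) next  # rim residues face sideways
    violations <- violations + sum(face[p$members] == -face[p$center])
  }
  expect_identical(violations, 0L)
})

test_that("vector patches equal the distance+angle brute-force filter", {
  sf <- sphere_fixture()
  patches <- generate_patches_vector(sf$fx$structure, sf$surf, radius = 14,
                                     angle_cutoff = 110)
  sv <- attr(patches, "solvent_vectors")
  ctr <- residue_centers(sf$fx$structure, sf$surf$key)
  for (p in patches[c(3, 17, 60)]) {
    keep <- character(0)
    for (k in rownames(ctr)) {
      dd <- sqrt(sum((ctr[k, ] - ctr[p$center, ])^2))
      ang <- acos(max(-1, min(1, sum(sv[k, ] * sv[p$center, ])))) * 180 / pi
      if (dd <= 14 && (ang < 110 || k == p$center)) keep <- c(keep, k)
    }
    expect_setequal(p$members, keep)
  }
})

test_that("patch methods are nested per centre at a common radius", {
  sf <- sphere_fixture()
  ia <- sf$fx$structure$atoms[
    sf$fx$structure$atoms$key %in% sf$fx$truth$interface, ]
  r <- ppiclust:::half_max_atom_distance(ia)
  m1 <- generate_patches_fixed(sf$fx$structure, sf$surf, r)
  m3 <- generate_patches_vector(sf$fx$structure, sf$surf, radius = r)
  for (i in seq_along(m1)) {
    expect_true(all(m3[[i]]$members %in% m1[[i]]$members))
  }
})

test_that("patch scoring: full-patch conserved set gives rho exactly 1", {
  sf <- sphere_fixture()
  patch <- list(surface_patch(sf$surf$key[1], sf$surf$key[1:8]))
  prof <- data.frame(key = sf$surf$key, s = 0, s_relative = NA_real_)
  scored <- score_patches(patch, sf$fx$structure, prof, criterion = "zero")
  expect_false(scored[[1]]$too_few)
  expect_identical(scored[[1]]$rho, 1)
})

test_that("patches with under two conserved residues carry the marker", {
  sf <- sphere_fixture()
  keys <- sf$surf$key[1:6]
  prof <- data.frame(key = sf$surf$key,
                     s = ifelse(sf$surf$key == keys[1], 0, 0.9),
                     s_relative = NA_real_)
  patch <- list(surface_patch(keys[1], keys))
  scored <- score_patches(patch, sf$fx$structure, prof, criterion = "zero")
  expect_true(scored[[1]]$too_few)
  expect_true(is.na(scored[[1]]$rho))
})

test_that("per-patch rho equals an independent recomputation", {
  spec <- fixture_spec(n_residues_per_chain = 80L, interface_size = 20L,
                       seed = 12)
  fx <- make_chain_sphere(spec)
  aln <- make_alignment(spec, fx$truth, fx$structure, "A")
  prof <- entropy_profile(aln, fx$structure, "A")
  surf <- surface_residues(fx$structure)
  patches <- generate_patches_fixed(fx$structure, surf, 13)
  scored <- score_patches(patches, fx$structure, prof)
  ctr <- residue_centers(fx$structure)
  for (p in scored[c(2, 20, 55)]) {
    if (p$too_few) next
    vals <- prof$s[match(p$members, prof$key)]
    cons <- p$members[vals < mean(vals)]
    expect_equal(p$rho, ms_brute(ctr[cons, , drop = FALSE]) /
                   ms_brute(ctr[p$members, , drop = FALSE]),
                 tolerance = 1e-12)
  }
})

test_that("overlap percentage follows its definition", {
  interface <- sprintf("A:%d", 1:10)
  expect_equal(patch_overlap_percent(interface, interface), 100)
  expect_equal(patch_overlap_percent(sprintf("B:%d", 1:10), interface), 0)
  expect_equal(patch_overlap_percent(sprintf("A:%d", 1:5), interface), 50)
  expect_equal(patch_overlap_percent(sprintf("A:%d", 3:30), interface), 80)
  expect_error(patch_overlap_percent(interface, character(0)), "empty")
  for (s in 1:20) {
    set.seed(s)
    members <- sample(sprintf("A:%d", 1:50), 20)
    expect_equal(patch_overlap_percent(members, interface),
                 overlap_brute(members, interface))
  }
})

test_that("interface ranking: top rank, z-score arithmetic, and tie rule", {
  mk <- function(center, rho, too_few = FALSE) {
    list(center = center, members = center, rho = rho,
         n_conserved = if (too_few) 0L else 3L, too_few = too_few)
  }
  comp <- list(mk("p1", 0.9), mk("p2", 1.0), mk("p3", 1.1))
  int <- mk("int", 1.3)
  r <- rank_interface(comp, int)
  expect_equal(r$interface_rank, 1L)
  expect_equal(r$z_score, 3.0, tolerance = 1e-12)
  # with enough patches, the top rank falls in the first decile bin
  many <- lapply(1:19, function(i) mk(sprintf("q%d", i), 1 - i / 100))
  expect_equal(rank_interface(many, int)$decile, 1L)
  # ties at the interface value do not push the interface down
  r2 <- rank_interface(list(mk("p1", 1.3), mk("p2", 1.0)), int)
  expect_equal(r2$interface_rank, 1L)
  # marker patches stay in the denominator but rank below numeric ones
  r3 <- rank_interface(list(mk("p1", 2.0), mk("p2", NA, TRUE)), mk("int", 1.5))
  expect_equal(r3$interface_rank, 2L)
  expect_equal(r3$n_patches, 2L)
  expect_equal(r3$decile, ceiling(10 * 2 / 3))
})

test_that("ranking equals a brute-force sort over 99 patches", {
  set.seed(77)
  rhos <- c(runif(90, 0.5, 2), rep(NA, 9))
  comp <- lapply(seq_along(rhos), function(i) {
    list(center = sprintf("p%d", i), members = sprintf("p%d", i),
         rho = rhos[i], n_conserved = ifelse(is.na(rhos[i]), 1L, 4L),
         too_few = is.na(rhos[i]))
  })
  int <- list(center = "int", members = "int", rho = 1.2, n_conserved = 5L,
              too_few = FALSE)
  r <- rank_interface(comp, int)
  expect_equal(r$interface_rank, 1L + sum(rhos > 1.2, na.rm = TRUE))
  expect_equal(r$decile, ceiling(10 * r$interface_rank / 100))
  # invariant to the order in which patches are supplied
  r_shuf <- rank_interface(comp[sample(99)], int)
  expect_equal(r_shuf$interface_rank, r$interface_rank)
  expect_equal(r_shuf$z_score, r$z_score)
})

test_that("a marker-valued interface is reported in the worst decile", {
  comp <- list(list(center = "p1", members = "p1", rho = 1.1,
                    n_conserved = 3L, too_few = FALSE))
  int <- list(center = "int", members = "int", rho = NA_real_,
              n_conserved = 1L, too_few = TRUE)
  r <- rank_interface(comp, int)
  expect_true(r$interface_too_few)
  expect_equal(r$decile, 10L)
})

test_that("interface deciles are uniform when conservation carries no signal", {
  n_rep <- 200
  dec <- integer(n_rep)
  for (s in seq_len(n_rep)) {
    spec <- fixture_spec(seed = 50000 + s, placement = "scattered")
    fx <- make_chain_sphere(spec)
    aln <- make_alignment(spec, fx$truth, fx$structure, "A")
    pred <- predict_binding_site(fx$structure, aln, "A", method = 1,
                                 true_interface = fx$truth$interface)
    dec[s] <- pred$ranking$decile
  }
  chi <- chisq.test(tabulate(dec, 10), p = rep(0.1, 10))
  expect_gt(chi$p.value, 0.01)
})
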