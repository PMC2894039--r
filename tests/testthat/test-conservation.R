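test_that("aligned FASTA reading normalises gaps and round-trips", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "AC-DE", ">b", "AC.DE", ">c", "acgde"), f)
  aln <- read_alignment(f)
  expect_equal(dim(aln$seqs), c(3L, 5L))
  expect_equal(aln$seqs[1, 3], "-")
  expect_equal(aln$seqs[2, 3], "-")
  expect_equal(aln$seqs[3, ], c("A", "C", "G", "D", "E"))
  f2 <- withr::local_tempfile(fileext = ".fasta")
  write_alignment(aln, f2)
  expect_equal(read_alignment(f2)$seqs, aln$seqs)
})

test_that("ragged or single-sequence alignments are rejected", {
  expect_error(alignment_from_strings(c("ACDE", "ACD")), "lengths")
  expect_error(alignment_from_strings("ACDE"), ">= 2")
})

test_that("column entropy: invariant, within-class, and two-class columns", {
  expect_equal(column_entropy(strsplit("AAAA", "")[[1]]), 0)
  # V, L, I, M all fall in one class: no penalty for these substitutions
  expect_equal(column_entropy(strsplit("VLIM", "")[[1]]), 0)
  expect_equal(column_entropy(strsplit("DDRR", "")[[1]]), log(2))
})

test_that("column entropy ignores gaps and unknowns, NA when unusable", {
  expect_equal(column_entropy(c("A", "-", "V", "X")), 0)
  expect_true(is.na(column_entropy(c("-", "-", "X"))))
})

test_that("entropy is invariant to within-class substitution and row order", {
  col <- c("D", "E", "R", "K", "A", "V", "G")
  swapped <- c("E", "D", "K", "R", "V", "A", "S")  # same classes per row
  expect_equal(column_entropy(col), column_entropy(swapped))
  for (s in 1:5) {
    col2 <- rand_column(30, s)
    set.seed(s + 100)
    expect_equal(column_entropy(sample(col2)), column_entropy(col2))
  }
})

test_that("entropy attains ln 7 exactly at the uniform 7-class column", {
  col <- c("A", "G", "D", "N", "R", "P", "H")
  expect_equal(column_entropy(col), log(7))
  # any other composition stays strictly below
  expect_lt(column_entropy(c("A", "A", "D", "N", "R", "P", "H")), log(7))
})

test_that("relative entropy: matched background gives 0, invariant gives ln 4", {
  bg <- c(0.25, 0.25, 0.25, 0.05, 0.05, 0.05, 0.1)
  # column distribution equal to background over observed classes
  col <- c(rep("A", 25), rep("G", 25), rep("D", 25), rep("N", 5),
           rep("R", 5), rep("P", 5), rep("H", 10))
  expect_equal(column_relative_entropy(col, bg), 0, tolerance = 1e-12)
  bg2 <- c(0.25, 0.25, 0.25, 0.25 - 0.15, 0.05, 0.05, 0.05)
  expect_equal(column_relative_entropy(rep("A", 10), bg2), log(4))
})

test_that("relative entropy matches brute-force summation on random columns", {
  for (s in 1:100) {
    col <- rand_column(50, s)
    set.seed(s + 1000)
    bg <- runif(7, 0.1, 1); bg <- bg / sum(bg)
    expect_equal(column_relative_entropy(col, bg), kl_brute(col, bg),
                 tolerance = 1e-12)
  }
})

test_that("relative entropy identity against plain entropy terms", {
  # sum p ln(p/q) = (sum p ln p) - (sum p ln q), each summed independently
  for (s in 1:20) {
    col <- rand_column(40, s)
    set.seed(s + 2000)
    bg <- runif(7, 0.1, 1); bg <- bg / sum(bg)
    cp <- table(factor(class_scheme()[col], levels = 1:7)) / length(col)
    t1 <- sum(cp[cp > 0] * log(cp[cp > 0]))
    t2 <- sum(cp[cp > 0] * log(bg[cp > 0]))
    expect_equal(column_relative_entropy(col, bg), t1 - t2, tolerance = 1e-12)
  }
})

test_that("background frequencies come from smoothed class counts", {
  bg <- background_from_sequences(c("DDEE", "RRKK"))
  expect_equal(bg[3], bg[5])
  expect_equal(bg[1], bg[2])  # unobserved classes at the pseudo-count floor
  expect_lt(bg[1], bg[3])
  expect_equal(sum(bg), 1, tolerance = 1e-12)
  bg_h <- background_from_sequences("H")
  expect_equal(which.max(bg_h), 7L)
  set.seed(5)
  seqs <- paste(sample(names(class_scheme()), 1000, replace = TRUE),
                collapse = "")
  bg_big <- background_from_sequences(seqs)
  counts <- table(factor(class_scheme()[strsplit(seqs, "")[[1]]],
                         levels = 1:7))
  expect_equal(bg_big, as.numeric(counts + 1) / sum(counts + 1),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("background table round-trips through its text format", {
  bg <- background_from_sequences("DDEERRKKAAGG")
  f <- withr::local_tempfile(fileext = ".txt")
  write_background(bg, f)
  expect_equal(read_background(f), bg, tolerance = 1e-9)
})

make_toy_chain <- function(seq3, chain = "A") {
  n <- length(seq3)
  structure_model(chain = chain, resno = seq_len(n), resid = seq3,
                  elety = "CA", elesym = "C",
                  x = seq_len(n) * 4, y = 0, z = 0)
}

test_that("query-to-structure mapping: identity and truncated chain", {
  seq3 <- c("ALA", "GLY", "ASP", "ARG", "HIS", "TRP")
  st <- make_toy_chain(seq3)
  aln <- alignment_from_strings(c("AGDRHW", "AGDKHW"))
  map <- map_query_to_structure(aln, st, "A")
  expect_equal(unname(map), residue_keys(st))
  expect_equal(names(map), as.character(1:6))
  # chain missing the two N-terminal residues of the query
  st2 <- make_toy_chain(seq3[3:6])
  expect_warning(map2 <- map_query_to_structure(aln, st2, "A"), "unmapped")
  expect_equal(unname(map2), residue_keys(st2))
  expect_equal(names(map2), as.character(3:6))
})

test_that("gapped query columns are skipped in the mapping", {
  st <- make_toy_chain(c("ALA", "GLY", "ASP"))
  aln <- alignment_from_strings(c("A-GD", "AKGD"))
  map <- map_query_to_structure(aln, st, "A")
  expect_equal(names(map), c("1", "3", "4"))
})

test_that("excessive identity mismatch is an error, small mismatch tolerated", {
  st <- make_toy_chain(c("ALA", "GLY", "ASP", "ARG"))
  aln_bad <- alignment_from_strings(c("AWWW", "AGDR"))
  expect_error(map_query_to_structure(aln_bad, st, "A"), "mismatch")
  aln_ok <- alignment_from_strings(c("AGDK", "AGDR"))  # 1/4 over tolerance
  expect_error(map_query_to_structure(aln_ok, st, "A"), "mismatch")
  map <- map_query_to_structure(aln_ok, st, "A", max_mismatch = 0.3)
  expect_equal(unname(map), residue_keys(st))
})

test_that("conserved selection uses strict inequalities and exact zeros", {
  st <- make_toy_chain(c("ALA", "GLY", "ASP"))
  prof <- data.frame(key = residue_keys(st), s = c(0.2, 0.4, 0.6),
                     s_relative = NA_real_)
  sel <- select_conserved(prof, prof$key, "mean")
  expect_equal(sel$members, "A:1")  # 0.4 is not strictly below the mean
  expect_equal(sel$mean_entropy, 0.4)
  prof2 <- data.frame(key = prof$key, s = c(0, 0, 0.5), s_relative = NA_real_)
  expect_setequal(select_conserved(prof2, prof2$key, "zero")$members,
                  c("A:1", "A:2"))
})

test_that("all three criteria match a brute-force filter on random profiles", {
  for (s in 1:25) {
    set.seed(s)
    n <- 40
    keys <- sprintf("A:%d", 1:n)
    vals <- round(runif(n, 0, log(7)), 3)
    vals[sample(n, 3)] <- 0
    prof <- data.frame(key = keys, s = vals, s_relative = NA_real_)
    m <- mean(vals); sdv <- sd(vals)
    expect_setequal(select_conserved(prof, keys, "mean")$members,
                    keys[vals < m])
    expect_setequal(select_conserved(prof, keys, "mean-sd")$members,
                    keys[vals < m - sdv])
    expect_setequal(select_conserved(prof, keys, "zero")$members,
                    keys[vals == 0])
  }
})

test_that("below-mean selection is non-empty unless all entropies tie", {
  for (s in 1:20) {
    set.seed(s)
    vals <- sample(c(0, 0.3, 0.7, 1.1), 12, replace = TRUE)
    if (length(unique(vals)) == 1) next
    prof <- data.frame(key = sprintf("A:%d", 1:12), s = vals,
                       s_relative = NA_real_)
    expect_gt(length(select_conserved(prof, prof$key, "mean")$members), 0)
  }
})

test_that("entropy profile maps fixture truth onto residues", {
  spec <- fixture_spec(seed = 21)
  fx <- make_complex(spec)
  aln <- make_alignment(spec, fx$truth, fx$structure, "A")
  prof <- entropy_profile(aln, fx$structure, "A")
  expect_equal(nrow(prof), length(residue_keys(subset_chains(fx$structure,
                                                             "A"))))
  planted <- prof$s[prof$key %in% fx$truth$conserved]
  expect_true(all(planted == 0))
  noise <- prof$s[!prof$key %in% fx$truth$conserved]
  expect_true(all(abs(noise - log(2)) < 0.35))
  expect_equal(abs(mean(noise) - log(2)) < 0.05, TRUE)
})

test_that("columns below the minimum depth are undefined", {
  st <- make_toy_chain(c("ALA", "GLY"))
  aln <- alignment_from_strings(c("AG", "A-", "A-"))
  prof <- entropy_profile(aln, st, "A", min_rows = 2L)
  expect_false(is.na(prof$s[1]))
  expect_true(is.na(prof$s[2]))
  expect_equal(prof$n_effective, c(3L, 1L))
})
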