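#' Read a multiple sequence alignment from aligned FASTA
#'
#' Residues are upper-cased; `-` and `.` are both stored as the gap
#' character `-`. Nonstandard letters (including `X`) are kept but flagged
#' with a warning; they are excluded from entropy counts downstream.
#'
#' @param path Aligned FASTA file with at least two rows.
#' @param query Index (or id) of the row corresponding to the structure's
#'   chain (default 1).
#' @return An object of class `msa`: list with `seqs` (character matrix,
#'   rows = sequences, columns = alignment positions), `ids`, `query_index`.
#' @export
read_alignment <- function(path, query = 1L) {
  fa <- bio3d::read.fasta(path, rm.dup = FALSE)
  mat <- toupper(fa$ali)
  mat[mat == "."] <- "-"
  new_alignment(mat, fa$id, query)
}

new_alignment <- function(mat, ids = NULL, query = 1L) {
  if (is.null(dim(mat))) mat <- matrix(mat, nrow = 1)
  if (nrow(mat) < 2L) stop("alignment needs >= 2 sequences, got ", nrow(mat))
  if (is.null(ids)) ids <- paste0("seq", seq_len(nrow(mat)))
  if (is.character(query)) {
    query <- match(query, ids)
    if (is.na(query)) stop("query id not found in alignment")
  }
  known <- c(names(class_scheme()), "-", "X")
  odd <- setdiff(unique(as.vector(mat)), known)
  if (length(odd)) {
    warning("nonstandard alignment letters treated as unknown: ",
            paste(odd, collapse = ", "))
  }
  out <- list(seqs = unname(mat), ids = ids, query_index = as.integer(query))
  class(out) <- "msa"
  out
}

#' Build an alignment object from character strings
#'
#' @param strings Character vector of equal-length gapped sequences.
#' @param ids Optional sequence identifiers.
#' @param query Query row index (default 1).
#' @return An `msa` object.
#' @export
alignment_from_strings <- function(strings, ids = NULL, query = 1L) {
  lens <- nchar(strings)
  if (length(unique(lens)) != 1L) {
    stop("ragged alignment rows; lengths: ", paste(lens, collapse = ", "))
  }
  mat <- toupper(do.call(rbind, strsplit(strings, "")))
  mat[mat == "."] <- "-"
  new_alignment(mat, ids, query)
}

#' Write an alignment to aligned FASTA
#'
#' @param alignment An `msa` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(alignment, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(alignment$seqs))) {
    writeLines(c(paste0(">", alignment$ids[i]),
                 paste(alignment$seqs[i, ], collapse = "")), con)
  }
  invisible(path)
}

#' @export
print.msa <- function(x, ...) {
  cat("msa:", nrow(x$seqs), "sequences x", ncol(x$seqs),
      "columns; query row", x$query_index, "\n")
  invisible(x)
}

#' Map alignment columns onto structure residues
#'
#' Aligns the ungapped query row against the chain's observed residue
#' sequence (global alignment) and returns, for each alignment column, the
#' residue key it describes. Columns for residues missing from the
#' coordinates are unmapped (dropped with a warning); identity mismatches are
#' tolerated up to `max_mismatch` of mapped positions.
#'
#' @param alignment An `msa` object.
#' @param structure A `structure_model`.
#' @param chain Chain identifier in `structure`.
#' @param max_mismatch Tolerated fraction of identity mismatches (default
#'   0.05).
#' @return Named character vector: names are alignment column indices,
#'   values residue keys.
#' @export
map_query_to_structure <- function(alignment, structure, chain,
                                   max_mismatch = 0.05) {
  qrow <- alignment$seqs[alignment$query_index, ]
  qcols <- which(qrow != "-")
  qseq <- qrow[qcols]
  cseq <- chain_sequence(structure, chain)
  if (length(qseq) == length(cseq) && all(qseq == cseq)) {
    out <- names(cseq)
    names(out) <- as.character(qcols)
    return(out)
  }
  aln <- Biostrings::pairwiseAlignment(
    pattern = paste(qseq, collapse = ""),
    subject = paste(cseq, collapse = ""),
    type = "global",
    substitutionMatrix = identity_submat(),
    gapOpening = 8, gapExtension = 2)
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  qi <- 0L; ci <- 0L
  cols <- integer(0); keys <- character(0); mism <- 0L
  for (t in seq_along(pa)) {
    if (pa[t] != "-") qi <- qi + 1L
    if (sa[t] != "-") ci <- ci + 1L
    if (pa[t] != "-" && sa[t] != "-") {
      cols <- c(cols, qcols[qi])
      keys <- c(keys, names(cseq)[ci])
      if (pa[t] != sa[t]) mism <- mism + 1L
    }
  }
  if (length(cols) == 0L) stop("query and chain sequence could not be aligned")
  frac <- mism / length(cols)
  if (frac > max_mismatch) {
    bad <- which(pa != sa & pa != "-" & sa != "-")
    stop(sprintf(paste0("query/chain identity mismatch fraction %.3f exceeds",
                        " tolerance %.3f (first mismatched alignment",
                        " position: %d)"), frac, max_mismatch,
                 if (length(bad)) bad[1] else NA_integer_))
  }
  n_drop <- sum(qrow != "-") - length(cols)
  if (n_drop > 0L) {
    warning(n_drop, " query position(s) missing from coordinates; ",
            "their columns are unmapped")
  }
  names(keys) <- as.character(cols)
  keys
}

identity_submat <- function() {
  letters <- c(names(class_scheme()), "X")
  m <- matrix(-1, length(letters), length(letters),
              dimnames = list(letters, letters))
  diag(m) <- 2
  m["X", ] <- 0; m[, "X"] <- 0
  m
}

# class probabilities of a column: counts over non-gap, standard residues
column_class_probs <- function(column, scheme = class_scheme()) {
  cls <- scheme[column]
  cls <- cls[!is.na(cls)]
  if (length(cls) == 0L) return(NULL)
  tab <- tabulate(cls, nbins = n_classes(scheme))
  list(p = tab / sum(tab), n = length(cls))
}

#' Shannon entropy of an alignment column over amino-acid classes
#'
#' Computes s = -sum_k p(k) ln p(k), where p(k) is the frequency of
#' amino-acid class k (7-class scheme by default) among the non-gap residues
#' of the column. Natural logarithm; within-class substitutions carry no
#' penalty. Gaps and unknown residues ('X') are excluded from the counts.
#'
#' @param column Character vector of aligned residues (one letter each).
#' @param scheme Class scheme, see [class_scheme()].
#' @return Entropy in nats, or `NA_real_` for a column with no usable
#'   residues (all gaps/unknowns).
#' @export
column_entropy <- function(column, scheme = class_scheme()) {
  cp <- column_class_probs(toupper(column), scheme)
  if (is.null(cp)) return(NA_real_)
  p <- cp$p[cp$p > 0]
  -sum(p * log(p))
}

#' Relative entropy (Kullback-Leibler divergence) of a column
#'
#' Computes sum_k p(k) ln(p(k)/p_back(k)) over the classes observed in the
#' column, against supplied background class frequencies. Larger values
#' indicate stronger deviation from background, i.e. stronger evolutionary
#' constraint. Only classes present in the column enter the sum; the
#' background is not renormalised over them.
#'
#' @param column Character vector of aligned residues.
#' @param background Numeric vector of background probabilities per class
#'   (length = number of classes, positive, summing to 1).
#' @param scheme Class scheme.
#' @return Relative entropy in nats, or `NA_real_` for an unusable column.
#' @export
column_relative_entropy <- function(column, background,
                                    scheme = class_scheme()) {
  stopifnot(length(background) == n_classes(scheme),
            abs(sum(background) - 1) < 1e-9)
  cp <- column_class_probs(toupper(column), scheme)
  if (is.null(cp)) return(NA_real_)
  obs <- which(cp$p > 0)
  if (any(background[obs] <= 0)) {
    stop("zero background probability for observed class(es): ",
         paste(obs[background[obs] <= 0], collapse = ", "))
  }
  sum(cp$p[obs] * log(cp$p[obs] / background[obs]))
}

#' Background class frequencies from a pool of sequences
#'
#' Pools all residues of the input strings, counts amino-acid classes, and
#' applies additive smoothing (pseudo-count 1 per class) so that no class
#' has zero probability.
#'
#' @param sequences Character vector of residue strings (gaps ignored).
#' @param scheme Class scheme.
#' @return Numeric vector of class probabilities (sums to 1).
#' @export
background_from_sequences <- function(sequences, scheme = class_scheme()) {
  if (length(sequences) == 0L) stop("no sequences supplied")
  chars <- toupper(unlist(strsplit(sequences, "")))
  cls <- scheme[chars]
  cls <- cls[!is.na(cls)]
  if (length(cls) == 0L) stop("no standard residues in input")
  k <- n_classes(scheme)
  tab <- tabulate(cls, nbins = k) + 1
  tab / sum(tab)
}

#' Read/write a background frequency table
#'
#' Plain text, one line per class: `<class index> <probability>`.
#'
#' @param path File path.
#' @return Numeric vector of probabilities in class order.
#' @export
read_background <- function(path) {
  df <- utils::read.table(path, col.names = c("class", "p"))
  out <- df$p[order(df$class)]
  if (abs(sum(out) - 1) > 1e-9) stop("background probabilities must sum to 1")
  out
}

#' @rdname read_background
#' @param background Numeric vector of class probabilities.
#' @export
write_background <- function(background, path) {
  writeLines(sprintf("%d %.10f", seq_along(background), background), path)
  invisible(path)
}

#' Per-residue entropy profile of a chain
#'
#' Scores every alignment column (plain entropy and, when a background is
#' supplied, relative entropy) and maps the scores onto structure residues
#' via [map_query_to_structure()]. Columns with fewer than `min_rows`
#' usable (non-gap, standard) residues are marked undefined to avoid
#' spurious zero entropies from near-empty columns.
#'
#' @param alignment An `msa` object.
#' @param structure A `structure_model`.
#' @param chain Chain identifier.
#' @param background Optional class background frequencies for relative
#'   entropy.
#' @param scheme Class scheme.
#' @param min_rows Minimum usable rows per column (default 2).
#' @param max_mismatch Passed to [map_query_to_structure()].
#' @return An object of class `entropy_profile`: data frame with columns
#'   key, chain, resno, insert, resid, column, s, s_relative (NA when no
#'   background), n_effective.
#' @export
entropy_profile <- function(alignment, structure, chain, background = NULL,
                            scheme = class_scheme(), min_rows = 2L,
                            max_mismatch = 0.05) {
  mapping <- map_query_to_structure(alignment, structure, chain, max_mismatch)
  cols <- as.integer(names(mapping))
  a <- structure$atoms
  idx <- match(mapping, a$key)
  s <- numeric(length(cols)); srel <- rep(NA_real_, length(cols))
  neff <- integer(length(cols))
  for (i in seq_along(cols)) {
    column <- alignment$seqs[, cols[i]]
    cp <- column_class_probs(column, scheme)
    neff[i] <- if (is.null(cp)) 0L else cp$n
    if (is.null(cp) || cp$n < min_rows) {
      s[i] <- NA_real_
      next
    }
    s[i] <- column_entropy(column, scheme)
    if (!is.null(background)) {
      srel[i] <- column_relative_entropy(column, background, scheme)
    }
  }
  out <- data.frame(key = unname(mapping), chain = a$chain[idx],
                    resno = a$resno[idx], insert = a$insert[idx],
                    resid = a$resid[idx], column = cols, s = s,
                    s_relative = srel, n_effective = neff,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("entropy_profile", "data.frame")
  out
}

#' Select conserved residues from an entropy profile
#'
#' Three criteria of increasing stringency, each evaluated with the mean
#' and standard deviation of entropy computed over the supplied residue set
#' itself: `"mean"` keeps residues with entropy strictly below the set mean;
#' `"mean-sd"` strictly below mean minus one standard deviation;
#' `"zero"` keeps fully conserved residues (entropy 0 within 1e-12).
#' For conservation scored by relative entropy (where larger means more
#' constrained), the sign is flipped internally so "below mean" always means
#' "more conserved than average".
#'
#' @param profile An `entropy_profile`.
#' @param over Residue keys to evaluate over (e.g. interface or patch
#'   members). Residues with undefined entropy are dropped.
#' @param criterion `"mean"`, `"mean-sd"`, or `"zero"`.
#' @param measure `"plain"` (column `s`) or `"relative"` (column
#'   `s_relative`, negated before thresholding).
#' @return An object of class `conserved_set`: list with `members` (keys),
#'   `criterion`, `mean_entropy`, `sd_entropy`, `evaluated` (keys actually
#'   scored).
#' @export
select_conserved <- function(profile, over,
                             criterion = c("mean", "mean-sd", "zero"),
                             measure = c("plain", "relative")) {
  criterion <- match.arg(criterion)
  measure <- match.arg(measure)
  if (length(over) == 0L) stop("empty residue set")
  rows <- profile[match(over, profile$key), , drop = FALSE]
  vals <- if (measure == "plain") rows$s else -rows$s_relative
  ok <- !is.na(vals)
  rows <- rows[ok, , drop = FALSE]; vals <- vals[ok]
  if (length(vals) == 0L) stop("no residues in the set have defined entropy")
  m <- mean(vals); sdv <- stats::sd(vals)
  if (is.na(sdv)) sdv <- 0
  sel <- switch(criterion,
                "mean" = vals < m,
                "mean-sd" = vals < m - sdv,
                "zero" = abs(if (measure == "plain") vals else rows$s) < 1e-12)
  out <- list(members = rows$key[sel], criterion = criterion,
              measure = measure, mean_entropy = m, sd_entropy = sdv,
              evaluated = rows$key)
  class(out) <- "conserved_set"
  out
}

#' @export
print.conserved_set <- function(x, ...) {
  cat("conserved_set:", length(x$members), "of", length(x$evaluated),
      "residues; criterion", x$criterion,
      sprintf("(<s> = %.4f, sd = %.4f nats)\n", x$mean_entropy, x$sd_entropy))
  invisible(x)
}

#' Write an entropy profile as TSV
#'
#' Columns: chain, resnum, icode, resname, s_plain, s_relative, n_effective.
#'
#' @param profile An `entropy_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_entropy_tsv <- function(profile, path) {
  df <- data.frame(chain = profile$chain, resnum = profile$resno,
                   icode = profile$insert, resname = profile$resid,
                   s_plain = profile$s, s_relative = profile$s_relative,
                   n_effective = profile$n_effective)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
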