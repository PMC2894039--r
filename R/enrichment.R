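#' Amino-acid enrichment in the conserved subset of an interface
#'
#' For each amino-acid type X, the enrichment E_X is the frequency of X
#' among the conserved residues divided by its frequency in the whole
#' interface. Amino acids absent from the interface carry `NA` (undefined),
#' not a number.
#'
#' @param conserved Character vector of conserved residue keys (or a
#'   `conserved_set`).
#' @param interface Character vector of interface residue keys (superset of
#'   conserved).
#' @param names3 Named character vector mapping residue keys to 3-letter
#'   residue names (e.g. from a structure via the internal residue table).
#' @return An object of class `enrichment_table`: data frame with columns
#'   aa (1-letter), count_conserved, count_interface, e_x; one row per
#'   standard amino acid.
#' @export
residue_enrichment <- function(conserved, interface, names3) {
  if (inherits(conserved, "conserved_set")) conserved <- conserved$members
  if (length(interface) == 0L) stop("empty interface")
  if (!all(conserved %in% interface)) {
    stop("conserved residues must be a subset of the interface")
  }
  miss <- setdiff(interface, names(names3))
  if (length(miss)) stop("no residue name for key(s): ",
                         paste(miss, collapse = ", "))
  aa_all <- sort(names(class_scheme()))
  to1 <- function(keys) bio3d::aa321(unname(names3[keys]))
  ci <- table(factor(to1(interface), levels = aa_all))
  cc <- table(factor(to1(conserved), levels = aa_all))
  fi <- as.numeric(ci) / length(interface)
  fc <- as.numeric(cc) / max(length(conserved), 1L)
  ex <- ifelse(as.numeric(ci) > 0, fc / fi, NA_real_)
  out <- data.frame(aa = aa_all, count_conserved = as.integer(cc),
                    count_interface = as.integer(ci), e_x = ex,
                    stringsAsFactors = FALSE)
  class(out) <- c("enrichment_table", "data.frame")
  out
}

#' Read per-residue ddG annotations from TSV
#'
#' Expected columns: chain, resnum, icode, resname, ddg (kcal/mol). When a
#' structure is supplied, residue names are checked against it to guard
#' against numbering drift between mutagenesis tables and coordinates.
#'
#' @param path TSV file path.
#' @param structure Optional `structure_model` for validation.
#' @return Data frame with columns key, resname, ddg.
#' @export
read_hotspot_annotations <- function(path, structure = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("chain", "resnum", "icode", "resname", "ddg")
  if (!all(need %in% names(df))) {
    stop("annotation file must have columns: ", paste(need, collapse = ", "))
  }
  df$icode[is.na(df$icode)] <- ""
  key <- res_key(df$chain, df$resnum, df$icode)
  if (any(!is.finite(df$ddg))) stop("non-finite ddG value(s)")
  if (!is.null(structure)) {
    known <- residue_names(structure, intersect(key, structure$atoms$key))
    miss <- setdiff(key, structure$atoms$key)
    if (length(miss)) {
      stop("annotation references unknown residue(s): ",
           paste(miss, collapse = ", "))
    }
    bad <- key[df$resname != unname(known[key])]
    if (length(bad)) {
      stop("residue-name mismatch between annotations and structure at: ",
           paste(bad, collapse = ", "))
    }
  }
  data.frame(key = key, resname = df$resname, ddg = df$ddg,
             stringsAsFactors = FALSE)
}

#' Localisation of experimental hot spots within conserved clusters
#'
#' For each ddG cutoff, counts the annotated residues at or above the
#' cutoff ("hot" residues) and the fraction of them that fall inside any
#' conserved sub-cluster.
#'
#' @param partition A `subcluster_partition` of the conserved residues
#'   (singletons count as clusters unless `exclude_singletons`).
#' @param annotations Data frame with columns key and ddg (see
#'   [read_hotspot_annotations()]).
#' @param cutoffs Numeric ddG cutoffs in kcal/mol (default c(1, 1.5, 2)).
#' @param exclude_singletons Drop one-residue clusters before testing
#'   membership (default FALSE).
#' @return Data frame with columns cutoff, n_hot, n_in_clusters, fraction.
#' @export
hotspot_localization <- function(partition, annotations,
                                 cutoffs = c(1, 1.5, 2),
                                 exclude_singletons = FALSE) {
  clusters <- partition$clusters
  if (exclude_singletons) {
    clusters <- clusters[vapply(clusters, length, 1L) > 1L]
  }
  inside <- unique(unlist(clusters))
  rows <- lapply(cutoffs, function(cut) {
    hot <- annotations$key[annotations$ddg >= cut]
    n_in <- sum(hot %in% inside)
    data.frame(cutoff = cut, n_hot = length(hot), n_in_clusters = n_in,
               fraction = if (length(hot)) n_in / length(hot) else 0)
  })
  do.call(rbind, rows)
}

#' Write an enrichment table as TSV
#'
#' @param table An `enrichment_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_enrichment_tsv <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
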