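# polynomial rolling hash of the serialised configuration (provenance stamp)
config_hash <- function(config) {
  bytes <- utf8ToInt(paste(deparse(config), collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

default_threshold <- function(flavor) if (flavor == "homodimer") 21 else 15
default_radius <- function(flavor) if (flavor == "homodimer") 22 else 15

#' Full conserved-residue clustering analysis of one interface
#'
#' Runs the whole per-interface pipeline: interface detection by buried
#' surface area, per-residue entropy from the alignment, conserved-set
#' selection, clustering ratio rho with a random-subset significance test,
#' average-linkage sub-clusters, amino-acid enrichment, and (when
#' annotations are given) hot-spot localisation. The analysed residues are
#' the interface residues of `chain`; its partner is `partner_chains`.
#'
#' @param structure A `structure_model` or path to a PDB file.
#' @param alignment An `msa` or path to an aligned FASTA whose query row
#'   matches `chain`.
#' @param chain Chain whose interface side is analysed.
#' @param partner_chains Chain id(s) of the binding partner.
#' @param flavor `"complex"` (default) or `"homodimer"`; sets the default
#'   sub-cluster threshold (15 or 21 A).
#' @param criterion Conservation criterion, see [select_conserved()].
#' @param measure `"plain"` entropy or `"relative"` (needs `background`).
#' @param background Optional class background frequencies (vector or file
#'   path); default for relative measure: frequencies of the analysed
#'   interface residues themselves.
#' @param burial_threshold Interface definition, A^2 (default 0.1).
#' @param subcluster_threshold Average-linkage threshold in A; default by
#'   `flavor`.
#' @param n_random Random subsets for the significance test (default 1000).
#' @param seed Integer seed for the random-subset draw (default 20100527).
#' @param annotations Optional ddG annotation data frame (or TSV path).
#' @param probe_radius,n_points SASA parameters.
#' @return An object of class `interface_analysis` bundling all results,
#'   with `print()` and `summary()` methods; see the returned list's
#'   elements `interface`, `profile`, `conserved`, `clustering`,
#'   `random_test`, `subclusters`, `enrichment`, `hotspots`, `config`.
#' @export
analyze_interface <- function(structure, alignment, chain, partner_chains,
                              flavor = c("complex", "homodimer"),
                              criterion = "mean", measure = "plain",
                              background = NULL, burial_threshold = 0.1,
                              subcluster_threshold = NULL, n_random = 1000L,
                              seed = 20100527L, annotations = NULL,
                              probe_radius = 1.4, n_points = 960L) {
  flavor <- match.arg(flavor)
  if (is.character(structure)) structure <- read_structure(structure)
  if (is.character(alignment)) alignment <- read_alignment(alignment)
  if (is.character(background)) background <- read_background(background)
  if (is.character(annotations)) {
    annotations <- read_hotspot_annotations(annotations, structure)
  }
  if (is.null(subcluster_threshold)) {
    subcluster_threshold <- default_threshold(flavor)
  }
  config <- list(chain = chain, partner_chains = partner_chains,
                 flavor = flavor, criterion = criterion, measure = measure,
                 burial_threshold = burial_threshold,
                 subcluster_threshold = subcluster_threshold,
                 n_random = n_random, seed = seed,
                 probe_radius = probe_radius, n_points = n_points)
  interface <- identify_interface(structure, chain, partner_chains,
                                  burial_threshold, probe_radius, n_points)
  if (length(interface$partner_a) == 0L) {
    stop("no interface residues found on chain ", chain)
  }
  if (measure == "relative" && is.null(background)) {
    background <- background_from_sequences(
      paste(bio3d::aa321(unname(residue_names(
        structure, c(interface$partner_a, interface$partner_b)))),
        collapse = ""))
  }
  profile <- entropy_profile(alignment, structure, chain,
                             background = background)
  conserved <- select_conserved(profile, interface$partner_a, criterion,
                                measure)
  centers <- residue_centers(structure, interface$partner_a)
  clustering <- clustering_ratio(
    centers[conserved$members, , drop = FALSE], centers)
  random_test <- NULL
  if (!clustering$too_few) {
    random_test <- random_subset_test(centers, length(conserved$members),
                                      clustering$m_s_subset, n_random, seed)
  }
  subclusters <- if (length(conserved$members) >= 1L) {
    average_linkage_subclusters(
      centers[conserved$members, , drop = FALSE], subcluster_threshold)
  } else NULL
  names3 <- residue_names(structure, interface$partner_a)
  enrichment <- residue_enrichment(conserved$members, interface$partner_a,
                                   names3)
  hotspots <- if (!is.null(annotations) && !is.null(subclusters)) {
    hotspot_localization(subclusters, annotations)
  } else NULL
  out <- list(interface = interface, profile = profile, conserved = conserved,
              clustering = clustering, random_test = random_test,
              subclusters = subclusters, enrichment = enrichment,
              hotspots = hotspots, config = config,
              config_hash = config_hash(config))
  class(out) <- "interface_analysis"
  out
}

#' @export
print.interface_analysis <- function(x, ...) {
  cat("Conserved-residue clustering analysis (", x$config$flavor, ")\n",
      sep = "")
  cat("  chain ", x$config$chain, " vs [",
      paste(x$config$partner_chains, collapse = ","), "]: ",
      length(x$interface$partner_a), " interface residues, ",
      length(x$conserved$members), " conserved (criterion ",
      x$config$criterion, ")\n", sep = "")
  cat(sprintf("  <s>_int = %.4f nats (sd %.4f)\n", x$conserved$mean_entropy,
              x$conserved$sd_entropy))
  if (!x$clustering$too_few) {
    cat(sprintf("  M_s,cons = %.4f, M_s,int = %.4f (1/A), rho = %.4f\n",
                x$clustering$m_s_subset, x$clustering$m_s_whole,
                x$clustering$rho))
  } else {
    cat("  too few conserved residues for a clustering score\n")
  }
  if (!is.null(x$random_test)) {
    cat(sprintf("  <M_s,random> = %.4f (sd %.4f), empirical p = %.4g\n",
                x$random_test$mean_random, x$random_test$sd_random,
                x$random_test$p_empirical))
  }
  if (!is.null(x$subclusters)) {
    cat("  sub-clusters at", x$subclusters$threshold, "A:",
        length(x$subclusters$clusters), "(sizes",
        paste(vapply(x$subclusters$clusters, length, 1L), collapse = ", "),
        ")\n")
  }
  if (!is.null(x$hotspots)) {
    for (i in seq_len(nrow(x$hotspots))) {
      cat(sprintf("  hot spots (ddG >= %.1f): %d/%d in conserved clusters\n",
                  x$hotspots$cutoff[i], x$hotspots$n_in_clusters[i],
                  x$hotspots$n_hot[i]))
    }
  }
  invisible(x)
}

#' @export
summary.interface_analysis <- function(object, ...) {
  x <- object
  out <- data.frame(
    chain = x$config$chain,
    n_interface = length(x$interface$partner_a),
    n_conserved = length(x$conserved$members),
    buried_area = sum(x$interface$delta_asa[x$interface$partner_a]),
    mean_entropy = x$conserved$mean_entropy,
    sd_entropy = x$conserved$sd_entropy,
    m_s_cons = x$clustering$m_s_subset,
    m_s_int = x$clustering$m_s_whole,
    rho = x$clustering$rho,
    p_empirical = if (is.null(x$random_test)) NA_real_ else
      x$random_test$p_empirical,
    n_subclusters = if (is.null(x$subclusters)) NA_integer_ else
      length(x$subclusters$clusters))
  rownames(out) <- NULL
  out
}

#' Write an interface analysis as a JSON report
#'
#' The report is deterministic for identical inputs, configuration and
#' seed (no timestamps) and carries the configuration hash.
#'
#' @param analysis An `interface_analysis`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_analysis_json <- function(analysis, path) {
  x <- analysis
  rep <- list(
    config = x$config, config_hash = x$config_hash,
    interface = list(partner_a = x$interface$partner_a,
                     partner_b = x$interface$partner_b,
                     delta_asa = as.list(round(x$interface$delta_asa, 6))),
    conserved = list(members = x$conserved$members,
                     criterion = x$conserved$criterion,
                     mean_entropy = x$conserved$mean_entropy,
                     sd_entropy = x$conserved$sd_entropy),
    clustering = list(m_s_cons = x$clustering$m_s_subset,
                      m_s_int = x$clustering$m_s_whole,
                      rho = x$clustering$rho),
    random_test = if (is.null(x$random_test)) NULL else
      list(n_trials = x$random_test$n_trials,
           mean_random = x$random_test$mean_random,
           sd_random = x$random_test$sd_random,
           p_empirical = x$random_test$p_empirical,
           seed = x$random_test$seed),
    subclusters = if (is.null(x$subclusters)) NULL else x$subclusters$clusters,
    enrichment = as.data.frame(x$enrichment),
    hotspots = x$hotspots)
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Rank surface patches by conserved-residue clustering
#'
#' Binding-site prediction for a single chain: detects surface residues,
#' generates overlapping patches by one of three schemes (fixed radius;
#' interface-adapted radius; adapted radius plus solvent-vector
#' constraint), scores the clustering of conserved residues within every
#' patch, and ranks patches by descending rho. In evaluation mode (when the
#' true interface is supplied) the true interface is scored as its own
#' residue set and its rank, decile, Z-score and the best patch overlap are
#' reported.
#'
#' @param structure A `structure_model` or PDB path (the chain is extracted).
#' @param alignment An `msa` or aligned FASTA path for the chain.
#' @param chain Chain identifier.
#' @param method Patch generation scheme 1, 2 or 3.
#' @param radius Patch radius in A. Default for method 1 by `flavor`
#'   (15 complex / 22 homodimer); methods 2-3 derive it from the true
#'   interface unless given explicitly.
#' @param flavor `"complex"` or `"homodimer"` (default radius only).
#' @param true_interface Optional character vector of interface residue
#'   keys, or an `interface_record` (side a), enabling evaluation mode and
#'   the adaptive radius.
#' @param angle_cutoff Solvent-vector angle cutoff in degrees (method 3,
#'   default 110).
#' @param k_neighbors Neighbours for solvent vectors (default 10).
#' @param criterion,measure,background Conservation scoring, as in
#'   [analyze_interface()].
#' @param rel_threshold Surface relative-accessibility cutoff (default
#'   0.05).
#' @param reference Maximal-accessibility reference table.
#' @param probe_radius,n_points SASA parameters.
#' @return An object of class `binding_site_prediction`: list with
#'   `patches` (scored data frame), and in evaluation mode `ranking` (a
#'   `patch_ranking`), `best_overlap_percent`, plus `config`.
#' @export
predict_binding_site <- function(structure, alignment, chain, method = 1L,
                                 radius = NULL,
                                 flavor = c("complex", "homodimer"),
                                 true_interface = NULL, angle_cutoff = 110,
                                 k_neighbors = 10L, criterion = "mean",
                                 measure = "plain", background = NULL,
                                 rel_threshold = 0.05,
                                 reference = max_accessibility(),
                                 probe_radius = 1.4, n_points = 960L) {
  flavor <- match.arg(flavor)
  if (is.character(structure)) structure <- read_structure(structure)
  if (is.character(alignment)) alignment <- read_alignment(alignment)
  if (is.character(background)) background <- read_background(background)
  if (inherits(true_interface, "interface_record")) {
    true_interface <- true_interface$partner_a
  }
  chain_st <- subset_chains(structure, chain)
  surface <- surface_residues(chain_st, rel_threshold, reference,
                              probe_radius, n_points)
  int_atoms <- if (!is.null(true_interface)) {
    chain_st$atoms[chain_st$atoms$key %in% true_interface, , drop = FALSE]
  } else NULL
  if (method == 1L && is.null(radius)) radius <- default_radius(flavor)
  if (method %in% c(2L, 3L) && is.null(radius)) {
    if (is.null(int_atoms)) {
      stop("methods 2 and 3 need the true interface (or an explicit radius)")
    }
    radius <- half_max_atom_distance(int_atoms)
  }
  patches <- switch(as.character(method),
    "1" = generate_patches_fixed(chain_st, surface, radius),
    "2" = generate_patches_fixed(chain_st, surface, radius),
    "3" = generate_patches_vector(chain_st, surface, radius = radius,
                                  angle_cutoff = angle_cutoff,
                                  k_neighbors = k_neighbors),
    stop("method must be 1, 2 or 3"))
  profile <- entropy_profile(alignment, structure, chain,
                             background = background)
  scored <- score_patches(patches, chain_st, profile, criterion, measure)
  config <- list(chain = chain, method = method, radius = radius,
                 angle_cutoff = if (method == 3L) angle_cutoff else NA,
                 criterion = criterion, measure = measure,
                 rel_threshold = rel_threshold)
  tab <- data.frame(
    center = vapply(scored, `[[`, "", "center"),
    size = vapply(scored, function(p) length(p$members), 1L),
    n_conserved = vapply(scored, function(p) as.integer(p$n_conserved), 1L),
    rho = vapply(scored, function(p) as.numeric(p$rho), 1),
    stringsAsFactors = FALSE)
  tab <- tab[order(-ifelse(is.na(tab$rho), -Inf, tab$rho)), , drop = FALSE]
  rownames(tab) <- NULL
  out <- list(patches = tab, surface = surface, scored = scored,
              config = config, config_hash = config_hash(config))
  if (!is.null(true_interface)) {
    int_patch <- score_one_patch(new_patch(NA_character_, true_interface),
                                 residue_centers(chain_st), profile,
                                 criterion, measure)
    out$ranking <- rank_interface(scored, int_patch)
    out$best_overlap_percent <- max(vapply(scored, patch_overlap_percent,
                                           1, interface = true_interface))
    out$true_interface <- true_interface
  }
  class(out) <- "binding_site_prediction"
  out
}

#' @export
print.binding_site_prediction <- function(x, ...) {
  cat("binding_site_prediction: chain ", x$config$chain, ", method ",
      x$config$method, ", radius ", sprintf("%.1f", x$config$radius),
      " A, ", nrow(x$patches), " patches\n", sep = "")
  top <- utils::head(x$patches, 5)
  cat("  top patch centres by rho:\n")
  for (i in seq_len(nrow(top))) {
    cat(sprintf("    %s  size %d, conserved %d, rho %s\n", top$center[i],
                top$size[i], top$n_conserved[i],
                ifelse(is.na(top$rho[i]), "-", sprintf("%.3f", top$rho[i]))))
  }
  if (!is.null(x$ranking)) {
    print(x$ranking)
    cat(sprintf("  best patch overlap with the true interface: %.1f%%\n",
                x$best_overlap_percent))
  }
  invisible(x)
}

#' @export
plot.binding_site_prediction <- function(x, ...) {
  if (!is.null(x$ranking)) {
    plot(x$ranking, ...)
  } else {
    rho <- x$patches$rho[!is.na(x$patches$rho)]
    graphics::hist(rho, breaks = 20, col = "grey80", border = "white",
                   main = "Conserved-residue clustering across surface patches",
                   xlab = expression(rho))
  }
  invisible(x)
}

#' Write a binding-site prediction as a JSON report
#'
#' @param prediction A `binding_site_prediction`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_prediction_json <- function(prediction, path) {
  x <- prediction
  rep <- list(config = x$config, config_hash = x$config_hash,
              patches = x$patches)
  if (!is.null(x$ranking)) {
    rep$interface_rank <- x$ranking$interface_rank
    rep$decile <- x$ranking$decile
    rep$rho_interface <- x$ranking$rho_interface
    rep$z_score <- x$ranking$z_score
    rep$best_overlap_percent <- x$best_overlap_percent
  }
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
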