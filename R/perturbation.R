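# Functional-validation statistics for miRNA perturbation experiments: probe
# collapsing, CDF / Kolmogorov-Smirnov comparisons by site class and
# AGO-binding-change analysis for inhibitor designs.

#' Collapse probe-level expression values to genes
#'
#' Genes with sign-contradictory probes (some positive and some negative
#' log2 fold-changes) are removed; remaining genes get the mean of their
#' probe values. Idempotent on collapsed tables.
#'
#' @param table data.frame(gene_id, probe_id, log2fc).
#' @return data.frame(gene_id, log2fc), one row per gene.
#' @export
collapse_probes <- function(table) {
  if (nrow(table) == 0L) stop("empty expression table")
  sp <- split(table$log2fc, table$gene_id)
  contradictory <- vapply(sp, function(v) min(v) < 0 && max(v) > 0, logical(1))
  means <- vapply(sp[!contradictory], mean, numeric(1))
  out <- data.frame(gene_id = names(means), log2fc = unname(means),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Compare expression-change distributions of two gene sets
#'
#' Two-sample Kolmogorov-Smirnov test of log2 fold-changes, with the ECDF
#' curves exported.
#'
#' @param group,control gene id vectors.
#' @param collapsed collapsed expression table from [collapse_probes()].
#' @return list(D, p, n_group, n_control, ecdf_group, ecdf_control).
#' @export
cdf_compare <- function(group, control, collapsed) {
  g <- collapsed$log2fc[collapsed$gene_id %in% group]
  c0 <- collapsed$log2fc[collapsed$gene_id %in% control]
  if (!length(g) || !length(c0)) stop("empty gene set after joining with table")
  ks <- suppressWarnings(stats::ks.test(g, c0))
  list(D = unname(ks$statistic), p = ks$p.value,
       n_group = length(g), n_control = length(c0),
       ecdf_group = stats::ecdf(g), ecdf_control = stats::ecdf(c0))
}

#' Build the named gene sets used in perturbation CDF analyses
#'
#' Modes: \code{"cluster_size"} (focal-miRNA genes with only N=1 sites vs any
#' N>1 site vs any peak-overlapping site), \code{"peak_combination"}
#' (chimera-defined, seak-in-peak, and both), and \code{"exclusive_canonical"}
#' (transcripts with only canonical or only non-canonical focal sites,
#' mutually exclusive, plus the bulged-8mer subset). The control set is genes
#' with chimeras of other miRNAs and none of the focal miRNA.
#'
#' @param sites data.frame with gene_id, mirna_id, N, peak_overlap (logical),
#'   seed_class, region_label; one row per site.
#' @param focal_mirna focal miRNA id.
#' @param mode set construction mode.
#' @param region_restrict optional region label (e.g. "three_prime_utr").
#' @return named list of gene id vectors including \code{control}.
#' @export
build_site_sets <- function(sites, focal_mirna,
                            mode = c("cluster_size", "peak_combination",
                                     "exclusive_canonical"),
                            region_restrict = NULL) {
  mode <- match.arg(mode)
  if (!is.null(region_restrict)) {
    sites <- sites[sites$region_label %in% region_restrict, , drop = FALSE]
  }
  focal <- sites[sites$mirna_id == focal_mirna, , drop = FALSE]
  other <- sites[sites$mirna_id != focal_mirna, , drop = FALSE]
  control <- setdiff(unique(other$gene_id), unique(focal$gene_id))
  canon <- CANONICAL_CLASSES
  sets <- switch(mode,
    cluster_size = {
      by_gene <- split(focal$N, focal$gene_id)
      n1 <- names(by_gene)[vapply(by_gene, function(x) all(x == 1L),
                                  logical(1))]
      n_multi <- names(by_gene)[vapply(by_gene, function(x) any(x > 1L),
                                       logical(1))]
      peak <- unique(focal$gene_id[focal$peak_overlap])
      list(N1 = n1, N_multi = n_multi, peak_overlap = peak)
    },
    peak_combination = {
      chim <- unique(focal$gene_id)
      seed_peak <- unique(sites$gene_id[sites$peak_overlap &
                                          sites$seed_class %in% canon &
                                          sites$mirna_id == focal_mirna])
      list(chimera = chim, seed_in_peak = seed_peak,
           both = intersect(chim, seed_peak))
    },
    exclusive_canonical = {
      by_gene <- split(focal$seed_class, focal$gene_id)
      canon_only <- names(by_gene)[vapply(by_gene,
                                          function(x) all(x %in% canon),
                                          logical(1))]
      noncanon_only <- names(by_gene)[vapply(by_gene,
                                             function(x) !any(x %in% canon),
                                             logical(1))]
      b8 <- focal$gene_id[focal$seed_class == "bulge_target" &
                            isTRUE_vec(focal$bulged_8mer)]
      list(canonical_only = canon_only, noncanonical_only = noncanon_only,
           bulged_8mer = intersect(unique(b8), noncanon_only))
    })
  c(sets, list(control = control))
}

isTRUE_vec <- function(x) if (is.null(x)) FALSE else x %in% TRUE

#' AGO-binding-change CDFs by site class
#'
#' Clusters passing the support filters (BC >= \code{min_bc}, normalised
#' density >= \code{min_density}) are scored by the log2 ratio of treated to
#' control normalised counts and split by site class: focal canonical 7-8mer
#' seed only, focal chimera only, both, and control (neither). Each class is
#' compared with the control by a KS test.
#'
#' @param treated,control named numeric vectors of normalised cluster counts.
#' @param clusters data.frame with cluster_id, BC, density, has_seed78,
#'   has_chimera, region_label.
#' @param min_bc minimum biological complexity (default 4).
#' @param min_density minimum normalised density (default 40).
#' @param region_restrict optional region label filter.
#' @return list(classes = per-class log-ratio vectors, ks = data.frame of
#'   per-class KS statistics vs control, n_filtered).
#' @export
binding_change_cdf <- function(treated, control, clusters, min_bc = 4L,
                               min_density = 40, region_restrict = NULL) {
  keep <- clusters$BC >= min_bc & clusters$density >= min_density
  if (!is.null(region_restrict)) {
    keep <- keep & clusters$region_label %in% region_restrict
  }
  cl <- clusters[keep, , drop = FALSE]
  lr <- log2(treated[cl$cluster_id] / control[cl$cluster_id])
  grp <- ifelse(cl$has_seed78 & cl$has_chimera, "both",
                ifelse(cl$has_seed78, "seed_only",
                       ifelse(cl$has_chimera, "chimera_only", "control")))
  classes <- split(as.numeric(lr), grp)
  ks <- NULL
  if (!is.null(classes$control)) {
    for (g in setdiff(names(classes), "control")) {
      t <- suppressWarnings(stats::ks.test(classes[[g]], classes$control))
      ks <- rbind(ks, data.frame(class = g, D = unname(t$statistic),
                                 p = t$p.value, n = length(classes[[g]]),
                                 stringsAsFactors = FALSE))
    }
  }
  list(classes = classes, ks = ks, n_filtered = sum(!keep))
}
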