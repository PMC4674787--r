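# Targeting specificity among miRNA seed-family paralogues: strict chimera
# assignment, positional pairing profiles, pairwise cross-MFE comparisons and
# member-specific motif discovery.

#' Strict (mismatch-free, unambiguous) chimera assignment
#'
#' Re-runs reverse mapping with zero mismatches; reads whose tied-best
#' candidate set still spans more than one miRNA are discarded, removing
#' ambiguity among seed-family members.
#'
#' @param reads sequence data.frame.
#' @param catalog miRNA catalogue.
#' @param ... further arguments to [find_mirna_hits()] (e.g. truncation).
#' @return resolved hits data.frame (single-candidate reads only).
#' @export
strict_assignment <- function(reads, catalog, ...) {
  hits <- find_mirna_hits(reads, catalog, seed_mismatch = 0L,
                          ext_mismatch = 0L, ...)
  hits <- hits[hits$n_candidates == 1L, , drop = FALSE]
  hits$candidate_ids <- hits$mirna_id
  rownames(hits) <- NULL
  hits
}

#' Positional pairing profile of a set of structures
#'
#' @param structures list of \code{duplex_structure}.
#' @param max_pos last miRNA position reported.
#' @return numeric vector: fraction of structures paired at each position
#'   2..max_pos.
#' @export
pairing_profile <- function(structures, max_pos = 22L) {
  pos <- as.character(2:max_pos)
  prof <- vapply(pos, function(p) {
    v <- vapply(structures, function(s)
      if (p %in% names(s$pairing)) s$pairing[[p]] else NA_integer_,
      integer(1))
    mean(v, na.rm = TRUE)
  }, numeric(1))
  prof
}

#' Pairwise cross-MFE comparison within a miRNA seed family
#'
#' For every (target-set owner, family member) pair, unconstrained duplex MFEs
#' are computed for the owner's target regions folded against the member.
#' One-tailed Welch t-tests ask whether cognate MFEs are lower than each cross
#' pairing. Owners with fewer than \code{min_sites} regions are excluded.
#'
#' @param members data.frame(mirna_id, seq) for the family (or catalogue rows).
#' @param target_sets named list (by mirna_id) of target-region vectors.
#' @param params energy parameters.
#' @param min_sites minimum regions per owner (default 20).
#' @param delta_strong mean cognate-vs-cross MFE gap (kcal/mol) flagged as
#'   strong specificity (default 6).
#' @return list(mfe_mean, mfe_n, tests, profiles, strong, excluded) of class
#'   \code{family_comparison}.
#' @export
pairwise_mfe <- function(members, target_sets,
                         params = default_energy_params(), min_sites = 20L,
                         delta_strong = 6) {
  ids <- members$mirna_id
  excluded <- ids[!(ids %in% names(target_sets)) |
                    lengths(target_sets[ids]) < min_sites]
  owners <- setdiff(ids, excluded)
  if (length(excluded)) {
    message("excluding members below site minimum: ",
            paste(excluded, collapse = ", "))
  }
  mfe <- list()
  for (ow in owners) {
    regions <- target_sets[[ow]]
    for (me in ids) {
      mseq <- members$seq[members$mirna_id == me]
      mfe[[paste(ow, me, sep = "\r")]] <- vapply(regions, function(r)
        hybrid_mfe(mseq, r, params)$mfe, numeric(1), USE.NAMES = FALSE)
    }
  }
  mfe_mean <- matrix(NA_real_, length(owners), length(ids),
                     dimnames = list(owner = owners, member = ids))
  mfe_n <- mfe_mean
  for (ow in owners) for (me in ids) {
    v <- mfe[[paste(ow, me, sep = "\r")]]
    mfe_mean[ow, me] <- mean(v)
    mfe_n[ow, me] <- length(v)
  }
  tests <- list()
  for (ow in owners) {
    cog <- mfe[[paste(ow, ow, sep = "\r")]]
    for (me in setdiff(ids, ow)) {
      cross <- mfe[[paste(ow, me, sep = "\r")]]
      p <- if (stats::sd(cog - cross) < 1e-12) 0.5 else
        stats::t.test(cog, cross, alternative = "less")$p.value
      tests[[length(tests) + 1L]] <- data.frame(
        owner = ow, member = me, mean_cognate = mean(cog),
        mean_cross = mean(cross), delta = mean(cross) - mean(cog),
        p_one_tailed = p,
        strong = (mean(cross) - mean(cog)) > delta_strong,
        stringsAsFactors = FALSE)
    }
  }
  tests <- do.call(rbind, tests)
  profiles <- NULL
  if (length(owners)) {
    lmax <- max(nchar(members$seq))
    profiles <- t(vapply(owners, function(ow) {
      mseq <- members$seq[members$mirna_id == ow]
      structs <- lapply(target_sets[[ow]], function(r)
        hybrid_mfe(mseq, r, params))
      pairing_profile(structs, max_pos = lmax)
    }, numeric(lmax - 1L)))
    rownames(profiles) <- owners
  }
  structure(list(mfe_mean = mfe_mean, mfe_n = mfe_n, tests = tests,
                 profiles = profiles, excluded = excluded),
            class = "family_comparison")
}

#' @export
print.family_comparison <- function(x, ...) {
  cat("miRNA family comparison:", nrow(x$mfe_mean), "owners x",
      ncol(x$mfe_mean), "members\n")
  print(round(x$mfe_mean, 2))
  invisible(x)
}

#' Member-specific enriched motifs for family paralogues
#'
#' For each family member and motif length, k-mers enriched in that member's
#' target regions against a pooled background are scored for complementarity
#' to the member's own sequence; the display string is the reverse complement
#' of the target motif so it reads along the miRNA.
#'
#' @param target_sets named list (by mirna_id) of target regions.
#' @param members data.frame(mirna_id, seq).
#' @param background pooled background regions (e.g. all AGO-bound regions).
#' @param lengths motif lengths (default c(6, 8, 10, 12)).
#' @param p_max enrichment p-value cutoff (default 1e-4).
#' @param top_n candidates per (member, length).
#' @return data.frame(mirna_id, k, motif, display (revcomp), p, s,
#'   matched_offset).
#' @export
family_motifs <- function(target_sets, members, background,
                          lengths = c(6L, 8L, 10L, 12L), p_max = 1e-4,
                          top_n = 5L) {
  rows <- list()
  for (m in names(target_sets)) {
    mseq <- members$seq[members$mirna_id == m]
    if (!length(mseq)) next
    for (k in lengths) {
      cand <- enriched_kmers(target_sets[[m]], background, k = k,
                             top_n = top_n)
      pfms <- attr(cand, "pfm")
      for (i in seq_len(nrow(cand))) {
        if (cand$p[i] > p_max) next
        ms <- match_score(pfms[[i]], mseq)
        rows[[length(rows) + 1L]] <- data.frame(
          mirna_id = m, k = k, motif = cand$motif[i],
          display = revcomp(cand$motif[i]), p = cand$p[i], s = ms$s,
          matched_offset = ms$matched_offset, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(mirna_id = character(0), k = integer(0),
                      motif = character(0), display = character(0),
                      p = numeric(0), s = numeric(0),
                      matched_offset = integer(0))
  }
  out
}
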