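# De-novo enriched k-mer discovery in chimera target regions, miRNA
# complementarity match scoring and the combined confidence statistic.

#' Build foreground and background region sets per eligible miRNA
#'
#' A miRNA is eligible with at least \code{min_chimeras} chimeras and
#' \code{min_sites} interactions. Backgrounds of \code{bg_factor} times the
#' foreground size are sampled without replacement from other miRNAs' regions,
#' excluding miRNAs of the same seed family; \code{n_draws} independent draws
#' are produced.
#'
#' @param interactions data.frame with mirna_id, target_region and N (chimera
#'   count per interaction).
#' @param catalog miRNA catalogue (family_id column).
#' @param min_chimeras minimum chimera count (default 50).
#' @param min_sites minimum interaction count (default 40).
#' @param bg_factor background:foreground size ratio (default 5).
#' @param n_draws number of independent background draws (default 3).
#' @param rng_seed sampling seed.
#' @param mirnas optional subset of miRNA ids to process (still subject to
#'   the eligibility thresholds).
#' @return named list per eligible miRNA: list(foreground, backgrounds).
#' @export
build_fg_bg <- function(interactions, catalog, min_chimeras = 50L,
                        min_sites = 40L, bg_factor = 5L, n_draws = 3L,
                        rng_seed = 1L, mirnas = NULL) {
  fam <- catalog$family_id[match(interactions$mirna_id, catalog$mirna_id)]
  n_chim <- tapply(interactions$N, interactions$mirna_id, sum)
  n_site <- table(interactions$mirna_id)
  eligible <- names(n_chim)[n_chim >= min_chimeras &
                              as.integer(n_site[names(n_chim)]) >= min_sites]
  if (!is.null(mirnas)) eligible <- intersect(eligible, mirnas)
  set.seed(rng_seed)
  out <- list()
  for (m in eligible) {
    fg <- interactions$target_region[interactions$mirna_id == m]
    m_fam <- catalog$family_id[catalog$mirna_id == m]
    pool <- interactions$target_region[interactions$mirna_id != m &
                                         fam != m_fam]
    need <- bg_factor * length(fg)
    if (length(pool) < need) {
      stop("background pool for ", m, " has ", length(pool),
           " regions; ", need, " required")
    }
    bgs <- lapply(seq_len(n_draws), function(d) sample(pool, need))
    out[[m]] <- list(foreground = fg, backgrounds = bgs)
  }
  out
}

# presence counts of every k-mer across a region set
kmer_presence <- function(regions, k) {
  km <- unlist(lapply(regions, function(r) {
    n <- nchar(r)
    if (n < k) return(character(0))
    unique(substring(r, 1:(n - k + 1L), k:n))
  }))
  table(km)
}

#' Enriched k-mers in foreground vs background regions
#'
#' Per-region presence of every k-mer is compared by a one-sided
#' hypergeometric test (over-representation in the foreground). Candidates
#' within Hamming distance 1 or a single-offset shift of a better-ranked
#' candidate are suppressed; survivors are refined into position-frequency
#' matrices from their foreground occurrences (exact and 1-mismatch).
#'
#' @param foreground,background character vectors of region sequences.
#' @param k motif length (default 7).
#' @param top_n maximum number of candidates returned (default 10).
#' @return data.frame(motif, p, count_fg, count_bg) with a list attribute
#'   \code{"pfm"} of position-frequency matrices.
#' @export
enriched_kmers <- function(foreground, background, k = 7L, top_n = 10L) {
  stopifnot(length(foreground) > 0L, length(background) > 0L)
  fg <- kmer_presence(foreground, k)
  bg <- kmer_presence(background, k)
  kmers <- union(names(fg), names(bg))
  a <- as.integer(fg[kmers]); a[is.na(a)] <- 0L
  b <- as.integer(bg[kmers]); b[is.na(b)] <- 0L
  n_fg <- length(foreground); n_bg <- length(background)
  # P(X >= a) with X ~ hypergeom drawing n_fg regions from those containing /
  # not containing the k-mer
  p <- stats::phyper(a - 1L, a + b, n_fg + n_bg - a - b, n_fg,
                     lower.tail = FALSE)
  ord <- order(p, -a)
  kept <- character(0)
  keep_idx <- integer(0)
  for (i in ord) {
    if (length(keep_idx) >= top_n) break
    cand <- kmers[i]
    redundant <- any(vapply(kept, function(kk) {
      str_mismatches(kk, cand) <= 1L ||
        substr(kk, 2L, k) == substr(cand, 1L, k - 1L) ||
        substr(kk, 1L, k - 1L) == substr(cand, 2L, k)
    }, logical(1)))
    if (redundant) next
    kept <- c(kept, cand)
    keep_idx <- c(keep_idx, i)
  }
  out <- data.frame(motif = kmers[keep_idx], p = p[keep_idx],
                    count_fg = a[keep_idx], count_bg = b[keep_idx],
                    stringsAsFactors = FALSE)
  attr(out, "pfm") <- lapply(out$motif, function(mo)
    build_pfm(mo, foreground, k))
  out
}

# position-frequency matrix from exact and 1-mismatch occurrences in regions
build_pfm <- function(motif, regions, k = nchar(motif),
                      pseudo = 0.25) {
  counts <- matrix(pseudo, 4L, k, dimnames = list(c("A", "C", "G", "T"), NULL))
  mset <- Biostrings::DNAStringSet(regions)
  m <- Biostrings::vmatchPattern(motif, mset, max.mismatch = 1L, fixed = TRUE)
  st <- Biostrings::startIndex(m)
  for (i in seq_along(st)) {
    s <- st[[i]]
    if (is.null(s) || !length(s)) next
    s <- s[s >= 1L & s + k - 1L <= nchar(regions[i])]
    for (p in s) {
      occ <- substr(regions[i], p, p + k - 1L)
      bb <- strsplit(occ, "")[[1]]
      ok <- bb %in% rownames(counts)
      counts[cbind(match(bb[ok], rownames(counts)), which(ok))] <-
        counts[cbind(match(bb[ok], rownames(counts)), which(ok))] + 1L
    }
  }
  sweep(counts, 2L, colSums(counts), "/")
}

# mean per-column information content (bits, uniform background)
pfm_information_content <- function(pfm) {
  ic <- apply(pfm, 2L, function(p) {
    p <- p[p > 0]
    2 + sum(p * log2(p))
  })
  mean(ic)
}

#' Match score of a motif against the cognate miRNA
#'
#' The motif PFM's reverse complement is slid (ungapped) along the miRNA; the
#' score at an offset is the mean per-column probability of the base
#' complementary to the miRNA, and s is the maximum over offsets.
#' \code{matched_offset} is the miRNA position where the motif's complement
#' begins.
#'
#' @param pfm 4 x k position-frequency matrix (rows A, C, G, T; target
#'   orientation).
#' @param mirna miRNA sequence (RNA or DNA).
#' @return list(s, matched_offset).
#' @export
match_score <- function(pfm, mirna) {
  mirna <- norm_dna(mirna)
  k <- ncol(pfm)
  L <- nchar(mirna)
  if (L < k) return(list(s = 0, matched_offset = NA_integer_))
  # reverse-complemented PFM aligns column c with miRNA position offset+c-1
  rc <- pfm[c("T", "G", "C", "A"), rev(seq_len(k)), drop = FALSE]
  rownames(rc) <- c("A", "C", "G", "T")
  bases <- strsplit(mirna, "")[[1]]
  s_off <- vapply(seq_len(L - k + 1L), function(o) {
    idx <- match(bases[o:(o + k - 1L)], rownames(rc))
    if (anyNA(idx)) return(0)
    mean(rc[cbind(idx, seq_len(k))])
  }, numeric(1))
  list(s = max(s_off), matched_offset = which.max(s_off))
}

#' Combined motif confidence
#'
#' c = (-log10(p) - 10) / 10 + (s - 0.35) * 6.7, monotone decreasing in p and
#' increasing in s.
#'
#' @param p enrichment p-value in (0, 1].
#' @param s match score in [0, 1].
#' @return c value.
#' @export
combined_confidence <- function(p, s) {
  if (any(p <= 0)) stop("p must be > 0")
  stopifnot(all(p <= 1), all(s >= 0), all(s <= 1))
  (-log10(p) - 10) / 10 + (s - 0.35) * 6.7
}

#' Discover and score enriched motifs for one miRNA
#'
#' Runs k-mer enrichment against each background draw, scores candidates for
#' miRNA complementarity (s), information content and combined confidence c,
#' and applies the retention thresholds s >= 0.35, IC/bp >= 1.75, c >= 1.
#' A motif is robust when retained in at least 2 of the draws.
#'
#' @param foreground foreground regions.
#' @param backgrounds list of background draws.
#' @param mirna cognate miRNA sequence.
#' @param k motif length (default 7).
#' @param top_n candidates per draw (default 10).
#' @param s_min,ic_min,c_min retention thresholds.
#' @return data.frame (one row per candidate per draw) with columns draw,
#'   motif, p, s, matched_offset, ic_per_bp, c, retained, robust, fg_fraction.
#' @export
discover_motifs <- function(foreground, backgrounds, mirna, k = 7L,
                            top_n = 10L, s_min = 0.35, ic_min = 1.75,
                            c_min = 1) {
  rows <- list()
  for (d in seq_along(backgrounds)) {
    cand <- enriched_kmers(foreground, backgrounds[[d]], k = k, top_n = top_n)
    pfms <- attr(cand, "pfm")
    for (i in seq_len(nrow(cand))) {
      ms <- match_score(pfms[[i]], mirna)
      ic <- pfm_information_content(pfms[[i]])
      cc <- combined_confidence(max(cand$p[i], 1e-300), ms$s)
      rows[[length(rows) + 1L]] <- data.frame(
        draw = d, motif = cand$motif[i], p = cand$p[i], s = ms$s,
        matched_offset = ms$matched_offset, ic_per_bp = ic, c = cc,
        retained = ms$s >= s_min && ic >= ic_min && cc >= c_min,
        fg_fraction = cand$count_fg[i] / length(foreground),
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  if (is.null(tab)) {
    return(data.frame(draw = integer(0), motif = character(0), p = numeric(0),
                      s = numeric(0), matched_offset = integer(0),
                      ic_per_bp = numeric(0), c = numeric(0),
                      retained = logical(0), robust = logical(0),
                      fg_fraction = numeric(0)))
  }
  n_ret <- tapply(tab$retained, tab$motif, sum)
  tab$robust <- as.integer(n_ret[tab$motif]) >= 2L
  tab
}

#' Motif intensity heat-map matrix across miRNA positions
#'
#' Per miRNA, the foreground occurrence fraction of each retained motif is
#' painted over the miRNA positions its complement matches
#' ([matched_offset, matched_offset + k - 1]); rows are ordered by
#' average-linkage hierarchical clustering of the intensity profiles.
#'
#' @param motif_tab rows of [discover_motifs()] output (retained rows are
#'   used), with a mirna_id column.
#' @param max_pos number of miRNA positions (columns) in the matrix.
#' @param k motif length (default 7).
#' @return numeric matrix (miRNAs x positions), row-ordered; empty (0-row)
#'   with a warning when nothing is retained.
#' @export
motif_position_heatmap <- function(motif_tab, max_pos = 22L, k = 7L) {
  ret <- motif_tab[motif_tab$retained, , drop = FALSE]
  if (nrow(ret) == 0L) {
    warning("no retained motifs; returning empty matrix")
    return(matrix(numeric(0), 0L, max_pos))
  }
  mirnas <- unique(ret$mirna_id)
  mat <- matrix(0, length(mirnas), max_pos,
                dimnames = list(mirnas, seq_len(max_pos)))
  for (i in seq_len(nrow(ret))) {
    o <- ret$matched_offset[i]
    cols <- o:min(o + k - 1L, max_pos)
    r <- ret$mirna_id[i]
    mat[r, cols] <- pmax(mat[r, cols], ret$fg_fraction[i])
  }
  if (nrow(mat) > 2L) {
    hc <- stats::hclust(stats::dist(mat), method = "average")
    mat <- mat[hc$order, , drop = FALSE]
  }
  mat
}
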