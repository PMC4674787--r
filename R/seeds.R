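# Classification of target regions against the cognate miRNA seed
# (positions 2-8): canonical classes, single-mismatch and single-bulge
# variants, G:U wobble tracking, junction-offset CDFs and positional
# variant-preference profiles.

CANONICAL_CLASSES <- c("8mer", "7mer-m8", "7mer-A1", "6mer")
VARIANT_CLASSES <- c("bulge_target", "mm8", "mm7", "bulge_mirna", "mm6")

# pair classes of target window bases against miRNA seed positions.
# For offset o (0-based) and seed positions p_hi..p_lo the target base at
# o + (p_hi - p) pairs miRNA position p (antiparallel).
seed_pairs_at <- function(region, mir, offset, p_lo = 2L, p_hi = 8L) {
  pos <- p_hi:p_lo
  tb <- substring(region, offset + 1L + (p_hi - pos), offset + 1L + (p_hi - pos))
  mb <- substring(mir, pos, pos)
  pt <- pair_type(mb, tb)
  names(pt) <- pos
  pt
}

#' Classify a canonical seed match in a target region
#'
#' Searches the reverse complement of miRNA positions 2-8 (and sub-motifs) in
#' the region. Classes: 8mer (perfect 2-8 pairing plus target A opposite
#' position 1), 7mer-m8 (perfect 2-8), 7mer-A1 (perfect 2-7 plus target A),
#' 6mer (perfect 2-7). The highest class wins; ties resolve to the leftmost
#' occurrence. With \code{allow_wobble} a single G:U pair within an otherwise
#' Watson-Crick site keeps its canonical class and the wobbled position is
#' reported; all other positions must pair Watson-Crick (unbounded wobble
#' tolerance would make near-arbitrary sequence classify as canonical).
#'
#' @param region target region (DNA letters, 5'->3').
#' @param mir mature miRNA sequence (DNA letters).
#' @param allow_wobble tolerate one G:U pair within canonical sites (default
#'   TRUE).
#' @return list(class, offset (0-based match start), wobble_positions) or NULL.
#' @export
canonical_match <- function(region, mir, allow_wobble = TRUE) {
  rlen <- nchar(region)
  max_wobble <- if (allow_wobble) 1L else 0L
  scan <- function(p_lo, p_hi, need_a) {
    w <- p_hi - p_lo + 1L
    lim <- rlen - w - if (need_a) 1L else 0L
    if (lim < 0L) return(NULL)
    for (o in 0:lim) {
      pt <- seed_pairs_at(region, mir, o, p_lo, p_hi)
      if (any(pt == "none") || sum(pt == "wobble") > max_wobble) next
      if (need_a && substr(region, o + w + 1L, o + w + 1L) != "A") next
      return(list(offset = o,
                  wobble_positions = as.integer(names(pt)[pt == "wobble"])))
    }
    NULL
  }
  for (cls in CANONICAL_CLASSES) {
    hit <- switch(cls,
                  "8mer" = scan(2L, 8L, TRUE),
                  "7mer-m8" = scan(2L, 8L, FALSE),
                  "7mer-A1" = scan(2L, 7L, TRUE),
                  "6mer" = scan(2L, 7L, FALSE))
    if (!is.null(hit)) {
      return(list(class = cls, offset = hit$offset,
                  wobble_positions = hit$wobble_positions))
    }
  }
  NULL
}

#' Classify single-edit seed variants in a target region
#'
#' Enumerates all sites one edit away from a canonical seed match: one
#' substitution (mm8 when the target A opposite position 1 is present, mm7 for
#' a mismatched 2-8 site, mm6 for a mismatched 2-7 site), one extra target
#' nucleotide between adjacent seed pairings (bulge_target, inserted base
#' recorded), and one bulged miRNA position with the opposing target base
#' absent (bulge_mirna). Non-edited positions must pair Watson-Crick; an
#' edited position that forms G:U is recorded as a wobble rather than a plain
#' mismatch (with \code{allow_wobble} such sites already classify as
#' canonical). The best site has the most seed pairs, then the deterministic
#' class order bulge_target > mm8 > mm7 > bulge_mirna > mm6, then the
#' smallest offset.
#'
#' @inheritParams canonical_match
#' @return list(class, offset, edit_position, inserted_base, wobble_positions,
#'   bulged_8mer) or NULL.
#' @export
variant_match <- function(region, mir, allow_wobble = TRUE) {
  rlen <- nchar(region)
  ok_pair <- "wc"
  cands <- list()
  add <- function(cls, offset, pos, base, pt, n_pairs, bulged_8mer = FALSE) {
    cands[[length(cands) + 1L]] <<- list(
      class = cls, offset = offset, edit_position = pos,
      inserted_base = base, n_pairs = n_pairs,
      wobble_positions = as.integer(names(pt)[pt == "wobble"]),
      bulged_8mer = bulged_8mer)
  }
  # substitution variants
  for (o in 0:max(-1L, rlen - 7L)) {
    if (o + 7L > rlen) next
    pt <- seed_pairs_at(region, mir, o, 2L, 8L)
    bad <- names(pt)[!(pt %in% ok_pair)]
    has_a <- o + 8L <= rlen && substr(region, o + 8L, o + 8L) == "A"
    if (length(bad) == 1L) {
      pos <- as.integer(bad)
      if (allow_wobble && pt[[bad]] == "wobble") next  # canonical's domain
      if (has_a) add("mm8", o, pos, NA_character_, pt, 6L)
      else add("mm7", o, pos, NA_character_, pt, 6L)
    }
  }
  for (o in 0:max(-1L, rlen - 6L)) {
    if (o + 6L > rlen) next
    pt <- seed_pairs_at(region, mir, o, 2L, 7L)
    bad <- names(pt)[!(pt %in% ok_pair)]
    if (length(bad) == 1L) {
      if (allow_wobble && pt[[bad]] == "wobble") next
      add("mm6", o, as.integer(bad), NA_character_, pt, 5L)
    }
  }
  # one extra target nucleotide between miRNA positions p and p+1:
  # target reads comp(m8)..comp(m_{p+1}) X comp(m_p)..comp(m2)
  for (o in 0:max(-1L, rlen - 8L)) {
    if (o + 8L > rlen) next
    for (p in 2L:7L) {
      hi_len <- 8L - p             # bases pairing positions 8..p+1
      up <- seed_pairs_at(substr(region, o + 1L, o + hi_len), mir, 0L,
                          p + 1L, 8L)
      ins <- substr(region, o + hi_len + 1L, o + hi_len + 1L)
      lo <- seed_pairs_at(substr(region, o + hi_len + 2L, o + 8L), mir, 0L,
                          2L, p)
      pt <- c(up, lo)
      if (all(pt %in% ok_pair)) {
        b8 <- o + 9L <= rlen && substr(region, o + 9L, o + 9L) == "A"
        add("bulge_target", o, p, ins, pt, 7L, bulged_8mer = b8)
      }
    }
  }
  # one bulged miRNA position p (3..7): target skips the opposing base
  for (o in 0:max(-1L, rlen - 6L)) {
    if (o + 6L > rlen) next
    for (p in 3L:7L) {
      hi_len <- 8L - p
      up <- seed_pairs_at(substr(region, o + 1L, o + hi_len), mir, 0L,
                          p + 1L, 8L)
      lo <- seed_pairs_at(substr(region, o + hi_len + 1L, o + 6L), mir, 0L,
                          2L, p - 1L)
      pt <- c(up, lo)
      if (all(pt %in% ok_pair)) add("bulge_mirna", o, p, NA_character_, pt, 6L)
    }
  }
  if (!length(cands)) return(NULL)
  score <- vapply(cands, function(x) {
    -(x$n_pairs * 1000L) + match(x$class, VARIANT_CLASSES) * 100L + x$offset
  }, numeric(1))
  best <- cands[[which.min(score)]]
  best$n_pairs <- NULL
  best
}

#' Classify one target region against its cognate miRNA
#'
#' Canonical classes take priority; single-edit variants are only reported when
#' no canonical site exists.
#'
#' @inheritParams canonical_match
#' @return list with class ("none" when no site), offset, edit_position,
#'   inserted_base, wobble_positions.
#' @export
classify_seed <- function(region, mir, allow_wobble = TRUE) {
  hit <- canonical_match(region, mir, allow_wobble)
  if (!is.null(hit)) {
    hit$edit_position <- NA_integer_
    hit$inserted_base <- NA_character_
    hit$bulged_8mer <- FALSE
    return(hit)
  }
  hit <- variant_match(region, mir, allow_wobble)
  if (!is.null(hit)) return(hit)
  list(class = "none", offset = NA_integer_, edit_position = NA_integer_,
       inserted_base = NA_character_, wobble_positions = integer(0),
       bulged_8mer = FALSE)
}

#' Classify all interactions against their cognate miRNAs
#'
#' @param interactions data.frame with mirna_id and target_region.
#' @param catalog miRNA catalogue.
#' @param allow_wobble see [canonical_match()].
#' @return data.frame of seed annotations, one row per interaction.
#' @export
classify_seeds <- function(interactions, catalog, allow_wobble = TRUE) {
  mir <- catalog$seq[match(interactions$mirna_id, catalog$mirna_id)]
  rows <- lapply(seq_len(nrow(interactions)), function(i) {
    h <- classify_seed(interactions$target_region[i], mir[i], allow_wobble)
    data.frame(interaction_id = interactions$interaction_id[i],
               mirna_id = interactions$mirna_id[i],
               class = h$class, offset = h$offset %||% NA_integer_,
               edit_position = h$edit_position,
               inserted_base = h$inserted_base,
               wobble_positions = paste(h$wobble_positions, collapse = ","),
               bulged_8mer = isTRUE(h$bulged_8mer), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Empirical CDF of seed-match offsets around the ligation junction
#'
#' Offsets are target-region starts of canonical matches relative to the
#' ligation junction (downstream positive). The enrichment summary is the
#' fraction of chimeras with a canonical match in [0, window) downstream minus
#' the same fraction after shuffling the miRNA-region assignment (derangement).
#'
#' @param pairs data.frame with mirna_id and target_region (regions begin at
#'   the junction); optional upstream_region column for the upstream check.
#' @param catalog miRNA catalogue.
#' @param window downstream window (default 75).
#' @param rng_seed seed for the shuffled assignment.
#' @return list(offsets, ecdf, downstream_frac, shuffled_frac, enrichment,
#'   upstream_frac).
#' @export
seed_position_cdf <- function(pairs, catalog, window = 75L, rng_seed = 1L) {
  if (nrow(pairs) == 0L) stop("no chimeras supplied")
  mir <- catalog$seq[match(pairs$mirna_id, catalog$mirna_id)]
  match_off <- function(regions, mirs) {
    vapply(seq_along(regions), function(i) {
      h <- canonical_match(regions[i], mirs[i])
      if (is.null(h)) NA_integer_ else h$offset
    }, integer(1))
  }
  off <- match_off(pairs$target_region, mir)
  down <- mean(!is.na(off) & off < window)
  up <- NA_real_
  if ("upstream_region" %in% names(pairs)) {
    uoff <- match_off(pairs$upstream_region, mir)
    up <- mean(!is.na(uoff))
  }
  perm <- derangement(nrow(pairs), rng_seed)
  soff <- match_off(pairs$target_region, mir[perm])
  shuf <- mean(!is.na(soff) & soff < window)
  obs <- off[!is.na(off)]
  list(offsets = off, ecdf = if (length(obs)) stats::ecdf(obs) else NULL,
       downstream_frac = down, shuffled_frac = shuf,
       enrichment = down - shuf, upstream_frac = up)
}

# permutation of 1..n with no fixed points, deterministic given seed
derangement <- function(n, rng_seed) {
  if (n < 2L) stop("derangement requires n >= 2")
  set.seed(rng_seed)
  p <- sample.int(n)
  fx <- which(p == seq_len(n))
  for (i in fx) {
    j <- if (i == n) i - 1L else i + 1L
    tmp <- p[i]; p[i] <- p[j]; p[j] <- tmp
  }
  if (any(p == seq_len(n))) {
    # possible only if a swap re-created a fixed point; rotate those entries
    fx <- which(p == seq_len(n))
    p[fx] <- p[c(fx[-1L], fx[1L])]
    if (length(fx) == 1L) {
      j <- if (fx == n) fx - 1L else fx + 1L
      tmp <- p[fx]; p[fx] <- p[j]; p[j] <- tmp
    }
  }
  stopifnot(all(p != seq_len(n)))
  p
}

#' Positional preference profiles for seed variants
#'
#' Per miRNA and variant type (mismatch, target bulge, miRNA bulge, wobble),
#' the frequency of the edited/wobbled position. Rows sum to 1. Positions with
#' frequency below \code{floor} in miRNAs with at least \code{min_sites}
#' classified variant sites are flagged as disallowed.
#'
#' @param seed_ann data.frame from [classify_seeds()].
#' @param min_sites minimum variant sites per miRNA (default 50).
#' @param floor disallowed-position frequency floor (default 0.01).
#' @return list(profiles, disallowed, excluded).
#' @export
positional_preference_profile <- function(seed_ann, min_sites = 50L,
                                          floor = 0.01) {
  types <- list(
    mismatch = list(rows = seed_ann$class %in% c("mm8", "mm7", "mm6"),
                    pos = seed_ann$edit_position, levels = 2:8),
    target_bulge = list(rows = seed_ann$class == "bulge_target",
                        pos = seed_ann$edit_position, levels = 2:7),
    mirna_bulge = list(rows = seed_ann$class == "bulge_mirna",
                       pos = seed_ann$edit_position, levels = 3:7))
  wob <- lapply(strsplit(seed_ann$wobble_positions, ","), as.integer)
  profiles <- list(); disallowed <- list(); excluded <- character(0)
  for (ty in names(types)) {
    t <- types[[ty]]
    sub <- seed_ann[t$rows, , drop = FALSE]
    pos <- t$pos[t$rows]
    mat <- NULL; dm <- NULL
    for (m in unique(seed_ann$mirna_id)) {
      p <- pos[sub$mirna_id == m]
      if (length(p) < min_sites) {
        excluded <- unique(c(excluded, m))
        next
      }
      f <- as.numeric(table(factor(p, levels = t$levels))) / length(p)
      mat <- rbind(mat, stats::setNames(f, t$levels))
      rownames(mat)[nrow(mat)] <- m
      dm <- rbind(dm, f < floor)
      rownames(dm)[nrow(dm)] <- m
    }
    profiles[[ty]] <- mat
    disallowed[[ty]] <- dm
  }
  # wobble profile over seed positions, among sites with >= 1 wobble
  wmat <- NULL
  has_w <- lengths(wob) > 0L
  for (m in unique(seed_ann$mirna_id)) {
    rows <- which(has_w & seed_ann$mirna_id == m)
    p <- unlist(wob[rows])
    if (length(p) < min_sites) next
    f <- as.numeric(table(factor(p, levels = 2:8))) / length(p)
    wmat <- rbind(wmat, stats::setNames(f, 2:8))
    rownames(wmat)[nrow(wmat)] <- m
  }
  profiles$wobble <- wmat
  list(profiles = profiles, disallowed = disallowed,
       excluded = unique(excluded))
}
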