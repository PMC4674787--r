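# Shared fixtures and independent oracles used across the suite.

rand_seq <- function(n, len, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  len <- rep_len(len, n)
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len[i], replace = TRUE),
          collapse = ""), character(1))
}

tiny_catalog <- function(seqs, ids = sprintf("mir%02d", seq_along(seqs))) {
  read_mirna_catalog(data.frame(mirna_id = ids, seq = seqs,
                                stringsAsFactors = FALSE))
}

# --- exhaustive sliding-window reverse-mapping oracle ------------------------
# Independent re-statement of the hit contract: miRNA 5' 8-mer with
# <= seed_mm mismatches, extension with <= ext_mm further mismatches;
# full-length spanning unless truncation mode; best = fewest mismatches then
# longest span. Returns data.frame(mirna_id, start, mismatches, span_len).
oracle_scan_read <- function(read, catalog, seed_mm = 1L, ext_mm = 2L,
                             truncation = FALSE, min_prefix = 12L) {
  res <- list()
  for (r in seq_len(nrow(catalog))) {
    mir <- catalog$seq[r]
    L <- nchar(mir)
    for (st in seq_len(max(0L, nchar(read) - 8L + 1L))) {
      avail <- min(L, nchar(read) - st + 1L)
      if (avail < 8L) next
      mm_vec <- utf8ToInt(substr(read, st, st + avail - 1L)) !=
        utf8ToInt(substr(mir, 1L, avail))
      if (sum(mm_vec[1:8]) > seed_mm) next
      if (!truncation) {
        if (avail < L) next
        if (sum(mm_vec[-(1:8)]) > ext_mm) next
        res[[length(res) + 1L]] <- data.frame(
          mirna_id = catalog$mirna_id[r], start = st,
          mismatches = sum(mm_vec), span_len = L)
      } else {
        lmax <- 8L
        for (l in seq(9L, avail)) {
          if (sum(mm_vec[9:l]) <= ext_mm) lmax <- l
        }
        while (lmax > 8L && mm_vec[lmax]) lmax <- lmax - 1L
        if (lmax < min_prefix) next
        res[[length(res) + 1L]] <- data.frame(
          mirna_id = catalog$mirna_id[r], start = st,
          mismatches = sum(mm_vec[1:lmax]), span_len = lmax)
      }
    }
  }
  if (!length(res)) return(NULL)
  df <- do.call(rbind, res)
  score <- df$mismatches * 1000L - df$span_len
  df[score == min(score), , drop = FALSE]
}

# --- brute-force duplex enumeration oracle -----------------------------------
# Enumerates every monotone antiparallel set of pairable positions (loop
# bounds respected) and scores it with its own straightforward energy walk.
oracle_duplex_best <- function(mir, tar, params) {
  pair_code2 <- function(a, b) {
    key <- paste0(a, b)
    m <- c(AT = 1, TA = 2, CG = 3, GC = 4, GT = 5, TG = 6)
    if (key %in% names(m)) m[[key]] else 0L
  }
  m <- nchar(mir); n <- nchar(tar)
  mb <- strsplit(mir, "")[[1]]; tb <- strsplit(tar, "")[[1]]
  codes <- outer(seq_len(m), seq_len(n),
                 Vectorize(function(i, j) pair_code2(mb[i], tb[j])))
  ends <- function(code) if (code %in% c(3L, 4L)) 0 else params$terminal_au
  bonus <- if (is.null(params$pair_bonus)) 0 else params$pair_bonus
  score <- function(pairs) {
    # pairs: matrix cols i, j in order of increasing i
    e <- ends(codes[pairs[1, 1], pairs[1, 2]]) +
      ends(codes[pairs[nrow(pairs), 1], pairs[nrow(pairs), 2]]) +
      bonus * nrow(pairs)
    if (nrow(pairs) > 1L) for (r in 2:nrow(pairs)) {
      gi <- pairs[r, 1] - pairs[r - 1, 1] - 1L
      gj <- pairs[r - 1, 2] - pairs[r, 2] - 1L
      e <- e + if (gi == 0L && gj == 0L) {
        params$stack[codes[pairs[r - 1, 1], pairs[r - 1, 2]],
                     codes[pairs[r, 1], pairs[r, 2]]]
      } else if (gi == 0L || gj == 0L) {
        params$bulge_open + params$bulge_ext * (gi + gj)
      } else {
        params$interior_open + params$interior_ext * (gi + gj)
      }
    }
    e
  }
  best <- 0
  recurse <- function(pairs, last_i, last_j) {
    if (last_i + 1L > m) return(invisible(NULL))
    for (i in seq(last_i + 1L, m)) {
      if (last_i > 0L && i - last_i - 1L > params$max_bulge) break
      jmax <- if (last_j == 0L) n else last_j - 1L
      jmin <- if (last_j == 0L) 1L else max(1L, last_j - 1L - params$max_bulge)
      if (jmax < jmin) next
      for (j in seq(jmax, jmin)) {
        if (codes[i, j] == 0L) next
        np <- rbind(pairs, c(i, j))
        s <- score(np)
        if (s < best) best <<- s
        recurse(np, i, j)
      }
    }
    invisible(NULL)
  }
  recurse(matrix(integer(0), 0, 2), 0L, 0L)
  best
}

# --- enumerate-all-single-edit seed-site oracle ------------------------------
# Lists every valid single-edit parse of `region` against the miRNA seed,
# with its own pair logic: non-edited positions pair Watson-Crick; an edited
# position forming G:U belongs to the canonical-with-wobble class and is
# skipped here when allow_wobble is on.
oracle_variant_set <- function(region, mir, allow_wobble = TRUE) {
  paired <- function(mpos, tbase) {
    paste0(substr(mir, mpos, mpos), tbase) %in% c("AT", "TA", "CG", "GC")
  }
  wobbly <- function(mpos, tbase) {
    paste0(substr(mir, mpos, mpos), tbase) %in% c("GT", "TG")
  }
  n <- nchar(region)
  out <- list()
  emit <- function(class, pos, offset, n_pairs) {
    out[[length(out) + 1L]] <<- data.frame(class = class, pos = pos,
                                           offset = offset,
                                           n_pairs = n_pairs)
  }
  rb <- strsplit(region, "")[[1]]
  # substitutions within a 2-8 window (target base o+1+ (8-p) opposes p)
  for (o in 0:(n - 7)) {
    if (o + 7 > n) next
    st <- vapply(8:2, function(p) paired(p, rb[o + 1 + (8 - p)]), logical(1))
    if (sum(!st) == 1L) {
      p <- (8:2)[!st]
      if (allow_wobble && wobbly(p, rb[o + 1 + (8 - p)])) next
      if (o + 8 <= n && rb[o + 8] == "A") emit("mm8", p, o, 6L)
      else emit("mm7", p, o, 6L)
    }
  }
  for (o in 0:(n - 6)) {
    if (o + 6 > n) next
    st <- vapply(7:2, function(p) paired(p, rb[o + 1 + (7 - p)]), logical(1))
    if (sum(!st) == 1L) {
      p <- (7:2)[!st]
      if (allow_wobble && wobbly(p, rb[o + 1 + (7 - p)])) next
      emit("mm6", p, o, 5L)
    }
  }
  # one extra target base between miRNA positions p and p+1
  for (o in 0:(n - 8)) {
    if (o + 8 > n) next
    for (p in 2:7) {
      hi <- 8 - p
      up_ok <- all(vapply(seq_len(hi), function(k)
        paired(9 - k, rb[o + k]), logical(1)))
      lo_ok <- all(vapply(seq_len(p - 1), function(k)
        paired(p + 1 - k, rb[o + hi + 1 + k]), logical(1)))
      if (up_ok && lo_ok) emit("bulge_target", p, o, 7L)
    }
  }
  # one bulged miRNA position p (target skips its partner)
  for (o in 0:(n - 6)) {
    if (o + 6 > n) next
    for (p in 3:7) {
      hi <- 8 - p
      up_ok <- all(vapply(seq_len(hi), function(k)
        paired(9 - k, rb[o + k]), logical(1)))
      lo_ok <- all(vapply(seq_len(p - 2), function(k)
        paired(p - k, rb[o + hi + k]), logical(1)))
      if (up_ok && lo_ok) emit("bulge_mirna", p, o, 6L)
    }
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

# --- exact two-sided Fisher p by hypergeometric enumeration ------------------
oracle_fisher_p <- function(a, b, c, d) {
  K <- a + b; n <- a + c; N <- a + b + c + d
  lo <- max(0L, K + n - N); hi <- min(K, n)
  probs <- stats::dhyper(lo:hi, K, N - K, n)
  p_obs <- stats::dhyper(a, K, N - K, n)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# naive O(n^2) interval overlap counter (0-based half-open)
oracle_overlaps <- function(q, s) {
  vapply(seq_len(nrow(q)), function(i) {
    sum(s$chrom == q$chrom[i] & s$start < q$end[i] & s$end > q$start[i])
  }, integer(1))
}

default_test_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_experiment(sim_config(reads_total = 8000L,
                                               n_sites = 150L,
                                               rng_seed = 42L))
    }
    cache
  }
})
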