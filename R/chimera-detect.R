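# Reverse-mapping of mature miRNAs into reads, flank extraction, unique genomic
# placement of target fragments, miRNA-locus filtering, false-ligation
# estimation and per-sample chimera rate summaries.

#' Load a mature miRNA catalogue
#'
#' Accepts a FASTA path or a data.frame with mirna_id and seq. Sequences are
#' normalised to DNA letters; the seed is positions 2-8 and miRNAs sharing an
#' identical seed heptamer are grouped into a family.
#'
#' @param x FASTA path or data.frame(mirna_id, seq).
#' @return data.frame(mirna_id, seq, seed, family_id).
#' @export
read_mirna_catalog <- function(x) {
  if (is.character(x) && length(x) == 1L) {
    df <- read_sequences(x, "fasta")
    cat_df <- data.frame(mirna_id = df$id, seq = df$seq, stringsAsFactors = FALSE)
  } else {
    cat_df <- data.frame(mirna_id = x$mirna_id, seq = norm_dna(x$seq),
                         stringsAsFactors = FALSE)
  }
  if (any(nchar(cat_df$seq) < 16L)) {
    stop("mature miRNA sequences must be at least 16 nt")
  }
  if (anyDuplicated(cat_df$mirna_id)) stop("duplicate miRNA ids")
  cat_df$seed <- substr(cat_df$seq, 2L, 8L)
  cat_df$family_id <- paste0("fam_", match(cat_df$seed, unique(cat_df$seed)))
  cat_df
}

#' Find mature miRNA segments inside reads
#'
#' A hit requires the miRNA 5' 8-mer to occur in the read with at most
#' \code{seed_mismatch} mismatches, extended toward the miRNA 3' end with at
#' most \code{ext_mismatch} further mismatches. In full-length mode the whole
#' miRNA must be spanned by the read; in truncation mode at least
#' \code{min_prefix} nt from the miRNA 5' end must be matched and the number of
#' absent 3' bases is recorded. Per read, the best placement wins (fewest
#' mismatches, then longest span); miRNAs tying for best form the candidate
#' set, resolved by [resolve_ambiguous()].
#'
#' @param reads sequence data.frame (id, seq, optionally sample_id, count).
#' @param catalog miRNA catalogue from [read_mirna_catalog()].
#' @param seed_mismatch max mismatches in the miRNA 5' 8-mer (default 1).
#' @param ext_mismatch max additional mismatches in the 3' extension (default 2).
#' @param truncation allow 3'-truncated miRNAs (default FALSE).
#' @param min_prefix minimum matched miRNA prefix in truncation mode (default 12).
#' @return data.frame of tied-best hits, one row per (read, miRNA): read_id,
#'   mirna_id, start, end (1-based span in read), mismatches,
#'   mismatch_positions, truncation_3p, n_candidates.
#' @export
find_mirna_hits <- function(reads, catalog, seed_mismatch = 1L,
                            ext_mismatch = 2L, truncation = FALSE,
                            min_prefix = 12L) {
  seqs <- reads$seq
  rset <- Biostrings::DNAStringSet(seqs)
  rlen <- nchar(seqs)
  out <- vector("list", nrow(catalog))
  for (k in seq_len(nrow(catalog))) {
    mir <- catalog$seq[k]
    L <- nchar(mir)
    seed8 <- substr(mir, 1L, 8L)
    m <- Biostrings::vmatchPattern(seed8, rset, max.mismatch = seed_mismatch,
                                   fixed = TRUE)
    st <- Biostrings::startIndex(m)
    nhit <- lengths(st)
    if (!sum(nhit)) next
    ridx <- rep.int(seq_along(st), nhit)
    pos <- unlist(st, use.names = FALSE)
    ok <- pos >= 1L
    ridx <- ridx[ok]; pos <- pos[ok]
    if (!length(ridx)) next
    res <- score_candidates(seqs[ridx], rlen[ridx], pos, mir, L,
                            seed_mismatch, ext_mismatch, truncation, min_prefix)
    keep <- !is.na(res$mism)
    if (!any(keep)) next
    out[[k]] <- data.frame(
      read_i = ridx[keep], mirna_id = catalog$mirna_id[k],
      start = pos[keep], end = pos[keep] + res$span_len[keep] - 1L,
      mismatches = res$mism[keep], mismatch_positions = res$mpos[keep],
      truncation_3p = res$trunc[keep], stringsAsFactors = FALSE)
  }
  hits <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(hits) || nrow(hits) == 0L) {
    return(data.frame(read_id = character(0), mirna_id = character(0),
                      start = integer(0), end = integer(0),
                      mismatches = integer(0), mismatch_positions = character(0),
                      truncation_3p = integer(0), n_candidates = integer(0)))
  }
  # best placement per (read, miRNA): fewest mismatches, then longest span
  span <- hits$end - hits$start + 1L
  ord <- order(hits$read_i, hits$mirna_id, hits$mismatches, -span, hits$start)
  hits <- hits[ord, , drop = FALSE]
  hits <- hits[!duplicated(hits[c("read_i", "mirna_id")]), , drop = FALSE]
  # tied-best candidates per read
  span <- hits$end - hits$start + 1L
  score <- hits$mismatches * 1000L - span
  best <- tapply(score, hits$read_i, min)
  hits <- hits[score == best[as.character(hits$read_i)], , drop = FALSE]
  ncand <- table(hits$read_i)
  hits$n_candidates <- as.integer(ncand[as.character(hits$read_i)])
  hits$read_id <- reads$id[hits$read_i]
  rownames(hits) <- NULL
  hits[, c("read_id", "mirna_id", "start", "end", "mismatches",
           "mismatch_positions", "truncation_3p", "read_i", "n_candidates")]
}

# evaluate one candidate placement per row; returns NA mism where invalid
score_candidates <- function(seq, rlen, pos, mir, L, seed_mm, ext_mm,
                             truncation, min_prefix) {
  n <- length(seq)
  mism <- rep(NA_integer_, n)
  span_len <- integer(n)
  trunc <- integer(n)
  mpos <- character(n)
  mir_raw <- charToRaw(mir)
  for (i in seq_len(n)) {
    avail <- min(L, rlen[i] - pos[i] + 1L)
    if (avail < 8L) next
    frag <- charToRaw(substr(seq[i], pos[i], pos[i] + avail - 1L))
    neq <- frag != mir_raw[seq_len(avail)]
    smm <- sum(neq[1:8])
    if (smm > seed_mm) next
    if (!truncation) {
      if (avail < L) next
      emm <- if (L > 8L) sum(neq[9:L]) else 0L
      if (emm > ext_mm) next
      mism[i] <- smm + emm
      span_len[i] <- L
      trunc[i] <- 0L
      mpos[i] <- paste(which(neq), collapse = ",")
    } else {
      # longest extension within the mismatch budget, then trim trailing
      # mismatches so the span ends on a matching base
      cum <- c(0L, cumsum(neq[seq(9L, avail)]))  # ext mismatches up to len 8+j
      lens <- 8L + which(cum[-1L] <= ext_mm)
      lmax <- if (length(lens)) max(lens) else 8L
      while (lmax > 8L && neq[lmax]) lmax <- lmax - 1L
      if (lmax < min_prefix) next
      mism[i] <- smm + sum(neq[seq_len(lmax)][-(1:8)])
      span_len[i] <- lmax
      trunc[i] <- L - lmax
      mpos[i] <- paste(which(neq[seq_len(lmax)]), collapse = ",")
    }
  }
  list(mism = mism, span_len = span_len, trunc = trunc, mpos = mpos)
}

#' Resolve reads whose best miRNA hit is ambiguous
#'
#' Among tied-best candidates (typically members of the same seed family) one
#' miRNA is chosen uniformly at random, deterministically for a given seed.
#' The full candidate set is retained in \code{candidate_ids} for the strict
#' family-analysis mode.
#'
#' @param hits data.frame from [find_mirna_hits()].
#' @param rng_seed integer seed.
#' @return data.frame with one row per read; adds \code{candidate_ids}.
#' @export
resolve_ambiguous <- function(hits, rng_seed = 1L) {
  if (nrow(hits) == 0L) {
    hits$candidate_ids <- character(0)
    return(hits)
  }
  key <- hits$read_id
  if (anyNA(key) || any(!nzchar(key))) stop("hits require read ids")
  cand <- vapply(split(hits$mirna_id, key),
                 function(x) paste(sort(x), collapse = ","), character(1))
  set.seed(rng_seed)
  # deterministic given seed: iterate reads in a stable order
  groups <- split(seq_len(nrow(hits)), key)
  pick <- vapply(groups[order(names(groups))], function(ix) {
    if (length(ix) == 1L) ix else ix[sample.int(length(ix), 1L)]
  }, integer(1))
  out <- hits[sort(pick), , drop = FALSE]
  out$candidate_ids <- unname(cand[out$read_id])
  rownames(out) <- NULL
  out
}

#' Extract chimera target fragments flanking a miRNA hit
#'
#' The 3' flank (downstream of the miRNA) yields a miR-first chimera, the 5'
#' flank a miR-last chimera; both can come from one read. Flanks shorter than
#' \code{min_len} are not emitted.
#'
#' @param reads sequence data.frame indexed by hit \code{read_i}.
#' @param hits resolved hits from [resolve_ambiguous()].
#' @param min_len minimum target fragment length (default 18).
#' @param sheet optional sample sheet to attach ligase status.
#' @return data.frame of chimeras: read_id, sample_id, mirna_id, orientation,
#'   fragment, truncation_3p, candidate_ids, ligase_treated.
#' @export
extract_flanks <- function(reads, hits, min_len = 18L, sheet = NULL) {
  idx <- match(hits$read_id, reads$id)
  seqs <- reads$seq[idx]
  five <- substr(seqs, 1L, hits$start - 1L)
  three <- substr(seqs, hits$end + 1L, nchar(seqs))
  samp <- if ("sample_id" %in% names(reads)) reads$sample_id[idx]
          else rep(NA_character_, length(idx))
  mk <- function(frag, orientation) {
    keep <- nchar(frag) >= min_len
    data.frame(read_id = hits$read_id[keep], sample_id = samp[keep],
               mirna_id = hits$mirna_id[keep],
               orientation = rep(orientation, sum(keep)),
               fragment = frag[keep], truncation_3p = hits$truncation_3p[keep],
               candidate_ids = hits$candidate_ids[keep],
               stringsAsFactors = FALSE)
  }
  out <- rbind(mk(three, "miR_first"), mk(five, "miR_last"))
  if (!is.null(sheet)) {
    out$ligase_treated <- sheet$ligase_treated[match(out$sample_id,
                                                     sheet$sample_id)]
  }
  rownames(out) <- NULL
  out
}

# all placements of `frags` in `genome` with <= max_mm mismatches.
# Fast path: exact 12-mer prefix anchor (PDict trusted band) with bounded
# mismatches elsewhere; fragments it misses fall back to an exhaustive scan.
genome_placements <- function(frags, genome, max_mm = 2L, anchor = 12L,
                              exhaustive_fallback = TRUE) {
  stopifnot(all(nchar(frags) >= anchor))
  hits_list <- vector("list", 2L * length(genome))
  li <- 0L
  for (strand in c("+", "-")) {
    pats <- if (strand == "+") frags else revcomp(frags)
    pd <- Biostrings::PDict(pats, tb.start = 1L, tb.width = anchor)
    for (ci in seq_along(genome)) {
      m <- Biostrings::matchPDict(pd, genome[[ci]], max.mismatch = max_mm)
      cnt <- lengths(m)
      if (!sum(cnt)) next
      fi <- rep.int(seq_along(pats), cnt)
      r <- unlist(m)
      gseq <- as.character(Biostrings::extractAt(genome[[ci]], r))
      mm <- str_mismatches(gseq, pats[fi])
      li <- li + 1L
      hits_list[[li]] <- data.frame(
        frag_i = fi, chrom = names(genome)[ci],
        start = BiocGenerics::start(r) - 1L, end = BiocGenerics::end(r),
        strand = strand, mismatches = as.integer(mm), stringsAsFactors = FALSE)
    }
  }
  hits <- if (li) do.call(rbind, hits_list[seq_len(li)]) else
    data.frame(frag_i = integer(0), chrom = character(0), start = integer(0),
               end = integer(0), strand = character(0), mismatches = integer(0))
  if (exhaustive_fallback) {
    # re-scan fragments that are unplaced or only imperfectly placed, to
    # guarantee the same sensitivity as a full Hamming scan
    best <- tapply(hits$mismatches, hits$frag_i, min)
    redo <- setdiff(seq_along(frags), as.integer(names(best)[best == 0L]))
    if (length(redo)) {
      hits <- hits[!(hits$frag_i %in% redo), , drop = FALSE]
      extra <- lapply(redo, function(fi) {
        rows <- list()
        for (strand in c("+", "-")) {
          pat <- if (strand == "+") frags[fi] else revcomp(frags[fi])
          m <- Biostrings::vmatchPattern(pat, genome, max.mismatch = max_mm,
                                         fixed = TRUE)
          for (ci in seq_along(m)) {
            r <- m[[ci]]
            if (!length(r)) next
            r <- r[BiocGenerics::start(r) >= 1L &
                     BiocGenerics::end(r) <= length(genome[[ci]])]
            if (!length(r)) next
            gseq <- as.character(Biostrings::extractAt(genome[[ci]],
                                                       IRanges::IRanges(
                                                         BiocGenerics::start(r),
                                                         BiocGenerics::end(r))))
            mm <- str_mismatches(gseq, rep(pat, length(r)))
            rows[[length(rows) + 1L]] <- data.frame(
              frag_i = fi, chrom = names(genome)[ci],
              start = BiocGenerics::start(r) - 1L, end = BiocGenerics::end(r),
              strand = strand, mismatches = as.integer(mm),
              stringsAsFactors = FALSE)
          }
        }
        if (length(rows)) do.call(rbind, rows) else NULL
      })
      extra <- extra[!vapply(extra, is.null, logical(1))]
      if (length(extra)) hits <- rbind(hits, do.call(rbind, extra))
    }
  }
  hits
}

#' Map chimera target fragments uniquely to the genome
#'
#' Both strands are searched with up to \code{max_mismatches} substitutions.
#' A fragment is retained only when exactly one best-scoring placement exists;
#' otherwise it is rejected as unmapped or multi-mapped.
#'
#' @param chimeras chimera data.frame from [extract_flanks()].
#' @param genome named \code{DNAStringSet}.
#' @param max_mismatches Hamming budget (default 2).
#' @return list with \code{alignments} (chimeras + chrom, start (0-based), end,
#'   strand, mismatches, unique) and \code{rejected} (read_id, reason).
#' @export
map_target <- function(chimeras, genome, max_mismatches = 2L) {
  if (nrow(chimeras) == 0L) {
    return(list(alignments = cbind(chimeras,
                                   data.frame(chrom = character(0), start = integer(0),
                                              end = integer(0), strand = character(0),
                                              mismatches = integer(0), unique = logical(0))),
                rejected = data.frame(read_id = character(0), reason = character(0))))
  }
  ufrag <- unique(chimeras$fragment)
  hits <- genome_placements(ufrag, genome, max_mm = max_mismatches)
  status <- data.frame(frag = ufrag, chrom = NA_character_, start = NA_integer_,
                       end = NA_integer_, strand = NA_character_,
                       mismatches = NA_integer_, reason = "unmapped",
                       stringsAsFactors = FALSE)
  if (nrow(hits)) {
    sp <- split(hits, hits$frag_i)
    for (key in names(sp)) {
      h <- sp[[key]]
      i <- as.integer(key)
      b <- h[h$mismatches == min(h$mismatches), , drop = FALSE]
      b <- b[!duplicated(b[c("chrom", "start", "strand")]), , drop = FALSE]
      if (nrow(b) == 1L) {
        status[i, c("chrom", "strand", "reason")] <- c(b$chrom, b$strand, "mapped")
        status$start[i] <- b$start
        status$end[i] <- b$end
        status$mismatches[i] <- b$mismatches
      } else {
        status$reason[i] <- "multimapped"
      }
    }
  }
  st <- status[match(chimeras$fragment, status$frag), , drop = FALSE]
  ok <- st$reason == "mapped"
  aln <- cbind(chimeras[ok, , drop = FALSE],
               st[ok, c("chrom", "start", "end", "strand", "mismatches"),
                  drop = FALSE])
  aln$unique <- rep(TRUE, nrow(aln))
  rownames(aln) <- NULL
  rejected <- data.frame(read_id = chimeras$read_id[!ok],
                         reason = st$reason[!ok], stringsAsFactors = FALSE)
  list(alignments = aln, rejected = rejected)
}

#' Remove target alignments overlapping annotated miRNA loci
#'
#' Any alignment overlapping a \code{mirna_locus} interval by at least 1 bp on
#' either strand is removed.
#'
#' @param alignments alignment data.frame from [map_target()].
#' @param annotation annotation \code{GRanges}.
#' @return filtered alignment data.frame.
#' @export
filter_mirna_loci <- function(alignments, annotation) {
  loci <- annotation[annotation$region_label == "mirna_locus"]
  if (!length(loci) || nrow(alignments) == 0L) return(alignments)
  gr <- GenomicRanges::GRanges(alignments$chrom,
                               IRanges::IRanges(alignments$start + 1L,
                                                alignments$end))
  drop <- IRanges::overlapsAny(gr, loci, ignore.strand = TRUE)
  out <- alignments[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Estimate the false-ligation rate from a genome-mixing design
#'
#' Each target fragment is assigned to the primary genome, the foreign genome,
#' both (ambiguous) or neither; the rate is foreign / (primary + foreign), with
#' ambiguous fragments excluded and reported.
#'
#' @param chimeras chimera data.frame (needs fragment, sample_id).
#' @param primary_genome,foreign_genome named \code{DNAStringSet}s.
#' @param max_mismatches Hamming budget per genome (default 2).
#' @return list with \code{rate}, per-sample table and category counts.
#' @export
estimate_false_ligation_rate <- function(chimeras, primary_genome,
                                         foreign_genome, max_mismatches = 2L) {
  if (identical(as.character(primary_genome), as.character(foreign_genome))) {
    stop("primary and foreign genomes are identical")
  }
  ufrag <- unique(chimeras$fragment)
  maps <- function(genome) {
    h <- genome_placements(ufrag, genome, max_mm = max_mismatches)
    seq_along(ufrag) %in% h$frag_i
  }
  in_primary <- maps(primary_genome)
  in_foreign <- maps(foreign_genome)
  category <- ifelse(in_primary & in_foreign, "both",
                     ifelse(in_primary, "primary",
                            ifelse(in_foreign, "foreign", "neither")))
  cat_per_read <- category[match(chimeras$fragment, ufrag)]
  tab <- table(factor(cat_per_read,
                      levels = c("primary", "foreign", "both", "neither")))
  rate <- as.numeric(tab["foreign"] / (tab["primary"] + tab["foreign"]))
  per_sample <- do.call(rbind, lapply(split(cat_per_read, chimeras$sample_id),
    function(x) {
      t <- table(factor(x, levels = c("primary", "foreign", "both", "neither")))
      data.frame(primary = t[["primary"]], foreign = t[["foreign"]],
                 both = t[["both"]], neither = t[["neither"]],
                 rate = t[["foreign"]] / (t[["primary"]] + t[["foreign"]]))
    }))
  list(rate = rate, counts = tab, per_sample = per_sample,
       category = cat_per_read)
}

#' Summarise chimera rates per sample and ligase status
#'
#' @param chimeras chimera data.frame (sample_id, orientation, read_id).
#' @param unique_read_counts named vector of unique read totals per sample.
#' @param sheet sample sheet (ligase status per sample).
#' @return list with per-sample table and plus/no-ligase enrichment ratio per
#'   orientation.
#' @export
chimera_rate_summary <- function(chimeras, unique_read_counts, sheet) {
  zero <- names(unique_read_counts)[unique_read_counts == 0]
  if (length(zero)) {
    warning("excluding zero-read sample(s): ", paste(zero, collapse = ", "))
    unique_read_counts <- unique_read_counts[unique_read_counts > 0]
  }
  samples <- names(unique_read_counts)
  # deduplicate by (read, orientation): one read may emit both flanks
  ch <- chimeras[!duplicated(chimeras[c("read_id", "orientation")]), ,
                 drop = FALSE]
  tab <- data.frame(sample_id = samples,
                    ligase_treated = sheet$ligase_treated[match(samples,
                                                                sheet$sample_id)],
                    unique_reads = as.numeric(unique_read_counts))
  for (ori in c("miR_first", "miR_last")) {
    n <- table(factor(ch$sample_id[ch$orientation == ori], levels = samples))
    tab[[paste0(ori, "_n")]] <- as.integer(n)
    tab[[paste0(ori, "_frac")]] <- as.numeric(n) / tab$unique_reads
  }
  ratio <- vapply(c("miR_first", "miR_last"), function(ori) {
    f <- tab[[paste0(ori, "_frac")]]
    mean(f[tab$ligase_treated]) / mean(f[!tab$ligase_treated])
  }, numeric(1))
  list(per_sample = tab, ligase_enrichment = ratio)
}
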