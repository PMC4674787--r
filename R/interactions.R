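# Clustering of same-miRNA chimeras into interactions, 75-nt target region
# definition, transcript-region annotation and non-chimeric read support.

REGION_PRIORITY <- c("three_prime_utr", "cds", "five_prime_utr", "noncoding",
                     "intron", "intergenic")

#' Cluster aligned chimeras into miRNA-target interactions
#'
#' Two chimeras merge iff they share the miRNA and strand and their genomic
#' intervals overlap by at least 1 bp (transitive closure). The interaction
#' interval is the union; N counts distinct chimeric reads; the ligation site
#' is the modal target-fragment 5' end (strand-aware; ties resolved to the
#' most upstream position on the strand).
#'
#' @param alignments alignment data.frame from [map_target()] (miRNA-locus
#'   filtered), with 0-based half-open coordinates.
#' @return data.frame of interactions: interaction_id, mirna_id, chrom, strand,
#'   start, end (0-based half-open), N, n_samples, samples, ligation_site.
#' @export
cluster_chimeras <- function(alignments) {
  if (nrow(alignments) == 0L) {
    return(data.frame(interaction_id = character(0), mirna_id = character(0),
                      chrom = character(0), strand = character(0),
                      start = integer(0), end = integer(0), N = integer(0),
                      n_samples = integer(0), samples = character(0),
                      ligation_site = integer(0)))
  }
  aln <- alignments[!duplicated(alignments[c("read_id", "orientation")]), ,
                    drop = FALSE]
  gr <- GenomicRanges::GRanges(aln$chrom,
                               IRanges::IRanges(aln$start + 1L, aln$end),
                               strand = aln$strand)
  key <- paste(aln$mirna_id, aln$strand, aln$chrom, sep = "\r")
  out <- vector("list", 0L)
  for (k in unique(key)) {
    ix <- which(key == k)
    red <- GenomicRanges::reduce(gr[ix], min.gapwidth = 0L)
    ov <- GenomicRanges::findOverlaps(gr[ix], red)
    grp <- S4Vectors::subjectHits(ov)[order(S4Vectors::queryHits(ov))]
    strand <- aln$strand[ix[1]]
    for (g in seq_along(red)) {
      mem <- ix[grp == g]
      five <- if (strand == "+") aln$start[mem] else aln$end[mem] - 1L
      tab <- table(five)
      modal <- as.integer(names(tab)[tab == max(tab)])
      lig <- if (strand == "+") min(modal) else max(modal)
      out[[length(out) + 1L]] <- data.frame(
        mirna_id = aln$mirna_id[mem[1]], chrom = aln$chrom[mem[1]],
        strand = strand,
        start = BiocGenerics::start(red[g]) - 1L,
        end = BiocGenerics::end(red[g]),
        N = length(mem),
        n_samples = length(unique(aln$sample_id[mem])),
        samples = paste(sort(unique(aln$sample_id[mem])), collapse = ","),
        ligation_site = lig, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start, res$mirna_id, res$strand), ,
             drop = FALSE]
  res$interaction_id <- sprintf("I%06d", seq_len(nrow(res)))
  rownames(res) <- NULL
  res[, c("interaction_id", "mirna_id", "chrom", "strand", "start", "end",
          "N", "n_samples", "samples", "ligation_site")]
}

#' Define the 75-nt target region of each interaction
#'
#' The region is 75 nt beginning at the ligation site, strand-aware, extended
#' beyond the sequenced fragment when needed. Clusters spanning more than
#' 100 nt are dropped (and counted); spans in (75, 100] are trimmed
#' symmetrically to 75 nt (the extra base removed from the upstream side).
#' Regions running past a chromosome end are clipped and flagged.
#'
#' @param interactions data.frame from [cluster_chimeras()].
#' @param genome named \code{DNAStringSet}.
#' @param window region length (default 75).
#' @param max_span clusters longer than this are omitted (default 100).
#' @return interactions with added target_region, region_start, region_end and
#'   clipped columns; attribute \code{"dropped_long"} counts omitted clusters.
#' @export
define_target_region <- function(interactions, genome, window = 75L,
                                 max_span = 100L) {
  span <- interactions$end - interactions$start
  drop <- span > max_span
  out <- interactions[!drop, , drop = FALSE]
  span <- span[!drop]
  n <- nrow(out)
  rs <- integer(n); re <- integer(n)
  for (i in seq_len(n)) {
    if (span[i] > window) {
      excess <- span[i] - window
      up <- ceiling(excess / 2); down <- floor(excess / 2)
      if (out$strand[i] == "+") {
        rs[i] <- out$start[i] + up; re[i] <- out$end[i] - down
      } else {
        rs[i] <- out$start[i] + down; re[i] <- out$end[i] - up
      }
    } else if (out$strand[i] == "+") {
      rs[i] <- out$ligation_site[i]; re[i] <- rs[i] + window
    } else {
      re[i] <- out$ligation_site[i] + 1L; rs[i] <- re[i] - window
    }
  }
  clen <- nchar(as.character(genome))[match(out$chrom, names(genome))]
  clipped <- rs < 0L | re > clen
  rs <- pmax(rs, 0L); re <- pmin(re, clen)
  seqs <- character(n)
  for (ci in unique(out$chrom)) {
    ix <- which(out$chrom == ci)
    seqs[ix] <- as.character(Biostrings::extractAt(
      genome[[ci]], IRanges::IRanges(rs[ix] + 1L, re[ix])))
  }
  neg <- out$strand == "-"
  seqs[neg] <- revcomp(seqs[neg])
  out$region_start <- rs
  out$region_end <- re
  out$target_region <- seqs
  out$clipped <- clipped
  attr(out, "dropped_long") <- sum(drop)
  rownames(out) <- NULL
  out
}

#' Annotate interactions with a transcript region label
#'
#' The label is chosen by midpoint overlap with priority
#' 3'UTR > CDS > 5'UTR > noncoding > intron > intergenic.
#'
#' @param interactions data.frame with chrom, start, end, strand.
#' @param annotation annotation \code{GRanges}.
#' @return character vector of region labels.
#' @export
annotate_region <- function(interactions, annotation) {
  ann <- annotation[annotation$region_label != "mirna_locus"]
  mid <- (interactions$start + interactions$end) %/% 2L
  gr <- GenomicRanges::GRanges(interactions$chrom,
                               IRanges::IRanges(mid + 1L, mid + 1L),
                               strand = interactions$strand)
  ov <- GenomicRanges::findOverlaps(gr, ann)
  lab <- rep("intergenic", nrow(interactions))
  if (length(ov)) {
    q <- S4Vectors::queryHits(ov)
    s <- S4Vectors::subjectHits(ov)
    pr <- match(ann$region_label[s], REGION_PRIORITY)
    best <- tapply(seq_along(q), q, function(ix) ix[which.min(pr[ix])])
    lab[as.integer(names(best))] <-
      ann$region_label[s[unlist(best, use.names = FALSE)]]
  }
  lab
}

#' Attach non-chimeric read support to interactions
#'
#' Per interaction: the number of overlapping non-chimeric reads, the number of
#' distinct biological samples contributing at least one such read (biological
#' complexity, BC) and a depth-normalised density (pseudo-count of 1, see
#' [normalize_counts()]).
#'
#' @param interactions data.frame from [cluster_chimeras()].
#' @param nonchimeric data.frame of aligned non-chimeric reads (chrom, start,
#'   end, strand, sample_id), 0-based half-open.
#' @param depths named per-sample total read counts.
#' @param scale normalisation scale (default per-million).
#' @return data.frame interaction_id, n_reads, BC, density, supported.
#' @export
peak_support <- function(interactions, nonchimeric, depths, scale = 1e6) {
  igr <- GenomicRanges::GRanges(interactions$chrom,
                                IRanges::IRanges(interactions$start + 1L,
                                                 interactions$end),
                                strand = interactions$strand)
  n <- nrow(interactions)
  nr <- integer(n); bc <- integer(n)
  if (nrow(nonchimeric)) {
    rgr <- GenomicRanges::GRanges(nonchimeric$chrom,
                                  IRanges::IRanges(nonchimeric$start + 1L,
                                                   nonchimeric$end),
                                  strand = nonchimeric$strand)
    ov <- GenomicRanges::findOverlaps(igr, rgr)
    q <- S4Vectors::queryHits(ov); s <- S4Vectors::subjectHits(ov)
    cnt <- table(factor(q, levels = seq_len(n)))
    nr <- as.integer(cnt)
    bcl <- tapply(nonchimeric$sample_id[s], factor(q, levels = seq_len(n)),
                  function(x) length(unique(x)))
    bc <- ifelse(is.na(bcl), 0L, as.integer(bcl))
  }
  density <- normalize_counts(nr, sum(depths), scale = scale)
  data.frame(interaction_id = interactions$interaction_id, n_reads = nr,
             BC = bc, density = density, supported = nr > 0L,
             stringsAsFactors = FALSE)
}
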