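# Sequence, genome, annotation and tabular IO, plus the read-preparation steps
# (demultiplexing, 3'-adapter trimming, PCR-duplicate collapse).
#
# Sequence streams are plain data.frames with columns id, seq, qual (NA for
# FASTA), and optionally sample_id / count, carrying an "alphabet" attribute
# ("DNA" or "RNA") recording the input alphabet before internal normalisation
# to DNA letters.

REGION_LABELS <- c("five_prime_utr", "cds", "three_prime_utr", "intron",
                   "noncoding", "mirna_locus")

new_seq_frame <- function(id, seq, qual = NA_character_, alphabet = "DNA") {
  df <- data.frame(id = as.character(id), seq = as.character(seq),
                   qual = as.character(qual), stringsAsFactors = FALSE)
  attr(df, "alphabet") <- alphabet
  df
}

#' Read sequences from FASTA or FASTQ
#'
#' Records are returned in file order. U (RNA) letters are normalised to T
#' internally; the original alphabet is recorded in the \code{"alphabet"}
#' attribute of the returned data frame.
#'
#' @param path file path.
#' @param format "fasta" or "fastq" (Sanger qualities).
#' @return data.frame with columns id, seq, qual and attribute "alphabet".
#' @export
read_sequences <- function(path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  set <- tryCatch(
    Biostrings::readBStringSet(path, format = format,
                               with.qualities = (format == "fastq")),
    error = function(e) stop("malformed ", format, " file '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  ids <- sub("\\s.*$", "", names(set))
  seqs <- as.character(set)
  bad <- grep("[^ACGTUNacgtun]", seqs)
  if (length(bad)) {
    stop("malformed record '", ids[bad[1]], "' (record ", bad[1],
         ", near line ", if (format == "fasta") NA else 4L * (bad[1] - 1L) + 2L,
         "): invalid nucleotide characters")
  }
  qual <- rep(NA_character_, length(seqs))
  if (format == "fastq") {
    qual <- as.character(S4Vectors::mcols(set)$qualities)
    mism <- which(nchar(qual) != nchar(seqs))
    if (length(mism)) {
      stop("FASTQ record '", ids[mism[1]], "' (near line ",
           4L * (mism[1] - 1L) + 2L, "): sequence length ",
           nchar(seqs[mism[1]]), " != quality length ", nchar(qual[mism[1]]))
    }
  }
  if (any(nchar(seqs) < 1L)) stop("empty sequence in ", path)
  alph <- if (any(grepl("[Uu]", seqs))) "RNA" else "DNA"
  new_seq_frame(ids, norm_dna(seqs), qual, alph)
}

#' Write a sequence stream to FASTA or FASTQ
#'
#' @param reads data.frame as returned by [read_sequences()].
#' @param path output path.
#' @param format "fasta" or "fastq"; FASTQ requires qualities.
#' @export
write_sequences <- function(reads, path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  if (format == "fasta") {
    writeLines(paste0(">", reads$id, "\n", reads$seq), path)
  } else {
    if (any(is.na(reads$qual))) stop("FASTQ output requires qualities")
    writeLines(paste0("@", reads$id, "\n", reads$seq, "\n+\n", reads$qual), path)
  }
  invisible(path)
}

#' Read a reference genome from FASTA
#'
#' @param path FASTA path.
#' @return named \code{DNAStringSet} of uppercase chromosome sequences.
#' @export
read_genome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  if (anyDuplicated(names(g))) stop("duplicate chromosome names in ", path)
  Biostrings::DNAStringSet(toupper(g))
}

#' Write a genome to FASTA
#' @param genome named DNAStringSet or named character vector.
#' @param path output path.
#' @export
write_genome <- function(genome, path) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' Read a sample sheet
#'
#' Tab-separated with header columns sample_id, index, ligase_treated,
#' species_tag. Indices must be unique and prefix-free so that each read can
#' match at most one sample.
#'
#' @param path TSV path.
#' @return data.frame sample sheet.
#' @export
read_sample_sheet <- function(path) {
  sheet <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_sample_sheet(sheet)
}

validate_sample_sheet <- function(sheet) {
  need <- c("sample_id", "index", "ligase_treated", "species_tag")
  if (!all(need %in% names(sheet))) {
    stop("sample sheet must have columns: ", paste(need, collapse = ", "))
  }
  sheet$index <- norm_dna(sheet$index)
  sheet$ligase_treated <- as.logical(sheet$ligase_treated)
  if (anyDuplicated(sheet$index)) stop("sample indices are not unique")
  for (i in seq_len(nrow(sheet))) {
    pref <- startsWith(sheet$index, sheet$index[i])
    if (sum(pref) > 1L) {
      stop("sample indices are not prefix-free ('", sheet$index[i],
           "' is a prefix of another index); a read could match two samples")
    }
  }
  sheet
}

#' Read a transcript-region annotation table
#'
#' BED-like TSV with columns chrom, start, end, strand, region_label, gene_id,
#' transcript_id. Coordinates in the file are 0-based half-open; the returned
#' \code{GRanges} uses the usual 1-based closed convention.
#'
#' @param path TSV path (with header).
#' @return \code{GRanges} with mcols region_label, gene_id, transcript_id.
#' @export
read_region_annotation <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  annotation_granges(df)
}

#' Build an annotation GRanges from a data.frame (0-based half-open coords)
#' @param df data.frame with chrom, start, end, strand, region_label, gene_id,
#'   transcript_id.
#' @return GRanges.
#' @export
annotation_granges <- function(df) {
  if (!all(df$region_label %in% REGION_LABELS)) {
    stop("unknown region_label(s): ",
         paste(setdiff(unique(df$region_label), REGION_LABELS), collapse = ", "))
  }
  if (any(df$start >= df$end)) stop("annotation requires start < end")
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = df$strand,
    region_label = df$region_label,
    gene_id = df$gene_id,
    transcript_id = df$transcript_id)
}

#' Write intervals as BED6
#'
#' @param df data.frame with chrom, start (0-based), end, name, score, strand.
#' @param path output path.
#' @export
write_bed <- function(df, path) {
  utils::write.table(df[, c("chrom", "start", "end", "name", "score", "strand")],
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Demultiplex reads by 5' sample index and trim the 3' adapter
#'
#' Each read is assigned to at most one sample by exact index match at the
#' configured offset (default: read 5' end). The 3' adapter is removed at the
#' leftmost match: full-length adapter occurrences tolerate one mismatch;
#' terminal suffix-prefix overlaps must be exact and at least
#' \code{min_adapter_overlap} long. Reads shorter than \code{min_length} after
#' index removal and trimming are dropped and counted.
#'
#' @param reads sequence data.frame (id, seq, qual).
#' @param sheet sample sheet data.frame (see [read_sample_sheet()]).
#' @param adapter 3' adapter sequence (default the pre-adenylated linker
#'   GTGTCAGTCACTTCCAGCGG).
#' @param min_adapter_overlap minimum terminal overlap trimmed (default 6).
#' @param index_offset 0-based offset of the sample index in the read.
#' @param min_length minimum insert length retained after trimming (default 18).
#' @return list with per-sample streams (\code{samples}), \code{unassigned}
#'   count and \code{dropped_short} count.
#' @export
demultiplex_and_trim <- function(reads, sheet,
                                 adapter = "GTGTCAGTCACTTCCAGCGG",
                                 min_adapter_overlap = 6L,
                                 index_offset = 0L,
                                 min_length = 18L) {
  stopifnot(nchar(adapter) >= 1L, min_adapter_overlap >= 1L)
  sheet <- validate_sample_sheet(sheet)
  adapter <- norm_dna(adapter)
  seqs <- reads$seq
  n <- length(seqs)
  assigned <- rep(NA_integer_, n)
  for (i in seq_len(nrow(sheet))) {
    idx <- sheet$index[i]
    hit <- substr(seqs, index_offset + 1L, index_offset + nchar(idx)) == idx
    assigned[hit & is.na(assigned)] <- i
  }
  unassigned <- sum(is.na(assigned))
  keep <- which(!is.na(assigned))
  # strip the index (and anything 5' of it)
  idx_len <- nchar(sheet$index)[assigned[keep]]
  ins <- substr(seqs[keep], index_offset + idx_len + 1L, nchar(seqs[keep]))
  qual <- reads$qual[keep]
  if (!all(is.na(qual))) {
    qual <- substr(qual, index_offset + idx_len + 1L, nchar(reads$qual[keep]))
  }
  cut <- adapter_cut_position(ins, adapter, min_adapter_overlap)
  has_cut <- !is.na(cut)
  ins[has_cut] <- substr(ins[has_cut], 1L, cut[has_cut] - 1L)
  qual[has_cut & !is.na(qual)] <- substr(qual[has_cut & !is.na(qual)], 1L,
                                         cut[has_cut & !is.na(qual)] - 1L)
  long_enough <- nchar(ins) >= min_length
  dropped_short <- sum(!long_enough)
  out <- data.frame(id = reads$id[keep], seq = ins, qual = qual,
                    sample_id = sheet$sample_id[assigned[keep]],
                    stringsAsFactors = FALSE)[long_enough, , drop = FALSE]
  rownames(out) <- NULL
  samples <- split(out, factor(out$sample_id, levels = sheet$sample_id))
  list(samples = samples, unassigned = unassigned,
       dropped_short = dropped_short, assigned = nrow(out))
}

# leftmost adapter position (1-based within each read), NA if none
adapter_cut_position <- function(seqs, adapter, min_overlap) {
  alen <- nchar(adapter)
  n <- length(seqs)
  cut <- rep(NA_integer_, n)
  # full-length occurrences, <= 1 mismatch, leftmost
  m <- Biostrings::vmatchPattern(adapter, Biostrings::DNAStringSet(seqs),
                                 max.mismatch = 1L, fixed = TRUE)
  st <- Biostrings::startIndex(m)
  full <- vapply(st, function(s) if (is.null(s) || !length(s)) NA_integer_
                 else min(s), integer(1))
  cut <- full
  # exact terminal suffix-prefix overlaps; longer overlap = more leftmost
  len <- nchar(seqs)
  for (ov in seq(alen - 1L, min_overlap)) {
    if (ov < 1L) break
    pref <- substr(adapter, 1L, ov)
    hit <- substr(seqs, len - ov + 1L, len) == pref & len >= ov
    pos <- len - ov + 1L
    better <- hit & (is.na(cut) | pos < cut)
    cut[better] <- pos[better]
  }
  cut
}

#' Collapse PCR duplicates within a sample
#'
#' Reads with identical sequence collapse to one record carrying a count.
#' Existing counts are summed, making the operation idempotent.
#'
#' @param reads per-sample sequence data.frame (id, seq, optionally count).
#' @return data.frame of unique sequences with \code{count}.
#' @export
collapse_duplicates <- function(reads) {
  if (nrow(reads) == 0L) {
    reads$count <- integer(0)
    return(reads)
  }
  cnt <- if ("count" %in% names(reads)) reads$count else rep(1L, nrow(reads))
  key <- if ("sample_id" %in% names(reads)) {
    paste(reads$sample_id, reads$seq, sep = "\r")
  } else reads$seq
  first <- !duplicated(key)
  out <- reads[first, , drop = FALSE]
  out$count <- as.integer(rowsum(cnt, key)[unique(key), 1L])
  src <- if ("member_ids" %in% names(reads)) reads$member_ids else reads$id
  members <- vapply(split(src, key), paste, character(1), collapse = ",")
  out$member_ids <- unname(members[unique(key)])
  rownames(out) <- NULL
  out
}

#' Normalise per-library cluster counts
#'
#' Adds a pseudo-count of 1 and scales to the library read depth:
#' value = (count + 1) / depth * scale.
#'
#' @param counts numeric matrix (clusters x libraries) or vector.
#' @param depths per-library total read counts (> 0).
#' @param scale per-million by default (1e6).
#' @return normalised matrix (or vector).
#' @export
normalize_counts <- function(counts, depths, scale = 1e6) {
  if (any(depths <= 0)) stop("library depths must be > 0")
  if (is.matrix(counts)) {
    if (ncol(counts) != length(depths)) stop("one depth per library required")
    sweep(counts + 1, 2L, depths, "/") * scale
  } else {
    (counts + 1) / depths * scale
  }
}
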