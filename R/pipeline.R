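# End-to-end convenience wrapper: demultiplex -> collapse -> reverse-map ->
# flank extraction -> unique placement -> miRNA-locus filter -> interaction
# clustering -> target regions -> annotation.

#' Run the chimera-discovery pipeline on a read library
#'
#' @param reads multiplexed sequence data.frame (e.g. from
#'   [read_sequences()] or [simulate_experiment()]).
#' @param sheet sample sheet.
#' @param catalog miRNA catalogue.
#' @param genome named \code{DNAStringSet}.
#' @param annotation annotation \code{GRanges} (or NULL to skip filtering and
#'   labels).
#' @param adapter 3' adapter sequence.
#' @param seed_mismatch,ext_mismatch,truncation,min_prefix see
#'   [find_mirna_hits()].
#' @param min_flank minimum target fragment length (default 18).
#' @param max_mismatches mapping Hamming budget (default 2).
#' @param mir_last_downstream include miR-last chimeras in clustering
#'   (default FALSE, matching the ligase-dependence of miR-first chimeras).
#' @param rng_seed seed for ambiguous-hit resolution.
#' @return list with reads-per-sample counts, chimeras, alignments,
#'   interactions (with target regions and labels), rejected fragments and
#'   stage accounting.
#' @export
run_pipeline <- function(reads, sheet, catalog, genome, annotation = NULL,
                         adapter = "GTGTCAGTCACTTCCAGCGG",
                         seed_mismatch = 1L, ext_mismatch = 2L,
                         truncation = FALSE, min_prefix = 12L,
                         min_flank = 18L, max_mismatches = 2L,
                         mir_last_downstream = FALSE, rng_seed = 1L) {
  demux <- demultiplex_and_trim(reads, sheet, adapter = adapter)
  collapsed <- do.call(rbind, lapply(demux$samples, collapse_duplicates))
  rownames(collapsed) <- NULL
  unique_reads <- vapply(demux$samples, function(df)
    nrow(collapse_duplicates(df)), integer(1))
  hits <- find_mirna_hits(collapsed, catalog, seed_mismatch = seed_mismatch,
                          ext_mismatch = ext_mismatch,
                          truncation = truncation, min_prefix = min_prefix)
  hits <- resolve_ambiguous(hits, rng_seed = rng_seed)
  chimeras <- extract_flanks(collapsed, hits, min_len = min_flank,
                             sheet = sheet)
  mapped <- map_target(chimeras, genome, max_mismatches = max_mismatches)
  aln <- mapped$alignments
  if (!is.null(annotation)) aln <- filter_mirna_loci(aln, annotation)
  clus_in <- if (mir_last_downstream) aln
             else aln[aln$orientation == "miR_first", , drop = FALSE]
  interactions <- cluster_chimeras(clus_in)
  interactions <- define_target_region(interactions, genome)
  if (!is.null(annotation)) {
    interactions$region_label <- annotate_region(interactions, annotation)
  }
  rates <- chimera_rate_summary(chimeras, unique_reads, sheet)
  list(collapsed = collapsed, unique_reads = unique_reads, hits = hits,
       chimeras = chimeras, alignments = aln, rejected = mapped$rejected,
       interactions = interactions, rates = rates,
       accounting = c(input = nrow(reads), assigned = demux$assigned,
                      unassigned = demux$unassigned,
                      dropped_short = demux$dropped_short,
                      collapsed = nrow(collapsed),
                      chimeras = nrow(chimeras), aligned = nrow(aln),
                      interactions = nrow(interactions)))
}
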