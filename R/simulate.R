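# Synthetic CLIP experiment generator: genomes, transcript annotations, miRNA
# catalogues with seed families, multiplexed read libraries with planted
# chimeras, expression tables, and byte-reproducible ground truth for every
# pipeline stage.

#' Default planted binding-mode archetypes
#'
#' Six binary pairing profiles over miRNA positions 2..L: seed only; seed plus
#' classic 13-16 supplementary pairing; seed plus extended 3' pairing;
#' seedless 3'-centric; seed with bipartite auxiliary pairing; seed with
#' tripartite auxiliary pairing.
#'
#' @param L miRNA length (default 22).
#' @return list of named integer vectors (positions 2..L).
#' @export
default_archetypes <- function(L = 22L) {
  prof <- function(...) {
    v <- stats::setNames(integer(L - 1L), 2:L)
    for (rng in list(...)) v[as.character(rng)] <- 1L
    v
  }
  list(seed_only = prof(2:8),
       seed_suppl_13_16 = prof(2:8, 13:16),
       seed_3p_extended = prof(2:8, 14:min(22L, L)),
       seedless_3p = prof(11:20),
       seed_bipartite = prof(2:8, 10:12, 17:21),
       seed_tripartite = prof(2:8, 9:11, 14:16, 19:21))
}

#' Build a synthetic-experiment configuration
#'
#' Defaults encode the emulated study conditions: miR-first chimeras at ~3%
#' of unique reads in ligase-treated samples and 10-fold fewer without ligase;
#' miR-first:miR-last ratio 14; miRNA truncations mostly 0 or 1 nt; a seed
#' class mixture with >30% mismatch+bulge and ~20% seedless sites; six
#' binding archetypes; optional cross-species contamination; PCR duplication
#' and uniform substitution errors.
#'
#' @param ... overrides of the default fields.
#' @return validated config list of class \code{sim_config}.
#' @export
sim_config <- function(...) {
  cfg <- list(
    rng_seed = 1L,
    n_chrom = 2L, chrom_len = 120000L, foreign_len = 80000L,
    n_genes = 50L, n_noncoding = 6L,
    utr5_len = 150L, cds_len = 900L, intron_len = 400L, utr3_len = 600L,
    n_mirnas = 18L, family_sizes = c(4L, 2L), mirna_len = c(21L, 22L),
    n_ligase = 6L, n_noligase = 2L, index_len = 5L,
    reads_total = 50000L, read_len = 100L,
    adapter = "GTGTCAGTCACTTCCAGCGG",
    chimera_frac = 0.03, ligase_ratio = 10, mir_last_ratio = 14,
    mirna_only_frac = 0.25,
    truncation_probs = c(`0` = 0.85, `1` = 0.12, `2` = 0.03),
    seed_class_mix = c(`8mer` = 0.10, `7mer-m8` = 0.12, `7mer-A1` = 0.12,
                       `6mer` = 0.11, mismatch = 0.20, bulge = 0.15,
                       seedless = 0.20),
    site_region_mix = c(three_prime_utr = 0.45, cds = 0.25, intron = 0.15,
                        five_prime_utr = 0.05, noncoding = 0.10),
    n_sites = 400L, frag_len = c(22L, 45L),
    contamination_frac = 0, pcr_dup_rate = 0.25, error_rate = 0.002,
    bg_pileup_frac = 0.6,
    effect_by_class = c(canonical = -0.4, mismatch = -0.15, bulge = -0.25,
                        seedless = -0.05),
    expr_noise_sd = 0.25)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  fr <- c(cfg$chimera_frac, cfg$contamination_frac, cfg$pcr_dup_rate,
          cfg$error_rate, cfg$mirna_only_frac, cfg$bg_pileup_frac)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  if (abs(sum(cfg$seed_class_mix) - 1) > 1e-9) {
    stop("seed_class_mix must sum to 1")
  }
  if (abs(sum(cfg$site_region_mix) - 1) > 1e-9) {
    stop("site_region_mix must sum to 1")
  }
  if (max(cfg$frag_len) + max(cfg$mirna_len) + cfg$index_len > cfg$read_len) {
    stop("read_len too short for index + miRNA + fragment")
  }
  class(cfg) <- "sim_config"
  cfg
}

# --- internal generator pieces ------------------------------------------------

sim_mirna_catalog <- function(cfg) {
  n <- cfg$n_mirnas
  lens <- sample(cfg$mirna_len, n, replace = TRUE)
  seqs <- character(n)
  ids <- character(n)
  fam_sizes <- cfg$family_sizes
  i <- 1L; f <- 1L
  seeds_used <- character(0)
  new_seed_seq <- function(len) {
    repeat {
      s <- random_dna(1L, len)
      if (!(substr(s, 2L, 8L) %in% seeds_used)) return(s)
    }
  }
  for (fs in fam_sizes) {
    base <- new_seed_seq(max(lens[i:(i + fs - 1L)]))
    seeds_used <- c(seeds_used, substr(base, 2L, 8L))
    for (k in seq_len(fs)) {
      L <- lens[i]
      s <- substr(base, 1L, min(12L, L))
      tail <- random_dna(1L, L - nchar(s))   # divergent 3' end
      seqs[i] <- paste0(s, tail)
      ids[i] <- sprintf("mir-%d%s", f, letters[k])
      i <- i + 1L
    }
    f <- f + 1L
  }
  while (i <= n) {
    L <- lens[i]
    seqs[i] <- new_seed_seq(L)
    seeds_used <- c(seeds_used, substr(seqs[i], 2L, 8L))
    ids[i] <- sprintf("mir-%d", f)
    i <- i + 1L; f <- f + 1L
  }
  read_mirna_catalog(data.frame(mirna_id = ids, seq = seqs,
                                stringsAsFactors = FALSE))
}

# gene/feature layout; returns annotation df (0-based half-open) and free gaps
sim_annotation <- function(cfg, chrom_names) {
  rows <- list()
  gaps <- list()
  gene_i <- 0L
  glen_coding <- cfg$utr5_len + cfg$cds_len + cfg$intron_len + cfg$utr3_len
  for (ci in seq_len(cfg$n_chrom)) {
    pos <- 400L
    per_chrom <- ceiling((cfg$n_genes + cfg$n_noncoding) / cfg$n_chrom)
    for (g in seq_len(per_chrom)) {
      noncoding <- gene_i >= cfg$n_genes
      if (gene_i >= cfg$n_genes + cfg$n_noncoding) break
      gene_i <- gene_i + 1L
      gid <- sprintf("gene%03d", gene_i)
      tid <- paste0(gid, ".t1")
      strand <- sample(c("+", "-"), 1L)
      if (noncoding) {
        len <- 800L
        if (pos + len + 400L > cfg$chrom_len) break
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = chrom_names[ci], start = pos, end = pos + len,
          strand = strand, region_label = "noncoding", gene_id = gid,
          transcript_id = tid, stringsAsFactors = FALSE)
        pos <- pos + len
      } else {
        if (pos + glen_coding + 400L > cfg$chrom_len) break
        half_cds <- cfg$cds_len %/% 2L
        feats <- list(c("five_prime_utr", cfg$utr5_len),
                      c("cds", half_cds),
                      c("intron", cfg$intron_len),
                      c("cds", cfg$cds_len - half_cds),
                      c("three_prime_utr", cfg$utr3_len))
        if (strand == "-") feats <- rev(feats)
        for (ft in feats) {
          len <- as.integer(ft[2])
          rows[[length(rows) + 1L]] <- data.frame(
            chrom = chrom_names[ci], start = pos, end = pos + len,
            strand = strand, region_label = ft[1], gene_id = gid,
            transcript_id = tid, stringsAsFactors = FALSE)
          pos <- pos + len
        }
      }
      gaps[[length(gaps) + 1L]] <- data.frame(chrom = chrom_names[ci],
                                              start = pos + 60L,
                                              end = pos + 340L)
      pos <- pos + 400L
    }
  }
  list(features = do.call(rbind, rows), gaps = do.call(rbind, gaps))
}

# construct the 75-nt target site for a (miRNA, archetype, seed class) triple;
# returns list(region, seed_offset, edit_pos)
design_site <- function(mir, profile, seed_class, region_len = 75L) {
  L <- nchar(mir)
  pos <- as.integer(names(profile))
  on <- pos[profile == 1L]
  # contiguous blocks of paired positions, highest positions first (they sit
  # closest to the ligation junction in the target)
  blocks <- split(on, cumsum(c(1L, diff(on) != 1L)))
  blocks <- blocks[order(-vapply(blocks, max, integer(1)))]
  seed_block_idx <- which(vapply(blocks, function(b) any(b <= 8L), logical(1)))
  pieces <- character(0)
  seed_rel <- NA_integer_   # offset of the seed complement within the insert
  cursor <- 0L
  for (bi in seq_along(blocks)) {
    b <- blocks[[bi]]
    piece <- revcomp(substr(mir, min(b), max(b)))
    if (bi > 1L) {
      sp <- random_dna(1L, sample(1:3, 1L))
      pieces <- c(pieces, sp)
      cursor <- cursor + nchar(sp)
    }
    if (bi %in% seed_block_idx) {
      # comp(m8) sits (max(b) - 8) bases into the block when the block
      # extends past position 8
      seed_rel <- cursor + max(0L, max(b) - 8L)
    }
    pieces <- c(pieces, piece)
    cursor <- cursor + nchar(piece)
  }
  insert <- paste(pieces, collapse = "")
  edit_pos <- NA_integer_
  if (!is.na(seed_rel) && seed_class != "seedless") {
    # the seed block pairs positions 2..8; its complement spans
    # insert[seed_rel+1 .. seed_rel+7] reading comp(m8)..comp(m2)
    sb_start <- seed_rel + 1L
    sb <- substr(insert, sb_start, sb_start + 6L)
    tail_base <- switch(seed_class,
                        `8mer` = "A", `7mer-m8` = sample(c("C", "G", "T"), 1L),
                        `7mer-A1` = "A", `6mer` = sample(c("C", "G", "T"), 1L),
                        sample(c("A", "C", "G", "T"), 1L))
    if (seed_class %in% c("7mer-A1", "6mer")) {
      # destroy position-8 pairing: first base of the block opposes m8
      sb <- paste0(nonpairing_base(substr(mir, 8L, 8L)), substr(sb, 2L, 7L))
    }
    if (seed_class == "mismatch") {
      # positions 3-7 only: an edit at 2 or 8 leaves an intact canonical
      # sub-site, which classifies (correctly) as canonical
      edit_pos <- sample(3:7, 1L)
      bi <- 8L - edit_pos + 1L         # block index opposing position edit_pos
      substr(sb, bi, bi) <- nonpairing_base(substr(mir, edit_pos, edit_pos))
    }
    if (seed_class == "bulge") {
      if (stats::runif(1) < 0.7) {     # extra target nucleotide
        edit_pos <- sample(3:6, 1L)    # inserted between edit_pos, edit_pos+1
        cut <- 8L - edit_pos           # after bases opposing 8..edit_pos+1
        # the inserted base must not pair either flanking miRNA position,
        # or the "bulge" silently reverts to a canonical helix
        flank <- c(substr(mir, edit_pos, edit_pos),
                   substr(mir, edit_pos + 1L, edit_pos + 1L))
        bad <- unlist(lapply(flank, function(b)
          switch(b, A = "T", C = "G", G = c("C", "T"), T = c("A", "G"))))
        pool <- setdiff(c("A", "C", "G", "T"), bad)
        ins_base <- if (length(pool)) sample(pool, 1L)
                    else sample(c("A", "C", "G", "T"), 1L)
        sb <- paste0(substr(sb, 1L, cut), ins_base,
                     substr(sb, cut + 1L, 7L))
      } else {                         # bulged miRNA position
        edit_pos <- sample(3:7, 1L)
        bi <- 8L - edit_pos + 1L
        sb <- paste0(substr(sb, 1L, bi - 1L), substr(sb, bi + 1L, 7L))
      }
    }
    insert <- paste0(substr(insert, 1L, seed_rel), sb, tail_base,
                     substr(insert, sb_start + 7L, nchar(insert)))
  }
  if (seed_class == "seedless" && any(on <= 8L)) {
    # archetype carries a seed but the class forbids it; scrub seed pairing
    sb_start <- seed_rel + 1L
    # region reads comp(m8)..comp(m2); scrub each slot against its own base
    scr <- paste(nonpairing_base(rev(strsplit(substr(mir, 2L, 8L),
                                              "")[[1]])), collapse = "")
    insert <- paste0(substr(insert, 1L, seed_rel), scr,
                     substr(insert, sb_start + 7L, nchar(insert)))
    seed_rel <- NA_integer_
  }
  if (nchar(insert) > region_len - 6L) insert <- substr(insert, 1L,
                                                        region_len - 6L)
  off0 <- sample(2:(region_len - nchar(insert) - 2L), 1L)
  region <- random_dna(1L, region_len)
  region <- paste0(substr(region, 1L, off0),
                   insert,
                   substr(region, off0 + nchar(insert) + 1L, region_len))
  seed_offset <- if (is.na(seed_rel)) NA_integer_ else off0 + seed_rel
  list(region = region, seed_offset = seed_offset, edit_pos = edit_pos)
}

apply_errors <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  vapply(seqs, function(s) {
    n <- nchar(s)
    k <- stats::rbinom(1L, n, rate)
    if (k == 0L) return(s)
    pos <- sample.int(n, k)
    for (p in pos) {
      substr(s, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                        substr(s, p, p)), 1L)
    }
    s
  }, character(1), USE.NAMES = FALSE)
}

#' Simulate a complete synthetic CLIP experiment
#'
#' Deterministic for a given \code{rng_seed}. Planted seed sites fall within
#' 75 nt downstream of ligation junctions, binding archetypes are realised as
#' target sequences complementary to the profiled miRNA positions, no-ligase
#' samples carry miR-first chimeras at 1/\code{ligase_ratio} the ligase rate,
#' and contaminant fragments are drawn from a second genome sharing no exact
#' 20-mer with the primary one.
#'
#' @param cfg configuration from [sim_config()].
#' @param out_dir optional directory; when given, genome/annotation/miRNA/
#'   read/expression/truth files are written as plain text.
#' @return list(genome, foreign_genome, annotation, annotation_df, catalog,
#'   sheet, reads, expression, truth, config).
#' @export
simulate_experiment <- function(cfg = sim_config(), out_dir = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$rng_seed)
  chrom_names <- paste0("chr", seq_len(cfg$n_chrom))
  chroms <- stats::setNames(random_dna(cfg$n_chrom, cfg$chrom_len),
                            chrom_names)
  foreign <- c(chrF = random_dna(1L, cfg$foreign_len))
  foreign <- remove_shared_kmers(foreign, chroms, k = 20L)
  catalog <- sim_mirna_catalog(cfg)
  ann <- sim_annotation(cfg, chrom_names)
  features <- ann$features
  gaps <- ann$gaps

  # miRNA hairpin loci in intergenic gaps; mature sequence embedded in genome
  mirna_rows <- list()
  for (i in seq_len(nrow(catalog))) {
    gi <- ((i - 1L) %% nrow(gaps)) + 1L
    gp <- gaps[gi, ]
    start <- gp$start + 20L + 80L * ((i - 1L) %/% nrow(gaps))
    mat <- catalog$seq[i]
    locus_end <- start + 20L + nchar(mat) + 20L
    substr(chroms[[gp$chrom]], start + 21L, start + 20L + nchar(mat)) <- mat
    mirna_rows[[i]] <- data.frame(chrom = gp$chrom, start = start,
                                  end = locus_end, strand = "+",
                                  region_label = "mirna_locus",
                                  gene_id = catalog$mirna_id[i],
                                  transcript_id = catalog$mirna_id[i],
                                  stringsAsFactors = FALSE)
  }
  features <- rbind(features, do.call(rbind, mirna_rows))

  # plant target sites
  archs <- default_archetypes(max(nchar(catalog$seq)))
  w_mirna <- (1 / seq_len(nrow(catalog)))
  w_mirna <- w_mirna / sum(w_mirna)
  placeable <- features[features$region_label %in%
                          names(cfg$site_region_mix), , drop = FALSE]
  placeable <- placeable[(placeable$end - placeable$start) >= 95L, ,
                         drop = FALSE]
  used <- list()
  sites <- list()
  for (s in seq_len(cfg$n_sites)) {
    mi <- sample.int(nrow(catalog), 1L, prob = w_mirna)
    mir <- catalog$seq[mi]
    lab <- sample(names(cfg$site_region_mix), 1L, prob = cfg$site_region_mix)
    cand <- placeable[placeable$region_label == lab, , drop = FALSE]
    placed <- FALSE
    for (try in 1:30) {
      fr <- cand[sample.int(nrow(cand), 1L), ]
      gpos <- sample(seq(fr$start + 5L, fr$end - 90L), 1L)
      win <- c(gpos - 150L, gpos + 150L)
      clash <- any(vapply(used, function(u)
        u$chrom == fr$chrom && u$pos > win[1] && u$pos < win[2], logical(1)))
      if (!clash) { placed <- TRUE; break }
    }
    if (!placed) next
    used[[length(used) + 1L]] <- list(chrom = fr$chrom, pos = gpos)
    cls <- sample(names(cfg$seed_class_mix), 1L, prob = cfg$seed_class_mix)
    arch <- if (cls == "seedless") 4L else sample(c(1L, 2L, 3L, 5L, 6L), 1L)
    prof <- archs[[arch]][seq_len(nchar(mir) - 1L)]
    # a site's label must be true of its sequence: the random backbone can by
    # chance contain a better seed motif (or, for seedless sites, any motif),
    # so redraw until the designed region classifies as planted
    grp <- function(x) ifelse(x %in% c("mm8", "mm7", "mm6"), "mismatch",
                       ifelse(x %in% c("bulge_target", "bulge_mirna"),
                              "bulge", ifelse(x == "none", "seedless", x)))
    for (attempt in 1:25) {
      d <- design_site(mir, prof, cls)
      got <- classify_seed(d$region, mir)$class
      if ((cls %in% c("8mer", "7mer-m8", "7mer-A1", "6mer") && got == cls) ||
          grp(got) == cls) {
        break
      }
    }
    strand <- fr$strand
    if (strand == "+") {
      lig <- gpos
      substr(chroms[[fr$chrom]], lig + 1L, lig + 75L) <- d$region
    } else {
      lig <- gpos + 74L
      substr(chroms[[fr$chrom]], gpos + 1L, gpos + 75L) <- revcomp(d$region)
    }
    sites[[length(sites) + 1L]] <- data.frame(
      site_id = sprintf("S%04d", length(sites) + 1L),
      mirna_id = catalog$mirna_id[mi], chrom = fr$chrom, strand = strand,
      lig_pos = lig, gene_id = fr$gene_id, region_label = lab,
      seed_class = cls, edit_pos = d$edit_pos,
      seed_offset = d$seed_offset, archetype = arch,
      stringsAsFactors = FALSE)
  }
  sites <- do.call(rbind, sites)

  # expression table (focal miRNA = most abundant, first catalogue entry)
  focal <- catalog$mirna_id[1L]
  class_group <- function(x) ifelse(x %in% c("8mer", "7mer-m8", "7mer-A1",
                                             "6mer"), "canonical", x)
  gene_fc <- stats::setNames(rep(0, length(unique(features$gene_id))),
                             unique(features$gene_id))
  foc_sites <- sites[sites$mirna_id == focal, , drop = FALSE]
  for (i in seq_len(nrow(foc_sites))) {
    g <- foc_sites$gene_id[i]
    gene_fc[g] <- gene_fc[g] +
      cfg$effect_by_class[[class_group(foc_sites$seed_class[i])]]
  }
  genes <- setdiff(unique(features$gene_id), catalog$mirna_id)
  expr <- do.call(rbind, lapply(genes, function(g) {
    np <- sample(2:3, 1L)
    data.frame(gene_id = g, probe_id = paste0(g, "_p", seq_len(np)),
               log2fc = gene_fc[[g]] + stats::rnorm(np, 0, cfg$expr_noise_sd),
               stringsAsFactors = FALSE)
  }))

  # sample sheet
  n_samp <- cfg$n_ligase + cfg$n_noligase
  idx <- unique_indices(n_samp, cfg$index_len)
  sheet <- data.frame(
    sample_id = sprintf("BR%02d", seq_len(n_samp)),
    index = idx,
    ligase_treated = rep(c(TRUE, FALSE), c(cfg$n_ligase, cfg$n_noligase)),
    species_tag = "primary", stringsAsFactors = FALSE)

  # reads
  reads <- sim_reads(cfg, sheet, catalog, chroms, foreign, sites, features)

  genome <- Biostrings::DNAStringSet(chroms)
  foreign_set <- Biostrings::DNAStringSet(foreign)
  annotation <- annotation_granges(features)
  truth <- list(reads = reads$truth, sites = sites,
                genes = data.frame(gene_id = names(gene_fc),
                                   true_log2fc = unname(gene_fc),
                                   stringsAsFactors = FALSE))
  out <- list(genome = genome, foreign_genome = foreign_set,
              annotation = annotation, annotation_df = features,
              catalog = catalog, sheet = sheet, reads = reads$reads,
              expression = expr, truth = truth, config = cfg)
  if (!is.null(out_dir)) write_experiment(out, out_dir)
  invisible(out)
}

unique_indices <- function(n, len) {
  repeat {
    idx <- unique(random_dna(4L * n, len))
    # prefix-free by equal length; just need n distinct
    if (length(idx) >= n) return(idx[seq_len(n)])
  }
}

remove_shared_kmers <- function(foreign, chroms, k = 20L) {
  prim <- unlist(lapply(chroms, function(s)
    substring(s, 1:(nchar(s) - k + 1L), k:nchar(s))), use.names = FALSE)
  prim <- unique(prim)
  f <- foreign[[1]]
  repeat {
    fk <- substring(f, 1:(nchar(f) - k + 1L), k:nchar(f))
    hit <- which(fk %in% prim)
    if (!length(hit)) break
    for (h in hit) {
      p <- h + (k %/% 2L)
      substr(f, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                        substr(f, p, p)), 1L)
    }
  }
  foreign[[1]] <- f
  foreign
}

# strand-aware transcript-orientation fragment starting at the ligation
# position (0-based genomic), length len
transcript_fragment <- function(chroms, chrom, strand, lig, len) {
  clen <- nchar(chroms[[chrom]])
  if (strand == "+") {
    end <- min(lig + len, clen)
    substr(chroms[[chrom]], lig + 1L, end)
  } else {
    start <- max(lig + 1L - len, 0L)
    revcomp(substr(chroms[[chrom]], start + 1L, lig + 1L))
  }
}

sim_reads <- function(cfg, sheet, catalog, chroms, foreign, sites, features) {
  n_samp <- nrow(sheet)
  per_sample <- round(cfg$reads_total / (1 + cfg$pcr_dup_rate /
                                           (1 - cfg$pcr_dup_rate))) %/% n_samp
  site_w <- stats::rgamma(nrow(sites), shape = 0.6)
  site_w <- site_w / sum(site_w)
  genic <- features[features$region_label %in%
                      c("five_prime_utr", "cds", "intron", "three_prime_utr",
                        "noncoding"), , drop = FALSE]
  seqs <- character(0); truth_rows <- vector("list", 0L)
  mk_chimera <- function(sample_id, orientation) {
    if (stats::runif(1) < cfg$contamination_frac) {
      flen <- sample(cfg$frag_len[1]:cfg$frag_len[2], 1L)
      fstart <- sample.int(nchar(foreign[[1]]) - flen, 1L)
      frag <- substr(foreign[[1]], fstart + 1L, fstart + flen)
      si <- sample.int(nrow(sites), 1L, prob = site_w)
      mi <- match(sites$mirna_id[si], catalog$mirna_id)
      type <- "contaminant"
      meta <- list(site_id = NA_character_, chrom = "chrF", strand = "+",
                   fstart = fstart)
    } else {
      si <- sample.int(nrow(sites), 1L, prob = site_w)
      mi <- match(sites$mirna_id[si], catalog$mirna_id)
      jit <- sample(c(0L, 0L, 0L, 1L, 2L, 4L), 1L)
      flen <- sample(cfg$frag_len[1]:cfg$frag_len[2], 1L)
      lig <- sites$lig_pos[si] + if (sites$strand[si] == "+") jit else -jit
      frag <- transcript_fragment(chroms, sites$chrom[si], sites$strand[si],
                                  lig, flen)
      type <- orientation
      fstart <- if (sites$strand[si] == "+") lig else lig + 1L - nchar(frag)
      meta <- list(site_id = sites$site_id[si], chrom = sites$chrom[si],
                   strand = sites$strand[si], fstart = fstart)
    }
    tr <- sample(as.integer(names(cfg$truncation_probs)), 1L,
                 prob = cfg$truncation_probs)
    mirseq <- catalog$seq[mi]
    mirseq <- substr(mirseq, 1L, nchar(mirseq) - tr)
    insert <- if (orientation == "miR_first") paste0(mirseq, frag)
              else paste0(frag, mirseq)
    list(insert = insert, type = type, mirna_id = catalog$mirna_id[mi],
         truncation = tr, meta = meta, flen = nchar(frag))
  }
  all_rows <- list()
  for (s in seq_len(n_samp)) {
    lig_on <- sheet$ligase_treated[s]
    f_first <- cfg$chimera_frac * (if (lig_on) 1 else 1 / cfg$ligase_ratio)
    f_last <- cfg$chimera_frac / cfg$mir_last_ratio
    n_first <- stats::rbinom(1L, per_sample, f_first)
    n_last <- stats::rbinom(1L, per_sample, f_last)
    n_mir <- round(per_sample * cfg$mirna_only_frac)
    n_bg <- per_sample - n_first - n_last - n_mir
    rows <- vector("list", per_sample)
    ri <- 0L
    for (i in seq_len(n_first)) {
      ch <- mk_chimera(sheet$sample_id[s], "miR_first")
      ri <- ri + 1L
      rows[[ri]] <- c(list(insert = ch$insert, sample = s, type = ch$type,
                           mirna_id = ch$mirna_id, truncation = ch$truncation,
                           orientation = "miR_first", flen = ch$flen), ch$meta)
    }
    for (i in seq_len(n_last)) {
      ch <- mk_chimera(sheet$sample_id[s], "miR_last")
      ri <- ri + 1L
      rows[[ri]] <- c(list(insert = ch$insert, sample = s, type = ch$type,
                           mirna_id = ch$mirna_id, truncation = ch$truncation,
                           orientation = "miR_last", flen = ch$flen), ch$meta)
    }
    for (i in seq_len(n_mir)) {
      mi <- sample.int(nrow(catalog), 1L)
      ri <- ri + 1L
      rows[[ri]] <- list(insert = catalog$seq[mi], sample = s,
                         type = "mirna_only", mirna_id = catalog$mirna_id[mi],
                         truncation = 0L, orientation = NA_character_,
                         flen = 0L, site_id = NA_character_,
                         chrom = NA_character_, strand = NA_character_,
                         fstart = NA_integer_)
    }
    for (i in seq_len(n_bg)) {
      ri <- ri + 1L
      if (stats::runif(1) < cfg$bg_pileup_frac && nrow(sites)) {
        si <- sample.int(nrow(sites), 1L, prob = site_w)
        off <- sample(-12:12, 1L)
        flen <- sample(26:36, 1L)
        lig <- sites$lig_pos[si] + if (sites$strand[si] == "+") off else -off
        frag <- transcript_fragment(chroms, sites$chrom[si],
                                    sites$strand[si], lig, flen)
        fstart <- if (sites$strand[si] == "+") lig else lig + 1L - nchar(frag)
        rows[[ri]] <- list(insert = frag, sample = s, type = "background",
                           mirna_id = NA_character_, truncation = 0L,
                           orientation = NA_character_, flen = nchar(frag),
                           site_id = sites$site_id[si],
                           chrom = sites$chrom[si], strand = sites$strand[si],
                           fstart = fstart)
      } else {
        fr <- genic[sample.int(nrow(genic), 1L), ]
        flen <- sample(26:36, 1L)
        fstart <- sample(seq(fr$start, max(fr$start, fr$end - flen)), 1L)
        frag <- transcript_fragment(chroms, fr$chrom, fr$strand,
                                    if (fr$strand == "+") fstart
                                    else fstart + flen - 1L, flen)
        rows[[ri]] <- list(insert = frag, sample = s, type = "background",
                           mirna_id = NA_character_, truncation = 0L,
                           orientation = NA_character_, flen = nchar(frag),
                           site_id = NA_character_, chrom = fr$chrom,
                           strand = fr$strand, fstart = fstart)
      }
    }
    all_rows <- c(all_rows, rows[seq_len(ri)])
  }
  truth <- do.call(rbind, lapply(all_rows, function(r)
    data.frame(sample_id = sheet$sample_id[r$sample], type = r$type,
               mirna_id = r$mirna_id, orientation = r$orientation,
               truncation = r$truncation, site_id = r$site_id,
               chrom = r$chrom, strand = r$strand, fstart = r$fstart,
               flen = r$flen, stringsAsFactors = FALSE)))
  inserts <- vapply(all_rows, function(r) r$insert, character(1))
  raw <- paste0(sheet$index[match(truth$sample_id, sheet$sample_id)],
                inserts, cfg$adapter)
  raw <- substr(raw, 1L, cfg$read_len)
  raw <- apply_errors(raw, cfg$error_rate)
  copies <- 1L + stats::rgeom(length(raw), prob = 1 - cfg$pcr_dup_rate)
  exp_idx <- rep(seq_along(raw), copies)
  ord <- sample(length(exp_idx))
  exp_idx <- exp_idx[ord]
  truth <- truth[exp_idx, , drop = FALSE]
  truth$read_id <- sprintf("r%07d", seq_along(exp_idx))
  rownames(truth) <- NULL
  reads <- new_seq_frame(truth$read_id, raw[exp_idx],
                         strrep("I", nchar(raw[exp_idx])))
  list(reads = reads, truth = truth)
}

write_experiment <- function(x, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_genome(x$genome, file.path(out_dir, "genome.fa"))
  write_genome(x$foreign_genome, file.path(out_dir, "foreign_genome.fa"))
  write_sequences(data.frame(id = x$catalog$mirna_id, seq = x$catalog$seq,
                             qual = NA),
                  file.path(out_dir, "mirnas.fa"), "fasta")
  write_sequences(x$reads, file.path(out_dir, "reads.fastq"), "fastq")
  wt <- function(df, f) utils::write.table(df, file.path(out_dir, f),
                                           sep = "\t", quote = FALSE,
                                           row.names = FALSE)
  wt(x$annotation_df, "annotation.tsv")
  wt(x$sheet, "sample_sheet.tsv")
  wt(x$expression, "expression.tsv")
  wt(x$truth$reads, "truth_reads.tsv")
  wt(x$truth$sites, "truth_sites.tsv")
  wt(x$truth$genes, "truth_genes.tsv")
  invisible(out_dir)
}

#' Sample binary pairing vectors from planted archetypes
#'
#' @param n number of rows.
#' @param flip_rate per-entry bit-flip noise (default 0.1).
#' @param rng_seed seed.
#' @param archetypes list of profiles (default [default_archetypes()]).
#' @param weights mixture weights over archetypes.
#' @return list(matrix, labels).
#' @export
simulate_pairing_matrix <- function(n, flip_rate = 0.1, rng_seed = 1L,
                                    archetypes = default_archetypes(),
                                    weights = NULL) {
  set.seed(rng_seed)
  k <- length(archetypes)
  if (is.null(weights)) weights <- rep(1 / k, k)
  labels <- sample.int(k, n, replace = TRUE, prob = weights)
  p <- length(archetypes[[1]])
  mat <- t(vapply(labels, function(l) {
    v <- archetypes[[l]]
    flip <- stats::runif(p) < flip_rate
    as.integer(xor(v == 1L, flip))
  }, integer(p)))
  colnames(mat) <- names(archetypes[[1]])
  rownames(mat) <- sprintf("I%06d", seq_len(n))
  list(matrix = mat, labels = labels)
}

#' Adjusted Rand index between two labelings
#' @param a,b integer/character vectors of equal length.
#' @return ARI in [-1, 1].
#' @export
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  exp_ij <- si * sj / n2
  (sij - exp_ij) / ((si + sj) / 2 - exp_ij)
}

#' Evaluate pipeline outputs against simulation ground truth
#'
#' @param detected chimera data.frame (read_id, mirna_id, orientation).
#' @param truth ground-truth list from [simulate_experiment()].
#' @param alignments optional aligned chimeras (read_id, chrom, start, strand).
#' @param seed_calls optional data.frame (site_id, predicted_class) after
#'   matching interactions to planted sites.
#' @param collapsed optional collapsed read table (id, member_ids) so that a
#'   detection on a duplicate-collapse representative counts for every copy.
#' @return list of per-stage precision/recall summaries.
#' @export
truth_eval <- function(detected, truth, alignments = NULL, seed_calls = NULL,
                       collapsed = NULL) {
  tr <- truth$reads
  expand <- function(ids) {
    if (is.null(collapsed) || !("member_ids" %in% names(collapsed))) {
      return(ids)
    }
    i <- match(ids, collapsed$id)
    mem <- collapsed$member_ids[i]
    mem[is.na(mem)] <- ids[is.na(mem)]
    unique(unlist(strsplit(mem, ",", fixed = TRUE)))
  }
  out <- list()
  for (ori in c("miR_first", "miR_last")) {
    pos <- tr$read_id[tr$type == ori]
    det <- expand(unique(detected$read_id[detected$orientation == ori]))
    tp <- sum(det %in% pos)
    out[[ori]] <- c(recall = tp / length(pos),
                    precision = if (length(det)) tp / length(det) else NA,
                    n_true = length(pos), n_detected = length(det))
  }
  neg <- tr$read_id[tr$type %in% c("background")]
  out$false_calls_from_nonmirna <-
    sum(expand(unique(detected$read_id)) %in% neg)
  if (!is.null(alignments)) {
    key <- match(alignments$read_id, tr$read_id)
    ok <- !is.na(key) & !is.na(tr$fstart[key]) &
      alignments$chrom == tr$chrom[key] &
      abs(alignments$start - tr$fstart[key]) <= 3L
    out$placement_accuracy <- mean(ok)
  }
  if (!is.null(seed_calls)) {
    grp <- function(x) ifelse(x %in% c("mm8", "mm7", "mm6"), "mismatch",
                       ifelse(x %in% c("bulge_target", "bulge_mirna"), "bulge",
                       ifelse(x == "none", "seedless", x)))
    out$seed_class_accuracy <- mean(grp(seed_calls$predicted_class) ==
                                      grp(seed_calls$true_class))
    out$seed_confusion <- table(truth = grp(seed_calls$true_class),
                                predicted = grp(seed_calls$predicted_class))
  }
  out
}
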