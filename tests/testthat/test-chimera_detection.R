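test_that("reverse mapping agrees with the exhaustive sliding-window oracle", {
  set.seed(21)
  catalog <- tiny_catalog(rand_seq(4, 22))
  reads <- character(220)
  # 120 random reads, 100 with a planted (possibly mutated) miRNA
  reads[1:120] <- rand_seq(120, 50)
  for (i in 121:220) {
    mir <- catalog$seq[sample.int(4, 1)]
    n_mut <- sample(0:3, 1)
    for (k in seq_len(n_mut)) {
      p <- sample(nchar(mir), 1)
      substr(mir, p, p) <- sample(c("A", "C", "G", "T"), 1)
    }
    fl <- rand_seq(1, 25)
    reads[i] <- paste0(substr(fl, 1, sample(0:3, 1)), mir, fl)
  }
  reads <- substr(reads, 1, 60)
  rdf <- data.frame(id = sprintf("r%03d", seq_along(reads)), seq = reads,
                    stringsAsFactors = FALSE)
  hits <- find_mirna_hits(rdf, catalog)
  for (i in seq_along(reads)) {
    expected <- oracle_scan_read(reads[i], catalog)
    got <- hits[hits$read_id == rdf$id[i], , drop = FALSE]
    if (is.null(expected)) {
      expect_equal(nrow(got), 0L, info = paste("read", i))
    } else {
      expect_setequal(got$mirna_id, unique(expected$mirna_id))
      expect_equal(sort(unique(got$mismatches)),
                   sort(unique(expected$mismatches)))
    }
  }
})

test_that("planted full-length miRNAs are recovered with exact spans", {
  set.seed(5)
  catalog <- tiny_catalog(rand_seq(3, 22))
  read <- paste0(catalog$seq[2], rand_seq(1, 30))
  rdf <- data.frame(id = "r1", seq = read, stringsAsFactors = FALSE)
  hits <- find_mirna_hits(rdf, catalog)
  expect_equal(hits$mirna_id, "mir02")
  expect_equal(hits$start, 1L)
  expect_equal(hits$end, 22L)
  expect_equal(hits$truncation_3p, 0L)
})

test_that("truncation mode records missing 3' bases and enforces the 12-nt floor", {
  set.seed(6)
  catalog <- tiny_catalog(rand_seq(1, 22))
  mir <- catalog$seq[1]
  # flank chosen so it cannot extend the apparent miRNA match
  flank <- paste(nonpairing_flank <- chartr("ACGT", "CAAC",
                                            substr(mir, 13, 32)), collapse = "")
  flank <- rand_seq(1, 30)
  if (substr(flank, 1, 1) == substr(mir, 13, 13)) {
    substr(flank, 1, 1) <- setdiff(c("A", "C", "G", "T"),
                                   substr(mir, 13, 13))[1]
  }
  read12 <- paste0(substr(mir, 1, 12), flank)
  rdf <- data.frame(id = "r1", seq = read12, stringsAsFactors = FALSE)
  expect_equal(nrow(find_mirna_hits(rdf, catalog)), 0L)  # full-length mode
  h <- find_mirna_hits(rdf, catalog, truncation = TRUE)
  expect_equal(h$truncation_3p, 10L)
  expect_equal(h$end - h$start + 1L, 12L)
  # an 11-nt prefix is below the floor
  read11 <- paste0(substr(mir, 1, 11), flank)
  if (substr(flank, 1, 1) == substr(mir, 12, 12)) {
    read11 <- paste0(substr(mir, 1, 11), "N", substr(flank, 2, nchar(flank)))
  }
  h11 <- find_mirna_hits(data.frame(id = "r1", seq = read11), catalog,
                         truncation = TRUE)
  expect_true(nrow(h11) == 0L || h11$end - h11$start + 1L >= 12L)
})

test_that("strict zero-mismatch hits are a subset of default hits", {
  set.seed(31)
  catalog <- tiny_catalog(rand_seq(5, 21))
  reads <- paste0(rand_seq(80, 3),
                  catalog$seq[sample.int(5, 80, replace = TRUE)],
                  rand_seq(80, 25))
  mut <- sample(80, 40)
  for (i in mut) {
    p <- sample(4:24, 1)
    substr(reads[i], p, p) <- sample(c("A", "C", "G", "T"), 1)
  }
  rdf <- data.frame(id = sprintf("r%03d", 1:80), seq = reads,
                    stringsAsFactors = FALSE)
  strict <- find_mirna_hits(rdf, catalog, seed_mismatch = 0L,
                            ext_mismatch = 0L)
  default <- find_mirna_hits(rdf, catalog)
  expect_true(all(strict$read_id %in% default$read_id))
})

test_that("tie resolution is deterministic and near-uniform", {
  # two miRNAs identical in sequence -> every hit is a two-way tie
  catalog <- tiny_catalog(rep(rand_seq(1, 22, seed = 8), 2),
                          ids = c("let7a", "let7c"))
  reads <- data.frame(id = sprintf("r%05d", 1:4000),
                      seq = paste0(catalog$seq[1], rand_seq(4000, 20)),
                      stringsAsFactors = FALSE)
  hits <- find_mirna_hits(reads, catalog)
  expect_true(all(hits$n_candidates == 2L))
  r1 <- resolve_ambiguous(hits, rng_seed = 99)
  r2 <- resolve_ambiguous(hits, rng_seed = 99)
  expect_identical(r1$mirna_id, r2$mirna_id)
  expect_equal(nrow(r1), 4000L)
  expect_identical(unique(r1$candidate_ids), "let7a,let7c")
  frac <- mean(r1$mirna_id == "let7a")
  expect_gt(frac, 0.48)  # binomial: 0.5 +- ~2.3 sd at n = 4000
  expect_lt(frac, 0.52)
  # single candidate is returned unchanged
  one <- hits[1, , drop = FALSE]; one$n_candidates <- 1L
  expect_identical(resolve_ambiguous(one, 1)$mirna_id, one$mirna_id)
})

test_that("flank extraction applies the 18-nt floor and both orientations", {
  set.seed(12)
  catalog <- tiny_catalog(rand_seq(1, 22))
  mir <- catalog$seq[1]
  mk <- function(five, three) {
    data.frame(id = "r1", seq = paste0(five, mir, three),
               stringsAsFactors = FALSE)
  }
  hit_for <- function(rdf) resolve_ambiguous(find_mirna_hits(rdf, catalog), 1)
  # 25-nt 3' flank -> one miR_first
  rdf <- mk("", rand_seq(1, 25))
  ch <- extract_flanks(rdf, hit_for(rdf))
  expect_equal(ch$orientation, "miR_first")
  expect_equal(nchar(ch$fragment), 25L)
  # 17-nt 3' flank -> nothing
  rdf <- mk("", rand_seq(1, 17))
  expect_equal(nrow(extract_flanks(rdf, hit_for(rdf))), 0L)
  # 20-nt 5' flank + 19-nt 3' flank -> one of each
  rdf <- mk(rand_seq(1, 20), rand_seq(1, 19))
  ch <- extract_flanks(rdf, hit_for(rdf))
  expect_setequal(ch$orientation, c("miR_first", "miR_last"))
  # re-inserting the fragment at its span reconstructs the read
  h <- hit_for(rdf)
  first <- ch[ch$orientation == "miR_first", ]
  last <- ch[ch$orientation == "miR_last", ]
  expect_identical(paste0(last$fragment,
                          substr(rdf$seq, h$start, h$end),
                          first$fragment), rdf$seq)
})

test_that("target mapping finds unique best placements and rejects multimappers", {
  set.seed(44)
  genome <- Biostrings::DNAStringSet(c(chr1 = rand_seq(1, 30000),
                                       chr2 = rand_seq(1, 20000)))
  n <- 120
  chrom <- sample(names(genome), n, replace = TRUE)
  start <- integer(n); strand <- sample(c("+", "-"), n, replace = TRUE)
  frags <- character(n)
  for (i in seq_len(n)) {
    len <- sample(20:40, 1)
    start[i] <- sample(length(genome[[chrom[i]]]) - len, 1)
    s <- as.character(genome[[chrom[i]]][(start[i] + 1):(start[i] + len)])
    nmut <- sample(0:2, 1)
    for (k in seq_len(nmut)) {
      p <- sample(len, 1)
      substr(s, p, p) <- sample(c("A", "C", "G", "T"), 1)
    }
    frags[i] <- if (strand[i] == "+") s else chimeraCLIP::revcomp(s)
  }
  chim <- data.frame(read_id = sprintf("r%03d", 1:n), sample_id = "s1",
                     mirna_id = "m", orientation = "miR_first",
                     fragment = frags, stringsAsFactors = FALSE)
  res <- map_target(chim, genome, max_mismatches = 2L)
  aln <- res$alignments
  ok <- merge(aln, data.frame(read_id = chim$read_id, true_chrom = chrom,
                              true_start = start, true_strand = strand))
  agree <- ok$chrom == ok$true_chrom & ok$start == ok$true_start &
    ok$strand == ok$true_strand
  expect_gte(mean(agree), 0.95)
  expect_gte(nrow(aln) / n, 0.95)
  expect_true(all(aln$unique))

  # exact duplicate at two loci is rejected as multi-mapped
  dup <- as.character(genome[[1]][101:130])
  g2 <- genome
  g2[[2]] <- Biostrings::DNAString(paste0(as.character(g2[[2]]), dup))
  res2 <- map_target(data.frame(read_id = "d1", sample_id = "s1",
                                mirna_id = "m", orientation = "miR_first",
                                fragment = dup, stringsAsFactors = FALSE),
                     g2)
  expect_equal(res2$rejected$reason, "multimapped")
})

test_that("miRNA-locus filtering matches a naive interval intersection", {
  set.seed(55)
  n <- 200
  aln <- data.frame(read_id = sprintf("r%03d", 1:n),
                    chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
                    start = sample(0:5000, n, replace = TRUE),
                    stringsAsFactors = FALSE)
  aln$end <- aln$start + sample(20:40, n, replace = TRUE)
  loci <- data.frame(chrom = sample(c("chr1", "chr2"), 30, replace = TRUE),
                     start = sample(0:5000, 30, replace = TRUE))
  loci$end <- loci$start + 70
  ann <- annotation_granges(data.frame(chrom = loci$chrom, start = loci$start,
                                       end = loci$end, strand = "+",
                                       region_label = "mirna_locus",
                                       gene_id = "m", transcript_id = "m"))
  kept <- filter_mirna_loci(aln, ann)
  expect_equal(nrow(aln) - nrow(kept), sum(oracle_overlaps(aln, loci) > 0))
  # half-open boundary: alignment beginning exactly at locus end is kept
  edge <- data.frame(read_id = "e", chrom = loci$chrom[1],
                     start = loci$end[1], end = loci$end[1] + 20)
  expect_equal(nrow(filter_mirna_loci(edge, ann)), 1L)
  inside <- data.frame(read_id = "i", chrom = loci$chrom[1],
                       start = loci$start[1] + 5, end = loci$start[1] + 25)
  expect_equal(nrow(filter_mirna_loci(inside, ann)), 0L)
})

test_that("false-ligation estimation recovers planted contamination", {
  set.seed(66)
  prim <- Biostrings::DNAStringSet(c(chr1 = rand_seq(1, 30000)))
  fore <- Biostrings::DNAStringSet(c(chrF = rand_seq(1, 20000)))
  pick <- function(g, n) {
    vapply(seq_len(n), function(i) {
      len <- sample(24:36, 1)
      st <- sample(length(g[[1]]) - len, 1)
      as.character(g[[1]][(st + 1):(st + len)])
    }, character(1))
  }
  mk <- function(frags) data.frame(read_id = seq_along(frags),
                                   sample_id = "s1", fragment = frags,
                                   stringsAsFactors = FALSE)
  # all-primary input: rate equals cross-mapping background (~0 here)
  r0 <- estimate_false_ligation_rate(mk(pick(prim, 400)), prim, fore)
  expect_lte(r0$rate, 0.005)
  # 5% planted foreign among 2000
  frags <- c(pick(prim, 1900), pick(fore, 100))
  r5 <- estimate_false_ligation_rate(mk(frags), prim, fore)
  expect_gt(r5$rate, 0.03)
  expect_lt(r5$rate, 0.07)
  # all-foreign input
  rall <- estimate_false_ligation_rate(mk(pick(fore, 100)), prim, fore)
  expect_equal(rall$rate, 1.0)
  expect_error(estimate_false_ligation_rate(mk(pick(prim, 5)), prim, prim),
               "identical")
})

test_that("chimera rate summaries report fractions and ligase enrichment", {
  sheet <- data.frame(sample_id = c("a", "b"), index = c("AA", "CC"),
                      ligase_treated = c(TRUE, FALSE), species_tag = "x")
  ch <- data.frame(read_id = sprintf("r%03d", 1:110),
                   sample_id = rep(c("a", "b"), c(100, 10)),
                   orientation = "miR_first", stringsAsFactors = FALSE)
  res <- chimera_rate_summary(ch, c(a = 10000, b = 10000), sheet)
  expect_equal(res$per_sample$miR_first_frac, c(0.01, 0.001))
  expect_equal(unname(res$ligase_enrichment["miR_first"]), 10)
  expect_warning(
    chimera_rate_summary(ch, c(a = 10000, b = 10000, z = 0), sheet),
    "zero-read")
})
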