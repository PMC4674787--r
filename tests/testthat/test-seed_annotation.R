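seed_site <- function(mir, p_lo = 2L, p_hi = 8L) {
  chimeraCLIP::revcomp(substr(mir, p_lo, p_hi))
}
embed <- function(core, left = 10, right = 10, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste0(rand_seq(1, left), core, rand_seq(1, right))
}
# avoid accidental extra seed homology around a planted core
clean_embed <- function(mir, core, seed = 1) {
  set.seed(seed)
  repeat {
    reg <- embed(core, 12, 12)
    pre <- sub(core, strrep("N", nchar(core)), reg, fixed = TRUE)
    if (is.null(canonical_match(pre, mir)) &&
        is.null(variant_match(pre, mir))) return(reg)
  }
}

test_that("canonical seed classes follow their definitions", {
  mir <- "TGGAATGTAAAGAAGTATGTAT"  # miR-1 mature sequence (DNA letters)
  s78 <- seed_site(mir)            # revcomp of positions 2-8
  s27 <- seed_site(mir, 2, 7)
  r8 <- clean_embed(mir, paste0(s78, "A"), 1)
  expect_equal(canonical_match(r8, mir)$class, "8mer")
  r7m8 <- clean_embed(mir, paste0(s78, "C"), 2)
  expect_equal(canonical_match(r7m8, mir)$class, "7mer-m8")
  bad8 <- chimeraCLIP:::nonpairing_base(substr(mir, 8, 8))
  r7a1 <- clean_embed(mir, paste0(bad8, s27, "A"), 3)
  expect_equal(canonical_match(r7a1, mir)$class, "7mer-A1")
  r6 <- clean_embed(mir, paste0(bad8, s27, "G"), 4)
  expect_equal(canonical_match(r6, mir)$class, "6mer")
  expect_null(canonical_match(strrep("A", 40), mir))
  # offset is the 0-based match start
  off <- canonical_match(r8, mir)$offset
  expect_equal(substr(r8, off + 1, off + 7), s78)
})

test_that("canonical classification matches an exhaustive sliding scan", {
  set.seed(101)
  mirs <- rand_seq(5, 22)
  # independent oracle: direct string comparison per offset, WC only
  oracle <- function(region, mir) {
    s78 <- seed_site(mir); s27 <- seed_site(mir, 2, 7)
    n <- nchar(region)
    for (cls in c("8mer", "7mer-m8", "7mer-A1", "6mer")) {
      for (o in 0:(n - 8)) {
        w <- substr(region, o + 1, o + 7)
        w6 <- substr(region, o + 1, o + 6)
        a7 <- substr(region, o + 8, o + 8)
        a6 <- substr(region, o + 7, o + 7)
        hit <- switch(cls,
                      "8mer" = w == s78 && a7 == "A",
                      "7mer-m8" = w == s78,
                      "7mer-A1" = w6 == s27 && a6 == "A",
                      "6mer" = w6 == s27)
        if (isTRUE(hit)) return(cls)
      }
    }
    "none"
  }
  for (i in 1:400) {
    mir <- mirs[(i %% 5) + 1]
    region <- if (i %% 3 == 0) {
      embed(seed_site(mir, 2, sample(7:8, 1)), sample(5:20, 1), 15)
    } else rand_seq(1, 40)
    got <- canonical_match(region, mir, allow_wobble = FALSE)
    expect_equal(if (is.null(got)) "none" else got$class,
                 oracle(region, mir), info = paste("case", i))
  }
})

test_that("every single-edit neighbour of a canonical site is classified correctly", {
  set.seed(202)
  mir <- rand_seq(1, 22)
  s78 <- seed_site(mir)
  pad_l <- rand_seq(1, 10); pad_r <- rand_seq(1, 10)
  # substitutions, insertions and deletions: the classifier must return a
  # the enumerate-all-edits oracle, with the maximal number of seed pairs;
  # canonical classification keeps priority when the edit leaves an intact
  # canonical sub-site (a bulge between positions 7 and 8 preserves a 6mer),
  # and repeat-containing seeds can make several parses equally valid
  check_against_oracle <- function(region) {
    got <- classify_seed(region, mir)
    canon <- canonical_match(region, mir)
    if (!is.null(canon)) {
      expect_equal(got$class, canon$class)
      return(invisible(NULL))
    }
    oracle <- oracle_variant_set(region, mir)
    expect_false(is.null(oracle))
    expect_true(any(oracle$class == got$class &
                      oracle$pos == got$edit_position),
                info = region)
    best_pairs <- max(oracle$n_pairs)
    got_pairs <- oracle$n_pairs[match(got$class, oracle$class)]
    expect_equal(got_pairs, best_pairs, info = region)
  }
  for (bi in 1:7) {
    p <- 9 - bi  # miRNA position opposed by block index bi
    core <- s78
    substr(core, bi, bi) <- chimeraCLIP:::nonpairing_base(substr(mir, p, p))
    check_against_oracle(paste0(pad_l, core, "G", pad_r))
    check_against_oracle(paste0(pad_l, core, "A", pad_r))
  }
  for (p in 2:7) {
    cut <- 8 - p
    core <- paste0(substr(s78, 1, cut), "A", substr(s78, cut + 1, 7))
    check_against_oracle(paste0(pad_l, core, "G", pad_r))
  }
  for (p in 3:7) {
    bi <- 9 - p
    core <- paste0(substr(s78, 1, bi - 1), substr(s78, bi + 1, 7))
    region <- paste0(pad_l, core, "G", pad_r)
    got <- classify_seed(region, mir)
    canon <- canonical_match(region, mir)
    oracle <- oracle_variant_set(region, mir)
    if (is.null(canon)) {
      expect_true(any(oracle$class == got$class &
                        oracle$pos == got$edit_position),
                  info = paste("pos", p))
    } else {
      expect_equal(got$class, canon$class, info = paste("pos", p))
    }
  }
  # random regions: classifier and oracle agree on existence and best class
  set.seed(203)
  for (i in 1:60) {
    region <- rand_seq(1, 30)
    got <- classify_seed(region, mir)
    canon <- canonical_match(region, mir)
    oracle <- oracle_variant_set(region, mir)
    if (!is.null(canon)) {
      expect_equal(got$class, canon$class)
    } else if (is.null(oracle)) {
      expect_equal(got$class, "none", info = region)
    } else {
      expect_true(any(oracle$class == got$class &
                        oracle$pos == got$edit_position), info = region)
      expect_equal(max(oracle$n_pairs[oracle$class == got$class]),
                   max(oracle$n_pairs), info = region)
    }
  }
})

test_that("the planted miR-124-style G bulge between positions 5 and 6 is recovered", {
  mir <- "TAAGGCACGCGGTGAATGCCAA"
  s78 <- seed_site(mir)
  core <- paste0(substr(s78, 1, 3), "G", substr(s78, 4, 7))  # between 5 and 6
  region <- clean_embed(mir, paste0(core, "C"), 7)
  got <- classify_seed(region, mir)
  expect_equal(got$class, "bulge_target")
  expect_equal(got$edit_position, 5L)
  expect_equal(got$inserted_base, "G")
})

test_that("canonical classes are nested and take priority over variants", {
  set.seed(33)
  for (i in 1:30) {
    mir <- rand_seq(1, 21)
    region <- clean_embed(mir, paste0(seed_site(mir), "A"), seed = 300 + i)
    got <- classify_seed(region, mir)
    expect_equal(got$class, "8mer")
    expect_true(is.na(got$edit_position))
    # the same region also contains the lower classes by nesting
    expect_false(is.null(canonical_match(region, mir)))
  }
})

test_that("G:U wobbles keep the canonical class and are demotable", {
  set.seed(44)
  repeat {
    mir <- rand_seq(1, 22)
    wob_pos <- which(strsplit(substr(mir, 2, 8), "")[[1]] %in% c("G", "T")) + 1
    if (length(wob_pos)) break
  }
  p <- wob_pos[1]
  core <- seed_site(mir)
  bi <- 9 - p
  wb <- if (substr(mir, p, p) == "G") "T" else "G"
  substr(core, bi, bi) <- wb
  region <- clean_embed(mir, paste0(core, "A"), 9)
  got <- canonical_match(region, mir, allow_wobble = TRUE)
  expect_equal(got$class, "8mer")
  expect_true(p %in% got$wobble_positions)
  strictv <- classify_seed(region, mir, allow_wobble = FALSE)
  expect_true(strictv$class %in% c("mm8", "mm7"))
})

test_that("seed-position CDF recovers planted junction-proximal enrichment", {
  set.seed(55)
  catalog <- tiny_catalog(rand_seq(6, 22))
  n <- 300
  mirna_id <- sample(catalog$mirna_id, n, replace = TRUE)
  mir <- catalog$seq[match(mirna_id, catalog$mirna_id)]
  planted <- runif(n) < 0.6
  region <- character(n)
  for (i in seq_len(n)) {
    region[i] <- if (planted[i]) {
      off <- sample(5:60, 1)
      r <- rand_seq(1, 75)
      paste0(substr(r, 1, off), seed_site(mir[i]),
             substr(r, off + 8, 75))
    } else rand_seq(1, 75)
  }
  res <- seed_position_cdf(data.frame(mirna_id = mirna_id,
                                      target_region = region,
                                      stringsAsFactors = FALSE), catalog)
  expect_gt(res$downstream_frac, 0.55)
  expect_gt(res$enrichment, 0.4)     # planted 60% over random background
  expect_lt(res$shuffled_frac, 0.25)
  # all matches planted at one offset -> CDF steps there
  one <- data.frame(mirna_id = catalog$mirna_id[1],
                    target_region = vapply(1:20, function(i) {
                      r <- rand_seq(1, 75)
                      paste0(substr(r, 1, 10), seed_site(catalog$seq[1]),
                             substr(r, 18, 75))
                    }, character(1)), stringsAsFactors = FALSE)
  r1 <- seed_position_cdf(one, catalog)
  expect_true(all(r1$offsets[!is.na(r1$offsets)] == 10))
  expect_error(seed_position_cdf(one[0, ], catalog), "no chimeras")
})

test_that("positional preference profiles normalise and flag exclusions", {
  ann <- data.frame(
    interaction_id = sprintf("I%03d", 1:120),
    mirna_id = rep(c("mA", "mB"), c(110, 10)),
    class = "bulge_target",
    offset = 5L,
    edit_position = c(rep(5L, 110), rep(3L, 10)),
    inserted_base = "G", wobble_positions = "",
    bulged_8mer = FALSE, stringsAsFactors = FALSE)
  res <- positional_preference_profile(ann, min_sites = 50)
  expect_equal(unname(res$profiles$target_bulge["mA", "5"]), 1.0)
  expect_equal(sum(res$profiles$target_bulge["mA", ]), 1.0)
  expect_true("mB" %in% res$excluded)
  # uniform planted mismatches spread ~ 1/7 each
  set.seed(9)
  ann2 <- data.frame(interaction_id = sprintf("J%04d", 1:1400),
                     mirna_id = "mC", class = "mm7", offset = 5L,
                     edit_position = sample(2:8, 1400, replace = TRUE),
                     inserted_base = NA, wobble_positions = "",
                     bulged_8mer = FALSE, stringsAsFactors = FALSE)
  res2 <- positional_preference_profile(ann2, min_sites = 50)
  expect_true(all(abs(res2$profiles$mismatch["mC", ] - 1 / 7) < 0.04))
})
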