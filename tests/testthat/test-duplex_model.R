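test_that("a miRNA folded against its exact reverse complement forms a full helix", {
  set.seed(1)
  mir <- rand_seq(1, 22)
  region <- embed <- paste0(rand_seq(1, 20),
                            chimeraCLIP::revcomp(substr(mir, 2, 22)),
                            rand_seq(1, 20))
  s <- hybrid_mfe(mir, region)
  expect_lt(s$mfe, 0)
  expect_true(all(s$pairing == 1L))
  expect_named(s$pairing, as.character(2:22))
  # partners strictly increase in 3'-anchored target coordinates
  expect_true(all(diff(s$partners_3p[s$pairing == 1L]) > 0))
})

test_that("no complementarity yields the empty structure at mfe 0", {
  s <- hybrid_mfe(paste(rep("A", 22), collapse = ""),
                  paste(rep("A", 60), collapse = ""))
  expect_equal(s$mfe, 0)
  expect_true(all(s$pairing == 0L))
  expect_equal(seed_aux_counts(s), c(seed_bp = 0L, aux_bp = 0L))
})

test_that("the DP optimum equals brute-force enumeration on random short pairs", {
  params <- default_energy_params()
  params$max_bulge <- 6L   # keeps both routes on the same structure space
  set.seed(7)
  n_agree <- 0L
  for (i in 1:120) {
    mir <- paste0("N", rand_seq(1, 8))  # position 1 is trimmed before folding
    substr(mir, 1, 1) <- "A"
    tar <- rand_seq(1, 9)
    got <- hybrid_mfe(mir, tar, params)
    want <- oracle_duplex_best(substr(mir, 2, 9), tar, params)
    expect_equal(got$mfe, min(0, want), tolerance = 1e-9,
                 info = paste(mir, tar))
    n_agree <- n_agree + 1L
  }
  expect_gte(n_agree, 100L)
})

test_that("a unit-cost energy table turns the DP into a longest noncrossing match solver", {
  params <- default_energy_params()
  params$stack[] <- 0
  params$pair_bonus <- -1     # -1 per pair, nothing else
  params$bulge_open <- 0; params$bulge_ext <- 0
  params$interior_open <- 0; params$interior_ext <- 0
  params$terminal_au <- 0
  params$max_bulge <- 15L
  # independent combinatorial oracle: longest antiparallel noncrossing chain
  # of pairable positions with gaps bounded by max_bulge, via its own DP over
  # (i, j) = "last pair", counting pairs instead of energies
  oracle_longest <- function(mir, tar, maxb) {
    m <- nchar(mir); n <- nchar(tar)
    ok <- function(a, b) paste0(a, b) %in% c("AT", "TA", "CG", "GC",
                                             "GT", "TG")
    mb <- strsplit(mir, "")[[1]]; tb <- strsplit(tar, "")[[1]]
    best <- matrix(-Inf, m, n)
    for (i in seq_len(m)) for (j in seq_len(n)) {
      if (!ok(mb[i], tb[j])) next
      b <- 1
      for (i1 in seq_len(i - 1)) for (j1 in seq(j + 1, n)) {
        if (j + 1 > n) break
        if (i - i1 - 1 > maxb || j1 - j - 1 > maxb) next
        if (is.finite(best[i1, j1])) b <- max(b, best[i1, j1] + 1)
      }
      best[i, j] <- b
    }
    if (all(!is.finite(best))) 0 else max(best[is.finite(best)])
  }
  set.seed(17)
  for (i in 1:40) {
    mir <- rand_seq(1, sample(8:12, 1))
    tar <- rand_seq(1, sample(8:14, 1))
    got <- hybrid_mfe(paste0("A", mir), tar, params)
    expect_equal(-got$mfe, oracle_longest(mir, tar, params$max_bulge),
                 info = paste(mir, tar))
  }
})

test_that("stacking energies accumulate as the sum over helix steps", {
  params <- default_energy_params()
  mir <- "ACUGGC"  # RNA input accepted; pos 1 trimmed -> CTGGC
  s <- hybrid_mfe(mir, "GCCAG", params)
  # hand-summed: CG/UA, UA/GC, GC/GC, GC/CG steps, no terminal CG penalty
  want <- params$stack["CG", "UA"] + params$stack["UA", "GC"] +
    params$stack["GC", "GC"] + params$stack["GC", "CG"]
  expect_equal(s$mfe, want)
})

test_that("forced constraints never improve the optimum and always pair the seed", {
  params <- default_energy_params()
  set.seed(23)
  n_pairs <- 250
  for (i in seq_len(n_pairs)) {
    mir <- rand_seq(1, 22)
    region <- rand_seq(1, 75)
    # plant a canonical site so the anchored constraint is satisfiable
    off <- sample(5:55, 1)
    site <- chimeraCLIP::revcomp(substr(mir, 2, 8))
    region <- paste0(substr(region, 1, off), site, "A",
                     substr(region, off + 9, 75))
    free <- hybrid_mfe(mir, region, params)
    forced <- hybrid_mfe(mir, region, params,
                         list(type = "seed_forced", positions = 2:8,
                              offset = off))
    expect_gte(forced$mfe + 1e-9, free$mfe)
    expect_true(all(forced$pairing[as.character(2:8)] == 1L))
    expect_equal(unname(forced$partners[as.character(2:8)]),
                 off + (8 - (2:8)) + 1)
    f34 <- hybrid_mfe(mir, region, params, list(type = "f34"))
    f56 <- hybrid_mfe(mir, region, params, list(type = "f56"))
    expect_gte(f34$mfe + 1e-9, free$mfe)
    expect_gte(f56$mfe + 1e-9, free$mfe)
    if (f34$feasible) {
      expect_true(all(f34$pairing[as.character(3:4)] == 1L))
    }
  }
})

test_that("constraint choice follows the seed annotation", {
  sm8 <- list(class = "8mer", offset = 10L)
  expect_equal(choose_constraint(sm8)[[1]]$type, "seed_forced")
  expect_equal(choose_constraint(sm8)[[1]]$positions, 2:8)
  sm6 <- list(class = "6mer", offset = 3L)
  expect_equal(choose_constraint(sm6)[[1]]$positions, 2:7)
  smm <- list(class = "mm7", offset = 5L)
  specs <- choose_constraint(smm)
  expect_equal(vapply(specs, `[[`, character(1), "type"), c("f34", "f56"))
  expect_equal(choose_constraint(NULL)[[1]]$type, "none")
  expect_equal(choose_constraint(list(class = "none"))[[1]]$type, "none")
})

test_that("structures and partner vectors stay mutually consistent", {
  set.seed(31)
  for (i in 1:50) {
    mir <- rand_seq(1, 22)
    s <- hybrid_mfe(mir, rand_seq(1, 75))
    expect_identical(s$pairing > 0L, s$partners > 0L)
    on <- s$partners[s$partners > 0L]
    expect_true(all(diff(on) < 0))  # antiparallel in region coordinates
    if (length(on)) {
      expect_equal(seed_aux_counts(s)[["seed_bp"]] +
                     seed_aux_counts(s)[["aux_bp"]], sum(s$pairing))
    }
  }
})

test_that("seed/auxiliary counts split at position 8", {
  set.seed(3)
  mir <- rand_seq(1, 22)
  region <- paste0(rand_seq(1, 10), chimeraCLIP::revcomp(substr(mir, 2, 22)),
                   rand_seq(1, 10))
  s <- hybrid_mfe(mir, region)
  expect_equal(seed_aux_counts(s), c(seed_bp = 7L, aux_bp = 14L))
})

test_that("constrained folding reaches full seed concordance on canonical sites", {
  set.seed(41)
  catalog <- tiny_catalog(rand_seq(4, 22))
  n <- 40
  ints <- data.frame(interaction_id = sprintf("I%03d", 1:n),
                     mirna_id = sample(catalog$mirna_id, n, replace = TRUE),
                     stringsAsFactors = FALSE)
  mir <- catalog$seq[match(ints$mirna_id, catalog$mirna_id)]
  ints$target_region <- vapply(seq_len(n), function(i) {
    off <- sample(5:55, 1)
    r <- rand_seq(1, 75)
    paste0(substr(r, 1, off), chimeraCLIP::revcomp(substr(mir[i], 2, 8)),
           "A", substr(r, off + 9, 75))
  }, character(1))
  ann <- classify_seeds(ints, catalog)
  expect_true(all(ann$class %in% c("8mer", "7mer-m8", "7mer-A1", "6mer")))
  dup <- predict_duplexes(ints, catalog, seed_ann = ann)
  conc <- seed_concordance(dup$structures, ann)
  expect_equal(conc$overall, 1.0)
  # unconstrained concordance cannot exceed the constrained one
  dup_free <- predict_duplexes(ints, catalog, seed_ann = NULL)
  conc_free <- seed_concordance(dup_free$structures, ann)
  expect_lte(conc_free$overall, conc$overall)
  expect_error(seed_concordance(list(), ann), "empty")
})

test_that("shuffled miRNA assignment raises duplex energies on planted data", {
  set.seed(47)
  catalog <- tiny_catalog(rand_seq(8, 22))
  n <- 120
  ints <- data.frame(interaction_id = sprintf("I%03d", 1:n),
                     mirna_id = sample(catalog$mirna_id, n, replace = TRUE),
                     stringsAsFactors = FALSE)
  mir <- catalog$seq[match(ints$mirna_id, catalog$mirna_id)]
  ints$target_region <- vapply(seq_len(n), function(i) {
    paste0(rand_seq(1, 20), chimeraCLIP::revcomp(substr(mir[i], 2, 16)),
           rand_seq(1, 30))
  }, character(1))
  res <- shuffle_assignment(ints, catalog, rng_seed = 5)
  expect_lt(mean(res$mfe_true), mean(res$mfe_shuffled))
  expect_lt(res$p_value, 0.01)
  expect_true(all(res$permutation != seq_len(n)))
  # degenerate single-miRNA input: shuffling changes nothing
  ints1 <- ints; ints1$mirna_id <- catalog$mirna_id[1]
  r1 <- shuffle_assignment(ints1, catalog, rng_seed = 5)
  expect_equal(r1$p_value, 1)
  expect_error(shuffle_assignment(ints[1, ], catalog), "at least 2")
})

test_that("derangements have no fixed points across many seeds", {
  for (seed in 1:400) {
    p <- chimeraCLIP:::derangement(sample(2:12, 1), seed)
    expect_true(all(p != seq_along(p)))
    expect_equal(sort(p), seq_along(p))
  }
})

test_that("energy parameter files round-trip and are validated", {
  params <- default_energy_params()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_energy_params(params, f)
  back <- read_energy_params(f)
  expect_equal(back$stack, params$stack)
  expect_equal(back$max_bulge, params$max_bulge)
  bad <- params; bad$stack[1, 1] <- 0.5
  expect_error(chimeraCLIP:::validate_energy_params(bad), "negative")
  expect_error(hybrid_mfe(rand_seq(1, 22), rand_seq(1, 101)), "100")
})
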