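# Intermolecular miRNA-target duplex prediction under forced-seed constraints,
# binary pairing profiles and the shuffled-assignment null.

PAIR_NAMES <- c("AU", "UA", "CG", "GC", "GU", "UG")

#' Default duplex energy parameters
#'
#' A nearest-neighbour stacking table (kcal/mol) approximating Turner-style
#' RNA values, with affine bulge and interior-loop penalties, a bound on
#' unpaired stretch length, and a terminal penalty for closing A:U / G:U
#' pairs. Stacks are indexed 5'->3' on the guide strand. Values are a
#' documented, swappable interface (see [read_energy_params()]); exact
#' agreement with any external folding tool is not claimed.
#'
#' @return list with stack matrix, bulge_open, bulge_ext, interior_open,
#'   interior_ext, max_bulge, terminal_au.
#' @export
default_energy_params <- function() {
  stack <- matrix(c(
    # AU     UA     CG     GC     GU     UG
    -0.9,  -1.1,  -2.2,  -2.1,  -0.6,  -1.4,   # AU
    -1.3,  -0.9,  -2.4,  -2.1,  -1.0,  -1.3,   # UA
    -2.1,  -2.1,  -3.3,  -2.4,  -1.4,  -2.1,   # CG
    -2.4,  -2.2,  -3.4,  -3.3,  -1.5,  -2.5,   # GC
    -1.3,  -1.4,  -2.5,  -2.1,  -0.5,  -0.2,   # GU
    -1.0,  -0.6,  -1.5,  -1.4,  -0.2,  -0.5),  # UG
    nrow = 6, byrow = TRUE, dimnames = list(PAIR_NAMES, PAIR_NAMES))
  list(stack = stack, bulge_open = 3.8, bulge_ext = 0.4,
       interior_open = 1.2, interior_ext = 0.4, max_bulge = 15L,
       terminal_au = 0.45, pair_bonus = 0)
}

validate_energy_params <- function(params) {
  stopifnot(is.matrix(params$stack), all(dim(params$stack) == c(6L, 6L)))
  if (any(params$stack >= 0)) stop("all stacking energies must be negative")
  pen <- c(params$bulge_open, params$bulge_ext, params$interior_open,
           params$interior_ext, params$terminal_au)
  if (anyNA(pen) || any(pen < 0)) {
    stop("loop and terminal penalties must be non-negative")
  }
  if ((params$pair_bonus %||% 0) > 0) stop("pair_bonus must be <= 0")
  params
}

#' Read duplex energy parameters from TSV
#'
#' Rows are either \code{stack <pair1> <pair2> <value>} (pairs among AU, UA,
#' CG, GC, GU, UG) or \code{param <name> <value>}.
#'
#' @param path TSV path.
#' @return parameter list as [default_energy_params()].
#' @export
read_energy_params <- function(path) {
  df <- utils::read.delim(path, header = FALSE,
                          col.names = c("type", "a", "b", "value"),
                          stringsAsFactors = FALSE)
  params <- default_energy_params()
  st <- df[df$type == "stack", , drop = FALSE]
  params$stack[cbind(match(st$a, PAIR_NAMES), match(st$b, PAIR_NAMES))] <-
    st$value
  pr <- df[df$type == "param", , drop = FALSE]
  for (i in seq_len(nrow(pr))) params[[pr$a[i]]] <- as.numeric(pr$value[i])
  params$max_bulge <- as.integer(params$max_bulge)
  validate_energy_params(params)
}

#' Write duplex energy parameters to TSV
#' @param params parameter list.
#' @param path output path.
#' @export
write_energy_params <- function(params, path) {
  lines <- character(0)
  for (a in PAIR_NAMES) for (b in PAIR_NAMES) {
    lines <- c(lines, paste("stack", a, b, params$stack[a, b], sep = "\t"))
  }
  for (nm in c("bulge_open", "bulge_ext", "interior_open", "interior_ext",
               "max_bulge", "terminal_au", "pair_bonus")) {
    lines <- c(lines, paste("param", nm, ".", params[[nm]], sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Predict the constrained intermolecular duplex MFE structure
#'
#' The first miRNA nucleotide is trimmed before folding (it does not pair in
#' AGO). The returned pairing vector covers miRNA positions 2..L (1 = paired
#' by Watson-Crick or G:U, 0 = unpaired); partners are target indices counted
#' from the region 3' end so that they increase with miRNA position. In
#' unconstrained mode an empty structure with mfe 0 is returned when no
#' negative-energy duplex exists; with forced pairs the constrained optimum is
#' returned regardless of sign (an infeasible constraint yields an empty
#' structure flagged \code{feasible = FALSE}).
#'
#' @param mirna mature miRNA sequence (position 1 included; RNA or DNA).
#' @param region target region sequence, at most 100 nt.
#' @param params energy parameters (see [default_energy_params()]).
#' @param constraint NULL, or a spec from [choose_constraint()]: list(type =
#'   "seed_forced", positions, offset) or list(type = "f34"/"f56").
#' @return object of class \code{duplex_structure}: list(mfe, pairing (named
#'   by positions 2..L), partners, partners_3p, constraint_used, feasible).
#' @export
hybrid_mfe <- function(mirna, region, params = default_energy_params(),
                       constraint = NULL) {
  region <- norm_dna(region)
  mirna <- norm_dna(mirna)
  if (nchar(region) > 100L) stop("target region longer than 100 nt")
  mir <- substr(mirna, 2L, nchar(mirna))   # trim position 1
  m <- nchar(mir)
  n <- nchar(region)
  required <- integer(0)
  anchor <- integer(m)
  ctype <- "none"
  if (!is.null(constraint) && constraint$type != "none") {
    ctype <- constraint$type
    if (ctype == "seed_forced") {
      pos <- constraint$positions          # miRNA coordinates, e.g. 2:8
      p_hi <- max(pos)
      o <- constraint$offset               # 0-based match start in region
      required <- pos - 1L                 # trimmed coordinates
      anchor[pos - 1L] <- o + (p_hi - pos) + 1L
      if (any(anchor[pos - 1L] < 1L) || any(anchor[pos - 1L] > n)) {
        stop("seed anchor outside target region")
      }
    } else if (ctype == "f34") {
      required <- c(2L, 3L)                # miRNA positions 3 and 4
    } else if (ctype == "f56") {
      required <- c(4L, 5L)                # miRNA positions 5 and 6
    } else stop("unknown constraint type: ", ctype)
  }
  res <- duplex_dp_cpp(mir, region, params$stack, params$bulge_open,
                       params$bulge_ext, params$interior_open,
                       params$interior_ext, params$max_bulge,
                       params$terminal_au, params$pair_bonus %||% 0,
                       required, anchor)
  pairing <- res$pairing
  mfe <- res$mfe
  feasible <- res$feasible
  if (ctype == "none" && (!feasible || mfe >= 0)) {
    pairing <- integer(m)
    mfe <- 0
    feasible <- TRUE
  }
  if (!feasible) {
    pairing <- integer(m)
    mfe <- 0
  }
  pos_names <- as.character(seq(2L, nchar(mirna)))
  partners <- stats::setNames(as.integer(pairing), pos_names)
  structure(list(mfe = mfe,
                 pairing = stats::setNames(as.integer(partners > 0L),
                                           pos_names),
                 partners = partners,
                 partners_3p = stats::setNames(
                   ifelse(partners > 0L, n - partners + 1L, 0L), pos_names),
                 constraint_used = ctype, feasible = feasible),
            class = "duplex_structure")
}

#' @export
print.duplex_structure <- function(x, ...) {
  cat("miRNA-target duplex: mfe =", round(x$mfe, 2), "kcal/mol,",
      sum(x$pairing), "paired positions, constraint =", x$constraint_used,
      "\n")
  cat(paste0(ifelse(x$pairing > 0, "|", "."), collapse = ""), "\n")
  invisible(x)
}

#' Choose the folding constraint implied by a seed annotation
#'
#' Canonical sites force the matched seed helix at its annotated target
#' offset (8mer and 7mer-m8: positions 2-8; 7mer-A1 and 6mer: positions 2-7;
#' 5mer: positions 2-6). Mismatch and bulge sites yield two constrained runs
#' (positions 3-4 and positions 5-6 forced paired); the lower-energy structure
#' is kept. Regions without seed homology fold unconstrained.
#'
#' @param seed_match list/row from [classify_seed()] (fields class, offset),
#'   or NULL.
#' @return list of constraint specs (one or two).
#' @export
choose_constraint <- function(seed_match) {
  if (is.null(seed_match) || seed_match$class == "none") {
    return(list(list(type = "none")))
  }
  cls <- seed_match$class
  if (cls %in% c("8mer", "7mer-m8", "7mer-A1", "6mer", "5mer")) {
    pos <- switch(cls, "8mer" = 2:8, "7mer-m8" = 2:8,
                  "7mer-A1" = 2:7, "6mer" = 2:7, "5mer" = 2:6)
    return(list(list(type = "seed_forced", positions = pos,
                     offset = seed_match$offset)))
  }
  list(list(type = "f34"), list(type = "f56"))
}

#' Fold one interaction with its annotation-derived constraint
#'
#' @param mirna,region sequences.
#' @param seed_match annotation from [classify_seed()] or NULL.
#' @param params energy parameters.
#' @return \code{duplex_structure} (lower-energy winner for two-run cases).
#' @export
hybrid_mfe_auto <- function(mirna, region, seed_match = NULL,
                            params = default_energy_params()) {
  specs <- choose_constraint(seed_match)
  runs <- lapply(specs, function(sp) hybrid_mfe(mirna, region, params, sp))
  feas <- vapply(runs, function(r) r$feasible, logical(1))
  if (!any(feas)) return(runs[[1L]])
  runs <- runs[feas]
  runs[[which.min(vapply(runs, function(r) r$mfe, numeric(1)))]]
}

#' Fold a set of interactions
#'
#' @param interactions data.frame with interaction_id, mirna_id,
#'   target_region.
#' @param catalog miRNA catalogue.
#' @param seed_ann optional seed annotations from [classify_seeds()] (enables
#'   forced-seed constraints).
#' @param params energy parameters.
#' @return list(structures, table) where table has interaction_id, mfe,
#'   constraint, pairing string over positions 2..L.
#' @export
predict_duplexes <- function(interactions, catalog, seed_ann = NULL,
                             params = default_energy_params()) {
  mir <- catalog$seq[match(interactions$mirna_id, catalog$mirna_id)]
  structures <- vector("list", nrow(interactions))
  for (i in seq_len(nrow(interactions))) {
    sm <- NULL
    if (!is.null(seed_ann)) {
      j <- match(interactions$interaction_id[i], seed_ann$interaction_id)
      if (!is.na(j)) sm <- as.list(seed_ann[j, , drop = FALSE])
    }
    structures[[i]] <- hybrid_mfe_auto(mir[i], interactions$target_region[i],
                                       sm, params)
  }
  tab <- data.frame(
    interaction_id = interactions$interaction_id,
    mirna_id = interactions$mirna_id,
    mfe = vapply(structures, function(s) s$mfe, numeric(1)),
    constraint = vapply(structures, function(s) s$constraint_used,
                        character(1)),
    pairing = vapply(structures, function(s)
      paste(s$pairing, collapse = ""), character(1)),
    stringsAsFactors = FALSE)
  list(structures = structures, table = tab)
}

#' Seed and auxiliary base-pair counts of a structure
#'
#' @param structure \code{duplex_structure}.
#' @return c(seed_bp, aux_bp): paired counts in positions 2-8 and 9..L.
#' @export
seed_aux_counts <- function(structure) {
  pos <- as.integer(names(structure$pairing))
  c(seed_bp = sum(structure$pairing[pos <= 8L]),
    aux_bp = sum(structure$pairing[pos > 8L]))
}

#' Concordance between predicted structures and annotated seed matches
#'
#' A structure is concordant when every position of the annotated canonical
#' class is paired to its matched target base. Reported overall and per class.
#'
#' @param structures list of \code{duplex_structure} (order matching
#'   \code{seed_ann}).
#' @param seed_ann seed annotations (canonical rows are evaluated).
#' @param region_len lengths of the folded regions (for 3'-anchored partner
#'   conversion); a single value is recycled.
#' @return list(overall, per_class, n).
#' @export
seed_concordance <- function(structures, seed_ann, region_len = 75L) {
  if (!length(structures)) stop("empty structure set")
  region_len <- rep_len(region_len, length(structures))
  canon <- which(seed_ann$class %in% CANONICAL_CLASSES)
  if (!length(canon)) stop("no canonical seed matches to evaluate")
  conc <- logical(length(canon))
  for (k in seq_along(canon)) {
    i <- canon[k]
    cls <- seed_ann$class[i]
    pos <- if (cls %in% c("8mer", "7mer-m8")) 2:8 else 2:7
    p_hi <- max(pos)
    want <- seed_ann$offset[i] + (p_hi - pos) + 1L
    got <- structures[[i]]$partners[as.character(pos)]
    conc[k] <- all(got == want)
  }
  per_class <- tapply(conc, seed_ann$class[canon], mean)
  list(overall = mean(conc), per_class = per_class, n = length(canon))
}

#' Shuffled-assignment null for duplex energies
#'
#' Each target region is re-assigned the miRNA of a different interaction
#' (derangement) and unconstrained MFEs of true and shuffled pairs are
#' compared by a two-tailed t-test.
#'
#' @param interactions data.frame with mirna_id, target_region.
#' @param catalog miRNA catalogue.
#' @param params energy parameters.
#' @param rng_seed permutation seed.
#' @return list(mfe_true, mfe_shuffled, p_value, t, permutation).
#' @export
shuffle_assignment <- function(interactions, catalog,
                               params = default_energy_params(),
                               rng_seed = 1L) {
  n <- nrow(interactions)
  if (n < 2L) stop("shuffling requires at least 2 interactions")
  mir <- catalog$seq[match(interactions$mirna_id, catalog$mirna_id)]
  perm <- derangement(n, rng_seed)
  mfe_true <- vapply(seq_len(n), function(i)
    hybrid_mfe(mir[i], interactions$target_region[i], params)$mfe, numeric(1))
  mfe_shuf <- vapply(seq_len(n), function(i)
    hybrid_mfe(mir[perm[i]], interactions$target_region[i], params)$mfe,
    numeric(1))
  if (stats::sd(mfe_true) < 1e-12 && stats::sd(mfe_shuf) < 1e-12) {
    # degenerate case, e.g. a single miRNA shared by all interactions: the
    # shuffle is a no-op and there is no evidence of a difference
    return(list(mfe_true = mfe_true, mfe_shuffled = mfe_shuf, p_value = 1,
                t = 0, permutation = perm))
  }
  tt <- stats::t.test(mfe_true, mfe_shuf, alternative = "two.sided")
  list(mfe_true = mfe_true, mfe_shuffled = mfe_shuf,
       p_value = tt$p.value, t = unname(tt$statistic), permutation = perm)
}
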