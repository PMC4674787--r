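# k-means clustering of binary pairing profiles into binding classes,
# per-miRNA Fisher enrichment and the k sweep.

#' Assemble the binary structure matrix
#'
#' Rows are interactions, columns miRNA positions 2..Lmax; positions beyond a
#' shorter miRNA's length are NA (explicit absent marker) and are excluded
#' from clustering via a column mask.
#'
#' @param duplexes result of [predict_duplexes()] (or its \code{table}).
#' @return integer matrix with rownames = interaction ids.
#' @export
structure_matrix <- function(duplexes) {
  tab <- if (is.list(duplexes) && !is.null(duplexes$table)) duplexes$table
         else duplexes
  vecs <- strsplit(tab$pairing, "")
  lmax <- max(lengths(vecs))
  mat <- t(vapply(vecs, function(v)
    c(as.integer(v), rep(NA_integer_, lmax - length(v))), integer(lmax)))
  rownames(mat) <- tab$interaction_id
  colnames(mat) <- as.character(seq(2L, lmax + 1L))
  mat
}

kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(0, k, ncol(x))
  i <- sample.int(n, 1L)
  centers[1L, ] <- x[i, ]
  d2 <- rowSums((x - rep(centers[1L, ], each = n))^2)
  for (j in 2:k) {
    if (all(d2 == 0)) i <- sample.int(n, 1L)
    else i <- sample.int(n, 1L, prob = d2)
    centers[j, ] <- x[i, ]
    d2 <- pmin(d2, rowSums((x - rep(centers[j, ], each = n))^2))
  }
  centers
}

#' Cluster pairing profiles into binding classes
#'
#' Euclidean k-means (equivalent to Hamming distance on binary rows, up to
#' scale) with k-means++ style seeding, best of \code{restarts} runs by
#' within-class sum of squares, deterministic for a given seed. Classes are
#' relabelled by descending mean seed-region (positions 2-8) pairing so labels
#' are stable across runs.
#'
#' @param mat structure matrix from [structure_matrix()].
#' @param k number of classes (>= 2, <= rows).
#' @param rng_seed integer seed.
#' @param restarts number of random restarts (default 50).
#' @param warm_start optional matrix of initial centers (masked columns) used
#'   as one extra restart.
#' @return object of class \code{binding_class_model}.
#' @export
kmeans_structures <- function(mat, k, rng_seed = 1L, restarts = 50L,
                              warm_start = NULL) {
  if (k < 2L) stop("k must be >= 2")
  if (k > nrow(mat)) stop("k exceeds the number of interactions")
  mask <- colSums(is.na(mat)) == 0L
  x <- mat[, mask, drop = FALSE]
  storage.mode(x) <- "double"
  set.seed(rng_seed)
  best <- NULL
  inits <- c(lapply(seq_len(restarts), function(r) kmeanspp_init(x, k)),
             if (!is.null(warm_start)) list(warm_start))
  for (centers in inits) {
    centers <- centers + stats::runif(length(centers), -1e-9, 1e-9)
    km <- tryCatch(
      suppressWarnings(stats::kmeans(x, centers = centers, iter.max = 100L,
                                     algorithm = "Lloyd")),
      error = function(e) NULL)  # e.g. an emptied cluster; skip this restart
    if (is.null(km)) next
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  if (is.null(best)) stop("k-means failed for all restarts")
  seed_cols <- intersect(colnames(x), as.character(2:8))
  seed_mean <- rowMeans(best$centers[, seed_cols, drop = FALSE])
  relab <- order(seed_mean, decreasing = TRUE)
  new_label <- match(seq_len(k), relab)
  assignments <- new_label[best$cluster]
  names(assignments) <- rownames(mat)
  centroids <- best$centers[relab, , drop = FALSE]
  rownames(centroids) <- seq_len(k)
  structure(list(k = k, centroids = centroids, assignments = assignments,
                 inertia = best$tot.withinss, rng_seed = rng_seed,
                 restarts = restarts, mask = mask),
            class = "binding_class_model")
}

#' @export
print.binding_class_model <- function(x, ...) {
  cat("binding-class model: k =", x$k, ", n =", length(x$assignments),
      ", inertia =", round(x$inertia, 1), "\n")
  print(table(class = x$assignments))
  invisible(x)
}

#' Assign new pairing profiles to the nearest binding class
#' @param object \code{binding_class_model}.
#' @param newdata structure matrix.
#' @param ... unused.
#' @export
predict.binding_class_model <- function(object, newdata, ...) {
  x <- newdata[, object$mask, drop = FALSE]
  d <- vapply(seq_len(object$k), function(j)
    rowSums((x - rep(object$centroids[j, ], each = nrow(x)))^2), numeric(nrow(x)))
  max.col(-d)
}

#' Sweep k and report inertia and mean silhouette
#'
#' Inertia is guaranteed non-increasing in k by warm-starting each k with the
#' previous solution's centroids plus the row farthest from its centroid.
#' The choice of k is left to the user.
#'
#' @param mat structure matrix.
#' @param k_range candidate k values (default 3:12).
#' @param rng_seed seed.
#' @param restarts restarts per k (default 10).
#' @param silhouette_max_n subsample size for the silhouette computation.
#' @return data.frame(k, inertia, mean_silhouette).
#' @export
sweep_k <- function(mat, k_range = 3:12, rng_seed = 1L, restarts = 10L,
                    silhouette_max_n = 2000L) {
  mask <- colSums(is.na(mat)) == 0L
  x <- mat[, mask, drop = FALSE]
  storage.mode(x) <- "double"
  out <- data.frame(k = k_range, inertia = NA_real_,
                    mean_silhouette = NA_real_)
  prev <- NULL
  set.seed(rng_seed)
  sil_idx <- if (nrow(x) > silhouette_max_n)
    sort(sample.int(nrow(x), silhouette_max_n)) else seq_len(nrow(x))
  dmat <- stats::dist(x[sil_idx, , drop = FALSE])
  for (r in seq_along(k_range)) {
    k <- k_range[r]
    warm <- NULL
    if (!is.null(prev)) {
      cen <- prev$centroids
      far <- which.max(rowSums((x - cen[prev$assignments, , drop = FALSE])^2))
      warm <- rbind(cen, x[far, ])
      if (nrow(warm) > k) warm <- warm[seq_len(k), , drop = FALSE]
    }
    mod <- kmeans_structures(mat, k, rng_seed = rng_seed + r,
                             restarts = restarts, warm_start = warm)
    out$inertia[r] <- mod$inertia
    cl <- mod$assignments[sil_idx]
    if (length(unique(cl)) > 1L && requireNamespace("cluster", quietly = TRUE)) {
      sil <- cluster::silhouette(as.integer(cl), dmat)
      out$mean_silhouette[r] <- mean(sil[, "sil_width"])
    }
    prev <- mod
  }
  out
}

#' Per-miRNA enrichment in binding classes (Fisher's exact test)
#'
#' For every miRNA with at least \code{min_sites} interactions and every
#' class, a two-sided Fisher exact test on the 2x2 table (miRNA-in-class,
#' miRNA-not-in-class, others-in-class, others-not-in-class); direction from
#' the odds ratio. No multiple-testing correction by default, matching a
#' fixed significance threshold; Benjamini-Hochberg optional.
#'
#' @param model \code{binding_class_model}.
#' @param mirna_ids miRNA id per interaction (same order as the clustered
#'   matrix rows).
#' @param min_sites minimum interactions per tested miRNA (default 50).
#' @param alpha significance threshold (default 1e-3).
#' @param correct "none" (default) or "BH".
#' @return list(table, summary) where summary gives the fraction of tested
#'   miRNAs significant in at least one class.
#' @export
mirna_class_enrichment <- function(model, mirna_ids, min_sites = 50L,
                                   alpha = 1e-3, correct = c("none", "BH")) {
  correct <- match.arg(correct)
  cl <- model$assignments
  stopifnot(length(mirna_ids) == length(cl))
  tot <- table(mirna_ids)
  tested <- names(tot)[tot >= min_sites]
  rows <- list()
  n_all <- length(cl)
  for (m in tested) {
    in_m <- mirna_ids == m
    for (g in seq_len(model$k)) {
      in_g <- cl == g
      a <- sum(in_m & in_g); b <- sum(in_m & !in_g)
      cc <- sum(!in_m & in_g); d <- n_all - a - b - cc
      ft <- stats::fisher.test(matrix(c(a, b, cc, d), 2L, byrow = TRUE))
      rows[[length(rows) + 1L]] <- data.frame(
        mirna_id = m, class = g, a = a, b = b, c = cc, d = d,
        odds_ratio = unname(ft$estimate), p_two_sided = ft$p.value,
        direction = if (unname(ft$estimate) >= 1) "enriched" else "depleted",
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  if (is.null(tab)) {
    return(list(table = NULL, summary = c(n_tested = 0, frac_significant = NA)))
  }
  p_use <- if (correct == "BH") stats::p.adjust(tab$p_two_sided, "BH")
           else tab$p_two_sided
  tab$significant <- p_use < alpha
  sig_mirnas <- unique(tab$mirna_id[tab$significant])
  list(table = tab,
       summary = c(n_tested = length(tested),
                   frac_significant = length(sig_mirnas) / length(tested)))
}
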