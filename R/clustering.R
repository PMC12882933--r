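#' Euclidean distances between the rows of a pair matrix
#'
#' Treats each letter's row of the (symmetric) dissimilarity matrix as a
#' 26-coordinate profile and computes Euclidean distances between profiles,
#' mirroring the common practice of handing the full square matrix to a
#' generic distance routine. By default the diagonal entries participate as
#' coordinates; `include_diagonal = FALSE` drops, for each pair (i, j), the
#' coordinates i and j (whose diagonal/self entries are not comparable
#' across rows).
#'
#' @param m A symmetric `pair_matrix`.
#' @param include_diagonal Keep the self-coordinates (default TRUE).
#' @return A [stats::dist] object over the letters.
#' @export
row_distances <- function(m, include_diagonal = TRUE) {
  v <- unclass(m)
  if (anyNA(v)) stop("missing values in matrix")
  if (include_diagonal) return(stats::dist(v))
  n <- nrow(v)
  D <- matrix(0, n, n, dimnames = dimnames(v))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      keep <- setdiff(seq_len(n), c(i, j))
      D[i, j] <- D[j, i] <- sqrt(sum((v[i, keep] - v[j, keep])^2))
    }
  }
  stats::as.dist(D)
}

ward_method <- function(variant = c("squared", "classic")) {
  switch(match.arg(variant), squared = "ward.D2", classic = "ward.D")
}

#' Ward hierarchical clustering of letters
#'
#' Agglomerative clustering under Ward's minimum-variance criterion. The
#' default `"squared"` variant applies the Lance-Williams update to squared
#' distances and reports square-rooted merge heights (`hclust` method
#' `ward.D2`, the form advocated by Murtagh & Legendre); `"classic"` is the
#' historical `ward.D` update on the distances as given.
#'
#' @param d A [stats::dist] object (e.g. from [row_distances()]) or a
#'   symmetric `pair_matrix` (then converted via [row_distances()]).
#' @param variant `"squared"` (default) or `"classic"`.
#' @return An [stats::hclust] tree over the letters.
#' @export
ward_dendrogram <- function(d, variant = c("squared", "classic")) {
  if (inherits(d, "pair_matrix")) d <- row_distances(d)
  stopifnot(inherits(d, "dist"))
  stats::hclust(d, method = ward_method(variant))
}

#' Cophenetic correlation of a dendrogram against a reference
#'
#' Pearson correlation, over all letter pairs, between the dendrogram's
#' cophenetic (merge-height) distances and a reference: either a `dist`
#' object (typically the row-distance object the tree was built from -
#' the standard `cor(cophenetic(hc), d)` usage) or a symmetric
#' `pair_matrix`, whose off-diagonal entries are used.
#'
#' @param dendrogram An [stats::hclust] tree.
#' @param reference A `dist` or symmetric `pair_matrix` over the same
#'   labels.
#' @return Pearson correlation over the 325 letter pairs.
#' @export
cophenetic_correlation <- function(dendrogram, reference) {
  coph <- stats::cophenetic(dendrogram)
  if (inherits(reference, "pair_matrix") || is.matrix(reference)) {
    if (!identical(rownames(reference), dendrogram$labels)) {
      stop("labels of reference and dendrogram differ")
    }
    ref <- stats::as.dist(unclass(reference))
  } else {
    stopifnot(inherits(reference, "dist"))
    if (!identical(attr(reference, "Labels"), dendrogram$labels)) {
      stop("labels of reference and dendrogram differ")
    }
    ref <- reference
  }
  stats::cor(as.vector(coph), as.vector(ref))
}

#' Cut a dendrogram into k groups
#'
#' @param dendrogram An [stats::hclust] tree.
#' @param k Number of groups, 1..n leaves.
#' @return A named integer vector of group memberships.
#' @export
cut_partition <- function(dendrogram, k) {
  n <- length(dendrogram$labels)
  if (length(k) != 1L || k < 1 || k > n) stop("invalid k")
  stats::cutree(dendrogram, k = k)
}

# leaf sets of the 25 internal nodes of an hclust tree, as canonical keys
node_leaf_sets <- function(hc) {
  n <- length(hc$labels)
  sets <- vector("list", n - 1L)
  for (i in seq_len(n - 1L)) {
    m <- hc$merge[i, ]
    left <- if (m[1] < 0) -m[1] else sets[[m[1]]]
    right <- if (m[2] < 0) -m[2] else sets[[m[2]]]
    sets[[i]] <- c(left, right)
  }
  lapply(sets, sort)
}

node_keys <- function(hc) {
  vapply(node_leaf_sets(hc), paste, "", collapse = ".")
}

#' Multiscale bootstrap AU values for cluster stability
#'
#' Approximately-unbiased (AU) support for each internal node of the Ward
#' tree, via multiscale bootstrap: the 26 coordinate columns of the
#' row-profile representation are resampled with replacement at sizes
#' `round(26 * r)` for each scale `r`; at every scale the proportion of
#' replicate trees containing each reference node (its bootstrap
#' probability BP_r) is recorded; the probit-transformed BP values are fit
#' by weighted least squares to `z(r) = v * sqrt(r) + c / sqrt(r)`; and
#' `AU = 1 - pnorm(v - c)`. With the single scale `{1}` the AU estimate
#' collapses back towards the naive bootstrap proportion.
#'
#' @param m A symmetric `pair_matrix`.
#' @param scales Scale multipliers (default `seq(0.5, 1.4, 0.1)`).
#' @param B Bootstrap replicates per scale (>= 100).
#' @param seed Integer seed driving all replicates.
#' @param variant Ward variant, see [ward_dendrogram()].
#' @param include_diagonal Passed to [row_distances()].
#' @return A list of class `"cluster_stability"`: `table` (one row per
#'   internal node: `node`, `members`, `bp` at scale 1 or the nearest
#'   scale, `au`), the reference `dendrogram`, `scales`, `B`, `seed`.
#'   Nodes never observed at any scale get `au = 0` and are flagged.
#' @export
multiscale_bootstrap_au <- function(m, scales = seq(0.5, 1.4, by = 0.1),
                                    B = 1000, seed = NULL,
                                    variant = c("squared", "classic"),
                                    include_diagonal = TRUE) {
  stopifnot(B >= 100, length(scales) >= 1, all(scales > 0))
  variant <- match.arg(variant)
  v <- unclass(m)
  n <- nrow(v)
  method <- ward_method(variant)

  # replicates always use plain row distances: once columns are resampled
  # the "self" coordinate is no longer identifiable, so the diagonal flag
  # only affects the reference tree
  ref <- ward_dendrogram(row_distances(m, include_diagonal), variant)
  keys <- node_keys(ref)
  sets <- node_leaf_sets(ref)

  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }

  counts <- matrix(0L, length(keys), length(scales))
  for (s in seq_along(scales)) {
    nprime <- max(3L, round(n * scales[s]))
    for (b in seq_len(B)) {
      cols <- sample.int(n, nprime, replace = TRUE)
      hb <- stats::hclust(stats::dist(v[, cols, drop = FALSE]), method = method)
      counts[, s] <- counts[, s] + as.integer(keys %in% node_keys(hb))
    }
  }
  bp <- counts / B

  au <- numeric(length(keys))
  flagged <- logical(length(keys))
  for (i in seq_along(keys)) {
    if (all(counts[i, ] == 0L)) {
      au[i] <- 0
      flagged[i] <- TRUE
      next
    }
    if (all(counts[i, ] == B)) {
      # present in every replicate at every scale: the probit fit is
      # degenerate at the boundary, so support is reported as certain
      au[i] <- 1
      next
    }
    p <- pmin(pmax(bp[i, ], 0.5 / B), 1 - 0.5 / B)
    z <- stats::qnorm(1 - p)
    if (length(scales) < 2L) {
      # v and c are not separately identifiable from one scale; at r = 1
      # the model collapses to z = v + c and AU reduces to the naive BP
      au[i] <- p[1]
      next
    }
    w <- B * stats::dnorm(z)^2 / (p * (1 - p)) # binomial delta-method weights
    X <- cbind(sqrt(scales), 1 / sqrt(scales))
    fit <- stats::lm.wfit(X, z, w)
    au[i] <- 1 - stats::pnorm(fit$coefficients[1] - fit$coefficients[2])
  }

  s1 <- which.min(abs(scales - 1))
  tab <- data.frame(
    node = seq_along(keys),
    members = vapply(sets, function(ix) paste(ref$labels[ix], collapse = ""),
                     ""),
    bp = bp[, s1],
    au = au,
    never_seen = flagged,
    stringsAsFactors = FALSE
  )
  structure(list(table = tab, dendrogram = ref, scales = scales, B = B,
                 seed = seed),
            class = "cluster_stability")
}

#' @export
print.cluster_stability <- function(x, ...) {
  cat(sprintf("multiscale bootstrap: B = %d per scale, %d scales\n",
              x$B, length(x$scales)))
  print(x$table[order(-x$table$au), ], row.names = FALSE)
  invisible(x)
}

#' Export a symmetric matrix as a weighted similarity edge list
#'
#' One edge per unordered letter pair, with similarity defined as the
#' reciprocal (default) or negation of the dissimilarity, for use in
#' external network-visualization tools.
#'
#' @param m A symmetric `pair_matrix`.
#' @param path Optional output path; when given, a CSV with a `# weight:`
#'   convention header is written.
#' @param weight `"reciprocal"` or `"negation"`.
#' @return A data frame `from, to, weight` (invisibly when `path` given).
#' @export
export_similarity_edges <- function(m, path = NULL,
                                    weight = c("reciprocal", "negation")) {
  weight <- match.arg(weight)
  v <- unclass(m)
  idx <- which(upper.tri(v), arr.ind = TRUE)
  w <- v[upper.tri(v)]
  w <- if (weight == "reciprocal") 1 / w else -w
  edges <- data.frame(from = rownames(v)[idx[, 1]],
                      to = colnames(v)[idx[, 2]],
                      weight = w, stringsAsFactors = FALSE)
  if (!is.null(path)) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# weight: %s of dissimilarity", weight), con)
    utils::write.csv(edges, con, row.names = FALSE, quote = FALSE)
    return(invisible(edges))
  }
  edges
}
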