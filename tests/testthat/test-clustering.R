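test_that("row_distances is Euclidean over row profiles", {
  m <- rbind(a = c(0, 0, 0), b = c(3, 4, 0), c = c(0, 0, 0))
  colnames(m) <- c("a", "b", "c")
  d <- as.matrix(row_distances(structure(m, class = c("pair_matrix",
                                                      "matrix"))))
  expect_equal(d["a", "b"], 5) # 3-4-5 triangle
  expect_equal(d["a", "c"], 0) # identical rows
  # triangle inequality on a random symmetric matrix
  set.seed(31)
  v <- matrix(runif(676), 26)
  v <- (v + t(v)) / 2
  dimnames(v) <- list(letters, letters)
  D <- as.matrix(row_distances(pair_matrix(v, "dissimilarity")))
  ok <- TRUE
  for (k in 1:26) ok <- ok && all(D <= outer(D[, k], D[k, ], "+") + 1e-12)
  expect_true(ok)
  expect_error(row_distances(pair_matrix(matrix(c(NA, runif(675)), 26),
                                         "dissimilarity")), "missing")
})

test_that("ward_dendrogram merges nearest clusters first", {
  D <- matrix(c(0, 1, 10, 1, 0, 10, 10, 10, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  hc <- ward_dendrogram(as.dist(D))
  expect_identical(sort(hc$merge[1, ]), c(-2L, -1L)) # {A,B} first
})

test_that("both Ward variants match a brute-force Lance-Williams oracle", {
  set.seed(99)
  for (rep in 1:8) {
    x <- matrix(rnorm(6 * 4), 6)
    rownames(x) <- letters[1:6]
    d <- dist(x)
    for (variant in c("squared", "classic")) {
      hc <- ward_dendrogram(d, variant)
      bf <- brute_force_ward(d, variant)
      expect_equal(hc$height, bf$height, tolerance = 1e-8)
      # same merge structure up to hclust's row ordering: compare the
      # multiset of merged leaf sets
      sets <- function(merge, labs) {
        out <- vector("list", nrow(merge))
        for (i in seq_len(nrow(merge))) {
          grab <- function(v) if (v < 0) labs[-v] else out[[v]]
          out[[i]] <- sort(c(grab(merge[i, 1]), grab(merge[i, 2])))
        }
        sort(vapply(out, paste, "", collapse = ""))
      }
      expect_identical(sets(hc$merge, hc$labels),
                       sets(bf$merge, rownames(x)))
    }
  }
})

test_that("merge heights never invert and cophenetic distances are ultrametric", {
  set.seed(12)
  for (rep in 1:5) {
    v <- matrix(runif(676, 0.5, 1.5), 26)
    v <- (v + t(v)) / 2
    dimnames(v) <- list(letters, letters)
    for (variant in c("squared", "classic")) {
      hc <- ward_dendrogram(row_distances(pair_matrix(v, "dissimilarity")),
                            variant)
      expect_true(all(diff(hc$height) >= -1e-10))
      C <- as.matrix(cophenetic(hc))
      # ultrametric: every triangle's two largest sides are equal
      for (k in 1:26) {
        expect_true(all(C <= pmax(outer(C[, k], rep(1, 26)),
                                  outer(rep(1, 26), C[k, ])) + 1e-10))
      }
    }
  }
})

test_that("cophenetic_correlation accepts both reference forms", {
  m <- braille_fixture("rt")
  d <- row_distances(m)
  hc <- ward_dendrogram(d)
  self <- stats::cophenetic(hc)
  expect_equal(cophenetic_correlation(hc, self), 1)
  expect_type(cophenetic_correlation(hc, m), "double")
  # 4-leaf hand example: two tight pairs far apart
  x <- rbind(a = c(0, 0), b = c(0, 1), c = c(10, 0), d = c(10, 1))
  h4 <- ward_dendrogram(dist(x), "classic")
  C <- as.matrix(stats::cophenetic(h4))
  expect_equal(C["a", "b"], 1)
  expect_equal(C["c", "d"], 1)
  expect_equal(C["a", "c"], C["b", "d"]) # joined at the root
  bad <- stats::hclust(dist(matrix(rnorm(8), 4)), "ward.D2")
  expect_error(cophenetic_correlation(bad, m), "labels")
})

test_that("cut_partition yields nested refinements", {
  hc <- ward_dendrogram(row_distances(braille_fixture("rt")))
  expect_identical(unname(cut_partition(hc, 1)), rep(1L, 26))
  expect_identical(sort(unname(cut_partition(hc, 26))), 1:26)
  expect_error(cut_partition(hc, 0), "invalid k")
  for (k in 1:25) {
    pk <- cut_partition(hc, k)
    pk1 <- cut_partition(hc, k + 1)
    # every k+1 block sits inside one k block
    expect_true(all(tapply(pk, pk1, function(x) length(unique(x))) == 1))
  }
})

test_that("AU values saturate for well-separated planted blocks", {
  n <- 10
  blocks <- rep(1:2, each = n / 2)
  v <- matrix(0.2, n, n) + 1 * outer(blocks, blocks, "!=")
  set.seed(3)
  v <- v + matrix(runif(n * n, 0, 0.02), n)
  v <- (v + t(v)) / 2
  diag(v) <- 0
  dimnames(v) <- list(letters[1:n], letters[1:n])
  st <- multiscale_bootstrap_au(structure(v, class = c("pair_matrix",
                                                       "matrix")),
                                B = 200, seed = 17)
  tab <- st$table
  keys <- vapply(strsplit(tab$members, ""),
                 function(x) paste(sort(x), collapse = ""), "")
  b1 <- paste(letters[1:5], collapse = "")
  b2 <- paste(letters[6:10], collapse = "")
  expect_true(all(c(b1, b2) %in% keys))
  expect_true(all(tab$au[keys %in% c(b1, b2)] >= 0.99))
})

test_that("single-scale multiscale bootstrap reduces to the naive bootstrap", {
  m <- braille_fixture("rt")
  sub <- unclass(m)[1:6, 1:6]
  pm <- structure(sub, class = c("pair_matrix", "matrix"))
  B <- 150
  st <- multiscale_bootstrap_au(pm, scales = 1, B = B, seed = 23)
  # replay the same seed stream with a hand-rolled naive bootstrap
  ref <- stats::hclust(dist(sub), "ward.D2")
  sets <- function(hc) {
    out <- vector("list", nrow(hc$merge))
    for (i in seq_len(nrow(hc$merge))) {
      grab <- function(v) if (v < 0) hc$labels[-v] else out[[v]]
      out[[i]] <- sort(c(grab(hc$merge[i, 1]), grab(hc$merge[i, 2])))
    }
    vapply(out, paste, "", collapse = ".")
  }
  keys <- sets(ref)
  counts <- numeric(length(keys))
  set.seed(23)
  for (b in seq_len(B)) {
    cols <- sample.int(6, 6, replace = TRUE)
    hb <- stats::hclust(dist(sub[, cols, drop = FALSE]), "ward.D2")
    counts <- counts + (keys %in% sets(hb))
  }
  expect_equal(st$table$bp, counts / B)
  expect_equal(st$table$au, counts / B)
})

test_that("similarity edge lists round-trip and rank inversely", {
  m <- braille_fixture("rt")
  edges <- export_similarity_edges(m)
  expect_identical(nrow(edges), 325L)
  v <- unclass(m)
  expect_equal(edges$weight, 1 / v[upper.tri(v)])
  # weights are monotone decreasing in dissimilarity
  expect_equal(cor(edges$weight, v[upper.tri(v)], method = "spearman"), -1)
  # 3x3 case and file round trip
  small <- matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3,
                  dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  e3 <- export_similarity_edges(structure(small, class = c("pair_matrix",
                                                           "matrix")),
                                weight = "negation")
  expect_identical(nrow(e3), 3L)
  path <- withr::local_tempfile(fileext = ".csv")
  export_similarity_edges(m, path)
  back <- utils::read.csv(path, comment.char = "#")
  expect_equal(back$weight, edges$weight)
})
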