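#' Letter-pair matrix
#'
#' The pipeline's central container: a 26 x 26 numeric matrix indexed
#' (first letter, second letter) in a-z order, tagged with what its cells
#' mean. `"accuracy"` cells are proportions correct (higher = easier to
#' tell apart = more dissimilar); `"adjusted_rt"` cells are
#' participant-normalized response times; `"dissimilarity"` cells are
#' generic dissimilarities (e.g. reciprocal adjusted RT).
#'
#' @param values A square numeric matrix with identical row/column letter
#'   names (defaults to a-z when unnamed and 26 x 26).
#' @param kind One of `"accuracy"`, `"adjusted_rt"`, `"dissimilarity"`.
#' @return The matrix with class `"pair_matrix"` and attributes `kind` and
#'   `symmetric` (checked, not declared).
#' @export
pair_matrix <- function(values,
                        kind = c("accuracy", "adjusted_rt", "dissimilarity")) {
  kind <- match.arg(kind)
  stopifnot(is.matrix(values), nrow(values) == ncol(values))
  if (is.null(rownames(values))) {
    stopifnot(nrow(values) == 26L)
    dimnames(values) <- list(letters, letters)
  }
  stopifnot(identical(rownames(values), colnames(values)))
  if (kind == "accuracy") {
    rng <- range(values, na.rm = TRUE)
    if (rng[1] < 0 || rng[2] > 1) stop("accuracy cells must lie in [0, 1]")
  }
  structure(values, kind = kind, symmetric = is_symmetric(values),
            class = c("pair_matrix", "matrix"))
}

#' @rdname pair_matrix
#' @param m A matrix.
#' @param tol Symmetry tolerance.
#' @export
is_symmetric <- function(m, tol = 1e-8) {
  d <- abs(m - t(m))
  if (all(is.na(d))) return(NA) # no comparable mirrored cells
  isTRUE(max(d, na.rm = TRUE) <= tol)
}

#' @export
print.pair_matrix <- function(x, ...) {
  cat(sprintf("pair matrix (%s, %s), %d x %d letters\n", attr(x, "kind"),
              if (isTRUE(attr(x, "symmetric"))) "symmetric" else "asymmetric",
              nrow(x), ncol(x)))
  if (anyNA(x)) cat(sum(is.na(x)), "missing cells\n")
  print(round(unclass(x)[seq_len(min(6, nrow(x))), seq_len(min(6, ncol(x)))], 3))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

pm_kind <- function(m) attr(m, "kind")

#' Filter trials for the accuracy or RT analysis
#'
#' Both analyses drop response times outside [0.2 s, 8 s]; the RT analysis
#' additionally drops error trials.
#'
#' @param trials A trial data frame as produced by [simulate_trials()] or
#'   [read_trials()]: columns `participant, session, list, trial, first,
#'   second, trial_type, response, rt_s`.
#' @param purpose `"accuracy"` or `"rt"`.
#' @param rt_min,rt_max Inclusion bounds in seconds.
#' @return The retained rows, with an `"exclusions"` attribute counting
#'   `rt_low`, `rt_high` and (for `"rt"`) `error` exclusions.
#' @export
filter_trials <- function(trials, purpose = c("accuracy", "rt"),
                          rt_min = 0.2, rt_max = 8) {
  purpose <- match.arg(purpose)
  stopifnot(all(c("first", "second", "trial_type", "response", "rt_s")
                %in% names(trials)))
  low <- trials$rt_s < rt_min
  high <- trials$rt_s > rt_max
  keep <- !(low | high)
  excl <- c(rt_low = sum(low), rt_high = sum(high))
  if (purpose == "rt") {
    err <- keep & trials$response != trials$trial_type
    excl <- c(excl, error = sum(err))
    keep <- keep & !err
  }
  out <- trials[keep, , drop = FALSE]
  attr(out, "exclusions") <- excl
  out
}

#' Accuracy matrix from trial data
#'
#' Cell (i, j) holds the accuracy for ordered pair (first = i, second = j):
#' by default each participant's proportion of correct responses on that
#' pair, averaged (unweighted) across participants; `pooled = TRUE` pools
#' trials over participants instead. Diagonal cells are same-pair
#' accuracies. Cells never observed are `NA` and reported in the
#' `"missing_cells"` attribute.
#'
#' @param trials Trials filtered with [filter_trials()] for `"accuracy"`.
#' @param pooled Pool trials across participants instead of averaging
#'   per-participant proportions.
#' @return A `pair_matrix` of kind `"accuracy"`.
#' @export
accuracy_matrix <- function(trials, pooled = FALSE) {
  correct <- as.numeric(trials$response == trials$trial_type)
  f1 <- factor(trials$first, levels = letters)
  f2 <- factor(trials$second, levels = letters)
  if (pooled) {
    cell <- tapply(correct, list(f1, f2), mean)
  } else {
    part <- factor(trials$participant)
    per <- tapply(correct, list(part, f1, f2), mean)
    cell <- apply(per, c(2, 3), mean, na.rm = TRUE)
    cell[is.nan(cell)] <- NA
  }
  dimnames(cell) <- list(letters, letters)
  out <- pair_matrix(as.matrix(cell), kind = "accuracy")
  miss <- which(is.na(cell), arr.ind = TRUE)
  attr(out, "missing_cells") <- if (nrow(miss)) {
    data.frame(first = letters[miss[, 1]], second = letters[miss[, 2]])
  } else NULL
  out
}

#' Adjusted-RT matrix from trial data
#'
#' Response times are rescaled within participants by dividing each
#' retained RT by that participant's mean retained RT (so every
#' participant's adjusted mean is 1, removing overall speed differences).
#' Each cell then holds the participant-wise median adjusted RT for that
#' ordered pair, averaged across participants.
#'
#' @param trials Trials filtered with [filter_trials()] for `"rt"` (correct
#'   trials within the RT bounds).
#' @return A `pair_matrix` of kind `"adjusted_rt"`.
#' @export
rt_matrix <- function(trials) {
  part <- factor(trials$participant)
  if (any(tab <- table(part) == 0L)) {
    warning("participants with no retained trials dropped: ",
            paste(names(tab)[tab], collapse = ", "))
  }
  pmean <- tapply(trials$rt_s, part, mean)
  adj <- trials$rt_s / pmean[as.character(part)]
  f1 <- factor(trials$first, levels = letters)
  f2 <- factor(trials$second, levels = letters)
  per <- tapply(adj, list(part, f1, f2), stats::median)
  cell <- apply(per, c(2, 3), mean, na.rm = TRUE)
  cell[is.nan(cell)] <- NA
  dimnames(cell) <- list(letters, letters)
  out <- pair_matrix(as.matrix(cell), kind = "adjusted_rt")
  miss <- which(is.na(cell), arr.ind = TRUE)
  attr(out, "missing_cells") <- if (nrow(miss)) {
    data.frame(first = letters[miss[, 1]], second = letters[miss[, 2]])
  } else NULL
  out
}

#' Directional-symmetry test for a pair matrix
#'
#' Pairs each above-diagonal cell (i, j) with its mirror (j, i) and runs a
#' paired t test, plus a default-prior (JZS, scale 0.707) two-sided Bayes
#' factor for the null of symmetry evaluated by numerical quadrature. For a
#' 26-letter matrix there are 325 pairs and 324 degrees of freedom. An
#' exactly symmetric matrix has zero differences everywhere; t is then
#' defined as 0.
#'
#' @param m A square `pair_matrix` (or plain matrix) with complete
#'   off-diagonal cells.
#' @return A list of class `"symmetry_test"`: `t`, `df`, `p`, `bf01`,
#'   `n_pairs`.
#' @export
symmetry_test <- function(m) {
  stopifnot(nrow(m) == ncol(m))
  up <- upper.tri(m)
  u <- m[up]
  l <- t(m)[up]
  if (anyNA(u) || anyNA(l)) stop("missing off-diagonal cells")
  d <- u - l
  n <- length(d)
  s <- stats::sd(d)
  t <- if (s == 0) 0 else mean(d) / (s / sqrt(n))
  p <- 2 * stats::pt(-abs(t), df = n - 1)
  structure(list(t = t, df = n - 1L, p = p, bf01 = jzs_bf01(t, n),
                 n_pairs = n),
            class = "symmetry_test")
}

#' @export
print.symmetry_test <- function(x, ...) {
  cat(sprintf("symmetry: t(%d) = %.3f, p = %.3g, BF01 = %.2f (n = %d pairs)\n",
              x$df, x$t, x$p, x$bf01, x$n_pairs))
  invisible(x)
}

#' Default-prior Bayes factor for a paired/one-sample t statistic
#'
#' Jeffreys-Zellner-Siow Bayes factor in favor of the null, computed from
#' the t statistic and sample size by integrating the Cauchy prior on the
#' standardized effect (written as a scale mixture: g ~ inverse-gamma(1/2,
#' rscale^2/2)) with [stats::integrate()].
#'
#' @param t Observed t statistic.
#' @param n Number of (paired) observations.
#' @param rscale Cauchy prior scale, default `sqrt(2)/2` (the conventional
#'   "medium" default).
#' @return BF01 (evidence for the null; values > 1 favor symmetry).
#' @export
jzs_bf01 <- function(t, n, rscale = sqrt(2) / 2) {
  stopifnot(n >= 2, is.finite(t))
  nu <- n - 1
  null_lik <- (1 + t^2 / nu)^(-(nu + 1) / 2)
  integrand <- function(g) {
    (1 + n * g)^(-1 / 2) *
      (1 + t^2 / ((1 + n * g) * nu))^(-(nu + 1) / 2) *
      (rscale^2 / 2)^(1 / 2) / gamma(1 / 2) *
      g^(-3 / 2) * exp(-rscale^2 / (2 * g))
  }
  alt_lik <- stats::integrate(integrand, 0, Inf, rel.tol = 1e-10)$value
  null_lik / alt_lik
}

#' Average the two triangles of a pair matrix
#'
#' `out[i, j] = out[j, i] = (in[i, j] + in[j, i]) / 2`; the diagonal is
#' unchanged. Idempotent.
#'
#' @param m A square `pair_matrix`.
#' @return A symmetric `pair_matrix` of the same kind.
#' @export
symmetrize <- function(m) {
  out <- (unclass(m) + t(unclass(m))) / 2
  pair_matrix(out, kind = pm_kind(m))
}

#' Convert an adjusted-RT matrix to a dissimilarity matrix
#'
#' Each adjusted-RT cell is replaced by its reciprocal, so that larger
#' values mean faster (easier) discrimination, i.e. greater dissimilarity.
#' Accuracy matrices pass through unchanged (relabelled): higher accuracy
#' already means more dissimilar.
#'
#' @param m A `pair_matrix` of kind `"adjusted_rt"` (strictly positive
#'   cells) or `"accuracy"`.
#' @return A `pair_matrix` of kind `"dissimilarity"`.
#' @export
to_dissimilarity <- function(m) {
  kind <- pm_kind(m)
  if (identical(kind, "accuracy")) {
    return(pair_matrix(unclass(m), kind = "dissimilarity"))
  }
  if (any(unclass(m) <= 0, na.rm = TRUE)) {
    stop("reciprocal undefined: nonpositive cell present")
  }
  pair_matrix(1 / unclass(m), kind = "dissimilarity")
}

#' Correlation between the upper triangles of two pair matrices
#'
#' @param m1,m2 Symmetric pair matrices over the same letters.
#' @param method `"spearman"` (average ranks for ties) or `"pearson"`.
#' @return The correlation over the off-diagonal upper-triangle entries
#'   (325 values for 26 letters).
#' @export
matrix_correlation <- function(m1, m2, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  if (!identical(dim(m1), dim(m2)) ||
      !identical(rownames(m1), rownames(m2))) {
    stop("matrices must share dimensions and letter order")
  }
  up <- upper.tri(m1)
  stats::cor(m1[up], m2[up], method = method)
}

#' Same-trial (diagonal) analysis
#'
#' Extracts per-letter same-pair performance from the two dissimilarity
#' matrices - the accuracy diagonal directly, and same-pair adjusted RT as
#' the reciprocal of the RT-dissimilarity diagonal - and correlates both
#' with per-letter informativeness scores.
#'
#' @param matrix_acc Symmetric accuracy-kind (or dissimilarity) matrix with
#'   a populated diagonal.
#' @param matrix_rt Symmetric RT-based dissimilarity matrix (cells are
#'   reciprocals of adjusted RT) with a populated diagonal.
#' @param scores A data frame `letter, score` from [letter_informativeness()].
#' @return A list: `table` (letter, informativeness, same_accuracy,
#'   same_rt), `r_accuracy`, `r_rt` (Pearson). A zero-variance column
#'   yields `NA` with a warning.
#' @export
same_trial_analysis <- function(matrix_acc, matrix_rt, scores) {
  da <- diag(unclass(matrix_acc))
  dr <- diag(unclass(matrix_rt))
  if (anyNA(da) || anyNA(dr)) stop("missing diagonal cells")
  stopifnot(identical(scores$letter, names(da)))
  same_rt <- 1 / dr
  tab <- data.frame(letter = scores$letter, informativeness = scores$score,
                    same_accuracy = unname(da), same_rt = unname(same_rt))
  safe_cor <- function(x, y) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      warning("zero variance: correlation undefined")
      return(NA_real_)
    }
    stats::cor(x, y)
  }
  list(table = tab,
       r_accuracy = safe_cor(tab$informativeness, tab$same_accuracy),
       r_rt = safe_cor(tab$informativeness, tab$same_rt))
}

#' Letter-frequency correlations for same trials
#'
#' Correlates user-supplied per-letter frequencies (e.g. from a corpus
#' database; none are shipped) with same-pair RT and accuracy.
#'
#' @param diag_table The `table` component of [same_trial_analysis()].
#' @param frequencies Named numeric vector covering all 26 letters.
#' @return A list with Pearson `r_rt` and `r_accuracy` (NA with a warning
#'   when a variable is constant).
#' @export
frequency_correlation <- function(diag_table, frequencies) {
  if (!all(diag_table$letter %in% names(frequencies))) {
    stop("frequencies missing for some letters")
  }
  f <- frequencies[diag_table$letter]
  safe_cor <- function(x, y) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      warning("zero variance: correlation undefined")
      return(NA_real_)
    }
    stats::cor(x, y)
  }
  list(r_rt = safe_cor(f, diag_table$same_rt),
       r_accuracy = safe_cor(f, diag_table$same_accuracy))
}
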