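#' Configuration for the delta-rule perceptron
#'
#' Defaults mirror the published training setup: a two-layer network (six
#' binary dot inputs, 26 sigmoid output units, no hidden layer), weights
#' initialized uniformly in +/-0.3, delta-rule updates after each pattern
#' presentation with learning rate 0.4 and a small momentum term, patterns
#' shuffled every epoch, for up to 5000 epochs or until the match score
#' stops improving.
#'
#' @param learning_rate Positive step size (default 0.4).
#' @param init_range Weights start uniform in `[-init_range, init_range]`.
#' @param max_epochs Maximum training epochs (>= 1).
#' @param momentum Momentum coefficient in [0, 1); the source text says only
#'   "a small momentum term", so 0.1 is used.
#' @param bias Add a constant bias input (default off: the published network
#'   has none, and only boundaries through the origin make strictly
#'   non-separable letters possible).
#' @param rule How a letter counts as classified: `"threshold"` requires all
#'   26 output units on the correct side of activation 0.5 (the natural atom
#'   of the 676-unit match score); `"argmax"` requires only that the correct
#'   unit is maximal.
#' @param patience Early stop after this many epochs without improvement of
#'   the match score (the stopping window is unspecified in the source;
#'   500 is used).
#' @param seed Optional integer seed for reproducible runs.
#' @return A list of class `"perceptron_config"`.
#' @export
perceptron_config <- function(learning_rate = 0.4, init_range = 0.3,
                              max_epochs = 5000, momentum = 0.1,
                              bias = FALSE,
                              rule = c("threshold", "argmax"),
                              patience = 500, seed = NULL) {
  rule <- match.arg(rule)
  stopifnot(learning_rate > 0, max_epochs >= 1, init_range >= 0,
            momentum >= 0, momentum < 1, patience >= 1)
  structure(list(learning_rate = learning_rate, init_range = init_range,
                 max_epochs = as.integer(max_epochs), momentum = momentum,
                 bias = bias, rule = rule, patience = as.integer(patience),
                 seed = seed),
            class = "perceptron_config")
}

#' Train the delta-rule network on an alphabet
#'
#' One-hot classification of the dot patterns: for each presented pattern
#' the activations are logistic sigmoids of the weighted inputs, the error
#' signal is the prediction error times the sigmoid derivative, and weights
#' are updated per pattern with momentum. After every epoch the match score
#' counts output units (over all letters) on the correct side of 0.5, out
#' of `n_letters^2` (676 for the full alphabet).
#'
#' @param alphabet A [braille_alphabet()] (or any binary pattern matrix with
#'   row names).
#' @param config A [perceptron_config()].
#' @return A list of class `"delta_trace"`: `match` (per-epoch scores),
#'   `weights` (final input-by-output matrix), `misclassified` (letters
#'   failing `config$rule` at the end), `epochs`, `max_match`, `config`.
#' @export
train_delta_rule <- function(alphabet, config = perceptron_config()) {
  stopifnot(inherits(config, "perceptron_config"))
  X <- unclass(alphabet)
  storage.mode(X) <- "double"
  n <- nrow(X)
  if (config$bias) X <- cbind(X, bias = 1)
  d <- ncol(X)
  targets <- diag(n)

  if (!is.null(config$seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(config$seed)
  }

  W <- matrix(stats::runif(d * n, -config$init_range, config$init_range), d, n)
  V <- matrix(0, d, n)
  lr <- config$learning_rate
  mom <- config$momentum
  match <- integer(config$max_epochs)
  best <- -1L
  since_best <- 0L
  epoch <- 0L

  while (epoch < config$max_epochs) {
    epoch <- epoch + 1L
    for (i in sample.int(n)) {
      x <- X[i, ]
      act <- 1 / (1 + exp(-drop(x %*% W)))
      delta <- (targets[i, ] - act) * act * (1 - act)
      V <- mom * V + lr * outer(x, delta)
      W <- W + V
    }
    if (!all(is.finite(W))) {
      stop("delta-rule training diverged to non-finite weights; ",
           "lower the learning rate")
    }
    act_all <- 1 / (1 + exp(-(X %*% W)))
    match[epoch] <- sum((act_all > 0.5) == (targets > 0.5))
    if (match[epoch] > best) {
      best <- match[epoch]
      since_best <- 0L
    } else {
      since_best <- since_best + 1L
      if (since_best >= config$patience) break
    }
  }

  act_all <- 1 / (1 + exp(-(X %*% W)))
  mis <- switch(config$rule,
    threshold = rownames(X)[apply((act_all > 0.5) != (targets > 0.5), 1, any)],
    argmax = rownames(X)[max.col(act_all, ties.method = "first") != seq_len(n)]
  )
  structure(list(match = match[seq_len(epoch)], weights = W,
                 misclassified = mis, epochs = epoch,
                 max_match = n * n, config = config),
            class = "delta_trace")
}

#' @export
print.delta_trace <- function(x, ...) {
  cat(sprintf("delta-rule trace: %d epochs, final match %d/%d\n",
              x$epochs, x$match[x$epochs], x$max_match))
  cat("misclassified:",
      if (length(x$misclassified)) paste(x$misclassified, collapse = ", ")
      else "(none)", "\n")
  invisible(x)
}

#' Exact strict-separability oracle with certificates
#'
#' Decides, as a linear-feasibility problem (not by training), whether a
#' weight vector exists that puts the target letter's pattern strictly on
#' the positive side and all 25 other patterns strictly on the negative
#' side. Without a bias the hyperplane passes through the origin and a
#' margin of 1 is imposed (scale-invariant): `w . x_letter >= 1` and
#' `w . x_other <= -1`. When infeasible, a Farkas-type witness is returned:
#' nonnegative coefficients on the other letters' patterns whose weighted
#' sum equals the target pattern (a conic-combination proof that no such
#' hyperplane exists). Either witness is mechanically checkable with
#' [verify_certificate()].
#'
#' @param alphabet A [braille_alphabet()], or any binary pattern matrix
#'   with row names (reduced alphabets are useful for testing).
#' @param letter Target letter (a row name of `alphabet`).
#' @param bias Allow an additive free threshold (affine separation).
#' @return A list of class `"separability_certificate"` with elements
#'   `letter`, `separable`, `bias`, and `witness` (named weight vector if
#'   separable, otherwise named nonnegative combination coefficients).
#' @examples
#' strict_separability(braille_alphabet(), "f")$separable # FALSE: f = a + i
#' @export
strict_separability <- function(alphabet, letter, bias = FALSE) {
  stopifnot(is.matrix(alphabet), !is.null(rownames(alphabet)),
            length(letter) == 1L, letter %in% rownames(alphabet))
  X <- unclass(alphabet)
  storage.mode(X) <- "double"
  if (bias) X <- cbind(X, bias = 1)
  idx <- which(rownames(X) == letter)
  x <- X[idx, ]
  others <- X[-idx, , drop = FALSE]
  d <- ncol(X)

  # primal: free w = u - v with A1 w >= 1
  A1 <- rbind(x, -others)
  prim <- lp_feasible_ge(cbind(A1, -A1), rep(1, nrow(A1)))
  if (prim$feasible) {
    w <- prim$x[seq_len(d)] - prim$x[d + seq_len(d)]
    names(w) <- colnames(X)
    cert <- list(letter = letter, separable = TRUE, bias = bias, witness = w)
  } else {
    # dual witness: y >= 0 with t(others) y = x
    dual <- lp_phase1(t(others), x)
    if (!dual$feasible) {
      stop("internal error: neither a separating vector nor a conic ",
           "certificate was found for letter ", letter)
    }
    y <- dual$x
    names(y) <- rownames(others)
    cert <- list(letter = letter, separable = FALSE, bias = bias,
                 witness = y[y > 1e-9])
  }
  structure(cert, class = "separability_certificate")
}

#' Mechanically re-verify a separability certificate
#'
#' For a separable certificate, checks every one-vs-rest inequality at the
#' margin; for a non-separable one, checks that the conic combination of
#' the other patterns reproduces the letter's pattern.
#'
#' @param cert A `"separability_certificate"`.
#' @param alphabet The alphabet it refers to.
#' @param tol Numerical tolerance.
#' @return `TRUE` if the witness checks out, `FALSE` otherwise.
#' @export
verify_certificate <- function(cert, alphabet, tol = 1e-6) {
  stopifnot(inherits(cert, "separability_certificate"))
  X <- unclass(alphabet)
  storage.mode(X) <- "double"
  if (cert$bias) X <- cbind(X, bias = 1)
  idx <- which(rownames(X) == cert$letter)
  x <- X[idx, ]
  others <- X[-idx, , drop = FALSE]
  if (cert$separable) {
    w <- cert$witness
    all(drop(others %*% w) <= -1 + tol) && sum(w * x) >= 1 - tol
  } else {
    y <- cert$witness
    if (any(y < -tol) || length(y) == 0L) return(FALSE)
    combo <- drop(y %*% others[names(y), , drop = FALSE])
    all(abs(combo - x) <= tol)
  }
}

#' @export
print.separability_certificate <- function(x, ...) {
  cat(sprintf("letter %s: %s (%s)\n", x$letter,
              if (x$separable) "strictly separable" else "NOT separable",
              if (x$bias) "bias allowed" else "through origin"))
  print(round(x$witness, 4))
  invisible(x)
}

#' Aggregate misclassification over repeated training runs
#'
#' @param traces A list of `"delta_trace"` objects from [train_delta_rule()].
#' @return A list with `frequency` (named per-letter misclassification
#'   counts over runs), `modal_set` (the most frequent exact misclassified
#'   set), `modal_size`, and `n_runs`.
#' @export
misclassification_report <- function(traces) {
  if (length(traces) == 0L) stop("no traces supplied")
  stopifnot(all(vapply(traces, inherits, TRUE, "delta_trace")))
  sets <- lapply(traces, function(tr) sort(tr$misclassified))
  freq <- table(unlist(sets))
  keys <- vapply(sets, paste, "", collapse = ",")
  modal_key <- names(sort(table(keys), decreasing = TRUE))[1L]
  modal <- if (nzchar(modal_key)) strsplit(modal_key, ",")[[1L]] else character()
  list(frequency = freq, modal_set = modal, modal_size = length(modal),
       n_runs = length(traces))
}
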