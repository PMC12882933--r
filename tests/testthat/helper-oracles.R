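# Independent oracles and fixture builders shared across test files. These
# deliberately avoid the package's own code paths.

# Brute-force agglomerative clustering via the Lance-Williams recurrence,
# O(n^3) with explicit distance updates; used to check ward_dendrogram.
# variant "squared": update on squared distances, report sqrt heights
# (ward.D2); "classic": update on raw distances (ward.D).
brute_force_ward <- function(d, variant = "squared") {
  D <- as.matrix(d)
  if (variant == "squared") D <- D^2
  n <- nrow(D)
  sizes <- rep(1, n)
  active <- seq_len(n)
  id <- -seq_len(n) # hclust merge convention
  merges <- matrix(0L, n - 1, 2)
  heights <- numeric(n - 1)
  members <- as.list(seq_len(n))
  for (step in seq_len(n - 1)) {
    best <- c(NA, NA)
    bestd <- Inf
    for (ii in seq_along(active)[-length(active)]) {
      for (jj in (ii + 1):length(active)) {
        i <- active[ii]; j <- active[jj]
        if (D[i, j] < bestd - 1e-12) {
          bestd <- D[i, j]; best <- c(i, j)
        }
      }
    }
    i <- best[1]; j <- best[2]
    heights[step] <- if (variant == "squared") sqrt(bestd) else bestd
    merges[step, ] <- sort(c(id[i], id[j]))
    # Lance-Williams Ward update towards every other active cluster
    for (k in setdiff(active, c(i, j))) {
      ai <- (sizes[i] + sizes[k]) / (sizes[i] + sizes[j] + sizes[k])
      aj <- (sizes[j] + sizes[k]) / (sizes[i] + sizes[j] + sizes[k])
      bb <- -sizes[k] / (sizes[i] + sizes[j] + sizes[k])
      D[i, k] <- D[k, i] <- ai * D[i, k] + aj * D[j, k] + bb * D[i, j]
    }
    sizes[i] <- sizes[i] + sizes[j]
    id[i] <- step
    active <- setdiff(active, j)
  }
  list(merge = merges, height = heights)
}

# Exhaustive grid decision of strict one-vs-rest separability through the
# origin for small binary alphabets: integer weight vectors in [-r, r]^d.
# For 4-dimensional 0/1 patterns any separable dichotomy admits a small
# integer certificate (rational vertex solutions have determinant-bounded
# entries), so r = 8 is exhaustive in practice.
grid_separable <- function(patterns, letter, r = 8) {
  d <- ncol(patterns)
  x <- patterns[letter, ]
  others <- patterns[setdiff(rownames(patterns), letter), , drop = FALSE]
  grid <- as.matrix(expand.grid(rep(list(-r:r), d)))
  scores_x <- drop(grid %*% x)
  scores_o <- grid %*% t(others)
  any(scores_x > 0 & apply(scores_o < 0, 1, all))
}

# Monte-Carlo JZS Bayes factor: sample g from its inverse-gamma(1/2,
# rscale^2/2) prior and average the marginal likelihood ratio.
mc_jzs_bf01 <- function(t, n, rscale = sqrt(2) / 2, nsim = 2e5) {
  nu <- n - 1
  g <- 1 / stats::rgamma(nsim, shape = 1 / 2, rate = rscale^2 / 2)
  alt <- mean((1 + n * g)^(-1 / 2) *
                (1 + t^2 / ((1 + n * g) * nu))^(-(nu + 1) / 2))
  (1 + t^2 / nu)^(-(nu + 1) / 2) / alt
}

# Minimal trial-log data frame in the canonical schema.
make_trials <- function(participant, first, second, response, rt_s,
                        list = 1L, session = 1L) {
  trial_type <- ifelse(first == second, "same", "different")
  data.frame(participant = participant, session = session, list = list,
             trial = seq_along(first), first = first, second = second,
             trial_type = trial_type, response = response, rt_s = rt_s,
             stringsAsFactors = FALSE)
}

# A small fixed two-participant schedule.
make_design_small <- function() {
  set.seed(1)
  make_design(sim_config(n_participants = 2))
}

# The four published letter groups, as sorted membership strings.
published_rt_blocks <- function() {
  sort(vapply(list(c("n", "o", "y", "z"),
                   c("l", "p", "q", "r", "s", "t", "v", "w"),
                   c("k", "m", "u", "x"),
                   letters[1:10]),
              function(x) paste(sort(x), collapse = ""), ""))
}

partition_blocks <- function(part) {
  unname(sort(vapply(split(names(part), part),
                     function(x) paste(sort(x), collapse = ""), "")))
}
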