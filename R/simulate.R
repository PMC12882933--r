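#' Configuration for the same-different trial simulator
#'
#' The defaults emulate the published design: 24 participants, 5 lists per
#' participant, each list 130 same + 130 different trials, covering all 650
#' ordered different pairs once per participant and each of the 26 same
#' pairs 25 times. The response model is a Gaussian-CDF psychometric link
#' with a lapse mixture; response times are lognormal with
#' participant-level speed heterogeneity; a small fraction of trials is
#' replaced by out-of-bounds RTs to exercise the 0.2-8 s filter.
#'
#' Parameter defaults are chosen to land near the published summary
#' statistics (overall accuracy in the mid-0.9s with ceiling cells, mean
#' RT around 1.5 s, 0.5% RT outliers); see the methods vignette.
#'
#' @param n_participants Number of simulated readers (default 24).
#' @param n_lists Lists per participant (default 5; must divide 650).
#' @param same_per_list,different_per_list Trials per list by type (130/130).
#' @param slope Psychometric slope on latent dissimilarity, different
#'   trials.
#' @param criterion Psychometric criterion (shift), different trials.
#' @param same_slope,same_criterion Link parameters for same trials, on
#'   letter fluency.
#' @param lapse Lapse rate in [0, 0.2]: that fraction of trials is answered
#'   at random.
#' @param mu0 Baseline log-RT (log seconds).
#' @param rt_coef Log-RT decrease per unit dissimilarity (different
#'   trials): easier pairs are answered faster.
#' @param same_rt_coef Log-RT decrease per unit fluency (same trials).
#' @param sigma Trial-level log-RT noise SD (> 0).
#' @param tau Participant speed SD on the log scale (> 0).
#' @param outlier_rate Fraction of trials replaced by out-of-bounds RTs,
#'   uniform on [0.05, 0.2) or (8, 12] seconds.
#' @param seed Integer seed consumed by [simulate_study()].
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_participants = 24, n_lists = 5,
                       same_per_list = 130, different_per_list = 130,
                       slope = 10, criterion = 0.3,
                       same_slope = 2, same_criterion = 0,
                       lapse = 0.02,
                       mu0 = log(1.45), rt_coef = 0.35, same_rt_coef = 0.15,
                       sigma = 0.32, tau = 0.2,
                       outlier_rate = 0.005, seed = 1) {
  stopifnot(lapse >= 0, lapse <= 0.2, sigma > 0, tau >= 0,
            outlier_rate >= 0, outlier_rate <= 1,
            n_participants >= 1, n_lists >= 1)
  structure(as.list(environment()), class = "sim_config")
}

#' The four published reaction-time clusters
#'
#' The default planted partition for the generator: the four letter groups
#' recovered from the RT-based dissimilarity matrix (with l and v in the
#' s-t-r-w-p-q group, as in the RT dendrogram).
#'
#' @return Named integer vector of block memberships for a-z.
#' @export
rt_cluster_partition <- function() {
  blocks <- list(c("n", "z", "o", "y"),
                 c("s", "t", "r", "w", "p", "q", "l", "v"),
                 c("m", "x", "k", "u"),
                 letters[1:10])
  out <- integer(26)
  names(out) <- letters
  for (b in seq_along(blocks)) out[blocks[[b]]] <- b
  out
}

#' Build the trial schedule
#'
#' Per participant: each of the 650 ordered different pairs appears exactly
#' once across the lists (130 per list), and each of the 26 same pairs
#' appears `same_per_list / 26` times per list (25 times in total under the
#' defaults). Lists 1-3 are labelled session 1 and the rest session 2;
#' trial order is randomized within list. Consumes the R random stream
#' (seed it, or use [simulate_study()]).
#'
#' @param config A [sim_config()].
#' @return A data frame `participant, session, list, trial, first, second,
#'   trial_type`.
#' @export
make_design <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  nl <- config$n_lists
  diff_pairs <- expand.grid(first = letters, second = letters,
                            stringsAsFactors = FALSE)
  diff_pairs <- diff_pairs[diff_pairs$first != diff_pairs$second, ]
  if (nrow(diff_pairs) %% nl != 0 ||
      nrow(diff_pairs) / nl != config$different_per_list) {
    stop("infeasible composition: 650 different pairs must split evenly ",
         "into n_lists blocks of different_per_list")
  }
  if (config$same_per_list %% 26 != 0) {
    stop("infeasible composition: same_per_list must be a multiple of 26")
  }
  reps_same <- config$same_per_list / 26
  session_of <- ifelse(seq_len(nl) <= ceiling(nl * 3 / 5), 1L, 2L)

  per_part <- function(p) {
    ord <- sample.int(nrow(diff_pairs))
    rows <- vector("list", nl)
    for (l in seq_len(nl)) {
      d_idx <- ord[(l - 1) * config$different_per_list +
                     seq_len(config$different_per_list)]
      d <- diff_pairs[d_idx, ]
      s <- data.frame(first = rep(letters, reps_same),
                      second = rep(letters, reps_same),
                      stringsAsFactors = FALSE)
      block <- rbind(cbind(d, trial_type = "different"),
                     cbind(s, trial_type = "same"))
      block <- block[sample.int(nrow(block)), ]
      block$participant <- p
      block$session <- session_of[l]
      block$list <- l
      block$trial <- seq_len(nrow(block))
      rows[[l]] <- block
    }
    do.call(rbind, rows)
  }
  out <- do.call(rbind, lapply(sprintf("p%02d", seq_len(config$n_participants)),
                               per_part))
  rownames(out) <- NULL
  out[, c("participant", "session", "list", "trial", "first", "second",
          "trial_type")]
}

#' Plant a latent dissimilarity structure
#'
#' The latent pairwise dissimilarity is `delta(i, j) = alpha * w(i, j) +
#' beta * [i, j in different blocks]`, rescaled to [0, 1], where `w` is the
#' informativeness-weighted dot mismatch between the two patterns
#' (normalized to [0, 1]). Per-letter fluency is the letter
#' informativeness score, driving same-trial difficulty.
#'
#' @param alphabet A [braille_alphabet()].
#' @param scores [letter_informativeness()] output.
#' @param partition Named block membership over a-z (default the published
#'   RT clusters).
#' @param alpha,beta Nonnegative weights of the pattern-mismatch and
#'   block-structure terms; both zero is rejected.
#' @return A list of class `"ground_truth"`: `delta` (symmetric 26 x 26,
#'   zero diagonal), `partition`, `fluency`.
#' @export
make_ground_truth <- function(alphabet = braille_alphabet(),
                              scores = letter_informativeness(alphabet),
                              partition = rt_cluster_partition(),
                              alpha = 1, beta = 1) {
  if (alpha == 0 && beta == 0) stop("degenerate flat structure: alpha = beta = 0")
  stopifnot(all(letters %in% names(partition)))
  H <- dot_statistics(alphabet)$informativeness
  X <- unclass(alphabet)
  wmis <- matrix(0, 26, 26, dimnames = list(letters, letters))
  for (d in 1:6) wmis <- wmis + H[d] * outer(X[, d], X[, d], "!=")
  wmis <- wmis / sum(H)
  blk <- outer(partition[letters], partition[letters], "!=") * 1
  delta <- alpha * wmis + beta * blk
  delta <- delta / max(delta)
  diag(delta) <- 0
  fl <- scores$score
  names(fl) <- scores$letter
  structure(list(delta = delta, partition = partition[letters],
                 fluency = fl),
            class = "ground_truth")
}

#' Simulate responses and response times for a schedule
#'
#' Different trials are answered "different" with probability
#' `(1 - lapse) * pnorm(slope * delta - criterion) + lapse / 2`; same
#' trials are answered "same" with probability `(1 - lapse) *
#' pnorm(same_slope * fluency + same_criterion) + lapse / 2`. Log RT is
#' `mu0 + speed(participant) - rt_coef * delta` (different) or
#' `mu0 + speed - same_rt_coef * fluency` (same), plus `N(0, sigma)` noise,
#' with participant speeds `N(0, tau)`. A fraction `outlier_rate` of RTs is
#' replaced by out-of-bounds values. Consumes the R random stream.
#'
#' @param design Schedule from [make_design()].
#' @param truth A [make_ground_truth()] object.
#' @param config A [sim_config()].
#' @return The design with `response` and `rt_s` columns appended.
#' @export
simulate_trials <- function(design, truth, config = sim_config()) {
  stopifnot(inherits(truth, "ground_truth"), inherits(config, "sim_config"))
  n <- nrow(design)
  is_same <- design$trial_type == "same"
  delta <- truth$delta[cbind(design$first, design$second)]
  fl <- truth$fluency[design$first]

  p_correct <- ifelse(
    is_same,
    (1 - config$lapse) *
      stats::pnorm(config$same_slope * fl + config$same_criterion) +
      config$lapse / 2,
    (1 - config$lapse) *
      stats::pnorm(config$slope * delta - config$criterion) +
      config$lapse / 2
  )
  correct <- stats::runif(n) < p_correct
  response <- ifelse(correct, design$trial_type,
                     ifelse(is_same, "different", "same"))

  parts <- unique(design$participant)
  speed <- stats::rnorm(length(parts), 0, config$tau)
  names(speed) <- parts
  mu <- config$mu0 + speed[design$participant] +
    ifelse(is_same, -config$same_rt_coef * fl, -config$rt_coef * delta)
  rt <- exp(mu + stats::rnorm(n, 0, config$sigma))

  out_n <- stats::rbinom(1, n, config$outlier_rate)
  if (out_n > 0) {
    idx <- sample.int(n, out_n)
    lo <- stats::runif(out_n) < 0.5
    rt[idx] <- ifelse(lo, stats::runif(out_n, 0.05, 0.2),
                      stats::runif(out_n, 8, 12))
  }

  design$response <- response
  design$rt_s <- rt
  design
}

#' Run the generator end to end
#'
#' Seeds the random stream from `config$seed`, builds the schedule, plants
#' the ground truth and simulates all trials.
#'
#' @param config A [sim_config()].
#' @param truth Optional [make_ground_truth()] override.
#' @return A list: `trials`, `truth`, `config`.
#' @export
simulate_study <- function(config = sim_config(),
                           truth = make_ground_truth()) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(config$seed)
  design <- make_design(config)
  trials <- simulate_trials(design, truth, config)
  list(trials = trials, truth = truth, config = config)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items;
#' 1 for identical partitions, about 0 for independent ones.
#'
#' @param a,b Membership vectors over the same items (matched by name when
#'   both are named).
#' @return The adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) b <- b[names(a)]
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  n2 <- choose2(sum(tab))
  expected <- sum_a * sum_b / n2
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
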