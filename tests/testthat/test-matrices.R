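test_that("filter_trials applies the RT bounds and the error rule", {
  tr <- make_trials(
    participant = rep("p1", 10),
    first = rep("a", 10),
    second = c(rep("b", 9), "a"),
    response = c(rep("different", 7), "same", "different", "same"),
    rt_s = c(0.1, 9.0, rep(1.5, 8))
  )
  # rows 1-2 out of bounds; row 8 an in-bounds error (responded same to a-b)
  acc <- filter_trials(tr, "accuracy")
  rt <- filter_trials(tr, "rt")
  expect_identical(nrow(acc), 8L)
  expect_identical(nrow(rt), 7L)
  expect_identical(attr(acc, "exclusions"), c(rt_low = 1L, rt_high = 1L))
  expect_identical(attr(rt, "exclusions"),
                   c(rt_low = 1L, rt_high = 1L, error = 1L))
  # boundary values are retained (bounds are exclusive)
  edge <- make_trials("p1", c("a", "a"), c("b", "b"),
                      c("different", "different"), c(0.2, 8))
  expect_identical(nrow(filter_trials(edge, "accuracy")), 2L)
})

test_that("accuracy_matrix averages per-participant proportions", {
  tr <- make_trials(
    participant = c("A", "A", "B"),
    first = rep("a", 3), second = rep("b", 3),
    response = c("different", "same", "different"),
    rt_s = rep(1, 3)
  )
  m <- accuracy_matrix(tr)
  expect_s3_class(m, "pair_matrix")
  expect_equal(m["a", "b"], (0.5 + 1) / 2)
  expect_equal(accuracy_matrix(tr, pooled = TRUE)["a", "b"], 2 / 3)
  expect_identical(nrow(attr(m, "missing_cells")), 675L)

  all_ok <- make_trials(rep("A", 4), rep("c", 4), rep("d", 4),
                        rep("different", 4), rep(1, 4))
  expect_equal(accuracy_matrix(all_ok)["c", "d"], 1)
})

test_that("rt_matrix normalizes within participants", {
  # all RTs equal: every observed cell is exactly 1
  tr <- make_trials(rep("A", 4), c("a", "b", "c", "d"),
                    c("b", "c", "d", "e"), rep("different", 4),
                    rep(2.5, 4))
  m <- rt_matrix(tr)
  expect_equal(unname(m[cbind(c("a", "b", "c", "d"),
                              c("b", "c", "d", "e"))]), rep(1, 4))
  # {1, 2, 3} s -> adjusted {0.5, 1, 1.5}
  tr2 <- make_trials(rep("A", 3), c("a", "b", "c"), c("b", "c", "d"),
                     rep("different", 3), c(1, 2, 3))
  m2 <- rt_matrix(tr2)
  expect_equal(unname(m2[cbind(c("a", "b", "c"), c("b", "c", "d"))]),
               c(0.5, 1, 1.5))
})

test_that("rt_matrix is invariant to participant speed scaling", {
  cfg <- sim_config(n_participants = 4, seed = 21, outlier_rate = 0)
  st <- simulate_study(cfg)
  tr <- filter_trials(st$trials, "rt") # rescale after filtering so the
  sped <- tr                           # retained set is held fixed
  one <- sped$participant == "p02"
  sped$rt_s[one] <- sped$rt_s[one] * 3.7
  m1 <- rt_matrix(tr)
  m2 <- rt_matrix(sped)
  expect_equal(unclass(m1), unclass(m2), ignore_attr = TRUE)
})

test_that("symmetry_test pairs the triangles and handles exact symmetry", {
  sym <- pair_matrix(matrix(0.9, 26, 26), kind = "accuracy")
  st <- symmetry_test(sym)
  expect_equal(st$t, 0)
  expect_identical(st$df, 324L)
  expect_identical(st$n_pairs, 325L)
  expect_gt(st$bf01, 1)

  asym <- unclass(braille_fixture("rt"))
  set.seed(5)
  asym <- asym + matrix(rnorm(676, sd = 0.01), 26)
  st2 <- symmetry_test(pair_matrix(asym, kind = "dissimilarity"))
  expect_identical(st2$df, 324L)
  miss <- asym
  miss[1, 2] <- NA
  expect_error(symmetry_test(miss), "missing")
})

test_that("JZS Bayes factor matches an independent Monte-Carlo oracle", {
  set.seed(77)
  for (case in list(c(0.637, 325), c(-1.96, 325), c(2.5, 40))) {
    q <- jzs_bf01(case[1], case[2])
    mc <- mc_jzs_bf01(case[1], case[2], nsim = 4e5)
    expect_lt(abs(q - mc) / q, 0.02)
  }
  # the published symmetry statistics imply the published Bayes factors
  expect_equal(round(jzs_bf01(0.637, 325), 1), 13.1, tolerance = 0.05)
  expect_equal(round(jzs_bf01(-1.96, 325), 2), 2.42, tolerance = 0.05)
})

test_that("symmetrize averages mirrored cells and is idempotent", {
  v <- unclass(braille_fixture("accuracy"))
  set.seed(8)
  v <- v + matrix(runif(676, 0, 0.001), 26) # break symmetry slightly
  v[v > 1] <- 1
  m <- pair_matrix(v, kind = "accuracy")
  s <- symmetrize(m)
  expect_true(attr(s, "symmetric"))
  expect_equal(s["a", "b"], (v["a", "b"] + v["b", "a"]) / 2)
  expect_equal(unclass(symmetrize(s)), unclass(s))
  expect_equal(diag(unclass(s)), diag(v)) # diagonal untouched
})

test_that("to_dissimilarity takes reciprocals of adjusted RTs", {
  v <- matrix(2, 26, 26)
  diag(v) <- 1
  m <- pair_matrix(v, kind = "adjusted_rt")
  d <- to_dissimilarity(m)
  expect_identical(attr(d, "kind"), "dissimilarity")
  expect_equal(d["a", "b"], 0.5)
  expect_equal(d["a", "a"], 1) # fixed point
  expect_equal(unclass(to_dissimilarity(
    pair_matrix(unclass(d), "adjusted_rt"))), v,
    ignore_attr = TRUE) # involution
  bad <- pair_matrix(matrix(c(-1, rep(1, 675)), 26), kind = "adjusted_rt")
  expect_error(to_dissimilarity(bad), "nonpositive")
  # accuracy matrices pass through relabelled
  acc <- braille_fixture("accuracy")
  expect_equal(unclass(to_dissimilarity(acc)), unclass(acc),
               ignore_attr = TRUE)
})

test_that("matrix_correlation works on the upper triangles", {
  m <- braille_fixture("rt")
  expect_equal(matrix_correlation(m, m), 1)
  expect_equal(matrix_correlation(m, m, "pearson"), 1)
  # 3x3 hand-computed Spearman: upper values (1,2,3) vs (3,5,4)
  a <- matrix(0, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  b <- a
  a[upper.tri(a)] <- c(1, 2, 3)
  b[upper.tri(b)] <- c(3, 5, 4)
  a <- a + t(a); b <- b + t(b)
  expect_equal(matrix_correlation(a, b, "spearman"), 0.5) # ranks 123 vs 132
  expect_error(matrix_correlation(m, a), "dimensions")
})

test_that("same_trial_analysis extracts diagonals and correlates", {
  acc <- braille_fixture("accuracy")
  rt <- braille_fixture("rt")
  li <- letter_informativeness()
  res <- same_trial_analysis(acc, rt, li)
  expect_identical(res$table$letter, letters)
  expect_equal(res$table$same_rt, unname(1 / diag(unclass(rt))))
  expect_equal(res$r_accuracy,
               cor(li$score, diag(unclass(acc))))
  # constant diagonal: undefined correlation, flagged
  flat <- pair_matrix(matrix(1, 26, 26), kind = "dissimilarity")
  expect_warning(r0 <- same_trial_analysis(flat, rt, li), "zero variance")
  expect_true(is.na(r0$r_accuracy))
})

test_that("frequency_correlation validates coverage and degenerate input", {
  acc <- braille_fixture("accuracy")
  rt <- braille_fixture("rt")
  tab <- same_trial_analysis(acc, rt, letter_informativeness())$table
  const <- setNames(rep(1, 26), letters)
  w <- capture_warnings(fc <- frequency_correlation(tab, const))
  expect_match(w, "zero variance", all = TRUE)
  expect_length(w, 2) # one per correlation
  expect_true(is.na(fc$r_rt))
  self <- setNames(tab$same_rt, tab$letter)
  expect_equal(frequency_correlation(tab, self)$r_rt, 1)
  expect_error(frequency_correlation(tab, self[1:20]), "missing")
})

test_that("accuracy cells converge to the planted response probability", {
  # 200 trials on one pair with known psychometric probability
  cfg <- sim_config(seed = 13, lapse = 0.05, outlier_rate = 0)
  truth <- make_ground_truth()
  n <- 200
  design <- data.frame(participant = "p01", session = 1L, list = 1L,
                       trial = seq_len(n), first = "a", second = "q",
                       trial_type = "different", stringsAsFactors = FALSE)
  set.seed(cfg$seed)
  tr <- simulate_trials(design, truth, cfg)
  p_true <- (1 - cfg$lapse) *
    pnorm(cfg$slope * truth$delta["a", "q"] - cfg$criterion) + cfg$lapse / 2
  p_hat <- mean(tr$response == "different")
  ci <- qnorm(0.999) * sqrt(p_true * (1 - p_true) / n)
  expect_lt(abs(p_hat - p_true), max(ci, 0.02))
})
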