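# Phase-1 simplex for linear feasibility problems.
#
# Decides feasibility of {x >= 0 : A x = b} by minimizing the sum of
# artificial variables with Bland's anti-cycling pivot rule. Dense tableau;
# intended for the small systems arising in the separability oracle
# (<= ~30 rows/~70 columns), where exactness to ~1e-9 suffices and no
# external LP solver is needed.

lp_phase1 <- function(A, b, tol = 1e-9) {
  stopifnot(is.matrix(A), length(b) == nrow(A))
  m <- nrow(A)
  n <- ncol(A)
  flip <- b < 0
  A[flip, ] <- -A[flip, , drop = FALSE]
  b[flip] <- -b[flip]

  # tableau: [A | I | b], artificial basis
  tab <- cbind(A, diag(m), b)
  basis <- n + seq_len(m)
  # reduced costs for cost vector c = (0,...,0, 1,...,1)
  cost <- c(rep(0, n), rep(1, m))
  red <- cost - colSums(tab[, seq_len(n + m), drop = FALSE])

  repeat {
    enter <- which(red < -tol)
    if (length(enter) == 0L) break
    j <- enter[1L] # Bland: lowest index
    col <- tab[, j]
    pos <- which(col > tol)
    if (length(pos) == 0L) break # unbounded cannot occur in phase 1
    ratio <- tab[pos, n + m + 1L] / col[pos]
    cand <- pos[ratio <= min(ratio) + tol]
    r <- cand[which.min(basis[cand])] # Bland on leaving variable
    piv <- tab[r, j]
    tab[r, ] <- tab[r, ] / piv
    upd <- setdiff(seq_len(m), r)
    tab[upd, ] <- tab[upd, , drop = FALSE] -
      outer(tab[upd, j], tab[r, ])
    red <- red - red[j] * tab[r, seq_len(n + m)]
    basis[r] <- j
  }

  x_full <- numeric(n + m)
  x_full[basis] <- tab[, n + m + 1L]
  art_sum <- sum(x_full[n + seq_len(m)])
  list(feasible = art_sum <= sqrt(tol), x = x_full[seq_len(n)])
}

# Feasibility of {x >= 0 : A x >= b} via surplus variables.
lp_feasible_ge <- function(A, b, tol = 1e-9) {
  m <- nrow(A)
  res <- lp_phase1(cbind(A, -diag(m)), b, tol = tol)
  list(feasible = res$feasible, x = res$x[seq_len(ncol(A))])
}
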