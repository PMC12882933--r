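#' Binary entropy
#'
#' Shannon entropy of a Bernoulli variable, `H(p) = -p log2 p -
#' (1-p) log2 (1-p)`, in bits, with the convention `0 log 0 = 0`. Used here
#' as the informativeness of a dot position: it is maximal (1 bit) when the
#' dot is raised in exactly half of the letters and zero when the dot is
#' universal or absent.
#'
#' @param p Proportion(s) in [0, 1].
#' @return Entropy value(s) in [0, 1] bits.
#' @examples
#' binary_entropy(0.5)    # 1
#' binary_entropy(21/26)  # 0.706, dot 1 of the braille alphabet
#' @export
binary_entropy <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop("`p` must lie in [0, 1]")
  }
  out <- numeric(length(p))
  inner <- p > 0 & p < 1
  q <- p[inner]
  out[inner] <- -q * log2(q) - (1 - q) * log2(1 - q)
  out
}

#' Per-dot information statistics
#'
#' For each of the six dot positions: its prevalence across the alphabet,
#' its binary-entropy informativeness, and its cue validities under a
#' uniform prior over letters. The presence cue validity `p(l|d)` is
#' `1 / n_d` for the `n_d` letters carrying dot `d` (how strongly a raised
#' dot points at any one of its letters); the absence cue validity
#' `p(l|~d)` is `1 / (26 - n_d)`. A dot raised in many letters therefore
#' has an informative absence and an uninformative presence, and vice
#' versa.
#'
#' @param alphabet A [braille_alphabet()].
#' @return A data frame with columns `dot`, `prevalence`, `informativeness`,
#'   `cv_presence`, `cv_absence`. A degenerate dot (present in all letters
#'   or none) gets `NA` for the undefined cue validity, with a warning.
#' @examples
#' dot_statistics(braille_alphabet())
#' @export
dot_statistics <- function(alphabet = braille_alphabet()) {
  stopifnot(inherits(alphabet, "braille_alphabet"))
  n <- nrow(alphabet)
  counts <- colSums(alphabet)
  if (any(counts == 0L) || any(counts == n)) {
    warning("degenerate alphabet: some dot is present in all or no letters; ",
            "the corresponding cue validity is undefined (NA)")
  }
  cv_p <- ifelse(counts == 0, NA_real_, 1 / counts)
  cv_a <- ifelse(counts == n, NA_real_, 1 / (n - counts))
  data.frame(
    dot = 1:6,
    prevalence = counts / n,
    informativeness = binary_entropy(counts / n),
    cv_presence = cv_p,
    cv_absence = cv_a,
    row.names = NULL
  )
}

#' Per-letter informativeness scores
#'
#' Averages the dot-level binary-entropy informativeness over each letter's
#' dots. The conventional definition (`from = "present"`) averages over the
#' raised dots, so a single-dot letter scores exactly its dot's entropy.
#' `from = "absent"` averages over the lowered positions instead; this
#' complement is provided because it, rather than the raised-dot mean, is
#' what reproduces the published same-trial correlations from the packaged
#' matrices (see the methods vignette).
#'
#' @param alphabet A [braille_alphabet()].
#' @param stats Output of [dot_statistics()] for that alphabet.
#' @param from Average over `"present"` (raised, default) or `"absent"`
#'   dot positions.
#' @return A data frame with columns `letter` and `score` (bits).
#' @examples
#' li <- letter_informativeness(braille_alphabet())
#' subset(li, letter == "e") # (H1 + H5) / 2 = 0.853
#' @export
letter_informativeness <- function(alphabet = braille_alphabet(),
                                   stats = dot_statistics(alphabet),
                                   from = c("present", "absent")) {
  stopifnot(inherits(alphabet, "braille_alphabet"),
            nrow(stats) == 6L, !is.null(stats$informativeness))
  from <- match.arg(from)
  H <- stats$informativeness
  score <- apply(alphabet, 1L, function(row) {
    sel <- if (from == "present") row == 1 else row == 0
    mean(H[sel])
  })
  data.frame(letter = rownames(alphabet), score = unname(score),
             row.names = NULL, stringsAsFactors = FALSE)
}
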