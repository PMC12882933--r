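#' The 26-letter braille alphabet as binary dot patterns
#'
#' Builds the standard (Grade 1, Latin) braille alphabet. Each letter is a
#' cell of six dot positions numbered column-major: 1, 2, 3 down the left
#' column and 4, 5, 6 down the right column. The first decade (a-j) uses
#' only the top two rows; k-t repeat those patterns with dot 3 added; u, v,
#' x, y, z add dot 6 to k, l, m, n, o; and w (a later addition to the
#' system) is the 180-degree rotation of r.
#'
#' @return A 26 x 6 binary matrix of class `"braille_alphabet"`, rows named
#'   `a`-`z`, columns `d1`-`d6`; entry 1 means the dot is raised.
#' @examples
#' ab <- braille_alphabet()
#' ab["w", ]        # 0 1 0 1 1 1
#' rowSums(ab)      # number of raised dots per letter
#' @export
braille_alphabet <- function() {
  base <- list(
    a = 1, b = c(1, 2), c = c(1, 4), d = c(1, 4, 5), e = c(1, 5),
    f = c(1, 2, 4), g = c(1, 2, 4, 5), h = c(1, 2, 5), i = c(2, 4),
    j = c(2, 4, 5)
  )
  pats <- vector("list", 26)
  names(pats) <- letters
  pats[1:10] <- base
  for (i in 1:10) pats[[i + 10]] <- sort(c(base[[i]], 3))
  from_third <- c(u = "k", v = "l", x = "m", y = "n", z = "o")
  for (nm in names(from_third)) {
    pats[[nm]] <- sort(c(pats[[from_third[[nm]]]], 6))
  }
  rotation <- c(6, 5, 4, 3, 2, 1) # 1<->6, 2<->5, 3<->4
  pats[["w"]] <- sort(rotation[pats[["r"]]])

  m <- t(vapply(pats, function(p) as.integer(1:6 %in% p), integer(6)))
  dimnames(m) <- list(letters, paste0("d", 1:6))
  if (any(rowSums(m) == 0)) {
    stop("internal error: empty braille cell in derived alphabet")
  }
  if (anyDuplicated(m)) {
    stop("internal error: duplicated dot pattern in derived alphabet")
  }
  structure(m, class = c("braille_alphabet", "matrix"))
}

#' @export
print.braille_alphabet <- function(x, ...) {
  cat("braille alphabet: 26 letters, 6 dot positions (1-3 left column,",
      "4-6 right)\n")
  print(unclass(x))
  invisible(x)
}

#' @export
as.data.frame.braille_alphabet <- function(x, ...) {
  data.frame(letter = rownames(x), unclass(x), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Proportion of letters carrying a given dot
#'
#' @param alphabet A [braille_alphabet()].
#' @param dot Dot position, an integer in 1-6.
#' @return The count of letters with the dot raised divided by the number of
#'   letters.
#' @examples
#' dot_prevalence(braille_alphabet(), 5) # 0.5
#' @export
dot_prevalence <- function(alphabet, dot) {
  stopifnot(inherits(alphabet, "braille_alphabet"))
  if (length(dot) != 1L || !dot %in% 1:6) {
    stop("`dot` must be a single position in 1..6")
  }
  mean(alphabet[, dot])
}

#' Hamming distance between two dot patterns
#'
#' Number of dot positions at which two patterns differ.
#'
#' @param x,y Either single letters (`"a"`-`"z"`, looked up in `alphabet`)
#'   or binary vectors of length 6.
#' @param alphabet Alphabet used to resolve letter arguments.
#' @return Integer count in 0-6.
#' @examples
#' pattern_mismatch("k", "u") # 1: they differ only at dot 6
#' @export
pattern_mismatch <- function(x, y, alphabet = braille_alphabet()) {
  as_pattern <- function(p) {
    if (is.character(p)) {
      stopifnot(length(p) == 1L, p %in% rownames(alphabet))
      return(alphabet[p, ])
    }
    stopifnot(length(p) == 6L, all(p %in% c(0, 1)))
    as.numeric(p)
  }
  sum(as_pattern(x) != as_pattern(y))
}

#' All pairwise Hamming distances over an alphabet
#'
#' @param alphabet A [braille_alphabet()].
#' @return A symmetric 26 x 26 integer matrix of dot mismatch counts.
#' @export
mismatch_matrix <- function(alphabet = braille_alphabet()) {
  m <- unclass(alphabet)
  # Hamming distance for binary rows via cross products
  ones <- m %*% t(m)
  zeros <- (1 - m) %*% t(1 - m)
  out <- ncol(m) - ones - zeros
  storage.mode(out) <- "integer"
  out
}

#' Write an alphabet as delimited text
#'
#' One row per letter with columns `letter,d1,...,d6` holding 0/1 flags.
#'
#' @param alphabet A [braille_alphabet()].
#' @param path Output file path.
#' @export
write_alphabet <- function(alphabet, path) {
  utils::write.csv(as.data.frame(alphabet), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
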