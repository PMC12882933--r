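#' Read a letter-pair matrix from delimited text
#'
#' Expects a 27 x 27 layout: a header row `letter,a,...,z`, one row per
#' letter, optionally preceded by `#` metadata comment lines (`# kind:`,
#' `# provenance:`, `# seed:`). Values are parsed at full precision;
#' symmetry is verified and recorded, not assumed.
#'
#' @param path Input file.
#' @param kind Override the matrix kind; default taken from the `# kind:`
#'   metadata line, else `"dissimilarity"`.
#' @return A [pair_matrix()].
#' @export
read_pair_matrix <- function(path, kind = NULL) {
  header <- grep("^#", readLines(path, n = 10), value = TRUE)
  if (is.null(kind)) {
    kl <- grep("^# kind:", header, value = TRUE)
    kind <- if (length(kl)) sub("^# kind:\\s*", "", kl[1]) else "dissimilarity"
  }
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (names(df)[1] != "letter" || ncol(df) != 27L || nrow(df) != 26L) {
    stop("malformed matrix file: expected header 'letter,a,...,z' and 26 rows")
  }
  if (!identical(df$letter, letters) ||
      !identical(names(df)[-1], letters)) {
    stop("malformed matrix file: rows/columns must be a-z in order")
  }
  v <- as.matrix(df[, -1])
  if (!is.numeric(v) || anyNA(v)) stop("non-numeric cell in matrix file")
  dimnames(v) <- list(letters, letters)
  out <- pair_matrix(v, kind = kind)
  prov <- grep("^# provenance:", header, value = TRUE)
  if (length(prov)) {
    attr(out, "provenance") <- sub("^# provenance:\\s*", "", prov[1])
  }
  out
}

#' Write a letter-pair matrix as delimited text
#'
#' Canonical a-z ordering, full precision, with `#` metadata lines
#' recording kind, symmetry, and optional provenance and seed.
#'
#' @param m A [pair_matrix()].
#' @param path Output file.
#' @param provenance Optional provenance string.
#' @param seed Optional seed to record.
#' @export
write_pair_matrix <- function(m, path, provenance = NULL, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# kind: %s", attr(m, "kind")), con)
  writeLines(sprintf("# symmetric: %s", isTRUE(attr(m, "symmetric"))), con)
  if (!is.null(provenance)) {
    writeLines(sprintf("# provenance: %s", provenance), con)
  }
  if (!is.null(seed)) writeLines(sprintf("# seed: %s", seed), con)
  v <- unclass(m)
  txt <- matrix(sprintf("%.17g", v), nrow(v), dimnames = dimnames(v))
  df <- data.frame(letter = rownames(m), txt, check.names = FALSE)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Packaged dissimilarity matrices
#'
#' Loads the published 26 x 26 matrices shipped with the package:
#' `"accuracy"` (proportion correct per ordered pair, symmetrized) and
#' `"rt"` (reciprocal of symmetrized median adjusted RT).
#'
#' @param which `"accuracy"` or `"rt"`.
#' @return A symmetric [pair_matrix()] (`accuracy` or `dissimilarity` kind).
#' @export
braille_fixture <- function(which = c("accuracy", "rt")) {
  which <- match.arg(which)
  file <- switch(which, accuracy = "table2_accuracy.csv",
                 rt = "table3_rt.csv")
  path <- system.file("extdata", file, package = "braillesim",
                      mustWork = TRUE)
  read_pair_matrix(path)
}

#' Read / write same-different trial logs
#'
#' Delimited text with header `participant,session,list,trial,first,second,
#' trial_type,response,rt_s` (RT in seconds). On read, `trial_type`
#' consistency with letter equality is validated.
#'
#' @param path File path.
#' @return `read_trials()`: the validated trial data frame (a warning and
#'   zero rows for a header-only file).
#' @export
read_trials <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("participant", "session", "list", "trial", "first", "second",
            "trial_type", "response", "rt_s")
  if (!identical(names(df), need)) {
    stop("trial file schema must be: ", paste(need, collapse = ","))
  }
  df$participant <- as.character(df$participant)
  if (nrow(df) == 0L) {
    warning("empty trial file")
    return(df)
  }
  bad <- (df$first == df$second) != (df$trial_type == "same")
  if (any(bad)) {
    stop("inconsistent trial_type at rows: ",
         paste(utils::head(which(bad), 5), collapse = ", "))
  }
  if (any(df$rt_s <= 0)) stop("nonpositive rt_s")
  df
}

#' @rdname read_trials
#' @param trials Trial data frame.
#' @param seed Optional seed recorded in a `#` header line.
#' @export
write_trials <- function(trials, path, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(seed)) writeLines(sprintf("# seed: %s", seed), con)
  utils::write.csv(trials, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a dendrogram as a Newick tree
#'
#' Branch lengths place each internal node at half its merge height (the
#' `ape` convention for `hclust` trees), so that the path length between
#' any two leaves equals their cophenetic distance.
#'
#' @param dendrogram An [stats::hclust] tree.
#' @param path Output file.
#' @return The Newick string (invisibly if written to `path`).
#' @export
export_newick <- function(dendrogram, path = NULL) {
  phy <- ape::as.phylo(dendrogram)
  str <- ape::write.tree(phy)
  if (!is.null(path)) {
    writeLines(str, path)
    return(invisible(str))
  }
  str
}
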