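#' Normalize item strings
#'
#' Lowercases, trims surrounding whitespace and joins internal whitespace with
#' underscores, matching the vocabulary convention of common pre-trained
#' embedding models ("polar bear" -> "polar_bear").
#'
#' @param x character vector of item strings.
#' @return character vector of normalized items.
#' @export
normalize_item <- function(x) {
  x <- tolower(trimws(as.character(x)))
  gsub("[[:space:]]+", "_", x)
}

#' Construct a word-vector set
#'
#' A `word_vector_set` holds one real-valued vector of fixed dimensionality
#' per unique item. It is the raw semantic representation from which cosine
#' distances are computed.
#'
#' @param items character vector of unique item names.
#' @param vectors numeric matrix, one row per item, `d >= 2` columns.
#' @return object of class `word_vector_set` with fields `items`, `vectors`
#'   (rownames = items) and `dim`.
#' @export
word_vector_set <- function(items, vectors) {
  items <- as.character(items)
  vectors <- as.matrix(vectors)
  if (length(items) != nrow(vectors))
    stop("length(items) must equal nrow(vectors)")
  if (ncol(vectors) < 2L)
    stop("vector dimensionality must be >= 2")
  if (anyDuplicated(items))
    stop("duplicate items after normalization: ",
         paste(unique(items[duplicated(items)]), collapse = ", "))
  if (!all(is.finite(vectors)))
    stop("all vector entries must be finite")
  norms <- sqrt(rowSums(vectors^2))
  if (any(norms == 0))
    stop("zero vector for item(s): ",
         paste(items[norms == 0], collapse = ", "))
  rownames(vectors) <- items
  structure(list(items = items, vectors = vectors, dim = ncol(vectors)),
            class = "word_vector_set")
}

#' @export
print.word_vector_set <- function(x, ...) {
  cat(sprintf("<word_vector_set: %d items, %d dimensions>\n",
              length(x$items), x$dim))
  invisible(x)
}

#' Read word vectors in word2vec text or binary format
#'
#' The text format is UTF-8 with a header line `"vocab_size dim"` followed by
#' one `"word v1 ... vd"` line per word. The binary dialect shares the text
#' header; each entry is then the word terminated by a space, followed by
#' `dim` little-endian float32 values (an optional trailing newline per entry
#' is tolerated).
#'
#' @param path file path.
#' @param format `"text"` or `"binary"`.
#' @param items optional character vector restricting the result to these
#'   items (compared after normalization when `normalize_case = TRUE`).
#' @param normalize_case lowercase/underscore-normalize words and requested
#'   items before matching (default `TRUE`).
#' @param skip_missing if `FALSE` (default) a requested item absent from the
#'   file is an error; if `TRUE` it is dropped with a warning and listed in
#'   the `missing` attribute of the result.
#' @return a [word_vector_set]; if any requested items were skipped, its
#'   `missing` field lists them.
#' @export
load_word_vectors <- function(path, format = c("text", "binary"),
                              items = NULL, normalize_case = TRUE,
                              skip_missing = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  parsed <- if (format == "text") read_w2v_text(path) else read_w2v_binary(path)
  words <- parsed$words
  vecs <- parsed$vectors
  if (normalize_case) words <- normalize_item(words)
  if (anyDuplicated(words)) {
    dups <- unique(words[duplicated(words)])
    warning("duplicate words after normalization (first occurrence kept): ",
            paste(utils::head(dups, 10L), collapse = ", "))
    keep <- !duplicated(words)
    words <- words[keep]
    vecs <- vecs[keep, , drop = FALSE]
  }
  missing <- character(0)
  if (!is.null(items)) {
    want <- if (normalize_case) normalize_item(items) else as.character(items)
    want <- unique(want)
    missing <- setdiff(want, words)
    if (length(missing) > 0L && !skip_missing)
      stop("items without a vector: ", paste(missing, collapse = ", "),
           " (use skip_missing = TRUE to drop them)")
    if (length(missing) > 0L)
      warning(length(missing), " requested item(s) had no vector and were skipped")
    keep <- match(setdiff(want, missing), words)
    words <- words[keep]
    vecs <- vecs[keep, , drop = FALSE]
  }
  vs <- word_vector_set(words, vecs)
  vs$missing <- missing
  vs
}

read_w2v_text <- function(path) {
  con <- file(path, open = "rt", encoding = "UTF-8")
  on.exit(close(con))
  header <- readLines(con, n = 1L)
  hd <- strsplit(trimws(header), "[[:space:]]+")[[1]]
  if (length(hd) != 2L || anyNA(suppressWarnings(as.integer(hd))))
    stop("malformed word2vec header (expected \"vocab_size dim\"): ", header)
  n <- as.integer(hd[1]); d <- as.integer(hd[2])
  lines <- readLines(con)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) != n)
    stop(sprintf("header announces %d words but file body has %d lines", n,
                 length(lines)))
  parts <- strsplit(trimws(lines), "[[:space:]]+")
  bad <- which(vapply(parts, length, 1L) != d + 1L)
  if (length(bad) > 0L)
    stop("line ", bad[1] + 1L, " does not have 1 word + ", d, " values")
  words <- vapply(parts, `[[`, "", 1L)
  vecs <- do.call(rbind, lapply(parts, function(p) as.numeric(p[-1L])))
  if (anyNA(vecs)) stop("non-numeric vector entries in file")
  list(words = words, vectors = vecs)
}

read_w2v_binary <- function(path) {
  con <- file(path, open = "rb")
  on.exit(close(con))
  header_raw <- raw(0)
  repeat {
    b <- readBin(con, "raw", n = 1L)
    if (length(b) == 0L) stop("malformed word2vec header: premature end of file")
    if (b == as.raw(10L)) break
    header_raw <- c(header_raw, b)
  }
  hd <- strsplit(trimws(rawToChar(header_raw)), "[[:space:]]+")[[1]]
  if (length(hd) != 2L || anyNA(suppressWarnings(as.integer(hd))))
    stop("malformed word2vec header (expected \"vocab_size dim\")")
  n <- as.integer(hd[1]); d <- as.integer(hd[2])
  words <- character(n)
  vecs <- matrix(NA_real_, n, d)
  for (i in seq_len(n)) {
    wraw <- raw(0)
    repeat {
      b <- readBin(con, "raw", n = 1L)
      if (length(b) == 0L)
        stop(sprintf("header announces %d words but file ends at word %d", n, i))
      if (b == as.raw(32L)) break
      if (b == as.raw(10L) && length(wraw) == 0L) next  # leading newline sep
      wraw <- c(wraw, b)
    }
    words[i] <- rawToChar(wraw)
    v <- readBin(con, "numeric", n = d, size = 4L, endian = "little")
    if (length(v) != d)
      stop(sprintf("truncated vector for word %d (\"%s\")", i, words[i]))
    vecs[i, ] <- v
  }
  list(words = words, vectors = vecs)
}

#' Write word vectors in word2vec text or binary format
#'
#' @param vs a [word_vector_set].
#' @param path output file path.
#' @param format `"text"` or `"binary"`.
#' @return `path`, invisibly.
#' @export
write_word_vectors <- function(vs, path, format = c("text", "binary")) {
  stopifnot(inherits(vs, "word_vector_set"))
  format <- match.arg(format)
  n <- length(vs$items); d <- vs$dim
  if (format == "text") {
    body <- vapply(seq_len(n), function(i) {
      paste(vs$items[i],
            paste(formatC(vs$vectors[i, ], format = "g", digits = 9),
                  collapse = " "))
    }, "")
    writeLines(c(paste(n, d), body), path, useBytes = TRUE)
  } else {
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeBin(charToRaw(paste0(n, " ", d, "\n")), con)
    for (i in seq_len(n)) {
      writeBin(charToRaw(paste0(vs$items[i], " ")), con)
      writeBin(as.numeric(vs$vectors[i, ]), con, size = 4L, endian = "little")
      writeBin(charToRaw("\n"), con)
    }
  }
  invisible(path)
}

#' Pairwise cosine-distance matrix
#'
#' Computes `D[i, j] = 1 - v_i . v_j / (||v_i|| ||v_j||)` for all item pairs.
#' The formal range is `[0, 2]`; values above 1 occur only for vector pairs
#' with negative cosine similarity and are deliberately not clamped.
#'
#' @param vs a [word_vector_set].
#' @return symmetric numeric matrix with zero diagonal and dimnames set to
#'   the item names.
#' @export
cosine_distance_matrix <- function(vs) {
  stopifnot(inherits(vs, "word_vector_set"))
  V <- vs$vectors
  norms <- sqrt(rowSums(V^2))
  if (any(norms == 0))
    stop("zero-norm vector for item(s): ",
         paste(vs$items[norms == 0], collapse = ", "))
  Vn <- V / norms
  D <- 1 - tcrossprod(Vn)
  D[D < 0] <- 0          # numerical noise below zero only
  D <- (D + t(D)) / 2
  diag(D) <- 0
  dimnames(D) <- list(vs$items, vs$items)
  D
}

#' Validate a cosine-distance matrix
#'
#' Checks symmetry (within `tol`), zero diagonal and the `[0, 2]` range.
#'
#' @param D numeric matrix with dimnames.
#' @param tol symmetry tolerance.
#' @param max_value upper bound on entries; 2 for cosine distances, `Inf`
#'   for general dissimilarity matrices.
#' @return `D`, invisibly; errors on violation.
#' @export
validate_distance_matrix <- function(D, tol = 1e-9, max_value = 2) {
  if (!is.matrix(D) || nrow(D) != ncol(D)) stop("D must be a square matrix")
  if (is.null(rownames(D))) stop("D must carry item names as dimnames")
  if (max(abs(D - t(D))) > tol) stop("D is not symmetric within ", tol)
  if (max(abs(diag(D))) > tol) stop("D diagonal is not zero")
  if (min(D) < -tol || max(D) > max_value + tol)
    stop("D entries outside [0, ", max_value, "]")
  invisible(D)
}

#' Read / write a labeled distance-matrix CSV
#'
#' The CSV has item names in the first column and as column headers.
#'
#' @param D distance matrix with dimnames.
#' @param path file path.
#' @return `write_distance_csv` returns `path` invisibly;
#'   `read_distance_csv` returns the labeled matrix.
#' @export
write_distance_csv <- function(D, path) {
  utils::write.csv(as.data.frame(D), path, row.names = TRUE)
  invisible(path)
}

#' @rdname write_distance_csv
#' @export
read_distance_csv <- function(path) {
  df <- utils::read.csv(path, row.names = 1L, check.names = FALSE)
  D <- as.matrix(df)
  storage.mode(D) <- "double"
  validate_distance_matrix(D, tol = 1e-6)
  D
}
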