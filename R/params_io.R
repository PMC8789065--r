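#' Read and write Potts parameters in the plain-text h/J dialect
#'
#' The on-disk format is line-oriented plain text over the fixed 21-symbol
#' ordering `"-ACDEFGHIKLMNPQRSTVWY"` (or the model's own reduced alphabet),
#' with 0-based indices:
#' \preformatted{
#' h i a value
#' J i j a b value
#' }
#' `write_potts_params()` emits fields first, then the upper-triangular
#' couplings (`i < j`) only; `read_potts_params()` symmetrizes, filling
#' `J[j,i,b,a]` from every `J[i,j,a,b]` line. Entries absent from the file are
#' zero (a warning reports how many field entries were missing). The
#' write-then-read round trip is exact.
#'
#' @param path File path.
#' @param L,q Dimensions of the model in the file.
#' @param alphabet Alphabet of length `q`.
#' @return `read_potts_params()` returns a [potts_model()];
#'   `write_potts_params()` returns `path` invisibly.
#' @export
read_potts_params <- function(path, L, q = 21, alphabet = default_alphabet(q)) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty parameter file")
  toks <- strsplit(trimws(lines), "[[:space:]]+")
  tag <- vapply(toks, `[[`, "", 1L)
  if (!all(tag %in% c("h", "J")))
    stop("malformed line(s): unknown record tag ",
         paste(unique(setdiff(tag, c("h", "J"))), collapse = " "))
  nf <- lengths(toks)
  if (any(tag == "h" & nf != 4L) || any(tag == "J" & nf != 6L))
    stop("malformed line(s): wrong field count")
  h <- matrix(0, L, q)
  J <- array(0, c(L, L, q, q))
  hset <- matrix(FALSE, L, q)
  ht <- toks[tag == "h"]
  if (length(ht)) {
    hm <- matrix(as.numeric(unlist(lapply(ht, `[`, 2:4))), ncol = 3L, byrow = TRUE)
    i <- hm[, 1L] + 1L; a <- hm[, 2L] + 1L
    if (anyNA(hm) || any(i < 1L | i > L | a < 1L | a > q))
      stop("h line with index out of range or non-numeric value")
    h[cbind(i, a)] <- hm[, 3L]
    hset[cbind(i, a)] <- TRUE
  }
  jt <- toks[tag == "J"]
  if (length(jt)) {
    jm <- matrix(as.numeric(unlist(lapply(jt, `[`, 2:6))), ncol = 5L, byrow = TRUE)
    i <- jm[, 1L] + 1L; j <- jm[, 2L] + 1L
    a <- jm[, 3L] + 1L; b <- jm[, 4L] + 1L
    if (anyNA(jm) || any(i < 1L | i > L | j < 1L | j > L | a < 1L | a > q |
                         b < 1L | b > q))
      stop("J line with index out of range or non-numeric value")
    if (any(i == j)) stop("J line with i == j (diagonal blocks must be absent)")
    J[cbind(i, j, a, b)] <- jm[, 5L]
    J[cbind(j, i, b, a)] <- jm[, 5L]
  }
  if (!all(hset))
    warning(sum(!hset), " field entries missing from ", path, "; filled as 0")
  potts_model(h, J, alphabet)
}

#' @rdname read_potts_params
#' @param model A [potts_model()] to serialize.
#' @export
write_potts_params <- function(model, path) {
  stopifnot(inherits(model, "potts_model"))
  L <- model$L; q <- model$q
  con <- file(path, "w")
  on.exit(close(con))
  ia <- expand.grid(a = seq_len(q), i = seq_len(L))
  writeLines(sprintf("h %d %d %.17g", ia$i - 1L, ia$a - 1L,
                     model$h[cbind(ia$i, ia$a)]), con)
  if (L >= 2L) for (i in seq_len(L - 1L)) for (j in (i + 1L):L) {
    blk <- model$J[i, j, , ]
    nz <- which(blk != 0, arr.ind = TRUE)
    if (nrow(nz))
      writeLines(sprintf("J %d %d %d %d %.17g", i - 1L, j - 1L,
                         nz[, 1L] - 1L, nz[, 2L] - 1L, blk[nz]), con)
  }
  invisible(path)
}
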