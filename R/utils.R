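#' @noRd
abort_if <- function(cond, msg, class) {
  if (cond) stop(errorCondition(msg, class = c(class, "itfpipe_error")))
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Box (moving-window) sums of a matrix via integral images
#'
#' Window is (2r+1) x (2r+1); out-of-image area is treated as zero but the
#' companion count matrix from [box_count_px()] gives the effective window
#' size so means are unbiased at borders.
#' @noRd
box_sum <- function(m, r) {
  nr <- nrow(m); nc <- ncol(m)
  cs <- matrix(0, nr + 1L, nc + 1L)
  cs[-1L, -1L] <- apply(apply(m, 2L, cumsum), 1L, cumsum) |> t()
  i1 <- pmax(seq_len(nr) - r, 1L); i2 <- pmin(seq_len(nr) + r, nr)
  j1 <- pmax(seq_len(nc) - r, 1L); j2 <- pmin(seq_len(nc) + r, nc)
  cs[i2 + 1L, j2 + 1L, drop = FALSE] - cs[i1, j2 + 1L, drop = FALSE] -
    cs[i2 + 1L, j1, drop = FALSE] + cs[i1, j1, drop = FALSE]
}

#' @noRd
box_count_px <- function(nr, nc, r) {
  ni <- pmin(seq_len(nr) + r, nr) - pmax(seq_len(nr) - r, 1L) + 1L
  nj <- pmin(seq_len(nc) + r, nc) - pmax(seq_len(nc) - r, 1L) + 1L
  outer(ni, nj)
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items;
#' 1 for identical partitions (up to label names), ~0 for independent ones.
#'
#' @param a,b vectors of cluster labels, same length.
#' @return A single number in \[-1, 1\].
#' @export
adjusted_rand_index <- function(a, b) {
  abort_if(length(a) != length(b), "labelings must have equal length",
           "itfpipe_invalid_parameter")
  tab <- table(a, b)
  n <- length(a)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  expected <- sum_a * sum_b / ch2(n)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)   # both partitions trivial
  (sum_ij - expected) / (max_idx - expected)
}

#' Write / read ASCII portable graymap (PGM, P2)
#'
#' Plain-text raster interchange used for masks and single-channel images.
#' Values are clamped to \[0, maxval\] integers.
#'
#' @param m numeric matrix (row = image row).
#' @param path file path.
#' @param maxval maximum gray value written to the header.
#' @return `write_pgm()` the path invisibly; `read_pgm()` an integer matrix.
#' @export
write_pgm <- function(m, path, maxval = 255L) {
  m <- pmin(pmax(round(m), 0L), maxval)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(m), nrow(m)), as.character(maxval)), con)
  write(t(m), con, ncolumns = ncol(m))
  invisible(path)
}

#' @rdname write_pgm
#' @export
read_pgm <- function(path) {
  toks <- scan(path, what = character(), quiet = TRUE, comment.char = "#")
  abort_if(toks[1] != "P2", "not an ASCII PGM (P2) file", "itfpipe_schema")
  nc <- as.integer(toks[2]); nr <- as.integer(toks[3])
  vals <- as.integer(toks[-(1:4)])
  matrix(vals, nr, nc, byrow = TRUE)
}

#' Write / read ASCII portable pixmap (PPM, P3) for RGB rasters
#'
#' @param arr numeric array height x width x 3.
#' @param path file path.
#' @return `write_ppm()` the path invisibly; `read_ppm()` an integer array.
#' @export
write_ppm <- function(arr, path) {
  abort_if(length(dim(arr)) != 3L || dim(arr)[3] != 3L,
           "expected an H x W x 3 array", "itfpipe_schema")
  arr <- pmin(pmax(round(arr), 0L), 255L)
  nr <- dim(arr)[1]; nc <- dim(arr)[2]
  # interleave channels pixel-by-pixel, row-major
  flat <- aperm(arr, c(3L, 2L, 1L))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P3", paste(nc, nr), "255"), con)
  write(as.vector(flat), con, ncolumns = 15L)
  invisible(path)
}

#' @rdname write_ppm
#' @export
read_ppm <- function(path) {
  toks <- scan(path, what = character(), quiet = TRUE, comment.char = "#")
  abort_if(toks[1] != "P3", "not an ASCII PPM (P3) file", "itfpipe_schema")
  nc <- as.integer(toks[2]); nr <- as.integer(toks[3])
  vals <- as.integer(toks[-(1:4)])
  aperm(array(vals, c(3L, nc, nr)), c(3L, 2L, 1L))
}

#' Write / read a numeric matrix as TSV with row ids
#' @param m matrix with rownames and colnames.
#' @param path file path.
#' @param id_col name of the first (row id) column.
#' @return `write_matrix_tsv()` the path invisibly; `read_matrix_tsv()` a matrix.
#' @export
write_matrix_tsv <- function(m, path, id_col = "id") {
  df <- data.frame(rownames(m), m, check.names = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
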