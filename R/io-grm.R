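#' Kinship matrix input/output
#'
#' Two interchange formats: plain dense text (tab-separated, header row of
#' sample ids, symmetric) and the GCTA binary GRM pair `.grm.bin`
#' (float32 lower triangle including the diagonal, row-major) plus
#' `.grm.id` (family and individual id columns).
#'
#' @param K symmetric matrix with sample ids as dimnames (text writer) or
#'   plain matrix (binary writer with `ids`).
#' @param path output file (text) or path prefix (binary: `.grm.bin` /
#'   `.grm.id` appended).
#' @param ids sample identifiers for the binary format.
#' @return The input path, invisibly (writers); the matrix (readers).
#' @name kinshipIO
NULL

#' @rdname kinshipIO
#' @export
writeKinshipText <- function(K, path) {
  ids <- rownames(K) %||% paste0("sample", seq_len(nrow(K)))
  df <- as.data.frame(K)
  names(df) <- ids
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname kinshipIO
#' @export
readKinshipText <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE)
  K <- as.matrix(df)
  rownames(K) <- colnames(K)
  if (!isSymmetric(K, tol = 1e-6))
    stop("kinship text file is not symmetric")
  K
}

#' @rdname kinshipIO
#' @export
writeGRMBinary <- function(K, path, ids = NULL) {
  n <- nrow(K)
  if (is.null(ids)) ids <- rownames(K) %||% paste0("sample", seq_len(n))
  lower <- K[upper.tri(K, diag = TRUE)]  # column-wise upper == row-wise lower
  con <- file(paste0(path, ".grm.bin"), "wb")
  writeBin(as.numeric(lower), con, size = 4)
  close(con)
  utils::write.table(data.frame(fid = ids, iid = ids),
                     paste0(path, ".grm.id"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE, sep = "\t")
  invisible(path)
}

#' @rdname kinshipIO
#' @export
readGRMBinary <- function(path) {
  idf <- utils::read.table(paste0(path, ".grm.id"), header = FALSE,
                           stringsAsFactors = FALSE)
  n <- nrow(idf)
  m <- n * (n + 1) / 2
  vals <- readBin(paste0(path, ".grm.bin"), what = "numeric", n = m + 1,
                  size = 4)
  if (length(vals) != m)
    stop("GRM binary size mismatch: expected ", m, " float32 values")
  K <- matrix(0, n, n)
  K[upper.tri(K, diag = TRUE)] <- vals
  K <- K + t(K) - diag(diag(K))
  dimnames(K) <- list(idf[[2]], idf[[2]])
  K
}
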