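#' Read PLINK 1 binary genotypes
#'
#' Decodes a `.bed/.bim/.fam` fileset (SNP-major PLINK 1 binary format:
#' magic bytes 0x6c 0x1b, mode byte 0x01, then one 2-bit code per genotype
#' packed 4 per byte, little-endian within the byte). Codes count copies of
#' the A1 allele as stored in the `.bim`: `00` = 2 copies, `10` = 1 copy,
#' `11` = 0 copies, `01` = missing.
#'
#' @param prefix path prefix (without extension).
#' @param maf optional MAF vector overriding the sample-computed values.
#' @param dropMonomorphic drop monomorphic SNPs instead of failing.
#' @return A [GenotypePanel-class]; `.bim` rows are attached as the
#'   `"bim"` attribute.
#' @export
readPlink <- function(prefix, maf = NULL, dropMonomorphic = FALSE) {
  bed <- paste0(prefix, ".bed")
  bim <- paste0(prefix, ".bim")
  fam <- paste0(prefix, ".fam")
  for (f in c(bed, bim, fam))
    if (!file.exists(f)) stop("missing PLINK file: ", f)

  famDf <- if (file.size(fam) == 0) {
    data.frame(V1 = character(), V2 = character())
  } else {
    utils::read.table(fam, header = FALSE, stringsAsFactors = FALSE)
  }
  bimDf <- utils::read.table(bim, header = FALSE, stringsAsFactors = FALSE,
                             colClasses = c("character", "character",
                                            "numeric", "integer",
                                            "character", "character"))
  n <- nrow(famDf)
  p <- nrow(bimDf)

  raw <- readBin(bed, what = "raw", n = file.size(bed))
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("bad .bed magic bytes (not a PLINK 1 binary file)")
  if (raw[3] != as.raw(0x01))
    stop("only SNP-major .bed files are supported (mode byte 0x01)")
  bytesPerSnp <- ceiling(n / 4)
  need <- 3 + bytesPerSnp * p
  if (length(raw) < need)
    stop("truncated .bed: expected ", need, " bytes, found ", length(raw),
         " (first missing byte at offset ", length(raw), ")")

  G <- matrix(NA_real_, n, p)
  if (p > 0 && n > 0) {
    body <- as.integer(raw[3 + seq_len(bytesPerSnp * p)])
    codes <- matrix(0L, 4 * bytesPerSnp, p)
    bm <- matrix(body, bytesPerSnp, p)
    codes[seq(1, 4 * bytesPerSnp, by = 4), ] <- bm %% 4L
    codes[seq(2, 4 * bytesPerSnp, by = 4), ] <- (bm %/% 4L) %% 4L
    codes[seq(3, 4 * bytesPerSnp, by = 4), ] <- (bm %/% 16L) %% 4L
    codes[seq(4, 4 * bytesPerSnp, by = 4), ] <- (bm %/% 64L) %% 4L
    codes <- codes[seq_len(n), , drop = FALSE]
    ## 00 -> 2 copies of A1, 10 -> 1, 11 -> 0, 01 -> missing
    lut <- c(`0` = 2, `1` = NA, `2` = 1, `3` = 0)
    G[] <- lut[codes + 1L]
  }
  GenotypePanel(G, maf = maf,
                sampleIds = as.character(famDf[[2]]),
                snpIds = as.character(bimDf[[2]]),
                dropMonomorphic = dropMonomorphic) -> panel
  attr(panel, "bim") <- bimDf
  panel
}

#' Write PLINK 1 binary genotypes
#'
#' Inverse of [readPlink()]: writes `.bed` (SNP-major), `.bim` and `.fam`
#' for a genotype panel. Genotypes are written as A1 counts with alleles
#' labelled A/B unless a `bim` attribute or argument supplies real ones.
#'
#' @param panel a [GenotypePanel-class].
#' @param prefix output path prefix.
#' @param bim optional 6-column `.bim` data.frame (chromosome, id, cM,
#'   position, A1, A2).
#' @param phenotype optional phenotype written to the `.fam` sixth column
#'   (default -9).
#' @return `prefix`, invisibly.
#' @export
writePlink <- function(panel, prefix, bim = NULL, phenotype = NULL) {
  G <- genotypes(panel)
  n <- nrow(G)
  p <- ncol(G)
  if (is.null(bim)) bim <- attr(panel, "bim")
  if (is.null(bim))
    bim <- data.frame(chr = 1, id = snpIds(panel), cm = 0,
                      pos = seq_len(p), a1 = "A", a2 = "B")
  fam <- data.frame(fid = sampleIds(panel), iid = sampleIds(panel),
                    pat = 0, mat = 0, sex = 0,
                    phe = if (is.null(phenotype)) -9 else phenotype)
  utils::write.table(bim, paste0(prefix, ".bim"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE, sep = "\t")
  utils::write.table(fam, paste0(prefix, ".fam"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE, sep = "\t")

  ## genotype value -> 2-bit code
  code <- matrix(1L, n, p)  # missing
  code[!is.na(G) & G == 2] <- 0L
  code[!is.na(G) & G == 1] <- 2L
  code[!is.na(G) & G == 0] <- 3L
  bytesPerSnp <- ceiling(n / 4)
  padded <- matrix(0L, 4 * bytesPerSnp, p)  # pad bits zeroed, as PLINK does
  padded[seq_len(n), ] <- code
  i1 <- seq(1, 4 * bytesPerSnp, by = 4)
  bytes <- padded[i1, , drop = FALSE] + 4L * padded[i1 + 1, , drop = FALSE] +
    16L * padded[i1 + 2, , drop = FALSE] + 64L * padded[i1 + 3, , drop = FALSE]
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(as.vector(bytes)), con)
  invisible(prefix)
}
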