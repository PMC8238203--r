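# .nss container: line 1 is a JSON header (sample table + locus table),
# every following line one stored code as "locusIndex <TAB> sampleIndex <TAB>
# code" (1-based indices). Zero codes are never written, which is what makes
# the file small; the triplet form makes the round trip lossless and
# auditable with standard text tools.

#' Write a GenotypeStore to the .nss container format
#'
#' @param store A `GenotypeStore`.
#' @param path Output path.
#' @param compress Write gzip-compressed text (default `FALSE`, plain text).
#' @return Invisibly, `path`.
#' @export
writeGenotypeStore <- function(store, path, compress = FALSE) {
  li <- lociInfo(store); rownames(li) <- NULL
  si <- sampleInfo(store); rownames(si) <- NULL
  header <- jsonlite::toJSON(
    list(format = "nss1",
         n_loci = nrow(store), n_samples = ncol(store),
         loci = li, samples = si),
    dataframe = "columns", na = "null", auto_unbox = TRUE, digits = NA)
  tg <- methods::as(genoCodes(store), "TsparseMatrix")
  ord <- order(tg@i, tg@j)
  con <- if (compress) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(as.character(header), con)
  if (length(ord))
    writeLines(paste(tg@i[ord] + 1L, tg@j[ord] + 1L, as.integer(tg@x[ord]),
                     sep = "\t"), con)
  invisible(path)
}

#' Read a GenotypeStore from a .nss container
#'
#' @param path Path written by [writeGenotypeStore()] (plain or gzipped).
#' @return A [GenotypeStore-class].
#' @export
readGenotypeStore <- function(path) {
  con <- file(path, "r")  # file() transparently reads gzip
  on.exit(close(con))
  header <- jsonlite::fromJSON(readLines(con, n = 1L))
  if (is.null(header$format) || header$format != "nss1")
    stop("not an nss1 container: ", path, call. = FALSE)
  body <- readLines(con)
  loci <- as.data.frame(header$loci, stringsAsFactors = FALSE)
  samples <- as.data.frame(header$samples, stringsAsFactors = FALSE)
  nl <- header$n_loci
  ns <- header$n_samples
  if (length(body)) {
    parts <- strsplit(body, "\t", fixed = TRUE)
    m <- matrix(as.integer(unlist(parts)), ncol = 3, byrow = TRUE)
    g <- Matrix::sparseMatrix(i = m[, 1], j = m[, 2], x = m[, 3],
                              dims = c(nl, ns))
  } else {
    g <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                              dims = c(nl, ns))
  }
  GenotypeStore(g, loci, samples)
}
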