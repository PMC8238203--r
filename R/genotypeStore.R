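#' @importFrom Matrix sparseMatrix drop0 rowSums colSums t
NULL

#' Construct a GenotypeStore from a code matrix and metadata
#'
#' @param geno Loci-by-samples matrix (dense or sparse) of genotype codes in
#'   \{-1, 0, 1, 2\}; zeros are dropped from storage.
#' @param loci `data.frame` with columns `chr`, `pos`, `ref`, `alt` and
#'   optionally `gene`, one row per locus.
#' @param samples `data.frame` of per-sample phenotypes with at least
#'   `sample_id`; typically also `cohort`, `status` ("case"/"control"),
#'   `age`, `braak`, `apoe`. Row order defines sample order.
#' @return A [GenotypeStore-class] object.
#' @export
GenotypeStore <- function(geno, loci, samples) {
  g <- methods::as(methods::as(geno, "CsparseMatrix"), "generalMatrix")
  g <- Matrix::drop0(g)
  if (is.null(loci$gene)) loci$gene <- NA_character_
  loci <- as.data.frame(lapply(loci, unname), stringsAsFactors = FALSE)
  rd <- S4Vectors::DataFrame(loci)
  rownames(g) <- paste(loci$chr, loci$pos, loci$alt, sep = ":")
  colnames(g) <- as.character(samples$sample_id)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(geno = g), rowData = rd,
    colData = S4Vectors::DataFrame(samples, row.names = as.character(samples$sample_id)))
  methods::new("GenotypeStore", se)
}

#' @rdname GenotypeStore
#' @param store A `GenotypeStore`.
#' @return `genoCodes` returns the sparse code matrix; `lociInfo` and
#'   `sampleInfo` the locus and sample tables as `data.frame`s; `locusKeys`
#'   the `"chr:pos:alt"` keys.
#' @export
genoCodes <- function(store) SummarizedExperiment::assay(store, "geno")

#' @rdname GenotypeStore
#' @export
lociInfo <- function(store) as.data.frame(SummarizedExperiment::rowData(store))

#' @rdname GenotypeStore
#' @export
sampleInfo <- function(store) as.data.frame(SummarizedExperiment::colData(store))

#' @rdname GenotypeStore
#' @export
locusKeys <- function(store) rownames(store)

#' Encode diploid GT calls as integer genotype codes
#'
#' Maps a VCF GT string over alleles \{0, 1, .\} to the sparse integer code:
#' 0 for ref/ref, 1 for heterozygous, 2 for alt/alt and -1 when either allele
#' is missing. Phased (`|`) and unphased (`/`) separators are equivalent.
#'
#' @param gt Character vector of diploid GT calls (e.g. `"0/1"`, `"1|1"`,
#'   `"./."`). `NA` encodes to -1.
#' @return Integer vector of codes in \{-1, 0, 1, 2\}.
#' @export
#' @examples
#' encodeGenotype(c("0/0", "0/1", "1|0", "1/1", "./.", "0/."))
encodeGenotype <- function(gt) {
  gt <- as.character(gt)
  a1 <- substr(gt, 1L, 1L)
  a2 <- substr(gt, 3L, 3L)
  ok <- !is.na(gt) & nchar(gt) == 3L & substr(gt, 2L, 2L) %in% c("/", "|")
  bad <- ok & !(a1 %in% c("0", "1", ".") & a2 %in% c("0", "1", "."))
  if (any(bad)) {
    hi <- ok & (a1 %in% as.character(2:9) | a2 %in% as.character(2:9))
    if (any(hi)) stop("multi-allelic genotype call (allele index >= 2) is unsupported: ",
                      gt[which(hi)[1]], call. = FALSE)
    stop("malformed GT call: ", gt[which(bad)[1]], call. = FALSE)
  }
  if (any(!ok & !is.na(gt)))
    stop("malformed GT call: ", gt[which(!ok & !is.na(gt))[1]], call. = FALSE)
  out <- rep(-1L, length(gt))
  det <- ok & a1 != "." & a2 != "."
  out[det] <- (a1[det] == "1") + (a2[det] == "1")
  out
}

#' Read a VCF into a sparse GenotypeStore
#'
#' Parses GT fields of a VCF v4.x file (all other FORMAT fields are ignored)
#' and encodes them with [encodeGenotype()]. Multi-allelic records are
#' skipped with a warning; pre-splitting with an external normalizer is the
#' supported path for such records. Sample order follows the metadata table.
#'
#' @param vcfPath Path to a VCF file (plain or gzipped).
#' @param metadata Per-sample metadata `data.frame` (see [GenotypeStore()]);
#'   its `sample_id` values must all be VCF sample columns.
#' @return A [GenotypeStore-class].
#' @export
readVcfGenotypes <- function(vcfPath, metadata) {
  v <- vcfR::read.vcfR(vcfPath, verbose = FALSE)
  fix <- vcfR::getFIX(v, getINFO = TRUE)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt, fixed = TRUE)
  if (any(multi)) {
    warning(sum(multi), " multi-allelic record(s) skipped; split them with a VCF normalizer to retain them")
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1, dimnames = list(NULL, names(gt)))
  ids <- as.character(metadata$sample_id)
  missing <- setdiff(ids, colnames(gt))
  if (length(missing))
    stop("metadata samples absent from VCF: ", paste(missing, collapse = ", "), call. = FALSE)
  keep <- which(!multi)
  gt <- gt[keep, ids, drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  codes <- matrix(encodeGenotype(gsub("\\|", "/", as.vector(gt))),
                  nrow = nrow(gt))
  loci <- data.frame(chr = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
                     ref = fix[, "REF"], alt = fix[, "ALT"],
                     gene = NA_character_, stringsAsFactors = FALSE)
  info <- if ("INFO" %in% colnames(fix)) fix[, "INFO"] else rep(NA_character_, nrow(fix))
  hasGene <- !is.na(info) & grepl("GENE=", info)
  loci$gene[hasGene] <- sub(".*GENE=([^;]+).*", "\\1", info[hasGene])
  GenotypeStore(codes, loci, metadata)
}

#' Read the sample-metadata TSV that accompanies a VCF
#'
#' Expects header columns `sample_id`, `cohort`, `status`, `age`, `braak`,
#' `apoe` (the last two may be empty).
#'
#' @param path Path to a tab-separated file.
#' @return A `data.frame`.
#' @export
readSampleMetadata <- function(path) {
  m <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  need <- c("sample_id", "cohort", "status", "age")
  miss <- setdiff(need, colnames(m))
  if (length(miss)) stop("metadata lacks columns: ", paste(miss, collapse = ", "), call. = FALSE)
  if (!all(m$status %in% c("case", "control")))
    stop("status must be 'case' or 'control'", call. = FALSE)
  m
}

#' Dense genotype code matrix for a subset of the store
#'
#' @param store A `GenotypeStore`.
#' @param loci Locus keys or row indices (default: all).
#' @param ids Sample ids or column indices (default: all).
#' @param missingToZero Replace missing codes (-1) by 0, the rule used when
#'   building classifier feature matrices. Default `FALSE` (codes kept as-is).
#' @return A dense integer matrix, loci in rows.
#' @export
denseCodes <- function(store, loci = NULL, ids = NULL, missingToZero = FALSE) {
  g <- genoCodes(store)
  if (!is.null(loci)) g <- g[loci, , drop = FALSE]
  if (!is.null(ids)) g <- g[, ids, drop = FALSE]
  m <- as.matrix(g)
  if (missingToZero) m[m < 0] <- 0
  storage.mode(m) <- "integer"
  m
}

# Per-locus tabulations of codes over a sample subset: counts of het, hom-alt
# and missing. Internal workhorse shared by minorAlleleStats and association.
codeCounts <- function(store, ids = NULL) {
  g <- genoCodes(store)
  if (!is.null(ids)) g <- g[, ids, drop = FALSE]
  tg <- methods::as(g, "TsparseMatrix")
  i <- tg@i + 1L
  x <- tg@x
  nl <- nrow(g)
  list(het  = tabulate(i[x == 1], nl),
       hom  = tabulate(i[x == 2], nl),
       miss = tabulate(i[x == -1], nl),
       n = ncol(g))
}

#' Per-locus minor-allele statistics over a sample subset
#'
#' Allele counting is chromosome-based (two alleles per non-missing sample);
#' missing genotypes are excluded from the denominator. The minor allele is
#' the alternate allele when its frequency is <= 0.5, otherwise the
#' reference. Loci with every genotype missing in the subset get `NA` MAF
#' and are flagged `defined = FALSE` (downstream ranking drops them).
#'
#' @param store A `GenotypeStore`.
#' @param ids Sample ids/indices of the subset (default: all samples).
#' @return `data.frame` with columns `key`, `altCount`, `nAlleles`, `af`
#'   (alternate-allele frequency), `maf`, `mfaIsAlt`, `defined`.
#' @export
minorAlleleStats <- function(store, ids = NULL) {
  if (!is.null(ids)) stopIfEmpty(ids, "sample subset")
  cc <- codeCounts(store, ids)
  altCount <- cc$het + 2L * cc$hom
  nAlleles <- 2L * (cc$n - cc$miss)
  af <- ifelse(nAlleles > 0, altCount / nAlleles, NA_real_)
  data.frame(key = locusKeys(store),
             altCount = altCount, nAlleles = nAlleles, af = af,
             maf = pmin(af, 1 - af),
             mfaIsAlt = !is.na(af) & af <= 0.5,
             defined = nAlleles > 0,
             stringsAsFactors = FALSE)
}

#' Write a GenotypeStore as a minimal VCF plus metadata TSV
#'
#' Emits an uncompressed VCF v4.2 body with GT-only FORMAT (gene annotations
#' carried in `INFO` as `GENE=`), so the standard VCF entry point of the
#' pipeline can be exercised on generated data.
#'
#' @param store A `GenotypeStore`.
#' @param vcfPath Output VCF path.
#' @param metadataPath Optional output path for the sample-metadata TSV.
#' @return Invisibly, `vcfPath`.
#' @export
writeStoreVcf <- function(store, vcfPath, metadataPath = NULL) {
  li <- lociInfo(store)
  codes <- denseCodes(store)
  gtmap <- c(`-1` = "./.", `0` = "0/0", `1` = "0/1", `2` = "1/1")
  gt <- matrix(gtmap[as.character(codes)], nrow = nrow(codes))
  info <- ifelse(is.na(li$gene), ".", paste0("GENE=", li$gene))
  con <- file(vcfPath, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", colnames(store)), collapse = "\t")), con)
  body <- cbind(li$chr, li$pos, ".", li$ref, li$alt, ".", "PASS", info, "GT", gt)
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  if (!is.null(metadataPath)) {
    utils::write.table(sampleInfo(store), metadataPath, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(vcfPath)
}
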