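## Haplotype panel input/output: phased VCF (via vcfR), a sidecar
## population map and ancestral-allele polarity, and a plain-text
## haplotype dialect for fixtures and round-tripping.

#' Read a phased VCF into a haplotype panel
#'
#' Expects biallelic SNPs with phased diploid genotypes (`GT` like `0|1`);
#' each sample contributes two chromosome rows in sample order (hapA then
#' hapB). Alleles are polarized to ancestral/derived using the `AA` INFO
#' tag when present, else a sidecar polarity TSV (`site_id
#' ancestral_allele`); sites whose ancestral allele cannot be resolved (or
#' matches neither REF nor ALT) are dropped with a warning giving the
#' count. Unphased genotypes are an error naming sample and site.
#'
#' @param path VCF file (plain text or bgzipped).
#' @param popmap path to a two-column TSV `sample population` covering
#'   every VCF sample (missing samples are an error), or `NULL` to label
#'   all chromosomes `"pop1"`.
#' @param polarity optional path to the sidecar polarity TSV; consulted for
#'   sites lacking a usable `AA` tag.
#' @return a [HaplotypeMatrix-class].
#' @export
readVcfHaplotypes <- function(path, popmap = NULL, polarity = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  ids <- fix[, "ID"]
  noId <- is.na(ids) | ids == "."
  ids[noId] <- paste0(fix[noId, "CHROM"], ":", fix[noId, "POS"])
  pos <- as.numeric(fix[, "POS"])
  if (any(nchar(ref) != 1L | nchar(alt) != 1L | grepl(",", alt)))
    stop("all VCF sites must be biallelic SNPs", call. = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = length(ids))
  samples <- colnames(gt)
  bad <- !grepl("^[01]\\|[01]$", gt)
  dim(bad) <- dim(gt)
  unphased <- which(bad, arr.ind = TRUE)
  if (nrow(unphased))
    stop(sprintf("unphased or non-biallelic genotype '%s' for sample '%s' at site '%s'",
                 gt[unphased[1, 1], unphased[1, 2]],
                 samples[unphased[1, 2]], ids[unphased[1, 1]]),
         call. = FALSE)
  # ancestral allele per site: AA INFO tag, else the sidecar table
  aa <- toupper(vcfR::extract.info(vcf, element = "AA"))
  if (is.null(aa)) aa <- rep(NA_character_, length(ids))
  if (!is.null(polarity)) {
    side <- read.delim(polarity, header = TRUE, sep = "\t",
                       colClasses = "character")  # "T" must stay a base, not TRUE
    if (!all(c("site_id", "ancestral_allele") %in% names(side)))
      stop("polarity file needs columns 'site_id' and 'ancestral_allele'",
           call. = FALSE)
    hit <- match(ids, side$site_id)
    use <- is.na(aa) & !is.na(hit)
    aa[use] <- toupper(side$ancestral_allele[hit[use]])
  }
  resolved <- !is.na(aa) & (aa == ref | aa == alt)
  if (!all(resolved)) {
    warning(sprintf("dropping %d site(s) without resolvable ancestral allele",
                    sum(!resolved)), call. = FALSE)
    if (!any(resolved)) stop("no polarizable sites remain", call. = FALSE)
  }
  keep <- which(resolved)
  hapA <- substr(gt, 1L, 1L) == "1"
  hapB <- substr(gt, 3L, 3L) == "1"
  n <- length(samples)
  alleles <- matrix(0L, 2L * n, length(keep))
  for (j in seq_along(keep)) {
    s <- keep[j]
    a <- as.integer(hapA[s, ]); b <- as.integer(hapB[s, ])
    if (aa[s] == alt[s]) { a <- 1L - a; b <- 1L - b }   # ALT is ancestral
    alleles[seq(1L, 2L * n, by = 2L), j] <- a
    alleles[seq(2L, 2L * n, by = 2L), j] <- b
  }
  pops <- rep("pop1", n)
  if (!is.null(popmap)) {
    pm <- read.delim(popmap, header = TRUE, sep = "\t",
                     colClasses = "character")
    if (!all(c("sample", "population") %in% names(pm)))
      stop("population map needs columns 'sample' and 'population'",
           call. = FALSE)
    hit <- match(samples, pm$sample)
    if (anyNA(hit))
      stop("sample(s) missing from the population map: ",
           paste(samples[is.na(hit)], collapse = ", "), call. = FALSE)
    pops <- pm$population[hit]
  }
  HaplotypeMatrix(alleles, positions = pos[keep], siteIds = ids[keep],
                  samplePopulations = rep(pops, each = 2L))
}

#' Write a haplotype panel as a minimal phased VCF
#'
#' Chromosomes are paired in row order into diploid pseudo-samples (the
#' row count must be even) with phased `GT` fields; the derived allele is
#' written as ALT `T` with REF `C` and an `AA=C` INFO tag, so reading the
#' file back reconstructs the polarized matrix.
#'
#' @param hap a [HaplotypeMatrix-class] with an even number of rows.
#' @param path output path.
#' @param chrom chromosome name for the CHROM column.
#' @return `path`, invisibly.
#' @export
writeVcfHaplotypes <- function(hap, path, chrom = "11") {
  stopifnot(is(hap, "HaplotypeMatrix"))
  n <- nChromosomes(hap)
  if (n %% 2L != 0L)
    stop("VCF export needs an even number of chromosomes (diploid pairs)",
         call. = FALSE)
  samples <- sprintf("sample%03d", seq_len(n %/% 2L))
  a <- hap@alleles[seq(1L, n, by = 2L), , drop = FALSE]
  b <- hap@alleles[seq(2L, n, by = 2L), , drop = FALSE]
  lines <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  for (s in seq_len(nSites(hap))) {
    gt <- paste0(a[, s], "|", b[, s])
    lines <- c(lines, paste(c(chrom, format(hap@positions[s], scientific = FALSE),
                              hap@siteIds[s], "C", "T", ".", "PASS", "AA=C",
                              "GT", gt), collapse = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Plain-text haplotype dialect
#'
#' A fixture-friendly panel format: `# metadata` comment lines, a
#' `positions` and a `site_ids` header line, then one row per chromosome
#' (`population<TAB>0/1 string`). `writeHaplotypePanel()` /
#' [readHaplotypePanel()] round-trip a panel exactly.
#'
#' @param hap a [HaplotypeMatrix-class].
#' @param path file path.
#' @return the panel (read) or `path` invisibly (write).
#' @export
writeHaplotypePanel <- function(hap, path) {
  stopifnot(is(hap, "HaplotypeMatrix"))
  lines <- c("# haplotype-panel v1",
             paste("positions", paste(format(hap@positions, scientific = FALSE,
                                             trim = TRUE), collapse = " ")),
             paste("site_ids", paste(hap@siteIds, collapse = " ")),
             paste0(hap@samplePopulations, "\t",
                    apply(hap@alleles, 1L, paste0, collapse = "")))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeHaplotypePanel
#' @export
readHaplotypePanel <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  posLine <- lines[startsWith(lines, "positions")]
  idLine <- lines[startsWith(lines, "site_ids")]
  if (length(posLine) != 1L || length(idLine) != 1L)
    stop("malformed haplotype panel '", path,
         "': need one 'positions' and one 'site_ids' line", call. = FALSE)
  positions <- as.numeric(strsplit(posLine, "\\s+")[[1]][-1])
  siteIds <- strsplit(idLine, "\\s+")[[1]][-1]
  rows <- lines[!startsWith(lines, "positions") & !startsWith(lines, "site_ids")]
  parts <- strsplit(rows, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad))
    stop("malformed chromosome row ", bad[1], " in '", path, "'",
         call. = FALSE)
  pops <- vapply(parts, `[[`, character(1), 1L)
  alleleStr <- vapply(parts, `[[`, character(1), 2L)
  if (any(nchar(alleleStr) != length(positions)))
    stop("chromosome row length does not match the number of sites in '",
         path, "'", call. = FALSE)
  if (any(grepl("[^01]", alleleStr)))
    stop("haplotype rows must contain only 0/1 in '", path, "'",
         call. = FALSE)
  alleles <- do.call(rbind, lapply(strsplit(alleleStr, ""), as.integer))
  HaplotypeMatrix(alleles, positions = positions, siteIds = siteIds,
                  samplePopulations = pops)
}
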