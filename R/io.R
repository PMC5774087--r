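# Readers and writers for the on-disk formats. The canonical genotype
# exchange format is the long TSV (chrom, pos, line, allele); a minimal VCF
# is supported as a convenience. BED-like files are 0-based half-open on
# disk; all in-memory coordinates are 1-based inclusive.

#' Write / read sparse genotype observations as long TSV
#'
#' Columns: chrom, pos (1-based), line, allele (P1/P2).
#'
#' @param observations data.frame (chrom, pos, line, allele).
#' @param path output file.
#' @return `write_genotype_tsv` returns `path` invisibly;
#'   `read_genotype_observations` the observations data.frame.
#' @export
write_genotype_tsv <- function(observations, path) {
  data.table::fwrite(observations[, c("chrom", "pos", "line", "allele")],
                     path, sep = "\t")
  invisible(path)
}

#' @rdname write_genotype_tsv
#' @param format `"tsv"` or `"vcf"`.
#' @param parents for VCF input, the two parent sample names defining the
#'   P1/P2 allele coding.
#' @export
read_genotype_observations <- function(path, format = c("tsv", "vcf"),
                                       parents = c("parent1", "parent2")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "tsv") {
    d <- as.data.frame(data.table::fread(path, sep = "\t"))
    need <- c("chrom", "pos", "line", "allele")
    if (!all(need %in% names(d)))
      stop("malformed genotype TSV: need columns ",
           paste(need, collapse = ", "))
    bad <- which(!(d$allele %in% c("P1", "P2")))
    if (length(bad))
      stop("malformed record at line ", bad[1] + 1L,
           ": allele '", d$allele[bad[1]], "'")
    return(d[, need])
  }
  .read_genotype_vcf(path, parents)
}

#' Write sparse genotype observations as a minimal VCF
#'
#' Emits a VCFv4.2 file with placeholder REF/ALT alleles, the two parents as
#' the first samples (homozygous reference / alternate), and one sample per
#' line with GT 0/0 (P1), 1/1 (P2) or ./. (unobserved).
#'
#' @inheritParams write_genotype_tsv
#' @param parents names for the two parent samples.
#' @export
write_genotype_vcf <- function(observations, path,
                               parents = c("parent1", "parent2")) {
  sites <- unique(observations[, c("chrom", "pos")])
  sites <- sites[order(sites$chrom, sites$pos), ]
  lines_id <- sort(unique(observations$line))
  key_site <- paste(sites$chrom, sites$pos)
  gt <- matrix("./.", nrow(sites), length(lines_id),
               dimnames = list(NULL, lines_id))
  ok <- paste(observations$chrom, observations$pos)
  gt[cbind(match(ok, key_site), match(observations$line, lines_id))] <-
    ifelse(observations$allele == "P1", "0/0", "1/1")
  header <- c("##fileformat=VCFv4.2",
              "##source=binqtl",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", parents, lines_id), collapse = "\t"))
  body <- paste(sites$chrom, sites$pos, ".", "A", "T", ".", "PASS", ".",
                "GT", "0/0", "1/1",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

.read_genotype_vcf <- function(path, parents) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF input requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  fix <- vcfR::getFIX(v)
  if (!all(parents %in% colnames(gt)))
    stop("unknown parent sample(s): ",
         paste(setdiff(parents, colnames(gt)), collapse = ", "))
  hom_ref <- function(g) !is.na(g) & g %in% c("0/0", "0|0")
  hom_alt <- function(g) !is.na(g) & g %in% c("1/1", "1|1")
  gp1 <- gt[, parents[1]]; gp2 <- gt[, parents[2]]
  # keep only sites where the parents are opposite homozygotes
  ok <- (hom_ref(gp1) & hom_alt(gp2)) | (hom_alt(gp1) & hom_ref(gp2))
  n_dropped <- sum(!ok)
  lines_id <- setdiff(colnames(gt), parents)
  out <- vector("list", length(lines_id))
  p1_is_ref <- hom_ref(gp1)
  for (k in seq_along(lines_id)) {
    g <- gt[, lines_id[k]]
    called <- ok & (hom_ref(g) | hom_alt(g))
    if (!any(called)) next
    allele <- ifelse(hom_ref(g[called]) == p1_is_ref[called], "P1", "P2")
    out[[k]] <- data.frame(chrom = fix[called, "CHROM"],
                           pos = as.numeric(fix[called, "POS"]),
                           line = lines_id[k], allele = allele,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(chrom = character(0), pos = numeric(0),
                      line = character(0), allele = character(0))
  rownames(res) <- NULL
  attr(res, "n_dropped_sites") <- n_dropped
  res
}

#' Write / read line mosaics as BED-like segment files
#'
#' Columns on disk: chrom, start (0-based), end (exclusive), line, genotype,
#' snp_count. A header comment states the coordinate convention.
#'
#' @param blocks mosaic blocks data.frame (line, chrom, start, end,
#'   genotype, snp_count), 1-based inclusive.
#' @param path output file.
#' @export
write_mosaics_bed <- function(blocks, path) {
  con <- file(path, "w")
  writeLines("# binqtl mosaics; coordinates 0-based half-open", con)
  utils::write.table(
    data.frame(chrom = blocks$chrom, start = blocks$start - 1,
               end = blocks$end, line = blocks$line,
               genotype = blocks$genotype, snp_count = blocks$snp_count),
    con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = TRUE)
  close(con)
  invisible(path)
}

#' @rdname write_mosaics_bed
#' @export
read_mosaics_bed <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, comment.char = "#")
  data.frame(line = d$line, chrom = d$chrom, start = d$start + 1,
             end = d$end, genotype = d$genotype, snp_count = d$snp_count,
             stringsAsFactors = FALSE)
}

#' Write a bin map to disk
#'
#' Emits `bins.tsv` (chrom, start, end; 1-based inclusive) and `geno.tsv`
#' (lines x bins matrix with codes 0 = P1, 2 = P2, 1 = HET, NA = missing).
#'
#' @param binmap a `bin_map`.
#' @param dir output directory (created if needed).
#' @export
write_bin_map <- function(binmap, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  data.table::fwrite(binmap$bins, file.path(dir, "bins.tsv"), sep = "\t")
  g <- data.frame(line = rownames(binmap$geno), binmap$geno,
                  check.names = FALSE, stringsAsFactors = FALSE)
  data.table::fwrite(g, file.path(dir, "geno.tsv"), sep = "\t")
  invisible(dir)
}

#' @rdname write_bin_map
#' @param layout optional `genome_layout` reattached to the object.
#' @export
read_bin_map <- function(dir, layout = NULL) {
  bins <- as.data.frame(data.table::fread(file.path(dir, "bins.tsv")))
  g <- as.data.frame(data.table::fread(file.path(dir, "geno.tsv")))
  geno <- as.matrix(g[, -1, drop = FALSE])
  storage.mode(geno) <- "integer"
  rownames(geno) <- g$line
  structure(list(bins = bins, geno = geno, layout = layout),
            class = "bin_map")
}

#' Write a genetic map as TSV
#'
#' @param genmap a `genetic_map`.
#' @param path output file (chrom, start, end, mid_bp, cM).
#' @export
write_genetic_map <- function(genmap, path) {
  data.table::fwrite(genmap$map, path, sep = "\t")
  invisible(path)
}

#' Write phenotypes as long TSV
#'
#' @param table data.frame (line, environment, trait, value).
#' @param path output file.
#' @export
write_phenotypes_tsv <- function(table, path) {
  data.table::fwrite(table, path, sep = "\t")
  invisible(path)
}

#' @rdname write_phenotypes_tsv
#' @export
read_phenotypes_tsv <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t"))
}
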