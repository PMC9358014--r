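#' Read and write pipeline file formats
#'
#' Plain-text serializers for every table the pipeline consumes or emits:
#' assembly skeleton TSV (`name`, `length`), evidence BED (0-based
#' half-open, with the evidence class in the name column), genotype TSV,
#' DEG TSV (`gene_id`, `log2fc`), synteny block TSV (8 columns) and GFF3
#' gene models (via rtracklayer). Each `read_*` inverts the matching
#' `write_*` exactly.
#'
#' @param x object to write (see each function).
#' @param path file path.
#' @name karyoregion-io
NULL

#' @rdname karyoregion-io
#' @export
write_skeleton_tsv <- function(x, path) {
  utils::write.table(x[, c("name", "length")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname karyoregion-io
#' @export
read_skeleton_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  class(df) <- c("assembly_skeleton", "data.frame")
  df
}

#' @rdname karyoregion-io
#' @export
write_evidence_bed <- function(x, path) {
  bed <- data.frame(chrom = x$chrom, start = format(x$start, scientific = FALSE,
                                                    trim = TRUE),
                    end = format(x$end, scientific = FALSE, trim = TRUE),
                    name = x$cls)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname karyoregion-io
#' @export
read_evidence_bed <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          col.names = c("chrom", "start", "end", "name"),
                          stringsAsFactors = FALSE)
  data.frame(cls = df$name, chrom = df$chrom,
             start = as.numeric(df$start), end = as.numeric(df$end),
             stringsAsFactors = FALSE)
}

#' @rdname karyoregion-io
#' @param genotypes list as returned by [generate_f1_genotypes()].
#' @export
write_genotypes_tsv <- function(genotypes, path) {
  g <- as.data.frame(genotypes$genotypes)
  g <- cbind(sex = genotypes$sex, g)
  utils::write.table(g, path, sep = "\t", quote = FALSE, row.names = FALSE)
  map_path <- paste0(path, ".map")
  utils::write.table(genotypes$map, map_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname karyoregion-io
#' @export
read_genotypes_tsv <- function(path) {
  g <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  map <- utils::read.table(paste0(path, ".map"), header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  list(genotypes = as.matrix(g[, -1, drop = FALSE]), sex = g$sex, map = map)
}

#' @rdname karyoregion-io
#' @export
write_deg_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname karyoregion-io
#' @export
read_deg_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' @rdname karyoregion-io
#' @export
write_synteny_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname karyoregion-io
#' @export
read_synteny_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' @rdname karyoregion-io
#' @param genes gene-model data.frame (`gene_id`, `chrom`, `start`, `end`,
#'   `strand`), 0-based half-open.
#' @export
write_genes_gff3 <- function(genes, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$start + 1, end = genes$end),
    strand = genes$strand %||% "*")
  S4Vectors::mcols(gr)$type <- "gene"
  S4Vectors::mcols(gr)$ID <- genes$gene_id
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @rdname karyoregion-io
#' @export
read_genes_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[S4Vectors::mcols(gr)$type == "gene"]
  df <- data.frame(
    gene_id = S4Vectors::mcols(gr)$ID,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE)
  df$strand[df$strand == "*"] <- "+"
  rownames(df) <- NULL
  df
}
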