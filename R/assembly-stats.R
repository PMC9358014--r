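#' Assembly contiguity statistics
#'
#' Computes total size, Nx/Lx contiguity statistics and simple length
#' summaries for a set of sequences. Nx is defined as the length of the
#' sequence at which the cumulative sum of descending-sorted lengths first
#' reaches x% of the total; Lx is that sequence's 1-based rank.
#'
#' @param lengths numeric vector of sequence lengths in bp (all > 0), or an
#'   assembly skeleton data.frame with a `length` column.
#' @param gc_fraction optional GC fraction (0-1) to carry through, e.g. from
#'   [gc_content()].
#' @return object of class `assembly_stats`: list with `total_bp`,
#'   `n_contigs`, `longest`, `shortest`, `mean`, `N50`, `L50`, `N75`,
#'   `L75`, `N90`, `L90`, `gc_fraction`.
#' @export
#' @examples
#' assembly_stats(c(40, 30, 20, 10))  # N50 30, L50 2
assembly_stats <- function(lengths, gc_fraction = NULL) {
  if (is.data.frame(lengths)) lengths <- lengths$length
  lengths <- as.numeric(lengths)
  stop_if_not(length(lengths) >= 1L, "assembly_stats: need at least one sequence")
  stop_if_not(all(is.finite(lengths)) && all(lengths > 0),
              "assembly_stats: all lengths must be positive")
  s <- sort(lengths, decreasing = TRUE)
  total <- sum(s)
  cum <- cumsum(s)
  nl <- function(x) {
    i <- which(cum >= total * x / 100)[1L]
    c(N = s[i], L = i)
  }
  n50 <- nl(50); n75 <- nl(75); n90 <- nl(90)
  structure(list(
    total_bp = total, n_contigs = length(s),
    longest = s[1L], shortest = s[length(s)], mean = total / length(s),
    N50 = n50[["N"]], L50 = n50[["L"]],
    N75 = n75[["N"]], L75 = n75[["L"]],
    N90 = n90[["N"]], L90 = n90[["L"]],
    gc_fraction = gc_fraction
  ), class = "assembly_stats")
}

#' @export
print.assembly_stats <- function(x, ...) {
  cat("Assembly statistics\n")
  cat(sprintf("  sequences: %d, total %s bp (mean %s)\n",
              x$n_contigs, format(x$total_bp, big.mark = ","),
              format(round(x$mean), big.mark = ",")))
  cat(sprintf("  longest %s, shortest %s\n",
              format(x$longest, big.mark = ","),
              format(x$shortest, big.mark = ",")))
  for (p in c(50, 75, 90))
    cat(sprintf("  N%d %s (L%d %d)\n", p,
                format(x[[paste0("N", p)]], big.mark = ","),
                p, x[[paste0("L", p)]]))
  if (!is.null(x$gc_fraction))
    cat(sprintf("  GC %.2f%%\n", 100 * x$gc_fraction))
  invisible(x)
}

#' Anchoring coverage percentage
#'
#' Share of the assembly placed into chromosome-scale sequences,
#' `100 * chrom_total / assembly_total`, rounded half-up to two decimals.
#' The same formula applies to counts (e.g. genes anchored on chromosomes
#' out of all predicted genes).
#'
#' @param chrom_total total bp (or count) anchored on chromosomes.
#' @param assembly_total total assembly bp (or total count).
#' @return percentage, two decimals.
#' @export
#' @examples
#' anchoring_coverage(722220000, 741974678)  # 97.34
anchoring_coverage <- function(chrom_total, assembly_total) {
  stop_if_not(is.numeric(chrom_total) && is.numeric(assembly_total),
              "anchoring_coverage: numeric inputs required")
  stop_if_not(chrom_total > 0 && assembly_total > 0,
              "anchoring_coverage: totals must be positive")
  stop_if_not(chrom_total <= assembly_total,
              "anchoring_coverage: anchored total exceeds assembly total")
  round_half_up(100 * chrom_total / assembly_total, 2)
}

#' Per-chromosome gene density
#'
#' Genes per Mb for each chromosome, with the densest and sparsest
#' chromosome reported (ties broken by chromosome-name order).
#'
#' @param gene_counts named integer vector of gene counts per chromosome.
#' @param skeleton assembly skeleton data.frame (`name`, `length`) or named
#'   numeric vector of chromosome lengths in bp.
#' @return list with `density` (data.frame: `chrom`, `n_genes`,
#'   `length_mb`, `density`), `highest`, `lowest` (chromosome names).
#' @export
gene_density <- function(gene_counts, skeleton) {
  if (is.data.frame(skeleton)) {
    lens <- stats::setNames(skeleton$length, skeleton$name)
  } else lens <- skeleton
  chroms <- names(gene_counts)
  missing <- setdiff(chroms, names(lens))
  stop_if_not(length(missing) == 0L,
              "gene_density: unknown chromosome(s): ",
              paste(missing, collapse = ", "))
  mb <- as.numeric(lens[chroms]) / 1e6
  dens <- round_half_up(as.numeric(gene_counts) / mb, 2)
  df <- data.frame(chrom = chroms, n_genes = as.integer(gene_counts),
                   length_mb = round_half_up(mb, 2), density = dens,
                   stringsAsFactors = FALSE)
  ord <- order(df$chrom)
  hi <- df$chrom[ord][which.max(df$density[ord])]
  lo <- df$chrom[ord][which.min(df$density[ord])]
  list(density = df, highest = hi, lowest = lo)
}

#' Linkage group to chromosome correspondence
#'
#' Assigns each linkage group (LG) the chromosome that carries a strict
#' majority of its mapped tags. LGs without a strict majority are flagged
#' unresolved rather than silently assigned.
#'
#' @param tag_positions data.frame with columns `lg`, `chrom` (and
#'   optionally `pos`): one row per mapped tag.
#' @return data.frame with columns `lg`, `chrom` (NA when unresolved),
#'   `n_support`, `n_total`, `resolved`.
#' @export
lg_chr_correspondence <- function(tag_positions) {
  stop_if_not(is.data.frame(tag_positions) &&
                all(c("lg", "chrom") %in% names(tag_positions)),
              "lg_chr_correspondence: need columns lg, chrom")
  stop_if_not(nrow(tag_positions) >= 1L, "lg_chr_correspondence: no tags")
  res <- lapply(split(tag_positions, tag_positions$lg), function(d) {
    tab <- sort(table(d$chrom), decreasing = TRUE)
    n <- nrow(d)
    top <- tab[1L]
    ok <- top > n / 2 && (length(tab) == 1L || tab[1L] > tab[2L])
    data.frame(lg = d$lg[1L],
               chrom = if (ok) names(tab)[1L] else NA_character_,
               n_support = as.integer(top), n_total = n, resolved = ok,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out[order(out$lg), , drop = FALSE]
}

#' GC content of sequences
#'
#' GC fraction of a `Biostrings::DNAStringSet` (or FASTA path), counting
#' G and C over unambiguous A/C/G/T bases only.
#'
#' @param x DNAStringSet or path to a FASTA file.
#' @return GC fraction in [0, 1].
#' @export
gc_content <- function(x) {
  if (is.character(x)) x <- Biostrings::readDNAStringSet(x)
  freq <- colSums(Biostrings::alphabetFrequency(x)[, c("A", "C", "G", "T"),
                                                  drop = FALSE])
  unname((freq[["G"]] + freq[["C"]]) / sum(freq))
}
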