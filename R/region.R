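#' Majority chromosome of an evidence set
#'
#' The chromosome carrying the largest share of evidence markers and that
#' share. An exact tie between top chromosomes is ambiguous and raises an
#' error rather than picking one silently.
#'
#' @param evidence data.frame with a `chrom` column (one row per marker).
#' @return list `chrom`, `fraction`.
#' @export
#' @examples
#' majority_chromosome(data.frame(chrom = c("chr08", "chr08", "chr03")))
majority_chromosome <- function(evidence) {
  stop_if_not(nrow(evidence) >= 1L, "majority_chromosome: no evidence")
  tab <- sort(table(evidence$chrom), decreasing = TRUE)
  if (length(tab) > 1L && tab[1L] == tab[2L])
    stop("majority_chromosome: tie between chromosomes ",
         paste(names(tab)[tab == tab[1L]], collapse = ", "), call. = FALSE)
  list(chrom = names(tab)[1L],
       fraction = as.numeric(tab[1L]) / nrow(evidence))
}

#' Minimal window containing a fraction of evidence segments
#'
#' The shortest genomic window that fully contains at least
#' `ceiling(fraction * n)` of the markers on one chromosome (a marker
#' counts only when its whole interval lies inside the window). This
#' operationalizes the rule that the region containing more than 90% of
#' the mapped sex-linked segments is taken as the sex-determining region.
#' Among equal-length optima the leftmost is returned.
#'
#' The scan sorts candidate window ends (marker interval ends); for each
#' end it takes the k-th largest start among markers ending at or before
#' it, which is the tightest feasible window with that end.
#'
#' @param markers data.frame with `start`, `end` columns (bp, half-open),
#'   all on one chromosome; point markers have `end = start + 1`.
#'   Duplicate positions count as distinct segments.
#' @param fraction required contained fraction, in (0, 1].
#' @param cls,chrom labels carried into the result.
#' @return object of class `region_window`: list with `cls`, `chrom`,
#'   `start`, `end`, `n_contained`, `n_total`, `containment_pct`
#'   (one decimal).
#' @export
minimal_covering_window <- function(markers, fraction = 0.9,
                                    cls = NA_character_,
                                    chrom = NA_character_) {
  stop_if_not(nrow(markers) >= 1L, "minimal_covering_window: no markers")
  stop_if_not(fraction > 0 && fraction <= 1,
              "minimal_covering_window: fraction must be in (0, 1]")
  if ("chrom" %in% names(markers)) {
    chs <- unique(markers$chrom)
    stop_if_not(length(chs) == 1L,
                "minimal_covering_window: markers on several chromosomes: ",
                paste(chs, collapse = ", "))
    if (is.na(chrom)) chrom <- chs
  }
  s <- markers$start; e <- markers$end
  stop_if_not(all(e >= s), "minimal_covering_window: end < start")
  n <- length(s)
  k <- ceiling(fraction * n)
  best <- NULL
  for (endv in sort(unique(e))) {
    idx <- which(e <= endv)
    if (length(idx) < k) next
    # tightest window ending at endv: k-th largest start among eligible
    st <- sort(s[idx], decreasing = TRUE)[k]
    len <- endv - st
    if (is.null(best) || len < best$len ||
        (len == best$len && st < best$start)) {
      n_in <- sum(s >= st & e <= endv)
      best <- list(start = st, end = endv, len = len, n_in = n_in)
    }
  }
  structure(list(
    cls = cls, chrom = chrom, start = best$start, end = best$end,
    n_contained = best$n_in, n_total = n,
    containment_pct = round_half_up(100 * best$n_in / n, 1)
  ), class = "region_window")
}

#' @export
print.region_window <- function(x, ...) {
  cat(sprintf("window [%s] %s:%.2f-%.2f Mb  %d/%d contained (%.1f%%)\n",
              x$cls, x$chrom, x$start / 1e6, x$end / 1e6,
              x$n_contained, x$n_total, x$containment_pct))
  invisible(x)
}

#' Integrate evidence windows and point markers into one region
#'
#' The final sex-determining region is the bounding hull (smallest single
#' interval) containing every per-class window and every point marker.
#' All inputs must be on one chromosome; mixed chromosomes raise an error
#' naming the offenders.
#'
#' @param windows list of `region_window` objects (or a data.frame with
#'   `chrom`, `start`, `end`).
#' @param points optional data.frame of additional markers (`chrom`,
#'   `start`, `end`).
#' @param predicted_sex_chromosome logical flag recorded on the result.
#' @return object of class `sex_region`: list with `chrom`, `start`,
#'   `end` (bp), `length_Mb` (two decimals), `windows`, `points`,
#'   `predicted_sex_chromosome`.
#' @export
integrate_evidence <- function(windows, points = NULL,
                               predicted_sex_chromosome = TRUE) {
  if (inherits(windows, "region_window")) windows <- list(windows)
  if (is.data.frame(windows)) {
    windows <- lapply(seq_len(nrow(windows)), function(i)
      structure(as.list(windows[i, , drop = FALSE]), class = "region_window"))
  }
  stop_if_not(length(windows) >= 1L || (!is.null(points) && nrow(points) > 0),
              "integrate_evidence: nothing to integrate")
  chroms <- c(vapply(windows, `[[`, character(1), "chrom"),
              if (!is.null(points)) as.character(points$chrom))
  chroms <- chroms[!is.na(chroms)]
  uch <- unique(chroms)
  if (length(uch) > 1L)
    stop("integrate_evidence: evidence on several chromosomes: ",
         paste(uch, collapse = ", "), call. = FALSE)
  starts <- c(vapply(windows, `[[`, numeric(1), "start"),
              if (!is.null(points)) points$start)
  ends <- c(vapply(windows, `[[`, numeric(1), "end"),
            if (!is.null(points)) points$end)
  lo <- min(starts); hi <- max(ends)
  structure(list(chrom = uch, start = lo, end = hi,
                 length_Mb = round_half_up((hi - lo) / 1e6, 2),
                 windows = windows, points = points,
                 predicted_sex_chromosome = predicted_sex_chromosome),
            class = "sex_region")
}

#' @export
print.sex_region <- function(x, ...) {
  cat(sprintf("sex-determining region: %s:%.2f-%.2f Mb (%.2f Mb)%s\n",
              x$chrom, x$start / 1e6, x$end / 1e6, x$length_Mb,
              if (isTRUE(x$predicted_sex_chromosome))
                sprintf("; %s predicted as the sex chromosome", x$chrom)
              else ""))
  invisible(x)
}

#' Genes overlapping (or contained in) a region
#'
#' Selects gene models intersecting the region by at least 1 bp
#' (`rule = "overlap"`, default) or lying fully inside it
#' (`rule = "contained"`), ordered by start.
#'
#' @param genes data.frame with `gene_id`, `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param region a `sex_region` (or any list with `chrom`, `start`,
#'   `end`).
#' @param rule `"overlap"` or `"contained"`.
#' @param known_chroms optional character vector; genes on chromosomes
#'   outside it raise an error.
#' @return data.frame subset of `genes`, ordered by start.
#' @export
genes_in_region <- function(genes, region, rule = c("overlap", "contained"),
                            known_chroms = NULL) {
  rule <- match.arg(rule)
  if (!is.null(known_chroms)) {
    bad <- setdiff(unique(genes$chrom), known_chroms)
    stop_if_not(length(bad) == 0L,
                "genes_in_region: unknown chromosome(s): ",
                paste(bad, collapse = ", "))
  }
  gr_genes <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$start + 1, genes$end))
  gr_region <- GenomicRanges::GRanges(
    region$chrom, IRanges::IRanges(region$start + 1, region$end))
  hits <- if (rule == "overlap")
    GenomicRanges::findOverlaps(gr_genes, gr_region)
  else
    GenomicRanges::findOverlaps(gr_genes, gr_region, type = "within")
  sel <- genes[sort(unique(S4Vectors::queryHits(hits))), , drop = FALSE]
  sel <- sel[order(sel$start), , drop = FALSE]
  rownames(sel) <- NULL
  sel
}

#' Delineate the sex-determining region from raw evidence
#'
#' Full delineation: predict the sex chromosome by evidence majority,
#' compute one minimal >= `fraction` containment window per evidence
#' class on that chromosome (classes with fewer than `min_class_n`
#' markers are carried as point/segment evidence instead of windows),
#' then integrate windows and points into the final region.
#'
#' @param evidence data.frame `cls`, `chrom`, `start`, `end`.
#' @param fraction required containment per class window.
#' @param min_class_n classes with fewer markers than this contribute
#'   their raw segments rather than a covering window.
#' @return object of class `sex_region` with a `majority` element added.
#' @export
delineate_region <- function(evidence, fraction = 0.9, min_class_n = 5L) {
  maj <- majority_chromosome(evidence)
  on_chr <- evidence[evidence$chrom == maj$chrom, , drop = FALSE]
  windows <- list(); points <- NULL
  for (cls in unique(on_chr$cls)) {
    mk <- on_chr[on_chr$cls == cls, , drop = FALSE]
    if (nrow(mk) >= min_class_n) {
      windows[[cls]] <- minimal_covering_window(mk, fraction, cls = cls,
                                                chrom = maj$chrom)
    } else {
      points <- rbind(points, mk[, c("chrom", "start", "end")])
    }
  }
  region <- integrate_evidence(windows, points)
  region$majority <- maj
  region
}
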