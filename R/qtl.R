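#' Binary-trait association LOD and PVE at one marker
#'
#' Desk-scale sex-association score for a biallelic marker against a
#' binary sex phenotype. The LOD is the base-10 log likelihood ratio of
#' the saturated 2x2 multinomial association model against independence
#' (equivalently `G2 / (2 ln 10)` for the likelihood-ratio G statistic);
#' the phenotypic variance explained is the squared correlation between
#' 0/1 genotype and sex codes (the phi coefficient squared), times 100.
#' A perfectly sex-linked marker therefore scores PVE = 100.
#'
#' @param genotype vector with two classes (0/1, factor or character).
#' @param sex vector with two classes, same length.
#' @return list `lod`, `pve_pct`, `n`, `monomorphic`. A monomorphic
#'   marker (or single-sex input) is flagged and returns NA scores.
#' @export
#' @examples
#' binary_trait_lod(rep(0:1, each = 50), rep(c("F", "M"), each = 50))
binary_trait_lod <- function(genotype, sex) {
  stop_if_not(length(genotype) == length(sex),
              "binary_trait_lod: genotype and sex lengths differ")
  keep <- !is.na(genotype) & !is.na(sex)
  genotype <- genotype[keep]; sex <- sex[keep]
  n <- length(genotype)
  stop_if_not(n >= 4, "binary_trait_lod: need n >= 4")
  g <- factor(genotype); s <- factor(sex)
  if (nlevels(g) < 2L || nlevels(s) < 2L)
    return(list(lod = NA_real_, pve_pct = NA_real_, n = n, monomorphic = TRUE))
  stop_if_not(nlevels(g) == 2L && nlevels(s) == 2L,
              "binary_trait_lod: genotype and sex must each have two classes")
  tab <- table(g, s)
  # G statistic: 2 * sum obs * log(obs/exp), zero cells contribute zero
  exp_ <- outer(rowSums(tab), colSums(tab)) / n
  nz <- tab > 0
  g2 <- 2 * sum(tab[nz] * log(tab[nz] / exp_[nz]))
  phi <- stats::cor(as.integer(g) - 1L, as.integer(s) - 1L)
  list(lod = g2 / (2 * log(10)), pve_pct = 100 * phi^2, n = n,
       monomorphic = FALSE)
}

#' Genome scan of sex association
#'
#' Applies [binary_trait_lod()] to every marker of an F1 genotype matrix,
#' producing a table of QTL records on one linkage group.
#'
#' @param genotypes 0/1 matrix, offspring x markers.
#' @param sex vector of sex labels.
#' @param map data.frame `marker`, `cM` matching the matrix columns.
#' @param lg linkage-group id recorded on each row.
#' @return data.frame `lg`, `marker`, `position_cM`, `lod`, `pve_pct`.
#' @export
scan_sex_association <- function(genotypes, sex, map, lg = "LG1") {
  stop_if_not(ncol(genotypes) == nrow(map),
              "scan_sex_association: map rows must match genotype columns")
  res <- lapply(seq_len(ncol(genotypes)), function(j) {
    r <- binary_trait_lod(genotypes[, j], sex)
    data.frame(lg = lg, marker = map$marker[j], position_cM = map$cM[j],
               lod = r$lod, pve_pct = r$pve_pct, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Filter QTL records by LOD thresholds and select PVE = 100
#'
#' Counts records passing the chromosome-wide and genome-wide LOD
#' thresholds, bins the PVE distribution (> 90; 95-99.9; exactly 100) and
#' selects the records with PVE = 100%, the set carried into the
#' sex-determining-region analysis.
#'
#' @param records data.frame with columns `lg`, `position_cM`, `lod`,
#'   `pve_pct`.
#' @param lod_chromwide,lod_genomewide LOD thresholds (defaults 5.2, 7.0).
#' @param pve_tol numeric tolerance for "PVE equals 100".
#' @return object of class `qtl_screen`: list with
#'   `n_total_pass_chromwide`, `n_pass_genomewide`, `pve_histogram`
#'   (named counts among chromosome-wide passes: `gt90`, `b95_99.9`,
#'   `eq100`), `selected` (records with PVE = 100 passing the
#'   chromosome-wide threshold), `span_cM` (see [qtl_span_cM()]; NULL when
#'   nothing selected or records span several LGs).
#' @export
filter_qtls <- function(records, lod_chromwide = 5.2, lod_genomewide = 7.0,
                        pve_tol = 1e-8) {
  stop_if_not(lod_chromwide >= 0 && lod_genomewide >= lod_chromwide,
              "filter_qtls: need 0 <= lod_chromwide <= lod_genomewide")
  if (is.null(records) || nrow(records) == 0L) {
    return(structure(list(n_total_pass_chromwide = 0L, n_pass_genomewide = 0L,
                          pve_histogram = c(gt90 = 0L, "b95_99.9" = 0L,
                                            eq100 = 0L),
                          selected = records, span_cM = NULL),
                     class = "qtl_screen"))
  }
  ok <- !is.na(records$lod)
  pass_c <- records[ok & records$lod >= lod_chromwide, , drop = FALSE]
  n_g <- sum(pass_c$lod >= lod_genomewide)
  pve <- pass_c$pve_pct
  hist <- c(gt90 = sum(pve > 90),
            "b95_99.9" = sum(pve >= 95 & pve <= 99.9),
            eq100 = sum(abs(pve - 100) <= pve_tol))
  selected <- pass_c[abs(pve - 100) <= pve_tol, , drop = FALSE]
  span <- if (nrow(selected) > 0 && length(unique(selected$lg)) == 1L)
    qtl_span_cM(selected) else NULL
  structure(list(n_total_pass_chromwide = nrow(pass_c),
                 n_pass_genomewide = n_g, pve_histogram = hist,
                 selected = selected, span_cM = span),
            class = "qtl_screen")
}

#' @export
print.qtl_screen <- function(x, ...) {
  cat("Sex-association QTL screen\n")
  cat(sprintf("  chromosome-wide passes: %d (genome-wide: %d)\n",
              x$n_total_pass_chromwide, x$n_pass_genomewide))
  cat(sprintf("  PVE > 90%%: %d;  95-99.9%%: %d;  = 100%%: %d\n",
              x$pve_histogram[["gt90"]], x$pve_histogram[["b95_99.9"]],
              x$pve_histogram[["eq100"]]))
  if (!is.null(x$span_cM))
    cat(sprintf("  PVE=100 span: %.2f-%.2f cM (width %.2f cM)\n",
                x$span_cM[["min"]], x$span_cM[["max"]], x$span_cM[["width"]]))
  invisible(x)
}

#' Genetic span of selected QTLs
#'
#' Minimum, maximum and width (cM, two decimals) of the map positions of
#' a selected QTL set, which must sit on a single linkage group.
#'
#' @param selected data.frame with columns `lg`, `position_cM`.
#' @return named numeric vector `min`, `max`, `width`.
#' @export
#' @examples
#' qtl_span_cM(data.frame(lg = "LG1", position_cM = c(11.56, 81.49)))
qtl_span_cM <- function(selected) {
  stop_if_not(nrow(selected) >= 1L, "qtl_span_cM: no selected records")
  lgs <- unique(selected$lg)
  stop_if_not(length(lgs) == 1L,
              "qtl_span_cM: records span several linkage groups: ",
              paste(lgs, collapse = ", "))
  lo <- min(selected$position_cM); hi <- max(selected$position_cM)
  c(min = round_half_up(lo, 2), max = round_half_up(hi, 2),
    width = round_half_up(hi - lo, 2))
}

#' Permutation LOD threshold
#'
#' Optional empirical threshold: the 95th percentile of the maximum LOD
#' over label permutations, the usual genome-wide control for binary-trait
#' scans. Off by default in the pipeline, which uses fixed thresholds.
#'
#' @param genotypes,sex,map as in [scan_sex_association()].
#' @param n_perm number of label shuffles.
#' @param quantile percentile of the null maximum to return.
#' @return numeric LOD threshold.
#' @export
permutation_lod_threshold <- function(genotypes, sex, map, n_perm = 1000,
                                      quantile = 0.95) {
  maxima <- vapply(seq_len(n_perm), function(i) {
    s <- sample(sex)
    max(scan_sex_association(genotypes, s, map)$lod, na.rm = TRUE)
  }, numeric(1))
  unname(stats::quantile(maxima, quantile, type = 7))
}
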