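#' Expression direction from a log2 fold-change
#'
#' Positive log2(male/female) fold-changes are male-biased, negative ones
#' female-biased. Exactly zero is ambiguous: it is returned as `NA` and
#' excluded from downstream direction logic.
#'
#' @param log2fc numeric vector.
#' @return character vector `"male"` / `"female"` / `NA`.
#' @export
#' @examples
#' direction_from_log2fc(c(8.3753, -2.4828))
direction_from_log2fc <- function(log2fc) {
  out <- ifelse(log2fc > 0, "male", ifelse(log2fc < 0, "female",
                                           NA_character_))
  as.character(out)
}

#' Direction-concordant DEGs across two contrasts
#'
#' Intersects the male-vs-female and male-vs-pseudofemale DEG tables
#' within the region gene set and keeps genes differentially expressed in
#' both contrasts with the same direction. Genes with a zero fold-change
#' in either contrast are excluded as ambiguous.
#'
#' @param region_genes character vector of gene ids in the region (or a
#'   data.frame with a `gene_id` column); DEG rows outside it are
#'   ignored.
#' @param deg_mf,deg_mp data.frames `gene_id`, `log2fc`; duplicate gene
#'   ids within a table are an error.
#' @return object of class `concordance`: list with `concordant`
#'   (data.frame `gene_id`, `log2fc_mf`, `log2fc_mp`, `direction`),
#'   `n_concordant`, `n_male`, `n_female`, `n_deg_mf`, `n_deg_mp`
#'   (region-restricted contrast counts with `_male`/`_female` splits).
#' @export
concordant_degs <- function(region_genes, deg_mf, deg_mp) {
  if (is.data.frame(region_genes)) region_genes <- region_genes$gene_id
  for (nm in c("deg_mf", "deg_mp")) {
    d <- get(nm)
    dup <- d$gene_id[duplicated(d$gene_id)]
    stop_if_not(length(dup) == 0L, "concordant_degs: duplicate gene ids in ",
                nm, ": ", paste(unique(dup), collapse = ", "))
  }
  mf <- deg_mf[deg_mf$gene_id %in% region_genes, , drop = FALSE]
  mp <- deg_mp[deg_mp$gene_id %in% region_genes, , drop = FALSE]
  mf$dir <- direction_from_log2fc(mf$log2fc)
  mp$dir <- direction_from_log2fc(mp$log2fc)
  shared <- merge(mf, mp, by = "gene_id", suffixes = c("_mf", "_mp"))
  conc <- shared[!is.na(shared$dir_mf) & !is.na(shared$dir_mp) &
                   shared$dir_mf == shared$dir_mp, , drop = FALSE]
  conc <- data.frame(gene_id = conc$gene_id,
                     log2fc_mf = conc$log2fc_mf, log2fc_mp = conc$log2fc_mp,
                     direction = conc$dir_mf, stringsAsFactors = FALSE)
  conc <- conc[order(conc$gene_id), , drop = FALSE]
  rownames(conc) <- NULL
  structure(list(
    concordant = conc,
    n_concordant = nrow(conc),
    n_male = sum(conc$direction == "male"),
    n_female = sum(conc$direction == "female"),
    n_deg_mf = nrow(mf), n_deg_mf_male = sum(mf$dir == "male", na.rm = TRUE),
    n_deg_mf_female = sum(mf$dir == "female", na.rm = TRUE),
    n_deg_mp = nrow(mp), n_deg_mp_male = sum(mp$dir == "male", na.rm = TRUE),
    n_deg_mp_female = sum(mp$dir == "female", na.rm = TRUE)
  ), class = "concordance")
}

#' @export
print.concordance <- function(x, ...) {
  cat(sprintf(paste0("DEG concordance: %d male-vs-female DEGs (%d/%d), ",
                     "%d male-vs-pseudofemale DEGs;\n  %d concordant ",
                     "(%d male-biased, %d female-biased)\n"),
              x$n_deg_mf, x$n_deg_mf_male, x$n_deg_mf_female,
              x$n_deg_mp, x$n_concordant, x$n_male, x$n_female))
  invisible(x)
}

#' Sex-specific GO terms among concordant DEGs
#'
#' A level-2 GO term is sex-specific when all of its concordant member
#' genes share one expression direction (and it has at least one member).
#' No ontology traversal is performed: terms are compared at the level
#' given in the annotation.
#'
#' @param gene_go data.frame with columns `gene_id`, `go_term` (one row
#'   per gene-term link; only concordant genes should be supplied).
#' @param directions named character vector gene_id -> "male"/"female"
#'   (e.g. from [concordant_degs()]).
#' @return data.frame `go_term`, `direction`, `n_genes`, `genes`
#'   (";"-joined), sex-specific terms only.
#' @export
sex_specific_go_terms <- function(gene_go, directions) {
  stop_if_not(nrow(gene_go) >= 1L, "sex_specific_go_terms: no annotations")
  gene_go <- gene_go[gene_go$gene_id %in% names(directions), , drop = FALSE]
  res <- lapply(split(gene_go, gene_go$go_term), function(d) {
    dirs <- unique(directions[unique(d$gene_id)])
    if (length(dirs) != 1L) return(NULL)
    genes <- sort(unique(d$gene_id))
    data.frame(go_term = d$go_term[1L], direction = dirs,
               n_genes = length(genes),
               genes = paste(genes, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    return(data.frame(go_term = character(0), direction = character(0),
                      n_genes = integer(0), genes = character(0)))
  out <- out[order(out$direction, out$go_term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Tag genes carrying sex-related KEGG pathways
#'
#' @param gene_kegg data.frame `gene_id`, `kegg_pathways` (";"-separated;
#'   `NA` or "" for none).
#' @param pathways character vocabulary of sex-related pathways
#'   (default [sex_related_pathways()]); matching is case-insensitive.
#' @return data.frame `gene_id`, `sex_pathways` (";"-joined matches),
#'   genes with at least one match.
#' @export
kegg_sex_tagged <- function(gene_kegg, pathways = sex_related_pathways()) {
  pl <- tolower(trimws(pathways))
  res <- lapply(seq_len(nrow(gene_kegg)), function(i) {
    p <- gene_kegg$kegg_pathways[i]
    if (is.na(p) || !nzchar(p)) return(NULL)
    items <- trimws(strsplit(p, ";")[[1]])
    hit <- items[tolower(items) %in% pl]
    if (length(hit) == 0L) return(NULL)
    data.frame(gene_id = gene_kegg$gene_id[i],
               sex_pathways = paste(hit, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    return(data.frame(gene_id = character(0), sex_pathways = character(0)))
  rownames(out) <- NULL
  out
}

#' Select candidate sex-determining genes
#'
#' Combines the GO sex-specific gene set and the sex-related-KEGG gene
#' set under a configurable rule. The published integration rule is not
#' fully specified, so the report always carries both component sets:
#' `union` (default), `go_only`, `kegg_only`, or `manual` with an
#' explicit `manual_ids` list.
#'
#' @param concordance a [concordant_degs()] result.
#' @param go_terms result of [sex_specific_go_terms()].
#' @param kegg_tags result of [kegg_sex_tagged()].
#' @param rule selection rule.
#' @param manual_ids character vector for `rule = "manual"`.
#' @param annotations optional data.frame `gene_id`, `nr_description`.
#' @return object of class `candidate_report`: list with `candidates`
#'   (data.frame `gene_id`, `direction`, `nr_description`,
#'   `sex_pathways`), `n_male`, `n_female`, `go_genes`, `kegg_genes`,
#'   `rule`.
#' @export
select_candidates <- function(concordance, go_terms, kegg_tags,
                              rule = c("union", "go_only", "kegg_only",
                                       "manual"),
                              manual_ids = NULL, annotations = NULL) {
  rule <- match.arg(rule)
  go_genes <- sort(unique(unlist(strsplit(go_terms$genes, ";"))))
  kegg_genes <- sort(unique(kegg_tags$gene_id))
  ids <- switch(rule,
                union = sort(union(go_genes, kegg_genes)),
                go_only = go_genes,
                kegg_only = kegg_genes,
                manual = {
                  stop_if_not(!is.null(manual_ids),
                              "select_candidates: manual rule needs manual_ids")
                  sort(unique(manual_ids))
                })
  dirs <- stats::setNames(concordance$concordant$direction,
                          concordance$concordant$gene_id)
  paths <- stats::setNames(kegg_tags$sex_pathways, kegg_tags$gene_id)
  cand <- data.frame(
    gene_id = ids,
    direction = unname(dirs[ids]),
    nr_description = if (!is.null(annotations))
      annotations$nr_description[match(ids, annotations$gene_id)]
    else rep(NA_character_, length(ids)),
    sex_pathways = unname(paths[ids]),
    stringsAsFactors = FALSE)
  structure(list(candidates = cand,
                 n_male = sum(cand$direction == "male", na.rm = TRUE),
                 n_female = sum(cand$direction == "female", na.rm = TRUE),
                 go_genes = go_genes, kegg_genes = kegg_genes, rule = rule),
            class = "candidate_report")
}

#' @export
print.candidate_report <- function(x, ...) {
  cat(sprintf("candidate screen (rule = %s): %d candidates (%d male-biased, %d female-biased)\n",
              x$rule, nrow(x$candidates), x$n_male, x$n_female))
  cat(sprintf("  GO sex-specific genes: %d;  sex-related-KEGG genes: %d\n",
              length(x$go_genes), length(x$kegg_genes)))
  invisible(x)
}
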