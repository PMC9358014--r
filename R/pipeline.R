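#' Run the full analysis pipeline on simulated or supplied inputs
#'
#' Orchestrates one configured run: input generation (or loading),
#' assembly summary, sex-association QTL screen, evidence-based region
#' delineation with gene extraction, concordant-DEG candidate screening,
#' and synteny-based karyotype inference. Each stage's outputs are
#' written under `out_dir` and checksummed into the consolidated JSON
#' report. The region track and the synteny track are independent: a
#' failure in one is recorded in the report without aborting the other.
#'
#' @param config a [sim_config()] driving the synthetic inputs.
#' @param out_dir output directory (created if needed).
#' @param fraction containment fraction for the region windows.
#' @param lod_chromwide,lod_genomewide QTL LOD thresholds.
#' @param rule candidate selection rule (see [select_candidates()]).
#' @param ancestral_n ancestral haploid chromosome number for the
#'   karyotype inference; the ancestral species is the configured
#'   assembly (`config$ancestral_name`).
#' @param proto_n optional proto-karyotype haploid number (trajectory
#'   metadata).
#' @param dry_run logical; print the stage plan and write nothing.
#' @return object of class `pipeline_report` (invisibly the parsed
#'   report list); written to `out_dir/report.json`.
#' @export
run_pipeline <- function(config, out_dir,
                         fraction = 0.9,
                         lod_chromwide = 5.2, lod_genomewide = 7.0,
                         rule = "union",
                         ancestral_n = 29L, proto_n = NULL,
                         dry_run = FALSE) {
  stages <- c("simulate", "summarize", "qtl", "region", "screen", "synteny")
  if (dry_run) {
    cat("pipeline plan:\n")
    for (s in stages) cat("  -", s, "\n")
    return(invisible(stages))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(package = "karyoregion",
                 version = as.character(utils::packageVersion("karyoregion")),
                 seed = config$seed,
                 parameters = list(fraction = fraction,
                                   lod_chromwide = lod_chromwide,
                                   lod_genomewide = lod_genomewide,
                                   rule = rule, ancestral_n = ancestral_n),
                 stages = list())
  files <- character(0)
  track <- function(expr, stage) {
    tryCatch({
      val <- force(expr)
      report$stages[[stage]] <<- c(list(status = "ok"), val)
      TRUE
    }, error = function(e) {
      report$stages[[stage]] <<- list(status = "error",
                                      message = conditionMessage(e))
      FALSE
    })
  }

  # -- inputs ---------------------------------------------------------
  skel <- generate_assembly(config)
  evidence <- generate_evidence(config)
  f1 <- generate_f1_genotypes(config)
  degs <- generate_deg_tables(config)
  genes <- generate_gene_models(config)
  blocks <- generate_synteny_blocks(config)
  files <- c(files,
             write_skeleton_tsv(skel, file.path(out_dir, "assembly.tsv")),
             write_evidence_bed(evidence, file.path(out_dir, "evidence.bed")),
             write_genotypes_tsv(f1, file.path(out_dir, "genotypes.tsv")),
             write_deg_tsv(degs$deg_mf, file.path(out_dir, "deg_mf.tsv")),
             write_deg_tsv(degs$deg_mp, file.path(out_dir, "deg_mp.tsv")),
             write_genes_gff3(genes, file.path(out_dir, "genes.gff3")),
             write_synteny_tsv(blocks, file.path(out_dir, "blocks.tsv")))
  report$stages$simulate <- list(status = "ok",
                                 n_evidence = nrow(evidence),
                                 n_genes = nrow(genes),
                                 n_blocks = nrow(blocks))

  # -- assembly summary ----------------------------------------------
  track({
    st <- assembly_stats(skel)
    list(total_bp = st$total_bp, n_chroms = st$n_contigs,
         N50 = st$N50, L50 = st$L50)
  }, "summarize")

  # -- region track: QTL screen + delineation + genes ----------------
  region <- NULL
  track({
    scan <- scan_sex_association(f1$genotypes, f1$sex, f1$map)
    screen <- filter_qtls(scan, lod_chromwide, lod_genomewide)
    utils::write.table(scan, file.path(out_dir, "qtl_scan.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(n_pass_chromwide = screen$n_total_pass_chromwide,
         n_pass_genomewide = screen$n_pass_genomewide,
         n_pve100 = unname(screen$pve_histogram[["eq100"]]),
         span_cM = if (!is.null(screen$span_cM))
           unname(screen$span_cM[["width"]]) else NA)
  }, "qtl")
  ok_region <- track({
    region <- delineate_region(evidence, fraction = fraction)
    in_region <- genes_in_region(genes, region,
                                 known_chroms = skel$name)
    utils::write.table(
      data.frame(chrom = region$chrom, start = region$start,
                 end = region$end),
      file.path(out_dir, "region.bed"), sep = "\t", quote = FALSE,
      row.names = FALSE, col.names = FALSE)
    attr(region, "genes") <- in_region
    list(chrom = region$chrom, start = region$start, end = region$end,
         length_Mb = region$length_Mb,
         majority_fraction = region$majority$fraction,
         n_region_genes = nrow(in_region))
  }, "region")
  track({
    stop_if_not(ok_region, "region stage failed upstream")
    in_region <- attr(region, "genes")
    conc <- concordant_degs(in_region$gene_id, degs$deg_mf, degs$deg_mp)
    utils::write.table(conc$concordant,
                       file.path(out_dir, "concordant_degs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(n_deg_mf = conc$n_deg_mf, n_deg_mp = conc$n_deg_mp,
         n_concordant = conc$n_concordant,
         n_male = conc$n_male, n_female = conc$n_female)
  }, "screen")

  # -- synteny track --------------------------------------------------
  track({
    rels <- lapply(split(blocks, blocks$species_a), classify_relationships)
    g <- build_homology_graph(rels)
    cl <- find_evolution_clusters(g)
    ki <- karyotype_inference(cl$clusters, config$ancestral_name,
                              ancestral_n, proto_n)
    write_synteny_tsv(do.call(rbind, lapply(rels, `[[`, "relationships")),
                      file.path(out_dir, "relationships.tsv"))
    utils::write.table(ki$events, file.path(out_dir, "karyotype.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(n_clusters = length(cl$clusters),
         inferred_n = stats::setNames(as.list(ki$events$inferred_n),
                                      ki$events$species))
  }, "synteny")

  out_files <- list.files(out_dir, full.names = TRUE)
  out_files <- out_files[!grepl("report[.]json$", out_files)]
  report$checksums <- as.list(tools::md5sum(sort(out_files)))
  names(report$checksums) <- basename(names(report$checksums))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  failed <- vapply(report$stages, function(s) identical(s$status, "error"),
                   logical(1))
  if (any(failed))
    warning("pipeline stages failed: ",
            paste(names(report$stages)[failed], collapse = ", "),
            call. = FALSE)
  class(report) <- "pipeline_report"
  invisible(report)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("pipeline report (seed %d)\n", x$seed))
  for (nm in names(x$stages))
    cat(sprintf("  %-9s %s\n", nm, x$stages[[nm]]$status))
  if (!is.null(x$stages$region) && x$stages$region$status == "ok")
    cat(sprintf("  final region: %s %.2f Mb\n",
                x$stages$region$chrom, x$stages$region$length_Mb))
  invisible(x)
}
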