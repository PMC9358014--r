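#' Chromosome table of the P. ussuriensis assembly
#'
#' The 26 chromosome-level sequences of the female *Pseudobagrus
#' ussuriensis* assembly with their linkage-group correspondence, physical
#' length (Mb), genetic length (cM), anchored gene count and gene density
#' (genes/Mb). These printed per-chromosome figures are the reference
#' inputs for the assembly-summary arithmetic and the default chromosome
#' frame of the synthetic-data generators.
#'
#' @return data.frame with columns `chrom`, `lg`, `length_mb`,
#'   `genetic_cm`, `n_genes`, `density`.
#' @export
#' @examples
#' sum(pu_chromosome_table()$length_mb)  # 722.22
pu_chromosome_table <- function() {
  df <- read.table(header = TRUE, stringsAsFactors = FALSE, text = "
chrom lg length_mb genetic_cm n_genes density
chr01 LG4 44.39 100.28 1555 35.03
chr02 LG3 42.31 121.38 1376 32.52
chr03 LG2 40.92 134.97 1231 30.08
chr04 LG5 37.81 103.10 1210 32.00
chr05 LG8 34.58 85.47 1074 31.06
chr06 LG7 33.77 103.94 1058 31.33
chr07 LG9 33.32 102.64 1090 32.71
chr08 LG1 32.06 108.52 912 28.45
chr09 LG6 29.58 116.98 967 32.69
chr10 LG13 29.44 91.20 751 25.51
chr11 LG12 28.53 151.36 978 34.28
chr12 LG20 28.21 106.71 965 34.21
chr13 LG11 27.56 110.15 648 23.51
chr14 LG23 26.75 109.60 860 32.15
chr15 LG10 26.48 87.00 868 32.78
chr16 LG15 25.77 84.26 805 31.24
chr17 LG14 22.93 118.50 879 38.33
chr18 LG16 22.81 98.47 822 36.04
chr19 LG21 22.37 90.78 848 37.91
chr20 LG22 22.30 92.32 881 39.51
chr21 LG19 19.40 79.15 649 33.45
chr22 LG25 19.03 105.93 681 35.79
chr23 LG18 18.56 93.55 559 30.12
chr24 LG24 18.43 96.61 684 37.11
chr25 LG17 17.46 82.53 633 36.25
chr26 LG26 17.45 81.31 680 38.97
")
  df
}

#' Default chromosome lengths in bp
#'
#' Named vector of the 26 chromosome lengths (bp) of the reference
#' assembly, i.e. `pu_chromosome_table()$length_mb * 1e6`.
#'
#' @return named numeric vector, names `chr01`..`chr26`.
#' @export
pu_chrom_lengths <- function() {
  tab <- pu_chromosome_table()
  stats::setNames(tab$length_mb * 1e6, tab$chrom)
}

#' Sex-linked evidence summary on chr08
#'
#' The per-class sex-linked evidence mapped to chr08 of the assembly:
#' the window holding 55/57 of the fully sex-linked QTLs, the window
#' holding 314/326 of the male-specific 2b-RAD tags, the male-specific
#' microsatellite PuGT54 (a point at 19.48 Mb) and a male-specific SCAR
#' sequence (8.36-8.37 Mb). Coordinates are bp, 0-based half-open.
#' Feeding this table to [integrate_evidence()] reproduces the final
#' 16.83 Mb sex-determining region.
#'
#' @return data.frame with columns `cls`, `chrom`, `start`, `end`,
#'   `n_contained`, `n_total` (NA for single markers).
#' @export
pu_sex_evidence <- function() {
  data.frame(
    cls = c("qtl", "rad_tag", "ssr", "scar"),
    chrom = "chr08",
    start = c(7.20e6, 6.90e6, 19.48e6, 8.36e6),
    end   = c(22.96e6, 23.73e6, 19.48e6 + 1, 8.37e6),
    n_contained = c(55L, 314L, NA, NA),
    n_total = c(57L, 326L, NA, NA),
    stringsAsFactors = FALSE
  )
}

#' Candidate sex-determining genes of the chr08 region
#'
#' The sixteen candidate sex-determining genes screened from the chr08
#' sex-determining region, with the male-vs-female log2 fold-change,
#' NR description and annotated sex-related KEGG pathways
#' (";"-separated, `NA` when none).
#'
#' @return data.frame with columns `gene_id`, `log2fc_mf`,
#'   `nr_description`, `kegg_pathways`.
#' @export
candidate_gene_table <- function() {
  df <- data.frame(
    gene_id = c("Chr08.223", "Chr08.303", "Chr08.358", "Chr08.368",
                "Chr08.399", "Chr08.409", "Chr08.428", "Chr08.520",
                "Chr08.527", "Chr08.566", "Chr08.570", "Chr08.571",
                "Chr08.572", "Chr08.622", "Chr08.746", "Chr08.760"),
    log2fc_mf = c(8.3753, 8.5218, -2.4828, 4.4330, 4.3033, 10.8953,
                  -7.3091, -4.4996, -4.2231, 3.5367, 3.4892, 4.4797,
                  3.5372, 3.2926, -4.8826, -4.7110),
    nr_description = c(
      "Nuclear receptor subfamily 4 group A member 2 (nr4a2)",
      "Low-density lipoprotein receptor-related protein 2 (lrp2)",
      "Acyl-CoA-binding protein (acbp)",
      "Interferon-induced helicase C domain-containing protein 1 (ifih1)",
      "Caspase-8 (casp8)",
      "Homeobox protein Hox-D3 (hoxd3a)",
      "Cell division cycle-associated protein 7 (cdca7)",
      "Serine/threonine-protein phosphatase 2A regulatory subunit B beta (ppp2r3b)",
      "Cell division cycle protein 16 homolog (cdc16)",
      "Sterol 26-hydroxylase, mitochondrial (cyp27a1)",
      "Collagen alpha-2(IV) chain (col4a2)",
      "Collagen alpha-2(IV) chain (col4a2)",
      "Collagen alpha-1(IV) chain (col4a1)",
      "3-Beta-hydroxysteroid dehydrogenase/Delta 5->4-isomerase (hsd3b)",
      "Testis-expressed protein 30 (tex30)",
      "Frizzled-5 (fzd5)"),
    kegg_pathways = c(
      "Aldosterone synthesis and secretion",
      "Hedgehog signaling pathway;Cholesterol metabolism",
      "PPAR signaling pathway",
      "RIG-I-like receptor signaling pathway",
      "TNF signaling pathway",
      NA,
      NA,
      "PI3K-Akt signaling pathway",
      "Cell cycle;Oocyte meiosis;Progesterone-mediated oocyte maturation",
      "PPAR signaling pathway;Cholesterol metabolism",
      "PI3K-Akt signaling pathway",
      "PI3K-Akt signaling pathway",
      "PI3K-Akt signaling pathway",
      "Aldosterone synthesis and secretion;Steroid hormone biosynthesis;Ovarian steroidogenesis;Cortisol synthesis and secretion",
      NA,
      "Wnt signaling pathway"),
    stringsAsFactors = FALSE
  )
  df
}

#' Sex-related KEGG pathway vocabulary
#'
#' Editable default list of KEGG pathways treated as sex-related when
#' tagging candidate genes. Matching is case-insensitive.
#'
#' @return character vector of pathway names.
#' @export
sex_related_pathways <- function() {
  c("TGF-beta signaling pathway",
    "Wnt signaling pathway",
    "Estrogen signaling pathway",
    "Ovarian steroidogenesis",
    "PI3K-Akt signaling pathway",
    "Aldosterone synthesis and secretion",
    "Cholesterol metabolism",
    "Steroid hormone biosynthesis",
    "Progesterone-mediated oocyte maturation",
    "Oocyte meiosis",
    "Cortisol synthesis and secretion",
    "PPAR signaling pathway",
    "TNF signaling pathway",
    "RIG-I-like receptor signaling pathway",
    "Hedgehog signaling pathway",
    "Cell cycle")
}

#' Pairwise chromosome relationship edges among five catfish genomes
#'
#' Chromosome-to-chromosome homology edges between *P. ussuriensis* (Pu)
#' and each of *P. fulvidraco* (Pf), *I. punctatus* (Ip), *S. meridionalis*
#' (Sm) and *P. hypophthalmus* (Ph), encoding the published pairwise
#' synteny relationships. Non-bijective relationships (fusions/fissions)
#' are enumerated explicitly; the one-to-one edges required to complete
#' the four published evolution-cluster memberships are inferred from
#' those memberships (the underlying one-to-one lists are not printed
#' chromosome-by-chromosome). Conserved one-to-one pairs outside the four
#' clusters are intentionally omitted: they form no evolution cluster.
#'
#' @return data.frame with columns `species_a`, `chrom_a`, `species_b`,
#'   `chrom_b`, `label`.
#' @seealso [build_homology_graph()], [find_evolution_clusters()]
#' @export
catfish_relationship_edges <- function() {
  edge <- function(sb, txt, label) {
    # txt: "puChrom bChrom" pairs
    m <- do.call(rbind, strsplit(strsplit(txt, ";")[[1]], " "))
    data.frame(species_a = "Pu", chrom_a = m[, 1], species_b = sb,
               chrom_b = m[, 2], label = label, stringsAsFactors = FALSE)
  }
  rbind(
    # Pu vs Pf: three one-to-two, two two-to-one
    edge("Pf", "chr1 chr2;chr1 chr23;chr2 chr7;chr2 chr8;chr3 chr7;chr3 chr16",
         "one-to-two"),
    edge("Pf", "chr21 chr2;chr4 chr1;chr23 chr1", "two-to-one"),
    edge("Pf", "chr5 chr5;chr9 chr9;chr13 chr15;chr18 chr19", "one-to-one"),
    # Pu vs Ip: five one-to-two, one two-to-one
    edge("Ip", paste0("chr1 chr10;chr1 chr20;chr2 chr13;chr2 chr29;",
                      "chr3 chr12;chr3 chr25;chr5 chr11;chr5 chr12;",
                      "chr9 chr2;chr9 chr22"), "one-to-two"),
    edge("Ip", "chr18 chr2", "two-to-one"),
    edge("Ip", "chr21 chr21;chr13 chr19;chr4 chr7;chr23 chr27", "one-to-one"),
    # Pu vs Sm: four one-to-two, one two-to-one
    edge("Sm", paste0("chr1 chr9;chr1 chr20;chr2 chr7;chr2 chr28;",
                      "chr3 chr23;chr3 chr29;chr9 chr18;chr9 chr27"),
         "one-to-two"),
    edge("Sm", "chr13 chr18", "two-to-one"),
    edge("Sm", "chr21 chr19;chr5 chr1;chr18 chr14;chr4 chr6;chr23 chr26",
         "one-to-one"),
    # Pu vs Ph: four one-to-two
    edge("Ph", paste0("chr1 chr11;chr1 chr21;chr2 chr12;chr2 chr28;",
                      "chr3 chr19;chr3 chr29;chr9 chr24;chr9 chr30"),
         "one-to-two"),
    edge("Ph", "chr21 chr20;chr5 chr2;chr13 chr13;chr18 chr18;chr4 chr4;chr23 chr25",
         "one-to-one")
  )
}
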