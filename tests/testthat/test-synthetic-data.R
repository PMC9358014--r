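test_that("default assembly matches the configured chromosome frame", {
  cfg <- sim_config(seed = 1)
  skel <- generate_assembly(cfg)
  expect_equal(nrow(skel), 26L)
  expect_equal(max(skel$length), 44390000)
  expect_equal(min(skel$length), 17450000)
  expect_equal(sum(skel$length), 722220000)

  tiny <- sim_config(seed = 1, chrom_lengths = c(chrA = 1000),
                     planted_region = list(chrom = "chrA", start = 100,
                                           end = 900),
                     n_evidence_per_class = c(tag = 5),
                     containment_fraction = 1)
  expect_equal(sum(generate_assembly(tiny)$length), 1000)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(seed = 1, chrom_lengths = c(chrA = -5)),
               "positive")
  expect_error(sim_config(seed = 1,
                          planted_region = list(chrom = "chr08",
                                                start = 1e6, end = 99e6)),
               "outside")
  expect_error(sim_config(seed = 1, containment_fraction = 0), "fraction")
})

test_that("generated FASTA sequences match skeleton lengths and target GC", {
  cfg <- sim_config(seed = 3, chrom_lengths = c(chrA = 40000, chrB = 20000),
                    planted_region = list(chrom = "chrA", start = 0,
                                          end = 10000))
  skel <- generate_assembly(cfg, fasta = TRUE, gc = 0.40)
  seqs <- attr(skel, "sequences")
  expect_equal(unname(Biostrings::width(seqs)), skel$length)
  expect_lt(abs(gc_content(seqs) - 0.40), 0.02)
})

test_that("evidence containment realizes the configured fraction exactly", {
  cfg <- sim_config(seed = 2)
  ev <- generate_evidence(cfg)
  pr <- cfg$planted_region
  inside <- ev$chrom == pr$chrom & ev$start >= pr$start & ev$end <= pr$end
  expect_equal(sum(inside & ev$cls == "rad_tag"), 314L)
  expect_equal(sum(ev$cls == "rad_tag"), 326L)
  # everything not inside is off the planted chromosome by construction
  expect_true(all(ev$chrom[!inside] != pr$chrom))
  # output sorted within class
  for (cl in unique(ev$cls)) {
    d <- ev[ev$cls == cl, ]
    expect_false(is.unsorted(order(d$chrom, d$start)))
  }

  cfg55 <- sim_config(seed = 2, n_evidence_per_class = c(qtl = 57),
                      containment_fraction = 0.965)
  ev55 <- generate_evidence(cfg55)
  expect_equal(sum(ev55$chrom == "chr08" & ev55$start >= pr$start &
                     ev55$end <= pr$end), 55L)

  cfg_all <- sim_config(seed = 2, n_evidence_per_class = c(tag = 10),
                        containment_fraction = 1)
  ev_all <- generate_evidence(cfg_all)
  expect_true(all(ev_all$chrom == "chr08" & ev_all$start >= pr$start &
                    ev_all$end <= pr$end))
})

test_that("F1 genotypes have a perfectly linked sex locus and Haldane decay", {
  cfg <- sim_config(seed = 5, n_offspring = 200, n_markers = 50)
  f1 <- generate_f1_genotypes(cfg)
  expect_lte(abs(sum(f1$sex == "M") - sum(f1$sex == "F")), 1L)
  carrier <- as.integer(f1$sex == "M")
  expect_equal(unname(f1$genotypes[, f1$sex_locus]), carrier)

  # discordance at every marker within joint binomial 99.9% bounds of the
  # Haldane recombination fraction for its map distance
  locus_cm <- f1$map$cM[f1$map$marker == f1$sex_locus]
  n <- cfg$n_offspring
  for (j in seq_len(ncol(f1$genotypes))) {
    d <- abs(f1$map$cM[j] - locus_cm)
    r <- 0.5 * (1 - exp(-2 * d / 100))
    disc <- sum(f1$genotypes[, j] != carrier)
    expect_gte(disc, qbinom(0.0005, n, r))
    expect_lte(disc, qbinom(0.9995, n, r))
  }
})

test_that("DEG tables realize the overlap specification exactly", {
  cfg <- sim_config(seed = 4)
  degs <- generate_deg_tables(cfg)
  expect_equal(nrow(degs$deg_mf), 181L)
  expect_equal(nrow(degs$deg_mp), 150L)
  conc <- concordant_degs(sprintf("Chr08.%03d", 1:554),
                          degs$deg_mf, degs$deg_mp)
  expect_equal(conc$n_concordant, 135L)
  expect_equal(conc$n_male, 65L)
  expect_equal(conc$n_female, 70L)
  expect_equal(conc$n_deg_mf_male, 85L)
  expect_equal(conc$n_deg_mf_female, 96L)

  # small hand-enumerable spec
  small <- sim_config(seed = 4,
                      deg_overlap_spec = c(concordant_male = 3,
                                           concordant_female = 2,
                                           discordant = 4, mf_only = 3,
                                           mp_only = 2),
                      n_region_genes = 20)
  d2 <- generate_deg_tables(small)
  c2 <- concordant_degs(sprintf("Chr08.%03d", 1:20), d2$deg_mf, d2$deg_mp)
  expect_equal(c2$n_concordant, 5L)

  zero <- sim_config(seed = 4,
                     deg_overlap_spec = c(concordant_male = 0,
                                          concordant_female = 0,
                                          discordant = 0, mf_only = 0,
                                          mp_only = 0))
  d0 <- generate_deg_tables(zero)
  expect_equal(nrow(d0$deg_mf), 0L)
  expect_equal(nrow(d0$deg_mp), 0L)

  big <- sim_config(seed = 4, n_region_genes = 50)
  expect_error(generate_deg_tables(big), "available")
})

test_that("synteny blocks have equal spans and realize event arithmetic", {
  cfg <- sim_config(seed = 6)
  bl <- generate_synteny_blocks(cfg)
  expect_equal(bl$end_a - bl$start_a, bl$end_b - bl$start_b)

  # fission of one 30 Mb chromosome at 12 Mb -> derived 12 and 18 Mb
  fis <- sim_config(seed = 6, chrom_lengths = c(chrZ = 30e6),
                    planted_region = list(chrom = "chrZ", start = 0,
                                          end = 10e6),
                    synteny_history = list(
                      sp1 = list(list(type = "fission", chrom = "chrZ",
                                      breakpoint = 12e6,
                                      new = c("chrZa", "chrZb")))))
  k <- derived_karyotypes(fis)$sp1
  expect_equal(sort(unname(k)), c(12e6, 18e6))

  bad <- sim_config(seed = 6, synteny_history = list(
    sp1 = list(list(type = "fusion", chroms = c("chr01", "nope"),
                    new = "x"))))
  expect_error(generate_synteny_blocks(bad), "unknown chromosome")

  # identity history -> classifier sees only one-to-one
  ident <- sim_config(seed = 6, synteny_history = list(same = list()))
  rel <- classify_relationships(generate_synteny_blocks(ident))
  expect_true(all(rel$relationships$label == "one-to-one"))
})

test_that("identical seed and config give identical outputs; substreams are isolated", {
  a <- sim_config(seed = 11); b <- sim_config(seed = 11)
  expect_identical(generate_evidence(a), generate_evidence(b))
  expect_identical(generate_f1_genotypes(a), generate_f1_genotypes(b))
  expect_identical(generate_deg_tables(a), generate_deg_tables(b))
  expect_identical(generate_synteny_blocks(a), generate_synteny_blocks(b))
  # running another generator in between must not perturb a substream
  ev1 <- generate_evidence(a)
  invisible(generate_f1_genotypes(a))
  invisible(generate_assembly(a, fasta = FALSE))
  ev2 <- generate_evidence(a)
  expect_identical(ev1, ev2)
  expect_false(identical(generate_evidence(sim_config(seed = 12)), ev1))
})

test_that("every generated file round-trips through the package readers", {
  cfg <- sim_config(seed = 8, n_offspring = 20, n_markers = 10,
                    n_region_genes = 30)
  dir <- withr::local_tempdir()
  skel <- generate_assembly(cfg)
  write_skeleton_tsv(skel, file.path(dir, "s.tsv"))
  expect_equal(read_skeleton_tsv(file.path(dir, "s.tsv"))$length,
               skel$length)

  ev <- generate_evidence(cfg)
  write_evidence_bed(ev, file.path(dir, "e.bed"))
  ev2 <- read_evidence_bed(file.path(dir, "e.bed"))
  expect_equal(ev2$start, ev$start)
  expect_equal(ev2$cls, ev$cls)

  f1 <- generate_f1_genotypes(cfg)
  write_genotypes_tsv(f1, file.path(dir, "g.tsv"))
  g2 <- read_genotypes_tsv(file.path(dir, "g.tsv"))
  expect_equal(unname(g2$genotypes), unname(f1$genotypes))
  expect_equal(g2$sex, f1$sex)
  expect_equal(g2$map$cM, f1$map$cM)

  degs <- generate_deg_tables(cfg, gene_ids = sprintf("g%03d", 1:300))
  write_deg_tsv(degs$deg_mf, file.path(dir, "d.tsv"))
  expect_equal(read_deg_tsv(file.path(dir, "d.tsv")), degs$deg_mf)

  genes <- generate_gene_models(cfg, n_outside = 10)
  write_genes_gff3(genes, file.path(dir, "genes.gff3"))
  g3 <- read_genes_gff3(file.path(dir, "genes.gff3"))
  expect_equal(g3[order(g3$gene_id), c("gene_id", "chrom", "start", "end")],
               genes[order(genes$gene_id),
                     c("gene_id", "chrom", "start", "end")],
               ignore_attr = TRUE)

  bl <- generate_synteny_blocks(cfg)
  write_synteny_tsv(bl, file.path(dir, "b.tsv"))
  expect_equal(read_synteny_tsv(file.path(dir, "b.tsv")), bl)
})
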