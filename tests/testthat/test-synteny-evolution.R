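two_chrom_cfg <- function(history, lengths = c(chrX = 30e6, chrY = 20e6)) {
  sim_config(seed = 1, chrom_lengths = lengths,
             planted_region = list(chrom = names(lengths)[1], start = 0,
                                   end = 1e6),
             synteny_history = history)
}

test_that("classifier recovers fusion and fission labels from blocks", {
  fus <- two_chrom_cfg(list(sp = list(list(type = "fusion",
                                           chroms = c("chrX", "chrY"),
                                           new = "chrF"))))
  rel <- classify_relationships(generate_synteny_blocks(fus))
  expect_equal(rel$relationships$label[rel$relationships$chrom_a == "chrF"],
               "one-to-two")

  fis <- two_chrom_cfg(list(sp = list(list(type = "fission", chrom = "chrX",
                                           breakpoint = 12e6,
                                           new = c("chrXa", "chrXb")))))
  rel2 <- classify_relationships(generate_synteny_blocks(fis))
  labs <- rel2$relationships
  expect_equal(labs$label[labs$chrom_a %in% c("chrXa", "chrXb")],
               c("two-to-one", "two-to-one"))
  expect_equal(labs$label[labs$chrom_a == "chrY"], "one-to-one")

  ident <- two_chrom_cfg(list(sp = list()))
  rel3 <- classify_relationships(generate_synteny_blocks(ident))
  expect_true(all(rel3$relationships$label == "one-to-one"))
})

test_that("labels are direction-consistent when sides are swapped", {
  cfg <- two_chrom_cfg(list(sp = list(list(type = "fusion",
                                           chroms = c("chrX", "chrY"),
                                           new = "chrF"))))
  bl <- generate_synteny_blocks(cfg)
  swapped <- data.frame(species_a = bl$species_b, chrom_a = bl$chrom_b,
                        start_a = bl$start_b, end_a = bl$end_b,
                        species_b = bl$species_a, chrom_b = bl$chrom_a,
                        start_b = bl$start_a, end_b = bl$end_a)
  rel <- classify_relationships(swapped)
  # the fused chromosome's partners are two-to-one from the ancestral side
  expect_true(all(rel$relationships$label[rel$relationships$chrom_a %in%
                                            c("chrX", "chrY")] ==
                    "two-to-one"))
})

test_that("small blocks and low coverage are filtered before labelling", {
  bl <- data.frame(species_a = "d", chrom_a = c("c1", "c1"),
                   start_a = c(0, 10e6), end_a = c(10e6, 10e6 + 3e4),
                   species_b = "anc", chrom_b = c("a1", "a2"),
                   start_b = c(0, 0), end_b = c(10e6, 3e4))
  rel <- classify_relationships(bl, min_block_bp = 5e4,
                                lengths_a = c(c1 = 10.03e6),
                                lengths_b = c(a1 = 10e6, a2 = 8e6))
  # the 30 kb block to a2 is below min_block_bp: c1 stays one-to-one
  expect_equal(rel$relationships$label[rel$relationships$chrom_a == "c1"],
               "one-to-one")
  expect_error(classify_relationships(rbind(
    bl, transform(bl, species_a = "other"))), "species pairs")
})

test_that("homology graph has one node per chromosome and labelled edges", {
  e1 <- data.frame(species_a = "A", chrom_a = paste0("c", 1:3),
                   species_b = "B", chrom_b = paste0("c", 1:3),
                   label = "one-to-one")
  e2 <- data.frame(species_a = "A", chrom_a = paste0("c", 1:3),
                   species_b = "C", chrom_b = paste0("c", 1:3),
                   label = "one-to-one")
  g <- build_homology_graph(rbind(e1, e2))
  expect_equal(igraph::vcount(g), 9L)
  expect_equal(igraph::ecount(g), 6L)
  expect_equal(igraph::vcount(build_homology_graph(e1[0, ])), 0L)
})

test_that("components agree with a union-find oracle on random graphs", {
  set.seed(77)
  for (i in 1:150) {
    n <- sample(3:25, 1)
    chroms <- paste0("c", seq_len(n))
    n_edges <- sample(1:30, 1)
    ed <- data.frame(species_a = "A",
                     chrom_a = sample(chroms, n_edges, replace = TRUE),
                     species_b = "B",
                     chrom_b = sample(chroms, n_edges, replace = TRUE),
                     label = "one-to-one")
    g <- build_homology_graph(ed)
    comp <- igraph::components(g)
    got <- canon_partition(split(names(comp$membership), comp$membership))
    nodes <- igraph::V(g)$name
    want <- canon_partition(oracle_components(
      nodes, paste("A", ed$chrom_a, sep = ":"),
      paste("B", ed$chrom_b, sep = ":")))
    expect_equal(got, want)
  }
})

test_that("the encoded catfish relationships yield the four known clusters", {
  g <- build_homology_graph(catfish_relationship_edges())
  cl <- find_evolution_clusters(g)
  expect_length(cl$clusters, 4L)
  # Pu_chr1, Pu_chr21 and Pf_chr2 sit in one cluster
  c1 <- Filter(function(x) any(x$members$species == "Pu" &
                                 x$members$chrom == "chr1"), cl$clusters)
  expect_length(c1, 1L)
  mem <- paste(c1[[1]]$members$species, c1[[1]]$members$chrom)
  expect_true(all(c("Pu chr1", "Pu chr21", "Pf chr2") %in% mem))
  # per-species member counts of the largest (most complex) cluster
  big <- cl$clusters[[1]]
  expect_equal(as.integer(big$counts[c("Pu", "Pf", "Ip", "Sm", "Ph")]),
               c(3L, 4L, 5L, 5L, 5L))
})

test_that("an all-bijective graph contains no evolution cluster", {
  e <- data.frame(species_a = "A", chrom_a = paste0("c", 1:4),
                  species_b = "B", chrom_b = paste0("c", 1:4),
                  label = "one-to-one")
  cl <- find_evolution_clusters(build_homology_graph(e))
  expect_length(cl$clusters, 0L)
  expect_length(cl$conserved, 4L)
})

test_that("event inference follows count parsimony with ancestral reference", {
  g <- build_homology_graph(catfish_relationship_edges())
  cl <- find_evolution_clusters(g)
  # cluster holding Ph_chr30 (four Ph chromosomes vs three ancestral)
  c3 <- Filter(function(x) any(x$members$species == "Ph" &
                                 x$members$chrom == "chr30"), cl$clusters)[[1]]
  ev3 <- infer_events(c3, "Ip")
  expect_equal(ev3$n_fissions[ev3$species == "Ph"], 1L)
  expect_equal(ev3$n_fusions[ev3$species == "Ph"], 0L)
  # Pu has 3 chromosomes vs 3 ancestral but a non-bijective direct
  # relationship: a count-neutral rearrangement
  expect_equal(ev3$n_fusions[ev3$species == "Pu"], 1L)
  expect_equal(ev3$n_fissions[ev3$species == "Pu"], 1L)
  # cluster holding Pu_chr1: two Pu vs three ancestral -> one fusion
  c1 <- Filter(function(x) any(x$members$species == "Pu" &
                                 x$members$chrom == "chr1"), cl$clusters)[[1]]
  ev1 <- infer_events(c1, "Ip")
  expect_equal(ev1$n_fusions[ev1$species == "Pu"], 1L)
  expect_equal(ev1$n_fissions[ev1$species == "Pu"], 0L)
  # equal counts with bijective direct partners -> no events
  expect_equal(unlist(ev1[ev1$species == "Sm", c("n_fusions", "n_fissions")],
                      use.names = FALSE), c(0L, 0L))
  expect_error(infer_events(c1, "Zz"), "absent")
})

test_that("karyotype inference reproduces the published chromosome numbers", {
  g <- build_homology_graph(catfish_relationship_edges())
  cl <- find_evolution_clusters(g)
  ki <- karyotype_inference(cl$clusters, "Ip", 29, proto_n = 25)
  ev <- ki$events
  expect_equal(ev$inferred_n[ev$species == "Ph"], 30)
  expect_equal(ev$inferred_n[ev$species == "Pu"], 26)
  expect_equal(ev$inferred_n[ev$species == "Pf"], 26)
  expect_equal(ev$inferred_n[ev$species == "Sm"], 29)
  expect_equal(ev$trajectory[ev$species == "Pu"], "25-29-26")

  none <- karyotype_inference(list(), "Ip", 29)
  expect_equal(nrow(none$events), 0L)
})

test_that("inferred chromosome numbers match generated derived karyotypes", {
  set.seed(55)
  for (seed in 1:10) {
    lens <- stats::setNames(sample(5:40, 8) * 1e6, paste0("a", 1:8))
    history <- list(spA = list(
      list(type = "fusion", chroms = c("a1", "a2"), new = "fA"),
      list(type = "fission", chrom = "a3",
           breakpoint = floor(lens[["a3"]] / 3), new = c("a3a", "a3b")),
      list(type = "fusion", chroms = c("a4", "a5"), new = "fB")))
    cfg <- sim_config(seed = seed, chrom_lengths = lens,
                      planted_region = list(chrom = "a1", start = 0,
                                            end = 1e6),
                      synteny_history = history)
    bl <- generate_synteny_blocks(cfg)
    rel <- classify_relationships(bl)
    cl <- find_evolution_clusters(build_homology_graph(rel))
    ki <- karyotype_inference(cl$clusters, "anc", length(lens))
    actual_n <- length(derived_karyotypes(cfg)$spA)
    expect_equal(ki$events$inferred_n[ki$events$species == "spA"], actual_n)
    # material conservation under the history
    expect_equal(sum(derived_karyotypes(cfg)$spA), sum(lens))
  }
})
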