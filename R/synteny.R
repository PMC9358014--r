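#' Classify pairwise chromosome syntenic relationships
#'
#' Aggregates alignment blocks for one species pair into per-chromosome
#' partner lists and labels each chromosome's relationship. A partner is
#' kept when its total aligned bp reaches `min_coverage` times the
#' shorter of the two chromosomes, counting only blocks of at least
#' `min_block_bp`; this suppresses repeat-driven noise blocks. Labels:
#' `one-to-one` (mutually exclusive single partners), `one-to-two` /
#' `one-to-many` (a chromosome whose two / more partners map back only to
#' it), `two-to-one` (two chromosomes sharing one partner), `unassigned`
#' (no surviving partner). Chromosomes on more entangled subgraphs are
#' labelled `one-to-many`.
#'
#' @param blocks data.frame with columns `species_a`, `chrom_a`,
#'   `start_a`, `end_a`, `species_b`, `chrom_b`, `start_b`, `end_b`.
#' @param min_coverage fraction of the shorter chromosome that must be
#'   aligned for a partner to count.
#' @param min_block_bp minimum individual block length.
#' @param lengths_a,lengths_b optional named chromosome lengths (bp); when
#'   absent, lengths are estimated as the maximum aligned end coordinate.
#' @return object of class `synteny_relationships`: list with
#'   `relationships` (one row per `chrom_a`: `label`, `partners`,
#'   `aligned_bp`) and `edges` (`species_a`, `chrom_a`, `species_b`,
#'   `chrom_b`, `aligned_bp`, `label`) for graph building.
#' @export
classify_relationships <- function(blocks, min_coverage = 0.2,
                                   min_block_bp = 50000,
                                   lengths_a = NULL, lengths_b = NULL) {
  stop_if_not(nrow(blocks) >= 1L, "classify_relationships: no blocks")
  pair <- unique(blocks[, c("species_a", "species_b")])
  stop_if_not(nrow(pair) == 1L,
              "classify_relationships: blocks span several species pairs: ",
              paste(apply(pair, 1, paste, collapse = "-"), collapse = ", "))
  sp_a <- pair$species_a; sp_b <- pair$species_b
  if (is.null(lengths_a))
    lengths_a <- vapply(split(blocks$end_a, blocks$chrom_a), max, numeric(1))
  if (is.null(lengths_b))
    lengths_b <- vapply(split(blocks$end_b, blocks$chrom_b), max, numeric(1))
  b <- blocks[(blocks$end_a - blocks$start_a) >= min_block_bp, , drop = FALSE]
  agg <- stats::aggregate(cbind(aligned = end_a - start_a) ~ chrom_a + chrom_b,
                          data = b, FUN = sum)
  thr <- min_coverage * pmin(lengths_a[agg$chrom_a], lengths_b[agg$chrom_b])
  agg <- agg[agg$aligned >= thr, , drop = FALSE]
  # degree maps over surviving partner relations
  deg_a <- table(agg$chrom_a)   # partners per a-chromosome
  deg_b <- table(agg$chrom_b)   # partners per b-chromosome
  label_of <- function(ca) {
    part <- agg[agg$chrom_a == ca, , drop = FALSE]
    np <- nrow(part)
    if (np == 0L) return("unassigned")
    back <- deg_b[part$chrom_b]  # how many a-chroms each partner has
    if (np == 1L) {
      if (back == 1L) return("one-to-one")
      if (back == 2L) return("two-to-one")
      return("one-to-many")
    }
    if (all(back == 1L)) return(if (np == 2L) "one-to-two" else "one-to-many")
    "one-to-many"
  }
  chroms <- sort(names(lengths_a))
  rel <- do.call(rbind, lapply(chroms, function(ca) {
    part <- agg[agg$chrom_a == ca, , drop = FALSE]
    part <- part[order(-part$aligned), , drop = FALSE]
    data.frame(species_a = sp_a, chrom_a = ca, species_b = sp_b,
               label = label_of(ca),
               partners = paste(part$chrom_b, collapse = ";"),
               aligned_bp = paste(part$aligned, collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  edges <- do.call(rbind, lapply(chroms, function(ca) {
    part <- agg[agg$chrom_a == ca, , drop = FALSE]
    if (nrow(part) == 0L) return(NULL)
    data.frame(species_a = sp_a, chrom_a = ca, species_b = sp_b,
               chrom_b = part$chrom_b, aligned_bp = part$aligned,
               label = label_of(ca), stringsAsFactors = FALSE)
  }))
  rownames(rel) <- NULL
  structure(list(relationships = rel, edges = edges),
            class = "synteny_relationships")
}

#' @export
print.synteny_relationships <- function(x, ...) {
  tab <- table(x$relationships$label)
  cat(sprintf("synteny relationships %s vs %s: %s\n",
              x$relationships$species_a[1L], x$relationships$species_b[1L],
              paste(sprintf("%d %s", as.integer(tab), names(tab)),
                    collapse = ", ")))
  invisible(x)
}

#' Build the cross-species chromosome homology graph
#'
#' One node per (species, chromosome), one labelled edge per surviving
#' partner relation, across any number of species pairs.
#'
#' @param edges a data.frame with columns `species_a`, `chrom_a`,
#'   `species_b`, `chrom_b`, `label` (e.g. [catfish_relationship_edges()]
#'   or the `edges` of [classify_relationships()]), or a list of such
#'   data.frames / `synteny_relationships` objects.
#' @return igraph graph; vertex attribute `species` and `chrom`, edge
#'   attribute `label`.
#' @export
build_homology_graph <- function(edges) {
  if (inherits(edges, "synteny_relationships")) edges <- list(edges)
  if (is.list(edges) && !is.data.frame(edges)) {
    edges <- do.call(rbind, lapply(edges, function(e) {
      if (inherits(e, "synteny_relationships")) e$edges else e
    }))
  }
  if (is.null(edges) || nrow(edges) == 0L)
    return(igraph::make_empty_graph(directed = FALSE))
  from <- paste(edges$species_a, edges$chrom_a, sep = ":")
  to <- paste(edges$species_b, edges$chrom_b, sep = ":")
  g <- igraph::graph_from_data_frame(
    data.frame(from = from, to = to, label = edges$label,
               stringsAsFactors = FALSE),
    directed = FALSE)
  parts <- strsplit(igraph::V(g)$name, ":", fixed = TRUE)
  igraph::V(g)$species <- vapply(parts, `[[`, character(1), 1L)
  igraph::V(g)$chrom <- vapply(parts, function(p)
    paste(p[-1L], collapse = ":"), character(1))
  g
}

#' Find chromosome evolution clusters
#'
#' Connected components of the homology graph that contain at least one
#' non-one-to-one edge are evolution clusters (components whose edges are
#' all bijective are conserved groups, reported separately). Clusters are
#' ordered by size descending, then lexicographically by member names.
#'
#' @param graph igraph from [build_homology_graph()].
#' @return list with `clusters` and `conserved`: each element a list with
#'   `members` (data.frame `species`, `chrom`), `counts` (per-species
#'   chromosome counts) and `graph` (the component subgraph).
#' @export
find_evolution_clusters <- function(graph) {
  if (igraph::vcount(graph) == 0L)
    return(list(clusters = list(), conserved = list()))
  comp <- igraph::components(graph)
  groups <- split(igraph::V(graph)$name, comp$membership)
  info <- lapply(groups, function(vs) {
    sg <- igraph::induced_subgraph(graph, vs)
    members <- data.frame(species = igraph::V(sg)$species,
                          chrom = igraph::V(sg)$chrom,
                          stringsAsFactors = FALSE)
    members <- members[order(members$species, members$chrom), , drop = FALSE]
    rownames(members) <- NULL
    list(members = members,
         counts = table(members$species),
         graph = sg,
         nonbijective = any(igraph::E(sg)$label != "one-to-one"))
  })
  key <- vapply(info, function(x)
    paste(paste(x$members$species, x$members$chrom, sep = ":"),
          collapse = ","), character(1))
  sizes <- vapply(info, function(x) nrow(x$members), numeric(1))
  info <- info[order(-sizes, key)]
  is_cluster <- vapply(info, `[[`, logical(1), "nonbijective")
  list(clusters = lapply(info[is_cluster], function(x)
    x[c("members", "counts", "graph")]),
    conserved = lapply(info[!is_cluster], function(x)
      x[c("members", "counts", "graph")]))
}

#' Infer fusion/fission events within one cluster
#'
#' Count-parsimony event inference against a designated ancestral
#' species: a species with fewer cluster chromosomes than the ancestor
#' underwent that many fusions, one with more that many fissions. A
#' species with an equal count whose direct relationship to the ancestral
#' chromosomes is non-bijective is recorded as one fission plus one
#' fusion (a count-neutral rearrangement); without direct evidence
#' against the ancestor it is reported unchanged.
#'
#' @param cluster one element of `find_evolution_clusters()$clusters`.
#' @param ancestral_species species name; must be present in the cluster.
#' @return data.frame `species`, `n_chroms`, `n_fusions`, `n_fissions`
#'   (ancestral species excluded).
#' @export
infer_events <- function(cluster, ancestral_species) {
  members <- cluster$members
  stop_if_not(ancestral_species %in% members$species,
              "infer_events: ancestral species ", ancestral_species,
              " absent from cluster")
  k_a <- sum(members$species == ancestral_species)
  sg <- cluster$graph
  el <- igraph::as_data_frame(sg, what = "edges")
  vsp <- stats::setNames(igraph::V(sg)$species, igraph::V(sg)$name)
  res <- lapply(setdiff(unique(members$species), ancestral_species),
                function(sp) {
    k_s <- sum(members$species == sp)
    if (k_s < k_a) { fus <- k_a - k_s; fis <- 0L }
    else if (k_s > k_a) { fus <- 0L; fis <- k_s - k_a }
    else {
      direct <- el[(vsp[el$from] == sp & vsp[el$to] == ancestral_species) |
                     (vsp[el$from] == ancestral_species & vsp[el$to] == sp), ,
                   drop = FALSE]
      rearranged <- nrow(direct) > 0 && any(direct$label != "one-to-one")
      fus <- fis <- if (rearranged) 1L else 0L
    }
    data.frame(species = sp, n_chroms = k_s, n_fusions = as.integer(fus),
               n_fissions = as.integer(fis), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out[order(out$species), , drop = FALSE]
}

#' Karyotype inference across clusters
#'
#' Sums fusion/fission events over all clusters per species and infers
#' each haploid chromosome number as
#' `ancestral_n - total fusions + total fissions`. Chromosomes outside
#' the clusters are one-to-one conserved and contribute no events. An
#' optional `proto_n` is reporting-only metadata for the
#' proto -> ancestral -> derived trajectory string.
#'
#' @param clusters `find_evolution_clusters()$clusters`.
#' @param ancestral_species,ancestral_n ancestral karyotype (species name
#'   and haploid chromosome number).
#' @param proto_n optional earlier haploid number for the trajectory.
#' @return object of class `karyotype_inference`: list with `events`
#'   (data.frame `species`, `n_fusions`, `n_fissions`, `inferred_n`,
#'   `trajectory`), `ancestral_species`, `ancestral_n`, `proto_n`.
#' @export
karyotype_inference <- function(clusters, ancestral_species, ancestral_n,
                                proto_n = NULL) {
  stop_if_not(is_count(ancestral_n) && ancestral_n >= 1,
              "karyotype_inference: ancestral_n must be a positive integer")
  per <- lapply(clusters, infer_events, ancestral_species = ancestral_species)
  all_ev <- do.call(rbind, per)
  species <- sort(unique(all_ev$species))
  ev <- do.call(rbind, lapply(species, function(sp) {
    d <- all_ev[all_ev$species == sp, , drop = FALSE]
    data.frame(species = sp, n_fusions = sum(d$n_fusions),
               n_fissions = sum(d$n_fissions), stringsAsFactors = FALSE)
  }))
  if (is.null(ev))
    ev <- data.frame(species = character(0), n_fusions = integer(0),
                     n_fissions = integer(0))
  ev$inferred_n <- ancestral_n - ev$n_fusions + ev$n_fissions
  ev$trajectory <- if (!is.null(proto_n))
    sprintf("%d-%d-%d", proto_n, ancestral_n, ev$inferred_n)
  else sprintf("%d-%d", ancestral_n, ev$inferred_n)
  structure(list(events = ev, ancestral_species = ancestral_species,
                 ancestral_n = as.integer(ancestral_n), proto_n = proto_n),
            class = "karyotype_inference")
}

#' @export
print.karyotype_inference <- function(x, ...) {
  cat(sprintf("karyotype inference (ancestor %s, n = %d)\n",
              x$ancestral_species, x$ancestral_n))
  for (i in seq_len(nrow(x$events)))
    cat(sprintf("  %s: %d fusions, %d fissions -> n = %d (%s)\n",
                x$events$species[i], x$events$n_fusions[i],
                x$events$n_fissions[i], x$events$inferred_n[i],
                x$events$trajectory[i]))
  invisible(x)
}
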