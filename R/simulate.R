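#' Simulation configuration
#'
#' Builds and validates the configuration driving every synthetic-data
#' generator. Defaults emulate the study conditions of the reference
#' assembly: the 26 chromosome lengths of the published chromosome table,
#' a planted sex-determining region of 16.83 Mb (6.90-23.73 Mb) on chr08,
#' per-class evidence counts matching the mapped sex-linked marker sets
#' (57 fully sex-linked QTLs, 326 male-specific RAD tags, one SSR, one
#' SCAR), a containment fraction of 0.963, an F1 mapping family of 100
#' offspring typed at 200 markers on a 108.52 cM linkage group, and a DEG
#' overlap specification reproducing the printed 181/150/135 cascade.
#'
#' @param seed integer; the single root seed. Each generator derives its
#'   own substream by a fixed offset, so adding a generator never perturbs
#'   another's output.
#' @param chrom_lengths named numeric vector of chromosome lengths (bp).
#' @param planted_region list with `chrom`, `start`, `end` (bp): where
#'   sex-linked evidence is concentrated.
#' @param n_evidence_per_class named integer vector: evidence count per
#'   class.
#' @param containment_fraction fraction in (0, 1] of each class placed
#'   inside the planted region.
#' @param n_offspring,n_markers F1 family size and marker count.
#' @param map_length_cM genetic length of the simulated linkage group.
#' @param recomb_rate cM per Mb, used when converting physical to genetic
#'   coordinates.
#' @param heterogametic `"male"` (XX/XY, default) or `"female"` (ZZ/ZW).
#' @param deg_overlap_spec named integer vector with elements
#'   `concordant_male`, `concordant_female`, `discordant`, `mf_only`,
#'   `mp_only`: planted counts of concordant, discordant and
#'   single-contrast differentially expressed genes.
#' @param n_region_genes number of gene models planted inside the region.
#' @param synteny_history named list: per derived species, a list of
#'   fusion/fission event specs (see [generate_synteny_blocks()]).
#' @param ancestral_name species label of the ancestral (input) karyotype
#'   in generated synteny blocks.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       chrom_lengths = pu_chrom_lengths(),
                       planted_region = list(chrom = "chr08",
                                             start = 6.90e6, end = 23.73e6),
                       n_evidence_per_class = c(qtl = 57L, rad_tag = 326L,
                                                ssr = 1L, scar = 1L),
                       containment_fraction = 0.963,
                       n_offspring = 100L,
                       n_markers = 200L,
                       map_length_cM = 108.52,
                       recomb_rate = 3.68,
                       heterogametic = c("male", "female"),
                       deg_overlap_spec = c(concordant_male = 65L,
                                            concordant_female = 70L,
                                            discordant = 10L,
                                            mf_only = 36L, mp_only = 5L,
                                            mf_only_male = 10L),
                       n_region_genes = 554L,
                       synteny_history = list(
                         derived = list(
                           list(type = "fusion",
                                chroms = c("chr25", "chr26"),
                                new = "chr25f26"),
                           list(type = "fission", chrom = "chr01",
                                breakpoint = 20e6,
                                new = c("chr01a", "chr01b")))),
                       ancestral_name = "anc") {
  heterogametic <- match.arg(heterogametic)
  stop_if_not(is_count(seed), "sim_config: seed must be a single integer")
  stop_if_not(length(chrom_lengths) >= 1L && !is.null(names(chrom_lengths)),
              "sim_config: chrom_lengths must be named")
  stop_if_not(all(chrom_lengths > 0), "sim_config: chromosome lengths must be positive")
  stop_if_not(anyDuplicated(names(chrom_lengths)) == 0L,
              "sim_config: duplicated chromosome names")
  pr <- planted_region
  stop_if_not(pr$chrom %in% names(chrom_lengths),
              "sim_config: planted region chromosome not in assembly")
  stop_if_not(pr$start >= 0 && pr$end > pr$start &&
                pr$end <= chrom_lengths[[pr$chrom]],
              "sim_config: planted region outside its chromosome")
  stop_if_not(containment_fraction > 0 && containment_fraction <= 1,
              "sim_config: containment_fraction must be in (0, 1]")
  stop_if_not(all(n_evidence_per_class >= 0),
              "sim_config: evidence counts must be >= 0")
  stop_if_not(n_offspring >= 2 && n_markers >= 1,
              "sim_config: need n_offspring >= 2 and n_markers >= 1")
  stop_if_not(all(deg_overlap_spec >= 0), "sim_config: DEG counts must be >= 0")
  structure(list(
    seed = as.integer(seed), chrom_lengths = chrom_lengths,
    planted_region = pr, n_evidence_per_class = n_evidence_per_class,
    containment_fraction = containment_fraction,
    n_offspring = as.integer(n_offspring), n_markers = as.integer(n_markers),
    map_length_cM = map_length_cM, recomb_rate = recomb_rate,
    heterogametic = heterogametic, deg_overlap_spec = deg_overlap_spec,
    n_region_genes = as.integer(n_region_genes),
    synteny_history = synteny_history, ancestral_name = ancestral_name
  ), class = "sim_config")
}

# run code under a derived sub-seed, restoring the caller's RNG state
with_substream <- function(config, offset, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  # keep derived seeds inside 32-bit integer range
  set.seed((config$seed %% 1000000L) * 1000L + offset)
  force(code)
}

#' Generate an assembly skeleton (and optional FASTA)
#'
#' Emits the chromosome-name/length frame configured in `config`,
#' optionally with random sequences of matching lengths at a target GC
#' fraction.
#'
#' @param config a [sim_config()].
#' @param fasta logical; also generate random sequences?
#' @param gc target GC fraction of generated sequence.
#' @return data.frame `name`, `length` of class `assembly_skeleton`;
#'   when `fasta = TRUE`, attribute `"sequences"` holds a
#'   `Biostrings::DNAStringSet`.
#' @export
generate_assembly <- function(config, fasta = FALSE, gc = 0.39) {
  skel <- data.frame(name = names(config$chrom_lengths),
                     length = as.numeric(config$chrom_lengths),
                     stringsAsFactors = FALSE)
  class(skel) <- c("assembly_skeleton", "data.frame")
  if (fasta) {
    seqs <- with_substream(config, 1L, {
      p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
      Biostrings::DNAStringSet(vapply(skel$length, function(n) {
        paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
      }, character(1)))
    })
    names(seqs) <- skel$name
    attr(skel, "sequences") <- seqs
  }
  skel
}

#' Generate sex-linked evidence markers
#'
#' For each evidence class, places exactly
#' `round(containment_fraction * n)` markers uniformly inside the planted
#' region and the remainder uniformly across the genome excluding the
#' planted chromosome, so containment on the sex chromosome equals the
#' configured fraction exactly. Markers are points (1 bp intervals).
#'
#' @param config a [sim_config()].
#' @return data.frame `cls`, `chrom`, `start`, `end` (0-based half-open),
#'   sorted by class, chromosome and start.
#' @export
generate_evidence <- function(config) {
  pr <- config$planted_region
  other <- config$chrom_lengths[setdiff(names(config$chrom_lengths), pr$chrom)]
  with_substream(config, 2L, {
    out <- lapply(names(config$n_evidence_per_class), function(cls) {
      n <- config$n_evidence_per_class[[cls]]
      if (n == 0L) return(NULL)
      n_in <- round(config$containment_fraction * n)
      n_out <- n - n_in
      if (n_out > 0 && length(other) == 0L)
        stop("generate_evidence: no chromosome available outside the planted region",
             call. = FALSE)
      pos_in <- floor(stats::runif(n_in, pr$start, pr$end - 1))
      if (n_out > 0) {
        chr_out <- sample(names(other), n_out, replace = TRUE,
                          prob = as.numeric(other))
        pos_out <- floor(stats::runif(n_out, 0, other[chr_out] - 1))
      } else {
        chr_out <- character(0); pos_out <- numeric(0)
      }
      data.frame(cls = cls,
                 chrom = c(rep(pr$chrom, n_in), chr_out),
                 start = c(pos_in, pos_out),
                 stringsAsFactors = FALSE)
    })
    ev <- do.call(rbind, out)
    ev$end <- ev$start + 1
    ev <- ev[order(ev$cls, ev$chrom, ev$start), ]
    rownames(ev) <- NULL
    ev
  })
}

#' Generate F1 genotypes with a planted sex locus
#'
#' Simulates a male-heterogametic (XX/XY; or ZZ/ZW when configured
#' female-heterogametic) F1 mapping family. One designated marker is
#' perfectly sex-linked; at every other marker the offspring genotype
#' equals its sex-locus genotype flipped with the Haldane recombination
#' fraction for the cM distance, `r = (1 - exp(-2 d / 100)) / 2`.
#' Sexes are balanced to within one individual.
#'
#' @param config a [sim_config()].
#' @return list: `genotypes` (0/1 matrix, offspring x markers; 1 = the
#'   heterogametic-parent allele), `sex` (character vector "M"/"F"),
#'   `map` (data.frame `marker`, `cM`), `sex_locus` (marker name).
#' @export
generate_f1_genotypes <- function(config) {
  n <- config$n_offspring; m <- config$n_markers
  with_substream(config, 3L, {
    cm <- sort(stats::runif(m, 0, config$map_length_cM))
    sex_idx <- which.min(abs(cm - config$map_length_cM / 2))
    markers <- sprintf("m%03d", seq_len(m))
    sex <- rep(c("M", "F"), length.out = n)
    # heterogametic-parent allele: carried by males under XY, females under ZW
    carrier <- if (config$heterogametic == "male") "M" else "F"
    g_sex <- as.integer(sex == carrier)
    geno <- matrix(0L, n, m, dimnames = list(NULL, markers))
    for (j in seq_len(m)) {
      d <- abs(cm[j] - cm[sex_idx])
      r <- 0.5 * (1 - exp(-2 * d / 100))
      flip <- stats::rbinom(n, 1L, r)
      geno[, j] <- as.integer(xor(g_sex, flip))
    }
    list(genotypes = geno, sex = sex,
         map = data.frame(marker = markers, cM = cm, stringsAsFactors = FALSE),
         sex_locus = markers[sex_idx])
  })
}

#' Generate two differential-expression tables with planted overlap
#'
#' Builds male-vs-female (`deg_mf`) and male-vs-pseudofemale (`deg_mp`)
#' DEG tables over a pool of region gene ids so that the realized counts
#' of concordant male-biased, concordant female-biased, discordant and
#' single-contrast genes equal `deg_overlap_spec` exactly. Signs of the
#' log2 fold-change encode direction (positive = male-biased); magnitudes
#' are uniform on [1, 10]. Discordant genes are male-biased in `deg_mf`
#' and female-biased in `deg_mp`; when the spec names `mf_only_male`,
#' that many of the mf-only genes are male-biased (the rest
#' female-biased), otherwise single-contrast signs are random.
#'
#' @param config a [sim_config()].
#' @param gene_ids optional character pool of gene ids; defaults to
#'   `n_region_genes` ids named like the chr08 region genes.
#' @return list of two data.frames `deg_mf`, `deg_mp`, each with columns
#'   `gene_id`, `log2fc`.
#' @export
generate_deg_tables <- function(config, gene_ids = NULL) {
  spec <- config$deg_overlap_spec
  need <- c("concordant_male", "concordant_female", "discordant",
            "mf_only", "mp_only")
  stop_if_not(all(need %in% names(spec)),
              "generate_deg_tables: deg_overlap_spec must name ",
              paste(need, collapse = ", "))
  if (is.null(gene_ids))
    gene_ids <- sprintf("Chr08.%03d", seq_len(config$n_region_genes))
  mf_only_male <- if ("mf_only_male" %in% names(spec))
    spec[["mf_only_male"]] else NA_integer_
  stop_if_not(is.na(mf_only_male) || mf_only_male <= spec[["mf_only"]],
              "generate_deg_tables: mf_only_male exceeds mf_only")
  total <- sum(spec[need])
  stop_if_not(total <= length(gene_ids),
              "generate_deg_tables: spec requires ", total,
              " genes but only ", length(gene_ids), " available")
  with_substream(config, 4L, {
    ids <- sample(gene_ids, total)
    grp <- rep(need, times = spec[need])
    lfc <- function(k, sign) sign * stats::runif(k, 1, 10)
    mf <- mp <- list()
    split_ids <- split(ids, factor(grp, levels = need))
    cm <- split_ids$concordant_male; cf <- split_ids$concordant_female
    dc <- split_ids$discordant
    mf_only <- split_ids$mf_only; mp_only <- split_ids$mp_only
    # discordant genes: male-biased in mf, female-biased in mp
    deg_mf <- data.frame(
      gene_id = c(cm, cf, dc, mf_only),
      log2fc = c(lfc(length(cm), 1), lfc(length(cf), -1),
                 lfc(length(dc), 1),
                 lfc(length(mf_only),
                     if (is.na(mf_only_male))
                       sample(c(-1, 1), length(mf_only), replace = TRUE)
                     else rep(c(1, -1), c(mf_only_male,
                                          length(mf_only) - mf_only_male)))),
      stringsAsFactors = FALSE)
    deg_mp <- data.frame(
      gene_id = c(cm, cf, dc, mp_only),
      log2fc = c(lfc(length(cm), 1), lfc(length(cf), -1),
                 lfc(length(dc), -1),
                 lfc(length(mp_only), sample(c(-1, 1), length(mp_only),
                                             replace = TRUE))),
      stringsAsFactors = FALSE)
    deg_mf <- deg_mf[order(deg_mf$gene_id), ]; rownames(deg_mf) <- NULL
    deg_mp <- deg_mp[order(deg_mp$gene_id), ]; rownames(deg_mp) <- NULL
    list(deg_mf = deg_mf, deg_mp = deg_mp)
  })
}

#' Generate gene models, planting a fixed number inside the region
#'
#' Lays out non-overlapping gene models: `n_region_genes` evenly spaced
#' inside the planted region and `n_outside` distributed over the other
#' chromosomes, for interval-query and fixture-recovery tests.
#'
#' @param config a [sim_config()].
#' @param n_outside genes placed outside the planted chromosome.
#' @return data.frame `gene_id`, `chrom`, `start`, `end`, `strand`
#'   (0-based half-open).
#' @export
generate_gene_models <- function(config, n_outside = 100L) {
  pr <- config$planted_region
  n_in <- config$n_region_genes
  with_substream(config, 6L, {
    span <- pr$end - pr$start
    step <- span / n_in
    glen <- max(1, floor(step * 0.5))
    starts_in <- floor(pr$start + (seq_len(n_in) - 1L) * step)
    df_in <- data.frame(
      gene_id = sprintf("%s.%03d", sub("^chr", "Chr", pr$chrom), seq_len(n_in)),
      chrom = pr$chrom, start = starts_in, end = starts_in + glen,
      stringsAsFactors = FALSE)
    other <- config$chrom_lengths[setdiff(names(config$chrom_lengths), pr$chrom)]
    df_out <- NULL
    if (n_outside > 0 && length(other) > 0) {
      chr <- sample(names(other), n_outside, replace = TRUE)
      st <- floor(stats::runif(n_outside, 0, other[chr] - glen - 1))
      df_out <- data.frame(
        gene_id = sprintf("Gout.%03d", seq_len(n_outside)),
        chrom = chr, start = st, end = st + glen, stringsAsFactors = FALSE)
    }
    df <- rbind(df_in, df_out)
    df$strand <- sample(c("+", "-"), nrow(df), replace = TRUE)
    df <- df[order(df$chrom, df$start), ]
    rownames(df) <- NULL
    df
  })
}

#' Generate pairwise synteny blocks realizing a fusion/fission history
#'
#' Treats the configured assembly as the ancestral karyotype and, for each
#' derived species in `synteny_history`, applies its fusion/fission events
#' and tiles every resulting chromosome into alignment blocks (default
#' 1 Mb; a sub-tile remainder attaches to the last tile). Each block's two
#' spans have equal length, so a relationship classifier applied to the
#' output recovers the generating history.
#'
#' Event specs are lists: `list(type = "fusion", chroms = c(a, b),
#' new = name)` concatenates chromosome `a` then `b`;
#' `list(type = "fission", chrom = a, breakpoint = bp, new = c(n1, n2))`
#' splits at `bp` (coordinate on the current derived chromosome). Events
#' apply sequentially, so later events may reference earlier products.
#'
#' @param config a [sim_config()].
#' @param tile block length in bp.
#' @return data.frame with columns `species_a`, `chrom_a`, `start_a`,
#'   `end_a`, `species_b`, `chrom_b`, `start_b`, `end_b`; side `a` is the
#'   derived species, side `b` the ancestral assembly.
#' @export
generate_synteny_blocks <- function(config, tile = 1e6) {
  anc <- config$chrom_lengths
  out <- lapply(names(config$synteny_history), function(sp) {
    # derived state: per derived chromosome, ordered ancestral segments
    segs <- lapply(names(anc), function(ch)
      data.frame(anc_chrom = ch, anc_start = 0, anc_end = anc[[ch]],
                 stringsAsFactors = FALSE))
    names(segs) <- names(anc)
    for (ev in config$synteny_history[[sp]]) {
      if (ev$type == "fusion") {
        miss <- setdiff(ev$chroms, names(segs))
        if (length(miss))
          stop("generate_synteny_blocks: unknown chromosome(s) ",
               paste(miss, collapse = ", "), " in fusion for ", sp,
               call. = FALSE)
        fused <- do.call(rbind, segs[ev$chroms])
        segs <- segs[setdiff(names(segs), ev$chroms)]
        segs[[ev$new]] <- fused
      } else if (ev$type == "fission") {
        if (!ev$chrom %in% names(segs))
          stop("generate_synteny_blocks: unknown chromosome ", ev$chrom,
               " in fission for ", sp, call. = FALSE)
        s <- segs[[ev$chrom]]
        lens <- s$anc_end - s$anc_start
        offs <- cumsum(c(0, lens))
        bp <- ev$breakpoint
        stop_if_not(bp > 0 && bp < sum(lens),
                    "generate_synteny_blocks: breakpoint outside ", ev$chrom)
        left <- right <- NULL
        for (i in seq_len(nrow(s))) {
          if (offs[i + 1] <= bp) left <- rbind(left, s[i, ])
          else if (offs[i] >= bp) right <- rbind(right, s[i, ])
          else {
            cut <- s$anc_start[i] + (bp - offs[i])
            l <- s[i, ]; l$anc_end <- cut
            r <- s[i, ]; r$anc_start <- cut
            left <- rbind(left, l); right <- rbind(right, r)
          }
        }
        segs <- segs[setdiff(names(segs), ev$chrom)]
        segs[[ev$new[1]]] <- left
        segs[[ev$new[2]]] <- right
      } else stop("generate_synteny_blocks: unknown event type ", ev$type,
                  call. = FALSE)
    }
    # tile derived chromosomes into blocks
    rows <- list()
    for (dch in names(segs)) {
      s <- segs[[dch]]
      dpos <- 0
      for (i in seq_len(nrow(s))) {
        seg_len <- s$anc_end[i] - s$anc_start[i]
        n_tiles <- max(1L, floor(seg_len / tile))
        cuts <- (seq_len(n_tiles - 1L)) * tile
        bounds <- c(0, cuts, seg_len)
        for (k in seq_len(n_tiles)) {
          b0 <- bounds[k]; b1 <- bounds[k + 1]
          rows[[length(rows) + 1L]] <- data.frame(
            species_a = sp, chrom_a = dch,
            start_a = dpos + b0, end_a = dpos + b1,
            species_b = config$ancestral_name, chrom_b = s$anc_chrom[i],
            start_b = s$anc_start[i] + b0, end_b = s$anc_start[i] + b1,
            stringsAsFactors = FALSE)
        }
        dpos <- dpos + seg_len
      }
    }
    do.call(rbind, rows)
  })
  blocks <- do.call(rbind, out)
  rownames(blocks) <- NULL
  blocks
}

#' Derived chromosome lengths implied by a synteny history
#'
#' Convenience for checking conservation of material: applies each
#' species' events to the ancestral karyotype and returns the derived
#' chromosome lengths.
#'
#' @param config a [sim_config()].
#' @return named list (per species) of named length vectors.
#' @export
derived_karyotypes <- function(config) {
  blocks <- generate_synteny_blocks(config)
  lapply(split(blocks, blocks$species_a), function(b) {
    vapply(split(b, b$chrom_a), function(d) sum(d$end_a - d$start_a),
           numeric(1))
  })
}
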