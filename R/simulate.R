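# Synthetic methylome generator. Produces genomes, annotations, planted
# motif instances with known methylation states, and lognormal ipdR
# kinetic tracks, so that every pipeline stage can be tested against
# ground truth without any external data.

#' Kinetic model presets per modification type
#'
#' Median ipdR at methylated bases is 4.0 for m6A, 3.0 for m4C and 1.5
#' for m5C, reflecting the ordering of kinetic signal strengths of the
#' three marks (m5C is near the detection floor). Background (and
#' unmethylated-site) median is 1.0 by construction. `sigma` is the
#' per-read lognormal scale; the per-position ipdR is an aggregate over
#' reads, so its scale is `sigma / sqrt(coverage)`. Coverage is Poisson
#' and independent of methylation state.
#'
#' @param mod_type one of `m6A`, `m4C`, `m5C`.
#' @param coverage_mean mean reads per strand.
#' @param sigma per-read lognormal scale.
#' @return list `mu_meth, mu_unmeth, sigma, coverage_mean`.
#' @export
kinetic_model <- function(mod_type = "m6A", coverage_mean = 60, sigma = 0.25) {
  mu <- switch(mod_type, m6A = 4.0, m4C = 3.0, m5C = 1.5,
               stop("unknown mod_type: ", mod_type))
  list(mu_meth = mu, mu_unmeth = 1.0, sigma = sigma,
       coverage_mean = coverage_mean)
}

#' Generate a random genome
#'
#' I.i.d. bases at the stated GC fraction; deterministic under seed.
#'
#' @param length genome length in bases.
#' @param gc_fraction probability of G or C at each position.
#' @param seed RNG seed.
#' @param contig_id name of the single contig.
#' @return named character vector of length 1.
#' @export
generate_genome <- function(length, gc_fraction = 0.5, seed = 1L,
                            contig_id = "contig1") {
  stopifnot(length > 0, gc_fraction > 0, gc_fraction < 1)
  seq <- with_seed(seed, {
    p <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
           G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
    paste(sample(names(p), length, replace = TRUE, prob = p), collapse = "")
  })
  stats::setNames(seq, contig_id)
}

#' Generate a non-overlapping gene annotation
#'
#' Places `n_genes` CDS features with alternating strands, lengths drawn
#' uniformly from `gene_len`, separated by intergenic gaps of at least
#' `min_gap` bp (remaining space distributed randomly among the gaps).
#' COG letters are assigned round-robin from `cog_letters`. Optionally one
#' gap is widened to at least `reserve_gap_bp` (e.g. to host a planted
#' replication-origin motif cluster).
#'
#' @param genome named character vector (single contig).
#' @param n_genes number of CDS features.
#' @param seed RNG seed.
#' @param gene_len length range (uniform draw).
#' @param min_gap minimum intergenic gap in bp.
#' @param cog_letters letters assigned round-robin.
#' @param reserve_gap_bp widen one random gap to at least this many bp.
#' @return annotation data.frame (1-based inclusive coordinates).
#' @export
generate_annotation <- function(genome, n_genes, seed = 1L,
                                gene_len = c(300L, 1500L), min_gap = 150L,
                                cog_letters = c("K", "T", "H", "E", "J"),
                                reserve_gap_bp = 0L) {
  len <- nchar(genome[[1]])
  with_seed(seed, {
    lens <- sample(gene_len[1]:gene_len[2], n_genes, replace = TRUE)
    n_gaps <- n_genes + 1L
    base_gaps <- rep(min_gap, n_gaps)
    if (reserve_gap_bp > min_gap) {
      base_gaps[sample.int(n_gaps - 2L, 1L) + 1L] <- reserve_gap_bp
    }
    slack <- len - sum(lens) - sum(base_gaps)
    if (slack < 0) stop("infeasible packing: genes + gaps exceed genome")
    extra <- if (slack > 0) stats::rmultinom(1, slack, rep(1, n_gaps))[, 1]
             else rep(0L, n_gaps)
    gaps <- base_gaps + extra
    starts <- cumsum(gaps[seq_len(n_genes)]) +
      c(0L, cumsum(lens[-n_genes])) + 1L  # 1-based starts
    data.frame(
      contig_id = names(genome)[1], start = as.integer(starts),
      end = as.integer(starts + lens - 1L),
      strand = rep_len(c("+", "-"), n_genes), feature_type = "CDS",
      gene_id = sprintf("gene%04d", seq_len(n_genes)),
      product = "hypothetical protein",
      cog_letter = rep_len(cog_letters, n_genes), stringsAsFactors = FALSE)
  })
}

# Mutate one base of each listed instance so it no longer matches the
# pattern; `avoid` positions (0-based) are never touched.
break_instances <- function(seq, instances, motif, avoid = integer(0)) {
  sym <- strsplit(motif$pattern, "")[[1]]
  bases <- strsplit(seq, "")[[1]]
  avoid_set <- if (length(avoid)) unique(avoid) else integer(0)
  for (i in seq_len(nrow(instances))) {
    s <- instances$start[i]
    offs <- sample(seq_along(sym))  # random breakable offset
    done <- FALSE
    for (o in offs) {
      pos0 <- s + o - 1L
      alt <- setdiff(c("A", "C", "G", "T"), IUPAC_SETS[[sym[o]]])
      if (!length(alt) || pos0 %in% avoid_set) next
      bases[pos0 + 1L] <- sample(alt, 1L)
      done <- TRUE
      break
    }
    if (!done) stop("could not break motif instance at ", s)
  }
  paste(bases, collapse = "")
}

# One concrete realization of an IUPAC pattern.
realize_pattern <- function(pattern) {
  sym <- strsplit(pattern, "")[[1]]
  paste(vapply(sym, function(s) {
    set <- IUPAC_SETS[[s]]
    if (length(set) == 1) set else sample(set, 1L)
  }, character(1)), collapse = "")
}

# Greedily pick n starts from candidate 0-based starts with pairwise
# spacing >= L, also avoiding `occupied` starts (same spacing rule).
pick_spaced <- function(candidates, n, L, occupied = integer(0)) {
  picked <- integer(0)
  for (p in candidates[sample.int(length(candidates))]) {
    if (length(picked) >= n) break
    if (all(abs(c(picked, occupied) - p) >= L) || (!length(picked) &&
                                                   !length(occupied)))
      picked <- c(picked, p)
  }
  if (length(picked) < n)
    stop("could not place ", n, " non-overlapping motif instances")
  picked
}

#' Plant a methylome with known ground truth
#'
#' Scrubs naturally occurring instances of the motif from the genome
#' (point mutations at the methylatable base), then plants exactly
#' `n_instances` concrete realizations at random non-overlapping
#' positions, so the truth table has exactly the requested counts. A
#' subset of `n_unmethylated` instances is designated unmethylated with
#' fraction `f_reg` of them placed inside gene regulatory regions (or all
#' of them upstream of genes of one COG letter when `cog_target_letter`
#' is set); the remainder of the genome is fully methylated. Optionally an
#' extra cluster of `ori_count` instances is written into one intergenic
#' region of `ori_region_bp` bp, emulating a replication-origin motif
#' cluster.
#'
#' @param genome named character vector (single contig).
#' @param genes annotation data.frame.
#' @param motif a [motif_spec()].
#' @param n_instances number of motif instances to plant.
#' @param n_unmethylated number of instances left unmethylated.
#' @param f_reg fraction of unmethylated instances placed in regulatory
#'   regions.
#' @param ori_count,ori_region_bp size of the optional planted intergenic
#'   cluster (0 = none).
#' @param cog_target_letter when set, all unmethylated instances are
#'   placed in regulatory regions of genes with this COG letter.
#' @param seed RNG seed.
#' @param cfg configuration list (regulatory-region geometry).
#' @return list: edited `genome`, `truth` table (instances with `state`,
#'   `planted_regulatory` and `ori` columns), `ori_region` (0-based
#'   half-open interval or NULL), and the `regions` used.
#' @export
plant_methylome <- function(genome, genes, motif, n_instances,
                            n_unmethylated, f_reg = 0.6, ori_count = 0L,
                            ori_region_bp = 600L, cog_target_letter = NULL,
                            seed = 1L, cfg = pipeline_config()) {
  stopifnot(n_unmethylated <= n_instances)
  contig <- names(genome)[1]
  L <- nchar(motif$pattern)
  regions <- define_regulatory_regions(genes, genome, cfg)
  with_seed(seed, {
    seq <- genome[[1]]
    # 1. scrub natural occurrences
    for (iter in 1:25) {
      nat <- find_motif_instances(stats::setNames(seq, contig), motif)
      if (!nrow(nat)) break
      seq <- break_instances(seq, nat, motif)
      if (iter == 25) stop("failed to scrub natural motif instances")
    }
    glen <- nchar(seq)

    # 2. choose planting positions
    target_regions <- if (!is.null(cog_target_letter)) {
      regions[!is.na(regions$cog_letter) &
                regions$cog_letter == cog_target_letter, , drop = FALSE]
    } else regions
    n_reg <- if (!is.null(cog_target_letter)) n_unmethylated
             else round(f_reg * n_unmethylated)
    region_starts <- unlist(lapply(seq_len(nrow(target_regions)), function(i) {
      lo <- target_regions$start[i]
      hi <- target_regions$end[i] - L
      if (hi >= lo) lo:hi else integer(0)
    }))
    if (length(region_starts) < n_reg)
      stop("not enough regulatory-region space to plant ", n_reg, " sites")
    reg_pos <- if (n_reg > 0) pick_spaced(region_starts, n_reg, L)
               else integer(0)
    uni_pos <- pick_spaced(0:(glen - L), n_instances - n_reg, L,
                           occupied = reg_pos)
    planted <- sort(c(reg_pos, uni_pos))

    # 3. optional ori cluster in one intergenic region
    ori_region <- NULL
    ori_pos <- integer(0)
    if (ori_count > 0) {
      nc <- extract_noncoding_regions(genes, stats::setNames(seq, contig))
      nc <- nc[nc$end - nc$start >= ori_region_bp, , drop = FALSE]
      if (!nrow(nc)) stop("no intergenic region of ", ori_region_bp, " bp")
      big <- nc[which.max(nc$end - nc$start), ]
      mid <- (big$start + big$end) %/% 2L
      ori_region <- c(max(big$start, mid - ori_region_bp %/% 2L), 0L)
      ori_region[2] <- ori_region[1] + ori_region_bp
      ori_pos <- pick_spaced(ori_region[1]:(ori_region[2] - L), ori_count, L,
                             occupied = planted)
      planted <- sort(c(planted, ori_pos))
    }

    # 4. write realizations
    bases <- strsplit(seq, "")[[1]]
    for (p in planted) {
      bases[(p + 1L):(p + L)] <- strsplit(realize_pattern(motif$pattern),
                                          "")[[1]]
    }
    seq <- paste(bases, collapse = "")

    # 5. remove any incidental instances created at planting boundaries
    for (iter in 1:25) {
      inst <- find_motif_instances(stats::setNames(seq, contig), motif)
      extra <- inst[!inst$start %in% planted, , drop = FALSE]
      if (!nrow(extra)) break
      avoid <- unlist(lapply(planted, function(p) p:(p + L - 1L)))
      seq <- break_instances(seq, extra, motif, avoid = avoid)
      if (iter == 25) stop("failed to remove incidental motif instances")
    }
    inst <- find_motif_instances(stats::setNames(seq, contig), motif)
    if (nrow(inst) != length(planted))
      stop("planting failed: expected ", length(planted), " instances, got ",
           nrow(inst))

    # 6. truth states
    unmeth_pos <- reg_pos
    n_more <- n_unmethylated - length(unmeth_pos)
    if (n_more > 0) {
      pool <- setdiff(uni_pos,
                      inst$start[footprint_overlaps(inst, regions)])
      if (length(pool) < n_more)
        stop("not enough out-of-region instances for unmethylated truth")
      unmeth_pos <- c(unmeth_pos, pool[sample.int(length(pool), n_more)])
    }
    truth <- inst
    truth$state <- ifelse(truth$start %in% unmeth_pos, "unmethylated",
                          "methylated")
    truth$planted_regulatory <- truth$start %in% reg_pos
    truth$ori <- truth$start %in% ori_pos
    list(genome = stats::setNames(seq, contig), truth = truth,
         ori_region = ori_region, regions = regions)
  })
}

#' Simulate a kinetic track for a planted methylome
#'
#' Every genome position carrying the motif's methylatable nucleotide (on
#' either strand) receives Poisson coverage and a lognormal ipdR whose
#' median is `mu_meth` at truth-methylated methylatable bases and
#' `mu_unmeth` (1.0) everywhere else, with per-position scale
#' `sigma / sqrt(coverage)`. Coverage is independent of methylation state
#' by construction, making the coverage-parity diagnostic of
#' [call_summary()] a real test. Positions drawing coverage 0 stay absent
#' from the track.
#'
#' @param genome named character vector (single contig).
#' @param truth truth table from [plant_methylome()].
#' @param motif the planted [motif_spec()].
#' @param model kinetic model from [kinetic_model()].
#' @param seed RNG seed.
#' @return a [kinetic_track()].
#' @export
simulate_kinetics <- function(genome, truth, motif,
                              model = kinetic_model("m6A"), seed = 1L) {
  contig <- names(genome)[1]
  len <- nchar(genome[[1]])
  mb <- meth_base(motif)
  mb_comp <- chartr("ACGT", "TGCA", mb)
  bases <- strsplit(genome[[1]], "")[[1]]
  track <- kinetic_track(stats::setNames(len, contig))
  meth <- truth[truth$state == "methylated", , drop = FALSE]
  with_seed(seed, {
    for (strand in c("+", "-")) {
      pos <- if (strand == "+") which(bases == mb) else which(bases == mb_comp)
      if (!length(pos)) next
      mu <- rep(model$mu_unmeth, length(pos))
      meth_pos0 <- if (strand == "+") meth$meth_pos_fwd else meth$meth_pos_rev
      meth_pos0 <- meth_pos0[!is.na(meth_pos0)]
      mu[match(meth_pos0 + 1L, pos, nomatch = 0L)] <- model$mu_meth
      cov <- stats::rpois(length(pos), model$coverage_mean)
      keep <- cov > 0
      ipdR <- stats::rlnorm(sum(keep), meanlog = log(mu[keep]),
                            sdlog = model$sigma / sqrt(cov[keep]))
      track <- track_set(track, contig, strand, pos[keep], ipdR, cov[keep])
    }
    track
  })
}

#' Build a complete synthetic scenario
#'
#' Presets:
#' \describe{
#'   \item{orphan_regulatory}{200 kb genome, 150 genes, 500 GATC (m6A)
#'     instances of which 20 are unmethylated with 60\% placed in
#'     regulatory regions -- an orphan MTase with regulatory signature.}
#'   \item{rm_system}{as above but zero unmethylated sites: an MTase
#'     protecting its genome within a restriction-modification system.}
#'   \item{ori_cluster}{400 ATCGAT (m6A) instances on 200 kb (1/500 bp
#'     background density) plus 20 extra instances in one 600 bp
#'     intergenic region -- the replication-origin signature.}
#'   \item{m5c_low_signal}{as orphan_regulatory but a CCGG m5C motif with
#'     the weak m5C kinetic preset, so calling sensitivity degrades
#'     measurably.}
#'   \item{cog_targeted}{as orphan_regulatory but all unmethylated sites
#'     placed upstream of COG letter K genes.}
#' }
#'
#' @param preset scenario name.
#' @param seed RNG seed (controls genome, annotation, planting and
#'   kinetics).
#' @param dir when non-NULL, the input files (FASTA, GFF3, kinetics CSV,
#'   motif TSV) and a truth TSV are written there.
#' @param cfg configuration list.
#' @return list with `genome, genes, motif, truth, track, model, regions,
#'   ori_region, preset, seed` and (when written) `paths`.
#' @export
build_scenario <- function(preset = c("orphan_regulatory", "rm_system",
                                      "ori_cluster", "m5c_low_signal",
                                      "cog_targeted"),
                           seed = 1L, dir = NULL, cfg = pipeline_config()) {
  preset <- match.arg(preset)
  glen <- 200000L
  n_genes <- 150L
  par <- switch(preset,
    orphan_regulatory = list(motif = motif_spec("GATC", 1L, "m6A"),
                             n_inst = 500L, n_unmeth = 20L, f_reg = 0.6,
                             ori = 0L, cog = NULL, model = kinetic_model("m6A"),
                             reserve = 0L),
    rm_system = list(motif = motif_spec("GATC", 1L, "m6A"),
                     n_inst = 500L, n_unmeth = 0L, f_reg = 0.6, ori = 0L,
                     cog = NULL, model = kinetic_model("m6A"), reserve = 0L),
    ori_cluster = list(motif = motif_spec("ATCGAT", 4L, "m6A"),
                       n_inst = 400L, n_unmeth = 0L, f_reg = 0.6, ori = 20L,
                       cog = NULL, model = kinetic_model("m6A"),
                       reserve = 800L),
    m5c_low_signal = list(motif = motif_spec("CCGG", 0L, "m5C"),
                          n_inst = 500L, n_unmeth = 20L, f_reg = 0.6,
                          ori = 0L, cog = NULL,
                          model = kinetic_model("m5C"), reserve = 0L),
    cog_targeted = list(motif = motif_spec("GATC", 1L, "m6A"),
                        n_inst = 500L, n_unmeth = 12L, f_reg = 1,
                        ori = 0L, cog = "K", model = kinetic_model("m6A"),
                        reserve = 0L))
  genome0 <- generate_genome(glen, 0.5, seed)
  genes <- generate_annotation(genome0, n_genes, seed + 1L,
                               reserve_gap_bp = par$reserve)
  planted <- plant_methylome(genome0, genes, par$motif, par$n_inst,
                             par$n_unmeth, f_reg = par$f_reg,
                             ori_count = par$ori,
                             cog_target_letter = par$cog,
                             seed = seed + 2L, cfg = cfg)
  track <- simulate_kinetics(planted$genome, planted$truth, par$motif,
                             par$model, seed + 3L)
  out <- list(genome = planted$genome, genes = genes, motif = par$motif,
              truth = planted$truth, track = track, model = par$model,
              regions = planted$regions, ori_region = planted$ori_region,
              preset = preset, seed = seed)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(fasta = file.path(dir, "genome.fasta"),
                  gff = file.path(dir, "genes.gff3"),
                  kinetics = file.path(dir, "kinetics.csv"),
                  motifs = file.path(dir, "motifs.tsv"),
                  truth = file.path(dir, "truth.tsv"))
    write_genome_fasta(out$genome, paths$fasta)
    write_gff3(genes, paths$gff)
    write_kinetics(track, paths$kinetics, genome = out$genome)
    utils::write.table(
      data.frame(pattern = par$motif$pattern,
                 meth_offset_fwd = par$motif$meth_offset_fwd + 1L,
                 mod_type = par$motif$mod_type),
      paths$motifs, sep = "\t", row.names = FALSE, quote = FALSE)
    truth_out <- out$truth
    truth_out$scenario_seed <- seed
    utils::write.table(truth_out, paths$truth, sep = "\t",
                       row.names = FALSE, quote = FALSE)
    out$paths <- paths
  }
  out
}
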