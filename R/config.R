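#' Pipeline configuration
#'
#' Returns the list of numeric constants used throughout the workflow. Each
#' default is the value used in the analyses this package implements; override
#' individual fields by name.
#'
#' @param ... named overrides for any field.
#'
#' @details Fields and units:
#' \describe{
#'   \item{under_meth_weight}{weight of the average motif ipdR in the
#'     under-methylated threshold (0.1): the threshold approximates the ipdR
#'     expected if 10\% of molecules were methylated.}
#'   \item{meth_weight}{weight of the average motif ipdR in the methylated
#'     threshold (0.5).}
#'   \item{central_fraction}{fraction of ranked ipdR values kept when
#'     computing trimmed means (0.6, i.e. the central 60\%).}
#'   \item{min_coverage}{minimum per-strand read coverage for a confident
#'     call (20 reads).}
#'   \item{n_resamplings}{composition-matched random samplings used for
#'     background fractions (1000).}
#'   \item{n_permutations}{iterations of the cluster permutation null
#'     (10000).}
#'   \item{cluster_min_size}{minimum run length for an unmethylated-site
#'     cluster (3).}
#'   \item{cluster_alpha}{significance level for cluster permutation
#'     p-values (0.01).}
#'   \item{noncoding_alpha}{Bonferroni-corrected significance threshold for
#'     the non-coding motif-cluster scan (1e-5).}
#'   \item{flank_regions}{number of flanking non-coding regions used to
#'     estimate local motif density (100, up to 50 per side).}
#'   \item{window_bp, step_bp, span_bp}{density-profile window (500 bp),
#'     step (50 bp) and span (50 kb).}
#'   \item{upstream_bp, downstream_bp}{regulatory-region extent around a CDS
#'     start (100 bp upstream, 50 bp downstream).}
#'   \item{similarity_threshold}{bitscore-ratio similarity score at or above
#'     which a database hit counts as a potential ortholog (35).}
#'   \item{conservation_fraction}{fraction of species in a taxon that must
#'     carry an ortholog for an MTase to be called conserved (0.5, strict
#'     greater-than).}
#'   \item{family_identity_cutoff}{minimum pairwise protein identity within
#'     an orphan MTase family cluster (0.35).}
#'   \item{noncoding_tail}{"ge" (default) for P(X >= observed) in the
#'     non-coding binomial scan, or "gt" for P(X > observed).}
#'   \item{rng_seed}{seed for all stochastic steps.}
#' }
#'
#' @return named list of configuration values.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    under_meth_weight = 0.1,
    meth_weight = 0.5,
    central_fraction = 0.6,
    min_coverage = 20L,
    n_resamplings = 1000L,
    n_permutations = 10000L,
    cluster_min_size = 3L,
    cluster_alpha = 0.01,
    noncoding_alpha = 1e-5,
    flank_regions = 100L,
    window_bp = 500L,
    step_bp = 50L,
    span_bp = 50000L,
    upstream_bp = 100L,
    downstream_bp = 50L,
    similarity_threshold = 35,
    conservation_fraction = 0.5,
    family_identity_cutoff = 0.35,
    noncoding_tail = "ge",
    rng_seed = 1L
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(cfg))
    if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
    cfg[names(over)] <- over
  }
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  num <- setdiff(names(cfg), "noncoding_tail")
  stopifnot(all(vapply(cfg[num], function(x) is.numeric(x) && x > 0, logical(1))))
  stopifnot(cfg$central_fraction > 0, cfg$central_fraction <= 1)
  stopifnot(cfg$under_meth_weight >= 0, cfg$under_meth_weight <= 1,
            cfg$meth_weight >= 0, cfg$meth_weight <= 1)
  stopifnot(cfg$noncoding_tail %in% c("ge", "gt"))
  invisible(cfg)
}

#' Read a pipeline configuration from a YAML file
#'
#' Fields mirror [pipeline_config()]; unspecified fields keep their defaults.
#'
#' @param path YAML file.
#' @return configuration list.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  do.call(pipeline_config, vals)
}

# Run code under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards so package functions never disturb user RNG.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  code
}
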