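# Synthetic xenograft proteomics data: log-normal intensities over a
# 2 treatment x 2 duration design, two-species composition (human tumor
# proteins plus mouse microenvironment proteins), planted log2 effects and
# intensity-dependent (left-censored) missingness.

#' Simulation configuration
#'
#' Parameters of the synthetic xenograft proteomics experiment. Defaults
#' emulate a quantified human proteome of 1845 proteins plus mouse-origin
#' stromal proteins, four groups (si-NT / si-hVDAC1 crossed with short / long
#' treatment) in triplicate, log-normal intensities, a 10% fraction of truly
#' differentially expressed proteins, sigmoidal left-censoring of low
#' intensities, and one exceptional replicate pair (replicate 1 of both
#' long-term groups, globally down-shifted) for the quality-control path to
#' find.
#'
#' @param n_human_proteins,n_mouse_proteins Number of human / mouse proteins.
#' @param replicates_per_group Replicates per experimental group.
#' @param baseline_log2_mean Mean of per-protein baseline log2 intensity.
#' @param protein_level_sd Between-protein spread (sd) of baselines, log2 units.
#' @param baseline_log2_sd Within-group replicate noise sd, log2 units.
#' @param de_fraction Fraction of proteins carrying a true effect, between 0 and 1.
#' @param effect_log2_range Length-2 nonnegative ordered range of true |log2|
#'   effect magnitudes; signs are drawn at random.
#' @param censor_midpoint Log2 intensity at which the censoring probability is
#'   0.5; `-Inf` disables censoring.
#' @param censor_steepness Slope of the censoring sigmoid, 1/log2 units;
#'   `Inf` gives a hard detection threshold at `censor_midpoint`.
#' @param outlier_sample_shift Global log2 shift added to the designated
#'   exceptional replicates (replicate 1 of each long-term group); 0 disables.
#' @param seed Integer seed; all generator randomness derives from it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_human_proteins = 1845L,
                       n_mouse_proteins = 400L,
                       replicates_per_group = 3L,
                       baseline_log2_mean = 25,
                       protein_level_sd = 2.5,
                       baseline_log2_sd = 0.5,
                       de_fraction = 0.1,
                       effect_log2_range = c(1, 3),
                       censor_midpoint = 22,
                       censor_steepness = 1,
                       outlier_sample_shift = -3,
                       seed = 1L) {
  cfg <- list(
    n_human_proteins = check_count(n_human_proteins, "n_human_proteins"),
    n_mouse_proteins = check_count(n_mouse_proteins, "n_mouse_proteins", min = 0L),
    groups = design_groups(),
    replicates_per_group = check_count(replicates_per_group, "replicates_per_group", min = 2L),
    baseline_log2_mean = check_number(baseline_log2_mean, "baseline_log2_mean"),
    protein_level_sd = check_number(protein_level_sd, "protein_level_sd", min = 0),
    baseline_log2_sd = check_number(baseline_log2_sd, "baseline_log2_sd", min = 0),
    de_fraction = check_number(de_fraction, "de_fraction", min = 0, max = 1),
    effect_log2_range = effect_log2_range,
    censor_midpoint = check_number(censor_midpoint, "censor_midpoint", allow_inf = TRUE),
    censor_steepness = check_number(censor_steepness, "censor_steepness", min = 0, allow_inf = TRUE),
    outlier_sample_shift = check_number(outlier_sample_shift, "outlier_sample_shift"),
    seed = check_count(seed, "seed", min = 0L)
  )
  if (!is.numeric(effect_log2_range) || length(effect_log2_range) != 2L ||
      any(is.na(effect_log2_range)) || any(effect_log2_range < 0) ||
      effect_log2_range[1] > effect_log2_range[2]) {
    stop_config("effect_log2_range", "must be a nonnegative ordered pair")
  }
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation configuration\n")
  cat(sprintf("  proteins: %d human + %d mouse\n", x$n_human_proteins, x$n_mouse_proteins))
  cat(sprintf("  design: %d groups x %d replicates\n", length(x$groups), x$replicates_per_group))
  cat(sprintf("  DE fraction %.3g, |log2 effect| in [%g, %g]\n",
              x$de_fraction, x$effect_log2_range[1], x$effect_log2_range[2]))
  cat(sprintf("  censoring: midpoint %g, steepness %g; outlier shift %g\n",
              x$censor_midpoint, x$censor_steepness, x$outlier_sample_shift))
  invisible(x)
}

#' Intensity-dependent left-censoring
#'
#' Sets each entry of a log2 matrix to missing (`NA`) independently with
#' probability `plogis(steepness * (midpoint - value))`, so low-intensity
#' measurements are preferentially lost — the missing-not-at-random mechanism
#' by which non-detections arise in label-free proteomics. Already-missing
#' entries stay missing; observed entries are unchanged.
#'
#' With the same seed, the uniform draw for each cell is shared across calls,
#' so raising `midpoint` (or the censoring probability generally) can only add
#' missing entries, never remove them.
#'
#' @param log2_matrix Numeric matrix of log2 intensities (may contain `NA`).
#' @param midpoint Log2 value with 50% censoring probability; `-Inf` disables.
#' @param steepness Sigmoid slope; `Inf` censors exactly the values below
#'   `midpoint` (values equal to the midpoint are censored with probability
#'   one half).
#' @param seed Integer seed for the censoring draws.
#' @return The matrix with censored entries set to `NA`.
#' @export
apply_mnar_censoring <- function(log2_matrix, midpoint, steepness, seed) {
  stopifnot(is.matrix(log2_matrix), is.numeric(log2_matrix))
  midpoint <- check_number(midpoint, "midpoint", allow_inf = TRUE)
  steepness <- check_number(steepness, "steepness", min = 0, allow_inf = TRUE)
  seed <- check_count(seed, "seed", min = 0L)

  p <- stats::plogis(steepness * (midpoint - log2_matrix))
  p[is.nan(p)] <- 0.5  # Inf * 0 at value == midpoint with infinite steepness
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  u <- matrix(stats::runif(length(log2_matrix)), nrow = nrow(log2_matrix))
  out <- log2_matrix
  out[!is.na(p) & u < p] <- NA_real_
  out
}

# Seed hygiene: set the RNG deterministically for a block, then restore
# whatever state the caller had.
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Simulate a xenograft proteomics experiment
#'
#' Generates a raw intensity table (zero encodes "not detected"), protein
#' annotations, a sample sheet for the four-group design, and a ground-truth
#' table of planted effects. Each log2 intensity is drawn from
#' `Normal(baseline_i + effect_{i,g}, baseline_log2_sd)` where per-protein
#' baselines are `Normal(baseline_log2_mean, protein_level_sd)`; effects are
#' applied to the si-hVDAC1 group of the affected duration. The matrix is then
#' passed through [apply_mnar_censoring()] and exponentiated, censored cells
#' becoming zeros. Replicate 1 of each long-term group receives
#' `outlier_sample_shift` before censoring, emulating a degraded sample pair.
#'
#' All randomness derives from `config$seed` (the censoring stage uses
#' `seed + 1`), so identical configurations give byte-identical output.
#'
#' @param config A [sim_config()].
#' @return A list with elements `intensity` (proteins x samples matrix),
#'   `annotations` (accession, gene, organism, unique_peptides),
#'   `samples` (sample sheet data frame), and `truth` (per-protein organism,
#'   baseline, per-contrast true DE flag and log2 effect).
#' @export
simulate_experiment <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  n_h <- config$n_human_proteins
  n_m <- config$n_mouse_proteins
  n <- n_h + n_m
  reps <- config$replicates_per_group
  groups <- config$groups

  old <- local_seed(config$seed)
  on.exit(restore_seed(old))

  accession <- c(sprintf("HP%05d", seq_len(n_h)),
                 if (n_m > 0) sprintf("MP%05d", seq_len(n_m)))
  gene <- c(sprintf("HGENE%d", seq_len(n_h)),
            if (n_m > 0) sprintf("Mgene%d", seq_len(n_m)))
  organism <- rep(c("human", "mouse"), c(n_h, n_m))
  unique_peptides <- stats::rpois(n, lambda = 3)

  baseline <- stats::rnorm(n, config$baseline_log2_mean, config$protein_level_sd)

  # Planted effects: a DE protein is affected in one or both durations
  # (at least one), magnitude uniform over the configured range, sign random.
  is_de <- stats::runif(n) < config$de_fraction
  affected <- matrix(FALSE, n, 2, dimnames = list(NULL, DURATIONS))
  pick <- matrix(stats::runif(2 * n) < 0.5, n, 2)
  none <- which(!pick[, 1] & !pick[, 2])
  if (length(none)) {
    first <- stats::runif(length(none)) < 0.5
    pick[none, 1] <- first
    pick[none, 2] <- !first
  }
  affected[is_de, ] <- pick[is_de, ]
  mag <- matrix(stats::runif(2 * n, config$effect_log2_range[1],
                             config$effect_log2_range[2]), n, 2)
  sgn <- matrix(sign(stats::runif(2 * n) - 0.5), n, 2)
  effect <- mag * sgn * affected

  samples <- expand.grid(replicate = seq_len(reps),
                         treatment = TREATMENTS,
                         duration = DURATIONS,
                         stringsAsFactors = FALSE)[, c("treatment", "duration", "replicate")]
  samples$sample_id <- sprintf("%s_%s_r%d", samples$treatment,
                               samples$duration, samples$replicate)
  samples$included <- TRUE
  samples <- samples[, c("sample_id", "treatment", "duration", "replicate", "included")]

  mu <- matrix(baseline, n, nrow(samples))
  hv <- samples$treatment == "si-hVDAC1"
  for (d in DURATIONS) {
    cols <- which(hv & samples$duration == d)
    if (length(cols)) mu[, cols] <- mu[, cols] + effect[, d]
  }
  # Exceptional replicate pair: replicate 1 of each long-term group.
  outlier_cols <- which(samples$duration == "long" & samples$replicate == 1L)
  mu[, outlier_cols] <- mu[, outlier_cols] + config$outlier_sample_shift

  logm <- mu + matrix(stats::rnorm(length(mu), 0, config$baseline_log2_sd),
                      n, ncol(mu))
  dimnames(logm) <- list(accession, samples$sample_id)

  logm <- apply_mnar_censoring(logm, config$censor_midpoint,
                               config$censor_steepness,
                               seed = config$seed + 1L)
  intensity <- 2^logm
  intensity[is.na(intensity)] <- 0

  annotations <- data.frame(accession = accession, gene = gene,
                            organism = organism,
                            unique_peptides = unique_peptides,
                            stringsAsFactors = FALSE)
  truth <- data.frame(accession = accession, gene = gene, organism = organism,
                      baseline = baseline,
                      de_short = is_de & affected[, "short"],
                      de_long = is_de & affected[, "long"],
                      effect_short = effect[, "short"],
                      effect_long = effect[, "long"],
                      stringsAsFactors = FALSE)
  truth$effect_short[!truth$de_short] <- 0
  truth$effect_long[!truth$de_long] <- 0

  list(intensity = intensity, annotations = annotations,
       samples = samples, truth = truth)
}

#' Simulate gene-set collections with planted enrichment
#'
#' Builds a GMT-serializable collection over the human gene universe of a
#' simulated truth table. "Enriched" terms draw their members by weighted
#' sampling without replacement in which truly differentially expressed genes
#' carry `enriched_odds` times the weight of null genes; the remaining terms
#' sample uniformly.
#'
#' @param truth Truth table from [simulate_experiment()].
#' @param n_terms Total number of terms.
#' @param size_range Length-2 range of term sizes (members per term).
#' @param n_enriched_terms Number of terms with planted enrichment.
#' @param enriched_odds Sampling-weight ratio of DE genes inside enriched terms.
#' @param seed Integer seed.
#' @return A `gene_set_db`: list with `sets` (named list of member symbol
#'   vectors) and `info` (term, description, enriched flag, odds used).
#' @export
simulate_gene_sets <- function(truth, n_terms = 50L, size_range = c(10L, 50L),
                               n_enriched_terms = 5L, enriched_odds = 8,
                               seed = 1L) {
  n_terms <- check_count(n_terms, "n_terms")
  n_enriched_terms <- check_count(n_enriched_terms, "n_enriched_terms", min = 0L)
  enriched_odds <- check_number(enriched_odds, "enriched_odds", min = 1)
  seed <- check_count(seed, "seed", min = 0L)
  if (n_enriched_terms > n_terms) {
    stop_config("n_enriched_terms", "must not exceed n_terms")
  }

  universe <- unique(truth$gene[truth$organism == "human"])
  de_genes <- unique(truth$gene[truth$organism == "human" &
                                  (truth$de_short | truth$de_long)])
  if (!is.numeric(size_range) || length(size_range) != 2L ||
      any(size_range < 1) || size_range[1] > size_range[2] ||
      size_range[2] > length(universe)) {
    stop_config("size_range", "must be an ordered pair within the gene universe size")
  }

  old <- local_seed(seed)
  on.exit(restore_seed(old))

  w_enriched <- ifelse(universe %in% de_genes, enriched_odds, 1)
  sets <- vector("list", n_terms)
  enriched <- seq_len(n_terms) <= n_enriched_terms
  sizes <- size_range[1] - 1L +
    sample.int(size_range[2] - size_range[1] + 1L, n_terms, replace = TRUE)
  for (i in seq_len(n_terms)) {
    w <- if (enriched[i]) w_enriched else rep(1, length(universe))
    sets[[i]] <- sort(sample(universe, sizes[i], prob = w))
  }
  names(sets) <- sprintf("TERM%04d", seq_len(n_terms))
  info <- data.frame(term = names(sets),
                     description = ifelse(enriched, "planted enrichment", "null term"),
                     enriched = enriched,
                     odds = ifelse(enriched, enriched_odds, 1),
                     stringsAsFactors = FALSE)
  structure(list(sets = sets, info = info), class = "gene_set_db")
}

#' @export
print.gene_set_db <- function(x, ...) {
  cat(sprintf("Gene-set collection: %d terms, sizes %d-%d\n",
              length(x$sets), min(lengths(x$sets)), max(lengths(x$sets))))
  invisible(x)
}
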