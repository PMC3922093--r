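#' The 14 immune-signature genes
#'
#' Gene symbols of the 14 signature members annotated to the GO term
#' "immune system process" (GO:0002376): MHC class II components,
#' chemokines, immunoglobulins, and related regulators. These are the
#' default planted signature of [generate_cohort()] and the default
#' signature of [signature_classifier()].
#'
#' @return Character vector of 14 gene symbols.
#' @export
#' @examples
#' immune_signature_genes()
immune_signature_genes <- function() {
  c("BNIP3", "CCL18", "CD74", "CD86", "CXCL11", "CXCL9", "HLA-DMA",
    "HLA-DPB1", "HLA-DRB4", "HLA-DRB5", "IDO1", "IGHA1", "IGLL1", "ORM1")
}

#' Configuration for a synthetic expression cohort
#'
#' Captures the cohort structure the downstream analysis assumes: a small
#' imbalanced two-class design (default 33 non-recurrent vs 12 metachronous
#' metastasis), a large probe background, and a planted block of signature
#' genes that is down-regulated in the metastatic class through per-sample
#' random subsets ("not always the same genes"), which defeats univariate
#' differential expression while remaining multivariately separable.
#'
#' @param n_nonrecurrent,n_metastatic Samples per class (defaults 33 and 12).
#' @param n_probes Total number of probes (default 44000, a whole-genome
#'   4x44K-style array).
#' @param signature_genes Symbols of the planted signature genes; one probe
#'   per gene by default (see `duplicate_signature_probes`).
#' @param effect_size Mean down-shift delta of a hit signature probe in a
#'   metastatic sample, in transformed-scale units (default 2).
#' @param penetrance Probability that a given signature gene is down-shifted
#'   in a given metastatic sample (default 0.7).
#' @param noise_sd Within-group standard deviation on the transformed scale
#'   (default 1).
#' @param baseline_mean,baseline_sd Location and spread of the per-probe
#'   baseline distribution (defaults 8 and 2).
#' @param followup_range Follow-up window in months for censored
#'   non-recurrent cases (default `c(41, 115)`).
#' @param dfs_median_metastatic Median disease-free survival of metastatic
#'   cases in months (default 13).
#' @param dfs_sigma Log-scale standard deviation of the metastatic DFS
#'   log-normal; the default `sqrt(2 * log(17/13))` makes the mean 17 months
#'   when the median is 13.
#' @param duplicate_signature_probes If `TRUE`, each signature gene gets a
#'   second probe (for testing probe-to-gene collapse).
#' @param seed Integer seed; all generator randomness flows from it.
#'
#' @return An object of class `"cohort_config"` (a validated list).
#' @export
#' @examples
#' cohort_config(n_probes = 500, seed = 1)
cohort_config <- function(n_nonrecurrent = 33L, n_metastatic = 12L,
                          n_probes = 44000L,
                          signature_genes = immune_signature_genes(),
                          effect_size = 2, penetrance = 0.7, noise_sd = 1,
                          baseline_mean = 8, baseline_sd = 2,
                          followup_range = c(41, 115),
                          dfs_median_metastatic = 13,
                          dfs_sigma = sqrt(2 * log(17 / 13)),
                          duplicate_signature_probes = FALSE,
                          seed = 1L) {
  cfg <- list(n_nonrecurrent = as.integer(n_nonrecurrent),
              n_metastatic = as.integer(n_metastatic),
              n_probes = as.integer(n_probes),
              signature_genes = as.character(signature_genes),
              effect_size = effect_size, penetrance = penetrance,
              noise_sd = noise_sd, baseline_mean = baseline_mean,
              baseline_sd = baseline_sd, followup_range = followup_range,
              dfs_median_metastatic = dfs_median_metastatic,
              dfs_sigma = dfs_sigma,
              duplicate_signature_probes = isTRUE(duplicate_signature_probes),
              seed = as.integer(seed))
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  if (cfg$n_nonrecurrent < 1L || cfg$n_metastatic < 1L)
    stopf("invalid cohort config: n_nonrecurrent and n_metastatic must both be >= 1")
  if (cfg$n_nonrecurrent + cfg$n_metastatic < 4L)
    stopf("invalid cohort config: n_nonrecurrent + n_metastatic must be >= 4")
  if (cfg$penetrance < 0 || cfg$penetrance > 1)
    stopf("invalid cohort config: penetrance must lie in [0, 1]")
  if (!is.finite(cfg$noise_sd) || cfg$noise_sd <= 0)
    stopf("invalid cohort config: noise_sd must be > 0")
  n_sig_probes <- length(cfg$signature_genes) *
    (1L + cfg$duplicate_signature_probes)
  if (cfg$n_probes < n_sig_probes)
    stopf("invalid cohort config: n_probes must be >= number of signature probes (%d)",
          n_sig_probes)
  if (anyDuplicated(cfg$signature_genes))
    stopf("invalid cohort config: signature_genes contains duplicates")
  if (length(cfg$followup_range) != 2L ||
      cfg$followup_range[1] <= 0 ||
      cfg$followup_range[2] < cfg$followup_range[1])
    stopf("invalid cohort config: followup_range must be 0 < lo <= hi")
  if (cfg$dfs_median_metastatic <= 0)
    stopf("invalid cohort config: dfs_median_metastatic must be > 0")
  invisible(cfg)
}

#' Generate a synthetic expression cohort with a planted signature
#'
#' Draws a probes-by-samples matrix on a transformed (post-normalization)
#' scale: each probe has its own baseline (normal with mean
#' `baseline_mean`, sd `baseline_sd`) plus i.i.d. Gaussian noise
#' (`noise_sd`). In each metastatic sample an independent
#' Bernoulli(`penetrance`) subset of the signature probes is shifted down by
#' `effect_size`, emulating heterogeneous down-regulation where no single
#' gene is always affected. Disease-free survival is uniform on
#' `followup_range` with event 0 (censored) for non-recurrent cases and
#' log-normal with the configured median (event 1) for metastatic cases.
#'
#' The random stream is laid out so that cohorts generated from the same
#' seed but different `effect_size` share baselines, noise and hit patterns;
#' the shift is applied deterministically afterwards. This monotone coupling
#' underlies the recovery-curve tests.
#'
#' @param config A [cohort_config()].
#' @return An object of class `"synthetic_cohort"`: a list with elements
#'   `expression` (matrix, probes x samples), `metadata` (data.frame with
#'   `sample_id`, `label`, `dfs_months`, `event`), `probe_annotation`
#'   (data.frame `probe_id`, `gene_symbol`; some symbols empty),
#'   `genesets` (data.frame `term_id`, `term_name`, `gene_symbol`),
#'   `truth` (planted probe ids) and `config`.
#' @export
#' @examples
#' co <- generate_cohort(cohort_config(n_probes = 200, seed = 1))
#' dim(co$expression)
#' table(co$metadata$label)
generate_cohort <- function(config = cohort_config()) {
  if (!inherits(config, "cohort_config")) config <- do.call(cohort_config, config)
  validate_cohort_config(config)
  cfg <- config
  with_seed(cfg$seed, {
    n1 <- cfg$n_nonrecurrent; n2 <- cfg$n_metastatic; n <- n1 + n2
    sample_ids <- c(sprintf("NR%02d", seq_len(n1)), sprintf("MM%02d", seq_len(n2)))
    label <- c(rep("non_recurrent", n1), rep("metastatic", n2))

    sig_genes <- cfg$signature_genes
    n_sig <- length(sig_genes)
    dup <- cfg$duplicate_signature_probes
    probe_ids <- sprintf("P%06d", seq_len(cfg$n_probes))
    sig_idx <- seq_len(n_sig)
    sig_probes <- probe_ids[sig_idx]
    if (dup) {
      dup_idx <- n_sig + seq_len(n_sig)
      sig_probes <- c(sig_probes, probe_ids[dup_idx])
    }

    baseline <- rnorm(cfg$n_probes, cfg$baseline_mean, cfg$baseline_sd)
    x <- baseline + matrix(rnorm(cfg$n_probes * n, 0, cfg$noise_sd),
                           nrow = cfg$n_probes, ncol = n)
    dimnames(x) <- list(probe_ids, sample_ids)

    # per metastatic sample, an independent subset of signature genes is hit;
    # a duplicated probe follows its gene's hit indicator
    hits <- matrix(rbinom(n_sig * n2, 1L, cfg$penetrance), nrow = n_sig)
    met_cols <- n1 + seq_len(n2)
    x[sig_idx, met_cols] <- x[sig_idx, met_cols] - cfg$effect_size * hits
    if (dup) x[dup_idx, met_cols] <- x[dup_idx, met_cols] - cfg$effect_size * hits

    dfs_nr <- runif(n1, cfg$followup_range[1], cfg$followup_range[2])
    dfs_mm <- rlnorm(n2, meanlog = log(cfg$dfs_median_metastatic),
                     sdlog = cfg$dfs_sigma)
    metadata <- data.frame(sample_id = sample_ids, label = label,
                           dfs_months = c(dfs_nr, dfs_mm),
                           event = c(rep(0L, n1), rep(1L, n2)),
                           stringsAsFactors = FALSE)

    annotation <- synth_probe_annotation(probe_ids, sig_probes, sig_genes, dup)
    genesets <- synth_genesets(annotation, sig_genes)

    structure(list(expression = x, metadata = metadata,
                   probe_annotation = annotation, genesets = genesets,
                   truth = sig_probes, config = cfg),
              class = "synthetic_cohort")
  })
}

# background annotation: ~70% of background probes carry a generic symbol,
# the rest are symbol-less (mirrors arrays where many probes lack a symbol)
synth_probe_annotation <- function(probe_ids, sig_probes, sig_genes, dup) {
  symbol <- character(length(probe_ids))
  names(symbol) <- probe_ids
  symbol[sig_probes] <- if (dup) rep(sig_genes, 2L) else sig_genes
  bg <- setdiff(probe_ids, sig_probes)
  annotated <- bg[runif(length(bg)) < 0.7]
  symbol[annotated] <- sprintf("GENE%05d", seq_along(annotated))
  data.frame(probe_id = probe_ids, gene_symbol = unname(symbol[probe_ids]),
             stringsAsFactors = FALSE)
}

# gene sets: the immune term holds the planted signature plus a sprinkling of
# background genes; additional random terms provide a null background
synth_genesets <- function(annotation, sig_genes) {
  bg_genes <- setdiff(unique(annotation$gene_symbol), c(sig_genes, ""))
  extra <- head(bg_genes, min(10L, length(bg_genes)))
  immune <- data.frame(term_id = "GO:0002376", term_name = "immune system process",
                       gene_symbol = c(sig_genes, extra), stringsAsFactors = FALSE)
  pool <- setdiff(bg_genes, extra)
  others <- NULL
  n_terms <- min(20L, max(0L, length(pool) %/% 15L))
  if (n_terms > 0L) {
    members <- split(sample(pool, n_terms * 15L),
                     rep(seq_len(n_terms), each = 15L))
    others <- do.call(rbind, lapply(seq_len(n_terms), function(i) {
      data.frame(term_id = sprintf("TERM:%04d", i),
                 term_name = sprintf("background process %d", i),
                 gene_symbol = members[[i]], stringsAsFactors = FALSE)
    }))
  }
  rbind(immune, others)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d probes x %d samples (%d non-recurrent, %d metastatic)\n",
              nrow(x$expression), ncol(x$expression),
              sum(x$metadata$label == "non_recurrent"),
              sum(x$metadata$label == "metastatic")))
  cat(sprintf("Planted signature: %d probes (delta = %g, penetrance = %g, noise sd = %g)\n",
              length(x$truth), x$config$effect_size, x$config$penetrance,
              x$config$noise_sd))
  cat(sprintf("Seed: %d\n", x$config$seed))
  invisible(x)
}

#' Generate a synthetic qPCR Ct table
#'
#' Emulates a TaqMan validation experiment: per-gene baseline Ct values,
#' a reference gene (`ACTB`) for every sample, a calibrator sample (`HT29`)
#' with Ct for every gene, and a metastatic group whose target-gene Ct
#' values are shifted *up* by `effect` cycles (higher Ct = lower
#' expression). A per-sample loading offset is added to all of a sample's
#' Ct values; it cancels in the delta-Ct step.
#'
#' @param n_per_group Samples per class (default 11, as in the validation
#'   cohort).
#' @param genes Target gene symbols (default the five validated markers).
#' @param effect Up-shift in cycles of the metastatic group's target Cts
#'   (default 2, i.e. a four-fold expression reduction).
#' @param seed Integer seed.
#' @param ct_sd Within-group Ct standard deviation in cycles (default 0.7).
#' @return A data.frame of class `"ct_table"` with columns `sample_id`,
#'   `group`, `gene`, `ct`, and attributes `reference` (`"ACTB"`) and
#'   `calibrator` (`"HT29"`).
#' @export
#' @examples
#' ct <- generate_qpcr(n_per_group = 4, genes = c("CD74", "CXCL9"), effect = 2, seed = 1)
#' head(ct)
generate_qpcr <- function(n_per_group = 11L, genes = c("CD74", "CXCL9",
                          "CXCL11", "HLA-DMA", "IDO1"), effect = 2,
                          seed = 1L, ct_sd = 0.7) {
  n_per_group <- as.integer(n_per_group)
  if (n_per_group < 2L) stopf("invalid qPCR config: n_per_group must be >= 2")
  genes <- as.character(genes)
  if (length(genes) == 0L) stopf("invalid qPCR config: genes must be non-empty")
  if (anyDuplicated(genes)) stopf("invalid qPCR config: duplicate gene symbols")
  reference <- "ACTB"; calibrator <- "HT29"
  with_seed(seed, {
    gene_base <- setNames(runif(length(genes), 24, 29), genes)
    ref_base <- 19
    samples <- c(sprintf("NR%02d", seq_len(n_per_group)),
                 sprintf("MM%02d", seq_len(n_per_group)))
    group <- rep(c("non_recurrent", "metastatic"), each = n_per_group)
    offset <- rnorm(length(samples), 0, 0.5)   # loading/input amount
    rows <- lapply(seq_along(samples), function(i) {
      shift <- if (group[i] == "metastatic") effect else 0
      data.frame(sample_id = samples[i], group = group[i],
                 gene = c(genes, reference),
                 ct = c(gene_base + shift + offset[i] + rnorm(length(genes), 0, ct_sd),
                        ref_base + offset[i] + rnorm(1, 0, 0.15)),
                 stringsAsFactors = FALSE)
    })
    cal <- data.frame(sample_id = calibrator, group = "calibrator",
                      gene = c(genes, reference),
                      ct = c(gene_base + rnorm(length(genes), 0, 0.15),
                             ref_base + rnorm(1, 0, 0.15)),
                      stringsAsFactors = FALSE)
    out <- do.call(rbind, c(rows, list(cal)))
    rownames(out) <- NULL
    structure(out, reference = reference, calibrator = calibrator,
              class = c("ct_table", "data.frame"))
  })
}
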