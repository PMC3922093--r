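#!/usr/bin/env Rscript
# Optional, offline-unfriendly workflow: score a locally downloaded
# expression cohort (GEO series-matrix format) with the 14-probe immune
# signature at the published operating point (cutoff 8.5) and, if outcome
# metadata are supplied, compute ROC/AUC and the log-rank stratification.
# This is NOT run by the test suite: it requires the deposited cohort
# (accession GSE31905), which is not shipped.
#
# Usage:
#   Rscript scripts/reproduce_geo_cohort.R --series-matrix GSE31905_series_matrix.txt \
#       [--metadata meta.tsv] [--cutoff 8.5] [--out results/geo]
# The optional metadata TSV needs columns: sample_id, label, dfs_months, event
# (sample ids must match the series-matrix column accessions; labels
# "metastatic" / "non_recurrent").

suppressPackageStartupMessages(library(metasig))

args <- commandArgs(trailingOnly = TRUE)
opt <- list(series_matrix = NULL, metadata = NULL, cutoff = 8.5, out = "results/geo")
i <- 1L
while (i <= length(args)) {
  key <- args[i]
  if (key == "--series-matrix") { opt$series_matrix <- args[i + 1L]; i <- i + 2L }
  else if (key == "--metadata") { opt$metadata <- args[i + 1L]; i <- i + 2L }
  else if (key == "--cutoff") { opt$cutoff <- as.numeric(args[i + 1L]); i <- i + 2L }
  else if (key == "--out") { opt$out <- args[i + 1L]; i <- i + 2L }
  else stop("unknown argument: ", key)
}
if (is.null(opt$series_matrix))
  stop("--series-matrix is required (download the series-matrix file first)")

x <- read_series_matrix(opt$series_matrix)
sig <- signature_probe_table()
probes <- sig$probe_id[sig$go_immune == "Yes"]
missing <- setdiff(probes, rownames(x))
if (length(missing))
  stop("signature probes absent from the matrix: ", paste(missing, collapse = ", "))

dir.create(opt$out, recursive = TRUE, showWarnings = FALSE)
counts <- below_median_counts(x, probes, mode = "loo")
fit <- signature_classifier(x, probes, cutoff = opt$cutoff)
out <- data.frame(sample_id = names(counts), count = unname(counts),
                  predicted = as.character(fit$predicted))

if (!is.null(opt$metadata)) {
  md <- read_metadata(opt$metadata)
  md <- md[match(names(counts), md$sample_id), ]
  roc <- roc_analysis(counts, md$label)
  i8 <- which(roc$thresholds == opt$cutoff)
  cat(sprintf("AUC = %.3f\n", roc$auc))
  cat(sprintf("At cutoff %.1f: sensitivity %.0f%%, specificity %.0f%%\n",
              opt$cutoff, 100 * roc$sensitivity[i8], 100 * roc$specificity[i8]))
  lr <- logrank_test(md$dfs_months, md$event, fit$predicted)
  cat(sprintf("Log-rank (Mantel-Cox): chi-sq %.2f, p = %.4g\n",
              unname(lr$statistic), lr$p.value))
  out$true <- md$label
}

path <- file.path(opt$out, "signature_scores.tsv")
write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
cat("written:", path, "\n")
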