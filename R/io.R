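# All on-disk formats are tab-separated UTF-8 text with '#' comment lines.
# Writers emit a provenance comment block (package version, seed, stage
# parameters) sufficient to re-run the stage; no timestamps, so outputs are
# byte-identical for fixed inputs and seed.

provenance_header <- function(stage, seed = NULL, params = NULL) {
  lines <- c(sprintf("# metasig %s", as.character(packageVersion("metasig"))),
             sprintf("# stage: %s", stage))
  if (!is.null(seed)) lines <- c(lines, sprintf("# seed: %d", as.integer(seed)))
  if (!is.null(params) && length(params))
    lines <- c(lines, sprintf("# param %s: %s", names(params),
                              vapply(params, function(v)
                                paste(format(v), collapse = ","), character(1))))
  lines
}

check_rectangular <- function(path) {
  nf <- count.fields(path, sep = "\t", comment.char = "#", quote = "")
  nf <- nf[!is.na(nf)]
  if (length(nf) == 0L) stopf("%s: no data rows", path)
  if (length(unique(nf)) != 1L) {
    # report the first physical line deviating from the modal width
    lines <- readLines(path)
    keep <- !grepl("^\\s*#", lines) & nzchar(lines)
    widths <- lengths(strsplit(lines[keep], "\t", fixed = TRUE))
    modal <- as.integer(names(sort(table(widths), decreasing = TRUE))[1])
    bad <- which(keep)[which(widths != modal)[1]]
    stopf("%s: ragged row at line %d (%d fields, expected %d)",
          path, bad, widths[which(widths != modal)[1]], modal)
  }
  invisible(TRUE)
}

#' Read a probes-by-samples expression matrix from TSV
#'
#' Expects a header row of sample ids, a first column of probe ids and
#' numeric cells; `#` lines are comments. Duplicate ids, ragged rows and
#' non-numeric cells are rejected with the offending line named.
#'
#' @param path File path.
#' @return Numeric matrix with probe row names and sample column names.
#' @export
read_expression <- function(path) {
  check_rectangular(path)
  d <- read.delim(path, comment.char = "#", check.names = FALSE,
                  stringsAsFactors = FALSE, quote = "")
  if (ncol(d) < 2L) stopf("%s: expected a probe-id column plus sample columns", path)
  probes <- as.character(d[[1]])
  if (any(!nzchar(probes))) stopf("%s: empty probe id", path)
  if (anyDuplicated(probes))
    stopf("%s: duplicate probe id '%s'", path, probes[duplicated(probes)][1])
  vals <- d[, -1, drop = FALSE]
  nonnum <- !vapply(vals, is.numeric, logical(1))
  if (any(nonnum)) {
    col <- which(nonnum)[1]
    bad_row <- which(is.na(suppressWarnings(as.numeric(vals[[col]]))) |
                       !grepl("^[-+0-9.eE ]*$", vals[[col]]))[1]
    stopf("%s: non-numeric value in column '%s', data row %d",
          path, names(vals)[col], if (is.na(bad_row)) 1L else bad_row)
  }
  samples <- names(vals)
  if (anyDuplicated(samples))
    stopf("%s: duplicate sample id '%s'", path, samples[duplicated(samples)][1])
  x <- as.matrix(vals)
  dimnames(x) <- list(probes, samples)
  x
}

#' Write an expression matrix to TSV
#'
#' Numeric cells are written with 17 significant digits so that
#' `read_expression(write_expression(x))` round-trips exactly.
#'
#' @param x Numeric matrix with dimnames.
#' @param path Output path.
#' @param seed Seed recorded in the provenance header.
#' @param stage Stage name recorded in the header.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path, seed = NULL, stage = "expression") {
  x <- as.matrix(x)
  hdr <- provenance_header(stage, seed)
  fmt <- matrix(formatC(x, digits = 17, format = "g"), nrow = nrow(x))
  con <- file(path, open = "wt"); on.exit(close(con))
  writeLines(hdr, con)
  writeLines(paste(c("probe_id", colnames(x)), collapse = "\t"), con)
  writeLines(paste(rownames(x), apply(fmt, 1L, paste, collapse = "\t"),
                   sep = "\t"), con)
  invisible(path)
}

write_tsv_with_header <- function(d, path, stage, seed = NULL, params = NULL) {
  con <- file(path, open = "wt"); on.exit(close(con))
  writeLines(provenance_header(stage, seed, params), con)
  suppressWarnings(write.table(d, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  invisible(path)
}

#' Read a sample-metadata table
#'
#' Columns `sample_id`, `label`, `dfs_months`, `event`.
#'
#' @param path File path.
#' @return Data.frame.
#' @export
read_metadata <- function(path) {
  check_rectangular(path)
  d <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE, quote = "")
  req <- c("sample_id", "label", "dfs_months", "event")
  if (!all(req %in% names(d)))
    stopf("%s: metadata needs columns %s", path, paste(req, collapse = ", "))
  if (anyDuplicated(d$sample_id))
    stopf("%s: duplicate sample id '%s'", path, d$sample_id[duplicated(d$sample_id)][1])
  d
}

#' Read a probe annotation table
#'
#' Columns `probe_id`, `gene_symbol`; an empty symbol marks an
#' unannotated probe.
#'
#' @param path File path.
#' @return Data.frame.
#' @export
read_probe_annotation <- function(path) {
  d <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                  quote = "", colClasses = "character")
  if (!all(c("probe_id", "gene_symbol") %in% names(d)))
    stopf("%s: annotation needs columns probe_id and gene_symbol", path)
  if (anyDuplicated(d$probe_id))
    stopf("%s: duplicate probe id '%s'", path, d$probe_id[duplicated(d$probe_id)][1])
  d$gene_symbol[is.na(d$gene_symbol)] <- ""
  d
}

#' Read gene-set memberships (long TSV or GAF-lite)
#'
#' The long TSV dialect has columns `term_id`, `term_name`, `gene_symbol`,
#' one membership pair per row. GAF-lite files (`format = "gaf"`) are
#' tab-separated with the symbol in column 3 and the term id in column 5;
#' only those two columns are consumed.
#'
#' @param path File path.
#' @param format `"tsv"` (default) or `"gaf"`.
#' @return Data.frame with `term_id`, `term_name`, `gene_symbol`.
#' @export
read_genesets <- function(path, format = c("tsv", "gaf")) {
  format <- match.arg(format)
  if (format == "gaf") {
    d <- read.delim(path, comment.char = "!", header = FALSE,
                    stringsAsFactors = FALSE, quote = "")
    if (ncol(d) < 5L) stopf("%s: GAF-lite needs at least 5 columns", path)
    return(data.frame(term_id = as.character(d[[5]]),
                      term_name = as.character(d[[5]]),
                      gene_symbol = as.character(d[[3]]),
                      stringsAsFactors = FALSE))
  }
  check_rectangular(path)
  d <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE, quote = "")
  if (!all(c("term_id", "gene_symbol") %in% names(d)))
    stopf("%s: gene sets need columns term_id and gene_symbol", path)
  if (!"term_name" %in% names(d)) d$term_name <- d$term_id
  d[, c("term_id", "term_name", "gene_symbol")]
}

#' Read a qPCR Ct table
#'
#' Columns `sample_id`, `group`, `gene`, `ct`.
#'
#' @param path File path.
#' @param reference,calibrator Reference gene and calibrator sample id
#'   recorded as attributes.
#' @return Data.frame of class `"ct_table"`.
#' @export
read_ct_table <- function(path, reference = "ACTB", calibrator = "HT29") {
  check_rectangular(path)
  d <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE, quote = "")
  req <- c("sample_id", "group", "gene", "ct")
  if (!all(req %in% names(d)))
    stopf("%s: Ct table needs columns %s", path, paste(req, collapse = ", "))
  structure(d, reference = reference, calibrator = calibrator,
            class = c("ct_table", "data.frame"))
}

#' Read the expression block of a GEO series-matrix file
#'
#' Convenience reader for series-matrix text files: metadata lines are
#' prefixed with `!`; the probes-by-samples block sits between the
#' `!series_matrix_table_begin` and `!series_matrix_table_end` sentinels,
#' with quoted ids and a header row of sample accessions.
#'
#' @param path File path.
#' @return Numeric matrix, probes x samples.
#' @export
read_series_matrix <- function(path) {
  lines <- readLines(path)
  beg <- grep("^!series_matrix_table_begin", lines)
  end <- grep("^!series_matrix_table_end", lines)
  if (length(beg) != 1L || length(end) != 1L || end <= beg + 1L)
    stopf("%s: series-matrix sentinels not found or block empty", path)
  block <- lines[(beg + 1L):(end - 1L)]
  block <- gsub('"', "", block, fixed = TRUE)
  d <- read.delim(text = block, check.names = FALSE, stringsAsFactors = FALSE)
  probes <- as.character(d[[1]])
  x <- as.matrix(d[, -1, drop = FALSE])
  if (!is.numeric(x)) stopf("%s: non-numeric values in the matrix block", path)
  rownames(x) <- probes
  x
}

#' Write a synthetic cohort to a directory
#'
#' Writes the four TSVs a cohort consists of — `expression.tsv`,
#' `metadata.tsv`, `probe_annotation.tsv`, `genesets.tsv` — each with a
#' provenance header carrying the generator seed.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  seed <- cohort$config$seed
  write_expression(cohort$expression, file.path(dir, "expression.tsv"),
                   seed = seed, stage = "simulate")
  write_tsv_with_header(cohort$metadata, file.path(dir, "metadata.tsv"),
                        "simulate", seed)
  write_tsv_with_header(cohort$probe_annotation,
                        file.path(dir, "probe_annotation.tsv"), "simulate", seed)
  write_tsv_with_header(cohort$genesets, file.path(dir, "genesets.tsv"),
                        "simulate", seed)
  invisible(dir)
}
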