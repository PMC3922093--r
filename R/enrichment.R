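#' Map probes to unique gene symbols
#'
#' Drops probes with an empty or missing symbol and collapses duplicate
#' symbols, keeping the first occurrence (stable order).
#'
#' @param probes Character vector of probe ids.
#' @param annotation Either a data.frame with columns `probe_id` and
#'   `gene_symbol`, or a named character vector (names = probe ids).
#' @return Character vector of unique, non-empty gene symbols.
#' @export
#' @examples
#' ann <- data.frame(probe_id = c("p1", "p2", "p3"),
#'                   gene_symbol = c("CD74", "", "CD74"))
#' map_probes_to_genes(c("p1", "p2", "p3"), ann)
map_probes_to_genes <- function(probes, annotation) {
  if (is.data.frame(annotation)) {
    if (!all(c("probe_id", "gene_symbol") %in% names(annotation)))
      stopf("annotation needs columns probe_id and gene_symbol")
    map <- setNames(as.character(annotation$gene_symbol),
                    as.character(annotation$probe_id))
  } else {
    map <- annotation
  }
  sym <- unname(map[as.character(probes)])
  sym <- sym[!is.na(sym) & nzchar(sym)]
  unique(sym)
}

# build a term -> member list restricted to the universe
as_term_list <- function(genesets) {
  if (is.data.frame(genesets)) {
    if (!all(c("term_id", "gene_symbol") %in% names(genesets)))
      stopf("gene sets need columns term_id and gene_symbol (optionally term_name)")
    terms <- split(as.character(genesets$gene_symbol),
                   as.character(genesets$term_id))
    nm <- if ("term_name" %in% names(genesets)) {
      tapply(as.character(genesets$term_name), as.character(genesets$term_id),
             function(v) v[1])
    } else setNames(names(terms), names(terms))
    list(terms = lapply(terms, unique), names = nm[names(terms)])
  } else if (is.list(genesets)) {
    list(terms = lapply(genesets, unique),
         names = setNames(names(genesets), names(genesets)))
  } else stopf("gene sets must be a data.frame or a named list")
}

#' Unconditional hypergeometric gene-set over-representation
#'
#' For each term, tests whether the selected genes overlap the term more
#' than expected from a random draw of the same size out of the universe.
#' The p-value is the exact upper tail `P(X >= a)` of the hypergeometric
#' distribution; the odds ratio is `(a d)/(b c)` of the sample 2x2 table
#' (`b = n - a`, `c = K - a`, `d = N - K - b`), reported as `Inf` when a
#' margin is exhausted; the expected overlap is `n K / N`. Terms with no
#' overlap are omitted (their upper-tail p is 1 by definition). No
#' multiple-testing correction is applied; rows are sorted by p.
#'
#' @param selected Character vector of selected gene symbols. Symbols
#'   outside the universe are dropped with a warning.
#' @param genesets Term memberships: data.frame (`term_id`, `gene_symbol`,
#'   optional `term_name`) or named list of symbol vectors. Ancestor
#'   closure, if wanted, must be pre-computed in the input.
#' @param universe Universe of gene symbols; defaults to all genes carrying
#'   at least one term annotation (the conventional default for array
#'   enrichment). Term memberships are restricted to the universe and
#'   empty terms dropped.
#' @return A data.frame of class `"enrichment_result"` with columns
#'   `term_id`, `pvalue`, `odds_ratio`, `expected`, `count` (a), `size`
#'   (K), `term_name`, `genes` (comma-separated overlap), plus attributes
#'   `n` (effective selection size) and `N` (universe size).
#' @export
#' @examples
#' sets <- data.frame(term_id = "T1", term_name = "toy",
#'                    gene_symbol = c("a", "b", "c", "d"))
#' hypergeom_enrich(c("a", "b"), sets, universe = letters[1:10])
hypergeom_enrich <- function(selected, genesets, universe = NULL) {
  tl <- as_term_list(genesets)
  if (is.null(universe)) universe <- unique(unlist(tl$terms, use.names = FALSE))
  universe <- unique(as.character(universe))
  N <- length(universe)
  if (N < 1L) stopf("empty gene universe")

  selected <- unique(as.character(selected))
  outside <- setdiff(selected, universe)
  if (length(outside))
    warnf("%d selected symbol(s) outside the universe dropped: %s",
          length(outside), paste(head(outside, 5L), collapse = ", "))
  sel <- intersect(selected, universe)
  n <- length(sel)
  if (n == 0L) stopf("no selected genes remain within the universe")

  members <- lapply(tl$terms, intersect, universe)
  K <- lengths(members)
  keep <- K >= 1L
  members <- members[keep]; K <- K[keep]

  rows <- lapply(seq_along(members), function(i) {
    ov <- intersect(sel, members[[i]])
    a <- length(ov)
    if (a == 0L) return(NULL)
    Ki <- K[[i]]
    b <- n - a; cc <- Ki - a; d <- N - Ki - b
    orat <- if (b == 0L || cc == 0L) Inf else (a * d) / (b * cc)
    data.frame(term_id = names(members)[i],
               pvalue = phyper(a - 1L, Ki, N - Ki, n, lower.tail = FALSE),
               odds_ratio = orat,
               expected = n * Ki / N,
               count = a, size = Ki,
               term_name = unname(tl$names[names(members)[i]]),
               genes = paste(sort(ov), collapse = ", "),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(term_id = character(), pvalue = numeric(),
                      odds_ratio = numeric(), expected = numeric(),
                      count = integer(), size = integer(),
                      term_name = character(), genes = character(),
                      stringsAsFactors = FALSE)
  out <- out[order(out$pvalue, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  attr(out, "n") <- n
  attr(out, "N") <- N
  out
}

#' Reconstruct selection and universe sizes from a printed enrichment table
#'
#' Published over-representation tables often print, per term, the
#' expected overlap `n K / N` and the 2x2 odds ratio to two decimals but
#' omit the selection size `n` and universe size `N`. Given at least two
#' rows with distinct term sizes, this performs an exhaustive integer grid
#' search (`n` from `max(count)` to `n_max`, `N` over `N_range`) for the
#' pair under which every row's recomputed expected value and odds ratio
#' round to the printed values.
#'
#' @param rows Data.frame with columns `expected`, `odds_ratio`, `count`
#'   (overlap a) and `size` (term size K), as printed (2 decimals).
#' @param n_max Upper bound of the selection-size grid (default 100).
#' @param N_range Universe-size grid bounds (default `c(1000, 50000)`).
#' @param digits Printed rounding (default 2).
#' @return Named integer vector `c(n = ..., N = ...)`.
#'   Errors if no pair is consistent, or lists the candidates if several
#'   are.
#' @export
#' @examples
#' rows <- data.frame(expected = c(1.47, 1.04, 0.10),
#'                    odds_ratio = c(26.94, 31.69, 73.05),
#'                    count = c(14, 13, 5), size = c(874, 620, 58))
#' reconstruct_table_params(rows)
reconstruct_table_params <- function(rows, n_max = 100L,
                                     N_range = c(1000L, 50000L),
                                     digits = 2L) {
  req <- c("expected", "odds_ratio", "count", "size")
  if (!all(req %in% names(rows)))
    stopf("rows must have columns %s", paste(req, collapse = ", "))
  if (nrow(rows) < 2L || length(unique(rows$size)) < 2L)
    stopf("need at least 2 rows with distinct term sizes")

  Ns <- seq.int(N_range[1], N_range[2])
  cand_n <- integer(0); cand_N <- integer(0)
  for (n in seq.int(max(rows$count), n_max)) {
    ok <- rep(TRUE, length(Ns))
    for (i in seq_len(nrow(rows))) {
      a <- rows$count[i]; K <- rows$size[i]
      b <- n - a; cc <- K - a
      if (b < 0L || cc < 0L) { ok[] <- FALSE; break }
      d <- Ns - K - b
      ok <- ok & d >= 0L &
        round(n * K / Ns, digits) == rows$expected[i] &
        (if (b == 0L || cc == 0L) is.infinite(rows$odds_ratio[i])
         else round((a * d) / (b * cc), digits) == rows$odds_ratio[i])
      if (!any(ok)) break
    }
    if (any(ok)) {
      cand_n <- c(cand_n, rep.int(n, sum(ok)))
      cand_N <- c(cand_N, Ns[ok])
    }
  }
  if (length(cand_n) == 0L)
    stopf("no (n, N) pair over the grid is consistent with the printed table")
  if (length(cand_n) > 1L)
    stopf("ambiguous reconstruction; consistent candidates: %s",
          paste(sprintf("(n=%d, N=%d)", cand_n, cand_N), collapse = ", "))
  c(n = cand_n, N = cand_N)
}

#' The published signature probe table
#'
#' The packaged transcription of the 44-probe signature annotation table:
#' 30 probes with a gene symbol (14 of them flagged as annotated to the GO
#' term "immune system process") and 14 placeholder rows with an empty
#' symbol standing in for the unprinted symbol-less probes (their ids are
#' synthetic; see the file header).
#'
#' @return Data.frame with columns `probe_id`, `gene_symbol`, `gene_name`,
#'   `go_immune`.
#' @export
#' @examples
#' tab <- signature_probe_table()
#' sum(tab$go_immune == "Yes")
signature_probe_table <- function() {
  path <- system.file("extdata", "signature_probes.tsv", package = "metasig")
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
             colClasses = "character")
}

#' The published enrichment table
#'
#' The packaged transcription of the GO over-representation table for the
#' signature genes (47 biological-process terms with printed p-value, odds
#' ratio, expected overlap, overlap count and term size). Selection and
#' universe sizes are not printed; [reconstruct_table_params()] recovers
#' them.
#'
#' @return Data.frame with columns `term_id`, `pvalue`, `odds_ratio`,
#'   `expected`, `count`, `size`, `term_name`.
#' @export
#' @examples
#' head(enrichment_table())
enrichment_table <- function() {
  path <- system.file("extdata", "enrichment_table.tsv", package = "metasig")
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
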