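#' Build the 2x2 contingency table for one GO term
#'
#' Cells: `a` study genes annotated with the term, `b` study genes without,
#' `c` background-only genes with the term, `d` background-only genes
#' without. Genes lacking any GO annotation count in the "without" cells.
#'
#' @param study_genes Character vector of study gene ids (must be a subset
#'   of the background).
#' @param background_genes Character vector of all background gene ids.
#' @param term GO term id.
#' @param go_map Gene-to-GO table (`gene_id`, `go_id`), already propagated
#'   if ancestor counting is wanted.
#' @return A list of class `contingency_table` with `a`, `b`, `c`, `d`.
#' @export
build_contingency <- function(study_genes, background_genes, term, go_map) {
  if (!all(study_genes %in% background_genes))
    stop("study gene absent from background")
  with_term <- unique(go_map$gene_id[go_map$go_id == term])
  a <- sum(study_genes %in% with_term)
  b <- length(study_genes) - a
  bg_only <- setdiff(background_genes, study_genes)
  cc <- sum(bg_only %in% with_term)
  d <- length(bg_only) - cc
  structure(list(a = a, b = b, c = cc, d = d), class = "contingency_table")
}

#' Test one 2x2 table: Pearson chi-squared with Fisher fallback
#'
#' Expected counts are computed from the margins; the p-value comes from
#' Pearson's chi-squared test (1 df, no continuity correction) unless any
#' expected cell count is below 5, in which case a two-sided Fisher's exact
#' test is used instead. Direction is over- or under-representation of the
#' term in the study set relative to expectation.
#'
#' @param table A `contingency_table` (or list with `a`, `b`, `c`, `d`).
#' @return List of class `enrichment_test`: `p`, `test_used`, `direction`,
#'   `expected` (matrix), `table`.
#' @export
term_test <- function(table) {
  m <- matrix(c(table$a, table$b, table$c, table$d), nrow = 2L,
              byrow = TRUE,
              dimnames = list(c("study", "background_only"),
                              c("with_term", "without_term")))
  n <- sum(m)
  if (any(rowSums(m) == 0L) || any(colSums(m) == 0L))
    return(structure(list(p = 1, test_used = "degenerate",
                          direction = NA_character_,
                          expected = m * NA_real_, table = table),
                     class = "enrichment_test"))
  expected <- outer(rowSums(m), colSums(m)) / n
  if (any(expected < 5)) {
    p <- stats::fisher.test(m, alternative = "two.sided")$p.value
    used <- "fisher_exact"
  } else {
    p <- suppressWarnings(
      stats::chisq.test(m, correct = FALSE)$p.value)
    used <- "chi_squared"
  }
  structure(list(p = p, test_used = used,
                 direction = if (m[1L, 1L] >= expected[1L, 1L]) "over"
                             else "under",
                 expected = expected, table = table),
            class = "enrichment_test")
}

#' Propagate gene annotations up the is-a hierarchy
#'
#' A gene annotated with a child term is counted under every ancestor term
#' as well, mirroring the usual GO true-path rule.
#'
#' @param go_map Gene-to-GO table (`gene_id`, `go_id`).
#' @param ontology Ontology table (`go_id`, `parent`); `NA` parent for the
#'   root. Cycles are an error.
#' @return The propagated, de-duplicated gene-to-GO table.
#' @export
propagate_annotations <- function(go_map, ontology) {
  parent_of <- stats::setNames(ontology$parent, ontology$go_id)
  cur <- data.table::as.data.table(go_map)[, c("gene_id", "go_id")]
  out <- cur
  for (step in seq_len(nrow(ontology) + 1L)) {
    nxt <- cur[!is.na(parent_of[cur$go_id])]
    if (nrow(nxt) == 0L) break
    nxt$go_id <- unname(parent_of[nxt$go_id])
    cur <- nxt
    out <- rbind(out, nxt)
    if (step > nrow(ontology)) stop("cyclic ontology")
  }
  unique(out)
}

#' GO term enrichment of a study gene set against a background
#'
#' One test per term with at least one study gene after upward propagation
#' of annotations; results are sorted by ascending p. No multiple-testing
#' correction is applied to the reported p (Benjamini-Hochberg q-values are
#' emitted as an extra column).
#'
#' @param study_genes Study gene ids (e.g. genes carrying non-synonymous
#'   SNPs).
#' @param background_genes All gene ids (the full gene-model set, including
#'   genes without GO annotation).
#' @param go_map Gene-to-GO table.
#' @param ontology Optional ontology table for is-a propagation.
#' @return data.table: `go_id`, `name` (if the ontology carries names),
#'   cells `a`-`d`, `expected_a`, `p`, `q`, `test_used`, `direction`.
#' @export
enrich_all <- function(study_genes, background_genes, go_map,
                       ontology = NULL) {
  map <- if (!is.null(ontology)) propagate_annotations(go_map, ontology)
         else data.table::as.data.table(go_map)
  terms <- unique(map$go_id[map$gene_id %in% study_genes])
  rows <- lapply(terms, function(tm) {
    tab <- build_contingency(study_genes, background_genes, tm, map)
    tst <- term_test(tab)
    data.table::data.table(go_id = tm, a = tab$a, b = tab$b, c = tab$c,
                           d = tab$d,
                           expected_a = tst$expected[1L, 1L],
                           p = tst$p, test_used = tst$test_used,
                           direction = tst$direction)
  })
  res <- data.table::rbindlist(rows)
  if (nrow(res) == 0L) return(res)
  res$q <- stats::p.adjust(res$p, method = "BH")
  if (!is.null(ontology) && "name" %in% names(ontology))
    res$name <- ontology$name[match(res$go_id, ontology$go_id)]
  res[order(p)]
}

#' Write/read the simple gene-to-GO and ontology TSV formats
#' @param x Table to write.
#' @param path File path.
#' @return `path` invisibly, or the read data.table.
#' @export
write_go_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_go_tsv
#' @export
read_go_tsv <- function(path) {
  data.table::fread(path, sep = "\t")
}
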