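#' Expected study-set count of an annotated term
#'
#' With `K` background genes annotated to a term, a study set of `n`
#' annotated genes and an annotated background of size `N`, the expected
#' count under random draws is `K * n / N`.
#'
#' @param K Annotated background genes for the term.
#' @param n Annotated study-set size.
#' @param N Annotated background size.
#' @return `K * n / N`.
#' @export
expected_count <- function(K, n, N) {
  if (any(N <= 0)) abort("background size N must be positive")
  K * n / N
}

#' Upper-tail hypergeometric enrichment p-value
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)` — the one-sided Fisher
#' over-representation probability of seeing `k` or more study genes
#' annotated to a term.
#'
#' @param k Observed study-set count for the term.
#' @param K Annotated background genes for the term.
#' @param n Annotated study-set size.
#' @param N Annotated background size.
#' @return Upper-tail probability in `(0, 1]`.
#' @export
hyper_p <- function(k, K, n, N) {
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Back-solve an annotated background size from a printed expected count
#'
#' Enrichment services usually print `Expected = K * n / N` without
#' publishing `N`; this inverts the formula (`N = K * n / expected`,
#' rounded) so their p-values can be reproduced.
#'
#' @param K Annotated background genes for the term.
#' @param n Annotated study-set size.
#' @param expected Printed expected count.
#' @return Background size `N` (integer).
#' @export
backsolve_background <- function(K, n, expected) {
  as.integer(round(K * n / expected))
}

#' GO term over-representation test
#'
#' One-sided hypergeometric (Fisher upper-tail) test of each GO term's
#' over-representation in a study gene set against an annotated background.
#' No multiple-testing correction is applied by default, matching the common
#' raw `p < 0.05` reporting of enrichment services; Benjamini-Hochberg
#' adjusted p-values are available behind `fdr = TRUE`.
#'
#' @param study_genes Character vector of study gene ids.
#' @param annotation Annotation tibble (`gene_id`, `go_id`, `ontology`,
#'   `term`), e.g. from [read_annotation_table()].
#' @param alpha Significance level for the `significant` flag (default 0.05).
#' @param fdr Add Benjamini-Hochberg adjusted p-values (default FALSE).
#' @param background_size Optional named vector of per-ontology annotated
#'   background sizes `N`, overriding the count of distinct annotated genes
#'   in `annotation`.
#' @return A tibble of class `"bsa_enrichment"`, sorted by p-value:
#'   `go_id`, `term`, `ontology`, `annotated` (K), `count` (k), `expected`,
#'   `p_value`, `significant`, `gene_ids` (list-column), and `p_adjust` when
#'   `fdr = TRUE`. Study genes absent from the background are dropped from
#'   `n` with a warning; terms with zero study count are skipped.
#' @export
go_enrich <- function(study_genes, annotation, alpha = 0.05, fdr = FALSE,
                      background_size = NULL) {
  assert_cols(annotation, c("gene_id", "go_id", "ontology", "term"),
              "annotation")
  study_genes <- unique(study_genes)
  known <- study_genes %in% annotation$gene_id
  if (any(!known)) {
    warn(sprintf("%d study gene(s) absent from the annotated background were excluded",
                 sum(!known)))
  }
  study <- study_genes[known]

  res <- list()
  for (ont in unique(annotation$ontology)) {
    ann <- annotation[annotation$ontology == ont, ]
    N <- if (!is.null(background_size) && ont %in% names(background_size)) {
      background_size[[ont]]
    } else {
      dplyr::n_distinct(ann$gene_id)
    }
    study_ont <- intersect(study, ann$gene_id)
    n <- length(study_ont)
    if (n == 0L) next
    terms <- dplyr::distinct(ann, .data$go_id, .data$term)
    for (i in seq_len(nrow(terms))) {
      gid <- terms$go_id[i]
      genes_term <- unique(ann$gene_id[ann$go_id == gid])
      k_genes <- intersect(study_ont, genes_term)
      k <- length(k_genes)
      if (k == 0L) next
      K <- length(genes_term)
      res[[length(res) + 1L]] <- tibble(
        go_id = gid, term = terms$term[i], ontology = ont,
        annotated = K, count = k,
        expected = expected_count(K, n, N),
        p_value = hyper_p(k, K, n, N),
        n_study = n, n_background = N,
        gene_ids = list(sort(k_genes)))
    }
  }
  out <- bind_rows(res)
  if (nrow(out) == 0L) {
    out <- tibble(go_id = character(), term = character(),
                  ontology = character(), annotated = integer(),
                  count = integer(), expected = numeric(),
                  p_value = numeric(), n_study = integer(),
                  n_background = integer(), gene_ids = list())
  }
  out <- arrange(out, .data$p_value)
  out$significant <- out$p_value < alpha
  if (fdr) out$p_adjust <- stats::p.adjust(out$p_value, "BH")
  class(out) <- c("bsa_enrichment", class(out))
  out
}
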