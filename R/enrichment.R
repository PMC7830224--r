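#' Configuration for over-representation analysis
#'
#' @param p_threshold significance threshold before correction. The default
#'   5e-15 is deliberately conservative so that the number of significant
#'   terms stays comparable to the size of a typical study gene set.
#' @param correction `"bonferroni"` (threshold division by the number of
#'   tested terms) or `"none"`.
#' @param min_annotated terms with fewer study-set genes than this are not
#'   tested and do not count toward the Bonferroni denominator.
#' @return List of class `ora_config`.
#' @export
ora_config <- function(p_threshold = 5e-15,
                       correction = c("bonferroni", "none"),
                       min_annotated = 1L) {
  correction <- match.arg(correction)
  stopifnot(is.numeric(p_threshold), length(p_threshold) == 1L,
            p_threshold > 0, p_threshold <= 1,
            min_annotated >= 1L)
  structure(list(p_threshold = p_threshold, correction = correction,
                 min_annotated = as.integer(min_annotated)),
            class = "ora_config")
}

#' One-sided Fisher over-representation tail probability
#'
#' Probability of observing `k` or more study-set genes annotated to a term,
#' for a hypergeometric draw of `n_set` genes from a background of `N` genes
#' of which `K` are annotated. Identical to the one-sided Fisher exact test
#' on the 2x2 incidence table.
#'
#' @param k study-set genes annotated to the term.
#' @param n_set study-set size.
#' @param K background genes annotated to the term.
#' @param N background size.
#' @return Upper-tail probability `P(X >= k)`, vectorized over its arguments.
#' @examples
#' fisher_over(3, 3, 3, 10)  # 1 / choose(10, 3)
#' @export
fisher_over <- function(k, n_set, K, N) {
  if (any(k < 0) || any(k > n_set) || any(n_set > N) ||
      any(k > K) || any(K > N))
    stop("fisher_over: arguments must satisfy 0 <= k <= n_set <= N and k <= K <= N")
  stats::phyper(k - 1, K, N - K, n_set, lower.tail = FALSE)
}

#' Run the over-representation analysis over an ontology
#'
#' Tests every term carrying at least `min_annotated` study genes (after
#' true-path propagation) against the background with [fisher_over()].
#' Bonferroni control divides the threshold by the number of tested terms.
#' Study symbols missing from the background are dropped with a warning.
#'
#' @param dag an [ontology_dag()].
#' @param ann an [propagate()] result covering the background genes.
#' @param gene_set character vector of study gene symbols.
#' @param config an [ora_config()].
#' @param namespace restrict testing to terms of this namespace; the Gene
#'   Ontology convention is `"biological_process"`. Use `NULL` to test all.
#' @return data.frame of class `ora_result` with one row per tested term:
#'   `term_id`, `name`, `k`, `n_set`, `K`, `N`, `p_value`, `significant`,
#'   sorted by ascending p-value with `term_id` as tiebreak. The Bonferroni
#'   denominator is attached as attribute `m`, the corrected threshold as
#'   `threshold`.
#' @export
run_ora <- function(dag, ann, gene_set, config = ora_config(),
                    namespace = "biological_process") {
  stopifnot(inherits(dag, "ontology_dag"), inherits(ann, "annotation_map"),
            inherits(config, "ora_config"))
  gene_set <- unique(toupper(gene_set))
  missing <- setdiff(gene_set, ann$background_genes)
  if (length(missing)) {
    warning("dropping ", length(missing),
            " study symbol(s) not in background: ",
            paste(utils::head(missing, 5), collapse = ", "),
            if (length(missing) > 5) ", ...")
    gene_set <- setdiff(gene_set, missing)
  }
  if (!length(gene_set))
    stop("study gene set is empty after intersection with the background")

  term_ids <- dag$terms$term_id
  if (!is.null(namespace)) {
    term_ids <- term_ids[dag$terms$namespace %in% namespace]
    if (!length(term_ids))
      stop("no terms in namespace '", paste(namespace, collapse = ","),
           "'; pass namespace = NULL to test all terms")
  }

  # incidence counts from the propagated map, one pass over the genes
  all_prop <- ann$propagated
  K_tab <- table(factor(unlist(all_prop, use.names = FALSE), levels = term_ids))
  k_tab <- table(factor(unlist(all_prop[gene_set], use.names = FALSE),
                        levels = term_ids))
  K <- as.integer(K_tab); k <- as.integer(k_tab)
  N <- length(ann$background_genes); n_set <- length(gene_set)

  testable <- K >= 1L & k >= config$min_annotated
  res <- data.frame(term_id = term_ids[testable],
                    name = dag$terms$name[match(term_ids[testable],
                                                dag$terms$term_id)],
                    k = k[testable], n_set = n_set,
                    K = K[testable], N = N,
                    stringsAsFactors = FALSE)
  res$p_value <- fisher_over(res$k, res$n_set, res$K, res$N)
  m <- nrow(res)
  threshold <- if (config$correction == "bonferroni" && m > 0)
    config$p_threshold / m else config$p_threshold
  res$significant <- res$p_value < threshold
  res <- res[order(res$p_value, res$term_id), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "m") <- m
  attr(res, "threshold") <- threshold
  class(res) <- c("ora_result", "data.frame")
  res
}
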