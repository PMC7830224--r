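#' Certainty of significant terms
#'
#' Rank-based certainty over the significant term set: the fraction of
#' significant terms with a strictly smaller p-value,
#' `Cert(Ti) = |{Tk : p(Tk) < p(Ti)}| / nT`. Under this as-printed
#' definition the minimum-p term has certainty 0; the complement variant
#' `1 - |{p(Tk) < p(Ti)}|/nT` inverts the ranking so that the most
#' significant term scores highest (see the methods vignette for why both
#' are offered).
#'
#' @param p_values numeric vector of p-values of the significant terms,
#'   optionally named by term id.
#' @param complement use the complement variant.
#' @return Numeric vector of certainties in `[0, 1)` (complement: `(0, 1]`).
#' @export
certainty <- function(p_values, complement = FALSE) {
  if (!length(p_values)) stop("certainty: empty significant term set")
  nT <- length(p_values)
  cert <- vapply(p_values, function(pi) sum(p_values < pi), numeric(1)) / nT
  if (complement) cert <- 1 - cert
  cert
}

#' Shannon-style information value of a term
#'
#' `Info = -e * p * ln(p)` with `p = k / n_set`, the share of study genes
#' annotated to the term. The factor `e` normalizes the maximum to 1,
#' attained at `p = 1/e`; the boundary cases `p = 0` and `p = 1` carry no
#' information and score 0.
#'
#' @param k study genes annotated to the term (vectorized).
#' @param n_set study-set size.
#' @return Numeric vector of information values in `[0, 1]`.
#' @export
information_value <- function(k, n_set) {
  stopifnot(n_set >= 1, all(k >= 0), all(k <= n_set))
  p <- k / n_set
  ifelse(p == 0 | p == 1, 0, -exp(1) * p * log(p))
}

#' Remarkableness scores for significant terms
#'
#' Combines [certainty()] and [information_value()] into the remarkableness
#' `Rem = Cert * Info` used to rank significant terms as candidate branch
#' headlines.
#'
#' @param ora an [run_ora()] result (only rows with `significant == TRUE`
#'   are scored).
#' @param complement passed to [certainty()].
#' @return data.frame `term_id`, `p_value`, `k`, `cert`, `info`, `rem`.
#' @export
term_scores <- function(ora, complement = FALSE) {
  stopifnot(inherits(ora, "data.frame"))
  sig <- ora[ora$significant, , drop = FALSE]
  if (!nrow(sig)) stop("term_scores: no significant terms")
  cert <- certainty(sig$p_value, complement = complement)
  info <- information_value(sig$k, sig$n_set)
  data.frame(term_id = sig$term_id, p_value = sig$p_value, k = sig$k,
             cert = cert, info = info, rem = cert * info,
             stringsAsFactors = FALSE)
}

#' Computed ABC analysis
#'
#' Data-driven partition of positively valued items into the "important few"
#' (set A), the proportional middle (set B) and the "trivial many" (set C).
#' Items are sorted in descending value order and the ABC curve of
#' cumulative item fraction versus cumulative value fraction is formed. The
#' A/B boundary is the curve point closest (Euclidean) to the ideal point
#' (0, 1); the B/C boundary is the first point at or after it where the
#' curve's segment slope drops to the break-even `dy/dx <= 1`. A boundary
#' never splits a block of tied values: the whole tie block joins the more
#' important set (except in the fully degenerate all-equal case, which is
#' partitioned by the curve alone with a warning).
#'
#' @param values non-negative numeric vector, named by item id; at least 3
#'   items, not all zero.
#' @return Object of class `abc_partition`: list with `set_a`, `set_b`,
#'   `set_c` (item ids in descending value order), `boundary_ab`,
#'   `boundary_bc` (indices into the sorted order), `order` (sorted item
#'   ids) and `curve` (data.frame `x`, `y`).
#' @examples
#' abc_analysis(c(a = 100, b = 1, c = 1, d = 1))$set_a
#' @export
abc_analysis <- function(values) {
  if (length(values) < 3) stop("abc_analysis: need at least 3 items")
  if (any(values < 0) || all(values == 0))
    stop("abc_analysis: values must be non-negative and not all zero")
  if (is.null(names(values))) names(values) <- as.character(seq_along(values))
  ord <- order(-values)   # stable: tied items keep their input order
  v <- values[ord]
  n <- length(v)
  x <- seq_len(n) / n
  y <- cumsum(v) / sum(v)
  dist <- sqrt(x^2 + (1 - y)^2)
  i_ab <- which.min(dist)
  degenerate <- length(unique(v)) == 1L
  if (degenerate)
    warning("abc_analysis: all item values are equal; partition is degenerate")
  extend_over_ties <- function(i) {
    if (degenerate || i >= n) return(i)
    while (i < n && v[i + 1] == v[i]) i <- i + 1L
    i
  }
  i_ab <- extend_over_ties(i_ab)
  # segment slope after point i: n * v[i+1] / sum(v); break even at 1
  slope_after <- c(n * v[-1] / sum(v), 0)
  i_bc <- i_ab
  while (i_bc < n && slope_after[i_bc] > 1) i_bc <- i_bc + 1L
  i_bc <- extend_over_ties(i_bc)
  ids <- names(v)
  structure(list(set_a = ids[seq_len(i_ab)],
                 set_b = if (i_bc > i_ab) ids[seq(i_ab + 1L, i_bc)] else character(),
                 set_c = if (i_bc < n) ids[seq(i_bc + 1L, n)] else character(),
                 boundary_ab = unname(i_ab), boundary_bc = unname(i_bc),
                 order = ids, values = unname(v),
                 curve = data.frame(x = c(0, x), y = c(0, y))),
            class = "abc_partition")
}

#' @export
print.abc_partition <- function(x, ...) {
  cat("ABC partition: |A| =", length(x$set_a),
      " |B| =", length(x$set_b), " |C| =", length(x$set_c), "\n")
  invisible(x)
}

#' Details: significant terms at the tip of a significant branch
#'
#' A detail is a significant term with no significant descendant, i.e. the
#' most specific significant statement along its branch of the polyhierarchy.
#'
#' @param dag an [ontology_dag()].
#' @param significant_terms character vector of significant term ids.
#' @param relations relation types treated as ancestry.
#' @return Character vector of detail term ids (sorted).
#' @export
find_details <- function(dag, significant_terms,
                         relations = c("is_a", "part_of", "regulates")) {
  stopifnot(inherits(dag, "ontology_dag"))
  if (!length(significant_terms)) stop("find_details: empty significant set")
  anc <- term_ancestors(dag, relations)
  has_sig_desc <- unique(unlist(anc[significant_terms], use.names = FALSE))
  sort(setdiff(significant_terms, has_sig_desc))
}

#' Headlines: most remarkable significant term per branch
#'
#' For every detail and every distinct path from that detail up to a root,
#' the significant on-path term with maximal remarkableness is selected;
#' ties along a path are broken toward the term nearest the detail (the more
#' specific statement). The headline set is the union over all details and
#' paths, computed by champion propagation over the ancestor sub-DAG, which
#' is equivalent to exhaustive path enumeration without materializing the
#' (possibly exponential) path set.
#'
#' @param dag an [ontology_dag()].
#' @param details detail term ids from [find_details()].
#' @param scores data.frame from [term_scores()] covering all significant
#'   terms (details included).
#' @param relations relation types treated as ancestry.
#' @return Character vector of headline term ids (sorted).
#' @export
find_headlines <- function(dag, details, scores,
                           relations = c("is_a", "part_of", "regulates")) {
  stopifnot(inherits(dag, "ontology_dag"), is.data.frame(scores))
  if (!length(details)) return(character())
  rem <- stats::setNames(scores$rem, scores$term_id)
  if (!all(details %in% names(rem)))
    stop("find_headlines: details missing from the score table")
  anc <- term_ancestors(dag, relations)
  e <- dag$edges[dag$edges$relation %in% relations, , drop = FALSE]
  parents <- split(e$parent, e$child)
  # process nodes children-first so champions flow upward
  ids <- dag$terms$term_id
  g <- igraph::graph_from_data_frame(e[, c("child", "parent")],
                                     directed = TRUE, vertices = ids)
  topo <- as.character(names(igraph::topo_sort(g, mode = "out")))
  headlines <- character()
  for (d in details) {
    sub <- c(d, anc[[d]])
    champ <- stats::setNames(vector("list", length(sub)), sub)
    champ[[d]] <- d                    # a detail is significant by definition
    for (v in topo) {
      if (!v %in% sub || is.null(champ[[v]])) next
      for (p in parents[[v]]) {
        if (!p %in% sub) next
        cand <- champ[[v]]
        if (!is.na(rem[p])) {
          # the parent takes over only with strictly larger remarkableness;
          # equality keeps the incumbent, which lies nearer the detail
          cand <- ifelse(rem[p] > rem[cand], p, cand)
        }
        champ[[p]] <- unique(c(champ[[p]], cand))
      }
    }
    tops <- sub[!vapply(parents[sub], function(p)
      any(p %in% sub), logical(1))]   # maximal elements = roots of the sub-DAG
    headlines <- c(headlines, unlist(champ[tops], use.names = FALSE))
  }
  sort(unique(headlines))
}

#' Reduce headlines to the important few (ABC set A)
#'
#' Applies [abc_analysis()] to the remarkableness of the headline terms and
#' keeps set A. With fewer than 3 headlines the ABC curve is undefined and
#' all headlines are returned with a warning.
#'
#' @param headlines headline term ids.
#' @param scores data.frame from [term_scores()].
#' @return Character vector of retained headline ids.
#' @export
select_important_headlines <- function(headlines, scores) {
  if (length(headlines) < 3) {
    warning("fewer than 3 headlines; keeping all")
    return(headlines)
  }
  rem <- stats::setNames(scores$rem, scores$term_id)
  abc_analysis(rem[headlines])$set_a
}

#' Subsume headlines into functional areas
#'
#' Iteratively replaces groups of headlines by a common ancestor term until
#' the set is no larger than `target_max` (aiming at Miller's 5--9 range of
#' human-graspable set sizes). Reduction proceeds in abstraction passes:
#' at the start of a pass every ontology term that is a strict ancestor of
#' at least two current members is a candidate; candidates are ranked by
#' depth (maximal longest-path distance from a root), then by larger member
#' coverage, then lexicographic term id, and are executed in that order,
#' each absorbing those of its covered members still present — so the most
#' specific common ancestor always wins the genes it covers. Passes repeat
#' while the set is still larger than `target_max`. A single pass with
#' several disjoint high-coverage ancestors can overshoot below
#' `target_min`; singleton members are never collapsed, so overshoot only
#' happens when no finer merge exists. If no ancestor covers two members
#' while the set is still above `target_max`, the irreducible set is
#' returned with a warning.
#'
#' @param dag an [ontology_dag()].
#' @param headlines character vector of headline term ids.
#' @param target_min,target_max bounds of the target range (default 5--9).
#' @param relations relation types treated as ancestry.
#' @return Object of class `subsumption`: list with `areas` (final term
#'   ids), `history` (one row per merge: ancestor, members absorbed) and the
#'   original `headlines`.
#' @export
subsume <- function(dag, headlines, target_min = 5L, target_max = 9L,
                    relations = c("is_a", "part_of", "regulates")) {
  stopifnot(inherits(dag, "ontology_dag"), target_min <= target_max)
  H <- unique(headlines)
  anc <- term_ancestors(dag, relations)
  depth <- .term_depths(dag, relations)
  history <- list()
  while (length(H) > target_max) {
    cover <- .ancestor_cover(H, anc)
    if (!length(cover)) {
      warning("subsume: no common ancestor covers two headlines; ",
              "returning irreducible set of ", length(H))
      break
    }
    # deepest first, then widest coverage, then term id
    ord <- names(cover)[order(-depth[names(cover)], -lengths(cover),
                              names(cover))]
    removed <- character()
    for (pick in ord) {
      if (pick %in% removed) next
      absorbed <- setdiff(intersect(cover[[pick]], H), pick)
      if (length(absorbed) < 2L) next
      H <- sort(unique(c(setdiff(H, absorbed), pick)))
      removed <- c(removed, absorbed)
      history[[length(history) + 1L]] <-
        data.frame(ancestor = pick, member = absorbed,
                   stringsAsFactors = FALSE)
    }
    if (!length(removed)) break
  }
  structure(list(areas = sort(H),
                 history = if (length(history)) do.call(rbind, history) else
                   data.frame(ancestor = character(), member = character()),
                 headlines = sort(unique(headlines))),
            class = "subsumption")
}

# strict ancestors of >= 2 members, with the members they cover
.ancestor_cover <- function(H, anc) {
  a_flat <- unlist(anc[H], use.names = FALSE)
  member <- rep(H, lengths(anc[H]))
  keep <- !a_flat %in% NA
  sp <- split(member[keep], a_flat[keep])
  sp <- lapply(sp, unique)
  sp[lengths(sp) >= 2L]
}

# longest-path depth from a root, for every term
.term_depths <- function(dag, relations = c("is_a", "part_of", "regulates")) {
  ids <- dag$terms$term_id
  e <- dag$edges[dag$edges$relation %in% relations, , drop = FALSE]
  depth <- stats::setNames(rep(0, length(ids)), ids)
  if (!nrow(e)) return(depth)
  g <- igraph::graph_from_data_frame(e[, c("child", "parent")],
                                     directed = TRUE, vertices = ids)
  ord <- rev(as.character(names(igraph::topo_sort(g, mode = "out"))))
  parents <- split(e$parent, e$child)
  for (v in ord) {
    p <- parents[[v]]
    if (!is.null(p)) depth[v] <- 1 + max(depth[p])
  }
  depth
}

#' @export
print.subsumption <- function(x, ...) {
  cat("subsumption:", length(x$headlines), "headline(s) ->",
      length(x$areas), "functional area(s)\n")
  invisible(x)
}

#' Classify every DAG node for rendering
#'
#' Assigns each term its most specific applicable class with precedence
#' `functional_area > headline > detail > significant > structural`,
#' mirroring the node-color semantics of the classified polyhierarchy plot
#' (structural connectors uncolored, significant nodes red, details green,
#' headlines yellow, functional areas violet).
#'
#' @param dag an [ontology_dag()].
#' @param ora an [run_ora()] result.
#' @param details,headlines,areas term id vectors from the reduction steps.
#' @return data.frame `term_id`, `class` (factor with the five levels).
#' @export
classify_nodes <- function(dag, ora, details, headlines, areas) {
  stopifnot(inherits(dag, "ontology_dag"))
  cls <- stats::setNames(rep("structural", nrow(dag$terms)), dag$terms$term_id)
  sig <- ora$term_id[ora$significant]
  cls[intersect(sig, names(cls))] <- "significant"
  cls[intersect(details, names(cls))] <- "detail"
  cls[intersect(headlines, names(cls))] <- "headline"
  cls[intersect(areas, names(cls))] <- "functional_area"
  data.frame(term_id = names(cls),
             class = factor(unname(cls),
                            levels = c("structural", "significant", "detail",
                                       "headline", "functional_area")),
             stringsAsFactors = FALSE)
}

#' Export a classified DAG to DOT
#'
#' Writes a Graphviz DOT rendering of the ontology with node fill colors
#' following the classification semantics: structural white, significant
#' red, detail green, headline yellow, functional area violet.
#'
#' @param dag an [ontology_dag()].
#' @param classes data.frame from [classify_nodes()] (optional; all nodes
#'   structural when missing).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
export_dot <- function(dag, classes = NULL, path) {
  stopifnot(inherits(dag, "ontology_dag"))
  fill <- c(structural = "white", significant = "red", detail = "green",
            headline = "yellow", functional_area = "violet")
  cls <- stats::setNames(rep("structural", nrow(dag$terms)), dag$terms$term_id)
  if (!is.null(classes)) cls[classes$term_id] <- as.character(classes$class)
  quote_id <- function(x) paste0('"', x, '"')
  nm <- dag$terms$name[match(names(cls), dag$terms$term_id)]
  nodes <- sprintf('  %s [label="%s", style=filled, fillcolor=%s];',
                   quote_id(names(cls)),
                   gsub('"', "'", paste0(names(cls), "\\n", nm)),
                   fill[cls])
  style <- c(is_a = "solid", part_of = "dashed", regulates = "dotted")
  edges <- sprintf('  %s -> %s [style=%s];',
                   quote_id(dag$edges$child), quote_id(dag$edges$parent),
                   style[dag$edges$relation])
  writeLines(c("digraph ontology {", "  rankdir=BT;", nodes, edges, "}"),
             path)
  invisible(path)
}
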