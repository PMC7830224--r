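#' Construct a validated ontology DAG
#'
#' Builds the central ontology container from a term table and a typed edge
#' list. Edges point from child to parent (`child` "is_a"/"part_of"/
#' "regulates" `parent`), mirroring the child-to-root orientation of the Gene
#' Ontology. Validation enforces unique term identifiers, resolvable parents
#' and acyclicity; roots (no parents) and leaves (no children) are derived
#' from the edge set.
#'
#' @param terms data.frame with columns `term_id`, `name`, `namespace`.
#' @param edges data.frame with columns `child`, `parent`, `relation`
#'   (relation in `is_a`, `part_of`, `regulates`). May have zero rows.
#' @return An object of class `ontology_dag`: a list with elements `terms`,
#'   `edges`, `roots`, `leaves`.
#' @examples
#' terms <- data.frame(term_id = c("T:1", "T:2"), name = c("root", "leaf"),
#'                     namespace = "synthetic")
#' edges <- data.frame(child = "T:2", parent = "T:1", relation = "is_a")
#' dag <- ontology_dag(terms, edges)
#' dag$roots
#' @export
ontology_dag <- function(terms, edges) {
  stopifnot(is.data.frame(terms), is.data.frame(edges))
  terms <- terms[, c("term_id", "name", "namespace")]
  terms$term_id <- as.character(terms$term_id)
  if (anyDuplicated(terms$term_id))
    stop("duplicate term_id: ",
         paste(unique(terms$term_id[duplicated(terms$term_id)]), collapse = ", "))
  if (nrow(edges)) {
    edges <- data.frame(child = as.character(edges$child),
                        parent = as.character(edges$parent),
                        relation = as.character(edges$relation),
                        stringsAsFactors = FALSE)
    bad_rel <- setdiff(unique(edges$relation), c("is_a", "part_of", "regulates"))
    if (length(bad_rel))
      stop("unsupported relation(s): ", paste(bad_rel, collapse = ", "))
    dangling <- setdiff(unique(c(edges$child, edges$parent)), terms$term_id)
    if (length(dangling))
      stop("edge references unknown term(s): ", paste(dangling, collapse = ", "))
  } else {
    edges <- data.frame(child = character(), parent = character(),
                        relation = character(), stringsAsFactors = FALSE)
  }
  g <- igraph::graph_from_data_frame(
    edges[, c("child", "parent")], directed = TRUE,
    vertices = terms$term_id)
  if (!igraph::is_dag(g)) {
    cyc <- .find_cycle_edge(edges)
    stop("cycle detected in ontology (e.g. edge ", cyc, ")")
  }
  roots <- setdiff(terms$term_id, edges$child)
  leaves <- setdiff(terms$term_id, edges$parent)
  structure(list(terms = terms, edges = edges, roots = roots, leaves = leaves),
            class = "ontology_dag")
}

# locate one edge participating in a cycle, for the error message
.find_cycle_edge <- function(edges) {
  ids <- unique(c(edges$child, edges$parent))
  state <- stats::setNames(integer(length(ids)), ids)  # 0 white 1 grey 2 black
  par <- split(edges$parent, edges$child)
  hit <- NULL
  visit <- function(v) {
    if (!is.null(hit)) return()
    state[[v]] <<- 1L
    for (p in par[[v]]) {
      if (state[[p]] == 1L) { hit <<- paste0(v, " -> ", p); return() }
      if (state[[p]] == 0L) visit(p)
      if (!is.null(hit)) return()
    }
    state[[v]] <<- 2L
  }
  for (v in ids) if (state[[v]] == 0L) visit(v)
  if (is.null(hit)) "<unknown>" else hit
}

#' @export
print.ontology_dag <- function(x, ...) {
  cat("ontology_dag:", nrow(x$terms), "terms,", nrow(x$edges), "edges,",
      length(x$roots), "root(s),", length(x$leaves), "leaf/leaves\n")
  invisible(x)
}

#' Parse an OBO flat file into an ontology DAG
#'
#' Reads OBO 1.2/1.4 `[Term]` stanzas. Obsolete terms are dropped together
#' with any edge touching them; `is_a` and the `part_of`/`regulates`
#' relationships are kept, any other relationship type is ignored with a
#' warning. Dangling parent identifiers and cycles are hard errors.
#'
#' @param path path to an OBO file.
#' @return An [ontology_dag()].
#' @export
parse_obo <- function(path) {
  lines <- readLines(path, warn = FALSE)
  # stanza boundaries
  starts <- grep("^\\[", lines)
  if (!length(starts)) stop("no stanzas found in ", path)
  ends <- c(starts[-1] - 1L, length(lines))
  keep <- lines[starts] == "[Term]"
  term_rows <- list(); edge_rows <- list(); skipped_rel <- character()
  for (i in which(keep)) {
    block <- lines[seq(starts[i] + 1L, ends[i])]
    block <- block[nzchar(block)]
    val <- function(key) {
      m <- grep(paste0("^", key, ":"), block, value = TRUE)
      sub("\\s*!.*$", "", sub(paste0("^", key, ":\\s*"), "", m))
    }
    id <- val("id")[1]
    if (is.na(id) || !nzchar(id)) next
    if (any(grepl("true", val("is_obsolete")))) next
    nm <- val("name")[1]
    ns <- val("namespace")[1]
    if (is.na(ns)) ns <- "unknown"
    isa <- val("is_a")
    rels <- val("relationship")
    edge <- NULL
    if (length(isa))
      edge <- data.frame(child = id, parent = trimws(isa), relation = "is_a",
                         stringsAsFactors = FALSE)
    if (length(rels)) {
      parts <- strsplit(trimws(rels), "\\s+")
      rtype <- vapply(parts, `[`, "", 1L)
      rtarget <- vapply(parts, `[`, "", 2L)
      ok <- rtype %in% c("part_of", "regulates")
      skipped_rel <- c(skipped_rel, rtype[!ok])
      if (any(ok))
        edge <- rbind(edge, data.frame(child = id, parent = rtarget[ok],
                                       relation = rtype[ok],
                                       stringsAsFactors = FALSE))
    }
    term_rows[[length(term_rows) + 1L]] <-
      data.frame(term_id = id, name = if (is.na(nm)) id else nm,
                 namespace = ns, stringsAsFactors = FALSE)
    if (!is.null(edge)) edge_rows[[length(edge_rows) + 1L]] <- edge
  }
  if (length(skipped_rel))
    warning("ignored relationship type(s): ",
            paste(unique(skipped_rel), collapse = ", "))
  terms <- do.call(rbind, term_rows)
  if (is.null(terms)) stop("no non-obsolete [Term] stanzas in ", path)
  edges <- if (length(edge_rows)) do.call(rbind, edge_rows) else
    data.frame(child = character(), parent = character(), relation = character())
  # edges pointing at obsolete (dropped) terms are dangling -> hard error,
  # but edges *from* dropped terms have vanished with their stanza already
  ontology_dag(terms, edges)
}

#' Write an ontology DAG as an OBO flat file
#'
#' Inverse of [parse_obo()] for the stanza fields the package uses; a
#' write/re-parse round trip preserves the term set and the typed edge set.
#'
#' @param dag an [ontology_dag()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(dag, path) {
  stopifnot(inherits(dag, "ontology_dag"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  by_child <- split(dag$edges, dag$edges$child)
  for (i in seq_len(nrow(dag$terms))) {
    id <- dag$terms$term_id[i]
    out <- c("[Term]",
             paste0("id: ", id),
             paste0("name: ", dag$terms$name[i]),
             paste0("namespace: ", dag$terms$namespace[i]))
    e <- by_child[[id]]
    if (!is.null(e)) {
      isa <- e$parent[e$relation == "is_a"]
      oth <- e[e$relation != "is_a", ]
      out <- c(out,
               if (length(isa)) paste0("is_a: ", isa),
               if (nrow(oth)) paste0("relationship: ", oth$relation, " ", oth$parent))
    }
    writeLines(c(out, ""), con)
  }
  invisible(path)
}

#' Ancestor sets for every term
#'
#' Returns, for each term, all terms reachable by repeatedly following
#' child-to-parent edges of the selected relation types (the term itself is
#' not included). Follows the true-path convention of treating `part_of` and
#' `regulates` like `is_a` by default; restrict with `relations = "is_a"`.
#'
#' @param dag an [ontology_dag()].
#' @param relations character vector of relation types to traverse.
#' @return Named list mapping `term_id` to a character vector of ancestors.
#' @export
term_ancestors <- function(dag, relations = c("is_a", "part_of", "regulates")) {
  stopifnot(inherits(dag, "ontology_dag"))
  ids <- dag$terms$term_id
  e <- dag$edges[dag$edges$relation %in% relations, , drop = FALSE]
  anc <- stats::setNames(vector("list", length(ids)), ids)
  if (!nrow(e)) return(lapply(anc, function(x) character()))
  g <- igraph::graph_from_data_frame(e[, c("child", "parent")],
                                     directed = TRUE, vertices = ids)
  # topo_sort puts children before parents (edges run child -> parent);
  # reverse it so each node's parents are finished before the node itself
  ord <- rev(as.character(names(igraph::topo_sort(g, mode = "out"))))
  parents <- split(e$parent, e$child)
  for (v in ord) {
    p <- parents[[v]]
    if (is.null(p)) { anc[[v]] <- character(); next }
    anc[[v]] <- unique(c(p, unlist(anc[p], use.names = FALSE)))
  }
  anc
}

#' Descendant sets for every term
#'
#' Companion of [term_ancestors()]: `t` is a descendant of `s` iff `s` is an
#' ancestor of `t`.
#'
#' @inheritParams term_ancestors
#' @return Named list mapping `term_id` to a character vector of descendants.
#' @export
term_descendants <- function(dag, relations = c("is_a", "part_of", "regulates")) {
  anc <- term_ancestors(dag, relations)
  ids <- names(anc)
  desc <- stats::setNames(vector("list", length(ids)), ids)
  for (id in ids) desc[[id]] <- character()
  child_of <- rep(ids, lengths(anc))
  anc_flat <- unlist(anc, use.names = FALSE)
  if (length(anc_flat)) {
    sp <- split(child_of, anc_flat)
    desc[names(sp)] <- lapply(sp, unique)
  }
  desc
}

#' Propagate gene annotations up the ontology (true-path rule)
#'
#' A gene annotated to a term is implicitly annotated to every ancestor of
#' that term. The propagated map is the direct map closed under the ancestor
#' relation; propagation is idempotent.
#'
#' @param dag an [ontology_dag()].
#' @param direct named list mapping gene symbol to a character vector of
#'   directly annotated term ids. Symbols are uppercased; duplicate symbols
#'   are collapsed with a warning.
#' @param relations relation types treated as ancestry (default all three,
#'   the true-path convention).
#' @return An object of class `annotation_map`: list with `direct`,
#'   `propagated` (both named lists) and `background_genes`.
#' @export
propagate <- function(dag, direct,
                      relations = c("is_a", "part_of", "regulates")) {
  stopifnot(inherits(dag, "ontology_dag"), is.list(direct))
  genes <- toupper(names(direct))
  if (anyDuplicated(genes)) {
    warning("collapsing duplicate gene symbols: ",
            paste(unique(genes[duplicated(genes)]), collapse = ", "))
    direct <- lapply(split(direct, genes), function(x)
      unique(as.character(unlist(x, use.names = FALSE))))
    genes <- names(direct)
  } else {
    names(direct) <- genes
  }
  used <- unique(unlist(direct, use.names = FALSE))
  unknown <- setdiff(used, dag$terms$term_id)
  if (length(unknown))
    stop("annotation references unknown term(s): ",
         paste(unknown, collapse = ", "))
  anc <- term_ancestors(dag, relations)
  propagated <- lapply(direct, function(ts)
    unique(c(ts, unlist(anc[ts], use.names = FALSE))))
  structure(list(direct = direct, propagated = propagated,
                 background_genes = genes),
            class = "annotation_map")
}

#' @export
print.annotation_map <- function(x, ...) {
  cat("annotation_map:", length(x$background_genes), "genes,",
      length(unique(unlist(x$propagated, use.names = FALSE))),
      "annotated terms after propagation\n")
  invisible(x)
}

#' Count study-set genes annotated to a term
#'
#' The over-representation numerator: the number of genes of `gene_set`
#' carrying `term_id` in their propagated annotation.
#'
#' @param ann an [propagate()] result.
#' @param term_id single term id.
#' @param gene_set character vector of gene symbols (uppercased internally).
#' @return Integer count in `[0, length(gene_set)]`.
#' @export
term_gene_count <- function(ann, term_id, gene_set) {
  stopifnot(inherits(ann, "annotation_map"), length(term_id) == 1L)
  gene_set <- unique(toupper(gene_set))
  gene_set <- intersect(gene_set, names(ann$propagated))
  if (!length(gene_set)) return(0L)
  sum(vapply(ann$propagated[gene_set],
             function(ts) term_id %in% ts, logical(1)))
}

#' Read a two-column gene-to-term annotation table
#'
#' @param path TSV with columns gene symbol and term id (no header by
#'   default).
#' @param header logical; does the file carry a header line?
#' @return Named list mapping gene symbol to term ids, suitable for
#'   [propagate()].
#' @export
read_annotations <- function(path, header = FALSE) {
  df <- utils::read.table(path, sep = "\t", header = header,
                          stringsAsFactors = FALSE)
  names(df)[1:2] <- c("gene", "term")
  lapply(split(df$term, toupper(df$gene)), unique)
}

#' Write a two-column gene-to-term annotation table
#'
#' @param direct named list mapping gene symbol to term ids.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(direct, path) {
  df <- data.frame(gene = rep(names(direct), lengths(direct)),
                   term = unlist(direct, use.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a newline-delimited gene list
#'
#' @param path text file, one symbol per line; blank lines and `#` comments
#'   are skipped.
#' @return Character vector of uppercased unique symbols, input order.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x <- x[nzchar(x) & !startsWith(x, "#")]
  unique(toupper(x))
}
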