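# Independent oracles: each reimplements the checked quantity by a different
# route (enumeration, fixed-point iteration, explicit loops) so tests never
# compare an implementation with itself.

# ancestor sets by boolean-matrix fixed point (vs topological propagation)
oracle_ancestors <- function(term_ids, edges) {
  n <- length(term_ids)
  A <- matrix(FALSE, n, n, dimnames = list(term_ids, term_ids))
  for (i in seq_len(nrow(edges))) A[edges$child[i], edges$parent[i]] <- TRUE
  repeat {
    A2 <- A | ((A %*% A) > 0)
    if (identical(A2, A)) break
    A <- A2
  }
  lapply(stats::setNames(term_ids, term_ids),
         function(t) term_ids[A[t, ]])
}

# hypergeometric upper tail by exhaustive subset enumeration (N small)
oracle_hyper_tail <- function(k, n_set, K, N) {
  if (n_set == 0) return(as.numeric(k <= 0))
  subsets <- utils::combn(N, n_set)
  overlap <- colSums(subsets <= K)
  mean(overlap >= k)
}

# percentage-bend correlation, written as explicit per-step loops
oracle_pbcor <- function(x, y, beta = 0.2) {
  n <- length(x)
  pbos <- function(v) {
    w <- sort(abs(v - median(v)))
    om <- w[floor((1 - beta) * n + 0.5)]
    psi <- (v - median(v)) / om
    i1 <- 0; i2 <- 0; s <- 0
    for (j in seq_len(n)) {
      if (psi[j] < -1) i1 <- i1 + 1
      else if (psi[j] > 1) i2 <- i2 + 1
      else s <- s + v[j]
    }
    list(om = om, phi = (om * (i2 - i1) + s) / (n - i1 - i2))
  }
  bx <- pbos(x); by <- pbos(y)
  a <- numeric(n); b <- numeric(n)
  for (j in seq_len(n)) {
    a[j] <- min(1, max(-1, (x[j] - bx$phi) / bx$om))
    b[j] <- min(1, max(-1, (y[j] - by$phi) / by$om))
  }
  num <- 0; da <- 0; db <- 0
  for (j in seq_len(n)) {
    num <- num + a[j] * b[j]; da <- da + a[j]^2; db <- db + b[j]^2
  }
  r <- num / sqrt(da * db)
  tt <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p_value = 2 * stats::pt(abs(tt), n - 2, lower.tail = FALSE))
}

# A/B boundary of the ABC curve by brute-force distance minimization
oracle_abc_ab_boundary <- function(values) {
  v <- sort(values, decreasing = TRUE)
  n <- length(v)
  best <- Inf; best_i <- NA
  for (i in seq_len(n)) {
    d <- sqrt((i / n)^2 + (1 - sum(v[seq_len(i)]) / sum(v))^2)
    if (d < best) { best <- d; best_i <- i }
  }
  best_i
}

# headline set by exhaustive enumeration of every detail-to-root path
oracle_headlines <- function(dag, details, rem) {
  parents <- split(dag$edges$parent, dag$edges$child)
  paths_up <- function(v) {
    p <- parents[[v]]
    if (is.null(p)) return(list(v))
    out <- list()
    for (q in p) for (pp in paths_up(q)) out[[length(out) + 1L]] <- c(v, pp)
    out
  }
  hl <- character()
  for (d in details) {
    for (path in paths_up(d)) {
      sig <- path[path %in% names(rem)]
      best <- sig[1]   # nearest the detail wins ties
      for (t in sig) if (rem[t] > rem[best]) best <- t
      hl <- c(hl, best)
    }
  }
  sort(unique(hl))
}

# small fixed DAGs used across tests
chain_dag <- function() {
  ontology_dag(
    data.frame(term_id = c("T:root", "T:a", "T:b"),
               name = c("root", "a", "b"), namespace = "synthetic"),
    data.frame(child = c("T:a", "T:b"), parent = c("T:root", "T:a"),
               relation = "is_a"))
}

diamond_dag <- function() {
  ontology_dag(
    data.frame(term_id = c("T:root", "T:l", "T:r", "T:d"),
               name = c("root", "left", "right", "detail"),
               namespace = "synthetic"),
    data.frame(child = c("T:l", "T:r", "T:d", "T:d"),
               parent = c("T:root", "T:root", "T:l", "T:r"),
               relation = "is_a"))
}

# random DAG as raw tables (nodes indexed so edges always point upward)
random_dag_tables <- function(n, seed, p_edge = 0.1) {
  set.seed(seed)
  ids <- sprintf("R:%03d", seq_len(n))
  e <- list()
  for (i in 2:n) {
    par <- which(stats::runif(i - 1) < p_edge)
    if (!length(par)) par <- sample.int(i - 1, 1)
    e[[i]] <- data.frame(child = ids[i], parent = ids[par],
                         relation = "is_a", stringsAsFactors = FALSE)
  }
  list(terms = data.frame(term_id = ids, name = ids,
                          namespace = "synthetic", stringsAsFactors = FALSE),
       edges = do.call(rbind, e))
}
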