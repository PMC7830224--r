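test_that("certainty ranks by strictly smaller p-values", {
  p <- c(a = 1e-20, b = 1e-18, c = 1e-16, d = 1e-14, e = 1e-12)
  cert <- certainty(p)
  expect_equal(unname(cert["a"]), 0)
  expect_equal(unname(cert["e"]), 4 / 5)
  expect_equal(certainty(rep(0.5, 4)), rep(0, 4))   # strict inequality
  comp <- certainty(p, complement = TRUE)
  expect_equal(unname(comp["a"]), 1)
  expect_error(certainty(numeric()), "empty")
})

test_that("information value hits its closed-form anchors", {
  expect_equal(information_value(1, exp(1)), 1, tolerance = 1e-12)
  expect_equal(information_value(5, 5), 0, tolerance = 1e-12)
  expect_equal(information_value(0, 5), 0)
  expect_equal(information_value(1, 2), -exp(1) * 0.5 * log(0.5),
               tolerance = 1e-12)
  k <- 0:72
  expect_true(all(information_value(k, 72) >= 0 &
                    information_value(k, 72) <= 1))
})

test_that("remarkableness is the exact product of certainty and information", {
  ora <- data.frame(term_id = sprintf("T:%d", 1:6),
                    k = c(10, 20, 26, 30, 5, 2), n_set = 72,
                    K = 50, N = 2000,
                    p_value = 10^-(20:15), significant = TRUE)
  sc <- term_scores(ora)
  expect_equal(sc$rem, sc$cert * sc$info)
  expect_true(all(sc$rem >= 0 & sc$rem < 1))
  expect_equal(sc$rem[which.min(sc$p_value)], 0)
})

test_that("ABC analysis solves the documented small cases", {
  abc <- suppressWarnings(abc_analysis(stats::setNames(rep(3, 8),
                                                       paste0("i", 1:8))))
  expect_equal(length(abc$set_a), 4)   # diagonal curve: nearest point at 0.5
  expect_warning(abc_analysis(rep(1, 4)), "degenerate")
  abc2 <- abc_analysis(c(a = 100, b = 1, c = 1, d = 1))
  expect_equal(abc2$set_a, "a")
  expect_error(abc_analysis(c(1, 2)), "at least 3")
  expect_error(abc_analysis(c(0, 0, 0)), "not all zero")
})

test_that("ABC partitions are ordered and match the boundary oracle", {
  for (s in 1:100) {
    set.seed(s)
    n <- sample(5:30, 1)
    v <- stats::setNames(stats::rexp(n) * 10, sprintf("x%02d", seq_len(n)))
    abc <- abc_analysis(v)
    expect_setequal(c(abc$set_a, abc$set_b, abc$set_c), names(v))
    expect_identical(c(abc$set_a, abc$set_b, abc$set_c), abc$order)
    if (length(abc$set_b)) expect_gte(min(v[abc$set_a]), max(v[abc$set_b]))
    if (length(abc$set_b) && length(abc$set_c))
      expect_gte(min(v[abc$set_b]), max(v[abc$set_c]))
    expect_equal(abc$boundary_ab, oracle_abc_ab_boundary(v))
    # mass concentration: A holds at least its item share of the value mass
    expect_gte(sum(v[abc$set_a]) / sum(v), length(abc$set_a) / length(v))
  }
})

test_that("details are the significant branch tips", {
  dag <- chain_dag()
  expect_equal(find_details(dag, c("T:root", "T:a", "T:b")), "T:b")
  dia <- diamond_dag()
  expect_setequal(find_details(dia, c("T:root", "T:l", "T:r")),
                  c("T:l", "T:r"))
  expect_error(find_details(dag, character()), "empty")
})

test_that("details match a brute-force descendant scan on random DAGs", {
  for (s in 1:10) {
    tab <- random_dag_tables(40, seed = 100 + s)
    dag <- ontology_dag(tab$terms, tab$edges)
    set.seed(s)
    sig <- sample(tab$terms$term_id, 12)
    anc <- oracle_ancestors(tab$terms$term_id, tab$edges)
    want <- sort(Filter(function(t)
      !any(vapply(setdiff(sig, t), function(s2) t %in% anc[[s2]],
                  logical(1))), sig))
    expect_equal(find_details(dag, sig), want)
  }
})

scores_for <- function(ids, rem) {
  data.frame(term_id = ids, p_value = NA_real_, k = NA_integer_,
             cert = NA_real_, info = NA_real_, rem = rem)
}

test_that("the most remarkable on-path term is the branch headline", {
  dag <- chain_dag()
  sc <- scores_for(c("T:root", "T:a", "T:b"), c(0.1, 0.9, 0.2))
  expect_equal(find_headlines(dag, "T:b", sc), "T:a")
  # an isolated significant term is its own headline
  iso <- ontology_dag(data.frame(term_id = "T:x", name = "x",
                                 namespace = "synthetic"),
                      data.frame(child = character(), parent = character(),
                                 relation = character()))
  expect_equal(find_headlines(iso, "T:x", scores_for("T:x", 0.5)), "T:x")
})

test_that("diamond paths select the union of per-path maxima", {
  dia <- diamond_dag()
  sc <- scores_for(c("T:root", "T:l", "T:r", "T:d"), c(0.1, 0.8, 0.6, 0.3))
  rem <- stats::setNames(sc$rem, sc$term_id)
  expect_equal(find_headlines(dia, "T:d", sc),
               oracle_headlines(dia, "T:d", rem))
  expect_setequal(find_headlines(dia, "T:d", sc), c("T:l", "T:r"))
})

test_that("headline propagation equals path enumeration on random DAGs", {
  for (s in 1:10) {
    tab <- random_dag_tables(18, seed = 200 + s, p_edge = 0.18)
    dag <- ontology_dag(tab$terms, tab$edges)
    set.seed(s)
    sig <- sample(tab$terms$term_id, 8)
    rem <- stats::setNames(round(stats::runif(8), 3), sig)
    det <- find_details(dag, sig)
    sc <- scores_for(sig, unname(rem))
    expect_equal(find_headlines(dag, det, sc),
                 oracle_headlines(dag, det, rem))
  }
})

test_that("ties in remarkableness keep the term nearest the detail", {
  dag <- chain_dag()
  sc <- scores_for(c("T:root", "T:a", "T:b"), c(0.2, 0.5, 0.5))
  expect_equal(find_headlines(dag, "T:b", sc), "T:b")
})

test_that("a headline set below the target range is left untouched", {
  dag <- chain_dag()
  out <- subsume(dag, c("T:a", "T:b"))
  expect_setequal(out$areas, c("T:a", "T:b"))
  expect_equal(nrow(out$history), 0)
})

test_that("twelve headlines under three disjoint parents collapse to three areas", {
  terms <- data.frame(
    term_id = c("T:root", sprintf("T:p%d", 1:3), sprintf("T:h%02d", 1:12)),
    name = "t", namespace = "synthetic")
  edges <- rbind(
    data.frame(child = sprintf("T:p%d", 1:3), parent = "T:root",
               relation = "is_a"),
    data.frame(child = sprintf("T:h%02d", 1:12),
               parent = rep(sprintf("T:p%d", 1:3), each = 4),
               relation = "is_a"))
  dag <- ontology_dag(terms, edges)
  out <- subsume(dag, sprintf("T:h%02d", 1:12))
  expect_setequal(out$areas, sprintf("T:p%d", 1:3))
})

test_that("subsumption never grows the set and areas cover what they absorbed", {
  cfg <- sim_config(seed = 8, n_terms = 200, n_genes = 400,
                    n_planted_leaves = 15, n_theme_genes = 40,
                    leaf_membership = 8)
  dag <- gen_ontology(cfg)
  set.seed(1)
  H <- sample(dag$planted_leaves, 12)
  out <- subsume(dag, H)
  expect_lte(length(out$areas), length(H))
  if (nrow(out$history)) {
    anc <- term_ancestors(dag)
    ok <- mapply(function(a, m) a == m || a %in% anc[[m]],
                 out$history$ancestor, out$history$member)
    expect_true(all(ok))
  }
})

test_that("an irreducible oversized set is returned with a warning", {
  terms <- data.frame(term_id = sprintf("T:i%02d", 1:12), name = "t",
                      namespace = "synthetic")
  edges <- data.frame(child = character(), parent = character(),
                      relation = character())
  dag <- ontology_dag(terms, edges)
  expect_warning(out <- subsume(dag, terms$term_id), "irreducible")
  expect_equal(length(out$areas), 12)
})

test_that("node classes follow the specificity precedence", {
  dag <- chain_dag()
  ora <- data.frame(term_id = c("T:a", "T:b"), significant = c(TRUE, TRUE))
  cls <- classify_nodes(dag, ora, details = "T:b",
                        headlines = "T:b", areas = "T:a")
  got <- stats::setNames(as.character(cls$class), cls$term_id)
  expect_equal(unname(got["T:root"]), "structural")
  expect_equal(unname(got["T:a"]), "functional_area")
  expect_equal(unname(got["T:b"]), "headline")  # headline beats detail
})

test_that("fewer than three headlines skip ABC selection with a warning", {
  sc <- scores_for(c("T:x", "T:y"), c(0.4, 0.2))
  expect_warning(out <- select_important_headlines(c("T:x", "T:y"), sc),
                 "fewer than 3")
  expect_setequal(out, c("T:x", "T:y"))
})

test_that("DOT export renders every node and edge with class colors", {
  dag <- chain_dag()
  ora <- data.frame(term_id = "T:b", significant = TRUE)
  cls <- classify_nodes(dag, ora, "T:b", "T:b", character())
  f <- tempfile(fileext = ".dot")
  export_dot(dag, cls, f)
  txt <- readLines(f)
  expect_true(any(grepl("fillcolor=yellow", txt)))
  expect_true(any(grepl('"T:b" -> "T:a"', txt)))
})
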