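test_that("panel assembly reports the Venn arithmetic of its subsets", {
  p <- assemble_panel(c("a", "b", "c"), c("d", "e", "f", "g"))
  expect_equal(unname(p$summary), c(3L, 4L, 0L, 7L))
  same <- assemble_panel(c("x", "y"), c("y", "x"))
  expect_equal(unname(same$summary["n_union"]), 2L)
  expect_equal(unname(same$summary["n_shared"]), 2L)
})

test_that("gene-set intersection recovers exactly the planted overlap", {
  set.seed(77)
  shared <- sprintf("SH%03d", 1:50)
  a <- sample(c(sprintf("A%03d", 1:77), shared))    # 127 symbols
  b <- sample(c(sprintf("B%03d", 1:102), shared))   # 152 symbols
  expect_equal(intersect_gene_sets(a, b), sort(shared))
  expect_equal(intersect_gene_sets(a, a), sort(a))
  expect_equal(intersect_gene_sets(sprintf("A%d", 1:3), sprintf("B%d", 1:3)),
               character())
})

toy_models <- function() {
  validate_gene_models(data.frame(
    gene = "GX", chrom = "chr1", strand = "+",
    feature = c("span", "utr5", "cds", "cds", "utr3"),
    start = c(1000L, 1000L, 1100L, 1400L, 1700L),
    end = c(2000L, 1100L, 1300L, 1600L, 2000L)))
}

test_that("location classes follow containment priority", {
  m <- toy_models()
  # VCF pos is 1-based: base at 0-based 1150 is pos 1151
  expect_equal(as.character(classify_location("chr1", 1151, m)$location),
               "exonic")
  expect_equal(as.character(classify_location("chr1", 1051, m)$location),
               "utr5")
  expect_equal(as.character(classify_location("chr1", 1801, m)$location),
               "utr3")
  expect_equal(as.character(classify_location("chr1", 1350, m)$location),
               "intronic")
  # 10 bases past the gene end, inside the 25-base padding
  expect_equal(as.character(classify_location("chr1", 2010, m)$location),
               "intergenic")
  expect_true(is.na(classify_location("chr1", 2010, m)$gene))
})

test_that("every base of the toy model classifies as its containing interval", {
  m <- toy_models()
  pos0 <- 1000:1999
  got <- as.character(classify_location(rep("chr1", 1000), pos0 + 1, m)$location)
  want <- rep("intronic", 1000)
  want[pos0 >= 1000 & pos0 < 1100] <- "utr5"
  want[pos0 >= 1100 & pos0 < 1300] <- "exonic"
  want[pos0 >= 1400 & pos0 < 1600] <- "exonic"
  want[pos0 >= 1700 & pos0 < 2000] <- "utr3"
  expect_equal(got, want)
})

test_that("overlapping genes resolve by CDS containment", {
  m <- validate_gene_models(data.frame(
    gene = c("A", "A", "B", "B"), chrom = "chr2", strand = "+",
    feature = c("span", "cds", "span", "cds"),
    start = c(100L, 400L, 300L, 320L), end = c(500L, 450L, 700L, 340L)))
  hit <- classify_location("chr2", 331, m)   # inside B's CDS, A's intron
  expect_equal(hit$gene, "B")
  expect_equal(as.character(hit$location), "exonic")
})

test_that("exact Hardy-Weinberg proportions are retained with p = 1", {
  res <- hwe_filter(c(25, 50, 25))
  expect_equal(res$p_value, 1)
  expect_true(res$retained)
  expect_equal(unname(res$p), 0.5)
  expect_equal(res$e_ref_hom + res$e_het + res$e_alt_hom, 100)
})

test_that("monomorphic variants pass and extreme disequilibrium is dropped", {
  expect_true(hwe_filter(c(100, 0, 0))$retained)
  for (m in c("fisher_expected", "exact", "midp")) {
    res <- hwe_filter(c(50, 0, 50), method = m)
    expect_false(res$retained)
    expect_lt(res$p_value, 1e-10)
  }
})

test_that("expected counts always derive from the observed allele frequency", {
  g <- gen_genotypes(sim_config(seed = 2, n_variants = 20))
  res <- hwe_filter(g)
  n <- rowSums(as.matrix(g))
  expect_equal(res$p, (2 * g$n_ref_hom + g$n_het) / (2 * n))
  expect_equal(res$e_ref_hom + res$e_het + res$e_alt_hom, n)
})

test_that("coverage acceptance is strict at the depth bound", {
  expect_true(coverage_accept(rep(21, 50)))
  expect_false(coverage_accept(c(rep(200, 49), 20)))
  expect_true(coverage_accept(rep(200, 50)))
  expect_error(coverage_accept(numeric()), "empty")
})

test_that("location tables partition the variants and find silent genes", {
  v <- data.frame(
    gene = c("A", "A", "B", NA),
    location = c("exonic", "utr3", "intronic", "intergenic"))
  tab <- variant_location_table(v, panel_genes = c("A", "B", "C"))
  expect_equal(unname(tab$by_location["total"]),
               sum(tab$by_location[c("exonic", "utr5", "utr3",
                                     "intronic", "intergenic")]))
  expect_equal(tab$zero_variant_genes, "C")
  empty <- variant_location_table(data.frame(location = character()))
  expect_true(all(empty$by_location == 0))
})

test_that("percentage-bend correlation is exact on concordant pairs", {
  x <- c(1, 3, 2, 8, 5, 4, 9, 7, 6, 10)
  expect_equal(percentage_bend_correlation(x, x)$r, 1, tolerance = 1e-12)
  expect_equal(percentage_bend_correlation(x, -x)$r, -1, tolerance = 1e-12)
  expect_error(percentage_bend_correlation(rep(1, 10), x), "constant")
})

test_that("a contaminated pair matches the step-by-step reference", {
  x <- c(1.1, 2.3, 2.9, 4.2, 5.0, 6.1, 7.3, 8.2, 9.0, 60)
  y <- c(2.0, 2.8, 4.1, 4.6, 6.2, 6.8, 8.1, 9.4, 10.2, 1.5)
  got <- percentage_bend_correlation(x, y)
  ref <- oracle_pbcor(x, y)
  expect_equal(got$r, ref$r, tolerance = 1e-10)
  expect_equal(got$p_value, ref$p_value, tolerance = 1e-10)
  # robustness: one gross outlier wrecks Pearson but not the bend estimator
  expect_gt(abs(got$r), abs(stats::cor(x, y)))
})

test_that("on clean normal samples the bend estimator tracks Pearson", {
  set.seed(11)
  diffs <- replicate(20, {
    x <- stats::rnorm(200)
    y <- 0.6 * x + sqrt(1 - 0.36) * stats::rnorm(200)
    abs(percentage_bend_correlation(x, y)$r - stats::cor(x, y))
  })
  expect_lt(mean(diffs), 0.05)
})

test_that("the estimator stays within [-1, 1] on arbitrary input", {
  set.seed(12)
  for (i in 1:20) {
    x <- stats::rcauchy(15); y <- stats::rcauchy(15)
    r <- percentage_bend_correlation(x, y)$r
    expect_gte(r, -1); expect_lte(r, 1)
  }
})

test_that("VCF genotype counts round-trip, decomposing multiallelic sites", {
  f <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "S1", "S2", "S3", "S4"), collapse = "\t"),
    paste(c("chr1", "101", ".", "A", "G", ".", "PASS", ".", "GT",
            "0/0", "0/1", "1/1", "0|1"), collapse = "\t"),
    paste(c("chr1", "202", ".", "C", "G,T", ".", "PASS", ".", "GT",
            "0/1", "1/2", "2/2", "0/0"), collapse = "\t")), f)
  got <- read_variant_genotypes(f)
  expect_equal(nrow(got), 3)          # one biallelic + two decomposed rows
  expect_equal(got$n_het[1], 2)
  g_alt <- got[got$alt == "G" & got$pos == 202, ]
  expect_equal(c(g_alt$n_ref_hom, g_alt$n_het, g_alt$n_alt_hom), c(2, 2, 0))
  t_alt <- got[got$alt == "T", ]
  expect_equal(c(t_alt$n_ref_hom, t_alt$n_het, t_alt$n_alt_hom), c(2, 1, 1))
})

test_that("cohort-ratio arithmetic scales cases by the control count", {
  expect_equal(expected_outcome_subjects(60, 74, 779), 60 * 74 / 779)
  expect_equal(expected_outcome_subjects(10, 0, 5), 0)
  expect_error(expected_outcome_subjects(0, 1, 1))
})

test_that("gene model validation rejects malformed tables", {
  expect_error(validate_gene_models(data.frame(gene = "A")), "columns")
  bad <- data.frame(gene = "A", chrom = "c", strand = "+",
                    feature = "enhancer", start = 1L, end = 2L)
  expect_error(validate_gene_models(bad), "feature")
  nospan <- data.frame(gene = "A", chrom = "c", strand = "+",
                       feature = "cds", start = 1L, end = 2L)
  expect_error(validate_gene_models(nospan), "span")
})
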