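#' Assemble a gene panel from two subsets
#'
#' Forms the union of two gene subsets with per-gene provenance labels and
#' the Venn arithmetic of the merge (subset sizes, intersection, union).
#'
#' @param subset1,subset2 character vectors of gene symbols (uppercased,
#'   de-duplicated internally).
#' @return Object of class `gene_panel`: list with `entries` (data.frame
#'   `gene`, `subset1`, `subset2`) and `summary` (named integer vector
#'   `n_subset1`, `n_subset2`, `n_shared`, `n_union`).
#' @examples
#' assemble_panel(c("TNF", "IL6"), c("TNF", "COMT"))$summary
#' @export
assemble_panel <- function(subset1, subset2) {
  stopifnot(length(subset1) > 0, length(subset2) > 0)
  s1 <- unique(toupper(subset1)); s2 <- unique(toupper(subset2))
  genes <- sort(union(s1, s2))
  entries <- data.frame(gene = genes, subset1 = genes %in% s1,
                        subset2 = genes %in% s2, stringsAsFactors = FALSE)
  structure(list(entries = entries,
                 summary = c(n_subset1 = length(s1), n_subset2 = length(s2),
                             n_shared = length(intersect(s1, s2)),
                             n_union = length(genes))),
            class = "gene_panel")
}

#' @export
print.gene_panel <- function(x, ...) {
  s <- x$summary
  cat(sprintf("gene_panel: %d genes (subset1 %d, subset2 %d, shared %d)\n",
              s["n_union"], s["n_subset1"], s["n_subset2"], s["n_shared"]))
  invisible(x)
}

#' Order-insensitive gene set intersection
#'
#' @param a,b character vectors of gene symbols.
#' @return Sorted uppercased intersection.
#' @export
intersect_gene_sets <- function(a, b) {
  sort(intersect(unique(toupper(a)), unique(toupper(b))))
}

#' Load the packaged pain-panel gene lists
#'
#' Returns the two panel subsets shipped with the package: subset 1, the 29
#' key genes selected by a computational functional-genomics reduction of
#' 540 pain-relevant genes, and subset 2, the 50 genes shared by two
#' independent proposals of persistent-pain genes.
#'
#' @return List with character vectors `subset1` and `subset2`.
#' @export
pain_panel_genes <- function() {
  path <- system.file("extdata", "pain_panel_genes.tsv", package = "panelora")
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  list(subset1 = df$gene[df$subset1], subset2 = df$gene[df$subset2])
}

#' Expected persistent-pain subjects in a planned sample
#'
#' Scales the case-to-control ratio of a reference cohort to a planned
#' sample size: `n_planned * n_cases / n_controls`.
#'
#' @param n_planned planned number of samples.
#' @param n_cases cohort subjects with the outcome.
#' @param n_controls cohort subjects without the outcome.
#' @return Expected number of subjects with the outcome.
#' @examples
#' expected_outcome_subjects(60, 74, 779)  # ~5.7
#' @export
expected_outcome_subjects <- function(n_planned, n_cases, n_controls) {
  stopifnot(n_planned > 0, n_cases >= 0, n_controls > 0)
  n_planned * n_cases / n_controls
}

#' Read BED-like gene models
#'
#' Expects a TSV with header columns `gene`, `chrom`, `strand`, `feature`,
#' `start`, `end`, where `feature` is one of `span`, `cds`, `utr5`, `utr3`
#' and coordinates are 0-based half-open (BED convention). Each gene must
#' have exactly one `span` row containing all its other intervals.
#'
#' @param path TSV file path.
#' @return data.frame of class `gene_models`.
#' @export
read_gene_models <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  validate_gene_models(df)
}

#' Validate a gene-model table
#'
#' @param df data.frame with columns `gene`, `chrom`, `strand`, `feature`,
#'   `start`, `end` (0-based half-open).
#' @return The validated data.frame, classed `gene_models`.
#' @export
validate_gene_models <- function(df) {
  need <- c("gene", "chrom", "strand", "feature", "start", "end")
  if (!all(need %in% names(df)))
    stop("gene models need columns: ", paste(need, collapse = ", "))
  bad <- setdiff(unique(df$feature), c("span", "cds", "utr5", "utr3"))
  if (length(bad)) stop("unknown feature(s): ", paste(bad, collapse = ", "))
  if (any(df$end <= df$start)) stop("intervals must satisfy start < end")
  for (g in unique(df$gene)) {
    rows <- df[df$gene == g, ]
    sp <- rows[rows$feature == "span", ]
    if (nrow(sp) != 1L) stop("gene ", g, " must have exactly one span row")
    sub <- rows[rows$feature != "span", ]
    if (nrow(sub) && (any(sub$start < sp$start) || any(sub$end > sp$end)))
      stop("gene ", g, ": feature intervals exceed the gene span")
  }
  class(df) <- c("gene_models", "data.frame")
  df
}

#' Classify variant positions against gene models
#'
#' Assigns each variant a location class by containment priority: a position
#' inside a CDS exon is `exonic`; inside a 5'/3' UTR interval `utr5`/`utr3`;
#' elsewhere inside a gene span `intronic`; inside the padded span (or
#' nowhere) `intergenic`. When several genes overlap a position, the gene
#' whose CDS contains it wins, otherwise the first gene in genomic order.
#' VCF positions are 1-based; gene-model intervals 0-based half-open.
#'
#' @param chrom,pos vectors of variant chromosome and 1-based position.
#' @param models a [read_gene_models()] table.
#' @param padding bases of padding around the gene span that still count as
#'   targeted (classified `intergenic`); default 25.
#' @return data.frame `chrom`, `pos`, `gene` (NA outside every span),
#'   `location` (factor: exonic, utr5, utr3, intronic, intergenic).
#' @export
classify_location <- function(chrom, pos, models, padding = 25) {
  stopifnot(inherits(models, "data.frame"), length(chrom) == length(pos))
  pos0 <- pos - 1L  # 0-based coordinate of the variant base
  spans <- models[models$feature == "span", , drop = FALSE]
  spans <- spans[order(spans$chrom, spans$start), , drop = FALSE]
  n <- length(pos0)
  gene <- rep(NA_character_, n)
  location <- rep("intergenic", n)
  feature_at <- function(g, p) {
    sub <- models[models$gene == g & models$feature != "span", , drop = FALSE]
    hit <- sub$feature[sub$start <= p & p < sub$end]
    if ("cds" %in% hit) "exonic"
    else if ("utr5" %in% hit) "utr5"
    else if ("utr3" %in% hit) "utr3"
    else "intronic"
  }
  for (i in seq_len(n)) {
    inside <- spans$chrom == chrom[i] & spans$start <= pos0[i] &
      pos0[i] < spans$end
    if (!any(inside)) next
    cand <- spans$gene[inside]
    feats <- vapply(cand, feature_at, "", p = pos0[i])
    pick <- if (any(feats == "exonic")) which(feats == "exonic")[1] else 1L
    gene[i] <- cand[pick]
    location[i] <- feats[pick]
  }
  data.frame(chrom = chrom, pos = pos, gene = gene,
             location = factor(location,
                               levels = c("exonic", "utr5", "utr3",
                                          "intronic", "intergenic")),
             stringsAsFactors = FALSE)
}

#' Read variant records with genotype counts from a VCF
#'
#' Parses a VCF with GT genotypes and tabulates, per record and alternate
#' allele, the diploid genotype counts relative to that allele. Multiallelic
#' records are decomposed into one row per alternate allele (a genotype
#' heterozygous for two different alternates counts as heterozygous for
#' each).
#'
#' @param path VCF file path (plain text or bgzipped).
#' @return data.frame `chrom`, `pos`, `ref`, `alt`, `n_ref_hom`, `n_het`,
#'   `n_alt_hom` (`n_ref_hom` counts genotypes without the allele).
#' @export
read_variant_genotypes <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  fix <- vcfR::getFIX(v)
  out <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    g <- gt[i, ]
    alleles <- strsplit(gsub("\\|", "/", g[!is.na(g)]), "/", fixed = FALSE)
    for (j in seq_along(alts)) {
      dose <- vapply(alleles, function(a) sum(a == as.character(j)), numeric(1))
      out[[length(out) + 1L]] <- data.frame(
        chrom = fix[i, "CHROM"], pos = as.integer(fix[i, "POS"]),
        ref = fix[i, "REF"], alt = alts[j],
        n_ref_hom = sum(dose == 0), n_het = sum(dose == 1),
        n_alt_hom = sum(dose == 2), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

# exact test of HWE conditioning on the allele counts; optionally mid-p
.exact_hwe_p <- function(n_ref_hom, n_het, n_alt_hom, midp = FALSE) {
  n <- n_ref_hom + n_het + n_alt_hom
  nA <- 2 * n_ref_hom + n_het
  nB <- 2 * n_alt_hom + n_het
  nrare <- min(nA, nB)
  if (nrare == 0) return(1)
  hets <- seq(nrare %% 2, nrare, by = 2)
  logp <- vapply(hets, function(h) {
    hom_r <- (nrare - h) / 2
    hom_c <- n - h - hom_r
    h * log(2) + lgamma(n + 1) - lgamma(hom_r + 1) - lgamma(h + 1) -
      lgamma(hom_c + 1) + lgamma(nA + 1) + lgamma(nB + 1) - lgamma(2 * n + 1)
  }, numeric(1))
  probs <- exp(logp - max(logp))
  probs <- probs / sum(probs)
  i <- match(n_het, hets)
  pv <- sum(probs[probs <= probs[i] * (1 + 1e-9)])
  if (midp) pv <- pv - probs[i] / 2
  min(1, pv)
}

#' Hardy-Weinberg equilibrium test and filter
#'
#' Compares observed genotype counts with the Hardy-Weinberg expectation
#' `(n p^2, 2 n p q, n q^2)` computed from the observed allele frequency,
#' and retains variants compatible with equilibrium (`p_value >= alpha`).
#' Three tests are offered: `"fisher_expected"` (default) runs Fisher's
#' exact test on the 2x3 table of observed versus rounded expected counts —
#' a deliberately conservative screen that treats the expectation as a
#' pseudo-sample; `"exact"` is the standard exact HWE test conditioning on
#' the allele counts; `"midp"` is its mid-p variant, whose rejection rate is
#' closest to the nominal level. Monomorphic variants are in equilibrium by
#' convention (`p_value = 1`).
#'
#' @param counts data.frame (or matrix) with columns `n_ref_hom`, `n_het`,
#'   `n_alt_hom`; a bare numeric vector of length 3 is also accepted.
#' @param alpha retention threshold on the p-value (default 0.05).
#' @param method `"fisher_expected"`, `"exact"` or `"midp"`.
#' @return data.frame of class `hwe_result` with the observed counts,
#'   allele frequency `p`, expected counts, `p_value` and `retained`.
#' @examples
#' hwe_filter(c(25, 50, 25))          # exact HWE proportions: retained
#' hwe_filter(c(50, 0, 50))$retained  # extreme disequilibrium: dropped
#' @export
hwe_filter <- function(counts, alpha = 0.05,
                       method = c("fisher_expected", "exact", "midp")) {
  method <- match.arg(method)
  if (is.numeric(counts) && is.null(dim(counts)) && length(counts) == 3)
    counts <- data.frame(n_ref_hom = counts[1], n_het = counts[2],
                         n_alt_hom = counts[3])
  counts <- as.data.frame(counts)
  stopifnot(all(c("n_ref_hom", "n_het", "n_alt_hom") %in% names(counts)))
  obs <- as.matrix(counts[, c("n_ref_hom", "n_het", "n_alt_hom")])
  if (any(obs < 0)) stop("negative genotype counts")
  n <- rowSums(obs)
  if (any(n < 1)) stop("each variant needs at least one genotype")
  p <- (2 * obs[, 1] + obs[, 2]) / (2 * n)
  q <- 1 - p
  exp_counts <- cbind(e_ref_hom = n * p^2, e_het = 2 * n * p * q,
                      e_alt_hom = n * q^2)
  pv <- numeric(nrow(obs))
  for (i in seq_len(nrow(obs))) {
    if (p[i] == 0 || p[i] == 1) { pv[i] <- 1; next }
    pv[i] <- switch(method,
      fisher_expected = stats::fisher.test(
        rbind(obs[i, ], round(exp_counts[i, ])))$p.value,
      exact = .exact_hwe_p(obs[i, 1], obs[i, 2], obs[i, 3]),
      midp = .exact_hwe_p(obs[i, 1], obs[i, 2], obs[i, 3], midp = TRUE))
  }
  res <- data.frame(counts[, c("n_ref_hom", "n_het", "n_alt_hom")],
                    p = p, exp_counts, p_value = pv,
                    retained = pv >= alpha)
  rownames(res) <- NULL
  class(res) <- c("hwe_result", "data.frame")
  res
}

#' Per-base coverage acceptance of a target region
#'
#' A region counts as successfully analyzed only if the read depth of every
#' base exceeds `min_depth` (strictly: a base at exactly `min_depth` fails).
#'
#' @param depths numeric vector of per-base read depths over the padded
#'   region.
#' @param min_depth strict lower bound (default 20).
#' @return Single logical.
#' @examples
#' coverage_accept(rep(21, 100))          # TRUE
#' coverage_accept(c(rep(200, 99), 20))   # FALSE: one base at the bound
#' @export
coverage_accept <- function(depths, min_depth = 20) {
  if (!length(depths)) stop("coverage_accept: empty region")
  all(depths > min_depth)
}

#' Tabulate variants by location class
#'
#' @param variants data.frame with a `location` column (factor or character
#'   with classes exonic, utr5, utr3, intronic, intergenic) and optionally a
#'   `gene` column.
#' @param panel_genes optional character vector of all panel genes, used to
#'   report genes without any variant.
#' @return List with `by_location` (named counts incl. `total`),
#'   `by_gene` (data.frame `gene`, `n_variants`) and `zero_variant_genes`.
#' @export
variant_location_table <- function(variants, panel_genes = NULL) {
  lv <- c("exonic", "utr5", "utr3", "intronic", "intergenic")
  loc <- factor(as.character(variants$location), levels = lv)
  counts <- table(loc)
  by_location <- c(as.integer(counts), sum(counts))
  names(by_location) <- c(lv, "total")
  by_gene <- NULL; zero <- character()
  if (!is.null(variants$gene) || !is.null(panel_genes)) {
    g <- as.character(variants$gene)
    g <- g[!is.na(g)]
    tab <- table(g)
    genes <- if (is.null(panel_genes)) names(tab) else unique(toupper(panel_genes))
    by_gene <- data.frame(gene = genes,
                          n_variants = as.integer(tab[genes]),
                          stringsAsFactors = FALSE)
    by_gene$n_variants[is.na(by_gene$n_variants)] <- 0L
    zero <- by_gene$gene[by_gene$n_variants == 0L]
  }
  list(by_location = by_location, by_gene = by_gene,
       zero_variant_genes = zero)
}

#' Percentage-bend correlation
#'
#' Robust correlation after Wilcox (1994): each vector is standardized by a
#' bend scale (the `floor((1 - beta) n + 0.5)`-th smallest absolute
#' deviation from the median) around a bend-adjusted location, residuals are
#' clipped to `[-1, 1]`, and the clipped residuals are correlated. The
#' fraction `beta` (default 0.2, the conventional choice) controls how many
#' extreme observations are downweighted. The p-value uses the Student-t
#' approximation `T = r sqrt((n-2)/(1-r^2))` with `n - 2` degrees of
#' freedom, two-sided.
#'
#' @param x,y numeric vectors of equal length `n >= 4`.
#' @param beta bend fraction in `[0, 0.5)`.
#' @return List with `r`, `p_value`, `n`, `beta`.
#' @examples
#' set.seed(1)
#' x <- rnorm(50); y <- x + rnorm(50)
#' percentage_bend_correlation(x, y)$r
#' @export
percentage_bend_correlation <- function(x, y, beta = 0.2) {
  stopifnot(length(x) == length(y), beta >= 0, beta < 0.5)
  n <- length(x)
  if (n < 4) stop("percentage_bend_correlation: need n >= 4")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    stop("percentage_bend_correlation: constant vector")
  bend <- function(v) {
    w <- sort(abs(v - stats::median(v)))
    omega <- w[floor((1 - beta) * n + 0.5)]
    if (omega <= 0)
      stop("percentage_bend_correlation: zero bend scale (vector constant ",
           "after bending)")
    psi <- (v - stats::median(v)) / omega
    i1 <- sum(psi < -1); i2 <- sum(psi > 1)
    sv <- ifelse(abs(psi) <= 1, v, 0)
    phi <- (omega * (i2 - i1) + sum(sv)) / (n - i1 - i2)
    u <- (v - phi) / omega
    pmin(1, pmax(-1, u))
  }
  a <- bend(x); b <- bend(y)
  r <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  p <- if (is.finite(tstat)) 2 * stats::pt(abs(tstat), n - 2,
                                           lower.tail = FALSE) else 0
  list(r = r, p_value = p, n = n, beta = beta)
}
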