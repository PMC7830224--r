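#' Simulation configuration
#'
#' Collects every knob of the synthetic-data generators. Defaults mirror the
#' dimensions of a realistic amplicon-panel study at desk scale: a 500-term
#' ontology over 2000 background genes, a 72-gene study set, and 61
#' genotyped subjects. The planted-theme parameters encode a strong,
#' functionally coherent signal: one internal "theme" term with
#' `n_planted_leaves` leaf children, a pool of `n_theme_genes` background
#' genes each annotated to `leaf_membership` of those leaves, and a study
#' set drawn with sampling weight `enrichment_factor` on the pool (see the
#' methods vignette for the power reasoning behind the defaults).
#'
#' @param seed master seed; every generator derives its own fixed stream
#'   from it, so adding a generator never perturbs existing draws.
#' @param n_terms,n_layers,max_parents ontology size and shape.
#' @param n_genes background gene count.
#' @param annotation_exponent power-law exponent of leaf-term annotation
#'   sizes.
#' @param n_planted_leaves leaf terms of the planted theme module (0
#'   disables planting).
#' @param n_theme_genes,leaf_membership size of the theme gene pool and how
#'   many planted leaves each pool gene is annotated to.
#' @param planted_terms explicit planted term ids (default `NULL`: the
#'   theme's leaves chosen by [gen_ontology()]).
#' @param enrichment_factor sampling weight of pool genes when drawing the
#'   study set; 1 means no enrichment (null case).
#' @param n_study study gene-set size.
#' @param n_subjects,maf,inbreeding_f genotype simulation: subjects, minor
#'   allele frequency, inbreeding coefficient F (0 = exact HWE).
#' @param n_variants number of simulated variants.
#' @param n_panel_genes,length_range,mean_variants,target_rho per-gene
#'   variant-count table: panel size, gene-length range (bases), mean
#'   variant count per gene, and the population correlation between length
#'   and count.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_terms = 500L, n_layers = 6L, max_parents = 3L,
                       n_genes = 2000L, annotation_exponent = 1.5,
                       n_planted_leaves = 40L, n_theme_genes = 80L,
                       leaf_membership = 18L, planted_terms = NULL,
                       enrichment_factor = 100, n_study = 72L,
                       n_subjects = 61L, maf = 0.2, inbreeding_f = 0,
                       n_variants = 100L,
                       n_panel_genes = 72L, length_range = c(500, 20000),
                       mean_variants = 9.6, target_rho = 0.6) {
  stopifnot(n_terms >= 3, max_parents >= 1, enrichment_factor >= 1,
            maf > 0, maf <= 0.5, inbreeding_f >= -1, inbreeding_f <= 1,
            length(length_range) == 2, target_rho >= 0, target_rho < 1)
  structure(as.list(environment()), class = "sim_config")
}

# independent, reproducible seed per generator stream
.stream_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) %% 1e6) * 1009 + stream * 9973) %% 2147483647L
}

#' Generate a layered random ontology DAG
#'
#' Builds a single-root layered DAG: terms are spread over layers of
#' increasing size and every non-root term draws 1..`max_parents` parents
#' from shallower layers (preferentially the adjacent one), which makes the
#' graph acyclic by construction. Relations are mostly `is_a` with a
#' minority of `part_of`/`regulates`. When `n_planted_leaves > 0` a theme
#' module is planted: a theme term in an intermediate layer becomes the
#' primary parent of `n_planted_leaves` bottom-layer leaves, and about half
#' of the leaves carry one additional cross-link to a shallow term
#' (multi-parentage is the norm in real ontologies). The theme and its
#' planted leaves are recorded in the returned object (`$theme`,
#' `$planted_leaves`).
#'
#' @param config a [sim_config()].
#' @return An [ontology_dag()] with namespace `"synthetic"` and, when
#'   planting is enabled, elements `theme` and `planted_leaves`.
#' @export
gen_ontology <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(.stream_seed(config$seed, 1L))
  n <- config$n_terms
  n_layers <- max(2L, min(config$n_layers, n))
  ids <- sprintf("SYN:%07d", seq_len(n))
  terms <- data.frame(term_id = ids,
                      name = sprintf("synthetic process %d", seq_len(n)),
                      namespace = "synthetic", stringsAsFactors = FALSE)
  # layer sizes grow with depth; root alone in layer 0
  w <- seq_len(n_layers - 1L)
  sizes <- pmax(1L, round((n - 1L) * w / sum(w)))
  while (sum(sizes) > n - 1L) sizes[which.max(sizes)] <- sizes[which.max(sizes)] - 1L
  while (sum(sizes) < n - 1L) sizes[length(sizes)] <- sizes[length(sizes)] + 1L
  layer <- c(0L, rep(seq_len(n_layers - 1L), times = sizes))
  edges <- vector("list", n)
  for (i in which(layer > 0L)) {
    shallower <- which(layer < layer[i])
    wgt <- ifelse(layer[shallower] == layer[i] - 1L, 4, 1)
    n_par <- sample.int(config$max_parents, 1L)
    par <- shallower[sample.int(length(shallower),
                                min(n_par, length(shallower)), prob = wgt)]
    edges[[i]] <- data.frame(
      child = ids[i], parent = ids[par],
      relation = sample(c("is_a", "part_of", "regulates"), length(par),
                        replace = TRUE, prob = c(0.8, 0.15, 0.05)),
      stringsAsFactors = FALSE)
  }
  edges <- do.call(rbind, edges)
  theme <- NULL; planted <- character()
  if (config$n_planted_leaves > 0L) {
    theme_layer <- min(3L, n_layers - 2L)
    cand <- which(layer == theme_layer)
    theme <- ids[cand[sample.int(length(cand), 1L)]]
    bottom <- setdiff(ids[layer == n_layers - 1L], c(edges$parent, theme))
    n_pl <- min(config$n_planted_leaves, length(bottom))
    planted <- sort(sample(bottom, n_pl))
    # planted leaves form a clean functional module below the theme: the
    # theme is their primary parent; a minority keep one cross-link to a
    # shallow term so multi-parentage is represented
    edges <- edges[!edges$child %in% planted, , drop = FALSE]
    new_e <- data.frame(child = planted, parent = theme, relation = "is_a",
                        stringsAsFactors = FALSE)
    shallow <- ids[layer >= 1L & layer < theme_layer]
    crossed <- planted[stats::runif(n_pl) < 0.5]
    if (length(crossed) && length(shallow))
      new_e <- rbind(new_e, data.frame(
        child = crossed,
        parent = sample(shallow, length(crossed), replace = TRUE),
        relation = "part_of", stringsAsFactors = FALSE))
    edges <- rbind(edges, new_e)
  }
  dag <- ontology_dag(terms, edges)
  dag$theme <- theme
  dag$planted_leaves <- planted
  dag
}

#' Generate gene annotations with planted enrichment
#'
#' Annotates background genes to leaf terms with power-law term sizes, adds
#' a pool of theme genes annotated across the planted leaves, and draws a
#' study set in which pool genes are oversampled by `enrichment_factor`
#' (factor 1 reduces to a uniform draw, the null case). The returned truth
#' records what was planted and the realized per-term fold enrichment.
#'
#' @param dag an [gen_ontology()] result (or any [ontology_dag()]).
#' @param config a [sim_config()]; `config$planted_terms` overrides the
#'   DAG's recorded planted leaves.
#' @return List with `ann` (an [propagate()] result), `study_set`
#'   (character), and `truth` (list: `theme`, `planted_terms`, `pool`,
#'   `realized_fold` named by planted term).
#' @export
gen_annotations_with_planting <- function(dag, config = sim_config()) {
  stopifnot(inherits(dag, "ontology_dag"), inherits(config, "sim_config"))
  set.seed(.stream_seed(config$seed, 2L))
  planted <- config$planted_terms
  if (is.null(planted)) planted <- dag$planted_leaves
  if (length(setdiff(planted, dag$terms$term_id)))
    stop("planted terms not in the ontology")
  genes <- sprintf("G%05d", seq_len(config$n_genes))
  leaves <- sample(dag$leaves)
  wgt <- seq_along(leaves)^(-config$annotation_exponent)
  direct <- lapply(genes, function(g) {
    k <- sample.int(3L, 1L)
    leaves[sample.int(length(leaves), min(k, length(leaves)), prob = wgt)]
  })
  names(direct) <- genes
  pool <- character()
  if (length(planted) && config$n_theme_genes > 0L) {
    pool <- sort(sample(genes, min(config$n_theme_genes, length(genes))))
    m <- min(config$leaf_membership, length(planted))
    for (g in pool)
      direct[[g]] <- unique(c(direct[[g]], sample(planted, m)))
  }
  study_w <- ifelse(genes %in% pool, config$enrichment_factor, 1)
  study <- sort(sample(genes, min(config$n_study, length(genes)),
                       prob = study_w))
  ann <- propagate(dag, direct)
  fold <- vapply(planted, function(t) {
    k <- term_gene_count(ann, t, study)
    K <- term_gene_count(ann, t, genes)
    if (K == 0) return(NA_real_)
    (k / length(study)) / (K / length(genes))
  }, numeric(1))
  list(ann = ann, study_set = study,
       truth = list(theme = dag$theme, planted_terms = planted,
                    pool = pool, realized_fold = fold))
}

#' Generate diploid genotype count trios
#'
#' Draws per-variant genotype counts from the inbreeding model
#' `(p^2 + F p q, 2 p q (1 - F), q^2 + F p q)` with `p = 1 - maf`;
#' `F = 0` gives the exact Hardy-Weinberg expectation, `F = 1` eliminates
#' heterozygotes and `F = -1` (only valid at `maf = 0.5`) makes every
#' subject heterozygous.
#'
#' @param config a [sim_config()] (uses `n_variants`, `n_subjects`, `maf`,
#'   `inbreeding_f`, `seed`).
#' @return data.frame `n_ref_hom`, `n_het`, `n_alt_hom`, one row per
#'   variant.
#' @export
gen_genotypes <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"), config$n_subjects >= 1)
  set.seed(.stream_seed(config$seed, 3L))
  p <- 1 - config$maf; q <- config$maf; F <- config$inbreeding_f
  probs <- c(p^2 + F * p * q, 2 * p * q * (1 - F), q^2 + F * p * q)
  if (any(probs < -1e-12))
    stop("invalid genotype probabilities: F = ", F,
         " too negative for maf = ", config$maf)
  probs <- pmax(probs, 0)
  draws <- stats::rmultinom(config$n_variants, config$n_subjects, probs)
  data.frame(n_ref_hom = draws[1, ], n_het = draws[2, ],
             n_alt_hom = draws[3, ])
}

#' Generate a per-gene variant-count table correlated with gene length
#'
#' Gene lengths are uniform on `length_range`; variant counts are Poisson
#' with a rate affine in length, with the slope calibrated so the population
#' correlation between length and count is `target_rho` at the requested
#' mean count. Short genes naturally end up with zero counts.
#'
#' @param config a [sim_config()] (uses `n_panel_genes`, `length_range`,
#'   `mean_variants`, `target_rho`, `seed`).
#' @return data.frame `gene`, `length`, `n_variants`.
#' @export
gen_variant_table <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"), config$n_panel_genes >= 4)
  set.seed(.stream_seed(config$seed, 4L))
  a <- config$length_range[1]; b <- config$length_range[2]
  len <- stats::runif(config$n_panel_genes, a, b)
  V <- (b - a)^2 / 12
  rho <- config$target_rho
  slope <- if (rho == 0) 0 else
    sqrt(config$mean_variants * rho^2 / ((1 - rho^2) * V))
  intercept <- config$mean_variants - slope * (a + b) / 2
  rate <- pmax(intercept + slope * len, 0)
  data.frame(gene = sprintf("PG%03d", seq_len(config$n_panel_genes)),
             length = round(len),
             n_variants = stats::rpois(config$n_panel_genes, rate))
}

#' Generate BED-like gene models for a synthetic panel
#'
#' Lays `n_panel_genes` genes head to tail on one synthetic chromosome per
#' ten genes, each with a 5'-UTR, 2--5 CDS exons separated by introns, and a
#' 3'-UTR inside its span.
#'
#' @param config a [sim_config()].
#' @return A validated `gene_models` data.frame (0-based half-open).
#' @export
gen_gene_models <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(.stream_seed(config$seed, 5L))
  rows <- list()
  cursor <- 10000L; chrom_i <- 1L
  for (i in seq_len(config$n_panel_genes)) {
    if (i %% 10L == 1L && i > 1L) { chrom_i <- chrom_i + 1L; cursor <- 10000L }
    L <- round(stats::runif(1, config$length_range[1], config$length_range[2]))
    L <- max(L, 600L)
    start <- cursor
    end <- start + L
    gene <- sprintf("PG%03d", i)
    chrom <- sprintf("chrS%d", chrom_i)
    u5 <- max(50L, round(0.05 * L)); u3 <- max(80L, round(0.12 * L))
    n_ex <- sample(2:5, 1L)
    cds_span <- c(start + u5, end - u3)
    cuts <- sort(round(stats::runif(2L * n_ex - 2L, cds_span[1], cds_span[2])))
    bounds <- unique(c(cds_span[1], cuts, cds_span[2]))
    # alternate exon/intron blocks; guarantee at least one exon
    blocks <- cbind(bounds[-length(bounds)], bounds[-1])
    blocks <- blocks[blocks[, 2] > blocks[, 1], , drop = FALSE]
    ex_idx <- seq(1L, nrow(blocks), by = 2L)
    rows[[length(rows) + 1L]] <- data.frame(
      gene = gene, chrom = chrom, strand = "+",
      feature = c("span", "utr5", rep("cds", length(ex_idx)), "utr3"),
      start = c(start, start, blocks[ex_idx, 1], end - u3),
      end = c(end, start + u5, blocks[ex_idx, 2], end),
      stringsAsFactors = FALSE)
    cursor <- end + sample(200:2000, 1L)
  }
  validate_gene_models(do.call(rbind, rows))
}

#' Generate located variants with genotypes for a synthetic panel
#'
#' Places variants uniformly across the padded spans of the gene models
#' (larger genes collect proportionally more variants) and attaches genotype
#' count trios from [gen_genotypes()].
#'
#' @param config a [sim_config()].
#' @param models a `gene_models` table, default [gen_gene_models()].
#' @return data.frame `chrom`, `pos` (1-based), `ref`, `alt`, `n_ref_hom`,
#'   `n_het`, `n_alt_hom`.
#' @export
gen_variants <- function(config = sim_config(), models = gen_gene_models(config)) {
  geno <- gen_genotypes(config)
  set.seed(.stream_seed(config$seed, 6L))
  spans <- models[models$feature == "span", , drop = FALSE]
  pad <- 25L
  w <- spans$end - spans$start + 2L * pad
  pick <- sample.int(nrow(spans), config$n_variants, replace = TRUE,
                     prob = w)
  pos0 <- spans$start[pick] - pad +
    floor(stats::runif(config$n_variants) * w[pick])
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, config$n_variants, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "")
  df <- data.frame(chrom = spans$chrom[pick], pos = pos0 + 1L,
                   ref = ref, alt = alt, geno, stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$pos), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write variant genotype counts as a VCF
#'
#' Expands genotype count trios into per-sample GT columns and writes a
#' minimal VCF 4.2 file that [read_variant_genotypes()] round-trips.
#'
#' @param variants data.frame with `chrom`, `pos`, `ref`, `alt`,
#'   `n_ref_hom`, `n_het`, `n_alt_hom` (all rows must total the same number
#'   of subjects).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_variant_vcf <- function(variants, path) {
  n <- unique(variants$n_ref_hom + variants$n_het + variants$n_alt_hom)
  if (length(n) != 1L) stop("rows disagree on the number of subjects")
  samples <- sprintf("S%03d", seq_len(n))
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  body <- vapply(seq_len(nrow(variants)), function(i) {
    v <- variants[i, ]
    gt <- c(rep("0/0", v$n_ref_hom), rep("0/1", v$n_het),
            rep("1/1", v$n_alt_hom))
    paste(c(v$chrom, v$pos, ".", v$ref, v$alt, ".", "PASS", ".", "GT", gt),
          collapse = "\t")
  }, "")
  writeLines(c(header, body), path)
  invisible(path)
}
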