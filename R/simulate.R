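# run code under a fixed seed without disturbing the caller's RNG stream,
# so generators are pure functions of (spec, seed)
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulation specification
#'
#' Parameters for the synthetic-data generators. Defaults emulate the
#' structure of the whole-brain single-cell atlas the co-expression
#' analysis runs on — 265 metacell groups with tens of cells
#' each, negative-binomial UMI counts with log-normal library sizes — plus
#' the four-region replicate FPKM design of hippocampal subfield studies
#' and a four-cell-type mRNA/protein comparison.
#'
#' @param seed integer seed; every generator output is a pure function of
#'   the spec including this seed.
#' @param n_genes number of simulated genes.
#' @param n_groups number of metacell groups (default 265).
#' @param cells_per_group cells per group (default 60).
#' @param libsize_meanlog,libsize_sdlog log-normal library-size parameters
#'   (defaults `log(4000)`, 0.3).
#' @param mean_range range of per-gene base relative expression, sampled
#'   log-uniformly (default 0.05 to 20).
#' @param size_range range of per-gene negative-binomial size
#'   (1/dispersion) parameters (default 0.5 to 2, i.e. substantial
#'   overdispersion).
#' @param sigma_background log-sd of independent per-gene, per-group
#'   biological variation (default 0.3).
#' @param sigma_module log-sd of the shared group-level variation of
#'   planted module genes (default 0.8, so module signal dominates
#'   sampling noise in group averages).
#' @param modules list of planted co-expression modules, each
#'   `list(genes = <symbols>, rho = <target Spearman>)` with
#'   `|rho| < 1`.
#' @param gene_names optional gene symbols (default `Gene0001`, ...).
#' @param universe_size annotation universe size (default 15000).
#' @param baseline_rate baseline annotation flag probability (default 0.2).
#' @param enriched_genes genes of the planted enriched set (default: drawn
#'   at generation time, size `enriched_size`).
#' @param enriched_size size of the planted enriched set (default 900).
#' @param odds_ratio planted annotation odds ratio (default 3).
#' @param regions region labels of the replicate design (default the four
#'   dorsal hippocampal subfields).
#' @param n_replicates replicates per region (default 3).
#' @param marker_fold planted regional fold change (default 3).
#' @param marker_frac fraction of genes planted as markers of each region
#'   (default 0.05).
#' @param fpkm_meanlog,fpkm_sdlog log-normal base FPKM parameters
#'   (defaults `log(15)`, 0.8).
#' @param noise_sdlog log-sd of replicate noise in the FPKM design
#'   (default 0.25).
#' @param concordance_r target mRNA-protein concordance (default 0.63).
#' @param conc_genes,conc_celltypes size of the mRNA/protein comparison
#'   (defaults 150 genes, 4 cell types).
#' @return A `SimulationSpec` list.
#' @export
simulation_spec <- function(seed = 1L,
                            n_genes = 120L,
                            n_groups = 265L,
                            cells_per_group = 60L,
                            libsize_meanlog = log(4000),
                            libsize_sdlog = 0.3,
                            mean_range = c(0.05, 20),
                            size_range = c(0.5, 2),
                            sigma_background = 0.3,
                            sigma_module = 1.2,
                            modules = list(),
                            gene_names = NULL,
                            universe_size = 15000L,
                            baseline_rate = 0.2,
                            enriched_genes = NULL,
                            enriched_size = 900L,
                            odds_ratio = 3,
                            regions = c("dDG", "dCA3", "dCA2", "dCA1"),
                            n_replicates = 3L,
                            marker_fold = 3,
                            marker_frac = 0.05,
                            fpkm_meanlog = log(15),
                            fpkm_sdlog = 0.8,
                            noise_sdlog = 0.25,
                            concordance_r = 0.63,
                            conc_genes = 150L,
                            conc_celltypes = 4L) {
  if (is.null(gene_names)) {
    gene_names <- sprintf("Gene%04d", seq_len(n_genes))
  }
  stopifnot(length(gene_names) == n_genes)
  for (mod in modules) {
    if (abs(mod$rho) >= 1) {
      stop("infeasible module target: |rho| must be < 1", call. = FALSE)
    }
    if (!all(mod$genes %in% gene_names)) {
      stop("module genes must be among the simulated gene names",
           call. = FALSE)
    }
  }
  stopifnot(baseline_rate >= 0, baseline_rate < 1, odds_ratio > 0,
            marker_fold > 0, abs(concordance_r) < 1)
  structure(as.list(environment()), class = "SimulationSpec")
}

#' Simulate a single-cell count matrix with planted co-expression modules
#'
#' Cells are assigned to metacell groups; each gene has a base relative
#' expression and a per-group biological level (log-normal around the
#' base). Genes of a planted module share a Gaussian copula across groups:
#' their latent group levels are equicorrelated normals with Pearson
#' correlation `2*sin(pi*rho/6)`, the value for which the Spearman
#' correlation of the (monotone) log-normal group levels equals the target
#' `rho`. Counts are negative binomial with library-size-scaled means, so
#' the planted correlation survives the full
#' normalize-aggregate-correlate pipeline at the default group sizes.
#'
#' @param spec a [simulation_spec()].
#' @return list with `counts` (a [count_matrix()]) and `meta` (a
#'   [cell_meta()] with columns `cell`, `metacell`, `region`); the
#'   group-level mean matrix is attached as attribute `"group_means"`.
#' @export
simulate_counts <- function(spec) {
  stopifnot(inherits(spec, "SimulationSpec"))
  .with_seed(spec$seed, {
    G <- spec$n_groups
    n_cells <- G * spec$cells_per_group
    grp <- rep(seq_len(G), each = spec$cells_per_group)
    group_names <- sprintf("mc%03d", seq_len(G))
    cells <- sprintf("cell%05d", seq_len(n_cells))

    mu <- exp(stats::runif(spec$n_genes, log(spec$mean_range[1]),
                           log(spec$mean_range[2])))
    size_g <- stats::runif(spec$n_genes, spec$size_range[1],
                           spec$size_range[2])

    # group-level biological levels: independent background jitter
    M <- mu * exp(matrix(stats::rnorm(spec$n_genes * G,
                                      sd = spec$sigma_background),
                         spec$n_genes, G))
    # planted modules: equicorrelated Gaussian copula on the group levels
    for (mod in spec$modules) {
      idx <- match(mod$genes, spec$gene_names)
      m <- length(idx)
      r_lat <- 2 * sin(pi * mod$rho / 6)
      Sigma <- matrix(r_lat, m, m)
      diag(Sigma) <- 1
      Z <- matrix(stats::rnorm(G * m), G, m) %*% chol(Sigma)
      M[idx, ] <- mu[idx] * exp(spec$sigma_module * t(Z))
    }

    P <- sweep(M, 2, colSums(M), "/")
    lib <- stats::rlnorm(n_cells, spec$libsize_meanlog, spec$libsize_sdlog)
    MU <- sweep(P[, grp, drop = FALSE], 2, lib, "*")
    counts <- matrix(
      stats::rnbinom(length(MU), mu = as.numeric(MU), size = size_g),
      nrow = spec$n_genes)

    cm <- count_matrix(counts, spec$gene_names, cells, unit = "counts")
    meta <- cell_meta(data.frame(
      cell = cells,
      metacell = group_names[grp],
      region = sprintf("region%02d", (grp - 1L) %/% 27L + 1L),
      stringsAsFactors = FALSE))
    attr(cm, "group_means") <- M
    list(counts = cm, meta = meta)
  })
}

#' Simulate an annotation table with a planted odds ratio
#'
#' Every universe gene is flagged Bernoulli(`baseline_rate`); genes of the
#' enriched set are flagged with the probability `p'` solving
#' `p'/(1-p') = odds_ratio * baseline/(1-baseline)`, so the planted
#' enrichment has exactly the requested odds ratio in expectation.
#'
#' @param spec a [simulation_spec()].
#' @param flag name of the generated flag set (default `"substrate"`).
#' @return An [annotation_table()]; the enriched gene set is attached as
#'   attribute `"enriched_genes"`.
#' @export
simulate_annotation <- function(spec, flag = "substrate") {
  stopifnot(inherits(spec, "SimulationSpec"))
  .with_seed(spec$seed + 1L, {
    universe <- sprintf("Ugene%05d", seq_len(spec$universe_size))
    enriched <- spec$enriched_genes
    if (is.null(enriched)) {
      enriched <- sample(universe, spec$enriched_size)
    }
    if (!all(enriched %in% universe)) {
      stop("enriched set must be a subset of the universe", call. = FALSE)
    }
    b <- spec$baseline_rate
    if (b == 0) {
      if (spec$odds_ratio > 1) {
        stop("cannot plant an odds ratio > 1 against a zero baseline",
             call. = FALSE)
      }
      p_enr <- 0
    } else {
      odds <- spec$odds_ratio * b / (1 - b)
      p_enr <- odds / (1 + odds)
    }
    p <- ifelse(universe %in% enriched, p_enr, b)
    flagged <- universe[stats::runif(length(universe)) < p]
    tab <- annotation_table(universe, stats::setNames(list(flagged), flag))
    attr(tab, "enriched_genes") <- enriched
    tab
  })
}

#' Simulate a replicate FPKM matrix with planted regional markers
#'
#' Non-marker genes share a base mean across all regions; each region gets
#' a planted marker set whose mean in that region is `marker_fold` times
#' the base. Replicates add multiplicative log-normal noise
#' (`noise_sdlog`).
#'
#' @param spec a [simulation_spec()].
#' @return A [replicate_matrix()]; the planted markers are attached as
#'   attribute `"markers"` (named list, region -> gene symbols).
#' @export
simulate_replicate_fpkm <- function(spec) {
  stopifnot(inherits(spec, "SimulationSpec"))
  stopifnot(length(spec$regions) >= 2, spec$n_replicates >= 2)
  .with_seed(spec$seed + 2L, {
    genes <- sprintf("Fgene%04d", seq_len(spec$n_genes))
    base <- stats::rlnorm(spec$n_genes, spec$fpkm_meanlog, spec$fpkm_sdlog)
    n_mark <- max(1L, round(spec$marker_frac * spec$n_genes))
    pool <- sample(genes, n_mark * length(spec$regions))
    markers <- split(pool, rep(spec$regions, each = n_mark))[spec$regions]

    region_means <- matrix(base, spec$n_genes, length(spec$regions),
                           dimnames = list(genes, spec$regions))
    for (r in spec$regions) {
      region_means[markers[[r]], r] <-
        region_means[markers[[r]], r] * spec$marker_fold
    }
    regions <- rep(spec$regions, each = spec$n_replicates)
    vals <- region_means[, regions, drop = FALSE] *
      exp(matrix(stats::rnorm(spec$n_genes * length(regions),
                              sd = spec$noise_sdlog),
                 spec$n_genes, length(regions)))
    m <- replicate_matrix(vals, genes, regions,
                          rep(seq_len(spec$n_replicates),
                              times = length(spec$regions)))
    attr(m, "markers") <- markers
    m
  })
}

# latent correlation whose per-gene sample z-scoring over n cell types
# yields the target measured concordance in expectation; solves the
# small-sample attenuation E[r] ~ rho * (1 - (1 - rho^2) / (2 * (n - 1)))
.calibrate_latent_r <- function(target, n_celltypes) {
  if (target == 0) return(0)
  f <- function(rho) rho * (1 - (1 - rho^2) / (2 * (n_celltypes - 1))) -
    abs(target)
  sign(target) * stats::uniroot(f, c(0, 0.9999), tol = 1e-10)$root
}

#' Simulate paired mRNA and protein abundance tables
#'
#' Draws a latent bivariate-normal z-structure per (gene, cell type) pair
#' with correlation calibrated so that the concordance measured by the
#' pipeline — per-gene sample z-scoring across the (few) cell types,
#' then pooled Pearson correlation — equals the target in expectation,
#' and back-transforms each modality to positive abundances by a per-gene
#' increasing affine map (which the z-scoring inverts exactly).
#'
#' @param spec a [simulation_spec()].
#' @return list of two gene x cell-type abundance matrices, `mrna` and
#'   `protein`, with common rownames/colnames.
#' @export
simulate_mrna_protein <- function(spec) {
  stopifnot(inherits(spec, "SimulationSpec"))
  .with_seed(spec$seed + 3L, {
    ng <- spec$conc_genes
    nc <- spec$conc_celltypes
    genes <- sprintf("Pgene%04d", seq_len(ng))
    cts <- if (nc == 4) c("astrocyte", "microglia", "neuron",
                          "oligodendrocyte")
           else sprintf("celltype%02d", seq_len(nc))
    rho <- .calibrate_latent_r(spec$concordance_r, nc)
    zm <- matrix(stats::rnorm(ng * nc), ng, nc)
    zp <- rho * zm + sqrt(1 - rho^2) * matrix(stats::rnorm(ng * nc), ng, nc)

    to_abund <- function(z, meanlog) {
      a <- stats::rlnorm(ng, meanlog, 0.5)
      out <- a + (a / 5) * z
      pmax(out, a * 0.01)  # guard against astronomically rare |z| > 5
    }
    mrna <- to_abund(zm, log(100))
    protein <- to_abund(zp, log(1000))
    dimnames(mrna) <- dimnames(protein) <- list(genes, cts)
    list(mrna = mrna, protein = protein)
  })
}
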