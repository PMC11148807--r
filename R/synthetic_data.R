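#' Configuration for the droplet simulator
#'
#' Describes a mixture of droplet populations as seen in single-nuclei
#' preparations of solid tissue: intact nuclei of one or more cell types
#' (mostly unspliced transcripts, strong nuclear-gene signal, low
#' mitochondrial content), empty droplets carrying cytoplasmic ambient RNA
#' (high spliced fraction, weak nuclear signal, elevated mitochondrial
#' fraction) and contaminated nuclei (a nucleus plus a large ambient
#' admixture). Classes whose name starts with `"nucleus_"` are cell types;
#' `"empty"` and `"contaminated"` are recognised contamination classes.
#'
#' @param n_droplets Number of droplets.
#' @param class_fractions Named fractions over droplet classes; must sum to 1.
#' @param n_genes,n_mito_genes,n_nuclear_genes,markers_per_type Gene-panel
#'   layout: the first `n_mito_genes` genes are mitochondrial, the next
#'   `n_nuclear_genes` nuclear-enriched, then `markers_per_type` markers per
#'   nucleus cell type, the rest background.
#' @param spliced_fraction_params Per-class `c(alpha, beta)` of the Beta
#'   distribution the droplet-level spliced fraction is drawn from.
#' @param depth_params Per-class `c(mean, dispersion)` of the negative
#'   binomial total-count distribution (dispersion is the NB size).
#' @param profile_fractions Per-class `c(mito, nuclear)` target shares of the
#'   expression profile allotted to the mitochondrial and nuclear blocks.
#' @param marker_share Share of a nucleus profile on its own marker block.
#' @param ambient_profile_weights Named weights of the nucleus cell types in
#'   the ambient pool; defaults to the nucleus class fractions.
#' @param contamination_mix Ambient fraction mixed into contaminated nuclei.
#' @param seed Integer seed.
#' @return A validated `droplet_sim_config` list.
#' @export
droplet_sim_config <- function(n_droplets = 2000,
                               class_fractions = c(nucleus_CM = 0.35,
                                                   nucleus_FB = 0.15,
                                                   nucleus_EC = 0.10,
                                                   empty = 0.30,
                                                   contaminated = 0.10),
                               n_genes = 500,
                               n_mito_genes = 13,
                               n_nuclear_genes = 40,
                               markers_per_type = 25,
                               spliced_fraction_params = NULL,
                               depth_params = NULL,
                               profile_fractions = NULL,
                               marker_share = 0.25,
                               ambient_profile_weights = NULL,
                               contamination_mix = 0.5,
                               seed = 1L) {
  if (is.null(names(class_fractions)) || any(!nzchar(names(class_fractions)))) {
    stop("class_fractions must be named")
  }
  if (abs(sum(class_fractions) - 1) > 1e-9) {
    stop("class fractions must sum to 1 (within 1e-9)")
  }
  if (any(class_fractions < 0)) stop("class fractions must be non-negative")
  classes <- names(class_fractions)
  types <- classes[startsWith(classes, "nucleus_")]
  if (length(types) == 0L) stop("at least one nucleus_<celltype> class is required")
  counts <- c(n_droplets = n_droplets, n_genes = n_genes,
              n_mito_genes = n_mito_genes, n_nuclear_genes = n_nuclear_genes,
              markers_per_type = markers_per_type)
  if (any(counts[-1] <= 0)) stop("gene-panel counts must be strictly positive")
  if (n_mito_genes + n_nuclear_genes + length(types) * markers_per_type > n_genes) {
    stop("gene panel blocks exceed n_genes")
  }

  default_spliced <- function(cl) {
    if (cl == "empty") c(27, 3)               # mean 0.90: cytoplasmic ambient RNA
    else if (cl == "contaminated") c(12, 8)   # mean 0.60
    else c(6, 18)                             # mean 0.25: nuclear transcripts
  }
  if (is.null(spliced_fraction_params)) {
    spliced_fraction_params <- lapply(stats::setNames(classes, classes), default_spliced)
  }
  default_depth <- function(cl) {
    if (cl == "empty") c(800, 1)
    else if (cl == "contaminated") c(2500, 2)
    else c(3000, 2)
  }
  if (is.null(depth_params)) {
    depth_params <- lapply(stats::setNames(classes, classes), default_depth)
  }
  default_profile <- function(cl) {
    if (cl == "empty") c(mito = 0.25, nuclear = 0.04)
    else if (cl == "contaminated") c(mito = 0.35, nuclear = 0.12)
    else c(mito = 0.02, nuclear = 0.30)
  }
  if (is.null(profile_fractions)) {
    profile_fractions <- lapply(stats::setNames(classes, classes), default_profile)
  }
  for (cl in classes) {
    sp <- spliced_fraction_params[[cl]]
    dp <- depth_params[[cl]]
    if (is.null(sp) || any(sp <= 0)) stop("Beta parameters must be strictly positive (class ", cl, ")")
    if (is.null(dp) || any(dp <= 0)) stop("NB mean and dispersion must be strictly positive (class ", cl, ")")
  }
  if (is.null(ambient_profile_weights)) {
    w <- class_fractions[types]
    if (sum(w) == 0) w <- stats::setNames(rep(1, length(types)), types)
    ambient_profile_weights <- w / sum(w)
  }
  structure(list(
    n_droplets = as.integer(n_droplets),
    class_fractions = class_fractions,
    n_genes = as.integer(n_genes),
    n_mito_genes = as.integer(n_mito_genes),
    n_nuclear_genes = as.integer(n_nuclear_genes),
    markers_per_type = as.integer(markers_per_type),
    spliced_fraction_params = spliced_fraction_params,
    depth_params = depth_params,
    profile_fractions = profile_fractions,
    marker_share = marker_share,
    ambient_profile_weights = ambient_profile_weights,
    contamination_mix = contamination_mix,
    seed = as.integer(seed),
    cell_types = types
  ), class = "droplet_sim_config")
}

# gene panel layout shared by profiles and the exported gene sets
droplet_gene_layout <- function(cfg) {
  types <- cfg$cell_types
  gene <- character(cfg$n_genes)
  block <- character(cfg$n_genes)
  i <- 1L
  mito_idx <- seq_len(cfg$n_mito_genes)
  gene[mito_idx] <- sprintf("MT-%02d", mito_idx)
  block[mito_idx] <- "mito"
  i <- cfg$n_mito_genes
  nuc_idx <- i + seq_len(cfg$n_nuclear_genes)
  gene[nuc_idx] <- sprintf("NUC-%03d", seq_along(nuc_idx))
  block[nuc_idx] <- "nuclear"
  i <- i + cfg$n_nuclear_genes
  for (tp in types) {
    idx <- i + seq_len(cfg$markers_per_type)
    short <- sub("^nucleus_", "", tp)
    gene[idx] <- sprintf("MK%s-%02d", short, seq_along(idx))
    block[idx] <- paste0("marker_", short)
    i <- i + cfg$markers_per_type
  }
  if (i < cfg$n_genes) {
    idx <- (i + 1L):cfg$n_genes
    gene[idx] <- sprintf("BG-%03d", seq_along(idx))
    block[idx] <- "background"
  }
  data.frame(gene = gene, block = block, stringsAsFactors = FALSE)
}

# rescale mito/nuclear blocks of a profile to target shares, keeping the
# relative composition of the remainder
reweight_blocks <- function(p, layout, mito, nuclear) {
  is_mito <- layout$block == "mito"
  is_nuc <- layout$block == "nuclear"
  rest <- !(is_mito | is_nuc)
  out <- numeric(length(p))
  out[is_mito] <- mito * p[is_mito] / sum(p[is_mito])
  out[is_nuc] <- nuclear * p[is_nuc] / sum(p[is_nuc])
  out[rest] <- (1 - mito - nuclear) * p[rest] / sum(p[rest])
  out
}

# per-class multinomial gene profiles
droplet_class_profiles <- function(cfg, layout) {
  types <- cfg$cell_types
  n <- cfg$n_genes
  base <- lapply(stats::setNames(types, types), function(tp) {
    pf <- cfg$profile_fractions[[tp]]
    short <- sub("^nucleus_", "", tp)
    own <- layout$block == paste0("marker_", short)
    is_mito <- layout$block == "mito"
    is_nuc <- layout$block == "nuclear"
    rest <- !(own | is_mito | is_nuc)
    p <- numeric(n)
    p[is_mito] <- pf[["mito"]] / sum(is_mito)
    p[is_nuc] <- pf[["nuclear"]] / sum(is_nuc)
    p[own] <- cfg$marker_share / sum(own)
    p[rest] <- (1 - pf[["mito"]] - pf[["nuclear"]] - cfg$marker_share) / sum(rest)
    p
  })
  ambient_raw <- Reduce(`+`, Map(`*`, base, as.list(cfg$ambient_profile_weights[types])))
  profiles <- base
  if ("empty" %in% names(cfg$class_fractions)) {
    pf <- cfg$profile_fractions[["empty"]]
    profiles[["empty"]] <- reweight_blocks(ambient_raw, layout, pf[["mito"]], pf[["nuclear"]])
  }
  if ("contaminated" %in% names(cfg$class_fractions)) {
    pf <- cfg$profile_fractions[["contaminated"]]
    profiles[["contaminated_by_type"]] <- lapply(base, function(p) {
      mixed <- (1 - cfg$contamination_mix) * p + cfg$contamination_mix * ambient_raw
      reweight_blocks(mixed, layout, pf[["mito"]], pf[["nuclear"]])
    })
  }
  profiles
}

#' Simulate a droplet dataset with spliced/unspliced layers
#'
#' Per droplet the total count is drawn from the class negative binomial,
#' gene counts are multinomial over the class profile (empty droplets use the
#' ambient profile, an abundance-weighted mixture of the cell-type profiles
#' reweighted toward mitochondrial and away from nuclear genes), and each
#' gene's count is split into spliced/unspliced by a droplet-level Beta draw
#' from the class's spliced-fraction parameters.
#'
#' @param cfg A [droplet_sim_config()].
#' @return A `droplet_dataset` list: `spliced` and `unspliced` cells x genes
#'   `dgCMatrix` layers, `gene_meta` (gene, block), `truth` (per-droplet
#'   `droplet_class` and underlying `celltype`), `gene_sets` (mito, nuclear
#'   and per-type marker sets, ready for [compute_qc_metrics()]) and the
#'   config.
#' @export
generate_droplet_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "droplet_sim_config"))
  if (cfg$n_droplets == 0L) stop("n_droplets = 0: nothing to generate")
  layout <- droplet_gene_layout(cfg)
  profiles <- droplet_class_profiles(cfg, layout)
  classes <- names(cfg$class_fractions)
  with_seed(cfg$seed, {
    droplet_class <- sample(classes, cfg$n_droplets, replace = TRUE,
                            prob = cfg$class_fractions)
    celltype <- rep(NA_character_, cfg$n_droplets)
    is_nuc <- startsWith(droplet_class, "nucleus_")
    celltype[is_nuc] <- droplet_class[is_nuc]
    contaminated <- droplet_class == "contaminated"
    if (any(contaminated)) {
      celltype[contaminated] <- sample(cfg$cell_types, sum(contaminated),
                                       replace = TRUE,
                                       prob = cfg$ambient_profile_weights[cfg$cell_types])
    }
    depth <- integer(cfg$n_droplets)
    for (cl in classes) {
      idx <- which(droplet_class == cl)
      if (length(idx) == 0L) next
      dp <- cfg$depth_params[[cl]]
      depth[idx] <- pmax(1L, stats::rnbinom(length(idx), size = dp[2L], mu = dp[1L]))
    }
    spliced_frac <- numeric(cfg$n_droplets)
    for (cl in classes) {
      idx <- which(droplet_class == cl)
      if (length(idx) == 0L) next
      sp <- cfg$spliced_fraction_params[[cl]]
      spliced_frac[idx] <- stats::rbeta(length(idx), sp[1L], sp[2L])
    }
    total <- matrix(0L, cfg$n_droplets, cfg$n_genes)
    spliced <- matrix(0L, cfg$n_droplets, cfg$n_genes)
    for (d in seq_len(cfg$n_droplets)) {
      cl <- droplet_class[d]
      p <- if (cl == "contaminated") {
        profiles$contaminated_by_type[[celltype[d]]]
      } else if (cl == "empty") {
        profiles$empty
      } else {
        profiles[[cl]]
      }
      cnt <- as.integer(stats::rmultinom(1L, depth[d], p))
      total[d, ] <- cnt
      spliced[d, ] <- stats::rbinom(cfg$n_genes, cnt, spliced_frac[d])
    }
    barcodes <- sprintf("BC%05d", seq_len(cfg$n_droplets))
    dimnames(total) <- list(barcodes, layout$gene)
    dimnames(spliced) <- list(barcodes, layout$gene)
    unspliced <- total - spliced
    marker_sets <- split(layout$gene[startsWith(layout$block, "marker_")],
                         sub("^marker_", "", layout$block[startsWith(layout$block, "marker_")]))
    gene_sets <- c(
      list(mito = layout$gene[layout$block == "mito"],
           nuclear = layout$gene[layout$block == "nuclear"]),
      marker_sets
    )
    structure(list(
      spliced = methods::as(Matrix::Matrix(spliced, sparse = TRUE), "CsparseMatrix"),
      unspliced = methods::as(Matrix::Matrix(unspliced, sparse = TRUE), "CsparseMatrix"),
      gene_meta = layout,
      truth = list(droplet_class = droplet_class, celltype = celltype,
                   spliced_fraction = spliced_frac),
      gene_sets = gene_sets,
      config = cfg
    ), class = "droplet_dataset")
  })
}

#' Configuration for the planted-module expression simulator
#'
#' @param n_cells,n_genes Matrix dimensions.
#' @param module_sizes Integer sizes of the planted modules; their sum must
#'   not exceed `n_genes`.
#' @param loading Factor loading in (0, 1), recycled per module. Two genes of
#'   the same module have population correlation `loading^2` in gaussian mode.
#' @param mode `"gaussian"` (latent values returned directly) or `"counts"`
#'   (values mapped through `exp()` then Poisson-sampled and thinned).
#' @param sparsity_target Fraction of zeros targeted in counts mode (in
#'   expectation, via Bernoulli dropout). Default 0.5, the typical zero share
#'   of genes that survive rare-gene filtering in single-nuclei data.
#' @param log_mean Baseline log intensity in counts mode: the Poisson rate is
#'   `exp(log_mean + value)`. Default 1, putting the average retained gene at
#'   roughly 4-5 counts per cell.
#' @param seed Integer seed.
#' @return A validated `module_sim_config` list.
#' @export
module_sim_config <- function(n_cells = 5000, n_genes = 200,
                              module_sizes = rep(20L, 4L),
                              loading = 0.8,
                              mode = c("counts", "gaussian"),
                              sparsity_target = 0.5,
                              log_mean = 1,
                              seed = 1L) {
  mode <- match.arg(mode)
  if (sum(module_sizes) > n_genes) stop("sum of module_sizes exceeds n_genes")
  if (any(loading <= 0 | loading >= 1)) stop("loadings must lie in (0, 1)")
  if (sparsity_target < 0 || sparsity_target >= 1) stop("sparsity_target must lie in [0, 1)")
  loading <- rep_len(loading, length(module_sizes))
  structure(list(n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
                 module_sizes = as.integer(module_sizes), loading = loading,
                 mode = mode, sparsity_target = sparsity_target,
                 log_mean = log_mean, seed = as.integer(seed)),
            class = "module_sim_config")
}

#' Simulate an expression matrix with planted co-expressed gene modules
#'
#' Latent-factor model: each module `m` has a per-cell factor
#' `f_m ~ N(0, 1)`; a gene of module `m` takes the value
#' `loading * f_m + sqrt(1 - loading^2) * eps` with `eps ~ N(0, 1)`, and
#' background genes are pure noise. In counts mode the latent values are
#' mapped through `exp()`, Poisson-sampled and thinned by entry-wise
#' Bernoulli dropout to reach the sparsity target in expectation.
#'
#' @param cfg A [module_sim_config()].
#' @return List with `matrix` (cells x genes; counts in counts mode), `truth`
#'   (`module_of_gene`, `NA` for background; plus the per-cell factors) and
#'   the config.
#' @export
generate_module_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "module_sim_config"))
  with_seed(cfg$seed, {
    n_mod <- length(cfg$module_sizes)
    module_of_gene <- rep(NA_integer_, cfg$n_genes)
    if (n_mod > 0L && sum(cfg$module_sizes) > 0L) {
      module_of_gene[seq_len(sum(cfg$module_sizes))] <-
        rep(seq_len(n_mod), cfg$module_sizes)
    }
    factors <- matrix(stats::rnorm(cfg$n_cells * max(n_mod, 1L)),
                      cfg$n_cells, max(n_mod, 1L))
    values <- matrix(stats::rnorm(cfg$n_cells * cfg$n_genes),
                     cfg$n_cells, cfg$n_genes)
    for (m in seq_len(n_mod)) {
      idx <- which(module_of_gene == m)
      l <- cfg$loading[m]
      values[, idx] <- l * factors[, m] + sqrt(1 - l^2) * values[, idx]
    }
    genes <- sprintf("G%04d", seq_len(cfg$n_genes))
    cells <- sprintf("C%05d", seq_len(cfg$n_cells))
    dimnames(values) <- list(cells, genes)
    if (cfg$mode == "counts") {
      counts <- matrix(stats::rpois(length(values), exp(cfg$log_mean + values)),
                       nrow(values), ncol(values), dimnames = dimnames(values))
      z0 <- mean(counts == 0)
      if (cfg$sparsity_target > z0) {
        # entry-wise dropout raises the zero fraction to the target in
        # expectation while leaving surviving counts untouched
        d <- (cfg$sparsity_target - z0) / (1 - z0)
        drop <- matrix(stats::runif(length(counts)) < d, nrow(counts))
        counts[drop] <- 0L
      }
      values <- counts
    }
    list(matrix = values,
         truth = list(module_of_gene = module_of_gene, factors = factors),
         config = cfg)
  })
}

#' Simulate a single-molecule spatial table with expression domains
#'
#' Molecules are placed uniformly within their domain (a disc or an
#' axis-aligned rectangle) and carry a gene drawn from the domain's profile,
#' emulating spatially segregated expression territories on a slide.
#'
#' @param width,height Slide extent in pixels; the slide spans
#'   `[0, width] x [0, height]`.
#' @param domains List of domains. A disc is
#'   `list(type = "disc", center = c(x, y), radius = r, profile = c(GENE = w, ...))`;
#'   a rectangle is `list(type = "rect", xlim = c(a, b), ylim = c(c, d),
#'   profile = ...)`. Optional `weight` sets the domain's share of molecules
#'   (default equal).
#' @param n_molecules Number of molecules.
#' @param seed Integer seed.
#' @param section Section label stamped on every molecule.
#' @return List with `molecules` (data frame `x`, `y`, `gene`, `section`) and
#'   `truth` (`domain_of_molecule`).
#' @export
generate_molecule_table <- function(width, height, domains, n_molecules,
                                    seed = 1L, section = "S1") {
  if (length(domains) == 0L) stop("at least one domain is required")
  for (d in domains) {
    if (is.null(d$profile) || length(d$profile) == 0L) stop("every domain needs a gene profile")
    if (identical(d$type, "disc")) {
      if (d$center[1] - d$radius < 0 || d$center[1] + d$radius > width ||
          d$center[2] - d$radius < 0 || d$center[2] + d$radius > height) {
        stop("disc domain extends beyond the slide")
      }
    } else if (identical(d$type, "rect")) {
      if (d$xlim[1] < 0 || d$xlim[2] > width || d$ylim[1] < 0 || d$ylim[2] > height) {
        stop("rect domain extends beyond the slide")
      }
    } else {
      stop("domain type must be 'disc' or 'rect'")
    }
  }
  weights <- vapply(domains, function(d) if (is.null(d$weight)) 1 else d$weight, 1.0)
  with_seed(seed, {
    if (n_molecules == 0L) {
      molecules <- data.frame(x = numeric(0), y = numeric(0),
                              gene = character(0), section = character(0),
                              stringsAsFactors = FALSE)
      return(list(molecules = molecules, truth = list(domain_of_molecule = integer(0))))
    }
    dom <- sample(seq_along(domains), n_molecules, replace = TRUE,
                  prob = weights / sum(weights))
    x <- numeric(n_molecules)
    y <- numeric(n_molecules)
    gene <- character(n_molecules)
    for (i in seq_along(domains)) {
      idx <- which(dom == i)
      if (length(idx) == 0L) next
      d <- domains[[i]]
      if (identical(d$type, "disc")) {
        r <- d$radius * sqrt(stats::runif(length(idx)))
        th <- stats::runif(length(idx), 0, 2 * pi)
        x[idx] <- d$center[1] + r * cos(th)
        y[idx] <- d$center[2] + r * sin(th)
      } else {
        x[idx] <- stats::runif(length(idx), d$xlim[1], d$xlim[2])
        y[idx] <- stats::runif(length(idx), d$ylim[1], d$ylim[2])
      }
      gene[idx] <- sample(names(d$profile), length(idx), replace = TRUE,
                          prob = d$profile / sum(d$profile))
    }
    molecules <- data.frame(x = x, y = y, gene = gene, section = section,
                            stringsAsFactors = FALSE)
    list(molecules = molecules, truth = list(domain_of_molecule = dom))
  })
}

#' Simulate a pair of differential-expression result tables
#'
#' Builds two DE tables whose significant-gene sets overlap by a requested
#' amount and whose shared-gene log fold changes are drawn from a bivariate
#' normal with a requested correlation — a fixture for Jaccard and
#' logFC-correlation comparisons.
#'
#' @param n_genes Universe size.
#' @param shared_fraction Fraction of each table's significant set that is
#'   shared with the other.
#' @param logfc_correlation Population correlation of shared-gene logFCs, in
#'   `[-1, 1]`.
#' @param seed Integer seed.
#' @param n_sig Significant genes per table (default 15% of the universe).
#' @return List with `table_a`, `table_b` (gene, logFC, pvalue, fdr,
#'   significant) and `expected_jaccard` computed exactly from the
#'   constructed sets.
#' @export
generate_de_comparison <- function(n_genes, shared_fraction, logfc_correlation,
                                   seed = 1L, n_sig = round(0.15 * n_genes)) {
  if (shared_fraction < 0 || shared_fraction > 1) stop("shared_fraction must lie in [0, 1]")
  if (abs(logfc_correlation) > 1) stop("logfc_correlation must lie in [-1, 1]")
  n_shared <- round(shared_fraction * n_sig)
  if (2 * n_sig - n_shared > n_genes) stop("significant sets do not fit in the universe")
  genes <- sprintf("G%05d", seq_len(n_genes))
  set_a <- genes[seq_len(n_sig)]
  set_b <- genes[c(seq_len(n_shared),
                   if (n_sig > n_shared) (n_sig + 1L):(2L * n_sig - n_shared))]
  expected_jaccard <- length(intersect(set_a, set_b)) / length(union(set_a, set_b))
  with_seed(seed, {
    rho <- logfc_correlation
    z1 <- stats::rnorm(n_shared)
    z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n_shared)
    make_table <- function(sig_set, shared_lfc) {
      sig <- genes %in% sig_set
      lfc <- stats::rnorm(n_genes, 0, 0.1)
      lfc[seq_len(n_shared)] <- shared_lfc
      own <- setdiff(sig_set, genes[seq_len(n_shared)])
      lfc[match(own, genes)] <- stats::rnorm(length(own))
      p <- stats::runif(n_genes, 0.2, 1)
      p[sig] <- stats::runif(sum(sig), 0, 1e-6)
      data.frame(gene = genes, logFC = lfc, pvalue = p,
                 fdr = stats::p.adjust(p, "BH"), significant = sig,
                 stringsAsFactors = FALSE)
    }
    list(table_a = make_table(set_a, z1),
         table_b = make_table(set_b, z2),
         expected_jaccard = expected_jaccard)
  })
}
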