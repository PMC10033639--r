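## Synthetic-data generators.
##
## Three seeded simulators emulate the data the analysis modules consume:
## a pooled knockout screen read out in two host genotypes, a multi-sample
## single-cell expression cohort with a planted focal-gene/gene-set
## coupling, and exponential survival arms. Ground truth is always
## returned next to the data so recovery can be tested; analysis code
## never reads it.

#' Configuration for the pooled-screen simulator
#'
#' Describes a pooled CRISPR knockout screen implanted into two host
#' genotype arms (\code{WT} and \code{CD8KO}) and sequenced at one or more
#' stages. The generative chain is: lognormal plasmid guide abundance, a
#' per-mouse multinomial implantation bottleneck of \code{cells_per_mouse}
#' cells, per-generation multiplicative selection \code{exp(s * t)} on
#' clone weights, and a single multinomial sequencing draw per sample at a
#' Poisson-drawn depth.
#'
#' @param seed Integer seed; fully determines the simulator output.
#' @param n_genes Number of targeted genes in the library.
#' @param guides_per_gene Guides per targeted gene (default 4, the usual
#'   knockout-library design).
#' @param n_ntc Number of non-targeting control guides (default 100).
#' @param cells_per_mouse Cells implanted per mouse (default 200000).
#' @param mice_per_arm Mice per genotype arm at each stage (default 6, so
#'   each genotype contributes about a dozen animals across the early and
#'   late stages).
#' @param stages Named numeric vector mapping stage label to the number of
#'   effective selection rounds elapsed at harvest; default
#'   \code{c(early = 2, late = 4)}, chosen so that a clone under strong
#'   selection (per-round log-fitness of order 1) is still measurable
#'   above the raw-count filter at realistic sequencing depth.
#' @param depth_per_sample Expected sequencing reads per sample. The
#'   default \code{NULL} resolves to \code{4000 *} the number of guides,
#'   i.e. about 4000x read coverage per guide.
#' @param plasmid_sigma Lognormal scale of the plasmid-library skew
#'   (default 0.5).
#' @param selection Named list mapping gene symbols to a length-2 numeric
#'   \code{c(s_WT, s_CD8KO)} of per-generation log-fitness coefficients.
#'   Unlisted genes have \code{s = 0}; non-targeting controls always do.
#' @param barcode_length Sample barcode length in nt (default 8).
#' @return An object of class \code{screen_sim_config}.
#' @export
screen_sim_config <- function(seed,
                              n_genes = 714L,
                              guides_per_gene = 4L,
                              n_ntc = 100L,
                              cells_per_mouse = 200000L,
                              mice_per_arm = 6L,
                              stages = c(early = 2, late = 4),
                              depth_per_sample = NULL,
                              plasmid_sigma = 0.5,
                              selection = list(),
                              barcode_length = 8L) {
  stopifnot_count(seed, "seed", min = 0L)
  stopifnot_count(n_genes, "n_genes")
  stopifnot_count(guides_per_gene, "guides_per_gene")
  stopifnot_count(n_ntc, "n_ntc", min = 0L)
  stopifnot_count(cells_per_mouse, "cells_per_mouse")
  stopifnot_count(mice_per_arm, "mice_per_arm")
  if (length(stages) < 1L || is.null(names(stages)) ||
      any(!nzchar(names(stages))) || any(stages < 0)) {
    stop("`stages` must be a named vector of generation counts t >= 0",
         call. = FALSE)
  }
  n_guides <- n_genes * guides_per_gene + n_ntc
  if (n_guides < 1L) stop("library has zero guides", call. = FALSE)
  if (is.null(depth_per_sample)) depth_per_sample <- 4000 * n_guides
  stopifnot_positive(depth_per_sample, "depth_per_sample")
  stopifnot_positive(plasmid_sigma, "plasmid_sigma")
  if (!is.list(selection) ||
      (length(selection) && is.null(names(selection)))) {
    stop("`selection` must be a named list of c(s_WT, s_CD8KO) pairs",
         call. = FALSE)
  }
  for (s in selection) {
    if (!is.numeric(s) || length(s) != 2L || anyNA(s)) {
      stop("each `selection` entry must be numeric c(s_WT, s_CD8KO)",
           call. = FALSE)
    }
  }
  if (NTC_GENE_LABEL %in% names(selection)) {
    stop("non-targeting controls cannot carry selection", call. = FALSE)
  }
  structure(
    list(seed = as.integer(seed), n_genes = as.integer(n_genes),
         guides_per_gene = as.integer(guides_per_gene),
         n_ntc = as.integer(n_ntc),
         cells_per_mouse = as.integer(cells_per_mouse),
         mice_per_arm = as.integer(mice_per_arm),
         stages = stages, depth_per_sample = depth_per_sample,
         plasmid_sigma = plasmid_sigma, selection = selection,
         barcode_length = as.integer(barcode_length)),
    class = "screen_sim_config")
}

random_unique_kmers <- function(n, k) {
  draw <- function(m) {
    vapply(seq_len(m), function(i) {
      paste(sample(c("A", "C", "G", "T"), k, replace = TRUE),
            collapse = "")
    }, character(1))
  }
  out <- draw(n)
  while (anyDuplicated(out)) {
    dup <- which(duplicated(out))
    out[dup] <- draw(length(dup))
  }
  out
}

#' Simulate a two-arm pooled knockout screen
#'
#' @param cfg A \code{\link{screen_sim_config}}.
#' @return A list with elements \code{library} (guide library data frame:
#'   \code{guide_id}, \code{gene}, \code{protospacer}, \code{is_ntc}),
#'   \code{sheet} (sample sheet: \code{sample_id}, \code{genotype},
#'   \code{stage}, \code{mouse_id}, \code{barcode}), \code{counts}
#'   (integer guide x sample matrix), and \code{truth} (per-gene
#'   \code{s_WT}, \code{s_CD8KO} used by the generator).
#' @examples
#' sim <- simulate_screen(screen_sim_config(
#'   seed = 1, n_genes = 20, n_ntc = 10, cells_per_mouse = 5000,
#'   mice_per_arm = 2, depth_per_sample = 5e4))
#' dim(sim$counts)
#' @export
simulate_screen <- function(cfg) {
  if (!inherits(cfg, "screen_sim_config")) {
    stop("`cfg` must be a screen_sim_config", call. = FALSE)
  }
  with_seed(cfg$seed, {
    genes <- sprintf("KIN%04d", seq_len(cfg$n_genes))
    guide_gene <- rep(genes, each = cfg$guides_per_gene)
    guide_id <- paste0(guide_gene, "_g",
                       rep(seq_len(cfg$guides_per_gene), cfg$n_genes))
    if (cfg$n_ntc > 0L) {
      guide_id <- c(guide_id, sprintf("NTC_%04d", seq_len(cfg$n_ntc)))
      guide_gene <- c(guide_gene, rep(NTC_GENE_LABEL, cfg$n_ntc))
    }
    n_guides <- length(guide_id)
    lib <- data.frame(
      guide_id = guide_id, gene = guide_gene,
      protospacer = random_unique_kmers(n_guides, 20L),
      is_ntc = guide_gene == NTC_GENE_LABEL,
      stringsAsFactors = FALSE)

    ## per-guide selection per genotype; 0 unless listed, NTC always 0
    s_wt <- s_ko <- numeric(n_guides)
    for (g in names(cfg$selection)) {
      idx <- which(lib$gene == g)
      s_wt[idx] <- cfg$selection[[g]][1]
      s_ko[idx] <- cfg$selection[[g]][2]
    }

    genotypes <- c("WT", "CD8KO")
    n_samples <- length(genotypes) * length(cfg$stages) * cfg$mice_per_arm
    sheet <- do.call(rbind, lapply(genotypes, function(gt) {
      do.call(rbind, lapply(names(cfg$stages), function(st) {
        data.frame(
          sample_id = sprintf("%s_%s_m%02d", gt, st,
                              seq_len(cfg$mice_per_arm)),
          genotype = gt, stage = st,
          mouse_id = sprintf("%s_%s_mouse%02d", gt, st,
                             seq_len(cfg$mice_per_arm)),
          stringsAsFactors = FALSE)
      }))
    }))
    sheet$barcode <- random_unique_kmers(n_samples, cfg$barcode_length)

    plasmid_w <- exp(rnorm(n_guides, 0, cfg$plasmid_sigma))
    plasmid_w <- plasmid_w / sum(plasmid_w)

    counts <- matrix(0L, nrow = n_guides, ncol = n_samples,
                     dimnames = list(lib$guide_id, sheet$sample_id))
    for (j in seq_len(n_samples)) {
      s <- if (sheet$genotype[j] == "WT") s_wt else s_ko
      t_gen <- cfg$stages[[sheet$stage[j]]]
      bottleneck <- as.numeric(
        rmultinom(1, cfg$cells_per_mouse, plasmid_w))
      w <- bottleneck * exp(s * t_gen)
      if (sum(w) <= 0) {
        stop("degenerate clone weights (all zero) in sample ",
             sheet$sample_id[j], call. = FALSE)
      }
      depth <- rpois(1, cfg$depth_per_sample)
      counts[, j] <- as.integer(rmultinom(1, depth, w / sum(w)))
    }

    truth_genes <- c(genes, if (cfg$n_ntc > 0L) NTC_GENE_LABEL)
    first <- match(truth_genes, lib$gene)
    truth <- data.frame(gene = truth_genes,
                        s_WT = s_wt[first], s_CD8KO = s_ko[first],
                        stringsAsFactors = FALSE)
    list(library = lib, sheet = sheet, counts = counts, truth = truth)
  })
}

#' Configuration for the single-cell cohort simulator
#'
#' Emulates a multi-sample single-cell expression cohort: marker-defined
#' cell types, a focal gene detected only in tumor cells with a per-sample
#' detection probability that spans the cohort median, and a designated
#' program gene set whose mean expression rises in focal-gene-low samples
#' by a configurable effect size.
#'
#' @param seed Integer seed.
#' @param n_samples Number of patient samples (default 28).
#' @param cells_per_sample Cells per sample (default 120).
#' @param n_genes Size of the gene universe, fillers included
#'   (default 400).
#' @param marker_sets Named list mapping cell type to marker symbols. The
#'   default is the standard brain-tumor panel (SOX2 tumor, CD14/CD68
#'   macrophage, CD3D T cell, CD79A B cell, MBP oligodendrocyte, PECAM1
#'   endothelial, PDGFRB pericyte).
#' @param type_props Named numeric of cell-type proportions (same names
#'   as \code{marker_sets}); normalized internally.
#' @param focal_gene Symbol of the focal gene (default \code{"CHEK2"}),
#'   expressed only in tumor cells.
#' @param focal_detect_range Length-2 numeric: the per-sample focal-gene
#'   detection probabilities are equally spaced over this interval
#'   (default \code{c(0.10, 0.70)}), so per-sample positive frequency
#'   spans the cohort median.
#' @param program_genes Symbols of the planted program gene set (default
#'   20 interferon-like signature genes).
#' @param coupling Log-scale effect size: program-gene mean expression in
#'   a sample is multiplied by \code{exp(coupling * lowness)} where
#'   lowness rescales the sample's focal detection probability to [0, 1]
#'   (1 = lowest). \code{coupling = 0} removes the association.
#' @param dropout Per-entry Bernoulli dropout probability applied to
#'   non-marker background counts (default 0.3).
#' @param size_disp Negative-binomial size (inverse overdispersion) for
#'   counts (default 2).
#' @return An object of class \code{scrna_sim_config}.
#' @export
scrna_sim_config <- function(seed,
                             n_samples = 28L,
                             cells_per_sample = 120L,
                             n_genes = 400L,
                             marker_sets = NULL,
                             type_props = NULL,
                             focal_gene = "CHEK2",
                             focal_detect_range = c(0.10, 0.70),
                             program_genes = sprintf("IFNSIG%02d", 1:20),
                             coupling = 1,
                             dropout = 0.3,
                             size_disp = 2) {
  stopifnot_count(seed, "seed", min = 0L)
  stopifnot_count(n_samples, "n_samples", min = 2L)
  stopifnot_count(cells_per_sample, "cells_per_sample")
  stopifnot_count(n_genes, "n_genes")
  if (is.null(marker_sets)) {
    marker_sets <- list(
      tumor = "SOX2", macrophage = c("CD14", "CD68"), tcell = "CD3D",
      bcell = "CD79A", oligodendrocyte = "MBP", endothelial = "PECAM1",
      pericyte = "PDGFRB")
  }
  if (!is.list(marker_sets) || is.null(names(marker_sets)) ||
      !"tumor" %in% names(marker_sets)) {
    stop("`marker_sets` must be a named list including a 'tumor' type",
         call. = FALSE)
  }
  if (is.null(type_props)) {
    type_props <- c(tumor = 0.55, macrophage = 0.20, tcell = 0.07,
                    bcell = 0.02, oligodendrocyte = 0.08,
                    endothelial = 0.05, pericyte = 0.03)
    type_props <- type_props[names(marker_sets)]
    type_props[is.na(type_props)] <- 0.05
  }
  if (!setequal(names(type_props), names(marker_sets))) {
    stop("`type_props` names must match `marker_sets` names",
         call. = FALSE)
  }
  type_props <- type_props[names(marker_sets)] / sum(type_props)
  if (!is.character(program_genes) || length(program_genes) == 0L) {
    stop("`program_genes` must be a nonempty character vector",
         call. = FALSE)
  }
  if (!is.character(focal_gene) || length(focal_gene) != 1L) {
    stop("`focal_gene` must be a single symbol", call. = FALSE)
  }
  if (length(focal_detect_range) != 2L ||
      any(focal_detect_range < 0 | focal_detect_range > 1)) {
    stop("`focal_detect_range` must be two probabilities", call. = FALSE)
  }
  if (dropout < 0 || dropout >= 1) {
    stop("`dropout` must be in [0, 1)", call. = FALSE)
  }
  stopifnot_positive(size_disp, "size_disp")
  structure(
    list(seed = as.integer(seed), n_samples = as.integer(n_samples),
         cells_per_sample = as.integer(cells_per_sample),
         n_genes = as.integer(n_genes), marker_sets = marker_sets,
         type_props = type_props, focal_gene = focal_gene,
         focal_detect_range = as.numeric(focal_detect_range),
         program_genes = program_genes, coupling = as.numeric(coupling),
         dropout = as.numeric(dropout), size_disp = as.numeric(size_disp)),
    class = "scrna_sim_config")
}

#' Simulate a multi-sample single-cell expression cohort
#'
#' @param cfg A \code{\link{scrna_sim_config}}.
#' @return A list with \code{cpm} (gene x cell CPM matrix), \code{meta}
#'   (per-cell \code{cell_id}, \code{sample_id}, \code{true_type}), and
#'   \code{truth} (per-sample focal detection probability and program
#'   elevation actually used).
#' @export
simulate_scrna <- function(cfg) {
  if (!inherits(cfg, "scrna_sim_config")) {
    stop("`cfg` must be an scrna_sim_config", call. = FALSE)
  }
  with_seed(cfg$seed, {
    markers <- unique(unlist(cfg$marker_sets))
    special <- unique(c(markers, cfg$focal_gene, cfg$program_genes))
    n_fill <- max(0L, cfg$n_genes - length(special))
    genes <- c(special, sprintf("GENE%04d", seq_len(n_fill)))
    n_genes <- length(genes)

    ## baseline lognormal mean per background gene, shared across cells
    base_mu <- stats::rlnorm(n_genes, meanlog = 0, sdlog = 1)
    names(base_mu) <- genes
    base_mu[markers] <- 0            # markers are purely type-specific
    base_mu[cfg$focal_gene] <- 0     # focal gene handled separately
    base_mu[cfg$program_genes] <- 2  # common program baseline

    p_focal <- seq(cfg$focal_detect_range[1], cfg$focal_detect_range[2],
                   length.out = cfg$n_samples)
    lowness <- if (diff(range(p_focal)) > 0) {
      (max(p_focal) - p_focal) / diff(range(p_focal))
    } else {
      rep(0, cfg$n_samples)
    }
    program_mult <- exp(cfg$coupling * lowness)

    n_cells <- cfg$n_samples * cfg$cells_per_sample
    types <- names(cfg$marker_sets)
    cpm <- matrix(0, nrow = n_genes, ncol = n_cells,
                  dimnames = list(genes, NULL))
    meta <- data.frame(cell_id = sprintf("cell%06d", seq_len(n_cells)),
                       sample_id = rep(sprintf("S%02d",
                                               seq_len(cfg$n_samples)),
                                       each = cfg$cells_per_sample),
                       true_type = NA_character_,
                       stringsAsFactors = FALSE)
    colnames(cpm) <- meta$cell_id

    cell <- 0L
    for (s in seq_len(cfg$n_samples)) {
      mu_s <- base_mu
      mu_s[cfg$program_genes] <- mu_s[cfg$program_genes] * program_mult[s]
      for (i in seq_len(cfg$cells_per_sample)) {
        cell <- cell + 1L
        ty <- sample(types, 1L, prob = cfg$type_props)
        meta$true_type[cell] <- ty
        counts <- stats::rnbinom(n_genes, mu = mu_s,
                                 size = cfg$size_disp)
        if (cfg$dropout > 0) {
          counts <- counts *
            stats::rbinom(n_genes, 1L, 1 - cfg$dropout)
        }
        counts[match(cfg$marker_sets[[ty]], genes)] <-
          stats::rnbinom(length(cfg$marker_sets[[ty]]), mu = 50,
                         size = cfg$size_disp) + 5L
        if (ty == "tumor" && stats::runif(1) < p_focal[s]) {
          counts[match(cfg$focal_gene, genes)] <-
            stats::rnbinom(1L, mu = 5, size = cfg$size_disp) + 1L
        }
        tot <- sum(counts)
        if (tot == 0) {          # pathological empty cell: one token count
          counts[1L] <- 1L
          tot <- 1L
        }
        cpm[, cell] <- counts / tot * 1e6
      }
    }
    truth <- data.frame(sample_id = sprintf("S%02d",
                                            seq_len(cfg$n_samples)),
                        p_focal = p_focal,
                        program_mult = program_mult,
                        stringsAsFactors = FALSE)
    list(cpm = cpm, meta = meta, truth = truth)
  })
}

#' Configuration for the survival simulator
#'
#' @param seed Integer seed.
#' @param groups Named list mapping group label to
#'   \code{list(n = <count>, hazard = <rate per day>)}.
#' @param censor_time Administrative censoring horizon (days); subjects
#'   alive at this time are censored.
#' @return An object of class \code{survival_sim_config}.
#' @export
survival_sim_config <- function(seed, groups, censor_time = Inf) {
  stopifnot_count(seed, "seed", min = 0L)
  if (!is.list(groups) || length(groups) == 0L ||
      is.null(names(groups))) {
    stop("`groups` must be a named list", call. = FALSE)
  }
  for (g in groups) {
    if (!is.list(g) || is.null(g$n) || is.null(g$hazard)) {
      stop("each group needs `n` and `hazard`", call. = FALSE)
    }
    stopifnot_count(g$n, "n")
    stopifnot_positive(g$hazard, "hazard")
  }
  if (!is.numeric(censor_time) || length(censor_time) != 1L ||
      is.na(censor_time) || censor_time < 0) {
    stop("`censor_time` must be a nonnegative number", call. = FALSE)
  }
  structure(list(seed = as.integer(seed), groups = groups,
                 censor_time = censor_time),
            class = "survival_sim_config")
}

#' Simulate exponential survival arms with administrative censoring
#'
#' @param cfg A \code{\link{survival_sim_config}}.
#' @return A survival table data frame: \code{subject_id}, \code{time},
#'   \code{event} (1 = event observed, 0 = censored), \code{group}.
#' @export
simulate_survival <- function(cfg) {
  if (!inherits(cfg, "survival_sim_config")) {
    stop("`cfg` must be a survival_sim_config", call. = FALSE)
  }
  with_seed(cfg$seed, {
    out <- do.call(rbind, lapply(names(cfg$groups), function(g) {
      n <- cfg$groups[[g]]$n
      t_true <- stats::rexp(n, rate = cfg$groups[[g]]$hazard)
      data.frame(subject_id = sprintf("%s_%03d", g, seq_len(n)),
                 time = pmin(t_true, cfg$censor_time),
                 event = as.integer(t_true <= cfg$censor_time),
                 group = g, stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    out
  })
}
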