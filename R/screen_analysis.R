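## Screen scoring: raw-count filter, CPM+1 normalization, arm means,
## WT-over-CD8KO fold changes, non-targeting-control envelope calls,
## gene-level ranking and early-vs-late temporal selection tests.

#' Flag guide x sample entries passing the raw-count filter
#'
#' Entries with raw counts below \code{min_raw} are excluded from
#' downstream arm means; the counts themselves are never altered.
#'
#' @param raw Integer guide x sample count matrix.
#' @param min_raw Minimum raw count retained (default 40; counts < 40
#'   are excluded).
#' @return Logical matrix of the same shape: TRUE = passes.
#' @export
apply_count_filter <- function(raw, min_raw = 40) {
  if (!is.matrix(raw) || any(raw < 0) || any(raw != floor(raw))) {
    stop("`raw` must be a nonnegative integer matrix", call. = FALSE)
  }
  zero_samples <- colSums(raw) == 0
  if (any(zero_samples)) {
    warning("all-zero sample(s): ",
            paste(colnames(raw)[zero_samples], collapse = ", "),
            "; every guide excluded there", call. = FALSE)
  }
  raw >= min_raw
}

#' Normalize raw counts to CPM + 1
#'
#' Per entry: raw / (total reads for all guides in the sample) * 1e6 + 1.
#' Sample totals always use the full library, filtered guides included.
#'
#' @param raw Integer guide x sample count matrix.
#' @return Numeric matrix of normalized counts (every value >= 1).
#' @export
normalize_cpm <- function(raw) {
  if (!is.matrix(raw) || any(raw < 0)) {
    stop("`raw` must be a nonnegative matrix", call. = FALSE)
  }
  totals <- colSums(raw)
  if (any(totals <= 0)) {
    stop("zero total reads in sample(s): ",
         paste(colnames(raw)[totals <= 0], collapse = ", "),
         call. = FALSE)
  }
  sweep(raw, 2, totals, "/") * 1e6 + 1
}

#' Per-guide group means of normalized counts
#'
#' Averages normalized counts over each group's samples, using only
#' entries that pass the raw-count filter. A guide must pass in at least
#' \code{max(2, ceiling(half the group's samples))} samples of a group to
#' be usable in comparisons involving that group; otherwise it is marked
#' for exclusion there.
#'
#' @param norm Normalized count matrix from \code{\link{normalize_cpm}}.
#' @param sheet Sample sheet; rows must match \code{colnames(norm)}.
#' @param pass Logical pass-flag matrix from
#'   \code{\link{apply_count_filter}}.
#' @param group_by \code{"genotype"} (default) or
#'   \code{"genotype_stage"}.
#' @return List with \code{means} (guide x group matrix; NA where
#'   unusable), \code{n_pass} (passing-sample counts) and \code{usable}
#'   (logical guide x group matrix).
#' @export
aggregate_arm <- function(norm, sheet, pass,
                          group_by = c("genotype", "genotype_stage")) {
  group_by <- match.arg(group_by)
  sheet <- validate_sample_sheet(sheet)
  if (!identical(colnames(norm), sheet$sample_id)) {
    stop("column order of `norm` must match the sample sheet",
         call. = FALSE)
  }
  stopifnot(identical(dim(norm), dim(pass)))
  grp <- if (group_by == "genotype") sheet$genotype else
    paste(sheet$genotype, sheet$stage, sep = ":")
  groups <- unique(grp)
  means <- n_pass <- matrix(
    NA_real_, nrow = nrow(norm), ncol = length(groups),
    dimnames = list(rownames(norm), groups))
  usable <- matrix(FALSE, nrow(norm), length(groups),
                   dimnames = dimnames(means))
  for (g in groups) {
    js <- which(grp == g)
    if (length(js) == 0L) stop("empty group: ", g, call. = FALSE)
    p <- pass[, js, drop = FALSE]
    x <- norm[, js, drop = FALSE]
    x[!p] <- NA_real_
    np <- rowSums(p)
    mn <- rowSums(x, na.rm = TRUE) / np
    mn[np == 0L] <- NA_real_
    need <- max(2L, ceiling(length(js) / 2))
    means[, g] <- mn
    n_pass[, g] <- np
    usable[, g] <- np >= need
  }
  list(means = means, n_pass = n_pass, usable = usable,
       group_by = group_by)
}

#' Per-guide WT-over-CD8KO fold changes
#'
#' fc = mean_WT / mean_CD8KO on arm means of normalized (CPM + 1)
#' counts. Guides unusable in either arm (raw-count filter) are classed
#' \code{low_count_excluded}; guides with both arm means < \code{min_norm}
#' are classed \code{unanalyzable}; the rest await envelope
#' classification.
#'
#' @param arm Result of \code{\link{aggregate_arm}} grouped by genotype,
#'   with \code{WT} and \code{CD8KO} columns.
#' @param lib Guide library.
#' @param min_norm Minimum normalized arm mean for analysis (default 5).
#' @return Data frame: guide_id, gene, is_ntc, mean_wt, mean_cd8ko, fc,
#'   log2fc, class.
#' @export
guide_fold_changes <- function(arm, lib, min_norm = 5) {
  lib <- validate_guide_library(lib)
  m <- arm$means
  if (!all(c("WT", "CD8KO") %in% colnames(m))) {
    stop("arm means must contain WT and CD8KO groups", call. = FALSE)
  }
  stopifnot(identical(rownames(m), lib$guide_id))
  fc <- m[, "WT"] / m[, "CD8KO"]
  res <- data.frame(
    guide_id = lib$guide_id, gene = lib$gene, is_ntc = lib$is_ntc,
    mean_wt = m[, "WT"], mean_cd8ko = m[, "CD8KO"],
    fc = fc, log2fc = log2(fc),
    class = "neutral", stringsAsFactors = FALSE, row.names = NULL)
  both_low <- !is.na(res$mean_wt) & !is.na(res$mean_cd8ko) &
    res$mean_wt < min_norm & res$mean_cd8ko < min_norm
  res$class[both_low] <- "unanalyzable"
  excluded <- !(arm$usable[, "WT"] & arm$usable[, "CD8KO"])
  res$class[excluded] <- "low_count_excluded"
  res$fc[excluded] <- NA_real_
  res$log2fc[excluded] <- NA_real_
  res
}

#' Fold-change envelope of the non-targeting controls
#'
#' Summarizes the fold changes of usable non-targeting control guides;
#' the min and max bound the null band used for enrichment/depletion
#' calls.
#'
#' @param results Guide table from \code{\link{guide_fold_changes}}.
#' @return Object of class \code{ntc_envelope}: \code{max_ntc_fc},
#'   \code{min_ntc_fc}, \code{ntc_fc_mean}, \code{ntc_fc_sd},
#'   \code{n_ntc_used}.
#' @export
ntc_envelope <- function(results) {
  use <- results$is_ntc &
    !results$class %in% c("low_count_excluded", "unanalyzable")
  fcs <- results$fc[use]
  if (length(fcs) < 2L) {
    stop("need at least two usable non-targeting control guides",
         call. = FALSE)
  }
  structure(list(max_ntc_fc = max(fcs), min_ntc_fc = min(fcs),
                 ntc_fc_mean = mean(fcs), ntc_fc_sd = stats::sd(fcs),
                 n_ntc_used = length(fcs)),
            class = "ntc_envelope")
}

#' Classify guides against the non-targeting-control envelope
#'
#' A targeting guide is enriched when its fold change strictly exceeds
#' the most enriched non-targeting guide, depleted when strictly below
#' the most depleted one, neutral otherwise. Strict inequalities mean a
#' non-targeting guide is never labeled enriched or depleted; excluded
#' and unanalyzable classes are left untouched.
#'
#' @param results Guide table from \code{\link{guide_fold_changes}}.
#' @param envelope An \code{\link{ntc_envelope}}; computed from
#'   \code{results} when omitted.
#' @return The guide table with \code{class} filled in.
#' @export
classify_by_ntc_envelope <- function(results, envelope = NULL) {
  if (is.null(envelope)) envelope <- ntc_envelope(results)
  open <- results$class == "neutral"
  enr <- open & !is.na(results$fc) & results$fc > envelope$max_ntc_fc
  dep <- open & !is.na(results$fc) & results$fc < envelope$min_ntc_fc
  results$class[enr] <- "enriched"
  results$class[dep] <- "depleted"
  attr(results, "envelope") <- envelope
  results
}

#' Gene-level summary ranked by depletion
#'
#' Aggregates classified guide results per targeted gene: call counts,
#' mean log2 fold change over usable guides, a depletion rank (most
#' negative mean log2fc = rank 1), and a two-sided Welch t p-value of
#' the gene's guide log2fcs against the non-targeting guide log2fcs
#' (with a Benjamini-Hochberg adjusted column).
#'
#' @param results Classified guide table from
#'   \code{\link{classify_by_ntc_envelope}}.
#' @return Data frame: gene, n_guides_used, n_depleted, n_enriched,
#'   mean_log2fc, depletion_rank (NA when no usable guide), p_vs_ntc,
#'   q_vs_ntc, no_usable_guides flag.
#' @export
gene_summary <- function(results) {
  usable <- !results$class %in% c("low_count_excluded", "unanalyzable")
  ntc_l2 <- results$log2fc[results$is_ntc & usable]
  tgt <- results[!results$is_ntc, , drop = FALSE]
  genes <- unique(tgt$gene)
  rows <- lapply(genes, function(g) {
    gi <- tgt[tgt$gene == g, , drop = FALSE]
    use <- !gi$class %in% c("low_count_excluded", "unanalyzable")
    l2 <- gi$log2fc[use]
    p <- if (length(l2) >= 2L && length(ntc_l2) >= 2L &&
             (stats::sd(l2) > 0 || stats::sd(ntc_l2) > 0)) {
      stats::t.test(l2, ntc_l2)$p.value
    } else NA_real_
    data.frame(
      gene = g, n_guides_used = sum(use),
      n_depleted = sum(gi$class == "depleted"),
      n_enriched = sum(gi$class == "enriched"),
      mean_log2fc = if (any(use)) mean(l2) else NA_real_,
      p_vs_ntc = p, no_usable_guides = !any(use),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  ranked <- which(!out$no_usable_guides)
  out$depletion_rank <- NA_integer_
  out$depletion_rank[ranked] <-
    rank(out$mean_log2fc[ranked], ties.method = "first")
  out$q_vs_ntc <- stats::p.adjust(out$p_vs_ntc, method = "BH")
  out[order(out$depletion_rank), ]
}

## Welch two-sample t with explicit degenerate handling: both groups
## constant and equal -> t = 0, p = 1; constant but unequal -> p floored
## at the double-precision minimum with a flag.
welch_test <- function(x, y) {
  nx <- length(x); ny <- length(y)
  if (nx < 2L || ny < 2L) {
    stop("need >= 2 observations per group", call. = FALSE)
  }
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx == 0 && vy == 0) {
    if (mean(x) == mean(y)) {
      return(list(t = 0, df = nx + ny - 2, p = 1, underflow = FALSE))
    }
    return(list(t = sign(mean(x) - mean(y)) * Inf, df = nx + ny - 2,
                p = .Machine$double.xmin, underflow = TRUE))
  }
  se2 <- vx / nx + vy / ny
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df),
       underflow = FALSE)
}

#' Early-versus-late selection test for one gene in one arm
#'
#' Pools the gene's guide-level normalized counts (entries passing the
#' raw-count filter) over the mice of each stage within a genotype and
#' compares early vs late with an unpaired two-tailed Welch t-test, with
#' no multiplicity adjustment. The direction of selection is the sign of
#' (mean_late - mean_early).
#'
#' @param norm Normalized count matrix.
#' @param sheet Sample sheet.
#' @param pass Pass-flag matrix from \code{\link{apply_count_filter}}.
#' @param lib Guide library.
#' @param gene Gene symbol.
#' @param genotype \code{"WT"} or \code{"CD8KO"}.
#' @param stages Length-2 character: stages to compare
#'   (default \code{c("early", "late")}).
#' @return Data frame row: gene, genotype, mean_early, mean_late,
#'   t_statistic, df, p_two_sided, direction, n_early, n_late,
#'   p_underflow flag.
#' @export
temporal_selection_test <- function(norm, sheet, pass, lib, gene,
                                    genotype = c("WT", "CD8KO"),
                                    stages = c("early", "late")) {
  genotype <- match.arg(genotype)
  lib <- validate_guide_library(lib)
  sheet <- validate_sample_sheet(sheet)
  gidx <- which(lib$gene == gene)
  if (length(gidx) == 0L) stop("unknown gene: ", gene, call. = FALSE)
  pool <- function(st) {
    js <- which(sheet$genotype == genotype & sheet$stage == st)
    v <- norm[gidx, js, drop = FALSE]
    v[pass[gidx, js, drop = FALSE]]
  }
  x_early <- pool(stages[1]); x_late <- pool(stages[2])
  if (length(x_early) < 2L || length(x_late) < 2L) {
    stop("need >= 2 usable observations per stage for ", gene,
         " in ", genotype, call. = FALSE)
  }
  w <- welch_test(x_early, x_late)
  data.frame(gene = gene, genotype = genotype,
             mean_early = mean(x_early), mean_late = mean(x_late),
             t_statistic = w$t, df = w$df, p_two_sided = w$p,
             direction = sign(mean(x_late) - mean(x_early)),
             n_early = length(x_early), n_late = length(x_late),
             p_underflow = w$underflow, stringsAsFactors = FALSE)
}

#' Library fold representation
#'
#' Implanted cells per library guide, floored to an integer: e.g.
#' 200000 cells/mouse across 11 mice over a 3000-guide library gives
#' 733X.
#'
#' @param cells_per_mouse Cells implanted per mouse.
#' @param n_mice Number of mice.
#' @param n_guides Number of guides in the library.
#' @return Integer fold coverage.
#' @export
representation_coverage <- function(cells_per_mouse, n_mice, n_guides) {
  stopifnot_count(cells_per_mouse, "cells_per_mouse")
  stopifnot_count(n_mice, "n_mice", min = 0L)
  stopifnot_count(n_guides, "n_guides")
  as.integer(floor(cells_per_mouse * n_mice / n_guides))
}

#' Score a screen end to end
#'
#' Filter, normalize, aggregate arms, compute fold changes, and classify
#' against the non-targeting-control envelope.
#'
#' @param raw Raw guide x sample count matrix.
#' @param lib Guide library.
#' @param sheet Sample sheet.
#' @param min_raw Raw-count filter threshold (default 40).
#' @param min_norm Unanalyzable threshold on arm means (default 5).
#' @return List: \code{guides} (classified guide table), \code{genes}
#'   (gene summary), \code{envelope}, \code{norm}, \code{pass},
#'   \code{arm}.
#' @export
score_screen <- function(raw, lib, sheet, min_raw = 40, min_norm = 5) {
  lib <- validate_guide_library(lib)
  sheet <- validate_sample_sheet(sheet)
  stopifnot(identical(rownames(raw), lib$guide_id))
  pass <- apply_count_filter(raw, min_raw = min_raw)
  norm <- normalize_cpm(raw)
  arm <- aggregate_arm(norm, sheet, pass, group_by = "genotype")
  guides <- guide_fold_changes(arm, lib, min_norm = min_norm)
  guides <- classify_by_ntc_envelope(guides)
  list(guides = guides, genes = gene_summary(guides),
       envelope = attr(guides, "envelope"),
       norm = norm, pass = pass, arm = arm)
}
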