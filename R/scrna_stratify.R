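## Tumor-intrinsic stratification of single-cell cohorts: marker-argmax
## cell typing, per-sample focal-gene-positive frequency, median
## dichotomization, rank-based recovery-curve AUC gene-set scores,
## Mann-Whitney group comparison and Welch differential expression.

#' Annotate cells by marker-panel argmax
#'
#' Per cell, each type's score is the mean log1p(CPM) over that type's
#' markers; the label is the best-scoring type when its score is
#' positive, otherwise "unassigned". Ties break deterministically in
#' panel order. Panel symbols missing from the gene universe are dropped
#' with a warning.
#'
#' @param m Gene x cell CPM matrix (rownames = symbols).
#' @param panel Named list mapping cell type to marker symbols.
#' @return Character vector of cell-type labels, one per cell.
#' @export
annotate_cells <- function(m, panel) {
  if (!is.list(panel) || length(panel) == 0L || is.null(names(panel))) {
    stop("`panel` must be a nonempty named list", call. = FALSE)
  }
  panel <- lapply(panel, function(g) {
    miss <- setdiff(g, rownames(m))
    if (length(miss)) {
      warning("markers absent from gene universe dropped: ",
              paste(miss, collapse = ", "), call. = FALSE)
    }
    intersect(g, rownames(m))
  })
  if (all(lengths(panel) == 0L)) {
    stop("no panel marker present in the gene universe", call. = FALSE)
  }
  scores <- vapply(panel, function(g) {
    if (length(g) == 0L) return(rep(-Inf, ncol(m)))
    colMeans(log1p(m[g, , drop = FALSE]))
  }, numeric(ncol(m)))
  if (ncol(m) == 1L) scores <- matrix(scores, nrow = 1L,
                                      dimnames = list(NULL, names(panel)))
  best <- max.col(scores, ties.method = "first")
  lab <- names(panel)[best]
  lab[scores[cbind(seq_len(nrow(scores)), best)] <= 0] <- "unassigned"
  lab
}

#' Per-sample frequency of focal-gene-positive tumor cells
#'
#' Fraction of a sample's tumor-compartment cells with focal-gene
#' CPM > 0. Samples with no tumor cells are dropped with a warning.
#'
#' @param m Gene x cell CPM matrix.
#' @param sample_ids Per-cell sample labels.
#' @param cell_types Per-cell type labels (from
#'   \code{\link{annotate_cells}} or ground truth).
#' @param focal_gene Focal gene symbol.
#' @param compartment Cell type defining the compartment
#'   (default \code{"tumor"}).
#' @return Named numeric vector of per-sample frequencies in [0, 1].
#' @export
focal_positive_frequency <- function(m, sample_ids, cell_types,
                                     focal_gene,
                                     compartment = "tumor") {
  if (!focal_gene %in% rownames(m)) {
    stop("focal gene not in gene universe: ", focal_gene,
         call. = FALSE)
  }
  stopifnot(length(sample_ids) == ncol(m),
            length(cell_types) == ncol(m))
  in_comp <- cell_types == compartment
  samples <- unique(sample_ids)
  pos <- m[focal_gene, ] > 0
  freqs <- vapply(samples, function(s) {
    sel <- in_comp & sample_ids == s
    if (!any(sel)) return(NA_real_)
    mean(pos[sel])
  }, numeric(1))
  names(freqs) <- samples
  if (anyNA(freqs)) {
    warning("sample(s) without ", compartment, " cells dropped: ",
            paste(samples[is.na(freqs)], collapse = ", "),
            call. = FALSE)
    freqs <- freqs[!is.na(freqs)]
  }
  freqs
}

#' Dichotomize samples at the cohort median frequency
#'
#' The cohort median (standard midpoint median) of the per-sample
#' frequencies is the cutoff: strictly above goes to "high", the rest
#' (ties at the median included) to "low".
#'
#' @param freqs Named numeric vector of per-sample frequencies.
#' @return Data frame (sample_id, freq, label) with the cutoff in
#'   attribute \code{"median"}.
#' @export
dichotomize_samples <- function(freqs) {
  if (length(freqs) < 2L) {
    stop("need at least two samples to dichotomize", call. = FALSE)
  }
  med <- stats::median(freqs)
  if (diff(range(freqs)) == 0) {
    warning("all frequencies identical; degenerate stratification ",
            "(all samples labeled low)", call. = FALSE)
  }
  out <- data.frame(sample_id = names(freqs), freq = unname(freqs),
                    label = ifelse(freqs > med, "high", "low"),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "median") <- med
  out
}

#' Per-cell gene-set activity by recovery-curve AUC
#'
#' For each cell, genes are ranked by descending expression (ties broken
#' by one seeded random permutation shared across cells) and the
#' recovery curve c(k) counts set genes at rank <= k. The score is
#' sum(c(k), k = 1..max_rank) normalized by its maximum
#' sum(min(k, m)), with m set genes in the universe, so a cell whose top
#' m genes are exactly the set scores 1 and a cell with no set gene in
#' the top max_rank scores 0. Only ranks matter, so any monotone
#' transform of a cell's expression leaves its score unchanged.
#'
#' @param m Gene x cell expression matrix (any monotone scale).
#' @param gene_set Character vector of set member symbols.
#' @param max_rank_frac Top fraction of the ranking integrated
#'   (default 0.05); \code{max_rank = ceiling(frac * n_genes)}.
#' @param tie_seed Seed of the tie-breaking permutation (default 1).
#' @return Numeric vector of per-cell scores in [0, 1]; attributes
#'   \code{max_rank} and \code{tie_seed} record the parameters.
#' @export
auc_score <- function(m, gene_set, max_rank_frac = 0.05,
                      tie_seed = 1L) {
  set_idx <- which(rownames(m) %in% gene_set)
  if (length(set_idx) == 0L) {
    stop("gene set has empty intersection with the gene universe",
         call. = FALSE)
  }
  n_genes <- nrow(m)
  max_rank <- max(1L, as.integer(ceiling(max_rank_frac * n_genes)))
  n_set <- length(set_idx)
  tb <- with_seed(tie_seed, sample.int(n_genes))
  denom <- if (max_rank >= n_set) {
    n_set * (n_set + 1) / 2 + n_set * (max_rank - n_set)
  } else {
    max_rank * (max_rank + 1) / 2
  }
  scores <- vapply(seq_len(ncol(m)), function(j) {
    ord <- order(-m[, j], tb)
    r <- integer(n_genes)
    r[ord] <- seq_len(n_genes)
    rs <- r[set_idx]
    rs <- rs[rs <= max_rank]
    sum(max_rank - rs + 1) / denom
  }, numeric(1))
  names(scores) <- colnames(m)
  attr(scores, "max_rank") <- max_rank
  attr(scores, "tie_seed") <- tie_seed
  scores
}

#' Two-sided Mann-Whitney comparison of two score groups
#'
#' Exact permutation p by full enumeration of group assignments when
#' both groups have at most \code{exact_max} observations (ties
#' handled); otherwise the tie-corrected normal approximation of the U
#' statistic (no continuity correction).
#'
#' @param x,y Numeric score vectors for the two groups.
#' @param exact_max Largest per-group size for exact enumeration
#'   (default 8).
#' @return List: \code{U} (statistic for \code{x}), \code{p}
#'   (two-sided), \code{method}.
#' @export
compare_groups_mw <- function(x, y, exact_max = 8L) {
  if (length(x) < 1L || length(y) < 1L) {
    stop("both groups must be nonempty", call. = FALSE)
  }
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  pooled <- c(x, y)
  r <- rank(pooled)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (n1 <= exact_max && n2 <= exact_max) {
    splits <- utils::combn(N, n1)
    stat <- apply(splits, 2, function(idx) {
      sum(r[idx]) - n1 * (n1 + 1) / 2
    })
    p <- mean(abs(stat - mu) >= abs(U - mu) - 1e-9)
    return(list(U = U, p = p, method = "exact enumeration"))
  }
  ties <- table(pooled)
  sigma2 <- n1 * n2 / 12 *
    ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  p <- if (sigma2 <= 0) 1 else {
    min(1, 2 * stats::pnorm(-abs(U - mu) / sqrt(sigma2)))
  }
  list(U = U, p = p, method = "normal approximation (tie-corrected)")
}

#' Welch differential expression between focal-positive and -negative
#' tumor cells
#'
#' Per gene: Welch t with Satterthwaite degrees of freedom between
#' tumor-compartment cells with focal-gene CPM > 0 and those with
#' CPM = 0; two-sided p and a Benjamini-Hochberg adjusted q column.
#'
#' @param m Gene x cell CPM matrix.
#' @param cell_types Per-cell type labels.
#' @param focal_gene Focal gene symbol (excluded from the result).
#' @param compartment Compartment cell type (default \code{"tumor"}).
#' @return Data frame: gene, mean_pos, mean_neg, t, df, p, q.
#' @export
welch_de <- function(m, cell_types, focal_gene,
                     compartment = "tumor") {
  if (!focal_gene %in% rownames(m)) {
    stop("focal gene not in gene universe: ", focal_gene,
         call. = FALSE)
  }
  tum <- m[, cell_types == compartment, drop = FALSE]
  pos <- tum[focal_gene, ] > 0
  if (sum(pos) < 2L || sum(!pos) < 2L) {
    stop("need >= 2 tumor cells in each focal-gene stratum",
         call. = FALSE)
  }
  xp <- tum[, pos, drop = FALSE]
  xn <- tum[, !pos, drop = FALSE]
  np <- ncol(xp); nn <- ncol(xn)
  mp <- rowMeans(xp); mn <- rowMeans(xn)
  vp <- rowSums((xp - mp)^2) / (np - 1)
  vn <- rowSums((xn - mn)^2) / (nn - 1)
  se2 <- vp / np + vn / nn
  t <- (mp - mn) / sqrt(se2)
  df <- se2^2 / ((vp / np)^2 / (np - 1) + (vn / nn)^2 / (nn - 1))
  p <- 2 * stats::pt(-abs(t), df)
  zero <- se2 == 0
  t[zero] <- 0
  p[zero] <- 1
  df[zero] <- np + nn - 2
  out <- data.frame(gene = rownames(m), mean_pos = mp, mean_neg = mn,
                    t = t, df = df, p = p,
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[out$gene != focal_gene, , drop = FALSE]
  out$q <- stats::p.adjust(out$p, method = "BH")
  out
}
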