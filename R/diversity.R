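# Alpha diversity (Chao1, ACE, Shannon, Simpson) with rank-sum group
# comparison, and Bray-Curtis beta diversity with PCoA, NMDS and PERMANOVA.

.abMatrix <- function(x) {
  # internal: accept an AbundanceExperiment or a samples-by-taxa matrix and
  # return samples-by-taxa
  if (is(x, "AbundanceExperiment")) t(abundances(x)) else as.matrix(x)
}

.chao1 <- function(counts) {
  counts <- counts[counts > 0]
  S <- length(counts)
  if (S == 0) return(0)
  F1 <- sum(counts == 1)
  F2 <- sum(counts == 2)
  if (F2 > 0) S + F1^2 / (2 * F2) else S + F1 * (F1 - 1) / 2
}

#' Per-sample alpha-diversity indices
#'
#' Shannon (natural log by default) and Simpson (1 - sum p^2) are computed on
#' the relative abundances directly. Chao1 (classic form: S_obs + F1^2/(2 F2),
#' falling back to S_obs + F1(F1-1)/2 when no doubletons) and ACE (abundance-
#' based coverage estimator, rare cutoff 10, via \pkg{vegan}) need integer
#' singleton/doubleton counts, so abundances are rescaled to pseudo-counts
#' totalling \code{pseudo_count_total} and rounded.
#'
#' @param x an [AbundanceExperiment-class] or samples-by-taxa matrix of
#'   relative abundances.
#' @param pseudo_count_total integer total the rows are rescaled to for the
#'   richness estimators (default 10000).
#' @param base logarithm base for Shannon: "ln" (nats, default) or "log2".
#' @return data.frame: sample_id, observed, chao1, ace, shannon, simpson.
#' @export
alphaDiversity <- function(x, pseudo_count_total = 10000,
                           base = c("ln", "log2")) {
  base <- match.arg(base)
  m <- .abMatrix(x)
  out <- data.frame(sample_id = rownames(m) %||% paste0("S", seq_len(nrow(m))))
  res <- t(apply(m, 1, function(p) {
    if (sum(p) <= 0) {
      warning("all-zero sample; indices set to 0")
      return(c(observed = 0, chao1 = 0, ace = 0, shannon = 0, simpson = 0))
    }
    p <- p / sum(p)
    pp <- p[p > 0]
    sh <- -sum(pp * log(pp))
    if (base == "log2") sh <- sh / log(2)
    counts <- round(p * pseudo_count_total)
    ace <- suppressWarnings(vegan::estimateR(counts)[["S.ACE"]])
    if (!is.finite(ace)) ace <- sum(counts > 0)
    c(observed = sum(p > 0), chao1 = .chao1(counts), ace = ace,
      shannon = sh, simpson = 1 - sum(pp^2))
  }))
  cbind(out, as.data.frame(res))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Compare alpha-diversity indices between two groups
#'
#' Two-sided Wilcoxon rank-sum test per index (exact when sample sizes allow
#' and there are no ties, otherwise the normal approximation with tie
#' correction).
#'
#' @param div output of [alphaDiversity()].
#' @param groups factor of group labels, parallel to the rows of \code{div}.
#' @return data.frame: index, W statistic, p_value.
#' @export
compareAlpha <- function(div, groups) {
  groups <- factor(groups)
  if (nlevels(groups) != 2 || any(table(groups) < 2))
    stop("input error: need two groups with n >= 2 each")
  idx <- c("observed", "chao1", "ace", "shannon", "simpson")
  res <- lapply(idx, function(i) {
    # ties fall back to the normal approximation with tie correction
    w <- suppressWarnings(stats::wilcox.test(div[[i]] ~ groups, exact = NULL))
    data.frame(index = i, W = unname(w$statistic), p_value = w$p.value)
  })
  do.call(rbind, res)
}

#' Bray-Curtis dissimilarity matrix
#'
#' \code{d(i,j) = sum|x_i - x_j| / sum(x_i + x_j)} via \code{vegan::vegdist}.
#' A pair of all-zero samples has undefined dissimilarity; it is set to 0 and
#' flagged in \code{attr(d, "zero_pairs")}.
#'
#' @param x an [AbundanceExperiment-class] or samples-by-taxa matrix.
#' @return a \code{dist} object in \code{[0, 1]}.
#' @export
brayCurtis <- function(x) {
  m <- .abMatrix(x)
  if (any(m < 0)) stop("input error: negative abundances")
  d <- suppressWarnings(vegan::vegdist(m, method = "bray"))
  if (anyNA(d)) {
    attr(d, "zero_pairs") <- sum(is.na(d))
    d[is.na(d)] <- 0
  }
  d
}

#' Principal coordinates analysis (classical metric scaling)
#'
#' Double-centres \code{-D^2/2} and eigendecomposes (via
#' \code{stats::cmdscale}). Negative eigenvalues are reported as-is (no
#' Cailliez/Lingoes correction); explained-variance fractions use only the
#' positive eigenvalues in the denominator.
#'
#' @param d a \code{dist} or square symmetric matrix.
#' @param k number of axes to keep (default all informative ones).
#' @return list of class \code{"chipbiome_ordination"}: coordinates (samples
#'   x axes, ordered by descending eigenvalue), eigenvalues, explained,
#'   method = "PCoA".
#' @export
pcoaOrdination <- function(d, k = NULL) {
  if (is.matrix(d)) {
    if (!isSymmetric(unname(d))) stop("input error: distance matrix not symmetric")
    d <- stats::as.dist(d)
  }
  n <- attr(d, "Size")
  k <- k %||% (n - 1)
  fit <- stats::cmdscale(d, k = k, eig = TRUE)
  eig <- fit$eig
  pos <- eig[eig > 1e-12]
  keep <- seq_len(min(k, length(pos)))
  coords <- fit$points[, keep, drop = FALSE]
  colnames(coords) <- paste0("PCo", keep)
  structure(list(coordinates = coords, eigenvalues = eig,
                 explained = eig[keep] / sum(pos), stress = NA_real_,
                 method = "PCoA"),
            class = "chipbiome_ordination")
}

#' Non-metric multidimensional scaling
#'
#' Kruskal stress-1 minimisation (via \code{vegan::metaMDS} /
#' \code{monoMDS}) from multiple random starts; the lowest-stress solution is
#' returned. Deterministic under a fixed seed.
#'
#' @param d a \code{dist} or square symmetric matrix.
#' @param k embedding dimension (default 2).
#' @param n_starts maximum random starts (default 20).
#' @param seed RNG seed.
#' @return list of class \code{"chipbiome_ordination"}: coordinates, stress
#'   in \code{[0, 1]}, method = "NMDS".
#' @export
nmdsOrdination <- function(d, k = 2, n_starts = 20, seed = 42) {
  if (is.matrix(d)) {
    if (!isSymmetric(unname(d))) stop("input error: distance matrix not symmetric")
    d <- stats::as.dist(d)
  }
  set.seed(seed)
  fit <- suppressWarnings(
    vegan::metaMDS(d, k = k, try = n_starts, trymax = n_starts,
                   trace = 0, autotransform = FALSE, wascores = FALSE))
  coords <- vegan::scores(fit, display = "sites")
  colnames(coords) <- paste0("NMDS", seq_len(ncol(coords)))
  structure(list(coordinates = coords, eigenvalues = NULL,
                 explained = NULL, stress = fit$stress, method = "NMDS"),
            class = "chipbiome_ordination")
}

#' @export
print.chipbiome_ordination <- function(x, ...) {
  cat(x$method, "ordination:", nrow(x$coordinates), "samples,",
      ncol(x$coordinates), "axes\n")
  if (x$method == "NMDS") cat("  stress:", signif(x$stress, 3), "\n")
  else cat("  explained:", paste(signif(x$explained, 3), collapse = ", "), "\n")
  invisible(x)
}

#' PERMANOVA on a distance matrix
#'
#' Permutational multivariate analysis of variance (via
#' \code{vegan::adonis2}): pseudo-F from the within/between sum-of-squares
#' partition of the distance matrix, p-value as
#' \code{(1 + #permutations with F >= F_obs) / (1 + n_permutations)} under
#' freely permuted labels.
#'
#' @param d a \code{dist} or square symmetric matrix.
#' @param groups factor of group labels.
#' @param n_permutations number of label permutations (default 999).
#' @param seed RNG seed.
#' @return list: pseudo_F, p_value, n_permutations, R2.
#' @export
permanovaTest <- function(d, groups, n_permutations = 999, seed = 42) {
  if (is.matrix(d)) d <- stats::as.dist(d)
  groups <- factor(groups)
  if (any(table(groups) < 2)) stop("input error: need >= 2 samples per group")
  if (max(d) - min(d) < 1e-12)
    stop("constant distances: pseudo-F undefined")
  set.seed(seed)
  df <- data.frame(group = groups)
  fit <- vegan::adonis2(d ~ group, data = df, permutations = n_permutations)
  list(pseudo_F = fit$F[1], p_value = fit$`Pr(>F)`[1],
       n_permutations = n_permutations, R2 = fit$R2[1])
}
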