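# LEfSe-style differential abundance: Kruskal-Wallis screen followed by
# bootstrapped linear-discriminant effect sizes on abundances rescaled to a
# per-sample total of 1e6. The study design is two-group, so the subclass
# Wilcoxon step of the published cascade degenerates to the screen and is a
# pass-through (a hook is kept for subclass structure).

#' Kruskal-Wallis screen over taxa
#'
#' Per-taxon Kruskal-Wallis test (tie-corrected H, chi-square p), equivalent
#' to the Wilcoxon rank-sum test for two groups. Taxa constant across all
#' samples get p = 1 and are flagged.
#'
#' @param x an [AbundanceExperiment-class] or samples-by-taxa matrix.
#' @param groups factor of group labels.
#' @return data.frame: taxon, statistic, p_value, constant.
#' @export
kruskalWallisScreen <- function(x, groups) {
  m <- .abMatrix(x)
  groups <- factor(groups)
  if (nlevels(groups) < 2 || any(table(groups) < 2))
    stop("input error: need >= 2 groups with n >= 2")
  res <- apply(m, 2, function(v) {
    if (max(v) - min(v) == 0) return(c(NA_real_, 1, 1))
    k <- stats::kruskal.test(v, groups)
    c(unname(k$statistic), k$p.value, 0)
  })
  data.frame(taxon = colnames(m), statistic = res[1, ], p_value = res[2, ],
             constant = res[3, ] == 1, row.names = NULL,
             stringsAsFactors = FALSE)
}

# One LDA bootstrap round on the rescaled matrix: returns per-feature
# (|raw class-mean difference| + |scaled LD coefficient|)/2, the quantity the
# published effect-size procedure averages over rounds.
.ldaRound <- function(X, groups, idx) {
  Xs <- X[idx, , drop = FALSE]
  gs <- droplevels(groups[idx])
  # guard degenerate within-class variance: tiny jitter, flagged upstream
  regularized <- FALSE
  for (j in seq_len(ncol(Xs))) {
    if (any(tapply(Xs[, j], gs, stats::var) < 1e-10, na.rm = TRUE)) {
      Xs[, j] <- Xs[, j] + stats::rnorm(nrow(Xs), 0, max(stats::sd(Xs[, j]), 1) * 1e-5)
      regularized <- TRUE
    }
  }
  # compositional profiles are collinear by construction; lda warns, harmlessly
  z <- tryCatch(suppressWarnings(MASS::lda(Xs, grouping = gs, tol = 1e-10)),
                error = function(e) NULL)
  if (is.null(z)) return(NULL)
  w <- z$scaling[, 1]
  w <- w / sqrt(sum(w^2))
  ld <- drop(Xs %*% w)
  lev <- levels(gs)
  eff <- abs(mean(ld[gs == lev[1]]) - mean(ld[gs == lev[2]]))
  gm <- abs(colMeans(Xs[gs == lev[1], , drop = FALSE]) -
            colMeans(Xs[gs == lev[2], , drop = FALSE]))
  list(score = (gm + abs(w * eff)) / 2, regularized = regularized)
}

#' Bootstrapped LDA effect sizes for screened taxa
#'
#' Follows the published LEfSe effect-size procedure: per-sample profiles are
#' rescaled to a total of 1e6; over \code{n_boot} rounds a fraction
#' \code{subsample_frac} of each class is drawn and a two-class LDA fitted;
#' the per-taxon effect is the mean over rounds of (|raw class-mean
#' difference| + |unit-norm LD coefficient x LD class separation|)/2, and the
#' reported score is \code{sign * log10(1 + effect)} with the sign set by the
#' enriched group.
#'
#' @param x an [AbundanceExperiment-class] or samples-by-taxa matrix of
#'   relative abundances (rows summing to 1).
#' @param groups factor of group labels (two levels).
#' @param taxa taxa to score (normally those passing the screen).
#' @param n_boot bootstrap rounds (default 30).
#' @param subsample_frac per-class subsample fraction (default 2/3).
#' @param seed RNG seed.
#' @return data.frame: taxon, lda_score (signed log10), enriched_group,
#'   regularized.
#' @export
ldaEffectSize <- function(x, groups, taxa, n_boot = 30, subsample_frac = 2/3,
                          seed = 42) {
  m <- .abMatrix(x)
  groups <- factor(groups)
  stopifnot(nlevels(groups) == 2, all(taxa %in% colnames(m)))
  if (!length(taxa)) return(data.frame(taxon = character(),
                                       lda_score = numeric(),
                                       enriched_group = character(),
                                       regularized = logical()))
  set.seed(seed)
  X <- m * 1e6                      # per-mille-of-a-million scaling
  X <- X[, taxa, drop = FALSE]
  lev <- levels(groups)
  i1 <- which(groups == lev[1]); i2 <- which(groups == lev[2])
  n1 <- max(2L, ceiling(subsample_frac * length(i1)))
  n2 <- max(2L, ceiling(subsample_frac * length(i2)))
  acc <- matrix(0, 0, length(taxa))
  reg <- FALSE
  tries <- 0
  while (nrow(acc) < n_boot && tries < 10 * n_boot) {
    tries <- tries + 1
    idx <- c(sample(i1, n1), sample(i2, n2))
    r <- .ldaRound(X, groups, idx)
    if (is.null(r)) next
    acc <- rbind(acc, r$score)
    reg <- reg || r$regularized
  }
  if (!nrow(acc)) stop("LDA failed in every bootstrap round")
  eff <- colMeans(acc)
  mdiff <- colMeans(X[i1, , drop = FALSE]) - colMeans(X[i2, , drop = FALSE])
  enriched <- ifelse(mdiff >= 0, lev[1], lev[2])
  data.frame(taxon = taxa,
             lda_score = sign(mdiff) * log10(1 + abs(eff)),
             enriched_group = enriched, regularized = reg,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' LEfSe-style differential-abundance cascade
#'
#' Kruskal-Wallis screen at \code{alpha}, then [ldaEffectSize()] on the
#' survivors; taxa with \code{|lda_score| >= lda_threshold} are reported. No
#' multiple-testing correction by default (the cascade's convention); set
#' \code{adjust = TRUE} to add a Benjamini-Hochberg column and filter on it.
#'
#' @param x an [AbundanceExperiment-class] or samples-by-taxa matrix.
#' @param groups factor of group labels (two levels).
#' @param alpha screen significance level (default 0.05).
#' @param lda_threshold absolute log10 effect-size cutoff (default 2).
#' @param rank label recorded in the output (default "species").
#' @param n_boot,subsample_frac,seed passed to [ldaEffectSize()].
#' @param adjust apply Benjamini-Hochberg to the screen p-values.
#' @return data.frame: taxon, rank, kw_p (and kw_p_adj), lda_score,
#'   enriched_group — one row per reported taxon, by decreasing |lda_score|.
#' @export
lefse <- function(x, groups, alpha = 0.05, lda_threshold = 2,
                  rank = "species", n_boot = 30, subsample_frac = 2/3,
                  seed = 42, adjust = FALSE) {
  scr <- kruskalWallisScreen(x, groups)
  scr$kw_p_adj <- stats::p.adjust(scr$p_value, "BH")
  sig <- scr[!scr$constant &
               (if (adjust) scr$kw_p_adj else scr$p_value) < alpha, ]
  eff <- ldaEffectSize(x, groups, sig$taxon, n_boot = n_boot,
                       subsample_frac = subsample_frac, seed = seed)
  out <- merge(sig, eff, by = "taxon")
  out <- out[abs(out$lda_score) >= lda_threshold, ]
  out <- out[order(-abs(out$lda_score)), ]
  res <- data.frame(taxon = out$taxon, rank = rep(rank, nrow(out)),
                    kw_p = out$p_value,
                    kw_p_adj = out$kw_p_adj, lda_score = out$lda_score,
                    enriched_group = out$enriched_group,
                    row.names = NULL, stringsAsFactors = FALSE)
  if (!adjust) res$kw_p_adj <- NULL
  res
}

#' Rank-nested enrichment table for a cladogram
#'
#' Re-runs the cascade on abundances aggregated to genus, family and order
#' (via [aggregateToRank()]) and stacks the per-rank results with lineage
#' columns, the input a cladogram rendering needs.
#'
#' @param x a species-level [AbundanceExperiment-class] with taxonomy.
#' @param groups factor of group labels.
#' @param ... passed to [lefse()].
#' @return data.frame: taxon, rank, kw_p, lda_score, enriched_group, lineage.
#' @export
buildCladogramTable <- function(x, groups, ...) {
  stopifnot(is(x, "AbundanceExperiment"))
  tx <- taxonomy(x)
  ranks <- c("species", "genus", "family", "order")
  missing_rank <- setdiff(c("genus", "family", "order"), colnames(tx))
  if (length(missing_rank)) {
    warning("lineage incomplete (", paste(missing_rank, collapse = ", "),
            "); reporting species level only")
    ranks <- "species"
  }
  pieces <- lapply(ranks, function(r) {
    xr <- aggregateToRank(x, r)
    res <- lefse(xr, groups, rank = r, ...)
    if (!nrow(res)) return(res)
    if (r == "species") {
      lin <- tx[match(res$taxon, rownames(x)), , drop = FALSE]
      res$lineage <- paste(lin$order, lin$family, lin$genus, res$taxon, sep = "|")
    } else {
      lin <- taxonomy(xr)[match(res$taxon, rownames(xr)), , drop = FALSE]
      res$lineage <- switch(r,
        genus = paste(lin$order, lin$family, res$taxon, sep = "|"),
        family = paste(lin$order, res$taxon, sep = "|"),
        order = res$taxon)
    }
    res
  })
  do.call(rbind, pieces[vapply(pieces, nrow, 1L) > 0])
}
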