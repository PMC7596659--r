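# Cross-platform validation: delta-Ct qPCR relative quantification against
# array calls, and species-cytokine Spearman correlation.

#' Delta-Ct qPCR relative abundance
#'
#' \code{2^(ct_universal - ct_specific) * 10000}: the species-specific signal
#' referenced to a universal 16S amplification of the same sample, scaled so
#' that equal threshold cycles read 10,000. Censored (no-amplification)
#' specific reactions return 0.
#'
#' @param ct_universal universal-primer threshold cycle(s).
#' @param ct_specific species-specific threshold cycle(s).
#' @param censored logical, specific reaction(s) failed to amplify.
#' @return relative abundance value(s), vectorised.
#' @examples
#' qpcrRelativeAbundance(20, 20)   # 10000
#' qpcrRelativeAbundance(20, 21)   # 5000
#' @export
qpcrRelativeAbundance <- function(ct_universal, ct_specific,
                                  censored = FALSE) {
  if (any(is.na(ct_universal))) stop("missing universal Ct")
  out <- 2^(ct_universal - ct_specific) * 10000
  out[rep_len(censored, length(out))] <- 0
  out
}

#' Quantify every target in a Ct table
#'
#' Pairs each sample's specific-target Ct with that sample's UNIVERSAL entry
#' and applies [qpcrRelativeAbundance()].
#'
#' @param ct data.frame sample_id, target, ct, censored (see
#'   [renderCtTable()] / [readCtTable()]).
#' @return data.frame: sample_id, target, value, censored.
#' @export
qpcrQuantify <- function(ct) {
  uni <- ct[ct$target == "UNIVERSAL", ]
  sp <- ct[ct$target != "UNIVERSAL", ]
  ctu <- uni$ct[match(sp$sample_id, uni$sample_id)]
  if (anyNA(ctu))
    stop("missing universal Ct for sample(s): ",
         paste(unique(sp$sample_id[is.na(ctu)]), collapse = ", "))
  data.frame(sample_id = sp$sample_id, target = sp$target,
             value = qpcrRelativeAbundance(ctu, sp$ct, sp$censored),
             censored = sp$censored,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Array vs qPCR concordance per target species
#'
#' For each target: a two-sided Wilcoxon rank-sum group test on each
#' platform, agreement of the group-median difference signs, and the
#' Spearman correlation between platforms across samples (censored qPCR
#' values excluded).
#'
#' @param x an [AbundanceExperiment-class].
#' @param ct qPCR Ct table.
#' @param groups factor of group labels, parallel to the samples of \code{x}.
#' @param targets species to compare (default: all specific targets in
#'   \code{ct} present on the array).
#' @return data.frame: target, p_array, p_qpcr, sign_array, sign_qpcr,
#'   sign_agree, rho, rho_p, n.
#' @export
comparePlatforms <- function(x, ct, groups, targets = NULL) {
  stopifnot(is(x, "AbundanceExperiment"))
  q <- qpcrQuantify(ct)
  groups <- factor(groups)
  if (is.null(targets)) targets <- unique(q$target)
  miss <- setdiff(targets, rownames(x))
  if (length(miss)) {
    warning("target(s) missing on array, skipped: ",
            paste(miss, collapse = ", "))
    targets <- setdiff(targets, miss)
  }
  rows <- lapply(targets, function(tg) {
    arr <- abundances(x)[tg, ]
    qt <- q[q$target == tg, ]
    qv <- qt$value[match(colnames(x), qt$sample_id)]
    keep <- !is.na(qv) & !qt$censored[match(colnames(x), qt$sample_id)]
    meddiff <- function(v, g) {
      d <- stats::median(v[g == levels(groups)[1]]) -
           stats::median(v[g == levels(groups)[2]])
      sign(d)
    }
    p_arr <- stats::wilcox.test(arr ~ groups, exact = FALSE)$p.value
    p_q <- stats::wilcox.test(qv[keep] ~ groups[keep], exact = FALSE)$p.value
    s_arr <- meddiff(arr, groups); s_q <- meddiff(qv[keep], groups[keep])
    rho <- if (stats::sd(arr[keep]) == 0 || stats::sd(qv[keep]) == 0) {
      warning("constant platform values for ", tg, "; rho undefined")
      c(NA_real_, NA_real_)
    } else {
      ctest <- suppressWarnings(
        stats::cor.test(arr[keep], qv[keep], method = "spearman",
                        exact = FALSE))
      c(unname(ctest$estimate), ctest$p.value)
    }
    data.frame(target = tg, p_array = p_arr, p_qpcr = p_q,
               sign_array = s_arr, sign_qpcr = s_q,
               sign_agree = s_arr == s_q,
               rho = rho[1], rho_p = rho[2], n = sum(keep),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Species-cytokine Spearman correlation table
#'
#' Rank correlation (average-rank ties, two-sided p by the t approximation)
#' between every species and every cytokine, within one group (case-only by
#' default, matching how such panels are usually screened). Constant
#' variables yield NA rho and are flagged. Raw p-values carry significance
#' tiers (* p < 0.05, ** p < 0.01); a Benjamini-Hochberg column is added for
#' transparency but not used for filtering.
#'
#' @param x an [AbundanceExperiment-class] or samples-by-taxa matrix.
#' @param metadata data.frame with sample_id, group and cytokine columns.
#' @param cytokines cytokine column names (default: the six-panel names
#'   present in \code{metadata}).
#' @param group group to correlate within, or \code{"all"} for every sample
#'   (default \code{"ALL"}).
#' @param min_n minimum samples required after filtering (default 3).
#' @return data.frame: species, cytokine, rho, p_value, p_adj, tier,
#'   constant.
#' @export
spearmanMatrix <- function(x, metadata, cytokines = NULL, group = "ALL",
                           min_n = 3) {
  m <- .abMatrix(x)
  idx <- match(rownames(m), metadata$sample_id)
  if (anyNA(idx)) stop("metadata missing sample(s)")
  md <- metadata[idx, , drop = FALSE]
  if (is.null(cytokines))
    cytokines <- intersect(c("IL-1B", "IL-2R", "IL-6", "IL-8", "IL-10",
                             "TNF-a"), colnames(md))
  if (!length(cytokines)) stop("no cytokine columns found")
  keep <- if (identical(group, "all")) rep(TRUE, nrow(md)) else md$group == group
  if (sum(keep) < min_n)
    stop("input error: fewer than ", min_n, " samples in group '", group, "'")
  m <- m[keep, , drop = FALSE]; md <- md[keep, , drop = FALSE]
  grid <- expand.grid(species = colnames(m), cytokine = cytokines,
                      stringsAsFactors = FALSE)
  res <- t(mapply(function(sp, cy) {
    a <- m[, sp]; b <- md[[cy]]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(c(NA_real_, NA_real_, 1))
    ct <- suppressWarnings(stats::cor.test(a, b, method = "spearman",
                                           exact = FALSE))
    c(unname(ct$estimate), ct$p.value, 0)
  }, grid$species, grid$cytokine))
  out <- data.frame(grid, rho = res[, 1], p_value = res[, 2],
                    constant = res[, 3] == 1, row.names = NULL)
  out$p_adj <- stats::p.adjust(out$p_value, "BH")
  out$tier <- ifelse(!is.na(out$p_value) & out$p_value < 0.01, "**",
                     ifelse(!is.na(out$p_value) & out$p_value < 0.05, "*", ""))
  out[, c("species", "cytokine", "rho", "p_value", "p_adj", "tier", "constant")]
}
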