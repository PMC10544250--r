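# Age-corrected cross-group testing: Kruskal-Wallis across clinical groups,
# Dunn's post hoc pairwise z tests on the same midranks (with tie
# correction), Benjamini-Hochberg adjustment, and the age-versus-disease
# feature partition.

# internal: Dunn z for one pair from pooled midranks
dunn_z <- function(ranks, groups, g1, g2, tie_term, N) {
  r1 <- ranks[groups == g1]
  r2 <- ranks[groups == g2]
  se <- sqrt((N * (N + 1) / 12 - tie_term / (12 * (N - 1))) *
               (1 / length(r1) + 1 / length(r2)))
  (mean(r1) - mean(r2)) / se
}

#' Kruskal-Wallis and Dunn's post hoc tests per feature
#'
#' For each feature: a Kruskal-Wallis H test (midranks, tie-corrected)
#' across the clinical groups, followed by Dunn's pairwise z tests on the
#' same ranks for the requested comparisons, with a Benjamini-Hochberg
#' adjustment. The default adjustment family is global (all features x all
#' requested pairs jointly, the more conservative choice); `"per_pair"`
#' adjusts each pair's p values across features separately.
#'
#' @param values Subjects x features matrix (typically age-corrected
#'   centiles from [centile_transform()]; any strictly monotone transform
#'   of the pooled values gives identical results).
#' @param groups Factor of group memberships, one per subject.
#' @param comparisons List of length-2 character vectors of group pairs, or
#'   `"all"` for every pair of represented groups.
#' @param adjust_family `"global"` or `"per_pair"`.
#' @param effect_pair Pair used for the reported direction and effect size
#'   (difference in mean value, second minus first... reported as
#'   `effect_pair[1]` minus `effect_pair[2]`).
#' @return Object of class `comparison_result`: list with `features`
#'   (feature, H, p_kw), `pairs` (feature, group1, group2, z, p_raw,
#'   p_adj), and `effects` (feature, direction, effect for `effect_pair`).
#' @export
kruskal_dunn <- function(values, groups, comparisons = "all",
                         adjust_family = c("global", "per_pair"),
                         effect_pair = c("T1D", "CTR")) {
  adjust_family <- match.arg(adjust_family)
  groups <- droplevels(factor(groups))
  counts <- table(groups)
  small <- names(counts)[counts < 2]
  if (length(small)) {
    warning("excluding group(s) with < 2 members: ", paste(small, collapse = ", "))
    keep <- !(groups %in% small)
    values <- values[keep, , drop = FALSE]
    groups <- droplevels(groups[keep])
  }
  if (nlevels(groups) < 2) stop("need at least 2 groups with >= 2 members",
                                call. = FALSE)
  gl <- levels(groups)
  if (identical(comparisons, "all")) {
    comparisons <- utils::combn(gl, 2, simplify = FALSE)
  }
  feats <- colnames(values) %||% as.character(seq_len(ncol(values)))
  feat_rows <- vector("list", ncol(values))
  pair_rows <- vector("list", ncol(values))
  eff_rows <- vector("list", ncol(values))
  for (j in seq_len(ncol(values))) {
    v <- values[, j]
    ok <- !is.na(v)
    vj <- v[ok]
    gj <- groups[ok]
    kw <- stats::kruskal.test(vj, gj)
    feat_rows[[j]] <- data.frame(feature = feats[j],
                                 H = unname(kw$statistic), p_kw = kw$p.value)
    rk <- rank(vj)
    N <- length(vj)
    tt <- table(vj)
    tie_term <- sum(tt^3 - tt)
    pr <- do.call(rbind, lapply(comparisons, function(cp) {
      if (!all(cp %in% gj)) return(NULL)
      z <- dunn_z(rk, gj, cp[1], cp[2], tie_term, N)
      data.frame(feature = feats[j], group1 = cp[1], group2 = cp[2],
                 z = z, p_raw = 2 * stats::pnorm(-abs(z)))
    }))
    pair_rows[[j]] <- pr
    if (all(effect_pair %in% gj)) {
      m1 <- vj[gj == effect_pair[1]]
      m2 <- vj[gj == effect_pair[2]]
      eff_rows[[j]] <- data.frame(
        feature = feats[j],
        direction = sign(stats::median(m1) - stats::median(m2)),
        effect = mean(m1) - mean(m2)
      )
    }
  }
  pairs <- do.call(rbind, pair_rows)
  if (adjust_family == "global") {
    pairs$p_adj <- stats::p.adjust(pairs$p_raw, method = "BH")
  } else {
    key <- paste(pairs$group1, pairs$group2)
    pairs$p_adj <- stats::ave(pairs$p_raw, key,
                              FUN = function(p) stats::p.adjust(p, "BH"))
  }
  structure(list(
    features = do.call(rbind, feat_rows),
    pairs = pairs,
    effects = do.call(rbind, eff_rows)
  ), class = "comparison_result")
}

#' Partition features into age- and disease-associated classes
#'
#' Combines the Spearman age screen (BH FDR on its p values) with the
#' age-corrected disease comparison (adjusted p for the disease pair) to
#' label every feature `age-only`, `disease-only`, `both`, or `neither` —
#' the axes of the age-versus-disease feature map.
#'
#' @param age_screen Data frame from [spearman_age_screen()].
#' @param comparison A `comparison_result` from [kruskal_dunn()].
#' @param age_fdr BH FDR threshold for the age flag.
#' @param disease_alpha Adjusted-p threshold for the disease flag.
#' @param disease_pair Group pair defining the disease comparison.
#' @return Object of class `feature_partition`: list with `features` (data
#'   frame: feature, age_associated, disease_associated, label, signed age
#'   and disease effect magnitudes) and `counts` (named label counts).
#' @export
partition_features <- function(age_screen, comparison, age_fdr = 0.05,
                               disease_alpha = 0.05,
                               disease_pair = c("T1D", "CTR")) {
  dis <- comparison$pairs[comparison$pairs$group1 == disease_pair[1] &
                            comparison$pairs$group2 == disease_pair[2], ]
  feats <- age_screen$feature
  if (!setequal(feats, dis$feature)) {
    missing_f <- union(setdiff(feats, dis$feature), setdiff(dis$feature, feats))
    stop("feature(s) missing from one input: ", paste(missing_f, collapse = ", "),
         call. = FALSE)
  }
  dis <- dis[match(feats, dis$feature), ]
  age_q <- stats::p.adjust(age_screen$p, method = "BH")
  age_flag <- !is.na(age_q) & age_q < age_fdr
  dis_flag <- !is.na(dis$p_adj) & dis$p_adj < disease_alpha
  label <- ifelse(age_flag & dis_flag, "both",
           ifelse(age_flag, "age-only",
           ifelse(dis_flag, "disease-only", "neither")))
  eff <- comparison$effects
  eff <- eff[match(feats, eff$feature), ]
  out <- data.frame(
    feature = feats, age_associated = age_flag, disease_associated = dis_flag,
    label = factor(label, levels = c("age-only", "disease-only", "both", "neither")),
    age_effect = age_screen$rho, disease_effect = eff$effect
  )
  structure(list(features = out, counts = table(out$label)),
            class = "feature_partition")
}
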