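#' Disease-stage classification
#'
#' Assigns the study groups from the FIB-4 score and decompensation history:
#' a chronic-liver-disease subject is ACLD iff FIB-4 >= 1.75 (closed cutoff)
#' and/or a previous or current decompensation episode; otherwise non-ACLD.
#' ACLD splits into compensated/decompensated per the decompensation flag,
#' and FIB-4 risk categories are low < 1.3, intermediate 1.3-2.67
#' (inclusive), high > 2.67.
#'
#' @param scores A `score_panel` (or anything with a `fib4` element).
#' @param decompensated Logical decompensation history.
#' @param cld Logical; is the subject a chronic-liver-disease patient?
#'   Controls bypass staging.
#' @return List with `group` (`control` / `non-ACLD` / `ACLD`), `acld_stage`
#'   (`compensated` / `decompensated`, `NA` otherwise) and `fib4_category`
#'   (`low` / `intermediate` / `high`). A CLD subject with missing FIB-4 and
#'   no decompensation history is explicitly `unclassifiable`.
#' @export
classify_stage <- function(scores, decompensated = FALSE, cld = TRUE) {
  fib4 <- if (is.list(scores)) scores$fib4 else scores
  decompensated <- isTRUE(decompensated)
  if (!cld)
    return(list(group = "control", acld_stage = NA_character_,
                fib4_category = NA_character_))
  if (is.na(fib4) && !decompensated)
    return(list(group = "unclassifiable", acld_stage = NA_character_,
                fib4_category = NA_character_))
  acld <- decompensated || (!is.na(fib4) && fib4 >= 1.75)
  cat <- if (is.na(fib4)) NA_character_
         else if (fib4 < 1.3) "low"
         else if (fib4 <= 2.67) "intermediate"
         else "high"
  list(group = if (acld) "ACLD" else "non-ACLD",
       acld_stage = if (acld) {
         if (decompensated) "decompensated" else "compensated"
       } else NA_character_,
       fib4_category = cat)
}

#' Median and interquartile range
#'
#' Quartiles by linear interpolation (the common type-7 convention).
#'
#' @param values Numeric vector; `NA`s dropped; at least one finite value.
#' @return Named numeric vector `median`, `q1`, `q3`.
#' @export
median_iqr <- function(values) {
  v <- values[is.finite(values)]
  if (length(v) == 0L)
    stop_hepavol("hepavol_empty_input", "no finite values")
  q <- quantile(v, c(0.5, 0.25, 0.75), names = FALSE, type = 7)
  c(median = q[1], q1 = q[2], q3 = q[3])
}

#' Kruskal-Wallis test across groups
#'
#' Rank-based H with tie correction and a chi-square p-value with k-1
#' degrees of freedom (delegates to [stats::kruskal.test()]). Fully
#' degenerate input (all values identical) is reported as H = 0, p = 1.
#'
#' @param groups List of numeric vectors, each non-empty.
#' @return List with `H`, `p`, `df`.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (any(vapply(groups, length, 1L) == 0L))
    stop_hepavol("hepavol_empty_input", "every group needs >= 1 value")
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, 1L)))
  if (length(unique(x)) == 1L)
    return(list(H = 0, p = 1, df = length(groups) - 1L))
  kt <- kruskal.test(x, g)
  list(H = unname(kt$statistic), p = kt$p.value, df = unname(kt$parameter))
}

# Two-sided Mann-Whitney U p-value. Exact enumeration when both groups are
# small (<= 8) and tie-free; otherwise the normal approximation with tie and
# continuity correction.
mwu_p <- function(a, b) {
  exact <- length(a) <= 8 && length(b) <= 8 &&
    !anyDuplicated(c(a, b))
  wt <- suppressWarnings(wilcox.test(a, b, exact = exact, correct = TRUE))
  wt$p.value
}

#' Pairwise Mann-Whitney tests with Bonferroni correction
#'
#' Two-sided U tests for each requested pair of groups; corrected
#' p = min(1, raw x number of pairs).
#'
#' @param groups Named list of numeric vectors.
#' @param pairs List of length-2 character vectors naming the comparisons;
#'   default all pairs.
#' @return Data.frame with `a`, `b`, `p_raw`, `p_bonferroni` (`NA` for
#'   degenerate pairs, i.e. an empty group).
#' @export
pairwise_mwu_bonferroni <- function(groups, pairs = NULL) {
  stopifnot(is.list(groups), !is.null(names(groups)))
  if (is.null(pairs)) {
    nm <- names(groups)
    pairs <- list()
    for (i in seq_along(nm)) for (j in seq_len(i - 1L))
      pairs[[length(pairs) + 1L]] <- c(nm[j], nm[i])
  }
  m <- length(pairs)
  res <- lapply(pairs, function(pr) {
    a <- groups[[pr[1]]]; b <- groups[[pr[2]]]
    p <- if (length(a) == 0L || length(b) == 0L) NA_real_ else mwu_p(a, b)
    data.frame(a = pr[1], b = pr[2], p_raw = p,
               p_bonferroni = pmin(1, p * m), stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Percent decrease between two group medians
#'
#' `100 (median_ref - median_new) / median_ref`, reported to one decimal;
#' positive for decreases.
#'
#' @param median_ref Reference (earlier-stage) median; must be > 0.
#' @param median_new Comparison median.
#' @return Percent decrease, rounded to one decimal.
#' @examples
#' percent_decrease(3.9, 2.8)  # 28.2
#' @export
percent_decrease <- function(median_ref, median_new) {
  if (!is.finite(median_ref) || median_ref <= 0)
    stop_hepavol("hepavol_empty_input", "reference median must be > 0")
  unname(round(100 * (median_ref - median_new) / median_ref, 1))
}

#' Spearman rank correlation with t-approximation p-value
#'
#' rho as the Pearson correlation of midranks; two-sided p from
#' t = rho sqrt((n-2)/(1-rho^2)) with n-2 degrees of freedom. Pairs with
#' missing values are dropped (pairwise-complete); fewer than 3 complete
#' pairs gives `NA`.
#'
#' @param x,y Numeric vectors of equal length.
#' @return List with `rho`, `p`, `n`.
#' @export
spearman_rho <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  n <- sum(ok)
  if (n < 3L) return(list(rho = NA_real_, p = NA_real_, n = n))
  r <- cor(rank(x[ok]), rank(y[ok]))
  if (abs(r) >= 1) return(list(rho = r, p = 0, n = n))
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  list(rho = r, p = 2 * pt(-abs(tstat), n - 2), n = n)
}

#' Correlation map between VVRs and biomarkers
#'
#' Spearman rho and uncorrected p for every VVR x biomarker pair,
#' pairwise-complete over missing biomarkers (liver stiffness and HVPG are
#' available only in subsets).
#'
#' @param vvr_table Data.frame of per-subject VVRs (columns used: any of
#'   `tvvr_pct`, `hvvr_pct`, `pvvr_pct`).
#' @param biomarker_table Data.frame of per-subject biomarkers, same row
#'   order.
#' @param subgroup Optional logical vector selecting a subject subset.
#' @return Data.frame with `vvr`, `biomarker`, `rho`, `p`, `n`.
#' @export
spearman_map <- function(vvr_table, biomarker_table, subgroup = NULL) {
  if (nrow(vvr_table) != nrow(biomarker_table))
    stop_hepavol("hepavol_shape_mismatch", "tables must have equal rows")
  if (!is.null(subgroup)) {
    vvr_table <- vvr_table[subgroup, , drop = FALSE]
    biomarker_table <- biomarker_table[subgroup, , drop = FALSE]
  }
  vv <- intersect(c("tvvr_pct", "hvvr_pct", "pvvr_pct"), names(vvr_table))
  out <- list()
  for (v in vv) for (b in names(biomarker_table)) {
    if (!is.numeric(biomarker_table[[b]])) next
    s <- spearman_rho(vvr_table[[v]], biomarker_table[[b]])
    out[[length(out) + 1L]] <- data.frame(vvr = v, biomarker = b,
                                          rho = s$rho, p = s$p, n = s$n,
                                          stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# One VVR variable through the whole group-comparison machinery.
compare_groups_one <- function(values, grp, levels) {
  gs <- lapply(levels, function(g)
    values[which(grp == g & is.finite(values))])
  names(gs) <- levels
  nonempty <- vapply(gs, length, 1L) > 0
  med <- lapply(gs, function(v) if (length(v)) median_iqr(v) else
    c(median = NA_real_, q1 = NA_real_, q3 = NA_real_))
  kw <- if (sum(nonempty) >= 2) kruskal_wallis(gs[nonempty])
        else list(H = NA_real_, p = NA_real_, df = NA_integer_)
  pw <- pairwise_mwu_bonferroni(gs)
  # percent decreases between successive / extreme group medians
  dec <- NULL
  cmb <- utils::combn(seq_along(levels), 2)
  for (k in seq_len(ncol(cmb))) {
    i <- cmb[1, k]; j <- cmb[2, k]
    m1 <- med[[i]]["median"]; m2 <- med[[j]]["median"]
    d <- if (is.finite(m1) && m1 > 0 && is.finite(m2))
      percent_decrease(m1, m2) else NA_real_
    dec <- rbind(dec, data.frame(from = levels[i], to = levels[j],
                                 percent_decrease = unname(d),
                                 stringsAsFactors = FALSE))
  }
  list(median_iqr = med, kruskal_wallis = kw, pairwise = pw,
       percent_decreases = dec)
}

#' Full cohort statistics report
#'
#' Per-group median/IQR, Kruskal-Wallis, Bonferroni-corrected pairwise
#' Mann-Whitney tests and percent decreases for each VVR, plus the Spearman
#' correlation maps for the whole CLD cohort and the two CLD subgroups.
#'
#' @param cohort Cohort data.frame ([simulate_cohort()] layout, scores
#'   included).
#' @param vvr Data.frame of measured per-subject VVRs (`tvvr_pct`,
#'   `hvvr_pct`, `pvvr_pct`), same row order as `cohort`.
#' @return A `cohort_stats_report` list: `groups`, per-VVR comparison
#'   blocks, and `spearman` (list of maps: `cld`, `non_acld`, `acld`).
#' @export
cohort_stats <- function(cohort, vvr) {
  levels <- c("control", "non-ACLD", "ACLD")
  grp <- factor(cohort$group, levels = levels)
  comparisons <- lapply(c(tvvr = "tvvr_pct", hvvr = "hvvr_pct",
                          pvvr = "pvvr_pct"),
                        function(col) compare_groups_one(vvr[[col]], grp, levels))
  biom <- cohort[, intersect(c("albumin", "bilirubin", "platelets", "fib4",
                               "albi", "meld_na", "lsm_kpa", "hvpg_mmhg",
                               "spleen_volume_cc"), names(cohort)),
                 drop = FALSE]
  cld <- cohort$group %in% c("non-ACLD", "ACLD")
  spearman <- list(
    cld = spearman_map(vvr, biom, cld),
    non_acld = spearman_map(vvr, biom, cohort$group == "non-ACLD"),
    acld = spearman_map(vvr, biom, cohort$group == "ACLD"))
  structure(list(groups = levels, n = table(grp), comparisons = comparisons,
                 spearman = spearman),
            class = "cohort_stats_report")
}

#' Subgroup analyses by clinical stage and FIB-4 category
#'
#' Applies the same Kruskal-Wallis + pairwise machinery to the CLD cohort
#' partitioned (a) by clinical disease stage — non-ACLD, compensated ACLD,
#' decompensated ACLD — and (b) by FIB-4 risk category (low, intermediate,
#' high). Empty subgroups mark their comparisons undefined (`NA`) and the
#' run continues.
#'
#' @param cohort Cohort data.frame with `group`, `decompensated`, `fib4`.
#' @param vvr Per-subject VVR data.frame, same row order.
#' @return List with `stage` and `fib4_category` blocks (per VVR).
#' @export
subgroup_analyses <- function(cohort, vvr) {
  cld <- cohort$group %in% c("non-ACLD", "ACLD")
  stage <- ifelse(!cld, NA,
           ifelse(cohort$group == "non-ACLD", "non-ACLD",
           ifelse(cohort$decompensated %in% TRUE, "dACLD", "cACLD")))
  fib_cat <- vapply(seq_len(nrow(cohort)), function(i) {
    if (!cld[i]) return(NA_character_)
    f <- cohort$fib4[i]
    if (!is.finite(f)) NA_character_
    else if (f < 1.3) "low" else if (f <= 2.67) "intermediate" else "high"
  }, character(1))
  run <- function(partition, levels) {
    grp <- factor(partition, levels = levels)
    lapply(c(tvvr = "tvvr_pct", hvvr = "hvvr_pct", pvvr = "pvvr_pct"),
           function(col) compare_groups_one(vvr[[col]], grp, levels))
  }
  list(stage = run(stage, c("non-ACLD", "cACLD", "dACLD")),
       fib4_category = run(fib_cat, c("low", "intermediate", "high")))
}

#' @export
print.cohort_stats_report <- function(x, ...) {
  cat("<cohort_stats_report>\n")
  for (nm in names(x$comparisons)) {
    cmp <- x$comparisons[[nm]]
    meds <- vapply(cmp$median_iqr, function(m)
      sprintf("%.2f (%.2f-%.2f)", m["median"], m["q1"], m["q3"]), "")
    cat(sprintf("  %s: %s | KW p = %.3g\n", toupper(nm),
                paste(paste(x$groups, meds, sep = " "), collapse = ", "),
                cmp$kruskal_wallis$p))
  }
  invisible(x)
}
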