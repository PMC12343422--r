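#' Calibrated biomarker marginals per study group
#'
#' Median and quartile levels of the clinical covariates for healthy
#' controls, non-advanced (non-ACLD) and advanced chronic liver disease
#' (ACLD) patients, plus the per-group vessel-to-volume-ratio (VVR) targets.
#' Skewed covariates are modelled as log-normal distributions matched to
#' median and interquartile range; age is Gaussian (mean, SD). AST/ALT are
#' not reported group-wise in the source tables; their levels were chosen
#' clinically plausible and such that the implied median FIB-4 reproduces
#' the reported group medians (0.8 non-ACLD, 3.5 ACLD). Liver stiffness and
#' hepatic venous pressure gradient carry availability fractions matching
#' the reported per-variable n.
#'
#' @return A data.frame with columns `group`, `variable`, `median`, `q1`,
#'   `q3`, `dist` (`"lognormal"` or `"normal"`), `available` (fraction of
#'   subjects with the measurement).
#' @export
group_marginals <- function() {
  row <- function(group, variable, median, q1, q3, dist = "lognormal",
                  available = 1) {
    data.frame(group = group, variable = variable, median = median,
               q1 = q1, q3 = q3, dist = dist, available = available,
               stringsAsFactors = FALSE)
  }
  rbind(
    # healthy controls: no laboratory panel, imaging volumes only
    row("control", "age", 62.5, NA, NA, dist = "normal"),  # SD in `q3` slot:
    row("control", "spleen_volume_cc", 130.2, 69.9, 218.9),
    row("control", "liver_volume_cc", 1289.5, 1113.9, 1663.0),
    row("control", "hvvr", 2.1, 1.8, 2.7),
    row("control", "pvvr", 1.7, 1.2, 1.9),

    row("non-ACLD", "age", 41.4, NA, NA, dist = "normal"),
    row("non-ACLD", "albumin", 4.22, 3.72, 4.50),
    row("non-ACLD", "bilirubin", 0.5, 0.4, 1.0),
    row("non-ACLD", "platelets", 295.5, 222.5, 355.0),
    row("non-ACLD", "ast", 30, 22, 42),
    row("non-ACLD", "alt", 28, 18, 45),
    row("non-ACLD", "sodium", 140, 138, 142),
    row("non-ACLD", "creatinine", 0.80, 0.68, 0.95),
    row("non-ACLD", "inr", 1.00, 0.95, 1.10),
    row("non-ACLD", "lsm", 7.9, 6.1, 11.8, available = 14 / 44),
    row("non-ACLD", "spleen_volume_cc", 232.1, 132.3, 330.7),
    row("non-ACLD", "liver_volume_cc", 1712.2, 1407.0, 2008.3),
    row("non-ACLD", "hvvr", 1.7, 1.1, 2.2),
    row("non-ACLD", "pvvr", 1.2, 0.9, 1.6),

    row("ACLD", "age", 57.7, NA, NA, dist = "normal"),
    row("ACLD", "albumin", 3.90, 3.30, 4.23),
    row("ACLD", "bilirubin", 1.0, 0.6, 2.1),
    row("ACLD", "platelets", 130.5, 81.2, 174.8),
    row("ACLD", "ast", 51, 35, 80),
    row("ACLD", "alt", 42, 25, 65),
    row("ACLD", "sodium", 138, 135, 141),
    row("ACLD", "creatinine", 0.90, 0.72, 1.10),
    row("ACLD", "inr", 1.20, 1.10, 1.40),
    row("ACLD", "lsm", 25.7, 13.1, 37.4, available = 51 / 118),
    row("ACLD", "hvpg", 16.0, 13.0, 21.8, available = 50 / 118),
    row("ACLD", "spleen_volume_cc", 405.1, 210.6, 695.5),
    row("ACLD", "liver_volume_cc", 1758.2, 1346.4, 2219.7),
    row("ACLD", "hvvr", 1.0, 0.7, 1.4),
    row("ACLD", "pvvr", 1.2, 0.9, 1.5)
  )
}

# Gaussian age parameters (mean, sd) and male fraction per group.
group_demographics <- function() {
  data.frame(group = c("control", "non-ACLD", "ACLD"),
             age_mean = c(62.5, 41.4, 57.7),
             age_sd = c(11.7, 12.6, 12.3),
             male_frac = c(0.343, 0.500, 0.653),
             decomp_frac = c(0, 0, 0.4),
             stringsAsFactors = FALSE)
}

#' Rank-correlation targets of the cohort copula
#'
#' Spearman correlation targets between the latent per-subject VVR values
#' and the biomarkers, encoding the reported sign structure: the hepatic
#' VVR correlates positively with albumin and platelet count and negatively
#' with bilirubin, AST, INR, liver stiffness and spleen volume (portal VVR
#' similarly but weaker), plus clinically sensible lab-lab dependencies
#' (AST-ALT, platelet-spleen, bilirubin-INR, ...).
#'
#' @return A symmetric positive-definite matrix with dimnames over
#'   `hvvr, pvvr, albumin, bilirubin, platelets, ast, alt, sodium,
#'   creatinine, inr, lsm, spleen_volume_cc, liver_volume_cc`.
#' @export
copula_spearman_targets <- function() {
  vars <- c("hvvr", "pvvr", "albumin", "bilirubin", "platelets", "ast",
            "alt", "sodium", "creatinine", "inr", "lsm",
            "spleen_volume_cc", "liver_volume_cc")
  R <- diag(length(vars))
  dimnames(R) <- list(vars, vars)
  set_r <- function(a, b, v) {
    R[a, b] <<- v
    R[b, a] <<- v
  }
  set_r("hvvr", "pvvr", 0.40)
  set_r("hvvr", "albumin", 0.30)
  set_r("hvvr", "bilirubin", -0.35)
  set_r("hvvr", "platelets", 0.40)
  set_r("hvvr", "ast", -0.25)
  set_r("hvvr", "sodium", 0.15)
  set_r("hvvr", "creatinine", -0.10)
  set_r("hvvr", "inr", -0.30)
  set_r("hvvr", "lsm", -0.40)
  set_r("hvvr", "spleen_volume_cc", -0.35)
  set_r("pvvr", "albumin", 0.22)
  set_r("pvvr", "bilirubin", -0.25)
  set_r("pvvr", "platelets", 0.18)
  set_r("pvvr", "ast", -0.12)
  set_r("pvvr", "inr", -0.18)
  set_r("pvvr", "lsm", -0.18)
  set_r("pvvr", "spleen_volume_cc", -0.20)
  set_r("albumin", "bilirubin", -0.30)
  set_r("albumin", "inr", -0.30)
  set_r("bilirubin", "inr", 0.35)
  set_r("bilirubin", "lsm", 0.25)
  set_r("platelets", "spleen_volume_cc", -0.45)
  set_r("ast", "alt", 0.60)
  set_r("lsm", "spleen_volume_cc", 0.30)
  set_r("lsm", "inr", 0.25)
  R
}

# Log-normal parameters matched to median and IQR.
lnorm_params <- function(median, q1, q3) {
  list(meanlog = log(median), sdlog = (log(q3) - log(q1)) / (2 * qnorm(0.75)))
}

# Draw n subjects of one group: latent Gaussian copula -> marginals.
simulate_group <- function(group, n, marginals, copula) {
  if (n == 0L) return(NULL)
  demo <- group_demographics()
  demo <- demo[demo$group == group, ]
  mg <- marginals[marginals$group == group, ]
  have <- intersect(colnames(copula), mg$variable)
  R <- copula[have, have, drop = FALSE]
  # Spearman target -> Pearson correlation of the latent Gaussians
  Rp <- 2 * sin(pi * R / 6)
  diag(Rp) <- 1
  L <- tryCatch(chol(Rp), error = function(e)
    stop_hepavol("hepavol_copula", "copula correlation not positive definite"))
  Z <- matrix(rnorm(n * length(have)), n) %*% L
  colnames(Z) <- have
  U <- pnorm(Z)
  out <- data.frame(row.names = seq_len(n))
  for (v in have) {
    m <- mg[mg$variable == v, ]
    p <- lnorm_params(m$median, m$q1, m$q3)
    x <- stats::qlnorm(U[, v], p$meanlog, p$sdlog)
    if (m$available < 1) { # missing-at-random availability subset
      x[runif(n) >= m$available] <- NA_real_
    }
    out[[v]] <- x
  }
  # variables outside the copula (ACLD hvpg), correlated with nothing
  for (v in setdiff(mg$variable, c(have, "age"))) {
    m <- mg[mg$variable == v, ]
    p <- lnorm_params(m$median, m$q1, m$q3)
    x <- rlnorm(n, p$meanlog, p$sdlog)
    if (m$available < 1) x[runif(n) >= m$available] <- NA_real_
    out[[v]] <- x
  }
  out$age <- pmax(18, rnorm(n, demo$age_mean, demo$age_sd))
  out$sex <- ifelse(runif(n) < demo$male_frac, "m", "f")
  out$decompensated <- if (group == "ACLD") runif(n) < demo$decomp_frac
                       else FALSE
  out$group <- group
  out
}

#' Simulate a single subject record
#'
#' Draws one subject of the given group from the calibrated marginals and
#' copula. For bulk simulation use [simulate_cohort()], which vectorises the
#' same machinery.
#'
#' @param group `"control"`, `"non-ACLD"` or `"ACLD"`.
#' @param effect_profile Marginal table as returned by [group_marginals()].
#' @param copula_spec Spearman target matrix as from
#'   [copula_spearman_targets()].
#' @param seed Integer seed.
#' @return A one-row data.frame (see [simulate_cohort()] for columns).
#' @export
simulate_subject <- function(group, effect_profile = group_marginals(),
                             copula_spec = copula_spearman_targets(),
                             seed = 1L) {
  if (!group %in% c("control", "non-ACLD", "ACLD"))
    stop_hepavol("hepavol_bad_group", "unknown group label '%s'", group)
  with_seed(seed, normalize_cohort(
    simulate_group(group, 1L, effect_profile, copula_spec)))
}

# Harmonize columns across groups and attach ids/scores.
normalize_cohort <- function(df) {
  cols <- c("subject_id", "group", "decompensated", "age", "sex", "albumin",
            "bilirubin", "platelets", "ast", "alt", "sodium", "creatinine",
            "inr", "lsm_kpa", "hvpg_mmhg", "spleen_volume_cc",
            "liver_volume_cc", "target_hvvr_pct", "target_pvvr_pct")
  names(df)[names(df) == "lsm"] <- "lsm_kpa"
  names(df)[names(df) == "hvpg"] <- "hvpg_mmhg"
  names(df)[names(df) == "hvvr"] <- "target_hvvr_pct"
  names(df)[names(df) == "pvvr"] <- "target_pvvr_pct"
  for (c in setdiff(cols, names(df))) df[[c]] <- rep(NA, nrow(df))
  df <- df[, cols, drop = FALSE]
  df
}

#' Simulate a study cohort
#'
#' Draws `n_control + n_non_acld + n_acld` subject records with group-specific
#' biomarker marginals, the configured rank-correlation structure, and
#' per-subject VVR targets drawn from group-specific log-normal distributions
#' centred on the published group medians. The default sizes are the study's
#' 35 / 44 / 118. Identical seeds give identical cohorts.
#'
#' @param n_control,n_non_acld,n_acld Group sizes (>= 0).
#' @param seed Integer seed.
#' @param effect_profile,copula_spec Calibration overrides; see
#'   [group_marginals()] and [copula_spearman_targets()].
#' @return A data.frame, one row per subject, with columns `subject_id`,
#'   `group`, `decompensated`, demographics, laboratory values (`NA` for
#'   controls and unavailable measurements), `lsm_kpa`, `hvpg_mmhg`, organ
#'   volumes, latent `target_hvvr_pct` / `target_pvvr_pct`, and the derived
#'   `fib4`, `albi`, `meld_na` scores.
#' @export
simulate_cohort <- function(n_control = 35L, n_non_acld = 44L,
                            n_acld = 118L, seed = 1L,
                            effect_profile = group_marginals(),
                            copula_spec = copula_spearman_targets()) {
  ns <- c(n_control, n_non_acld, n_acld)
  if (any(ns < 0))
    stop_hepavol("hepavol_bad_group", "group sizes must be >= 0")
  with_seed(seed, {
    parts <- list(simulate_group("control", n_control, effect_profile, copula_spec),
                  simulate_group("non-ACLD", n_non_acld, effect_profile, copula_spec),
                  simulate_group("ACLD", n_acld, effect_profile, copula_spec))
    parts <- Filter(Negate(is.null), lapply(parts, function(p)
      if (is.null(p)) NULL else normalize_cohort(p)))
    if (length(parts) == 0L) {
      df <- normalize_cohort(data.frame(group = character(0)))
    } else {
      df <- do.call(rbind, parts)
    }
    if (nrow(df) > 0) {
      df$subject_id <- sprintf("S%03d", seq_len(nrow(df)))
      df <- add_scores(df)
    } else {
      df$fib4 <- df$albi <- df$meld_na <- numeric(0)
    }
    rownames(df) <- NULL
    df
  })
}

#' Phantom specification for one simulated subject
#'
#' Maps a cohort row to a [phantom_spec()] carrying the subject's VVR
#' targets; geometry stays at the desk-scale default.
#'
#' @param record One cohort row.
#' @param seed Base seed; the subject index is folded in so every subject
#'   gets a distinct, reproducible phantom.
#' @param ... Overrides forwarded to [phantom_spec()].
#' @return A `phantom_spec`.
#' @export
phantom_spec_for_subject <- function(record, seed = 1L, ...) {
  idx <- suppressWarnings(as.integer(sub("^S", "", record$subject_id)))
  if (is.na(idx)) idx <- 0L
  phantom_spec(target_hvvr_pct = record$target_hvvr_pct,
               target_pvvr_pct = record$target_pvvr_pct,
               seed = child_seed(seed + 131L * idx, "phantom"),
               ...)
}
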