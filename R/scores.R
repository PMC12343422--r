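#' Clinical liver scores: FIB-4, ALBI, MELD-Na
#'
#' Computes the serum-based panel used to stage chronic liver disease:
#' \itemize{
#'   \item FIB-4 = age (years) x AST (U/L) / (platelets (Giga/L) x sqrt(ALT (U/L)))
#'   \item ALBI = 0.66 log10(bilirubin, umol/L) - 0.085 x albumin (g/L)
#'   \item MELD-Na, the UNOS sodium-adjusted variant:
#'     MELD = 10 (0.957 ln creatinine + 0.378 ln bilirubin + 1.120 ln INR + 0.643)
#'     with creatinine, bilirubin and INR floored at 1.0 and creatinine capped
#'     at 4.0 mg/dL; when MELD > 11,
#'     MELD-Na = MELD + 1.32 (137 - Na) - 0.033 MELD (137 - Na) with sodium
#'     clamped to 125-137 mmol/L; the result is clamped to 6-40 points.
#' }
#' Unit conversions are applied internally: bilirubin mg/dL -> umol/L
#' (x 17.1), albumin g/dL -> g/L (x 10).
#'
#' A missing laboratory value yields `NA` for every score depending on it —
#' an explicit missing-score marker, never a silent zero. Non-missing,
#' non-positive laboratory values are an error.
#'
#' @param record A one-row data.frame or named list with (a subset of)
#'   `age`, `ast`, `alt`, `platelets`, `albumin` (g/dL), `bilirubin` (mg/dL),
#'   `sodium` (mmol/L), `creatinine` (mg/dL), `inr`.
#' @return A `score_panel`: list with `fib4`, `albi`, `meld_na` (any of which
#'   may be `NA`).
#' @examples
#' compute_scores(list(age = 60, ast = 40, alt = 30, platelets = 150))$fib4
#' @export
compute_scores <- function(record) {
  g <- function(nm) {
    v <- record[[nm]]
    if (is.null(v) || length(v) == 0L) return(NA_real_)
    v <- as.numeric(v[1])
    if (!is.na(v) && v <= 0 && nm != "albi")
      stop_hepavol("hepavol_invalid_lab", "%s must be positive (got %g)", nm, v)
    v
  }
  age <- g("age"); ast <- g("ast"); alt <- g("alt"); plt <- g("platelets")
  alb <- g("albumin"); bili <- g("bilirubin"); na_mmol <- g("sodium")
  creat <- g("creatinine"); inr <- g("inr")

  fib4 <- if (anyNA(c(age, ast, alt, plt))) NA_real_
          else age * ast / (plt * sqrt(alt))

  albi <- if (anyNA(c(bili, alb))) NA_real_
          else 0.66 * log10(bili * 17.1) - 0.085 * (alb * 10)

  meld_na <- if (anyNA(c(bili, creat, inr, na_mmol))) NA_real_ else {
    cr <- min(max(creat, 1), 4)
    bi <- max(bili, 1)
    ir <- max(inr, 1)
    meld <- 10 * (0.957 * log(cr) + 0.378 * log(bi) + 1.120 * log(ir) + 0.643)
    meld <- min(max(meld, 6), 40)
    if (meld > 11) {
      na_c <- min(max(na_mmol, 125), 137)
      meld <- meld + 1.32 * (137 - na_c) - 0.033 * meld * (137 - na_c)
    }
    min(max(meld, 6), 40)
  }
  structure(list(fib4 = fib4, albi = albi, meld_na = meld_na),
            class = "score_panel")
}

#' Append score columns to a cohort table
#'
#' Row-wise [compute_scores()] over a cohort data.frame; adds `fib4`, `albi`
#' and `meld_na` columns (`NA` where the inputs are missing, e.g. controls
#' without laboratory panels).
#'
#' @param cohort Data.frame with the laboratory columns of [compute_scores()].
#' @return The cohort with three extra columns.
#' @export
add_scores <- function(cohort) {
  panels <- lapply(seq_len(nrow(cohort)), function(i)
    compute_scores(cohort[i, , drop = FALSE]))
  cohort$fib4 <- vapply(panels, `[[`, numeric(1), "fib4")
  cohort$albi <- vapply(panels, `[[`, numeric(1), "albi")
  cohort$meld_na <- vapply(panels, `[[`, numeric(1), "meld_na")
  cohort
}
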