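## Clinical HDGC eligibility and cohort composition.
##
## A patient qualifies as hereditary diffuse gastric cancer (HDGC) by meeting
## at least one of four clinical conditions built from histology, age at
## diagnosis and family history:
##   1. two or more gastric-cancer (GC) cases among first/second-degree
##      relatives together with a confirmed diffuse-GC case before age 50
##      ("strict" reading; a "lenient" reading accepts >=2 GC relatives OR a
##      single confirmed diffuse-GC relative before 50 — the published
##      criterion wording supports both, so the reading is a config switch);
##   2. three or more confirmed diffuse-GC cases among first/second-degree
##      relatives, at any age;
##   3. the patient's own diffuse GC diagnosed before age 40 with no family
##      history of diffuse GC;
##   4. personal or family history of diffuse GC together with lobular breast
##      cancer, at least one diagnosed before age 50.

.FAMILY_COLS <- c("patient_id", "degree", "diagnosis", "age_at_dx", "confirmed")

#' Classify HDGC eligibility for one patient
#'
#' @param patient a list or one-row data.frame with `age_at_dx` (years),
#'   `histology` (`"diffuse"` or `"other"`) and logical
#'   `personal_lobular_breast`.
#' @param family data.frame of relatives (possibly 0 rows) with columns
#'   `degree` (1 or 2), `diagnosis` (`"GC"`, `"diffuse_GC"`,
#'   `"lobular_breast"`), `age_at_dx`, and logical `confirmed`. Unconfirmed
#'   diffuse-GC entries count as generic GC for condition 1's case count but
#'   not towards any diffuse-specific clause.
#' @param condition1 which reading of condition 1 to apply (see above).
#' @return list with integer `conditions_met` (subset of 1:4) and logical
#'   `eligible` (true iff any condition is met).
#' @export
classifyHdgc <- function(patient, family = NULL,
                         condition1 = c("strict", "lenient")) {
  condition1 <- match.arg(condition1)
  if (is.null(family) || nrow(family) == 0L)
    family <- data.frame(degree = integer(), diagnosis = character(),
                         age_at_dx = numeric(), confirmed = logical())
  if (!patient$histology %in% c("diffuse", "other"))
    stop("unknown histology: ", patient$histology)
  rel <- family[family$degree %in% c(1L, 2L), , drop = FALSE]
  gc_like <- rel$diagnosis %in% c("GC", "diffuse_GC")
  diffuse_conf <- rel$diagnosis == "diffuse_GC" & rel$confirmed
  diffuse_any <- rel$diagnosis == "diffuse_GC"
  lobular <- rel$diagnosis == "lobular_breast"

  n_gc <- sum(gc_like)
  diffuse_conf_u50 <- diffuse_conf & rel$age_at_dx < 50

  c1 <- if (condition1 == "strict") {
    n_gc >= 2L && any(diffuse_conf_u50)
  } else {
    n_gc >= 2L || any(diffuse_conf_u50)
  }
  c2 <- sum(diffuse_conf) >= 3L
  c3 <- patient$histology == "diffuse" && patient$age_at_dx < 40 &&
    !any(diffuse_any)
  ## condition 4: co-occurrence of diffuse GC and lobular breast cancer in
  ## the personal+family history, one of them before age 50
  personal_diffuse <- patient$histology == "diffuse"
  personal_lb <- isTRUE(patient$personal_lobular_breast)
  has_diffuse <- personal_diffuse || any(diffuse_any)
  has_lobular <- personal_lb || any(lobular)
  u50 <- (personal_diffuse && patient$age_at_dx < 50) ||
    any(rel$age_at_dx[diffuse_any | lobular] < 50)
  c4 <- has_diffuse && has_lobular && u50

  met <- which(c(c1, c2, c3, c4))
  list(conditions_met = met, eligible = length(met) > 0L)
}

#' Classify HDGC eligibility for a whole cohort
#'
#' @param clinical data.frame, one row per patient, with `patient_id` plus
#'   the fields [classifyHdgc()] needs.
#' @param family data.frame of relatives with a `patient_id` column.
#' @param condition1 passed through to [classifyHdgc()].
#' @return data.frame with `patient_id`, logical `cond1`..`cond4`,
#'   `eligible`, and `first_condition` (smallest condition met, NA if none).
#' @export
classifyHdgcCohort <- function(clinical, family = NULL,
                               condition1 = c("strict", "lenient")) {
  condition1 <- match.arg(condition1)
  .assertColumns(clinical, c("patient_id", "age_at_dx", "histology"),
                 "clinical manifest")
  if (!is.null(family)) .assertColumns(family, .FAMILY_COLS, "family history")
  res <- lapply(seq_len(nrow(clinical)), function(i) {
    fam <- if (is.null(family)) NULL else
      family[family$patient_id == clinical$patient_id[i], , drop = FALSE]
    classifyHdgc(as.list(clinical[i, , drop = FALSE]), fam, condition1)
  })
  met <- t(vapply(res, function(r) 1:4 %in% r$conditions_met, logical(4)))
  data.frame(patient_id = clinical$patient_id,
             cond1 = met[, 1], cond2 = met[, 2],
             cond3 = met[, 3], cond4 = met[, 4],
             eligible = rowSums(met) > 0,
             first_condition = apply(met, 1L, function(m)
               if (any(m)) which(m)[1] else NA_integer_),
             stringsAsFactors = FALSE)
}

.compRow <- function(category, level, count, n) {
  data.frame(category = category, level = level, count = count,
             percent = carrierPercent(count, n), stringsAsFactors = FALSE)
}

#' Cohort composition table
#'
#' Tabulates the cohort the way clinical baseline tables are reported:
#' counts with one-decimal percentages by age band (<40 / >=40), sex, family
#' history of diffuse GC, qualifying HDGC condition, AJCC tumor/node/
#' metastasis category, AJCC stage, and EBV status.
#'
#' @param clinical data.frame with `patient_id`, `age_at_dx`, `sex`,
#'   `t_category`, `n_category`, `m_category`, `stage`, `ebv_status`.
#' @param eligibility output of [classifyHdgcCohort()] for the same patients.
#' @param family optional relatives table, used for the family-history rows.
#' @return data.frame with `category`, `level`, `count`, `percent`.
#' @export
cohortComposition <- function(clinical, eligibility, family = NULL) {
  if (nrow(clinical) == 0L) stop("at least one patient is required")
  n <- nrow(clinical)
  fam_diffuse <- if (is.null(family)) rep(FALSE, n) else
    clinical$patient_id %in%
      family$patient_id[family$diagnosis == "diffuse_GC"]
  bands <- list(
    .compRow("age", "<40", sum(clinical$age_at_dx < 40), n),
    .compRow("age", ">=40", sum(clinical$age_at_dx >= 40), n),
    .compRow("sex", "male", sum(clinical$sex == "male"), n),
    .compRow("sex", "female", sum(clinical$sex == "female"), n),
    .compRow("family_history_diffuse_GC", "yes", sum(fam_diffuse), n),
    .compRow("family_history_diffuse_GC", "no", sum(!fam_diffuse), n))
  conds <- lapply(1:4, function(k)
    .compRow("condition", as.character(k),
             sum(eligibility[[paste0("cond", k)]]), n))
  stage <- list(
    .compRow("t_category", "T1-T2", sum(clinical$t_category %in% c("T1", "T2")), n),
    .compRow("t_category", "T3-T4", sum(clinical$t_category %in% c("T3", "T4")), n),
    .compRow("n_category", "N0-N1", sum(clinical$n_category %in% c("N0", "N1")), n),
    .compRow("n_category", "N2-N3", sum(clinical$n_category %in% c("N2", "N3")), n),
    .compRow("m_category", "M0", sum(clinical$m_category == "M0"), n),
    .compRow("m_category", "M1", sum(clinical$m_category == "M1"), n),
    .compRow("stage", "I-II", sum(clinical$stage %in% c("I", "II")), n),
    .compRow("stage", "III-IV", sum(clinical$stage %in% c("III", "IV")), n),
    .compRow("ebv_status", "positive", sum(clinical$ebv_status == "positive"), n),
    .compRow("ebv_status", "negative", sum(clinical$ebv_status == "negative"), n),
    .compRow("ebv_status", "unknown", sum(clinical$ebv_status == "unknown"), n))
  do.call(rbind, c(bands, conds, stage))
}
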