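# The reference hypertension content: pure decision functions for
# blood-pressure grading, the diagnosis workflow, measurement-driven
# ("autofill") diagnosis suggestions, beta-blocker contraindications and
# emergency referral, plus access to the shipped declarative content pack
# that wires the same logic into CDS services.

BP_CATEGORIES <- c("normal", "high-normal", "grade-1", "grade-2", "grade-3")

# Inclusive lower bounds of the systolic / diastolic category intervals:
# systolic  <130 | 130-139 | 140-159 | 160-179 | >=180
# diastolic  <85 |  85-89  |  90-99  | 100-109 | >=110
SBP_CUTS <- c(130, 140, 160, 180)
DBP_CUTS <- c(85, 90, 100, 110)

#' Categorize blood pressure into hypertension grades
#'
#' Systolic and diastolic components are graded independently through the
#' interval tables (systolic <130 / 130-139 / 140-159 / 160-179 / >=180 mmHg,
#' diastolic <85 / 85-89 / 90-99 / 100-109 / >=110 mmHg) and the more severe
#' of the two component categories is returned (ESC convention).
#'
#' @param sbp Systolic blood pressure in mmHg (integer-valued, 60-260).
#' @param dbp Diastolic blood pressure in mmHg (integer-valued, 30-160).
#' @return A character vector over `"normal"`, `"high-normal"`,
#'   `"grade-1"`, `"grade-2"`, `"grade-3"`; vectorized over inputs.
#' @examples
#' categorize_bp(145, 92)  # "grade-1"
#' categorize_bp(128, 82)  # "normal"
#' categorize_bp(120, 112) # "grade-3" (diastolic forces the grade)
#' @export
categorize_bp <- function(sbp, dbp) {
  if (any(sbp < 60 | sbp > 260) || any(dbp < 30 | dbp > 160)) {
    cds_abort("blood pressure outside the physiological range (60-260 / 30-160 mmHg)",
              "out_of_range_error")
  }
  severity <- pmax(findInterval(sbp, SBP_CUTS), findInterval(dbp, DBP_CUTS))
  BP_CATEGORIES[severity + 1L]
}

#' Hypertension diagnosis workflow
#'
#' Implements the diagnosis flowchart for undiagnosed patients: elevated
#' office BP (>=140 systolic or >=90 diastolic) before home confirmation
#' triggers short-term self-monitoring plus a follow-up appointment; after
#' the patient has been sent home for confirmation, persistently elevated
#' BP triggers the grade categorization card and a diagnosis suggestion;
#' otherwise the BP is categorized as normal or high-normal.
#'
#' @param diagnosed Has the patient already been diagnosed hypertensive?
#' @param sent_home Has the patient been sent home for diagnosis
#'   confirmation (short-term self-monitoring)?
#' @param sbp,dbp Latest office blood pressure in mmHg.
#' @return Character vector of card ids (possibly empty: the flow applies
#'   to undiagnosed patients only).
#' @export
diagnosis_flow <- function(diagnosed, sent_home, sbp, dbp) {
  stopifnot(is.logical(diagnosed), is.logical(sent_home))
  if (isTRUE(diagnosed)) return(character())
  elevated <- sbp >= 140 || dbp >= 90
  category <- categorize_bp(sbp, dbp)
  if (!isTRUE(sent_home)) {
    if (elevated) {
      c("CARD SELF-MONITORING", "CARD FOLLOW-UP")
    } else if (category == "high-normal") {
      "CARD HIGH-NORMAL-BP"
    } else {
      "CARD NORMAL-BP"
    }
  } else {
    if (elevated) {
      grade_card <- switch(category,
        `grade-1` = "CARD 4",
        `grade-2` = "CARD GRADE-2",
        `grade-3` = "CARD GRADE-3"
      )
      c(grade_card, "CARD DIAGNOSE-HTN")
    } else if (category == "high-normal") {
      "CARD HIGH-NORMAL-BP"
    } else {
      "CARD NORMAL-BP"
    }
  }
}

# Threshold table for measurement-driven diagnosis suggestions. All strict
# inequalities, taken literally from the guideline wording ("less than 60",
# "more than 5.5", "less than 40%", "less than 60 mL/min").
AUTOFILL_THRESHOLDS <- list(
  list(concept = "HeartRate", op = "<", value = 60, card = "CARD BRADYCARDIA"),
  list(concept = "SerumPotassium", op = ">", value = 5.5,
       card = "CARD HYPERKALEMIA"),
  list(concept = "LVEF", op = "<", value = 40, card = "CARD LOW-LVEF"),
  list(concept = "eGFR", op = "<", value = 60, card = "CARD CKD")
)

#' Measurement-driven diagnosis suggestions
#'
#' Scans the bundle's latest measurements against the autofill thresholds:
#' bradycardia (heart rate < 60 /min), hyperkalemia (potassium
#' > 5.5 mmol/L), severe left-ventricular dysfunction (ejection fraction
#' < 40 %), chronic kidney disease (eGFR < 60 mL/min). Absent measurements
#' emit nothing; boundary values do not trigger.
#'
#' @param bundle A `fhir_bundle`.
#' @param registry Concept registry; defaults to the shipped hypertension
#'   pack's registry.
#' @return Character vector of suggested-diagnosis card ids.
#' @export
autofill_findings <- function(bundle, registry = hypertension_pack()$registry) {
  out <- character()
  for (th in AUTOFILL_THRESHOLDS) {
    cc <- resolve_concept(registry, th$concept)
    m <- select_latest(bundle, cc)
    if (is.null(m) || is.null(m$value)) next
    hit <- if (th$op == "<") m$value < th$value else m$value > th$value
    if (isTRUE(hit)) out <- c(out, th$card)
  }
  out
}

#' Medication contraindication warnings
#'
#' For a proposed beta-blocking agent (ATC class C07), emits the compelling
#' side-effect warning card when the patient has asthma, a high-grade
#' sinoatrial or A-V block, or bradycardia (latest heart rate < 60 /min).
#' Other drug classes return no warnings in the shipped pack (the schema
#' supports more).
#'
#' @param proposed_atc ATC code or class prefix of the proposed medication.
#' @param bundle A `fhir_bundle`.
#' @param registry Concept registry (defaults to the shipped pack's).
#' @return Character vector of warning card ids.
#' @export
medication_contraindications <- function(proposed_atc, bundle,
                                         registry = hypertension_pack()$registry) {
  stopifnot(nzchar(proposed_atc))
  if (!startsWith(normalize_code(proposed_atc), "C07")) return(character())
  asthma <- has_active_condition(bundle, resolve_concept(registry, "Asthma"))
  block <- has_active_condition(bundle, resolve_concept(registry, "AVBlock"))
  hr <- select_latest(bundle, resolve_concept(registry, "HeartRate"))
  brady <- !is.null(hr) && !is.null(hr$value) && hr$value < 60
  if (asthma || block || brady) "CARD 38" else character()
}

#' Emergency referral check
#'
#' A referral to emergency services is advised when the clinic blood
#' pressure exceeds 180/110 mmHg (strictly greater on either component).
#'
#' @param sbp,dbp Clinic blood pressure in mmHg.
#' @return `"CARD EMERGENCY"` or `character(0)`.
#' @export
emergency_referral_check <- function(sbp, dbp) {
  if (any(sbp < 60 | sbp > 260) || any(dbp < 30 | dbp > 160)) {
    cds_abort("blood pressure outside the physiological range (60-260 / 30-160 mmHg)",
              "out_of_range_error")
  }
  if (sbp > 180 || dbp > 110) "CARD EMERGENCY" else character()
}

# --- shipped pack access --------------------------------------------------

.pack_cache <- new.env(parent = emptyenv())

#' Path to the shipped hypertension content pack
#' @return Directory path inside the installed package.
#' @export
hypertension_pack_dir <- function() {
  system.file("extdata", "packs", "hypertension", package = "cdscards",
              mustWork = TRUE)
}

#' The shipped hypertension content pack
#'
#' Loads (and caches) the declarative hypertension pack: concept registry,
#' rules, card templates and service descriptors.
#'
#' @param reload Force a fresh load from disk.
#' @return A `cds_pack`.
#' @export
hypertension_pack <- function(reload = FALSE) {
  if (reload || is.null(.pack_cache$hypertension)) {
    .pack_cache$hypertension <- load_pack(hypertension_pack_dir())
  }
  .pack_cache$hypertension
}

#' Plot the blood-pressure categorization grid
#'
#' Visualizes `categorize_bp()` over the integer grid of systolic and
#' diastolic pressures, showing the five categories and the max-severity
#' combination rule.
#'
#' @param sbp_range,dbp_range Integer ranges to sweep.
#' @return A ggplot object.
#' @export
plot_bp_grid <- function(sbp_range = 90:220, dbp_range = 50:130) {
  grid <- expand.grid(sbp = sbp_range, dbp = dbp_range)
  grid$category <- factor(categorize_bp(grid$sbp, grid$dbp),
                          levels = BP_CATEGORIES)
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$sbp, y = .data$dbp,
                                     fill = .data$category)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_d(name = "BP category") +
    ggplot2::labs(x = "Systolic BP (mmHg)", y = "Diastolic BP (mmHg)",
                  title = "Office blood-pressure categorization") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
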