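# Seeded generator of patient bundles for named clinical scenarios, so that
# every shipped service and card is exercisable without any external data.
# Values are drawn uniformly within clinically plausible per-scenario
# ranges; the generator's job is coverage of rule branches, not
# epidemiology. Timestamps are generated relative to an injectable "now" so
# latest-value selection is deterministic.

SCENARIO_REGISTRY <- list(
  `normal-bp` = list(
    description = "Undiagnosed patient with normal office blood pressure",
    parameters = list(sbp_range = c(105, 125), dbp_range = c(65, 80),
                      n_bp_readings = 2)
  ),
  `high-normal` = list(
    description = "Undiagnosed patient in the high-normal BP band",
    parameters = list(sbp_range = c(130, 139), dbp_range = c(70, 84),
                      n_bp_readings = 2)
  ),
  `grade1-newly-presenting` = list(
    description = "Undiagnosed patient, first elevated office reading, not yet sent home for confirmation",
    parameters = list(sbp_range = c(140, 159), dbp_range = c(90, 99),
                      n_bp_readings = 2)
  ),
  `grade2-confirmed` = list(
    description = "Undiagnosed patient sent home for confirmation, grade-2 BP persists",
    parameters = list(sbp_range = c(160, 179), dbp_range = c(100, 109),
                      n_bp_readings = 2, sent_home = TRUE)
  ),
  `resistant-hypertension` = list(
    description = "Diagnosed hypertensive on three antihypertensive classes including a diuretic, BP still uncontrolled",
    parameters = list(sbp_range = c(145, 170), dbp_range = c(92, 105),
                      n_bp_readings = 3,
                      med_atc_codes = list(
                        diuretic = c("C03CA01", "C03AA03"),
                        acei_arb = c("C09AA02", "C09AA05", "C09CA01"),
                        ccb = c("C08CA01", "C08CA05")
                      ))
  ),
  bradycardia = list(
    description = "Heart rate strictly below 60 /min",
    parameters = list(hr_range = c(40, 59))
  ),
  hyperkalemia = list(
    description = "Serum potassium strictly above 5.5 mmol/L",
    parameters = list(k_range = c(5.6, 7.0))
  ),
  `low-lvef` = list(
    description = "Left ventricular ejection fraction strictly below 40 %",
    parameters = list(lvef_range = c(20, 39))
  ),
  `low-egfr-ckd` = list(
    description = "eGFR strictly below 60 mL/min",
    parameters = list(egfr_range = c(30, 59))
  ),
  `goal-monitoring` = list(
    description = "Diagnosed hypertensive on monotherapy with BP above target",
    parameters = list(sbp_range = c(140, 155), dbp_range = c(85, 95),
                      n_bp_readings = 3, med_atc_codes = list(
                        acei_arb = c("C09AA02", "C09AA05")
                      ))
  )
)

#' List the registered synthetic-patient scenarios
#'
#' @return A tibble with columns `name`, `description` and a `parameters`
#'   list-column documenting each scenario's value ranges.
#' @export
list_scenarios <- function() {
  tibble(
    name = names(SCENARIO_REGISTRY),
    description = vapply(SCENARIO_REGISTRY, `[[`, "", "description"),
    parameters = unname(lapply(SCENARIO_REGISTRY, `[[`, "parameters"))
  )
}

runif_int <- function(range) sample(seq(range[1], range[2]), 1L)
runif_grid <- function(range, by = 0.1) {
  sample(seq(range[1], range[2], by = by), 1L)
}

#' Generate a synthetic patient bundle for a named scenario
#'
#' Deterministic per `(name, seed)`: the same pair always yields a
#' byte-identical serialized bundle. Generated values stay inside the
#' scenario's declared ranges and the bundle passes full parse/validate.
#'
#' @param name A scenario name from [list_scenarios()].
#' @param seed Integer seed for the scenario's private RNG stream.
#' @param now Reference date; observation timestamps are generated at or
#'   before it.
#' @return A `fhir_bundle`.
#' @export
generate_scenario <- function(name, seed = 1L,
                              now = as.Date("2024-06-01")) {
  spec <- SCENARIO_REGISTRY[[name]]
  if (is.null(spec)) {
    cds_abort(paste0("unknown scenario '", name, "' (see list_scenarios())"),
              "scenario_not_found")
  }
  now <- as.Date(now)
  p <- spec$parameters
  with_local_seed(seed, {
    pid <- "patient-1"
    patient <- build_patient(
      id = pid,
      gender = sample(c("female", "male"), 1L),
      birth_date = format(now - sample(23000:33000, 1L), "%Y-%m-%d")
    )
    res <- list()
    add <- function(x) res[[length(res) + 1L]] <<- x
    date_at <- function(days_ago) format(now - days_ago, "%Y-%m-%d")

    if (!is.null(p$sbp_range)) {
      n <- p$n_bp_readings %||% 2
      for (i in seq_len(n)) {
        # reading n is the latest (closest to now) and carries the
        # scenario-defining values; earlier readings are unconstrained
        latest <- i == n
        sbp <- if (latest) runif_int(p$sbp_range) else runif_int(c(110, 175))
        dbp <- if (latest) runif_int(p$dbp_range) else runif_int(c(65, 105))
        add(build_bp_panel(sprintf("bp-%d", i), sbp, dbp,
                           date_at((n - i) * 14L + 1L), pid))
      }
    }
    if (isTRUE(p$sent_home)) {
      add(build_flag_observation("flag-sent-home", "SentHomeForConfirmation",
                                 TRUE, date_at(15L), pid))
    }
    if (!is.null(p$med_atc_codes)) {
      add(build_condition("cond-htn", "http://hl7.org/fhir/sid/icd-10",
                          "I10", "Essential (primary) hypertension", pid))
      i <- 0L
      for (class_codes in p$med_atc_codes) {
        i <- i + 1L
        add(build_medication_statement(
          sprintf("med-%d", i), sample(class_codes, 1L),
          "antihypertensive agent", pid
        ))
      }
    }
    if (!is.null(p$hr_range)) {
      add(build_observation("obs-hr", "http://loinc.org", "8867-4",
                            "Heart rate", runif_int(p$hr_range), "/min",
                            date_at(1L), pid))
    }
    if (!is.null(p$k_range)) {
      add(build_observation("obs-k", "http://loinc.org", "2823-3",
                            "Potassium [Moles/volume] in Serum or Plasma",
                            runif_grid(p$k_range), "mmol/L",
                            date_at(2L), pid))
    }
    if (!is.null(p$lvef_range)) {
      add(build_observation("obs-lvef", "http://loinc.org", "10230-1",
                            "Left ventricular ejection fraction",
                            runif_int(p$lvef_range), "%",
                            date_at(3L), pid))
    }
    if (!is.null(p$egfr_range)) {
      add(build_observation("obs-egfr", "http://loinc.org", "33914-3",
                            "Glomerular filtration rate (estimated)",
                            runif_int(p$egfr_range), "mL/min",
                            date_at(4L), pid))
    }
    fhir_bundle(patient, res)
  })
}

#' Scenario-to-card contract table
#'
#' For each synthetic scenario, the card ids that must (and a set that must
#' not) appear when all shipped hypertension services are invoked against a
#' generated bundle. This is the end-to-end contract the test suite
#' verifies across seeds.
#'
#' @return A tibble with columns `scenario`, `must_appear`, `must_not_appear`
#'   (list-columns of card-id character vectors).
#' @export
scenario_expected_cards <- function() {
  contract <- list(
    `normal-bp` = list(
      must = "CARD NORMAL-BP",
      not = c("CARD HIGH-NORMAL-BP", "CARD SELF-MONITORING", "CARD FOLLOW-UP",
              "CARD 4", "CARD 18", "CARD 7", "CARD EMERGENCY")
    ),
    `high-normal` = list(
      must = c("CARD HIGH-NORMAL-BP", "CARD 7"),
      not = c("CARD NORMAL-BP", "CARD SELF-MONITORING", "CARD DIAGNOSE-HTN")
    ),
    `grade1-newly-presenting` = list(
      must = c("CARD SELF-MONITORING", "CARD FOLLOW-UP", "CARD 7"),
      not = c("CARD 4", "CARD DIAGNOSE-HTN", "CARD NORMAL-BP", "CARD 18",
              "CARD EMERGENCY")
    ),
    `grade2-confirmed` = list(
      must = c("CARD GRADE-2", "CARD DIAGNOSE-HTN", "CARD 7"),
      not = c("CARD 4", "CARD GRADE-3", "CARD SELF-MONITORING",
              "CARD NORMAL-BP", "CARD EMERGENCY")
    ),
    `resistant-hypertension` = list(
      must = c("CARD 18", "CARD 31", "CARD 11", "CARD 7", "CARD 21"),
      not = c("CARD SELF-MONITORING", "CARD EMERGENCY", "CARD NORMAL-BP")
    ),
    bradycardia = list(
      must = "CARD BRADYCARDIA",
      not = c("CARD 38", "CARD HYPERKALEMIA", "CARD EMERGENCY")
    ),
    hyperkalemia = list(
      must = "CARD HYPERKALEMIA",
      not = c("CARD BRADYCARDIA", "CARD CKD")
    ),
    `low-lvef` = list(
      must = "CARD LOW-LVEF",
      not = c("CARD BRADYCARDIA", "CARD HYPERKALEMIA")
    ),
    `low-egfr-ckd` = list(
      must = "CARD CKD",
      not = c("CARD BRADYCARDIA", "CARD LOW-LVEF")
    ),
    `goal-monitoring` = list(
      must = c("CARD 11", "CARD 7", "CARD 21"),
      not = c("CARD 18", "CARD EMERGENCY", "CARD NORMAL-BP")
    )
  )
  tibble(
    scenario = names(contract),
    must_appear = unname(lapply(contract, `[[`, "must")),
    must_not_appear = unname(lapply(contract, `[[`, "not"))
  )
}
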