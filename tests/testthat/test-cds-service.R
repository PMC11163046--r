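# Service layer: discovery, prefetch resolution, invocation semantics.

test_that("discovery lists one service per populated purpose category, sorted", {
  doc <- discovery(test_pack())
  ids <- vapply(doc$services, `[[`, "", "id")
  expect_identical(ids, sort(ids))
  expect_true(all(c("hypertension-diagnosis", "hypertension-goal-management",
                    "hypertension-lifestyle-advice",
                    "hypertension-complication-referral") %in% ids))
  expect_true(all(vapply(doc$services, `[[`, "", "hook") == "patient-view"))
  expect_identical(discovery(list()), list(services = list()))
})

test_that("prefetch resolution returns the newest match under _sort/_count", {
  pack <- test_pack()
  b <- fhir_bundle(build_patient(), list(
    build_bp_panel("bp-old", 150, 95, "2024-01-01"),
    build_bp_panel("bp-new", 145, 92, "2024-02-01")
  ))
  svc <- pack$services[["hypertension-diagnosis"]]
  pf <- resolve_prefetch(svc, b)
  expect_length(pf$bpPanel, 1)
  expect_identical(pf$bpPanel[[1]]$id, "bp-new")
  expect_length(pf$potassium, 0) # empty entry, not an error
  expect_length(pf$patient, 1)
})

test_that("unsupported prefetch templates are rejected at startup", {
  expect_error(
    cdscards:::validate_prefetch_template("Foo?bar=1", "svc"),
    class = "prefetch_schema_error"
  )
  expect_error(
    cdscards:::validate_prefetch_template(
      "Observation?subject={{context.patientId}}", "svc"),
    class = "prefetch_schema_error"
  )
  expect_error(
    cdscards:::new_service_descriptor("svc", rule_ids = "R 1",
                                      prefetch = list(x = "Foo?bar=1")),
    class = "prefetch_schema_error"
  )
})

test_that("invoking with a resistant-hypertension bundle emits CARD 18 with three actions", {
  pack <- test_pack()
  b <- generate_scenario("resistant-hypertension", seed = 5, now = FIXED_NOW)
  req <- cds_request(patient_id = "patient-1")
  resp <- invoke(pack, "hypertension-complication-referral", req, b,
                 now = FIXED_NOW)
  expect_length(resp$cards, 1)
  actions <- resp$cards[[1]]$suggestions[[1]]$actions
  expect_length(actions, 3)
  types <- vapply(actions, function(a) a$resource$resourceType, "")
  expect_identical(types, c("ServiceRequest", "Appointment", "ServiceRequest"))
  # patient-activity order, follow-up at now + 2 weeks, cardiology referral
  expect_identical(actions[[1]]$resource$code$coding[[1]]$code, "85354-9")
  expect_identical(actions[[2]]$resource$start,
                   format(FIXED_NOW + 14, "%Y-%m-%d"))
  expect_identical(actions[[3]]$resource$performerType$coding[[1]]$code,
                   "175651000")
})

test_that("an undiagnosed elevated-BP patient gets self-monitoring guidance", {
  pack <- test_pack()
  b <- fhir_bundle(build_patient(),
                   list(build_bp_panel("bp1", 150, 95, "2024-05-20")))
  req <- cds_request(patient_id = "patient-1")
  resp <- invoke(pack, "hypertension-diagnosis", req, b, now = FIXED_NOW)
  summaries <- vapply(resp$cards, `[[`, "", "summary")
  expect_length(resp$cards, 2)
  expect_match(summaries[1], "self-monitoring")
  expect_match(summaries[2], "follow-up appointment")
})

test_that("a bundle with no relevant data yields an empty cards array", {
  pack <- test_pack()
  req <- cds_request(patient_id = "patient-1")
  for (svc in names(pack$services)) {
    resp <- invoke(pack, svc, req, empty_bundle(), now = FIXED_NOW)
    expect_identical(resp$cards, list(), label = svc)
  }
})

test_that("unknown services and malformed requests raise HTTP-like errors", {
  pack <- test_pack()
  req <- cds_request(patient_id = "patient-1")
  expect_error(invoke(pack, "no-such-service", req, empty_bundle()),
               class = "service_not_found")
  expect_error(cds_request(patient_id = ""), class = "bad_request")
  bad_hook <- cds_request(hook = "order-select", patient_id = "patient-1")
  expect_error(invoke(pack, "hypertension-diagnosis", bad_hook,
                      empty_bundle()),
               class = "bad_request")
})

test_that("client-supplied prefetch overrides the server-side data source", {
  pack <- test_pack()
  source <- fhir_bundle(build_patient(),
                        list(build_bp_panel("bp1", 150, 95, "2024-05-20")))
  # client says the BP is normal; its prefetch wins over the stored panel
  client_obs <- cdscards:::resource_to_json_list(
    build_bp_panel("bp-client", 118, 72, "2024-05-25")
  )
  req <- cds_request(patient_id = "patient-1",
                     prefetch = list(bpPanel = list(client_obs)))
  resp <- invoke(pack, "hypertension-diagnosis", req, source,
                 now = FIXED_NOW)
  summaries <- vapply(resp$cards, `[[`, "", "summary")
  expect_match(summaries, "categorized as normal", all = TRUE)
})

test_that("discovery and invoke payloads validate against the bundled schemas", {
  pack <- test_pack()
  expect_identical(
    nrow(validate_json_schema(discovery(pack), cds_hooks_schema("discovery"))),
    0L
  )
  req <- cds_request(patient_id = "patient-1")
  for (nm in c("resistant-hypertension", "grade2-confirmed", "bradycardia")) {
    b <- generate_scenario(nm, seed = 2, now = FIXED_NOW)
    for (svc in names(pack$services)) {
      resp <- invoke(pack, svc, req, b, now = FIXED_NOW)
      v <- validate_json_schema(resp, cds_hooks_schema("response"))
      expect_identical(nrow(v), 0L, label = paste(nm, svc))
    }
  }
})

test_that("invocation is deterministic up to card uuids", {
  pack <- test_pack()
  b <- generate_scenario("resistant-hypertension", seed = 9, now = FIXED_NOW)
  req <- cds_request(patient_id = "patient-1", hook_instance = "fixed")
  r1 <- invoke(pack, "hypertension-complication-referral", req, b,
               now = FIXED_NOW)
  r2 <- invoke(pack, "hypertension-complication-referral", req, b,
               now = FIXED_NOW)
  expect_identical(strip_uuids(r1), strip_uuids(r2))
})
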