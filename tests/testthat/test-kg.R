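devices <- default_devices()

test_that("the ontology declares the expected class structure", {
  kg <- build_ontology()
  subclasses_of <- function(cls) {
    tr <- tidy(kg)
    sort(sub(adl_iri(""), "", tr$subject[
      tr$predicate == "http://www.w3.org/2000/01/rdf-schema#subClassOf" &
        tr$object == adl_iri(cls)]))
  }
  expect_equal(subclasses_of("Problem"),
               sort(c("TooLongDuration", "DivergenceFromProtocol",
                      "ExtraSteps", "MissingSteps")))
  expect_length(subclasses_of("FeatureOfInterest"), 4)
  expect_length(subclasses_of("Sensor"), 4)
  # SSN/SOSA alignment is declared locally
  tr <- tidy(kg)
  expect_true(any(tr$object == "http://www.w3.org/ns/sosa/Observation"))
})

mini_instance <- function() {
  obs <- make_observations(
    devices, c("Cabinet (Food)", "Cooker", "Fridge Door1", "Drawer 1"),
    c(0, 60, 120, 180))
  act <- make_activity("act_P001_01", obs)
  roster <- tibble::tibble(participant_id = "P001", group = "HC")
  used <- devices[devices$name %in% obs$device_name, ]
  list(act = act, obs = obs, roster = roster, devices = used)
}

test_that("to_rdf maps one activity with 4 observations to the documented triple pattern", {
  m <- mini_instance()
  schema <- build_ontology()
  kg <- to_rdf(m$act, m$obs, m$roster, m$devices, schema)
  inst <- kg_size(kg) - kg_size(schema)
  # 6 activity literals+type, 1 refersToUser, 4 consistsOf,
  # 4 obs x (type, start, device, feature), 4 devices x 2, 1 patient type
  expect_equal(inst, 6 + 1 + 4 + 4 * 4 + 4 * 2 + 1)
  act_iri <- adl_resource("activity/act_P001_01")
  tr <- tidy(kg)
  expect_equal(sum(tr$subject == act_iri &
                     tr$predicate == adl_iri("consistsOf")), 4)
  expect_equal(tr$object[tr$subject == act_iri &
                           tr$predicate == adl_iri("refersToUser")],
               adl_resource("patient/P001"))
  # empty input leaves the schema untouched
  empty <- to_rdf(m$act[0, ], m$obs[0, ], m$roster[0, ], m$devices[0, ])
  expect_equal(kg_size(empty), kg_size(schema))
})

test_that("IRIs are deterministic: identical inputs give identical graphs", {
  m <- mini_instance()
  kg1 <- to_rdf(m$act, m$obs, m$roster, m$devices)
  kg2 <- to_rdf(m$act, m$obs, m$roster, m$devices)
  expect_equal(dplyr::arrange(tidy(kg1), subject, predicate, object),
               dplyr::arrange(tidy(kg2), subject, predicate, object))
})

test_that("to_rdf rejects dangling observation references", {
  m <- mini_instance()
  m$act$observation_ids <- list(c(m$obs$observation_id, "obs_ghost"))
  expect_error(to_rdf(m$act, m$obs, m$roster, m$devices), "obs_ghost")
})

test_that("conformance checking reports constructed defects and nothing else", {
  m <- mini_instance()
  kg <- to_rdf(m$act, m$obs, m$roster, m$devices)
  expect_equal(nrow(check_conformance(kg)), 0)
  # remove the activity's user link
  broken <- kg
  broken$triples <- broken$triples[
    broken$triples$predicate != adl_iri("refersToUser"), ]
  v <- check_conformance(broken)
  expect_equal(nrow(v), 1)
  expect_match(v$subject, "activity/act_P001_01")
  # strip one observation's device link
  broken2 <- kg
  drop <- broken2$triples$predicate == adl_iri("refersToDevice") &
    grepl("obs_0001", broken2$triples$subject)
  broken2$triples <- broken2$triples[!drop, ]
  v2 <- check_conformance(broken2)
  expect_equal(nrow(v2), 1)
  expect_match(v2$requirement, "refersToDevice")
  # an undeclared predicate is flagged
  broken3 <- kg_add(kg, tibble::tibble(
    subject = adl_resource("activity/act_P001_01"),
    predicate = adl_iri("made_up"), object = "x",
    object_kind = "literal", datatype = NA_character_))
  expect_match(check_conformance(broken3)$requirement, "declared")
})

test_that("Turtle and N-Triples round-trips preserve the triple set", {
  m <- mini_instance()
  kg <- to_rdf(m$act, m$obs, m$roster, m$devices)
  for (fmt in c("nt", "ttl")) {
    f <- withr::local_tempfile(fileext = paste0(".", fmt))
    if (fmt == "nt") { write_ntriples(kg, f); back <- read_ntriples(f) }
    else { write_turtle(kg, f); back <- read_turtle(f) }
    expect_equal(kg_size(back), kg_size(kg))
    expect_equal(dplyr::arrange(tidy(back), subject, predicate, object),
                 dplyr::arrange(tidy(kg), subject, predicate, object))
    # identical graph serializes byte-identically
    f2 <- withr::local_tempfile()
    if (fmt == "nt") write_ntriples(back, f2) else write_turtle(back, f2)
    expect_identical(readLines(f2), readLines(f))
  }
})

test_that("subclass closure returns problem instances typed by any subclass", {
  m <- mini_instance()
  m$act$duration_s <- 2400
  kg <- to_rdf(m$act, m$obs, m$roster, m$devices)
  res <- run_rules(kg)
  probs <- kg_instances(res$kg, adl_iri("Problem"))
  expect_equal(sort(probs), sort(res$problems$problem_iri))
  expect_true(length(probs) > 0)
})
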