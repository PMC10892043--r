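devices <- default_devices()

# one activity with the given duration and observation device/offset layout
activity_kg <- function(duration_s, device_names, offsets_s, pk = "act_P001_01") {
  obs <- make_observations(devices, device_names, offsets_s,
                           id_prefix = paste0("obs_", pk))
  act <- make_activity(pk, obs)
  act$duration_s <- duration_s
  act$end <- act$start + duration_s
  roster <- tibble::tibble(participant_id = "P001", group = "HC")
  list(kg = to_rdf(act, obs, roster, devices),
       act = act, obs = obs)
}

proto3 <- c("Cabinet (Food)", "Cooker", "Fridge Door1")

test_that("duration rule fires strictly above 2100 s with the duration as rate", {
  for (case in list(list(1800, 0L), list(2100, 0L), list(2101, 1L),
                    list(2400, 1L))) {
    m <- activity_kg(case[[1]], proto3, c(0, 60, 120))
    p <- rule_too_long_duration(m$kg)
    expect_equal(nrow(p), case[[2]], label = paste(case[[1]], "s"))
    if (case[[2]] == 1) {
      expect_equal(p$rate, case[[1]])
      expect_equal(p$type, "TooLongDuration")
      expect_equal(p$patient_id, "P001")
      expect_equal(p$date, m$act$start)
    }
  }
})

test_that("step-count rules use strict thresholds on distinct observations", {
  layouts <- list(list(7, "MissingSteps"), list(9, "MissingSteps"),
                  list(10, NULL), list(20, NULL),
                  list(21, "ExtraSteps"), list(25, "ExtraSteps"))
  for (l in layouts) {
    k <- l[[1]]
    names_k <- c(proto3, rep("Drawer 1", k - 3))
    m <- activity_kg(1500, names_k, seq(0, by = 30, length.out = k))
    p <- dplyr::bind_rows(rule_extra_steps(m$kg), rule_missing_steps(m$kg))
    if (is.null(l[[2]])) {
      expect_equal(nrow(p), 0, label = paste(k, "steps"))
    } else {
      expect_equal(p$type, l[[2]], label = paste(k, "steps"))
      expect_equal(p$rate, k)
    }
  }
})

test_that("duplicate consistsOf links do not inflate the distinct step count", {
  m <- activity_kg(1500, c(proto3, rep("Drawer 1", 18)),
                   seq(0, by = 30, length.out = 21))
  # assert a duplicate membership triple; the graph is a set, and the count
  # is over distinct observations
  dup <- tidy(m$kg)
  dup <- dup[dup$predicate == adl_iri("consistsOf"), ][1, ]
  kg2 <- kg_add(m$kg, dup)
  p <- rule_extra_steps(kg2)
  expect_equal(p$rate, 21)
})

test_that("divergence fires iff some combination violates the protocol order", {
  # conformant: cabinet < cooker < fridge
  ok <- activity_kg(1500, proto3, c(0, 60, 120))
  expect_equal(nrow(rule_divergence(ok$kg)), 0)
  # any permutation breaking the order fires
  wrong <- activity_kg(1500, c("Fridge Door1", "Cabinet (Food)", "Cooker"),
                       c(0, 60, 120))
  p <- rule_divergence(wrong$kg)
  expect_equal(p$type, "DivergenceFromProtocol")
  expect_equal(p$activity_pk, "act_P001_01")
  # a second cabinet event after the cooker forms a violating combination
  late_cab <- activity_kg(1500,
                          c("Cabinet (Food)", "Cooker", "Cabinet (Food)",
                            "Fridge Door1"),
                          c(0, 60, 90, 120))
  expect_equal(nrow(rule_divergence(late_cab$kg)), 1)
  # no cooker observation: rule not applicable
  no_cooker <- activity_kg(1500, c("Cabinet (Food)", "Fridge Door1"),
                           c(60, 0))
  expect_equal(nrow(rule_divergence(no_cooker$kg)), 0)
  # simultaneous steps violate the strict order
  tie <- activity_kg(1500, proto3, c(0, 60, 60))
  expect_equal(nrow(rule_divergence(tie$kg)), 1)
})

test_that("run_rules unions the rules, enriches the graph and is idempotent", {
  m <- activity_kg(2400, c(proto3, "Drawer 1"), c(60, 0, 120, 180))
  # violates duration (2400 > 2100), missing steps (4 < 10) and divergence
  res <- run_rules(m$kg)
  expect_equal(sort(res$problems$type),
               sort(c("TooLongDuration", "MissingSteps",
                      "DivergenceFromProtocol")))
  expect_equal(anyDuplicated(res$problems$problem_iri), 0)
  # constructed triples follow the four-triple template
  tr <- tidy(res$kg)
  for (iri in res$problems$problem_iri) {
    expect_equal(sum(tr$subject == iri), 4)
  }
  # problems are queryable as Problem instances (enrichment soundness)
  expect_equal(sort(kg_instances(res$kg, adl_iri("Problem"))),
               sort(res$problems$problem_iri))
  # rerun on the enriched graph changes nothing
  res2 <- run_rules(res$kg)
  expect_equal(res2$problems, res$problems)
  expect_equal(kg_size(res2$kg), kg_size(res$kg))
  # empty instance graph yields nothing
  expect_equal(nrow(run_rules(build_ontology())$problems), 0)
})

test_that("rule thresholds respond monotonically", {
  set.seed(91)
  s <- random_activity_set(30)
  n_too_long <- sapply(c(1500, 2100, 2700), function(thr) {
    nrow(rule_too_long_duration(s$kg, rule_config(duration_threshold_s = thr)))
  })
  expect_true(all(diff(n_too_long) <= 0))
  n_missing <- sapply(c(12, 10, 5), function(thr) {
    nrow(rule_missing_steps(s$kg, rule_config(missing_steps_threshold = thr)))
  })
  expect_true(all(diff(n_missing) <= 0))
})

test_that("no activity is flagged with both extra and missing steps", {
  set.seed(92)
  s <- random_activity_set(40)
  res <- run_rules(s$kg)
  both <- intersect(
    res$problems$activity_pk[res$problems$type == "ExtraSteps"],
    res$problems$activity_pk[res$problems$type == "MissingSteps"])
  expect_length(both, 0)
})

test_that("graph-pattern engine agrees with the brute-force oracle", {
  set.seed(93)
  for (rep in 1:10) {
    s <- random_activity_set(sample(5:25, 1))
    engine <- run_rules(s$kg)$problems
    oracle <- brute_force_oracle(s$activities, s$observations)
    expect_same_problems(engine, oracle)
    expect_equal(engine$rate[order(engine$problem_iri)],
                 oracle$rate[order(oracle$problem_iri)])
  }
})

test_that("shipped SPARQL rule files agree with the engine via rdflib", {
  set.seed(94)
  s <- random_activity_set(12)
  engine <- run_rules(s$kg)$problems
  nt <- withr::local_tempfile(fileext = ".nt")
  write_ntriples(s$kg, nt)
  script <- system.file("scripts", "run_sparql_rules.py", package = "adlgraph")
  rqdir <- system.file("extdata", "sparql", package = "adlgraph")
  out <- system2("python", c(script, nt, rqdir), stdout = TRUE)
  recs <- jsonlite::fromJSON(paste(out, collapse = "\n"))
  expect_setequal(names(recs), engine$problem_iri)
  for (iri in engine$problem_iri) {
    row <- engine[engine$problem_iri == iri, ]
    expect_equal(recs[[iri]]$type, row$type)
    expect_equal(recs[[iri]]$patient, adl_resource(paste0("patient/",
                                                          row$patient_id)))
    if (!is.na(row$rate)) expect_equal(recs[[iri]]$rate, row$rate)
  }
})
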