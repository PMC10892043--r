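XSD <- "http://www.w3.org/2001/XMLSchema#"
RDF <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#"
RDFS <- "http://www.w3.org/2000/01/rdf-schema#"
OWL <- "http://www.w3.org/2002/07/owl#"
SOSA <- "http://www.w3.org/ns/sosa/"
SSN <- "http://www.w3.org/ns/ssn/"
ADL <- "http://example.org/adl#"
ADLR <- "http://example.org/adl/resource/"

adl_prefixes <- function() {
  c(rdf = RDF, rdfs = RDFS, owl = OWL, xsd = XSD,
    sosa = SOSA, ssn = SSN, adl = ADL, adlr = ADLR)
}

iri_rdf_type <- paste0(RDF, "type")
iri_subclass <- paste0(RDFS, "subClassOf")

adl <- function(local) paste0(ADL, local)
adlr <- function(local) paste0(ADLR, local)

#' An in-memory RDF knowledge graph
#'
#' `kg_new()` creates an empty graph; a graph is a set of (subject,
#' predicate, object) triples held in a tibble, where each object is either
#' an IRI or a typed literal. `kg_add()` adds triples (duplicates are
#' collapsed — a graph is a set); `kg_size()` counts triples.
#'
#' @param triples optional triple tibble with columns `subject`, `predicate`,
#'   `object`, `object_kind` (`"iri"` or `"literal"`), `datatype` (XSD
#'   datatype IRI, `NA` for IRIs and plain strings).
#' @return `kg_new()` and `kg_add()` return an `adl_kg` object.
#' @examples
#' kg <- kg_new()
#' kg_size(kg)
#' @export
kg_new <- function(triples = NULL) {
  empty <- tibble(subject = character(0), predicate = character(0),
                  object = character(0), object_kind = character(0),
                  datatype = character(0))
  triples <- if (is.null(triples)) empty else as_tibble(triples)
  structure(list(triples = distinct(triples), prefixes = adl_prefixes()),
            class = "adl_kg")
}

#' @rdname kg_new
#' @param kg an `adl_kg` object.
#' @export
kg_add <- function(kg, triples) {
  stopifnot(inherits(kg, "adl_kg"))
  kg$triples <- distinct(bind_rows(kg$triples, as_tibble(triples)))
  kg
}

#' @rdname kg_new
#' @export
kg_size <- function(kg) nrow(kg$triples)

#' @export
#' @method print adl_kg
print.adl_kg <- function(x, ...) {
  cat("<adl_kg> RDF knowledge graph:", nrow(x$triples), "triples\n")
  invisible(x)
}

#' @export
#' @method tidy adl_kg
tidy.adl_kg <- function(x, ...) x$triples

#' @export
#' @method glance adl_kg
glance.adl_kg <- function(x, ...) {
  inst <- kg_instance_triples(x)
  tibble(n_triples = nrow(x$triples),
         n_schema_triples = nrow(x$triples) - nrow(inst),
         n_instance_triples = nrow(inst),
         n_activities = length(kg_instances(x, adl("Activity"))),
         n_problems = length(kg_instances(x, adl("Problem"))))
}

triple_iri <- function(s, p, o) {
  tibble(subject = s, predicate = p, object = o,
         object_kind = "iri", datatype = NA_character_)
}

triple_lit <- function(s, p, lex, datatype = NA_character_) {
  tibble(subject = s, predicate = p, object = lex,
         object_kind = "literal", datatype = datatype)
}

lit_string <- function(s, p, x) triple_lit(s, p, x, paste0(XSD, "string"))
lit_datetime <- function(s, p, t) {
  triple_lit(s, p, format_instant(t), paste0(XSD, "dateTime"))
}
lit_decimal <- function(s, p, x) {
  triple_lit(s, p, sprintf("%.3f", x), paste0(XSD, "decimal"))
}
lit_integer <- function(s, p, x) {
  triple_lit(s, p, sprintf("%d", as.integer(x)), paste0(XSD, "integer"))
}

# objects of pred for given subjects (or all), as tibble(subject, object)
kg_pred <- function(kg, predicate) {
  kg$triples %>%
    filter(.data$predicate == !!predicate) %>%
    select("subject", "object", "datatype")
}

#' Query instances of a class, honouring the subclass hierarchy
#'
#' Returns every subject typed (rdf:type) with the class or with any
#' transitive rdfs:subClassOf descendant of it — the subclass-closure
#' reasoning the framework relies on (e.g. instances of any of the four
#' problem subclasses are instances of the problem class).
#'
#' @param kg an `adl_kg`.
#' @param class_iri class IRI, e.g. `adl_iri("Problem")`.
#' @return Character vector of instance IRIs, sorted.
#' @export
kg_instances <- function(kg, class_iri) {
  subs <- kg_subclasses(kg, class_iri)
  kg$triples %>%
    filter(.data$predicate == iri_rdf_type, .data$object %in% subs) %>%
    pull(.data$subject) %>% unique() %>% sort()
}

# transitive rdfs:subClassOf closure, including the class itself
kg_subclasses <- function(kg, class_iri) {
  edges <- kg$triples %>%
    filter(.data$predicate == iri_subclass, .data$object_kind == "iri")
  found <- class_iri
  repeat {
    more <- edges$subject[edges$object %in% found]
    new <- setdiff(more, found)
    if (length(new) == 0) return(found)
    found <- c(found, new)
  }
}

#' IRIs of the ADL vocabulary
#'
#' Helpers to mint IRIs in the ontology namespace (`adl_iri`) and the
#' instance namespace (`adl_resource`).
#'
#' @param local local name.
#' @export
adl_iri <- function(local) adl(local)

#' @rdname adl_iri
#' @export
adl_resource <- function(local) adlr(local)

PROBLEM_TYPES <- c("TooLongDuration", "DivergenceFromProtocol",
                   "ExtraSteps", "MissingSteps")

FEATURE_CLASSES <- c("MotionFeature", "DoorFeature", "PanicFeature",
                     "ConsumptionFeature")

SENSOR_CLASS_BY_KIND <- c(
  motion = "MotionSensor", door = "DoorSensor",
  panic = "PanicSensor", wall_plug = "WallPlug"
)

# feature-of-interest singletons live in the schema graph
feature_individual <- function(feature_class) {
  adlr(paste0("feature/", slugify(feature_class)))
}

ADL_OBJECT_PROPERTIES <- tibble::tribble(
  ~name,                 ~domain,       ~range,
  "consistsOf",          "Activity",    "Observation",
  "refersToUser",        "Activity",    "Patient",
  "refersToDevice",      "Observation", "Device",
  "hasFeatureOfInterest","Observation", "FeatureOfInterest",
  "observesProperty",    "Observation", "ObservableProperty",
  "isProblemOf",         "Problem",     "Patient",
  "problematicActivity", "Problem",     "Activity"
)

ADL_DATA_PROPERTIES <- tibble::tribble(
  ~name,                    ~domain,       ~range,
  "activity_pk",            "Activity",    "string",
  "activity_start",         "Activity",    "dateTime",
  "activity_end",           "Activity",    "dateTime",
  "activity_name",          "Activity",    "string",
  "activity_duration",      "Activity",    "decimal",
  "observation_start_time", "Observation", "dateTime",
  "observation_end_time",   "Observation", "dateTime",
  "device_name",            "Device",      "string",
  "problem_date",           "Problem",     "dateTime",
  "problem_rate",           "Problem",     "decimal"
)

#' Build the ADL Recognition Ontology schema graph
#'
#' Constructs the schema-only knowledge graph: an SSN/SOSA-aligned ontology
#' for activity-of-daily-living recognition. Core classes are `Sensor` (with
#' one subclass per device kind), `Observation`, `Activity`,
#' `FeatureOfInterest` (four subclasses, one per sensed feature),
#' `ObservableProperty`, `Patient`, `Device`, and `Problem` with exactly
#' four subclasses: `TooLongDuration`, `DivergenceFromProtocol`,
#' `ExtraSteps` and `MissingSteps`. Alignment with the public SSN/SOSA
#' vocabularies is declared by `owl:equivalentClass` links; no external
#' ontology is fetched. Four feature-of-interest individuals (one per
#' subclass) are part of the schema so instance observations can link to
#' them.
#'
#' @return An `adl_kg` holding the schema triples.
#' @examples
#' kg <- build_ontology()
#' length(kg_instances(kg, adl_iri("FeatureOfInterest")))
#' @export
build_ontology <- function() {
  owl_class <- paste0(OWL, "Class")
  equiv <- paste0(OWL, "equivalentClass")
  t <- list()
  classes <- c("Device", "Sensor", SENSOR_CLASS_BY_KIND, "Observation",
               "Activity", "FeatureOfInterest", FEATURE_CLASSES,
               "ObservableProperty", "Patient", "Problem", PROBLEM_TYPES)
  t[[1]] <- triple_iri(adl(classes), iri_rdf_type, owl_class)
  t[[2]] <- triple_iri(adl("Sensor"), iri_subclass, adl("Device"))
  t[[3]] <- triple_iri(adl(unname(SENSOR_CLASS_BY_KIND)), iri_subclass,
                       adl("Sensor"))
  t[[4]] <- triple_iri(adl(FEATURE_CLASSES), iri_subclass,
                       adl("FeatureOfInterest"))
  t[[5]] <- triple_iri(adl(PROBLEM_TYPES), iri_subclass, adl("Problem"))
  # alignment with the public SSN/SOSA vocabulary
  t[[6]] <- triple_iri(
    adl(c("Sensor", "Observation", "FeatureOfInterest", "ObservableProperty")),
    equiv,
    paste0(SOSA, c("Sensor", "Observation", "FeatureOfInterest",
                   "ObservableProperty")))
  t[[7]] <- triple_iri(adl(ADL_OBJECT_PROPERTIES$name), iri_rdf_type,
                       paste0(OWL, "ObjectProperty"))
  t[[8]] <- triple_iri(adl(ADL_OBJECT_PROPERTIES$name), paste0(RDFS, "domain"),
                       adl(ADL_OBJECT_PROPERTIES$domain))
  t[[9]] <- triple_iri(adl(ADL_OBJECT_PROPERTIES$name), paste0(RDFS, "range"),
                       adl(ADL_OBJECT_PROPERTIES$range))
  t[[10]] <- triple_iri(adl(ADL_DATA_PROPERTIES$name), iri_rdf_type,
                        paste0(OWL, "DatatypeProperty"))
  t[[11]] <- triple_iri(adl(ADL_DATA_PROPERTIES$name), paste0(RDFS, "domain"),
                        adl(ADL_DATA_PROPERTIES$domain))
  t[[12]] <- triple_iri(adl(ADL_DATA_PROPERTIES$name), paste0(RDFS, "range"),
                        paste0(XSD, ADL_DATA_PROPERTIES$range))
  t[[13]] <- triple_iri(feature_individual(FEATURE_CLASSES), iri_rdf_type,
                        adl(FEATURE_CLASSES))
  kg_new(bind_rows(t))
}

# instance triples = triples whose subject is not in the adl/owl schema space
kg_instance_triples <- function(kg) {
  kg$triples %>% filter(startsWith(.data$subject, ADLR))
}

#' Convert tabular records to RDF and assemble the knowledge graph
#'
#' Maps activities, observations, participants and devices onto the ADL
#' Recognition Ontology. Per activity: a type triple, `activity_pk`,
#' `activity_start`, `activity_end`, `activity_name`, `activity_duration`
#' (seconds, xsd:decimal), one `refersToUser` and one `consistsOf` per
#' member observation. Per observation: a type triple,
#' `observation_start_time`, `refersToDevice` and `hasFeatureOfInterest`.
#' Per device: a type triple (the sensor subclass for its kind) and
#' `device_name`. Per participant: a type triple. IRIs are minted
#' deterministically from primary keys, so identical inputs give identical
#' graphs.
#'
#' @param activities activities tibble ([segment_activities()]).
#' @param observations observations tibble ([events_to_observations()]).
#' @param participants roster tibble (`participant_id`, `group`).
#' @param devices device registry tibble.
#' @param schema schema graph to extend; defaults to [build_ontology()].
#' @return An `adl_kg` with schema plus instance triples.
#' @export
to_rdf <- function(activities, observations, participants, devices,
                   schema = build_ontology()) {
  devices <- validate_devices(devices)
  activities <- as_tibble(activities)
  observations <- as_tibble(observations)
  participants <- validate_roster(participants)
  missing_obs <- setdiff(unlist(activities$observation_ids),
                         observations$observation_id)
  if (length(missing_obs) > 0) {
    abort(paste0("activities reference observation(s) absent from input: ",
                 paste(missing_obs, collapse = ", ")))
  }
  t <- list()
  if (nrow(devices) > 0) {
    dev_iri <- adlr(paste0("device/", slugify(devices$name)))
    t[[length(t) + 1]] <- triple_iri(
      dev_iri, iri_rdf_type, adl(unname(SENSOR_CLASS_BY_KIND[devices$kind])))
    t[[length(t) + 1]] <- lit_string(dev_iri, adl("device_name"), devices$name)
  }
  if (nrow(participants) > 0) {
    t[[length(t) + 1]] <- triple_iri(
      adlr(paste0("patient/", participants$participant_id)),
      iri_rdf_type, adl("Patient"))
  }
  if (nrow(observations) > 0) {
    obs_iri <- adlr(paste0("observation/", observations$observation_id))
    dev_by_id <- setNames(slugify(devices$name), devices$device_id)
    t[[length(t) + 1]] <- triple_iri(obs_iri, iri_rdf_type, adl("Observation"))
    t[[length(t) + 1]] <- lit_datetime(obs_iri, adl("observation_start_time"),
                                       observations$start)
    t[[length(t) + 1]] <- triple_iri(
      obs_iri, adl("refersToDevice"),
      adlr(paste0("device/", unname(dev_by_id[observations$device_id]))))
    t[[length(t) + 1]] <- triple_iri(
      obs_iri, adl("hasFeatureOfInterest"),
      feature_individual(observations$feature_of_interest))
  }
  if (nrow(activities) > 0) {
    act_iri <- adlr(paste0("activity/", activities$pk))
    t[[length(t) + 1]] <- triple_iri(act_iri, iri_rdf_type, adl("Activity"))
    t[[length(t) + 1]] <- lit_string(act_iri, adl("activity_pk"),
                                     activities$pk)
    t[[length(t) + 1]] <- lit_datetime(act_iri, adl("activity_start"),
                                       activities$start)
    t[[length(t) + 1]] <- lit_datetime(act_iri, adl("activity_end"),
                                       activities$end)
    t[[length(t) + 1]] <- lit_string(act_iri, adl("activity_name"),
                                     activities$name)
    t[[length(t) + 1]] <- lit_decimal(act_iri, adl("activity_duration"),
                                      activities$duration_s)
    t[[length(t) + 1]] <- triple_iri(
      act_iri, adl("refersToUser"),
      adlr(paste0("patient/", activities$participant_id)))
    co <- tidyr::unnest(
      tibble(act = act_iri, obs = activities$observation_ids), "obs")
    t[[length(t) + 1]] <- triple_iri(
      co$act, adl("consistsOf"), adlr(paste0("observation/", co$obs)))
  }
  kg_add(schema, bind_rows(t))
}

#' Check schema conformance of a knowledge graph
#'
#' Lightweight integrity checking in lieu of full OWL reasoning: reports
#' instances missing required properties (an activity without a user, start,
#' end or name; an observation without a device or feature-of-interest
#' link; a problem without a patient), instance triples whose predicate is
#' not declared in the ontology, and dangling `consistsOf` targets. A valid
#' graph yields an empty report.
#'
#' @param kg an `adl_kg` built by [to_rdf()].
#' @return A tibble of violations (`subject`, `requirement`, `message`);
#'   zero rows when the graph conforms.
#' @export
check_conformance <- function(kg) {
  v <- list()
  flag <- function(subjects, requirement) {
    if (length(subjects) > 0) {
      v[[length(v) + 1]] <<- tibble(
        subject = subjects, requirement = requirement,
        message = paste0(requirement, " missing or invalid for <",
                         subjects, ">"))
    }
  }
  need <- function(instances, pred) {
    setdiff(instances, unique(kg_pred(kg, adl(pred))$subject))
  }
  acts <- kg_instances(kg, adl("Activity"))
  for (p in c("refersToUser", "activity_start", "activity_end",
              "activity_name", "activity_pk")) {
    flag(need(acts, p), paste0("Activity requires ", p))
  }
  obs <- kg_instances(kg, adl("Observation"))
  for (p in c("refersToDevice", "hasFeatureOfInterest",
              "observation_start_time")) {
    flag(need(obs, p), paste0("Observation requires ", p))
  }
  probs <- kg_instances(kg, adl("Problem"))
  flag(need(probs, "isProblemOf"), "Problem requires isProblemOf")
  # every instance predicate must be declared in the ontology
  declared <- c(iri_rdf_type,
                adl(c(ADL_OBJECT_PROPERTIES$name, ADL_DATA_PROPERTIES$name)))
  inst <- kg_instance_triples(kg)
  undecl <- inst %>% filter(!.data$predicate %in% declared)
  flag(unique(undecl$predicate), "predicate declared in ontology")
  # consistsOf must point at observations present in the graph
  co <- kg_pred(kg, adl("consistsOf"))
  flag(unique(co$object[!co$object %in% obs]),
       "consistsOf target is an Observation")
  if (length(v) == 0) {
    return(tibble(subject = character(0), requirement = character(0),
                  message = character(0)))
  }
  bind_rows(v)
}
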