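---
title: "Detecting problems in smart-home activities of daily living with a knowledge graph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting problems in smart-home activities of daily living with a knowledge graph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adlgraph)
```

## The problem

Difficulty with instrumental activities of daily living (ADLs) — meal
preparation above all — is an early functional marker along the dementia
spectrum. A kitchen instrumented with unobtrusive sensors (motion, door,
drawer and cabinet contacts, and wall plugs metering appliance power) can
observe how a person executes a scripted task without cameras or wearables.
`adlgraph` implements the full chain from raw sensor streams to
clinician-readable problem reports:

1. **Ingest** — segment the two raw time-series dialects into events:
   boolean state-change *signals* and wattage *consumption* series.
2. **Compose** — cluster events into observations and observations into
   named ADL activities using protocol templates.
3. **Represent** — convert everything into an RDF knowledge graph under an
   SSN/SOSA-aligned ontology.
4. **Detect** — run four declarative rules over the graph to derive problem
   instances (too long duration, divergence from protocol, extra steps,
   missing steps) and enrich the graph with them.
5. **Report** — aggregate problems per cognitive-status group (HC, SCD,
   MCI) and export dashboard-ready data.

Because no sensor data set is distributed, the package carries a seeded
cohort simulator; every claim the test suite makes is made against streams
it generates.

## Event segmentation

A signal event opens at a `0 → 1` transition and closes at the next
`1 → 0` of the same device. Readings whose old and new values coincide
carry no information and are dropped. A repeated `0 → 1` without an
intervening closure is ignored with a warning: the pairing rule assumes
alternation, and keeping the first opening preserves the earliest evidence.
A signal still open at stream end is, by default, closed at the stream's
last timestamp and flagged `terminated = FALSE` rather than dropped, so the
evidence remains available to activity composition.

A wall plug is classified *in use* when a reading is at or above the
consumption threshold and *idle* strictly below it. The threshold defaults
to 5 W — the empirical idle/active boundary for household appliances on a
metered plug. The boundary itself counts as in use, making "below the
threshold" literally the off condition; the test suite pins this by sweeping
4.9 / 5.0 / 5.1 W. Every sub-threshold dip closes the running event (no
debounce): how long a dip may last before the session should be considered
ended is not knowable from the data model, so the package does not guess.

Contact sensors sometimes miss a closure (a cabinet door left ajar),
yielding events of implausible length. `normalize_events()` truncates any
signal event longer than `max_plausible_signal_duration_s` (default 4 h) to
exactly that duration and flags it unterminated.

Timestamps are ISO 8601 UTC instants held at millisecond precision, and all
durations are exact second differences as decimals — the problem rules
compare durations in seconds, so nothing coarser would be faithful.

## From events to activities

The original study protocol clustered events into activities by manual
inspection; `adlgraph` replaces this with template matching, the automated
direction the study itself points to. A `ProtocolTemplate` names the task,
its room, the devices whose events may join the cluster, the *trigger*
appliance that identifies the task (cooker for hot meal, kettle for hot
beverage, toaster for cold meal preparation), and the maximum gap between
consecutive observation starts, `max_gap_s`.

Observations on member devices chain into a cluster while consecutive
starts differ by at most `max_gap_s`; a cluster containing a trigger
observation becomes an activity spanning all its member observations. The
default gap is 900 s (15 min): no published value exists, and 900 s sits
well below the 2100 s normal-duration bound, so one task cannot silently
absorb the next. Each observation joins at most one activity; templates are
matched in order and ties go to the earlier cluster, which is deterministic
for sorted input. Motion observations join any template in their room but
never trigger: continuous room presence accompanies a task, it does not
identify one.

The activity interval spans all member observations
(`start = min start`, `end = max end`). How an activity's bounds should
relate to the enclosing motion event is not defined anywhere authoritative;
spanning all members is the choice that makes duration a pure function of
the members.

## The knowledge graph

The ADL Recognition Ontology declares `Sensor` (one subclass per device
kind), `Observation`, `Activity`, `FeatureOfInterest` (four subclasses:
motion, door, panic, consumption), `ObservableProperty`, `Patient`,
`Device`, and `Problem` with exactly four subclasses — one per detectable
problem type. Alignment with the public SSN/SOSA vocabularies is declared
through `owl:equivalentClass` links on local classes; nothing is fetched
from the network.

`to_rdf()` mints IRIs deterministically from primary keys
(`{base}/activity/{pk}`, `{base}/observation/{id}`,
`{base}/patient/{id}`, `{base}/device/{slug}`), so identical inputs give
graphs equal as triple sets. Instants are `xsd:dateTime` literals and
durations are materialized as `xsd:decimal` seconds on an
`activity_duration` property. Comparing a dateTime difference against an
`xsd:duration` constant is not portable across SPARQL 1.1 engines, whereas
decimal seconds are order-isomorphic to durations and directly testable;
this is a deliberate, documented representation choice. Each observation
additionally links to one of four feature-of-interest individuals shipped
with the schema — the link every observation is required to have, and one
the conformance checker verifies.

The store itself is an embedded, in-memory triple table. Reasoning is
deliberately limited to transitive subclass closure (`kg_instances()`) plus
schema-conformance reporting (`check_conformance()`): the framework's rules
need exactly that much inference and no more. Graphs serialize to Turtle
and N-Triples in a canonical sorted form, so serialization is byte-stable
and round-trips exactly.

## The four problem rules

All four rules are instantiated by default for "Hot Meal Preparation", the
task with the richest data; the thresholds are clinician-set constants:

| rule | fires when | rate reported |
|---|---|---|
| TooLongDuration | duration strictly > 2100 s (35 min) | duration (s) |
| ExtraSteps | distinct observations strictly > 20 | count |
| MissingSteps | distinct observations strictly < 10 | count |
| DivergenceFromProtocol | some (cabinet, cooker, fridge) combination out of order | — |

The divergence rule encodes the protocol's prescribed order — food cabinet,
then cooker, then fridge door. For each activity containing at least one
observation on every protocol device it enumerates every combination of one
observation per device and fires when any combination violates the strict
chronological order `t1 < t2 < t3`. An activity lacking a protocol device
entirely is *not applicable* rather than divergent — the declarative form
requires at least one observation per device, and the package follows it.

Each fired rule constructs four triples — the problem's type, its patient
(`isProblemOf`), its date (the activity start) and either its rate
(`problem_rate`) or the problematic activity (`problematicActivity`) — and
asserts them into the graph. Problem IRIs are minted deterministically per
(rule, activity), which the published query form leaves unspecified (an
unbound subject in a CONSTRUCT template emits nothing under standard
semantics); deterministic minting both repairs that and makes re-running
the rules on an already-enriched graph a no-op. The published rule
*table* describes the step-count check as a single two-sided comparison,
but the executable query forms are two one-sided rules (> 20, < 10); the
queries carry the semantics, so the package implements them.

The engine executes these rules as relational joins over the triple table —
the same graph patterns a SPARQL engine would match. Two independent
routes check it: `brute_force_oracle()`, a loop-based reimplementation over
plain records, must agree on randomized graphs; and the four rules shipped
as SPARQL 1.1 `CONSTRUCT` files (`inst/extdata/sparql/*.rq`) are executed
by an external RDF engine in a test and must construct the same problems.

## The synthetic cohort

The simulator emulates the pilot's study conditions: 13 healthy controls,
14 participants with subjective cognitive decline, 13 with mild cognitive
impairment, each performing the hot meal task once. Durations are sampled
per group from a truncated normal with the published group means (HC
1782.36 s, SCD 2179.81 s, MCI 2399 s); step counts from a rounded normal
with the published means (15.72, 15.63, 18.37, floor 1); divergence flags
from the published per-group deviation rates (0.81, 0.81, 1.0). Only the
means and rates are published: the dispersions (duration sd 400 s, step sd
4) are simulator choices fixed once — plausible within-group variability
for a timed kitchen task — and everything downstream treats them as given.
A participation knob (default 1) exists because the pilot notes not every
participant completed every task, but no published value pins it.

A generated activity emits: a kitchen motion signal spanning exactly the
planned duration; one short door signal pair per door step; and a cooker
wattage series idle outside and 800–1500 W inside the cooking window (only
the ≥ 5 W classification matters downstream). Steps are spaced by
`min(duration/steps, 850 s)` so a plan always chains into one cluster under
the 900 s default gap. Divergence is injected by moving the fridge event
before the cabinet event — the minimal permutation the divergence rule
detects. The generator returns its ground-truth plans, and the test suite
requires the pipeline to recover durations, step counts and divergence
flags *exactly* for a full 40-participant cohort.

What the simulator does not emulate: multi-occupancy, sensor dropout and
connectivity loss, overlapping or interleaved tasks, physiologically
realistic appliance load curves, and day-to-day within-person variability.
Tests passing on synthetic streams therefore demonstrate the correctness of
the machinery, not field performance on real homes.

## Reporting

`summarize_problems()` reports, per group, the percentage of participants
with at least one problem of each type; a participant with several problems
of one type counts once. The denominator is the number of participants in
the group with at least one activity of the target name, not the group
size: published group percentages imply task-level denominators smaller
than the groups, and participants who never performed the task cannot be
flagged. The missing-steps column is emitted even when all zeros.
`export_dashboard()` writes the three dashboard sections (event log,
activity log, problems over time) as byte-stable JSON.

## Numerical and scale choices

* All randomness flows from a single integer seed; every pipeline product
  is byte-stable under a fixed seed.
* Strict inequalities everywhere the rules state them; boundary values
  (5.0 W, 2100 s, 10 and 20 steps) are pinned by dedicated tests.
* Simultaneous protocol steps (equal start times) violate the strict order
  and count as divergence.
* Test problem sizes: randomized rule-equivalence uses 100 graphs of up to
  ~30 activities; stochastic-ordering checks use 20 cohorts of 40
  participants; parameter-recovery uses 200 activities per group. These
  sizes give stable statistics while keeping the whole suite fast.

## Known limitations

* Single-occupancy assumption throughout; streams from cohabiting persons
  are not disambiguated.
* The per-seed group ordering of duration-problem rates (HC ≤ SCD ≤ MCI)
  is a population-level property: with 13–14 participants per group and
  one activity each, adjacent groups (SCD vs MCI, mean gap ≈ 220 s against
  a sampling sd of the rate difference ≈ 0.18) invert in a minority of
  seeds. Pooled across seeds the ordering is unambiguous, and the test
  suite asserts both facts explicitly.
* The Turtle reader accepts the subset the writer emits (no blank nodes,
  collections or language tags) — it is a round-trip companion, not a
  general parser.
* Rules ship instantiated for the hot-meal task; the other two tasks are
  configurable but carry no published thresholds.
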