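# Extra-steps rule: distinct-observation count strictly above 20.
PREFIX adl:  <http://example.org/adl#>
PREFIX adlr: <http://example.org/adl/resource/>
CONSTRUCT {
  ?problem a adl:ExtraSteps ;
           adl:isProblemOf ?patient ;
           adl:problem_date ?start ;
           adl:problem_rate ?steps .
}
WHERE {
  { SELECT ?activity ?activity_pk ?patient ?start (COUNT(DISTINCT ?event) AS ?steps)
    WHERE {
      ?activity a adl:Activity ;
                adl:activity_name "Hot Meal Preparation" ;
                adl:activity_pk ?activity_pk ;
                adl:activity_start ?start ;
                adl:refersToUser ?patient ;
                adl:consistsOf ?event .
    }
    GROUP BY ?activity ?activity_pk ?patient ?start
    HAVING (COUNT(DISTINCT ?event) > 20)
  }
  BIND(IRI(CONCAT(STR(adlr:), "problem/extrasteps/", ?activity_pk)) AS ?problem)
}
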