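# Too-long-duration rule: one problem per hot-meal activity whose duration
# (decimal seconds) strictly exceeds 2100 s.
PREFIX adl:  <http://example.org/adl#>
PREFIX adlr: <http://example.org/adl/resource/>
PREFIX xsd:  <http://www.w3.org/2001/XMLSchema#>
CONSTRUCT {
  ?problem a adl:TooLongDuration ;
           adl:isProblemOf ?patient ;
           adl:problem_date ?start ;
           adl:problem_rate ?duration .
}
WHERE {
  ?activity a adl:Activity ;
            adl:activity_pk ?activity_pk ;
            adl:activity_start ?start ;
            adl:activity_end ?end ;
            adl:activity_name "Hot Meal Preparation" ;
            adl:refersToUser ?patient ;
            adl:activity_duration ?duration .
  FILTER( ?duration > 2100 )
  BIND(IRI(CONCAT(STR(adlr:), "problem/toolongduration/", ?activity_pk)) AS ?problem)
}
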