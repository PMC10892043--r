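# Divergence-from-protocol rule: the protocol prescribes food cabinet, then
# cooker, then fridge door. Fires for every activity containing at least one
# observation per protocol device for which some combination of one
# observation per device violates the strict chronological order.
PREFIX adl:  <http://example.org/adl#>
PREFIX adlr: <http://example.org/adl/resource/>
CONSTRUCT {
  ?problem a adl:DivergenceFromProtocol ;
           adl:isProblemOf ?patient ;
           adl:problem_date ?start ;
           adl:problematicActivity ?activity .
}
WHERE {
  ?activity a adl:Activity ;
            adl:activity_pk ?activity_pk ;
            adl:activity_start ?start ;
            adl:activity_name "Hot Meal Preparation" ;
            adl:refersToUser ?patient .
  ?activity adl:consistsOf ?event1 .
  ?event1 adl:observation_start_time ?time1 ; adl:refersToDevice ?device1 .
  ?device1 adl:device_name "Cabinet (Food)" .
  ?activity adl:consistsOf ?event2 .
  ?event2 adl:observation_start_time ?time2 ; adl:refersToDevice ?device2 .
  ?device2 adl:device_name "Cooker" .
  ?activity adl:consistsOf ?event3 .
  ?event3 adl:observation_start_time ?time3 ; adl:refersToDevice ?device3 .
  ?device3 adl:device_name "Fridge Door1" .
  FILTER( !(?time1 < ?time2 && ?time2 < ?time3) )
  BIND(IRI(CONCAT(STR(adlr:), "problem/divergencefromprotocol/", ?activity_pk)) AS ?problem)
}
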