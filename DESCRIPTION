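Package: emsdes
Title: Rule-Based Discrete-Event Simulation of Emergency Medical Services
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: A rule-based discrete-event simulator for emergency medical
    services (EMS). Ingests standardized incident logs, rosters, bases and
    hospitals into a validated scenario bundle; cleans raw dispatch data
    (area restriction with "external" attribution, timestamp-consistency
    rules, event grouping, roster expansion); simulates priority-dependent
    dispatching (closest-idle, historic-else-closest, multicopter-vs-ground)
    with speed-profile travel times; computes response-time KPIs (event
    response time under three variants, response-time compliance rate,
    prehospital time, utilization, overtime, demand profiles); and supports
    capacity planning via the unlimited-resources upper bound, an iterative
    reserve-capacity algorithm, and greedy covering location allocation for
    multicopter bases. Includes a synthetic-scenario generator emulating the
    statistical structure of confidential dispatch-center data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    geosphere,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
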