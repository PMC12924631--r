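Package: swinesim
Title: Agent-Based Simulation of Growth and Nutrient Requirements in
    Growing-Finishing Pigs
Version: 0.1.0
Authors@R:
    person("swinesim", "maintainers", email = "maintainers@swinesim.org",
           role = c("aut", "cre"))
Description: A daily-timestep, individual-based simulator of
    growing-finishing pigs (20 to 130 kg) built on the 2012 Swine NRC
    equation set. Each pig is an agent with its own stochastic body-weight
    gain; the model tracks body composition (protein, lipid, water, ash),
    metabolizable energy intake, feed intake, thermal environment effects,
    and full daily nutrient requirements (SID lysine and the essential
    amino acids, STTD phosphorus, calcium, minerals, vitamins). Includes
    Monte-Carlo replication statistics (mean, SD, 95% CI trajectories) and
    a verification harness comparing stochastic output against the
    deterministic reference equations by linear regression.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    graphics,
    grDevices,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
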