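Package: winterbird
Title: Optimal Winter Fattening and Nocturnal Hypothermia in Small Birds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stochastic dynamic programming model of adaptive body temperature
    and fat regulation in a small boreal passerine ("the little bird in winter").
    The package solves, by backward induction over a discrete lattice of fat
    reserves, hypothermia depth, weather and 5-minute time periods, for the
    behaviour policy that maximises whole-winter survival under a
    starvation-predation trade-off, then forward-simulates cohorts of birds that
    follow the optimal policy. It reproduces the classic predictions of winter
    fattening and facultative night-time hypothermia: daily fat gain
    trajectories, dusk and dawn reserves, depth and timing of nocturnal
    hypothermia, pre-dawn rewarming, and the survival value of hypothermic
    energy savings.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
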