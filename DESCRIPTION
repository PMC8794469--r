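Package: exploreExploit
Title: Latent Explore/Exploit State Analysis for Restless Bandit Behavior
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analyzing explore/exploit dynamics in restless
    two-armed bandit choice behavior. Simulates drifting reward schedules
    and arbitrary choice policies, generates synthetic cohorts with known
    ground truth, labels exploratory choices with a tied two-parameter
    hidden Markov model (Baum-Welch fitting, Viterbi decoding, and two
    four-parameter variants), fits a suite of seven reinforcement-learning
    likelihood models (delta rule, softmax, choice kernel, lapse,
    asymmetric learning), characterizes switching dynamics with geometric
    mixture models, converts fitted transition matrices into
    Boltzmann/Arrhenius energy landscapes, and computes model-free
    behavioral metrics (win-stay/lose-shift, conditional mutual
    information, tetrachoric label agreement, ROC separability, matching
    law).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
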