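Package: mossense
Title: Smartphone Behavioral Sensing, Context-Aware Intervention
    Recommendation and Passive Depression Detection
Version: 0.1.0
Authors@R:
    person("Mossense", "Developers", email = "mossense@example.org",
           role = c("aut", "cre"))
Description: Tools for digital phenotyping of depressive symptoms from
    smartphone sensor streams.  Computes behavioral proxy features
    (general activity from accelerometer windows, walking time, WiFi
    fingerprint based time at home, GPS mobility metrics including
    location variance, communication and calendar counts), aggregates
    them into 120-dimensional descriptors of the two weeks preceding
    each biweekly PHQ-9 self report, and classifies clinically relevant
    depression (PHQ-9 >= 11) with leave-one-subject-out cross-validated
    random forests and RBF support vector machines.  Also implements a
    two-phase context-sensitive recommender that scores baskets of
    cognitive-behavioral-therapy interventions against the last 24 hours
    of behavior, trial-style evaluation statistics (adherence bands,
    Wilcoxon signed-rank symptom progression, Spearman usage-symptom
    correlation), and a synthetic multi-week sensor-stream simulator so
    the whole pipeline is testable without participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
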