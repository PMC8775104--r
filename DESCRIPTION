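Package: megtonus
Title: Regional Tonic Neuroelectric Activity Biomarkers from MEG Current Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for regional measures of tonic neuroelectric
    activation derived from localized MEG current events. Screens individual
    currents against empty-room "dark counts" with a per-region, per-subject
    random-forest classifier built on four local geometric features; normalizes
    regional current counts to volume-normalized densities; builds a normative
    z-score atlas; quantifies short- and long-term test-retest reliability with
    a Welch comparison between correction methods; classifies symptom
    presence/absence with jackknifed stepwise linear discriminant classifiers;
    and tests cortical versus adjacent white-matter differential activity with
    volume-based expected counts. Includes a synthetic cohort generator that
    emulates solver output (per-region multinomial counts with subject-stable
    activation, session noise, symptom-linked shifts, and geometrically
    atypical contaminant currents) so the full pipeline is exercisable without
    access-restricted recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    randomForest,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
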