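Package: photocap
Title: Leaf Photosynthetic Capacity from A/Ci Curves and Leaf Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the maximum Rubisco carboxylation rate (Vcmax) and the
    maximum electron-transport rate (Jmax) of C3 leaves from gas-exchange
    CO2-response (A/Ci) curves using the Farquhar-von Caemmerer-Berry model
    with an explicit limitation-state partition, normalizes them to 25 degrees
    Celsius with an Arrhenius temperature response, derives leaf pigment and
    structural traits from spectrophotometric absorbances, partitions leaf
    nitrogen into Rubisco, bioenergetics and light-harvesting pools, and
    relates Vcmax25 to leaf nitrogen, chlorophyll and carotenoid content
    through correlation, linear-regression and random-forest importance
    analyses. Includes a synthetic winter-wheat field-season generator with
    known ground truth so the whole inference chain can be exercised and
    validated without field data, and a reproducible pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    randomForest,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
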