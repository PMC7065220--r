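Package: cassleaf
Title: Steady-State and Dynamic Limitation Analysis of Cassava Leaf Photosynthesis
Version: 0.1.0
Authors@R: person("cassleaf", "developers", role = c("aut", "cre"),
    email = "cassleaf@example.org")
Description: Tools for diagnosing and simulating limitations to C3 leaf
    photosynthesis, developed around cassava (Manihot esculenta) gas-exchange
    protocols. Fits A/ci response curves with the
    Farquhar-von Caemmerer-Berry (FvCB) model including triose-phosphate
    utilization, estimates mesophyll conductance by the variable-J
    chlorophyll-fluorescence method, partitions steady-state limitation into
    stomatal, mesophyll and biochemical shares (Grassi-Magnani), analyses
    photosynthetic induction and stomatal opening/closing kinetics under
    fluctuating light, and couples a dynamic Ball-Berry stomatal model with
    Rubisco activation and FvCB demand to quantify carbon and water-use
    efficiency losses under fluctuating light. Includes a synthetic
    gas-exchange data generator so every stage is testable without
    instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
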