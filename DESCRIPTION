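Package: nematrack
Title: Locomotion and Chemotaxis Analysis for Nematode Plate Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Quantifies nematode behaviour from plate-based tracking data:
    chemotaxis-index scoring of two-point odorant assays, per-animal
    locomotion kinematics (speed filtering, track length, head-swinging
    index), sliding-window detection of pirouette-like reorientations with
    per-animal event rates, and rank-based group comparisons with bootstrap
    effect sizes. Ships a correlated-random-walk simulator of worm tracks
    and multinomial plate endpoints so every stage can be validated by
    parameter recovery against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
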