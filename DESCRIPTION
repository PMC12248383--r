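Package: rrow
Title: Neuroeconomic Analysis of Restaurant Row Foraging Behavior
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for analyzing trial-level behavior from the Restaurant Row
    foraging task, in which a mouse budgets a fixed daily session across four
    serially visited, flavor-distinct feeding sites with tone-cued delay costs.
    Implements indifference-point (Heaviside step) threshold estimation for
    offer-zone and wait-zone decisions, offer-value and value-left quit
    economics, sunk-cost survival analysis with a 0-s control and bootstrap
    delta envelope, regret-related violation/nonviolation trial-sequence
    analysis, threshold-optimality scoring against food-maximizing and
    subjective-value-maximizing theoretical policies, session time-budget
    accounting, conditioned-place-preference delta scores, and an agent-based
    generative simulator of the task with recorded ground truth for
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
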