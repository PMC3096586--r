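Package: ptbox
Title: Probabilistic Timebox Queries for Gene Expression Time Courses
Version: 0.1.0
Authors@R:
    person("ptbox", "developers", email = "ptbox@example.org", role = c("aut", "cre"))
Description: Graphical-style timebox queries over gene-expression time
    courses, evaluated probabilistically. An ordered set of timeboxes
    (rectangles in time/value space) is compiled into a linear left-to-right
    hidden Markov model: each box becomes a normal-emission state whose mean
    is the box mid-height, whose standard deviation is a quarter of the box
    height, and whose geometric state duration matches the box width;
    uncovered time ranges become uniform-emission waiting states. Time
    courses are ranked by forward-algorithm log-likelihood and the top-m
    returned. The classic deterministic all-points-inside timebox query is
    included for comparison, together with a synthetic time-course generator
    (phase shift, speed variation, outliers, noise) and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
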