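Package: diurnalmusic
Title: Diurnal Patterns in Music Streaming Audio Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting diurnal structure in music listening
    behaviour from streaming-event logs. Events are filtered, audio
    features are aggregated per unique hour of the week, and k-means
    clustering with automated elbow selection partitions the week into
    recurring within-day subdivisions (morning, afternoon, evening, night,
    late night/early morning). Additional analyses relate hourly
    audio-feature variability to an activity-diversity index computed from
    time-use diaries, train a feed-forward neural network that classifies
    tracks and playlists to subdivisions with a circular error metric for
    agreement scoring, and compute one-sample preference statistics with
    Bonferroni correction for representative tracks. A synthetic-data
    module generates event logs, track catalogs, activity diaries and
    rating tables with known ground truth for end-to-end recovery testing.
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
    tools,
    tidyr,
    utils,
    withr
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
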