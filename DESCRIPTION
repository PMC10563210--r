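Package: searchscape
Title: Spatiotemporal Analysis of Disease-Related Search-Index Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An infodemiology toolkit for region-by-month search-volume
    panels (such as Baidu Index or Google Trends extracts). Provides
    multiplicative STL decomposition with trend- and seasonal-strength
    scoring and seasonal-peak detection; spatial autocorrelation analysis
    (global and local Moran's I with permutation inference, Getis-Ord Gi*
    hot-spot classification, the standard deviational ellipse); ordinary
    kriging with variogram fitting, polynomial trend removal and
    leave-one-out cross-validation; Spearman validation of an index series
    against an annual prevalence series with exact small-sample p-values;
    seasonal demand-share summaries; and a synthetic-data generator that
    emulates the statistical structure such panels exhibit, so the whole
    pipeline can be exercised without proprietary platform extracts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
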