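#' Bundled reference confusion matrices
#'
#' Published zero-shot evaluation results on the CASAS HH101 and HH125
#' smart homes ship with the package as plain-text confusion matrices
#' (rows = truth, columns = predicted). Scenario 1 trains on bathe / cook /
#' wash dinner dishes / watch TV / read and recognizes sleep / toilet /
#' relax zero-shot; scenario 2 trains on cook breakfast / wash dishes /
#' phone / dress / eat dinner and recognizes cook lunch / personal hygiene /
#' eat lunch. They serve as worked examples for [class_metrics()]: feeding
#' them through the one-vs-rest equations reproduces the reported per-class
#' accuracy and F-measure columns. The HH125 scenario-1 matrix is not
#' bundled: as printed it is internally inconsistent with its own per-class
#' report (its Toilet row duplicates HH101's), so it cannot serve as a
#' worked example.
#'
#' @param dataset `"hh101"` or `"hh125"`.
#' @param scenario 1 or 2 (`"hh125"` only has scenario 2; see above).
#' @return A `zs_confusion` object.
#' @export
reference_confusion <- function(dataset = c("hh101", "hh125"), scenario = 1) {
  dataset <- match.arg(dataset)
  scenario <- as.integer(scenario)
  if (dataset == "hh125" && scenario == 1) {
    abort(paste0("the hh125 scenario-1 matrix is internally inconsistent ",
                 "as published and is not bundled."))
  }
  path <- system.file(
    "extdata", sprintf("confusion_%s_scenario%d.tsv", dataset, scenario),
    package = "adlzero", mustWork = FALSE)
  if (!nzchar(path)) abort("no such reference confusion matrix.")
  df <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                          check.names = FALSE)
  as_zs_confusion(as.matrix(df))
}

#' Seen/unseen label sets of the two reference scenarios
#'
#' @param scenario 1 or 2.
#' @return A list with `seen` and `unseen` character vectors.
#' @export
reference_scenario_labels <- function(scenario = 1) {
  if (as.integer(scenario) == 1) {
    list(seen = c("Bathe", "Cook", "Wash Dinner Dishes", "Watch TV", "Read"),
         unseen = c("Sleep", "Toilet", "Relax"))
  } else {
    list(seen = c("Cook Breakfast", "Wash Dishes", "Phone", "Dress",
                  "Eat Dinner"),
         unseen = c("Cook Lunch", "Personal Hygiene", "Eat Lunch"))
  }
}
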