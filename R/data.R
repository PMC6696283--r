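#' Curated reference table of monensin transformation products
#'
#' Twelve reported transformation products of the polyether ionophore
#' monensin (plus the two parent standards MON A and MON B), with reported
#' retention times, sodiated m/z values, molecular formulas, transformation
#' shorthand, intensity classes, parent assignments and isomer annotations,
#' compiled from electrochemical (glassy-carbon and boron-doped diamond
#' electrodes), rat-liver-microsome and acid-hydrolysis experiments. This
#' is the worked case study for the suspect-screening pipeline.
#'
#' The printed transformation shorthand is reproduced verbatim and is known
#' to disagree with the exact element difference by -2H in two rows (TP 1
#' and TP 3); path labels derived from the formulas are authoritative.
#' One reported m/z (TP 8) is consistent with omitting the electron-mass
#' correction and deviates from the electron-corrected value by ~0.0006 Da.
#'
#' @param tp_only Drop the two parent standard rows when `TRUE`.
#' @return A data.frame with columns `id`, `method`, `rt_s`, `mz` (reported
#'   sodiated m/z), `formula` (reported, Na included), `neutral_formula`,
#'   `adduct`, `transformation_label` (verbatim shorthand),
#'   `intensity_class`, `parent_formula` (neutral; `NA` for the standards)
#'   and `isomer_annotation`.
#' @export
#' @examples
#' mon_tp_table()
mon_tp_table <- function(tp_only = FALSE) {
  path <- system.file("extdata", "monensin_tp_table.csv",
                      package = "tpscreen", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(rt_s = "numeric", mz = "numeric"))
  split <- lapply(tab$formula, split_adduct_formula)
  tab$neutral_formula <- vapply(split, function(s) format_formula(s$neutral),
                                character(1))
  tab$adduct <- vapply(split, `[[`, character(1), "adduct")
  for (col in c("parent_formula", "isomer_annotation", "transformation_label"))
    tab[[col]][is.na(tab[[col]])] <- ""
  if (tp_only) tab <- tab[startsWith(tab$id, "TP"), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}
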