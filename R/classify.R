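#' Morphological selection criteria
#'
#' The screening windows for fertilization-suitable sperm: the acrosome
#' should comprise 40-70% of the head area; the head width-to-length ratio
#' should be near the accepted 3:5 norm; the midpiece should be approximately
#' as long as the head and continue its axis; the head should contain no
#' large vacuole and at most two small ones occupying together at most 20% of
#' the head; residual cytoplasm is an anomaly only when it exceeds one third
#' of the head area. All windows are closed intervals.
#'
#' @param acrosome_window acrosome-head ratio window, percent.
#' @param radii_window head width/length ratio window. The default
#'   `[0.48, 0.72]` brackets the 3:5 norm widely enough that reference cells
#'   with ratios 0.48-0.7 are not excluded on this criterion (see vignette).
#' @param midpiece_window midpiece-head length ratio window.
#' @param max_small_vacuoles maximum count of small vacuoles.
#' @param max_vacuole_fraction maximum total vacuole area fraction of head.
#' @param large_vacuole_forbidden disqualify any single large vacuole.
#' @param max_residual_cytoplasm residual cytoplasm fails only strictly above
#'   this fraction (default 1/3).
#' @param max_axis_offset_deg maximum head/midpiece axis offset; evaluated
#'   only when axis data exists.
#' @return object of class `selection_criteria`.
#' @export
selection_criteria <- function(acrosome_window = c(40, 70),
                               radii_window = c(0.48, 0.72),
                               midpiece_window = c(0.8, 1.4),
                               max_small_vacuoles = 2,
                               max_vacuole_fraction = 0.20,
                               large_vacuole_forbidden = TRUE,
                               max_residual_cytoplasm = 1 / 3,
                               max_axis_offset_deg = 20) {
  for (w in list(acrosome_window, radii_window, midpiece_window))
    if (length(w) != 2 || w[1] > w[2]) stop("windows must be non-empty intervals")
  if (max_small_vacuoles < 0 || max_vacuole_fraction <= 0 ||
      max_residual_cytoplasm <= 0 || max_axis_offset_deg <= 0)
    stop("thresholds must be positive")
  structure(list(acrosome_window = acrosome_window,
                 radii_window = radii_window,
                 midpiece_window = midpiece_window,
                 max_small_vacuoles = max_small_vacuoles,
                 max_vacuole_fraction = max_vacuole_fraction,
                 large_vacuole_forbidden = large_vacuole_forbidden,
                 max_residual_cytoplasm = max_residual_cytoplasm,
                 max_axis_offset_deg = max_axis_offset_deg),
            class = "selection_criteria")
}

#' Classify one cell against the selection criteria
#'
#' Deterministic pass/fail per criterion. Windows are closed intervals;
#' residual cytoplasm fails only strictly above the limit (a blob of exactly
#' one third of the head is not an anomaly). An indeterminate measurement
#' (for example an acrosome ratio without class contrast) makes the cell
#' unselected with a distinct `"indeterminate"` status - conservative for a
#' fertilization-selection context. The axis-continuation criterion is
#' evaluated only when an axis offset is available and is otherwise marked
#' `"not_evaluated"` without blocking selection.
#'
#' @param m one-row tibble / list of morphometrics (see [measure_cell()]);
#'   required fields: `acrosome_head_ratio_pct`, `radii_ratio`,
#'   `midpiece_head_ratio`, `vacuole_count`, `vacuole_area_fraction`,
#'   `residual_cytoplasm_fraction`; optional: `any_large_vacuole`,
#'   `axis_offset_deg`, `flags`.
#' @param criteria a [selection_criteria()].
#' @return list with `cell_id`, `per_criterion` (named character vector with
#'   values `"pass"`, `"fail"`, `"indeterminate"`, `"not_evaluated"`) and
#'   `selected` (TRUE iff every evaluable criterion passes and none is
#'   indeterminate).
#' @export
classify_cell <- function(m, criteria = selection_criteria()) {
  m <- as.list(m)
  flags <- if (!is.null(m$flags)) m$flags else ""
  in_window <- function(v, w) !is.na(v) && v >= w[1] && v <= w[2]

  acr <- if (grepl("acrosome_indeterminate", flags) ||
             is.na(m$acrosome_head_ratio_pct)) "indeterminate"
         else if (in_window(m$acrosome_head_ratio_pct, criteria$acrosome_window))
           "pass" else "fail"
  rad <- if (in_window(m$radii_ratio, criteria$radii_window)) "pass" else "fail"
  mid <- if (in_window(m$midpiece_head_ratio, criteria$midpiece_window))
    "pass" else "fail"
  any_large <- isTRUE(m$any_large_vacuole)
  vac <- if (m$vacuole_count <= criteria$max_small_vacuoles &&
             m$vacuole_area_fraction <= criteria$max_vacuole_fraction &&
             !(criteria$large_vacuole_forbidden && any_large)) "pass" else "fail"
  cyt <- if (m$residual_cytoplasm_fraction > criteria$max_residual_cytoplasm)
    "fail" else "pass"
  axis_off <- m$axis_offset_deg
  axs <- if (is.null(axis_off) || is.na(axis_off)) "not_evaluated"
         else if (axis_off <= criteria$max_axis_offset_deg) "pass" else "fail"

  per <- c(acrosome = acr, radii = rad, midpiece = mid, vacuoles = vac,
           residual_cytoplasm = cyt, axis_continuation = axs)
  selected <- !any(per == "fail") && !any(per == "indeterminate")
  list(cell_id = if (!is.null(m$cell_id)) m$cell_id else NA,
       per_criterion = per, selected = selected)
}

#' Apply the selection criteria to a table of cells
#'
#' Classifies every row, returns the annotated table, the selected subset,
#' and a summary of how many cells failed each criterion.
#'
#' @param morphometrics tibble of per-cell morphometrics (one row per cell).
#' @param criteria a [selection_criteria()].
#' @return list with `table` (input plus one status column per criterion and
#'   a logical `selected`), `selected` (the selected subset), `n_selected`,
#'   and `summary` (named failure counts per criterion).
#' @export
select_cells <- function(morphometrics, criteria = selection_criteria()) {
  n <- nrow(morphometrics)
  crit_names <- c("acrosome", "radii", "midpiece", "vacuoles",
                  "residual_cytoplasm", "axis_continuation")
  if (n == 0) {
    tab <- morphometrics
    for (cn in crit_names) tab[[paste0("crit_", cn)]] <- character(0)
    tab$selected <- logical(0)
    return(list(table = tab, selected = tab, n_selected = 0L,
                summary = stats::setNames(integer(length(crit_names)), crit_names)))
  }
  res <- lapply(seq_len(n), function(i) classify_cell(morphometrics[i, ], criteria))
  tab <- morphometrics
  for (cn in crit_names)
    tab[[paste0("crit_", cn)]] <-
      vapply(res, function(r) unname(r$per_criterion[cn]), character(1))
  tab$selected <- vapply(res, `[[`, logical(1), "selected")
  fails <- vapply(crit_names, function(cn)
    sum(vapply(res, function(r) r$per_criterion[cn] == "fail", logical(1))),
    integer(1))
  list(table = tab, selected = tab[tab$selected, , drop = FALSE],
       n_selected = sum(tab$selected), summary = fails)
}
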