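#' Reference cell measurements
#'
#' Built-in reference table of five sperm cells (a-e) measured by stain-free
#' off-axis quantitative phase imaging inside microdroplets: acrosome-head
#' area ratio in percent, head radii ratio (width/length), midpiece-head
#' length ratio, and vacuole / residual-cytoplasm presence (none of these
#' five cells shows either). Under the default [selection_criteria()] cells
#' a, b and c are suitable while d and e fail the 40-70% acrosome window.
#'
#' @return tibble with columns `cell`, `cell_id`, `acrosome_head_ratio_pct`,
#'   `radii_ratio`, `midpiece_head_ratio`, `vacuole_count`,
#'   `vacuole_area_fraction`, `any_large_vacuole`,
#'   `residual_cytoplasm_fraction`, `axis_offset_deg`, `flags`.
#' @examples
#' sel <- select_cells(reference_cells())
#' sel$n_selected
#' @export
reference_cells <- function() {
  tibble::tibble(
    cell = c("a", "b", "c", "d", "e"),
    cell_id = 1:5,
    acrosome_head_ratio_pct = c(59.64, 47.3, 65.04, 31.01, 38.96),
    radii_ratio = c(0.57, 0.56, 0.63, 0.7, 0.48),
    midpiece_head_ratio = c(1.24, 1.11, 1.13, 1.16, 1.32),
    vacuole_count = 0L,
    vacuole_area_fraction = 0,
    any_large_vacuole = FALSE,
    residual_cytoplasm_fraction = 0,
    axis_offset_deg = NA_real_,
    flags = "")
}
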