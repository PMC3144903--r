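#' Published external pathogenicity predictions (metadata only)
#'
#' The BTPKD E3258K substitution was also scored by two external,
#' database-backed prediction tools (PolyPhen-2 and SIFT) whose models
#' cannot be recomputed from first principles. Their published scores are
#' carried here as descriptive metadata alongside the Align-GVGD scores
#' this package does recompute; nothing in the package derives them.
#'
#' @return A tibble with columns `tool`, `metric`, `value` and
#'   `recomputable` (whether `pkdscan` recomputes the quantity).
#' @export
external_prediction_metadata <- function() {
  tibble::tibble(
    tool = c(
      "PolyPhen-2", "PolyPhen-2", "PolyPhen-2",
      "Align-GVGD", "Align-GVGD",
      "SIFT", "SIFT", "SIFT"
    ),
    metric = c(
      "score", "sensitivity", "specificity",
      "GV", "GD",
      "sequences at position", "median sequence conservation", "score"
    ),
    value = c(0.991, 0.60, 0.96, 0.00, 56.87, 10, 3.45, 0.00),
    recomputable = c(FALSE, FALSE, FALSE, TRUE, TRUE, FALSE, FALSE, FALSE)
  )
}
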