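#' Published benchmark results of the texture-feature matcher
#'
#' EER and Rank-1 identification rates (percent) of the Gabor-texture
#' matcher reported for the original 58-subject visual-search study, per
#' probe size (NoET in 2, 4, 8, 16) on its short-term (`ST`: within-visit
#' 70/30 split) and long-term (`LT`: two-week re-test) datasets, at a
#' 128 x 128 trajectory-image size. These published cells are the inputs
#' to the report arithmetic in [relative_change()] — e.g. the Rank-1 loss
#' from ST to LT; they are not reproduced by the synthetic pipeline.
#'
#' @return Data frame with columns `NoET`, `eer_st`, `eer_lt`, `rank1_st`,
#'   `rank1_lt`.
#' @export
reference_gwt_results <- function() {
  data.frame(
    NoET = c(2, 4, 8, 16),
    eer_st = c(11.49, 6.06, 2.44, 0.89),
    eer_lt = c(20.03, 14.08, 11.48, 10.41),
    rank1_st = c(49.02, 71.75, 88.16, 96.44),
    rank1_lt = c(28.19, 42.59, 55.57, 66.12))
}
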