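#' Nitrogen fertilization regime design
#'
#' The six-regime design of the emulated field trial: a common basal dressing
#' plus two top dressings whose sum spans 40 %--160 % of the recommended rate
#' (91 kg N/ha, regime N3). Totals are computed as `basal + top1 + top2`.
#'
#' @return data.frame with one row per regime: `regime`, `basal`, `top1`,
#'   `top2`, `total` (kg N/ha) and `percent` (of the recommended rate).
#' @export
#' @examples
#' regime_design()
regime_design <- function() {
  basal <- rep(36.4, 6)
  top1 <- c(54.6, 36.4, 27.3, 18.2, 9.1, 0)
  top2 <- top1
  data.frame(
    regime = paste0("N", 1:6),
    basal = basal, top1 = top1, top2 = top2,
    total = basal + top1 + top2,
    percent = c(160, 120, 100, 80, 60, 40),
    stringsAsFactors = FALSE
  )
}
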