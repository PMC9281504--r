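#' Published reference comparison tables
#'
#' Group-level summary statistics (means, SDs, test statistics and effect
#' sizes per parameter) from a published 16-participant study of manual
#' wheelchair propulsion with and without a badminton racket, paced at
#' 1.4 m/s over 20 m on a 26-inch multi-sport wheelchair. `"bilateral"` is
#' the 2x2 condition-by-hand comparison; `"unilateral"` compares the
#' dominant hand with vs without the racket. These are the summaries the
#' effect-size reproduction (`cohens_d_pooled()` applied to the printed
#' means and SDs) and the directional pattern of [racket_effects()] are
#' anchored to. P values are kept as printed (strings such as `"<0.001"`).
#'
#' @param which `"unilateral"` or `"bilateral"`.
#' @return A tibble keyed by `parameter` (`po_peak`, `mz_peak`,
#'   `ftot_peak`, `fef`, `ror`, `ai`, `pt`, `ct`, `pa`).
#' @export
reference_comparison <- function(which = c("unilateral", "bilateral")) {
  which <- match.arg(which)
  path <- system.file("extdata", paste0("reference_", which, ".csv"),
                      package = "pushrim", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(
                    parameter = readr::col_character(),
                    .default = readr::col_guess()
                  ))
}
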