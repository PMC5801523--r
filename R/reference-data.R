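#' Synthetic normative reference shipped with the package
#'
#' Loads `inst/extdata/normative_reference_synthetic.csv`: per-condition
#' location and scale of waist AP NPL computed from one paper-scale run of
#' the package's own simulator at its default configuration (seed 20,
#' failures excluded). It exists so composite scoring has a working default
#' and is SYNTHETIC: it is not a population normative table and must not be
#' interpreted clinically. Supply your own [normative_reference()] for any
#' real analysis.
#'
#' @return A [normative_reference()] (raw scale).
#' @export
synthetic_reference <- function() {
  path <- system.file("extdata", "normative_reference_synthetic.csv",
                      package = "swaybam", mustWork = TRUE)
  d <- utils::read.csv(path)
  normative_reference(d$condition, d$location, d$scale, log_scale = FALSE)
}
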