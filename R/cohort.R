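#' Reference cohort of seven focal-cortical-dysplasia patients
#'
#' Electrode counts and demographics for the seven-patient FCD cohort
#' (four adults, three children; 36-76 implanted electrodes each) whose
#' imbalance regime the synthetic generator emulates. The NSOZ:SOZ electrode
#' ratio ranges from 3.75 to 19, which is why the imbalance-aware classifiers
#' and losses exist at all.
#'
#' @return Tibble with columns `patient`, `age`, `sex`, `group`
#'   (`"adult"`/`"child"`), `n_soz`, `n_nsoz`.
#' @examples
#' dplyr::mutate(fcd_cohort(), ratio = n_nsoz / n_soz,
#'               total = n_soz + n_nsoz)
#' @export
fcd_cohort <- function() {
  tibble::tibble(
    patient = paste0("Pt", 1:7),
    age = c(15, 32, 25, 39, 6, 5, 5),
    sex = c("M", "M", "M", "F", "M", "F", "M"),
    group = c(rep("adult", 4), rep("child", 3)),
    n_soz = c(7, 10, 16, 10, 3, 3, 6),
    n_nsoz = c(63, 56, 60, 40, 33, 57, 36)
  )
}
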