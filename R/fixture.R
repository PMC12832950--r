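#' Eleven first-line mCRPC randomized trials reporting rPFS and OS
#'
#' Summary treatment effects (hazard ratio and 95% CI, intervention vs
#' comparator) for radiographic progression-free survival (surrogate) and
#' overall survival (true endpoint) from eleven phase 3 randomized trials of
#' first-line treatments for asymptomatic or mildly symptomatic, ARPi-naive
#' metastatic castration-resistant prostate cancer. Sample sizes are the sums
#' of the randomized arm sizes of the analyzed comparison. KEYNOTE-641
#' contributes its no-prior-abiraterone subgroup (n = 245 + 242) to match the
#' first-line population of the other trials. PEACEIII is flagged as
#' violating the proportional-hazards assumption for OS and is therefore
#' dropped from the `primary` analysis set.
#'
#' @return a validated [trial_table()] with 11 rows (95% intervals).
#' @seealso [build_analysis_set()] for the primary / sensitivity subsets.
#' @export
#' @examples
#' tab <- mcrpc_trials()
#' nrow(tab)
#' sum(build_analysis_set(tab, "primary")$records$n_patients)
mcrpc_trials <- function() {
  trial_table(
    trial_id = c("ACIS", "Alliance A031201", "COU-AA-302", "PEACEIII",
                 "ERA 223", "IPATential150", "KEYNOTE-641", "NCT02294461",
                 "PREVAIL", "PROpel", "TALAPRO-2"),
    n_patients = c(982L, 1311L, 1088L, 446L, 806L, 1101L, 487L, 388L,
                   1717L, 796L, 805L),
    hr_surrogate  = c(0.70, 0.86, 0.52, 0.69, 1.152, 0.84, 1.14, 0.31, 0.32, 0.68, 0.667),
    lcl_surrogate = c(0.60, 0.76, 0.45, 0.54, 0.960, 0.71, 0.89, 0.20, 0.28, 0.57, 0.551),
    ucl_surrogate = c(0.83, 0.97, 0.61, 0.87, 1.383, 0.99, 1.44, 0.46, 0.37, 0.81, 0.807),
    hr_true  = c(0.95, 0.89, 0.81, 0.69, 1.195, 0.90, 1.02, 0.33, 0.73, 0.81, 0.796),
    lcl_true = c(0.81, 0.78, 0.70, 0.52, 0.950, 0.76, 0.80, 0.16, 0.63, 0.67, 0.661),
    ucl_true = c(1.11, 1.01, 0.93, 0.90, 1.505, 1.07, 1.31, 0.67, 0.85, 1.00, 0.958),
    ph_ok_surrogate = rep(TRUE, 11L),
    ph_ok_true = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE),
    notes = c("apalutamide + abiraterone vs abiraterone",
              "enzalutamide vs enzalutamide + abiraterone",
              "abiraterone vs placebo",
              "radium-223 + enzalutamide vs enzalutamide; OS PH violated",
              "radium-223 + abiraterone vs abiraterone",
              "ipatasertib + abiraterone vs abiraterone",
              "pembrolizumab + enzalutamide vs enzalutamide; no-prior-abiraterone subgroup",
              "enzalutamide vs placebo (Asian study)",
              "enzalutamide vs placebo",
              "olaparib + abiraterone vs abiraterone",
              "talazoparib + enzalutamide vs enzalutamide"),
    level = 0.95
  )
}
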