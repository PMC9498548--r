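## Packaged causal-loop diagram of the social determinants of health that
## drive CKD disparity in minority communities, with its ten labelled
## feedback loops (six reinforcing R1-R6, four balancing B1-B4).
##
## The individual arrow signs are a reconstruction: each loop narrative
## (underpaid employment -> low income -> poverty -> unemployment, poverty
## and underpaid employment -> stress, housing quality vs environmental
## toxins, public-assistance corrections, etc.) is encoded as an explicit
## signed cycle whose sign product realises the loop's published
## reinforcing/balancing label, with shared edges sign-consistent across
## loops. The "PublicAssistance" closure that distinguishes the balancing
## poverty-health loops (B2/B4) from the reinforcing one (R6) is part of
## that reconstruction.

sdoh_edges <- function() {
  E <- function(src, dst, sign, channel) signed_edge(src, dst, sign, channel)
  list(
    # economic deprivation core (R1, R2)
    E("UnderpaidEmployment", "LowIncome",            +1, "disparity"),
    E("LowIncome",           "Poverty",              +1, "disparity"),
    E("Poverty",             "Unemployment",         +1, "disparity"),
    E("Unemployment",        "UnderpaidEmployment",  +1, "disparity"),
    E("SubstandardEducation", "UnderpaidEmployment", +1, "disparity"),
    E("Poverty",             "SubstandardEducation", +1, "disparity"),
    # stress and health (R3)
    E("UnderpaidEmployment", "Stress",               +1, "disparity"),
    E("Poverty",             "Stress",               +1, "disparity"),
    E("Stress",              "PoorHealth",           +1, "general"),
    E("PoorHealth",          "Unemployment",         +1, "general"),
    # morbidity/mortality (R4, R5)
    E("PoorHealth",          "Morbidity",            +1, "general"),
    E("Morbidity",           "Mortality",            +1, "general"),
    E("PoorHealth",          "Mortality",            +1, "general"),
    E("Mortality",           "Poverty",              +1, "general"),
    E("Poverty",             "PoorHealth",           +1, "general"),
    # access to care (R6, B4)
    E("Poverty",             "LimitedAccessToCare",  +1, "disparity"),
    E("LimitedAccessToCare", "PoorHealth",           +1, "general"),
    E("PoorHealth",          "Poverty",              +1, "general"),
    # sick leave and medical care (B1)
    E("UnderpaidEmployment", "LessSickLeave",        +1, "disparity"),
    E("LessSickLeave",       "MedicalCareAccess",    -1, "disparity"),
    E("MedicalCareAccess",   "PoorHealth",           -1, "general"),
    E("PoorHealth",          "UnderpaidEmployment",  -1, "general"),
    # food access and public assistance (B2)
    E("Poverty",             "LimitedHealthyFood",   +1, "disparity"),
    E("LimitedHealthyFood",  "PoorHealth",           +1, "general"),
    E("PoorHealth",          "PublicAssistance",     +1, "general"),
    E("PublicAssistance",    "Poverty",              -1, "general"),
    # housing and environmental toxins (B3)
    E("QualityStableHousing", "EnvironmentalToxins", -1, "disparity"),
    E("EnvironmentalToxins", "PoorHealth",           +1, "general"),
    E("PublicAssistance",    "QualityStableHousing", +1, "general"),
    # non-loop disparity influences
    E("Poverty",             "SocialSupport",        -1, "disparity"),
    E("Unemployment",        "InsuranceCoverage",    -1, "disparity"),
    E("Poverty",             "Transportation",       -1, "disparity")
  )
}

#' Social-determinants-of-health causal loop diagram
#'
#' The packaged signed diagram of social determinants (poverty, underpaid
#' employment, low income, education, stress, food and housing access,
#' environmental toxins, access to care, public assistance, morbidity and
#' mortality) influencing CKD incidence and progression in minority
#' communities. Edge channels mark disparity-driven arrows versus general
#' social influences. Individual arrow signs are a documented
#' reconstruction encoding each loop narrative so that the ten labelled
#' loops ([sdoh_loop_labels()]) carry their published polarity.
#'
#' @return A [causal_diagram()].
#' @seealso [sdoh_loop_labels()], [classify_labeled_loops()]
#' @export
#' @examples
#' d <- sdoh_diagram()
#' classify_labeled_loops(d, sdoh_loop_labels())$counts
sdoh_diagram <- function() {
  causal_diagram(sdoh_edges())
}

#' Labelled feedback loops of the social-determinants diagram
#'
#' The ten named cycles of [sdoh_diagram()]: reinforcing loops R1-R6
#' (economic deprivation, education, stress, morbidity/mortality, access
#' to care) and balancing loops B1-B4 (sick leave and medical care, food
#' access, housing/toxins, public assistance).
#'
#' @return Named list mapping label to the ordered node sequence of its
#'   cycle (first node not repeated at the end).
#' @export
sdoh_loop_labels <- function() {
  list(
    R1 = c("UnderpaidEmployment", "LowIncome", "Poverty", "Unemployment"),
    R2 = c("SubstandardEducation", "UnderpaidEmployment", "LowIncome", "Poverty"),
    R3 = c("UnderpaidEmployment", "Stress", "PoorHealth", "Unemployment"),
    R4 = c("PoorHealth", "Morbidity", "Mortality", "Poverty"),
    R5 = c("PoorHealth", "Mortality", "Poverty"),
    R6 = c("Poverty", "LimitedAccessToCare", "PoorHealth"),
    B1 = c("UnderpaidEmployment", "LessSickLeave", "MedicalCareAccess", "PoorHealth"),
    B2 = c("Poverty", "LimitedHealthyFood", "PoorHealth", "PublicAssistance"),
    B3 = c("QualityStableHousing", "EnvironmentalToxins", "PoorHealth", "PublicAssistance"),
    B4 = c("Poverty", "LimitedAccessToCare", "PoorHealth", "PublicAssistance")
  )
}
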