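# CHA2DS2-VASc and HAS-BLED clinical risk scores, per their canonical
# published definitions (Lip et al. 2010; Pisters et al. 2010). Both operate
# on a per-patient profile data frame and are strict about missing data:
# an NA in any component is an error, never a silent zero.

get_component <- function(profile, name, score) {
  if (!name %in% names(profile)) {
    stop(sprintf("%s: required column `%s` is missing", score, name),
         call. = FALSE)
  }
  x <- profile[[name]]
  if (anyNA(x)) {
    stop(sprintf("%s: column `%s` contains missing values", score, name),
         call. = FALSE)
  }
  x
}

get_flag <- function(profile, name, score) {
  check_binary(get_component(profile, name, score), name)
}

check_age <- function(age, validate) {
  if (!is.numeric(age)) stop("`age` must be numeric", call. = FALSE)
  if (validate && any(age < 18 | age > 120)) {
    stop("age outside [18, 120]; disable `validate` to bypass", call. = FALSE)
  }
  age
}

#' CHA2DS2-VASc stroke-risk score
#'
#' Integer score in 0..9: congestive heart failure +1, hypertension +1,
#' age >= 75 +2, diabetes +1, prior stroke/TIA +2, vascular disease +1,
#' age 65-74 +1, female sex +1.
#'
#' @param profile data frame with columns `age` (years), `sex` (`"male"` /
#'   `"female"`), and logical/0-1 columns `chf`, `hypertension`, `diabetes`,
#'   `prior_stroke_tia`, `vascular_disease`. Missing values are an error.
#' @param validate require age in \[18, 120\].
#' @return integer vector of scores, one per row of `profile`.
#' @export
#' @examples
#' cha2ds2_vasc(data.frame(
#'   age = 76, sex = "female", chf = FALSE, hypertension = TRUE,
#'   diabetes = TRUE, prior_stroke_tia = FALSE, vascular_disease = FALSE
#' )) # 2 (age) + 1 + 1 + 1 (female) = 5
cha2ds2_vasc <- function(profile, validate = TRUE) {
  age <- check_age(get_component(profile, "age", "CHA2DS2-VASc"), validate)
  sex <- get_component(profile, "sex", "CHA2DS2-VASc")
  if (!all(sex %in% c("male", "female"))) {
    stop("`sex` must be \"male\" or \"female\"", call. = FALSE)
  }
  score <- get_flag(profile, "chf", "CHA2DS2-VASc") +
    get_flag(profile, "hypertension", "CHA2DS2-VASc") +
    2L * (age >= 75) +
    get_flag(profile, "diabetes", "CHA2DS2-VASc") +
    2L * get_flag(profile, "prior_stroke_tia", "CHA2DS2-VASc") +
    get_flag(profile, "vascular_disease", "CHA2DS2-VASc") +
    (age >= 65 & age < 75) +
    (sex == "female")
  as.integer(score)
}

#' HAS-BLED bleeding-risk score
#'
#' Integer score in 0..9: hypertension +1, abnormal renal function +1,
#' abnormal liver function +1, stroke history +1, bleeding history or
#' predisposition +1, labile INR +1, age > 65 +1, antiplatelet/NSAID use +1,
#' alcohol excess +1.
#'
#' @param profile data frame with `age` plus logical/0-1 columns
#'   `hypertension`, `renal_disease`, `liver_disease`, `bleeding_history`,
#'   `labile_inr`, `alcohol_use`, `nsaid_or_antiplatelet` and (unless
#'   `stroke` is supplied) `prior_stroke_tia`.
#' @param stroke optional logical vector overriding the stroke-history
#'   component, e.g. to count an index stroke that postdates the
#'   thromboembolism-free window used for CHA2DS2-VASc.
#' @param validate require age in \[18, 120\].
#' @return integer vector of scores.
#' @export
has_bled <- function(profile, stroke = NULL, validate = TRUE) {
  age <- check_age(get_component(profile, "age", "HAS-BLED"), validate)
  if (is.null(stroke)) {
    stroke <- get_flag(profile, "prior_stroke_tia", "HAS-BLED")
  } else {
    stroke <- check_binary(stroke, "stroke")
    if (length(stroke) != nrow(profile)) {
      stop("`stroke` must have one value per profile row", call. = FALSE)
    }
  }
  score <- get_flag(profile, "hypertension", "HAS-BLED") +
    get_flag(profile, "renal_disease", "HAS-BLED") +
    get_flag(profile, "liver_disease", "HAS-BLED") +
    stroke +
    get_flag(profile, "bleeding_history", "HAS-BLED") +
    get_flag(profile, "labile_inr", "HAS-BLED") +
    (age > 65) +
    get_flag(profile, "nsaid_or_antiplatelet", "HAS-BLED") +
    get_flag(profile, "alcohol_use", "HAS-BLED")
  as.integer(score)
}
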