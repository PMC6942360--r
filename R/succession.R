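# Age-dependent succession modifiers of extinction and colonization.
#
# Habitat preference along the successional gradient is encoded as a pair
# of functions of patch age (time steps since patch creation):
#
#   early: suitability is highest in freshly disturbed patches and decays
#          as succession proceeds — extinction rises along a positive
#          sigmoid (rate 0.09), colonization falls along its complement.
#   late:  the mirror image — extinction falls, colonization rises.
#   mid:   suitability peaks at age 50 — extinction is U-shaped
#          (exp(-0.08*age) below 50, exp(0.08*(age-100)) at or above 50,
#          so the two branches meet at exp(-4) and the curve is symmetric
#          about 50), colonization is the unimodal complement
#          (1 - exp(...)), maximal at age 50.
#
# All outputs are clamped to [0,1]; for mid-successional species this
# saturates extinction at 1 (and colonization at 0) once age exceeds 100.

succession_check <- function(preference, age) {
  if (!is.character(preference) || length(preference) != 1L ||
      !preference %in% c("early", "mid", "late")) {
    stop("preference must be one of \"early\", \"mid\", \"late\"",
         call. = FALSE)
  }
  if (any(age < 0)) stop("age must be non-negative", call. = FALSE)
}

#' Successional extinction modifier E_it
#'
#' Probability multiplier capturing how patch age (successional stage)
#' raises local extinction risk for a species of the given preference.
#' Vectorised over `age`.
#'
#' @param preference `"early"`, `"mid"` or `"late"`.
#' @param age patch age(s) in time steps, non-negative.
#' @return extinction probability/ies in `[0, 1]`.
#' @examples
#' extinction_modifier("early", 0)   # 0.5
#' extinction_modifier("mid", 50)    # exp(-4), the suitability optimum
#' @export
extinction_modifier <- function(preference, age) {
  succession_check(preference, age)
  out <- switch(preference,
    early = 1 / (1 + exp(-0.09 * age)),
    late = 1 / (1 + exp(0.09 * age)),
    mid = ifelse(age < 50, exp(-0.08 * age), exp(0.08 * (age - 100)))
  )
  clamp01(out)
}

#' Successional colonization modifier C_it
#'
#' Probability multiplier capturing how patch age affects the chance that
#' a colonization attempt finds suitable habitat. Vectorised over `age`.
#' For every preference and age, `colonization_modifier("early", a) +
#' colonization_modifier("late", a) == 1`: the two sigmoids are
#' complementary.
#'
#' @inheritParams extinction_modifier
#' @return colonization probability/ies in `[0, 1]`.
#' @examples
#' colonization_modifier("mid", 0)   # 0: a fresh patch is unsuitable
#' colonization_modifier("mid", 50)  # 1 - exp(-4), the optimum
#' @export
colonization_modifier <- function(preference, age) {
  succession_check(preference, age)
  out <- switch(preference,
    early = 1 / (1 + exp(0.09 * age)),
    late = 1 / (1 + exp(-0.09 * age)),
    mid = ifelse(age < 50, 1 - exp(-0.08 * age), 1 - exp(0.08 * (age - 100)))
  )
  clamp01(out)
}
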