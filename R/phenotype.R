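#' Excess BMI loss (EBMIL)
#'
#' Percentage of the BMI excess above 25 kg/m\eqn{^2} that was lost between
#' baseline and follow-up:
#' \deqn{EBMIL = 100 - \frac{final - 25}{initial - 25} \times 100.}
#' Values above 100 (final BMI below 25) and negative values (weight gain)
#' are passed through unclamped: downstream models treat EBMIL as a
#' continuous regression target.
#'
#' @param initial_bmi Baseline BMI in kg/m\eqn{^2}; must exceed 25 for the
#'   excess to be defined.
#' @param final_bmi Follow-up BMI in kg/m\eqn{^2}.
#' @return EBMIL in percent, vectorised over the inputs.
#' @examples
#' compute_ebmil(45.1, 28.5)  # 82.59
#' compute_ebmil(40, 40)      # 0: no change
#' @export
compute_ebmil <- function(initial_bmi, final_bmi) {
  stopifnot(is.numeric(initial_bmi), is.numeric(final_bmi))
  if (any(!is.finite(initial_bmi)) || any(!is.finite(final_bmi)))
    stop("BMI values must be finite")
  if (any(initial_bmi <= 25))
    stop("initial_bmi must exceed 25 kg/m^2 for excess BMI to be defined")
  100 - (final_bmi - 25) / (initial_bmi - 25) * 100
}

#' Inverse of the EBMIL transform
#'
#' Recovers the follow-up BMI from an EBMIL value and the baseline BMI.
#' Used by the cohort simulator so that both the EBMIL and percent-BMI-loss
#' outcomes are derived from one generated truth.
#'
#' @inheritParams compute_ebmil
#' @param ebmil EBMIL in percent.
#' @return Final BMI in kg/m\eqn{^2}.
#' @export
invert_ebmil <- function(initial_bmi, ebmil) {
  if (any(initial_bmi <= 25)) stop("initial_bmi must exceed 25 kg/m^2")
  25 + (1 - ebmil / 100) * (initial_bmi - 25)
}

#' Percent BMI loss
#'
#' Relative BMI reduction from baseline, \code{100 * (initial - final) /
#' initial}.  Used as the confirmatory outcome alongside EBMIL.
#'
#' @inheritParams compute_ebmil
#' @return Percent BMI loss, vectorised.
#' @export
compute_pct_bmi_loss <- function(initial_bmi, final_bmi) {
  stopifnot(is.numeric(initial_bmi), is.numeric(final_bmi))
  if (any(!is.finite(initial_bmi)) || any(!is.finite(final_bmi)))
    stop("BMI values must be finite")
  if (any(initial_bmi <= 0)) stop("initial_bmi must be positive")
  100 * (initial_bmi - final_bmi) / initial_bmi
}

.sex_levels     <- c("female", "male")
.surgery_levels <- c("proximal", "distal")

#' Derive outcome variables for a cohort
#'
#' Validates a raw phenotype table and appends the two derived outcomes,
#' EBMIL and percent BMI loss.  Row order is preserved.
#'
#' @param phenotypes A data frame with columns \code{sample_id}, \code{age},
#'   \code{sex} (\code{"female"}/\code{"male"}), \code{initial_bmi},
#'   \code{final_bmi} and \code{surgery_type}
#'   (\code{"proximal"}/\code{"distal"}).
#' @return The cohort data frame with \code{ebmil} and \code{pct_bmi_loss}
#'   columns appended; \code{sex} and \code{surgery_type} coerced to
#'   factors with fixed level order (female/proximal first).
#' @export
derive_outcomes <- function(phenotypes) {
  required <- c("sample_id", "age", "sex", "initial_bmi", "final_bmi",
                "surgery_type")
  missing_cols <- setdiff(required, names(phenotypes))
  if (length(missing_cols))
    stop("phenotype table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  ph <- as.data.frame(phenotypes, stringsAsFactors = FALSE)
  if (nrow(ph) == 0L) {
    ph$ebmil <- numeric(0)
    ph$pct_bmi_loss <- numeric(0)
    return(ph)
  }
  if (anyDuplicated(ph$sample_id)) stop("duplicate sample_id in phenotypes")
  bad_sex <- setdiff(unique(as.character(ph$sex)), .sex_levels)
  if (length(bad_sex))
    stop("unknown sex label(s): ", paste(bad_sex, collapse = ", "))
  bad_surg <- setdiff(unique(as.character(ph$surgery_type)), .surgery_levels)
  if (length(bad_surg))
    stop("unknown surgery_type label(s): ", paste(bad_surg, collapse = ", "),
         " (only proximal/distal Roux-en Y procedures are supported)")
  if (anyNA(ph$initial_bmi) || anyNA(ph$final_bmi))
    stop("missing BMI values")
  if (any(ph$age <= 0) || any(ph$initial_bmi <= 0) || any(ph$final_bmi <= 0))
    stop("ages and BMIs must be positive")
  ph$sex <- factor(as.character(ph$sex), levels = .sex_levels)
  ph$surgery_type <- factor(as.character(ph$surgery_type),
                            levels = .surgery_levels)
  ph$ebmil <- compute_ebmil(ph$initial_bmi, ph$final_bmi)
  ph$pct_bmi_loss <- compute_pct_bmi_loss(ph$initial_bmi, ph$final_bmi)
  ph
}
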