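#' Radiation response of non-growing follicles
#'
#' Bundles the radiosensitivity parameter (LD50, the dose destroying half the
#' NGF population) with the treatment modality. The default LD50 of 2 Gy is
#' the conservative literature estimate for the human ovary; the true value
#' may be lower, so it is user-overridable.
#'
#' @param ld50_gy Median lethal dose for NGFs in Gy; must be positive.
#' @param modality `"photon"` (doses in Gy) or `"proton"` (doses in Cobalt
#'   Gray Equivalent, CGE, i.e. physical dose with a constant RBE of 1.1
#'   already applied; treated numerically equal to Gy).
#' @return An object of class `"radiation_response"`.
#' @examples
#' radiation_response()
#' radiation_response(ld50_gy = 1.5, modality = "proton")
#' @export
radiation_response <- function(ld50_gy = 2.0,
                               modality = c("photon", "proton")) {
  modality <- match.arg(modality)
  if (!is.numeric(ld50_gy) || length(ld50_gy) != 1L || !is.finite(ld50_gy) ||
      ld50_gy <= 0)
    stop("'ld50_gy' must be a single positive dose in Gy", call. = FALSE)
  structure(list(ld50_gy = ld50_gy, modality = modality),
            class = "radiation_response")
}

#' Surviving fraction of NGFs after a radiation dose
#'
#' Single-hit exponential kill: `S(d) = 2^(-d / LD50)`, the unique memoryless
#' dose-response consistent with an LD50 (half the population survives each
#' LD50 of dose, so survival is multiplicative over split doses).
#' Fractionation and dose-rate effects are deliberately ignored; `dose` is the
#' total physical dose to the ovary.
#'
#' @param dose Dose in Gy (or CGE), non-negative. Vectorised.
#' @param ld50_gy Median lethal dose in Gy (default 2).
#' @return Fraction of NGFs surviving, in (0, 1].
#' @examples
#' surviving_fraction(0)   # 1
#' surviving_fraction(2)   # 0.5
#' surviving_fraction(12)  # 2^-6
#' @export
surviving_fraction <- function(dose, ld50_gy = 2.0) {
  if (!is.numeric(dose) || any(!is.finite(dose)))
    stop("'dose' must be finite numeric Gy", call. = FALSE)
  if (any(dose < 0))
    stop("'dose' must be non-negative", call. = FALSE)
  if (!is.numeric(ld50_gy) || length(ld50_gy) != 1L || ld50_gy <= 0)
    stop("'ld50_gy' must be a single positive dose in Gy", call. = FALSE)
  2^(-dose / ld50_gy)
}

#' Dose value with its modality unit label
#'
#' Numeric passthrough for both modalities: a proton dose expressed in CGE
#' already embeds the constant RBE of 1.1, so it is numerically equivalent to
#' Gy for the survival model. The unit label is kept for reporting.
#'
#' @param value Dose in Gy (photon) or CGE (proton); non-negative. Vectorised.
#' @param modality `"photon"` or `"proton"`.
#' @return `value`, with attribute `unit` set to `"Gy"` or `"CGE"`.
#' @examples
#' effective_dose(3, "photon")
#' attr(effective_dose(3, "proton"), "unit")  # "CGE"
#' @export
effective_dose <- function(value, modality = c("photon", "proton")) {
  modality <- match.arg(modality)
  if (!is.numeric(value) || any(!is.finite(value)) || any(value < 0))
    stop("dose 'value' must be finite, non-negative numeric", call. = FALSE)
  structure(value, unit = if (modality == "photon") "Gy" else "CGE")
}

#' @export
print.radiation_response <- function(x, ...) {
  cat(sprintf("NGF radiation response: LD50 = %g Gy, %s therapy (%s)\n",
              x$ld50_gy, x$modality,
              if (x$modality == "photon") "Gy" else "CGE"))
  invisible(x)
}
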