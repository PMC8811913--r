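#' Construct a spectral measurement record
#'
#' @param a473,a630,a663,a750 Absorbances of the acetone extract at 473,
#'   630, 663 and 750 nm (750 nm is the turbidity baseline).
#' @param v Pigment extraction volume (mL).
#' @param V Sampled culture volume (mL).
#' @param l Optical path length (cm).
#' @return data.frame of class `"spectral_measurement"` (vectorized over
#'   absorbances; `v`, `V`, `l` are recycled).
#' @export
spectral_measurement <- function(a473, a630, a663, a750, v = 1, V = 1, l = 1) {
  for (a in list(a473, a630, a663, a750)) {
    if (!is.numeric(a) || !all(is.finite(a))) {
      stop_input("absorbances must be finite numerics")
    }
  }
  check_number(v, "v", 0, strict_lower = TRUE)
  check_number(V, "V", 0, strict_lower = TRUE)
  check_number(l, "l", 0, strict_lower = TRUE)
  out <- data.frame(a473 = a473, a630 = a630, a663 = a663, a750 = a750,
                    v = v, V = V, l = l)
  class(out) <- c("spectral_measurement", class(out))
  out
}

# Trichromatic coefficients for chlorophyll a, chlorophyll c and total
# carotenoids in acetone extracts. The published chlorophyll-a equation
# repeats the (A663 - A750) difference in its second term, almost certainly
# a misprint for (A630 - A750); both readings are computed and `variant`
# selects which is reported. The carotenoid equation names a "Chl b" term
# although the organism has chlorophyll c, not b; the chlorophyll-c value
# is substituted there and the substitution is flagged in the output.
PIG_CHLA_1 <- 11.77
PIG_CHLA_2 <- 0.32
PIG_CHLC_1 <- 26.27
PIG_CHLC_2 <- 3.52
PIG_CAR_A473 <- 1000
PIG_CAR_CHLA <- 8.08
PIG_CAR_CHLB <- 1
PIG_CAR_DENOM <- 183.4

#' Quantify chlorophylls and carotenoids from extract absorbances
#'
#' Applies the trichromatic equations for chlorophyll a, chlorophyll c and
#' total carotenoids to baseline-corrected absorbance differences, scaled
#' by `v / (l * V)` to convert in-extract to in-culture concentrations
#' (mg/L). Two chlorophyll-a variants are always computed: `"as_printed"`
#' uses `(11.77 - 0.32) * (A663 - A750)` exactly as published,
#' `"corrected"` uses `11.77 * (A663 - A750) - 0.32 * (A630 - A750)`;
#' `variant` selects which one is reported (and fed into the carotenoid
#' equation). Negative concentrations (possible with noisy baselines) are
#' preserved in the `*_raw` columns and clipped to zero in the reported
#' columns, with a warning.
#'
#' @param m A [spectral_measurement()] (or data.frame with its columns).
#' @param variant `"as_printed"` (default) or `"corrected"`.
#' @return data.frame with columns `chl_a`, `chl_c`, `carotenoids` (mg/L,
#'   clipped at 0), their `*_raw` counterparts, and `variant`. Attribute
#'   `"chl_b_note"` records the chlorophyll-c substitution in the
#'   carotenoid term.
#' @export
#' @examples
#' m <- spectral_measurement(a473 = 0.5, a630 = 0.12, a663 = 0.4, a750 = 0.02)
#' quantify_pigments(m)
quantify_pigments <- function(m, variant = c("as_printed", "corrected")) {
  variant <- match.arg(variant)
  need <- c("a473", "a630", "a663", "a750", "v", "V", "l")
  if (!all(need %in% names(m))) {
    stop_input("`m` must have columns ", paste(need, collapse = ", "))
  }
  check_number(m$v, "v", 0, strict_lower = TRUE)
  check_number(m$V, "V", 0, strict_lower = TRUE)
  check_number(m$l, "l", 0, strict_lower = TRUE)
  k <- m$v / (m$l * m$V)
  da <- m$a663 - m$a750
  dc <- m$a630 - m$a750
  d4 <- m$a473 - m$a750

  chla_printed <- (PIG_CHLA_1 - PIG_CHLA_2) * da * k
  chla_corrected <- (PIG_CHLA_1 * da - PIG_CHLA_2 * dc) * k
  chla <- if (variant == "as_printed") chla_printed else chla_corrected
  chlc <- (PIG_CHLC_1 * dc - PIG_CHLC_2 * da) * k
  car <- (PIG_CAR_A473 * d4 - PIG_CAR_CHLA * chla * m$l -
            PIG_CAR_CHLB * chlc * m$l) * k / PIG_CAR_DENOM

  if (any(c(chla, chlc, car) < 0)) {
    warning("negative pigment concentration(s) clipped to 0; ",
            "raw values kept in *_raw columns", call. = FALSE)
  }
  out <- data.frame(chl_a = pmax(chla, 0), chl_c = pmax(chlc, 0),
                    carotenoids = pmax(car, 0),
                    chl_a_raw = chla, chl_c_raw = chlc, carotenoids_raw = car,
                    variant = variant)
  attr(out, "chl_b_note") <-
    "carotenoid equation's Chl b term evaluated with the Chl c value"
  out
}

#' Invert the pigment equations into an absorbance spectrum
#'
#' Constructs the four absorbances that make [quantify_pigments()] return
#' the requested concentrations exactly, for either equation variant.
#' Used by the synthetic generator to produce spectra with known ground
#' truth.
#'
#' @param chl_a,chl_c,carotenoids Target concentrations (mg/L, >= 0);
#'   vectors of a common length.
#' @param v,V,l Extraction volume (mL), sample volume (mL), path (cm).
#' @param baseline_a750 Turbidity baseline added to all four absorbances.
#' @param variant Which chlorophyll-a equation the spectrum should satisfy.
#' @return A [spectral_measurement()].
#' @export
#' @examples
#' m <- generate_spectrum(1, 0.2, 5)
#' quantify_pigments(m)[, 1:3]
generate_spectrum <- function(chl_a, chl_c, carotenoids, v = 1, V = 1, l = 1,
                              baseline_a750 = 0,
                              variant = c("as_printed", "corrected")) {
  variant <- match.arg(variant)
  check_number(chl_a, "chl_a", 0)
  check_number(chl_c, "chl_c", 0)
  check_number(carotenoids, "carotenoids", 0)
  check_number(v, "v", 0, strict_lower = TRUE)
  check_number(V, "V", 0, strict_lower = TRUE)
  check_number(l, "l", 0, strict_lower = TRUE)
  check_number(baseline_a750, "baseline_a750")
  k <- v / (l * V)

  if (variant == "as_printed") {
    da <- chl_a / ((PIG_CHLA_1 - PIG_CHLA_2) * k)
    dc <- (chl_c / k + PIG_CHLC_2 * da) / PIG_CHLC_1
  } else {
    # joint 2x2 solve of the corrected chl a equation with the chl c one
    det <- PIG_CHLA_1 * PIG_CHLC_1 - PIG_CHLA_2 * PIG_CHLC_2
    da <- (PIG_CHLC_1 * chl_a + PIG_CHLA_2 * chl_c) / (k * det)
    dc <- (PIG_CHLA_1 * chl_c + PIG_CHLC_2 * chl_a) / (k * det)
  }
  d4 <- (carotenoids * PIG_CAR_DENOM / k +
           PIG_CAR_CHLA * chl_a * l + PIG_CAR_CHLB * chl_c * l) / PIG_CAR_A473

  a750 <- rep_len(baseline_a750, length(da))
  a663 <- a750 + da
  a630 <- a750 + dc
  a473 <- a750 + d4
  if (any(c(a473, a630, a663, a750) < 0)) {
    stop_input("target concentrations admit no non-negative absorbances ",
               "at this baseline")
  }
  spectral_measurement(a473 = a473, a630 = a630, a663 = a663, a750 = a750,
                       v = v, V = V, l = l)
}

#' Convert a culture concentration to a per-cell quota
#'
#' mg/L equals micrograms/mL, so dividing by the cell density (cells/mL)
#' and scaling by 1e6 yields micrograms per 1e6 cells.
#'
#' @param concentration Concentration in mg per litre of culture.
#' @param cell_density Cell density in cells/mL (> 0).
#' @return Quota in micrograms per 1e6 cells.
#' @export
#' @examples
#' per_cell_quota(1, 1e6)  # 1 microgram per 1e6 cells
per_cell_quota <- function(concentration, cell_density) {
  check_number(cell_density, "cell_density", 0, strict_lower = TRUE)
  if (!is.numeric(concentration)) stop_input("`concentration` must be numeric")
  concentration / cell_density * 1e6
}
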