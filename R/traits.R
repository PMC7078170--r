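#' Upper-tail probability of the chi-square distribution
#'
#' For one degree of freedom the survival function has the closed form
#' `p = erfc(sqrt(x / 2))`, evaluated here through the normal tail
#' (`erfc(z) = 2 * pnorm(z * sqrt(2), lower.tail = FALSE)`); for general
#' degrees of freedom it is the regularized upper incomplete gamma function
#' `Q(df / 2, x / 2)`.
#'
#' @param x Non-negative statistic value(s).
#' @param df Degrees of freedom (default 1).
#' @return Upper-tail probability in `(0, 1]`.
#' @export
chi2_sf <- function(x, df = 1) {
  if (any(!is.finite(x)) || any(x < 0)) stop("`x` must be non-negative")
  if (df <= 0) stop("`df` must be > 0")
  if (df == 1) {
    2 * stats::pnorm(sqrt(x), lower.tail = FALSE)  # erfc(sqrt(x/2))
  } else {
    stats::pgamma(x / 2, df / 2, lower.tail = FALSE)
  }
}

#' Chi-square goodness-of-fit test of a segregation ratio
#'
#' Tests observed dominant : recessive counts against an expected Mendelian
#' ratio (default 3:1). With `yates = TRUE` (default) the continuity
#' correction subtracts 0.5 from each `|O - E|` (not below zero) before
#' squaring, the usual practice for a 1-df goodness-of-fit test on a
#' moderate sample.
#'
#' @param n_dominant,n_recessive Observed class counts (>= 0, total > 0).
#' @param ratio Expected ratio as a length-2 positive vector, default `c(3, 1)`.
#' @param yates Apply the Yates continuity correction.
#' @return Object of class `seg_test`: list with `statistic`, `parameter`
#'   (df = 1), `p.value`, `observed`, `expected`, `ratio`, `yates`.
#' @examples
#' chisq_ratio_test(818, 288)            # statistic 0.583, p 0.445
#' chisq_ratio_test(818, 288, yates = FALSE)
#' @export
chisq_ratio_test <- function(n_dominant, n_recessive, ratio = c(3, 1),
                             yates = TRUE) {
  obs <- c(dominant = n_dominant, recessive = n_recessive)
  if (any(obs < 0)) stop("counts must be >= 0")
  total <- sum(obs)
  if (total <= 0) stop("total count must be > 0")
  if (length(ratio) != 2L || any(ratio <= 0)) {
    stop("`ratio` must be two positive components")
  }
  expected <- total * ratio / sum(ratio)
  if (any(expected < 5)) {
    warning("an expected class count is below 5; the chi-square approximation is weak")
  }
  dev <- abs(obs - expected)
  if (yates) dev <- pmax(dev - 0.5, 0)
  stat <- sum(dev^2 / expected)
  structure(list(statistic = stat, parameter = 1L, p.value = chi2_sf(stat, 1),
                 observed = obs, expected = expected, ratio = ratio,
                 yates = yates),
            class = "seg_test")
}

#' @export
print.seg_test <- function(x, ...) {
  cat(sprintf("Segregation chi-square test against %g:%g%s\n",
              x$ratio[1], x$ratio[2],
              if (x$yates) " (Yates-corrected)" else ""))
  cat(sprintf("  observed: %d dominant : %d recessive (expected %.1f : %.1f)\n",
              x$observed[1], x$observed[2], x$expected[1], x$expected[2]))
  cat(sprintf("  X-squared = %.3f, df = 1, p = %.3f\n", x$statistic, x$p.value))
  invisible(x)
}

#' Chlorophyll and carotenoid concentrations from absorbances
#'
#' Converts spectrophotometric absorbances at 663.2, 646.8 and 470 nm into
#' pigment concentrations with the Lichtenthaler equations for 100% acetone
#' (the coefficient set matching these wavelengths):
#' \deqn{chl_a = 12.25 A_{663.2} - 2.79 A_{646.8}}
#' \deqn{chl_b = 21.50 A_{646.8} - 5.10 A_{663.2}}
#' \deqn{car = (1000 A_{470} - 1.82\, chl_a - 85.02\, chl_b) / 198}
#' in ug/mL of extract, then scales to ug per g fresh weight by
#' `volume_ml / mass_g`. Small negative results (measurement noise near zero)
#' are floored at 0 with a warning.
#'
#' @param A663_2,A646_8,A470 Absorbances (>= 0); vectorized.
#' @param mass_g Fresh sample mass in g (> 0).
#' @param volume_ml Extract volume in mL (> 0).
#' @param coef Named list of equation coefficients, overridable for other
#'   solvent systems.
#' @return `data.frame` with columns `chl_a`, `chl_b`, `carotenoids` in
#'   ug per g fresh weight.
#' @examples
#' pigment_concentrations(1.0, 0.4, 0.5) # 11.134, 3.50, 0.920
#' @export
pigment_concentrations <- function(A663_2, A646_8, A470, mass_g = 1,
                                   volume_ml = 1,
                                   coef = lichtenthaler_coefficients()) {
  if (any(c(A663_2, A646_8, A470) < 0)) stop("absorbances must be >= 0")
  if (any(mass_g <= 0) || any(volume_ml <= 0)) {
    stop("mass and volume must be > 0")
  }
  chl_a <- coef$chl_a[1] * A663_2 + coef$chl_a[2] * A646_8
  chl_b <- coef$chl_b[1] * A646_8 + coef$chl_b[2] * A663_2
  car <- (coef$car[1] * A470 + coef$car[2] * chl_a + coef$car[3] * chl_b) /
    coef$car[4]
  out <- data.frame(chl_a = chl_a, chl_b = chl_b, carotenoids = car)
  scale <- volume_ml / mass_g
  out <- out * scale
  if (any(out < 0)) {
    warning("negative pigment concentration(s) floored at 0")
    out[out < 0] <- 0
  }
  out
}

#' Lichtenthaler coefficients for 100% acetone
#'
#' @return Named list with components `chl_a`, `chl_b` (two linear
#'   coefficients each) and `car` (A470 factor, chl a and chl b corrections,
#'   denominator).
#' @export
lichtenthaler_coefficients <- function() {
  list(chl_a = c(12.25, -2.79),
       chl_b = c(21.50, -5.10),
       car = c(1000, -1.82, -85.02, 198))
}

#' Summarize pigment replicates
#'
#' Computes concentrations per replicate and returns mean and standard
#' deviation per sample group, the usual presentation for measurements taken
#' in biological triplicate.
#'
#' @param df `data.frame` with columns `sample`, `A663_2`, `A646_8`, `A470`
#'   and optionally `mass_g`, `volume_ml` (default 1 each).
#' @return `data.frame`, one row per sample x pigment, with `mean` and `sd`.
#' @export
pigment_summary <- function(df) {
  need <- c("sample", "A663_2", "A646_8", "A470")
  if (!all(need %in% names(df))) {
    stop("input needs columns: ", paste(need, collapse = ", "))
  }
  conc <- pigment_concentrations(df$A663_2, df$A646_8, df$A470,
                                 mass_g = df$mass_g %||% 1,
                                 volume_ml = df$volume_ml %||% 1)
  long <- do.call(rbind, lapply(names(conc), function(p) {
    data.frame(sample = df$sample, pigment = p, value = conc[[p]],
               stringsAsFactors = FALSE)
  }))
  agg <- stats::aggregate(value ~ sample + pigment, data = long,
                          FUN = function(v) c(mean = mean(v), sd = stats::sd(v)))
  data.frame(sample = agg$sample, pigment = agg$pigment,
             mean = agg$value[, "mean"], sd = agg$value[, "sd"],
             stringsAsFactors = FALSE)
}
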