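#' Fraction cleaved from gel band densities
#'
#' Fraction cleavage for one lane is the summed product-band density divided
#' by the total of product and substrate band densities. Invariant to
#' rescaling all densities by a common factor (exposure, staining).
#'
#' @param product_densities Non-negative densities of the product band(s).
#' @param substrate_density Non-negative density of the uncleaved substrate
#'   band.
#' @return Fraction in \[0, 1\]; `NA` (with a warning) when every density is
#'   zero, since the lane carries no signal.
#' @examples
#' fraction_cleaved(c(30, 30), 40) # 0.6
#' @export
fraction_cleaved <- function(product_densities, substrate_density) {
  if (any(product_densities < 0) || substrate_density < 0) {
    abort("Band densities must be non-negative.")
  }
  total <- sum(product_densities) + substrate_density
  if (total == 0) {
    warn("All band densities are zero; fraction cleaved is undefined (NA).")
    return(NA_real_)
  }
  sum(product_densities) / total
}

#' Hill sigmoid concentration-response model
#'
#' \deqn{f(C) = f_{max} \frac{C^h}{C^h + EC_{1/2max}^h}}
#'
#' At `concentration == ec50` the response is exactly `f_max / 2`, making
#' the fitted `ec50` the literal half-maximal enzyme concentration
#' (EC\eqn{_{1/2max}}). Strictly increasing in concentration.
#'
#' @param concentration Cas9 concentration(s), nM (> 0; 0 allowed and maps
#'   to 0 response).
#' @param f_max Plateau fraction cleaved, in (0, 1\].
#' @param ec50 Half-maximal concentration, nM.
#' @param hill Hill exponent (default 2, the fixed value used for
#'   single-turnover cleavage fits).
#' @return Fraction(s) cleaved.
#' @export
hill_sigmoid <- function(concentration, f_max, ec50, hill = 2) {
  if (f_max <= 0 || f_max > 1 || ec50 <= 0 || hill <= 0) {
    abort("Require f_max in (0,1], ec50 > 0, hill > 0.")
  }
  if (any(concentration < 0)) abort("Concentrations must be non-negative.")
  f_max * concentration^hill / (concentration^hill + ec50^hill)
}

#' Twofold (or other) serial dilution series
#'
#' @param start Top concentration, nM (default 600 nM, the usual top of a
#'   single-turnover titration).
#' @param factor Dilution factor per step (> 1; default 2).
#' @param n_steps Number of concentrations (default 5, reaching 37.5 nM from
#'   600).
#' @return Strictly decreasing numeric vector of length `n_steps`.
#' @examples
#' serial_dilution() # 600 300 150 75 37.5
#' @export
serial_dilution <- function(start = 600, factor = 2, n_steps = 5) {
  if (start <= 0 || factor <= 1 || n_steps < 1) {
    abort("Require start > 0, factor > 1, n_steps >= 1.")
  }
  start / factor^(seq_len(n_steps) - 1)
}

#' Somatic mutagenesis rate from read counts
#'
#' Reads with mutations at the guide's cleavage site divided by the sum of
#' those reads and reads that keep the wild-type sequence.
#'
#' @param mutant_reads,wildtype_reads Non-negative read counts; their sum
#'   must be positive.
#' @return Rate in \[0, 1\].
#' @examples
#' mutagenesis_rate(80, 120) # 0.4
#' @export
mutagenesis_rate <- function(mutant_reads, wildtype_reads) {
  if (any(mutant_reads < 0) || any(wildtype_reads < 0)) {
    abort("Read counts must be non-negative.")
  }
  total <- mutant_reads + wildtype_reads
  if (any(total == 0)) abort("mutant_reads + wildtype_reads must be positive.")
  mutant_reads / total
}

# EC50 initial guess: concentration whose observed fraction is closest to
# half the observed maximum (the empirical half-max crossing)
start_ec50_candidates <- function(conc, frac) {
  half <- max(frac) / 2
  crossing <- conc[which.min(abs(frac - half))]
  unique(c(crossing, exp(mean(log(conc))), min(conc), max(conc)))
}

# fit one replicate's points; returns tibble row.  Levenberg-Marquardt can
# hit a singular Jacobian from an unlucky start (the path collapses onto
# the ec50 lower bound, where d/d ec50 vanishes), so several data-driven
# starts are tried in order and the first convergent fit is kept.
fit_one_curve <- function(conc, frac, hill, fix_hill) {
  start_fmax <- min(max(max(frac), 0.05), 1)
  df <- data.frame(conc = conc, frac = frac)
  fit <- NULL
  for (start_ec in start_ec50_candidates(conc, frac)) {
    fit <- tryCatch(
      {
        if (fix_hill) {
          h <- hill
          minpack.lm::nlsLM(
            frac ~ f_max * conc^h / (conc^h + ec50^h),
            data = df,
            start = list(f_max = start_fmax, ec50 = start_ec),
            lower = c(f_max = 1e-6, ec50 = 1e-6),
            upper = c(f_max = 1, ec50 = Inf),
            control = minpack.lm::nls.lm.control(maxiter = 200)
          )
        } else {
          minpack.lm::nlsLM(
            frac ~ f_max * conc^h / (conc^h + ec50^h),
            data = df,
            start = list(f_max = start_fmax, ec50 = start_ec, h = 1),
            lower = c(f_max = 1e-6, ec50 = 1e-6, h = 0.2),
            upper = c(f_max = 1, ec50 = Inf, h = 10),
            control = minpack.lm::nls.lm.control(maxiter = 200)
          )
        }
      },
      error = function(e) NULL
    )
    if (!is.null(fit)) break
  }
  if (is.null(fit)) {
    return(tibble(f_max = NA_real_, ec50 = NA_real_,
                  hill = if (fix_hill) hill else NA_real_,
                  converged = FALSE, rss = NA_real_))
  }
  cf <- coef(fit)
  tibble(
    f_max = unname(cf["f_max"]), ec50 = unname(cf["ec50"]),
    hill = if (fix_hill) hill else unname(cf["h"]),
    converged = TRUE, rss = sum(residuals(fit)^2)
  )
}

#' Fit EC(1/2max) from cleavage curves
#'
#' Fits the [hill_sigmoid()] model by bounded nonlinear least squares to
#' fraction-cleaved versus Cas9 concentration data, with the Hill exponent
#' held fixed (default 2) unless `fix_hill = FALSE`. By default each
#' replicate is fitted separately and the per-guide EC(1/2max) is reported
#' as the mean with its standard error of the mean across replicate fits;
#' `pooled = TRUE` instead fits all points of a guide jointly.
#'
#' A guide is censored when its aggregated EC(1/2max) exceeds
#' `censor_threshold` (default 1000 nM) or no replicate fit converges; a
#' censored estimate is reported as `"> <threshold>"` in `ec50_label`
#' because such values are too high to be measured accurately within the
#' titration range.
#'
#' @param data Tibble in long format with columns `concentration_nM` and
#'   `fraction`, plus optional `guide_id` and `replicate` columns. At least
#'   3 distinct concentrations per fitted curve are required.
#' @param hill Fixed Hill exponent (default 2).
#' @param fix_hill Keep the exponent fixed (default `TRUE`); when `FALSE`
#'   the exponent is a free parameter.
#' @param censor_threshold Censoring bound in nM (default 1000).
#' @param pooled Pool replicates into one fit per guide.
#' @return An object of class `ec50_fit`: list with `fits` (one row per
#'   guide x replicate fit), `summary` (one row per guide: `ec50`, `sem`,
#'   `f_max`, `hill`, `censored`, `ec50_label`, `n_replicates`), `data`,
#'   and the fitting settings. Use [tidy()][generics::tidy] /
#'   [glance()][generics::glance] to extract tibbles.
#' @examples
#' curve <- simulate_cleavage_curve(ec50 = 150, noise_sd = 0, seed = 1)
#' fit_ec50(curve)
#' @export
fit_ec50 <- function(data, hill = 2, fix_hill = TRUE, censor_threshold = 1000,
                     pooled = FALSE) {
  data <- as_tibble(data)
  if (!"concentration_nM" %in% names(data) && "concentration" %in% names(data)) {
    data$concentration_nM <- data$concentration
  }
  if (!all(c("concentration_nM", "fraction") %in% names(data))) {
    abort("`data` needs columns concentration_nM and fraction.")
  }
  if (!"guide_id" %in% names(data)) data$guide_id <- "guide"
  if (!"replicate" %in% names(data)) data$replicate <- 1L
  if (any(data$concentration_nM <= 0)) abort("Concentrations must be > 0.")
  if (any(data$fraction < 0 | data$fraction > 1)) {
    abort("Fractions must lie in [0, 1].")
  }

  fits <- data |>
    group_by(.data$guide_id,
             replicate = if (pooled) 1L else .data$replicate) |>
    summarise(
      n_conc = length(unique(.data$concentration_nM)),
      fit = list(
        if (length(unique(.data$concentration_nM)) < 3) {
          abort(sprintf(
            "Guide %s: need >= 3 distinct concentrations to fit, got %d.",
            .data$guide_id[1], length(unique(.data$concentration_nM))
          ))
        } else {
          fit_one_curve(.data$concentration_nM, .data$fraction, hill, fix_hill)
        }
      ),
      .groups = "drop"
    ) |>
    tidyr::unnest("fit")

  summary <- fits |>
    group_by(.data$guide_id) |>
    summarise(
      n_replicates = n(),
      # sem before ec50: summarise lets later expressions see freshly
      # created columns, which would shadow the per-replicate estimates
      sem = if (sum(.data$converged) > 1) {
        sd(.data$ec50[.data$converged]) / sqrt(sum(.data$converged))
      } else NA_real_,
      ec50 = if (any(.data$converged)) mean(.data$ec50[.data$converged]) else NA_real_,
      f_max = if (any(.data$converged)) mean(.data$f_max[.data$converged]) else NA_real_,
      hill = if (fix_hill) .env$hill else mean(.data$hill[.data$converged]),
      .groups = "drop"
    ) |>
    mutate(
      censored = is.na(.data$ec50) | .data$ec50 > censor_threshold,
      ec50_label = ifelse(.data$censored,
                          paste0("> ", format(censor_threshold)),
                          format(signif(.data$ec50, 4), trim = TRUE))
    )

  structure(
    list(fits = fits, summary = summary, data = data,
         hill = hill, fix_hill = fix_hill,
         censor_threshold = censor_threshold, pooled = pooled),
    class = "ec50_fit"
  )
}

#' @export
print.ec50_fit <- function(x, ...) {
  cat(sprintf("<ec50_fit> %d guide(s), hill %s %g, censor > %g nM%s\n",
              nrow(x$summary), if (x$fix_hill) "fixed at" else "free, mean",
              mean(x$summary$hill), x$censor_threshold,
              if (x$pooled) ", pooled replicates" else ""))
  print(x$summary)
  invisible(x)
}

#' Tidy an EC50 fit into one row per guide
#'
#' @param x An `ec50_fit` object.
#' @param ... Unused.
#' @return The per-guide summary tibble (`guide_id`, `ec50`, `sem`, `f_max`,
#'   `hill`, `censored`, `ec50_label`, `n_replicates`).
#' @method tidy ec50_fit
#' @export
tidy.ec50_fit <- function(x, ...) {
  x$summary |>
    select(all_of(c("guide_id", "ec50", "sem", "f_max", "hill",
                    "censored", "ec50_label", "n_replicates")))
}

#' One-row overview of an EC50 fit
#'
#' @param x An `ec50_fit` object.
#' @param ... Unused.
#' @return Tibble with `n_guides`, `n_censored`, `hill`, `fix_hill`,
#'   `censor_threshold`, `pooled`.
#' @method glance ec50_fit
#' @export
glance.ec50_fit <- function(x, ...) {
  tibble(
    n_guides = nrow(x$summary),
    n_censored = sum(x$summary$censored),
    hill = x$hill, fix_hill = x$fix_hill,
    censor_threshold = x$censor_threshold, pooled = x$pooled
  )
}

#' Observed data with fitted values for an EC50 fit
#'
#' @param x An `ec50_fit` object.
#' @param ... Unused.
#' @return The input data with a `.fitted` column from each guide's
#'   aggregated parameters (censored guides give `NA`).
#' @method augment ec50_fit
#' @export
augment.ec50_fit <- function(x, ...) {
  x$data |>
    left_join(x$summary |> select(all_of(c("guide_id", "ec50", "f_max", "hill", "censored"))),
              by = "guide_id") |>
    mutate(.fitted = ifelse(
      .data$censored | is.na(.data$ec50), NA_real_,
      .data$f_max * .data$concentration_nM^.data$hill /
        (.data$concentration_nM^.data$hill + .data$ec50^.data$hill)
    )) |>
    select(-all_of(c("ec50", "f_max", "hill", "censored")))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics augment
#' @export
generics::augment
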