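#' Normalize raw responses to control wells
#'
#' Viability assessment: raw values are normalized to the vehicle mean
#' (100%) and, in `"vehicle+baseline"` mode, additionally to the
#' positive-control (maximal kill) mean (0%). Cell-death assessment
#' (`direction = "death"`) swaps the anchors: vehicle becomes 0% and the
#' positive control 100%.
#'
#' @param points data frame with columns `response_raw` and `role`
#'   (`vehicle` / `positive` / `treated`); e.g. built from per-well fold
#'   changes or endpoint metrics.
#' @param mode `"vehicle"` (vehicle-only) or `"vehicle+baseline"`.
#' @param direction `"viability"` or `"death"`.
#' @return `points` with an added `response_pct` column.
#' @export
#' @examples
#' pts <- data.frame(response_raw = c(200, 40, 120),
#'                   role = c("vehicle", "positive", "treated"))
#' normalize_viability(pts, mode = "vehicle+baseline")$response_pct
normalize_viability <- function(points,
                                mode = c("vehicle", "vehicle+baseline"),
                                direction = c("viability", "death")) {
  mode <- match.arg(mode)
  direction <- match.arg(direction)
  if (!all(c("response_raw", "role") %in% names(points)))
    stop("points needs columns response_raw and role", call. = FALSE)
  veh <- points$response_raw[points$role == "vehicle"]
  if (!length(veh)) stop("no vehicle wells present", call. = FALSE)
  m_veh <- mean(veh)
  if (direction == "death" || mode == "vehicle+baseline") {
    pos <- points$response_raw[points$role == "positive"]
    if (!length(pos))
      stop("no positive-control wells present (required for ",
           if (direction == "death") "death normalization" else
             "baseline normalization", ")", call. = FALSE)
    m_pos <- mean(pos)
    if (m_veh == m_pos)
      stop("vehicle and positive-control means are equal: zero denominator",
           call. = FALSE)
  }
  points$response_pct <- if (direction == "viability") {
    if (mode == "vehicle") {
      if (m_veh == 0) stop("vehicle mean is zero", call. = FALSE)
      points$response_raw / m_veh * 100
    } else {
      (points$response_raw - m_pos) / (m_veh - m_pos) * 100
    }
  } else {
    (points$response_raw - m_veh) / (m_pos - m_veh) * 100
  }
  points
}

#' The four-parameter logistic curve
#'
#' `Y = bottom + (top - bottom) / (1 + 10^((log_ic50 - x) * hill))`,
#' evaluated at `x = log10(concentration)`.
#'
#' @param x log10 molar concentration(s).
#' @param top,bottom asymptotes (response scale).
#' @param hill slope; negative for inhibitory curves in this
#'   parameterization.
#' @param log_ic50 log10 molar half-maximal concentration.
#' @return Predicted response(s).
#' @export
pl4 <- function(x, top, bottom, hill, log_ic50) {
  bottom + (top - bottom) / (1 + 10^((log_ic50 - x) * hill))
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of the variable-slope log(inhibitor/agonist) vs.
#' normalized-response model
#' `Y = bottom + (top - bottom) / (1 + 10^((logIC50 - X) * hill))`
#' on `X = log10(concentration)`, with multi-start Levenberg-Marquardt
#' optimization (5 data-driven starts).
#'
#' @param conc molar concentrations (> 0), at least 5 distinct values.
#' @param resp normalized responses (same length).
#' @param direction `"inhibitory"` (response falls with dose, IC50) or
#'   `"stimulatory"` (response rises, EC50); sets the starting Hill sign
#'   only — the fitted slope is free.
#' @param n_starts number of starting points for log IC50.
#' @return A `dose_response_fit`: `top`, `bottom`, `hill`, `log_ic50`,
#'   `ic50` (molar), `rss`, `df`, `n_points`, `fitted`, `degenerate`.
#' @export
#' @examples
#' conc <- 10^seq(-9, -4, length.out = 8)
#' resp <- pl4(log10(conc), 100, 0, -1, -6)
#' fit <- fit_4pl(conc, resp)
#' fit$log_ic50
fit_4pl <- function(conc, resp, direction = c("inhibitory", "stimulatory"),
                    n_starts = 5) {
  direction <- match.arg(direction)
  ok <- is.finite(conc) & is.finite(resp) & conc > 0
  conc <- conc[ok]; resp <- resp[ok]
  if (length(unique(conc)) < 5)
    stop("need >= 5 distinct concentrations (df >= 1)", call. = FALSE)
  x <- log10(conc)
  n <- length(x)
  if (stats::sd(resp) < 1e-12 * max(1, abs(mean(resp)))) {
    return(structure(list(top = mean(resp), bottom = mean(resp), hill = NA,
                          log_ic50 = NA, ic50 = NA, rss = 0, df = n - 4L,
                          n_points = n, fitted = rep(mean(resp), n),
                          degenerate = TRUE),
                     class = "dose_response_fit"))
  }
  hill0 <- if (direction == "inhibitory") -1 else 1
  starts <- stats::quantile(x, probs = seq(0.1, 0.9,
                                           length.out = max(1, n_starts)))
  top0 <- max(resp); bot0 <- min(resp)
  best <- NULL
  dat <- data.frame(x = x, y = resp)
  for (s in starts) for (h0 in unique(c(hill0, -hill0))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ bottom + (top - bottom) / (1 + 10^((log_ic50 - x) * hill)),
        data = dat,
        start = list(top = top0, bottom = bot0, hill = h0, log_ic50 = s),
        control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-10,
                                             ptol = 1e-10)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss - 1e-12)
      best <- list(fit = fit, rss = rss)
  }
  if (is.null(best))
    stop("4PL fit did not converge from any start", call. = FALSE)
  cf <- stats::coef(best$fit)
  structure(list(top = unname(cf["top"]), bottom = unname(cf["bottom"]),
                 hill = unname(cf["hill"]),
                 log_ic50 = unname(cf["log_ic50"]),
                 ic50 = 10^unname(cf["log_ic50"]),
                 rss = best$rss, df = n - 4L, n_points = n,
                 fitted = stats::fitted(best$fit), degenerate = FALSE),
            class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  if (x$degenerate) {
    cat("<dose_response_fit> degenerate (constant responses; IC50 unidentifiable)\n")
  } else {
    cat(sprintf(
      "<dose_response_fit> top %.3g, bottom %.3g, hill %.3g, logIC50 %.4g (IC50 %.3g M), RSS %.4g on %d df\n",
      x$top, x$bottom, x$hill, x$log_ic50, x$ic50, x$rss, x$df))
  }
  invisible(x)
}

#' Compare two log IC50 values with the extra sum-of-squares F test
#'
#' Fits the two datasets separately (each with its own four parameters)
#' and jointly with a shared log IC50 (asymptotes and slope still
#' per-dataset), then tests the improvement:
#' `F = ((RSS_shared - RSS_separate) / (df_shared - df_separate)) /
#' (RSS_separate / df_separate)`, with the p-value from the F
#' distribution. Significance cut-off in this field is p < 0.05.
#'
#' @param conc_a,resp_a,conc_b,resp_b the two dose-response datasets.
#' @param n_starts starting points per fit.
#' @return List: `F`, `p_value`, `df_num`, `df_den`, `rss_separate`,
#'   `rss_shared`, `fit_a`, `fit_b`, `log_ic50_shared`.
#' @export
compare_logic50 <- function(conc_a, resp_a, conc_b, resp_b, n_starts = 5) {
  fit_a <- fit_4pl(conc_a, resp_a, n_starts = n_starts)
  fit_b <- fit_4pl(conc_b, resp_b, n_starts = n_starts)
  rss_sep <- fit_a$rss + fit_b$rss
  df_sep <- fit_a$df + fit_b$df
  if (df_sep <= 0) stop("non-positive residual df", call. = FALSE)
  dat <- data.frame(
    x = c(log10(conc_a), log10(conc_b)),
    y = c(resp_a, resp_b),
    g = rep(c(0, 1), c(length(conc_a), length(conc_b))))
  best <- NULL
  for (s in unique(c(fit_a$log_ic50, fit_b$log_ic50,
                     mean(c(fit_a$log_ic50, fit_b$log_ic50))))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ (1 - g) * (bot_a + (top_a - bot_a) /
                         (1 + 10^((lic - x) * hill_a))) +
          g * (bot_b + (top_b - bot_b) / (1 + 10^((lic - x) * hill_b))),
        data = dat,
        start = list(top_a = fit_a$top, bot_a = fit_a$bottom,
                     hill_a = fit_a$hill, top_b = fit_b$top,
                     bot_b = fit_b$bottom, hill_b = fit_b$hill, lic = s),
        control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-10,
                                             ptol = 1e-10)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best))
    stop("shared-IC50 joint fit did not converge", call. = FALSE)
  rss_sh <- max(best$rss, rss_sep)   # nested model cannot beat the full one
  df_sh <- nrow(dat) - 7L
  f_stat <- ((rss_sh - rss_sep) / (df_sh - df_sep)) / (rss_sep / df_sep)
  list(F = f_stat,
       p_value = stats::pf(f_stat, df_sh - df_sep, df_sep,
                           lower.tail = FALSE),
       df_num = df_sh - df_sep, df_den = df_sep,
       rss_separate = rss_sep, rss_shared = rss_sh,
       fit_a = fit_a, fit_b = fit_b,
       log_ic50_shared = unname(stats::coef(best$fit)["lic"]))
}

#' Z-factor screen quality score
#'
#' `1 - (3 * SD(negative) + 3 * SD(positive)) / (mean(negative) -
#' mean(positive))`, using sample standard deviations. Scores above 0.5
#' indicate an excellent assay; overlapping control distributions give
#' negative scores.
#'
#' @param negative,positive control values (>= 2 each).
#' @return The Z-factor.
#' @export
#' @examples
#' z_factor(c(95, 100, 105), c(5, 10, 15))
z_factor <- function(negative, positive) {
  if (length(negative) < 2 || length(positive) < 2)
    stop("need >= 2 values per control group", call. = FALSE)
  denom <- mean(negative) - mean(positive)
  if (denom == 0)
    stop("undefined Z-factor: control means are equal", call. = FALSE)
  1 - (3 * stats::sd(negative) + 3 * stats::sd(positive)) / denom
}

#' Growth-rate (GR) metric
#'
#' Normalizes a treated well's growth to the negative control on the
#' doubling scale: `GR = 2^(log2(fc_treated) / log2(fc_vehicle)) - 1`,
#' where each `fc` is the per-well fold change of the viability metric
#' from T0. GR is 1 when the well grows like the vehicle control, 0 at
#' complete growth arrest, and negative when the well regresses
#' (cytotoxic response).
#'
#' @param fc_treated,fc_vehicle positive fold changes from T0;
#'   `fc_vehicle` must differ from 1 (the control must grow).
#' @return GR value(s); vectorized over `fc_treated`.
#' @export
#' @examples
#' gr_metric(2, 4)   # slowed growth -> between 0 and 1
#' gr_metric(0.5, 4) # regression -> negative
gr_metric <- function(fc_treated, fc_vehicle) {
  if (any(!is.finite(fc_treated) | fc_treated <= 0) ||
      !is.finite(fc_vehicle) || fc_vehicle <= 0)
    stop("fold changes must be positive and finite", call. = FALSE)
  if (fc_vehicle == 1)
    stop("undefined GR: vehicle control has zero net growth (fold change 1)",
         call. = FALSE)
  2^(log2(fc_treated) / log2(fc_vehicle)) - 1
}

#' Normalized drug response (NDR) metric
#'
#' Uses both the negative (vehicle) and positive (maximal-kill) controls
#' to place a treated well's fold change on a common response scale with
#' the anchor values: NDR > 1 proliferative effect; 1 normal growth as in
#' the negative control; 0 complete growth inhibition; -1 complete
#' killing (as in the positive control).
#'
#' With `f = log2` of each fold change, `NDR = f_t / f_v` for growing
#' wells (`f_t >= 0`) and `f_t / |f_p|` for regressing wells
#' (`f_t < 0`) — a piecewise-log form that satisfies every anchor
#' exactly and is strictly increasing in `fc_treated`.
#'
#' @param fc_treated positive fold change(s) of the treated well from T0.
#' @param fc_vehicle vehicle-control fold change, must be > 1 (growing).
#' @param fc_positive positive-control fold change, must be < 1
#'   (declining).
#' @return NDR value(s); vectorized over `fc_treated`.
#' @export
#' @examples
#' ndr_metric(4, 4, 0.25)    # 1: grows like the vehicle control
#' ndr_metric(1, 4, 0.25)    # 0: complete growth inhibition
#' ndr_metric(0.25, 4, 0.25) # -1: complete killing
ndr_metric <- function(fc_treated, fc_vehicle, fc_positive) {
  if (!is.finite(fc_vehicle) || fc_vehicle <= 1)
    stop("negative (vehicle) control must grow: fc_vehicle > 1 required",
         call. = FALSE)
  if (!is.finite(fc_positive) || fc_positive >= 1 || fc_positive <= 0)
    stop("positive control must decline: 0 < fc_positive < 1 required",
         call. = FALSE)
  if (any(!is.finite(fc_treated) | fc_treated <= 0))
    stop("fc_treated must be positive and finite", call. = FALSE)
  f_t <- log2(fc_treated)
  ifelse(f_t >= 0, f_t / log2(fc_vehicle), f_t / abs(log2(fc_positive)))
}

#' Classify a GR/NDR value as a drug-effect category
#'
#' Values near 1 indicate normal growth (as the negative control), values
#' in (0, 1) a cytostatic response, values near 0 complete growth
#' inhibition, negative values a cytotoxic response, and values above 1 a
#' proliferative effect.
#'
#' @param x finite GR or NDR value(s).
#' @param tol half-width of the bands treated as "approximately 1" and
#'   "approximately 0".
#' @return Character vector of classifications.
#' @export
#' @examples
#' classify_response(c(1.2, 1.0, 0.5, 0.02, -0.4))
classify_response <- function(x, tol = 0.05) {
  if (any(!is.finite(x))) stop("inputs must be finite", call. = FALSE)
  vapply(x, function(v) {
    if (abs(v - 1) <= tol) "normal"
    else if (v > 1) "proliferative"
    else if (abs(v) <= tol) "complete growth inhibition"
    else if (v < 0) "cytotoxic"
    else "cytostatic"
  }, character(1))
}

#' Least-squares pairwise regression between two measured parameters
#'
#' Ordinary least squares of `y` on `x`, reporting slope, bias
#' (intercept) and R², plus a summary of the residuals about the line of
#' unity (x = y) used when comparing two measurement modalities.
#'
#' @param x,y paired finite measurements (>= 3 pairs).
#' @return List: `slope`, `bias`, `r_squared`, `unity_rmse`,
#'   `unity_bias` (mean of y - x), `n`.
#' @export
pairwise_regression <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need >= 3 paired finite values", call. = FALSE)
  if (stats::sd(x) == 0) stop("zero variance in x", call. = FALSE)
  fit <- stats::lm(y ~ x)
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((y - mean(y))^2)
  list(slope = unname(stats::coef(fit)[2]),
       bias = unname(stats::coef(fit)[1]),
       r_squared = if (tss == 0) 1 else 1 - rss / tss,
       unity_rmse = sqrt(mean((y - x)^2)),
       unity_bias = mean(y - x),
       n = length(x))
}

#' GR/NDR response table for a plate
#'
#' Combines per-well endpoint fold changes with the plate map: control
#' fold changes are pooled by geometric mean, then each treated well
#' receives its GR, NDR and classification.
#'
#' @param fc per-well fold changes: data frame with `well_id` and `fc`.
#' @param pm a [plate_map()].
#' @param tol classification tolerance, see [classify_response()].
#' @param fc_floor fold changes at or below this value (e.g. a
#'   maximal-kill well whose measured viable area reached 0) are clamped
#'   to it so the log-scale metrics stay defined; complete killing then
#'   maps to the most negative finite response.
#' @return Tibble with one row per treated well: `well_id`, `drug`,
#'   `concentration`, `fc`, `gr`, `ndr`, `classification`, plus the
#'   pooled `fc_vehicle` / `fc_positive` as attributes.
#' @export
response_table <- function(fc, pm, tol = 0.05, fc_floor = 0.01) {
  m <- merge(fc, as.data.frame(pm), by = "well_id")
  m$fc <- pmax(m$fc, fc_floor)
  fc_veh <- geom_mean(m$fc[m$role == "vehicle"])
  fc_pos <- geom_mean(m$fc[m$role == "positive"])
  tr <- m[m$role == "treated", , drop = FALSE]
  gr <- vapply(tr$fc, gr_metric, numeric(1), fc_vehicle = fc_veh)
  ndr <- vapply(tr$fc, ndr_metric, numeric(1), fc_vehicle = fc_veh,
                fc_positive = fc_pos)
  out <- tibble::tibble(well_id = tr$well_id, drug = tr$drug,
                        concentration = tr$concentration, fc = tr$fc,
                        gr = gr, ndr = ndr,
                        classification = classify_response(ndr, tol = tol))
  attr(out, "fc_vehicle") <- fc_veh
  attr(out, "fc_positive") <- fc_pos
  out
}
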