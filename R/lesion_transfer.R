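# Lesion information transfer: per-position deviation of a mismatch
# ensemble from a control ensemble, with autocorrelation-corrected standard
# errors, empirical tail probabilities against the control distribution, and
# Welch mean-difference tests on effective sample sizes.

# Integrated autocorrelation time by the initial-positive-sequence rule:
# tau = 1 + 2 * sum of autocorrelations up to the first non-positive lag.
# Effective sample size n/tau, floored at 2.
.ess <- function(x, max_lag = NULL) {
  n <- length(x)
  if (n < 3L || stats::sd(x) == 0) return(list(tau = 1, n_eff = n))
  if (is.null(max_lag)) max_lag <- min(n - 1L, max(10L, floor(10 * log10(n))))
  rho <- stats::acf(x, lag.max = max_lag, plot = FALSE,
                    demean = TRUE)$acf[-1L]
  pos <- which(rho <= 0)
  keep <- if (length(pos)) seq_len(pos[1L] - 1L) else seq_along(rho)
  tau <- max(1, 1 + 2 * sum(rho[keep]))
  list(tau = tau, n_eff = max(2, n / tau))
}

#' Tail probability and mean-difference test
#'
#' Given samples from a mismatch ensemble and a control ensemble for one
#' (position, parameter) cell, returns the empirical two-sided tail
#' probability — the fraction of control samples deviating from the control
#' mean by at least the observed |mean difference| — and a Welch two-sample
#' p-value computed on autocorrelation-corrected effective sample sizes.
#'
#' @param mm,control numeric sample vectors (n >= 30 each).
#' @param correct_autocorr use effective sample sizes (default TRUE; with
#'   independent frames the correction is neutral).
#' @return list: \code{delta} (mean difference mm - control),
#'   \code{tail_probability}, \code{p_value}, \code{se} (corrected SE of the
#'   difference), \code{n_eff_mm}, \code{n_eff_control}.
#' @export
significance_assessment <- function(mm, control, correct_autocorr = TRUE) {
  if (length(mm) < 30L || length(control) < 30L) stop("need n >= 30 per sample")
  if (stats::sd(control) == 0) stop("degenerate (constant) control sample")
  delta <- mean(mm) - mean(control)
  tail_probability <- mean(abs(control - mean(control)) >= abs(delta))
  e_m <- if (correct_autocorr) .ess(mm) else list(n_eff = length(mm))
  e_c <- if (correct_autocorr) .ess(control) else list(n_eff = length(control))
  v_m <- stats::var(mm) / e_m$n_eff
  v_c <- stats::var(control) / e_c$n_eff
  se <- sqrt(v_m + v_c)
  t_stat <- delta / se
  df <- (v_m + v_c)^2 / (v_m^2 / (e_m$n_eff - 1) + v_c^2 / (e_c$n_eff - 1))
  p_value <- 2 * stats::pt(-abs(t_stat), df)
  list(delta = delta, tail_probability = tail_probability, p_value = p_value,
       se = se, t = t_stat, df = df,
       n_eff_mm = e_m$n_eff, n_eff_control = e_c$n_eff)
}

#' Lesion-transfer deviation profile
#'
#' Per (position, parameter) comparison of a mismatch ensemble against a
#' control ensemble on a shared grid: means, the absolute deviation of the
#' means, SDs, naive and autocorrelation-corrected SEs, the empirical tail
#' probability and the Welch p-value. Positions are relative coordinates
#' with the lesion at 0; translational and rotational parameters carry a
#' \code{units} column so they can be displayed separately.
#'
#' @param mm,control tidy series data frames with columns \code{frame},
#'   \code{position}, \code{parameter}, \code{value} (e.g. the \code{inter}
#'   or \code{intra} element of \code{\link{analyze_trajectory}}).
#' @param correct_autocorr forwarded to
#'   \code{\link{significance_assessment}}.
#' @return data frame of class \code{transfer_profile}: one row per cell
#'   with \code{mean_mm}, \code{mean_control}, \code{abs_deviation},
#'   \code{sd_mm}, \code{sd_control}, \code{se_mm}, \code{se_naive_mm},
#'   \code{tail_probability}, \code{p_value}.
#' @export
deviation_profile <- function(mm, control, correct_autocorr = TRUE) {
  need <- c("frame", "position", "parameter", "value")
  if (!all(need %in% names(mm)) || !all(need %in% names(control)))
    stop("series need columns frame, position, parameter, value")
  grid_m <- unique(mm[, c("position", "parameter")])
  grid_c <- unique(control[, c("position", "parameter")])
  gm <- paste(grid_m$position, grid_m$parameter)
  gc_ <- paste(grid_c$position, grid_c$parameter)
  if (!setequal(gm, gc_)) stop("mismatch and control grids differ")
  grid <- grid_m[order(grid_m$parameter, grid_m$position), ]
  trans_params <- c("shear", "stretch", "stagger", "shift", "slide", "rise")
  rows <- vector("list", nrow(grid))
  key_m <- paste(mm$position, mm$parameter)
  key_c <- paste(control$position, control$parameter)
  for (i in seq_len(nrow(grid))) {
    k <- paste(grid$position[i], grid$parameter[i])
    xm <- mm$value[key_m == k]
    xc <- control$value[key_c == k]
    sig <- significance_assessment(xm, xc, correct_autocorr = correct_autocorr)
    rows[[i]] <- data.frame(
      position = grid$position[i], parameter = grid$parameter[i],
      units = if (grid$parameter[i] %in% trans_params) "A" else "deg",
      mean_mm = mean(xm), mean_control = mean(xc),
      abs_deviation = abs(sig$delta),
      sd_mm = stats::sd(xm), sd_control = stats::sd(xc),
      se_mm = stats::sd(xm) / sqrt(sig$n_eff_mm),
      se_naive_mm = stats::sd(xm) / sqrt(length(xm)),
      se_delta = sig$se,
      tail_probability = sig$tail_probability, p_value = sig$p_value,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("transfer_profile", "data.frame")
  out
}

#' Flag significantly perturbed cells and report the transfer range
#'
#' A cell is flagged when its empirical tail probability is at most
#' \code{alpha} and its mean-difference p-value is at most \code{alpha_t}.
#' The transfer range is the maximum |position| among flagged cells.
#'
#' @param profile a \code{transfer_profile}.
#' @param alpha tail-probability level (default 0.05).
#' @param alpha_t mean-difference test level (default 0.01).
#' @param adjust p-value adjustment across cells: "none" (default; per-cell
#'   tests) or "BH" (Benjamini-Hochberg).
#' @return list with the flagged \code{profile} (added columns
#'   \code{tail_flag}, \code{p_flag}, \code{flagged}), \code{flagged_cells}
#'   and \code{range} (0 when nothing is flagged).
#' @export
transfer_range <- function(profile, alpha = 0.05, alpha_t = 0.01,
                           adjust = c("none", "BH")) {
  stopifnot(inherits(profile, "transfer_profile"))
  if (nrow(profile) == 0L) stop("empty profile")
  adjust <- match.arg(adjust)
  p <- if (adjust == "BH") stats::p.adjust(profile$p_value, "BH")
  else profile$p_value
  profile$p_adjusted <- p
  profile$tail_flag <- profile$tail_probability <= alpha
  profile$p_flag <- p <= alpha_t
  profile$flagged <- profile$tail_flag & profile$p_flag
  fl <- profile[profile$flagged, c("position", "parameter", "abs_deviation",
                                   "tail_probability", "p_value")]
  list(profile = profile, flagged_cells = fl,
       range = if (nrow(fl)) max(abs(fl$position)) else 0L)
}
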